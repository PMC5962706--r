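# Independent brute-force oracles. These deliberately share no code with the
# package: plain loops and base R only, so agreement is evidence, not echo.

# BH step-up computed literally from its definition
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  sorted <- p[ord]
  q <- sorted * m / seq_len(m)
  # enforce monotonicity from the largest rank down
  if (m >= 2) {
    for (i in (m - 1):1) {
      q[i] <- min(q[i], q[i + 1])
    }
  }
  q <- pmin(q, 1)
  out <- numeric(m)
  out[ord] <- q
  out
}

# one-sided / two-sided Welch or pooled t via stats::t.test
oracle_t <- function(x, y, alternative = "greater", var_equal = FALSE) {
  tt <- t.test(x, y, alternative = alternative, var.equal = var_equal)
  list(t = unname(tt$statistic), df = unname(tt$parameter), p = tt$p.value)
}

# CH index by a different decomposition: total sum of squares minus within
oracle_ch <- function(m, labels) {
  n <- nrow(m)
  k <- length(unique(labels))
  tot <- sum(sweep(m, 2, colMeans(m))^2)
  w <- 0
  for (lab in unique(labels)) {
    sub <- m[labels == lab, , drop = FALSE]
    w <- w + sum(sweep(sub, 2, colMeans(sub))^2)
  }
  b <- tot - w
  (b / (k - 1)) / (w / (n - k))
}

# O(n^3) complete-linkage agglomeration; returns merge heights in order
oracle_complete_linkage_heights <- function(m) {
  clusters <- as.list(seq_len(nrow(m)))
  d <- as.matrix(dist(m))
  heights <- numeric(0)
  while (length(clusters) > 1) {
    best <- Inf
    bi <- bj <- NA
    for (i in seq_along(clusters)) {
      for (j in seq_along(clusters)) {
        if (i < j) {
          h <- max(d[clusters[[i]], clusters[[j]]])
          if (h < best) {
            best <- h
            bi <- i
            bj <- j
          }
        }
      }
    }
    heights <- c(heights, best)
    clusters[[bi]] <- c(clusters[[bi]], clusters[[bj]])
    clusters[[bj]] <- NULL
  }
  heights
}

# prevalence by explicit set operations on a probe x sample logical matrix
oracle_prevalence <- function(det, probe_orgs, rule) {
  n <- ncol(det)
  out <- list()
  for (org in unique(probe_orgs)) {
    rows <- which(probe_orgs == org)
    if (rule == "union") {
      hit_samples <- unique(unlist(lapply(rows, function(r) which(det[r, ]))))
      out[[org]] <- 100 * length(hit_samples) / n
    } else {
      out[[org]] <- 100 * max(vapply(rows, function(r) sum(det[r, ]), numeric(1))) / n
    }
  }
  out
}

# Venn membership by direct subset testing
oracle_partition <- function(sets) {
  orgs <- sort(unique(unlist(sets)))
  sapply(orgs, function(o) {
    paste(names(sets)[vapply(sets, function(s) o %in% s, logical(1))],
      collapse = "+"
    )
  })
}
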