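# Independent naive reference implementations used as oracles. These are kept
# deliberately separate from the package code paths: plain loops and textbook
# formulas only.

naive_r2 <- function(t, p) {
  mt <- mean(t); mp <- mean(p)
  num <- 0; dt <- 0; dp <- 0
  for (i in seq_along(t)) {
    num <- num + (t[i] - mt) * (p[i] - mp)
    dt <- dt + (t[i] - mt)^2
    dp <- dp + (p[i] - mp)^2
  }
  (num / sqrt(dt * dp))^2
}

naive_rmse <- function(t, p) {
  s <- 0
  for (i in seq_along(t)) s <- s + (t[i] - p[i])^2
  sqrt(s / length(t))
}

naive_q2 <- function(t, p) {
  press <- 0; tss <- 0; mt <- mean(t)
  for (i in seq_along(t)) {
    press <- press + (t[i] - p[i])^2
    tss <- tss + (t[i] - mt)^2
  }
  1 - press / tss
}

naive_recalls <- function(t, p) {
  out <- c()
  for (cl in sort(unique(t))) {
    hit <- 0; tot <- 0
    for (i in seq_along(t)) {
      if (t[i] == cl) {
        tot <- tot + 1
        if (p[i] == cl) hit <- hit + 1
      }
    }
    out[cl] <- hit / tot
  }
  out
}

naive_balanced_accuracy <- function(t, p) mean(naive_recalls(t, p))

# elementwise loop versions of the four mixture-descriptor schemes
naive_scheme <- function(scheme, D1, D2, x1 = NULL) {
  m <- length(D1)
  if (scheme == "average") {
    out <- numeric(m)
    for (i in 1:m) out[i] <- (D1[i] + D2[i]) / 2
    out
  } else if (scheme == "sum_absdiff") {
    out <- numeric(2 * m)
    for (i in 1:m) {
      out[i] <- D1[i] + D2[i]
      out[m + i] <- abs(D1[i] - D2[i])
    }
    out
  } else if (scheme == "weighted_sum") {
    out <- numeric(m)
    for (i in 1:m) out[i] <- x1 * D1[i] + (1 - x1) * D2[i]
    out
  } else {
    out <- numeric(2 * m)
    for (i in 1:m) {
      out[i] <- x1 * D1[i] + (1 - x1) * D2[i]
      out[m + i] <- abs(x1 * D1[i] - (1 - x1) * D2[i])
    }
    out
  }
}
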