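# Independent brute-force reference implementations used as oracles.
# These deliberately use naive loops / direct formula transcription and
# share no code with the package internals.

oracle_sampen <- function(x, m, r) {
  n <- length(x)
  nt <- n - m # Richman-Moorman: same template count at both lengths
  count_m <- function(mm) {
    cnt <- 0L
    for (i in seq_len(nt)) {
      for (j in seq_len(nt)) {
        if (i == j) next
        d <- 0
        for (k in 0:(mm - 1)) d <- max(d, abs(x[i + k] - x[j + k]))
        if (d <= r) cnt <- cnt + 1L
      }
    }
    cnt / 2
  }
  b <- count_m(m)
  a <- count_m(m + 1)
  if (b == 0 || a == 0) return(NA_real_)
  -log(a / b)
}

oracle_permutation_entropy <- function(x, m) {
  pats <- character(0)
  for (i in seq_len(length(x) - m + 1)) {
    w <- x[i:(i + m - 1)]
    pats <- c(pats, paste(order(w, method = "radix"), collapse = "-"))
  }
  tab <- table(pats)
  p <- as.numeric(tab) / sum(tab)
  -sum(p * log(p))
}

oracle_shannon_entropy <- function(x, bins) {
  if (min(x) == max(x)) return(0)
  br <- seq(min(x), max(x), length.out = bins + 1)
  cnt <- hist(x, breaks = br, plot = FALSE)$counts
  p <- cnt[cnt > 0] / length(x)
  (-sum(p * log2(p))) / log2(bins)
}

oracle_tpr <- function(x) {
  n <- length(x)
  cnt <- 0L
  for (i in 2:(n - 1)) {
    if ((x[i] - x[i - 1]) * (x[i] - x[i + 1]) > 0) cnt <- cnt + 1L
  }
  cnt / n
}

oracle_poincare <- function(x) {
  n <- length(x)
  m <- mean(x)
  s1 <- 0
  s2 <- 0
  for (i in 1:(n - 1)) {
    s1 <- s1 + (x[i + 1] - x[i])^2 / 2
    s2 <- s2 + (x[i + 1] + x[i] - 2 * m)^2 / 2
  }
  list(Sd1 = sqrt(s1 / (n - 1)), Sd2 = sqrt(s2 / (n - 1)))
}

oracle_kappa <- function(cm) {
  cm <- unclass(cm)
  M <- sum(cm)
  po <- sum(diag(cm)) / M
  pe <- sum(rowSums(cm) * colSums(cm)) / M / M
  (po - pe) / (1 - pe)
}

# generic direct-form IIR filtering of the rational transfer function
oracle_iir <- function(b, a, x) {
  as.numeric(signal::filter(b, a, x))
}

# polynomial evaluation of the transfer function on the unit circle
oracle_response <- function(b, a, f, fs) {
  w <- 2 * pi * f / fs
  zb <- vapply(w, function(wi) sum(b * exp(-1i * wi * (seq_along(b) - 1))), complex(1))
  za <- vapply(w, function(wi) sum(a * exp(-1i * wi * (seq_along(a) - 1))), complex(1))
  zb / za
}

# small labeled Gaussian-blob dataset for classifier tests
make_blobs <- function(n_per = 50, k = 3, sep = 6, p = 2, seed = 1) {
  set.seed(seed)
  X <- do.call(rbind, lapply(seq_len(k), function(cl) {
    matrix(rnorm(n_per * p, mean = cl * sep), n_per, p)
  }))
  df <- as.data.frame(X)
  names(df) <- paste0("f", seq_len(p))
  df$label <- factor(rep(seq_len(k), each = n_per))
  tibble::as_tibble(df)
}

unwrap_phase <- function(ph) {
  for (i in 2:length(ph)) {
    while (ph[i] - ph[i - 1] > pi) ph[i] <- ph[i] - 2 * pi
    while (ph[i] - ph[i - 1] < -pi) ph[i] <- ph[i] + 2 * pi
  }
  ph
}
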