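# construct a window_series directly from an SMA vector
make_ws <- function(sma, excluded = rep(FALSE, length(sma)), window_s = 5) {
  ws <- data.frame(
    window_start_s = (seq_along(sma) - 1) * window_s,
    sma_g = sma, excluded = excluded
  )
  attr(ws, "window_s") <- window_s
  attr(ws, "sample_rate_hz") <- 10
  class(ws) <- c("window_series", "data.frame")
  ws
}

# independent exhaustive-scan oracle for bout detection: walks the windows
# one by one, opening a run on an active window and closing it on anything else
bout_oracle <- function(sma, excluded, threshold = 0.135, window_s = 5) {
  out <- data.frame(start = integer(0), len = integer(0), intensity = numeric(0))
  i <- 1
  n <- length(sma)
  while (i <= n) {
    if (!excluded[i] && sma[i] >= threshold) {
      j <- i
      while (j + 1 <= n && !excluded[j + 1] && sma[j + 1] >= threshold) j <- j + 1
      out <- rbind(out, data.frame(
        start = i, len = j - i + 1, intensity = mean(sma[i:j])
      ))
      i <- j + 1
    } else {
      i <- i + 1
    }
  }
  out
}

# small clustered regression problem with known structure
make_lmm_data <- function(seed, n_pat = 30, per = 2, p = 5,
                          beta = c(1.5, -1, rep(0, 3)),
                          sigma_b = 2, sigma_e = 1.5) {
  set.seed(seed)
  n <- n_pat * per
  cl <- rep(sprintf("P%02d", seq_len(n_pat)), each = per)
  x <- matrix(stats::rnorm(n * p), n, p,
    dimnames = list(NULL, paste0("v", seq_len(p)))
  )
  u <- stats::rnorm(n_pat, 0, sigma_b)[rep(seq_len(n_pat), each = per)]
  y <- 2 + drop(x %*% beta) + u + stats::rnorm(n, 0, sigma_e)
  list(x = x, y = y, cluster = cl, beta = beta)
}

# lme4 oracle fit on a make_lmm_data() problem (formula needs real columns)
lmer_oracle <- function(d, intercept_only = FALSE) {
  df <- data.frame(y = d$y, d$x, cluster = d$cluster)
  fml <- if (intercept_only) {
    y ~ 1 + (1 | cluster)
  } else {
    stats::as.formula(paste(
      "y ~", paste(colnames(d$x), collapse = " + "), "+ (1 | cluster)"
    ))
  }
  lme4::lmer(fml, data = df, REML = FALSE)
}
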