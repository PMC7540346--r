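# Independent oracles and fixture generators used across the test files.

# Exact-enough TV denoising oracle, independent of the package's direct
# algorithm: accelerated projected gradient (FISTA) on the dual problem
#   min_z 0.5 ||y - D^T z||^2  s.t.  ||z||_inf <= lam.
tv_oracle <- function(y, lam, iters = 8000) {
  n <- length(y)
  if (n < 2L || lam <= 0) return(y)
  D <- diff(diag(n))
  z <- numeric(n - 1L); zy <- z; t <- 1
  for (k in seq_len(iters)) {
    g <- -D %*% (y - crossprod(D, zy))
    znew <- pmin(lam, pmax(-lam, zy - 0.25 * g))
    tn <- (1 + sqrt(1 + 4 * t^2)) / 2
    zy <- znew + ((t - 1) / tn) * (znew - z)
    z <- znew; t <- tn
  }
  as.vector(y - crossprod(D, z))
}

# Synthetic channel on the package's generative model: sparse bipolar
# spikes + low-frequency baseline (+ optional white noise at a given SNR).
gen_channel <- function(seed, n = 1019, n_spikes = 8, snr_db = NULL) {
  set.seed(seed)
  u <- numeric(n)
  margin <- max(5L, round(n * 0.1))
  for (k in sample(seq(margin, n - margin), n_spikes)) {
    a <- runif(1, 0.4, 1)
    u[k] <- a
    u[min(n, k + 2)] <- -a
  }
  low <- 0.4 * sin(2 * pi * seq_len(n) / n * 3 + runif(1, 0, 6))
  clean <- u + low
  noisy <- clean
  if (!is.null(snr_db)) {
    sigma <- sqrt(mean(clean^2) * 10^(-snr_db / 10))
    noisy <- clean + rnorm(n, sd = sigma)
  }
  list(clean = clean, noisy = noisy, sparse = u, low = low)
}

# Dense reference high-pass operator built independently of the package's
# banded path: base-R difference/sum matrices and a dense solve.
dense_highpass_matrix <- function(n, fc, d) {
  D <- diff(diag(n))
  S <- abs(D)
  B1 <- crossprod(D); C1 <- crossprod(S)
  B <- diag(n); C <- diag(n)
  for (i in seq_len(d)) { B <- B %*% B1; C <- C %*% C1 }
  A <- B + tan(pi * fc)^(2 * d) * C
  solve(A, B)
}

# Connected-component count and centroids for a binary image (4-neighbour
# flood fill; small images only).
label_components <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (s in which(mask)) {
    if (lab[s] != 0L) next
    cur <- cur + 1L
    queue <- s
    while (length(queue) > 0L) {
      p <- queue[[1L]]; queue <- queue[-1L]
      if (lab[p] != 0L || !mask[p]) next
      lab[p] <- cur
      i <- (p - 1L) %% nrow(mask) + 1L
      j <- (p - 1L) %/% nrow(mask) + 1L
      nb <- c(if (i > 1L) p - 1L, if (i < nrow(mask)) p + 1L,
              if (j > 1L) p - nrow(mask), if (j < ncol(mask)) p + nrow(mask))
      queue <- c(queue, nb[lab[nb] == 0L & mask[nb]])
    }
  }
  cents <- NULL
  if (cur > 0L) {
    cents <- t(vapply(seq_len(cur), function(k) {
      idx <- which(lab == k, arr.ind = TRUE)
      colMeans(idx)
    }, numeric(2)))
  }
  list(n = cur, centroids = cents)
}

# A few cheap coordinate-descent passes to polish a candidate for the
# randomized solver lower-bound check.
cd_polish <- function(x, u, cfg, passes = 3, step = 0.05) {
  best <- lpfsc_cost(x, u, cfg)
  for (p in seq_len(passes)) {
    for (i in seq_along(u)) {
      for (delta in c(-step, step, -u[i])) {
        cand <- u; cand[i] <- cand[i] + delta
        cc <- lpfsc_cost(x, cand, cfg)
        if (cc < best) { best <- cc; u <- cand }
      }
    }
  }
  list(u = u, cost = best)
}
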