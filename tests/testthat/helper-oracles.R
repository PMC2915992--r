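# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own computational paths.

# exhaustive single-change-point maximum-likelihood scan: the breakpoint
# position m (1..M-1) minimizing the two-segment residual sum of squares
# (ties -> leftmost)
scan_oracle <- function(y) {
  M <- length(y)
  rss <- vapply(seq_len(M - 1), function(m) {
    a <- y[1:m]; b <- y[(m + 1):M]
    sum((a - mean(a))^2) + sum((b - mean(b))^2)
  }, numeric(1))
  which.min(rss)
}

# literal correspondence analysis of an indicator matrix: eigenvalues and
# row principal coordinates via an eigendecomposition of S'S (not svd)
ca_oracle <- function(Z) {
  P <- Z / sum(Z)
  r <- rowSums(P)
  cm <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - outer(r, cm)) %*% diag(1 / sqrt(cm))
  e <- eigen(t(S) %*% S, symmetric = TRUE)
  keep <- e$values > 1e-10
  V <- e$vectors[, keep, drop = FALSE]
  list(eigenvalues = e$values[keep],
       row_scores = diag(1 / sqrt(r)) %*% S %*% V)
}

# full disjunctive coding over observed levels, mirroring the definition
# (kept separate from the package internals)
indicator_oracle <- function(v) {
  do.call(cbind, lapply(seq_len(ncol(v)), function(j) {
    levs <- sort(unique(v[, j]))
    sapply(levs, function(l) as.numeric(v[, j] == l))
  }))
}

# two-level step signal
make_signal <- function(y, sample_id = "s1", chromosome = "1") {
  probe_signal(sample_id, chromosome, paste0("p", seq_along(y)),
               seq_along(y) * 1000, y)
}

# tiny three-population CNV matrix with one perfectly discriminating
# variable and noise variables
make_toy_matrix <- function(n_per = 4, n_noise = 3, seed = 42) {
  set.seed(seed)
  n <- 3 * n_per
  disc <- rep(c(-1L, 0L, 1L), each = n_per)
  noise <- matrix(sample(c(-1L, 0L, 1L), n * n_noise, replace = TRUE),
                  n, n_noise)
  v <- cbind(disc, noise)
  colnames(v) <- c("disc", paste0("n", seq_len(n_noise)))
  rownames(v) <- sprintf("S%02d", seq_len(n))
  v
}

# align signs of score matrices before comparison (axes are defined up
# to reflection)
align_signs <- function(a, b) {
  for (j in seq_len(ncol(a)))
    if (sum(a[, j] * b[, j]) < 0) b[, j] <- -b[, j]
  b
}
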