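# MCA, MCDA, Eq-style variable ranking and the permutation test

test_that("mca matches a brute-force indicator CA on small toys", {
  set.seed(401)
  for (r in 1:5) {
    v <- matrix(sample(c(-1L, 0L, 1L), 8 * 4, replace = TRUE), 8, 4)
    # guard against constant columns (dropped by mca by design)
    keep <- apply(v, 2, function(col) length(unique(col)) > 1)
    v <- v[, keep, drop = FALSE]
    if (ncol(v) < 2) next
    m <- mca(v, n_axes = 3)
    oracle <- ca_oracle(indicator_oracle(v))
    k <- min(length(m$eigenvalues), length(oracle$eigenvalues))
    expect_equal(m$eigenvalues[1:k], oracle$eigenvalues[1:k],
                 tolerance = 1e-10)
    ka <- min(ncol(m$all_scores), ncol(oracle$row_scores), 3)
    # compare retained axes up to sign (skip near-degenerate pairs)
    ev <- m$eigenvalues
    for (j in seq_len(ka)) {
      if (j > 1 && abs(ev[j] - ev[j - 1]) < 1e-8) next
      if (j < length(ev) && abs(ev[j + 1] - ev[j]) < 1e-8) next
      a <- m$all_scores[, j]; b <- oracle$row_scores[, j]
      if (sum(a * b) < 0) b <- -b
      expect_equal(unname(a), unname(b), tolerance = 1e-8)
    }
  }
})

test_that("one binary variable yields two pure score groups", {
  v <- cbind(g = rep(c(0L, 1L), each = 5),
             h = rep(c(0L, 1L), each = 5))
  m <- mca(v)
  s1 <- m$scores[, 1]
  expect_equal(length(unique(round(s1, 10))), 2)
  expect_true(max(s1[1:5]) < min(s1[6:10]) ||
                min(s1[1:5]) > max(s1[6:10]))
  # scores are centered with non-negative eigenvalues
  expect_true(all(m$eigenvalues >= 0))
  expect_lt(abs(mean(s1)), 1e-10)
})

test_that("distributional equivalence: duplication invariances", {
  v <- make_toy_matrix()
  m1 <- mca(v, n_axes = 2)
  # duplicating every variable (same conditional profiles, same relative
  # masses) leaves eigenvalues and subject scores exactly unchanged
  m2 <- mca(cbind(v, v), n_axes = 2)
  expect_equal(m1$eigenvalues[1:4], m2$eigenvalues[1:4],
               tolerance = 1e-10)
  s2 <- align_signs(m1$scores, m2$scores)
  expect_equal(unname(m1$scores), unname(s2), tolerance = 1e-10)
  # duplicating a single variable re-weights it: scores move only
  # slightly (this is why block reduction keeps one representative)
  m3 <- mca(cbind(v, dup = v[, 1]), n_axes = 2)
  expect_gt(abs(cor(m1$scores[, 1], m3$scores[, 1])), 0.95)
})

test_that("mca input validation", {
  expect_error(mca(matrix(0L, 5, 3)), "constant")
  expect_error(mca(matrix(c(0L, 1L), 1, 2)), "2 subjects")
})

test_that("mcda separates labeled groups and caps directions at l-1", {
  v <- make_toy_matrix(n_per = 5)
  labels <- rep(c("A", "B", "C"), each = 5)
  fit <- mcda(v, labels, n_axes = 2)
  expect_lte(ncol(fit$centroids), 2)
  # between-class variance non-increasing across directions
  expect_true(all(diff(fit$between_var) <= 1e-12))

  # two classes perfectly separated by one variable
  v2 <- cbind(d = rep(c(0L, 1L), each = 6),
              n = rep(c(0L, 1L, 1L, 0L), 3))
  lab2 <- rep(c("x", "y"), each = 6)
  f2 <- mcda(v2, lab2, n_axes = 2)
  expect_equal(ncol(f2$centroids), 1)
  sc <- f2$subject_scores[, 1]
  expect_lt(max(abs(sc[1:6] - mean(sc[1:6]))), 1e-8)

  expect_error(mcda(v, rep("A", 15)), "2 classes")
  expect_error(mcda(v, c("A", rep("B", 14))), "at least 2 subjects")
})

test_that("rank_variables matches direct evaluation of the correlation", {
  v <- make_toy_matrix(n_per = 4)
  labels <- rep(c("A", "B", "C"), each = 4)
  fit <- mcda(v, labels, n_axes = 2)
  rk <- rank_variables(fit, v)
  # brute-force: class-aggregated indicator, unweighted class mean
  Z <- indicator_oracle(v)
  agg <- rbind(colMeans(Z[1:4, ]), colMeans(Z[5:8, ]), colMeans(Z[9:12, ]))
  V <- fit$centroids
  for (j in seq_len(ncol(Z))) {
    xc <- agg[, j] - mean(agg[, j])
    best <- 0
    for (lam in seq_len(ncol(V))) {
      den <- sqrt(sum(V[, lam]^2) * sum(xc^2))
      rho <- if (den > 0) sum(V[, lam] * xc) / den else 0
      best <- max(best, abs(rho))
    }
    expect_equal(rk$levels$max_abs_rho[j], best, tolerance = 1e-10)
  }
  expect_true(all(abs(rk$levels$max_abs_rho) <= 1))
  # the perfect discriminator tops the ranking
  expect_equal(which.max(rk$variables$rank_score),
               which(rk$variables$variable == "disc"))
})

# a class-determined variable against class-balanced noise: the noise
# aggregates are identical in every class, so the between-class geometry
# is rank 1 and exactly aligned with the variable's aggregated profile.
# Class-balance of the noise is destroyed by almost every permutation,
# which keeps permuted correlations strictly below 1.
balanced_toy <- function() {
  labels <- rep(c("A", "B", "C", "D"), each = 5)
  disc <- as.integer(labels == "A")
  mk <- function(counts, seed) {
    set.seed(seed)
    unlist(lapply(1:4, function(i) sample(rep(c(-1L, 0L, 1L), counts))))
  }
  v <- cbind(disc = disc, n1 = mk(c(2, 2, 1), 1),
             n2 = mk(c(1, 2, 2), 2), n3 = mk(c(2, 1, 2), 3))
  rownames(v) <- sprintf("S%02d", seq_along(labels))
  list(v = v, labels = labels)
}

test_that("an aligned perfect discriminator attains |rho| = 1", {
  tt <- balanced_toy()
  fit <- mcda(tt$v, tt$labels, n_axes = 8)
  rk <- rank_variables(fit, tt$v)
  expect_equal(rk$variables$rank_score[rk$variables$variable == "disc"],
               1, tolerance = 1e-10)
  # class-balanced variables carry no between-class signal
  expect_equal(rk$variables$rank_score[rk$variables$variable == "n1"],
               0, tolerance = 1e-10)
})

test_that("variables constant across classes get rho = 0", {
  # a variable varying within but not between classes
  v <- cbind(d = rep(c(0L, 1L), each = 6),
             flat = rep(c(0L, 1L), 6))
  lab <- rep(c("x", "y"), each = 6)
  rk <- rank_variables(mcda(v, lab, n_axes = 2), v)
  expect_equal(rk$variables$rank_score[rk$variables$variable == "flat"], 0,
               tolerance = 1e-10)
})

test_that("selected high-rho variables preserve the cluster structure", {
  set.seed(402)
  # three populations, 6 informative variables among 30
  n_per <- 10
  labels <- rep(c("P1", "P2", "P3"), each = n_per)
  v <- matrix(sample(c(-1L, 0L, 1L), 30 * 30, replace = TRUE,
                     prob = c(0.1, 0.8, 0.1)), 30, 30)
  for (j in 1:6) {
    lev <- c(-1L, 0L, 1L)[(j %% 3) + 1]
    pop <- (j %% 3) + 1
    carrier <- labels == paste0("P", pop)
    v[carrier, j] <- lev
    v[!carrier, j] <- if (lev == 0L) 1L else 0L
  }
  colnames(v) <- paste0("b", 1:30)
  fit <- mcda(v, labels, n_axes = 2)
  rk <- rank_variables(fit, v)
  sel <- rk$variables$variable[rk$variables$rank_score > 0.5]
  expect_true(all(paste0("b", 1:6) %in% sel))
  m_sel <- mca(v[, sel, drop = FALSE], n_axes = 2)
  # cluster assignment by nearest class centroid on the selected-variable
  # MCA reproduces the labels
  cent <- apply(m_sel$scores, 2, function(s) tapply(s, labels, mean))
  d2 <- as.matrix(dist(rbind(cent, m_sel$scores)))[-(1:3), 1:3]
  assigned <- rownames(cent)[apply(d2, 1, which.min)]
  expect_gte(mean(assigned == labels), 0.9)
})

test_that("permutation test attains the lower bound and is reproducible", {
  tt <- balanced_toy()
  p1 <- permutation_test(tt$v, tt$labels, n_perm = 99, seed = 7, n_axes = 8)
  p2 <- permutation_test(tt$v, tt$labels, n_perm = 99, seed = 7, n_axes = 8)
  expect_identical(p1, p2)
  # the aligned perfect discriminator reaches the attainable minimum
  expect_equal(p1$p_value[p1$variable == "disc"], 1 / 100)
  expect_true(all(p1$p_value >= 1 / 100 & p1$p_value <= 1))
})
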