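# profile/cohort simulators and the FDR calibration harness

test_that("simulate_profile is reproducible and honors its truth model", {
  a <- simulate_profile(n_probes = 2000, seed = 9)
  b <- simulate_profile(n_probes = 2000, seed = 9)
  expect_identical(a$signal$y, b$signal$y)
  expect_identical(a$truth, b$truth)
  d <- simulate_profile(n_probes = 2000, seed = 10)
  expect_false(identical(a$signal$y, d$signal$y))
  # truth is piecewise constant and consistent with the breakpoint list
  expect_equal(a$true_breakpoints, which(diff(a$truth) != 0))
  expect_true(all(a$truth %in% c(-1L, 0L, 1L)))
  # defaults are the single-copy levels log2(3/2), log2(1/2)
  expect_true(all(a$true_amplitudes %in% c(0, log2(3 / 2), log2(1 / 2))))
  # y = amplitudes + noise with the stated sd (rough check)
  expect_lt(abs(sd(a$signal$y - a$true_amplitudes) - 0.2), 0.02)
})

test_that("noiseless profiles are recovered exactly", {
  sp <- simulate_profile(n_probes = 1500, sigma = 0, seed = 21,
                         neutral_len = c(100, 300),
                         altered_len = c(10, 40))
  fit <- sbl_fit(sp$signal, a = 0.5, sigma2_init = 1e-6)
  rk <- backward_eliminate(sp$signal, fit, min_seg_len = 3)
  seg <- classify_segments(apply_threshold(rk, 4, sp$signal), T = 4,
                           baseline = 0)
  expect_equal(survivors_at(rk, 4), sp$true_breakpoints)
  st <- rep(c(Loss = -1L, Neutral = 0L, Gain = 1L)[seg$segments$state],
            seg$segments$n_probes)
  expect_equal(unname(st), sp$truth)
  # amplitudes exact
  expect_equal(seg$segments$amplitude,
               unique_rle <- rle(sp$true_amplitudes)$values)
})

test_that("fdr_curve pools counts and reports NA when nothing is called", {
  cfg <- list(n_probes = 800, neutral_len = c(80, 150),
              altered_len = c(10, 30), sigma = 0.2)
  tab <- fdr_curve(cfg, a = 0.3, T_grid = c(4, 1e9),
                   min_seg_len_grid = 3, n_reps = 3, seed = 31)
  expect_equal(nrow(tab), 2)
  big <- tab[tab$T == 1e9, ]
  expect_equal(big$called, 0)
  expect_true(is.na(big$fdr))
  expect_equal(big$sensitivity, 0)
  ok <- tab[tab$T == 4, ]
  expect_gt(ok$sensitivity, 0.5)
})

test_that("fdr decreases in T and min_seg_len; vanishes without noise", {
  cfg <- list(n_probes = 2000, neutral_len = c(100, 300),
              altered_len = c(5, 30), sigma = 0.25)
  tab <- fdr_curve(cfg, a = 0.2, T_grid = c(3, 5, 8),
                   min_seg_len_grid = c(1, 5), n_reps = 8, seed = 32)
  for (L in unique(tab$min_seg_len)) {
    f <- tab$fdr[tab$min_seg_len == L]
    expect_true(all(diff(f[!is.na(f)]) <= 0.02))
  }
  # noiseless: perfect calls at moderate T
  tab0 <- fdr_curve(list(n_probes = 800, sigma = 0,
                         neutral_len = c(100, 200),
                         altered_len = c(10, 30)),
                    a = 0.5, T_grid = 4, min_seg_len_grid = 1,
                    n_reps = 2, seed = 33)
  expect_equal(tab0$fdr, 0)
  expect_equal(tab0$sensitivity, 1)
})

test_that("simulate_cohort builds a consistent stratified cohort", {
  sc <- simulate_cohort(n_per_pop = c(15, 15, 15), n_blocks = 25,
                        n_pop_informative = 5, n_causal = 3, seed = 41)
  sc2 <- simulate_cohort(n_per_pop = c(15, 15, 15), n_blocks = 25,
                         n_pop_informative = 5, n_causal = 3, seed = 41)
  expect_identical(sc$table$Y, sc2$table$Y)
  expect_identical(sc$phenotype, sc2$phenotype)
  expect_equal(length(sc$phenotype), 45)
  expect_equal(dim(sc$carriers), c(45, 25))
  expect_length(intersect(sc$causal, sc$informative), 0)
  # informative blocks have strongly differentiated frequencies
  fr <- as.matrix(sc$blocks[sc$informative, grep("^freq", names(sc$blocks))])
  expect_true(all(apply(fr, 1, max) - apply(fr, 1, min) > 0.5))
  # carriers actually carry signal: mean shift at causal block probes
  b <- sc$blocks[sc$causal[1], ]
  idx <- b$start:b$end
  car <- sc$carriers[, sc$causal[1]] == 1
  shift <- mean(colMeans(sc$table$Y[idx, car, drop = FALSE])) -
    mean(colMeans(sc$table$Y[idx, !car, drop = FALSE]))
  expect_gt(abs(shift), 0.3)
})

test_that("null cohort: uniform case bias and OR 1 break all links", {
  sc <- simulate_cohort(n_per_pop = c(30, 30), n_blocks = 20,
                        n_pop_informative = 0, n_causal = 0,
                        effect_or = 1, case_bias = c(0.5, 0.5), seed = 42)
  # phenotype unrelated to population
  tab <- table(sc$population, sc$phenotype)
  expect_gt(chisq.test(tab)$p.value, 0.01)
})

test_that("MCA on a strongly structured cohort separates populations", {
  sc <- simulate_cohort(n_per_pop = c(25, 25, 25), n_blocks = 40,
                        n_pop_informative = 20, n_causal = 0,
                        sigma = 0.15, seed = 43)
  # use the true carrier matrix as calls (segmentation tested elsewhere)
  calls <- sc$carriers *
    matrix(sc$blocks$type, nrow(sc$carriers), ncol(sc$carriers),
           byrow = TRUE)
  m <- mca(calls, n_axes = 2)
  # silhouette of the population labeling on axes 1-2
  d <- as.matrix(dist(m$scores))
  sil <- vapply(seq_len(nrow(d)), function(i) {
    own <- sc$population == sc$population[i]
    a <- mean(d[i, own & seq_len(nrow(d)) != i])
    b <- min(vapply(setdiff(unique(sc$population), sc$population[i]),
                    function(p) mean(d[i, sc$population == p]),
                    numeric(1)))
    (b - a) / max(a, b)
  }, numeric(1))
  expect_gt(mean(sil), 0.5)
})
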