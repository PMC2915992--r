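# Synthetic log2-ratio profiles and stratified case-control cohorts with
# known truth, plus the FDR/sensitivity calibration harness.
#
# Default alteration levels are the copy-number arithmetic on a diploid
# background: a single-copy gain is log2(3/2) ~ +0.585 and a single-copy
# loss log2(1/2) = -1.  Noise is iid Gaussian, the error model the
# segmentation assumes; wave/GC artifacts are out of scope.

.with_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv()))
    get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv())
          else if (exists(".Random.seed", globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  force(expr)
}

#' Simulate one piecewise-constant log2-ratio profile
#'
#' Alternating Neutral / altered segments with lengths drawn uniformly
#' from the given ranges (the profile starts Neutral); each altered
#' segment is a gain with probability \code{p_gain}, a loss otherwise.
#' Gaussian noise of standard deviation \code{sigma} is added.  The full
#' per-probe truth is returned.
#'
#' @param n_probes number of probes (default 5000).
#' @param neutral_len (min, max) Neutral segment length in probes.
#' @param altered_len (min, max) altered segment length in probes.
#' @param gain_level log2 amplitude of gains (default log2(3/2)).
#' @param loss_level log2 amplitude of losses (default log2(1/2) = -1).
#' @param p_gain probability an altered segment is a gain.
#' @param sigma noise standard deviation (>= 0).
#' @param seed RNG seed (required).
#' @param sample_id,chromosome labels for the emitted signal.
#' @return an object of class \code{SimProfile}: \code{signal} (a
#'   \code{ProbeSignal}), \code{truth} (per-probe \{-1,0,+1\}),
#'   \code{true_breakpoints}, \code{sigma}, \code{seed}.
#' @export
simulate_profile <- function(n_probes = 5000,
                             neutral_len = c(200, 2000),
                             altered_len = c(5, 100),
                             gain_level = log2(3 / 2),
                             loss_level = log2(1 / 2),
                             p_gain = 0.5, sigma = 0.2, seed,
                             sample_id = "sim", chromosome = "1") {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_probes >= 2, all(neutral_len >= 1), all(altered_len >= 1),
            sigma >= 0)
  .with_seed(seed, {
    lens <- integer(0); sts <- integer(0); lvs <- numeric(0)
    total <- 0
    altered <- FALSE
    while (total < n_probes) {
      if (altered) {
        len <- sample(altered_len[1]:altered_len[2], 1)
        st <- if (runif(1) < p_gain) 1L else -1L
        lv <- if (st == 1L) gain_level else loss_level
      } else {
        len <- sample(neutral_len[1]:neutral_len[2], 1)
        st <- 0L; lv <- 0
      }
      lens <- c(lens, len); sts <- c(sts, st); lvs <- c(lvs, lv)
      total <- total + len
      altered <- !altered
    }
    truth <- rep(sts, lens)[seq_len(n_probes)]
    amp <- rep(lvs, lens)[seq_len(n_probes)]
    y <- amp + rnorm(n_probes, 0, sigma)
    pos <- seq_len(n_probes) * 1000
    sig <- probe_signal(sample_id, chromosome,
                        paste0("p", seq_len(n_probes)), pos, y)
    structure(list(signal = sig, truth = truth,
                   true_breakpoints = which(diff(truth) != 0),
                   true_amplitudes = amp, sigma = sigma, seed = seed),
              class = "SimProfile")
  })
}

#' FDR / sensitivity calibration over a (T, MinSegLen) grid
#'
#' Simulates \code{n_reps} chromosomes, fits the SBL model once per
#' replicate at sparseness \code{a}, runs backward elimination once per
#' \code{min_seg_len}, and evaluates every threshold \code{T} post hoc.
#' Probe-level pooled counts: FDR is the fraction of called-altered
#' probes whose truth is Neutral; sensitivity the fraction of truly
#' altered probes called altered.  Cells with no altered calls report
#' \code{NA} FDR.
#'
#' @param sim_config list of arguments for \code{simulate_profile}
#'   (without \code{seed}).
#' @param a SBL sparseness hyperparameter (default 0.2, the sensitive
#'   preset).
#' @param T_grid thresholds to evaluate.
#' @param min_seg_len_grid minimum segment lengths to evaluate.
#' @param n_reps number of simulated chromosomes.
#' @param seed RNG seed; replicate r uses \code{seed + r}.
#' @return data.frame: T, min_seg_len, fdr, sensitivity, called, false,
#'   true_altered.
#' @export
fdr_curve <- function(sim_config = list(), a = 0.2,
                      T_grid = c(3, 4, 5, 6, 8),
                      min_seg_len_grid = c(1, 3, 5),
                      n_reps = 10, seed) {
  if (missing(seed)) stop("seed is required")
  stopifnot(n_reps >= 1)
  grid <- expand.grid(T = T_grid, min_seg_len = min_seg_len_grid)
  called <- false <- recalled <- numeric(nrow(grid))
  truth_altered_total <- 0
  for (r in seq_len(n_reps)) {
    sp <- do.call(simulate_profile,
                  c(sim_config, list(seed = seed + r)))
    fit <- sbl_fit(sp$signal, a = a)
    truth_alt <- sp$truth != 0
    truth_altered_total <- truth_altered_total + sum(truth_alt)
    for (L in min_seg_len_grid) {
      rk <- backward_eliminate(sp$signal, fit, min_seg_len = L)
      for (tt in T_grid) {
        seg <- apply_threshold(rk, tt, sp$signal)
        seg <- classify_segments(seg, T = tt)
        st <- rep(c(Loss = -1L, Neutral = 0L,
                    Gain = 1L)[seg$segments$state],
                  seg$segments$n_probes)
        i <- which(grid$T == tt & grid$min_seg_len == L)
        call_alt <- st != 0
        called[i] <- called[i] + sum(call_alt)
        false[i] <- false[i] + sum(call_alt & !truth_alt)
        recalled[i] <- recalled[i] + sum(call_alt & truth_alt)
      }
    }
  }
  data.frame(T = grid$T, min_seg_len = grid$min_seg_len,
             fdr = ifelse(called > 0, false / called, NA_real_),
             sensitivity = recalled / truth_altered_total,
             called = called, false = false,
             true_altered = truth_altered_total)
}

# Calibrate conditional logistic coefficients so that every causal
# block's model-implied marginal odds ratio equals exp(target).
# Enumeration over 2^(k-1) carrier combinations x populations; k is
# small (a handful of causal blocks).
.calibrate_marginal_or <- function(f_c, bias_levels, pop_w, target,
                                   n_sweep = 25, tol = 1e-10) {
  k <- length(f_c)
  if (k == 0) return(numeric(0))
  beta <- rep(target, k)
  center <- function(b) sum(b * f_c)
  marg_log_or <- function(b, j) {
    others <- setdiff(seq_len(k), j)
    combos <- if (length(others))
      as.matrix(expand.grid(rep(list(0:1), length(others)))) else
        matrix(0, 1, 0)
    w <- apply(combos, 1, function(x)
      prod(ifelse(x == 1, f_c[others], 1 - f_c[others])))
    base <- as.vector(combos %*% b[others]) - center(b)
    p1 <- p0 <- 0
    for (g in seq_along(pop_w)) {
      p1 <- p1 + pop_w[g] * sum(w * stats::plogis(bias_levels[g] +
                                                    base + b[j]))
      p0 <- p0 + pop_w[g] * sum(w * stats::plogis(bias_levels[g] + base))
    }
    log(p1 / (1 - p1)) - log(p0 / (1 - p0))
  }
  for (s in seq_len(n_sweep)) {
    delta <- 0
    for (j in seq_len(k)) {
      cur <- marg_log_or(beta, j)
      adj <- target - cur
      beta[j] <- beta[j] + adj
      delta <- max(delta, abs(adj))
    }
    if (delta < tol) break
  }
  beta
}

#' Simulate a stratified case-control cohort with known truth
#'
#' Builds a genome of \code{n_blocks} candidate CNV loci (blocks of
#' consecutive probes separated by Neutral gaps) and a cohort drawn from
#' several populations.  Each block has a per-population carrier
#' frequency: most blocks share one frequency across populations,
#' \code{n_pop_informative} blocks differ strongly between populations
#' (driving MCA separation), and \code{n_causal} of the non-informative
#' blocks carry a phenotype effect.  Carriers of a block get its gain or
#' loss amplitude over the block probes; Gaussian noise is added.  The
#' phenotype follows a logistic model: population-specific baseline case
#' fraction (\code{case_bias}, the stratification confounder) plus
#' \code{log(effect_or)} per carried causal block.
#'
#' @param n_per_pop subjects per population (vector; its length sets the
#'   number of populations; default c(100, 100, 100)).
#' @param n_blocks number of CNV blocks (default 200).
#' @param n_pop_informative blocks with population-differentiated
#'   frequencies (default 20).
#' @param n_causal causal blocks (default 5).
#' @param effect_or per-carrier odds ratio of the causal blocks
#'   (default 3).
#' @param causal_freq (min, max) carrier frequency of causal blocks,
#'   shared across populations (default c(0.3, 0.45): the association
#'   design targets common CNVs; rare-variant tests are out of scope).
#' @param case_bias baseline case proportion per population
#'   (default c(0.3, 0.6, 0.3): the second population mimics an
#'   over-sampled case group).
#' @param block_len (min, max) block length in probes.
#' @param gap_len (min, max) Neutral gap length in probes.
#' @param gain_level,loss_level,p_gain,sigma as in
#'   \code{simulate_profile}.
#' @param seed RNG seed (required).
#' @return an object of class \code{SimCohort}: \code{table}
#'   (\code{CohortTable}), \code{population}, \code{phenotype},
#'   \code{carriers} (subjects x blocks 0/1 truth), \code{blocks}
#'   (probe ranges, type, frequencies), \code{causal},
#'   \code{informative}, \code{seed}.
#' @export
simulate_cohort <- function(n_per_pop = c(100, 100, 100), n_blocks = 200,
                            n_pop_informative = 20, n_causal = 5,
                            effect_or = 3, causal_freq = c(0.3, 0.45),
                            case_bias = NULL,
                            block_len = c(8, 15), gap_len = c(10, 20),
                            gain_level = log2(3 / 2),
                            loss_level = log2(1 / 2),
                            p_gain = 0.5, sigma = 0.2, seed) {
  if (missing(seed)) stop("seed is required")
  n_pop <- length(n_per_pop)
  if (is.null(case_bias)) {
    case_bias <- rep(0.3, n_pop)
    if (n_pop >= 2) case_bias[2] <- 0.6
  }
  stopifnot(all(n_per_pop > 0), n_blocks >= 1, effect_or > 0,
            length(case_bias) == n_pop,
            n_pop_informative + n_causal <= n_blocks)
  .with_seed(seed, {
    n <- sum(n_per_pop)
    pop <- rep(paste0("POP", seq_len(n_pop)), n_per_pop)
    subj <- sprintf("S%03d", seq_len(n))

    # genome layout: gap, block, gap, block, ...
    starts <- ends <- integer(n_blocks)
    pos <- 0L
    for (b in seq_len(n_blocks)) {
      pos <- pos + sample(gap_len[1]:gap_len[2], 1)
      starts[b] <- pos + 1L
      pos <- pos + sample(block_len[1]:block_len[2], 1)
      ends[b] <- pos
    }
    m <- pos + sample(gap_len[1]:gap_len[2], 1)
    type <- ifelse(runif(n_blocks) < p_gain, 1L, -1L)
    level <- ifelse(type == 1L, gain_level, loss_level)

    base_freq <- runif(n_blocks, 0.05, 0.4)
    freq <- matrix(base_freq, n_pop, n_blocks, byrow = TRUE)
    informative <- sample(n_blocks, n_pop_informative)
    for (b in informative) {
      f <- rep(0.05, n_pop)
      f[sample(n_pop, 1)] <- 0.8
      freq[, b] <- f
    }
    causal <- sample(setdiff(seq_len(n_blocks), informative), n_causal)
    for (b in causal)
      freq[, b] <- runif(1, causal_freq[1], causal_freq[2])

    pop_i <- rep(seq_len(n_pop), n_per_pop)
    carriers <- matrix(0L, n, n_blocks,
                       dimnames = list(subj, sprintf("blk%03d",
                                                     seq_len(n_blocks))))
    for (b in seq_len(n_blocks))
      carriers[, b] <- rbinom(n, 1, freq[pop_i, b])

    # effect_or is the MARGINAL per-block odds ratio an epidemiologist
    # would measure in a 2x2 table.  In a joint logistic model,
    # non-collapsibility shrinks the marginal OR below the conditional
    # one, so the conditional coefficients are calibrated by exact
    # enumeration over the discrete joint distribution of the other
    # causal carriers and the population mixture.
    bias_levels <- log(case_bias / (1 - case_bias))
    pop_w <- n_per_pop / n
    f_c <- freq[1, causal]
    beta <- .calibrate_marginal_or(f_c, bias_levels, pop_w,
                                   log(effect_or))
    eta <- bias_levels[pop_i] +
      as.vector(carriers[, causal, drop = FALSE] %*% beta) -
      sum(beta * f_c)
    phenotype <- rbinom(n, 1, 1 / (1 + exp(-eta)))

    amp <- matrix(0, n, m)
    for (b in seq_len(n_blocks)) {
      idx <- starts[b]:ends[b]
      amp[, idx] <- outer(carriers[, b] * level[b], rep(1, length(idx)))
    }
    Y <- t(amp + matrix(rnorm(n * m, 0, sigma), n, m))
    probes <- data.frame(name = paste0("p", seq_len(m)),
                         chromosome = "1",
                         position = seq_len(m) * 1000,
                         stringsAsFactors = FALSE)
    table <- .new_cohort_table(probes, Y, subj)
    blocks <- data.frame(block = colnames(carriers),
                         start = starts, end = ends, type = type,
                         causal = seq_len(n_blocks) %in% causal,
                         informative = seq_len(n_blocks) %in% informative,
                         t(freq))
    names(blocks)[seq(7, 6 + n_pop)] <- paste0("freq_POP", seq_len(n_pop))
    structure(list(table = table, population = pop,
                   phenotype = phenotype, carriers = carriers,
                   blocks = blocks, causal = sort(causal),
                   informative = sort(informative), sigma = sigma,
                   seed = seed),
              class = "SimCohort")
  })
}

#' @export
print.SimCohort <- function(x, ...) {
  cat(sprintf(paste0("SimCohort: %d subjects (%s), %d probes, ",
                     "%d blocks (%d informative, %d causal)\n"),
              length(x$phenotype),
              paste(table(x$population), collapse = "/"),
              nrow(x$table$probes), nrow(x$blocks),
              length(x$informative), length(x$causal)))
  invisible(x)
}
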