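# Piecewise-constant segmentation of a probe signal.
#
# Model: y = F w + e with F the normalized step basis (column m jumps
# after probe m, zero mean, unit norm).  The Gram matrix of any subset of
# columns is a Markov kernel G[m,n] = u(m)/u(n) (m <= n, u(m) =
# sqrt(m/(M-m))) whose inverse is tridiagonal, so least-squares weights,
# t-statistics and the SBL posterior are all O(M).  Dense M x M algebra is
# never used.

.signal_y <- function(signal) {
  if (inherits(signal, "ProbeSignal")) signal$y
  else if (is.numeric(signal)) as.numeric(signal)
  else stop("signal must be a ProbeSignal or a numeric vector")
}

# f_m' y for all m = 1..M-1 (y centered internally)
.step_z <- function(y) {
  M <- length(y)
  yc <- y - mean(y)
  S <- cumsum(yc)[seq_len(M - 1)]
  m <- as.numeric(seq_len(M - 1))   # avoid integer overflow in m*(M-m)
  -S * sqrt(M / (m * (M - m)))
}

.check_breakpoints <- function(breakpoints, M) {
  if (length(breakpoints) == 0) return(integer(0))
  b <- as.integer(breakpoints)
  if (any(b < 1) || any(b > M - 1)) stop("breakpoint index out of range")
  if (anyDuplicated(b) || is.unsorted(b, strictly = TRUE))
    stop("breakpoints must be strictly increasing and distinct (a ",
         "duplicate implies an empty segment)")
  b
}

# least-squares weights on the restricted basis and diag((F'F)^-1);
# z = .step_z(y) may be passed precomputed (backward elimination calls
# this once per removal)
.ls_weights <- function(y, breakpoints, z_full = NULL) {
  M <- length(y)
  k <- length(breakpoints)
  P <- .bkp_gram_inv_cpp(as.integer(breakpoints), M)
  if (is.null(z_full)) z_full <- .step_z(y)
  z <- z_full[breakpoints]
  w <- P$diag * z
  if (k > 1) {
    w[-k] <- w[-k] + P$offdiag * z[-1]
    w[-1] <- w[-1] + P$offdiag * z[-k]
  }
  list(w = w, gram_inv_diag = P$diag)
}

#' Sparse Bayesian learning fit of the breakpoint model
#'
#' Fits the maximum a posteriori piecewise-constant decomposition of a
#' log2-ratio signal.  All M-1 candidate breakpoints start active with a
#' common precision; evidence-style fixed-point sweeps alternate the
#' Gaussian posterior of the weights with hyperparameter updates under a
#' Gamma(a, b) prior on each precision, pruning breakpoints whose
#' precision diverges.  Larger \code{a} enforces more sparseness (fewer
#' breakpoints); \code{b = 0} is the uninformative default.  The fit is
#' fully deterministic.
#'
#' @param signal a \code{ProbeSignal} or numeric vector of log2 ratios.
#' @param a sparseness hyperparameter, in (0, 1]; typical range 0.2-0.8.
#' @param b hyperprior scale, >= 0 (default 0, uninformative).
#' @param max_iter maximum number of sweeps.
#' @param tol relative convergence tolerance on the precision vector.
#' @param alpha_max precision cap above which a breakpoint is deactivated.
#' @param w_floor absolute weight below which a breakpoint is deactivated.
#' @param sigma2_init optional initial noise variance; by default a robust
#'   estimate from first differences.
#' @return an object of class \code{SBLFit} with elements
#'   \code{breakpoints} (probe indices; a breakpoint at m separates probes
#'   m and m+1), \code{w}, \code{alpha}, \code{sigma2}, \code{n_iter},
#'   \code{converged}.
#' @export
sbl_fit <- function(signal, a = 0.5, b = 0, max_iter = 10000, tol = 1e-8,
                    alpha_max = 1e8, w_floor = 1e-8, sigma2_init = NULL) {
  y <- .signal_y(signal)
  if (length(y) < 2) stop("need at least 2 probes")
  if (any(!is.finite(y))) stop("non-finite values in y")
  if (!(a > 0 && a <= 1)) stop("a must be in (0, 1]")
  if (b < 0) stop("b must be >= 0")
  .cnvsbl_env$sbl_calls <- .cnvsbl_env$sbl_calls + 1L
  res <- .sbl_core_cpp(y, a, b, as.integer(max_iter), tol, alpha_max,
                       w_floor, if (is.null(sigma2_init)) -1 else sigma2_init)
  if (!res$converged)
    warning("SBL did not converge in ", max_iter, " iterations")
  structure(list(breakpoints = as.integer(res$breakpoints), w = res$w,
                 alpha = res$alpha, a = a, b = b, sigma2 = res$sigma2,
                 n_iter = res$n_iter, converged = res$converged,
                 M = length(y),
                 sample_id = if (inherits(signal, "ProbeSignal"))
                   signal$sample_id else NA_character_,
                 chromosome = if (inherits(signal, "ProbeSignal"))
                   signal$chromosome else NA_character_),
            class = "SBLFit")
}

#' @export
print.SBLFit <- function(x, ...) {
  cat(sprintf(
    "SBLFit: %d active breakpoint(s), sigma2 = %.4g, %d iteration(s)%s\n",
    length(x$breakpoints), x$sigma2, x$n_iter,
    if (x$converged) "" else " (not converged)"))
  invisible(x)
}

#' Segment amplitudes for a fixed breakpoint set
#'
#' The amplitude of each segment is the mean log2 ratio of the probes it
#' contains, the least-squares reconstruction once breakpoints are fixed.
#'
#' @param signal a \code{ProbeSignal} or numeric vector.
#' @param breakpoints strictly increasing probe indices in 1..M-1.
#' @return numeric vector of length \code{length(breakpoints) + 1}.
#' @export
fit_amplitudes <- function(signal, breakpoints) {
  y <- .signal_y(signal)
  b <- .check_breakpoints(breakpoints, length(y))
  bounds <- c(0L, b, length(y))
  vapply(seq_len(length(bounds) - 1),
         function(s) mean(y[(bounds[s] + 1):bounds[s + 1]]), numeric(1))
}

#' Breakpoint t-statistics
#'
#' For the restricted basis F_I of the active breakpoints,
#' t_j = |w_j| / sqrt(sigma2 * [(F_I' F_I)^-1]_jj), with w the
#' least-squares weights.  Computed in O(M) via the tridiagonal structure
#' of the restricted Gram matrix.  For an isolated breakpoint between two
#' terminal segments this reduces to the two-sample statistic
#' |m2 - m1| / (sigma * sqrt(1/L1 + 1/L2)).
#'
#' @param signal a \code{ProbeSignal} or numeric vector.
#' @param breakpoints strictly increasing probe indices.
#' @param sigma2 noise variance (> 0), typically from the SBL fit.
#' @return numeric vector of t-scores, one per breakpoint.
#' @export
t_statistics <- function(signal, breakpoints, sigma2) {
  y <- .signal_y(signal)
  b <- .check_breakpoints(breakpoints, length(y))
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  if (length(b) == 0) return(numeric(0))
  ls <- .ls_weights(y, b)
  abs(ls$w) / sqrt(sigma2 * ls$gram_inv_diag)
}

#' Backward elimination ranking of breakpoints
#'
#' Iteratively removes the breakpoint with the lowest current t-score,
#' re-fitting amplitudes at each step, and records the score at removal.
#' Breakpoints bounding a segment shorter than \code{min_seg_len} probes
#' are removed first (weakest bounding breakpoint first) and can never
#' survive, whatever the threshold.  The complete elimination order is
#' returned so that any threshold T can be applied afterwards without
#' re-running the SBL fit; survivor sets are nested in T by construction
#' (scores are monotonized along the order).
#'
#' @param signal the \code{ProbeSignal} the fit was computed on.
#' @param fit an \code{SBLFit} for the same signal.
#' @param min_seg_len minimum segment length in probes (default 3).
#' @return an object of class \code{BreakpointRanking}.
#' @export
backward_eliminate <- function(signal, fit, min_seg_len = 3) {
  y <- .signal_y(signal)
  stopifnot(inherits(fit, "SBLFit"))
  if (fit$M != length(y)) stop("fit does not match signal length")
  M <- length(y)
  active <- sort(fit$breakpoints)
  z_full <- .step_z(y)
  rec_bkp <- integer(0); rec_t <- numeric(0); rec_forced <- logical(0)
  while (length(active) > 0) {
    k <- length(active)
    ls <- .ls_weights(y, active, z_full)
    t <- abs(ls$w) / sqrt(fit$sigma2 * ls$gram_inv_diag)
    seg_len <- diff(c(0L, active, M))
    short <- which(seg_len < min_seg_len)
    if (length(short) > 0) {
      cand <- unique(pmin(pmax(c(short - 1L, short), 1L), k))
      cand <- sort(cand)
      j <- cand[which.min(t[cand])]   # weakest; ties -> leftmost
      forced <- TRUE
    } else {
      j <- which.min(t)               # ties -> leftmost
      forced <- FALSE
    }
    if (length(j) != 1 || is.na(j))
      stop("non-finite t-scores during backward elimination")
    rec_bkp <- c(rec_bkp, active[j])
    rec_t <- c(rec_t, t[j])
    rec_forced <- c(rec_forced, forced)
    active <- active[-j]
  }
  ord <- data.frame(breakpoint = rec_bkp, t_removal = rec_t,
                    forced = rec_forced)
  # nesting: survival is decided on the running maximum of the ordinary
  # removal scores, so survivors(T1) is a subset of survivors(T2) for
  # T1 >= T2
  crit <- rep(NA_real_, nrow(ord))
  run <- -Inf
  for (i in seq_len(nrow(ord))) {
    if (!ord$forced[i]) {
      run <- max(run, ord$t_removal[i])
      crit[i] <- run
    }
  }
  ord$t_critical <- crit
  structure(list(order = ord, min_seg_len = min_seg_len, M = M,
                 sigma2 = fit$sigma2, n_initial = length(fit$breakpoints),
                 sample_id = fit$sample_id, chromosome = fit$chromosome),
            class = "BreakpointRanking")
}

#' @export
print.BreakpointRanking <- function(x, ...) {
  cat(sprintf(
    "BreakpointRanking: %d breakpoint(s) ranked (min_seg_len = %d)\n",
    nrow(x$order), x$min_seg_len))
  invisible(x)
}

#' Surviving breakpoints at a threshold
#'
#' @param ranking a \code{BreakpointRanking}.
#' @param T critical t value (>= 0); survival is inclusive (t >= T).
#' @return sorted integer vector of surviving breakpoint indices.
#' @export
survivors_at <- function(ranking, T) {
  stopifnot(inherits(ranking, "BreakpointRanking"))
  if (T < 0) stop("T must be >= 0")
  o <- ranking$order
  sort(o$breakpoint[!o$forced & !is.na(o$t_critical) & o$t_critical >= T])
}

.make_segment_set <- function(signal, breakpoints, sigma2,
                              states = NULL, baseline = NA_real_) {
  stopifnot(inherits(signal, "ProbeSignal"))
  M <- length(signal$y)
  b <- .check_breakpoints(breakpoints, M)
  amps <- fit_amplitudes(signal, b)
  bounds <- c(0L, b, M)
  s <- seq_len(length(bounds) - 1)
  start <- bounds[s] + 1L
  end <- bounds[s + 1]
  seg <- data.frame(
    start = start, end = end,
    start_bp = signal$positions[start], end_bp = signal$positions[end],
    start_probe = signal$probe_names[start],
    n_probes = end - start + 1L,
    amplitude = amps,
    state = if (is.null(states)) rep(NA_character_, length(s)) else states,
    stringsAsFactors = FALSE)
  structure(list(sample_id = signal$sample_id,
                 chromosome = signal$chromosome,
                 segments = seg, baseline = baseline, sigma2 = sigma2,
                 M = M, has_positions = signal$has_positions),
            class = "SegmentSet")
}

#' @export
print.SegmentSet <- function(x, ...) {
  cat(sprintf(
    "SegmentSet: sample %s chr %s, %d segment(s) (%d Gain, %d Loss)\n",
    x$sample_id, x$chromosome, nrow(x$segments),
    sum(x$segments$state == "Gain", na.rm = TRUE),
    sum(x$segments$state == "Loss", na.rm = TRUE)))
  invisible(x)
}

#' Apply a t threshold to a backward-elimination ranking
#'
#' Rebuilds the (unclassified) piecewise-constant segmentation keeping
#' the breakpoints whose critical score is at least \code{T}.  The
#' ranking is specific to its \code{min_seg_len}; passing a different one
#' is an error (re-run \code{backward_eliminate}).
#'
#' @param ranking a \code{BreakpointRanking}.
#' @param T critical t value.
#' @param signal the \code{ProbeSignal} the ranking came from.
#' @param min_seg_len optional consistency check.
#' @return an unclassified \code{SegmentSet} (states are \code{NA}).
#' @export
apply_threshold <- function(ranking, T, signal, min_seg_len = NULL) {
  stopifnot(inherits(ranking, "BreakpointRanking"))
  if (!is.null(min_seg_len) && min_seg_len != ranking$min_seg_len)
    stop("min_seg_len differs from the ranking's (", ranking$min_seg_len,
         "); re-run backward_eliminate")
  if (length(signal$y) != ranking$M) stop("signal does not match ranking")
  .make_segment_set(signal, survivors_at(ranking, T), ranking$sigma2)
}
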