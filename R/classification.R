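# Gain/Neutral/Loss classification of reconstructed segments against a
# per-chromosome baseline, alteration limits estimated from a reference
# population's X chromosome, and the cohort summary report.

#' Per-chromosome baseline amplitude
#'
#' The Neutral (2-copy, for autosomes) level is the median of all
#' reconstructed segment amplitudes on the chromosome.  Segments are
#' weighted equally by default; probe-weighting is available.  The user
#' may fix the baseline instead, which is required when whole-chromosome
#' alterations are suspected (the median convention calls states relative
#' to the chromosome's own dominant level).
#'
#' @param segments a \code{SegmentSet}.
#' @param override fixed baseline value; bypasses estimation.
#' @param probe_weighted weight amplitudes by segment probe counts.
#' @return baseline amplitude (log2 ratio units).
#' @export
estimate_baseline <- function(segments, override = NULL,
                              probe_weighted = FALSE) {
  if (!is.null(override)) return(as.numeric(override))
  stopifnot(inherits(segments, "SegmentSet"))
  if (nrow(segments$segments) < 1) stop("no segments")
  a <- segments$segments$amplitude
  if (!probe_weighted) return(median(a))
  w <- segments$segments$n_probes
  o <- order(a)
  a <- a[o]; w <- w[o]
  cw <- cumsum(w) / sum(w)
  a[which(cw >= 0.5)[1]]
}

#' Classify segments into Loss / Neutral / Gain
#'
#' A segment of L probes with amplitude c is called altered when its
#' departure from the baseline is significant at the same critical value
#' T that governed breakpoint selection, using the z-like score
#' |c - baseline| * sqrt(L) / sigma.  Gains lie above the baseline,
#' Losses below; everything else is Neutral.
#'
#' @param segments a \code{SegmentSet} (typically from
#'   \code{apply_threshold}).
#' @param T critical value (>= 0).
#' @param baseline baseline amplitude; default
#'   \code{estimate_baseline(segments)}.
#' @param sigma2 noise variance; default the value stored in
#'   \code{segments} by the SBL fit.
#' @return the \code{SegmentSet} with states filled in and the baseline
#'   recorded.
#' @export
classify_segments <- function(segments, T, baseline = NULL, sigma2 = NULL) {
  stopifnot(inherits(segments, "SegmentSet"))
  if (is.null(baseline)) baseline <- estimate_baseline(segments)
  if (is.null(sigma2)) sigma2 <- segments$sigma2
  if (!(sigma2 > 0)) stop("sigma2 must be > 0")
  if (T < 0) stop("T must be >= 0")
  s <- segments$segments
  score <- abs(s$amplitude - baseline) * sqrt(s$n_probes) / sqrt(sigma2)
  state <- rep("Neutral", nrow(s))
  state[score >= T & s$amplitude > baseline] <- "Gain"
  state[score >= T & s$amplitude < baseline] <- "Loss"
  segments$segments$state <- state
  segments$baseline <- baseline
  segments
}

#' Alteration limits from a reference population's X chromosome
#'
#' In a mixed-sex reference, female X segments sit at the 2-copy level
#' and male X segments one copy lower; the separation between the two
#' amplitude distributions calibrates how far from baseline a real
#' one-copy change lies on this platform.  The Loss limit is the midpoint
#' between the female and male medians (relative to the female level);
#' the Gain limit mirrors it rescaled by log2(3/2)/|log2(1/2)|, the
#' 3-copy versus 1-copy amplitude ratio.
#'
#' @param reference a \code{CohortTable} containing X-chromosome probes.
#' @param sex character vector ("male"/"female", or "M"/"F") per sample.
#' @return an \code{AlterationLimits} object: list with \code{low} (< 0)
#'   and \code{high} (> 0), relative to the female baseline.
#' @export
estimate_limits_from_reference <- function(reference, sex) {
  stopifnot(inherits(reference, "CohortTable"))
  sex <- tolower(substr(as.character(sex), 1, 1))
  if (length(sex) != length(reference$sample_ids))
    stop("sex must have one entry per sample")
  if (!all(sex %in% c("m", "f"))) stop("sex entries must be male/female")
  if (!any(sex == "m") || !any(sex == "f"))
    stop("reference must contain both males and females")
  i <- reference$probes$chromosome == "X"
  if (!any(i)) stop("reference contains no X-chromosome probes")
  amp <- apply(reference$Y[i, , drop = FALSE], 2, median)
  f <- median(amp[sex == "f"])
  m <- median(amp[sex == "m"])
  if (!(m < f)) stop("male X level is not below the female level; ",
                     "check the sex labels")
  low <- (m - f) / 2
  high <- -low * log2(3 / 2) / abs(log2(1 / 2))
  structure(list(low = low, high = high), class = "AlterationLimits")
}

#' Fixed alteration limits
#' @param low Loss bound (< 0), relative to baseline.
#' @param high Gain bound (> 0).
#' @return an \code{AlterationLimits} object.
#' @export
alteration_limits <- function(low, high) {
  if (!(low < 0 && high > 0)) stop("need low < 0 < high")
  structure(list(low = low, high = high), class = "AlterationLimits")
}

#' @export
print.AlterationLimits <- function(x, ...) {
  cat(sprintf("AlterationLimits: (%.3g, %.3g)\n", x$low, x$high))
  invisible(x)
}

#' Cohort segmentation summary
#'
#' Counts altered segments genome-wide and per chromosome.  When
#' \code{limits} are given, segments are re-called against them on the
#' baseline-centered amplitude; otherwise the stored Gain/Loss states are
#' used.  Segments whose centered amplitude falls inside the limits
#' interval, or whose base-pair length falls outside \code{length_base},
#' are discarded and reported in the NOTE line.
#'
#' @param all_segments list of classified \code{SegmentSet}s.
#' @param limits optional \code{AlterationLimits}.
#' @param length_base numeric (min, max) segment length in bases.
#' @return an object of class \code{cohort_summary}; its \code{print}
#'   method renders the console block, \code{as.data.frame} the
#'   per-chromosome table.
#' @export
summarize_cohort <- function(all_segments, limits = NULL,
                             length_base = c(0, Inf)) {
  if (inherits(all_segments, "SegmentSet"))
    all_segments <- list(all_segments)
  d <- .segments_as_df(all_segments)
  if (is.null(d)) stop("no segments to summarize")
  base <- vapply(all_segments, function(s)
    if (is.na(s$baseline)) 0 else s$baseline, numeric(1))
  d$centered <- d$amplitude -
    rep(base, vapply(all_segments,
                     function(s) nrow(s$segments), integer(1)))
  d$len <- d$end_bp - d$start_bp + 1
  if (!is.null(limits)) {
    stopifnot(inherits(limits, "AlterationLimits"))
    d$call <- ifelse(d$centered > limits$high, "Gain",
                     ifelse(d$centered < limits$low, "Loss", "Neutral"))
  } else {
    d$call <- d$state
  }
  keep <- d$call %in% c("Gain", "Loss") &
    d$len >= length_base[1] & d$len <= length_base[2]
  kept <- d[keep, , drop = FALSE]
  by_chrom <- do.call(rbind, lapply(split(kept, kept$chromosome), function(g)
    data.frame(chromosome = g$chromosome[1], segments = nrow(g),
               gains = sum(g$call == "Gain"), losses = sum(g$call == "Loss"),
               stringsAsFactors = FALSE)))
  if (!is.null(by_chrom))
    by_chrom <- by_chrom[order(.chrom_order(by_chrom$chromosome)), ]
  structure(list(
    n_samples = length(unique(d$sample)),
    n_discarded = sum(!keep),
    limits = limits, length_base = length_base,
    total = nrow(kept),
    gains = sum(kept$call == "Gain"),
    losses = sum(kept$call == "Loss"),
    by_chrom = by_chrom,
    length_summary = if (nrow(kept)) summary(kept$len) else NULL,
    segments = kept), class = "cohort_summary")
}

#' @export
print.cohort_summary <- function(x, ...) {
  cat(sprintf("Summary results for %d individuals\n\n", x$n_samples))
  lim <- if (is.null(x$limits)) "(classified states)" else
    sprintf("(%.3g, %.3g)", x$limits$low, x$limits$high)
  cat(sprintf(paste0(
    "NOTE: %d segments with length not in the range %g-%g bases and with\n",
    "mean log2ratio in the range %s have been discarded\n\n"),
    x$n_discarded, x$length_base[1], x$length_base[2], lim))
  pg <- if (x$total) 100 * x$gains / x$total else 0
  pl <- if (x$total) 100 * x$losses / x$total else 0
  cat("Number of Total Segments:\n")
  cat("  segments   Gains   %   Losses   %\n")
  cat(sprintf("  %8d   %5d   %.1f   %6d   %.1f\n\n",
              x$total, x$gains, pg, x$losses, pl))
  if (!is.null(x$length_summary)) {
    cat("Summary of length of segments:\n")
    print(x$length_summary)
    cat("\n")
  }
  if (!is.null(x$by_chrom)) {
    cat("Number of Total Segments by chromosome:\n")
    cat("  segments   Gains   Losses\n")
    for (i in seq_len(nrow(x$by_chrom)))
      cat(sprintf("Chromosome %s   %d   %d   %d\n",
                  x$by_chrom$chromosome[i], x$by_chrom$segments[i],
                  x$by_chrom$gains[i], x$by_chrom$losses[i]))
  }
  invisible(x)
}

#' @export
as.data.frame.cohort_summary <- function(x, ...) x$by_chrom
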