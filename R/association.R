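# Case-control association of CNV blocks: logistic likelihood-ratio
# tests with covariate adjustment and multiplicity correction.

#' Likelihood-ratio test for one CNV
#'
#' Compares a logistic model with the supplied covariates to the same
#' model with the CNV added as a categorical term (indicator coding over
#' its observed levels); the statistic is twice the log-likelihood
#' difference, referred to a chi-squared distribution with
#' (observed levels - 1) degrees of freedom.
#'
#' @param phenotype binary (0/1 or logical) outcome per subject.
#' @param cnv per-subject call in \{-1, 0, +1\}.
#' @param covariates optional data.frame of covariates (e.g. sex, age,
#'   MCA axis scores).
#' @return list with \code{lrt}, \code{df}, \code{p}, \code{testable},
#'   \code{converged}.  A constant CNV is flagged untestable (all-NA
#'   statistics) rather than an error, so batch runs continue.
#' @export
lrt_assoc <- function(phenotype, cnv, covariates = NULL) {
  y <- if (is.logical(phenotype)) as.integer(phenotype) else
    as.integer(as.numeric(phenotype) != 0)
  if (length(unique(y)) < 2) stop("phenotype must have both classes")
  if (length(cnv) != length(y)) stop("cnv and phenotype lengths differ")
  lev <- unique(cnv[!is.na(cnv)])
  if (length(lev) < 2)
    return(list(lrt = NA_real_, df = NA_integer_, p = NA_real_,
                testable = FALSE, converged = NA))
  d <- data.frame(.y = y)
  if (!is.null(covariates)) {
    covariates <- as.data.frame(covariates)
    if (nrow(covariates) != length(y)) stop("covariate rows must match")
    d <- cbind(d, covariates)
  }
  d$.cnv <- factor(cnv)
  rhs0 <- if (is.null(covariates) || ncol(covariates) == 0) "1" else
    paste(sprintf("`%s`", names(covariates)), collapse = " + ")
  f0 <- stats::as.formula(paste(".y ~", rhs0))
  f1 <- stats::as.formula(paste(".y ~", rhs0, "+ .cnv"))
  ctl <- list(maxit = 100)
  warned <- FALSE
  wh <- function(w) { warned <<- TRUE; invokeRestart("muffleWarning") }
  m0 <- withCallingHandlers(
    glm(f0, family = binomial(), data = d, control = ctl), warning = wh)
  m1 <- withCallingHandlers(
    glm(f1, family = binomial(), data = d, control = ctl), warning = wh)
  lrt <- max(m0$deviance - m1$deviance, 0)
  df <- length(lev) - 1L
  list(lrt = lrt, df = df, p = pchisq(lrt, df, lower.tail = FALSE),
       testable = TRUE,
       converged = m0$converged && m1$converged && !warned)
}

#' Association tests across all CNV blocks
#'
#' Runs \code{lrt_assoc} for every block of a reduced CNV matrix, in
#' genome order, and appends Benjamini-Hochberg and Bonferroni adjusted
#' p-values.  Untestable (constant) blocks yield NA rows and do not
#' count toward the number of tests.
#'
#' @param phenotype binary outcome per subject (aligned with the matrix
#'   rows).
#' @param x a reduced \code{CNVMatrix}.
#' @param covariates optional data.frame of covariates.
#' @return data.frame of class \code{cnv_assoc}: block_id,
#'   representative probe, chromosome, position, LRT, df, p, p_BH,
#'   p_Bonferroni, testable.
#' @export
multi_cnv_assoc <- function(phenotype, x, covariates = NULL) {
  stopifnot(inherits(x, "CNVMatrix"))
  v <- x$values
  if (length(phenotype) != nrow(v))
    stop("phenotype length does not match the number of subjects")
  blocks <- x$blocks
  if (is.null(blocks))
    blocks <- data.frame(block_id = seq_len(ncol(v)),
                         chromosome = x$markers$chromosome,
                         start_bp = x$markers$position,
                         representative = colnames(v),
                         stringsAsFactors = FALSE)
  o <- order(.chrom_order(blocks$chromosome), blocks$start_bp)
  res <- lapply(o, function(j) {
    r <- lrt_assoc(phenotype, v[, j], covariates)
    data.frame(block_id = blocks$block_id[j],
               representative = blocks$representative[j],
               chromosome = blocks$chromosome[j],
               position = blocks$start_bp[j],
               LRT = r$lrt, df = r$df, p = r$p, testable = r$testable,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_BH <- bh_adjust(out$p)
  m <- sum(!is.na(out$p))
  out$p_Bonferroni <- pmin(out$p * m, 1)
  rownames(out) <- NULL
  class(out) <- c("cnv_assoc", "data.frame")
  out
}

#' Benjamini-Hochberg step-up adjustment
#'
#' Adjusted p-values p(i) * m / i with cumulative-minimum monotonicity
#' enforcement; NA entries are passed through and excluded from m.
#'
#' @param p numeric vector of raw p-values in [0, 1] (NA allowed).
#' @return adjusted p-values, same length and order.
#' @export
bh_adjust <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  out <- rep(NA_real_, length(p))
  ok <- which(!is.na(p))
  m <- length(ok)
  if (m == 0) return(out)
  po <- p[ok]
  o <- order(po, decreasing = TRUE)
  adj <- pmin(1, cummin(po[o] * m / seq(m, 1)))
  out[ok[o]] <- adj
  out
}
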