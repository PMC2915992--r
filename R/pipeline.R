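# Pipeline orchestration: per sample x chromosome segmentation tasks,
# deterministic aggregation, intermediate persistence with a config hash
# so the threshold can be re-adjusted without re-running the SBL fit.

#' Pipeline run configuration
#'
#' Collects every tunable of the pipeline; a run is fully reproducible
#' from the configuration plus the input table.
#'
#' @param dialect input table dialect.
#' @param a,b SBL hyperparameters.
#' @param T critical t value for backward elimination and
#'   classification.
#' @param min_seg_len minimum segment length in probes.
#' @param max_iter,tol SBL iteration controls.
#' @param baseline optional fixed baseline amplitude.
#' @param limits optional \code{AlterationLimits} for the summary.
#' @param length_base (min, max) segment length filter in bases.
#' @param var_simil,sub_variation block-reduction parameters.
#' @param n_axes MCA axes retained (and used as association covariates).
#' @param n_workers parallel workers for sample x chromosome tasks.
#' @param seed RNG seed for any stochastic downstream step.
#' @param out_dir output directory; \code{NULL} keeps everything in
#'   memory.
#' @return a \code{RunConfig} list.
#' @export
run_config <- function(dialect = "beadstudio", a = 0.5, b = 0, T = 4,
                       min_seg_len = 3, max_iter = 10000, tol = 1e-8,
                       baseline = NULL, limits = NULL,
                       length_base = c(0, Inf),
                       var_simil = 0.99, sub_variation = 0.90,
                       n_axes = 2, n_workers = 1, seed = 1,
                       out_dir = NULL) {
  structure(list(dialect = dialect, a = a, b = b, T = T,
                 min_seg_len = min_seg_len, max_iter = max_iter,
                 tol = tol, baseline = baseline, limits = limits,
                 length_base = length_base, var_simil = var_simil,
                 sub_variation = sub_variation, n_axes = n_axes,
                 n_workers = n_workers, seed = seed, out_dir = out_dir),
            class = "RunConfig")
}

# hash of the fields the SBL + BE stages depend on; T is excluded on
# purpose (re-thresholding must hit the fast path)
.sbl_hash <- function(config, signal) {
  key <- list(a = config$a, b = config$b, max_iter = config$max_iter,
              tol = config$tol, min_seg_len = config$min_seg_len,
              sample = signal$sample_id, chromosome = signal$chromosome,
              M = length(signal$y), y_head = head(signal$y, 5))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(deparse(key), f)
  unname(tools::md5sum(f))
}

#' Segment and classify one sample x chromosome signal
#'
#' \code{sbl_fit} -> \code{backward_eliminate} -> \code{apply_threshold}
#' -> \code{classify_segments}.  With an \code{out_dir} configured, the
#' breakpoint ranking is persisted together with a hash of the
#' SBL-relevant configuration; a re-run that only changes \code{T}
#' re-uses it and skips the SBL fit entirely.
#'
#' @param signal a \code{ProbeSignal}.
#' @param config a \code{RunConfig}.
#' @return a classified \code{SegmentSet}.
#' @export
run_sample <- function(signal, config = run_config()) {
  stopifnot(inherits(signal, "ProbeSignal"), inherits(config, "RunConfig"))
  hash <- .sbl_hash(config, signal)
  cache <- NULL
  if (!is.null(config$out_dir)) {
    dir.create(file.path(config$out_dir, "intermediates"),
               showWarnings = FALSE, recursive = TRUE)
    cache <- file.path(config$out_dir, "intermediates",
                       sprintf("%s_chr%s.rds",
                               gsub("[^A-Za-z0-9_.-]", "_",
                                    signal$sample_id),
                               signal$chromosome))
  }
  ranking <- NULL
  if (!is.null(cache) && file.exists(cache)) {
    st <- readRDS(cache)
    if (identical(st$hash, hash)) ranking <- st$ranking
  }
  if (is.null(ranking)) {
    fit <- sbl_fit(signal, a = config$a, b = config$b,
                   max_iter = config$max_iter, tol = config$tol)
    ranking <- backward_eliminate(signal, fit,
                                  min_seg_len = config$min_seg_len)
    if (!is.null(cache))
      saveRDS(list(hash = hash, ranking = ranking), cache)
  }
  seg <- apply_threshold(ranking, config$T, signal)
  classify_segments(seg, T = config$T,
                    baseline = config$baseline)
}

#' Run the full pipeline on a cohort table
#'
#' Segments every sample x chromosome task (independently, optionally in
#' parallel; results are identical for any worker count), classifies,
#' summarizes, builds and reduces the CNV matrix, computes the MCA, and
#' -- when a phenotype is supplied -- runs the MCA-adjusted association
#' scan.  With an \code{out_dir}, per-sample segment tables and the
#' cohort artifacts are written as TSV.
#'
#' @param table a \code{CohortTable}.
#' @param config a \code{RunConfig}.
#' @param phenotype optional binary outcome per sample (in
#'   \code{table$sample_ids} order).
#' @param covariates optional data.frame of extra covariates.
#' @return list with \code{segments} (list of \code{SegmentSet}),
#'   \code{summary}, \code{matrix}, \code{reduced}, \code{mca},
#'   \code{assoc} (NULL without phenotype).
#' @export
run_cohort <- function(table, config = run_config(), phenotype = NULL,
                       covariates = NULL) {
  stopifnot(inherits(table, "CohortTable"), inherits(config, "RunConfig"))
  if (length(table$sample_ids) == 0 || nrow(table$probes) == 0)
    stop("empty cohort")
  tasks <- expand.grid(sample = table$sample_ids,
                       chromosome = unique(table$probes$chromosome),
                       stringsAsFactors = FALSE)
  tasks <- tasks[order(match(tasks$sample, table$sample_ids),
                       .chrom_order(tasks$chromosome)), ]
  worker <- function(i) {
    tryCatch(run_sample(extract_signal(table, tasks$sample[i],
                                       tasks$chromosome[i]), config),
             error = function(e)
               structure(list(sample = tasks$sample[i],
                              chromosome = tasks$chromosome[i],
                              message = conditionMessage(e)),
                         class = "cnvsbl_task_error"))
  }
  idx <- seq_len(nrow(tasks))
  segments <- if (config$n_workers > 1)
    parallel::mclapply(idx, worker, mc.cores = config$n_workers)
  else lapply(idx, worker)
  failed <- Filter(function(s) inherits(s, "cnvsbl_task_error"), segments)
  if (length(failed) > 0)
    stop("failed task(s):\n", paste(vapply(failed, function(f)
      sprintf("  %s chr%s: %s", f$sample, f$chromosome, f$message),
      character(1)), collapse = "\n"))
  summary <- summarize_cohort(segments, limits = config$limits,
                              length_base = config$length_base)
  mat <- build_cnv_matrix(segments, table$probes)
  reduced <- tryCatch(
    reduce_blocks(mat, var_simil = config$var_simil,
                  sub_variation = config$sub_variation),
    error = function(e) NULL)
  mc <- if (!is.null(reduced))
    tryCatch(mca(reduced, n_axes = config$n_axes),
             error = function(e) NULL) else NULL
  assoc <- NULL
  if (!is.null(phenotype) && !is.null(reduced)) {
    covs <- covariates
    if (!is.null(mc)) {
      axes <- as.data.frame(mc$scores)
      names(axes) <- paste0("MCA", seq_len(ncol(axes)))
      covs <- if (is.null(covs)) axes else cbind(covs, axes)
    }
    assoc <- multi_cnv_assoc(phenotype, reduced, covs)
  }
  if (!is.null(config$out_dir)) {
    od <- config$out_dir
    dir.create(od, showWarnings = FALSE, recursive = TRUE)
    for (s in unique(vapply(segments, function(x) x$sample_id,
                            character(1))))
      write_segment_table(
        Filter(function(x) x$sample_id == s, segments),
        file.path(od, sprintf("segments_%s.tsv",
                              gsub("[^A-Za-z0-9_.-]", "_", s))))
    if (!is.null(reduced))
      write_cnv_matrix(reduced, file.path(od, "cnv_matrix.tsv"))
    if (!is.null(mc))
      write.table(data.frame(subject = rownames(mc$scores), mc$scores),
                  file.path(od, "mca_scores.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
    if (!is.null(assoc))
      write.table(assoc, file.path(od, "association.tsv"), sep = "\t",
                  quote = FALSE, row.names = FALSE)
  }
  list(segments = segments, summary = summary, matrix = mat,
       reduced = reduced, mca = mc, assoc = assoc)
}
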