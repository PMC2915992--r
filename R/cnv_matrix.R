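# Subjects x markers categorical matrix of CNV calls and its reduction
# to recurrent CNV blocks.

#' Build the subjects x markers CNV call matrix
#'
#' Expands each subject's classified segmentation to a per-probe state
#' vector, coded Loss = -1, Neutral = 0, Gain = +1.  All subjects must
#' have been segmented against the same probe index, and each subject's
#' segments must tile every chromosome's probes exactly.
#'
#' @param all_segments list of classified \code{SegmentSet}s (one or more
#'   per subject; multiple chromosomes per subject are combined).
#' @param probe_index data.frame with columns \code{name},
#'   \code{chromosome}, \code{position} (e.g. \code{table$probes}).
#' @return an object of class \code{CNVMatrix}: list with \code{values}
#'   (integer matrix, subjects in rows), \code{markers} (the probe
#'   index) and \code{blocks} (\code{NULL} until \code{reduce_blocks}).
#' @export
build_cnv_matrix <- function(all_segments, probe_index) {
  stopifnot(is.data.frame(probe_index),
            all(c("name", "chromosome", "position") %in% names(probe_index)))
  if (inherits(all_segments, "SegmentSet"))
    all_segments <- list(all_segments)
  samples <- unique(vapply(all_segments, function(s) s$sample_id,
                           character(1)))
  n <- length(samples)
  m <- nrow(probe_index)
  vals <- matrix(NA_integer_, n, m,
                 dimnames = list(samples, probe_index$name))
  code <- c(Loss = -1L, Neutral = 0L, Gain = 1L)
  chrom_cols <- split(seq_len(m), probe_index$chromosome)
  for (s in all_segments) {
    cols <- chrom_cols[[s$chromosome]]
    if (is.null(cols) || length(cols) != s$M)
      stop("segment set for sample ", s$sample_id, " chromosome ",
           s$chromosome, " does not match the probe index")
    if (any(is.na(s$segments$state)))
      stop("unclassified segments for sample ", s$sample_id,
           "; run classify_segments first")
    st <- rep(code[s$segments$state], s$segments$n_probes)
    if (length(st) != length(cols))
      stop("segments do not tile chromosome ", s$chromosome,
           " for sample ", s$sample_id)
    vals[s$sample_id, cols] <- st
  }
  if (anyNA(vals))
    stop("some probes are not covered by any segment; segmentation must ",
         "tile the probe index for every subject")
  structure(list(values = vals, markers = probe_index, blocks = NULL),
            class = "CNVMatrix")
}

#' @export
print.CNVMatrix <- function(x, ...) {
  cat(sprintf("CNVMatrix: %d subjects x %d markers%s\n",
              nrow(x$values), ncol(x$values),
              if (is.null(x$blocks)) "" else
                sprintf(" (%d blocks)", nrow(x$blocks))))
  invisible(x)
}

#' Reduce a CNV matrix to recurrent CNV blocks
#'
#' Markers whose minor category frequency (fraction of subjects differing
#' from the modal value) is below \code{1 - sub_variation} are first
#' discarded as non-recurrent.  The remaining markers are then grouped by
#' a greedy left-to-right scan within each chromosome: a block grows
#' while the proportion of subjects whose call at the candidate column
#' equals their call at the block's first column is at least
#' \code{var_simil}; each block is represented by its first column.
#' Filtering before grouping makes the reduction idempotent at fixed
#' parameters.
#'
#' @param x a \code{CNVMatrix}.
#' @param var_simil agreement proportion for merging, in (0, 1]
#'   (default 0.99).
#' @param sub_variation recurrence parameter in (0, 1] (default 0.90):
#'   blocks varying in fewer than \code{1 - sub_variation} of subjects
#'   are dropped.
#' @return a reduced \code{CNVMatrix}; \code{blocks} maps each retained
#'   block to its marker range and representative probe.
#' @export
reduce_blocks <- function(x, var_simil = 0.99, sub_variation = 0.90) {
  stopifnot(inherits(x, "CNVMatrix"))
  if (!(var_simil > 0 && var_simil <= 1)) stop("var_simil must be in (0,1]")
  if (!(sub_variation > 0 && sub_variation <= 1))
    stop("sub_variation must be in (0,1]")
  v <- x$values
  n <- nrow(v)
  minor <- apply(v, 2, function(col) 1 - max(tabulate(col + 2L, 3L)) / n)
  varying <- which(minor >= (1 - sub_variation))
  if (length(varying) == 0) stop("no recurrent blocks retained")
  blocks <- list()
  for (chrom in unique(x$markers$chromosome)) {
    cols <- varying[x$markers$chromosome[varying] == chrom]
    if (length(cols) == 0) next
    first <- cols[1]
    start <- cols[1]
    prev <- cols[1]
    for (j in cols[-1]) {
      agree <- mean(v[, first] == v[, j])
      if (agree >= var_simil) { prev <- j; next }
      blocks[[length(blocks) + 1]] <- c(start, prev, first)
      first <- j; start <- j; prev <- j
    }
    blocks[[length(blocks) + 1]] <- c(start, prev, first)
  }
  b <- do.call(rbind, blocks)
  rep_col <- b[, 3]
  blocks_df <- data.frame(
    block_id = seq_along(rep_col),
    chromosome = x$markers$chromosome[rep_col],
    start_bp = x$markers$position[b[, 1]],
    end_bp = x$markers$position[b[, 2]],
    representative = x$markers$name[rep_col],
    n_markers = b[, 2] - b[, 1] + 1L,
    stringsAsFactors = FALSE)
  vals <- v[, rep_col, drop = FALSE]
  colnames(vals) <- blocks_df$representative
  structure(list(values = vals,
                 markers = x$markers[rep_col, , drop = FALSE],
                 blocks = blocks_df),
            class = "CNVMatrix")
}

#' Read back a CNV matrix written by \code{write_cnv_matrix}
#' @param path path of the subjects x blocks table; block definitions
#'   are read from \code{paste0(path, ".blocks")} when present.
#' @return a \code{CNVMatrix}.
#' @export
read_cnv_matrix <- function(path) {
  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  vals <- as.matrix(d[, -1, drop = FALSE])
  storage.mode(vals) <- "integer"
  rownames(vals) <- d[[1]]
  bp <- paste0(path, ".blocks")
  blocks <- NULL
  markers <- data.frame(name = colnames(vals),
                        chromosome = "1",
                        position = seq_len(ncol(vals)),
                        stringsAsFactors = FALSE)
  if (file.exists(bp)) {
    blocks <- read.delim(bp, stringsAsFactors = FALSE,
                         colClasses = c(chromosome = "character"))
    markers <- data.frame(name = blocks$representative,
                          chromosome = blocks$chromosome,
                          position = blocks$start_bp,
                          stringsAsFactors = FALSE)
  }
  structure(list(values = vals, markers = markers, blocks = blocks),
            class = "CNVMatrix")
}

#' Write a reduced CNV matrix and its block definitions
#' @param x a \code{CNVMatrix}.
#' @param path output path for the subjects x blocks table; block
#'   definitions go to \code{paste0(path, ".blocks")} when present.
#' @return \code{path}, invisibly.
#' @export
write_cnv_matrix <- function(x, path) {
  stopifnot(inherits(x, "CNVMatrix"))
  out <- data.frame(subject = rownames(x$values), x$values,
                    check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(x$blocks))
    write.table(x$blocks, paste0(path, ".blocks"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  invisible(path)
}
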