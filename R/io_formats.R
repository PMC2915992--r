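# Probe-table input/output: BeadStudio-style, GTC3-style and generic
# tab-delimited log2-ratio tables; per-sample splitting; BED and segment
# table export.  Internal coordinates are 1-based inclusive; BED output is
# 0-based half-open.

.normalize_chrom <- function(x) {
  x <- sub("^chr", "", as.character(x), ignore.case = TRUE)
  x <- toupper(x)
  ok <- x %in% c(as.character(1:22), "X", "Y")
  if (!all(ok))
    stop("unrecognized chromosome label(s): ",
         paste(unique(x[!ok]), collapse = ", "))
  x
}

.chrom_order <- function(x) match(x, c(as.character(1:22), "X", "Y"))

#' Construct a per-sample, per-chromosome probe signal
#'
#' The elementary unit the segmentation consumes: one sample's log2 ratios
#' on one chromosome at strictly increasing positions.
#'
#' @param sample_id sample identifier.
#' @param chromosome chromosome label (1..22, X, Y; "chr" prefix allowed).
#' @param probe_names character vector of probe names.
#' @param positions 1-based base-pair positions, strictly increasing.
#' @param y numeric log2 ratios, finite, same length as \code{positions}.
#' @param has_positions logical; \code{FALSE} when positions are
#'   consecutive pseudo-coordinates (positionless generic input).
#' @return an object of class \code{ProbeSignal}.
#' @export
probe_signal <- function(sample_id, chromosome, probe_names, positions, y,
                         has_positions = TRUE) {
  chromosome <- .normalize_chrom(chromosome)
  positions <- as.numeric(positions)
  y <- as.numeric(y)
  if (length(positions) != length(y) || length(probe_names) != length(y))
    stop("probe_names, positions and y must have equal length")
  if (any(!is.finite(y)))
    stop("non-finite log2 ratios in ProbeSignal; drop them at read time")
  if (length(positions) > 1 && any(diff(positions) <= 0))
    stop("positions must be strictly increasing within a chromosome")
  structure(list(sample_id = as.character(sample_id),
                 chromosome = chromosome,
                 probe_names = as.character(probe_names),
                 positions = positions, y = y,
                 has_positions = isTRUE(has_positions)),
            class = "ProbeSignal")
}

#' @export
print.ProbeSignal <- function(x, ...) {
  cat(sprintf("ProbeSignal: sample %s, chromosome %s, %d probes\n",
              x$sample_id, x$chromosome, length(x$y)))
  invisible(x)
}

.new_cohort_table <- function(probes, Y, sample_ids, n_dropped = 0L,
                              has_positions = TRUE) {
  stopifnot(nrow(probes) == nrow(Y), ncol(Y) == length(sample_ids))
  colnames(Y) <- sample_ids
  structure(list(probes = probes, Y = Y,
                 sample_ids = as.character(sample_ids),
                 n_dropped = as.integer(n_dropped),
                 has_positions = isTRUE(has_positions)),
            class = "CohortTable")
}

#' @export
print.CohortTable <- function(x, ...) {
  cat(sprintf("CohortTable: %d probes x %d samples (%d dropped at read)\n",
              nrow(x$probes), length(x$sample_ids), x$n_dropped))
  invisible(x)
}

# header alias table; gtc3 names are configuration, not a format claim
.dialect_aliases <- list(
  beadstudio = c(name = "Name", chr = "Chr", position = "Position"),
  gtc3       = c(name = "ProbeSet", chr = "Chromosome", position = "Position"),
  generic    = c(name = "Name", chr = "Chr", position = "Position"))

#' Read a probe-level log2-ratio table
#'
#' Reads a tab-delimited table whose first columns identify the probes
#' (name, chromosome, position) followed by one log2-ratio column per
#' sample.  The dialect is always explicit; it is never sniffed.
#'
#' Probes carrying a non-finite ratio in any sample are dropped (the count
#' is kept in the returned object and reported with a message): the
#' segmentation model assumes a dense vector per chromosome.
#'
#' @param path file path.
#' @param dialect one of \code{"beadstudio"}, \code{"gtc3"},
#'   \code{"generic"}.  Dialects only differ in the expected header names
#'   of the probe columns; \code{gtc3} names can be overridden via
#'   \code{aliases}.
#' @param has_positions if \code{FALSE} (generic dialect only) the table
#'   has no position column and consecutive integer pseudo-positions are
#'   assigned per chromosome.
#' @param aliases optional named character vector overriding the header
#'   names (\code{name}, \code{chr}, \code{position}).
#' @return a \code{CohortTable}.
#' @export
read_log2_table <- function(path,
                            dialect = c("beadstudio", "gtc3", "generic"),
                            has_positions = TRUE, aliases = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (!has_positions && dialect != "generic")
    stop("positionless input is only supported by the generic dialect")
  al <- .dialect_aliases[[dialect]]
  if (!is.null(aliases)) al[names(aliases)] <- aliases

  d <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  need <- if (has_positions) al[c("name", "chr", "position")] else
    al[c("name", "chr")]
  for (col in need)
    if (!col %in% names(d))
      stop(sprintf("malformed header: expected column '%s' (dialect %s)",
                   col, dialect))
  sample_cols <- setdiff(names(d), need)
  if (length(sample_cols) < 1) stop("no sample columns found")

  nm <- as.character(d[[al[["name"]]]])
  if (anyDuplicated(nm))
    stop("duplicated probe name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  chr <- .normalize_chrom(d[[al[["chr"]]]])
  if (has_positions) {
    pos <- as.numeric(d[[al[["position"]]]])
  } else {
    pos <- stats::ave(seq_along(chr), chr, FUN = seq_along)
  }

  Y <- as.matrix(d[sample_cols])
  storage.mode(Y) <- "double"
  keep <- rowSums(!is.finite(Y)) == 0
  n_dropped <- sum(!keep)
  if (n_dropped > 0)
    message(n_dropped, " probe(s) with non-finite ratios dropped")
  probes <- data.frame(name = nm, chromosome = chr, position = pos,
                       stringsAsFactors = FALSE)[keep, , drop = FALSE]
  Y <- Y[keep, , drop = FALSE]

  o <- order(.chrom_order(probes$chromosome), probes$position)
  probes <- probes[o, , drop = FALSE]
  Y <- Y[o, , drop = FALSE]
  rownames(probes) <- NULL
  for (cc in unique(probes$chromosome)) {
    p <- probes$position[probes$chromosome == cc]
    if (length(p) > 1 && any(diff(p) <= 0))
      stop("duplicated/non-increasing positions on chromosome ", cc)
  }
  .new_cohort_table(probes, Y, sample_cols, n_dropped, has_positions)
}

#' Write a cohort table in BeadStudio-style layout
#'
#' @param table a \code{CohortTable}.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_log2_table <- function(table, path) {
  stopifnot(inherits(table, "CohortTable"))
  out <- data.frame(Name = table$probes$name,
                    Chr = table$probes$chromosome,
                    Position = table$probes$position,
                    table$Y, check.names = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract one sample x chromosome signal from a cohort table
#'
#' @param table a \code{CohortTable}.
#' @param sample sample id.
#' @param chromosome chromosome label.
#' @return a \code{ProbeSignal}.
#' @export
extract_signal <- function(table, sample, chromosome) {
  stopifnot(inherits(table, "CohortTable"))
  chromosome <- .normalize_chrom(chromosome)
  if (!sample %in% table$sample_ids) stop("unknown sample: ", sample)
  i <- table$probes$chromosome == chromosome
  if (!any(i)) stop("no probes on chromosome ", chromosome)
  probe_signal(sample, chromosome, table$probes$name[i],
               table$probes$position[i], table$Y[i, sample],
               has_positions = table$has_positions)
}

#' Split a multi-sample table into one file per sample
#'
#' Creates \code{out_dir} (conventionally \code{rawData/}) with one
#' BeadStudio-layout file per sample, named \code{<sample_id>.txt}.
#'
#' @param table a \code{CohortTable}.
#' @param out_dir output directory.
#' @param overwrite allow writing into an existing non-empty directory.
#' @return character vector of file paths, one per sample.
#' @export
split_by_sample <- function(table, out_dir, overwrite = FALSE) {
  stopifnot(inherits(table, "CohortTable"))
  if (dir.exists(out_dir) && length(dir(out_dir)) > 0 && !overwrite)
    stop("directory ", out_dir, " is not empty; use overwrite = TRUE")
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (s in table$sample_ids) {
    fn <- file.path(out_dir, paste0(gsub("[^A-Za-z0-9_.-]", "_", s), ".txt"))
    out <- data.frame(Name = table$probes$name,
                      Chr = table$probes$chromosome,
                      Position = table$probes$position,
                      y = table$Y[, s], check.names = FALSE)
    names(out)[4] <- s
    write.table(out, fn, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, fn)
  }
  paths
}

.segments_as_df <- function(segments) {
  if (inherits(segments, "SegmentSet")) segments <- list(segments)
  do.call(rbind, lapply(segments, function(s) {
    stopifnot(inherits(s, "SegmentSet"))
    if (nrow(s$segments) == 0) return(NULL)
    data.frame(sample = s$sample_id, chromosome = s$chromosome,
               s$segments, has_positions = s$has_positions,
               stringsAsFactors = FALSE)
  }))
}

#' Export altered segments in BED format
#'
#' Gain/Loss segments only; 1-based inclusive internal coordinates are
#' converted to BED's 0-based half-open convention and a "chr" prefix is
#' added.
#'
#' @param segments a \code{SegmentSet} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
export_bed <- function(segments, path) {
  d <- .segments_as_df(segments)
  if (!is.null(d) && any(!d$has_positions))
    stop("segments lack genomic positions; BED export is undefined")
  con <- file(path, "w")
  on.exit(close(con))
  if (is.null(d)) return(invisible(path))
  d <- d[d$state %in% c("Gain", "Loss"), , drop = FALSE]
  if (nrow(d) == 0) return(invisible(path))
  lines <- sprintf("chr%s\t%d\t%d\t%s", d$chromosome,
                   as.integer(d$start_bp) - 1L, as.integer(d$end_bp),
                   paste0(d$sample, ":", d$state))
  writeLines(lines, con)
  invisible(path)
}

#' Write a tab-delimited segment table
#'
#' Columns: sample, chromosome, start probe name, start/end bp, number of
#' probes, mean log2 ratio and state (\code{Loss}/\code{Neutral}/
#' \code{Gain}).
#'
#' @param segments a \code{SegmentSet} or list of them.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
write_segment_table <- function(segments, path) {
  d <- .segments_as_df(segments)
  if (is.null(d))
    d <- data.frame(sample = character(0), chromosome = character(0),
                    start_probe = character(0), start_bp = numeric(0),
                    end_bp = numeric(0), n_probes = integer(0),
                    amplitude = numeric(0), state = character(0))
  out <- d[c("sample", "chromosome", "start_probe", "start_bp", "end_bp",
             "n_probes", "amplitude", "state")]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read back a segment table written by \code{write_segment_table}
#' @param path file path.
#' @return a data.frame.
#' @export
read_segment_table <- function(path) {
  read.delim(path, stringsAsFactors = FALSE,
             colClasses = c(chromosome = "character"))
}
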