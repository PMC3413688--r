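#' Sample-by-VT community matrix
#'
#' Container for a community abundance table over virtual taxa (VT), the
#' SSU rRNA sequence-based operational taxa used for closed-reference
#' assignment of AMF amplicon reads.  Rows are samples, columns VT.  A
#' matrix is either in `"counts"` mode (non-negative integers, raw
#' assigned-read counts) or `"proportions"` mode (rows sum to 1, the
#' proportional composition used for all dissimilarity-based analyses).
#'
#' @param values numeric matrix with sample rownames and VT colnames.
#' @param metadata optional data.frame describing the sampling design; must
#'   contain a `sample_id` column covering every row of `values`.  Typical
#'   columns: `plot`, `grid_point`, `date` (Date), `x_m`, `y_m`.
#' @param mode `"counts"` or `"proportions"`.
#' @return object of class `community_matrix`: a list with elements
#'   `values`, `mode`, `metadata`.
#' @export
community_matrix <- function(values, metadata = NULL,
                             mode = c("counts", "proportions")) {
  mode <- match.arg(mode)
  values <- as.matrix(values)
  if (is.null(rownames(values)))
    stop("community matrix needs sample rownames")
  if (ncol(values) > 0 && is.null(colnames(values)))
    stop("community matrix needs VT colnames")
  if (anyDuplicated(rownames(values)))
    stop("duplicated sample ids")
  if (any(values < 0) || any(!is.finite(values)))
    stop("abundances must be finite and non-negative")
  if (mode == "counts" && any(abs(values - round(values)) > 1e-8))
    stop("counts mode requires integer values")
  if (mode == "proportions") {
    rs <- rowSums(values)
    bad <- rs > 0 & abs(rs - 1) > 1e-9
    if (any(bad))
      stop("proportions mode: rows do not sum to 1: ",
           paste(rownames(values)[bad], collapse = ", "))
  }
  if (!is.null(metadata)) {
    metadata <- as.data.frame(metadata)
    if (!"sample_id" %in% names(metadata))
      stop("metadata needs a 'sample_id' column")
    if (anyDuplicated(metadata$sample_id))
      stop("duplicated sample_id in metadata")
    missing <- setdiff(rownames(values), metadata$sample_id)
    if (length(missing))
      stop("samples absent from metadata: ", paste(missing, collapse = ", "))
    metadata <- metadata[match(rownames(values), metadata$sample_id), ,
                         drop = FALSE]
    rownames(metadata) <- metadata$sample_id
  }
  structure(list(values = values, mode = mode, metadata = metadata),
            class = "community_matrix")
}

#' @export
dim.community_matrix <- function(x) dim(x$values)

#' @export
as.matrix.community_matrix <- function(x, ...) x$values

#' @export
print.community_matrix <- function(x, ...) {
  cat(sprintf("community_matrix: %d samples x %d VT (%s)\n",
              nrow(x$values), ncol(x$values), x$mode))
  if (x$mode == "counts")
    cat(sprintf("  reads: total %d, per-sample range %d-%d\n",
                as.integer(sum(x$values)),
                as.integer(min(rowSums(x$values))),
                as.integer(max(rowSums(x$values)))))
  if (!is.null(x$metadata))
    cat("  metadata:", paste(names(x$metadata), collapse = ", "), "\n")
  invisible(x)
}

#' Subset a community matrix by sample
#'
#' @param m community_matrix.
#' @param samples character vector of sample ids to keep (order preserved).
#' @return community_matrix restricted to `samples`.
#' @export
subset_samples <- function(m, samples) {
  stopifnot(inherits(m, "community_matrix"))
  missing <- setdiff(samples, rownames(m$values))
  if (length(missing))
    stop("unknown samples: ", paste(missing, collapse = ", "))
  community_matrix(m$values[samples, , drop = FALSE],
                   metadata = if (!is.null(m$metadata))
                     m$metadata[samples, , drop = FALSE],
                   mode = m$mode)
}

#' Build a count matrix from read-to-VT assignments
#'
#' Tabulates assigned reads into a samples x VT count matrix.  Every sample
#' present in `design` gets a row, including samples with zero assigned
#' reads (they are only dropped later, by [filter_matrix()]).
#'
#' @param assignments data.frame with columns `read_id`, `sample_id`,
#'   `vt_id`; rows with `NA` vt_id (unassigned reads) are ignored.
#' @param design data.frame of sample metadata with a `sample_id` column.
#' @return community_matrix in counts mode.
#' @export
build_matrix <- function(assignments, design) {
  design <- as.data.frame(design)
  if (!"sample_id" %in% names(design))
    stop("design needs a 'sample_id' column")
  a <- assignments[!is.na(assignments$vt_id), , drop = FALSE]
  unknown <- setdiff(unique(a$sample_id), design$sample_id)
  if (length(unknown))
    stop("assignments refer to samples absent from design: ",
         paste(unknown, collapse = ", "))
  samples <- as.character(design$sample_id)
  vts <- sort(unique(as.character(a$vt_id)))
  if (nrow(a)) {
    tab <- table(factor(a$sample_id, levels = samples),
                 factor(a$vt_id, levels = vts))
    counts <- matrix(as.integer(tab), nrow = length(samples),
                     dimnames = list(samples, vts))
  } else {
    counts <- matrix(0L, nrow = length(samples), ncol = 0,
                     dimnames = list(samples, NULL))
  }
  community_matrix(counts, metadata = design, mode = "counts")
}

#' Filter a count matrix by sample depth and VT prevalence
#'
#' Removes samples whose assigned-read total falls below
#' `min_sample_hits`, and (optionally) singleton VT.  A singleton VT is,
#' by default, a taxon represented by exactly one read in the whole
#' matrix (`singleton = "reads"`); `singleton = "samples"` instead treats
#' occurrence in exactly one sample as singleton status.  Sample and VT
#' filters are iterated to a fixed point so the result does not depend on
#' application order; VT left with zero reads after sample removal are
#' dropped as unobserved.  A removal log is attached as attribute
#' `"removal_log"`.
#'
#' @param m community_matrix in counts mode.
#' @param min_sample_hits minimum assigned reads for a sample to be kept.
#' @param drop_singleton_vt drop singleton VT?
#' @param singleton singleton definition, `"reads"` (total count 1) or
#'   `"samples"` (present in one sample).
#' @return filtered community_matrix (counts).
#' @export
filter_matrix <- function(m, min_sample_hits = 10, drop_singleton_vt = TRUE,
                          singleton = c("reads", "samples")) {
  stopifnot(inherits(m, "community_matrix"))
  if (m$mode != "counts") stop("filter_matrix expects a counts matrix")
  singleton <- match.arg(singleton)
  x <- m$values
  log <- data.frame(entity = character(), type = character(),
                    reason = character(), stringsAsFactors = FALSE)
  repeat {
    rs <- rowSums(x)
    drop_s <- rs < min_sample_hits
    if (any(drop_s)) {
      log <- rbind(log, data.frame(entity = rownames(x)[drop_s],
                                   type = "sample", reason = "low_count"))
      x <- x[!drop_s, , drop = FALSE]
      if (!nrow(x)) stop("all samples removed by depth filter")
      next
    }
    cs <- colSums(x)
    if (drop_singleton_vt) {
      single <- if (singleton == "reads") cs == 1 else colSums(x > 0) == 1
    } else single <- rep(FALSE, ncol(x))
    unobserved <- cs == 0
    drop_v <- single | unobserved
    if (any(drop_v)) {
      log <- rbind(log, data.frame(
        entity = colnames(x)[drop_v], type = "vt",
        reason = ifelse(unobserved[drop_v], "unobserved", "singleton")))
      x <- x[, !drop_v, drop = FALSE]
      next
    }
    break
  }
  out <- community_matrix(x,
                          metadata = if (!is.null(m$metadata))
                            m$metadata[rownames(x), , drop = FALSE],
                          mode = "counts")
  attr(out, "removal_log") <- log
  out
}

#' Normalise a count matrix to proportional composition
#'
#' Divides each cell by its row total so that every sample's VT profile
#' sums to one.
#'
#' @param m community_matrix in counts mode.
#' @return community_matrix in proportions mode.
#' @export
normalise <- function(m) {
  stopifnot(inherits(m, "community_matrix"))
  x <- m$values
  rs <- rowSums(x)
  if (any(rs == 0))
    stop("cannot normalise zero-read sample(s): ",
         paste(rownames(x)[rs == 0], collapse = ", "))
  community_matrix(x / rs, metadata = m$metadata, mode = "proportions")
}

#' Read / write community matrices and design tables
#'
#' TSV interchange: the matrix file has samples in rows (first column
#' `sample_id`) and VT in columns; the design file has one row per sample
#' with ISO-8601 dates.
#'
#' @param path file path.
#' @param metadata optional design data.frame or path to a design TSV.
#' @param mode matrix mode, `"counts"` or `"proportions"`.
#' @return `read_community_matrix`: a community_matrix;
#'   `read_design`: a data.frame with `date` parsed to Date.
#' @export
read_community_matrix <- function(path, metadata = NULL, mode = "counts") {
  tab <- utils::read.delim(path, check.names = FALSE,
                           stringsAsFactors = FALSE)
  if (names(tab)[1] != "sample_id")
    stop("matrix TSV must start with a 'sample_id' column")
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab$sample_id
  if (is.character(metadata)) metadata <- read_design(metadata)
  community_matrix(vals, metadata = metadata, mode = mode)
}

#' @rdname read_community_matrix
#' @param m community_matrix to write.
#' @export
write_community_matrix <- function(m, path) {
  stopifnot(inherits(m, "community_matrix"))
  out <- data.frame(sample_id = rownames(m$values), m$values,
                    check.names = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname read_community_matrix
#' @export
read_design <- function(path) {
  d <- utils::read.delim(path, stringsAsFactors = FALSE)
  if (!"sample_id" %in% names(d))
    stop("design TSV needs a 'sample_id' column")
  if ("date" %in% names(d)) d$date <- as.Date(d$date)
  d
}
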