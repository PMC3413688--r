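#' Per-group sampling summary of a community matrix
#'
#' One row per plot-by-date group: number of samples, mean and range of
#' assigned reads per sample, and the number of VT observed in the group
#' (the union of taxa present in any member sample, not the sum of
#' per-sample richness).
#'
#' @param m community_matrix in counts mode with `plot` and `date`
#'   metadata.
#' @return data.frame with columns `plot`, `date`, `n_samples`,
#'   `mean_reads`, `min_reads`, `max_reads`, `n_vt`.
#' @export
summarise_by_group <- function(m) {
  stopifnot(inherits(m, "community_matrix"), m$mode == "counts")
  meta <- m$metadata
  if (is.null(meta) || !all(c("plot", "date") %in% names(meta)))
    stop("metadata with 'plot' and 'date' required")
  key <- interaction(meta$plot, as.character(meta$date), drop = TRUE)
  rows <- lapply(levels(key), function(k) {
    idx <- which(key == k)
    x <- m$values[idx, , drop = FALSE]
    rs <- rowSums(x)
    data.frame(plot = meta$plot[idx[1]],
               date = as.character(meta$date[idx[1]]),
               n_samples = length(idx),
               mean_reads = mean(rs),
               min_reads = min(rs), max_reads = max(rs),
               n_vt = sum(colSums(x) > 0),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out[order(out$plot, out$date), ]
}

#' Run the full study workflow
#'
#' Orchestrates the pipeline from whichever inputs are supplied:
#' either raw reads (`reads` + `barcodes`, demultiplexed first), or
#' payload reads plus alignment hits (`hits` + `reference`, assigned to
#' VT and tabulated), or a ready count matrix (`matrix`).  Later stages
#' are always run: depth/singleton filtering, normalisation, the group
#' summary, the spatial and seasonal PERMANOVA (the seasonal model in
#' both term orders), dispersion homogeneity checks for both groupings,
#' Poisson richness comparisons, spatial and temporal distance-decay
#' tests, and (optionally) the thinning study.
#'
#' @param matrix community_matrix in counts mode with design metadata, or
#'   `NULL` if building from reads/hits.
#' @param reads raw read data.frame (`read_id`, `sequence`), optional.
#' @param barcodes barcode map (required with `reads`).
#' @param hits alignment-hit data.frame (required unless `matrix` given).
#' @param reference named reference sequences (for subject lengths).
#' @param design sample metadata (required unless carried by `matrix`).
#' @param criteria a [match_criteria()].
#' @param min_length minimum payload length at demultiplexing.
#' @param min_sample_hits sample depth filter threshold.
#' @param n_perm permutations for PERMANOVA and decay tests.
#' @param thinning_n number of thinned matrices (0 = skip the study).
#' @param thinning_n_perm PERMANOVA permutations inside the thinning
#'   study.
#' @param seed seed recorded in the report and used for every randomised
#'   stage.
#' @return list of class `amf_report`.
#' @export
run_pipeline <- function(matrix = NULL, reads = NULL, barcodes = NULL,
                         hits = NULL, reference = NULL, design = NULL,
                         criteria = match_criteria(), min_length = 170,
                         min_sample_hits = 10, n_perm = 999,
                         thinning_n = 0, thinning_n_perm = 199,
                         seed = 1L) {
  report <- list(seed = seed)

  if (is.null(matrix)) {
    if (is.null(design)) stop("design metadata required")
    payload <- reads
    if (!is.null(barcodes)) {
      dm <- demultiplex(reads, barcodes, min_length = min_length)
      report$preprocess <- dm$stats
      payload <- dm$reads
    }
    if (is.null(hits) || is.null(reference))
      stop("hits and reference required to assign reads")
    qlen <- stats::setNames(payload$length, payload$read_id)
    slen <- stats::setNames(nchar(reference), names(reference))
    asg <- assign_reads(hits, qlen, slen, criteria)
    asg$sample_id <- payload$sample_id[match(asg$read_id, payload$read_id)]
    report$n_assigned <- sum(!is.na(asg$vt_id))
    matrix <- build_matrix(asg, design)
  }
  report$dims_unfiltered <- dim(matrix$values)
  filtered <- filter_matrix(matrix, min_sample_hits = min_sample_hits)
  report$dims_filtered <- dim(filtered$values)
  report$removal_log <- attr(filtered, "removal_log")
  report$matrix <- filtered
  report$group_summary <- summarise_by_group(filtered)

  prop <- normalise(filtered)
  meta <- filtered$metadata
  subsets <- study_subsets(meta)

  sp <- subsets$spatial
  msp <- meta[match(sp, meta$sample_id), ]
  dsp <- distance_matrix(subset_samples(prop, sp))
  report$spatial_permanova <- permanova(
    dsp, data.frame(Plot = msp$plot, row.names = msp$sample_id),
    n_perm = n_perm, seed = seed)
  report$spatial_dispersion <- dispersion_test(dsp, stats::setNames(
    factor(msp$plot), msp$sample_id))
  report$spatial_richness <- poisson_richness_test(
    sample_richness(subset_samples(filtered, sp)), msp$plot)
  report$spatial_decay <- decay_test(dsp, msp, "spatial",
                                     n_perm = n_perm, seed = seed + 1L)

  se <- subsets$seasonal
  mse <- meta[match(se, meta$sample_id), ]
  dse <- distance_matrix(subset_samples(prop, se))
  fac <- data.frame(Season = factor(as.character(mse$date)),
                    SampleID = factor(mse$grid_point),
                    row.names = mse$sample_id)
  report$seasonal_permanova <- permanova(dse, fac, n_perm = n_perm,
                                         seed = seed + 2L)
  report$seasonal_permanova_reversed <- permanova(
    dse, fac[, c("SampleID", "Season")], n_perm = n_perm, seed = seed + 3L)
  report$seasonal_dispersion <- dispersion_test(dse, stats::setNames(
    fac$Season, rownames(fac)))
  report$seasonal_richness <- poisson_richness_test(
    sample_richness(subset_samples(filtered, se)), fac$Season)
  report$temporal_decay <- decay_test(dse, mse, "temporal",
                                      n_perm = n_perm, seed = seed + 4L)

  if (thinning_n > 0)
    report$thinning <- thinning_study(filtered, n_matrices = thinning_n,
                                      n_perm = thinning_n_perm,
                                      seed = seed + 5L)
  class(report) <- "amf_report"
  report
}

#' @export
print.amf_report <- function(x, ...) {
  cat("=== AMF soil community analysis report (seed", x$seed, ") ===\n")
  if (!is.null(x$preprocess)) print(x$preprocess)
  cat(sprintf("matrix: %d x %d before filtering, %d x %d after\n",
              x$dims_unfiltered[1], x$dims_unfiltered[2],
              x$dims_filtered[1], x$dims_filtered[2]))
  cat("\n-- sampling summary --\n"); print(x$group_summary)
  cat("\n-- spatial model (plots, final date) --\n")
  print(x$spatial_permanova)
  print(x$spatial_dispersion)
  print(x$spatial_richness)
  print(x$spatial_decay)
  cat("\n-- seasonal model (repeat-sampled plot) --\n")
  print(x$seasonal_permanova)
  print(x$seasonal_dispersion)
  print(x$seasonal_richness)
  print(x$temporal_decay)
  if (!is.null(x$thinning)) { cat("\n"); print(x$thinning) }
  invisible(x)
}
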