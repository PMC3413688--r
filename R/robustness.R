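#' Thin a count matrix to a fixed per-sample depth
#'
#' Each sample's reads are subsampled without replacement to exactly
#' `depth` (multivariate hypergeometric per row), removing read-depth
#' differences between samples before re-analysis.
#'
#' @param m community_matrix in counts mode; every row sum must be at
#'   least `depth`.
#' @param depth target reads per sample.
#' @param seed optional RNG seed.
#' @return thinned community_matrix (counts), same dimensions.
#' @export
thin_matrix <- function(m, depth, seed = NULL) {
  stopifnot(inherits(m, "community_matrix"), m$mode == "counts")
  x <- m$values
  rs <- rowSums(x)
  if (any(rs < depth))
    stop("sample(s) below target depth ", depth, ": ",
         paste(rownames(x)[rs < depth], collapse = ", "))
  if (!is.null(seed)) set.seed(seed)
  out <- x
  for (i in seq_len(nrow(x))) {
    if (rs[i] == depth) next
    pool <- rep.int(seq_len(ncol(x)), x[i, ])
    kept <- sample(pool, depth)
    out[i, ] <- tabulate(kept, nbins = ncol(x))
  }
  community_matrix(out, metadata = m$metadata, mode = "counts")
}

# identify the study's two analysis subsets from the sampling design:
# spatial = all plots on the final collection date; seasonal = the
# plot(s) sampled on more than one date
study_subsets <- function(metadata) {
  if (is.null(metadata) || !all(c("plot", "date") %in% names(metadata)))
    stop("metadata with 'plot' and 'date' columns required")
  final_date <- max(metadata$date)
  spatial <- metadata$sample_id[metadata$date == final_date]
  multi <- names(which(tapply(metadata$date, metadata$plot,
                              function(d) length(unique(d))) > 1))
  seasonal <- metadata$sample_id[metadata$plot %in% multi]
  list(spatial = as.character(spatial), seasonal = as.character(seasonal),
       seasonal_plots = multi, final_date = final_date)
}

run_thinned_analyses <- function(mt, meta, subsets, n_perm, eps = 1e-3) {
  prop <- normalise(mt)
  res <- list(p_spatial = NA_real_, p_season = NA_real_,
              p_sampleid = NA_real_,
              slope_spatial = NA_real_, slope_temporal = NA_real_)
  sp <- subsets$spatial
  if (length(sp) >= 3) {
    dsp <- distance_matrix(subset_samples(prop, sp))
    msp <- meta[match(sp, meta$sample_id), ]
    pv <- permanova(dsp, data.frame(Plot = msp$plot,
                                    row.names = msp$sample_id),
                    n_perm = n_perm)
    res$p_spatial <- pv$table["Plot", "p_perm"]
    pr <- build_pairs(dsp, msp, "spatial")
    res$slope_spatial <- fit_decay(pr, eps = eps)$slope_logit
  }
  se <- subsets$seasonal
  if (length(se) >= 4) {
    dse <- distance_matrix(subset_samples(prop, se))
    mse <- meta[match(se, meta$sample_id), ]
    pv <- permanova(dse,
                    data.frame(Season = factor(mse$date),
                               SampleID = factor(mse$grid_point),
                               row.names = mse$sample_id),
                    n_perm = n_perm)
    res$p_season <- pv$table["Season", "p_perm"]
    res$p_sampleid <- pv$table["SampleID", "p_perm"]
    pr <- build_pairs(dse, mse, "temporal")
    res$slope_temporal <- fit_decay(pr, eps = eps)$slope_logit
  }
  res
}

#' Depth-equalisation (thinning) robustness study
#'
#' Repeats the main analyses on many randomly thinned copies of the final
#' count matrix, every sample equalised to a common depth (by default the
#' smallest row total).  For each thinned matrix the spatial PERMANOVA
#' (plots on the final date), the seasonal PERMANOVA (season + within-plot
#' sample identity in the repeatedly sampled plot) and the two
#' distance-decay slopes are recomputed; decay significance is not
#' re-assessed by permutation inside the study — only the slope signs are
#' recorded and summarised.  Sample and singleton filters are not
#' re-applied after thinning.
#'
#' @param m filtered community_matrix (counts) with design metadata.
#' @param n_matrices number of thinned matrices (default 1000).
#' @param depth common depth (default: minimum row sum).
#' @param alpha per-matrix significance threshold (default 0.05; both
#'   strict and non-strict counts are reported).
#' @param n_perm PERMANOVA permutations per thinned matrix (default 199,
#'   keeping the repetition affordable; use more for headline runs).
#' @param seed RNG seed for the whole study.
#' @return object of class `amf_thinning`: summary fractions plus the
#'   per-matrix record table.
#' @export
thinning_study <- function(m, n_matrices = 1000, depth = NULL, alpha = 0.05,
                           n_perm = 199, seed = NULL) {
  stopifnot(inherits(m, "community_matrix"), m$mode == "counts")
  meta <- m$metadata
  subsets <- study_subsets(meta)
  if (is.null(depth)) depth <- min(rowSums(m$values))
  if (!is.null(seed)) set.seed(seed)
  rec <- vector("list", n_matrices)
  for (b in seq_len(n_matrices)) {
    mt <- thin_matrix(m, depth)
    r <- run_thinned_analyses(mt, meta, subsets, n_perm)
    rec[[b]] <- data.frame(matrix = b, p_spatial = r$p_spatial,
                           p_season = r$p_season,
                           p_sampleid = r$p_sampleid,
                           slope_spatial = r$slope_spatial,
                           slope_temporal = r$slope_temporal)
  }
  rec <- do.call(rbind, rec)
  structure(list(
    n_matrices = n_matrices, depth = depth, alpha = alpha,
    n_perm = n_perm, seed = seed,
    frac_spatial_significant = mean(rec$p_spatial < alpha),
    frac_spatial_significant_le = mean(rec$p_spatial <= alpha),
    frac_seasonal_significant = mean(rec$p_season < alpha),
    frac_sampleid_significant = mean(rec$p_sampleid < alpha),
    frac_spatial_slope_negative = mean(rec$slope_spatial < 0),
    frac_temporal_slope_negative = mean(rec$slope_temporal < 0),
    records = rec),
    class = "amf_thinning")
}

#' @export
print.amf_thinning <- function(x, ...) {
  cat(sprintf("Thinning study: %d matrices at depth %d (alpha = %g, %d perms)\n",
              x$n_matrices, x$depth, x$alpha, x$n_perm))
  cat(sprintf("  spatial PERMANOVA significant: %.1f%% of matrices\n",
              100 * x$frac_spatial_significant))
  cat(sprintf("  seasonal PERMANOVA significant: %.1f%%\n",
              100 * x$frac_seasonal_significant))
  cat(sprintf("  spatial decay slope negative (similarity): %.1f%%\n",
              100 * x$frac_spatial_slope_negative))
  cat(sprintf("  temporal decay slope negative: %.1f%%\n",
              100 * x$frac_temporal_slope_negative))
  invisible(x)
}

#' Compare taxonomic assignments between two read-length sets
#'
#' Given best-hit assignments of the same reads at a reference length and
#' at a trimmed length, reports: the percentage of reads with identical
#' outcomes (no-hit on both sides counts as identical); the same
#' percentage after excluding reads unassigned in either set; trimmed-set
#' VT richness and its percentage of the reference richness; and, after
#' tabulating per-sample VT profiles, normalising them to proportions and
#' dropping samples with fewer than `min_sample_reads` assigned reads in
#' either set, the mean sample-wise Bray-Curtis dissimilarity and Pearson
#' correlation between the two sets (over the union VT set).
#'
#' @param reference_assignments named character vector, read_id to VT id
#'   (`NA` = no hit) at the reference length.
#' @param trimmed_assignments same, at the trimmed length; must cover the
#'   same reads.
#' @param sample_of named character vector, read_id to sample_id.
#' @param min_sample_reads per-sample minimum assigned reads for the
#'   profile comparison (default 10).
#' @return one-row data.frame of class `amf_trimcmp`.
#' @export
trim_compare <- function(reference_assignments, trimmed_assignments,
                         sample_of, min_sample_reads = 10) {
  ref <- reference_assignments
  trm <- trimmed_assignments
  sym <- c(setdiff(names(ref), names(trm)), setdiff(names(trm), names(ref)))
  if (length(sym))
    stop("read sets differ: ", paste(sym, collapse = ", "))
  trm <- trm[names(ref)]
  n <- length(ref)
  same <- (is.na(ref) & is.na(trm)) |
    (!is.na(ref) & !is.na(trm) & ref == trm)
  both_hit <- !is.na(ref) & !is.na(trm)
  n_identical <- sum(same)
  n_identical_nh <- sum(same & both_hit)

  rich_ref <- length(unique(ref[!is.na(ref)]))
  rich_trm <- length(unique(trm[!is.na(trm)]))

  vts <- sort(unique(c(ref[!is.na(ref)], trm[!is.na(trm)])))
  samples <- sort(unique(sample_of[names(ref)]))
  count_mat <- function(assign) {
    hit <- !is.na(assign)
    tab <- table(factor(sample_of[names(assign)[hit]], levels = samples),
                 factor(assign[hit], levels = vts))
    matrix(as.numeric(tab), nrow = length(samples),
           dimnames = list(samples, vts))
  }
  cr <- count_mat(ref)
  ct <- count_mat(trm)
  keep <- rowSums(cr) >= min_sample_reads & rowSums(ct) >= min_sample_reads
  mean_bc <- mean_r <- NA_real_
  if (any(keep)) {
    pr <- cr[keep, , drop = FALSE] / rowSums(cr[keep, , drop = FALSE])
    pt <- ct[keep, , drop = FALSE] / rowSums(ct[keep, , drop = FALSE])
    bcs <- vapply(seq_len(nrow(pr)),
                  function(i) bray_curtis(pr[i, ], pt[i, ]), numeric(1))
    # identical profiles correlate perfectly even when flat (zero variance)
    rr <- vapply(seq_len(nrow(pr)), function(i) {
      if (isTRUE(all.equal(pr[i, ], pt[i, ]))) return(1)
      if (stats::sd(pr[i, ]) == 0 || stats::sd(pt[i, ]) == 0)
        return(NA_real_)
      stats::cor(pr[i, ], pt[i, ])
    }, numeric(1))
    mean_bc <- mean(bcs)
    mean_r <- mean(rr, na.rm = TRUE)
  }
  out <- data.frame(
    n_reads_compared = n,
    n_identical = n_identical,
    identical_hit_pct = 100 * n_identical / n,
    n_identical_no_nohits = n_identical_nh,
    identical_hit_pct_no_nohits = 100 * n_identical_nh / sum(both_hit),
    richness = rich_trm,
    richness_pct_of_reference = 100 * rich_trm / rich_ref,
    n_samples_compared = sum(keep),
    mean_bc_to_reference = mean_bc,
    mean_pearson_r_to_reference = mean_r)
  class(out) <- c("amf_trimcmp", "data.frame")
  out
}
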