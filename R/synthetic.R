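#' Simulation configuration for the synthetic study
#'
#' Collects the parameters of the synthetic data generator, whose defaults
#' emulate the sampling structure the analysis pipeline expects: three
#' 10 x 10 m forest plots with a 3 x 3 sampling grid at 5 m spacing, one
#' plot revisited on four collection dates across a growing season and the
#' other two sampled on the final date only; 37 virtual taxa; per-sample
#' assigned-read depths spanning 13-1986; about 5.8% of raw reads
#' assignable to AMF; read lengths 170-557 nt with median near 382; plot
#' level compositional differences, no seasonal effect, and a weak
#' logit-scale spatial decay of community similarity.
#'
#' @param n_vt number of virtual taxa in the reference (default 37).
#' @param n_plots number of plots (default 3; the first is revisited).
#' @param grid_spacing grid spacing within a plot, metres (default 5).
#' @param plot_offsets list of (x, y) plot origins in metres; the default
#'   places the three plots at the corners of a triangle of side 40 m so
#'   that the largest pairwise sample distance is about 50 m.
#' @param dates collection dates; the first plot is sampled on all of
#'   them, the others on the last.
#' @param plot_effect_size SD of plot-specific log-abundance shifts
#'   (0 = no plot effect).
#' @param season_effect_size SD of date-specific log-abundance shifts
#'   (default 0: communities are temporally stable).
#' @param spatial_decay_beta target logit-similarity decay slope per
#'   metre (negative; default -0.011).
#' @param spatial_range range of the Gaussian spatial correlation of
#'   log-abundance fields, metres.
#' @param theta Dirichlet concentration of sample compositions about the
#'   local expected composition (smaller = more overdispersion).
#' @param sigma_log_mean SD of the baseline VT log-abundance means
#'   (controls dominance structure and so per-sample richness).
#' @param depth_range range of assigned reads per retained sample
#'   (default c(13, 1986); depths are drawn log-uniformly).
#' @param n_low_depth number of failed samples drawn with < 10 assigned
#'   reads, to be removed by the depth filter (default 10).
#' @param amf_read_fraction fraction of raw reads that are AMF-derived
#'   (default 0.058).
#' @param read_length c(min, max, median) of read lengths in nt.
#' @param read_length_sd SD of the (truncated normal) read length draw.
#' @param error_rate per-base substitution error rate of simulated reads.
#' @param ref_length reference amplicon length, nt.
#' @param divergence minimum pairwise dissimilarity between reference
#'   sequences, percent.
#' @param n_decoy_templates size of the shuffled-sequence decoy pool used
#'   for non-target reads.
#' @param seed integer seed making the whole generation deterministic.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_vt = 37, n_plots = 3, grid_spacing = 5,
                       plot_offsets = list(c(0, 0), c(40, 0),
                                           c(20, 34.641)),
                       dates = as.Date(c("2009-05-25", "2009-06-30",
                                         "2009-07-22", "2009-09-03")),
                       plot_effect_size = 0.75, season_effect_size = 0,
                       spatial_decay_beta = -0.002, spatial_range = 20,
                       theta = 4, sigma_log_mean = 1.3,
                       depth_range = c(13, 1986), n_low_depth = 10,
                       amf_read_fraction = 0.058,
                       read_length = c(min = 170, max = 557, median = 382),
                       read_length_sd = 90,
                       error_rate = 0, ref_length = 520, divergence = 10,
                       n_decoy_templates = 20, seed = 1L) {
  cfg <- list(n_vt = n_vt, n_plots = n_plots, grid_spacing = grid_spacing,
              plot_offsets = plot_offsets, dates = as.Date(dates),
              plot_effect_size = plot_effect_size,
              season_effect_size = season_effect_size,
              spatial_decay_beta = spatial_decay_beta,
              spatial_range = spatial_range, theta = theta,
              sigma_log_mean = sigma_log_mean,
              depth_range = depth_range, n_low_depth = n_low_depth,
              amf_read_fraction = amf_read_fraction,
              read_length = read_length, read_length_sd = read_length_sd,
              error_rate = error_rate, ref_length = ref_length,
              divergence = divergence,
              n_decoy_templates = n_decoy_templates,
              seed = as.integer(seed))
  stopifnot(cfg$n_vt >= 2, cfg$depth_range[1] >= 1,
            cfg$amf_read_fraction > 0, cfg$amf_read_fraction <= 1,
            cfg$error_rate >= 0, cfg$error_rate < 1,
            cfg$plot_effect_size >= 0, cfg$season_effect_size >= 0,
            length(cfg$plot_offsets) >= cfg$n_plots)
  class(cfg) <- "sim_config"
  cfg
}

#' Sampling design of the synthetic study
#'
#' @param cfg a [sim_config()].
#' @return data.frame with `sample_id`, `plot`, `grid_point` (1-9),
#'   `date`, `x_m`, `y_m`; the first plot appears on every date, the
#'   others on the final date only.
#' @export
study_design <- function(cfg) {
  plots <- LETTERS[seq_len(cfg$n_plots)]
  gx <- rep(0:2 * cfg$grid_spacing, times = 3)
  gy <- rep(0:2 * cfg$grid_spacing, each = 3)
  rows <- list()
  for (p in seq_along(plots)) {
    pdates <- if (p == 1) cfg$dates else cfg$dates[length(cfg$dates)]
    off <- cfg$plot_offsets[[p]]
    for (d in as.character(pdates)) {
      rows[[length(rows) + 1]] <- data.frame(
        plot = plots[p], grid_point = 1:9, date = as.Date(d),
        x_m = off[1] + gx, y_m = off[2] + gy)
    }
  }
  out <- do.call(rbind, rows)
  out <- data.frame(sample_id = sprintf("S%02d", seq_len(nrow(out))), out,
                    stringsAsFactors = FALSE)
  rownames(out) <- out$sample_id
  out
}

random_dna <- function(n, len) {
  vapply(seq_len(n), function(i)
    paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
          collapse = ""), character(1))
}

pairwise_identity <- function(seqs) {
  chars <- lapply(seqs, function(s) strsplit(s, "")[[1]])
  n <- length(seqs)
  out <- matrix(100, n, n)
  if (n > 1) {
    for (i in 1:(n - 1)) for (j in (i + 1):n) {
      id <- 100 * mean(chars[[i]] == chars[[j]])
      out[i, j] <- out[j, i] <- id
    }
  }
  out
}

#' Generate a synthetic VT reference database
#'
#' Produces `n_vt` random reference amplicon sequences whose pairwise
#' identity is verified (by exhaustive comparison) to be at most
#' `100 - divergence` percent, so that closed-reference assignment at the
#' 97% identity threshold is unambiguous whenever read error rates are
#' small relative to the divergence.  This is a synthetic stand-in for a
#' curated VT reference database; it carries no biological sequence
#' signal.
#'
#' @param n_vt number of reference sequences.
#' @param seq_length sequence length, nt.
#' @param divergence minimum pairwise dissimilarity, percent.
#' @param seed optional RNG seed.
#' @return named character vector of sequences (`VT00001`, ...).
#' @export
make_reference <- function(n_vt, seq_length = 520, divergence = 10,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (divergence <= 0 || divergence >= 75)
    stop("divergence infeasible for random sequences (need 0 < d < 75)")
  seqs <- random_dna(n_vt, seq_length)
  for (try in 1:50) {
    idm <- pairwise_identity(seqs)
    diag(idm) <- 0
    bad <- which(apply(idm, 1, max) > 100 - divergence)
    if (!length(bad)) break
    seqs[bad] <- random_dna(length(bad), seq_length)
  }
  idm <- pairwise_identity(seqs); diag(idm) <- 0
  if (max(idm) > 100 - divergence)
    stop("could not achieve requested reference divergence")
  names(seqs) <- sprintf("VT%05d", seq_len(n_vt))
  seqs
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1
  g / sum(g)
}

# calibration constant mapping the target logit decay slope to the SD of
# the spatially correlated log-abundance field: sd = sqrt(-beta * kappa).
# kappa was fixed once by simulating the generator (plot effect off)
# across a grid of field SDs and regressing fitted final-date decay
# slopes on sd^2.
.kappa_spatial <- 39

#' Simulate true community compositions over the sampling design
#'
#' Per-sample expected compositions come from VT log-abundance scores:
#' a common baseline (normal, SD `sigma_log_mean`), plot-specific shifts
#' (SD `plot_effect_size`), date-specific shifts (SD
#' `season_effect_size`, zero by default) and, per VT, a spatially
#' autocorrelated Gaussian field over the sample coordinates (Gaussian
#' correlation with range `spatial_range`; field SD calibrated so the
#' expected fitted logit decay slope approximates `spatial_decay_beta`).
#' Scores are softmax-transformed and realised compositions drawn from a
#' Dirichlet with concentration `theta`, giving compositional
#' overdispersion around the local expectation.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `proportions` (community_matrix, proportions mode,
#'   with design metadata) and `design` (the metadata data.frame).
#' @export
simulate_communities <- function(cfg, seed = NULL) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  design <- study_design(cfg)
  n <- nrow(design)
  V <- cfg$n_vt

  base <- stats::rnorm(V, 0, cfg$sigma_log_mean)
  plots <- unique(design$plot)
  # random direction, fixed per-VT root-mean-square magnitude: every plot
  # shift has the same effective size, only its orientation varies
  plot_eff <- matrix(stats::rnorm(length(plots) * V),
                     nrow = length(plots), dimnames = list(plots, NULL))
  if (cfg$plot_effect_size > 0) {
    nrm <- sqrt(rowSums(plot_eff^2))
    plot_eff <- plot_eff / nrm * cfg$plot_effect_size * sqrt(V)
  } else plot_eff[] <- 0
  dates <- unique(design$date)
  seas_eff <- matrix(stats::rnorm(length(dates) * V, 0,
                                  cfg$season_effect_size),
                     nrow = length(dates),
                     dimnames = list(as.character(dates), NULL))

  coords <- as.matrix(design[, c("x_m", "y_m")])
  h <- as.matrix(stats::dist(coords))
  C <- exp(-(h / cfg$spatial_range)^2)
  sd_field <- sqrt(max(-cfg$spatial_decay_beta, 0) * .kappa_spatial)
  Lt <- chol(C + diag(1e-8, n))
  field <- sd_field * crossprod(Lt, matrix(stats::rnorm(n * V), n, V))

  eta <- matrix(base, n, V, byrow = TRUE) +
    plot_eff[design$plot, , drop = FALSE] +
    seas_eff[as.character(design$date), , drop = FALSE] +
    field
  w <- exp(eta)
  w <- w / rowSums(w)
  props <- t(apply(w, 1, function(wi) rdirichlet1(cfg$theta * wi)))
  dimnames(props) <- list(design$sample_id, sprintf("VT%05d", seq_len(V)))
  list(proportions = community_matrix(props, metadata = design,
                                      mode = "proportions"),
       design = design)
}

#' Simulate the final sample-by-VT count matrix of a study
#'
#' Draws true compositions with [simulate_communities()], assigns each
#' sample a read depth (log-uniform within `depth_range`; `n_low_depth`
#' randomly chosen samples instead get fewer than 10 reads, emulating
#' failed samples that the depth filter later removes) and realises
#' counts as a multinomial draw per sample.
#'
#' @param cfg a [sim_config()].
#' @param seed optional override of `cfg$seed`.
#' @return list with `counts` (community_matrix with metadata), `truth`
#'   (the true proportions matrix) and `design`.
#' @export
simulate_study_matrix <- function(cfg, seed = NULL) {
  comm <- simulate_communities(cfg, seed)
  props <- comm$proportions$values
  design <- comm$design
  n <- nrow(props)
  depths <- round(exp(stats::runif(n, log(cfg$depth_range[1]),
                                   log(cfg$depth_range[2]))))
  if (cfg$n_low_depth > 0) {
    low <- sample.int(n, min(cfg$n_low_depth, n))
    depths[low] <- sample(0:9, length(low), replace = TRUE)
  }
  counts <- t(vapply(seq_len(n), function(i) {
    if (depths[i] == 0) integer(ncol(props))
    else as.integer(stats::rmultinom(1, depths[i], props[i, ]))
  }, integer(ncol(props))))
  dimnames(counts) <- dimnames(props)
  list(counts = community_matrix(counts, metadata = design, mode = "counts"),
       truth = comm$proportions, design = design)
}

#' Generate barcodes for a set of samples
#'
#' @param sample_ids sample identifiers.
#' @param width barcode length, nt (default 8).
#' @param seed optional RNG seed.
#' @return data.frame with `barcode`, `sample_id` (barcodes unique).
#' @export
make_barcodes <- function(sample_ids, width = 8, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- length(sample_ids)
  bcs <- character(0)
  while (length(bcs) < n)
    bcs <- unique(c(bcs, random_dna(n, width)))
  data.frame(barcode = bcs[seq_len(n)], sample_id = sample_ids,
             stringsAsFactors = FALSE)
}

draw_read_lengths <- function(n, cfg) {
  L <- round(stats::rnorm(n, cfg$read_length["median"],
                          cfg$read_length_sd))
  pmin(pmax(L, cfg$read_length["min"]), cfg$read_length["max"])
}

add_errors <- function(seqs, rate) {
  if (rate == 0) return(seqs)
  vapply(seqs, function(s) {
    ch <- strsplit(s, "")[[1]]
    hit <- which(stats::runif(length(ch)) < rate)
    if (length(hit)) {
      for (i in hit)
        ch[i] <- sample(setdiff(c("A", "C", "G", "T"), ch[i]), 1)
    }
    paste(ch, collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate barcoded amplicon reads from true compositions
#'
#' For each sample: an assigned-read depth is drawn within
#' `cfg$depth_range`, AMF reads are drawn from the sample's true VT
#' proportions and non-target reads (making up the remaining
#' `1 - amf_read_fraction` of the library) from a decoy pool of shuffled
#' reference sequences.  Each read is the sample barcode, the forward
#' primer, and a 5' template fragment whose length follows the configured
#' distribution (capped at the template length), with per-base
#' substitution errors at `error_rate`.
#'
#' @param truth community_matrix of true proportions (from
#'   [simulate_communities()]), or the list returned by it.
#' @param cfg a [sim_config()].
#' @param barcodes data.frame `barcode`, `sample_id` covering all samples.
#' @param reference named reference sequences (from [make_reference()]).
#' @param fwd_primer forward primer prepended to every read.
#' @param seed optional override of `cfg$seed`.
#' @return list with `reads` (data.frame `read_id`, `sequence`, raw reads
#'   with barcode and primer) and `truth_table` (data.frame `read_id`,
#'   `sample_id`, `vt_id` (`NA` for non-target), `length`).
#' @export
simulate_reads <- function(truth, cfg, barcodes, reference,
                           fwd_primer = "TTGGAGGGCAAGTCTGGTGCC",
                           seed = NULL) {
  if (is.list(truth) && !inherits(truth, "community_matrix"))
    truth <- truth$proportions
  stopifnot(inherits(truth, "community_matrix"))
  set.seed(if (is.null(seed)) cfg$seed else seed)
  props <- truth$values
  samples <- rownames(props)
  bmap <- stats::setNames(barcodes$barcode, barcodes$sample_id)
  if (any(!samples %in% names(bmap)))
    stop("barcode map does not cover all samples")
  vts <- colnames(props)
  if (any(!vts %in% names(reference)))
    stop("reference does not cover all VT")

  decoys <- vapply(seq_len(cfg$n_decoy_templates), function(i) {
    tmpl <- reference[[1 + (i - 1) %% length(reference)]]
    paste(sample(strsplit(tmpl, "")[[1]]), collapse = "")
  }, character(1))

  rows <- list()
  rid <- 0L
  for (s in samples) {
    n_amf <- round(exp(stats::runif(1, log(cfg$depth_range[1]),
                                    log(cfg$depth_range[2]))))
    n_total <- max(n_amf, round(n_amf / cfg$amf_read_fraction))
    n_decoy <- n_total - n_amf
    vt_draw <- sample(vts, n_amf, replace = TRUE, prob = props[s, ])
    tmpl <- c(unname(reference[vt_draw]),
              sample(decoys, n_decoy, replace = TRUE))
    vt_id <- c(vt_draw, rep(NA_character_, n_decoy))
    lens <- pmin(draw_read_lengths(length(tmpl), cfg), nchar(tmpl))
    frag <- add_errors(substr(tmpl, 1, lens), cfg$error_rate)
    ids <- sprintf("read%07d", rid + seq_along(tmpl))
    rid <- rid + length(tmpl)
    rows[[s]] <- data.frame(
      read_id = ids, sample_id = s, vt_id = vt_id, length = nchar(frag),
      sequence = paste0(bmap[s], fwd_primer, frag),
      stringsAsFactors = FALSE)
  }
  all <- do.call(rbind, rows)
  rownames(all) <- NULL
  list(reads = all[, c("read_id", "sequence")],
       truth_table = all[, c("read_id", "sample_id", "vt_id", "length")])
}

#' Simulate tabular alignment hits for payload reads
#'
#' A desk-scale stand-in for an external aligner: every read is compared
#' ungapped, from its 5' end, against the same-length prefix of every
#' reference sequence; references matching at or above `min_report_identity`
#' percent produce one hit row.  Identity is the exact mismatch fraction
#' of that comparison.  The score surrogate is fixed and documented:
#' bitscore = 2 L (identity/100 - 0.25) (monotone in both length and
#' identity; 0.25 is the random-sequence expectation) and
#' e-value = 1e9 * 2^(-bitscore).  Tests depend only on thresholded
#' behaviour, never on the absolute scale of the surrogate.
#'
#' @param reads demultiplexed payload reads (`read_id`, `sequence`).
#' @param reference named reference sequences.
#' @param min_report_identity lowest identity reported as a hit row
#'   (default 80; genuinely non-target reads fall far below this).
#' @return hit data.frame in the 12-column tabular dialect.
#' @export
simulate_hits <- function(reads, reference, min_report_identity = 80) {
  lens <- nchar(reads$sequence)
  reflens <- nchar(reference)
  maxlen <- max(reflens, lens)
  # pad reads and references with distinct non-base codes so padded
  # positions always count as mismatches; the overhang is subtracted
  enc <- function(s, pad) {
    v <- utf8ToInt(s)
    c(v, rep.int(pad, maxlen - length(v)))
  }
  M <- t(vapply(reads$sequence, enc, integer(maxlen), pad = 1L,
                USE.NAMES = FALSE))
  out <- vector("list", length(reference))
  for (v in names(reference)) {
    refv <- enc(reference[[v]], 2L)
    mm_full <- rowSums(t(t(M) != refv))
    aln <- pmin(lens, reflens[[v]])
    mm <- mm_full - (maxlen - aln)
    pid <- 100 * (1 - mm / aln)
    sel <- which(pid >= min_report_identity)
    if (length(sel)) {
      bits <- 2 * aln[sel] * (pid[sel] / 100 - 0.25)
      out[[v]] <- data.frame(
        qseqid = reads$read_id[sel], sseqid = v,
        pident = round(pid[sel], 2), length = aln[sel],
        mismatch = mm[sel], gapopen = 0, qstart = 1, qend = aln[sel],
        sstart = 1, send = aln[sel], evalue = 1e9 * 2^(-bits),
        bitscore = round(bits, 1), stringsAsFactors = FALSE)
    }
  }
  res <- do.call(rbind, out)
  if (is.null(res)) {
    empty <- data.frame(qseqid = character(0), sseqid = character(0),
                        stringsAsFactors = FALSE)
    for (cc in hit_cols[3:12]) empty[[cc]] <- numeric(0)
    return(empty)
  }
  res <- res[order(match(res$qseqid, reads$read_id), res$sseqid), ]
  rownames(res) <- NULL
  res
}

#' Write hits in the 12-column tabular format
#'
#' @param hits hit data.frame.
#' @param path output path.
#' @export
write_hits <- function(hits, path) {
  utils::write.table(hits, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
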