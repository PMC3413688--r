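# shared fixtures built in code

NS31 <- "TTGGAGGGCAAGTCTGGTGCC"

toy_barcodes <- function() {
  data.frame(barcode = c("ACGTACGT", "TTTTCCCC", "GGGGAAAA"),
             sample_id = c("S1", "S2", "S3"),
             stringsAsFactors = FALSE)
}

random_payload <- function(n, seed = 42) {
  set.seed(seed)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

make_raw_read <- function(barcode, payload, primer = NS31) {
  paste0(barcode, primer, payload)
}

# small count matrix with plot/date design for pipeline-level tests
toy_community <- function() {
  counts <- matrix(c(13, 5, 0, 2,
                     20, 0, 4, 0,
                     1,  9, 9, 1,
                     0, 12, 3, 5), nrow = 4, byrow = TRUE,
                   dimnames = list(paste0("S", 1:4), paste0("VT0000", 1:4)))
  meta <- data.frame(sample_id = paste0("S", 1:4),
                     plot = c("A", "A", "B", "B"),
                     grid_point = c(1, 2, 1, 2),
                     date = as.Date(rep("2009-09-03", 4)),
                     x_m = c(0, 5, 40, 45), y_m = c(0, 0, 0, 0),
                     stringsAsFactors = FALSE)
  community_matrix(counts, metadata = meta, mode = "counts")
}

# a tiny simulation configuration for read-level round trips
small_cfg <- function(seed = 3) {
  sim_config(seed = seed, depth_range = c(13, 60), amf_read_fraction = 0.5,
             n_low_depth = 0,
             dates = as.Date(c("2009-05-25", "2009-09-03")))
}
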