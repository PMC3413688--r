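#' Read amplicon reads from FASTA
#'
#' @param path FASTA file (optionally gzipped).
#' @return data.frame with columns `read_id` (first whitespace-delimited
#'   token of the header) and `sequence` (upper case).
#' @export
read_reads_fasta <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  ids <- sub("\\s.*$", "", names(ss))
  data.frame(read_id = ids, sequence = toupper(as.character(ss)),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Write reads to FASTA
#'
#' Sample attribution, when present, is kept as a `sample=` annotation in
#' the header.
#'
#' @param reads data.frame with `read_id`, `sequence` and optionally
#'   `sample_id`.
#' @param path output path.
#' @export
write_reads_fasta <- function(reads, path) {
  hdr <- reads$read_id
  if (!is.null(reads$sample_id))
    hdr <- paste0(hdr, " sample=", reads$sample_id)
  ss <- Biostrings::DNAStringSet(reads$sequence)
  names(ss) <- hdr
  Biostrings::writeXStringSet(ss, path)
  invisible(path)
}

#' Read a barcode-to-sample map
#'
#' @param path 2-column TSV (barcode, sample_id), no header required; a
#'   header line is detected by a non-DNA first field.
#' @return data.frame with columns `barcode`, `sample_id`.
#' @export
read_barcode_map <- function(path) {
  tab <- utils::read.delim(path, header = FALSE, stringsAsFactors = FALSE)
  if (!grepl("^[ACGTNacgtn]+$", tab[1, 1])) tab <- tab[-1, , drop = FALSE]
  data.frame(barcode = toupper(tab[[1]]), sample_id = as.character(tab[[2]]),
             stringsAsFactors = FALSE)
}

validate_barcodes <- function(barcodes) {
  barcodes <- as.data.frame(barcodes)
  if (!all(c("barcode", "sample_id") %in% names(barcodes)))
    stop("barcode map needs columns 'barcode' and 'sample_id'")
  if (!nrow(barcodes)) stop("barcode map is empty")
  if (length(unique(nchar(barcodes$barcode))) != 1)
    stop("barcodes differ in length")
  if (anyDuplicated(barcodes$barcode)) stop("duplicated barcodes")
  if (anyDuplicated(barcodes$sample_id)) stop("duplicated sample ids")
  if (!all(grepl("^[ACGT]+$", barcodes$barcode)))
    stop("barcodes must be unambiguous DNA (A/C/G/T)")
  barcodes
}

hamming <- function(a, b) {
  stopifnot(nchar(a) == nchar(b))
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
}

#' Demultiplex barcoded amplicon reads
#'
#' Each raw read is expected to start with an 8-nt sample barcode followed
#' by the forward PCR primer (NS31 for the Glomeromycota SSU amplicon) and
#' the template payload.  Reads are accepted only if (checked in this
#' order) the leading bases match a known barcode, the following bases
#' match the forward primer, and the remaining payload is at least
#' `min_length` nt after barcode and primer removal.  Matching is exact by
#' default; `max_primer_mismatches` allows a Hamming-distance budget on the
#' primer only.  Reads containing characters outside A/C/G/T/N, or with an
#' ambiguous base in the barcode region, are rejected at the barcode step.
#'
#' @param reads data.frame with `read_id`, `sequence` (e.g. from
#'   [read_reads_fasta()]).
#' @param barcodes data.frame with `barcode`, `sample_id`.
#' @param fwd_primer forward primer sequence (default NS31).
#' @param min_length minimum payload length (nt) after stripping.
#' @param max_primer_mismatches allowed mismatches in the primer region.
#' @return list with `reads` (data.frame `read_id`, `sample_id`,
#'   `sequence`, `length`; input order preserved) and `stats`
#'   (class `amf_demux_stats`).
#' @export
demultiplex <- function(reads, barcodes,
                        fwd_primer = "TTGGAGGGCAAGTCTGGTGCC",
                        min_length = 170, max_primer_mismatches = 0) {
  barcodes <- validate_barcodes(barcodes)
  if (!nzchar(fwd_primer)) stop("empty forward primer")
  fwd_primer <- toupper(fwd_primer)
  bw <- nchar(barcodes$barcode[1])
  pw <- nchar(fwd_primer)
  seqs <- toupper(reads$sequence)
  n <- length(seqs)

  ok_alpha <- grepl("^[ACGTN]*$", seqs) & nzchar(seqs)
  bc <- substr(seqs, 1L, bw)
  sample <- barcodes$sample_id[match(bc, barcodes$barcode)]
  bad_barcode <- !ok_alpha | is.na(sample) | nchar(seqs) < bw

  prim <- substr(seqs, bw + 1L, bw + pw)
  if (max_primer_mismatches == 0) {
    prim_ok <- prim == fwd_primer
  } else {
    pchars <- strsplit(fwd_primer, "")[[1]]
    prim_ok <- vapply(prim, function(p) {
      nchar(p) == pw && sum(strsplit(p, "")[[1]] != pchars) <=
        max_primer_mismatches
    }, logical(1), USE.NAMES = FALSE)
  }
  bad_primer <- !bad_barcode & !prim_ok

  payload <- substr(seqs, bw + pw + 1L, nchar(seqs))
  too_short <- !bad_barcode & !bad_primer & nchar(payload) < min_length

  pass <- !(bad_barcode | bad_primer | too_short)
  out <- data.frame(read_id = reads$read_id[pass],
                    sample_id = sample[pass],
                    sequence = payload[pass],
                    length = nchar(payload[pass]),
                    stringsAsFactors = FALSE, row.names = NULL)
  lens <- out$length
  stats <- structure(list(
    n_input = n, n_pass = sum(pass),
    n_bad_barcode = sum(bad_barcode),
    n_bad_primer = sum(bad_primer),
    n_too_short = sum(too_short),
    length_min = if (length(lens)) min(lens) else NA_integer_,
    length_max = if (length(lens)) max(lens) else NA_integer_,
    length_median = if (length(lens)) stats::median(lens) else NA_real_),
    class = "amf_demux_stats")
  list(reads = out, stats = stats)
}

#' @export
print.amf_demux_stats <- function(x, ...) {
  cat("Demultiplexing:", x$n_input, "reads in;", x$n_pass, "passed\n")
  cat(sprintf("  rejected: %d bad barcode, %d bad primer, %d too short\n",
              x$n_bad_barcode, x$n_bad_primer, x$n_too_short))
  if (!is.na(x$length_min))
    cat(sprintf("  kept lengths %d-%d nt (median %.0f)\n",
                x$length_min, x$length_max, x$length_median))
  invisible(x)
}

#' Trim reads from the 3' end to a fixed length
#'
#' Used by the read-length robustness experiment: the 5' end is preserved
#' and the 3' end cut to exactly `target_length` nt.  Reads shorter than
#' the target are dropped.  When `select_longer_than` is set, only reads
#' strictly longer than that many nt enter the experiment at all (the
#' study design selects reads >400 nt before trimming to 400, 350, 300,
#' 250, 200 and 170).
#'
#' @param reads demultiplexed read data.frame (`read_id`, `sample_id`,
#'   `sequence`, `length`).
#' @param target_length trimmed length (nt).
#' @param select_longer_than optional strict lower bound applied before
#'   trimming.
#' @return read data.frame with all kept sequences of `target_length` nt.
#' @export
trim_reads <- function(reads, target_length, select_longer_than = NULL) {
  if (target_length < 1) stop("target_length must be >= 1")
  keep <- reads$length >= target_length
  if (!is.null(select_longer_than))
    keep <- keep & reads$length > select_longer_than
  out <- reads[keep, , drop = FALSE]
  out$sequence <- substr(out$sequence, 1L, target_length)
  out$length <- nchar(out$sequence)
  rownames(out) <- NULL
  out
}

#' Summarise read lengths
#'
#' Median uses the midpoint convention for even n (mean of the central
#' pair).
#'
#' @param reads read data.frame with a `length` column, or a numeric
#'   vector of lengths.
#' @return named numeric vector `c(min, max, median)`.
#' @export
length_summary <- function(reads) {
  lens <- if (is.data.frame(reads)) reads$length else reads
  if (!length(lens)) stop("no reads")
  c(min = min(lens), max = max(lens), median = stats::median(lens))
}
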