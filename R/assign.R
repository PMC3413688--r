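#' Closed-reference match criteria
#'
#' The three conditions a tabular alignment hit must satisfy for a read to
#' be assignable to a reference VT: percent identity at least
#' `min_identity`; alignment length within `max_len_diff` nt of the length
#' of the shorter of query and subject; e-value strictly below
#' `max_evalue`.
#'
#' @param min_identity minimum percent identity (default 97).
#' @param max_len_diff maximum |alignment length - min(query, subject)
#'   length| in nt (default 10).
#' @param max_evalue strict e-value upper bound (default 1e-50).
#' @return list of class `match_criteria`.
#' @export
match_criteria <- function(min_identity = 97, max_len_diff = 10,
                           max_evalue = 1e-50) {
  if (min_identity <= 0 || max_len_diff <= 0 || max_evalue <= 0)
    stop("criteria thresholds must be positive")
  structure(list(min_identity = min_identity, max_len_diff = max_len_diff,
                 max_evalue = max_evalue), class = "match_criteria")
}

hit_cols <- c("qseqid", "sseqid", "pident", "length", "mismatch", "gapopen",
              "qstart", "qend", "sstart", "send", "evalue", "bitscore")

#' Parse a 12-column tabular alignment-hit file
#'
#' Standard tab-separated dialect (qseqid sseqid pident length mismatch
#' gapopen qstart qend sstart send evalue bitscore).  Lines starting with
#' `#` are skipped.  Malformed rows raise errors naming the offending line
#' number; when length maps are supplied, unknown ids raise errors naming
#' the id.
#'
#' @param path hit file path.
#' @param query_lengths optional named vector, read_id to nt.
#' @param subject_lengths optional named vector, VT id to nt.
#' @return data.frame of hits, one row per alignment.
#' @export
parse_hits <- function(path, query_lengths = NULL, subject_lengths = NULL) {
  lines <- readLines(path)
  keep <- !grepl("^\\s*#", lines) & nzchar(trimws(lines))
  lineno <- which(keep)
  if (!length(lineno)) {
    out <- as.data.frame(stats::setNames(
      rep(list(character(0)), 2), hit_cols[1:2]))
    for (cc in hit_cols[3:12]) out[[cc]] <- numeric(0)
    return(out)
  }
  fields <- strsplit(lines[keep], "\t|\\s+")
  nf <- lengths(fields)
  if (any(nf != 12))
    stop("malformed hit row (expected 12 fields) at line(s): ",
         paste(lineno[nf != 12], collapse = ", "))
  mat <- do.call(rbind, fields)
  out <- data.frame(qseqid = mat[, 1], sseqid = mat[, 2],
                    stringsAsFactors = FALSE)
  for (j in 3:12) {
    v <- suppressWarnings(as.numeric(mat[, j]))
    if (anyNA(v))
      stop("non-numeric value in column '", hit_cols[j], "' at line(s): ",
           paste(lineno[is.na(v)], collapse = ", "))
    out[[hit_cols[j]]] <- v
  }
  if (!is.null(query_lengths)) {
    unk <- setdiff(unique(out$qseqid), names(query_lengths))
    if (length(unk))
      stop("query id(s) without known length: ", paste(unk, collapse = ", "))
  }
  if (!is.null(subject_lengths)) {
    unk <- setdiff(unique(out$sseqid), names(subject_lengths))
    if (length(unk))
      stop("subject id(s) without known length: ",
           paste(unk, collapse = ", "))
  }
  out
}

#' Test hits against the match criteria
#'
#' Vectorised predicate over hit rows: identity >= threshold, alignment
#' length within `max_len_diff` of the shorter sequence, e-value strictly
#' below the bound.
#'
#' @param hits hit data.frame (see [parse_hits()]).
#' @param qlen query length(s), nt (recycled).
#' @param slen subject length(s), nt (recycled).
#' @param criteria a [match_criteria()] object.
#' @return logical vector, one element per hit.
#' @export
passes_criteria <- function(hits, qlen, slen, criteria = match_criteria()) {
  stopifnot(inherits(criteria, "match_criteria"))
  hits$pident >= criteria$min_identity &
    abs(hits$length - pmin(qlen, slen)) <= criteria$max_len_diff &
    hits$evalue < criteria$max_evalue
}

#' Select the best passing hit for one query
#'
#' Among hits that satisfy the criteria, picks the subject with maximal
#' bitscore; ties are broken by lower e-value, then lexicographically
#' smallest subject id, so the choice is deterministic and independent of
#' input order.
#'
#' @param hits hit rows sharing one `qseqid`.
#' @param qlen query length (nt).
#' @param subject_lengths named vector, VT id to nt.
#' @param criteria a [match_criteria()] object.
#' @return best subject id, or `NA_character_` if no hit passes.
#' @export
best_hit <- function(hits, qlen, subject_lengths,
                     criteria = match_criteria()) {
  if (!nrow(hits)) return(NA_character_)
  if (length(unique(hits$qseqid)) > 1)
    stop("best_hit expects hits for a single query")
  ok <- passes_criteria(hits, qlen, subject_lengths[hits$sseqid], criteria)
  h <- hits[ok, , drop = FALSE]
  if (!nrow(h)) return(NA_character_)
  h <- h[order(-h$bitscore, h$evalue, h$sseqid), , drop = FALSE]
  h$sseqid[1]
}

#' Assign every read to its best-matching VT
#'
#' Applies [passes_criteria()] and the best-hit rule to a whole hit table
#' at once.  Reads present in `query_lengths` but receiving no passing hit
#' get `NA` (no assignment) — under closed-reference picking such reads
#' are discarded downstream.
#'
#' @param hits hit data.frame.
#' @param query_lengths named vector, read_id to nt (defines the read set).
#' @param subject_lengths named vector, VT id to nt.
#' @param criteria a [match_criteria()] object.
#' @return data.frame with columns `read_id`, `vt_id` (NA when
#'   unassigned), one row per read in `query_lengths`.
#' @export
assign_reads <- function(hits, query_lengths, subject_lengths,
                         criteria = match_criteria()) {
  unkq <- setdiff(unique(hits$qseqid), names(query_lengths))
  if (length(unkq))
    stop("query id(s) without known length: ", paste(unkq, collapse = ", "))
  unks <- setdiff(unique(hits$sseqid), names(subject_lengths))
  if (length(unks))
    stop("subject id(s) without known length: ",
         paste(unks, collapse = ", "))
  vt <- stats::setNames(rep(NA_character_, length(query_lengths)),
                        names(query_lengths))
  if (nrow(hits)) {
    ok <- passes_criteria(hits, query_lengths[hits$qseqid],
                          subject_lengths[hits$sseqid], criteria)
    h <- hits[ok, , drop = FALSE]
    if (nrow(h)) {
      h <- h[order(h$qseqid, -h$bitscore, h$evalue, h$sseqid), ,
             drop = FALSE]
      first <- !duplicated(h$qseqid)
      vt[h$qseqid[first]] <- h$sseqid[first]
    }
  }
  data.frame(read_id = names(vt), vt_id = unname(vt),
             stringsAsFactors = FALSE, row.names = NULL)
}
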