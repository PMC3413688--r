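hit_row <- function(qseqid = "r1", sseqid = "VT00113", pident = 98.5,
                    length = 380, mismatch = 0, gapopen = 0, qstart = 1,
                    qend = 380, sstart = 1, send = 380, evalue = 1e-160,
                    bitscore = 560) {
  data.frame(qseqid = qseqid, sseqid = sseqid, pident = pident,
             length = length, mismatch = mismatch, gapopen = gapopen,
             qstart = qstart, qend = qend, sstart = sstart, send = send,
             evalue = evalue, bitscore = bitscore, stringsAsFactors = FALSE)
}

test_that("parse_hits reads the 12-column dialect and reports bad rows", {
  tmp <- tempfile()
  writeLines(c("# comment",
               "r1\tVT00113\t98.5\t380\t0\t0\t1\t380\t1\t380\t1e-160\t560",
               "r2\tVT00042\t97.0\t200\t6\t0\t1\t200\t1\t200\t1e-80\t300"),
             tmp)
  h <- parse_hits(tmp)
  expect_equal(nrow(h), 2)
  expect_equal(h$pident[1], 98.5)
  expect_equal(h$evalue[1], 1e-160)
  expect_equal(h$sseqid[2], "VT00042")

  empty <- tempfile(); writeLines(character(0), empty)
  expect_equal(nrow(parse_hits(empty)), 0)

  bad <- tempfile()
  writeLines("r1\tVT00113\tnot_a_number\t380\t0\t0\t1\t380\t1\t380\t1e-160\t560",
             bad)
  expect_error(parse_hits(bad), "pident")
  short <- tempfile(); writeLines("r1\tVT00113\t98.5", short)
  expect_error(parse_hits(short), "12 fields")
  expect_error(parse_hits(tmp, query_lengths = c(r1 = 380)), "r2")
})

test_that("parsed row count equals non-comment line count", {
  set.seed(9)
  n <- 25
  lines <- sprintf("r%d\tVT%05d\t%.1f\t%d\t0\t0\t1\t100\t1\t100\t1e-60\t%d",
                   1:n, sample(100, n), runif(n, 90, 100),
                   sample(170:400, n, TRUE), sample(200:600, n))
  comments <- sprintf("# c%d", 1:5)
  tmp <- tempfile()
  writeLines(sample(c(lines, comments)), tmp)
  expect_equal(nrow(parse_hits(tmp)), n)
})

test_that("match criteria implement the identity, length-difference and e-value rules", {
  crit <- match_criteria()
  base <- hit_row()
  # identity threshold is inclusive at 97
  expect_false(passes_criteria(hit_row(pident = 96.9), 380, 500, crit))
  expect_true(passes_criteria(hit_row(pident = 97.0), 380, 500, crit))
  # alignment length within 10 nt of the shorter sequence
  expect_false(passes_criteria(hit_row(pident = 97, length = 369),
                               380, 500, crit))
  expect_true(passes_criteria(hit_row(pident = 97, length = 370),
                              380, 500, crit))
  # e-value bound is strict
  expect_false(passes_criteria(hit_row(evalue = 1e-50), 380, 500, crit))
  expect_true(passes_criteria(hit_row(evalue = 0.9e-50), 380, 500, crit))
  # the shorter of query and subject is what counts
  expect_true(passes_criteria(hit_row(length = 500), 600, 505, crit))
})

test_that("best_hit picks maximal bitscore with deterministic tie-breaks", {
  slen <- c(VT00101 = 500, VT00099 = 500, VT00050 = 500)
  h <- rbind(hit_row(sseqid = "VT00101", bitscore = 560),
             hit_row(sseqid = "VT00050", bitscore = 540))
  expect_equal(best_hit(h, 380, slen), "VT00101")
  # no passing hit
  h2 <- hit_row(pident = 90)
  expect_equal(best_hit(h2, 380, c(VT00113 = 500)), NA_character_)
  expect_equal(best_hit(h2[0, ], 380, slen), NA_character_)
  # tie on bitscore and evalue: lexicographically smallest subject
  h3 <- rbind(hit_row(sseqid = "VT00101"), hit_row(sseqid = "VT00099"))
  expect_equal(best_hit(h3, 380, slen), "VT00099")
  # order independence
  set.seed(1)
  h4 <- rbind(hit_row(sseqid = "VT00101", bitscore = 520, evalue = 1e-120),
              hit_row(sseqid = "VT00099", bitscore = 560, evalue = 1e-150),
              hit_row(sseqid = "VT00050", bitscore = 560, evalue = 1e-160))
  picks <- replicate(10, best_hit(h4[sample(3), ], 380, slen))
  expect_true(all(picks == picks[1]))
})

test_that("assign_reads matches per-query best_hit and keeps unmatched reads as NA", {
  slen <- c(VT00001 = 500, VT00002 = 500)
  qlen <- c(r1 = 380, r2 = 380, r3 = 380)
  hits <- rbind(hit_row("r1", "VT00001", bitscore = 500),
                hit_row("r1", "VT00002", bitscore = 510),
                hit_row("r2", "VT00001", pident = 90))
  a <- assign_reads(hits, qlen, slen)
  expect_equal(a$vt_id[a$read_id == "r1"], "VT00002")
  expect_true(is.na(a$vt_id[a$read_id == "r2"]))
  expect_true(is.na(a$vt_id[a$read_id == "r3"]))
  expect_error(assign_reads(hits, qlen[2:3], slen), "query")
})

test_that("build_matrix tabulates assignments against the design", {
  design <- data.frame(sample_id = c("S1", "S2"))
  asg <- data.frame(read_id = paste0("r", 1:4),
                    sample_id = c("S1", "S1", "S1", "S1"),
                    vt_id = c("VT1", "VT1", "VT1", "VT2"))
  m <- build_matrix(asg, design)
  expect_equal(unname(m$values["S1", c("VT1", "VT2")]), c(3, 1))
  expect_equal(unname(rowSums(m$values)["S2"]), 0)
  # empty stream -> all-zero matrix over the design
  m0 <- build_matrix(asg[0, ], design)
  expect_equal(nrow(m0$values), 2)
  expect_true(all(m0$values == 0))
  expect_error(build_matrix(data.frame(read_id = "r", sample_id = "SX",
                                       vt_id = "VT1"), design), "SX")
})

test_that("matrix total equals the number of assigned reads", {
  set.seed(4)
  n <- 500
  asg <- data.frame(read_id = paste0("r", 1:n),
                    sample_id = sample(paste0("S", 1:6), n, TRUE),
                    vt_id = sample(c(paste0("VT", 1:8), NA), n, TRUE))
  m <- build_matrix(asg, data.frame(sample_id = paste0("S", 1:6)))
  expect_equal(sum(m$values), sum(!is.na(asg$vt_id)))
})

test_that("filter_matrix removes shallow samples and singleton VT to a fixed point", {
  counts <- rbind(S1 = c(9, 0, 0),   # 9 hits: removed
                  S2 = c(9, 2, 1),   # 12 hits: kept (11 after VT3 goes)
                  S3 = c(5, 5, 0))
  colnames(counts) <- c("VT1", "VT2", "VT3")
  m <- community_matrix(counts, mode = "counts")
  f <- filter_matrix(m)
  expect_equal(rownames(f$values), c("S2", "S3"))
  # VT3 is a singleton once S1 is gone; its removal keeps S2 above 10
  expect_false("VT3" %in% colnames(f$values))
  log <- attr(f, "removal_log")
  expect_setequal(log$entity, c("S1", "VT3"))
  # no cell increases
  expect_true(all(f$values <= counts[rownames(f$values),
                                     colnames(f$values)]))
})

test_that("filter_matrix is the identity on clean matrices and errors when empty", {
  counts <- rbind(S1 = c(10, 5), S2 = c(4, 8))
  colnames(counts) <- c("VT1", "VT2")
  m <- community_matrix(counts, mode = "counts")
  f <- filter_matrix(m)
  expect_equal(f$values, m$values)
  expect_equal(nrow(attr(f, "removal_log")), 0)
  low <- community_matrix(rbind(S1 = c(VT1 = 3)), mode = "counts")
  expect_error(filter_matrix(low), "all samples removed")
})

test_that("singleton definition can be per-read or per-sample occurrence", {
  counts <- rbind(S1 = c(10, 2, 0), S2 = c(10, 0, 5))
  colnames(counts) <- c("VT1", "VT2", "VT3")
  m <- community_matrix(counts, mode = "counts")
  # per-read: no VT has total 1, nothing removed
  expect_equal(ncol(filter_matrix(m)$values), 3)
  # per-sample occurrence: VT2 and VT3 occur in one sample each
  f <- filter_matrix(m, singleton = "samples")
  expect_equal(colnames(f$values), "VT1")
})

test_that("normalise divides by row totals and is idempotent", {
  counts <- rbind(S1 = c(3, 1), S2 = c(13, 0))
  colnames(counts) <- c("VT1", "VT2")
  m <- community_matrix(counts, mode = "counts")
  p <- normalise(m)
  expect_equal(unname(p$values["S1", ]), c(0.75, 0.25))
  expect_equal(unname(p$values["S2", ]), c(1, 0))
  expect_equal(rowSums(p$values), c(S1 = 1, S2 = 1))
  zero <- community_matrix(rbind(S1 = c(VT1 = 0, VT2 = 0),
                                 S2 = c(VT1 = 2, VT2 = 1)),
                           mode = "counts")
  expect_error(normalise(zero), "S1")
})

test_that("simulated hits carry exact identities and assignment recovers the truth", {
  cfg <- small_cfg()
  comm <- simulate_communities(cfg)
  ref <- make_reference(cfg$n_vt, cfg$ref_length, cfg$divergence, seed = 5)
  bcs <- make_barcodes(comm$design$sample_id, seed = 6)
  sim <- simulate_reads(comm, cfg, bcs, ref)
  dm <- demultiplex(sim$reads, bcs)
  hits <- simulate_hits(dm$reads, ref)
  # identity recount oracle: recompare the read to the reference prefix
  idx <- sample(nrow(hits), min(25, nrow(hits)))
  for (i in idx) {
    r <- dm$reads$sequence[dm$reads$read_id == hits$qseqid[i]]
    s <- ref[[hits$sseqid[i]]]
    L <- hits$length[i]
    mm <- sum(strsplit(substr(r, 1, L), "")[[1]] !=
                strsplit(substr(s, 1, L), "")[[1]])
    expect_equal(hits$pident[i], round(100 * (1 - mm / L), 2))
  }
  qlen <- setNames(dm$reads$length, dm$reads$read_id)
  slen <- setNames(nchar(ref), names(ref))
  asg <- assign_reads(hits, qlen, slen)
  truth <- sim$truth_table[match(asg$read_id, sim$truth_table$read_id), ]
  same <- (is.na(asg$vt_id) & is.na(truth$vt_id)) |
    (!is.na(asg$vt_id) & !is.na(truth$vt_id) & asg$vt_id == truth$vt_id)
  expect_true(all(same))
})
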