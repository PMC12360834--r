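test_that("asymmetric substitution scores follow the bisulfite contract", {
  ct <- scoring_scheme(mode = "ct")
  # genomic C vs read T is a full match: perfect 4-mer score
  al <- bisulfite_sw("ATGT", "ACGT", ct)
  expect_equal(al$score, 8)
  expect_equal(al$cigar, "4M")
  expect_equal(al$ref_start, 0)
  expect_equal(al$ref_end, 4)
  # genomic T vs read C is a mismatch: the converted direction is one-way
  expect_lt(bisulfite_sw("ACGT", "ATGT", ct)$score, 8)
  # GA mirror
  ga <- scoring_scheme(mode = "ga")
  expect_equal(bisulfite_sw("AACT", "AGCT", ga)$score, 8)
  expect_lt(bisulfite_sw("AGCT", "AACT", ga)$score, 8)
  expect_error(bisulfite_sw("", "ACGT", ct), "empty")
  expect_error(scoring_scheme(match = -1))
})

test_that("with asymmetry disabled the DP equals an independent local aligner", {
  set.seed(20)
  sym <- scoring_scheme(mode = "none")
  for (i in 1:120) {
    q <- random_seq(sample(5:60, 1))
    r <- random_seq(sample(5:60, 1))
    # sometimes make r a mutated copy of q so non-trivial alignments occur
    if (i %% 2 == 0) {
      ch <- strsplit(q, "")[[1]]
      nm <- max(1, rbinom(1, length(ch), 0.1))
      ch[sample(length(ch), nm)] <- sample(BASES, nm, replace = TRUE)
      r <- paste(ch, collapse = "")
    }
    expect_equal(bisulfite_sw(q, r, sym)$score, ref_local_align(q, r))
  }
})

test_that("asymmetry can only help fully converted copies", {
  set.seed(21)
  for (i in 1:50) {
    seg <- random_seq(120)
    off <- sample(60, 1)
    readseq <- full_ct(substr(seg, off, off + 49))
    s_ct <- bisulfite_sw(readseq, seg, scoring_scheme(mode = "ct"))$score
    s_sym <- bisulfite_sw(readseq, seg, scoring_scheme(mode = "none"))$score
    expect_gte(s_ct, s_sym)
    expect_equal(s_ct, 2 * 50)  # perfect score for the converted copy
  }
})

test_that("CIGAR reference span matches the reported coordinates", {
  set.seed(22)
  sch <- scoring_scheme(mode = "ct")
  for (i in 1:60) {
    q <- random_seq(sample(10:60, 1))
    r <- random_seq(sample(20:120, 1))
    al <- bisulfite_sw(q, r, sch)
    if (al$score == 0) next
    ops <- regmatches(al$cigar, gregexpr("\\d+[MID]", al$cigar))[[1]]
    n <- as.integer(sub(".$", "", ops)); op <- sub("^\\d+", "", ops)
    expect_equal(sum(n[op %in% c("M", "D")]), al$ref_end - al$ref_start)
    expect_equal(sum(n[op %in% c("M", "I")]), al$query_end - al$query_start)
  }
})

toy_index <- function(len = 10000, seed = 30) {
  ref <- toy_genome(len, seed = seed)
  list(ref = ref,
       gi = build_genome_index(ref, index_params(500, 300,
                                                 sketch_config(master_seed = 77))))
}

test_that("error-free converted reads map back to their exact origin", {
  fx <- toy_index()
  set.seed(31)
  for (i in 1:20) {
    off <- sample(9000, 1)
    window <- substr(fx$ref[[1]], off, off + 149)
    # forward strand: C->T converted copy
    fwd <- map_read("fwd", full_ct(window), fx$gi)
    expect_true(fwd$mapped)
    expect_equal(fwd$pos, off - 1)
    expect_equal(fwd$strand_mode, "CT_forward")
    expect_equal(fwd$score, 300)
    # bottom strand: the sequenced read is revcomp of the window with its
    # cytosines converted; it appears as G->A relative to the forward ref
    bottom <- full_ct(rc_oracle(window))
    rev <- map_read("rev", bottom, fx$gi)
    expect_true(rev$mapped)
    expect_equal(rev$pos, off - 1)
    expect_equal(rev$strand_mode, "GA_revcomp")
  }
})

test_that("alien reads are unmapped and over-long reads are rejected", {
  fx <- toy_index()
  set.seed(32)
  # a read over a disjoint composition cannot vote (toy genome lacks long
  # homopolymers): require no candidate hits, then expect UNMAPPED
  alien <- strrep("CA", 75)
  al <- map_read("alien", alien, fx$gi)
  expect_false(al$mapped)
  expect_error(map_read("long", random_seq(301), fx$gi), "long")
})

test_that("reads from duplicated regions get mapping quality zero", {
  set.seed(33)
  block <- random_seq(1000)
  ref <- setNames(paste0(block, random_seq(2000), block), "dup")
  gi <- build_genome_index(ref, index_params(500, 300, sketch_config(master_seed = 5)))
  readseq <- full_ct(substr(block, 301, 450))
  al <- map_read("r", readseq, gi)
  expect_true(al$mapped)
  expect_equal(al$mapq, 0L)
  expect_equal(al$secondary_best_score, al$score)
  # and a unique read keeps a positive mapq
  uniq <- map_read("u", full_ct(substr(ref[[1]], 1501, 1650)), gi)
  expect_gt(uniq$mapq, 0)
})

test_that("align_file writes conservative, deterministic SAM", {
  fx <- toy_index(6000, seed = 34)
  dir <- tempfile(); dir.create(dir)
  # empty FASTQ -> header-only SAM
  empty_fq <- file.path(dir, "empty.fq"); file.create(empty_fq)
  s0 <- align_file(empty_fq, fx$gi, file.path(dir, "empty.sam"))
  expect_equal(s0, list(n_reads = 0L, n_mapped = 0L, n_unmapped = 0L))
  lines <- readLines(file.path(dir, "empty.sam"))
  expect_true(all(startsWith(lines, "@")))
  expect_true(any(grepl("^@SQ\tSN:toy\tLN:6000", lines)))
  # simulate a handful of reads and align
  prof <- flat_methylation(fx$ref, 0.5)
  sim <- simulate_reads(fx$ref, prof, 40, 150, 0.01, seed = 3)
  fq <- file.path(dir, "r.fq"); write_fastq(sim$reads, fq)
  sam1 <- file.path(dir, "a1.sam"); sam4 <- file.path(dir, "a4.sam")
  s1 <- align_file(fq, fx$gi, sam1, threads = 1)
  s4 <- align_file(fq, fx$gi, sam4, threads = 4)
  expect_equal(s1$n_mapped + s1$n_unmapped, s1$n_reads)
  expect_equal(s1$n_reads, 40L)
  expect_identical(readLines(sam1), readLines(sam4))  # thread-invariant bytes
  # SAM structural checks: one record per read, CIGAR spans SEQ
  recs <- readLines(sam1); recs <- recs[!startsWith(recs, "@")]
  expect_equal(length(recs), 40)
  f <- strsplit(recs, "\t")
  for (x in f) {
    if (bitwAnd(as.integer(x[2]), 4L) > 0) next
    ops <- regmatches(x[6], gregexpr("\\d+[MIS]", x[6]))[[1]]
    expect_equal(sum(as.integer(sub(".$", "", ops))), nchar(x[10]))
  }
})

test_that("malformed FASTQ is reported with file context", {
  bad <- tempfile(fileext = ".fq")
  writeLines(c("@r1", "ACGT", "oops"), bad)
  fx <- toy_index(2000, seed = 35)
  expect_error(align_file(bad, fx$gi, tempfile()), "malformed FASTQ")
})
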