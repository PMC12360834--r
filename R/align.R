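#' Bisulfite-asymmetric scoring scheme
#'
#' Affine-gap local-alignment scores with a bisulfite-asymmetric
#' substitution rule: in CT mode a genomic C aligned to a read T earns the
#' full match reward (the read may carry a converted unmethylated cytosine)
#' while a genomic T against a read C stays a mismatch; GA mode mirrors
#' this (genomic G vs read A is a match) for bottom-strand reads mapped on
#' the forward reference. `mode = "none"` disables the asymmetry.
#'
#' @param match match reward (> 0).
#' @param mismatch mismatch score (< 0).
#' @param gap_open score of the first base of a gap (< 0).
#' @param gap_extend score of each further gap base (< 0).
#' @param mode `"ct"`, `"ga"`, or `"none"`.
#' @return A list of class `bh_scoring`.
#' @export
scoring_scheme <- function(match = 2L, mismatch = -3L, gap_open = -5L,
                           gap_extend = -2L, mode = c("ct", "ga", "none")) {
  mode <- match.arg(mode)
  stopifnot(match > 0, mismatch < 0, gap_open < 0, gap_extend < 0)
  structure(list(match = as.integer(match), mismatch = as.integer(mismatch),
                 gap_open = as.integer(gap_open),
                 gap_extend = as.integer(gap_extend), mode = mode),
            class = "bh_scoring")
}

#' Bisulfite-asymmetric local alignment
#'
#' Smith–Waterman-style local alignment under the asymmetric substitution
#' function of `scheme`, with affine gaps. Traceback prefers diagonal over
#' deletion over insertion, so results are deterministic. Asymmetric
#' matches are reported as `M` in the CIGAR like ordinary matches.
#'
#' @param read read sequence (query).
#' @param segment_seq segment (reference window) sequence.
#' @param scheme a [scoring_scheme()].
#' @return List with `score`, `ref_start`/`ref_end` (0-based half-open),
#'   `query_start`/`query_end` (0-based half-open), `cigar` (M/I/D over the
#'   aligned region). A best score of 0 reports `NA` coordinates.
#' @examples
#' bisulfite_sw("ATGT", "ACGT", scoring_scheme(mode = "ct"))$score  # 8
#' @export
bisulfite_sw <- function(read, segment_seq, scheme = scoring_scheme()) {
  stopifnot(inherits(scheme, "bh_scoring"))
  if (!nzchar(read) || !nzchar(segment_seq)) stop("empty read or segment")
  cpp_bisulfite_sw(read, segment_seq, scheme$match, scheme$mismatch,
                   scheme$gap_open, scheme$gap_extend, scheme$mode)
}

cigar_ref_len <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(n[op %in% c("M", "D", "N", "=", "X")])
}

cigar_query_len <- function(cigar) {
  if (is.na(cigar) || cigar == "*") return(0L)
  ops <- regmatches(cigar, gregexpr("\\d+[MIDNSHP=X]", cigar))[[1]]
  n <- as.integer(sub("[A-Z=]$", "", ops))
  op <- sub("^\\d+", "", ops)
  sum(n[op %in% c("M", "I", "S", "=", "X")])
}

#' Map a single read against the paired genome index
#'
#' Two attempts are made, matching a directional bisulfite library: the
#' read as given is sketched and queried against the CT index and its
#' candidates extended under the CT scheme; the reverse complement is
#' queried against the GA index and extended under the GA scheme. The
#' single highest-scoring alignment wins (ties broken by contig order then
#' position). The read is unmapped when no candidate passes the vote rule
#' or the best score falls below `min_score_fraction * match * read_len`.
#' The mapping-quality surrogate is 0 when the two best distinct positions
#' tie, else `min(60, 4 * (best - second_best))`.
#'
#' @param read_id read name.
#' @param read read sequence (length at most the index overlap `tau`).
#' @param gindex a [build_genome_index()] object.
#' @param rule a [candidate_rule()].
#' @param scoring base [scoring_scheme()] (its mode is set per attempt).
#' @param min_score_fraction acceptance threshold as a fraction of the
#'   perfect-match score.
#' @return A list of class `bh_alignment` (fields `read_id`, `mapped`,
#'   `contig`, `pos` (0-based), `strand_mode`, `score`, `cigar`,
#'   `query_start`, `query_end`, `mapq`, `n_candidates`,
#'   `secondary_best_score`, `seq_out`).
#' @export
map_read <- function(read_id, read, gindex, rule = candidate_rule(),
                     scoring = scoring_scheme(), min_score_fraction = 0.66) {
  stopifnot(inherits(gindex, "bh_genome_index"))
  read <- toupper(read)
  tau <- gindex$params$tau
  if (nchar(read) > tau)
    stop("read '", read_id, "' is longer (", nchar(read),
         " bp) than the index overlap tau (", tau, " bp)")
  attempts <- list(
    list(seq = read, mode = "ct", strand_mode = "CT_forward"),
    list(seq = revcomp(read), mode = "ga", strand_mode = "GA_revcomp"))
  hits <- list()
  n_candidates <- 0L
  for (at in attempts) {
    idx <- gindex[[at$mode]]
    km <- shingle(at$seq, idx$config$k)
    if (!length(km)) next
    sk <- m3hash_sketch(km, idx$config, at$mode)
    cand <- query_index(sk, idx, rule)
    n_candidates <- n_candidates + nrow(cand)
    if (!nrow(cand)) next
    sch <- scoring; sch$mode <- at$mode
    segs <- idx$segments[match(cand$segment_id, idx$segments$segment_id), ]
    for (s in seq_len(nrow(segs))) {
      al <- bisulfite_sw(at$seq, segs$sequence[s], sch)
      if (al$score <= 0) next
      hits[[length(hits) + 1L]] <- list(
        contig = segs$contig[s], pos = segs$start[s] + al$ref_start,
        score = al$score, cigar = al$cigar,
        query_start = al$query_start, query_end = al$query_end,
        strand_mode = at$strand_mode, seq_out = at$seq)
    }
  }
  unmapped <- list(read_id = read_id, mapped = FALSE, contig = NA_character_,
                   pos = NA_integer_, strand_mode = NA_character_,
                   score = 0L, cigar = NA_character_,
                   query_start = NA_integer_, query_end = NA_integer_,
                   mapq = 0L, n_candidates = n_candidates,
                   secondary_best_score = NA_integer_, seq_out = read)
  class(unmapped) <- "bh_alignment"
  if (!length(hits)) return(unmapped)
  contig_rank <- match(vapply(hits, `[[`, "", "contig"), names(gindex$contigs))
  scores <- vapply(hits, `[[`, 0L, "score")
  poss <- vapply(hits, `[[`, 0L, "pos")
  ord <- order(-scores, contig_rank, poss)
  hits <- hits[ord]; scores <- scores[ord]
  best <- hits[[1L]]
  if (best$score < min_score_fraction * scoring$match * nchar(read))
    return(unmapped)
  # best score at each distinct position, for the mapq surrogate
  key <- vapply(hits, function(h) paste(h$contig, h$pos), "")
  second <- 0L; tie <- FALSE
  seen_other <- key != key[1L]
  if (any(seen_other)) {
    second <- max(scores[seen_other])
    tie <- second == best$score
  }
  mapq <- if (tie) 0L else min(60L, 4L * (best$score - second))
  structure(list(read_id = read_id, mapped = TRUE, contig = best$contig,
                 pos = best$pos, strand_mode = best$strand_mode,
                 score = best$score, cigar = best$cigar,
                 query_start = best$query_start, query_end = best$query_end,
                 mapq = as.integer(mapq), n_candidates = n_candidates,
                 secondary_best_score = if (second > 0) as.integer(second) else NA_integer_,
                 seq_out = best$seq_out),
            class = "bh_alignment")
}

sam_header <- function(gindex, cl = "bishash") {
  c("@HD\tVN:1.6\tSO:unknown",
    sprintf("@SQ\tSN:%s\tLN:%d", names(gindex$contigs), gindex$contigs),
    sprintf("@PG\tID:bishash\tPN:bishash\tVN:%s\tCL:%s",
            as.character(packageVersion("bishash")), cl))
}

sam_record <- function(aln, qual = NULL) {
  seq_out <- aln$seq_out
  if (is.null(qual)) qual <- strrep("I", nchar(seq_out))
  if (!aln$mapped) {
    return(paste(aln$read_id, 4L, "*", 0L, 0L, "*", "*", 0L, 0L,
                 seq_out, qual, paste0("XC:i:", aln$n_candidates), sep = "\t"))
  }
  flag <- if (aln$strand_mode == "GA_revcomp") 16L else 0L
  # soft-clip the unaligned read ends so the CIGAR spans the stored SEQ
  lead <- aln$query_start
  trail <- nchar(seq_out) - aln$query_end
  cigar <- paste0(if (lead > 0) paste0(lead, "S") else "", aln$cigar,
                  if (trail > 0) paste0(trail, "S") else "")
  paste(aln$read_id, flag, aln$contig, aln$pos + 1L, aln$mapq, cigar,
        "*", 0L, 0L, seq_out, qual,
        paste0("AS:i:", aln$score),
        paste0("XC:i:", aln$n_candidates),
        paste0("XM:Z:", if (flag == 16L) "GA" else "CT"),
        sep = "\t")
}

read_fastq <- function(path) {
  x <- tryCatch(Biostrings::readDNAStringSet(path, format = "fastq"),
                error = function(e) stop("malformed FASTQ '", path, "': ",
                                         conditionMessage(e), call. = FALSE))
  setNames(as.character(x), sub("\\s.*$", "", names(x)))
}

#' Align a FASTQ file and write SAM
#'
#' Streams reads through [map_read()] and writes one SAM record per read
#' (FLAG 4 for unmapped reads, FLAG 16 for bottom-strand alignments, tags
#' `AS` score, `XC` candidate count, `XM` conversion mode). Reads are
#' processed in input order; the `threads` argument is accepted for
#' interface compatibility and validated, but processing is serial so
#' output bytes never depend on it.
#'
#' @param fastq_path input FASTQ (gzip-transparent).
#' @param index index: a `bh_genome_index` or a path from [write_index()].
#' @param out_sam_path output SAM path.
#' @param rule a [candidate_rule()].
#' @param scoring a [scoring_scheme()].
#' @param min_score_fraction see [map_read()].
#' @param threads positive integer (accepted; output-invariant).
#' @param cl command line recorded in the SAM `@PG` header.
#' @return List `summary`: `n_reads`, `n_mapped`, `n_unmapped`.
#' @export
align_file <- function(fastq_path, index, out_sam_path,
                       rule = candidate_rule(), scoring = scoring_scheme(),
                       min_score_fraction = 0.66, threads = 1L,
                       cl = "bishash align") {
  stopifnot(threads >= 1)
  gindex <- if (inherits(index, "bh_genome_index")) index else read_index(index)
  reads <- read_fastq(fastq_path)
  con <- file(out_sam_path, "w")
  on.exit(close(con))
  writeLines(sam_header(gindex, cl), con)
  n_mapped <- 0L
  if (length(reads)) {
    recs <- character(length(reads))
    for (i in seq_along(reads)) {
      aln <- map_read(names(reads)[i], reads[[i]], gindex, rule, scoring,
                      min_score_fraction)
      if (aln$mapped) n_mapped <- n_mapped + 1L
      recs[i] <- sam_record(aln)
    }
    writeLines(recs, con)
  }
  list(n_reads = length(reads), n_mapped = n_mapped,
       n_unmapped = length(reads) - n_mapped)
}
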