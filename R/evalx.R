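#' Parse alignment records from a SAM file
#'
#' Minimal reader for the evaluator: returns one row per record with the
#' fields the evaluation needs. Multi-segment records are not expected
#' (single-end pipeline).
#'
#' @param sam_path SAM file path.
#' @return data.frame with `read_id`, `flag`, `contig`, `pos` (1-based SAM
#'   POS, 0 for unmapped), `mapq`, `cigar`.
#' @export
read_sam <- function(sam_path) {
  if (!file.exists(sam_path)) stop("SAM file not found: ", sam_path)
  lines <- readLines(sam_path)
  lines <- lines[!startsWith(lines, "@")]
  if (!length(lines))
    return(data.frame(read_id = character(0), flag = integer(0),
                      contig = character(0), pos = integer(0),
                      mapq = integer(0), cigar = character(0),
                      stringsAsFactors = FALSE))
  f <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(f)
  if (any(nf < 11))
    stop("unparsable SAM record at data line ", which(nf < 11)[1],
         " (fewer than 11 fields)")
  flag <- suppressWarnings(as.integer(vapply(f, `[[`, "", 2L)))
  pos <- suppressWarnings(as.integer(vapply(f, `[[`, "", 4L)))
  mapq <- suppressWarnings(as.integer(vapply(f, `[[`, "", 5L)))
  if (anyNA(flag) || anyNA(pos) || anyNA(mapq))
    stop("unparsable SAM record: non-numeric FLAG/POS/MAPQ")
  data.frame(read_id = vapply(f, `[[`, "", 1L), flag = flag,
             contig = vapply(f, `[[`, "", 3L), pos = pos, mapq = mapq,
             cigar = vapply(f, `[[`, "", 6L), stringsAsFactors = FALSE)
}

#' Score alignments against the simulated ground truth
#'
#' A mapped read is counted correct when its contig matches the truth
#' record and its reported leftmost position is within `tolerance_bp` of
#' the true 0-based start (SAM positions are 1-based; the conversion is
#' internal). The false discovery rate is the fraction of mapped reads
#' that are incorrect, defined as 0 when nothing is mapped.
#'
#' @param sam_path SAM file (or a data.frame from [read_sam()]).
#' @param truth_path truth TSV from [write_truth()] (or its data.frame).
#' @param tolerance_bp positional tolerance in bp (default 1).
#' @param require_strand if `TRUE`, the alignment strand (FLAG bit 16 =>
#'   `-`) must also match the truth strand.
#' @return A list of class `bh_eval`: `n_reads`, `n_mapped`, `n_correct`,
#'   `n_incorrect`, `pct_correct_all` and `pct_correct_mapped` (percent of
#'   all reads resp. of mapped reads within tolerance), `fdr`.
#' @export
evaluate_alignments <- function(sam_path, truth_path, tolerance_bp = 1L,
                                require_strand = FALSE) {
  sam <- if (is.data.frame(sam_path)) sam_path else read_sam(sam_path)
  truth <- if (is.data.frame(truth_path)) truth_path else read_truth(truth_path)
  missing <- setdiff(sam$read_id, truth$read_id)
  if (length(missing))
    stop("read ids absent from the truth table: ",
         paste(utils::head(missing, 5), collapse = ", "),
         if (length(missing) > 5) sprintf(" (and %d more)", length(missing) - 5))
  m <- match(sam$read_id, truth$read_id)
  mapped <- bitwAnd(sam$flag, 4L) == 0L
  pos0 <- sam$pos - 1L
  ok <- mapped & sam$contig == truth$contig[m] &
    abs(pos0 - truth$start_0based[m]) <= tolerance_bp
  if (require_strand) {
    strand <- ifelse(bitwAnd(sam$flag, 16L) != 0L, "-", "+")
    ok <- ok & strand == truth$strand[m]
  }
  n_reads <- nrow(sam); n_mapped <- sum(mapped); n_correct <- sum(ok)
  n_incorrect <- n_mapped - n_correct
  structure(list(
    n_reads = n_reads, n_mapped = n_mapped, n_correct = n_correct,
    n_incorrect = n_incorrect,
    pct_correct_all = if (n_reads > 0) 100 * n_correct / n_reads else 0,
    pct_correct_mapped = if (n_mapped > 0) 100 * n_correct / n_mapped else 0,
    fdr = if (n_mapped > 0) n_incorrect / n_mapped else 0,
    tolerance_bp = as.integer(tolerance_bp)), class = "bh_eval")
}

#' @export
print.bh_eval <- function(x, ...) {
  cat(sprintf(paste0("alignment evaluation (tolerance %d bp):\n",
                     "  reads %d | mapped %d | correct %d | incorrect %d\n",
                     "  %% correct (all) %.2f | %% correct (mapped) %.2f | FDR %.4f\n"),
              x$tolerance_bp, x$n_reads, x$n_mapped, x$n_correct,
              x$n_incorrect, x$pct_correct_all, x$pct_correct_mapped, x$fdr))
  invisible(x)
}
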