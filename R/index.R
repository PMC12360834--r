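#' Indexing parameters
#'
#' `T` is the segment length and `tau` the minimum overlap between
#' consecutive segments; `tau` must be at least the maximum read length so
#' every read window is fully contained in some segment. Segments step by
#' `T - tau`, with the final segment anchored at the contig end.
#'
#' @param T segment length in bp.
#' @param tau overlap in bp, `1 <= tau < T`.
#' @param sketch an [sketch_config()]; its metric list is replaced per
#'   conversion mode at build time (identity + the mode's collapse).
#' @return An object of class `bh_index_params`.
#' @export
index_params <- function(T = 500L, tau = 300L, sketch = sketch_config()) {
  T <- as.integer(T); tau <- as.integer(tau)
  if (!(T > tau && tau >= 1)) stop("need T > tau >= 1")
  structure(list(T = T, tau = tau, sketch = sketch), class = "bh_index_params")
}

#' Read a (possibly gzipped) FASTA reference
#'
#' @param path FASTA file path.
#' @return Named character vector of contig sequences (uppercase).
#' @export
read_reference <- function(path) {
  if (!file.exists(path)) stop("reference FASTA not found: ", path)
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("reference FASTA is empty: ", path)
  seqs <- toupper(as.character(x))
  names(seqs) <- sub("\\s.*$", "", names(x))
  seqs
}

#' Split a reference into overlapping segments
#'
#' Per contig, segments of length `T` start at multiples of `T - tau`; the
#' final segment is anchored so it ends exactly at the contig end, which
#' guarantees every window of length at most `tau` lies entirely inside at
#' least one segment. Contigs shorter than `T` yield one whole-contig
#' segment.
#'
#' @param reference named character vector of contig sequences, or a FASTA
#'   path.
#' @param params an [index_params()] object.
#' @return A data.frame with columns `segment_id`, `contig`, `start`
#'   (0-based), `length`, `sequence`.
#' @export
segment_genome <- function(reference, params) {
  stopifnot(inherits(params, "bh_index_params"))
  if (is.character(reference) && length(reference) == 1 && is.null(names(reference)))
    reference <- read_reference(reference)
  if (length(reference) == 0) stop("empty reference")
  T <- params$T; step <- T - params$tau
  out <- vector("list", length(reference))
  for (ci in seq_along(reference)) {
    len <- nchar(reference[[ci]])
    if (len <= T) {
      starts <- 0L
    } else {
      starts <- seq.int(0L, len - T, by = step)
      if (starts[length(starts)] < len - T) starts <- c(starts, len - T)
    }
    lens <- pmin(T, len - starts)
    out[[ci]] <- data.frame(
      contig = names(reference)[ci], start = as.integer(starts),
      length = as.integer(lens),
      sequence = substring(reference[[ci]], starts + 1L, starts + lens),
      stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  res <- cbind(segment_id = seq_len(nrow(res)), res)
  rownames(res) <- NULL
  res
}

mode_metrics <- function(mode) c("identity", mode)

#' Build a sketch-value index over reference segments
#'
#' Sketches every segment under the conversion mode's metric pair
#' (identity + C/T collapse for `"ct"`, identity + G/A collapse for `"ga"`,
#' partitioning under the same collapse) and stores every defined sketch
#' entry in an ordered associative table keyed by (sketch coordinate, hash
#' value) whose payload is the sorted list of segment ids carrying that
#' value.
#'
#' @param segments data.frame from [segment_genome()].
#' @param params an [index_params()].
#' @param mode `"ct"` or `"ga"`.
#' @return An object of class `bh_segment_index`.
#' @export
build_index <- function(segments, params, mode = c("ct", "ga")) {
  mode <- match.arg(mode)
  stopifnot(inherits(params, "bh_index_params"))
  cfg <- params$sketch
  cfg <- sketch_config(k = cfg$k, kappa = cfg$kappa, metrics = mode_metrics(mode),
                       R = cfg$R, master_seed = cfg$master_seed)
  nslots <- cfg$z * cfg$Delta * cfg$R
  if (nrow(segments) > 0) {
    sk <- cpp_sketch_seqs(segments$sequence, cfg$k, cfg$kappa, cfg$metrics,
                          cfg$R, cfg$master_seed, mode)
    keep <- !is.na(sk)
    lookup <- data.table::data.table(
      coord = rep.int(seq_len(nslots), ncol(sk))[keep],
      value = sk[keep],
      segment_id = rep(segments$segment_id, each = nslots)[keep])
    lookup <- unique(lookup)
  } else {
    lookup <- data.table::data.table(coord = integer(0), value = numeric(0),
                                     segment_id = integer(0))
  }
  data.table::setkeyv(lookup, c("coord", "value"))
  structure(list(mode = mode, config = cfg, params = params,
                 lookup = lookup,
                 segments = segments[, c("segment_id", "contig", "start", "length",
                                         "sequence")]),
            class = "bh_segment_index")
}

#' Candidate selection rule
#'
#' Segments are kept when their vote count is at least
#' `max(min_votes, ceiling(fraction * best_count))`, ranked by votes
#' (ties by ascending segment id) and capped at `max_candidates`.
#'
#' @param min_votes minimum absolute vote count.
#' @param fraction fraction of the best vote count required.
#' @param max_candidates cap on returned candidates.
#' @return A list of class `bh_candidate_rule`.
#' @export
candidate_rule <- function(min_votes = 2L, fraction = 0.8, max_candidates = 10L) {
  stopifnot(min_votes >= 1, fraction >= 0, fraction <= 1, max_candidates >= 1)
  structure(list(min_votes = as.integer(min_votes), fraction = fraction,
                 max_candidates = as.integer(max_candidates)),
            class = "bh_candidate_rule")
}

#' Query an index with a read sketch
#'
#' Looks up every defined coordinate of the read sketch and counts, per
#' segment, how many (cell, metric, repetition, value) coordinates agree —
#' the segment's vote count.
#'
#' @param read_sketch an `m3_sketch` built with the index's configuration.
#' @param index a `bh_segment_index`.
#' @param select a [candidate_rule()].
#' @return data.frame with columns `segment_id`, `vote_count`, ordered by
#'   decreasing votes then ascending segment id.
#' @export
query_index <- function(read_sketch, index, select = candidate_rule()) {
  stopifnot(inherits(read_sketch, "m3_sketch"), inherits(index, "bh_segment_index"))
  if (!identical(read_sketch$fingerprint, index$config$fingerprint) ||
      !identical(read_sketch$index_mode, index$mode))
    stop("read sketch configuration does not match the index")
  v <- as.numeric(read_sketch$values)
  def <- which(!is.na(v))
  empty <- data.frame(segment_id = integer(0), vote_count = integer(0))
  if (!length(def) || nrow(index$lookup) == 0) return(empty)
  hits <- index$lookup[data.table::data.table(coord = def, value = v[def]),
                       on = c("coord", "value"), nomatch = NULL]
  if (nrow(hits) == 0) return(empty)
  counts <- hits[, list(vote_count = .N), by = "segment_id"]
  thr <- max(select$min_votes, ceiling(select$fraction * max(counts$vote_count)))
  counts <- counts[counts$vote_count >= thr, ]
  data.table::setorderv(counts, c("vote_count", "segment_id"), c(-1L, 1L))
  counts <- utils::head(as.data.frame(counts), select$max_candidates)
  rownames(counts) <- NULL
  counts
}

#' Build the paired CT/GA genome index
#'
#' Builds both conversion-mode indexes (forward reads vs the C/T index,
#' reverse-complemented reads vs the G/A index) over one segmentation.
#'
#' @inheritParams segment_genome
#' @return List of class `bh_genome_index` with elements `ct`, `ga`,
#'   `params`, `contigs` (named contig lengths).
#' @export
build_genome_index <- function(reference, params = index_params()) {
  if (is.character(reference) && length(reference) == 1 && is.null(names(reference)))
    reference <- read_reference(reference)
  segs <- segment_genome(reference, params)
  structure(list(ct = build_index(segs, params, "ct"),
                 ga = build_index(segs, params, "ga"),
                 params = params,
                 contigs = setNames(nchar(reference), names(reference))),
            class = "bh_genome_index")
}

INDEX_FORMAT_VERSION <- 1L

#' Write / read a genome index
#'
#' The container is R-native serialization with a format-version stamp and
#' the sketch configuration fingerprint, checked on load.
#'
#' @param index a `bh_genome_index`.
#' @param path file path (conventionally `.bhx`).
#' @return `write_index` returns `path` invisibly; `read_index` the index.
#' @export
write_index <- function(index, path) {
  stopifnot(inherits(index, "bh_genome_index"))
  saveRDS(list(magic = "bishash-index", version = INDEX_FORMAT_VERSION,
               fingerprint = index$ct$config$fingerprint, index = index),
          path)
  invisible(path)
}

#' @rdname write_index
#' @export
read_index <- function(path) {
  if (!file.exists(path)) stop("index file not found: ", path)
  x <- readRDS(path)
  if (!identical(x$magic, "bishash-index"))
    stop("not a bishash index file: ", path)
  if (!identical(x$version, INDEX_FORMAT_VERSION))
    stop("unsupported index format version: ", x$version)
  if (!identical(x$fingerprint, x$index$ct$config$fingerprint))
    stop("index fingerprint mismatch (corrupt file?)")
  x$index
}
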