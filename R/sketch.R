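#' Sketch configuration for multi-metric MinHash
#'
#' Bundles the tunables of a multi-metric MinHash sketch: the k-mer length
#' `k`, the prefix length `kappa` used to partition the k-mer universe into
#' `z = 3^kappa` cells (the prefix is read in a 3-letter collapsed alphabet
#' so that bisulfite conversion cannot move a k-mer across cells), the
#' ordered metric family (`"identity"`, `"ct"` for the C/T letter collapse,
#' `"ga"` for G/A), the number of independent seeded repetitions `R` per
#' (cell, metric) coordinate, and the master seed from which all per-slot
#' hash seeds are derived deterministically.
#'
#' @param k shingle (k-mer) length in bases, `1 <= k <= 31`.
#' @param kappa partition prefix length; `z = 3^kappa` cells; `kappa < k`.
#' @param metrics ordered character vector of metric modes, each one of
#'   `"identity"`, `"ct"`, `"ga"`.
#' @param R repetitions (independent hash seeds) per (cell, metric).
#' @param master_seed non-negative integer-valued seed (< 2^53).
#' @return An object of class `m3_config`.
#' @examples
#' cfg <- sketch_config(k = 16, kappa = 2, metrics = c("identity", "ct"))
#' cfg$z   # 9 cells
#' @export
sketch_config <- function(k = 16L, kappa = 2L, metrics = c("identity", "ct"),
                          R = 4L, master_seed = 42) {
  k <- as.integer(k); kappa <- as.integer(kappa); R <- as.integer(R)
  stopifnot(k >= 1, k <= 31, kappa >= 0, kappa < k, R >= 1, length(metrics) >= 1)
  if (!all(metrics %in% c("identity", "ct", "ga")))
    stop("metrics must be drawn from 'identity', 'ct', 'ga'")
  if (master_seed < 0 || master_seed != floor(master_seed) || master_seed >= 2^53)
    stop("master_seed must be a non-negative integer below 2^53")
  cfg <- structure(list(k = k, kappa = kappa, z = 3L^kappa,
                        metrics = as.character(metrics),
                        Delta = length(metrics), R = R,
                        master_seed = as.numeric(master_seed)),
                   class = "m3_config")
  cfg$fingerprint <- config_fingerprint(cfg)
  cfg
}

config_fingerprint <- function(cfg) {
  paste("m3", cfg$k, cfg$kappa, paste(cfg$metrics, collapse = "+"),
        cfg$R, format(cfg$master_seed, scientific = FALSE), sep = ":")
}

#' @export
print.m3_config <- function(x, ...) {
  cat(sprintf("m3hash config: k=%d kappa=%d (z=%d) metrics=%s R=%d seed=%s\n",
              x$k, x$kappa, x$z, paste(x$metrics, collapse = ","), x$R,
              format(x$master_seed, scientific = FALSE)))
  invisible(x)
}

#' Extract the distinct k-mer set of a sequence
#'
#' Uppercases the input and returns each distinct length-`k` substring made
#' only of A/C/G/T, in order of first occurrence. Windows touching any other
#' letter (e.g. N) are dropped; sequences shorter than `k` yield an empty
#' set.
#'
#' @param sequence a single nucleotide string.
#' @param k k-mer length.
#' @return Character vector of distinct k-mers (possibly empty).
#' @examples
#' shingle("ACGTA", 3)   # "ACG" "CGT" "GTA"
#' @export
shingle <- function(sequence, k) {
  stopifnot(is.character(sequence), length(sequence) == 1)
  cpp_shingle(sequence, as.integer(k))
}

#' Collapse a k-mer under a metric mode
#'
#' `"ct"` maps every C to T, `"ga"` maps every G to A, `"identity"` leaves
#' the k-mer unchanged. Two k-mers are equivalent under a metric exactly
#' when their collapsed images are equal; the collapse is idempotent.
#'
#' @param kmer character vector of k-mers over A/C/G/T.
#' @param mode one of `"identity"`, `"ct"`, `"ga"`.
#' @return Character vector of collapsed images.
#' @export
collapse_kmer <- function(kmer, mode = c("identity", "ct", "ga")) {
  mode <- match.arg(mode)
  cpp_collapse(kmer, mode)
}

#' Partition cell of a k-mer
#'
#' Encodes the first `kappa` letters of the k-mer, read in the 3-letter
#' collapsed alphabet of `index_mode`, as a base-3 number. Digits are the
#' alphabetical rank of the collapsed letter: A=0, G=1, merged C/T=2 under
#' `"ct"`; merged G/A=0, C=1, T=2 under `"ga"`. Cells range over
#' `0 .. 3^kappa - 1`.
#'
#' @param kmer character vector of k-mers.
#' @param kappa prefix length, at most the k-mer length.
#' @param index_mode `"ct"` or `"ga"`.
#' @return Integer vector of cell indices.
#' @examples
#' partition_index("CGAA", 2, "ct")  # C -> merged (2), G -> 1: cell 7
#' @export
partition_index <- function(kmer, kappa, index_mode = c("ct", "ga")) {
  index_mode <- match.arg(index_mode)
  cpp_partition_index(kmer, as.integer(kappa), index_mode)
}

#' Seeded metric-respecting k-mer hash
#'
#' Hashes the collapsed image of a k-mer with a 64-bit mixing function, so
#' that k-mers equivalent under the metric always receive equal values
#' (required for MinHash sketches to estimate metric-mediated Jaccard
#' similarity). Values are 53-bit non-negative integers stored exactly in
#' doubles.
#'
#' @inheritParams collapse_kmer
#' @param seed non-negative integer-valued hash seed.
#' @return Numeric vector of hash values.
#' @export
base_hash <- function(kmer, mode = c("identity", "ct", "ga"), seed = 0) {
  mode <- match.arg(mode)
  cpp_base_hash(kmer, mode, as.numeric(seed))
}

#' Build a multi-metric MinHash sketch
#'
#' For every (cell `i`, metric `j`, repetition `r`) coordinate, the sketch
#' stores the minimum seeded hash of the collapsed images of the k-mers
#' falling in cell `i`; coordinates of cells that received no k-mer are
#' undefined (`NA`). Since partitioning depends only on the cell prefix,
#' undefined status is identical across metrics and repetitions of a cell.
#'
#' @param kmers character vector of k-mers (a k-mer set), e.g. from
#'   [shingle()].
#' @param config an [sketch_config()] object.
#' @param index_mode `"ct"` or `"ga"`; governs partitioning only.
#' @return An `m3_sketch`: list with `values` (numeric array `z x Delta x R`,
#'   `NA` = undefined), `fingerprint`, `index_mode`, `config`.
#' @export
m3hash_sketch <- function(kmers, config, index_mode = c("ct", "ga")) {
  index_mode <- match.arg(index_mode)
  stopifnot(inherits(config, "m3_config"))
  v <- cpp_sketch(as.character(kmers), config$k, config$kappa, config$metrics,
                  config$R, config$master_seed, index_mode)
  structure(list(values = array(v, dim = c(config$z, config$Delta, config$R)),
                 fingerprint = config$fingerprint,
                 index_mode = index_mode, config = config),
            class = "m3_sketch")
}

#' Compare two multi-metric MinHash sketches
#'
#' For each (cell, repetition) pair the match indicator is 1 when some
#' metric's values are defined and equal, or when the cell is empty in both
#' sketches; a cell empty on one side only never matches. `xi_s` (the
#' multi-metric match statistic) is the mean indicator over cells and
#' repetitions and estimates the multi-metric Jaccard similarity.
#'
#' @param a,b `m3_sketch` objects built with identical configurations and
#'   index modes.
#' @return A list of class `m3_match` with `xi_per_cell` (length-`z` means
#'   over repetitions), `xi_s`, and `vote_count` (number of equal defined
#'   coordinates).
#' @export
compare_sketches <- function(a, b) {
  stopifnot(inherits(a, "m3_sketch"), inherits(b, "m3_sketch"))
  if (!identical(a$fingerprint, b$fingerprint) ||
      !identical(a$index_mode, b$index_mode))
    stop("sketches were built with different configurations")
  va <- a$values; vb <- b$values
  eq <- !is.na(va) & !is.na(vb) & va == vb           # z x Delta x R
  empty_a <- is.na(va[, 1, 1]); empty_b <- is.na(vb[, 1, 1])
  z <- dim(va)[1]; R <- dim(va)[3]
  xi_ir <- apply(eq, c(1, 3), any)                   # z x R: exists j
  xi_ir <- matrix(xi_ir, nrow = z, ncol = R)
  xi_ir[empty_a & empty_b, ] <- TRUE                 # both undefined: match
  xi_per_cell <- rowMeans(xi_ir)
  structure(list(xi_per_cell = xi_per_cell, xi_s = mean(xi_per_cell),
                 vote_count = sum(eq)),
            class = "m3_match")
}

#' Classic and multi-metric Jaccard similarity of two k-mer sets
#'
#' The classic Jaccard similarity is `|A ∩ B| / |A ∪ B|` (0 when both sets
#' are empty). The multi-metric variant partitions the k-mer universe into
#' the cells of `index_mode` and, per cell, picks the metric maximising the
#' metric-mediated intersection — the number of members of A in the cell
#' whose collapsed image also occurs among the collapsed images of B's
#' members in the cell — then sums the per-cell maxima over `|A ∪ B|`.
#' Because the per-cell terms are independent, the maximum over all
#' `Delta^z` metric assignments decomposes cell by cell.
#'
#' @param a,b character vectors of k-mers (k-mer sets).
#' @inheritParams m3hash_sketch
#' @return A list of class `jaccard_report`: `classic`, `multi_metric`, and
#'   `per_cell_best_metric` (1-based index into `config$metrics` of the
#'   metric attaining each cell's maximum; ties resolve to the first listed
#'   metric, cells with zero intersection report `NA`).
#' @export
multi_metric_jaccard <- function(a, b, config, index_mode = c("ct", "ga")) {
  index_mode <- match.arg(index_mode)
  stopifnot(inherits(config, "m3_config"))
  a <- unique(as.character(a)); b <- unique(as.character(b))
  n_union <- length(union(a, b))
  classic <- if (n_union == 0) 0 else length(intersect(a, b)) / n_union
  z <- config$z
  best <- numeric(z); best_metric <- rep(NA_integer_, z)
  if (n_union > 0) {
    cell_a <- if (length(a)) cpp_partition_index(a, config$kappa, index_mode) else integer(0)
    cell_b <- if (length(b)) cpp_partition_index(b, config$kappa, index_mode) else integer(0)
    for (i in seq_len(z) - 1L) {
      ai <- a[cell_a == i]; bi <- b[cell_b == i]
      if (!length(ai) || !length(bi)) next
      for (j in seq_along(config$metrics)) {
        m <- config$metrics[j]
        cnt <- sum(cpp_collapse(ai, m) %in% cpp_collapse(bi, m))
        if (cnt > best[i + 1L]) { best[i + 1L] <- cnt; best_metric[i + 1L] <- j }
      }
    }
  }
  mm <- if (n_union == 0) 0 else sum(best) / n_union
  structure(list(classic = classic, multi_metric = mm,
                 per_cell_best_metric = best_metric),
            class = "jaccard_report")
}
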