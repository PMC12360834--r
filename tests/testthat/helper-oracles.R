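# Independent oracles and fixture builders shared across the suite.
# Oracles deliberately avoid the package's own code paths.

BASES <- c("A", "C", "G", "T")

`%||%` <- function(a, b) if (is.null(a)) b else a

random_seq <- function(n, bases = BASES) {
  paste(sample(bases, n, replace = TRUE), collapse = "")
}

# random k-mer set of about n distinct k-mers
random_kmer_set <- function(n, k) {
  unique(vapply(seq_len(n), function(i) random_seq(k), character(1)))
}

# a pair of k-mer sets with controlled overlap
random_set_pair <- function(n, k, shared_frac = 0.5) {
  shared <- random_kmer_set(ceiling(n * shared_frac), k)
  a <- unique(c(shared, random_kmer_set(n, k)))
  b <- unique(c(shared, random_kmer_set(n, k)))
  list(a = a, b = b)
}

classic_jaccard <- function(a, b) {
  u <- length(union(a, b))
  if (u == 0) 0 else length(intersect(a, b)) / u
}

collapse_str <- function(x, mode) {
  switch(mode,
         identity = x,
         ct = chartr("C", "T", x),
         ga = chartr("G", "A", x),
         stop("bad mode"))
}

# partition of a k-mer set by collapsed kappa-prefix, independent of the
# package: digit = alphabetical rank of the collapsed letter
oracle_cells <- function(kmers, kappa, index_mode) {
  if (!length(kmers)) return(integer(0))
  pref <- collapse_str(substr(kmers, 1, kappa), index_mode)
  alphabet <- sort(unique(collapse_str(BASES, index_mode)))
  vapply(strsplit(pref, ""), function(ltrs) {
    sum((match(ltrs, alphabet) - 1L) * 3L^rev(seq_along(ltrs) - 1L))
  }, numeric(1))
}

# metric-mediated intersection count: members of a whose collapsed image
# occurs among collapsed images of b
med_intersection <- function(a, b, mode) {
  sum(collapse_str(a, mode) %in% collapse_str(b, mode))
}

# exhaustive Delta^z maximisation of the multi-metric Jaccard similarity
jsim_exhaustive <- function(a, b, metrics, kappa, index_mode) {
  a <- unique(a); b <- unique(b)
  u <- length(union(a, b))
  if (u == 0) return(0)
  z <- 3L^kappa
  ca <- oracle_cells(a, kappa, index_mode)
  cb <- oracle_cells(b, kappa, index_mode)
  per_cell <- lapply(seq_len(z) - 1L, function(i) {
    vapply(metrics, function(m) med_intersection(a[ca == i], b[cb == i], m),
           numeric(1))
  })
  grid <- expand.grid(rep(list(seq_along(metrics)), z))
  best <- 0
  for (g in seq_len(nrow(grid))) {
    tot <- sum(vapply(seq_len(z), function(i) per_cell[[i]][grid[g, i][[1]]],
                      numeric(1)))
    if (tot > best) best <- tot
  }
  best / u
}

# closed-form expectation of the multi-metric match statistic:
# (1/z) * sum_i [1 - prod_j (1 - J(c_j(A_i), c_j(B_i)))],
# both-empty cells counting as matches, one-empty cells as non-matches
closed_form_xi <- function(a, b, metrics, kappa, index_mode) {
  z <- 3L^kappa
  ca <- oracle_cells(a, kappa, index_mode)
  cb <- oracle_cells(b, kappa, index_mode)
  terms <- vapply(seq_len(z) - 1L, function(i) {
    ai <- a[ca == i]; bi <- b[cb == i]
    if (!length(ai) && !length(bi)) return(1)
    if (!length(ai) || !length(bi)) return(0)
    js <- vapply(metrics, function(m)
      classic_jaccard(unique(collapse_str(ai, m)), unique(collapse_str(bi, m))),
      numeric(1))
    1 - prod(1 - js)
  }, numeric(1))
  mean(terms)
}

# reference affine-gap local aligner (score only), symmetric matches,
# full-matrix form kept deliberately naive. Same gap convention as the
# package documents: first gap base costs gap_open, each further base
# gap_extend, gaps open from the match state.
ref_local_align <- function(q, r, match = 2, mismatch = -3,
                            gap_open = -5, gap_extend = -2) {
  qc <- strsplit(toupper(q), "")[[1]]
  rc <- strsplit(toupper(r), "")[[1]]
  n <- length(qc); m <- length(rc)
  NEG <- -1e9
  H <- matrix(0, n + 1, m + 1)
  D <- matrix(NEG, n + 1, m + 1)
  I <- matrix(NEG, n + 1, m + 1)
  for (i in seq_len(n)) {
    for (j in seq_len(m)) {
      s <- if (qc[i] == rc[j]) match else mismatch
      H[i + 1, j + 1] <- max(0, max(H[i, j], D[i, j], I[i, j]) + s)
      D[i + 1, j + 1] <- max(H[i + 1, j] + gap_open, D[i + 1, j] + gap_extend)
      I[i + 1, j + 1] <- max(H[i, j + 1] + gap_open, I[i, j + 1] + gap_extend)
    }
  }
  max(H)
}

# reverse complement, independent of the package helper
rc_oracle <- function(x) {
  paste(rev(strsplit(chartr("ACGT", "TGCA", x), "")[[1]]), collapse = "")
}

# fully bisulfite-convert a sequence (every C -> T)
full_ct <- function(x) chartr("C", "T", x)

# write a minimal FASTQ for fixture reads
fixture_fastq <- function(ids, seqs, path) {
  writeLines(paste0("@", ids, "\n", seqs, "\n+\n",
                    strrep("I", nchar(seqs))), path)
  path
}

toy_genome <- function(len = 10000, seed = 99, name = "toy") {
  set.seed(seed)
  setNames(paste(sample(BASES, len, replace = TRUE), collapse = ""), name)
}

default_test_params <- function(T = 500, tau = 300, seed = 42)
  index_params(T, tau, sketch_config(k = 16, kappa = 2, R = 4, master_seed = seed))
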