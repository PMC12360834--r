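#' Generate a synthetic reference genome
#'
#' Bases are drawn i.i.d. at the target GC content; optionally, CpG-island
#' blocks (elevated GC and explicitly planted CG dinucleotides) are
#' embedded so that "normal", CpG-structured methylation landscapes can be
#' exercised. Island intervals are recorded in the `islands` attribute
#' (one data.frame of 0-based `start`/`end` per contig) for use by
#' [assign_methylation()]. This is a synthetic stand-in for a real genome,
#' built for desk-scale simulation studies.
#'
#' @param n_contigs number of contigs.
#' @param contig_len length of each contig in bp.
#' @param gc_content background GC fraction, strictly in (0, 1).
#' @param cpg_island_density fraction of each contig covered by islands.
#' @param island_len island length in bp.
#' @param seed RNG seed.
#' @return Named character vector of contig sequences with an `islands`
#'   attribute.
#' @export
generate_reference <- function(n_contigs = 1L, contig_len = 200000L,
                               gc_content = 0.42, cpg_island_density = 0.01,
                               island_len = 600L, seed = 1) {
  stopifnot(contig_len >= 1, gc_content > 0, gc_content < 1,
            cpg_island_density >= 0, cpg_island_density < 1)
  with_seed(seed, {
    seqs <- character(n_contigs)
    islands <- vector("list", n_contigs)
    base_p <- c(A = (1 - gc_content) / 2, C = gc_content / 2,
                G = gc_content / 2, T = (1 - gc_content) / 2)
    for (ci in seq_len(n_contigs)) {
      s <- sample(names(base_p), contig_len, replace = TRUE, prob = base_p)
      n_isl <- floor(cpg_island_density * contig_len / island_len)
      isl <- data.frame(start = integer(0), end = integer(0))
      if (n_isl > 0 && contig_len > island_len) {
        starts <- sort(sample.int(contig_len - island_len, n_isl))
        # drop overlapping islands, keep the earlier one
        keep <- c(TRUE, diff(starts) >= island_len)
        starts <- starts[keep]
        for (st in starts) {
          idx <- st:(st + island_len - 1L)
          s[idx] <- sample(names(base_p), island_len, replace = TRUE,
                           prob = c(A = 0.2, C = 0.3, G = 0.3, T = 0.2))
          # plant CG dinucleotides at an elevated rate
          at <- which(runif(island_len - 1L) < 0.08)
          s[st + at - 1L] <- "C"; s[st + at] <- "G"
        }
        isl <- data.frame(start = starts - 1L,
                          end = starts - 1L + island_len)
      }
      seqs[ci] <- paste(s, collapse = "")
      islands[[ci]] <- isl
    }
    names(seqs) <- sprintf("contig_%d", seq_len(n_contigs))
    names(islands) <- names(seqs)
    attr(seqs, "islands") <- islands
    seqs
  })
}

#' Assign a methylation probability landscape
#'
#' Produces, per contig, one methylation probability per forward-strand
#' cytosine and one per guanine (the proxy for bottom-strand cytosines at
#' the same site). `"normal"` mirrors vertebrate biology qualitatively:
#' CpG-context cytosines are hypermethylated (default 0.8) except inside
#' CpG islands (hypomethylated, default 0.2), and non-CpG cytosines carry a
#' small residual probability (default 0.02). `"random"` draws every
#' probability independently from uniform(0, 1), emulating a disordered
#' landscape such as a cancer methylome.
#'
#' @param reference named character vector of contigs (an `islands`
#'   attribute, as set by [generate_reference()], marks island intervals).
#' @param mode `"normal"` or `"random"`.
#' @param p_cpg,p_island,p_noncpg probabilities used by `"normal"` mode.
#' @param seed RNG seed (used by `"random"` mode).
#' @return A list of class `bh_methylation_profile`: per contig, numeric
#'   vectors `c_prob` and `g_prob` of the contig length with `NA` at
#'   positions without a C (resp. G).
#' @export
assign_methylation <- function(reference, mode = c("normal", "random"),
                               p_cpg = 0.8, p_island = 0.2, p_noncpg = 0.02,
                               seed = 1) {
  mode <- match.arg(mode)
  islands <- attr(reference, "islands")
  out <- with_seed(seed, lapply(seq_along(reference), function(ci) {
    s <- strsplit(reference[[ci]], "")[[1]]
    n <- length(s)
    c_prob <- rep(NA_real_, n); g_prob <- rep(NA_real_, n)
    cpos <- which(s == "C"); gpos <- which(s == "G")
    if (mode == "random") {
      c_prob[cpos] <- runif(length(cpos))
      g_prob[gpos] <- runif(length(gpos))
    } else {
      in_island <- rep(FALSE, n)
      isl <- islands[[ci]]
      if (!is.null(isl) && nrow(isl))
        for (r in seq_len(nrow(isl)))
          in_island[(isl$start[r] + 1L):isl$end[r]] <- TRUE
      # forward C in CpG context: next base is G
      c_cpg <- cpos[cpos < n & s[pmin(cpos + 1L, n)] == "G"]
      c_prob[cpos] <- p_noncpg
      c_prob[c_cpg] <- ifelse(in_island[c_cpg], p_island, p_cpg)
      # bottom-strand C sits at a forward G; CpG context when preceded by C
      g_cpg <- gpos[gpos > 1L & s[pmax(gpos - 1L, 1L)] == "C"]
      g_prob[gpos] <- p_noncpg
      g_prob[g_cpg] <- ifelse(in_island[g_cpg], p_island, p_cpg)
    }
    list(c_prob = c_prob, g_prob = g_prob)
  }))
  names(out) <- names(reference)
  structure(out, mode = mode, class = "bh_methylation_profile")
}

#' Constant methylation profile (for calibration checks)
#'
#' @param reference named character vector of contigs.
#' @param prob single methylation probability applied to every C and G site.
#' @return A `bh_methylation_profile`.
#' @export
flat_methylation <- function(reference, prob) {
  stopifnot(prob >= 0, prob <= 1)
  out <- lapply(reference, function(sq) {
    s <- strsplit(sq, "")[[1]]
    n <- length(s)
    c_prob <- rep(NA_real_, n); g_prob <- rep(NA_real_, n)
    c_prob[s == "C"] <- prob; g_prob[s == "G"] <- prob
    list(c_prob = c_prob, g_prob = g_prob)
  })
  structure(out, mode = "flat", class = "bh_methylation_profile")
}

#' Simulate directional bisulfite reads
#'
#' Each read takes a uniform position over all (contig, offset) windows and
#' a uniform strand. Forward-strand reads copy the reference substring and
#' convert each C to T with probability one minus the site's methylation
#' probability. Bottom-strand reads take the reverse complement of the
#' window and convert its cytosines (forward-strand Gs) using the G-site
#' profile, so they appear as G-to-A changes relative to the forward
#' reference. Uniform substitution errors (to a random different base) are
#' applied last. Base qualities are constant `"I"`.
#'
#' @param reference named character vector of contigs.
#' @param profile a `bh_methylation_profile` over the same contigs.
#' @param n_reads number of reads.
#' @param read_len read length in bp (at most the shortest contig).
#' @param error_rate per-base substitution error probability in `[0, 1)`.
#' @param seed RNG seed.
#' @return List with `reads` (data.frame `id`, `seq`, `qual`) and `truth`
#'   (data.frame `read_id`, `contig`, `start_0based`, `strand`,
#'   `n_conversions`, `n_errors`).
#' @export
simulate_reads <- function(reference, profile, n_reads, read_len = 300L,
                           error_rate = 0.01, seed = 7) {
  stopifnot(inherits(profile, "bh_methylation_profile"),
            error_rate >= 0, error_rate < 1, n_reads >= 0)
  read_len <- as.integer(read_len)
  clens <- nchar(reference)
  if (read_len > min(clens))
    stop("read_len (", read_len, ") exceeds the shortest contig (",
         min(clens), " bp)")
  n_windows <- clens - read_len + 1L
  bases <- c("A", "C", "G", "T")
  with_seed(seed, {
    ids <- sprintf("read_%06d", seq_len(n_reads))
    seqs <- character(n_reads)
    contig <- character(n_reads); start0 <- integer(n_reads)
    strand <- character(n_reads)
    ncv <- integer(n_reads); ner <- integer(n_reads)
    for (i in seq_len(n_reads)) {
      ci <- if (length(reference) == 1) 1L else
        sample.int(length(reference), 1L, prob = n_windows)
      off <- sample.int(n_windows[ci], 1L) - 1L        # 0-based
      fwd <- runif(1) < 0.5
      sub <- substr(reference[[ci]], off + 1L, off + read_len)
      ch <- strsplit(sub, "")[[1]]
      if (fwd) {
        cpos <- which(ch == "C")
        p <- profile[[ci]]$c_prob[off + cpos]
      } else {
        ch <- rev(chartr("ACGT", "TGCA", ch))
        cpos <- which(ch == "C")
        # read position j sits at forward coordinate off + read_len - j + 1
        p <- profile[[ci]]$g_prob[off + read_len - cpos + 1L]
      }
      conv <- logical(0)
      if (length(cpos)) {
        conv <- runif(length(cpos)) < (1 - p)
        ch[cpos[conv]] <- "T"
      }
      err <- which(runif(read_len) < error_rate)
      for (e in err) ch[e] <- sample(setdiff(bases, ch[e]), 1L)
      seqs[i] <- paste(ch, collapse = "")
      contig[i] <- names(reference)[ci]; start0[i] <- off
      strand[i] <- if (fwd) "+" else "-"
      ncv[i] <- sum(conv); ner[i] <- length(err)
    }
    list(reads = data.frame(id = ids, seq = seqs,
                            qual = strrep("I", read_len),
                            stringsAsFactors = FALSE),
         truth = data.frame(read_id = ids, contig = contig,
                            start_0based = start0, strand = strand,
                            n_conversions = ncv, n_errors = ner,
                            stringsAsFactors = FALSE))
  })
}

#' Write simulator outputs
#'
#' @param reads data.frame from [simulate_reads()]`$reads`.
#' @param path output path (`.gz` for gzip).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  if (nrow(reads))
    writeLines(paste0("@", reads$id, "\n", reads$seq, "\n+\n", reads$qual), con)
  invisible(path)
}

#' @rdname write_fastq
#' @param x character vector of contig sequences (for `write_fasta`) or a
#'   truth data.frame (for `write_truth`).
#' @export
write_fasta <- function(x, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(setNames(as.character(x), names(x))),
                              path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
write_truth <- function(x, path) {
  write.table(x, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a simulator truth table
#'
#' @param path TSV written by [write_truth()].
#' @return data.frame of truth records.
#' @export
read_truth <- function(path) {
  if (!file.exists(path)) stop("truth table not found: ", path)
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}
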