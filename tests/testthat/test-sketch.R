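test_that("shingling enumerates distinct ACGT k-mers and drops N windows", {
  expect_setequal(shingle("ACGTA", 3), c("ACG", "CGT", "GTA"))
  expect_equal(shingle("AAAA", 3), "AAA")
  expect_equal(shingle("ACNGA", 3), character(0))
  expect_equal(shingle("acgta", 3), shingle("ACGTA", 3))  # case folding
  expect_equal(shingle("AC", 3), character(0))
  # N breaks the window but flanks still contribute
  expect_setequal(shingle("ACGTNACGT", 4), c("ACGT"))
})

test_that("letter collapse is the declared idempotent map", {
  expect_equal(collapse_kmer("ACT", "ct"), "ATT")
  expect_equal(collapse_kmer("ACG", "ga"), "ACA")
  expect_equal(collapse_kmer("TTT", "ct"), "TTT")
  expect_equal(collapse_kmer("ACGT", "identity"), "ACGT")
  expect_error(collapse_kmer("ACX", "ct"), "malformed")
  set.seed(1)
  for (m in c("ct", "ga")) {
    km <- random_kmer_set(50, 8)
    once <- collapse_kmer(km, m)
    expect_identical(collapse_kmer(once, m), once)  # idempotent
  }
})

test_that("partition cells follow the base-3 collapsed-prefix encoding", {
  expect_equal(partition_index("AAGT", 2, "ct"), 0L)
  expect_equal(partition_index("CGAA", 2, "ct"), 7L)  # C->merged(2), G->1
  # GA mode: merged G/A image is A (digit 0), C = 1, T = 2
  expect_equal(partition_index("GAAA", 2, "ga"), 0L)
  expect_equal(partition_index("CTAA", 2, "ga"), 5L)  # 1*3 + 2
  expect_error(partition_index("AG", 3, "ct"), "kappa")
  # kappa = 2 yields exactly 9 reachable cells
  set.seed(2)
  km <- random_kmer_set(3000, 4)
  cells <- partition_index(km, 2, "ct")
  expect_setequal(unique(cells), 0:8)
  # oracle agreement on the encoding
  expect_equal(cells, as.integer(oracle_cells(km, 2, "ct")))
  expect_equal(partition_index(km, 2, "ga"), as.integer(oracle_cells(km, 2, "ga")))
})

test_that("hashes are constant on metric classes and seed-sensitive", {
  all3 <- apply(expand.grid(BASES, BASES, BASES), 1, paste, collapse = "")
  for (m in c("ct", "ga")) {
    img <- collapse_kmer(all3, m)
    h <- base_hash(all3, m, seed = 7)
    # exhaustive over all 3-mers: equal collapsed image <=> equal hash here
    for (cls in split(h, img)) expect_true(all(cls == cls[1]))
    expect_equal(length(unique(h)), length(unique(img)))
  }
  expect_equal(base_hash("ACT", "ct", 5), base_hash("ATT", "ct", 5))
  expect_false(base_hash("ACT", "identity", 5) == base_hash("ATT", "identity", 5))
  set.seed(3)
  km <- random_kmer_set(100, 10)
  expect_true(any(base_hash(km, "identity", 1) != base_hash(km, "identity", 2)))
  expect_identical(base_hash(km, "identity", 1), base_hash(km, "identity", 1))
})

test_that("sketch construction honours the undefined-cell convention", {
  cfg <- sketch_config(k = 6, kappa = 2, metrics = c("identity", "ct"), R = 3,
                       master_seed = 11)
  s_empty <- m3hash_sketch(character(0), cfg, "ct")
  expect_true(all(is.na(s_empty$values)))
  set.seed(4)
  km <- random_kmer_set(40, 6)
  s1 <- m3hash_sketch(km, cfg, "ct")
  s2 <- m3hash_sketch(km, cfg, "ct")
  expect_identical(s1$values, s2$values)  # bitwise determinism
  # undefined status depends only on the cell: constant across metric and rep
  na_by_cell <- apply(is.na(s1$values), 1, function(x) all(x) || !any(x))
  expect_true(all(na_by_cell))
  occupied <- sort(unique(partition_index(km, cfg$kappa, "ct")))
  expect_identical(which(!is.na(s1$values[, 1, 1])) - 1L, occupied)
})

test_that("C->T image sequences share all collapse-metric sketch entries", {
  cfg <- sketch_config(k = 3, kappa = 1, metrics = c("identity", "ct"), R = 4,
                       master_seed = 5)
  a <- shingle("ACGACGAC", 3)
  b <- shingle(chartr("C", "T", "ACGACGAC"), 3)
  sa <- m3hash_sketch(a, cfg, "ct")
  sb <- m3hash_sketch(b, cfg, "ct")
  ct_a <- sa$values[, 2, ]; ct_b <- sb$values[, 2, ]
  expect_identical(ct_a[!is.na(ct_a)], ct_b[!is.na(ct_b)])
})

test_that("sketch comparison: identity, disjointness, symmetry, range", {
  cfg <- sketch_config(k = 4, kappa = 1, metrics = c("identity", "ct"), R = 5,
                       master_seed = 9)
  set.seed(5)
  km <- random_kmer_set(30, 4)
  s <- m3hash_sketch(km, cfg, "ct")
  expect_equal(compare_sketches(s, s)$xi_s, 1)
  # no shared raw or collapsed k-mer, every cell occupied on both sides
  a <- c("AGGG", "GGGG", "TGGG")
  b <- c("AGGA", "GGGA", "TGGA")
  expect_equal(med_intersection(a, b, "identity") + med_intersection(a, b, "ct"), 0)
  sa <- m3hash_sketch(a, cfg, "ct"); sb <- m3hash_sketch(b, cfg, "ct")
  expect_false(any(is.na(sa$values)) || any(is.na(sb$values)))
  expect_equal(compare_sketches(sa, sb)$xi_s, 0)
  # symmetry and range over random pairs
  for (i in 1:10) {
    p <- random_set_pair(25, 4, shared_frac = runif(1))
    x <- m3hash_sketch(p$a, cfg, "ct"); y <- m3hash_sketch(p$b, cfg, "ct")
    f <- compare_sketches(x, y); g <- compare_sketches(y, x)
    expect_identical(f$xi_s, g$xi_s)
    expect_identical(f$vote_count, g$vote_count)
    expect_true(f$xi_s >= 0 && f$xi_s <= 1)
    expect_lte(f$vote_count, cfg$z * cfg$Delta * cfg$R)
  }
  # both-empty cells count as matches
  one <- m3hash_sketch("AAAA", cfg, "ct")  # only cell 0 occupied
  cmp <- compare_sketches(one, one)
  expect_equal(cmp$xi_per_cell, c(1, 1, 1))
  other <- m3hash_sketch("GAAA", cfg, "ct")  # only cell 1 occupied
  # cells 0 and 1 are each empty on one side only (non-match); cell 2 is
  # empty on both sides (match) -> xi_s = 1/3
  expect_equal(compare_sketches(one, other)$xi_s, 1 / 3)
  cfg2 <- sketch_config(k = 4, kappa = 1, metrics = "identity", R = 5)
  expect_error(compare_sketches(one, m3hash_sketch("AAAA", cfg2, "ct")),
               "different configurations")
})

test_that("multi-metric Jaccard: conventions and reduction to classic", {
  cfg1 <- sketch_config(k = 4, kappa = 0, metrics = "identity", R = 1)
  set.seed(6)
  km <- random_kmer_set(20, 4)
  r <- multi_metric_jaccard(km, km, cfg1, "ct")
  expect_equal(r$classic, 1)
  expect_equal(r$multi_metric, 1)
  r0 <- multi_metric_jaccard(character(0), character(0), cfg1, "ct")
  expect_equal(r0$classic, 0)
  expect_equal(r0$multi_metric, 0)
  a <- c("AGGG", "GGGG"); b <- c("AGGA", "TGGA")
  cfg2 <- sketch_config(k = 4, kappa = 1, metrics = c("identity", "ct"), R = 1)
  expect_equal(multi_metric_jaccard(a, b, cfg2, "ct")$multi_metric, 0)
  # Delta = 1 (identity), z = 1: multi-metric equals classic
  for (i in 1:100) {
    p <- random_set_pair(15, 4, shared_frac = runif(1))
    r <- multi_metric_jaccard(p$a, p$b, cfg1, "ct")
    expect_equal(r$multi_metric, r$classic)
    expect_equal(r$classic, classic_jaccard(p$a, p$b))
  }
})

test_that("per-cell maximisation agrees with the exhaustive assignment oracle", {
  set.seed(7)
  for (i in 1:40) {
    kappa <- sample(0:1, 1)
    metrics <- list(c("identity"), c("identity", "ct"),
                    c("identity", "ct", "ga"))[[sample(3, 1)]]
    cfg <- sketch_config(k = 4, kappa = kappa, metrics = metrics, R = 1)
    p <- random_set_pair(sample(5:25, 1), 4, shared_frac = runif(1))
    mine <- multi_metric_jaccard(p$a, p$b, cfg, "ct")$multi_metric
    oracle <- jsim_exhaustive(p$a, p$b, metrics, kappa, "ct")
    expect_equal(mine, oracle)
  }
})

test_that("adding the collapse metric never lowers the match statistic", {
  # seeds for slot (j, r) do not depend on the metric list, so the
  # two-metric indicator dominates the identity-only indicator pointwise
  set.seed(8)
  for (i in 1:10) {
    p <- random_set_pair(30, 6, shared_frac = 0.3)
    c1 <- sketch_config(k = 6, kappa = 1, metrics = "identity", R = 50,
                        master_seed = 100 + i)
    c2 <- sketch_config(k = 6, kappa = 1, metrics = c("identity", "ct"), R = 50,
                        master_seed = 100 + i)
    x1 <- compare_sketches(m3hash_sketch(p$a, c1, "ct"), m3hash_sketch(p$b, c1, "ct"))
    x2 <- compare_sketches(m3hash_sketch(p$a, c2, "ct"), m3hash_sketch(p$b, c2, "ct"))
    expect_gte(x2$xi_s, x1$xi_s)
  }
})

test_that("sketch config validation enforces the structural invariants", {
  expect_equal(sketch_config(kappa = 2)$z, 9L)
  expect_error(sketch_config(k = 2, kappa = 2))          # kappa < k
  expect_error(sketch_config(metrics = "xy"), "metrics")
  expect_error(sketch_config(master_seed = -1), "master_seed")
  expect_error(sketch_config(R = 0))
})
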