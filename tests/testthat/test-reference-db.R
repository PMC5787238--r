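test_that("reference construction expands variants and tracks sources", {
  ref <- smurf_reference(
    ids = c("a", "b", "c"),
    sequences = c("ACGTACGTACGT", "ACGTRCGTACGT", "NNNNACGTACGT"),
    taxonomy = c("k;p;s1", "k;p;s2", "k;p;s3")
  )
  expect_equal(nrow(ref), 1L + 2L)      # c has 4 ambiguous positions -> dropped
  expect_equal(attr(ref, "n_discarded"), 1L)
  expect_setequal(ref$id[ref$source_id == "b"], c("b_v1", "b_v2"))
  expect_setequal(ref$sequence[ref$source_id == "b"],
                  c("ACGTACGTACGT", "ACGTGCGTACGT"))
  expect_false(anyDuplicated(ref$id) > 0)
})

test_that("amplicons are located by the two-mismatch primer rule", {
  fwd <- "TGGCGGACGGGTGAGTAA"
  rev <- "CTGCTGCCTCCCGTAGGA"
  primers <- data.frame(region_id = 1L, forward = fwd, reverse = rev)
  set.seed(3)
  core <- rand_seq(200)
  x <- rand_seq(40); y <- rand_seq(40)
  seq_exact <- paste0(x, fwd, core, oracle_revcomp(rev), y)

  ref <- smurf_reference("t1", seq_exact, "k;s")
  amp <- locate_amplicons(ref, primers)
  expect_true(amp$amplified)
  expect_equal(amp$fwd_mm, 0L)
  expect_equal(amp$rev_mm, 0L)
  # amplicon is exactly the core, 0-based half-open, primers excluded
  expect_equal(amp$start, 40L + nchar(fwd))
  expect_equal(amp$end, 40L + nchar(fwd) + 200L)
  expect_equal(substr(seq_exact, amp$start + 1L, amp$end), core)

  # three substitutions inside the forward primer site -> not amplified
  set.seed(4)
  fwd_broken <- mutate_at(fwd, c(2, 7, 13))
  ref3 <- smurf_reference("t3", paste0(x, fwd_broken, core,
                                       oracle_revcomp(rev), y), "k;s")
  expect_false(locate_amplicons(ref3, primers)$amplified)

  # two substitutions in each primer site -> boundary of the <=2 rule, amplified
  fwd2 <- mutate_at(fwd, c(2, 7))
  rev_site2 <- mutate_at(oracle_revcomp(rev), c(3, 9))
  ref2 <- smurf_reference("t2", paste0(x, fwd2, core, rev_site2, y), "k;s")
  amp2 <- locate_amplicons(ref2, primers)
  expect_true(amp2$amplified)
  expect_equal(amp2$fwd_mm, 2L)
  expect_equal(amp2$rev_mm, 2L)
})

test_that("amplicon location agrees with a brute-force window scan", {
  fwd <- "GCACAAGCGGTGGAGCAT"
  rev <- "CGCTCGTTGCGGGACTTA"
  primers <- data.frame(region_id = 1L, forward = fwd, reverse = rev)
  set.seed(21)
  for (case in 1:20) {
    # random backbone, primer sites planted with 0-3 mutations each
    n_mut_f <- sample(0:3, 1); n_mut_r <- sample(0:3, 1)
    seq <- paste0(
      rand_seq(sample(20:80, 1)),
      mutate_at(fwd, sample(18, n_mut_f)),
      rand_seq(sample(120:300, 1)),
      mutate_at(oracle_revcomp(rev), sample(18, n_mut_r)),
      rand_seq(sample(20:80, 1))
    )
    ref <- smurf_reference(paste0("c", case), seq, "k;s")
    got <- locate_amplicons(ref, primers)
    want <- oracle_amplicon(seq, fwd, rev)
    expect_equal(got$amplified, want$amplified, info = paste("case", case))
    if (want$amplified) {
      expect_equal(got$start, want$start, info = paste("case", case))
      expect_equal(got$end, want$end, info = paste("case", case))
      expect_equal(got$fwd_mm, want$fwd_mm)
      expect_equal(got$rev_mm, want$rev_mm)
    }
  }
})

test_that("k-mer database obeys the mixture-matrix invariants", {
  db <- toy_db(n_taxa = 8L, n_regions = 3L, k = 50L, seed = 5L)
  J <- length(db$R)
  expect_true(all(db$R == 3L))
  # paired-end: one row per (taxon, region), each entry 1/R_j
  expect_equal(nrow(db$entries), 8L * 3L)
  expect_true(all(abs(db$M@x - 1 / 3) < 1e-15))
  expect_equal(unname(Matrix::colSums(db$M)), rep(1, J))

  db1 <- toy_db(n_taxa = 8L, n_regions = 3L, k = 50L, seed = 5L,
                mode = "single")
  expect_equal(nrow(db1$entries), 2L * 8L * 3L)
  expect_true(all(abs(db1$M@x * 3 / 0.5 - round(db1$M@x * 3 / 0.5)) < 1e-12))
  expect_equal(unname(Matrix::colSums(db1$M)), rep(1, J))
  # single-end rows are half-length
  expect_true(all(nchar(db1$kmer_rows$kmer) == 50L))
  expect_true(all(nchar(db$kmer_rows$kmer) == 100L))
})

test_that("amplicons shorter than the read length are not usable", {
  fwd <- "TGGCGGACGGGTGAGTAA"; rev <- "CTGCTGCCTCCCGTAGGA"
  primers <- data.frame(region_id = 1L, forward = fwd, reverse = rev)
  set.seed(9)
  short_core <- rand_seq(30)   # shorter than k = 60
  ref <- smurf_reference("s", paste0(rand_seq(20), fwd, short_core,
                                     oracle_revcomp(rev), rand_seq(20)),
                         "k;s")
  expect_true(locate_amplicons(ref, primers)$amplified)
  expect_error(build_region_kmer_db(ref, primers, k = 60L),
               "no reference sequence is amplified")
})

test_that("a k-mer occurring in two regions occupies two rows", {
  # same core planted in two regions of one taxon
  set.seed(13)
  f1 <- rand_seq(18); r1 <- rand_seq(18)
  f2 <- rand_seq(18); r2 <- rand_seq(18)
  core <- rand_seq(120)
  seq <- paste0(rand_seq(15), f1, core, oracle_revcomp(r1), rand_seq(15),
                f2, core, oracle_revcomp(r2), rand_seq(15))
  ref <- smurf_reference("dup", seq, "k;s")
  primers <- data.frame(region_id = 1:2, forward = c(f1, f2),
                        reverse = c(r1, r2))
  db <- build_region_kmer_db(ref, primers, k = 55L)
  expect_equal(nrow(db$kmer_rows), 2L)
  expect_equal(length(unique(db$kmer_rows$kmer)), 1L)
  expect_equal(length(unique(db$kmer_rows$region_id)), 2L)
  expect_equal(db$R, 2L)
  expect_equal(unname(Matrix::colSums(db$M)), 1)
})

test_that("footprint groups refine as regions are added", {
  # two taxa identical in region 1 but differing in region 2
  db <- toy_db(n_taxa = 2L, n_regions = 2L, k = 40L, core_len = 100L,
               pool_sizes = c(1L, 2L), seed = 31L)
  g1 <- compute_theoretical_groups(db, regions = 1L)
  g12 <- compute_theoretical_groups(db, regions = 1:2)
  expect_equal(unname(sort(g1$sizes)), 2L)
  expect_equal(unname(sort(g12$sizes)), c(1L, 1L))
  expect_equal(g1$unique_fraction, 0)
  expect_equal(g12$unique_fraction, 1)

  # all-identical footprints collapse to one group
  db_same <- toy_db(n_taxa = 3L, n_regions = 2L, k = 40L, core_len = 100L,
                    pool_sizes = 1L, seed = 32L)
  g_same <- compute_theoretical_groups(db_same)
  expect_length(g_same$groups, 1L)
  expect_equal(unname(g_same$sizes), 3L)

  # all-distinct footprints: every group a singleton
  db_dist <- toy_db(n_taxa = 6L, n_regions = 2L, k = 40L, core_len = 100L,
                    seed = 33L)
  expect_equal(compute_theoretical_groups(db_dist)$unique_fraction, 1)
})

test_that("enlarging the region subset never merges groups", {
  set.seed(44)
  for (rep in 1:8) {
    db <- toy_db(n_taxa = 30L, n_regions = 3L, k = 40L, core_len = 90L,
                 pool_sizes = sample(2:10, 3, replace = TRUE),
                 seed = 100L + rep)
    uf_prev <- -1
    max_prev <- Inf
    for (m in 1:3) {
      g <- compute_theoretical_groups(db, regions = seq_len(m))
      # refinement: largest group can only shrink, unique fraction only grow
      expect_lte(max(g$sizes), max_prev)
      expect_gte(g$unique_fraction, uf_prev)
      # every taxon's group size is non-increasing
      if (m > 1L) {
        sz_now <- g$sizes[g$membership]
        expect_true(all(sz_now <= sz_before))
      }
      sz_before <- g$sizes[g$membership]
      uf_prev <- g$unique_fraction
      max_prev <- max(g$sizes)
    }
  }
})

test_that("k-mer database round-trips through its directory format", {
  db <- toy_db(n_taxa = 6L, n_regions = 2L, k = 45L, seed = 8L)
  dir <- withr::local_tempdir()
  write_kmer_db(db, dir)
  expect_true(file.exists(file.path(dir, "manifest.json")))
  back <- read_kmer_db(dir)
  expect_equal(back$k, db$k)
  expect_equal(back$mode, db$mode)
  expect_equal(back$R, db$R)
  expect_equal(back$kmer_rows, db$kmer_rows)
  expect_equal(as.matrix(back$M), as.matrix(db$M))
  expect_equal(back$reference$sequence, db$reference$sequence)
  expect_equal(back$primers$forward, db$primers$forward)
})
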