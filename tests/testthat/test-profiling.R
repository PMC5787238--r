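test_that("read/k-mer probabilities follow the constant-error model", {
  # two taxa, one region, k-mers 38 nt concatenated to 76 nt (paired)
  db <- toy_db(n_taxa = 2L, n_regions = 1L, k = 38L, core_len = 90L,
               seed = 61L)
  km <- db$kmer_rows$kmer
  expect_equal(nchar(km[1]), 76L)
  set.seed(62)
  reads <- as_read_table(
    list(`1` = c(km[1],                      # exact
                 mutate_at(km[1], 10),       # one mismatch
                 mutate_at(km[2], c(3, 40, 60)))),  # three -> above cap
    threshold = 0)
  match <- compute_read_kmer_probabilities(reads, db, p_e = 0.005, cap = 2L)
  E <- as.matrix(match$E)
  rows <- match(km, db$kmer_rows$kmer)
  i_exact <- match(km[1], match$sequence)
  expect_equal(E[i_exact, rows[1]], 0.995^76)
  i_mm1 <- which(match$sequence != km[1] & rowSums(E) > 0)
  expect_equal(unname(E[i_mm1, rows[1]]), (0.005 / 3) * 0.995^75)
  # pair above the cap is absent; that read is flagged unmatched, and the
  # exact and 1-mm reads each match only their own k-mer
  expect_true(any(!match$matched))
  expect_equal(sum(E > 0), 2L)

  # error-free limit: p_e -> 0 gives probability 1 for an exact match
  match0 <- compute_read_kmer_probabilities(reads, db, p_e = 0, cap = 2L)
  expect_equal(as.matrix(match0$E)[i_exact, rows[1]], 1)

  # length inconsistency is rejected with the region named
  bad <- as_read_table(list(`1` = "ACGTACGT"), threshold = 0)
  expect_error(compute_read_kmer_probabilities(bad, db), "region 1")
})

test_that("candidate filter removes perfect-primer taxa without reads", {
  db <- toy_db(n_taxa = 3L, n_regions = 2L, k = 40L, core_len = 100L,
               seed = 63L)
  # reads from taxa 1 and 2 only, in both regions
  km <- function(j, r) db$entries$kmer[db$entries$taxon == j &
                                         db$entries$region_id == r]
  reads <- as_read_table(list(`1` = c(rep(km(1, 1), 50), rep(km(2, 1), 50)),
                              `2` = c(rep(km(1, 2), 50), rep(km(2, 2), 50))),
                         threshold = 0)
  match <- compute_read_kmer_probabilities(reads, db)
  cand <- filter_candidate_bacteria(db, match)
  # taxon 3 has perfect primer matches but no matched reads -> removed
  expect_setequal(cand, c(1L, 2L))

  # a taxon without any perfect-match region is retained regardless
  db2 <- db
  db2$amplicons$fwd_mm[db2$amplicons$taxon == 3L] <- 1L
  cand2 <- filter_candidate_bacteria(db2, match)
  expect_setequal(cand2, 1:3)
})

test_that("EM fixed point solves the degenerate and closed-form cases", {
  # single candidate: immediately pi = 1
  Q <- Matrix::Matrix(matrix(c(0.5, 0.3), 2, 1), sparse = TRUE)
  em <- em_reconstruct(Q, Matrix::Diagonal(1), counts = c(10L, 5L))
  expect_equal(em$pi, 1)
  expect_true(em$converged)

  # disjoint single k-mers with counts 75 / 25: multinomial MLE [0.75, 0.25]
  E <- Matrix::Matrix(diag(2), sparse = TRUE)
  M <- Matrix::Diagonal(2)
  em <- em_reconstruct(E, M, counts = c(75L, 25L))
  expect_equal(em$pi, c(0.75, 0.25), tolerance = 1e-6)

  # identical Q columns: the symmetric point is a fixed point
  Qsym <- Matrix::Matrix(matrix(c(0.4, 0.2, 0.4, 0.2), 2, 2), sparse = TRUE)
  em <- em_reconstruct(Qsym, Matrix::Diagonal(2), counts = c(30L, 20L))
  expect_equal(em$pi, c(0.5, 0.5), tolerance = 1e-12)
  expect_equal(em$iterations, 1L)

  expect_error(em_reconstruct(E * 0, M, counts = c(1L, 1L)), "no reads")
})

test_that("EM keeps the likelihood non-decreasing and pi on the simplex", {
  for (seed in 1:12) {
    inst <- random_em_instance(n_reads = sample(5:30, 1),
                               n_taxa = sample(2:8, 1), seed = seed)
    em <- em_reconstruct(inst$Q, Matrix::Diagonal(ncol(inst$Q)), inst$counts,
                         tol = 1e-10)
    expect_true(all(diff(em$loglik) >= -1e-9 * abs(em$loglik[-1])))
    expect_true(all(em$pi >= 0))
    expect_equal(sum(em$pi), 1, tolerance = 1e-12)
  }
})

test_that("EM attains the grid-search maximum on small instances", {
  # convexity: the fixed point must reach the global optimum, checked
  # against a dense simplex grid for up to 3 candidates
  for (seed in 1:6) {
    n_taxa <- sample(2:3, 1)
    inst <- random_em_instance(n_reads = sample(4:20, 1), n_taxa = n_taxa,
                               seed = 100 + seed)
    em <- em_reconstruct(inst$Q, Matrix::Diagonal(n_taxa), inst$counts,
                         tol = 1e-12, max_iter = 50000L)
    grid_best <- oracle_grid_loglik(inst$Q, inst$counts, step = 1e-3,
                                    final_step = 1e-6)
    em_ll <- em$loglik[length(em$loglik)]
    expect_lte(abs(em_ll - grid_best), 1e-6)
  }
})

test_that("profiles are invariant to read order and duplicate collapsing", {
  db <- toy_db(n_taxa = 5L, n_regions = 2L, k = 40L, core_len = 100L,
               seed = 64L)
  comm <- smurf_community(1:5, c(5, 4, 3, 2, 1))
  raw <- simulate_region_reads(comm, db, total_reads = 2000L, error_rate = 0,
                               seed = 9L, collapse = FALSE)
  fit1 <- smurf(as_read_table(raw, threshold = 0), db)
  shuffled <- lapply(raw, function(x) sample(x))
  fit2 <- smurf(as_read_table(shuffled, threshold = 0), db)
  expect_equal(fit1$x, fit2$x, tolerance = 1e-9)

  # listing duplicates individually vs collapsed counts is identical:
  # as_read_table always collapses, so compare against a manually built
  # one-copy-per-row table with counts
  tabs <- lapply(raw, function(x) {
    d <- as.data.frame(table(x), stringsAsFactors = FALSE)
    out <- data.frame(sequence = d$x, count = as.integer(d$Freq))
    attr(out, "N") <- sum(out$count); attr(out, "N_before") <- sum(out$count)
    attr(out, "n_discarded") <- 0L
    out
  })
  manual <- structure(list(tables = tabs, mode = "paired", L = 80L,
                           threshold = 0,
                           stats = data.frame(input = 2000L,
                                              quality_failed = 0L,
                                              unassigned = 0L,
                                              assigned = 2000L,
                                              low_freq_discarded = 0L,
                                              retained = 2000L)),
                      class = "smurf_reads")
  fit3 <- smurf(manual, db)
  expect_equal(fit1$x, fit3$x, tolerance = 1e-9)
})

test_that("the profile is insensitive to the assumed error probability", {
  db <- toy_db(n_taxa = 6L, n_regions = 3L, k = 40L, core_len = 100L,
               seed = 65L)
  comm <- smurf_community(1:6, c(6, 5, 4, 3, 2, 1))
  reads <- simulate_region_reads(comm, db, total_reads = 3000L,
                                 error_rate = 0, seed = 10L,
                                 sampling = "expected")
  fits <- lapply(c(0.001, 0.005, 0.02), function(pe)
    smurf(reads, db, p_e = pe))
  expect_equal(fits[[1]]$x, fits[[2]]$x, tolerance = 1e-6)
  expect_equal(fits[[2]]$x, fits[[3]]$x, tolerance = 1e-6)
})

test_that("frequency normalization divides by the region count", {
  expect_equal(normalize_frequencies(c(0.5, 0.5), c(1L, 1L)), c(0.5, 0.5))
  expect_equal(normalize_frequencies(c(0.5, 0.5), c(1L, 2L)), c(2 / 3, 1 / 3))
  expect_equal(normalize_frequencies(c(1, 0), c(3L, 5L)), c(1, 0))
  # pruning zeroes tiny proportions before normalizing
  expect_equal(normalize_frequencies(c(1, 1e-15), c(1L, 1L)), c(1, 0))
  expect_error(normalize_frequencies(c(0, 0), c(1L, 1L)), "zero")
  expect_error(normalize_frequencies(c(0.5, 0.5), c(1L, 0L)), "R_j")
})

test_that("fit object methods expose the estimate coherently", {
  db <- toy_db(n_taxa = 4L, n_regions = 2L, k = 40L, core_len = 100L,
               seed = 66L)
  comm <- smurf_community(1:4, c(0.4, 0.3, 0.2, 0.1))
  reads <- simulate_region_reads(comm, db, 2000L, error_rate = 0, seed = 11L,
                                 sampling = "expected")
  fit <- smurf(reads, db)
  expect_s3_class(fit, "smurf_fit")
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-12)
  expect_equal(sum(coef(fit, "pi")), 1, tolerance = 1e-12)
  expect_equal(unname(stats::logLik(fit))[1], fit$loglik[length(fit$loglik)])
  tab <- profile_table(fit)
  expect_equal(sum(tab$x), 1, tolerance = 1e-12)
  expect_output(print(fit), "Multi-region")
  expect_output(print(summary(fit)), "Community profile")
})
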