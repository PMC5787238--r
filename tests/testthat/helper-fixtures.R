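# Fixture builders shared across test files.  Everything is generated in
# code at test time; no stored data.

# small fully-distinguishable toy database
toy_db <- function(n_taxa = 10L, n_regions = 3L, k = 60L, core_len = 150L,
                   pool_sizes = n_taxa, seed = 42L, mode = "paired") {
  syn <- synthetic_reference(n_taxa, n_regions = n_regions,
                             core_len = core_len, pool_sizes = pool_sizes,
                             seed = seed)
  build_region_kmer_db(syn$reference, syn$primers, k = k, mode = mode)
}

# write paired-end FASTQ files (with primers re-attached, uniform Phred 40)
# for a community simulated from a paired-end toy db; returns the two paths
write_fastq_fixture <- function(db, community, reads_per_member, dir,
                                qualities = NULL) {
  k <- db$k
  r1 <- character(0); r2 <- character(0)
  for (mi in seq_along(community$members)) {
    j <- community$members[mi]
    ent <- db$entries[db$entries$taxon == j, , drop = FALSE]
    for (e in seq_len(nrow(ent))) {
      p <- db$primers[db$primers$region_id == ent$region_id[e], ]
      n <- reads_per_member[mi]
      r1 <- c(r1, rep(paste0(p$forward, substr(ent$kmer[e], 1L, k)), n))
      r2 <- c(r2, rep(paste0(p$reverse, substr(ent$kmer[e], k + 1L, 2L * k)), n))
    }
  }
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wfq <- function(seqs, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- sprintf("read%06d", seq_along(seqs))
    q <- if (is.null(qualities))
      Biostrings::BStringSet(strrep("I", nchar(seqs)))
    else Biostrings::BStringSet(qualities)
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    path
  }
  c(wfq(r1, file.path(dir, "reads_R1.fastq")),
    wfq(r2, file.path(dir, "reads_R2.fastq")))
}

# sparse random EM instance for property tests: returns list(Q, counts)
random_em_instance <- function(n_reads, n_taxa, seed) {
  set.seed(seed)
  Q <- matrix(stats::runif(n_reads * n_taxa)^3, n_reads, n_taxa)
  Q[sample(length(Q), length(Q) %/% 3)] <- 0
  # every read must retain support under some taxon
  zero <- rowSums(Q) == 0
  Q[zero, sample(n_taxa, sum(zero), replace = TRUE)] <- stats::runif(sum(zero))
  list(Q = Matrix::Matrix(Q, sparse = TRUE),
       counts = sample(1:50, n_reads, replace = TRUE))
}
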