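# Simulation and evaluation: synthetic toy references, power-law
# communities, multi-region amplicon read simulation, weighted
# precision/recall scoring, greedy region ordering and the incremental
# region-addition experiment.

#' Generate a synthetic toy reference with embedded primer sites
#'
#' Builds `n_taxa` full-length toy sequences, each carrying one amplicon per
#' region laid out as
#' `pad | fwd | core | revcomp(rev) | pad | fwd2 | core2 | ...` with exact
#' primer sites, so every taxon is amplified in every region.  Region cores
#' are drawn without replacement from per-region variant pools;
#' `pool_sizes < n_taxa` engineers shared footprints in that region (several
#' taxa reuse one core) while the joint core combination stays unique per
#' taxon whenever the pools allow it.
#'
#' @param n_taxa Number of reference sequences.
#' @param n_regions Number of regions (primer pairs generated to order).
#' @param core_len Amplicon core length in nt (default 200, the order of the
#'   real multi-region amplicons).
#' @param pool_sizes Integer vector (recycled over regions) of distinct core
#'   variants available per region; default `n_taxa` (all distinct).
#' @param pad_len Unamplified spacer length between amplicons.
#' @param seed RNG seed for reproducibility.
#' @return List with `reference` (a [smurf_reference]) and `primers`.
#' @export
synthetic_reference <- function(n_taxa, n_regions = 3L, core_len = 200L,
                                pool_sizes = n_taxa, pad_len = 30L,
                                seed = 1L) {
  stopifnot(n_taxa >= 1L, n_regions >= 1L, core_len >= 20L)
  pool_sizes <- rep_len(as.integer(pool_sizes), n_regions)
  set.seed(seed)
  rand_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n, TRUE),
                                collapse = "")
  primers <- data.frame(
    region_id = seq_len(n_regions),
    forward = vapply(seq_len(n_regions), function(i) rand_dna(18L), character(1)),
    reverse = vapply(seq_len(n_regions), function(i) rand_dna(18L), character(1)),
    stringsAsFactors = FALSE
  )
  # per-region pools of distinct cores
  pools <- lapply(seq_len(n_regions), function(r) {
    repeat {
      p <- unique(vapply(seq_len(pool_sizes[r] * 2L),
                         function(i) rand_dna(core_len), character(1)))
      if (length(p) >= pool_sizes[r]) return(p[seq_len(pool_sizes[r])])
    }
  })
  # assign cores so that joint combinations are unique across taxa
  repeat {
    choice <- vapply(seq_len(n_regions), function(r)
      sample(pool_sizes[r], n_taxa, replace = pool_sizes[r] < n_taxa),
      integer(n_taxa))
    choice <- matrix(choice, nrow = n_taxa)
    if (prod(pool_sizes) < n_taxa ||
        !anyDuplicated(apply(choice, 1L, paste, collapse = ","))) break
  }
  seqs <- vapply(seq_len(n_taxa), function(j) {
    parts <- vapply(seq_len(n_regions), function(r) {
      paste0(primers$forward[r], pools[[r]][choice[j, r]],
             revcomp(primers$reverse[r]), rand_dna(pad_len))
    }, character(1))
    paste0(rand_dna(pad_len), paste(parts, collapse = ""))
  }, character(1))
  tax <- sprintf("Bacteria;SynthPhylum;SynthGenus;Synthetic_species_%03d",
                 seq_len(n_taxa))
  list(
    reference = smurf_reference(sprintf("syn%04d", seq_len(n_taxa)), seqs, tax),
    primers = as_primers(primers)
  )
}

#' Construct a simulated community
#'
#' @param members Taxon indices into the reference.
#' @param frequencies Relative frequencies (normalized to sum 1).
#' @return Object of class `smurf_community`.
#' @export
smurf_community <- function(members, frequencies) {
  stopifnot(length(members) == length(frequencies), all(frequencies > 0),
            !anyDuplicated(members))
  structure(list(members = as.integer(members),
                 frequencies = frequencies / sum(frequencies)),
            class = "smurf_community")
}

#' Sample a power-law community from the reference
#'
#' Draws `n` distinct taxa uniformly without replacement and assigns rank
#' frequencies proportional to 1/rank (so half of a 100-member community
#' holds a cumulative frequency of only about 13%, making the profiling
#' problem dominated by rare members).
#'
#' @param ref A [smurf_reference] (or its row count).
#' @param n Community size (default 100).
#' @param seed RNG seed.
#' @return A [smurf_community]; member order is rank order, frequencies
#'   strictly decreasing.
#' @export
sample_power_law_community <- function(ref, n = 100L, seed = 1L) {
  J <- if (is.numeric(ref)) as.integer(ref) else nrow(ref)
  if (n > J) stop("community size n exceeds the reference size", call. = FALSE)
  set.seed(seed)
  members <- sample.int(J, n)
  f <- (1 / seq_len(n))
  smurf_community(members, f / sum(f))
}

#' @export
print.smurf_community <- function(x, ...) {
  cat("smurf_community: ", length(x$members), " members, top frequency ",
      sprintf("%.3f", max(x$frequencies)), "\n", sep = "")
  invisible(x)
}

# split a read budget equally over regions, remainder spread
# deterministically over the first regions
split_reads_over_regions <- function(total, n_regions) {
  base <- total %/% n_regions
  extra <- total %% n_regions
  base + (seq_len(n_regions) <= extra)
}

# integer counts summing to n, proportional to p (largest-remainder rounding)
largest_remainder_counts <- function(n, p) {
  raw <- n * p / sum(p)
  cnt <- floor(raw)
  short <- n - sum(cnt)
  if (short > 0L) {
    bump <- order(raw - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[bump] <- cnt[bump] + 1L
  }
  as.integer(cnt)
}

# i.i.d. uniform substitution errors at the given per-base rate
add_substitution_errors <- function(seqs, rate) {
  if (rate <= 0 || length(seqs) == 0L) return(seqs)
  L <- nchar(seqs[1])
  chars <- matrix(unlist(strsplit(seqs, "", fixed = TRUE)),
                  nrow = length(seqs), byrow = TRUE)
  hit <- which(matrix(stats::runif(length(chars)) < rate, nrow = nrow(chars)))
  if (length(hit) > 0L) {
    bases <- c("A", "C", "G", "T")
    # substitute to a uniformly chosen *different* base
    repl <- vapply(chars[hit], function(b)
      sample(setdiff(bases, b), 1L), character(1))
    chars[hit] <- repl
  }
  apply(chars, 1L, paste, collapse = "")
}

#' Simulate multi-region amplicon reads from a community
#'
#' The total read budget is split equally across the selected regions
#' (remainder to the first regions, so per-region counts always sum to
#' `total_reads`).  Within a region, reads are drawn multinomially from the
#' community members amplified there, with probabilities proportional to
#' their frequencies renormalized over the amplified members (modelling PCR
#' dropout of non-amplified taxa); each read is the member's region k-mer,
#' then corrupted by i.i.d. uniform substitutions at `error_rate`.
#'
#' @param community A [smurf_community].
#' @param db A `smurf_kmer_db` covering the community members.
#' @param total_reads Total reads over all regions (default 200000).
#' @param regions Region subset (default all).
#' @param error_rate Per-base substitution probability (default 0.005).
#' @param seed RNG seed.
#' @param sampling `"multinomial"` (default) draws per-taxon read counts
#'   from the multinomial; `"expected"` uses the deterministic expected
#'   counts (largest-remainder rounding), for exact-recovery experiments.
#' @param collapse Return a collapsed `smurf_reads` table (default TRUE) or
#'   the raw per-region read vectors.
#' @param threshold Low-frequency read filter applied when collapsing.
#' @return A `smurf_reads` object (or a named list of character vectors when
#'   `collapse = FALSE`).  Regions where no community member is amplified
#'   receive zero reads, with a warning.
#' @export
simulate_region_reads <- function(community, db, total_reads = 200000L,
                                  regions = db$regions, error_rate = 0.005,
                                  seed = 1L,
                                  sampling = c("multinomial", "expected"),
                                  collapse = TRUE, threshold = 1e-4) {
  sampling <- match.arg(sampling)
  stopifnot(inherits(community, "smurf_community"),
            inherits(db, "smurf_kmer_db"))
  regions <- sort(as.integer(regions))
  stopifnot(all(regions %in% db$regions))
  set.seed(seed)
  per_region <- split_reads_over_regions(as.integer(total_reads),
                                         length(regions))
  out <- stats::setNames(vector("list", length(regions)),
                         as.character(regions))
  for (ri in seq_along(regions)) {
    r <- regions[ri]
    ent <- db$entries[db$entries$region_id == r &
                        db$entries$taxon %in% community$members, , drop = FALSE]
    amp_members <- intersect(community$members, ent$taxon)
    if (length(amp_members) == 0L) {
      warning("no community member is amplified in region ", r,
              "; simulating zero reads there")
      out[[ri]] <- character(0)
      next
    }
    f <- community$frequencies[match(amp_members, community$members)]
    f <- f / sum(f)
    cnt <- if (sampling == "multinomial") {
      as.vector(stats::rmultinom(1L, per_region[ri], f))
    } else {
      largest_remainder_counts(per_region[ri], f)
    }
    reads <- character(0)
    for (mi in seq_along(amp_members)) {
      if (cnt[mi] == 0L) next
      kms <- ent$kmer[ent$taxon == amp_members[mi]]
      if (db$mode == "paired") {
        reads <- c(reads, rep(kms[1L], cnt[mi]))
      } else {
        # single-end: each read comes off one of the two amplicon ends
        pick <- sample(length(kms), cnt[mi], replace = TRUE)
        reads <- c(reads, kms[pick])
      }
    }
    out[[ri]] <- add_substitution_errors(reads, error_rate)
  }
  if (!collapse) return(out)
  as_read_table(out, mode = db$mode, threshold = threshold)
}

#' Write simulated reads as FASTQ
#'
#' One FASTQ per region, uniform Phred 40 qualities.  Paired-end simulated
#' reads (concatenated 2k-mers) are split back into the two k-length mates
#' and written to `_R1`/`_R2` files.  When a primer table is supplied the
#' region's forward primer is prepended to R1 mates and the reverse primer
#' to R2 mates, so the files mimic sequencer output that [prepare_reads()]
#' can demultiplex and trim.
#'
#' @param region_reads Named list of per-region read vectors
#'   (`collapse = FALSE` output of [simulate_region_reads()]).
#' @param dir Output directory.
#' @param mode `"paired"` or `"single"`.
#' @param prefix File name prefix.
#' @param primers Optional primer table used to re-attach primer prefixes.
#' @return Character vector of the files written, invisibly.
#' @export
write_simulated_fastq <- function(region_reads, dir, mode = "paired",
                                  prefix = "sim", primers = NULL) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  files <- character(0)
  wfq <- function(seqs, ids, path) {
    x <- Biostrings::DNAStringSet(seqs)
    names(x) <- ids
    q <- Biostrings::BStringSet(vapply(nchar(seqs), function(n)
      paste(rep("I", n), collapse = ""), character(1)))
    Biostrings::writeXStringSet(x, path, format = "fastq", qualities = q)
    path
  }
  for (rn in names(region_reads)) {
    seqs <- region_reads[[rn]]
    if (length(seqs) == 0L) next
    fwd <- rev <- ""
    if (!is.null(primers)) {
      p <- as_primers(as.data.frame(primers))
      p <- p[p$region_id == as.integer(rn), , drop = FALSE]
      if (nrow(p) == 1L) { fwd <- p$forward; rev <- p$reverse }
    }
    ids <- sprintf("%s_region%s_read%06d", prefix, rn, seq_along(seqs))
    if (mode == "paired") {
      k <- nchar(seqs[1]) %/% 2L
      files <- c(files,
                 wfq(paste0(fwd, substr(seqs, 1L, k)), ids,
                     file.path(dir, sprintf("%s_region%s_R1.fastq", prefix, rn))),
                 wfq(paste0(rev, substr(seqs, k + 1L, 2L * k)), ids,
                     file.path(dir, sprintf("%s_region%s_R2.fastq", prefix, rn))))
    } else {
      files <- c(files,
                 wfq(paste0(fwd, seqs), ids,
                     file.path(dir, sprintf("%s_region%s.fastq", prefix, rn))))
    }
  }
  invisible(files)
}

#' Weighted precision and recall of a reconstruction
#'
#' Simulated and reconstructed communities are compared by exact full-length
#' 16S sequence identity: a simulated member m and a reconstructed taxon r
#' match only if their complete reference sequences are equal (a single
#' mismatch counts as an error).  Weighted recall is `sum_m f_m I_m` over
#' simulated members; weighted precision `sum_r x_r I_r` over the
#' reconstructed taxa with `x > 0`.
#'
#' @param community The simulated [smurf_community].
#' @param fit The `smurf_fit` reconstruction.
#' @param ref Reference set (defaults to the fit's).
#' @return List of class `smurf_eval`: `recall`, `precision`,
#'   `n_reconstructed`, `I_m`, `I_r`.
#' @export
weighted_precision_recall <- function(community, fit, ref = fit$db$reference) {
  sim_seq <- ref$sequence[community$members]
  rec_idx <- fit$taxon[fit$x > 0]
  rec_x <- fit$x[fit$x > 0]
  rec_seq <- ref$sequence[rec_idx]
  I_m <- sim_seq %in% rec_seq
  I_r <- rec_seq %in% sim_seq
  structure(list(
    recall = sum(community$frequencies * I_m),
    precision = if (length(rec_x)) sum(rec_x * I_r) else 0,
    n_reconstructed = length(rec_idx),
    I_m = I_m, I_r = I_r
  ), class = "smurf_eval")
}

#' @export
print.smurf_eval <- function(x, ...) {
  cat(sprintf(
    "weighted recall %.4f, weighted precision %.4f (%d reconstructed taxa)\n",
    x$recall, x$precision, x$n_reconstructed))
  invisible(x)
}

#' Greedy region ordering by footprint-group count
#'
#' Orders regions by iteratively appending the region whose addition
#' maximizes the number of distinct footprint groups given the regions
#' already chosen (ties broken by the smaller region id).  Group counts
#' along the returned order are non-decreasing, since adding a region can
#' only split groups.
#'
#' @param db A `smurf_kmer_db`.
#' @return List with `order` (region ids) and `group_counts` after each
#'   addition.
#' @export
greedy_region_ordering <- function(db) {
  remaining <- db$regions
  chosen <- integer(0)
  counts <- integer(0)
  while (length(remaining) > 0L) {
    n_groups <- vapply(remaining, function(r)
      length(compute_theoretical_groups(db, c(chosen, r))$groups), integer(1))
    best <- remaining[n_groups == max(n_groups)]
    pick <- min(best)
    chosen <- c(chosen, pick)
    counts <- c(counts, max(n_groups))
    remaining <- setdiff(remaining, pick)
  }
  list(order = chosen, group_counts = counts)
}

#' Incremental region-addition experiment
#'
#' Reconstructs the same simulated mixture with 1, 2, ..., all regions
#' (added in the greedy order), keeping the total read budget constant so
#' the per-region depth falls as regions are added, and scores each
#' reconstruction by weighted precision/recall and mean community-member
#' ambiguity.
#'
#' @param db A `smurf_kmer_db`.
#' @param community A [smurf_community].
#' @param total_reads Constant total read budget.
#' @param error_rate Simulator substitution rate.
#' @param seed RNG seed (one simulation per region count).
#' @param ... Passed to [smurf()].
#' @return Data frame with one row per region count: `n_regions`, `regions`,
#'   `precision`, `recall`, `n_reconstructed`, `mean_member_ambiguity`.
#' @export
region_sweep <- function(db, community, total_reads = 200000L,
                         error_rate = 0.005, seed = 1L, ...) {
  ord <- greedy_region_ordering(db)$order
  rows <- vector("list", length(ord))
  for (m in seq_along(ord)) {
    regs <- sort(ord[seq_len(m)])
    reads <- simulate_region_reads(community, db, total_reads, regs,
                                   error_rate, seed = seed)
    sub <- subset_db_regions(db, regs)
    fit <- smurf(reads, sub, ...)
    ev <- weighted_precision_recall(community, fit)
    amb <- member_ambiguity(community, sub)
    rows[[m]] <- data.frame(
      n_regions = m, regions = paste(regs, collapse = ","),
      precision = ev$precision, recall = ev$recall,
      n_reconstructed = ev$n_reconstructed,
      mean_member_ambiguity = amb
    )
  }
  do.call(rbind, rows)
}

# mean theoretical ambiguity (= footprint group size) of community members
member_ambiguity <- function(community, db) {
  fp <- compute_theoretical_groups(db)
  sz <- rep(NA_real_, length(db$R))
  sz[!is.na(fp$membership)] <- fp$sizes[fp$membership[!is.na(fp$membership)]]
  mean(sz[community$members], na.rm = TRUE)
}

#' Restrict a k-mer database to a region subset
#'
#' Rebuilds `R`, the k-mer rows and `M` for the chosen regions; taxa
#' amplified in none of them get `R_j = 0`.
#'
#' @param db A `smurf_kmer_db`.
#' @param regions Region ids to keep.
#' @return A `smurf_kmer_db` over the subset.
#' @export
subset_db_regions <- function(db, regions) {
  regions <- sort(as.integer(regions))
  stopifnot(all(regions %in% db$regions))
  if (identical(regions, db$regions)) return(db)
  ent <- db$entries[db$entries$region_id %in% regions, , drop = FALSE]
  J <- length(db$R)
  R <- integer(J)
  # paired: one entry per (taxon, region); single: two
  per <- if (db$mode == "paired") 1L else 2L
  tab <- table(factor(ent$taxon, levels = seq_len(J)))
  R[] <- as.integer(tab) / per
  key <- paste(ent$region_id, ent$kmer, sep = ":")
  rows_keys <- sort(unique(key))
  h <- match(key, rows_keys)
  weight <- if (db$mode == "paired") 1 else 0.5
  M <- Matrix::sparseMatrix(i = h, j = ent$taxon, x = weight / R[ent$taxon],
                            dims = c(length(rows_keys), J))
  out <- db
  out$primers <- db$primers[db$primers$region_id %in% regions, , drop = FALSE]
  out$regions <- regions
  out$amplicons <- db$amplicons[db$amplicons$region_id %in% regions, ,
                                drop = FALSE]
  out$R <- R
  out$kmer_rows <- data.frame(
    region_id = as.integer(sub(":.*$", "", rows_keys)),
    kmer = sub("^[^:]*:", "", rows_keys), stringsAsFactors = FALSE)
  ent$row <- h
  out$entries <- ent
  out$M <- M
  out
}
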