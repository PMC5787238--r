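# Profiling core: read-to-kmer matching probabilities, candidate-bacteria
# filtering, the EM fixed-point estimator of read proportions, and the
# copy-number (amplified-region-count) normalization to frequencies.

# Hamming mismatch counts between two sets of equal-length sequences;
# returns an n x m integer matrix.  Sizes here are post-collapse unique
# reads vs per-region k-mers, so a dense count matrix is fine.
hamming_matrix <- function(a, b) {
  L <- unique(c(nchar(a), nchar(b)))
  if (length(L) != 1L)
    stop("sequences being compared differ in length", call. = FALSE)
  am <- matrix(utf8ToInt(paste(a, collapse = "")), nrow = length(a),
               ncol = L, byrow = TRUE)
  bm <- matrix(utf8ToInt(paste(b, collapse = "")), nrow = length(b),
               ncol = L, byrow = TRUE)
  mm <- matrix(0L, length(a), length(b))
  for (p in seq_len(L)) {
    mm <- mm + outer(am[, p], bm[, p], "!=")
  }
  mm
}

#' Read-to-kmer matching probabilities
#'
#' Matches every retained unique read against the k-mers of its region and
#' stores, for pairs with at most `cap` mismatches,
#' `E[i, h] = (p_e/3)^n_e * (1 - p_e)^(L - n_e)` — the probability of
#' observing read i given that it originated from k-mer h under a constant
#' per-base error probability `p_e` with independent positions.  Pairs above
#' the cap are absent (probability treated as zero).
#'
#' @param reads A `smurf_reads` object.
#' @param db A `smurf_kmer_db` built with the matching `k`/mode.
#' @param p_e Per-base sequencing error probability (default 0.005; results
#'   are nearly independent of this choice).
#' @param cap Read/k-mer mismatch cap (default 2).
#' @return An object of class `smurf_match`: list with sparse `E`
#'   (unique reads x k-mer rows of `db$M`), parallel sparse `n_e`, `counts`
#'   per unique read, `read_region`, read sequences, and the per-region
#'   tally of reads that matched no k-mer (excluded from the likelihood).
#' @export
compute_read_kmer_probabilities <- function(reads, db, p_e = 0.005, cap = 2L) {
  stopifnot(inherits(reads, "smurf_reads"), inherits(db, "smurf_kmer_db"))
  if (reads$mode != db$mode)
    stop("read table is ", reads$mode, "-end but database is ", db$mode,
         "-end", call. = FALSE)
  expected_len <- if (db$mode == "paired") 2L * db$k else db$k
  trip_i <- trip_h <- trip_ne <- list()
  seqs <- character(0); counts <- integer(0); read_region <- integer(0)
  offset <- 0L
  for (rn in names(reads$tables)) {
    region <- as.integer(rn)
    tab <- reads$tables[[rn]]
    if (nrow(tab) == 0L) next
    if (any(nchar(tab$sequence) != expected_len))
      stop("region ", region, ": read length ",
           unique(nchar(tab$sequence))[1], " does not match the database (",
           expected_len, " nt)", call. = FALSE)
    rows <- which(db$kmer_rows$region_id == region)
    if (length(rows) > 0L) {
      mm <- hamming_matrix(tab$sequence, db$kmer_rows$kmer[rows])
      hit <- which(mm <= cap, arr.ind = TRUE)
      if (nrow(hit) > 0L) {
        trip_i[[rn]] <- offset + hit[, 1L]
        trip_h[[rn]] <- rows[hit[, 2L]]
        trip_ne[[rn]] <- mm[hit]
      }
    }
    seqs <- c(seqs, tab$sequence)
    counts <- c(counts, tab$count)
    read_region <- c(read_region, rep(region, nrow(tab)))
    offset <- offset + nrow(tab)
  }
  n <- length(seqs)
  i <- as.integer(unlist(trip_i, use.names = FALSE))
  h <- as.integer(unlist(trip_h, use.names = FALSE))
  ne <- as.integer(unlist(trip_ne, use.names = FALSE))
  L <- expected_len
  E <- Matrix::sparseMatrix(i = i, j = h,
                            x = (p_e / 3)^ne * (1 - p_e)^(L - ne),
                            dims = c(n, nrow(db$kmer_rows)))
  NE <- Matrix::sparseMatrix(i = i, j = h, x = ne + 1L,  # store n_e + 1 so 0 is representable
                             dims = c(n, nrow(db$kmer_rows)))
  matched <- tabulate(i, nbins = n) > 0L
  structure(list(
    E = E, n_e = NE, p_e = p_e, cap = as.integer(cap), L = L,
    sequence = seqs, counts = counts, read_region = read_region,
    matched = matched,
    unmatched_by_region = tapply(!matched, read_region, sum)
  ), class = "smurf_match")
}

#' Filter candidate bacteria by perfect-primer regions without read support
#'
#' A taxon is removed from the candidate set iff some region exists where
#' both of its primers match its sequence perfectly (0 mismatches) and the
#' region's amplicon yields a k-mer, yet no retained read matched any of the
#' taxon's k-mers in that region.  Taxa amplified only through imperfect
#' primer sites are retained regardless of read support.  Regions with no
#' retained reads at all (e.g. a database region the experiment did not
#' sequence) are excluded from the rule — absence of an entire region's
#' data says nothing about any taxon.
#'
#' @param db A `smurf_kmer_db`.
#' @param match A `smurf_match` from [compute_read_kmer_probabilities()].
#' @return Integer vector of retained taxon indices (among taxa with
#'   `R_j > 0`).
#' @export
filter_candidate_bacteria <- function(db, match) {
  # k-mer rows with at least one matching read, weighted by retained reads
  row_support <- Matrix::colSums(match$E[match$counts > 0, , drop = FALSE] > 0) > 0
  amp <- db$amplicons
  # region is "amplified" in db only when long enough for a k-mer; entries
  # table is the authority for which (taxon, region) pairs produced k-mers
  ent <- db$entries
  sequenced <- unique(match$read_region[match$counts > 0])
  perfect <- amp$amplified & amp$fwd_mm == 0L & amp$rev_mm == 0L &
    amp$region_id %in% sequenced
  drop <- rep(FALSE, length(db$R))
  pf <- amp[perfect, , drop = FALSE]
  if (nrow(pf) > 0L) {
    for (idx in seq_len(nrow(pf))) {
      j <- pf$taxon[idx]; r <- pf$region_id[idx]
      rows_jr <- ent$row[ent$taxon == j & ent$region_id == r]
      if (length(rows_jr) > 0L && !any(row_support[rows_jr])) drop[j] <- TRUE
    }
  }
  which(db$R > 0L & !drop)
}

#' EM fixed-point estimation of read proportions
#'
#' Maximizes the convex likelihood `prod_i p_i^{c_i}` with
#' `p_i = sum_j Q_ij pi_j` and `Q = E M` over the candidate taxa, using the
#' multiplicative fixed-point update
#' `pi_j <- pi_j * (1/N) * sum_i c_i Q_ij / p_i`, starting from the uniform
#' vector.  Unique reads enter weighted by their counts, which is
#' mathematically identical to iterating over individual reads.  Reads that
#' matched no k-mer (or no candidate taxon) are excluded from `N`.
#'
#' @param E Sparse read-by-kmer probability matrix (or a `smurf_match`).
#' @param M Sparse kmer-by-taxon mixture matrix restricted to candidates.
#' @param counts Integer read multiplicities.
#' @param tol Convergence tolerance on `max_j |pi^(t+1) - pi^(t)|`
#'   (default 1e-8).
#' @param max_iter Iteration cap (default 10000).
#' @return List with `pi`, `loglik` trace (one value per iteration, natural
#'   log), `iterations`, `converged`, `N` (reads used) and `used` (logical
#'   per unique read).
#' @export
em_reconstruct <- function(E, M, counts, tol = 1e-8, max_iter = 10000L) {
  if (inherits(E, "smurf_match")) { counts <- E$counts; E <- E$E }
  stopifnot(nrow(M) == ncol(E), length(counts) == nrow(E))
  Q <- E %*% M
  used <- Matrix::rowSums(Q) > 0 & counts > 0
  Q <- Q[used, , drop = FALSE]
  cnt <- counts[used]
  N <- sum(cnt)
  if (N == 0L) stop("no reads matched any candidate k-mer", call. = FALSE)
  J <- ncol(Q)
  if (J < 1L) stop("empty candidate set", call. = FALSE)
  pi <- rep(1 / J, J)
  ll <- numeric(0)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    p_i <- as.vector(Q %*% pi)
    ll_t <- sum(cnt * log(p_i))
    if (!is.finite(ll_t))
      stop("non-finite log-likelihood at iteration ", it, call. = FALSE)
    ll <- c(ll, ll_t)
    pi_new <- pi * as.vector(Matrix::crossprod(Q, cnt / p_i)) / N
    delta <- max(abs(pi_new - pi))
    pi <- pi_new
    if (delta < tol) { converged <- TRUE; break }
  }
  list(pi = pi, loglik = ll, iterations = it, converged = converged,
       N = N, used = used)
}

#' Normalize read proportions to taxon frequencies
#'
#' Converts the read-proportion vector pi to relative taxon frequencies by
#' dividing each entry by the taxon's number of amplified regions `R_j`
#' (which equals its number of k-mers in paired-end mode) and renormalizing:
#' `x_j = (pi_j / R_j) / sum_j (pi_j / R_j)`.
#'
#' @param pi Nonnegative read-proportion vector.
#' @param R Parallel vector of amplified-region counts (`R_j >= 1` wherever
#'   `pi_j > 0`).
#' @param prune Entries of `pi` below this are zeroed first (numeric
#'   cleanup; default 1e-12, far below any reportable frequency).
#' @return Frequency vector `x` summing to 1, zero wherever `pi` is zero.
#' @export
normalize_frequencies <- function(pi, R, prune = 1e-12) {
  stopifnot(length(pi) == length(R))
  pi[pi < prune] <- 0
  if (all(pi == 0)) stop("all proportions are zero", call. = FALSE)
  if (any(pi > 0 & R < 1L)) stop("R_j < 1 for a supported taxon", call. = FALSE)
  w <- ifelse(pi > 0, pi / R, 0)
  w / sum(w)
}

#' Fit the multi-region community profile
#'
#' The main estimator: matches the prepared reads against the k-mer
#' database, applies the candidate-bacteria filter, estimates the read
#' proportions pi by the EM fixed point, and converts them to taxon
#' frequencies x by amplified-region-count normalization.
#'
#' @param reads A `smurf_reads` object (see [prepare_reads()] /
#'   [as_read_table()]).
#' @param db A `smurf_kmer_db` (see [build_region_kmer_db()]).
#' @param p_e Per-base error probability of the read model (default 0.005).
#' @param cap Read/k-mer mismatch cap (default 2).
#' @param tol,max_iter EM convergence controls.
#' @param prune Post-EM cleanup threshold on pi.
#' @param candidate_filter Apply the perfect-primer/no-reads candidate
#'   filter (default TRUE).
#' @return An object of class `smurf_fit` with components `taxon`
#'   (candidate indices into `db$reference`), `pi`, `x`, `R`, `loglik`,
#'   `iterations`, `converged`, `n_reads`, plus the db and parameters.
#' @seealso [coef.smurf_fit()], [summary.smurf_fit()], [profile_table()]
#' @export
smurf <- function(reads, db, p_e = 0.005, cap = 2L, tol = 1e-8,
                  max_iter = 10000L, prune = 1e-12, candidate_filter = TRUE) {
  match <- compute_read_kmer_probabilities(reads, db, p_e = p_e, cap = cap)
  candidates <- if (candidate_filter) filter_candidate_bacteria(db, match)
                else which(db$R > 0L)
  if (length(candidates) == 0L)
    stop("candidate filter removed every taxon", call. = FALSE)
  em <- em_reconstruct(match$E, db$M[, candidates, drop = FALSE],
                       match$counts, tol = tol, max_iter = max_iter)
  x <- normalize_frequencies(em$pi, db$R[candidates], prune = prune)
  pi <- em$pi
  pi[pi < prune] <- 0
  fit <- list(
    taxon = candidates, pi = pi, x = x, R = db$R[candidates],
    loglik = em$loglik, iterations = em$iterations,
    converged = em$converged, n_reads = em$N,
    reads_per_region = vapply(reads$tables, attr, integer(1), "N"),
    unmatched_by_region = match$unmatched_by_region,
    p_e = p_e, cap = as.integer(cap), tol = tol, db = db,
    call = match.call()
  )
  class(fit) <- "smurf_fit"
  fit
}

#' Tidy per-taxon profile table
#'
#' @param fit A `smurf_fit`.
#' @param min_x Only taxa with `x > min_x` are returned (default 0 keeps all
#'   supported taxa).
#' @return Data frame with `taxon_id`, `source_id`, `taxonomy`, `pi`, `x`,
#'   `R`, sorted by decreasing `x`.
#' @export
profile_table <- function(fit, min_x = 0) {
  stopifnot(inherits(fit, "smurf_fit"))
  keep <- fit$x > min_x
  ref <- fit$db$reference
  out <- data.frame(
    taxon_id = ref$id[fit$taxon[keep]],
    source_id = ref$source_id[fit$taxon[keep]],
    taxonomy = ref$taxonomy[fit$taxon[keep]],
    pi = fit$pi[keep], x = fit$x[keep], R = fit$R[keep],
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$x, out$taxon_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' @export
print.smurf_fit <- function(x, ...) {
  cat("Multi-region 16S community profile (EM maximum likelihood)\n")
  cat("  reads used: ", x$n_reads, " over ",
      length(x$reads_per_region), " regions; candidates: ",
      length(x$taxon), "; supported taxa (x > 0): ", sum(x$x > 0), "\n",
      sep = "")
  cat("  EM: ", x$iterations, " iterations, ",
      if (x$converged) "converged" else "NOT converged",
      ", final log-likelihood ", format(x$loglik[length(x$loglik)]),
      "\n", sep = "")
  invisible(x)
}

#' @export
summary.smurf_fit <- function(object, min_x = 1e-4, ...) {
  tab <- profile_table(object, min_x = min_x)
  out <- list(table = tab, n_reads = object$n_reads,
              iterations = object$iterations, converged = object$converged,
              loglik = object$loglik[length(object$loglik)], min_x = min_x)
  class(out) <- "summary.smurf_fit"
  out
}

#' @export
print.summary.smurf_fit <- function(x, ...) {
  cat("Community profile: ", nrow(x$table), " taxa with x > ", x$min_x,
      " (", x$n_reads, " reads, logLik ", format(x$loglik), ")\n\n", sep = "")
  tab <- x$table
  tab$pi <- signif(tab$pi, 4); tab$x <- signif(tab$x, 4)
  print(utils::head(tab[, c("taxon_id", "taxonomy", "pi", "x", "R")], 25L),
        right = FALSE)
  if (nrow(tab) > 25L) cat("... ", nrow(tab) - 25L, " more rows\n", sep = "")
  invisible(x)
}

#' Extract estimated frequencies
#'
#' @param object A `smurf_fit`.
#' @param type `"x"` for normalized taxon frequencies (default) or `"pi"`
#'   for raw read proportions.
#' @param ... Unused.
#' @return Named numeric vector over candidate taxa.
#' @export
coef.smurf_fit <- function(object, type = c("x", "pi"), ...) {
  type <- match.arg(type)
  stats::setNames(object[[type]], object$db$reference$id[object$taxon])
}

#' @export
logLik.smurf_fit <- function(object, ...) {
  val <- object$loglik[length(object$loglik)]
  structure(val, df = length(object$taxon) - 1L, nobs = object$n_reads,
            class = "logLik")
}

#' @export
plot.smurf_fit <- function(x, which = c("profile", "loglik"), n_top = 20L, ...) {
  which <- match.arg(which)
  if (which == "loglik") {
    graphics::plot(seq_along(x$loglik), x$loglik, type = "l",
                   xlab = "EM iteration", ylab = "log-likelihood", ...)
  } else {
    tab <- profile_table(x)
    tab <- utils::head(tab, n_top)
    graphics::barplot(tab$x, names.arg = tab$taxon_id, las = 2,
                      ylab = "estimated frequency x", ...)
  }
  invisible(x)
}
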