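# Read processing: FASTQ input, quality filtering, primer-based region
# assignment with barcode/primer trimming, exact collapsing to unique reads
# and the low-frequency read filter.

#' Read a FASTQ file
#'
#' @param path FASTQ path, optionally gzipped.
#' @return List with `sequence` (character) and `quality` (list of integer
#'   Phred vectors, offset-33 decoded).
#' @export
read_fastq <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fastq", with.qualities = TRUE)
  quals <- as.character(S4Vectors::mcols(x)$qualities)
  list(
    sequence = as.character(x),
    quality = lapply(quals, function(q) utf8ToInt(q) - 33L)
  )
}

#' Quality-filter reads
#'
#' A read is discarded when (i) strictly more than `max_frac_low` of its
#' bases have Phred below `q_main` (defaults: 25% below 30), (ii) strictly
#' more than `max_very_low` bases have Phred below `q_low` (defaults: 3
#' below 10), or (iii) it contains any ambiguous base call such as N.
#'
#' @param sequences Character vector of read sequences.
#' @param qualities List of integer Phred vectors, parallel to `sequences`.
#' @param q_main,max_frac_low,q_low,max_very_low Filter thresholds.
#' @return Data frame with `keep` (logical) and `reason`
#'   (`"low_quality"`, `"very_low_quality"`, `"ambiguous_base"` or `NA`).
#' @export
quality_filter_reads <- function(sequences, qualities,
                                 q_main = 30L, max_frac_low = 0.25,
                                 q_low = 10L, max_very_low = 3L) {
  stopifnot(length(sequences) == length(qualities))
  n <- length(sequences)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    q <- qualities[[i]]
    if (length(q) != nchar(sequences[i]))
      stop("quality/sequence length mismatch at record ", i, call. = FALSE)
    if (mean(q < q_main) > max_frac_low) reason[i] <- "low_quality"
    else if (sum(q < q_low) > max_very_low) reason[i] <- "very_low_quality"
    else if (grepl("[^ACGT]", sequences[i])) reason[i] <- "ambiguous_base"
  }
  data.frame(keep = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Assign reads to regions by primer and trim
#'
#' After dropping `barcode_len` leading bases, the next bases of each read
#' are compared against every primer of the requested orientation; the read
#' is assigned to the unique region whose primer matches with at most
#' `max_mismatch` mismatches (IUPAC-aware), then barcode and primer are
#' stripped and the remainder truncated to `L`.  Reads matching no primer,
#' matching two or more primers equally well, or too short to yield `L`
#' bases after trimming, go to an unassigned bin.
#'
#' @param sequences Character vector of reads (quality-filtered).
#' @param primers Primer table.
#' @param L Trimmed read length to keep.
#' @param barcode_len Leading bases to drop before the primer (default 0:
#'   inputs are assumed sample-demultiplexed).
#' @param max_mismatch Primer mismatch cap (default 2).
#' @param orientation `"forward"` to match forward primers (R1 mates) or
#'   `"reverse"` to match reverse primers (R2 mates).
#' @return Data frame with `region_id` (NA when unassigned), `trimmed`
#'   sequence (NA when unassigned) and `reason`.
#' @export
demultiplex_and_trim <- function(sequences, primers, L, barcode_len = 0L,
                                 max_mismatch = 2L,
                                 orientation = c("forward", "reverse")) {
  orientation <- match.arg(orientation)
  primers <- as_primers(as.data.frame(primers))
  prim_seq <- if (orientation == "forward") primers$forward else primers$reverse
  prim_bits <- lapply(prim_seq, iupac_bits)
  plen <- nchar(prim_seq)
  n <- length(sequences)
  region <- rep(NA_integer_, n)
  trimmed <- rep(NA_character_, n)
  reason <- rep(NA_character_, n)
  for (i in seq_len(n)) {
    s <- sequences[i]
    mm <- rep(NA_integer_, nrow(primers))
    for (p in seq_len(nrow(primers))) {
      if (nchar(s) < barcode_len + plen[p] + L) next
      win <- substr(s, barcode_len + 1L, barcode_len + plen[p])
      mm[p] <- count_primer_mismatches(prim_seq[p], win)
    }
    if (all(is.na(mm))) { reason[i] <- "too_short"; next }
    best <- min(mm, na.rm = TRUE)
    if (best > max_mismatch) { reason[i] <- "no_primer_match"; next }
    hits <- which(!is.na(mm) & mm == best)
    if (length(hits) > 1L) { reason[i] <- "ambiguous_primer"; next }
    region[i] <- primers$region_id[hits]
    start <- barcode_len + plen[hits] + 1L
    trimmed[i] <- substr(s, start, start + L - 1L)
  }
  data.frame(region_id = region, trimmed = trimmed, reason = reason,
             stringsAsFactors = FALSE)
}

#' Collapse reads and apply the low-frequency filter
#'
#' Collapses a region's reads by exact sequence into (sequence, count) pairs
#' and discards unique reads seen strictly fewer than
#' `threshold * N_before` times, where `N_before` is the region's read count
#' before this filter.  The default threshold of 1e-4 sets the lowest
#' detectable frequency at 0.01% while suppressing false positives caused by
#' sequencing errors.
#'
#' @param sequences Character vector of same-length trimmed reads from one
#'   region.
#' @param threshold Minimum frequency fraction (default `1e-4`).
#' @return Data frame (`sequence`, `count`) sorted by decreasing count then
#'   sequence, with attributes `N` (retained), `N_before` and `n_discarded`.
#' @export
collapse_and_filter_reads <- function(sequences, threshold = 1e-4) {
  if (length(sequences) == 0L) {
    out <- data.frame(sequence = character(0), count = integer(0))
    attr(out, "N") <- 0L; attr(out, "N_before") <- 0L
    attr(out, "n_discarded") <- 0L
    return(out)
  }
  if (length(unique(nchar(sequences))) != 1L)
    stop("reads in a region must share one length", call. = FALSE)
  tab <- table(sequences)
  cnt <- as.integer(tab)
  N_before <- sum(cnt)
  # epsilon guards the strict "< threshold * N" rule against binary
  # floating-point representation of the threshold
  keep <- cnt >= threshold * N_before - 1e-9
  out <- data.frame(sequence = names(tab)[keep], count = cnt[keep],
                    stringsAsFactors = FALSE)
  out <- out[order(-out$count, out$sequence), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "N") <- sum(out$count)
  attr(out, "N_before") <- N_before
  attr(out, "n_discarded") <- N_before - sum(out$count)
  out
}

#' Prepare a region read table from FASTQ input
#'
#' Runs the full preprocessing chain — quality filter, primer-based region
#' assignment and trimming, exact collapse, low-frequency filter — and
#' returns the per-region unique-read tables the profiler consumes.  For
#' paired-end data the two mates are paired by record order, each is matched
#' against the forward / reverse primer of the same region, and the retained
#' pair is stored as the concatenation forward-mate || reverse-mate (2L nt),
#' mirroring the paired k-mer construction.
#'
#' @param fastq Path to the (R1) FASTQ file.
#' @param primers Primer table.
#' @param L Trimmed read length per mate.
#' @param fastq2 Optional R2 FASTQ for paired-end data.
#' @param barcode_len,max_mismatch Passed to [demultiplex_and_trim()].
#' @param threshold Low-frequency read filter fraction.
#' @param quality_params List of overrides for [quality_filter_reads()].
#' @return An object of class `smurf_reads`: list with `tables` (named by
#'   region id), `mode`, `L`, and a `stats` data frame of per-stage tallies.
#' @export
prepare_reads <- function(fastq, primers, L, fastq2 = NULL, barcode_len = 0L,
                          max_mismatch = 2L, threshold = 1e-4,
                          quality_params = list()) {
  r1 <- read_fastq(fastq)
  if (length(r1$sequence) == 0L)
    stop("empty FASTQ input: ", fastq, call. = FALSE)
  qf1 <- do.call(quality_filter_reads,
                 c(list(r1$sequence, r1$quality), quality_params))
  paired <- !is.null(fastq2)
  if (paired) {
    r2 <- read_fastq(fastq2)
    if (length(r2$sequence) != length(r1$sequence))
      stop("mate files differ in record count", call. = FALSE)
    qf2 <- do.call(quality_filter_reads,
                   c(list(r2$sequence, r2$quality), quality_params))
    keep <- qf1$keep & qf2$keep
  } else {
    keep <- qf1$keep
  }
  d1 <- demultiplex_and_trim(r1$sequence[keep], primers, L, barcode_len,
                             max_mismatch, "forward")
  if (paired) {
    d2 <- demultiplex_and_trim(r2$sequence[keep], primers, L, barcode_len,
                               max_mismatch, "reverse")
    ok <- !is.na(d1$region_id) & !is.na(d2$region_id) &
      d1$region_id == d2$region_id
    region <- d1$region_id[ok]
    seqs <- paste0(d1$trimmed[ok], d2$trimmed[ok])
  } else {
    ok <- !is.na(d1$region_id)
    region <- d1$region_id[ok]
    seqs <- d1$trimmed[ok]
  }
  tables <- lapply(split(seqs, region), collapse_and_filter_reads,
                   threshold = threshold)
  stats <- data.frame(
    input = length(r1$sequence),
    quality_failed = sum(!keep),
    unassigned = sum(!ok),
    assigned = sum(ok),
    low_freq_discarded = sum(vapply(tables, attr, integer(1), "n_discarded")),
    retained = sum(vapply(tables, attr, integer(1), "N"))
  )
  structure(list(tables = tables, mode = if (paired) "paired" else "single",
                 L = as.integer(L), threshold = threshold, stats = stats),
            class = "smurf_reads")
}

#' Construct a read table directly from sequences
#'
#' Convenience constructor used by the simulator and by tests: takes a named
#' list of per-region read sequence vectors (already trimmed) and applies
#' collapsing plus the low-frequency filter.
#'
#' @param region_reads Named list (names = region ids) of character vectors.
#' @param mode `"paired"` or `"single"`.
#' @param threshold Low-frequency filter fraction.
#' @return A `smurf_reads` object.
#' @export
as_read_table <- function(region_reads, mode = "paired", threshold = 1e-4) {
  tables <- lapply(region_reads, collapse_and_filter_reads,
                   threshold = threshold)
  n_in <- sum(lengths(region_reads))
  structure(list(
    tables = tables, mode = mode,
    L = if (n_in) unique(nchar(unlist(region_reads)))[1] else NA_integer_,
    threshold = threshold,
    stats = data.frame(
      input = n_in, quality_failed = 0L, unassigned = 0L, assigned = n_in,
      low_freq_discarded = sum(vapply(tables, attr, integer(1), "n_discarded")),
      retained = sum(vapply(tables, attr, integer(1), "N"))
    )), class = "smurf_reads")
}

#' @export
print.smurf_reads <- function(x, ...) {
  cat("smurf_reads (", x$mode, "-end): ", length(x$tables), " regions, ",
      x$stats$retained, " reads retained of ", x$stats$input, " input\n",
      sep = "")
  for (r in names(x$tables)) {
    cat("  region ", r, ": ", attr(x$tables[[r]], "N"), " reads, ",
        nrow(x$tables[[r]]), " unique\n", sep = "")
  }
  invisible(x)
}
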