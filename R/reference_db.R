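# Reference database handling: load a full-length 16S reference (FASTA +
# taxonomy), expand degenerate bases, locate primer-defined amplicons and
# build the per-region k-mer database with the sparse mixture matrix M.

#' Construct a reference set
#'
#' Takes full-length 16S sequences (possibly containing IUPAC ambiguity
#' codes) with their taxonomy strings and applies degenerate-base expansion:
#' each source record is duplicated over all combinations of its ambiguous
#' positions (up to 4^3 = 64 variants); records with more than three
#' ambiguous positions are discarded.  Expanded variants are distinct
#' entries for reconstruction but retain the source id for reporting.
#'
#' @param ids Character vector of unique sequence identifiers.
#' @param sequences Character vector of IUPAC DNA strings.
#' @param taxonomy Character vector of semicolon-delimited rank strings
#'   (recycled if length 1).
#' @param max_ambiguous Passed to [expand_ambiguous_sequence()].
#' @return An object of class `smurf_reference`: a data frame with columns
#'   `id`, `source_id`, `sequence`, `taxonomy`, one row per (expanded)
#'   reference sequence, plus attribute `n_discarded`.
#' @export
smurf_reference <- function(ids, sequences, taxonomy, max_ambiguous = 3L) {
  stopifnot(length(ids) == length(sequences), !anyDuplicated(ids))
  if (length(taxonomy) == 1L) taxonomy <- rep(taxonomy, length(ids))
  stopifnot(length(taxonomy) == length(ids))
  sequences <- toupper(sequences)

  needs <- grepl("[^ACGT]", sequences)
  out_id <- out_src <- out_seq <- out_tax <- vector("list", length(ids))
  n_discarded <- 0L
  for (r in seq_along(ids)) {
    if (!needs[r]) {
      out_id[[r]] <- ids[r]; out_seq[[r]] <- sequences[r]
    } else {
      ex <- expand_ambiguous_sequence(sequences[r], max_ambiguous)
      if (length(ex) == 0L) { n_discarded <- n_discarded + 1L; next }
      out_id[[r]] <- if (length(ex) == 1L) ids[r]
                     else paste0(ids[r], "_v", seq_along(ex))
      out_seq[[r]] <- ex
    }
    out_src[[r]] <- rep(ids[r], length(out_id[[r]]))
    out_tax[[r]] <- rep(taxonomy[r], length(out_id[[r]]))
  }
  ref <- data.frame(
    id = unlist(out_id), source_id = unlist(out_src),
    sequence = unlist(out_seq), taxonomy = unlist(out_tax),
    stringsAsFactors = FALSE
  )
  if (nrow(ref) < 1L) stop("all reference records were discarded", call. = FALSE)
  attr(ref, "n_discarded") <- n_discarded
  class(ref) <- c("smurf_reference", "data.frame")
  ref
}

#' Read a reference set from FASTA plus a taxonomy table
#'
#' FASTA headers (up to the first whitespace) are the sequence ids; the
#' taxonomy file is 2-column tab-separated (id, semicolon-ranked lineage),
#' the format both Greengenes and SILVA exports use.  Ids present in the
#' FASTA but absent from the taxonomy table get the label `"Unclassified"`.
#'
#' @param fasta Path to a FASTA file (optionally gzipped).
#' @param taxonomy Path to the taxonomy TSV, or `NULL` for none.
#' @inheritParams smurf_reference
#' @return A [smurf_reference] object.
#' @export
read_reference <- function(fasta, taxonomy = NULL, max_ambiguous = 3L) {
  seqs <- Biostrings::readDNAStringSet(fasta)
  ids <- sub("\\s.*$", "", names(seqs))
  tax <- rep("Unclassified", length(ids))
  if (!is.null(taxonomy)) {
    tt <- utils::read.delim(taxonomy, header = FALSE, stringsAsFactors = FALSE,
                            colClasses = "character", quote = "")
    hit <- match(ids, tt[[1]])
    tax[!is.na(hit)] <- tt[[2]][hit[!is.na(hit)]]
  }
  smurf_reference(ids, as.character(seqs), tax, max_ambiguous)
}

#' @export
print.smurf_reference <- function(x, ...) {
  cat("smurf_reference: ", nrow(x), " sequences (",
      length(unique(x$source_id)), " source records, ",
      attr(x, "n_discarded"), " discarded)\n", sep = "")
  invisible(x)
}

#' Read or fetch a primer table
#'
#' A primer table has columns `region_id` (small integer), `forward` and
#' `reverse` (IUPAC DNA, written 5'->3').  `default_primers()` returns the
#' packaged six-pair multi-region set; `v4_primers()` the standard V4 pair.
#'
#' @param path Tab-separated file with columns region_id, forward, reverse.
#' @return A data frame of class `smurf_primers`.
#' @export
read_primers <- function(path) {
  p <- utils::read.delim(path, stringsAsFactors = FALSE, quote = "")
  as_primers(p)
}

as_primers <- function(p) {
  stopifnot(all(c("region_id", "forward", "reverse") %in% names(p)))
  p$region_id <- as.integer(p$region_id)
  if (anyDuplicated(p$region_id)) stop("duplicate region_id", call. = FALSE)
  if (any(nchar(p$forward) < 10L) || any(nchar(p$reverse) < 10L))
    stop("primer shorter than 10 nt", call. = FALSE)
  p <- p[order(p$region_id), c("region_id", "forward", "reverse")]
  rownames(p) <- NULL
  class(p) <- c("smurf_primers", "data.frame")
  p
}

#' @rdname read_primers
#' @export
default_primers <- function() {
  read_primers(system.file("extdata", "primers_six_regions.tsv",
                           package = "smurf16S", mustWork = TRUE))
}

#' @rdname read_primers
#' @export
v4_primers <- function() {
  read_primers(system.file("extdata", "primers_v4.tsv",
                           package = "smurf16S", mustWork = TRUE))
}

#' Locate primer-defined amplicons on every reference sequence
#'
#' For each reference sequence the forward strand is scanned for the
#' best-matching (fewest mismatches, leftmost tie-break) forward-primer site
#' and, downstream of it, the best site of the reverse-complemented reverse
#' primer.  The sequence is "amplified" in the region iff both best sites
#' have at most `max_mismatch` mismatches and the inter-primer amplicon is
#' non-empty.  Coordinates are 0-based half-open and exclude the primer
#' bases, matching reads whose primers have been trimmed off.
#'
#' @param ref A [smurf_reference].
#' @param primers A primer table (single row or several regions).
#' @param max_mismatch Per-primer mismatch tolerance (default 2).
#' @return Data frame with one row per (region, taxon): `region_id`, `taxon`
#'   (row index in `ref`), `amplified`, `start`, `end`, `fwd_mm`, `rev_mm`.
#' @export
locate_amplicons <- function(ref, primers, max_mismatch = 2L) {
  primers <- as_primers(as.data.frame(primers))
  seq_bits <- lapply(ref$sequence, iupac_bits)
  res <- vector("list", nrow(primers))
  for (r in seq_len(nrow(primers))) {
    fwd_bits <- iupac_bits(primers$forward[r])
    rev_bits <- iupac_bits(revcomp(primers$reverse[r]))
    P_f <- length(fwd_bits); P_r <- length(rev_bits)
    n <- nrow(ref)
    amp <- logical(n); st <- en <- rep(NA_integer_, n)
    fmm <- rmm <- rep(NA_integer_, n)
    for (j in seq_len(n)) {
      sb <- seq_bits[[j]]
      mm_f <- scan_primer_bits(sb, fwd_bits)
      if (length(mm_f) == 0L) next
      f_pos <- which.min(mm_f)            # leftmost minimum
      fmm[j] <- mm_f[f_pos]
      amp_start <- f_pos + P_f            # 1-based first base after fwd primer
      if (amp_start + P_r - 1L > length(sb)) next
      mm_r <- scan_primer_bits(sb[amp_start:length(sb)], rev_bits)
      if (length(mm_r) == 0L) next
      r_off <- which.min(mm_r)
      rmm[j] <- mm_r[r_off]
      rev_start <- amp_start + r_off - 1L # 1-based start of reverse site
      st[j] <- amp_start - 1L             # 0-based amplicon start
      en[j] <- rev_start - 1L             # 0-based half-open amplicon end
      amp[j] <- fmm[j] <= max_mismatch && rmm[j] <= max_mismatch &&
        en[j] > st[j]
    }
    res[[r]] <- data.frame(
      region_id = primers$region_id[r], taxon = seq_len(n),
      amplified = amp, start = st, end = en, fwd_mm = fmm, rev_mm = rmm
    )
  }
  do.call(rbind, res)
}

#' Build the per-region k-mer database and mixture matrix
#'
#' For every (taxon, amplified region) the read-length k-mer(s) the taxon
#' would produce are recorded: in paired-end mode the first `k` bases of the
#' amplicon concatenated with the first `k` bases of its reverse complement
#' (one row of length 2k); in single-end mode those two k-length pieces as
#' two separate rows.  Regions whose amplicon is shorter than `k` count as
#' not amplified for the taxon.  `R[j]` is the number of amplified regions of
#' taxon `j` and the sparse mixture matrix `M` holds
#' `M[h, j] = Pr(kmer = h | bacterium = j)`, i.e. `1/R_j` per row in
#' paired-end mode and `0.5/R_j` in single-end mode, so each amplified
#' taxon's column sums to 1.  A k-mer sequence occurring in two regions
#' occupies two distinct rows.
#'
#' @param ref A [smurf_reference].
#' @param primers Primer table.
#' @param k Read length in nt (the per-end read length for paired-end data).
#' @param mode `"paired"` or `"single"`.
#' @param max_mismatch Primer mismatch tolerance for amplification.
#' @return An object of class `smurf_kmer_db`.
#' @export
build_region_kmer_db <- function(ref, primers, k, mode = c("paired", "single"),
                                 max_mismatch = 2L) {
  mode <- match.arg(mode)
  stopifnot(k >= 1L)
  primers <- as_primers(as.data.frame(primers))
  if (nrow(primers) == 0L) stop("empty primer set", call. = FALSE)
  amp <- locate_amplicons(ref, primers, max_mismatch)
  # amplicons shorter than the read length cannot generate a k-mer
  amp$amplified <- amp$amplified & !is.na(amp$start) &
    (amp$end - amp$start) >= k

  ok <- amp[amp$amplified, , drop = FALSE]
  ent <- NULL
  if (nrow(ok) > 0L) {
    amplicon <- substr(ref$sequence[ok$taxon], ok$start + 1L, ok$end)
    fwd_piece <- substr(amplicon, 1L, k)
    rev_piece <- substr(vapply(amplicon, revcomp, character(1), USE.NAMES = FALSE), 1L, k)
    if (mode == "paired") {
      ent <- data.frame(region_id = ok$region_id, taxon = ok$taxon,
                        kmer = paste0(fwd_piece, rev_piece), weight = 1)
    } else {
      ent <- rbind(
        data.frame(region_id = ok$region_id, taxon = ok$taxon,
                   kmer = fwd_piece, weight = 0.5),
        data.frame(region_id = ok$region_id, taxon = ok$taxon,
                   kmer = rev_piece, weight = 0.5)
      )
    }
  }
  J <- nrow(ref)
  R <- integer(J)
  tab <- table(factor(ok$taxon, levels = seq_len(J)))
  R[] <- as.integer(tab)

  if (is.null(ent) || nrow(ent) == 0L)
    stop("no reference sequence is amplified by any primer pair", call. = FALSE)

  key <- paste(ent$region_id, ent$kmer, sep = ":")
  rows <- data.frame(key = sort(unique(key)), stringsAsFactors = FALSE)
  rows$region_id <- as.integer(sub(":.*$", "", rows$key))
  rows$kmer <- sub("^[^:]*:", "", rows$key)
  h <- match(key, rows$key)
  M <- Matrix::sparseMatrix(
    i = h, j = ent$taxon, x = ent$weight / R[ent$taxon],
    dims = c(nrow(rows), J)
  )
  db <- list(
    k = as.integer(k), mode = mode, max_mismatch = as.integer(max_mismatch),
    primers = primers, regions = primers$region_id,
    reference = ref, amplicons = amp, R = R,
    kmer_rows = rows[, c("region_id", "kmer")],
    entries = data.frame(region_id = ent$region_id, taxon = ent$taxon,
                         kmer = ent$kmer, row = h),
    M = M
  )
  class(db) <- "smurf_kmer_db"
  db
}

#' @export
print.smurf_kmer_db <- function(x, ...) {
  cat("smurf_kmer_db: ", length(x$R), " taxa, ", length(x$regions),
      " regions, ", nrow(x$kmer_rows), " k-mer rows (k = ", x$k, ", ",
      x$mode, "-end)\n", sep = "")
  cat("  un-amplifiable taxa (R_j = 0): ", sum(x$R == 0L), "\n", sep = "")
  invisible(x)
}

# per-taxon footprint keys over a region subset: ordered tuple of the taxon's
# k-mer (or "-" absent-marker) per region; taxa with R_j = 0 get NA
footprint_keys <- function(db, regions = db$regions) {
  regions <- sort(as.integer(regions))
  stopifnot(length(regions) >= 1L, all(regions %in% db$regions))
  J <- length(db$R)
  parts <- matrix("-", nrow = J, ncol = length(regions))
  for (ci in seq_along(regions)) {
    e <- db$entries[db$entries$region_id == regions[ci], , drop = FALSE]
    if (nrow(e) == 0L) next
    km <- vapply(split(e$kmer, e$taxon),
                 function(z) paste(sort(z), collapse = "+"), character(1))
    parts[as.integer(names(km)), ci] <- km
  }
  keys <- apply(parts, 1L, paste, collapse = "|")
  keys[db$R == 0L] <- NA_character_
  keys
}

#' Footprint groups and theoretical resolution
#'
#' Partitions the amplified taxa into groups with identical footprints — the
#' ordered tuple of per-region k-mers (with absent-markers for regions a
#' taxon is not amplified in) restricted to `regions`.  Taxa in a group of
#' size one are uniquely identifiable with that region subset.
#'
#' @param db A `smurf_kmer_db`.
#' @param regions Region subset (default: all regions in the db).
#' @return Class `smurf_footprints`: list with `membership` (group index per
#'   taxon, NA for un-amplifiable taxa), `groups` (list of taxon index
#'   vectors), `sizes`, `size_histogram` and `unique_fraction`.
#' @export
compute_theoretical_groups <- function(db, regions = db$regions) {
  keys <- footprint_keys(db, regions)
  live <- which(!is.na(keys))
  fac <- factor(keys[live])
  groups <- split(live, fac)
  sizes <- lengths(groups)
  membership <- rep(NA_integer_, length(keys))
  membership[live] <- as.integer(fac)
  out <- list(
    regions = sort(as.integer(regions)),
    membership = membership,
    footprint = keys,
    groups = groups,
    sizes = sizes,
    size_histogram = table(sizes),
    unique_fraction = if (length(live)) sum(sizes == 1L) / length(live) else NA_real_
  )
  class(out) <- "smurf_footprints"
  out
}

#' @export
print.smurf_footprints <- function(x, ...) {
  cat("smurf_footprints over regions {",
      paste(x$regions, collapse = ","), "}: ",
      length(x$groups), " groups over ", sum(x$sizes), " taxa; ",
      sprintf("%.1f%%", 100 * x$unique_fraction), " uniquely identifiable\n",
      sep = "")
  invisible(x)
}

#' Persist / load a k-mer database directory
#'
#' The database is written as a directory holding a JSON manifest (k, mode,
#' mismatch tolerance, primer table, version) and gzipped tab-separated
#' tables for the reference, amplicon map, k-mer rows and the M triplets —
#' portable and diff-able.
#'
#' @param db A `smurf_kmer_db`.
#' @param dir Output directory (created if missing).
#' @return `write_kmer_db` returns `dir` invisibly; `read_kmer_db` the
#'   reconstructed `smurf_kmer_db`.
#' @export
write_kmer_db <- function(db, dir) {
  stopifnot(inherits(db, "smurf_kmer_db"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  manifest <- list(
    format = "smurf_kmer_db", version = as.character(utils::packageVersion("smurf16S")),
    k = db$k, mode = db$mode, max_mismatch = db$max_mismatch,
    primers = db$primers
  )
  jsonlite::write_json(manifest, file.path(dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, dataframe = "columns")
  wtsv <- function(d, f) {
    con <- gzfile(file.path(dir, f), "w")
    on.exit(close(con))
    utils::write.table(d, con, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  wtsv(as.data.frame(db$reference), "reference.tsv.gz")
  wtsv(db$amplicons, "amplicons.tsv.gz")
  wtsv(cbind(row = seq_len(nrow(db$kmer_rows)), db$kmer_rows), "kmers.tsv.gz")
  wtsv(data.frame(taxon = seq_along(db$R), R = db$R), "R.tsv.gz")
  tm <- Matrix::summary(db$M)
  wtsv(data.frame(row = tm$i, taxon = tm$j, value = tm$x), "M_triplets.tsv.gz")
  wtsv(db$entries, "entries.tsv.gz")
  invisible(dir)
}

#' @rdname write_kmer_db
#' @export
read_kmer_db <- function(dir) {
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  rtsv <- function(f) utils::read.delim(file.path(dir, f),
                                        stringsAsFactors = FALSE, quote = "")
  ref <- rtsv("reference.tsv.gz")
  class(ref) <- c("smurf_reference", "data.frame")
  rows <- rtsv("kmers.tsv.gz")
  Rtab <- rtsv("R.tsv.gz")
  trip <- rtsv("M_triplets.tsv.gz")
  db <- list(
    k = as.integer(manifest$k), mode = manifest$mode,
    max_mismatch = as.integer(manifest$max_mismatch),
    primers = as_primers(as.data.frame(manifest$primers)),
    regions = sort(as.integer(manifest$primers$region_id)),
    reference = ref, amplicons = rtsv("amplicons.tsv.gz"),
    R = as.integer(Rtab$R),
    kmer_rows = rows[, c("region_id", "kmer")],
    entries = rtsv("entries.tsv.gz"),
    M = Matrix::sparseMatrix(i = trip$row, j = trip$taxon, x = trip$value,
                             dims = c(nrow(rows), nrow(Rtab)))
  )
  class(db) <- "smurf_kmer_db"
  db
}
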