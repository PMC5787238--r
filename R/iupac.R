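# IUPAC nucleotide handling: bitmask encoding, degenerate-base expansion and
# set-aware mismatch counting.  Primer bases are degenerate (IUPAC codes);
# reference and read bases are expected to be unambiguous A/C/G/T after
# expansion / quality filtering.

# bit encoding: A=1, C=2, G=4, T=8; a degenerate code is the union of its bits
.IUPAC_BITS <- c(
  A = 1L, C = 2L, G = 4L, T = 8L,
  R = 5L, Y = 10L, S = 6L, W = 9L, K = 12L, M = 3L,
  B = 14L, D = 13L, H = 11L, V = 7L, N = 15L
)

.IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# encode a DNA string (possibly degenerate) as an integer bitmask vector;
# unknown characters raise an error naming the first offending position
iupac_bits <- function(seq) {
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bits <- .IUPAC_BITS[chars]
  if (anyNA(bits)) {
    pos <- which(is.na(bits))[1]
    stop("non-IUPAC character '", chars[pos], "' at position ", pos,
         call. = FALSE)
  }
  unname(bits)
}

#' Expand a sequence containing IUPAC ambiguity codes
#'
#' Every degenerate position is substituted by each base in its IUPAC set and
#' the Cartesian product of all substitutions is returned, alphabetical at
#' each position.  Records with more than `max_ambiguous` degenerate positions
#' are discarded (an empty character vector is returned), mirroring the
#' reference-database preparation rule that caps the expansion at 64 variants
#' per source sequence.
#'
#' @param seq A single DNA string over the IUPAC alphabet.
#' @param max_ambiguous Maximum number of degenerate positions tolerated
#'   before the sequence is discarded (default 3, i.e. at most 4^3 = 64
#'   expanded variants).
#' @return Character vector of unambiguous sequences (possibly empty).
#' @examples
#' expand_ambiguous_sequence("ACRT")  # "ACAT" "ACGT"
#' @export
expand_ambiguous_sequence <- function(seq, max_ambiguous = 3L) {
  stopifnot(is.character(seq), length(seq) == 1L, nzchar(seq))
  chars <- strsplit(toupper(seq), "", fixed = TRUE)[[1]]
  bad <- !chars %in% names(.IUPAC_SETS)
  if (any(bad)) {
    pos <- which(bad)[1]
    stop("non-IUPAC character '", chars[pos], "' at position ", pos,
         call. = FALSE)
  }
  sets <- .IUPAC_SETS[chars]
  n_amb <- sum(lengths(sets) > 1L)
  if (n_amb > max_ambiguous) return(character(0))
  if (n_amb == 0L) return(paste(chars, collapse = ""))
  out <- ""
  for (s in sets) {
    out <- as.vector(t(outer(out, s, paste0)))
  }
  out
}

#' Count primer-template mismatches
#'
#' Compares a (possibly degenerate) primer against an unambiguous template
#' window of the same length.  A position matches iff the template base is a
#' member of the primer base's IUPAC set; only substitutions are considered,
#' never indels.
#'
#' @param primer IUPAC DNA string.
#' @param window Unambiguous DNA string of the same length.
#' @return Integer mismatch count.
#' @export
count_primer_mismatches <- function(primer, window) {
  if (nchar(primer) != nchar(window))
    stop("primer and window lengths differ (", nchar(primer), " vs ",
         nchar(window), ")", call. = FALSE)
  pb <- iupac_bits(primer)
  wb <- iupac_bits(window)
  sum(bitwAnd(pb, wb) == 0L)
}

# reverse complement preserving IUPAC degeneracy (via Biostrings)
revcomp <- function(seq) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(seq)))
}

# mismatch count of `primer_bits` against every window of `seq_bits`;
# returns integer vector over window start offsets 1..(S-P+1), or integer(0)
# when the sequence is shorter than the primer
scan_primer_bits <- function(seq_bits, primer_bits) {
  P <- length(primer_bits)
  S <- length(seq_bits)
  if (S < P) return(integer(0))
  n_win <- S - P + 1L
  mm <- integer(n_win)
  idx <- seq_len(n_win)
  for (p in seq_len(P)) {
    mm <- mm + (bitwAnd(seq_bits[idx + (p - 1L)], primer_bits[p]) == 0L)
  }
  mm
}
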