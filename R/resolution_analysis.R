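# Resolution analysis: footprint groups of the reconstructed profile,
# effective-sequence-count ambiguity (exponentiated Shannon entropy), and
# profile postprocessing (taxonomy merging + low-frequency group filter).

#' Collapse a profile into footprint groups
#'
#' Reference sequences sharing the same footprint — identical k-mers over
#' all amplified regions, including which regions are amplified at all —
#' cannot be told apart by the profiler.  This partitions the supported taxa
#' (`x > 0`) into such groups and sums member frequencies.
#'
#' @param fit A `smurf_fit`.
#' @param db The `smurf_kmer_db` the fit was computed on (defaults to the
#'   one stored in the fit).
#' @return An object of class `smurf_groups`: data frame with `group_id`,
#'   `frequency`, `footprint`, `size`, `members` (comma-separated sequence
#'   ids), `taxonomy` (representative: the highest-frequency member's),
#'   ordered by decreasing frequency then footprint.
#' @export
assign_groups <- function(fit, db = fit$db) {
  stopifnot(inherits(fit, "smurf_fit"))
  supp <- which(fit$x > 0)
  taxa <- fit$taxon[supp]
  xs <- fit$x[supp]
  keys <- footprint_keys(db)[taxa]
  grp <- split(seq_along(taxa), keys)
  freq <- vapply(grp, function(ii) sum(xs[ii]), numeric(1))
  size <- lengths(grp)
  members <- vapply(grp, function(ii)
    paste(db$reference$id[taxa[ii]], collapse = ","), character(1))
  taxonomy <- vapply(grp, function(ii) {
    top <- ii[which.max(xs[ii])]
    db$reference$taxonomy[taxa[top]]
  }, character(1))
  out <- data.frame(
    footprint = names(grp), frequency = freq, size = size,
    members = members, taxonomy = taxonomy, stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency, out$footprint), , drop = FALSE]
  out$group_id <- seq_len(nrow(out))
  rownames(out) <- NULL
  out <- out[, c("group_id", "frequency", "size", "footprint", "members",
                 "taxonomy")]
  attr(out, "member_taxa") <- lapply(grp[order(-freq, names(grp))],
                                     function(ii) taxa[ii])
  class(out) <- c("smurf_groups", "data.frame")
  out
}

#' @export
print.smurf_groups <- function(x, ...) {
  cat("smurf_groups: ", nrow(x), " footprint groups, total frequency ",
      format(sum(x$frequency)), "\n", sep = "")
  tab <- as.data.frame(x)[, c("group_id", "frequency", "size", "taxonomy")]
  tab$frequency <- signif(tab$frequency, 4)
  print(utils::head(tab, 15L), right = FALSE)
  if (nrow(x) > 15L) cat("... ", nrow(x) - 15L, " more groups\n", sep = "")
  invisible(x)
}

#' Effective number of sequences (ambiguity)
#'
#' Given the footprint groups matched to one target organism, each group's
#' frequency is split equally among its member sequences, the resulting
#' per-sequence weights are normalized, and the exponent of their Shannon
#' entropy (natural log) is returned.  A single group with equal weights
#' gives exactly the group size; lower values mean higher resolution.
#'
#' @param frequencies Nonnegative group frequencies (at least one positive).
#' @param sizes Parallel integer group sizes (members per group).
#' @return The ambiguity, a value >= 1.
#' @export
compute_ambiguity <- function(frequencies, sizes) {
  stopifnot(length(frequencies) == length(sizes), all(frequencies >= 0),
            all(sizes >= 1L))
  if (sum(frequencies) <= 0)
    stop("no positive group frequency; ambiguity undefined", call. = FALSE)
  w <- rep(frequencies / sizes, sizes)
  w <- w / sum(w)
  w <- w[w > 0]
  exp(-sum(w * log(w)))
}

#' Per-organism ambiguity report
#'
#' Matches groups to target labels through the reference taxonomy (the
#' stand-in for an external classification service) at the chosen rank and
#' computes each label's ambiguity.
#'
#' @param groups A `smurf_groups`.
#' @param level Taxonomy rank used as the label: `"species"` (last rank,
#'   default) or `"genus"` (second to last), or an integer rank index.
#' @return Data frame with `label`, `ambiguity`, `n_groups`, `n_sequences`,
#'   `frequency`; attribute `mean_ambiguity` holds the across-label mean.
#' @export
ambiguity_report <- function(groups, level = "species") {
  lab <- taxonomy_label(groups$taxonomy, level)
  by <- split(seq_len(nrow(groups)), lab)
  out <- data.frame(
    label = names(by),
    ambiguity = vapply(by, function(ii)
      compute_ambiguity(groups$frequency[ii], groups$size[ii]), numeric(1)),
    n_groups = lengths(by),
    n_sequences = vapply(by, function(ii) sum(groups$size[ii]), integer(1)),
    frequency = vapply(by, function(ii) sum(groups$frequency[ii]), numeric(1)),
    stringsAsFactors = FALSE
  )
  out <- out[order(-out$frequency), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_ambiguity") <- mean(out$ambiguity)
  out
}

# extract a rank label from semicolon-delimited lineages
taxonomy_label <- function(taxonomy, level = "species") {
  ranks <- strsplit(taxonomy, ";", fixed = TRUE)
  ranks <- lapply(ranks, trimws)
  idx <- function(r) {
    if (is.numeric(level)) return(min(level, length(r)))
    if (level == "species") length(r) else max(1L, length(r) - 1L)
  }
  vapply(ranks, function(r) r[idx(r)], character(1))
}

#' Postprocess a grouped profile
#'
#' Merges groups sharing the same label at the chosen taxonomy rank
#' (frequencies added), discards merged entries with total frequency below
#' `min_freq` (default 0.001, i.e. 0.1%), and renormalizes the remainder to
#' sum to one.
#'
#' @param groups A `smurf_groups`.
#' @param level Taxonomy rank for merging (see [ambiguity_report()]).
#' @param min_freq Post-merge frequency floor (default 0.001).
#' @return Data frame with `label`, `frequency` (renormalized),
#'   `raw_frequency`, `n_groups`, `n_sequences`, sorted by frequency.
#' @export
postprocess_profile <- function(groups, level = "species", min_freq = 0.001) {
  lab <- taxonomy_label(groups$taxonomy, level)
  by <- split(seq_len(nrow(groups)), lab)
  merged <- data.frame(
    label = names(by),
    raw_frequency = vapply(by, function(ii) sum(groups$frequency[ii]),
                           numeric(1)),
    n_groups = lengths(by),
    n_sequences = vapply(by, function(ii) sum(groups$size[ii]), integer(1)),
    stringsAsFactors = FALSE
  )
  merged <- merged[merged$raw_frequency >= min_freq, , drop = FALSE]
  if (nrow(merged) == 0L)
    stop("every merged entry fell below min_freq = ", min_freq,
         "; lower min_freq", call. = FALSE)
  merged$frequency <- merged$raw_frequency / sum(merged$raw_frequency)
  merged <- merged[order(-merged$frequency, merged$label),
                   c("label", "frequency", "raw_frequency", "n_groups",
                     "n_sequences")]
  rownames(merged) <- NULL
  merged
}
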