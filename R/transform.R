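#' Rarefy samples to a common depth
#'
#' Subsamples each sample's reads without replacement (multivariate
#' hypergeometric, via [vegan::rrarefy()]) so that every retained sample sums
#' exactly to `depth`. Samples with fewer than `depth` reads are dropped with
#' a warning.
#'
#' @param cm a [community_matrix()] (or coercible).
#' @param depth target reads per sample (>= 1).
#' @param seed optional integer seed; the ambient RNG stream is untouched.
#' @return A [community_matrix()] whose columns all sum to `depth`.
#' @export
rarefy <- function(cm, depth, seed = NULL) {
  cm <- as_community_matrix(cm)
  if (length(depth) != 1 || is.na(depth) || depth < 1) {
    abort("`depth` must be a single integer >= 1.")
  }
  depth <- as.integer(depth)
  totals <- colSums(cm$counts)
  keep <- totals >= depth
  if (!any(keep)) abort("all samples are below the rarefaction depth.")
  if (any(!keep)) {
    warn(sprintf("dropping %d sample(s) below depth %d: %s",
                 sum(!keep), depth, paste(colnames(cm$counts)[!keep], collapse = ", ")))
  }
  m <- cm$counts[, keep, drop = FALSE]
  out <- with_seed_opt(seed, withCallingHandlers(
    t(vegan::rrarefy(t(m), depth)),
    # vegan flags tables whose smallest count is large as possibly not raw
    # counts; our inputs are validated integer counts, so this is noise
    warning = function(w) {
      if (grepl("observed counts", conditionMessage(w))) {
        invokeRestart("muffleWarning")
      }
    }))
  community_matrix(matrix(as.integer(out), nrow(out), ncol(out), dimnames = dimnames(m)),
                   taxonomy = cm$taxonomy)
}

#' Filter taxa by prevalence and mean relative abundance
#'
#' Keeps taxa detected (count > 0) in strictly more than `min_prevalence`
#' samples and whose relative abundance, averaged (or maximised, see
#' `abundance_stat`) across samples, is strictly above `min_mean_relabund`.
#' The defaults reproduce the conventional network pre-filter: present in
#' more than two samples and above 0.2% abundance.
#'
#' @inheritParams rarefy
#' @param min_prevalence number of samples a taxon must strictly exceed.
#' @param min_mean_relabund proportion the taxon's mean (or max) relative
#'   abundance must strictly exceed.
#' @param abundance_stat `"mean"` (default) or `"max"` across samples.
#' @return A filtered [community_matrix()]; taxon order preserved.
#' @export
filter_taxa <- function(cm, min_prevalence = 2, min_mean_relabund = 0.002,
                        abundance_stat = c("mean", "max")) {
  cm <- as_community_matrix(cm)
  abundance_stat <- match.arg(abundance_stat)
  if (min_prevalence < 0 || min_mean_relabund < 0) abort("thresholds must be >= 0.")
  m <- cm$counts
  prev <- rowSums(m > 0)
  ra <- relative_abundance_values(m)
  stat <- if (abundance_stat == "mean") rowMeans(ra) else apply(ra, 1, max)
  keep <- prev > min_prevalence & stat > min_mean_relabund
  community_matrix(m[keep, , drop = FALSE], taxonomy = cm$taxonomy)
}

relative_abundance_values <- function(m) {
  totals <- colSums(m)
  sweep(m, 2, ifelse(totals > 0, totals, 1), "/")
}

#' Derived matrices
#'
#' `to_relative_abundance()` column-normalises counts to proportions (all-zero
#' samples stay zero); `to_presence_absence()` binarises as `counts > 0`.
#'
#' @inheritParams rarefy
#' @return A numeric matrix with the same dimnames as the counts.
#' @export
to_relative_abundance <- function(cm) {
  m <- as_counts_matrix(cm)
  relative_abundance_values(m)
}

#' @rdname to_relative_abundance
#' @export
to_presence_absence <- function(cm) {
  m <- as_counts_matrix(cm)
  (m > 0) * 1L
}

#' Split a community matrix by metadata group
#'
#' @inheritParams rarefy
#' @param md sample metadata with columns `sample_id` and `group` covering
#'   every sample of `cm`.
#' @return A named list of [community_matrix()] objects, one per group; the
#'   union of their samples is exactly the input sample set.
#' @export
split_by_group <- function(cm, md) {
  cm <- as_community_matrix(cm)
  sids <- colnames(cm$counts)
  idx <- match(sids, md$sample_id)
  if (anyNA(idx)) {
    abort(sprintf("no metadata for sample(s): %s",
                  paste(sids[is.na(idx)], collapse = ", ")))
  }
  groups <- md$group[idx]
  lapply(split(sids, groups), function(s) {
    community_matrix(cm$counts[, s, drop = FALSE], taxonomy = cm$taxonomy)
  })
}
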