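#' Alpha diversity
#'
#' `shannon()` returns the Shannon index H = -sum(q log q) over the non-zero
#' proportions of a single sample's counts (natural log by default;
#' `base = 2` for bits). `observed_richness()` counts taxa with count > 0.
#' `alpha_diversity()` tabulates both for every sample of a community matrix.
#'
#' @param x non-negative count vector for one sample, with at least one
#'   positive entry.
#' @param base logarithm base (default `exp(1)`, i.e. nats).
#' @return `shannon()` and `observed_richness()` return a scalar;
#'   `alpha_diversity()` a tibble with one row per sample.
#' @examples
#' shannon(c(10, 10, 10, 10))  # log(4)
#' @export
shannon <- function(x, base = exp(1)) {
  if (any(x < 0)) abort("counts must be non-negative.")
  if (sum(x) == 0) abort("Shannon index undefined for an all-zero sample.")
  as.numeric(vegan::diversity(x, index = "shannon", base = base))
}

#' @rdname shannon
#' @export
observed_richness <- function(x) {
  if (sum(x) == 0) abort("richness undefined for an all-zero sample.")
  sum(x > 0)
}

#' @rdname shannon
#' @param cm a [community_matrix()] (or coercible).
#' @export
alpha_diversity <- function(cm, base = exp(1)) {
  m <- as_counts_matrix(cm)
  if (any(colSums(m) == 0)) abort("all-zero sample(s) present.")
  tibble(
    sample_id = colnames(m),
    shannon = unname(apply(m, 2, shannon, base = base)),
    richness = unname(apply(m, 2, observed_richness))
  )
}

#' Bray-Curtis dissimilarity between samples
#'
#' d(a, b) = sum|a_i - b_i| / sum(a_i + b_i) over taxa, computed with
#' [vegan::vegdist()].
#'
#' @inheritParams alpha_diversity
#' @return A `stats::dist` object over samples with attribute
#'   `method = "bray"`.
#' @export
bray_curtis <- function(cm) {
  m <- as_counts_matrix(cm)
  if (ncol(m) < 2) abort("need at least 2 samples.")
  if (any(colSums(m) == 0)) abort("Bray-Curtis undefined for all-zero samples.")
  vegan::vegdist(t(m), method = "bray")
}

#' UPGMA clustering of a distance matrix
#'
#' Average-linkage agglomerative clustering yielding an ultrametric
#' dendrogram. Ties are broken by `stats::hclust()`'s deterministic
#' first-encountered order, so output is reproducible.
#'
#' @param dm a `stats::dist` object (e.g. from [bray_curtis()]).
#' @return An [ape::as.phylo()] tree whose leaves are the sample ids; write
#'   Newick with [ape::write.tree()] or [upgma_newick()].
#' @export
upgma <- function(dm) {
  if (!inherits(dm, "dist")) dm <- stats::as.dist(dm)
  if (attr(dm, "Size") < 2) abort("need at least 2 samples to cluster.")
  ape::as.phylo(stats::hclust(dm, method = "average"))
}

#' @rdname upgma
#' @export
upgma_newick <- function(dm) {
  ape::write.tree(upgma(dm))
}

#' Analysis of similarities (ANOSIM)
#'
#' Rank-based permutation test of group differences in a distance matrix.
#' R = (mean between-group rank - mean within-group rank) / (M / 2) with
#' M = n(n-1)/2 ranks over all pairwise distances; the p-value is
#' `(1 + #permuted R >= observed R) / (1 + n_permutations)` under random
#' relabelling.
#'
#' @param dm a `stats::dist` over samples.
#' @param groups group label per sample (same order as the distance labels);
#'   at least 2 groups with at least 2 members each.
#' @param n_permutations number of label permutations (default 9999).
#' @param seed optional integer seed.
#' @return An object of class `anosim_result`; see [glance.anosim_result()].
#' @export
anosim_test <- function(dm, groups, n_permutations = 9999, seed = NULL) {
  if (!inherits(dm, "dist")) dm <- stats::as.dist(dm)
  n <- attr(dm, "Size")
  groups <- as.character(groups)
  if (length(groups) != n) abort("`groups` must have one label per sample.")
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2)) {
    abort("need >= 2 groups with >= 2 members each.")
  }
  rk <- rank(as.numeric(dm))
  M <- n * (n - 1) / 2
  pair_i <- pair_j <- integer(M)
  k <- 1L
  for (j in 1:(n - 1)) {  # dist stores pairs column-wise: (j, i) for i > j
    idx <- (j + 1):n
    pair_i[k:(k + length(idx) - 1)] <- idx
    pair_j[k:(k + length(idx) - 1)] <- j
    k <- k + length(idx)
  }
  r_stat <- function(g) {
    within <- g[pair_i] == g[pair_j]
    (mean(rk[!within]) - mean(rk[within])) / (M / 2)
  }
  r_obs <- r_stat(groups)
  r_perm <- with_seed_opt(seed, {
    vapply(seq_len(n_permutations), function(...) r_stat(sample(groups)), numeric(1))
  })
  p <- (1 + sum(r_perm >= r_obs)) / (1 + n_permutations)
  structure(
    list(r = r_obs, p_value = p, n_permutations = n_permutations,
         groups = groups, r_permuted = r_perm),
    class = "anosim_result"
  )
}

#' @export
print.anosim_result <- function(x, ...) {
  cat(sprintf("ANOSIM: R = %.4f, p = %.4g (%d permutations, %d groups)\n",
              x$r, x$p_value, x$n_permutations, length(unique(x$groups))))
  invisible(x)
}

#' Tidiers for ANOSIM results
#' @param x an `anosim_result`.
#' @param ... unused.
#' @return `glance()` returns a one-row tibble (`r`, `p_value`,
#'   `n_permutations`, `n_groups`); `tidy()` the permutation distribution.
#' @export
glance.anosim_result <- function(x, ...) {
  tibble(r = x$r, p_value = x$p_value, n_permutations = x$n_permutations,
         n_groups = length(unique(x$groups)))
}

#' @rdname glance.anosim_result
#' @export
tidy.anosim_result <- function(x, ...) {
  tibble(permutation = seq_along(x$r_permuted), r = x$r_permuted)
}

#' PCA of relative abundances
#'
#' Principal component analysis of samples in taxon space: columns (taxa)
#' are mean-centred but not variance-scaled, the usual convention for
#' proportion data.
#'
#' @param ram relative-abundance matrix (taxa x samples), e.g. from
#'   [to_relative_abundance()]; a [community_matrix()] is converted.
#' @param n_components number of components to keep; clipped to the rank
#'   with a warning.
#' @return An object of class `pca_result` with elements `scores` (tibble:
#'   `sample_id`, `PC1`, ...) and `explained` (variance fractions,
#'   non-increasing).
#' @export
pca_scores <- function(ram, n_components = 2) {
  if (inherits(ram, "community_matrix") || is.data.frame(ram)) {
    ram <- to_relative_abundance(ram)
  }
  if (ncol(ram) < 2) abort("need at least 2 samples.")
  fit <- prcomp(t(ram), center = TRUE, scale. = FALSE)
  rank <- sum(fit$sdev > max(fit$sdev) * 1e-12)
  if (n_components > rank) {
    warn(sprintf("n_components clipped from %d to rank %d.", n_components, rank))
    n_components <- rank
  }
  explained <- fit$sdev^2 / sum(fit$sdev^2)
  scores <- as_tibble(fit$x[, seq_len(n_components), drop = FALSE])
  scores <- dplyr::bind_cols(tibble(sample_id = colnames(ram)), scores)
  structure(list(scores = scores, explained = explained[seq_len(n_components)]),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf("PCA: %d components, explained %s\n", length(x$explained),
              paste(sprintf("%.1f%%", 100 * x$explained), collapse = ", ")))
  invisible(x)
}

#' @rdname pca_scores
#' @param x a `pca_result`.
#' @param ... unused.
#' @export
tidy.pca_result <- function(x, ...) x$scores

#' @rdname pca_scores
#' @param colour_by optional vector (one value per sample) to colour points.
#' @param object a `pca_result`.
#' @export
autoplot.pca_result <- function(object, colour_by = NULL, ...) {
  df <- object$scores
  if (!is.null(colour_by)) df$group <- colour_by
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2)) +
    ggplot2::labs(
      x = sprintf("PC1 (%.1f%%)", 100 * object$explained[1]),
      y = sprintf("PC2 (%.1f%%)", 100 * object$explained[2])
    ) +
    ggplot2::theme_minimal()
  if (is.null(colour_by)) p + ggplot2::geom_point() else
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$group))
}

#' Environmental heterogeneity per group
#'
#' Z-standardises the chosen variables jointly over all samples, then returns
#' the mean pairwise Euclidean distance within each group — a scalar measure
#' of how variable the abiotic environment is inside each group. Constant
#' variables (sd = 0) are dropped with a warning.
#'
#' @param md metadata tibble with a `group` column.
#' @param variables numeric metadata columns to use (default salinity plus
#'   the three nutrients).
#' @return Tibble with `group`, `n_samples`, `heterogeneity`.
#' @export
environmental_heterogeneity <- function(md,
                                        variables = c("salinity", "nitrate",
                                                      "silicate", "phosphate")) {
  missing_cols <- setdiff(variables, names(md))
  if (length(missing_cols)) {
    abort(sprintf("metadata lacks variable(s): %s", paste(missing_cols, collapse = ", ")))
  }
  X <- as.matrix(md[variables])
  if (!is.numeric(X)) abort("heterogeneity variables must be numeric.")
  if (anyNA(X)) abort("missing values in heterogeneity variables.")
  sds <- apply(X, 2, sd)
  if (any(sds == 0)) {
    warn(sprintf("dropping constant variable(s): %s",
                 paste(variables[sds == 0], collapse = ", ")))
    X <- X[, sds > 0, drop = FALSE]
  }
  Z <- scale(X)
  out <- lapply(split(seq_len(nrow(Z)), md$group), function(idx) {
    d <- stats::dist(Z[idx, , drop = FALSE])
    tibble(n_samples = length(idx),
           heterogeneity = if (length(idx) < 2) 0 else mean(d))
  })
  dplyr::bind_rows(out, .id = "group")
}

#' Rarefaction curve for one sample
#'
#' Mean observed richness over `reps` seeded subsamples (without
#' replacement) at each requested depth. The Monte-Carlo mean converges to
#' the exact hypergeometric expectation
#' `E[S_d] = sum_i (1 - choose(T - t_i, d) / choose(T, d))`.
#'
#' @param x count vector for one sample.
#' @param depths subsampling depths (each <= `sum(x)`).
#' @param reps subsamples per depth.
#' @param seed optional integer seed.
#' @return Tibble with `depth` and `richness` (mean over reps).
#' @export
rarefaction_curve <- function(x, depths, reps = 100, seed = NULL) {
  total <- sum(x)
  if (any(depths < 1) || any(depths > total)) {
    abort("`depths` must lie in [1, sum(x)].")
  }
  pool <- rep(seq_along(x), times = x)
  with_seed_opt(seed, {
    rich <- vapply(depths, function(d) {
      if (d == total) return(sum(x > 0))
      mean(vapply(seq_len(reps), function(...) {
        length(unique(sample(pool, d)))
      }, numeric(1)))
    }, numeric(1))
    tibble(depth = as.integer(depths), richness = rich)
  })
}
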