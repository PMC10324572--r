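#' Checkerboard score (C-score)
#'
#' For every unordered pair of taxa (rows) i, j the number of checkerboard
#' units is `CU_ij = (R_i - S_ij)(R_j - S_ij)`, where `R` are row totals and
#' `S_ij` the number of samples where both taxa occur. The C-score is the
#' mean CU over all pairs; large values indicate species segregation.
#'
#' @param pam binary presence-absence matrix (taxa x samples), e.g. from
#'   [to_presence_absence()]; counts are binarised.
#' @return Non-negative scalar.
#' @export
c_score <- function(pam) {
  m <- binarize_pam(pam)
  if (nrow(m) < 2) abort("need at least 2 taxa (rows).")
  S <- tcrossprod(m)
  R <- rowSums(m)
  Ri <- matrix(R, nrow(m), nrow(m))  # CU_ij = (R_i - S_ij)(R_j - S_ij)
  CU <- (Ri - S) * (t(Ri) - S)
  mean(CU[upper.tri(CU)])
}

binarize_pam <- function(pam) {
  if (inherits(pam, "community_matrix") || is.data.frame(pam)) {
    pam <- to_presence_absence(pam)
  }
  m <- (as.matrix(pam) > 0) * 1L
  storage.mode(m) <- "integer"
  m
}

#' Sequential-swap randomization
#'
#' Randomises a binary matrix under fixed row and column totals by
#' repeatedly flipping random 2x2 checkerboard submatrices
#' (`[[1,0],[0,1]]` <-> `[[0,1],[1,0]]`). `n_steps` counts accepted swaps;
#' rejected proposals are free. A matrix with no checkerboard (equivalently
#' a zero C-score) cannot be swapped and is returned unchanged with a
#' warning.
#'
#' @inheritParams c_score
#' @param n_steps number of accepted swaps to perform.
#' @param seed optional integer seed.
#' @param max_tries proposal budget per accepted swap before giving up (safety valve).
#' @return Binary matrix with identical row and column totals.
#' @export
sequential_swap <- function(pam, n_steps, seed = NULL, max_tries = 1e7) {
  m <- binarize_pam(pam)
  if (nrow(m) < 2 || ncol(m) < 2 || c_score(m) == 0) {
    warn("matrix has no 2x2 checkerboard submatrix; returned unchanged.")
    return(m)
  }
  res <- with_seed_opt(seed,
    cpp_swap_chain(m, as.integer(n_steps), 0L, max_tries))
  out <- res$matrix
  dimnames(out) <- dimnames(m)
  out
}

#' C-score null-model test with standardized effect size
#'
#' Compares the observed C-score against a fixed-row, fixed-column null
#' distribution generated by the sequential-swap Markov chain: after
#' `burn_in` accepted swaps, the C-score is recorded after each of
#' `n_simulations` further accepted swaps. The standardized effect size is
#' `SES = (C_obs - mean(null)) / sd(null)` (sample sd). SES > 2 is read as
#' segregation, SES < -2 as aggregation, and |SES| <= 2 as consistent with
#' stochastic assembly.
#'
#' @inheritParams sequential_swap
#' @param n_simulations number of recorded null states (default 30000).
#' @param burn_in accepted swaps discarded before recording (default 1000).
#' @param ses_threshold |SES| cutoff for a deterministic verdict (default 2).
#' @return An object of class `null_model_result` with the observed score,
#'   null mean/sd, `ses`, tail probabilities `p_upper` / `p_lower`, the
#'   verdict, and the recorded null scores. Use [glance()] / [tidy()] /
#'   [autoplot()].
#' @export
null_model_test <- function(pam, n_simulations = 30000, burn_in = 1000,
                            seed = NULL, ses_threshold = 2, max_tries = 1e7) {
  m <- binarize_pam(pam)
  if (n_simulations < 100) abort("`n_simulations` must be >= 100.")
  obs <- c_score(m)
  if (obs == 0) abort("matrix has no checkerboard structure; null chain cannot move.")
  res <- with_seed_opt(seed,
    cpp_swap_chain(m, as.integer(burn_in), as.integer(n_simulations), max_tries))
  null_scores <- res$scores
  null_mean <- mean(null_scores)
  null_sd <- sd(null_scores)
  if (null_sd == 0) abort("degenerate null distribution (sd = 0); SES undefined.")
  ses <- (obs - null_mean) / null_sd
  verdict <- if (ses > ses_threshold) "segregation"
    else if (ses < -ses_threshold) "aggregation" else "stochastic"
  structure(
    list(c_score_obs = obs, null_mean = null_mean, null_sd = null_sd,
         ses = ses,
         p_upper = mean(null_scores >= obs),
         p_lower = mean(null_scores <= obs),
         n_simulations = n_simulations, burn_in = burn_in, seed = seed,
         ses_threshold = ses_threshold, verdict = verdict,
         null_scores = null_scores),
    class = "null_model_result"
  )
}

#' @export
print.null_model_result <- function(x, ...) {
  cat(sprintf(
    "C-score null model: obs = %.4f, null = %.4f (sd %.4f), SES = %.2f -> %s\n",
    x$c_score_obs, x$null_mean, x$null_sd, x$ses, x$verdict))
  invisible(x)
}

#' Tidiers for null-model results
#' @param x a `null_model_result`.
#' @param ... unused.
#' @return `glance()` returns a one-row summary tibble; `tidy()` the
#'   recorded null C-scores.
#' @export
glance.null_model_result <- function(x, ...) {
  tibble(c_score_obs = x$c_score_obs, null_mean = x$null_mean,
         null_sd = x$null_sd, ses = x$ses, p_upper = x$p_upper,
         p_lower = x$p_lower, n_simulations = x$n_simulations,
         verdict = x$verdict)
}

#' @rdname glance.null_model_result
#' @export
tidy.null_model_result <- function(x, ...) {
  tibble(draw = seq_along(x$null_scores), c_score = x$null_scores)
}

#' @rdname glance.null_model_result
#' @param object a `null_model_result`.
#' @export
autoplot.null_model_result <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$c_score)) +
    ggplot2::geom_histogram(bins = 50, fill = "grey70", colour = "grey40") +
    ggplot2::geom_vline(xintercept = object$c_score_obs, colour = "firebrick") +
    ggplot2::labs(x = "null C-score", y = "count",
                  title = sprintf("SES = %.2f (%s)", object$ses, object$verdict)) +
    ggplot2::theme_minimal()
}

#' Levins niche breadth
#'
#' For taxon j with across-sample usage proportions
#' `u_ij = count_ij / sum_i count_ij`, Levins breadth is
#' `B_j = 1 / sum_i u_ij^2` (the inverse Simpson concentration of its
#' abundance across samples, between 1 and the number of samples). The
#' community-level breadth `Bcom` is the mean of `B_j` over taxa with
#' positive totals; wider Bcom indicates a community of habitat
#' generalists.
#'
#' @param cm a [community_matrix()] (or coercible).
#' @return An object of class `niche_breadth` with `taxa` (tibble:
#'   `taxon_id`, `b`) and `bcom`. `tidy()` returns the per-taxon table,
#'   `glance()` a one-row summary.
#' @export
levins_breadth <- function(cm) {
  m <- as_counts_matrix(cm)
  totals <- rowSums(m)
  if (any(totals == 0)) {
    warn(sprintf("excluding %d taxa with zero total count.", sum(totals == 0)))
    m <- m[totals > 0, , drop = FALSE]
    totals <- totals[totals > 0]
  }
  if (nrow(m) == 0) abort("no taxa with positive counts.")
  u <- m / totals
  b <- 1 / rowSums(u^2)
  structure(
    list(taxa = tibble(taxon_id = rownames(m), b = unname(b)),
         bcom = mean(b), n_samples = ncol(m)),
    class = "niche_breadth"
  )
}

#' @export
print.niche_breadth <- function(x, ...) {
  cat(sprintf("Levins niche breadth: %d taxa, Bcom = %.3f (max possible %d)\n",
              nrow(x$taxa), x$bcom, x$n_samples))
  invisible(x)
}

#' @rdname levins_breadth
#' @param x a `niche_breadth` object.
#' @param ... unused.
#' @export
tidy.niche_breadth <- function(x, ...) x$taxa

#' @rdname levins_breadth
#' @export
glance.niche_breadth <- function(x, ...) {
  tibble(bcom = x$bcom, n_taxa = nrow(x$taxa), n_samples = x$n_samples)
}
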