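#' Occurrence frequency and mean relative abundance per taxon
#'
#' The two axes of the Sloan neutral-model fit: for each taxon, `p` is its
#' relative abundance averaged over all samples (zeros included) and `f` the
#' fraction of samples in which it is detected (count > 0).
#'
#' @param cm a [community_matrix()] (or coercible) with >= 2 samples,
#'   ideally rarefied to a common depth.
#' @return Tibble with `taxon_id`, `p`, `f`.
#' @export
occurrence_frequency <- function(cm) {
  m <- as_counts_matrix(cm)
  if (ncol(m) < 2) abort("need at least 2 samples.")
  if (all(m == 0)) abort("empty count table.")
  ra <- relative_abundance_values(m)
  tibble(taxon_id = rownames(m), p = unname(rowMeans(ra)),
         f = unname(rowMeans(m > 0)))
}

#' Sloan neutral-model predicted occurrence frequency
#'
#' Under the neutral model, a taxon with metacommunity relative abundance
#' `p` has local relative abundances that are approximately Beta-distributed
#' with shape parameters `Nm p` and `Nm (1 - p)`, where `Nm` is the product
#' of community size and immigration rate. The predicted occurrence
#' frequency is the probability that this Beta variable exceeds the
#' detection limit `d`, i.e. the upper tail `1 - pbeta(d, Nm p, Nm (1 - p))`.
#'
#' @param p mean relative abundance(s) in (0, 1).
#' @param nm composite dispersal parameter Nm > 0.
#' @param d detection limit in (0, 1) (typically 1/N, one read).
#' @return Predicted frequencies in `[0, 1]`, non-decreasing in `p`.
#' @export
predict_frequency <- function(p, nm, d) {
  if (any(p <= 0) || any(p >= 1)) abort("`p` must be in (0, 1).")
  if (nm <= 0) abort("`nm` must be > 0.")
  if (d <= 0 || d >= 1) abort("`d` must be in (0, 1).")
  pbeta(d, nm * p, nm * (1 - p), lower.tail = FALSE)
}

wilson_interval <- function(phat, n, level) {
  z <- qnorm(1 - (1 - level) / 2)
  denom <- 1 + z^2 / n
  centre <- (phat + z^2 / (2 * n)) / denom
  half <- z * sqrt(phat * (1 - phat) / n + z^2 / (4 * n^2)) / denom
  list(lower = pmax(0, centre - half), upper = pmin(1, centre + half))
}

#' Fit the Sloan neutral community model
#'
#' Fits the composite parameter `Nm` by nonlinear least squares between
#' observed occurrence frequencies and [predict_frequency()] over mean
#' relative abundance. Goodness of fit is the Ostman coefficient
#' `R^2 = 1 - SSres/SStot` about the mean observed frequency; it is 1 for a
#' perfect fit and can be <= 0 when the neutral expectation describes the
#' data worse than a constant. Each taxon is partitioned as `"above"`,
#' `"neutral"` or `"below"` according to whether its observed frequency
#' falls outside a Wilson binomial band (level `ci_level`, n = number of
#' samples) around its predicted frequency.
#'
#' The least-squares objective is minimised over `log(Nm)` on
#' `[1e-3 N, 10 N]` by a coarse log-spaced grid followed by
#' [stats::optimize()] refinement (tolerance 1e-8), which is deterministic
#' and robust for this one-dimensional problem.
#'
#' @section Detection limit:
#' A taxon at true relative abundance `x` in a sample of `N` reads is
#' detected with probability `1 - (1 - x)^N`, a smooth curve, not a step.
#' The beta-tail prediction approximates this kernel by a step at the
#' detection limit `d`. The default places the step at the kernel's median,
#' `d = 1 - 2^(-1/N)` (approximately `ln(2)/N`), the abundance at which a
#' taxon has a 50% chance of appearing among `N` reads; in simulations this
#' removes most of the upward bias in the fitted `m` that the conventional
#' one-read limit `d = 1/N` incurs. Set `detection_limit = 1/N` explicitly
#' to reproduce that convention.
#'
#' @param x a [community_matrix()] (or coercible), ideally rarefied; or a
#'   data frame with columns `p` and `f` (then `n_reads` and `n_samples`
#'   must be given).
#' @param ci_level prediction-band level (default 0.95).
#' @param ... passed between methods.
#' @return An object of class `ncm_fit` with components `m`, `nm`, `n_reads`
#'   (N), `detection_limit`, `r_squared`, `ci_level`, `n_samples` and a
#'   per-taxon tibble `taxa` (`taxon_id`, `p`, `f`, `f_pred`, `lower`,
#'   `upper`, `partition`). Use [tidy()], [glance()], [autoplot()].
#' @export
fit_ncm <- function(x, ...) UseMethod("fit_ncm")

#' @rdname fit_ncm
#' @export
fit_ncm.default <- function(x, ci_level = 0.95, detection_limit = NULL, ...) {
  m <- as_counts_matrix(x)
  depths <- colSums(m)
  if (length(unique(depths)) > 1) {
    warn("unequal sample depths; N set to the mean depth (consider `rarefy()`).")
  }
  N <- mean(depths)
  occ <- occurrence_frequency(m)
  fit_ncm(as.data.frame(occ), n_reads = N, n_samples = ncol(m),
          ci_level = ci_level, detection_limit = detection_limit)
}

#' @rdname fit_ncm
#' @param n_reads community size N (reads per sample).
#' @param n_samples number of samples the frequencies were computed from.
#' @param detection_limit detection limit `d`; default `1 - 2^(-1/N)`, the
#'   median of the read-sampling detection kernel (see Details). Use `1/N`
#'   for the one-read convention.
#' @export
fit_ncm.data.frame <- function(x, n_reads, n_samples, ci_level = 0.95,
                               detection_limit = NULL, ...) {
  stopifnot(all(c("p", "f") %in% names(x)))
  N <- n_reads
  d <- detection_limit %||% (1 - 2^(-1 / N))
  keep <- x$f > 0 & x$p > 0 & x$p < 1
  dropped <- sum(!keep)
  if (dropped > 0) {
    x <- x[keep, , drop = FALSE]
  }
  if (nrow(x) < 10) {
    warn(sprintf("only %d taxa with informative frequencies; fit may be unstable.",
                 nrow(x)))
  }
  if (nrow(x) < 2) abort("too few taxa to fit the neutral model.")
  sse <- function(log_nm) {
    sum((x$f - predict_frequency(x$p, exp(log_nm), d))^2)
  }
  lo <- log(1e-3 * N); hi <- log(10 * N)
  grid <- seq(lo, hi, length.out = 100)
  vals <- vapply(grid, sse, numeric(1))
  i <- which.min(vals)
  opt <- optimize(sse, c(grid[max(1, i - 1)], grid[min(length(grid), i + 1)]),
                  tol = 1e-8)
  nm <- exp(opt$minimum)
  f_pred <- predict_frequency(x$p, nm, d)
  ss_res <- sum((x$f - f_pred)^2)
  ss_tot <- sum((x$f - mean(x$f))^2)
  band <- wilson_interval(f_pred, n_samples, ci_level)
  partition <- dplyr::case_when(
    x$f > band$upper ~ "above",
    x$f < band$lower ~ "below",
    TRUE ~ "neutral"
  )
  taxa <- tibble(
    taxon_id = x$taxon_id %||% paste0("taxon_", seq_len(nrow(x))),
    p = x$p, f = x$f, f_pred = f_pred,
    lower = band$lower, upper = band$upper, partition = partition
  )
  structure(
    list(m = nm / N, nm = nm, n_reads = N, detection_limit = d,
         r_squared = 1 - ss_res / ss_tot, ci_level = ci_level,
         n_samples = n_samples, n_dropped = dropped, taxa = taxa,
         optim = opt),
    class = "ncm_fit"
  )
}

#' @export
print.ncm_fit <- function(x, ...) {
  cat(sprintf(
    "Sloan neutral community model fit\n  N = %.0f reads, Nm = %.1f, m = %.4f, R^2 = %.3f\n  %d taxa: %s\n",
    x$n_reads, x$nm, x$m, x$r_squared, nrow(x$taxa),
    paste(sprintf("%s %d", names(table(x$taxa$partition)),
                  as.integer(table(x$taxa$partition))), collapse = ", ")
  ))
  invisible(x)
}

#' Tidiers for neutral-model fits
#' @param x an `ncm_fit`.
#' @param ... unused.
#' @return `tidy()` returns the per-taxon tibble; `glance()` a one-row
#'   summary (`m`, `nm`, `n_reads`, `r_squared`, partition counts).
#' @export
tidy.ncm_fit <- function(x, ...) x$taxa

#' @rdname tidy.ncm_fit
#' @export
glance.ncm_fit <- function(x, ...) {
  ps <- partition_summary(x)
  counts <- setNames(ps$n_taxa, ps$partition)
  tibble(
    m = x$m, nm = x$nm, n_reads = x$n_reads, r_squared = x$r_squared,
    n_taxa = nrow(x$taxa),
    n_above = counts[["above"]] %||% 0L,
    n_neutral = counts[["neutral"]] %||% 0L,
    n_below = counts[["below"]] %||% 0L
  )
}

#' Partition counts of a neutral-model fit
#'
#' @param fit an `ncm_fit`.
#' @return Tibble with `partition` (above/neutral/below) and `n_taxa`;
#'   counts sum to the number of fitted taxa.
#' @export
partition_summary <- function(fit) {
  stopifnot(inherits(fit, "ncm_fit"))
  lv <- factor(fit$taxa$partition, levels = c("above", "neutral", "below"))
  tab <- table(lv)
  tibble(partition = names(tab), n_taxa = as.integer(tab))
}

#' @rdname tidy.ncm_fit
#' @param object an `ncm_fit`.
#' @export
autoplot.ncm_fit <- function(object, ...) {
  df <- object$taxa
  ord <- order(df$p)
  band <- df[ord, ]
  ggplot2::ggplot(df, ggplot2::aes(.data$p, .data$f)) +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$f_pred),
                       colour = "blue") +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$lower),
                       colour = "blue", linetype = "dashed") +
    ggplot2::geom_line(data = band, ggplot2::aes(y = .data$upper),
                       colour = "blue", linetype = "dashed") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$partition), alpha = 0.7) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_colour_manual(values = c(above = "darkgreen",
                                            neutral = "grey40",
                                            below = "firebrick")) +
    ggplot2::labs(
      x = "mean relative abundance (log scale)",
      y = "occurrence frequency",
      title = sprintf("Neutral model: m = %.3f, R² = %.3f",
                      object$m, object$r_squared)
    ) +
    ggplot2::theme_minimal()
}
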