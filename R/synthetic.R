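#' Simulate a skewed metacommunity abundance vector
#'
#' Draws a relative-abundance vector for `s_taxa` taxa from a Dirichlet
#' distribution whose concentration decays over ranked taxa
#' (`alpha_k = shape / k`), giving the long-tailed, log-series-like
#' rank-abundance curves typical of microbial surveys.
#'
#' @param s_taxa number of taxa (>= 1).
#' @param shape concentration scale; smaller values give steeper dominance.
#' @param seed optional integer seed.
#' @return Numeric vector of length `s_taxa`, non-negative, summing to 1,
#'   sorted in decreasing abundance.
#' @export
simulate_metacommunity <- function(s_taxa, shape = 2, seed = NULL) {
  if (length(s_taxa) != 1 || s_taxa < 1) abort("`s_taxa` must be a single integer >= 1.")
  if (s_taxa == 1) return(1)
  with_seed_opt(seed, {
    alpha <- shape / seq_len(s_taxa)
    g <- stats::rgamma(s_taxa, shape = alpha, rate = 1)
    if (all(g == 0)) g[1] <- 1
    sort(g / sum(g), decreasing = TRUE)
  })
}

#' Simulate neutral local communities
#'
#' Forward-simulates Moran-type neutral dynamics for independent local
#' communities of fixed size `n_individuals` coupled to a metacommunity `p`
#' by an immigration rate `m`: each death is replaced either by an immigrant
#' drawn from `p` or by the offspring of a uniformly chosen surviving local
#' individual. One generation is a full community turnover
#' (`n_individuals` death/replacement events).
#'
#' Under `convention = "per_event"` the immigrant probability per replacement
#' is exactly `m`. The chain's stationary taxon frequencies are then
#' beta-binomial with composite parameter `m (N - 1) / (1 - m)`, which only
#' approaches the `N m` of the Sloan occurrence-frequency model for small
#' `m`. Under `convention = "sloan"` (the default for parameter-recovery
#' studies) the per-event probability is set to `N m / (N - 1 + N m)` so that
#' the stationary composite parameter equals `N m` exactly and the nominal
#' `m` is the true Sloan immigration rate of the generated data. See the
#' methods vignette for the derivation.
#'
#' @param n_samples number of local communities.
#' @param n_individuals community size N (reads per sample).
#' @param m immigration rate in (0, 1].
#' @param metacommunity relative-abundance vector `p` (non-negative, sums
#'   to 1), e.g. from [simulate_metacommunity()].
#' @param burn_in_generations generations of burn-in (full turnovers).
#' @param convention `"sloan"` or `"per_event"`, see Details.
#' @param seed optional integer seed.
#' @return A [community_matrix()] with taxa `taxon_1..S` and samples
#'   `sample_1..n`; every column sums to `n_individuals`.
#' @export
simulate_neutral_communities <- function(n_samples, n_individuals, m,
                                         metacommunity,
                                         burn_in_generations = 50,
                                         convention = c("sloan", "per_event"),
                                         seed = NULL) {
  convention <- match.arg(convention)
  if (m <= 0 || m > 1) abort("`m` must be in (0, 1].")
  if (n_individuals < 1) abort("`n_individuals` must be >= 1.")
  p <- metacommunity
  if (any(p < 0) || abs(sum(p) - 1) > 1e-9) {
    abort("`metacommunity` must be non-negative and sum to 1.")
  }
  N <- as.integer(n_individuals)
  m_event <- switch(convention,
    per_event = m,
    sloan = if (m >= 1) 1 else (N * m) / (N - 1 + N * m)
  )
  counts <- with_seed_opt(seed,
    cpp_neutral_sim(p, as.integer(n_samples), N, m_event,
                    as.integer(burn_in_generations)))
  dimnames(counts) <- list(paste0("taxon_", seq_along(p)),
                           paste0("sample_", seq_len(n_samples)))
  community_matrix(counts)
}

#' Simulate niche-structured communities along a salinity-like gradient
#'
#' Each taxon has a Gaussian response to the gradient: the expected abundance
#' of taxon j in sample i is proportional to
#' `capacity_j * exp(-(gradient_i - optimum_j)^2 / (2 tolerance_j^2))`.
#' Reads are drawn multinomially per sample, so realised tables carry
#' sampling noise on top of the deterministic niche structure. With two
#' guilds of taxa whose optima sit at opposite ends of the gradient this
#' produces the segregated (checkerboarded) presence-absence structure that
#' deterministic, environmentally filtered assembly leaves behind.
#'
#' @param gradient numeric vector of gradient values (one per sample),
#'   interpreted as salinity in permille for the metadata.
#' @param optimum,tolerance,capacity per-taxon Gaussian response parameters;
#'   recycled to a common length. `tolerance` must be > 0.
#' @param reads_per_sample sequencing depth per sample (>= 1).
#' @param seed optional integer seed.
#' @return A list with elements `community` (a [community_matrix()]) and
#'   `metadata` (tibble with `sample_id`, `salinity`, `habitat`, `group`).
#' @export
simulate_niche_communities <- function(gradient, optimum, tolerance, capacity = 1,
                                       reads_per_sample = 1000, seed = NULL) {
  n <- length(gradient)
  s_taxa <- max(length(optimum), length(tolerance), length(capacity))
  optimum <- rep_len(optimum, s_taxa)
  tolerance <- rep_len(tolerance, s_taxa)
  capacity <- rep_len(capacity, s_taxa)
  if (any(tolerance <= 0)) abort("`tolerance` must be > 0.")
  if (reads_per_sample < 1) abort("`reads_per_sample` must be >= 1.")
  expected <- vapply(gradient, function(g) {
    capacity * exp(-(g - optimum)^2 / (2 * tolerance^2))
  }, numeric(s_taxa))
  expected <- matrix(expected, nrow = s_taxa)
  counts <- with_seed_opt(seed, {
    vapply(seq_len(n), function(i) {
      w <- expected[, i]
      if (sum(w) <= 0) w <- rep(1, s_taxa)  # degenerate sample: uniform
      as.integer(stats::rmultinom(1, reads_per_sample, w))
    }, integer(s_taxa))
  })
  counts <- matrix(counts, nrow = s_taxa)
  dimnames(counts) <- list(paste0("taxon_", seq_len(s_taxa)),
                           paste0("sample_", seq_len(n)))
  md <- tibble(
    sample_id = colnames(counts),
    salinity = as.numeric(gradient),
    habitat = "water",
    group = ifelse(gradient <= stats::median(gradient),
                   "low-salinity-water", "high-salinity-water")
  )
  list(community = community_matrix(counts), metadata = md)
}

# nutrient ranges (uM) observed in the two salinity regimes
.low_salinity_ranges <- list(
  salinity = c(0, 14.58), nitrate = c(67.47, 494.4),
  silicate = c(1.13, 157.64), phosphate = c(4.155, 26.885)
)
.high_salinity_ranges <- list(
  salinity = c(21.08, 33), nitrate = c(0.139, 149.223),
  silicate = c(0.22, 65.031), phosphate = c(0.016, 6.481)
)

#' Generate grouped sample metadata
#'
#' Draws synthetic metadata for the four habitat-by-salinity groups used
#' throughout the package: low-salinity samples with salinity uniform on
#' [0, 14.58) permille and nutrients uniform within the wide low-salinity
#' ranges (nitrate 67.47-494.4, silicate 1.13-157.64, phosphate
#' 4.155-26.885 uM), and high-salinity samples with salinity above 21.08
#' permille and nutrients within the narrower high-salinity ranges
#' (nitrate 0.139-149.223, silicate 0.22-65.031, phosphate 0.016-6.481 uM).
#'
#' @param n_per_group samples per group (>= 1).
#' @param habitats habitats to generate (default water and sediment, giving
#'   four groups).
#' @param seed optional integer seed.
#' @return A metadata tibble (`sample_id`, `salinity`, `nitrate`, `silicate`,
#'   `phosphate`, `habitat`, `group`).
#' @export
generate_group_metadata <- function(n_per_group, habitats = c("water", "sediment"),
                                    seed = NULL) {
  if (n_per_group < 1) abort("`n_per_group` must be >= 1.")
  with_seed_opt(seed, {
    rows <- list()
    for (hab in habitats) {
      for (level in c("low", "high")) {
        rng <- if (level == "low") .low_salinity_ranges else .high_salinity_ranges
        draw <- function(v) stats::runif(n_per_group, rng[[v]][1], rng[[v]][2])
        rows[[paste(level, hab)]] <- tibble(
          sample_id = paste0(level, "_", hab, "_", seq_len(n_per_group)),
          salinity = draw("salinity"),
          nitrate = draw("nitrate"),
          silicate = draw("silicate"),
          phosphate = draw("phosphate"),
          habitat = hab,
          group = paste0(level, "-salinity-", hab)
        )
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Generate a random binary presence-absence matrix
#'
#' Entries are iid Bernoulli(`fill`). With `reject_empty = TRUE` (default)
#' matrices containing an all-zero or all-one row or column are redrawn, so
#' every taxon and sample is informative for null-model chains.
#'
#' @param n_rows,n_cols dimensions.
#' @param fill occupancy probability in (0, 1].
#' @param reject_empty redraw until no all-zero/all-one row or column.
#' @param seed optional integer seed.
#' @return Binary integer matrix with taxon/sample dimnames.
#' @export
generate_random_binary_matrix <- function(n_rows, n_cols, fill = 0.5,
                                          reject_empty = TRUE, seed = NULL) {
  if (fill <= 0 || fill > 1) abort("`fill` must be in (0, 1].")
  with_seed_opt(seed, {
    repeat {
      m <- matrix(as.integer(stats::runif(n_rows * n_cols) < fill), n_rows, n_cols)
      if (!reject_empty || fill == 1) break
      rs <- rowSums(m); cs <- colSums(m)
      if (all(rs > 0) && all(rs < n_cols) && all(cs > 0) && all(cs < n_rows)) break
    }
    dimnames(m) <- list(paste0("taxon_", seq_len(n_rows)),
                        paste0("sample_", seq_len(n_cols)))
    m
  })
}
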