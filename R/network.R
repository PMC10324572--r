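#' Significant Spearman co-occurrence edges
#'
#' Computes Spearman's rank correlation (average ranks for ties) between all
#' taxon pairs across samples, with a two-sided p-value from the
#' t-approximation, and keeps pairs with `|r| > r_min` and `p < p_max`.
#' Constant taxa (no rank variation) have undefined correlations and are
#' skipped with a warning. No multiple-testing correction is applied by
#' default, matching the conventional |r| > 0.6, p < 0.05 rule;
#' `p_adjust = "BH"` switches the threshold to Benjamini-Hochberg adjusted
#' p-values.
#'
#' @param ram relative-abundance (or count) matrix, taxa x samples; a
#'   [community_matrix()] is converted to relative abundances. Apply
#'   [filter_taxa()] beforehand to reduce to prevalent, non-rare taxa.
#' @param r_min correlation magnitude threshold (strict, default 0.6).
#' @param p_max p-value threshold (strict, default 0.05).
#' @param p_adjust `"none"` (default) or `"BH"`.
#' @return Tibble with `taxon_a`, `taxon_b`, `r`, `p_value`, `sign`.
#' @export
spearman_edges <- function(ram, r_min = 0.6, p_max = 0.05,
                           p_adjust = c("none", "BH")) {
  p_adjust <- match.arg(p_adjust)
  if (inherits(ram, "community_matrix") || is.data.frame(ram)) {
    ram <- to_relative_abundance(ram)
  }
  n <- ncol(ram)
  if (n < 4) abort("need at least 4 samples for edge screening.")
  constant <- apply(ram, 1, function(v) length(unique(v)) == 1)
  if (any(constant)) {
    warn(sprintf("skipping %d constant taxa (undefined correlation).",
                 sum(constant)))
    ram <- ram[!constant, , drop = FALSE]
  }
  if (nrow(ram) < 2) return(tibble(taxon_a = character(), taxon_b = character(),
                                   r = numeric(), p_value = numeric(),
                                   sign = character()))
  r <- cor(t(ram), method = "spearman")
  idx <- which(upper.tri(r), arr.ind = TRUE)
  rv <- r[idx]
  rv_c <- pmin(pmax(rv, -1 + 1e-15), 1 - 1e-15)
  tstat <- rv_c * sqrt((n - 2) / (1 - rv_c^2))
  pv <- 2 * pt(-abs(tstat), df = n - 2)
  pv_eff <- if (p_adjust == "BH") stats::p.adjust(pv, "BH") else pv
  keep <- abs(rv) > r_min & pv_eff < p_max
  tibble(
    taxon_a = rownames(ram)[idx[keep, 1]],
    taxon_b = rownames(ram)[idx[keep, 2]],
    r = rv[keep],
    p_value = pv[keep],
    sign = ifelse(rv[keep] >= 0, "positive", "negative")
  )
}

#' Build a co-occurrence network from an edge list
#'
#' @param edges tibble from [spearman_edges()] (columns `taxon_a`,
#'   `taxon_b`, optionally `r`, `p_value`, `sign`).
#' @param taxa optional character vector of node ids to include even when
#'   isolated (default: only taxa incident to an edge).
#' @return A simple undirected [igraph::graph] with edge attributes carried
#'   over.
#' @export
build_network <- function(edges, taxa = NULL) {
  if (nrow(edges) == 0) {
    return(igraph::make_empty_graph(n = length(taxa %||% character()),
                                    directed = FALSE))
  }
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges), directed = FALSE,
    vertices = if (is.null(taxa)) NULL else unique(c(taxa, edges$taxon_a, edges$taxon_b))
  )
  igraph::simplify(g, edge.attr.comb = "first")
}

local_clustering <- function(g) {
  cc <- igraph::transitivity(g, type = "localundirected", isolates = "zero")
  cc[is.na(cc)] <- 0  # degree-1 nodes
  cc
}

#' Network topology summary
#'
#' Density `2E / V(V-1)`, diameter and average path length over reachable
#' pairs (component-wise, weighted by the number of reachable pairs),
#' average local clustering coefficient (isolates and degree-1 nodes
#' contribute 0), modularity of the greedy module partition, and the
#' fraction of positive edges (when the graph carries a `sign` edge
#' attribute).
#'
#' @param net an [igraph::graph], e.g. from [build_network()].
#' @return One-row tibble: `n_nodes`, `n_edges`, `positive_edge_fraction`,
#'   `density`, `diameter`, `avg_path_length`, `avg_clustering`,
#'   `modularity`, `n_modules`.
#' @export
topology <- function(net) {
  V <- igraph::vcount(net)
  if (V == 0) abort("empty network.")
  E <- igraph::ecount(net)
  sign_attr <- igraph::edge_attr(net, "sign")
  pos_frac <- if (!is.null(sign_attr) && E > 0) mean(sign_attr == "positive") else NA_real_
  if (V == 1) {
    return(tibble(n_nodes = 1L, n_edges = 0L, positive_edge_fraction = pos_frac,
                  density = NA_real_, diameter = NA_real_,
                  avg_path_length = NA_real_, avg_clustering = 0,
                  modularity = NA_real_, n_modules = 1L))
  }
  mods <- detect_modules(net)
  tibble(
    n_nodes = V, n_edges = E,
    positive_edge_fraction = pos_frac,
    density = 2 * E / (V * (V - 1)),
    diameter = if (E == 0) NA_real_ else igraph::diameter(net, unconnected = TRUE),
    avg_path_length = if (E == 0) NA_real_ else
      igraph::mean_distance(net, unconnected = TRUE),
    avg_clustering = mean(local_clustering(net)),
    modularity = attr(mods, "modularity"),
    n_modules = length(unique(mods$module))
  )
}

#' Detect network modules
#'
#' Greedy modularity maximisation ([igraph::cluster_fast_greedy()], which is
#' deterministic), with modules relabelled 1, 2, ... by decreasing size.
#'
#' @param net an [igraph::graph].
#' @param seed kept for interface stability; the greedy algorithm is
#'   deterministic, so it is unused.
#' @return Tibble with `node` and `module`; attribute `"modularity"` holds
#'   the partition's modularity Q.
#' @export
detect_modules <- function(net, seed = NULL) {
  V <- igraph::vcount(net)
  if (V == 0) abort("empty network.")
  nodes <- igraph::V(net)$name %||% as.character(seq_len(V))
  if (igraph::ecount(net) == 0) {
    out <- tibble(node = nodes, module = seq_len(V))
    attr(out, "modularity") <- NA_real_
    return(out)
  }
  comm <- igraph::cluster_fast_greedy(net)
  memb <- igraph::membership(comm)
  sizes <- sort(table(memb), decreasing = TRUE)
  relabel <- setNames(seq_along(sizes), names(sizes))
  out <- tibble(node = nodes, module = as.integer(relabel[as.character(memb)]))
  attr(out, "modularity") <- unname(igraph::modularity(net, memb))
  out
}

#' Fraction of nodes covered by the largest modules
#'
#' @param modules tibble from [detect_modules()].
#' @param k number of largest modules (default 8).
#' @return Fraction in `[0, 1]`.
#' @export
module_coverage <- function(modules, k = 8) {
  sizes <- sort(table(modules$module), decreasing = TRUE)
  sum(head(sizes, k)) / nrow(modules)
}

#' Erdos-Renyi ensemble comparison
#'
#' Draws `n_random` G(n, m) graphs with exactly the observed node and edge
#' counts, computes average clustering, average path length and greedy
#' modularity for each, and reports ensemble means/sds together with the
#' real network's z-scores. Real networks whose clustering and modularity
#' exceed the random expectation while path lengths stay comparable show
#' the "small-world", modular signature.
#'
#' @param net an [igraph::graph] with >= 2 nodes.
#' @param n_random ensemble size (default 1000).
#' @param seed optional integer seed.
#' @return An object of class `er_ensemble`: list with `ensemble` (tibble of
#'   per-graph metrics), `observed`, `summary` (tibble with metric, observed,
#'   null mean/sd, z).
#' @export
er_ensemble <- function(net, n_random = 1000, seed = NULL) {
  V <- igraph::vcount(net)
  E <- igraph::ecount(net)
  if (V < 2) abort("need at least 2 nodes.")
  if (E > V * (V - 1) / 2) abort("edge count exceeds the simple-graph maximum.")
  metrics <- function(g) {
    c(clustering = mean(local_clustering(g)),
      path_length = if (igraph::ecount(g) == 0) NA_real_ else
        igraph::mean_distance(g, unconnected = TRUE),
      modularity = if (igraph::ecount(g) == 0) NA_real_ else
        igraph::modularity(g, igraph::membership(igraph::cluster_fast_greedy(g))))
  }
  ens <- with_seed_opt(seed, {
    t(vapply(seq_len(n_random), function(...) {
      metrics(igraph::sample_gnm(V, E))
    }, numeric(3)))
  })
  ens <- as_tibble(as.data.frame(ens))
  obs <- metrics(net)
  mu <- vapply(ens, mean, numeric(1), na.rm = TRUE)
  sg <- vapply(ens, sd, numeric(1), na.rm = TRUE)
  structure(
    list(ensemble = ens, observed = obs,
         summary = tibble(
           metric = names(obs), observed = unname(obs),
           null_mean = unname(mu), null_sd = unname(sg),
           z = unname(ifelse(sg > 0, (obs - mu) / sg,
                             ifelse(obs == mu, 0, NA_real_)))
         ),
         n_random = n_random),
    class = "er_ensemble"
  )
}

#' @export
print.er_ensemble <- function(x, ...) {
  cat(sprintf("Erdos-Renyi ensemble (%d graphs):\n", x$n_random))
  print(as.data.frame(x$summary), row.names = FALSE)
  invisible(x)
}

#' @rdname er_ensemble
#' @param x an `er_ensemble`.
#' @param ... unused.
#' @export
glance.er_ensemble <- function(x, ...) x$summary

#' Degree-distribution model comparison
#'
#' Fits a power law `p(k) ~ k^-alpha` to the degree distribution by least
#' squares on log-log frequencies (k >= 1), and a Poisson distribution by
#' maximum likelihood (lambda = mean degree). Each model's R-squared is
#' computed against the observed degree proportions on the linear scale, and
#' the better-fitting family is reported. Scale-free co-occurrence networks
#' prefer the power law; G(n, m) random graphs the Poisson.
#'
#' @param net an [igraph::graph] with >= 10 nodes.
#' @return One-row tibble: `alpha`, `r_squared_power_law`, `lambda`,
#'   `r_squared_poisson`, `preferred`, `degenerate`.
#' @export
degree_distribution_fit <- function(net) {
  deg <- igraph::degree(net)
  if (length(deg) < 10) abort("need at least 10 nodes.")
  if (length(unique(deg)) == 1) {
    return(tibble(alpha = NA_real_, r_squared_power_law = NA_real_,
                  lambda = mean(deg), r_squared_poisson = NA_real_,
                  preferred = NA_character_, degenerate = TRUE))
  }
  tab <- table(deg[deg >= 1])
  k <- as.numeric(names(tab))
  prop <- as.numeric(tab) / length(deg)
  # power law: least squares on log-log observed frequencies
  fit <- stats::lm(log(prop) ~ log(k))
  alpha <- -unname(stats::coef(fit)[2])
  pred_pl <- exp(stats::fitted(fit))
  lambda <- mean(deg)
  pred_pois <- dpois(k, lambda)
  r2 <- function(pred) 1 - sum((prop - pred)^2) / sum((prop - mean(prop))^2)
  r2_pl <- r2(pred_pl)
  r2_pois <- r2(pred_pois)
  tibble(alpha = alpha, r_squared_power_law = r2_pl,
         lambda = lambda, r_squared_poisson = r2_pois,
         preferred = if (r2_pl >= r2_pois) "power_law" else "poisson",
         degenerate = FALSE)
}

#' Natural connectivity
#'
#' The spectral robustness measure
#' `ln((1/V) * sum_i exp(lambda_i))` over the adjacency eigenvalues
#' `lambda_i`, computed with an overflow-safe log-sum-exp. A single node
#' gives 0; the empty graph is 0 by convention.
#'
#' @param net an [igraph::graph] or a symmetric adjacency matrix.
#' @return Scalar natural connectivity.
#' @export
natural_connectivity <- function(net) {
  A <- if (inherits(net, "igraph")) {
    as.matrix(igraph::as_adjacency_matrix(net, sparse = FALSE))
  } else as.matrix(net)
  V <- nrow(A)
  if (V == 0) return(0)
  lambda <- eigen(A, symmetric = TRUE, only.values = TRUE)$values
  mx <- max(lambda)
  mx + log(sum(exp(lambda - mx))) - log(V)
}

#' Natural-connectivity robustness curve
#'
#' For each removal fraction f, deletes `floor(f * V)` uniformly random
#' nodes, computes the natural connectivity of the induced subgraph
#' (surviving isolates retained), and averages over `reps` repetitions.
#' The curve starts at the intact-network value at f = 0 (computed exactly,
#' no sampling).
#'
#' @param net an [igraph::graph].
#' @param removal_fractions strictly increasing grid in `[0, 1]` (default
#'   0 to 0.8 by 0.05).
#' @param reps random removals per fraction (default 100).
#' @param seed optional integer seed.
#' @return An object of class `robustness_curve`: tibble with `fraction`,
#'   `natural_connectivity`, plus attributes `reps`, `seed`.
#' @export
robustness_curve <- function(net, removal_fractions = seq(0, 0.8, by = 0.05),
                             reps = 100, seed = NULL) {
  V <- igraph::vcount(net)
  if (V == 0) abort("empty network.")
  if (is.unsorted(removal_fractions, strictly = TRUE)) {
    abort("`removal_fractions` must be strictly increasing.")
  }
  nc <- with_seed_opt(seed, {
    vapply(removal_fractions, function(f) {
      n_rm <- floor(f * V)
      if (n_rm == 0) return(natural_connectivity(net))
      if (n_rm >= V) return(0)
      mean(vapply(seq_len(reps), function(...) {
        keep <- sample.int(V, V - n_rm)
        natural_connectivity(igraph::induced_subgraph(net, keep))
      }, numeric(1)))
    }, numeric(1))
  })
  out <- tibble(fraction = removal_fractions, natural_connectivity = nc)
  class(out) <- c("robustness_curve", class(out))
  attr(out, "reps") <- reps
  attr(out, "seed") <- seed
  out
}

#' @rdname robustness_curve
#' @param object a `robustness_curve`.
#' @param ... unused.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$fraction, .data$natural_connectivity)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = "fraction of nodes removed", y = "natural connectivity") +
    ggplot2::theme_minimal()
}

#' Degree-centrality hub ranking per module
#'
#' @param net an [igraph::graph].
#' @param modules optional tibble from [detect_modules()]; computed if
#'   missing.
#' @param top_k hubs to flag per module (default 3).
#' @return Tibble with `node`, `module`, `degree`, `centrality`
#'   (degree / (V - 1)), `rank_in_module`, `is_hub`.
#' @export
hub_scores <- function(net, modules = NULL, top_k = 3) {
  if (is.null(modules)) modules <- detect_modules(net)
  V <- igraph::vcount(net)
  deg <- igraph::degree(net)
  nodes <- igraph::V(net)$name %||% as.character(seq_len(V))
  tibble(node = nodes, degree = as.integer(deg),
         centrality = if (V > 1) unname(deg) / (V - 1) else 0) |>
    dplyr::left_join(modules, by = "node") |>
    dplyr::group_by(.data$module) |>
    dplyr::arrange(dplyr::desc(.data$degree), .data$node, .by_group = TRUE) |>
    dplyr::mutate(rank_in_module = dplyr::row_number(),
                  is_hub = .data$rank_in_module <= top_k) |>
    dplyr::ungroup()
}
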