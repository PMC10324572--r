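test_that("Spearman edge screening matches a brute-force rank oracle", {
  ram <- withr::with_seed(1, {
    m <- matrix(rpois(12 * 10, 6), 12, 10,
                dimnames = list(paste0("t", 1:12), paste0("s", 1:10)))
    sweep(m, 2, colSums(m), "/")
  })
  edges <- spearman_edges(ram, r_min = 0.6, p_max = 0.05)
  # every pair re-screened from first principles
  expected <- list()
  for (i in 1:11) for (j in (i + 1):12) {
    o <- spearman_brute(ram[i, ], ram[j, ])
    if (abs(o$r) > 0.6 && o$p < 0.05) {
      expected[[length(expected) + 1]] <-
        data.frame(a = rownames(ram)[i], b = rownames(ram)[j], r = o$r)
    }
  }
  expected <- do.call(rbind, expected)
  if (is.null(expected)) {
    expect_equal(nrow(edges), 0)
  } else {
    expect_equal(nrow(edges), nrow(expected))
    key <- function(a, b) paste(pmin(a, b), pmax(a, b))
    expect_setequal(key(edges$taxon_a, edges$taxon_b), key(expected$a, expected$b))
    expect_equal(sort(edges$r), sort(expected$r), tolerance = 1e-12)
  }
})

test_that("perfect monotone pairs are kept with the right sign; constant taxa skipped", {
  base <- c(1, 2, 3, 4, 5, 6)
  ram <- rbind(up = base, up2 = base * 2, down = rev(base), flat = rep(1, 6))
  colnames(ram) <- paste0("s", 1:6)
  expect_warning(edges <- spearman_edges(ram), "constant")
  key <- paste(edges$taxon_a, edges$taxon_b)
  expect_equal(edges$r[key == "up up2"], 1)
  expect_equal(edges$sign[key == "up down"], "negative")
  expect_equal(edges$r[key == "up down"], -1)
  expect_error(spearman_edges(ram[, 1:3]), "4 samples")
})

test_that("network construction gives a simple graph with verifiable degrees", {
  empty <- build_network(tibble::tibble(taxon_a = character(), taxon_b = character()))
  expect_equal(igraph::vcount(empty), 0)
  tri <- build_network(tibble::tibble(
    taxon_a = c("a", "b", "c"), taxon_b = c("b", "c", "a"),
    r = c(0.9, 0.8, -0.7), p_value = c(0.01, 0.01, 0.01),
    sign = c("positive", "positive", "negative")))
  expect_equal(igraph::vcount(tri), 3)
  expect_equal(topology(tri)$density, 1)
  expect_equal(topology(tri)$positive_edge_fraction, 2 / 3)
  # degree recount oracle on a random edge set
  edges <- withr::with_seed(2, {
    pairs <- t(combn(paste0("n", 1:8), 2))
    keep <- sample(nrow(pairs), 12)
    tibble::tibble(taxon_a = pairs[keep, 1], taxon_b = pairs[keep, 2])
  })
  g <- build_network(edges)
  deg <- igraph::degree(g)
  manual <- table(c(edges$taxon_a, edges$taxon_b))
  expect_equal(unname(deg[names(manual)]), as.integer(manual))
})

test_that("topology metrics match closed forms on K5, a path, and a star", {
  k5 <- igraph::make_full_graph(5)
  t5 <- topology(k5)
  expect_equal(t5$density, 1)
  expect_equal(t5$avg_clustering, 1)
  expect_equal(t5$avg_path_length, 1)
  expect_equal(t5$diameter, 1)

  path <- igraph::make_graph(~ A - B, B - C)
  tp <- topology(path)
  expect_equal(tp$avg_path_length, 4 / 3)
  expect_equal(tp$diameter, 2)

  star <- igraph::make_star(6, mode = "undirected")
  cc <- igraph::transitivity(star, type = "localundirected", isolates = "zero")
  expect_true(all(cc == 0))
  expect_equal(topology(star)$avg_clustering, 0)
})

test_that("module detection recovers planted cliques and reports true modularity", {
  g <- igraph::disjoint_union(igraph::make_full_graph(5), igraph::make_full_graph(5))
  g <- igraph::add_edges(g, c(1, 6))
  igraph::V(g)$name <- paste0("v", 1:10)
  mods <- detect_modules(g)
  expect_equal(sort(unique(mods$module)), c(1, 2))
  expect_equal(length(unique(mods$module[1:5])), 1)
  expect_equal(length(unique(mods$module[6:10])), 1)
  expect_equal(nrow(mods), 10)
  # modularity equals the direct formula evaluation on the returned partition
  q_direct <- modularity_brute(g, mods$module)
  expect_equal(attr(mods, "modularity"), q_direct, tolerance = 1e-12)
  expect_equal(module_coverage(mods, 1), 0.5)
  expect_equal(module_coverage(mods, 8), 1)
})

test_that("G(n,m) ensembles have exact edge counts and flag planted structure", {
  g <- igraph::disjoint_union(igraph::make_full_graph(6), igraph::make_full_graph(6))
  g <- igraph::add_edges(g, c(1, 7))
  ens <- er_ensemble(g, n_random = 60, seed = 5)
  expect_true(all(withr::with_seed(5, vapply(1:60, function(...) {
    igraph::ecount(igraph::sample_gnm(igraph::vcount(g), igraph::ecount(g)))
  }, numeric(1))) == igraph::ecount(g)))
  sm <- ens$summary
  expect_gt(sm$observed[sm$metric == "clustering"],
            sm$null_mean[sm$metric == "clustering"])
  expect_gt(sm$observed[sm$metric == "modularity"],
            sm$null_mean[sm$metric == "modularity"])
  # forced graph: K5 ensemble is always K5, z-scores 0
  k5 <- igraph::make_full_graph(5)
  ek <- er_ensemble(k5, n_random = 20, seed = 1)
  expect_true(all(ek$summary$z == 0))
  expect_error(er_ensemble(igraph::make_empty_graph(1, directed = FALSE)), "2 nodes")
})

test_that("degree-distribution comparison separates scale-free from random graphs", {
  pl_wins <- pois_wins <- 0
  for (s in 1:10) {
    ba <- withr::with_seed(s, igraph::sample_pa(100, m = 2, directed = FALSE))
    er <- withr::with_seed(s, igraph::sample_gnm(100, 200))
    fb <- degree_distribution_fit(ba)
    fe <- degree_distribution_fit(er)
    expect_gt(fb$alpha, 0)
    pl_wins <- pl_wins + (fb$preferred == "power_law")
    pois_wins <- pois_wins + (fe$preferred == "poisson")
  }
  expect_gte(pl_wins, 8)
  expect_gte(pois_wins, 6)  # majority of seeds
  ring <- igraph::make_ring(12)
  expect_true(degree_distribution_fit(ring)$degenerate)
})

test_that("natural connectivity matches eigenvalue closed forms", {
  expect_equal(natural_connectivity(igraph::make_empty_graph(1, directed = FALSE)), 0)
  k3 <- igraph::make_full_graph(3)
  expect_equal(natural_connectivity(k3), log((exp(2) + 2 * exp(-1)) / 3),
               tolerance = 1e-12)
  for (n in 2:20) {
    kn <- igraph::make_full_graph(n)
    closed <- log((exp(n - 1) + (n - 1) * exp(-1)) / n)
    expect_lt(abs(natural_connectivity(kn) - closed), 1e-9)
  }
  # accepts a plain adjacency matrix too
  A <- as.matrix(igraph::as_adjacency_matrix(k3))
  expect_equal(natural_connectivity(A), natural_connectivity(k3))
})

test_that("robustness curves start at the intact value and order by density", {
  k10 <- igraph::make_full_graph(10)
  rc <- robustness_curve(k10, removal_fractions = seq(0, 0.8, 0.2), reps = 10, seed = 1)
  expect_equal(rc$natural_connectivity[rc$fraction == 0], natural_connectivity(k10))
  expect_true(all(diff(rc$natural_connectivity) <= 1e-9))  # non-increasing for K_n
  # denser network dominates at every fraction
  sparse <- igraph::sample_gnm(10, 12)
  rc_sparse <- robustness_curve(sparse, seq(0, 0.8, 0.2), reps = 30, seed = 2)
  expect_true(all(rc$natural_connectivity >= rc_sparse$natural_connectivity))
  expect_error(robustness_curve(k10, c(0.4, 0.2)), "increasing")
})

test_that("hub scores rank by degree within modules", {
  star <- igraph::make_star(7, mode = "undirected")
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:6))
  hs <- hub_scores(star)
  expect_equal(hs$node[hs$rank_in_module == 1][1], "hub")
  expect_true(all(hs$centrality >= 0 & hs$centrality <= 1))
  expect_equal(hs$centrality[hs$node == "hub"], 1)
  # top-1 per module equals argmax of independently recomputed degrees
  g <- igraph::disjoint_union(igraph::make_star(5, mode = "undirected"),
                              igraph::make_full_graph(4))
  igraph::V(g)$name <- paste0("n", 1:9)
  mods <- detect_modules(g)
  hs2 <- hub_scores(g, mods)
  deg <- igraph::degree(g)
  for (mod in unique(hs2$module)) {
    nodes <- mods$node[mods$module == mod]
    top <- hs2$node[hs2$module == mod & hs2$rank_in_module == 1]
    expect_equal(unname(deg[top]), max(deg[nodes]))
  }
})
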