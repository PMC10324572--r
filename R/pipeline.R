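#' Default run configuration
#'
#' Returns the full configuration list for [run_full_analysis()] with the
#' package defaults: rarefaction depth 1732 reads, null model with 30,000
#' recorded swap states after 1,000 burn-in swaps, network pre-filter
#' (prevalence > 2 samples, mean relative abundance > 0.2%), edge thresholds
#' |r| > 0.6 and p < 0.05, 1,000-graph random ensembles, and a 95% neutral
#' prediction band. Values supplied in `...` (or loaded from YAML via
#' [read_run_config()]) override the defaults.
#'
#' @param ... named overrides of any default.
#' @return A named list of class `run_config`.
#' @export
run_config <- function(...) {
  cfg <- list(
    counts = NULL, metadata = NULL,       # file paths or in-memory objects
    simulate = NULL,                      # optional simulator spec (list)
    orientation = "taxa_rows",
    rarefaction_depth = 1732,
    group_column = "group",
    ncm_ci_level = 0.95,
    null_n_simulations = 30000,
    null_burn_in = 1000,
    network_prevalence = 2,
    network_abundance = 0.002,
    network_r_min = 0.6,
    network_p_max = 0.05,
    network_n_random = 1000,
    robustness_fractions = seq(0, 0.8, by = 0.05),
    robustness_reps = 100,
    seed = 1,
    outdir = NULL
  )
  over <- list(...)
  if (length(over) == 1 && is.list(over[[1]]) && is.null(names(over))) over <- over[[1]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) abort(sprintf("unknown config field(s): %s",
                                     paste(unknown, collapse = ", ")))
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param path YAML file of overrides.
#' @export
read_run_config <- function(path) {
  run_config(yaml::read_yaml(path))
}

resolve_inputs <- function(cfg) {
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    seed <- cfg$seed
    md <- generate_group_metadata(sim$n_per_group %||% 10,
                                  habitats = sim$habitats %||% "water",
                                  seed = seed)
    s_taxa <- sim$s_taxa %||% 200
    kind <- sim$kind %||% "neutral"
    if (kind == "neutral") {
      p <- simulate_metacommunity(s_taxa, seed = seed + 1)
      cm <- simulate_neutral_communities(
        n_samples = nrow(md),
        n_individuals = sim$n_individuals %||% cfg$rarefaction_depth,
        m = sim$m %||% 0.3, metacommunity = p,
        burn_in_generations = sim$burn_in_generations %||% 50,
        seed = seed + 2)
    } else if (kind == "niche") {
      half <- floor(s_taxa / 2)
      sim_out <- simulate_niche_communities(
        gradient = md$salinity,
        optimum = c(rep(sim$optimum_low %||% 5, half),
                    rep(sim$optimum_high %||% 28, s_taxa - half)),
        tolerance = sim$tolerance %||% 5,
        capacity = simulate_metacommunity(s_taxa, seed = seed + 1),
        reads_per_sample = sim$n_individuals %||% cfg$rarefaction_depth,
        seed = seed + 2)
      cm <- sim_out$community
    } else abort(sprintf("unknown simulator kind '%s'.", kind))
    colnames(cm$counts) <- md$sample_id
    return(list(cm = cm, md = md))
  }
  cm <- if (is.character(cfg$counts)) {
    read_counts_table(cfg$counts, orientation = cfg$orientation)
  } else as_community_matrix(cfg$counts)
  md <- if (is.character(cfg$metadata)) {
    read_sample_metadata(cfg$metadata)
  } else validate_sample_metadata(cfg$metadata)
  list(cm = cm, md = md)
}

analyse_group <- function(cm_g, cfg, seed) {
  res <- list()
  res$alpha <- alpha_diversity(cm_g)
  res$ncm <- tryCatch(glance(fit_ncm(cm_g, ci_level = cfg$ncm_ci_level)),
                      error = function(e) tibble(error = conditionMessage(e)))
  res$null_model <- tryCatch(
    glance(null_model_test(cm_g, n_simulations = cfg$null_n_simulations,
                           burn_in = cfg$null_burn_in, seed = seed)),
    error = function(e) tibble(error = conditionMessage(e)))
  res$niche_breadth <- glance(levins_breadth(cm_g))
  filtered <- filter_taxa(cm_g, cfg$network_prevalence, cfg$network_abundance)
  res$network <- tryCatch({
    edges <- spearman_edges(filtered, r_min = cfg$network_r_min,
                            p_max = cfg$network_p_max)
    net <- build_network(edges)
    if (igraph::vcount(net) == 0) {
      list(topology = tibble(n_nodes = 0L, n_edges = 0L),
           robustness = NULL, modules = NULL, hubs = NULL)
    } else {
      mods <- detect_modules(net)
      list(
        topology = topology(net),
        module_coverage_top8 = module_coverage(mods, 8),
        natural_connectivity = natural_connectivity(net),
        robustness = robustness_curve(net, cfg$robustness_fractions,
                                      reps = cfg$robustness_reps, seed = seed),
        hubs = hub_scores(net, mods)
      )
    }
  }, error = function(e) list(error = conditionMessage(e)))
  res
}

#' Run the full assembly-inference pipeline
#'
#' Loads (or simulates) a count table and metadata, rarefies, splits samples
#' by group, and per group computes alpha diversity, the Sloan neutral-model
#' fit, the C-score null-model test, Levins niche breadth, and the
#' co-occurrence network with topology and robustness. Across groups it also
#' computes Bray-Curtis distances, the UPGMA dendrogram, ANOSIM and PCA.
#' All randomness derives from `cfg$seed`, so identical configs give
#' identical reports. When `cfg$outdir` is set, per-stage tables (CSV/TSV),
#' the dendrogram (Newick) and a combined JSON report are written there.
#'
#' @param cfg a [run_config()] (or a list of overrides).
#' @return A list report: `config`, `samples`, `alpha`, `anosim`, `pca`,
#'   `heterogeneity` (when nutrients are present), `upgma_newick`, and
#'   `groups` (named per-group result lists).
#' @export
run_full_analysis <- function(cfg = run_config()) {
  if (!inherits(cfg, "run_config")) cfg <- run_config(cfg)
  inputs <- resolve_inputs(cfg)
  cm <- inputs$cm
  md <- inputs$md
  cm <- rarefy(cm, cfg$rarefaction_depth, seed = cfg$seed)
  md <- md[match(colnames(cm$counts), md$sample_id), ]

  report <- list(config = unclass(cfg))
  report$samples <- tibble(sample_id = colnames(cm$counts),
                           group = md$group)
  dm <- bray_curtis(cm)
  report$upgma_newick <- upgma_newick(dm)
  report$anosim <- if (length(unique(md$group)) >= 2 &&
                       all(table(md$group) >= 2)) {
    glance(anosim_test(dm, md$group, n_permutations = 999, seed = cfg$seed))
  }
  report$pca <- tidy(pca_scores(cm))
  if (all(c("nitrate", "silicate", "phosphate") %in% names(md))) {
    report$heterogeneity <- environmental_heterogeneity(md)
  }
  report$alpha <- dplyr::left_join(alpha_diversity(cm),
                                   md[c("sample_id", "group")], by = "sample_id")

  groups <- split_by_group(cm, md)
  report$groups <- lapply(seq_along(groups), function(i) {
    analyse_group(groups[[i]], cfg, seed = cfg$seed + i)
  })
  names(report$groups) <- names(groups)

  if (!is.null(cfg$outdir)) write_report_files(report, cfg$outdir)
  report
}

serialize_report <- function(report) {
  strip <- function(x) {
    if (inherits(x, "robustness_curve")) return(as.data.frame(x))
    if (is.list(x) && !is.data.frame(x)) return(lapply(x, strip))
    x
  }
  strip(report[setdiff(names(report), "config")])
}

write_report_files <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  jsonlite::write_json(serialize_report(report),
                       file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")
  writeLines(report$upgma_newick, file.path(outdir, "upgma.nwk"))
  readr::write_csv(report$alpha, file.path(outdir, "alpha_diversity.csv"))
  for (g in names(report$groups)) {
    rb <- report$groups[[g]]$network$robustness
    if (!is.null(rb)) {
      readr::write_csv(as.data.frame(rb),
                       file.path(outdir, sprintf("robustness_%s.csv", g)))
    }
  }
  writeLines(make_report(report), file.path(outdir, "report.md"))
  invisible(outdir)
}

fmt_num <- function(x, digits = 3) {
  if (is.null(x) || length(x) == 0 || is.na(x)) "-" else formatC(x, digits = digits, format = "fg")
}

#' Render a Markdown summary of a pipeline report
#'
#' One table row per group with the fitted immigration rate and R-squared,
#' SES and its verdict, community niche breadth, and network size/topology
#' highlights; missing sections are noted rather than fatal.
#'
#' @param report a list returned by [run_full_analysis()].
#' @return A character vector of Markdown lines.
#' @export
make_report <- function(report) {
  lines <- c("# Community assembly report", "")
  if (!is.null(report$anosim)) {
    lines <- c(lines, sprintf("ANOSIM across groups: R = %s, p = %s",
                              fmt_num(report$anosim$r),
                              fmt_num(report$anosim$p_value)), "")
  }
  header <- "| group | m | R2 | SES | verdict | Bcom | nodes | edges | +edge frac |"
  sep <- "|---|---|---|---|---|---|---|---|---|"
  rows <- vapply(names(report$groups), function(g) {
    x <- report$groups[[g]]
    ncm <- x$ncm; nm <- x$null_model; nb <- x$niche_breadth
    topo <- x$network$topology
    no_net <- is.null(topo) || !is.null(x$network$error) ||
      (!is.null(topo$n_nodes) && topo$n_nodes == 0)
    sprintf("| %s | %s | %s | %s | %s | %s | %s | %s | %s |",
            g,
            fmt_num(ncm$m), fmt_num(ncm$r_squared),
            fmt_num(nm$ses), nm$verdict %||% "-",
            fmt_num(nb$bcom),
            if (no_net) "no network" else topo$n_nodes,
            if (no_net) "-" else topo$n_edges,
            if (no_net) "-" else fmt_num(topo$positive_edge_fraction))
  }, character(1))
  c(lines, header, sep, rows, "")
}
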