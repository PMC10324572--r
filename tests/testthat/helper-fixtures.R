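# shared fixtures and independent brute-force oracles

toy_cm <- function() {
  m <- matrix(c(5L, 3L, 0L, 2L, 1L, 4L), nrow = 3,
              dimnames = list(paste0("otu", 1:3), c("s1", "s2")))
  community_matrix(m)
}

random_cm <- function(n_taxa, n_samples, lambda = 5, seed = 1) {
  withr::with_seed(seed, {
    m <- matrix(rpois(n_taxa * n_samples, lambda), n_taxa, n_samples,
                dimnames = list(paste0("t", seq_len(n_taxa)),
                                paste0("s", seq_len(n_samples))))
    community_matrix(m)
  })
}

# C-score by explicit double loop over all taxon pairs
c_score_brute <- function(m) {
  m <- (m > 0) * 1
  S <- nrow(m); tot <- 0; np <- 0
  for (i in 1:(S - 1)) for (j in (i + 1):S) {
    sij <- sum(m[i, ] == 1 & m[j, ] == 1)
    tot <- tot + (sum(m[i, ]) - sij) * (sum(m[j, ]) - sij)
    np <- np + 1
  }
  tot / np
}

# Spearman r and two-sided t-approximation p for one pair, from first principles
spearman_brute <- function(a, b) {
  ra <- rank(a); rb <- rank(b)
  r <- sum((ra - mean(ra)) * (rb - mean(rb))) /
    sqrt(sum((ra - mean(ra))^2) * sum((rb - mean(rb))^2))
  n <- length(a)
  tt <- r * sqrt((n - 2) / (1 - r^2))
  list(r = r, p = 2 * pt(-abs(tt), n - 2))
}

# exact hypergeometric expectation of richness at subsampling depth d
expected_richness_hyper <- function(counts, d) {
  total <- sum(counts)
  sum(1 - exp(lchoose(total - counts, d) - lchoose(total, d)))
}

# all binary matrices with the given row/column margins (tiny cases only)
enumerate_fixed_margin_matrices <- function(rs, cs) {
  nr <- length(rs); nc <- length(cs)
  cells <- expand.grid(rep(list(0:1), nr * nc))
  out <- list()
  for (i in seq_len(nrow(cells))) {
    m <- matrix(as.integer(cells[i, ]), nr, nc)
    if (all(rowSums(m) == rs) && all(colSums(m) == cs)) out[[length(out) + 1]] <- m
  }
  out
}

matrix_key <- function(m) paste(as.integer(m), collapse = "")

# modularity Q evaluated directly from its definition
modularity_brute <- function(g, membership) {
  A <- as.matrix(igraph::as_adjacency_matrix(g, sparse = FALSE))
  k <- rowSums(A)
  m2 <- sum(k)
  q <- 0
  for (i in seq_len(nrow(A))) for (j in seq_len(nrow(A))) {
    if (membership[i] == membership[j]) q <- q + A[i, j] - k[i] * k[j] / m2
  }
  unname(q / m2)
}
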