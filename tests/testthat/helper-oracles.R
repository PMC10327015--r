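# Independent oracles and tiny fixtures used across the suite.

# lower-tail binomial probability by direct pmf enumeration
brute_binom_lower <- function(x, n, p) {
  i <- 0:x
  sum(choose(n, i) * p^i * (1 - p)^(n - i))
}

# independent check of DBSCAN semantics: cluster core points by connected
# components of the core-core <= eps graph (igraph), then verify border and
# noise assignment rules
check_dbscan_semantics <- function(pts, eps, min_pts, labels) {
  d <- as.matrix(stats::dist(pts))
  n_nb <- rowSums(d <= eps + 1e-12)        # neighborhood includes the point
  core <- n_nb >= min_pts
  if (!any(core)) return(all(labels == 0L))
  adj <- (d <= eps + 1e-12) & outer(core, core, "&")
  diag(adj) <- FALSE
  g <- igraph::graph_from_adjacency_matrix(adj[core, core, drop = FALSE],
                                           mode = "undirected")
  comp <- igraph::components(g)$membership
  core_idx <- which(core)
  # (1) core points in one component share a label, distinct components differ
  core_lab <- labels[core_idx]
  if (any(core_lab == 0L)) return(FALSE)
  if (length(unique(paste(comp, core_lab))) != length(unique(comp)))
    return(FALSE)
  if (length(unique(core_lab)) != length(unique(comp))) return(FALSE)
  # (2) non-core points: labeled iff within eps of a core point, and then
  #     with the label of some core neighbor
  for (i in which(!core)) {
    nb_core <- core_idx[d[i, core_idx] <= eps + 1e-12]
    if (!length(nb_core)) {
      if (labels[i] != 0L) return(FALSE)
    } else {
      if (!labels[i] %in% labels[nb_core]) return(FALSE)
    }
  }
  TRUE
}

# hand-built four-mouse screen: one pedigree, two mutations, known zygosity
tiny_screen <- function() {
  mice <- data.frame(
    mouse_id = c("G1A", "G2A", "G3A", "G3B", "W1", "W2"),
    generation = c("G1", "G2", "G3", "G3", "WT", "WT"),
    pedigree_id = c(rep("PED1", 4), "WT", "WT"),
    week = 1L,
    tester_id = c("t1", "t1", "t1", "t2", "t1", "t2"),
    sex = c("M", "F", "M", "F", "F", "M"),
    survived_to_weaning = TRUE,
    dam_id = c(NA, NA, "G2A", "G2A", NA, NA),
    stringsAsFactors = FALSE)
  mutations <- data.frame(
    mutation_id = c("M1", "M2"),
    gene_id = c("geneA", "geneB"),
    chromosome = c("1", "2"),
    damage_class = c("probably_damaging", "probably_benign"),
    lethal = FALSE,
    mode = "recessive",
    effect_size_performance = 1,
    effect_on_learning = 0,
    stringsAsFactors = FALSE)
  genotypes <- data.frame(
    mouse_id = c("G1A", "G1A", "G2A", "G2A", "G3A", "G3A", "G3B", "G3B"),
    mutation_id = rep(c("M1", "M2"), 4),
    zygosity = c("HET", "HET", "HET", "REF", "VAR", "REF", "HET", "HET"),
    stringsAsFactors = FALSE)
  trials <- data.frame(
    mouse_id = c("G3A", "G3B", "W1", "W2"),
    trial_1 = c(30, 32, 34, 36), trial_2 = c(34, 36, 38, 40),
    trial_3 = c(38, 40, 42, 44), trial_4 = c(42, 44, 46, 48),
    trial_5 = c(46, 48, 50, 52), trial_6 = c(50, 52, 54, 56),
    stringsAsFactors = FALSE)
  screen_dataset(mice, mutations, genotypes, trials)
}

# small simulated screen reused by several files (generated once per run)
small_screen <- local({
  cache <- NULL
  function() {
    if (is.null(cache))
      cache <<- simulate_screen(sim_params(), n_pedigrees = 6L, seed = 42L)
    cache
  }
})
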