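test_that("zygosity tabulation computes dam-conditional expectations", {
  # 40 G3 offspring, all from het dams -> expected VAR fraction 1/4
  make_ds <- function(dam_het_frac) {
    n <- 40L
    g2 <- sprintf("G2_%02d", 1:4)
    het_dams <- g2[seq_len(round(4 * dam_het_frac))]
    dams <- rep(g2, each = 10L)
    g3 <- sprintf("G3_%02d", 1:n)
    mice <- data.frame(
      mouse_id = c("G1", g2, g3, "W1", "W2"),
      generation = c("G1", rep("G2", 4), rep("G3", n), "WT", "WT"),
      pedigree_id = c(rep("P1", 5 + n), "WT", "WT"),
      week = 1L, tester_id = "t", sex = "F", survived_to_weaning = TRUE,
      dam_id = c(NA, rep(NA, 4), dams, NA, NA), stringsAsFactors = FALSE)
    muts <- data.frame(mutation_id = "M1", gene_id = "g1", chromosome = "1",
                       damage_class = "probably_damaging", lethal = FALSE,
                       mode = "recessive", effect_size_performance = 1,
                       effect_on_learning = 0, stringsAsFactors = FALSE)
    zyg <- ifelse(dams %in% het_dams, "VAR", "HET")  # content irrelevant here
    geno <- data.frame(
      mouse_id = c("G1", g2, g3),
      mutation_id = "M1",
      zygosity = c("HET", ifelse(g2 %in% het_dams, "HET", "REF"), zyg),
      stringsAsFactors = FALSE)
    trials <- data.frame(mouse_id = c(g3, "W1", "W2"),
                         trial_1 = 30, trial_2 = 31, trial_3 = 32,
                         trial_4 = 33, trial_5 = 34, trial_6 = 35,
                         stringsAsFactors = FALSE)
    trials$trial_1 <- 30 + seq_len(nrow(trials)) * 0.1  # non-degenerate WT
    screen_dataset(mice, muts, geno, trials)
  }
  zt <- tabulate_zygosity(make_ds(1))
  expect_equal(zt$expected_var_frac, 0.25)
  expect_equal(zt$n_informative, 40L)
  zt <- tabulate_zygosity(make_ds(0.5))
  expect_equal(zt$expected_var_frac, 0.125)
  expect_equal(zt$n_informative, 20L)
})

test_that("exact binomial deficit test matches brute-force pmf enumeration", {
  for (n in c(10L, 23L, 40L, 60L)) {
    for (x in unique(pmin(n, c(0L, 1L, 3L, 7L, 12L, n %/% 4, n)))) {
      expect_equal(mendelian_distortion_test(x, n, 0.25),
                   brute_binom_lower(x, n, 0.25), tolerance = 1e-12,
                   label = sprintf("x=%d n=%d", x, n))
    }
  }
  # the worked examples: total loss of homozygotes among 40 informative
  p0 <- mendelian_distortion_test(0L, 40L, 0.25)
  expect_equal(p0, 0.75^40, tolerance = 1e-12)
  expect_lt(p0, 2e-5)
  # a Mendelian-consistent count is unremarkable
  expect_gt(mendelian_distortion_test(10L, 40L, 0.25), 0.5)
  expect_error(mendelian_distortion_test(0L, 10L, 0), "positive")
})

test_that("lethality flagging survives Bonferroni at pedigree scale", {
  # one fully penetrant lethal among 60 mutations; 40 informative offspring
  zt <- data.frame(
    mutation_id = sprintf("M%02d", 1:60),
    gene_id = sprintf("g%02d", 1:60), pedigree_id = "P1",
    n_ref = 10L, n_het = 20L,
    n_var = c(0L, rep(10L, 59)),
    n_genotyped = 40L, n_informative = 40L,
    expected_var_frac = 0.25, stringsAsFactors = FALSE)
  class(zt) <- c("zygosity_table", "data.frame")
  res <- detect_lethals(zt)
  expect_true(res$lethal_flag[1])
  expect_false(any(res$lethal_flag[-1]))
  expect_equal(res$p_threshold[1], 0.05 / 60)
  # no informative offspring -> skipped
  zt$n_informative[2] <- 0L
  res <- detect_lethals(zt)
  expect_true(is.na(res$p_distortion[2]))
})

test_that("association scan agrees with stats::lm per mutation and coding", {
  ds <- small_screen()
  sc <- score_screen(ds)
  lr <- association_scan(ds, sc, phenotype = "avg_normalized")
  ph <- tapply(sc$normalized, sc$mouse_id, mean)
  checked <- 0L
  for (i in sample.int(nrow(lr), 25L)) {
    row <- lr[i, ]
    if (is.na(row$p)) next
    ped_mice <- ds$mice$mouse_id[ds$mice$pedigree_id == row$pedigree_id &
                                   ds$mice$generation == "G3"]
    ped_mice <- intersect(ped_mice, names(ph))
    g <- ds$genotypes[ds$genotypes$mutation_id == row$mutation_id &
                        ds$genotypes$mouse_id %in% ped_mice, ]
    dose <- setNames(ifelse(g$zygosity == "VAR", 2L,
                            ifelse(g$zygosity == "HET", 1L, 0L)), g$mouse_id)
    x <- switch(row$model, recessive = as.numeric(dose == 2L),
                additive = as.numeric(dose), dominant = as.numeric(dose >= 1L))
    fit <- summary(lm(ph[names(dose)] ~ x))
    expect_equal(row$effect, fit$coefficients["x", 1], tolerance = 1e-9)
    expect_equal(row$se, fit$coefficients["x", 2], tolerance = 1e-9)
    expect_equal(row$p, fit$coefficients["x", 4], tolerance = 1e-9)
    checked <- checked + 1L
  }
  expect_gte(checked, 10L)
})

test_that("a planted recessive shift ranks first within its pedigree", {
  set.seed(77)
  recovered <- 0L
  for (s in 1:10) {
    n <- 53L
    ids <- sprintf("m%02d", 1:n)
    dose <- matrix(sample(0:2, n * 20, replace = TRUE, prob = c(.4, .45, .15)),
                   n, 20L)
    dose[, 1] <- c(rep(2L, 8L), rep(1L, 30L), rep(0L, 15L))
    y <- rnorm(n, 0, 1) + 2 * (dose[, 1] == 2L)   # +2 SD in homozygotes
    mice <- data.frame(mouse_id = c(ids, "W1", "W2", "W3"),
                       generation = c(rep("G3", n), rep("WT", 3)),
                       pedigree_id = c(rep("P1", n), rep("WT", 3)),
                       week = 1L, tester_id = "t", sex = "M",
                       survived_to_weaning = TRUE, dam_id = NA_character_,
                       stringsAsFactors = FALSE)
    muts <- data.frame(mutation_id = sprintf("M%02d", 1:20),
                       gene_id = sprintf("g%02d", 1:20), chromosome = "1",
                       damage_class = "unknown", lethal = FALSE,
                       mode = "recessive", effect_size_performance = 1,
                       effect_on_learning = 0, stringsAsFactors = FALSE)
    geno <- data.frame(
      mouse_id = rep(ids, each = 20L),
      mutation_id = rep(muts$mutation_id, n),
      zygosity = c("REF", "HET", "VAR")[as.vector(t(dose)) + 1L],
      stringsAsFactors = FALSE)
    base <- 50 + 5 * y
    trials <- data.frame(mouse_id = c(ids, "W1", "W2", "W3"),
                         trial_1 = c(base, 49, 50, 51))
    for (k in 2:6) trials[[paste0("trial_", k)]] <- trials$trial_1
    ds <- screen_dataset(mice, muts, geno, trials)
    sc <- score_screen(ds)
    lr <- association_scan(ds, sc, phenotype = "avg_normalized",
                           model = "recessive")
    best <- lr[order(lr$p), ]
    recovered <- recovered + (best$mutation_id[1] == "M01")
  }
  expect_gte(recovered, 9L)
})

test_that("degenerate codings give NA and ranking breaks ties as documented", {
  lr <- structure(data.frame(
    mutation_id = c("A", "B", "C", "D"),
    gene_id = "g", pedigree_id = "P", model = "recessive",
    n_ref = 1L, n_het = 1L, n_var = c(5L, 5L, 8L, 5L),
    effect = c(1, -3, 3, 2), se = 1,
    p = c(1e-3, 1e-6, 1e-6, NA), p_adj = NA_real_,
    stringsAsFactors = FALSE), class = c("linkage_result", "data.frame"))
  rk <- candidate_rank(lr)
  # p first; B and C tie on p and |effect|, so n_var (8 > 5) breaks the tie
  expect_equal(rk$mutation_id, c("C", "B", "A"))
  expect_equal(rk$direction[rk$mutation_id == "B"], "sub-performance")
  expect_equal(rk$direction[rk$mutation_id == "C"], "super-performance")
  # all-VAR coding is constant -> NA p
  ds <- tiny_screen()
  ds$genotypes$zygosity[ds$genotypes$mouse_id %in% c("G3A", "G3B")] <- "VAR"
  sc <- score_screen(ds)
  lr2 <- association_scan(ds, sc, model = "dominant", min_var = 1L)
  expect_true(all(is.na(lr2$p)))
})

test_that("saturation counts qualifying genes against the universe", {
  ds <- small_screen()
  k <- 3L
  sat <- saturation_estimate(ds, k = k, m = 6L, genes_total = 25000L,
                             genes_autosomal = 24000L)
  # independent brute-force recount
  g3 <- ds$mice$mouse_id[ds$mice$generation == "G3"]
  tested <- intersect(ds$trials$mouse_id, g3)
  qual_genes <- character(0)
  for (i in seq_len(nrow(ds$mutations))) {
    mu <- ds$mutations[i, ]
    if (!mu$damage_class %in% c("probably_damaging", "probably_null")) next
    nv <- sum(ds$genotypes$mutation_id == mu$mutation_id &
                ds$genotypes$zygosity == "VAR" &
                ds$genotypes$mouse_id %in% tested)
    if (nv >= k) qual_genes <- c(qual_genes, mu$gene_id)
  }
  expect_equal(sat$n_genes_all, length(unique(qual_genes)))
  expect_equal(sat$fraction_all, length(unique(qual_genes)) / 25000)
  expect_gte(sat$fraction_autosomal, sat$fraction_all * 24000 / 25000)
  # monotone in k and in class strictness
  sat5 <- saturation_estimate(ds, k = 5L)
  expect_lte(sat5$n_genes_all, sat$n_genes_all)
  sat_null <- saturation_estimate(ds, k = k,
                                  severe_classes = "probably_null")
  expect_lte(sat_null$n_genes_all, sat$n_genes_all)
  expect_error(saturation_estimate(ds, k = 0L), ">= 1")
  # toy arithmetic: 2 qualifying genes in a universe of 10
  expect_equal(2 / 10, 0.2)
})
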