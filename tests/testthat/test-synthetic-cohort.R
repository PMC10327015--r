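test_that("G3 segregation matches Mendelian expectation (pooled 1/8 VAR)", {
  p <- sim_params(frac_lethal = 0, frac_superperformance = 0)
  ds <- simulate_screen(p, n_pedigrees = 60L, seed = 7L)
  g3 <- ds$mice$mouse_id[ds$mice$generation == "G3"]
  g <- ds$genotypes[ds$genotypes$mouse_id %in% g3, ]
  n <- nrow(g)
  expect_gt(n, 1e4)
  frac <- mean(g$zygosity == "VAR")
  se <- sqrt(0.125 * 0.875 / n)
  expect_lt(abs(frac - 0.125), 3 * se)
  # HET fraction: 1/2 from het dams, 1/2 from ref dams -> 1/2 overall
  expect_lt(abs(mean(g$zygosity == "HET") - 0.5),
            3 * sqrt(0.25 / n) + 0.01)
})

test_that("fully penetrant lethal alleles leave no homozygous G3", {
  p <- sim_params(frac_lethal = 0.2, lethal_penetrance = 1)
  ped <- generate_pedigree(p, 1L, seed = 5L)
  lethal <- ped$mutations$mutation_id[ped$mutations$lethal]
  expect_gt(length(lethal), 0L)
  g3 <- ped$mice$mouse_id[ped$mice$generation == "G3"]
  g <- ped$genotypes[ped$genotypes$mouse_id %in% g3 &
                       ped$genotypes$mutation_id %in% lethal, ]
  expect_equal(sum(g$zygosity == "VAR"), 0L)
  # pedigree still reaches its target size despite the removals
  expect_gte(length(g3), p$g3_per_pedigree[1])
})

test_that("increasing lethal penetrance monotonically depletes homozygotes", {
  fracs <- sapply(c(0, 0.5, 1), function(pen) {
    p <- sim_params(frac_lethal = 1, lethal_penetrance = pen,
                    frac_superperformance = 0)
    ds <- simulate_screen(p, n_pedigrees = 12L, seed = 3L)
    g3 <- ds$mice$mouse_id[ds$mice$generation == "G3"]
    g <- ds$genotypes[ds$genotypes$mouse_id %in% g3, ]
    mean(g$zygosity == "VAR")
  })
  expect_true(all(diff(fracs) < 0))
  expect_equal(fracs[3], 0)
})

test_that("identical seed and params give identical datasets", {
  a <- simulate_screen(sim_params(), n_pedigrees = 4L, seed = 11L)
  b <- simulate_screen(sim_params(), n_pedigrees = 4L, seed = 11L)
  expect_identical(a$mice, b$mice)
  expect_identical(a$genotypes, b$genotypes)
  expect_identical(a$trials, b$trials)
  d <- simulate_screen(sim_params(), n_pedigrees = 4L, seed = 12L)
  expect_false(identical(a$trials, d$trials))
})

test_that("damage classes follow the screen-wide frequencies", {
  probs <- sim_params()$damage_class_probs
  cls <- assign_damage_classes(50000L, probs, seed = 2L)
  emp <- table(factor(cls, levels = names(probs))) / 50000
  for (k in names(probs)) {
    se <- sqrt(probs[[k]] * (1 - probs[[k]]) / 50000)
    expect_lt(abs(emp[[k]] - probs[[k]]), 4 * se, label = k)
  }
  # degenerate distribution
  expect_true(all(assign_damage_classes(100L, c(1, 0, 0, 0, 0)) ==
                    "probably_benign"))
  expect_length(assign_damage_classes(0L, probs), 0L)
  expect_error(assign_damage_classes(10L, c(0.5, 0.5, 0.5, 0, 0)), "sum")
})

test_that("trial model honors planted structure under zero noise", {
  p <- sim_params(baseline_latency_sd = 0, trial_noise_sd = 0,
                  tester_effect_sd = 0, learning_increment_sd = 0,
                  nonlearner_slope_sd = 0, nonlearner_baseline_shift = 0,
                  load_effect_t_per_var = 0, frac_nonlearner = 0)
  mice <- data.frame(
    mouse_id = c("A", "B", "C"), generation = "G3", pedigree_id = "P",
    week = 1L, tester_id = "t", sex = "M", survived_to_weaning = TRUE,
    dam_id = NA_character_, stringsAsFactors = FALSE)
  muts <- data.frame(mutation_id = "M1", gene_id = "g", chromosome = "1",
                     damage_class = "unknown", lethal = FALSE,
                     mode = "recessive", effect_size_performance = 1.4,
                     effect_on_learning = 0, stringsAsFactors = FALSE)
  geno <- data.frame(mouse_id = c("A", "B", "C"), mutation_id = "M1",
                     zygosity = c("VAR", "HET", "REF"),
                     stringsAsFactors = FALSE)
  tr <- simulate_trials(mice, muts, geno, p, nonlearner_ids = character(0),
                        seed = 1L)$trials
  lat <- as.matrix(tr[, -1]); rownames(lat) <- tr$mouse_id
  # learners gain every trial; recessive multiplier hits VAR baseline only
  expect_true(all(lat[, 6] > lat[, 1]))
  expect_equal(lat["A", 1] / lat["C", 1], 1.4)
  expect_equal(lat["B", 1], lat["C", 1])   # HET unaffected when recessive
  # planted non-learner with zero noise is flat
  tr2 <- simulate_trials(mice, muts, geno, p, nonlearner_ids = "C",
                         seed = 1L)$trials
  flat <- as.numeric(tr2[tr2$mouse_id == "C", -1])
  expect_equal(diff(flat), rep(0, 5))
  # unknown mutation reference errors
  geno_bad <- within(geno, mutation_id[1] <- "MX")
  expect_error(simulate_trials(mice, muts, geno_bad, p), "MX")
})

test_that("weekly batching respects rates and keeps controls per week", {
  p <- sim_params(mice_per_week = 600L, wt_per_week = 8L)
  mice <- do.call(rbind, lapply(1:36, function(i)
    generate_pedigree(sim_params(), i, seed = i)$mice))
  b <- batch_into_weeks(mice, p, seed = 1L)
  g3 <- b$mice[b$mice$generation == "G3", ]
  per_week <- table(g3$week)
  expect_true(all(per_week <= 600L))
  expect_equal(b$n_weeks, length(per_week))
  wt <- b$mice[b$mice$generation == "WT", ]
  expect_equal(nrow(wt), 8L * b$n_weeks)
  expect_true(all(table(wt$week) == 8L))
  # pedigrees stay intact within a week
  expect_true(all(tapply(g3$week, g3$pedigree_id,
                         function(w) length(unique(w))) == 1L))
  # out-of-range weekly rate warns but proceeds
  expect_warning(sim_params(mice_per_week = 50L), "100-900")
})

test_that("misconfigured mutation minimum is rejected", {
  expect_error(sim_params(min_mutations_per_G1 = 150L,
                          mean_mutations_per_G1 = 60), "5 SD")
})
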