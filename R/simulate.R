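#' Assign PolyPhen-style damage classes
#'
#' Draws damage classes i.i.d. from the screen-wide class frequencies
#' (defaults: probably benign 38.3%, possibly damaging 15.1%, probably
#' damaging 38.8%, probably null 4.5%, unknown 3.3%).
#'
#' @param x either a mutations data.frame (gets its `damage_class` column
#'   set) or a single non-negative integer (returns a character vector).
#' @param probs probability 5-vector over
#'   `c("probably_benign","possibly_damaging","probably_damaging",
#'   "probably_null","unknown")`; must sum to 1.
#' @param seed optional RNG seed.
#' @return same shape as `x`.
#' @export
assign_damage_classes <- function(x, probs = sim_params()$damage_class_probs,
                                  seed = NULL) {
  if (length(probs) != 5L || abs(sum(probs) - 1) > 1e-9 || any(probs < 0))
    stop_format("probs must be 5 non-negative values summing to 1")
  draw <- function(n) {
    if (n == 0L) return(character(0))
    sample(damage_classes, n, replace = TRUE, prob = probs)
  }
  with_seed(seed, {
    if (is.data.frame(x)) {
      x$damage_class <- draw(nrow(x))
      x
    } else {
      stopifnot(is.numeric(x), length(x) == 1L, x >= 0)
      draw(as.integer(x))
    }
  })
}

# analytic wild-type raw-latency SD at trial t (1-based) under the linear
# latency model; used to plant load effects on the T-score scale
wt_trial_sd <- function(params, t) {
  sqrt(params$baseline_latency_sd^2 +
         ((t - 1) * params$learning_increment_sd)^2 +
         params$tester_effect_sd^2 + params$trial_noise_sd^2)
}

#' Simulate one ENU pedigree
#'
#' Generates the mutation set of a G1 male (heterozygous at every site),
#' its G2 daughters (each mutation inherited HET with probability 1/2) and
#' the G3 offspring of the G1 x G2 backcross, with per-mutation Mendelian
#' segregation given each G3 mouse's dam genotype. Homozygous-lethal G3
#' conceptuses are removed before output with probability
#' `lethal_penetrance`, which distorts the observed genotype ratios — the
#' footprint the Mendelian-distortion test looks for. Only autosomes are
#' mutagenized.
#'
#' @param params [sim_params()].
#' @param pedigree_index integer used to build stable ids.
#' @param genes_total size of the gene universe mutation targets are drawn
#'   from.
#' @param seed optional RNG seed (the screen-level generator seeds once and
#'   leaves this `NULL`).
#' @param force_super `NA` (default) draws the superperformance plant with
#'   probability `frac_superperformance`; `TRUE`/`FALSE` force it.
#' @return list with `mutations`, `mice` (G1, G2, G3 rows; `week` and
#'   `tester_id` unset until [batch_into_weeks()]), `genotypes` (long),
#'   and `nonlearner_ids` (planted flat-curve G3 mice).
#' @export
generate_pedigree <- function(params = sim_params(), pedigree_index = 1L,
                              genes_total = 25000L, seed = NULL,
                              force_super = NA) {
  validate_sim_params(params)
  with_seed(seed, {
    ped <- sprintf("PED%04d", pedigree_index)
    k <- 0L
    for (i in 1:1000) {
      k <- stats::rpois(1L, params$mean_mutations_per_G1)
      if (k >= params$min_mutations_per_G1) break
    }
    if (k < params$min_mutations_per_G1)
      stop_format("could not draw >= %d mutations around mean %g",
                  params$min_mutations_per_G1, params$mean_mutations_per_G1)

    muts <- data.frame(
      mutation_id = sprintf("%s_M%03d", ped, seq_len(k)),
      gene_id = sprintf("gene%05d", sample.int(genes_total, k, replace = TRUE)),
      chromosome = as.character(sample.int(19L, k, replace = TRUE)),
      damage_class = NA_character_,
      lethal = stats::runif(k) < params$frac_lethal,
      mode = "recessive",
      effect_size_performance = 1,
      effect_on_learning = 0,
      stringsAsFactors = FALSE)
    muts <- assign_damage_classes(muts, params$damage_class_probs)
    # at most one planted behavioral-effect mutation per pedigree, so that
    # linkage-recovery checks against ground truth are unambiguous
    plant <- stats::runif(1) < params$frac_superperformance
    if (!is.na(force_super)) plant <- isTRUE(force_super)
    if (plant && any(!muts$lethal)) {
      pick <- sample(which(!muts$lethal), 1L)
      muts$effect_size_performance[pick] <- params$super_effect
      muts$damage_class[pick] <- "probably_damaging"
    }

    g1_id <- sprintf("%s_G1", ped)
    n2 <- sample(params$g2_daughters[1]:params$g2_daughters[2], 1L)
    g2_ids <- sprintf("%s_G2_%02d", ped, seq_len(n2))
    # G2 daughters: each mutation transmitted HET with probability 1/2
    g2_geno <- matrix(stats::rbinom(n2 * k, 1L, 0.5), n2, k)

    # the target is the number of weaned G3 mice the cross yields; litters
    # are topped up until it is reached, so recessive lethality distorts
    # the observed genotype ratios without shrinking the pedigree
    n3_target <- sample(params$g3_per_pedigree[1]:params$g3_per_pedigree[2],
                        1L)
    g3_geno <- matrix(0L, 0L, k)
    dam_idx <- integer(0)
    for (round in 1:10) {
      deficit <- n3_target - nrow(g3_geno)
      if (deficit <= 0L) break
      nb <- max(deficit * 2L, 8L)
      di <- sample.int(n2, nb, replace = TRUE)
      # sire always HET; dam contributes a mutant allele only if herself HET
      dam_het <- g2_geno[di, , drop = FALSE]
      gb <- matrix(stats::rbinom(nb * k, 1L, 0.5), nb, k) +
        matrix(stats::rbinom(nb * k, 1L, 0.5 * as.vector(dam_het)), nb, k)
      # recessive lethality: VAR conceptuses lost with given penetrance
      keep <- rep(TRUE, nb)
      if (any(muts$lethal) && params$lethal_penetrance > 0) {
        hom_lethal <- gb[, muts$lethal, drop = FALSE] == 2L
        die <- matrix(stats::runif(length(hom_lethal)) <
                        params$lethal_penetrance, nrow(hom_lethal))
        keep <- rowSums(hom_lethal & die) == 0L
      }
      g3_geno <- rbind(g3_geno, gb[keep, , drop = FALSE])
      dam_idx <- c(dam_idx, di[keep])
    }
    if (nrow(g3_geno) > n3_target) {
      g3_geno <- g3_geno[seq_len(n3_target), , drop = FALSE]
      dam_idx <- dam_idx[seq_len(n3_target)]
    }
    n3 <- nrow(g3_geno)

    g3_ids <- sprintf("%s_G3_%03d", ped, seq_len(n3))
    n_var <- rowSums(g3_geno == 2L)
    p_surv <- pmin(1, pmax(0.5, params$survival_base -
                                  params$survival_load_coef * n_var))
    survived <- stats::runif(n3) < p_surv

    mice <- data.frame(
      mouse_id = c(g1_id, g2_ids, g3_ids),
      generation = c("G1", rep("G2", n2), rep("G3", n3)),
      pedigree_id = ped,
      week = NA_integer_,
      tester_id = NA_character_,
      sex = c("M", rep("F", n2), sample(c("F", "M"), n3, replace = TRUE)),
      survived_to_weaning = c(TRUE, rep(TRUE, n2), survived),
      dam_id = c(NA_character_, rep(NA_character_, n2), g2_ids[dam_idx]),
      stringsAsFactors = FALSE)

    zyg <- function(m) zygosity_levels[m + 1L]
    genotypes <- data.frame(
      mouse_id = c(rep(g1_id, k),
                   rep(g2_ids, each = k),
                   rep(g3_ids, each = k)),
      mutation_id = rep(muts$mutation_id, times = 1L + n2 + n3),
      zygosity = c(rep("HET", k),
                   zyg(as.vector(t(g2_geno))),
                   zyg(as.vector(t(g3_geno)))),
      stringsAsFactors = FALSE)

    nonlearners <- g3_ids[survived][
      stats::runif(sum(survived)) < params$frac_nonlearner]

    list(mutations = muts, mice = mice, genotypes = genotypes,
         nonlearner_ids = nonlearners)
  })
}

#' Assign testing weeks and testers
#'
#' Packs pedigrees, in order and intact, into weekly testing batches of at
#' most `mice_per_week` G3 mice, adds `wt_per_week` untrained wild-type
#' control mice to every week, and assigns each tested mouse to one of
#' `n_testers` testers. G1/G2 animals inherit their pedigree's (first)
#' week. Weekly rates outside the practical 100--900 range draw a warning,
#' not an error.
#'
#' @param mice pedigree table (G1/G2/G3 rows, `week` unset).
#' @param params [sim_params()].
#' @param seed optional RNG seed.
#' @return list `mice` (input rows plus WT controls, weeks and testers
#'   filled in) and `n_weeks`.
#' @export
batch_into_weeks <- function(mice, params = sim_params(), seed = NULL) {
  with_seed(seed, {
    g3 <- which(mice$generation == "G3")
    if (length(g3)) {
      peds <- unique(mice$pedigree_id[g3])
      per_ped <- table(factor(mice$pedigree_id[g3], levels = peds))
      week_of_ped <- integer(length(peds))
      wk <- 1L; used <- 0L
      for (i in seq_along(peds)) {
        if (used > 0L && used + per_ped[i] > params$mice_per_week) {
          wk <- wk + 1L; used <- 0L
        }
        week_of_ped[i] <- wk
        used <- used + per_ped[i]
      }
      names(week_of_ped) <- peds
      mice$week[mice$pedigree_id %in% peds] <-
        week_of_ped[mice$pedigree_id[mice$pedigree_id %in% peds]]
      n_weeks <- max(week_of_ped)
    } else n_weeks <- 0L

    testers <- sprintf("tester%02d", seq_len(params$n_testers))
    tested <- mice$generation == "G3"
    mice$tester_id[tested] <- sample(testers, sum(tested), replace = TRUE)

    if (n_weeks > 0L && params$wt_per_week > 0L) {
      wt <- data.frame(
        mouse_id = sprintf("WT_w%02d_%03d",
                           rep(seq_len(n_weeks), each = params$wt_per_week),
                           rep(seq_len(params$wt_per_week), n_weeks)),
        generation = "WT",
        pedigree_id = "WT",
        week = rep(seq_len(n_weeks), each = params$wt_per_week),
        tester_id = sample(testers, n_weeks * params$wt_per_week,
                           replace = TRUE),
        sex = sample(c("F", "M"), n_weeks * params$wt_per_week,
                     replace = TRUE),
        survived_to_weaning = TRUE,
        dam_id = NA_character_,
        stringsAsFactors = FALSE)
      mice <- rbind(mice, wt)
    }
    list(mice = mice, n_weeks = n_weeks)
  })
}

#' Simulate rotarod trial series
#'
#' Fall latency of mouse i at trial t follows a linear learning model:
#' `latency = baseline_i * perf_multiplier_i + slope_i * (t - 1) +
#' load_i(t) + tester_week_effect + noise`, truncated at zero. Baseline and
#' slope are drawn per mouse from a correlated bivariate normal
#' (`baseline_slope_corr`); planted non-learners draw their slope around
#' zero instead. `perf_multiplier_i` multiplies the baseline by
#' `effect_size_performance` of every carried effect mutation whose mode is
#' satisfied (recessive: VAR; dominant: HET or VAR; additive: square-root
#' multiplier for HET). `load_i(t)` shifts trial t by
#' `load_effect_t_per_var / 10 * sd_wt(t)` seconds per homozygous mutation,
#' i.e. a constant displacement on the T-score scale. Tester effects are
#' additive constants per (week, tester).
#'
#' @param mice pedigree table with weeks/testers assigned (WT included);
#'   only surviving WT and G3 mice are tested.
#' @param mutations mutations table.
#' @param genotypes long zygosity table.
#' @param params [sim_params()].
#' @param nonlearner_ids mouse ids of planted non-learners; `NULL` draws
#'   them here at rate `frac_nonlearner`.
#' @param seed optional RNG seed.
#' @return list `trials` (phenotype data.frame) and `nonlearner_ids`.
#' @export
simulate_trials <- function(mice, mutations, genotypes,
                            params = sim_params(), nonlearner_ids = NULL,
                            seed = NULL) {
  unknown <- setdiff(genotypes$mutation_id, mutations$mutation_id)
  if (length(unknown))
    stop_format("genotypes reference unknown mutation(s): %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  with_seed(seed, {
    tested <- mice[mice$survived_to_weaning &
                     mice$generation %in% c("WT", "G3"), , drop = FALSE]
    n <- nrow(tested)
    if (n == 0L)
      return(list(trials = stats::setNames(
        data.frame(matrix(nrow = 0L, ncol = 7L)), trial_cols),
        nonlearner_ids = character(0)))

    # per-mouse genetic summaries from the long genotype table
    g <- genotypes[genotypes$mouse_id %in% tested$mouse_id, , drop = FALSE]
    m <- mutations[match(g$mutation_id, mutations$mutation_id), ]
    dose <- ifelse(g$zygosity == "VAR", 2L, ifelse(g$zygosity == "HET", 1L, 0L))
    hit <- (m$mode == "recessive" & dose == 2L) |
      (m$mode == "dominant" & dose >= 1L) |
      (m$mode == "additive" & dose >= 1L)
    frac <- ifelse(m$mode == "additive" & dose == 1L, 0.5, 1)
    lmu <- hit & m$effect_size_performance != 1
    mult <- rep(1, n)
    if (any(lmu)) {
      lm_by <- tapply(m$effect_size_performance[lmu]^frac[lmu],
                      g$mouse_id[lmu], prod)
      idx <- match(names(lm_by), tested$mouse_id)
      mult[idx] <- as.numeric(lm_by)
    }
    slope_add <- rep(0, n)
    lea <- hit & m$effect_on_learning != 0
    if (any(lea)) {
      sa <- tapply(m$effect_on_learning[lea] * frac[lea], g$mouse_id[lea], sum)
      slope_add[match(names(sa), tested$mouse_id)] <- as.numeric(sa)
    }
    n_var <- rep(0L, n)
    nv <- tapply(dose == 2L, g$mouse_id, sum)
    n_var[match(names(nv), tested$mouse_id)] <- as.integer(nv)
    slope_add <- slope_add + params$learning_effect_per_var * n_var

    if (is.null(nonlearner_ids)) {
      cand <- tested$mouse_id[tested$generation == "G3"]
      nonlearner_ids <- cand[stats::runif(length(cand)) < params$frac_nonlearner]
    }
    nl <- tested$mouse_id %in% nonlearner_ids

    # correlated (baseline, slope) draw
    zb <- stats::rnorm(n); zs <- stats::rnorm(n)
    rho <- params$baseline_slope_corr
    baseline <- params$baseline_latency_mean + params$baseline_latency_sd * zb
    slope <- params$learning_increment_mean +
      params$learning_increment_sd * (rho * zb + sqrt(1 - rho^2) * zs)
    slope[nl] <- params$nonlearner_slope_sd * stats::rnorm(sum(nl))
    baseline[nl] <- params$baseline_latency_mean +
      params$nonlearner_baseline_shift +
      params$nonlearner_baseline_sd_factor * params$baseline_latency_sd * zb[nl]

    # additive tester-by-week constants
    key <- paste(tested$week, tested$tester_id, sep = "|")
    uk <- sort(unique(key))
    te <- stats::setNames(stats::rnorm(length(uk), 0, params$tester_effect_sd),
                          uk)[key]

    lat <- matrix(0, n, 6L)
    for (t in 1:6) {
      load_t <- params$load_effect_t_per_var / 10 * wt_trial_sd(params, t) *
        n_var
      lat[, t] <- baseline * mult + (slope + slope_add) * (t - 1L) + load_t +
        te + stats::rnorm(n, 0, params$trial_noise_sd)
    }
    lat <- pmax(lat, 0)
    trials <- data.frame(mouse_id = tested$mouse_id, lat,
                         stringsAsFactors = FALSE)
    names(trials) <- trial_cols
    list(trials = trials, nonlearner_ids = nonlearner_ids)
  })
}

#' Simulate a complete synthetic screen
#'
#' Runs [generate_pedigree()] for `n_pedigrees` pedigrees,
#' [batch_into_weeks()] and [simulate_trials()], and returns a validated
#' [screen_dataset()] whose `truth` element records the planted
#' non-learners and behavioral-effect mutations.
#'
#' @param params [sim_params()].
#' @param n_pedigrees number of G1 pedigrees (default 12, about one testing
#'   week at the default pedigree size).
#' @param genes_total gene universe size for mutation targets.
#' @param seed RNG seed; fixes every draw of the simulation.
#' @return a `screen_dataset` with ground-truth annotations.
#' @export
simulate_screen <- function(params = sim_params(), n_pedigrees = 12L,
                            genes_total = 25000L, seed = 1L) {
  validate_sim_params(params)
  with_seed(stage_seed(seed, "simulate"), {
    force_super <- rep(NA, n_pedigrees)
    if (!is.na(params$n_super_pedigrees)) {
      if (params$n_super_pedigrees > n_pedigrees)
        stop_format("n_super_pedigrees exceeds n_pedigrees")
      force_super <- seq_len(n_pedigrees) %in%
        sample.int(n_pedigrees, params$n_super_pedigrees)
    }
    peds <- lapply(seq_len(n_pedigrees), function(i)
      generate_pedigree(params, i, genes_total = genes_total,
                        force_super = force_super[i]))
    mutations <- do.call(rbind, lapply(peds, `[[`, "mutations"))
    mice <- do.call(rbind, lapply(peds, `[[`, "mice"))
    genotypes <- do.call(rbind, lapply(peds, `[[`, "genotypes"))
    nonlearners <- unlist(lapply(peds, `[[`, "nonlearner_ids"))

    b <- batch_into_weeks(mice, params)
    tr <- simulate_trials(b$mice, mutations, genotypes, params,
                          nonlearner_ids = nonlearners)
    truth <- list(
      nonlearner_ids = nonlearners,
      effect_mutations = mutations$mutation_id[
        mutations$effect_size_performance != 1 | mutations$effect_on_learning != 0],
      params = params, n_pedigrees = n_pedigrees, seed = seed)
    screen_dataset(b$mice, mutations, genotypes, tr$trials, truth = truth)
  })
}

#' Simulate a wild-type-only control cohort
#'
#' Untrained wild-type mice spread over testing weeks, with the same
#' latency model as the screen but no mutations. Used to study the
#' behavior of T-scores and outlier thresholds under the null.
#'
#' @param n_mice total wild-type mice.
#' @param n_weeks testing weeks they are spread over.
#' @param params [sim_params()].
#' @param seed RNG seed.
#' @return a `screen_dataset` with only WT animals.
#' @export
simulate_wt_cohort <- function(n_mice, n_weeks = 1L, params = sim_params(),
                               seed = 1L) {
  stopifnot(n_mice >= 1L, n_weeks >= 1L)
  with_seed(stage_seed(seed, "wt"), {
    testers <- sprintf("tester%02d", seq_len(params$n_testers))
    mice <- data.frame(
      mouse_id = sprintf("WT_%05d", seq_len(n_mice)),
      generation = "WT", pedigree_id = "WT",
      week = rep_len(seq_len(n_weeks), n_mice),
      tester_id = sample(testers, n_mice, replace = TRUE),
      sex = sample(c("F", "M"), n_mice, replace = TRUE),
      survived_to_weaning = TRUE, dam_id = NA_character_,
      stringsAsFactors = FALSE)
    muts <- data.frame(mutation_id = character(0), gene_id = character(0),
                       chromosome = character(0), damage_class = character(0),
                       lethal = logical(0), mode = character(0),
                       effect_size_performance = numeric(0),
                       effect_on_learning = numeric(0))
    geno <- data.frame(mouse_id = character(0), mutation_id = character(0),
                       zygosity = character(0))
    tr <- simulate_trials(mice, muts, geno, params,
                          nonlearner_ids = character(0))
    screen_dataset(mice, muts, geno, tr$trials,
                   truth = list(nonlearner_ids = character(0),
                                effect_mutations = character(0),
                                params = params, seed = seed))
  })
}
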