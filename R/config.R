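#' Simulation parameters for a synthetic ENU screen
#'
#' Returns the full set of generator tunables with defaults matching the
#' breeding scheme and screening logistics of a large rotarod ENU screen:
#' G1 males carrying on average 60 coding/splicing mutations (males with
#' fewer than 30 are not bred), 10--15 G2 daughters per G1, ~40--60 G3 mice
#' per pedigree from the G1 x G2 backcross, weekly testing batches of about
#' 600 mutant mice (100--900 feasible) alongside untrained wild-type
#' controls, and PolyPhen-style damage-class frequencies of
#' 38.3/15.1/38.8/4.5/3.3 percent.
#'
#' Latencies follow a linear-in-trial model: each mouse draws a baseline
#' fall latency and a per-trial learning increment (correlated negatively,
#' so poor starters learn faster), plus an additive tester-by-week constant
#' and i.i.d. trial noise. Planted structure — non-learner mice with flat
#' curves, recessive superperformance alleles, recessive lethals that
#' distort Mendelian ratios, and a per-homozygous-mutation load penalty —
#' gives downstream stages known ground truth.
#'
#' @param ... overrides of any default listed below.
#' @return a classed list of parameters (`sim_params`).
#' @section Parameters:
#' \describe{
#'   \item{mean_mutations_per_G1 / min_mutations_per_G1}{Poisson mean (60)
#'     and lower acceptance bound (30) for mutations carried by a G1 male.}
#'   \item{g2_daughters, g3_per_pedigree}{integer ranges, default 10--15 and
#'     40--60.}
#'   \item{mice_per_week, wt_per_week}{batch sizes: 600 mutant mice per
#'     testing week and 25 untrained wild-type controls.}
#'   \item{damage_class_probs}{probabilities of the five damage classes.}
#'   \item{frac_lethal}{fraction of mutations that are recessive lethal
#'     (default 0.055, i.e. roughly one mutation in six severely damaging
#'     times one gene in three essential).}
#'   \item{lethal_penetrance}{probability a homozygous lethal conceptus is
#'     lost before weaning (default 1).}
#'   \item{frac_superperformance, n_super_pedigrees, super_effect}{each
#'     pedigree carries one planted recessive superperformance allele with
#'     probability `frac_superperformance` (or, when `n_super_pedigrees`
#'     is set, exactly that many pedigrees do); the allele multiplies
#'     homozygotes' latency by `super_effect` (default 1.4, the scale of
#'     the strongest superperformance alleles seen on an accelerating
#'     rotarod).}
#'   \item{frac_nonlearner}{fraction of G3 mice with flat learning curves
#'     (default 0.08).}
#'   \item{baseline_latency_mean/sd}{seconds; default 35 and 6, placing the
#'     wild-type trial-6 maximum linear speed near 1.0 m/min.}
#'   \item{learning_increment_mean/sd}{seconds gained per trial (4, 0.45),
#'     placing the wild-type trial-6 maximum linear speed near 1.0 m/min.}
#'   \item{nonlearner_slope_sd, nonlearner_baseline_shift,
#'     nonlearner_baseline_sd_factor}{the stereotyped non-learning
#'     phenotype: flat curves (slope around 0, SD 0.15), a higher starting
#'     latency (+5 s) and 0.3 times the baseline spread of learners —
#'     higher first-trial performance, no gain across trials, forming the
#'     compact, density-separated second cluster such screens exhibit.}
#'   \item{baseline_slope_corr}{correlation between baseline and learning
#'     increment (default -0.3).}
#'   \item{trial_noise_sd, tester_effect_sd, n_testers}{seconds; 3, 2, 6.}
#'   \item{load_effect_t_per_var}{additive shift of every trial's T-score
#'     per homozygous mutation carried (default -0.05).}
#'   \item{learning_effect_per_var}{additive slope change (s/trial) per
#'     homozygous mutation (default 0).}
#'   \item{survival_base, survival_load_coef}{post-weaning survival
#'     probability `survival_base - survival_load_coef * n_VAR`, clamped to
#'     [0.5, 1] (defaults 0.99, 0.004).}
#'   \item{x_mutation_rate}{rate of spontaneous X-linked mutations per
#'     pedigree (default 0; the X is not mutagenized in G3 mice).}
#' }
#' @export
sim_params <- function(...) {
  p <- list(
    mean_mutations_per_G1 = 60,
    min_mutations_per_G1 = 30L,
    g2_daughters = c(10L, 15L),
    g3_per_pedigree = c(40L, 60L),
    mice_per_week = 600L,
    wt_per_week = 25L,
    damage_class_probs = c(probably_benign = 0.383, possibly_damaging = 0.151,
                           probably_damaging = 0.388, probably_null = 0.045,
                           unknown = 0.033),
    frac_lethal = 0.055,
    lethal_penetrance = 1,
    frac_superperformance = 0.05,
    n_super_pedigrees = NA_integer_,
    super_effect = 1.4,
    frac_nonlearner = 0.08,
    baseline_latency_mean = 35,
    baseline_latency_sd = 6,
    learning_increment_mean = 4,
    learning_increment_sd = 0.45,
    nonlearner_slope_sd = 0.15,
    nonlearner_baseline_shift = 5,
    nonlearner_baseline_sd_factor = 0.3,
    baseline_slope_corr = -0.3,
    trial_noise_sd = 1.5,
    tester_effect_sd = 2,
    n_testers = 6L,
    load_effect_t_per_var = -0.05,
    learning_effect_per_var = 0,
    survival_base = 0.99,
    survival_load_coef = 0.004,
    x_mutation_rate = 0
  )
  over <- list(...)
  bad <- setdiff(names(over), names(p))
  if (length(bad))
    stop_format("unknown sim_params field(s): %s", paste(bad, collapse = ", "))
  p[names(over)] <- over
  validate_sim_params(structure(p, class = "sim_params"))
}

validate_sim_params <- function(p) {
  stopifnot(inherits(p, "sim_params"))
  if (abs(sum(p$damage_class_probs) - 1) > 1e-9)
    stop_format("damage_class_probs must sum to 1")
  if (any(p$damage_class_probs < 0))
    stop_format("damage_class_probs must be non-negative")
  if (length(p$g2_daughters) != 2L || diff(p$g2_daughters) < 0)
    stop_format("g2_daughters must be a non-empty [lo, hi] range")
  if (length(p$g3_per_pedigree) != 2L || diff(p$g3_per_pedigree) < 0)
    stop_format("g3_per_pedigree must be a non-empty [lo, hi] range")
  # a minimum far above the mean would make G1 acceptance vanishingly rare
  if (p$min_mutations_per_G1 > p$mean_mutations_per_G1 +
        5 * sqrt(p$mean_mutations_per_G1))
    stop_format("min_mutations_per_G1 exceeds mean + 5 SD; no G1 male would qualify")
  if (p$mice_per_week < 100L || p$mice_per_week > 900L)
    warning("mice_per_week outside the practical 100-900 screening range",
            call. = FALSE)
  for (f in c("lethal_penetrance", "frac_lethal", "frac_superperformance",
              "frac_nonlearner"))
    if (p[[f]] < 0 || p[[f]] > 1) stop_format("%s must be in [0, 1]", f)
  if (p$super_effect <= 0) stop_format("super_effect must be > 0")
  if (abs(p$baseline_slope_corr) > 1)
    stop_format("baseline_slope_corr must be in [-1, 1]")
  p
}

#' @export
print.sim_params <- function(x, ...) {
  cat("<sim_params>\n")
  for (nm in names(x)) {
    v <- x[[nm]]
    cat(sprintf("  %-24s %s\n", nm, paste(format(v, digits = 4),
                                          collapse = ", ")))
  }
  invisible(x)
}

#' Full run configuration
#'
#' Flat key/value configuration covering both the simulator ([sim_params()])
#' and the analysis stages; serializable to a flat YAML file. Unknown keys
#' are rejected on construction and on read.
#'
#' @param ... overrides of any simulator or analysis default. Analysis keys:
#'   `n_pedigrees` (12), `reference` (`"wt"` or `"cohort"` Z-score
#'   reference), `scaling` (`"per_trial"` or `"pooled"` weekly factor),
#'   `dbscan_eps` (`"auto"` = k-distance elbow, or a number),
#'   `dbscan_min_pts` (10), `outlier_sd` (3), `mutation_count_cap` (15),
#'   `alpha` (0.05), `genes_total` (25000), `genes_autosomal` (24000),
#'   `saturation_k` (5), `saturation_m` (6), `map_phenotype`
#'   (`"avg_normalized"`; see [association_scan()]), `phenotype_trial` (6).
#' @return a classed flat list (`run_config`).
#' @export
run_config <- function(...) {
  cfg <- c(unclass(sim_params()),
           list(n_pedigrees = 12L,
                reference = "wt",
                scaling = "per_trial",
                dbscan_eps = "auto",
                dbscan_min_pts = 10L,
                outlier_sd = 3,
                mutation_count_cap = 15L,
                alpha = 0.05,
                genes_total = 25000L,
                genes_autosomal = 24000L,
                saturation_k = 5L,
                saturation_m = 6L,
                map_phenotype = "avg_normalized",
                phenotype_trial = 6L))
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad))
    stop_format("unknown run_config field(s): %s", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  validate_sim_params(do.call(sim_params, cfg[names(unclass(sim_params()))]))
  structure(cfg, class = "run_config")
}

#' @rdname run_config
#' @param x a `run_config`.
#' @return `as_sim_params()`: the embedded [sim_params()].
#' @export
as_sim_params <- function(x) {
  stopifnot(inherits(x, "run_config"))
  do.call(sim_params, unclass(x)[names(unclass(sim_params()))])
}

#' Read / write a run configuration
#'
#' The on-disk format is a flat YAML mapping (key: value); vector-valued
#' keys (ranges, probabilities) are YAML sequences.
#'
#' @param path file path.
#' @param cfg a [run_config()].
#' @return `read_run_config()` a `run_config`; `write_run_config()` the
#'   path, invisibly.
#' @export
read_run_config <- function(path) {
  if (!file.exists(path)) stop_format("config file not found: '%s'", path)
  vals <- yaml::read_yaml(path)
  if (!is.list(vals)) stop_format("config file must be a flat key/value mapping")
  vals <- lapply(vals, function(v) if (is.list(v)) unlist(v) else v)
  if (!is.null(vals$n_super_pedigrees) && is.na(vals$n_super_pedigrees))
    vals$n_super_pedigrees <- NA_integer_
  do.call(run_config, vals)
}

#' @rdname read_run_config
#' @export
write_run_config <- function(cfg, path) {
  stopifnot(inherits(cfg, "run_config"))
  # named vectors become YAML maps so their names survive the round trip
  out <- lapply(unclass(cfg), function(v)
    if (!is.null(names(v))) as.list(v) else v)
  yaml::write_yaml(out, path)
  invisible(path)
}
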