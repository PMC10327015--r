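#' Run the full screen pipeline
#'
#' One reproducible end-to-end run: simulate a synthetic screen, score it
#' against weekly wild-type controls, extract learning features, cluster
#' mice into learning / non-learning groups and compare them, flag lethal
#' mutations from Mendelian distortion, scan genotype-phenotype
#' associations and rank candidates, compute outlier-performance rates,
#' mutation-load and survival-load summaries, the genome-saturation
#' estimate, and the spontaneous-mutation-rate arithmetic seeded with the
#' observed outlier fractions. A single seed is expanded into independent
#' per-stage streams, so re-running with the same config and seed
#' reproduces every numeric field.
#'
#' @param config a [run_config()].
#' @param seed master RNG seed.
#' @param out_dir optional directory; when given, the four dataset TSVs,
#'   the config and `report.json` are written there.
#' @return a `run_report` list with per-stage summaries.
#' @export
run_screen <- function(config = run_config(), seed = 1L, out_dir = NULL) {
  stopifnot(inherits(config, "run_config"))
  params <- as_sim_params(config)

  ds <- simulate_screen(params, n_pedigrees = config$n_pedigrees, seed = seed)
  scores <- score_screen(ds, reference = config$reference,
                         scaling = config$scaling)
  lp <- learning_params(scores)
  g3_ids <- ds$mice$mouse_id[ds$mice$generation == "G3"]
  lp_g3 <- lp[lp$mouse_id %in% g3_ids, , drop = FALSE]

  # clustering runs on median-smoothed curves; statistics stay unsmoothed
  lp_smooth <- learning_params(scores, smooth = TRUE)
  cl <- cluster_learning(lp_smooth[lp_smooth$mouse_id %in% g3_ids, ,
                                   drop = FALSE],
                         eps = config$dbscan_eps,
                         min_pts = config$dbscan_min_pts)
  gt <- if (!cl$no_separation &&
            min(table(cl$labels$label)[c("learning", "non_learning")],
                na.rm = TRUE) >= 2L)
    group_tests(lp_g3, cl$labels) else NULL

  lethals <- detect_lethals(ds, alpha = config$alpha)
  linkage <- association_scan(ds, scores, phenotype = config$map_phenotype,
                              trial = config$phenotype_trial)
  candidates <- candidate_rank(linkage)

  nv <- tapply(ds$genotypes$zygosity == "VAR", ds$genotypes$mouse_id, sum)
  counts <- as.integer(nv[lp_g3$mouse_id]); counts[is.na(counts)] <- 0L
  perf_out <- outlier_rates(
    detect_outliers(lp_g3$avg_performance, n_sd = config$outlier_sd,
                    ids = lp_g3$mouse_id), ds)
  learn_out <- outlier_rates(
    detect_outliers(lp_g3$avg_learning_rate, n_sd = config$outlier_sd,
                    ids = lp_g3$mouse_id), ds)
  load <- load_analysis(counts, lp_g3, cap = config$mutation_count_cap)
  surv <- survival_fit(ds)
  sat <- saturation_estimate(ds, k = config$saturation_k,
                             m = config$saturation_m,
                             genes_total = config$genes_total,
                             genes_autosomal = config$genes_autosomal)
  evo <- list(
    performance = evolution_probability(mutation_rate_preset("mouse_hi"),
                                        100 * perf_out$fraction),
    learning = evolution_probability(mutation_rate_preset("mouse_hi"),
                                     100 * learn_out$fraction))

  report <- structure(list(
    schema_version = "1.0",
    seed = seed,
    config = unclass(config),
    dataset = list(n_mice = nrow(ds$mice),
                   n_g3_tested = sum(lp$mouse_id %in% g3_ids),
                   n_wt = sum(ds$mice$generation == "WT"),
                   n_mutations = nrow(ds$mutations),
                   n_weeks = length(unique(
                     ds$mice$week[ds$mice$mouse_id %in% ds$trials$mouse_id]))),
    scoring = list(weeks_scored = length(unique(scores$week)),
                   wt_normalized_mean = mean(
                     scores$normalized[scores$mouse_id %in%
                       ds$mice$mouse_id[ds$mice$generation == "WT"]])),
    clusters = list(no_separation = cl$no_separation,
                    sizes = as.list(table(cl$labels$label)),
                    eps = cl$eps,
                    summary = cl$summary,
                    tests = gt),
    lethality = list(n_tested = sum(!is.na(lethals$p_distortion)),
                     n_flagged = sum(lethals$lethal_flag, na.rm = TRUE)),
    candidates = utils::head(candidates, 10L),
    outliers = list(
      performance = perf_out[c("n", "n_outliers", "fraction", "n_mice",
                               "n_var_calls", "mice_per_outlier",
                               "hom_mutations_per_outlier")],
      learning = learn_out[c("n", "n_outliers", "fraction", "n_mice",
                             "n_var_calls", "mice_per_outlier",
                             "hom_mutations_per_outlier")]),
    load = load[c("bins", "fits", "cap", "cor_initial_learning")],
    survival = surv[c("a", "b", "se_b", "r_squared", "p_slope",
                      "degenerate")],
    saturation = sat[c("n_genes_autosomal", "n_genes_all",
                       "fraction_autosomal", "fraction_all", "k", "m")],
    evolution = list(
      performance = unclass(evo$performance)[1:5],
      learning = unclass(evo$learning)[1:5]),
    truth = ds$truth[c("nonlearner_ids", "effect_mutations")]),
    class = "run_report")

  if (!is.null(out_dir)) {
    write_screen(ds, out_dir)
    write_run_config(config, file.path(out_dir, "config.yaml"))
    jsonlite::write_json(report_for_json(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  report
}

# strip S3 classes so jsonlite serializes plain lists and data.frames
report_for_json <- function(x) {
  if (is.data.frame(x)) {
    class(x) <- "data.frame"
    x
  } else if (is.list(x)) {
    lapply(x, report_for_json)
  } else x
}

#' @export
print.run_report <- function(x, ...) {
  cat("<run_report>\n")
  cat(sprintf("  seed %s; %d pedigrees, %d mutations, %d G3 mice tested over %d weeks\n",
              x$seed, x$config$n_pedigrees, x$dataset$n_mutations,
              x$dataset$n_g3_tested, x$dataset$n_weeks))
  cat(sprintf("  WT normalized mean: %.6f\n", x$scoring$wt_normalized_mean))
  sz <- x$clusters$sizes
  cat(sprintf("  clusters: %s%s\n",
              paste(sprintf("%s %s", names(sz), unlist(sz)), collapse = ", "),
              if (x$clusters$no_separation) " [no separation]" else ""))
  cat(sprintf("  lethality: %d of %d tested mutations flagged\n",
              x$lethality$n_flagged, x$lethality$n_tested))
  po <- x$outliers$performance
  cat(sprintf("  performance outliers: %d (%.2f%%), %.0f mice and %.0f homozygous mutations per outlier\n",
              po$n_outliers, 100 * po$fraction,
              po$mice_per_outlier, po$hom_mutations_per_outlier))
  cat(sprintf("  saturation: %.1f%% autosomal, %.1f%% all genes\n",
              100 * x$saturation$fraction_autosomal,
              100 * x$saturation$fraction_all))
  invisible(x)
}
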