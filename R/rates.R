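#' Detect outlier performers
#'
#' Flags values more than `n_sd` standard deviations above the mean — the
#' operational definition of outlier (super)performance, motivated by
#' wild-type cohorts in which no mouse strays beyond 3 SD. One-sided above
#' the mean by default; `direction = "both"` also takes the lower tail.
#' Mean and SD default to the scanned cohort itself; a wild-type reference
#' can be supplied instead via `center`/`spread`.
#'
#' @param values numeric vector (length >= 2), e.g. per-mouse average
#'   T-score or average learning rate.
#' @param n_sd threshold in standard deviations (default 3).
#' @param direction `"above"` (default) or `"both"`.
#' @param center,spread optional reference mean and SD (default: computed
#'   from `values`).
#' @param ids optional identifiers aligned with `values`.
#' @return an `outlier_report` list: `mean`, `sd`, `threshold`,
#'   `n_outliers`, `fraction`, `outlier_ids`, `outliers` (logical).
#' @export
detect_outliers <- function(values, n_sd = 3, direction = c("above", "both"),
                            center = NULL, spread = NULL, ids = NULL) {
  direction <- match.arg(direction)
  values <- as.numeric(values)
  if (length(values) < 2L) stop_format("need at least 2 values")
  mu <- center %||% mean(values)
  sdv <- spread %||% stats::sd(values)
  if (!is.finite(sdv) || sdv == 0) {
    warning("zero spread: no outliers detectable", call. = FALSE)
    out <- rep(FALSE, length(values))
  } else {
    out <- values > mu + n_sd * sdv
    if (direction == "both") out <- out | values < mu - n_sd * sdv
  }
  structure(list(
    mean = mu, sd = sdv, n_sd = n_sd, direction = direction,
    threshold = mu + n_sd * sdv,
    n = length(values), n_outliers = sum(out),
    fraction = sum(out) / length(values),
    outliers = out,
    outlier_ids = if (!is.null(ids)) ids[out] else which(out)),
    class = "outlier_report")
}

#' @export
print.outlier_report <- function(x, ...) {
  cat(sprintf("<outlier_report> %d of %d values above mean %.2f + %g x SD %.2f (threshold %.2f): %.2f%%\n",
              x$n_outliers, x$n, x$mean, x$n_sd, x$sd, x$threshold,
              100 * x$fraction))
  invisible(x)
}

#' Outlier rates per mouse and per homozygous mutation
#'
#' Completes an [detect_outliers()] report with the screen-level rates:
#' how many mice were screened per outlier, and how many homozygous
#' mutation calls were examined per outlier. Raw numerators and
#' denominators are always carried so any rounding is auditable.
#'
#' @param report an `outlier_report`.
#' @param n_mice total mutant mice screened (or a `screen_dataset`, from
#'   which tested G3 mice and VAR calls are counted).
#' @param n_var_calls total homozygous (VAR) calls across those mice.
#' @return the report, with `n_mice`, `n_var_calls`, `mice_per_outlier`,
#'   `hom_mutations_per_outlier` and `infinite_rate` added.
#' @export
outlier_rates <- function(report, n_mice, n_var_calls = NULL) {
  stopifnot(inherits(report, "outlier_report"))
  if (inherits(n_mice, "screen_dataset")) {
    ds <- n_mice
    g3_tested <- intersect(
      ds$mice$mouse_id[ds$mice$generation == "G3"], ds$trials$mouse_id)
    n_mice <- length(g3_tested)
    n_var_calls <- sum(ds$genotypes$zygosity == "VAR" &
                         ds$genotypes$mouse_id %in% g3_tested)
  }
  report$n_mice <- n_mice
  report$n_var_calls <- n_var_calls
  report$infinite_rate <- report$n_outliers == 0L
  report$mice_per_outlier <- if (report$infinite_rate) Inf
    else n_mice / report$n_outliers
  report$hom_mutations_per_outlier <-
    if (is.null(n_var_calls)) NA_real_
    else if (report$infinite_rate) Inf
    else n_var_calls / report$n_outliers
  report
}

#' Mutation-load analysis
#'
#' Bins mice by their homozygous mutation count and summarizes performance
#' per bin (n, mean average T-score, mean initial score, mean learning
#' rate, coefficient of variation of average T-score). Beyond some load
#' the variability of performance changes drastically; fits of performance
#' against load are therefore restricted to counts at or below `cap`
#' (default 15). Reports least-squares slopes (with SE and p) of average
#' T-score, initial score and learning rate on mutation count over
#' individual mice with `count <= cap`, and the per-mouse correlation
#' between initial performance and learning rate.
#'
#' @param counts integer vector of per-mouse homozygous mutation counts.
#' @param lp matching [learning_params()] rows (same order).
#' @param cap maximum count included in the fits (default 15).
#' @param min_bin_n bins with fewer mice are dropped from the bin summary
#'   fits display (default 1, i.e. keep all).
#' @return a `load_analysis` list: `bins` (per-count summary), `fits`
#'   (slope table), `cor_initial_learning`, `cap`.
#' @export
load_analysis <- function(counts, lp, cap = 15L, min_bin_n = 1L) {
  stopifnot(length(counts) == nrow(lp))
  counts <- as.integer(counts)
  byc <- split(seq_along(counts), counts)
  bins <- do.call(rbind, lapply(names(byc), function(k) {
    i <- byc[[k]]
    avg <- lp$avg_performance[i]
    data.frame(count = as.integer(k), n = length(i),
               mean_avg_t = mean(avg),
               mean_initial = mean(lp$initial_performance[i]),
               mean_learning_rate = mean(lp$avg_learning_rate[i]),
               cv = if (length(i) > 1L && mean(avg) != 0)
                 stats::sd(avg) / abs(mean(avg)) else NA_real_)
  }))
  bins <- bins[bins$n >= min_bin_n, , drop = FALSE]

  keep <- counts <= cap
  fits <- NULL
  if (length(unique(counts[keep])) >= 3L) {
    fit1 <- function(metric, y) {
      f <- ols_columns(y[keep], cbind(counts[keep]))
      cbind(metric = metric, f)
    }
    fits <- rbind(fit1("avg_performance", lp$avg_performance),
                  fit1("initial_performance", lp$initial_performance),
                  fit1("avg_learning_rate", lp$avg_learning_rate))
  } else {
    log_msg("fewer than 3 populated count bins at or below cap; fits skipped")
  }
  structure(list(
    bins = bins, fits = fits, cap = cap,
    cor_initial_learning = stats::cor(lp$initial_performance,
                                      lp$avg_learning_rate)),
    class = "load_analysis")
}

#' @export
print.load_analysis <- function(x, ...) {
  cat(sprintf("<load_analysis> %d count bins, fit cap %d, cor(initial, learning) = %.3f\n",
              nrow(x$bins), x$cap, x$cor_initial_learning))
  if (!is.null(x$fits)) print(x$fits, row.names = FALSE)
  invisible(x)
}

#' Logarithmic survival-load fit
#'
#' Least-squares fit of the number of surviving mice per homozygous
#' mutation count to `a + b * ln(count)`, for counts >= 1 (a count of zero
#' never enters the log term). Captures the observed pattern that
#' survivors thin out logarithmically as mutation load grows.
#'
#' @param counts mutation-count bin values (>= 0), or a `screen_dataset`
#'   (per-mouse VAR counts and weaning survival are tallied internally).
#' @param n_surviving surviving mice per bin, aligned with `counts`.
#' @return a `survival_fit` list: `a`, `b`, `se_b`, `r_squared`,
#'   `p_slope`, `degenerate` flag, and the fitted table.
#' @export
survival_fit <- function(counts, n_surviving = NULL) {
  if (inherits(counts, "screen_dataset")) {
    ds <- counts
    g3 <- ds$mice[ds$mice$generation == "G3", ]
    nv <- tapply(ds$genotypes$zygosity == "VAR", ds$genotypes$mouse_id, sum)
    k <- as.integer(nv[g3$mouse_id]); k[is.na(k)] <- 0L
    surv <- tapply(g3$survived_to_weaning, k, sum)
    counts <- as.integer(names(surv))
    n_surviving <- as.integer(surv)
  }
  stopifnot(length(counts) == length(n_surviving))
  keep <- counts >= 1L
  x <- log(counts[keep]); y <- n_surviving[keep]
  if (length(unique(x)) < 2L || stats::var(y) == 0) {
    return(structure(list(a = NA_real_, b = NA_real_, se_b = NA_real_,
                          r_squared = NA_real_, p_slope = NA_real_,
                          degenerate = TRUE,
                          table = data.frame(count = counts,
                                             n_surviving = n_surviving)),
                     class = "survival_fit"))
  }
  f <- ols_columns(y, cbind(x))
  a <- mean(y) - f$effect * mean(x)
  ss_tot <- sum((y - mean(y))^2)
  ss_res <- sum((y - (a + f$effect * x))^2)
  structure(list(a = a, b = f$effect, se_b = f$se,
                 r_squared = 1 - ss_res / ss_tot, p_slope = f$p,
                 degenerate = FALSE,
                 table = data.frame(count = counts,
                                    n_surviving = n_surviving)),
            class = "survival_fit")
}

#' @export
print.survival_fit <- function(x, ...) {
  if (x$degenerate) cat("<survival_fit> degenerate (flat or single bin)\n")
  else cat(sprintf("<survival_fit> n = %.2f %+.2f ln(count); R^2 = %.3f, slope p = %.3g\n",
                   x$a, x$b, x$r_squared, x$p_slope))
  invisible(x)
}

#' Evolutionary probability of a behavior-modifying homozygous mutation
#'
#' Reproduces the spontaneous-mutation arithmetic for the chance emergence
#' of a behavior-modifying homozygous mutation: with a per-base-pair
#' per-replication rate r, a specific homozygous mutation arises at
#' probability r x r; multiplying by the fraction of homozygous mutations
#' found to modify the behavior (0.15 for motor performance, 0.27 for
#' motor learning, each entered as printed, i.e. the percentage figure
#' used as a bare factor) gives the modified probability, also expressed
#' in percent of mutations per replication as `modified / r x 100`.
#' `strict_percent = TRUE` instead divides the factor by 100 (0.0015 /
#' 0.0027) for users who want the literal percentage interpretation.
#'
#' @param rate per-base-pair per-replication mutation rate (> 0); see
#'   [rate_table()] for published presets.
#' @param factor behavior-modifying fraction as printed (e.g. 0.15).
#' @param strict_percent treat `factor` as a percentage (divide by 100)?
#' @return an `evolution_estimate` list: `per_bp_rate`,
#'   `homozygous_probability` (= rate^2), `modifying_factor`,
#'   `modified_probability` (= rate^2 x factor), `percent_form`
#'   (= modified / rate x 100).
#' @export
evolution_probability <- function(rate, factor = 0.15,
                                  strict_percent = FALSE) {
  if (!is.numeric(rate) || rate <= 0) stop_format("rate must be > 0")
  if (!is.numeric(factor) || factor < 0) stop_format("factor must be >= 0")
  f <- if (strict_percent) factor / 100 else factor
  hom <- rate * rate
  modified <- hom * f
  structure(list(per_bp_rate = rate,
                 homozygous_probability = hom,
                 modifying_factor = f,
                 modified_probability = modified,
                 percent_form = modified / rate * 100,
                 strict_percent = strict_percent),
            class = "evolution_estimate")
}

#' @export
print.evolution_estimate <- function(x, ...) {
  cat("<evolution_estimate>\n")
  cat(sprintf("  rate per bp per replication: %.3g\n", x$per_bp_rate))
  cat(sprintf("  homozygous probability r^2:  %.3g\n",
              x$homozygous_probability))
  cat(sprintf("  modifying factor:            %.4g\n", x$modifying_factor))
  cat(sprintf("  modified probability:        %.3g (%.3g%% of mutations per replication)\n",
              x$modified_probability, x$percent_form))
  invisible(x)
}

#' Published spontaneous mutation-rate estimates
#'
#' The five published per-base-pair per-replication spontaneous
#' mutation-rate estimates used as presets for
#' [evolution_probability()]: three for mouse, two for human.
#'
#' @return data.frame with `preset`, `rate`, `organism`.
#' @export
rate_table <- function() {
  data.frame(
    preset = c("mouse_lo", "mouse_mid", "mouse_hi", "human_lo", "human_hi"),
    rate = c(1.8e-10, 5.4e-9, 7.9e-9, 5.0e-11, 1.2e-8),
    organism = c("mouse", "mouse", "mouse", "human", "human"),
    stringsAsFactors = FALSE)
}

#' @rdname rate_table
#' @param preset one of the preset names in `rate_table()`.
#' @return `mutation_rate_preset()`: the rate as a number.
#' @export
mutation_rate_preset <- function(preset) {
  tab <- rate_table()
  i <- match(preset, tab$preset)
  if (is.na(i))
    stop_format("unknown preset '%s'; valid presets: %s", preset,
                paste(tab$preset, collapse = ", "))
  tab$rate[i]
}
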