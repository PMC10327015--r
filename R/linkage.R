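#' Tabulate zygosity among G3 offspring
#'
#' Counts REF/HET/VAR calls per mutation among genotyped G3 mice and
#' computes the Mendelian expectation for the VAR fraction from each
#' mouse's dam: with a heterozygous sire throughout, a heterozygous dam
#' contributes VAR offspring at 1/4 and a reference dam at 0. Offspring of
#' heterozygous dams are the informative ones for a homozygote deficit.
#'
#' @param dataset a [screen_dataset()].
#' @return a `zygosity_table` data.frame, one row per mutation:
#'   `mutation_id`, `gene_id`, `pedigree_id`, `n_ref`, `n_het`, `n_var`,
#'   `n_genotyped`, `n_informative` (het-dam offspring), and
#'   `expected_var_frac` (mean expectation over genotyped offspring).
#'   Mutations with no genotyped G3 mice are excluded.
#' @export
tabulate_zygosity <- function(dataset) {
  stopifnot(inherits(dataset, "screen_dataset"))
  mice <- dataset$mice
  g3 <- mice$mouse_id[mice$generation == "G3"]
  g <- dataset$genotypes[dataset$genotypes$mouse_id %in% g3, , drop = FALSE]
  if (nrow(g) == 0L)
    return(structure(data.frame(), class = c("zygosity_table", "data.frame")))
  dam <- mice$dam_id[match(g$mouse_id, mice$mouse_id)]
  damkey <- paste(dam, g$mutation_id)
  genokey <- paste(dataset$genotypes$mouse_id, dataset$genotypes$mutation_id)
  dam_zyg <- dataset$genotypes$zygosity[match(damkey, genokey)]
  informative <- !is.na(dam_zyg) & dam_zyg == "HET"

  f <- factor(g$mutation_id)
  counts <- function(lvl) as.integer(tapply(g$zygosity == lvl, f, sum))
  out <- data.frame(
    mutation_id = levels(f),
    n_ref = counts("REF"), n_het = counts("HET"), n_var = counts("VAR"),
    n_genotyped = as.integer(table(f)),
    n_informative = as.integer(tapply(informative, f, sum)),
    stringsAsFactors = FALSE)
  out$expected_var_frac <- 0.25 * out$n_informative / out$n_genotyped
  mm <- match(out$mutation_id, dataset$mutations$mutation_id)
  out <- cbind(out[1L], gene_id = dataset$mutations$gene_id[mm],
               pedigree_id = sub("_M[0-9]+$", "", out$mutation_id),
               out[-1L])
  missing <- setdiff(dataset$mutations$mutation_id, out$mutation_id)
  if (length(missing))
    log_msg("excluding %d mutation(s) with no genotyped G3 mice",
            length(missing))
  structure(out, class = c("zygosity_table", "data.frame"))
}

#' Exact test for Mendelian-ratio distortion
#'
#' One-sided exact binomial test for a deficit of homozygous (VAR)
#' offspring against the segregation expectation — the signature of a
#' recessive lethal allele. Only a deficit is tested; an excess of
#' homozygotes is not the phenotype sought.
#'
#' @param n_var observed VAR offspring among the informative (het-dam)
#'   offspring.
#' @param n_informative number of informative offspring.
#' @param expected expected VAR fraction among informative offspring
#'   (1/4 under het x het).
#' @return the lower-tail exact binomial p-value.
#' @export
mendelian_distortion_test <- function(n_var, n_informative, expected = 0.25) {
  if (expected <= 0 || n_informative < 1L)
    stop_format("distortion test needs a positive expected fraction and offspring")
  stats::binom.test(n_var, n_informative, p = expected,
                    alternative = "less")$p.value
}

#' Flag probable lethal mutations from ratio distortion
#'
#' Applies [mendelian_distortion_test()] to every mutation in a
#' [tabulate_zygosity()] table and flags those whose homozygote deficit
#' survives a Bonferroni correction across the mutations of the same
#' pedigree. Mutations with no informative offspring, or fewer than
#' `min_genotyped` genotyped mice, are skipped (`p = NA`).
#'
#' @param zygosity a `zygosity_table` (or a `screen_dataset`, tabulated
#'   internally).
#' @param alpha significance level before correction (default 0.05).
#' @param correction `"bonferroni"` within pedigree (default) or `"BH"`
#'   across the screen.
#' @param min_genotyped minimum genotyped G3 mice for the test (default 10).
#' @return the table with columns `p_distortion`, `p_threshold`,
#'   `lethal_flag` appended.
#' @export
detect_lethals <- function(zygosity, alpha = 0.05,
                           correction = c("bonferroni", "BH"),
                           min_genotyped = 10L) {
  if (inherits(zygosity, "screen_dataset"))
    zygosity <- tabulate_zygosity(zygosity)
  correction <- match.arg(correction)
  z <- as.data.frame(zygosity)
  testable <- z$n_informative > 0L & z$n_genotyped >= min_genotyped
  z$p_distortion <- NA_real_
  z$p_distortion[testable] <- mapply(
    function(x, n) mendelian_distortion_test(x, n, 0.25),
    z$n_var[testable], z$n_informative[testable])
  if (correction == "bonferroni") {
    n_tests <- stats::ave(as.numeric(testable), z$pedigree_id, FUN = sum)
    z$p_threshold <- alpha / pmax(n_tests, 1)
    z$lethal_flag <- !is.na(z$p_distortion) & z$p_distortion < z$p_threshold
  } else {
    z$p_threshold <- alpha
    padj <- rep(NA_real_, nrow(z))
    padj[testable] <- stats::p.adjust(z$p_distortion[testable], "BH")
    z$lethal_flag <- !is.na(padj) & padj < alpha
  }
  structure(z, class = c("zygosity_table", "data.frame"))
}

# closed-form simple linear regression of y on each column of X;
# algebraically identical to stats::lm per column (cross-checked in tests)
ols_columns <- function(y, X) {
  n <- length(y)
  sx <- colSums(X); sy <- sum(y)
  sxx <- colSums(X^2); sxy <- as.vector(crossprod(X, y)); syy <- sum(y^2)
  Sxx <- sxx - sx^2 / n
  Sxy <- sxy - sx * sy / n
  Syy <- syy - sy^2 / n
  b <- ifelse(Sxx > 0, Sxy / Sxx, NA_real_)
  rss <- pmax(Syy - b * Sxy, 0)
  df <- n - 2L
  s2 <- if (df > 0) rss / df else rep(NA_real_, length(rss))
  se <- sqrt(s2 / Sxx)
  tval <- b / se
  p <- 2 * stats::pt(-abs(tval), df)
  data.frame(effect = b, se = se, t = tval, p = p, n = n)
}

#' Genotype-phenotype association scan
#'
#' Per-mutation least-squares regression of a phenotype on a genotype
#' coding, within each pedigree, under one or all of three inheritance
#' codings: recessive (VAR = 1, else 0), additive (REF = 0, HET = 1,
#' VAR = 2) and dominant (HET/VAR = 1). Reports effect (phenotype units per
#' coding unit), standard error and two-sided p-value, with multiple-
#' testing correction by Bonferroni within pedigree (default) or
#' Benjamini-Hochberg across the screen. The recessive model requires at
#' least `min_var` homozygous mice; codings that are constant within the
#' pedigree yield `NA`.
#'
#' @param dataset a [screen_dataset()].
#' @param scores a [score_screen()] result for the same dataset.
#' @param phenotype `"avg_normalized"` (default: per-mouse mean weekly
#'   normalized score over the six trials, which integrates a latency
#'   multiplier across the whole series), `"normalized"` (single-trial
#'   normalized score at `trial`) or `"learning_rate"` (average T-score
#'   learning rate).
#' @param trial trial used for the `"normalized"` phenotype (default 6).
#' @param model `"all"` (default) or one of `"recessive"`, `"additive"`,
#'   `"dominant"`.
#' @param min_var minimum homozygotes for the recessive model (default 3).
#' @param p_adjust `"bonferroni"` (within pedigree) or `"BH"` (screen-wide).
#' @return a `linkage_result` data.frame, one row per mutation x model:
#'   `mutation_id`, `gene_id`, `pedigree_id`, `model`, `n_ref`, `n_het`,
#'   `n_var`, `effect`, `se`, `p`, `p_adj`.
#' @export
association_scan <- function(dataset, scores,
                             phenotype = c("avg_normalized", "normalized",
                                           "learning_rate"),
                             trial = 6L,
                             model = c("all", "recessive", "additive",
                                       "dominant"),
                             min_var = 3L,
                             p_adjust = c("bonferroni", "BH")) {
  stopifnot(inherits(dataset, "screen_dataset"),
            inherits(scores, "score_matrix"))
  phenotype <- match.arg(phenotype)
  model <- match.arg(model)
  p_adjust <- match.arg(p_adjust)
  models <- if (model == "all") inheritance_modes else model

  if (phenotype == "avg_normalized") {
    ph <- tapply(scores$normalized, scores$mouse_id, mean)
    ph <- stats::setNames(as.numeric(ph), names(ph))
  } else if (phenotype == "normalized") {
    sel <- scores[scores$trial == trial, ]
    ph <- stats::setNames(sel$normalized, sel$mouse_id)
  } else {
    lp <- learning_params(scores)
    ph <- stats::setNames(lp$avg_learning_rate, lp$mouse_id)
  }

  mice <- dataset$mice
  g3 <- mice[mice$generation == "G3" & mice$mouse_id %in% names(ph), ]
  res <- list()
  for (ped in unique(g3$pedigree_id)) {
    ids <- g3$mouse_id[g3$pedigree_id == ped]
    y <- ph[ids]
    g <- dataset$genotypes[dataset$genotypes$mouse_id %in% ids, ]
    if (nrow(g) == 0L) next
    mut_ids <- sort(unique(g$mutation_id))
    dose <- matrix(0L, length(ids), length(mut_ids),
                   dimnames = list(ids, mut_ids))
    dose[cbind(match(g$mouse_id, ids), match(g$mutation_id, mut_ids))] <-
      ifelse(g$zygosity == "VAR", 2L, ifelse(g$zygosity == "HET", 1L, 0L))
    n_ref <- colSums(dose == 0L); n_het <- colSums(dose == 1L)
    n_var <- colSums(dose == 2L)
    for (mod in models) {
      X <- switch(mod,
                  recessive = (dose == 2L) * 1,
                  additive = dose * 1,
                  dominant = (dose >= 1L) * 1)
      fit <- ols_columns(y, X)
      if (mod == "recessive")
        fit[n_var < min_var, c("effect", "se", "t", "p")] <- NA_real_
      res[[length(res) + 1L]] <- data.frame(
        mutation_id = mut_ids, pedigree_id = ped, model = mod,
        n_ref = n_ref, n_het = n_het, n_var = n_var,
        effect = fit$effect, se = fit$se, p = fit$p,
        row.names = NULL, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, res)
  if (is.null(out)) stop_format("no genotyped G3 mice with phenotypes")
  out$gene_id <- dataset$mutations$gene_id[
    match(out$mutation_id, dataset$mutations$mutation_id)]
  if (p_adjust == "bonferroni") {
    n_tests <- stats::ave(as.numeric(!is.na(out$p)),
                          paste(out$pedigree_id, out$model), FUN = sum)
    out$p_adj <- pmin(out$p * pmax(n_tests, 1), 1)
  } else {
    out$p_adj <- stats::ave(out$p, out$model,
                            FUN = function(p) stats::p.adjust(p, "BH"))
  }
  out <- out[, c("mutation_id", "gene_id", "pedigree_id", "model",
                 "n_ref", "n_het", "n_var", "effect", "se", "p", "p_adj")]
  structure(out, phenotype = phenotype, trial = trial,
            class = c("linkage_result", "data.frame"))
}

#' Rank candidate mutations
#'
#' Collapses a [association_scan()] result to its best (smallest-p) model
#' per mutation and ranks candidates by the tuple (p ascending, |effect|
#' descending, homozygote count descending). On a performance phenotype a
#' positive effect — longer latency in carriers — is labeled
#' super-performance, a negative one sub-performance.
#'
#' @param linkage a `linkage_result`.
#' @return data.frame of per-mutation best rows with `direction`,
#'   `candidate_score` (-log10 p) and `rank`.
#' @export
candidate_rank <- function(linkage) {
  stopifnot(inherits(linkage, "linkage_result"))
  lr <- as.data.frame(linkage)
  lr <- lr[!is.na(lr$p), , drop = FALSE]
  if (nrow(lr) == 0L) return(lr)
  best <- do.call(rbind, lapply(split(lr, lr$mutation_id),
                                function(d) d[which.min(d$p), , drop = FALSE]))
  ord <- order(best$p, -abs(best$effect), -best$n_var)
  best <- best[ord, , drop = FALSE]
  best$direction <- ifelse(best$effect > 0, "super-performance",
                           "sub-performance")
  best$candidate_score <- -log10(best$p)
  best$rank <- seq_len(nrow(best))
  rownames(best) <- NULL
  best
}

#' Genome saturation estimate
#'
#' Fraction of genes carrying a severely damaging or destroying mutation
#' that was brought to homozygosity in at least `k` G3 mice, each tested
#' `m` times on the rotarod. Reported both against the autosomal gene
#' universe (the mutagenized fraction of the genome; the X chromosome of
#' G3 mice is wild-type derived) and against all genes.
#'
#' @param dataset a [screen_dataset()].
#' @param k minimum homozygous (VAR) tested mice per mutation (default 5).
#' @param m required trials per mouse (default 6).
#' @param severe_classes damage classes counted as severe damage or
#'   destruction.
#' @param genes_total,genes_autosomal gene universe sizes (defaults 25000
#'   and 24000).
#' @return a `saturation_report` list: qualifying gene counts and
#'   fractions (autosomal and all-chromosome), plus per-damage-class
#'   mutation tallies.
#' @export
saturation_estimate <- function(dataset, k = 5L, m = 6L,
                                severe_classes = c("probably_damaging",
                                                   "probably_null"),
                                genes_total = 25000L,
                                genes_autosomal = 24000L) {
  stopifnot(inherits(dataset, "screen_dataset"))
  if (k < 1L || m < 1L) stop_format("k and m must be >= 1")
  tri <- dataset$trials
  n_trials <- rowSums(is.finite(as.matrix(tri[paste0("trial_", 1:6)])))
  tested_ids <- tri$mouse_id[n_trials >= m]
  g3 <- dataset$mice$mouse_id[dataset$mice$generation == "G3"]
  g <- dataset$genotypes
  vv <- g[g$zygosity == "VAR" & g$mouse_id %in% intersect(tested_ids, g3), ]
  n_var_tested <- table(vv$mutation_id)
  muts <- dataset$mutations
  muts$n_var_tested <- as.integer(n_var_tested[muts$mutation_id])
  muts$n_var_tested[is.na(muts$n_var_tested)] <- 0L
  qual <- muts$damage_class %in% severe_classes & muts$n_var_tested >= k
  genes_all <- unique(muts$gene_id[qual])
  genes_auto <- unique(muts$gene_id[qual & muts$chromosome != "X"])
  structure(list(
    k = k, m = m, severe_classes = severe_classes,
    n_genes_autosomal = length(genes_auto),
    n_genes_all = length(genes_all),
    genes_autosomal = genes_autosomal, genes_total = genes_total,
    fraction_autosomal = length(genes_auto) / genes_autosomal,
    fraction_all = length(genes_all) / genes_total,
    damage_class_tally = table(factor(muts$damage_class,
                                      levels = damage_classes)),
    qualifying_mutations = muts$mutation_id[qual]),
    class = "saturation_report")
}

#' @export
print.saturation_report <- function(x, ...) {
  cat("<saturation_report>\n")
  cat(sprintf("  severe classes: %s; >= %d homozygous mice x %d trials\n",
              paste(x$severe_classes, collapse = ", "), x$k, x$m))
  cat(sprintf("  autosomal: %d / %d genes = %.1f%%\n", x$n_genes_autosomal,
              x$genes_autosomal, 100 * x$fraction_autosomal))
  cat(sprintf("  all:       %d / %d genes = %.1f%%\n", x$n_genes_all,
              x$genes_total, 100 * x$fraction_all))
  invisible(x)
}
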