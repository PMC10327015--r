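#' Assemble a screen dataset
#'
#' Bundles the four tables of a forward motor screen — animals, induced
#' mutations, zygosity calls and rotarod trial series — into a validated
#' `screen_dataset` object, the container every downstream stage consumes.
#'
#' @param mice data.frame with columns `mouse_id`, `generation` (one of
#'   `"WT","G1","G2","G3"`), `pedigree_id`, `week` (positive integer; the
#'   weekly testing batch), `tester_id`, `sex` (`"F"`/`"M"`),
#'   `survived_to_weaning` (logical) and `dam_id` (mother's `mouse_id`;
#'   `NA` for WT/G1/G2 animals).
#' @param mutations data.frame with columns `mutation_id`, `gene_id`,
#'   `chromosome`, `damage_class` (one of the five PolyPhen-style classes),
#'   `lethal` (logical), `mode` (`"recessive"`, `"additive"`, `"dominant"`),
#'   `effect_size_performance` (latency multiplier on affected genotypes,
#'   1 = neutral) and `effect_on_learning` (additive per-trial latency change
#'   in seconds, 0 = neutral).
#' @param genotypes long data.frame, one row per (mouse, mutation) pair, with
#'   columns `mouse_id`, `mutation_id`, `zygosity` (`"REF"/"HET"/"VAR"`).
#' @param trials data.frame with columns `mouse_id`, `trial_1` .. `trial_6`
#'   (fall latencies in seconds, non-negative).
#' @param truth optional list of simulation ground truth (non-learner ids,
#'   planted effect mutations); `NULL` for real data.
#' @param validate run [validate_screen()]? Default `TRUE`.
#' @return An object of class `screen_dataset`: a list with elements
#'   `mice`, `mutations`, `genotypes`, `trials`, `truth`.
#' @seealso [read_screen()], [write_screen()], [simulate_screen()]
#' @export
screen_dataset <- function(mice, mutations, genotypes, trials, truth = NULL,
                           validate = TRUE) {
  x <- structure(list(mice = as.data.frame(mice),
                      mutations = as.data.frame(mutations),
                      genotypes = as.data.frame(genotypes),
                      trials = as.data.frame(trials),
                      truth = truth),
                 class = "screen_dataset")
  if (validate) validate_screen(x)
  x
}

mice_cols <- c("mouse_id", "generation", "pedigree_id", "week", "tester_id",
               "sex", "survived_to_weaning", "dam_id")
mutation_cols <- c("mutation_id", "gene_id", "chromosome", "damage_class",
                   "lethal", "mode", "effect_size_performance",
                   "effect_on_learning")
genotype_cols <- c("mouse_id", "mutation_id", "zygosity")
trial_cols <- c("mouse_id", paste0("trial_", 1:6))

#' Validate a screen dataset
#'
#' Checks the structural invariants the analysis relies on: required columns,
#' legal factor levels, referential integrity (every trial series and
#' genotype row resolves to a known mouse/mutation), wild-type animals carry
#' no mutation calls, and every week containing tested mutant mice also
#' contains concurrent wild-type controls.
#'
#' @param x a `screen_dataset`.
#' @return `x`, invisibly; stops with an informative error otherwise.
#' @export
validate_screen <- function(x) {
  stopifnot(inherits(x, "screen_dataset"))
  need <- function(df, cols, name) {
    miss <- setdiff(cols, names(df))
    if (length(miss))
      stop_format("%s table is missing column(s): %s", name,
                  paste(miss, collapse = ", "))
  }
  need(x$mice, mice_cols, "pedigree")
  need(x$mutations, mutation_cols, "mutations")
  need(x$genotypes, genotype_cols, "genotype")
  need(x$trials, trial_cols, "phenotype")

  if (anyDuplicated(x$mice$mouse_id))
    stop_format("duplicated mouse_id in pedigree table")
  bad <- setdiff(x$mice$generation, generations)
  if (length(bad)) stop_format("unknown generation label(s): %s",
                               paste(bad, collapse = ", "))
  bad <- setdiff(x$genotypes$zygosity, zygosity_levels)
  if (length(bad))
    stop_format("zygosity values outside {REF,HET,VAR}: %s",
                paste(unique(bad), collapse = ", "))
  bad <- setdiff(x$mutations$damage_class, damage_classes)
  if (length(bad)) stop_format("unknown damage class(es): %s",
                               paste(bad, collapse = ", "))

  unknown <- setdiff(x$trials$mouse_id, x$mice$mouse_id)
  if (length(unknown))
    stop_format("phenotype rows reference unknown mouse_id(s): %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  unknown <- setdiff(x$genotypes$mouse_id, x$mice$mouse_id)
  if (length(unknown))
    stop_format("genotype rows reference unknown mouse_id(s): %s",
                paste(utils::head(unknown, 5L), collapse = ", "))
  unknown <- setdiff(x$genotypes$mutation_id, x$mutations$mutation_id)
  if (length(unknown))
    stop_format("genotype rows reference unknown mutation_id(s): %s",
                paste(utils::head(unknown, 5L), collapse = ", "))

  lat <- as.matrix(x$trials[, paste0("trial_", 1:6), drop = FALSE])
  if (nrow(lat) && (any(!is.finite(lat)) || any(lat < 0)))
    stop_format("fall latencies must be finite and non-negative")

  wt_ids <- x$mice$mouse_id[x$mice$generation == "WT"]
  if (any(x$genotypes$mouse_id %in% wt_ids))
    stop_format("wild-type mice must not carry mutation calls")

  # every G3 mouse must be genotyped at every mutation of its pedigree
  if (nrow(x$genotypes)) {
    ped_of <- x$mice$pedigree_id[match(x$genotypes$mouse_id, x$mice$mouse_id)]
    ped_muts <- tapply(x$genotypes$mutation_id, ped_of,
                       function(m) length(unique(m)))
    g3 <- x$mice[x$mice$generation == "G3", , drop = FALSE]
    calls <- table(x$genotypes$mouse_id)
    n_calls <- as.integer(calls[g3$mouse_id])
    n_calls[is.na(n_calls)] <- 0L
    expect <- as.integer(ped_muts[g3$pedigree_id])
    bad <- g3$mouse_id[!is.na(expect) & n_calls < expect]
    if (length(bad))
      stop_format("G3 mouse/mice missing zygosity calls for pedigree mutations: %s",
                  paste(utils::head(bad, 5L), collapse = ", "))
  }

  # every week with tested mutant mice needs wild-type controls in that week
  tested <- x$mice[x$mice$mouse_id %in% x$trials$mouse_id, , drop = FALSE]
  if (nrow(tested)) {
    enu_weeks <- unique(tested$week[tested$generation != "WT"])
    wt_weeks <- unique(tested$week[tested$generation == "WT"])
    orphan <- setdiff(enu_weeks, wt_weeks)
    if (length(orphan))
      stop_format("week(s) with tested mutant mice but no wild-type controls: %s",
                  paste(sort(orphan), collapse = ", "))
  }
  invisible(x)
}

#' @export
print.screen_dataset <- function(x, ...) {
  gen <- table(factor(x$mice$generation, levels = generations))
  cat("<screen_dataset>\n")
  cat(sprintf("  mice:      %d (%s)\n", nrow(x$mice),
              paste(sprintf("%s %d", names(gen), gen), collapse = ", ")))
  cat(sprintf("  mutations: %d in %d pedigrees\n", nrow(x$mutations),
              length(unique(x$mice$pedigree_id[x$mice$generation != "WT"]))))
  cat(sprintf("  genotypes: %d zygosity calls (%d VAR)\n", nrow(x$genotypes),
              sum(x$genotypes$zygosity == "VAR")))
  cat(sprintf("  trials:    %d mice with 6-trial rotarod series\n",
              nrow(x$trials)))
  wk <- x$mice$week[x$mice$mouse_id %in% x$trials$mouse_id]
  if (length(wk)) cat(sprintf("  weeks:     %d testing weeks\n",
                              length(unique(wk))))
  invisible(x)
}

#' Write a screen dataset to tab-separated files
#'
#' Writes `pedigree.tsv`, `mutations.tsv`, `genotype.tsv` and
#' `phenotype.tsv` with fixed column order and rows sorted by id, so
#' repeated writes of the same dataset are byte-identical.
#'
#' @param x a `screen_dataset`.
#' @param dir output directory (created if absent).
#' @return named character vector of the four file paths, invisibly.
#' @export
write_screen <- function(x, dir) {
  stopifnot(inherits(x, "screen_dataset"))
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    stop_format("cannot create output directory '%s'", dir)
  w <- function(df, cols, ord, file) {
    df <- df[do.call(order, unname(df[ord])), cols, drop = FALSE]
    path <- file.path(dir, file)
    con <- file(path, open = "wb", encoding = "UTF-8")
    on.exit(close(con), add = TRUE)
    utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE,
                       na = "NA", fileEncoding = "UTF-8", eol = "\n")
    path
  }
  paths <- c(
    pedigree = w(x$mice, mice_cols, "mouse_id", "pedigree.tsv"),
    mutations = w(x$mutations, mutation_cols, "mutation_id", "mutations.tsv"),
    genotype = w(x$genotypes, genotype_cols, c("mouse_id", "mutation_id"),
                 "genotype.tsv"),
    phenotype = w(x$trials, trial_cols, "mouse_id", "phenotype.tsv"))
  invisible(paths)
}

read_tsv_checked <- function(path, cols, name) {
  if (!file.exists(path)) stop_format("%s file not found: '%s'", name, path)
  df <- utils::read.delim(path, sep = "\t", header = TRUE,
                          colClasses = "character", stringsAsFactors = FALSE,
                          fileEncoding = "UTF-8")
  miss <- setdiff(cols, names(df))
  if (length(miss))
    stop_format("%s file '%s' is missing column(s): %s", name, path,
                paste(miss, collapse = ", "))
  df[, cols, drop = FALSE]
}

#' Read a screen dataset from tab-separated files
#'
#' Counterpart of [write_screen()]. Reads the four TSV tables from a
#' directory (or explicit paths), cross-links and validates them.
#'
#' @param dir directory containing `pedigree.tsv`, `mutations.tsv`,
#'   `genotype.tsv`, `phenotype.tsv`; individual paths may override.
#' @param genotype,phenotype,pedigree,mutations explicit file paths.
#' @param validate run [validate_screen()]? Default `TRUE`.
#' @return a `screen_dataset`.
#' @export
read_screen <- function(dir = NULL,
                        genotype = file.path(dir, "genotype.tsv"),
                        phenotype = file.path(dir, "phenotype.tsv"),
                        pedigree = file.path(dir, "pedigree.tsv"),
                        mutations = file.path(dir, "mutations.tsv"),
                        validate = TRUE) {
  mice <- read_tsv_checked(pedigree, mice_cols, "pedigree")
  mice$week <- as.integer(mice$week)
  mice$survived_to_weaning <- as.logical(mice$survived_to_weaning)
  muts <- read_tsv_checked(mutations, mutation_cols, "mutations")
  muts$lethal <- as.logical(muts$lethal)
  muts$effect_size_performance <- as.numeric(muts$effect_size_performance)
  muts$effect_on_learning <- as.numeric(muts$effect_on_learning)
  geno <- read_tsv_checked(genotype, genotype_cols, "genotype")
  bad <- which(!geno$zygosity %in% zygosity_levels)
  if (length(bad))
    stop_format("genotype file '%s': invalid zygosity at data line(s) %s",
                genotype, paste(utils::head(bad, 5L), collapse = ", "))
  tri <- read_tsv_checked(phenotype, trial_cols, "phenotype")
  for (cc in paste0("trial_", 1:6)) tri[[cc]] <- as.numeric(tri[[cc]])
  screen_dataset(mice, muts, geno, tri, validate = validate)
}
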