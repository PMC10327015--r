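#' @keywords internal
"_PACKAGE"

# Run an expression under a local RNG seed, restoring global state afterwards.
# seed = NULL runs the expression with whatever RNG state is current.
with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(rm(".Random.seed", envir = globalenv()), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

# Deterministic per-stage seed stream derived from one master seed, so that
# changing e.g. clustering settings does not perturb simulation draws.
stage_seed <- function(seed, stage) {
  if (is.null(seed)) return(NULL)
  offs <- c(simulate = 11L, trials = 23L, batch = 37L, wt = 41L,
            score = 53L, cluster = 67L, map = 79L, rates = 83L)
  if (!stage %in% names(offs)) stop("unknown seed stage: ", stage)
  (as.integer(seed) %% 20000000L) * 100L + offs[[stage]]
}

`%||%` <- function(a, b) if (is.null(a)) b else a

zygosity_levels <- c("REF", "HET", "VAR")
damage_classes <- c("probably_benign", "possibly_damaging",
                    "probably_damaging", "probably_null", "unknown")
inheritance_modes <- c("recessive", "additive", "dominant")
generations <- c("WT", "G1", "G2", "G3")

stop_format <- function(...) stop(sprintf(...), call. = FALSE)

log_msg <- function(...) message(format(Sys.time(), "%H:%M:%S "), sprintf(...))
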