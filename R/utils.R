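`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive a reproducible sub-seed from a master seed
#'
#' Every stage of the pipeline draws its randomness through a sub-seed derived
#' from a single master seed and a stage tag, so that any stage can be re-run
#' in isolation and reproduce its output exactly.
#'
#' @param master_seed integer master seed.
#' @param tag character tag naming the stage (e.g. `"bold_run_3"`).
#' @return an integer in `[0, 2^31)` usable with [set.seed()].
#' @export
derive_seed <- function(master_seed, tag) {
  stopifnot(is.numeric(master_seed), length(master_seed) == 1L)
  h <- sum(utf8ToInt(as.character(tag)) * seq_along(utf8ToInt(as.character(tag))))
  v <- ((abs(master_seed) %% 83492791) * 7919 + (h %% 104729) * 131 + 17) %% 2147483629
  as.integer(v)
}

# Run code under a temporary RNG state; NULL seed means "use current stream".
with_seed <- function(seed, code) {
  if (is.null(seed)) force(code) else withr::with_seed(as.integer(seed), code)
}

stop_stage <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}

is_count <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
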