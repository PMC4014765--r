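`%||%` <- function(a, b) if (is.null(a)) b else a

#' Derive named per-stage random seeds from one root seed
#'
#' All randomness in the pipeline flows from a single root seed that is
#' expanded into named per-stage streams, so any stage can be re-run in
#' isolation and reproduce its draws.
#'
#' @param seed integer root seed.
#' @param stages character vector of stage names.
#' @return named integer vector of seeds, one per stage.
#' @keywords internal
derive_seeds <- function(seed, stages) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- globalenv()$.Random.seed
  on.exit({
    if (is.null(old)) {
      rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  s <- sample.int(.Machine$integer.max - 1L, length(stages))
  names(s) <- stages
  s
}

stop_mixshrink <- function(stage, ...) {
  stop(sprintf("[%s] %s", stage, paste0(...)), call. = FALSE)
}
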