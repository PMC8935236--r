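#' @importFrom rlang abort warn inform %||%
#' @importFrom tibble tibble as_tibble
#' @importFrom dplyr mutate filter select arrange group_by summarise ungroup
#'   bind_rows left_join rename n across
#' @importFrom Rcpp sourceCpp
#' @useDynLib fersigr, .registration = TRUE
NULL

# typed error helper so callers (and the fuzz tests) can distinguish
# format problems from programming errors
stop_format <- function(msg, ...) {
  abort(msg, class = "fersigr_format_error", ...)
}

stop_input <- function(msg, ...) {
  abort(msg, class = "fersigr_input_error", ...)
}

`%theninform%` <- function(cond, msg) {
  if (isTRUE(cond)) inform(msg)
  invisible(cond)
}

# draw a block-specific seed from a master seed so that adding one output
# block never perturbs the RNG stream of another; kept < 2^31
block_seed <- function(seed, block) {
  offsets <- c(
    expression = 11L, survival = 23L, mutation = 37L, stage = 41L,
    singlecell = 53L, icb = 67L, control = 79L, nmf = 97L
  )
  off <- offsets[[block]]
  as.integer((as.numeric(seed) * 1009 + off) %% 2147483629)
}

with_block_seed <- function(seed, block, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else {
    NULL
  }
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(block_seed(seed, block))
  force(code)
}
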