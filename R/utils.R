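#' @keywords internal
"_PACKAGE"

#' @useDynLib thyrocad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom rlang abort .data
#' @importFrom stats rnorm runif predict sd var quantile
#' @importFrom utils head
NULL

# Round half away from zero for non-negative values, i.e. the usual
# "round half up" convention for 8-bit intensities (base round() ties to even).
round_half_up <- function(x) floor(x + 0.5)

clip01 <- function(x) pmin(pmax(x, 0), 1)

clip255 <- function(x) pmin(pmax(x, 0), 255)

#' Derive a stage-specific seed from a global seed
#'
#' All randomness in the pipeline flows from one global seed; each stage
#' draws its own seed through this deterministic hash of the stage name so
#' that stages are individually reproducible and mutually decorrelated.
#'
#' @param seed integer global seed.
#' @param stage character stage name.
#' @return An integer seed in `[0, 2^31 - 2]`.
#' @export
derive_seed <- function(seed, stage) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.character(stage))
  h <- as.double(seed %% 2147483647L)
  for (ch in utf8ToInt(stage)) {
    h <- (h * 31 + ch) %% 2147483647
  }
  as.integer(h)
}

# Evaluate `expr` under a local RNG state seeded with `seed`, restoring the
# caller's RNG afterwards. Everything stochastic in the package goes through
# this so that library users' RNG streams are never disturbed.
with_seed <- function(seed, expr) {
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
  set.seed(as.integer(seed %% 2147483647))
  expr
}

stop_param <- function(msg, field = NULL) {
  abort(msg, class = "thyrocad_parameter_error", field = field)
}

stop_config <- function(msg) abort(msg, class = "thyrocad_config_error")

stop_data <- function(msg) abort(msg, class = "thyrocad_data_error")

stop_dim <- function(msg) abort(msg, class = "thyrocad_dimension_error")

stop_degenerate <- function(msg) abort(msg, class = "thyrocad_degenerate_error")
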