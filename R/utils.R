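#' @keywords internal
"_PACKAGE"

# Internal validation helpers ------------------------------------------------

stop_validation <- function(...) {
  stop(structure(
    class = c("nmrmixsim_validation_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

stop_format <- function(...) {
  stop(structure(
    class = c("nmrmixsim_format_error", "error", "condition"),
    list(message = paste0(...), call = sys.call(-1))
  ))
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                 allow_infinite = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_validation(name, " must be a single non-missing number")
  if (!allow_infinite && !is.finite(x))
    stop_validation(name, " must be finite")
  if (x < lower) stop_validation(name, " must be >= ", lower)
  if (x > upper) stop_validation(name, " must be <= ", upper)
  invisible(x)
}

#' Derive a deterministic child seed from a root seed
#'
#' Substream seeds are derived from one root seed so that every group and
#' replicate gets its own reproducible random stream. The derivation keeps
#' seeds inside the 32-bit signed integer range.
#'
#' @param root_seed Integer root seed.
#' @param ... One or more integer offsets identifying the substream
#'   (e.g. group index, replicate index).
#' @return A single integer seed.
#' @export
derive_seed <- function(root_seed, ...) {
  offs <- c(...)
  s <- as.double(root_seed) %% 2147483647
  for (o in offs) {
    s <- (s * 48271 + as.double(o) + 1) %% 2147483647
  }
  as.integer(s)
}

# Local RNG scope: evaluates expr with the given seed without clobbering the
# caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (is.null(old)) {
        if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
          rm(".Random.seed", envir = globalenv())
      } else assign(".Random.seed", old, envir = globalenv())
    })
    set.seed(seed)
  }
  expr
}
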