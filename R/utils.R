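#' @keywords internal
"_PACKAGE"

#' Evaluate an expression with a temporary RNG seed
#'
#' Runs `expr` with the R random number generator seeded to `seed`, then
#' restores the caller's RNG state, so generators are reproducible without
#' clobbering user-level randomness.
#'
#' @param seed integer scalar seed.
#' @param expr expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

#' Wrap angles in degrees to the orientation interval (-90, 90]
#'
#' Orientations are axial quantities: theta and theta + 180 describe the same
#' structure. Angles are reduced modulo 180 into (-90, 90].
#'
#' @param deg numeric vector of angles in degrees.
#' @return numeric vector in (-90, 90].
#' @export
#' @examples
#' wrap_orientation(c(0, 90, 91, -90, 180, 270))
wrap_orientation <- function(deg) {
  out <- ((deg + 90) %% 180) - 90
  out[out == -90] <- 90
  out
}

# Stop with a classed condition so callers/tests can distinguish error kinds.
abort_cmq <- function(msg, class) {
  stop(structure(class = c(class, "cmquant_error", "error", "condition"),
                 list(message = msg, call = sys.call(-1))))
}

# Scalar validators used across modules.
check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, allow_inf = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) ||
      (!allow_inf && !is.finite(x))) {
    abort_cmq(sprintf("`%s` must be a single finite number", name),
              "cmquant_invalid_spec")
  }
  ok_low <- if (strict_lower) x > lower else x >= lower
  if (!ok_low || x > upper) {
    abort_cmq(sprintf("`%s` = %g outside allowed range %s%g, %g]",
                      name, x, if (strict_lower) "(" else "[", lower, upper),
              "cmquant_invalid_spec")
  }
  invisible(x)
}
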