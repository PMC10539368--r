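# Internal helpers shared across modules.

# Run `expr` under a local, seeded RNG without disturbing the caller's stream.
# All generators funnel through this so a dataset is a pure function of
# (spec, seed).
with_local_seed <- function(seed, expr) {
  stopifnot(is.numeric(seed), length(seed) == 1, is.finite(seed))
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
  set.seed(as.integer(seed))
  expr
}

check_number <- function(x, name, min = -Inf, strict = FALSE) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict && x <= min) {
    abort(sprintf("`%s` must be > %s.", name, format(min)))
  }
  if (!strict && x < min) {
    abort(sprintf("`%s` must be >= %s.", name, format(min)))
  }
  invisible(x)
}

#' Retrieve the ground truth attached to a simulated dataset
#'
#' Every simulator in the package records the parameters actually used to
#' synthesize a dataset (amplitudes, rates, regression coefficients,
#' preference probabilities, ...) so downstream recovery can be checked.
#'
#' @param x An object returned by one of the `simulate_*()` functions.
#' @return A named list of generating parameters.
#' @export
ground_truth <- function(x) {
  gt <- attr(x, "ground_truth", exact = TRUE)
  if (is.null(gt)) abort("`x` carries no ground-truth attribute.")
  gt
}

set_ground_truth <- function(x, gt) {
  attr(x, "ground_truth") <- gt
  x
}

#' Serialize / restore ground truth
#'
#' Ground truth round-trips losslessly through its JSON sidecar
#' representation.
#'
#' @param gt A ground-truth list.
#' @param path File path for the JSON sidecar.
#' @return `write_ground_truth()` returns `path` invisibly;
#'   `read_ground_truth()` returns the list.
#' @export
write_ground_truth <- function(gt, path) {
  jsonlite::write_json(gt, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_ground_truth
#' @export
read_ground_truth <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
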