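## small internal helpers shared across modules

#' Evaluate code under a fixed RNG seed, restoring the caller's RNG state
#' @noRd
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

## signed shoelace area of a closed polygon (vertices not repeated)
polygonArea <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

polygonPerimeter <- function(x, y) {
  dx <- diff(c(x, x[1])); dy <- diff(c(y, y[1]))
  sum(sqrt(dx^2 + dy^2))
}

## Ramanujan's second approximation to the ellipse perimeter; relative
## error below 1e-9 for the aspect ratios used here
ellipsePerimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}

#' The logistic (sigmoid) link used throughout the package
#'
#' \code{sigmoid(0)} is exactly 0.5: a zero logit sits on the decision
#' threshold, positive logits give positive predictions.
#'
#' @param x numeric logits.
#' @return numeric probabilities in (0, 1).
#' @export
sigmoid <- function(x) plogis(x)

stopIfNot01Labels <- function(labels) {
  if (!all(labels %in% c(0, 1)))
    stop("labels must be binary 0/1")
  invisible(labels)
}
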