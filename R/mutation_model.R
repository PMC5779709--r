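# Two-state (red/green) mutation model for bi-allelic markers.

#' Two-allele mutation model
#'
#' Forward-in-time mutation rates between the two marker states: `u` is the
#' rate red -> green and `v` the rate green -> red, in units of expected
#' mutations per site.  The stationary frequencies are v/(u+v) red and
#' u/(u+v) green.  Alternatively give `pi0`, the stationary frequency of
#' the red ("1") allele, which sets u = 1/(2*pi0), v = 1/(2*(1-pi0)); the
#' symmetric case pi0 = 0.5 gives u = v = 1.
#'
#' @param u,v positive mutation rates.
#' @param pi0 stationary red-allele frequency in (0, 1); overrides `u`, `v`.
#' @return An object of class `"mutation_model"` with elements `u` and `v`.
#' @export
mutation_model <- function(u = 1, v = 1, pi0 = NULL) {
  if (!is.null(pi0)) {
    stopifnot(pi0 > 0, pi0 < 1)
    u <- 1 / (2 * pi0)
    v <- 1 / (2 * (1 - pi0))
  }
  stopifnot(u > 0, v > 0)
  structure(list(u = u, v = v), class = "mutation_model")
}

#' @export
print.mutation_model <- function(x, ...) {
  cat(sprintf("Two-allele mutation model: u = %g (red->green), v = %g (green->red); stationary red frequency %g\n",
              x$u, x$v, x$v / (x$u + x$v)))
  invisible(x)
}

stationary_red <- function(model) model$v / (model$u + model$v)
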