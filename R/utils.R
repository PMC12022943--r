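# Physical constants and small shared helpers.

# Gas constant, J mol^-1 K^-1. Energies are reported in kJ/mol throughout,
# so RT in kJ/mol is gas_constant_kj() * T.
GAS_CONSTANT_J <- 8.314

gas_constant_kj <- function() GAS_CONSTANT_J / 1000

# 1 e.nm in debye.
DEBYE_PER_E_NM <- 48.03

kT_kj <- function(temperature) gas_constant_kj() * temperature

#' Convert Celsius to Kelvin
#'
#' @param celsius Temperature in degrees Celsius.
#' @return Temperature in kelvin (`celsius + 273.15`).
#' @export
celsius_to_kelvin <- function(celsius) celsius + 273.15

stopifnot_scalar_number <- function(x, name, lower = -Inf, upper = Inf,
                                    strict_lower = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x)) {
    abort(sprintf("`%s` must be a single finite number.", name))
  }
  if (strict_lower && x <= lower) {
    abort(sprintf("`%s` must be > %g.", name, lower))
  }
  if (!strict_lower && x < lower) {
    abort(sprintf("`%s` must be >= %g.", name, lower))
  }
  if (x > upper) {
    abort(sprintf("`%s` must be <= %g.", name, upper))
  }
  invisible(x)
}

# Wrap values into the periodic interval [-period/2, period/2).
wrap_periodic <- function(x, period = 1) {
  x - period * round(x / period)
}

# Multiplicative lognormal noise with a given coefficient of variation.
# Keeps fluorescence-like observables strictly positive; noise_cv = 0 is exact.
lognormal_noise <- function(n, noise_cv) {
  if (noise_cv == 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + noise_cv^2))
  exp(rnorm(n, mean = -sdlog^2 / 2, sd = sdlog))
}

with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      get(".Random.seed", envir = globalenv())
    } else NULL
    on.exit({
      if (is.null(old)) {
        rm(".Random.seed", envir = globalenv())
      } else {
        assign(".Random.seed", old, envir = globalenv())
      }
    }, add = TRUE)
    set.seed(seed)
  }
  force(expr)
}
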