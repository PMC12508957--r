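# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_number <- function(x, name, lower = -Inf, upper = Inf,
                         strict_lower = FALSE, strict_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stopf("'%s' must be a single finite number", name)
  if (strict_lower && x <= lower) stopf("'%s' must be > %g", name, lower)
  if (!strict_lower && x < lower) stopf("'%s' must be >= %g", name, lower)
  if (strict_upper && x >= upper) stopf("'%s' must be < %g", name, upper)
  if (!strict_upper && x > upper) stopf("'%s' must be <= %g", name, upper)
  invisible(x)
}

# hours per second, used when converting enzyme Vmax (mg/s) into ODE rates (mg/h)
SECONDS_PER_HOUR <- 3600

# Boltzmann constant (J/K) and water viscosity at 37 C (Pa s), for the
# Stokes-Einstein micelle diffusivity used by the in vitro dissolution model.
BOLTZMANN_J_PER_K <- 1.380649e-23
WATER_VISCOSITY_37C_PA_S <- 6.92e-4
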