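#' @keywords internal
"_PACKAGE"

## Unit conversions used at the clinical-record boundary.
## Model-internal units are minutes, mmol/L, mU/L, L/mU/min.
.MIN_PER_HOUR <- 60
.MU_PER_U <- 1000
.MMOL_PER_G_GLUCOSE <- 1000 / 180.156

#' Convert an insulin rate in U/h to model units (mU/min)
#' @param u_per_h numeric vector of insulin rates in U/h
#' @return numeric vector in mU/min
#' @export
insulin_u_per_h_to_mu_per_min <- function(u_per_h) {
  u_per_h * .MU_PER_U / .MIN_PER_HOUR
}

#' Convert a carbohydrate rate in g/h to model units (mmol/min)
#' @param g_per_h numeric vector of dextrose-equivalent carbohydrate rates in g/h
#' @return numeric vector in mmol/min
#' @export
carb_g_per_h_to_mmol_per_min <- function(g_per_h) {
  g_per_h * .MMOL_PER_G_GLUCOSE / .MIN_PER_HOUR
}

## Composite trapezoid on a uniform or non-uniform grid.
.trapz <- function(x, y) {
  n <- length(x)
  if (n < 2L) return(0)
  sum((x[-1] - x[-n]) * (y[-1] + y[-n])) / 2
}

.clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

.is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

## Run `expr` under a deterministic seed without disturbing the caller's RNG
## stream. All seeded randomness in the package goes through this helper.
.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  expr
}

## Derive a bounded child seed from a base seed and integer offsets, keeping the
## result a valid 32-bit R integer. Fixed offsets mean adding a block or metric
## never perturbs the substream of another.
.child_seed <- function(seed, ...) {
  offs <- c(...)
  s <- (as.double(seed) + sum(as.double(offs) * seq_along(offs) * 10007)) %% 2147483629
  as.integer(s)
}
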