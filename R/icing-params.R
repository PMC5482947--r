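## Parameters of the three-compartment glucose-insulin kinetic model
## (ICING family). All rates are per minute, volumes in litres,
## concentrations mmol/L (glucose) or mU/L (insulin).

.PARAM_FIELDS <- c(
  "p_G", "alpha_G", "alpha_I", "n_K", "n_L", "n_I", "n_C", "x_L",
  "V_G", "V_I", "EGP", "CNS",
  "u_en_basal", "u_en_max", "u_en_slope", "u_en_intercept"
)

#' Glucose-insulin model parameters
#'
#' Construct and validate the parameter set of the glucose-insulin compartment
#' model. Every parameter is configuration: no default is hard-coded in the
#' computational routines; [default_icing_params()] loads the versioned
#' defaults file shipped with the package.
#'
#' @param p_G endogenous (non-insulin-mediated) glucose clearance rate (1/min)
#' @param alpha_G saturation of insulin-mediated glucose uptake (L/mU)
#' @param alpha_I saturation of hepatic insulin clearance (L/mU)
#' @param n_K renal insulin clearance rate (1/min)
#' @param n_L hepatic insulin clearance rate (1/min)
#' @param n_I plasma-interstitium insulin transfer rate (1/min)
#' @param n_C interstitial insulin degradation rate (1/min)
#' @param x_L first-pass hepatic extraction fraction of endogenous insulin
#'   (dimensionless, in `[0, 1)`)
#' @param V_G glucose distribution volume (L)
#' @param V_I insulin distribution volume (L)
#' @param EGP endogenous glucose production (mmol/min)
#' @param CNS central-nervous-system glucose uptake (mmol/min)
#' @param u_en_basal,u_en_max,u_en_slope,u_en_intercept endogenous insulin
#'   secretion model `u_en(G) = min(u_en_max, max(u_en_basal,
#'   u_en_slope * G + u_en_intercept))` (mU/min). Set `u_en_basal = u_en_max = 0`
#'   for fully suppressed endogenous secretion.
#' @param printed_nk_sign logical audit flag. The model's renal clearance term
#'   acts as a loss on plasma insulin (the default, `FALSE`); setting `TRUE`
#'   flips the sign of the `n_K` term so the plasma-insulin equation can be
#'   evaluated exactly as sometimes typeset.
#'
#' @return An object of class `icing_params` (a named list).
#' @seealso [default_icing_params()], [read_icing_params()]
#' @export
icing_params <- function(p_G, alpha_G, alpha_I, n_K, n_L, n_I, n_C, x_L,
                         V_G, V_I, EGP, CNS,
                         u_en_basal, u_en_max, u_en_slope, u_en_intercept,
                         printed_nk_sign = FALSE) {
  p <- list(
    p_G = p_G, alpha_G = alpha_G, alpha_I = alpha_I, n_K = n_K, n_L = n_L,
    n_I = n_I, n_C = n_C, x_L = x_L, V_G = V_G, V_I = V_I, EGP = EGP,
    CNS = CNS, u_en_basal = u_en_basal, u_en_max = u_en_max,
    u_en_slope = u_en_slope, u_en_intercept = u_en_intercept,
    printed_nk_sign = isTRUE(printed_nk_sign)
  )
  class(p) <- "icing_params"
  validate_icing_params(p)
  p
}

#' Validate a model parameter set
#'
#' @param params an `icing_params` object
#' @return `params`, invisibly, if valid; otherwise an error naming the
#'   offending field.
#' @export
validate_icing_params <- function(params) {
  for (f in .PARAM_FIELDS) {
    v <- params[[f]]
    if (!.is_number(v)) .stopf("parameter '%s' must be a single finite number", f)
  }
  strictly_pos <- c("n_K", "n_L", "n_I", "n_C", "V_G", "V_I")
  for (f in strictly_pos) {
    if (params[[f]] <= 0) .stopf("parameter '%s' must be > 0", f)
  }
  ## degenerate zeros are meaningful (no endogenous clearance / no saturation)
  for (f in c("p_G", "alpha_G", "alpha_I")) {
    if (params[[f]] < 0) .stopf("parameter '%s' must be >= 0", f)
  }
  if (params$x_L < 0 || params$x_L >= 1) .stopf("parameter 'x_L' must lie in [0, 1)")
  if (params$EGP < 0) .stopf("parameter 'EGP' must be >= 0")
  if (params$CNS < 0) .stopf("parameter 'CNS' must be >= 0")
  if (params$u_en_basal < 0 || params$u_en_max < 0) {
    .stopf("endogenous secretion bounds 'u_en_basal'/'u_en_max' must be >= 0")
  }
  if (params$u_en_max < params$u_en_basal) {
    .stopf("parameter 'u_en_max' must be >= 'u_en_basal'")
  }
  invisible(params)
}

#' Default model parameters
#'
#' Loads the versioned defaults file shipped in `extdata/icing_defaults.json`.
#' The values are literature defaults for the adult ICING model; they are
#' configuration, and any of them can be overridden.
#'
#' @param ... named overrides of individual parameters.
#' @return An `icing_params` object.
#' @examples
#' p <- default_icing_params()
#' p_nosecretion <- default_icing_params(u_en_basal = 0, u_en_max = 0)
#' @export
default_icing_params <- function(...) {
  path <- system.file("extdata", "icing_defaults.json", package = "sivar",
                      mustWork = TRUE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)$parameters
  over <- list(...)
  if (length(over)) {
    bad <- setdiff(names(over), c(.PARAM_FIELDS, "printed_nk_sign"))
    if (length(bad)) .stopf("unknown parameter(s): %s", paste(bad, collapse = ", "))
    raw[names(over)] <- over
  }
  do.call(icing_params, raw)
}

#' Read model parameters from a JSON or YAML file
#'
#' The file must map parameter names exactly as in [icing_params()].
#'
#' @param path path to a `.json`, `.yml` or `.yaml` file. A top-level
#'   `parameters` key is honoured; otherwise the mapping itself is used.
#' @return An `icing_params` object.
#' @export
read_icing_params <- function(path) {
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    json = jsonlite::read_json(path, simplifyVector = TRUE),
    yml = ,
    yaml = yaml::read_yaml(path),
    .stopf("unsupported parameter file extension '%s' (use json/yaml)", ext)
  )
  if (!is.null(raw$parameters)) raw <- raw$parameters
  do.call(icing_params, raw)
}

#' Write model parameters to a JSON file
#'
#' @param params an `icing_params` object
#' @param path output path (`.json`)
#' @return `path`, invisibly.
#' @export
write_icing_params <- function(params, path) {
  validate_icing_params(params)
  jsonlite::write_json(list(parameters = unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Endogenous insulin secretion rate
#'
#' Bounded, non-decreasing saturating-linear secretion as a function of blood
#' glucose: `min(u_en_max, max(u_en_basal, u_en_slope * G + u_en_intercept))`.
#'
#' @param G blood glucose (mmol/L), vectorised
#' @param params an `icing_params` object
#' @return secretion rate (mU/min), same length as `G`
#' @export
u_en_rate <- function(G, params) {
  .clamp(params$u_en_slope * G + params$u_en_intercept,
         params$u_en_basal, params$u_en_max)
}

#' @export
print.icing_params <- function(x, ...) {
  cat("Glucose-insulin model parameters\n")
  vals <- unlist(x[.PARAM_FIELDS])
  for (f in .PARAM_FIELDS) cat(sprintf("  %-16s %g\n", f, vals[[f]]))
  if (isTRUE(x$printed_nk_sign)) cat("  (printed n_K sign audit flag is ON)\n")
  invisible(x)
}
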