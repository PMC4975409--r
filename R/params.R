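#' @useDynLib atriafit, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom tibble tibble as_tibble
#' @importFrom rlang abort warn %||% .data
#' @importFrom generics tidy glance
#' @import dplyr
NULL

# canonical parameter order; must match enum ParIdx in src/minmod.cpp
mm_par_names <- c(
  "u_o", "u_u", "theta_v", "theta_w", "theta_vminus", "theta_o",
  "tau_v1m", "tau_v2m", "tau_vp", "tau_w1m", "tau_w2m", "k_wm", "u_wm",
  "tau_wp", "tau_fi", "tau_o1", "tau_o2", "tau_so1", "tau_so2", "k_so",
  "u_so", "tau_s1", "tau_s2", "k_s", "u_s", "tau_si", "tau_winf",
  "w_inf_star"
)

# parameters perturbed multiplicatively during annealing (positive scale
# parameters); the rest (thresholds/midpoints/levels) move additively
mm_par_multiplicative <- c(
  grep("^tau_", mm_par_names, value = TRUE),
  grep("^k_", mm_par_names, value = TRUE)
)

#' Create a model parameter set
#'
#' Builds a validated parameter set for the four-variable minimal ionic
#' model: membrane potential `u` plus gates `v`, `w`, `s`, with a fast
#' inward, a slow outward and a slow inward phenomenological current.
#' Voltages are dimensionless (0 near rest, about 1 at the plateau); all
#' `tau_*` are in ms.
#'
#' @param ... named parameter values overriding the bundled default set.
#' @param values optional named numeric vector or list of parameter values
#'   (overrides applied on top of the defaults before `...`).
#' @return An object of class `mm_params`: a named numeric vector of the 28
#'   model parameters.
#' @export
#' @examples
#' p <- model_parameters()
#' p2 <- model_parameters(tau_si = 2.5)
model_parameters <- function(..., values = NULL) {
  p <- default_parameters()
  ov <- c(as.list(values %||% list()), list(...))
  if (length(ov)) {
    bad <- setdiff(names(ov), mm_par_names)
    if (length(bad)) {
      abort(paste0("unknown model parameter(s): ", paste(bad, collapse = ", ")))
    }
    p[names(ov)] <- as.numeric(unlist(ov))
  }
  validate_parameters(p)
}

new_mm_params <- function(x) {
  structure(as.numeric(x)[seq_along(mm_par_names)],
            names = mm_par_names, class = "mm_params")
}

#' Validate a parameter set
#'
#' Checks the model invariants: all time constants and steepnesses
#' positive, thresholds in `[0, 1)`, and `0 <= u_o < theta_v < u_u`.
#'
#' @param p named numeric vector, list or `mm_params` with all 28
#'   parameters.
#' @return A validated `mm_params` (invisibly errors otherwise).
#' @export
validate_parameters <- function(p) {
  p <- unlist(p)[mm_par_names]
  if (anyNA(p)) abort("missing model parameter values")
  taus <- p[grep("^tau_", names(p))]
  if (any(taus <= 0)) abort("all tau_* parameters must be > 0")
  ks <- p[grep("^k_", names(p))]
  if (any(ks <= 0)) abort("all k_* steepness parameters must be > 0")
  th <- p[c("theta_v", "theta_w", "theta_vminus", "theta_o")]
  if (any(th < 0 | th >= 1)) abort("thresholds must lie in [0, 1)")
  if (!(p[["u_o"]] >= 0 && p[["u_o"]] < p[["theta_v"]] &&
        p[["theta_v"]] < p[["u_u"]])) {
    abort("require 0 <= u_o < theta_v < u_u")
  }
  new_mm_params(p)
}

#' Bundled default parameter set
#'
#' The published epicardial reference set of the minimal four-variable
#' human action-potential model, bundled as `inst/extdata/params/default.json`.
#' It is the standard initial condition for fitting.
#'
#' @return An `mm_params` object.
#' @export
default_parameters <- function() {
  path <- system.file("extdata", "params", "default.json",
                      package = "atriafit", mustWork = TRUE)
  read_parameters(path)
}

#' Read / write parameter sets as JSON
#'
#' Parameter sets are serialized as a flat JSON object keyed by parameter
#' name.
#'
#' @param path file path.
#' @rdname parameters_json
#' @return `read_parameters()` returns an `mm_params` object;
#'   `write_parameters()` returns `path` invisibly.
#' @export
read_parameters <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  validate_parameters(unlist(x))
}

#' @param params an `mm_params` object.
#' @rdname parameters_json
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "mm_params"))
  jsonlite::write_json(as.list(unclass(params)), path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' @export
print.mm_params <- function(x, ...) {
  cat("<mm_params> four-variable minimal model parameter set\n")
  print(unclass(x))
  invisible(x)
}

#' @export
tidy.mm_params <- function(x, ...) {
  tibble(term = names(x), estimate = as.numeric(x),
         kind = ifelse(names(x) %in% mm_par_multiplicative,
                       "scale", "level"))
}

#' Default fit mask
#'
#' Names of the parameters frozen during fitting, leaving 21 adjustable
#' parameters. The normalization and excitability anchors `u_o`, `u_u`
#' and `theta_v` pin the dimensionless voltage scale; the sub-threshold
#' shape parameters `theta_vminus`, `theta_o`, `tau_winf` and
#' `w_inf_star` are additionally frozen because they have minimal effect
#' on AP morphology and restitution in the physiological operating range
#' while degenerate values (e.g. a recovery threshold at the resting
#' potential) silence the tissue outright. The mask is configurable via
#' [fit_config()].
#'
#' @return Character vector of frozen parameter names.
#' @export
default_fit_mask <- function() {
  c("u_o", "u_u", "theta_v",
    "theta_vminus", "theta_o", "tau_winf", "w_inf_star")
}
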