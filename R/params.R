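#' Model parameters with homeostasis constraints
#'
#' Builds the full parameter set of the cartilage oxidative-stress model from
#' its free parameters, filling in the three derived quantities that pin the
#' control state `(M, D, R, E, U) = (1, 0, 1, 1, 1)` as an equilibrium:
#'
#' * `R_0 = 1 / (1 + epsilon)` — ATP production peaks at the control
#'   ROS-per-cell ratio;
#' * `alpha_M = delta_R` — ROS release balances clearance when all cells are
#'   functional;
#' * `delta_E = k_E / (lambda_E * (1 + lambda_E))` — ATP utilization balances
#'   production at the control state.
#'
#' Defaults are the published calibration for the 7 J/cm^2 drop-tower impact
#' series. `k_D` is the ROS-release multiplier of dysfunctional cells
#' (dysfunctional mitochondria leak roughly twice the baseline ROS, hence the
#' default of 2).
#'
#' @param k_S Rate of stress-induced mitochondrial damage (per unit stress per
#'   hour).
#' @param delta_D Apoptosis rate of dysfunctional-mitochondria cells under
#'   stress (per unit stress per hour).
#' @param delta_R ROS clearance rate (per hour).
#' @param s_C Oxidative-stress scaling constant (dimensionless).
#' @param k_E ATP-production scale (per hour).
#' @param lambda_E ATP-production shape constant (dimensionless).
#' @param k_U GAG logistic rate (per hour).
#' @param lambda_U GAG-ATP coupling constant (dimensionless).
#' @param epsilon Division guard, also fixing `R_0` (dimensionless, > 0).
#' @param alpha Stress exponent; must be strictly greater than 1 so the
#'   stress switch is continuously differentiable at its threshold.
#' @param k_D ROS-release multiplier of dysfunctional cells (dimensionless).
#'
#' @return An object of class `cartox_params`: a named list with the eleven
#'   free parameters plus the derived `R_0`, `alpha_M` and `delta_E`.
#' @examples
#' p <- cartox_params()
#' p$alpha_M == p$delta_R
#' tidy(p)
#' @export
cartox_params <- function(k_S = 2.7938, delta_D = 9.9626, delta_R = 0.0727,
                          s_C = 9.517, k_E = 0.0961, lambda_E = 0.0418,
                          k_U = 5, lambda_U = 0.3387, epsilon = 1e-4,
                          alpha = 1 + epsilon, k_D = 2) {
  free <- list(k_S = k_S, delta_D = delta_D, delta_R = delta_R, s_C = s_C,
               k_E = k_E, lambda_E = lambda_E, k_U = k_U, lambda_U = lambda_U,
               epsilon = epsilon, alpha = alpha, k_D = k_D)
  for (nm in names(free)) {
    v <- free[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v)) {
      abort(sprintf("parameter `%s` must be a single finite number", nm))
    }
    if (v <= 0) {
      abort(sprintf("parameter `%s` must be > 0 (got %g)", nm, v))
    }
  }
  if (alpha <= 1) {
    abort(sprintf("parameter `alpha` must be > 1 strictly (got %g)", alpha))
  }
  out <- free
  out$R_0 <- 1 / (1 + epsilon)
  out$alpha_M <- delta_R
  out$delta_E <- k_E / (lambda_E * (1 + lambda_E))
  structure(out, class = "cartox_params")
}

#' @export
print.cartox_params <- function(x, ...) {
  cat("<cartox_params>\n")
  df <- tidy(x)
  fmt <- format(df$value, digits = 6)
  for (i in seq_len(nrow(df))) {
    cat(sprintf("  %-9s %12s  (%s)\n", df$term[i], fmt[i], df$role[i]))
  }
  invisible(x)
}

.free_param_names <- c("k_S", "delta_D", "delta_R", "s_C", "k_E", "lambda_E",
                       "k_U", "lambda_U", "epsilon", "alpha", "k_D")
.derived_param_names <- c("R_0", "alpha_M", "delta_E")
.param_key_order <- c("k_S", "delta_D", "alpha_M", "k_D", "delta_R", "s_C",
                      "alpha", "k_E", "lambda_E", "R_0", "epsilon", "delta_E",
                      "k_U", "lambda_U")

#' @export
tidy.cartox_params <- function(x, ...) {
  terms <- .param_key_order
  tibble(term = terms,
         value = map_dbl(terms, ~ x[[.x]]),
         role = ifelse(terms %in% .derived_param_names, "derived", "free"))
}

#' Modify free parameters, re-deriving the constrained ones
#'
#' @param params A [cartox_params()] object.
#' @param ... Named free parameters to replace (any of `k_S`, `delta_D`,
#'   `delta_R`, `s_C`, `k_E`, `lambda_E`, `k_U`, `lambda_U`, `epsilon`,
#'   `alpha`, `k_D`).
#' @return A new `cartox_params` object with constraints re-applied.
#' @examples
#' update_params(cartox_params(), delta_R = 0.1)$alpha_M
#' @export
update_params <- function(params, ...) {
  stopifnot(inherits(params, "cartox_params"))
  repl <- list(...)
  bad <- setdiff(names(repl), .free_param_names)
  if (length(bad)) {
    abort(sprintf("not a free parameter: %s", paste(bad, collapse = ", ")))
  }
  free <- params[.free_param_names]
  free[names(repl)] <- repl
  do.call(cartox_params, free)
}

# parameter vector in the order expected by the compiled right-hand side
param_vector <- function(params) {
  vapply(.param_key_order, function(nm) params[[nm]], numeric(1))
}

#' Read and write parameter sets as flat key-value configuration files
#'
#' All fourteen parameters (free and derived) are stored under flat keys
#' `k_S`, `delta_D`, `alpha_M`, `k_D`, `delta_R`, `s_C`, `alpha`, `k_E`,
#' `lambda_E`, `R_0`, `epsilon`, `delta_E`, `k_U`, `lambda_U`. The format is
#' chosen from the file extension (`.json`, `.yaml` or `.yml`). On reading,
#' the set is rebuilt from the free parameters and the stored derived values
#' are checked against the constraint relationships.
#'
#' @param params A [cartox_params()] object.
#' @param path File path ending in `.json`, `.yaml` or `.yml`.
#' @return `write_params()` returns `path` invisibly; `read_params()` returns
#'   a `cartox_params` object.
#' @export
write_params <- function(params, path) {
  stopifnot(inherits(params, "cartox_params"))
  vals <- as.list(param_vector(params))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(vals, path, auto_unbox = TRUE, digits = NA)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(vals, path, precision = 15)
  } else {
    abort("unsupported parameter file extension (use .json or .yaml)")
  }
  invisible(path)
}

#' @rdname write_params
#' @export
read_params <- function(path) {
  vals <- read_flat_config(path)
  missing <- setdiff(.free_param_names, names(vals))
  if (length(missing)) {
    abort(sprintf("parameter file lacks keys: %s",
                  paste(missing, collapse = ", ")))
  }
  p <- do.call(cartox_params, vals[.free_param_names])
  for (nm in intersect(.derived_param_names, names(vals))) {
    stored <- as.numeric(vals[[nm]])
    if (abs(stored - p[[nm]]) > 1e-6 * max(1, abs(p[[nm]]))) {
      warn(sprintf(
        "stored `%s` (%g) disagrees with its constraint value (%g); using the constraint",
        nm, stored, p[[nm]]))
    }
  }
  p
}

# flat key-value file in JSON or YAML
read_flat_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("no such file: %s", path))
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    abort("unsupported config extension (use .json or .yaml)")
  }
}
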