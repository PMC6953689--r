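# Power-law (multiple log-linear) regression and replicate summaries.

#' Fit a power-law model by log-linear least squares
#'
#' Fits `response = c * prod_i (predictor_i + offset_i)^e_i` by ordinary least
#' squares on natural logarithms: `ln y ~ sum_i e_i ln(x_i + o_i)`. The
#' multiplier `c` is the exponentiated intercept. Offsets encode shifted
#' predictors such as the `(x + 1)` moisture term, so zero moisture is
#' admissible.
#'
#' @param data A data frame of experiment records.
#' @param response Name of the response column (strictly positive).
#' @param predictors Character vector of predictor column names (strictly
#'   positive after applying their offsets).
#' @param offsets Named numeric vector of per-predictor offsets, e.g.
#'   `c(moisture = 1)`. Predictors not named get offset 0.
#'
#' @return An object of class `power_law_fit` with elements `coefficient`,
#'   `exponents` (named), `adj_r_squared`, `n_records`, `residual_log_sd`,
#'   `response`, `offsets` and the underlying `lm` fit. [tidy()] and
#'   [glance()] methods are provided.
#' @examples
#' grid <- study_design_grid()
#' grid$energy <- impulse_energy(grid$peak_ka, grid$bulk_gcm3, grid$moisture)
#' fit_power_law(grid, "energy", c("peak_ka", "bulk_gcm3", "moisture"),
#'               offsets = c(moisture = 1))
#' @export
fit_power_law <- function(data, response, predictors, offsets = c()) {
  stopifnot(is.data.frame(data), is.character(response), length(response) == 1,
            is.character(predictors), length(predictors) >= 1)
  miss <- setdiff(c(response, predictors), names(data))
  if (length(miss)) stop("`data` is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  stray <- setdiff(names(offsets), predictors)
  if (length(stray)) stop("offsets name unknown predictor(s): ",
                          paste(stray, collapse = ", "), call. = FALSE)
  p <- length(predictors)
  if (nrow(data) < p + 2)
    stop("need at least ", p + 2, " records to fit ", p, " exponents", call. = FALSE)

  off <- stats::setNames(rep(0, p), predictors)
  off[names(offsets)] <- offsets

  y <- data[[response]]
  if (any(!is.finite(y)) || any(y <= 0))
    stop("response `", response, "` must be strictly positive (record ",
         paste(utils::head(which(!is.finite(y) | y <= 0), 3), collapse = ", "),
         ")", call. = FALSE)
  logs <- lapply(predictors, function(v) {
    z <- data[[v]] + off[[v]]
    if (any(!is.finite(z)) || any(z <= 0))
      stop("predictor `", v, "` must be strictly positive after its offset (record ",
           paste(utils::head(which(!is.finite(z) | z <= 0), 3), collapse = ", "),
           ")", call. = FALSE)
    log(z)
  })
  df <- stats::setNames(as.data.frame(logs), predictors)
  df[[".logy"]] <- log(y)

  fit <- stats::lm(stats::reformulate(predictors, response = ".logy"), data = df)
  if (fit$rank < p + 1)
    stop("singular design: predictors are collinear in log space", call. = FALSE)
  # noiseless round-trip grids are a designed use; lm's perfect-fit caveat
  # is expected there and not informative
  s <- withCallingHandlers(
    summary(fit),
    warning = function(w) {
      if (grepl("essentially perfect fit", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  structure(
    list(coefficient = unname(exp(stats::coef(fit)[1])),
         exponents = stats::coef(fit)[-1],
         adj_r_squared = s$adj.r.squared,
         n_records = nrow(data),
         residual_log_sd = s$sigma,
         response = response,
         offsets = off,
         lm_fit = fit),
    class = "power_law_fit"
  )
}

#' @export
print.power_law_fit <- function(x, digits = 4, ...) {
  terms <- paste0(names(x$exponents), "^", signif(x$exponents, digits),
                  collapse = " * ")
  cat(sprintf("<power_law_fit>  %s = %s * %s\n", x$response,
              signif(x$coefficient, digits), terms))
  cat(sprintf("  n = %d, adj R^2 = %.6g, residual log-SD = %.4g\n",
              x$n_records, x$adj_r_squared, x$residual_log_sd))
  invisible(x)
}

#' Tidy a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return A tibble with one row per model term: the multiplier (term
#'   `"(coefficient)"`, on the response scale) and one exponent per predictor.
#' @method tidy power_law_fit
#' @export
tidy.power_law_fit <- function(x, ...) {
  tibble::tibble(
    term = c("(coefficient)", names(x$exponents)),
    estimate = c(x$coefficient, unname(x$exponents)),
    role = c("multiplier", rep("exponent", length(x$exponents)))
  )
}

#' One-row summary of a power-law fit
#'
#' @param x A `power_law_fit`.
#' @param ... Unused.
#' @return A tibble with `adj_r_squared`, `residual_log_sd` and `n_records`.
#' @method glance power_law_fit
#' @export
glance.power_law_fit <- function(x, ...) {
  tibble::tibble(adj_r_squared = x$adj_r_squared,
                 residual_log_sd = x$residual_log_sd,
                 n_records = x$n_records)
}

#' Predict from a power-law fit
#'
#' @param object A `power_law_fit`.
#' @param newdata Data frame containing the fit's predictor columns.
#' @param ... Unused.
#' @return Numeric vector of responses on the original scale.
#' @export
predict.power_law_fit <- function(object, newdata, ...) {
  vals <- object$coefficient
  for (v in names(object$exponents)) {
    z <- newdata[[v]] + object$offsets[[v]]
    if (is.null(newdata[[v]])) stop("`newdata` lacks column ", v, call. = FALSE)
    vals <- vals * z^object$exponents[[v]]
  }
  vals
}

#' Heating efficiency implied by one critical-ignition record
#'
#' At the ignition boundary the delivered heat just matches the required
#' ignition energy, so the efficiency is their ratio:
#' `phi = 100 * E_ig / (measured impulse energy)`, with `E_ig` computed from
#' the record's bed and `energy_j` the measured total discharge energy
#' (the per-mm model energy times bed thickness).
#'
#' @param record One or more rows of an experiment-record table flagged
#'   `is_critical`, with bed columns and a positive measured `energy_j`.
#' @param thermo A [thermo_params()] object.
#' @return Numeric vector, percent.
#' @export
efficiency_from_critical <- function(record, thermo = thermo_params()) {
  stopifnot(is.data.frame(record))
  need <- c("bulk_gcm3", "moisture", "thickness_mm", "energy_j", "is_critical")
  miss <- setdiff(need, names(record))
  if (length(miss)) stop("record is missing column(s): ",
                         paste(miss, collapse = ", "), call. = FALSE)
  if (!all(record$is_critical))
    stop("efficiency is only defined at critical (boundary) records", call. = FALSE)
  if (any(record$energy_j <= 0)) {
    bad <- which(record$energy_j <= 0)
    id <- if ("record_id" %in% names(record)) record$record_id[bad] else bad
    stop("measured impulse energy must be positive (record ",
         paste(utils::head(id, 3), collapse = ", "), ")", call. = FALSE)
  }
  bed <- tibble::tibble(species = NA_character_,
                        bulk_gcm3 = record$bulk_gcm3, solid_gcm3 = Inf,
                        moisture = record$moisture,
                        thickness_mm = record$thickness_mm)
  100 * ignition_energy(bed, thermo) / record$energy_j
}

#' Mean and sample standard deviation of replicate measurements
#'
#' @param values Numeric vector of at least two replicate values.
#' @return A tibble with columns `mean`, `sd` (n-1 denominator) and `n`.
#' @examples
#' summarize_replicates(c(1, 2, 3))
#' @export
summarize_replicates <- function(values) {
  if (!is.numeric(values) || length(values) < 2)
    stop("need at least two replicate values", call. = FALSE)
  tibble::tibble(mean = mean(values), sd = stats::sd(values), n = length(values))
}
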