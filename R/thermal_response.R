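# Cubic temperature-response fits, optimum-temperature extraction and Q10.

#' Construct a response-versus-temperature series
#'
#' @param temperature temperatures in degrees C; at least 4 distinct values.
#' @param response response values (ETRmax, Asat, NPQ, RD, gm, ...), finite.
#' @param response_name label for the response variable.
#' @param replicate_id optional replicate label.
#' @return An object of class `thermal_series` (a data frame with metadata
#'   attributes).
#' @export
thermal_series <- function(temperature, response, response_name = "response",
                           replicate_id = "") {
  check_number(temperature, "temperature")
  check_number(response, "response")
  if (length(temperature) != length(response))
    stopf("temperature and response lengths differ")
  if (length(unique(temperature)) < 4L)
    stopf("a cubic fit needs at least 4 distinct temperatures")
  structure(
    data.frame(temperature = as.numeric(temperature),
               response = as.numeric(response)),
    response_name = as.character(response_name),
    replicate_id = as.character(replicate_id),
    class = c("thermal_series", "data.frame")
  )
}

#' Fit a cubic temperature-response curve
#'
#' Ordinary least-squares fit of `response = c0 + c1*T + c2*T^2 + c3*T^3`
#' over the observed temperature domain, with the optimum temperature taken
#' where the first derivative of the fitted polynomial is zero (see
#' [optimum_temperature()]).
#'
#' @param series a [thermal_series()], or a data frame with columns
#'   `temperature` and `response`.
#' @return An object of class `cubic_thermal_fit` with components
#'   `coefficients` (c0..c3), `domain`, `t_opt`, `boundary` (TRUE when the
#'   optimum sits at a domain endpoint), `lm` (the underlying [stats::lm()]
#'   fit) and `series`. Has `coef()`, `predict()`, `print()`, `residuals()`,
#'   `summary()` and `plot()` methods.
#' @examples
#' ts <- thermal_series(c(5, 15, 25, 35), c(2, 6, 8, 3), "Asat")
#' fit <- fit_cubic(ts)
#' fit$t_opt
#' @export
fit_cubic <- function(series) {
  if (!inherits(series, "thermal_series"))
    series <- thermal_series(series$temperature, series$response)
  fit <- stats::lm(response ~ poly(temperature, 3, raw = TRUE), data = series)
  cf <- unname(stats::coef(fit))
  if (anyNA(cf)) stopf("rank-deficient cubic design (too few distinct temperatures)")
  dom <- range(series$temperature)
  opt <- cubic_optimum(cf, dom)
  structure(
    list(coefficients = stats::setNames(cf, c("c0", "c1", "c2", "c3")),
         domain = dom, t_opt = opt$t_opt, boundary = opt$boundary,
         lm = fit, series = series,
         response_name = attr(series, "response_name"),
         replicate_id = attr(series, "replicate_id")),
    class = "cubic_thermal_fit"
  )
}

# evaluate a cubic given coefficients c0..c3
eval_cubic <- function(cf, t) cf[1] + cf[2] * t + cf[3] * t^2 + cf[4] * t^3

# locate the optimum of a cubic on a closed domain: among real roots of the
# derivative inside the domain with negative second derivative, take the one
# with the highest fitted response; otherwise fall back to the better
# endpoint, flagged as a boundary optimum.
cubic_optimum <- function(cf, domain) {
  d1 <- c(cf[2], 2 * cf[3], 3 * cf[4])  # derivative coefficients
  roots <- numeric(0)
  if (abs(d1[3]) > 0) {
    disc <- d1[2]^2 - 4 * d1[3] * d1[1]
    if (disc >= 0)
      roots <- (-d1[2] + c(-1, 1) * sqrt(disc)) / (2 * d1[3])
  } else if (abs(d1[2]) > 0) {
    roots <- -d1[1] / d1[2]
  }
  sec <- function(t) 2 * cf[3] + 6 * cf[4] * t
  cand <- roots[roots >= domain[1] & roots <= domain[2] & sec(roots) < 0]
  if (length(cand)) {
    vals <- eval_cubic(cf, cand)
    return(list(t_opt = cand[which.max(vals)], boundary = FALSE))
  }
  ends <- eval_cubic(cf, domain)
  list(t_opt = domain[which.max(ends)], boundary = TRUE)
}

#' Optimum temperature of a fitted cubic
#'
#' Returns the temperature at which the fitted cubic attains its maximum:
#' the real root of the derivative quadratic inside the data domain with
#' negative second derivative (an interior maximum), or, when no such root
#' exists, the domain endpoint with the higher fitted value, flagged
#' `boundary = TRUE` (reported in "greater-than" style rather than `NA`).
#'
#' @param fit a [fit_cubic()] result.
#' @return List with `t_opt` (degrees C) and `boundary` (logical).
#' @export
optimum_temperature <- function(fit) {
  stopifnot(inherits(fit, "cubic_thermal_fit"))
  list(t_opt = fit$t_opt, boundary = fit$boundary)
}

#' @export
coef.cubic_thermal_fit <- function(object, ...) object$coefficients

#' @export
predict.cubic_thermal_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$series$temperature else {
    if (is.list(newdata)) newdata$temperature else newdata
  }
  unname(eval_cubic(object$coefficients, t))
}

#' @export
residuals.cubic_thermal_fit <- function(object, ...) {
  object$series$response - predict(object)
}

#' @export
print.cubic_thermal_fit <- function(x, ...) {
  cat(sprintf("<cubic_thermal_fit> %s vs temperature on [%g, %g] degC\n",
              x$response_name, x$domain[1], x$domain[2]))
  cat("  coefficients:", paste(sprintf("%s = %.5g", names(x$coefficients),
                                       x$coefficients), collapse = ", "), "\n")
  cat(sprintf("  t_opt = %.3g degC%s\n", x$t_opt,
              if (x$boundary) " (boundary: no interior maximum)" else ""))
  invisible(x)
}

#' @export
summary.cubic_thermal_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  residual sd = %.4g on %d points\n",
              stats::sigma(object$lm), nrow(object$series)))
  invisible(summary(object$lm))
}

#' @export
plot.cubic_thermal_fit <- function(x, ...) {
  t <- seq(x$domain[1], x$domain[2], length.out = 200)
  graphics::plot(x$series$temperature, x$series$response,
                 xlab = "temperature (degC)", ylab = x$response_name, ...)
  graphics::lines(t, predict(x, t))
  graphics::abline(v = x$t_opt, lty = 2)
  invisible(x)
}

#' Temperature coefficient Q10
#'
#' `Q10 = (g2 / g1)^(10 / (t2 - t1))`: the factor by which a rate changes
#' per 10 degrees C, computed from rates `g1` at `t1` and `g2` at `t2`.
#' For mesophyll conductance the convention is to use mean gm at 15 and
#' 25 degrees C.
#'
#' @param g1,g2 rates (> 0) at temperatures `t1`, `t2`.
#' @param t1,t2 temperatures in degrees C, `t1 != t2`.
#' @return Dimensionless Q10.
#' @examples
#' q10(1, 2, 15, 25) # 2
#' @export
q10 <- function(g1, g2, t1, t2) {
  check_number(g1, "g1", positive = TRUE)
  check_number(g2, "g2", positive = TRUE)
  check_number(t1, "t1")
  check_number(t2, "t2")
  if (any(t1 == t2)) stopf("t1 and t2 must differ")
  (g2 / g1)^(10 / (t2 - t1))
}

#' Fit per-replicate cubics and summarise optima
#'
#' Fits one cubic per replicate in a long table (columns `replicate_id`,
#' `temperature_c`, `response`) and reports each replicate's optimum plus
#' the mean and standard error of the interior optima. A pooled single fit
#' across replicates is available via `pooled = TRUE`.
#'
#' @param d data frame with columns `replicate_id`, `temperature_c`,
#'   `response`.
#' @param response_name label for the response.
#' @param pooled fit one cubic to all points instead of per replicate.
#' @return List with `per_replicate` (data frame: `replicate_id, c0..c3,
#'   t_opt, boundary`) and `summary` (`mean_t_opt`, `se_t_opt`, `n`).
#' @export
fit_thermal_table <- function(d, response_name = "response", pooled = FALSE) {
  need <- c("replicate_id", "temperature_c", "response")
  if (!all(need %in% names(d))) stopf("missing thermal-series columns")
  if (pooled) {
    fit <- fit_cubic(thermal_series(d$temperature_c, d$response, response_name))
    per <- data.frame(replicate_id = "(pooled)",
                      t(fit$coefficients),
                      t_opt = fit$t_opt, boundary = fit$boundary)
    return(list(per_replicate = per,
                summary = data.frame(mean_t_opt = fit$t_opt, se_t_opt = NA,
                                     n = 1L),
                fits = list(fit)))
  }
  fits <- lapply(split(d, d$replicate_id), function(g)
    fit_cubic(thermal_series(g$temperature_c, g$response, response_name,
                             replicate_id = g$replicate_id[1])))
  per <- do.call(rbind, lapply(fits, function(f)
    data.frame(replicate_id = f$replicate_id, t(f$coefficients),
               t_opt = f$t_opt, boundary = f$boundary)))
  rownames(per) <- NULL
  topt <- per$t_opt
  list(per_replicate = per,
       summary = data.frame(
         mean_t_opt = mean(topt),
         se_t_opt = stats::sd(topt) / sqrt(length(topt)),
         n = length(topt)),
       fits = fits)
}
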