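# Rapid light-response curves of ETR: rational and waiting-in-line models,
# photoinhibition classification, and least-squares fitting.

#' Rational (Smith-type) light-response model
#'
#' Saturating hyperbola `ETR = AQE * Q / sqrt(1 + (AQE * Q / ETRmax)^2)`,
#' where `Q` is PPFD. Monotone increasing with initial slope `AQE`,
#' approaching `ETRmax` asymptotically; the model for non-photoinhibited
#' curves.
#'
#' @param ppfd PPFD, umol photons m-2 s-1 (>= 0). Vectorised.
#' @param aqe apparent quantum efficiency (initial slope), > 0.
#' @param etr_max saturating ETR, umol electrons m-2 s-1, > 0.
#' @return ETR at each `ppfd`.
#' @examples
#' rational_model(10000, aqe = 0.3, etr_max = 60) # ~59.99, near saturation
#' @export
rational_model <- function(ppfd, aqe, etr_max) {
  check_number(ppfd, "ppfd", nonneg = TRUE)
  check_number(aqe, "aqe", positive = TRUE, len = 1)
  check_number(etr_max, "etr_max", positive = TRUE, len = 1)
  aqe * ppfd / sqrt(1 + (aqe * ppfd / etr_max)^2)
}

#' Waiting-in-line light-response model
#'
#' `ETR = AQE * Q * exp(-AQE * Q / (ETRmax * e))`: rises with initial slope
#' `AQE` to a unique interior maximum of exactly `ETRmax` at
#' `Q* = ETRmax * e / AQE`, then declines; the model for photoinhibited
#' curves whose ETR falls at high light.
#'
#' @inheritParams rational_model
#' @return ETR at each `ppfd`.
#' @examples
#' waiting_in_line_model(60 * exp(1) / 0.3, aqe = 0.3, etr_max = 60) # 60
#' @export
waiting_in_line_model <- function(ppfd, aqe, etr_max) {
  check_number(ppfd, "ppfd", nonneg = TRUE)
  check_number(aqe, "aqe", positive = TRUE, len = 1)
  check_number(etr_max, "etr_max", positive = TRUE, len = 1)
  aqe * ppfd * exp(-aqe * ppfd / (etr_max * exp(1)))
}

#' Construct a rapid light-response curve
#'
#' @param ppfd PPFD levels, non-negative, strictly increasing, >= 4 points.
#' @param etr measured ETR at each level, finite.
#' @param replicate_id free-form replicate label.
#' @param temperature measurement temperature, degrees C (may be `NA`).
#' @return An object of class `light_curve` (a data frame with metadata
#'   attributes).
#' @export
light_curve <- function(ppfd, etr, replicate_id = "", temperature = NA_real_) {
  check_number(ppfd, "ppfd", nonneg = TRUE)
  check_number(etr, "etr")
  if (length(ppfd) != length(etr)) stopf("ppfd and etr lengths differ")
  if (length(ppfd) < 4L) stopf("a light curve needs at least 4 points")
  if (any(diff(ppfd) <= 0)) stopf("ppfd must be strictly increasing")
  structure(
    data.frame(ppfd = as.numeric(ppfd), etr = as.numeric(etr)),
    replicate_id = as.character(replicate_id),
    temperature = as.numeric(temperature),
    class = c("light_curve", "data.frame")
  )
}

#' Classify a light curve as photoinhibited
#'
#' Operational rule: the curve is photoinhibited when the mean ETR over the
#' top quartile of PPFD levels falls below 95% of the maximum observed ETR,
#' i.e. when ETR visibly declines at high light.
#'
#' @param curve a [light_curve()].
#' @return Logical scalar.
#' @export
classify_photoinhibition <- function(curve) {
  stopifnot(inherits(curve, "light_curve"))
  n <- nrow(curve)
  top <- curve$etr[curve$ppfd >= stats::quantile(curve$ppfd, 0.75, type = 7)]
  peak <- max(curve$etr)
  if (peak <= 0) return(FALSE)
  mean(top) < 0.95 * peak
}

#' Fit a light-response curve
#'
#' Least-squares fit of ETR versus PPFD to either the [rational_model()] or
#' the [waiting_in_line_model()], returning the apparent quantum efficiency
#' (AQE, initial slope) and the saturating / peak electron transport rate
#' (ETRmax). When `model` is not given, the waiting-in-line model is used if
#' [classify_photoinhibition()] flags a high-light decline, otherwise the
#' rational model.
#'
#' Optimisation is bounded Levenberg-Marquardt (via \pkg{minpack.lm}) from a
#' deterministic multi-start grid: the base start takes AQE from the slope of
#' the two lowest-PPFD points and ETRmax from the maximum observed ETR, and
#' further starts scale those by fixed factors. The best converged start (by
#' SSE) wins.
#'
#' @param curve a [light_curve()].
#' @param model `"rational"`, `"waiting_in_line"`, or `NULL` for automatic
#'   selection.
#' @return An object of class `light_curve_fit` with components `model`,
#'   `aqe`, `etr_max`, `sse`, `converged`, `fitted`, `curve`,
#'   `photoinhibited`. Has `coef()`, `predict()`, `residuals()`, `print()`,
#'   `summary()` and `plot()` methods.
#' @examples
#' q <- c(0, 25, 50, 100, 200, 400, 800, 1600)
#' cv <- light_curve(q, rational_model(q, 0.25, 80))
#' fit <- fit_light_curve(cv)
#' coef(fit)
#' @export
fit_light_curve <- function(curve, model = NULL) {
  stopifnot(inherits(curve, "light_curve"))
  photo <- classify_photoinhibition(curve)
  if (is.null(model)) {
    model <- if (photo) "waiting_in_line" else "rational"
  } else {
    model <- match.arg(model, c("rational", "waiting_in_line"))
  }
  fn <- switch(model,
    rational = rational_model,
    waiting_in_line = waiting_in_line_model
  )

  # base start: AQE from the slope of the two lowest-PPFD points
  # (guarding against a zero denominator), ETRmax from the observed peak
  dq <- curve$ppfd[2] - curve$ppfd[1]
  aqe0 <- (curve$etr[2] - curve$etr[1]) / dq
  if (!is.finite(aqe0) || aqe0 <= 0) aqe0 <- 0.3
  emax0 <- max(curve$etr)
  if (!is.finite(emax0) || emax0 <= 0) emax0 <- 1

  # deterministic multi-start: fixed scale factors, no RNG
  starts <- rbind(
    c(1, 1), c(0.5, 1), c(2, 1), c(1, 0.7), c(1, 1.5)
  )
  best <- NULL
  for (k in seq_len(nrow(starts))) {
    par0 <- c(aqe = aqe0 * starts[k, 1], etr_max = emax0 * starts[k, 2])
    res <- tryCatch(
      minpack.lm::nls.lm(
        par = par0,
        lower = c(1e-8, 1e-8),
        fn = function(p) curve$etr - fn(curve$ppfd, p[1], p[2]),
        control = minpack.lm::nls.lm.control(maxiter = 200)
      ),
      error = function(e) NULL
    )
    if (is.null(res)) next
    sse <- sum(res$fvec^2)
    conv <- res$info %in% 1:4
    if (is.null(best) || (conv && !best$conv) ||
        (conv == best$conv && sse < best$sse)) {
      best <- list(par = res$par, sse = sse, conv = conv)
    }
  }
  if (is.null(best))
    stopf("light-curve fit failed to converge from all starts (replicate %s)",
          attr(curve, "replicate_id"))

  fitted <- fn(curve$ppfd, best$par[1], best$par[2])
  structure(
    list(
      model = model,
      aqe = unname(best$par[1]), etr_max = unname(best$par[2]),
      sse = best$sse, converged = best$conv,
      photoinhibited = photo,
      fitted = fitted, curve = curve,
      replicate_id = attr(curve, "replicate_id"),
      temperature = attr(curve, "temperature")
    ),
    class = "light_curve_fit"
  )
}

#' @export
coef.light_curve_fit <- function(object, ...) {
  c(aqe = object$aqe, etr_max = object$etr_max)
}

#' @export
predict.light_curve_fit <- function(object, newdata = NULL, ...) {
  fn <- switch(object$model,
    rational = rational_model, waiting_in_line = waiting_in_line_model)
  q <- if (is.null(newdata)) object$curve$ppfd else {
    if (is.list(newdata)) newdata$ppfd else newdata
  }
  fn(q, object$aqe, object$etr_max)
}

#' @export
residuals.light_curve_fit <- function(object, ...) {
  object$curve$etr - object$fitted
}

#' @export
print.light_curve_fit <- function(x, ...) {
  cat(sprintf("<light_curve_fit> model = %s%s\n", x$model,
              if (x$photoinhibited) " (photoinhibited)" else ""))
  cat(sprintf("  AQE = %.4g  ETRmax = %.4g  SSE = %.4g  converged = %s\n",
              x$aqe, x$etr_max, x$sse, x$converged))
  invisible(x)
}

#' @export
summary.light_curve_fit <- function(object, ...) {
  n <- nrow(object$curve)
  rmse <- sqrt(object$sse / n)
  out <- c(coef(object), sse = object$sse, rmse = rmse, n = n)
  print(object)
  cat(sprintf("  RMSE = %.4g over %d points\n", rmse, n))
  invisible(out)
}

#' @export
plot.light_curve_fit <- function(x, ...) {
  q <- seq(0, max(x$curve$ppfd) * 1.05, length.out = 200)
  graphics::plot(x$curve$ppfd, x$curve$etr,
                 xlab = "PPFD (umol photons m-2 s-1)",
                 ylab = "ETR (umol electrons m-2 s-1)", ...)
  graphics::lines(q, predict(x, q))
  invisible(x)
}

#' Fit a table of light curves
#'
#' Convenience wrapper: fits every `replicate_id` x `temperature_c` group in
#' a long-format table (columns `replicate_id`, `temperature_c`, `ppfd`,
#' `etr`) and returns one row per curve.
#'
#' @param d data frame with columns `replicate_id`, `temperature_c`, `ppfd`,
#'   `etr`.
#' @return Data frame: `replicate_id, temperature_c, model, aqe, etr_max,
#'   sse, converged`.
#' @export
fit_light_curve_table <- function(d) {
  need <- c("replicate_id", "temperature_c", "ppfd", "etr")
  if (!all(need %in% names(d))) stopf("missing light-curve columns")
  key <- interaction(d$replicate_id, d$temperature_c, drop = TRUE)
  rows <- lapply(split(d, key), function(g) {
    g <- g[order(g$ppfd), ]
    fit <- fit_light_curve(light_curve(g$ppfd, g$etr,
                                       replicate_id = g$replicate_id[1],
                                       temperature = g$temperature_c[1]))
    data.frame(replicate_id = g$replicate_id[1],
               temperature_c = g$temperature_c[1],
               model = fit$model, aqe = fit$aqe, etr_max = fit$etr_max,
               sse = fit$sse, converged = fit$converged)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
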