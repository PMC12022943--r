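# Exchange-trace fitting: mono/biexponential models, chi-square-halving model
# selection, amplitude-weighted rate constants, and Arrhenius analysis.
#
# The exchange rate constant from a multiexponential fit is the
# amplitude-weighted arithmetic mean of the component rate constants,
# k = sum(a_i k_i) / sum(a_i). A biexponential description is retained only
# when it decreases the chi-square (residual sum of squares) of the best
# monoexponential fit to half or less (inclusive at exactly one half).

exp_model <- function(time, offset, a, k, sign) {
  offset + sign * colSums(a * exp(-outer(k, time)))
}

#' Fit a mono- or biexponential model to an exchange trace
#'
#' Least-squares fit of `I(t) = offset + s * sum(a_i exp(-k_i t))` with `s = -1`
#' for donor-rise traces and `s = +1` for acceptor-decay traces. Amplitudes and
#' rates are fitted on the log scale (positivity enforced); components are
#' returned ordered by decreasing rate.
#'
#' @param trace Kinetic-trace tibble (`time` in s, `intensity` in a.u.) with a
#'   `channel` attribute, e.g. from [read_trace()] or [gen_exchange_trace()].
#' @param n Number of exponential components, 1 or 2.
#' @param channel Override for the trace's channel attribute
#'   (`"donor"`/`"acceptor"`).
#' @return An `exchange_fit`: `components` tibble (`amplitude`, `rate`),
#'   `offset`, `chi2` (residual sum of squares), `n_components`, `k_weighted`,
#'   and a `bound_warning` flag when a rate approaches the resolvable range.
#'   Methods: [tidy()], [glance()], [autoplot()], `predict()`.
#' @export
fit_exponentials <- function(trace, n = 1, channel = NULL) {
  if (!n %in% c(1, 2)) abort("`n` must be 1 or 2")
  time <- trace$time
  intensity <- trace$intensity
  validate_trace_times(time)
  if (length(time) < 10) abort("trace too short to fit (need >= 10 points)")
  channel <- channel %||% attr(trace, "channel") %||% "donor"
  sgn <- if (channel == "donor") -1 else 1

  offset0 <- if (sgn < 0) max(intensity) else min(intensity)
  amp0 <- abs(intensity[1] - offset0)
  if (amp0 == 0) amp0 <- diff(range(intensity)) + 1e-12
  # crude time scale: time at which half the total change has happened
  change <- abs(intensity - intensity[1])
  t_half <- time[which.min(abs(change - max(change) / 2))]
  if (t_half <= 0) t_half <- median(time[time > 0])
  k0 <- log(2) / t_half

  df <- data.frame(time = time, intensity = intensity)
  fit_once <- function(start) {
    form <- if (n == 1) {
      intensity ~ offset + sgn * exp(la1) * exp(-exp(lk1) * time)
    } else {
      intensity ~ offset + sgn * (exp(la1) * exp(-exp(lk1) * time) +
                                  exp(la2) * exp(-exp(lk2) * time))
    }
    tryCatch(
      minpack.lm::nlsLM(form, data = df, start = start,
                        control = minpack.lm::nls.lm.control(maxiter = 500)),
      error = function(e) NULL
    )
  }
  starts <- if (n == 1) {
    list(list(offset = offset0, la1 = log(amp0), lk1 = log(k0)),
         list(offset = offset0, la1 = log(amp0), lk1 = log(k0 / 5)),
         list(offset = offset0, la1 = log(amp0), lk1 = log(k0 * 5)))
  } else {
    list(list(offset = offset0, la1 = log(amp0 * 0.6), lk1 = log(k0 * 3),
              la2 = log(amp0 * 0.4), lk2 = log(k0 / 3)),
         list(offset = offset0, la1 = log(amp0 * 0.8), lk1 = log(k0),
              la2 = log(amp0 * 0.2), lk2 = log(k0 / 10)),
         list(offset = offset0, la1 = log(amp0 * 0.5), lk1 = log(k0 * 10),
              la2 = log(amp0 * 0.5), lk2 = log(k0)))
  }
  fits <- purrr::compact(lapply(starts, fit_once))
  if (length(fits) == 0) abort("exponential fit failed to converge from all starts")
  rss <- vapply(fits, function(f) sum(residuals(f)^2), numeric(1))
  fit <- fits[[which.min(rss)]]

  est <- coef(fit)
  a <- exp(est[grep("^la", names(est))])
  k <- exp(est[grep("^lk", names(est))])
  ord <- order(k, decreasing = TRUE)
  a <- unname(a[ord]); k <- unname(k[ord])
  dt <- min(diff(time)); span <- max(time) - min(time)
  bound_warning <- any(k > 10 / dt) || any(k < 0.01 / span)
  if (bound_warning) {
    warn("a fitted rate constant is at the edge of the resolvable range for this time grid")
  }
  structure(
    list(
      components = tibble(amplitude = a, rate = k),
      offset = unname(est[["offset"]]),
      chi2 = min(rss),
      n_components = n,
      k_weighted = sum(a * k) / sum(a),
      channel = channel,
      temperature = attr(trace, "temperature"),
      bound_warning = bound_warning,
      iterations = fit$convInfo$finIter %||% NA_integer_,
      data = tibble(time = time, intensity = intensity)
    ),
    class = "exchange_fit"
  )
}

#' @export
print.exchange_fit <- function(x, ...) {
  cat(sprintf("<exchange_fit> %d component(s), %s channel\n", x$n_components, x$channel))
  print(as.data.frame(x$components), row.names = FALSE)
  cat(sprintf("  offset = %.4g | chi2 = %.4g | k_weighted = %.4g s^-1\n",
              x$offset, x$chi2, x$k_weighted))
  invisible(x)
}

#' @export
predict.exchange_fit <- function(object, newdata = NULL, ...) {
  t <- if (is.null(newdata)) object$data$time else newdata$time
  sgn <- if (object$channel == "donor") -1 else 1
  exp_model(t, object$offset, object$components$amplitude,
            object$components$rate, sgn)
}

#' @rdname fit_exponentials
#' @param x,object An `exchange_fit`.
#' @param ... Unused.
#' @method tidy exchange_fit
#' @export
tidy.exchange_fit <- function(x, ...) {
  dplyr::bind_rows(
    tibble(term = paste0("a", seq_len(nrow(x$components))),
           estimate = x$components$amplitude),
    tibble(term = paste0("k", seq_len(nrow(x$components))),
           estimate = x$components$rate),
    tibble(term = "offset", estimate = x$offset)
  )
}

#' @rdname fit_exponentials
#' @method glance exchange_fit
#' @export
glance.exchange_fit <- function(x, ...) {
  tibble(n_components = x$n_components, chi2 = x$chi2,
         k_weighted = x$k_weighted, channel = x$channel,
         bound_warning = x$bound_warning)
}

#' @rdname fit_exponentials
#' @method autoplot exchange_fit
#' @export
autoplot.exchange_fit <- function(object, ...) {
  grid <- tibble(time = seq(min(object$data$time), max(object$data$time),
                            length.out = 400))
  grid$intensity <- predict(object, grid)
  ggplot(object$data, aes(x = .data$time, y = .data$intensity)) +
    geom_point(size = 0.6, alpha = 0.6) +
    geom_line(data = grid, colour = "firebrick") +
    labs(x = "time (s)", y = "fluorescence (a.u.)",
         title = sprintf("%d-exponential fit, k_w = %.3g s^-1",
                         object$n_components, object$k_weighted))
}

#' Chi-square-halving model selection
#'
#' Chooses the biexponential fit if and only if its chi-square is half or less
#' of the monoexponential chi-square (inclusive at exactly one half);
#' otherwise the monoexponential fit is retained.
#'
#' @param fit1 Monoexponential `exchange_fit`.
#' @param fit2 Biexponential `exchange_fit` on the same trace.
#' @return The chosen fit, with the chi-square ratio attached as
#'   `attr(, "chi2_ratio")`.
#' @export
select_model <- function(fit1, fit2) {
  ratio <- fit2$chi2 / fit1$chi2
  chosen <- if (ratio <= 0.5) fit2 else fit1
  attr(chosen, "chi2_ratio") <- ratio
  chosen
}

#' Amplitude-weighted exchange rate constant
#'
#' `k = sum(a_i k_i) / sum(a_i)` over the fitted components.
#'
#' @param fit An `exchange_fit` (or anything with a `components` tibble).
#' @return The weighted rate constant in s^-1.
#' @export
weighted_rate <- function(fit) {
  a <- fit$components$amplitude
  k <- fit$components$rate
  if (sum(a) == 0) abort("weighted rate undefined: total amplitude is zero")
  sum(a * k) / sum(a)
}

#' Fit mono and biexponential models and select between them
#'
#' Convenience pipeline stage: fits both models, applies [select_model()], and
#' returns the chosen fit (whose `k_weighted` is the exchange rate constant).
#'
#' @inheritParams fit_exponentials
#' @return The selected `exchange_fit`.
#' @export
fit_exchange <- function(trace, channel = NULL) {
  f1 <- fit_exponentials(trace, n = 1, channel = channel)
  f2 <- tryCatch(fit_exponentials(trace, n = 2, channel = channel),
                 error = function(e) NULL)
  if (is.null(f2)) return(f1)
  select_model(f1, f2)
}

#' Arrhenius analysis of rate constants
#'
#' Linear regression of `ln k` on `1/T`; the activation energy is
#' `Ea = -slope * R` (kJ/mol, R = 8.314 J mol^-1 K^-1) and the pre-exponential
#' factor `A = exp(intercept)` (s^-1).
#'
#' @param series Data frame with columns `temperature` (K) and `k` (s^-1),
#'   e.g. from [gen_arrhenius_series()]; >= 3 temperatures required.
#' @return An `arrhenius_fit` with `Ea`, `A`, standard errors, and the fitted
#'   temperatures. Methods: [tidy()], [glance()], [autoplot()].
#' @export
fit_arrhenius <- function(series) {
  series <- as_tibble(series)
  if (!all(c("temperature", "k") %in% names(series))) {
    abort("`series` must have columns `temperature` and `k`")
  }
  if (nrow(series) < 3) abort("Arrhenius fit needs >= 3 (temperature, k) points")
  if (any(series$k <= 0)) abort("rate constants must be > 0")
  df <- data.frame(inv_T = 1 / series$temperature, ln_k = log(series$k))
  fit <- lm(ln_k ~ inv_T, data = df)
  sl <- coef(fit)[["inv_T"]]; ic <- coef(fit)[["(Intercept)"]]
  se <- tryCatch(suppressWarnings(sqrt(diag(vcov(fit)))),
                 error = function(e) c(NA_real_, NA_real_))
  structure(
    list(
      Ea = -sl * gas_constant_kj(),
      A = exp(ic),
      se = c(Ea = unname(se[2]) * gas_constant_kj(),
             ln_A = unname(se[1])),
      temps = series$temperature,
      lm = fit,
      data = series
    ),
    class = "arrhenius_fit"
  )
}

#' @export
print.arrhenius_fit <- function(x, ...) {
  cat(sprintf("<arrhenius_fit> Ea = %.4g kJ/mol (se %.2g) | A = %.3g s^-1 | %d temperatures\n",
              x$Ea, x$se[["Ea"]], x$A, length(x$temps)))
  invisible(x)
}

#' @rdname fit_arrhenius
#' @param x,object An `arrhenius_fit`.
#' @param ... Unused.
#' @method tidy arrhenius_fit
#' @export
tidy.arrhenius_fit <- function(x, ...) {
  tibble(term = c("Ea", "A"), estimate = c(x$Ea, x$A),
         std.error = c(x$se[["Ea"]], x$A * x$se[["ln_A"]]))
}

#' @rdname fit_arrhenius
#' @method glance arrhenius_fit
#' @export
glance.arrhenius_fit <- function(x, ...) {
  tibble(Ea = x$Ea, A = x$A, n_temps = length(x$temps),
         r.squared = suppressWarnings(summary(x$lm)$r.squared))
}

#' @rdname fit_arrhenius
#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  df <- tibble(inv_T = 1 / object$data$temperature, ln_k = log(object$data$k))
  ggplot(df, aes(x = .data$inv_T, y = .data$ln_k)) +
    geom_point() +
    geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                colour = "steelblue", linewidth = 0.5) +
    labs(x = "1/T (K^-1)", y = "ln k",
         title = sprintf("Ea = %.1f kJ/mol, A = %.2g s^-1", object$Ea, object$A))
}

#' @importFrom stats residuals predict
NULL
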