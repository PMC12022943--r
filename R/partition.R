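# Simple-partition model fitting and between-condition comparison.
#
# The fluorescence of a solute titrated with liposomes follows the hyperbolic
# partition form I([L]) = (I_W + I_M K_P V_L [L]) / (1 + K_P V_L [L]), whose
# asymptotes are the all-aqueous (I_W) and all-membrane (I_M) intensities and
# whose half-transition sits at [L] = 1 / (K_P V_L). Fits are performed on
# untransformed intensities with uniform weights; K_P is parametrized on the
# log10 scale, which both enforces K_P >= 0 and yields the standard error of
# log10 K_P (the normally distributed quantity used for averaging and testing)
# directly from the fit.

#' Fit the simple-partition model to a titration
#'
#' Least-squares fit of `I([L]) = (I_W + I_M K_P V_L [L]) / (1 + K_P V_L [L])`
#' to fluorescence intensity versus lipid concentration.
#'
#' @param data Data frame with columns `lipid_conc` (M) and `intensity` (a.u.);
#'   e.g. from [read_titration()] or [gen_partition_curve()]. Replicates may be
#'   pooled: the fit uses all rows.
#' @param molar_volume Lipid molar volume V_L in dm^3/mol (default 0.8).
#' @return A `partition_fit` object: estimates and standard errors for
#'   `K_P`, `log10_KP`, `I_W`, `I_M`, plus residual norm and iteration count.
#'   Methods: [tidy()], [glance()], [autoplot()], `predict()`.
#' @export
fit_partition <- function(data, molar_volume = 0.8) {
  data <- as_tibble(data)
  if (!all(c("lipid_conc", "intensity") %in% names(data))) {
    abort("`data` must have columns `lipid_conc` and `intensity`")
  }
  stopifnot_scalar_number(molar_volume, "molar_volume", lower = 0, strict_lower = TRUE)
  n_conc <- length(unique(data$lipid_conc))
  if (n_conc < 4) abort("need >= 4 distinct lipid concentrations to fit the partition model")
  if (diff(range(data$intensity)) == 0) {
    abort("degenerate data: all intensities are equal, the partition model is unidentifiable")
  }

  # initialization: aqueous intensity from the lowest concentrations, membrane
  # intensity from the highest, K_P from the concentration nearest mid-intensity
  ord <- order(data$lipid_conc)
  i_w0 <- mean(data$intensity[ord][seq_len(max(1, nrow(data) %/% 10))])
  i_m0 <- mean(data$intensity[rev(ord)][seq_len(max(1, nrow(data) %/% 10))])
  mid <- (i_w0 + i_m0) / 2
  l_mid <- data$lipid_conc[which.min(abs(data$intensity - mid))]
  if (l_mid <= 0) l_mid <- median(data$lipid_conc[data$lipid_conc > 0])
  lk0 <- log10(1 / (molar_volume * l_mid))

  fit <- tryCatch(
    minpack.lm::nlsLM(
      intensity ~ (I_W + I_M * 10^lk * molar_volume * lipid_conc) /
        (1 + 10^lk * molar_volume * lipid_conc),
      data = data,
      start = list(I_W = i_w0, I_M = i_m0, lk = lk0),
      control = minpack.lm::nls.lm.control(maxiter = 500)
    ),
    error = function(e) abort(sprintf("partition fit failed to converge: %s", conditionMessage(e)))
  )

  est <- coef(fit)
  se <- tryCatch(sqrt(diag(vcov(fit))), error = function(e) rep(NA_real_, 3))
  names(se) <- names(est)
  resid <- data$intensity - predict(fit)
  structure(
    list(
      K_P = 10^est[["lk"]],
      log10_KP = est[["lk"]],
      I_W = est[["I_W"]],
      I_M = est[["I_M"]],
      se = c(log10_KP = se[["lk"]], I_W = se[["I_W"]], I_M = se[["I_M"]],
             K_P = 10^est[["lk"]] * log(10) * se[["lk"]]),
      molar_volume = molar_volume,
      residual_norm = sqrt(sum(resid^2)),
      iterations = fit$convInfo$finIter %||% NA_integer_,
      n = nrow(data),
      data = data,
      nls = fit
    ),
    class = "partition_fit"
  )
}

#' @export
print.partition_fit <- function(x, ...) {
  cat("<partition_fit>\n")
  cat(sprintf("  log10 K_P = %.3f (se %.3f) | K_P = %.3g\n",
              x$log10_KP, x$se[["log10_KP"]], x$K_P))
  cat(sprintf("  I_W = %.4g, I_M = %.4g | V_L = %g dm^3/mol | n = %d | ||resid|| = %.3g (%d iter)\n",
              x$I_W, x$I_M, x$molar_volume, x$n, x$residual_norm, x$iterations))
  invisible(x)
}

#' @export
predict.partition_fit <- function(object, newdata = NULL, ...) {
  lc <- if (is.null(newdata)) object$data$lipid_conc else newdata$lipid_conc
  partition_model(lc, object$K_P, object$I_W, object$I_M, object$molar_volume)
}

#' @rdname fit_partition
#' @param x,object A `partition_fit`.
#' @param ... Unused.
#' @method tidy partition_fit
#' @export
tidy.partition_fit <- function(x, ...) {
  tibble(
    term = c("log10_KP", "K_P", "I_W", "I_M"),
    estimate = c(x$log10_KP, x$K_P, x$I_W, x$I_M),
    std.error = c(x$se[["log10_KP"]], x$se[["K_P"]], x$se[["I_W"]], x$se[["I_M"]])
  )
}

#' @rdname fit_partition
#' @method glance partition_fit
#' @export
glance.partition_fit <- function(x, ...) {
  tibble(log10_KP = x$log10_KP, K_P = x$K_P, molar_volume = x$molar_volume,
         residual_norm = x$residual_norm, iterations = x$iterations, n = x$n)
}

#' @rdname fit_partition
#' @method autoplot partition_fit
#' @export
autoplot.partition_fit <- function(object, ...) {
  rng <- range(object$data$lipid_conc[object$data$lipid_conc > 0])
  grid <- tibble(lipid_conc = 10^seq(log10(rng[1]), log10(rng[2]), length.out = 200))
  grid$intensity <- predict(object, grid)
  ggplot(object$data, aes(x = .data$lipid_conc, y = .data$intensity)) +
    geom_point() +
    geom_line(data = grid, colour = "steelblue") +
    scale_x_log10() +
    labs(x = "[lipid] (M)", y = "fluorescence (a.u.)",
         title = sprintf("log10 K_P = %.2f", object$log10_KP))
}

#' @export
as_report.partition_fit <- function(x, config = memperm_config(), ...) {
  rep <- as_report.default(glance(x), config)
  rep$parameters <- as.data.frame(tidy(x))
  rep
}

#' Compare log10 partition coefficients between two conditions
#'
#' Welch two-sample, two-tailed unequal-variance t-test on the log10 K_P
#' estimates of two groups of replicates (the log-scale estimates are the
#' normally distributed quantities).
#'
#' @param groupA,groupB Numeric vectors of log10 K_P estimates (>= 2 each).
#' @return A one-row tibble: group means, difference, `statistic`, `df`,
#'   `p.value`.
#' @export
compare_logKP <- function(groupA, groupB) {
  if (length(groupA) < 2 || length(groupB) < 2) {
    abort("each group needs >= 2 replicate log10 K_P estimates")
  }
  if (sd(groupA) == 0 && sd(groupB) == 0) {
    same <- isTRUE(all.equal(mean(groupA), mean(groupB)))
    return(tibble(
      mean_A = mean(groupA), mean_B = mean(groupB),
      difference = mean(groupA) - mean(groupB),
      statistic = if (same) 0 else Inf, df = NA_real_,
      p.value = if (same) 1 else 0
    ))
  }
  ht <- t.test(groupA, groupB, alternative = "two.sided", var.equal = FALSE)
  tibble(
    mean_A = mean(groupA), mean_B = mean(groupB),
    difference = mean(groupA) - mean(groupB),
    statistic = unname(ht$statistic), df = unname(ht$parameter),
    p.value = ht$p.value
  )
}
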