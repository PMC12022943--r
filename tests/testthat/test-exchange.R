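test_that("a noiseless monoexponential is inverted to better than 0.1%", {
  tr <- gen_exchange_trace(tibble::tibble(amplitude = 0.8, rate = 1e-3),
                           time = seq(0, 6000, length.out = 200))
  fit <- fit_exponentials(tr, n = 1)
  expect_equal(fit$components$rate, 1e-3, tolerance = 1e-3)
  expect_equal(fit$components$amplitude, 0.8, tolerance = 1e-3)
  expect_equal(fit$offset, 1, tolerance = 1e-6)
})

test_that("a redundant second component leaves the weighted rate unchanged", {
  tr <- gen_exchange_trace(tibble::tibble(amplitude = 0.8, rate = 1e-3),
                           time = seq(0, 6000, length.out = 200))
  fit2 <- fit_exponentials(tr, n = 2)
  expect_equal(fit2$k_weighted, 1e-3, tolerance = 0.01)
})

test_that("biexponential parameters are recovered across noisy replicates", {
  mix <- two_component_mix()
  fits <- lapply(1:50, function(s) {
    tr <- gen_exchange_trace(mix, noise_cv = 0.01, seed = s)
    fit_exponentials(tr, n = 2)
  })
  k1 <- vapply(fits, function(f) f$components$rate[1], numeric(1))
  k2 <- vapply(fits, function(f) f$components$rate[2], numeric(1))
  a1 <- vapply(fits, function(f) f$components$amplitude[1], numeric(1))
  expect_equal(median(k1), 2.0e-4, tolerance = 0.05)
  expect_equal(median(k2), 3.33e-5, tolerance = 0.15)
  expect_equal(median(a1), 0.7, tolerance = 0.05)
})

test_that("chi-square halving selects the biexponential inclusively at 0.5", {
  fake <- function(chi2, n) {
    structure(list(chi2 = chi2, n_components = n,
                   components = tibble::tibble(amplitude = 1, rate = 1e-3)),
              class = "exchange_fit")
  }
  expect_equal(select_model(fake(1, 1), fake(0.49, 2))$n_components, 2)
  expect_equal(select_model(fake(1, 1), fake(0.51, 2))$n_components, 1)
  expect_equal(select_model(fake(1, 1), fake(0.50, 2))$n_components, 2)
})

test_that("the weighted rate is the amplitude-weighted mean and is bounded", {
  fit <- structure(list(components = tibble::tibble(amplitude = c(0.3, 0.7),
                                                    rate = c(1e-2, 1e-3))),
                   class = "exchange_fit")
  expect_equal(weighted_rate(fit), 3.7e-3)

  single <- structure(list(components = tibble::tibble(amplitude = 2, rate = 5e-4)),
                      class = "exchange_fit")
  expect_equal(weighted_rate(single), 5e-4)

  zero <- structure(list(components = tibble::tibble(amplitude = c(0, 0),
                                                     rate = c(1e-2, 1e-3))),
                    class = "exchange_fit")
  expect_error(weighted_rate(zero), "amplitude")

  # scale invariance and boundedness over random mixtures
  set.seed(42)
  for (i in 1:25) {
    a <- runif(3); k <- 10^runif(3, -5, -2)
    f <- structure(list(components = tibble::tibble(amplitude = a, rate = k)),
                   class = "exchange_fit")
    fs <- structure(list(components = tibble::tibble(amplitude = 13 * a, rate = k)),
                    class = "exchange_fit")
    expect_equal(weighted_rate(f), weighted_rate(fs), tolerance = 1e-12)
    expect_gte(weighted_rate(f), min(k))
    expect_lte(weighted_rate(f), max(k))
  }
})

test_that("donor-rise and acceptor-decay traces yield the same weighted rate", {
  mix <- two_component_mix()
  kd <- fit_exchange(gen_exchange_trace(mix, noise_cv = 0.01, seed = 77,
                                        channel = "donor"))$k_weighted
  ka <- fit_exchange(gen_exchange_trace(mix, noise_cv = 0.01, seed = 78,
                                        baseline = 0.2,
                                        channel = "acceptor"))$k_weighted
  expect_equal(kd, ka, tolerance = 0.1)
})

test_that("Arrhenius fit-generate round trips are exact in the noiseless case", {
  set.seed(7)
  for (i in 1:20) {
    A <- 10^runif(1, 0, 20)
    Ea <- runif(1, 0, 200)
    fit <- fit_arrhenius(gen_arrhenius_series(A, Ea))
    expect_equal(fit$Ea, Ea, tolerance = 1e-10)
    expect_equal(fit$A, A, tolerance = 1e-10)
  }
})

test_that("a zero activation energy gives zero slope and A = k", {
  fit <- fit_arrhenius(gen_arrhenius_series(A = 3.3e5, Ea = 0))
  expect_equal(fit$Ea, 0, tolerance = 1e-10)
  expect_equal(fit$A, 3.3e5, tolerance = 1e-10)
})

test_that("the regression matches the two-point closed form on noiseless data", {
  s <- gen_arrhenius_series(A = 2.6e17, Ea = 125,
                            temps = c(288.15, 298.15, 310.15))
  fit <- fit_arrhenius(s)
  # closed form from any pair of points on the exact line
  ea_pair <- 8.314e-3 * log(s$k[1] / s$k[3]) / (1 / 310.15 - 1 / 288.15)
  expect_equal(fit$Ea, ea_pair, tolerance = 1e-10)
  expect_error(fit_arrhenius(s[1:2, ]), ">= 3")
})

test_that("traces that are too short or non-monotone are rejected", {
  tr <- gen_exchange_trace(tibble::tibble(amplitude = 1, rate = 1e-3),
                           time = seq(0, 100, length.out = 5))
  expect_error(fit_exponentials(tr, n = 1), ">= 10")
  expect_error(fit_exponentials(tr, n = 3), "1 or 2")
})
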