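grid_fes <- function(fn, lo = -1.2, hi = 1.2, n = 121) {
  g <- seq(lo, hi, length.out = n)
  fes2d(g, g, outer(g, g, fn), units = "normalized")
}

test_that("on a symmetric quadratic bowl the string stays a straight segment", {
  f <- grid_fes(function(x, y) x^2 + y^2)
  path <- mfep_string(f, start = c(-1, -1) / sqrt(2), end = c(1, 1) / sqrt(2),
                      n_nodes = 50)
  # the straight segment through the origin is a steepest-descent fixed point
  expect_lt(max(abs(path$cv1 - path$cv2)), 1e-6)
  # nodes are equidistant in arclength after reparametrization
  seg <- diff(path$s)
  expect_lt(diff(range(seg)) / mean(seg), 1e-3)
})

test_that("the valley surface yields the y = 0 path with unit barrier", {
  f <- grid_fes(function(x, y) (1 - x^2)^2 + 5 * y^2)
  path <- mfep_string(f, start = c(-1, 0), end = c(1, 0), n_nodes = 101)
  expect_lt(max(abs(path$cv2)), 0.02)
  barrier <- max(path$F) - min(path$F)
  expect_equal(barrier, 1, tolerance = 0.02)

  prof <- project_1d(path)
  expect_equal(min(prof$F), 0)
  b <- barriers(prof)
  expect_equal(b$dG_translocation, 1, tolerance = 0.02)
  expect_equal(abs(b$min_location), 1, tolerance = 0.02)
})

test_that("the MFEP bottleneck matches a shortest-bottleneck graph search", {
  fes <- analytic_fes("membrane", depth = 12, min_loc = 0.15, width = 0.05,
                      coupling = 120)
  n <- 101
  g <- seq(-0.5, 0.5, length.out = n)
  f <- fes2d(g, g, outer(g, g, fes$fn) - min(outer(g, g, fes$fn)))
  path <- mfep_string(f, start = c(-0.15, -0.15), end = c(0.15, 0.15),
                      n_nodes = 80)
  mfep_max <- max(path$F)
  idx_of <- function(p) c(which.min(abs(g - p[1])), which.min(abs(g - p[2])))
  oracle_max <- oracle_bottleneck(f$F, idx_of(c(-0.15, -0.15)),
                                  idx_of(c(0.15, 0.15)))
  # agreement within one grid cell's free-energy range
  cell_range <- max(abs(diff(f$F))) + max(abs(diff(t(f$F))))
  expect_lt(abs(mfep_max - oracle_max), cell_range)
})

test_that("the converged path never tops the straight-line segment", {
  set.seed(17)
  for (i in 1:5) {
    cx <- runif(4, -0.8, 0.8); cy <- runif(4, -0.8, 0.8)
    h <- runif(4, 2, 8); w <- runif(4, 0.1, 0.3)
    fn <- function(x, y) {
      out <- 0
      for (j in 1:4) out <- out + h[j] * exp(-((x - cx[j])^2 + (y - cy[j])^2) / (2 * w[j]^2))
      out
    }
    f <- grid_fes(fn, lo = -1, hi = 1, n = 101)
    start <- c(-0.9, -0.9); end <- c(0.9, 0.9)
    path <- tryCatch(mfep_string(f, start = start, end = end, n_nodes = 60,
                                 max_iter = 20000),
                     error = function(e) e$path)
    straight <- cbind(seq(start[1], end[1], length.out = 200),
                      seq(start[2], end[2], length.out = 200))
    f_straight <- max(fes_interp(f, straight[, 1], straight[, 2]))
    expect_lte(max(path$F), f_straight + 1e-9)
  }
})

test_that("projection keeps the lower free energy in shared cv1 bins", {
  path <- tibble::tibble(node = 1:5,
                         cv1 = c(0, 0.1, 0.1, 0.2, 0.3),
                         cv2 = 0,
                         s = seq(0, 1, length.out = 5),
                         F = c(3, 2, 1, 5, 4))
  attr(path, "spacing") <- 0.1
  class(path) <- c("mfep_path", class(path))
  prof <- project_1d(path)
  expect_equal(prof$F[prof$cv1 == 0.1], 1 - 1)  # min of (2, 1), shifted to 0
  expect_equal(nrow(prof), 4)
  # a path running along the cv1 axis projects to itself
  path2 <- tibble::tibble(node = 1:4, cv1 = c(0, 0.1, 0.2, 0.3), cv2 = 0,
                          s = seq(0, 0.3, by = 0.1), F = c(2, 0, 1, 3))
  attr(path2, "spacing") <- 0.1
  class(path2) <- c("mfep_path", class(path2))
  prof2 <- project_1d(path2)
  expect_equal(prof2$F, c(2, 0, 1, 3))
})

test_that("barrier extraction handles flat, monotone and membrane profiles", {
  flat <- structure(tibble::tibble(cv1 = seq(-4, 4, 0.1), F = 0),
                    class = c("profile_1d", "tbl_df", "tbl", "data.frame"))
  b <- barriers(flat)
  expect_equal(b$dG_desorption, 0)
  expect_equal(b$dG_translocation, 0)

  mono <- structure(tibble::tibble(cv1 = seq(0, 4, 0.1),
                                   F = seq(0, 4, 0.1) * 2.5),
                    class = c("profile_1d", "tbl_df", "tbl", "data.frame"))
  bm <- barriers(mono)
  expect_equal(bm$dG_desorption, mean(seq(3.4, 4, 0.1)) * 2.5)
  expect_equal(bm$dG_translocation, 0)  # F(0) - min

  off <- structure(tibble::tibble(cv1 = seq(1, 4, 0.1), F = 1),
                   class = c("profile_1d", "tbl_df", "tbl", "data.frame"))
  expect_error(barriers(off), "centre")
})

test_that("non-convergence raises a diagnostic error carrying the last path", {
  f <- grid_fes(function(x, y) (1 - x^2)^2 + 5 * y^2)
  err <- tryCatch(
    mfep_string(f, start = c(-1, 0.5), end = c(1, 0.5), n_nodes = 60,
                max_iter = 2),
    error = function(e) e
  )
  expect_s3_class(err, "memperm_mfep_error")
  expect_s3_class(err$path, "mfep_path")
  expect_equal(nrow(err$path), 60)
})
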