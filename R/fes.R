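# Free-energy-surface reconstruction from deposited hills, replicate
# averaging and symmetrization, and CV rescaling.
#
# The accumulated bias is V(s) = sum_i h_i exp(-sum_d wrap(s_d - c_id)^2 /
# (2 sigma_id^2)) with periodic wrapping on the normalized CV square. For
# tempered deposition the free-energy estimate is F = -(gamma/(gamma-1)) V;
# the untempered estimate F = -V is available for the pre-threshold regime.

#' Construct a gridded 2D free-energy surface
#'
#' @param cv1,cv2 Grid axes (strictly increasing).
#' @param F Matrix of free energies, `length(cv1) x length(cv2)`, kJ/mol.
#' @param units `"normalized"` or `"nm"`.
#' @param gamma Bias factor recorded in the metadata.
#' @param n_replicates,se Replicate count and pointwise standard-error matrix
#'   (from [average_symmetrize()]).
#' @param z_box Mean z-box dimension used for rescaling, nm.
#' @return A `fes2d` object.
#' @export
fes2d <- function(cv1, cv2, F, units = c("normalized", "nm"), gamma = NA_real_,
                  n_replicates = 1L, se = NULL, z_box = NA_real_) {
  units <- match.arg(units)
  if (!is.matrix(F) || nrow(F) != length(cv1) || ncol(F) != length(cv2)) {
    abort("`F` must be a length(cv1) x length(cv2) matrix")
  }
  if (any(diff(cv1) <= 0) || any(diff(cv2) <= 0)) {
    abort("grid axes must be strictly increasing")
  }
  structure(
    list(cv1 = cv1, cv2 = cv2, F = F, units = units, gamma = gamma,
         n_replicates = as.integer(n_replicates), se = se, z_box = z_box),
    class = "fes2d"
  )
}

#' @export
print.fes2d <- function(x, ...) {
  cat(sprintf("<fes2d> %d x %d grid (%s) | F range [%.3g, %.3g] kJ/mol | gamma %.3g | %d replicate(s)\n",
              length(x$cv1), length(x$cv2), x$units, min(x$F), max(x$F),
              x$gamma, x$n_replicates))
  invisible(x)
}

#' @rdname fes2d
#' @param x A `fes2d`.
#' @param ... Unused.
#' @method tidy fes2d
#' @export
tidy.fes2d <- function(x, ...) {
  grid <- expand.grid(cv1 = x$cv1, cv2 = x$cv2)
  out <- tibble(cv1 = grid$cv1, cv2 = grid$cv2, F = as.vector(x$F))
  if (!is.null(x$se)) out$se <- as.vector(x$se)
  out
}

#' Reconstruct a free-energy surface from hills
#'
#' Sums the deposited Gaussian bias on a regular grid over the normalized CV
#' square \[-0.5, 0.5\]^2 (with periodic wrapping of the CV coordinates) and
#' converts bias to free energy, shifted so min(F) = 0.
#'
#' @param hills Hills tibble from [read_hills()] or [gen_hills_from_fes()].
#' @param grid_resolution Points per axis.
#' @param gamma Bias factor for the well-tempered estimator; default: taken
#'   from the hills' `bias_factor` column.
#' @param periodic Wrap CV distances on the unit square (default TRUE).
#' @param estimator `"well_tempered"` (`F = -(gamma/(gamma-1)) V`, default) or
#'   `"negative_bias"` (`F = -V`, appropriate before tempering sets in).
#' @param chunk Hills summed per block (memory/speed trade-off).
#' @return A [fes2d()] in normalized units.
#' @export
reconstruct_fes <- function(hills, grid_resolution = 201L, gamma = NULL,
                            periodic = TRUE,
                            estimator = c("well_tempered", "negative_bias"),
                            chunk = 5000L) {
  estimator <- match.arg(estimator)
  if (nrow(hills) == 0) abort("empty hill list: nothing to reconstruct")
  gamma <- gamma %||% hills$bias_factor[[1]]
  if (estimator == "well_tempered" && gamma <= 1) {
    abort("well-tempered estimator needs gamma > 1")
  }
  g <- seq(-0.5, 0.5, length.out = as.integer(grid_resolution))
  spacing <- g[2] - g[1]
  if (spacing > min(hills$sigma1, hills$sigma2) / 2 + 1e-12) {
    warn("grid spacing exceeds sigma/2; the reconstruction may be under-resolved")
  }
  V <- matrix(0, length(g), length(g))
  idx <- seq_len(nrow(hills))
  for (block in split(idx, ceiling(idx / chunk))) {
    dx <- outer(g, hills$center1[block], "-")
    dy <- outer(g, hills$center2[block], "-")
    if (periodic) {
      dx <- wrap_periodic(dx)
      dy <- wrap_periodic(dy)
    }
    gx <- exp(-sweep(dx^2, 2, 2 * hills$sigma1[block]^2, "/"))
    gy <- exp(-sweep(dy^2, 2, 2 * hills$sigma2[block]^2, "/"))
    V <- V + gx %*% (hills$height[block] * t(gy))
  }
  F <- if (estimator == "well_tempered") -(gamma / (gamma - 1)) * V else -V
  F <- F - min(F)
  fes2d(g, g, F, units = "normalized", gamma = gamma)
}

#' Rescale normalized CV axes to absolute distances
#'
#' Multiplies both normalized CV axes by the averaged z-box dimension; free
#' energies are unchanged. Applying it to an already-rescaled surface is an
#' error (unit guard).
#'
#' @param fes A [fes2d()] in normalized units.
#' @param z_box_mean Mean z-box dimension, nm.
#' @return The rescaled `fes2d` (units `"nm"`).
#' @export
rescale_cvs <- function(fes, z_box_mean) {
  if (fes$units != "normalized") {
    abort("surface is already in nm; refusing to rescale twice")
  }
  stopifnot_scalar_number(z_box_mean, "z_box_mean", lower = 0, strict_lower = TRUE)
  fes2d(fes$cv1 * z_box_mean, fes$cv2 * z_box_mean, fes$F, units = "nm",
        gamma = fes$gamma, n_replicates = fes$n_replicates, se = fes$se,
        z_box = z_box_mean)
}

#' Average replicate surfaces and symmetrize
#'
#' Each replicate is shifted to min 0, surfaces are averaged pointwise, and
#' the mean is symmetrized under point inversion through the origin,
#' `F(cv1, cv2) <- (F(cv1, cv2) + F(-cv1, -cv2)) / 2` (leaflet equivalence),
#' then re-shifted to min 0. The pointwise standard error over replicates is
#' carried along (symmetrized the same way).
#'
#' @param fes_list A list of [fes2d()] objects on identical grids (a single
#'   `fes2d` is accepted).
#' @return A `fes2d` with `n_replicates` and `se` set.
#' @export
average_symmetrize <- function(fes_list) {
  if (inherits(fes_list, "fes2d")) fes_list <- list(fes_list)
  if (length(fes_list) == 0) abort("no surfaces to average")
  ref <- fes_list[[1]]
  for (f in fes_list[-1]) {
    if (!isTRUE(all.equal(f$cv1, ref$cv1)) || !isTRUE(all.equal(f$cv2, ref$cv2))) {
      abort("grid mismatch between replicate surfaces")
    }
  }
  if (max(abs(ref$cv1 + rev(ref$cv1))) > 1e-9 ||
      max(abs(ref$cv2 + rev(ref$cv2))) > 1e-9) {
    abort("symmetrization requires grid axes symmetric about zero")
  }
  shifted <- lapply(fes_list, function(f) f$F - min(f$F))
  mean_F <- Reduce(`+`, shifted) / length(shifted)
  n <- length(shifted)
  se <- if (n > 1) {
    sq <- Reduce(`+`, lapply(shifted, function(m) (m - mean_F)^2))
    sqrt(sq / (n - 1)) / sqrt(n)
  } else {
    matrix(0, nrow(mean_F), ncol(mean_F))
  }
  inv <- function(m) m[rev(seq_len(nrow(m))), rev(seq_len(ncol(m))), drop = FALSE]
  F_sym <- (mean_F + inv(mean_F)) / 2
  se_sym <- (se + inv(se)) / 2
  F_sym <- F_sym - min(F_sym)
  fes2d(ref$cv1, ref$cv2, F_sym, units = ref$units, gamma = ref$gamma,
        n_replicates = n, se = se_sym, z_box = ref$z_box)
}

#' @rdname fes2d
#' @param object A `fes2d`.
#' @method autoplot fes2d
#' @export
autoplot.fes2d <- function(object, ...) {
  df <- tidy(object)
  ggplot(df, aes(x = .data$cv1, y = .data$cv2, fill = .data$F)) +
    geom_raster() +
    scale_fill_viridis_c(name = "F (kJ/mol)") +
    coord_equal() +
    labs(x = sprintf("CV1 (%s)", object$units), y = sprintf("CV2 (%s)", object$units))
}

#' Evaluate a fes2d surface at arbitrary points (bilinear)
#'
#' @param fes A [fes2d()].
#' @param cv1,cv2 Coordinates of the query points (recycled to equal length).
#' @return Interpolated free energies, kJ/mol.
#' @export
fes_interp <- function(fes, cv1, cv2) {
  bilinear_interp(fes$cv1, fes$cv2, fes$F, cbind(cv1, cv2))
}

bilinear_interp <- function(gx, gy, M, pts) {
  x <- pmin(pmax(pts[, 1], gx[1]), gx[length(gx)])
  y <- pmin(pmax(pts[, 2], gy[1]), gy[length(gy)])
  i <- pmin(findInterval(x, gx), length(gx) - 1L)
  j <- pmin(findInterval(y, gy), length(gy) - 1L)
  tx <- (x - gx[i]) / (gx[i + 1L] - gx[i])
  ty <- (y - gy[j]) / (gy[j + 1L] - gy[j])
  unname(M[cbind(i, j)] * (1 - tx) * (1 - ty) +
           M[cbind(i + 1L, j)] * tx * (1 - ty) +
           M[cbind(i, j + 1L)] * (1 - tx) * ty +
           M[cbind(i + 1L, j + 1L)] * tx * ty)
}
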