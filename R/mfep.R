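# Zero-temperature string method: minimum free-energy path extraction,
# 1D projection, and barrier estimation.

fes_gradient_grids <- function(fes) {
  F <- fes$F
  gx <- fes$cv1; gy <- fes$cv2
  n <- length(gx); m <- length(gy)
  dFdx <- F; dFdy <- F
  dFdx[2:(n - 1), ] <- (F[3:n, ] - F[1:(n - 2), ]) /
    (gx[3:n] - gx[1:(n - 2)])
  dFdx[1, ] <- (F[2, ] - F[1, ]) / (gx[2] - gx[1])
  dFdx[n, ] <- (F[n, ] - F[n - 1, ]) / (gx[n] - gx[n - 1])
  dFdy[, 2:(m - 1)] <- sweep(F[, 3:m] - F[, 1:(m - 2)], 2,
                             gy[3:m] - gy[1:(m - 2)], "/")
  dFdy[, 1] <- (F[, 2] - F[, 1]) / (gy[2] - gy[1])
  dFdy[, m] <- (F[, m] - F[, m - 1]) / (gy[m] - gy[m - 1])
  list(dFdx = dFdx, dFdy = dFdy)
}

reparametrize_equal_arclength <- function(nodes) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  s <- c(0, cumsum(seg))
  total <- s[length(s)]
  if (total == 0) return(nodes)
  target <- seq(0, total, length.out = nrow(nodes))
  cbind(approx(s, nodes[, 1], xout = target)$y,
        approx(s, nodes[, 2], xout = target)$y)
}

#' Minimum free-energy path by the zero-temperature string method
#'
#' Evolves a discretized path between two basins down the free-energy
#' gradient: interior nodes are displaced along the bilinear-interpolated
#' `-grad F`, then the string is reparametrized to equal arclength, until the
#' maximum node displacement per iteration falls below `tol`.
#'
#' @param fes A [fes2d()].
#' @param start,end Path endpoints as (cv1, cv2); defaults are the metadynamics
#'   basins (0, 0) and (0.48, 0.48) in normalized units (scaled by `z_box`
#'   for surfaces in nm).
#' @param n_nodes Number of string nodes (default 100).
#' @param step Descent step as a fraction of the grid spacing per iteration
#'   (the gradient is normalized by its maximum over nodes; default 0.1).
#' @param tol Convergence threshold on the maximum node displacement, in axis
#'   units (default 1e-4).
#' @param max_iter Iteration cap; non-convergence raises an error of class
#'   `memperm_mfep_error` carrying the last path in its `path` field.
#' @return An `mfep_path` tibble (`node`, `cv1`, `cv2`, `s` arclength, `F`)
#'   with attributes `iterations` and `units`.
#' @export
mfep_string <- function(fes, start = NULL, end = NULL, n_nodes = 100,
                        step = 0.1, tol = 1e-4, max_iter = 5000) {
  scale <- if (fes$units == "nm" && is.finite(fes$z_box)) fes$z_box else 1
  start <- start %||% c(0, 0)
  end <- end %||% (c(0.48, 0.48) * scale)
  in_grid <- function(p) {
    p[1] >= fes$cv1[1] && p[1] <= tail(fes$cv1, 1) &&
      p[2] >= fes$cv2[1] && p[2] <= tail(fes$cv2, 1)
  }
  if (!in_grid(start) || !in_grid(end)) abort("start/end must lie inside the grid")

  grads <- fes_gradient_grids(fes)
  spacing <- min(diff(fes$cv1)[1], diff(fes$cv2)[1])
  nodes <- cbind(seq(start[1], end[1], length.out = n_nodes),
                 seq(start[2], end[2], length.out = n_nodes))
  interior <- 2:(n_nodes - 1)
  converged <- FALSE
  it <- 0L
  while (it < max_iter) {
    it <- it + 1L
    old <- nodes
    gx <- bilinear_interp(fes$cv1, fes$cv2, grads$dFdx, nodes[interior, , drop = FALSE])
    gy <- bilinear_interp(fes$cv1, fes$cv2, grads$dFdy, nodes[interior, , drop = FALSE])
    gmax <- max(sqrt(gx^2 + gy^2), 1e-12)
    h <- step * spacing / gmax
    nodes[interior, 1] <- nodes[interior, 1] - h * gx
    nodes[interior, 2] <- nodes[interior, 2] - h * gy
    nodes[, 1] <- pmin(pmax(nodes[, 1], fes$cv1[1]), tail(fes$cv1, 1))
    nodes[, 2] <- pmin(pmax(nodes[, 2], fes$cv2[1]), tail(fes$cv2, 1))
    nodes <- reparametrize_equal_arclength(nodes)
    disp <- max(sqrt(rowSums((nodes - old)^2)))
    if (disp < tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged) {
    abort(sprintf("string method did not converge in %d iterations (last displacement %.3g)",
                  max_iter, disp),
          class = "memperm_mfep_error",
          path = finish_path(nodes, fes, it))
  }
  finish_path(nodes, fes, it)
}

finish_path <- function(nodes, fes, iterations) {
  seg <- sqrt(rowSums(diff(nodes)^2))
  out <- tibble(
    node = seq_len(nrow(nodes)),
    cv1 = nodes[, 1], cv2 = nodes[, 2],
    s = c(0, cumsum(seg)),
    F = bilinear_interp(fes$cv1, fes$cv2, fes$F, nodes)
  )
  attr(out, "iterations") <- iterations
  attr(out, "units") <- fes$units
  attr(out, "spacing") <- min(diff(fes$cv1)[1], diff(fes$cv2)[1])
  class(out) <- c("mfep_path", class(out))
  out
}

#' Project an MFEP onto the CV1 coordinate
#'
#' The path free energy becomes a function of each node's `cv1`; nodes sharing
#' a `cv1` bin keep the lower free energy, and the profile is shifted so its
#' minimum is 0.
#'
#' @param path An `mfep_path` from [mfep_string()].
#' @param bin_width Width of the cv1 bins; defaults to the grid spacing of the
#'   surface the path was traced on.
#' @return A `profile_1d` tibble (`cv1`, `F`), ordered by `cv1`.
#' @export
project_1d <- function(path, bin_width = NULL) {
  bin_width <- bin_width %||% attr(path, "spacing") %||% 0.005
  out <- path |>
    mutate(cv1 = round(.data$cv1 / bin_width) * bin_width) |>
    group_by(.data$cv1) |>
    summarise(F = min(.data$F), .groups = "drop") |>
    arrange(.data$cv1) |>
    mutate(F = .data$F - min(.data$F))
  attr(out, "units") <- attr(path, "units")
  class(out) <- c("profile_1d", class(out))
  out
}

#' Desorption and translocation barriers from a 1D profile
#'
#' The desorption barrier is the free energy of the bulk plateau above the
#' global minimum, `dG_d = F(bulk) - F(min)`; the translocation barrier is the
#' profile height at the bilayer centre, `F(cv1 = 0) - F(min)` (evaluated by
#' linear interpolation, regardless of whether cv1 = 0 is a maximum).
#'
#' @param profile A `profile_1d` from [project_1d()].
#' @param bulk_region Length-2 cv1 interval averaged as the bulk plateau;
#'   default: the outer 15 percent of the profile's large-`|cv1|` end.
#' @param min_region Optional length-2 cv1 interval restricting the search for
#'   the global minimum.
#' @return A one-row tibble: `dG_desorption`, `dG_translocation`,
#'   `min_location` (all energies kJ/mol).
#' @export
barriers <- function(profile, bulk_region = NULL, min_region = NULL) {
  cv1 <- profile$cv1; F <- profile$F
  hi <- max(abs(cv1))
  if (min(cv1) > 0 || max(cv1) < 0) {
    abort("profile does not span the bilayer centre (cv1 = 0)")
  }
  bulk_region <- bulk_region %||% c(0.85 * hi, hi)
  if (bulk_region[1] > max(abs(cv1))) abort("bulk region lies outside the profile")
  in_bulk <- abs(cv1) >= bulk_region[1] & abs(cv1) <= bulk_region[2]
  if (!any(in_bulk)) abort("bulk region contains no profile points")
  search <- rep(TRUE, length(cv1))
  if (!is.null(min_region)) {
    search <- cv1 >= min_region[1] & cv1 <= min_region[2]
    if (!any(search)) abort("minimum-search region lies outside the profile")
  }
  f_min <- min(F[search])
  min_loc <- cv1[search][which.min(F[search])]
  f_bulk <- mean(F[in_bulk])
  f_centre <- approx(cv1, F, xout = 0)$y
  tibble(dG_desorption = f_bulk - f_min,
         dG_translocation = f_centre - f_min,
         min_location = min_loc)
}

#' @rdname project_1d
#' @param object A `profile_1d`.
#' @param ... Unused.
#' @method autoplot profile_1d
#' @export
autoplot.profile_1d <- function(object, ...) {
  ggplot(object, aes(x = .data$cv1, y = .data$F)) +
    geom_line() +
    labs(x = sprintf("CV1 (%s)", attr(object, "units") %||% ""),
         y = "F (kJ/mol)")
}

#' Overlay an MFEP on a surface plot
#'
#' @param fes A [fes2d()].
#' @param path An `mfep_path`.
#' @return A ggplot object.
#' @export
plot_fes_path <- function(fes, path) {
  autoplot(fes) +
    geom_path(data = as_tibble(path), aes(x = .data$cv1, y = .data$cv2),
              inherit.aes = FALSE, colour = "black")
}
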