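# Analytic free-energy surfaces on the normalized CV square and a
# well-tempered Metropolis walker that deposits Gaussian hills on them.
#
# Surfaces are parametrized along the diagonal coordinate u = (cv1 + cv2)/2
# with a stiff periodic coupling in v = cv1 - cv2, mimicking the near-diagonal
# valley traced by a rigid solute whose two CV anchor points sit 0.51 nm apart.

#' Analytic toy free-energy surfaces
#'
#' Returns a periodic analytic surface `F(x, y)` (kJ/mol) on the normalized CV
#' square \[-0.5, 0.5\]^2, together with its prescribed minima and barriers.
#'
#' * `"double_well"`: minima on the diagonal at `u = +/- min_loc`, barrier
#'   `barrier` kJ/mol between them (cosine double well, exactly periodic).
#' * `"single_well"`: one diagonal minimum at `u = 0` of depth `depth`.
#' * `"flat"`: identically zero (bias-flatness checks).
#' * `"valley"`: quartic double well along cv1 with a harmonic transverse
#'   channel, `F = barrier (1 - (x / min_loc)^2)^2 + stiff y^2` (string-method
#'   oracle surface; not periodic in x).
#' * `"membrane"`: bulk plateau at 0, Gaussian interfacial minima of depth
#'   `depth` at `u = +/- min_loc`, and a central translocation barrier; the
#'   prescribed desorption barrier is `depth` and the translocation barrier is
#'   `F(0) - F(min)` (both returned).
#'
#' @param kind Surface family (see above).
#' @param barrier Barrier height parameter, kJ/mol.
#' @param depth Well depth parameter, kJ/mol (membrane/single_well).
#' @param min_loc Location of the minima along the relevant coordinate
#'   (normalized units).
#' @param width Gaussian width of the membrane minima (normalized units).
#' @param coupling Transverse stiffness (kJ/mol over the full period).
#' @return A list with elements `fn(x, y)`, `kind`, `minima` (normalized
#'   (cv1, cv2) minima), `desorption`, `translocation` (prescribed barriers,
#'   kJ/mol, NA when undefined).
#' @export
analytic_fes <- function(kind = c("double_well", "single_well", "flat",
                                  "valley", "membrane"),
                         barrier = 10, depth = 20, min_loc = 0.25,
                         width = 0.05, coupling = 50) {
  kind <- match.arg(kind)
  couple <- function(x, y) (coupling / 2) * (1 - cos(2 * pi * wrap_periodic(x - y)))
  out <- switch(kind,
    double_well = {
      # the exactly periodic cosine form pins the minima at u = +/- 0.25
      if (abs(min_loc - 0.25) > 1e-12) {
        abort("double_well is defined with minima at u = +/- 0.25")
      }
      fn <- function(x, y) {
        u <- (x + y) / 2
        (barrier / 2) * (1 + cos(4 * pi * u)) + couple(x, y)
      }
      list(fn = fn, minima = rbind(c(0.25, 0.25), c(-0.25, -0.25)),
           desorption = NA_real_, translocation = barrier)
    },
    single_well = {
      fn <- function(x, y) {
        u <- (x + y) / 2
        (depth / 2) * (1 - cos(2 * pi * u)) + couple(x, y)
      }
      list(fn = fn, minima = rbind(c(0, 0)),
           desorption = depth, translocation = NA_real_)
    },
    flat = {
      list(fn = function(x, y) 0 * x, minima = rbind(c(0, 0)),
           desorption = 0, translocation = 0)
    },
    valley = {
      fn <- function(x, y) barrier * (1 - (x / min_loc)^2)^2 + coupling * y^2
      list(fn = fn, minima = rbind(c(min_loc, 0), c(-min_loc, 0)),
           desorption = NA_real_, translocation = barrier)
    },
    membrane = {
      g <- function(d) exp(-wrap_periodic(d)^2 / (2 * width^2))
      fn <- function(x, y) {
        u <- (x + y) / 2
        -depth * (g(u - min_loc) + g(u + min_loc)) + couple(x, y)
      }
      f_min <- -depth * (1 + exp(-(2 * min_loc)^2 / (2 * width^2)))
      f_ctr <- -2 * depth * exp(-min_loc^2 / (2 * width^2))
      list(fn = fn, minima = rbind(c(min_loc, min_loc), c(-min_loc, -min_loc)),
           desorption = 0 - f_min, translocation = f_ctr - f_min)
    }
  )
  structure(c(out, list(kind = kind)), class = "analytic_fes")
}

#' Deposit tempered Gaussian hills on an analytic surface
#'
#' Runs a 2D overdamped Metropolis walker on `fes$fn` plus the accumulated
#' bias, depositing a Gaussian hill every `stride` moves. Hills keep the
#' initial height `h0` until the local bias exceeds `threshold`, after which
#' heights are tempered well-tempered style,
#' `h = h0 exp(-(V - threshold) / ((gamma - 1) kT))`, mirroring
#' transition-tempered deposition once a transition path is established.
#'
#' @param fes An [analytic_fes()] surface.
#' @param n_hills Number of hills to deposit.
#' @param h0 Initial hill height, kJ/mol (default 0.015).
#' @param sigma Hill width in normalized units (default 0.02, both axes).
#' @param gamma Bias factor (> 1, default 30).
#' @param threshold Tempering threshold, kJ/mol (default 10).
#' @param temperature Walker temperature, kelvin (default 310.15).
#' @param stride Metropolis moves per deposited hill.
#' @param step Proposal standard deviation (normalized units).
#' @param start Starting point, normalized (cv1, cv2); defaults to the first
#'   minimum of `fes`.
#' @param grid_n Resolution of the internal bias grid.
#' @param seed Integer seed (required for reproducibility; deterministic given
#'   the seed).
#' @return A hills tibble (`time`, `center1`, `center2`, `sigma1`, `sigma2`,
#'   `height`, `bias_factor`) acceptable to [reconstruct_fes()] and
#'   [write_hills()].
#' @export
gen_hills_from_fes <- function(fes, n_hills = 20000, h0 = 0.015, sigma = 0.02,
                               gamma = 30, threshold = 10,
                               temperature = 310.15,
                               stride = 20, step = 0.03,
                               start = NULL, grid_n = 201L, seed = 1L) {
  stopifnot_scalar_number(h0, "h0", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(sigma, "sigma", lower = 0, strict_lower = TRUE)
  stopifnot_scalar_number(gamma, "gamma", lower = 1, strict_lower = TRUE)
  kT <- kT_kj(temperature)
  grid_n <- as.integer(grid_n)
  spacing <- 1 / grid_n
  centers <- -0.5 + (seq_len(grid_n) - 0.5) * spacing
  bias <- matrix(0, grid_n, grid_n)

  idx_of <- function(s) {
    i <- floor((s + 0.5) / spacing) + 1L
    ((i - 1L) %% grid_n) + 1L
  }
  # precomputed Gaussian patch offsets (5 sigma support)
  half <- ceiling(5 * sigma / spacing)
  offs <- -half:half
  doffs <- offs * spacing

  s <- if (is.null(start)) as.numeric(fes$minima[1, ]) else start
  f_fn <- fes$fn
  e_cur <- f_fn(s[1], s[2]) + bias[idx_of(s[1]), idx_of(s[2])]

  out_c1 <- numeric(n_hills); out_c2 <- numeric(n_hills); out_h <- numeric(n_hills)

  with_seed(seed, {
    prop <- matrix(rnorm(2 * n_hills * stride, 0, step), ncol = 2)
    uacc <- runif(n_hills * stride)
    move <- 0L
    for (i in seq_len(n_hills)) {
      for (m in seq_len(stride)) {
        move <- move + 1L
        s_new <- wrap_periodic(s + prop[move, ])
        e_new <- f_fn(s_new[1], s_new[2]) + bias[idx_of(s_new[1]), idx_of(s_new[2])]
        if (e_new <= e_cur || uacc[move] < exp(-(e_new - e_cur) / kT)) {
          s <- s_new
          e_cur <- e_new
        }
      }
      v_here <- bias[idx_of(s[1]), idx_of(s[2])]
      h <- if (v_here > threshold) {
        h0 * exp(-(v_here - threshold) / ((gamma - 1) * kT))
      } else h0
      out_c1[i] <- s[1]; out_c2[i] <- s[2]; out_h[i] <- h

      ii <- ((idx_of(s[1]) - 1L + offs) %% grid_n) + 1L
      jj <- ((idx_of(s[2]) - 1L + offs) %% grid_n) + 1L
      dx <- wrap_periodic(centers[ii] - s[1])
      dy <- wrap_periodic(centers[jj] - s[2])
      patch <- h * exp(-outer(dx^2, dy^2, "+") / (2 * sigma^2))
      bias[ii, jj] <- bias[ii, jj] + patch
      e_cur <- f_fn(s[1], s[2]) + bias[idx_of(s[1]), idx_of(s[2])]
    }
  })

  tibble(time = seq_len(n_hills), center1 = out_c1, center2 = out_c2,
         sigma1 = sigma, sigma2 = sigma, height = out_h, bias_factor = gamma)
}
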