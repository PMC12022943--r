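# Toy bilayer trajectory generator.
#
# Emulates the observables the descriptor module measures: a rigid solute
# proxy (four macrocycle "N" sites plus a diametrically opposite "S" pair at
# 0.51 nm from the N-plane centre) placed at sampled depth and tilt, mirrored
# lipid leaflets whose acyl C-H bonds are planted at prescribed order
# parameters, water donors planted at prescribed hydrogen-bond geometries, and
# partial charges giving a prescribed dipole along the ring normal.

unit_vector_from_tilt <- function(theta_deg, phi) {
  th <- theta_deg * pi / 180
  c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
}

any_perpendicular <- function(u) {
  ref <- if (abs(u[3]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  w <- c(u[2] * ref[3] - u[3] * ref[2],
         u[3] * ref[1] - u[1] * ref[3],
         u[1] * ref[2] - u[2] * ref[1])
  w / sqrt(sum(w^2))
}

#' Generate a toy bilayer trajectory
#'
#' Builds a [traj_bundle()] with a rigid solute proxy at sampled insertion
#' depth (N-plane centre of mass above the bilayer centre, in nm) and tilt
#' (angle of the N-centre to S-pair-centre vector from the +z box normal, in
#' degrees), mirrored lipid leaflets (so the all-lipid bilayer centre of mass
#' sits exactly at the box midplane), planted C-H orientations realising a
#' prescribed acyl-chain order-parameter profile, water donors planted at
#' hydrogen-bond-true and hydrogen-bond-decoy geometries around the solute's
#' sulfonamide-oxygen proxies, and solute partial charges realising a
#' prescribed dipole along the macrocycle normal.
#'
#' With `depth_sd = 0` and `tilt_sd = 0` the plants are delta-distributed and
#' the descriptor analyses recover `depth_mean` and `tilt_mean` exactly.
#'
#' @param n_frames Number of frames.
#' @param box Box dimensions in nm (length 3).
#' @param depth_mean,depth_sd Gaussian insertion-depth distribution of the
#'   solute N-plane centre (nm above bilayer centre). Defaults 1.41 and 0.07.
#' @param tilt_mean,tilt_sd Gaussian tilt distribution in degrees (folded into
#'   \[0, 180\]). Defaults 31 and 4.
#' @param n_lipids_per_leaflet Lipids per leaflet (square lattice in xy).
#' @param chain_length Acyl-chain carbons per lipid.
#' @param order_profile Function `(carbon_index, lateral_distance_nm) -> -S_CD`
#'   giving the planted order parameter (must lie in \[-1, 0.5\]).
#' @param hbond_true,hbond_decoy_distance,hbond_decoy_angle Numbers of planted
#'   water donors that satisfy the geometric H-bond criteria, fail on
#'   donor-acceptor distance, and fail on the donor angle, respectively.
#' @param dipole_e_nm Planted solute dipole magnitude in e nm, directed along
#'   the ring normal (0.05 e nm is about 2.4 D).
#' @param seed Integer seed.
#' @return A [traj_bundle()]; the planted per-frame `depth` and `tilt` are
#'   attached as a tibble in `attr(, "truth")`.
#' @export
gen_toy_trajectory <- function(n_frames = 100,
                               box = c(6, 6, 10),
                               depth_mean = 1.41, depth_sd = 0.07,
                               tilt_mean = 31, tilt_sd = 4,
                               n_lipids_per_leaflet = 16,
                               chain_length = 8,
                               order_profile = function(carbon, r) 0.2,
                               hbond_true = 2,
                               hbond_decoy_distance = 1,
                               hbond_decoy_angle = 1,
                               dipole_e_nm = 0.05,
                               seed = NULL) {
  if (depth_sd < 0 || tilt_sd < 0) abort("depth_sd and tilt_sd must be >= 0")
  if (tilt_mean < 0 || tilt_mean > 180) abort("tilt must lie in [0, 180] degrees")
  z_mid <- box[3] / 2

  # topology layout: solute first, then lipids (upper leaflet then mirrored
  # lower leaflet), then planted waters
  solute_names <- c("N1", "N2", "N3", "N4", "S1", "S2", "O1", "O2")
  n_solute <- length(solute_names)
  q_total <- dipole_e_nm / 0.51
  solute_charge <- c(rep(-q_total / 4, 4), rep(q_total / 2, 2), 0, 0)

  side <- ceiling(sqrt(n_lipids_per_leaflet))
  lat <- expand.grid(ix = seq_len(side) - 1, iy = seq_len(side) - 1)[seq_len(n_lipids_per_leaflet), ]
  lip_x <- (lat$ix + 0.5) * box[1] / side
  lip_y <- (lat$iy + 0.5) * box[2] / side
  atoms_per_lipid <- 1 + 3 * chain_length  # P + (C, H, H) per carbon
  lipid_names <- c("P", unlist(lapply(seq_len(chain_length), function(j) {
    c(sprintf("C%d", j), sprintf("H%dA", j), sprintf("H%dB", j))
  })))

  n_waters <- hbond_true + hbond_decoy_distance + hbond_decoy_angle
  water_names <- rep(c("OW", "HW1"), n_waters)

  topo <- tibble(
    name = c(solute_names,
             rep(lipid_names, 2 * n_lipids_per_leaflet),
             water_names),
    resname = c(rep("RDP", n_solute),
                rep("POPC", 2 * n_lipids_per_leaflet * atoms_per_lipid),
                rep("SOL", 2 * n_waters)),
    resid = c(rep(1L, n_solute),
              rep(seq_len(2 * n_lipids_per_leaflet) + 1L, each = atoms_per_lipid),
              rep(seq_len(n_waters) + 1L + 2L * n_lipids_per_leaflet, each = 2)),
    charge = c(solute_charge, rep(0, 2 * n_lipids_per_leaflet * atoms_per_lipid),
               rep(0, 2 * n_waters))
  )

  truth <- tibble(frame = seq_len(n_frames), depth = NA_real_, tilt = NA_real_)

  frames <- with_seed(seed, {
    lapply(seq_len(n_frames), function(f) {
      depth <- depth_mean + if (depth_sd > 0) rnorm(1, 0, depth_sd) else 0
      tilt <- tilt_mean + if (tilt_sd > 0) rnorm(1, 0, tilt_sd) else 0
      tilt <- abs(tilt)
      if (tilt > 180) tilt <- 360 - tilt
      truth$depth[f] <<- depth
      truth$tilt[f] <<- tilt

      u <- unit_vector_from_tilt(tilt, runif(1, 0, 2 * pi))
      w <- any_perpendicular(u)
      v2 <- c(u[2] * w[3] - u[3] * w[2], u[3] * w[1] - u[1] * w[3],
              u[1] * w[2] - u[2] * w[1])
      c1 <- c(box[1] / 2, box[2] / 2, z_mid + depth)
      c2 <- c1 + 0.51 * u
      ring_r <- 0.2
      n_sites <- rbind(c1 + ring_r * w, c1 + ring_r * v2,
                       c1 - ring_r * w, c1 - ring_r * v2)
      s_sites <- rbind(c2 + 0.25 * w, c2 - 0.25 * w)
      o_sites <- rbind(c2 + 0.15 * v2, c2 - 0.15 * v2)
      solute <- rbind(n_sites, s_sites, o_sites)

      # upper leaflet, then an exact mirror through z_mid so that the
      # all-lipid centre of mass is exactly at the box midplane
      upper <- matrix(NA_real_, nrow = n_lipids_per_leaflet * atoms_per_lipid, ncol = 3)
      row <- 1L
      for (l in seq_len(n_lipids_per_leaflet)) {
        px <- lip_x[l]; py <- lip_y[l]; pz <- z_mid + 2.0
        upper[row, ] <- c(px, py, pz); row <- row + 1L
        r_lat <- sqrt((px - c1[1])^2 + (py - c1[2])^2)
        for (j in seq_len(chain_length)) {
          cz <- pz - 0.13 * j
          cpos <- c(px, py, cz)
          upper[row, ] <- cpos; row <- row + 1L
          s_target <- order_profile(j, r_lat)
          if (s_target < -1 || s_target > 0.5) {
            abort("order_profile targets must lie in [-1, 0.5]")
          }
          cos2 <- (1 - 2 * s_target) / 3
          th_ch <- acos(sqrt(cos2))
          for (h in 1:2) {
            phi <- runif(1, 0, 2 * pi)
            dir <- c(sin(th_ch) * cos(phi), sin(th_ch) * sin(phi), cos(th_ch))
            upper[row, ] <- cpos + 0.109 * dir; row <- row + 1L
          }
        }
      }
      lower <- upper
      lower[, 3] <- 2 * z_mid - upper[, 3]

      # planted waters: donor OW with its HW1 pointing at an O acceptor
      waters <- matrix(NA_real_, nrow = 2 * n_waters, ncol = 3)
      wrow <- 1L
      place_water <- function(acc, dist, angle_deg) {
        dir <- c(1, 0, 0)
        d_pos <- acc - dist * dir
        ang <- angle_deg * pi / 180
        h_dir <- c(cos(ang), sin(ang), 0)
        h_pos <- d_pos + 0.1 * h_dir
        rbind(d_pos, h_pos)
      }
      acc_cycle <- function(i) o_sites[(i - 1) %% 2 + 1, ]
      i_w <- 1L
      for (i in seq_len(hbond_true)) {
        waters[wrow:(wrow + 1), ] <- place_water(acc_cycle(i_w), 0.30, 0)
        wrow <- wrow + 2L; i_w <- i_w + 1L
      }
      for (i in seq_len(hbond_decoy_distance)) {
        waters[wrow:(wrow + 1), ] <- place_water(acc_cycle(i_w), 0.45, 0)
        wrow <- wrow + 2L; i_w <- i_w + 1L
      }
      for (i in seq_len(hbond_decoy_angle)) {
        waters[wrow:(wrow + 1), ] <- place_water(acc_cycle(i_w), 0.30, 45)
        wrow <- wrow + 2L; i_w <- i_w + 1L
      }

      rbind(solute, upper, lower, waters)
    })
  })

  bundle <- traj_bundle(frames, box, topo, time = seq_len(n_frames) - 1)
  attr(bundle, "truth") <- truth
  bundle
}
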