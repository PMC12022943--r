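# Per-frame bilayer descriptors: transverse collective variables and tilt,
# depth histograms Boltzmann-inverted to partial free energies, geometric
# hydrogen bonds, distance-resolved acyl-chain order parameters, and
# instantaneous dipole moments.

default_lipid_resnames <- c("POPC", "POPE", "DPPC", "DOPC", "LIP")

com_z <- function(xyz, idx) mean(xyz[idx, 3])

#' Transverse collective variables and tilt
#'
#' For every frame computes `cv1` (signed transverse distance from the
#' macrocycle-N centre of mass to the bilayer centre of mass, nm), `cv2` (the
#' same for the centre of mass of the two diametrically opposite S atoms), and
#' the tilt `theta` (degrees): the angle between the CV1-to-CV2 displacement
#' vector and the +z box normal, reported unfolded on \[0, 180\].
#'
#' The bilayer centre of mass is computed from all lipid atoms (unweighted
#' geometric centre), which is robust to leaflet asymmetry.
#'
#' @param bundle A [traj_bundle()].
#' @param n_atoms,s_atoms Integer atom indices of the macrocycle N atoms and
#'   the S pair; defaults select names starting with "N"/"S" in the solute
#'   residue `RDP`.
#' @param lipid_atoms Indices defining the bilayer; default: all atoms whose
#'   `resname` is a common phospholipid name.
#' @return A tibble (`frame`, `time`, `cv1`, `cv2`, `theta`).
#' @export
compute_cvs <- function(bundle, n_atoms = NULL, s_atoms = NULL,
                        lipid_atoms = NULL) {
  topo <- bundle$topology
  if (is.null(n_atoms)) {
    n_atoms <- which(topo$resname == "RDP" & grepl("^N", topo$name))
  }
  if (is.null(s_atoms)) {
    s_atoms <- which(topo$resname == "RDP" & grepl("^S", topo$name))
  }
  if (is.null(lipid_atoms)) {
    lipid_atoms <- which(topo$resname %in% default_lipid_resnames)
  }
  if (length(n_atoms) == 0 || length(s_atoms) == 0 || length(lipid_atoms) == 0) {
    abort("empty selection: N, S, and lipid groups must all be non-empty")
  }
  purrr::map_dfr(seq_len(n_frames(bundle)), function(f) {
    xyz <- bundle$frames[[f]]
    zb <- com_z(xyz, lipid_atoms)
    c1 <- colMeans(xyz[n_atoms, , drop = FALSE])
    c2 <- colMeans(xyz[s_atoms, , drop = FALSE])
    d <- c2 - c1
    nd <- sqrt(sum(d^2))
    theta <- if (nd == 0) NA_real_ else acos(pmin(1, pmax(-1, d[3] / nd))) * 180 / pi
    tibble(frame = f, time = bundle$time[f],
           cv1 = c1[3] - zb, cv2 = c2[3] - zb, theta = theta)
  })
}

#' Partial free-energy profile from depth sampling
#'
#' Bins the transverse location into a normalized relative-frequency histogram
#' `d(z)` (integrating to 1) and Boltzmann-inverts it,
#' `dG(z) = -RT ln d(z)`, shifted so the minimum is 0. Empty bins are masked
#' (NA).
#'
#' @param series A tibble from [compute_cvs()] (or any data frame), or a bare
#'   numeric vector of depths.
#' @param which Column to bin when `series` is a data frame (`"cv1"` or
#'   `"cv2"`).
#' @param bin_width Bin width in nm.
#' @param temperature Temperature in kelvin.
#' @return A tibble (`z` bin centres, `density`, `dG` in kJ/mol).
#' @export
depth_free_energy <- function(series, which = c("cv1", "cv2"),
                              bin_width = 0.05, temperature = 310.15) {
  z <- if (is.numeric(series)) series else {
    which <- match.arg(which)
    series[[which]]
  }
  z <- z[is.finite(z)]
  if (length(z) < 500) abort("depth free energy needs >= 500 samples")
  stopifnot_scalar_number(bin_width, "bin_width", lower = 0, strict_lower = TRUE)
  edges <- seq(floor(min(z) / bin_width) * bin_width,
               ceiling(max(z) / bin_width) * bin_width + bin_width / 2,
               by = bin_width)
  counts <- graphics::hist(z, breaks = edges, plot = FALSE)$counts
  if (sum(counts > 0) == 1) {
    warn("degenerate depth distribution: all samples fall in one bin")
  }
  density <- counts / (length(z) * bin_width)
  rt <- kT_kj(temperature)
  dg <- ifelse(density > 0, -rt * log(density), NA_real_)
  dg <- dg - min(dg, na.rm = TRUE)
  tibble(z = head(edges, -1) + bin_width / 2, density = density, dG = dg)
}

#' Geometric hydrogen-bond criteria
#'
#' @param max_angle Maximum hydrogen-donor-acceptor angle at the donor,
#'   degrees (default 30).
#' @param max_distance Maximum donor-acceptor distance, nm (default 0.35).
#' @param angle_at Vertex of the angle criterion: `"donor"` (angle between
#'   the D->H and D->A directions, default) or `"hydrogen"` (angle D-H-A).
#' @return An `hbond_criteria` list.
#' @export
hbond_criteria <- function(max_angle = 30, max_distance = 0.35,
                           angle_at = c("donor", "hydrogen")) {
  structure(list(max_angle = max_angle, max_distance = max_distance,
                 angle_at = match.arg(angle_at)),
            class = "hbond_criteria")
}

vec_angle_deg <- function(v1, v2) {
  cosang <- sum(v1 * v2) / sqrt(sum(v1^2) * sum(v2^2))
  acos(pmin(1, pmax(-1, cosang))) * 180 / pi
}

#' Count geometric hydrogen bonds
#'
#' A bond is counted between a donor (with its bonded hydrogen) and an
#' acceptor when the donor-acceptor distance is below `max_distance` and the
#' angle criterion is below `max_angle`.
#'
#' @param bundle A [traj_bundle()].
#' @param donors Tibble with integer columns `donor` and `hydrogen` (atom
#'   indices; every donor must carry its hydrogen) and an optional `category`.
#' @param acceptors Integer vector of acceptor atom indices, or a tibble with
#'   `atom` and optional `category`.
#' @param criteria An [hbond_criteria()].
#' @return A tibble of individual bonds (`frame`, `donor`, `hydrogen`,
#'   `acceptor`, plus any categories). Summarise with [hbond_per_frame()] and
#'   [hbond_averages()].
#' @export
count_hbonds <- function(bundle, donors, acceptors, criteria = hbond_criteria()) {
  donors <- as_tibble(donors)
  if (!all(c("donor", "hydrogen") %in% names(donors)) || anyNA(donors$hydrogen)) {
    abort("every donor must come with its bonded hydrogen (`donor`, `hydrogen` columns)")
  }
  if (is.data.frame(acceptors)) {
    acc_idx <- acceptors$atom
    acc_cat <- if ("category" %in% names(acceptors)) {
      acceptors$category
    } else {
      rep(NA_character_, length(acc_idx))
    }
  } else {
    acc_idx <- acceptors
    acc_cat <- rep(NA_character_, length(acc_idx))
  }
  don_cat <- if ("category" %in% names(donors)) {
    donors$category
  } else {
    rep(NA_character_, nrow(donors))
  }
  if (length(acc_idx) == 0 || nrow(donors) == 0) {
    abort("donor and acceptor selections must be non-empty")
  }

  purrr::map_dfr(seq_len(n_frames(bundle)), function(f) {
    xyz <- bundle$frames[[f]]
    rows <- list()
    for (i in seq_len(nrow(donors))) {
      d <- xyz[donors$donor[i], ]
      h <- xyz[donors$hydrogen[i], ]
      da <- sweep(xyz[acc_idx, , drop = FALSE], 2, d)
      dist <- sqrt(rowSums(da^2))
      ok <- which(dist < criteria$max_distance & dist > 0)
      for (j in ok) {
        ang <- if (criteria$angle_at == "donor") {
          vec_angle_deg(h - d, xyz[acc_idx[j], ] - d)
        } else {
          vec_angle_deg(d - h, xyz[acc_idx[j], ] - h)
        }
        if (ang < criteria$max_angle) {
          rows[[length(rows) + 1]] <- tibble(
            frame = f, donor = donors$donor[i], hydrogen = donors$hydrogen[i],
            acceptor = acc_idx[j], donor_category = don_cat[i],
            acceptor_category = acc_cat[j]
          )
        }
      }
    }
    dplyr::bind_rows(rows)
  })
}

#' Per-frame hydrogen-bond counts
#'
#' @param bonds Output of [count_hbonds()].
#' @param n_frames Total number of frames (frames with zero bonds are kept).
#' @return A tibble (`frame`, `n`).
#' @export
hbond_per_frame <- function(bonds, n_frames) {
  counts <- tibble(frame = seq_len(n_frames))
  if (nrow(bonds) == 0) return(mutate(counts, n = 0L))
  dplyr::left_join(counts,
                   dplyr::count(bonds, .data$frame),
                   by = "frame") |>
    mutate(n = dplyr::coalesce(.data$n, 0L))
}

#' Time-averaged hydrogen-bond counts per category pair
#'
#' @inheritParams hbond_per_frame
#' @return A tibble (`donor_category`, `acceptor_category`, `mean_n`): the
#'   average instantaneous number of bonds per frame in each category pair.
#' @export
hbond_averages <- function(bonds, n_frames) {
  if (nrow(bonds) == 0) {
    return(tibble(donor_category = character(0), acceptor_category = character(0),
                  mean_n = numeric(0)))
  }
  bonds |>
    dplyr::count(.data$donor_category, .data$acceptor_category) |>
    mutate(mean_n = .data$n / n_frames) |>
    dplyr::select(-"n")
}

# lateral (xy) minimum-image distance from one point to a set of points
min_lateral_dist <- function(xy_ref, xy_set, box_xy) {
  dx <- wrap_periodic(xy_set[, 1] - xy_ref[1], box_xy[1])
  dy <- wrap_periodic(xy_set[, 2] - xy_ref[2], box_xy[2])
  min(sqrt(dx^2 + dy^2))
}

#' Distance-resolved acyl-chain order parameters
#'
#' Computes the deuterium order parameter per chain carbon,
#' `S_CD = <3 cos^2(theta_CH) - 1> / 2` with `theta_CH` the C-H bond angle to
#' the bilayer normal (+z), reported with the conventional sign flip as
#' `-S_CD`. Lipids are assigned to radial shells by the minimum lateral
#' (xy, minimum-image) distance between their phosphorus atom and any solute
#' atom in that frame.
#'
#' @param bundle A [traj_bundle()].
#' @param shells Shell edges in nm; default `c(0.6, 1.0)` giving shells
#'   R < 0.6, 0.6 <= R < 1.0, R >= 1.0.
#' @param solute_atoms Indices of the solute (default: residue `RDP`).
#' @param lipid_resnames Residue names treated as lipids.
#' @param carbon_pattern,hydrogen_pattern Regexes extracting the carbon index
#'   from lipid atom names; a hydrogen `H7B` belongs to carbon `C7`.
#' @return A tibble (`carbon`, `shell`, `minus_scd`, `n_samples`); empty
#'   shells are absent (masked).
#' @export
order_parameters <- function(bundle, shells = c(0.6, 1.0),
                             solute_atoms = NULL,
                             lipid_resnames = default_lipid_resnames,
                             carbon_pattern = "^C(\\d+)$",
                             hydrogen_pattern = "^H(\\d+)[A-Z]?$") {
  topo <- bundle$topology
  if (is.null(solute_atoms)) solute_atoms <- which(topo$resname == "RDP")
  if (length(solute_atoms) == 0) abort("empty solute selection")
  lip <- which(topo$resname %in% lipid_resnames)
  if (length(lip) == 0) abort("empty lipid selection")

  is_c <- grepl(carbon_pattern, topo$name) & topo$resname %in% lipid_resnames
  is_h <- grepl(hydrogen_pattern, topo$name) & topo$resname %in% lipid_resnames
  c_tab <- tibble(atom = which(is_c),
                  resid = topo$resid[is_c],
                  carbon = as.integer(sub(carbon_pattern, "\\1", topo$name[is_c])))
  h_tab <- tibble(atom = which(is_h),
                  resid = topo$resid[is_h],
                  carbon = as.integer(sub(hydrogen_pattern, "\\1", topo$name[is_h])))
  if (nrow(c_tab) == 0 || nrow(h_tab) == 0) {
    abort("could not resolve C-H pairs from the topology names")
  }
  pairs <- dplyr::inner_join(c_tab, h_tab, by = c("resid", "carbon"),
                             suffix = c("_c", "_h"), relationship = "many-to-many")
  p_atoms <- tibble(atom = which(topo$name == "P" & topo$resname %in% lipid_resnames),
                    resid = topo$resid[topo$name == "P" & topo$resname %in% lipid_resnames])
  if (nrow(p_atoms) == 0) abort("no lipid phosphorus atoms found for shell assignment")

  shell_label <- function(r) {
    cut(r, breaks = c(-Inf, shells, Inf),
        labels = c(sprintf("R<%.1f", shells[1]),
                   if (length(shells) > 1) {
                     sprintf("%.1f-%.1f", head(shells, -1), tail(shells, -1))
                   },
                   sprintf("R>=%.1f", tail(shells, 1))))
  }

  res <- purrr::map_dfr(seq_len(n_frames(bundle)), function(f) {
    xyz <- bundle$frames[[f]]
    box_xy <- bundle$box[f, 1:2]
    sol_xy <- xyz[solute_atoms, 1:2, drop = FALSE]
    r_by_resid <- vapply(seq_len(nrow(p_atoms)), function(i) {
      min_lateral_dist(xyz[p_atoms$atom[i], 1:2], sol_xy, box_xy)
    }, numeric(1))
    names(r_by_resid) <- as.character(p_atoms$resid)
    ch <- xyz[pairs$atom_h, , drop = FALSE] - xyz[pairs$atom_c, , drop = FALSE]
    cos2 <- (ch[, 3]^2) / rowSums(ch^2)
    tibble(carbon = pairs$carbon,
           shell = shell_label(unname(r_by_resid[as.character(pairs$resid)])),
           scd = (3 * cos2 - 1) / 2)
  })
  res |>
    group_by(.data$carbon, .data$shell) |>
    summarise(minus_scd = -mean(.data$scd), n_samples = dplyr::n(),
              .groups = "drop") |>
    arrange(.data$carbon, .data$shell)
}

#' Instantaneous dipole moment of a charged selection
#'
#' `mu = sum q_i (r_i - r_centroid)` converted to debye (1 e nm = 48.03 D),
#' with the orientation reported as the angle between the dipole and the
#' macrocycle-plane normal (best-fit plane of the ring atoms). For a
#' net-neutral selection the centroid reference leaves the dipole
#' origin-independent; a net-charged selection triggers a warning and the
#' centroid convention is documented behaviour.
#'
#' @param bundle A [traj_bundle()] whose topology carries `charge` (e).
#' @param selection Atom indices of the solute (default: residue `RDP`).
#' @param ring_atoms Atom indices defining the ring plane (default: names
#'   starting with "N" within the selection).
#' @return A tibble (`frame`, `mu_debye`, `angle_deg`).
#' @export
dipole_moment <- function(bundle, selection = NULL, ring_atoms = NULL) {
  topo <- bundle$topology
  if (is.null(selection)) selection <- which(topo$resname == "RDP")
  if (length(selection) == 0) abort("empty selection")
  q <- topo$charge[selection]
  if (abs(sum(q)) > 1e-6) {
    warn("selection has net charge; dipole is reported about the selection centroid")
  }
  if (is.null(ring_atoms)) {
    ring_atoms <- selection[grepl("^N", topo$name[selection])]
  }
  purrr::map_dfr(seq_len(n_frames(bundle)), function(f) {
    xyz <- bundle$frames[[f]]
    r <- xyz[selection, , drop = FALSE]
    r0 <- colMeans(r)
    mu <- colSums(q * sweep(r, 2, r0))
    mu_mag <- sqrt(sum(mu^2)) * DEBYE_PER_E_NM
    ang <- NA_real_
    if (length(ring_atoms) >= 3 && mu_mag > 0) {
      ring <- sweep(xyz[ring_atoms, , drop = FALSE], 2,
                    colMeans(xyz[ring_atoms, , drop = FALSE]))
      normal <- svd(ring)$v[, 3]
      ang <- vec_angle_deg(mu, normal)
      if (ang > 90) ang <- 180 - ang  # plane normal has no preferred sign
    }
    tibble(frame = f, mu_debye = mu_mag, angle_deg = ang)
  })
}
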