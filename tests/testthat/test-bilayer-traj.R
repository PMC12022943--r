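make_bundle <- function(frames, box = c(6, 6, 10), names, resnames,
                        resids = seq_along(names), charges = 0) {
  traj_bundle(frames, box,
              tibble::tibble(name = names, resname = resnames, resid = resids,
                             charge = charges))
}

# one solute atom plus n single-carbon lipids, each carrying one C-H bond
# pointing along the supplied unit vector
one_pair_per_lipid_bundle <- function(dirs) {
  n <- nrow(dirs)
  c_pos <- matrix(runif(3 * n, 1, 5), ncol = 3)
  xyz <- matrix(NA_real_, nrow = 1 + 3 * n, ncol = 3)
  xyz[1, ] <- c(3, 3, 8)
  xyz[1 + seq(1, 3 * n, by = 3), ] <- c_pos            # P
  xyz[1 + seq(2, 3 * n, by = 3), ] <- c_pos            # C1
  xyz[1 + seq(3, 3 * n, by = 3), ] <- c_pos + 0.109 * dirs  # H1A
  make_bundle(list(xyz),
              names = c("X", rep(c("P", "C1", "H1A"), n)),
              resnames = c("RDP", rep("POPC", 3 * n)),
              resids = c(1, rep(seq_len(n) + 1, each = 3)))
}

test_that("collective variables are signed transverse distances", {
  # four N at z = 3.0, S pair at z = 3.2, two lipid atoms with COM z = 1.6
  xyz <- rbind(
    matrix(c(1, 1, 3, 1, 2, 3, 2, 1, 3, 2, 2, 3), ncol = 3, byrow = TRUE),
    matrix(c(1.4, 1.5, 3.2, 1.6, 1.5, 3.2), ncol = 3, byrow = TRUE),
    matrix(c(3, 3, 1.2, 3, 3, 2.0), ncol = 3, byrow = TRUE)
  )
  b <- make_bundle(list(xyz), names = c("N1", "N2", "N3", "N4", "S1", "S2", "P", "P"),
                   resnames = c(rep("RDP", 6), "POPC", "POPC"))
  cv <- compute_cvs(b)
  expect_equal(cv$cv1, 3.0 - 1.6)
  expect_equal(cv$cv2, 3.2 - 1.6)
  expect_equal(cv$theta, 0)  # CV1->CV2 vector along +z

  # in-plane displacement -> theta = 90
  xyz2 <- xyz
  xyz2[5:6, 3] <- 3.0
  xyz2[5:6, 1] <- xyz2[5:6, 1] + 1
  b2 <- make_bundle(list(xyz2), names = b$topology$name,
                    resnames = b$topology$resname)
  expect_equal(compute_cvs(b2)$theta, 90)
})

test_that("collective variables are invariant to a rigid z-translation", {
  b <- gen_toy_trajectory(n_frames = 5, n_lipids_per_leaflet = 4,
                          chain_length = 2, box = c(6, 6, 14), seed = 3)
  cv <- compute_cvs(b)
  shifted <- b
  shifted$frames <- lapply(b$frames, function(m) { m[, 3] <- m[, 3] + 1.3; m })
  cv2 <- compute_cvs(shifted)
  expect_equal(cv2$cv1, cv$cv1, tolerance = 1e-12)
  expect_equal(cv2$cv2, cv$cv2, tolerance = 1e-12)
  expect_equal(cv2$theta, cv$theta, tolerance = 1e-12)
})

test_that("uniform depth samples give a flat partial free-energy profile", {
  set.seed(5)
  z <- runif(1e5, 0, 2)
  prof <- depth_free_energy(z, bin_width = 0.1, temperature = 310.15)
  inner <- prof$dG[prof$z > 0.05 & prof$z < 1.95]
  # binomial sampling error on ~5000 counts/bin -> dG ripple well under 0.2 kJ/mol
  expect_lt(max(inner) - min(inner), 0.2)
})

test_that("Gaussian depths Boltzmann-invert to the harmonic closed form", {
  set.seed(6)
  z <- rnorm(2e5, 1.5, 0.1)
  prof <- depth_free_energy(z, bin_width = 0.02, temperature = 310.15)
  rt <- 8.314 * 310.15 / 1000
  # dG(1.6) - dG(1.5) = RT/2 for a harmonic well of sd 0.1
  dg <- approx(prof$z, prof$dG, xout = c(1.5, 1.6))$y
  expect_equal(dg[2] - dg[1], rt / 2, tolerance = 0.15)
  # full profile matches RT (z - mu)^2 / (2 sd^2) where well sampled
  sel <- abs(prof$z - 1.5) < 0.25 & !is.na(prof$dG)
  analytic <- rt * (prof$z[sel] - 1.5)^2 / (2 * 0.1^2)
  expect_lt(sqrt(mean((prof$dG[sel] - (analytic - min(analytic)))^2)), 0.15)
})

test_that("free-energy inversion recovers a double-well potential", {
  # draw samples from exp(-U/RT) on a fine grid (independent brute-force route)
  rt <- 8.314 * 310.15 / 1000
  zg <- seq(-1, 1, length.out = 2000)
  U <- 8 * (zg^2 - 0.36)^2  # wells at +-0.6, barrier 8 * 0.36^2... scaled
  set.seed(7)
  z <- sample(zg, 2e5, replace = TRUE, prob = exp(-U / rt))
  prof <- depth_free_energy(z, bin_width = 0.05, temperature = 310.15)
  sel <- !is.na(prof$dG)
  U_at <- approx(zg, U - min(U), xout = prof$z[sel])$y
  expect_lt(max(abs(prof$dG[sel] - U_at), na.rm = TRUE), 0.5)
  # bimodal: a positive barrier separates the two modes
  mid <- which.min(abs(prof$z))
  expect_gt(prof$dG[mid], max(prof$dG[which.min(abs(prof$z + 0.6))],
                              prof$dG[which.min(abs(prof$z - 0.6))]))
})

test_that("depth profiles demand enough samples and flag degenerate input", {
  expect_error(depth_free_energy(rnorm(100)), ">= 500")
  expect_warning(depth_free_energy(rep(1, 600), bin_width = 0.5), "one bin")
})

test_that("hydrogen bonds follow the distance and angle criteria exactly", {
  mk <- function(a_pos) {
    xyz <- rbind(c(0, 0, 0), c(0.1, 0, 0), a_pos)
    make_bundle(list(xyz), names = c("OW", "HW1", "O1"),
                resnames = c("SOL", "SOL", "RDP"))
  }
  donors <- tibble::tibble(donor = 1L, hydrogen = 2L)
  # collinear at 0.30 nm: bond
  expect_equal(nrow(count_hbonds(mk(c(0.3, 0, 0)), donors, 3L)), 1)
  # collinear at 0.40 nm: distance fail
  expect_equal(nrow(count_hbonds(mk(c(0.4, 0, 0)), donors, 3L)), 0)
  # 45 degrees off the D->H axis at 0.30 nm: angle fail
  a45 <- 0.3 * c(cos(pi / 4), sin(pi / 4), 0)
  expect_equal(nrow(count_hbonds(mk(a45), donors, 3L)), 0)
  # exactly at the criteria boundary: strict inequalities
  expect_equal(nrow(count_hbonds(mk(c(0.35, 0, 0)), donors, 3L)), 0)
})

test_that("hydrogen-bond counting matches an O(N^2) brute-force scan", {
  set.seed(11)
  for (rep in 1:5) {
    nd <- 30; na <- 40
    d_pos <- matrix(runif(3 * nd, 0, 1.2), ncol = 3)
    h_dir <- matrix(rnorm(3 * nd), ncol = 3)
    h_dir <- h_dir / sqrt(rowSums(h_dir^2))
    h_pos <- d_pos + 0.1 * h_dir
    a_pos <- matrix(runif(3 * na, 0, 1.2), ncol = 3)
    xyz <- rbind(d_pos, h_pos, a_pos)
    b <- make_bundle(list(xyz), box = c(5, 5, 5),
                     names = c(rep("OW", nd), rep("HW1", nd), rep("O1", na)),
                     resnames = rep("SOL", nd * 2 + na))
    donors <- tibble::tibble(donor = seq_len(nd), hydrogen = nd + seq_len(nd))
    acceptors <- 2 * nd + seq_len(na)
    bonds <- count_hbonds(b, donors, acceptors)
    expect_equal(nrow(bonds), oracle_hbonds_frame(xyz, donors, acceptors))
  }
})

test_that("per-frame counts and category averages summarise the planted bonds", {
  b <- gen_toy_trajectory(n_frames = 8, n_lipids_per_leaflet = 4,
                          chain_length = 2, hbond_true = 2,
                          hbond_decoy_distance = 1, hbond_decoy_angle = 1,
                          seed = 13)
  topo <- b$topology
  donors <- tibble::tibble(donor = which(topo$name == "OW"),
                           hydrogen = which(topo$name == "HW1"),
                           category = "water_OH")
  acceptors <- tibble::tibble(atom = which(topo$resname == "RDP" &
                                             grepl("^O", topo$name)),
                              category = "sulfonamide_O")
  bonds <- count_hbonds(b, donors, acceptors)
  pf <- hbond_per_frame(bonds, 8)
  expect_equal(pf$n, rep(2L, 8))
  avg <- hbond_averages(bonds, 8)
  expect_equal(avg$mean_n, 2)
  expect_equal(avg$acceptor_category, "sulfonamide_O")
  expect_error(count_hbonds(b, tibble::tibble(donor = 1L, hydrogen = NA_integer_),
                            acceptors), "hydrogen")
})

test_that("order parameters hit the perpendicular and parallel extremes", {
  mk_op <- function(h_offset) {
    xyz <- rbind(c(3, 3, 8),                      # solute atom
                 c(1, 1, 7), c(1, 1, 6.8),        # P, C1
                 c(1, 1, 6.8) + h_offset,         # H1A
                 c(1, 1, 6.8) + h_offset)         # H1B
    make_bundle(list(xyz), names = c("X", "P", "C1", "H1A", "H1B"),
                resnames = c("RDP", rep("POPC", 4)), resids = c(1, 2, 2, 2, 2))
  }
  perp <- order_parameters(mk_op(c(0.109, 0, 0)))
  expect_equal(perp$minus_scd, 0.5)
  par <- order_parameters(mk_op(c(0, 0, 0.109)))
  expect_equal(par$minus_scd, -1)
})

test_that("isotropic C-H orientations average to zero order", {
  set.seed(21)
  n <- 1e4
  dirs <- matrix(rnorm(3 * n), ncol = 3)
  dirs <- dirs / sqrt(rowSums(dirs^2))
  scd <- (3 * dirs[, 3]^2 - 1) / 2
  # package computation on one big frame: one C-H pair per lipid residue
  b <- one_pair_per_lipid_bundle(dirs)
  op <- order_parameters(b)
  expect_equal(sum(op$n_samples), n)
  pooled <- sum(op$minus_scd * op$n_samples) / n
  expect_equal(pooled, -mean(scd), tolerance = 1e-10)
  expect_lt(abs(pooled), 3 * 0.447 / sqrt(n))
})

test_that("planted Gaussian tilt distributions match the analytic order parameter", {
  set.seed(22)
  n <- 1e4
  th <- rnorm(n, 35, 8) * pi / 180
  phi <- runif(n, 0, 2 * pi)
  dirs <- cbind(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
  b <- one_pair_per_lipid_bundle(dirs)
  op <- order_parameters(b)
  analytic <- -integrate(function(t) {
    ((3 * cos(t * pi / 180)^2 - 1) / 2) * dnorm(t, 35, 8)
  }, -Inf, Inf)$value
  pooled <- sum(op$minus_scd * op$n_samples) / n
  expect_equal(pooled, analytic, tolerance = 0.02)
})

test_that("shell assignment resolves lipids by lateral distance to the solute", {
  b <- gen_toy_trajectory(n_frames = 4, n_lipids_per_leaflet = 16,
                          chain_length = 3,
                          order_profile = function(carbon, r) {
                            if (r < 0.6) 0.4 else if (r < 1.0) 0.25 else 0.1
                          },
                          depth_sd = 0, tilt_sd = 0, seed = 23)
  op <- order_parameters(b)
  wide <- tidyr::pivot_wider(op, id_cols = "carbon", names_from = "shell",
                             values_from = "minus_scd")
  if (all(c("R<0.6", "R>=1.0") %in% names(wide))) {
    expect_true(all(wide[["R<0.6"]] > wide[["R>=1.0"]], na.rm = TRUE))
  }
  expect_true(all(op$minus_scd >= -1 & op$minus_scd <= 0.5))
})

test_that("dipole moments convert charge geometry to debye", {
  xyz <- rbind(c(1, 1, 1), c(1, 1, 1.1))
  b <- make_bundle(list(xyz), names = c("A", "B"), resnames = c("RDP", "RDP"),
                   resids = c(1, 1), charges = c(-0.5, 0.5))
  dm <- dipole_moment(b, selection = 1:2, ring_atoms = integer(0))
  expect_equal(dm$mu_debye, 0.5 * 0.1 * 48.03, tolerance = 1e-6)

  b0 <- make_bundle(list(xyz), names = c("A", "B"), resnames = c("RDP", "RDP"),
                    resids = c(1, 1), charges = c(0, 0))
  expect_equal(dipole_moment(b0, selection = 1:2, ring_atoms = integer(0))$mu_debye, 0)
})

test_that("dipole magnitude is invariant under rigid rotation", {
  b <- gen_toy_trajectory(n_frames = 3, seed = 31)
  dm <- dipole_moment(b)
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  rot <- b
  rot$frames <- lapply(b$frames, function(m) m %*% t(R))
  dm2 <- dipole_moment(rot)
  expect_equal(dm2$mu_debye, dm$mu_debye, tolerance = 1e-9)
  expect_equal(dm2$angle_deg, dm$angle_deg, tolerance = 1e-6)
  # the planted dipole lies along the ring normal
  expect_lt(max(dm$angle_deg), 1e-4)
})
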