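# Independent oracles used to check the implementation paths. These are kept
# deliberately naive (direct formula evaluation, exhaustive search, O(N^2)
# scans) and share no code with the package internals they verify.

# Welch two-sample two-tailed p-value by direct formula evaluation.
oracle_welch_p <- function(a, b) {
  va <- var(a) / length(a)
  vb <- var(b) / length(b)
  t_stat <- (mean(a) - mean(b)) / sqrt(va + vb)
  df <- (va + vb)^2 / (va^2 / (length(a) - 1) + vb^2 / (length(b) - 1))
  2 * pt(-abs(t_stat), df)
}

# Exhaustive grid search for the simple-partition parameters (refined twice).
oracle_partition_grid <- function(lipid_conc, intensity, molar_volume,
                                  lk_range = c(3, 9)) {
  rss_of <- function(lk, iw, im) {
    x <- 10^lk * molar_volume * lipid_conc
    sum((intensity - (iw + im * x) / (1 + x))^2)
  }
  iw_range <- range(intensity) + c(-1, 1) * diff(range(intensity)) * 0.2
  im_range <- iw_range
  best <- c(NA, NA, NA, Inf)
  for (pass in 1:3) {
    lks <- seq(lk_range[1], lk_range[2], length.out = 41)
    iws <- seq(iw_range[1], iw_range[2], length.out = 31)
    ims <- seq(im_range[1], im_range[2], length.out = 31)
    for (lk in lks) for (iw in iws) for (im in ims) {
      r <- rss_of(lk, iw, im)
      if (r < best[4]) best <- c(lk, iw, im, r)
    }
    dl <- diff(lk_range) / 10; di <- diff(iw_range) / 10
    lk_range <- best[1] + c(-dl, dl)
    iw_range <- best[2] + c(-di, di)
    im_range <- best[3] + c(-di, di)
  }
  list(log10_KP = best[1], I_W = best[2], I_M = best[3], rss = best[4])
}

# O(N^2) brute-force hydrogen-bond scan over one frame; angle at the donor.
oracle_hbonds_frame <- function(xyz, donors, acceptors, max_dist = 0.35,
                                max_angle = 30) {
  n <- 0L
  for (i in seq_len(nrow(donors))) {
    d <- xyz[donors$donor[i], ]
    h <- xyz[donors$hydrogen[i], ]
    for (a_idx in acceptors) {
      a <- xyz[a_idx, ]
      dist <- sqrt(sum((a - d)^2))
      if (dist >= max_dist || dist == 0) next
      v1 <- h - d; v2 <- a - d
      ang <- acos(min(1, max(-1, sum(v1 * v2) /
                               sqrt(sum(v1^2) * sum(v2^2))))) * 180 / pi
      if (ang < max_angle) n <- n + 1L
    }
  }
  n
}

# Shortest-bottleneck (minimax) path value between two grid cells on an
# 8-connected grid: binary search over the threshold with flood-fill
# connectivity checks.
oracle_bottleneck <- function(F, start_idx, end_idx) {
  n <- nrow(F); m <- ncol(F)
  connected_below <- function(thr) {
    open <- F <= thr
    if (!open[start_idx[1], start_idx[2]] || !open[end_idx[1], end_idx[2]]) {
      return(FALSE)
    }
    reach <- matrix(FALSE, n, m)
    reach[start_idx[1], start_idx[2]] <- TRUE
    repeat {
      grown <- reach
      for (di in -1:1) for (dj in -1:1) {
        if (di == 0 && dj == 0) next
        src <- reach[max(1, 1 - di):min(n, n - di), max(1, 1 - dj):min(m, m - dj)]
        grown[max(1, 1 + di):min(n, n + di), max(1, 1 + dj):min(m, m + dj)] <-
          grown[max(1, 1 + di):min(n, n + di), max(1, 1 + dj):min(m, m + dj)] | src
      }
      grown <- grown & open
      if (grown[end_idx[1], end_idx[2]]) return(TRUE)
      if (all(grown == reach)) return(FALSE)
      reach <- grown
    }
  }
  vals <- sort(unique(as.vector(F)))
  lo <- 1L; hi <- length(vals)
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (connected_below(vals[mid])) hi <- mid else lo <- mid + 1L
  }
  vals[lo]
}

# Fine-grid trapezoid quadrature for the overlap integral on arbitrary
# functional forms (independent of the package trapezoid path).
oracle_overlap <- function(f_donor, f_acc, lo, hi, n = 200001) {
  wl <- seq(lo, hi, length.out = n)
  fd <- f_donor(wl); ea <- f_acc(wl)
  h <- wl[2] - wl[1]
  trap <- function(y) h * (sum(y) - (y[1] + y[length(y)]) / 2)
  trap(fd * ea * wl^4) / trap(fd)
}

two_component_mix <- function() {
  tibble::tibble(amplitude = c(0.7, 0.3), rate = c(2.0e-4, 3.33e-5))
}
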