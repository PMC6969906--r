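# Independent geometric oracle for the radial law, plus closed-loop helpers.
#
# The oracle never calls forward_map(): it models the retina as K + 1 sensing
# points uniformly spaced along the cap arc (angles beta * k / K), which were
# uniformly spaced on the flat base before deformation (flat radii
# (D/2) * k / K). A stimulus at flat radius L1 is perceived at the planar
# radius R * sin(angle) of the nearest discrete sensing point.
oracle_forward_radius <- function(L1, R, D, K = 1e6) {
  s <- D / 2
  beta <- asin(D / (2 * R))
  k <- round(L1 / s * K)
  R * sin(beta * k / K)
}

oracle_displacement <- function(L1, R, D, K = 1e6) {
  out <- numeric(length(L1))
  inside <- L1 > 0 & L1 < D / 2
  out[inside] <- abs(oracle_forward_radius(L1[inside], R, D, K) - L1[inside])
  out
}

# Brute-force count of 'bad' frames for a line-grid test: pure line-disk
# geometry plus the discrete oracle, no package mapping code.
brute_force_bad_count <- function(canvas, spacing, x0, y0, R, D, delta,
                                  step = 0.05) {
  s <- D / 2
  count_orientation <- function(offsets, centre_perp, centre_par, par_max) {
    bad <- 0L
    for (o in offsets) {
      d <- abs(o - centre_perp)
      if (d >= s) next
      half_chord <- sqrt(s^2 - d^2)
      u <- seq(-half_chord, half_chord, by = step)
      # clip to the canvas extent along the line
      pos <- centre_par + u
      u <- u[pos >= 0 & pos <= par_max]
      if (!length(u)) next
      L1 <- sqrt(d^2 + u^2)
      if (max(oracle_displacement(L1, R, D)) >= delta) bad <- bad + 1L
    }
    bad
  }
  m <- canvas[1L]; n <- canvas[2L]
  count_orientation(seq(0, m - 1, by = spacing), y0, x0, n - 1) +
    count_orientation(seq(0, n - 1, by = spacing), x0, y0, m - 1)
}

# End-to-end closed loop: simulate a patient with one cap lesion on a grid
# test and estimate the lesion centre from the normalized heatmap.
closed_loop <- function(test, x0, y0, D, R = 250, delta = 2,
                        theta_locate = 0.5) {
  lesion <- if (D > 0) list(make_lesion(x0, y0, R = R, D = D)) else list()
  log <- run_test(test, lesion, psychometric_params(threshold_delta = delta))
  C <- collapse_responses(test, log)
  H <- normalize_heatmap(C)
  eta <- distortion_percentage(H, theta = 0)$eta
  est <- tryCatch(estimate_lesion(H, theta_locate), error = function(e) NULL)
  list(eta = eta, centroid = if (is.null(est)) NULL else est$centroid,
       n_bad = sum(log$bits == 0L))
}

centroid_error <- function(loop, x0, y0) {
  if (is.null(loop$centroid)) return(Inf)
  sqrt(sum((loop$centroid - c(x0, y0))^2))
}

grid_test_800 <- function() generate_grid_test(c(800, 800), 10)

checkerboard <- function(m, n, cell = 8) {
  r <- ((seq_len(m) - 1) %/% cell) %% 2
  c <- ((seq_len(n) - 1) %/% cell) %% 2
  outer(r, c, function(a, b) as.numeric(xor(a == 1, b == 1)))
}

# label columns the way package point functions do
as_points_mat <- function(p) {
  p <- matrix(as.numeric(p), nrow = nrow(p))
  colnames(p) <- c("x", "y")
  p
}
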