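test_that("make_lesion validates geometry and derives beta", {
  les <- make_lesion(400, 400, R = 250, variant = "half_sphere")
  expect_equal(les$D, 500)
  expect_equal(les$beta, pi / 2)

  cap <- make_lesion(400, 400, R = 250, D = 125)
  expect_equal(cap$beta, asin(0.25))

  expect_error(make_lesion(400, 400, R = 0, D = 10), "R must be > 0")
  expect_error(make_lesion(400, 400, R = 250, D = -1), "D must be >= 0")
  expect_error(make_lesion(400, 400, R = 250, D = 600), "D must be <= 2R")
  expect_error(make_lesion(400, 400, R = 250, D = 100,
                           variant = "half_sphere"), "D = 2R")
})

test_that("forward map fixes the centre and everything outside the support", {
  cap <- make_lesion(100, -50, R = 80, D = 90)
  s <- cap$D / 2
  expect_identical(forward_map(c(100, -50), cap), c(x = 100, y = -50))
  # boundary and exterior points are exact fixed points (bitwise identity)
  set.seed(42)
  ang <- runif(50, 0, 2 * pi)
  rad <- c(rep(s, 10), runif(40, s, 5 * s))
  pts <- cbind(100 + rad * cos(ang), -50 + rad * sin(ang))
  expect_identical(forward_map(pts, cap), as_points_mat(pts))
})

test_that("forward map reproduces the closed-form worked values", {
  half <- make_lesion(400, 400, R = 250, variant = "half_sphere")
  out <- forward_map(c(400 + 250 / 3, 400), half)
  expect_equal(unname(out[1]), 525, tolerance = 1e-12)  # L2 = 250 sin(pi/6)
  expect_equal(unname(out[2]), 400, tolerance = 1e-12)

  cap <- make_lesion(400, 400, R = 250, D = 125)
  out <- forward_map(c(400, 400 + 31.25), cap)
  # frozen from a 20-digit symbolic evaluation of 250 sin(asin(1/4)/2)
  expect_equal(unname(out[2]) - 400, 31.501073120682025, tolerance = 1e-9)
  expect_equal(unname(out[1]), 400, tolerance = 1e-12)
})

test_that("radial law is monotone, expansive, and direction preserving", {
  set.seed(7)
  for (i in 1:20) {
    R <- runif(1, 50, 400)
    D <- runif(1, 0.2, 2) * R
    les <- make_lesion(0, 0, R = R, D = D)
    s <- D / 2
    L1 <- seq(0, s, length.out = 400)
    pts <- cbind(L1, 0)
    L2 <- forward_map(pts, les)[, 1]
    expect_true(all(diff(L2) > 0))                 # strictly increasing
    expect_true(all(L2 >= L1))                     # expansion
    interior <- L1 > s * 0.05 & L1 < s * 0.95
    expect_true(all(L2[interior] > L1[interior]))  # strict in the interior

    # direction preservation for off-axis points
    ang <- runif(50, 0, 2 * pi)
    rad <- runif(50, s * 0.05, s * 0.95)
    p <- cbind(rad * cos(ang), rad * sin(ang))
    q <- forward_map(p, les)
    dtheta <- atan2(q[, 2], q[, 1]) - atan2(p[, 2], p[, 1])
    dtheta <- (dtheta + pi) %% (2 * pi) - pi
    expect_lt(max(abs(dtheta)), 1e-12)
  }
})

test_that("cap with D = 2R reproduces the half-sphere law exactly", {
  R <- 250
  cap <- make_lesion(0, 0, R = R, D = 2 * R)
  L1 <- seq(0, R, length.out = 200)
  L2 <- forward_map(cbind(L1, 0), cap)[, 1]
  expect_equal(L2, R * sin(pi * L1 / (2 * R)), tolerance = 1e-12)
})

test_that("displacement vanishes as the cavity diameter shrinks", {
  sup_disp <- function(D) {
    les <- make_lesion(0, 0, R = 250, D = D)
    L1 <- seq(0, D / 2, length.out = 2000)
    max(displacement_magnitude(cbind(L1, 0), les))
  }
  sups <- vapply(c(125, 60, 10, 1, 0.01), sup_disp, numeric(1))
  expect_true(all(diff(sups) < 0))
  expect_lt(sups[length(sups)], 1e-6)

  # severity ordering of the two canonical cavity sizes at R = 250
  expect_gt(sup_disp(125), sup_disp(60))

  # D = 0 is the identity everywhere
  none <- make_lesion(0, 0, R = 250, D = 0)
  pts <- cbind(runif(100, -300, 300), runif(100, -300, 300))
  expect_identical(forward_map(pts, none), as_points_mat(pts))
})

test_that("displacement magnitude matches the worked half-sphere value", {
  half <- make_lesion(0, 0, R = 250, variant = "half_sphere")
  expect_equal(displacement_magnitude(c(250 / 3, 0), half),
               125 - 250 / 3, tolerance = 1e-9)
  expect_equal(displacement_magnitude(c(250, 0), half), 0)
})

test_that("inverse map is the exact inverse of the forward map", {
  lesions <- list(
    make_lesion(400, 400, R = 250, variant = "half_sphere"),
    make_lesion(400, 400, R = 250, D = 125),
    make_lesion(-20, 60, R = 90, D = 30)
  )
  set.seed(11)
  for (les in lesions) {
    s <- les$D / 2
    ang <- runif(1000, 0, 2 * pi)
    rad <- sqrt(runif(1000)) * s * 0.999
    pts <- cbind(les$x0 + rad * cos(ang), les$y0 + rad * sin(ang))
    rt <- inverse_map(forward_map(pts, les), les)
    expect_lt(max(sqrt(rowSums((rt - pts)^2))), 1e-9)
    # worked inverse value: half sphere, L2 = 125 -> L1 = 250/3
    if (les$variant == "half_sphere")
      expect_equal(unname(inverse_map(c(les$x0 + 125, les$y0), les)[1]) - les$x0,
                   250 / 3, tolerance = 1e-9)
    # exterior points are untouched
    out <- cbind(les$x0 + (s + runif(100, 0, 100)), les$y0)
    expect_identical(inverse_map(out, les), as_points_mat(out))
  }
})

test_that("forward map agrees with the discrete sensing-point oracle", {
  set.seed(3)
  for (i in 1:10) {
    R <- runif(1, 50, 400)
    D <- runif(1, 0.2, 2) * R
    les <- make_lesion(0, 0, R = R, D = D)
    L1 <- runif(200, 0, D / 2 * 0.999)
    got <- forward_map(cbind(L1, 0), les)[, 1]
    expect_lt(max(abs(got - oracle_forward_radius(L1, R, D))), 1e-3)
  }
})

test_that("build_field caches the composed map and respects support locality", {
  expect_equal(build_field(c(40, 50), list())$dx, matrix(0, 40, 50))

  les <- make_lesion(20, 15, R = 12, D = 18)
  fld <- build_field(c(40, 50), les)
  # matches pointwise forward_map at sampled pixel centres
  for (p in list(c(20, 15), c(22, 18), c(5, 5), c(49, 39))) {
    fw <- forward_map(p, les)
    expect_equal(fld$dx[p[2] + 1, p[1] + 1], unname(fw[1] - p[1]),
                 tolerance = 1e-9)
    expect_equal(fld$dy[p[2] + 1, p[1] + 1], unname(fw[2] - p[2]),
                 tolerance = 1e-9)
  }
  # zero outside the support disk
  xs <- rep(0:49, each = 40); ys <- rep(0:39, times = 50)
  outside <- (xs - 20)^2 + (ys - 15)^2 >= 9^2
  expect_true(all(fld$dx[outside] == 0 & fld$dy[outside] == 0))

  # disjoint supports compose to the union of single-lesion fields
  l1 <- make_lesion(10, 10, R = 10, D = 12)
  l2 <- make_lesion(40, 30, R = 10, D = 12)
  both <- build_field(c(40, 50), list(l1, l2))
  expect_equal(both$dx, build_field(c(40, 50), l1)$dx +
                 build_field(c(40, 50), l2)$dx, tolerance = 1e-12)
  # overlapping supports warn
  l3 <- make_lesion(12, 10, R = 10, D = 12)
  expect_warning(build_field(c(40, 50), list(l1, l3)), "overlap")
})

test_that("lesion configurations round-trip through JSON", {
  lesions <- list(make_lesion(300, 420, R = 250, D = 125),
                  make_lesion(100, 100, R = 50, variant = "half_sphere"))
  path <- withr::local_tempfile(fileext = ".json")
  write_lesions(lesions, path)
  back <- read_lesions(path)
  expect_equal(back, lesions)
})
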