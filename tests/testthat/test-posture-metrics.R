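test_that("curvature index matches hand and oracle values", {
  r <- curvature_index(c(0, 0), c(2, 5), c(0, 10))
  expect_equal(r$x, 10)
  expect_equal(r$f, 2)
  expect_equal(r$ci, 20)

  # apex on the chord
  expect_equal(curvature_index(c(0, 0), c(0, 3), c(0, 10))$ci, 0)

  # slanted chord, checked against the twice-area/base point-line oracle
  r <- curvature_index(c(0, 0), c(0, 4), c(3, 4))
  expect_equal(r$x, 5)
  expect_equal(r$f, dist_point_line(c(0, 4), c(0, 0), c(3, 4)))
  expect_equal(r$f, 2.4)
  expect_equal(r$ci, 48)

  expect_error(curvature_index(c(1, 1), c(0, 0), c(1, 1)), "degenerate chord")
})

test_that("curvature index is invariant under rigid motion and scaling", {
  set.seed(3)
  for (i in 1:30) {
    u <- stats::runif(2, -10, 10); a <- stats::runif(2, -10, 10)
    l <- stats::runif(2, -10, 10)
    base <- curvature_index(u, a, l)
    th <- stats::runif(1, 0, 2 * pi)
    sh <- stats::runif(2, -50, 50)
    sc <- stats::runif(1, 0.1, 10)
    moved <- curvature_index(rigid(u, th, sh, sc), rigid(a, th, sh, sc),
                             rigid(l, th, sh, sc))
    expect_equal(moved$ci, base$ci, tolerance = 1e-9)
    # x and f scale linearly, their ratio does not
    expect_equal(moved$x, sc * base$x, tolerance = 1e-9)
  }
})

test_that("curvature index is zero iff apex is collinear with the limits", {
  set.seed(4)
  for (i in 1:20) {
    u <- stats::runif(2, -10, 10)
    l <- stats::runif(2, -10, 10)
    t <- stats::runif(1)
    on_chord <- u + t * (l - u)
    expect_lt(curvature_index(u, on_chord, l)$ci, 1e-9)
    perp <- c(-(l - u)[2], (l - u)[1])
    off <- on_chord + 0.5 * perp / sqrt(sum(perp^2))
    expect_gt(curvature_index(u, off, l)$ci, 1e-6)
  }
})

test_that("swapping the limit vertebrae leaves x, f and ci unchanged", {
  a <- curvature_index(c(1, 2), c(4, 7), c(3, 13))
  b <- curvature_index(c(3, 13), c(4, 7), c(1, 2))
  expect_equal(a$x, b$x)
  expect_equal(a$f, b$f)
  expect_equal(a$ci, b$ci)
})

test_that("distances and angles follow planar geometry", {
  expect_equal(point_distance(c(0, 0), c(3, 4)), 5)
  expect_equal(point_distance(c(2, 2), c(2, 2)), 0)
  set.seed(5)
  for (i in 1:10) {
    a <- stats::runif(2); b <- stats::runif(2)
    th <- stats::runif(1, 0, 2 * pi); sh <- stats::runif(2, -5, 5)
    expect_equal(point_distance(rigid(a, th, sh), rigid(b, th, sh)),
                 point_distance(a, b), tolerance = 1e-9)
  }
  expect_equal(segment_angle(c(1, 0), c(0, 0), c(0, 1)), 90)
  expect_equal(segment_angle(c(1, 0), c(0, 0), c(2, 0)), 0)
  expect_equal(segment_angle(c(-1, 0), c(0, 0), c(1, 0)), 180)
  expect_equal(segment_angle(c(1, 0), c(0, 0), c(1, 1)), 45)
  expect_error(segment_angle(c(0, 0), c(0, 0), c(1, 0)), "degenerate angle")
})

test_that("polygon area matches shoelace basics and a Monte-Carlo oracle", {
  expect_equal(polygon_area(rbind(c(0, 0), c(1, 0), c(1, 1), c(0, 1))), 1)
  expect_equal(polygon_area(rbind(c(0, 0), c(4, 0), c(0, 3))), 6)
  expect_error(polygon_area(rbind(c(0, 0), c(1, 1))), "insufficient vertices")

  # rejection-sampling oracle on a random convex polygon
  set.seed(6)
  pts <- matrix(stats::runif(16, 0, 10), 8L, 2L)
  hull <- pts[grDevices::chull(pts), ]
  area <- polygon_area(hull)
  n_mc <- 40000L
  xs <- stats::runif(n_mc, 0, 10); ys <- stats::runif(n_mc, 0, 10)
  # convex polygon membership: consistent cross-product sign over edges
  m <- nrow(hull)
  inside <- rep(TRUE, n_mc)
  for (i in seq_len(m)) {
    a <- hull[i, ]; b <- hull[if (i == m) 1L else i + 1L, ]
    cr <- (b[1] - a[1]) * (ys - a[2]) - (b[2] - a[2]) * (xs - a[1])
    inside <- inside & (cr <= 0)
  }
  est <- 100 * mean(inside)
  se <- 100 * stats::sd(inside) / sqrt(n_mc)
  expect_lt(abs(est - area), 4 * se)
})

test_that("polygon area is rigid-invariant and scales quadratically", {
  set.seed(8)
  V <- matrix(stats::runif(10, -5, 5), 5L, 2L)
  V <- V[grDevices::chull(V), ]
  base <- polygon_area(V)
  th <- 1.1; sh <- c(3, -2); sc <- 2.5
  Vm <- t(apply(V, 1L, rigid, theta = th, shift = sh))
  expect_equal(polygon_area(Vm), base, tolerance = 1e-9)
  expect_equal(polygon_area(sc * V), sc^2 * base, tolerance = 1e-9)
})

test_that("measure_frame evaluates the protocol and absorbs calibration scale", {
  protocol <- protocol_config(
    regions = list(list(label = "cervical", upper = "U", apex = "A",
                        lower = "L")))
  fr <- landmark_frame(1L, list(U = c(0, 0), A = c(2, 5), L = c(0, 10)))
  out <- measure_frame(fr, identity_calibration(), protocol)
  expect_equal(out$value[out$metric == "cervical_ci"], 20)
  expect_false(any(out$missing))

  # same pixels x10 under a 0.1 cm/px calibration: identical metrics
  scale_model <- fit_calibration(data.frame(
    u_px = c(0, 100, 0), v_px = c(0, 0, 100),
    x_cm = c(0, 10, 0), y_cm = c(0, 0, 10)))
  fr10 <- landmark_frame(1L, list(U = c(0, 0), A = c(20, 50), L = c(0, 100)))
  out10 <- measure_frame(fr10, scale_model, protocol)
  expect_equal(out10$value, out$value, tolerance = 1e-9)

  # missing apex flags the metric instead of dropping it
  fr_missing <- landmark_frame(2L, list(U = c(0, 0), L = c(0, 10)))
  outm <- measure_frame(fr_missing, identity_calibration(), protocol)
  expect_true(outm$missing[outm$metric == "cervical_ci"])
  expect_true(is.na(outm$value[outm$metric == "cervical_ci"]))
})

test_that("protocol validation names unknown landmarks", {
  protocol <- protocol_config(
    distances = list(list(name = "d", from = "a", to = "zz")))
  expect_error(validate_protocol(protocol, c("a", "b")), "zz")
  expect_silent(validate_protocol(protocol, c("a", "zz")))
})
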