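scene_basic <- function(...) {
  turntable_scene(list(axis = c(0, 0, 0), nose = c(0, 10, 12),
                       shoulder = c(15, 30, 0)),
                  camera_distance = 300, focal_px = 1500,
                  image_size = c(2048, 1536), ...)
}

test_that("pinhole projection respects the turntable geometry", {
  sc <- scene_basic()
  pp <- c(u = 1024, v = 768)
  for (ang in c(0, 37, 90, 180, 271)) {
    expect_equal(project_point(sc, c(0, 0, 0), ang), pp)
  }
  expect_equal(project_point(sc, c(0, 10, 12), 0),
               project_point(sc, c(0, 10, 12), 360))

  # supplementary angles mirror about the principal point's vertical line
  # for points in the X-Y plane; oracle = closed-form pinhole evaluation
  p <- c(8, 20, 0)
  for (phi in c(10, 35, 60)) {
    a <- project_point(sc, p, phi)
    b <- project_point(sc, p, 180 - phi)
    th <- phi * pi / 180
    lateral <- 8 * cos(th)
    depth <- 300 + 8 * sin(th)
    expect_equal(unname(a), c(1024 + 1500 * lateral / depth,
                              768 - 1500 * 20 / depth), tolerance = 1e-9)
    expect_equal(b[["u"]] - 1024, -(a[["u"]] - 1024), tolerance = 1e-9)
    expect_equal(b[["v"]], a[["v"]], tolerance = 1e-9)
  }

  expect_error(project_point(sc, c(0, 0, 300.0001), 0),
               "projection domain")
  expect_error(turntable_scene(list(a = c(400, 0, 0)), camera_distance = 300),
               "radial")
})

test_that("a revolution at 0.7 rpm and 30 Hz yields 2571 frames", {
  sc <- turntable_scene(list(axis = c(0, 100, 0)), platform_rpm = 0.7,
                        frame_rate = 30, camera_distance = 300)
  frames <- simulate_rotation(sc, 1L)
  expect_equal(length(unique(frames$frame_index)), floor(30 * 60 / 0.7))
  expect_equal(length(unique(frames$frame_index)), 2571L)
  expect_true(all(frames$rotation_angle_deg >= 0 &
                    frames$rotation_angle_deg < 360))
  # on-axis landmark is pinned to the same pixel in every noise-free frame
  expect_equal(stats::sd(frames$u_px), 0)
  expect_equal(stats::sd(frames$v_px), 0)
})

test_that("simulation is deterministic in the seed", {
  sc1 <- scene_basic(noise_sd_px = 1.5, seed = 99, platform_rpm = 20)
  sc2 <- scene_basic(noise_sd_px = 1.5, seed = 99, platform_rpm = 20)
  sc3 <- scene_basic(noise_sd_px = 1.5, seed = 100, platform_rpm = 20)
  f1 <- simulate_rotation(sc1, 1L)
  f2 <- simulate_rotation(sc2, 1L)
  f3 <- simulate_rotation(sc3, 1L)
  expect_identical(f1, f2)
  expect_false(identical(f1$u_px, f3$u_px))
})

test_that("far-side landmarks are occluded", {
  sc <- turntable_scene(list(front = c(0, 50, 10)), camera_distance = 300,
                        platform_rpm = 20)
  frames <- simulate_rotation(sc, 1L)
  # the front marker disappears once rotated behind the axis plane
  angles_seen <- frames$rotation_angle_deg[frames$landmark == "front"]
  expect_true(all(cos(angles_seen * pi / 180) >= 0))
  expect_lt(length(unique(frames$frame_index)),
            floor(20 * 60 / 20 * 30) + 1L)
})

test_that("select_frames orders nearest-first with earlier-frame ties", {
  tab <- data.frame(frame_index = 1:3, rotation_angle_deg = c(88, 90, 92),
                    landmark = "p", u_px = 0, v_px = 0)
  sel <- select_frames(tab, 90, 2)
  expect_equal(attr(sel, "selected_frames"), c(2L, 1L, 3L))
  expect_warning(empty <- select_frames(tab, 270, 0.5), "empty selection")
  expect_equal(nrow(empty), 0L)
  expect_true(attr(empty, "empty_selection"))
  # wrap-around angles measure circularly
  tab2 <- data.frame(frame_index = 1:2, rotation_angle_deg = c(359, 183),
                     landmark = "p", u_px = 0, v_px = 0)
  expect_equal(attr(select_frames(tab2, 1, 5), "selected_frames"), 1L)
})

test_that("a full revolution yields exactly 26 selected frames at profile", {
  sc <- turntable_scene(list(spine = c(0, 120, 0)), camera_distance = 300,
                        platform_rpm = 0.7, frame_rate = 30)
  frames <- simulate_rotation(sc, 1L)
  sel <- select_frames(frames, 90, 2, max_frames = 26L)
  expect_equal(length(attr(sel, "selected_frames")), 26L)
})

test_that("projected chord length approaches L|cos(phi)| orthographically", {
  # antero-posterior chord of length 20 at the orthographic limit: large
  # camera distance with focal scaled to keep magnification at 5 px/cm
  L <- 20
  d <- 2e5
  sc <- turntable_scene(list(a = c(0, 0, -L / 2), b = c(0, 0, L / 2)),
                        camera_distance = d, focal_px = 5 * d,
                        image_size = c(2048, 1536))
  for (phi in c(0, 15, 30, 60, 85)) {
    ang <- 90 + phi   # phi measured from profile
    pa <- project_point(sc, c(0, 0, -L / 2), ang)
    pb <- project_point(sc, c(0, 0, L / 2), ang)
    chord_px <- sqrt(sum((pa - pb)^2))
    expected <- 5 * L * abs(cos(phi * pi / 180))
    expect_lt(abs(chord_px - expected), 0.001 * 5 * L)
  }
})

test_that("projected chord length shrinks monotonically away from profile", {
  sc <- turntable_scene(list(a = c(0, 0, -10), b = c(0, 0, 10)),
                        camera_distance = 400, focal_px = 2000)
  lens <- vapply(seq(0, 90, by = 5), function(phi) {
    pa <- project_point(sc, c(0, 0, -10), 90 + phi)
    pb <- project_point(sc, c(0, 0, 10), 90 + phi)
    sqrt(sum((pa - pb)^2))
  }, numeric(1L))
  expect_true(all(diff(lens) <= 1e-9))
})

test_that("window-averaged measurements beat single frames", {
  # noise-free: the mean absolute error over a symmetric window around
  # profile is bounded by the worst single-frame error in the window
  sc <- turntable_scene(list(a = c(0, 0, -10), b = c(0, 0, 10)),
                        camera_distance = 400, focal_px = 400,
                        platform_rpm = 20, occlusion_depth = 12)
  frames <- simulate_rotation(sc, 1L)
  sel <- select_frames(frames, 90, 5, max_frames = 100L)
  chord <- vapply(split(sel, sel$frame_index), function(fr) {
    sqrt((fr$u_px[1] - fr$u_px[2])^2 + (fr$v_px[1] - fr$v_px[2])^2)
  }, numeric(1L))
  err_mean <- abs(mean(chord) - 20)
  err_single <- max(abs(chord - 20))
  expect_lte(err_mean, err_single)

  # with noise: SD of the window mean over seeded replicates is below the
  # single-frame SD
  single <- numeric(20L); window_mean <- numeric(20L)
  for (s in 1:20) {
    scn <- turntable_scene(list(a = c(0, 0, -10), b = c(0, 0, 10)),
                           camera_distance = 400, focal_px = 400,
                           platform_rpm = 20, noise_sd_px = 1,
                           occlusion_depth = 12, seed = s)
    fs <- simulate_rotation(scn, 1L)
    ss <- select_frames(fs, 90, 5, max_frames = 30L)
    ch <- vapply(split(ss, ss$frame_index), function(fr) {
      sqrt((fr$u_px[1] - fr$u_px[2])^2 + (fr$v_px[1] - fr$v_px[2])^2)
    }, numeric(1L))
    single[s] <- ch[1L]
    window_mean[s] <- mean(ch)
  }
  expect_lt(stats::sd(window_mean), stats::sd(single))
})

test_that("rectangle fixture recovers truth: exactly without noise, within
           sampling error with noise", {
  g0 <- generate_rectangle_fixture(noise_sd_px = 0, n_frames = 5L)
  model <- fit_calibration(g0$marks)
  expect_lt(model$residual_rms, 1e-9)
  rep0 <- run_pipeline(g0$frames, model, g0$protocol)
  w <- rep0$metrics$width$summary
  h <- rep0$metrics$height$summary
  expect_equal(w$mean, 25, tolerance = 1e-9)
  expect_equal(h$mean, 15, tolerance = 1e-9)
  expect_lt(w$sd, 1e-9)

  # ~0.2 cm annotation noise at 5 px/cm magnification
  px_per_cm <- 1500 / 300
  gn <- generate_rectangle_fixture(noise_sd_px = 0.2 * px_per_cm,
                                   n_frames = 30L, seed = 12)
  repn <- run_pipeline(gn$frames, fit_calibration(gn$marks), gn$protocol)
  for (metric in c("width", "height")) {
    s <- repn$metrics[[metric]]$summary
    truth <- gn$truth[[metric]]
    se <- s$sd / sqrt(s$n)
    expect_lt(abs(s$mean - truth), 3 * se + 1e-12)
  }

  # seeding contract
  g1 <- generate_rectangle_fixture(noise_sd_px = 2, seed = 5)
  g2 <- generate_rectangle_fixture(noise_sd_px = 2, seed = 5)
  expect_identical(g1$frames, g2$frames)
})
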