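test_that("CoG is the amplitude-weighted centroid", {
  expect_equal(unname(compute_cog(rbind(c(10, -20, 55)), 123)),
               c(10, -20, 55))
  expect_equal(unname(compute_cog(rbind(c(0, 0, 0), c(2, 0, 0)), c(3, 3))),
               c(1, 0, 0))
  # hand evaluation of the weighted-mean formula
  expect_equal(unname(compute_cog(rbind(c(0, 0, 0), c(3, 0, 0), c(0, 3, 0)),
                                  c(1, 2, 3))),
               c(1.0, 1.5, 0.0))
  expect_error(compute_cog(matrix(0, 0, 3), numeric(0)), "no sites")
  expect_error(compute_cog(rbind(c(1, 2, 3)), 0), "positive")
})

test_that("CoG matches a brute-force oracle and its invariances hold", {
  set.seed(101)
  for (i in 1:25) {
    n <- sample(3:40, 1)
    coords <- matrix(rnorm(3 * n, sd = 20), ncol = 3)
    w <- runif(n, 1, 500)
    got <- unname(compute_cog(coords, w))
    want <- oracle_weighted_mean(coords, w)
    expect_equal(got, want, tolerance = 1e-12)
    # uniform amplitude scaling leaves the CoG unchanged
    expect_equal(got, unname(compute_cog(coords, w * 17)),
                 tolerance = 1e-9)
    # rigid translation translates the CoG identically
    shift <- rnorm(3)
    expect_equal(unname(compute_cog(sweep(coords, 2, shift, "+"), w)),
                 got + shift, tolerance = 1e-9)
  }
})

test_that("CoG lies inside the convex hull of its sites", {
  set.seed(55)
  for (i in 1:10) {
    n <- sample(4:30, 1)
    xy <- matrix(rnorm(2 * n, sd = 15), ncol = 2)
    coords <- cbind(xy, 0)
    w <- runif(n, 1, 100)
    cog <- compute_cog(coords, w)
    h <- rev(chull(xy))   # counterclockwise
    expect_true(tmsmap:::point_in_hull(cog[1], cog[2],
                                       xy[h, 1], xy[h, 2], tol = 1e-7))
  }
})

test_that("planar areas: exact polygons and dense-grid alpha shapes", {
  # axis-aligned square, convex hull: exact
  expect_equal(planar_area(c(0, 10, 10, 0), c(0, 0, 10, 10),
                           "convex_hull"), 100, tolerance = 1e-9)
  # right triangle, legs 3 and 4
  expect_equal(planar_area(c(0, 3, 0), c(0, 0, 4), "convex_hull"), 6,
               tolerance = 1e-9)
  # dense grid filling a 20 x 30 rectangle, alpha ample: within 5% of 600
  g <- expand.grid(x = seq(0, 20, by = 2), y = seq(0, 30, by = 2))
  a <- planar_area(g$x, g$y, "alpha_shape", alpha = 15)
  expect_lt(abs(a - 600) / 600, 0.05)
})

test_that("alpha-shape area is bounded by the hull and monotone in alpha", {
  set.seed(77)
  x <- rnorm(60, sd = 12); y <- rnorm(60, sd = 12)
  hull <- planar_area(x, y, "convex_hull")
  alphas <- c(2, 5, 10, 20, 50, 1e6)
  areas <- vapply(alphas,
                  function(a) planar_area(x, y, "alpha_shape", alpha = a),
                  numeric(1))
  expect_true(all(areas <= hull + 1e-6))
  expect_true(all(diff(areas) >= -1e-9))
  # alpha -> infinity recovers the hull
  expect_equal(areas[length(areas)], hull, tolerance = 1e-6)
})

test_that("Delaunay triangulation passes the empty-circumcircle oracle", {
  set.seed(31)
  for (i in 1:5) {
    n <- sample(10:35, 1)
    x <- runif(n, 0, 50); y <- runif(n, 0, 50)
    tris <- delaunay_triangulation(x, y)
    expect_gt(nrow(tris), 0)
    expect_true(oracle_is_delaunay(x, y, tris))
    # the triangles partition the convex hull
    tot <- sum(vapply(seq_len(nrow(tris)), function(k) {
      tr <- tris[k, ]
      tmsmap:::triangle_area(x[tr[1]], y[tr[1]], x[tr[2]], y[tr[2]],
                             x[tr[3]], y[tr[3]])
    }, numeric(1)))
    expect_equal(tot, planar_area(x, y, "convex_hull"), tolerance = 1e-6)
  }
})

test_that("3-D areas are computed on the best-fit plane", {
  # square tilted out of the XY plane: area preserved by the projection
  sq <- cbind(c(0, 10, 10, 0), c(0, 0, 10, 10), 0)
  rot <- function(p, th) {
    R <- rbind(c(1, 0, 0),
               c(0, cos(th), -sin(th)),
               c(0, sin(th), cos(th)))
    p %*% t(R)
  }
  tilted <- rot(sq, 0.6)
  expect_equal(as.numeric(compute_area(tilted, "convex_hull")), 100,
               tolerance = 1e-9)
  # degenerate maps: <3 sites or collinear sites give area 0 with a flag
  expect_warning(a2 <- compute_area(sq[1:2, ]), "degenerate")
  expect_identical(as.numeric(a2), 0)
  expect_true(attr(a2, "degenerate"))
  line <- cbind(1:5, 2 * (1:5), 0)
  expect_warning(a3 <- compute_area(line), "degenerate")
  expect_identical(as.numeric(a3), 0)
})

test_that("summarize_map joins, propagates missing, scale-invariant", {
  coords <- data.frame(stim_id = 1:4,
                       x = c(0, 10, 10, 0), y = c(0, 0, 10, 10),
                       z = c(70, 70, 70, 70))
  mk <- function(a) c(-a / 2, a / 2)
  recs <- detect_meps(lapply(c(100, 200, 300, 400), mk), stim_ids = 1:4)
  mp <- summarize_map("m", recs, coords, method = "convex_hull")
  expect_false(mp$missing)
  expect_equal(mp$area, 100)
  expect_equal(unname(mp$cog),
               oracle_weighted_mean(as.matrix(coords[, c("x", "y", "z")]),
                                    c(100, 200, 300, 400)),
               tolerance = 1e-12)
  # amplitudes scaled x10: identical CoG
  recs10 <- recs; recs10$peak_to_peak <- recs10$peak_to_peak * 10
  expect_equal(summarize_map("m", recs10, coords)$cog, mp$cog,
               tolerance = 1e-9)
  # no accepted MEPs: missing outcome, not an error
  none <- detect_meps(replicate(4, numeric(4), simplify = FALSE),
                      stim_ids = 1:4)
  expect_true(summarize_map("m", none, coords)$missing)
  # unknown stim id: join failure
  bad <- recs; bad$stim_id <- c(1, 2, 3, 99)
  expect_error(summarize_map("m", bad, coords), "99")
})

test_that("CoG recovery: median error below 2 mm over noisy sessions", {
  cfg <- sim_config(n_per_group = 2, n_stims = 100, noise_sd = 20,
                    seed = 2024)
  errs <- vapply(1:30, function(k) {
    ses <- simulate_tms_session(cfg, paste0("R", k), "longissimus_L5")
    recs <- process_epochs(session_epoch_list(ses), ses$sampling_rate,
                           stim_ids = ses$sites$stim_id, filter = FALSE)
    mp <- summarize_map("longissimus_L5", recs, ses$sites)
    sqrt(sum((mp$cog - ses$true_cog)^2))
  }, numeric(1))
  expect_lt(median(errs), 2)
})

test_that("hemisphere pooling mirrors left-side X coordinates only", {
  tab <- data.frame(cog_x = c(10, -12), cog_y = c(1, 2),
                    hemisphere = c("right", "left"))
  out <- pool_hemispheres(tab)
  expect_equal(out$cog_x, c(10, 12))
  expect_equal(out$cog_y, tab$cog_y)
})
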