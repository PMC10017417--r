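# frustum pot lateral-surface sample: radius grows linearly bottom -> top
frustum_points <- function(n, r_bottom, r_top, height, noise_sd = 0,
                           seed = 1) {
  withr::with_seed(seed, {
    h <- runif(n)
    r <- r_bottom + (r_top - r_bottom) * h
    a <- runif(n, 0, 2 * pi)
    pts <- cbind(r * cos(a), r * sin(a), h * height)
    if (noise_sd > 0) pts <- pts + matrix(rnorm(3 * n, 0, noise_sd), n, 3)
    pts
  })
}

test_that("circle fit is exact on exact circles and errors on degeneracy", {
  ang <- (1:36) / 36 * 2 * pi
  fit <- fit_circle_lsm(cbind(cos(ang), sin(ang)))
  expect_equal(fit$center, c(0, 0), tolerance = 1e-9)
  expect_equal(fit$radius, 1, tolerance = 1e-9)

  expect_error(fit_circle_lsm(rbind(c(0, 0), c(1, 1))), "at least 3")
  expect_error(fit_circle_lsm(cbind(1:5, 2 * (1:5) + 3)), "collinear")
})

test_that("circle fit matches a grid-refinement oracle on noisy data", {
  pts <- withr::with_seed(11, {
    a <- runif(100, 0, 2 * pi)
    cbind(5 * cos(a) + 2, 5 * sin(a) - 1) + matrix(rnorm(200, 0, 0.01),
                                                   100, 2)
  })
  fit <- fit_circle_lsm(pts)
  orc <- oracle_circle(pts)
  expect_lt(abs(fit$radius - 5), 0.02)
  expect_lt(abs(fit$radius - orc$radius), 0.02)
  expect_lt(sqrt(sum((fit$center - orc$center)^2)), 0.02)
})

test_that("circle fit is invariant to translation and rotation", {
  pts <- withr::with_seed(4, {
    a <- runif(50, 0, 2 * pi)
    cbind(3 * cos(a), 3 * sin(a)) + matrix(rnorm(100, 0, 0.05), 50, 2)
  })
  f0 <- fit_circle_lsm(pts)
  th <- 0.7
  R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
  moved <- pts %*% t(R) + matrix(c(10, -20), 50, 2, byrow = TRUE)
  f1 <- fit_circle_lsm(moved)
  expect_equal(f1$radius, f0$radius, tolerance = 1e-9)
  expect_equal(as.numeric(f1$center),
               as.numeric(R %*% f0$center + c(10, -20)), tolerance = 1e-9)
})

test_that("pot detection finds the widest slab of a frustum", {
  cl <- point_cloud(frustum_points(6000, 40, 60, 100, noise_sd = 0.05))
  pot <- detect_pot(cl, delta_d = 10)
  expect_equal(pot$r_max, 60, tolerance = 2)
  expect_equal(pot$h, 100, tolerance = 10)
  # oracle: fit every slab independently and take the argmax radius
  z <- cl$points[, 3]
  radii <- sapply(0:9, function(s) {
    idx <- z >= s * 10 & z < (s + 1) * 10
    fit_circle_lsm(cl$points[idx, 1:2])$radius
  })
  # slab boundary membership differs at one z plane; agree to fit noise
  expect_equal(pot$r_max, max(radii), tolerance = 0.01)
})

test_that("constant-radius pots stop the slab climb immediately", {
  cl <- point_cloud(frustum_points(4000, 50, 50, 100, noise_sd = 0.05,
                                   seed = 3))
  pot <- detect_pot(cl, delta_d = 10)
  expect_lte(pot$h, 10)
})

test_that("single-slab clouds give one circle and zero height", {
  cl <- point_cloud(frustum_points(500, 30, 31, 5, seed = 9))
  pot <- detect_pot(cl, delta_d = 10)
  expect_equal(nrow(pot$slabs), 1)
  expect_equal(pot$h, 0)
})

test_that("pot removal separates pot from plant with high recall", {
  plant <- generate_plant(plant_spec(architecture = "FBBS",
                                     n_siliques = 10, seed = 8))
  cl <- plant$cloud
  pot <- detect_pot(cl)
  kept <- remove_pot(cl, pot)
  is_pot <- cl$labels == 0L
  pot_recall <- 1 - sum(kept$labels == 0L) / sum(is_pot)
  plant_above <- cl$labels != 0L & cl$points[, 3] > pot$z_min + pot$h
  plant_retained <- sum(kept$labels != 0L &
                          kept$points[, 3] > pot$z_min + pot$h) /
    sum(plant_above)
  expect_gte(pot_recall, 0.99)
  expect_gte(plant_retained, 0.99)
  # points above the pot band are never removed
  above <- cl$points[, 3] > pot$z_min + pot$h
  expect_equal(sum(above), sum(kept$points[, 3] > pot$z_min + pot$h))
})

test_that("a stem crossing the pot interior is culled inside the band only", {
  pot_pts <- frustum_points(4000, 40, 60, 100, noise_sd = 0.05, seed = 5)
  stem <- make_tube(800, 2, 300, base = c(0, 0, 20), seed = 6)
  cl <- point_cloud(rbind(pot_pts, stem),
                    labels = c(rep(0L, nrow(pot_pts)), rep(1L, nrow(stem))))
  pot <- detect_pot(cl)
  kept <- remove_pot(cl, pot)
  # stem points inside the band are removed (documented collateral) ...
  stem_in_band <- stem[, 3] <= pot$z_min + pot$h
  expect_equal(sum(kept$labels == 1L), sum(!stem_in_band), tolerance = 0.02)
  # ... and the stem above the band survives untouched
  expect_gte(sum(kept$labels == 1L), sum(!stem_in_band) * 0.99)
})
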