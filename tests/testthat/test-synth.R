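test_that("generation is byte-identical per seed", {
  s <- plant_spec(n_siliques = 8, seed = 77)
  a <- generate_plant(s)
  b <- generate_plant(s)
  expect_identical(a$cloud$points, b$cloud$points)
  expect_identical(a$cloud$labels, b$cloud$labels)
  expect_identical(a$truth$siliques, b$truth$siliques)
})

test_that("a plant without siliques has only pot and branch labels", {
  p <- generate_plant(plant_spec(n_siliques = 0, seed = 5))
  expect_true(all(p$cloud$labels <= nrow(p$truth$branches)))
  expect_equal(p$truth$sn, 0)
})

test_that("requested length distribution is realized", {
  p <- suppressWarnings(
    generate_plant(plant_spec(architecture = "MBCS", n_siliques = 200,
                              silique_len_mean = 60, silique_len_sd = 5,
                              seed = 13)))
  expect_equal(nrow(p$truth$siliques), 200)
  expect_lt(abs(mean(p$truth$siliques$true_length) - 60), 1)
})

test_that("true volumes equal cross-section area times length", {
  p <- generate_plant(plant_spec(n_siliques = 10, seed = 3))
  expect_equal(p$truth$siliques$true_volume,
               p$truth$siliques$true_length * 3 * 1.5)
  expect_equal(p$truth$total_sv, sum(p$truth$siliques$true_volume))
})

test_that("labels partition the cloud", {
  p <- generate_plant(plant_spec(n_siliques = 6, seed = 9))
  expect_length(p$cloud$labels, n_points(p$cloud))
  expect_true(all(p$cloud$labels >= 0))
  expect_true(all(p$cloud$labels <=
                    nrow(p$truth$branches) + nrow(p$truth$siliques)))
})

test_that("degradation behaves as specified", {
  p <- generate_plant(plant_spec(n_siliques = 6, seed = 10))
  same <- degrade(p$cloud, 0, 0, seed = 1)
  expect_identical(same, p$cloud)

  half <- degrade(p$cloud, 0, 0.5, seed = 2)
  expect_lt(abs(n_points(half) / n_points(p$cloud) - 0.5), 0.01)
  expect_length(half$labels, n_points(half))

  noisy <- degrade(p$cloud, 0.2, 0, seed = 3)
  expect_equal(n_points(noisy), n_points(p$cloud))
  expect_gt(mean(abs(noisy$points - p$cloud$points)), 0.1)
})

test_that("plant artifacts write as text files", {
  dir <- withr::local_tempdir()
  p <- generate_plant(plant_spec(n_siliques = 4, seed = 2))
  write_plant(p, dir, name = "demo")
  expect_true(file.exists(file.path(dir, "demo.ply")))
  expect_true(file.exists(file.path(dir, "demo_siliques.csv")))
  expect_true(file.exists(file.path(dir, "demo_truth.json")))
  back <- read_cloud(file.path(dir, "demo.ply"))
  expect_identical(back$points, p$cloud$points)
  expect_identical(back$labels, p$cloud$labels)
})
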