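sub_from <- function(m) new_sub_skeleton(as.matrix(m))

test_that("mean connected distance averages every edge", {
  a <- sub_from(rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0), c(4, 0, 0)))
  expect_equal(mean_connected_distance(list(a)), 4 / 3)
  b <- sub_from(rbind(c(0, 0, 0), c(1, 0, 0)))
  d <- sub_from(rbind(c(0, 0, 0), c(3, 0, 0)))
  expect_equal(mean_connected_distance(list(b, d)), 2)
  expect_error(mean_connected_distance(list(sub_from(matrix(0, 1, 3)))),
               "no edges")
  # random fixture equals exhaustive edge enumeration
  pts <- withr::with_seed(1, matrix(runif(30), 10, 3))
  s <- sub_from(pts)
  expect_equal(mean_connected_distance(list(s)),
               mean(sqrt(rowSums((pts[-1, ] - pts[-10, ])^2))))
})

test_that("collinear halves merge; bent or distant pairs do not", {
  left <- sub_from(cbind(0:4, 0, 0))
  right <- sub_from(cbind(6:10, 0, 0))
  m <- try_merge(left, right, dsk_bar = 1)
  expect_false(is.null(m))
  expect_equal(nrow(m$points), 10)
  expect_equal(subskeleton_length(m), 10)

  perp <- sub_from(cbind(0, 1:5, 0) + matrix(c(5, 1, 0), 5, 3, byrow = TRUE))
  expect_null(try_merge(left, perp, dsk_bar = 1))

  far <- sub_from(cbind(11:15, 0, 0))   # gap 6 = 6 x dsk_bar
  expect_null(try_merge(left, far, dsk_bar = 1))
})

test_that("splitting severs sharp interior points only", {
  straight <- sub_from(cbind(0:6, 0, 0))
  expect_length(try_split(straight), 1)

  vee <- sub_from(rbind(c(0, 2, 0), c(0, 1, 0), c(0, 0, 0),
                        c(1, 0, 0), c(2, 0, 0)))
  frags <- try_split(vee)
  expect_length(frags, 2)

  # zig-zag with interior angles 170, 160, 175 -> split only at 160
  ang_pt <- function(prev, ang_deg, step = 1, dir_prev) {
    th <- (180 - ang_deg) * pi / 180
    R <- matrix(c(cos(th), -sin(th), sin(th), cos(th)), 2, 2)
    dir_new <- as.numeric(R %*% dir_prev)
    list(p = prev + step * dir_new, dir = dir_new)
  }
  p <- matrix(c(0, 0), 1, 2); dir <- c(1, 0)
  p <- rbind(p, p[1, ] + dir)
  for (a in c(170, 160, 175)) {
    st <- ang_pt(p[nrow(p), ], a, dir_prev = dir)
    dir <- st$dir
    p <- rbind(p, st$p)
  }
  zig <- sub_from(cbind(p, 0))
  frags2 <- try_split(zig)
  expect_length(frags2, 2)
  expect_equal(nrow(frags2[[1]]$points), 3)  # cut after the 160-degree vertex
})

test_that("optimization repairs the two textbook failure cases", {
  # one pod split into two classes -> one sub-skeleton out
  halves <- list(sub_from(cbind(0:5, 0, 0)), sub_from(cbind(7:12, 0, 0)))
  out <- optimize_subskeletons(halves)
  expect_length(out, 1)

  # two pods fused at a sharp junction -> two sub-skeletons out
  fused <- sub_from(rbind(cbind(0:5, 0, 0),
                          cbind(5 - (1:5) * cos(pi / 4), (1:5) * sin(pi / 4),
                                0)))
  out2 <- optimize_subskeletons(list(fused))
  expect_length(out2, 2)
})

test_that("optimization conserves points and is idempotent", {
  for (seed in 1:20) {
    subs <- withr::with_seed(seed, {
      lapply(seq_len(sample(3:6, 1)), function(i) {
        n <- sample(4:12, 1)
        pts <- make_curve_class(n, sample(c("line", "L", "arc"), 1),
                                seed = seed * 100 + i, spacing = 2)
        # keep classes well apart so merges can only happen within a class
        sub_from(sweep(pts, 2, c(0, 0, 100 * i), "+"))
      })
    })
    once <- optimize_subskeletons(subs)
    all_in <- do.call(rbind, lapply(subs, `[[`, "points"))
    all_out <- do.call(rbind, lapply(once, `[[`, "points"))
    expect_equal(nrow(all_out), nrow(all_in))
    key <- function(m) sort(apply(round(m, 9), 1, paste, collapse = "|"))
    expect_identical(key(all_out), key(all_in))

    twice <- optimize_subskeletons(once)
    expect_length(twice, length(once))
    k1 <- sort(vapply(once, function(s) key(s$points)[1], ""))
    k2 <- sort(vapply(twice, function(s) key(s$points)[1], ""))
    expect_identical(k2, k1)
  }
})

test_that("merging leaves junction angles above the split threshold", {
  left <- sub_from(cbind(0:4, 0, 0))
  # slightly tilted continuation, still under the 15-degree merge gate
  right_pts <- cbind(6:10, (0:4) * tan(10 * pi / 180), 0)
  m <- try_merge(left, sub_from(right_pts), dsk_bar = 1)
  expect_false(is.null(m))
  # no interior vertex of the merged polyline violates the split rule
  expect_length(try_split(m), 1)
})
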