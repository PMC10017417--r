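test_that("DBSCAN separates blobs, joins chains, and matches the oracle", {
  blob1 <- withr::with_seed(1, matrix(rnorm(30, sd = 0.1), 10, 3))
  blob2 <- blob1 + 100
  cc <- cluster_skeleton(rbind(blob1, blob2), eps = 1, min_pts = 3)
  expect_length(cc$classes, 2)
  expect_length(cc$noise, 0)

  chain <- cbind(seq(0, 19) * 0.5, 0, 0)
  cc2 <- cluster_skeleton(chain, eps = 0.8, min_pts = 2)
  expect_length(cc2$classes, 1)

  pts <- withr::with_seed(3, matrix(runif(60, 0, 10), 20, 3))
  got <- cluster_skeleton(pts, eps = 2.5, min_pts = 3)$labels
  want <- oracle_dbscan(pts, 2.5, 3)
  # same partition up to label renumbering
  expect_equal(got == 0, want == 0)
  for (cl in unique(want[want > 0])) {
    members <- which(want == cl)
    expect_length(unique(got[members]), 1)
  }
})

test_that("tangents follow the chord rules", {
  p <- rbind(c(0, 0, 0), c(1, 0, 0), c(2, 0, 0))
  expect_equal(tangent_at(p, 2), c(1, 0, 0))
  ends <- rbind(c(0, 0, 0), c(0, 0, 2))
  expect_equal(tangent_at(ends, 2), c(0, 0, 1))
  tri <- rbind(c(0, 0, 0), c(1, 0, 0), c(1, 1, 0))
  expect_equal(tangent_at(tri, 2), c(1, 1, 0) / sqrt(2))
  expect_error(tangent_at(matrix(0, 1, 3), 1), "isolated")
})

test_that("end points of chains and arcs are recognized", {
  chain <- cbind(0:9, 0, 0)
  expect_true(is_end_point(1, chain))
  expect_true(is_end_point(10, chain))
  expect_false(is_end_point(5, chain))

  arc <- make_curve_class(15, "arc", seed = 2)
  ends <- which(vapply(1:15, is_end_point, TRUE, class_points = arc))
  # oracle: the true ends of a curve class are the end points of the
  # shortest Hamiltonian path on a 10-point subsample containing them
  sub_idx <- round(seq(1, 15, length.out = 10))
  orc <- oracle_shortest_path(arc[sub_idx, ])
  orc_ends <- sub_idx[orc$order[c(1, 10)]]
  expect_setequal(intersect(ends, orc_ends), orc_ends)
})

test_that("connect_class recovers the generative order of curve samples", {
  line <- cbind((1:10) * 2, 0, 0)
  s <- connect_class(line)
  expect_equal(nrow(s$points), 10)
  expect_true(all(s$order == 1:10) || all(s$order == 10:1))

  L <- make_curve_class(24, "L", seed = 4)
  sL <- connect_class(L)
  rho <- suppressWarnings(cor(sL$order, seq_len(24), method = "spearman"))
  expect_equal(abs(rho), 1)

  two <- matrix(c(0, 0, 0, 1, 1, 1), 2, 3, byrow = TRUE)
  s2 <- connect_class(two)
  expect_equal(nrow(s2$points), 2)
  expect_equal(subskeleton_length(s2), sqrt(3))
})

test_that("polylines are single paths: n-1 edges, interior degree 2", {
  for (seed in 1:5) {
    pts <- make_curve_class(40, "arc", seed = seed)
    s <- connect_class(pts)
    expect_equal(nrow(s$points), 40)
    expect_setequal(s$order, 1:40)          # every point exactly once
    edges <- nrow(s$points) - 1             # consecutive-point edges only
    expect_equal(edges, 39)
  }
})

test_that("connected paths stay near the exhaustive shortest path", {
  for (seed in 1:6) {
    pts <- make_curve_class(9, sample(c("line", "L", "arc"), 1), seed = seed)
    s <- connect_class(pts)
    orc <- oracle_shortest_path(pts)
    expect_lte(subskeleton_length(s), 1.05 * orc$length)
  }
})

test_that("direction correction forbids the backward short-cut edge", {
  # hairpin: leg 1 ends at A (index 5), the turn point (6) is the true
  # continuation, and D (index 7) on the return leg sits closer to A than
  # the turn does — but behind the travel direction. The A-D edge is the
  # classic misconnection and must never appear.
  hair <- cbind(rbind(c(0, 0), c(1, 0), c(2, 0), c(3, 0), c(4, 0),
                      c(5, 0.7),              # turn
                      c(3.2, 0.9), c(2.2, 1.1), c(1.2, 1.3), c(0.2, 1.5)),
                0)
  A <- 5; D <- 7; B <- 6
  expect_lt(sqrt(sum((hair[A, ] - hair[D, ])^2)),
            sqrt(sum((hair[A, ] - hair[B, ])^2)))   # D really is closer
  s <- connect_class(hair)
  pos <- match(seq_len(10), s$order)
  expect_gt(abs(pos[A] - pos[D]), 1)     # no A-D edge
  expect_equal(abs(pos[A] - pos[B]), 1)  # A connects to the true turn
})

test_that("cross-class edges never appear", {
  a <- make_curve_class(15, "line", seed = 6)
  b <- make_curve_class(15, "line", seed = 7)
  b[, 2] <- b[, 2] + 100
  skel <- rbind(a, b)
  subs <- connect_skeleton(skel, eps = 5, min_pts = 2, smooth_passes = 0,
                           drop_junctions = FALSE)
  expect_length(subs, 2)
  for (s in subs) {
    spread <- diff(range(s$points[, 2]))
    expect_lt(spread, 50)   # no polyline spans both classes
  }
})
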