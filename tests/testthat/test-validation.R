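test_that("recall ratios follow their defining fractions", {
  r <- recalls(100, 100, 100)
  expect_equal(c(r$re_el, r$re_lm, r$re_em), c(100, 100, 100))
  r2 <- recalls(90, 100, 120)
  expect_equal(r2$re_el, 90)
  expect_equal(r2$re_lm, 100 / 120 * 100)
  expect_equal(round(r2$re_lm, 2), 83.33)
  expect_equal(r2$re_em, 75)
  r3 <- recalls(0, 10, 10)
  expect_equal(c(r3$re_el, r3$re_lm, r3$re_em), c(0, 100, 0))
  expect_error(recalls(5, 0, 10), "positive")
})

test_that("agreement statistics match the textbook formulas", {
  x <- c(1, 2, 3, 4, 5)
  a <- agreement(x, x)
  expect_equal(a$r2, 1)
  expect_equal(a$rmse, 0)
  expect_equal(a$r, 1)

  b <- agreement(-x + 10, x)
  expect_equal(b$r, -1)

  est <- c(12, 15, 13, 19, 22, 24, 21, 30, 28, 33)
  tru <- c(10, 14, 15, 18, 20, 25, 23, 28, 30, 31)
  g <- agreement(est, tru)
  # hand formulas
  r_hand <- sum((est - mean(est)) * (tru - mean(tru))) /
    sqrt(sum((est - mean(est))^2) * sum((tru - mean(tru))^2))
  expect_equal(g$r, r_hand)
  expect_equal(g$r2, r_hand^2)
  expect_equal(g$rmse, sqrt(mean((est - tru)^2)))
  expect_true(g$r2 >= 0 && g$r2 <= 1)

  ident <- agreement(est, tru, r2_method = "identity")
  expect_equal(ident$r2, 1 - sum((est - tru)^2) / sum((tru - mean(tru))^2))

  expect_error(agreement(1:3, 1:4), "same length")
  expect_error(agreement(1:3, c(2, 2, 2)), "constant")
})
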