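test_that("period_change computes cellwise deltas and change-SDs", {
  m <- matrix(c(1, 2, 3, 4), 2, 2)
  # identical epochs: zero deltas, zero sigma
  ch0 <- period_change(stack2(m, m), stack2(m, m), 2000, 2020)
  expect_true(all(grid_values(ch0$d_hfi) == 0))
  expect_equal(ch0$sigma_d_hfi, 0)
  # uniform +5 shift: constant delta, zero sigma
  ch5 <- period_change(stack2(m, m + 5), stack2(m, m), 2000, 2020)
  expect_true(all(grid_values(ch5$d_hfi) == 5))
  expect_equal(ch5$sigma_d_hfi, 0)
  expect_error(period_change(stack2(m, m), stack2(m, m), 2000, 2015),
               "not present")
})

test_that("change-SD matches the analytic SD of a block mixture of shifts", {
  # half the cells shift +a, half +b, no noise: SD = |a-b|/2 * sqrt(n/(n-1))
  # with the sample convention; compare against sd() of the planted deltas
  n <- 20
  m0 <- matrix(50, n, n)
  shifts <- matrix(rep(c(4, -2), each = n * n / 2), n, n)
  ch <- period_change(stack2(m0, m0 + shifts), stack2(m0, m0), 2000, 2020)
  expect_equal(ch$sigma_d_hfi, sd(as.vector(shifts)), tolerance = 1e-12)
})

test_that("classify_quadrant applies the sign rules and significance rule", {
  # build a change object with sigma 1 on both axes via planted deltas
  n <- 100
  set.seed(6)
  dh <- matrix(rnorm(n * n), n, n)
  de <- matrix(rnorm(n * n), n, n)
  base <- matrix(50, n, n)
  ch <- period_change(stack2(base, base + dh), stack2(base, base + de),
                      2000, 2020)
  q <- classify_quadrant(ch, sigma_fraction = 0.1)
  sh <- 0.1 * ch$sigma_d_hfi; se <- 0.1 * ch$sigma_d_eqi
  pick <- function(cond) unique(q$values[cond])
  expect_equal(pick(dh >= sh & de >= se), QUADRANT_CLASSES[["coordination"]])
  expect_equal(pick(dh <= -sh & de >= se),
               QUADRANT_CLASSES[["good_for_nature"]])
  expect_equal(pick(dh <= -sh & de <= -se),
               QUADRANT_CLASSES[["degradation"]])
  expect_equal(pick(dh >= sh & de <= -se), QUADRANT_CLASSES[["conflict"]])
  # a cell tiny on one axis is insignificant under the "or" rule ...
  expect_equal(pick(abs(dh) < 0.05 * sh & de > 2 * se),
               QUADRANT_CLASSES[["insignificant"]])
  # ... but keeps its quadrant under the "and" rule
  q_and <- classify_quadrant(ch, sigma_fraction = 0.1, rule = "and")
  expect_equal(unique(q_and$values[abs(dh) < 0.05 * sh & de > 2 * se &
                                     dh >= 0]),
               QUADRANT_CLASSES[["coordination"]])
  # partition property: every unmasked cell has exactly one known code
  expect_true(all(q$values[!q$mask] %in% QUADRANT_CLASSES))
})

test_that("negating both change grids swaps opposite quadrants", {
  n <- 40
  set.seed(7)
  dh <- matrix(rnorm(n * n), n, n); de <- matrix(rnorm(n * n), n, n)
  base <- matrix(50, n, n)
  q1 <- classify_quadrant(period_change(stack2(base, base + dh),
                                        stack2(base, base + de), 2000, 2020))
  q2 <- classify_quadrant(period_change(stack2(base, base - dh),
                                        stack2(base, base - de), 2000, 2020))
  swap <- c(`1` = 3, `2` = 4, `3` = 1, `4` = 2, `5` = 5)
  expect_equal(unname(swap[as.character(q1$values)]), as.vector(q2$values))
})

test_that("the insignificant share is non-decreasing in sigma_fraction", {
  n <- 30
  set.seed(8)
  base <- matrix(50, n, n)
  ch <- period_change(stack2(base, base + matrix(rnorm(n * n), n, n)),
                      stack2(base, base + matrix(rnorm(n * n), n, n)),
                      2000, 2020)
  shares <- vapply(c(0.05, 0.1, 0.2, 0.5, 1), function(f) {
    p <- area_proportions(classify_quadrant(ch, sigma_fraction = f))
    p$percent[p$class == "insignificant"]
  }, 0)
  expect_true(all(diff(shares) >= 0))
})

test_that("area_proportions counts classes and honours region masks", {
  spec <- synthetic_raster_spec(shape = c(20, 20), noise_sd = 0,
                                nodata_fraction = 0)
  b <- generate_coupled_stacks(spec)
  q <- classify_quadrant(period_change(b$hfi, b$eqi, 2000, 2020))
  p <- area_proportions(q)
  expect_equal(p$percent[1:4], rep(25, 4))
  expect_equal(sum(p$percent), 100, tolerance = 1e-12)
  # planted 3:5 coordination:conflict fixture recovered exactly
  lay <- data.frame(row0 = c(1, 4), row1 = c(3, 8), col0 = 1, col1 = 8,
                    class = c("coordination", "conflict"),
                    d_hfi = c(10, 10), d_eqi = c(10, -10))
  sp2 <- synthetic_raster_spec(shape = c(8, 8), block_layout = lay,
                               noise_sd = 0, nodata_fraction = 0)
  b2 <- generate_coupled_stacks(sp2)
  q2 <- classify_quadrant(period_change(b2$hfi, b2$eqi, 2000, 2020))
  p2 <- area_proportions(q2)
  co <- p2$count[p2$class == "coordination"]
  cf <- p2$count[p2$class == "conflict"]
  expect_equal(co / cf, 3 / 5)
  # region restriction and empty-region error
  left <- matrix(rep(c(TRUE, FALSE), each = 200), 20, 20)
  expect_equal(sum(area_proportions(q, left)$count), 200L)
  expect_error(area_proportions(q, matrix(FALSE, 20, 20)), "no unmasked")
})
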