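test_that("evi_proxies returns interpolated percentiles over unmasked cells", {
  g <- g_(matrix(1:100, 10, 10))
  expect_equal(unname(evi_proxies(g)), c(5.95, 95.05))
  g2 <- g_(matrix(c(0, 1), 1, 2))
  expect_equal(unname(evi_proxies(g2)), c(0.05, 0.95))
  expect_error(evi_proxies(g_(matrix(0.4, 3, 3))), "degenerate")
  expect_error(evi_proxies(g, p_soil = 95, p_veg = 5))
  # masked cells are excluded from the percentile pool
  v <- matrix(1:100, 10, 10); v[1:50] <- NA
  expect_equal(unname(evi_proxies(g_(v))[2]), unname(quantile(51:100, 0.95)))
})

test_that("compute_fvc applies the linear rescale with clamping", {
  g <- g_(matrix(c(0.5, 0.9, 0.05, 0.95), 2, 2))
  f <- compute_fvc(g, 0.1, 0.9)
  expect_equal(f$values[1, 1], 0.5)   # (0.5-0.1)/0.8
  expect_equal(f$values[2, 1], 1.0)   # at the vegetated reference
  expect_equal(f$values[1, 2], 0.0)   # clamped below soil reference
  expect_error(compute_fvc(g, 0.9, 0.1), "below")
  # clamping guarantees [0,1] for arbitrary inputs
  wild <- compute_fvc(g_(matrix(rnorm(100, 0, 10), 10, 10)), 0.1, 0.9)
  expect_true(all(grid_values(wild) >= 0 & grid_values(wild) <= 1))
})

test_that("compute_eqi averages the three indicators onto 0-100", {
  one <- function(x) g_(matrix(x, 2, 2))
  expect_equal(compute_eqi(one(1), one(1), one(1))$values[1, 1], 100)
  expect_equal(compute_eqi(one(0), one(0), one(0))$values[1, 1], 0)
  expect_equal(compute_eqi(one(0.3), one(0.6), one(0.9))$values[1, 1], 60)
  # symmetric in its arguments and monotone in each
  set.seed(2)
  a <- g_(matrix(runif(9), 3, 3)); b <- g_(matrix(runif(9), 3, 3))
  cc <- g_(matrix(runif(9), 3, 3))
  expect_equal(compute_eqi(a, b, cc)$values, compute_eqi(cc, a, b)$values)
  bumped <- compute_eqi(grid_map(a, function(v) pmin(v + 0.05, 1)), b, cc)
  expect_true(all(bumped$values >= compute_eqi(a, b, cc)$values - 1e-12))
  expect_error(compute_eqi(one(1.4), one(0.5), one(0.5)), "\\[0, 1\\]")
  # mask union propagates
  am <- g_(matrix(c(NA, 0.5, 0.5, 0.5), 2, 2))
  expect_identical(sum(compute_eqi(am, one(0.5), one(0.5))$mask), 1L)
})

test_that("minmax_normalize maps endpoints, preserves order, idempotent", {
  expect_equal(minmax_normalize(c(2, 4, 6), 0, 100), c(0, 50, 100))
  expect_equal(minmax_normalize(c(0.2, 0.8), 0, 1), c(0, 1))
  # already-normalized data are unchanged
  x <- c(0, 0.25, 1)
  expect_equal(minmax_normalize(x, 0, 1), x)
  # strictly monotone
  set.seed(3)
  y <- rnorm(50)
  expect_identical(order(minmax_normalize(y, 0, 1)), order(y))
  expect_error(minmax_normalize(g_(matrix(5, 2, 2)), 0, 1), "degenerate")
})

test_that("pooled-epoch normalization shares one min-max across the stack", {
  s <- stack2(matrix(c(0, 10), 1, 2), matrix(c(0, 20), 1, 2))
  pooled <- minmax_normalize(s, 0, 100, domain = "pooled")
  expect_equal(max(grid_values(pooled$grids[[1]])), 50)   # epoch-1 max -> 50
  expect_equal(max(grid_values(pooled$grids[[2]])), 100)
  per <- minmax_normalize(s, 0, 100, domain = "per-epoch")
  expect_equal(max(grid_values(per$grids[[1]])), 100)
})

test_that("jenks_breaks finds the optimal contiguous partition", {
  expect_equal(jenks_breaks(c(1, 2, 3, 10, 11, 12), 2), 3)
  expect_identical(jenks_breaks(c(5, 1, 9), 1), numeric(0))
  # saturated partition: every distinct value its own class, zero SSE
  x <- c(2, 7, 11, 20)
  b <- jenks_breaks(x, 4)
  expect_equal(jenks_sse(x, b), 0)
  expect_error(jenks_breaks(c(1, 1, 2), 3), "distinct")
  # spot-check optimality against the exhaustive oracle
  set.seed(4)
  for (i in 1:20) {
    x <- round(rnorm(sample(6:12, 1)), 2)
    if (length(unique(x)) < 4) next
    k <- sample(2:4, 1)
    expect_equal(jenks_sse(x, jenks_breaks(x, k)),
                 exhaustive_jenks_sse(x, k), tolerance = 1e-10)
  }
})

test_that("classify_natural_breaks keeps class ranges fixed across epochs", {
  set.seed(5)
  s <- stack2(matrix(runif(100, 0, 50), 10, 10),
              matrix(runif(100, 30, 100), 10, 10))
  cl <- classify_natural_breaks(s, k = 5)
  expect_length(cl$breaks, 4)
  expect_length(cl$classes, 2)
  # a cell valued at a break goes to the lower class
  g <- g_(matrix(c(1, 2, 3, 10, 11, 12), 2, 3))
  cg <- classify_natural_breaks(g, k = 2)
  expect_equal(cg$classes$values[matrix(c(1, 2), 1)], 1)  # value 3 == break
  expect_equal(sort(unique(as.vector(cg$classes$values))), c(1, 2))
})
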