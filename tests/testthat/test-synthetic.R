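test_that("raster generator is deterministic and validates its spec", {
  sp <- synthetic_raster_spec(shape = c(16, 16), noise_sd = 2,
                              nodata_fraction = 0.1, seed = 21)
  a <- generate_coupled_stacks(sp)
  b <- generate_coupled_stacks(sp)
  expect_identical(a$hfi$grids[[2]]$values, b$hfi$grids[[2]]$values)
  expect_identical(a$eqi$grids[[3]]$values, b$eqi$grids[[3]]$values)
  expect_error(synthetic_raster_spec(shape = c(1, 5)), "degenerate")
  expect_error(synthetic_raster_spec(epochs = 2000), "two strictly")
  over <- quadrant_block_layout(c(10, 10))
  over$row1[1] <- 7   # now overlaps the block below
  expect_error(synthetic_raster_spec(shape = c(10, 10), block_layout = over),
               "overlap")
})

test_that("planted block trends are realised in the block means", {
  sp <- synthetic_raster_spec(shape = c(40, 40), noise_sd = 0.5,
                              nodata_fraction = 0, seed = 3)
  b <- generate_coupled_stacks(sp)
  d_hfi <- stack_epoch(b$hfi, 2020)$values - stack_epoch(b$hfi, 2000)$values
  for (i in seq_len(nrow(sp$block_layout))) {
    blk <- sp$block_layout[i, ]
    got <- mean(d_hfi[blk$row0:blk$row1, blk$col0:blk$col1])
    expect_equal(got, blk$d_hfi, tolerance = 0.15)  # ~4 sigma sampling band
  }
  # the common nodata mask is identical across epochs and both stacks
  sp2 <- synthetic_raster_spec(shape = c(30, 30), nodata_fraction = 0.2,
                               seed = 4)
  b2 <- generate_coupled_stacks(sp2)
  expect_identical(b2$hfi$grids[[1]]$mask, b2$eqi$grids[[3]]$mask)
})

test_that("SEM generator reproduces the planted cross-indicator correlation", {
  B <- matrix(c(0, 0, 0.6, 0), 2, 2, byrow = TRUE)
  ls <- latent_model_spec(c("A", "B"), B, list(A = "a1", B = "b1"),
                          c(a1 = 0.9, b1 = 0.9), n = 5000, seed = 2)
  tb <- generate_sem_table(ls)
  # population correlation 0.9 * 0.6 * 0.9 = 0.486
  expect_lt(abs(cor(tb$data$a1, tb$data$b1) - 0.486), 0.03)
  expect_equal(tb$truth$path_matrix[2, 1], 0.6)
  expect_equal(unname(tb$truth$loadings), c(0.9, 0.9))
  # exported columns are standardized
  expect_equal(sd(tb$data$a1), 1, tolerance = 1e-12)
})

test_that("zero paths give independent blocks; unit loadings give identity", {
  B0 <- matrix(0, 2, 2)
  ls0 <- latent_model_spec(c("A", "B"), B0, list(A = "a1", B = "b1"),
                           c(a1 = 0.9, b1 = 0.9), n = 4000, seed = 5)
  tb0 <- generate_sem_table(ls0)
  expect_lt(abs(cor(tb0$data$a1, tb0$data$b1)), 0.05)
  ls1 <- latent_model_spec(c("A", "B"), B0, list(A = "a1", B = "b1"),
                           c(a1 = 1, b1 = 1), n = 500, seed = 6)
  tb1 <- generate_sem_table(ls1)
  expect_equal(cor(tb1$data$a1, tb1$latents[, "A"]), 1, tolerance = 1e-12)
  expect_error(latent_model_spec(c("A", "B"), matrix(c(0, 0.6, 0, 0), 2, 2,
                                                     byrow = TRUE),
                                 list(A = "a1", B = "b1"),
                                 c(a1 = 0.9, b1 = 0.9), n = 500),
               "lower-triangular")
})

test_that("explicit noise SDs are honoured with analytic standardized truth", {
  B <- matrix(c(0, 0, 0.6, 0), 2, 2, byrow = TRUE)
  ls <- latent_model_spec(c("A", "B"), B, list(A = "a1", B = "b1"),
                          c(a1 = 0.8, b1 = 0.8),
                          structural_noise_sd = c(A = 1, B = 1),
                          measurement_noise_sd = c(a1 = 0.6, b1 = 0.6),
                          n = 6000, seed = 7)
  tb <- generate_sem_table(ls)
  # Var(B) = 0.36 + 1; standardized path 0.6 / sqrt(1.36)
  expect_equal(tb$truth$path_matrix[2, 1], 0.6 / sqrt(1.36))
  lam <- 0.8 / sqrt(0.64 + 0.36)
  expect_equal(unname(tb$truth$loadings["a1"]), lam)
  expect_equal(cor(tb$data$a1, tb$data$b1),
               lam^2 * tb$truth$path_matrix[2, 1], tolerance = 0.035)
})

test_that("driver rasters realise the requested correlation structure", {
  prs <- data.frame(a = "PRE", b = "TEM", r = 0.8)
  drv <- generate_driver_rasters(c(100, 100), prs, seed = 8)
  expect_named(drv, DRIVER_NAMES)
  expect_equal(cor(grid_values(drv$PRE), grid_values(drv$TEM)), 0.8,
               tolerance = 0.05)
  # uncorrelated pair stays near zero
  expect_lt(abs(cor(grid_values(drv$ELE), grid_values(drv$GDP))), 0.05)
  # determinism
  drv2 <- generate_driver_rasters(c(100, 100), prs, seed = 8)
  expect_identical(drv$NL$values, drv2$NL$values)
  # infeasible correlation matrix is rejected
  bad <- data.frame(a = c("PRE", "PRE", "TEM"), b = c("TEM", "ET", "ET"),
                    r = c(0.9, 0.9, -0.9))
  expect_error(generate_driver_rasters(c(10, 10), bad, seed = 1),
               "positive semi-definite")
  expect_error(generate_driver_rasters(c(10, 10),
                                       data.frame(a = "PRE", b = "TEM", r = 1)),
               "\\(-1, 1\\)")
})

test_that("planted r = 0.99 pair is flagged by the downstream VIF", {
  drv <- generate_driver_rasters(c(60, 60),
                                 data.frame(a = "NL", b = "PD", r = 0.99),
                                 seed = 9)
  tab <- as.data.frame(lapply(drv, grid_values))
  names(tab) <- names(drv)
  v <- vif(tab, c("NL", "PD"))
  expect_gt(min(v), 6)        # 1/(1-0.99^2) ~ 50.3
  drv0 <- generate_driver_rasters(c(60, 60), NULL, seed = 10)
  tab0 <- as.data.frame(lapply(drv0, grid_values))
  expect_lt(max(vif(tab0)), 1.1)
})

test_that("analysis bundle plants the latent model within every region", {
  rs <- synthetic_raster_spec(shape = c(70, 70), noise_sd = 1,
                              nodata_fraction = 0.02, seed = 12)
  bun <- generate_analysis_bundle(rs)
  tab <- build_driver_table(bun$drivers, bun$ccd_grid, bun$quadrant_map)
  expect_setequal(unique(tab$region),
                  c("coordination", "good_for_nature", "degradation",
                    "conflict"))
  R <- bun$truth$latent_correlation
  for (reg in c("coordination", "conflict")) {
    rows <- tab[tab$region == reg, ]
    z <- qnorm((rank(rows$CCD) - 0.5) / nrow(rows))
    # indicator-CCD correlation ~ loading * latent correlation
    expect_lt(abs(cor(rows$NL, z) - 0.9 * R["Hum", "CCD"]), 0.1)
    expect_lt(abs(cor(rows$NPP, z) - 0.9 * R["Veg", "CCD"]), 0.1)
  }
})
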