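test_that("path_model_spec validates blocks and acyclicity", {
  expect_error(path_model_spec(c("A", "B"), list(A = "x", B = "x"),
                               data.frame(from = "A", to = "B")),
               "exactly one block")
  expect_error(path_model_spec(c("A", "B"), list(A = "x1", B = "x2"),
                               data.frame(from = "B", to = "A")),
               "acyclic")
  expect_error(path_model_spec(c("A", "B"), list(A = "x1", B = "x2"),
                               data.frame(from = "A", to = "Z")),
               "not a declared latent")
  sp <- default_path_model()
  expect_s3_class(sp, "path_model_spec")
  expect_identical(sum(sp$adj), 9L)
})

test_that("single-indicator blocks collapse to chained standardized OLS", {
  set.seed(20)
  n <- 400
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- -0.5 * d$x1 + rnorm(n)
  d$x3 <- 0.4 * d$x1 + 0.3 * d$x2 + rnorm(n)
  sp <- path_model_spec(c("A", "B", "C"),
                        list(A = "x1", B = "x2", C = "x3"),
                        data.frame(from = c("A", "A", "B"),
                                   to = c("B", "C", "C")))
  fit <- fit_pls_pm(d, sp)
  oracle <- chained_ols_paths(d, sp)
  expect_equal(fit$path_matrix, oracle, tolerance = 1e-8)
  expect_equal(unname(fit$loadings), rep(1, 3), tolerance = 1e-12)
  # latent scores are the standardized indicators
  expect_equal(fit$scores[, "A"], as.numeric(scale(d$x1)), tolerance = 1e-8)
})

test_that("latent scores are standardized and loadings bounded", {
  ls <- default_latent_model(n = 800, seed = 21)
  tb <- generate_sem_table(ls)
  fit <- fit_pls_pm(tb$data, default_path_model())
  expect_true(fit$converged)
  expect_equal(unname(colMeans(fit$scores)), rep(0, 5), tolerance = 1e-8)
  expect_equal(unname(apply(fit$scores, 2, sd)), rep(1, 5), tolerance = 1e-8)
  expect_true(all(abs(fit$loadings) <= 1 + 1e-8))
  # sign convention: summed loadings non-negative per block
  for (l in names(fit$spec$blocks)) {
    expect_gte(sum(fit$loadings[fit$spec$blocks[[l]]]), 0)
  }
})

test_that("planted paths are recovered on synthetic indicator tables", {
  ls <- default_latent_model(n = 5000, seed = 22)
  tb <- generate_sem_table(ls)
  fit <- fit_pls_pm(tb$data, default_path_model())
  edges <- which(fit$spec$adj, arr.ind = TRUE)
  err <- fit$path_matrix[edges] - tb$truth$path_matrix[edges]
  expect_lt(mean(abs(err)), 0.06)
  # inner schemes agree closely on a well-behaved model
  f2 <- fit_pls_pm(tb$data, default_path_model(scheme = "centroid"))
  expect_equal(f2$path_matrix[edges], fit$path_matrix[edges],
               tolerance = 0.02)
})

test_that("uncorrelated blocks yield near-zero paths", {
  set.seed(23)
  n <- 5000
  d <- as.data.frame(matrix(rnorm(n * 4), n, 4))
  names(d) <- c("x1", "x2", "y1", "y2")
  sp <- path_model_spec(c("A", "B"),
                        list(A = c("x1", "x2"), B = c("y1", "y2")),
                        data.frame(from = "A", to = "B"))
  fit <- suppressWarnings(fit_pls_pm(d, sp))
  expect_lt(abs(fit$path_matrix["B", "A"]), 0.05)
})

test_that("fit rejects constant indicators and missing columns", {
  d <- data.frame(x1 = rnorm(50), x2 = rep(2, 50))
  sp <- path_model_spec(c("A", "B"), list(A = "x1", B = "x2"),
                        data.frame(from = "A", to = "B"))
  expect_error(fit_pls_pm(d, sp), "constant indicator")
  expect_error(fit_pls_pm(d[, "x1", drop = FALSE], sp), "missing")
})

test_that("gof combines communality and R2 with printed threshold labels", {
  # single-indicator chain: communalities 1, so GOF = sqrt(mean R2)
  set.seed(24)
  n <- 300
  d <- data.frame(x1 = rnorm(n))
  d$x2 <- 0.5 * d$x1 + rnorm(n)
  sp <- path_model_spec(c("A", "B"), list(A = "x1", B = "x2"),
                        data.frame(from = "A", to = "B"))
  fit <- fit_pls_pm(d, sp)
  expect_equal(fit$gof, sqrt(mean(fit$communality) * fit$r2[["B"]]),
               tolerance = 1e-12)
  expect_equal(gof(fit)$gof, abs(cor(d$x1, d$x2)), tolerance = 1e-10)
  expect_identical(gof_label(0.09), "poor")
  expect_identical(gof_label(0.10), "weak")
  expect_identical(gof_label(0.25), "medium")
  expect_identical(gof_label(0.36), "strong")
  expect_identical(gof_label(0.5), "strong")
})

test_that("gof is invariant to indicator order and latent relabeling", {
  ls <- default_latent_model(n = 600, seed = 25)
  tb <- generate_sem_table(ls)
  base <- fit_pls_pm(tb$data, default_path_model())
  shuffled <- tb$data[, sample(names(tb$data))]
  f2 <- fit_pls_pm(shuffled, default_path_model())
  expect_equal(f2$gof, base$gof, tolerance = 1e-10)
  # relabel latents (same structure, new names)
  blocks <- list(T2 = c("ELE", "SLO"), H2 = c("NL", "PD", "GDP"),
                 C2 = c("PRE", "TEM", "ET"), V2 = c("NPP", "FVC", "kNDVI"),
                 Y2 = "CCD")
  paths <- data.frame(
    from = c("T2", "T2", "T2", "H2", "H2", "H2", "C2", "C2", "V2"),
    to   = c("H2", "V2", "Y2", "C2", "V2", "Y2", "V2", "Y2", "Y2"))
  f3 <- fit_pls_pm(tb$data, path_model_spec(names(blocks), blocks, paths))
  expect_equal(f3$gof, base$gof, tolerance = 1e-10)
  # excluding the single-indicator response block changes only communality
  g_incl <- gof(base, include_single = TRUE)$gof
  g_excl <- gof(base, include_single = FALSE)$gof
  expect_false(isTRUE(all.equal(g_incl, g_excl)))
})
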