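# Loss function, prediction dispatch, the simplex engine and K_X
# calibration.

test_that("the loss formula evaluates as printed", {
  # perfect predictions
  obs <- list(zero_variate("Li", 5), deb_dataset("growth_dw", 1:3, c(1, 2, 3)))
  expect_identical(loss_mre(obs, list(5, c(1, 2, 3))), 0)
  # single datum hand case: Y = 2, Yhat = 1, beta = 1 -> 0.5
  expect_identical(loss_mre(list(zero_variate("Li", 2)), list(1)), 0.5)
  # weight rescaling leaves the ratio unchanged
  obs2 <- list(zero_variate("Li", 2, weight = 10),
               deb_dataset("growth_dw", 1:2, c(4, 8), weights = c(10, 10)))
  obs1 <- list(zero_variate("Li", 2, weight = 1),
               deb_dataset("growth_dw", 1:2, c(4, 8), weights = c(1, 1)))
  preds <- list(1, c(5, 7))
  expect_equal(loss_mre(obs2, preds), loss_mre(obs1, preds), tolerance = 1e-15)
  # dataset reordering leaves the pooled loss unchanged
  expect_equal(loss_mre(rev(obs1), rev(preds)), loss_mre(obs1, preds),
               tolerance = 1e-15)
  # symmetric variant is zero at perfection and bounded by 2
  expect_identical(loss_mre(obs, list(5, c(1, 2, 3)), symmetric = TRUE), 0)
  expect_lt(loss_mre(list(zero_variate("Li", 2)), list(1e6), symmetric = TRUE), 2)
  # error paths
  expect_error(loss_mre(list(list(y = 0, weights = 1)), list(1)), "non-zero")
  expect_error(loss_mre(list(zero_variate("Li", 1, weight = 0)), list(1)),
               "positive")
  expect_error(zero_variate("Li", 0), "non-zero")
})

test_that("prediction dispatch covers the registered types and rejects others", {
  sched <- seq(7, 28, by = 7)
  ds <- generate_growth_series(
    synthetic_spec(flat, list(mode = "constant", temp_C = 20, chl = 10),
                   schedule = sched, sigma = 0, seed = 3))
  # a series generated by the simulator predicts itself exactly
  expect_lt(loss_mre(list(ds), list(predict_dataset(flat, ds))), 1e-10)
  expect_error(predict_dataset(flat, deb_dataset("growth_shell", 1, 1)),
               "registered types")
  expect_error(predict_dataset(flat, zero_variate("W_unknown", 1)),
               "registered traits")
  # zero-variate dispatch reaches the embryo solver
  ab <- predict_dataset(flat, zero_variate("ab", 10))
  expect_equal(ab, initial_reserve(flat, e_b = 1)$age_at_birth,
               tolerance = 1e-6)
  # fecundity-versus-length uses the reproduction machinery pointwise
  fec <- predict_dataset(flat, deb_dataset("fecundity_length", c(4, 6, 8),
                                           c(1, 1, 1),
                                           context = list(f = 1)))
  expect_true(all(diff(fec) > 0))
})

test_that("the simplex engine minimises a known function like the reference", {
  rosen <- function(x) 100 * (x[2] - x[1]^2)^2 + (1 - x[1])^2
  mine <- oysterDEB:::nelder_mead(rosen, c(-1.2, 1), step = 0.5,
                                  tol = 1e-10, max_iter = 2000)
  ref <- stats::optim(c(-1.2, 1), rosen, method = "Nelder-Mead",
                      control = list(maxit = 5000, reltol = 1e-12))
  expect_lt(sum(abs(mine$par - c(1, 1))), 1e-3)
  expect_lte(mine$value, ref$value + 1e-8)
  expect_true(all(diff(mine$trace) <= 0))  # accepted best is non-increasing
})

test_that("estimation with no free parameters returns the initial loss", {
  zv <- generate_zero_variate_table(flat, list(Li = list(f = 1),
                                               Wdi = list(f = 1)))
  fit <- estimate_deb(flat, zv, free = character(0))
  expect_identical(fit$iterations, 0L)
  expect_lt(fit$mre, 1e-12)
  expect_error(estimate_deb(flat, zv, free = "not_a_param"), "not in")
})

test_that("a single-parameter estimation recovers the truth from clean data", {
  sched <- seq(7, 56, by = 7)
  ds <- generate_growth_series(
    synthetic_spec(flat, list(mode = "constant", temp_C = 20, chl = 10),
                   schedule = sched, sigma = 0, seed = 5))
  init <- perturbed_init(flat, "p_M", seed = 31, lo = 1.15, hi = 1.15)
  fit <- estimate_deb(init, list(ds), free = "p_M", max_iter = 120,
                      restarts = 0)
  expect_lt(rel_err(fit$params$p_M, flat$p_M), 0.02)
  expect_lt(fit$mre, 1e-3)
  expect_true(all(diff(fit$trace) <= 1e-12))
})

test_that("K_X calibration recovers the generating half-saturation", {
  mk <- function(params, scale = 1) {
    lapply(c(2, 10) * scale, function(chl) {
      generate_growth_series(
        synthetic_spec(params, list(mode = "constant", temp_C = 20, chl = chl),
                       schedule = seq(7, 42, by = 7), sigma = 0, seed = 7),
        name = paste0("chl", chl))
    })
  }
  cal <- calibrate_KX(flat, mk(flat))
  expect_lt(rel_err(cal$K_X, 1.84), 0.02)
  # implied feeding levels at the lab rations match the printed values
  expect_identical(round_half_up(unname(cal$f_implied["chl_2"]), 2), 0.52)
  expect_identical(round_half_up(unname(cal$f_implied["chl_10"]), 2), 0.84)
  # scale equivariance: doubling chlorophyll doubles the recovered K_X
  x <- as.list(flat); x$K_X <- 2 * x$K_X
  p2 <- deb_params(x, species = "o_edulis")
  cal2 <- calibrate_KX(flat, mk(p2, scale = 2))
  expect_lt(rel_err(cal2$K_X, 2 * 1.84), 0.02)
  # f-mode data cannot calibrate K_X
  dsf <- generate_growth_series(
    synthetic_spec(flat, list(mode = "constant", temp_C = 20, f = 0.8),
                   schedule = seq(7, 28, by = 7), sigma = 0, seed = 9))
  expect_error(calibrate_KX(flat, list(dsf)), "chlorophyll")
})
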