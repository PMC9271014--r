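# Energy fluxes, state derivatives and compound parameters.

test_that("maintenance persists without food and feeding is off before birth", {
  st <- organism_state(E = 1000, V = 1, E_H = flat$E_Hp)
  fl <- compute_fluxes(flat, st, f = 0, T_corr = 1)
  expect_identical(fl$p_A, 0)
  expect_identical(fl$p_X, 0)
  expect_gt(fl$p_S, 0)
  # embryo: no feeding even at f = 1
  emb <- organism_state(E = 0.005, V = 1e-9, E_H = flat$E_Hb / 2)
  expect_identical(compute_fluxes(flat, emb, f = 1, T_corr = 1)$p_A, 0)
})

test_that("flux values match direct evaluation of the printed parameters", {
  # flat oyster, V = 1 cm^3, e = 1, T_corr = 1, fully accelerated (s = 5.9):
  # p_S = [p_M]*V = 15.68 J/d; p_A = 5.9 * 91 * 1 = 536.9 J/d
  st <- organism_state(E = flat$p_Am / flat$v, V = 1, E_H = flat$E_Hp)
  fl <- compute_fluxes(flat, st, f = 1, T_corr = 1, s = 5.9)
  expect_equal(fl$p_S, 15.68, tolerance = 1e-12)
  expect_equal(fl$p_A, 5.9 * 91, tolerance = 1e-12)
  expect_equal(fl$e, 1, tolerance = 1e-12)
})

test_that("the kappa rule balances exactly at random states", {
  set.seed(11)
  for (p in list(flat, gigas)) {
    E_m <- p$p_Am / p$v
    for (i in 1:20) {
      V <- 10^runif(1, -6, 2)
      st <- organism_state(E = runif(1, 0.05, 1.2) * E_m * V, V = V,
                           E_H = runif(1, 0, p$E_Hp),
                           E_R = runif(1, 0, 50))
      fl <- compute_fluxes(p, st, f = runif(1), T_corr = runif(1, 0.2, 1.4),
                           s = runif(1, 1, p$s_M))
      expect_equal(fl$p_G + fl$p_S, p$kap * fl$p_C, tolerance = 1e-12)
      expect_equal(fl$p_R + fl$p_J, (1 - p$kap) * fl$p_C, tolerance = 1e-12)
    }
  }
})

test_that("flux computation rejects invalid inputs and flags starvation", {
  st <- organism_state(E = 10, V = 1, E_H = flat$E_Hp)
  expect_error(compute_fluxes(flat, c(-1, 1, 32, 0, 0, 0, 0, 0, 0, 0),
                              f = 0.5, T_corr = 1), "negative")
  expect_error(compute_fluxes(flat, st, f = 1.5, T_corr = 1), "\\[0, 1\\]")
  expect_error(compute_fluxes(flat, st, f = 0.5, T_corr = 0), "positive")
  # nearly empty reserve at f = 0: somatic branch cannot pay maintenance
  expect_true(compute_fluxes(flat, st, f = 0, T_corr = 1)$starvation)
})

test_that("derivatives respect the maturity ceiling and weak homeostasis", {
  p <- flat
  E_m <- p$p_Am / p$v
  adult <- organism_state(E = 0.9 * E_m * 8, V = 8, E_H = p$E_Hp, E_R = 5)
  d <- state_derivatives(p, adult, f = 0.9, T_corr = 1, s = p$s_M)
  fl <- compute_fluxes(p, adult, f = 0.9, T_corr = 1, s = p$s_M)
  expect_identical(unname(d["EH"]), 0)
  expect_equal(unname(d["ER"]), fl$p_R, tolerance = 1e-12)
  # weak homeostasis: at e = f the reserve density is stationary
  for (f in c(0.3, 0.7, 1)) {
    st <- organism_state(E = f * E_m * 8, V = 8, E_H = p$E_Hp)
    d <- state_derivatives(p, st, f = f, T_corr = 1, s = p$s_M)
    de <- (d["E"] - (st[1] / st[2]) * d["V"]) / (st[2] * E_m)
    expect_lt(abs(de), 1e-13)
  }
})

test_that("fast derivative closure agrees exactly with the reference", {
  set.seed(21)
  core <- oysterDEB:::fast_deriv_factory(flat, ageing = TRUE)
  E_m <- flat$p_Am / flat$v
  for (i in 1:30) {
    V <- 10^runif(1, -11, 2)
    y <- organism_state(E = runif(1, 0, 1.2) * E_m * V, V = V,
                        E_H = 10^runif(1, -4, log10(32)),
                        E_R = runif(1, 0, 100),
                        q = runif(1) * 1e-8, h = runif(1) * 1e-4)
    f <- runif(1); TC <- runif(1, 0.3, 1.5); s <- runif(1, 1, 5.9)
    a <- core(unclass(y), f, TC, s)
    b <- unname(state_derivatives(flat, y, f, TC, s = s, ageing = TRUE))
    expect_equal(a, b, tolerance = 1e-13)
  }
})

test_that("a 10-day fixed-step Euler oracle matches the adaptive solver", {
  st <- lab_juvenile()
  TC <- temperature_correction(flat, celsius_to_kelvin(20))
  core <- oysterDEB:::fast_deriv_factory(flat)
  rhs <- function(t, y) core(y, f = 0.84, TC = TC, s = flat$s_M)
  ye <- oysterDEB:::euler(rhs, st, 0, 10, 1e-3)
  tr <- simulate_deb(flat, constant_forcing(20, f = 0.84), st, 10,
                     deb_options(dt_out = 10))
  ya <- tr$state[nrow(tr$state), ]
  expect_lt(max(abs(ye[1:4] - ya[1:4]) / pmax(abs(ya[1:4]), 1e-12)), 1e-3)
})

test_that("compound parameters reproduce the printed reserve capacities", {
  cpf <- compound_parameters(flat)
  cpg <- compound_parameters(gigas)
  expect_equal(cpf$E_m, 91 / 0.020, tolerance = 1e-12)      # 4550 J/cm^3
  expect_equal(cpg$E_m, 372 / 0.0054, tolerance = 1e-12)    # ~68889 J/cm^3
  expect_lt(cpf$E_m, cpg$E_m)  # the basis of gigas' starvation tolerance
  expect_gt(flat$kap, gigas$kap)
  # z = 1 when p_Am = p_M / kap at L_ref = 1 cm
  x <- as.list(flat)
  x$p_Am <- x$p_M / x$kap
  expect_equal(compound_parameters(deb_params(x))$L_m, 1, tolerance = 1e-12)
})

test_that("ingestion temperature response can be decoupled from maintenance", {
  st <- organism_state(E = 2000, V = 1, E_H = flat$E_Hp)
  coupled <- compute_fluxes(flat, st, f = 0.8, T_corr = 0.7)
  same <- compute_fluxes(flat, st, f = 0.8, T_corr = 0.7,
                         T_corr_ingestion = 0.7)
  expect_identical(coupled, same)
  dec <- compute_fluxes(flat, st, f = 0.8, T_corr = 0.7,
                        T_corr_ingestion = 0.35)
  expect_equal(dec$p_A, coupled$p_A / 2, tolerance = 1e-12)
  expect_identical(dec$p_S, coupled$p_S)   # maintenance untouched
  expect_identical(dec$p_C, coupled$p_C)
  # the simulator option feeds a separate Arrhenius block to feeding only
  tp <- as.list(flat)[c("T_ref", "T_A", "T_L", "T_AL", "T_H", "T_AH")]
  tp$T_A <- 2 * tp$T_A   # steeper thermal response of ingestion
  a <- simulate_deb(flat, constant_forcing(15, f = 0.8), lab_juvenile(), 20,
                    deb_options(ingestion_temp = tp))
  b <- simulate_deb(flat, constant_forcing(15, f = 0.8), lab_juvenile(), 20)
  # at 15 C (< T_ref) the steeper block depresses assimilation, hence growth
  expect_lt(utils::tail(a$observables$dw_g, 1),
            utils::tail(b$observables$dw_g, 1))
})

test_that("acceleration factor follows the life stage", {
  p <- flat
  pre <- organism_state(E = 1e-4, V = 1e-7, E_H = p$E_Hs / 2)
  expect_identical(acceleration_factor(p, pre), 1)
  post <- organism_state(E = 1, V = 1, E_H = p$E_Hj * 2)
  expect_identical(acceleration_factor(p, post), p$s_M)
  mid <- organism_state(E = 1e-3, V = 1e-5, E_H = p$E_Hs * 8)
  s_mid <- acceleration_factor(p, mid)
  expect_gte(s_mid, 1)
  expect_lte(s_mid, p$s_M)
})
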