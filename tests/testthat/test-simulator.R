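# Integration under forcing: growth ordering, starvation, the von
# Bertalanffy limit, energy conservation, determinism and initialisation.

test_that("growth increases with ration and stops without food", {
  st <- lab_juvenile()
  hi <- simulate_deb(flat, constant_forcing(20, chl = 10), st, 42)
  lo <- simulate_deb(flat, constant_forcing(20, chl = 2), st, 42)
  gr_hi <- growth_rate(hi$observables$dw_g[1], utils::tail(hi$observables$dw_g, 1), 42)
  gr_lo <- growth_rate(lo$observables$dw_g[1], utils::tail(lo$observables$dw_g, 1), 42)
  expect_gt(gr_hi, 0)
  expect_gt(gr_lo, 0)
  expect_gt(gr_hi, gr_lo)
  # no food: reserve declines monotonically until starvation death
  starved <- simulate_deb(flat, constant_forcing(20, f = 0), st, 2000,
                          deb_options(dt_out = 2))
  expect_true(starved$died)
  expect_true(all(diff(starved$state[, "E"]) < 0))
  expect_identical(starved$events$event[nrow(starved$events)],
                   "starvation_death")
})

test_that("constant-condition growth follows the von Bertalanffy closed form", {
  f <- 0.8
  T_C <- 20
  st <- init_from_weight(flat, 0.87, wet = TRUE, e = f)
  tr <- simulate_deb(flat, constant_forcing(T_C, f = f), st, 4000,
                     deb_options(dt_out = 20))
  cp <- compound_parameters(flat, f = f)
  TC <- temperature_correction(flat, celsius_to_kelvin(T_C))
  L0 <- tr$observables$length_cm[1]
  L_closed <- cp$Lw_inf - (cp$Lw_inf - L0) * exp(-cp$r_B * TC * tr$time)
  expect_lt(max(abs(tr$observables$length_cm - L_closed)) / cp$Lw_inf, 0.005)
  # reserve density is capped by the feeding level under constant food
  expect_true(all(tr$observables$e <= f + 1e-6))
})

test_that("the full energy budget closes to solver tolerance", {
  st <- lab_juvenile()
  tr <- simulate_deb(flat, constant_forcing(20, chl = 10), st, 42)
  expect_lt(energy_balance(tr)$rel_error, 1e-6)
  # seasonal forcing with spawning and brooding events included
  fc <- generate_forcing(list(mode = "seasonal", temp_mean = 12, temp_amp = 7,
                              temp_phase = 120, chl_mean = 5, chl_amp = 4,
                              chl_phase = 100), 365)
  ad <- init_from_weight(flat, 20, wet = TRUE)
  trs <- simulate_deb(flat, fc, ad, 365, deb_options(spawning = TRUE))
  expect_lt(energy_balance(trs)$rel_error, 1e-6)
  # and over an interior window
  expect_lt(energy_balance(trs, from = 50, to = 300)$rel_error, 1e-6)
})

test_that("trajectories are deterministic and grid-independent", {
  st <- lab_juvenile()
  fc <- constant_forcing(15, chl = 5)
  a <- simulate_deb(flat, fc, st, 60)
  b <- simulate_deb(flat, fc, st, 60)
  expect_identical(a$state, b$state)          # byte-for-byte
  fine <- simulate_deb(flat, fc, st, 60, deb_options(dt_out = 0.5))
  shared <- match(a$time, fine$time)
  expect_false(anyNA(shared))
  expect_lt(max(abs(a$observables$dw_g -
                    fine$observables$dw_g[shared]) /
                a$observables$dw_g), 1e-6)
})

test_that("init_from_weight inverts the weight model", {
  for (w in c(0.05, 0.87, 20)) {
    st <- init_from_weight(flat, w, wet = TRUE)
    expect_lt(abs(wet_weight(flat, st) - w) / w, 1e-9)
  }
  st <- init_from_weight(flat, 1.5, wet = FALSE, e = 0.4, E_R = 3)
  expect_lt(abs(dry_weight(flat, st) - 1.5) / 1.5, 1e-9)
  expect_identical(unname(unclass(st)[4]), 3)
  # e = 0: all tissue is structure (plus buffer)
  st0 <- init_from_weight(flat, 1, wet = FALSE, e = 0)
  expect_identical(unname(unclass(st0)[1]), 0)
  expect_equal(flat$d_V * st0[2], 1, tolerance = 1e-9, ignore_attr = TRUE)
  # brute-force oracle: dense grid search over V
  w <- 0.87
  dw <- w * flat$dw_ww_ratio
  E_m <- flat$p_Am / flat$v
  Vg <- seq(1e-6, dw / flat$d_V, length.out = 200000)
  wg <- flat$d_V * Vg + flat$w_E * 0.8 * E_m * Vg / flat$mu_E
  V_star <- Vg[which.min(abs(wg - dw))]
  st <- init_from_weight(flat, w, wet = TRUE)
  expect_lt(abs(st[2] - V_star) / V_star, 1e-4)
  expect_error(init_from_weight(flat, 1e-4, wet = FALSE, E_R = 1e5), "buffer")
})

test_that("run_scenario reports zero error against its own output", {
  sched <- seq(7, 42, by = 7)
  ds <- generate_growth_series(
    synthetic_spec(flat, list(mode = "constant", temp_C = 20, chl = 10),
                   schedule = sched, sigma = 0, seed = 1))
  res <- run_scenario(list(
    species = flat,
    forcing = data.frame(day = c(0, 42), temp_C = 20, chl = 10),
    init_weight_g = 0.87, horizon = 42,
    options = list(spawning = FALSE),
    observations = list(ds)))
  expect_lt(res$errors$mre, 1e-9)
  expect_error(run_scenario(list(species = flat,
                                 forcing = data.frame(day = 0:1, x = 1:2),
                                 init_weight_g = 1, horizon = 1)),
               "temp_C|chl|'day'")
})

test_that("std-mode parameter sets simulate post-metamorphic growth only", {
  st <- init_from_weight(gigas_std, 1.13, wet = TRUE)
  tr <- simulate_deb(gigas_std, constant_forcing(20, chl = 10), st, 42)
  expect_gt(utils::tail(tr$observables$dw_g, 1), tr$observables$dw_g[1])
  expect_error(initial_reserve(gigas_std), "asj")
})
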