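# Initial reserve, life-stage events, spawning, brooding and lifespan.

test_that("initial reserve solves its defining fixed-point problem", {
  ir <- initial_reserve(flat, e_b = 1)
  # re-integrating the embryo from the returned egg energy must hit the
  # birth threshold with the requested reserve density
  sol <- oysterDEB:::embryo_path(flat, ir$E_0)
  expect_true(sol$reached)
  expect_lt(abs(sol$e - 1), 1e-6)
  expect_equal(unname(sol$state[3]), flat$E_Hb, tolerance = 1e-6)
  # monotone: richer eggs for higher reserve density at birth
  E0s <- vapply(c(0.5, 0.75, 1), function(eb) {
    initial_reserve(flat, e_b = eb)$E_0
  }, numeric(1))
  expect_true(all(diff(E0s) > 0))
})

test_that("life-history events appear in order with non-decreasing lengths", {
  tr <- oysterDEB:::grow_from_egg(flat, f = 1, until = "puberty")
  ev <- detect_events(tr)
  expect_identical(ev$event, c("birth", "release", "settlement",
                               "metamorphosis", "puberty"))
  expect_true(all(diff(ev$age_d) > 0))
  expect_true(all(diff(ev$length_cm) >= 0))
  expect_true(all(diff(ev$dryweight_g) > 0))
  # age at birth agrees with the embryo solution used by initial_reserve
  ir <- initial_reserve(flat, e_b = 1)
  expect_equal(ev$age_d[1], ir$age_at_birth, tolerance = 1e-4)
})

test_that("the emergent acceleration factor matches the reported values", {
  # s_M = L(end of metamorphosis) / L(settlement) from the life cycle at f=1
  tr <- oysterDEB:::grow_from_egg(flat, f = 1, until = "metamorphosis")
  ev <- detect_events(tr)
  Ls <- ev$length_cm[ev$event == "settlement"] * flat$del_Mb
  Lj <- ev$length_cm[ev$event == "metamorphosis"] * flat$del_M
  expect_lt(abs(Lj / Ls - 5.9) / 5.9, 0.10)   # flat oyster: 5.9
  trg <- oysterDEB:::grow_from_egg(gigas, f = 1, until = "metamorphosis")
  evg <- detect_events(trg)
  Lsg <- evg$length_cm[evg$event == "settlement"] * gigas$del_Mb
  Ljg <- evg$length_cm[evg$event == "metamorphosis"] * gigas$del_M
  expect_lt(abs(Ljg / Lsg - 4.8) / 4.8, 0.10)  # Pacific oyster: 4.8
})

test_that("spawning empties the stated buffer fraction and counts eggs", {
  st <- organism_state(E = 1000, V = 1, E_H = flat$E_Hp, E_R = 100)
  sp <- apply_spawning(st, flat, E_0 = 0.02)
  expect_equal(sp$state[4], 55, tolerance = 1e-12, ignore_attr = TRUE)
  expect_equal(sp$energy_released, 45, tolerance = 1e-12)
  # energy bookkeeping: eggs * E_0 equals the released energy exactly
  expect_equal(sp$eggs * 0.02, sp$energy_released, tolerance = 1e-12)
  # kap_R = 0 is a no-op
  x <- as.list(flat); x$kap_R <- 0
  p0 <- deb_params(x)
  sp0 <- apply_spawning(st, p0, E_0 = 0.02)
  expect_identical(unname(sp0$state[4]), 100)
  expect_identical(sp0$energy_released, 0)
  # egg count scales linearly with the released energy at fixed E_0
  st2 <- organism_state(E = 1000, V = 1, E_H = flat$E_Hp, E_R = 300)
  sp2 <- apply_spawning(st2, flat, E_0 = 0.02)
  expect_equal(sp2$eggs / sp$eggs, 3, tolerance = 1e-12)
  # spawning before puberty is an error
  juv <- organism_state(E = 1000, V = 1, E_H = flat$E_Hp / 2, E_R = 10)
  expect_error(apply_spawning(juv, flat), "puberty")
})

test_that("brooding multiplies feeding by 0.8 while active", {
  expect_identical(brooding_multiplier(TRUE), 0.8)
  expect_identical(brooding_multiplier(FALSE), 1)
  # a brooding adult grows more slowly than a non-brooding one
  ad <- init_from_weight(flat, 20, wet = TRUE)
  ad[4] <- 0.06 * (flat$p_Am / flat$v) * ad[2]  # buffer above the trigger
  base <- deb_options(dt_out = 5, spawning = TRUE, spawn_refractory_d = 400,
                      brood_duration = 60)
  with_brood <- simulate_deb(flat, constant_forcing(20, f = 0.8), ad, 100, base)
  no_brood <- simulate_deb(flat, constant_forcing(20, f = 0.8), ad, 100,
                           utils::modifyList(base, list(brood_factor = 1)))
  expect_identical(nrow(with_brood$spawns), 1L)
  expect_true(with_brood$spawns$brooding[1])
  expect_lt(max(with_brood$observables$dw_g),
            max(no_brood$observables$dw_g))
})

test_that("lifespan diverges without ageing and shortens when warm", {
  # negligible ageing acceleration: survival outlasts any finite horizon
  x <- as.list(flat); x$h_a <- 1e-30
  p0 <- deb_params(x)
  ls0 <- lifespan(p0, f = 0.9, horizon = 3000)
  expect_gt(ls0$mean_lifespan_d, 0.99 * 3000)
  # hazard accumulates faster at higher temperature
  warm <- lifespan(flat, f = 0.9, T_K = celsius_to_kelvin(25))
  cold <- lifespan(flat, f = 0.9, T_K = celsius_to_kelvin(15))
  expect_lt(warm$mean_lifespan_d, cold$mean_lifespan_d)
})
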