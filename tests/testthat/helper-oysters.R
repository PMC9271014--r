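# Shared fixtures: packaged parameter sets and synthetic-data builders.

flat <- deb_species("o_edulis")
gigas <- deb_species("c_gigas_amp")
gigas_std <- deb_species("c_gigas_std")

# a typical lab-experiment juvenile (spat of ~0.87 g wet weight)
lab_juvenile <- function(params = flat, e = 0.8) {
  init_from_weight(params, 0.87, wet = TRUE, e = e)
}

# the synthetic estimation design used for recovery experiments: dry-weight
# growth at two rations, shell length, respiration versus temperature, and
# three life-history traits including reproduction (which identifies kappa)
recovery_datasets <- function(params, sigma = 0, seed = 1) {
  sched <- seq(14, 160, by = 14)
  s1 <- generate_growth_series(
    synthetic_spec(params, list(mode = "constant", temp_C = 20, chl = 10),
                   schedule = sched, sigma = sigma, seed = seed),
    name = "dw_hi")
  s2 <- generate_growth_series(
    synthetic_spec(params, list(mode = "constant", temp_C = 20, chl = 2),
                   schedule = sched, sigma = sigma, seed = seed + 1000),
    name = "dw_lo")
  s3 <- generate_growth_series(
    synthetic_spec(params, list(mode = "constant", temp_C = 20, chl = 10),
                   schedule = sched, sigma = sigma, seed = seed + 3000),
    name = "len_hi", type = "growth_length")
  rx <- c(3, 8, 15, 20, 25, 30)
  rctx <- list(init_weight_g = 0.87, f = 0.84)
  rtruth <- predict_dataset(params, deb_dataset("respiration_T", rx,
                                                rep(1, 6), context = rctx))
  ry <- if (sigma > 0) {
    rtruth * exp(oysterDEB:::with_local_seed(seed + 4000,
                                             stats::rnorm(6, 0, sigma)))
  } else rtruth
  s4 <- deb_dataset("respiration_T", rx, ry, context = rctx, name = "resp")
  zv <- generate_zero_variate_table(
    params, list(Li = list(f = 1), Wdi = list(f = 1), Ri = list(f = 1)),
    sigma = sigma, seed = seed + 2000)
  c(list(s1, s2, s3, s4), zv)
}

# multiplicatively perturbed start for estimation (fractions kept below 1)
perturbed_init <- function(params, free, seed, lo = 0.85, hi = 1.15) {
  set.seed(seed)
  x <- as.list(params)
  for (k in free) x[[k]] <- x[[k]] * stats::runif(1, lo, hi)
  if (!is.null(x$kap)) x$kap <- min(x$kap, 0.995)
  deb_params(x, species = attr(params, "species"))
}

rel_err <- function(a, b) abs(a - b) / abs(b)

# predict a single life-history trait through the public dispatch
predict_trait_pub <- function(params, name, ctx = list()) {
  predict_dataset(params, zero_variate(name, 1, context = ctx))
}
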