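test_that("nitrate partition reproduces the steady-state denitrification share", {
  p <- nitrate_partition(2.34, 2.051)
  expect_equal(p$r_no3_denit, 0.166, tolerance = 1e-2)
  expect_equal(p$fraction_denit, 0.071, tolerance = 1e-2)
  expect_equal(p$r_no2_anammox, 1.32 * 2.051)
  expect_equal(p$r_no3_recycled, 0.26 * 2.051)
  expect_false(p$infeasible)

  # no anammox: everything is denitrification
  p0 <- nitrate_partition(1.7, 0)
  expect_equal(p0$r_no3_denit, 1.7)
  expect_equal(p0$fraction_denit, 1)

  # exact coupling
  pc <- nitrate_partition(1.06 * 2, 2)
  expect_equal(pc$r_no3_denit, 0, tolerance = 1e-12)

  expect_warning(nitrate_partition(1, 2), "infeasible")
  expect_warning(p_und <- nitrate_partition(0, 1), "infeasible")
  expect_true(is.na(p_und$fraction_denit))
})

test_that("partition satisfies the reconstruction identity and monotonicity", {
  set.seed(3)
  for (i in 1:200) {
    r_no3 <- runif(1, 0, 5); r_nh4 <- runif(1, 0, 5)
    p <- suppressWarnings(nitrate_partition(r_no3, r_nh4))
    expect_lt(abs(p$r_no3_denit + (1.32 - 0.26) * r_nh4 - r_no3), 1e-9)
  }
  # fraction_denit decreases as anammox activity grows at fixed nitrate
  fr <- vapply(seq(0, 2, 0.1),
               function(r) suppressWarnings(nitrate_partition(2.34, r))$fraction_denit,
               numeric(1))
  expect_true(all(diff(fr) < 0))
})

test_that("electron ratios from the printed reactor rates reproduce the reported 1.13", {
  # ammonium rate derived from the printed total N consumption (4.04 mmol
  # N/d over 0.92 L) minus the printed nitrate rate
  r_nh4_p <- 4.04 / 0.92 - 2.34
  rp <- guild_rates("propane", 0.35, r_nh4_p, 2.34, basis = "per_litre")
  ep <- electron_ratio(rp)
  expect_equal(ep$e_ratio, 1.12, tolerance = 1e-2)
  expect_lt(abs(ep$e_ratio - 1.13), 0.07)

  r_nh4_b <- 3.62 / 0.92 - 2.06
  rb <- guild_rates("butane", 0.24, r_nh4_b, 2.06, basis = "per_litre")
  eb <- electron_ratio(rb)
  expect_equal(eb$e_ratio, 1.15, tolerance = 1e-2)
  expect_lt(abs(eb$e_ratio - 1.13), 0.12)

  expect_error(electron_ratio(guild_rates("propane", 1, 1, 0)), "undefined")
})

test_that("electron balance closes exactly for idealized composed stoichiometry", {
  # compose nitrate->nitrite reduction (2 e-/N), idealized 1:1 anammox
  # (NH4+ + NO2- -> N2) and denitrification of the remaining nitrite
  # (3 e-/N), with the alkane supplying exactly the demanded electrons
  set.seed(5)
  for (alk in c("propane", "butane")) {
    e_alk <- if (alk == "propane") 20 else 26
    for (i in 1:20) {
      g <- runif(1, 0.5, 5)           # nitrate reduced to nitrite
      a <- runif(1, 0, g)             # nitrite consumed by ideal anammox
      d <- g - a                      # nitrite denitrified
      r_alkane <- (2 * g + 3 * d) / e_alk
      rates <- guild_rates(alk, r_alkane, r_nh4 = a, r_no3 = g,
                           r_n2 = 2 * a + 2 * d, basis = "per_litre")
      expect_equal(electron_ratio(rates)$e_ratio, 1, tolerance = 1e-12)
    }
  }
})

test_that("nitrogen balance closure matches the reported reactor totals", {
  rates <- guild_rates("propane", 0.32, 1.70, 4.04 - 1.70, r_n2 = 4.23)
  nb <- nitrogen_balance(rates)
  expect_equal(nb$n_consumed, 4.04)
  expect_equal(nb$n_produced, 4.23)
  expect_equal(nb$n_closure, 4.23 / 4.04, tolerance = 1e-12)
  expect_equal(nb$n_closure, 1.047, tolerance = 1e-3)

  nb2 <- nitrogen_balance(guild_rates("propane", 0, 1, 0, r_n2 = 1))
  expect_equal(nb2$n_closure, 1)

  expect_error(nitrogen_balance(guild_rates("propane", 1, 0, 0)), "undefined")
  # net nitrite accumulation counts as product; net consumption does not
  nb3 <- nitrogen_balance(guild_rates("propane", 0, 1, 1, r_n2 = 1,
                                      r_no2 = 0.5))
  expect_equal(nb3$n_produced, 1.5)
  nb4 <- nitrogen_balance(guild_rates("propane", 0, 1, 1, r_n2 = 1,
                                      r_no2 = -0.5))
  expect_equal(nb4$n_produced, 1)
})

test_that("anammox batch ratios compare against the theoretical 1.32 and 0.26", {
  ex <- anammox_ratio_check(1.32 * 2, 2, 0.26 * 2)
  expect_equal(ex$ratio_no2_nh4, 1.32)
  expect_equal(ex$ratio_no3_nh4, 0.26)
  expect_equal(ex$dev_no2, 0)
  expect_equal(ex$dev_no3, 0)

  obs <- anammox_ratio_check(1.42, 1.0, 0.27)
  expect_equal(obs$dev_no2, 0.0758, tolerance = 1e-3)
  expect_equal(obs$dev_no3, 0.0385, tolerance = 1e-3)

  expect_error(anammox_ratio_check(1, 0, 0.2), "undefined")
})

test_that("simulated anammox batch deltas stay within 10% of theory at 5% noise", {
  set.seed(19)
  dn_nh4 <- 3
  truth <- c(no2 = 1.32 * dn_nh4, nh4 = dn_nh4, no3 = 0.26 * dn_nh4)
  noisy <- truth * (1 + rnorm(3, 0, 0.05))
  chk <- anammox_ratio_check(noisy[["no2"]], noisy[["nh4"]], noisy[["no3"]])
  expect_lt(abs(chk$dev_no2), 0.10)
  expect_lt(abs(chk$dev_no3), 0.10)
})

test_that("DNRA flags respond to nitrate depletion and nitrite accumulation", {
  # high-alkane batch: nitrite accumulates, nitrate depletes, ammonium rises
  out <- simulate_reactor(sim_config("C", seed = 21, noise_rel = 0))
  fl <- dnra_flags(out$truth$NO3, out$truth$NO2, out$truth$NH4)
  expect_true(fl$nitrate_depleted)
  expect_true(fl$nitrite_accumulated)
  expect_true(fl$net_ammonium_production)
  expect_true(fl$dnra_expected)

  # steady coupled operation: nothing triggers
  outB <- simulate_reactor(sim_config("B", seed = 21, noise_rel = 0,
                                      duration = 3, cycle_length = 3))
  flB <- dnra_flags(outB$truth$NO3, outB$truth$NO2, outB$truth$NH4)
  expect_false(flB$nitrate_depleted)
  expect_false(flB$nitrite_accumulated)
  expect_false(flB$net_ammonium_production)
  expect_false(flB$dnra_expected)

  # nitrite accumulation alone (nitrate still present) is not enough
  no3 <- liquid_series("NO3", c(5, 4.5, 4, 3.5, 3))
  no2 <- liquid_series("NO2", c(0, 0.4, 0.8, 1.2, 1.5))
  nh4 <- liquid_series("NH4", c(5, 4.8, 4.6, 4.4, 4.2))
  fl3 <- dnra_flags(no3, no2, nh4)
  expect_true(fl3$nitrite_accumulated)
  expect_false(fl3$nitrate_depleted)
  expect_false(fl3$dnra_expected)

  expect_error(dnra_flags(liquid_series("NO3", numeric(0), numeric(0)),
                          no2, nh4), "empty")
})
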