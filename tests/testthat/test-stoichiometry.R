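reg <- default_registry()

test_that("integer-coefficient reactions balance every element and charge exactly", {
  for (nm in c("propane_nitrate_to_nitrite", "propane_nitrite_to_n2",
               "butane_nitrate_to_nitrite", "butane_nitrite_to_n2")) {
    res <- element_balance(reg$reactions[[nm]])
    expect_true(all(res == 0), info = nm)
    expect_identical(charge_balance(reg$reactions[[nm]]), 0)
  }
})

test_that("anammox stoichiometry balances to the printed two-decimal precision", {
  res <- element_balance(reg$reactions$anammox)
  expect_true(all(abs(res) <= 0.02))
  # hand summation: LHS N = 2.32, RHS N = 2.04 + 0.26 + 0.066 x 0.15
  expect_equal(unname(res[["N"]]), -0.0101, tolerance = 1e-10)
  expect_lt(abs(charge_balance(reg$reactions$anammox)), 0.01)
  expect_equal(charge_balance(reg$reactions$anammox), -0.004, tolerance = 1e-10)
})

test_that("an identity reaction leaves zero residuals", {
  cps <- list(a = compound("a", c(C = 1, H = 4)),
              b = compound("b", c(C = 1, H = 4)))
  rxn <- reaction("id", c(a = -1, b = 1), cps, reference = "a")
  expect_true(all(element_balance(rxn) == 0))
  expect_identical(charge_balance(rxn), 0)
})

test_that("element balance is linear in the stoichiometric coefficients", {
  r1 <- reg$reactions$anammox
  r3 <- reg$reactions$propane_nitrite_to_n2
  set.seed(11)
  for (i in 1:10) {
    a <- runif(1, -2, 2); b <- runif(1, -2, 2)
    all_nm <- union(names(r1$stoich), names(r3$stoich))
    st <- setNames(numeric(length(all_nm)), all_nm)
    st[names(r1$stoich)] <- st[names(r1$stoich)] + a * r1$stoich
    st[names(r3$stoich)] <- st[names(r3$stoich)] + b * r3$stoich
    st <- st[st != 0]
    if (!any(st < 0) || !any(st > 0)) next
    rxn <- reaction("sum", st, reg$compounds, reference = names(st)[1])
    want <- setNames(numeric(length(union(names(element_balance(r1)),
                                          names(element_balance(r3))))),
                     union(names(element_balance(r1)), names(element_balance(r3))))
    e1 <- element_balance(r1); e3 <- element_balance(r3)
    want[names(e1)] <- want[names(e1)] + a * e1
    want[names(e3)] <- want[names(e3)] + b * e3
    got <- element_balance(rxn)
    expect_identical(sort(names(got)), sort(names(want)))
    expect_lt(max(abs(got[names(want)] - want)), 1e-12)
  }
})

test_that("compound and reaction validation rejects malformed input", {
  expect_error(compound("x", c(Xx = 1)), "unknown element")
  expect_error(compound("x", c(C = -1)), ">= 0")
  expect_error(compound("x", numeric(0)), "at least one element")
  expect_error(reaction("r", c(NO3 = -1), reg$compounds, "NO3"),
               "reactant.*product|product")
  expect_error(reaction("r", c(NO3 = -1, NO2 = 1, H2O = 0), reg$compounds,
                        "H2O"), "nonzero")
})

test_that("registered redox conversions follow oxidation-state accounting", {
  expect_equal(electrons_per_mole("C3H8", "propane_to_co2"), 20)
  expect_equal(electrons_per_mole("C4H10", "butane_to_co2"), 26)
  expect_equal(electrons_per_mole("NH4", "ammonium_to_n2"), 3)
  expect_equal(electrons_per_mole("NO3", "nitrate_to_n2"), 5)
  expect_equal(electrons_per_mole("NO3", "nitrate_to_nitrite"), 2)
  expect_equal(electrons_per_mole("NO2", "nitrite_to_n2"), 3)
  expect_equal(electrons_per_mole("NO2", "nitrite_to_ammonium"), 6)
  # product of the conversion carries no further electrons
  expect_equal(electrons_per_mole("N2", "nitrate_to_n2"), 0)
  # stepwise additivity: NO3->NO2 plus NO2->N2 equals NO3->N2
  expect_equal(electrons_per_mole("NO3", "nitrate_to_nitrite") +
                 electrons_per_mole("NO2", "nitrite_to_n2"),
               electrons_per_mole("NO3", "nitrate_to_n2"))
  expect_error(electrons_per_mole("NO3", "nitrate_to_mars"),
               "unsupported redox conversion")
  expect_error(electrons_per_mole("C3H8", "nitrate_to_n2"),
               "neither substrate nor product")
})

test_that("reaction free energies match the literature values within table tolerance", {
  dg1 <- delta_g_prime(reg$reactions$propane_nitrate_to_nitrite)
  expect_lt(abs(dg1 - (-1348)) / 1348, 0.03)
  dg3 <- delta_g_prime(reg$reactions$propane_nitrite_to_n2)
  expect_lt(abs(dg3 - (-2385)) / 2385, 0.03)
})

test_that("free energy of an identity reaction is zero and missing species fail loudly", {
  cps <- list(a = compound("a", c(C = 1), gf_prime = -100),
              b = compound("b", c(C = 1), gf_prime = -100))
  rxn <- reaction("id", c(a = -1, b = 1), cps, reference = "a")
  expect_identical(delta_g_prime(rxn), 0)
  # the biomass term has no tabulated formation energy
  expect_error(delta_g_prime(reg$reactions$anammox), "biomass")
  # but a caller-supplied value unblocks the computation
  expect_silent(delta_g_prime(reg$reactions$anammox,
                              formation = c(biomass = -67)))
})
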