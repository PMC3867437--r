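test_that("paternity certainty mixes the EPM extents and rises with Coalition-Male frequency", {
  expect_equal(paternity_certainty(model_params(e_coal = 0, e_noncoal = 0), 0.3), 1)
  p <- model_params(e_coal = 0.02, e_noncoal = 0.15)
  expect_equal(paternity_certainty(p, 1), 1 - 0.02)
  expect_equal(paternity_certainty(p, 0), 1 - 0.15)
  expect_equal(paternity_certainty(p, 0.4), 1 - (0.4 * 0.02 + 0.6 * 0.15))
  q <- seq(0, 1, by = 0.1)
  expect_true(all(diff(paternity_certainty(p, q)) >= 0))
})

test_that("pairing table has female-frequency rows and (q, 1-q) columns, clamped corners warned", {
  st <- population_state(0.2, 0.3, 0.5, q_coal = 0.4)
  # independence when assortment is off
  tab <- pairing_table(model_params(a_assort = 0), st)
  expect_equal(unname(tab[, "Coal"]), c(0.2, 0.3, 0.5) * 0.4)
  # no Coalition Males
  tab0 <- suppressWarnings(pairing_table(model_params(a_assort = 0.8),
                        population_state(0.2, 0.3, 0.5, q_coal = 0)))
  expect_equal(unname(tab0[, "Coal"]), c(0, 0, 0))
  # demand exceeding supply is clamped with a warning; marginals still hold
  p1 <- model_params(a_assort = 1)
  st1 <- population_state(0.6, 0.2, 0.2, q_coal = 0.5)
  expect_warning(tab1 <- pairing_table(p1, st1), "clamped")
  expect_equal(unname(tab1[, "Coal"]), c(0.5, 0, 0))
  expect_equal(unname(colSums(tab1)), c(0.5, 0.5))
  expect_equal(unname(rowSums(tab1)), c(0.6, 0.2, 0.2))
  # generic case marginals
  tab2 <- pairing_table(model_params(a_assort = 0.5), st)
  expect_equal(unname(colSums(tab2)), c(0.4, 0.6))
  expect_equal(unname(rowSums(tab2)), c(0.2, 0.3, 0.5))
  expect_true(all(tab2 >= 0 & tab2 <= 1))
})

test_that("male fitness equals the exhaustive branch-enumeration oracle", {
  draws <- rand_params(12, seed = 41)
  for (i in seq_len(nrow(draws))) {
    p <- as_model_params(draws[i, ])
    st <- rand_state(seed = 800 + i)
    oracle <- enum_male_fitness(p, st)
    expect_equal(suppressWarnings(fitness_coalition_male(p, st)),
                 oracle$w_coal, tolerance = 1e-12)
    expect_equal(suppressWarnings(fitness_noncoalition_male(p, st)),
                 oracle$w_noncoal, tolerance = 1e-12)
  }
  # the canonical midpoint check
  p <- model_params()
  st <- population_state(1/3, 1/3, q_coal = 0.5)
  oracle <- enum_male_fitness(p, st)
  mp <- male_profile(p, st)
  expect_equal(mp$w_coal, oracle$w_coal)
  expect_equal(mp$w_noncoal, oracle$w_noncoal)
  expect_equal(mp$advantage, oracle$w_coal - oracle$w_noncoal)
  expect_equal(mp$pi_paternity, paternity_certainty(p, 0.5))
})

test_that("indistinguishable male strategies have exactly zero advantage", {
  draws <- rand_params(25, seed = 51, a_assort = 0)
  for (i in seq_len(nrow(draws))) {
    p <- as_model_params(draws[i, ])
    p$e_coal <- p$e_noncoal
    p$b_coal <- p$b_noncoal
    st <- rand_state(seed = 900 + i)
    expect_lt(abs(male_advantage(p, st)), 1e-12)
  }
})

test_that("extra-pair matings by Non-coalition Males penalize Coalition Males", {
  # equal care, large EPM gap, no assortment: advantage strictly negative
  p <- model_params(b_coal = 0.05, b_noncoal = 0.05, e_coal = 0,
                    e_noncoal = 0.2, r_kin = 0, a_assort = 0)
  for (sd in 1:10) {
    st <- rand_state(seed = 60 + sd)
    if (st$q_coal == 0) next
    expect_lt(male_advantage(p, st), 0)
  }
})

test_that("male-female assortment expands the scope for Coalition Males under kin selection", {
  draws <- rand_params(100, seed = 61)
  st <- population_state(0.4, 0.6, 0, q_coal = 0.3)
  # strong assortment with x_cm > q_coal over-demands Coalition Males, so the
  # clamp warning is expected here
  gain <- vapply(seq_len(nrow(draws)), function(i) {
    p <- as_model_params(draws[i, ])
    p$r_kin <- 0.6
    p$a_assort <- 0.75
    hi <- suppressWarnings(male_advantage(p, st))
    p$a_assort <- 0
    hi - male_advantage(p, st)
  }, numeric(1))
  expect_gt(mean(gain), 0)
})
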