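st_mixed <- population_state(0.2, 0.3, 0.5, q_coal = 0.4)

test_that("meeting distribution applies like-with-like assortment", {
  st <- population_state(0.2, 0.3, 0.5)
  md0 <- meeting_distribution(model_params(r_kin = 0), st, "CM")
  expect_equal(c(md0$p_meet_cm, md0$p_meet_om, md0$p_meet_im), c(0.2, 0.3, 0.5))

  md1 <- meeting_distribution(model_params(r_kin = 1), st, "OM")
  expect_equal(md1$p_meet_om, 1)
  expect_equal(md1$p_meet_cm + md1$p_meet_im, 0)

  md <- meeting_distribution(model_params(r_kin = 0.5), st, "CM")
  expect_equal(c(md$p_meet_cm, md$p_meet_om, md$p_meet_im), c(0.6, 0.15, 0.25))
  expect_equal(md$p_meet_cm + md$p_meet_om + md$p_meet_im, 1)
})

test_that("offspring survival is the clamped sum of baseline, allo, and paternal effects", {
  expect_equal(offspring_survival(model_params(s0 = 0.6), 0, 0), 0.6)
  expect_equal(offspring_survival(model_params(s0 = 0.75, b_allo = 0.5), 1, 0.1), 1)
  expect_equal(offspring_survival(model_params(s0 = 0.5, b_allo = -0.5), 1, 0), 0)
})

test_that("paternal-care expectation follows the assortative pairing distribution", {
  p0 <- model_params(a_assort = 0, b_coal = 0.1, b_noncoal = 0.02, r_kin = 1)
  # random pairing: all strategies share the same expectation; r_kin = 1 means
  # every paired Coalition Male is partnered, so the q-mixture is exact
  for (s in c("CM", "OM", "IM"))
    expect_equal(expected_paternal_care(p0, st_mixed, s),
                 0.4 * 0.1 + 0.6 * 0.02)

  # no Coalition Males: everyone gets the Non-coalition care level
  st_q0 <- population_state(0.2, 0.3, 0.5, q_coal = 0)
  for (s in c("CM", "OM", "IM"))
    expect_equal(suppressWarnings(  # over-demand at q = 0 clamps, by design
      expected_paternal_care(model_params(a_assort = 0.7), st_q0, s)),
      model_params()$b_noncoal)

  # full assortment: CMs always pair with Coalition Males, residual to others
  p1 <- model_params(a_assort = 1, r_kin = 0, b_coal = 0.1, b_noncoal = 0)
  st1 <- population_state(0.2, 0.3, 0.5, q_coal = 0.5)
  expect_equal(expected_paternal_care(p1, st1, "CM"), 1 * (0.5 * 0.1))
  resid <- (0.5 - 0.2 * 1) / 0.8
  expect_equal(resid, 0.375)
  expect_equal(expected_paternal_care(p1, st1, "OM"), resid * 0.5 * 0.1)
  # female-side Coalition-Male mass equals the male supply q_coal
  expect_equal(0.2 * 1 + 0.8 * resid, 0.5)
})

test_that("Independent Mother fitness is the geometric renewal sum", {
  p <- model_params(s0 = 0.6, sf = 0.95, T_ibi = 5)
  expect_equal(fitness_im(p, care = 0), 0.6 / (1 - 0.95^5))
  # death after the first cycle: exactly one reproductive attempt
  expect_equal(fitness_im(model_params(s0 = 0.7, sf = 0)), 0.7)
  # zero offspring survival gives zero fitness
  expect_equal(fitness_im(model_params(s0 = 0)), 0)
})

test_that("OM and CM fitness reduce to IM fitness when their interactions confer nothing", {
  # no Cooperative Mothers to exploit
  p <- model_params(b_allo = 0.4, delta_ibi = 1.5)
  st <- population_state(0, 0.6, 0.4, q_coal = 0.3)
  expect_equal(fitness_om(p, st, 0.02), fitness_im(p, 0.02), tolerance = 1e-10)

  # full kin segregation: an OM only ever meets OMs
  p1 <- model_params(b_allo = 0.4, delta_ibi = 1.5, r_kin = 1)
  expect_equal(fitness_om(p1, st_mixed, 0), fitness_im(p1, 0), tolerance = 1e-10)

  # cooperation confers nothing and there are no defectors to exploit a CM
  p2 <- model_params(delta_ibi = 0, b_allo = 0)
  st2 <- population_state(0.3, 0, 0.7, q_coal = 0.2)
  expect_equal(fitness_cm(p2, st2, 0.05), fitness_im(p2, 0.05), tolerance = 1e-10)
  p3 <- model_params(delta_ibi = 0, b_allo = 0, r_kin = 1)
  expect_equal(fitness_cm(p3, st_mixed, 0), fitness_im(p3, 0), tolerance = 1e-10)
})

test_that("full segregation with a real cooperation benefit puts CM strictly above IM", {
  for (p in list(model_params(r_kin = 1, delta_ibi = 1.5, b_allo = 0),
                 model_params(r_kin = 1, delta_ibi = 0.5, b_allo = 0.3))) {
    expect_gt(fitness_cm(p, st_mixed, 0.02), fitness_im(p, 0.02))
  }
})

test_that("kin selection and exploitable CMs raise the respective fitnesses monotonically", {
  draws <- rand_params(50, seed = 21, b_allo = c(0, 0.5), r_kin = 0, a_assort = 0)
  for (i in seq_len(nrow(draws))) {
    p0 <- as_model_params(draws[i, ])
    st <- rand_state(seed = 500 + i)
    p1 <- p0; p1$r_kin <- 0.2
    expect_gte(fitness_cm(p1, st, 0.03), fitness_cm(p0, st, 0.03) - 1e-12)

    # more CMs to exploit cannot hurt an OM when allo-care is beneficial
    st_lo <- population_state(0.1, 0.5, 0.4, st$q_coal)
    st_hi <- population_state(0.4, 0.5, 0.1, st$q_coal)
    expect_gte(fitness_om(p0, st_hi, 0.03), fitness_om(p0, st_lo, 0.03) - 1e-12)
  }
})

test_that("the female profile mean is the frequency-weighted strategy mix", {
  draws <- rand_params(20, seed = 31)
  for (i in seq_len(nrow(draws))) {
    p <- as_model_params(draws[i, ])
    st <- rand_state(seed = 700 + i)
    fp <- suppressWarnings(female_profile(p, st))
    expect_equal(fp$w_mean,
                 st$x_cm * fp$w_cm + st$y_om * fp$w_om + st$z_im * fp$w_im,
                 tolerance = 1e-10)
    expect_gte(fp$w_mean, min(fp$w_im, fp$w_om, fp$w_cm) - 1e-12)
    expect_lte(fp$w_mean, max(fp$w_im, fp$w_om, fp$w_cm) + 1e-12)
    expect_true(all(c(fp$w_im, fp$w_om, fp$w_cm) >= 0))
  }
  # monomorphic IM population: mean fitness is IM fitness
  p <- model_params()
  st_im <- population_state(0, 0, 1, q_coal = 0.5)
  fp <- female_profile(p, st_im)
  expect_equal(fp$w_mean, fp$w_im)
})
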