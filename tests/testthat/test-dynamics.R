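test_that("replicator step preserves the simplex and fixes vertices and equal-fitness states", {
  draws <- rand_params(10, seed = 71)
  for (i in seq_len(nrow(draws))) {
    p <- as_model_params(draws[i, ])
    st <- rand_state(seed = 1000 + i)
    # high-assortment draws can hit the pairing clamp; that warning is expected
    nxt <- suppressWarnings(replicator_step(p, st))
    expect_lt(abs(nxt$x_cm + nxt$y_om + nxt$z_im - 1), 1e-12)
    expect_true(all(c(nxt$x_cm, nxt$y_om, nxt$z_im) >= 0))
    expect_equal(nxt$q_coal, st$q_coal)
  }
  p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
  for (v in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))) {
    st <- population_state(v[1], v[2], v[3], q_coal = 0.5)
    nxt <- replicator_step(p, st)
    expect_equal(c(nxt$x_cm, nxt$y_om, nxt$z_im), v)
  }
  # all strategies payoff-equivalent (no cooperation benefit, no defectors):
  # the interior state on the CM-IM edge is a fixed point
  p_eq <- model_params(delta_ibi = 0, b_allo = 0)
  st_eq <- population_state(0.4, 0, 0.6, q_coal = 0.3)
  nxt <- replicator_step(p_eq, st_eq)
  expect_equal(c(nxt$x_cm, nxt$y_om, nxt$z_im), c(0.4, 0, 0.6), tolerance = 1e-12)
})

test_that("trajectories are constant at vertices and track the fitness ordering stepwise", {
  p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
  tr <- trajectory(p, population_state(0, 1, 0, q_coal = 0.5), max_steps = 10)
  expect_true(tr$converged)
  expect_true(all(tr$states$y_om == 1))

  # each frequency moves in the direction of its relative fitness
  st0 <- population_state(0.25, 0.35, 0.4, q_coal = 0.5)
  tr <- trajectory(p, st0, max_steps = 40)
  s <- tr$states
  for (k in seq_len(nrow(s) - 1)) {
    fp <- female_profile(p, population_state(s$x_cm[k], s$y_om[k], s$z_im[k],
                                             q_coal = s$q_coal[k]))
    expect_equal(sign(s$x_cm[k + 1] - s$x_cm[k]),
                 sign(s$x_cm[k] * (fp$w_cm - fp$w_mean)))
    expect_equal(sign(s$z_im[k + 1] - s$z_im[k]),
                 sign(s$z_im[k] * (fp$w_im - fp$w_mean)))
  }

  # with OM favored near the OM vertex, CMs go extinct and the OM share
  # grows; once CMs are gone OM and IM are payoff-equivalent, so the path
  # settles on the OM-IM edge near the OM vertex
  p_om <- model_params(b_allo = 0.4, delta_ibi = 1.5, r_kin = 0)
  tr <- trajectory(p_om, population_state(0.02, 0.93, 0.05, q_coal = 0.5),
                   max_steps = 3000, tol = 1e-12)
  last <- tr$states[nrow(tr$states), ]
  expect_true(tr$converged)
  expect_lt(last$x_cm, 1e-6)
  expect_gt(last$y_om, 0.93)
  cls_near <- female_profile(p_om, population_state(0.02, 0.93, 0.05, 0.5))
  expect_gt(cls_near$w_om, cls_near$w_im)  # OM strictly favored on the path
})

test_that("simplex classification matches analytic dominance patterns", {
  # no cooperation benefit: CM can never strictly beat IM while OMs exist
  cls <- classify_simplex(model_params(delta_ibi = 0, b_allo = 0),
                          q_coal = 0.3, grid_resolution = 19)
  interior <- cls[cls$y_om > 0, ]
  expect_gt(nrow(interior), 150)
  expect_true(all(interior$w_cm <= interior$w_im + 1e-9))

  # full segregation with a benefit: CM favored everywhere
  cls2 <- classify_simplex(model_params(r_kin = 1, delta_ibi = 1.5, b_allo = 0.2),
                           q_coal = 0.3, grid_resolution = 15)
  expect_true(all(cls2$label == "CM"))

  # labels stable under grid refinement away from classification boundaries
  p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
  c15 <- classify_simplex(p, 0.5, 15)
  c45 <- classify_simplex(p, 0.5, 45)
  key <- function(d) sprintf("%.10f_%.10f", d$x_cm, d$y_om)
  shared <- merge(data.frame(k = key(c15), lab15 = c15$label,
                             m = pmin(abs(c15$d_cm_om), abs(c15$d_om_im),
                                      abs(c15$d_cm_im))),
                  data.frame(k = key(c45), lab45 = c45$label))
  away <- shared[shared$m > 0.05, ]
  expect_gt(nrow(away), 50)
  expect_true(all(away$lab15 == away$lab45))
})

test_that("the CM-OM edge equilibrium brackets the basin and honors boundary cases", {
  # full segregation with benefit: whole edge favors CM
  b1 <- cm_om_edge_equilibrium(model_params(r_kin = 1, delta_ibi = 1.5), 0.3)
  expect_equal(b1$boundary_case, "cm_always")
  expect_equal(b1$basin_cm, 1)

  # no benefit: OM weakly dominates everywhere on the edge
  p0 <- model_params(delta_ibi = 0, b_allo = 0)
  b0 <- cm_om_edge_equilibrium(p0, 0.3)
  expect_equal(b0$boundary_case, "om_always")
  expect_equal(b0$basin_cm, 0)
  xs <- seq(0, 1, length.out = 50)
  gaps <- vapply(xs, function(x) {
    st <- population_state(x, 1 - x, 0, q_coal = 0.3)
    fitness_cm(p0, st) - fitness_om(p0, st)
  }, numeric(1))
  expect_true(all(gaps <= 1e-10))

  # interior root: the fitness gap vanishes at the returned equilibrium
  p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
  b <- cm_om_edge_equilibrium(p, 0.5, tol = 1e-10)
  expect_equal(b$boundary_case, "interior")
  st <- population_state(b$x_star, 1 - b$x_star, 0, q_coal = 0.5)
  fp <- female_profile(p, st)
  expect_lt(abs(fp$w_cm - fp$w_om), 1e-8)
  expect_equal(b$basin_cm, 1 - b$x_star)

  # invariant to pre-scan refinement
  b2 <- cm_om_edge_equilibrium(p, 0.5, tol = 1e-6, n_scan = 400)
  expect_lt(abs(b2$x_star - b$x_star), 2e-6)
})

test_that("edge trajectories flow away from the unstable equilibrium", {
  p <- model_params(b_allo = 0.3, delta_ibi = 1.5)
  b <- cm_om_edge_equilibrium(p, 0.5)
  up <- trajectory(p, population_state(min(b$x_star + 0.05, 1),
                                       1 - min(b$x_star + 0.05, 1), 0, 0.5),
                   max_steps = 400)
  dn <- trajectory(p, population_state(max(b$x_star - 0.05, 0),
                                       1 - max(b$x_star - 0.05, 0), 0, 0.5),
                   max_steps = 400)
  expect_gt(up$states$x_cm[nrow(up$states)], b$x_star + 0.05)
  expect_lt(dn$states$x_cm[nrow(dn$states)], b$x_star - 0.05)
  # the edge is invariant: no Independent Mothers ever reappear
  expect_true(all(up$states$z_im == 0))
})
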