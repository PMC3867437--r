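# Shared fixtures: random valid parameter sets / states, and small
# independent oracles used across test files.

rand_params <- function(n, seed, ...) {
  sample_params(param_ranges(...), n, seed)
}

rand_state <- function(seed) {
  s <- uniform_simplex_state(1, seed = seed)
  population_state(s$x_cm, s$y_om, s$z_im, s$q_coal)
}

# Independent enumeration oracle for male fitness: exhaustive sum over the
# discrete (partnered?, paired-female-strategy) outcome branches, built from
# the exported female fitness functions and pairing table -- no sampling.
enum_male_fitness <- function(p, st) {
  tab <- suppressWarnings(pairing_table(p, st))
  q <- st$q_coal
  wf <- function(care) c(CM = fitness_cm(p, st, care), OM = fitness_om(p, st, care),
                         IM = fitness_im(p, care))
  cond <- function(col, denom) {
    if (denom > 0) tab[, col] / denom
    else if (col == "Coal" && st$x_cm * p$a_assort > 0) c(CM = 1, OM = 0, IM = 0)
    else c(CM = st$x_cm, OM = st$y_om, IM = st$z_im)
  }
  c_coal <- cond("Coal", q)
  c_non <- cond("Non", 1 - q)
  Pi <- paternity_certainty(p, q)
  pi_m <- p$r_kin + (1 - p$r_kin) * q
  fp <- suppressWarnings(female_profile(p, st))  # clamped corners expected
  w_mean <- fp$w_mean
  E <- function(d, care) sum(d * wf(care))
  w_coal <- pi_m * (Pi * E(c_coal, p$b_coal) + p$e_coal * w_mean) +
    (1 - pi_m) * (Pi * E(c_coal, p$b_noncoal) + p$e_noncoal * w_mean)
  w_non <- Pi * E(c_non, p$b_noncoal) + p$e_noncoal * w_mean
  list(w_coal = w_coal, w_noncoal = w_non)
}
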