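# Stochastic individual-lifetime simulator. It implements the model's event
# rules directly (yearly survival draws, partner search, pairing, defection,
# births) with no reference to the closed-form fitness expressions, and so
# serves as the brute-force oracle those expressions are validated against.

.strategy_code <- function(strategy) {
  match(match.arg(strategy, c("IM", "OM", "CM")), c("IM", "OM", "CM")) - 1L
}

# meeting distribution + realized-care probability for a focal female
.oracle_inputs <- function(p, state, strategy) {
  md <- meeting_distribution(p, state, strategy)
  ch <- .care_hi_prob(p, state$x_cm, state$q_coal)
  p_hi <- if (strategy == "CM") ch$cm else ch$other
  list(md = md, p_care_hi = p_hi)
}

#' Simulate one female reproductive lifetime
#'
#' Draws a full event history for one female of the given strategy: her mate
#' type (once per lifetime, fixing the paternal-care level her offspring
#' receive), then cycle by cycle her interactants, births, offspring survival
#' outcomes, pair formation/dissolution, and death. This pure-R simulator
#' records every event; for large-scale moment estimation use
#' [estimate_fitness()], which runs a compiled implementation of the same
#' event rules.
#'
#' @param p A [model_params()] object.
#' @param state A [population_state()].
#' @param strategy `"IM"`, `"OM"`, or `"CM"`.
#' @return A list of class `lifetime_record`: `strategy`, `events` (data
#'   frame with columns `type`, `year`), `offspring` (0/1 survival indicator
#'   per birth), `total` (offspring surviving to breeding age).
#' @export
simulate_lifetime <- function(p, state, strategy = c("IM", "OM", "CM")) {
  p <- validate_params(p)
  strategy <- match.arg(strategy)
  oi <- .oracle_inputs(p, state, strategy)
  care <- if (stats::runif(1) < oi$p_care_hi) p$b_coal else p$b_noncoal
  S_im <- .surv_off(p$s0, p$b_allo, 0, care)
  S_allo <- .surv_off(p$s0, p$b_allo, 1, care)
  cyc_long <- p$T_ibi
  cyc_short <- p$T_ibi - p$delta_ibi
  survive_cycle <- function(len) {
    whole <- floor(len)
    if (whole > 0 && any(stats::runif(whole) >= p$sf)) return(FALSE)
    frac <- len - whole
    !(frac > 0 && stats::runif(1) >= p$sf^frac)
  }
  events <- list()
  offspring <- integer(0)
  year <- 0
  add <- function(type) events[[length(events) + 1L]] <<- list(type = type, year = year)
  birth <- function(S) offspring[length(offspring) + 1L] <<- as.integer(stats::runif(1) < S)
  alive <- TRUE
  paired <- FALSE
  while (alive) {
    if (strategy == "IM") {
      add("im_cycle"); birth(S_im)
      if (!survive_cycle(cyc_long)) alive <- FALSE
      year <- year + cyc_long
    } else if (strategy == "OM") {
      u <- stats::runif(1)
      if (u < oi$md$p_meet_cm && stats::runif(1) < 0.5) {
        add("coop_cycle"); birth(S_allo)          # exploits the allo-parent
        if (!survive_cycle(cyc_short)) alive <- FALSE
        year <- year + cyc_short
      } else {
        add("im_cycle"); birth(S_im)
        if (!survive_cycle(cyc_long)) alive <- FALSE
        year <- year + cyc_long
      }
    } else {                                      # CM
      if (!paired) {
        u <- stats::runif(1)
        if (u < oi$md$p_meet_cm) {
          add("search_met_CM")
          paired <- TRUE                          # search costs no time
        } else if (u < oi$md$p_meet_cm + oi$md$p_meet_om) {
          add("search_met_OM")
          if (stats::runif(1) < 0.5) {
            add("sucker_period")                  # allo-mothers, no own birth
            if (!survive_cycle(cyc_short)) alive <- FALSE
            year <- year + cyc_short
          } else {
            add("im_cycle"); birth(S_im)
            if (!survive_cycle(cyc_long)) alive <- FALSE
            year <- year + cyc_long
          }
        } else {
          add("search_met_IM")
          add("im_cycle"); birth(S_im)
          if (!survive_cycle(cyc_long)) alive <- FALSE
          year <- year + cyc_long
        }
      } else {
        add("coop_cycle"); birth(S_allo)
        self_ok <- survive_cycle(cyc_short)
        year <- year + cyc_short
        if (!self_ok) {
          alive <- FALSE
        } else if (!survive_cycle(cyc_short)) {   # partner's survival draw
          add("pair_dissolved")
          paired <- FALSE
        }
      }
    }
  }
  add("death")
  ev <- data.frame(type = vapply(events, `[[`, "", "type"),
                   year = vapply(events, `[[`, 0, "year"))
  structure(list(strategy = strategy, events = ev, offspring = offspring,
                 total = sum(offspring)),
            class = "lifetime_record")
}

#' Monte Carlo fitness estimate from simulated lifetimes
#'
#' Simulates `n_lifetimes` independent reproductive lifetimes with the
#' compiled event-rule simulator and returns the mean and standard error of
#' total offspring surviving to breeding age. This is the package's
#' independent check on the closed-form fitness functions
#' ([fitness_im()], [fitness_om()], [fitness_cm()]).
#'
#' @inheritParams simulate_lifetime
#' @param n_lifetimes Number of lifetimes (`>= 2`).
#' @param seed Integer seed (applied with `set.seed`).
#' @param engine `"cpp"` (default) or `"r"`; the pure-R engine replays
#'   [simulate_lifetime()] and is used to cross-validate the compiled one.
#' @return A list with `mean`, `se`, `n`, `strategy`.
#' @export
#' @examples
#' p <- model_params()
#' st <- population_state(0.3, 0.3, q_coal = 0.5)
#' est <- estimate_fitness(p, st, "IM", n_lifetimes = 5000, seed = 1)
#' c(closed_form = fitness_im(p, care = expected_paternal_care(p, st, "IM")),
#'   monte_carlo = est$mean)
estimate_fitness <- function(p, state, strategy = c("IM", "OM", "CM"),
                             n_lifetimes = 1e5, seed = 1,
                             engine = c("cpp", "r")) {
  p <- validate_params(p)
  strategy <- match.arg(strategy)
  engine <- match.arg(engine)
  stopifnot(n_lifetimes >= 2)
  n <- as.integer(n_lifetimes)
  set.seed(seed)
  if (engine == "cpp") {
    oi <- .oracle_inputs(p, state, strategy)
    totals <- cpp_lifetime_totals(n, .strategy_code(strategy),
                                  p$s0, p$sf, p$b_allo, p$T_ibi, p$delta_ibi,
                                  p$b_coal, p$b_noncoal, oi$p_care_hi,
                                  oi$md$p_meet_cm, oi$md$p_meet_om,
                                  oi$md$p_meet_im)
  } else {
    totals <- vapply(seq_len(n),
                     function(i) simulate_lifetime(p, state, strategy)$total,
                     numeric(1))
  }
  list(mean = mean(totals), se = stats::sd(totals) / sqrt(n), n = n,
       strategy = strategy)
}

#' Compare closed-form fitness with the lifetime oracle at random points
#'
#' Draws `k` random (parameter, state) points, computes the three closed-form
#' female fitnesses, estimates each by Monte Carlo over `n_lifetimes`
#' simulated lifetimes, and reports the standardized deviation
#' `(closed - mc) / se` per strategy and point.
#'
#' @param ranges A [param_ranges()] object to draw parameters from.
#' @param k Number of random points.
#' @param n_lifetimes Lifetimes per estimate.
#' @param seed Root seed.
#' @return A data frame of class `oracle_check` with one row per (point,
#'   strategy): the point index, strategy, closed-form value, Monte Carlo
#'   mean, standard error, and z-score.
#' @export
oracle_check <- function(ranges = default_ranges(), k = 20,
                         n_lifetimes = 1e5, seed = 1) {
  draws <- sample_params(ranges, k, seed)
  rows <- vector("list", 3L * k)
  for (i in seq_len(k)) {
    p <- as_model_params(draws[i, ])
    st_df <- uniform_simplex_state(1, seed = draw_seed(seed, 10000 + i))
    st <- population_state(st_df$x_cm, st_df$y_om, st_df$z_im, st_df$q_coal)
    w <- .female_w(p, st$x_cm, st$y_om, st$z_im, st$q_coal)
    closed <- c(IM = w$w_im, OM = w$w_om, CM = w$w_cm)
    for (j in seq_along(closed)) {
      strat <- names(closed)[j]
      est <- estimate_fitness(p, st, strat, n_lifetimes,
                              seed = draw_seed(seed, 20000 + 3 * i + j))
      rows[[3L * (i - 1L) + j]] <- data.frame(
        point = i, strategy = strat, closed = unname(closed[j]),
        mc_mean = est$mean, mc_se = est$se,
        z = (unname(closed[j]) - est$mean) / est$se)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("oracle_check", "data.frame")
  out
}
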