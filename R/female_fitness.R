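# Closed-form expected lifetime fitness of the three female strategies.
#
# All fitnesses are expected counts of offspring surviving to breeding
# adulthood over a mother's lifetime, under a renewal convention in which an
# offspring is credited at the start of each reproductive cycle and the
# mother must survive the cycle (probability sf^length) to begin the next.
# Internal .w_* kernels are pure arithmetic and vectorize over states, care
# levels, and parameter vectors; the exported functions add validation and
# classed returns.

# -- vectorized kernels -------------------------------------------------------

.surv_off <- function(s0, b_allo, allo, care) {
  pmin(pmax(s0 + b_allo * allo + care, 0), 1)
}

# IM renewal: credit S, survive T_ibi to repeat => S / (1 - sf^T)
.w_im <- function(p, care) {
  d1 <- p$sf^p$T_ibi
  .surv_off(p$s0, p$b_allo, 0, care) / (1 - d1)
}

# OM renewal over one encounter cycle:
#   meet CM  (prob (1-r) x): coin -> exploit (allo survival, short cycle)
#                                  or both revert to IM behaviour
#   meet OM/IM:              independent IM cycle
.w_om <- function(p, x, y, z, care) {
  r <- p$r_kin
  p_cm <- (1 - r) * x
  p_rest <- 1 - p_cm                       # r + (1-r)(y+z) on the simplex
  d1 <- p$sf^p$T_ibi
  d2 <- p$sf^(p$T_ibi - p$delta_ibi)
  S_im <- .surv_off(p$s0, p$b_allo, 0, care)
  S_allo <- .surv_off(p$s0, p$b_allo, 1, care)
  num <- p_cm * 0.5 * (S_allo + S_im) + p_rest * S_im
  den <- 1 - (p_cm * 0.5 * (d2 + d1) + p_rest * d1)
  if (any(den <= 0)) stop("OM renewal denominator <= 0 (requires sf < 1)")
  num / den
}

# CM two-state system (Search V_S, Paired V_P):
#   V_S = p_cc V_P + p_co [ 1/2 (0 + d2 V_S) + 1/2 (S_im + d1 V_S) ]
#                  + p_ci (S_im + d1 V_S)
#   V_P = S_coop + d2^2 V_P + d2 (1 - d2) V_S
# Meeting an OM resolves by fair coin into the sucker's payoff (one
# allomothering period of length T - delta, no own offspring) or an IM cycle;
# a CM-CM pair persists while both mothers survive, the survivor of a
# dissolved pair returns to Search.
.w_cm <- function(p, x, y, z, care, value = c("search", "paired")) {
  value <- match.arg(value)
  r <- p$r_kin
  p_cc <- r + (1 - r) * x
  p_co <- (1 - r) * y
  p_ci <- (1 - r) * z
  d1 <- p$sf^p$T_ibi
  d2 <- p$sf^(p$T_ibi - p$delta_ibi)
  S_im <- .surv_off(p$s0, p$b_allo, 0, care)
  S_coop <- .surv_off(p$s0, p$b_allo, 1, care)
  A <- p_cc * d2 / (1 + d2)                 # = p_cc d2 (1 - d2) / (1 - d2^2)
  B <- p_co * 0.5 * (d1 + d2) + p_ci * d1
  C <- p_cc * S_coop / (1 - d2^2) + (p_co * 0.5 + p_ci) * S_im
  den <- 1 - A - B
  if (any(den <= 0)) stop("CM renewal system singular (requires sf < 1)")
  V_S <- C / den
  if (value == "search") V_S else (S_coop + d2 * (1 - d2) * V_S) / (1 - d2^2)
}

# Pair-formation bookkeeping on the female side.
# P(CM pairs with a Coalition Male)    = a + (1 - a) q
# P(OM/IM pair with a Coalition Male)  = residual mass, clamped to [0, 1]
# P(a Coalition Male found a partner)  = r + (1 - r) q
.pair_coal_prob <- function(p, x, q) {
  P_cm <- p$a_assort + (1 - p$a_assort) * q
  P_other <- ifelse(x >= 1 - 1e-12, q, (q - x * P_cm) / (1 - x))
  clamped <- P_other < 0 | P_other > 1
  list(cm = P_cm, other = pmin(pmax(P_other, 0), 1),
       partnered = p$r_kin + (1 - p$r_kin) * q, clamped = clamped)
}

# Probability that a female of each strategy receives the Coalition care
# level b_coal: she must pair with a Coalition Male who himself found a
# coalition partner. Otherwise she receives b_noncoal.
.care_hi_prob <- function(p, x, q) {
  pc <- .pair_coal_prob(p, x, q)
  list(cm = pc$cm * pc$partnered, other = pc$other * pc$partnered,
       clamped = pc$clamped)
}

# Full female fitness vector at a state. Fitness is evaluated at each of the
# two realizable care levels and mixed with the pairing probabilities, which
# is the exact expectation over the discrete mate outcome (it differs from
# evaluating at the mean care only where the survival clamp binds).
.female_w <- function(p, x, y, z, q) {
  ch <- .care_hi_prob(p, x, q)
  mix <- function(fun, prob_hi) {
    prob_hi * fun(p$b_coal) + (1 - prob_hi) * fun(p$b_noncoal)
  }
  w_im <- mix(function(c) .w_im(p, c), ch$other)
  w_om <- mix(function(c) .w_om(p, x, y, z, c), ch$other)
  w_cm <- mix(function(c) .w_cm(p, x, y, z, c), ch$cm)
  list(w_im = w_im, w_om = w_om, w_cm = w_cm,
       w_mean = x * w_cm + y * w_om + z * w_im, clamped = ch$clamped)
}

# -- exported operations ------------------------------------------------------

#' Distribution of a focal female's next female interactant
#'
#' With kin-selection strength `r_kin`, a female meets her own strategy with
#' probability `r_kin + (1 - r_kin) * f_own` and any other strategy `s` with
#' probability `(1 - r_kin) * f_s`, where `f` are population frequencies.
#'
#' @param p A [model_params()] object.
#' @param state A [population_state()].
#' @param self_strategy One of `"CM"`, `"OM"`, `"IM"`.
#' @return A list of class `female_meeting_distribution` with fields
#'   `p_meet_cm`, `p_meet_om`, `p_meet_im` (summing to 1).
#' @export
#' @examples
#' st <- population_state(0.2, 0.3, 0.5)
#' meeting_distribution(model_params(r_kin = 0.5), st, "CM")
meeting_distribution <- function(p, state, self_strategy = c("CM", "OM", "IM")) {
  p <- validate_params(p)
  self_strategy <- match.arg(self_strategy)
  r <- p$r_kin
  f <- c(CM = state$x_cm, OM = state$y_om, IM = state$z_im)
  pr <- (1 - r) * f
  pr[self_strategy] <- r + (1 - r) * f[self_strategy]
  out <- list(p_meet_cm = unname(pr["CM"]), p_meet_om = unname(pr["OM"]),
              p_meet_im = unname(pr["IM"]))
  class(out) <- "female_meeting_distribution"
  out
}

#' Offspring survival to breeding adulthood
#'
#' `clamp(s0 + b_allo * allo + care, 0, 1)`: baseline survival plus the
#' allo-parental effect (if the offspring received allo-care) plus the
#' paternal-care increment.
#'
#' @param p A [model_params()] object.
#' @param allo 0/1 indicator of allo-parental care.
#' @param care Paternal-care survival increment (`>= 0`).
#' @return A probability.
#' @export
offspring_survival <- function(p, allo = 0, care = 0) {
  p <- validate_params(p)
  stopifnot(all(care >= 0), all(allo %in% c(0, 1)))
  .surv_off(p$s0, p$b_allo, allo, care)
}

#' Expected paternal-care increment for a female strategy
#'
#' Cooperative Mothers pair with Coalition Males with probability
#' `a_assort + (1 - a_assort) * q_coal`; the other strategies split the
#' residual Coalition-Male mass, clamped to `[0, 1]` (a warning is emitted if
#' assortment over-allocates Coalition Males). A paired Coalition Male
#' provides `b_coal` only if he himself found a coalition partner
#' (probability `r_kin + (1 - r_kin) * q_coal`), otherwise `b_noncoal`.
#'
#' @inheritParams meeting_distribution
#' @param female_strategy One of `"CM"`, `"OM"`, `"IM"`.
#' @return The expected survival increment from paternal care.
#' @export
expected_paternal_care <- function(p, state, female_strategy = c("CM", "OM", "IM")) {
  p <- validate_params(p)
  female_strategy <- match.arg(female_strategy)
  pc <- .pair_coal_prob(p, state$x_cm, state$q_coal)
  if (any(pc$clamped))
    warning("assortment over-allocates Coalition Males; residual pairing ",
            "probability clamped to [0, 1]")
  P <- if (female_strategy == "CM") pc$cm else pc$other
  care_if_coal <- pc$partnered * p$b_coal + (1 - pc$partnered) * p$b_noncoal
  P * care_if_coal + (1 - P) * p$b_noncoal
}

#' Lifetime fitness of an Independent Mother
#'
#' An IM's payoff is not contingent on interactions with other females: each
#' cycle she produces an offspring surviving with probability
#' `s0 + care` (clamped) and continues with probability `sf^T_ibi`, giving
#' `S / (1 - sf^T_ibi)`.
#'
#' @param p A [model_params()] object.
#' @param care Paternal-care survival increment received by her offspring.
#' @return Expected lifetime count of offspring surviving to breeding age.
#' @export
fitness_im <- function(p, care = 0) {
  p <- validate_params(p)
  if (p$sf >= 1) stop("sf = 1 gives a non-finite reproductive horizon")
  stopifnot(all(care >= 0))
  .w_im(p, care)
}

#' Lifetime fitness of an Opportunistic Mother
#'
#' Each cycle the OM draws an interactant from [meeting_distribution()]. On
#' meeting a CM, a fair coin decides whether the OM reproduces first and
#' exploits the allo-parent (allo survival benefit and the shortened
#' interbirth interval) or the CM opts to reproduce first, the OM refuses to
#' allo-parent, and both act as Independent Mothers for the cycle. Meetings
#' with OMs or IMs are independent IM-style cycles. Solved in closed form
#' from the renewal equation `V = sum_o P_o (S_o + d_o V)`.
#'
#' @inheritParams fitness_im
#' @param state A [population_state()].
#' @return Expected lifetime surviving-offspring count.
#' @export
fitness_om <- function(p, state, care = 0) {
  p <- validate_params(p)
  stopifnot(all(care >= 0))
  .w_om(p, state$x_cm, state$y_om, state$z_im, care)
}

#' Lifetime fitness of a Cooperative Mother
#'
#' A CM searches for a cooperative partner: encounters with IMs cost an IM
#' cycle, encounters with OMs resolve by fair coin into the sucker's payoff
#' (an allomothering period of `T_ibi - delta_ibi` years with no own
#' offspring) or an IM cycle, and on meeting another CM the two engage in
#' reciprocal allo-parenting for as long as both survive, each enjoying the
#' allo-care survival benefit and the shortened interbirth interval. If the
#' partner dies the survivor returns to searching. Solved as a two-state
#' (Search/Paired) linear system; the returned value is the Search state,
#' where every CM lifetime begins.
#'
#' @inheritParams fitness_om
#' @return Expected lifetime surviving-offspring count.
#' @export
fitness_cm <- function(p, state, care = 0) {
  p <- validate_params(p)
  stopifnot(all(care >= 0))
  .w_cm(p, state$x_cm, state$y_om, state$z_im, care)
}

#' Female fitness profile at a population state
#'
#' Evaluates the three strategy fitnesses and their frequency-weighted mean.
#' Each strategy's fitness is the exact mixture over its mate outcome: with
#' probability "paired with a partnered Coalition Male" her offspring receive
#' care `b_coal`, otherwise `b_noncoal` (see [expected_paternal_care()] for
#' the pairing probabilities).
#'
#' @inheritParams fitness_om
#' @return A list of class `female_fitness_profile` with fields `w_im`,
#'   `w_om`, `w_cm`, `w_mean`.
#' @export
#' @examples
#' female_profile(model_params(), population_state(0.3, 0.3, q_coal = 0.5))
female_profile <- function(p, state) {
  p <- validate_params(p)
  w <- .female_w(p, state$x_cm, state$y_om, state$z_im, state$q_coal)
  if (any(w$clamped))
    warning("assortment over-allocates Coalition Males; residual pairing ",
            "probability clamped to [0, 1]")
  out <- list(w_im = w$w_im, w_om = w$w_om, w_cm = w$w_cm, w_mean = w$w_mean)
  class(out) <- "female_fitness_profile"
  out
}

#' @export
print.female_fitness_profile <- function(x, ...) {
  cat(sprintf("<female_fitness_profile> IM %.4f  OM %.4f  CM %.4f  (mean %.4f)\n",
              x$w_im, x$w_om, x$w_cm, x$w_mean))
  invisible(x)
}
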