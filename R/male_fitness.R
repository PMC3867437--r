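# Fitness of Coalition and Non-coalition Males: within-pair siring weighted
# by population paternity certainty, plus extra-pair gains proportional to
# mean female fitness, over the assortative male-female pairing distribution.

# -- vectorized kernels -------------------------------------------------------

.paternity <- function(p, q) 1 - (q * p$e_coal + (1 - q) * p$e_noncoal)

# Joint pairing table entries (Coalition column), with demand clamped to the
# available Coalition-Male supply q; the residual mass is split between OM and
# IM females in proportion to their frequencies.
.pairing_coal_col <- function(p, x, y, z, q) {
  raw_cm <- x * (p$a_assort + (1 - p$a_assort) * q)
  P_cm <- pmin(raw_cm, q)
  resid <- pmax(q - P_cm, 0)
  yz <- y + z
  P_om <- ifelse(yz > 0, resid * y / yz, 0)
  P_im <- ifelse(yz > 0, resid * z / yz, 0)
  list(cm = P_cm, om = P_om, im = P_im, clamped = raw_cm > q + 1e-15)
}

# Female-strategy distribution conditional on the male's type. For a male
# type absent from the population (q = 0 Coalition, q = 1 Non-coalition) the
# rare-mutant limit is used: assortment weight x * a_assort toward CM females
# if positive, else random pairing by frequency.
.cond_female_given_male <- function(p, x, y, z, q) {
  col <- .pairing_coal_col(p, x, y, z, q)
  eps <- 1e-300
  qpos <- q > 0
  mut_w <- x * p$a_assort
  mut_cm <- ifelse(mut_w > 0, 1, x)
  mut_om <- ifelse(mut_w > 0, 0, y)
  mut_im <- ifelse(mut_w > 0, 0, z)
  coal <- list(cm = ifelse(qpos, col$cm / pmax(q, eps), mut_cm),
               om = ifelse(qpos, col$om / pmax(q, eps), mut_om),
               im = ifelse(qpos, col$im / pmax(q, eps), mut_im))
  qn <- 1 - q
  qnpos <- qn > 0
  non <- list(cm = ifelse(qnpos, (x - col$cm) / pmax(qn, eps), x),
              om = ifelse(qnpos, (y - col$om) / pmax(qn, eps), y),
              im = ifelse(qnpos, (z - col$im) / pmax(qn, eps), z))
  list(coal = coal, non = non, clamped = col$clamped)
}

.male_w <- function(p, x, y, z, q) {
  cond <- .cond_female_given_male(p, x, y, z, q)
  wb <- function(care) {
    list(im = .w_im(p, care), om = .w_om(p, x, y, z, care),
         cm = .w_cm(p, x, y, z, care))
  }
  w_hi <- wb(p$b_coal)
  w_lo <- wb(p$b_noncoal)
  Edist <- function(d, w) d$cm * w$cm + d$om * w$om + d$im * w$im
  E_coal_hi <- Edist(cond$coal, w_hi)   # partnered Coalition Male's mate
  E_coal_lo <- Edist(cond$coal, w_lo)   # unpartnered Coalition Male's mate
  E_non_lo <- Edist(cond$non, w_lo)
  Pi <- .paternity(p, q)
  pi_m <- p$r_kin + (1 - p$r_kin) * q
  w_mean <- .female_w(p, x, y, z, q)$w_mean
  w_coal <- pi_m * (Pi * E_coal_hi + p$e_coal * w_mean) +
    (1 - pi_m) * (Pi * E_coal_lo + p$e_noncoal * w_mean)
  w_noncoal <- Pi * E_non_lo + p$e_noncoal * w_mean
  list(w_coal = w_coal, w_noncoal = w_noncoal,
       advantage = w_coal - w_noncoal, pi_paternity = Pi,
       clamped = cond$clamped)
}

# -- exported operations ------------------------------------------------------

#' Population paternity certainty
#'
#' The probability that a male's within-pair provisioning goes toward his own
#' biological offspring: `1 - (q_coal * e_coal + (1 - q_coal) * e_noncoal)`.
#' More extra-pair mating activity in the population lowers it; a higher
#' frequency of (less promiscuous) Coalition Males raises it.
#'
#' @param p A [model_params()] object.
#' @param q_coal Frequency of Coalition Males.
#' @return A probability.
#' @export
paternity_certainty <- function(p, q_coal) {
  p <- validate_params(p)
  stopifnot(all(q_coal >= 0 & q_coal <= 1))
  .paternity(p, q_coal)
}

#' Joint pairing table of female strategies and male types
#'
#' `P(CM, Coal) = x_cm * (a_assort + (1 - a_assort) * q_coal)`, clamped to the
#' Coalition-Male supply `q_coal` (with a warning when assortative demand
#' exceeds supply); the residual Coalition mass is allocated to OM and IM
#' females in proportion to their frequencies, and the Non-coalition column
#' is each row total minus its Coalition entry. Row sums equal the female
#' frequencies and column sums equal `(q_coal, 1 - q_coal)`.
#'
#' @param p A [model_params()] object.
#' @param state A [population_state()].
#' @return A 3 x 2 matrix (rows CM/OM/IM, columns Coal/Non) of class
#'   `pairing_table`, with a logical attribute `clamped`.
#' @export
pairing_table <- function(p, state) {
  p <- validate_params(p)
  x <- state$x_cm; y <- state$y_om; z <- state$z_im; q <- state$q_coal
  col <- .pairing_coal_col(p, x, y, z, q)
  if (col$clamped)
    warning("assortative demand for Coalition Males exceeds supply q_coal; ",
            "P(CM, Coal) clamped to q_coal")
  tab <- matrix(c(col$cm, col$om, col$im,
                  x - col$cm, y - col$om, z - col$im),
                nrow = 3, dimnames = list(c("CM", "OM", "IM"),
                                          c("Coal", "Non")))
  structure(tab, clamped = col$clamped, class = c("pairing_table", "matrix", "array"))
}

#' Fitness of a Coalition Male
#'
#' A Coalition Male finds a coalition partner with probability
#' `r_kin + (1 - r_kin) * q_coal`. Partnered, he provides care `b_coal`,
#' mates extra-pair at extent `e_coal`, and his within-pair siring is the
#' paternity certainty times the expected fitness of his mate (drawn from the
#' Coalition column of the [pairing_table()], re-evaluated at his actual care
#' level). Unpartnered he behaves as a Non-coalition Male (care `b_noncoal`,
#' EPM `e_noncoal`) while still pairing as a Coalition-type male. The
#' extra-pair gain is the EPM extent times mean female fitness.
#'
#' @inheritParams pairing_table
#' @return Expected lifetime sired offspring surviving to breeding age.
#' @export
fitness_coalition_male <- function(p, state) {
  p <- validate_params(p)
  .male_w(p, state$x_cm, state$y_om, state$z_im, state$q_coal)$w_coal
}

#' Fitness of a Non-coalition Male
#'
#' `Pi * E[w_female(care = b_noncoal) | paired male is Non-coalition] +
#' e_noncoal * w_mean`, with the mate-strategy distribution from the
#' Non-coalition column of the [pairing_table()].
#'
#' @inheritParams pairing_table
#' @return Expected lifetime sired offspring surviving to breeding age.
#' @export
fitness_noncoalition_male <- function(p, state) {
  p <- validate_params(p)
  .male_w(p, state$x_cm, state$y_om, state$z_im, state$q_coal)$w_noncoal
}

#' Male fitness profile and Coalition-Male advantage
#'
#' @inheritParams pairing_table
#' @return A list of class `male_fitness_profile` with fields `w_coal`,
#'   `w_noncoal`, `advantage` (`w_coal - w_noncoal`), and `pi_paternity`.
#' @export
#' @examples
#' male_profile(model_params(), population_state(1/3, 1/3, q_coal = 0.5))
male_profile <- function(p, state) {
  p <- validate_params(p)
  w <- .male_w(p, state$x_cm, state$y_om, state$z_im, state$q_coal)
  if (any(w$clamped))
    warning("assortative demand for Coalition Males exceeds supply q_coal; ",
            "pairing table clamped")
  out <- list(w_coal = w$w_coal, w_noncoal = w$w_noncoal,
              advantage = w$advantage, pi_paternity = w$pi_paternity)
  class(out) <- "male_fitness_profile"
  out
}

#' @rdname male_profile
#' @return `male_advantage()` returns the signed difference
#'   `w_coal - w_noncoal` alone.
#' @export
male_advantage <- function(p, state) {
  male_profile(p, state)$advantage
}

#' @export
print.male_fitness_profile <- function(x, ...) {
  cat(sprintf("<male_fitness_profile> Coal %.4f  Non %.4f  advantage %+.4f  Pi %.4f\n",
              x$w_coal, x$w_noncoal, x$advantage, x$pi_paternity))
  invisible(x)
}
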