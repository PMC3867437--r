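#' Model parameters for the cooperative-breeding model
#'
#' Bundles one point of the 11-dimensional parameter space of the
#' cooperative-breeding model: life-history rates, the effects of
#' allo-parental and paternal care on offspring survival, extra-pair mating
#' (EPM) extents of the two male strategies, and the two assortment
#' strengths.
#'
#' @param s0 Baseline probability that an offspring survives to breeding
#'   adulthood, absent allo-parental and paternal care.
#' @param sf Annual survival probability of a mother (must be `< 1`; the
#'   fitness series diverge for an immortal mother).
#' @param b_allo Marginal change in offspring survival to adulthood caused by
#'   allo-parental care. May be negative (net cost).
#' @param T_ibi Interbirth interval (years) of an Independent Mother.
#' @param delta_ibi Decrease (years) in the interbirth interval for mothers
#'   who share the lactational load; must satisfy `0 <= delta_ibi < T_ibi`.
#' @param e_noncoal,e_coal Lifetime extra-pair mating extents of
#'   Non-coalition and Coalition Males. Coalition Males mate-guard each other,
#'   so `e_coal <= e_noncoal`.
#' @param b_noncoal,b_coal Marginal paternal-care effects on offspring
#'   survival for Non-coalition and partnered Coalition Males. Coalitions reap
#'   an economy of scale, so `b_noncoal <= b_coal`.
#' @param r_kin Kin-selection (like-with-like) assortment strength within each
#'   sex: the probability of interacting with one's own strategy regardless of
#'   its frequency.
#' @param a_assort Strength of positive assortment between Cooperative
#'   Mothers and Coalition Males at pair formation.
#'
#' @return An object of class `model_params` (a validated named list).
#'   Defaults are the midpoints of the hypothesized empirical ranges (see
#'   [default_ranges()]).
#' @seealso [validate_params()], [sample_params()], [female_profile()]
#' @export
#' @examples
#' p <- model_params(r_kin = 0.2, b_allo = 0.3)
#' p$sf
model_params <- function(s0 = 0.625, sf = 0.945, b_allo = 0, T_ibi = 5,
                         delta_ibi = 1.25, e_noncoal = 0.1, e_coal = 0.025,
                         b_noncoal = 0.025, b_coal = 0.05,
                         r_kin = 0, a_assort = 0) {
  p <- list(s0 = s0, sf = sf, b_allo = b_allo, T_ibi = T_ibi,
            delta_ibi = delta_ibi, e_noncoal = e_noncoal, e_coal = e_coal,
            b_noncoal = b_noncoal, b_coal = b_coal,
            r_kin = r_kin, a_assort = a_assort)
  class(p) <- "model_params"
  validate_params(p)
}

#' Field names of a `model_params` object, in canonical order
#' @keywords internal
param_fields <- function() {
  c("s0", "sf", "b_allo", "T_ibi", "delta_ibi", "e_noncoal", "e_coal",
    "b_noncoal", "b_coal", "r_kin", "a_assort")
}

#' Validate a parameter set
#'
#' Checks every invariant of the parameter space (probability bounds, ordering
#' of the EPM extents and paternal-care effects, `delta_ibi < T_ibi`) and
#' returns the object unchanged when all hold.
#'
#' @param p A `model_params` object or a named list with the same fields.
#' @return `p`, invisibly classed as `model_params`, if valid.
#' @export
validate_params <- function(p) {
  fl <- param_fields()
  missing <- setdiff(fl, names(p))
  if (length(missing) > 0L)
    stop("model_params missing field(s): ", paste(missing, collapse = ", "))
  for (f in fl) {
    v <- p[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("field '", f, "': must be a single finite number")
  }
  chk <- function(ok, field, what) {
    if (!ok) stop("field '", field, "': ", what, " violated", call. = FALSE)
  }
  chk(p$s0 >= 0 && p$s0 <= 1, "s0", "0 <= s0 <= 1")
  chk(p$sf >= 0 && p$sf < 1, "sf", "0 <= sf < 1")
  chk(p$b_allo >= -1 && p$b_allo <= 1, "b_allo", "-1 <= b_allo <= 1")
  chk(p$T_ibi > 0, "T_ibi", "T_ibi > 0")
  chk(p$delta_ibi >= 0, "delta_ibi", "delta_ibi >= 0")
  chk(p$delta_ibi < p$T_ibi, "delta_ibi", "delta_ibi < T_ibi")
  chk(p$e_noncoal >= 0 && p$e_noncoal <= 1, "e_noncoal", "0 <= e_noncoal <= 1")
  chk(p$e_coal >= 0, "e_coal", "e_coal >= 0")
  chk(p$e_coal <= p$e_noncoal, "e_coal", "ordering e_coal <= e_noncoal")
  chk(p$b_coal >= 0 && p$b_coal <= 1, "b_coal", "0 <= b_coal <= 1")
  chk(p$b_noncoal >= 0, "b_noncoal", "b_noncoal >= 0")
  chk(p$b_noncoal <= p$b_coal, "b_noncoal", "ordering b_noncoal <= b_coal")
  chk(p$r_kin >= 0 && p$r_kin <= 1, "r_kin", "0 <= r_kin <= 1")
  chk(p$a_assort >= 0 && p$a_assort <= 1, "a_assort", "0 <= a_assort <= 1")
  if (!inherits(p, "model_params")) class(p) <- "model_params"
  p
}

#' @export
print.model_params <- function(x, ...) {
  cat("<model_params>\n")
  v <- unlist(x[param_fields()])
  print(round(v, 6))
  invisible(x)
}

#' Hypothesized parameter ranges
#'
#' A `param_ranges` object holds a `c(lo, hi)` bound pair per model parameter;
#' Monte Carlo experiments draw each field independently uniform on its
#' interval (with rejection of draws violating the two ordering constraints).
#' [default_ranges()] returns the empirically motivated ranges: offspring
#' survival between chimpanzee-like and hunter-gatherer values (0.5-0.75),
#' maternal annual survival 0.90-0.99, allo-parental effect spanning net cost
#' to net benefit (-0.5-0.5), a fixed chimpanzee-like 5-year interbirth
#' interval, interbirth-interval reduction 0.5-2.0 years, EPM extents 0-0.2
#' (Non-coalition) and 0-0.05 (Coalition), paternal-care effects 0-0.05
#' (Non-coalition) and 0-0.1 (Coalition), and assortment strengths 0-1.
#'
#' @param ... Named `c(lo, hi)` pairs (or single numbers, treated as
#'   degenerate ranges) overriding the defaults, e.g.
#'   `param_ranges(r_kin = c(0, 0.5), sf = 0.95)`.
#' @return An object of class `param_ranges`: a named list of length-2
#'   numeric vectors.
#' @export
#' @examples
#' rg <- param_ranges(r_kin = 0, a_assort = 0)  # conservative: no assortment
#' rg$s0
param_ranges <- function(...) {
  rg <- list(s0 = c(0.5, 0.75), sf = c(0.90, 0.99), b_allo = c(-0.5, 0.5),
             T_ibi = c(5, 5), delta_ibi = c(0.5, 2.0),
             e_noncoal = c(0, 0.2), e_coal = c(0, 0.05),
             b_noncoal = c(0, 0.05), b_coal = c(0, 0.1),
             r_kin = c(0, 1), a_assort = c(0, 1))
  dots <- list(...)
  bad <- setdiff(names(dots), names(rg))
  if (length(bad) > 0L)
    stop("unknown parameter range(s): ", paste(bad, collapse = ", "))
  for (f in names(dots)) {
    v <- as.numeric(dots[[f]])
    if (length(v) == 1L) v <- c(v, v)
    rg[[f]] <- v
  }
  validate_ranges(rg)
}

#' @rdname param_ranges
#' @export
default_ranges <- function() param_ranges()

#' @keywords internal
validate_ranges <- function(rg) {
  for (f in param_fields()) {
    v <- rg[[f]]
    if (is.null(v) || length(v) != 2L || any(!is.finite(v)))
      stop("range '", f, "': need finite c(lo, hi)")
    if (v[1] > v[2]) stop("range '", f, "': lo > hi")
  }
  # bounds must sit inside the valid parameter domain; probe the corners that
  # can violate marginal (non-ordering) invariants
  probe <- lapply(rg, function(v) v[1])
  probe_hi <- lapply(rg, function(v) v[2])
  # ordering constraints are enforced at sampling time, not on the boxes;
  # temporarily satisfy them for the corner probes
  fix_order <- function(q) {
    q$e_coal <- min(q$e_coal, q$e_noncoal)
    q$b_noncoal <- min(q$b_noncoal, q$b_coal)
    q$delta_ibi <- min(q$delta_ibi, q$T_ibi - 1e-9)
    q
  }
  validate_params(fix_order(probe))
  validate_params(fix_order(probe_hi))
  class(rg) <- "param_ranges"
  rg
}

# Deterministic per-draw seed stream: results are independent of execution
# order and two experiments sharing a root seed share their draws (common
# random numbers).
draw_seed <- function(root, i) {
  m <- 2147483647
  as.integer((abs(as.numeric(root)) %% m + 48271 * (as.numeric(i) %% 44488)) %% m)
}

#' Sample parameter sets uniformly from hypothesized ranges
#'
#' Draws `n` parameter sets, each field independently uniform on its
#' `[lo, hi]` interval. Whole draws violating an ordering constraint
#' (`e_coal <= e_noncoal`, `b_noncoal <= b_coal`) are rejected and redrawn, so
#' the accepted sample is uniform on the constrained region. Each draw uses
#' its own RNG stream derived from `seed` and the draw index, making results
#' reproducible and order-independent.
#'
#' @param ranges A [param_ranges()] object.
#' @param n Number of parameter sets (`>= 1`).
#' @param seed Integer root seed.
#' @return A `data.frame` with `n` rows and one column per model parameter
#'   (class `param_draws`); rows convert back via [as_model_params()].
#' @export
#' @examples
#' draws <- sample_params(default_ranges(), n = 5, seed = 1)
#' as_model_params(draws[1, ])
sample_params <- function(ranges, n, seed) {
  ranges <- validate_ranges(ranges)
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  n <- as.integer(n)
  fl <- param_fields()
  out <- matrix(NA_real_, nrow = n, ncol = length(fl),
                dimnames = list(NULL, fl))
  for (i in seq_len(n)) {
    set.seed(draw_seed(seed, i))
    repeat {
      u <- stats::runif(length(fl))
      v <- vapply(seq_along(fl), function(j) {
        b <- ranges[[fl[j]]]
        b[1] + u[j] * (b[2] - b[1])
      }, numeric(1))
      names(v) <- fl
      if (v["e_coal"] <= v["e_noncoal"] && v["b_noncoal"] <= v["b_coal"] &&
          v["delta_ibi"] < v["T_ibi"]) break
    }
    out[i, ] <- v
  }
  out <- as.data.frame(out)
  class(out) <- c("param_draws", "data.frame")
  out
}

#' Convert a parameter-draw row to a `model_params` object
#' @param row One row of a `param_draws` data frame (or any named list/row
#'   with the model-parameter fields).
#' @export
as_model_params <- function(row) {
  p <- as.list(row)[param_fields()]
  p <- lapply(p, as.numeric)
  class(p) <- "model_params"
  validate_params(p)
}

#' Population state: female strategy frequencies and Coalition-Male frequency
#'
#' The female strategy frequencies (Cooperative `x_cm`, Opportunistic `y_om`,
#' Independent `z_im`) live on the 2-simplex; `q_coal` is the frequency of
#' Coalition Males among males.
#'
#' @param x_cm,y_om,z_im Female strategy frequencies; must sum to 1 within
#'   `1e-12`. If `z_im` is omitted it is computed as `1 - x_cm - y_om`.
#' @param q_coal Frequency of Coalition Males, in `[0, 1]`.
#' @return An object of class `population_state`.
#' @export
#' @examples
#' population_state(0.3, 0.3, q_coal = 0.5)
population_state <- function(x_cm, y_om, z_im = NULL, q_coal = 0) {
  if (is.null(z_im)) z_im <- 1 - x_cm - y_om
  st <- list(x_cm = x_cm, y_om = y_om, z_im = z_im, q_coal = q_coal)
  for (f in names(st)) {
    v <- st[[f]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v))
      stop("state field '", f, "' must be a single finite number")
    if (v < -1e-12 || v > 1 + 1e-12)
      stop("state field '", f, "' outside [0, 1]")
  }
  if (abs(st$x_cm + st$y_om + st$z_im - 1) > 1e-12)
    stop("female frequencies must sum to 1 (within 1e-12)")
  st$x_cm <- min(max(st$x_cm, 0), 1)
  st$y_om <- min(max(st$y_om, 0), 1)
  st$z_im <- min(max(st$z_im, 0), 1)
  st$q_coal <- min(max(st$q_coal, 0), 1)
  class(st) <- "population_state"
  st
}

#' @export
print.population_state <- function(x, ...) {
  cat(sprintf("<population_state> CM %.4f  OM %.4f  IM %.4f | Coalition males %.4f\n",
              x$x_cm, x$y_om, x$z_im, x$q_coal))
  invisible(x)
}

#' Draw population states uniformly
#'
#' Female frequencies are uniform on the 2-simplex (sorted-uniform spacings),
#' `q_coal` uniform on `[0, 1]`. Used by experiments whose design does not fix
#' the population state.
#'
#' @param n Number of states to draw.
#' @param seed Optional integer seed; if `NULL` the current RNG state is used.
#' @return A `data.frame` with columns `x_cm`, `y_om`, `z_im`, `q_coal`.
#' @export
uniform_simplex_state <- function(n = 1, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  u1 <- stats::runif(n)
  u2 <- stats::runif(n)
  lo <- pmin(u1, u2)
  hi <- pmax(u1, u2)
  data.frame(x_cm = lo, y_om = hi - lo, z_im = 1 - hi,
             q_coal = stats::runif(n))
}
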