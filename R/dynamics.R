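# Deterministic evolutionary dynamics of the female strategy frequencies:
# discrete-time (proportional-fitness) replicator updates, classification of
# the strategy simplex by favored strategy, and the basin of attraction for
# Cooperative Mothers via the unstable CM-OM edge equilibrium.

#' One discrete-time replicator step
#'
#' Updates each female strategy frequency proportionally to its relative
#' fitness, `x' = x * w / w_mean`; the Coalition-Male frequency is left
#' unchanged (male dynamics are not part of the female replicator system).
#' Vertices of the simplex are fixed points for any fitnesses.
#'
#' @param p A [model_params()] object.
#' @param state A [population_state()].
#' @return The updated [population_state()].
#' @export
replicator_step <- function(p, state) {
  prof <- female_profile(p, state)
  if (!is.finite(prof$w_mean) || prof$w_mean <= 0)
    stop("population fitness collapse (mean female fitness is zero)")
  x <- state$x_cm * prof$w_cm / prof$w_mean
  y <- state$y_om * prof$w_om / prof$w_mean
  z <- state$z_im * prof$w_im / prof$w_mean
  s <- x + y + z
  population_state(x / s, y / s, z / s, q_coal = state$q_coal)
}

#' Iterate the replicator dynamics
#'
#' Repeats [replicator_step()] until the L1 change in female frequencies
#' drops below `tol` or `max_steps` is reached.
#'
#' @inheritParams replicator_step
#' @param state0 Initial [population_state()].
#' @param max_steps Maximum number of steps (`>= 1`).
#' @param tol Convergence tolerance on the L1 frequency change (`> 0`).
#' @return A list of class `trajectory_result`: `states` (a data frame with
#'   one row per visited state, including the start), `converged`, `n_steps`.
#' @export
trajectory <- function(p, state0, max_steps = 1000, tol = 1e-10) {
  stopifnot(max_steps >= 1, tol > 0)
  states <- matrix(NA_real_, nrow = max_steps + 1, ncol = 4,
                   dimnames = list(NULL, c("x_cm", "y_om", "z_im", "q_coal")))
  cur <- state0
  states[1, ] <- c(cur$x_cm, cur$y_om, cur$z_im, cur$q_coal)
  converged <- FALSE
  n <- 0L
  for (k in seq_len(max_steps)) {
    nxt <- replicator_step(p, cur)
    n <- k
    states[k + 1, ] <- c(nxt$x_cm, nxt$y_om, nxt$z_im, nxt$q_coal)
    l1 <- abs(nxt$x_cm - cur$x_cm) + abs(nxt$y_om - cur$y_om) +
      abs(nxt$z_im - cur$z_im)
    cur <- nxt
    if (l1 < tol) { converged <- TRUE; break }
  }
  structure(list(states = as.data.frame(states[seq_len(n + 1), , drop = FALSE]),
                 converged = converged, n_steps = n),
            class = "trajectory_result")
}

#' Classify the female strategy simplex by favored strategy
#'
#' Evaluates the female fitness profile on a triangular lattice over the
#' 2-simplex and labels each point with the strategy of highest fitness
#' (ties within `1e-12` labeled `"tie"`). The pairwise fitness differences
#' are returned so the OM = IM contour (and any other boundary) can be drawn.
#'
#' @inheritParams replicator_step
#' @param q_coal Coalition-Male frequency held fixed across the lattice.
#' @param grid_resolution Number of lattice subdivisions per edge (`>= 2`).
#' @return A data frame of class `simplex_classification` with columns
#'   `x_cm`, `y_om`, `z_im`, `w_im`, `w_om`, `w_cm`, `label`, `d_cm_om`,
#'   `d_om_im`, `d_cm_im`.
#' @export
classify_simplex <- function(p, q_coal = 0, grid_resolution = 30) {
  p <- validate_params(p)
  stopifnot(grid_resolution >= 2)
  res <- as.integer(grid_resolution)
  ij <- expand.grid(i = 0:res, j = 0:res)
  ij <- ij[ij$i + ij$j <= res, ]
  x <- ij$i / res
  y <- ij$j / res
  z <- 1 - x - y
  w <- .female_w(p, x, y, z, q_coal)
  wm <- cbind(CM = w$w_cm, OM = w$w_om, IM = w$w_im)
  top <- apply(wm, 1, max)
  is_top <- wm >= top - 1e-12
  label <- ifelse(rowSums(is_top) > 1, "tie", colnames(wm)[max.col(wm)])
  out <- data.frame(x_cm = x, y_om = y, z_im = z,
                    w_im = w$w_im, w_om = w$w_om, w_cm = w$w_cm,
                    label = label,
                    d_cm_om = w$w_cm - w$w_om,
                    d_om_im = w$w_om - w$w_im,
                    d_cm_im = w$w_cm - w$w_im)
  attr(out, "q_coal") <- q_coal
  attr(out, "resolution") <- res
  class(out) <- c("simplex_classification", "data.frame")
  out
}

# w_cm - w_om along the CM-OM edge (z_im = 0), vectorized over x.
.edge_gap <- function(p, q_coal, x) {
  w <- .female_w(p, x, 1 - x, 0, q_coal)
  w$w_cm - w$w_om
}

#' Unstable CM-OM edge equilibrium and the Cooperative-Mother basin
#'
#' On the simplex edge with no Independent Mothers (`z_im = 0`, the
#' conservative setting for Cooperative Mothers), finds the frequency
#' `x_star` where `w_cm = w_om` by bisection on the sign of the fitness gap.
#' Initial frequencies above `x_star` flow to Cooperative-Mother fixation, so
#' the CM basin of attraction is `1 - x_star`. If Cooperative Mothers are
#' favored across the whole edge the basin is 1 (`boundary_case =
#' "cm_always"`); if never, 0 (`"om_always"`). With multiple sign changes the
#' unstable crossing (gap changing from negative to positive with increasing
#' `x`) at the largest `x` is returned -- the conservative, smallest-basin
#' choice -- and `multiple` is flagged.
#'
#' @inheritParams classify_simplex
#' @param tol Bisection tolerance in frequency (`> 0`).
#' @param n_scan Number of pre-scan points used to bracket sign changes.
#' @return A list of class `basin_result`: `x_star`, `basin_cm`
#'   (`= 1 - x_star`), `boundary_case` (`"interior"`, `"cm_always"` or
#'   `"om_always"`), `multiple`, `q_coal`.
#' @export
#' @examples
#' cm_om_edge_equilibrium(model_params(b_allo = 0.3, delta_ibi = 1.5), q_coal = 0.5)
cm_om_edge_equilibrium <- function(p, q_coal = 0, tol = 1e-6, n_scan = 200) {
  p <- validate_params(p)
  stopifnot(tol > 0, n_scan >= 2)
  xs <- seq(0, 1, length.out = n_scan)
  g <- .edge_gap(p, q_coal, xs)
  eps <- 1e-14
  res <- function(x_star, bc, multiple = FALSE) {
    structure(list(x_star = x_star, basin_cm = 1 - x_star,
                   boundary_case = bc, multiple = multiple, q_coal = q_coal),
              class = "basin_result")
  }
  if (min(g) > -eps) return(res(0, "cm_always"))
  if (max(g) < eps) return(res(1, "om_always"))
  lo_idx <- which(g[-length(g)] < 0 & g[-1] > 0)   # unstable: - to +
  hi_idx <- which(g[-length(g)] > 0 & g[-1] < 0)   # stable:   + to -
  bisect <- function(lo, hi, glo) {
    while (hi - lo > tol) {
      mid <- (lo + hi) / 2
      gm <- .edge_gap(p, q_coal, mid)
      same_side <- if (glo < 0) gm < 0 else gm > 0
      if (same_side) { lo <- mid } else { hi <- mid }
    }
    (lo + hi) / 2
  }
  if (length(lo_idx) > 0) {
    i <- max(lo_idx)
    x_star <- bisect(xs[i], xs[i + 1], glo = -1)
    return(res(x_star, "interior", multiple = length(lo_idx) + length(hi_idx) > 1))
  }
  # only stable (+ to -) crossings: no unstable edge equilibrium separates the
  # vertices; report the last crossing, flagged, so downstream summaries stay
  # total over degenerate parameter corners
  i <- max(hi_idx)
  x_star <- bisect(xs[i], xs[i + 1], glo = +1)
  res(x_star, "interior", multiple = TRUE)
}

#' @export
print.basin_result <- function(x, ...) {
  cat(sprintf("<basin_result> x* = %.6f  CM basin = %.6f  (%s%s)\n",
              x$x_star, x$basin_cm, x$boundary_case,
              if (isTRUE(x$multiple)) ", multiple crossings" else ""))
  invisible(x)
}
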