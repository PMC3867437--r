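# Monte Carlo experiment drivers: basin-of-attraction sweeps, Coalition-Male
# advantage surfaces, and (x_cm, q_coal) region grids. The drivers compose
# the fitness and dynamics modules; parameter draws use per-draw seed streams
# so the same root seed yields common random numbers across grid values.

.sweep_fields <- c(maternal_survival = "sf", kin_selection = "r_kin",
                   alloparental_effect = "b_allo")

# One shared block of parameter draws plus per-draw population draws.
# Returns a list of column vectors usable directly by the vectorized fitness
# kernels (fields may be overridden by the caller before evaluation).
.draw_block <- function(ranges, n_draws, seed) {
  draws <- sample_params(ranges, n_draws, seed)
  states <- uniform_simplex_state(n_draws, seed = draw_seed(seed, 900001))
  list(p = as.list(draws), states = states, draws = draws)
}

# Vectorized basin computation across parameter draws (pv: list of parameter
# vectors, q: vector). Same contract as cm_om_edge_equilibrium, bisected to
# tolerance `tol`; returns basin_cm per draw.
.basin_many <- function(pv, q, tol = 1e-6, n_scan = 200) {
  n <- length(q)
  xs <- seq(0, 1, length.out = n_scan)
  G <- vapply(xs, function(x) .edge_gap(pv, q, x), numeric(n))
  if (n == 1L) G <- matrix(G, nrow = 1L)
  eps <- 1e-14
  x_star <- rep(NA_real_, n)
  gmin <- apply(G, 1, min)
  gmax <- apply(G, 1, max)
  cm_always <- gmin > -eps
  om_always <- !cm_always & gmax < eps
  x_star[cm_always] <- 0
  x_star[om_always] <- 1
  interior <- which(!cm_always & !om_always)
  if (length(interior) > 0) {
    lo <- hi <- glo_neg <- rep(NA_real_, length(interior))
    for (k in seq_along(interior)) {
      g <- G[interior[k], ]
      up <- which(g[-n_scan] < 0 & g[-1] > 0)
      if (length(up) > 0) {
        i <- max(up); glo_neg[k] <- 1
      } else {
        i <- max(which(g[-n_scan] > 0 & g[-1] < 0)); glo_neg[k] <- 0
      }
      lo[k] <- xs[i]; hi[k] <- xs[i + 1]
    }
    sub <- function(v) if (length(v) == n) v[interior] else v
    pv_i <- lapply(pv, sub)
    q_i <- q[interior]
    while (max(hi - lo) > tol) {
      mid <- (lo + hi) / 2
      gm <- .edge_gap(pv_i, q_i, mid)
      low_side <- ifelse(glo_neg == 1, gm < 0, gm > 0)
      new_lo <- ifelse(low_side, mid, lo)
      new_hi <- ifelse(low_side, hi, mid)
      lo <- new_lo
      hi <- new_hi
    }
    x_star[interior] <- (lo + hi) / 2
  }
  1 - x_star
}

.summarise_grid <- function(values_by_grid, grid, n_draws, seed, var_name) {
  summ <- data.frame(
    value = grid,
    mean = vapply(values_by_grid, mean, numeric(1)),
    lower = vapply(values_by_grid, function(v) unname(stats::quantile(v, 0.025)), numeric(1)),
    upper = vapply(values_by_grid, function(v) unname(stats::quantile(v, 0.975)), numeric(1)),
    n_draws = n_draws)
  structure(list(summary = summ,
                 draws = do.call(cbind, values_by_grid),
                 sweep_var = var_name, seed = seed),
            class = "sweep_result")
}

#' Basin-of-attraction sweep for Cooperative Mothers
#'
#' For each grid value of the swept parameter, fixes that parameter, draws
#' `n_draws` parameter sets uniformly from `ranges` (with a uniform
#' Coalition-Male frequency per draw), computes the Cooperative-Mother basin
#' of attraction via [cm_om_edge_equilibrium()] for each draw, and returns
#' the mean with an empirical 95% band (2.5/97.5 percentiles of the per-draw
#' basins). The same parameter draws are reused at every grid value (common
#' random numbers), so the sweep isolates the effect of the swept parameter.
#'
#' The default ranges fix `r_kin = a_assort = 0` (the conservative,
#' no-assortment setting) because the empirically hypothesized ranges the
#' Monte Carlo design draws from do not cover the assortment strengths.
#'
#' @param ranges A [param_ranges()] object for the non-swept parameters.
#' @param sweep_var One of `"maternal_survival"` (annual maternal survival
#'   `sf`, the repeated-interaction parameter), `"kin_selection"` (`r_kin`),
#'   `"alloparental_effect"` (`b_allo`).
#' @param grid Numeric grid of values for the swept parameter.
#' @param n_draws Parameter draws per grid value (`>= 2`).
#' @param seed Integer root seed.
#' @param q_coal Coalition-Male frequency: a fixed value (default 0.5), or
#'   `NA` to draw it uniformly per parameter draw.
#' @return A `sweep_result`: `summary` data frame (`value`, `mean`, `lower`,
#'   `upper`, `n_draws`), the per-draw `draws` matrix, `sweep_var`, `seed`.
#' @export
#' @examples
#' sw <- basin_sweep(sweep_var = "kin_selection", grid = c(0, 0.25),
#'                   n_draws = 20, seed = 1)
#' sw$summary
basin_sweep <- function(ranges = param_ranges(r_kin = 0, a_assort = 0),
                        sweep_var = c("maternal_survival", "kin_selection",
                                      "alloparental_effect"),
                        grid = NULL, n_draws = 1000, seed = 1, q_coal = 0.5) {
  sweep_var <- match.arg(sweep_var)
  stopifnot(n_draws >= 2)
  field <- .sweep_fields[[sweep_var]]
  if (is.null(grid)) {
    grid <- switch(sweep_var,
                   maternal_survival = seq(0.90, 0.99, length.out = 7),
                   kin_selection = seq(0, 0.5, length.out = 6),
                   alloparental_effect = seq(-0.5, 0.5, length.out = 6))
  }
  dom <- param_ranges()[[field]]
  if (field != "b_allo" && (min(grid) < dom[1] || max(grid) > dom[2]) ||
      field == "b_allo" && (min(grid) < -1 || max(grid) > 1))
    stop("grid outside the valid domain of '", field, "'")
  blk <- .draw_block(ranges, n_draws, seed)
  q <- if (is.na(q_coal)) blk$states$q_coal else rep(q_coal, n_draws)
  vals <- lapply(grid, function(v) {
    pv <- blk$p
    pv[[field]] <- rep(v, n_draws)
    .basin_many(pv, q)
  })
  .summarise_grid(vals, grid, n_draws, seed, sweep_var)
}

#' Coalition-Male advantage as a function of strategy differences
#'
#' Reproduces the advantage-surface design: with kin selection and
#' male-female assortment switched off (`r_kin = a_assort = 0`), sweeps
#' either the extra-pair mating difference `e_noncoal - e_coal` (with
#' `e_coal` fixed) or the paternal-care difference `b_coal - b_noncoal`
#' (with `b_noncoal` fixed) over a grid; at each grid value the remaining
#' parameters are drawn from `ranges` and the population state uniformly
#' (female frequencies on the simplex, `q_coal` on `[0, 1]`), and the mean
#' Coalition-Male advantage with its empirical 95% band is reported, plus
#' the location where the mean crosses zero (linear interpolation between
#' grid points), if it does.
#'
#' @param ranges A [param_ranges()] object for the non-fixed parameters.
#' @param axis `"epm_difference"` or `"care_difference"`.
#' @param grid Grid of non-negative differences; defaults to the hypothesized
#'   range of the difference (0-0.2 for EPM, 0-0.1 for care).
#' @param fixed_other Fixed level of `e_coal` (EPM axis) or `b_noncoal`
#'   (care axis); default 0.025, the midpoint of each one's hypothesized range.
#' @param n_draws Parameter draws per grid value (`>= 2`).
#' @param seed Integer root seed.
#' @param state Optional fixed [population_state()] used for every draw;
#'   default `NULL` draws a fresh uniform state per parameter draw.
#' @return A `sweep_result` (see [basin_sweep()]) with an extra
#'   `sign_change` element (`NA` if the mean never crosses zero).
#' @export
male_advantage_surface <- function(ranges = default_ranges(),
                                   axis = c("epm_difference", "care_difference"),
                                   grid = NULL, fixed_other = 0.025,
                                   n_draws = 1000, seed = 1, state = NULL) {
  axis <- match.arg(axis)
  stopifnot(n_draws >= 2, fixed_other >= 0)
  if (is.null(grid)) {
    grid <- if (axis == "epm_difference") seq(0, 0.2, length.out = 9)
            else seq(0, 0.1, length.out = 9)
  }
  if (any(grid < 0)) stop("grid of differences must be non-negative")
  blk <- .draw_block(ranges, n_draws, seed)
  st <- if (is.null(state)) blk$states
        else data.frame(x_cm = state$x_cm, y_om = state$y_om,
                        z_im = state$z_im, q_coal = state$q_coal)
  vals <- lapply(grid, function(d) {
    pv <- blk$p
    pv$r_kin <- rep(0, n_draws)
    pv$a_assort <- rep(0, n_draws)
    if (axis == "epm_difference") {
      pv$e_coal <- rep(fixed_other, n_draws)
      pv$e_noncoal <- rep(fixed_other + d, n_draws)
    } else {
      pv$b_noncoal <- rep(fixed_other, n_draws)
      pv$b_coal <- rep(fixed_other + d, n_draws)
    }
    .male_w(pv, st$x_cm, st$y_om, st$z_im, st$q_coal)$advantage
  })
  out <- .summarise_grid(vals, grid, n_draws, seed, axis)
  m <- out$summary$mean
  sc <- NA_real_
  flip <- which(m[-length(m)] >= 0 & m[-1] < 0)
  if (length(flip) > 0) {
    i <- flip[1]
    sc <- grid[i] + (grid[i + 1] - grid[i]) * m[i] / (m[i] - m[i + 1])
  }
  out$sign_change <- sc
  out
}

#' Coalition-Male favored regions over strategy frequencies
#'
#' For each combination of kin-selection level `r_values` and male-female
#' assortment level `a_values`, and each cell of a grid over the frequency of
#' Cooperative Mothers `x_cm` and of Coalition Males `q_coal` (with no
#' Independent Mothers: `y_om = 1 - x_cm`), draws `n_draws` parameter sets
#' and computes the mean Coalition-Male advantage; a cell is *favored* when
#' the mean is positive. The same parameter draws are shared by every cell
#' and combination.
#'
#' @param ranges A [param_ranges()] object.
#' @param r_values,a_values Kin-selection and assortment levels to cross.
#' @param grid_resolution Number of grid points per axis over `[0, 1]`.
#' @param n_draws Parameter draws per cell (`>= 1`).
#' @param seed Integer root seed.
#' @return A list of class `region_grid_set`: `grids` (one data frame per
#'   (r, a) combination with columns `x_cm`, `q_coal`, `mean_advantage`,
#'   `favored`), `r_values`, `a_values`, `grid`, `n_draws`, `seed`.
#' @export
male_region_grid <- function(ranges = default_ranges(),
                             r_values = c(0, 0.3, 0.6),
                             a_values = c(0, 0.375, 0.75),
                             grid_resolution = 10, n_draws = 100, seed = 1) {
  stopifnot(n_draws >= 1, grid_resolution >= 2)
  blk <- .draw_block(ranges, max(n_draws, 2L), seed)
  ax <- seq(0, 1, length.out = grid_resolution)
  cells <- expand.grid(x_cm = ax, q_coal = ax)
  grids <- list()
  for (r in r_values) for (a in a_values) {
    pv <- blk$p
    pv$r_kin <- rep(r, length(pv$r_kin))
    pv$a_assort <- rep(a, length(pv$a_assort))
    pv <- lapply(pv, function(v) v[seq_len(n_draws)])
    adv <- vapply(seq_len(nrow(cells)), function(i) {
      mean(.male_w(pv, cells$x_cm[i], 1 - cells$x_cm[i], 0, cells$q_coal[i])$advantage)
    }, numeric(1))
    g <- data.frame(x_cm = cells$x_cm, q_coal = cells$q_coal,
                    mean_advantage = adv, favored = adv > 0)
    grids[[sprintf("r=%g,a=%g", r, a)]] <- g
  }
  structure(list(grids = grids, r_values = r_values, a_values = a_values,
                 grid = ax, n_draws = n_draws, seed = seed),
            class = "region_grid_set")
}

#' Fraction of (x_cm, q_coal) cells favoring Coalition Males
#'
#' @param rgs A `region_grid_set` from [male_region_grid()].
#' @param r,a The combination to summarize.
#' @return The favored-area fraction in `[0, 1]`.
#' @export
favored_area <- function(rgs, r, a) {
  key <- sprintf("r=%g,a=%g", r, a)
  g <- rgs$grids[[key]]
  if (is.null(g)) stop("no grid for ", key)
  mean(g$favored)
}

#' @export
print.sweep_result <- function(x, ...) {
  cat(sprintf("<sweep_result> %s, %d draws/grid value\n", x$sweep_var,
              x$summary$n_draws[1]))
  print(x$summary, row.names = FALSE)
  invisible(x)
}

#' @export
plot.sweep_result <- function(x, ylab = "outcome", ...) {
  s <- x$summary
  graphics::plot(s$value, s$mean, type = "l", ylim = range(s$lower, s$upper),
                 xlab = x$sweep_var, ylab = ylab, ...)
  graphics::lines(s$value, s$lower, lty = 2)
  graphics::lines(s$value, s$upper, lty = 2)
  invisible(x)
}
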