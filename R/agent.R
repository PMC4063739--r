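# Stochastic agent-based twin of the deterministic model. Exact
# continuous-time simulation: propensities are constant between events
# (substrate only changes at division events), so the Gillespie algorithm is
# exact for this system.

#' Stochastic agent-based simulation of a batch culture
#'
#' Simulates individual cells in a culture volume `volume_ml`: per-cell
#' division waiting times are exponential at the Monod rate for the current
#' substrate concentration, tc cells additionally die at rate
#' `death_rate_tc`, and on stationary entry (substrate below
#' `stationary_s_frac * c_total`) each non-tc cell switches to the tc state by
#' an independent Bernoulli(`p_tc`) draw. Every division consumes
#' `cell_dw / yield_gpg` grams of substrate. The number of completed divisions
#' of each tc cell before its death is recorded; the tc state is heritable.
#'
#' The per-ml carrying capacity of the published parameter set is ~6e8
#' cells, so agent runs are intended for small volumes (the guard caps the
#' expected total event count; exceeding `max_cells` is an explicit error
#' rather than a silent truncation).
#'
#' @param params a [PopModelParams-class].
#' @param n0 initial number of non-tc cells (>= 1).
#' @param seed integer random seed (mandatory; no hidden global state).
#' @param duration simulated time, h.
#' @param volume_ml culture volume, ml. Biomass concentration (mg/ml) is
#'   cell count times `cell_dw` (g) times 1e3, divided by `volume_ml`.
#' @param n0_tc initial number of tc cells.
#' @param dt_out output grid spacing, h.
#' @param post_transfer whether this batch follows a serial transfer (matters
#'   for `death_window = "post_transfer"`).
#' @param max_cells memory/time guard on the cell count.
#' @return A list with elements `trajectory` (a [Trajectory-class]),
#'   `tc_divisions_completed` (integer vector: divisions completed by each tc
#'   cell that died during the run), and `tc_divisions_alive` (same for tc
#'   cells still alive at the end).
#' @examples
#' p <- popModelParams(c_total = 0.02, stationary_s_frac = 0.05)
#' sim <- agentSimulate(p, n0 = 500, seed = 1, duration = 10,
#'                      volume_ml = 1e-4)
#' @export
agentSimulate <- function(params, n0, seed, duration, volume_ml,
                          n0_tc = 0, dt_out = 0.05, post_transfer = FALSE,
                          max_cells = 5e6) {
  stopifnot(is(params, "PopModelParams"))
  validObject(params)
  if (missing(seed) || !is.numeric(seed) || length(seed) != 1L)
    stop("an explicit integer seed is required")
  if (n0 < 1) stop("n0 must be >= 1")
  if (volume_ml <= 0) stop("volume_ml must be > 0")

  capacity <- n0 + n0_tc +
    ceiling(params@yield_gpg * params@c_total * volume_ml * 1e-3 /
              params@cell_dw)
  if (capacity > max_cells)
    stop(sprintf(paste0("expected cell count %.3g exceeds max_cells = %.3g; ",
                        "reduce volume_ml or c_total"), capacity, max_cells))

  death_on <- params@death_window == "always" || isTRUE(post_transfer)
  mu_n_max <- log(2) / params@gen_time_ntc
  mu_t_max <- if (is.finite(params@gen_time_tc)) log(2) / params@gen_time_tc else 0
  delta <- if (death_on) params@death_rate_tc else 0
  ks <- params@ks
  div_cost <- params@cell_dw * 1e3 / params@yield_gpg  # mg substrate/division
  s_star_conc <- params@stationary_s_frac * params@c_total

  grid <- seq(0, duration, by = dt_out)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)
  ng <- length(grid)
  rec_n <- integer(ng); rec_t <- integer(ng); rec_s <- numeric(ng)

  withSeed(seed, {
    N_n <- as.integer(n0)
    N_t <- as.integer(n0_tc)
    S <- params@c_total * volume_ml          # mg substrate in the volume
    tc_div <- rep(0L, N_t)                   # divisions so far, per living tc cell
    completed <- integer(0)
    switched <- FALSE
    t_switch <- NA_real_
    t <- 0
    gi <- 1L

    record_until <- function(tt) {
      while (gi <= ng && grid[gi] <= tt + 1e-12) {
        rec_n[gi] <<- N_n; rec_t[gi] <<- N_t; rec_s[gi] <<- S
        gi <<- gi + 1L
      }
    }

    repeat {
      s_conc <- S / volume_ml
      if (!switched && s_conc <= s_star_conc) {
        nsw <- rbinom(1, N_n, params@p_tc)
        N_n <- N_n - nsw
        N_t <- N_t + nsw
        if (nsw > 0) tc_div <- c(tc_div, rep(0L, nsw))
        switched <- TRUE
        t_switch <- t
        s_conc <- S / volume_ml
      }
      f <- s_conc / (ks + s_conc)
      can_divide <- S >= div_cost
      r_div_n <- if (can_divide) N_n * mu_n_max * f else 0
      r_div_t <- if (can_divide) N_t * mu_t_max * f else 0
      r_death <- N_t * delta
      R <- r_div_n + r_div_t + r_death
      if (R <= 0) { record_until(duration); break }
      dt <- rexp(1, R)
      t_next <- t + dt
      if (t_next > duration) { record_until(duration); break }
      record_until(t_next)
      t <- t_next
      u <- runif(1) * R
      if (u < r_div_n) {
        N_n <- N_n + 1L
        S <- S - div_cost
      } else if (u < r_div_n + r_div_t) {
        i <- sample.int(N_t, 1L)
        tc_div[i] <- tc_div[i] + 1L
        tc_div <- c(tc_div, 0L)
        N_t <- N_t + 1L
        S <- S - div_cost
      } else {
        i <- sample.int(N_t, 1L)
        completed <- c(completed, tc_div[i])
        tc_div <- tc_div[-i]
        N_t <- N_t - 1L
      }
    }
    if (S < 0) S <- 0

    b_ntc <- rec_n * params@cell_dw * 1e3 / volume_ml
    b_tc <- rec_t * params@cell_dw * 1e3 / volume_ml
    d <- .trajFrame(grid, rec_s / volume_ml, b_ntc, b_tc, params@cell_dw)
    traj <- new("Trajectory", data = d, params = params,
                stationary_time = t_switch, stationary_state = list(),
                batch = 1)
    list(trajectory = traj,
         tc_divisions_completed = completed,
         tc_divisions_alive = tc_div)
  })
}
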