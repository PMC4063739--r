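# Deterministic two-subpopulation Monod model: batch growth, stationary-phase
# switching into the transfer-competent (tc) state, tc death, serial transfer.

#' Monod specific growth rate
#'
#' `mu(s) = (ln 2 / gen_time) * s / (ks + s)`: the specific growth rate of a
#' population with generation time `gen_time` at saturating substrate,
#' saturating with half-maximal rate at `s = ks`.
#'
#' @param s substrate concentration, mg/ml (vectorised).
#' @param gen_time generation time at saturation, h (`Inf` gives rate 0).
#' @param ks half-saturation constant, mg/ml.
#' @return Specific growth rate, per h.
#' @examples
#' monodRate(4.25, gen_time = 1, ks = 0.02)
#' monodRate(0.02, 1, 0.02) == log(2) / 2   # half-saturation identity
#' @export
monodRate <- function(s, gen_time, ks) {
  if (!is.numeric(gen_time) || length(gen_time) != 1L || is.na(gen_time) ||
      gen_time <= 0)
    stop("gen_time must be a single positive number")
  if (!is.numeric(ks) || length(ks) != 1L || is.na(ks) || ks <= 0)
    stop("ks must be a single positive number")
  if (any(s < 0)) stop("substrate concentration must be >= 0")
  (log(2) / gen_time) * s / (ks + s)
}

#' Apply the stationary-phase switch
#'
#' On entry into stationary phase a fraction `p_tc` of the non-tc biomass
#' converts to the transfer-competent state. Total biomass is conserved
#' exactly and the state is marked stationary.
#'
#' @param state a [CultureState-class].
#' @param p_tc switching probability in `[0, 1]`.
#' @return The switched `CultureState`.
#' @examples
#' stationarySwitch(cultureState(s = 0.001, b_ntc = 1), p_tc = 0.025)
#' @export
stationarySwitch <- function(state, p_tc) {
  stopifnot(is(state, "CultureState"))
  if (!is.numeric(p_tc) || length(p_tc) != 1L || is.na(p_tc) ||
      p_tc < 0 || p_tc > 1)
    stop("p_tc must be a single number in [0, 1]")
  moved <- p_tc * state@b_ntc
  cultureState(t = state@t, s = state@s,
               b_ntc = state@b_ntc - moved, b_tc = state@b_tc + moved,
               in_stationary = TRUE)
}

#' Dilute a stationary culture into fresh medium
#'
#' Serial transfer: both biomass compartments are scaled by the dilution
#' factor (which therefore preserves the tc fraction), substrate is reset to
#' the fresh-medium concentration, and the batch clock restarts at zero.
#'
#' @param end_state the `CultureState` at the end of the previous batch.
#' @param params a [PopModelParams-class]; supplies `dilution` and `c_total`.
#' @param dilution optional override of `params@dilution`.
#' @return The inoculated `CultureState` of the next batch.
#' @export
serialTransfer <- function(end_state, params, dilution = NULL) {
  stopifnot(is(end_state, "CultureState"), is(params, "PopModelParams"))
  d <- if (is.null(dilution)) params@dilution else dilution
  if (d <= 0 || d > 1) stop("dilution must be in (0, 1]")
  cultureState(t = 0, s = params@c_total,
               b_ntc = end_state@b_ntc * d, b_tc = end_state@b_tc * d,
               in_stationary = FALSE)
}

## shared right-hand side of the ODE; y = (s, b_ntc, b_tc). Substrate below
## 1e-10 mg/ml is treated as exhausted: it is ~10 orders below working
## concentrations and freezing it there keeps the integrator from stalling on
## the asymptotic decay to zero.
.popdynRhs <- function(t, y, p) {
  s <- if (y[1] > 1e-10) y[1] else 0
  f <- s / (p$ks + s)
  mu_n <- p$mu_n_max * f
  mu_t <- p$mu_t_max * f
  db_n <- mu_n * y[2]
  db_t <- (mu_t - p$delta) * y[3]
  ds <- -(mu_n * y[2] + mu_t * y[3]) / p$yield
  list(c(ds, db_n, db_t))
}

## biomass columns are mg dw/ml, cell_dw is g: cells/ml = mg * 1e-3 / g
.trajFrame <- function(t, s, b_ntc, b_tc, cell_dw) {
  s <- pmax(s, 0)
  b_ntc <- pmax(b_ntc, 0)
  b_tc <- pmax(b_tc, 0)
  b_total <- b_ntc + b_tc
  data.frame(t_h = t, s_mg_ml = s, b_ntc = b_ntc, b_tc = b_tc,
             b_total = b_total, cells_total = b_total * 1e-3 / cell_dw,
             tc_fraction = ifelse(b_total > 0, b_tc / b_total, 0))
}

#' Simulate one batch culture
#'
#' Integrates the two-subpopulation Monod model
#' \deqn{dB_{ntc}/dt = \mu_{ntc}(S) B_{ntc}}
#' \deqn{dB_{tc}/dt  = \mu_{tc}(S) B_{tc} - \delta_{tc} B_{tc}}
#' \deqn{dS/dt = -(\mu_{ntc} B_{ntc} + \mu_{tc} B_{tc}) / Y}
#' with an adaptive stiff-capable integrator ([deSolve::lsodar]). Stationary
#' entry is detected by a root on `S = stationary_s_frac * c_total`; at that
#' instant a fraction `p_tc` of non-tc biomass switches to the tc state, once
#' per batch. With `death_window = "always"` the tc death term is active
#' throughout; with `"post_transfer"` it is active only when
#' `post_transfer = TRUE` (batches following a serial transfer).
#'
#' @param params a [PopModelParams-class].
#' @param init a [CultureState-class]; the inoculum.
#' @param duration batch duration, h.
#' @param dt_out output grid spacing, h.
#' @param post_transfer whether this batch follows a serial transfer.
#' @param rtol,atol integrator tolerances.
#' @return A [Trajectory-class].
#' @examples
#' p <- popModelParams()
#' # 1e6 cells/ml inoculum: 1e6 * 2e-12 g * 1e3 mg/g = 2e-3 mg/ml
#' tr <- simulateBatch(p, cultureState(s = 4.25, b_ntc = 2e-3), 24)
#' stationaryEntry(tr)
#' @export
simulateBatch <- function(params, init, duration, dt_out = 0.05,
                          post_transfer = FALSE, rtol = 1e-8, atol = 1e-12) {
  stopifnot(is(params, "PopModelParams"), is(init, "CultureState"))
  validObject(params); validObject(init)
  if (duration <= 0) stop("duration must be > 0")

  death_on <- params@death_window == "always" || isTRUE(post_transfer)
  p <- list(ks = params@ks,
            mu_n_max = log(2) / params@gen_time_ntc,
            mu_t_max = if (is.finite(params@gen_time_tc))
              log(2) / params@gen_time_tc else 0,
            delta = if (death_on) params@death_rate_tc else 0,
            yield = params@yield_gpg)
  s_star <- params@stationary_s_frac * params@c_total

  grid <- seq(0, duration, by = dt_out)
  if (grid[length(grid)] < duration) grid <- c(grid, duration)

  y0 <- c(s = init@s, b_ntc = init@b_ntc, b_tc = init@b_tc)
  switched <- FALSE
  t_stat <- NA_real_
  stat_state <- list()

  if (init@s <= s_star || init@in_stationary) {
    ## inoculated at/below the stationary threshold: switch immediately
    sw <- stationarySwitch(cultureState(t = 0, s = init@s, b_ntc = init@b_ntc,
                                        b_tc = init@b_tc), params@p_tc)
    y0 <- c(s = sw@s, b_ntc = sw@b_ntc, b_tc = sw@b_tc)
    switched <- TRUE
    t_stat <- 0
    stat_state <- list(sw)
  }

  integrate <- function(y, times, root = FALSE) {
    if (root) {
      out <- deSolve::lsodar(y, times, .popdynRhs, p, rtol = rtol, atol = atol,
                             rootfunc = function(t, y, p) y[1] - s_star)
    } else {
      out <- deSolve::lsoda(y, times, .popdynRhs, p, rtol = rtol, atol = atol)
    }
    if (any(!is.finite(out)))
      stop("non-finite values in ODE integration; check parameters and inoculum")
    out
  }

  if (!switched) {
    out1 <- integrate(y0, grid, root = TRUE)
    troot <- attr(out1, "troot")
    if (is.null(troot) || !length(troot)) {
      d <- .trajFrame(out1[, "time"], out1[, "s"], out1[, "b_ntc"],
                      out1[, "b_tc"], params@cell_dw)
      return(new("Trajectory", data = d, params = params,
                 stationary_time = NA_real_, stationary_state = list(),
                 batch = 1))
    }
    t_stat <- troot[1]
    nr <- nrow(out1)
    pre_state <- cultureState(t = t_stat, s = max(out1[nr, "s"], 0),
                              b_ntc = max(out1[nr, "b_ntc"], 0),
                              b_tc = max(out1[nr, "b_tc"], 0))
    sw <- stationarySwitch(pre_state, params@p_tc)
    stat_state <- list(sw)
    ## keep pre-switch rows that fall on the grid (strictly before the root)
    pre <- out1[out1[, "time"] %in% grid & out1[, "time"] < t_stat, ,
                drop = FALSE]
    post_grid <- grid[grid >= t_stat]
    times2 <- unique(c(t_stat, post_grid))
    y1 <- c(s = sw@s, b_ntc = sw@b_ntc, b_tc = sw@b_tc)
    if (length(times2) > 1) {
      out2 <- integrate(y1, times2)
      out2 <- out2[out2[, "time"] %in% post_grid, , drop = FALSE]
    } else {
      out2 <- matrix(c(t_stat, y1), nrow = 1,
                     dimnames = list(NULL, c("time", "s", "b_ntc", "b_tc")))
      out2 <- out2[out2[, "time"] %in% post_grid, , drop = FALSE]
    }
    tt <- c(pre[, "time"], out2[, "time"])
    d <- .trajFrame(tt, c(pre[, "s"], out2[, "s"]),
                    c(pre[, "b_ntc"], out2[, "b_ntc"]),
                    c(pre[, "b_tc"], out2[, "b_tc"]), params@cell_dw)
  } else {
    out <- integrate(y0, grid)
    d <- .trajFrame(out[, "time"], out[, "s"], out[, "b_ntc"], out[, "b_tc"],
                    params@cell_dw)
  }
  new("Trajectory", data = d, params = params, stationary_time = t_stat,
      stationary_state = stat_state, batch = 1)
}

#' Simulate a serial-transfer experiment
#'
#' Chains [simulateBatch()] and [serialTransfer()]: each batch runs either for
#' a fixed duration or until stationary entry plus a hold period, then a
#' `dilution` fraction of the culture inoculates fresh medium. Batches after
#' the first are flagged `post_transfer`, so with
#' `death_window = "post_transfer"` tc death acts only there.
#'
#' @param params a [PopModelParams-class].
#' @param protocol a [SerialProtocol-class].
#' @param init inoculum `CultureState` of the first batch.
#' @param dt_out output grid spacing, h.
#' @return A list of [Trajectory-class], one per batch, with per-batch clocks
#'   (each starts at `t = 0`).
#' @examples
#' p <- popModelParams()
#' sims <- simulateSerial(p, serialProtocol(n_batches = 2),
#'                        cultureState(s = 4.25, b_ntc = 2e-3))
#' @export
simulateSerial <- function(params, protocol, init, dt_out = 0.05) {
  stopifnot(is(params, "PopModelParams"), is(protocol, "SerialProtocol"))
  validObject(protocol)
  out <- vector("list", protocol@n_batches)
  state <- init
  for (b in seq_len(protocol@n_batches)) {
    if (is.na(protocol@batch_hours)) {
      tr <- simulateBatch(params, state, protocol@max_hours, dt_out = dt_out,
                          post_transfer = b > 1)
      ts <- stationaryTime(tr)
      if (is.na(ts))
        stop(sprintf("batch %d never reached stationary phase within %g h",
                     b, protocol@max_hours))
      stop_t <- min(ts + protocol@hold_hours, protocol@max_hours)
      keep <- tr@data$t_h <= stop_t + 1e-9
      tr@data <- tr@data[keep, , drop = FALSE]
    } else {
      tr <- simulateBatch(params, state, protocol@batch_hours,
                          dt_out = dt_out, post_transfer = b > 1)
    }
    tr@batch <- b
    out[[b]] <- tr
    if (b < protocol@n_batches)
      state <- serialTransfer(finalState(tr), params,
                              dilution = protocol@dilution)
  }
  out
}

#' Ordinary least-squares exponential rate
#'
#' Fits `log(value) ~ time` and returns the slope (per h) with its coefficient
#' of determination. Used for growth-rate, doubling-time and decay-rate
#' estimation.
#'
#' @param times_h time points, h.
#' @param values strictly positive measurements (turbidity, biomass).
#' @return `list(rate_per_h, intercept_log, r_squared, n)`.
#' @export
fitExponentialRate <- function(times_h, values) {
  if (length(times_h) != length(values)) stop("times and values differ in length")
  ok <- is.finite(times_h) & is.finite(values)
  times_h <- times_h[ok]; values <- values[ok]
  if (any(values <= 0)) stop("values must be strictly positive for a log fit")
  if (length(values) < 2) stop("need at least 2 points")
  fit <- lm(log(values) ~ times_h)
  ## summary() warns on noise-free (perfect) fits; those are legitimate here
  r2 <- suppressWarnings(summary(fit)$r.squared)
  list(rate_per_h = unname(coef(fit)[2]),
       intercept_log = unname(coef(fit)[1]),
       r_squared = r2,
       n = length(values))
}

#' Generation time from a turbidity time course
#'
#' The generation time is `ln 2 / mu`, where `mu` is the slope of the
#' ordinary least-squares regression of natural-log culture turbidity against
#' time over at least 5 points in exponential phase. Fits with
#' `R^2 <= 0.96` are flagged as unreliable.
#'
#' @param times_h time points in the exponential window, h (>= 5 points).
#' @param turbidity strictly positive turbidity (or biomass) readings.
#' @return `list(generation_time_min, generation_time_h, mu_per_h, r_squared,
#'   r2_ok, n)`.
#' @examples
#' t <- seq(0, 4, by = 0.5)
#' fitGenerationTime(t, 0.01 * 2^t)   # doubling every hour -> 60 min
#' @export
fitGenerationTime <- function(times_h, turbidity) {
  if (length(times_h) < 5) stop("need at least 5 points in exponential phase")
  fit <- fitExponentialRate(times_h, turbidity)
  if (fit$n < 5) stop("need at least 5 points in exponential phase")
  mu <- fit$rate_per_h
  list(generation_time_min = 60 * log(2) / mu,
       generation_time_h = log(2) / mu,
       mu_per_h = mu,
       r_squared = fit$r_squared,
       r2_ok = fit$r_squared > 0.96,
       n = fit$n)
}

#' Lag time of a batch trajectory
#'
#' Lag is the difference between the time the total biomass first reaches
#' `threshold` and the time a pure exponential at `reference_rate` starting
#' from the same inoculum would need. Crossing times are interpolated on the
#' log-biomass scale.
#'
#' @param traj a [Trajectory-class].
#' @param reference_rate reference exponential rate, per h.
#' @param threshold biomass threshold, mg/ml (must exceed the inoculum).
#' @return Lag time, h.
#' @export
lagTime <- function(traj, reference_rate, threshold) {
  stopifnot(is(traj, "Trajectory"))
  if (reference_rate <= 0) stop("reference_rate must be > 0")
  d <- traj@data
  b <- d$b_total
  if (b[1] <= 0) stop("inoculum biomass must be > 0")
  if (threshold <= b[1]) stop("threshold must exceed the inoculum biomass")
  idx <- which(b >= threshold)
  if (!length(idx)) stop("trajectory never reaches the threshold")
  i <- idx[1]
  t_cross <- if (i == 1) d$t_h[1] else {
    lb <- log(b)
    d$t_h[i - 1] + (log(threshold) - lb[i - 1]) / (lb[i] - lb[i - 1]) *
      (d$t_h[i] - d$t_h[i - 1])
  }
  ideal <- log(threshold / b[1]) / reference_rate
  t_cross - ideal
}

#' Exponential-window subset of a trajectory
#'
#' Returns the grid points where substrate still exceeds `s_factor * ks`, the
#' regime where Monod growth is effectively exponential. Points with zero
#' total biomass are dropped.
#'
#' @param traj a [Trajectory-class].
#' @param s_factor multiple of `ks` defining "excess substrate".
#' @return A `data.frame` subset of the trajectory grid.
#' @export
exponentialWindow <- function(traj, s_factor = 10) {
  stopifnot(is(traj, "Trajectory"))
  d <- traj@data
  d[d$s_mg_ml > s_factor * traj@params@ks & d$b_total > 0, , drop = FALSE]
}

#' Late-exponential window of a trajectory
#'
#' The subset of [exponentialWindow()] where total biomass has passed the
#' geometric midpoint between the inoculum and the window maximum. In a
#' post-transfer batch this is the regime where a dying tc subpopulation has
#' decayed to insignificance, so the fitted rate reflects the growing
#' population alone.
#'
#' @inheritParams exponentialWindow
#' @return A `data.frame` subset of the trajectory grid.
#' @export
lateExponentialWindow <- function(traj, s_factor = 10) {
  d <- exponentialWindow(traj, s_factor = s_factor)
  if (nrow(d) < 2) return(d)
  mid <- sqrt(d$b_total[1] * max(d$b_total))
  d[d$b_total >= mid, , drop = FALSE]
}

#' Write a trajectory to CSV
#'
#' Columns: `t_h, s_mg_ml, b_ntc, b_tc, cells_total, tc_fraction`.
#'
#' @param traj a [Trajectory-class].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
writeTrajectoryCsv <- function(traj, path) {
  stopifnot(is(traj, "Trajectory"))
  d <- traj@data[, c("t_h", "s_mg_ml", "b_ntc", "b_tc", "cells_total",
                     "tc_fraction")]
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}
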