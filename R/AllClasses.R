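#' @import methods
#' @importFrom stats lm coef rexp runif rbinom rnorm rlnorm setNames aov
#'   anova ptukey pt sd density var complete.cases
NULL

#' Parameters of the two-subpopulation Monod growth model
#'
#' Holds every rate and stoichiometric constant of the transfer-competence
#' population model: batch growth of ordinary (non-transfer-competent, "non-tc")
#' cells and of transfer-competent ("tc") cells on a single limiting substrate,
#' with Monod kinetics, stationary-phase switching of a fraction `p_tc` of
#' non-tc cells into the tc state, first-order tc death, and serial 1:1000
#' transfer into fresh medium.
#'
#' @slot c_total consumable substrate concentration of fresh medium, mg/ml.
#' @slot ks Monod half-saturation constant, mg/ml.
#' @slot yield_gpg biomass produced per substrate consumed, g/g.
#' @slot cell_dw dry weight of a single cell, g.
#' @slot gen_time_ntc generation time of non-tc cells at substrate
#'   saturation, h.
#' @slot gen_time_tc generation time of tc cells at substrate saturation, h
#'   (`Inf` disables tc division).
#' @slot death_rate_tc first-order death rate of tc cells, per h.
#' @slot p_tc probability that a non-tc cell switches to the tc state on entry
#'   into stationary phase (0.025 for the wild-type element, 0.5 for the
#'   derepressed regulator deletion).
#' @slot dilution volume fraction carried into the next batch at serial
#'   transfer.
#' @slot stationary_s_frac fraction of `c_total` below which residual
#'   substrate declares stationary phase.
#' @slot death_window `"always"` applies tc death from the moment tc cells
#'   exist; `"post_transfer"` restricts it to batches after a serial transfer.
#' @export
setClass("PopModelParams",
  representation(
    c_total = "numeric", ks = "numeric", yield_gpg = "numeric",
    cell_dw = "numeric", gen_time_ntc = "numeric", gen_time_tc = "numeric",
    death_rate_tc = "numeric", p_tc = "numeric", dilution = "numeric",
    stationary_s_frac = "numeric", death_window = "character"
  )
)

setValidity("PopModelParams", function(object) {
  msg <- character(0)
  num1 <- function(x) length(x) == 1L && is.numeric(x) && !is.na(x)
  for (sl in c("c_total", "ks", "yield_gpg", "cell_dw", "gen_time_ntc",
               "gen_time_tc", "death_rate_tc", "p_tc", "dilution",
               "stationary_s_frac")) {
    if (!num1(slot(object, sl))) msg <- c(msg, paste0(sl, " must be a single number"))
  }
  if (length(msg)) return(msg)
  if (object@c_total < 0) msg <- c(msg, "c_total must be >= 0")
  if (object@ks <= 0) msg <- c(msg, "ks must be > 0")
  if (object@yield_gpg <= 0) msg <- c(msg, "yield_gpg must be > 0")
  if (object@cell_dw <= 0) msg <- c(msg, "cell_dw must be > 0")
  if (object@gen_time_ntc <= 0) msg <- c(msg, "gen_time_ntc must be > 0")
  if (object@gen_time_tc <= 0) msg <- c(msg, "gen_time_tc must be > 0")
  if (object@death_rate_tc < 0) msg <- c(msg, "death_rate_tc must be >= 0")
  if (object@p_tc < 0 || object@p_tc > 1) msg <- c(msg, "p_tc must be in [0, 1]")
  if (object@dilution <= 0 || object@dilution > 1)
    msg <- c(msg, "dilution must be in (0, 1]")
  if (object@stationary_s_frac <= 0 || object@stationary_s_frac >= 1)
    msg <- c(msg, "stationary_s_frac must be in (0, 1)")
  if (!object@death_window %in% c("always", "post_transfer"))
    msg <- c(msg, "death_window must be 'always' or 'post_transfer'")
  if (length(msg)) msg else TRUE
})

#' Construct model parameters
#'
#' Defaults are the published wild-type parameter set of the model: total
#' consumable carbon 4.25 mg/ml, single-cell dry weight 2e-12 g, yield
#' 0.3 g/g, Ks 0.02 mg/ml, non-tc generation time 1 h, tc generation time 2 h,
#' tc death rate 0.4 per h, switching probability 0.025 (use `p_tc = 0.5` for
#' the derepressed-regulator scenario) and a 1:1000 serial transfer.
#'
#' @param c_total,ks,yield_gpg,cell_dw,gen_time_ntc,gen_time_tc,death_rate_tc,p_tc,dilution,stationary_s_frac,death_window
#'   see the slot documentation of [PopModelParams-class].
#' @return A `PopModelParams` object.
#' @examples
#' popModelParams()
#' popModelParams(p_tc = 0.5)  # regulator-deletion scenario
#' @export
popModelParams <- function(c_total = 4.25, ks = 0.02, yield_gpg = 0.3,
                           cell_dw = 2e-12, gen_time_ntc = 1,
                           gen_time_tc = 2, death_rate_tc = 0.4,
                           p_tc = 0.025, dilution = 1 / 1000,
                           stationary_s_frac = 1e-3,
                           death_window = c("always", "post_transfer")) {
  death_window <- match.arg(death_window)
  new("PopModelParams", c_total = c_total, ks = ks, yield_gpg = yield_gpg,
      cell_dw = cell_dw, gen_time_ntc = gen_time_ntc,
      gen_time_tc = gen_time_tc, death_rate_tc = death_rate_tc, p_tc = p_tc,
      dilution = dilution, stationary_s_frac = stationary_s_frac,
      death_window = death_window)
}

setMethod("show", "PopModelParams", function(object) {
  cat("PopModelParams\n")
  cat(sprintf("  substrate: c_total = %g mg/ml, Ks = %g mg/ml, yield = %g g/g\n",
              object@c_total, object@ks, object@yield_gpg))
  cat(sprintf("  cells: dw = %g g, gen time non-tc = %g h, tc = %g h\n",
              object@cell_dw, object@gen_time_ntc, object@gen_time_tc))
  cat(sprintf("  tc: death rate = %g /h (%s), P_tc = %g\n",
              object@death_rate_tc, object@death_window, object@p_tc))
  cat(sprintf("  transfer: dilution = %g, stationary below %g x c_total\n",
              object@dilution, object@stationary_s_frac))
  invisible(NULL)
})

#' @describeIn PopModelParams-class coerce the parameter set to a named list.
#' @param x a `PopModelParams` object.
#' @param ... ignored.
#' @export
setMethod("as.list", "PopModelParams", function(x, ...) {
  nm <- slotNames(x)
  setNames(lapply(nm, function(s) slot(x, s)), nm)
})

#' State of one batch culture
#'
#' @slot t time within the batch, h.
#' @slot s substrate concentration, mg/ml.
#' @slot b_ntc non-tc biomass, mg dry weight/ml.
#' @slot b_tc tc biomass, mg dry weight/ml.
#' @slot in_stationary whether stationary phase has been declared.
#' @export
setClass("CultureState",
  representation(t = "numeric", s = "numeric", b_ntc = "numeric",
                 b_tc = "numeric", in_stationary = "logical")
)

setValidity("CultureState", function(object) {
  msg <- character(0)
  for (sl in c("t", "s", "b_ntc", "b_tc")) {
    v <- slot(object, sl)
    if (length(v) != 1L || !is.finite(v)) msg <- c(msg, paste0(sl, " must be a finite number"))
  }
  if (length(msg)) return(msg)
  if (object@s < 0) msg <- c(msg, "s must be >= 0")
  if (object@b_ntc < 0) msg <- c(msg, "b_ntc must be >= 0")
  if (object@b_tc < 0) msg <- c(msg, "b_tc must be >= 0")
  if (length(object@in_stationary) != 1L || is.na(object@in_stationary))
    msg <- c(msg, "in_stationary must be TRUE or FALSE")
  if (length(msg)) msg else TRUE
})

#' Construct a culture state
#'
#' @param t time, h.
#' @param s substrate concentration, mg/ml.
#' @param b_ntc,b_tc biomass of the two subpopulations, mg/ml.
#' @param in_stationary stationary-phase flag.
#' @return A `CultureState`.
#' @examples
#' cultureState(s = 4.25, b_ntc = 2e-3)  # 1e6 cells/ml at 2e-12 g dw/cell
#' @export
cultureState <- function(t = 0, s = 4.25, b_ntc = 0, b_tc = 0,
                         in_stationary = FALSE) {
  new("CultureState", t = t, s = s, b_ntc = b_ntc, b_tc = b_tc,
      in_stationary = in_stationary)
}

setMethod("show", "CultureState", function(object) {
  cat(sprintf(
    "CultureState: t = %g h, s = %g mg/ml, b_ntc = %g, b_tc = %g mg/ml%s\n",
    object@t, object@s, object@b_ntc, object@b_tc,
    if (object@in_stationary) " [stationary]" else ""))
  invisible(NULL)
})

#' Serial-transfer protocol
#'
#' Either a fixed per-batch duration (`batch_hours`) or a
#' stop-at-stationary-plus-hold rule (`batch_hours = NA`, then each batch runs
#' until stationary entry plus `hold_hours`, capped at `max_hours`).
#'
#' @slot n_batches number of successive batch cultures.
#' @slot batch_hours fixed batch duration, h, or `NA` for the hold rule.
#' @slot hold_hours hours held after stationary entry when `batch_hours` is `NA`.
#' @slot max_hours safety cap on a single batch, h.
#' @slot dilution volume fraction transferred between batches.
#' @export
setClass("SerialProtocol",
  representation(n_batches = "numeric", batch_hours = "numeric",
                 hold_hours = "numeric", max_hours = "numeric",
                 dilution = "numeric")
)

setValidity("SerialProtocol", function(object) {
  msg <- character(0)
  if (length(object@n_batches) != 1L || object@n_batches < 1)
    msg <- c(msg, "n_batches must be >= 1")
  if (!is.na(object@batch_hours) && object@batch_hours <= 0)
    msg <- c(msg, "batch_hours must be > 0 (or NA)")
  if (object@hold_hours < 0) msg <- c(msg, "hold_hours must be >= 0")
  if (object@max_hours <= 0) msg <- c(msg, "max_hours must be > 0")
  if (object@dilution <= 0 || object@dilution > 1)
    msg <- c(msg, "dilution must be in (0, 1]")
  if (length(msg)) msg else TRUE
})

#' Construct a serial-transfer protocol
#'
#' @param n_batches number of batches.
#' @param batch_hours fixed batch duration in h, or `NA` to run each batch to
#'   stationary entry plus `hold_hours`.
#' @param hold_hours post-stationary hold, h.
#' @param max_hours cap on a single batch, h.
#' @param dilution transfer volume fraction (default 1:1000).
#' @return A `SerialProtocol`.
#' @examples
#' serialProtocol(n_batches = 2)
#' @export
serialProtocol <- function(n_batches = 2, batch_hours = NA_real_,
                           hold_hours = 2, max_hours = 72,
                           dilution = 1 / 1000) {
  new("SerialProtocol", n_batches = n_batches, batch_hours = batch_hours,
      hold_hours = hold_hours, max_hours = max_hours, dilution = dilution)
}

setMethod("show", "SerialProtocol", function(object) {
  dur <- if (is.na(object@batch_hours))
    sprintf("to stationary + %g h (max %g h)", object@hold_hours, object@max_hours)
  else sprintf("%g h each", object@batch_hours)
  cat(sprintf("SerialProtocol: %g batches, %s, dilution %g\n",
              object@n_batches, dur, object@dilution))
  invisible(NULL)
})

#' Time course of one batch culture
#'
#' A fixed-grid time series of substrate and subpopulation biomass, with
#' derived columns for total biomass, total cell density and the tc biomass
#' fraction. Created by [simulateBatch()], [simulateSerial()] or
#' [agentSimulate()].
#'
#' @slot data `data.frame` with columns `t_h`, `s_mg_ml`, `b_ntc`, `b_tc`,
#'   `b_total`, `cells_total`, `tc_fraction`.
#' @slot params the `PopModelParams` used.
#' @slot stationary_time time of stationary entry within the batch, h
#'   (`NA` if never reached).
#' @slot stationary_state empty list, or a list holding the `CultureState`
#'   immediately after the stationary switch was applied.
#' @slot batch batch index within a serial experiment (1 for a single batch).
#' @export
setClass("Trajectory",
  representation(data = "data.frame", params = "PopModelParams",
                 stationary_time = "numeric", stationary_state = "list",
                 batch = "numeric")
)

setValidity("Trajectory", function(object) {
  d <- object@data
  need <- c("t_h", "s_mg_ml", "b_ntc", "b_tc", "b_total", "cells_total",
            "tc_fraction")
  if (!all(need %in% names(d)))
    return(paste("data must have columns", paste(need, collapse = ", ")))
  if (nrow(d) >= 2 && any(diff(d$t_h) <= 0))
    return("time must be strictly increasing")
  if (any(d$s_mg_ml < -1e-12) || any(d$b_ntc < -1e-12) || any(d$b_tc < -1e-12))
    return("substrate and biomass must be non-negative")
  if (any(d$tc_fraction < -1e-12 | d$tc_fraction > 1 + 1e-12, na.rm = TRUE))
    return("tc_fraction must lie in [0, 1]")
  TRUE
})

setMethod("show", "Trajectory", function(object) {
  d <- object@data
  cat(sprintf("Trajectory: batch %d, %d points over %g h\n",
              as.integer(object@batch), nrow(d), max(d$t_h) - min(d$t_h)))
  if (!is.na(object@stationary_time))
    cat(sprintf("  stationary entry at t = %.3f h (tc fraction %.4g)\n",
                object@stationary_time,
                stats::approx(d$t_h, d$tc_fraction,
                              xout = object@stationary_time, rule = 2)$y))
  cat(sprintf("  final: %.4g mg/ml biomass, %.4g cells/ml, tc fraction %.4g\n",
              d$b_total[nrow(d)], d$cells_total[nrow(d)],
              d$tc_fraction[nrow(d)]))
  invisible(NULL)
})

#' @describeIn Trajectory-class extract the time-course table.
#' @param x a `Trajectory`.
#' @param row.names,optional,... passed on conventionally; ignored.
#' @export
setMethod("as.data.frame", "Trajectory",
          function(x, row.names = NULL, optional = FALSE, ...) x@data)

#' @describeIn Trajectory-class the time of stationary entry (h), `NA` if the
#'   batch never reached it.
#' @export
stationaryTime <- function(x) {
  stopifnot(is(x, "Trajectory"))
  x@stationary_time
}

#' @describeIn Trajectory-class the `CultureState` immediately after the
#'   stationary switch (or `NULL` if stationary phase was never reached).
#' @export
stationaryEntry <- function(x) {
  stopifnot(is(x, "Trajectory"))
  if (length(x@stationary_state)) x@stationary_state[[1]] else NULL
}

#' @describeIn Trajectory-class the culture state at the final grid point.
#' @export
finalState <- function(x) {
  stopifnot(is(x, "Trajectory"))
  d <- x@data
  n <- nrow(d)
  cultureState(t = d$t_h[n], s = max(d$s_mg_ml[n], 0),
               b_ntc = max(d$b_ntc[n], 0), b_tc = max(d$b_tc[n], 0),
               in_stationary = !is.na(x@stationary_time))
}
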