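# Calling reporter-positive subpopulation fractions from per-cell
# fluorescence intensity tables, with detection-limit accounting. Input
# begins at per-cell intensities (no image segmentation here).

#' @importFrom mclust Mclust mclustBIC
NULL

#' Reporter-calling configuration
#'
#' Exactly one threshold strategy is active:
#' * `"background"` — kernel-density mode of the (assumed dominant) off
#'   component on the log scale, plus `k` times the off-component spread
#'   estimated from the values below the mode. Appropriate when positives
#'   are a minority.
#' * `"mixture"` — two-component Gaussian mixture on log intensity (EM via
#'   \pkg{mclust}); the threshold is the equal-posterior boundary between the
#'   components. Works at any on-fraction provided the components separate.
#' * `"fixed"` — a user-supplied intensity threshold.
#'
#' Intensities are normalised to a reference exposure (`ref_exposure_ms`,
#' default 20 ms) by per-ms scaling before thresholding.
#'
#' @slot strategy one of `"background"`, `"mixture"`, `"fixed"`.
#' @slot k multiplier on the off-component spread (background strategy).
#' @slot threshold fixed intensity threshold (fixed strategy), on the
#'   normalised scale.
#' @slot ref_exposure_ms reference exposure time, ms.
#' @export
setClass("ReporterCallConfig",
  representation(strategy = "character", k = "numeric", threshold = "numeric",
                 ref_exposure_ms = "numeric")
)

setValidity("ReporterCallConfig", function(object) {
  msg <- character(0)
  if (!object@strategy %in% c("background", "mixture", "fixed"))
    msg <- c(msg, "strategy must be 'background', 'mixture' or 'fixed'")
  if (object@strategy == "fixed" && !is.finite(object@threshold))
    msg <- c(msg, "fixed strategy needs a finite threshold")
  if (object@k <= 0) msg <- c(msg, "k must be > 0")
  if (object@ref_exposure_ms <= 0) msg <- c(msg, "ref_exposure_ms must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a reporter-calling configuration
#'
#' @param strategy threshold strategy, see [ReporterCallConfig-class].
#' @param k spread multiplier for the background strategy.
#' @param threshold fixed threshold (normalised intensity units).
#' @param ref_exposure_ms reference exposure, ms.
#' @return A `ReporterCallConfig`.
#' @examples
#' reporterCallConfig()                       # background mode + 3 sd
#' reporterCallConfig("fixed", threshold = 500)
#' @export
reporterCallConfig <- function(strategy = c("background", "mixture", "fixed"),
                               k = 3, threshold = NA_real_,
                               ref_exposure_ms = 20) {
  strategy <- match.arg(strategy)
  new("ReporterCallConfig", strategy = strategy, k = k, threshold = threshold,
      ref_exposure_ms = ref_exposure_ms)
}

setMethod("show", "ReporterCallConfig", function(object) {
  cat(sprintf("ReporterCallConfig: strategy = %s", object@strategy))
  if (object@strategy == "background") cat(sprintf(" (mode + %g sd)", object@k))
  if (object@strategy == "fixed") cat(sprintf(" (threshold %g)", object@threshold))
  cat(sprintf(", reference exposure %g ms\n", object@ref_exposure_ms))
  invisible(NULL)
})

.normalizeIntensity <- function(intensity, exposure_ms, ref_exposure_ms) {
  if (is.null(exposure_ms)) return(intensity)
  intensity / exposure_ms * ref_exposure_ms
}

## threshold on the normalised intensity scale
.estimateThreshold <- function(x, cfg) {
  if (cfg@strategy == "fixed") return(cfg@threshold)
  pos <- x[x > 0]
  eps <- if (length(pos)) min(pos) * 1e-3 else 1e-9
  y <- log(x + eps)
  if (cfg@strategy == "background") {
    d <- density(y)
    mode_y <- d$x[which.max(d$y)]
    lower <- y[y <= mode_y]
    sd_off <- sqrt(mean((mode_y - lower)^2))
    if (!is.finite(sd_off) || sd_off == 0) sd_off <- stats::mad(y)
    return(exp(mode_y + cfg@k * sd_off) - eps)
  }
  ## mixture: 2-component Gaussian EM on log intensity
  fit <- Mclust(y, G = 2, modelNames = c("E", "V"), verbose = FALSE)
  if (is.null(fit)) stop("mixture fit failed; try another threshold strategy")
  mu <- fit$parameters$mean
  sg <- sqrt(fit$parameters$variance$sigmasq)
  if (length(sg) == 1) sg <- rep(sg, 2)
  pr <- fit$parameters$pro
  hi <- which.max(mu); lo <- which.min(mu)
  if (abs(mu[hi] - mu[lo]) < 1e-8) return(exp(mu[hi]) - eps)
  f <- function(t) pr[lo] * stats::dnorm(t, mu[lo], sg[lo]) -
    pr[hi] * stats::dnorm(t, mu[hi], sg[hi])
  bound <- tryCatch(stats::uniroot(f, c(mu[lo], mu[hi]))$root,
                    error = function(e) (mu[lo] + mu[hi]) / 2)
  exp(bound) - eps
}

#' Wilson score confidence interval for a proportion
#'
#' @param x number of successes.
#' @param n number of trials.
#' @param conf confidence level.
#' @return `c(lower, upper)`.
#' @examples
#' wilsonCI(30, 1000)
#' @export
wilsonCI <- function(x, n, conf = 0.95) {
  if (n < 1 || x < 0 || x > n) stop("need 0 <= x <= n, n >= 1")
  z <- stats::qnorm(1 - (1 - conf) / 2)
  p <- x / n
  den <- 1 + z^2 / n
  ctr <- (p + z^2 / (2 * n)) / den
  hw <- z * sqrt(p * (1 - p) / n + z^2 / (4 * n^2)) / den
  c(lower = max(0, ctr - hw), upper = min(1, ctr + hw))
}

.checkIntensityTable <- function(table) {
  need <- c("cell_id", "intensity")
  if (!is.data.frame(table) || !all(need %in% names(table)))
    stop("table must be a data.frame with columns cell_id and intensity ",
         "(optionally channel, exposure_ms)")
  if (nrow(table) < 1) stop("empty intensity table")
  if (any(table$intensity < 0)) stop("intensities must be >= 0")
  invisible(table)
}

#' Fraction of reporter-positive cells
#'
#' Calls each cell positive when its exposure-normalised intensity exceeds
#' the configured threshold, and returns the positive fraction with a 95%
#' Wilson score interval.
#'
#' @param table `data.frame` with columns `cell_id`, `intensity` and
#'   optionally `channel` and `exposure_ms`.
#' @param cfg a [ReporterCallConfig-class].
#' @param channel restrict to one channel label (required when several are
#'   present).
#' @param conf confidence level of the interval.
#' @return `list(fraction, n_positive, n, ci, threshold)`.
#' @examples
#' tab <- data.frame(cell_id = 1:100, intensity = c(rep(10, 97), rep(1e4, 3)))
#' callPositiveFraction(tab, reporterCallConfig("fixed", threshold = 100))
#' @export
callPositiveFraction <- function(table, cfg = reporterCallConfig(),
                                 channel = NULL, conf = 0.95) {
  .checkIntensityTable(table)
  stopifnot(is(cfg, "ReporterCallConfig"))
  validObject(cfg)
  if (!is.null(channel)) {
    table <- table[table$channel == channel, , drop = FALSE]
    if (nrow(table) < 1) stop("no cells for channel ", channel)
  } else if ("channel" %in% names(table) &&
             length(unique(table$channel)) > 1) {
    stop("several channels present: pick one with `channel`")
  }
  if (anyDuplicated(table$cell_id))
    stop("one intensity per (cell, channel) required")
  x <- .normalizeIntensity(table$intensity,
                           if ("exposure_ms" %in% names(table))
                             table$exposure_ms else NULL,
                           cfg@ref_exposure_ms)
  thr <- .estimateThreshold(x, cfg)
  npos <- sum(x > thr)
  n <- length(x)
  list(fraction = npos / n, n_positive = npos, n = n,
       ci = wilsonCI(npos, n, conf), threshold = thr)
}

#' Quadrant fractions of a dual-reporter experiment
#'
#' Splits matched cells by positivity in two channels (e.g. GFP and mCherry)
#' and returns the fractions of the four quadrants, in the order
#' `-/-`, `+/-`, `-/+`, `+/+` (first sign: channel 1). The fractions sum to
#' 1 exactly.
#'
#' @param ch1,ch2 per-channel intensities: named numeric vectors (names =
#'   cell ids) or data.frames with `cell_id`, `intensity`, optional
#'   `exposure_ms`. Cell ids must match one-to-one.
#' @param cfg a single [ReporterCallConfig-class] used for both channels, or
#'   a list of two configs.
#' @return `list(fractions, counts, n, thresholds)`.
#' @examples
#' g <- setNames(c(10, 10, 5e3, 6e3), paste0("c", 1:4))
#' m <- setNames(c(12, 4e3, 8, 7e3), paste0("c", 1:4))
#' dualQuadrantFractions(g, m, reporterCallConfig("fixed", threshold = 100))
#' @export
dualQuadrantFractions <- function(ch1, ch2, cfg = reporterCallConfig()) {
  as_tab <- function(v, nm) {
    if (is.data.frame(v)) return(.checkIntensityTable(v))
    if (is.null(names(v))) stop(nm, ": intensities need cell ids (names)")
    data.frame(cell_id = names(v), intensity = unname(v))
  }
  t1 <- as_tab(ch1, "ch1"); t2 <- as_tab(ch2, "ch2")
  if (anyDuplicated(t1$cell_id) || anyDuplicated(t2$cell_id))
    stop("duplicate cell ids within a channel")
  if (!setequal(t1$cell_id, t2$cell_id))
    stop("unmatched cell ids between the two channels")
  t2 <- t2[match(t1$cell_id, t2$cell_id), , drop = FALSE]
  cfgs <- if (is.list(cfg)) cfg else list(cfg, cfg)
  if (length(cfgs) != 2) stop("cfg must be one config or a list of two")
  call1 <- callPositiveFraction(t1, cfgs[[1]])
  call2 <- callPositiveFraction(t2, cfgs[[2]])
  x1 <- .normalizeIntensity(t1$intensity,
                            t1[["exposure_ms"]], cfgs[[1]]@ref_exposure_ms)
  x2 <- .normalizeIntensity(t2$intensity,
                            t2[["exposure_ms"]], cfgs[[2]]@ref_exposure_ms)
  p1 <- x1 > call1$threshold
  p2 <- x2 > call2$threshold
  counts <- c(`-/-` = sum(!p1 & !p2), `+/-` = sum(p1 & !p2),
              `-/+` = sum(!p1 & p2), `+/+` = sum(p1 & p2))
  n <- length(p1)
  list(fractions = counts / n, counts = counts, n = n,
       thresholds = c(ch1 = call1$threshold, ch2 = call2$threshold))
}

#' Microscopy detection limit for a rare subpopulation
#'
#' With `n` cells inspected, the smallest observable positive fraction is one
#' positive cell, `1/n` (the reported floor of roughly 1 fluorescent cell
#' among 1,000-10,000). When zero positives are observed, the one-sided 95%
#' upper bound on the true fraction is the rule-of-three bound `3/n`.
#'
#' @param n_cells number of cells inspected (>= 1).
#' @return `list(floor, upper95_zero, n)`.
#' @examples
#' detectionLimit(1000)
#' @export
detectionLimit <- function(n_cells) {
  if (n_cells < 1) stop("n_cells must be >= 1")
  list(floor = 1 / n_cells, upper95_zero = 3 / n_cells, n = n_cells)
}
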