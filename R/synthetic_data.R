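# Seeded generators producing every input the analysis modules consume, each
# returning its ground truth alongside the data so recovery tests key off the
# truth rather than hard-coded numbers.

#' Evaluate code under a fixed RNG seed
#'
#' Sets the seed, evaluates `code`, and restores the previous global RNG
#' state, so seeded generators leave no hidden state behind.
#'
#' @param seed integer seed.
#' @param code expression to evaluate.
#' @return The value of `code`.
#' @export
withSeed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed))
    stop("seed must be a single integer")
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_old) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  code
}

#' Generate a noisy growth curve
#'
#' Simulates a batch culture with [simulateBatch()] and turns total biomass
#' into a turbidity reading (`od_scale` proportionality) with multiplicative
#' lognormal measurement noise of standard deviation `noise_sd_log` on the
#' natural-log scale.
#'
#' @param seed integer seed.
#' @param params a [PopModelParams-class] (use `p_tc = 0.5` for the
#'   derepressed scenario).
#' @param inoculum_cells_per_ml starting cell density.
#' @param duration simulated time, h.
#' @param dt_sample sampling interval of the turbidity readings, h.
#' @param noise_sd_log sd of the log-scale measurement noise (0 = noise-free).
#' @param od_scale turbidity units per mg/ml biomass.
#' @return `list(data, truth)`: `data` has columns `time_h`, `od`; `truth`
#'   carries the parameters, the noise-free trajectory and the seed.
#' @export
genGrowthCurve <- function(seed, params = popModelParams(),
                           inoculum_cells_per_ml = 1e6, duration = 24,
                           dt_sample = 0.25, noise_sd_log = 0.02,
                           od_scale = 1) {
  init <- cultureState(s = params@c_total,
                       b_ntc = inoculum_cells_per_ml * params@cell_dw * 1e3)
  traj <- simulateBatch(params, init, duration, dt_out = dt_sample)
  d <- traj@data
  withSeed(seed, {
    noise <- if (noise_sd_log > 0)
      exp(rnorm(nrow(d), 0, noise_sd_log)) else rep(1, nrow(d))
    data <- data.frame(time_h = d$t_h, od = od_scale * d$b_total * noise)
    list(data = data,
         truth = list(params = params, trajectory = traj,
                      od_scale = od_scale, noise_sd_log = noise_sd_log,
                      seed = seed))
  })
}

#' Generate a replicated CFU dataset
#'
#' Draws lognormal replicate counts around stated geometric means: plating
#' scatter is multiplicative, so replicates are
#' `10^(log10(geomean) + N(0, sd_log10))`.
#'
#' @param seed integer seed.
#' @param groups `data.frame` with columns `strain`, `medium`,
#'   `geomean_cfu_per_ml` (> 0), one row per group.
#' @param n_replicates replicates per group (study convention: biological
#'   triplicates).
#' @param sd_log10 replicate scatter on the log10 scale (0 = exact means).
#' @return `list(data, truth)`: `data` is a CFU table (`strain`, `medium`,
#'   `replicate`, `cfu_per_ml`).
#' @export
genCfuDataset <- function(seed, groups, n_replicates = 3, sd_log10 = 0.2) {
  need <- c("strain", "medium", "geomean_cfu_per_ml")
  if (!is.data.frame(groups) || !all(need %in% names(groups)))
    stop("groups must have columns ", paste(need, collapse = ", "))
  if (any(groups$geomean_cfu_per_ml <= 0)) stop("geometric means must be > 0")
  if (sd_log10 < 0) stop("sd_log10 must be >= 0")
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(groups)), function(i) {
      lg <- log10(groups$geomean_cfu_per_ml[i]) +
        rnorm(n_replicates, 0, sd_log10)
      data.frame(strain = groups$strain[i], medium = groups$medium[i],
                 replicate = seq_len(n_replicates), cfu_per_ml = 10^lg)
    })
    list(data = do.call(rbind, rows),
         truth = list(groups = groups, n_replicates = n_replicates,
                      sd_log10 = sd_log10, seed = seed))
  })
}

#' Generate a transfer assay (donor and transconjugant counts)
#'
#' Lognormal replicate scatter around per-strain geometric means of donor and
#' transconjugant CFU/ml; the true transfer frequency of each strain is the
#' ratio of the geometric means.
#'
#' @param seed integer seed.
#' @param strains `data.frame` with columns `strain`,
#'   `donor_geomean_cfu_per_ml`, `transconjugant_geomean_cfu_per_ml`.
#' @param n_replicates replicates per strain.
#' @param sd_log10 scatter on the log10 scale.
#' @return `list(data, truth)`: `data` has one row per replicate with
#'   `strain`, `replicate`, `donor_cfu_per_ml`, `transconjugant_cfu_per_ml`.
#' @export
genTransferAssay <- function(seed, strains, n_replicates = 3,
                             sd_log10 = 0.2) {
  need <- c("strain", "donor_geomean_cfu_per_ml",
            "transconjugant_geomean_cfu_per_ml")
  if (!is.data.frame(strains) || !all(need %in% names(strains)))
    stop("strains must have columns ", paste(need, collapse = ", "))
  withSeed(seed, {
    rows <- lapply(seq_len(nrow(strains)), function(i) {
      don <- 10^(log10(strains$donor_geomean_cfu_per_ml[i]) +
                   rnorm(n_replicates, 0, sd_log10))
      trc <- 10^(log10(strains$transconjugant_geomean_cfu_per_ml[i]) +
                   rnorm(n_replicates, 0, sd_log10))
      data.frame(strain = strains$strain[i], replicate = seq_len(n_replicates),
                 donor_cfu_per_ml = don, transconjugant_cfu_per_ml = trc)
    })
    truth_freq <- strains$transconjugant_geomean_cfu_per_ml /
      strains$donor_geomean_cfu_per_ml
    list(data = do.call(rbind, rows),
         truth = list(strains = strains,
                      frequency = setNames(truth_freq, strains$strain),
                      n_replicates = n_replicates, sd_log10 = sd_log10,
                      seed = seed))
  })
}

#' Generate a single-cell intensity table
#'
#' A two-component (off/on) lognormal intensity mixture at a true on-fraction
#' in the 0.001-1 range, mimicking single-cell reporter fluorescence at a
#' fixed exposure. On-cell identities are returned as ground truth.
#'
#' @param seed integer seed.
#' @param n number of cells.
#' @param on_fraction true probability that a cell is in the on state.
#' @param off_meanlog,off_sdlog log-scale parameters of the off component.
#' @param on_meanlog,on_sdlog log-scale parameters of the on component.
#' @param exposure_ms exposure time recorded for every cell, ms.
#' @param channel channel label.
#' @return `list(data, truth)`: `data` has columns `cell_id`, `channel`,
#'   `intensity`, `exposure_ms`; `truth$on` is the logical on-state vector
#'   and `truth$n_on` its count.
#' @export
genCellIntensities <- function(seed, n = 1000, on_fraction = 0.03,
                               off_meanlog = log(100), off_sdlog = 0.3,
                               on_meanlog = log(5000), on_sdlog = 0.4,
                               exposure_ms = 20, channel = "mcherry") {
  if (on_fraction < 0 || on_fraction > 1) stop("on_fraction must be in [0, 1]")
  if (n < 1) stop("n must be >= 1")
  withSeed(seed, {
    on <- runif(n) < on_fraction
    intensity <- numeric(n)
    intensity[!on] <- rlnorm(sum(!on), off_meanlog, off_sdlog)
    intensity[on] <- rlnorm(sum(on), on_meanlog, on_sdlog)
    data <- data.frame(cell_id = sprintf("cell%05d", seq_len(n)),
                       channel = channel, intensity = intensity,
                       exposure_ms = exposure_ms)
    list(data = data,
         truth = list(on = on, n_on = sum(on), on_fraction = on_fraction,
                      seed = seed))
  })
}

## one planted constellation (or decoy) on its own contig; the decoy violates
## exactly one screening criterion
.plantConstellation <- function(genome_id, contig_id,
                                violation = c("none", "evalue", "identity",
                                              "int_window", "core_window")) {
  violation <- match.arg(violation)
  anchor_start <- round(runif(1, 5e4, 1.5e5))
  anchor_end <- anchor_start + 899
  evalue <- if (violation == "evalue") 1e-12 else 1e-40
  identity_core <- if (violation == "identity") 70 else round(runif(1, 85, 95))
  d_int <- if (violation == "int_window") 3e4 else round(runif(1, 6e3, 1.8e4))
  d_core <- if (violation == "core_window") 1.5e5 else
    round(runif(1, max(2.2e4, d_int + 5e3), 7.5e4))
  int_start <- anchor_end + d_int
  int_end <- int_start + 1199
  core_start <- anchor_end + d_core
  core_end <- core_start + round(runif(1, 1.2e4, 2.5e4))
  trna_start <- int_end + round(runif(1, 100, 1500))
  trna_end <- trna_start + 75
  feats <- data.frame(
    genome_id = genome_id, contig_id = contig_id,
    kind = c("tciR_hit", "integrase", "tRNA_gly", "core_block"),
    start = c(anchor_start, int_start, trna_start, core_start),
    end = c(anchor_end, int_end, trna_end, core_end),
    strand = sample(c("+", "-"), 4, replace = TRUE),
    evalue = c(evalue, NA, NA, NA),
    pct_identity = c(98, NA, NA, identity_core))
  o <- order(feats$start)
  if (any(feats$start[o][-1] <= feats$end[o][-4]))
    stop("overlapping planted features")   # defensive; layout avoids overlap
  list(features = feats,
       truth = data.frame(genome_id = genome_id, contig_id = contig_id,
                          anchor_start = anchor_start, anchor_end = anchor_end,
                          is_plant = violation == "none",
                          violation = violation))
}

#' Generate a synthetic genome feature table with planted ICE constellations
#'
#' Plants complete anchor/integrase/tRNA-Gly/core-block constellations
#' (which the default screen must call) and, optionally, decoy
#' constellations each violating exactly one screening criterion: anchor
#' E-value 1e-12 (above the 1e-15 cutoff), core identity 70% (below 75%),
#' integrase 30 kb from the anchor (outside 5-20 kb), or core 150 kb away
#' (outside 1-100 kb). Each constellation sits on its own contig.
#'
#' @param seed integer seed.
#' @param n_plants number of complete constellations.
#' @param decoys character vector of decoy violations, any of `"evalue"`,
#'   `"identity"`, `"int_window"`, `"core_window"` (repeats allowed).
#' @return `list(data, truth)`: `data` is the feature table (rows shuffled),
#'   `truth` one row per constellation with `is_plant` and the violation.
#' @export
genFeatureTable <- function(seed, n_plants = 1,
                            decoys = c("evalue", "identity", "int_window",
                                       "core_window")) {
  if (n_plants < 0) stop("n_plants must be >= 0")
  if (length(decoys))
    stopifnot(all(decoys %in% c("evalue", "identity", "int_window",
                                "core_window")))
  withSeed(seed, {
    spec <- c(rep("none", n_plants), decoys)
    if (!length(spec))
      return(list(data = validateFeatureTable(
               data.frame(genome_id = character(0), contig_id = character(0),
                          kind = character(0), start = numeric(0),
                          end = numeric(0))),
             truth = data.frame()))
    pieces <- lapply(seq_along(spec), function(i)
      .plantConstellation(genome_id = sprintf("genome%02d", i),
                          contig_id = sprintf("contig%02d", i),
                          violation = spec[i]))
    feats <- do.call(rbind, lapply(pieces, `[[`, "features"))
    truth <- do.call(rbind, lapply(pieces, `[[`, "truth"))
    feats <- feats[sample.int(nrow(feats)), , drop = FALSE]
    rownames(feats) <- NULL
    list(data = validateFeatureTable(feats), truth = truth)
  })
}
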