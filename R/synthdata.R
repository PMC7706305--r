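# Synthetic heat-stress phenotyping experiment.
#
# The generator emulates the factorial design of a rosette heat-stress
# screen: 2 genotypes (WT, hsp101) x 4 treatments (control and 3/6/9 h at
# 45 C) x n replicates, imaged daily from one day before stress (DAS -1)
# to 7 days after. The latent dynamics are:
#  - logistic rosette growth with a multiplicative growth-rate penalty
#    proportional to stress hours, applied from the stress day onward;
#  - an acute projected-area shrink on the stress day (wilting/leaf
#    movement) that decays over two days;
#  - an Fv/Fm dip on the stress day whose deficit decays linearly to zero
#    after a per-genotype delay (WT 1 day, hsp101 2 days by default);
#  - loss of photochemical quenching (qP) on the stress day, modulated by a
#    per-plant latent tolerance that also modulates the post-stress growth
#    penalty, coupling early quenching retention to later rosette area;
#  - leaf-temperature elevation proportional to stress hours, decaying daily;
#  - Bernoulli mortality on the stress day under the 9 h treatment only, and
#    a small probability of plants that never grow;
#  - morphology responses: reduced leaf aspect ratio (slenderness) and
#    increased leaf-length irregularity (compactness) under stress.
# All hsp101-specific extras are scaled by a per-treatment genotype-gap
# factor, maximal for the 6 h treatment.

#' Build the factorial experiment design
#'
#' Creates the full genotype x treatment x replicate plant registry, placed
#' on trays of 20 positions with the two genotypes interleaved within each
#' treatment block (physical positions are shuffled within each tray).
#'
#' @param nReps biological replicates per genotype per treatment (>= 1).
#' @param seed integer seed (used only for the within-tray position shuffle).
#' @param days imaging days as DAS; default -1..7.
#' @param protocol a [LightProtocol-class]; default six-step light curve.
#' @return an [ExperimentDesign-class]. With `nReps = 20` this is 160 plants
#'   on 8 trays.
#' @examples
#' d <- buildDesign(20, seed = 1)
#' nrow(plants(d))  # 160
#' @export
buildDesign <- function(nReps, seed = 1L,
                        days = -1:7, protocol = LightProtocol()) {
  if (length(nReps) != 1L || !is.finite(nReps) || nReps < 1)
    stop("nReps must be a positive integer")
  nReps <- as.integer(nReps)
  rows <- expand.grid(genotype = GENOTYPES, replicate = seq_len(nReps),
                      treatment = TREATMENTS, stringsAsFactors = FALSE,
                      KEEP.OUT.ATTRS = FALSE)
  # treatment blocks, genotypes interleaved -> trays of 20 get an even split
  rows <- rows[order(match(rows$treatment, TREATMENTS)), ]
  n <- nrow(rows)
  rows$tray <- (seq_len(n) - 1L) %/% 20L + 1L
  rows$position <- (seq_len(n) - 1L) %% 20L + 1L
  rows$position <- withSeed(seed, {
    unsplit(lapply(split(rows$position, rows$tray), sample), rows$tray)
  })
  rows$plant_id <- sprintf("%s_%s_r%02d", rows$genotype, rows$treatment,
                           rows$replicate)
  rownames(rows) <- NULL
  new("ExperimentDesign",
      plants = rows[, c("plant_id", "genotype", "treatment", "tray",
                        "position", "replicate")],
      days = as.integer(days), protocol = protocol)
}

# Per-day deficit-recovery weight: 1 on the stress day, decaying linearly to
# 0 after `delay` days; 0 before the stress day. Vectorized over plants.
recoveryWeight <- function(das, delay) {
  ifelse(das < 0, 0, pmax(0, 1 - das / pmax(delay, .Machine$double.eps)))
}

#' Simulate the latent plant-day states of an experiment
#'
#' Draws per-plant latent variables (tolerance, baselines, mortality) and
#' evolves every plant through the imaging days. Dead plants emit no states
#' from their death day onward; plants that never grow stay alive but tiny
#' and are flagged in the registry for the downstream exclusion filter.
#'
#' @param design an [ExperimentDesign-class].
#' @param params a [SimulationParams-class].
#' @param seed integer seed; the full output is deterministic given
#'   (design, params, seed).
#' @return a [SimulatedExperiment-class] whose `states` hold, per alive
#'   plant-day: `true_area_mm2`, `qymax_true`, `fm_factor`, `qp_retention`,
#'   `npq_retention`, `temp_offset_c`, `leaf_count`, `leaf_aspect`,
#'   `lobe_jitter`, `fm_plant` and `tolerance`.
#' @export
simulateExperiment <- function(design, params = SimulationParams(), seed = 1L) {
  stopifnot(is(design, "ExperimentDesign"), is(params, "SimulationParams"))
  validObject(design); validObject(params)
  p <- params
  reg <- plants(design)
  n <- nrow(reg)
  days <- sort(imagingDays(design))

  lat <- withSeed(childSeed(seed, 1), {
    data.frame(
      tolerance = stats::runif(n),
      area0 = p@initialArea * exp(stats::rnorm(n, 0, p@areaCV)),
      qybase = stats::rnorm(n, p@qymaxBaseline, p@qymaxPlantSD),
      fm_plant = exp(stats::rnorm(n, 0, p@fmPlantCV)),
      runt = stats::runif(n) < p@runtProbability,
      death_draw = stats::runif(n),
      leaf_count = pmax(4, round(p@leafCount + stats::rnorm(n, 0, 1)))
    )
  })
  reg <- cbind(reg, lat)
  reg$died <- reg$treatment == "HS9h" & reg$death_draw < p@deathProbability
  reg$death_draw <- NULL
  reg$excluded <- reg$died | reg$runt
  # runts: barely grow at all
  reg$area0[reg$runt] <- reg$area0[reg$runt] * 0.25

  hours <- stressHours(reg$treatment)
  gap <- unname(p@genotypeGap[reg$treatment])
  isH <- as.numeric(reg$genotype == "hsp101")
  tol <- reg$tolerance

  # growth-rate multiplier applied from DAS 0 onward
  pen <- p@growthPenaltyPerHour * hours *
    (1 + p@hsp101GrowthExtra * gap * isH) *
    (1 - p@toleranceGrowthCoupling * (tol - 0.5))
  growthMult <- clamp(1 - pen, 0, 1)
  rate <- p@growthRate * ifelse(reg$runt, 0.2, 1)

  # stress-day depressions
  dip <- p@qyDipPerHour * hours * (1 + p@hsp101DipExtra * gap * isH)
  delay <- unname(p@recoveryDelay[reg$genotype])
  fmDep <- pmin(p@fmDepressionCap,
                p@fmDepressionPerHour * hours * (1 + 0.3 * gap * isH))
  qpDrop0 <- p@qpDropPerHour * hours * (1 + p@hsp101QpExtra * gap * isH) *
    clamp(1.5 - p@toleranceQpCoupling * tol, 0, 2)
  qpRecDays <- pmax(1, hours / 3) + p@hsp101QpRecoveryExtra * gap * isH
  aspect <- p@leafAspect *
    clamp(1 - p@aspectDropPerHour * hours * (1 + p@hsp101MorphExtra * gap * isH),
          0.3, 1)
  jitterStressed <- p@lobeJitter *
    (1 + p@stressJitterBoost * hours / 9 * (1 + p@hsp101MorphExtra * gap * isH))

  # evolve areas day by day (Euler logistic, daily step)
  ndays <- length(days)
  A <- matrix(NA_real_, n, ndays)
  A[, 1] <- reg$area0
  for (j in seq_len(ndays - 1)) {
    das <- days[j]
    r <- rate * if (das >= 0) growthMult else 1
    A[, j + 1] <- A[, j] + r * A[, j] * (1 - A[, j] / p@carryingCapacity)
  }

  states <- do.call(rbind, lapply(seq_len(ndays), function(j) {
    das <- days[j]
    alive <- !(reg$died & das >= 0)
    shrink <- if (das < 0) rep(1, n) else
      1 - p@acuteAreaDropPerHour * hours * (1 + 0.3 * gap * isH) *
        pmax(0, 1 - das / 2)
    data.frame(
      plant_id = reg$plant_id, genotype = reg$genotype,
      treatment = reg$treatment, tray = reg$tray, position = reg$position,
      das = das, alive = alive,
      true_area_mm2 = A[, j] * shrink,
      qymax_true = pmax(0.05, reg$qybase -
        dip * recoveryWeight(rep(das, n), delay)),
      fm_factor = if (das < 0) rep(1, n) else 1 - fmDep * 0.5^das,
      qp_retention = clamp(1 - qpDrop0 * recoveryWeight(rep(das, n), qpRecDays),
                           0.05, 1),
      npq_retention = clamp(1 - p@npqDropFactor * qpDrop0 *
                              recoveryWeight(rep(das, n), qpRecDays), 0.05, 1),
      temp_offset_c = if (das < 0) rep(0, n) else
        p@tempOffsetPerHour * hours * p@tempDecayPerDay^das,
      leaf_count = reg$leaf_count,
      leaf_aspect = if (das < 0) rep(p@leafAspect, n) else aspect,
      lobe_jitter = if (das < 0) rep(p@lobeJitter, n) else jitterStressed,
      fm_plant = reg$fm_plant,
      tolerance = tol,
      stringsAsFactors = FALSE
    )[alive, ]
  }))
  rownames(states) <- NULL

  new("SimulatedExperiment", design = design, params = params,
      states = states,
      registry = reg[, c("plant_id", "genotype", "treatment", "tray",
                         "position", "replicate", "tolerance", "runt",
                         "died", "excluded")])
}

#' Render a parametric rosette mask for one plant-day state
#'
#' Draws the rosette as a centre disk plus `leaf_count` elliptic leaf lobes
#' with seeded angular and length jitter, then rescales the figure so that
#' its pixel area matches the state's true projected area to within a few
#' percent (well inside 5%). Leaf aspect ratio and length jitter come from
#' the state, so morphology traits respond to stress.
#'
#' @param state one row of the `states` table of a
#'   [SimulatedExperiment-class] (needs `true_area_mm2`, `leaf_count`,
#'   `leaf_aspect`, `lobe_jitter`).
#' @param grid integer (nrow, ncol) of the raster.
#' @param scale mm per pixel.
#' @param seed integer seed; identical state + seed gives a bit-identical
#'   raster.
#' @return a [RosetteMask-class].
#' @export
renderRosetteMask <- function(state, grid = c(224L, 224L), scale = 0.5,
                              seed = 1L) {
  targetPx <- state$true_area_mm2 / scale^2
  if (targetPx < 1) stop("target area below one pixel at this scale")
  nL <- max(1L, as.integer(state$leaf_count))
  aspect <- max(1, state$leaf_aspect)
  jit <- state$lobe_jitter
  nr <- as.integer(grid[1]); nc <- as.integer(grid[2])
  cx <- (nr + 1) / 2; cy <- (nc + 1) / 2

  draws <- withSeed(seed, list(
    ang = 2 * pi * (seq_len(nL) - 1) / nL + stats::rnorm(nL, 0, 0.12),
    len = clamp(1 - jit * abs(stats::rnorm(nL)), 0.35, 1)
  ))

  xs <- matrix(rep(seq_len(nr), nc), nr, nc) - cx
  ys <- matrix(rep(seq_len(nc), each = nr), nr, nc) - cy

  render <- function(R) {
    mask <- xs^2 + ys^2 <= (0.25 * R)^2   # centre disk
    off <- 0.5 * (1 - 1 / nL)             # lobe centre offset fraction
    for (i in seq_len(nL)) {
      a <- 0.5 * R * draws$len[i]
      b <- max(1, a / aspect)
      d <- 2 * a * off
      ca <- cos(draws$ang[i]); sa <- sin(draws$ang[i])
      u <- ca * xs + sa * ys - d
      v <- -sa * xs + ca * ys
      mask <- mask | ((u / a)^2 + (v / b)^2 <= 1)
    }
    mask
  }

  R <- sqrt(targetPx)          # initial guess; refined below
  for (it in 1:3) {
    if ((0.5 * R) * (1 + 2 * 0.5 * (1 - 1 / nL)) + 2 > min(nr, nc) / 2)
      stop("render-overflow: rosette exceeds grid at this scale")
    mask <- render(R)
    got <- sum(mask)
    if (abs(got - targetPx) / targetPx < 0.01) break
    R <- R * sqrt(targetPx / max(got, 1))
  }
  RosetteMask(mask, scale)
}

#' Simulate one raw fluorescence light curve
#'
#' Generates the dark-adapted pair (F0, Fm) and the per-step light-adapted
#' triplets (F0', Ft', Fm') implied by the plant's latent state: Fm carries
#' the plant level and the stress-day depression; F0 follows from the true
#' Fv/Fm; Fm' declines with actinic intensity through a saturating NPQ
#' response; Ft' is placed between F0' and Fm' by the photochemical
#' quenching coefficient qP, whose stress-day retention carries the latent
#' tolerance signal. Multiplicative Gaussian noise is added per curve and
#' per signal; the per-step ordering (Fm' > Ft' >= F0') and the
#' monotone decline of Fm' across steps are enforced after noise.
#'
#' @param state one row of the `states` table (needs `qymax_true`,
#'   `fm_factor`, `fm_plant`, `qp_retention`, `npq_retention`).
#' @param protocol a [LightProtocol-class].
#' @param params a [SimulationParams-class].
#' @param seed integer seed.
#' @return a [RawFluorescence-class].
#' @export
simulateFluorescenceDay <- function(state, protocol = LightProtocol(),
                                    params = SimulationParams(), seed = 1L) {
  p <- params
  I <- protocol@actinicIntensities
  Fm <- p@fmBaseline * state$fm_plant * state$fm_factor
  F0 <- Fm * (1 - state$qymax_true)
  npq <- p@npqMax * I / (I + p@npqHalf) * state$npq_retention
  Fmp <- Fm / (1 + npq)
  F0p <- F0 * Fmp / Fm
  qp <- 1 / (1 + I / p@qpHalf) * state$qp_retention
  Ftp <- Fmp - qp * (Fmp - F0p)

  noisy <- withSeed(seed, {
    curve <- exp(stats::rnorm(1, 0, p@curveNoiseCV))
    sig <- function(x) x * curve * exp(stats::rnorm(length(x), 0, p@signalNoiseCV))
    list(F0 = sig(F0), Fm = sig(Fm), F0p = sig(F0p), Ftp = sig(Ftp),
         Fmp = sig(Fmp))
  })
  F0 <- noisy$F0; Fm <- noisy$Fm
  F0 <- min(F0, 0.98 * Fm)
  Fmp <- noisy$Fmp
  for (k in seq_along(Fmp)[-1]) Fmp[k] <- min(Fmp[k], Fmp[k - 1] * 0.999)
  F0p <- pmin(noisy$F0p, 0.995 * Fmp)
  Ftp <- clamp(noisy$Ftp, F0p, 0.999 * Fmp)
  RawFluorescence(F0, Fm, data.frame(F0p = F0p, Ftp = Ftp, Fmp = Fmp))
}

#' Simulate a thermal raster for one plant-day
#'
#' Background pixels sit at ambient temperature; rosette pixels at ambient
#' minus transpiration cooling plus the state's stress offset and a
#' plant-level jitter, with per-pixel Gaussian noise everywhere.
#'
#' @param mask a [RosetteMask-class] (must have foreground pixels).
#' @param state one row of the `states` table (needs `temp_offset_c`).
#' @param params a [SimulationParams-class].
#' @param seed integer seed.
#' @return a [ThermalRaster-class] of the same shape as the mask.
#' @export
simulateThermalDay <- function(mask, state, params = SimulationParams(),
                               seed = 1L) {
  stopifnot(is(mask, "RosetteMask"))
  p <- params
  m <- mask@mask
  if (!any(m)) stop("empty mask: no rosette pixels to heat")
  withSeed(seed, {
    g <- matrix(p@ambientTemp + stats::rnorm(length(m), 0, p@thermalNoiseSD),
                nrow(m), ncol(m))
    g[m] <- g[m] - p@transpirationCooling + state$temp_offset_c +
      stats::rnorm(1, 0, p@plantTempSD)
    ThermalRaster(g)
  })
}

#' Simulate a full experiment down to the trait table
#'
#' Runs the whole generator-extraction chain in memory: latent states, then
#' per plant-day a rendered rosette mask, a thermal raster and a raw
#' fluorescence curve, from which all morphology, temperature and
#' fluorescence traits are derived and assembled into a long-format
#' [TraitTable-class].
#'
#' @param design an [ExperimentDesign-class].
#' @param params a [SimulationParams-class].
#' @param seed integer master seed.
#' @param grid,scale raster geometry passed to [renderRosetteMask()].
#' @param morphology set FALSE to skip mask rendering and morphology/
#'   temperature traits (fluorescence only; much faster).
#' @return list with elements `table` (the [TraitTable-class]), `experiment`
#'   (the [SimulatedExperiment-class]).
#' @export
simulateTraitTable <- function(design, params = SimulationParams(), seed = 1L,
                               grid = c(224L, 224L), scale = 0.5,
                               morphology = TRUE) {
  sim <- simulateExperiment(design, params, seed)
  st <- plantStates(sim)
  recs <- vector("list", nrow(st))
  for (i in seq_len(nrow(st))) {
    row <- st[i, ]
    s1 <- childSeed(seed, 3L * i + 1L)
    raw <- simulateFluorescenceDay(row, lightProtocol(design), params, s1)
    rec <- list(plant = row, das = row$das, raw = raw,
                fluor = deriveFluorescence(raw))
    if (morphology) {
      msk <- renderRosetteMask(row, grid, scale, childSeed(seed, 3L * i + 2L))
      thr <- simulateThermalDay(msk, row, params, childSeed(seed, 3L * i + 3L))
      tr <- maskTraits(msk, thr)
      rec$morpho <- tr[setdiff(names(tr), "temperature")]
      rec$temperature <- tr$temperature
    } else {
      # no mask rendering: carry the rosette size from the latent state (the
      # renderer reproduces it within 1% anyway) so size-based analyses
      # remain available in fluorescence-only runs
      rec$morpho <- list(area = row$true_area_mm2)
    }
    recs[[i]] <- rec
  }
  list(table = assembleTraitTable(recs), experiment = sim)
}
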