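# The synthetic experiment generator: design arithmetic, determinism, and
# recovery of every injected effect.

test_that("design enumerates the full factorial on trays of 20", {
  d <- buildDesign(20, seed = 1)
  p <- plants(d)
  expect_equal(nrow(p), 160)
  expect_equal(length(unique(p$tray)), 8)
  expect_true(all(table(p$tray) == 20))
  expect_true(all(table(p$genotype, p$treatment) == 20))
  # genotypes evenly split within every tray
  expect_true(all(table(p$tray, p$genotype) == 10))

  d1 <- buildDesign(1)
  expect_equal(nrow(plants(d1)), 8)
  expect_equal(length(unique(plants(d1)$tray)), 1)

  expect_identical(plants(buildDesign(20, seed = 3)),
                   plants(buildDesign(20, seed = 3)))
  expect_false(identical(plants(buildDesign(20, seed = 3)),
                         plants(buildDesign(20, seed = 4))))
  expect_error(buildDesign(0), "positive")
})

test_that("simulation is deterministic and respects the alive invariant", {
  d <- buildDesign(5, seed = 2)
  a <- simulateExperiment(d, SimulationParams(), seed = 9)
  b <- simulateExperiment(d, SimulationParams(), seed = 9)
  expect_identical(plantStates(a), plantStates(b))
  expect_identical(plantRegistry(a), plantRegistry(b))
  st <- plantStates(a)
  # once dead, no further records: dead plants only appear before DAS 0
  dead <- plantRegistry(a)$plant_id[plantRegistry(a)$died]
  expect_true(all(st$das[st$plant_id %in% dead] < 0))
})

test_that("mortality hits only the longest treatment at the configured rate", {
  d <- buildDesign(100, seed = 2)
  sim <- simulateExperiment(d, SimulationParams(deathProbability = 0.1),
                            seed = 5)
  reg <- plantRegistry(sim)
  expect_true(all(reg$treatment[reg$died] == "HS9h"))
  # 200 plants under HS9h, expectation 20
  expect_gt(sum(reg$died), 8)
  expect_lt(sum(reg$died), 36)
  sim0 <- simulateExperiment(d, SimulationParams(deathProbability = 0),
                             seed = 5)
  expect_equal(sum(plantRegistry(sim0)$died), 0)
})

test_that("stress hours never increase the expected final rosette area", {
  d <- buildDesign(20, seed = 3)
  sim <- simulateExperiment(d, SimulationParams(), seed = 3)
  st <- plantStates(sim)
  last <- st[st$das == 7, ]
  means <- tapply(last$true_area_mm2, last$treatment, mean)
  expect_true(means["control"] > means["HS3h"])
  expect_true(means["HS3h"] > means["HS6h"])
  expect_true(means["HS6h"] > means["HS9h"])
})

nullParams <- function() SimulationParams(
  growthPenaltyPerHour = 0, acuteAreaDropPerHour = 0, qyDipPerHour = 0,
  fmDepressionPerHour = 0, qpDropPerHour = 0, tempOffsetPerHour = 0,
  aspectDropPerHour = 0, stressJitterBoost = 0, deathProbability = 0,
  runtProbability = 0)

test_that("with all stress parameters zero no trait responds to treatment", {
  # Within one experiment the trait tests share plant-level latents, so the
  # rejection rate is checked across independent replicate experiments: the
  # per-replicate rates must average to the nominal level (3-SE band using
  # the across-replicate spread).
  seeds <- 1:12
  rates <- vapply(seeds, function(s) {
    res <- simulateTraitTable(buildDesign(6, seed = s), nullParams(),
                              seed = s, morphology = FALSE)
    dd <- traitData(res$table)
    ps <- c()
    for (tr in unique(dd$trait)) {
      sub <- dd[dd$trait == tr, ]
      for (day in c(0L, 5L)) {
        x <- sub$value[sub$das == day & sub$treatment == "HS6h"]
        y <- sub$value[sub$das == day & sub$treatment == "control"]
        ps <- c(ps, studentsTTest(x, y)$p)
      }
    }
    expect_gte(length(ps), 50)
    mean(ps < 0.05)
  }, numeric(1))
  se <- sd(rates) / sqrt(length(rates))
  expect_lt(abs(mean(rates) - 0.05), 3 * max(se, 0.005))
})

test_that("injected area penalty and temperature offset are recovered within 20%", {
  d <- buildDesign(20, seed = 6)
  params <- SimulationParams(signalNoiseCV = 0.01)
  sim <- simulateExperiment(d, params, seed = 6)
  st <- plantStates(sim)
  # temperature offset on the stress day, via simulated thermal rasters
  s6 <- st[st$das == 0 & st$treatment == "HS6h" & st$genotype == "WT", ]
  s0 <- st[st$das == 0 & st$treatment == "control" & st$genotype == "WT", ]
  getTemp <- function(rows, off) {
    vapply(seq_len(nrow(rows)), function(i) {
      m <- renderRosetteMask(rows[i, ], grid = c(128, 128), scale = 1,
                             seed = i + off)
      rosetteTemperature(m, simulateThermalDay(m, rows[i, ], params,
                                               seed = 1000 + i + off))
    }, numeric(1))
  }
  diffT <- mean(getTemp(s6, 0)) - mean(getTemp(s0, 5000))
  injected <- 0.25 * 6   # tempOffsetPerHour x hours
  expect_lt(abs(diffT - injected) / injected, 0.2)
})

test_that("zero tolerance coupling decouples early quenching from later area", {
  d <- buildDesign(50, seed = 8)
  res <- simulateTraitTable(
    d, SimulationParams(toleranceQpCoupling = 0, toleranceGrowthCoupling = 0),
    seed = 8, morphology = FALSE)
  cc <- crossTimeCorrelation(res$table, "Fq_Lss5", 0, "area", 7)
  stressed <- cc[cc$treatment != "control", ]
  expect_true(all(abs(stressed$r) < 0.3))  # zero within Monte-Carlo error
})

test_that("rendered masks match the target area and are seed-stable", {
  state <- data.frame(true_area_mm2 = 400, leaf_count = 9, leaf_aspect = 2.8,
                      lobe_jitter = 0.1)
  m <- renderRosetteMask(state, grid = c(128, 128), scale = 0.5, seed = 3)
  expect_lt(abs(sum(maskMatrix(m)) - 1600) / 1600, 0.05)
  m2 <- renderRosetteMask(state, grid = c(128, 128), scale = 0.5, seed = 3)
  expect_identical(maskMatrix(m), maskMatrix(m2))
  expect_false(identical(maskMatrix(m),
                         maskMatrix(renderRosetteMask(state, c(128, 128),
                                                      0.5, seed = 4))))
  # one round leaf: a near-disk
  one <- data.frame(true_area_mm2 = 300, leaf_count = 1, leaf_aspect = 1,
                    lobe_jitter = 0)
  mo <- renderRosetteMask(one, grid = c(64, 64), scale = 1, seed = 1)
  expect_lt(momentShape(mo)$eccentricity, 0.1)
  big <- data.frame(true_area_mm2 = 5e4, leaf_count = 9, leaf_aspect = 2.8,
                    lobe_jitter = 0.1)
  expect_error(renderRosetteMask(big, grid = c(64, 64), scale = 0.5),
               "overflow")
})

test_that("noise-free fluorescence reproduces the configured quantum yield", {
  params <- SimulationParams(signalNoiseCV = 0, curveNoiseCV = 0,
                             qymaxPlantSD = 0)
  state <- data.frame(qymax_true = 0.8, fm_factor = 1, fm_plant = 1,
                      qp_retention = 1, npq_retention = 1)
  raw <- simulateFluorescenceDay(state, LightProtocol(), params, seed = 1)
  expect_length(validateFluorescence(raw), 0)
  expect_equal(nrow(raw@steps), 6)
  der <- deriveFluorescence(raw)
  expect_equal(der$QYmax, 0.8, tolerance = 1e-12)
  # light response: Fm' strictly decreasing across steps
  expect_true(all(diff(raw@steps$Fmp) < 0))

  # stress-day Fm depression lowers Fm' at every light step
  stressed <- state; stressed$fm_factor <- 1 - 0.05 * 6
  raws <- simulateFluorescenceDay(stressed, LightProtocol(), params, seed = 1)
  expect_true(all(raws@steps$Fmp < raw@steps$Fmp))
  expect_lt(raws@Fm, raw@Fm)
})

test_that("fluorescence invariants survive measurement noise", {
  set.seed(1)
  params <- SimulationParams()
  state <- data.frame(qymax_true = 0.65, fm_factor = 0.8, fm_plant = 1.1,
                      qp_retention = 0.7, npq_retention = 0.8)
  for (s in 1:50) {
    raw <- simulateFluorescenceDay(state, LightProtocol(), params, seed = s)
    expect_length(validateFluorescence(raw), 0)
  }
})

test_that("thermal rasters carry the configured offset and reject empty masks", {
  m <- RosetteMask(rasterDisk(64, 20))
  params <- SimulationParams(thermalNoiseSD = 0.05, plantTempSD = 0)
  hot <- data.frame(temp_offset_c = 1.5)
  cold <- data.frame(temp_offset_c = 0)
  th <- simulateThermalDay(m, hot, params, seed = 2)
  tc <- simulateThermalDay(m, cold, params, seed = 3)
  expect_equal(rosetteTemperature(m, th) - rosetteTemperature(m, tc), 1.5,
               tolerance = 0.05)
  # background stays ambient
  expect_equal(mean(th@grid[!maskMatrix(m)]), 22, tolerance = 0.05)
  empty <- RosetteMask(matrix(FALSE, 8, 8))
  expect_error(simulateThermalDay(empty, hot, params), "empty")
})
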