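# Pipeline orchestration: simulate -> extract -> stats -> classify ->
# report, with the plant-exclusion quality filter, seeded determinism and a
# hashed run manifest.

#' Remove excluded plants from a trait table
#'
#' Implements the quality filter of the analysis: plants that died or never
#' grew are removed from every imaging day before any statistics.
#'
#' @param table a [TraitTable-class].
#' @param registry data.frame with `plant_id` and either an `excluded`
#'   logical column or `died` / `runt` flags (as produced by
#'   [simulateExperiment()]); alternatively a character vector of plant ids
#'   to exclude.
#' @return the filtered [TraitTable-class]. Counts are reported via
#'   `message()`; excluding every plant yields an empty table with a
#'   warning.
#' @export
applyExclusionFilter <- function(table, registry) {
  stopifnot(is(table, "TraitTable"))
  excl <- if (is.character(registry)) registry
  else if (!is.null(registry$excluded)) registry$plant_id[registry$excluded]
  else if (all(c("died", "runt") %in% names(registry)))
    registry$plant_id[registry$died | registry$runt]
  else stop("registry must carry an 'excluded' column, died/runt flags, or be a vector of ids")
  d <- traitData(table)
  keep <- !(d$plant_id %in% excl)
  dropped <- unique(d$plant_id[!keep])
  message(length(dropped), " plants excluded; ",
          length(unique(d$plant_id[keep])), " plants retained")
  if (!any(keep)) warning("exclusion filter removed every plant")
  TraitTable(d[keep, , drop = FALSE])
}

#' Number of plant-day record groups in a trait table
#'
#' @param table a [TraitTable-class].
#' @return count of distinct (plant, day) pairs.
#' @export
countRecordGroups <- function(table) {
  d <- traitData(table)
  nrow(unique(d[, c("plant_id", "das")]))
}

#' Day of quantum-yield recovery for a genotype under one treatment
#'
#' The first DAS (>= 0) at which the group's mean dark-adapted Fv/Fm is back
#' within `margin` of the same genotype's control mean — a practical
#' equivalence criterion that is robust to the per-day sampling noise of a
#' significance test.
#'
#' @param table a [TraitTable-class].
#' @param genotype "WT" or "hsp101".
#' @param treatment one heat-stress level.
#' @param margin absolute Fv/Fm equivalence margin (default 0.01).
#' @return integer DAS of recovery, or NA if the deficit persists through
#'   the last imaging day.
#' @export
qymaxRecoveryDay <- function(table, genotype, treatment, margin = 0.01) {
  d <- traitData(table)
  d <- d[d$trait == "QYmax" & d$genotype == genotype, ]
  days <- sort(unique(d$das[d$das >= 0]))
  for (day in days) {
    ctrl <- mean(d$value[d$treatment == "control" & d$das == day])
    grp <- mean(d$value[d$treatment == treatment & d$das == day])
    if (is.finite(ctrl) && is.finite(grp) && ctrl - grp <= margin)
      return(as.integer(day))
  }
  NA_integer_
}

#' Default pipeline configuration
#'
#' @param outDir output directory.
#' @param seed master seed; fixes the whole run.
#' @param nReps replicates per genotype x treatment.
#' @param ... overrides of any configuration field (`grid`, `scale`,
#'   `writeImages`, `morphology`, `params` as a named list of
#'   [SimulationParams()] overrides, `statTraits`, `cvFolds`,
#'   `traitsCsv` / `registryCsv` to skip simulation and ingest data).
#' @return configuration list for [runPipeline()].
#' @export
defaultRunConfig <- function(outDir = "phenoheat_run", seed = 1L,
                             nReps = 20L, ...) {
  cfg <- list(outDir = outDir, seed = as.integer(seed), nReps = nReps,
              grid = c(224L, 224L), scale = 0.5,
              writeImages = FALSE, morphology = TRUE,
              params = list(),
              statTraits = c("area", "QYmax", "Fq_Lss5", "NPQ_Lss5",
                             "temperature", "compactness", "SOL",
                             "perimeter"),
              cvFolds = 5L,
              doStats = TRUE, doCorrelogram = TRUE, doClassify = TRUE,
              traitsCsv = NULL, registryCsv = NULL)
  over <- list(...)
  bad <- setdiff(names(over), names(cfg))
  if (length(bad)) stop("unknown config fields: ", paste(bad, collapse = ", "))
  cfg[names(over)] <- over
  cfg
}

#' Read a pipeline configuration from a YAML file
#'
#' Flat key/value YAML mapping onto [defaultRunConfig()] fields; referenced
#' input paths must exist at validation time.
#'
#' @param path YAML file.
#' @return configuration list.
#' @export
readRunConfig <- function(path) {
  raw <- yaml::read_yaml(path)
  cfg <- do.call(defaultRunConfig, raw)
  for (f in c("traitsCsv", "registryCsv"))
    if (!is.null(cfg[[f]]) && !file.exists(cfg[[f]]))
      stop("configured path does not exist: ", cfg[[f]])
  cfg
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> extract -> filter -> stats -> classify and writes
#' every result table plus a manifest with the md5 hash of each output, so
#' a repeated run under the same seed is verifiably identical. When the
#' configuration provides `traitsCsv` (and optionally `registryCsv`), the
#' simulation stage is skipped and the provided data are analysed instead.
#'
#' @param config list from [defaultRunConfig()] or [readRunConfig()].
#' @return the manifest, invisibly. Output files: `design.csv`,
#'   `registry.csv`, `traits.csv` (filtered), `ttests.csv`,
#'   `interactions.csv`, `correlogram.csv`, `classification.csv`,
#'   `manifest.json`, and under `masks/`, `thermal/` the per plant-day
#'   rasters when `writeImages` is on.
#' @export
runPipeline <- function(config = defaultRunConfig()) {
  t0 <- proc.time()[["elapsed"]]
  stage <- function(name) message(sprintf("[%6.1fs] %s",
                                          proc.time()[["elapsed"]] - t0, name))
  dir.create(config$outDir, showWarnings = FALSE, recursive = TRUE)
  out <- function(f) file.path(config$outDir, f)
  written <- character(0)
  params <- do.call(SimulationParams, config$params)

  if (is.null(config$traitsCsv)) {
    stage("simulate + extract")
    design <- buildDesign(config$nReps, seed = config$seed)
    simres <- simulateTraitTable(design, params, seed = config$seed,
                                 grid = config$grid, scale = config$scale,
                                 morphology = config$morphology)
    registry <- plantRegistry(simres$experiment)
    table <- simres$table
    utils::write.csv(plants(design), out("design.csv"), row.names = FALSE)
    utils::write.csv(registry, out("registry.csv"), row.names = FALSE)
    written <- c(written, "design.csv", "registry.csv")
    if (isTRUE(config$writeImages)) {
      stage("write rasters")
      dir.create(out("masks"), showWarnings = FALSE)
      dir.create(out("thermal"), showWarnings = FALSE)
      st <- plantStates(simres$experiment)
      for (i in seq_len(nrow(st))) {
        row <- st[i, ]
        msk <- renderRosetteMask(row, config$grid, config$scale,
                                 childSeed(config$seed, 3L * i + 2L))
        thr <- simulateThermalDay(msk, row, params,
                                  childSeed(config$seed, 3L * i + 3L))
        base <- sprintf("%s_das%+d", row$plant_id, row$das)
        writeMaskPNG(msk, out(file.path("masks", paste0(base, ".png"))))
        writeThermalTIFF(thr, out(file.path("thermal", paste0(base, ".tif"))))
      }
    }
  } else {
    stage("ingest user-supplied traits")
    table <- readTraitTable(config$traitsCsv)
    registry <- if (!is.null(config$registryCsv))
      utils::read.csv(config$registryCsv, stringsAsFactors = FALSE)
    else data.frame(plant_id = character(0), excluded = logical(0))
  }

  stage("exclusion filter")
  if (nrow(registry)) table <- applyExclusionFilter(table, registry)
  writeTraitTable(table, out("traits.csv"))
  written <- c(written, "traits.csv")

  present <- intersect(config$statTraits, unique(traitData(table)$trait))
  if (isTRUE(config$doStats)) {
  stage("temporal statistics")
  tt <- do.call(rbind, lapply(present, function(tr) {
    do.call(rbind, lapply(c("HS3h", "HS6h", "HS9h"), function(tm) {
      rbind(
        cbind(trait = tr, contrast = paste0("WT:", tm, "-control"),
              compareByDay(table, tr, list(genotype = "WT", treatment = tm),
                           list(genotype = "WT", treatment = "control"))),
        cbind(trait = tr, contrast = paste0(tm, ":hsp101-WT"),
              compareByDay(table, tr,
                           list(genotype = "hsp101", treatment = tm),
                           list(genotype = "WT", treatment = tm))))
    }))
  }))
  utils::write.csv(tt, out("ttests.csv"), row.names = FALSE)

  ia <- do.call(rbind, lapply(present, function(tr) {
    do.call(rbind, lapply(c("HS3h", "HS6h", "HS9h"), function(tm) {
      fit <- fitInteractionModel(table, tr, tm)
      do.call(rbind, lapply(names(fit), function(cf)
        data.frame(trait = tr, treatment = tm, coef = cf,
                   estimate = fit[[cf]]$estimate, se = fit[[cf]]$se,
                   t = fit[[cf]]$statistic, df = fit[[cf]]$df,
                   p = fit[[cf]]$p, stars = fit[[cf]]$stars)))
    }))
  }))
  utils::write.csv(ia, out("interactions.csv"), row.names = FALSE)
  written <- c(written, "ttests.csv", "interactions.csv")
  }

  if (isTRUE(config$doCorrelogram)) {
  stage("cross-time correlogram")
  days <- sort(unique(traitData(table)$das))
  days <- days[days >= 0]
  cg <- crossTimeGrid(table, "Fq_Lss5", "area", days, days)
  utils::write.csv(cg, out("correlogram.csv"), row.names = FALSE)
  written <- c(written, "correlogram.csv")
  }

  if (isTRUE(config$doClassify)) {
  stage("classification")
  dir.create(out("models"), showWarnings = FALSE)
  cls <- do.call(rbind, lapply(TREATMENTS, function(g) {
    fm <- suppressWarnings(buildFeatures(table, g))
    cv <- cvAccuracy(fm, k = config$cvFolds,
                     seed = childSeed(config$seed, match(g, TREATMENTS)))
    final <- suppressWarnings(
      fitL1Logistic(fm, lambda = stats::median(cv$lambda)))
    writeClassifierJSON(final, out(file.path("models", paste0(g, ".json"))))
    data.frame(group = g, n = nrow(fm@X), accuracy = cv$accuracy,
               lambda = stats::median(cv$lambda),
               top_traits = paste(rankTraits(final, 10), collapse = ";"))
  }))
  utils::write.csv(cls, out("classification.csv"), row.names = FALSE)
  written <- c(written, "classification.csv")
  }

  stage("manifest")
  manifest <- list(
    package = as.character(utils::packageVersion("heatPheno")),
    seed = config$seed,
    n_plants = length(unique(traitData(table)$plant_id)),
    n_record_groups = countRecordGroups(table),
    files = as.list(tools::md5sum(vapply(written, out, character(1))))
  )
  names(manifest$files) <- written
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       pretty = TRUE)
  stage("done")
  invisible(manifest)
}
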