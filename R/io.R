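# File formats: trait tables and raw-signal tables as CSV, masks as 8-bit
# PNG (0 background / 255 rosette), thermal rasters as 32-bit float TIFF
# storing degrees C / 100 (TIFF float samples round-trip only inside [0,1];
# the convention covers 0-100 C and is undone on read).

#' Read and write trait tables as CSV
#'
#' @param table a [TraitTable-class].
#' @param path file path.
#' @return `readTraitTable()` returns a [TraitTable-class];
#'   `writeTraitTable()` returns the path invisibly.
#' @export
writeTraitTable <- function(table, path) {
  stopifnot(is(table, "TraitTable"))
  utils::write.csv(traitData(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeTraitTable
#' @export
readTraitTable <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  d$das <- as.integer(d$das)
  TraitTable(d)
}

#' Read and write rosette masks as single-channel PNG
#'
#' Foreground is stored as 255, background as 0. The mm/px scale is not part
#' of the PNG and must be supplied on read.
#'
#' @param mask a [RosetteMask-class].
#' @param path file path.
#' @param scale mm per pixel to attach on read.
#' @export
writeMaskPNG <- function(mask, path) {
  stopifnot(is(mask, "RosetteMask"))
  png::writePNG(mask@mask * 1, path)
  invisible(path)
}

#' @rdname writeMaskPNG
#' @export
readMaskPNG <- function(path, scale = 1) {
  img <- png::readPNG(path)
  if (length(dim(img)) == 3) img <- img[, , 1]
  RosetteMask(img > 0.5, scale)
}

#' Read and write thermal rasters as 32-bit float TIFF
#'
#' Stored as degrees C divided by 100 so that float samples stay inside the
#' TIFF [0, 1] range; `readThermalTIFF()` undoes the scaling.
#'
#' @param raster a [ThermalRaster-class] (values must lie in 0-100 C).
#' @param path file path.
#' @export
writeThermalTIFF <- function(raster, path) {
  stopifnot(is(raster, "ThermalRaster"))
  g <- raster@grid
  if (any(g < 0 | g > 100))
    stop("thermal values outside the storable 0-100 C range")
  tiff::writeTIFF(g / 100, path, bits.per.sample = 32, compression = "none")
  invisible(path)
}

#' @rdname writeThermalTIFF
#' @export
readThermalTIFF <- function(path) {
  ThermalRaster(tiff::readTIFF(path) * 100)
}

#' Read and write raw fluorescence light-curve tables
#'
#' CSV with one row per plant-day: `plant_id, das, f0, fm`, then
#' `f0p_lss1..K`, `ftp_lss1..K`, `fmp_lss1..K`.
#'
#' @param records list of lists with elements `plant_id`, `das`, `raw`
#'   (a [RawFluorescence-class]).
#' @param path file path.
#' @export
writeRawFluorescenceCSV <- function(records, path) {
  rows <- lapply(records, function(r) {
    s <- r$raw@steps
    k <- nrow(s)
    vals <- c(f0 = r$raw@F0, fm = r$raw@Fm,
              stats::setNames(s$F0p, paste0("f0p_lss", seq_len(k))),
              stats::setNames(s$Ftp, paste0("ftp_lss", seq_len(k))),
              stats::setNames(s$Fmp, paste0("fmp_lss", seq_len(k))))
    cbind(data.frame(plant_id = r$plant_id, das = r$das), t(vals))
  })
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' @rdname writeRawFluorescenceCSV
#' @return `readRawFluorescenceCSV()` returns a list of records, each with
#'   `plant_id`, `das` and a [RawFluorescence-class] `raw`.
#' @export
readRawFluorescenceCSV <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  k <- sum(grepl("^f0p_lss", names(d)))
  lapply(seq_len(nrow(d)), function(i) {
    list(plant_id = d$plant_id[i], das = as.integer(d$das[i]),
         raw = RawFluorescence(d$f0[i], d$fm[i], data.frame(
           F0p = as.numeric(d[i, paste0("f0p_lss", seq_len(k))]),
           Ftp = as.numeric(d[i, paste0("ftp_lss", seq_len(k))]),
           Fmp = as.numeric(d[i, paste0("fmp_lss", seq_len(k))]))))
  })
}
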