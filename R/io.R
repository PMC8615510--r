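# Shared I/O: TIFF/PNG images, schema-checked CSV tables, ROI JSON, and
# the umbrella runStage() dispatcher that writes reproducible run
# directories (resolved config, manifest with checksums, log).

#' Read an RGB or gray image from TIFF or PNG
#'
#' Values are converted to float in [0, 1]; the original bit depth is
#' recorded in the "bitDepth" attribute.
#'
#' @param path path to a .tif/.tiff or .png file.
#' @return numeric array (rows x cols [x channels]) in [0, 1].
#' @export
readImageFile <- function(path) {
  if (!file.exists(path)) stop("cannot read image: ", path)
  ext <- tolower(tools::file_ext(path))
  img <- tryCatch(switch(ext,
                         tif = , tiff = tiff::readTIFF(path, info = TRUE),
                         png = png::readPNG(path, info = TRUE),
                         stop("unsupported image format '", ext, "'")),
                  error = function(e)
                    stop("failed to read image '", path, "': ",
                         conditionMessage(e)))
  # readTIFF/readPNG already rescale integer data to [0,1]
  info <- attr(img, "info")
  bits <- if (!is.null(info$bit.depth)) info$bit.depth else
    if (!is.null(info$bits.per.sample)) info$bits.per.sample else NA
  attributes(img) <- list(dim = dim(img))
  attr(img, "bitDepth") <- bits
  img
}

#' Write an image as TIFF or PNG
#'
#' @param image numeric array in [0, 1].
#' @param path output path ending in .tif/.tiff or .png.
#' @return the path, invisibly.
#' @export
writeImageFile <- function(image, path) {
  ext <- tolower(tools::file_ext(path))
  image <- clip01(image)
  switch(ext,
         tif = , tiff = tiff::writeTIFF(image, path, bits.per.sample = 8L),
         png = png::writePNG(image, path),
         stop("unsupported image format '", ext, "'"))
  invisible(path)
}

#' Read and validate a viability time-course CSV
#'
#' Expected columns: time_days, value, replicate, culture.  Offending
#' rows (non-finite time or value, negative value) are listed in the
#' error.
#'
#' @param path CSV file with a header row.
#' @return validated data.frame.
#' @export
readViabilityTable <- function(path) {
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("time_days", "value", "replicate", "culture")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("viability table is missing column(s): ",
         paste(miss, collapse = ", "))
  bad <- which(!is.finite(tab$time_days) | !is.finite(tab$value) |
                 tab$value < 0)
  if (length(bad))
    stop("invalid viability rows: ", paste(bad, collapse = ", "))
  tab
}

#' Read and validate a dose-response CSV
#'
#' In "effect" mode the file carries pre-computed dead fractions
#' (dose_ug_ml, E_mean, E_sd, n); in "absorbance" mode it carries raw
#' absorbances (dose_ug_ml, absorbance_mean, absorbance_sd, n) which are
#' converted against the zero-dose control row via
#' \code{\link{deadFraction}}.
#'
#' @param path CSV file with a header row.
#' @param mode "effect" or "absorbance".
#' @return data.frame with columns dose_ug_ml, E_mean, E_sd, n.
#' @export
readDoseResponseTable <- function(path, mode = c("effect", "absorbance")) {
  mode <- match.arg(mode)
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!"dose_ug_ml" %in% names(tab))
    stop("dose-response table is missing column: dose_ug_ml")
  bad <- which(!is.finite(tab$dose_ug_ml) | tab$dose_ug_ml < 0)
  if (length(bad))
    stop("invalid dose rows: ", paste(bad, collapse = ", "))
  if (mode == "effect") {
    miss <- setdiff(c("E_mean"), names(tab))
    if (length(miss))
      stop("dose-response table is missing column(s): ",
           paste(miss, collapse = ", "))
    return(tab)
  }
  need <- c("absorbance_mean", "absorbance_sd")
  miss <- setdiff(need, names(tab))
  if (length(miss))
    stop("absorbance table is missing column(s): ",
         paste(miss, collapse = ", "))
  ctrl <- tab[tab$dose_ug_ml == 0, ]
  if (nrow(ctrl) != 1L)
    stop("absorbance mode requires exactly one zero-dose control row")
  df <- deadFraction(tab$absorbance_mean, ctrl$absorbance_mean,
                     tab$absorbance_sd)
  out <- data.frame(dose_ug_ml = tab$dose_ug_ml, E_mean = df$E,
                    E_sd = df$sigmaE,
                    n = if ("n" %in% names(tab)) tab$n else NA_integer_)
  out$E_mean[out$dose_ug_ml == 0] <- 0
  out
}

#' Write/read ROI definitions as JSON
#'
#' @param rois list of \code{\link{rectRoi}} ROIs.
#' @param path JSON path.
#' @return \code{writeRoiJson}: the path invisibly; \code{readRoiJson}:
#'   the ROI list.
#' @export
writeRoiJson <- function(rois, path) {
  jsonlite::write_json(rois, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname writeRoiJson
#' @export
readRoiJson <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  lapply(seq_len(length(raw$row0) %||% length(raw)), function(i) {
    if (is.data.frame(raw))
      rectRoi(raw$row0[i], raw$col0[i], raw$height[i], raw$width[i])
    else rectRoi(raw[[i]]$row0, raw[[i]]$col0, raw[[i]]$height,
                 raw[[i]]$width)
  })
}

stageLog <- function(logPath, level, msg) {
  line <- jsonlite::toJSON(list(time = format(Sys.time(), "%Y-%m-%dT%H:%M:%S"),
                                level = level, msg = msg),
                           auto_unbox = TRUE)
  cat(line, "\n", file = logPath, append = TRUE, sep = "")
  message("[", level, "] ", msg)
}

#' Run a named pipeline stage reproducibly
#'
#' Dispatches to one of the pipeline stages, writes its outputs into the
#' configured directory together with the resolved configuration
#' (config.json), a manifest of produced files with MD5 checksums
#' (manifest.json), and a structured log (run.log).  Deterministic
#' stages re-run with an identical config reproduce identical checksums.
#'
#' @param config list with fields \code{stage} (one of
#'   "synth_histology", "synth_vessels", "synth_viability",
#'   "synth_dose", "growth_fit", "dr_fit"), \code{outDir}, \code{seed},
#'   and a stage-specific \code{params} list (for the synth stages,
#'   arguments of the matching generator; for the fit stages, an
#'   \code{input} CSV path).
#' @return the manifest list, invisibly.
#' @export
runStage <- function(config) {
  need <- c("stage", "outDir")
  if (!all(need %in% names(config)))
    stop("config must contain: ", paste(need, collapse = ", "))
  outDir <- config$outDir
  dir.create(outDir, recursive = TRUE, showWarnings = FALSE)
  logPath <- file.path(outDir, "run.log")
  if (file.exists(logPath)) unlink(logPath)
  params <- config$params %||% list()
  seed <- config$seed %||% 1L
  stageLog(logPath, "info", paste("stage:", config$stage))

  files <- character(0)
  emit <- function(name) files <<- c(files, file.path(outDir, name))

  switch(config$stage,
    synth_histology = {
      spec <- do.call(histologySpec, c(params, list(seed = seed)))
      res <- synthHistology(spec)
      writeImageFile(res$image, file.path(outDir, "histology.png"))
      emit("histology.png")
      writeImageFile(res$compartmentMask / 255,
                     file.path(outDir, "compartments.png"))
      emit("compartments.png")
      truth <- res$truth
      truth$labelImage <- NULL; truth$cellMask <- NULL
      jsonlite::write_json(truth, file.path(outDir, "histology.truth.json"),
                           auto_unbox = TRUE, digits = NA, dataframe = "rows")
      emit("histology.truth.json")
    },
    synth_vessels = {
      spec <- do.call(vesselSpec, c(params, list(seed = seed)))
      res <- synthVessels(spec)
      writeImageFile(res$image, file.path(outDir, "vessels.png"))
      emit("vessels.png")
      truth <- res$truth[c("totalLengthUm", "junctionCount", "seed")]
      jsonlite::write_json(truth, file.path(outDir, "vessels.truth.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("vessels.truth.json")
    },
    synth_viability = {
      res <- do.call(synthViability, c(params, list(seed = seed)))
      utils::write.csv(res$series, file.path(outDir, "viability.csv"),
                       row.names = FALSE)
      emit("viability.csv")
      jsonlite::write_json(res$truth,
                           file.path(outDir, "viability.truth.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("viability.truth.json")
    },
    synth_dose = {
      res <- do.call(synthDoseResponse, c(params, list(seed = seed)))
      utils::write.csv(res$table, file.path(outDir, "dose_response.csv"),
                       row.names = FALSE)
      emit("dose_response.csv")
      jsonlite::write_json(res$truth,
                           file.path(outDir, "dose_response.truth.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("dose_response.truth.json")
    },
    growth_fit = {
      series <- readViabilityTable(params$input)
      fit <- fitLogistic(series)
      rep <- list(C0 = fit@C0, Cmax = fit@Cmax, d_per_day = fit@d,
                  rss = fit@rss, se = as.list(fit@se),
                  converged = fit@converged, message = fit@message)
      jsonlite::write_json(rep, file.path(outDir, "growth_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("growth_fit.json")
      tt <- seq(min(series$time_days), max(series$time_days),
                length.out = 200)
      utils::write.csv(data.frame(time_days = tt,
                                  value = logisticGrowth(tt, fit@C0,
                                                         fit@Cmax, fit@d)),
                       file.path(outDir, "growth_curve.csv"),
                       row.names = FALSE)
      emit("growth_curve.csv")
    },
    dr_fit = {
      tab <- readDoseResponseTable(params$input,
                                   mode = params$mode %||% "effect")
      fit <- fitHill(tab)
      rep <- list(Emax = fit@Emax, EC50_log10 = fit@EC50,
                  EC50_ug_ml = fit@EC50Linear, h = fit@h,
                  IC50_ug_ml = if (fit@IC50Reached) fit@IC50
                  else "not reached",
                  rss = fit@rss, converged = fit@converged)
      jsonlite::write_json(rep, file.path(outDir, "hill_fit.json"),
                           auto_unbox = TRUE, digits = NA)
      emit("hill_fit.json")
      dd <- 10^seq(log10(min(tab$dose_ug_ml[tab$dose_ug_ml > 0])) - 1,
                   log10(max(tab$dose_ug_ml)) + 0.5, length.out = 200)
      utils::write.csv(data.frame(dose_ug_ml = dd,
                                  E = hillCurve(log10(dd), fit@Emax,
                                                fit@EC50, fit@h)),
                       file.path(outDir, "hill_curve.csv"),
                       row.names = FALSE)
      emit("hill_curve.csv")
    },
    stop("unknown stage '", config$stage, "'")
  )

  cfgPath <- file.path(outDir, "config.json")
  jsonlite::write_json(config, cfgPath, auto_unbox = TRUE, digits = NA,
                       force = TRUE)
  manifest <- list(
    tool = paste("tecquant",
                 as.character(utils::packageVersion("tecquant"))),
    stage = config$stage,
    configHash = unname(tools::md5sum(cfgPath)),
    files = lapply(files, function(f)
      list(path = basename(f), md5 = unname(tools::md5sum(f)))))
  jsonlite::write_json(manifest, file.path(outDir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)
  stageLog(logPath, "info", "done")
  invisible(manifest)
}
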