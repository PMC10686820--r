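#' @include imaging-segment.R
NULL

.delim <- function(file) {
  if (grepl("\\.tsv$", file, ignore.case = TRUE)) "\t" else ","
}

#' Read a colony position table
#'
#' Reads a CSV or TSV (by extension) with header columns `tip_id` and
#' `x_mm`; optional columns (`y_mm`, `z_mm`, `radius_px`, ...) are kept
#' but ignored by the estimator. Malformed rows (non-numeric `x_mm`)
#' are reported with their line numbers and dropped.
#'
#' @param file Path to the table.
#' @return data.frame with at least `tip_id` and `x_mm`.
#' @seealso [colonySetsFromTable()] to build [ColonySet-class] objects.
#' @export
readColonyTable <- function(file) {
  df <- utils::read.table(file, header = TRUE, sep = .delim(file),
                          stringsAsFactors = FALSE)
  need <- c("tip_id", "x_mm")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing required column(s): ", paste(miss, collapse = ", "))
  x <- suppressWarnings(as.numeric(df$x_mm))
  bad <- which(is.na(x) & !is.na(df$x_mm) & df$x_mm != "")
  bad <- union(bad, which(is.na(x)))
  if (length(bad)) {
    warning(length(bad), " malformed row(s) dropped (file lines ",
            paste(utils::head(bad + 1L, 10), collapse = ", "),
            if (length(bad) > 10) ", ..." else "", ")")
    df <- df[-bad, , drop = FALSE]
    x <- x[-bad]
  }
  df$x_mm <- x
  df
}

#' Build colony sets from a position table
#'
#' Splits a colony table by `tip_id` and builds one [ColonySet-class]
#' per tip. Rows whose position falls outside `[0, h]` are rejected
#' with a warning reporting the count; unsorted positions are sorted
#' (with a warning from the constructor).
#'
#' @param df data.frame from [readColonyTable()].
#' @param geometry A [ConeGeometry-class].
#' @param dilutionFactor,gelVolume Passed to [ColonySet()].
#' @return Named list of [ColonySet-class], one per tip.
#' @export
colonySetsFromTable <- function(df, geometry, dilutionFactor = 100,
                                gelVolume = NULL) {
  h <- geometry@axialLength
  out <- df$x_mm < 0 | df$x_mm > h
  if (any(out)) {
    warning(sum(out), " row(s) rejected: x_mm outside [0, ", h, "] mm")
    df <- df[!out, , drop = FALSE]
  }
  hasRadial <- all(c("y_mm", "z_mm") %in% names(df))
  sets <- lapply(split(df, df$tip_id), function(g) {
    ord <- order(g$x_mm)
    g <- g[ord, , drop = FALSE]
    ColonySet(g$x_mm, geometry, tipId = g$tip_id[1],
              dilutionFactor = dilutionFactor, gelVolume = gelVolume,
              radial = if (hasRadial) cbind(g$y_mm, g$z_mm) else NULL)
  })
  sets[order(names(sets))]
}

#' Write colony sets as a position table
#'
#' @param sets A [ColonySet-class] or list of them.
#' @param file Output path; `.tsv` extension switches to tab delimiter.
#' @return Invisibly, the written data.frame.
#' @export
writeColonyTable <- function(sets, file) {
  if (is(sets, "ColonySet")) sets <- list(sets)
  rows <- lapply(sets, function(cs) {
    n <- nColonies(cs)
    d <- data.frame(tip_id = rep(cs@tipId, n), x_mm = cs@positions)
    if (nrow(cs@radial)) {
      d$y_mm <- cs@radial[, "y_mm"]
      d$z_mm <- cs@radial[, "z_mm"]
    }
    d
  })
  hasRadial <- vapply(rows, function(d) "y_mm" %in% names(d), logical(1))
  if (any(hasRadial) && !all(hasRadial))
    rows <- lapply(rows, function(d) {
      if (!"y_mm" %in% names(d)) { d$y_mm <- NA_real_; d$z_mm <- NA_real_ }
      d
    })
  df <- do.call(rbind, rows)
  rownames(df) <- NULL
  utils::write.table(df, file, sep = .delim(file), row.names = FALSE,
                     quote = FALSE)
  invisible(df)
}

.estimateRecord <- function(est, tipId) {
  data.frame(tip_id = tipId,
             n_colonies = est@nCounted,
             x1_mm = est@interval[1], x2_mm = est@interval[2],
             cfu_per_ml_sample = est@cfuPerMlSample,
             below_lod = est@belowLod)
}

#' Write estimation results
#'
#' One record per tip: `tip_id`, `n_colonies`, `x1_mm`, `x2_mm`,
#' `cfu_per_ml_sample`, `below_lod`; as CSV or JSON-lines.
#'
#' @param estimates Named list of [CfuEstimate-class] (names = tip ids),
#'   or a single estimate.
#' @param file Output path.
#' @param format `"csv"` or `"jsonl"` (guessed from the extension by
#'   default).
#' @return Invisibly, the records data.frame.
#' @export
writeResults <- function(estimates, file, format = NULL) {
  if (is(estimates, "CfuEstimate"))
    estimates <- stats::setNames(list(estimates), "tip1")
  if (is.null(names(estimates)))
    names(estimates) <- sprintf("tip%d", seq_along(estimates))
  df <- do.call(rbind, Map(.estimateRecord, estimates, names(estimates)))
  rownames(df) <- NULL
  if (is.null(format))
    format <- if (grepl("\\.jsonl?$", file, ignore.case = TRUE)) "jsonl"
              else "csv"
  if (format == "jsonl") {
    con <- file(file, "w"); on.exit(close(con))
    for (i in seq_len(nrow(df)))
      writeLines(jsonlite::toJSON(as.list(df[i, , drop = FALSE]),
                                  auto_unbox = TRUE, digits = NA,
                                  na = "null"), con)
  } else {
    utils::write.csv(df, file, row.names = FALSE, quote = FALSE)
  }
  invisible(df)
}

#' Read estimation results written by [writeResults()]
#'
#' @param file Path to a CSV or JSON-lines results file.
#' @return data.frame of records.
#' @export
readResults <- function(file) {
  if (grepl("\\.jsonl?$", file, ignore.case = TRUE)) {
    rows <- lapply(readLines(file), function(l) {
      rec <- jsonlite::fromJSON(l)
      rec[vapply(rec, is.null, logical(1))] <- NA
      as.data.frame(rec)
    })
    df <- do.call(rbind, rows)
  } else {
    df <- utils::read.csv(file, stringsAsFactors = FALSE)
  }
  df$below_lod <- as.logical(df$below_lod)
  df
}

#' Read a vessel geometry from a config file
#'
#' YAML or JSON with either `profile: p200` or explicit keys `shape`,
#' `axial_length_mm`, `volume_uL`.
#'
#' @param file Path (`.yaml`/`.yml`/`.json`).
#' @return A [ConeGeometry-class].
#' @export
readGeometryConfig <- function(file) {
  cfg <- if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::fromJSON(file)
  else yaml::read_yaml(file)
  if (!is.null(cfg$profile)) return(geometryProfile(cfg$profile))
  need <- c("shape", "axial_length_mm", "volume_uL")
  miss <- setdiff(need, names(cfg))
  if (length(miss))
    stop("geometry config missing key(s): ", paste(miss, collapse = ", "))
  ConeGeometry(shape = cfg$shape, axialLength = cfg$axial_length_mm,
               volume = cfg$volume_uL)
}

#' Write a vessel geometry config
#'
#' @param geom A [ConeGeometry-class].
#' @param file Path (`.yaml`/`.yml`/`.json`).
#' @return Invisibly, `file`.
#' @export
writeGeometryConfig <- function(geom, file) {
  cfg <- list(shape = geom@shape, axial_length_mm = geom@axialLength,
              volume_uL = geom@volume)
  if (grepl("\\.json$", file, ignore.case = TRUE))
    jsonlite::write_json(cfg, file, auto_unbox = TRUE, digits = NA)
  else yaml::write_yaml(cfg, file)
  invisible(file)
}

#' Write a synthetic tip image (with ground-truth sidecar)
#'
#' Writes the pixels as 16-bit PNG or TIFF and, when the image carries
#' ground truth, a JSON sidecar (`<file>.json`) holding the truth
#' table, optics, geometry, apex and tilt, so image fixtures remain
#' testable.
#'
#' @param image A [SyntheticTipImage-class].
#' @param file Output path (`.png` or `.tif`/`.tiff`).
#' @param sidecar Write the JSON sidecar? Default TRUE.
#' @return Invisibly, `file`.
#' @export
writeTipImage <- function(image, file, sidecar = TRUE) {
  px <- image@pixels
  if (grepl("\\.tiff?$", file, ignore.case = TRUE))
    tiff::writeTIFF(px, file, bits.per.sample = 16L)
  else png::writePNG(px, file)
  if (sidecar) {
    meta <- list(
      optics = list(pixel_size_um = image@optics@pixelSize,
                    noise_sd = image@optics@noiseSd,
                    background = image@optics@background),
      geometry = list(shape = image@geometry@shape,
                      axial_length_mm = image@geometry@axialLength,
                      volume_uL = image@geometry@volume),
      apex_px = image@apex, axis_angle_deg = image@axisAngle,
      base_radius_mm = image@baseRadius,
      resolution_warning = image@resolutionWarning,
      truth = image@truth)
    jsonlite::write_json(meta, paste0(file, ".json"), auto_unbox = TRUE,
                         digits = NA, dataframe = "columns")
  }
  invisible(file)
}

#' Read a tip image written by [writeTipImage()]
#'
#' @param file Path to the PNG/TIFF; the JSON sidecar is read when
#'   present.
#' @return A [SyntheticTipImage-class] (with empty truth and NA
#'   apex/angle when no sidecar exists).
#' @export
readTipImage <- function(file) {
  px <- if (grepl("\\.tiff?$", file, ignore.case = TRUE))
    tiff::readTIFF(file)
  else png::readPNG(file)
  if (length(dim(px)) == 3L)                 # colour: luminance convert
    px <- 0.2126 * px[, , 1] + 0.7152 * px[, , 2] + 0.0722 * px[, , 3]
  side <- paste0(file, ".json")
  if (file.exists(side)) {
    meta <- jsonlite::fromJSON(side)
    optics <- OpticsProfile(pixelSize = meta$optics$pixel_size_um,
                            noiseSd = meta$optics$noise_sd,
                            background = meta$optics$background)
    geom <- ConeGeometry(shape = meta$geometry$shape,
                         axialLength = meta$geometry$axial_length_mm,
                         volume = meta$geometry$volume_uL)
    truth <- as.data.frame(meta$truth)
    if (!nrow(truth))
      truth <- data.frame(x_mm = numeric(), row_px = numeric(),
                          col_px = numeric(), r_px = numeric())
    new("SyntheticTipImage", pixels = px, optics = optics,
        geometry = geom, truth = truth, apex = meta$apex_px,
        axisAngle = meta$axis_angle_deg,
        baseRadius = meta$base_radius_mm,
        resolutionWarning = isTRUE(meta$resolution_warning))
  } else {
    new("SyntheticTipImage", pixels = px, optics = OpticsProfile(),
        geometry = geometryProfile("p200"),
        truth = data.frame(x_mm = numeric(), row_px = numeric(),
                           col_px = numeric(), r_px = numeric()),
        apex = c(NA_real_, NA_real_), axisAngle = NA_real_,
        baseRadius = NA_real_, resolutionWarning = FALSE)
  }
}
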