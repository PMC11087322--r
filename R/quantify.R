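# End-to-end quantification: image(s) -> segmentation -> detection ->
# calibrated areas -> density matrix -> screen summary, with CSV/JSON output.

#' Quantify halos on one plate image
#'
#' Runs the full per-image pipeline: CIELAB conversion, b*-band
#' segmentation, rounded-region detection, and calibrated area computation.
#' Cells listed in `manual_masks` are measured by counting positive pixels
#' inside the supplied circle instead of (or in addition to) automatic
#' detection, mirroring the manual fallback used when automatic extraction
#' fails.
#'
#' @param image An [rgb_image()] or a path readable by
#'   [read_plate_image()].
#' @param layout A [grid_layout()].
#' @param cal A [calibrate()] record.
#' @param seg A [segmentation_params()].
#' @param det A [detection_params()].
#' @param manual_masks Optional data frame `cell_id`, `cx`, `cy`, `r`
#'   (pixels): manual circles that replace automatic detection for those
#'   cells.
#' @return Data frame of regions with columns of [detect_halos()] plus
#'   `area_cm2` and `method` ("auto" or "manual").
#' @export
quantify_plate <- function(image, layout, cal,
                           seg = segmentation_params(),
                           det = detection_params(),
                           manual_masks = NULL) {
  if (is.character(image)) image <- read_plate_image(image)
  if (layout$image_width != dim(image)[2] ||
      layout$image_height != dim(image)[1])
    stop("quantify_plate: layout does not match image dimensions (",
         dim(image)[2], " x ", dim(image)[1], " px)", call. = FALSE)
  lab <- srgb_to_lab(image)
  mask <- blue_mask(lab, seg)
  regions <- detect_halos(mask, layout, det)
  regions$method <- rep("auto", nrow(regions))
  if (!is.null(manual_masks) && nrow(manual_masks) > 0) {
    stopifnot(all(c("cell_id", "cx", "cy", "r") %in% names(manual_masks)))
    regions <- regions[!regions$cell_id %in% manual_masks$cell_id, ]
    for (k in seq_len(nrow(manual_masks))) {
      mm <- manual_masks[k, ]
      cnt <- pixel_count_in_circle(mask, c(mm$cx, mm$cy), mm$r)
      regions <- rbind(regions, data.frame(
        region_id = NA_integer_, cell_id = mm$cell_id,
        clone = unname(layout$clone_labels[mm$cell_id]),
        pixel_count = cnt, centroid_x = mm$cx, centroid_y = mm$cy,
        equivalent_radius = sqrt(cnt / pi),
        circularity = NA_real_, method = "manual",
        stringsAsFactors = FALSE))
    }
  }
  regions$area_cm2 <- region_area_cm2(regions$pixel_count, cal)
  rownames(regions) <- NULL
  regions
}

# fixed-precision CSV so repeated runs are byte-identical
.write_csv_fixed <- function(df, path, digits = 4) {
  num <- vapply(df, is.double, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf(paste0("%.", digits, "f"), x))
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a density matrix as CSV
#'
#' Clones as rows, `"T{temp}_d{day}"` columns, areas at fixed 4-decimal
#' precision.
#'
#' @param dm A [build_density_matrix()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_density_matrix_csv <- function(dm, path) {
  df <- data.frame(clone = rownames(dm), unclass(dm),
                   check.names = FALSE, stringsAsFactors = FALSE)
  .write_csv_fixed(df, path)
}

# resolve a config given as a path or list
.load_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config))
      stop("config file not found: ", config, call. = FALSE)
    config <- jsonlite::read_json(config, simplifyVector = TRUE)
  }
  stopifnot(is.list(config))
  config
}

#' Run the full screening quantification
#'
#' Orchestrates quantification over a set of plate images, one image per
#' (temperature, day) condition, and writes the tabular outputs: a
#' per-region CSV, a per-clone halo-area record CSV, the clones x
#' conditions density-matrix CSV, and a screen-summary JSON. Every
#' parameter actually used is recorded in `params.json` alongside the
#' outputs for provenance.
#'
#' The configuration (list, or path to a JSON file) has entries:
#' \describe{
#'   \item{images}{data frame / array of objects with `path`,
#'     `temperature_C`, `day`.}
#'   \item{layout}{arguments to [grid_layout()] except the image
#'     dimensions, which are taken from the first image: `n_rows`,
#'     `n_cols`, `clone_labels`, optional `origin`, `cell_size`.}
#'   \item{calibration}{`pixel_length` + `physical_length_mm`, or
#'     `mm_per_pixel`.}
#'   \item{segmentation, detection}{optional parameter overrides.}
#'   \item{manual_masks}{optional: `path`, `cell_id`, `cx`, `cy`, `r` rows
#'     applied to the matching image.}
#'   \item{n_screened}{optional clone count for the hit-rate summary;
#'     defaults to the number of labeled cells.}
#'   \item{out_dir}{output directory.}
#' }
#'
#' @param config Configuration list or JSON path.
#' @return Invisibly, a list with `regions`, `records`, `density_matrix`,
#'   `summary`, and the output paths.
#' @export
run_quantify <- function(config) {
  cfg <- .load_config(config)
  for (f in c("images", "layout", "calibration", "out_dir"))
    if (is.null(cfg[[f]]))
      stop("run_quantify: config is missing '", f, "'", call. = FALSE)
  images <- as.data.frame(cfg$images)
  stopifnot(all(c("path", "temperature_C", "day") %in% names(images)))
  missing <- images$path[!file.exists(images$path)]
  if (length(missing))
    stop("run_quantify: image file(s) not found: ",
         paste(missing, collapse = ", "), call. = FALSE)

  first <- read_plate_image(images$path[1])
  lay_args <- cfg$layout
  lay_args$image_width <- dim(first)[2]
  lay_args$image_height <- dim(first)[1]
  if (!is.null(lay_args$clone_labels))
    lay_args$clone_labels <- unlist(lay_args$clone_labels)
  layout <- do.call(grid_layout, lay_args)

  cal <- do.call(calibrate, as.list(cfg$calibration))
  seg <- do.call(segmentation_params,
                 if (is.null(cfg$segmentation)) list() else as.list(cfg$segmentation))
  det <- do.call(detection_params,
                 if (is.null(cfg$detection)) list() else as.list(cfg$detection))

  all_regions <- list()
  records <- list()
  for (i in seq_len(nrow(images))) {
    img <- if (i == 1) first else read_plate_image(images$path[i])
    mm <- NULL
    if (!is.null(cfg$manual_masks)) {
      mmall <- as.data.frame(cfg$manual_masks)
      mm <- mmall[mmall$path == images$path[i], , drop = FALSE]
      if (nrow(mm) == 0) mm <- NULL
    }
    regions <- quantify_plate(img, layout, cal, seg, det, manual_masks = mm)
    if (nrow(regions)) {
      regions$image <- images$path[i]
      regions$temperature_C <- images$temperature_C[i]
      regions$day <- images$day[i]
      all_regions[[i]] <- regions
      rec <- regions[!is.na(regions$clone), ]
      if (nrow(rec))
        records[[i]] <- data.frame(clone = rec$clone,
                                   temperature_C = rec$temperature_C,
                                   day = rec$day, area_cm2 = rec$area_cm2,
                                   stringsAsFactors = FALSE)
    }
  }
  regions <- if (length(all_regions)) do.call(rbind, all_regions) else
    data.frame()
  records <- if (length(records)) do.call(rbind, records) else
    data.frame(clone = character(), temperature_C = numeric(),
               day = numeric(), area_cm2 = numeric(),
               stringsAsFactors = FALSE)

  clones <- sort(unique(stats::na.omit(unname(layout$clone_labels))))
  conditions <- unique(images[, c("temperature_C", "day")])
  dm <- build_density_matrix(records, clones, conditions)
  positives <- rownames(dm)[rowSums(unclass(dm)) > 0]
  n_screened <- if (!is.null(cfg$n_screened)) cfg$n_screened else length(clones)
  summary <- summarize_screen(n_screened, positives)

  out <- cfg$out_dir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  paths <- list(regions = file.path(out, "regions.csv"),
                records = file.path(out, "records.csv"),
                density_matrix = file.path(out, "density_matrix.csv"),
                summary = file.path(out, "summary.json"),
                params = file.path(out, "params.json"))
  if (nrow(regions))
    .write_csv_fixed(regions[, c("image", "temperature_C", "day", "region_id",
                                 "cell_id", "clone", "pixel_count",
                                 "centroid_x", "centroid_y", "circularity",
                                 "method", "area_cm2")], paths$regions)
  else .write_csv_fixed(regions, paths$regions)
  .write_csv_fixed(records, paths$records)
  write_density_matrix_csv(dm, paths$density_matrix)
  jsonlite::write_json(unclass(summary), paths$summary, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  jsonlite::write_json(list(segmentation = unclass(seg),
                            detection = unclass(det),
                            calibration = unclass(cal),
                            layout = list(n_rows = layout$n_rows,
                                          n_cols = layout$n_cols,
                                          origin = layout$origin,
                                          cell_size = layout$cell_size),
                            images = images),
                       paths$params, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(list(regions = regions, records = records, density_matrix = dm,
                 summary = summary, paths = paths))
}
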