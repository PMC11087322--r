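# Synthetic plate generator: renders back-lit agar plates with grid lines
# and disk-shaped halos of known CIELAB color, plus the ground truth needed
# to score the detection pipeline.

#' Describe a synthetic plate
#'
#' Parametric description of a simulated back-lit plate: a uniform agar
#' background (optionally with a linear illumination ramp on L*), thin blue
#' grid lines at a known pixel and physical spacing dividing the plate into
#' square cells, disk-shaped halos rendered from target CIELAB values, and
#' additive Gaussian sensor noise on the encoded 8-bit channels.
#'
#' Defaults mirror the screening setup the generator emulates: a 20-cell
#' grid (5 rows x 4 columns) of 13 mm squares — room for 12 positive and 8
#' control clones — imaged at 100 px per square (0.13 mm/px), an agar
#' background that is bright and faintly yellow, and halos drawn at b*
#' values inside the blue detection band.
#'
#' @param width,height Image size in pixels.
#' @param background_lab `c(L, a, b)` of the agar background.
#' @param grid_spacing_px Pixels between consecutive grid lines (cell side).
#' @param grid_spacing_mm Physical spacing of the grid lines in mm.
#' @param grid_color_lab `c(L, a, b)` of the grid lines. The default is a
#'   deep blue (b* = -40) that falls outside the default detection band, as
#'   drawn pen lines typically do.
#' @param line_width_px Grid line width in pixels (<= 2 recommended).
#' @param halos Data frame with columns `cell_id`, `center_x`, `center_y`,
#'   `radius_px`, `target_b`, `halo_L` (one row per halo). Each disk must
#'   lie inside its cell, clear of the grid lines.
#' @param noise_sigma SD of additive Gaussian noise on the 8-bit channels.
#' @param gradient_amplitude Peak-to-peak linear ramp added to L* across the
#'   image width (0 = perfectly uniform back-lighting).
#' @return A `plate_spec` object.
#' @export
synthetic_plate_spec <- function(width = 400, height = 500,
                                 background_lab = c(82, 2, 8),
                                 grid_spacing_px = 100,
                                 grid_spacing_mm = 13,
                                 grid_color_lab = c(45, 15, -40),
                                 line_width_px = 2,
                                 halos = NULL,
                                 noise_sigma = 0,
                                 gradient_amplitude = 0) {
  stopifnot(width >= 1, height >= 1, grid_spacing_px > 0,
            grid_spacing_mm > 0, line_width_px >= 0, noise_sigma >= 0)
  if (is.null(halos))
    halos <- data.frame(cell_id = character(), center_x = numeric(),
                        center_y = numeric(), radius_px = numeric(),
                        target_b = numeric(), halo_L = numeric(),
                        stringsAsFactors = FALSE)
  need <- c("cell_id", "center_x", "center_y", "radius_px", "target_b",
            "halo_L")
  if (!all(need %in% names(halos)))
    stop("synthetic_plate_spec: halos needs columns ",
         paste(need, collapse = ", "), call. = FALSE)
  if (any(halos$radius_px <= 0))
    stop("synthetic_plate_spec: halo radii must be > 0", call. = FALSE)
  spec <- structure(list(width = as.integer(width),
                         height = as.integer(height),
                         background_lab = as.numeric(background_lab),
                         grid_spacing_px = grid_spacing_px,
                         grid_spacing_mm = grid_spacing_mm,
                         grid_color_lab = as.numeric(grid_color_lab),
                         line_width_px = line_width_px,
                         halos = halos,
                         noise_sigma = noise_sigma,
                         gradient_amplitude = gradient_amplitude),
                    class = "plate_spec")
  lay <- plate_layout(spec)
  for (k in seq_len(nrow(halos))) {
    h <- halos[k, ]
    if (h$center_x - h$radius_px < 0 || h$center_x + h$radius_px > width ||
        h$center_y - h$radius_px < 0 || h$center_y + h$radius_px > height)
      stop("synthetic_plate_spec: halo ", k, " extends outside the image",
           call. = FALSE)
    b <- cell_bounds(lay, h$cell_id)
    m <- line_width_px  # keep disks clear of the cell-edge grid lines
    if (h$center_x - h$radius_px < b[1] + m || h$center_x + h$radius_px > b[3] - m ||
        h$center_y - h$radius_px < b[2] + m || h$center_y + h$radius_px > b[4] - m)
      stop("synthetic_plate_spec: halo ", k, " does not fit inside cell ",
           h$cell_id, call. = FALSE)
  }
  spec
}

#' Grid layout implied by a plate spec
#'
#' @param spec A [synthetic_plate_spec()].
#' @param clone_labels Optional clone labels passed to [grid_layout()].
#' @return A [grid_layout()] with square cells of `grid_spacing_px`.
#' @export
plate_layout <- function(spec, clone_labels = NULL) {
  stopifnot(inherits(spec, "plate_spec"))
  grid_layout(n_rows = floor(spec$height / spec$grid_spacing_px),
              n_cols = floor(spec$width / spec$grid_spacing_px),
              image_width = spec$width, image_height = spec$height,
              clone_labels = clone_labels,
              cell_size = c(spec$grid_spacing_px, spec$grid_spacing_px))
}

# run expr with a fixed RNG state, restoring the caller's state afterwards
.with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit(if (has) assign(".Random.seed", old, envir = globalenv())
          else suppressWarnings(rm(".Random.seed", envir = globalenv())))
  set.seed(seed)
  expr
}

#' Render a synthetic plate image with ground truth
#'
#' Deterministic for a fixed `(spec, seed)` pair: the scene (background,
#' grid lines, halos, illumination ramp) is composed in CIELAB, encoded to
#' 8-bit sRGB, and Gaussian sensor noise is added last on the encoded
#' channels. The ground truth reflects the noise-free halo geometry, so
#' distinct seeds change only the noise.
#'
#' @param spec A [synthetic_plate_spec()].
#' @param seed Integer seed for the noise.
#' @return List with components `image` (an [rgb_image()]), and
#'   `ground_truth`: a list of `mask` (logical matrix of true halo pixels),
#'   `halos` (data frame with true `pixel_count` and `area_cm2` per halo),
#'   `calibration` (a [calibrate()] record from the grid spacing), and
#'   `layout` (the implied [grid_layout()]).
#' @export
generate_plate <- function(spec, seed = 1L) {
  stopifnot(inherits(spec, "plate_spec"))
  w <- spec$width; h <- spec$height
  canvas <- array(0, c(h, w, 3))
  canvas[, , 1] <- spec$background_lab[1]
  canvas[, , 2] <- spec$background_lab[2]
  canvas[, , 3] <- spec$background_lab[3]

  # grid lines at every multiple of the spacing, both orientations
  if (spec$line_width_px > 0) {
    centers_v <- seq(0, w, by = spec$grid_spacing_px)
    centers_h <- seq(0, h, by = spec$grid_spacing_px)
    xc <- seq_len(w) - 0.5
    yc <- seq_len(h) - 0.5
    on_line <- function(coord, centers)
      Reduce(`|`, lapply(centers, function(c0)
        coord >= c0 - spec$line_width_px / 2 &
        coord < c0 + spec$line_width_px / 2))
    line_mask <- outer(on_line(yc, centers_h), rep(TRUE, w), `&`) |
                 outer(rep(TRUE, h), on_line(xc, centers_v), `&`)
    for (p in 1:3) {
      plane <- canvas[, , p]
      plane[line_mask] <- spec$grid_color_lab[p]
      canvas[, , p] <- plane
    }
  }

  gt_mask <- matrix(FALSE, h, w)
  cal <- calibrate(pixel_length = spec$grid_spacing_px,
                   physical_length_mm = spec$grid_spacing_mm)
  halos <- spec$halos
  halos$pixel_count <- integer(nrow(halos))
  for (k in seq_len(nrow(halos))) {
    disk <- rasterize_disk(w, h, c(halos$center_x[k], halos$center_y[k]),
                           halos$radius_px[k])
    for (p in 1:3) {
      plane <- canvas[, , p]
      plane[disk] <- c(halos$halo_L[k], 0, halos$target_b[k])[p]
      canvas[, , p] <- plane
    }
    gt_mask <- gt_mask | disk
    halos$pixel_count[k] <- sum(disk)
  }
  halos$area_cm2 <- region_area_cm2(halos$pixel_count, cal)

  if (spec$gradient_amplitude != 0) {
    ramp <- spec$gradient_amplitude * ((seq_len(w) - 0.5) / w - 0.5)
    canvas[, , 1] <- sweep(canvas[, , 1], 2, ramp, `+`)
  }

  img <- lab_to_srgb(structure(canvas, class = "lab_image"))
  if (spec$noise_sigma > 0) {
    noisy <- .with_seed(seed, {
      unclass(img) + stats::rnorm(length(img), sd = spec$noise_sigma)
    })
    img <- rgb_image(array(pmin(pmax(round(noisy), 0), 255), dim(noisy)))
  }

  list(image = img,
       ground_truth = list(mask = gt_mask, halos = halos, calibration = cal,
                           layout = plate_layout(spec)))
}

#' Read a plate spec from JSON
#'
#' @param path JSON file with the fields of [synthetic_plate_spec()]
#'   (`halos` as an array of objects).
#' @return A `plate_spec`.
#' @export
read_plate_spec <- function(path) {
  if (!file.exists(path)) stop("cannot read spec: ", path, call. = FALSE)
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!is.null(j$halos) && length(j$halos)) j$halos <- as.data.frame(j$halos)
  else j$halos <- NULL
  do.call(synthetic_plate_spec, j)
}

#' Write ground truth as JSON plus a PNG mask
#'
#' @param gt The `ground_truth` component of [generate_plate()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, the paths written.
#' @export
write_ground_truth <- function(gt, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  jpath <- file.path(dir, "ground_truth.json")
  mpath <- file.path(dir, "true_mask.png")
  jsonlite::write_json(
    list(mm_per_pixel = gt$calibration$mm_per_pixel, halos = gt$halos),
    jpath, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  write_plate_png(gt$mask, mpath)
  invisible(c(jpath, mpath))
}
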