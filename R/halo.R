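# Blue-halo segmentation and rounded-region detection.
#
# Pixel geometry convention: the R matrix element [i, j] (1-based) is the
# pixel whose center sits at continuous coordinates (x, y) = (j - 0.5,
# i - 0.5), i.e. the image occupies [0, width) x [0, height) with the origin
# at the top-left corner. Membership of a pixel in a circle or cell is
# decided by its center.

#' Segmentation parameters for the blue b* band
#'
#' A pixel is scored positive when its b* falls strictly inside
#' `(b_lo, b_hi)`. The defaults are the blue band of an azurine-dye halo on
#' a back-lit plate: `-20 < b* < -5`, more negative being bluer. Whether
#' pixels bluer than `b_lo` should also count is data-dependent;
#' `extend_blue = TRUE` drops the lower bound (positive iff `b* < b_hi`).
#'
#' @param b_lo Lower b* bound (exclusive). Default -20.
#' @param b_hi Upper b* bound (exclusive); must satisfy `b_lo < b_hi <= 0`.
#'   Default -5.
#' @param extend_blue If `TRUE`, ignore `b_lo` and accept every pixel with
#'   `b* < b_hi`.
#' @return A `segmentation_params` list.
#' @export
segmentation_params <- function(b_lo = -20, b_hi = -5, extend_blue = FALSE) {
  stopifnot(is.numeric(b_lo), is.numeric(b_hi), length(b_lo) == 1L,
            length(b_hi) == 1L)
  if (!(b_lo < b_hi) || b_hi > 0)
    stop("segmentation_params: need b_lo < b_hi <= 0", call. = FALSE)
  structure(list(b_lo = b_lo, b_hi = b_hi,
                 extend_blue = isTRUE(extend_blue)),
            class = "segmentation_params")
}

#' Detection parameters for rounded regions
#'
#' @param min_area_px Minimum region size in pixels; smaller components are
#'   treated as noise.
#' @param min_circularity Minimum circularity `4*pi*A / P^2` (1 for a disk);
#'   default 0.6 keeps rasterized disks and rejects elongated shapes such as
#'   grid lines.
#' @param closing_radius_px Radius of the morphological closing applied
#'   before labeling, to bridge noise-induced dropouts.
#' @param max_hole_frac Holes (enclosed background) up to this fraction of
#'   their surrounding region's area are filled before measuring. Sensor
#'   dropouts inside a halo are small relative to the halo and get filled;
#'   the plate cells enclosed by a blue grid-line lattice are much larger
#'   than the lattice itself and are left open, so the lattice cannot be
#'   flooded into a solid false positive.
#' @return A `detection_params` list.
#' @export
detection_params <- function(min_area_px = 50L, min_circularity = 0.6,
                             closing_radius_px = 2L, max_hole_frac = 0.5) {
  if (min_area_px < 1) stop("min_area_px must be >= 1", call. = FALSE)
  if (min_circularity <= 0 || min_circularity > 1)
    stop("min_circularity must be in (0, 1]", call. = FALSE)
  if (closing_radius_px < 0) stop("closing_radius_px must be >= 0", call. = FALSE)
  if (max_hole_frac < 0) stop("max_hole_frac must be >= 0", call. = FALSE)
  structure(list(min_area_px = as.integer(min_area_px),
                 min_circularity = min_circularity,
                 closing_radius_px = as.integer(closing_radius_px),
                 max_hole_frac = max_hole_frac),
            class = "detection_params")
}

#' Threshold the b* channel into a binary positive-response mask
#'
#' @param lab A `lab_image` from [srgb_to_lab()].
#' @param params A [segmentation_params()].
#' @return Logical matrix (height x width), `TRUE` for positive pixels.
#' @export
blue_mask <- function(lab, params = segmentation_params()) {
  if (!inherits(lab, "lab_image"))
    stop("blue_mask: expected a lab_image", call. = FALSE)
  if (!inherits(params, "segmentation_params"))
    params <- do.call(segmentation_params, params)
  b <- lab[, , 3]
  if (params$extend_blue) b < params$b_hi
  else b > params$b_lo & b < params$b_hi
}

# Shift a matrix by (di, dj), padding with `fill`.
.shift_mat <- function(m, di, dj, fill = FALSE) {
  out <- matrix(fill, nrow(m), ncol(m))
  si <- seq_len(nrow(m)); sj <- seq_len(ncol(m))
  ti <- si - di; tj <- sj - dj
  ok_i <- ti >= 1 & ti <= nrow(m); ok_j <- tj >= 1 & tj <= ncol(m)
  out[si[ok_i], sj[ok_j]] <- m[ti[ok_i], tj[ok_j]]
  out
}

# 8-connected labeling: EBImage::bwlabel is 4-connected, so labels touching
# only diagonally are merged afterwards with a small union-find over labels.
.label8 <- function(mask) {
  lab <- EBImage::bwlabel(EBImage::Image(t(mask)))
  lab <- t(EBImage::imageData(lab))
  storage.mode(lab) <- "integer"
  n <- max(lab)
  if (n < 2) return(lab)
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) { parent[i] <<- parent[parent[i]]; i <- parent[i] }; i }
  for (d in list(c(1, 1), c(1, -1))) {
    s <- .shift_mat(lab, d[1], d[2], 0L)
    sel <- lab > 0L & s > 0L & lab != s
    if (any(sel)) {
      pairs <- unique(cbind(lab[sel], s[sel]))
      storage.mode(pairs) <- "integer"
      for (k in seq_len(nrow(pairs))) {
        a <- find(pairs[k, 1]); b <- find(pairs[k, 2])
        if (a != b) parent[max(a, b)] <- min(a, b)
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  relab <- match(root, sort(unique(root)))
  out <- lab
  out[lab > 0] <- relab[lab[lab > 0]]
  out
}

# Fill enclosed background regions (4-connected holes in the 8-connected
# foreground) whose area is at most `frac` times the area of the component
# that surrounds them; filled pixels inherit that component's label.
.fill_small_holes <- function(lab, frac) {
  if (frac <= 0) return(lab)
  bg <- lab == 0L
  bglab <- EBImage::bwlabel(EBImage::Image(t(bg)))  # 4-connected
  bglab <- t(EBImage::imageData(bglab))
  storage.mode(bglab) <- "integer"
  border <- unique(c(bglab[1, ], bglab[nrow(bglab), ],
                     bglab[, 1], bglab[, ncol(bglab)]))
  holes <- setdiff(seq_len(max(bglab)), border)
  if (!length(holes)) return(lab)
  fg_area <- tabulate(lab[lab > 0L], nbins = max(lab))
  # label of the strongest foreground neighbor at each pixel
  nb <- matrix(0L, nrow(lab), ncol(lab))
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    nb <- pmax(nb, .shift_mat(lab, d[1], d[2], 0L))
  hole_area <- tabulate(bglab[bglab > 0L], nbins = max(bglab))
  for (h in holes) {
    sel <- bglab == h
    owner <- nb[sel]
    owner <- owner[owner > 0L]
    if (!length(owner)) next
    own <- as.integer(names(which.max(table(owner))))
    if (hole_area[h] <= frac * fg_area[own]) lab[sel] <- own
  }
  lab
}

# Perimeter estimate: count exposed pixel edge faces (Manhattan boundary
# length) and scale by pi/4, the Cauchy-Crofton factor that makes the
# estimate unbiased for smooth convex outlines averaged over orientation.
# Returns a vector indexed by label.
.label_perimeter <- function(lab, n) {
  edges <- numeric(n)
  for (d in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1))) {
    s <- .shift_mat(lab, d[1], d[2], 0)
    exposed <- lab > 0 & s != lab
    edges <- edges + tabulate(lab[exposed], nbins = n)
  }
  edges * pi / 4
}

#' Detect rounded halo regions in a binary mask
#'
#' Applies morphological closing, labels 8-connected components, fills
#' small enclosed holes (see `max_hole_frac` in [detection_params()]),
#' discards components smaller than `min_area_px` or with circularity
#' `4*pi*A/P^2` below `min_circularity`, assigns each survivor
#' to the grid cell containing its centroid, and keeps at most one region
#' per cell (largest pixel count wins; discarded extras are messaged).
#'
#' @param mask Logical matrix from [blue_mask()].
#' @param layout A [grid_layout()] matching the mask dimensions, or `NULL`
#'   to skip cell assignment.
#' @param params A [detection_params()].
#' @return Data frame with one row per retained region: `region_id`,
#'   `cell_id`, `clone`, `pixel_count`, `centroid_x`, `centroid_y`,
#'   `equivalent_radius`, `circularity`. Empty mask gives zero rows.
#' @export
detect_halos <- function(mask, layout = NULL, params = detection_params()) {
  stopifnot(is.logical(mask), is.matrix(mask))
  if (!inherits(params, "detection_params"))
    params <- do.call(detection_params, params)
  if (!is.null(layout)) {
    if (!inherits(layout, "grid_layout"))
      stop("detect_halos: layout must be a grid_layout", call. = FALSE)
    if (layout$image_width != ncol(mask) || layout$image_height != nrow(mask))
      stop("detect_halos: layout dimensions do not match the mask",
           call. = FALSE)
  }
  empty <- data.frame(region_id = integer(), cell_id = character(),
                      clone = character(), pixel_count = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      equivalent_radius = numeric(), circularity = numeric(),
                      stringsAsFactors = FALSE)
  if (!any(mask)) return(empty)

  m <- EBImage::Image(t(mask))
  if (params$closing_radius_px > 0) {
    brush <- EBImage::makeBrush(2L * params$closing_radius_px + 1L, "disc")
    m <- EBImage::closing(m, brush)
  }
  lab <- .label8(t(EBImage::imageData(m)) > 0)
  n <- max(lab)
  if (n == 0) return(empty)
  lab <- .fill_small_holes(lab, params$max_hole_frac)

  idx <- which(lab > 0, arr.ind = TRUE)
  lv <- lab[lab > 0]
  area <- tabulate(lv, nbins = n)
  cx <- tapply(idx[, 2] - 0.5, lv, mean)   # pixel centers, 0-based coords
  cy <- tapply(idx[, 1] - 0.5, lv, mean)
  perim <- .label_perimeter(lab, n)
  circ <- 4 * pi * area / perim^2

  keep <- area >= params$min_area_px & circ >= params$min_circularity
  if (!any(keep)) return(empty)
  regions <- data.frame(
    region_id = seq_len(n)[keep],
    cell_id = NA_character_,
    clone = NA_character_,
    pixel_count = area[keep],
    centroid_x = as.numeric(cx[keep]),
    centroid_y = as.numeric(cy[keep]),
    equivalent_radius = sqrt(area[keep] / pi),
    circularity = circ[keep],
    stringsAsFactors = FALSE
  )

  if (!is.null(layout)) {
    regions$cell_id <- cell_at(layout, regions$centroid_x, regions$centroid_y)
    regions$clone <- unname(layout$clone_labels[regions$cell_id])
    # at most one region per cell: largest pixel_count, then lowest id
    ranked <- regions[order(-regions$pixel_count, regions$region_id), ]
    dup <- !is.na(ranked$cell_id) & duplicated(ranked$cell_id)
    if (any(dup))
      message(sum(dup), " extra region(s) dropped (one halo kept per cell)")
    regions <- ranked[!dup, ]
    regions <- regions[order(regions$region_id), ]
  }
  rownames(regions) <- NULL
  regions
}

#' Count positive pixels inside a circular mask
#'
#' Mirrors the manual measurement mode: a circle of given center and radius
#' is laid over the mask and positive pixels whose centers fall inside
#' (distance <= r) are counted.
#'
#' @param mask Logical matrix.
#' @param center Numeric `c(x, y)` in pixel coordinates (origin top-left).
#' @param radius Circle radius in pixels, > 0.
#' @return Integer pixel count.
#' @export
pixel_count_in_circle <- function(mask, center, radius) {
  stopifnot(is.logical(mask), is.matrix(mask), length(center) == 2L)
  if (!is.finite(radius) || radius <= 0)
    stop("pixel_count_in_circle: radius must be > 0", call. = FALSE)
  w <- ncol(mask); h <- nrow(mask)
  if (center[1] + radius <= 0 || center[1] - radius >= w ||
      center[2] + radius <= 0 || center[2] - radius >= h)
    stop("pixel_count_in_circle: circle does not intersect the image",
         call. = FALSE)
  # restrict to the bounding box to stay cheap on large images
  j0 <- max(1L, floor(center[1] - radius)); j1 <- min(w, ceiling(center[1] + radius) + 1L)
  i0 <- max(1L, floor(center[2] - radius)); i1 <- min(h, ceiling(center[2] + radius) + 1L)
  jj <- j0:j1; ii <- i0:i1
  sub <- mask[ii, jj, drop = FALSE]
  dx2 <- outer(rep(1, length(ii)), (jj - 0.5 - center[1])^2)
  dy2 <- outer((ii - 0.5 - center[2])^2, rep(1, length(jj)))
  sum(sub & (dx2 + dy2 <= radius^2))
}

#' Rasterize a disk onto a pixel grid
#'
#' Marks every pixel whose center lies within `radius` of `center`. Used by
#' the synthetic generator and handy for constructing reference masks.
#'
#' @param width,height Image dimensions in pixels.
#' @param center Numeric `c(x, y)`.
#' @param radius Radius in pixels.
#' @return Logical matrix (height x width).
#' @export
rasterize_disk <- function(width, height, center, radius) {
  x <- (seq_len(width) - 0.5) - center[1]
  y <- (seq_len(height) - 0.5) - center[2]
  outer(y^2, x^2, `+`) <= radius^2
}
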