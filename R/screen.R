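# Plate grid layout, density matrix, clone ranking, and screen summary.

#' Define the plate's cell grid
#'
#' The plate region is divided into an `n_rows` x `n_cols` grid of equal
#' rectangular cells (half-open pixel rectangles, 0-based), each optionally
#' labeled with a clone name. Cell ids are `"r{row}c{col}"`, row-major from
#' the top-left.
#'
#' @param n_rows,n_cols Grid dimensions (>= 1).
#' @param image_width,image_height Image dimensions in pixels.
#' @param clone_labels Character vector of clone names, either named by cell
#'   id or of length `n_rows * n_cols` in row-major order (NA for unused
#'   cells).
#' @param origin Pixel `c(x, y)` of the grid's top-left corner; default
#'   `c(0, 0)`.
#' @param cell_size Pixel `c(width, height)` of one cell; default fills the
#'   image evenly.
#' @return A `grid_layout` object.
#' @export
grid_layout <- function(n_rows, n_cols, image_width, image_height,
                        clone_labels = NULL, origin = c(0, 0),
                        cell_size = NULL) {
  stopifnot(n_rows >= 1, n_cols >= 1, image_width >= 1, image_height >= 1)
  if (is.null(cell_size))
    cell_size <- c((image_width - origin[1]) / n_cols,
                   (image_height - origin[2]) / n_rows)
  ids <- as.vector(t(outer(seq_len(n_rows), seq_len(n_cols),
                           function(r, c) sprintf("r%dc%d", r, c))))
  labels <- rep(NA_character_, length(ids)); names(labels) <- ids
  if (!is.null(clone_labels)) {
    if (!is.null(names(clone_labels))) {
      unknown <- setdiff(names(clone_labels), ids)
      if (length(unknown))
        stop("grid_layout: labels for nonexistent cells: ",
             paste(unknown, collapse = ", "), call. = FALSE)
      labels[names(clone_labels)] <- clone_labels
    } else {
      if (length(clone_labels) != length(ids))
        stop("grid_layout: unnamed clone_labels must have length n_rows*n_cols",
             call. = FALSE)
      labels[] <- clone_labels
    }
  }
  structure(list(n_rows = as.integer(n_rows), n_cols = as.integer(n_cols),
                 image_width = as.integer(image_width),
                 image_height = as.integer(image_height),
                 origin = as.numeric(origin),
                 cell_size = as.numeric(cell_size),
                 cell_ids = ids, clone_labels = labels),
            class = "grid_layout")
}

#' @export
print.grid_layout <- function(x, ...) {
  cat(sprintf("<grid_layout %d x %d cells over %d x %d px, %d labeled>\n",
              x$n_rows, x$n_cols, x$image_width, x$image_height,
              sum(!is.na(x$clone_labels))))
  invisible(x)
}

#' Cell id at a pixel coordinate
#'
#' @param layout A [grid_layout()].
#' @param x,y Pixel coordinates (vectorized, origin top-left).
#' @return Character vector of cell ids; `NA` outside the grid.
#' @export
cell_at <- function(layout, x, y) {
  col <- floor((x - layout$origin[1]) / layout$cell_size[1]) + 1
  row <- floor((y - layout$origin[2]) / layout$cell_size[2]) + 1
  ok <- col >= 1 & col <= layout$n_cols & row >= 1 & row <= layout$n_rows
  out <- rep(NA_character_, length(x))
  out[ok] <- sprintf("r%dc%d", row[ok], col[ok])
  out
}

#' Pixel bounds of a cell
#'
#' @param layout A [grid_layout()].
#' @param cell_id Cell id such as `"r2c3"`.
#' @return Numeric `c(x0, y0, x1, y1)`, half-open.
#' @export
cell_bounds <- function(layout, cell_id) {
  m <- regmatches(cell_id, regexec("^r([0-9]+)c([0-9]+)$", cell_id))[[1]]
  if (length(m) != 3L) stop("bad cell id: ", cell_id, call. = FALSE)
  r <- as.integer(m[2]); c <- as.integer(m[3])
  if (r < 1 || r > layout$n_rows || c < 1 || c > layout$n_cols)
    stop("cell out of range: ", cell_id, call. = FALSE)
  c(layout$origin[1] + (c - 1) * layout$cell_size[1],
    layout$origin[2] + (r - 1) * layout$cell_size[2],
    layout$origin[1] + c * layout$cell_size[1],
    layout$origin[2] + r * layout$cell_size[2])
}

# round halves away from zero (the reporting convention for percentages),
# not banker's rounding
.round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5) / p
}

#' Assemble halo-area records into a clones x conditions density matrix
#'
#' @param records Data frame with columns `clone`, `temperature_C`, `day`,
#'   `area_cm2` (one row per measured halo; absent combinations mean no
#'   halo).
#' @param clones Ordered character vector of clone labels (matrix rows).
#' @param conditions Data frame with columns `temperature_C` and `day`
#'   (matrix columns, in order).
#' @return A `density_matrix`: numeric matrix with `clones` as rownames and
#'   `"T{temp}_d{day}"` colnames, zero where no halo was recorded, with the
#'   conditions stored as an attribute.
#' @export
build_density_matrix <- function(records, clones, conditions) {
  stopifnot(is.data.frame(conditions),
            all(c("temperature_C", "day") %in% names(conditions)))
  cond_id <- sprintf("T%g_d%g", conditions$temperature_C, conditions$day)
  if (anyDuplicated(cond_id))
    stop("build_density_matrix: duplicated conditions", call. = FALSE)
  if (anyDuplicated(clones))
    stop("build_density_matrix: duplicated clone labels", call. = FALSE)
  dm <- matrix(0, length(clones), length(cond_id),
               dimnames = list(clones, cond_id))
  if (nrow(records) > 0) {
    stopifnot(all(c("clone", "temperature_C", "day", "area_cm2")
                  %in% names(records)))
    if (any(!records$clone %in% clones))
      stop("build_density_matrix: unknown clone(s): ",
           paste(unique(setdiff(records$clone, clones)), collapse = ", "),
           call. = FALSE)
    rid <- sprintf("T%g_d%g", records$temperature_C, records$day)
    if (any(!rid %in% cond_id))
      stop("build_density_matrix: record outside declared conditions: ",
           paste(unique(setdiff(rid, cond_id)), collapse = ", "),
           call. = FALSE)
    key <- paste(records$clone, rid)
    if (anyDuplicated(key))
      stop("build_density_matrix: duplicate (clone, condition) record: ",
           key[duplicated(key)][1], call. = FALSE)
    if (any(!is.finite(records$area_cm2)) || any(records$area_cm2 < 0))
      stop("build_density_matrix: areas must be finite and >= 0",
           call. = FALSE)
    dm[cbind(match(records$clone, clones), match(rid, cond_id))] <-
      records$area_cm2
  }
  structure(dm, conditions = conditions, class = c("density_matrix", "matrix"))
}

#' Rank clones by breadth and size of response
#'
#' Implements the screening selection rule: on a given incubation day, tier
#' 1 contains the clones showing a halo (area > 0) at *all* requested
#' temperatures — the fast, broad responders; every other clone is tier 2.
#' Within a tier, clones are ordered by descending total area over the
#' requested conditions, with ties broken alphabetically, so the ranking is
#' deterministic.
#'
#' @param dm A [build_density_matrix()] result.
#' @param day Incubation day to rank on.
#' @param temperatures Numeric vector of temperatures that tier-1 clones
#'   must all respond at.
#' @return Data frame `clone`, `tier` (1 or 2), `total_area_cm2`, `rank`.
#' @export
rank_clones <- function(dm, day, temperatures) {
  stopifnot(inherits(dm, "density_matrix"))
  wanted <- sprintf("T%g_d%g", temperatures, day)
  missing <- setdiff(wanted, colnames(dm))
  if (length(missing))
    stop("rank_clones: condition(s) absent from matrix: ",
         paste(missing, collapse = ", "), call. = FALSE)
  sub <- unclass(dm)[, wanted, drop = FALSE]
  tier <- ifelse(apply(sub > 0, 1, all), 1L, 2L)
  total <- rowSums(sub)
  ord <- order(tier, -total, rownames(dm))
  out <- data.frame(clone = rownames(dm)[ord], tier = tier[ord],
                    total_area_cm2 = unname(total[ord]),
                    rank = seq_len(nrow(dm)),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Summarize a screen as a hit rate
#'
#' @param n_screened Number of clones evaluated (> 0).
#' @param positive_clones Character vector of positive clone labels (or an
#'   integer count).
#' @return A `screen_summary` list: `n_screened`, `n_positive`,
#'   `positive_clones`, and `hit_rate_percent` (one decimal, halves rounded
#'   away from zero).
#' @examples
#' summarize_screen(563, sprintf("LP%d", 1:12))$hit_rate_percent  # 2.1
#' @export
summarize_screen <- function(n_screened, positive_clones) {
  if (!is.finite(n_screened) || n_screened <= 0)
    stop("summarize_screen: n_screened must be positive", call. = FALSE)
  if (is.numeric(positive_clones) && length(positive_clones) == 1L) {
    n_pos <- as.integer(positive_clones)
    positive_clones <- character(0)
  } else {
    if (anyDuplicated(positive_clones))
      stop("summarize_screen: duplicated positive clone labels", call. = FALSE)
    n_pos <- length(positive_clones)
  }
  if (n_pos > n_screened)
    stop("summarize_screen: more positives than screened clones", call. = FALSE)
  structure(list(n_screened = as.integer(n_screened), n_positive = n_pos,
                 positive_clones = positive_clones,
                 hit_rate_percent = .round_half_up(100 * n_pos / n_screened, 1)),
            class = "screen_summary")
}

#' @export
print.screen_summary <- function(x, ...) {
  cat(sprintf("%d / %d clones positive (%.1f%%)\n",
              x$n_positive, x$n_screened, x$hit_rate_percent))
  invisible(x)
}
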