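# Independent scalar oracles, coded separately from the package internals
# so agreement is a real check and not a tautology.

# Scalar sRGB (0..255) -> CIELAB, using the eps/kappa formulation of the
# CIE 1976 functions (mathematically equivalent to the rational-constant
# piecewise form, but a different code path).
oracle_srgb_to_lab <- function(rgb) {
  lin <- numeric(3)
  for (i in 1:3) {
    c <- rgb[i] / 255
    lin[i] <- if (c <= 0.04045) c / 12.92 else ((c + 0.055) / 1.055)^2.4
  }
  X <- 0.4124564 * lin[1] + 0.3575761 * lin[2] + 0.1804375 * lin[3]
  Y <- 0.2126729 * lin[1] + 0.7151522 * lin[2] + 0.0721750 * lin[3]
  Z <- 0.0193339 * lin[1] + 0.1191920 * lin[2] + 0.9503041 * lin[3]
  eps <- 216 / 24389
  kappa <- 24389 / 27
  f <- function(t) if (t > eps) t^(1 / 3) else (kappa * t + 16) / 116
  fx <- f(X * 100 / 95.047)
  fy <- f(Y * 100 / 100.000)
  fz <- f(Z * 100 / 108.883)
  c(L = 116 * fy - 16, a = 500 * (fx - fy), b = 200 * (fy - fz))
}

# Brute-force count of pixels whose center lies within `radius` of `center`
# on a width x height grid (double loop; no shared code with the package).
oracle_disk_pixel_count <- function(width, height, center, radius) {
  n <- 0L
  for (i in seq_len(height)) {
    for (j in seq_len(width)) {
      dx <- (j - 0.5) - center[1]
      dy <- (i - 0.5) - center[2]
      if (dx * dx + dy * dy <= radius * radius) n <- n + 1L
    }
  }
  n
}

# Brute-force 8-connected component labeling by flood fill (small masks).
oracle_label8 <- function(mask) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  cur <- 0L
  for (i0 in seq_len(nrow(mask))) for (j0 in seq_len(ncol(mask))) {
    if (mask[i0, j0] && lab[i0, j0] == 0L) {
      cur <- cur + 1L
      stack <- list(c(i0, j0))
      while (length(stack)) {
        p <- stack[[length(stack)]]
        stack[[length(stack)]] <- NULL
        if (p[1] < 1 || p[1] > nrow(mask) || p[2] < 1 || p[2] > ncol(mask))
          next
        if (!mask[p[1], p[2]] || lab[p[1], p[2]] != 0L) next
        lab[p[1], p[2]] <- cur
        for (di in -1:1) for (dj in -1:1)
          if (di || dj) stack[[length(stack) + 1L]] <- c(p[1] + di, p[2] + dj)
      }
    }
  }
  lab
}

# random full ORF: start codon, n-1 non-stop codons, one stop codon
random_orf <- function(n_codons) {
  sense <- setdiff(names(haloquant:::.codon_table), c("TAA", "TAG", "TGA"))
  paste(c("ATG", sample(sense, n_codons - 1, replace = TRUE),
          sample(c("TAA", "TAG", "TGA"), 1)), collapse = "")
}

# A standard 12-clone plate spec: 4 rows x 3 cols of 100 px (13 mm) cells,
# one halo per requested cell at the cell center.
make_screen_spec <- function(radii, target_b, halo_L = 58,
                             noise_sigma = 0, cells = NULL, ...) {
  n_rows <- 4; n_cols <- 3
  if (is.null(cells)) {
    rc <- expand.grid(c = seq_len(n_cols), r = seq_len(n_rows))
    cells <- sprintf("r%dc%d", rc$r, rc$c)[seq_along(radii)]
  }
  m <- regmatches(cells, regexec("^r([0-9]+)c([0-9]+)$", cells))
  rr <- vapply(m, function(x) as.integer(x[2]), 1L)
  cc <- vapply(m, function(x) as.integer(x[3]), 1L)
  halos <- data.frame(cell_id = cells,
                      center_x = (cc - 0.5) * 100,
                      center_y = (rr - 0.5) * 100,
                      radius_px = radii,
                      target_b = rep_len(target_b, length(radii)),
                      halo_L = rep_len(halo_L, length(radii)),
                      stringsAsFactors = FALSE)
  synthetic_plate_spec(width = n_cols * 100, height = n_rows * 100,
                       halos = halos, noise_sigma = noise_sigma, ...)
}
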