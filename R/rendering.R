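# Visual rendering of simulated populations: dermatoscopy-style blurred
# positional histograms, histology-style vertical sections, and diagnostic
# overhead scatter maps.  Renders are pure functions of (snapshot, membrane,
# spec); images are returned as numeric arrays and can be written as PNG.

#' Render specification
#'
#' @param extent rendered region \code{c(Lx, Ly)} in micrometres.
#' @param pitch pixel pitch (micrometres per pixel).
#' @param sigma Gaussian blur standard deviation (micrometres).
#' @param mode color mode: \code{"dermatoscopic"}, \code{"generation"},
#'   \code{"altitude"} or \code{"strain"}.
#' @param slab histologic slab: \code{list(axis=, position=, thickness=,
#'   width=, height=)} (micrometres); axis \code{"x"} or \code{"y"} is the
#'   section normal.
#' @return an object of class \code{nevo_render_spec}.
#' @export
render_spec <- function(extent = c(5000, 5000), pitch = 10, sigma = 20,
                        mode = "dermatoscopic",
                        slab = list(axis = "y", position = NULL,
                                    thickness = 30, width = 1200,
                                    height = 250)) {
  stopifnot(pitch > 0, sigma >= 0, slab$thickness > 0)
  structure(list(extent = as.numeric(extent), pitch = pitch, sigma = sigma,
                 mode = mode, slab = slab),
            class = "nevo_render_spec")
}

# separable Gaussian blur of a matrix (kernel truncated at 4 sigma);
# renormalized kernel conserves mass away from the borders
.gauss_blur <- function(m, sigma_px) {
  if (sigma_px <= 0) return(m)
  r <- max(1L, ceiling(4 * sigma_px))
  k <- exp(-(-r:r)^2 / (2 * sigma_px^2))
  k <- k / sum(k)
  conv1 <- function(v) {
    n <- length(v)
    out <- numeric(n)
    for (j in -r:r) {
      idx <- pmin(pmax(seq_len(n) + j, 1L), n)
      out <- out + k[j + r + 1L] * v[idx]
    }
    out
  }
  m <- apply(m, 2, conv1)
  t(apply(m, 1, conv1))
}

#' Dermatoscopy-style rendering
#'
#' 2D horizontally resolved histogram of cell positions, Gaussian-filtered
#' and normalized; every melanocyte radiates pigment radially symmetrically
#' irrespective of depth.
#'
#' @param snapshot cell data frame (columns \code{x}, \code{y}).
#' @param spec a [render_spec()].
#' @param normalize divide by the 99.5th intensity percentile and clip.
#' @return list with \code{intensity} (pixel matrix; attribute
#'   \code{"histogram"} holds the raw counts) and \code{rgb} (H x W x 3
#'   array, brown-on-skin colormap).
#' @export
render_dermatoscopic <- function(snapshot, spec = render_spec(),
                                 normalize = TRUE) {
  nx <- max(1L, ceiling(spec$extent[1] / spec$pitch))
  ny <- max(1L, ceiling(spec$extent[2] / spec$pitch))
  h <- matrix(0, nx, ny)
  if (nrow(snapshot)) {
    ix <- pmin(pmax(floor(snapshot$x / spec$pitch), 0L), nx - 1L) + 1L
    iy <- pmin(pmax(floor(snapshot$y / spec$pitch), 0L), ny - 1L) + 1L
    for (k in seq_along(ix)) h[ix[k], iy[k]] <- h[ix[k], iy[k]] + 1
  }
  img <- .gauss_blur(h, spec$sigma / spec$pitch)
  if (normalize) {
    top <- quantile(img, 0.995)
    if (top > 0) img <- pmin(img / top, 1)
  }
  skin <- c(0.94, 0.82, 0.72)
  brown <- c(0.35, 0.19, 0.09)
  rgb <- array(0, c(nx, ny, 3))
  for (ch in 1:3) rgb[, , ch] <- skin[ch] + (brown[ch] - skin[ch]) * img
  out <- list(intensity = img, rgb = rgb)
  attr(out$intensity, "histogram") <- h
  out
}

#' Histology-style vertical section
#'
#' Renders the membrane profile along a section line plus one brown disk per
#' cell whose centre lies inside the slab, at its (along-section, altitude)
#' position.  Default canvas 1200 x 250 micrometres.
#'
#' @param snapshot cell data frame (\code{x}, \code{y}, \code{z},
#'   \code{radius}).
#' @param membrane a [membrane_model()].
#' @param spec a [render_spec()]; \code{spec$slab} places the section.
#' @return list with \code{canvas} (pixel matrix: 0 background, 1 membrane
#'   profile, 2 cell disk) and \code{cells} (data frame of drawn disks).
#' @export
render_histologic <- function(snapshot, membrane, spec = render_spec()) {
  sl <- spec$slab
  pos <- if (is.null(sl$position)) membrane$extent[2] / 2 else sl$position
  along_x <- identical(sl$axis, "y")     # section normal is y: draw along x
  coord <- if (along_x) snapshot$y else snapshot$x
  along <- if (along_x) snapshot$x else snapshot$y
  keep <- abs(coord - pos) <= sl$thickness / 2
  ctr0 <- if (along_x) membrane$extent[1] / 2 else membrane$extent[2] / 2
  a0 <- ctr0 - sl$width / 2
  cells <- data.frame(along = along[keep] - a0, z = snapshot$z[keep],
                      radius = snapshot$radius[keep])
  cells <- cells[cells$along >= 0 & cells$along <= sl$width, , drop = FALSE]
  px <- spec$pitch / 5                   # finer pitch for the small canvas
  nx <- ceiling(sl$width / px); ny <- ceiling(sl$height / px)
  canvas <- matrix(0, nx, ny)
  # membrane profile along the section line
  xs <- (seq_len(nx) - 0.5) * px
  u <- if (along_x) cbind(a0 + xs, pos) else cbind(pos, a0 + xs)
  u[, 1] <- pmin(pmax(u[, 1], 0), membrane$extent[1])
  u[, 2] <- pmin(pmax(u[, 2], 0), membrane$extent[2])
  prof <- chart_inverse(membrane, u)[, 3]
  iz <- pmin(pmax(floor(prof / px), 0L), ny - 1L) + 1L
  canvas[cbind(seq_len(nx), iz)] <- 1
  # cell disks
  if (nrow(cells)) {
    for (k in seq_len(nrow(cells))) {
      cx <- cells$along[k] / px; cz <- cells$z[k] / px; cr <- cells$radius[k] / px
      i0 <- max(1L, floor(cx - cr)); i1 <- min(nx, ceiling(cx + cr))
      j0 <- max(1L, floor(cz - cr)); j1 <- min(ny, ceiling(cz + cr))
      if (i0 > i1 || j0 > j1) next
      for (i in i0:i1) for (j in j0:j1)
        if ((i - 0.5 - cx)^2 + (j - 0.5 - cz)^2 <= cr^2) canvas[i, j] <- 2
    }
  }
  list(canvas = canvas, cells = cells)
}

#' Diagnostic overhead rendering
#'
#' Color-coded overhead scatter of the population: generation numbers on a
#' fixed 0--60 scale, altitude on a fixed 0--200 micrometre scale, or one
#' color per nest strain.
#'
#' @param snapshot cell data frame.
#' @param spec a [render_spec()] with \code{mode} one of \code{"generation"},
#'   \code{"altitude"}, \code{"strain"}.
#' @return list with \code{points} (x, y), \code{value} (mapped scalar or
#'   strain index), \code{colors} (hex color per cell) and \code{scale}
#'   (the fixed scale bounds).
#' @export
render_overhead <- function(snapshot, spec = render_spec(mode = "generation")) {
  mode <- spec$mode
  stopifnot(mode %in% c("generation", "altitude", "strain"))
  ramp <- grDevices::colorRamp(c("#2c2cdc", "#2cdcdc", "#dcdc2c", "#dc2c2c"))
  if (mode == "generation") {
    sc <- c(0, 60)
    v <- pmin(pmax(snapshot$generation, sc[1]), sc[2])
    cols <- grDevices::rgb(ramp((v - sc[1]) / diff(sc)), maxColorValue = 255)
  } else if (mode == "altitude") {
    sc <- c(0, 200)
    v <- pmin(pmax(snapshot$z, sc[1]), sc[2])
    cols <- grDevices::rgb(ramp((v - sc[1]) / diff(sc)), maxColorValue = 255)
  } else {
    sc <- NULL
    v <- snapshot$strain
    pal <- grDevices::hcl.colors(max(length(unique(v[snapshot$nested])), 1L),
                                 "Dark 3")
    idx <- match(v, sort(unique(v[snapshot$nested])))
    cols <- ifelse(snapshot$nested, pal[idx], "#888888")
  }
  list(points = data.frame(x = snapshot$x, y = snapshot$y), value = v,
       colors = cols, scale = sc)
}

#' Write an RGB render to a PNG file
#'
#' @param render result of [render_dermatoscopic()] (or any H x W x 3 array).
#' @param path output path.
#' @export
write_render_png <- function(render, path) {
  arr <- if (is.list(render)) render$rgb else render
  if (!capabilities("png")) stop("PNG device not available")
  grDevices::png(path, width = dim(arr)[1], height = dim(arr)[2])
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit({ graphics::par(op); grDevices::dev.off() })
  graphics::plot.new()
  graphics::rasterImage(aperm(arr, c(2, 1, 3))[dim(arr)[2]:1, , , drop = FALSE],
                        0, 0, 1, 1, interpolate = FALSE)
  invisible(path)
}
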