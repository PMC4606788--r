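#' Rendering geometry for synthetic section images
#'
#' @param cell_px nominal fibre cell size in pixels (fibres are laid out on a
#'   near-square grid and jittered into a Voronoi tessellation).
#' @param boundary_width laminin boundary width in pixels (odd values render
#'   exactly; even values are widened by one).
#' @param jitter seed-point jitter as a fraction of `cell_px`.
#' @param laminin_boundary,laminin_interior 405 nm channel values on / off
#'   the boundary.
#' @param channel_boundary_value value of the protein channels on boundary
#'   pixels.
#' @return a `render_geometry` list.
#' @export
render_geometry <- function(cell_px = 64, boundary_width = 3, jitter = 0.15,
                            laminin_boundary = 60000, laminin_interior = 500,
                            channel_boundary_value = 0) {
  if (boundary_width < 1) stop_config("boundary_width must be >= 1")
  if (cell_px < 2 * boundary_width + 4) {
    stop_config("cell_px too small to fit an interior next to the boundary")
  }
  structure(list(cell_px = cell_px, boundary_width = boundary_width,
                 jitter = jitter, laminin_boundary = laminin_boundary,
                 laminin_interior = laminin_interior,
                 channel_boundary_value = channel_boundary_value),
            class = "render_geometry")
}

#' Render a synthetic 4-channel section image
#'
#' Draws the fibres of a generated section as a jittered Voronoi-like
#' polygonal tessellation: seed points on a near-square grid (one per fibre),
#' every pixel assigned to its nearest seed, boundaries of
#' `geometry$boundary_width` pixels between neighbouring fibres and along the
#' image edge. The laminin (405 nm) channel is bright on boundaries only;
#' each fibre interior is filled with the fibre's three channel signals
#' (rounded to integer intensity) plus optional pixel noise. A ground-truth
#' label map records the fibre id of every interior pixel (0 on boundaries).
#'
#' @param fibres fibre table with `fibre_id`, `od_488`, `od_546`, `od_647`
#'   (e.g. from [generate_control_section()]).
#' @param geometry a [render_geometry()].
#' @param pixel_noise_sd per-pixel Gaussian noise SD (intensity units).
#' @param seed RNG seed for jitter and pixel noise.
#' @param section_id identifier stored on the image.
#' @return list with `image` (a [section_image()]), `labels` (integer matrix,
#'   fibre id per pixel, 0 = boundary) and `fill_values` (the integer channel
#'   values actually painted per fibre).
#' @export
render_section_image <- function(fibres, geometry = render_geometry(),
                                 pixel_noise_sd = 0, seed = NULL,
                                 section_id = "rendered") {
  if (nrow(fibres) < 1) stop_input("at least one fibre is required")
  n <- nrow(fibres)
  cell <- geometry$cell_px
  bw <- geometry$boundary_width
  gc_ <- ceiling(sqrt(n))
  gr_ <- ceiling(n / gc_)
  width <- gc_ * cell
  height <- gr_ * cell

  with_seed(seed, {
    grid_r <- ((seq_len(n) - 1) %/% gc_) + 1
    grid_c <- ((seq_len(n) - 1) %% gc_) + 1
    jit <- geometry$jitter * cell
    sy <- (grid_r - 0.5) * cell + jit * (runif(n) - 0.5)
    sx <- (grid_c - 0.5) * cell + jit * (runif(n) - 0.5)

    # nearest-seed assignment, restricted per seed to a local window
    labels <- matrix(0L, height, width)
    mind <- matrix(Inf, height, width)
    rows <- seq_len(height) - 0.5
    cols <- seq_len(width) - 0.5
    halo <- 1.6 * cell
    for (k in seq_len(n)) {
      ri <- which(rows > sy[k] - halo & rows < sy[k] + halo)
      ci <- which(cols > sx[k] - halo & cols < sx[k] + halo)
      d <- outer((rows[ri] - sy[k])^2, (cols[ci] - sx[k])^2, `+`)
      sub <- mind[ri, ci, drop = FALSE]
      upd <- d < sub
      sub[upd] <- d[upd]
      mind[ri, ci] <- sub
      lsub <- labels[ri, ci, drop = FALSE]
      lsub[upd] <- k
      labels[ri, ci] <- lsub
    }
    # pixels outside every halo (possible when the last grid row is short)
    miss <- which(labels == 0L)
    if (length(miss)) {
      mr <- ((miss - 1) %% height) + 1
      mc <- ((miss - 1) %/% height) + 1
      for (i in seq_along(miss)) {
        labels[miss[i]] <- which.min((rows[mr[i]] - sy)^2 + (cols[mc[i]] - sx)^2)
      }
    }

    # inter-fibre edges (one-sided, 1 px), thickened to the requested width
    edge <- matrix(FALSE, height, width)
    edge[-height, ] <- edge[-height, ] | (labels[-height, ] != labels[-1, ])
    edge[, -width] <- edge[, -width] | (labels[, -width] != labels[, -1])
    r <- bw %/% 2
    boundary <- if (r > 0) {
      brush <- EBImage::makeBrush(2 * r + 1, shape = "box")
      EBImage::imageData(EBImage::dilate(EBImage::Image(edge * 1), brush)) > 0
    } else {
      edge
    }
    boundary[seq_len(bw), ] <- TRUE
    boundary[height - seq_len(bw) + 1, ] <- TRUE
    boundary[, seq_len(bw)] <- TRUE
    boundary[, width - seq_len(bw) + 1] <- TRUE
    labels[boundary] <- 0L

    clamp16 <- function(x) round(pmin(pmax(x, 0), SIGNAL_MAX))
    fill <- data.frame(
      fibre_id = fibres$fibre_id,
      od_488 = clamp16(fibres$od_488),
      od_546 = clamp16(fibres$od_546),
      od_647 = clamp16(fibres$od_647)
    )
    paint <- function(values) {
      ch <- matrix(geometry$channel_boundary_value, height, width)
      idx <- labels > 0L
      ch[idx] <- values[labels[idx]]
      if (pixel_noise_sd > 0) {
        ch <- ch + rnorm(length(ch), 0, pixel_noise_sd)
      }
      clamp16(ch)
    }
    lam <- matrix(geometry$laminin_interior, height, width)
    lam[boundary] <- geometry$laminin_boundary
    if (pixel_noise_sd > 0) lam <- lam + rnorm(length(lam), 0, pixel_noise_sd)
    channels <- list(
      "405" = clamp16(lam),
      "488" = paint(fill$od_488),
      "546" = paint(fill$od_546),
      "647" = paint(fill$od_647)
    )
    list(image = section_image(channels, section_id = section_id),
         labels = labels, fill_values = fill)
  })
}

#' Write / read a 4-channel section as multi-page 16-bit TIFF
#'
#' Pages are stored in wavelength order 405, 488, 546, 647.
#'
#' @param image a [section_image()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_section_tiff <- function(image, path) {
  pages <- lapply(image$channels[c("405", "488", "546", "647")],
                  function(ch) ch / SIGNAL_MAX)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L, reduce = FALSE)
  invisible(path)
}

#' @rdname write_section_tiff
#' @param channel_map named integer vector mapping channel name to page index.
#' @param section_id identifier for the loaded image.
#' @export
read_section_tiff <- function(path, channel_map = c("405" = 1, "488" = 2,
                                                    "546" = 3, "647" = 4),
                              section_id = basename(path)) {
  pages <- tiff::readTIFF(path, all = TRUE)
  channels <- lapply(channel_map, function(i) round(pages[[i]] * SIGNAL_MAX))
  names(channels) <- names(channel_map)
  section_image(channels, section_id = section_id)
}

#' Write a ground-truth label map as 16-bit TIFF
#'
#' @param labels integer label matrix (0 = boundary).
#' @param path output file.
#' @export
write_label_tiff <- function(labels, path) {
  tiff::writeTIFF(labels / SIGNAL_MAX, path, bits.per.sample = 16L,
                  reduce = FALSE)
  invisible(path)
}
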