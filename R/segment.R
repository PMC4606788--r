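#' 4-channel section image container
#'
#' @param channels named list of 2D intensity matrices with names `"405"`
#'   (laminin), `"488"` (COX-I), `"546"` (porin), `"647"` (NDUFB8); all the
#'   same shape, values in `[0, 65535]`.
#' @param pixel_size optional pixel size in micrometres.
#' @param section_id section identifier.
#' @return object of class `section_image`.
#' @export
section_image <- function(channels, pixel_size = NULL, section_id = "section") {
  need <- c("405", "488", "546", "647")
  if (!all(need %in% names(channels))) {
    stop_input("channels must be named ", paste(need, collapse = ", "))
  }
  channels <- channels[need]
  dims <- lapply(channels, dim)
  if (any(vapply(dims, is.null, logical(1)))) {
    stop_input("each channel must be a matrix")
  }
  if (length(unique(vapply(dims, paste, character(1), collapse = "x"))) != 1) {
    stop_input("all channels must have the same shape")
  }
  rng <- range(unlist(lapply(channels, range)))
  if (rng[1] < 0 || rng[2] > SIGNAL_MAX) {
    stop_input("channel values must lie in [0, 65535]")
  }
  structure(list(channels = channels, pixel_size = pixel_size,
                 section_id = section_id),
            class = "section_image")
}

#' Build the laminin mask from the 405 nm channel
#'
#' Thresholds the laminin channel (Otsu by default, manual override) to mark
#' fibre-boundary pixels, then applies a morphological closing to seal small
#' (1-2 px) gaps in the basement-membrane outline.
#'
#' @param image_405 2D laminin intensity matrix.
#' @param threshold_method `"otsu"` or `"manual"`.
#' @param manual_threshold threshold intensity when `threshold_method` is
#'   `"manual"` (pixels `>=` threshold are laminin-positive).
#' @param closing_radius disc radius (px) of the morphological closing;
#'   0 disables it.
#' @return logical matrix, `TRUE` on laminin-positive pixels, with the
#'   threshold used stored in attribute `"threshold"`.
#' @export
build_laminin_mask <- function(image_405,
                               threshold_method = c("otsu", "manual"),
                               manual_threshold = NULL,
                               closing_radius = 1) {
  threshold_method <- match.arg(threshold_method)
  if (is.null(dim(image_405)) || length(image_405) == 0) {
    stop_input("image_405 must be a non-empty matrix")
  }
  if (threshold_method == "manual") {
    if (is.null(manual_threshold)) {
      stop_input("manual_threshold required for threshold_method = 'manual'")
    }
    thr <- manual_threshold
  } else {
    if (diff(range(image_405)) == 0) {
      stop_input("constant image: Otsu threshold is degenerate; ",
                 "supply a manual threshold")
    }
    thr <- EBImage::otsu(EBImage::Image(image_405 / SIGNAL_MAX),
                         range = c(0, 1), levels = 256L) * SIGNAL_MAX
  }
  mask <- image_405 >= thr
  if (closing_radius >= 1) {
    brush <- EBImage::makeBrush(2 * closing_radius + 1, shape = "disc")
    mask <- EBImage::imageData(
      EBImage::closing(EBImage::Image(mask * 1), brush)) > 0
  }
  attr(mask, "threshold") <- thr
  mask
}

# minimal union-find for diagonal label merging
.uf_find <- function(parent, i) {
  while (parent[i] != i) {
    parent[i] <- parent[parent[i]]
    i <- parent[i]
  }
  i
}

# Convex-hull pixel count by Pick's theorem (A + B/2 + 1) so that solidity is
# a ratio of pixel counts, matching regionprops conventions.
.hull_pixel_count <- function(y, x) {
  n <- length(y)
  if (n <= 3) return(n)
  h <- grDevices::chull(x, y)
  hx <- x[h]; hy <- y[h]
  m <- length(h)
  if (m < 3) return(n)
  j <- c(seq_len(m)[-1], 1L)
  area <- abs(sum(hx * hy[j] - hx[j] * hy)) / 2
  gcd2 <- function(a, b) ifelse(b == 0, a, Recall(b, a %% b))
  bpts <- sum(gcd2(abs(hx[j] - hx), abs(hy[j] - hy)))
  area + bpts / 2 + 1
}

#' Label fibres as connected components of the mask complement
#'
#' Fibre interiors are the connected components of the complement of the
#' laminin mask. Ids are assigned in row-major centroid order (top-to-bottom,
#' then left-to-right) so they are stable across runs for reproducible joins.
#'
#' @param mask logical laminin mask from [build_laminin_mask()].
#' @param connectivity 4 or 8 (default 8).
#' @return object of class `fibre_regions`: list with `regions` (data.frame:
#'   `fibre_id`, `area_px`, `centroid_y`, `centroid_x` (0-based), `solidity`,
#'   `touches_border`) and `labels` (integer matrix of fibre ids).
#' @export
label_fibres <- function(mask, connectivity = 8) {
  if (!connectivity %in% c(4, 8)) stop_input("connectivity must be 4 or 8")
  interiors <- !mask
  lab <- EBImage::imageData(EBImage::bwlabel(EBImage::Image(interiors * 1)))
  storage.mode(lab) <- "integer"
  nr <- nrow(lab); nc <- ncol(lab)
  nlab <- max(lab)
  if (nlab > 0 && connectivity == 8) {
    # bwlabel is 4-connected; union labels that touch diagonally
    a1 <- lab[-nr, -nc]; b1 <- lab[-1, -1]      # down-right
    a2 <- lab[-nr, -1]; b2 <- lab[-1, -nc]      # down-left
    pick <- function(a, b) {
      keep <- a > 0L & b > 0L & a != b
      cbind(a[keep], b[keep])
    }
    pairs <- unique(rbind(pick(a1, b1), pick(a2, b2)))
    if (nrow(pairs) > 0) {
      parent <- seq_len(nlab)
      for (i in seq_len(nrow(pairs))) {
        ra <- .uf_find(parent, pairs[i, 1])
        rb <- .uf_find(parent, pairs[i, 2])
        if (ra != rb) parent[max(ra, rb)] <- min(ra, rb)
      }
      roots <- vapply(seq_len(nlab), function(i) .uf_find(parent, i), 1L)
      lab[lab > 0L] <- roots[lab[lab > 0L]]
    }
  }
  idx <- which(lab > 0L)
  if (length(idx) == 0) {
    return(structure(list(
      regions = data.frame(fibre_id = integer(), area_px = integer(),
                           centroid_y = numeric(), centroid_x = numeric(),
                           solidity = numeric(), touches_border = logical()),
      labels = lab), class = "fibre_regions"))
  }
  rows <- ((idx - 1L) %% nr) + 1L
  cols <- ((idx - 1L) %/% nr) + 1L
  f <- factor(lab[idx])
  area <- as.integer(table(f))
  cy <- tapply(rows, f, mean) - 1   # 0-based
  cx <- tapply(cols, f, mean) - 1
  border <- as.logical(tapply(rows == 1L | rows == nr | cols == 1L | cols == nc,
                              f, any))
  sol <- mapply(function(yy, xx) {
    min(1, length(yy) / .hull_pixel_count(yy, xx))
  }, split(rows, f), split(cols, f))
  ord <- order(cy, cx)
  old_ids <- as.integer(levels(f))[ord]
  remap <- integer(max(old_ids))
  remap[old_ids] <- seq_along(old_ids)
  lab[lab > 0L] <- remap[lab[lab > 0L]]
  regions <- data.frame(
    fibre_id = seq_along(ord),
    area_px = area[ord],
    centroid_y = as.numeric(cy[ord]),
    centroid_x = as.numeric(cx[ord]),
    solidity = as.numeric(sol[ord]),
    touches_border = border[ord],
    row.names = NULL
  )
  structure(list(regions = regions, labels = lab), class = "fibre_regions")
}

#' Filter fibre regions
#'
#' Removes unwanted regions (vessels, background, clipped fibres) by area,
#' solidity and image-border contact. Rejection reasons are recorded in the
#' `"rejections"` attribute of the result.
#'
#' @param fs a `fibre_regions` object from [label_fibres()].
#' @param min_area_px,max_area_px retained area range (pixels).
#' @param min_solidity minimum solidity (region area / convex-hull area).
#' @param exclude_border drop regions touching the image border.
#' @return filtered `fibre_regions`; removed regions are zeroed in `labels`
#'   but retained ids are unchanged.
#' @export
filter_regions <- function(fs, min_area_px = 300, max_area_px = Inf,
                           min_solidity = 0.6, exclude_border = TRUE) {
  if (min_area_px < 0 || min_solidity < 0) {
    stop_input("thresholds must be non-negative")
  }
  if (min_area_px > max_area_px) stop_input("min_area_px must be <= max_area_px")
  r <- fs$regions
  reason <- rep(NA_character_, nrow(r))
  reason[r$area_px < min_area_px] <- "below min_area_px"
  reason[r$area_px > max_area_px] <- "above max_area_px"
  reason[is.na(reason) & r$solidity < min_solidity] <- "below min_solidity"
  reason[is.na(reason) & exclude_border & r$touches_border] <- "touches border"
  keep <- is.na(reason)
  labels <- fs$labels
  if (any(!keep)) {
    drop_ids <- r$fibre_id[!keep]
    labels[labels %in% drop_ids] <- 0L
  }
  out <- structure(list(regions = r[keep, , drop = FALSE], labels = labels),
                   class = "fibre_regions")
  attr(out, "rejections") <- data.frame(fibre_id = r$fibre_id[!keep],
                                        reason = reason[!keep])
  out
}

#' Measure per-fibre mean channel signals
#'
#' Computes the arithmetic mean of each non-laminin channel over the interior
#' pixels of every retained region, on the brightness-monotone signal scale.
#'
#' @param image a [section_image()].
#' @param fs a `fibre_regions` object (after filtering).
#' @return data.frame of fibre measurements: `section_id`, `fibre_id`,
#'   `area_px`, `centroid_y`, `centroid_x`, `od_488`, `od_546`, `od_647`.
#' @export
measure_fibre_ods <- function(image, fs) {
  r <- fs$regions
  if (nrow(r) == 0) {
    return(data.frame(section_id = character(), fibre_id = integer(),
                      area_px = integer(), centroid_y = numeric(),
                      centroid_x = numeric(), od_488 = numeric(),
                      od_546 = numeric(), od_647 = numeric()))
  }
  lab <- fs$labels
  idx <- which(lab > 0L)
  f <- factor(lab[idx], levels = r$fibre_id)
  counts <- as.numeric(table(f))
  empty <- counts == 0
  if (any(empty)) {
    warning("excluding ", sum(empty), " empty region(s)")
  }
  ch_mean <- function(name) {
    v <- image$channels[[name]][idx]
    as.numeric(tapply(v, f, mean))
  }
  out <- data.frame(
    section_id = image$section_id,
    fibre_id = r$fibre_id,
    area_px = r$area_px,
    centroid_y = r$centroid_y,
    centroid_x = r$centroid_x,
    od_488 = ch_mean("488"),
    od_546 = ch_mean("546"),
    od_647 = ch_mean("647")
  )
  out[!empty, , drop = FALSE]
}

#' Segment a section image end-to-end
#'
#' Laminin mask, connected-component labelling, region filtering and
#' per-fibre measurement in one call.
#'
#' @param image a [section_image()].
#' @param threshold_method,manual_threshold,closing_radius passed to
#'   [build_laminin_mask()].
#' @param connectivity passed to [label_fibres()].
#' @param min_area_px,max_area_px,min_solidity,exclude_border passed to
#'   [filter_regions()].
#' @return list with `measurements` (fibre table), `regions`
#'   (`fibre_regions`) and `mask`.
#' @export
segment_section <- function(image,
                            threshold_method = "otsu",
                            manual_threshold = NULL,
                            closing_radius = 1,
                            connectivity = 8,
                            min_area_px = 300, max_area_px = Inf,
                            min_solidity = 0.6, exclude_border = TRUE) {
  mask <- build_laminin_mask(image$channels[["405"]], threshold_method,
                             manual_threshold, closing_radius)
  fs <- label_fibres(mask, connectivity)
  fs <- filter_regions(fs, min_area_px, max_area_px, min_solidity,
                       exclude_border)
  list(measurements = measure_fibre_ods(image, fs), regions = fs, mask = mask)
}

#' Read a per-fibre measurement table from CSV
#'
#' Supports both the package's brightness-monotone signal convention and the
#' inverted 16-bit optical-density convention of densitometry exports
#' (0 = brightest, 65535 = darkest), which is flipped to the signal scale
#' `S = 65535 - OD` on import.
#'
#' @param path CSV with columns `fibre_id`, `od_488`, `od_546`, `od_647`
#'   (optionally `section_id`, geometry columns).
#' @param od_convention `"signal"` or `"inverted16"`.
#' @return fibre measurement data.frame on the signal scale.
#' @export
read_fibre_table <- function(path, od_convention = c("signal", "inverted16")) {
  od_convention <- match.arg(od_convention)
  x <- utils::read.csv(path)
  need <- c("fibre_id", "od_488", "od_546", "od_647")
  if (!all(need %in% names(x))) {
    stop_input("fibre table must have columns ", paste(need, collapse = ", "))
  }
  if (od_convention == "inverted16") {
    for (col in c("od_488", "od_546", "od_647")) {
      x[[col]] <- SIGNAL_MAX - x[[col]]
    }
  }
  x
}
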