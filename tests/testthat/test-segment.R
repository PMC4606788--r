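# Renders a small noiseless section shared by several segmentation checks.
local_rendered_grid <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) {
      cfg <- simulation_config(n_fibres = 100, seed = 3, noise_sd = 0)
      sec <- generate_control_section(cfg)
      cache <<- list(
        section = sec,
        render = render_section_image(sec$fibres, render_geometry(cell_px = 48),
                                      pixel_noise_sd = 0, seed = 5)
      )
    }
    cache
  }
})

test_that("single-fibre render fills the interior with the planted values exactly", {
  fib <- data.frame(fibre_id = 1L, od_488 = 1200, od_546 = 3400, od_647 = 560)
  r <- render_section_image(fib, render_geometry(cell_px = 40), seed = 1)
  inside <- r$labels == 1L
  expect_gt(sum(inside), 0)
  expect_true(all(r$image$channels[["488"]][inside] == 1200))
  expect_true(all(r$image$channels[["546"]][inside] == 3400))
  expect_true(all(r$image$channels[["647"]][inside] == 560))
  expect_error(render_section_image(fib[0, ]), class = "quadfibre_input_error")
  expect_error(render_geometry(cell_px = 8, boundary_width = 5),
               class = "quadfibre_config_error")
})

test_that("10x10 grid renders 100 distinct interior regions and a consistent laminin histogram", {
  r <- local_rendered_grid()$render
  ids <- setdiff(unique(as.vector(r$labels)), 0L)
  expect_length(ids, 100)
  # laminin channel is bimodal: boundary fraction from the histogram matches
  # the drawn boundary area in the label map within 1%
  lam <- r$image$channels[["405"]]
  hist_boundary_frac <- mean(lam > 30000)
  map_boundary_frac <- mean(r$labels == 0L)
  expect_lt(abs(hist_boundary_frac - map_boundary_frac), 0.01)
})

test_that("laminin mask thresholding behaves on degenerate and bimodal input", {
  zero <- matrix(0, 20, 20)
  m <- build_laminin_mask(zero, "manual", manual_threshold = 100)
  expect_false(any(m))
  expect_error(build_laminin_mask(zero, "otsu"), class = "quadfibre_input_error")
  # Otsu lands between the two modes of a bimodal image
  bim <- matrix(c(rep(500, 200), rep(60000, 200)), 20, 20)
  thr <- attr(build_laminin_mask(bim, "otsu"), "threshold")
  expect_gt(thr, 500)
  expect_lt(thr, 60000)
  # agreement with the renderer's boundary on a synthetic section
  r <- local_rendered_grid()$render
  mask <- build_laminin_mask(r$image$channels[["405"]])
  expect_gt(mean(mask == (r$labels == 0L)), 0.99)
})

test_that("label_fibres handles degenerate masks and seals 1 px boundary gaps", {
  full <- matrix(TRUE, 10, 10)
  expect_equal(nrow(label_fibres(full)$regions), 0)
  # two interiors separated by a boundary line with a single-pixel gap:
  # closing seals the gap so two regions remain
  mask <- matrix(FALSE, 21, 11)
  mask[11, ] <- TRUE        # horizontal boundary
  mask[11, 6] <- FALSE      # 1 px gap
  mask[1, ] <- TRUE; mask[21, ] <- TRUE; mask[, 1] <- TRUE; mask[, 11] <- TRUE
  sealed <- EBImage::imageData(EBImage::closing(EBImage::Image(mask * 1),
                                                EBImage::makeBrush(3, "disc"))) > 0
  fs <- label_fibres(sealed)
  expect_equal(nrow(fs$regions), 2)
  # ids are ordered by centroid, row-major
  expect_true(all(diff(fs$regions$centroid_y) >= 0))
})

test_that("filter_regions applies each predicate and logs rejections", {
  r <- local_rendered_grid()$render
  fs <- label_fibres(build_laminin_mask(r$image$channels[["405"]]))
  ident <- filter_regions(fs, min_area_px = 0, max_area_px = Inf,
                          min_solidity = 0, exclude_border = FALSE)
  expect_equal(nrow(ident$regions), nrow(fs$regions))

  # planted low-solidity "vessel": a thin cross shape
  mask <- matrix(TRUE, 40, 40)
  mask[5:35, 19:21] <- FALSE
  mask[19:21, 5:35] <- FALSE
  fsx <- label_fibres(mask)
  expect_equal(nrow(fsx$regions), 1)
  expect_lt(fsx$regions$solidity, 0.7)
  filt <- filter_regions(fsx, min_area_px = 0, min_solidity = 0.7,
                         exclude_border = FALSE)
  expect_equal(nrow(filt$regions), 0)
  expect_equal(attr(filt, "rejections")$reason, "below min_solidity")

  # border-touching region removal
  maskb <- matrix(TRUE, 30, 30)
  maskb[1:10, 1:10] <- FALSE     # touches the border
  maskb[15:25, 15:25] <- FALSE   # interior
  fsb <- label_fibres(maskb)
  keep <- filter_regions(fsb, min_area_px = 0, min_solidity = 0,
                         exclude_border = TRUE)
  expect_equal(nrow(keep$regions), 1)
  expect_false(any(keep$regions$touches_border))
  expect_error(filter_regions(fsb, min_area_px = 10, max_area_px = 5),
               class = "quadfibre_input_error")
})

test_that("measured means are exact on constant and noiseless input, bounded under noise", {
  grid <- local_rendered_grid()
  r <- grid$render
  seg <- segment_section(r$image, min_area_px = 300)
  expect_equal(nrow(seg$measurements), 100)

  # constant field: every fibre mean equals the constant
  const <- r$image
  const$channels[["488"]][] <- 1234
  segc <- segment_section(const, min_area_px = 300)
  expect_true(all(segc$measurements$od_488 == 1234))

  # noiseless render: means equal painted values exactly (match regions to
  # truth by majority overlap)
  match_truth <- function(seg, labels) {
    vapply(seg$measurements$fibre_id, function(id) {
      tl <- labels[seg$regions$labels == id]
      as.integer(names(which.max(table(tl[tl > 0]))))
    }, integer(1))
  }
  truth_id <- match_truth(seg, r$labels)
  expect_equal(sort(truth_id), 1:100)
  fill <- r$fill_values[truth_id, ]
  expect_equal(seg$measurements$od_488, fill$od_488, tolerance = 1e-12)
  expect_equal(seg$measurements$od_546, fill$od_546, tolerance = 1e-12)
  expect_equal(seg$measurements$od_647, fill$od_647, tolerance = 1e-12)

  # pixel noise: means stay within 3 * noise / sqrt(area) of painted values
  rn <- render_section_image(grid$section$fibres, render_geometry(cell_px = 48),
                             pixel_noise_sd = 100, seed = 6)
  segn <- segment_section(rn$image, min_area_px = 300)
  tid <- match_truth(segn, rn$labels)
  filln <- rn$fill_values[tid, ]
  # 4 sigma: 100 fibres are tested simultaneously
  bound <- 4 * 100 / sqrt(segn$measurements$area_px)
  expect_true(all(abs(segn$measurements$od_488 - filln$od_488) < bound + 0.5))
})

test_that("segmentation recovers planted fibres one-to-one on rendered sections", {
  r <- local_rendered_grid()$render
  seg <- segment_section(r$image, min_area_px = 300)
  ious <- vapply(1:100, function(k) {
    tk <- r$labels == k
    ids <- seg$regions$labels[tk]
    ids <- ids[ids > 0]
    if (!length(ids)) return(0)
    m <- as.integer(names(which.max(table(ids))))
    sk <- seg$regions$labels == m
    sum(tk & sk) / sum(tk | sk)
  }, numeric(1))
  expect_gte(mean(ious > 0.7), 0.95)
  # determinism
  seg2 <- segment_section(r$image, min_area_px = 300)
  expect_identical(seg$measurements, seg2$measurements)
})

test_that("section TIFF round-trips through 16-bit multi-page files", {
  fib <- data.frame(fibre_id = 1:4, od_488 = c(100, 200, 300, 400),
                    od_546 = c(1000, 2000, 3000, 4000),
                    od_647 = c(10, 20, 30, 40))
  r <- render_section_image(fib, render_geometry(cell_px = 32), seed = 2)
  path <- tempfile(fileext = ".tiff")
  write_section_tiff(r$image, path)
  back <- read_section_tiff(path)
  for (ch in c("405", "488", "546", "647")) {
    expect_equal(back$channels[[ch]], r$image$channels[[ch]],
                 ignore_attr = TRUE)
  }
})

test_that("inverted-convention tables are flipped to the signal scale on import", {
  tab <- data.frame(fibre_id = 1:2, od_488 = c(1000, 2000),
                    od_546 = c(3000, 4000), od_647 = c(5000, 6000))
  path <- tempfile(fileext = ".csv")
  write.csv(tab, path, row.names = FALSE)
  sig <- read_fibre_table(path, "signal")
  expect_equal(sig$od_488, tab$od_488)
  inv <- read_fibre_table(path, "inverted16")
  expect_equal(inv$od_488, 65535 - tab$od_488)
})
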