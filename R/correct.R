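#' Summarise a no-primary-control (NPC) section
#'
#' Computes the background model used for correction: global mean signal of
#' the 488 and 546 nm channels, and for the 647 nm channel (whose secondary
#' shows mass-dependent off-target binding) one hundred percentile-group
#' means. NPC fibres are unstained for porin, so they are ranked into the
#' 100 equal-count groups by their own 546 nm signal, which tracks
#' mitochondrial mass through non-specific binding; empty groups (fewer than
#' 100 fibres) are filled by linear interpolation between neighbouring
#' groups.
#'
#' @param npc NPC fibre table with `od_488`, `od_546`, `od_647`.
#' @return object of class `npc_summary`: `mean_488`, `mean_546`,
#'   `group_means_647` (length 100), `n_fibres`, `section_id`.
#' @export
summarise_npc <- function(npc) {
  if (is.null(npc) || nrow(npc) == 0) stop_input("NPC table is empty")
  n <- nrow(npc)
  g <- percentile_groups(npc$od_546)
  means <- tapply(npc$od_647, factor(g, levels = 1:100), mean)
  means <- as.numeric(means)
  if (anyNA(means)) {
    filled <- which(!is.na(means))
    means <- stats::approx(filled, means[filled], xout = 1:100, rule = 2)$y
  }
  structure(list(mean_488 = mean(npc$od_488),
                 mean_546 = mean(npc$od_546),
                 group_means_647 = means,
                 n_fibres = n,
                 section_id = npc$section_id[1] %||% "npc"),
            class = "npc_summary")
}

#' Percentile-group assignment
#'
#' Assigns each value to one of 100 equal-count percentile groups by rank:
#' `g = ceiling(100 * rank / n)` with average ranks for ties.
#'
#' @param x numeric vector.
#' @param groups number of groups (100 per the correction scheme).
#' @return integer vector of group indices in `1..groups`.
#' @export
percentile_groups <- function(x, groups = 100L) {
  n <- length(x)
  if (n == 0) stop_input("cannot group an empty vector")
  pmin(as.integer(ceiling(groups * rank(x, ties.method = "average") / n)),
       groups)
}

#' Global background subtraction
#'
#' Subtracts the NPC channel mean from a fibre's mean signal. Values at or
#' below zero are clipped to `epsilon` (and flagged) rather than dropped, so
#' fibre counts entering category proportions are preserved.
#'
#' @param od fibre mean signal(s).
#' @param npc_mean NPC channel mean.
#' @param epsilon clipping floor (signal units).
#' @return list with `value` (corrected signal) and `clipped` (logical).
#' @export
correct_global <- function(od, npc_mean, epsilon = 1) {
  if (any(!is.finite(od)) || !is.finite(npc_mean)) {
    stop_input("inputs must be finite")
  }
  v <- od - npc_mean
  clipped <- v <= 0
  v[clipped] <- epsilon
  list(value = v, clipped = clipped)
}

#' Porin-percentile-matched NDUFB8 correction
#'
#' The off-target 647 nm background grows with mitochondrial mass, so a
#' global subtraction would over-correct low-mass and under-correct
#' high-mass fibres. Each sample fibre is assigned a porin percentile group
#' (rank of its 546 nm signal within the section, `g = ceiling(100*rank/n)`,
#' average ranks for ties) and its 647 nm signal is corrected by the mean
#' NPC 647 signal of the matching percentile group.
#'
#' @param fibres fibre table with `od_546` and `od_647`.
#' @param npc an `npc_summary` from [summarise_npc()].
#' @param epsilon clipping floor.
#' @return `fibres` with added columns `porin_pct_group`, `ndufb8_corr`,
#'   `ndufb8_clipped`.
#' @export
correct_ndufb8_percentile_matched <- function(fibres, npc, epsilon = 1) {
  if (nrow(fibres) == 0) stop_input("fibre table is empty")
  if (!inherits(npc, "npc_summary")) stop_input("npc must be an npc_summary")
  g <- percentile_groups(fibres$od_546)
  corr <- fibres$od_647 - npc$group_means_647[g]
  clipped <- corr <= 0
  corr[clipped] <- epsilon
  fibres$porin_pct_group <- g
  fibres$ndufb8_corr <- corr
  fibres$ndufb8_clipped <- clipped
  fibres
}

#' Log-transform corrected fibre signals
#'
#' Applies the natural log to the background-corrected signals, yielding the
#' `_T` columns on which the control regressions and Z-scores are defined.
#'
#' @param fibres fibre table with `coxi_corr`, `porin_corr`, `ndufb8_corr`.
#' @return `fibres` with added `coxi_T`, `porin_T`, `ndufb8_T`.
#' @export
log_transform <- function(fibres) {
  for (col in c("coxi_corr", "porin_corr", "ndufb8_corr")) {
    if (!col %in% names(fibres)) stop_input("missing column ", col)
    if (any(fibres[[col]] <= 0)) {
      stop("internal error: non-positive corrected value reached log_transform")
    }
  }
  fibres$coxi_T <- log(fibres$coxi_corr)
  fibres$porin_T <- log(fibres$porin_corr)
  fibres$ndufb8_T <- log(fibres$ndufb8_corr)
  fibres
}

#' Full background correction of a fibre table
#'
#' COX-I (488) and porin (546) are corrected by subtracting the NPC global
#' channel means; NDUFB8 (647) by the porin-percentile-matched NPC group
#' mean. Corrected values are floored at `epsilon` (flagged), then
#' log-transformed.
#'
#' @param fibres fibre measurement table (`od_488`, `od_546`, `od_647`).
#' @param npc an `npc_summary` or raw NPC fibre table.
#' @param epsilon clipping floor (signal units).
#' @return corrected fibre table with `*_corr`, `*_clipped` and `*_T`
#'   columns; the number of clipped fibres per channel is reported in the
#'   `"clip_counts"` attribute.
#' @export
correct_fibres <- function(fibres, npc, epsilon = 1) {
  if (nrow(fibres) == 0) stop_input("fibre table is empty")
  if (!inherits(npc, "npc_summary")) npc <- summarise_npc(npc)
  cc <- correct_global(fibres$od_488, npc$mean_488, epsilon)
  fibres$coxi_corr <- cc$value
  fibres$coxi_clipped <- cc$clipped
  pc <- correct_global(fibres$od_546, npc$mean_546, epsilon)
  fibres$porin_corr <- pc$value
  fibres$porin_clipped <- pc$clipped
  fibres <- correct_ndufb8_percentile_matched(fibres, npc, epsilon)
  fibres <- log_transform(fibres)
  attr(fibres, "clip_counts") <- c(coxi = sum(fibres$coxi_clipped),
                                   porin = sum(fibres$porin_clipped),
                                   ndufb8 = sum(fibres$ndufb8_clipped))
  fibres
}

#' Serialise / load an NPC summary as JSON
#'
#' @param npc an `npc_summary`.
#' @param path JSON file path.
#' @export
write_npc_summary <- function(npc, path) {
  jsonlite::write_json(unclass(npc), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_npc_summary
#' @export
read_npc_summary <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(x, class = "npc_summary")
}
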