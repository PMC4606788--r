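#' Classification thresholds
#'
#' Porin (mitochondrial mass) bands in control-SD units and COX-I / NDUFB8
#' deficiency bands in SEE units. The default deficient cut of -6 SD may be
#' replaced by red-fibre calibration
#' ([calibrate_deficiency_threshold()]), in which case `calibrated` is set
#' and the source fibres recorded.
#'
#' @param porin_cuts increasing cuts `(-3, -2, +2, +3)` separating
#'   very_low / low / normal / high / very_high.
#' @param protein_cuts decreasing cuts `(-3, -4.5, -6)` separating
#'   normal / int_plus / int_minus / deficient.
#' @param calibrated logical; `TRUE` when the deficient cut came from
#'   red-fibre calibration.
#' @param calibration named list of provenance (protein, source fibre ids).
#' @return object of class `classification_thresholds`.
#' @export
classification_thresholds <- function(porin_cuts = c(-3, -2, 2, 3),
                                      protein_cuts = c(-3, -4.5, -6),
                                      calibrated = FALSE,
                                      calibration = NULL) {
  if (length(porin_cuts) != 4 || any(diff(porin_cuts) <= 0)) {
    stop_config("porin_cuts must be 4 strictly increasing values")
  }
  if (length(protein_cuts) != 3 || any(diff(protein_cuts) >= 0)) {
    stop_config("protein_cuts must be 3 strictly decreasing values")
  }
  structure(list(porin_cuts = porin_cuts, protein_cuts = protein_cuts,
                 calibrated = calibrated, calibration = calibration),
            class = "classification_thresholds")
}

#' Porin Z-score
#'
#' `(porin_T - porin_mu_T) / porin_sd_T` against the control model.
#'
#' @param porin_T log-transformed corrected porin signal.
#' @param model a `control_model`.
#' @return numeric Z-score(s).
#' @export
score_porin_z <- function(porin_T, model) {
  if (!is.finite(model$porin_sd_T) || model$porin_sd_T <= 0) {
    stop_input("control model has degenerate porin SD")
  }
  (porin_T - model$porin_mu_T) / model$porin_sd_T
}

#' Protein Z-score against the control regression
#'
#' Deviation of the fibre's log protein signal from the level predicted by
#' its porin, in units of the control regression's standard error of
#' estimate: `z = (protein_T - (intercept + slope * porin_T)) / see`.
#'
#' @param protein_T log-transformed corrected protein signal.
#' @param porin_T log-transformed corrected porin signal.
#' @param fit a `regression_fit`.
#' @return numeric Z-score(s).
#' @export
score_protein_z <- function(protein_T, porin_T, fit) {
  if (!is.finite(fit$see) || fit$see <= 0) {
    stop_input("degenerate control fit: see must be > 0 for scoring")
  }
  (protein_T - (fit$intercept + fit$slope * porin_T)) / fit$see
}

#' Classify fibres by porin Z-score
#'
#' Mass bands: very_low `z < -3`; low `-3 <= z < -2`; normal
#' `-2 <= z <= +2`; high `+2 < z <= +3`; very_high `z > +3`
#' (exhaustive and disjoint; boundary closure is deterministic).
#'
#' @param porin_z numeric Z-score(s).
#' @param thresholds a [classification_thresholds()].
#' @return factor with levels very_low, low, normal, high, very_high.
#' @export
classify_porin <- function(porin_z, thresholds = classification_thresholds()) {
  ct <- thresholds$porin_cuts
  out <- ifelse(porin_z < ct[1], "very_low",
         ifelse(porin_z < ct[2], "low",
         ifelse(porin_z <= ct[3], "normal",
         ifelse(porin_z <= ct[4], "high", "very_high"))))
  factor(out, levels = PORIN_CLASSES)
}

#' Classify fibres by protein Z-score
#'
#' Deficiency bands: normal `z > -3`; intermediate(+) `-4.5 < z <= -3`;
#' intermediate(-) `deficient_cut < z <= -4.5`; deficient
#' `z <= deficient_cut` (default cut -6, possibly red-fibre calibrated).
#' Band boundaries are closed on the deficient side.
#'
#' @param z numeric protein Z-score(s).
#' @param thresholds a [classification_thresholds()].
#' @return factor with levels normal, int_plus, int_minus, deficient.
#' @export
classify_protein <- function(z, thresholds = classification_thresholds()) {
  ct <- thresholds$protein_cuts
  out <- ifelse(z > ct[1], "normal",
         ifelse(z > ct[2], "int_plus",
         ifelse(z > ct[3], "int_minus", "deficient")))
  factor(out, levels = PROTEIN_CLASSES)
}

#' Calibrate the deficiency boundary from red-appearing fibres
#'
#' Replaces the default -6 SD deficient cut by the highest protein Z-score
#' observed among fibres that appear red on the quadruple
#' immunofluorescence (expressing porin but neither COX-I nor NDUFB8), so
#' that every flagged fibre classifies as deficient.
#'
#' @param scores scored fibre table with `fibre_id` and `coxi_z` /
#'   `ndufb8_z`.
#' @param red_fibre_ids fibre ids of red-appearing fibres (non-empty subset
#'   of `scores$fibre_id`).
#' @param protein `"coxi"` or `"ndufb8"`.
#' @param thresholds thresholds to update.
#' @return updated [classification_thresholds()] with `calibrated = TRUE`.
#' @export
calibrate_deficiency_threshold <- function(scores, red_fibre_ids,
                                           protein = c("coxi", "ndufb8"),
                                           thresholds = classification_thresholds()) {
  protein <- match.arg(protein)
  if (length(red_fibre_ids) == 0) {
    stop_input("calibration requires at least one red fibre")
  }
  if (!all(red_fibre_ids %in% scores$fibre_id)) {
    stop_input("red_fibre_ids must be a subset of the scored fibres")
  }
  zcol <- paste0(protein, "_z")
  cut <- max(scores[[zcol]][scores$fibre_id %in% red_fibre_ids])
  if (cut >= -3) {
    warning("calibrated deficient cut (", signif(cut, 3),
            ") is implausibly high (>= -3 SD)")
  }
  ct <- thresholds$protein_cuts
  ct[3] <- cut
  # keep the cuts strictly decreasing even for implausible calibrations
  if (ct[2] <= ct[3]) ct[2] <- ct[3] + 1e-6
  if (ct[1] <= ct[2]) ct[1] <- ct[2] + 1e-6
  classification_thresholds(
    porin_cuts = thresholds$porin_cuts, protein_cuts = ct,
    calibrated = TRUE,
    calibration = list(protein = protein, cut = cut,
                       source_fibre_ids = red_fibre_ids)
  )
}

#' Score and classify a corrected section
#'
#' Computes porin, COX-I and NDUFB8 Z-scores for every fibre against the
#' control model, assigns the categorical labels, and summarises
#' per-category counts and percentages.
#'
#' @param fibres corrected fibre table (from [correct_fibres()]).
#' @param model a `control_model`.
#' @param thresholds a [classification_thresholds()].
#' @return list with `fibres` (classified table: Z-scores, three class
#'   labels, clip flags) and `summary` (per-scheme counts, percentages and
#'   `n`).
#' @export
classify_section <- function(fibres, model,
                             thresholds = classification_thresholds()) {
  need <- c("porin_T", "coxi_T", "ndufb8_T")
  if (!all(need %in% names(fibres))) {
    stop_input("fibres must contain ", paste(need, collapse = ", "),
               " (run correct_fibres first)")
  }
  fibres$porin_z <- score_porin_z(fibres$porin_T, model)
  fibres$coxi_z <- score_protein_z(fibres$coxi_T, fibres$porin_T,
                                   model$coxi_fit)
  fibres$ndufb8_z <- score_protein_z(fibres$ndufb8_T, fibres$porin_T,
                                     model$ndufb8_fit)
  fibres$porin_class <- classify_porin(fibres$porin_z, thresholds)
  fibres$coxi_class <- classify_protein(fibres$coxi_z, thresholds)
  fibres$ndufb8_class <- classify_protein(fibres$ndufb8_z, thresholds)
  summary <- list(
    n = nrow(fibres),
    porin = tabulate_proportions(fibres, "porin"),
    coxi = tabulate_proportions(fibres, "coxi"),
    ndufb8 = tabulate_proportions(fibres, "ndufb8"),
    thresholds = thresholds
  )
  list(fibres = fibres, summary = summary)
}
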