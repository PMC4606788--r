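#' Simulation configuration for synthetic muscle sections
#'
#' Defines the generative model for synthetic single-fibre immunofluorescence
#' data. Control fibres follow the structure assumed by the analysis pipeline:
#' log-signal porin (mitochondrial mass) is Gaussian, and log-signal COX-I /
#' NDUFB8 are linear in log porin with Gaussian residual scatter whose scale
#' is the regression standard error of estimate (SEE). Stored 16-bit channel
#' signals are `exp(latent)` plus the section's non-specific background and
#' additive measurement noise, clamped to `[0, 65535]`.
#'
#' Patient sections are parametrised mixtures: each fibre is assigned a
#' category per protein (`normal`, `int_plus`, `int_minus`, `deficient`) and
#' deficient categories are displaced below the control regression line by
#' `planted_shifts[category]` SEE units (small residual jitter
#' `shift_jitter_sd`, in Z units, around the planted level). Ragged-red
#' fibres get very high porin (latent Z drawn in `rrf_porin_z_range`) with
#' both proteins fixed at a basal latent constant.
#'
#' The no-primary-control (NPC) background model: all channels have a flat
#' base level; the 647 nm channel additionally carries an off-target
#' component that grows with mitochondrial mass,
#' `npc_base_647 + npc_slope_647 * exp(porin_T - porin_mu_T)`, and the
#' 546 nm channel a weaker mass-tracking term with coefficient
#' `npc_mass_546`. Sample sections carry the same additive background, which
#' is what the NPC-based correction removes.
#'
#' @param n_fibres number of fibres in the section.
#' @param porin_mu_T,porin_sd_T mean and SD of latent log-signal porin.
#' @param coxi_intercept,coxi_slope,coxi_see control regression truth for
#'   log COX-I on log porin (SEE = residual SD).
#' @param ndufb8_intercept,ndufb8_slope,ndufb8_see same for NDUFB8.
#' @param genotype_preset one of `"control"`, `"isolated_CIV"`,
#'   `"isolated_CI"`, `"single_deletion"`, `"multiple_deletions"`,
#'   `"m3243AG"`, `"mt_tW_plateau"`.
#' @param class_fractions list with elements `coxi` and `ndufb8`, each a
#'   named numeric vector over `normal`, `int_plus`, `int_minus`,
#'   `deficient` summing to 1. Interpretation depends on the preset (see
#'   Details of [generate_patient_section()]).
#' @param planted_shifts named Z-unit displacements per deficient category;
#'   defaults are the classification band midpoints (`int_plus` -3.75,
#'   `int_minus` -5.25) and -7.5 for the open-ended deficient band.
#' @param shift_jitter_sd residual scatter (Z units) of planted deficient
#'   fibres around their planted level.
#' @param rrf_fraction fraction of ragged-red fibres.
#' @param rrf_porin_z_range porin latent Z range for ragged-red fibres.
#' @param rrf_basal_coxi_T,rrf_basal_ndufb8_T basal latent protein levels of
#'   ragged-red fibres; default 7.5 SEE below the regression prediction at
#'   the control mean porin.
#' @param npc_base_488,npc_base_546,npc_base_647 flat NPC background (signal
#'   units) per channel.
#' @param npc_slope_647 off-target 647 background per unit relative mass.
#' @param npc_mass_546 mass-tracking 546 background per unit relative mass.
#' @param md_both_fraction `multiple_deletions` preset: fraction of affected
#'   fibres in which both complexes are down-regulated.
#' @param noise_sd additive measurement noise SD (signal units).
#' @param seed RNG seed (integer) or `NULL`.
#' @return object of class `simulation_config` (a validated list).
#' @export
simulation_config <- function(n_fibres = 1000,
                              porin_mu_T = 9.2,
                              porin_sd_T = 0.35,
                              coxi_intercept = 0.7,
                              coxi_slope = 0.9,
                              coxi_see = 0.15,
                              ndufb8_intercept = 0.4,
                              ndufb8_slope = 0.9,
                              ndufb8_see = 0.15,
                              genotype_preset = "control",
                              class_fractions = list(
                                coxi   = c(normal = 1, int_plus = 0, int_minus = 0, deficient = 0),
                                ndufb8 = c(normal = 1, int_plus = 0, int_minus = 0, deficient = 0)
                              ),
                              planted_shifts = c(normal = 0, int_plus = -3.75,
                                                 int_minus = -5.25, deficient = -7.5),
                              shift_jitter_sd = 0.2,
                              rrf_fraction = 0,
                              rrf_porin_z_range = c(3, 5),
                              rrf_basal_coxi_T = NULL,
                              rrf_basal_ndufb8_T = NULL,
                              npc_base_488 = 300,
                              npc_base_546 = 300,
                              npc_base_647 = 300,
                              npc_slope_647 = 600,
                              npc_mass_546 = 600,
                              md_both_fraction = 0.5,
                              noise_sd = 100,
                              seed = NULL) {
  presets <- c("control", "isolated_CIV", "isolated_CI", "single_deletion",
               "multiple_deletions", "m3243AG", "mt_tW_plateau")
  genotype_preset <- match.arg(genotype_preset, presets)
  cfg <- list(
    n_fibres = n_fibres, porin_mu_T = porin_mu_T, porin_sd_T = porin_sd_T,
    coxi_intercept = coxi_intercept, coxi_slope = coxi_slope, coxi_see = coxi_see,
    ndufb8_intercept = ndufb8_intercept, ndufb8_slope = ndufb8_slope,
    ndufb8_see = ndufb8_see, genotype_preset = genotype_preset,
    class_fractions = class_fractions, planted_shifts = planted_shifts,
    shift_jitter_sd = shift_jitter_sd, rrf_fraction = rrf_fraction,
    rrf_porin_z_range = rrf_porin_z_range,
    rrf_basal_coxi_T = rrf_basal_coxi_T %||%
      (coxi_intercept + coxi_slope * porin_mu_T - 7.5 * coxi_see),
    rrf_basal_ndufb8_T = rrf_basal_ndufb8_T %||%
      (ndufb8_intercept + ndufb8_slope * porin_mu_T - 7.5 * ndufb8_see),
    npc_base_488 = npc_base_488, npc_base_546 = npc_base_546,
    npc_base_647 = npc_base_647, npc_slope_647 = npc_slope_647,
    npc_mass_546 = npc_mass_546, md_both_fraction = md_both_fraction,
    noise_sd = noise_sd, seed = seed
  )
  validate_simulation_config(cfg)
  class(cfg) <- "simulation_config"
  cfg
}

validate_simulation_config <- function(cfg) {
  if (length(cfg$n_fibres) != 1 || is.na(cfg$n_fibres) || cfg$n_fibres < 0) {
    stop_config("n_fibres must be a single non-negative number")
  }
  if (cfg$porin_sd_T <= 0) stop_config("porin_sd_T must be > 0")
  if (cfg$coxi_see <= 0 || cfg$ndufb8_see <= 0) {
    stop_config("standard errors of estimate (coxi_see, ndufb8_see) must be > 0")
  }
  if (cfg$noise_sd < 0) stop_config("noise_sd must be >= 0")
  if (cfg$rrf_fraction < 0 || cfg$rrf_fraction > 1) {
    stop_config("rrf_fraction must lie in [0, 1]")
  }
  for (prot in c("coxi", "ndufb8")) {
    fr <- cfg$class_fractions[[prot]]
    if (is.null(fr) || !all(PROTEIN_CLASSES %in% names(fr))) {
      stop_config("class_fractions$", prot, " must name all of: ",
                  paste(PROTEIN_CLASSES, collapse = ", "))
    }
    fr <- fr[PROTEIN_CLASSES]
    if (any(fr < 0) || any(fr > 1)) {
      stop_config("class_fractions$", prot, " must lie in [0, 1]")
    }
    if (abs(sum(fr) - 1) > 1e-8) {
      stop_config("class_fractions$", prot, " must sum to 1 (got ", sum(fr), ")")
    }
  }
  if (!all(PROTEIN_CLASSES %in% names(cfg$planted_shifts))) {
    stop_config("planted_shifts must name all protein categories")
  }
  invisible(cfg)
}

# Map uniforms to protein categories by cumulative class fractions.
.assign_classes <- function(u, fractions) {
  fr <- fractions[PROTEIN_CLASSES]
  cuts <- cumsum(fr)
  idx <- findInterval(u, c(0, utils::head(cuts, -1)), rightmost.closed = FALSE)
  PROTEIN_CLASSES[pmin(pmax(idx, 1L), 4L)]
}

# One band towards normal (single-deletion preset: complex I slightly less
# affected than complex IV).
.one_band_milder <- function(cls) {
  i <- match(cls, PROTEIN_CLASSES)
  PROTEIN_CLASSES[pmax(i - 1L, 1L)]
}

# Protein category implied by a planted Z displacement under the default bands.
.class_from_shift <- function(z) {
  ifelse(z > -3, "normal",
         ifelse(z > -4.5, "int_plus",
                ifelse(z > -6, "int_minus", "deficient")))
}

# Shared generator for control and patient sections. All random draws happen
# unconditionally and in a fixed order so that a patient configuration with
# zero deficient fractions reproduces the control path bit-for-bit under the
# same seed.
.generate_section <- function(cfg, section_id) {
  n <- as.integer(cfg$n_fibres)
  empty_fibres <- data.frame(section_id = character(), fibre_id = integer(),
                             od_488 = numeric(), od_546 = numeric(),
                             od_647 = numeric())
  empty_truth <- data.frame(fibre_id = integer(), true_porin_T = numeric(),
                            true_coxi_T = numeric(), true_ndufb8_T = numeric(),
                            true_porin_class = character(),
                            true_coxi_class = character(),
                            true_ndufb8_class = character(),
                            is_ragged_red = logical(), rel_mass = numeric())
  if (n == 0) return(list(fibres = empty_fibres, truth = empty_truth))

  porin_T <- rnorm(n, cfg$porin_mu_T, cfg$porin_sd_T)
  u_sev <- runif(n)
  u_sub <- runif(n)
  resid_cox <- rnorm(n)
  resid_nd <- rnorm(n)
  u_rrf <- runif(n)
  u_rrf_z <- runif(n)
  e488 <- rnorm(n)
  e546 <- rnorm(n)
  e647 <- rnorm(n)

  is_rrf <- u_rrf < cfg$rrf_fraction
  zr <- cfg$rrf_porin_z_range
  porin_T[is_rrf] <- cfg$porin_mu_T +
    cfg$porin_sd_T * (zr[1] + (zr[2] - zr[1]) * u_rrf_z[is_rrf])

  fr <- cfg$class_fractions
  cox_class <- rep("normal", n)
  nd_class <- rep("normal", n)
  z_cox <- numeric(n)
  z_nd <- numeric(n)
  shifts <- cfg$planted_shifts

  preset <- cfg$genotype_preset
  if (preset == "isolated_CIV") {
    cox_class <- .assign_classes(u_sev, fr$coxi)
    z_cox <- unname(shifts[cox_class])
  } else if (preset == "isolated_CI") {
    nd_class <- .assign_classes(u_sev, fr$ndufb8)
    z_nd <- unname(shifts[nd_class])
  } else if (preset == "single_deletion") {
    # simultaneous decline, complex IV slightly more affected
    cox_class <- .assign_classes(u_sev, fr$coxi)
    nd_class <- .one_band_milder(cox_class)
    z_cox <- unname(shifts[cox_class])
    z_nd <- unname(shifts[nd_class])
  } else if (preset == "multiple_deletions") {
    # one population CI-deficient only, a second with both complexes down
    nd_class <- .assign_classes(u_sev, fr$ndufb8)
    affected <- nd_class != "normal"
    both <- affected & u_sub < cfg$md_both_fraction
    cox_class[both] <- nd_class[both]
    z_nd <- unname(shifts[nd_class])
    z_cox <- unname(shifts[cox_class])
  } else if (preset == "m3243AG") {
    # rotated-L trajectory: complex IV only declines once CI is deficient
    nd_class <- .assign_classes(u_sev, fr$ndufb8)
    ci_def <- nd_class == "deficient"
    cox_class[ci_def] <- .assign_classes(u_sub[ci_def], fr$coxi)
    z_nd <- unname(shifts[nd_class])
    z_cox <- unname(shifts[cox_class])
  } else if (preset == "mt_tW_plateau") {
    # COX-I falls to a common plateau just inside the deficient band while
    # NDUFB8 spans a wide severity range across the same fibres
    cox_sampled <- .assign_classes(u_sev, fr$coxi)
    affected <- cox_sampled != "normal"
    z_cox[affected] <- -6.75
    cox_class <- .class_from_shift(z_cox)
    cox_class[!affected] <- "normal"
    z_nd[affected] <- -3 - 7 * u_sub[affected]
    nd_class <- .class_from_shift(z_nd)
    nd_class[!affected] <- "normal"
  }

  pred_cox <- cfg$coxi_intercept + cfg$coxi_slope * porin_T
  pred_nd <- cfg$ndufb8_intercept + cfg$ndufb8_slope * porin_T
  cox_dev <- ifelse(cox_class == "normal", resid_cox,
                    z_cox + cfg$shift_jitter_sd * resid_cox)
  nd_dev <- ifelse(nd_class == "normal", resid_nd,
                   z_nd + cfg$shift_jitter_sd * resid_nd)
  coxi_T <- pred_cox + cfg$coxi_see * cox_dev
  ndufb8_T <- pred_nd + cfg$ndufb8_see * nd_dev

  coxi_T[is_rrf] <- cfg$rrf_basal_coxi_T
  ndufb8_T[is_rrf] <- cfg$rrf_basal_ndufb8_T
  cox_class[is_rrf] <- "deficient"
  nd_class[is_rrf] <- "deficient"

  porin_z_true <- (porin_T - cfg$porin_mu_T) / cfg$porin_sd_T
  porin_class <- as.character(classify_porin(porin_z_true))

  rel_mass <- exp(porin_T - cfg$porin_mu_T)
  clamp <- function(x) pmin(pmax(x, 0), SIGNAL_MAX)
  od_488 <- clamp(exp(coxi_T) + cfg$npc_base_488 + cfg$noise_sd * e488)
  od_546 <- clamp(exp(porin_T) + cfg$npc_base_546 +
                    cfg$npc_mass_546 * rel_mass + cfg$noise_sd * e546)
  od_647 <- clamp(exp(ndufb8_T) + cfg$npc_base_647 +
                    cfg$npc_slope_647 * rel_mass + cfg$noise_sd * e647)

  list(
    fibres = data.frame(
      section_id = section_id, fibre_id = seq_len(n),
      od_488 = od_488, od_546 = od_546, od_647 = od_647
    ),
    truth = data.frame(
      fibre_id = seq_len(n),
      true_porin_T = porin_T, true_coxi_T = coxi_T, true_ndufb8_T = ndufb8_T,
      true_porin_class = porin_class,
      true_coxi_class = cox_class, true_ndufb8_class = nd_class,
      is_ragged_red = is_rrf, rel_mass = rel_mass
    )
  )
}

#' Generate a synthetic control section
#'
#' Draws `n_fibres` control fibres from the generative model of
#' [simulation_config()] (all planted categories "normal") and converts them
#' to stored 16-bit channel signals.
#'
#' @param cfg a [simulation_config()] with `genotype_preset = "control"`.
#' @param section_id section identifier stored in the output table.
#' @return list with `fibres` (per-fibre signal table: `section_id`,
#'   `fibre_id`, `od_488`, `od_546`, `od_647`) and `truth` (latent levels and
#'   planted categories per fibre).
#' @export
generate_control_section <- function(cfg, section_id = "control") {
  validate_simulation_config(cfg)
  if (cfg$genotype_preset != "control") {
    stop_config("generate_control_section requires genotype_preset = 'control'")
  }
  with_seed(cfg$seed, .generate_section(cfg, section_id))
}

#' Generate a synthetic patient section
#'
#' Generates a section whose deficient subpopulations follow the joint
#' complex I / complex IV trajectory of the chosen genotype preset:
#'
#' * `isolated_CIV` / `isolated_CI` — only one protein is affected, with
#'   categories drawn from its `class_fractions`.
#' * `single_deletion` — both decline together; NDUFB8 one band milder than
#'   COX-I.
#' * `multiple_deletions` — a population with decreased NDUFB8 only plus a
#'   second population (`md_both_fraction` of affected fibres) in which both
#'   complexes are equally down-regulated.
#' * `m3243AG` — COX-I falls below normal only in fibres whose NDUFB8 is
#'   already deficient (rotated-L trajectory).
#' * `mt_tW_plateau` — COX-I of affected fibres sits at a common plateau
#'   just inside the deficient band while NDUFB8 spans a wide severity range.
#'
#' Ragged-red fibres (fraction `rrf_fraction`) get porin latent Z in
#' `rrf_porin_z_range` and basal constant protein levels.
#'
#' @inheritParams generate_control_section
#' @param cfg a [simulation_config()] with a non-control `genotype_preset`.
#' @return list with `fibres` and `truth` as in
#'   [generate_control_section()].
#' @export
generate_patient_section <- function(cfg, section_id = "patient") {
  validate_simulation_config(cfg)
  if (cfg$genotype_preset == "control") {
    stop_config("generate_patient_section requires a non-control genotype_preset")
  }
  with_seed(cfg$seed, .generate_section(cfg, section_id))
}

#' Generate a matched no-primary-control (NPC) section
#'
#' The NPC is a serial section processed without the COX-I / porin / NDUFB8
#' primary antibodies, so its channels measure only non-specific secondary
#' binding. When `truth` is supplied (the sample section's ground truth) the
#' NPC fibres reuse the sample's latent mitochondrial masses, emulating a
#' serial section of the same biopsy; otherwise `n` fresh masses are drawn
#' from the control distribution.
#'
#' Channel model per fibre: `od_488 = npc_base_488 + noise`;
#' `od_546 = npc_base_546 + npc_mass_546 * rel_mass + noise`;
#' `od_647 = npc_base_647 + npc_slope_647 * rel_mass + noise`, where
#' `rel_mass = exp(porin_T - porin_mu_T)` is the fibre's relative
#' mitochondrial mass.
#'
#' @param cfg a [simulation_config()].
#' @param truth optional ground-truth table from a generated section.
#' @param n number of NPC fibres when `truth` is not given.
#' @param section_id section identifier.
#' @return data.frame with `section_id`, `fibre_id`, `od_488`, `od_546`,
#'   `od_647`.
#' @export
generate_npc_section <- function(cfg, truth = NULL, n = NULL,
                                 section_id = "npc") {
  validate_simulation_config(cfg)
  if (is.null(truth) && is.null(n)) {
    stop_input("either a ground-truth table or n must be supplied")
  }
  seed <- if (is.null(cfg$seed)) NULL else (cfg$seed + 1L) %% .Machine$integer.max
  with_seed(seed, {
    if (!is.null(truth)) {
      if (nrow(truth) == 0) stop_input("truth table is empty")
      porin_T <- truth$true_porin_T
    } else {
      porin_T <- rnorm(n, cfg$porin_mu_T, cfg$porin_sd_T)
    }
    m <- length(porin_T)
    rel_mass <- exp(porin_T - cfg$porin_mu_T)
    clamp <- function(x) pmin(pmax(x, 0), SIGNAL_MAX)
    data.frame(
      section_id = section_id, fibre_id = seq_len(m),
      od_488 = clamp(cfg$npc_base_488 + cfg$noise_sd * rnorm(m)),
      od_546 = clamp(cfg$npc_base_546 + cfg$npc_mass_546 * rel_mass +
                       cfg$noise_sd * rnorm(m)),
      od_647 = clamp(cfg$npc_base_647 + cfg$npc_slope_647 * rel_mass +
                       cfg$noise_sd * rnorm(m))
    )
  })
}
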