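#' Run the full quantification pipeline
#'
#' Orchestrates the pipeline end-to-end and writes a self-describing report
#' bundle: classified CSV, summary JSON (thresholds, model provenance,
#' seeds, software version), optional run-to-run comparison table, profile
#' plot and a plain-text log of every stage.
#'
#' The configuration (list, or path to a YAML/JSON file) must contain either
#' a `simulate` block (synthetic study: `n_controls` control subjects plus a
#' patient section are generated, each with a matched NPC) or a `tables`
#' block (`patient`, `npc` and a named list `controls` of per-fibre CSV
#' paths, plus optional `od_convention`). Optional blocks: `thresholds`
#' (`porin_cuts`, `protein_cuts`), `compare_with` (path to a second
#' classified CSV; a day-1 vs day-2 style comparison table is written),
#' `plot` (logical, default `TRUE`), `seed`, `out_dir`.
#'
#' @param config configuration list or path to a YAML/JSON config file.
#' @param out_dir output directory (overrides `config$out_dir`).
#' @return (invisibly) list with `classified`, `summary`, `model`, and the
#'   paths written.
#' @export
run_pipeline <- function(config, out_dir = NULL) {
  if (is.character(config)) {
    config <- if (grepl("[.]json$", config)) {
      jsonlite::read_json(config, simplifyVector = TRUE)
    } else {
      yaml::read_yaml(config)
    }
  }
  out_dir <- out_dir %||% config$out_dir
  if (is.null(out_dir)) stop_config("config must name out_dir")
  seed <- config$seed %||% 1L

  # validate before any computation
  sim <- config$simulate
  tabs <- config$tables
  if (is.null(sim) && is.null(tabs)) {
    stop_config("config must contain a 'simulate' or 'tables' block")
  }
  if (!is.null(tabs)) {
    if (is.null(tabs$controls) || length(tabs$controls) == 0) {
      stop_config("config must name control subjects (tables$controls)")
    }
    if (is.null(tabs$patient) || is.null(tabs$npc)) {
      stop_config("tables block must name 'patient' and 'npc' files")
    }
  } else if ((sim$n_controls %||% 0) < 1) {
    stop_config("config must name control subjects (simulate$n_controls >= 1)")
  }

  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(out_dir, "run.log")
  cat("", file = log_path)
  logf <- function(...) {
    cat(format(Sys.time(), "%Y-%m-%d %H:%M:%S "), paste0(...), "\n",
        sep = "", file = log_path, append = TRUE)
  }
  logf("quadfibre ", as.character(utils::packageVersion("quadfibre")),
       " | seed = ", seed)

  thr_cfg <- config$thresholds %||% list()
  thresholds <- classification_thresholds(
    porin_cuts = thr_cfg$porin_cuts %||% c(-3, -2, 2, 3),
    protein_cuts = thr_cfg$protein_cuts %||% c(-3, -4.5, -6)
  )

  if (!is.null(sim)) {
    logf("stage simulate: ", sim$n_controls, " control subject(s) + patient")
    ctrl_par <- sim$control %||% list()
    pat_par <- sim$patient %||% list()
    controls <- list()
    for (i in seq_len(sim$n_controls)) {
      cfg_i <- do.call(simulation_config,
                       modifyList(ctrl_par, list(seed = seed + i)))
      sec <- generate_control_section(cfg_i, sprintf("control%02d", i))
      npc <- generate_npc_section(cfg_i, truth = sec$truth,
                                  section_id = sprintf("npc_control%02d", i))
      controls[[sprintf("control%02d", i)]] <-
        correct_fibres(sec$fibres, summarise_npc(npc))
    }
    pat_preset <- pat_par$genotype_preset %||% "control"
    cfg_p <- do.call(simulation_config,
                     modifyList(pat_par, list(seed = seed + 1000L,
                                              genotype_preset = pat_preset)))
    pat <- if (pat_preset == "control") {
      generate_control_section(cfg_p, "patient")
    } else {
      generate_patient_section(cfg_p, "patient")
    }
    npc_p <- generate_npc_section(cfg_p, truth = pat$truth,
                                  section_id = "npc_patient")
    patient <- correct_fibres(pat$fibres, summarise_npc(npc_p))
  } else {
    conv <- tabs$od_convention %||% "signal"
    logf("stage load: tables (od convention: ", conv, ")")
    npc_tab <- read_fibre_table(tabs$npc, conv)
    npc_sum <- summarise_npc(npc_tab)
    controls <- lapply(tabs$controls, function(p) {
      correct_fibres(read_fibre_table(p, conv), npc_sum)
    })
    patient <- correct_fibres(read_fibre_table(tabs$patient, conv), npc_sum)
  }

  logf("stage fit-controls: pooling ", length(controls), " subject(s)")
  pool <- sample_control_pool(controls, seed = seed)
  model <- build_control_model(pool)
  logf("control model: porin mu = ", signif(model$porin_mu_T, 5),
       ", sd = ", signif(model$porin_sd_T, 4),
       "; COX-I see = ", signif(model$coxi_fit$see, 4),
       "; NDUFB8 see = ", signif(model$ndufb8_fit$see, 4))

  logf("stage classify: ", nrow(patient), " fibres")
  cls <- classify_section(patient, model, thresholds)
  classified_path <- file.path(out_dir, "classified.csv")
  utils::write.csv(cls$fibres, classified_path, row.names = FALSE)

  n_def <- sum(cls$fibres$coxi_class == "deficient") +
    sum(cls$fibres$ndufb8_class == "deficient")
  no_deficiency <- n_def == 0
  if (no_deficiency) logf("no deficiency detected")

  comparisons_path <- NULL
  if (!is.null(config$compare_with)) {
    logf("stage compare: against ", config$compare_with)
    other <- utils::read.csv(config$compare_with)
    comp <- rbind(cbind(protein = "coxi",
                        compare_runs(cls$fibres, other, "coxi")),
                  cbind(protein = "ndufb8",
                        compare_runs(cls$fibres, other, "ndufb8")))
    comparisons_path <- file.path(out_dir, "comparisons.csv")
    utils::write.csv(comp, comparisons_path, row.names = FALSE)
  }

  plot_path <- NULL
  if (config$plot %||% TRUE) {
    logf("stage plot")
    plot_path <- file.path(out_dir, "profile.png")
    save_profile_plot(make_profile_plot(cls$fibres, thresholds), plot_path)
  }

  model_path <- file.path(out_dir, "model.json")
  write_control_model(model, model_path)
  summary_path <- file.path(out_dir, "summary.json")
  summ <- list(
    package_version = as.character(utils::packageVersion("quadfibre")),
    seed = seed,
    n_fibres = cls$summary$n,
    no_deficiency_detected = no_deficiency,
    thresholds = unclass(thresholds),
    model_provenance = model$provenance,
    clip_counts = as.list(attr(patient, "clip_counts")),
    porin = cls$summary$porin,
    coxi = cls$summary$coxi,
    ndufb8 = cls$summary$ndufb8
  )
  jsonlite::write_json(summ, summary_path, auto_unbox = TRUE, digits = NA,
                       null = "null", dataframe = "rows")
  logf("done")

  invisible(list(
    classified = cls$fibres, summary = summ, model = model,
    paths = list(classified = classified_path, summary = summary_path,
                 model = model_path, comparisons = comparisons_path,
                 plot = plot_path, log = log_path)
  ))
}
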