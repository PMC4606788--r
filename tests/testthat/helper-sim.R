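# Shared builders for simulated study material. Everything is generated in
# code at test time; sizes are kept modest so the suite stays fast.

# One corrected control subject: section + matched NPC + correction.
make_corrected_control <- function(n_fibres = 1000, seed = 1, ...) {
  cfg <- simulation_config(n_fibres = n_fibres, seed = seed, ...)
  sec <- generate_control_section(cfg)
  npc <- generate_npc_section(cfg, truth = sec$truth)
  correct_fibres(sec$fibres, summarise_npc(npc))
}

# Control model fitted on a pool of `n_subjects` corrected subjects.
make_control_model <- function(n_subjects = 3, n_fibres = 1000, seed0 = 100,
                               pool_seed = 11) {
  ctrls <- lapply(seq_len(n_subjects), function(i) {
    make_corrected_control(n_fibres, seed = seed0 + i)
  })
  names(ctrls) <- paste0("c", seq_len(n_subjects))
  build_control_model(sample_control_pool(ctrls, seed = pool_seed))
}

# Cache the default study-size model: several acceptance-style tests score
# against the same 3 x 1000 control pool.
.model_cache <- new.env(parent = emptyenv())
default_control_model <- function() {
  if (is.null(.model_cache$model)) {
    .model_cache$model <- make_control_model()
  }
  .model_cache$model
}

# A corrected patient section plus its ground truth.
make_corrected_patient <- function(cfg) {
  sec <- generate_patient_section(cfg)
  npc <- generate_npc_section(cfg, truth = sec$truth)
  list(corrected = correct_fibres(sec$fibres, summarise_npc(npc)),
       truth = sec$truth, raw = sec$fibres, npc = npc)
}

# Regression fit with known parameters, for scoring oracles.
manual_fit <- function(intercept, slope, see, protein = "coxi", n = 1000) {
  structure(list(protein = protein, intercept = intercept, slope = slope,
                 see = see, r2 = NA_real_, n = n,
                 residual_normality = NULL),
            class = "regression_fit")
}
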