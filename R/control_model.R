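#' Pool control fibres by stratified random sampling
#'
#' Builds the pooled control sample used to fit the control model: the
#' subject with the fewest fibres sets the per-subject count, and that many
#' fibres are drawn from every control subject by simple random sampling
#' without replacement.
#'
#' @param controls named list of corrected fibre tables (one per control
#'   subject; healthy and disease controls both qualify).
#' @param seed RNG seed for the sampling.
#' @return object of class `control_pool`: `fibres` (pooled table with a
#'   `subject` column), `n_per_subject`, `subjects`, `seed`.
#' @export
sample_control_pool <- function(controls, seed = NULL) {
  if (length(controls) == 0) stop_input("at least one control subject required")
  ns <- vapply(controls, nrow, integer(1))
  if (any(ns == 0)) {
    stop_input("control subject(s) with no fibres: ",
               paste(names(controls)[ns == 0], collapse = ", "))
  }
  if (is.null(names(controls))) {
    names(controls) <- paste0("control", seq_along(controls))
  }
  n_per <- min(ns)
  fibres <- with_seed(seed, {
    do.call(rbind, lapply(names(controls), function(s) {
      tab <- controls[[s]]
      take <- sample.int(nrow(tab), n_per, replace = FALSE)
      cbind(subject = s, tab[take, , drop = FALSE])
    }))
  })
  rownames(fibres) <- NULL
  structure(list(fibres = fibres, n_per_subject = n_per,
                 subjects = names(controls), seed = seed),
            class = "control_pool")
}

#' Box-Cox transformation diagnostic
#'
#' Profile-likelihood estimate of the Box-Cox exponent over a grid on
#' `[-2, 2]` (step 0.05). The pipeline always uses the log transform; this
#' diagnostic checks that log (`lambda = 0`) is near-optimal for the
#' background-corrected data, warning when `|lambda| > 0.5`. A flat profile
#' (degenerate scale) accepts any lambda without warning.
#'
#' @param values positive numeric vector, `n >= 20`.
#' @return `lambda_hat`, with the profile grid in attributes `"lambda"` and
#'   `"loglik"`.
#' @export
check_boxcox_lambda <- function(values) {
  if (any(values <= 0)) stop_input("Box-Cox requires strictly positive values")
  if (length(values) < 20) stop_input("need at least 20 values")
  bc <- MASS::boxcox(values ~ 1, lambda = seq(-2, 2, 0.05), plotit = FALSE)
  lambda_hat <- bc$x[which.max(bc$y)]
  flat <- diff(range(bc$y)) < 1e-6 * max(1, abs(max(bc$y)))
  if (!flat && abs(lambda_hat) > 0.5) {
    warning("Box-Cox lambda_hat = ", signif(lambda_hat, 3),
            ": log transform may not be adequate for these data")
  }
  attr(lambda_hat, "lambda") <- bc$x
  attr(lambda_hat, "loglik") <- bc$y
  lambda_hat
}

#' Normality tests (Shapiro-Wilk and D'Agostino-Pearson omnibus)
#'
#' Report-only validation of the log transform and regression residuals.
#' Shapiro-Wilk is run on a seeded random subsample of 5000 when `n > 5000`
#' (the exact test's implementation range); the D'Agostino-Pearson K2
#' omnibus test (combining the transformed skewness and kurtosis statistics)
#' is computed on the full data. Warns (does not abort) below `alpha`.
#'
#' @param values numeric vector, `n >= 8`.
#' @param alpha warning threshold for the p-values.
#' @param subsample_seed seed for the Shapiro-Wilk subsample at `n > 5000`.
#' @return list with `W`, `p_shapiro`, `K2`, `p_dagostino`, `n`.
#' @export
test_normality <- function(values, alpha = 0.01, subsample_seed = 1L) {
  values <- values[is.finite(values)]
  n <- length(values)
  if (n < 8) stop_input("normality tests require n >= 8")
  if (stats::sd(values) == 0) stop_input("zero-variance input")
  sw_values <- if (n > 5000) {
    with_seed(subsample_seed, values[sample.int(n, 5000)])
  } else {
    values
  }
  sw <- stats::shapiro.test(sw_values)
  dp <- dagostino_pearson(values)
  if (sw$p.value < alpha || dp$p.value < alpha) {
    warning("normality test(s) below alpha = ", alpha,
            " (Shapiro p = ", signif(sw$p.value, 3),
            ", D'Agostino p = ", signif(dp$p.value, 3), ")")
  }
  list(W = unname(sw$statistic), p_shapiro = sw$p.value,
       K2 = dp$K2, p_dagostino = dp$p.value, n = n)
}

#' D'Agostino-Pearson omnibus K2 test
#'
#' Combines D'Agostino's transformed skewness statistic with the
#' Anscombe-Glynn transformed kurtosis statistic; under normality
#' `K2 = Zg1^2 + Zg2^2` is approximately chi-squared with 2 degrees of
#' freedom.
#'
#' @param x numeric vector, `n >= 8`.
#' @return list with `Zg1`, `Zg2`, `K2`, `p.value`.
#' @export
dagostino_pearson <- function(x) {
  x <- x[is.finite(x)]
  n <- length(x)
  if (n < 8) stop_input("D'Agostino-Pearson test requires n >= 8")
  m <- mean(x)
  m2 <- mean((x - m)^2)
  if (m2 == 0) stop_input("zero-variance input")
  g1 <- mean((x - m)^3) / m2^1.5
  b2 <- mean((x - m)^4) / m2^2

  # skewness (D'Agostino 1970)
  Y <- g1 * sqrt((n + 1) * (n + 3) / (6 * (n - 2)))
  beta2 <- 3 * (n^2 + 27 * n - 70) * (n + 1) * (n + 3) /
    ((n - 2) * (n + 5) * (n + 7) * (n + 9))
  W2 <- -1 + sqrt(2 * (beta2 - 1))
  delta <- 1 / sqrt(log(sqrt(W2)))
  alpha <- sqrt(2 / (W2 - 1))
  Zg1 <- delta * log(Y / alpha + sqrt((Y / alpha)^2 + 1))

  # kurtosis (Anscombe-Glynn 1983)
  Eb2 <- 3 * (n - 1) / (n + 1)
  varb2 <- 24 * n * (n - 2) * (n - 3) / ((n + 1)^2 * (n + 3) * (n + 5))
  xk <- (b2 - Eb2) / sqrt(varb2)
  sqrtbeta1 <- 6 * (n^2 - 5 * n + 2) / ((n + 7) * (n + 9)) *
    sqrt(6 * (n + 3) * (n + 5) / (n * (n - 2) * (n - 3)))
  A <- 6 + 8 / sqrtbeta1 * (2 / sqrtbeta1 + sqrt(1 + 4 / sqrtbeta1^2))
  Zg2 <- ((1 - 2 / (9 * A)) -
            ((1 - 2 / A) / (1 + xk * sqrt(2 / (A - 4))))^(1 / 3)) /
    sqrt(2 / (9 * A))

  K2 <- Zg1^2 + Zg2^2
  list(Zg1 = Zg1, Zg2 = Zg2, K2 = K2,
       p.value = stats::pchisq(K2, df = 2, lower.tail = FALSE))
}

#' Fit a control protein regression
#'
#' Ordinary least squares of the log-transformed protein signal on log
#' porin over the pooled control fibres. The residual scale is the standard
#' error of estimate, `see = sqrt(SSE / (n - 2))`, which is the Z-score
#' denominator for that protein. Residual normality is tested and stored
#' (validation, not a gate).
#'
#' @param pool a `control_pool` (or a corrected fibre data.frame with
#'   `porin_T` and the protein `_T` column).
#' @param protein `"coxi"` or `"ndufb8"`.
#' @return object of class `regression_fit`: `protein`, `intercept`,
#'   `slope`, `see`, `r2`, `n`, `residual_normality`.
#' @export
fit_protein_regression <- function(pool, protein = c("coxi", "ndufb8")) {
  protein <- match.arg(protein)
  fibres <- if (inherits(pool, "control_pool")) pool$fibres else pool
  ycol <- paste0(protein, "_T")
  if (!all(c("porin_T", ycol) %in% names(fibres))) {
    stop_input("pool must contain porin_T and ", ycol)
  }
  x <- fibres$porin_T
  y <- fibres[[ycol]]
  n <- length(x)
  if (n < 3) stop_input("regression requires at least 3 fibres")
  if (stats::var(x) == 0) stop_input("zero porin_T variance: cannot fit")
  fit <- stats::lm(y ~ x)
  res <- stats::residuals(fit)
  see <- sqrt(sum(res^2) / (n - 2))
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - sum(res^2) / sst else NA_real_
  normality <- tryCatch(
    suppressWarnings(test_normality(res)),
    error = function(e) list(W = NA_real_, p_shapiro = NA_real_,
                             K2 = NA_real_, p_dagostino = NA_real_, n = n)
  )
  structure(list(protein = protein,
                 intercept = unname(stats::coef(fit)[1]),
                 slope = unname(stats::coef(fit)[2]),
                 see = see, r2 = r2, n = n,
                 residual_normality = normality),
            class = "regression_fit")
}

#' Build the control model
#'
#' Assembles the complete description of the control population: mean and
#' SD of pooled `porin_T` plus the COX-I and NDUFB8 regressions on porin,
#' with provenance (subjects, per-subject count, sampling seed, date).
#'
#' @param pool a `control_pool` from [sample_control_pool()] (or a corrected
#'   fibre data.frame).
#' @return object of class `control_model`.
#' @export
build_control_model <- function(pool) {
  fibres <- if (inherits(pool, "control_pool")) pool$fibres else pool
  if (!"porin_T" %in% names(fibres)) stop_input("pool must contain porin_T")
  mu <- mean(fibres$porin_T)
  sdv <- stats::sd(fibres$porin_T)
  if (!is.finite(sdv) || sdv <= 0) {
    stop_input("porin_T SD must be positive")
  }
  structure(list(
    porin_mu_T = mu, porin_sd_T = sdv,
    coxi_fit = fit_protein_regression(fibres, "coxi"),
    ndufb8_fit = fit_protein_regression(fibres, "ndufb8"),
    provenance = list(
      subjects = if (inherits(pool, "control_pool")) pool$subjects else NA,
      n_per_subject = if (inherits(pool, "control_pool")) pool$n_per_subject
                      else nrow(fibres),
      seed = if (inherits(pool, "control_pool")) pool$seed else NULL,
      date = format(Sys.Date())
    )
  ), class = "control_model")
}

#' Serialise / load a control model as JSON
#'
#' @param model a `control_model`.
#' @param path JSON file path.
#' @export
write_control_model <- function(model, path) {
  payload <- list(
    schema = "quadfibre_control_model/1",
    porin_mu_T = model$porin_mu_T, porin_sd_T = model$porin_sd_T,
    coxi_fit = unclass(model$coxi_fit),
    ndufb8_fit = unclass(model$ndufb8_fit),
    provenance = model$provenance
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA,
                       null = "null")
  invisible(path)
}

#' @rdname write_control_model
#' @export
read_control_model <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (!identical(x$schema, "quadfibre_control_model/1")) {
    stop_input("unrecognised control model schema")
  }
  structure(list(
    porin_mu_T = x$porin_mu_T, porin_sd_T = x$porin_sd_T,
    coxi_fit = structure(x$coxi_fit, class = "regression_fit"),
    ndufb8_fit = structure(x$ndufb8_fit, class = "regression_fit"),
    provenance = x$provenance
  ), class = "control_model")
}
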