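#' Tabulate category proportions
#'
#' Counts and percentages per category for one classification scheme, in
#' fixed label order (porin: very_low..very_high; proteins:
#' normal/int_plus/int_minus/deficient). Percentages are computed on the
#' unrounded proportions and displayed to 1 decimal.
#'
#' @param classified classified fibre table (from [classify_section()]) or
#'   any data.frame with a `<scheme>_class` column.
#' @param scheme `"porin"`, `"coxi"` or `"ndufb8"`.
#' @return object of class `category_proportions`: data.frame with
#'   `category`, `count`, `percent`, plus attribute `"n"`.
#' @export
tabulate_proportions <- function(classified, scheme = c("coxi", "ndufb8", "porin")) {
  scheme <- match.arg(scheme)
  if (nrow(classified) == 0) stop_input("classified table is empty")
  col <- paste0(scheme, "_class")
  if (!col %in% names(classified)) stop_input("missing column ", col)
  levels <- if (scheme == "porin") PORIN_CLASSES else PROTEIN_CLASSES
  f <- factor(as.character(classified[[col]]), levels = levels)
  counts <- as.integer(table(f))
  n <- sum(counts)
  out <- data.frame(category = levels, count = counts,
                    percent = round(100 * counts / n, 1))
  attr(out, "n") <- n
  class(out) <- c("category_proportions", class(out))
  out
}

#' Two-proportion Z comparison with normal-approximation CI
#'
#' Compares two sample proportions with the Z test for two population
#' proportions. The 95% confidence interval for the difference uses the
#' unpooled Wald form,
#' `diff +/- z * sqrt(p1(1-p1)/n1 + p2(1-p2)/n2)`, reported in percentage
#' points; the test statistic uses the pooled proportion, per convention.
#'
#' @param p1,p2 sample proportions in `[0, 1]`.
#' @param n1,n2 sample sizes (fibre counts).
#' @param alpha significance level (CI level is `1 - alpha`).
#' @param category optional category label carried into the output.
#' @return one-row data.frame: `category`, `p1`, `n1`, `p2`, `n2`, `diff`,
#'   `ci_low`, `ci_high` (percentage points), `z_stat`, `p_value`.
#' @export
compare_proportions <- function(p1, n1, p2, n2, alpha = 0.05,
                                category = NA_character_) {
  if (any(c(p1, p2) < 0) || any(c(p1, p2) > 1)) {
    stop_input("proportions must lie in [0, 1]")
  }
  if (n1 < 1 || n2 < 1) stop_input("sample sizes must be >= 1")
  zcrit <- stats::qnorm(1 - alpha / 2)
  diff <- p1 - p2
  se_unpooled <- sqrt(p1 * (1 - p1) / n1 + p2 * (1 - p2) / n2)
  p_pool <- (p1 * n1 + p2 * n2) / (n1 + n2)
  se_pooled <- sqrt(p_pool * (1 - p_pool) * (1 / n1 + 1 / n2))
  z <- if (se_pooled == 0) 0 else diff / se_pooled
  p_value <- 2 * stats::pnorm(-abs(z))
  data.frame(
    category = category, p1 = p1, n1 = n1, p2 = p2, n2 = n2,
    diff = 100 * diff,
    ci_low = 100 * (diff - zcrit * se_unpooled),
    ci_high = 100 * (diff + zcrit * se_unpooled),
    z_stat = z, p_value = p_value
  )
}

#' Compare category proportions between two classified runs
#'
#' Category-by-category two-proportion comparisons between two runs of the
#' pipeline (e.g. serial sections processed on two days), mirroring the
#' layout of a day-1 vs day-2 reproducibility table.
#'
#' @param classified_A,classified_B classified fibre tables.
#' @param scheme `"coxi"`, `"ndufb8"` or `"porin"`.
#' @param alpha significance level.
#' @return data.frame with one row per category.
#' @export
compare_runs <- function(classified_A, classified_B,
                         scheme = c("coxi", "ndufb8", "porin"),
                         alpha = 0.05) {
  scheme <- match.arg(scheme)
  ta <- tabulate_proportions(classified_A, scheme)
  tb <- tabulate_proportions(classified_B, scheme)
  if (!identical(ta$category, tb$category)) {
    stop_input("category schemes differ between runs")
  }
  na <- attr(ta, "n")
  nb <- attr(tb, "n")
  out <- do.call(rbind, lapply(seq_len(nrow(ta)), function(i) {
    if (ta$count[i] == 0 && tb$count[i] == 0) {
      warning("category '", ta$category[i], "' absent in both runs")
      data.frame(category = ta$category[i], p1 = 0, n1 = na, p2 = 0, n2 = nb,
                 diff = 0, ci_low = 0, ci_high = 0, z_stat = 0, p_value = 1)
    } else {
      compare_proportions(ta$count[i] / na, na, tb$count[i] / nb, nb,
                         alpha = alpha, category = ta$category[i])
    }
  }))
  rownames(out) <- NULL
  out
}

#' Compare visual (COX/SDH) and objective classifications
#'
#' Compares user-supplied visual classification counts against the
#' objective immunofluorescence classification, after mapping visual
#' categories (COX-positive, intermediate(+), intermediate(-),
#' COX-deficient) onto the objective scheme.
#'
#' @param visual_counts data.frame with `category` and `count` columns
#'   (visual classification).
#' @param objective classified fibre table.
#' @param scheme objective scheme to compare against (default `"coxi"`).
#' @param mapping named character vector mapping visual category names to
#'   objective categories; the default maps COX activity categories to the
#'   COX-I abundance bands.
#' @param alpha significance level.
#' @return data.frame of per-category comparisons (visual minus objective),
#'   with the mapping recorded in the `"mapping"` attribute.
#' @export
compare_visual_vs_objective <- function(visual_counts, objective,
                                        scheme = "coxi",
                                        mapping = c(positive = "normal",
                                                    int_plus = "int_plus",
                                                    int_minus = "int_minus",
                                                    deficient = "deficient"),
                                        alpha = 0.05) {
  if (!all(c("category", "count") %in% names(visual_counts))) {
    stop_input("visual_counts must have 'category' and 'count' columns")
  }
  unmapped <- setdiff(visual_counts$category, names(mapping))
  if (length(unmapped) > 0) {
    stop_input("unmapped visual categories: ", paste(unmapped, collapse = ", "))
  }
  tob <- tabulate_proportions(objective, scheme)
  n_ob <- attr(tob, "n")
  n_vis <- sum(visual_counts$count)
  out <- do.call(rbind, lapply(seq_len(nrow(visual_counts)), function(i) {
    target <- mapping[[visual_counts$category[i]]]
    ob_count <- tob$count[tob$category == target]
    compare_proportions(visual_counts$count[i] / n_vis, n_vis,
                        ob_count / n_ob, n_ob,
                        alpha = alpha, category = target)
  }))
  rownames(out) <- NULL
  attr(out, "mapping") <- mapping
  out
}
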