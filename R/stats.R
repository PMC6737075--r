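#' Two-way ANOVA with Sidak post-hoc comparisons
#'
#' Fixed-effects 2x2 ANOVA of a per-mouse measurement on genotype,
#' treatment and their interaction, using type-II sums of squares (which
#' coincide with the textbook decomposition on balanced data and imply no
#' factor ordering when group sizes differ). The post-hoc family is the
#' four cell-wise comparisons of interest — treatment effect within each
#' genotype and genotype effect within each treatment — each tested on the
#' pooled residual variance and Sidak-adjusted for the family size
#' actually used (echoed in the output).
#'
#' @param table A measurement table (see [read_measurements()] or
#'   [simulate_morphometry()]).
#' @return An object of class `bbm_anova`: list with `anova` (term, sum of
#'   squares, df, F, p; residual row included), `posthoc` (comparison,
#'   estimate, t, df, raw and Sidak-adjusted p, family size `m`), and
#'   `cell_means`.
#' @export
two_way_anova <- function(table) {
  table <- validate_measurements(table)
  table$genotype <- factor(table$genotype, levels = c("control", "ko"))
  table$treatment <- factor(table$treatment, levels = c("vehicle", "glp2"))
  cells <- table(table$genotype, table$treatment)
  if (any(cells == 0))
    stop("empty design cell: every genotype x treatment combination needs data",
         call. = FALSE)
  if (any(cells < 2))
    stop("need >= 2 observations per cell", call. = FALSE)

  fit <- stats::lm(value ~ genotype * treatment, data = table)
  if (stats::sigma(fit) == 0 || !is.finite(stats::sigma(fit)) ||
      stats::sigma(fit) < sqrt(.Machine$double.eps) * mean(abs(table$value) + 1))
    stop("degenerate data: zero residual variance", call. = FALSE)
  atab <- car::Anova(fit, type = 2)

  terms_map <- c("genotype" = "genotype", "treatment" = "treatment",
                 "genotype:treatment" = "interaction",
                 "Residuals" = "residual")
  anova_df <- data.frame(term = unname(terms_map[rownames(atab)]),
                         sum_sq = atab[["Sum Sq"]], df = atab[["Df"]],
                         statistic = atab[["F value"]],
                         p_value = atab[["Pr(>F)"]],
                         stringsAsFactors = FALSE)

  agg <- stats::aggregate(value ~ genotype + treatment, data = table, mean)
  nobs <- stats::aggregate(value ~ genotype + treatment, data = table, length)
  agg$n <- nobs$value
  mse <- sum(stats::residuals(fit)^2) / stats::df.residual(fit)
  dfres <- stats::df.residual(fit)

  cell <- function(g, t) agg[agg$genotype == g & agg$treatment == t, ]
  cmp <- list(
    glp2_within_control = list(a = cell("control", "glp2"),
                               b = cell("control", "vehicle")),
    glp2_within_ko      = list(a = cell("ko", "glp2"),
                               b = cell("ko", "vehicle")),
    ko_within_vehicle   = list(a = cell("ko", "vehicle"),
                               b = cell("control", "vehicle")),
    ko_within_glp2      = list(a = cell("ko", "glp2"),
                               b = cell("control", "glp2"))
  )
  m <- length(cmp)
  ph <- do.call(rbind, lapply(names(cmp), function(nm) {
    a <- cmp[[nm]]$a; b <- cmp[[nm]]$b
    est <- a$value - b$value
    se <- sqrt(mse * (1 / a$n + 1 / b$n))
    tstat <- est / se
    p <- 2 * stats::pt(-abs(tstat), df = dfres)
    data.frame(comparison = nm, estimate = est, t = tstat, df = dfres,
               p_value = p, stringsAsFactors = FALSE)
  }))
  ph$adj_p <- sidak_adjust(ph$p_value, m)
  ph$m <- m

  structure(list(anova = anova_df, posthoc = ph, cell_means = agg),
            class = "bbm_anova")
}

#' @export
print.bbm_anova <- function(x, ...) {
  cat("Two-way ANOVA (type II SS)\n")
  print(x$anova, row.names = FALSE)
  cat("\nSidak post-hoc comparisons (m =", x$posthoc$m[1], ")\n")
  print(x$posthoc[, c("comparison", "estimate", "p_value", "adj_p")],
        row.names = FALSE)
  invisible(x)
}

#' Sidak multiplicity adjustment
#'
#' `1 - (1 - p)^m`, capped at 1; the family-wise error adjustment for `m`
#' independent comparisons.
#'
#' @param p P-value(s) in \[0, 1\].
#' @param m Family size (>= 1).
#' @return Adjusted p-value(s).
#' @export
#' @examples
#' sidak_adjust(0.0127, 4)
sidak_adjust <- function(p, m) {
  if (!is.numeric(p) || any(!is.finite(p)) || any(p < 0) || any(p > 1))
    stop("p-values must lie in [0, 1]", call. = FALSE)
  if (!is.numeric(m) || length(m) != 1L || m < 1)
    stop("'m' must be a single value >= 1", call. = FALSE)
  pmin(1, -expm1(m * log1p(-p)))
}

#' Relative expression by the 2^-ddCt method
#'
#' Per sample, `dCt = target Ct - reference Ct`; `ddCt` subtracts the mean
#' `dCt` of the control group; relative expression is `2^-ddCt` (classic
#' efficiency-2 amplification, no efficiency correction). The per-group
#' summary fold is `2^(-mean ddCt)` — the geometric mean of the per-sample
#' folds — so the control group's summary fold is exactly 1 by
#' construction.
#'
#' @param ct A CT table (see [read_ct_table()] or [simulate_ct()]).
#' @param control_group Label of the calibrator group in `ct$group`.
#' @return List with `per_sample` (sample, group, dCt, ddCt, fold) and
#'   `per_group` (group, mean ddCt, summary fold, n).
#' @export
ddct_fold <- function(ct, control_group) {
  ct <- validate_ct_table(ct)
  if (!control_group %in% ct$group)
    stop("control group '", control_group, "' absent from CT table",
         call. = FALSE)
  miss <- !is.finite(ct$reference_ct) | !is.finite(ct$target_ct)
  if (any(miss))
    stop("missing CT value for sample ", ct$sample_id[which(miss)[1]],
         call. = FALSE)
  dct <- ct$target_ct - ct$reference_ct
  ddct <- dct - mean(dct[ct$group == control_group])
  per_sample <- data.frame(sample_id = ct$sample_id, group = ct$group,
                           dct = dct, ddct = ddct, fold = 2^(-ddct),
                           stringsAsFactors = FALSE)
  agg <- stats::aggregate(ddct ~ group, data = per_sample, mean)
  nn <- stats::aggregate(ddct ~ group, data = per_sample, length)
  per_group <- data.frame(group = agg$group, mean_ddct = agg$ddct,
                          fold = 2^(-agg$ddct), n = nn$ddct,
                          stringsAsFactors = FALSE)
  list(per_sample = per_sample, per_group = per_group)
}

#' Normalize densitometry to the vehicle-treated control group
#'
#' Each band intensity is divided by its paired internal-control intensity,
#' then by the mean ratio of the vehicle-treated control group, so that
#' group's mean relative expression is 1.
#'
#' @param values Numeric band intensities of the protein of interest.
#' @param internal_control_values Paired internal-control intensities
#'   (same length, all > 0).
#' @param group_labels Group label per sample.
#' @param control_group Label of the reference group (default
#'   `"control_vehicle"`).
#' @return Data.frame: `group`, `ratio`, `relative_expression`.
#' @export
normalize_to_vehicle_control <- function(values, internal_control_values,
                                         group_labels,
                                         control_group = "control_vehicle") {
  if (length(values) != length(internal_control_values) ||
      length(values) != length(group_labels))
    stop("'values', 'internal_control_values' and 'group_labels' must have ",
         "equal length", call. = FALSE)
  if (any(internal_control_values <= 0))
    stop("internal-control values must be strictly positive", call. = FALSE)
  if (!control_group %in% group_labels)
    stop("control group '", control_group, "' absent", call. = FALSE)
  ratio <- values / internal_control_values
  ref <- mean(ratio[group_labels == control_group])
  data.frame(group = group_labels, ratio = ratio,
             relative_expression = ratio / ref, stringsAsFactors = FALSE)
}
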