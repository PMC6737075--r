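#' Classifier settings
#'
#' Bundles the constants that define the pattern classifier: the normalized
#' baseline (0.5), the minimum deviation that counts as a change (0.3), the
#' maximum difference that still counts as no change (0.1), the floor applied
#' to normalized values (0.01, so that zero counts map to the bottom of the
#' 0.01--1.0 range), and the two-sided significance level for the template
#' correlation (0.05 at df = 2, i.e. four group values).
#'
#' @param baseline Normalized baseline expression for unchanged groups.
#' @param change_threshold Minimum normalized deviation defining a change.
#' @param nochange_threshold Maximum pairwise difference defining no change.
#' @param floor Lower bound applied to normalized values after division.
#' @param alpha Two-sided significance level for the template correlation.
#' @return An object of class `classifier_settings`.
#' @export
#' @examples
#' classifier_settings()
classifier_settings <- function(baseline = 0.5, change_threshold = 0.3,
                                nochange_threshold = 0.1, floor = 0.01,
                                alpha = 0.05) {
  stopifnot_scalar_number(baseline, "baseline", positive = TRUE)
  stopifnot_scalar_number(change_threshold, "change_threshold")
  stopifnot_scalar_number(nochange_threshold, "nochange_threshold")
  stopifnot_scalar_number(floor, "floor", positive = TRUE)
  stopifnot_scalar_number(alpha, "alpha", positive = TRUE)
  if (change_threshold <= 0)
    stop("'change_threshold' must be strictly positive (a zero-variance ",
         "template has no defined correlation)", call. = FALSE)
  if (nochange_threshold <= 0 || nochange_threshold >= change_threshold)
    stop("need 0 < nochange_threshold < change_threshold", call. = FALSE)
  if (baseline + change_threshold > 1)
    stop("baseline + change_threshold must not exceed 1 ",
         "(normalized values are capped at 1)", call. = FALSE)
  if (alpha >= 1) stop("'alpha' must be below 1", call. = FALSE)
  structure(list(baseline = baseline, change_threshold = change_threshold,
                 nochange_threshold = nochange_threshold, floor = floor,
                 alpha = alpha),
            class = "classifier_settings")
}

#' Normalize a protein's four group counts to its maximum
#'
#' Each count is divided by the largest of the four, then floored at
#' `settings$floor`, giving values in `[floor, 1]` with the maximum group at
#' exactly 1. A protein with all four counts zero carries no pattern
#' information and is excluded (returns `NULL` with a message) rather than
#' aborting the run.
#'
#' @param counts Numeric vector of four non-negative counts in canonical
#'   group order (see [bbm_groups()]).
#' @param settings A [classifier_settings()] object.
#' @return Named numeric vector of four normalized values, or `NULL` if all
#'   counts are zero.
#' @export
#' @examples
#' normalize_profile(c(0, 50, 100, 25))
normalize_profile <- function(counts, settings = classifier_settings()) {
  if (!is.numeric(counts) || length(counts) != 4L || anyNA(counts))
    stop("'counts' must be four non-missing numeric values", call. = FALSE)
  if (any(counts < 0)) stop("counts must be non-negative", call. = FALSE)
  if (all(counts == 0)) {
    message("all four counts are zero; protein excluded from classification")
    return(NULL)
  }
  out <- pmax(counts / max(counts), settings$floor)
  names(out) <- bbm_groups()
  out
}

#' Build the template expression models
#'
#' Each template is an idealized four-value profile on the canonical group
#' order: a category-1 pattern deviates only in the GLP-2-treated control
#' group (a treatment effect requiring the intact IE-IGF-1R), a category-2
#' pattern deviates in both knockout groups (an effect of receptor loss
#' alone). Up- and down-regulated variants add or subtract
#' `change_threshold` from the baseline. Pearson correlation is invariant to
#' positive affine transformations of the template, so only the pattern —
#' which groups deviate, and in which direction — matters, not the deviation
#' magnitude.
#'
#' @param settings A [classifier_settings()] object.
#' @return Named list of four numeric templates in fixed order:
#'   `cat1_up`, `cat1_down`, `cat2_up`, `cat2_down`.
#' @export
#' @examples
#' build_templates()$cat1_up
build_templates <- function(settings = classifier_settings()) {
  b <- settings$baseline
  d <- settings$change_threshold
  grp <- bbm_groups()
  mk <- function(v) stats::setNames(v, grp)
  list(
    cat1_up   = mk(c(b, b + d, b, b)),
    cat1_down = mk(c(b, b - d, b, b)),
    cat2_up   = mk(c(b, b, b + d, b + d)),
    cat2_down = mk(c(b, b, b - d, b - d))
  )
}

# Which groups each template marks as changed (indices in canonical order).
template_changed_groups <- function() {
  list(cat1_up = 2L, cat1_down = 2L, cat2_up = 3:4, cat2_down = 3:4)
}

#' Pearson correlation of a profile against a template
#'
#' Returns the sample Pearson correlation of the four normalized values
#' against the four template values, its square, and a two-sided p-value
#' from `t = r * sqrt(df / (1 - r^2))` with df = 2 (four paired values).
#' A perfect correlation (`r = +/-1`) returns the smallest representable
#' positive p rather than an error. A zero-variance profile has no defined
#' correlation; `defined = FALSE` is returned and such profiles are handled
#' by the no-change rule in [classify_counts()].
#'
#' @param profile Four normalized values (see [normalize_profile()]).
#' @param template Four template values (see [build_templates()]).
#' @return List with elements `r`, `r_squared`, `p_value`, `defined`.
#' @export
correlate_template <- function(profile, template) {
  if (length(profile) != 4L || length(template) != 4L)
    stop("profile and template must each have four values", call. = FALSE)
  if (stats::var(template) == 0)
    stop("template has zero variance; correlation undefined", call. = FALSE)
  if (stats::var(profile) == 0)
    return(list(r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                defined = FALSE))
  r <- stats::cor(profile, template)
  r <- min(1, max(-1, r))
  df <- 2
  if (abs(r) >= 1) {
    p <- .Machine$double.xmin
  } else {
    tstat <- r * sqrt(df / (1 - r^2))
    p <- 2 * stats::pt(-abs(tstat), df = df)
    p <- max(p, .Machine$double.xmin)
  }
  list(r = r, r_squared = r^2, p_value = p, defined = TRUE)
}

# Classify one normalized profile. Returns a one-row data.frame.
# Threshold comparisons carry a small epsilon so profiles sitting exactly on
# a boundary (e.g. a pairwise difference of precisely 0.1) are not tipped
# over by floating-point rounding.
classify_profile <- function(profile, templates, settings) {
  eps <- 1e-9
  changed_idx <- template_changed_groups()
  scores <- lapply(templates, function(tp) correlate_template(profile, tp))
  defined <- vapply(scores, `[[`, logical(1), "defined")

  diffs <- abs(outer(profile, profile, "-"))
  all_nochange <- all(diffs[upper.tri(diffs)] <=
                        settings$nochange_threshold + eps)

  res <- data.frame(category = "unclassified", template = NA_character_,
                    r = NA_real_, r_squared = NA_real_, p_value = NA_real_,
                    change_ok = NA, nochange_ok = NA, tie = FALSE,
                    stringsAsFactors = FALSE)

  if (!any(defined)) {
    # flat profile: no correlation defined; fall through to the no-change rule
    res$category <- if (all_nochange) "null" else "unclassified"
    return(res)
  }

  # Mirrored templates (up vs down) are negative affine flips of one another,
  # so their R^2 always agree; a call means the profile follows the template,
  # not its mirror, so candidates are ranked by largest positive r.
  rvals <- vapply(scores, `[[`, numeric(1), "r")
  pos <- which(is.finite(rvals) & rvals > 0)
  if (!length(pos)) {
    res$category <- if (all_nochange) "null" else "unclassified"
    return(res)
  }
  best <- pos[rvals[pos] == max(rvals[pos])]
  if (length(best) > 1L) {
    # equal fit to distinct biological interpretations: never guess
    res$tie <- TRUE
    res$category <- if (all_nochange) "null" else "unclassified"
    return(res)
  }

  name <- names(templates)[best]
  sc <- scores[[best]]
  res$template <- name
  res$r <- sc$r
  res$r_squared <- sc$r_squared
  res$p_value <- sc$p_value

  ch <- changed_idx[[name]]
  unch <- setdiff(seq_len(4L), ch)
  base_est <- mean(profile[unch])
  dev <- profile[ch] - base_est
  change_ok <- if (grepl("_up$", name)) {
    all(dev >= settings$change_threshold - eps)
  } else {
    all(dev <= -(settings$change_threshold - eps))
  }
  unch_diffs <- abs(outer(profile[unch], profile[unch], "-"))
  nochange_ok <- all(unch_diffs[upper.tri(unch_diffs)] <=
                       settings$nochange_threshold + eps)
  res$change_ok <- change_ok
  res$nochange_ok <- nochange_ok

  if (sc$p_value < settings$alpha && change_ok && nochange_ok) {
    res$category <- name
  } else if (all_nochange) {
    res$category <- "null"
  }
  res
}

#' Classify every protein in a count table
#'
#' For each protein the four group counts are normalized to their maximum
#' ([normalize_profile()]), correlated against each template model
#' ([build_templates()]), and the best-fitting template's category is called
#' when three conditions hold simultaneously: the correlation is significant
#' at `settings$alpha` (two-sided, df = 2), every group the template marks
#' as changed deviates from the mean of the unchanged groups by at least
#' `change_threshold`, and the unchanged groups differ pairwise by at most
#' `nochange_threshold`. A profile whose four values all differ pairwise by
#' at most `nochange_threshold` is called `"null"`; anything else is
#' `"unclassified"`. Ties in template fit are never resolved by guessing
#' (`tie = TRUE`, no category call).
#'
#' @param counts A spectral-count table as returned by [read_count_table()]
#'   or [simulate_proteome()]: columns `protein_id`, `gene_symbol`, and the
#'   four canonical group columns.
#' @param settings A [classifier_settings()] object.
#' @return A data.frame with one row per classified protein: identifier,
#'   gene symbol, called category, best template, `r`, `r_squared`,
#'   `p_value`, threshold flags, and the fold changes of interest
#'   (treated/vehicle control; each knockout group over its matched
#'   control). Proteins excluded for all-zero counts are listed in the
#'   `excluded` attribute.
#' @export
classify_counts <- function(counts, settings = classifier_settings()) {
  counts <- validate_count_table(counts)
  templates <- build_templates(settings)
  grp <- bbm_groups()
  mat <- as.matrix(counts[, grp])

  keep <- rowSums(mat) > 0
  excluded <- counts$protein_id[!keep]
  if (length(excluded))
    message(length(excluded), " protein(s) excluded (all four counts zero): ",
            paste(utils::head(excluded, 5), collapse = ", "),
            if (length(excluded) > 5) ", ..." else "")

  rows <- lapply(which(keep), function(i) {
    prof <- pmax(mat[i, ] / max(mat[i, ]), settings$floor)
    out <- classify_profile(prof, templates, settings)
    out$protein_id <- counts$protein_id[i]
    out$gene_symbol <- counts$gene_symbol[i]
    out$fold_glp2_control <- fold_change(mat[i, ], "control_glp2", "control_vehicle")
    out$fold_ko_vehicle <- fold_change(mat[i, ], "ko_vehicle", "control_vehicle")
    out$fold_ko_glp2 <- fold_change(mat[i, ], "ko_glp2", "control_glp2")
    out
  })
  res <- do.call(rbind, rows)
  if (is.null(res)) {
    res <- data.frame(protein_id = character(), gene_symbol = character(),
                      category = character(), template = character(),
                      r = numeric(), r_squared = numeric(), p_value = numeric(),
                      change_ok = logical(), nochange_ok = logical(),
                      tie = logical(), fold_glp2_control = numeric(),
                      fold_ko_vehicle = numeric(), fold_ko_glp2 = numeric(),
                      stringsAsFactors = FALSE)
  } else {
    res <- res[, c("protein_id", "gene_symbol", "category", "template", "r",
                   "r_squared", "p_value", "change_ok", "nochange_ok", "tie",
                   "fold_glp2_control", "fold_ko_vehicle", "fold_ko_glp2")]
    rownames(res) <- NULL
  }
  attr(res, "excluded") <- excluded
  attr(res, "settings") <- settings
  res
}

#' Fold change between two groups
#'
#' Plain ratio of one group's value over another's, computed on raw counts
#' or on a normalized profile — the per-protein scaling cancels, so the two
#' give identical results. A zero denominator yields `NA` with a warning.
#'
#' @param x Named numeric vector carrying the canonical group names, or an
#'   unnamed vector of four values in canonical order.
#' @param numerator,denominator Group names (see [bbm_groups()]).
#' @return The ratio, or `NA` if the denominator is zero.
#' @export
#' @examples
#' fold_change(c(100, 143, 100, 100), "control_glp2", "control_vehicle")
fold_change <- function(x, numerator, denominator) {
  if (is.null(names(x))) {
    if (length(x) != 4L)
      stop("unnamed 'x' must have four values in canonical order", call. = FALSE)
    names(x) <- bbm_groups()
  }
  for (g in c(numerator, denominator))
    if (!g %in% names(x))
      stop("unknown group '", g, "'", call. = FALSE)
  if (x[[denominator]] == 0) {
    warning("zero denominator in fold change (", denominator, ")")
    return(NA_real_)
  }
  unname(x[[numerator]] / x[[denominator]])
}
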