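#' Pipeline configuration
#'
#' Assembles one reproducible run: either paths to an existing count table
#' and annotation map, or simulation settings used to generate them; the
#' classifier settings; the enrichment significance level; and a global
#' seed fanned out to per-stage seeds by fixed offsets so stages can be
#' rerun in isolation.
#'
#' @param counts_file,annotation_file Optional paths to existing TSV
#'   inputs; when `NULL` the corresponding table is simulated.
#' @param simulation A [sim_config()] used when inputs are simulated.
#' @param settings A [classifier_settings()].
#' @param alpha Enrichment significance level on BH-adjusted p-values.
#' @param focal_term Term used to subset proteins before classification;
#'   `NULL` selects the most significantly enriched term (if any reaches
#'   `alpha`), otherwise all proteins are classified.
#' @param seed Global seed; overrides the simulation seed.
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(counts_file = NULL, annotation_file = NULL,
                            simulation = sim_config(),
                            settings = classifier_settings(),
                            alpha = 0.05, focal_term = NULL, seed = 1L) {
  for (f in c(counts_file, annotation_file))
    if (!is.null(f) && !file.exists(f))
      stop("input file not found: ", f, call. = FALSE)
  stopifnot(inherits(simulation, "sim_config"),
            inherits(settings, "classifier_settings"))
  simulation$seed <- as.integer(seed)
  structure(list(counts_file = counts_file,
                 annotation_file = annotation_file,
                 simulation = simulation, settings = settings,
                 alpha = alpha, focal_term = focal_term,
                 seed = as.integer(seed)),
            class = "pipeline_config")
}

#' Run the full analysis pipeline
#'
#' Executes the stages in the study's analysis order — obtain the
#' proteome (read or simulate), test annotation terms for enrichment among
#' the proteins showing any expression change, subset to the focal term,
#' classify expression patterns against the template models, and write all
#' artifacts plus a run manifest. Identical configuration and seed produce
#' byte-identical artifacts.
#'
#' The enrichment query is the set of proteins whose normalized profile
#' spans more than the no-change threshold (i.e. shows some differential
#' expression); the universe is the whole identified table.
#'
#' @param config A [pipeline_config()] object.
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with the stage tables, the manifest, and the
#'   paths of all written artifacts.
#' @export
run_pipeline <- function(config, out_dir) {
  stopifnot(inherits(config, "pipeline_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  st <- config$settings
  message(sprintf(
    "classifier constants: floor=%g baseline=%g change>=%g nochange<=%g alpha=%g",
    st$floor, st$baseline, st$change_threshold, st$nochange_threshold,
    st$alpha))
  message("note: correlations use the four pooled group values (df = 2); ",
          "p-values at n = 4 are fragile and are gated by the change/no-change ",
          "thresholds")

  manifest <- list(seed = config$seed,
                   package_version = as.character(utils::packageVersion("bbmpattern")),
                   settings = unclass(st), alpha = config$alpha,
                   complete = FALSE)

  # stage 1: proteome
  truth <- NULL
  if (is.null(config$counts_file)) {
    sim <- simulate_proteome(config$simulation)
    counts <- sim$counts
    truth <- sim$truth
    manifest$simulation <- unclass(config$simulation)
  } else {
    counts <- read_count_table(config$counts_file)
    manifest$counts_file <- config$counts_file
  }
  manifest$proteins_in <- nrow(counts)

  # stage 2: annotation + enrichment
  if (is.null(config$annotation_file)) {
    if (is.null(truth))
      stop("an annotation file is required when counts are read from disk",
           call. = FALSE)
    annotation <- simulate_annotation(truth, config$simulation)
  } else {
    annotation <- read_annotation(config$annotation_file)
  }
  changed <- changed_proteins(counts, st)
  enr <- enrich_terms(changed$gene_symbol, annotation, counts$gene_symbol)
  manifest$query_size <- nrow(changed)
  manifest$terms_tested <- nrow(enr)

  # stage 3: subset to the focal term
  focal <- config$focal_term
  if (is.null(focal) && nrow(enr) && enr$adj_p[1] < config$alpha)
    focal <- enr$term[1]
  subset_tab <- if (!is.null(focal))
    select_term_proteins(focal, annotation, counts) else counts
  manifest$focal_term <- if (is.null(focal)) "none" else focal
  manifest$proteins_subset <- nrow(subset_tab)

  # stage 4: classification
  results <- classify_counts(subset_tab, st)
  manifest$proteins_classified <- nrow(results)
  manifest$proteins_excluded <- length(attr(results, "excluded"))
  stopifnot(manifest$proteins_subset ==
              manifest$proteins_classified + manifest$proteins_excluded)

  paths <- list(counts = file.path(out_dir, "counts.tsv"),
                annotation = file.path(out_dir, "annotation.tsv"),
                enrichment = file.path(out_dir, "enrichment.tsv"),
                classification = file.path(out_dir, "classification.tsv"),
                manifest = file.path(out_dir, "manifest.yaml"))
  write_count_table(counts, paths$counts)
  write_annotation(annotation, paths$annotation)
  write_enrichment(enr, paths$enrichment, config$alpha)
  write_results(results, paths$classification)
  if (!is.null(truth)) {
    paths$truth <- file.path(out_dir, "truth.tsv")
    write_tsv_with_comments(truth, paths$truth, NULL)
  }
  manifest$complete <- TRUE
  yaml::write_yaml(manifest, paths$manifest)

  invisible(list(counts = counts, truth = truth, annotation = annotation,
                 enrichment = enr, classification = results,
                 manifest = manifest, paths = paths))
}

# Proteins whose normalized profile spans more than the no-change
# threshold: the differential-expression screen feeding the enrichment
# query. All-zero proteins are never "changed".
changed_proteins <- function(counts, settings = classifier_settings()) {
  counts <- validate_count_table(counts)
  mat <- as.matrix(counts[, bbm_groups()])
  keep <- rowSums(mat) > 0
  spread <- rep(FALSE, nrow(mat))
  if (any(keep)) {
    norm <- mat[keep, , drop = FALSE] / apply(mat[keep, , drop = FALSE], 1, max)
    norm <- pmax(norm, settings$floor)
    spread[keep] <- (apply(norm, 1, max) - apply(norm, 1, min)) >
      settings$nochange_threshold
  }
  out <- counts[spread, , drop = FALSE]
  rownames(out) <- NULL
  out
}
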