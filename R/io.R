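#' Read a spectral-count table
#'
#' Reads a delimited text table of per-protein spectral counts across the
#' four pooled animal groups and validates it into the canonical layout:
#' columns `protein_id`, `gene_symbol`, then the four group columns in
#' canonical order (see [bbm_groups()]). Any export layout can be adapted
#' through the column-mapping arguments without editing the file. Lines
#' starting with `#` are ignored. Rejections are reported with the
#' offending row or identifier; no row is ever dropped silently.
#'
#' @param path Path to the file.
#' @param id_col Name of the protein-identifier column in the file.
#' @param symbol_col Name of the gene-symbol column in the file.
#' @param group_cols Named character vector mapping each canonical group
#'   name to the corresponding column name in the file. Defaults to the
#'   canonical names themselves.
#' @param sep Field separator; tab by default, use `","` for CSV exports.
#' @return A validated data.frame of class `bbm_counts`.
#' @export
read_count_table <- function(path, id_col = "protein_id",
                             symbol_col = "gene_symbol",
                             group_cols = stats::setNames(bbm_groups(), bbm_groups()),
                             sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  grp <- bbm_groups()
  if (is.null(names(group_cols)) || !setequal(names(group_cols), grp))
    stop("'group_cols' must be named by the four canonical groups", call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE,
                           check.names = FALSE)
  needed <- c(id_col, symbol_col, unname(group_cols))
  missing_cols <- setdiff(needed, names(raw))
  if (length(missing_cols))
    stop("missing column(s) in ", path, ": ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  out <- data.frame(protein_id = as.character(raw[[id_col]]),
                    gene_symbol = as.character(raw[[symbol_col]]),
                    stringsAsFactors = FALSE)
  for (g in grp) {
    v <- raw[[group_cols[[g]]]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))))
      stop("non-numeric count in column '", group_cols[[g]], "' at data line ",
           bad[1], call. = FALSE)
    }
    out[[g]] <- v
  }
  out <- validate_count_table(out)
  message("read ", nrow(out), " proteins from ", path)
  out
}

# Schema validation shared by the reader and the simulator.
validate_count_table <- function(x) {
  grp <- bbm_groups()
  needed <- c("protein_id", "gene_symbol", grp)
  missing_cols <- setdiff(needed, names(x))
  if (length(missing_cols))
    stop("count table lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  dup <- x$protein_id[duplicated(x$protein_id)]
  if (length(dup))
    stop("duplicated protein identifier(s): ",
         paste(unique(dup), collapse = ", "), call. = FALSE)
  if (any(x$protein_id == "" | is.na(x$protein_id)))
    stop("empty protein identifier at row ",
         which(x$protein_id == "" | is.na(x$protein_id))[1], call. = FALSE)
  for (g in grp) {
    if (!is.numeric(x[[g]]))
      stop("column '", g, "' is not numeric", call. = FALSE)
    if (anyNA(x[[g]]) || any(x[[g]] < 0))
      stop("negative or missing count in column '", g, "' (protein ",
           x$protein_id[which(is.na(x[[g]]) | x[[g]] < 0)[1]], ")",
           call. = FALSE)
  }
  x <- x[, needed]
  class(x) <- c("bbm_counts", "data.frame")
  x
}

#' Write a spectral-count table
#'
#' @param x A count table (see [read_count_table()]).
#' @param path Output path; tab-separated with a header row.
#' @param comments Optional character vector written as `#`-prefixed
#'   provenance lines before the header.
#' @export
write_count_table <- function(x, path, comments = NULL) {
  x <- validate_count_table(x)
  write_tsv_with_comments(as.data.frame(x), path, comments)
}

#' Read a term-to-gene annotation map
#'
#' A two-column tab-separated file (term, gene symbol), one pair per line,
#' header optional, aggregated into a named list of gene sets. Stands in
#' for a flat GO cellular-component annotation.
#'
#' @param path Path to the file.
#' @param sep Field separator.
#' @return Named list mapping each term to a character vector of gene
#'   symbols.
#' @export
read_annotation <- function(path, sep = "\t") {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.table(path, header = TRUE, sep = sep, quote = "",
                           comment.char = "#", stringsAsFactors = FALSE)
  if (ncol(raw) < 2L) stop("annotation file needs two columns (term, gene)",
                           call. = FALSE)
  if (nrow(raw) == 0L) stop("annotation file is empty: ", path, call. = FALSE)
  term <- as.character(raw[[1]])
  gene <- as.character(raw[[2]])
  if (any(gene == "")) stop("empty gene symbol at data line ",
                            which(gene == "")[1], call. = FALSE)
  split(gene, term)
}

#' Write an annotation map
#'
#' @param annotation Named list of gene-symbol vectors.
#' @param path Output path (two-column TSV with header).
#' @export
write_annotation <- function(annotation, path) {
  df <- data.frame(term = rep(names(annotation), lengths(annotation)),
                   gene_symbol = unlist(annotation, use.names = FALSE),
                   stringsAsFactors = FALSE)
  write_tsv_with_comments(df, path, NULL)
}

#' Write classification results
#'
#' One row per protein with the category call, correlation statistics,
#' threshold flags and fold changes; classifier settings are echoed as
#' `#`-prefixed comment lines so every output records the constants it was
#' produced under.
#'
#' @param results Data.frame from [classify_counts()].
#' @param path Output path.
#' @export
write_results <- function(results, path) {
  settings <- attr(results, "settings")
  comments <- if (!is.null(settings))
    sprintf("%s = %s", names(settings),
            vapply(settings, format, character(1)))
  write_tsv_with_comments(as.data.frame(results), path, comments)
}

#' Write an enrichment table
#'
#' @param terms Data.frame from [enrich_terms()].
#' @param path Output path.
#' @param alpha Significance level echoed into the comment header.
#' @export
write_enrichment <- function(terms, path, alpha = 0.05) {
  write_tsv_with_comments(as.data.frame(terms),
                          path, sprintf("alpha = %s", format(alpha)))
}

#' Read a per-mouse measurement table
#'
#' Columns: `mouse_id`, `genotype` (`control`/`ko`), `treatment`
#' (`vehicle`/`glp2`), `value`, and optionally `unit`.
#'
#' @param path Path to a TSV file.
#' @return Validated data.frame.
#' @export
read_measurements <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  validate_measurements(x)
}

validate_measurements <- function(x) {
  for (col in c("mouse_id", "genotype", "treatment", "value"))
    if (!col %in% names(x))
      stop("measurement table lacks column '", col, "'", call. = FALSE)
  if (!all(x$genotype %in% c("control", "ko")))
    stop("'genotype' must be 'control' or 'ko'", call. = FALSE)
  if (!all(x$treatment %in% c("vehicle", "glp2")))
    stop("'treatment' must be 'vehicle' or 'glp2'", call. = FALSE)
  if (!is.numeric(x$value) || any(!is.finite(x$value)))
    stop("'value' must be finite numeric", call. = FALSE)
  x
}

#' Read a qPCR CT table
#'
#' Columns: `sample_id`, `group`, `target_ct`, `reference_ct` (cycles).
#' Values outside the typical 10--40 cycle range trigger a warning.
#'
#' @param path Path to a TSV file.
#' @return Validated data.frame.
#' @export
read_ct_table <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  x <- utils::read.table(path, header = TRUE, sep = "\t", quote = "",
                         comment.char = "#", stringsAsFactors = FALSE)
  validate_ct_table(x)
}

validate_ct_table <- function(x) {
  for (col in c("sample_id", "group", "target_ct", "reference_ct"))
    if (!col %in% names(x))
      stop("CT table lacks column '", col, "'", call. = FALSE)
  ct <- c(x$target_ct, x$reference_ct)
  if (!is.numeric(ct)) stop("CT values must be numeric", call. = FALSE)
  if (any(is.finite(ct) & (ct < 10 | ct > 40)))
    warning("CT value(s) outside the typical 10-40 cycle range")
  x
}

write_tsv_with_comments <- function(df, path, comments) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  if (length(comments))
    writeLines(paste0("# ", comments), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
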