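# Small constructors shared across test files.

tmp_tsv <- function() tempfile(fileext = ".tsv")

make_counts <- function(...) {
  rows <- list(...)
  df <- data.frame(
    protein_id = vapply(rows, `[[`, character(1), 1),
    gene_symbol = vapply(rows, `[[`, character(1), 2),
    stringsAsFactors = FALSE
  )
  mat <- t(vapply(rows, function(r) as.numeric(r[3:6]), numeric(4)))
  colnames(mat) <- bbm_groups()
  cbind(df, as.data.frame(mat))
}

# Balanced 2x2 measurement table from per-cell value vectors given in
# canonical group order.
make_measurements <- function(cv, cg, kv, kg, unit = "um") {
  vals <- list(control_vehicle = cv, control_glp2 = cg,
               ko_vehicle = kv, ko_glp2 = kg)
  do.call(rbind, lapply(names(vals), function(g) {
    data.frame(
      mouse_id = sprintf("%s_%d", g, seq_along(vals[[g]])),
      genotype = if (startsWith(g, "ko")) "ko" else "control",
      treatment = if (endsWith(g, "glp2")) "glp2" else "vehicle",
      value = vals[[g]], unit = unit, stringsAsFactors = FALSE
    )
  }))
}

# Score a classification against planted truth: fraction of planted
# proteins recovered (category and direction both correct) and fraction of
# null proteins called into any category.
score_recovery <- function(results, truth) {
  m <- merge(results, truth, by = "protein_id",
             suffixes = c("_call", "_truth"))
  base_call <- sub("_(up|down)$", "", m$category_call)
  dir_call <- ifelse(grepl("_(up|down)$", m$category_call),
                     sub("^.*_(up|down)$", "\\1", m$category_call),
                     NA_character_)
  planted <- m$category_truth %in% c("cat1", "cat2")
  rec <- if (any(planted))
    mean(base_call[planted] == m$category_truth[planted] &
           dir_call[planted] == m$direction[planted]) else NA_real_
  mis <- mean(base_call[!planted] %in% c("cat1", "cat2"))
  list(recovery = rec, null_miscall = mis)
}
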