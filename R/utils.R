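#' Canonical group order
#'
#' Every four-group quantity in the package uses this fixed column order:
#' vehicle-treated control, GLP-2-treated control, vehicle-treated
#' IE-IGF-1R knockout, GLP-2-treated knockout. A single unambiguous
#' convention prevents silent template misalignment.
#'
#' @return Character vector of the four canonical group names.
#' @export
bbm_groups <- function() {
  c("control_vehicle", "control_glp2", "ko_vehicle", "ko_glp2")
}

# Run code under a fixed seed without disturbing the caller's RNG stream.
with_seed <- function(seed, code) {
  if (!is.numeric(seed) || length(seed) != 1L || !is.finite(seed))
    stop("'seed' must be a single finite number", call. = FALSE)
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed))
  force(code)
}

stopifnot_scalar_number <- function(x, name, positive = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x))
    stop(sprintf("'%s' must be a single finite number", name), call. = FALSE)
  if (positive && x <= 0)
    stop(sprintf("'%s' must be strictly positive", name), call. = FALSE)
  invisible(x)
}
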