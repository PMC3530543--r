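# internal helpers shared across modules

#' Evaluate an expression under a temporary RNG seed
#'
#' Restores the caller's RNG state afterwards so library code never clobbers
#' a user's random stream.
#' @noRd
with_seed <- function(seed, expr) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

#' @noRd
check_proportion <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 || x > 1)
    stopf("'%s' must be a single proportion in [0, 1]", name)
  invisible(x)
}

# condition label convention used throughout: "<tissue>:<dpa>"
condition_label <- function(tissue, dpa) paste0(tissue, ":", dpa)

split_condition <- function(label) {
  parts <- strsplit(label, ":", fixed = TRUE)
  data.frame(
    tissue = vapply(parts, `[`, "", 1L),
    dpa = as.numeric(vapply(parts, `[`, "", 2L))
  )
}
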