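# Internal helpers shared across modules.

#' Round half away from zero
#'
#' Seconds-to-frames conversions use round-half-away-from-zero so that,
#' e.g., 15 s at 8.91 Hz gives 134 frames. Base `round()` rounds half to
#' even, which would make window sizes depend on representation noise.
#'
#' @param x numeric vector.
#' @return integer vector.
#' @keywords internal
#' @noRd
round_half_away <- function(x) {
  as.integer(sign(x) * floor(abs(x) + 0.5))
}

# Evaluate `expr` under a fixed RNG seed, restoring the caller's RNG state.
with_seed <- function(seed, expr) {
  if (!is.numeric(seed) || length(seed) != 1L || is.na(seed)) {
    stop("`seed` must be a single integer", call. = FALSE)
  }
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) {
    old <- get(".Random.seed", envir = globalenv(), inherits = FALSE)
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      },
      add = TRUE
    )
  }
  set.seed(as.integer(seed))
  expr
}

stopifnot_scalar_pos <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x <= 0) {
    stop(sprintf("`%s` must be a single positive number", name),
         call. = FALSE)
  }
  invisible(x)
}
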