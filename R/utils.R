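# Internal helpers shared across modules.

# Run code with a temporarily-seeded RNG, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# Shift a matrix by (dr, dc) with replicate (clamped) border padding.
shift_replicate <- function(m, dr, dc) {
  nr <- nrow(m); nc <- ncol(m)
  ri <- pmin(pmax(seq_len(nr) + dr, 1L), nr)
  ci <- pmin(pmax(seq_len(nc) + dc, 1L), nc)
  m[ri, ci, drop = FALSE]
}

# Separable 3-tap filtering with replicate padding: applies `krow` down rows
# then `kcol` across columns (taps ordered offset -1, 0, +1).
filter3_sep <- function(m, krow, kcol) {
  stopifnot(length(krow) == 3L, length(kcol) == 3L)
  a <- krow[1] * shift_replicate(m, -1L, 0L) +
       krow[2] * m +
       krow[3] * shift_replicate(m, +1L, 0L)
  kcol[1] * shift_replicate(a, 0L, -1L) +
    kcol[2] * a +
    kcol[3] * shift_replicate(a, 0L, +1L)
}

check_scalar <- function(x, name, lower = -Inf, upper = Inf,
                         open_lower = FALSE, open_upper = FALSE) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop(name, " must be a single finite number", call. = FALSE)
  lo_ok <- if (open_lower) x > lower else x >= lower
  hi_ok <- if (open_upper) x < upper else x <= upper
  if (!lo_ok || !hi_ok)
    stop(name, " = ", x, " is outside the allowed range ",
         if (open_lower) "(" else "[", lower, ", ", upper,
         if (open_upper) ")" else "]", call. = FALSE)
  invisible(x)
}

as_matrix_image <- function(x) {
  if (inherits(x, "Image")) x <- EBImage::imageData(x)
  if (is.matrix(x)) return(x)
  if (is.array(x) && length(dim(x)) == 2L) return(matrix(x, dim(x)[1], dim(x)[2]))
  stop("expected a 2-D single-channel image (matrix)", call. = FALSE)
}
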