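# internal helpers shared across modules

#' Round half away from zero
#'
#' Rounding used for display of percentages and kappa: exact halves go up,
#' unlike base [round()], which rounds half to even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

# Run code with a temporary RNG seed, restoring global RNG state afterwards.
with_local_seed <- function(seed, code) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (has_old) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  }, add = TRUE)
  set.seed(seed)
  force(code)
}

# Translate a matrix by (dr, dc): out[r + dr, c + dc] = m[r, c].
# Cells with no source are set to `fill` (border clipping / background pad).
shift_matrix <- function(m, dr, dc, fill = 0L) {
  h <- nrow(m); w <- ncol(m)
  out <- matrix(fill, h, w)
  rs <- max(1, 1 + dr):min(h, h + dr)
  cs <- max(1, 1 + dc):min(w, w + dc)
  if (dr >= h || dr <= -h || dc >= w || dc <= -w) return(out)
  out[rs, cs] <- m[rs - dr, cs - dc, drop = FALSE]
  out
}

# (row, col) -> linear index into an H x W matrix (column-major, as R stores it)
linear_index <- function(row, col, h) (col - 1L) * h + row

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)
warnf <- function(fmt, ...) warning(sprintf(fmt, ...), call. = FALSE)
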