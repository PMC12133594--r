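## Internal helpers shared across modules.

## circularly shift an array by k along dimension d (periodic wrap)
.cshift <- function(a, k, d) {
  n <- dim(a)[d]
  idx <- ((seq_len(n) - 1 - k) %% n) + 1
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[d]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

## shift with edge clamping (Neumann): out-of-range neighbours repeat the edge
.cshiftClamp <- function(a, k, d) {
  n <- dim(a)[d]
  idx <- pmin(pmax(seq_len(n) - k, 1L), n)
  args <- rep(list(quote(expr = )), length(dim(a)))
  args[[d]] <- idx
  do.call(`[`, c(list(a), args, list(drop = FALSE)))
}

## population variance (divides by n, not n-1)
.popVar <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) < 2L) return(NA_real_)
  mean((x - mean(x))^2)
}

#' Project a 3D scalar field onto the monolayer plane
#'
#' Weighted average over the z axis, used to reduce 3D simulation fields
#' (e.g. tensor components of the coarse-grained stress) to the 2D maps the
#' interface statistics operate on.
#'
#' @param values numeric array `[nx, ny, nz]`.
#' @param weights optional `[nx, ny, nz]` nonnegative weights (typically the
#'   total cell mass \eqn{\sum_i \phi_i^2}); default is an unweighted mean.
#' @return an `[nx, ny]` matrix.
#' @export
zProject <- function(values, weights = NULL) {
  stopifnot(length(dim(values)) == 3L)
  if (is.null(weights)) return(apply(values, c(1, 2), mean))
  stopifnot(all(dim(weights) == dim(values)), all(weights >= 0))
  num <- apply(values * weights, c(1, 2), sum)
  den <- apply(weights, c(1, 2), sum)
  out <- num / den
  out[den == 0] <- 0
  out
}
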