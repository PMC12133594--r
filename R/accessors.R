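## Accessor functions for the S4 containers (slot access stays internal).

#' Extract the raw value array of a field object
#'
#' @param x a [Field2D-class], [StressField-class] or [Monolayer-class]
#'   object.
#' @return For `fieldValues`, the numeric array of values.
#' @export
fieldValues <- function(x) {
  stopifnot(is(x, "Field2D") || is(x, "StressField"))
  x@values
}

#' @rdname fieldValues
#' @return For `pixelSize`, the pixel/grid spacing.
#' @export
pixelSize <- function(x) {
  if (is(x, "Field2D")) x@pixelSize else if (is(x, "StressField")) x@spacing
  else stop("no pixel size for objects of class ", class(x))
}

#' @rdname fieldValues
#' @return For `fieldUnit`, the unit label.
#' @export
fieldUnit <- function(x) {
  stopifnot(is(x, "Field2D") || is(x, "StressField"))
  x@unit
}

#' Per-cell summaries of a monolayer state
#'
#' @param x a [Monolayer-class] object.
#' @return `cellTypes`: character vector of type labels; `polarityAngles`:
#'   numeric vector of polarity angles; `cellTractions` / `cellVelocities`:
#'   `nCell x 3` matrices; `extrusionFlags`: step index of extrusion per cell
#'   (`NA` if still in the monolayer); `phiField`: the `[nx,ny,nz]` phase
#'   field of one cell; `simConfigOf`: the [SimConfig-class] of the state.
#' @export
cellTypes <- function(x) { stopifnot(is(x, "Monolayer")); x@type }

#' @rdname cellTypes
#' @export
polarityAngles <- function(x) { stopifnot(is(x, "Monolayer")); x@theta }

#' @rdname cellTypes
#' @export
cellTractions <- function(x) { stopifnot(is(x, "Monolayer")); x@traction }

#' @rdname cellTypes
#' @export
cellVelocities <- function(x) { stopifnot(is(x, "Monolayer")); x@velocity }

#' @rdname cellTypes
#' @export
extrusionFlags <- function(x) { stopifnot(is(x, "Monolayer")); x@extrudedAt }

#' @rdname cellTypes
#' @param i cell index.
#' @export
phiField <- function(x, i) {
  stopifnot(is(x, "Monolayer"), i >= 1, i <= dim(x@phi)[4])
  x@phi[, , , i]
}

#' @rdname cellTypes
#' @export
simConfigOf <- function(x) { stopifnot(is(x, "Monolayer")); x@config }

#' Number of cells in a monolayer or configuration
#' @param x a [Monolayer-class] or [SimConfig-class] object.
#' @return integer cell count.
#' @export
nCells <- function(x) {
  if (is(x, "Monolayer")) length(x@theta)
  else if (is(x, "SimConfig")) x@nCell
  else stop("nCells is defined for Monolayer and SimConfig objects")
}
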