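## Occupancy maps and Euclidean distance to the population interface.
##
## An occupancy map is a character matrix with entries "A", "B" or "none":
## the per-pixel type label of a two-population monolayer.  The interface is
## the set of pixels where the two labelled regions meet (8-connected label
## adjacency); distance maps give, for each pixel, the Euclidean distance to
## the nearest interface pixel.

#' Per-pixel type occupancy of a simulated monolayer
#'
#' Labels each (x, y) column of the simulation grid with the type of the
#' cell carrying the largest column-integrated \eqn{\phi_i^2} mass, or
#' `"none"` where the total column mass falls below `threshold` times the
#' maximum column mass.  Extruded cells can be excluded so the map tracks
#' the resident monolayer.
#'
#' @param state a [Monolayer-class], or a 4D phi array `[nx,ny,nz,nCell]`.
#' @param types type labels per cell (taken from the state if omitted).
#' @param exclude logical per cell: drop these cells (e.g. extruded ones).
#' @param threshold relative column-mass floor below which a pixel is
#'   labelled `"none"`.
#' @return character matrix `[nx, ny]` with entries `"A"`, `"B"`, `"none"`.
#' @export
occupancyMap <- function(state, types = NULL, exclude = NULL,
                         threshold = 0.05) {
  if (is(state, "Monolayer")) {
    phi <- state@phi
    if (is.null(types)) types <- state@type
    if (is.null(exclude)) exclude <- !is.na(state@extrudedAt)
  } else phi <- state
  stopifnot(length(dim(phi)) == 4L, !is.null(types))
  nc <- dim(phi)[4]
  if (is.null(exclude)) exclude <- rep(FALSE, nc)
  nx <- dim(phi)[1]; ny <- dim(phi)[2]
  colMassA <- matrix(0, nx, ny); colMassB <- matrix(0, nx, ny)
  bestMass <- matrix(0, nx, ny)
  bestType <- matrix("none", nx, ny)
  for (i in seq_len(nc)) {
    if (exclude[i]) next
    m <- apply(phi[, , , i]^2, c(1, 2), sum)
    upd <- m > bestMass
    bestMass[upd] <- m[upd]
    bestType[upd] <- types[i]
  }
  bestType[bestMass < threshold * max(bestMass)] <- "none"
  bestType
}

## interface pixels: labelled pixels 8-adjacent to the opposite label
.interfaceMask <- function(occ, periodic = c(FALSE, FALSE)) {
  isA <- occ == "A"; isB <- occ == "B"
  shift2 <- function(m, dx, dy) {
    out <- m
    out <- if (periodic[1]) .cshift(out, dx, 1L) else .cshiftClamp(out, dx, 1L)
    out <- if (periodic[2]) .cshift(out, dy, 2L) else .cshiftClamp(out, dy, 2L)
    out
  }
  nearB <- matrix(FALSE, nrow(occ), ncol(occ))
  nearA <- matrix(FALSE, nrow(occ), ncol(occ))
  for (dx in -1:1) for (dy in -1:1) {
    if (dx == 0 && dy == 0) next
    nearB <- nearB | shift2(isB, dx, dy)
    nearA <- nearA | shift2(isA, dx, dy)
  }
  (isA & nearB) | (isB & nearA)
}

#' Euclidean distance to the two-population interface
#'
#' Interface pixels are defined by 8-connected adjacency between the two
#' labelled regions; each pixel's value is the Euclidean distance (in pixel
#' units) to the nearest interface pixel, zero exactly on the interface.
#' For periodic simulation domains the map is computed on a tiled copy so
#' distances wrap correctly.
#'
#' @param occ occupancy matrix (entries `"A"`, `"B"`, `"none"`).
#' @param periodic logical length 2: periodicity in x and y.
#' @return list with `distance` (`[nx, ny]` matrix, pixel units) and
#'   `interface` (logical interface mask).
#' @export
interfaceDistance <- function(occ, periodic = c(FALSE, FALSE)) {
  stopifnot(is.matrix(occ))
  if (!any(occ == "A") || !any(occ == "B"))
    stop("data error: occupancy must contain both types to define an interface")
  iface <- .interfaceMask(occ, periodic)
  img <- 1 - iface
  tx <- if (periodic[1]) 3L else 1L
  ty <- if (periodic[2]) 3L else 1L
  if (tx > 1L || ty > 1L) {
    big <- matrix(0, nrow(img) * tx, ncol(img) * ty)
    for (a in seq_len(tx)) for (b in seq_len(ty))
      big[(a - 1) * nrow(img) + seq_len(nrow(img)),
          (b - 1) * ncol(img) + seq_len(ncol(img))] <- img
    d <- as.matrix(EBImage::imageData(EBImage::distmap(big,
                                                       metric = "euclidean")))
    ox <- (tx %/% 2) * nrow(img); oy <- (ty %/% 2) * ncol(img)
    d <- d[ox + seq_len(nrow(img)), oy + seq_len(ncol(img))]
  } else {
    d <- as.matrix(EBImage::imageData(EBImage::distmap(img,
                                                       metric = "euclidean")))
  }
  list(distance = d, interface = iface)
}

#' Straight two-interface occupancy geometry
#'
#' Builds the collision-assay geometry: type A occupies a central band in x
#' and type B the complement, which yields two straight interfaces under
#' periodic x.
#'
#' @param nx,ny grid size in pixels.
#' @param bandFraction fraction of the x extent occupied by type A.
#' @return character occupancy matrix.
#' @export
genOccupancyGeometry <- function(nx, ny, bandFraction = 0.5) {
  stopifnot(nx > 2, ny > 1, bandFraction > 0, bandFraction < 1)
  occ <- matrix("B", nx, ny)
  half <- round(nx * bandFraction / 2)
  mid <- nx / 2
  occ[abs(seq_len(nx) - 0.5 - mid) < half, ] <- "A"
  occ
}
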