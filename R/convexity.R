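## Interface convexity of a labelled island.

## perimeter of a closed polygon given vertex coordinates
.polyPerimeter <- function(x, y) {
  sum(sqrt(diff(c(x, x[1]))^2 + diff(c(y, y[1]))^2))
}

#' Convexity of a region's interface
#'
#' Quantifies how indented the boundary of an island of one cell type is:
#' the ratio of the perimeter of the region's convex hull to the perimeter
#' of the region itself.  A convex region scores 1; indentations lengthen
#' the boundary without changing the hull, so indented regions score below
#' 1.  (The reciprocal, region perimeter over hull perimeter, is returned
#' in the attributes for reference.)  The pixel mask is lightly smoothed
#' before contour extraction so staircase pixelation does not inflate the
#' measured perimeter.
#'
#' @param mask logical or 0/1 matrix; must contain a single connected
#'   component.
#' @param smooth standard deviation (pixels) of the Gaussian smoothing
#'   applied before contour extraction.
#' @return convexity in (0, 1], with attributes `perimeter`,
#'   `hullPerimeter` and `reciprocal`.
#' @export
interfaceConvexity <- function(mask, smooth = 1) {
  mask <- (mask > 0) * 1
  if (sum(mask) == 0) stop("data error: empty mask")
  lab <- EBImage::bwlabel(mask)
  if (max(lab) != 1L)
    stop("data error: mask must be one connected component (found ",
         max(lab), ")")
  img <- mask
  if (smooth > 0) {
    k <- EBImage::makeBrush(2 * ceiling(3 * smooth) + 1, shape = "Gaussian",
                            sigma = smooth)
    img <- as.matrix(EBImage::imageData(EBImage::filter2(EBImage::Image(mask),
                                                         k)))
  }
  cl <- contourLines(x = seq_len(nrow(img)), y = seq_len(ncol(img)),
                     z = img, levels = 0.5)
  if (!length(cl)) stop("data error: no boundary contour found")
  lens <- vapply(cl, function(cc) length(cc$x), numeric(1))
  cc <- cl[[which.max(lens)]]
  per <- .polyPerimeter(cc$x, cc$y)
  hull <- chull(cc$x, cc$y)
  hullPer <- .polyPerimeter(cc$x[hull], cc$y[hull])
  out <- hullPer / per
  attr(out, "perimeter") <- per
  attr(out, "hullPerimeter") <- hullPer
  attr(out, "reciprocal") <- per / hullPer
  out
}
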