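## Stress coarse-graining and fluctuation statistics.

#' Coarse-grained stress from a per-node traction field
#'
#' Computes the nearest-neighbour moment tensor
#' \deqn{\sigma(x) = \frac{1}{a_0^3} \sum_{j \in N(x)} r^{xj} \otimes T^j,}
#' where the sum runs over the 6-connected neighbourhood in 3D (4-connected
#' in 2D), \eqn{r^{xj} = x - x_j} and \eqn{T^j} is the traction vector
#' carried by node \eqn{j}.  Negative values indicate compression.  The
#' domain wraps periodically in x and y; along z the stencil drops missing
#' neighbours at the walls.
#'
#' @param tractions numeric array `[nx, ny, nz, 3]` (3D) or `[nx, ny, 2]`
#'   (2D) of per-node traction vectors.
#' @param a0 grid spacing.
#' @param periodic logical length 2: wrap in x and y.
#' @param unit,time metadata passed to the result.
#' @return a [StressField-class].
#' @seealso [nodeTractionField()] to distribute per-cell tractions onto
#'   grid nodes.
#' @export
coarseGrainStress <- function(tractions, a0 = 1, periodic = c(TRUE, TRUE),
                              unit = "sim", time = 0) {
  d <- dim(tractions)
  if (is.null(d) || !(length(d) %in% c(3L, 4L)))
    stop("data error: tractions must be [nx,ny,nz,3] or [nx,ny,2]")
  ndim <- length(d) - 1L
  if (d[length(d)] != ndim)
    stop("data error: last dimension must hold the ", ndim, " traction components")
  shift <- function(a, k, dd) {
    if (dd <= 2L && periodic[dd]) .cshift(a, k, dd)
    else if (dd <= 2L) .cshiftClamp(a, k, dd)
    else a  # placeholder, z handled separately
  }
  if (ndim == 3L) {
    out <- array(0, c(d[1:3], 3, 3))
    for (ax in 1:3) for (comp in 1:3) {
      Tc <- tractions[, , , comp, drop = FALSE]
      dim(Tc) <- d[1:3]
      if (ax < 3L) {
        plus <- shift(Tc, -1L, ax)   # value at x + e_ax
        minus <- shift(Tc, +1L, ax)  # value at x - e_ax
        contrib <- (minus - plus) / a0^2
      } else {
        nz <- d[3]
        plus <- Tc[, , c(2:nz, nz), drop = FALSE]; dim(plus) <- d[1:3]
        minus <- Tc[, , c(1, 1:(nz - 1)), drop = FALSE]; dim(minus) <- d[1:3]
        ## drop the missing neighbour at the walls
        plus[, , nz] <- 0
        minus[, , 1] <- 0
        contrib <- (minus - plus) / a0^2
      }
      out[, , , ax, comp] <- contrib
    }
    new("StressField", values = out, spacing = a0, unit = unit, time = time)
  } else {
    out <- array(0, c(d[1:2], 2, 2))
    for (ax in 1:2) for (comp in 1:2) {
      Tc <- tractions[, , comp]
      plus <- shift(Tc, -1L, ax)
      minus <- shift(Tc, +1L, ax)
      out[, , ax, comp] <- (minus - plus) / a0^2
    }
    new("StressField", values = out, spacing = a0, unit = unit, time = time)
  }
}

#' Isotropic (scalar) view of a stress tensor field
#'
#' `"2d-half-trace"` returns \eqn{(\sigma_{xx} + \sigma_{yy})/2} of a 2D
#' tensor field; `"3d-in-plane"` returns the same in-plane half trace of a
#' 3D tensor field per node (project with [zProject()] to obtain the 2D
#' in-plane isotropic stress map).
#'
#' @param stress a [StressField-class] or [Stress2DField-class].
#' @param mode scalarization mode; must match the tensor dimensionality.
#' @return numeric matrix (2D input) or `[nx, ny, nz]` array (3D input).
#' @export
isotropicStress <- function(stress,
                            mode = c("2d-half-trace", "3d-in-plane")) {
  mode <- match.arg(mode)
  if (is(stress, "Stress2DField")) {
    if (mode != "2d-half-trace")
      stop("mode '3d-in-plane' needs a 3D StressField")
    v <- stress@values
    return((v[, , 1] + v[, , 2]) / 2)
  }
  stopifnot(is(stress, "StressField"))
  d <- dim(stress@values)
  if (length(d) == 4L) {
    if (mode != "2d-half-trace")
      stop("mode '3d-in-plane' needs a 3D StressField")
    return((stress@values[, , 1, 1] + stress@values[, , 2, 2]) / 2)
  }
  if (mode != "3d-in-plane")
    stop("mode '2d-half-trace' needs a 2D stress tensor")
  (stress@values[, , , 1, 1] + stress@values[, , , 2, 2]) / 2
}

#' Out-of-plane stress component of a 3D stress field
#' @param stress a 3D [StressField-class].
#' @return `[nx, ny, nz]` array of \eqn{\sigma_{zz}}.
#' @export
sigmaZZ <- function(stress) {
  stopifnot(is(stress, "StressField"))
  if (length(dim(stress@values)) != 5L)
    stop("unsupported mode: sigma_zz requires a 3D stress field")
  stress@values[, , , 3, 3]
}

#' Susceptibility of a sample of field values
#'
#' \eqn{\chi = N (\langle A^2\rangle - \langle A\rangle^2)}: the population
#' variance scaled by the declared sample-size convention N (number of cells,
#' or number of pixels as a proxy when cell counts are inconvenient).
#'
#' @param values numeric sample (NA/non-finite values dropped).
#' @param N sample-size convention; defaults to the number of finite values.
#' @return `chi` with attribute `"N"` recording the convention used.
#' @examples
#' susceptibility(c(0, 2), N = 2)  # 2 * var_pop = 2
#' @export
susceptibility <- function(values, N = NULL) {
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("insufficient data: susceptibility needs at least 2 samples")
  if (is.null(N)) N <- length(values)
  chi <- N * .popVar(values)
  attr(chi, "N") <- N
  chi
}

#' Susceptibility profile versus distance from the interface
#'
#' Pixels are binned by their Euclidean distance to the two-population
#' interface, separately per type; the susceptibility is computed per bin
#' from all pixel values across space and frames, with N taken as the mean
#' number of contributing pixels per frame (pixel convention).  Bins with
#' fewer than 2 samples are reported as `NA`, not zero.
#'
#' @param frames numeric array `[nx, ny, nt]` of scalar field frames.
#' @param occ occupancy matrix, or `[nx, ny, nt]` array of occupancy frames
#'   (character).
#' @param binWidth distance bin width in pixels.
#' @param maxDist largest distance binned; default covers the domain.
#' @param normalize if `TRUE`, divide by the maximum bin value.
#' @param periodic passed to [interfaceDistance()].
#' @param types which type labels to profile.
#' @return data.frame with `type`, `distance` (bin center), `chi`, `n`
#'   (mean pixels per frame); attribute `"normalization"` records `"none"`
#'   or `"max"` (per type).
#' @export
susceptibilityProfile <- function(frames, occ, binWidth = 5, maxDist = NULL,
                                  normalize = FALSE,
                                  periodic = c(FALSE, FALSE),
                                  types = c("A", "B")) {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1))
  nt <- dim(frames)[3]
  occArr <- if (is.matrix(occ)) array(occ, c(dim(occ), nt)) else occ
  stopifnot(all(dim(occArr)[1:2] == dim(frames)[1:2]),
            dim(occArr)[3] == nt)
  if (is.null(maxDist)) maxDist <- min(dim(frames)[1:2]) / 2
  breaks <- seq(0, maxDist + binWidth, by = binWidth)
  nb <- length(breaks) - 1L

  samples <- vector("list", length(types)); names(samples) <- types
  counts <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  for (ty in types) samples[[ty]] <- vector("list", nb)
  staticOcc <- is.matrix(occ)
  dmap <- NULL
  for (f in seq_len(nt)) {
    o <- occArr[, , f]
    if (is.null(dmap) || !staticOcc)
      dmap <- interfaceDistance(o, periodic)$distance
    bin <- findInterval(dmap, breaks, rightmost.closed = TRUE)
    for (ty in types) {
      sel <- o == ty & bin >= 1 & bin <= nb
      if (!any(sel)) next
      b <- bin[sel]; v <- frames[, , f][sel]
      for (k in unique(b)) {
        samples[[ty]][[k]] <- c(samples[[ty]][[k]], v[b == k])
        counts[k, ty] <- counts[k, ty] + sum(b == k)
      }
    }
  }
  out <- do.call(rbind, lapply(types, function(ty) {
    chi <- vapply(seq_len(nb), function(k) {
      v <- samples[[ty]][[k]]
      if (length(v) < 2L) return(NA_real_)
      as.numeric(susceptibility(v, N = counts[k, ty] / nt))
    }, numeric(1))
    data.frame(type = ty, distance = breaks[-length(breaks)] + binWidth / 2,
               chi = chi, n = counts[, ty] / nt)
  }))
  if (normalize) {
    for (ty in types) {
      sel <- out$type == ty
      m <- max(out$chi[sel], na.rm = TRUE)
      out$chi[sel] <- out$chi[sel] / m
    }
  }
  attr(out, "normalization") <- if (normalize) "max" else "none"
  attr(out, "Nconvention") <- "pixels per frame in bin"
  out
}

#' Masked spatial autocorrelation and zero-crossing correlation length
#'
#' Radially averaged, normalized spatial autocorrelation of a scalar field
#' within a mask (the region of one cell type), averaged over frames.  The
#' per-frame mean over the mask is subtracted; pair sums are computed with
#' zero-padded FFTs and normalized by the number of valid pixel pairs at
#' each lag.  The correlation length is the first zero crossing of C(r)
#' (linear interpolation between radial bins); if C never crosses zero the
#' length is right-censored at the largest lag.
#'
#' @param frames `[nx, ny, nt]` array (or a matrix for a single frame).
#' @param mask logical matrix selecting the region (default: all pixels).
#' @param maxLag largest lag (pixels); default `min(nx, ny)/2`.
#' @return list with `curve` (data.frame `r`, `C`, `npairs`), `length`
#'   (zero-crossing length in pixels) and `censored` (logical).
#' @export
spatialAutocorrelation <- function(frames, mask = NULL, maxLag = NULL) {
  if (length(dim(frames)) == 2L) frames <- array(frames, c(dim(frames), 1))
  nx <- dim(frames)[1]; ny <- dim(frames)[2]; nt <- dim(frames)[3]
  if (is.null(mask)) mask <- matrix(TRUE, nx, ny)
  stopifnot(all(dim(mask) == c(nx, ny)))
  if (max(rowSums(mask)) < 32 && max(colSums(mask)) < 32)
    stop("mask region too small: need >= 32 pixels of linear extent")
  if (is.null(maxLag)) maxLag <- floor(min(nx, ny) / 2)
  px <- 2L * nx; py <- 2L * ny
  m <- matrix(0, px, py); m[1:nx, 1:ny] <- mask
  mhat <- fft(m)
  pairs <- Re(fft(Mod(mhat)^2, inverse = TRUE)) / (px * py)
  num <- matrix(0, px, py)
  for (f in seq_len(nt)) {
    v <- frames[, , f]
    v[!mask] <- 0
    mu <- sum(v) / sum(mask)
    v[mask] <- v[mask] - mu
    vp <- matrix(0, px, py); vp[1:nx, 1:ny] <- v
    vhat <- fft(vp)
    num <- num + Re(fft(Mod(vhat)^2, inverse = TRUE)) / (px * py)
  }
  pairs <- pairs * nt
  C <- num / pmax(pairs, 1e-9)
  C[pairs < nt] <- NA  # lags with no valid pairs
  ## radial average over lags
  lx <- c(0:(px / 2), -((px / 2 - 1):1))
  ly <- c(0:(py / 2), -((py / 2 - 1):1))
  r <- sqrt(outer(lx^2, ly^2, `+`))
  keep <- r <= maxLag & !is.na(C) & pairs >= nt
  rb <- round(r[keep])
  cv <- C[keep]; w <- pairs[keep]
  sums <- tapply(cv * w, rb, sum)
  wts <- tapply(w, rb, sum)
  np <- tapply(w, rb, sum) / nt
  rr <- as.numeric(names(sums))
  Cr <- as.numeric(sums / wts)
  o <- order(rr); rr <- rr[o]; Cr <- Cr[o]; np <- as.numeric(np)[o]
  Cr <- Cr / Cr[1]
  ## first zero crossing, linearly interpolated
  censored <- TRUE
  len <- max(rr)
  idx <- which(Cr <= 0)
  if (length(idx)) {
    k <- idx[1]
    censored <- FALSE
    if (k == 1L) len <- rr[1]
    else {
      r0 <- rr[k - 1]; r1 <- rr[k]; c0 <- Cr[k - 1]; c1 <- Cr[k]
      len <- r0 + c0 * (r1 - r0) / (c0 - c1)
    }
  }
  list(curve = data.frame(r = rr, C = Cr, npairs = np),
       length = len, censored = censored)
}

#' @rdname spatialAutocorrelation
#' @param occ optional occupancy matrix; when given, one correlation length
#'   is returned per type label in `types`.
#' @param types type labels to analyse when `occ` is supplied.
#' @return `correlationLength` returns a data.frame with `type`, `length`,
#'   `censored`.
#' @export
correlationLength <- function(frames, occ = NULL, types = c("A", "B"),
                              maxLag = NULL) {
  if (is.null(occ)) {
    a <- spatialAutocorrelation(frames, maxLag = maxLag)
    return(data.frame(type = "all", length = a$length,
                      censored = a$censored))
  }
  do.call(rbind, lapply(types, function(ty) {
    a <- spatialAutocorrelation(frames, mask = occ == ty, maxLag = maxLag)
    data.frame(type = ty, length = a$length, censored = a$censored)
  }))
}
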