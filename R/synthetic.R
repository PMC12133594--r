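## Synthetic-data generators.
##
## Each generator is a pure function of its arguments including the seed:
## the same call reproduces the same output bit-exactly.  Generated ground
## truths carry their true parameters as attributes so downstream tests
## never re-derive them.

#' Stationary Gaussian random field with squared-exponential covariance
#'
#' Spectral synthesis of frames of a zero-mean Gaussian field with
#' covariance \eqn{C(r) = v\,\exp(-r^2 / (2\ell^2))} on a periodic grid.
#' White noise is filtered in Fourier space with the square root of the
#' squared-exponential spectrum and rescaled so the expected variance
#' equals `variance` exactly.  `ell = 0` gives white noise.
#'
#' @param nx,ny grid size (pixels).
#' @param ell correlation length \eqn{\ell} in pixels; must be below a
#'   quarter of the smaller grid extent.
#' @param variance target field variance.
#' @param nFrames number of independent frames.
#' @param seed integer seed.
#' @return `[nx, ny, nFrames]` array with attributes `ell`, `variance`,
#'   `seed`.
#' @export
genGaussianField <- function(nx, ny = nx, ell, variance = 1, nFrames = 1,
                             seed = 1) {
  if (ell < 0 || ell >= min(nx, ny) / 4)
    stop("configuration error: need 0 <= ell < min(nx, ny)/4")
  set.seed(seed)
  kx <- matrix(.kvec(nx, 1), nx, ny)
  ky <- matrix(.kvec(ny, 1), nx, ny, byrow = TRUE)
  H <- exp(-(kx^2 + ky^2) * ell^2 / 4)
  scale <- sqrt(variance * nx * ny / sum(H^2))
  out <- array(0, c(nx, ny, nFrames))
  ## with unit white noise, Var(field) = scale^2 * sum(H^2)/(nx*ny)
  for (f in seq_len(nFrames)) {
    w <- matrix(rnorm(nx * ny), nx, ny)
    out[, , f] <- Re(fft(fft(w) * H, inverse = TRUE)) / (nx * ny) * scale
  }
  attr(out, "ell") <- ell
  attr(out, "variance") <- variance
  attr(out, "seed") <- seed
  out
}

#' Smooth stress/traction ground-truth pair for stress-inversion benchmarks
#'
#' Draws two smooth Gaussian random potentials and maps them through the
#' adjoint of the discrete force-balance (divergence) operator, producing a
#' smooth random symmetric 2D stress tensor that lies in the identifiable
#' class of the force-balance inversion, with the boundary gauge (zero mean
#' boundary normal and shear stress) applied.  The paired traction is the
#' exact discrete forward image \eqn{t = -\nabla\cdot\sigma}.
#'
#' @param nx,ny grid size (>= 64 recommended).
#' @param smoothness correlation length (pixels) of the generating
#'   potentials; must be positive.
#' @param targetSd standard deviation to which the largest stress component
#'   is scaled.
#' @param pixelSize pixel size (um).
#' @param seed integer seed.
#' @return list with `stress` ([Stress2DField-class]) and `traction`
#'   ([TractionField2D-class]); attribute `params` records the call.
#' @export
genStressTractionPair <- function(nx = 128, ny = nx, smoothness = 8,
                                  targetSd = 1, pixelSize = 1, seed = 1) {
  if (smoothness <= 0)
    stop("configuration error: smoothness must be positive")
  w <- genGaussianField(nx, ny, ell = smoothness, variance = 1,
                        nFrames = 2, seed = seed)
  A <- .bismA(nx, ny, pixelSize)
  wvec <- c(as.vector(w[, , 1]), as.vector(w[, , 2]))
  s <- as.vector(Matrix::crossprod(A, wvec))
  n <- nx * ny
  sxx <- matrix(s[1:n], nx, ny)
  syy <- matrix(s[n + 1:n], nx, ny)
  sxy <- matrix(s[2 * n + 1:n], nx, ny)
  sc <- targetSd / max(sd(sxx), sd(syy), sd(sxy))
  g <- .bismGauge(sxx * sc, syy * sc, sxy * sc)
  stress <- stress2DField(array(c(g$sxx, g$syy, g$sxy), c(nx, ny, 3)),
                          pixelSize = pixelSize)
  traction <- forwardTractionFromStress(stress)
  out <- list(stress = stress, traction = traction)
  attr(out, "params") <- list(nx = nx, ny = ny, smoothness = smoothness,
                              targetSd = targetSd, seed = seed)
  out
}

#' Scalar field frames with boosted variance near the interface
#'
#' Ground truth for the susceptibility profile: independent Gaussian pixels
#' whose variance is multiplied by `boost` within `bandWidth` pixels of the
#' two-population interface.
#'
#' @param occ occupancy matrix.
#' @param boost variance multiplication factor inside the band.
#' @param bandWidth band half-width in pixels.
#' @param baseVariance variance outside the band.
#' @param nFrames number of frames.
#' @param periodic passed to [interfaceDistance()].
#' @param seed integer seed.
#' @return `[nx, ny, nFrames]` array with attributes recording the truth.
#' @export
genInterfaceVarianceField <- function(occ, boost = 4, bandWidth = 10,
                                      baseVariance = 1, nFrames = 10,
                                      periodic = c(FALSE, FALSE), seed = 1) {
  stopifnot(boost > 0, bandWidth > 0)
  d <- interfaceDistance(occ, periodic)$distance
  sdMap <- sqrt(baseVariance) * ifelse(d <= bandWidth, sqrt(boost), 1)
  set.seed(seed)
  nx <- nrow(occ); ny <- ncol(occ)
  out <- array(rnorm(nx * ny * nFrames), c(nx, ny, nFrames)) *
    array(sdMap, c(nx, ny, nFrames))
  attr(out, "boost") <- boost
  attr(out, "bandWidth") <- bandWidth
  attr(out, "seed") <- seed
  out
}

#' Synthetic extrusion catalog with a prescribed interface-distance law
#'
#' Samples event positions within one type's region, either uniformly or
#' with probability decaying exponentially with distance from the
#' interface, and assigns frames uniformly.
#'
#' @param occ occupancy matrix.
#' @param nEvents number of events.
#' @param type type label whose region receives the events.
#' @param bias `"uniform"` or `"exp"`.
#' @param decay e-folding distance (pixels) of the exponential bias.
#' @param nFrames number of frames the events are spread over.
#' @param periodic passed to [interfaceDistance()].
#' @param seed integer seed.
#' @return data.frame `frame`, `x`, `y`, `type` with attribute `params`.
#' @export
genExtrusionCatalog <- function(occ, nEvents, type = "B",
                                bias = c("uniform", "exp"), decay = 10,
                                nFrames = 1, periodic = c(FALSE, FALSE),
                                seed = 1) {
  bias <- match.arg(bias)
  d <- interfaceDistance(occ, periodic)$distance
  sel <- which(occ == type)
  if (!length(sel)) stop("no pixels of type ", type)
  wt <- if (bias == "uniform") rep(1, length(sel))
        else exp(-d[sel] / decay)
  set.seed(seed)
  idx <- sample(sel, nEvents, replace = TRUE, prob = wt)
  xy <- arrayInd(idx, dim(occ))
  out <- data.frame(frame = sample.int(nFrames, nEvents, replace = TRUE),
                    x = xy[, 1], y = xy[, 2],
                    type = type)
  attr(out, "params") <- list(bias = bias, decay = decay, seed = seed,
                              nEvents = nEvents)
  out
}

#' Noisy bead-displacement field from a known traction
#'
#' Forward Boussinesq displacement of a traction field plus i.i.d. Gaussian
#' noise, emulating PIV output for traction-recovery benchmarks.
#'
#' @param traction a [TractionField2D-class].
#' @param substrate an [ElasticSubstrate-class].
#' @param noiseSd standard deviation of the additive noise (um); may be
#'   given as a fraction of `max |u|` via `noiseRel`.
#' @param noiseRel optional relative noise level; overrides `noiseSd`.
#' @param seed integer seed.
#' @return a [DisplacementField2D-class] with attributes `noiseSd`, `seed`.
#' @export
genDisplacementFromTraction <- function(traction, substrate, noiseSd = 0,
                                        noiseRel = NULL, seed = 1) {
  u <- forwardDisplacement(traction, substrate)
  if (!is.null(noiseRel)) noiseSd <- noiseRel * max(abs(u@values))
  v <- u@values
  if (noiseSd > 0) {
    set.seed(seed)
    v <- v + array(rnorm(length(v), sd = noiseSd), dim(v))
  }
  out <- displacementField(v, pixelSize = u@pixelSize, frame = u@frame)
  attr(out, "noiseSd") <- noiseSd
  attr(out, "seed") <- seed
  out
}

#' Band-limited random traction field
#'
#' Zero-mean periodic Gaussian random traction with squared-exponential
#' correlation, the ground truth of the traction-recovery benchmark (the
#' smooth, spatially coherent tractions a confluent monolayer exerts).
#'
#' @param nx,ny grid size.
#' @param ell correlation length in pixels.
#' @param sdT standard deviation of each traction component (Pa).
#' @param pixelSize pixel size (um).
#' @param seed integer seed.
#' @return a [TractionField2D-class] with attribute `params`.
#' @export
genTractionField <- function(nx = 128, ny = nx, ell = 6, sdT = 50,
                             pixelSize = 1, seed = 1) {
  f <- genGaussianField(nx, ny, ell = ell, variance = sdT^2, nFrames = 2,
                        seed = seed)
  out <- tractionField(array(c(f[, , 1] - mean(f[, , 1]),
                               f[, , 2] - mean(f[, , 2])), c(nx, ny, 2)),
                       pixelSize = pixelSize)
  attr(out, "params") <- list(ell = ell, sdT = sdT, seed = seed)
  out
}
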