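## Traction recovery and tissue-stress inference.
##
## forwardDisplacement(): Boussinesq half-space convolution in Fourier space
## (validation oracle for the inversion).
## fttc(): Tikhonov-regularized Fourier-transform traction cytometry.
## bism(): Bayesian inversion stress microscopy -- regularized least-squares
## inversion of 2D force balance div(sigma) = -t for the symmetric tissue
## stress tensor, with the undetermined additive constants (pressure/shear
## gauge) fixed by zero mean normal stress on the domain boundary.

#' Construct an elastic substrate description
#'
#' @param E Young modulus (Pa).
#' @param nu Poisson ratio; 0.5 for incompressible silicone gels.
#' @param lambdaFTTC Tikhonov regularization for [fttc()].
#' @param LambdaBISM dimensionless regularization for [bism()].
#' @return an [ElasticSubstrate-class] object.
#' @export
elasticSubstrate <- function(E, nu = 0.5, lambdaFTTC = 9e-9,
                             LambdaBISM = 1e-6) {
  new("ElasticSubstrate", E = E, nu = nu, lambdaFTTC = lambdaFTTC,
      LambdaBISM = LambdaBISM)
}

#' Construct 2D field objects
#'
#' Thin constructors over the [Field2D-class] subclasses.
#'
#' @param values array `[nx, ny, 2]` (x, y channels) for displacement and
#'   traction, `[nx, ny, 3]` (xx, yy, xy channels) for stress.
#' @param pixelSize pixel size (um).
#' @param unit unit label.
#' @param frame frame index.
#' @return the corresponding [Field2D-class] subclass object.
#' @export
displacementField <- function(values, pixelSize = 1, unit = "um",
                              frame = 1L) {
  new("DisplacementField2D", values = values, pixelSize = pixelSize,
      unit = unit, frame = as.integer(frame))
}

#' @rdname displacementField
#' @export
tractionField <- function(values, pixelSize = 1, unit = "Pa", frame = 1L) {
  new("TractionField2D", values = values, pixelSize = pixelSize,
      unit = unit, frame = as.integer(frame))
}

#' @rdname displacementField
#' @export
stress2DField <- function(values, pixelSize = 1, unit = "Pa*um", frame = 1L) {
  new("Stress2DField", values = values, pixelSize = pixelSize,
      unit = unit, frame = as.integer(frame))
}

## Fourier wavenumbers for an n-point grid with spacing d (cycles -> rad/um)
.kvec <- function(n, d) {
  i <- c(0:floor((n - 1) / 2), -(ceiling((n - 1) / 2):1))
  2 * pi * i / (n * d)
}

## Boussinesq half-space Green tensor per Fourier mode.
## Returns list(Gxx, Gyy, Gxy) of nx x ny matrices; the k = 0 entry is 0
## (rigid mode excluded; force balance over the field of view).
.greensTensor <- function(nx, ny, d, E, nu) {
  kx <- matrix(.kvec(nx, d), nx, ny)
  ky <- matrix(.kvec(ny, d), nx, ny, byrow = TRUE)
  k2 <- kx^2 + ky^2
  k <- sqrt(k2)
  pref <- 2 * (1 + nu) / (E * k^3)
  Gxx <- pref * ((1 - nu) * k2 + nu * ky^2)
  Gyy <- pref * ((1 - nu) * k2 + nu * kx^2)
  Gxy <- pref * (-nu * kx * ky)
  Gxx[1, 1] <- Gyy[1, 1] <- Gxy[1, 1] <- 0
  list(Gxx = Gxx, Gyy = Gyy, Gxy = Gxy)
}

#' Substrate displacement generated by a traction field
#'
#' Forward Boussinesq model: the displacement of the surface of a
#' linear-elastic half-space under a periodic traction field,
#' \eqn{\hat u(k) = G(k) \hat t(k)} with the standard half-space Green
#' tensor for Young modulus E and Poisson ratio \eqn{\nu}.  Used as the
#' validation oracle for [fttc()].
#'
#' @param traction a [TractionField2D-class] (Pa) on a square-pixel grid.
#' @param substrate an [ElasticSubstrate-class].
#' @return a [DisplacementField2D-class] (um).
#' @export
forwardDisplacement <- function(traction, substrate) {
  stopifnot(is(traction, "TractionField2D"), is(substrate, "ElasticSubstrate"))
  v <- traction@values
  nx <- dim(v)[1]; ny <- dim(v)[2]
  G <- .greensTensor(nx, ny, traction@pixelSize, substrate@E, substrate@nu)
  tx <- fft(v[, , 1]); ty <- fft(v[, , 2])
  ux <- Re(fft(G$Gxx * tx + G$Gxy * ty, inverse = TRUE)) / (nx * ny)
  uy <- Re(fft(G$Gxy * tx + G$Gyy * ty, inverse = TRUE)) / (nx * ny)
  displacementField(array(c(ux, uy), c(nx, ny, 2)),
                    pixelSize = traction@pixelSize, unit = "um",
                    frame = traction@frame)
}

#' Fourier-transform traction cytometry
#'
#' Recovers the traction field from a substrate displacement field by
#' Tikhonov-regularized inversion of the Boussinesq forward model, one
#' Fourier mode at a time:
#' \eqn{\hat t = (G^T G + \lambda I)^{-1} G^T \hat u}.  The displacement is
#' drift-corrected (mean subtracted) and the zero-frequency (rigid) traction
#' mode is set to zero, so the recovered traction field has zero mean.
#'
#' @param displacement a [DisplacementField2D-class] (um).
#' @param substrate an [ElasticSubstrate-class]; `lambdaFTTC` is its
#'   regularization (default \eqn{9 \times 10^{-9}}).
#' @param lambda optional override of the regularization parameter.
#' @return a [TractionField2D-class] (Pa).
#' @export
fttc <- function(displacement, substrate, lambda = NULL) {
  stopifnot(is(displacement, "DisplacementField2D"),
            is(substrate, "ElasticSubstrate"))
  lam <- if (is.null(lambda)) substrate@lambdaFTTC else lambda
  if (lam < 0) stop("configuration error: lambdaFTTC must be >= 0")
  v <- displacement@values
  nx <- dim(v)[1]; ny <- dim(v)[2]
  G <- .greensTensor(nx, ny, displacement@pixelSize, substrate@E,
                     substrate@nu)
  ux <- fft(v[, , 1] - mean(v[, , 1]))
  uy <- fft(v[, , 2] - mean(v[, , 2]))
  ## G is symmetric; M = G^2 + lambda I, solved mode-wise in closed form
  m11 <- G$Gxx^2 + G$Gxy^2 + lam
  m22 <- G$Gyy^2 + G$Gxy^2 + lam
  m12 <- G$Gxy * (G$Gxx + G$Gyy)
  det <- m11 * m22 - m12^2
  b1 <- G$Gxx * ux + G$Gxy * uy
  b2 <- G$Gxy * ux + G$Gyy * uy
  thx <- (m22 * b1 - m12 * b2) / det
  thy <- (m11 * b2 - m12 * b1) / det
  thx[1, 1] <- thy[1, 1] <- 0    # rigid mode
  tx <- Re(fft(thx, inverse = TRUE)) / (nx * ny)
  ty <- Re(fft(thy, inverse = TRUE)) / (nx * ny)
  tractionField(array(c(tx, ty), c(nx, ny, 2)),
                pixelSize = displacement@pixelSize, unit = "Pa",
                frame = displacement@frame)
}

## 1D derivative matrix: central differences, one-sided at the boundary.
.derivMatrix <- function(n, h) {
  i <- c(seq_len(n - 2) + 1L, seq_len(n - 2) + 1L, 1L, 1L, n, n)
  j <- c(seq_len(n - 2) + 2L, seq_len(n - 2), 1L, 2L, n, n - 1L)
  x <- c(rep(1 / (2 * h), n - 2), rep(-1 / (2 * h), n - 2),
         -1 / h, 1 / h, 1 / h, -1 / h)
  Matrix::sparseMatrix(i = i, j = j, x = x, dims = c(n, n))
}

## Discrete divergence operator A mapping sigma = (xx, yy, xy) stacked
## column-major to t-residuals: (div sigma)_x, (div sigma)_y.
.bismOperator <- function(nx, ny, h) {
  Dx <- Matrix::kronecker(Matrix::Diagonal(ny), .derivMatrix(nx, h))
  Dy <- Matrix::kronecker(.derivMatrix(ny, h), Matrix::Diagonal(nx))
  Z <- Matrix::sparseMatrix(i = integer(), j = integer(), x = numeric(),
                            dims = c(nx * ny, nx * ny))
  rbind(cbind(Dx, Z, Dy), cbind(Z, Dy, Dx))
}

## cache of Cholesky factorizations keyed by grid/regularization
.bismCache <- new.env(parent = emptyenv())

.bismA <- function(nx, ny, h) {
  key <- paste("A", nx, ny, signif(h, 12), sep = "_")
  if (is.null(.bismCache[[key]]))
    .bismCache[[key]] <- .bismOperator(nx, ny, h)
  .bismCache[[key]]
}

.bismSystem <- function(nx, ny, h, Lambda) {
  key <- paste(nx, ny, signif(h, 12), signif(Lambda, 12), sep = "_")
  if (!is.null(.bismCache[[key]])) return(.bismCache[[key]])
  A <- .bismA(nx, ny, h)
  AAt <- Matrix::tcrossprod(A)
  scale <- max(Matrix::diag(AAt))   # makes Lambda dimensionless
  M <- AAt + Lambda * scale * Matrix::Diagonal(nrow(AAt))
  ch <- Matrix::Cholesky(M, LDL = FALSE)
  out <- list(A = A, chol = ch)
  .bismCache[[key]] <- out
  out
}

## gauge: zero mean normal stress on the domain boundary (and zero mean
## boundary shear); constants are in the null space of the balance operator
.bismGauge <- function(sxx, syy, sxy) {
  nx <- nrow(sxx); ny <- ncol(sxx)
  sxx <- sxx - mean(sxx[c(1L, nx), ])
  syy <- syy - mean(syy[, c(1L, ny)])
  bnd <- rbind(sxy[c(1L, nx), ], t(sxy[, c(1L, ny)]))
  sxy <- sxy - mean(bnd)
  list(sxx = sxx, syy = syy, sxy = sxy)
}

#' Bayesian inversion stress microscopy
#'
#' Infers the 2D tissue stress tensor from the traction field by solving the
#' mechanical force balance \eqn{\nabla\cdot\sigma = -t} as a
#' Tikhonov-regularized least-squares inversion,
#' \eqn{\sigma = A^T (A A^T + \Lambda\,s\,I)^{-1} b}, where A is the
#' discrete divergence operator, \eqn{b = -t} and s normalizes the system
#' matrix so \eqn{\Lambda} is dimensionless.  The additive constants left
#' undetermined by force balance are fixed by requiring zero mean normal
#' (and shear) stress on the domain boundary.
#'
#' @param traction a [TractionField2D-class] (Pa).
#' @param Lambda regularization weight (default \eqn{10^{-6}}).
#' @return a [Stress2DField-class] with channels (xx, yy, xy) in Pa*um.
#' @export
bism <- function(traction, Lambda = 1e-6) {
  stopifnot(is(traction, "TractionField2D"))
  v <- traction@values
  nx <- dim(v)[1]; ny <- dim(v)[2]
  if (nx * ny == 0L) stop("data error: empty traction field")
  sys <- .bismSystem(nx, ny, traction@pixelSize, Lambda)
  b <- -c(as.vector(v[, , 1]), as.vector(v[, , 2]))
  y <- Matrix::solve(sys$chol, b)
  s <- as.vector(Matrix::crossprod(sys$A, y))
  n <- nx * ny
  g <- .bismGauge(matrix(s[1:n], nx, ny), matrix(s[n + 1:n], nx, ny),
                  matrix(s[2 * n + 1:n], nx, ny))
  stress2DField(array(c(g$sxx, g$syy, g$sxy), c(nx, ny, 3)),
                pixelSize = traction@pixelSize, unit = "Pa*um",
                frame = traction@frame)
}

#' Traction implied by a 2D stress field
#'
#' Computes \eqn{t = -\nabla\cdot\sigma} by central differences (one-sided
#' at the boundary).  This is the forward model used to validate [bism()].
#'
#' @param stress a [Stress2DField-class].
#' @return a [TractionField2D-class].
#' @export
forwardTractionFromStress <- function(stress) {
  stopifnot(is(stress, "Stress2DField"))
  v <- stress@values
  nx <- dim(v)[1]; ny <- dim(v)[2]
  A <- .bismA(nx, ny, stress@pixelSize)
  sig <- c(as.vector(v[, , 1]), as.vector(v[, , 2]), as.vector(v[, , 3]))
  t <- -as.vector(A %*% sig)
  n <- nx * ny
  tractionField(array(c(t[1:n], t[n + 1:n]), c(nx, ny, 2)),
                pixelSize = stress@pixelSize, unit = "Pa",
                frame = stress@frame)
}
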