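test_that("forward Boussinesq displacement: linearity and closed form", {
  sub <- elasticSubstrate(E = 1e4)
  z <- tractionField(array(0, c(32, 32, 2)))
  expect_equal(fieldValues(forwardDisplacement(z, sub)),
               array(0, c(32, 32, 2)))

  # single-frequency traction: compare against the analytic Green tensor
  n <- 64; d <- 1
  k1 <- 2 * pi / (n * d)
  x <- (0:(n - 1)) * d
  tx <- matrix(7 * cos(k1 * x), n, n)       # traction along x, varying in x
  tr <- tractionField(array(c(tx, 0 * tx), c(n, n, 2)), pixelSize = d)
  u <- forwardDisplacement(tr, sub)
  # at k = (k1, 0): Gxx = 2(1+nu)/(E k) * (1-nu)  (ky = 0)
  nu <- 0.5
  Gxx <- 2 * (1 + nu) * (1 - nu) / (sub@E * k1)
  expect_equal(fieldValues(u)[, , 1], Gxx * tx, tolerance = 1e-10)
  expect_equal(max(abs(fieldValues(u)[, , 2])), 0, tolerance = 1e-12)

  # displacement scales as 1/E
  u2 <- forwardDisplacement(tr, elasticSubstrate(E = 2e4))
  expect_equal(fieldValues(u2), fieldValues(u) / 2, tolerance = 1e-12)
})

test_that("fttc inverts the forward model and suppresses noise", {
  sub <- elasticSubstrate(E = 3e4)
  z <- displacementField(array(0, c(32, 32, 2)))
  expect_equal(fieldValues(fttc(z, sub)), array(0, c(32, 32, 2)))

  gt <- genTractionField(64, 64, ell = 6, sdT = 50, seed = 3)
  u0 <- forwardDisplacement(gt, sub)
  t0 <- fttc(u0, sub, lambda = 0)
  nrmse <- sqrt(mean((fieldValues(t0) - fieldValues(gt))^2)) /
    sd(fieldValues(gt))
  expect_lt(nrmse, 0.05)                    # exact modulo roundoff

  # recovered traction has (near) zero mean: rigid mode removed
  expect_lt(max(abs(apply(fieldValues(t0), 3, mean))),
            1e-6 * max(abs(fieldValues(t0))))

  # error decreases over a decade of decreasing regularization (no noise)
  errs <- vapply(c(1e-6, 1e-7), function(l) {
    tt <- fttc(u0, sub, lambda = l)
    sqrt(mean((fieldValues(tt) - fieldValues(gt))^2))
  }, numeric(1))
  expect_lt(errs[2], errs[1])

  # with 5% noise the default regularization keeps high correlation
  un <- genDisplacementFromTraction(gt, sub, noiseRel = 0.05, seed = 11)
  tn <- fttc(un, sub)
  expect_gt(cor(as.vector(fieldValues(tn)), as.vector(fieldValues(gt))),
            0.85)

  expect_error(fttc(u0, sub, lambda = -1), "configuration error")
})

test_that("forward traction from stress matches closed forms", {
  # constant stress: zero traction
  s <- stress2DField(array(5, c(24, 24, 3)))
  expect_equal(max(abs(fieldValues(forwardTractionFromStress(s)))), 0)

  # sigma = diag(p(x), p(x)) with linear p: constant t_x = -dp/dx, t_y = 0
  n <- 32
  p <- matrix((1:n) * 0.5, n, n)
  s2 <- stress2DField(array(c(p, p, 0 * p), c(n, n, 3)))
  t2 <- fieldValues(forwardTractionFromStress(s2))
  expect_equal(t2[, , 1], matrix(-0.5, n, n), tolerance = 1e-12)
  expect_equal(max(abs(t2[, , 2])), 0, tolerance = 1e-12)

  # smooth periodic stress: central differences match the spectral
  # derivative away from the (non-periodic) boundary stencils
  f <- genGaussianField(48, 48, ell = 6, variance = 1, nFrames = 3, seed = 9)
  s3 <- stress2DField(array(c(f[, , 1], f[, , 2], f[, , 3]), c(48, 48, 3)))
  t3 <- fieldValues(forwardTractionFromStress(s3))
  kx <- mechcompete:::.kvec(48, 1)
  dx <- function(m) Re(fft(fft(m) * matrix(1i * kx, 48, 48), inverse = TRUE)) / 48^2
  dy <- function(m) t(dx(t(m)))
  t3spec <- -(dx(f[, , 1]) + dy(f[, , 3]))
  i <- 3:46
  relerr <- sqrt(mean((t3[i, i, 1] - t3spec[i, i])^2)) / sd(t3spec[i, i])
  expect_lt(relerr, 0.05)
})

test_that("bism recovers ground-truth stress and is linear", {
  # zero traction: zero stress under the default gauge
  z <- tractionField(array(0, c(32, 32, 2)))
  expect_equal(max(abs(fieldValues(bism(z)))), 0, tolerance = 1e-12)

  # forward-inverse round trip on a synthetic pair
  gt <- genStressTractionPair(64, 64, smoothness = 6, seed = 4)
  est <- bism(gt$traction, Lambda = 1e-6)
  m <- 3:62
  err <- sqrt(sum((fieldValues(est)[m, m, ] -
                   fieldValues(gt$stress)[m, m, ])^2)) /
    sqrt(sum(fieldValues(gt$stress)[m, m, ]^2))
  expect_lt(err, 0.1)

  # isotropic stress of the recovery matches the truth
  isoErr <- sqrt(mean((isotropicStress(est)[m, m] -
                       isotropicStress(gt$stress)[m, m])^2)) /
    sd(isotropicStress(gt$stress)[m, m])
  expect_lt(isoErr, 0.1)

  # linearity of the inversion
  g2 <- genStressTractionPair(64, 64, smoothness = 8, seed = 5)
  tl <- tractionField(2 * fieldValues(gt$traction) -
                      0.5 * fieldValues(g2$traction))
  lhs <- fieldValues(bism(tl))
  rhs <- 2 * fieldValues(bism(gt$traction)) -
    0.5 * fieldValues(bism(g2$traction))
  expect_equal(lhs, rhs, tolerance = 1e-8)
})

test_that("all inversion operations are linear in their field argument", {
  sub <- elasticSubstrate(E = 2e4)
  t1 <- genTractionField(48, 48, ell = 6, seed = 1)
  t2 <- genTractionField(48, 48, ell = 8, seed = 2)
  mix <- tractionField(3 * fieldValues(t1) + 2 * fieldValues(t2))
  expect_equal(fieldValues(forwardDisplacement(mix, sub)),
               3 * fieldValues(forwardDisplacement(t1, sub)) +
                 2 * fieldValues(forwardDisplacement(t2, sub)),
               tolerance = 1e-10)
  u1 <- forwardDisplacement(t1, sub); u2 <- forwardDisplacement(t2, sub)
  umix <- displacementField(3 * fieldValues(u1) + 2 * fieldValues(u2))
  expect_equal(fieldValues(fttc(umix, sub)),
               3 * fieldValues(fttc(u1, sub)) + 2 * fieldValues(fttc(u2, sub)),
               tolerance = 1e-8)
})
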