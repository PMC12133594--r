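test_that("lattice initialization matches the reference geometries", {
  # the reference full-scale run: 400 cells tile a 320 x 320 plane as 20 x 20
  lay <- mechcompete:::.latticeLayout(400, 320, 320, 1, 8)
  expect_equal(lay$ncols, 20L)
  expect_equal(lay$nrows, 20)
  expect_equal(lay$sx, 16)

  # overflow: too many cells for the grid names the violated dimension
  expect_error(mechcompete:::.latticeLayout(64, 40, 40, 1, 8),
               "do not fit.*x|y")

  # single cell: centered in x, y, resting on the substrate
  cfg <- tinyPassiveConfig(nSim = 1L)
  st <- initializeMonolayer(cfg)
  p2 <- st@phi[, , , 1]^2
  cx <- sum(rowSums(p2) * ((1:28) - 0.5)) / sum(p2)
  expect_equal(cx, 14, tolerance = 0.05)
  expect_gt(sum(p2 * st@substrate^2), 0)   # touches the substrate field

  # polarity seeded: same seed, same angles
  st2 <- initializeMonolayer(cfg)
  expect_identical(st@theta, st2@theta)

  # initial phase-field volume within 10% of the target
  expect_equal(cellVolume(st, i = 1), targetVolume(cfg), tolerance = 0.1)
})

test_that("cellVolume integrates phi^2 over the grid", {
  expect_equal(cellVolume(array(0, c(4, 4, 4))), 0)
  expect_equal(cellVolume(array(1, c(4, 5, 6))), 120)
  expect_equal(cellVolume(array(1, c(4, 4, 4)), a0 = 2), 64 * 8)
  bad <- array(1, c(3, 3, 3)); bad[1] <- NA
  expect_error(cellVolume(bad), "data error")
})

test_that("functional derivative is the exact gradient of the energy", {
  cfg <- tinyPassiveConfig(nx = 20, ny = 20, nz = 14, R0 = 4, nSim = 1L)

  # phi = 0 everywhere: all terms vanish
  z <- monolayerFromPhi(array(0, c(20, 20, 14, 1)), cfg,
                        substrate = initializeMonolayer(cfg)@substrate)
  expect_equal(max(abs(functionalDerivative(z, 1))), 0)

  # perturbation test against the independent energy oracle
  st <- initializeMonolayer(cfg)
  dF <- functionalDerivative(st)
  E0 <- energyOracle(st)
  expect_equal(totalEnergy(st), E0, tolerance = 1e-10)
  set.seed(20)
  dphi <- array(rnorm(prod(dim(st@phi)), sd = 1e-4), dim(st@phi))
  st1 <- st; st1@phi <- st@phi + dphi
  dE <- energyOracle(st1) - E0
  predicted <- sum(dF * dphi) * cfg@a0^3
  expect_equal(dE, predicted, tolerance = 1e-3)

  # overlapping cells with repulsion: derivative positive in the overlap
  cfg2 <- tinyActiveConfig(nSim = 1L)
  two <- initializeMonolayer(cfg2)
  # place the two droplets on top of each other
  two@phi[, , , 2] <- two@phi[, , , 1]
  dF1 <- functionalDerivative(two, 1)
  core <- two@phi[, , , 2]^2 > 0.5
  expect_gt(mean(dF1[core]), 0)
})

test_that("shape tensor is trace-free and tracks elongation", {
  cfg <- tinyPassiveConfig(nx = 36, ny = 28, nz = 24, R0 = 5, nSim = 1L)
  st <- initializeMonolayer(cfg)
  S <- shapeTensor(st, 1)
  expect_lt(abs(sum(diag(S))), 1e-10 * sum(abs(S)))

  # spherically symmetric droplet: S vanishes relative to the gradient norm
  gradNorm <- -sum(diag(shapeTensor(st, 1))) + {
    f <- st@phi[, , , 1]
    gx <- (f[c(2:36, 1), , ] - f[c(36, 1:35), , ]) / 2
    sum(gx^2) * 3  # order-of-magnitude scale of int |grad phi|^2
  }
  expect_lt(max(abs(S)), 0.01 * gradNorm)

  # analytic ellipsoidal profile elongated along x: quadrature oracle gives
  # the positive eigenvalue along the elongation axis
  nx <- 40; ny <- 30; nz <- 30
  xs <- (1:nx) - 0.5; ys <- (1:ny) - 0.5; zs <- (1:nz) - 0.5
  r <- sqrt(outer(outer(((xs - 20) / 12)^2, ((ys - 15) / 6)^2, `+`),
                  ((zs - 15) / 6)^2, `+`))
  phi <- array(0.5 * (1 + tanh(2 * (1 - r) / 0.2)), c(nx, ny, nz, 1))
  cfge <- simConfig(nx = nx, ny = ny, nz = nz, nCell = 1, R0 = 5,
                    geometry = "single")
  ste <- monolayerFromPhi(phi, cfge)
  Se <- shapeTensor(ste, 1)
  expect_gt(Se[1, 1], Se[2, 2])
  expect_gt(Se[1, 1], 0)
  expect_lt(Se[2, 2], 0)
})

test_that("interaction stress composes the specified terms", {
  cfg <- tinyActiveConfig(nSim = 1L)
  st <- initializeMonolayer(cfg)

  # with all active stresses off, the stress is isotropic -sum dF
  passiveParams <- cellTypeParams(zetaS = 0, zetaQ = 0, alpha = 0, Dr = 0)
  cfg0 <- simConfig(nx = 32, ny = 16, nz = 14, nCell = 2, R0 = 5,
                    geometry = "collision-two-interfaces",
                    typeParams = list(A = passiveParams, B = passiveParams),
                    nSim = 1L, seed = 5L)
  st0 <- initializeMonolayer(cfg0)
  Pi0 <- fieldValues(interactionStress(st0))
  dF <- functionalDerivative(st0)
  isoOracle <- -(dF[, , , 1] + dF[, , , 2])
  expect_equal(Pi0[, , , 1, 1], isoOracle, tolerance = 1e-10)
  expect_equal(Pi0[, , , 2, 2], isoOracle, tolerance = 1e-10)
  expect_equal(max(abs(Pi0[, , , 1, 2])), 0, tolerance = 1e-12)

  # the substrate active term is proportional to phi_w Q_w: difference
  # between runs that differ only in zeta_Q vanishes off the substrate
  pQ <- cellTypeParams(zetaQ = 0)
  cfgQ <- simConfig(nx = 32, ny = 16, nz = 14, nCell = 2, R0 = 5,
                    geometry = "collision-two-interfaces",
                    typeParams = list(A = pQ, B = pQ), nSim = 1L, seed = 5L)
  stQ <- initializeMonolayer(cfgQ)
  stQ@phi <- st@phi; stQ@theta <- st@theta
  dPi <- fieldValues(interactionStress(st)) -
    fieldValues(interactionStress(stQ))
  zqsum <- 2 * cfg@typeParams$A@zetaQ
  oracleQ <- -zqsum * st@substrate     # times Qw = diag(1, -1/2, -1/2)
  expect_equal(dPi[, , , 1, 1], oracleQ, tolerance = 1e-10)
  expect_equal(dPi[, , , 2, 2], -0.5 * oracleQ, tolerance = 1e-10)
  expect_equal(dPi[, , , 3, 3], -0.5 * oracleQ, tolerance = 1e-10)
  # off the substrate the tanh tail is negligible: no active push there
  topLayer <- dim(oracleQ)[3]
  expect_lt(max(abs(dPi[, , topLayer, , ])), 1e-8)
})

test_that("velocity and traction follow the overdamped force balance", {
  # all fields zero: traction zero, velocity is the self-propulsion
  cfg <- tinyActiveConfig(nSim = 1L)
  z <- monolayerFromPhi(array(0, c(32, 16, 14, 2)), cfg,
                        theta = c(0, pi / 2), types = c("A", "B"),
                        substrate = initializeMonolayer(cfg)@substrate)
  vt <- computeVelocityTraction(z)
  expect_equal(max(abs(vt$traction)), 0)
  alpha <- cfg@typeParams$A@alpha
  expect_equal(vt$velocity[1, ], c(alpha, 0, 0) / cfg@xi, tolerance = 1e-12)
  expect_equal(vt$velocity[2, ], c(0, alpha, 0) / cfg@xi, tolerance = 1e-10)

  # generic state: traction equals an independent R quadrature of the
  # stress-gradient integral (shared stress + per-cell substrate activity)
  st <- initializeMonolayer(cfg)
  vt2 <- computeVelocityTraction(st)
  Pi <- fieldValues(interactionStress(st))
  zq <- vapply(st@type, function(ty) cfg@typeParams[[ty]]@zetaQ, numeric(1))
  zqsum <- sum(zq)
  Qw <- diag(c(1, -0.5, -0.5))
  grad <- function(f, d) {
    n <- dim(f)[d]
    if (d < 3) (mechcompete:::.cshift(f, -1, d) -
                mechcompete:::.cshift(f, 1, d)) / 2
    else {
      up <- f[, , c(2:n, n)]; dn <- f[, , c(1, 1:(n - 1))]
      den <- array(2, dim(f)); den[, , c(1, n)] <- 1
      (up - dn) / den
    }
  }
  for (i in 1:2) {
    f <- st@phi[, , , i]
    g <- list(grad(f, 1), grad(f, 2), grad(f, 3))
    Fi <- numeric(3)
    for (a in 1:3) {
      acc <- 0
      for (b in 1:3) {
        Pab <- Pi[, , , a, b]
        # replace the shared zetaQ sum with this cell's own coefficient,
        # in-plane components only (fibres act in-plane)
        if (a == b && a < 3)
          Pab <- Pab + (zqsum - zq[i]) * st@substrate * Qw[a, a]
        if (a == b && a == 3)
          Pab <- Pab + zqsum * st@substrate * Qw[a, a]
        acc <- acc + sum(Pab * g[[b]])
      }
      Fi[a] <- -acc * cfg@a0^3
    }
    expect_equal(unname(vt2$traction[i, ]), Fi, tolerance = 1e-8)
  }
})

test_that("polarity dynamics aligns to the traction and diffuses", {
  # aligned polarity is unchanged without noise
  expect_equal(polarityStep(0.3, cos(0.3), sin(0.3), 1, 0, 0.1), 0.3)
  # a quarter-turn misalignment relaxes by dt/tau of the angle
  set.seed(1)
  th <- polarityStep(pi / 2, 1, 0, tauPol = 1, Dr = 0, dt = 0.1)
  expect_equal(th, pi / 2 - 0.05 * pi)
  # zero traction: no deterministic drift
  expect_equal(polarityStep(1.2, 0, 0, 1, 0, 0.1), 1.2)
  # wrap stays in (-pi, pi]
  expect_lte(polarityStep(pi, cos(-3), sin(-3), 10, 0, 0.5), pi)

  # rotational diffusion: <cos(theta - theta0)> decays as exp(-Dr t)
  n <- 10000; Dr <- 0.4; dt <- 0.05; nsteps <- 40
  set.seed(2)
  th <- rep(0, n)
  zero <- rep(0, n)
  for (k in seq_len(nsteps)) th <- polarityStep(th, zero, zero, 1, Dr, dt)
  expect_equal(mean(cos(th)), exp(-Dr * nsteps * dt), tolerance = 0.05)
})

test_that("time stepping: frozen dynamics, energy descent, equivariance", {
  # Gamma = 0 and zero velocity leave the fields untouched
  p0 <- cellTypeParams(alpha = 0, zetaS = 0, zetaQ = 0, Dr = 0)
  cfg0 <- simConfig(nx = 16, ny = 16, nz = 10, nCell = 1, R0 = 4,
                    geometry = "single", Gamma = 0,
                    typeParams = list(A = p0, B = p0), nSim = 2L, seed = 3L)
  z <- monolayerFromPhi(array(0, c(16, 16, 10, 1)), cfg0,
                        substrate = initializeMonolayer(cfg0)@substrate)
  z1 <- simStep(z, 2L)
  expect_identical(z1@phi, z@phi)

  # passive relaxation: free energy never increases
  cfg <- tinyPassiveConfig(nSim = 500L)
  st <- simStep(initializeMonolayer(cfg), 500L)
  e <- attr(st, "energy")
  expect_true(all(diff(e) <= 1e-6 * abs(e[-length(e)])))

  # periodic translation equivariance: shifting the initial condition in x
  # commutes with stepping (same noise draws)
  cfgA <- tinyActiveConfig(Dr = 0.05, nSim = 10L)
  stA <- initializeMonolayer(cfgA)
  k <- 7L
  stB <- stA
  stB@phi <- mechcompete:::.cshift(stA@phi, k, 1L)
  set.seed(99); outA <- simStep(stA, 10L)
  set.seed(99); outB <- simStep(stB, 10L)
  expect_equal(mechcompete:::.cshift(outA@phi, k, 1L), outB@phi,
               tolerance = 1e-10)
  expect_equal(outA@theta, outB@theta, tolerance = 1e-10)

  # numerical blow-up raises an instability error naming dt and the step
  pBad <- cellTypeParams(kappaCC = 80, alpha = 0, Dr = 0)
  cfgBad <- simConfig(nx = 24, ny = 12, nz = 12, nCell = 2, R0 = 5,
                      geometry = "collision-two-interfaces",
                      typeParams = list(A = pBad, B = pBad), nSim = 50L,
                      seed = 4L)
  stBad <- initializeMonolayer(cfgBad)
  stBad@phi[, , , 2] <- stBad@phi[, , , 1]   # deep overlap + huge repulsion
  expect_error(simStep(stBad, 50L), "numerical instability.*dt")
})

test_that("runSimulation archives are deterministic in the seed", {
  cfg <- tinyActiveConfig(Dr = 0.05, nSim = 0L)
  res0 <- runSimulation(cfg)
  expect_equal(res0$state@stepIndex, 0L)           # initial state only
  expect_equal(length(res0$energy), 0L)
  expect_true(all(res0$diagnostics$step == 0))

  cfg2 <- tinyActiveConfig(Dr = 0.05, nSim = 30L)
  r1 <- runSimulation(cfg2, saveEvery = 15L)
  r2 <- runSimulation(cfg2, saveEvery = 15L)
  expect_identical(r1$events, r2$events)           # bit-identical catalogs
  expect_identical(r1$energy, r2$energy)
  expect_identical(r1$state@phi, r2$state@phi)
  expect_equal(dim(r1$frames$occ)[3], 2L)
  expect_equal(r1$manifest$seed, cfg2@seed)
  expect_equal(r1$manifest$configHash, r2$manifest$configHash)
})
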