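# Shared fixtures and small independent oracles.

# tiny passive single-cell configuration (fast relaxation runs)
tinyPassiveConfig <- function(nx = 28, ny = 28, nz = 16, R0 = 5,
                              nSim = 100L, seed = 5L, ...) {
  p <- cellTypeParams(alpha = 0, zetaS = 0, zetaQ = 0, Dr = 0, ...)
  simConfig(nx = nx, ny = ny, nz = nz, nCell = 1, R0 = R0,
            geometry = "single", typeParams = list(A = p, B = p),
            nSim = nSim, seed = seed)
}

# small active two-cell configuration
tinyActiveConfig <- function(seed = 5L, Dr = 0, nSim = 20L) {
  p <- cellTypeParams(Dr = Dr)
  simConfig(nx = 32, ny = 16, nz = 14, nCell = 2, R0 = 5,
            geometry = "collision-two-interfaces",
            typeParams = list(A = p, B = p), nSim = nSim, seed = seed)
}

# build a Monolayer directly from a phi array (bypassing initialization)
monolayerFromPhi <- function(phi, config, theta = NULL, types = NULL,
                             substrate = NULL) {
  nc <- dim(phi)[4]
  if (is.null(theta)) theta <- rep(0, nc)
  if (is.null(types)) types <- rep("A", nc)
  if (is.null(substrate))
    substrate <- array(0, dim(phi)[1:3])
  new("Monolayer", phi = phi, theta = theta, type = types,
      velocity = matrix(0, nc, 3), traction = matrix(0, nc, 3),
      extrudedAt = rep(NA_real_, nc), substrate = substrate,
      stepIndex = 0L, config = config)
}

# independent total-energy oracle: recompute F from the discrete definition
# (link sums, double-counted pair terms) directly in R
energyOracle <- function(state) {
  cfg <- state@config
  lam <- cfg@lambda; a0 <- cfg@a0; h3 <- a0^3
  V0 <- targetVolume(cfg)
  phi <- state@phi
  nc <- dim(phi)[4]
  phiw <- state@substrate
  well <- 16 * phiw^2 * (1 - phiw)^2
  linkdot <- function(a, b) {
    s <- 0
    nx <- dim(a)[1]; ny <- dim(a)[2]; nz <- dim(a)[3]
    s <- s + sum((a[c(2:nx, 1), , ] - a) * (b[c(2:nx, 1), , ] - b))
    s <- s + sum((a[, c(2:ny, 1), ] - a) * (b[, c(2:ny, 1), ] - b))
    s <- s + sum((a[, , 2:nz] - a[, , 1:(nz - 1)]) *
                 (b[, , 2:nz] - b[, , 1:(nz - 1)]))
    s / a0^2
  }
  total <- 0
  for (i in seq_len(nc)) {
    p <- cfg@typeParams[[state@type[i]]]
    f <- phi[, , , i]
    total <- total + p@gamma / lam *
      (sum(4 * f^2 * (1 - f)^2) * h3 + lam^2 * linkdot(f, f) * h3)
    V <- sum(f^2) * h3
    total <- total + p@mu * (1 - V / V0)^2
    for (j in seq_len(nc)) {
      if (j == i) next
      g <- phi[, , , j]
      total <- total + p@kappaCC / lam^2 * sum(f^2 * g^2) * h3
      total <- total + p@omegaCC * linkdot(f, g) * h3
    }
    total <- total + p@kappaCS / lam^2 * sum(f^2 * phiw^2) * h3
    total <- total - p@omegaCS / lam^2 * sum(f^2 * well) * h3
  }
  total
}

# even-odd point-in-polygon test (for rasterizing analytic shapes)
pointInPolygon <- function(x, y, px, py) {
  n <- length(px)
  inside <- rep(FALSE, length(x))
  j <- n
  for (i in seq_len(n)) {
    cross <- (py[i] > y) != (py[j] > y)
    xint <- (px[j] - px[i]) * (y - py[i]) / (py[j] - py[i]) + px[i]
    inside <- xor(inside, cross & (x < xint))
    j <- i
  }
  inside
}

polygonMask <- function(px, py, n = 101) {
  ctr <- (n + 1) / 2
  g <- expand.grid(x = seq_len(n) - ctr, y = seq_len(n) - ctr)
  matrix(as.numeric(pointInPolygon(g$x, g$y, px, py)), n, n)
}

polygonPerimeter <- function(px, py)
  sum(sqrt(diff(c(px, px[1]))^2 + diff(c(py, py[1]))^2))
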