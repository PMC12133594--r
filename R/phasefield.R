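## R-level interface of the multiphase-field monolayer simulator.
##
## Model summary: each cell i is a 3D phase field phi_i on a grid periodic
## in x and y with a rigid substrate at the bottom.  The free energy has
## Cahn-Hilliard bulk + gradient terms (cortex tension gamma, interface
## width lambda), a soft volume constraint mu around V0 = (4/3) pi R0^3,
## kappa repulsion and omega adhesion couplings between cells and with the
## substrate.  Interface relaxation follows time-dependent Ginzburg-Landau
## dynamics with an advective term that rigidly translates each cell with
## its overdamped velocity v_i = (alpha p_i + F_i^int)/xi, where the
## interaction force integrates the interaction stress (an isotropic part
## from the functional derivatives plus deviatoric active stresses) against
## the cell's own gradient.  Polarity follows contact inhibition of
## locomotion: it relaxes toward the traction direction with time tauPol
## and diffuses with rotational diffusivity Dr.

#' Construct per-type mechanical parameters
#'
#' Defaults follow the model's reference parameterization (simulation
#' units): cortex tension `gamma = 0.008`, compressibility `mu = 45`,
#' active stresses `zetaS = 4e-5` and `zetaQ = -0.01`, substrate friction
#' handled globally.  Adhesion and numerical couplings default to values
#' for which a single passive cell relaxes to a stable resolved droplet;
#' the two-type competition scenarios modify `omegaCC`/`omegaCS` per type.
#'
#' @param gamma,mu,omegaCC,omegaCS,kappaCC,kappaCS,zetaS,zetaQ,alpha,Dr,tauPol
#'   see [CellTypeParams-class].
#' @return a [CellTypeParams-class] object.
#' @export
cellTypeParams <- function(gamma = 0.008, mu = 45, omegaCC = 0.004,
                           omegaCS = 0.03, kappaCC = 0.15, kappaCS = 0.02,
                           zetaS = 4e-5, zetaQ = -0.01, alpha = 0.02,
                           Dr = 0.01, tauPol = 20) {
  new("CellTypeParams", gamma = gamma, mu = mu, omegaCC = omegaCC,
      omegaCS = omegaCS, kappaCC = kappaCC, kappaCS = kappaCS,
      zetaS = zetaS, zetaQ = zetaQ, alpha = alpha, Dr = Dr,
      tauPol = tauPol)
}

#' Construct a simulation configuration
#'
#' Performs an explicit-Euler stability estimate at construction: the
#' stiffest relaxational terms behave like diffusion with coefficient
#' `D = Gamma * 2 * gamma * lambda` (plus adhesion contributions), so `dt`
#' must stay below `a0^2 / (6 D)` with a safety margin.
#'
#' @param nx,ny,nz grid size; x and y are periodic, z is bounded.
#' @param nCell number of cells.
#' @param R0 initial cell radius (grid units).
#' @param geometry `"mixed"` (random type assignment),
#'   `"collision-two-interfaces"` (type A central band in x) or `"single"`.
#' @param typeParams named list of [CellTypeParams-class] (`A`, `B`).
#' @param a0 grid spacing.
#' @param Gamma interface mobility.
#' @param lambda interface width (>= 2 a0).
#' @param xi substrate friction.
#' @param dt time step.
#' @param nSim number of steps.
#' @param vbar reference speed; the characteristic time for a cell to move
#'   its own size is `tau = 2 R0 / vbar`.
#' @param seed run seed.
#' @return a [SimConfig-class] object.
#' @export
simConfig <- function(nx, ny, nz, nCell, R0,
                      geometry = c("collision-two-interfaces", "mixed",
                                   "single"),
                      typeParams = list(A = cellTypeParams(),
                                        B = cellTypeParams()),
                      a0 = 1, Gamma = 2, lambda = 2 * a0, xi = 1, dt = 0.2,
                      nSim = 1000L, vbar = 0.02, seed = 1L) {
  geometry <- match.arg(geometry)
  cfg <- new("SimConfig", nx = as.integer(nx), ny = as.integer(ny),
             nz = as.integer(nz), a0 = a0, nCell = as.integer(nCell),
             R0 = R0, Gamma = Gamma, lambda = lambda, xi = xi, dt = dt,
             nSim = as.integer(nSim), vbar = vbar, geometry = geometry,
             typeParams = typeParams, seed = as.integer(seed))
  gmax <- max(vapply(typeParams, function(p) p@gamma, numeric(1)))
  omax <- max(vapply(typeParams, function(p) p@omegaCC, numeric(1)))
  D <- Gamma * 2 * (gmax + 2 * omax) * lambda
  dtmax <- a0^2 / (6 * D)
  if (dt > dtmax)
    stop(sprintf(
      "configuration error: dt = %g exceeds the explicit-Euler stability estimate %.3g",
      dt, dtmax))
  cfg
}

#' Reference volume of a configuration
#' @param config a [SimConfig-class].
#' @return \eqn{V_0 = (4/3)\pi R_0^3}.
#' @export
targetVolume <- function(config) 4 / 3 * pi * config@R0^3

## static substrate field: tanh profile of width lambda at height zs
.substrateField <- function(nx, ny, nz, a0, lambda, zs = 2 * lambda) {
  z <- ((seq_len(nz)) - 0.5) * a0
  prof <- 0.5 * (1 - tanh(2 * (z - zs) / lambda))
  array(rep(prof, each = nx * ny), c(nx, ny, nz))
}

.substrateTop <- function(lambda) 2 * lambda

## parameter list (per-cell vectors) for the C++ kernels
.paramList <- function(config, types) {
  tp <- config@typeParams
  get <- function(slot) vapply(types, function(ty) slot(tp[[ty]], slot),
                               numeric(1))
  list(gamma = get("gamma"), mu = get("mu"), omegaCC = get("omegaCC"),
       omegaCS = get("omegaCS"), kappaCC = get("kappaCC"),
       kappaCS = get("kappaCS"), zetaS = get("zetaS"),
       zetaQ = get("zetaQ"), alpha = get("alpha"), Dr = get("Dr"),
       tauPol = get("tauPol"))
}


## Simple cubic lattice tiling the whole periodic domain: the domain size
## sets the packing density (spacing 2*R0 reproduces close packing of
## droplets).  Errors when the cells cannot fit without deep overlap.
.latticeLayout <- function(nCell, nx, ny, a0, R0) {
  best <- NULL
  for (ncols in seq_len(nCell)) {
    if (nCell %% ncols != 0) next
    nrows <- nCell / ncols
    sx <- nx * a0 / ncols; sy <- ny * a0 / nrows
    if (is.null(best) || abs(sx - sy) < best$d)
      best <- list(ncols = ncols, nrows = nrows, sx = sx, sy = sy,
                   d = abs(sx - sy))
  }
  if (min(best$sx, best$sy) < 1.2 * R0) {
    dimn <- if (best$sx <= best$sy) "x" else "y"
    stop(sprintf(
      "configuration error: %d cells do not fit the grid (lattice spacing %.2f < 1.2*R0 along %s)",
      nCell, min(best$sx, best$sy), dimn))
  }
  best
}

#' Initialize a monolayer on a simple cubic lattice
#'
#' Cells start as diffuse-interface droplets of radius `R0` (tanh profile
#' of width `lambda`, radius corrected by `lambda/4` so the phase-field
#' volume \eqn{\int\phi^2} matches \eqn{V_0}) resting on the substrate, on
#' a 2D square lattice with spacing `2 R0`.  For the collision geometry,
#' type A occupies a central band in x and type B the complement, giving
#' two straight interfaces under periodic x.  Polarity angles are drawn
#' uniformly from \eqn{[-\pi, \pi)} using the run seed.
#'
#' @param config a [SimConfig-class].
#' @return a [Monolayer-class].
#' @export
initializeMonolayer <- function(config) {
  nx <- config@nx; ny <- config@ny; nz <- config@nz
  a0 <- config@a0; R0 <- config@R0; lam <- config@lambda
  nc <- config@nCell
  if (R0 < 2 * a0) stop("configuration error: R0 must be >= 2*a0")
  best <- .latticeLayout(nc, nx, ny, a0, R0)
  ncols <- best$ncols; nrows <- best$nrows
  set.seed(config@seed)
  zs <- .substrateTop(lam)
  cz0 <- zs + R0
  Rinit <- R0 + lam / 4

  if (config@geometry == "single") {
    centers <- cbind(nx * a0 / 2, ny * a0 / 2)
  } else {
    ij <- arrayInd(seq_len(nc), c(ncols, nrows))
    centers <- cbind((ij[, 1] - 0.5) * best$sx, (ij[, 2] - 0.5) * best$sy)
  }
  types <- switch(config@geometry,
    "single" = rep("A", nc),
    "mixed" = sample(rep(c("A", "B"), length.out = nc)),
    "collision-two-interfaces" = ifelse(
      centers[, 1] >= nx * a0 / 4 & centers[, 1] < 3 * nx * a0 / 4,
      "A", "B"))

  xs <- (seq_len(nx) - 0.5) * a0
  ys <- (seq_len(ny) - 0.5) * a0
  zsq <- (seq_len(nz) - 0.5) * a0
  phi <- array(0, c(nx, ny, nz, nc))
  Lx <- nx * a0; Ly <- ny * a0
  for (c in seq_len(nc)) {
    dx <- abs(xs - centers[c, 1]); dx <- pmin(dx, Lx - dx)
    dy <- abs(ys - centers[c, 2]); dy <- pmin(dy, Ly - dy)
    dz <- zsq - cz0
    r <- sqrt(outer(outer(dx^2, dy^2, `+`), dz^2, `+`))
    phi[, , , c] <- 0.5 * (1 + tanh(2 * (Rinit - r) / lam))
  }
  theta <- runif(nc, -pi, pi)
  new("Monolayer", phi = phi, theta = theta, type = types,
      velocity = matrix(0, nc, 3), traction = matrix(0, nc, 3),
      extrudedAt = rep(NA_real_, nc),
      substrate = .substrateField(nx, ny, nz, a0, lam),
      stepIndex = 0L, config = config)
}

#' Phase-field volume of a cell
#'
#' \eqn{V = \int \phi^2 dx}, approximated by the node sum times
#' \eqn{a_0^3}.  The soft compressibility constraint holds this near
#' \eqn{V_0}.
#'
#' @param phi a 3D phase-field array (or a [Monolayer-class] plus cell
#'   index `i`).
#' @param a0 grid spacing.
#' @param i cell index when `phi` is a [Monolayer-class].
#' @return the volume (simulation units).
#' @export
cellVolume <- function(phi, a0 = 1, i = NULL) {
  if (is(phi, "Monolayer")) {
    a0 <- phi@config@a0
    phi <- phiField(phi, i)
  }
  if (any(!is.finite(phi))) stop("data error: phi contains non-finite values")
  sum(phi^2) * a0^3
}

## internal: run the field computation for the current state
.fields <- function(state) {
  cfg <- state@config
  .pf_fields(state@phi, state@substrate,
             dim(state@phi), .paramList(cfg, state@type),
             cfg@a0, cfg@lambda, cfg@Gamma, cfg@xi, targetVolume(cfg))
}

#' Functional derivative of the free energy
#'
#' Returns \eqn{\delta F/\delta\phi_i}: the Cahn-Hilliard bulk + gradient
#' terms, the volume soft constraint, cell-cell repulsion and adhesion, and
#' substrate repulsion and adhesion, discretized so the derivative is the
#' exact gradient of the discrete energy reported by [totalEnergy()]
#' (adhesion cross-terms use each cell's own omega, unsymmetrized).
#'
#' @param state a [Monolayer-class].
#' @param i cell index; `NULL` returns the 4D array for all cells.
#' @return 3D array (one cell) or 4D array (all cells).
#' @export
functionalDerivative <- function(state, i = NULL) {
  f <- .fields(state)
  if (is.null(i)) f$dF else f$dF[, , , i]
}

#' Total discrete free energy of the state
#' @param state a [Monolayer-class].
#' @return the scalar free energy (simulation units).
#' @export
totalEnergy <- function(state) .fields(state)$energy

#' Deviatoric shape tensor of a cell
#'
#' \eqn{S_i = -\int (\nabla\phi_i)^T \nabla\phi_i dx + \frac{1}{3}
#' \mathrm{Tr}[\cdot]\, I}: trace-free by construction, zero for a
#' spherically symmetric cell, and negative along the elongation axis.
#'
#' @param state a [Monolayer-class].
#' @param i cell index.
#' @return a 3x3 matrix.
#' @export
shapeTensor <- function(state, i) {
  f <- .fields(state)
  matrix(f$S[, i], 3, 3)
}

#' Interaction stress field
#'
#' \eqn{\Pi^{int}(x) = (\sum_i -\delta F/\delta\phi_i) I +
#' \sum_i(-\zeta_S^i \phi_i S_i) + \sum_i(-\zeta_Q^i \phi_w Q_w)}, the
#' stress whose integral against \eqn{\nabla\phi_i} gives each cell's
#' interaction force and traction.
#'
#' @param state a [Monolayer-class].
#' @return a 3D [StressField-class].
#' @export
interactionStress <- function(state) {
  f <- .fields(state)
  cfg <- state@config
  d <- dim(state@phi)[1:3]
  out <- array(0, c(d, 3, 3))
  Qw <- diag(c(1, -0.5, -0.5))
  piQ <- -f$zQsum * state@substrate
  for (a in 1:3) out[, , , a, a] <- f$Piso + piQ * Qw[a, a]
  comp <- list(c(1, 1), c(2, 2), c(3, 3), c(1, 2), c(1, 3), c(2, 3))
  for (q in seq_along(comp)) {
    a <- comp[[q]][1]; b <- comp[[q]][2]
    out[, , , a, b] <- out[, , , a, b] + f$PiS[, , , q]
    if (a != b) out[, , , b, a] <- out[, , , b, a] + f$PiS[, , , q]
  }
  new("StressField", values = out, spacing = cfg@a0, unit = "sim",
      time = as.numeric(state@stepIndex))
}

#' Per-cell velocity and traction
#'
#' Overdamped force balance: the interaction force is
#' \eqn{F_i^{int} = -\int \Pi^{int} \cdot \nabla\phi_i\, dx}, the
#' self-propulsion force \eqn{F_i^{sp} = \alpha \hat p_i}, and
#' \eqn{v_i = (F_i^{sp} + F_i^{int})/\xi}, so the traction transmitted to
#' the substrate is \eqn{T_i = \xi v_i - F_i^{sp} = F_i^{int}}.
#'
#' @param state a [Monolayer-class].
#' @return list with `velocity` and `traction` (`nCell x 3` matrices).
#' @export
computeVelocityTraction <- function(state) {
  cfg <- state@config
  if (cfg@xi == 0) stop("configuration error: xi must be nonzero")
  f <- .fields(state)
  types <- state@type
  alpha <- vapply(types, function(ty) cfg@typeParams[[ty]]@alpha, numeric(1))
  p <- cbind(cos(state@theta), sin(state@theta), 0)
  vel <- (alpha * p + f$Fint) / cfg@xi
  list(velocity = vel, traction = f$Fint)
}

#' One explicit polarity update (Euler-Maruyama)
#'
#' The polarity angle relaxes toward the direction of the in-plane traction
#' with timescale `tauPol` and diffuses with rotational diffusivity `Dr`:
#' \eqn{\theta \leftarrow \theta - \Delta\theta\, dt/\tau_{pol} +
#' \sqrt{2 D_r dt}\, z}.  \eqn{\Delta\theta} is the signed in-plane angle
#' separating the polarity from the traction direction, wrapped to
#' \eqn{(-\pi, \pi]}; when the in-plane traction vanishes the alignment
#' term is skipped (the target direction is undefined) and only diffusion
#' acts.
#'
#' @param theta polarity angles.
#' @param Tx,Ty in-plane traction components per cell.
#' @param tauPol,Dr,dt dynamics constants.
#' @return updated angles wrapped to \eqn{[-\pi, \pi]}.
#' @export
polarityStep <- function(theta, Tx, Ty, tauPol, Dr, dt) {
  wrap <- function(x) {
    x <- (x + pi) %% (2 * pi) - pi
    x[x == -pi] <- pi
    x
  }
  Tx <- rep_len(Tx, length(theta))
  Ty <- rep_len(Ty, length(theta))
  mag <- sqrt(Tx^2 + Ty^2)
  dtheta <- wrap(theta - atan2(Ty, Tx))
  out <- ifelse(mag > 1e-10, theta - dtheta / tauPol * dt, theta)
  out <- out + sqrt(2 * Dr * dt) * rnorm(length(theta))
  wrap(out)
}

## step-0 diagnostics rows computed in R (initial contact, volume, centres)
.initialDiagnostics <- function(state) {
  cfg <- state@config
  nc <- nCells(state)
  a0 <- cfg@a0; h3 <- a0^3
  nx <- cfg@nx; ny <- cfg@ny; nz <- cfg@nz
  pw2 <- state@substrate^2
  rows <- lapply(seq_len(nc), function(c) {
    p2 <- state@phi[, , , c]^2
    mass <- sum(p2)
    ax <- 2 * pi * ((seq_len(nx)) - 0.5) / nx
    ay <- 2 * pi * ((seq_len(ny)) - 0.5) / ny
    wx <- apply(p2, 1, sum); wy <- apply(p2, 2, sum); wz <- apply(p2, 3, sum)
    cx <- atan2(sum(wx * sin(ax)) / mass, sum(wx * cos(ax)) / mass) /
      (2 * pi) * nx
    if (cx < 0) cx <- cx + nx
    cy <- atan2(sum(wy * sin(ay)) / mass, sum(wy * cos(ay)) / mass) /
      (2 * pi) * ny
    if (cy < 0) cy <- cy + ny
    data.frame(step = 0, id = c, V = mass * h3,
               contact = sum(p2 * pw2) * h3,
               cx = (cx + 0.5) * a0, cy = (cy + 0.5) * a0,
               cz = sum(wz * ((seq_len(nz)) - 0.5) * a0) / mass,
               Tx = 0, Ty = 0, Tz = 0, vx = 0, vy = 0, vz = 0,
               theta = state@theta[c], type = state@type[c])
  })
  do.call(rbind, rows)
}

.diagColumns <- c("step", "id", "V", "contact", "cx", "cy", "cz",
                  "Tx", "Ty", "Tz", "vx", "vy", "vz", "theta")

#' Advance a monolayer by explicit time steps
#'
#' Each step: functional derivatives and interaction stress; per-cell
#' velocity and traction; first-order upwind advection with the rigid
#' per-cell velocity plus relaxation
#' \eqn{\phi \leftarrow \phi + dt(-v\cdot\nabla\phi - \Gamma\,\delta
#' F/\delta\phi)}; polarity update.  Raises a numerical-instability error
#' naming `dt` and the step if any field exceeds \eqn{|\phi| > 2}.
#'
#' @param state a [Monolayer-class].
#' @param nSteps number of steps to advance.
#' @return updated [Monolayer-class] with attributes `diagnostics`
#'   (per-step per-cell table) and `energy` (free energy at the start of
#'   each step).
#' @export
simStep <- function(state, nSteps = 1L) {
  cfg <- state@config
  res <- .pf_run(state@phi, state@theta, state@substrate, dim(state@phi),
                 .paramList(cfg, state@type), cfg@a0, cfg@lambda,
                 cfg@Gamma, cfg@xi, cfg@dt, targetVolume(cfg),
                 as.integer(nSteps))
  if (res$errStep > 0)
    stop(sprintf(
      "numerical instability: |phi| > 2 at step %d (dt = %g); reduce dt",
      state@stepIndex + res$errStep, cfg@dt))
  diagn <- as.data.frame(res$diag)
  names(diagn) <- .diagColumns
  diagn$step <- diagn$step + state@stepIndex
  diagn$type <- state@type[diagn$id]
  nc <- nCells(state)
  lastRows <- diagn[diagn$step == max(diagn$step), ]
  out <- new("Monolayer", phi = res$phi, theta = res$theta,
             type = state@type,
             velocity = as.matrix(lastRows[order(lastRows$id),
                                           c("vx", "vy", "vz")]),
             traction = as.matrix(lastRows[order(lastRows$id),
                                           c("Tx", "Ty", "Tz")]),
             extrudedAt = state@extrudedAt, substrate = state@substrate,
             stepIndex = state@stepIndex + as.integer(nSteps),
             config = cfg)
  attr(out, "diagnostics") <- diagn
  attr(out, "energy") <- res$energy
  out
}

#' Distribute per-cell tractions onto grid nodes
#'
#' Each cell's traction vector is spread over the nodes with weight
#' \eqn{\phi_i^2 a_0^3 / \int\phi_i^2 dx}, so the node sum reproduces the
#' per-cell traction.  This is the traction-density field consumed by
#' [coarseGrainStress()].
#'
#' @param state a [Monolayer-class].
#' @param tractions optional `nCell x 3` matrix (defaults to the state's
#'   last computed tractions).
#' @return array `[nx, ny, nz, 3]`.
#' @export
nodeTractionField <- function(state, tractions = NULL) {
  if (is.null(tractions)) tractions <- state@traction
  d <- dim(state@phi)
  h3 <- state@config@a0^3
  out <- array(0, c(d[1:3], 3))
  for (c in seq_len(d[4])) {
    p2 <- state@phi[, , , c]^2
    w <- p2 * h3 / (sum(p2) * h3)
    for (k in 1:3) out[, , , k] <- out[, , , k] + w * tractions[c, k]
  }
  out
}

#' Run a full simulation
#'
#' Deterministic given the config seed.  Advances the state in chunks of
#' `saveEvery` steps; at every save point records the 2D occupancy map of
#' the resident (non-extruded) cells, the z-projected in-plane isotropic
#' stress and out-of-plane stress component of the coarse-grained stress
#' field, re-detects extrusions on the accumulated diagnostics, and logs
#' progress.  Returns everything needed by the downstream statistics.
#'
#' @param config a [SimConfig-class].
#' @param saveEvery save interval in steps (default: `nSim`, i.e. only the
#'   final state).
#' @param progress print per-chunk progress lines (energy, mean speed,
#'   extrusion count)?
#' @return list with `state` (final [Monolayer-class] with extrusion flags
#'   set), `diagnostics`, `energy` (per step), `events` (extrusion
#'   catalog), `frames` (list: `step`, `occ`, `iso`, `szz`) and `manifest`.
#' @export
runSimulation <- function(config, saveEvery = NULL, progress = FALSE) {
  if (is.null(saveEvery)) saveEvery <- max(config@nSim, 1L)
  state <- initializeMonolayer(config)
  diagn <- .initialDiagnostics(state)
  energy <- numeric(0)
  occs <- list(); isos <- list(); szzs <- list(); steps <- integer(0)
  nleft <- config@nSim
  while (nleft > 0L) {
    chunk <- min(saveEvery, nleft)
    state <- simStep(state, chunk)
    diagn <- rbind(diagn, attr(state, "diagnostics"))
    energy <- c(energy, attr(state, "energy"))
    nleft <- nleft - chunk
    events <- detectExtrusions(diagn, config@R0)
    flags <- rep(NA_real_, nCells(state))
    flags[events$id] <- events$step
    state@extrudedAt <- flags
    ## save frames
    resident <- is.na(flags) | flags > state@stepIndex
    occ <- occupancyMap(state@phi, types = state@type, exclude = !resident)
    tr <- state@traction
    ntf <- nodeTractionField(state)
    sf <- coarseGrainStress(ntf, a0 = config@a0, time = state@stepIndex)
    w <- array(0, dim(state@phi)[1:3])
    for (c in which(resident)) w <- w + state@phi[, , , c]^2
    occs[[length(occs) + 1L]] <- occ
    isos[[length(isos) + 1L]] <-
      zProject(isotropicStress(sf, "3d-in-plane"), w)
    szzs[[length(szzs) + 1L]] <- zProject(sigmaZZ(sf), w)
    steps <- c(steps, state@stepIndex)
    if (progress)
      message(sprintf(
        "step %d/%d: F = %.4g, mean speed = %.3g, extrusions = %d",
        state@stepIndex, config@nSim, energy[length(energy)],
        mean(sqrt(rowSums(state@velocity^2))), nrow(events)))
  }
  events <- detectExtrusions(diagn, config@R0)
  flags <- rep(NA_real_, nCells(state))
  flags[events$id] <- events$step
  state@extrudedAt <- flags
  nf <- length(occs)
  d2 <- c(config@nx, config@ny)
  frames <- list(
    step = steps,
    occ = if (nf) array(unlist(occs), c(d2, nf)),
    iso = if (nf) array(unlist(isos), c(d2, nf)),
    szz = if (nf) array(unlist(szzs), c(d2, nf)))
  manifest <- runManifest("runSimulation", config)
  list(state = state, diagnostics = diagn, energy = energy,
       events = events, frames = frames, manifest = manifest)
}

#' Reference study configurations
#'
#' `competitionScenario()` is the two-type collision assay used throughout
#' the package's validation: a 60 x 30 x 20 grid with 36 cells of radius 5
#' (type A central band, two interfaces under periodic x).  Type A is the
#' cohesive winner analog (cell-cell adhesion 0.004, cell-substrate 0.01);
#' type B the loser analog with an 8-fold lower cell-cell adhesion (5e-4)
#' and higher cell-substrate adhesion (0.04), the adhesion contrast under
#' which the low-cohesion type is eliminated at the interface.  Activity:
#' alpha = 0.08, Dr = 0.1, tauPol = 10, with the reference active stresses
#' zetaS = 4e-5 and zetaQ = -0.01.
#'
#' `passiveControlConfig()` is the homogeneous passive negative control
#' (no activity, no noise): 16 cells of radius 8 on a 64 x 64 x 24 grid.
#'
#' @param seed run seed.
#' @param nSim number of steps.
#' @return a [SimConfig-class].
#' @export
competitionScenario <- function(seed = 1L, nSim = 1500L) {
  winner <- cellTypeParams(omegaCC = 0.004, omegaCS = 0.01,
                           alpha = 0.08, Dr = 0.1, tauPol = 10)
  loser <- cellTypeParams(omegaCC = 0.0005, omegaCS = 0.04,
                          alpha = 0.08, Dr = 0.1, tauPol = 10)
  simConfig(nx = 60, ny = 30, nz = 20, nCell = 36, R0 = 5,
            geometry = "collision-two-interfaces",
            typeParams = list(A = winner, B = loser),
            nSim = nSim, seed = seed)
}

#' @rdname competitionScenario
#' @export
passiveControlConfig <- function(seed = 1L, nSim = 2000L) {
  passive <- cellTypeParams(alpha = 0, zetaS = 0, zetaQ = 0, Dr = 0)
  simConfig(nx = 64, ny = 64, nz = 24, nCell = 16, R0 = 8,
            geometry = "mixed",
            typeParams = list(A = passive, B = passive),
            nSim = nSim, seed = seed)
}
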