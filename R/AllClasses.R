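## Central S4 containers.
##
## Image-like quantities (2D vector/tensor fields, 3D stress tensors, the
## multiphase-field monolayer state) are held in validated S4 objects;
## tabular results (event catalogs, distance profiles) are plain data.frames.

setClassUnion("numericOrNULL", c("numeric", "NULL"))

## ---------------------------------------------------------------------------
## Simulation configuration
## ---------------------------------------------------------------------------

#' Per-type mechanical parameters of a simulated cell population
#'
#' Holds the mechanical constants of one cell type in the multiphase-field
#' model: cortex tension, compressibility, cell-cell and cell-substrate
#' adhesion and repulsion couplings, active-stress strengths, self-propulsion
#' and polarity dynamics constants.  All values are in simulation units
#' (grid spacing \eqn{a_0 = 1}).
#'
#' @slot gamma cortex tension \eqn{\gamma > 0}.
#' @slot mu compressibility \eqn{\mu > 0}; soft volume constraint strength.
#' @slot omegaCC cell-cell adhesion coupling \eqn{\omega_{cc} \ge 0}.
#' @slot omegaCS cell-substrate adhesion coupling \eqn{\omega_{cs} \ge 0}.
#' @slot kappaCC cell-cell repulsion strength \eqn{\kappa_{cc} \ge 0}.
#' @slot kappaCS cell-substrate repulsion strength \eqn{\kappa_{cs} \ge 0}.
#' @slot zetaS cell-cell (shape) active stress strength \eqn{\zeta_S}.
#' @slot zetaQ cell-substrate active stress strength \eqn{\zeta_Q}.
#' @slot alpha self-propulsion force strength \eqn{\alpha \ge 0}.
#' @slot Dr rotational diffusivity \eqn{D_r \ge 0} of the polarity angle.
#' @slot tauPol polarity alignment time \eqn{\tau_{pol} > 0}.
#' @seealso [cellTypeParams()]
#' @exportClass CellTypeParams
setClass("CellTypeParams",
  representation(
    gamma = "numeric", mu = "numeric",
    omegaCC = "numeric", omegaCS = "numeric",
    kappaCC = "numeric", kappaCS = "numeric",
    zetaS = "numeric", zetaQ = "numeric",
    alpha = "numeric", Dr = "numeric", tauPol = "numeric"
  )
)

setValidity("CellTypeParams", function(object) {
  msg <- character()
  for (s in slotNames(object)) {
    v <- slot(object, s)
    if (length(v) != 1L || !is.finite(v))
      msg <- c(msg, sprintf("slot '%s' must be a single finite number", s))
  }
  if (length(msg) == 0L) {
    if (object@gamma <= 0) msg <- c(msg, "gamma must be > 0")
    if (object@mu <= 0) msg <- c(msg, "mu must be > 0")
    if (object@kappaCC < 0) msg <- c(msg, "kappaCC must be >= 0")
    if (object@kappaCS < 0) msg <- c(msg, "kappaCS must be >= 0")
    if (object@tauPol <= 0) msg <- c(msg, "tauPol must be > 0")
    if (object@Dr < 0) msg <- c(msg, "Dr must be >= 0")
  }
  if (length(msg)) msg else TRUE
})

#' Configuration of a multiphase-field monolayer simulation
#'
#' Bundles the grid geometry (periodic in x and y, bounded in z), global
#' numerical constants, per-type mechanical parameters and the initial
#' geometry of a simulation run.  Use [simConfig()] to construct one.
#'
#' @slot nx,ny,nz grid node counts.
#' @slot a0 grid spacing (simulation length unit, default 1).
#' @slot nCell number of cells.
#' @slot R0 initial cell radius in grid units.
#' @slot Gamma interface mobility of the relaxational dynamics.
#' @slot lambda diffuse-interface width (default \eqn{2 a_0}).
#' @slot xi substrate friction.
#' @slot dt time step.
#' @slot nSim number of time steps.
#' @slot vbar reference cell speed defining the characteristic time
#'   \eqn{\tau = 2 R_0/\bar v}.
#' @slot geometry `"mixed"` or `"collision-two-interfaces"`.
#' @slot typeParams named list with [CellTypeParams-class] entries `A` and `B`.
#' @slot seed integer seed for the run's random number generator.
#' @exportClass SimConfig
setClass("SimConfig",
  representation(
    nx = "integer", ny = "integer", nz = "integer", a0 = "numeric",
    nCell = "integer", R0 = "numeric",
    Gamma = "numeric", lambda = "numeric", xi = "numeric",
    dt = "numeric", nSim = "integer", vbar = "numeric",
    geometry = "character", typeParams = "list", seed = "integer"
  )
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@nx < 1L || object@ny < 1L || object@nz < 1L)
    msg <- c(msg, "grid dimensions must be positive")
  if (object@a0 <= 0) msg <- c(msg, "a0 must be > 0")
  if (object@dt <= 0) msg <- c(msg, "dt must be > 0")
  if (object@lambda < 2 * object@a0)
    msg <- c(msg, "lambda must be >= 2*a0 (diffuse interface must be resolved)")
  if (object@xi <= 0) msg <- c(msg, "xi (substrate friction) must be > 0")
  if (object@vbar <= 0) msg <- c(msg, "vbar must be > 0 (tau = 2*R0/vbar)")
  if (!object@geometry %in% c("mixed", "collision-two-interfaces", "single"))
    msg <- c(msg, "geometry must be 'mixed', 'collision-two-interfaces' or 'single'")
  if (!all(c("A", "B") %in% names(object@typeParams)))
    msg <- c(msg, "typeParams must have entries 'A' and 'B'")
  else if (!all(vapply(object@typeParams[c("A", "B")],
                       function(p) is(p, "CellTypeParams"), logical(1))))
    msg <- c(msg, "typeParams entries must be CellTypeParams objects")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Monolayer state
## ---------------------------------------------------------------------------

#' State of a simulated cell monolayer
#'
#' Collection of per-cell 3D phase fields \eqn{\phi_i} on a shared periodic
#' grid, together with polarity angles, per-cell velocities and tractions,
#' the static substrate field and extrusion flags.  Construct with
#' [initializeMonolayer()] and advance with [simStep()] or [runSimulation()].
#'
#' @slot phi numeric array `[nx, ny, nz, nCell]` of phase fields, nominally
#'   in \eqn{[0, 1]}; the diffuse interface and the soft volume constraint
#'   under compression produce bounded overshoot (validity allows
#'   \eqn{[-0.5, 1.5]}; the dynamics aborts beyond \eqn{|\phi| > 2}).
#' @slot theta polarity angles in \eqn{[-\pi, \pi]}, one per cell.
#' @slot type character vector of type labels (`"A"` or `"B"`).
#' @slot velocity,traction `nCell x 3` matrices of the last computed per-cell
#'   velocity and traction vectors.
#' @slot extrudedAt step index at which each cell was flagged extruded
#'   (`NA` while in the monolayer).
#' @slot substrate static substrate field \eqn{\phi_w} on `[nx, ny, nz]`.
#' @slot stepIndex current step index.
#' @slot config the [SimConfig-class] that produced this state.
#' @exportClass Monolayer
setClass("Monolayer",
  representation(
    phi = "array", theta = "numeric", type = "character",
    velocity = "matrix", traction = "matrix",
    extrudedAt = "numeric", substrate = "array",
    stepIndex = "integer", config = "SimConfig"
  )
)

setValidity("Monolayer", function(object) {
  msg <- character()
  d <- dim(object@phi)
  cfg <- object@config
  if (length(d) != 4L)
    msg <- c(msg, "phi must be a 4D array [nx, ny, nz, nCell]")
  else {
    if (!all(d[1:3] == c(cfg@nx, cfg@ny, cfg@nz)))
      msg <- c(msg, "phi grid dimensions disagree with config")
    if (d[4] != length(object@theta) || d[4] != length(object@type))
      msg <- c(msg, "per-cell slots must have one entry per cell")
  }
  if (any(!is.finite(object@phi)))
    msg <- c(msg, "phi contains non-finite values")
  else if (min(object@phi) < -0.5 || max(object@phi) > 1.5)
    msg <- c(msg, "phi exceeds the bounded overshoot range [-0.5, 1.5]")
  if (!all(object@type %in% c("A", "B")))
    msg <- c(msg, "type labels must be 'A' or 'B'")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Stress fields
## ---------------------------------------------------------------------------

#' Tensor stress field on a grid
#'
#' Coarse-grained simulation stress (3D, 3x3 per node) or inferred tissue
#' stress (2D, 2x2 per node).  The `values` array has the tensor indices
#' last: `[nx, ny, nz, 3, 3]` for 3D, `[nx, ny, 2, 2]` for 2D.
#'
#' @slot values numeric array of tensor components.
#' @slot spacing grid spacing (one number; physical or simulation units).
#' @slot unit character unit label (e.g. `"sim"`, `"Pa*um"`).
#' @slot time time index or time stamp of the frame.
#' @seealso [isotropicStress()], [coarseGrainStress()]
#' @exportClass StressField
setClass("StressField",
  representation(values = "array", spacing = "numeric", unit = "character",
                 time = "numeric")
)

setValidity("StressField", function(object) {
  d <- dim(object@values)
  msg <- character()
  if (!(length(d) %in% c(4L, 5L)))
    msg <- c(msg, "values must be [nx,ny,2,2] (2D) or [nx,ny,nz,3,3] (3D)")
  else {
    td <- tail(d, 2)
    if (!(all(td == 2L) && length(d) == 4L) &&
        !(all(td == 3L) && length(d) == 5L))
      msg <- c(msg, "trailing tensor dims must be 2x2 (2D) or 3x3 (3D)")
  }
  if (any(!is.finite(object@values)))
    msg <- c(msg, "stress values must be finite")
  if (length(object@spacing) != 1L || object@spacing <= 0)
    msg <- c(msg, "spacing must be a single positive number")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## 2D image-like fields for the traction/stress inference chain
## ---------------------------------------------------------------------------

#' 2D multi-channel field on a pixel grid
#'
#' Base class for planar fields used by the traction-force-microscopy chain.
#' `values` is `[nx, ny, nChannel]`.  Subclasses fix the channel meaning:
#' [DisplacementField2D-class] and [TractionField2D-class] have channels
#' `(x, y)`; [Stress2DField-class] has channels `(xx, yy, xy)`.
#'
#' @slot values numeric array `[nx, ny, nChannel]`.
#' @slot pixelSize pixel size in micrometres.
#' @slot unit unit label of the values.
#' @slot frame frame index.
#' @exportClass Field2D
setClass("Field2D",
  representation(values = "array", pixelSize = "numeric", unit = "character",
                 frame = "integer")
)

setValidity("Field2D", function(object) {
  msg <- character()
  if (length(dim(object@values)) != 3L)
    msg <- c(msg, "values must be a 3D array [nx, ny, nChannel]")
  if (any(!is.finite(object@values)))
    msg <- c(msg, "values must be finite")
  if (length(object@pixelSize) != 1L || object@pixelSize <= 0)
    msg <- c(msg, "pixelSize must be a single positive number")
  if (length(msg)) msg else TRUE
})

#' @rdname Field2D-class
#' @exportClass DisplacementField2D
setClass("DisplacementField2D", contains = "Field2D")

#' @rdname Field2D-class
#' @exportClass TractionField2D
setClass("TractionField2D", contains = "Field2D")

#' @rdname Field2D-class
#' @exportClass Stress2DField
setClass("Stress2DField", contains = "Field2D")

setValidity("DisplacementField2D", function(object)
  if (dim(object@values)[3] != 2L) "displacement needs 2 channels (x, y)" else TRUE)
setValidity("TractionField2D", function(object)
  if (dim(object@values)[3] != 2L) "traction needs 2 channels (x, y)" else TRUE)
setValidity("Stress2DField", function(object)
  if (dim(object@values)[3] != 3L) "stress needs 3 channels (xx, yy, xy)" else TRUE)

#' Linear-elastic substrate description for traction recovery
#'
#' Material and regularization constants for the half-space elasticity model
#' used by [forwardDisplacement()], [fttc()] and [bism()].
#'
#' @slot E Young modulus in Pa.
#' @slot nu Poisson ratio in \eqn{[0, 0.5]} (0.5 for incompressible silicone).
#' @slot lambdaFTTC Tikhonov regularization of the Fourier-space traction
#'   inversion.
#' @slot LambdaBISM dimensionless regularization of the stress inversion,
#'   scaled internally by the norm of the force-balance operator.
#' @exportClass ElasticSubstrate
setClass("ElasticSubstrate",
  representation(E = "numeric", nu = "numeric", lambdaFTTC = "numeric",
                 LambdaBISM = "numeric")
)

setValidity("ElasticSubstrate", function(object) {
  msg <- character()
  if (object@E <= 0) msg <- c(msg, "E must be > 0")
  if (object@nu < 0 || object@nu > 0.5) msg <- c(msg, "nu must be in [0, 0.5]")
  if (object@lambdaFTTC < 0) msg <- c(msg, "lambdaFTTC must be >= 0")
  if (object@LambdaBISM < 0) msg <- c(msg, "LambdaBISM must be >= 0")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## Energetics
## ---------------------------------------------------------------------------

#' Constant-volume shape sequence for the cell-elimination energetics model
#'
#' Describes the cylinder-to-cone-to-sphere sequence a cell passes through
#' when it is eliminated from the monolayer.  The apical radius and the
#' final sphere radius are fixed (default 10 um each); the basal radius
#' varies; every shape keeps the volume \eqn{V = (4/3)\pi r_s^3}.
#'
#' @slot apicalRadius apical radius \eqn{r_a} in micrometres.
#' @slot sphereRadius sphere radius \eqn{r_s} in micrometres.
#' @slot volume conserved volume \eqn{(4/3)\pi r_s^3} in \eqn{\mu m^3}.
#' @seealso [shapeSequence()], [shapeAreas()], [eliminationWork()]
#' @exportClass ShapeSequence
setClass("ShapeSequence",
  representation(apicalRadius = "numeric", sphereRadius = "numeric",
                 volume = "numeric")
)

setValidity("ShapeSequence", function(object) {
  msg <- character()
  if (object@apicalRadius <= 0) msg <- c(msg, "apicalRadius must be > 0")
  if (object@sphereRadius <= 0) msg <- c(msg, "sphereRadius must be > 0")
  vref <- 4 / 3 * pi * object@sphereRadius^3
  if (abs(object@volume - vref) > 1e-9 * vref)
    msg <- c(msg, "volume must equal (4/3)*pi*sphereRadius^3")
  if (length(msg)) msg else TRUE
})

#' Adhesion and tension parameters of two competing cell types
#'
#' Per-area adhesion energies and surface tensions entering the elimination
#' work of each type.  Type I and type II meet at a shared interface; by
#' default half of a cell's lateral contact is with its own type.
#'
#' @slot omegaS_I,omegaS_II cell-substrate adhesion energy per area.
#' @slot omegaC_I,omegaC_II same-type cell-cell adhesion energy per area.
#' @slot omegaC_cross cross-type adhesion per area (cancels in the work
#'   difference; retained for completeness).
#' @slot k_I,k_II surface tension (energy per area).
#' @slot contactFraction fraction of lateral contact with the same type.
#' @exportClass AdhesionEnergetics
setClass("AdhesionEnergetics",
  representation(
    omegaS_I = "numeric", omegaS_II = "numeric",
    omegaC_I = "numeric", omegaC_II = "numeric",
    omegaC_cross = "numeric",
    k_I = "numeric", k_II = "numeric",
    contactFraction = "numeric"
  )
)

setValidity("AdhesionEnergetics", function(object) {
  msg <- character()
  if (object@k_I <= 0 || object@k_II <= 0) msg <- c(msg, "k must be > 0")
  adh <- c(object@omegaS_I, object@omegaS_II, object@omegaC_I,
           object@omegaC_II, object@omegaC_cross)
  if (any(adh < 0)) msg <- c(msg, "adhesion parameters must be >= 0")
  if (object@contactFraction < 0 || object@contactFraction > 1)
    msg <- c(msg, "contactFraction must be in [0, 1]")
  if (length(msg)) msg else TRUE
})

## ---------------------------------------------------------------------------
## show methods
## ---------------------------------------------------------------------------

setMethod("show", "SimConfig", function(object) {
  cat(sprintf("SimConfig: %d x %d x %d grid (a0 = %g), %d cells, R0 = %g\n",
              object@nx, object@ny, object@nz, object@a0, object@nCell,
              object@R0))
  cat(sprintf("  geometry = %s, dt = %g, nSim = %d, seed = %d\n",
              object@geometry, object@dt, object@nSim, object@seed))
  cat(sprintf("  tau = 2*R0/vbar = %g (vbar = %g)\n",
              2 * object@R0 / object@vbar, object@vbar))
})

setMethod("show", "Monolayer", function(object) {
  ex <- sum(!is.na(object@extrudedAt))
  cat(sprintf("Monolayer: %d cells (%d A, %d B) at step %d; %d extruded\n",
              length(object@theta), sum(object@type == "A"),
              sum(object@type == "B"), object@stepIndex, ex))
})

setMethod("show", "StressField", function(object) {
  d <- dim(object@values)
  dim <- if (length(d) == 5L) "3D" else "2D"
  cat(sprintf("StressField (%s): grid %s, spacing %g, unit '%s'\n",
              dim, paste(head(d, -2), collapse = " x "), object@spacing,
              object@unit))
})

setMethod("show", "Field2D", function(object) {
  d <- dim(object@values)
  cat(sprintf("%s: %d x %d pixels, %d channel(s), pixel %g um, unit '%s'\n",
              class(object), d[1], d[2], d[3], object@pixelSize, object@unit))
})

setMethod("show", "ShapeSequence", function(object) {
  cat(sprintf(
    "ShapeSequence: r_a = %g um, r_s = %g um, V = %.1f um^3 (constant)\n",
    object@apicalRadius, object@sphereRadius, object@volume))
})
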