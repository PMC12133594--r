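## Analytic energetics of cell elimination.
##
## A cell leaving the monolayer passes through a constant-volume shape
## sequence: cylinder (basal radius = apical radius) -> cone (basal radius
## shrinks to 0) -> sphere (detached).  The work along the path has an
## adhesive part (the cell does work against its substrate and lateral
## adhesions as those contact areas shrink) and a tension part k*dA_tot.
## Because all areas are state functions of the shape, the path work equals
## the endpoint difference; the two legs are reported separately.

#' Construct a constant-volume shape sequence
#'
#' @param apicalRadius apical radius \eqn{r_a} (um); held constant.
#' @param sphereRadius radius \eqn{r_s} (um) of the final detached sphere.
#' @return a [ShapeSequence-class] with volume \eqn{(4/3)\pi r_s^3}.
#' @examples
#' seqn <- shapeSequence()
#' shapeAreas("sphere", 0, seqn)$Atot  # 4*pi*10^2
#' @export
shapeSequence <- function(apicalRadius = 10, sphereRadius = 10) {
  new("ShapeSequence", apicalRadius = apicalRadius,
      sphereRadius = sphereRadius, volume = 4 / 3 * pi * sphereRadius^3)
}

#' Surface areas of one shape in the elimination sequence
#'
#' Heights are solved from volume conservation.  `As` is the basal
#' (substrate-contact) disk, `Acc` the lateral (neighbour-contact) surface,
#' `Aapical` the free apical surface, and `Atot` their sum (the closed
#' surface of the shape).  The sphere has no substrate or lateral contact.
#'
#' @param shape `"cylinder"`, `"frustum"` or `"sphere"`.  A frustum with
#'   `rb = 0` is the cone endpoint; with `rb = apicalRadius` it coincides
#'   with the cylinder.
#' @param rb basal radius (um); ignored for the sphere.
#' @param seq a [ShapeSequence-class].
#' @return list with `As`, `Acc`, `Aapical`, `Atot`, `height`, `volume`.
#' @export
shapeAreas <- function(shape = c("cylinder", "frustum", "sphere"), rb = NULL,
                       seq = shapeSequence()) {
  shape <- match.arg(shape)
  stopifnot(is(seq, "ShapeSequence"))
  ra <- seq@apicalRadius
  V <- seq@volume
  if (shape == "sphere") {
    rs <- seq@sphereRadius
    return(list(As = 0, Acc = 0, Aapical = 0, Atot = 4 * pi * rs^2,
                height = 2 * rs, volume = V))
  }
  if (shape == "cylinder") rb <- ra
  if (is.null(rb) || rb < 0)
    stop("geometry error: basal radius rb must be >= 0")
  ## frustum (cone for rb = 0, cylinder for rb = ra): V = pi*h/3*(ra^2+ra*rb+rb^2)
  denom <- ra^2 + ra * rb + rb^2
  if (denom <= 0) stop("geometry error: no nonnegative height exists")
  h <- 3 * V / (pi * denom)
  slant <- sqrt(h^2 + (ra - rb)^2)
  As <- pi * rb^2
  Acc <- pi * (ra + rb) * slant
  Aapical <- pi * ra^2
  list(As = As, Acc = Acc, Aapical = Aapical, Atot = As + Acc + Aapical,
       height = h, volume = pi * h / 3 * denom)
}

#' Adhesion/tension parameter set for two competing types
#'
#' @param omegaS_I,omegaS_II cell-substrate adhesion energy per area.
#' @param omegaC_I,omegaC_II same-type cell-cell adhesion energy per area.
#' @param omegaC_cross cross-type adhesion per area (drops out of the work
#'   difference between the two types).
#' @param k_I,k_II surface tension per area.
#' @param contactFraction fraction of the lateral surface in contact with
#'   same-type neighbours (0.5: half the perimeter faces the other type).
#' @return an [AdhesionEnergetics-class] object.
#' @export
adhesionEnergetics <- function(omegaS_I, omegaS_II, omegaC_I, omegaC_II,
                               omegaC_cross = 0, k_I = 1, k_II = k_I,
                               contactFraction = 0.5) {
  new("AdhesionEnergetics",
      omegaS_I = omegaS_I, omegaS_II = omegaS_II,
      omegaC_I = omegaC_I, omegaC_II = omegaC_II,
      omegaC_cross = omegaC_cross, k_I = k_I, k_II = k_II,
      contactFraction = contactFraction)
}

## area changes over one leg of the path, as a named list of dAs, dAcc, dAtot
.areaDelta <- function(from, to) {
  list(dAs = to$As - from$As, dAcc = to$Acc - from$Acc,
       dAtot = to$Atot - from$Atot)
}

#' Work needed to eliminate a cell of one type
#'
#' Evaluates the elimination work for the focal type over the constant-volume
#' cylinder -> cone -> sphere path:
#' \deqn{dW = (\omega_s^{opp} - \omega_s^{own})\, dA_s
#'        - f\,\omega_c^{own}\, dA_{cc} + k^{own}\, dA_{tot},}
#' where \eqn{f} is the same-type contact fraction.  The substrate term uses
#' the adhesion difference because the winning neighbour re-occupies the
#' substrate area the losing cell vacates; the cross-type lateral term is
#' identical for both types and is omitted.
#'
#' @param params an [AdhesionEnergetics-class] object.
#' @param type `"I"` or `"II"`: which type is being eliminated.
#' @param seq a [ShapeSequence-class].
#' @return list with `total` (work over the full path), `legs` (work per
#'   path leg: `cylinderToCone`, `coneToSphere`), `terms` (decomposition into
#'   `substrate`, `cellcell`, `tension` over the full path), `normalizer`
#'   (\eqn{dW_0^k}: magnitude of the pure-tension work with all adhesions
#'   zero) and `normalized` (`total / normalizer`).
#' @examples
#' ae <- adhesionEnergetics(omegaS_I = 0.2, omegaS_II = 0.4,
#'                          omegaC_I = 0.8, omegaC_II = 0.1, k_I = 1)
#' eliminationWork(ae, "I")$normalized
#' @export
eliminationWork <- function(params, type = c("I", "II"),
                            seq = shapeSequence()) {
  type <- match.arg(type)
  stopifnot(is(params, "AdhesionEnergetics"))
  own <- if (type == "I")
    list(omegaS = params@omegaS_I, omegaC = params@omegaC_I, k = params@k_I)
  else
    list(omegaS = params@omegaS_II, omegaC = params@omegaC_II, k = params@k_II)
  opp <- if (type == "I") params@omegaS_II else params@omegaS_I
  f <- params@contactFraction

  cyl <- shapeAreas("cylinder", seq = seq)
  cone <- shapeAreas("frustum", rb = 0, seq = seq)
  sph <- shapeAreas("sphere", seq = seq)
  legs <- list(cylinderToCone = .areaDelta(cyl, cone),
               coneToSphere = .areaDelta(cone, sph))

  wleg <- function(dA)
    c(substrate = (opp - own$omegaS) * dA$dAs,
      cellcell = -f * own$omegaC * dA$dAcc,
      tension = own$k * dA$dAtot)
  terms1 <- wleg(legs$cylinderToCone)
  terms2 <- wleg(legs$coneToSphere)
  terms <- terms1 + terms2
  total <- sum(terms)
  dAtotPath <- legs$cylinderToCone$dAtot + legs$coneToSphere$dAtot
  normalizer <- abs(own$k * dAtotPath)
  list(total = total,
       legs = list(cylinderToCone = sum(terms1), coneToSphere = sum(terms2)),
       terms = as.list(terms),
       normalizer = normalizer,
       normalized = total / normalizer)
}

#' Win/lose phase diagram over adhesion differences
#'
#' Evaluates the normalized work difference
#' \eqn{\Delta W = (dW^{II} - dW^{I}) / dW_0^k} on a grid of cell-cell and
#' cell-substrate adhesion differences
#' \eqn{\Delta\omega_{cc} = \omega_c^{II} - \omega_c^{I}} and
#' \eqn{\Delta\omega_{cs} = \omega_s^{II} - \omega_s^{I}}, holding the mean
#' of each pair at the baseline.  \eqn{\Delta W > 0} means type II takes more
#' work to eliminate, i.e. type II wins at the interface.  The diagram
#' contains a region with \eqn{\Delta\omega_{cc} > 0},
#' \eqn{\Delta\omega_{cs} < 0} and \eqn{\Delta W > 0}: higher cell-cell
#' adhesion can win despite lower cell-substrate adhesion.
#'
#' @param deltaOmegaCC,deltaOmegaCS numeric grids of adhesion differences
#'   (energy per area, same units as `k`).
#' @param baseline named list with `omegaC`, `omegaS`, `k`: the shared
#'   baseline parameters.  Defaults span both signs of \eqn{\Delta W}.
#' @param seq a [ShapeSequence-class].
#' @return a list with `deltaW` (matrix `[length(deltaOmegaCC),
#'   length(deltaOmegaCS)]` of normalized work differences), the axes, and
#'   `baseline`.
#' @export
phaseDiagram <- function(deltaOmegaCC = seq(-0.5, 0.5, length.out = 50),
                         deltaOmegaCS = seq(-0.5, 0.5, length.out = 50),
                         baseline = list(omegaC = 0.5, omegaS = 0.5, k = 1),
                         seq = shapeSequence()) {
  stopifnot(all(c("omegaC", "omegaS", "k") %in% names(baseline)),
            baseline$k > 0)
  m <- matrix(NA_real_, length(deltaOmegaCC), length(deltaOmegaCS))
  for (i in seq_along(deltaOmegaCC)) {
    dcc <- deltaOmegaCC[i]
    for (j in seq_along(deltaOmegaCS)) {
      dcs <- deltaOmegaCS[j]
      ae <- adhesionEnergetics(
        omegaS_I = max(baseline$omegaS - dcs / 2, 0),
        omegaS_II = max(baseline$omegaS + dcs / 2, 0),
        omegaC_I = max(baseline$omegaC - dcc / 2, 0),
        omegaC_II = max(baseline$omegaC + dcc / 2, 0),
        k_I = baseline$k)
      wI <- eliminationWork(ae, "I", seq)
      wII <- eliminationWork(ae, "II", seq)
      m[i, j] <- (wII$total - wI$total) / wI$normalizer
    }
  }
  list(deltaW = m, deltaOmegaCC = deltaOmegaCC, deltaOmegaCS = deltaOmegaCS,
       baseline = baseline)
}
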