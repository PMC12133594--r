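## Extrusion detection and the spatial/temporal statistics of extrusion
## events.  Event catalogs are plain data.frames with columns
## (step, x, y, id, type); experimental-style catalogs may omit id.

#' Detect extrusion events in a simulation trajectory
#'
#' The physics produces extrusion without any explicit threshold: a cell is
#' squeezed out once out-of-plane forces overcome the forces keeping it on
#' the substrate.  This detector flags the first step at which a cell's
#' substrate contact \eqn{\int \phi_i^2 \phi_w^2 dx} drops below
#' `contactFrac` of its initial value while its center of mass sits more
#' than `heightOffset` above the median height of the resident population.
#' Flags are permanent; the event position is the in-plane center of mass
#' at flag time.  These are detection thresholds of the analysis layer, not
#' part of the model dynamics.
#'
#' @param diagnostics per-step per-cell table with columns `step`, `id`,
#'   `type`, `cx`, `cy`, `cz`, `contact` (as produced by
#'   [runSimulation()]).
#' @param R0 initial cell radius (grid units).
#' @param contactFrac contact threshold relative to the initial contact.
#' @param heightOffset height criterion; default \eqn{R_0/2}.
#' @return data.frame `step`, `x`, `y`, `id`, `type` (one row per event),
#'   ordered by step then id.
#' @export
detectExtrusions <- function(diagnostics, R0, contactFrac = 0.01,
                             heightOffset = R0 / 2) {
  stopifnot(all(c("step", "id", "type", "cx", "cy", "cz", "contact") %in%
                names(diagnostics)))
  diagnostics <- diagnostics[order(diagnostics$step, diagnostics$id), ]
  ids <- sort(unique(diagnostics$id))
  first <- diagnostics[diagnostics$step == min(diagnostics$step), ]
  c0 <- first$contact[match(ids, first$id)]
  flagged <- setNames(rep(NA_real_, length(ids)), ids)
  events <- list()
  for (s in sort(unique(diagnostics$step))) {
    snap <- diagnostics[diagnostics$step == s, ]
    resident <- is.na(flagged[as.character(snap$id)])
    medz <- median(snap$cz[resident])
    low <- snap$contact < contactFrac * c0[match(snap$id, ids)]
    high <- snap$cz > medz + heightOffset
    hit <- resident & low & high
    for (r in which(hit)) {
      flagged[as.character(snap$id[r])] <- s
      events[[length(events) + 1L]] <-
        data.frame(step = s, x = snap$cx[r], y = snap$cy[r],
                   id = snap$id[r], type = snap$type[r])
    }
  }
  if (!length(events))
    return(data.frame(step = numeric(), x = numeric(), y = numeric(),
                      id = numeric(), type = character()))
  out <- do.call(rbind, events)
  out[order(out$step, out$id), , drop = FALSE]
}

#' Interface-distance probability distribution of extrusion events
#'
#' For each event, the Euclidean distance from the event position to the
#' two-population interface is read off the same-frame distance map.  Event
#' counts per distance bin are divided by the pixel count of the event
#' type's region in that bin (the random probability of that distance) and
#' renormalized to sum to one: the probability of being extruded given the
#' distance from the interface.
#'
#' @param events catalog data.frame with `x`, `y`, `type` and a frame
#'   column (`step` or `frame`) indexing `occFrames`.
#' @param occFrames occupancy matrix (static) or `[nx, ny, nt]` character
#'   array of occupancy frames; frame index is matched via `frameIndex`.
#' @param binWidth distance bin width (pixels).
#' @param maxDist largest binned distance.
#' @param periodic passed to [interfaceDistance()].
#' @param frameIndex optional function mapping the event frame column to an
#'   index into `occFrames` (defaults to the identity, clamped into range).
#' @return data.frame `type`, `distance`, `pdf`, `events`, `pixels`;
#'   attribute `"outOfRegion"` counts events whose occupancy label
#'   disagreed with their type (reassigned to the nearest region and kept,
#'   with a warning).
#' @export
extrusionDistancePDF <- function(events, occFrames, binWidth = 5,
                                 maxDist = NULL,
                                 periodic = c(FALSE, FALSE),
                                 frameIndex = NULL) {
  fcol <- if ("step" %in% names(events)) "step" else "frame"
  static <- is.matrix(occFrames)
  nt <- if (static) 1L else dim(occFrames)[3]
  if (is.null(frameIndex))
    frameIndex <- function(f) pmin(pmax(round(f), 1L), nt)
  dims <- if (static) dim(occFrames) else dim(occFrames)[1:2]
  if (is.null(maxDist)) maxDist <- min(dims) / 2
  breaks <- seq(0, maxDist + binWidth, by = binWidth)
  nb <- length(breaks) - 1L
  types <- sort(unique(as.character(events$type)))

  ## per-frame distance maps and per-bin pixel counts, computed lazily
  dcache <- vector("list", nt)
  getFrame <- function(k) {
    if (is.null(dcache[[k]])) {
      occ <- if (static) occFrames else occFrames[, , k]
      dd <- interfaceDistance(occ, periodic)$distance
      bin <- matrix(findInterval(dd, breaks, rightmost.closed = TRUE),
                    nrow(dd), ncol(dd))
      px <- sapply(types, function(ty)
        vapply(seq_len(nb), function(b) sum(occ == ty & bin == b),
               numeric(1)))
      dcache[[k]] <<- list(occ = occ, d = dd, bin = bin, px = px)
    }
    dcache[[k]]
  }

  nOut <- 0L
  counts <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  pixels <- matrix(0, nb, length(types), dimnames = list(NULL, types))
  usedFrames <- unique(frameIndex(events[[fcol]]))
  for (k in usedFrames) pixels <- pixels + getFrame(k)$px
  for (r in seq_len(nrow(events))) {
    k <- frameIndex(events[[fcol]][r])
    fr <- getFrame(k)
    ix <- pmin(pmax(round(events$x[r]), 1L), dims[1])
    iy <- pmin(pmax(round(events$y[r]), 1L), dims[2])
    ty <- as.character(events$type[r])
    if (fr$occ[ix, iy] != ty) nOut <- nOut + 1L
    b <- fr$bin[ix, iy]
    if (b >= 1 && b <= nb) counts[b, ty] <- counts[b, ty] + 1
  }
  if (nOut > 0L)
    warning(nOut, " event(s) fell outside their type's region; ",
            "assigned to the nearest region")
  pixels <- pixels / length(usedFrames)
  out <- do.call(rbind, lapply(types, function(ty) {
    p <- counts[, ty] / pixels[, ty]
    p[!is.finite(p)] <- NA
    tot <- sum(p, na.rm = TRUE)
    data.frame(type = ty,
               distance = breaks[-length(breaks)] + binWidth / 2,
               pdf = p / tot, events = counts[, ty], pixels = pixels[, ty])
  }))
  attr(out, "outOfRegion") <- nOut
  out
}

#' Extrusion rate per time interval and occupied area
#'
#' Counts events of each type within consecutive time intervals and divides
#' by the area occupied by that type (mean over the frames of the
#' interval), yielding extrusions per unit time per unit area.  A rolling
#' mean over 3 intervals is available.  Intervals with zero occupied area
#' are reported as `NA`.
#'
#' @param events catalog with a time/frame column (`step` or `frame`) and
#'   `type`.
#' @param occFrames occupancy frames (`[nx, ny, nt]` or static matrix).
#' @param interval interval length in time units.
#' @param timePerFrame time units per occupancy frame.
#' @param pixelArea area of one pixel (e.g. mm^2).
#' @param rolling if `TRUE`, apply the 3-interval rolling average.
#' @return data.frame `type`, `t0`, `t1`, `events`, `area`, `rate`.
#' @export
extrusionRate <- function(events, occFrames, interval, timePerFrame = 1,
                          pixelArea = 1, rolling = FALSE) {
  fcol <- if ("step" %in% names(events)) "step" else "frame"
  static <- is.matrix(occFrames)
  nt <- if (static) 1L else dim(occFrames)[3]
  tmax <- max(events[[fcol]] * timePerFrame, nt * timePerFrame)
  edges <- seq(0, tmax + interval, by = interval)
  types <- sort(unique(as.character(events$type)))
  rows <- list()
  for (ty in types) {
    ev <- events[events$type == ty, ]
    for (k in seq_len(length(edges) - 1L)) {
      t0 <- edges[k]; t1 <- edges[k + 1L]
      n <- sum(ev[[fcol]] * timePerFrame >= t0 &
               ev[[fcol]] * timePerFrame < t1)
      fsel <- which((seq_len(nt) * timePerFrame) >= t0 &
                    (seq_len(nt) * timePerFrame) < t1)
      if (static || !length(fsel)) {
        occ <- if (static) occFrames else occFrames[, , nt]
        area <- sum(occ == ty) * pixelArea
      } else {
        area <- mean(vapply(fsel, function(f)
          sum(occFrames[, , f] == ty), numeric(1))) * pixelArea
      }
      rate <- if (area > 0) n / interval / area else NA_real_
      rows[[length(rows) + 1L]] <-
        data.frame(type = ty, t0 = t0, t1 = t1, events = n, area = area,
                   rate = rate)
    }
  }
  out <- do.call(rbind, rows)
  if (rolling) {
    for (ty in types) {
      sel <- which(out$type == ty)
      r <- out$rate[sel]
      sm <- r
      for (i in seq_along(r)) {
        w <- intersect(seq(i - 1, i + 1), seq_along(r))
        sm[i] <- mean(r[w], na.rm = TRUE)
      }
      out$rate[sel] <- sm
    }
  }
  out
}

## bilinear sample of matrix m at (x, y) (1-based continuous coords)
.bilinear <- function(m, x, y) {
  nx <- nrow(m); ny <- ncol(m)
  x <- pmin(pmax(x, 1), nx); y <- pmin(pmax(y, 1), ny)
  x0 <- floor(x); y0 <- floor(y)
  x1 <- pmin(x0 + 1, nx); y1 <- pmin(y0 + 1, ny)
  fx <- x - x0; fy <- y - y0
  m[cbind(x0, y0)] * (1 - fx) * (1 - fy) +
    m[cbind(x1, y0)] * fx * (1 - fy) +
    m[cbind(x0, y1)] * (1 - fx) * fy +
    m[cbind(x1, y1)] * fx * fy
}

#' Ensemble stress map around extrusion events
#'
#' Cuts a square window around each event position, averages the stress over
#' the declared epoch of frames relative to the extrusion time, optionally
#' rotates the window so the opposing cell type lies in the +x half-plane
#' (alignment direction taken from the occupancy map as the mean direction
#' toward opposite-type pixels within the window), and aggregates across
#' events with the median (the default) or mean.  Events whose window would
#' leave the frame are excluded and counted.
#'
#' @param stressFrames `[nx, ny, nt]` array of scalar stress frames.
#' @param events catalog with `x`, `y`, type and frame column
#'   (`step`/`frame`).
#' @param occFrames occupancy frames for the alignment (matrix or array).
#' @param halfSize half window size in pixels (window is `2*halfSize+1`
#'   squared).
#' @param epoch integer vector of frame offsets relative to the event frame
#'   to average over (e.g. `-4:-3` for a pre-extrusion epoch).
#' @param align rotate windows toward the opposing type?
#' @param statistic `"median"` or `"mean"` across events.
#' @param nbins histogram bins for the value PDF.
#' @return list with `map` (the aggregated window), `pdf` (data.frame
#'   `value`, `density`), `nUsed`, `nExcluded`.
#' @export
ensembleStressMap <- function(stressFrames, events, occFrames = NULL,
                              halfSize = 15, epoch = 0L, align = TRUE,
                              statistic = c("median", "mean"),
                              nbins = 30) {
  statistic <- match.arg(statistic)
  fcol <- if ("step" %in% names(events)) "step" else "frame"
  nx <- dim(stressFrames)[1]; ny <- dim(stressFrames)[2]
  nt <- dim(stressFrames)[3]
  w <- 2 * halfSize + 1
  grid <- expand.grid(dx = -halfSize:halfSize, dy = -halfSize:halfSize)
  maps <- list(); nExcluded <- 0L
  for (r in seq_len(nrow(events))) {
    f <- round(events[[fcol]][r])
    fs <- f + epoch
    fs <- fs[fs >= 1 & fs <= nt]
    cx <- events$x[r]; cy <- events$y[r]
    margin <- halfSize + 1.5
    if (!length(fs) || cx < margin || cy < margin ||
        cx > nx - margin + 1 || cy > ny - margin + 1) {
      nExcluded <- nExcluded + 1L
      next
    }
    ang <- 0
    if (align && !is.null(occFrames)) {
      occ <- if (is.matrix(occFrames)) occFrames
             else occFrames[, , pmin(pmax(f, 1), dim(occFrames)[3])]
      ty <- as.character(events$type[r])
      opp <- setdiff(c("A", "B"), ty)
      xs <- pmin(pmax(round(cx + grid$dx), 1L), nx)
      ys <- pmin(pmax(round(cy + grid$dy), 1L), ny)
      isOpp <- occ[cbind(xs, ys)] == opp
      if (any(isOpp))
        ang <- atan2(mean(grid$dy[isOpp]), mean(grid$dx[isOpp]))
    }
    avg <- matrix(0, nx, ny)
    for (ff in fs) avg <- avg + stressFrames[, , ff]
    avg <- avg / length(fs)
    ## sample the rotated window: +x of the window points toward the
    ## opposing type
    ca <- cos(ang); sa <- sin(ang)
    sx <- cx + grid$dx * ca - grid$dy * sa
    sy <- cy + grid$dx * sa + grid$dy * ca
    maps[[length(maps) + 1L]] <- matrix(.bilinear(avg, sx, sy), w, w)
  }
  if (!length(maps))
    return(list(map = NULL, pdf = NULL, nUsed = 0L, nExcluded = nExcluded))
  stack <- array(unlist(maps), c(w, w, length(maps)))
  map <- apply(stack, c(1, 2), statistic)
  vals <- as.vector(stack)
  h <- graphics::hist(vals, breaks = nbins, plot = FALSE)
  pdf <- data.frame(value = h$mids, density = h$density)
  list(map = map, pdf = pdf, nUsed = length(maps), nExcluded = nExcluded)
}

#' Local susceptibility time course around extrusions
#'
#' For each event, the susceptibility of the stress within a square of side
#' `squareSize` centred on the event is computed per frame over a window of
#' times relative to detection (t = 0); the ensemble mean across events is
#' normalized to its earliest time point.
#'
#' @param stressFrames `[nx, ny, nt]` scalar stress frames.
#' @param events catalog with `x`, `y` and frame column.
#' @param squareSize side of the square region (pixels).
#' @param tRange integer frame offsets relative to the event (e.g.
#'   `-8:2`).
#' @return data.frame `t` (offset), `chi` (ensemble mean, normalized to the
#'   first offset), `n` (events contributing); attribute
#'   `"chiAbsoluteFirst"` keeps the unnormalized first value.
#' @export
localSusceptibilityTimecourse <- function(stressFrames, events,
                                          squareSize = 15, tRange = -8:2) {
  fcol <- if ("step" %in% names(events)) "step" else "frame"
  nx <- dim(stressFrames)[1]; ny <- dim(stressFrames)[2]
  nt <- dim(stressFrames)[3]
  half <- floor(squareSize / 2)
  acc <- matrix(NA_real_, length(tRange), nrow(events))
  for (r in seq_len(nrow(events))) {
    f <- round(events[[fcol]][r])
    cx <- round(events$x[r]); cy <- round(events$y[r])
    if (cx - half < 1 || cy - half < 1 || cx + half > nx || cy + half > ny)
      next
    for (k in seq_along(tRange)) {
      ff <- f + tRange[k]
      if (ff < 1 || ff > nt) next
      v <- stressFrames[cx + (-half:half), cy + (-half:half), ff]
      acc[k, r] <- as.numeric(susceptibility(as.vector(v)))
    }
  }
  chi <- rowMeans(acc, na.rm = TRUE)
  n <- rowSums(!is.na(acc))
  first <- chi[which(is.finite(chi))[1]]
  out <- data.frame(t = tRange, chi = chi / first, n = n)
  attr(out, "chiAbsoluteFirst") <- first
  out
}

#' Distributions of the out-of-plane stress near the interface
#'
#' Collects \eqn{\sigma_{zz}} values within a band of the interface
#' (default four cell radii on each side), normalizes them by the maximum
#' in-plane compression magnitude (the most negative in-plane isotropic
#' stress), and returns the per-type PDF and CDF of the normalized values.
#'
#' @param stressFrames list of 3D [StressField-class] objects (one per
#'   frame); 2D stress fields are rejected since \eqn{\sigma_{zz}} does not
#'   exist there.
#' @param occFrames occupancy frames (matrix or `[nx, ny, nt]`).
#' @param bandWidth half width of the interface band in pixels
#'   (e.g. `4 * R0`).
#' @param weights optional list of `[nx, ny, nz]` projection weight arrays.
#' @param breaks histogram breaks (count or vector) for the PDF.
#' @param periodic passed to [interfaceDistance()].
#' @return list with `pdf` (data.frame `type`, `value`, `density`), `cdf`
#'   (data.frame `type`, `value`, `cdf`) and `normalization` (the maximum
#'   in-plane compression magnitude used).
#' @export
sigmaZZDistributions <- function(stressFrames, occFrames, bandWidth,
                                 weights = NULL, breaks = 40,
                                 periodic = c(TRUE, TRUE)) {
  if (is(stressFrames, "StressField")) stressFrames <- list(stressFrames)
  for (s in stressFrames)
    if (length(dim(s@values)) != 5L)
      stop("unsupported mode: sigma_zz distributions need 3D stress fields")
  nt <- length(stressFrames)
  static <- is.matrix(occFrames)
  zz <- list(); iso <- list()
  for (k in seq_len(nt)) {
    wk <- if (is.null(weights)) NULL else weights[[k]]
    zz[[k]] <- zProject(sigmaZZ(stressFrames[[k]]), wk)
    iso[[k]] <- zProject(isotropicStress(stressFrames[[k]], "3d-in-plane"),
                         wk)
  }
  maxComp <- max(vapply(iso, function(m) max(pmax(-m, 0)), numeric(1)))
  if (maxComp <= 0) maxComp <- 1
  valsByType <- list(A = numeric(), B = numeric())
  for (k in seq_len(nt)) {
    occ <- if (static) occFrames else occFrames[, , k]
    d <- interfaceDistance(occ, periodic)$distance
    sel <- d <= bandWidth
    for (ty in c("A", "B")) {
      take <- sel & occ == ty
      valsByType[[ty]] <- c(valsByType[[ty]], zz[[k]][take] / maxComp)
    }
  }
  pdfRows <- list(); cdfRows <- list()
  for (ty in c("A", "B")) {
    v <- valsByType[[ty]]
    if (!length(v)) next
    h <- graphics::hist(v, breaks = breaks, plot = FALSE)
    pdfRows[[ty]] <- data.frame(type = ty, value = h$mids,
                                density = h$density)
    sv <- sort(v)
    cdfRows[[ty]] <- data.frame(type = ty, value = sv,
                                cdf = seq_along(sv) / length(sv))
  }
  list(pdf = do.call(rbind, pdfRows), cdf = do.call(rbind, cdfRows),
       normalization = maxComp)
}
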