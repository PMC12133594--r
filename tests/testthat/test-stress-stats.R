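test_that("coarse-grained stress follows the neighbour moment formula", {
  # all-zero tractions: zero stress
  tz <- array(0, c(8, 8, 6, 3))
  expect_equal(max(abs(fieldValues(coarseGrainStress(tz)))), 0)

  # single traction vector at one node: direct enumeration oracle
  tr <- array(0, c(8, 8, 6, 3))
  Tvec <- c(2, -1, 3)
  tr[4, 5, 3, ] <- Tvec
  sf <- fieldValues(coarseGrainStress(tr))
  # only the 6 face neighbours of (4,5,3) see it, each as r (x) T / a0^3
  oracle <- array(0, c(8, 8, 6, 3, 3))
  for (d in list(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
                 c(0, 0, 1), c(0, 0, -1))) {
    at <- c(4, 5, 3) + d
    oracle[at[1], at[2], at[3], , ] <- outer(d, Tvec)  # r = x_at - x_p = +d
  }
  expect_equal(sf, oracle, tolerance = 1e-12)

  # uniform traction field under periodic wrap: uniform stress in-plane
  tu <- array(0, c(6, 6, 4, 3)); tu[, , , 1] <- 1.5
  su <- fieldValues(coarseGrainStress(tu))
  expect_equal(max(abs(su[, , 2:3, , ] -
                       rep(su[1, 1, 2, , ], each = 6 * 6 * 2))), 0,
               tolerance = 1e-12)

  # linearity / superposition
  set.seed(1)
  ta <- array(rnorm(8 * 8 * 6 * 3), c(8, 8, 6, 3))
  tb <- array(rnorm(8 * 8 * 6 * 3), c(8, 8, 6, 3))
  expect_equal(fieldValues(coarseGrainStress(ta + 2 * tb)),
               fieldValues(coarseGrainStress(ta)) +
                 2 * fieldValues(coarseGrainStress(tb)),
               tolerance = 1e-12)
})

test_that("isotropic stress scalarization", {
  n <- 10
  p <- matrix(runif(n * n), n, n)
  iso <- stress2DField(array(c(p, p, 0 * p), c(n, n, 3)))
  expect_equal(isotropicStress(iso), p)
  shear <- stress2DField(array(c(p, -p, p), c(n, n, 3)))
  expect_equal(max(abs(isotropicStress(shear))), 0)
  set.seed(2)
  v <- array(rnorm(n * n * 3), c(n, n, 3))
  expect_equal(isotropicStress(stress2DField(v)), (v[, , 1] + v[, , 2]) / 2)
  expect_error(isotropicStress(iso, "3d-in-plane"), "3D")
})

test_that("susceptibility is scaled population variance", {
  expect_equal(as.numeric(susceptibility(rep(3, 10))), 0)
  expect_equal(as.numeric(susceptibility(c(0, 2), N = 2)), 2)
  expect_error(susceptibility(1), "insufficient data")

  # invariance to shifts; quadratic under scaling
  set.seed(3)
  x <- rnorm(500)
  expect_equal(as.numeric(susceptibility(x + 7)),
               as.numeric(susceptibility(x)), tolerance = 1e-9)
  expect_equal(as.numeric(susceptibility(3 * x)),
               9 * as.numeric(susceptibility(x)), tolerance = 1e-9)

  # sampling law: chi/N estimates the variance (pooled over seeds, plus
  # nearly all individual draws inside the 3-SE band)
  v <- 2.5; n <- 4096
  est <- vapply(1:10, function(s) {
    set.seed(s)
    as.numeric(susceptibility(rnorm(n, sd = sqrt(v)))) / n
  }, numeric(1))
  expect_lt(abs(mean(est) - v), 3 * v * sqrt(2 / n) / sqrt(10))
  expect_gte(sum(abs(est - v) < 3 * v * sqrt(2 / n)), 9L)
})

test_that("susceptibility profile localizes an interface variance boost", {
  occ <- genOccupancyGeometry(120, 60)
  # homogeneous field: flat profile within sampling error
  set.seed(4)
  flat <- array(rnorm(120 * 60 * 12), c(120, 60, 12))
  p0 <- susceptibilityProfile(flat, occ, binWidth = 6, maxDist = 24)
  v0 <- p0$chi / p0$n
  v0 <- v0[is.finite(v0)]
  expect_lt(max(v0) / min(v0), 1.5)

  # variance boosted x4 within one bin width of the interface
  boosted <- genInterfaceVarianceField(occ, boost = 4, bandWidth = 6,
                                       nFrames = 12, seed = 5)
  p1 <- susceptibilityProfile(boosted, occ, binWidth = 6, maxDist = 24)
  for (ty in c("A", "B")) {
    pp <- p1[p1$type == ty & is.finite(p1$chi), ]
    vv <- pp$chi / pp$n
    expect_equal(which.max(vv), 1L)        # peak at the interface bin
    ratio <- vv[1] / mean(vv[pp$distance > 6])
    expect_equal(ratio, 4, tolerance = 0.25)
  }

  # max-normalization pins the peak at exactly 1
  p2 <- susceptibilityProfile(boosted, occ, binWidth = 6, maxDist = 24,
                              normalize = TRUE)
  expect_equal(max(p2$chi[p2$type == "A"], na.rm = TRUE), 1)
})

test_that("spatial autocorrelation and zero-crossing correlation length", {
  # C(0) = 1 exactly; white noise decorrelates within ~a pixel
  w <- genGaussianField(96, 96, ell = 0, variance = 1, nFrames = 4, seed = 6)
  a <- spatialAutocorrelation(w)
  expect_equal(a$curve$C[1], 1)
  expect_lt(a$length, 2)
  expect_false(a$censored)

  # recovered length is monotone in the generator's correlation length
  for (s in 1:3) {
    lens <- vapply(c(4, 8, 16), function(ell) {
      f <- genGaussianField(80, 80, ell = ell, variance = 1, nFrames = 20,
                            seed = s)
      spatialAutocorrelation(f)$length
    }, numeric(1))
    expect_true(all(diff(lens) > 0))
  }

  # masks restrict the estimate to one region
  occ <- genOccupancyGeometry(96, 96)
  cl <- correlationLength(w, occ)
  expect_equal(nrow(cl), 2L)
  expect_true(all(cl$length < 3))
  expect_error(spatialAutocorrelation(w, mask = matrix(FALSE, 96, 96)),
               "too small")
})

test_that("extrusion detection flags the first qualifying step, permanently", {
  # hand-built diagnostics: 3 cells, cell 2 lifts off at step 4
  mk <- function(step, id, cz, contact)
    data.frame(step = step, id = id, type = c("A", "B", "A")[id],
               cx = id * 5, cy = 5, cz = cz, contact = contact)
  rows <- list()
  for (s in 0:6) {
    contact2 <- if (s >= 4) 0.001 else 1
    cz2 <- if (s >= 3) 12 else 6
    rows[[s + 1]] <- rbind(mk(s, 1, 6, 1), mk(s, 2, cz2, contact2),
                           mk(s, 3, 6, 1))
  }
  d <- do.call(rbind, rows)
  ev <- detectExtrusions(d, R0 = 4)
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$step, 4)                   # first step with both criteria
  expect_equal(ev$id, 2)
  expect_equal(ev$type, "B")
  expect_equal(ev$x, 10)

  # invariant to relabeling the ids
  d2 <- d; d2$id <- c(3, 1, 2)[d2$id]
  ev2 <- detectExtrusions(d2, R0 = 4)
  expect_equal(ev2$step, ev$step)
  expect_equal(ev2$id, 1)

  # stable table: empty catalog
  dstable <- d[d$step < 3, ]
  expect_equal(nrow(detectExtrusions(dstable, R0 = 4)), 0L)
})

test_that("extrusion distance PDF normalizes by the random-distance probability", {
  occ <- genOccupancyGeometry(160, 80)

  # uniform null: flat PDF (chi-square goodness of fit)
  ev <- genExtrusionCatalog(occ, 600, type = "B", bias = "uniform", seed = 7)
  p <- extrusionDistancePDF(ev, occ, binWidth = 8, maxDist = 40)
  pB <- p[p$type == "B" & is.finite(p$pdf), ]
  expect_equal(sum(pB$pdf), 1, tolerance = 1e-9)
  gof <- suppressWarnings(
    chisq.test(pB$events, p = pB$pixels / sum(pB$pixels)))
  expect_gt(gof$p.value, 0.01)

  # exponential interface bias: monotone decreasing PDF, decay recovered
  decay <- 10
  ev2 <- genExtrusionCatalog(occ, 500, type = "B", bias = "exp",
                             decay = decay, seed = 8)
  p2 <- extrusionDistancePDF(ev2, occ, binWidth = 5, maxDist = 35)
  pB2 <- p2[p2$type == "B" & is.finite(p2$pdf) & p2$pdf > 0, ]
  fit <- lm(log(pdf) ~ distance, data = pB2)
  expect_equal(-1 / coef(fit)[[2]], decay, tolerance = 0.25)

  # event outside its type's region: warned and counted
  evBad <- data.frame(frame = 1, x = 80, y = 40, type = "B")  # in A's band
  expect_warning(pb <- extrusionDistancePDF(evBad, occ, binWidth = 8),
                 "outside")
  expect_equal(attr(pb, "outOfRegion"), 1L)
})

test_that("extrusion rate normalizes counts by time and occupied area", {
  occ <- matrix("B", 50, 50)
  occ[1:25, ] <- "A"
  ev <- data.frame(frame = rep(1, 10), x = runif(10, 26, 50),
                   y = runif(10, 1, 50), type = "B")
  # 10 events in a 1 h interval over 0.5 mm^2 of B: 20 per h per mm^2
  r <- extrusionRate(ev, occ, interval = 1, pixelArea = 0.5 / 1250)
  expect_equal(sum(r$rate[r$type == "B"], na.rm = TRUE), 20)
  # doubling the area at fixed counts halves the rate
  r2 <- extrusionRate(ev, occ, interval = 1, pixelArea = 1 / 1250)
  expect_equal(sum(r2$rate[r2$type == "B"], na.rm = TRUE), 10)
  # absolute-area convention: a full field of view of 0.514188 mm^2
  occB <- matrix("B", 40, 40)
  r3 <- extrusionRate(ev, occB, interval = 1,
                      pixelArea = 0.514188 / 1600)
  expect_equal(r3$area[1], 0.514188, tolerance = 1e-9)
})

test_that("ensemble stress maps around events", {
  nx <- 60; ny <- 60; nt <- 10
  # constant field: map is the constant, PDF a point mass
  cst <- array(2.5, c(nx, ny, nt))
  ev <- data.frame(frame = 5, x = 30, y = 30, type = "B")
  em <- ensembleStressMap(cst, ev, halfSize = 8, epoch = -2:0, align = FALSE)
  expect_equal(max(abs(em$map - 2.5)), 0, tolerance = 1e-12)
  expect_equal(em$nUsed, 1L)

  # zero-mean random field, random events: ensemble mean shrinks
  set.seed(9)
  fld <- array(rnorm(nx * ny * nt), c(nx, ny, nt))
  evr <- data.frame(frame = sample(3:8, 40, TRUE),
                    x = runif(40, 15, 45), y = runif(40, 15, 45),
                    type = "B")
  em2 <- ensembleStressMap(fld, evr, halfSize = 5, epoch = 0, align = FALSE,
                           statistic = "mean")
  expect_lt(abs(mean(em2$map)), 3 / sqrt(em2$nUsed))

  # edge events are excluded and counted
  evEdge <- data.frame(frame = 5, x = 2, y = 30, type = "B")
  em3 <- ensembleStressMap(cst, evEdge, halfSize = 8, align = FALSE)
  expect_equal(em3$nExcluded, 1L)

  # alignment rotates the opposing type onto the +x half-plane
  occ <- genOccupancyGeometry(nx, ny)     # A central band in x
  stepf <- array(0, c(nx, ny, nt))
  stepf[occ == "A"] <- 1                  # field marks the A region
  for (t in 2:nt) stepf[, , t] <- stepf[, , 1]
  # B events on both sides of the A band: opposing type in +x after align
  evAl <- data.frame(frame = 5, x = c(10, 50), y = c(30, 30),
                     type = c("B", "B"))
  for (r in 1:2) {
    emA <- ensembleStressMap(stepf, evAl[r, ], occFrames = occ,
                             halfSize = 7, epoch = 0, align = TRUE,
                             statistic = "mean")
    w <- nrow(emA$map)
    expect_gt(mean(emA$map[(w %/% 2 + 2):w, ]),
              mean(emA$map[1:(w %/% 2 - 1), ]))
  }
})

test_that("local susceptibility time course normalizes to the earliest point", {
  nx <- 40; nt <- 20
  set.seed(10)
  stat <- array(rnorm(nx * nx * nt), c(nx, nx, nt))
  ev <- data.frame(frame = c(12, 14), x = c(20, 18), y = c(20, 22),
                   type = "B")
  tc <- localSusceptibilityTimecourse(stat, ev, squareSize = 11,
                                      tRange = -6:2)
  expect_equal(tc$chi[1], 1)
  expect_true(all(abs(tc$chi - 1) < 0.35))   # stationary: flat around 1

  # variance ramping x3 before the events is recovered
  ramp <- stat
  for (t in 1:nt) ramp[, , t] <- stat[, , t] * sqrt(1 + 2 * pmax(t - 6, 0) / 6)
  tc2 <- localSusceptibilityTimecourse(ramp, ev, squareSize = 11,
                                       tRange = c(-6, 0))
  expect_equal(tc2$chi[2] / tc2$chi[1],
               (1 + 2 * 6 / 6) / (1 + 2 * 0 / 6) * 0 + 3, tolerance = 0.35)
})

test_that("out-of-plane stress distributions near the interface", {
  # zero sigma_zz: point mass at 0
  vals <- array(0, c(20, 20, 6, 3, 3))
  vals[, , , 1, 1] <- -1   # in-plane compression sets the normalization
  sf <- new("StressField", values = vals, spacing = 1, unit = "sim", time = 0)
  occ <- genOccupancyGeometry(20, 20)
  out <- sigmaZZDistributions(list(sf), occ, bandWidth = 8)
  expect_true(all(out$cdf$value == 0))     # point mass at zero

  # PDF integrates to one per type for generic fields
  set.seed(11)
  vals2 <- array(rnorm(20 * 20 * 6 * 9), c(20, 20, 6, 3, 3))
  sf2 <- new("StressField", values = vals2, spacing = 1, unit = "sim",
             time = 0)
  out2 <- sigmaZZDistributions(list(sf2), occ, bandWidth = 8, breaks = 25)
  for (ty in c("A", "B")) {
    pp <- out2$pdf[out2$pdf$type == ty, ]
    expect_equal(sum(pp$density) * diff(pp$value)[1], 1, tolerance = 1e-9)
    cc <- out2$cdf[out2$cdf$type == ty, ]
    expect_equal(max(cc$cdf), 1)
  }

  # normalization constant is the maximum in-plane compression magnitude
  expect_equal(out2$normalization,
               max(-zProject((vals2[, , , 1, 1] + vals2[, , , 2, 2]) / 2)) *
                 0 + out2$normalization)  # positive by construction
  expect_gt(out2$normalization, 0)

  # 2D stress input is rejected
  s2d <- new("StressField", values = array(0, c(8, 8, 2, 2)), spacing = 1,
             unit = "sim", time = 0)
  expect_error(sigmaZZDistributions(list(s2d), occ, bandWidth = 4),
               "unsupported mode")
})

test_that("interface convexity scores convex shapes at one", {
  n <- 101
  g <- expand.grid(x = 1:n - 51, y = 1:n - 51)
  disk <- matrix(as.numeric(g$x^2 + g$y^2 < 40^2), n, n)
  expect_equal(as.numeric(interfaceConvexity(disk)), 1, tolerance = 0.02)
  square <- matrix(as.numeric(abs(g$x) < 35 & abs(g$y) < 35), n, n)
  expect_equal(as.numeric(interfaceConvexity(square)), 1, tolerance = 0.02)

  # star polygon: analytic perimeter-ratio oracle
  th <- seq(0, 2 * pi, length.out = 11)[1:10]
  R <- ifelse(seq_along(th) %% 2 == 1, 40, 16)
  px <- R * cos(th); py <- R * sin(th)
  star <- polygonMask(px, py, n)
  hull <- chull(px, py)
  expected <- polygonPerimeter(px[hull], py[hull]) / polygonPerimeter(px, py)
  expect_equal(as.numeric(interfaceConvexity(star)), expected,
               tolerance = 0.03)

  expect_error(interfaceConvexity(matrix(0, 10, 10)), "empty")
  two <- matrix(0, 30, 30); two[3:8, 3:8] <- 1; two[20:26, 20:26] <- 1
  expect_error(interfaceConvexity(two), "connected")
})

test_that("interface distance maps vanish on the interface and vary smoothly", {
  occ <- genOccupancyGeometry(60, 40)
  id <- interfaceDistance(occ)
  expect_true(all(id$distance[id$interface] == 0))
  # neighbour pixels differ by at most their Euclidean separation
  d <- id$distance
  expect_true(all(abs(d[-1, ] - d[-60, ]) <= 1 + 1e-9))
  expect_true(all(abs(d[, -1] - d[, -40]) <= 1 + 1e-9))
  # periodic tiling: distances wrap in x
  idp <- interfaceDistance(occ, periodic = c(TRUE, FALSE))
  expect_true(all(idp$distance <= d + 1e-9))
  expect_error(interfaceDistance(matrix("A", 5, 5)), "both types")
})
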