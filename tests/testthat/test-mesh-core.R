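test_that("edge interpolant passes through its endpoints for arbitrary normals", {
  set.seed(42)
  for (k in 1:50) {
    xA <- rnorm(3); xB <- rnorm(3)
    if (sqrt(sum((xB - xA)^2)) < 1e-3) next
    nA <- rnorm(3); nA <- nA / sqrt(sum(nA^2))
    nB <- rnorm(3); nB <- nB / sqrt(sum(nB^2))
    ec <- nagataCoefficients(xA, xB, nA, nB)
    expect_true(all(is.finite(c(ec$c1, ec$c2))))
    ends <- evalEdgeInterpolant(xA, xB, ec, c(0, 1))
    expect_lt(max(abs(ends[1, ] - xA)), 1e-10)
    expect_lt(max(abs(ends[2, ] - xB)), 1e-10)
  }
})

test_that("planar symmetric normals give the straight chord", {
  ec <- nagataCoefficients(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, 1))
  expect_lt(max(abs(c(ec$c1, ec$c2))), 1e-12)
})

test_that("circle-arc edge beats the chord (radial-error oracle)", {
  # two points on the unit circle at +-30 degrees with exact radial normals
  a <- c(cos(-pi / 6), sin(-pi / 6), 0)
  b <- c(cos(pi / 6), sin(pi / 6), 0)
  ec <- nagataCoefficients(a, b, a, b)
  t <- seq(0, 1, length.out = 201)
  pts <- evalEdgeInterpolant(a, b, ec, t)
  radialErr <- abs(sqrt(rowSums(pts^2)) - 1)
  chord <- outer(1 - t, a) + outer(t, b)
  chordErr <- abs(sqrt(rowSums(chord^2)) - 1)
  expect_lt(radialErr[101], chordErr[101])      # midpoint closer to the circle
  expect_lt(max(radialErr), max(chordErr))      # uniformly better
})

test_that("degenerate-normal configurations stay finite (quadratic failure mode)", {
  # normals antiparallel and nearly parallel to the chord
  d <- c(1, 0, 0)
  nA <- c(0.999, 0.04471017781221, 0); nA <- nA / sqrt(sum(nA^2))
  nB <- -nA
  ec <- nagataCoefficients(c(0, 0, 0), d, nA, nB)
  expect_true(all(is.finite(c(ec$c1, ec$c2))))
  ends <- evalEdgeInterpolant(c(0, 0, 0), d, ec, c(0, 1))
  expect_lt(max(abs(ends[1, ])), 1e-10)
  expect_lt(max(abs(ends[2, ] - d)), 1e-10)
})

test_that("edge construction rejects bad inputs", {
  expect_error(nagataCoefficients(c(0, 0, 0), c(0, 0, 0), c(0, 0, 1), c(0, 0, 1)),
               "degenerate")
  expect_error(nagataCoefficients(c(0, 0, 0), c(1, 0, 0), c(0, 0, 2), c(0, 0, 1)),
               "unit")
})

test_that("face patch reproduces its boundary curves exactly", {
  mesh <- sphere320
  fc <- mesh@faces[17, ]
  t <- seq(0, 1, length.out = 11)
  # patch restricted to the edge (v1 -> v2): barycentric (1-t, t, 0)
  onEdge <- evalFacePatch(mesh, 17, cbind(1 - t, t, 0))
  ec <- nagataCoefficients(mesh@vertices[fc[1], ], mesh@vertices[fc[2], ],
                           mesh@normals[fc[1], ], mesh@normals[fc[2], ])
  curve <- evalEdgeInterpolant(mesh@vertices[fc[1], ], mesh@vertices[fc[2], ], ec, t)
  expect_lt(max(abs(onEdge - curve)), 1e-10)
  # third edge (v1 -> v3): barycentric (1-t, 0, t)
  onEdge3 <- evalFacePatch(mesh, 17, cbind(1 - t, 0, t))
  ec3 <- nagataCoefficients(mesh@vertices[fc[1], ], mesh@vertices[fc[3], ],
                            mesh@normals[fc[1], ], mesh@normals[fc[3], ])
  curve3 <- evalEdgeInterpolant(mesh@vertices[fc[1], ], mesh@vertices[fc[3], ], ec3, t)
  expect_lt(max(abs(onEdge3 - curve3)), 1e-10)
})

test_that("flat triangle with coincident normals is the Euclidean triangle", {
  v <- rbind(c(0, 0, 0), c(1, 0, 0), c(0.5, sqrt(3) / 2, 0), c(0.5, -sqrt(3) / 2, 0))
  f <- rbind(c(1, 2, 3), c(2, 1, 4))
  n <- matrix(rep(c(0, 0, 1), 4), ncol = 3, byrow = TRUE)
  mesh <- surfaceMesh(v, f, normals = n)
  g <- faceGeometry(mesh)
  expect_equal(g$area, rep(sqrt(3) / 4, 2), tolerance = 1e-12)
  expect_lt(max(abs(g$H)), 1e-10)
  expect_lt(max(abs(g$KG)), 1e-10)
})

test_that("sphere octant patch area beats the flat triangle area", {
  v <- rbind(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  f <- rbind(c(1, 2, 3))
  mesh <- suppressWarnings(surfaceMesh(v, f, normals = v))
  g <- faceGeometry(mesh, order = 5)
  flat <- sqrt(3) / 2
  octant <- pi / 2
  expect_lt(abs(g$area - octant), abs(flat - octant))
})

test_that("sphere faces recover H = 1/R and KG = 1/R^2, improving with refinement", {
  for (cs in list(list(m = sphere320, tolH = 0.02),
                  list(m = sphere2000, tolH = 0.004))) {
    g <- faceGeometry(cs$m)
    expect_equal(mean(g$H), 1 / 50, tolerance = cs$tolH)
    expect_equal(mean(g$KG), 1 / 2500, tolerance = 2.5 * cs$tolH)
    expect_true(all(g$H^2 >= g$KG - 1e-6))  # means, not pointwise values
  }
  eCoarse <- abs(mean(faceGeometry(sphere320)$H) - 0.02)
  eFine <- abs(mean(faceGeometry(sphere2000)$H) - 0.02)
  expect_lt(eFine, eCoarse)
})

test_that("cylinder faces give H = 1/(2r), KG = 0", {
  mesh <- cylinderStrip(r = 1, nseg = 96)
  g <- faceGeometry(mesh)
  expect_equal(mean(g$H), 0.5, tolerance = 0.005)
  expect_lt(max(abs(g$KG)), 5e-3)
  # developability improves with refinement
  gf <- faceGeometry(cylinderStrip(r = 1, nseg = 144))
  expect_lt(max(abs(gf$KG)), max(abs(g$KG)))
})

test_that("area and volume of a refined icosphere match the closed forms", {
  av <- totalAreaVolume(sphere2000)
  expect_equal(av[["area"]], 4 * pi * 2500, tolerance = 1e-4)
  expect_equal(av[["volume"]], 4 / 3 * pi * 125000, tolerance = 2e-4)
  # refinement convergence (monotone error decrease)
  errA <- sapply(list(sphere320, sphere500, sphere2000), function(m)
    abs(totalAreaVolume(m)[["area"]] - 4 * pi * 2500))
  expect_true(all(diff(errA) < 0))
})

test_that("inside-out orientation is rejected", {
  v <- sphere320@vertices / 50
  f <- sphere320@faces[, c(1, 3, 2)]
  expect_error(totalAreaVolume(surfaceMesh(v, f, normals = v)), "inside-out")
})

test_that("Gauss-Bonnet holds on closed genus-0 meshes", {
  # smooth, adequately resolved surfaces only: the fused-sphere union has a
  # sharp neck crease invisible to face-wise quadrature, and an 8-face
  # octahedron is far too coarse for pointwise curvature
  for (mesh in list(sphere500, sphere2000, prolateMesh(40, 60, 7))) {
    g <- faceGeometry(mesh)
    tol <- if (nFaces(mesh) >= 2000) 0.02 else 0.12
    expect_equal(sum(g$KG * g$area), 4 * pi, tolerance = tol)
  }
})

test_that("fused-sphere fixture matches its closed-form union geometry", {
  geo <- fusedSpheresGeometry(30, 0.15)
  mesh <- fusedSpheresMesh(30, 0.15, frequency = 10)
  av <- totalAreaVolume(mesh)
  expect_equal(av[["area"]], geo$area, tolerance = 0.01)
  expect_equal(av[["volume"]], geo$volume, tolerance = 0.01)
  # closed-form reduced volume tends to 1/sqrt(2) as the neck shrinks
  expect_equal(fusedSpheresGeometry(30, 0.01)$nu, 1 / sqrt(2), tolerance = 1e-4)
})

test_that("prolate fixture degenerates to a sphere when a = c", {
  m <- prolateMesh(50, 50, 5)
  expect_equal(reducedVolume(m), 1, tolerance = 1e-3)
  mp <- prolateMesh(40, 70, 5)
  expect_lt(reducedVolume(mp), 1)
})

test_that("icosphere targets a face area and reports the achieved one", {
  m <- icosphereMesh(50, targetFaceArea = 14.786)
  achieved <- attr(m, "achievedFaceArea")
  expect_lt(abs(achieved - 14.786) / 14.786, 0.1)
  expect_equal(achieved, 4 * pi * 2500 / nFaces(m))
})

test_that("analytic stomatocyte fixture is closed, invaginated and scalable", {
  m <- stomatocyteMesh(50, 20, 10, 5, targetArea = 4 * pi * 2500)
  expect_equal(eulerCharacteristic(m), 2)
  av <- totalAreaVolume(m)
  expect_equal(av[["area"]], 4 * pi * 2500, tolerance = 1e-9)
  expect_lt(reducedVolume(m), 1)
  g <- faceGeometry(m)
  # the bud interior carries negative mean and positive Gaussian curvature
  bud <- sum(g$area[g$H < -0.01 & g$KG > 0]) / sum(g$area)
  expect_gt(bud, 0.05)
  # and the neck carries saddle (negative Gaussian) curvature
  expect_gt(sum(g$KG < 0), 0)
})
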