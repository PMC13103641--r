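# Geodesic sphere meshes and analytic shape fixtures. Vertices lie exactly on
# the target surface and normals are the exact analytic normals, so geometry
# tests have a clean reference.

icosahedronBase <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
             c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
             c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
             c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
             c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
             c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  # enforce outward orientation
  for (k in seq_len(nrow(f))) {
    a <- v[f[k, 1], ]; b <- v[f[k, 2], ]; cc <- v[f[k, 3], ]
    cr <- c((b[2] - a[2]) * (cc[3] - a[3]) - (b[3] - a[3]) * (cc[2] - a[2]),
            (b[3] - a[3]) * (cc[1] - a[1]) - (b[1] - a[1]) * (cc[3] - a[3]),
            (b[1] - a[1]) * (cc[2] - a[2]) - (b[2] - a[2]) * (cc[1] - a[1]))
    if (sum(cr * (a + b + cc)) < 0) f[k, ] <- f[k, c(1, 3, 2)]
  }
  list(v = v, f = f)
}

# Class-I geodesic subdivision with frequency nu: each base face splits into
# nu^2 triangles (20 nu^2 faces, 10 nu^2 + 2 vertices). Shared edge points are
# generated once per undirected base edge, so the mesh is watertight by
# construction.
geodesicSphere <- function(frequency) {
  nu <- as.integer(frequency)
  stopifnot(nu >= 1)
  base <- icosahedronBase()
  verts <- base$v
  edgeKey <- function(a, b) paste(min(a, b), max(a, b))
  edgePts <- new.env(parent = emptyenv())
  getEdge <- function(a, b) {
    k <- edgeKey(a, b)
    ids <- get0(k, envir = edgePts)
    if (is.null(ids)) {
      lo <- min(a, b); hi <- max(a, b)
      ids <- integer(nu - 1)
      for (t in seq_len(nu - 1)) {
        p <- verts[lo, ] * (1 - t / nu) + verts[hi, ] * (t / nu)
        verts <<- rbind(verts, p)
        ids[t] <- nrow(verts)
      }
      assign(k, ids, envir = edgePts)
    }
    if (a <= b) ids else rev(ids)
  }
  faces <- matrix(0L, 0, 3)
  for (fb in seq_len(nrow(base$f))) {
    A <- base$f[fb, 1]; B <- base$f[fb, 2]; C <- base$f[fb, 3]
    eAB <- if (nu > 1) getEdge(A, B) else integer(0)
    eAC <- if (nu > 1) getEdge(A, C) else integer(0)
    eBC <- if (nu > 1) getEdge(B, C) else integer(0)
    vid <- matrix(NA_integer_, nu + 1, nu + 1)  # [i+1, j+1], i toward B, j toward C
    vid[1, 1] <- A; vid[nu + 1, 1] <- B; vid[1, nu + 1] <- C
    if (nu > 1) {
      for (t in seq_len(nu - 1)) {
        vid[t + 1, 1] <- eAB[t]
        vid[1, t + 1] <- eAC[t]
        vid[nu - t + 1, t + 1] <- eBC[t]
      }
      if (nu > 2) {
        for (i in 1:(nu - 2)) for (j in 1:(nu - 1 - i)) {
          p <- (verts[A, ] * (nu - i - j) + verts[B, ] * i + verts[C, ] * j) / nu
          verts <- rbind(verts, p)
          vid[i + 1, j + 1] <- nrow(verts)
        }
      }
    }
    for (i in 0:(nu - 1)) for (j in 0:(nu - 1 - i)) {
      faces <- rbind(faces, c(vid[i + 1, j + 1], vid[i + 2, j + 1], vid[i + 1, j + 2]))
      if (i + j <= nu - 2)
        faces <- rbind(faces,
                       c(vid[i + 2, j + 1], vid[i + 2, j + 2], vid[i + 1, j + 2]))
    }
  }
  verts <- verts / sqrt(rowSums(verts^2))
  list(v = verts, f = faces)
}

#' Icosphere fixture
#'
#' Geodesic sphere with \code{20 * frequency^2} faces, exact radial normals.
#' When \code{targetFaceArea} is given instead of a frequency, the frequency
#' whose mean face area is closest to the target is chosen and the achieved
#' face count is reported in an attribute; arbitrary face counts are not
#' reachable with class-I geodesic meshes, so the nearest \code{20 nu^2} is
#' used.
#'
#' @param radius sphere radius, nm
#' @param frequency geodesic frequency (faces = 20 frequency^2)
#' @param targetFaceArea desired mean face area, nm^2 (used when
#'   \code{frequency} is NULL)
#' @return a \linkS4class{SurfaceMesh} with attribute \code{achievedFaceArea}
#' @export
icosphereMesh <- function(radius = 50, frequency = NULL, targetFaceArea = NULL) {
  if (is.null(frequency)) {
    if (is.null(targetFaceArea)) stop("give frequency or targetFaceArea")
    frequency <- max(1L, as.integer(round(sqrt(4 * pi * radius^2 /
                                               (20 * targetFaceArea)))))
  }
  g <- geodesicSphere(frequency)
  m <- surfaceMesh(g$v * radius, g$f, normals = g$v)
  attr(m, "achievedFaceArea") <- 4 * pi * radius^2 / nrow(g$f)
  m
}

#' Prolate spheroid fixture
#'
#' Maps a geodesic sphere onto the spheroid \eqn{x^2/a^2 + y^2/a^2 + z^2/c^2
#' = 1} with exact ellipsoid normals; \code{a = c} degenerates to a sphere.
#'
#' @param a equatorial semi-axis (nm)
#' @param c polar semi-axis (nm), \code{c >= a} for a prolate shape
#' @param frequency geodesic frequency
#' @export
prolateMesh <- function(a, c, frequency = 5) {
  g <- geodesicSphere(frequency)
  v <- cbind(g$v[, 1] * a, g$v[, 2] * a, g$v[, 3] * c)
  n <- cbind(g$v[, 1] / a, g$v[, 2] / a, g$v[, 3] / c)
  n <- n / sqrt(rowSums(n^2))
  surfaceMesh(v, g$f, normals = n)
}

#' Fused two-sphere fixture
#'
#' Two equal spheres of the given radius whose centers sit at \eqn{\pm c} on
#' the z axis with \eqn{c = r\sqrt{1 - \rho^2}}, joined across the plane
#' z = 0 with a circular neck of radius \eqn{\rho r}. As the neck fraction
#' \eqn{\rho \to 0} the reduced volume approaches \eqn{1/\sqrt 2}, the value
#' for two tangent equal spheres. Vertices lie exactly on the union surface
#' and carry the exact sphere normals.
#'
#' @param radius sphere radius r (nm)
#' @param neck neck radius as a fraction of r (default 0.05)
#' @param frequency geodesic frequency of the underlying sphere mesh
#' @return a \linkS4class{SurfaceMesh}
#' @export
fusedSpheresMesh <- function(radius = 50, neck = 0.05, frequency = 8) {
  stopifnot(neck > 0, neck < 1)
  g <- geodesicSphere(frequency)
  cz <- radius * sqrt(1 - neck^2)
  alpha0 <- pi - acos(cz / radius)
  v <- matrix(0, nrow(g$v), 3)
  n <- matrix(0, nrow(g$v), 3)
  for (i in seq_len(nrow(g$v))) {
    p <- g$v[i, ]
    phi <- atan2(p[2], p[1])
    theta <- acos(max(-1, min(1, p[3])))
    up <- theta <= pi / 2
    th <- if (up) theta else pi - theta
    alpha <- th * alpha0 / (pi / 2)
    dir <- c(sin(alpha) * cos(phi), sin(alpha) * sin(phi),
             if (up) cos(alpha) else -cos(alpha))
    cen <- c(0, 0, if (up) cz else -cz)
    v[i, ] <- cen + radius * dir
    n[i, ] <- dir
  }
  surfaceMesh(v, g$f, normals = n)
}

#' Closed-form geometry of the fused two-sphere surface
#'
#' @param radius sphere radius r
#' @param neck neck radius fraction
#' @return list with area, volume and the reduced volume of the union
#' @export
fusedSpheresGeometry <- function(radius = 50, neck = 0.05) {
  r <- radius
  cz <- r * sqrt(1 - neck^2)
  h <- r - cz  # cap height removed on each sphere
  area <- 2 * (4 * pi * r^2 - 2 * pi * r * h)
  vol <- 2 * (4 / 3 * pi * r^3 - pi * h^2 * (3 * r - h) / 3)
  list(area = area, volume = vol,
       nu = reducedVolume(area, vol))
}

#' Analytic stomatocyte (invaginated sphere) fixture
#'
#' A surface of revolution: an outer sphere of the given radius carrying a
#' spherical inward bud of radius \code{budRadius}, connected through a
#' circular neck of radius \code{neckRadius} near the south pole. Vertices
#' and normals are exact on both spherical parts (the membrane's outward
#' side faces the bud lumen, which connects to the exterior through the
#' neck). When \code{targetArea} is given the mesh is scaled uniformly to
#' that total area, which leaves the reduced volume unchanged.
#'
#' @param radius outer sphere radius, nm
#' @param budRadius invagination radius, nm
#' @param neckRadius neck radius, nm (smaller than both)
#' @param frequency geodesic frequency of the underlying sphere mesh
#' @param targetArea optional total area to scale to, nm^2
#' @return a \linkS4class{SurfaceMesh}
#' @export
stomatocyteMesh <- function(radius = 50, budRadius = 20, neckRadius = 10,
                            frequency = 5, targetArea = NULL) {
  stopifnot(neckRadius < budRadius, neckRadius < radius)
  R <- radius; r <- budRadius; rn <- neckRadius
  zn <- -sqrt(R^2 - rn^2)
  thetaN <- acos(zn / R)
  zc <- zn + sqrt(r^2 - rn^2)
  alpha0 <- acos((zn - zc) / r)
  L1 <- R * thetaN
  L2 <- r * alpha0
  L <- L1 + L2
  g <- geodesicSphere(frequency)
  v <- matrix(0, nrow(g$v), 3); n <- matrix(0, nrow(g$v), 3)
  for (i in seq_len(nrow(g$v))) {
    p <- g$v[i, ]
    phi <- atan2(p[2], p[1])
    s <- acos(max(-1, min(1, p[3]))) / pi * L
    if (s <= L1) {
      th <- s / R
      dir <- c(sin(th) * cos(phi), sin(th) * sin(phi), cos(th))
      v[i, ] <- R * dir
      n[i, ] <- dir
    } else {
      al <- alpha0 - (s - L1) / r
      dir <- c(sin(al) * cos(phi), sin(al) * sin(phi), cos(al))
      v[i, ] <- c(0, 0, zc) + r * dir
      n[i, ] <- -dir           # outward side faces the bud lumen
    }
  }
  if (!is.null(targetArea)) {
    m0 <- surfaceMesh(v, g$f, normals = n)
    sc <- sqrt(targetArea / totalAreaVolume(m0)[["area"]])
    v <- v * sc
  }
  surfaceMesh(v, g$f, normals = n)
}
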