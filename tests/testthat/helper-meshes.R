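# Shared small meshes, built once per test run.
sphere320 <- icosphereMesh(50, frequency = 4)    # 320 faces
sphere500 <- icosphereMesh(50, frequency = 5)    # 500 faces
sphere2000 <- icosphereMesh(50, frequency = 10)  # 2000 faces

# A tiny closed mesh: regular octahedron (8 faces), outward normals
octahedron <- function(radius = 1) {
  v <- rbind(c(1, 0, 0), c(-1, 0, 0), c(0, 1, 0), c(0, -1, 0),
             c(0, 0, 1), c(0, 0, -1)) * radius
  f <- rbind(c(1, 3, 5), c(3, 2, 5), c(2, 4, 5), c(4, 1, 5),
             c(3, 1, 6), c(2, 3, 6), c(4, 2, 6), c(1, 4, 6))
  surfaceMesh(v, f, normals = v / radius)
}

# Open cylinder section mesh of radius r: strip around the z axis, used for
# principal-curvature checks (H = 1/(2r) pattern not used; we check via
# closed forms on faces). Kept open, so only faceGeometry applies.
cylinderStrip <- function(r = 1, nseg = 48, h = 0.2, nz = 3) {
  th <- seq(0, 2 * pi, length.out = nseg + 1)[-(nseg + 1)]
  zs <- seq(0, h, length.out = nz)
  v <- NULL; n <- NULL
  for (z in zs) {
    v <- rbind(v, cbind(r * cos(th), r * sin(th), z))
    n <- rbind(n, cbind(cos(th), sin(th), 0))
  }
  f <- NULL
  for (iz in seq_len(nz - 1)) for (k in seq_len(nseg)) {
    k2 <- k %% nseg + 1
    a <- (iz - 1) * nseg + k;  b <- (iz - 1) * nseg + k2
    c2 <- iz * nseg + k2;      d <- iz * nseg + k
    f <- rbind(f, c(a, b, c2), c(a, c2, d))
  }
  suppressWarnings(surfaceMesh(v, f, normals = n))
}

defaultComposition <- c(DOPE = 0.6, DOPS = 0.2, DOPC = 0.2)
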