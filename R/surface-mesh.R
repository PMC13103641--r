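#' @include AllGenerics.R
NULL

#' Curved triangulated surface
#'
#' A closed, oriented triangle mesh whose vertices carry positions and
#' \emph{independent} unit normal vectors. The normals are degrees of freedom
#' of the model, not derived quantities: together with the vertex positions
#' they define extended Nagata edge interpolants and hence curved triangular
#' patches on which mean and Gaussian curvature are evaluated from the full
#' shape operator.
#'
#' @slot vertices numeric matrix (n x 3), positions in nm.
#' @slot normals numeric matrix (n x 3), unit vertex normals.
#' @slot faces integer matrix (m x 3), 1-based vertex indices, consistently
#'   oriented (counter-clockwise seen from outside).
#' @slot edges integer matrix (e x 2), vertex pairs with the lower index first.
#' @slot edgeFaces integer matrix (e x 2), the one or two faces incident to
#'   each edge (0 marks a boundary slot).
#' @slot faceEdges integer matrix (m x 3), edge ids per face in the order
#'   (v1-v2, v2-v3, v3-v1).
#' @export
setClass("SurfaceMesh",
  representation(vertices = "matrix", normals = "matrix", faces = "matrix",
                 edges = "matrix", edgeFaces = "matrix", faceEdges = "matrix"))

setValidity("SurfaceMesh", function(object) {
  v <- object@vertices; n <- object@normals; f <- object@faces
  if (ncol(v) != 3 || ncol(n) != 3 || ncol(f) != 3)
    return("vertices, normals and faces must have 3 columns")
  if (nrow(n) != nrow(v)) return("one normal per vertex required")
  if (!all(is.finite(v))) return("non-finite vertex positions")
  nl <- sqrt(rowSums(n^2))
  if (any(abs(nl - 1) > 1e-6)) return("vertex normals must be unit length")
  if (any(f < 1) || any(f > nrow(v))) return("face indices out of range")
  if (any(f[, 1] == f[, 2] | f[, 2] == f[, 3] | f[, 1] == f[, 3]))
    return("degenerate face with repeated vertex")
  if (nrow(object@edges) > 0 && nrow(object@faceEdges) != nrow(f))
    return("faceEdges inconsistent with faces")
  TRUE
})

#' Construct a SurfaceMesh
#'
#' Builds edge topology from the triangle list and checks two-manifoldness.
#' When \code{normals} is \code{NULL} the vertex normals are initialized from
#' area-weighted incident face normals (with a warning), which is only a
#' starting guess: in a simulation they relax as independent degrees of
#' freedom.
#'
#' @param vertices n x 3 matrix of positions (nm).
#' @param faces m x 3 integer matrix of 1-based vertex triples.
#' @param normals optional n x 3 matrix of unit normals.
#' @return a \linkS4class{SurfaceMesh}
#' @export
surfaceMesh <- function(vertices, faces, normals = NULL) {
  vertices <- as.matrix(vertices)
  storage.mode(vertices) <- "double"
  faces <- as.matrix(faces)
  storage.mode(faces) <- "integer"
  top <- cppBuildTopology(faces, nrow(vertices))
  if (is.null(normals)) {
    warning("no vertex normals supplied; initializing from area-weighted face normals")
    normals <- matrix(0, nrow(vertices), 3)
    for (k in seq_len(nrow(faces))) {
      a <- vertices[faces[k, 1], ]; b <- vertices[faces[k, 2], ]
      c <- vertices[faces[k, 3], ]
      fn <- c((b[2] - a[2]) * (c[3] - a[3]) - (b[3] - a[3]) * (c[2] - a[2]),
              (b[3] - a[3]) * (c[1] - a[1]) - (b[1] - a[1]) * (c[3] - a[3]),
              (b[1] - a[1]) * (c[2] - a[2]) - (b[2] - a[2]) * (c[1] - a[1]))
      normals[faces[k, ], ] <- normals[faces[k, ], ] + rep(fn, each = 3)
    }
    normals <- normals / sqrt(rowSums(normals^2))
  }
  normals <- as.matrix(normals)
  storage.mode(normals) <- "double"
  new("SurfaceMesh", vertices = vertices, normals = normals, faces = faces,
      edges = top$EV, edgeFaces = top$EF, faceEdges = top$FE)
}

#' @describeIn surfaceMesh vertex positions
#' @param x a SurfaceMesh
#' @export
setMethod("meshVertices", "SurfaceMesh", function(x) x@vertices)

#' @export
setMethod("meshNormals", "SurfaceMesh", function(x) x@normals)

#' @export
setMethod("meshFaces", "SurfaceMesh", function(x) x@faces)

#' @export
setMethod("meshEdges", "SurfaceMesh", function(x) x@edges)

#' @export
setMethod("nVertices", "SurfaceMesh", function(x) nrow(x@vertices))

#' @export
setMethod("nFaces", "SurfaceMesh", function(x) nrow(x@faces))

#' @export
setMethod("nEdges", "SurfaceMesh", function(x) nrow(x@edges))

setMethod("show", "SurfaceMesh", function(object) {
  chi <- nVertices(object) - nEdges(object) + nFaces(object)
  cat("SurfaceMesh:", nVertices(object), "vertices,", nEdges(object), "edges,",
      nFaces(object), "faces (Euler characteristic", paste0(chi, ")\n"))
  if (isClosedMesh(object)) {
    av <- totalAreaVolume(object)
    cat(sprintf("  closed; area %.4g nm^2, volume %.4g nm^3, reduced volume %.4f\n",
                av["area"], av["volume"], reducedVolume(av["area"], av["volume"])))
  } else cat("  open (boundary edges present)\n")
})

#' Is every edge shared by exactly two faces?
#' @param mesh a SurfaceMesh
#' @export
isClosedMesh <- function(mesh) all(mesh@edgeFaces > 0)

#' Euler characteristic V - E + F
#' @param mesh a SurfaceMesh
#' @export
eulerCharacteristic <- function(mesh)
  nVertices(mesh) - nEdges(mesh) + nFaces(mesh)

#' Per-face geometry of the curved elements
#'
#' Assembles the extended Nagata patch on every face and integrates area,
#' mean curvature H (average of the principal curvatures, positive for a
#' sphere with outward normals), Gaussian curvature KG and the signed volume
#' contribution with a symmetric triangle quadrature. H and KG are reported
#' as area-weighted means over the quadrature points.
#'
#' @param x a \linkS4class{SurfaceMesh}
#' @param order quadrature order (1, 2, 3, 4 or 5+; default 4: the cheapest
#'   symmetric rule with all-positive weights, so integrated squared
#'   curvature is non-negative)
#' @param svdTol relative singular value cutoff of the pseudo-inverse used in
#'   the edge-interpolant construction
#' @return data.frame with columns area (nm^2), H (1/nm), KG (1/nm^2),
#'   volume (nm^3) and ok (degenerate-metric flag)
#' @export
setMethod("faceGeometry", "SurfaceMesh", function(x, order = 4, svdTol = 1e-8) {
  if (order < 1) stop("quadrature order must be >= 1")
  g <- cppMeshGeometry(x@vertices, x@normals, x@faces, x@edges, x@faceEdges,
                       as.integer(order), svdTol)
  as.data.frame(g)
})

#' Total area and enclosed volume
#'
#' Integrates the curved patches over a closed oriented mesh. The volume uses
#' the divergence theorem and is positive for outward orientation; an
#' inside-out mesh raises an error.
#'
#' @param x a \linkS4class{SurfaceMesh}
#' @param order quadrature order
#' @return named numeric vector c(area =, volume =)
#' @export
setMethod("totalAreaVolume", "SurfaceMesh", function(x, order = 4) {
  if (!isClosedMesh(x)) stop("mesh is not closed: area/volume undefined")
  g <- faceGeometry(x, order = order)
  vol <- sum(g$volume)
  if (vol <= 0) stop("non-positive enclosed volume: mesh orientation is inside-out")
  c(area = sum(g$area), volume = vol)
})

#' Reduced volume
#'
#' \eqn{\nu = 6\sqrt{\pi} V / A^{3/2}}; equals 1 for a sphere and
#' \eqn{1/\sqrt{2}} for two fused equal spheres.
#'
#' @param x total area (nm^2), or a SurfaceMesh
#' @param volume total volume (nm^3) when \code{x} is an area
#' @export
setMethod("reducedVolume", "ANY", function(x, volume = NULL, ...) {
  if (is(x, "SurfaceMesh")) {
    av <- totalAreaVolume(x, ...)
    return(6 * sqrt(pi) * av[["volume"]] / av[["area"]]^1.5)
  }
  6 * sqrt(pi) * volume / x^1.5
})
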