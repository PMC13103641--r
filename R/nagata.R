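#' Extended Nagata edge interpolant
#'
#' Builds the coefficients of the cubic edge curve
#' \deqn{\varphi(t) = x_A + (d - c_1 - c_2)\,t + c_1 t^2 + c_2 t^3, \quad
#'       d = x_B - x_A,}
#' whose endpoint tangents are orthogonal both to the vertex normals and to
#' the binormal estimates \eqn{d \times n}. The four orthogonality conditions
#' form an underdetermined linear system in \eqn{(c_1, c_2)} solved
#' minimum-norm through a Moore--Penrose pseudo-inverse, which keeps the
#' construction finite for normal configurations where the quadratic-only
#' interpolant breaks down (for instance normals nearly parallel to the
#' chord).
#'
#' @param xA,xB distinct endpoint positions (length-3 numerics, nm)
#' @param nA,nB unit endpoint normals
#' @param svdTol relative singular-value cutoff of the pseudo-inverse
#' @return list with 3-vectors \code{c1} (quadratic) and \code{c2} (cubic);
#'   both zero gives the straight chord
#' @examples
#' ec <- nagataCoefficients(c(0, 0, 0), c(1, 0, 0), c(0, 0, 1), c(0, 0, 1))
#' stopifnot(max(abs(c(ec$c1, ec$c2))) < 1e-12)  # planar chord stays straight
#' @export
nagataCoefficients <- function(xA, xB, nA, nB, svdTol = 1e-8) {
  xA <- as.numeric(xA); xB <- as.numeric(xB)
  if (sqrt(sum((xB - xA)^2)) < 1e-12) stop("degenerate edge: coincident endpoints")
  for (nn in list(nA, nB))
    if (abs(sqrt(sum(nn^2)) - 1) > 1e-6) stop("normals must be unit length")
  cppEdgeCoefficients(xA, xB, as.numeric(nA), as.numeric(nB), svdTol)
}

#' Evaluate an edge interpolant
#'
#' @param xA,xB endpoints
#' @param coef list with c1 and c2 as returned by [nagataCoefficients()]
#' @param t parameter values in \[0, 1\]
#' @return length(t) x 3 matrix of curve points
#' @export
evalEdgeInterpolant <- function(xA, xB, coef, t) {
  cppEdgeEval(as.numeric(xA), as.numeric(xB), as.numeric(coef$c1),
              as.numeric(coef$c2), as.numeric(t))
}

#' Evaluate a curved face patch
#'
#' The three edge interpolants of a face assemble into a cubic triangular
#' patch that restricts exactly to the edge curves on the boundary.
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param face face index
#' @param bary k x 3 matrix of barycentric coordinates (rows sum to 1;
#'   column order follows the face's vertex order)
#' @param svdTol pseudo-inverse cutoff
#' @return k x 3 matrix of surface points
#' @export
evalFacePatch <- function(mesh, face, bary, svdTol = 1e-8) {
  bary <- as.matrix(bary)
  if (any(abs(rowSums(bary) - 1) > 1e-9)) stop("barycentric rows must sum to 1")
  cppPatchEval(mesh@vertices, mesh@normals, mesh@faces, mesh@edges,
               mesh@faceEdges, as.integer(face), bary, svdTol)
}
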