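# Mesh input/output: OFF, PLY (ascii) and legacy VTK polydata (ascii).
# VTK and PLY carry vertex normals; VTK additionally carries per-face scalar
# fields as CELL_DATA, which is how compositions, curvatures and peptide
# occupancies travel alongside snapshots.

#' Read a triangle mesh
#'
#' @param path file path
#' @param format one of "off", "ply", "vtk"; guessed from the extension when
#'   missing
#' @return a \linkS4class{SurfaceMesh}; per-face fields found in the file are
#'   attached as attribute \code{faceFields} (a named list)
#' @export
readMesh <- function(path, format = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("off", "ply", "vtk"))
  switch(format,
         off = readOFF(path),
         ply = readPLY(path),
         vtk = readVTK(path))
}

#' Write a triangle mesh
#'
#' @param mesh a \linkS4class{SurfaceMesh}
#' @param path output path
#' @param format "off", "ply" or "vtk" (guessed from the extension when
#'   missing); OFF stores no normals
#' @param faceFields named list of per-face numeric vectors written as cell
#'   data (VTK only)
#' @export
writeMesh <- function(mesh, path, format = NULL, faceFields = NULL) {
  if (is.null(format))
    format <- tolower(tools::file_ext(path))
  format <- match.arg(format, c("off", "ply", "vtk"))
  switch(format,
         off = writeOFF(mesh, path),
         ply = writePLY(mesh, path),
         vtk = writeVTK(mesh, path, faceFields))
  invisible(path)
}

fmtNum <- function(x) sprintf("%.17g", x)

writeOFF <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("OFF", con)
  writeLines(paste(nVertices(mesh), nFaces(mesh), nEdges(mesh)), con)
  writeLines(apply(mesh@vertices, 1, function(r) paste(fmtNum(r), collapse = " ")), con)
  writeLines(apply(mesh@faces - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
}

readOFF <- function(path) {
  ln <- readLines(path)
  ln <- ln[!grepl("^\\s*#", ln) & nzchar(trimws(ln))]
  if (toupper(trimws(ln[1])) != "OFF") stop("not an OFF file")
  hdr <- scan(text = ln[2], quiet = TRUE)
  nv <- hdr[1]; nf <- hdr[2]
  v <- matrix(scan(text = ln[3:(2 + nv)], quiet = TRUE), nv, 3, byrow = TRUE)
  fr <- lapply(ln[(3 + nv):(2 + nv + nf)], function(s) scan(text = s, quiet = TRUE))
  if (any(vapply(fr, function(r) r[1], 0) != 3)) stop("non-triangular faces")
  f <- do.call(rbind, lapply(fr, function(r) r[2:4] + 1))
  surfaceMesh(v, f)
}

writePLY <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nVertices(mesh)),
               "property double x", "property double y", "property double z",
               "property double nx", "property double ny", "property double nz",
               paste("element face", nFaces(mesh)),
               "property list uchar int vertex_indices", "end_header"), con)
  vn <- cbind(mesh@vertices, mesh@normals)
  writeLines(apply(vn, 1, function(r) paste(fmtNum(r), collapse = " ")), con)
  writeLines(apply(mesh@faces - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
}

readPLY <- function(path) {
  ln <- readLines(path)
  endh <- which(trimws(ln) == "end_header")[1]
  if (is.na(endh)) stop("not an ascii PLY file")
  hdr <- ln[1:endh]
  if (!any(grepl("format ascii", hdr))) stop("only ascii PLY supported")
  nv <- as.integer(sub(".*element vertex\\s+", "", grep("element vertex", hdr, value = TRUE)[1]))
  nf <- as.integer(sub(".*element face\\s+", "", grep("element face", hdr, value = TRUE)[1]))
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property (float|double)", trimws(hdr), value = TRUE))
  vl <- ln[(endh + 1):(endh + nv)]
  vm <- matrix(scan(text = vl, quiet = TRUE), nv, length(props), byrow = TRUE)
  colnames(vm) <- props
  fl <- ln[(endh + nv + 1):(endh + nv + nf)]
  fr <- lapply(fl, function(s) scan(text = s, quiet = TRUE))
  if (any(vapply(fr, function(r) r[1], 0) != 3)) stop("non-triangular faces")
  f <- do.call(rbind, lapply(fr, function(r) r[2:4] + 1))
  v <- vm[, c("x", "y", "z")]
  if (all(c("nx", "ny", "nz") %in% props)) {
    n <- vm[, c("nx", "ny", "nz")]
    surfaceMesh(v, f, normals = n / sqrt(rowSums(n^2)))
  } else {
    surfaceMesh(v, f)
  }
}

writeVTK <- function(mesh, path, faceFields = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0", "vesiform surface mesh", "ASCII",
               "DATASET POLYDATA",
               paste("POINTS", nVertices(mesh), "double")), con)
  writeLines(apply(mesh@vertices, 1, function(r) paste(fmtNum(r), collapse = " ")), con)
  writeLines(paste("POLYGONS", nFaces(mesh), 4 * nFaces(mesh)), con)
  writeLines(apply(mesh@faces - 1L, 1, function(r) paste(c(3, r), collapse = " ")), con)
  writeLines(paste("POINT_DATA", nVertices(mesh)), con)
  writeLines("NORMALS normals double", con)
  writeLines(apply(mesh@normals, 1, function(r) paste(fmtNum(r), collapse = " ")), con)
  if (!is.null(faceFields) && length(faceFields)) {
    writeLines(paste("CELL_DATA", nFaces(mesh)), con)
    for (nm in names(faceFields)) {
      writeLines(paste("SCALARS", nm, "double 1"), con)
      writeLines("LOOKUP_TABLE default", con)
      writeLines(fmtNum(as.numeric(faceFields[[nm]])), con)
    }
  }
}

readVTK <- function(path) {
  ln <- readLines(path)
  ip <- grep("^POINTS", ln)[1]
  nv <- as.integer(strsplit(trimws(ln[ip]), "\\s+")[[1]][2])
  pts <- scan(text = ln[(ip + 1):length(ln)], n = 3 * nv, quiet = TRUE)
  v <- matrix(pts, nv, 3, byrow = TRUE)
  ig <- grep("^POLYGONS", ln)[1]
  nf <- as.integer(strsplit(trimws(ln[ig]), "\\s+")[[1]][2])
  pol <- scan(text = ln[(ig + 1):length(ln)], n = 4 * nf, quiet = TRUE)
  pm <- matrix(pol, nf, 4, byrow = TRUE)
  if (any(pm[, 1] != 3)) stop("non-triangular faces")
  f <- pm[, 2:4] + 1
  inorm <- grep("^NORMALS", ln)
  n <- NULL
  if (length(inorm)) {
    nvals <- scan(text = ln[(inorm[1] + 1):length(ln)], n = 3 * nv, quiet = TRUE)
    n <- matrix(nvals, nv, 3, byrow = TRUE)
    n <- n / sqrt(rowSums(n^2))
  }
  mesh <- if (is.null(n)) surfaceMesh(v, f) else surfaceMesh(v, f, normals = n)
  icd <- grep("^CELL_DATA", ln)
  if (length(icd)) {
    fields <- list()
    isc <- grep("^SCALARS", ln)
    isc <- isc[isc > icd[1]]
    for (k in isc) {
      nm <- strsplit(trimws(ln[k]), "\\s+")[[1]][2]
      vals <- scan(text = ln[(k + 2):length(ln)], n = nf, quiet = TRUE)
      fields[[nm]] <- vals
    }
    attr(mesh, "faceFields") <- fields
  }
  mesh
}
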