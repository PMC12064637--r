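#' Read a surface mesh from STL or PLY
#'
#' Binary and ASCII STL and ASCII PLY are supported; the format is detected
#' from the extension and file content. STL facets are welded into a shared
#' vertex table by exact coordinate match before the watertightness check.
#'
#' @param path file path (`.stl` or `.ply`).
#' @param check if `TRUE` (default) error on a non-watertight mesh, naming
#'   the open-edge count.
#' @return a [triangle_mesh()], orientation-normalized.
#' @export
read_mesh <- function(path, check = TRUE) {
  if (!file.exists(path)) stop("file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  m <- switch(ext,
    stl = read_stl(path),
    ply = read_ply(path),
    stop("unsupported mesh format: .", ext, " (use STL or PLY)"))
  if (check) {
    rep <- watertight_report(m)
    if (!rep$watertight)
      stop(sprintf("mesh in '%s' is not watertight: %d open edge(s)",
                   path, rep$n_open_edges))
  }
  normalize_orientation(m)
}

#' Write a surface mesh to STL or PLY
#'
#' @param mesh a [triangle_mesh()].
#' @param path destination (`.stl` or `.ply`).
#' @param binary for STL, write the binary (float32) layout; ASCII otherwise.
#' @return `path`, invisibly.
#' @export
write_mesh <- function(mesh, path, binary = TRUE) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    stl = write_stl(mesh, path, binary = binary),
    ply = write_ply(mesh, path),
    stop("unsupported mesh format: .", ext, " (use STL or PLY)"))
  invisible(path)
}

read_stl <- function(path) {
  con <- file(path, "rb")
  header <- readBin(con, "raw", 80L)
  ntri <- readBin(con, "integer", 1L, size = 4L, endian = "little")
  sz <- file.size(path)
  close(con)
  is_binary <- length(ntri) == 1L && !is.na(ntri) && sz == 84 + 50 * as.numeric(ntri)
  first <- readLines(path, n = 1L, warn = FALSE)
  if (!is_binary && !grepl("^\\s*solid", first))
    stop("file is neither valid binary nor ASCII STL: ", path)
  tri <- if (is_binary) read_stl_binary(path, ntri) else read_stl_ascii(path)
  weld_triangles(tri)
}

read_stl_binary <- function(path, ntri) {
  con <- file(path, "rb")
  on.exit(close(con))
  readBin(con, "raw", 84L)
  rec <- readBin(con, "raw", 50L * ntri)
  idx <- rep(seq_len(ntri) - 1L, each = 36L) * 50L +
    rep(12L + seq_len(36L), ntri) # skip the 12 normal bytes, take 9 floats
  vals <- readBin(rec[idx], "double", n = 9L * ntri, size = 4L, endian = "little")
  matrix(vals, ncol = 3L, byrow = TRUE)  # 3*ntri rows of xyz
}

read_stl_ascii <- function(path) {
  lines <- readLines(path, warn = FALSE)
  vlines <- grep("^\\s*vertex\\s", lines, value = TRUE)
  if (length(vlines) %% 3L != 0L) stop("malformed ASCII STL: ", path)
  toks <- strsplit(trimws(vlines), "\\s+")
  vals <- vapply(toks, function(t) as.numeric(t[2:4]), numeric(3))
  t(vals)
}

# 3*ntri x 3 coordinate rows (triangle-soup) -> welded triangle_mesh
weld_triangles <- function(coords) {
  ntri <- nrow(coords) / 3L
  key <- paste(coords[, 1], coords[, 2], coords[, 3], sep = ",")
  verts <- coords[!duplicated(key), , drop = FALSE]
  faces <- matrix(match(key, unique(key)), ncol = 3L, byrow = TRUE)
  # float32 quantization can collapse nearly-coincident vertices; the
  # resulting zero-area faces (repeated index) are dropped, which keeps
  # the edge pairing of a closed surface intact
  degen <- faces[, 1] == faces[, 2] | faces[, 2] == faces[, 3] |
    faces[, 1] == faces[, 3]
  triangle_mesh(verts, faces[!degen, , drop = FALSE])
}

write_stl <- function(mesh, path, binary = TRUE) {
  a <- face_corner(mesh, 1); b <- face_corner(mesh, 2); c <- face_corner(mesh, 3)
  e1 <- b - a; e2 <- c - a
  n <- cbind(e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
             e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
             e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1])
  l <- sqrt(rowSums(n^2)); l[l < 1e-300] <- 1
  n <- n / l
  nf <- nrow(mesh$faces)
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeBin(raw(80L), con)
    writeBin(as.integer(nf), con, size = 4L, endian = "little")
    dat <- t(cbind(n, a, b, c))  # 12 floats per facet, column-per-facet
    for (i in seq_len(nf)) {
      writeBin(dat[, i], con, size = 4L, endian = "little")
      writeBin(raw(2L), con)
    }
  } else {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines("solid mesh", con)
    for (i in seq_len(nf)) {
      writeLines(sprintf("  facet normal %.9g %.9g %.9g", n[i, 1], n[i, 2], n[i, 3]), con)
      writeLines("    outer loop", con)
      writeLines(sprintf("      vertex %.17g %.17g %.17g",
                         c(a[i, 1], b[i, 1], c[i, 1]),
                         c(a[i, 2], b[i, 2], c[i, 2]),
                         c(a[i, 3], b[i, 3], c[i, 3])), con)
      writeLines("    endloop", con)
      writeLines("  endfacet", con)
    }
    writeLines("endsolid mesh", con)
  }
  invisible(path)
}

read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!identical(trimws(lines[1]), "ply")) stop("not a PLY file: ", path)
  if (!any(grepl("format ascii", lines[1:10])))
    stop("only ASCII PLY is supported: ", path)
  endh <- which(trimws(lines) == "end_header")[1]
  nvert <- as.integer(sub(".*element vertex\\s+", "",
                          grep("element vertex", lines[1:endh], value = TRUE)[1]))
  nface <- as.integer(sub(".*element face\\s+", "",
                          grep("element face", lines[1:endh], value = TRUE)[1]))
  vt <- lines[endh + seq_len(nvert)]
  vm <- do.call(rbind, lapply(strsplit(trimws(vt), "\\s+"),
                              function(t) as.numeric(t[1:3])))
  ft <- lines[endh + nvert + seq_len(nface)]
  fm <- do.call(rbind, lapply(strsplit(trimws(ft), "\\s+"), function(t) {
    k <- as.integer(t[1])
    if (k != 3L) stop("only triangle faces are supported in PLY")
    as.integer(t[2:4]) + 1L
  }))
  triangle_mesh(vm, fm)
}

write_ply <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               sprintf("element vertex %d", nrow(mesh$vertices)),
               "property double x", "property double y", "property double z",
               sprintf("element face %d", nrow(mesh$faces)),
               "property list uchar int vertex_indices", "end_header"), con)
  writeLines(sprintf("%.17g %.17g %.17g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("3 %d %d %d", mesh$faces[, 1] - 1L,
                     mesh$faces[, 2] - 1L, mesh$faces[, 3] - 1L), con)
  invisible(path)
}

#' Read / write a surgical case description file
#'
#' A case file is a JSON document naming the two mesh files (relative paths
#' are resolved against the case file's directory) plus the access
#' direction, plane count and safety margin.
#'
#' @param path JSON case file with fields `bone`, `tumor`, `access` (3-vector),
#'   `n_planes`, `margin_mm`.
#' @return [read_case_file()]: a canonicalized [canonicalize_case()] object.
#' @export
read_case_file <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = TRUE)
  for (f in c("bone", "tumor", "access", "n_planes"))
    if (is.null(doc[[f]])) stop("case file missing field: ", f)
  dir <- dirname(normalizePath(path))
  resolve <- function(p) if (file.exists(p)) p else file.path(dir, p)
  bone <- read_mesh(resolve(doc$bone))
  tumor <- read_mesh(resolve(doc$tumor))
  canonicalize_case(bone, tumor, as.numeric(doc$access),
                    n_planes = doc$n_planes,
                    margin_mm = if (is.null(doc$margin_mm)) 0 else doc$margin_mm)
}

#' @rdname read_case_file
#' @param bone_path,tumor_path mesh file names to record.
#' @param access,n_planes,margin_mm case parameters to record.
#' @export
write_case_file <- function(path, bone_path, tumor_path, access, n_planes,
                            margin_mm = 0) {
  jsonlite::write_json(list(bone = bone_path, tumor = tumor_path,
                            access = as.numeric(access),
                            n_planes = as.integer(n_planes),
                            margin_mm = as.numeric(margin_mm)),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
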