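#' Triangulated surface mesh
#'
#' A minimal closed-triangle-mesh container: an `n x 3` vertex matrix (mm)
#' and an `m x 3` face index matrix (1-based, outward-oriented).
#'
#' @param vertices numeric matrix, one vertex per row.
#' @param faces integer matrix, one triangle per row.
#' @return object of class `surface_mesh`.
#' @export
surface_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices)
  faces <- as.matrix(faces)
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            max(faces) <= nrow(vertices), min(faces) >= 1)
  storage.mode(faces) <- "integer"
  structure(list(vertices = vertices, faces = faces), class = "surface_mesh")
}

#' @export
print.surface_mesh <- function(x, ...) {
  cat("surface_mesh:", nrow(x$vertices), "vertices,",
      nrow(x$faces), "faces\n")
  invisible(x)
}

#' Subdivided icosahedron sphere mesh
#'
#' Generates a unit icosphere by recursive edge-midpoint subdivision of an
#' icosahedron with vertices re-projected to the unit sphere, then scales by
#' (possibly anisotropic) semi-axes and translates. Subdivision level `k`
#' yields `20 * 4^k` faces.
#'
#' @param subdiv subdivision level (0 = icosahedron).
#' @param radius scalar radius or length-3 semi-axes (mm).
#' @param center mesh center (length 3, mm).
#' @return a [surface_mesh()].
#' @examples
#' icosphere(3, radius = 15)                    # sphere, 1280 faces
#' icosphere(3, radius = c(20, 20, 40))         # prolate ellipsoid
#' @export
icosphere <- function(subdiv = 3, radius = 1, center = c(0, 0, 0)) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c(phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    edge_mid <- new.env(parent = emptyenv())
    nv <- nrow(v)
    vlist <- vector("list", nrow(f) * 3)
    midpoint <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      idx <- edge_mid[[key]]
      if (is.null(idx)) {
        m <- (v[i, ] + v[j, ]) / 2
        m <- m / sqrt(sum(m^2))
        nv <<- nv + 1
        vlist[[nv - nrow(v)]] <<- m
        idx <- nv
        edge_mid[[key]] <- idx
      }
      idx
    }
    newf <- matrix(0L, nrow(f) * 4, 3)
    for (k in seq_len(nrow(f))) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- midpoint(a, b); bc <- midpoint(b, cc); ca <- midpoint(cc, a)
      newf[(k - 1) * 4 + 1:4, ] <- rbind(c(a, ab, ca), c(b, bc, ab),
                                         c(cc, ca, bc), c(ab, bc, ca))
    }
    v <- rbind(v, do.call(rbind, vlist[seq_len(nv - nrow(v))]))
    f <- newf
  }
  if (length(radius) == 1) radius <- rep(radius, 3)
  v <- sweep(v, 2, radius, `*`)
  v <- sweep(v, 2, center, `+`)
  surface_mesh(v, f)
}

#' Enclosed volume of a closed mesh
#'
#' Signed-tetrahedron (divergence theorem) volume; positive for
#' outward-oriented faces.
#'
#' @param mesh a [surface_mesh()].
#' @return volume in ml (vertices in mm).
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE]
  c_ <- v[f[, 3], , drop = FALSE]
  vol <- sum(a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) +
               a[, 2] * (b[, 3] * c_[, 1] - b[, 1] * c_[, 3]) +
               a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])) / 6
  vol / 1000
}

#' Rigid transform of a mesh
#'
#' @param mesh a [surface_mesh()].
#' @param rotation 3x3 rotation matrix.
#' @param translation length-3 vector (mm).
#' @return transformed [surface_mesh()].
#' @export
transform_mesh <- function(mesh, rotation = diag(3),
                           translation = c(0, 0, 0)) {
  v <- mesh$vertices %*% t(rotation)
  v <- sweep(v, 2, translation, `+`)
  surface_mesh(v, mesh$faces)
}

#' ASCII PLY export / import
#'
#' Writes and reads triangle meshes in ASCII PLY, the exchange format used
#' for the emitted endo/epicardial surface series.
#'
#' @param mesh a [surface_mesh()].
#' @param path file path.
#' @return `read_ply` returns a [surface_mesh()]; `write_ply` its path,
#'   invisibly.
#' @export
write_ply <- function(mesh, path) {
  v <- mesh$vertices; f <- mesh$faces
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("ply", "format ascii 1.0",
               paste("element vertex", nrow(v)),
               "property float x", "property float y", "property float z",
               paste("element face", nrow(f)),
               "property list uchar int vertex_indices", "end_header"), con)
  utils::write.table(format(v, trim = TRUE, digits = 9), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  utils::write.table(cbind(3L, f - 1L), con, row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_ply
#' @export
read_ply <- function(path) {
  lines <- readLines(path)
  hdr_end <- match("end_header", lines)
  if (is.na(hdr_end)) stop("not an ASCII PLY file: ", path)
  nv <- as.integer(sub("element vertex ", "",
                       grep("^element vertex", lines, value = TRUE)[1]))
  nf <- as.integer(sub("element face ", "",
                       grep("^element face", lines, value = TRUE)[1]))
  vtx <- utils::read.table(text = lines[hdr_end + seq_len(nv)])
  fc <- utils::read.table(text = lines[hdr_end + nv + seq_len(nf)])
  if (any(fc[, 1] != 3)) stop("only triangle faces are supported")
  surface_mesh(as.matrix(vtx[, 1:3]), as.matrix(fc[, 2:4]) + 1L)
}

#' Endo/epicardial surface pair
#'
#' Two closed meshes (endocardium inside epicardium) with a time label.
#'
#' @param endo,epi [surface_mesh()] objects.
#' @param label time stamp (ms) or other identifier.
#' @return object of class `surface_pair`.
#' @export
surface_pair <- function(endo, epi, label = NA_real_) {
  stopifnot(inherits(endo, "surface_mesh"), inherits(epi, "surface_mesh"))
  structure(list(endo = endo, epi = epi, label = label),
            class = "surface_pair")
}
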