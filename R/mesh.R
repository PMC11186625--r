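# Triangular surface meshes: minimal readers/writers for the common ASCII
# interchange formats, simple constructors used in tests, a watertightness
# check with small-hole filling, and voxelization by parity ray casting.
# No mesh library ships with the R stack here, so the needed primitives
# are implemented directly.

#' Triangular mesh
#'
#' @param vertices numeric `n x 3` matrix of vertex coordinates (mm).
#' @param faces integer `m x 3` matrix of 1-based vertex indices.
#' @return object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces) {
  vertices <- as.matrix(vertices); storage.mode(vertices) <- "double"
  faces <- as.matrix(faces); storage.mode(faces) <- "integer"
  stopifnot(ncol(vertices) == 3, ncol(faces) == 3,
            min(faces) >= 1, max(faces) <= nrow(vertices))
  structure(list(vertices = vertices, faces = faces), class = "tri_mesh")
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("<tri_mesh> %d vertices, %d faces\n",
              nrow(x$vertices), nrow(x$faces)))
  invisible(x)
}

#' Read a triangular mesh (OBJ, ASCII PLY or ASCII STL)
#'
#' @param path file path; the format is inferred from the extension.
#' @return a [tri_mesh()].
#' @export
read_mesh <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext,
         obj = read_obj(path),
         ply = read_ply(path),
         stl = read_stl_ascii(path),
         stop("unsupported mesh format: ", ext))
}

read_obj <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vs <- ln[startsWith(ln, "v ")]
  fs <- ln[startsWith(ln, "f ")]
  v <- do.call(rbind, lapply(strsplit(trimws(sub("^v", "", vs)), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(sub("^f", "", fs)), "\\s+"),
                             function(p) as.integer(sub("/.*", "", p[1:3]))))
  tri_mesh(v, f)
}

read_ply <- function(path) {
  ln <- readLines(path, warn = FALSE)
  if (!grepl("ascii", ln[2])) stop("only ASCII PLY is supported")
  nv <- as.integer(sub(".*vertex ", "", grep("element vertex", ln, value = TRUE)[1]))
  nf <- as.integer(sub(".*face ", "", grep("element face", ln, value = TRUE)[1]))
  hdr <- which(ln == "end_header")
  v <- do.call(rbind, lapply(strsplit(trimws(ln[hdr + seq_len(nv)]), "\\s+"),
                             function(p) as.numeric(p[1:3])))
  f <- do.call(rbind, lapply(strsplit(trimws(ln[hdr + nv + seq_len(nf)]), "\\s+"),
                             function(p) as.integer(p[2:4]) + 1L))
  tri_mesh(v, f)
}

read_stl_ascii <- function(path) {
  ln <- readLines(path, warn = FALSE)
  vx <- grep("^\\s*vertex", ln, value = TRUE)
  coords <- do.call(rbind, lapply(strsplit(trimws(vx), "\\s+"),
                                  function(p) as.numeric(p[2:4])))
  # merge duplicate vertices so edges can be matched
  key <- apply(round(coords, 9), 1, paste, collapse = ",")
  uid <- match(key, unique(key))
  v <- coords[!duplicated(key), , drop = FALSE]
  f <- matrix(uid, ncol = 3, byrow = TRUE)
  tri_mesh(v, f)
}

#' Write a mesh as OBJ
#' @param mesh a [tri_mesh()].
#' @param path output file.
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
}

#' Axis-aligned box mesh
#' @param side side length(s) in mm (scalar or length 3).
#' @param center centre coordinates (mm).
#' @export
cube_mesh <- function(side = 20, center = c(0, 0, 0)) {
  if (length(side) == 1) side <- rep(side, 3)
  h <- side / 2
  v <- as.matrix(expand.grid(c(-h[1], h[1]), c(-h[2], h[2]), c(-h[3], h[3])))
  v <- sweep(v, 2, center, `+`)
  f <- rbind(c(1,3,2), c(2,3,4), c(5,6,7), c(6,8,7),
             c(1,2,5), c(2,6,5), c(3,7,4), c(4,7,8),
             c(1,5,3), c(3,5,7), c(2,4,6), c(4,8,6))
  tri_mesh(v, f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere.
#' @param radius sphere radius (mm).
#' @param subdivisions number of 4-to-1 triangle subdivisions.
#' @param center centre coordinates (mm).
#' @export
icosphere <- function(radius = 10, subdivisions = 3, center = c(0, 0, 0)) {
  t <- (1 + sqrt(5)) / 2
  v <- rbind(c(-1,t,0), c(1,t,0), c(-1,-t,0), c(1,-t,0),
             c(0,-1,t), c(0,1,t), c(0,-1,-t), c(0,1,-t),
             c(t,0,-1), c(t,0,1), c(-t,0,-1), c(-t,0,1))
  f <- rbind(c(1,12,6), c(1,6,2), c(1,2,8), c(1,8,11), c(1,11,12),
             c(2,6,10), c(6,12,5), c(12,11,3), c(11,8,7), c(8,2,9),
             c(4,10,5), c(4,5,3), c(4,3,7), c(4,7,9), c(4,9,10),
             c(5,10,6), c(3,5,12), c(7,3,11), c(9,7,8), c(10,9,2))
  for (s in seq_len(subdivisions)) {
    nv <- nrow(v); nf <- nrow(f)
    edge_id <- new.env(parent = emptyenv())
    mid <- function(i, j) {
      key <- paste(min(i, j), max(i, j))
      id <- edge_id[[key]]
      if (!is.null(id)) return(id)
      v <<- rbind(v, (v[i, ] + v[j, ]) / 2)
      edge_id[[key]] <- nrow(v)
      nrow(v)
    }
    newf <- matrix(0L, 4 * nf, 3)
    for (k in seq_len(nf)) {
      a <- f[k, 1]; b <- f[k, 2]; cc <- f[k, 3]
      ab <- mid(a, b); bc <- mid(b, cc); ca <- mid(cc, a)
      newf[4 * k - 3, ] <- c(a, ab, ca)
      newf[4 * k - 2, ] <- c(b, bc, ab)
      newf[4 * k - 1, ] <- c(cc, ca, bc)
      newf[4 * k, ]     <- c(ab, bc, ca)
    }
    f <- newf
  }
  v <- v / sqrt(rowSums(v^2)) * radius
  v <- sweep(v, 2, center, `+`)
  tri_mesh(v, f)
}

# Edge usage table: each undirected edge of a watertight mesh appears in
# exactly two faces.
edge_counts <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Is a mesh watertight?
#' @param mesh a [tri_mesh()].
#' @return logical.
#' @export
is_watertight <- function(mesh) all(edge_counts(mesh) == 2)

#' Rasterize a closed surface mesh into a binary reference volume
#'
#' A voxel is foreground iff its centre lies inside the closed surface,
#' determined by parity counting of ray-triangle intersections along the
#' z axis. Meshes with small boundary holes are closed by fan
#' triangulation first; larger openings are an error.
#'
#' @param mesh a [tri_mesh()] in mm.
#' @param voxel_size isotropic voxel size (mm).
#' @param max_hole_edges boundary loops with at most this many edges are
#'   fan-filled before rasterization.
#' @param margin voxels of empty padding around the mesh bounding box.
#' @return a [reference_volume()] of kind `surface_mask`; the mm offset of
#'   the volume centre in mesh coordinates is stored in `$origin`.
#' @export
rasterize_surface <- function(mesh, voxel_size = 1, max_hole_edges = 8L,
                              margin = 2L) {
  if (!is_watertight(mesh)) {
    mesh <- fill_holes(mesh, max_hole_edges)
    if (!is_watertight(mesh))
      stop("OpenMeshError: mesh is not watertight and holes are too large to fill")
  }
  v <- mesh$vertices; f <- mesh$faces
  lo <- apply(v, 2, min) - margin * voxel_size
  hi <- apply(v, 2, max) + margin * voxel_size
  nx <- ceiling((hi[1] - lo[1]) / voxel_size)
  ny <- ceiling((hi[2] - lo[2]) / voxel_size)
  nz <- ceiling((hi[3] - lo[3]) / voxel_size)
  # voxel-centre coordinates; tiny irrational-ish offset keeps ray origins
  # off triangle edges (robust parity counting)
  eps <- voxel_size * 1.18e-5
  xs <- lo[1] + (seq_len(nx) - 0.5) * voxel_size + eps
  ys <- lo[2] + (seq_len(ny) - 0.5) * voxel_size + 2.7 * eps
  zs <- lo[3] + (seq_len(nz) - 0.5) * voxel_size

  # per (x, y) column, collect z of every ray-triangle intersection
  hits <- vector("list", nx * ny)
  for (k in seq_len(nrow(f))) {
    p1 <- v[f[k, 1], ]; p2 <- v[f[k, 2], ]; p3 <- v[f[k, 3], ]
    xr <- range(p1[1], p2[1], p3[1]); yr <- range(p1[2], p2[2], p3[2])
    ix <- which(xs >= xr[1] - voxel_size & xs <= xr[2] + voxel_size)
    iy <- which(ys >= yr[1] - voxel_size & ys <= yr[2] + voxel_size)
    if (!length(ix) || !length(iy)) next
    gx <- rep(xs[ix], times = length(iy))
    gy <- rep(ys[iy], each = length(ix))
    # barycentric test in the xy plane
    d <- (p2[2] - p3[2]) * (p1[1] - p3[1]) + (p3[1] - p2[1]) * (p1[2] - p3[2])
    if (abs(d) < 1e-14) next  # triangle vertical in z: never crossed transversally
    l1 <- ((p2[2] - p3[2]) * (gx - p3[1]) + (p3[1] - p2[1]) * (gy - p3[2])) / d
    l2 <- ((p3[2] - p1[2]) * (gx - p3[1]) + (p1[1] - p3[1]) * (gy - p3[2])) / d
    l3 <- 1 - l1 - l2
    inside <- l1 >= 0 & l2 >= 0 & l3 >= 0
    if (!any(inside)) next
    zhit <- l1[inside] * p1[3] + l2[inside] * p2[3] + l3[inside] * p3[3]
    cols <- (rep(iy, each = length(ix))[inside] - 1L) * nx +
      rep(ix, times = length(iy))[inside]
    for (i in seq_along(cols)) {
      cc <- cols[i]
      hits[[cc]] <- c(hits[[cc]], zhit[i])
    }
  }

  vol <- array(0, c(ny, nx, nz))
  for (cc in which(lengths(hits) > 0)) {
    zh <- sort(hits[[cc]])
    if (length(zh) %% 2 != 0) next  # grazing hit; skip ill-posed column
    ix <- (cc - 1L) %% nx + 1L
    iy <- (cc - 1L) %/% nx + 1L
    for (j in seq(1, length(zh), by = 2)) {
      sel <- zs > zh[j] & zs < zh[j + 1]
      vol[iy, ix, sel] <- 1
    }
  }
  centre_mm <- c((lo[1] + nx * voxel_size / 2 + voxel_size * 0),
                 (lo[2] + ny * voxel_size / 2),
                 (lo[3] + nz * voxel_size / 2))
  reference_volume(vol, voxel_size, "surface_mask", origin = centre_mm)
}

# Fan-fill boundary loops with at most max_edges edges.
fill_holes <- function(mesh, max_edges = 8L) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  cnt <- table(key)
  bkeys <- names(cnt)[cnt == 1]
  if (!length(bkeys)) return(mesh)
  bedges <- e[key %in% bkeys, , drop = FALSE]
  # chain boundary edges into loops
  remaining <- seq_len(nrow(bedges))
  loops <- list()
  while (length(remaining)) {
    i <- remaining[1]; remaining <- remaining[-1]
    loop <- bedges[i, ]
    repeat {
      nxt <- NULL
      for (j in remaining) {
        if (bedges[j, 1] == loop[length(loop)]) { nxt <- j; add <- bedges[j, 2]; break }
        if (bedges[j, 2] == loop[length(loop)]) { nxt <- j; add <- bedges[j, 1]; break }
      }
      if (is.null(nxt)) break
      remaining <- setdiff(remaining, nxt)
      if (add == loop[1]) break
      loop <- c(loop, add)
    }
    loops[[length(loops) + 1]] <- loop
  }
  newf <- f
  for (loop in loops) {
    if (length(loop) > max_edges) next
    for (k in 2:(length(loop) - 1))
      newf <- rbind(newf, c(loop[1], loop[k], loop[k + 1]))
  }
  m2 <- tri_mesh(mesh$vertices, newf)
  # orientation of the fan may be flipped; parity rasterization does not
  # depend on winding, only the edge-count check does
  m2
}
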