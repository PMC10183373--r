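#' Closed triangulated surface mesh
#'
#' The segmentation unit for one nucleus or one cell membrane: a closed,
#' genus-0, consistently outward-wound triangle mesh in physical coordinates
#' (µm), tagged with a time-frame index and an instance identity.
#'
#' @param vertices numeric matrix, one row per vertex, columns `(x, y, z)` µm.
#' @param faces integer matrix, one row per triangle, 1-based vertex indices.
#' @param frame_index integer time index.
#' @param instance_id integer identity of the segmented object.
#' @return An object of class `tri_mesh`.
#' @export
tri_mesh <- function(vertices, faces, frame_index = 0L, instance_id = 0L) {
  vertices <- as.matrix(vertices)
  faces <- matrix(as.integer(as.matrix(faces)), ncol = 3)
  if (ncol(vertices) != 3) stop("vertices must have 3 columns (x, y, z)")
  if (any(faces < 1L) || any(faces > nrow(vertices)))
    stop("face indices out of range")
  structure(
    list(vertices = unname(vertices), faces = unname(faces),
         frame_index = as.integer(frame_index),
         instance_id = as.integer(instance_id)),
    class = "tri_mesh"
  )
}

#' @export
print.tri_mesh <- function(x, ...) {
  cat(sprintf("tri_mesh: %d vertices, %d faces (frame %d, instance %d)\n",
              nrow(x$vertices), nrow(x$faces), x$frame_index, x$instance_id))
  cat(sprintf("  volume %.4g um^3\n", mesh_volume(x)))
  invisible(x)
}

is_tri_mesh <- function(x) inherits(x, "tri_mesh")

#' Undirected edge list of a mesh
#'
#' @param mesh a [tri_mesh].
#' @return integer matrix with two columns, each row one undirected edge
#'   (smaller index first), each edge listed once.
#' @keywords internal
mesh_edges <- function(mesh) {
  f <- mesh$faces
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  e <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  nv <- max(f) + 1
  e[!duplicated(e[, 1] * nv + e[, 2]), , drop = FALSE]
}

edge_counts <- function(faces) {
  e <- rbind(faces[, c(1, 2)], faces[, c(2, 3)], faces[, c(3, 1)])
  key <- paste(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
  table(key)
}

#' Check mesh closedness and topology
#'
#' A valid mesh is a closed 2-manifold: every undirected edge is shared by
#' exactly two faces, and for a genus-0 surface V - E + F = 2.
#'
#' @param mesh a [tri_mesh].
#' @param require_genus0 also require Euler characteristic 2.
#' @return `TRUE` invisibly; otherwise an error describing the defect.
#' @export
validate_mesh <- function(mesh, require_genus0 = TRUE) {
  stopifnot(is_tri_mesh(mesh))
  cnt <- edge_counts(mesh$faces)
  if (any(cnt != 2L))
    stop("mesh is not closed: ", sum(cnt != 2L), " edge(s) not shared by exactly 2 faces")
  V <- nrow(mesh$vertices); E <- length(cnt); F <- nrow(mesh$faces)
  if (require_genus0 && (V - E + F) != 2L)
    stop("mesh Euler characteristic is ", V - E + F, ", expected 2")
  invisible(TRUE)
}

is_closed_mesh <- function(mesh) {
  all(edge_counts(mesh$faces) == 2L)
}

#' Signed mesh volume
#'
#' Volume enclosed by a closed mesh via the divergence theorem (sum of signed
#' tetrahedra against the vertex centroid); positive for outward winding.
#'
#' @param mesh a [tri_mesh].
#' @return signed volume in µm³.
#' @export
mesh_volume <- function(mesh) {
  v <- mesh$vertices
  ctr <- colMeans(v)
  a <- v[mesh$faces[, 1], , drop = FALSE] - rep(ctr, each = nrow(mesh$faces))
  b <- v[mesh$faces[, 2], , drop = FALSE] - rep(ctr, each = nrow(mesh$faces))
  c_ <- v[mesh$faces[, 3], , drop = FALSE] - rep(ctr, each = nrow(mesh$faces))
  det3 <- a[, 1] * (b[, 2] * c_[, 3] - b[, 3] * c_[, 2]) -
    a[, 2] * (b[, 1] * c_[, 3] - b[, 3] * c_[, 1]) +
    a[, 3] * (b[, 1] * c_[, 2] - b[, 2] * c_[, 1])
  sum(det3) / 6
}

#' Force outward face winding
#'
#' @param mesh a [tri_mesh].
#' @return the mesh, with faces flipped if the signed volume was negative.
#' @keywords internal
ensure_outward <- function(mesh) {
  if (mesh_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

icosahedron_vf <- function() {
  p <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1, p, 0), c(1, p, 0), c(-1, -p, 0), c(1, -p, 0),
    c(0, -1, p), c(0, 1, p), c(0, -1, -p), c(0, 1, -p),
    c(p, 0, -1), c(p, 0, 1), c(-p, 0, -1), c(-p, 0, 1)
  )
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2)
  )
  list(v = v, f = f)
}

#' Icosphere mesh
#'
#' Subdivided icosahedron projected onto a sphere: the template used for all
#' raycast mesh initialisations. Subdivision level `s` gives `20 * 4^s` faces.
#'
#' @param center sphere center `(x, y, z)` in µm.
#' @param radius sphere radius in µm; must be positive.
#' @param subdivisions non-negative integer subdivision level.
#' @inheritParams tri_mesh
#' @return a [tri_mesh].
#' @export
make_icosphere <- function(center, radius, subdivisions = 2L,
                           frame_index = 0L, instance_id = 0L) {
  if (!is.numeric(radius) || length(radius) != 1L || radius <= 0)
    stop("radius must be a positive scalar")
  if (subdivisions < 0) stop("subdivisions must be >= 0")
  ico <- icosahedron_vf()
  v <- ico$v; f <- ico$f
  for (s in seq_len(subdivisions)) {
    mid_cache <- new.env(hash = TRUE, parent = emptyenv())
    verts <- lapply(seq_len(nrow(v)), function(i) v[i, ])
    midpoint <- function(a, b) {
      key <- paste(min(a, b), max(a, b))
      idx <- mid_cache[[key]]
      if (!is.null(idx)) return(idx)
      m <- (verts[[a]] + verts[[b]]) / 2
      m <- m / sqrt(sum(m^2))
      verts[[length(verts) + 1L]] <<- m
      idx <- length(verts)
      mid_cache[[key]] <- idx
      idx
    }
    nf <- matrix(0L, nrow = 4L * nrow(f), ncol = 3L)
    for (t in seq_len(nrow(f))) {
      v1 <- f[t, 1]; v2 <- f[t, 2]; v3 <- f[t, 3]
      a <- midpoint(v1, v2); b <- midpoint(v2, v3); c_ <- midpoint(v3, v1)
      nf[(t - 1L) * 4L + 1:4, ] <- rbind(
        c(v1, a, c_), c(v2, b, a), c(v3, c_, b), c(a, b, c_)
      )
    }
    v <- do.call(rbind, verts)
    f <- nf
  }
  v <- v * radius
  v <- sweep(v, 2, as.numeric(center), "+")
  ensure_outward(tri_mesh(v, f, frame_index, instance_id))
}

#' Per-vertex outward unit normals
#'
#' The normal at a node is the average of the unit normals of the triangles
#' meeting that node, renormalised. Degenerate (zero-area) faces contribute
#' nothing; a vertex whose averaged normal vanishes is an error.
#'
#' @param mesh a [tri_mesh] with outward winding.
#' @return numeric matrix of unit normals, one row per vertex.
#' @export
vertex_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  e1 <- v[f[, 2], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  e2 <- v[f[, 3], , drop = FALSE] - v[f[, 1], , drop = FALSE]
  fn <- cbind(
    e1[, 2] * e2[, 3] - e1[, 3] * e2[, 2],
    e1[, 3] * e2[, 1] - e1[, 1] * e2[, 3],
    e1[, 1] * e2[, 2] - e1[, 2] * e2[, 1]
  )
  len <- sqrt(rowSums(fn^2))
  ok <- len > 1e-300
  fn[ok, ] <- fn[ok, , drop = FALSE] / len[ok]
  fn[!ok, ] <- 0
  grp <- c(f[, 1], f[, 2], f[, 3])
  out <- matrix(0, nrow(v), 3)
  acc <- rowsum(rbind(fn, fn, fn), grp)
  out[as.integer(rownames(acc)), ] <- acc
  nl <- sqrt(rowSums(out^2))
  if (any(nl < 1e-12))
    stop("degenerate vertex: averaged normal has zero length")
  out / nl
}

#' Axis-aligned bounding box of a mesh
#'
#' @param mesh a [tri_mesh].
#' @return list with `min` and `max`, each `(x, y, z)` in µm.
#' @export
bounding_box <- function(mesh) {
  v <- mesh$vertices
  if (nrow(v) == 0) stop("empty mesh")
  list(min = apply(v, 2, min), max = apply(v, 2, max))
}

#' Set of spheres used for raycast mesh initialisation
#'
#' @param centers numeric matrix, one row per sphere, columns `(x, y, z)` µm.
#' @param radii positive radii in µm, one per sphere.
#' @return An object of class `sphere_set`.
#' @export
sphere_set <- function(centers, radii) {
  centers <- rbind(centers)
  if (length(radii) != nrow(centers)) stop("one radius per center required")
  if (any(radii <= 0)) stop("radii must be positive")
  # union must be connected: chain of pairwise intersections
  n <- nrow(centers)
  if (n > 1) {
    adj <- as.matrix(stats::dist(centers)) <= outer(radii, radii, "+")
    seen <- rep(FALSE, n); stack <- 1L; seen[1] <- TRUE
    while (length(stack)) {
      cur <- stack[1]; stack <- stack[-1]
      nb <- which(adj[cur, ] & !seen)
      seen[nb] <- TRUE; stack <- c(stack, nb)
    }
    if (!all(seen)) stop("sphere union is not connected")
  }
  structure(list(centers = unname(centers), radii = as.numeric(radii)),
            class = "sphere_set")
}

#' Initialise a mesh over a union of spheres by raycasting
#'
#' An icosphere template centred at the centroid of the sphere centers has
#' each vertex pushed along its ray to the farthest intersection with the
#' union-of-spheres boundary, producing a star-convex envelope of the union.
#'
#' @param spheres a [sphere_set].
#' @param subdivisions icosphere subdivision level.
#' @inheritParams tri_mesh
#' @return a [tri_mesh].
#' @export
raycast_from_spheres <- function(spheres, subdivisions = 2L,
                                 frame_index = 0L, instance_id = 0L) {
  stopifnot(inherits(spheres, "sphere_set"))
  c0 <- colMeans(spheres$centers)
  inside <- sqrt(rowSums(sweep(spheres$centers, 2, c0)^2)) <= spheres$radii
  if (!any(inside))
    stop("invalid geometry: centroid of sphere centers lies outside the union")
  tmpl <- make_icosphere(c(0, 0, 0), 1, subdivisions)
  dirs <- tmpl$vertices
  tmax <- apply(dirs, 1, function(d) {
    tt <- 0
    for (s in seq_len(nrow(spheres$centers))) {
      m <- spheres$centers[s, ] - c0
      dm <- sum(d * m)
      disc <- dm^2 - (sum(m^2) - spheres$radii[s]^2)
      if (disc >= 0) {
        t1 <- dm + sqrt(disc)
        if (t1 > tt) tt <- t1
      }
    }
    tt
  })
  v <- sweep(dirs * tmax, 2, c0, "+")
  ensure_outward(tri_mesh(v, tmpl$faces, frame_index, instance_id))
}

#' Initialise a mesh over a voxel region by raycasting
#'
#' Rays are cast from the region's center of mass toward the vertices of an
#' icosphere template; each vertex is repositioned to the farthest in-region
#' sample along its ray (marched at a quarter of the smallest spacing), i.e.
#' onto the inner surface of the region.
#'
#' @param region a [volume] whose data is logical/0-1, non-empty and
#'   connected, with its center of mass inside the region.
#' @param subdivisions icosphere subdivision level.
#' @inheritParams tri_mesh
#' @return a [tri_mesh].
#' @export
raycast_from_region <- function(region, subdivisions = 2L,
                                frame_index = 0L, instance_id = 0L) {
  stopifnot(is_volume(region))
  mask <- region$data != 0
  idx <- which(mask, arr.ind = TRUE)  # columns (k, j, i)
  if (nrow(idx) == 0) stop("empty region")
  ctr_xyz <- colMeans(voxel_centers(region, idx))
  nv <- nearest_voxel(region, ctr_xyz)
  d <- dim(mask)
  if (nv[1] < 1 || nv[1] > d[1] || nv[2] < 1 || nv[2] > d[2] ||
      nv[3] < 1 || nv[3] > d[3] || !mask[nv[1], nv[2], nv[3]])
    stop("invalid geometry: region center of mass lies outside the region")
  tmpl <- make_icosphere(c(0, 0, 0), 1, subdivisions)
  step <- min(region$spacing) / 4
  ext <- voxel_centers(region, idx)
  tmax <- sqrt(sum((apply(ext, 2, max) - apply(ext, 2, min))^2)) + 2 * step
  v <- cpp_region_raymarch(as.logical(mask), d, region$spacing, region$origin,
                           ctr_xyz, tmpl$vertices, step, tmax)
  ensure_outward(tri_mesh(v, tmpl$faces, frame_index, instance_id))
}

#' Voxelize a closed mesh onto a grid
#'
#' A voxel gets value 1 exactly when its center lies inside the mesh, decided
#' by ray-parity along +x with a deterministic sub-voxel perturbation against
#' edge/vertex hits.
#'
#' @param mesh a closed [tri_mesh].
#' @param grid a [volume] supplying the target geometry (its data values are
#'   ignored).
#' @return a binary [volume] on the same grid.
#' @export
binarize <- function(mesh, grid) {
  stopifnot(is_tri_mesh(mesh), is_volume(grid))
  if (!is_closed_mesh(mesh)) stop("invalid mesh: not closed")
  d <- vol_dims(grid)
  inside <- cpp_voxelize(mesh$vertices, mesh$faces, d, grid$spacing,
                         grid$origin)
  volume(array(as.integer(inside), dim = d), grid$spacing, grid$origin)
}

#' Points-inside-mesh test
#'
#' @param points matrix with columns `(x, y, z)` (µm).
#' @param mesh a closed [tri_mesh].
#' @return logical vector.
#' @keywords internal
points_in_mesh <- function(points, mesh) {
  cpp_points_in_mesh(rbind(points), mesh$vertices, mesh$faces)
}
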