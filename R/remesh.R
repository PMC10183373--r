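# Isotropic remeshing: iterative long-edge bisection, short-edge collapse
# (guarded by the manifold link condition) and tangential Laplacian
# relaxation. Keeps the surface closed and genus 0. Splits and collapses are
# batched per sweep (edges touching an already-modified vertex wait for the
# next sweep) so the edge list is rebuilt once per sweep, not per edge.

edge_lengths <- function(v, e) {
  sqrt(rowSums((v[e[, 1], , drop = FALSE] - v[e[, 2], , drop = FALSE])^2))
}

faces_with_edge <- function(f, a, b) {
  which((f[, 1] == a | f[, 2] == a | f[, 3] == a) &
          (f[, 1] == b | f[, 2] == b | f[, 3] == b))
}

# split edge (a,b) at its midpoint, preserving orientation
split_edge <- function(v, f, a, b) {
  rows <- faces_with_edge(f, a, b)
  m <- (v[a, ] + v[b, ]) / 2
  v <- rbind(v, m)
  mi <- nrow(v)
  newf <- list()
  opp <- integer(0)
  for (r in rows) {
    tri <- f[r, ]
    pos_a <- which(tri == a)
    succ <- tri[pos_a %% 3 + 1]
    t3 <- tri[!(tri %in% c(a, b))]
    opp <- c(opp, t3)
    if (succ == b) {
      newf[[length(newf) + 1L]] <- rbind(c(a, mi, t3), c(mi, b, t3))
    } else {
      newf[[length(newf) + 1L]] <- rbind(c(b, mi, t3), c(mi, a, t3))
    }
  }
  f <- rbind(f[-rows, , drop = FALSE], do.call(rbind, newf))
  list(v = v, f = f, opp = opp, mid = mi)
}

vertex_neighbors <- function(f, nv) {
  e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
  nb <- vector("list", nv)
  sp <- split(c(e[, 2], e[, 1]), c(e[, 1], e[, 2]))
  for (nm in names(sp)) nb[[as.integer(nm)]] <- unique(sp[[nm]])
  nb
}

drop_unused_vertices <- function(v, f) {
  used <- sort(unique(as.vector(f)))
  remap <- integer(nrow(v))
  remap[used] <- seq_along(used)
  list(v = v[used, , drop = FALSE],
       f = matrix(remap[f], ncol = 3))
}

tangential_relax <- function(v, f, lambda = 0.2) {
  msh <- tri_mesh(v, f)
  n <- vertex_normals(msh)
  nbm <- neighbor_mean_op(msh)
  d <- nbm(v) - v
  d_tan <- d - n * rowSums(d * n)
  v + lambda * d_tan
}

split_sweeps <- function(v, f, l_max, max_sweeps = 60L, max_vertices = 2e5) {
  for (sweep in seq_len(max_sweeps)) {
    e <- mesh_edges(tri_mesh(v, f))
    len <- edge_lengths(v, e)
    long <- which(len > l_max)
    if (!length(long)) return(list(v = v, f = f, done = TRUE))
    # a conforming mesh needs at least ~len/l_max vertices per long edge;
    # refuse bounds that would blow the vertex budget
    if (nrow(v) + length(long) > max_vertices ||
        sum(ceiling(len[long] / l_max)) > max_vertices)
      stop("remesh failure: bounds infeasible (vertex budget exceeded)")
    # splits leave vertex positions untouched, so every long edge of the
    # sweep's snapshot can be bisected in sequence; child edges are
    # re-measured next sweep
    long <- long[order(len[long], decreasing = TRUE)]
    for (idx in long) {
      res <- split_edge(v, f, e[idx, 1], e[idx, 2])
      v <- res$v; f <- res$f
    }
  }
  list(v = v, f = f, done = FALSE)
}

collapse_sweeps <- function(v, f, l_min, l_max, max_sweeps = 60L) {
  for (sweep in seq_len(max_sweeps)) {
    e <- mesh_edges(tri_mesh(v, f))
    len <- edge_lengths(v, e)
    short <- which(len < l_min)
    if (!length(short)) break
    short <- short[order(len[short])]
    nb <- vertex_neighbors(f, nrow(v))
    dirty <- rep(FALSE, nrow(v))
    any_collapse <- FALSE
    for (idx in short) {
      a <- e[idx, 1]; b <- e[idx, 2]
      if (dirty[a] || dirty[b]) next
      rows <- faces_with_edge(f, a, b)
      if (length(rows) != 2L) next
      opp <- setdiff(unique(as.vector(f[rows, ])), c(a, b))
      common <- intersect(nb[[a]], nb[[b]])
      if (!setequal(common, opp)) { dirty[c(a, b)] <- TRUE; next }
      m <- (v[a, ] + v[b, ]) / 2
      ring <- setdiff(union(nb[[a]], nb[[b]]), c(a, b))
      dmax <- max(sqrt(rowSums(sweep(v[ring, , drop = FALSE], 2, m)^2)))
      if (dmax > l_max) { dirty[c(a, b)] <- TRUE; next }
      v[a, ] <- m
      f <- f[-rows, , drop = FALSE]
      f[f == b] <- a
      dirty[c(a, b, ring)] <- TRUE
      any_collapse <- TRUE
    }
    cln <- drop_unused_vertices(v, f)
    v <- cln$v; f <- cln$f
    if (!any_collapse) break
    if (nrow(f) < 4L) stop("remesh failure: bounds infeasible for this mesh")
  }
  list(v = v, f = f)
}

#' Isotropic remeshing to an edge-length band
#'
#' Repeatedly bisects edges longer than `l_max` and collapses edges shorter
#' than `l_min` (only when the collapse keeps the surface a closed 2-manifold
#' and creates no over-long edge), with gentle tangential Laplacian
#' relaxation to even out triangle shape. A mesh already inside the band is
#' returned untouched. The upper bound is enforced; the lower bound is
#' best-effort, since a collapse is refused whenever it would break
#' manifoldness.
#'
#' @param mesh a closed [tri_mesh].
#' @param l_min,l_max target edge-length band in µm, `0 < l_min < l_max`.
#' @param max_passes safety cap on split/collapse/relax passes.
#' @return a closed [tri_mesh] with edges in (approximately) the band.
#' @export
remesh <- function(mesh, l_min, l_max, max_passes = 12L) {
  stopifnot(is_tri_mesh(mesh))
  if (!(l_min > 0 && l_min < l_max)) stop("need 0 < l_min < l_max")
  v <- mesh$vertices; f <- mesh$faces
  e <- mesh_edges(mesh)
  len <- edge_lengths(v, e)
  if (all(len >= l_min & len <= l_max)) return(mesh)
  for (pass in seq_len(max_passes)) {
    sp <- split_sweeps(v, f, l_max)
    if (!sp$done) stop("remesh failure: edge splitting did not terminate")
    v <- sp$v; f <- sp$f
    cl <- collapse_sweeps(v, f, l_min, l_max)
    v <- cl$v; f <- cl$f
    v <- tangential_relax(v, f)
    e <- mesh_edges(tri_mesh(v, f))
    len <- edge_lengths(v, e)
    if (all(len <= l_max * 1.001) && all(len >= l_min * 0.5)) break
  }
  out <- ensure_outward(tri_mesh(v, f, mesh$frame_index, mesh$instance_id))
  if (!is_closed_mesh(out)) stop("remesh failure: surface no longer closed")
  out
}
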