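#' Per-instance best Jaccard index and centroid offset
#'
#' For each ground-truth label `i`, `JI_i = max_j |Ti n Pj| / |Ti u Pj|` over
#' predicted labels `j`, and `dCM_i` is the physical distance between the
#' centroid of `Ti` and the centroid of the argmax prediction. Ground-truth
#' instances with no overlapping prediction get `best_ji = 0` and a missing
#' `delta_cm`. Argmax ties break toward the lower predicted label.
#'
#' @param gt,pred integer-label [volume]s of identical shape and spacing.
#' @return An object of class `match_result`: a list with `records` (data
#'   frame: `gt_label`, `matched_pred_label`, `best_ji`, `delta_cm`) and `n`.
#' @export
best_ji_map <- function(gt, pred) {
  stopifnot(is_volume(gt), is_volume(pred))
  if (!identical(vol_dims(gt), vol_dims(pred)))
    stop("shape mismatch between ground truth and prediction")
  g <- as.integer(gt$data); p <- as.integer(pred$data)
  glabs <- sort(unique(g[g > 0L]))
  plabs <- sort(unique(p[p > 0L]))
  gsize <- table(factor(g[g > 0L], levels = glabs))
  psize <- table(factor(p[p > 0L], levels = plabs))
  centroid <- function(vol, lab_arr, lab) {
    idx <- which(array(lab_arr, vol_dims(vol)) == lab, arr.ind = TRUE)
    colMeans(voxel_centers(vol, idx))
  }
  recs <- data.frame(gt_label = glabs, matched_pred_label = NA_integer_,
                     best_ji = 0, delta_cm = NA_real_)
  if (length(plabs)) {
    both <- g > 0L & p > 0L
    inter <- table(factor(g[both], levels = glabs),
                   factor(p[both], levels = plabs))
    for (r in seq_along(glabs)) {
      iv <- as.numeric(inter[r, ])
      if (all(iv == 0)) next
      ji <- iv / (as.numeric(gsize[r]) + as.numeric(psize) - iv)
      best <- which.max(ji)  # first max = lowest label on ties
      recs$best_ji[r] <- ji[best]
      recs$matched_pred_label[r] <- plabs[best]
      cg <- centroid(gt, g, glabs[r])
      cp <- centroid(pred, p, plabs[best])
      recs$delta_cm[r] <- sqrt(sum((cg - cp)^2))
    }
  }
  structure(list(records = recs, n = length(glabs)), class = "match_result")
}

#' @export
print.match_result <- function(x, ...) {
  cat(sprintf("match_result: %d ground-truth instance(s), mean best JI %.3f\n",
              x$n, mean(x$records$best_ji)))
  invisible(x)
}

bbox_ji <- function(a, b) {
  lo <- pmax(a$min, b$min)
  hi <- pmin(a$max, b$max)
  if (any(hi <= lo)) return(0)
  inter <- prod(hi - lo)
  va <- prod(a$max - a$min)
  vb <- prod(b$max - b$min)
  inter / (va + vb - inter)
}

#' Detection accuracy by bidirectional bounding-box mapping
#'
#' Each predicted instance maps to the ground-truth instance with the highest
#' bounding-box Jaccard index (to none when every JI is zero), and
#' symmetrically for ground truth. A prediction and a ground-truth instance
#' that are singly mapped to each other count as a true positive. Multiple
#' predictions mapping to one ground-truth instance are false positives;
#' ground-truth instances that are unmapped, share a prediction, or are
#' otherwise not part of a mutual single pair are false negatives.
#'
#' @param gt_boxes,pred_boxes lists of boxes (`list(min =, max =)`, as
#'   returned by [bounding_box()]).
#' @return list with integer elements `TP`, `FP`, `FN`.
#' @export
detection_match <- function(gt_boxes, pred_boxes) {
  ng <- length(gt_boxes); np <- length(pred_boxes)
  if (ng == 0L) return(list(TP = 0L, FP = 0L, FN = 0L))
  if (np == 0L) return(list(TP = 0L, FP = 0L, FN = ng))
  ji <- matrix(0, ng, np)
  for (i in seq_len(ng))
    for (j in seq_len(np))
      ji[i, j] <- bbox_ji(gt_boxes[[i]], pred_boxes[[j]])
  map_p <- apply(ji, 2, function(col) if (all(col == 0)) NA_integer_ else which.max(col))
  map_g <- apply(ji, 1, function(row) if (all(row == 0)) NA_integer_ else which.max(row))
  preds_per_gt <- tabulate(map_p[!is.na(map_p)], nbins = ng)
  gts_per_pred <- tabulate(map_g[!is.na(map_g)], nbins = np)
  TP <- 0L; FP <- 0L; FN <- 0L
  for (j in seq_len(np)) {
    g <- map_p[j]
    if (!is.na(g) && preds_per_gt[g] >= 2L) FP <- FP + 1L
  }
  for (i in seq_len(ng)) {
    p <- map_g[i]
    mutual_single <- !is.na(p) && !is.na(map_p[p]) && map_p[p] == i &&
      preds_per_gt[i] == 1L && gts_per_pred[p] == 1L
    if (mutual_single) TP <- TP + 1L else FN <- FN + 1L
  }
  list(TP = TP, FP = FP, FN = FN)
}

mesh_centroid <- function(mesh) colMeans(mesh$vertices)

box_volume <- function(b) prod(pmax(b$max - b$min, 0))

# fraction of box `inner`'s volume lying inside box `outer`
box_containment <- function(inner, outer) {
  lo <- pmax(inner$min, outer$min)
  hi <- pmin(inner$max, outer$max)
  if (any(hi <= lo)) return(0)
  vi <- box_volume(inner)
  if (vi == 0) return(0)
  prod(hi - lo) / vi
}

#' Track instances across frames by bounding-box overlap
#'
#' Greedy frame-to-frame linking: active tracks are matched to current-frame
#' meshes in decreasing order of bounding-box Jaccard index, accepting links
#' above `j_min`; unmatched meshes start new tracks. Divisions are recorded
#' in two ways: a track that disappears while its last box overlaps the
#' first boxes of two or more tracks born that frame records those tracks as
#' its children; and a track whose linked box suddenly shrinks (below
#' `div_shrink` of its previous box volume) while a newborn track also sits
#' largely inside its previous box (containment above `div_containment`) is
#' re-read as a division — the parent ends and both meshes start child
#' tracks.
#'
#' @param frames list of per-frame lists of [tri_mesh].
#' @param j_min minimum bounding-box JI to accept a link.
#' @param div_shrink volume-drop factor that flags a division on a linked
#'   track.
#' @param div_containment minimum fraction of a daughter box inside the
#'   parent box.
#' @return list of tracks; each track is a list with `track_id`,
#'   `parent_track_id` (or `NA`) and a data frame `points` with columns
#'   `frame_index`, `instance_id`, `x`, `y`, `z` (centroid, µm) and the box
#'   corners.
#' @export
track_bboxes <- function(frames, j_min = 0.1, div_shrink = 0.75,
                         div_containment = 0.6) {
  stopifnot(length(frames) >= 1L)
  tracks <- list()
  active <- integer(0)  # track ids active in the previous frame
  point_row <- function(t, mesh) {
    bb <- bounding_box(mesh)
    ctr <- mesh_centroid(mesh)
    data.frame(frame_index = t, instance_id = mesh$instance_id,
               x = ctr[1], y = ctr[2], z = ctr[3],
               xmin = bb$min[1], ymin = bb$min[2], zmin = bb$min[3],
               xmax = bb$max[1], ymax = bb$max[2], zmax = bb$max[3])
  }
  last_box <- function(tr) {
    r <- tr$points[nrow(tr$points), ]
    list(min = c(r$xmin, r$ymin, r$zmin), max = c(r$xmax, r$ymax, r$zmax))
  }
  for (t in seq_along(frames)) {
    meshes <- frames[[t]]
    if (t == 1L) {
      for (m in meshes) {
        tracks[[length(tracks) + 1L]] <-
          list(track_id = length(tracks) + 1L, parent_track_id = NA_integer_,
               points = point_row(t, m))
      }
      active <- seq_along(tracks)
      next
    }
    boxes_cur <- lapply(meshes, bounding_box)
    na <- length(active); nc <- length(meshes)
    linked_track <- rep(FALSE, na); linked_mesh <- rep(FALSE, nc)
    if (na > 0 && nc > 0) {
      ji <- matrix(0, na, nc)
      for (a in seq_len(na))
        for (c_ in seq_len(nc))
          ji[a, c_] <- bbox_ji(last_box(tracks[[active[a]]]), boxes_cur[[c_]])
      repeat {
        ji_masked <- ji
        ji_masked[linked_track, ] <- -1
        ji_masked[, linked_mesh] <- -1
        best <- which(ji_masked == max(ji_masked), arr.ind = TRUE)
        if (max(ji_masked) < j_min) break
        a <- best[1, 1]; c_ <- best[1, 2]  # first index = lower id on ties
        tid <- active[a]
        tracks[[tid]]$points <- rbind(tracks[[tid]]$points,
                                      point_row(t, meshes[[c_]]))
        linked_track[a] <- TRUE; linked_mesh[c_] <- TRUE
      }
    }
    new_ids <- integer(0)
    for (c_ in which(!linked_mesh)) {
      tracks[[length(tracks) + 1L]] <-
        list(track_id = length(tracks) + 1L, parent_track_id = NA_integer_,
             points = point_row(t, meshes[[c_]]))
      new_ids <- c(new_ids, length(tracks))
    }
    # division candidates: a vanished track overlapping >= 2 newborn boxes
    for (a in which(!linked_track)) {
      lb <- last_box(tracks[[active[a]]])
      kids <- new_ids[vapply(new_ids, function(nid)
        bbox_ji(lb, last_box(tracks[[nid]])) > 0, logical(1))]
      if (length(kids) >= 2L)
        for (k in kids) tracks[[k]]$parent_track_id <- tracks[[active[a]]]$track_id
    }
    # division re-classification: a linked track that shrank sharply while a
    # newborn track also sits inside its previous box
    survivors <- active[linked_track]
    demoted <- integer(0)
    for (tid in survivors) {
      pts <- tracks[[tid]]$points
      if (nrow(pts) < 2L) next
      prev <- pts[nrow(pts) - 1L, ]
      prev_box <- list(min = c(prev$xmin, prev$ymin, prev$zmin),
                       max = c(prev$xmax, prev$ymax, prev$zmax))
      cur <- pts[nrow(pts), ]
      cur_box <- list(min = c(cur$xmin, cur$ymin, cur$zmin),
                      max = c(cur$xmax, cur$ymax, cur$zmax))
      if (box_volume(cur_box) >= div_shrink * box_volume(prev_box)) next
      if (box_containment(cur_box, prev_box) < div_containment) next
      sibs <- new_ids[vapply(new_ids, function(nid) {
        fb <- last_box(tracks[[nid]])
        box_containment(fb, prev_box) >= div_containment &&
          box_volume(fb) < div_shrink * box_volume(prev_box) &&
          is.na(tracks[[nid]]$parent_track_id)
      }, logical(1))]
      if (!length(sibs)) next
      # parent ends at t-1; its linked mesh becomes child 1, first sibling
      # child 2
      tracks[[tid]]$points <- pts[-nrow(pts), , drop = FALSE]
      tracks[[length(tracks) + 1L]] <-
        list(track_id = length(tracks) + 1L,
             parent_track_id = tracks[[tid]]$track_id,
             points = cur)
      child1 <- length(tracks)
      tracks[[sibs[1]]]$parent_track_id <- tracks[[tid]]$track_id
      demoted <- c(demoted, tid)
      new_ids <- c(new_ids, child1)
    }
    active <- c(setdiff(survivors, demoted), new_ids)
  }
  tracks
}

#' Number of tracked cells per frame
#'
#' @param tracks output of [track_bboxes()].
#' @param n_frames total number of frames.
#' @return integer vector of per-frame active-track counts.
#' @export
cell_counts <- function(tracks, n_frames) {
  counts <- integer(n_frames)
  for (tr in tracks) {
    f <- tr$points$frame_index
    counts[f] <- counts[f] + 1L
  }
  counts
}

#' Instantaneous nucleus speeds from tracks
#'
#' One speed per consecutive frame pair within each track:
#' `|delta centroid| / frame_interval`.
#'
#' @param tracks output of [track_bboxes()].
#' @param frame_interval_minutes imaging interval in minutes.
#' @return numeric vector of speeds in µm/min (histogram-ready).
#' @export
velocity_distribution <- function(tracks, frame_interval_minutes = 1) {
  speeds <- numeric(0)
  for (tr in tracks) {
    p <- tr$points
    if (nrow(p) < 2L) next
    consecutive <- diff(p$frame_index) == 1L
    d <- sqrt(diff(p$x)^2 + diff(p$y)^2 + diff(p$z)^2)
    speeds <- c(speeds, d[consecutive] / frame_interval_minutes)
  }
  speeds
}
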