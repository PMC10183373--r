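# Interchange: multi-page TIFF volumes/stacks with a JSON spacing sidecar,
# PLY/OBJ meshes carrying instance_id/frame_index, CSV tables and a
# simplified TrackMate-style XML track export.

sidecar_path <- function(path) paste0(path, ".json")

#' Write a volume as a multi-page TIFF
#'
#' Pages are z slices. Values are rescaled to the TIFF range; the spacing,
#' origin and value range travel in a JSON sidecar (`<path>.json`) so the
#' round trip is value-exact to the bit depth.
#'
#' @param vol a [volume].
#' @param path output file.
#' @param bits 16 (integer, exact for integer data up to 65535) or 32
#'   (float).
#' @export
write_volume <- function(vol, path, bits = 16L) {
  stopifnot(is_volume(vol))
  d <- vol_dims(vol)
  lo <- min(vol$data); hi <- max(vol$data)
  if (bits == 16L && all(vol$data >= 0) && hi <= 65535 &&
      all(vol$data == round(vol$data))) {
    # integer data: store on the full 16-bit scale so the round trip is exact
    lo <- 0; scale <- 65535
  } else {
    scale <- if (hi > lo) hi - lo else 1
  }
  pages <- lapply(seq_len(d[1]), function(k)
    (vol$data[k, , ] - lo) / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = bits)
  jsonlite::write_json(
    list(spacing = vol$spacing, origin = vol$origin,
         value_min = lo, value_scale = scale, nz = d[1],
         n_channels = 1L, n_frames = 1L),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a volume written by [write_volume()]
#'
#' @param path TIFF file.
#' @param spacing override when no sidecar is present; without either the
#'   read fails.
#' @return a [volume].
#' @export
read_volume <- function(path, spacing = NULL) {
  stacks <- read_stack(path, spacing = spacing)
  stacks[[1]][[1]]
}

#' Read a (multi-frame, multi-channel) TIFF stack
#'
#' Pages are interpreted as `(t, c, z)` nested, z fastest, using the JSON
#' sidecar written alongside by this package (or `n_channels`/`n_frames`
#' arguments). Voxel spacing must come from the sidecar or the `spacing`
#' override; otherwise the read fails rather than guessing.
#'
#' @param path TIFF file.
#' @param spacing spacing override (scalar or `(sz, sy, sx)` µm).
#' @param n_channels,n_frames layout override when no sidecar exists.
#' @return nested list: `[[frame]][[channel]]` of [volume]s.
#' @export
read_stack <- function(path, spacing = NULL, n_channels = NULL,
                       n_frames = NULL) {
  meta <- NULL
  if (file.exists(sidecar_path(path)))
    meta <- jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  if (is.null(spacing)) {
    if (is.null(meta))
      stop("format error: no voxel spacing available (no sidecar, no override)")
    spacing <- meta$spacing
  }
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  nc <- n_channels %||% (if (!is.null(meta)) meta$n_channels else 1L)
  nf <- n_frames %||% (if (!is.null(meta)) meta$n_frames else 1L)
  nz <- length(pages) / (nc * nf)
  if (nz != round(nz))
    stop("format error: ", length(pages),
         " pages do not factor into frames x channels x z = ",
         nf, " x ", nc, " x z")
  nz <- as.integer(nz)
  lo <- if (!is.null(meta)) meta$value_min else 0
  sc <- if (!is.null(meta)) meta$value_scale else 1
  origin <- if (!is.null(meta)) meta$origin else c(0, 0, 0)
  out <- vector("list", nf)
  p <- 1L
  for (t in seq_len(nf)) {
    out[[t]] <- vector("list", nc)
    for (ch in seq_len(nc)) {
      arr <- array(0, c(nz, nrow(pages[[p]]), ncol(pages[[p]])))
      for (k in seq_len(nz)) {
        pg <- pages[[p]]
        if (length(dim(pg)) == 3L) pg <- pg[, , 1]  # drop alpha if present
        arr[k, , ] <- pg * sc + lo
        p <- p + 1L
      }
      out[[t]][[ch]] <- volume(arr, spacing, origin)
    }
  }
  out
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a label triplet as a three-channel TIFF
#'
#' Channel order mask, border, dt (z fastest within each channel), recorded
#' in the sidecar.
#'
#' @param triplet a `label_triplet`.
#' @param path output file.
#' @export
write_labels <- function(triplet, path) {
  d <- vol_dims(triplet$mask)
  pages <- list()
  for (ch in list(triplet$mask, triplet$border, triplet$dt))
    for (k in seq_len(d[1]))
      pages[[length(pages) + 1L]] <- ch$data[k, , ] / DT_SATURATION
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  jsonlite::write_json(
    list(spacing = triplet$mask$spacing, origin = triplet$mask$origin,
         value_min = 0, value_scale = DT_SATURATION, nz = d[1],
         n_channels = 3L, n_frames = 1L,
         channel_order = c("mask", "border", "dt")),
    sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a label triplet written by [write_labels()]
#' @param path TIFF file.
#' @return a `label_triplet`.
#' @export
read_labels <- function(path) {
  chans <- read_stack(path)[[1]]
  rnd <- function(v) { v$data <- round(v$data); v }
  label_triplet(mask = rnd(chans[[1]]), border = rnd(chans[[2]]),
                dt = rnd(chans[[3]]))
}

#' Write a mesh as PLY
#'
#' Binary little-endian by default (ASCII available); `instance_id` and
#' `frame_index` are stored as header comments.
#'
#' @param mesh a [tri_mesh].
#' @param path output file.
#' @param binary write binary little-endian (default) or ASCII.
#' @export
write_mesh_ply <- function(mesh, path, binary = TRUE) {
  nv <- nrow(mesh$vertices); nf <- nrow(mesh$faces)
  hdr <- c("ply",
           if (binary) "format binary_little_endian 1.0" else "format ascii 1.0",
           paste("comment instance_id", mesh$instance_id),
           paste("comment frame_index", mesh$frame_index),
           paste("element vertex", nv),
           "property float x", "property float y", "property float z",
           paste("element face", nf),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(hdr, con, sep = "\n")
    writeBin(as.vector(t(mesh$vertices)), con, size = 4, endian = "little")
    for (r in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(mesh$faces[r, ] - 1L), con, size = 4,
               endian = "little")
    }
  } else {
    vl <- apply(mesh$vertices, 1, function(v)
      paste(formatC(v, format = "g", digits = 9), collapse = " "))
    fl <- apply(mesh$faces - 1L, 1, function(f)
      paste(c(3L, f), collapse = " "))
    writeLines(c(hdr, vl, fl), path)
  }
  invisible(path)
}

#' Read a PLY mesh written by [write_mesh_ply()]
#' @param path PLY file.
#' @return a [tri_mesh].
#' @export
read_mesh_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- character(0)
  repeat {
    line <- readLines(con, n = 1L)
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  binary <- any(grepl("binary_little_endian", hdr))
  gv <- function(pat) {
    ln <- grep(pat, hdr, value = TRUE)
    if (length(ln)) as.integer(strsplit(ln[1], " ")[[1]][3]) else NA_integer_
  }
  nv <- gv("^element vertex"); nf <- gv("^element face")
  iid <- {
    ln <- grep("^comment instance_id", hdr, value = TRUE)
    if (length(ln)) as.integer(strsplit(ln[1], " ")[[1]][3]) else 0L
  }
  fid <- {
    ln <- grep("^comment frame_index", hdr, value = TRUE)
    if (length(ln)) as.integer(strsplit(ln[1], " ")[[1]][3]) else 0L
  }
  if (binary) {
    v <- matrix(readBin(con, "numeric", n = 3 * nv, size = 4,
                        endian = "little"), ncol = 3, byrow = TRUE)
    f <- matrix(0L, nf, 3)
    for (r in seq_len(nf)) {
      readBin(con, "raw", n = 1L)
      f[r, ] <- readBin(con, "integer", n = 3L, size = 4,
                        endian = "little") + 1L
    }
  } else {
    txt <- readLines(con)
    v <- do.call(rbind, lapply(txt[seq_len(nv)], function(s)
      as.numeric(strsplit(trimws(s), "\\s+")[[1]])))
    f <- do.call(rbind, lapply(txt[nv + seq_len(nf)], function(s)
      as.integer(strsplit(trimws(s), "\\s+")[[1]][2:4]) + 1L))
  }
  tri_mesh(v, f, fid, iid)
}

#' Write a mesh as Wavefront OBJ
#' @inheritParams write_mesh_ply
#' @export
write_mesh_obj <- function(mesh, path) {
  lines <- c(paste("# instance_id", mesh$instance_id),
             paste("# frame_index", mesh$frame_index),
             apply(mesh$vertices, 1, function(v)
               paste("v", paste(formatC(v, format = "g", digits = 9),
                                collapse = " "))),
             apply(mesh$faces, 1, function(f)
               paste("f", paste(f, collapse = " "))))
  writeLines(lines, path)
  invisible(path)
}

#' Read a Wavefront OBJ mesh
#' @param path OBJ file.
#' @return a [tri_mesh].
#' @export
read_mesh_obj <- function(path) {
  txt <- readLines(path)
  num_comment <- function(pat) {
    ln <- grep(pat, txt, value = TRUE)
    if (length(ln)) as.integer(strsplit(ln[1], " ")[[1]][3]) else 0L
  }
  v <- do.call(rbind, lapply(grep("^v ", txt, value = TRUE), function(s)
    as.numeric(strsplit(trimws(s), "\\s+")[[1]][2:4])))
  f <- do.call(rbind, lapply(grep("^f ", txt, value = TRUE), function(s)
    as.integer(sub("/.*", "", strsplit(trimws(s), "\\s+")[[1]][2:4]))))
  tri_mesh(v, f, num_comment("^# frame_index"), num_comment("^# instance_id"))
}

#' Flatten tracks to a data frame / CSV
#'
#' @param tracks output of [track_bboxes()].
#' @param path optional CSV destination.
#' @return data frame with one row per track point.
#' @export
tracks_table <- function(tracks, path = NULL) {
  df <- do.call(rbind, lapply(tracks, function(tr) {
    cbind(track_id = tr$track_id, parent_track_id = tr$parent_track_id,
          tr$points)
  }))
  if (!is.null(path)) utils::write.csv(df, path, row.names = FALSE)
  df
}

#' Export tracks as simplified TrackMate-style XML
#'
#' Spots (one per track point) and edges (consecutive points within a track,
#' plus parent-to-daughter links), a documented subset of the TrackMate
#' schema sufficient for import into downstream track viewers.
#'
#' @param tracks output of [track_bboxes()].
#' @param path output XML file.
#' @export
export_trackmate_xml <- function(tracks, path) {
  doc <- xml2::xml_new_root("TrackMate", version = "simplified")
  model <- xml2::xml_add_child(doc, "Model", spatialunits = "micron")
  spots <- xml2::xml_add_child(model, "AllSpots")
  alltr <- xml2::xml_add_child(model, "AllTracks")
  spot_id <- 0L
  first_spot <- list(); last_spot <- list()
  for (tr in tracks) {
    ids <- integer(nrow(tr$points))
    for (r in seq_len(nrow(tr$points))) {
      spot_id <- spot_id + 1L
      ids[r] <- spot_id
      p <- tr$points[r, ]
      frame <- xml2::xml_add_child(
        spots, "Spot", ID = as.character(spot_id),
        FRAME = as.character(p$frame_index),
        POSITION_X = as.character(p$x), POSITION_Y = as.character(p$y),
        POSITION_Z = as.character(p$z))
    }
    first_spot[[as.character(tr$track_id)]] <- ids[1]
    last_spot[[as.character(tr$track_id)]] <- ids[length(ids)]
    trk <- xml2::xml_add_child(alltr, "Track",
                               TRACK_ID = as.character(tr$track_id))
    if (length(ids) > 1)
      for (r in seq_len(length(ids) - 1))
        xml2::xml_add_child(trk, "Edge",
                            SPOT_SOURCE_ID = as.character(ids[r]),
                            SPOT_TARGET_ID = as.character(ids[r + 1]))
  }
  for (tr in tracks) {
    if (!is.na(tr$parent_track_id)) {
      trk <- xml2::xml_add_child(alltr, "Track",
                                 TRACK_ID = paste0("lineage_",
                                                   tr$parent_track_id, "_",
                                                   tr$track_id))
      xml2::xml_add_child(
        trk, "Edge",
        SPOT_SOURCE_ID = as.character(last_spot[[as.character(tr$parent_track_id)]]),
        SPOT_TARGET_ID = as.character(first_spot[[as.character(tr$track_id)]]))
    }
  }
  xml2::write_xml(doc, path)
  invisible(path)
}
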