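# distance transform of two digitized balls on a shared grid
two_ball_dt <- function(sep, radius = 8, n = 48) {
  c0 <- (n - 1) / 2
  g <- volume(array(0, c(n, n, n)), 1)
  m1 <- make_icosphere(c(c0 - sep / 2, c0, c0), radius, 3, instance_id = 1L)
  m2 <- make_icosphere(c(c0 + sep / 2, c0, c0), radius, 3, instance_id = 2L)
  make_labels(list(m1, m2), g)$dt
}

test_that("threshold 3 separates close nuclei where threshold 1 merges them", {
  dt18 <- two_ball_dt(18)
  expect_length(threshold_regions(dt18, 3), 2L)

  dt15 <- two_ball_dt(15)  # overlapping balls
  expect_length(threshold_regions(dt15, 1), 1L)

  # a threshold above the maximum yields nothing
  expect_length(threshold_regions(dt18, max(dt18$data) + 1), 0L)
})

test_that("thresholds form a refinement hierarchy", {
  # every region at a higher threshold is contained in exactly one region
  # at any lower threshold (regions can only split, never leak, as the
  # threshold rises)
  dt <- two_ball_dt(16)
  for (pair in list(c(1, 3), c(2, 4), c(1, 5))) {
    lo <- threshold_regions(dt, pair[1])
    hi <- threshold_regions(dt, pair[2])
    lo_lab <- array(0L, dim(dt$data))
    for (r in lo) lo_lab[r$voxels] <- r$label
    for (r in hi) {
      parents <- unique(lo_lab[r$voxels])
      expect_length(parents, 1L)
      expect_gt(parents, 0L)
    }
  }
})

test_that("size bounds filter seed regions", {
  dt <- two_ball_dt(18)
  all_regions <- threshold_regions(dt, 3, s_min = 1, s_max = Inf)
  sizes <- vapply(all_regions, function(r) r$size, integer(1))
  expect_length(threshold_regions(dt, 3, s_min = max(sizes) + 1), 0L)
  expect_length(threshold_regions(dt, 3, s_min = 1, s_max = min(sizes) - 1),
                0L)
})

test_that("watershed growth floods each basin from its seed", {
  n <- 40; c0 <- (n - 1) / 2
  g <- volume(array(0, c(n, n, n)), 1)
  ball <- make_labels(list(make_icosphere(rep(c0, 3), 9, 3)), g)
  seeds <- threshold_regions(ball$dt, 3)
  grown <- grow_regions(seeds, ball$dt, 1)
  expect_length(grown, 1L)
  # grown region covers the whole interior {dt >= 1}
  interior <- which(ball$dt$data >= 1, arr.ind = TRUE)
  expect_identical(grown[[1]]$size, nrow(interior))

  dt2 <- two_ball_dt(18)
  seeds2 <- threshold_regions(dt2, 3)
  grown2 <- grow_regions(seeds2, dt2, 1)
  expect_length(grown2, 2L)
  # disjoint, and each grown region contains its seed
  ids <- array(0L, dim(dt2$data))
  for (r in grown2) ids[r$voxels] <- ids[r$voxels] + 1L
  expect_true(all(ids <= 1L))
  for (i in 1:2) {
    cover <- array(FALSE, dim(dt2$data))
    cover[grown2[[i]]$voxels] <- TRUE
    expect_true(all(cover[seeds2[[i]]$voxels]))
  }

  # a floor above every dt value leaves the seeds unchanged
  frozen <- grow_regions(seeds2, dt2, max(dt2$data) + 1)
  expect_identical(vapply(frozen, function(r) r$size, integer(1)),
                   vapply(seeds2, function(r) r$size, integer(1)))

  expect_error(grow_regions(c(seeds2, seeds2[1]), dt2), "overlap")
})

test_that("seed meshes inherit region labels and approximate the regions", {
  dt <- two_ball_dt(18)
  regions <- grow_regions(threshold_regions(dt, 3), dt, 1)
  meshes <- seed_meshes(regions, dt, 2L)
  expect_length(meshes, 2L)
  expect_identical(vapply(meshes, function(m) m$instance_id, integer(1)),
                   c(1L, 2L))
  # ball regions: mesh radius within 1 px of the dt >= 1 core radius
  for (i in 1:2) {
    com <- regions[[i]]$center_of_mass
    r <- sqrt(rowSums(sweep(meshes[[i]]$vertices, 2, com)^2))
    expect_lt(abs(mean(r) - 7), 1)  # radius-8 ball eroded once
  }
  expect_length(seed_meshes(list(), dt), 0L)
})

test_that("segment_nuclei recovers every ball and filters specks", {
  n <- 64; g <- volume(array(0, c(n, n, n)), 1)
  centers <- rbind(c(12, 12, 12), c(34, 12, 14), c(50, 30, 12),
                   c(16, 40, 40), c(44, 44, 44))
  meshes <- lapply(1:5, function(i)
    make_icosphere(centers[i, ], 8, 3, instance_id = i))
  lt <- make_labels(meshes, g)
  # 1 µm voxels: the shrinkage weight scales with mesh edge length, so it is
  # set for this grid rather than the package's 0.35 µm default
  res <- segment_nuclei(lt$dt, nucleus_dt_params(alpha = 2))
  expect_length(res, 5L)
  gt_labels <- voxelize_instances(meshes, g)
  pred <- voxelize_instances(lapply(res, function(r) r$mesh), g)
  ji <- best_ji_map(gt_labels, pred)
  expect_true(all(ji$records$best_ji >= 0.85))

  # a spurious speck produces no surviving mesh
  speck <- array(0, dim(lt$dt$data))
  speck[30:31, 50, 50] <- 3
  noisy_dt <- volume(lt$dt$data + speck, 1)
  res2 <- segment_nuclei(noisy_dt, nucleus_dt_params(alpha = 2), s_min = 1)
  expect_length(res2, 5L)
  expect_gte(attr(res2, "n_removed"), 1L)

  # an empty dt yields an empty result
  expect_length(segment_nuclei(volume(array(0, c(16, 16, 16)), 1)), 0L)
})

test_that("membrane meshes wrap cells and preserve nucleus identity", {
  # concentric phantom: nucleus ball inside a larger cell ball
  n <- 48; c0 <- (n - 1) / 2
  g <- volume(array(0, c(n, n, n)), 1)
  nuc <- make_icosphere(rep(c0, 3), 6, 2, instance_id = 7L)
  cell <- make_icosphere(rep(c0, 3), 13, 3, instance_id = 7L)
  mdt <- make_labels(list(cell), g)$dt
  res <- segment_membranes(list(nuc), volume(array(as.numeric(mdt$data),
                                                   dim(mdt$data)), 1),
                           membrane_dt_params(alpha = 2.5))
  expect_length(res, 1L)
  expect_identical(res[[1]]$mesh$instance_id, 7L)
  r <- sqrt(rowSums(sweep(res[[1]]$mesh$vertices, 2, rep(c0, 3))^2))
  expect_lt(abs(mean(r) - 13), 1)
  # the nucleus centroid stays inside the membrane mesh
  expect_true(activemesh:::points_in_mesh(rbind(colMeans(nuc$vertices)),
                                          res[[1]]$mesh))
  expect_length(segment_membranes(list(), mdt), 0L)
})

test_that("adjacent membrane meshes stay essentially disjoint", {
  fr <- noiseless_phantom(n_cells = 4, n = 80, seed = 3)
  mdt <- oracle_predict(fr$cell_meshes, fr$membrane, per_instance = TRUE)$dt
  nuc_meshes <- fr$nucleus_meshes
  res <- segment_membranes(nuc_meshes, mdt)
  g <- fr$membrane
  vols <- lapply(res, function(r) binarize(r$mesh, g))
  for (i in 1:3) for (j in (i + 1):4) {
    ov <- sum(vols[[i]]$data & vols[[j]]$data)
    expect_lt(ov / min(sum(vols[[i]]$data), sum(vols[[j]]$data)), 0.01)
  }
  # instance ids inherited from the nuclei
  expect_identical(vapply(res, function(r) r$mesh$instance_id, integer(1)),
                   vapply(nuc_meshes, function(m) m$instance_id, integer(1)))
})
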