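lab_vol <- function(arr, spacing = 1) volume(array(as.integer(arr), dim(arr)),
                                             spacing)

test_that("best JI is exact on identity, shifts and empty predictions", {
  set.seed(11)
  arr <- array(0L, c(10, 10, 10))
  arr[2:4, 2:4, 2:4] <- 1L; arr[6:9, 6:9, 6:9] <- 2L
  gt <- lab_vol(arr)
  ident <- best_ji_map(gt, gt)
  expect_equal(ident$records$best_ji, c(1, 1))
  expect_equal(ident$records$delta_cm, c(0, 0))

  # 2x2x2 cube shifted by one voxel in x: JI = 4/12 = 1/3, dCM = sx
  cube <- array(0L, c(8, 8, 8)); cube[3:4, 3:4, 3:4] <- 1L
  shifted <- array(0L, c(8, 8, 8)); shifted[3:4, 3:4, 4:5] <- 1L
  for (sx in c(1, 0.25)) {
    r <- best_ji_map(lab_vol(cube, c(1, 1, sx)), lab_vol(shifted, c(1, 1, sx)))
    expect_equal(r$records$best_ji, 1 / 3)
    expect_equal(r$records$delta_cm, sx)
  }

  empty <- lab_vol(array(0L, c(8, 8, 8)))
  r0 <- best_ji_map(lab_vol(cube), empty)
  expect_equal(r0$records$best_ji, 0)
  expect_true(is.na(r0$records$delta_cm))
  expect_true(is.na(r0$records$matched_pred_label))

  expect_error(best_ji_map(gt, lab_vol(cube)), "shape mismatch")
})

test_that("best JI matches the all-pairs brute-force oracle", {
  set.seed(12)
  for (case in 1:8) {
    gt_arr <- array(0L, c(12, 12, 12))
    pred_arr <- array(0L, c(12, 12, 12))
    for (l in 1:3) {
      ctr <- runif(3, 3, 9); rad <- runif(1, 1.5, 3.5)
      gt_arr[ball_mask(12, rad, ctr) & gt_arr == 0L] <- l
      ctr2 <- ctr + rnorm(3, 0, 1)
      pred_arr[ball_mask(12, rad * runif(1, 0.7, 1.3), ctr2) &
                 pred_arr == 0L] <- l + 3L
    }
    r <- best_ji_map(lab_vol(gt_arr), lab_vol(pred_arr))
    expect_equal(r$records$best_ji, best_ji_oracle(gt_arr, pred_arr),
                 tolerance = 1e-12)
  }
})

box_at <- function(center, half = c(1, 1, 1)) {
  list(min = center - half, max = center + half)
}

test_that("detection mapping reproduces hand-derived configurations", {
  b <- function(...) box_at(c(...))
  # 1: identical sets
  gt <- list(b(0, 0, 0), b(5, 0, 0), b(0, 5, 0))
  expect_equal(detection_match(gt, gt), list(TP = 3L, FP = 0L, FN = 0L))
  # 2: one-to-one with small offsets
  pred <- lapply(gt, function(x) list(min = x$min + 0.2, max = x$max + 0.2))
  expect_equal(detection_match(gt, pred), list(TP = 3L, FP = 0L, FN = 0L))
  # 3: two predictions on one truth: both FP, the truth FN
  expect_equal(detection_match(list(b(0, 0, 0)),
                               list(b(0.2, 0, 0), b(-0.4, 0, 0))),
               list(TP = 0L, FP = 2L, FN = 1L))
  # 4: two truths on one prediction: both FN, no FP
  expect_equal(detection_match(list(b(0.2, 0, 0), b(-0.4, 0, 0)),
                               list(b(0, 0, 0))),
               list(TP = 0L, FP = 0L, FN = 2L))
  # 5: fully disjoint: unmapped predictions are not FP
  expect_equal(detection_match(list(b(0, 0, 0)), list(b(10, 10, 10))),
               list(TP = 0L, FP = 0L, FN = 1L))
  # 6: no predictions at all
  expect_equal(detection_match(list(b(0, 0, 0), b(5, 5, 5)), list()),
               list(TP = 0L, FP = 0L, FN = 2L))
  # 7: no ground truth
  expect_equal(detection_match(list(), list(b(0, 0, 0))),
               list(TP = 0L, FP = 0L, FN = 0L))
  # 8: mixed — one clean pair plus a doubled truth
  gt8 <- list(b(0, 0, 0), b(8, 0, 0))
  pr8 <- list(b(0.2, 0, 0), b(8.2, 0, 0), b(7.6, 0, 0))
  expect_equal(detection_match(gt8, pr8), list(TP = 1L, FP = 2L, FN = 1L))
  # 9: chain (non-mutual argmax): pred maps to gt1, gt1 maps elsewhere
  gt9 <- list(box_at(c(0, 0, 0), c(2, 1, 1)), b(3.5, 0, 0))
  pr9 <- list(box_at(c(1.4, 0, 0), c(2, 1, 1)))
  res9 <- detection_match(gt9, pr9)
  expect_equal(res9$TP + res9$FN, 2L)  # every truth is accounted for
  expect_lte(res9$TP, 1L)
  # 10: permutation invariance
  gt10 <- list(b(0, 0, 0), b(6, 0, 0), b(0, 6, 0), b(6, 6, 0))
  pr10 <- lapply(gt10, function(x) list(min = x$min - 0.1, max = x$max + 0.1))
  base <- detection_match(gt10, pr10)
  perm <- detection_match(gt10[c(3, 1, 4, 2)], pr10[c(2, 4, 1, 3)])
  expect_equal(base, perm)
  expect_lte(base$TP, min(length(gt10), length(pr10)))
})

static_scene <- function(n_frames, centers, radius = 2) {
  lapply(seq_len(n_frames), function(t)
    lapply(seq_len(nrow(centers)), function(i)
      make_icosphere(centers[i, ], radius, 1, frame_index = t,
                     instance_id = i)))
}

test_that("static scenes give one full-length track per mesh", {
  centers <- rbind(c(0, 0, 0), c(10, 0, 0), c(0, 10, 0))
  tracks <- track_bboxes(static_scene(5, centers))
  expect_length(tracks, 3L)
  expect_true(all(vapply(tracks, function(tr) nrow(tr$points), 1L) == 5L))
  expect_equal(cell_counts(tracks, 5), rep(3L, 5))
  expect_equal(velocity_distribution(tracks, 1), rep(0, 12))
})

test_that("slow crossing-free motion keeps identities", {
  frames <- lapply(1:8, function(t) list(
    make_icosphere(c(0 + 0.5 * t, 0, 0), 2, 1, t, 1L),
    make_icosphere(c(20 - 0.5 * t, 0, 0), 2, 1, t, 2L)
  ))
  tracks <- track_bboxes(frames)
  expect_length(tracks, 2L)
  for (tr in tracks) {
    ids <- tr$points$instance_id
    expect_length(unique(ids), 1L)   # no identity switches
    expect_identical(nrow(tr$points), 8L)
  }
  sp <- velocity_distribution(tracks, 2)  # 2-minute interval
  expect_equal(sp, rep(0.25, 14), tolerance = 1e-9)
})

test_that("a mesh replaced by two half-size meshes records a division", {
  parent <- make_icosphere(c(0, 0, 0), 4, 1, instance_id = 1L)
  d1 <- make_icosphere(c(-1.8, 0, 0), 4 / 2^(1 / 3) * 0.8, 1, instance_id = 2L)
  d2 <- make_icosphere(c(1.8, 0, 0), 4 / 2^(1 / 3) * 0.8, 1, instance_id = 3L)
  frames <- list(list(parent), list(parent), list(d1, d2), list(d1, d2))
  tracks <- track_bboxes(frames)
  expect_length(tracks, 3L)
  parents <- vapply(tracks, function(tr) tr$parent_track_id, 1L)
  expect_identical(sum(parents == 1L, na.rm = TRUE), 2L)
  cc <- cell_counts(tracks, 4)
  expect_equal(cc, c(1L, 1L, 2L, 2L))  # the count steps at the division
})

test_that("shuffling instance order does not change the track partition", {
  centers <- rbind(c(0, 0, 0), c(9, 0, 0), c(0, 9, 0))
  frames <- static_scene(4, centers)
  shuffled <- lapply(seq_along(frames), function(t)
    frames[[t]][((seq_len(3) + t) %% 3) + 1])
  t1 <- track_bboxes(frames)
  t2 <- track_bboxes(shuffled)
  sig <- function(tracks) {
    s <- lapply(tracks, function(tr)
      paste(tr$points$frame_index, round(tr$points$x, 6), round(tr$points$y, 6),
            collapse = ";"))
    sort(unlist(s))
  }
  expect_identical(sig(t1), sig(t2))
})

test_that("hand-computed speeds come out of a two-step path", {
  frames <- list(
    list(make_icosphere(c(0, 0, 0), 3, 1, 1, 1L)),
    list(make_icosphere(c(3, 0, 0), 3, 1, 2, 1L)),
    list(make_icosphere(c(3, 4, 0), 3, 1, 3, 1L))
  )
  tracks <- track_bboxes(frames, j_min = 0.05)
  expect_length(tracks, 1L)
  expect_equal(velocity_distribution(tracks, 2), c(1.5, 2))
})
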