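test_that("SLF waypoint ROIs sit on the commissure planes, disjoint and mirrored", {
  rois <- define_slf_rois()
  expect_length(rois, 8L)
  for (r in rois) expect_s3_class(r, "waypoint_roi")
  # anterior ROIs on y = 2, posterior on y = -25
  for (h in c("L", "R")) {
    expect_equal(rois[[paste0(h, "_SLF_II_anterior")]]$y_mm, 2)
    expect_equal(rois[[paste0(h, "_SLF_III_anterior")]]$y_mm, 2)
    expect_equal(rois[[paste0(h, "_posterior")]]$y_mm, -25)
    # dorsal (II) box strictly above ventral (III) box: disjoint
    expect_gt(rois[[paste0(h, "_SLF_II_anterior")]]$z_range[1],
              rois[[paste0(h, "_SLF_III_anterior")]]$z_range[2])
  }
  # left/right are reflections in the midsagittal plane
  expect_equal(rois$L_SLF_II_anterior$x_range,
               rev(-rois$R_SLF_II_anterior$x_range))
  expect_equal(rois$L_posterior$x_range, rev(-rois$R_posterior$x_range))
})

test_that("plane ROIs transform analytically under axis-aligned affines", {
  roi <- waypoint_roi_plane("p", 2, c(10, 40), c(5, 20), 3)
  ident <- transform_rois(roi, diag(4))
  expect_equal(ident$y_mm, roi$y_mm)
  expect_equal(ident$x_range, roi$x_range)

  shift <- diag(4); shift[1:3, 4] <- c(1, -7, 2)
  moved <- transform_rois(roi, shift)
  expect_equal(moved$y_mm, -5)
  expect_equal(moved$x_range, c(11, 41))
  expect_equal(moved$z_range, c(7, 22))

  rot <- diag(4); rot[1, 2] <- 0.3
  expect_error(transform_rois(roi, rot), "roi_transform_error")
})

test_that("mask ROI resampling round-trips voxel counts within 2 percent", {
  set.seed(8)
  d3 <- c(20L, 20L, 20L)
  mask <- array(FALSE, d3)
  mask[6:15, 8:14, 5:16] <- TRUE
  aff <- diag(c(1.5, 1.5, 1.5, 1))
  roi <- waypoint_roi_mask("m", mask, aff)
  tr <- diag(4); tr[1:3, 4] <- c(0.6, -0.8, 0.4)   # sub-voxel translation
  target <- list(shape = d3, affine = aff)
  there <- transform_rois(roi, tr, target = target)
  back <- transform_rois(there, solve(tr), target = target)
  n0 <- sum(roi$mask); n1 <- sum(back$mask)
  expect_lt(abs(n1 - n0) / n0, 0.02)
})

test_that("waypoint assignment matches phantom construction exactly", {
  fx <- left_tracked()
  scene <- fx$scene
  tg <- fx$tg
  b2 <- assign_by_waypoints(tg, scene$rois$L_SLF_II_anterior,
                            scene$rois$L_posterior, "SLF_II", "L")
  b3 <- assign_by_waypoints(tg, scene$rois$L_SLF_III_anterior,
                            scene$rois$L_posterior, "SLF_III", "L")
  expect_gt(length(b2), 50L)
  expect_gt(length(b3), 50L)
  # disjoint anterior ROIs give disjoint branch membership
  expect_length(intersect(b2$indices, b3$indices), 0L)

  # ground truth: a streamline belongs to the bundle whose tube it runs in
  bid <- scene$field$bundle_id
  truth_of <- function(i) {
    s <- tg$streamlines[[i]]
    vox <- round(world_to_voxel(scene$affine, s))
    lin <- 1 + vox[, 1] + dim(bid)[1] * (vox[, 2] + dim(bid)[2] * vox[, 3])
    ids <- bid[lin[lin >= 1 & lin <= length(bid)]]
    ids <- ids[ids > 0]
    if (length(ids) == 0) return(NA_integer_)
    as.integer(names(which.max(table(ids))))
  }
  lab2 <- vapply(b2$indices, truth_of, integer(1L))
  lab3 <- vapply(b3$indices, truth_of, integer(1L))
  expect_true(all(lab2 == match("L_SLF_II", names(scene$specs))))
  expect_true(all(lab3 == match("L_SLF_III", names(scene$specs))))

  # membership is invariant to point-order reversal and ROI order
  tg_rev <- tractogram(lapply(tg$streamlines,
                              function(s) s[rev(seq_len(nrow(s))), ]),
                       tg$reference_affine, tg$reference_shape,
                       validate = FALSE)
  b2r <- assign_by_waypoints(tg_rev, scene$rois$L_posterior,
                             scene$rois$L_SLF_II_anterior, "SLF_II", "L")
  expect_identical(b2r$indices, b2$indices)

  # a streamline crossing only one ROI is not a member
  expect_warning(
    post_only <- assign_by_waypoints(
      tractogram(tg$streamlines[b2$indices], tg$reference_affine,
                 tg$reference_shape, validate = FALSE),
      scene$rois$L_SLF_III_anterior, scene$rois$L_posterior, "x", "L"),
    "empty bundle")
  expect_length(post_only$indices, 0L)
})

test_that("probability-map scoring averages trilinear samples along streamlines", {
  aff <- diag(c(1.5, 1.5, 1.5, 1))
  shape <- c(20L, 20L, 20L)
  sl <- cbind(seq(3, 25.5, by = 0.75), 15, 15)
  tg <- tractogram(list(sl), aff, shape)
  b <- tract_bundle("t", "L", tg, 1L)
  ones <- array(1, shape)
  expect_equal(score_against_probability_map(b, ones, aff), 1)
  expect_equal(score_against_probability_map(b, array(0, shape), aff), 0)
  # half the points in p = 1, half in p = 0: score ~ 0.5
  half <- array(0, shape)
  half[1:10, , ] <- 1   # world x < ~14.25
  sc <- score_against_probability_map(b, half, aff)
  expect_lt(abs(sc - 0.5), 0.06)
  expect_error(score_against_probability_map(b, ones * 2, aff),
               "probability_map_error")
})

test_that("bundle cleaning drops score and length outliers and nothing else", {
  aff <- diag(c(1.5, 1.5, 1.5, 1))
  shape <- c(80L, 30L, 30L)
  base <- lapply(1:100, function(i)
    cbind(seq(6, 66, by = 0.75), 15 + (i %% 10) * 0.5, 15))
  # one artificially doubled-length streamline
  outlier <- cbind(seq(6, 126, by = 0.75) / 1.08, 16, 15)
  tg <- tractogram(c(base, list(outlier)), aff, shape, validate = FALSE)
  b <- tract_bundle("t", "L", tg, seq_len(101L))
  cleaned <- clean_bundle(b, scores = NULL, length_z_max = 3)
  expect_false(101L %in% cleaned$indices)
  expect_identical(cleaned$indices, 1:100)

  # homogeneous bundle with default quantile cleaning retains >= 95%
  b100 <- tract_bundle("t", "L",
                       tractogram(base, aff, shape, validate = FALSE),
                       1:100)
  set.seed(2)
  scores <- runif(100, 0.8, 1)
  kept <- clean_bundle(b100, scores, score_quantile = 0.05)
  expect_gte(length(kept), 95L)
  # subset property
  expect_true(all(kept$indices %in% b100$indices))

  # identity settings are the identity
  ident <- clean_bundle(b, scores = rep(1, 101), score_quantile = 0,
                        length_z_max = Inf)
  expect_identical(ident$indices, b$indices)
})

test_that("the lesion screen applies the probability threshold rule", {
  d3 <- c(10L, 10L, 10L)
  prob <- array(0.1, d3)
  prob[6:10, , ] <- 0.9
  lesion_hi <- array(FALSE, d3); lesion_hi[7:8, 4:6, 4:6] <- TRUE
  lesion_lo <- array(FALSE, d3); lesion_lo[1:3, 4:6, 4:6] <- TRUE
  expect_identical(lesion_overlap_screen(lesion_hi, prob), "affected")
  expect_identical(lesion_overlap_screen(lesion_lo, prob), "not_affected")
  # single boundary voxel just above threshold flips the decision
  prob2 <- array(0.1, d3)
  prob2[5, 5, 5] <- 0.51
  lesion1 <- array(FALSE, d3); lesion1[5, 5, 5] <- TRUE
  expect_identical(lesion_overlap_screen(lesion1, prob2), "affected")
  prob2[5, 5, 5] <- 0.5
  expect_identical(lesion_overlap_screen(lesion1, prob2), "not_affected")
  # majority rule: one hot voxel among many cold ones is not enough
  lesion_mix <- lesion_lo; lesion_mix[5, 5, 5] <- TRUE
  prob2[5, 5, 5] <- 0.9
  expect_identical(lesion_overlap_screen(lesion_mix, prob2,
                                         rule = "majority"),
                   "not_affected")
  expect_warning(out <- lesion_overlap_screen(array(FALSE, d3), prob),
                 "empty lesion")
  expect_identical(out, "not_affected")
})

test_that("the scene's planted lesion is detected through the screen", {
  scene <- left_scene()
  expect_identical(
    lesion_overlap_screen(scene$lesion_mask, scene$prob_map$L_SLF_II),
    "affected")
  # the ventral bundle's map is not touched by the dorsal lesion
  expect_identical(
    lesion_overlap_screen(scene$lesion_mask, scene$prob_map$L_SLF_III),
    "not_affected")
})
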