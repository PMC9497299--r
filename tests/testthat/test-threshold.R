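make_box_roi <- function(grid, lo, hi) {
  occ <- array(FALSE, grid$shape)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(occ, grid)
}

test_that("lesion SUVmax finds the hottest ROI voxel with deterministic ties", {
  g <- small_grid(c(8, 8, 4))
  vals <- array(0.5, g$shape)
  roi <- make_box_roi(g, c(2, 2, 1), c(6, 6, 3))
  # uniform values: tie broken to the lexicographically smallest ROI index
  pet <- suv_volume(vals, g)
  peak <- lesion_suvmax(pet, roi)
  expect_equal(peak$suv, 0.5)
  expect_identical(peak$index, c(2L, 2L, 1L))

  vals[4, 5, 2] <- 7 # planted hottest voxel
  vals[8, 8, 4] <- 9 # global max outside the ROI
  pet <- suv_volume(vals, g)
  peak <- lesion_suvmax(pet, roi)
  expect_equal(peak$suv, 7)
  expect_identical(peak$index, c(4L, 5L, 2L))

  empty <- binary_mask(array(FALSE, g$shape), g)
  expect_error(lesion_suvmax(pet, empty), "empty")
})

test_that("threshold segmentation matches the hand-enumerated 3x3x3 example", {
  g <- small_grid(c(3, 3, 3))
  vals <- array(1, g$shape)
  vals[2, 2, 2] <- 10
  vals[1, 2, 2] <- vals[3, 2, 2] <- vals[2, 1, 2] <- vals[2, 3, 2] <-
    vals[2, 2, 1] <- vals[2, 2, 3] <- 6
  pet <- suv_volume(vals, g)
  roi <- binary_mask(array(TRUE, g$shape), g)
  seg <- threshold_segment(pet, roi, 50) # cutoff 5: centre + 6 face voxels
  expect_identical(sum(seg$occupancy), 7L)
  expect_true(seg$occupancy[2, 2, 2])
  expect_true(all(seg$occupancy[vals >= 5]))
  expect_false(any(seg$occupancy[vals < 5]))
})

test_that("t = 100% keeps only the SUVmax voxels connected to the seed", {
  g <- small_grid(c(9, 5, 3))
  vals <- array(1, g$shape)
  vals[2, 2, 2] <- vals[3, 2, 2] <- 8  # seed pair
  vals[8, 4, 2] <- 8                   # same value, disconnected at tau = 8
  pet <- suv_volume(vals, g)
  roi <- binary_mask(array(TRUE, g$shape), g)
  seg <- threshold_segment(pet, roi, 100)
  expect_identical(sum(seg$occupancy), 2L)
  expect_true(seg$occupancy[2, 2, 2] && seg$occupancy[3, 2, 2])
  expect_false(seg$occupancy[8, 4, 2])
})

test_that("zero uptake in the ROI is rejected", {
  g <- small_grid(c(5, 5, 3))
  pet <- suv_volume(array(0, g$shape), g)
  roi <- binary_mask(array(TRUE, g$shape), g)
  expect_error(threshold_segment(pet, roi, 50), "SUVmax is zero")
  expect_error(threshold_segment(pet, roi, 101), "t_percent")
})

test_that("seeded growth agrees with a breadth-first flood-fill oracle", {
  set.seed(14)
  for (rep in 1:6) {
    g <- small_grid(c(8, 7, 5))
    vals <- array(runif(prod(g$shape), 0, 10), g$shape)
    pet <- suv_volume(vals, g)
    roi <- make_box_roi(g, c(2, 2, 1), c(7, 6, 4))
    for (conn in c(26, 6)) for (clip in c(FALSE, TRUE)) {
      peak <- lesion_suvmax(pet, roi)
      for (tp in c(20, 50, 80)) {
        seg <- threshold_segment(pet, roi, tp, clip_to_roi = clip,
                                 connectivity = conn)
        want <- bfs_segment(vals, peak$index, (tp / 100) * peak$suv,
                            connectivity = conn,
                            region = if (clip) roi$occupancy else NULL)
        expect_identical(seg$occupancy, want)
      }
    }
  }
})

test_that("a suprathreshold bridge leaks into a decoy hot spot unless clipped", {
  g <- image_grid(c(40, 24, 16), spacing = c(4, 4, 5))
  ph <- make_phantom(g, lesion_center = c(50, 46, 37.5),
                     semi_axes = c(14, 12, 10), lesion_uptake = 10,
                     background_uptake = 0.2, psf_fwhm_mm = 10, noise_sd = 0,
                     decoy = list(center = c(78, 46, 37.5), radius_mm = 8,
                                  uptake = 8))
  # ROI around the lesion only, excluding the decoy
  roi <- make_box_roi(g, c(5, 4, 2), c(17, 20, 14))
  decoy_vox <- (stapleseg:::world_coordinates(g)$x - 78)^2 +
    (stapleseg:::world_coordinates(g)$y - 46)^2 +
    (stapleseg:::world_coordinates(g)$z - 37.5)^2 <= 8^2
  seg_free <- threshold_segment(ph$pet, roi, 14, clip_to_roi = FALSE)
  seg_clip <- threshold_segment(ph$pet, roi, 14, clip_to_roi = TRUE)
  expect_gt(sum(seg_free$occupancy & decoy_vox), 0)     # leakage reproduced
  expect_identical(sum(seg_clip$occupancy & decoy_vox), 0L) # and prevented
  expect_gt(sum(seg_clip$occupancy), 0)
})

test_that("a lesion whose reference is its own segmentation is recovered", {
  ph <- make_phantom(grid = image_grid(c(32, 32, 16), spacing = c(4, 4, 5)),
                     lesion_center = c(62, 62, 37.5),
                     semi_axes = c(16, 14, 12), seed = 15)
  roi <- default_roi(ph$truth, pad = 3)
  ref <- threshold_segment(ph$pet, roi, 30)
  sw <- sweep_thresholds(list(list(pet = ph$pet, roi = roi)), list(ref))
  expect_equal(sw$dice[1, match(30, sw$thresholds)], 1.0)
  expect_equal(sw$best_mean_dice, 1.0)
  expect_identical(length(sw$thresholds), 201L)
  expect_equal(sw$mean_dice, unname(colMeans(sw$dice)))
  expect_equal(sw$best_mean_dice, max(sw$mean_dice))
})

test_that("segmented volume is non-increasing in the threshold and lesion order is irrelevant", {
  set.seed(16)
  lesions <- list(); refs <- list()
  for (i in 1:3) {
    ph <- make_phantom(grid = image_grid(c(32, 32, 16), spacing = c(4, 4, 5)),
                       lesion_center = c(62, 62, 37.5) + runif(3, -4, 4),
                       semi_axes = runif(3, 10, 16), seed = 100 + i)
    roi <- default_roi(ph$truth, pad = 3)
    lesions[[i]] <- list(pet = ph$pet, roi = roi,
                         lesion_id = sprintf("L%d", i))
    refs[[i]] <- ph$truth
  }
  sw <- sweep_thresholds(lesions, refs, t_step = 2)
  # nesting: suprathreshold components shrink as t rises
  for (i in 1:3) {
    cap <- stapleseg:::lesion_capacity(lesions[[i]]$pet, lesions[[i]]$roi)
    sizes <- vapply(sw$thresholds,
                    function(t) sum(cap$capacity >= t / 100 * cap$suvmax),
                    numeric(1))
    expect_true(all(diff(sizes) <= 0))
  }
  perm <- c(3, 1, 2)
  sw_p <- sweep_thresholds(lesions[perm], refs[perm], t_step = 2)
  expect_identical(sw_p$best_threshold, sw$best_threshold)
  expect_equal(sw_p$dice[rownames(sw$dice), ], sw$dice)
  expect_equal(sw_p$per_lesion_best[names(sw$per_lesion_best)],
               sw$per_lesion_best)
})

test_that("validation evaluation applies one fixed threshold without refitting", {
  set.seed(17)
  lesions <- list(); refs <- list()
  for (i in 1:2) {
    ph <- make_phantom(grid = image_grid(c(32, 32, 16), spacing = c(4, 4, 5)),
                       lesion_center = c(62, 62, 37.5),
                       semi_axes = runif(3, 10, 16), seed = 200 + i)
    roi <- default_roi(ph$truth, pad = 3)
    lesions[[i]] <- list(pet = ph$pet, roi = roi)
    refs[[i]] <- threshold_segment(ph$pet, roi, 25)
  }
  ev <- evaluate_on_validation(25, lesions, refs)
  expect_equal(ev$dice, c(1, 1))
  expect_equal(ev$hausdorff_mm, c(0, 0))
  expect_identical(nrow(ev), 2L)
  expect_error(evaluate_on_validation(120, lesions, refs), "threshold")
})
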