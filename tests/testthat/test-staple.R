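test_that("unanimous raters recover the common mask with perfect performance", {
  oset <- unanimous_set()
  fit <- staple(oset)
  expect_true(fit$converged)
  expect_true(all(abs(fit$sensitivity - 1) < 1e-6))
  expect_true(all(abs(fit$specificity - 1) < 1e-6))
  expect_identical(consensus_mask(fit)$occupancy, oset$masks[[1]]$occupancy)
})

test_that("one E-step reproduces the hand-worked posterior weights", {
  # 4 x 4 x 1 grid, three raters, init p = q = 0.9. The union bounding box
  # plus margin covers all 16 voxels, so gamma = (4 + 3 + 3)/48 = 5/24.
  # With s raters voting 1 at a voxel, W = 5*9^s / (5*9^s + 19*9^(3-s)),
  # worked out per occupancy pattern:
  #   s = 3: 3645/3664,  s = 2: 405/576,  s = 1: 45/1584,  s = 0: 5/13856
  g <- image_grid(c(4, 4, 1), spacing = c(1, 1, 1))
  m1 <- m2 <- m3 <- array(FALSE, g$shape)
  m1[1:2, 1:2, 1] <- TRUE                       # 4 voxels
  m2[1, 1, 1] <- m2[2, 1, 1] <- m2[1, 2, 1] <- TRUE  # 3 voxels
  m3[1, 1, 1] <- m3[2, 2, 1] <- m3[3, 3, 1] <- TRUE  # 3 voxels
  fit <- staple(list(r1 = binary_mask(m1, g), r2 = binary_mask(m2, g),
                     r3 = binary_mask(m3, g)),
                max_iter = 1, bbox_margin = 5)
  expect_equal(fit$prior, 5 / 24, tolerance = 1e-12)
  W <- fit$weights
  expect_equal(W[1, 1, 1], 3645 / 3664, tolerance = 1e-9) # all three vote 1
  expect_equal(W[2, 1, 1], 405 / 576, tolerance = 1e-9)   # two votes
  expect_equal(W[3, 3, 1], 45 / 1584, tolerance = 1e-9)   # one vote
  expect_equal(W[4, 4, 1], 5 / 13856, tolerance = 1e-9)   # no votes
  expect_false(fit$converged)
  expect_identical(fit$n_iterations, 1L)
})

test_that("parameter recovery error shrinks with voxel count", {
  slab_truth <- function(shape, spacing = c(1, 1, 1)) {
    g <- image_grid(shape, spacing = spacing)
    occ <- array(FALSE, g$shape); occ[seq_len(shape[1] / 2), , ] <- TRUE
    binary_mask(occ, g)
  }
  p <- c(0.85, 0.9, 0.95); q <- c(0.92, 0.88, 0.9)
  om <- observer_model("iid_flip", sensitivity = p, specificity = q)
  err_at <- function(truth, seed) {
    os <- simulate_observers(truth, om, 3, seed = seed)
    fit <- staple(os)
    max(abs(fit$sensitivity - p), abs(fit$specificity - q))
  }
  e_small <- err_at(slab_truth(c(16, 16, 4)), 21)   # ~1e3 voxels
  e_large <- err_at(slab_truth(c(64, 64, 24)), 21)  # ~1e5 voxels
  expect_lt(e_large, e_small)
  expect_lt(e_large, 0.02)
})

test_that("complementing all masks swaps sensitivity and specificity", {
  g <- small_grid(c(20, 20, 8))
  occ <- array(FALSE, g$shape); occ[1:10, , ] <- TRUE
  truth <- binary_mask(occ, g)
  om <- observer_model("iid_flip", sensitivity = c(0.85, 0.92, 0.9),
                       specificity = c(0.9, 0.87, 0.94))
  os <- simulate_observers(truth, om, 3, seed = 31)
  comp <- lapply(os$masks, function(m) binary_mask(!m$occupancy, g))
  # margin large enough that both runs use the full grid as their region
  fit <- staple(os$masks, tol = 1e-10, max_iter = 50, bbox_margin = 64)
  fit_c <- staple(comp, tol = 1e-10, max_iter = 50, bbox_margin = 64)
  expect_equal(unname(fit_c$sensitivity), unname(fit$specificity),
               tolerance = 1e-6)
  expect_equal(unname(fit_c$specificity), unname(fit$sensitivity),
               tolerance = 1e-6)
})

test_that("two perfectly disagreeing raters leave the weights at the prior", {
  g <- small_grid(c(10, 10, 4))
  occ <- array(FALSE, g$shape); occ[1:5, , ] <- TRUE
  a <- binary_mask(occ, g)
  b <- binary_mask(!occ, g)
  fit <- staple(list(a = a, b = b), bbox_margin = 0)
  expect_true(fit$converged)
  expect_true(all(abs(fit$weights - fit$prior) < 1e-9))
})

test_that("the EM objective is non-decreasing for realistic observers", {
  ph <- make_phantom(grid = image_grid(c(32, 32, 16), spacing = c(4, 4, 5)),
                     lesion_center = c(62, 62, 37.5),
                     semi_axes = c(14, 12, 10), seed = 8)
  om <- observer_model("boundary_field", boundary_sd_mm = 3,
                       bias_mm = c(-2, 0, 2))
  os <- simulate_observers(ph$truth, om, 3, seed = 9)
  fit <- staple(os)
  ll <- fit$trace$loglik
  expect_true(all(diff(ll) >= -1e-6 * pmax(abs(ll[-length(ll)]), 1)))
})

test_that("the consensus is insensitive to the bounding-box margin", {
  ph <- make_phantom(grid = image_grid(c(32, 32, 16), spacing = c(4, 4, 5)),
                     lesion_center = c(62, 62, 37.5),
                     semi_axes = c(14, 12, 10), seed = 12)
  om <- observer_model("boundary_field", boundary_sd_mm = 2,
                       bias_mm = c(-1, 0, 1))
  os <- simulate_observers(ph$truth, om, 3, seed = 13)
  fit5 <- staple(os, bbox_margin = 5)
  fit10 <- staple(os, bbox_margin = 10)
  expect_identical(consensus_mask(fit5)$occupancy,
                   consensus_mask(fit10)$occupancy)
  expect_equal(unname(fit5$sensitivity), unname(fit10$sensitivity),
               tolerance = 1e-3)
})

test_that("degenerate inputs and cutoffs are rejected", {
  g <- small_grid(c(6, 6, 3))
  e <- binary_mask(array(FALSE, g$shape), g)
  expect_error(staple(list(a = e, b = e)), "empty")
  fit <- staple(unanimous_set())
  expect_error(consensus_mask(fit, cutoff = 0), "cutoff")
  expect_error(consensus_mask(fit, cutoff = 1), "cutoff")
  expect_error(staple(unanimous_set(), init_sensitivity = 1), "strictly")
})

test_that("weights exactly at the cutoff are included in the consensus", {
  g <- small_grid(c(4, 4, 1))
  w <- array(0, g$shape); w[2, 2, 1] <- 0.5; w[3, 3, 1] <- 0.4999
  fake <- structure(list(weights = w, grid = g), class = "staple")
  cm <- consensus_mask(fake, cutoff = 0.5)
  expect_true(cm$occupancy[2, 2, 1])
  expect_false(cm$occupancy[3, 3, 1])
  # all-zero weights give an empty mask
  fake0 <- structure(list(weights = array(0, g$shape), grid = g),
                     class = "staple")
  expect_identical(sum(consensus_mask(fake0)$occupancy), 0L)
})

test_that("model-object methods behave like a fitted model", {
  oset <- unanimous_set()
  fit <- staple(oset)
  co <- coef(fit)
  expect_identical(dim(co), c(3L, 2L))
  expect_identical(colnames(co), c("sensitivity", "specificity"))
  expect_s3_class(summary(fit), "summary.staple")
  expect_output(print(fit), "STAPLE")
  expect_identical(fitted(fit), fit$weights)
  expect_true(is.finite(as.numeric(logLik(fit))))
  pm <- predict(fit)
  expect_s3_class(pm, "binary_mask")
  sims <- simulate(fit, nsim = 2, seed = 99)
  expect_length(sims, 2)
  expect_s3_class(sims[[1]], "observer_set")
  expect_identical(names(sims[[1]]$masks), fit$observers)
})
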