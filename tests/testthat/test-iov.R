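unanimous_study <- function(n_lesions = 2, n_obs = 3) {
  g <- image_grid(c(16, 16, 8), spacing = c(4, 4, 5))
  sets <- list()
  for (i in seq_len(n_lesions)) {
    occ <- array(FALSE, g$shape)
    occ[(2 + i):(8 + i), 4:10, 3:6] <- TRUE
    m <- binary_mask(occ, g)
    for (mod in c("MRI", "MRI_PET")) {
      masks <- rep(list(m), n_obs)
      names(masks) <- paste0("obs", seq_len(n_obs))
      sets[[length(sets) + 1L]] <- observer_set(
        masks, lesion_id = sprintf("L%d", i), modality = mod)
    }
  }
  sets
}

test_that("unanimous observers give perfect agreement in every record", {
  sets <- unanimous_study(n_lesions = 2, n_obs = 3)
  iov <- compute_iov(sets)
  expect_identical(nrow(iov), 2L * 3L * 2L) # lesions x observers x modalities
  expect_true(all(iov$dice == 1))
  expect_true(all(iov$hausdorff_mm == 0))
  expect_equal(iov$volume_cm3, iov$consensus_volume_cm3)
})

test_that("mismatched observers across conditions are rejected", {
  sets <- unanimous_study(n_lesions = 1, n_obs = 3)
  names(sets[[2]]$masks)[1] <- "someone_else"
  expect_error(compute_iov(sets), "different observers")
})

test_that("a planted reduction in contouring noise raises the PET-condition Dice", {
  for (s in 1:2) {
    st <- make_study(n_lesions = 5, seed = 500 + s)
    iov <- compute_iov(st)
    m <- tapply(iov$dice, iov$modality, mean)
    expect_gt(m["MRI_PET"], m["MRI"])
  }
})

test_that("the signed-rank statistic matches a hand-worked n = 8 example", {
  # differences 2, -1, 4, 3, -2.5, 5, 1.5, 0.5; ranks of |d| are
  # 4, 2, 7, 6, 5, 8, 3, 1 so V = 4+7+6+8+3+1 = 29; exact two-sided
  # p = 2 * P(V <= 7) = 2 * 19/256 (19 subsets of {1..8} sum to <= 7)
  d <- c(2, -1, 4, 3, -2.5, 5, 1.5, 0.5)
  base <- c(10, 11, 9, 12, 13, 8, 10.5, 9.5)
  rec <- data.frame(
    lesion_id = rep(sprintf("L%d", 1:4), each = 2),
    observer_id = rep(c("a", "b"), 4),
    modality = "MRI",
    dice = base + d, hausdorff_mm = 1, volume_cm3 = 1,
    consensus_volume_cm3 = 1)
  rec2 <- rec; rec2$modality <- "MRI_PET"; rec2$dice <- base
  cmp <- compare_modalities(rbind(rec, rec2), "dice")
  expect_identical(cmp$wilcoxon_statistic, 29)
  expect_equal(cmp$p_value, 2 * 19 / 256, tolerance = 1e-12)
  expect_identical(cmp$n_pairs, 8L)
})

test_that("exact signed-rank p agrees with exhaustive sign enumeration", {
  set.seed(18)
  for (n in c(6, 9, 12)) {
    x <- round(runif(n, 5, 15), 3)
    y <- x + round(rnorm(n, 0.3, 1.2), 3)
    rec <- data.frame(
      lesion_id = sprintf("L%d", seq_len(n)), observer_id = "a",
      modality = "MRI", dice = x, hausdorff_mm = 1, volume_cm3 = 1,
      consensus_volume_cm3 = 1)
    rec2 <- rec; rec2$modality <- "MRI_PET"; rec2$dice <- y
    cmp <- compare_modalities(rbind(rec, rec2), "dice")
    expect_equal(cmp$p_value, enum_signed_rank_p(x - y), tolerance = 1e-12)
  }
})

test_that("degenerate and unbalanced record tables are rejected", {
  sets <- unanimous_study(n_lesions = 1, n_obs = 3)
  iov <- compute_iov(sets)
  expect_error(compare_modalities(iov, "dice"), "zero")
  expect_error(compare_modalities(iov[-1, ], "dice"), "once per modality")
})

test_that("the comparison is invariant to record ordering", {
  st <- make_study(n_lesions = 4, seed = 77)
  iov <- compute_iov(st)
  set.seed(19)
  shuffled <- iov[sample(nrow(iov)), ]
  a <- compare_modalities(iov, "hausdorff")
  b <- compare_modalities(shuffled, "hausdorff")
  expect_identical(a$p_value, b$p_value)
  expect_identical(a$wilcoxon_statistic, b$wilcoxon_statistic)
})

test_that("Spearman correlation reproduces its defining computation", {
  expect_equal(correlate_threshold_volume(1:10, (1:10)^2)$spearman_rho, 1.0)
  expect_equal(correlate_threshold_volume(10:1, (1:10)^3)$spearman_rho, -1.0)
  set.seed(20)
  x <- sample(seq(10, 40, 0.5), 10, replace = TRUE) # ties likely
  y <- runif(10, 1, 60)
  r <- correlate_threshold_volume(x, y)
  expect_equal(r$spearman_rho, spearman_oracle(x, y), tolerance = 1e-12)
  expect_true(r$p_value >= 0 && r$p_value <= 1)
  expect_error(correlate_threshold_volume(rep(14, 5), runif(5)), "constant")
  expect_error(correlate_threshold_volume(1:2, 1:2), "at least 3")
})

test_that("run_study produces a coherent, reproducible bundle of outputs", {
  cfg <- list(seed = 42,
              synthetic = list(n_lesions = 3, n_validation = 2),
              sweep = list(t_step = 2))
  out1 <- withr::local_tempdir()
  res <- run_study(cfg, out_dir = out1, quiet = TRUE)
  expect_identical(sort(list.files(out1)),
                   sort(c("iov.csv", "manifest.json", "stats.json",
                          "sweep.csv", "sweep_summary.json",
                          "validation.csv")))
  expect_identical(nrow(res$iov), 3L * 5L * 2L)
  expect_s3_class(res$sweep, "threshold_sweep")
  expect_identical(nrow(res$validation), 2L)
  # outputs parse and agree with the in-memory result
  sj <- jsonlite::read_json(file.path(out1, "sweep_summary.json"))
  expect_equal(sj$best_threshold, res$sweep$best_threshold)
  iov_csv <- utils::read.csv(file.path(out1, "iov.csv"))
  expect_equal(iov_csv$dice, res$iov$dice)

  # byte-identical rerun under the same seed
  out2 <- withr::local_tempdir()
  run_study(cfg, out_dir = out2, quiet = TRUE)
  for (f in list.files(out1))
    expect_identical(readLines(file.path(out1, f)),
                     readLines(file.path(out2, f)),
                     info = f)
})

test_that("a study without PET skips the sweep with a notice", {
  cfg <- list(seed = 5, synthetic = list(n_lesions = 2, modalities = "MRI"))
  expect_message(res <- run_study(cfg), "skipping the threshold sweep")
  expect_null(res$sweep)
  expect_null(res$stats)
  expect_identical(nrow(res$iov), 2L * 5L)
})
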