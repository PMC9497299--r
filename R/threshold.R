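#' Maximum SUV within a lesion region
#'
#' Returns the maximum standardized uptake value over the voxels of a
#' search region, together with the voxel attaining it. Ties are broken
#' toward the lexicographically smallest (i, j, k) index so the seed voxel
#' is deterministic.
#'
#' @param pet an [suv_volume()].
#' @param roi a non-empty [binary_mask()] on the same grid delimiting the
#'   lesion search region.
#' @return A list with `suv` (the maximum) and `index` (1-based voxel
#'   triple).
#' @export
lesion_suvmax <- function(pet, roi) {
  stopifnot(inherits(pet, "suv_volume"), inherits(roi, "binary_mask"))
  assert_same_grid(pet, roi)
  if (!any(roi$occupancy)) stop("ROI is empty", call. = FALSE)
  vals <- pet$values[roi$occupancy]
  smax <- max(vals)
  cand <- which(roi$occupancy & pet$values == smax, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2], cand[, 3]), , drop = FALSE]
  list(suv = smax, index = as.integer(cand[1, ]))
}

#' Default lesion search region from observer masks
#'
#' When no explicit region is given, the lesion is taken to be the bounding
#' box of the union of the available observer masks, padded by `pad` voxels
#' — an operational reading of "within the lesion" that needs no manual
#' input.
#'
#' @param masks an [observer_set()] or list of [binary_mask()] objects.
#' @param pad padding in voxels around the union bounding box.
#' @return A [binary_mask()] covering the padded box.
#' @export
default_roi <- function(masks, pad = 3) {
  if (inherits(masks, "observer_set")) masks <- masks$masks
  if (inherits(masks, "binary_mask")) masks <- list(masks)
  grid <- assert_same_grid(masks)
  union_any <- Reduce(`|`, lapply(masks, function(m) m$occupancy))
  if (!any(union_any)) stop("all masks are empty", call. = FALSE)
  idx <- which(union_any, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - pad, 1L)
  hi <- pmin(apply(idx, 2L, max) + pad, grid$shape)
  occ <- array(FALSE, grid$shape)
  occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
  binary_mask(occ, grid)
}

# max-min path capacity from the ROI SUVmax voxel; basis of all
# threshold segmentations so that sweeps and single cuts agree exactly
lesion_capacity <- function(pet, roi, clip_to_roi = FALSE, connectivity = 26) {
  if (!connectivity %in% c(6L, 26L))
    stop("'connectivity' must be 6 or 26", call. = FALSE)
  peak <- lesion_suvmax(pet, roi)
  if (peak$suv == 0)
    stop("SUVmax is zero in the ROI; thresholding is undefined",
         call. = FALSE)
  shp <- pet$grid$shape
  seed_lin <- peak$index[1] + (peak$index[2] - 1) * shp[1] +
    (peak$index[3] - 1) * shp[1] * shp[2]
  msk <- if (clip_to_roi) as.logical(roi$occupancy) else NULL
  cap <- .bottleneck_capacity(as.numeric(pet$values), shp, seed_lin,
                              as.integer(connectivity), msk)
  list(capacity = array(cap, shp), suvmax = peak$suv, seed = peak$index)
}

#' SUVmax-percentage threshold segmentation of a PET lesion
#'
#' Segments a lesion by thresholding at a percentage of its SUVmax: the
#' suprathreshold set is every voxel with SUV at or above
#' `t_percent/100 * SUVmax`, and the segmentation is its connected
#' component (26-neighbourhood by default) containing the SUVmax voxel.
#' With `clip_to_roi = TRUE` the growth is confined to the ROI, which
#' guards against leakage into nearby physiological hot spots such as the
#' pituitary gland; the default leaves the growth unclipped, reproducing
#' that failure mode when a suprathreshold bridge exists.
#'
#' @param pet an [suv_volume()].
#' @param roi a non-empty [binary_mask()] search region for the SUVmax (and
#'   growth clip when `clip_to_roi` is set).
#' @param t_percent threshold in percent of SUVmax, in `[0, 100]`.
#' @param clip_to_roi confine the component growth to the ROI?
#' @param connectivity 26 (default) or 6.
#' @return A [binary_mask()].
#' @export
threshold_segment <- function(pet, roi, t_percent, clip_to_roi = FALSE,
                              connectivity = 26) {
  if (t_percent < 0 || t_percent > 100)
    stop("'t_percent' must lie in [0, 100]", call. = FALSE)
  cap <- lesion_capacity(pet, roi, clip_to_roi = clip_to_roi,
                         connectivity = connectivity)
  binary_mask(cap$capacity >= (t_percent / 100) * cap$suvmax, pet$grid)
}

#' Sweep SUVmax-percentage thresholds and pick the Dice-maximizing one
#'
#' For each lesion, computes the threshold segmentation at every threshold
#' from `t_start` to `t_stop` in steps of `t_step` (percent of the lesion's
#' SUVmax) and scores it against the lesion's consensus reference with the
#' Dice coefficient. The selected threshold is the one maximizing the
#' unweighted mean Dice over lesions; ties break toward the smaller
#' threshold (the more inclusive segmentation). Per-lesion optima are
#' reported the same way.
#'
#' @param lesions a list with one entry per lesion, each a list with
#'   elements `pet` (an [suv_volume()]), optionally `roi` (a
#'   [binary_mask()]; defaults to the padded bounding box of the reference)
#'   and optionally `lesion_id`.
#' @param references list of non-empty consensus [binary_mask()] objects,
#'   aligned with `lesions`.
#' @param t_start,t_stop,t_step sweep grid in percent of SUVmax (defaults
#'   0, 100, 0.5: 201 thresholds).
#' @param clip_to_roi,connectivity passed to the segmentation (see
#'   [threshold_segment()]).
#' @param roi_pad padding for the default ROI when a lesion supplies none.
#' @return An object of class `threshold_sweep` with components
#'   `thresholds`, `dice` (lesions x thresholds matrix), `mean_dice`,
#'   `best_threshold`, `best_mean_dice` and `per_lesion_best`.
#' @export
sweep_thresholds <- function(lesions, references, t_start = 0, t_stop = 100,
                             t_step = 0.5, clip_to_roi = FALSE,
                             connectivity = 26, roi_pad = 3) {
  if (!is.list(lesions) || length(lesions) == 0L)
    stop("'lesions' must be a non-empty list", call. = FALSE)
  if (length(references) != length(lesions))
    stop("'lesions' and 'references' must be aligned lists", call. = FALSE)
  if (t_step <= 0 || t_stop <= t_start)
    stop("invalid threshold grid", call. = FALSE)
  thresholds <- seq(t_start, t_stop, by = t_step)
  n_les <- length(lesions)
  ids <- vapply(seq_len(n_les), function(i) {
    id <- lesions[[i]]$lesion_id
    if (is.null(id)) sprintf("lesion%02d", i) else as.character(id)
  }, character(1))

  dice_mat <- matrix(NA_real_, n_les, length(thresholds),
                     dimnames = list(ids, format(thresholds)))
  for (i in seq_len(n_les)) {
    les <- lesions[[i]]
    ref <- references[[i]]
    if (!inherits(ref, "binary_mask") || !any(ref$occupancy))
      stop(sprintf("reference for lesion '%s' must be a non-empty mask",
                   ids[i]), call. = FALSE)
    roi <- les$roi
    if (is.null(roi)) roi <- default_roi(ref, pad = roi_pad)
    assert_same_grid(les$pet, roi, ref)
    cap <- lesion_capacity(les$pet, roi, clip_to_roi = clip_to_roi,
                           connectivity = connectivity)
    cap_all <- as.numeric(cap$capacity)
    cap_ref <- cap_all[as.logical(ref$occupancy)]
    n_ref <- length(cap_ref)
    taus <- (thresholds / 100) * cap$suvmax
    n_seg <- vapply(taus, function(tau) sum(cap_all >= tau), numeric(1))
    n_int <- vapply(taus, function(tau) sum(cap_ref >= tau), numeric(1))
    dice_mat[i, ] <- ifelse(n_seg == 0, 0, 2 * n_int / (n_seg + n_ref))
  }
  mean_dice <- colMeans(dice_mat)
  best_i <- which.max(mean_dice) # first maximum = smallest threshold
  per_lesion_best <- thresholds[apply(dice_mat, 1L, which.max)]
  names(per_lesion_best) <- ids
  structure(list(
    thresholds = thresholds,
    dice = dice_mat,
    mean_dice = unname(mean_dice),
    best_threshold = thresholds[best_i],
    best_mean_dice = unname(mean_dice[best_i]),
    per_lesion_best = per_lesion_best,
    settings = list(clip_to_roi = clip_to_roi, connectivity = connectivity,
                    t_start = t_start, t_stop = t_stop, t_step = t_step)
  ), class = "threshold_sweep")
}

#' @export
print.threshold_sweep <- function(x, ...) {
  cat("SUVmax-percentage threshold sweep\n")
  cat(sprintf("  %d lesion(s), thresholds %g..%g%% in steps of %g\n",
              nrow(x$dice), x$settings$t_start, x$settings$t_stop,
              x$settings$t_step))
  cat(sprintf("  best threshold: %.1f%% of SUVmax (mean Dice %.3f)\n",
              x$best_threshold, x$best_mean_dice))
  invisible(x)
}

#' @export
summary.threshold_sweep <- function(object, ...) {
  at_best <- object$dice[, which.max(object$mean_dice)]
  structure(list(sweep = object,
                 dice_at_best = at_best,
                 per_lesion_best = object$per_lesion_best),
            class = "summary.threshold_sweep")
}

#' @export
print.summary.threshold_sweep <- function(x, ...) {
  print(x$sweep)
  cat(sprintf("  Dice at best threshold: %.3f +/- %.3f (range %.3f-%.3f)\n",
              mean(x$dice_at_best), stats::sd(x$dice_at_best),
              min(x$dice_at_best), max(x$dice_at_best)))
  cat("  per-lesion optimal thresholds (% of SUVmax):\n")
  print(x$per_lesion_best)
  invisible(x)
}

#' @export
coef.threshold_sweep <- function(object, ...) {
  c(best_threshold = object$best_threshold,
    best_mean_dice = object$best_mean_dice)
}

#' Plot Dice-versus-threshold curves
#'
#' One curve per lesion with its optimum marked by a red dot, plus the mean
#' curve in black.
#'
#' @param x a [sweep_thresholds()] result.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.threshold_sweep <- function(x, ...) {
  graphics::matplot(x$thresholds, t(x$dice), type = "l", lty = 1,
                    col = grDevices::grey(0.7),
                    xlab = "threshold (% of SUVmax)", ylab = "Dice",
                    main = "Dice vs SUVmax threshold", ...)
  graphics::lines(x$thresholds, x$mean_dice, lwd = 2)
  best_dice <- x$dice[cbind(seq_len(nrow(x$dice)),
                            match(x$per_lesion_best, x$thresholds))]
  graphics::points(x$per_lesion_best, best_dice, col = "red", pch = 16)
  graphics::abline(v = x$best_threshold, lty = 2)
  invisible(x)
}

#' Apply a fixed threshold to a validation set
#'
#' Segments every validation lesion at one fixed SUVmax percentage (no
#' re-optimization) and scores the result against the supplied reference
#' masks. If a threshold segmentation is empty while its reference is not,
#' its Dice is recorded as 0 and the Hausdorff distance as `NA` (undefined).
#'
#' @param threshold threshold in percent of SUVmax.
#' @param lesions,references as in [sweep_thresholds()].
#' @param clip_to_roi,connectivity,roi_pad as in [sweep_thresholds()].
#' @param percentile Hausdorff percentile, see [hausdorff()].
#' @return A `data.frame` with one row per lesion: `lesion_id`,
#'   `threshold_pct`, `dice`, `hausdorff_mm`, `volume_seg_cm3`,
#'   `volume_ref_cm3`.
#' @export
evaluate_on_validation <- function(threshold, lesions, references,
                                   clip_to_roi = FALSE, connectivity = 26,
                                   roi_pad = 3, percentile = 100) {
  if (threshold < 0 || threshold > 100)
    stop("'threshold' must lie in [0, 100]", call. = FALSE)
  if (length(references) != length(lesions))
    stop("'lesions' and 'references' must be aligned lists", call. = FALSE)
  rows <- lapply(seq_along(lesions), function(i) {
    les <- lesions[[i]]
    ref <- references[[i]]
    id <- if (is.null(les$lesion_id)) sprintf("lesion%02d", i)
          else as.character(les$lesion_id)
    roi <- les$roi
    if (is.null(roi)) roi <- default_roi(ref, pad = roi_pad)
    seg <- threshold_segment(les$pet, roi, threshold,
                             clip_to_roi = clip_to_roi,
                             connectivity = connectivity)
    m <- contour_metrics(seg, ref, percentile = percentile)
    data.frame(lesion_id = id, threshold_pct = threshold, dice = m$dice,
               hausdorff_mm = m$hausdorff_mm,
               volume_seg_cm3 = m$volume_a_cm3,
               volume_ref_cm3 = m$volume_b_cm3)
  })
  do.call(rbind, rows)
}
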