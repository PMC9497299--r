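#' Per-observer agreement with the modality consensus
#'
#' For every lesion and imaging condition, fits a STAPLE consensus to that
#' condition's observers only, then scores each observer's contour against
#' its own condition's consensus: Dice, Hausdorff distance (mm), observer
#' volume and consensus volume (cm^3). This is the inter-observer
#' variability table of a two-condition contouring study.
#'
#' @param study a `delineation_study` from [make_study()], or a flat list
#'   of [observer_set()] objects (grouped internally by lesion and
#'   modality).
#' @param cutoff consensus posterior cutoff, see [consensus_mask()].
#' @param percentile Hausdorff percentile, see [hausdorff()].
#' @param ... further arguments passed to [staple()].
#' @return A `data.frame` with one row per (lesion, observer, modality):
#'   `lesion_id`, `observer_id`, `modality`, `dice`, `hausdorff_mm`,
#'   `volume_cm3`, `consensus_volume_cm3`.
#' @export
compute_iov <- function(study, cutoff = 0.5, percentile = 100, ...) {
  sets <- study_sets(study)
  # same observers required in every condition of a lesion
  by_lesion <- split(sets, vapply(sets, function(s) s$lesion_id, character(1)))
  for (grp in by_lesion) {
    ids <- lapply(grp, function(s) sort(names(s$masks)))
    if (length(unique(ids)) > 1L)
      stop(sprintf("lesion '%s' has different observers across conditions",
                   grp[[1]]$lesion_id), call. = FALSE)
  }
  rows <- lapply(sets, function(s) {
    fit <- staple(s, ...)
    cm <- consensus_mask(fit, cutoff = cutoff)
    cvol <- mask_volume(cm)
    do.call(rbind, lapply(names(s$masks), function(ob) {
      m <- contour_metrics(s$masks[[ob]], cm, percentile = percentile)
      data.frame(lesion_id = s$lesion_id, observer_id = ob,
                 modality = s$modality, dice = m$dice,
                 hausdorff_mm = m$hausdorff_mm, volume_cm3 = m$volume_a_cm3,
                 consensus_volume_cm3 = cvol)
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

# flatten a delineation_study (or accept a ready list of observer_sets)
study_sets <- function(study) {
  if (inherits(study, "delineation_study")) {
    sets <- unlist(lapply(study$lesions, function(l) l$observers),
                   recursive = FALSE, use.names = FALSE)
  } else if (is.list(study) &&
             all(vapply(study, inherits, logical(1), "observer_set"))) {
    sets <- study
  } else {
    stop("'study' must be a delineation_study or a list of observer_set objects",
         call. = FALSE)
  }
  if (length(sets) == 0L) stop("no observer sets supplied", call. = FALSE)
  sets
}

#' Paired comparison of a metric between imaging conditions
#'
#' Two-sided Wilcoxon signed-rank test on the paired differences of one
#' metric between the two conditions, pairing on (lesion, observer). Pairs
#' with zero difference are dropped (Wilcoxon's original treatment); the
#' exact signed-rank null is used for up to 25 non-zero pairs, the normal
#' approximation with continuity correction above that.
#'
#' @param records the IOV table from [compute_iov()].
#' @param metric which column to compare: `"dice"`, `"hausdorff"` or
#'   `"volume"`.
#' @param alpha significance level carried in the report (default 0.05).
#' @return An object of class `modality_comparison`: `paired_metric`,
#'   `n_pairs` (all pairs), `n_nonzero` (pairs entering the statistic),
#'   `wilcoxon_statistic`, `p_value`, per-condition means, and `alpha`.
#' @export
compare_modalities <- function(records, metric = c("dice", "hausdorff", "volume"),
                               alpha = 0.05) {
  metric <- match.arg(metric)
  col <- switch(metric, dice = "dice", hausdorff = "hausdorff_mm",
                volume = "volume_cm3")
  mods <- sort(unique(records$modality))
  if (length(mods) != 2L)
    stop("records must contain exactly two modalities", call. = FALSE)
  a <- records[records$modality == mods[1], ]
  b <- records[records$modality == mods[2], ]
  ka <- paste(a$lesion_id, a$observer_id)
  kb <- paste(b$lesion_id, b$observer_id)
  if (!setequal(ka, kb) || anyDuplicated(ka) || anyDuplicated(kb))
    stop("every (lesion, observer) pair must appear once per modality",
         call. = FALSE)
  b <- b[match(ka, kb), ]
  x <- a[[col]]; y <- b[[col]]
  keep <- !is.na(x) & !is.na(y)
  if (any(!keep))
    warning(sum(!keep), " pair(s) dropped because the metric is undefined")
  x <- x[keep]; y <- y[keep]
  d <- x - y
  nz <- d != 0
  if (!any(nz))
    stop("all paired differences are zero; the signed-rank test is degenerate",
         call. = FALSE)
  n_nonzero <- sum(nz)
  ht <- suppressWarnings(stats::wilcox.test(
    x[nz], y[nz], paired = TRUE, exact = n_nonzero <= 25, correct = TRUE))
  structure(list(paired_metric = metric, n_pairs = length(d),
                 n_nonzero = n_nonzero,
                 wilcoxon_statistic = unname(ht$statistic),
                 p_value = ht$p.value,
                 mean_by_modality = stats::setNames(c(mean(x), mean(y)), mods),
                 alpha = alpha),
            class = "modality_comparison")
}

#' @export
print.modality_comparison <- function(x, ...) {
  mods <- names(x$mean_by_modality)
  cat(sprintf("Paired Wilcoxon signed-rank: %s, %s vs %s\n",
              x$paired_metric, mods[1], mods[2]))
  cat(sprintf("  means: %s = %.4g, %s = %.4g\n", mods[1],
              x$mean_by_modality[1], mods[2], x$mean_by_modality[2]))
  cat(sprintf("  n = %d pairs (%d non-zero), V = %g, p = %.4g (alpha %.2f)\n",
              x$n_pairs, x$n_nonzero, x$wilcoxon_statistic, x$p_value,
              x$alpha))
  invisible(x)
}

#' Correlation between optimal threshold and lesion volume
#'
#' Spearman rank correlation (average ranks for ties, two-sided p) between
#' each lesion's Dice-optimal SUVmax percentage and the volume of its
#' consensus delineation — a check that the selected threshold is not just
#' a surrogate for lesion size.
#'
#' @param per_lesion_best numeric vector of per-lesion optimal thresholds
#'   (percent of SUVmax), e.g. from [sweep_thresholds()].
#' @param volumes numeric vector of the corresponding volumes (cm^3).
#' @param alpha significance level carried in the report.
#' @return An object of class `threshold_volume_correlation` with
#'   `spearman_rho`, `p_value`, `n` and `alpha`.
#' @export
correlate_threshold_volume <- function(per_lesion_best, volumes,
                                       alpha = 0.05) {
  if (length(per_lesion_best) != length(volumes))
    stop("inputs must be aligned", call. = FALSE)
  if (length(volumes) < 3L) stop("need at least 3 lesions", call. = FALSE)
  if (stats::sd(per_lesion_best) == 0 || stats::sd(volumes) == 0)
    stop("Spearman correlation is undefined for a constant input",
         call. = FALSE)
  rho <- stats::cor(rank(per_lesion_best), rank(volumes))
  ht <- suppressWarnings(stats::cor.test(per_lesion_best, volumes,
                                         method = "spearman"))
  structure(list(spearman_rho = rho, p_value = ht$p.value,
                 n = length(volumes), alpha = alpha),
            class = "threshold_volume_correlation")
}

#' @export
print.threshold_volume_correlation <- function(x, ...) {
  cat(sprintf("Spearman rank correlation (threshold vs volume): rho = %.3f, p = %.4g, n = %d\n",
              x$spearman_rho, x$p_value, x$n))
  invisible(x)
}

#' Run a complete delineation study
#'
#' End-to-end driver: builds (or loads) the study data, computes the IOV
#' table per condition, compares the conditions with paired Wilcoxon tests
#' on Dice, Hausdorff and volume, sweeps SUVmax thresholds against the
#' PET-informed consensus, applies the selected threshold to an independent
#' validation set, and tests the threshold-volume correlation. When an
#' output directory is given, writes `iov.csv`, `sweep.csv`,
#' `sweep_summary.json`, `validation.csv`, `stats.json` and
#' `manifest.json`.
#'
#' @param config a list or the path of a YAML file. Recognised entries:
#'   `seed` (integer); `synthetic` (a list of arguments for [make_study()]
#'   plus optional `n_validation` and `n_validation_observers`); `inputs`
#'   (a list with `masks` and optionally `pets`, each a `data.frame` or CSV
#'   path — masks need columns `lesion_id`, `observer_id`, `modality`,
#'   `path`; pets need `lesion_id`, `path`); `sweep` (arguments for
#'   [sweep_thresholds()]); `cutoff` (consensus cutoff).
#' @param out_dir optional output directory, created if needed.
#' @param quiet suppress progress messages?
#' @return Invisibly, a list with `iov`, `stats`, `sweep`, `validation`,
#'   `correlation` and `manifest` (entries may be `NULL` when their inputs
#'   were absent).
#' @export
run_study <- function(config = list(), out_dir = NULL, quiet = FALSE) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  say <- function(...) if (!quiet) message(...)
  seed <- if (is.null(config$seed)) 1L else as.integer(config$seed)
  cutoff <- if (is.null(config$cutoff)) 0.5 else config$cutoff
  sweep_args <- config$sweep %||% list()

  # ---- assemble the study ------------------------------------------------
  n_val <- 0L
  n_val_obs <- 3L
  if (!is.null(config$inputs)) {
    loaded <- load_study_inputs(config$inputs)
    sets <- loaded$sets
    pets <- loaded$pets
    manifest_extra <- list(source = "files")
  } else {
    syn <- config$synthetic %||% list()
    n_val <- syn$n_validation %||% 0L
    n_val_obs <- syn$n_validation_observers %||% n_val_obs
    syn$n_validation <- NULL; syn$n_validation_observers <- NULL
    syn$seed <- seed
    say("simulating study bundle (seed ", seed, ")")
    bundle <- do.call(make_study, syn)
    sets <- study_sets(bundle)
    pets <- lapply(bundle$lesions, function(l) l$pet)
    names(pets) <- vapply(bundle$lesions, function(l) l$lesion_id,
                          character(1))
    manifest_extra <- list(source = "synthetic",
                           lesion_table = bundle$manifest$lesion_table,
                           n_validation = n_val)
  }

  modalities <- unique(vapply(sets, function(s) s$modality, character(1)))

  # ---- inter-observer variability ---------------------------------------
  say("computing IOV records for ", length(sets), " observer set(s)")
  iov <- compute_iov(sets, cutoff = cutoff)

  stats_reports <- NULL
  if (length(modalities) == 2L) {
    stats_reports <- lapply(c("dice", "hausdorff", "volume"),
                            function(m) compare_modalities(iov, m))
    names(stats_reports) <- c("dice", "hausdorff", "volume")
  } else {
    say("only one imaging condition present; skipping the paired comparison")
  }

  # ---- threshold sweep against the PET-informed consensus ---------------
  sweep <- validation <- correlation <- NULL
  if (length(pets) > 0L && "MRI_PET" %in% modalities) {
    pet_sets <- Filter(function(s) s$modality == "MRI_PET", sets)
    refs <- lapply(pet_sets, function(s)
      consensus_mask(staple(s), cutoff = cutoff))
    lesions <- lapply(pet_sets, function(s)
      list(pet = pets[[s$lesion_id]], roi = default_roi(s),
           lesion_id = s$lesion_id))
    say("sweeping SUVmax thresholds over ", length(lesions), " lesion(s)")
    sweep <- do.call(sweep_thresholds,
                     c(list(lesions = lesions, references = refs),
                       sweep_args))
    ref_vols <- vapply(refs, mask_volume, numeric(1))
    correlation <- correlate_threshold_volume(sweep$per_lesion_best, ref_vols)

    # independent synthetic validation group
    if (is.null(config$inputs) && n_val > 0L) {
      say("evaluating the selected threshold on ", n_val,
          " validation lesion(s)")
      vsyn <- config$synthetic %||% list()
      vsyn$n_validation <- NULL; vsyn$n_validation_observers <- NULL
      vsyn$n_lesions <- n_val
      vsyn$n_observers <- n_val_obs
      vsyn$modalities <- "MRI_PET"
      vsyn$seed <- seed + 104729L # independent stream for the validation group
      vbundle <- do.call(make_study, vsyn)
      vsets <- study_sets(vbundle)
      vrefs <- lapply(vsets, function(s)
        consensus_mask(staple(s), cutoff = cutoff))
      vles <- lapply(seq_along(vsets), function(i)
        list(pet = vbundle$lesions[[i]]$pet, roi = default_roi(vsets[[i]]),
             lesion_id = vsets[[i]]$lesion_id))
      validation <- evaluate_on_validation(sweep$best_threshold, vles, vrefs)
    }
  } else {
    say("PET inputs absent; skipping the threshold sweep")
  }

  manifest <- c(list(seed = seed, cutoff = cutoff,
                     modalities = modalities,
                     n_lesions = length(unique(iov$lesion_id)),
                     package_version = as.character(utils::packageVersion("stapleseg")),
                     r_version = R.version.string),
                manifest_extra)

  result <- list(iov = iov, stats = stats_reports, sweep = sweep,
                 validation = validation, correlation = correlation,
                 manifest = manifest)
  if (!is.null(out_dir)) write_study_outputs(result, out_dir, say)
  invisible(result)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

load_study_inputs <- function(inputs) {
  as_table <- function(x) if (is.character(x)) utils::read.csv(x) else x
  mtab <- as_table(inputs$masks)
  need <- c("lesion_id", "observer_id", "modality", "path")
  if (!all(need %in% names(mtab)))
    stop("mask table needs columns: ", paste(need, collapse = ", "),
         call. = FALSE)
  sets <- list()
  for (les in unique(mtab$lesion_id)) {
    for (mod in unique(mtab$modality[mtab$lesion_id == les])) {
      sub <- mtab[mtab$lesion_id == les & mtab$modality == mod, ]
      masks <- lapply(sub$path, read_mask)
      names(masks) <- sub$observer_id
      sets[[length(sets) + 1L]] <- observer_set(masks, lesion_id = les,
                                                modality = mod)
    }
  }
  pets <- list()
  if (!is.null(inputs$pets)) {
    ptab <- as_table(inputs$pets)
    if (!all(c("lesion_id", "path") %in% names(ptab)))
      stop("pet table needs columns: lesion_id, path", call. = FALSE)
    pets <- lapply(ptab$path, read_volume)
    names(pets) <- ptab$lesion_id
  }
  list(sets = sets, pets = pets)
}

write_study_outputs <- function(result, out_dir, say) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  path <- function(f) file.path(out_dir, f)
  utils::write.csv(result$iov, path("iov.csv"), row.names = FALSE)
  if (!is.null(result$stats) || !is.null(result$correlation)) {
    stats_json <- lapply(result$stats, unclass)
    if (!is.null(result$correlation))
      stats_json$threshold_volume <- unclass(result$correlation)
    jsonlite::write_json(stats_json, path("stats.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  if (!is.null(result$sweep)) {
    sw <- result$sweep
    long <- data.frame(
      lesion_id = rep(rownames(sw$dice), times = ncol(sw$dice)),
      threshold_pct = rep(sw$thresholds, each = nrow(sw$dice)),
      dice = as.vector(sw$dice))
    utils::write.csv(long, path("sweep.csv"), row.names = FALSE)
    jsonlite::write_json(
      list(best_threshold = sw$best_threshold,
           best_mean_dice = sw$best_mean_dice,
           per_lesion_best = as.list(sw$per_lesion_best),
           settings = sw$settings),
      path("sweep_summary.json"), auto_unbox = TRUE, digits = NA,
      pretty = TRUE)
  }
  if (!is.null(result$validation))
    utils::write.csv(result$validation, path("validation.csv"),
                     row.names = FALSE)
  manifest <- result$manifest
  if (is.data.frame(manifest$lesion_table))
    manifest$lesion_table <- manifest$lesion_table
  jsonlite::write_json(manifest, path("manifest.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, dataframe = "rows")
  say("study outputs written to ", normalizePath(out_dir))
}
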