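#' Fit a binary STAPLE consensus to multiple observer delineations
#'
#' Simultaneous truth and performance level estimation: an
#' expectation-maximization estimator that treats the unknown true
#' segmentation as a latent binary field and each observer `j` as a rater
#' with unknown sensitivity `p_j` (probability of marking a truly occupied
#' voxel) and specificity `q_j` (probability of leaving a truly background
#' voxel unmarked). The E-step computes, per voxel `i`, the posterior
#' probability `W_i` that the voxel is truly occupied,
#' \deqn{a_i = \gamma \prod_j p_j^{D_{ij}} (1-p_j)^{1-D_{ij}}, \quad
#'       b_i = (1-\gamma) \prod_j (1-q_j)^{D_{ij}} q_j^{1-D_{ij}}, \quad
#'       W_i = a_i / (a_i + b_i),}
#' where `D_ij` is observer `j`'s binary decision and `gamma` the global
#' foreground prior. The M-step re-estimates
#' `p_j = sum_i W_i D_ij / sum_i W_i` and
#' `q_j = sum_i (1-W_i)(1-D_ij) / sum_i (1-W_i)`. Iteration stops when the
#' relative change of `sum_i W_i` falls below `tol` or after `max_iter`
#' iterations.
#'
#' To keep the overwhelming background from dominating the prior, the
#' computation is restricted to the bounding box of the union of the input
#' masks padded by `bbox_margin` voxels; voxels outside are unanimous
#' background, carry weight 0, and are excluded from the E/M sums. `gamma`
#' is the mean observer occupancy fraction on that region (`prior =
#' "mean_occupancy"`, the default) or a fixed user value; it is not updated
#' during EM.
#'
#' @param masks an [observer_set()] or a named list of two or more
#'   [binary_mask()] objects on one grid (names are observer ids).
#' @param init_sensitivity,init_specificity initial `p_j` / `q_j`, scalar or
#'   one value per observer, strictly inside (0, 1). Default 0.9.
#' @param prior `"mean_occupancy"` (default) or `"fixed"`.
#' @param fixed_prior foreground prior in (0, 1); required when
#'   `prior = "fixed"`.
#' @param tol convergence tolerance on the relative change of `sum(W)`.
#' @param max_iter maximum EM iterations.
#' @param bbox_margin padding (voxels) around the union bounding box.
#' @return An object of class `staple` with components `weights` (posterior
#'   probability array over the full grid), `sensitivity`, `specificity`
#'   (named per-observer vectors), `prior`, `n_iterations`, `converged`,
#'   `trace` (a data.frame with per-iteration `sum_w`, `rel_change` and
#'   observed-data `loglik`), `grid`, `region` (index ranges of the
#'   restricted box) and `observers`.
#' @seealso [consensus_mask()], [compute_iov()]
#' @examples
#' g <- image_grid(c(12, 12, 6), spacing = c(4, 4, 5))
#' truth <- array(FALSE, g$shape); truth[4:9, 4:9, 2:5] <- TRUE
#' set.seed(1)
#' obs <- lapply(1:3, function(j) {
#'   flip <- array(stats::runif(prod(g$shape)) < 0.1, g$shape)
#'   binary_mask(xor(truth, flip), g)
#' })
#' names(obs) <- paste0("obs", 1:3)
#' fit <- staple(obs)
#' coef(fit)
#' @export
staple <- function(masks, init_sensitivity = 0.9, init_specificity = 0.9,
                   prior = c("mean_occupancy", "fixed"), fixed_prior = NULL,
                   tol = 1e-6, max_iter = 100, bbox_margin = 5) {
  prior <- match.arg(prior)
  if (inherits(masks, "observer_set")) {
    oset <- masks
  } else {
    oset <- observer_set(masks)
  }
  grid <- oset$grid
  J <- length(oset$masks)
  obs_ids <- names(oset$masks)
  if (tol <= 0) stop("'tol' must be positive", call. = FALSE)
  if (max_iter < 1) stop("'max_iter' must be at least 1", call. = FALSE)
  p <- rep_len(as.numeric(init_sensitivity), J)
  q <- rep_len(as.numeric(init_specificity), J)
  if (any(p <= 0 | p >= 1 | q <= 0 | q >= 1))
    stop("initial sensitivity/specificity must lie strictly in (0, 1)",
         call. = FALSE)

  occ <- lapply(oset$masks, function(m) m$occupancy)
  union_any <- Reduce(`|`, occ)
  if (!any(union_any))
    stop("all observer masks are empty; nothing to fuse", call. = FALSE)

  # restricted region: padded bounding box of the union of masks
  idx <- which(union_any, arr.ind = TRUE)
  lo <- pmax(apply(idx, 2L, min) - bbox_margin, 1L)
  hi <- pmin(apply(idx, 2L, max) + bbox_margin, grid$shape)
  region <- list(lo = as.integer(lo), hi = as.integer(hi))
  sub <- function(a) a[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  D <- vapply(occ, function(o) as.numeric(sub(o)), numeric(prod(hi - lo + 1L)))
  n <- nrow(D)

  gamma <- switch(prior,
    mean_occupancy = mean(D),
    fixed = {
      if (is.null(fixed_prior) || fixed_prior <= 0 || fixed_prior >= 1)
        stop("'fixed_prior' must be given in (0, 1) when prior = \"fixed\"",
             call. = FALSE)
      as.numeric(fixed_prior)
    })

  eps <- 1e-12
  clamp <- function(x) pmin(pmax(x, eps), 1 - eps)
  trace_sum_w <- trace_rel <- trace_ll <- numeric(0)
  prev_sum_w <- NA_real_
  converged <- FALSE
  W <- NULL

  for (it in seq_len(max_iter)) {
    # E-step in log space
    la <- log(gamma) + D %*% log(clamp(p)) + (1 - D) %*% log(clamp(1 - p))
    lb <- log(1 - gamma) + D %*% log(clamp(1 - q)) + (1 - D) %*% log(clamp(q))
    m <- pmax(la, lb)
    trace_ll <- c(trace_ll, sum(m + log(exp(la - m) + exp(lb - m))))
    W <- as.numeric(1 / (1 + exp(lb - la)))
    sum_w <- sum(W)
    rel <- if (is.na(prev_sum_w)) NA_real_
           else abs(sum_w - prev_sum_w) / max(prev_sum_w, .Machine$double.eps)
    trace_sum_w <- c(trace_sum_w, sum_w)
    trace_rel <- c(trace_rel, rel)
    if (!is.na(rel) && rel < tol) { converged <- TRUE; break }
    prev_sum_w <- sum_w
    # M-step
    if (sum_w <= 0)
      stop("EM collapse: sum of posterior weights is zero", call. = FALSE)
    if (n - sum_w <= 0)
      stop("EM collapse: sum of background weights is zero", call. = FALSE)
    p <- clamp(colSums(W * D) / sum_w)
    q <- clamp(colSums((1 - W) * (1 - D)) / (n - sum_w))
  }

  weights <- array(0, grid$shape)
  weights[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- W
  names(p) <- names(q) <- obs_ids
  structure(list(
    weights = weights,
    sensitivity = p,
    specificity = q,
    prior = gamma,
    n_iterations = length(trace_sum_w),
    converged = converged,
    trace = data.frame(iteration = seq_along(trace_sum_w),
                       sum_w = trace_sum_w, rel_change = trace_rel,
                       loglik = trace_ll),
    grid = grid,
    region = region,
    observers = obs_ids,
    lesion_id = oset$lesion_id,
    modality = oset$modality,
    call = match.call()
  ), class = "staple")
}

#' Extract the consensus mask from a STAPLE fit
#'
#' A voxel belongs to the consensus when its posterior foreground
#' probability `W_i` is at least `cutoff` (ties at the cutoff are included,
#' so a voxel at exactly 0.5 is occupied under the default).
#'
#' @param result a [staple()] fit.
#' @param cutoff posterior probability cutoff, strictly inside (0, 1).
#' @return A [binary_mask()].
#' @export
consensus_mask <- function(result, cutoff = 0.5) {
  stopifnot(inherits(result, "staple"))
  if (cutoff <= 0 || cutoff >= 1)
    stop("'cutoff' must lie strictly in (0, 1)", call. = FALSE)
  binary_mask(result$weights >= cutoff, result$grid)
}

#' @export
print.staple <- function(x, digits = 4, ...) {
  cat("Binary STAPLE consensus fit\n")
  cat(sprintf("  %d observers, foreground prior %.4g, %d EM iteration(s), %s\n",
              length(x$sensitivity), x$prior, x$n_iterations,
              if (x$converged) "converged" else "NOT converged"))
  print(round(coef(x), digits))
  invisible(x)
}

#' @export
coef.staple <- function(object, ...) {
  cbind(sensitivity = object$sensitivity,
        specificity = object$specificity)
}

#' @export
fitted.staple <- function(object, ...) object$weights

#' Predict method for STAPLE fits
#'
#' @param object a [staple()] fit.
#' @param cutoff posterior cutoff for `type = "mask"`.
#' @param type `"mask"` for the consensus [binary_mask()], `"weights"` for
#'   the posterior probability array.
#' @param ... unused.
#' @return A [binary_mask()] or a numeric array.
#' @export
predict.staple <- function(object, cutoff = 0.5,
                           type = c("mask", "weights"), ...) {
  type <- match.arg(type)
  if (type == "weights") return(object$weights)
  consensus_mask(object, cutoff = cutoff)
}

#' @export
logLik.staple <- function(object, ...) {
  ll <- object$trace$loglik[object$n_iterations]
  structure(ll, df = 2L * length(object$sensitivity),
            nobs = prod(object$region$hi - object$region$lo + 1L),
            class = "logLik")
}

#' @export
summary.staple <- function(object, cutoff = 0.5, ...) {
  cm <- consensus_mask(object, cutoff = cutoff)
  structure(list(fit = object, cutoff = cutoff,
                 consensus_volume_cm3 = mask_volume(cm),
                 consensus_voxels = sum(cm$occupancy)),
            class = "summary.staple")
}

#' @export
print.summary.staple <- function(x, digits = 4, ...) {
  print(x$fit, digits = digits)
  cat(sprintf("  consensus at cutoff %.2f: %d voxels, %.4g cm^3\n",
              x$cutoff, x$consensus_voxels, x$consensus_volume_cm3))
  cat(sprintf("  final log-likelihood: %.6g\n",
              x$fit$trace$loglik[x$fit$n_iterations]))
  invisible(x)
}

#' @export
plot.staple <- function(x, ...) {
  graphics::plot(x$trace$iteration, x$trace$loglik, type = "b",
                 xlab = "EM iteration", ylab = "observed-data log-likelihood",
                 main = "STAPLE convergence", ...)
  invisible(x)
}

#' Simulate observer delineations from a STAPLE fit
#'
#' Draws new observer sets from the fitted generative model: within the
#' fit's restricted region, each voxel's latent truth is Bernoulli with the
#' posterior weight `W_i`, and each observer marks it with probability
#' `p_j` (truth occupied) or `1 - q_j` (truth background). Voxels outside
#' the region stay background.
#'
#' @param object a [staple()] fit.
#' @param nsim number of replicate observer sets.
#' @param seed optional integer seed.
#' @param ... unused.
#' @return A list of `nsim` [observer_set()] objects.
#' @export
simulate.staple <- function(object, nsim = 1, seed = NULL, ...) {
  if (!is.null(seed)) set.seed(seed)
  lo <- object$region$lo; hi <- object$region$hi
  Wsub <- object$weights[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]]
  n <- length(Wsub)
  J <- length(object$sensitivity)
  replicate(nsim, simplify = FALSE, {
    truth <- stats::runif(n) < as.numeric(Wsub)
    masks <- lapply(seq_len(J), function(j) {
      pr <- ifelse(truth, object$sensitivity[j], 1 - object$specificity[j])
      occ <- array(FALSE, object$grid$shape)
      occ[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- stats::runif(n) < pr
      binary_mask(occ, object$grid)
    })
    names(masks) <- object$observers
    observer_set(masks, lesion_id = object$lesion_id,
                 modality = object$modality)
  })
}
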