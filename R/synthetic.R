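#' Default PET-scale study grid
#'
#' 64 x 64 x 32 voxels at 4 x 4 x 5 mm — the voxel size of a typical
#' brain-PET reconstruction matrix, kept small enough that whole studies
#' simulate in seconds.
#'
#' @return An [image_grid()].
#' @export
default_grid <- function() image_grid(c(64L, 64L, 32L), spacing = c(4, 4, 5))

# evaluate code under a temporary seed, restoring the RNG state afterwards
with_seed <- function(seed, code) {
  if (is.null(seed)) return(code)
  if (!exists(".Random.seed", globalenv(), inherits = FALSE)) stats::runif(1)
  old <- get(".Random.seed", globalenv())
  on.exit(assign(".Random.seed", old, globalenv()))
  set.seed(seed)
  code
}

# separable Gaussian convolution with row-renormalized kernels (so flat
# fields stay flat at the grid edges); fwhm_mm = 0 is the identity
gaussian_blur <- function(arr, grid, fwhm_mm) {
  if (fwhm_mm == 0) return(arr)
  sigma <- fwhm_mm / (2 * sqrt(2 * log(2)))
  out <- arr
  for (axis in 1:3) {
    n <- grid$shape[axis]
    sp <- grid$spacing[axis]
    K <- exp(-(sp * outer(seq_len(n), seq_len(n), "-"))^2 / (2 * sigma^2))
    K <- K / rowSums(K)
    perm <- c(axis, setdiff(1:3, axis))
    ap <- aperm(out, perm)
    m <- K %*% matrix(ap, nrow = n)
    out <- aperm(array(m, dim(ap)), order(perm))
  }
  out
}

# zero-mean unit-variance smooth random field: white noise filtered with a
# Gaussian of FWHM corr_length_mm, then standardized
smooth_field <- function(grid, corr_length_mm) {
  f <- array(stats::rnorm(prod(grid$shape)), grid$shape)
  f <- gaussian_blur(f, grid, corr_length_mm)
  (f - mean(f)) / stats::sd(f)
}

# signed Euclidean distance (mm) to the mask surface: negative inside,
# positive outside, zero on boundary voxels
signed_distance <- function(mask) {
  bnd <- boundary_voxels(mask)
  sites <- array(FALSE, mask$grid$shape)
  sites[bnd] <- TRUE
  d <- sqrt(array(.edt_sq(sites, mask$grid$shape, mask$grid$spacing),
                  mask$grid$shape))
  d[mask$occupancy] <- -d[mask$occupancy]
  d
}

world_coordinates <- function(grid) {
  shp <- grid$shape
  I <- array(rep(0:(shp[1] - 1), times = shp[2] * shp[3]), shp)
  J <- array(rep(rep(0:(shp[2] - 1), each = shp[1]), times = shp[3]), shp)
  K <- array(rep(0:(shp[3] - 1), each = shp[1] * shp[2]), shp)
  A <- grid$direction %*% diag(grid$spacing)
  list(x = grid$origin[1] + A[1, 1] * I + A[1, 2] * J + A[1, 3] * K,
       y = grid$origin[2] + A[2, 1] * I + A[2, 2] * J + A[2, 3] * K,
       z = grid$origin[3] + A[3, 1] * I + A[3, 2] * J + A[3, 3] * K)
}

#' Generate a PET lesion phantom
#'
#' Builds a ground-truth ellipsoidal lesion mask and a matching PET volume:
#' piecewise-constant uptake (background, lesion, and an optional spherical
#' decoy hot spot emulating the pituitary gland's physiological tracer
#' uptake) convolved with an isotropic Gaussian point-spread function and
#' degraded by additive Gaussian noise, clipped at zero. Truth voxels are
#' those whose centres lie inside the ellipsoid.
#'
#' @param grid an [image_grid()]; default [default_grid()].
#' @param lesion_center world mm coordinates of the lesion centre; default
#'   is the grid centre.
#' @param semi_axes ellipsoid semi-axes in mm.
#' @param lesion_uptake,background_uptake SUV of lesion and background;
#'   `lesion_uptake` must exceed `background_uptake >= 0`.
#' @param psf_fwhm_mm full width at half maximum of the Gaussian blur (mm);
#'   0 disables blurring.
#' @param noise_sd standard deviation of the additive Gaussian noise (SUV);
#'   0 disables noise.
#' @param decoy optional `list(center =, radius_mm =, uptake =)` describing
#'   a spherical hot spot; it must not overlap the lesion unless
#'   `allow_decoy_overlap = TRUE`.
#' @param allow_decoy_overlap allow the decoy to touch the lesion?
#' @param seed optional integer; the phantom is a pure function of its
#'   parameters and this seed.
#' @return A list with `pet` (an [suv_volume()]), `truth` (a
#'   [binary_mask()]) and `params` (the arguments actually used).
#' @export
make_phantom <- function(grid = default_grid(), lesion_center = NULL,
                         semi_axes = c(16, 14, 12), lesion_uptake = 8,
                         background_uptake = 0.2, psf_fwhm_mm = 6,
                         noise_sd = 0.2, decoy = NULL,
                         allow_decoy_overlap = FALSE, seed = NULL) {
  stopifnot(inherits(grid, "image_grid"))
  if (background_uptake < 0 || lesion_uptake <= background_uptake)
    stop("need lesion_uptake > background_uptake >= 0", call. = FALSE)
  if (length(semi_axes) != 3L || any(semi_axes < min(grid$spacing)))
    stop("'semi_axes' must be 3 values, each at least one voxel spacing",
         call. = FALSE)
  co <- world_coordinates(grid)
  lo_corner <- c(min(co$x), min(co$y), min(co$z))
  hi_corner <- c(max(co$x), max(co$y), max(co$z))
  if (is.null(lesion_center)) lesion_center <- (lo_corner + hi_corner) / 2
  if (any(lesion_center - semi_axes < lo_corner) ||
      any(lesion_center + semi_axes > hi_corner))
    stop("lesion extends beyond the grid", call. = FALSE)

  truth_arr <- ((co$x - lesion_center[1]) / semi_axes[1])^2 +
    ((co$y - lesion_center[2]) / semi_axes[2])^2 +
    ((co$z - lesion_center[3]) / semi_axes[3])^2 <= 1
  truth <- binary_mask(truth_arr, grid)

  img <- array(background_uptake, grid$shape)
  img[truth_arr] <- lesion_uptake
  if (!is.null(decoy)) {
    if (!all(c("center", "radius_mm", "uptake") %in% names(decoy)))
      stop("'decoy' needs center, radius_mm and uptake", call. = FALSE)
    dec_arr <- (co$x - decoy$center[1])^2 + (co$y - decoy$center[2])^2 +
      (co$z - decoy$center[3])^2 <= decoy$radius_mm^2
    if (any(dec_arr & truth_arr) && !allow_decoy_overlap)
      stop("decoy hot spot overlaps the lesion", call. = FALSE)
    img[dec_arr] <- decoy$uptake
  }
  img <- gaussian_blur(img, grid, psf_fwhm_mm)
  if (noise_sd > 0)
    img <- with_seed(seed, img + array(stats::rnorm(length(img), 0, noise_sd),
                                       dim(img)))
  img[img < 0] <- 0
  list(pet = suv_volume(img, grid), truth = truth,
       params = list(lesion_center = lesion_center, semi_axes = semi_axes,
                     lesion_uptake = lesion_uptake,
                     background_uptake = background_uptake,
                     psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
                     decoy = decoy, seed = seed))
}

#' Observer error model for simulated delineations
#'
#' Two generative modes. `"iid_flip"` draws every voxel of every observer
#' independently: a truly occupied voxel is marked with probability `p_j`
#' (the observer's sensitivity) and a background voxel left unmarked with
#' probability `q_j` (specificity) — exactly the rater model STAPLE
#' assumes, which makes parameter recovery a well-posed check.
#' `"boundary_field"` perturbs the truth surface instead: observer `j`
#' marks the voxels whose signed distance to the truth surface is at most
#' `bias_mm[j] + eps_j(x)`, where `eps_j` is a smooth zero-mean Gaussian
#' random field with pointwise sd `boundary_sd_mm[j]` and correlation
#' length `corr_length_mm`. That produces contiguous over- and
#' under-contoured regions resembling real contouring variation; a
#' positive bias systematically enlarges the contour.
#'
#' @param mode `"boundary_field"` or `"iid_flip"`.
#' @param sensitivity,specificity per-observer `p_j`, `q_j` for
#'   `"iid_flip"`, each in (0.5, 1); recycled as needed.
#' @param boundary_sd_mm,bias_mm per-observer field sd and constant bias in
#'   mm for `"boundary_field"`; recycled as needed.
#' @param corr_length_mm correlation length (FWHM, mm) of the smooth field.
#' @return An object of class `observer_model`.
#' @export
observer_model <- function(mode = c("boundary_field", "iid_flip"),
                           sensitivity = 0.9, specificity = 0.95,
                           boundary_sd_mm = 2, bias_mm = 0,
                           corr_length_mm = 10) {
  mode <- match.arg(mode)
  if (mode == "iid_flip") {
    if (any(sensitivity <= 0.5 | sensitivity >= 1) ||
        any(specificity <= 0.5 | specificity >= 1))
      stop("iid_flip sensitivity/specificity must lie in (0.5, 1)",
           call. = FALSE)
  } else {
    if (any(boundary_sd_mm < 0)) stop("'boundary_sd_mm' must be >= 0",
                                      call. = FALSE)
    if (corr_length_mm <= 0) stop("'corr_length_mm' must be > 0",
                                  call. = FALSE)
  }
  structure(list(mode = mode, sensitivity = sensitivity,
                 specificity = specificity, boundary_sd_mm = boundary_sd_mm,
                 bias_mm = bias_mm, corr_length_mm = corr_length_mm),
            class = "observer_model")
}

#' @export
print.observer_model <- function(x, ...) {
  if (x$mode == "iid_flip")
    cat("<observer_model> iid_flip, p =",
        paste(format(x$sensitivity), collapse = "/"), ", q =",
        paste(format(x$specificity), collapse = "/"), "\n")
  else
    cat("<observer_model> boundary_field, sd =",
        paste(format(x$boundary_sd_mm), collapse = "/"), "mm, bias =",
        paste(format(x$bias_mm), collapse = "/"), "mm, corr",
        format(x$corr_length_mm), "mm\n")
  invisible(x)
}

#' Simulate observer delineations of a known truth
#'
#' Draws `n_observers` contours of the ground-truth mask under an
#' [observer_model()]. Deterministic given `seed`.
#'
#' @param truth a non-empty [binary_mask()].
#' @param model an [observer_model()].
#' @param n_observers number of observers (>= 2).
#' @param seed optional integer seed.
#' @param lesion_id,modality labels attached to the returned set.
#' @param observer_ids optional character vector of observer ids.
#' @return An [observer_set()].
#' @export
simulate_observers <- function(truth, model, n_observers = 5, seed = NULL,
                               lesion_id = "lesion", modality = "MRI",
                               observer_ids = NULL) {
  stopifnot(inherits(truth, "binary_mask"), inherits(model, "observer_model"))
  if (n_observers < 2) stop("need at least 2 observers", call. = FALSE)
  if (!any(truth$occupancy)) stop("truth mask is empty", call. = FALSE)
  if (is.null(observer_ids))
    observer_ids <- sprintf("obs%02d", seq_len(n_observers))
  grid <- truth$grid
  with_seed(seed, {
    masks <- if (model$mode == "iid_flip") {
      p <- rep_len(model$sensitivity, n_observers)
      q <- rep_len(model$specificity, n_observers)
      lapply(seq_len(n_observers), function(j) {
        pr <- ifelse(truth$occupancy, p[j], 1 - q[j])
        binary_mask(array(stats::runif(length(pr)) < pr, grid$shape), grid)
      })
    } else {
      sdv <- rep_len(model$boundary_sd_mm, n_observers)
      bias <- rep_len(model$bias_mm, n_observers)
      sd_map <- signed_distance(truth)
      lapply(seq_len(n_observers), function(j) {
        eps <- if (sdv[j] > 0) sdv[j] * smooth_field(grid, model$corr_length_mm)
               else 0
        binary_mask(sd_map <= bias[j] + eps, grid)
      })
    }
    names(masks) <- observer_ids
    observer_set(masks, lesion_id = lesion_id, modality = modality)
  })
}

#' Generate a full synthetic delineation study
#'
#' Builds a bundle of lesions that mirrors the structure of a two-condition
#' contouring study: per lesion a phantom PET volume and ground truth with
#' randomized geometry and uptake, plus one simulated observer set per
#' imaging condition ("MRI" and "MRI_PET"), each generated under its own
#' error model. The default models give the PET-informed condition tighter
#' contouring noise, planting the effect that adding PET reduces
#' inter-observer variability. A manifest records every planted parameter.
#'
#' @param n_lesions number of lesions (default 27).
#' @param n_observers observers per lesion (default 5).
#' @param grid an [image_grid()].
#' @param seed master seed; the whole bundle is reproducible from it.
#' @param semi_axes_range range (mm) from which each lesion's three
#'   semi-axes are drawn uniformly.
#' @param lesion_uptake_range range of lesion SUV, drawn uniformly.
#' @param background_uptake,psf_fwhm_mm,noise_sd phantom imaging
#'   parameters, see [make_phantom()].
#' @param mri_model,pet_model [observer_model()] objects for the two
#'   conditions; `NULL` entries use the defaults described above.
#' @param modalities which conditions to simulate (subset of
#'   `c("MRI", "MRI_PET")`).
#' @return A list of class `delineation_study` with `lesions` (each a list
#'   with `lesion_id`, `pet`, `truth` and `observers`, a named list of
#'   [observer_set()]s) and `manifest`.
#' @export
make_study <- function(n_lesions = 27, n_observers = 5, grid = default_grid(),
                       seed = 1, semi_axes_range = c(8, 18),
                       lesion_uptake_range = c(5, 12),
                       background_uptake = 0.2, psf_fwhm_mm = 6,
                       noise_sd = 0.2, mri_model = NULL, pet_model = NULL,
                       modalities = c("MRI", "MRI_PET")) {
  if (n_lesions < 1) stop("'n_lesions' must be >= 1", call. = FALSE)
  modalities <- match.arg(modalities, several.ok = TRUE)
  if (is.null(mri_model))
    mri_model <- observer_model("boundary_field", boundary_sd_mm = 2.5,
                                bias_mm = seq(-1.2, 1.2,
                                              length.out = n_observers))
  if (is.null(pet_model))
    pet_model <- observer_model("boundary_field", boundary_sd_mm = 1.5,
                                bias_mm = seq(-0.6, 0.6,
                                              length.out = n_observers))
  models <- list(MRI = mri_model, MRI_PET = pet_model)

  with_seed(seed, {
    lesion_seeds <- sample.int(2^30, n_lesions * (1 + length(modalities)))
    co_centre <- (voxel_to_world(grid, c(1, 1, 1)) +
                    voxel_to_world(grid, grid$shape)) / 2
    lesions <- vector("list", n_lesions)
    manifest_rows <- vector("list", n_lesions)
    for (i in seq_len(n_lesions)) {
      id <- sprintf("lesion%02d", i)
      centre <- as.numeric(co_centre) + stats::runif(3, -8, 8)
      axes <- stats::runif(3, semi_axes_range[1], semi_axes_range[2])
      uptake <- stats::runif(1, lesion_uptake_range[1], lesion_uptake_range[2])
      ph_seed <- lesion_seeds[i]
      ph <- make_phantom(grid, lesion_center = centre, semi_axes = axes,
                         lesion_uptake = uptake,
                         background_uptake = background_uptake,
                         psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
                         seed = ph_seed)
      observers <- list()
      for (m in seq_along(modalities)) {
        mod <- modalities[m]
        obs_seed <- lesion_seeds[n_lesions * m + i]
        observers[[mod]] <- simulate_observers(
          ph$truth, models[[mod]], n_observers = n_observers,
          seed = obs_seed, lesion_id = id, modality = mod)
      }
      lesions[[i]] <- list(lesion_id = id, pet = ph$pet, truth = ph$truth,
                           observers = observers)
      manifest_rows[[i]] <- data.frame(
        lesion_id = id, centre_x = centre[1], centre_y = centre[2],
        centre_z = centre[3], semi_axis_x = axes[1], semi_axis_y = axes[2],
        semi_axis_z = axes[3], lesion_uptake = uptake,
        truth_volume_cm3 = mask_volume(ph$truth), phantom_seed = ph_seed)
    }
    structure(list(
      lesions = lesions,
      manifest = list(lesion_table = do.call(rbind, manifest_rows),
                      seed = seed, n_observers = n_observers,
                      modalities = modalities,
                      background_uptake = background_uptake,
                      psf_fwhm_mm = psf_fwhm_mm, noise_sd = noise_sd,
                      models = models)
    ), class = "delineation_study")
  })
}

#' @export
print.delineation_study <- function(x, ...) {
  cat("<delineation_study> ", length(x$lesions), " lesion(s), ",
      x$manifest$n_observers, " observers, conditions: ",
      paste(x$manifest$modalities, collapse = ", "), "\n", sep = "")
  invisible(x)
}
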