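## Synthetic PET/CT phantom cohorts with known ground truth.
## A phantom is a uniform noisy background plus one or more lesions with
## radially decaying Gaussian uptake profiles; simulated observers contour
## the truth with controllable error, emulating a multi-observer GTV study
## (n patients x k observers) without patient imaging.

#' Analytic threshold radius of a Gaussian-profile lesion
#'
#' For a noiseless lesion \code{SUV(r) = B + (P-B) exp(-r^2/(2 sigma^2))} on
#' background B, the surface where SUV equals \code{m * B} is the sphere of
#' radius \code{sigma * sqrt(2 * log((P-B)/(B*(m-1))))}.
#'
#' @param background background SUV B.
#' @param peak lesion peak SUV P (> m*B for a non-empty result).
#' @param sigma_mm profile standard deviation in mm.
#' @param multiplier background-relative threshold m (> 1).
#' @return radius in mm (NaN if the threshold exceeds the peak).
#' @export
analyticThresholdRadius <- function(background, peak, sigma_mm, multiplier) {
  sigma_mm * sqrt(2 * log((peak - background) / (background * (multiplier - 1))))
}

#' Overlap volume of two spheres
#'
#' Closed-form lens volume of two spheres of radii \code{r1}, \code{r2} with
#' center distance \code{d} (all mm; volume in mm^3).
#' @param r1,r2 radii (mm).
#' @param d center distance (mm).
#' @export
sphereOverlapVolume <- function(r1, r2, d) {
  full <- 4 / 3 * pi * pmin(r1, r2)^3
  lens <- pi * (r1 + r2 - d)^2 *
    (d^2 + 2 * d * (r1 + r2) - 3 * (r1 - r2)^2) / (12 * d)
  ifelse(d >= r1 + r2, 0, ifelse(d <= abs(r1 - r2), full, lens))
}

#' Analytic Dice coefficient of two spheres
#' @inheritParams sphereOverlapVolume
#' @export
spherePairDSC <- function(r1, r2, d) {
  2 * sphereOverlapVolume(r1, r2, d) / (4 / 3 * pi * (r1^3 + r2^3))
}

#' Voxelize a sphere on a grid
#'
#' Center-inclusion: a voxel belongs to the sphere iff its center does.
#' @param grid an [ImageGrid-class].
#' @param center world center (mm).
#' @param radius radius (mm).
#' @return a [BinaryMask-class].
#' @export
voxelizeSphere <- function(grid, center, radius) {
  BinaryMask(grid, .roi_voxels(grid, backgroundROI("sphere", center, radius)))
}

#' Phantom specification
#'
#' Defaults emulate the study setting: a PET grid at 2 mm isotropic
#' resolution, a planning-CT grid at 1 x 1 mm in-plane with 3 mm slices,
#' unit background uptake, and a single high-contrast lesion.
#'
#' @param pet_grid PET [ImageGrid-class] (default 64 x 64 x 48 at 2 mm).
#' @param ct_grid planning-CT [ImageGrid-class] (default 128 x 128 x 32 at
#'   1 x 1 x 3 mm, covering the same physical extent).
#' @param background_mean background SUV (default 1).
#' @param noise_sd additive Gaussian SUV noise (default 0.1).
#' @param lesions list of lesions, each \code{list(center, sigma_mm, peak)};
#'   default one lesion at the grid center with sigma 10 mm and peak SUV 9.
#' @param pet_to_ct [RigidTransform-class] PET world to CT world (default a
#'   small rotation plus a few-mm shift, as after rigid registration with
#'   residual setup difference).
#' @return a \code{PhantomSpec} list.
#' @export
phantomSpec <- function(pet_grid = ImageGrid(c(64, 64, 48), c(2, 2, 2)),
                        ct_grid = ImageGrid(c(128, 128, 32), c(1, 1, 3)),
                        background_mean = 1, noise_sd = 0.1,
                        lesions = NULL,
                        pet_to_ct = axisRotation(3, 2, c(3, -2, 1.5))) {
  if (is.null(lesions)) {
    ctr <- pet_grid@origin + (pet_grid@shape - 1) * pet_grid@spacing / 2
    lesions <- list(list(center = ctr, sigma_mm = 10, peak = 9))
  }
  for (l in lesions) {
    stopifnot(l$peak > background_mean, l$sigma_mm > 0, length(l$center) == 3)
  }
  stopifnot(background_mean > 0, noise_sd >= 0)
  structure(list(pet_grid = pet_grid, ct_grid = ct_grid,
                 background_mean = background_mean, noise_sd = noise_sd,
                 lesions = lesions, pet_to_ct = pet_to_ct),
            class = "PhantomSpec")
}

## noiseless SUV field of a spec on its PET grid
.phantom_field <- function(spec) {
  g <- spec$pet_grid
  ax <- lapply(1:3, function(a) g@origin[a] + (seq_len(g@shape[a]) - 1) * g@spacing[a])
  v <- array(spec$background_mean, dim = g@shape)
  for (l in spec$lesions) {
    d2 <- outer(outer((ax[[1]] - l$center[1])^2, (ax[[2]] - l$center[2])^2, "+"),
                (ax[[3]] - l$center[3])^2, "+")
    v <- v + (l$peak - spec$background_mean) * exp(-d2 / (2 * l$sigma_mm^2))
  }
  v
}

#' Generate a PET phantom
#'
#' SUV(x) = background + sum over lesions of (P-B) exp(-d^2 / (2 sigma^2))
#' plus Gaussian noise, clipped at 0. Identical seeds give identical output.
#' Truth masks are the noiseless field thresholded at each multiplier times
#' the background (for a single spherical lesion these are the analytic
#' spheres of [analyticThresholdRadius()]).
#'
#' @param spec a [phantomSpec()].
#' @param seed integer seed.
#' @param multipliers thresholds for the truth masks (default c(1.5, 2, 2.5)).
#' @return list: \code{suv} ([SUVImage-class] on the PET grid), \code{truth}
#'   (named list of [BinaryMask-class] per multiplier), \code{ct_grid},
#'   \code{transform} (PET to CT [RigidTransform-class]).
#' @export
generatePhantom <- function(spec, seed, multipliers = c(1.5, 2, 2.5)) {
  g <- spec$pet_grid
  clean <- .phantom_field(spec)
  noisy <- if (spec$noise_sd > 0) {
    withr::with_seed(as.integer(seed),
      pmax(clean + array(rnorm(length(clean), 0, spec$noise_sd), dim = g@shape), 0))
  } else clean
  truth <- lapply(multipliers, function(m)
    BinaryMask(g, clean >= m * spec$background_mean))
  names(truth) <- as.character(multipliers)
  list(suv = SUVImage(g, noisy), truth = truth, ct_grid = spec$ct_grid,
       transform = spec$pet_to_ct)
}

#' Observer-error specification
#'
#' Two generative models for a simulated contourer:
#' \itemize{
#'   \item \code{"parametric-sphere"}: the observer draws a sphere whose
#'     center is jittered (isotropic Gaussian, sd \code{center_jitter_sd} mm)
#'     and whose radius is jittered (Gaussian, sd \code{radius_jitter_sd} mm)
#'     plus a systematic expansion/contraction bias (mm).
#'   \item \code{"distance-field"}: the truth mask's signed Euclidean
#'     distance (negative inside) is thresholded at a smooth Gaussian random
#'     field (correlation length \code{field_smoothness} mm, sd
#'     \code{field_sd} mm) plus the bias, producing spatially correlated
#'     boundary errors of any shape.
#' }
#'
#' @param mode \code{"parametric-sphere"} or \code{"distance-field"}.
#' @param center_jitter_sd,radius_jitter_sd mm (parametric mode).
#' @param field_smoothness,field_sd mm (distance-field mode).
#' @param systematic_bias mm; positive expands the contour.
#' @return an \code{ObserverErrorSpec} list.
#' @export
observerErrorSpec <- function(mode = c("parametric-sphere", "distance-field"),
                              center_jitter_sd = 0, radius_jitter_sd = 0,
                              field_smoothness = 8, field_sd = 0,
                              systematic_bias = 0) {
  mode <- match.arg(mode)
  stopifnot(center_jitter_sd >= 0, radius_jitter_sd >= 0, field_sd >= 0,
            field_smoothness > 0)
  structure(list(mode = mode, center_jitter_sd = center_jitter_sd,
                 radius_jitter_sd = radius_jitter_sd,
                 field_smoothness = field_smoothness, field_sd = field_sd,
                 systematic_bias = systematic_bias),
            class = "ObserverErrorSpec")
}

## smooth Gaussian random field on a grid: white noise convolved with a
## separable Gaussian kernel (sd = smoothness mm per axis), rescaled to the
## requested pointwise sd (empirical normalization over the array).
.gaussian_field <- function(grid, smoothness_mm, sd_mm) {
  v <- array(rnorm(prod(grid@shape)), dim = grid@shape)
  for (a in 1:3) {
    s_vox <- smoothness_mm / grid@spacing[a]
    half <- max(1L, ceiling(3 * s_vox))
    k <- exp(-(seq(-half, half))^2 / (2 * s_vox^2))
    k <- k / sum(k)
    n <- grid@shape[a]
    ## convolution matrix with reflected boundaries
    K <- matrix(0, n, n)
    for (o in seq(-half, half)) {
      j <- seq_len(n) + o
      j <- ifelse(j < 1, 2 - j, ifelse(j > n, 2 * n - j, j))
      K[cbind(seq_len(n), j)] <- K[cbind(seq_len(n), j)] + k[o + half + 1]
    }
    perm <- c(a, setdiff(1:3, a))
    m <- K %*% matrix(aperm(v, perm), nrow = n)
    v <- aperm(array(m, dim = grid@shape[perm]), order(perm))
  }
  v / sd(v) * sd_mm
}

## signed distance (mm) to a mask surface, negative inside, computed exactly
## on a band around the mask and saturated at +-cap elsewhere
.signed_distance_band <- function(mask, cap_mm) {
  g <- mask@grid
  surf <- surfaceVoxels(mask)
  idx <- which(mask@voxels, arr.ind = TRUE)
  lo <- pmax(1L, apply(idx, 2, min) - ceiling(cap_mm / g@spacing))
  hi <- pmin(g@shape, apply(idx, 2, max) + ceiling(cap_mm / g@spacing))
  sub <- as.matrix(expand.grid(i = lo[1]:hi[1], j = lo[2]:hi[2], k = lo[3]:hi[3]))
  dists <- .nn_min_dist(voxelToWorld(g, sub), surf)
  out <- array(cap_mm, dim = g@shape)
  out[mask@voxels] <- -cap_mm
  lin <- (sub[, 3] - 1) * (g@shape[1] * g@shape[2]) + (sub[, 2] - 1) * g@shape[1] + sub[, 1]
  inside <- mask@voxels[lin]
  out[lin] <- ifelse(inside, -dists, dists)
  out
}

#' Simulate one observer's contour
#'
#' @param truth either \code{list(center, radius)} describing a spherical
#'   true GTV in world mm (parametric-sphere mode) or a non-empty
#'   [BinaryMask-class] (distance-field mode).
#' @param err an [observerErrorSpec()].
#' @param seed integer seed.
#' @param grid target [ImageGrid-class] for the contour (required in
#'   parametric mode; defaults to the truth mask's grid otherwise).
#' @return a non-empty [BinaryMask-class]. If a perturbation annihilates the
#'   mask the draw is resampled (up to 10 times) before erroring.
#' @export
simulateObserver <- function(truth, err, seed, grid = NULL) {
  for (try in 0:9) {
    m <- withr::with_seed(as.integer(seed) + 1000003L * try,
                          .simulate_observer_once(truth, err, grid))
    if (any(m@voxels)) return(m)
  }
  .gtv_error("emptyMaskError", "observer perturbation annihilated the mask 10 times")
}

.simulate_observer_once <- function(truth, err, grid) {
  if (err$mode == "parametric-sphere") {
    stopifnot(is.list(truth), !is.null(truth$center), !is.null(truth$radius))
    if (is.null(grid)) stop("parametric-sphere mode requires a target grid")
    ctr <- truth$center + rnorm(3, 0, err$center_jitter_sd)
    r <- truth$radius + rnorm(1, 0, err$radius_jitter_sd) + err$systematic_bias
    r <- max(r, 0.05 * truth$radius)
    voxelizeSphere(grid, ctr, r)
  } else {
    stopifnot(is(truth, "BinaryMask"))
    g <- if (is.null(grid)) truth@grid else grid
    cap <- 4 * err$field_sd + abs(err$systematic_bias) + max(g@spacing) + 1
    sdist <- .signed_distance_band(truth, cap)
    fld <- if (err$field_sd > 0)
      .gaussian_field(g, err$field_smoothness, err$field_sd)
    else array(0, dim = g@shape)
    BinaryMask(g, sdist <= fld + err$systematic_bias)
  }
}

#' Calibrate observer error to a target mean pairwise Dice coefficient
#'
#' Finds the parametric-sphere jitter scale at which two independent
#' simulated observers of a spherical truth of the given radius agree at the
#' requested expected pairwise DSC. The expectation is evaluated by Monte
#' Carlo over the closed-form sphere-pair Dice ([spherePairDSC()]), with
#' common random numbers so the curve is smooth in the scale; the scale is
#' then solved by root finding. Center jitter sd equals the scale; radius
#' jitter sd is half the scale.
#'
#' @param target_dsc requested expected pairwise DSC (0.3-0.95 is sensible).
#' @param radius_mm truth sphere radius (mm).
#' @param n_mc Monte-Carlo draws (default 4000).
#' @param seed seed for the calibration draws.
#' @return an [observerErrorSpec()] in parametric-sphere mode.
#' @export
calibrateObserverError <- function(target_dsc, radius_mm, n_mc = 4000, seed = 42) {
  stopifnot(target_dsc > 0.2, target_dsc < 0.99)
  Z <- withr::with_seed(as.integer(seed), matrix(rnorm(n_mc * 8), n_mc, 8))
  mean_dsc <- function(s) {
    c1 <- s * Z[, 1:3]; c2 <- s * Z[, 5:7]
    r1 <- pmax(radius_mm + 0.5 * s * Z[, 4], 0.05 * radius_mm)
    r2 <- pmax(radius_mm + 0.5 * s * Z[, 8], 0.05 * radius_mm)
    d <- pmax(sqrt(rowSums((c1 - c2)^2)), 1e-9)
    mean(spherePairDSC(r1, r2, d))
  }
  root <- uniroot(function(s) mean_dsc(s) - target_dsc,
                  lower = 1e-3 * radius_mm, upper = 1.5 * radius_mm,
                  tol = 1e-4 * radius_mm)
  observerErrorSpec("parametric-sphere",
                    center_jitter_sd = root$root,
                    radius_jitter_sd = root$root / 2)
}

#' Cohort specification
#'
#' Defaults mirror the study design: 7 patients, 6 observers. Per-patient
#' lesions vary in size (sigma 7-11 mm) and contrast (peak SUV 7-11) so
#' manual GTVs span a clinically plausible volume range; all observers share
#' one error level calibrated to a mean pairwise DSC of 0.60 unless
#' per-observer specs are given.
#'
#' @param n_patients number of patients (>= 1, default 7).
#' @param n_observers number of observers (>= 2, default 6).
#' @param observer_errors optional list of [observerErrorSpec()] of length
#'   \code{n_observers}; NULL for the calibrated common level.
#' @param target_dsc calibration target when \code{observer_errors} is NULL.
#' @param master_seed integer master seed; per-patient and per-observer seeds
#'   fan out deterministically from it.
#' @param phantoms optional list of [phantomSpec()] of length
#'   \code{n_patients}; NULL for the built-in per-patient variation.
#' @return a \code{CohortSpec} list.
#' @export
cohortSpec <- function(n_patients = 7, n_observers = 6, observer_errors = NULL,
                       target_dsc = 0.60, master_seed = 1, phantoms = NULL) {
  stopifnot(n_patients >= 1, n_observers >= 2)
  if (is.null(phantoms)) {
    phantoms <- lapply(seq_len(n_patients), function(p) {
      fr <- if (n_patients > 1) (p - 1) / (n_patients - 1) else 0.5
      g <- ImageGrid(c(64, 64, 48), c(2, 2, 2))
      ctr <- g@origin + (g@shape - 1) * g@spacing / 2
      phantomSpec(pet_grid = g,
                  lesions = list(list(center = ctr, sigma_mm = 7 + 4 * fr,
                                      peak = 7 + 4 * ((p * 3) %% (n_patients + 1)) /
                                        n_patients)))
    })
  }
  stopifnot(length(phantoms) == n_patients)
  if (!is.null(observer_errors)) stopifnot(length(observer_errors) == n_observers)
  structure(list(n_patients = n_patients, n_observers = n_observers,
                 observer_errors = observer_errors, target_dsc = target_dsc,
                 master_seed = as.integer(master_seed), phantoms = phantoms),
            class = "CohortSpec")
}

## deterministic seed fan-out, kept below 2^31
.sub_seed <- function(master, patient, observer = 0L) {
  as.integer((as.double(master) * 2654435761 + patient * 40503 + observer * 9973) %%
               2147483647)
}

#' Generate a synthetic cohort on disk
#'
#' Writes, per patient: the SUV image and truth masks on the PET grid, one
#' contour per observer on the CT grid (manual-contour emulation), the
#' PET-to-CT transform, and a JSON manifest tying them together (including a
#' suggested background ROI placed in lesion-free background). The true GTV
#' each observer contours is the background-relative threshold-2.0 surface,
#' mapped into CT world through the ground-truth transform.
#'
#' @param spec a [cohortSpec()].
#' @param out_dir output directory (created if needed).
#' @return character vector of manifest paths, invisibly.
#' @export
generateCohort <- function(spec, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  errs <- spec$observer_errors
  if (is.null(errs)) {
    ## calibrate once against the median lesion radius of the cohort
    radii <- vapply(spec$phantoms, function(ps)
      analyticThresholdRadius(ps$background_mean, ps$lesions[[1]]$peak,
                              ps$lesions[[1]]$sigma_mm, 2), numeric(1))
    err <- calibrateObserverError(spec$target_dsc, median(radii),
                                  seed = .sub_seed(spec$master_seed, 0L))
    errs <- rep(list(err), spec$n_observers)
  }
  manifests <- character(spec$n_patients)
  for (p in seq_len(spec$n_patients)) {
    ps <- spec$phantoms[[p]]
    pid <- sprintf("P%02d", p)
    pdir <- file.path(out_dir, pid)
    dir.create(pdir, showWarnings = FALSE)
    ph <- generatePhantom(ps, .sub_seed(spec$master_seed, p))
    writeVolume(ph$suv, file.path(pdir, "suv.nii.gz"))
    for (m in names(ph$truth))
      writeVolume(ph$truth[[m]], file.path(pdir, sprintf("truth_x%s.nii.gz", m)))
    writeTransform(ph$transform, file.path(pdir, "pet_to_ct.json"))
    lesion <- ps$lesions[[1]]
    r_true <- analyticThresholdRadius(ps$background_mean, lesion$peak,
                                      lesion$sigma_mm, 2)
    ct_center <- as.numeric(applyRigid(ph$transform, matrix(lesion$center, 1)))
    obs_paths <- character(spec$n_observers)
    for (o in seq_len(spec$n_observers)) {
      m <- simulateObserver(list(center = ct_center, radius = r_true), errs[[o]],
                            .sub_seed(spec$master_seed, p, o), grid = ps$ct_grid)
      obs_paths[o] <- sprintf("observer_%02d.nii.gz", o)
      writeVolume(m, file.path(pdir, obs_paths[o]))
    }
    names(obs_paths) <- sprintf("RO%d", seq_len(spec$n_observers))
    r_bg <- 6
    g_pet <- ps$pet_grid
    roi_x <- lesion$center[1] -
      (analyticThresholdRadius(ps$background_mean, lesion$peak,
                               lesion$sigma_mm, 1.5) + 10 + r_bg)
    ## keep the ROI sphere fully inside the grid on small phantoms
    roi_x <- max(roi_x, g_pet@origin[1] + r_bg)
    roi_center <- c(roi_x, lesion$center[2], lesion$center[3])
    man <- list(patient_id = pid, suv_image = "suv.nii.gz",
                observer_masks = as.list(obs_paths),
                truth_masks = as.list(setNames(
                  sprintf("truth_x%s.nii.gz", names(ph$truth)), names(ph$truth))),
                transform = "pet_to_ct.json",
                background_roi = list(shape = "sphere", center = roi_center,
                                      size = r_bg),
                lesion = lesion)
    manifests[p] <- file.path(pdir, "manifest.json")
    writeManifest(man, manifests[p])
  }
  invisible(manifests)
}
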