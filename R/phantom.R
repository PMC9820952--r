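#' Specification of a synthetic paired CBCT/CT phantom
#'
#' The phantom emulates the situation the segmentation model faces on
#' clinical data: two mirrored muscle-like ellipsoids (tapered towards their
#' superior extent, the region hardest to delineate on real scans) embedded
#' in a fat-like background next to a bone plate, surrounded by an air rim.
#' The same geometry is rendered twice: once with CT noise levels and once
#' with CBCT noise levels around identical per-compartment mean HU, so the
#' muscle HU distribution has a similar centre but a larger variance in the
#' CBCT rendering - the property that motivates training one model jointly
#' on both modalities.
#'
#' @param shape integer length-3, grid size in voxels.
#' @param spacing voxel size in mm.
#' @param muscle_center centre of the left muscle ellipsoid in mm, relative
#'   to the grid centre; the right muscle is its mirror image through the
#'   x = 0 plane.
#' @param muscle_semiaxes ellipsoid semi-axes in mm.
#' @param muscle_taper fractional shrinkage of the transverse semi-axes at
#'   the superior tip (0 = no taper, 0.5 = tip has half the girth).
#' @param bone_halfwidth half-extent in mm of the central bone plate.
#' @param hu per-compartment intensity model: mean HU plus the CT and CBCT
#'   noise standard deviations.  The CBCT muscle SD must be >= the CT SD.
#' @param smooth_fwhm full width at half maximum (mm) of the Gaussian
#'   point-spread function applied to both the anatomy and the noise.
#' @param air_rim thickness (mm) of the air shell at the grid boundary.
#' @param jitter SD (mm) of the random asymmetry applied independently to
#'   each side's centre (additively) and semi-axes (multiplicatively, as
#'   `exp(jitter/10)`-scale factors); 0 gives exactly mirrored muscles.
#' @return An object of class `mm_phantom_spec`.
#' @export
phantom_spec <- function(shape = c(64L, 64L, 64L),
                         spacing = c(0.5, 0.5, 0.5),
                         muscle_center = c(8, 0, -1),
                         muscle_semiaxes = c(4, 6, 10),
                         muscle_taper = 0.5,
                         bone_halfwidth = c(1.5, 10, 12),
                         hu = list(
                           muscle = c(mean = 60, sd_ct = 15, sd_cbct = 60),
                           fat    = c(mean = -100, sd_ct = 20, sd_cbct = 60),
                           bone   = c(mean = 900, sd_ct = 80, sd_cbct = 150),
                           air    = c(mean = -1000, sd_ct = 30, sd_cbct = 60)),
                         smooth_fwhm = 1.2,
                         air_rim = 1.5,
                         jitter = 0.5) {
  spec <- structure(list(shape = as.integer(shape), spacing = as.numeric(spacing),
                         muscle_center = muscle_center,
                         muscle_semiaxes = muscle_semiaxes,
                         muscle_taper = muscle_taper,
                         bone_halfwidth = bone_halfwidth, hu = hu,
                         smooth_fwhm = smooth_fwhm, air_rim = air_rim,
                         jitter = jitter),
                    class = "mm_phantom_spec")
  validate_phantom_spec(spec)
  spec
}

validate_phantom_spec <- function(spec) {
  if (any(spec$shape < 8L)) stop("phantom grid must be at least 8 voxels per axis")
  if (any(spec$spacing <= 0)) stop("spacing must be positive")
  if (any(spec$muscle_semiaxes <= 0)) stop("muscle semi-axes must be positive")
  if (spec$muscle_taper < 0 || spec$muscle_taper >= 1)
    stop("muscle_taper must lie in [0, 1)")
  if (spec$jitter < 0) stop("jitter must be non-negative")
  for (comp in names(spec$hu)) {
    p <- spec$hu[[comp]]
    if (any(p[c("sd_ct", "sd_cbct")] < 0)) stop("negative noise SD for ", comp)
  }
  if (spec$hu$muscle[["sd_cbct"]] < spec$hu$muscle[["sd_ct"]])
    stop("CBCT muscle HU SD must be >= CT muscle HU SD")
  invisible(spec)
}

# physical coordinates (mm) of voxel centres, grid centre at 0
phantom_coords <- function(shape, spacing) {
  lapply(1:3, function(a) (seq_len(shape[a]) - (shape[a] + 1) / 2) * spacing[a])
}

# logical mask of one tapered muscle ellipsoid; side = +1 (left) or -1 (right)
muscle_mask <- function(spec, side, center, semi) {
  cc <- phantom_coords(spec$shape, spec$spacing)
  cx <- side * center[1]
  zrel <- (cc[[3]] - center[3]) / semi[3]
  taper <- 1 - spec$muscle_taper * pmax(0, zrel)
  taper <- pmax(taper, 0.05)
  dx2 <- outer((cc[[1]] - cx)^2, rep(1, spec$shape[2]))
  dy2 <- outer(rep(1, spec$shape[1]), (cc[[2]] - center[2])^2)
  m <- array(FALSE, spec$shape)
  for (k in seq_len(spec$shape[3])) {
    t2 <- (semi[1] * taper[k])^2
    u2 <- (semi[2] * taper[k])^2
    m[, , k] <- dx2 / t2 + dy2 / u2 + zrel[k]^2 <= 1
  }
  m
}

phantom_compartments <- function(spec, jit_l, jit_r) {
  cc <- phantom_coords(spec$shape, spec$spacing)
  half <- spec$shape * spec$spacing / 2
  rim <- lapply(1:3, function(a) abs(cc[[a]]) > half[a] - spec$air_rim)
  air <- outer(outer(rim[[1]], rim[[2]], "|"), rim[[3]], "|")
  bone <- outer(outer(abs(cc[[1]]) <= spec$bone_halfwidth[1],
                      abs(cc[[2]]) <= spec$bone_halfwidth[2], "&"),
                abs(cc[[3]]) <= spec$bone_halfwidth[3], "&") & !air
  left  <- muscle_mask(spec, +1, spec$muscle_center + jit_l[1:3],
                       spec$muscle_semiaxes * exp(jit_l[4:6] / 10))
  right <- muscle_mask(spec, -1, spec$muscle_center + jit_r[1:3],
                       spec$muscle_semiaxes * exp(jit_r[4:6] / 10))
  left  <- left & !air & !bone
  right <- right & !air & !bone
  list(air = air, bone = bone & !left & !right, left = left, right = right)
}

#' Generate one synthetic paired CBCT/CT case
#'
#' Both modalities share the exact same geometry (the phantoms are generated
#' pre-aligned on a common grid, standing in for the clinical CBCT-to-CT
#' superimposition step) and one ground-truth label map.  The whole case is
#' reproducible from `(spec, seed)`.
#'
#' @param spec an [phantom_spec()].
#' @param seed integer seed controlling the anatomy jitter and the noise.
#' @param id case identifier; defaults to one derived from the seed.
#' @return A `mm_paired_case`: list with `id`, `cbct` and `ct`
#'   ([new_volume()]) and `truth` ([new_label_map()]).
#' @export
generate_case <- function(spec, seed, id = sprintf("case_s%d", seed)) {
  validate_phantom_spec(spec)
  set.seed(seed)
  jit_l <- rnorm(6, 0, spec$jitter)
  jit_r <- rnorm(6, 0, spec$jitter)
  comp <- phantom_compartments(spec, jit_l, jit_r)
  fat <- !(comp$air | comp$bone | comp$left | comp$right)
  shape <- spec$shape
  sigma_vox <- (spec$smooth_fwhm / 2.3548) / spec$spacing

  mean_vol <- array(spec$hu$fat[["mean"]], shape)
  mean_vol[comp$air]  <- spec$hu$air[["mean"]]
  mean_vol[comp$bone] <- spec$hu$bone[["mean"]]
  mean_vol[comp$left] <- spec$hu$muscle[["mean"]]
  mean_vol[comp$right] <- spec$hu$muscle[["mean"]]
  mean_sm <- array(gauss_smooth3(as.vector(mean_vol), shape, sigma_vox), shape)

  # correlated noise with marginal SD matched to the configured values:
  # white noise is smoothed by the same PSF, then rescaled by the inverse of
  # the kernel's L2 norm so the interior SD stays at the configured level
  l2 <- prod(vapply(sigma_vox, function(s) {
    if (s <= 0) return(1)
    r <- max(1L, ceiling(3 * s))
    k <- exp(-0.5 * (-r:r)^2 / s^2); k <- k / sum(k)
    sqrt(sum(k^2))
  }, 0))
  render <- function(which_sd) {
    sdv <- array(spec$hu$fat[[which_sd]], shape)
    sdv[comp$air]  <- spec$hu$air[[which_sd]]
    sdv[comp$bone] <- spec$hu$bone[[which_sd]]
    sdv[comp$left] <- spec$hu$muscle[[which_sd]]
    sdv[comp$right] <- spec$hu$muscle[[which_sd]]
    noise <- array(rnorm(prod(shape)), shape) * sdv
    noise <- array(gauss_smooth3(as.vector(noise), shape, sigma_vox), shape) / l2
    mean_sm + noise
  }
  ct <- render("sd_ct")
  cbct <- render("sd_cbct")

  truth <- array(0L, shape)
  truth[comp$left] <- 1L
  truth[comp$right] <- 2L
  origin <- -(shape - 1) / 2 * spec$spacing
  structure(list(id = id,
                 cbct = new_volume(cbct, spec$spacing, origin),
                 ct = new_volume(ct, spec$spacing, origin),
                 truth = new_label_map(truth, spec$spacing, origin)),
            class = "mm_paired_case")
}

#' Generate a reproducible phantom dataset with a train/val/test split
#'
#' Per-case sub-seeds are derived deterministically from the master seed, so
#' the same `(spec, n, seed)` always yields voxel-identical cases.
#'
#' @inheritParams generate_case
#' @param n number of cases (>= 1).
#' @param split named ratios for the train/val/test partition.
#' @return List with `cases` (list of paired cases) and `manifest`
#'   (case ids, sub-seeds, spec hash, split assignment).
#' @export
generate_dataset <- function(spec, n, seed,
                             split = c(train = 0.6, val = 0.2, test = 0.2)) {
  if (n < 1) stop("n must be >= 1")
  set.seed(seed)
  sub_seeds <- sample.int(.Machine$integer.max - 1L, n)
  ids <- sprintf("case_%03d", seq_len(n))
  sizes <- diff(round(cumsum(c(0, split)) * n))
  assignment <- rep(names(split), sizes)
  cases <- vector("list", n)
  for (i in seq_len(n)) cases[[i]] <- generate_case(spec, sub_seeds[i], id = ids[i])
  names(cases) <- ids
  manifest <- list(case_id = ids, seed = sub_seeds, split = assignment,
                   master_seed = seed, spec_hash = hash_object(unclass(spec)))
  list(cases = cases, manifest = manifest)
}

#' Simulate an imperfect observer annotation
#'
#' Perturbs a ground-truth label map by a smooth random displacement field,
#' emulating interobserver variation in manual delineation so that paired
#' agreement statistics have realistic inputs.  Magnitude 0 returns the
#' truth unchanged; labels always remain in \{0, 1, 2\}.
#'
#' @param truth an [new_label_map()].
#' @param error_model list with `magnitude` (RMS displacement in mm, >= 0)
#'   and `smoothness` (correlation length of the field, in voxels).
#' @param seed integer seed.
#' @return A perturbed [new_label_map()].
#' @export
simulate_observer <- function(truth, error_model = list(magnitude = 1, smoothness = 4),
                              seed = 1) {
  validate_label_map(truth)
  mag <- error_model$magnitude
  smooth <- if (is.null(error_model$smoothness)) 4 else error_model$smoothness
  if (mag < 0) stop("displacement magnitude must be non-negative")
  if (mag == 0) return(truth)
  set.seed(seed)
  shape <- dim(truth$labels)
  n <- prod(shape)
  disp <- matrix(0, n, 3)
  for (a in 1:3) {
    f <- gauss_smooth3(rnorm(n), shape, rep(smooth, 3))
    f <- f / sqrt(mean(f^2))              # unit RMS
    disp[, a] <- f * mag / truth$spacing[a]  # mm -> voxels
  }
  warped <- warp_nearest(as.numeric(truth$labels), shape, disp)
  new_label_map(array(warped, shape), truth$spacing, truth$origin)
}

# md5 of the canonical JSON rendering of an R object
hash_object <- function(x) {
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA), f)
  unname(tools::md5sum(f))
}
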