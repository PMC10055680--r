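#' Digital phantom constructor
#'
#' @param label_map integer array (nx x ny x nz); 0 is background.
#' @param region_params data frame with columns label, t1, t2, t1rho, pd,
#'   b1 — one row per nonzero label.
#' @param voxel_size mm triple.
#' @return An object of class `mrf_phantom`.
#' @export
digital_phantom <- function(label_map, region_params,
                            voxel_size = c(1, 1, 3)) {
  stopifnot(is.array(label_map), length(dim(label_map)) == 3)
  labs <- sort(unique(as.vector(label_map)))
  labs <- labs[labs != 0]
  if (!all(labs %in% region_params$label))
    stop("every nonzero label needs parameters")
  structure(list(label_map = label_map, region_params = region_params,
                 voxel_size = voxel_size), class = "mrf_phantom")
}

#' @export
print.mrf_phantom <- function(x, ...) {
  cat("mrf_phantom:", paste(dim(x$label_map), collapse = " x "),
      "voxels,", nrow(x$region_params), "regions\n")
  invisible(x)
}

#' Ground-truth parameter maps of a phantom
#'
#' @param phantom an `mrf_phantom`.
#' @return List of arrays `t1`, `t2`, `t1rho`, `pd`, `b1` (background NA,
#'   pd 0).
#' @export
phantom_truth_maps <- function(phantom) {
  lm <- phantom$label_map
  rp <- phantom$region_params
  lut <- function(col, bg) {
    v <- rep(bg, max(rp$label) + 1L)
    v[rp$label + 1L] <- rp[[col]]
    array(v[lm + 1L], dim = dim(lm))
  }
  list(t1 = lut("t1", NA_real_), t2 = lut("t2", NA_real_),
       t1rho = lut("t1rho", NA_real_), pd = lut("pd", 0),
       b1 = lut("b1", NA_real_))
}

# Sphere membership on an anisotropic voxel grid (voxel units in-plane).
sphere_mask <- function(shape, center, radius, voxel_size) {
  x <- seq_len(shape[1]); y <- seq_len(shape[2]); z <- seq_len(shape[3])
  dz_scale <- voxel_size[3] / voxel_size[1]
  dx2 <- (x - center[1])^2
  dy2 <- (y - center[2])^2
  dz2 <- ((z - center[3]) * dz_scale)^2
  outer(outer(dx2, dy2, `+`), dz2, `+`) <= radius^2
}

#' NIST-like sphere phantom
#'
#' A digital analogue of the standardized 14-sphere system phantom:
#' disjoint spheres on a circular layout, with T1 geometrically spaced
#' over 200-2500 ms, T2 over 5-600 ms and T1rho over 5-450 ms (the lower
#' bounds clamp the published 0 ms range ends to physically simulable
#' values).
#'
#' @param shape volume dimensions (default `c(64, 64, 1)`).
#' @param n_spheres number of spheres (default 14).
#' @param radius sphere radius in in-plane voxel units.
#' @param ring_radius layout circle radius in voxels.
#' @param t1_range,t2_range,t1rho_range ms ranges spanned geometrically
#'   across the spheres.
#' @param voxel_size mm triple.
#' @return An `mrf_phantom` with labels `1..n_spheres`.
#' @export
make_nist_like_phantom <- function(shape = c(64, 64, 1), n_spheres = 14,
                                   radius = 4, ring_radius = 23,
                                   t1_range = c(200, 2500),
                                   t2_range = c(5, 600),
                                   t1rho_range = c(5, 450),
                                   voxel_size = c(1, 1, 3)) {
  n_spheres <- as.integer(n_spheres)
  stopifnot(n_spheres >= 1)
  cx <- shape[1] / 2 + 0.5; cy <- shape[2] / 2 + 0.5
  cz <- (shape[3] + 1) / 2
  if (n_spheres == 1L) {
    centers <- cbind(cx, cy, cz)
  } else {
    th <- 2 * pi * (seq_len(n_spheres) - 1) / n_spheres
    centers <- cbind(cx + ring_radius * cos(th), cy + ring_radius * sin(th), cz)
    min_gap <- 2 * ring_radius * sin(pi / n_spheres)
    if (min_gap <= 2 * radius) stop("spheres overlap: reduce radius or n_spheres")
  }
  if (any(centers[, 1] - radius < 1 | centers[, 1] + radius > shape[1] |
          centers[, 2] - radius < 1 | centers[, 2] + radius > shape[2]))
    stop("spheres do not fit in the volume")

  gspace <- function(rng, n) {
    if (n == 1) sqrt(rng[1] * rng[2]) else
      exp(seq(log(rng[1]), log(rng[2]), length.out = n))
  }
  lm <- array(0L, dim = shape)
  for (i in seq_len(n_spheres)) {
    m <- sphere_mask(shape, centers[i, ], radius, voxel_size)
    lm[m] <- i
  }
  rp <- data.frame(label = seq_len(n_spheres),
                   t1 = gspace(t1_range, n_spheres),
                   t2 = gspace(t2_range, n_spheres),
                   t1rho = gspace(t1rho_range, n_spheres),
                   pd = 1, b1 = 1)
  digital_phantom(lm, rp, voxel_size)
}

#' Brain-like compartment phantom
#'
#' Concentric elliptical CSF / gray matter / white matter compartments
#' with optional focal lesions inside the white matter. Lesion
#' parameters default to the white-matter values elevated by
#' `lesion_spec$delta` (fractional increase on T1, T2 and T1rho),
#' emulating the elevated relaxation times of demyelinating lesions
#' relative to normal-appearing white matter.
#'
#' @param shape volume dimensions.
#' @param lesion_spec list of lesions, each a list with `center` (voxel
#'   x, y and optionally z), `radius` (voxels) and `delta` (fractional
#'   elevation, default 0.3). `NULL` for none.
#' @param wm,gm,csf named lists with t1, t2, t1rho, pd (ms / a.u.).
#' @param voxel_size mm triple.
#' @return An `mrf_phantom` with labels 1 = CSF, 2 = GM, 3 = WM,
#'   4, 5, ... = lesions, and an attribute-free `region_params` table.
#' @export
make_brain_like_phantom <- function(shape = c(64, 64, 1), lesion_spec = NULL,
                                    wm = list(t1 = 850, t2 = 70, t1rho = 80, pd = 0.8),
                                    gm = list(t1 = 1400, t2 = 95, t1rho = 100, pd = 0.9),
                                    csf = list(t1 = 4000, t2 = 1800, t1rho = 1500, pd = 1),
                                    voxel_size = c(1, 1, 3)) {
  cx <- shape[1] / 2 + 0.5; cy <- shape[2] / 2 + 0.5
  ax <- 0.45 * shape[1]; by <- 0.45 * shape[2]
  x <- seq_len(shape[1]); y <- seq_len(shape[2])
  r2 <- outer(((x - cx) / ax)^2, ((y - cy) / by)^2, `+`)
  sl <- matrix(0L, shape[1], shape[2])
  sl[r2 <= 1] <- 2L              # GM shell
  sl[r2 <= 0.78^2] <- 3L         # WM interior
  vr2 <- outer(((x - cx) / (0.14 * shape[1]))^2,
               ((y - cy) / (0.09 * shape[2]))^2, `+`)
  sl[vr2 <= 1] <- 1L             # central CSF (ventricle-like)
  lm <- array(rep(sl, shape[3]), dim = shape)

  rp <- data.frame(label = 1:3,
                   t1 = c(csf$t1, gm$t1, wm$t1),
                   t2 = c(csf$t2, gm$t2, wm$t2),
                   t1rho = c(csf$t1rho, gm$t1rho, wm$t1rho),
                   pd = c(csf$pd, gm$pd, wm$pd),
                   b1 = 1)
  if (!is.null(lesion_spec)) {
    for (i in seq_along(lesion_spec)) {
      les <- lesion_spec[[i]]
      delta <- if (is.null(les$delta)) 0.3 else les$delta
      ctr <- les$center
      if (length(ctr) == 2) ctr <- c(ctr, (shape[3] + 1) / 2)
      m <- sphere_mask(shape, ctr, les$radius, voxel_size)
      if (any(lm[m] != 3L))
        stop("lesion ", i, " is not fully inside white matter")
      lab <- 3L + i
      lm[m] <- lab
      rp <- rbind(rp, data.frame(label = lab,
                                 t1 = wm$t1 * (1 + delta),
                                 t2 = wm$t2 * (1 + delta),
                                 t1rho = wm$t1rho * (1 + delta),
                                 pd = wm$pd, b1 = 1))
    }
  }
  digital_phantom(lm, rp, voxel_size)
}

#' Golden-angle spoke table
#'
#' Within shot `s` (0-based), frame `k` (0-based) is acquired at azimuth
#' `(s * 180 / n_shots + k * GA) mod 360` degrees with the golden-angle
#' increment `GA = 180 * (sqrt(5) - 1) / 2 = 111.2461...` degrees; the
#' shot offsets are exactly `180 / n_shots` apart.
#'
#' @param n_frames frames (readouts) per shot.
#' @param n_shots number of interleaved shots.
#' @return Data frame with columns `shot`, `frame`, `angle_deg`.
#' @export
golden_angle_spokes <- function(n_frames, n_shots = 1L) {
  stopifnot(n_frames >= 1, n_shots >= 1)
  ga <- 180 * (sqrt(5) - 1) / 2
  g <- expand.grid(frame = 0:(n_frames - 1L), shot = 0:(n_shots - 1L))
  data.frame(shot = g$shot, frame = g$frame,
             angle_deg = (g$shot * 180 / n_shots + g$frame * ga) %% 360)
}

#' Center-out kz partition ordering
#'
#' @param nz number of kz partitions.
#' @return Integer permutation of `1..nz` starting at the central
#'   partition and alternating outward.
#' @export
kz_center_out <- function(nz) {
  stopifnot(nz >= 1)
  center <- floor(nz / 2) + 1L
  offs <- c(0L, as.vector(rbind(seq_len(nz), -seq_len(nz))))
  ord <- center + offs
  ord[ord >= 1L & ord <= nz][seq_len(nz)]
}

#' Acquisition configuration
#'
#' @param n_shots interleaved shots (angle offset `180 / n_shots`).
#' @param noise_sigma SD of the complex noise per sample (total over both
#'   quadratures: real and imaginary parts each have SD
#'   `noise_sigma / sqrt(2)`).
#' @param seed RNG seed; all randomness in the simulated acquisition
#'   flows from it.
#' @param mode `"direct"` (per-voxel fingerprints) or `"kspace"` (radial
#'   stack-of-stars sampling).
#' @param spokes_per_frame radial spokes per readout frame (kspace mode).
#' @param readout_samples samples along each spoke (kspace mode; default
#'   matches the in-plane matrix).
#' @return An object of class `mrf_acq_config`.
#' @export
acquisition_config <- function(n_shots = 1L, noise_sigma = 0, seed = 1L,
                               mode = c("direct", "kspace"),
                               spokes_per_frame = 1L,
                               readout_samples = NULL) {
  mode <- match.arg(mode)
  n_shots <- as.integer(n_shots)
  if (n_shots < 1L) stop("n_shots must be >= 1")
  if (noise_sigma < 0) stop("noise_sigma must be >= 0")
  structure(list(n_shots = n_shots, noise_sigma = noise_sigma,
                 seed = as.integer(seed), mode = mode,
                 spokes_per_frame = as.integer(spokes_per_frame),
                 readout_samples = readout_samples),
            class = "mrf_acq_config")
}

#' Simulate an acquisition of a digital phantom
#'
#' Direct mode: each region's fingerprint is simulated once (EPG), then
#' broadcast to its voxels scaled by PD; i.i.d. complex Gaussian noise is
#' added independently per shot and the shots are averaged, so the
#' averaged noise SD falls as `1 / sqrt(n_shots)`. Shots are drawn
#' sequentially from the seeded RNG, so shot `s` of an `n`-shot
#' acquisition reuses the same realization as shot `s` of a smaller one
#' under the same seed (common random numbers across shot counts).
#'
#' Kspace mode: per readout frame, the per-voxel signal image is sampled
#' along golden-angle radial spokes (direct non-uniform DFT) for each kz
#' partition in center-out order, with the same noise model applied to
#' the k-space samples.
#'
#' @param phantom an `mrf_phantom`.
#' @param schedule an `mrf_schedule`.
#' @param acq an [acquisition_config()].
#' @return Direct mode: an object of class `mrf_signals` (complex matrix
#'   voxels x readouts plus metadata). Kspace mode: an object of class
#'   `mrf_kspace` (see [recon_frames()]).
#' @export
simulate_acquisition <- function(phantom, schedule, acq = acquisition_config()) {
  stopifnot(inherits(phantom, "mrf_phantom"), inherits(schedule, "mrf_schedule"),
            inherits(acq, "mrf_acq_config"))
  shape <- dim(phantom$label_map)
  rp <- phantom$region_params
  pm <- cbind(rp$t1, rp$t2, rp$t1rho, 1, rp$b1)
  fp <- simulate_fingerprints(schedule, pm)  # regions x timepoints

  lab <- as.vector(phantom$label_map)
  row_of <- match(lab, rp$label)             # NA for background
  pd_of <- ifelse(is.na(row_of), 0, rp$pd[match(lab, rp$label)])
  n_vox <- length(lab)
  n_t <- schedule$n_readouts
  clean <- matrix(complex(real = 0), n_vox, n_t)
  nz <- which(!is.na(row_of))
  clean[nz, ] <- fp[row_of[nz], , drop = FALSE] * pd_of[nz]

  if (acq$mode == "direct") {
    set.seed(acq$seed)
    acc <- matrix(complex(real = 0), n_vox, n_t)
    for (s in seq_len(acq$n_shots)) {
      noise <- acq$noise_sigma / sqrt(2) *
        (matrix(rnorm(n_vox * n_t), n_vox) +
           1i * matrix(rnorm(n_vox * n_t), n_vox))
      acc <- acc + clean + noise
    }
    structure(list(signals = acc / acq$n_shots, shape = shape,
                   schedule_hash = schedule$hash, clean = NULL,
                   noise_sigma = acq$noise_sigma, n_shots = acq$n_shots,
                   seed = acq$seed, mode = "direct"),
              class = "mrf_signals")
  } else {
    simulate_kspace(clean, shape, schedule, acq)
  }
}

#' Clean (noiseless) signals of a phantom
#'
#' Convenience wrapper returning the direct-mode signal matrix without
#' noise, for oracles and error measurements.
#'
#' @inheritParams simulate_acquisition
#' @return An `mrf_signals` object with `noise_sigma = 0`.
#' @export
simulate_clean_signals <- function(phantom, schedule) {
  simulate_acquisition(phantom, schedule,
                       acquisition_config(n_shots = 1L, noise_sigma = 0))
}

#' @export
print.mrf_signals <- function(x, ...) {
  cat("mrf_signals:", nrow(x$signals), "voxels x", ncol(x$signals),
      "timepoints,", x$n_shots, "shot(s), sigma", x$noise_sigma, "\n")
  invisible(x)
}
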