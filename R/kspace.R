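#' Non-uniform DFT sampling of a 2D image
#'
#' Direct evaluation of the Fourier transform of `image` at arbitrary
#' k-space locations (DFT units: integer `kx`/`ky` coincide with the
#' Cartesian DFT grid). Pixel coordinates are centered, matching an
#' fftshifted Cartesian convention. The transform is exactly linear and
#' [nudft_adjoint()] is its exact adjoint, which is what the small image
#' grids used here require; no gridding approximation is involved.
#'
#' @param image complex (or numeric) matrix nx x ny.
#' @param kx,ky sample locations in DFT units.
#' @return Complex vector of samples.
#' @export
nudft_forward <- function(image, kx, ky) {
  stopifnot(is.matrix(image), length(kx) == length(ky))
  nx <- nrow(image); ny <- ncol(image)
  px <- (0:(nx - 1)) - floor(nx / 2)
  py <- (0:(ny - 1)) - floor(ny / 2)
  A <- exp(-2i * pi * outer(kx, px) / nx)
  B <- exp(-2i * pi * outer(ky, py) / ny)
  rowSums((A %*% image) * B)
}

#' Adjoint non-uniform DFT (optionally density-compensated)
#'
#' @param samples complex vector of k-space samples.
#' @param kx,ky sample locations in DFT units.
#' @param shape image dimensions `c(nx, ny)`.
#' @param weights optional density-compensation weights (default 1:
#'   the exact adjoint of [nudft_forward()]).
#' @return Complex nx x ny matrix.
#' @export
nudft_adjoint <- function(samples, kx, ky, shape, weights = NULL) {
  stopifnot(length(samples) == length(kx), length(kx) == length(ky))
  nx <- shape[1]; ny <- shape[2]
  px <- (0:(nx - 1)) - floor(nx / 2)
  py <- (0:(ny - 1)) - floor(ny / 2)
  A <- exp(-2i * pi * outer(kx, px) / nx)
  B <- exp(-2i * pi * outer(ky, py) / ny)
  w <- if (is.null(weights)) rep(1, length(samples)) else weights
  crossprod(Conj(A), (w * samples) * Conj(B))
}

#' Radial spoke sample coordinates
#'
#' @param angle_deg spoke azimuth in degrees.
#' @param n_samples samples along the spoke.
#' @param oversample radial oversampling factor: sample spacing is
#'   `1/oversample` DFT units, so `n_samples = oversample * N` spans the
#'   full `+/- N/2` band. The default 2x readout oversampling is standard
#'   for radial acquisitions and substantially reduces the ring
#'   discretization error of the density-compensated adjoint.
#' @return List with `kx`, `ky`, `kr`.
#' @export
radial_spoke_coords <- function(angle_deg, n_samples, oversample = 2) {
  kr <- ((0:(n_samples - 1)) - floor(n_samples / 2)) / oversample
  th <- angle_deg * pi / 180
  list(kx = kr * cos(th), ky = kr * sin(th), kr = kr)
}

# Ramp (Ram-Lak) density compensation for a set of radial spokes with
# radial spacing dk: area element |kr| * pi/n_spokes * dk, center sample
# pi dk^2 / (4 n_spokes) (the shared central disc split across spokes).
radial_dcf <- function(kr, n_spokes, dk = 0.5) {
  w <- abs(kr) * pi / n_spokes * dk
  w[kr == 0] <- pi * dk^2 / (4 * n_spokes)
  w
}

#' Sample a 2D image along radial spokes
#'
#' @param image2d complex matrix.
#' @param angles_deg spoke azimuths (degrees).
#' @param n_samples samples per spoke.
#' @param oversample radial oversampling factor (see
#'   [radial_spoke_coords()]).
#' @return Complex matrix n_spokes x n_samples.
#' @export
radial_sample_image <- function(image2d, angles_deg, n_samples,
                                oversample = 2) {
  out <- matrix(complex(1), length(angles_deg), n_samples)
  for (i in seq_along(angles_deg)) {
    co <- radial_spoke_coords(angles_deg[i], n_samples, oversample)
    out[i, ] <- nudft_forward(image2d, co$kx, co$ky)
  }
  out
}

#' Density-compensated adjoint reconstruction of radial samples
#'
#' @param samples complex matrix n_spokes x n_samples.
#' @param angles_deg spoke azimuths (degrees).
#' @param shape image dimensions `c(nx, ny)`.
#' @param oversample radial oversampling factor of the samples.
#' @return Complex nx x ny image (scaled as an approximate inverse).
#' @export
radial_recon_image <- function(samples, angles_deg, shape, oversample = 2) {
  n_spokes <- length(angles_deg)
  n_samples <- ncol(samples)
  kx <- ky <- kr <- numeric(0)
  for (i in seq_along(angles_deg)) {
    co <- radial_spoke_coords(angles_deg[i], n_samples, oversample)
    kx <- c(kx, co$kx); ky <- c(ky, co$ky); kr <- c(kr, co$kr)
  }
  w <- radial_dcf(kr, n_spokes, dk = 1 / oversample)
  nudft_adjoint(as.vector(t(samples)), kx, ky, shape, weights = w) /
    (shape[1] * shape[2])
}

# Radial stack-of-stars sampling of per-voxel signal timeseries.
# clean: voxels x timepoints; shape: c(nx, ny, nz).
simulate_kspace <- function(clean, shape, schedule, acq) {
  nx <- shape[1]; ny <- shape[2]; nz <- shape[3]
  n_t <- ncol(clean)
  oversample <- 2
  n_samples <- if (is.null(acq$readout_samples)) oversample * nx
  else acq$readout_samples
  spf <- acq$spokes_per_frame
  spokes <- golden_angle_spokes(n_t * spf, acq$n_shots)
  kz_order <- kz_center_out(nz)
  n_sp_frame <- acq$n_shots * spf

  set.seed(acq$seed)
  samples <- array(complex(1), dim = c(n_t, n_sp_frame, n_samples, nz))
  angle_tab <- array(NA_real_, dim = c(n_t, n_sp_frame))
  for (f in seq_len(n_t)) {
    img <- array(clean[, f], dim = shape)
    # Cartesian kz encoding: FFT along the partition dimension
    imgk <- if (nz > 1) aperm(apply(img, c(1, 2), stats::fft), c(2, 3, 1)) else img
    si <- 0L
    for (s in 0:(acq$n_shots - 1L)) {
      for (p in seq_len(spf)) {
        si <- si + 1L
        frame0 <- (f - 1L) * spf + (p - 1L)
        ang <- (s * 180 / acq$n_shots +
                  frame0 * 180 * (sqrt(5) - 1) / 2) %% 360
        angle_tab[f, si] <- ang
        co <- radial_spoke_coords(ang, n_samples, oversample)
        for (zi in seq_len(nz)) {
          z <- kz_order[zi]
          plane <- matrix(imgk[, , z], nx, ny)
          y <- nudft_forward(plane, co$kx, co$ky)
          if (acq$noise_sigma > 0)
            y <- y + acq$noise_sigma / sqrt(2) *
              complex(real = rnorm(n_samples), imaginary = rnorm(n_samples))
          samples[f, si, , zi] <- y
        }
      }
    }
  }
  structure(list(samples = samples, angles = angle_tab,
                 kz_order = kz_order, shape = shape,
                 n_samples = n_samples, oversample = oversample,
                 noise_sigma = acq$noise_sigma,
                 n_shots = acq$n_shots, seed = acq$seed,
                 schedule_hash = schedule$hash, mode = "kspace"),
            class = "mrf_kspace")
}

#' Reconstruct image frames from radial stack-of-stars k-space
#'
#' Density-compensated adjoint non-uniform DFT per frame and kz
#' partition, followed by an inverse FFT along kz.
#'
#' @param kspace an `mrf_kspace` object from [simulate_acquisition()].
#' @param frames which frames to reconstruct (default all).
#' @return Complex array nx x ny x nz x n_frames.
#' @export
recon_frames <- function(kspace, frames = NULL) {
  stopifnot(inherits(kspace, "mrf_kspace"))
  shape <- kspace$shape
  nz <- shape[3]
  if (is.null(frames)) frames <- seq_len(dim(kspace$samples)[1])
  out <- array(complex(1), dim = c(shape, length(frames)))
  for (fi in seq_along(frames)) {
    f <- frames[fi]
    angs <- kspace$angles[f, ]
    vol_k <- array(complex(1), dim = shape)
    for (zi in seq_len(nz)) {
      sam <- kspace$samples[f, , , zi, drop = FALSE]
      sam <- matrix(sam, nrow = length(angs))
      vol_k[, , kspace$kz_order[zi]] <-
        radial_recon_image(sam, angs, shape[1:2], kspace$oversample)
    }
    if (nz > 1) {
      vol_k <- aperm(apply(vol_k, c(1, 2), function(v) stats::fft(v, inverse = TRUE) / nz),
                     c(2, 3, 1))
    }
    out[, , , fi] <- vol_k
  }
  out
}
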