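#' ROI summary statistics
#'
#' Mean and population standard deviation (divisor `n`, the convention
#' recorded for ROI summaries) of a parameter map over a region of
#' interest.
#'
#' @param map numeric array or vector.
#' @param roi_mask logical array/vector of the same length.
#' @param label optional ROI name.
#' @return List with `label`, `n_voxels`, `mean`, `sd`.
#' @export
roi_stats <- function(map, roi_mask, label = NA_character_) {
  if (length(map) != length(roi_mask)) stop("map and mask sizes differ")
  v <- as.vector(map)[as.logical(roi_mask)]
  v <- v[is.finite(v)]
  if (!length(v)) stop("empty ROI mask")
  m <- mean(v)
  list(label = label, n_voxels = length(v), mean = m,
       sd = sqrt(mean((v - m)^2)))
}

#' Intraclass correlation coefficient of repeat scans
#'
#' One-way random-effects decomposition of paired scan/rescan values:
#' the within-subject variance is estimated from the paired differences,
#' `sigma_w^2 = mean(d^2) / 2`, the between-subject variance from the
#' subject means, `sigma_b^2 = var(means) - sigma_w^2 / 2` floored at 0,
#' and `ICC = sigma_b^2 / (sigma_b^2 + sigma_w^2)` clamped to `[0, 1]`.
#'
#' @param scan1,scan2 per-subject values from the two sessions.
#' @return List with `sigma_b_sq`, `sigma_w_sq`, `icc`.
#' @export
icc <- function(scan1, scan2) {
  if (length(scan1) != length(scan2)) stop("scan lengths differ")
  n <- length(scan1)
  if (n < 2) stop("need at least 2 subjects")
  d <- scan1 - scan2
  sw2 <- mean(d^2) / 2
  means <- (scan1 + scan2) / 2
  sb2 <- max(var(means) - sw2 / 2, 0)
  denom <- sb2 + sw2
  val <- if (denom == 0) 1 else min(max(sb2 / denom, 0), 1)
  list(sigma_b_sq = sb2, sigma_w_sq = sw2, icc = val)
}

#' Bland-Altman agreement analysis
#'
#' Bias (mean difference `x - y`) and 95% limits of agreement
#' `bias +/- 1.96 * SD(differences)` (sample SD, divisor `n - 1`).
#'
#' @param x,y paired measurements.
#' @return List with `bias`, `loa_low`, `loa_high`, `n`.
#' @export
bland_altman <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  if (length(x) < 2) stop("need at least 2 pairs")
  d <- x - y
  bias <- mean(d)
  s <- sd(d)
  list(bias = bias, loa_low = bias - 1.96 * s, loa_high = bias + 1.96 * s,
       n = length(d))
}

#' Paired two-tailed t-test
#'
#' The paired t statistic `t = mean(d) / (sd(d) / sqrt(n))` with
#' `df = n - 1` and the two-tailed p-value from the t-distribution
#' survival function.
#'
#' @param x,y paired measurements.
#' @return List with `t`, `df`, `p`.
#' @export
paired_ttest <- function(x, y) {
  if (length(x) != length(y)) stop("x and y lengths differ")
  n <- length(x)
  if (n < 2) stop("need at least 2 pairs")
  d <- x - y
  s <- sd(d)
  if (s == 0) stop("zero variance of paired differences")
  tt <- mean(d) / (s / sqrt(n))
  list(t = tt, df = n - 1, p = 2 * pt(-abs(tt), df = n - 1))
}

#' Magnitude-image SNR estimate
#'
#' `mean(signal ROI) / sd(noise ROI)` on a magnitude image (sample SD).
#' The simple mean/SD convention ignores the Rician bias of background
#' magnitude noise; `rician_correct = TRUE` divides the background SD by
#' `sqrt(2 - pi/2)` (the SD of a Rayleigh variate relative to its
#' underlying Gaussian sigma) to estimate the per-quadrature sigma.
#'
#' @param image magnitude volume.
#' @param signal_roi,noise_roi logical masks.
#' @param rician_correct apply the Rayleigh-background correction.
#' @return SNR (dimensionless), with the convention in attribute
#'   `"method"`.
#' @export
snr_estimate <- function(image, signal_roi, noise_roi,
                         rician_correct = FALSE) {
  sig <- as.vector(image)[as.logical(signal_roi)]
  noi <- as.vector(image)[as.logical(noise_roi)]
  if (!length(sig) || !length(noi)) stop("empty ROI")
  s <- sd(noi)
  if (s == 0) stop("zero noise SD")
  if (rician_correct) s <- s / sqrt(2 - pi / 2)
  structure(mean(sig) / s,
            method = if (rician_correct) "mean/sd, Rayleigh-corrected"
            else "mean/sd")
}

#' Per-region ROI table for a set of parameter maps
#'
#' @param maps an `mrf_maps` object.
#' @param label_map integer array of ROI labels (0 = ignore).
#' @param parameters which maps to summarize.
#' @return Data frame with columns roi, parameter, mean, sd, n.
#' @export
roi_table <- function(maps, label_map,
                      parameters = c("t1", "t2", "t1rho", "pd")) {
  labs <- sort(unique(as.vector(label_map)))
  labs <- labs[labs != 0]
  rows <- list()
  for (lb in labs) {
    m <- as.vector(label_map) == lb
    for (p in parameters) {
      st <- roi_stats(maps[[p]], m & as.vector(maps$mask), label = lb)
      rows[[length(rows) + 1L]] <- data.frame(
        roi = lb, parameter = p, mean = st$mean, sd = st$sd,
        n = st$n_voxels)
    }
  }
  do.call(rbind, rows)
}
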