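#' Match one signal to the dictionary
#'
#' Maximizes the magnitude of the complex inner product between the
#' (unit-norm) dictionary rows and the signal, making the match invariant
#' to global complex scaling (proton density and phase factor out). Ties
#' are broken by the lowest atom index.
#'
#' @param signal complex vector, one entry per dictionary timepoint.
#' @param dict an `mrf_dictionary`.
#' @return List with `atom_index`, `pd` (the inner-product magnitude, i.e.
#'   the complex scale of the best atom), and `score` (`pd / ||signal||`,
#'   in `[0, 1]`).
#' @export
match_voxel <- function(signal, dict) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (length(signal) != ncol(dict$fingerprints))
    stop("signal length does not match dictionary timepoints (schedule ",
         substr(dict$schedule_hash, 1, 8), ")")
  snorm <- sqrt(sum(Mod(signal)^2))
  if (snorm == 0) stop("all-zero signal cannot be matched")
  ip <- Mod(dict$fingerprints %*% Conj(signal))
  j <- which.max(ip)  # which.max takes the first maximum: lowest atom index
  list(atom_index = j, pd = ip[j], score = ip[j] / snorm)
}

# Inner-product magnitudes of a block of signals against all atoms:
# rows = voxels, cols = atoms.
score_block <- function(signals, atom_mat) {
  Mod(signals %*% Conj(t(atom_mat)))
}

#' Match a volume of signals to the dictionary
#'
#' Per-voxel dictionary matching with background masking, optional SVD
#' subspace matching and optional local quadratic refinement. With a
#' compressed dictionary the signals are first projected onto the SVD
#' basis and all inner products are computed in rank-r space. Refinement
#' evaluates the match scores of the +/-1-step neighbors along each of
#' the T1, T2 and T1rho axes and interpolates the score parabola in
#' log-parameter space, yielding sub-grid-step estimates clamped to one
#' grid step.
#'
#' @param signals an `mrf_signals` object from [simulate_acquisition()],
#'   or a complex matrix (voxels x timepoints).
#' @param dict an `mrf_dictionary` or `mrf_compressed`.
#' @param refine apply local quadratic refinement.
#' @param mask_frac voxels whose signal norm is below `mask_frac` times
#'   the 99th percentile of norms are masked (no-data).
#' @param chunk_size voxels matched per block.
#' @param shape optional integer volume dimensions for the output maps.
#' @return An object of class `mrf_maps`: volumes `pd`, `t1`, `t2`,
#'   `t1rho`, `b1`, `score`, logical `mask`, integer `atom_index`, and
#'   metadata (`no_data = NA`).
#' @export
match_volume <- function(signals, dict, refine = FALSE, mask_frac = 0.01,
                         chunk_size = 2048L, shape = NULL) {
  if (inherits(signals, "mrf_signals")) {
    if (!is.null(signals$schedule_hash) && !is.null(dict$schedule_hash) &&
        !identical(signals$schedule_hash, dict$schedule_hash))
      stop("signals were simulated from schedule ",
           substr(signals$schedule_hash, 1, 8),
           " but the dictionary was built from schedule ",
           substr(dict$schedule_hash, 1, 8))
    if (is.null(shape)) shape <- signals$shape
    sig <- signals$signals
  } else sig <- signals
  stopifnot(is.matrix(sig))
  compressed <- inherits(dict, "mrf_compressed")
  if (!compressed && !inherits(dict, "mrf_dictionary"))
    stop("dict must be an mrf_dictionary or mrf_compressed")

  n_t <- if (compressed) nrow(dict$basis) else ncol(dict$fingerprints)
  if (ncol(sig) != n_t)
    stop("signal length does not match dictionary timepoints (schedule ",
         substr(dict$schedule_hash, 1, 8), ")")
  n_vox <- nrow(sig)
  grid <- dict$grid
  atoms <- grid$atoms
  if (refine && is.null(grid$lookup))
    stop("refinement needs a product-lattice grid (see build_grid)")

  norms <- sqrt(rowSums(Mod(sig)^2))
  ref <- stats::quantile(norms, 0.99, names = FALSE)
  mask <- norms > 0 & norms >= mask_frac * ref

  if (compressed) {
    sig_m <- sig %*% Conj(dict$basis)
    atom_mat <- dict$projected
  } else {
    sig_m <- sig
    atom_mat <- dict$fingerprints
  }

  atom_index <- rep(NA_integer_, n_vox)
  pd <- score <- rep(NA_real_, n_vox)
  t1 <- t2 <- t1rho <- b1 <- rep(NA_real_, n_vox)

  vox <- which(mask)
  for (s in if (length(vox)) seq(1L, length(vox), by = chunk_size) else integer(0)) {
    idx <- vox[s:min(s + chunk_size - 1L, length(vox))]
    sc <- score_block(sig_m[idx, , drop = FALSE], atom_mat)
    best <- max.col(sc, ties.method = "first")
    ibest <- cbind(seq_along(idx), best)
    atom_index[idx] <- best
    pd[idx] <- sc[ibest]
    score[idx] <- sc[ibest] / norms[idx]
    t1[idx] <- atoms$t1[best]
    t2[idx] <- atoms$t2[best]
    t1rho[idx] <- atoms$t1rho[best]
    b1[idx] <- atoms$b1[best]
    if (refine) {
      rf <- refine_block(sc, best, grid)
      t1[idx] <- rf$t1; t2[idx] <- rf$t2; t1rho[idx] <- rf$t1rho
    }
  }

  to_vol <- function(v) if (is.null(shape)) v else array(v, dim = shape)
  structure(list(pd = to_vol(pd), t1 = to_vol(t1), t2 = to_vol(t2),
                 t1rho = to_vol(t1rho), b1 = to_vol(b1),
                 score = to_vol(score), mask = to_vol(mask),
                 atom_index = to_vol(atom_index),
                 shape = shape, refined = refine,
                 schedule_hash = dict$schedule_hash),
            class = "mrf_maps")
}

# Quadratic (log-domain) refinement along each relaxation axis.
# sc: voxel-block score matrix; best: argmax atom per voxel.
refine_block <- function(sc, best, grid) {
  atoms <- grid$atoms
  step <- log1p(grid$step_fraction)
  out <- list(t1 = atoms$t1[best], t2 = atoms$t2[best],
              t1rho = atoms$t1rho[best])
  axes <- list(
    t1 = list(i = atoms$i_t1[best], vals = grid$t1_values,
              nb = function(i, d) grid_atom_index(grid, i + d, atoms$i_t2[best],
                                                  atoms$i_t1rho[best], atoms$i_b1[best])),
    t2 = list(i = atoms$i_t2[best], vals = grid$t2_values,
              nb = function(i, d) grid_atom_index(grid, atoms$i_t1[best], i + d,
                                                  atoms$i_t1rho[best], atoms$i_b1[best])),
    t1rho = list(i = atoms$i_t1rho[best], vals = grid$t1rho_values,
                 nb = function(i, d) grid_atom_index(grid, atoms$i_t1[best],
                                                     atoms$i_t2[best], i + d,
                                                     atoms$i_b1[best])))
  rows <- seq_along(best)
  for (ax in names(axes)) {
    a <- axes[[ax]]
    lo <- a$nb(a$i, -1L)
    hi <- a$nb(a$i, +1L)
    ok <- lo > 0L & hi > 0L
    if (!any(ok)) next
    s0 <- sc[cbind(rows, best)]
    sl <- sh <- rep(NA_real_, length(best))
    sl[ok] <- sc[cbind(rows[ok], lo[ok])]
    sh[ok] <- sc[cbind(rows[ok], hi[ok])]
    denom <- sl - 2 * s0 + sh
    delta <- ifelse(ok & is.finite(denom) & denom < 0,
                    0.5 * (sl - sh) / denom, 0)
    delta <- pmax(pmin(delta, 1), -1)  # at most one grid step
    out[[ax]] <- ifelse(ok, out[[ax]] * exp(delta * step), out[[ax]])
  }
  out
}

#' @export
print.mrf_maps <- function(x, ...) {
  n <- length(x$mask)
  cat("mrf_maps:", n, "voxels,", sum(x$mask, na.rm = TRUE), "matched",
      if (x$refined) "(refined)" else "", "\n")
  invisible(x)
}
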