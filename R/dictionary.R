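#' Geometric parameter axis
#'
#' Values `min * (1 + step)^k` for `k = 0, 1, ...` up to the largest value
#' not exceeding `max` — the multiplicative 6% stepping used for the
#' dictionary's relaxation-time axes.
#'
#' @param min,max axis bounds in ms (`0 < min <= max`).
#' @param step_fraction relative step (default 0.06).
#' @return Ascending numeric vector starting at `min`.
#' @export
geometric_axis <- function(min, max, step_fraction = 0.06) {
  if (!is.finite(min) || !is.finite(max) || min <= 0 || max < min)
    stop("need 0 < min <= max")
  if (!is.finite(step_fraction) || step_fraction <= 0)
    stop("step_fraction must be > 0")
  # +1e-12 guards against log round-off excluding an exact endpoint
  k_max <- floor(log(max / min) / log1p(step_fraction) + 1e-12)
  min * (1 + step_fraction)^(0:k_max)
}

#' Build the dictionary parameter grid
#'
#' Cartesian product of geometric T1/T2/T1rho axes and a linear B1 axis,
#' filtered for physical plausibility (`t2 <= t1` and, by default,
#' `t1rho <= t1`), ordered lexicographically by (t1, t2, t1rho, b1).
#'
#' @param t1_range,t2_range,t1rho_range axis bounds in ms (length-2).
#' @param step_fraction geometric step (default 0.06).
#' @param b1_values B1+ scale axis (default single value 1).
#' @param enforce_t1rho_le_t1 also filter atoms with `t1rho > t1`.
#' @param t1_values,t2_values,t1rho_values explicit axis values overriding
#'   the geometric ranges (must be ascending).
#' @return An object of class `mrf_grid` with the four axis vectors, the
#'   filtered `atoms` data frame (parameter values plus axis indices) and
#'   an index lookup for neighborhood queries.
#' @export
build_grid <- function(t1_range = c(50, 3000), t2_range = c(2, 200),
                       t1rho_range = c(2, 200), step_fraction = 0.06,
                       b1_values = 1, enforce_t1rho_le_t1 = TRUE,
                       t1_values = NULL, t2_values = NULL,
                       t1rho_values = NULL) {
  t1v <- if (is.null(t1_values))
    geometric_axis(t1_range[1], t1_range[2], step_fraction) else sort(t1_values)
  t2v <- if (is.null(t2_values))
    geometric_axis(t2_range[1], t2_range[2], step_fraction) else sort(t2_values)
  trv <- if (is.null(t1rho_values))
    geometric_axis(t1rho_range[1], t1rho_range[2], step_fraction) else sort(t1rho_values)
  b1v <- sort(as.numeric(b1_values))
  if (!length(t1v) || !length(t2v) || !length(trv) || !length(b1v))
    stop("empty grid axis")
  n <- c(length(t1v), length(t2v), length(trv), length(b1v))
  # b1 varies fastest, t1 slowest -> lexicographic by (t1, t2, t1rho, b1)
  g <- expand.grid(i_b1 = seq_len(n[4]), i_t1rho = seq_len(n[3]),
                   i_t2 = seq_len(n[2]), i_t1 = seq_len(n[1]))
  atoms <- data.frame(
    t1 = t1v[g$i_t1], t2 = t2v[g$i_t2], t1rho = trv[g$i_t1rho],
    b1 = b1v[g$i_b1],
    i_t1 = g$i_t1, i_t2 = g$i_t2, i_t1rho = g$i_t1rho, i_b1 = g$i_b1)
  keep <- atoms$t2 <= atoms$t1
  if (enforce_t1rho_le_t1) keep <- keep & atoms$t1rho <= atoms$t1
  atoms <- atoms[keep, , drop = FALSE]
  rownames(atoms) <- NULL
  lin <- ((atoms$i_t1 - 1L) * n[2] + (atoms$i_t2 - 1L)) * n[3] + (atoms$i_t1rho - 1L)
  lin <- lin * n[4] + atoms$i_b1  # 1-based within b1
  lookup <- integer(prod(n))
  lookup[lin] <- seq_len(nrow(atoms))
  structure(list(t1_values = t1v, t2_values = t2v, t1rho_values = trv,
                 b1_values = b1v, atoms = atoms, dims = n,
                 step_fraction = step_fraction, lookup = lookup),
            class = "mrf_grid")
}

#' Custom atom-list grid
#'
#' Builds an `mrf_grid` from an explicit list of (t1, t2, t1rho, b1)
#' atoms — e.g. local neighborhoods around known tissue values — instead
#' of a full Cartesian product. Such grids support matching but not
#' quadratic refinement (no product-lattice neighborhood exists).
#'
#' @param t1,t2,t1rho,b1 equal-length vectors of atom parameters; `b1`
#'   recycled if scalar.
#' @param step_fraction nominal step recorded for error bookkeeping.
#' @return An `mrf_grid` with `lookup = NULL`.
#' @export
grid_from_atoms <- function(t1, t2, t1rho, b1 = 1, step_fraction = 0.06) {
  n <- length(t1)
  stopifnot(length(t2) == n, length(t1rho) == n)
  if (length(b1) == 1L) b1 <- rep(b1, n)
  atoms <- data.frame(t1 = t1, t2 = t2, t1rho = t1rho, b1 = b1,
                      i_t1 = NA_integer_, i_t2 = NA_integer_,
                      i_t1rho = NA_integer_, i_b1 = NA_integer_)
  atoms <- atoms[atoms$t2 <= atoms$t1, , drop = FALSE]
  atoms <- unique(atoms)
  ord <- order(atoms$t1, atoms$t2, atoms$t1rho, atoms$b1)
  atoms <- atoms[ord, , drop = FALSE]
  rownames(atoms) <- NULL
  structure(list(t1_values = sort(unique(atoms$t1)),
                 t2_values = sort(unique(atoms$t2)),
                 t1rho_values = sort(unique(atoms$t1rho)),
                 b1_values = sort(unique(atoms$b1)),
                 atoms = atoms, dims = NULL,
                 step_fraction = step_fraction, lookup = NULL),
            class = "mrf_grid")
}

# Row index of the atom at the given axis indices, or 0 if filtered/out of range.
grid_atom_index <- function(grid, i_t1, i_t2, i_t1rho, i_b1 = 1L) {
  n <- grid$dims
  bad <- i_t1 < 1L | i_t1 > n[1] | i_t2 < 1L | i_t2 > n[2] |
    i_t1rho < 1L | i_t1rho > n[3] | i_b1 < 1L | i_b1 > n[4]
  lin <- (((i_t1 - 1L) * n[2] + (i_t2 - 1L)) * n[3] + (i_t1rho - 1L)) * n[4] + i_b1
  out <- integer(length(lin))
  out[!bad] <- grid$lookup[lin[!bad]]
  out
}

#' @export
print.mrf_grid <- function(x, ...) {
  if (is.null(x$dims))
    cat("mrf_grid:", nrow(x$atoms), "atoms (custom list)\n")
  else
    cat("mrf_grid:", nrow(x$atoms), "atoms (",
        paste(x$dims, collapse = " x "), "before filtering )\n")
  invisible(x)
}

#' Simulate the fingerprint dictionary
#'
#' One EPG fingerprint per grid atom (PD = 1), simulated in chunks so the
#' raw (unnormalized) signals never exceed `chunk_size` rows in memory,
#' then L2-normalized row-wise with the original norms retained.
#'
#' @param grid an [build_grid()] result.
#' @param schedule an [build_schedule()] result.
#' @param chunk_size atoms simulated per chunk.
#' @param verbose print progress.
#' @return An object of class `mrf_dictionary` with `fingerprints`
#'   (complex matrix, atoms x timepoints, unit-norm rows), `norms`,
#'   `grid`, `schedule_hash` and the sequence config.
#' @export
build_dictionary <- function(grid, schedule, chunk_size = 512L,
                             verbose = FALSE) {
  stopifnot(inherits(grid, "mrf_grid"), inherits(schedule, "mrf_schedule"))
  atoms <- grid$atoms
  if (any(atoms$t2 > atoms$t1)) stop("internal error: unfiltered atom with t2 > t1")
  n_atoms <- nrow(atoms)
  fp <- matrix(complex(1), n_atoms, schedule$n_readouts)
  norms <- numeric(n_atoms)
  starts <- seq(1L, n_atoms, by = chunk_size)
  for (s in starts) {
    idx <- s:min(s + chunk_size - 1L, n_atoms)
    pm <- cbind(atoms$t1[idx], atoms$t2[idx], atoms$t1rho[idx], 1,
                atoms$b1[idx])
    raw <- simulate_fingerprints(schedule, pm)
    nr <- sqrt(rowSums(Mod(raw)^2))
    fp[idx, ] <- raw / nr
    norms[idx] <- nr
    if (verbose) message(sprintf("simulated %d / %d atoms", max(idx), n_atoms))
  }
  structure(list(fingerprints = fp, norms = norms, grid = grid,
                 schedule_hash = schedule$hash, config = schedule$config),
            class = "mrf_dictionary")
}

#' @export
print.mrf_dictionary <- function(x, ...) {
  cat("mrf_dictionary:", nrow(x$fingerprints), "atoms x",
      ncol(x$fingerprints), "timepoints, schedule",
      substr(x$schedule_hash, 1, 8), "\n")
  invisible(x)
}

#' SVD compression of a dictionary
#'
#' Computes the top right-singular-vector subspace of the fingerprint
#' matrix and projects the dictionary into it. For tall dictionaries
#' (more atoms than timepoints) the singular vectors are obtained from the
#' timepoints x timepoints Gram matrix accumulated in chunks, which is
#' mathematically identical to the direct SVD.
#'
#' @param dict an [build_dictionary()] result.
#' @param rank subspace rank; or
#' @param energy fraction of total squared singular value energy to retain
#'   (the smallest rank reaching it is used). If neither is given the
#'   default energy target is `1 - 1e-6`: fingerprint dictionaries are so
#'   strongly correlated that lax energy targets select ranks too small to
#'   discriminate atoms (99.9% of the energy of this sequence's dictionary
#'   sits in a rank-3 subspace), so the default is deliberately strict
#'   while still yielding a tiny subspace (rank ~10).
#' @param chunk_size rows per Gram-accumulation chunk.
#' @return An object of class `mrf_compressed` with orthonormal `basis`
#'   (timepoints x rank), `projected` (atoms x rank), `singular_values`,
#'   `energy_retained`, plus the grid, norms and schedule hash of the
#'   parent dictionary.
#' @export
compress_dictionary <- function(dict, rank = NULL, energy = NULL,
                                chunk_size = 4096L) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  if (is.null(rank) && is.null(energy)) energy <- 1 - 1e-6
  F <- dict$fingerprints
  n_atoms <- nrow(F); n_t <- ncol(F)
  if (!is.null(rank)) {
    rank <- as.integer(rank)
    if (rank < 1L || rank > min(n_atoms, n_t)) stop("rank out of range")
  }
  if (!is.null(energy) && (energy <= 0 || energy > 1))
    stop("energy must lie in (0, 1]")

  if (n_atoms > n_t) {
    G <- matrix(complex(1), n_t, n_t)
    for (s in seq(1L, n_atoms, by = chunk_size)) {
      idx <- s:min(s + chunk_size - 1L, n_atoms)
      G <- G + crossprod(Conj(F[idx, , drop = FALSE]), F[idx, , drop = FALSE])
    }
    eg <- eigen(G, symmetric = TRUE)
    sv2 <- pmax(Re(eg$values), 0)
    V <- eg$vectors
  } else {
    sv <- svd(F, nu = 0)
    sv2 <- sv$d^2
    V <- sv$v
  }
  total <- sum(sv2)
  cum <- cumsum(sv2) / total
  r <- if (!is.null(rank)) rank else which(cum >= energy)[1]
  basis <- V[, seq_len(r), drop = FALSE]
  projected <- F %*% Conj(basis)
  structure(list(basis = basis, projected = projected,
                 singular_values = sqrt(sv2), rank = r,
                 energy_retained = cum[r], grid = dict$grid,
                 norms = dict$norms, schedule_hash = dict$schedule_hash,
                 config = dict$config),
            class = "mrf_compressed")
}

#' @export
print.mrf_compressed <- function(x, ...) {
  cat(sprintf("mrf_compressed: rank %d, energy retained %.6f\n",
              x$rank, x$energy_retained))
  invisible(x)
}

#' Save / load a dictionary archive
#'
#' Stores the dictionary (and optionally its SVD compression) together
#' with the grid axes, schedule hash, ramp shape and package version in a
#' single hierarchical archive. Loading verifies structure; matching
#' refuses dictionaries whose schedule hash differs from the signals'.
#'
#' @param dict an `mrf_dictionary`.
#' @param path archive file path.
#' @param compressed optional `mrf_compressed` stored alongside.
#' @return `save_dictionary` returns `path` invisibly; `load_dictionary`
#'   returns a list with elements `dictionary` and (possibly `NULL`)
#'   `compressed`.
#' @export
save_dictionary <- function(dict, path, compressed = NULL) {
  stopifnot(inherits(dict, "mrf_dictionary"))
  obj <- list(
    fingerprints = dict$fingerprints, norms = dict$norms,
    grid = dict$grid,
    svd = if (!is.null(compressed)) list(
      basis = compressed$basis, projected = compressed$projected,
      singular_values = compressed$singular_values,
      rank = compressed$rank, energy_retained = compressed$energy_retained),
    attributes = list(
      tr = dict$config$tr, te = dict$config$te,
      ramp_shape = dict$config$ramp_shape,
      spin_lock_freq_hz = dict$config$spin_lock_freq_hz,
      schedule_hash = dict$schedule_hash,
      package_version = as.character(utils::packageVersion("mrfmap"))),
    config = dict$config)
  saveRDS(obj, path)
  invisible(path)
}

#' @rdname save_dictionary
#' @export
load_dictionary <- function(path) {
  obj <- readRDS(path)
  if (!all(c("fingerprints", "norms", "grid", "attributes") %in% names(obj)))
    stop("not a dictionary archive")
  dict <- structure(list(fingerprints = obj$fingerprints, norms = obj$norms,
                         grid = obj$grid,
                         schedule_hash = obj$attributes$schedule_hash,
                         config = obj$config),
                    class = "mrf_dictionary")
  comp <- NULL
  if (!is.null(obj$svd)) {
    comp <- structure(c(obj$svd, list(grid = obj$grid, norms = obj$norms,
                                      schedule_hash = obj$attributes$schedule_hash,
                                      config = obj$config)),
                      class = "mrf_compressed")
  }
  list(dictionary = dict, compressed = comp)
}
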