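#' Extended phase graph state
#'
#' An EPG state holds the configuration-state ladders of transverse and
#' longitudinal magnetization: `f_plus[k]` and `f_minus[k]` are the
#' dephased transverse states of order `k = 0..max_order` (with
#' `f_minus[k]` the conjugate representation of order `-k`, so
#' `f_minus[1] == Conj(F(-1))`), and `z[k]` the longitudinal states.
#' The phase convention throughout the package is `F = Mx + i*My`, and an
#' RF pulse of phase 0 rotates about the +x axis (right-handed).
#'
#' @param max_order highest dephasing order retained (ladder length
#'   `max_order + 1`). Orders beyond it are truncated on gradient shifts.
#' @return An object of class `epg_state` at thermal equilibrium
#'   (`z[0] = 1`, all other entries zero).
#' @export
epg_state <- function(max_order = 250L) {
  max_order <- as.integer(max_order)
  if (is.na(max_order) || max_order < 1L)
    stop("max_order must be a positive integer")
  n <- max_order + 1L
  structure(list(
    f_plus = complex(n), f_minus = complex(n),
    z = c(complex(real = 1), complex(n - 1L)),
    max_order = max_order
  ), class = "epg_state")
}

#' Tissue parameter set
#'
#' Relaxation times in milliseconds, proton density (arbitrary scale) and
#' the B1+ transmit scale multiplying nominal excitation flip angles.
#'
#' @param t1,t2,t1rho relaxation times in ms (positive).
#' @param pd proton density, arbitrary non-negative scale.
#' @param b1_scale dimensionless transmit-field scale (> 0).
#' @param check_t2_le_t1 enforce the physical constraint `t2 <= t1`
#'   (disable only for stress tests).
#' @return An object of class `tissue_params`.
#' @export
tissue_params <- function(t1, t2, t1rho, pd = 1, b1_scale = 1,
                          check_t2_le_t1 = TRUE) {
  vals <- c(t1 = t1, t2 = t2, t1rho = t1rho, pd = pd, b1_scale = b1_scale)
  if (any(!is.finite(vals))) stop("tissue parameters must be finite")
  if (t1 <= 0 || t2 <= 0 || t1rho <= 0) stop("relaxation times must be > 0")
  if (pd < 0) stop("pd must be >= 0")
  if (b1_scale <= 0) stop("b1_scale must be > 0")
  if (check_t2_le_t1 && t2 > t1) stop("t2 must not exceed t1")
  structure(list(t1 = t1, t2 = t2, t1rho = t1rho, pd = pd,
                 b1_scale = b1_scale), class = "tissue_params")
}

#' Apply an RF rotation to an EPG state
#'
#' Mixes each `(f_plus[k], f_minus[k], z[k])` triplet with the 3x3 EPG
#' rotation matrix for the given flip and phase. Phase 0 rotates about +x.
#'
#' @param state an [epg_state()].
#' @param flip_deg flip angle in degrees (>= 0).
#' @param phase_deg RF phase in degrees.
#' @return The rotated `epg_state`.
#' @export
epg_rf <- function(state, flip_deg, phase_deg = 0) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(flip_deg) || !is.finite(phase_deg))
    stop("flip and phase must be finite")
  if (flip_deg < 0) stop("flip_deg must be >= 0")
  a <- flip_deg * pi / 180
  p <- phase_deg * pi / 180
  eip <- exp(1i * p)
  ca2 <- cos(a / 2)^2
  sa2 <- sin(a / 2)^2
  sa <- sin(a)
  fp <- state$f_plus; fm <- state$f_minus; z <- state$z
  state$f_plus  <- ca2 * fp + eip^2 * sa2 * fm - 1i * eip * sa * z
  state$f_minus <- Conj(eip^2) * sa2 * fp + ca2 * fm + 1i * Conj(eip) * sa * z
  state$z       <- -0.5i * Conj(eip) * sa * fp + 0.5i * eip * sa * fm + cos(a) * z
  state
}

#' Shift the EPG ladder by one gradient dephasing cycle
#'
#' Models the unbalanced gradient moment of one FISP TR: `f_plus` moves up
#' one order, `f_minus` moves down one order with the `k = 0` crossover
#' (`f_plus[0]` becomes `Conj(f_minus[1])`), longitudinal states are
#' untouched and the highest order is truncated.
#'
#' @param state an [epg_state()].
#' @return The shifted `epg_state`.
#' @export
epg_grad_shift <- function(state) {
  stopifnot(inherits(state, "epg_state"))
  n <- state$max_order + 1L
  fp <- state$f_plus; fm <- state$f_minus
  state$f_plus <- c(Conj(fm[2]), fp[-n])
  state$f_minus <- c(fm[-1], complex(1))
  state
}

#' Free relaxation of an EPG state
#'
#' Transverse orders decay with T2, longitudinal orders with T1, and
#' `z[0]` recovers toward thermal equilibrium:
#' `z[0] <- z[0] * E1 + (1 - E1)` with `E1 = exp(-dt/T1)`.
#'
#' @param state an [epg_state()].
#' @param dt interval in ms (>= 0).
#' @param params a [tissue_params()].
#' @return The relaxed `epg_state`.
#' @export
epg_relax <- function(state, dt, params) {
  stopifnot(inherits(state, "epg_state"), inherits(params, "tissue_params"))
  if (!is.finite(dt) || dt < 0) stop("dt must be >= 0")
  e1 <- exp(-dt / params$t1)
  e2 <- exp(-dt / params$t2)
  state$f_plus <- state$f_plus * e2
  state$f_minus <- state$f_minus * e2
  state$z <- state$z * e1
  state$z[1] <- state$z[1] + (1 - e1)
  state
}

#' Spin-lock (T1rho) preparation
#'
#' The composite preparation (90y tip-down, balanced alternating-phase
#' spin-lock pulses with paired 180+/-x refocusing, tip-up, crusher) is
#' modeled as mono-exponential rotating-frame decay of the stored
#' longitudinal magnetization: every `z` order is scaled by
#' `exp(-tsl/T1rho)` and all transverse orders are crushed.
#'
#' @param state an [epg_state()].
#' @param tsl spin-lock duration in ms (>= 0).
#' @param params a [tissue_params()].
#' @return The prepared `epg_state`.
#' @export
t1rho_prep <- function(state, tsl, params) {
  stopifnot(inherits(state, "epg_state"), inherits(params, "tissue_params"))
  if (!is.finite(tsl) || tsl < 0) stop("tsl must be >= 0")
  att <- exp(-tsl / params$t1rho)
  state$z <- state$z * att
  state$f_plus[] <- 0
  state$f_minus[] <- 0
  state
}

#' Adiabatic inversion
#'
#' Instantaneous inversion with an efficiency factor: all `z` orders are
#' negated and scaled by `efficiency`; transverse orders are crushed.
#' The pulse duration itself is handled by the schedule as a relaxation
#' delay, not here. Adiabatic pulses are B1-insensitive, so the flip is
#' not scaled by `b1_scale`.
#'
#' @param state an [epg_state()].
#' @param efficiency inversion efficiency in `[0, 1]`.
#' @return The inverted `epg_state`.
#' @export
inversion <- function(state, efficiency = 1) {
  stopifnot(inherits(state, "epg_state"))
  if (!is.finite(efficiency) || efficiency < 0 || efficiency > 1)
    stop("efficiency must lie in [0, 1]")
  state$z <- -efficiency * state$z
  state$f_plus[] <- 0
  state$f_minus[] <- 0
  state
}

#' EPG state norm
#'
#' The quantity conserved by RF rotations:
#' `sum(|f_plus|^2 + |f_minus|^2 + 2*|z|^2)` over all orders.
#'
#' @param state an [epg_state()].
#' @return A non-negative scalar.
#' @export
epg_norm <- function(state) {
  sum(Mod(state$f_plus)^2 + Mod(state$f_minus)^2 + 2 * Mod(state$z)^2)
}

# Apply one compiled schedule op (see schedule_ops()) to an R-level state.
# Used for reference/testing; the batch path is the C++ kernel.
apply_op <- function(state, op, params) {
  code <- op[1]
  if (code == 1) {
    epg_rf(state, op[2] * params$b1_scale, op[3])
  } else if (code == 2) {
    epg_relax(state, op[2], params)
  } else if (code == 3) {
    state
  } else if (code == 4) {
    epg_grad_shift(state)
  } else if (code == 5) {
    state$f_plus[] <- 0; state$f_minus[] <- 0; state
  } else if (code == 6) {
    inversion(state, op[2])
  } else if (code == 7) {
    t1rho_prep(state, op[2], params)
  } else stop("unknown opcode")
}
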