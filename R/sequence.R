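#' Sequence configuration
#'
#' Timing and flip-angle parameters of the 3D-MRF acquisition train:
#' an adiabatic inversion, two FISP segments (T1/T2 encoding), two
#' ideally spoiled FLASH segments (T1/B1 encoding) and a T1rho module of
#' spin-lock preparations each followed by a FISP-like readout segment.
#'
#' @param tr repetition time in ms.
#' @param te echo time in ms (`te < tr`).
#' @param n_exc_fisp excitations per FISP segment.
#' @param fa_max_fisp1,fa_max_fisp2 peak flip angles (degrees) of the two
#'   FISP segments.
#' @param inter_segment_delay ms of free recovery between segments.
#' @param n_exc_flash excitations per FLASH segment.
#' @param fa_max_flash1,fa_max_flash2 peak flip angles of the FLASH segments.
#' @param tsl_list spin-lock durations in ms, ascending. The default is six
#'   values log-spaced over 2-45 ms.
#' @param n_exc_per_tsl excitations following each spin-lock preparation.
#' @param fa_max_t1rho peak flip angle of the T1rho readout segments.
#' @param recovery_delay ms of free recovery after each spin-lock segment.
#' @param inversion_duration duration of the adiabatic inversion pulse (ms),
#'   inserted as a relaxation delay after the instantaneous inversion.
#' @param inversion_efficiency inversion efficiency in `[0, 1]`.
#' @param spin_lock_freq_hz spin-lock amplitude in Hz; provenance metadata
#'   only (the mono-exponential prep model does not use it).
#' @param ramp_shape `"half_sine"` (default) or `"linear"` flip-angle ramp.
#' @param max_order EPG ladder truncation order for simulation.
#' @return An object of class `mrf_seq_config`.
#' @export
sequence_config <- function(tr = 7.5, te = 3.5,
                            n_exc_fisp = 250L,
                            fa_max_fisp1 = 20, fa_max_fisp2 = 60,
                            inter_segment_delay = 50,
                            n_exc_flash = 250L,
                            fa_max_flash1 = 20, fa_max_flash2 = 60,
                            tsl_list = exp(seq(log(2), log(45), length.out = 6)),
                            n_exc_per_tsl = 125L,
                            fa_max_t1rho = 20,
                            recovery_delay = 500,
                            inversion_duration = 10,
                            inversion_efficiency = 1,
                            spin_lock_freq_hz = 500,
                            ramp_shape = c("half_sine", "linear"),
                            max_order = 250L) {
  ramp_shape <- match.arg(ramp_shape)
  if (te <= 0 || tr <= te) stop("need 0 < te < tr")
  if (n_exc_fisp < 2L || n_exc_flash < 2L || n_exc_per_tsl < 2L)
    stop("segment excitation counts must be >= 2")
  if (length(tsl_list) > 0) {
    if (any(tsl_list < 0)) stop("tsl values must be >= 0")
    if (is.unsorted(tsl_list)) stop("tsl_list must be ascending")
  }
  if (inter_segment_delay < 0 || recovery_delay < 0 || inversion_duration < 0)
    stop("delays must be >= 0")
  if (inversion_efficiency < 0 || inversion_efficiency > 1)
    stop("inversion_efficiency must lie in [0, 1]")
  structure(list(
    tr = tr, te = te,
    n_exc_fisp = as.integer(n_exc_fisp),
    fa_max_fisp1 = fa_max_fisp1, fa_max_fisp2 = fa_max_fisp2,
    inter_segment_delay = inter_segment_delay,
    n_exc_flash = as.integer(n_exc_flash),
    fa_max_flash1 = fa_max_flash1, fa_max_flash2 = fa_max_flash2,
    tsl_list = as.numeric(tsl_list),
    n_exc_per_tsl = as.integer(n_exc_per_tsl),
    fa_max_t1rho = fa_max_t1rho,
    recovery_delay = recovery_delay,
    inversion_duration = inversion_duration,
    inversion_efficiency = inversion_efficiency,
    spin_lock_freq_hz = spin_lock_freq_hz,
    ramp_shape = ramp_shape,
    max_order = as.integer(max_order)
  ), class = "mrf_seq_config")
}

#' Flip-angle ramp for one segment
#'
#' @param n number of excitations (>= 2).
#' @param fa_max peak flip angle in degrees (>= 0).
#' @param ramp_shape `"half_sine"` gives `fa_max * sin(pi * i / (n - 1))`
#'   for `i = 0..n-1` (zero at both ends, peak at the middle);
#'   `"linear"` ramps 0 to `fa_max`.
#' @return Numeric vector of length `n`, starting at 0 with maximum `fa_max`.
#' @export
flip_angle_train <- function(n, fa_max, ramp_shape = c("half_sine", "linear")) {
  ramp_shape <- match.arg(ramp_shape)
  n <- as.integer(n)
  if (is.na(n) || n < 2L) stop("n must be >= 2")
  if (!is.finite(fa_max) || fa_max < 0) stop("fa_max must be >= 0")
  i <- seq_len(n) - 1L
  if (ramp_shape == "half_sine") fa_max * sin(pi * i / (n - 1L))
  else fa_max * i / (n - 1L)
}

# One readout segment: RF, relax to TE, readout, relax to end of TR, then
# either a gradient shift (FISP) or ideal spoiling (FLASH).
segment_ops <- function(fas, tr, te, spoiled) {
  end_code <- if (spoiled) 5 else 4
  do.call(rbind, lapply(fas, function(fa) {
    rbind(c(1, fa, 0), c(2, te, 0), c(3, 0, 0), c(2, tr - te, 0),
          c(end_code, 0, 0))
  }))
}

#' Build the acquisition schedule
#'
#' Assembles the ordered event list of the full fingerprint train:
#' inversion, FISP segment 1 (ramp to `fa_max_fisp1`), inter-segment delay,
#' FISP segment 2 (ramp to `fa_max_fisp2`), two spoiled FLASH segments with
#' the same flip-angle patterns, then one spin-lock preparation plus
#' FISP-like readout segment per entry of `tsl_list`, each followed by the
#' magnetization recovery delay. Every excitation is followed by exactly
#' one readout at TE, so the default schedule has
#' `4 * 250 + 6 * 125 = 1750` readouts.
#'
#' @param config a [sequence_config()].
#' @return An object of class `mrf_schedule` with elements `config`,
#'   `events` (a data frame of sequence events: inversion, excitation,
#'   delay, t1rho_prep, readout with times in ms), `ops` (the compiled
#'   operation table driving the simulator), `n_readouts`, and `hash`
#'   (a digest identifying the compiled schedule).
#' @export
build_schedule <- function(config = sequence_config()) {
  stopifnot(inherits(config, "mrf_seq_config"))
  ops <- list()
  events <- list()
  t <- 0
  add_event <- function(kind, time, flip = NA_real_, phase = NA_real_,
                        tsl = NA_real_, te = NA_real_) {
    events[[length(events) + 1L]] <<- data.frame(
      kind = kind, time_offset = time, flip_deg = flip, phase_deg = phase,
      tsl = tsl, te = te)
  }
  add_segment <- function(fas, spoiled) {
    ops[[length(ops) + 1L]] <<- segment_ops(fas, config$tr, config$te, spoiled)
    for (fa in fas) {
      add_event("excitation", t, flip = fa, phase = 0)
      add_event("readout", t + config$te, te = config$te)
      t <<- t + config$tr
    }
  }
  add_delay <- function(dur) {
    if (dur > 0) {
      ops[[length(ops) + 1L]] <<- matrix(c(2, dur, 0), 1)
      add_event("delay", t)
      t <<- t + dur
    }
  }

  add_event("inversion", t)
  ops[[1L]] <- matrix(c(6, config$inversion_efficiency, 0), 1)
  add_delay(config$inversion_duration)

  fas1 <- flip_angle_train(config$n_exc_fisp, config$fa_max_fisp1, config$ramp_shape)
  fas2 <- flip_angle_train(config$n_exc_fisp, config$fa_max_fisp2, config$ramp_shape)
  add_segment(fas1, spoiled = FALSE)
  add_delay(config$inter_segment_delay)
  add_segment(fas2, spoiled = FALSE)
  add_delay(config$inter_segment_delay)

  fasf1 <- flip_angle_train(config$n_exc_flash, config$fa_max_flash1, config$ramp_shape)
  fasf2 <- flip_angle_train(config$n_exc_flash, config$fa_max_flash2, config$ramp_shape)
  add_segment(fasf1, spoiled = TRUE)
  add_delay(config$inter_segment_delay)
  add_segment(fasf2, spoiled = TRUE)
  add_delay(config$inter_segment_delay)

  fas_rho <- flip_angle_train(config$n_exc_per_tsl, config$fa_max_t1rho, config$ramp_shape)
  for (tsl in config$tsl_list) {
    add_event("t1rho_prep", t, tsl = tsl)
    ops[[length(ops) + 1L]] <- matrix(c(7, tsl, 0), 1)
    t <- t + tsl
    add_segment(fas_rho, spoiled = FALSE)
    add_delay(config$recovery_delay)
  }

  ops <- do.call(rbind, ops)
  events <- do.call(rbind, events)
  n_readouts <- sum(events$kind == "readout")
  sched <- structure(list(config = config, events = events, ops = ops,
                          n_readouts = n_readouts, hash = NA_character_),
                     class = "mrf_schedule")
  sched$hash <- schedule_hash(sched)
  sched
}

#' Schedule digest
#'
#' MD5 digest of the compiled operation table, EPG truncation order and
#' inversion efficiency; used to refuse matching signals against a
#' dictionary simulated from a different schedule.
#'
#' @param schedule an `mrf_schedule`.
#' @return Character MD5 digest.
#' @export
schedule_hash <- function(schedule) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(c(format(c(dim(schedule$ops), schedule$config$max_order),
                      digits = 15),
               format(round(as.numeric(schedule$ops), 9), digits = 15)), f)
  unname(tools::md5sum(f))
}

#' @export
print.mrf_schedule <- function(x, ...) {
  cat("mrf_schedule:", x$n_readouts, "readouts,",
      nrow(x$events), "events, hash", substr(x$hash, 1, 8), "\n")
  invisible(x)
}

#' Simulate one fingerprint
#'
#' Runs the EPG engine over the compiled schedule for one tissue parameter
#' set and records `F+[0]` at each readout. FISP segments apply one
#' gradient shift per TR; FLASH segments are ideally spoiled; all
#' excitation flip angles are scaled by `b1_scale`; the result is scaled
#' by `pd`.
#'
#' @param schedule an [build_schedule()] result.
#' @param params a [tissue_params()].
#' @return Complex vector of length `schedule$n_readouts` with attribute
#'   `schedule_hash`.
#' @export
simulate_fingerprint <- function(schedule, params) {
  stopifnot(inherits(schedule, "mrf_schedule"), inherits(params, "tissue_params"))
  pm <- matrix(c(params$t1, params$t2, params$t1rho, params$pd,
                 params$b1_scale), 1)
  out <- epg_simulate_batch_cpp(schedule$ops, pm, schedule$config$max_order)
  structure(as.vector(out), schedule_hash = schedule$hash)
}

#' Simulate a batch of fingerprints
#'
#' Vector form of [simulate_fingerprint()] used by the dictionary builder
#' and the phantom simulator.
#'
#' @param schedule an `mrf_schedule`.
#' @param params_mat numeric matrix with columns t1, t2, t1rho, pd, b1.
#' @return Complex matrix, one row per parameter set.
#' @export
simulate_fingerprints <- function(schedule, params_mat) {
  stopifnot(inherits(schedule, "mrf_schedule"), is.matrix(params_mat),
            ncol(params_mat) == 5)
  epg_simulate_batch_cpp(schedule$ops, params_mat, schedule$config$max_order)
}

#' Write / read a schedule description
#'
#' Serializes the configuration and the sequence event table to a YAML
#' file for provenance, and reads it back.
#'
#' @param schedule an `mrf_schedule`.
#' @param path output file.
#' @return `write_schedule_yaml` returns `path` invisibly;
#'   `read_schedule_yaml` rebuilds the schedule from the stored config and
#'   verifies the stored hash.
#' @export
write_schedule_yaml <- function(schedule, path) {
  stopifnot(inherits(schedule, "mrf_schedule"))
  cfg <- unclass(schedule$config)
  yaml::write_yaml(list(config = cfg, hash = schedule$hash,
                        n_readouts = schedule$n_readouts,
                        events = schedule$events), path,
                   precision = 15L)
  invisible(path)
}

#' @rdname write_schedule_yaml
#' @export
read_schedule_yaml <- function(path) {
  obj <- yaml::read_yaml(path)
  cfg <- do.call(sequence_config, obj$config[setdiff(names(obj$config), NULL)])
  sched <- build_schedule(cfg)
  if (!identical(sched$hash, obj$hash))
    stop("stored schedule hash does not match rebuilt schedule")
  sched
}
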