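test_that("flip-angle ramps match their closed forms", {
  expect_equal(flip_angle_train(3, 20, "linear"), c(0, 10, 20))
  expect_equal(flip_angle_train(7, 0), rep(0, 7))
  # half-sine lobe fa_max * sin(pi i / (n-1))
  expect_equal(flip_angle_train(5, 60, "half_sine"),
               60 * sin(pi * 0:4 / 4), tolerance = 1e-12)
  expect_equal(flip_angle_train(5, 60)[2], 42.42641, tolerance = 1e-6)
  tr <- flip_angle_train(101, 35)
  expect_equal(tr[1], 0)
  expect_equal(max(tr), 35)
  expect_error(flip_angle_train(1, 20), ">= 2")
  expect_error(flip_angle_train(10, -5), ">= 0")
})

test_that("default schedule has the documented structure", {
  sched <- full_schedule()
  ev <- sched$events
  expect_equal(sched$n_readouts, 4 * 250 + 6 * 125)
  expect_equal(sum(ev$kind == "excitation"), 1750)
  expect_equal(sum(ev$kind == "inversion"), 1)
  preps <- ev[ev$kind == "t1rho_prep", ]
  expect_equal(nrow(preps), 6)
  expect_false(is.unsorted(preps$tsl))
  expect_equal(min(preps$tsl), 2)
  expect_equal(max(preps$tsl), 45)
  # events strictly ordered in time (readouts interleave at TE offsets)
  expect_false(is.unsorted(ev$time_offset))
  # each readout trails its excitation by TE
  ro <- ev$time_offset[ev$kind == "readout"]
  ex <- ev$time_offset[ev$kind == "excitation"]
  expect_equal(ro, ex + 3.5)
})

test_that("empty tsl_list drops the spin-lock module", {
  sched <- build_schedule(sequence_config(tsl_list = numeric(0)))
  expect_equal(sched$n_readouts, 1000)
  expect_equal(sum(sched$events$kind == "t1rho_prep"), 0)
})

test_that("schedule hash discriminates and yaml round-trips", {
  a <- short_schedule()
  b <- build_schedule(sequence_config(n_exc_fisp = 20L, n_exc_flash = 20L,
                                      n_exc_per_tsl = 10L, max_order = 40L,
                                      fa_max_fisp2 = 55))
  expect_false(identical(a$hash, b$hash))
  f <- tempfile(fileext = ".yaml")
  write_schedule_yaml(a, f)
  a2 <- read_schedule_yaml(f)
  expect_equal(a2$hash, a$hash)
  expect_equal(a2$ops, a$ops)
})

test_that("zero flip angles yield a zero fingerprint and PD scales linearly", {
  cfg <- sequence_config(n_exc_fisp = 10L, n_exc_flash = 10L,
                         n_exc_per_tsl = 5L, fa_max_fisp1 = 0,
                         fa_max_fisp2 = 0, fa_max_flash1 = 0,
                         fa_max_flash2 = 0, fa_max_t1rho = 0,
                         max_order = 20L)
  sched0 <- build_schedule(cfg)
  f0 <- simulate_fingerprint(sched0, tissue_params(1000, 80, 100))
  expect_equal(max(Mod(f0)), 0)

  sched <- short_schedule()
  f1 <- simulate_fingerprint(sched, tissue_params(1000, 80, 100, pd = 1))
  f2 <- simulate_fingerprint(sched, tissue_params(1000, 80, 100, pd = 2.5))
  expect_equal(f2, 2.5 * f1, tolerance = 1e-12, ignore_attr = TRUE)
})

test_that("T1rho only affects the spin-lock module", {
  sched <- short_schedule()
  n_pre <- 4 * sched$config$n_exc_fisp   # FISP + FLASH readouts
  fa <- simulate_fingerprint(sched, tissue_params(1000, 80, 60))
  fb <- simulate_fingerprint(sched, tissue_params(1000, 80, 150))
  expect_equal(fa[1:n_pre], fb[1:n_pre], tolerance = 1e-14)
  expect_gt(max(Mod(fa[(n_pre + 1):length(fa)] - fb[(n_pre + 1):length(fb)])),
            1e-6)
})

test_that("very large T1rho converges to the all-TSL-zero schedule", {
  cfg <- sequence_config(n_exc_fisp = 20L, n_exc_flash = 20L,
                         n_exc_per_tsl = 10L, max_order = 40L)
  cfg0 <- sequence_config(n_exc_fisp = 20L, n_exc_flash = 20L,
                          n_exc_per_tsl = 10L, max_order = 40L,
                          tsl_list = rep(0, 6))
  p_inf <- tissue_params(1000, 80, 1e12)
  f_inf <- simulate_fingerprint(build_schedule(cfg), p_inf)
  f_zero <- simulate_fingerprint(build_schedule(cfg0), p_inf)
  expect_equal(as.vector(f_inf), as.vector(f_zero), tolerance = 1e-9)
})

test_that("B1 scale separates tissues in the spoiled (FLASH) module", {
  sched <- short_schedule()
  nf <- sched$config$n_exc_fisp
  flash_idx <- (2 * nf + 1):(4 * nf)
  fa <- simulate_fingerprint(sched, tissue_params(1000, 80, 100, b1_scale = 1))
  fb <- simulate_fingerprint(sched, tissue_params(1000, 80, 100, b1_scale = 1.2))
  rel <- Mod(fa[flash_idx] - fb[flash_idx]) / max(Mod(fa))
  expect_gt(max(rel), 0.01)
})

test_that("fingerprints vary continuously with T1", {
  sched <- short_schedule()
  f0 <- simulate_fingerprint(sched, tissue_params(1000, 80, 100))
  f1 <- simulate_fingerprint(sched, tissue_params(1010, 80, 100))
  n0 <- f0 / sqrt(sum(Mod(f0)^2))
  n1 <- f1 / sqrt(sum(Mod(f1)^2))
  expect_lt(sqrt(sum(Mod(n0 - n1)^2)), 0.05)
  expect_gt(sqrt(sum(Mod(n0 - n1)^2)), 0)
})
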