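test_that("geometric axes match brute-force enumeration", {
  # independent oracle: repeated multiplication until the bound is passed
  enum_axis <- function(lo, hi, step) {
    v <- lo
    while (v[length(v)] * (1 + step) <= hi * (1 + 1e-12))
      v <- c(v, v[length(v)] * (1 + step))
    v
  }
  a <- geometric_axis(50, 3000, 0.06)
  expect_equal(a, enum_axis(50, 3000, 0.06), tolerance = 1e-12)
  expect_length(a, 71)
  expect_equal(a[1:3], c(50, 53, 56.18), tolerance = 1e-12)
  b <- geometric_axis(2, 200, 0.06)
  expect_equal(b, enum_axis(2, 200, 0.06), tolerance = 1e-12)
  expect_length(b, 80)
  expect_equal(geometric_axis(100, 100, 0.06), 100)
  expect_error(geometric_axis(10, 5), "min <= max")
  expect_error(geometric_axis(10, 20, 0), "> 0")
})

test_that("grid construction filters unphysical atoms and is ordered", {
  g <- build_grid(t1_values = 1000, t2_values = c(50, 2000),
                  t1rho_values = 50)
  expect_equal(nrow(g$atoms), 1)         # t2 = 2000 > t1 filtered
  expect_equal(g$atoms$t2, 50)

  g2 <- build_grid(t1_range = c(50, 3000), t2_range = c(2, 200),
                   t1rho_range = c(2, 200), enforce_t1rho_le_t1 = FALSE)
  expect_equal(g2$dims[1:3], c(71L, 80L, 80L))
  a <- g2$atoms
  # lexicographic by (t1, t2, t1rho, b1), stable across runs
  expect_false(is.unsorted(a$t1))
  key <- order(a$t1, a$t2, a$t1rho, a$b1)
  expect_equal(key, seq_len(nrow(a)))
  expect_true(all(a$t2 <= a$t1))
  g3 <- build_grid(t1_range = c(50, 3000), t2_range = c(2, 200),
                   t1rho_range = c(2, 200), enforce_t1rho_le_t1 = FALSE)
  expect_identical(g2$atoms, g3$atoms)
})

test_that("custom atom-list grids deduplicate and keep the t2<=t1 filter", {
  g <- grid_from_atoms(t1 = c(800, 800, 100), t2 = c(70, 70, 300),
                       t1rho = c(80, 80, 50))
  expect_equal(nrow(g$atoms), 1)
  expect_null(g$lookup)
})

test_that("dictionary rows are unit norm and round-trip their scale", {
  sched <- short_schedule()
  g <- grid_from_atoms(t1 = c(800, 1200), t2 = c(70, 90), t1rho = c(80, 110))
  d <- build_dictionary(g, sched, chunk_size = 1L)
  expect_equal(dim(d$fingerprints), c(2L, sched$n_readouts))
  expect_lt(max(abs(sqrt(rowSums(Mod(d$fingerprints)^2)) - 1)), 1e-9)
  # row * stored norm equals the raw fingerprint at PD = 1
  raw <- simulate_fingerprint(sched, tissue_params(800, 70, 80))
  expect_equal(d$fingerprints[1, ] * d$norms[1], as.vector(raw),
               tolerance = 1e-12)
})

test_that("SVD compression has exact limits and honours the energy target", {
  sched <- short_schedule()
  g <- build_grid(t1_range = c(400, 1600), t2_range = c(30, 120),
                  t1rho_range = c(40, 150), step_fraction = 0.25)
  d <- build_dictionary(g, sched)
  n_atoms <- nrow(d$fingerprints)

  full <- compress_dictionary(d, rank = min(n_atoms, ncol(d$fingerprints)))
  expect_equal(full$energy_retained, 1, tolerance = 1e-12)
  recon <- full$projected %*% t(Conj(full$basis))
  expect_lt(max(Mod(recon - d$fingerprints)), 1e-9)
  expect_lt(max(Mod(crossprod(Conj(full$basis), full$basis) -
                      diag(full$rank))), 1e-9)
  expect_true(all(diff(full$singular_values) <= 1e-9))

  # identical rows -> rank 1 carries all energy
  d2 <- d
  d2$fingerprints <- matrix(rep(d$fingerprints[1, ], 5), 5, byrow = TRUE)
  d2$norms <- rep(d$norms[1], 5)
  c1 <- compress_dictionary(d2, rank = 1)
  expect_equal(c1$energy_retained, 1, tolerance = 1e-10)

  # energy target picks the smallest rank reaching the cumulative sum
  ce <- compress_dictionary(d, energy = 0.999)
  sv2 <- compress_dictionary(d, rank = min(n_atoms, ncol(d$fingerprints)))$singular_values^2
  cum <- cumsum(sv2) / sum(sv2)
  expect_equal(ce$rank, which(cum >= 0.999)[1])
  expect_gte(ce$energy_retained, 0.999)
  # energy nondecreasing in rank
  er <- sapply(c(1, 2, 5, 10), function(r) compress_dictionary(d, rank = r)$energy_retained)
  expect_true(all(diff(er) >= -1e-12))
  expect_error(compress_dictionary(d, rank = 0), "rank")
})

test_that("gram-matrix and direct SVD routes agree", {
  sched <- short_schedule()
  g <- build_grid(t1_range = c(400, 1600), t2_range = c(30, 120),
                  t1rho_range = c(40, 150), step_fraction = 0.3)
  d <- build_dictionary(g, sched)                      # atoms > timepoints
  gram <- compress_dictionary(d, rank = 8)
  sv_direct <- svd(d$fingerprints)$d[1:8]
  expect_equal(gram$singular_values[1:8], sv_direct, tolerance = 1e-8)
  # and the direct route on a small dictionary (atoms < timepoints)
  gs <- grid_from_atoms(t1 = seq(600, 1400, by = 100),
                        t2 = seq(50, 130, by = 10),
                        t1rho = seq(60, 140, by = 10))
  ds <- build_dictionary(gs, sched)
  direct <- compress_dictionary(ds, rank = 4)
  expect_equal(direct$singular_values[1:4], svd(ds$fingerprints)$d[1:4],
               tolerance = 1e-8)
})

test_that("dictionary archives round-trip with their provenance", {
  sched <- short_schedule()
  g <- grid_from_atoms(t1 = c(800, 1200), t2 = c(70, 90), t1rho = c(80, 110))
  d <- build_dictionary(g, sched)
  comp <- compress_dictionary(d, rank = 2)
  f <- tempfile(fileext = ".rds")
  save_dictionary(d, f, compressed = comp)
  back <- load_dictionary(f)
  expect_equal(back$dictionary$fingerprints, d$fingerprints)
  expect_equal(back$dictionary$schedule_hash, sched$hash)
  expect_equal(back$compressed$basis, comp$basis)
  unlink(f)
})
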