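# Lazily built, cached fixtures shared across test files. Everything is
# generated in code; nothing is stored on disk.
.fixtures <- new.env(parent = emptyenv())

fix_get <- function(name, builder) {
  if (!exists(name, envir = .fixtures))
    assign(name, builder(), envir = .fixtures)
  get(name, envir = .fixtures)
}

# Short schedule for fast unit tests: 4 x 20 + 6 x 10 = 140 readouts.
short_schedule <- function() fix_get("short_sched", function() {
  build_schedule(sequence_config(n_exc_fisp = 20L, n_exc_flash = 20L,
                                 n_exc_per_tsl = 10L, max_order = 40L))
})

# Full default schedule (1750 readouts, EPG order 250) for physics checks.
full_schedule <- function() fix_get("full_sched", function() {
  build_schedule(sequence_config())
})

# Full-length schedule with EPG order 64 used for dictionary-scale tests;
# the truncation error against order 250 is below 1e-4 even at T2 = 200 ms.
dict_schedule <- function() fix_get("dict_sched", function() {
  build_schedule(sequence_config(max_order = 64L))
})

# ~5k-atom 6%-step dictionary on mid-range relaxation axes.
test_dictionary <- function() fix_get("test_dict", function() {
  grid <- build_grid(t1_range = c(500, 1280), t2_range = c(40, 102),
                     t1rho_range = c(40, 102), step_fraction = 0.06)
  build_dictionary(grid, dict_schedule())
})

# Tiny dictionary on the short schedule for matcher unit tests.
small_dictionary <- function() fix_get("small_dict", function() {
  grid <- build_grid(t1_range = c(600, 1100), t2_range = c(50, 100),
                     t1rho_range = c(50, 100), step_fraction = 0.12)
  build_dictionary(grid, short_schedule())
})

# Complex white Gaussian noise with total per-sample SD sigma.
cnoise <- function(n_row, n_col, sigma) {
  sigma / sqrt(2) * (matrix(rnorm(n_row * n_col), n_row) +
                       1i * matrix(rnorm(n_row * n_col), n_row))
}

# Root-mean-square magnitude of a complex vector/matrix.
rms_mod <- function(x) sqrt(mean(Mod(x)^2))

# NIST-like sphere phantom at desk scale plus a dictionary of local
# 6%-step neighborhoods (+/- 3 steps per axis) around each sphere's
# ground truth; the full published grid would be ~450k atoms and adds
# nothing to these property checks.
nist_phantom <- function() fix_get("nist_ph", function() {
  make_nist_like_phantom()
})

nist_dictionary <- function() fix_get("nist_dict", function() {
  rp <- nist_phantom()$region_params
  steps <- 1.06^(-3:3)
  atoms <- do.call(rbind, lapply(seq_len(nrow(rp)), function(i) {
    expand.grid(t1 = rp$t1[i] * steps, t2 = rp$t2[i] * steps,
                t1rho = rp$t1rho[i] * steps)
  }))
  g <- grid_from_atoms(atoms$t1, atoms$t2, atoms$t1rho)
  build_dictionary(g, dict_schedule())
})

# Brain phantom with two +30% lesions and a 6%-step dictionary covering
# the WM/GM/lesion neighborhood (CSF is deliberately outside the grid).
brain_lesions <- list(list(center = c(20, 40), radius = 3, delta = 0.3),
                      list(center = c(44, 24), radius = 3, delta = 0.3))

brain_phantom <- function() fix_get("brain_ph", function() {
  make_brain_like_phantom(lesion_spec = brain_lesions)
})

brain_dictionary <- function() fix_get("brain_dict", function() {
  g <- build_grid(t1_range = c(700, 1600), t2_range = c(50, 130),
                  t1rho_range = c(60, 140), step_fraction = 0.06)
  build_dictionary(g, dict_schedule())
})

# Mirror a set of voxel indices through the mid-sagittal (x) plane.
mirror_voxels <- function(idx, shape) {
  ij <- arrayInd(idx, shape)
  ij[, 1] <- shape[1] + 1L - ij[, 1]
  as.vector(ij[, 1] + (ij[, 2] - 1L) * shape[1] +
              (ij[, 3] - 1L) * shape[1] * shape[2])
}
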