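test_that("equilibrium state and constructor invariants hold", {
  s <- epg_state(10)
  expect_equal(length(s$f_plus), 11L)
  expect_equal(s$z[1], complex(real = 1))
  expect_true(all(s$f_plus == 0) && all(s$f_minus == 0))
  expect_error(epg_state(0), "positive")
})

test_that("tissue_params validates physical constraints", {
  p <- tissue_params(1000, 80, 100)
  expect_s3_class(p, "tissue_params")
  expect_error(tissue_params(100, 200, 50), "t2")
  expect_no_error(tissue_params(100, 200, 50, check_t2_le_t1 = FALSE))
  expect_error(tissue_params(-1, 10, 10), "> 0")
  expect_error(tissue_params(100, 50, 50, b1_scale = 0), "b1_scale")
})

test_that("zero flip is the identity and 180x inverts equilibrium", {
  s <- epg_state(5)
  s$f_plus[2] <- 0.3 + 0.1i
  s$f_minus[2] <- 0.2i
  s2 <- epg_rf(s, 0, 123)
  expect_equal(s2$f_plus, s$f_plus)
  expect_equal(s2$z, s$z)
  inv <- epg_rf(epg_state(5), 180, 0)
  expect_equal(inv$z[1], complex(real = -1), tolerance = 1e-12)
  expect_lt(max(Mod(inv$f_plus)), 1e-12)
})

test_that("90/90 pulse on equilibrium matches a single-isochromat Bloch rotation", {
  # Independent 3D rotation oracle under the shared convention:
  # axis at phase p in the xy-plane, F = Mx + i My.
  rot <- function(M, a_deg, p_deg) {
    a <- a_deg * pi / 180; p <- p_deg * pi / 180
    ca <- cos(a); sa <- sin(a); cp <- cos(p); sp <- sin(p)
    R <- rbind(c(cp^2 + sp^2 * ca, cp * sp * (1 - ca), sp * sa),
               c(cp * sp * (1 - ca), sp^2 + cp^2 * ca, -cp * sa),
               c(-sp * sa, cp * sa, ca))
    as.vector(R %*% M)
  }
  for (case in list(c(90, 90), c(90, 0), c(37, 15), c(120, 200))) {
    s <- epg_rf(epg_state(3), case[1], case[2])
    M <- rot(c(0, 0, 1), case[1], case[2])
    expect_equal(s$f_plus[1], complex(real = M[1], imaginary = M[2]),
                 tolerance = 1e-12)
    expect_equal(Re(s$z[1]), M[3], tolerance = 1e-12)
    # f_minus[0] is the conjugate representation of the same F(0)
    expect_equal(s$f_minus[1], Conj(s$f_plus[1]), tolerance = 1e-12)
  }
})

test_that("RF rotations preserve the EPG norm for arbitrary states", {
  set.seed(11)
  for (i in 1:20) {
    s <- epg_state(8)
    s$f_plus <- complex(real = rnorm(9), imaginary = rnorm(9))
    s$f_minus <- complex(real = rnorm(9), imaginary = rnorm(9))
    s$f_minus[1] <- Conj(s$f_plus[1])
    s$z <- complex(real = rnorm(9), imaginary = rnorm(9))
    n0 <- epg_norm(s)
    s2 <- epg_rf(s, runif(1, 0, 360), runif(1, 0, 360))
    expect_equal(epg_norm(s2), n0, tolerance = 1e-10)
  }
})

test_that("gradient shift moves transverse orders and composes", {
  s <- epg_state(5)
  expect_equal(epg_grad_shift(s)$z, s$z)  # z untouched
  s$f_plus[1] <- 1; s$f_minus[1] <- 1
  s1 <- epg_grad_shift(s)
  expect_equal(Re(s1$f_plus[2]), 1)
  expect_equal(s1$f_plus[1], complex(real = 0))
  s2 <- epg_grad_shift(s1)
  expect_equal(Re(s2$f_plus[3]), 1)
  # truncation: order max_order+1 is dropped
  st <- epg_state(2); st$f_plus[3] <- 1
  expect_true(all(epg_grad_shift(st)$f_plus[2:3] == c(0, 0)))
})

test_that("relaxation has the closed-form fixed points", {
  p <- tissue_params(1000, 80, 100)
  s <- epg_state(4)
  s$f_plus[2] <- 0.5; s$z[1] <- 0.2
  expect_equal(epg_relax(s, 0, p), s)           # dt = 0 identity
  far <- epg_relax(s, 1e9, p)                   # asymptotic equilibrium
  expect_equal(Re(far$z[1]), 1, tolerance = 1e-12)
  expect_lt(max(Mod(far$f_plus)), 1e-12)
  s0 <- epg_state(4); s0$z[1] <- 0
  expect_equal(Re(epg_relax(s0, 1000, p)$z[1]), 1 - exp(-1), tolerance = 1e-12)
  # inversion-recovery closed form: z = 1 - (1 - z0) exp(-dt/T1)
  for (z0 in c(-1, -0.3, 0.6)) {
    for (dt in c(50, 300, 1200)) {
      si <- epg_state(2); si$z[1] <- z0
      expect_equal(Re(epg_relax(si, dt, p)$z[1]),
                   1 - (1 - z0) * exp(-dt / 1000), tolerance = 1e-12)
    }
  }
  expect_error(epg_relax(s, -1, p), ">= 0")
})

test_that("spin-lock preparation decays z mono-exponentially and crushes F", {
  p <- tissue_params(1000, 80, 90)
  s <- epg_state(3)
  s$f_plus[1] <- 0.5; s$f_minus[1] <- 0.5; s$z[1] <- 0.8; s$z[2] <- 0.1
  s0 <- t1rho_prep(s, 0, p)
  expect_equal(Re(s0$z[1]), 0.8)                # tsl = 0 leaves z
  expect_true(all(s0$f_plus == 0))
  s1 <- t1rho_prep(s, 90, p)
  expect_equal(Re(s1$z[1]), 0.8 * exp(-1), tolerance = 1e-15)
  expect_equal(Re(s1$z[2]), 0.1 * exp(-1), tolerance = 1e-15)
  s2 <- t1rho_prep(s, 45, p)
  expect_equal(Re(s2$z[1]), 0.8 * exp(-0.5), tolerance = 1e-15)
  expect_error(t1rho_prep(s, -2, p), ">= 0")
  # attenuation strictly decreasing in tsl, increasing in t1rho
  att <- function(tsl, t1rho) {
    pp <- tissue_params(1000, 80, t1rho)
    Re(t1rho_prep(epg_state(2), tsl, pp)$z[1])
  }
  tsl <- seq(0, 100, by = 10)
  expect_true(all(diff(sapply(tsl, att, t1rho = 60)) < 0))
  rhos <- seq(20, 200, by = 20)
  expect_true(all(diff(sapply(rhos, function(r) att(40, r))) > 0))
})

test_that("inversion applies efficiency and rejects bad values", {
  expect_equal(Re(inversion(epg_state(2), 1)$z[1]), -1)
  expect_equal(Re(inversion(epg_state(2), 0)$z[1]), 0)
  s <- epg_state(2); s$z[1] <- 0.5
  expect_equal(Re(inversion(s, 0.95)$z[1]), -0.475)
  expect_error(inversion(epg_state(2), 1.2), "\\[0, 1\\]")
})

test_that("compiled batch kernel agrees with composed R operators", {
  sched <- short_schedule()
  p <- tissue_params(900, 70, 80, pd = 1.3, b1_scale = 0.9)
  fp_cpp <- simulate_fingerprint(sched, p)
  # step the R-level operators through the same op table
  s <- epg_state(sched$config$max_order)
  sig <- complex(sched$n_readouts); ir <- 0L
  for (i in seq_len(nrow(sched$ops))) {
    op <- sched$ops[i, ]
    if (op[1] == 3) { ir <- ir + 1L; sig[ir] <- s$f_plus[1] }
    s <- mrfmap:::apply_op(s, op, p)
  }
  expect_equal(as.vector(fp_cpp), sig * p$pd, tolerance = 1e-12)
})
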