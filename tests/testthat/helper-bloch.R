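# Independent single-voxel Bloch oracle: a population of isochromats
# uniformly spanning one gradient-dephasing cycle, advanced through the
# compiled schedule op table. Shares only the phase convention with the
# EPG engine (F = Mx + i*My, RF phase 0 rotates about +x, right-handed);
# the configuration-state ladder algebra is not used anywhere here.
bloch_fingerprint <- function(schedule, params, n_iso = 2000) {
  ops <- schedule$ops
  phi <- 2 * pi * (seq_len(n_iso) - 1) / n_iso  # per-shift dephasing angle
  cph <- cos(phi); sph <- sin(phi)
  Mx <- My <- rep(0, n_iso); Mz <- rep(1, n_iso)
  sig <- complex(schedule$n_readouts)
  ir <- 0L
  for (i in seq_len(nrow(ops))) {
    code <- ops[i, 1]
    if (code == 1) {            # RF rotation about in-plane axis at phase p
      a <- ops[i, 2] * params$b1_scale * pi / 180
      p <- ops[i, 3] * pi / 180
      # Rz(p) Rx(a) Rz(-p)
      ca <- cos(a); sa <- sin(a); cp <- cos(p); sp <- sin(p)
      r11 <- cp * cp + sp * sp * ca; r12 <- cp * sp * (1 - ca); r13 <- sp * sa
      r21 <- r12;                    r22 <- sp * sp + cp * cp * ca; r23 <- -cp * sa
      r31 <- -sp * sa;               r32 <- cp * sa;               r33 <- ca
      nx <- r11 * Mx + r12 * My + r13 * Mz
      ny <- r21 * Mx + r22 * My + r23 * Mz
      nz <- r31 * Mx + r32 * My + r33 * Mz
      Mx <- nx; My <- ny; Mz <- nz
    } else if (code == 2) {     # relaxation
      e1 <- exp(-ops[i, 2] / params$t1); e2 <- exp(-ops[i, 2] / params$t2)
      Mx <- Mx * e2; My <- My * e2; Mz <- Mz * e1 + (1 - e1)
    } else if (code == 3) {     # readout: ensemble-average transverse
      ir <- ir + 1L
      sig[ir] <- complex(real = mean(Mx), imaginary = mean(My))
    } else if (code == 4) {     # gradient dephasing over one cycle
      nx <- Mx * cph - My * sph
      ny <- Mx * sph + My * cph
      Mx <- nx; My <- ny
    } else if (code == 5) {     # ideal spoiling
      Mx[] <- 0; My[] <- 0
    } else if (code == 6) {     # inversion with efficiency
      Mz <- -ops[i, 2] * Mz; Mx[] <- 0; My[] <- 0
    } else if (code == 7) {     # spin-lock prep: rotating-frame decay
      Mz <- Mz * exp(-ops[i, 2] / params$t1rho); Mx[] <- 0; My[] <- 0
    } else stop("unknown opcode")
  }
  sig * params$pd
}
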