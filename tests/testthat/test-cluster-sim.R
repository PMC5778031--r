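# Synthetic-data stage: cluster construction, confinement, toy MD,
# proton-hop emulator, Wannier synthesis, analytic fixtures.

test_that("cluster templates have the right composition and shape", {
  chain <- build_cluster(confinement_spec("chain"), sim_params(seed = 1L))
  expect_equal(length(chain$elements), 45L)
  o <- chain$elements == "O"
  expect_lt(max(sqrt(chain$xyz[o, 1L]^2 + chain$xyz[o, 2L]^2)), 1)
  disc <- build_cluster(confinement_spec("disc"), sim_params(seed = 2L))
  expect_lt(max(abs(disc$xyz[disc$elements == "O", 3L])), 1)
  drop_p <- build_cluster(confinement_spec("droplet"),
                          sim_params(seed = 3L, protonated = TRUE))
  expect_equal(length(drop_p$elements), 79L)
  expect_equal(total_charge(drop_p, charge_model("nuclear_effective")), 1)
})

test_that("confinement energies match the quadratic forms and their gradients", {
  spec <- confinement_spec("chain", "narrow")  # K_xy = 2000 kJ/mol/nm^2
  f0 <- ideal_water_frame()                    # O on the axis
  expect_equal(confinement_energy(f0, spec)$energy, 0)
  f1 <- md_frame(f0$elements, f0$xyz + rep(c(1, 0, 0), each = 3L)) # O at x = 0.1 nm
  expect_equal(confinement_energy(f1, spec)$energy, 10)
  # forces equal the negative finite-difference gradient for all geometries
  set.seed(21)
  fr <- md_frame(c("O", "H", "H", "O", "H", "H"),
                 matrix(rnorm(18, sd = 2), 6L, 3L))
  for (g in list(confinement_spec("chain", "wide"), confinement_spec("disc"),
                 confinement_spec("droplet"))) {
    ce <- confinement_energy(fr, g)
    h <- 1e-5
    for (i in c(1L, 4L)) for (d in 1:3) {
      up <- fr; up$xyz[i, d] <- up$xyz[i, d] + h
      dn <- fr; dn$xyz[i, d] <- dn$xyz[i, d] - h
      num <- -(confinement_energy(up, g)$energy -
                 confinement_energy(dn, g)$energy) / (2 * h)
      expect_equal(ce$forces[i, d], num, tolerance = 1e-6)
    }
  }
})

test_that("NVE segments conserve energy and NVT equilibration targets 300 K", {
  # small dimer: energy drift under velocity Verlet stays well below 1% of KE
  two <- run_cluster_md("chain", protonated = FALSE, seed = 4L,
                        n_waters = 2L, equil_time = 0.5, segment_time = 1,
                        n_segments = 1L)
  E <- two$md$segments[[1L]]$energy
  ke_scale <- 0.5 * 3 * 6 * 8.31446e-3 * 300
  expect_lt(abs(E[length(E)] - E[1L]) / ke_scale, 0.01)
  # 15-water chain over its standard segments
  md <- chain_protonated_md()$md
  for (seg in md$segments) {
    E <- seg$energy
    ke_scale <- 0.5 * 3 * 46 * 8.31446e-3 * 300
    expect_lt(abs(E[length(E)] - E[1L]) / ke_scale, 0.01)
  }
  # long thermostatted run: mean kinetic temperature within 300 +/- 15 K
  nvt <- fixture("nvt_long", run_cluster_md("chain", protonated = FALSE,
                                            seed = 11L, equil_time = 10,
                                            segment_time = 0.25,
                                            n_segments = 1L))
  Ts <- nvt$md$nvt_temperature
  burn <- seq_len(round(length(Ts) / 5))
  expect_lt(abs(mean(Ts[-burn]) - 300), 15)
})

test_that("toy-MD spectra show bands at the model's own normal modes", {
  nm <- water_normal_modes()
  expect_equal(length(nm), 3L)
  one <- fixture("water_dimer", {
    spec <- confinement_spec("droplet")
    p <- sim_params(equil_time = 1, segment_time = 4, n_segments = 1L,
                    seed = 13L, n_waters = 2L)
    f0 <- build_cluster(spec, p)
    run_toy_md(f0, spec, p)
  })
  tr <- one$segments[[1L]]
  sp <- smooth_gaussian(spectrum_from_dipole(
    dipole_series(tr, charge_model()), spectral_config(dt = tr$dt)), 30)
  tot <- rowSums(sp$A)
  near <- function(nu0, win) {
    sel <- sp$nu > nu0 - win & sp$nu < nu0 + win
    max(tot[sel])
  }
  # distinct bend and stretch bands: local power near the normal modes far
  # exceeds the quiet window between them
  gap <- max(tot[sp$nu > 2200 & sp$nu < 3000])
  expect_gt(near(nm[1L], 150), 5 * gap)
  expect_gt(near(mean(nm[2:3]), 250), 5 * gap)
})

test_that("radial confinement is tighter for the narrow chain than the wide one", {
  rms_radial <- function(res) {
    tr <- res$md$segments[[1L]]
    o <- tr$elements == "O"
    sqrt(mean(tr$xyz[o, 1L, ]^2 + tr$xyz[o, 2L, ]^2))
  }
  narrow <- fixture("narrow_r", run_cluster_md("chain", "narrow",
                                               protonated = FALSE, seed = 6L,
                                               equil_time = 1, segment_time = 1,
                                               n_segments = 1L))
  wide <- fixture("wide_r", run_cluster_md("chain", "wide",
                                           protonated = FALSE, seed = 6L,
                                           equil_time = 1, segment_time = 1,
                                           n_segments = 1L))
  expect_lt(rms_radial(narrow), rms_radial(wide))
})

test_that("simulation output is bit-reproducible for a fixed seed", {
  a <- run_cluster_md("chain", protonated = TRUE, seed = 42L,
                      equil_time = 0.2, segment_time = 0.2, n_segments = 1L)
  b <- run_cluster_md("chain", protonated = TRUE, seed = 42L,
                      equil_time = 0.2, segment_time = 0.2, n_segments = 1L)
  expect_identical(a$md$segments[[1L]]$xyz, b$md$segments[[1L]]$xyz)
  c3 <- run_cluster_md("chain", protonated = TRUE, seed = 43L,
                       equil_time = 0.2, segment_time = 0.2, n_segments = 1L)
  expect_false(identical(a$md$segments[[1L]]$xyz, c3$md$segments[[1L]]$xyz))
})

test_that("the proton hopper is seeded, axis-faithful and silent at rate 0", {
  md <- chain_protonated_md()$md
  tr <- md$segments[[1L]]
  h0 <- attach_proton_hopper(tr, hopper_spec(hop_rate = 0), seed = 1L)
  expect_equal(max(abs(sweep(h0$mu, 2L, h0$mu[1L, ]))), 0)  # constant dipole
  sp0 <- spectrum_from_dipole(h0, spectral_config(dt = tr$dt))
  expect_equal(max(sp0$A), 0)
  h1 <- attach_proton_hopper(tr, hopper_spec(hop_rate = 20), seed = 2L)
  expect_equal(max(abs(h1$mu[, 1:2])), 0)  # chain policy: z only
  h1b <- attach_proton_hopper(tr, hopper_spec(hop_rate = 20), seed = 2L)
  expect_identical(h1$mu, h1b$mu)
  h1c <- attach_proton_hopper(tr, hopper_spec(hop_rate = 20), seed = 3L)
  expect_false(identical(h1$mu, h1c$mu))
  disc <- disc_protonated_md()$md$segments[[1L]]
  hd <- attach_proton_hopper(disc, hopper_spec(hop_rate = 20), seed = 4L)
  expect_equal(max(abs(hd$mu[, 3L])), 0)   # disc policy: in-plane only
})

test_that("synthesized Wannier centers follow the template and keep neutrality", {
  fr <- synthesize_wannier(ideal_water_frame(), jitter_sd = 0)
  th <- 104.52 * pi / 180
  u1 <- c(sin(th / 2), 0, cos(th / 2)); u2 <- c(-sin(th / 2), 0, cos(th / 2))
  expect_equal(fr$wannier[1L, ], 0.5 * u1, tolerance = 1e-12)
  expect_equal(fr$wannier[2L, ], 0.5 * u2, tolerance = 1e-12)
  expect_equal(sqrt(sum(fr$wannier[3L, ]^2)), 0.3, tolerance = 1e-12)
  expect_equal(fr$wannier[3L, ], -fr$wannier[4L, ], tolerance = 1e-12)
  expect_equal(total_charge(fr, charge_model("wannier_full")), 0)
  # 15-water chain: 60 centers; protonated chain: 64 with net +1
  chain <- build_cluster(confinement_spec("chain"), sim_params(seed = 2L))
  expect_equal(nrow(synthesize_wannier(chain)$wannier), 60L)
  pr <- jittered_chain_frames()[[1L]]
  frp <- synthesize_wannier(pr)
  expect_equal(nrow(frp$wannier), 60L)   # H3O+ also has 4 electron pairs
  expect_equal(total_charge(frp, charge_model("wannier_full")), 1)
  # jitter is seeded
  j1 <- synthesize_wannier(ideal_water_frame(), 0.05, seed = 8L)
  j2 <- synthesize_wannier(ideal_water_frame(), 0.05, seed = 8L)
  expect_identical(j1$wannier, j2$wannier)
})

test_that("oscillator fixtures honour their mode tables", {
  z <- generate_oscillator_dipole(NULL, N = 64L, dt = 0.5, seed = 1L)
  expect_equal(max(abs(z$series$mu)), 0)
  two <- generate_oscillator_dipole(
    data.frame(nu = c(1200, 1200), amplitude = c(1, 1), axis = c("x", "y"),
               phase = c(0, 0)), N = 4096L, dt = 0.5)
  sp <- spectrum_from_dipole(two$series, spectral_config(dt = 0.5))
  expect_equal(sp$A[, 1L], sp$A[, 2L], tolerance = 1e-12)
  one <- generate_oscillator_dipole(
    data.frame(nu = 3400, amplitude = 1, axis = "z", phase = 0.4),
    N = 2^14, dt = 0.5)
  spz <- spectrum_from_dipole(one$series, spectral_config(dt = 0.5))
  dnu <- diff(spz$nu[1:2])
  expect_lt(abs(spz$nu[which.max(spz$A[, 3L])] - 3400), dnu + 1e-9)
  expect_error(generate_oscillator_dipole(NULL, N = 8L), ">= 16")
})
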