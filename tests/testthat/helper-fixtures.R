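# Shared fixtures, computed lazily and cached for the whole test run.
# All fixtures are generated in code with fixed seeds; simulation sizes are
# kept at desk scale (a few ps per system).

.fixture_cache <- new.env(parent = emptyenv())

fixture <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache))
    assign(name, force(expr), envir = .fixture_cache)
  get(name, envir = .fixture_cache)
}

run_cluster_md <- function(geometry, width = "narrow", protonated = TRUE,
                           seed = 1L, n_segments = 2L, segment_time = 2,
                           equil_time = 2, n_waters = NULL) {
  spec <- confinement_spec(geometry, width)
  p <- sim_params(equil_time = equil_time, segment_time = segment_time,
                  n_segments = n_segments, seed = seed,
                  protonated = protonated, n_waters = n_waters)
  list(md = run_toy_md(build_cluster(spec, p), spec, p), spec = spec,
       params = p)
}

chain_protonated_md <- function()
  fixture("chain_prot", run_cluster_md("chain", protonated = TRUE, seed = 1L))

chain_neutral_md <- function()
  fixture("chain_neut", run_cluster_md("chain", protonated = FALSE, seed = 2L,
                                       equil_time = 1.5))

disc_protonated_md <- function()
  fixture("disc_prot", run_cluster_md("disc", protonated = TRUE, seed = 3L))

droplet_neutral_md <- function()
  fixture("droplet_neut", run_cluster_md("droplet", protonated = FALSE,
                                         seed = 5L, n_segments = 4L,
                                         segment_time = 1.5))

# ideal gas-phase water frame at the toy-model equilibrium geometry
ideal_water_frame <- function() {
  th <- 104.52 * pi / 180
  r0 <- 0.9572
  o <- c(0, 0, 0)
  h1 <- r0 * c(sin(th / 2), 0, cos(th / 2))
  h2 <- r0 * c(-sin(th / 2), 0, cos(th / 2))
  md_frame(c("O", "H", "H"), rbind(o, h1, h2))
}

# constant-geometry trajectory from one frame
static_trajectory <- function(frame, n = 3L, dt = 1) {
  md_trajectory(replicate(n, frame, simplify = FALSE), dt = dt)
}

# two-water + shared-proton construction with a prescribed H* offset from O1
# along the O1->O2 axis; used as an exact Zundel/Eigen oracle fixture
shared_proton_frame <- function(hstar_from_o1, o_sep = 2.5) {
  o1 <- c(0, 0, 0)
  o2 <- c(0, 0, o_sep)
  h_of <- function(o, sgn) rbind(o + c(0.76, sgn * 0.59, -0.2),
                                 o + c(-0.76, sgn * 0.59, -0.2))
  hs <- rbind(h_of(o1, 1), h_of(o2, -1))
  hstar <- c(0, 0, hstar_from_o1)
  md_frame(c("O", "O", rep("H", 5L)), rbind(o1, o2, hs, hstar))
}

# protonated chain ensemble: jittered copies of the built configuration
jittered_chain_frames <- function(n = 20L, sd = 0.03, seed = 7L) {
  fixture(sprintf("jitter_%d_%d", n, seed), {
    spec <- confinement_spec("chain")
    f0 <- build_cluster(spec, sim_params(protonated = TRUE, seed = seed))
    set.seed(seed)
    lapply(seq_len(n), function(i)
      md_frame(f0$elements,
               f0$xyz + matrix(rnorm(length(f0$xyz), sd = sd),
                               nrow(f0$xyz), 3L)))
  })
}

# brute-force H -> nearest-O coordination oracle (plain loops, independent of
# the vectorized implementation)
brute_coordination <- function(frame) {
  o <- which(frame$elements == "O")
  h <- which(frame$elements == "H")
  co <- integer(length(o))
  for (hi in h) {
    best <- 1L
    bd <- Inf
    for (k in seq_along(o)) {
      d <- sqrt(sum((frame$xyz[hi, ] - frame$xyz[o[k], ])^2))
      if (d < bd - 1e-12) { bd <- d; best <- k }
    }
    co[best] <- co[best] + 1L
  }
  co
}

expect_all_finite <- function(x) expect_true(all(is.finite(x)))
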