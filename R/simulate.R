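# Classical flexible-water cluster simulator: a desk-scale stand-in for
# ab initio MD that preserves the study protocol (harmonic confinement,
# NVT equilibration, NVE segments) so the spectral pipeline can be exercised
# end to end.

# toy force-field parameters (SPC/Fw-like): harmonic bonds/angle, fixed point
# charges, LJ on oxygen
.ff <- list(kb = 4431.53,        # kJ mol^-1 A^-2, E = kb/2 (r - r0)^2
            r0 = 0.9572,         # A
            ka = 412.6,          # kJ mol^-1 rad^-2 (bend near 1645 cm^-1)
            theta0 = 104.52 * pi / 180,
            qH = 0.41, qO = -0.82,   # e
            epsO = 0.650,        # kJ mol^-1
            sigO = 3.166)        # A

#' Harmonic confinement specification
#'
#' Quadratic wall potentials acting on the oxygen atoms that stabilize the
#' three cluster geometries: chains are confined radially
#' (U = K_xy (x^2+y^2)/2), discs axially plus a soft lateral term
#' (U = K_z z^2/2 + K_xy (x^2+y^2)/2), droplets isotropically
#' (U = K_r r^2/2).  Constants are in kJ mol^-1 nm^-2; the narrow and wide
#' chains use K_xy = 2000 and 20, the disc K_z = 2000 with K_xy = 30, the
#' droplet K_r = 40.
#'
#' @param geometry `"chain"`, `"disc"` or `"droplet"`.
#' @param width chain variant, `"narrow"` or `"wide"`.
#' @param K_xy,K_z,K_r override constants, kJ mol^-1 nm^-2 (>= 0).
#' @return an object of class `confinement_spec`.
#' @export
confinement_spec <- function(geometry = c("chain", "disc", "droplet"),
                             width = c("narrow", "wide"),
                             K_xy = NULL, K_z = NULL, K_r = NULL) {
  geometry <- match.arg(geometry)
  width <- match.arg(width)
  spec <- switch(geometry,
                 chain = list(K_xy = if (width == "narrow") 2000 else 20,
                              K_z = 0, K_r = 0),
                 disc = list(K_xy = 30, K_z = 2000, K_r = 0),
                 droplet = list(K_xy = 0, K_z = 0, K_r = 40))
  if (!is.null(K_xy)) spec$K_xy <- K_xy
  if (!is.null(K_z)) spec$K_z <- K_z
  if (!is.null(K_r)) spec$K_r <- K_r
  if (any(unlist(spec) < 0)) stop("confinement constants must be >= 0")
  label <- if (geometry == "chain") paste0("chain_", width) else geometry
  structure(c(list(geometry = geometry, label = label), spec),
            class = "confinement_spec")
}

#' Simulation parameters
#'
#' Defaults mirror the study protocol: T = 300 K, 15/15/26 waters for
#' chain/disc/droplet, 15 ps thermostatted equilibration, NVE segments of
#' 5 ps.
#'
#' @param T temperature, K.
#' @param dt integration time step, fs.
#' @param n_waters number of water molecules (default by geometry).
#' @param protonated add one excess proton.
#' @param equil_time thermostatted equilibration, ps.
#' @param segment_time NVE segment length, ps.
#' @param n_segments number of NVE segments.
#' @param seed root random seed (all substreams derive from it).
#' @param sample_every record every k-th integration step.
#' @param friction Langevin friction for equilibration, ps^-1.
#' @return an object of class `sim_params`.
#' @export
sim_params <- function(T = 300, dt = 0.5, n_waters = NULL, protonated = FALSE,
                       equil_time = 15, segment_time = 5, n_segments = 1L,
                       seed = 1L, sample_every = 2L, friction = 2) {
  if (T <= 0) stop("T must be > 0")
  if (dt <= 0) stop("dt must be > 0")
  if (!is.null(n_waters) && n_waters < 1L) stop("n_waters must be >= 1")
  structure(list(T = T, dt = dt, n_waters = n_waters, protonated = protonated,
                 equil_time = equil_time, segment_time = segment_time,
                 n_segments = as.integer(n_segments), seed = as.integer(seed),
                 sample_every = as.integer(sample_every), friction = friction),
            class = "sim_params")
}

default_n_waters <- function(geometry) if (geometry == "droplet") 26L else 15L

# unit vector at polar/azimuthal angles
unit_vec <- function(polar, azim)
  c(sin(polar) * cos(azim), sin(polar) * sin(azim), cos(polar))

# place two (or three) H around O with the equilibrium geometry; d1 is the
# unit direction of the first OH bond, azim the azimuth of the second around d1
water_hydrogens <- function(o, d1, azim) {
  ref <- if (abs(d1[3L]) < 0.9) c(0, 0, 1) else c(1, 0, 0)
  e1 <- ref - sum(ref * d1) * d1
  e1 <- e1 / sqrt(sum(e1^2))
  e2 <- c(d1[2L] * e1[3L] - d1[3L] * e1[2L],
          d1[3L] * e1[1L] - d1[1L] * e1[3L],
          d1[1L] * e1[2L] - d1[2L] * e1[1L])
  th <- .ff$theta0
  d2 <- cos(th) * d1 + sin(th) * (cos(azim) * e1 + sin(azim) * e2)
  rbind(o + .ff$r0 * d1, o + .ff$r0 * d2)
}

#' Build an initial cluster configuration
#'
#' Waters are placed on a hydrogen-bond-friendly template (chain: ~2.7 A O-O
#' spacing along z; disc: triangular lattice in the xy plane; droplet:
#' random close packing inside a sphere) with seeded random orientations.
#' With `protonated`, one extra H is placed 1.0 A from the central oxygen
#' (the chain center for chains, the oxygen nearest the centroid otherwise).
#'
#' @param spec a [confinement_spec].
#' @param params a [sim_params].
#' @return an [md_frame].
#' @export
build_cluster <- function(spec, params = sim_params()) {
  stopifnot(inherits(spec, "confinement_spec"))
  nw <- params$n_waters %||% default_n_waters(spec$geometry)
  if (nw < 2L) stop("need at least 2 waters")
  set.seed(substream_seed(params$seed, paste0("build_", spec$label)))
  o <- switch(spec$geometry,
    chain = cbind(0, 0, (seq_len(nw) - (nw + 1) / 2) * 2.7),
    disc = {
      a <- 2.8
      pts <- expand.grid(i = -6:6, j = -6:6)
      xy <- cbind(a * (pts$i + pts$j / 2), a * pts$j * sqrt(3) / 2)
      xy <- xy[order(rowSums(xy^2)), , drop = FALSE][seq_len(nw), ]
      cbind(xy, 0)
    },
    droplet = {
      R <- 5.2
      repeat {
        pos <- matrix(NA_real_, nw, 3L)
        k <- 0L
        for (try in seq_len(20000L)) {
          p <- stats::runif(3, -R, R)
          if (sum(p^2) > R^2) next
          if (k > 0L && min(rowSums((pos[seq_len(k), , drop = FALSE] -
                                       rep(p, each = k))^2)) < 2.6^2) next
          k <- k + 1L
          pos[k, ] <- p
          if (k == nw) break
        }
        if (k == nw) break
        R <- R * 1.1
      }
      sweep(pos, 2L, colMeans(pos))
    })
  xyz <- NULL
  elements <- character(0)
  for (i in seq_len(nw)) {
    d1 <- switch(spec$geometry,
      chain = c(0, 0, 1),                       # donor along the chain axis
      disc = unit_vec(pi / 2, stats::runif(1, 0, 2 * pi)),  # donor in plane
      droplet = unit_vec(acos(stats::runif(1, -1, 1)),
                         stats::runif(1, 0, 2 * pi)))
    hs <- water_hydrogens(o[i, ], d1, stats::runif(1, 0, 2 * pi))
    xyz <- rbind(xyz, o[i, ], hs)
    elements <- c(elements, "O", "H", "H")
  }
  if (isTRUE(params$protonated)) {
    centre <- if (spec$geometry == "chain") {
      ord <- order(o[, 3L])
      ord[ceiling(nw / 2)]
    } else which.min(rowSums(sweep(o, 2L, colMeans(o))^2))
    d <- unit_vec(acos(stats::runif(1, -1, 1)), stats::runif(1, 0, 2 * pi))
    xyz <- rbind(xyz, o[centre, ] + 1.0 * d)
    elements <- c(elements, "H")
  }
  rownames(xyz) <- NULL
  md_frame(elements, xyz)
}

#' Confinement energy and forces of a frame
#'
#' Sum of the geometry's quadratic wall terms over the oxygen atoms only
#' (hydrogens are dragged along through their bonds).
#'
#' @param frame an [md_frame].
#' @param spec a [confinement_spec].
#' @return list with `energy` (kJ/mol) and `forces` (kJ/mol/A, full n x 3
#'   matrix, zero rows for non-oxygen atoms).
#' @export
confinement_energy <- function(frame, spec) {
  stopifnot(inherits(frame, "md_frame"), inherits(spec, "confinement_spec"))
  o <- which(frame$elements == "O")
  x <- frame$xyz
  # constants are per nm^2; coordinates are A: K/100 is per A^2
  kxy <- spec$K_xy / 100; kz <- spec$K_z / 100; kr <- spec$K_r / 100
  f <- matrix(0, nrow(x), 3L)
  E <- 0
  if (kxy > 0) {
    E <- E + kxy / 2 * sum(x[o, 1L]^2 + x[o, 2L]^2)
    f[o, 1L] <- f[o, 1L] - kxy * x[o, 1L]
    f[o, 2L] <- f[o, 2L] - kxy * x[o, 2L]
  }
  if (kz > 0) {
    E <- E + kz / 2 * sum(x[o, 3L]^2)
    f[o, 3L] <- f[o, 3L] - kz * x[o, 3L]
  }
  if (kr > 0) {
    E <- E + kr / 2 * sum(x[o, ]^2)
    f[o, ] <- f[o, ] - kr * x[o, ]
  }
  list(energy = E, forces = f)
}

# Build the bonded/nonbonded interaction lists from an initial frame; the
# molecular topology is fixed for the whole run (the hop emulator, not the
# force field, represents Grotthuss chemistry).
build_topology <- function(frame) {
  asg <- assign_molecules(frame)
  n <- length(frame$elements)
  o <- asg$o_atoms
  mol <- integer(n)
  mol[o] <- seq_along(o)
  mol[asg$h_atoms] <- asg$h_parent
  q <- numeric(n)
  q[frame$elements == "H"] <- .ff$qH
  q[o] <- .ff$qO
  hyd <- which(asg$coordination == 3L)
  if (length(hyd)) q[o[hyd]] <- 1 - 3 * .ff$qH   # hydronium O: net molecule +1
  bonds <- cbind(i = o[asg$h_parent], j = asg$h_atoms)
  ang <- NULL
  for (m in seq_along(o)) {
    hs <- asg$h_atoms[asg$h_parent == m]
    if (length(hs) >= 2L) {
      cmb <- utils::combn(hs, 2L)
      ang <- rbind(ang, cbind(i = cmb[1L, ], j = o[m], k = cmb[2L, ]))
    }
  }
  pr <- utils::combn(n, 2L)
  keep <- mol[pr[1L, ]] != mol[pr[2L, ]]
  ii <- pr[1L, keep]; jj <- pr[2L, keep]
  list(n = n, masses = .atomic_masses[frame$elements], charges = q,
       bonds = bonds, angles = ang, nb_i = ii, nb_j = jj,
       nb_qq = q[ii] * q[jj],
       nb_lj = frame$elements[ii] == "O" & frame$elements[jj] == "O",
       o_atoms = o)
}

# total potential energy (kJ/mol) and forces (kJ/mol/A)
eval_forces <- function(x, top, spec) {
  n <- top$n
  # bonds
  bi <- top$bonds[, 1L]; bj <- top$bonds[, 2L]
  dxb <- x[bi, , drop = FALSE] - x[bj, , drop = FALSE]
  rb <- sqrt(rowSums(dxb^2))
  dr <- rb - .ff$r0
  Eb <- .ff$kb / 2 * sum(dr^2)
  fb <- dxb * (-.ff$kb * dr / rb)
  # angles
  ai <- top$angles[, 1L]; aj <- top$angles[, 2L]; ak <- top$angles[, 3L]
  u <- x[ai, , drop = FALSE] - x[aj, , drop = FALSE]
  w <- x[ak, , drop = FALSE] - x[aj, , drop = FALSE]
  ru <- sqrt(rowSums(u^2)); rw <- sqrt(rowSums(w^2))
  cth <- pmin(1, pmax(-1, rowSums(u * w) / (ru * rw)))
  th <- acos(cth)
  sth <- pmax(sqrt(1 - cth^2), 1e-8)
  dth <- th - .ff$theta0
  Ea <- .ff$ka / 2 * sum(dth^2)
  uh <- u / ru; wh <- w / rw
  dthd_i <- (uh * cth - wh) / (ru * sth)
  dthd_k <- (wh * cth - uh) / (rw * sth)
  fa_i <- -.ff$ka * dth * dthd_i
  fa_k <- -.ff$ka * dth * dthd_k
  # nonbonded (all intermolecular pairs; LJ on O-O)
  ii <- top$nb_i; jj <- top$nb_j
  dx <- x[ii, , drop = FALSE] - x[jj, , drop = FALSE]
  r2 <- rowSums(dx^2)
  invr2 <- 1 / r2
  invr <- sqrt(invr2)
  Ec <- .ke_coulomb * top$nb_qq * invr
  fscal <- .ke_coulomb * top$nb_qq * invr * invr2
  Elj <- 0
  if (any(top$nb_lj)) {
    s2 <- (.ff$sigO^2) * invr2[top$nb_lj]
    s6 <- s2^3
    s12 <- s6^2
    Elj <- 4 * .ff$epsO * sum(s12 - s6)
    fscal[top$nb_lj] <- fscal[top$nb_lj] +
      24 * .ff$epsO * (2 * s12 - s6) * invr2[top$nb_lj]
  }
  fnb <- dx * fscal
  # scatter-add all pair contributions
  grp <- c(bi, bj, ai, aj, ak, ii, jj)
  contrib <- rbind(fb, -fb, fa_i, -(fa_i + fa_k), fa_k, fnb, -fnb)
  f <- matrix(0, n, 3L)
  acc <- rowsum(contrib, grp)
  f[as.integer(rownames(acc)), ] <- acc
  # confinement on O
  kxy <- spec$K_xy / 100; kz <- spec$K_z / 100; kr <- spec$K_r / 100
  o <- top$o_atoms
  Ew <- 0
  if (kxy > 0) {
    Ew <- Ew + kxy / 2 * sum(x[o, 1L]^2 + x[o, 2L]^2)
    f[o, 1:2] <- f[o, 1:2] - kxy * x[o, 1:2]
  }
  if (kz > 0) {
    Ew <- Ew + kz / 2 * sum(x[o, 3L]^2)
    f[o, 3L] <- f[o, 3L] - kz * x[o, 3L]
  }
  if (kr > 0) {
    Ew <- Ew + kr / 2 * sum(x[o, ]^2)
    f[o, ] <- f[o, ] - kr * x[o, ]
  }
  list(E = Eb + Ea + sum(Ec) + Elj + Ew, F = f)
}

kinetic_energy <- function(v, m) 0.5 * sum(m * rowSums(v^2)) * .md_energy

kinetic_temperature <- function(v, m)
  2 * kinetic_energy(v, m) / (3 * length(m) * .kB)

#' Run the classical cluster simulation (NVT equilibration + NVE segments)
#'
#' Integrates the flexible-water toy model under harmonic confinement:
#' a BAOAB Langevin thermostat generates the T = 300 K ensemble, then
#' microcanonical (velocity-Verlet) segments are launched from decorrelated
#' snapshots; only the NVE segments are recorded and used for spectra.
#'
#' @param frame initial [md_frame] (see [build_cluster]).
#' @param spec a [confinement_spec].
#' @param params a [sim_params].
#' @return an object of class `toy_md`: list with `segments` (list of
#'   [md_trajectory], each carrying an `energy` series in kJ/mol),
#'   `nvt_temperature` (instantaneous kinetic temperature during
#'   equilibration, K), `topology`, `spec`, `params`.
#' @export
run_toy_md <- function(frame, spec, params = sim_params()) {
  stopifnot(inherits(frame, "md_frame"), inherits(spec, "confinement_spec"))
  top <- build_topology(frame)
  dt <- params$dt
  m <- top$masses
  set.seed(substream_seed(params$seed, paste0("md_", spec$label,
                                              if (isTRUE(params$protonated)) "_p" else "")))
  x <- frame$xyz
  v <- matrix(stats::rnorm(3 * top$n), top$n, 3L) *
    sqrt(.kB * params$T / (m * .md_energy))
  gam <- params$friction / 1000            # fs^-1
  c1 <- exp(-gam * dt)
  c2 <- sqrt((1 - c1^2) * .kB * params$T / .md_energy)
  fe <- eval_forces(x, top, spec)
  a <- fe$F / (m * .md_energy)
  check_stable <- function(v) {
    if (max(abs(v)) > 1)
      stop("integrator instability (|v| > 1 A/fs): reduce dt")
  }
  langevin_steps <- function(nsteps, record_T = FALSE) {
    Ts <- if (record_T) numeric(nsteps) else NULL
    for (s in seq_len(nsteps)) {
      v <- v + 0.5 * dt * a                     # B
      x <- x + 0.5 * dt * v                     # A
      v <- c1 * v + c2 / sqrt(m) * matrix(stats::rnorm(3 * top$n), top$n, 3L)  # O
      x <- x + 0.5 * dt * v                     # A
      fe <- eval_forces(x, top, spec)
      a <- fe$F / (m * .md_energy)
      v <- v + 0.5 * dt * a                     # B
      if (record_T) Ts[s] <- kinetic_temperature(v, m)
    }
    check_stable(v)
    x <<- x; v <<- v; a <<- a
    Ts
  }
  n_equil <- round(params$equil_time * 1000 / dt)
  nvt_T <- langevin_steps(n_equil, record_T = TRUE)
  segments <- vector("list", params$n_segments)
  n_seg <- round(params$segment_time * 1000 / dt)
  n_decor <- round(0.5 * 1000 / dt)        # 0.5 ps NVT between segments
  for (seg in seq_len(params$n_segments)) {
    if (seg > 1L) nvt_T <- c(nvt_T, langevin_steps(n_decor, record_T = TRUE))
    nrec <- n_seg %/% params$sample_every
    rec_x <- array(NA_real_, c(top$n, 3L, nrec))
    rec_E <- numeric(nrec)
    r <- 0L
    for (s in seq_len(n_seg)) {
      x <- x + v * dt + 0.5 * a * dt^2
      fe <- eval_forces(x, top, spec)
      a_new <- fe$F / (m * .md_energy)
      v <- v + 0.5 * (a + a_new) * dt
      a <- a_new
      if (s %% params$sample_every == 0L) {
        r <- r + 1L
        rec_x[, , r] <- x
        rec_E[r] <- fe$E + kinetic_energy(v, m)
      }
    }
    check_stable(v)
    frames <- lapply(seq_len(nrec), function(k)
      md_frame(frame$elements, rec_x[, , k],
               time = (k - 1) * dt * params$sample_every))
    tr <- md_trajectory(frames, dt = dt * params$sample_every,
                        segment_id = sprintf("%s_seg%02d", spec$label, seg),
                        geometry = spec$label,
                        protonated = isTRUE(params$protonated))
    tr$energy <- rec_E
    segments[[seg]] <- tr
  }
  structure(list(segments = segments, nvt_temperature = nvt_T,
                 topology = top, spec = spec, params = params),
            class = "toy_md")
}

#' @export
print.toy_md <- function(x, ...) {
  cat("toy_md:", x$spec$label,
      if (isTRUE(x$params$protonated)) "protonated," else "neutral,",
      length(x$segments), "NVE segment(s) of",
      x$params$segment_time, "ps\n")
  cat(sprintf("  mean NVT temperature: %.1f K (target %g K)\n",
              mean(x$nvt_temperature), x$params$T))
  invisible(x)
}

#' Normal-mode wavenumbers of the isolated toy-model water
#'
#' Numeric mass-weighted Hessian of the intramolecular part of the force
#' field at the equilibrium geometry; the three non-zero modes are the bend
#' and the symmetric/asymmetric stretches of the model (not of real water).
#'
#' @return sorted vector of the three vibrational wavenumbers, cm^-1.
#' @export
water_normal_modes <- function() {
  o <- c(0, 0, 0)
  h <- water_hydrogens(o, c(0, 0, 1), 0)
  x0 <- rbind(o, h)
  en <- function(xv) {
    x <- matrix(xv, 3L, 3L)
    d1 <- x[2L, ] - x[1L, ]; d2 <- x[3L, ] - x[1L, ]
    r1 <- sqrt(sum(d1^2)); r2 <- sqrt(sum(d2^2))
    th <- acos(sum(d1 * d2) / (r1 * r2))
    .ff$kb / 2 * ((r1 - .ff$r0)^2 + (r2 - .ff$r0)^2) +
      .ff$ka / 2 * (th - .ff$theta0)^2
  }
  xv <- as.numeric(x0)
  hstep <- 1e-4
  H <- matrix(0, 9L, 9L)
  for (i in 1:9) for (j in 1:9) {
    e <- function(si, sj) {
      z <- xv; z[i] <- z[i] + si * hstep; z[j] <- z[j] + sj * hstep; en(z)
    }
    H[i, j] <- (e(1, 1) - e(1, -1) - e(-1, 1) + e(-1, -1)) / (4 * hstep^2)
  }
  mass <- rep(.atomic_masses[c("O", "H", "H")], 3L)  # column-major: per coord
  Hm <- H / sqrt(outer(mass, mass)) / .md_energy
  ev <- eigen(Hm, symmetric = TRUE, only.values = TRUE)$values
  om <- sqrt(pmax(ev, 0))
  nu <- om / (2 * pi) / .c_cmfs
  sort(nu[nu > 100])
}

#' Proton-hop dipole emulator specification
#'
#' @param hop_rate Poisson hop rate of the defect, ps^-1.
#' @param transit_range min/max transit time of one hop, fs.
#' @param policy hop/projection axis policy: `"chain"` (hops along the
#'   z-ordered oxygen ladder; dipole projected onto z), `"disc"` (hops to
#'   in-plane neighbors; dipole projected onto xy), `"droplet"` (isotropic
#'   nearest-neighbor hops); `NULL` derives it from the trajectory geometry.
#' @param defect_charge charge riding the oxygen sites, e.
#' @return an object of class `hopper_spec`.
#' @export
hopper_spec <- function(hop_rate = 20, transit_range = c(5, 20), policy = NULL,
                        defect_charge = 1) {
  if (hop_rate < 0) stop("hop_rate must be >= 0")
  if (length(transit_range) != 2L || any(transit_range <= 0) ||
      transit_range[1L] > transit_range[2L])
    stop("transit_range must be a positive (min, max) pair in fs")
  structure(list(hop_rate = hop_rate, transit_range = transit_range,
                 policy = policy, defect_charge = defect_charge),
            class = "hopper_spec")
}

#' Stochastic proton-hop defect dipole
#'
#' Emulates the translational dipole of a delocalized excess-proton defect:
#' a +1 e charge occupies one oxygen site (sites are the trajectory's
#' time-averaged, centroid-referenced O positions) and performs
#' Poisson-timed hops to an adjacent site chosen by the axis policy, moving
#' linearly over a transit time drawn uniformly from `transit_range`.  The
#' per-policy projection (chain: z only; disc: xy only) guarantees that the
#' injected broadband power is polarized along the direction of maximal
#' cluster extension.  Hops beyond the chain ends are reflected.  The result
#' is meant to be added to a molecular dipole series ([add_dipole_series]).
#'
#' @param trajectory an `md_trajectory` (supplies the O sites and time grid).
#' @param hopper a [hopper_spec].
#' @param seed random seed (reproducible for a fixed seed).
#' @return a [dipole_series] labelled `"defect"`, e Angstrom.
#' @export
attach_proton_hopper <- function(trajectory, hopper = hopper_spec(), seed = 1L) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            inherits(hopper, "hopper_spec"))
  geom <- trajectory$geometry
  if (is.null(geom) || is.na(geom)) geom <- "droplet"
  policy <- hopper$policy %||%
    switch(sub("_.*", "", geom), chain = "chain", disc = "disc", "droplet")
  o <- which(trajectory$elements == "O")
  if (length(o) < 2L) stop("need at least two oxygen sites")
  nf <- n_frames(trajectory)
  # static site coordinates: time-mean O positions, centroid-referenced
  om <- apply(trajectory$xyz[o, , , drop = FALSE], c(1L, 2L), mean)
  om <- sweep(om, 2L, colMeans(om))
  sites <- switch(policy,
                  chain = cbind(0, 0, om[, 3L]),
                  disc = cbind(om[, 1:2], 0),
                  droplet = om)
  ns <- nrow(sites)
  set.seed(substream_seed(seed, "hopper"))
  zord <- order(sites[, 3L])
  rank_z <- match(seq_len(ns), zord)
  nbrs <- lapply(seq_len(ns), function(s) {
    d <- rowSums((sites - rep(sites[s, ], each = ns))^2)
    order(d)[2:min(4L, ns)]
  })
  start <- switch(policy,
                  chain = zord[ceiling(ns / 2)],
                  which.min(rowSums(sites^2)))
  t_end <- trajectory$times[nf]
  rate_fs <- hopper$hop_rate / 1000
  events <- list()
  s <- start
  t <- trajectory$times[1L]
  if (rate_fs > 0) repeat {
    t <- t + stats::rexp(1, rate_fs)
    if (t > t_end) break
    target <- if (policy == "chain") {
      rk <- rank_z[s]
      rk2 <- rk + sample(c(-1L, 1L), 1L)
      if (rk2 < 1L) rk2 <- 2L                 # reflective chain ends
      if (rk2 > ns) rk2 <- ns - 1L
      zord[rk2]
    } else sample(nbrs[[s]], 1L)
    dur <- stats::runif(1, hopper$transit_range[1L], hopper$transit_range[2L])
    events[[length(events) + 1L]] <- list(t0 = t, dur = dur, from = s, to = target)
    s <- target
    t <- t + dur
  }
  pos <- matrix(rep(sites[start, ], each = nf), nf, 3L)
  for (ev in events) {
    during <- trajectory$times >= ev$t0 & trajectory$times < ev$t0 + ev$dur
    after <- trajectory$times >= ev$t0 + ev$dur
    if (any(during)) {
      frac <- (trajectory$times[during] - ev$t0) / ev$dur
      pos[during, ] <- (1 - frac) %o% sites[ev$from, ] + frac %o% sites[ev$to, ]
    }
    if (any(after)) pos[after, ] <- rep(sites[ev$to, ], each = sum(after))
  }
  new_dipole_series(trajectory$times, hopper$defect_charge * pos,
                    label = "defect", dt = trajectory$dt)
}

#' Sum two dipole series on the same time grid
#' @param a,b [dipole_series] objects.
#' @return a `dipole_series` with combined label.
#' @export
add_dipole_series <- function(a, b) {
  stopifnot(inherits(a, "dipole_series"), inherits(b, "dipole_series"))
  if (nrow(a$mu) != nrow(b$mu) || any(abs(a$times - b$times) > 1e-8))
    stop("dipole series are not on the same time grid")
  new_dipole_series(a$times, a$mu + b$mu,
                    label = paste(a$label, b$label, sep = "+"), dt = a$dt)
}

#' Synthesize Wannier centers for a frame
#'
#' Places four electron-pair centers per water: two bond centers 0.5 A from
#' O along each O-H bond and two lone-pair centers 0.3 A from O along the
#' +/- normal of the HOH plane; a hydronium gets three bond centers and one
#' lone-pair center along the negative H-pyramid direction.  Optional
#' Gaussian jitter emulates electronic fluctuation.  Per-molecule
#' `wannier_full` charge is zero for water and +1 for the hydronium.
#'
#' @param frame an [md_frame].
#' @param jitter_sd Gaussian jitter standard deviation, A.
#' @param seed random seed for the jitter.
#' @return the frame with `wannier` populated (centers grouped per O, in O
#'   index order).
#' @export
synthesize_wannier <- function(frame, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(frame, "md_frame"))
  asg <- assign_molecules(frame)
  set.seed(substream_seed(seed, "wannier"))
  w <- NULL
  for (m in seq_along(asg$o_atoms)) {
    oi <- asg$o_atoms[m]
    op <- frame$xyz[oi, ]
    hs <- asg$h_atoms[asg$h_parent == m]
    uh <- lapply(hs, function(h) {
      d <- frame$xyz[h, ] - op
      d / sqrt(sum(d^2))
    })
    bond <- do.call(rbind, lapply(uh, function(u) op + 0.5 * u))
    lone <- if (length(uh) == 2L) {
      nrm <- c(uh[[1L]][2L] * uh[[2L]][3L] - uh[[1L]][3L] * uh[[2L]][2L],
               uh[[1L]][3L] * uh[[2L]][1L] - uh[[1L]][1L] * uh[[2L]][3L],
               uh[[1L]][1L] * uh[[2L]][2L] - uh[[1L]][2L] * uh[[2L]][1L])
      nrm <- nrm / sqrt(sum(nrm^2))
      rbind(op + 0.3 * nrm, op - 0.3 * nrm)
    } else {
      pyr <- -Reduce(`+`, uh)
      pyr <- pyr / sqrt(sum(pyr^2))
      matrix(op + 0.3 * pyr, 1L, 3L)
    }
    w <- rbind(w, bond, lone)
  }
  if (jitter_sd > 0)
    w <- w + matrix(stats::rnorm(length(w), sd = jitter_sd), nrow(w), 3L)
  rownames(w) <- NULL
  md_frame(frame$elements, frame$xyz, wannier = w, time = frame$time)
}

#' Synthesize Wannier centers for every frame of a trajectory
#'
#' @param trajectory an `md_trajectory`.
#' @param jitter_sd Gaussian jitter standard deviation, A.
#' @param seed random seed.
#' @return the trajectory with `wannier` populated.
#' @export
synthesize_wannier_trajectory <- function(trajectory, jitter_sd = 0, seed = 1L) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  frames <- lapply(seq_len(n_frames(trajectory)), function(i)
    synthesize_wannier(get_frame(trajectory, i), jitter_sd = jitter_sd,
                       seed = substream_seed(seed, paste0("wframe", i))))
  tr <- md_trajectory(frames, dt = trajectory$dt,
                      segment_id = trajectory$segment_id,
                      geometry = trajectory$geometry,
                      protonated = trajectory$protonated)
  tr$energy <- trajectory$energy
  tr
}

#' Analytic oscillator dipole fixture
#'
#' Builds a dipole series from sharp cosine modes plus an optional
#' Ornstein-Uhlenbeck component, together with its analytic reference
#' spectrum, for validating the spectral estimator.  The OU component is
#' injected into the dipole *derivative* (the dipole is its cumulative sum),
#' so the reference power spectral density of the derivative is the exact
#' Lorentzian `4 sd^2 tau / (1 + (2 pi f tau)^2)`.
#'
#' @param modes data frame (or NULL) with columns `nu` (cm^-1), `amplitude`
#'   (e A), `axis` ("x", "y", "z"), `phase` (rad).
#' @param ou_noise optional list `list(sd=, tau=, axis=)`: OU standard
#'   deviation (e A / fs), correlation time (fs), and axis.
#' @param N number of samples (>= 16).
#' @param dt sampling interval, fs.
#' @param seed random seed.
#' @return list with `series` (a [dipole_series]) and `reference`
#'   (`lines`: the mode table; `ou_psd`: function nu -> analytic one-sided
#'   PSD of the derivative, per cm^-1, or NULL).
#' @export
generate_oscillator_dipole <- function(modes = NULL, ou_noise = NULL,
                                       N = 4096L, dt = 0.5, seed = 1L) {
  if (N < 16L) stop("N must be >= 16")
  axis_idx <- c(x = 1L, y = 2L, z = 3L)
  t <- (seq_len(N) - 1L) * dt
  mu <- matrix(0, N, 3L)
  if (!is.null(modes) && nrow(modes) > 0L) {
    for (k in seq_len(nrow(modes))) {
      f <- wavenumber_to_freq(modes$nu[k])
      ph <- if ("phase" %in% names(modes)) modes$phase[k] else 0
      mu[, axis_idx[[modes$axis[k]]]] <- mu[, axis_idx[[modes$axis[k]]]] +
        modes$amplitude[k] * cos(2 * pi * f * t + ph)
    }
  }
  ou_psd <- NULL
  if (!is.null(ou_noise)) {
    set.seed(substream_seed(seed, "ou"))
    sd <- ou_noise$sd; tau <- ou_noise$tau
    ax <- axis_idx[[ou_noise$axis %||% "z"]]
    rho <- exp(-dt / tau)
    x <- numeric(N)
    innov <- stats::rnorm(N, sd = sd * sqrt(1 - rho^2))
    x[1L] <- stats::rnorm(1, sd = sd)
    for (i in 2:N) x[i] <- rho * x[i - 1L] + innov[i]
    mu[, ax] <- mu[, ax] + dt * cumsum(x)
    ou_psd <- function(nu) {
      f <- wavenumber_to_freq(nu)
      4 * sd^2 * tau / (1 + (2 * pi * f * tau)^2) * .c_cmfs
    }
  }
  list(series = new_dipole_series(t, mu, label = "oscillator", dt = dt),
       reference = list(lines = modes, ou_psd = ou_psd))
}
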