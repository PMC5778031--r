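#' Charge model for dipole assembly
#'
#' Two conventions are supported.  `nuclear_effective` builds the dipole from
#' nuclei alone with effective charges q_H = -q_O/2 = +1 e, which
#' overestimates the water molecular dipole but gives one excess proton
#' exactly its +1 e charge.  `wannier_full` uses valence core charges (O +6,
#' H +1) plus -2 e on each maximally localized Wannier center (four electron
#' pairs per water), capturing electronic polarization.
#'
#' @param mode `"nuclear_effective"` or `"wannier_full"`.
#' @return an object of class `charge_model` with a `charges` map (e).
#' @export
charge_model <- function(mode = c("nuclear_effective", "wannier_full")) {
  mode <- match.arg(mode)
  charges <- switch(mode,
                    nuclear_effective = c(O = -2, H = 1),
                    wannier_full = c(O = 6, H = 1, X = -2))
  structure(list(mode = mode, charges = charges), class = "charge_model")
}

#' @export
print.charge_model <- function(x, ...) {
  cat("charge_model:", x$mode, "-",
      paste(sprintf("q_%s = %+g e", names(x$charges), x$charges),
            collapse = ", "), "\n")
  invisible(x)
}

# squared-distance matrix between two coordinate sets (rows)
dist2_matrix <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), `+`) - 2 * a %*% t(b)
  d2[d2 < 0] <- 0
  d2
}

# nearest column index per row, with ties (within tol) broken toward the
# lower index
nearest_with_tiebreak <- function(d2, tol = 1e-9) {
  apply(d2, 1L, function(r) which(r <= min(r) + tol)[1L])
}

#' Assign hydrogens and Wannier centers to their parent oxygens
#'
#' Purely geometric per-frame assignment (no bond-topology memory): each H
#' goes to its nearest O, ties broken toward the lower atom index; each
#' Wannier center goes to its nearest O if within `wc_cutoff`, otherwise it
#' is left unassigned and flagged.  Geometric re-assignment every frame is
#' the standard defect tracker under Grotthuss topology changes.
#'
#' @param frame an [md_frame].
#' @param wc_cutoff Wannier-center assignment cutoff from the parent O,
#'   Angstrom (bond and lone-pair centers in water lie within ~0.5 A).
#' @return an object of class `molecule_assignment` with fields `o_atoms`,
#'   `h_atoms` (atom indices), `h_parent` (per-H index into `o_atoms`),
#'   `wc_parent` (per-center index into `o_atoms`, NA when unassigned),
#'   `coordination` (per-O assigned-H count), `unassigned_wc` (count).
#' @export
assign_molecules <- function(frame, wc_cutoff = 1.0) {
  stopifnot(inherits(frame, "md_frame"))
  o_atoms <- which(frame$elements == "O")
  h_atoms <- which(frame$elements == "H")
  if (!length(o_atoms)) stop("frame contains no oxygen atoms")
  if (!length(h_atoms)) stop("frame contains no hydrogen atoms")
  d2 <- dist2_matrix(frame$xyz[h_atoms, , drop = FALSE],
                     frame$xyz[o_atoms, , drop = FALSE])
  h_parent <- nearest_with_tiebreak(d2)
  coordination <- tabulate(h_parent, nbins = length(o_atoms))
  wc_parent <- NULL
  unassigned <- 0L
  if (!is.null(frame$wannier)) {
    d2w <- dist2_matrix(frame$wannier, frame$xyz[o_atoms, , drop = FALSE])
    wc_parent <- nearest_with_tiebreak(d2w)
    far <- d2w[cbind(seq_len(nrow(d2w)), wc_parent)] > wc_cutoff^2
    if (any(far)) {
      unassigned <- sum(far)
      wc_parent[far] <- NA_integer_
      warning(unassigned, " Wannier center(s) farther than ", wc_cutoff,
              " A from every O left unassigned")
    }
  }
  structure(list(o_atoms = o_atoms, h_atoms = h_atoms, h_parent = h_parent,
                 wc_parent = wc_parent, coordination = coordination,
                 unassigned_wc = unassigned),
            class = "molecule_assignment")
}

#' Locate the excess-proton defect
#'
#' The hydronium oxygen is the unique O with three assigned hydrogens.
#'
#' @param assignment a [molecule_assignment].
#' @return the hydronium O atom index, or `NULL` when every O has two H.
#' @export
find_excess_proton <- function(assignment) {
  stopifnot(inherits(assignment, "molecule_assignment"))
  co <- assignment$coordination
  if (any(co >= 4L))
    stop("defect multiplicity error: oxygen with coordination >= 4 ",
         "(unphysical frame or wrong protonation flag)")
  three <- which(co == 3L)
  if (length(three) > 1L)
    stop("defect multiplicity error: ", length(three),
         " oxygens with coordination 3")
  if (length(three) == 0L) return(NULL)
  assignment$o_atoms[three]
}

#' Classify the excess-proton solvation state (Zundel vs Eigen-like)
#'
#' Among the three hydronium hydrogens, the shared proton H* is the one with
#' the smallest distance asymmetry delta = |d(O1-H*) - d(O2-H*)|, where O1 is
#' the hydronium oxygen and O2 the nearest other oxygen to that hydrogen.
#' The state is Zundel when delta < `delta_threshold`.
#'
#' @param frame an [md_frame] with exactly one excess proton.
#' @param assignment a [molecule_assignment] for the same frame.
#' @param delta_threshold Zundel/Eigen discriminator on delta, Angstrom.
#' @return an object of class `zundel_state`: `hydronium_O`, `shared_H`,
#'   `partner_O` (atom indices), `delta` (A), `is_zundel`.
#' @export
classify_zundel <- function(frame, assignment, delta_threshold = 0.25) {
  hyd <- find_excess_proton(assignment)
  if (is.null(hyd)) stop("no excess proton in frame: cannot classify")
  o_atoms <- assignment$o_atoms
  if (length(o_atoms) < 2L) stop("need at least two oxygens")
  hyd_local <- match(hyd, o_atoms)
  hs <- assignment$h_atoms[assignment$h_parent == hyd_local]
  other_o <- o_atoms[o_atoms != hyd]
  best <- NULL
  for (h in hs) {
    dh <- sqrt(colSums((t(frame$xyz[other_o, , drop = FALSE]) -
                          frame$xyz[h, ])^2))
    j <- which(dh <= min(dh) + 1e-9)[1L]
    d1 <- sqrt(sum((frame$xyz[hyd, ] - frame$xyz[h, ])^2))
    delta <- unname(abs(d1 - dh[j]))
    if (is.null(best) || delta < best$delta)
      best <- list(shared_H = h, partner_O = other_o[j], delta = delta)
  }
  structure(list(hydronium_O = hyd, shared_H = best$shared_H,
                 partner_O = best$partner_O, delta = best$delta,
                 is_zundel = best$delta < delta_threshold),
            class = "zundel_state")
}

#' Per-frame excess-proton / Zundel records
#'
#' @param trajectory a protonated `md_trajectory`.
#' @param delta_threshold Zundel discriminator, Angstrom.
#' @return data frame with columns `frame`, `time_fs`, `hydronium_index`,
#'   `shared_H_index`, `partner_O_index`, `delta_A`, `is_zundel` (one row per
#'   frame), suitable for CSV export.
#' @export
zundel_records <- function(trajectory, delta_threshold = 0.25) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  nf <- n_frames(trajectory)
  rows <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(trajectory, i)
    z <- classify_zundel(fr, assign_molecules(fr), delta_threshold)
    rows[[i]] <- data.frame(frame = i, time_fs = trajectory$times[i],
                            hydronium_index = z$hydronium_O,
                            shared_H_index = z$shared_H,
                            partner_O_index = z$partner_O,
                            delta_A = z$delta, is_zundel = z$is_zundel)
  }
  do.call(rbind, rows)
}

#' Zundel occupation probability
#'
#' Fraction of trajectory frames whose excess proton is in the Zundel state.
#'
#' @inheritParams zundel_records
#' @return probability in [0, 1].
#' @export
zundel_occupation <- function(trajectory, delta_threshold = 0.25) {
  mean(zundel_records(trajectory, delta_threshold)$is_zundel)
}

#' Per-frame site selection for the Zundel complex O2H5+
#'
#' Selects, for every frame, the hydronium oxygen, its partner oxygen, the
#' five hydrogens assigned to the two, and (when centers are present) the
#' Wannier centers assigned to the two oxygens.
#'
#' @param trajectory a protonated `md_trajectory`.
#' @param delta_threshold Zundel discriminator, Angstrom (recorded only).
#' @return list (one element per frame) of lists with `atoms` and `wannier`
#'   index vectors, usable as the `subset` argument of [dipole_series].
#' @export
zundel_subset <- function(trajectory, delta_threshold = 0.25) {
  stopifnot(inherits(trajectory, "md_trajectory"))
  nf <- n_frames(trajectory)
  out <- vector("list", nf)
  for (i in seq_len(nf)) {
    fr <- get_frame(trajectory, i)
    asg <- assign_molecules(fr)
    z <- classify_zundel(fr, asg, delta_threshold)
    two_o <- c(z$hydronium_O, z$partner_O)
    loc <- match(two_o, asg$o_atoms)
    hs <- asg$h_atoms[asg$h_parent %in% loc]
    wsel <- integer(0)
    if (!is.null(asg$wc_parent))
      wsel <- which(asg$wc_parent %in% loc)
    out[[i]] <- list(atoms = sort(c(two_o, hs)), wannier = wsel)
  }
  out
}

#' Construct a dipole time series
#'
#' @param times sample times, fs (uniform grid).
#' @param mu numeric matrix, one row per time, columns x/y/z, e Angstrom.
#' @param label provenance: `"full"` (nuclei + Wannier centers),
#'   `"nuclear"` (effective charges), `"subgroup"` (Zundel projection) or a
#'   free label for synthetic fixtures.
#' @param dt sampling interval, fs; defaults to the time spacing.
#' @return an object of class `dipole_series`.
#' @export
new_dipole_series <- function(times, mu, label = "full",
                              dt = if (length(times) > 1L) times[2L] - times[1L] else 1) {
  mu <- as.matrix(mu)
  if (ncol(mu) != 3L) stop("mu must have 3 columns")
  if (nrow(mu) != length(times)) stop("times and mu lengths differ")
  if (!all(is.finite(mu))) stop("non-finite dipole values")
  structure(list(times = as.numeric(times), mu = mu, label = label,
                 dt = dt, derivative = FALSE),
            class = "dipole_series")
}

#' @export
print.dipole_series <- function(x, ...) {
  cat("dipole_series [", x$label, "]: ", nrow(x$mu), " samples, dt = ",
      x$dt, " fs", if (isTRUE(x$derivative)) " (derivative)", "\n", sep = "")
  invisible(x)
}

#' @export
plot.dipole_series <- function(x, ...) {
  graphics::matplot(x$times / 1000, x$mu, type = "l", lty = 1,
                    xlab = "t (ps)",
                    ylab = if (isTRUE(x$derivative))
                      "dmu/dt (e A / fs)" else "mu (e A)", ...)
  graphics::legend("topright", c("x", "y", "z"), lty = 1, col = 1:3, bty = "n")
  invisible(x)
}

#' Dipole time series of a trajectory
#'
#' Computes mu(t) = sum_i q_i r_i(t) over the selected sites under the given
#' charge model.  For selections with non-zero total charge the instantaneous
#' geometric center of the selected sites is used as origin, making the
#' dipole translation-independent; neutral selections are origin-independent
#' by construction.
#'
#' @param trajectory an `md_trajectory` (with Wannier centers when
#'   `model$mode == "wannier_full"`).
#' @param model a [charge_model].
#' @param subset optional per-frame site selection (list of
#'   `list(atoms=, wannier=)` as returned by [zundel_subset]); `NULL` selects
#'   all sites.
#' @param label series label; defaults to `"subgroup"` when a subset is
#'   given, otherwise to the model-appropriate label.
#' @return a [dipole_series] in e Angstrom.
#' @export
dipole_series <- function(trajectory, model = charge_model(), subset = NULL,
                          label = NULL) {
  stopifnot(inherits(trajectory, "md_trajectory"),
            inherits(model, "charge_model"))
  full <- model$mode == "wannier_full"
  if (full && is.null(trajectory$wannier))
    stop("wannier_full charge model requires Wannier centers on every frame")
  nf <- n_frames(trajectory)
  if (!is.null(subset)) {
    if (length(subset) != nf)
      stop("subset must supply one selection per frame")
    if (any(vapply(subset, function(s) length(s$atoms) == 0L, logical(1))))
      stop("empty atom selection in subset")
  }
  qa <- model$charges[trajectory$elements]
  if (anyNA(qa)) stop("charge model lacks charges for some elements")
  mu <- matrix(0, nf, 3L)
  for (i in seq_len(nf)) {
    if (is.null(subset)) {
      r <- trajectory$xyz[, , i]
      q <- qa
      if (full) {
        r <- rbind(r, trajectory$wannier[, , i])
        q <- c(qa, rep(model$charges[["X"]], dim(trajectory$wannier)[1L]))
      }
    } else {
      sel <- subset[[i]]
      r <- trajectory$xyz[, , i][sel$atoms, , drop = FALSE]
      q <- qa[sel$atoms]
      if (full) {
        r <- rbind(r, trajectory$wannier[, , i][sel$wannier, , drop = FALSE])
        q <- c(q, rep(model$charges[["X"]], length(sel$wannier)))
      }
    }
    m <- colSums(r * q)
    Q <- sum(q)
    if (abs(Q) > 1e-9) m <- m - Q * colMeans(r)
    mu[i, ] <- m
  }
  if (is.null(label))
    label <- if (!is.null(subset)) "subgroup" else
      if (full) "full" else "nuclear"
  new_dipole_series(trajectory$times, mu, label = label, dt = trajectory$dt)
}

#' Total charge of a frame under a charge model
#'
#' @param frame an [md_frame].
#' @param model a [charge_model].
#' @return total charge in e (Wannier centers included in `wannier_full`).
#' @export
total_charge <- function(frame, model = charge_model()) {
  q <- sum(model$charges[frame$elements])
  if (model$mode == "wannier_full" && !is.null(frame$wannier))
    q <- q + model$charges[["X"]] * nrow(frame$wannier)
  unname(q)
}
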