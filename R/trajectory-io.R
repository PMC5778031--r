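#' Construct a single trajectory frame
#'
#' A frame holds the element symbols and Cartesian coordinates (Angstrom) of
#' one snapshot, optionally together with maximally localized Wannier-center
#' positions used for the full nuclear-plus-electronic dipole.
#'
#' @param elements character vector of element symbols ("O", "H").
#' @param xyz numeric matrix, one row per atom, columns x/y/z in Angstrom.
#' @param wannier optional numeric matrix of Wannier-center coordinates
#'   (Angstrom); for the neutral and protonated water systems built here the
#'   center count is four per oxygen (one electron pair per center).
#' @param time frame time in fs.
#' @return an object of class `md_frame`.
#' @export
md_frame <- function(elements, xyz, wannier = NULL, time = 0) {
  xyz <- as.matrix(xyz)
  storage.mode(xyz) <- "double"
  dimnames(xyz) <- NULL
  if (nrow(xyz) != length(elements))
    stop("coordinate row count (", nrow(xyz), ") does not match element count (",
         length(elements), ")")
  if (ncol(xyz) != 3L) stop("coordinates must have 3 columns")
  if (!all(is.finite(xyz))) stop("non-finite coordinates in frame")
  if (!is.null(wannier)) {
    wannier <- as.matrix(wannier)
    storage.mode(wannier) <- "double"
    dimnames(wannier) <- NULL
    if (ncol(wannier) != 3L) stop("Wannier centers must have 3 columns")
    if (!all(is.finite(wannier))) stop("non-finite Wannier-center coordinates")
  }
  structure(list(elements = as.character(elements), xyz = xyz,
                 wannier = wannier, time = as.numeric(time)),
            class = "md_frame")
}

#' Construct a trajectory from a list of frames
#'
#' All frames must share the same element list; times are checked against a
#' uniform grid `t0 + k * dt`.
#'
#' @param frames list of [md_frame] objects.
#' @param dt time step between consecutive frames, fs (> 0).
#' @param segment_id label of the microcanonical (NVE) segment.
#' @param geometry cluster-geometry label (`"chain_narrow"`, `"chain_wide"`,
#'   `"disc"`, `"droplet"`) or `NA`.
#' @param protonated logical; whether the system carries one excess proton.
#' @return an object of class `md_trajectory`.
#' @export
md_trajectory <- function(frames, dt, segment_id = "seg1", geometry = NA_character_,
                          protonated = NA) {
  if (!is.numeric(dt) || length(dt) != 1L || !is.finite(dt) || dt <= 0)
    stop("dt must be a single positive number (fs)")
  if (length(frames) < 1L) stop("trajectory needs at least one frame")
  el <- frames[[1L]]$elements
  for (i in seq_along(frames)) {
    if (!identical(frames[[i]]$elements, el))
      stop("frame ", i, " has a different element list")
  }
  n <- length(el)
  nf <- length(frames)
  xyz <- array(NA_real_, c(n, 3L, nf))
  for (i in seq_len(nf)) xyz[, , i] <- frames[[i]]$xyz
  wann <- NULL
  has_w <- !vapply(frames, function(f) is.null(f$wannier), logical(1))
  if (all(has_w)) {
    nw <- nrow(frames[[1L]]$wannier)
    if (any(vapply(frames, function(f) nrow(f$wannier), integer(1)) != nw))
      stop("Wannier-center count varies across frames")
    wann <- array(NA_real_, c(nw, 3L, nf))
    for (i in seq_len(nf)) wann[, , i] <- frames[[i]]$wannier
  } else if (any(has_w)) {
    stop("Wannier centers present on some frames but not all")
  }
  t0 <- frames[[1L]]$time
  times <- t0 + dt * (seq_len(nf) - 1)
  structure(list(elements = el, xyz = xyz, wannier = wann, dt = dt,
                 times = times, segment_id = segment_id, geometry = geometry,
                 protonated = protonated),
            class = "md_trajectory")
}

#' @export
print.md_trajectory <- function(x, ...) {
  cat("md_trajectory:", n_frames(x), "frames x", length(x$elements), "atoms",
      sprintf("(dt = %g fs, %.3g ps)", x$dt, n_frames(x) * x$dt / 1000), "\n")
  cat("  elements:", paste(sprintf("%s:%d", names(table(x$elements)),
                                   table(x$elements)), collapse = " "), "\n")
  if (!is.null(x$wannier))
    cat("  Wannier centers:", dim(x$wannier)[1L], "per frame\n")
  if (!is.na(x$geometry))
    cat("  geometry:", x$geometry,
        if (isTRUE(x$protonated)) "(protonated)" else "(neutral)", "\n")
  invisible(x)
}

#' Number of frames in a trajectory
#' @param trajectory an `md_trajectory`.
#' @return integer frame count.
#' @export
n_frames <- function(trajectory) dim(trajectory$xyz)[3L]

#' Extract one frame from a trajectory
#' @param trajectory an `md_trajectory`.
#' @param i frame index.
#' @return an [md_frame].
#' @export
get_frame <- function(trajectory, i) {
  md_frame(trajectory$elements, trajectory$xyz[, , i, drop = TRUE],
           wannier = if (!is.null(trajectory$wannier))
             trajectory$wannier[, , i, drop = TRUE],
           time = trajectory$times[i])
}

normalize_symbol <- function(s) {
  s <- tolower(s)
  paste0(toupper(substring(s, 1, 1)), substring(s, 2))
}

# Parse concatenated XYZ blocks from a character vector of lines.  Returns a
# list of blocks, each list(symbols, xyz, comment).  `what` is used in error
# messages ("frame" or "block").
parse_xyz_blocks <- function(lines, what = "frame") {
  blocks <- list()
  pos <- 1L
  nline <- length(lines)
  k <- 0L
  while (pos <= nline) {
    if (!nzchar(trimws(lines[pos]))) { pos <- pos + 1L; next }
    k <- k + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[pos])))
    if (is.na(nat) || nat < 1L)
      stop("malformed atom-count header at ", what, " ", k)
    if (pos + 1L + nat > nline)
      stop("truncated coordinate block at ", what, " ", k,
           ": declared ", nat, " atoms but file ends early")
    comment <- lines[pos + 1L]
    body <- lines[(pos + 2L):(pos + 1L + nat)]
    toks <- strsplit(trimws(body), "[[:space:]]+")
    nt <- lengths(toks)
    if (any(nt < 4L))
      stop("malformed coordinate line in ", what, " ", k)
    sym <- normalize_symbol(vapply(toks, `[[`, "", 1L))
    xyz <- matrix(suppressWarnings(as.numeric(
      unlist(lapply(toks, function(t) t[2:4])))), ncol = 3L, byrow = TRUE)
    if (any(!is.finite(xyz)))
      stop("non-numeric coordinate in ", what, " ", k)
    # peek: if the next non-blank line is not a bare integer equal to a
    # plausible header, we either ended cleanly or the count was wrong
    blocks[[k]] <- list(symbols = sym, xyz = xyz, comment = comment)
    pos <- pos + 2L + nat
    if (pos <= nline && nzchar(trimws(lines[pos]))) {
      nxt <- suppressWarnings(as.integer(trimws(lines[pos])))
      if (is.na(nxt))
        stop("atom-count mismatch at ", what, " ", k,
             ": block does not end at a frame boundary")
    }
  }
  if (length(blocks) == 0L) stop("no coordinate blocks found")
  blocks
}

#' Read a multi-frame (extended) XYZ trajectory
#'
#' Reads concatenated XYZ blocks in file order.  Pseudo-atoms with symbol
#' `"X"` are interpreted as inline Wannier centers (the extended-XYZ dialect)
#' and split off into the frame's `wannier` field; all other symbols are
#' treated as nuclei.  Coordinates are in Angstrom.
#'
#' @param path path to the XYZ file.
#' @param dt time step between frames, fs.
#' @param segment_id,geometry,protonated metadata passed to [md_trajectory].
#' @return an `md_trajectory`.
#' @export
read_xyz_trajectory <- function(path, dt, segment_id = basename(path),
                                geometry = NA_character_, protonated = NA) {
  if (!is.numeric(dt) || length(dt) != 1L || is.na(dt) || dt <= 0)
    stop("dt must be a single positive number (fs)")
  if (!file.exists(path)) stop("file not found: ", path)
  blocks <- parse_xyz_blocks(readLines(path), what = "frame")
  frames <- lapply(seq_along(blocks), function(i) {
    b <- blocks[[i]]
    is_wc <- b$symbols == "X"
    md_frame(b$symbols[!is_wc], b$xyz[!is_wc, , drop = FALSE],
             wannier = if (any(is_wc)) b$xyz[is_wc, , drop = FALSE],
             time = (i - 1) * dt)
  })
  md_trajectory(frames, dt = dt, segment_id = segment_id,
                geometry = geometry, protonated = protonated)
}

#' Write a trajectory as multi-frame XYZ
#'
#' @param trajectory an `md_trajectory`.
#' @param path output path.
#' @param wannier `"inline"` appends Wannier centers as pseudo-atoms with
#'   symbol `"X"` to each frame; `"none"` omits them.
#' @param digits decimal digits for coordinates.
#' @return invisibly, the path.
#' @export
write_xyz_trajectory <- function(trajectory, path, wannier = c("inline", "none"),
                                 digits = 10) {
  wannier <- match.arg(wannier)
  inc_w <- wannier == "inline" && !is.null(trajectory$wannier)
  con <- file(path, "w")
  on.exit(close(con))
  fmt <- paste0("%-2s %.", digits, "f %.", digits, "f %.", digits, "f")
  for (i in seq_len(n_frames(trajectory))) {
    sym <- trajectory$elements
    xyz <- trajectory$xyz[, , i]
    if (inc_w) {
      sym <- c(sym, rep("X", dim(trajectory$wannier)[1L]))
      xyz <- rbind(xyz, trajectory$wannier[, , i])
    }
    writeLines(c(as.character(length(sym)),
                 sprintf("frame %d time_fs=%.6f", i, trajectory$times[i]),
                 sprintf(fmt, sym, xyz[, 1L], xyz[, 2L], xyz[, 3L])), con)
  }
  invisible(path)
}

#' Attach Wannier centers stored in a parallel XYZ-like file
#'
#' The center file must contain one coordinate block per trajectory frame
#' (dummy element symbols are allowed) and a constant center count.
#'
#' @param path path to the Wannier-center file.
#' @param trajectory an `md_trajectory` whose frames the blocks annotate.
#' @return the trajectory with `wannier` populated.
#' @export
read_wannier_centers <- function(path, trajectory) {
  if (!file.exists(path)) stop("file not found: ", path)
  blocks <- parse_xyz_blocks(readLines(path), what = "block")
  nf <- n_frames(trajectory)
  if (length(blocks) != nf)
    stop("Wannier block count (", length(blocks),
         ") does not match trajectory frame count (", nf, ")")
  counts <- vapply(blocks, function(b) nrow(b$xyz), integer(1))
  if (length(unique(counts)) != 1L)
    stop("Wannier-center count varies across blocks (",
         paste(unique(counts), collapse = ", "), ")")
  wann <- array(NA_real_, c(counts[1L], 3L, nf))
  for (i in seq_len(nf)) wann[, , i] <- blocks[[i]]$xyz
  trajectory$wannier <- wann
  trajectory
}

#' Write a direction-resolved spectrum as CSV
#'
#' Column contract: `wavenumber_cm-1, A_xx, A_yy, A_zz, A_xy_mean, error`
#' followed, when per-component segment statistics exist, by
#' `err_xx, err_yy, err_zz`.  `A_xy_mean` is the radial average
#' `(A_xx + A_yy)/2` and `error` the componentwise-mean standard error
#' (zero when no segment statistics are available).  Full double precision;
#' rows in increasing wavenumber.
#'
#' @param spectrum an [ir_spectrum].
#' @param path output path.
#' @return invisibly, the path.
#' @export
write_spectrum_table <- function(spectrum, path) {
  stopifnot(inherits(spectrum, "ir_spectrum"))
  if (length(spectrum$nu) == 0L) stop("refusing to write a spectrum with an empty grid")
  if (!all(is.finite(spectrum$nu)) || !all(is.finite(spectrum$A)))
    stop("non-finite values in spectrum")
  err <- spectrum$err
  d <- data.frame(`wavenumber_cm-1` = spectrum$nu,
                  A_xx = spectrum$A[, 1L], A_yy = spectrum$A[, 2L],
                  A_zz = spectrum$A[, 3L],
                  A_xy_mean = (spectrum$A[, 1L] + spectrum$A[, 2L]) / 2,
                  error = if (is.null(err)) 0 else rowMeans(err),
                  check.names = FALSE)
  if (!is.null(err)) {
    d$err_xx <- err[, 1L]; d$err_yy <- err[, 2L]; d$err_zz <- err[, 3L]
  }
  ok <- tryCatch(utils::write.csv(d, path, row.names = FALSE), error = function(e)
    stop("cannot write spectrum table to ", path, ": ", conditionMessage(e)))
  invisible(path)
}

#' Read a spectrum CSV written by [write_spectrum_table]
#'
#' @param path path to the CSV.
#' @return an [ir_spectrum].
#' @export
read_spectrum_table <- function(path) {
  d <- utils::read.csv(path, check.names = FALSE)
  need <- c("wavenumber_cm-1", "A_xx", "A_yy", "A_zz")
  if (!all(need %in% names(d)))
    stop("spectrum table lacks required columns: ",
         paste(setdiff(need, names(d)), collapse = ", "))
  err <- NULL
  if (all(c("err_xx", "err_yy", "err_zz") %in% names(d)))
    err <- cbind(xx = d$err_xx, yy = d$err_yy, zz = d$err_zz)
  ir_spectrum(d[["wavenumber_cm-1"]],
              cbind(xx = d$A_xx, yy = d$A_yy, zz = d$A_zz), err = err)
}
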