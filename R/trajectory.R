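#' Labelled particle trajectory
#'
#' A trajectory is a tibble in long form with columns `frame` (integer,
#' 1-based), `time` (ps), `species` (character label: O, H, C, Ca, WC, ...)
#' and `x`, `y`, `z` (Å), carrying the periodic box and the wrapping
#' convention as attributes.  Particle count and label order are constant
#' across frames and time stamps are strictly increasing.
#'
#' Coordinates may be stored unwrapped (required for displacement-based
#' dynamics such as mean squared displacements) or wrapped into the box
#' (natural for structural analysis); the `wrapped` flag records which
#' convention applies and is preserved on file round trips.
#'
#' @param species character vector of per-particle labels (one frame's worth).
#' @param positions numeric array `n_particles x 3 x n_frames` (or an
#'   `n x 3` matrix for a single frame), Å.
#' @param box a [sim_box()].
#' @param times numeric vector of frame times (ps), strictly increasing.
#' @param wrapped logical, coordinate convention flag.
#' @return a `trajectory` tibble.
#' @export
trajectory <- function(species, positions, box, times = NULL, wrapped = FALSE) {
  if (is.matrix(positions)) positions <- array(positions, c(dim(positions), 1))
  stopifnot(length(dim(positions)) == 3, dim(positions)[2] == 3)
  n <- dim(positions)[1]
  nf <- dim(positions)[3]
  if (length(species) != n) abort("`species` length must match particle count")
  if (is.null(times)) times <- seq_len(nf) - 1
  if (length(times) != nf) abort("`times` length must match frame count")
  if (nf > 1 && any(diff(times) <= 0)) {
    abort("frame times must be strictly increasing")
  }
  if (any(!is.finite(positions))) abort("positions must be finite")
  out <- tibble(
    frame = rep(seq_len(nf), each = n),
    time = rep(as.numeric(times), each = n),
    species = rep(as.character(species), nf),
    x = as.numeric(positions[, 1, ]),
    y = as.numeric(positions[, 2, ]),
    z = as.numeric(positions[, 3, ])
  )
  new_trajectory(out, box, wrapped)
}

new_trajectory <- function(df, box, wrapped) {
  structure(df,
            box = box, wrapped = isTRUE(wrapped),
            class = c("trajectory", class(tibble())))
}

#' @rdname trajectory
#' @param traj a `trajectory`.
#' @export
traj_box <- function(traj) attr(traj, "box")

#' @rdname trajectory
#' @export
traj_wrapped <- function(traj) isTRUE(attr(traj, "wrapped"))

#' @rdname trajectory
#' @export
n_frames <- function(traj) length(unique(traj$frame))

#' @rdname trajectory
#' @export
n_particles <- function(traj) sum(traj$frame == traj$frame[1])

#' Positions of one frame as a matrix
#'
#' @param traj a `trajectory`.
#' @param i frame index (1-based).
#' @return list with `species` (character) and `pos` (n x 3 matrix, Å).
#' @export
frame_positions <- function(traj, i = 1) {
  sel <- traj$frame == i
  if (!any(sel)) abort(sprintf("no frame %d in trajectory", i))
  list(species = traj$species[sel],
       pos = cbind(traj$x[sel], traj$y[sel], traj$z[sel]))
}

#' Positions of every frame as an array
#'
#' @param traj a `trajectory` (optionally filtered to one species).
#' @param species if non-NULL, keep only particles with this label.
#' @return array `n_particles x 3 x n_frames`.
#' @export
positions_array <- function(traj, species = NULL) {
  if (!is.null(species)) {
    traj <- traj[traj$species %in% species, , drop = FALSE]
  }
  nf <- length(unique(traj$frame))
  n <- nrow(traj) / nf
  if (n != round(n)) abort("particle count varies across frames")
  arr <- array(NA_real_, c(n, 3, nf))
  m <- cbind(traj$x, traj$y, traj$z)
  for (f in seq_len(nf)) {
    arr[, , f] <- m[traj$frame == unique(traj$frame)[f], , drop = FALSE]
  }
  arr
}
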