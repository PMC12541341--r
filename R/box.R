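#' Orthorhombic periodic simulation box
#'
#' Only orthorhombic (including cubic) boxes are supported; analysis-time
#' cells for the systems this package targets are cubic or orthorhombic.
#' Triclinic lattices raise an unsupported-geometry error at read time.
#'
#' @param edge_lengths numeric(3), box edges in Å, strictly positive.
#' @param periodic logical(3), per-axis periodicity flags.
#' @return object of class `sim_box`.
#' @examples
#' sim_box(c(36, 36, 36))
#' @export
sim_box <- function(edge_lengths, periodic = c(TRUE, TRUE, TRUE)) {
  edge_lengths <- as.numeric(edge_lengths)
  if (length(edge_lengths) != 3 || any(!is.finite(edge_lengths)) ||
      any(edge_lengths <= 0)) {
    abort("`edge_lengths` must be three finite, strictly positive lengths (Å)")
  }
  periodic <- rep_len(as.logical(periodic), 3)
  structure(list(edge_lengths = edge_lengths, periodic = periodic),
            class = "sim_box")
}

#' @export
print.sim_box <- function(x, ...) {
  cat(sprintf("<sim_box> %g x %g x %g Å (periodic: %s)\n",
              x$edge_lengths[1], x$edge_lengths[2], x$edge_lengths[3],
              paste(ifelse(x$periodic, "T", "F"), collapse = "")))
  invisible(x)
}

#' Build a box from a 3x3 lattice matrix, rejecting triclinic cells
#'
#' @param lattice 3x3 matrix of lattice vectors (rows), Å.
#' @param periodic logical(3) periodicity flags.
#' @return a [sim_box()].
#' @export
sim_box_from_lattice <- function(lattice, periodic = c(TRUE, TRUE, TRUE)) {
  lattice <- matrix(as.numeric(lattice), 3, 3)
  off <- lattice
  diag(off) <- 0
  if (any(abs(off) > 1e-10)) {
    abort(paste0("unsupported geometry: lattice is not orthorhombic ",
                 "(off-diagonal components present); only orthorhombic ",
                 "boxes are supported"),
          class = "pairfes_geometry_error")
  }
  sim_box(diag(lattice), periodic)
}

#' Minimum-image displacement between two positions
#'
#' Returns the displacement `b - a` wrapped into the primary image, i.e. each
#' periodic component lies in (-L/2, L/2] and its norm is the smallest over
#' all periodic images of `b`.
#'
#' @param a,b numeric(3) positions in Å (or n x 3 matrices of positions).
#' @param box a [sim_box()].
#' @return displacement(s) with the same shape as the inputs, Å.
#' @examples
#' minimum_image_displacement(c(0, 0, 0), c(9, 0, 0), sim_box(c(10, 10, 10)))
#' @export
minimum_image_displacement <- function(a, b, box) {
  if (!inherits(box, "sim_box")) abort("`box` must be a `sim_box`")
  vec_in <- is.null(dim(a))
  a <- matrix(a, ncol = 3)
  b <- matrix(b, ncol = 3)
  d <- b - a
  for (k in 1:3) {
    if (!box$periodic[k]) next
    L <- box$edge_lengths[k]
    w <- d[, k] - L * round(d[, k] / L)
    w[w <= -L / 2] <- w[w <= -L / 2] + L
    w[w > L / 2] <- w[w > L / 2] - L
    d[, k] <- w
  }
  if (vec_in && nrow(d) == 1) drop(d) else d
}

#' Wrap positions into the primary box [0, L)
#'
#' @param pos n x 3 matrix of positions, Å.
#' @param box a [sim_box()].
#' @return wrapped positions.
#' @export
wrap_positions <- function(pos, box) {
  pos <- matrix(pos, ncol = 3)
  for (k in 1:3) {
    if (!box$periodic[k]) next
    L <- box$edge_lengths[k]
    pos[, k] <- pos[, k] - L * floor(pos[, k] / L)
  }
  pos
}
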