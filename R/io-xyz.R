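#' Read and write extended-XYZ trajectories
#'
#' The dialect stores, per frame, a particle-count line, a comment line with
#' `Lattice="Lx 0 0 0 Ly 0 0 0 Lz" Time=<ps> Wrapped=<T|F>` keys, and one
#' `species x y z` record per particle (Å, 6 decimal places on write).
#' Canonically formatted files round-trip bit-identically; numeric content
#' round-trips within 1e-6.
#'
#' @param path file path.
#' @return [read_extended_xyz()] returns a [trajectory()];
#'   [write_extended_xyz()] returns `path` invisibly.
#' @examples
#' tr <- trajectory(c("O", "H"), matrix(c(1, 2, 3, 4, 5, 6), 2, 3, byrow = TRUE),
#'                  sim_box(c(10, 10, 10)))
#' f <- tempfile(fileext = ".xyz")
#' write_extended_xyz(tr, f)
#' tr2 <- read_extended_xyz(f)
#' @export
read_extended_xyz <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  i <- 1L
  frames <- list()
  species0 <- NULL
  box <- NULL
  wrapped <- FALSE
  times <- numeric()
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) {
      i <- i + 1L
      next
    }
    n <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(n) || n < 0) {
      abort(sprintf("parse error at line %d: expected a particle count, got '%s'",
                    i, lines[i]))
    }
    if (i + 1L + n > length(lines)) {
      abort(sprintf(
        "parse error at line %d: count line declares %d records but only %d lines remain",
        i, n, length(lines) - i - 1L))
    }
    comment <- lines[i + 1L]
    lat <- parse_key(comment, "Lattice")
    if (is.na(lat)) abort(sprintf("parse error at line %d: missing Lattice key", i + 1L))
    latv <- suppressWarnings(as.numeric(strsplit(trimws(lat), "\\s+")[[1]]))
    if (length(latv) != 9 || any(is.na(latv))) {
      abort(sprintf("parse error at line %d: Lattice must hold 9 numbers", i + 1L))
    }
    fbox <- sim_box_from_lattice(matrix(latv, 3, 3, byrow = TRUE))
    tval <- suppressWarnings(as.numeric(parse_key(comment, "Time")))
    if (is.na(tval)) tval <- length(frames)
    wval <- parse_key(comment, "Wrapped")
    if (!is.na(wval)) wrapped <- toupper(wval) %in% c("T", "TRUE")
    rec <- lines[i + 1L + seq_len(n)]
    parts <- strsplit(trimws(rec), "\\s+")
    bad <- which(vapply(parts, length, 1L) < 4L)
    if (length(bad)) {
      abort(sprintf("parse error at line %d: record has fewer than 4 fields",
                    i + 1L + bad[1]))
    }
    sp <- vapply(parts, `[[`, "", 1L)
    xyz <- t(vapply(parts, function(p) as.numeric(p[2:4]), numeric(3)))
    if (any(!is.finite(xyz))) {
      abort(sprintf("parse error near line %d: non-numeric coordinate", i + 2L))
    }
    if (is.null(species0)) {
      species0 <- sp
      box <- fbox
    } else if (!identical(sp, species0)) {
      abort(sprintf("parse error at line %d: species order differs between frames", i))
    }
    frames[[length(frames) + 1L]] <- xyz
    times <- c(times, tval)
    i <- i + 2L + n
  }
  if (!length(frames)) abort("no frames found")
  arr <- array(unlist(frames), c(nrow(frames[[1]]), 3, length(frames)))
  for (f in seq_along(frames)) arr[, , f] <- frames[[f]]
  trajectory(species0, arr, box, times, wrapped)
}

parse_key <- function(line, key) {
  m <- regmatches(line, regexpr(sprintf('%s="[^"]*"', key), line))
  if (length(m)) return(sub(sprintf('%s="([^"]*)"', key), "\\1", m))
  m <- regmatches(line, regexpr(sprintf("%s=\\S+", key), line))
  if (length(m)) return(sub(sprintf("%s=", key), "", m))
  NA_character_
}

#' @rdname read_extended_xyz
#' @param traj a [trajectory()].
#' @export
write_extended_xyz <- function(traj, path) {
  box <- traj_box(traj)
  L <- box$edge_lengths
  lat <- sprintf('Lattice="%s"',
                 paste(sprintf("%.6f", c(L[1], 0, 0, 0, L[2], 0, 0, 0, L[3])),
                       collapse = " "))
  con <- file(path, "w")
  on.exit(close(con))
  for (f in unique(traj$frame)) {
    sel <- traj$frame == f
    n <- sum(sel)
    writeLines(as.character(n), con)
    writeLines(sprintf('%s Properties=species:S:1:pos:R:3 Time=%.6f Wrapped=%s',
                       lat, traj$time[sel][1],
                       if (traj_wrapped(traj)) "T" else "F"), con)
    writeLines(sprintf("%s %.6f %.6f %.6f", traj$species[sel],
                       traj$x[sel], traj$y[sel], traj$z[sel]), con)
  }
  invisible(path)
}
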