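#' Gridded free-energy surfaces
#'
#' A `fes_grid` is a tibble with one column of bin centers per collective
#' variable, a `free_energy` column (kJ/mol), a `count` column (number of
#' samples, or weight mass, per bin) and a `visited` logical.  Unvisited bins
#' carry `NA` free energy -- they are flagged, never zero-filled.  Axis
#' metadata (name, bin edges) and the minimum-subtracted flag live in
#' attributes.  Rows are ordered with the last axis varying fastest.
#'
#' @param axes list of axes, each `list(name =, edges =)` with strictly
#'   increasing edges in CV units.
#' @param free_energy numeric vector over the grid (last axis fastest), kJ/mol.
#' @param count per-bin sample count (defaults to 1 for analytic surfaces).
#' @param min_subtracted logical flag; when `TRUE` the minimum over visited
#'   bins is zero.
#' @return a `fes_grid` tibble.
#' @export
fes_grid <- function(axes, free_energy, count = NULL, min_subtracted = FALSE) {
  nb <- vapply(axes, function(a) length(a$edges) - 1L, 1L)
  stopifnot(length(free_energy) == prod(nb))
  centers <- lapply(axes, function(a) (head(a$edges, -1) + tail(a$edges, -1)) / 2)
  # last axis fastest
  grid <- rev(expand.grid(rev(centers), KEEP.OUT.ATTRS = FALSE))
  names(grid) <- vapply(axes, `[[`, "", "name")
  if (is.null(count)) count <- rep(1, length(free_energy))
  visited <- count > 0 & is.finite(free_energy)
  fe <- free_energy
  fe[!visited] <- NA_real_
  if (min_subtracted && any(visited)) fe <- fe - min(fe[visited])
  out <- as_tibble(grid)
  out$free_energy <- fe
  out$count <- count
  out$visited <- visited
  structure(out, axes = axes, min_subtracted = isTRUE(min_subtracted),
            class = c("fes_grid", class(tibble())))
}

fes_axes <- function(fes) attr(fes, "axes")

fes_axis_names <- function(fes) vapply(fes_axes(fes), `[[`, "", "name")

fes_nbins <- function(fes) {
  vapply(fes_axes(fes), function(a) length(a$edges) - 1L, 1L)
}

fes_bin_volume <- function(fes) {
  prod(vapply(fes_axes(fes), function(a) mean(diff(a$edges)), 1.0))
}

#' Subtract the minimum over visited bins
#'
#' @param fes a [fes_grid()].
#' @return the grid with min over visited bins equal to zero.
#' @export
fes_min_subtract <- function(fes) {
  if (any(fes$visited)) {
    fes$free_energy <- fes$free_energy - min(fes$free_energy[fes$visited])
  }
  attr(fes, "min_subtracted") <- TRUE
  fes
}

#' Evaluate a 2D scalar field on a grid as a `fes_grid`
#'
#' @param field a `scalar_field_2d` (see [proton_transfer_surface()]).
#' @param axes list of two axes as in [fes_grid()].
#' @param min_subtracted subtract the global minimum.
#' @return a [fes_grid()] with every bin visited.
#' @export
fes_from_field <- function(field, axes, min_subtracted = TRUE) {
  stopifnot(inherits(field, "scalar_field_2d"), length(axes) == 2)
  c1 <- (head(axes[[1]]$edges, -1) + tail(axes[[1]]$edges, -1)) / 2
  c2 <- (head(axes[[2]]$edges, -1) + tail(axes[[2]]$edges, -1)) / 2
  g <- rev(expand.grid(rev(list(c1, c2)), KEEP.OUT.ATTRS = FALSE))
  vals <- field$f(g[[1]], g[[2]])
  fes_grid(axes, vals, min_subtracted = min_subtracted)
}

#' Write a free-energy grid as text
#'
#' Format: `#! FIELDS <cv...> free_energy count` followed by `#! SET` lines
#' with per-axis min/max/nbins and the minimum-subtracted flag, then one row
#' per grid point with the last axis varying fastest.  Unvisited bins are
#' written as `nan` with count 0.
#'
#' @param fes a [fes_grid()].
#' @param path file path.
#' @export
write_fes_grid <- function(fes, path) {
  axn <- fes_axis_names(fes)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(axn, collapse = " "),
                   "free_energy count"), con)
  for (a in fes_axes(fes)) {
    writeLines(sprintf("#! SET min_%s %.6f", a$name, min(a$edges)), con)
    writeLines(sprintf("#! SET max_%s %.6f", a$name, max(a$edges)), con)
    writeLines(sprintf("#! SET nbins_%s %d", a$name, length(a$edges) - 1L), con)
  }
  writeLines(sprintf("#! SET min_subtracted %s",
                     if (isTRUE(attr(fes, "min_subtracted"))) "T" else "F"), con)
  fe <- ifelse(fes$visited, sprintf("%.6f", fes$free_energy), "nan")
  m <- as.matrix(fes[, axn, drop = FALSE])
  rows <- apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " "))
  writeLines(paste(rows, fe, sprintf("%.6f", fes$count)), con)
  invisible(path)
}

#' @rdname write_fes_grid
#' @return [read_fes_grid()] returns a [fes_grid()].
#' @export
read_fes_grid <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!grepl("^#!\\s*FIELDS", lines[1])) {
    abort("parse error at line 1: expected '#! FIELDS ...' header")
  }
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", lines[1])), "\\s+")[[1]]
  axn <- setdiff(fields, c("free_energy", "count"))
  sets <- lines[grepl("^#!\\s*SET", lines)]
  getset <- function(key) {
    m <- sets[grepl(paste0("\\b", key, "\\b"), sets)]
    if (!length(m)) return(NA_character_)
    tail(strsplit(trimws(m[1]), "\\s+")[[1]], 1)
  }
  axes <- lapply(axn, function(nm) {
    lo <- as.numeric(getset(paste0("min_", nm)))
    hi <- as.numeric(getset(paste0("max_", nm)))
    nb <- as.integer(getset(paste0("nbins_", nm)))
    if (any(is.na(c(lo, hi, nb)))) {
      abort(sprintf("parse error: missing grid metadata for axis '%s'", nm))
    }
    list(name = nm, edges = seq(lo, hi, length.out = nb + 1L))
  })
  body <- lines[!grepl("^#", lines)]
  body <- body[nzchar(trimws(body))]
  parts <- strsplit(trimws(body), "\\s+")
  bad <- which(vapply(parts, length, 1L) != length(fields))
  if (length(bad)) abort(sprintf("parse error: row %d has wrong arity", bad[1]))
  m <- matrix(suppressWarnings(as.numeric(unlist(parts))),
              ncol = length(fields), byrow = TRUE)
  colnames(m) <- fields
  fe <- m[, "free_energy"]
  cnt <- if ("count" %in% fields) m[, "count"] else rep(1, nrow(m))
  fes_grid(axes, fe, cnt,
           min_subtracted = toupper(getset("min_subtracted")) %in% c("T", "TRUE"))
}
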