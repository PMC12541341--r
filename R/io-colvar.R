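#' Collective-variable record tables
#'
#' A CV table is a tibble with a `time` column (ps), one column per collective
#' variable (e.g. the ion--ion distance `d` in Å, coordination numbers
#' unitless), an accumulated bias column `bias` and a wall-energy column
#' `wall` (both kJ/mol).  On disk the COLVAR dialect is used: a declared-field
#' header `#! FIELDS time <cv...> opes.bias wall.bias` followed by
#' whitespace-separated numeric rows.
#'
#' @param time numeric vector, ps.
#' @param ... named CV columns.
#' @param bias,wall numeric, kJ/mol (recycled).
#' @return a tibble.
#' @export
cv_table <- function(time, ..., bias = 0, wall = 0) {
  tibble(time = as.numeric(time), ...,
         bias = rep_len(as.numeric(bias), length(time)),
         wall = rep_len(as.numeric(wall), length(time)))
}

#' Read a COLVAR-style CV table
#'
#' The first line must declare the fields (`#! FIELDS time d opes.bias ...`).
#' `opes.bias` (or `bias`) maps to the `bias` column and `wall.bias` (or
#' `wall`) to `wall`; if no bias field is declared the bias is taken as
#' identically zero and a warning is emitted.
#'
#' @param path file path.
#' @return a CV tibble as produced by [cv_table()].
#' @export
read_cv_table <- function(path) {
  if (!file.exists(path)) abort(sprintf("file not found: %s", path))
  lines <- readLines(path)
  if (!length(lines) || !grepl("^#!\\s*FIELDS", lines[1])) {
    abort("parse error at line 1: expected '#! FIELDS ...' header")
  }
  fields <- strsplit(trimws(sub("^#!\\s*FIELDS", "", lines[1])), "\\s+")[[1]]
  body <- lines[-1]
  body <- body[nzchar(trimws(body)) & !grepl("^#", body)]
  parts <- strsplit(trimws(body), "\\s+")
  arity <- vapply(parts, length, 1L)
  bad <- which(arity != length(fields))
  if (length(bad)) {
    abort(sprintf(
      "parse error at line %d: row has %d values but header declares %d fields",
      bad[1] + 1L, arity[bad[1]], length(fields)))
  }
  m <- matrix(as.numeric(unlist(parts)), ncol = length(fields), byrow = TRUE)
  if (any(is.na(m))) abort("parse error: non-numeric value in table body")
  colnames(m) <- fields
  out <- as_tibble(m)
  names(out)[names(out) == "opes.bias"] <- "bias"
  names(out)[names(out) == "wall.bias"] <- "wall"
  if (!"bias" %in% names(out)) {
    warn("no bias field declared; taking bias_energy identically 0")
    out$bias <- 0
  }
  if (!"wall" %in% names(out)) out$wall <- 0
  cvs <- setdiff(names(out), c("time", "bias", "wall"))
  out[, c("time", cvs, "bias", "wall")]
}

#' @rdname read_cv_table
#' @param table a CV tibble.
#' @export
write_cv_table <- function(table, path) {
  cvs <- setdiff(names(table), c("time", "bias", "wall"))
  fields <- c("time", cvs, "opes.bias", "wall.bias")
  m <- as.matrix(table[, c("time", cvs, "bias", "wall")])
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#! FIELDS", paste(fields, collapse = " ")), con)
  writeLines(apply(m, 1, function(r) paste(sprintf("%.6f", r), collapse = " ")),
             con)
  invisible(path)
}
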