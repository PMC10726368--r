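#' Read an XYZ file
#'
#' Standard XYZ dialect: first line is the atom count, second line a
#' free-form comment (kept as the geometry label), then one line per atom
#' with an element symbol and three Cartesian coordinates in Angstrom.
#'
#' @param file Path to an XYZ file, or a character scalar containing XYZ
#'   text (recognized by embedded newlines).
#' @return A [geometry()] tibble.
#' @seealso [write_xyz()], [read_engine_orientation()]
#' @export
read_xyz <- function(file) {
  lines <- text_lines(file)
  if (length(lines) < 1 || !grepl("^\\s*\\d+\\s*$", lines[1])) {
    stop("XYZ parse error at line 1: expected an atom count", call. = FALSE)
  }
  n <- as.integer(trimws(lines[1]))
  label <- if (length(lines) >= 2) lines[2] else ""
  if (length(lines) < n + 2) {
    stop("XYZ parse error at line ", length(lines) + 1,
         ": declared ", n, " atoms but file ends after ",
         max(length(lines) - 2L, 0L), " atom line(s)", call. = FALSE)
  }
  if (n == 0L) {
    return(geometry(character(), numeric(), numeric(), numeric(), label = label))
  }
  element <- character(n)
  xyz <- matrix(NA_real_, n, 3)
  for (i in seq_len(n)) {
    ln <- i + 2L
    tok <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(tok) < 4) {
      stop("XYZ parse error at line ", ln, ": expected 'symbol x y z', got '",
           lines[ln], "'", call. = FALSE)
    }
    vals <- suppressWarnings(as.numeric(tok[2:4]))
    if (anyNA(vals)) {
      stop("XYZ parse error at line ", ln, ": non-numeric coordinate in '",
           lines[ln], "'", call. = FALSE)
    }
    element[i] <- tok[1]
    xyz[i, ] <- vals
  }
  tryCatch(
    geometry(element, xyz[, 1], xyz[, 2], xyz[, 3], label = label),
    error = function(e) {
      stop("XYZ parse error: ", conditionMessage(e), call. = FALSE)
    }
  )
}

#' Write a geometry as XYZ text
#'
#' Coordinates are printed with eight decimals; element symbols (never
#' atomic numbers) are used on output. The geometry label becomes the
#' comment line.
#'
#' @param geom A [geometry()] (or data frame with `element`, `x`, `y`, `z`).
#' @param file Optional path; if `NULL` the XYZ text is returned invisibly
#'   as a character scalar.
#' @return The XYZ text, invisibly.
#' @export
write_xyz <- function(geom, file = NULL) {
  geom <- as_geometry(geom, degenerate = TRUE)
  body <- sprintf("%-3s %15.8f %15.8f %15.8f", geom$element, geom$x, geom$y, geom$z)
  txt <- paste(c(nrow(geom), geometry_label(geom), body), collapse = "\n")
  txt <- paste0(txt, "\n")
  if (!is.null(file)) writeLines(txt, file, sep = "")
  invisible(txt)
}

#' Read the final orientation block of a quantum-chemistry log
#'
#' Scans a Gaussian-style log for `Standard orientation:` (or
#' `Input orientation:`) coordinate blocks -- atomic number plus x, y, z in
#' Angstrom -- and returns the geometry of the last block, i.e. the final
#' optimized structure. No other log content is interpreted.
#'
#' @param file Path to the log file, or its content as a character scalar.
#' @return A [geometry()] tibble.
#' @export
read_engine_orientation <- function(file) {
  lines <- text_lines(file)
  starts <- grep("(Standard|Input) orientation:", lines)
  if (length(starts) == 0) {
    stop("no orientation block found in log input", call. = FALSE)
  }
  parse_block <- function(at) {
    dashed <- grep("^\\s*-{10,}\\s*$", lines)
    dashed <- dashed[dashed > at]
    if (length(dashed) < 3) {
      stop("truncated orientation block at line ", at, call. = FALSE)
    }
    from <- dashed[2] + 1L
    to <- dashed[3] - 1L
    if (to < from) stop("empty orientation block at line ", at, call. = FALSE)
    rows <- lapply(lines[from:to], function(l) {
      tok <- strsplit(trimws(l), "\\s+")[[1]]
      if (length(tok) < 6 || anyNA(suppressWarnings(as.numeric(tok)))) {
        stop("malformed orientation row: '", l, "'", call. = FALSE)
      }
      as.numeric(tok)
    })
    m <- do.call(rbind, rows)
    els <- element_data()
    idx <- match(as.integer(m[, 2]), els$atomic_number)
    if (anyNA(idx)) {
      stop("unsupported atomic number in orientation block: ",
           m[which(is.na(idx))[1], 2], call. = FALSE)
    }
    nc <- ncol(m)
    geometry(els$symbol[idx], m[, nc - 2], m[, nc - 1], m[, nc],
             label = "engine orientation")
  }
  parse_block(starts[length(starts)])
}

text_lines <- function(file) {
  if (length(file) == 1 && grepl("\n", file, fixed = TRUE)) {
    strsplit(file, "\n", fixed = TRUE)[[1]]
  } else {
    readLines(file, warn = FALSE)
  }
}
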