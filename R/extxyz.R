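#' @title Extended-XYZ dataset input/output
#' @description Labeled datasets (coordinates plus energy and per-atom
#'   forces) persist as extended-XYZ text: per frame an atom count, a comment
#'   line of `key=value` pairs including `energy` and a `Properties`
#'   descriptor, then one line per atom with species, position and force
#'   columns. Coordinates whose flattened dimension is not a multiple of 3
#'   (e.g. the two-dimensional Mueller-Brown surface) are zero-padded into
#'   3-vectors on write and un-padded on read via the `dim=` comment key.
#'   Floats are emitted with 17 significant digits so write-then-read is the
#'   identity on datasets.
#' @name extxyz
NULL

fmt17 <- function(x) sprintf("%.17g", x)

#' Write a labeled dataset as extended-XYZ
#'
#' @param dataset List of labeled samples: each with `coords`, `energy`,
#'   `forces`, and optionally `sample_id` and `provenance`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_extxyz <- function(dataset, path) {
  con <- file(path, open = "wt")
  on.exit(close(con))
  for (s in dataset) {
    D <- length(s$coords)
    stopifnot(length(s$forces) == D)
    pad <- (3L - D %% 3L) %% 3L
    coords <- c(s$coords, numeric(pad))
    forces <- c(s$forces, numeric(pad))
    nat <- length(coords) %/% 3L
    meta <- c(
      'Properties=species:S:1:pos:R:3:forces:R:3',
      paste0("energy=", fmt17(s$energy)),
      paste0("dim=", D)
    )
    if (!is.null(s$sample_id)) meta <- c(meta, paste0("sample_id=", s$sample_id))
    if (!is.null(s$provenance)) {
      meta <- c(meta, paste0('provenance="', s$provenance, '"'))
    }
    writeLines(as.character(nat), con)
    writeLines(paste(meta, collapse = " "), con)
    P <- matrix(coords, ncol = 3L, byrow = TRUE)
    Fm <- matrix(forces, ncol = 3L, byrow = TRUE)
    for (a in seq_len(nat)) {
      writeLines(paste("X", fmt17(P[a, 1]), fmt17(P[a, 2]), fmt17(P[a, 3]),
                       fmt17(Fm[a, 1]), fmt17(Fm[a, 2]), fmt17(Fm[a, 3])),
                 con)
    }
  }
  invisible(path)
}

parse_comment_line <- function(line) {
  # key=value pairs; values may be double-quoted strings
  out <- list()
  pat <- '([A-Za-z_][A-Za-z0-9_]*)=("[^"]*"|[^ ]+)'
  m <- gregexpr(pat, line, perl = TRUE)[[1]]
  if (m[1] == -1L) return(out)
  starts <- as.integer(m)
  lens <- attr(m, "match.length")
  for (i in seq_along(starts)) {
    kv <- substr(line, starts[i], starts[i] + lens[i] - 1L)
    eq <- regexpr("=", kv, fixed = TRUE)
    key <- substr(kv, 1L, eq - 1L)
    val <- substr(kv, eq + 1L, nchar(kv))
    val <- sub('^"', "", sub('"$', "", val))
    out[[key]] <- val
  }
  out
}

#' Read an extended-XYZ labeled dataset
#'
#' An empty file yields an empty dataset. A malformed frame (bad atom count,
#' missing force columns, missing energy) raises an error naming the frame
#' index and line number.
#'
#' @param path Input file path.
#' @return List of labeled samples (`coords`, `energy`, `forces`,
#'   `sample_id`, `provenance`).
#' @export
read_extxyz <- function(path) {
  lines <- readLines(path)
  dataset <- list()
  i <- 1L
  frame <- 0L
  while (i <= length(lines)) {
    if (!nzchar(trimws(lines[i]))) { i <- i + 1L; next }
    frame <- frame + 1L
    nat <- suppressWarnings(as.integer(trimws(lines[i])))
    if (is.na(nat) || nat < 1L) {
      stop("frame ", frame, " (line ", i, "): invalid atom count '",
           lines[i], "'")
    }
    if (i + 1L + nat > length(lines)) {
      stop("frame ", frame, " (line ", i, "): truncated frame")
    }
    meta <- parse_comment_line(lines[i + 1L])
    if (is.null(meta$energy)) {
      stop("frame ", frame, " (line ", i + 1L, "): missing energy field")
    }
    coords <- numeric(0); forces <- numeric(0)
    for (a in seq_len(nat)) {
      ln <- i + 1L + a
      tok <- strsplit(trimws(lines[ln]), "[ \t]+")[[1]]
      if (length(tok) < 7L) {
        stop("frame ", frame, " (line ", ln,
             "): expected species + 3 position + 3 force columns")
      }
      vals <- suppressWarnings(as.numeric(tok[2:7]))
      if (any(is.na(vals))) {
        stop("frame ", frame, " (line ", ln, "): non-numeric atom fields")
      }
      coords <- c(coords, vals[1:3])
      forces <- c(forces, vals[4:6])
    }
    D <- if (!is.null(meta$dim)) as.integer(meta$dim) else length(coords)
    dataset[[frame]] <- list(
      coords = coords[seq_len(D)],
      energy = as.numeric(meta$energy),
      forces = forces[seq_len(D)],
      sample_id = if (!is.null(meta$sample_id)) as.integer(meta$sample_id) else NA_integer_,
      provenance = if (!is.null(meta$provenance)) meta$provenance else NA_character_
    )
    i <- i + 2L + nat
  }
  dataset
}
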