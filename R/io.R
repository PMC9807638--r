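#' Lattice snapshot files
#'
#' A snapshot is plain text: L rows of L space-separated integers, 1 for a
#' cooperator and 0 for a defector. The first line of the file is the top
#' lattice row (matrix row 1).
#'
#' @param state a `lattice_state` (or a strategy matrix for
#'   `write_snapshot`).
#' @param path file path.
#' @return `write_snapshot` returns `path` invisibly; `read_snapshot`
#'   returns a `lattice_state` with `t = 0`.
#' @export
write_snapshot <- function(state, path) {
  cells <- if (inherits(state, "lattice_state")) state$cells else state
  stopifnot(is.matrix(cells), all(cells %in% c(0L, 1L)))
  lines <- apply(cells, 1, paste, collapse = " ")
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_snapshot
#' @export
read_snapshot <- function(path) {
  lines <- readLines(path)
  rows <- lapply(strsplit(trimws(lines), "\\s+"), as.integer)
  L <- length(rows)
  if (any(lengths(rows) != L))
    stop("snapshot is not a square lattice", call. = FALSE)
  cells <- do.call(rbind, rows)
  if (!all(cells %in% c(0L, 1L)))
    stop("snapshot entries must be 0 or 1", call. = FALSE)
  new_lattice_state(cells, 0L)
}

#' Render a lattice snapshot as a PNG image
#'
#' Cooperators are drawn red, defectors blue. Each site maps to a
#' `scale` x `scale` pixel block.
#'
#' @param state a `lattice_state`, strategy matrix, or path to a snapshot
#'   text file.
#' @param path output PNG path.
#' @param scale integer pixel magnification per site.
#' @return `path`, invisibly.
#' @export
render_snapshot <- function(state, path, scale = 1L) {
  if (is.character(state)) state <- read_snapshot(state)
  cells <- if (inherits(state, "lattice_state")) state$cells else state
  stopifnot(is.matrix(cells), scale >= 1)
  if (scale > 1) {
    idx_r <- rep(seq_len(nrow(cells)), each = scale)
    idx_c <- rep(seq_len(ncol(cells)), each = scale)
    cells <- cells[idx_r, idx_c]
  }
  img <- array(0, dim = c(nrow(cells), ncol(cells), 3))
  img[, , 1] <- cells        # red channel: cooperators
  img[, , 3] <- 1 - cells    # blue channel: defectors
  png::writePNG(img, path)
  invisible(path)
}
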