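#' Read / write connectomes as delimited text
#'
#' A connectome is stored as a TAB-delimited square weight matrix, with
#' a sidecar label file (one label per line) and an optional 4-column
#' coordinates file (label, x, y, z).  Paths for the sidecars default to
#' `<path>.labels` and `<path>.coords`.
#'
#' @param path weight-matrix file.
#' @param labels_path,coords_path sidecar files; `NULL` uses the
#'   defaults, and a missing default sidecar is skipped.
#' @return a `connectome`.
#' @export
read_connectome <- function(path, labels_path = NULL, coords_path = NULL) {
  W <- as.matrix(read.table(path, header = FALSE))
  labels_path <- labels_path %||% paste0(path, ".labels")
  coords_path <- coords_path %||% paste0(path, ".coords")
  labels <- if (file.exists(labels_path)) {
    readLines(labels_path)
  } else NULL
  coords <- if (file.exists(coords_path)) {
    tb <- read.table(coords_path, header = FALSE,
                     col.names = c("label", "x", "y", "z"))
    as.matrix(tb[, c("x", "y", "z")])
  } else NULL
  dimnames(W) <- NULL
  validate_connectome(W, labels, coords)
}

#' @rdname read_connectome
#' @param c a `connectome` to write.
#' @export
write_connectome <- function(c, path, labels_path = NULL,
                             coords_path = NULL) {
  stopifnot(inherits(c, "connectome"))
  write.table(format(c$weights, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  writeLines(c$labels, labels_path %||% paste0(path, ".labels"))
  if (!is.null(c$coordinates)) {
    df <- data.frame(label = c$labels, c$coordinates)
    write.table(df, coords_path %||% paste0(path, ".coords"), sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  invisible(path)
}

#' Read / write receptor maps as two-column TSV (label, value)
#'
#' The stored value is the raw density; normalisation is re-applied on
#' read so the map round-trips through [normalise_receptor_map()].
#'
#' @param path file path.
#' @return a `receptor_map`.
#' @export
read_receptor_map <- function(path) {
  tb <- read.table(path, header = FALSE, col.names = c("label", "value"))
  normalise_receptor_map(tb$value, labels = tb$label)
}

#' @rdname read_receptor_map
#' @param map a `receptor_map` to write.
#' @export
write_receptor_map <- function(map, path) {
  stopifnot(inherits(map, "receptor_map"))
  write.table(data.frame(map$labels, map$raw), path, sep = "\t",
              quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read / write BOLD time series as region-by-time TSV
#'
#' Header comment lines carry the metadata (`#TR <seconds>`); data rows
#' are one region per line, label first.
#'
#' @param path file path.
#' @return a `bold_ts`.
#' @export
read_bold <- function(path) {
  hdr <- readLines(path, n = 5)
  tr_line <- grep("^#TR", hdr, value = TRUE)
  if (length(tr_line) == 0) stop("missing #TR header in ", path)
  TR <- as.numeric(sub("^#TR\\s+", "", tr_line[1]))
  tb <- read.table(path, header = FALSE, comment.char = "#")
  labels <- as.character(tb[[1]])
  sig <- as.matrix(tb[, -1])
  dimnames(sig) <- NULL
  bold_ts(sig, TR = TR, labels = labels)
}

#' @rdname read_bold
#' @param b a `bold_ts` to write.
#' @export
write_bold <- function(b, path) {
  stopifnot(inherits(b, "bold_ts"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste("#TR", attr(b, "TR")), con)
  df <- data.frame(attr(b, "labels"),
                   format(unclass(b), digits = 17, trim = TRUE))
  write.table(df, con, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Write an FCD matrix or sample as TSV
#'
#' Matrices are written as plain window-by-window tables; samples as
#' two-column (value, lag) tables.
#'
#' @param x an `fcd_matrix` or `fcd_sample`.
#' @param path file path.
#' @export
write_fcd <- function(x, path) {
  if (inherits(x, "fcd_matrix")) {
    write.table(unclass(x), path, sep = "\t", quote = FALSE,
                row.names = FALSE, col.names = FALSE)
  } else if (inherits(x, "fcd_sample")) {
    write.table(data.frame(x$values, x$lags), path, sep = "\t",
                quote = FALSE, row.names = FALSE, col.names = FALSE)
  } else stop("x must be an fcd_matrix or fcd_sample")
  invisible(path)
}

#' @rdname write_fcd
#' @return `read_fcd_sample` returns an `fcd_sample`.
#' @export
read_fcd_sample <- function(path) {
  tb <- read.table(path, header = FALSE)
  structure(list(values = tb[[1]],
                 lags = if (ncol(tb) > 1) tb[[2]]
                        else rep(NA_real_, nrow(tb))),
            class = "fcd_sample")
}
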