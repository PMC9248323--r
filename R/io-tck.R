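#' Write a tractogram in MRtrix TCK format
#'
#' Float32 little-endian triplets with NaN streamline separators and an
#' Inf end-of-file marker; coordinates are written in world mm as stored.
#' Bundle labels, when present, go to a sidecar CSV keyed by 1-based
#' streamline index.
#'
#' @param tracts a [tractogram()].
#' @param path output `.tck` path.
#' @param labels_path optional CSV path for the streamline labels
#'   (defaults to `path` with a `_labels.csv` suffix when labels exist).
#' @return `path`, invisibly.
#' @export
write_tck <- function(tracts, path,
                      labels_path = sub("\\.tck$", "_labels.csv", path)) {
  stopifnot(inherits(tracts, "tractogram"))
  n <- length(tracts$streamlines)
  body <- paste0("mrtrix tracks\ndatatype: Float32LE\ncount: ", n, "\n")
  # the 'file' line states the byte offset of the binary section, which
  # depends on its own length; a second pass settles the fixed point
  offset <- nchar(body) + nchar("file: . \nEND\n") + 1
  for (i in 1:3) {
    header <- paste0(body, "file: . ", offset, "\nEND\n")
    if (nchar(header) == offset) break
    offset <- nchar(header)
  }
  con <- file(path, "wb")
  on.exit(close(con))
  writeChar(header, con, eos = NULL)
  for (s in tracts$streamlines) {
    writeBin(as.numeric(t(s)), con, size = 4, endian = "little")
    writeBin(rep(NaN, 3), con, size = 4, endian = "little")
  }
  writeBin(rep(Inf, 3), con, size = 4, endian = "little")
  if (!is.null(tracts$labels)) {
    utils::write.csv(data.frame(streamline = seq_len(n), label = tracts$labels),
                     labels_path, row.names = FALSE)
  }
  invisible(path)
}

#' Read a tractogram from MRtrix TCK format
#'
#' @param path `.tck` file.
#' @param labels_path optional labels CSV (`streamline,label`); the label
#'   count must match the streamline count.
#' @return a [tractogram()] with points in world mm.
#' @export
read_tck <- function(path, labels_path = NULL) {
  if (!file.exists(path) || file.size(path) == 0) {
    stop("empty or missing TCK file: ", path)
  }
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1L)
  if (!identical(magic, "mrtrix tracks")) stop("not a TCK file: ", path)
  offset <- NA
  datatype <- "Float32LE"
  repeat {
    line <- readLines(con, n = 1L)
    if (length(line) == 0L) stop("truncated TCK header in ", path)
    if (line == "END") break
    kv <- strsplit(line, ": ", fixed = TRUE)[[1]]
    if (kv[1] == "file") offset <- as.integer(strsplit(trimws(kv[2]), " ")[[1]][2])
    if (kv[1] == "datatype") datatype <- trimws(kv[2])
  }
  if (is.na(offset)) stop("TCK header has no 'file' entry in ", path)
  if (datatype != "Float32LE") stop("unsupported TCK datatype: ", datatype)
  seek(con, offset)
  n_float <- (file.size(path) - offset) / 4
  raw <- readBin(con, numeric(), n = n_float, size = 4, endian = "little")
  m <- matrix(raw, ncol = 3, byrow = TRUE)
  ends <- which(!is.finite(m[, 1]))
  streamlines <- list()
  start <- 1L
  for (e in ends) {
    if (is.infinite(m[e, 1])) break
    if (e > start) {
      streamlines[[length(streamlines) + 1L]] <- m[start:(e - 1L), , drop = FALSE]
    }
    start <- e + 1L
  }
  labels <- NULL
  if (!is.null(labels_path)) {
    lab <- utils::read.csv(labels_path)
    if (nrow(lab) != length(streamlines)) {
      stop("label count (", nrow(lab), ") does not match streamline count (",
           length(streamlines), ")")
    }
    labels <- as.character(lab$label[order(lab$streamline)])
  }
  tractogram(streamlines, labels)
}
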