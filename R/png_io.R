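# Minimal PNG codec: 8-bit RGB, no interlace, filter type 0 on every
# scanline. Writing is byte-deterministic (no timestamps, fixed zlib
# settings); reading supports exactly the subset this package writes.
# No PNG bindings for R are available on the target system, and
# byte-stable image output is part of the reproducibility contract.

.pkg_env <- new.env(parent = emptyenv())

.crc32 <- function(body) {
  hex <- digest::digest(body, algo = "crc32", serialize = FALSE)
  hex <- paste0(strrep("0", 8L - nchar(hex)), hex)
  sum(strtoi(substring(hex, c(1, 3, 5, 7), c(2, 4, 6, 8)), 16L) *
        c(16777216, 65536, 256, 1))
}

.u32 <- function(x) {
  x <- as.numeric(x)
  as.raw(c(x %/% 16777216, (x %/% 65536) %% 256, (x %/% 256) %% 256, x %% 256))
}

.chunk <- function(type, data) {
  body <- c(charToRaw(type), data)
  c(.u32(length(data)), body, .u32(.crc32(body)))
}

#' Write an image array as a PNG file
#'
#' @param img numeric array `H x W x 3` with values in `[0, 1]`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_png <- function(img, path) {
  stopifnot(length(dim(img)) == 3, dim(img)[3] == 3)
  h <- dim(img)[1]; w <- dim(img)[2]
  px <- as.integer(round(clamp(img, 0, 1) * 255))
  rgb <- aperm(array(px, dim(img)), c(3, 2, 1))  # (channel, col, row)
  bytes <- as.raw(as.vector(rgb))
  rowlen <- 3L * w + 1L
  lines <- raw(rowlen * h)
  starts <- (seq_len(h) - 1L) * rowlen
  keep <- rep(TRUE, rowlen * h)
  keep[starts + 1L] <- FALSE            # filter bytes stay 0x00
  lines[keep] <- bytes
  idat <- memCompress(lines, type = "gzip")   # zlib stream
  ihdr <- c(.u32(w), .u32(h), as.raw(c(8, 2, 0, 0, 0)))
  out <- c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
           .chunk("IHDR", ihdr), .chunk("IDAT", idat),
           .chunk("IEND", raw(0)))
  writeBin(out, path)
  invisible(path)
}

#' Read a PNG file written by [write_png()]
#'
#' @param path PNG file path.
#' @return numeric array `H x W x 3`, values in `[0, 1]`.
#' @export
read_png <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  if (!identical(raw[1:8], as.raw(c(137, 80, 78, 71, 13, 10, 26, 10))))
    stopf("not a PNG file: %s", path)
  pos <- 9L
  w <- h <- NULL; idat_parts <- list()
  n <- length(raw)
  u32at <- function(i) sum(as.numeric(raw[i:(i + 3)]) * c(16777216, 65536, 256, 1))
  while (pos <= n - 7L) {
    len <- u32at(pos)
    type <- rawToChar(raw[(pos + 4L):(pos + 7L)])
    data_from <- pos + 8L
    if (type == "IHDR") {
      w <- u32at(data_from); h <- u32at(data_from + 4L)
      bitdepth <- as.integer(raw[data_from + 8L])
      colortype <- as.integer(raw[data_from + 9L])
      if (bitdepth != 8L || colortype != 2L)
        stopf("unsupported PNG subtype (need 8-bit RGB): %s", path)
    } else if (type == "IDAT") {
      if (len > 0)
        idat_parts[[length(idat_parts) + 1L]] <- raw[data_from:(data_from + len - 1L)]
    } else if (type == "IEND") break
    pos <- pos + 12L + len
  }
  if (is.null(w)) stopf("corrupt PNG (no IHDR): %s", path)
  lines <- memDecompress(do.call(c, idat_parts), type = "gzip")
  rowlen <- 3L * w + 1L
  if (any(as.integer(lines[seq(1L, length(lines), by = rowlen)]) != 0L))
    stopf("unsupported PNG scanline filter in %s", path)
  keep <- rep(TRUE, length(lines))
  keep[seq(1L, length(lines), by = rowlen)] <- FALSE
  rgb <- as.integer(lines[keep]) / 255
  aperm(array(rgb, c(3, w, h)), c(3, 2, 1))
}
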