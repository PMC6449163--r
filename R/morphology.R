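#' Reconstructed neuronal morphology
#'
#' Wraps an SWC-style node table: one row per node with an integer id, a
#' structure type code (1 soma, 2 axon, 3 basal dendrite, 4 apical
#' dendrite), xyz coordinates and radius in micrometers, and the parent
#' id (-1 for the root). "Dendrite" throughout the package means type 3
#' or 4.
#'
#' @param nodes data.frame with columns `id`, `type`, `x`, `y`, `z`,
#'   `radius`, `parent`.
#' @return Object of class `"morphology"`.
#' @export
morphology <- function(nodes) {
  req <- c("id", "type", "x", "y", "z", "radius", "parent")
  if (!is.data.frame(nodes) || !all(req %in% names(nodes)))
    stop("morphology: nodes must be a data.frame with columns ",
         paste(req, collapse = ", "))
  nodes <- nodes[, req]
  if (nrow(nodes) == 0L) stop("morphology: empty node table")
  if (anyDuplicated(nodes$id))
    stop("morphology: duplicate node id ",
         nodes$id[duplicated(nodes$id)][1])
  roots <- which(nodes$parent == -1)
  if (length(roots) != 1L)
    stop("morphology: expected exactly one root (parent -1), found ",
         length(roots))
  nonroot <- nodes$parent != -1
  missing_parent <- !(nodes$parent[nonroot] %in% nodes$id)
  if (any(missing_parent)) {
    bad <- nodes$parent[nonroot][missing_parent][1]
    stop("morphology: dangling parent id ", bad)
  }
  if (any(nodes$radius < 0)) stop("morphology: negative radius")
  structure(list(nodes = nodes, soma_id = nodes$id[roots]),
            class = "morphology")
}

#' @export
print.morphology <- function(x, ...) {
  nd <- x$nodes
  cat(sprintf("<morphology> %d nodes (%d dendritic), root id %d\n",
              nrow(nd), sum(nd$type %in% c(3, 4)), x$soma_id))
  invisible(x)
}

#' Read an SWC morphology file
#'
#' Parses the standard whitespace-delimited 7-column SWC dialect
#' (`id type x y z radius parent`); lines starting with `#` are comments.
#' Parse errors report the offending line number.
#'
#' @param path Path to an SWC file.
#' @return A [morphology()].
#' @export
read_swc <- function(path) {
  if (!file.exists(path)) stop("read_swc: file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", lines))
  if (length(keep) == 0L) stop("read_swc: no data lines in ", path)
  rows <- vector("list", length(keep))
  for (k in seq_along(keep)) {
    ln <- keep[k]
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1]]
    if (length(fields) < 7L)
      stop(sprintf("read_swc: line %d has %d column(s), expected 7",
                   ln, length(fields)))
    vals <- suppressWarnings(as.numeric(fields[1:7]))
    if (anyNA(vals))
      stop(sprintf("read_swc: line %d has a non-numeric field", ln))
    rows[[k]] <- vals
  }
  m <- do.call(rbind, rows)
  nodes <- data.frame(id = as.integer(m[, 1]), type = as.integer(m[, 2]),
                      x = m[, 3], y = m[, 4], z = m[, 5],
                      radius = m[, 6], parent = as.integer(m[, 7]))
  tryCatch(morphology(nodes),
           error = function(e) stop("read_swc: ", conditionMessage(e),
                                    call. = FALSE))
}

#' Write a morphology as SWC
#' @param m A [morphology()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_swc <- function(m, path) {
  stopifnot(inherits(m, "morphology"))
  nd <- m$nodes
  lines <- sprintf("%d %d %.9g %.9g %.9g %.9g %d",
                   nd$id, nd$type, nd$x, nd$y, nd$z, nd$radius, nd$parent)
  writeLines(c("# SWC written by dvca1", lines), path)
  invisible(path)
}

#' 16-bit grayscale image container
#'
#' A rectangular grid of non-negative integer pixel values on the 16-bit
#' range, stored as a numeric matrix (rows = image rows, top to bottom).
#' By acquisition convention 0 is black and lighter values indicate more
#' immunoreactive protein.
#'
#' @param pixels Numeric matrix of values in \[0, 65535\].
#' @param pixel_size Optional micrometers per pixel.
#' @return Object of class `"gray_image"`.
#' @export
gray_image <- function(pixels, pixel_size = NULL) {
  if (!is.matrix(pixels) || !is.numeric(pixels))
    stop("gray_image: pixels must be a numeric matrix")
  if (any(!is.finite(pixels)) || any(pixels < 0) || any(pixels > 65535))
    stop("gray_image: pixel values must be finite and in [0, 65535]")
  structure(list(pixels = pixels, pixel_size = pixel_size),
            class = "gray_image")
}

#' @export
print.gray_image <- function(x, ...) {
  cat(sprintf("<gray_image> %d x %d px, range [%g, %g]\n",
              nrow(x$pixels), ncol(x$pixels),
              min(x$pixels), max(x$pixels)))
  invisible(x)
}

#' Read a 16-bit grayscale image (TIFF or PNG)
#' @param path Path to a `.tif`/`.tiff` or `.png` file.
#' @param pixel_size Optional micrometers per pixel to attach.
#' @return A [gray_image()].
#' @export
read_gray_image <- function(path, pixel_size = NULL) {
  if (!file.exists(path)) stop("read_gray_image: file not found: ", path)
  ext <- tolower(tools::file_ext(path))
  px <- switch(ext,
    tif = , tiff = {
      img <- tiff::readTIFF(path, as.is = TRUE)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      img
    },
    png = {
      img <- png::readPNG(path)
      if (length(dim(img)) == 3L) img <- img[, , 1]
      round(img * 65535)
    },
    stop("read_gray_image: unsupported extension '", ext,
         "' (use tif/tiff/png)")
  )
  gray_image(px, pixel_size = pixel_size)
}

#' Write a 16-bit grayscale image
#'
#' TIFF output goes through the tiff package; PNG output uses an
#' internal minimal 16-bit grayscale encoder (the png package writes
#' only 8 bits per sample), so both formats round-trip the full 16-bit
#' range exactly.
#'
#' @param img A [gray_image()].
#' @param path Output path ending in `.tif`, `.tiff`, or `.png`.
#' @return `path`, invisibly.
#' @export
write_gray_image <- function(img, path) {
  stopifnot(inherits(img, "gray_image"))
  ext <- tolower(tools::file_ext(path))
  switch(ext,
    tif = , tiff = tiff::writeTIFF(img$pixels / 65535, path,
                                   bits.per.sample = 16),
    png = write_png16(img$pixels, path),
    stop("write_gray_image: unsupported extension '", ext, "'")
  )
  invisible(path)
}

# --- minimal 16-bit grayscale PNG encoder -------------------------------

# CRC-32 (PNG/zlib polynomial), table-driven.
.crc32_table <- local({
  tab <- integer(256)
  for (n in 0:255) {
    c <- n
    for (k in 1:8)
      c <- if (bitwAnd(c, 1L) != 0L)
        bitwXor(bitwShiftR(c, 1), -306674912L) else bitwShiftR(c, 1)
    tab[n + 1] <- c
  }
  tab
})

crc32 <- function(bytes) {
  crc <- -1L
  for (x in as.integer(bytes))
    crc <- bitwXor(.crc32_table[bitwAnd(bitwXor(crc, x), 255L) + 1L],
                   bitwShiftR(crc, 8))
  bitwXor(crc, -1L)
}

# unsigned 32-bit big-endian bytes (accepts R's signed-int bit patterns)
u32be <- function(x) {
  x <- as.numeric(x) %% 4294967296
  as.raw(c(x %/% 16777216, x %/% 65536 %% 256, x %/% 256 %% 256,
           x %% 256))
}

write_png16 <- function(px, path) {
  m <- round(px)
  nr <- nrow(m); nc <- ncol(m)
  # scanlines: filter byte 0, then big-endian 16-bit samples
  lines <- matrix(0L, nrow = 1L + 2L * nc, ncol = nr)
  lines[2L * seq_len(nc), ] <- t(m %/% 256)
  lines[2L * seq_len(nc) + 1L, ] <- t(m %% 256)
  scan <- as.raw(as.vector(lines))
  # memCompress's "gzip" type emits an RFC-1950 zlib stream (0x78
  # header with an Adler-32 trailer), which is exactly the IDAT payload
  # PNG requires
  zlib <- memCompress(scan, type = "gzip")
  if (zlib[1] != as.raw(0x78))
    stop("write_png16: expected a zlib stream from memCompress")
  chunk <- function(type, data) {
    tr <- charToRaw(type)
    c(u32be(length(data)), tr, data, u32be(crc32(c(tr, data))))
  }
  ihdr <- c(u32be(nc), u32be(nr),
            as.raw(c(16, 0, 0, 0, 0)))  # 16-bit grayscale, no interlace
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(c(137, 80, 78, 71, 13, 10, 26, 10)),
             chunk("IHDR", ihdr), chunk("IDAT", zlib),
             chunk("IEND", raw(0))), con)
  invisible(path)
}
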