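#' Write a multi-page 16-bit grayscale TIFF
#'
#' Minimal uncompressed little-endian baseline TIFF writer for integer
#' image stacks in `[0, 65535]`.  One page per frame; each page is stored
#' as a single strip.
#'
#' @param stack numeric array `[H, W, T]` (or an `[H, W]` matrix); values
#'   are rounded and clamped to the 16-bit range.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tiff <- function(stack, path) {
  if (length(dim(stack)) == 2) dim(stack) <- c(dim(stack), 1)
  stopifnot(length(dim(stack)) == 3)
  H <- dim(stack)[1]; W <- dim(stack)[2]; TT <- dim(stack)[3]
  v <- round(stack); v[v < 0] <- 0; v[v > 65535] <- 65535
  storage.mode(v) <- "integer"

  con <- file(path, "wb")
  on.exit(close(con))
  w2 <- function(x) writeBin(as.integer(x), con, size = 2, endian = "little")
  w4 <- function(x) writeBin(as.integer(x), con, size = 4, endian = "little")

  # header: II, magic 42, offset of first IFD
  writeBin(charToRaw("II"), con)
  w2(42L)
  n_entries <- 9L
  ifd_size <- 2 + n_entries * 12 + 4
  data_size <- H * W * 2
  # layout: [8-byte header][page1 data][page1 IFD][page2 data][page2 IFD]...
  first_data <- 8L
  w4(first_data + data_size)  # offset of first IFD

  entry <- function(tag, type, count, value) {
    w2(tag); w2(type); w4(count)
    if (type == 3 && count == 1) { w2(value); w2(0L) } else w4(value)
  }

  offset <- first_data
  for (t in seq_len(TT)) {
    # pixel data, row-major within the page
    page <- t(v[, , t])           # transpose: TIFF rows are image rows
    pix <- as.integer(page)
    raw2 <- as.raw(rbind(pix %% 256L, pix %/% 256L))
    writeBin(raw2, con)
    ifd_off <- offset + data_size
    next_ifd <- if (t < TT) ifd_off + ifd_size + data_size else 0L
    w2(n_entries)
    entry(256L, 3L, 1L, W)            # ImageWidth
    entry(257L, 3L, 1L, H)            # ImageLength
    entry(258L, 3L, 1L, 16L)          # BitsPerSample
    entry(259L, 3L, 1L, 1L)           # Compression: none
    entry(262L, 3L, 1L, 1L)          # Photometric: BlackIsZero
    entry(273L, 4L, 1L, offset)       # StripOffsets
    entry(277L, 3L, 1L, 1L)           # SamplesPerPixel
    entry(278L, 3L, 1L, H)            # RowsPerStrip
    entry(279L, 4L, 1L, data_size)    # StripByteCounts
    w4(next_ifd)
    offset <- ifd_off + ifd_size
  }
  invisible(path)
}

#' Read a multi-page grayscale TIFF
#'
#' Reads uncompressed little-endian grayscale TIFFs with 8 or 16 bits per
#' sample (the subset [write_tiff()] produces, which also covers typical
#' raw camera exports).
#'
#' @param path TIFF file path.
#' @return Numeric array `[H, W, T]`.
#' @export
read_tiff <- function(path) {
  raw <- readBin(path, "raw", file.info(path)$size)
  u16 <- function(off) as.integer(raw[off + 1]) + 256L * as.integer(raw[off + 2])
  u32 <- function(off) {
    as.numeric(as.integer(raw[off + 1])) + 256 * as.integer(raw[off + 2]) +
      65536 * as.integer(raw[off + 3]) + 16777216 * as.integer(raw[off + 4])
  }
  if (rawToChar(raw[1:2]) != "II") stop("only little-endian TIFF supported")
  if (u16(2) != 42L) stop("not a TIFF file")
  ifd <- u32(4)
  frames <- list()
  while (ifd != 0) {
    n <- u16(ifd)
    tags <- list()
    for (e in seq_len(n)) {
      off <- ifd + 2 + (e - 1) * 12
      tag <- u16(off); type <- u16(off + 2); count <- u32(off + 4)
      val <- if (type == 3) u16(off + 8) else u32(off + 8)
      # multi-valued offsets (several strips) -> resolve first value
      if (count > 1) {
        ptr <- u32(off + 8)
        val <- if (type == 3) u16(ptr) else u32(ptr)
        attr(val, "ptr") <- ptr; attr(val, "count") <- count
        attr(val, "type") <- type
      }
      tags[[as.character(tag)]] <- val
    }
    W <- tags[["256"]]; H <- tags[["257"]]
    bits <- if (is.null(tags[["258"]])) 1L else tags[["258"]]
    comp <- if (is.null(tags[["259"]])) 1L else tags[["259"]]
    if (comp != 1) stop("compressed TIFF not supported")
    if (!bits %in% c(8L, 16L)) stop("only 8/16-bit grayscale supported")
    strip_off <- tags[["273"]]
    n_strips <- if (is.null(attr(strip_off, "count"))) 1L
                else attr(strip_off, "count")
    offs <- if (n_strips == 1) as.numeric(strip_off) else {
      ptr <- attr(strip_off, "ptr"); typ <- attr(strip_off, "type")
      sz <- if (typ == 3) 2 else 4
      sapply(seq_len(n_strips) - 1, function(i)
        if (typ == 3) u16(ptr + i * sz) else u32(ptr + i * sz))
    }
    counts_tag <- tags[["279"]]
    cnts <- if (is.null(attr(counts_tag, "count"))) as.numeric(counts_tag) else {
      ptr <- attr(counts_tag, "ptr"); typ <- attr(counts_tag, "type")
      sz <- if (typ == 3) 2 else 4
      sapply(seq_len(attr(counts_tag, "count")) - 1, function(i)
        if (typ == 3) u16(ptr + i * sz) else u32(ptr + i * sz))
    }
    bytes <- unlist(lapply(seq_along(offs), function(i)
      raw[(offs[i] + 1):(offs[i] + cnts[i])]))
    if (bits == 16L) {
      m <- matrix(as.integer(bytes), nrow = 2)
      pix <- m[1, ] + 256L * m[2, ]
    } else pix <- as.integer(bytes)
    frames[[length(frames) + 1]] <- t(matrix(pix, nrow = W, ncol = H))
    ifd <- u32(ifd + 2 + n * 12)
  }
  H <- nrow(frames[[1]]); W <- ncol(frames[[1]])
  arr <- array(0, c(H, W, length(frames)))
  for (t in seq_along(frames)) arr[, , t] <- frames[[t]]
  arr
}
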