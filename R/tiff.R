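# Minimal baseline TIFF support: uncompressed single-sample (grayscale)
# images, 8 or 16 bits per sample, multi-page via the IFD chain. Reading
# handles both byte orders and multi-strip files; writing emits little-endian
# single-strip pages. This exists because no TIFF package is available in the
# target library; the subset matches what tifffile/ImageJ write for plain
# grayscale stacks.

tiff_u16 <- function(r, off, little) {
  a <- as.integer(r[off + 1L]); b <- as.integer(r[off + 2L])
  if (little) a + 256L * b else b + 256L * a
}

tiff_u32 <- function(r, off, little) {
  v <- as.numeric(as.integer(r[off + 1:4]))
  if (little) sum(v * c(1, 256, 65536, 16777216)) else sum(rev(v) * c(1, 256, 65536, 16777216))
}

# Read `count` values of a given TIFF field type, inline or at an offset.
tiff_values <- function(r, type, count, value_off, little) {
  size <- switch(as.character(type), "1" = 1L, "3" = 2L, "4" = 4L,
                 stop("unsupported TIFF field type ", type))
  total <- size * count
  base <- if (total <= 4) value_off else tiff_u32(r, value_off, little)
  vapply(seq_len(count) - 1L, function(k) {
    o <- base + k * size
    switch(as.character(type),
           "1" = as.numeric(r[o + 1L]),
           "3" = as.numeric(tiff_u16(r, o, little)),
           "4" = tiff_u32(r, o, little))
  }, numeric(1))
}

# Returns list(pages = list of integer matrices (H x W), bits)
read_tiff <- function(path) {
  r <- readBin(path, what = "raw", n = file.size(path))
  if (length(r) < 8L) stop("not a TIFF file (too short): ", path)
  byte_order <- rawToChar(r[1:2])
  little <- byte_order == "II"
  if (!little && byte_order != "MM") stop("not a TIFF file (bad byte order mark): ", path)
  if (tiff_u16(r, 2L, little) != 42L) stop("not a TIFF file (bad magic): ", path)
  ifd_off <- tiff_u32(r, 4L, little)
  pages <- list()
  bits_seen <- integer(0)
  page <- 0L
  while (ifd_off != 0) {
    page <- page + 1L
    n_entries <- tiff_u16(r, ifd_off, little)
    tags <- list()
    for (e in seq_len(n_entries)) {
      eo <- ifd_off + 2L + (e - 1L) * 12L
      tag <- tiff_u16(r, eo, little)
      type <- tiff_u16(r, eo + 2L, little)
      count <- tiff_u32(r, eo + 4L, little)
      if (type %in% c(1L, 3L, 4L)) {
        tags[[as.character(tag)]] <- tiff_values(r, type, count, eo + 8L, little)
      }
    }
    g <- function(tag, default = NULL) {
      v <- tags[[as.character(tag)]]
      if (is.null(v)) default else v
    }
    W <- g(256); H <- g(257)
    if (is.null(W) || is.null(H)) stop("TIFF page ", page, " lacks image dimensions: ", path)
    bits <- g(258, 8)[1]
    if (!bits %in% c(8, 16))
      stop("TIFF page ", page, " has unsupported bit depth ", bits, ": ", path)
    if (g(259, 1) != 1)
      stop("TIFF page ", page, " is compressed (only uncompressed supported): ", path)
    if (g(277, 1) != 1)
      stop("TIFF page ", page, " is not single-channel grayscale: ", path)
    if (g(339, 1) != 1)
      stop("TIFF page ", page, " has non-integer sample format: ", path)
    offsets <- g(273); counts <- g(279)
    if (is.null(offsets)) stop("TIFF page ", page, " lacks strip offsets: ", path)
    if (is.null(counts)) counts <- H * W * bits / 8
    buf <- raw(0)
    for (s in seq_along(offsets)) {
      buf <- c(buf, r[(offsets[s] + 1):(offsets[s] + counts[s])])
    }
    need <- H * W * bits / 8
    if (length(buf) < need)
      stop("TIFF page ", page, " pixel data truncated: ", path)
    buf <- buf[seq_len(need)]
    if (bits == 8) {
      v <- as.integer(buf)
    } else {
      m <- matrix(as.integer(buf), nrow = 2L)
      v <- if (little) m[1L, ] + 256L * m[2L, ] else m[2L, ] + 256L * m[1L, ]
    }
    pages[[page]] <- t(matrix(v, nrow = W))  # data is row-major
    bits_seen <- c(bits_seen, as.integer(bits))
    ifd_off <- tiff_u32(r, ifd_off + 2L + n_entries * 12L, little)
  }
  if (length(pages) == 0L) stop("TIFF has no pages: ", path)
  if (length(unique(bits_seen)) != 1L)
    stop("TIFF pages have mixed bit depths: ", path)
  list(pages = pages, bits = bits_seen[1])
}

tiff_raw_u16 <- function(v) {
  as.raw(rbind(v %% 256L, v %/% 256L))
}

tiff_raw_u32 <- function(v) {
  v <- as.numeric(v)
  as.raw(rbind(v %% 256, (v %/% 256) %% 256, (v %/% 65536) %% 256, v %/% 16777216))
}

tiff_entry <- function(tag, type, count, value) {
  # type 3 = SHORT (inline, zero-padded), 4 = LONG
  val <- if (type == 3L) c(tiff_raw_u16(value), as.raw(c(0, 0))) else tiff_raw_u32(value)
  c(tiff_raw_u16(tag), tiff_raw_u16(type), tiff_raw_u32(count), val)
}

# pages: list of integer matrices sharing one (H, W); bits: 8 or 16.
write_tiff <- function(pages, path, bits) {
  stopifnot(bits %in% c(8L, 16L), length(pages) >= 1L)
  H <- nrow(pages[[1]]); W <- ncol(pages[[1]])
  bytes_per_page <- H * W * bits / 8
  n <- length(pages)
  n_entries <- 9L
  ifd_size <- 2L + n_entries * 12L + 4L
  # layout: 8-byte header, then all pixel data blocks, then all IFDs
  data_off <- 8 + bytes_per_page * (seq_len(n) - 1)
  ifd_base <- 8 + bytes_per_page * n
  ifd_off <- ifd_base + ifd_size * (seq_len(n) - 1)
  out <- c(charToRaw("II"), tiff_raw_u16(42L), tiff_raw_u32(ifd_off[1]))
  for (k in seq_len(n)) {
    m <- pages[[k]]
    if (nrow(m) != H || ncol(m) != W)
      stop("page ", k, " has shape ", nrow(m), "x", ncol(m),
           " but page 1 has ", H, "x", W)
    v <- as.integer(t(m))  # row-major
    out <- c(out, if (bits == 8) as.raw(v) else tiff_raw_u16(v))
  }
  for (k in seq_len(n)) {
    nxt <- if (k < n) ifd_off[k + 1] else 0
    ifd <- c(tiff_raw_u16(n_entries),
             tiff_entry(256L, 4L, 1L, W),
             tiff_entry(257L, 4L, 1L, H),
             tiff_entry(258L, 3L, 1L, bits),
             tiff_entry(259L, 3L, 1L, 1L),   # uncompressed
             tiff_entry(262L, 3L, 1L, 1L),   # BlackIsZero
             tiff_entry(273L, 4L, 1L, data_off[k]),
             tiff_entry(277L, 3L, 1L, 1L),
             tiff_entry(278L, 4L, 1L, H),
             tiff_entry(279L, 4L, 1L, bytes_per_page),
             tiff_raw_u32(nxt))
    out <- c(out, ifd)
  }
  writeBin(out, path)
  invisible(path)
}
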