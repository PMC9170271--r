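# Minimal NPY v1.0 reader/writer for 2-D little-endian float arrays,
# with transparent gzip support.  Covers exactly the packed benchmark
# array format (N x 39900 doubles or floats, C order); no other dtypes.

open_binary <- function(path, mode) {
  if (grepl("\\.gz$", path)) gzfile(path, mode) else file(path, mode)
}

#' Read a 2-D NPY array
#'
#' Reads an NPY (version 1.0) file holding a two-dimensional
#' little-endian `float32` or `float64` array, optionally
#' gzip-compressed (`.npy.gz`).
#'
#' @param path Path to the `.npy` or `.npy.gz` file.
#' @return Numeric matrix.
#' @export
read_npy_matrix <- function(path) {
  con <- open_binary(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (length(magic) < 6L ||
      !identical(magic, as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59)))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  if (as.integer(ver[1]) != 1L) stop("unsupported NPY version: ", as.integer(ver[1]))
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- regmatches(header, regexpr("'descr':\\s*'[^']+'", header))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", descr)
  if (!descr %in% c("<f8", "<f4")) stop("unsupported NPY dtype: ", descr)
  if (grepl("'fortran_order':\\s*True", header)) stop("Fortran-order NPY not supported")
  shape <- regmatches(header, regexpr("'shape':\\s*\\(([^)]*)\\)", header))
  dims <- as.integer(strsplit(gsub("[^0-9,]", "", shape), ",")[[1]])
  if (length(dims) != 2L) stop("expected a 2-D NPY array, got shape (", shape, ")")
  sz <- if (descr == "<f8") 8L else 4L
  vals <- readBin(con, "numeric", n = prod(dims), size = sz, endian = "little")
  if (length(vals) != prod(dims)) stop("truncated NPY payload in ", path)
  # C order: rows are contiguous
  matrix(vals, nrow = dims[1], ncol = dims[2], byrow = TRUE)
}

#' Write a 2-D NPY array
#'
#' Writes a numeric matrix as an NPY (version 1.0) little-endian
#' `float64` array in C order; gzip-compresses when `path` ends in
#' `.gz`.
#'
#' @param x Numeric matrix.
#' @param path Output path (`.npy` or `.npy.gz`).
#' @return `path`, invisibly.
#' @export
write_npy_matrix <- function(x, path) {
  stopifnot(is.matrix(x), is.numeric(x))
  header <- sprintf("{'descr': '<f8', 'fortran_order': False, 'shape': (%d, %d), }",
                    nrow(x), ncol(x))
  # pad so that 6 + 2 + 2 + header length is a multiple of 16, '\n' last
  total <- 10L + nchar(header) + 1L
  pad <- (16L - total %% 16L) %% 16L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- open_binary(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, 0x4e, 0x55, 0x4d, 0x50, 0x59, 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  writeBin(as.numeric(t(x)), con, size = 8L, endian = "little")
  invisible(path)
}
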