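# Minimal NPY (NumPy binary format, version 1.0) reader/writer for 2-d
# float32 arrays; used to exchange metric depth maps with Python tooling.

#' Read / write a matrix in NPY format
#'
#' Writes little-endian float32, Fortran (column-major) order, which is the
#' natural layout of an R matrix.  `read_npy()` accepts float32/float64 in
#' either order.
#'
#' @param x numeric matrix (NaN allowed, e.g. invalid depth pixels).
#' @param path file path.
#' @return `write_npy()`: `path` invisibly; `read_npy()`: a numeric matrix.
#' @export
write_npy <- function(x, path) {
  stopifnot(is.matrix(x))
  header <- sprintf(
    "{'descr': '<f4', 'fortran_order': True, 'shape': (%d, %d), }",
    nrow(x), ncol(x))
  # pad so magic(6) + version(2) + len(2) + header is a multiple of 64
  pad <- 64L - ((10L + nchar(header) + 1L) %% 64L)
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(as.raw(c(0x93, charToRaw("NUMPY"), 0x01, 0x00)), con)
  writeBin(as.integer(nchar(header)), con, size = 2, endian = "little")
  writeChar(header, con, eos = NULL)
  writeBin(as.numeric(x), con, size = 4, endian = "little")
  invisible(path)
}

#' @rdname write_npy
#' @export
read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 8)
  if (!identical(magic[1:6], as.raw(c(0x93, charToRaw("NUMPY")))))
    stop("not an NPY file: ", path)
  hlen <- readBin(con, "integer", 1, size = 2, endian = "little",
                  signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  m <- regmatches(header,
                  regexec("'descr':\\s*'([^']+)'.*'fortran_order':\\s*(True|False).*\\((\\d+),\\s*(\\d+)\\)?", header))[[1]]
  if (length(m) != 5) stop("unsupported NPY header: ", header)
  descr <- m[2]
  fortran <- m[3] == "True"
  shape <- as.integer(m[4:5])
  size <- if (grepl("f4$", descr)) 4L else if (grepl("f8$", descr)) 8L else
    stop("unsupported dtype: ", descr)
  vals <- readBin(con, "numeric", prod(shape), size = size,
                  endian = "little")
  if (fortran) matrix(vals, shape[1], shape[2])
  else t(matrix(vals, shape[2], shape[1]))
}
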