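# Internal helpers shared across modules.

sigmoid <- function(x) 1 / (1 + exp(-x))

#' @noRd
`%||%` <- function(a, b) if (is.null(a)) b else a

# Robust SD estimate from the median absolute deviation; 0.6745 is the
# normal-consistency factor (MAD of N(0, s) equals 0.6745 s).
MAD_SCALE <- 0.6745

# Deterministic sub-seed derivation so that, e.g., changing the number of
# units does not perturb the force-generator stream. Plain string hash into
# [0, 2^31 - 2].
substream_seed <- function(seed, name) {
  h <- as.double(seed %% 2147483647L)
  for (code in utf8ToInt(name)) {
    h <- (h * 31 + code) %% 2147483647
  }
  as.integer(h)
}

with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  force(code)
}

assert_count <- function(x, name, min = 1L) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min || x != round(x)) {
    stop(sprintf("`%s` must be a whole number >= %d", name, min), call. = FALSE)
  }
  as.integer(x)
}

assert_scalar <- function(x, name, min = -Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < min) {
    stop(sprintf("`%s` must be a finite numeric scalar >= %g", name, min), call. = FALSE)
  }
  as.double(x)
}

# ---------------------------------------------------------------------------
# Minimal NPY v1.0 codec (C-order, little-endian). Supports the dtypes used
# by Phy-style sorter outputs (int64/int32) plus float64 for basis arrays.
# ---------------------------------------------------------------------------

npy_descr <- function(what) {
  switch(what,
    int64 = "<i8", int32 = "<i4", int16 = "<i2", float64 = "<f8",
    stop("unsupported npy dtype: ", what)
  )
}

write_npy <- function(x, path, dtype = c("float64", "int64", "int32", "int16")) {
  dtype <- match.arg(dtype)
  dims <- if (is.null(dim(x))) length(x) else dim(x)
  shape <- paste0("(", paste(dims, collapse = ", "), if (length(dims) == 1L) "," else "", ")")
  header <- sprintf("{'descr': '%s', 'fortran_order': False, 'shape': %s, }",
                    npy_descr(dtype), shape)
  # pad so magic+version+len+header is a multiple of 64, newline-terminated
  base_len <- 10L + nchar(header) + 1L
  pad <- (64L - base_len %% 64L) %% 64L
  header <- paste0(header, strrep(" ", pad), "\n")
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(as.raw(0x93), charToRaw("NUMPY"), as.raw(c(1L, 0L))), con)
  writeBin(as.integer(nchar(header)), con, size = 2L, endian = "little")
  writeBin(charToRaw(header), con)
  vals <- if (is.null(dim(x))) as.vector(x) else as.vector(aperm(x, rev(seq_along(dims))))
  if (dtype == "float64") {
    writeBin(as.double(vals), con, size = 8L, endian = "little")
  } else if (dtype == "int64") {
    # emulate non-negative int64 byte-wise (sample indices fit a double)
    if (any(vals < 0)) stop("int64 npy writer supports non-negative values")
    bytes <- matrix(0L, 8L, length(vals))
    rem <- as.double(vals)
    for (k in 1:8) {
      bytes[k, ] <- as.integer(rem %% 256)
      rem <- floor(rem / 256)
    }
    writeBin(as.raw(bytes), con)
  } else {
    writeBin(as.integer(vals), con, size = ifelse(dtype == "int32", 4L, 2L),
             endian = "little")
  }
  invisible(path)
}

read_npy <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 6L)
  if (!identical(magic, c(as.raw(0x93), charToRaw("NUMPY")))) {
    stop("not an NPY file: ", path)
  }
  ver <- readBin(con, "raw", 2L)
  hlen <- readBin(con, "integer", 1L, size = 2L, endian = "little", signed = FALSE)
  header <- rawToChar(readBin(con, "raw", hlen))
  descr <- sub(".*'descr':\\s*'([^']+)'.*", "\\1", header)
  fortran <- grepl("'fortran_order':\\s*True", header)
  shape_s <- sub(".*'shape':\\s*\\(([^)]*)\\).*", "\\1", header)
  dims <- as.integer(strsplit(gsub("\\s", "", shape_s), ",")[[1]])
  n <- prod(dims)
  vals <- switch(descr,
    "<f8" = readBin(con, "double", n, size = 8L, endian = "little"),
    "<f4" = readBin(con, "double", n, size = 4L, endian = "little"),
    "<i8" = {
      bytes <- matrix(as.integer(readBin(con, "raw", 8L * n)), nrow = 8L)
      colSums(bytes * 256^(0:7))              # non-negative sample indices
    },
    "<i4" = readBin(con, "integer", n, size = 4L, endian = "little"),
    "<i2" = readBin(con, "integer", n, size = 2L, endian = "little"),
    "|u1" = as.integer(readBin(con, "raw", n)),
    stop("unsupported npy descr: ", descr)
  )
  if (length(dims) > 1L) {
    if (fortran) {
      vals <- array(vals, dim = dims)
    } else {
      vals <- aperm(array(vals, dim = rev(dims)), rev(seq_along(dims)))
    }
  }
  vals
}
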