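# JData-style annotated N-D array codec.
#
# Dimension ordering: `_ArraySize_` is declared in row-major (C) order and
# the serialized payload streams the last declared dimension fastest. For a
# 3D volume declared [nx, ny, nz] the decoded R array has dim c(nx, ny, nz)
# and index (i, j, k) addresses voxel x = i, y = j, z = k. Byte order is
# little-endian throughout.

jd_types <- c(uint8 = 1L, int8 = 1L, uint16 = 2L, int16 = 2L,
              uint32 = 4L, int32 = 4L, single = 4L, double = 8L)

jd_int_range <- list(
  uint8  = c(0, 255),           int8  = c(-128, 127),
  uint16 = c(0, 65535),         int16 = c(-32768, 32767),
  uint32 = c(0, 4294967295),    int32 = c(-2147483648, 2147483647)
)

jd_validate <- function(v, dtype) {
  if (dtype %in% names(jd_int_range)) {
    if (any(!is.finite(v)))
      vmc_error("non-finite values cannot be converted to an integer type",
                "jd_conversion_error")
    if (any(v != round(v)))
      vmc_error("non-integral values cannot be converted to an integer type",
                "jd_conversion_error")
    rng <- jd_int_range[[dtype]]
    if (any(v < rng[1] | v > rng[2]))
      vmc_error(sprintf("values out of range for element type '%s'", dtype),
                "jd_conversion_error")
  }
  invisible(v)
}

# round-trip through IEEE float32, the declared precision of "single"
jd_to_float32 <- function(v) {
  readBin(writeBin(as.numeric(v), raw(), size = 4L, endian = "little"),
          "numeric", length(v), size = 4L, endian = "little")
}

jd_pack <- function(v, dtype) {
  v <- as.numeric(v)
  jd_validate(v, dtype)
  switch(dtype,
    uint8  = writeBin(as.integer(v), raw(), size = 1L, endian = "little"),
    int8   = writeBin(as.integer(v), raw(), size = 1L, endian = "little"),
    uint16 = writeBin(as.integer(v), raw(), size = 2L, endian = "little"),
    int16  = writeBin(as.integer(v), raw(), size = 2L, endian = "little"),
    uint32 = {
      u <- v %% 4294967296
      u <- ifelse(u >= 2147483648, u - 4294967296, u)
      writeBin(as.integer(u), raw(), size = 4L, endian = "little")
    },
    int32  = writeBin(as.integer(v), raw(), size = 4L, endian = "little"),
    single = writeBin(v, raw(), size = 4L, endian = "little"),
    double = writeBin(v, raw(), size = 8L, endian = "little")
  )
}

jd_unpack <- function(bytes, dtype, n) {
  switch(dtype,
    uint8  = readBin(bytes, "integer", n, size = 1L, signed = FALSE,
                     endian = "little"),
    int8   = readBin(bytes, "integer", n, size = 1L, signed = TRUE,
                     endian = "little"),
    uint16 = readBin(bytes, "integer", n, size = 2L, signed = FALSE,
                     endian = "little"),
    int16  = readBin(bytes, "integer", n, size = 2L, signed = TRUE,
                     endian = "little"),
    uint32 = {
      x <- as.numeric(readBin(bytes, "integer", n, size = 4L,
                              endian = "little"))
      x[x < 0] <- x[x < 0] + 4294967296
      x
    },
    int32  = readBin(bytes, "integer", n, size = 4L, endian = "little"),
    single = readBin(bytes, "numeric", n, size = 4L, endian = "little"),
    double = readBin(bytes, "numeric", n, size = 8L, endian = "little")
  )
}

#' Encode a typed N-D array as a JData annotation object
#'
#' Produces a plain R list carrying `_ArrayType_`, `_ArraySize_` and either
#' `_ArrayData_` (row-major flattened values) or, with `compress = TRUE`,
#' a zlib-compressed Base64 payload under `_ArrayZipType_`/`_ArrayZipSize_`/
#' `_ArrayZipData_`. The object serializes with any standard JSON writer.
#'
#' @param x numeric or integer vector/array with at least one dimension.
#' @param dtype element type, one of `"uint8"`, `"int8"`, `"uint16"`,
#'   `"int16"`, `"uint32"`, `"int32"`, `"single"`, `"double"`. Defaults to
#'   `"int32"` for integer input and `"double"` otherwise.
#' @param compress logical; emit the zlib+Base64 form.
#' @return a list ready for JSON serialization.
#' @seealso [jd_decode()]
#' @export
#' @examples
#' obj <- jd_encode(array(1:24, c(2, 3, 4)), "uint8", compress = TRUE)
#' identical(jd_decode(obj), array(1:24, c(2, 3, 4)))
jd_encode <- function(x, dtype = NULL, compress = FALSE) {
  if (is.null(dtype)) dtype <- if (is.integer(x)) "int32" else "double"
  if (!dtype %in% names(jd_types))
    vmc_error(sprintf("unsupported element type '%s'", dtype),
              "jd_type_error")
  dims <- dim(x) %||% length(x)
  v <- if (length(dims) > 1) {
    as.vector(aperm(x, rev(seq_along(dims)))) # row-major stream
  } else {
    as.vector(x)
  }
  obj <- list(`_ArrayType_` = dtype, `_ArraySize_` = as.integer(dims))
  if (compress) {
    bytes <- jd_pack(v, dtype)
    obj$`_ArrayZipType_` <- "zlib"
    obj$`_ArrayZipSize_` <- as.integer(dims)
    b64 <- jsonlite::base64_enc(memCompress(bytes, "gzip"))
    obj$`_ArrayZipData_` <- gsub("[\r\n]", "", b64) # single-line payload
  } else {
    jd_validate(as.numeric(v), dtype)
    obj$`_ArrayData_` <- if (dtype == "single") {
      jd_to_float32(v)
    } else if (dtype %in% c("double", "uint32")) {
      as.numeric(v)
    } else {
      as.integer(v)
    }
  }
  obj
}

#' Decode a JData annotation object into a typed N-D array
#'
#' Accepts both the uncompressed `_ArrayData_` form and the
#' `_ArrayZipData_` form (zlib only). The returned array carries the
#' declared shape; the element type is attached as attribute `"jd_dtype"`.
#'
#' @param obj a list with JData annotation keys, e.g. parsed from JSON.
#' @return an integer or numeric array of the declared shape.
#' @seealso [jd_encode()]
#' @export
jd_decode <- function(obj) {
  if (!is.list(obj) || is.null(obj$`_ArrayType_`))
    vmc_error("not a JData array annotation (missing _ArrayType_)",
              "jd_format_error")
  dtype <- obj$`_ArrayType_`
  if (!dtype %in% names(jd_types))
    vmc_error(sprintf("unsupported element type '%s'", dtype),
              "jd_type_error")
  dims <- as.integer(unlist(obj$`_ArraySize_` %||% obj$`_ArrayZipSize_`))
  if (length(dims) < 1 || any(dims < 1))
    vmc_error("missing or invalid array dimensions", "jd_format_error")
  n <- prod(dims)
  if (!is.null(obj$`_ArrayZipData_`)) {
    ztype <- obj$`_ArrayZipType_` %||% ""
    if (!identical(ztype, "zlib"))
      vmc_error(sprintf("unsupported compression codec '%s'", ztype),
                "jd_codec_error")
    zraw <- tryCatch(jsonlite::base64_dec(obj$`_ArrayZipData_`),
                     error = function(e)
                       vmc_error("malformed Base64 payload",
                                 "jd_decode_error"))
    bytes <- tryCatch(memDecompress(zraw, "gzip"),
                      error = function(e)
                        vmc_error("corrupt zlib payload",
                                  "jd_payload_error"))
    if (length(bytes) != n * jd_types[[dtype]])
      vmc_error(sprintf(
        "payload holds %d bytes but %d x %d = %d expected",
        length(bytes), n, jd_types[[dtype]], n * jd_types[[dtype]]),
        "jd_payload_error")
    v <- jd_unpack(bytes, dtype, n)
  } else if (!is.null(obj$`_ArrayData_`)) {
    v <- unlist(obj$`_ArrayData_`, use.names = FALSE)
    if (length(v) != n)
      vmc_error(sprintf("payload holds %d values but %d expected",
                        length(v), n), "jd_payload_error")
    # "single" values are quantized to their declared float32 precision,
    # so decimal JSON transport round-trips bit-exactly
    v <- if (dtype == "single") jd_to_float32(v)
         else if (dtype %in% c("double", "uint32")) as.numeric(v)
         else as.integer(v)
  } else {
    vmc_error("annotation carries neither _ArrayData_ nor _ArrayZipData_",
              "jd_format_error")
  }
  x <- if (length(dims) > 1) {
    aperm(array(v, dim = rev(dims)), rev(seq_along(dims)))
  } else {
    v
  }
  attr(x, "jd_dtype") <- dtype
  x
}

# is this list a JData array annotation?
jd_is_array <- function(x) is.list(x) && !is.null(x$`_ArrayType_`)
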