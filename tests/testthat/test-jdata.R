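# typed N-D array codec: round trips, compression, and failure modes

jd_all_types <- c("uint8", "int8", "uint16", "int16",
                  "uint32", "int32", "single", "double")

random_array_of <- function(dtype, dims) {
  n <- prod(dims)
  v <- switch(dtype,
    uint8 = sample(0:255, n, replace = TRUE),
    int8 = sample(-128:127, n, replace = TRUE),
    uint16 = sample(0:65535, n, replace = TRUE),
    int16 = sample(-32768:32767, n, replace = TRUE),
    uint32 = floor(runif(n, 0, 4294967296)),
    int32 = as.integer(runif(n, -2147483648, 2147483647)),
    single = as_float32(rnorm(n, sd = 100)),
    double = rnorm(n, sd = 100)
  )
  if (length(dims) > 1) array(v, dims) else v
}

strip <- function(x) { attr(x, "jd_dtype") <- NULL; x }

test_that("random arrays of every element type survive the full JSON round trip", {
  set.seed(42)
  for (rep in 1:100) {
    dtype <- sample(jd_all_types, 1)
    nd <- sample(1:4, 1)
    dims <- sample(1:6, nd, replace = TRUE)
    a <- random_array_of(dtype, dims)
    compress <- rep %% 2 == 0
    obj <- jd_encode(a, dtype, compress = compress)
    # through an actual JSON serializer and strict parser
    txt <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = I(17))
    back <- jd_decode(jsonlite::parse_json(txt, simplifyVector = FALSE))
    expect_identical(strip(back),
                     if (is.array(a) || is.matrix(a)) a else a,
                     label = sprintf("%s %s (compress=%s)", dtype,
                                     paste(dims, collapse = "x"), compress))
    expect_identical(attr(back, "jd_dtype"), dtype)
  }
})

test_that("compressed and uncompressed encodings decode identically", {
  set.seed(7)
  for (dtype in jd_all_types) {
    a <- random_array_of(dtype, c(5, 7))
    expect_identical(strip(jd_decode(jd_encode(a, dtype, compress = TRUE))),
                     strip(jd_decode(jd_encode(a, dtype, compress = FALSE))))
  }
})

test_that("declared annotation keys match the chosen form", {
  obj <- jd_encode(matrix(c(1, 2, 3), 1, 3), "double")
  expect_identical(obj$`_ArrayType_`, "double")
  expect_identical(obj$`_ArraySize_`, c(1L, 3L))
  expect_identical(as.numeric(obj$`_ArrayData_`), c(1, 2, 3))
  expect_null(obj$`_ArrayZipData_`)

  z <- jd_encode(matrix(0L, 2, 2), "uint8", compress = TRUE)
  expect_identical(z$`_ArrayZipType_`, "zlib")
  raw <- memDecompress(jsonlite::base64_dec(z$`_ArrayZipData_`), "gzip")
  expect_identical(raw, as.raw(rep(0, 4)))
})

test_that("row-major declaration order maps index (i,j,k) to voxel (x,y,z)", {
  a <- array(seq_len(24), c(2, 3, 4))
  obj <- jd_encode(a, "int32")
  # serialized stream runs the last declared dimension fastest
  expect_identical(obj$`_ArrayData_`[1:4], as.integer(a[1, 1, 1:4]))
  expect_identical(strip(jd_decode(obj)), a)
})

test_that("payloads produced by an independent zlib implementation decode", {
  py <- python_bin()
  skip_if(!nzchar(py), "no python interpreter found")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import zlib, base64, struct",
    "data = struct.pack('<3B', 1, 2, 3)",
    "print(base64.b64encode(zlib.compress(data)).decode())"
  ), script)
  b64 <- system2(py, script, stdout = TRUE)
  obj <- list(`_ArrayType_` = "uint8", `_ArraySize_` = 3L,
              `_ArrayZipType_` = "zlib", `_ArrayZipSize_` = 3L,
              `_ArrayZipData_` = b64)
  expect_identical(strip(jd_decode(obj)), c(1L, 2L, 3L))
})

test_that("this codec's zlib payloads are readable by an independent zlib", {
  py <- python_bin()
  skip_if(!nzchar(py), "no python interpreter found")
  a <- array(as.double(1:12), c(3, 4))
  obj <- jd_encode(a, "double", compress = TRUE)
  b64file <- tempfile(); writeLines(obj$`_ArrayZipData_`, b64file)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import zlib, base64, struct, sys",
    sprintf("raw = zlib.decompress(base64.b64decode(open('%s').read()))",
            b64file),
    "vals = struct.unpack('<12d', raw)",
    "print(' '.join(repr(v) for v in vals))"
  ), script)
  out <- system2(py, script, stdout = TRUE)
  vals <- as.numeric(strsplit(out, " ")[[1]])
  # row-major stream of the 3x4 array
  expect_identical(vals, as.vector(t(a)))
})

test_that("malformed inputs raise typed errors", {
  # byte-count mismatch against the declared shape
  obj <- jd_encode(matrix(1:4, 2, 2), "uint8", compress = TRUE)
  obj$`_ArraySize_` <- c(2L, 2L)
  obj$`_ArrayZipSize_` <- c(2L, 2L)
  obj$`_ArrayZipData_` <- jsonlite::base64_enc(
    memCompress(as.raw(1:5), "gzip"))
  expect_error(jd_decode(obj), class = "jd_payload_error")

  obj2 <- jd_encode(1:3, "uint8", compress = TRUE)
  obj2$`_ArrayZipType_` <- "lzma"
  expect_error(jd_decode(obj2), class = "jd_codec_error")

  obj3 <- jd_encode(1:3, "uint8", compress = TRUE)
  obj3$`_ArrayZipData_` <- "@@@not-base64@@@"
  expect_error(jd_decode(obj3), class = c("jd_decode_error"))

  expect_error(jd_encode(1:3, "float128"), class = "jd_type_error")
  expect_error(jd_encode(c(1, NA), "int32"), class = "jd_conversion_error")
  expect_error(jd_encode(c(1, Inf), "uint8"), class = "jd_conversion_error")
  expect_error(jd_encode(c(1.5), "int16"), class = "jd_conversion_error")
  expect_error(jd_encode(c(-1), "uint16"), class = "jd_conversion_error")
})
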