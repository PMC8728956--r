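# Shared scene builders for the test suite. All fixtures are generated in
# code; nothing is read from disk.

# ballistic slab: no scattering, absorption mua, straight path of `depth`
# voxels along +z (1 mm voxels)
ballistic_doc <- function(mua = 0.1, depth = 10, photons = 100,
                          dir = c(0, 0, 1), pos = c(30, 30, 0),
                          dim = c(60, 60, depth), n = 1,
                          bc = "aaaaaa", t1 = 1e-7) {
  list(
    Session = list(ID = "ballistic", Photons = photons, RNGSeed = 1),
    Forward = list(T0 = 0, T1 = t1, Dt = t1),
    Optode = list(Source = list(Type = "pencil", Pos = pos, Dir = dir)),
    Domain = list(
      Dim = dim, LengthUnit = 1,
      Media = list(list(mua = 0, mus = 0, g = 1, n = 1),
                   list(mua = mua, mus = 0, g = 1, n = n)),
      BoundaryCondition = bc
    ),
    Shapes = list(list(Grid = list(Tag = 1, Size = dim)))
  )
}

# weight ledger imbalance, relative to launched weight
conservation_error <- function(res) {
  abs(res$absorbed + res$escaped + res$expired + res$roulette_net -
      res$launched) / res$launched
}

# brute-force voxel-center membership oracle, deliberately written as
# plain per-voxel loops, independent of the vectorized rasterizer
oracle_rasterize <- function(shapes, dim, default_tag = 0L) {
  vol <- array(as.integer(default_tag), dim)
  inside <- function(kind, spec, c) {
    switch(kind,
      sphere = sum((c - unlist(spec$O))^2) <= spec$R^2,
      box = {
        O <- unlist(spec$O); S <- unlist(spec$Size)
        all(c >= O) && all(c <= O + S)
      },
      cylinder = {
        C0 <- unlist(spec$C0); C1 <- unlist(spec$C1)
        v <- C1 - C0; L2 <- sum(v^2)
        tt <- sum((c - C0) * v) / L2
        tt >= 0 && tt <= 1 && sum((c - C0 - tt * v)^2) <= spec$R^2
      },
      FALSE)
  }
  for (s in shapes) {
    kind <- tolower(names(s)[1])
    spec <- s[[1]]
    if (kind == "grid") {
      vol[] <- as.integer(spec$Tag)
    } else if (kind %in% c("xlayers", "ylayers", "zlayers")) {
      ax <- match(substr(kind, 1, 1), c("x", "y", "z"))
      for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
        for (k in seq_len(dim[3])) {
          idx <- c(i, j, k)[ax] - 1
          for (layer in spec) {
            l <- unlist(layer)
            if (idx >= l[1] && idx <= l[2]) vol[i, j, k] <- as.integer(l[3])
          }
        }
    } else {
      for (i in seq_len(dim[1])) for (j in seq_len(dim[2]))
        for (k in seq_len(dim[3])) {
          if (inside(kind, spec, c(i, j, k) - 0.5))
            vol[i, j, k] <- as.integer(spec$Tag)
        }
    }
  }
  vol
}

# float32 quantization helper: values exactly representable in "single"
as_float32 <- function(x) {
  readBin(writeBin(as.numeric(x), raw(), size = 4L), "numeric",
          length(x), size = 4L)
}

python_bin <- function() {
  p <- Sys.which("python")
  if (!nzchar(p)) p <- Sys.which("python3")
  p
}
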