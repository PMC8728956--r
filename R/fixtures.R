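# Built-in benchmark scenes. These define the package's study conditions:
# optical properties are typical soft-tissue values at NIR wavelengths and
# grids are 60 mm cubes at 1 mm resolution.

#' Generate a benchmark simulation document
#'
#' Emits a schema-valid input JSON document for one of the built-in
#' benchmark scenes:
#'
#' * `homogeneous_cube`: 60^3 mm uniform low-scattering cube
#'   (mua 0.005/mm, mus 1/mm, g 0.01, n 1), pencil beam into z, one exit
#'   detector, absorbing boundaries.
#' * `layered_slab`: three z-layers with distinct tissue-like optics,
#'   pencil beam, two detectors on the illuminated face.
#' * `embedded_sphere`: absorbing/scattering sphere (r = 10) embedded in a
#'   low-absorption background cube.
#' * `infinite_cyclic`: homogeneous diffusive medium (mua 0.005/mm,
#'   mus 10/mm, g 0.9, n 1, so mus' = 1/mm), isotropic point source at the
#'   center, cyclic boundaries on all six faces emulating an infinite
#'   medium, single 3 ns gate (CW).
#'
#' @param kind one of the names above.
#' @param photons photon-count override.
#' @param seed RNG seed stored in the document.
#' @param path optional file to write the JSON to.
#' @return the document list (invisibly when `path` is given).
#' @export
make_fixture <- function(kind = c("homogeneous_cube", "layered_slab",
                                  "embedded_sphere", "infinite_cyclic"),
                         photons = NULL, seed = 1L, path = NULL) {
  kind <- match.arg(kind)
  air <- list(mua = 0, mus = 0, g = 1, n = 1)
  doc <- switch(kind,
    homogeneous_cube = list(
      Session = list(ID = "homogeneous_cube", Photons = 1e5,
                     RNGSeed = seed),
      Forward = list(T0 = 0, T1 = 5e-9, Dt = 5e-9),
      Optode = list(
        Source = list(Type = "pencil", Pos = c(30, 30, 0),
                      Dir = c(0, 0, 1)),
        Detector = list(list(Pos = c(25, 30, 0), R = 2))
      ),
      Domain = list(
        Dim = c(60L, 60L, 60L), LengthUnit = 1,
        Media = list(air,
                     list(mua = 0.005, mus = 1, g = 0.01, n = 1)),
        BoundaryCondition = "aaaaaa"
      ),
      Shapes = list(list(Grid = list(Tag = 1, Size = c(60L, 60L, 60L))))
    ),
    layered_slab = list(
      Session = list(ID = "layered_slab", Photons = 1e5, RNGSeed = seed),
      Forward = list(T0 = 0, T1 = 5e-9, Dt = 5e-9),
      Optode = list(
        Source = list(Type = "pencil", Pos = c(30, 30, 0),
                      Dir = c(0, 0, 1)),
        Detector = list(list(Pos = c(35, 30, 0), R = 2),
                        list(Pos = c(20, 30, 0), R = 2))
      ),
      Domain = list(
        Dim = c(60L, 60L, 60L), LengthUnit = 1,
        Media = list(air,
                     list(mua = 0.019, mus = 7.8, g = 0.89, n = 1.37),
                     list(mua = 0.004, mus = 6.0, g = 0.90, n = 1.37),
                     list(mua = 0.020, mus = 9.0, g = 0.89, n = 1.37)),
        BoundaryCondition = "aaaaaa"
      ),
      Shapes = list(
        list(Grid = list(Tag = 1, Size = c(60L, 60L, 60L))),
        list(ZLayers = list(c(0, 9, 1), c(10, 29, 2), c(30, 59, 3)))
      )
    ),
    embedded_sphere = list(
      Session = list(ID = "embedded_sphere", Photons = 1e5,
                     RNGSeed = seed),
      Forward = list(T0 = 0, T1 = 5e-9, Dt = 5e-9),
      Optode = list(
        Source = list(Type = "pencil", Pos = c(30, 30, 0),
                      Dir = c(0, 0, 1)),
        Detector = list(list(Pos = c(25, 30, 0), R = 2))
      ),
      Domain = list(
        Dim = c(60L, 60L, 60L), LengthUnit = 1,
        Media = list(air,
                     list(mua = 0.002, mus = 1, g = 0.01, n = 1.37),
                     list(mua = 0.050, mus = 5, g = 0.90, n = 1.37)),
        BoundaryCondition = "aaaaaa"
      ),
      Shapes = list(
        list(Grid = list(Tag = 1, Size = c(60L, 60L, 60L))),
        list(Sphere = list(O = c(30, 30, 30), R = 10, Tag = 2))
      )
    ),
    infinite_cyclic = list(
      Session = list(ID = "infinite_cyclic", Photons = 1e6,
                     RNGSeed = seed),
      Forward = list(T0 = 0, T1 = 3e-9, Dt = 3e-9),
      Optode = list(
        Source = list(Type = "isotropic", Pos = c(30, 30, 30),
                      Dir = c(0, 0, 1))
      ),
      Domain = list(
        Dim = c(60L, 60L, 60L), LengthUnit = 1,
        Media = list(air,
                     list(mua = 0.005, mus = 10, g = 0.9, n = 1)),
        BoundaryCondition = "cccccc"
      ),
      Shapes = list(list(Grid = list(Tag = 1, Size = c(60L, 60L, 60L))))
    )
  )
  if (!is.null(photons)) doc$Session$Photons <- photons
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    return(invisible(doc))
  }
  doc
}
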