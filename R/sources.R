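# Source-family sampling surface.
#
# Parameter packing (also documented in the shipped schema):
#   cone      param1[1] = half-angle (rad), uniform in solid angle
#   gaussian  param1[1] = 1/e beam waist (grid units)
#   disk      param1[1] = radius (grid units)
#   planar/pattern/fourier  param1[1:3], param2[1:3] = patch edge vectors
#   fourier   param1[4] = kx + phase/(2*pi) (phase packed in the fraction),
#             param2[4] = ky; launch weight (1 + cos(2*pi*(kx*u+ky*v)
#             + phase))/2 over patch coordinates (u, v) in [0,1)^2
#   line/slit param1[1:3] = segment vector from Pos
#   pattern3d param1[1:3] = region extents (grid units)

source_type_code <- function(type) {
  code <- match(type, vmc_source_types) - 1L
  if (is.na(code))
    vmc_error(sprintf("unknown source type '%s'", type), "source_type_error")
  code
}

# pack a parsed source for the C++ kernel
prep_source <- function(src) {
  out <- list(type = source_type_code(src$type),
              pos = as.numeric(src$pos),
              dir = as.numeric(src$dir),
              param1 = as.numeric(src$param1),
              param2 = as.numeric(src$param2),
              focus = as.numeric(src$focus %||% Inf),
              pattern = NULL, pattern_dim = integer(0))
  if (src$type %in% c("pattern", "pattern3d")) {
    if (is.null(src$pattern))
      vmc_error("pattern source without a pattern array",
                "source_config_error")
    if (any(src$pattern < 0))
      vmc_error("pattern weights must be nonnegative",
                "source_config_error")
    out$pattern <- as.numeric(src$pattern)
    out$pattern_dim <- as.integer(dim(src$pattern) %||%
                                  length(src$pattern))
  }
  if (src$type %in% c("planar", "pattern", "fourier")) {
    a1 <- sum(src$param1[1:3]^2); a2 <- sum(src$param2[1:3]^2)
    if (a1 == 0 || a2 == 0)
      vmc_error("zero-area planar-type source patch", "source_config_error")
  }
  out
}

#' Sample photon launch states for a source
#'
#' Draws initial position, direction and weight for `n` photon packets,
#' using the same per-photon random substreams as the transport kernel:
#' row `i` reproduces the launch of photon `i-1` of a run with the same
#' `seed` and `worker`.
#'
#' @param src a source description: either `cfg$source` from a parsed
#'   config, or a list with `type`, `pos`, `dir` and optionally `param1`,
#'   `param2`, `focus`, `pattern`.
#' @param n number of draws.
#' @param seed,worker RNG stream selectors (as in [run_simulation()]).
#' @return matrix with columns `x, y, z, vx, vy, vz, w`.
#' @export
#' @examples
#' s <- list(type = "isotropic", pos = c(30, 30, 30), dir = c(0, 0, 1))
#' colMeans(sample_launch(s, 1000)[, 4:6])
sample_launch <- function(src, n, seed = 1L, worker = 0L) {
  src <- normalize_source(src)
  cpp_sample_launch(prep_source(src), as.double(n), as.integer(seed),
                    as.integer(worker))
}

normalize_source <- function(src) {
  src$param1 <- c(as.numeric(src$param1 %||% numeric(0)), rep(0, 4))[1:4]
  src$param2 <- c(as.numeric(src$param2 %||% numeric(0)), rep(0, 4))[1:4]
  src$focus <- src$focus %||% Inf
  nd <- sqrt(sum(src$dir^2))
  if (nd < 1e-12)
    vmc_error("source direction must be nonzero", "source_config_error")
  src$dir <- src$dir / nd
  src
}

#' Redirect launch directions toward or away from a focal point
#'
#' For area sources a finite focal length `f` bends each ray through the
#' focal point at `patch center + f * dir`: positive `f` converges rays
#' toward the point, negative `f` diverges them from the virtual point
#' behind the patch, and infinite `f` leaves the beam collimated. This is
#' the same construction the transport kernel applies at launch.
#'
#' @param pos n x 3 matrix of sampled launch positions.
#' @param src source description (see [sample_launch()]); `src$focus` is
#'   the focal length.
#' @return n x 3 matrix of unit direction vectors.
#' @export
apply_focus <- function(pos, src) {
  src <- normalize_source(src)
  pos <- matrix(as.numeric(pos), ncol = 3)
  f <- src$focus
  if (!is.finite(f))
    return(matrix(src$dir, nrow(pos), 3, byrow = TRUE))
  if (f == 0)
    vmc_error("zero focal length is degenerate", "source_config_error")
  ctr <- src$pos
  if (src$type %in% c("planar", "pattern", "fourier"))
    ctr <- ctr + 0.5 * (src$param1[1:3] + src$param2[1:3])
  else if (src$type %in% c("line", "slit", "pattern3d"))
    ctr <- ctr + 0.5 * src$param1[1:3]
  fp <- ctr + f * src$dir
  d <- sweep(-pos, 2, fp, "+")
  nn <- sqrt(rowSums(d^2))
  if (any(nn < 1e-12))
    vmc_error("sample coincides with the focal point", "source_geom_error")
  sign(f) * d / nn
}
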