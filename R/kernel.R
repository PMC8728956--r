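# Transport-kernel wrappers: single-worker runs, replay, and the
# elementary samplers exposed for validation.

detp_colnames <- function(nmedia) {
  m <- seq_len(nmedia)
  c("detid", "weight",
    paste0("ppath_", m), paste0("nscat_", m),
    "x", "y", "z", "vx", "vy", "vz",
    "momentum", "w0", "seed_lo", "seed_hi")
}

# run one worker's photon block; returns a raw (unnormalized) part
run_photons <- function(cfg, nphotons, seed, worker = 0L,
                        roulette_threshold = 1e-4, roulette_p = 0.1) {
  stopifnot(inherits(cfg, "voxmc_config"))
  cfg <- realize_volume(cfg)
  dom <- cfg$domain
  fmt <- if (dom$media_format == "muamus_float") 1L else 0L
  vol <- dom$volume
  if (fmt == 0L) storage.mode(vol) <- "integer"
  else storage.mode(vol) <- "double"
  out <- cpp_run_kernel(
    vol, fmt, dom$media, dom$dim, dom$length_unit,
    cfg$forward$t0, cfg$forward$t1, cfg$forward$dt,
    prep_source(cfg$source),
    cfg$detectors, dom$boundary,
    cfg$session$do_mismatch, roulette_threshold, roulette_p,
    as.double(nphotons), as.integer(seed), as.integer(worker),
    0L, matrix(numeric(0), 0, 2), numeric(0))
  nmedia <- nrow(dom$media) - 1L
  if (length(out$detp)) colnames(out$detp) <- detp_colnames(nmedia)
  structure(list(
    flux = out$flux, nevents = out$nevents, detp = out$detp,
    absorbed = out$absorbed, escaped = out$escaped,
    expired = out$expired, roulette_net = out$roulette_net,
    launched = out$launched, nphoton = nphotons,
    seed = as.integer(seed), workers = 1L,
    worker_ids = as.integer(worker),
    roulette = c(threshold = roulette_threshold, p = roulette_p),
    normalized = FALSE, config = cfg
  ), class = "voxmc_result")
}

#' Replay detected photons into a per-voxel sensitivity (Jacobian) grid
#'
#' Re-simulates every detected photon from its stored RNG substream key,
#' reproducing the forward trajectory exactly, and accumulates pathlength
#' times detected weight per voxel. Replay integrity is enforced: the
#' replayed exit position and direction must match the recorded values
#' bit for bit.
#'
#' @param result a `voxmc_result` with detected photons, or a detected
#'   photon matrix with the columns written by the forward run.
#' @param cfg the simulation config; defaults to `result$config`.
#' @param roulette_threshold,roulette_p Russian-roulette settings; must
#'   match the forward run (taken from it automatically when `result` is
#'   a `voxmc_result`).
#' @return list with `jacobian` (3D array, mm x weight per voxel),
#'   `pathsum` (per-photon total replayed pathlength, mm), and `detp`
#'   (the re-detected photon table).
#' @export
replay_photons <- function(result, cfg = NULL,
                           roulette_threshold = 1e-4, roulette_p = 0.1) {
  if (inherits(result, "voxmc_result")) {
    cfg <- cfg %||% result$config
    detp <- result$detp
    if (!is.null(result$roulette)) {
      roulette_threshold <- unname(result$roulette["threshold"])
      roulette_p <- unname(result$roulette["p"])
    }
  } else {
    detp <- result
  }
  stopifnot(inherits(cfg, "voxmc_config"))
  if (is.null(detp) || !length(detp))
    vmc_error("no detected photons to replay", "replay_input_error")
  cfg <- realize_volume(cfg)
  dom <- cfg$domain
  fmt <- if (dom$media_format == "muamus_float") 1L else 0L
  vol <- dom$volume
  if (fmt == 0L) storage.mode(vol) <- "integer" else
    storage.mode(vol) <- "double"
  keys <- detp[, c("seed_lo", "seed_hi"), drop = FALSE]
  out <- cpp_run_kernel(
    vol, fmt, dom$media, dom$dim, dom$length_unit,
    cfg$forward$t0, cfg$forward$t1, cfg$forward$dt,
    prep_source(cfg$source),
    cfg$detectors, dom$boundary,
    cfg$session$do_mismatch, roulette_threshold, roulette_p,
    0, cfg$session$seed, 0L,
    1L, keys, detp[, "weight"])
  nmedia <- nrow(dom$media) - 1L
  if (length(out$detp)) colnames(out$detp) <- detp_colnames(nmedia)
  if (nrow(out$detp) != nrow(detp) ||
      !identical(unname(out$detp[, c("x", "y", "z", "vx", "vy", "vz")]),
                 unname(detp[, c("x", "y", "z", "vx", "vy", "vz")])))
    vmc_error("replayed trajectories diverge from the recorded detections",
              "replay_integrity_error")
  list(jacobian = out$jacobian, pathsum = out$pathsum, detp = out$detp)
}

#' Draw dimensionless scattering path lengths
#'
#' Samples `s* = -log(u)`, `u` uniform on (0, 1]; the physical hop length
#' in a medium is `s*/mus` so the mean free path is `1/mus`.
#'
#' @param n number of draws.
#' @param seed RNG seed.
#' @return numeric vector, mean 1.
#' @export
path_sample <- function(n, seed = 1L) {
  cpp_path_sample(as.double(n), as.integer(seed))
}

#' Draw Henyey-Greenstein deflection cosines
#'
#' `g = 0` reduces to isotropic scattering; the distribution's mean cosine
#' equals `g`.
#'
#' @param n number of draws.
#' @param g anisotropy in `[-1, 1]`.
#' @param seed RNG seed.
#' @return numeric vector of deflection cosines.
#' @export
hg_sample <- function(n, g, seed = 1L) {
  stopifnot(g >= -1, g <= 1)
  cpp_hg_sample(as.double(n), g, as.integer(seed))
}

#' Unpolarized Fresnel reflectance
#'
#' Average of the s- and p-polarized power reflectances for light crossing
#' a planar interface from index `n_in` to `n_out`; returns 1 beyond the
#' critical angle.
#'
#' @param cos_theta cosine(s) of the incidence angle, in `[0, 1]`.
#' @param n_in,n_out refractive indices on the incident and far side.
#' @return reflectance in `[0, 1]`, vectorized over `cos_theta`.
#' @export
#' @examples
#' fresnel_reflectance(1, 1.37, 1.0) # ((0.37)/(2.37))^2
fresnel_reflectance <- function(cos_theta, n_in, n_out) {
  cpp_fresnel(as.numeric(cos_theta), n_in, n_out)
}
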