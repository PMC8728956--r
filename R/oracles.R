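# Diffusion-theory references used to validate the transport kernel.

#' Diffusion parameters of a scattering medium
#'
#' Computes the reduced scattering coefficient `musp = mus * (1 - g)`, the
#' diffusion coefficient `D = 1 / (3 * (mua + musp))` (mm) and the
#' effective attenuation `mueff = sqrt(3 * mua * (mua + musp))` (1/mm).
#'
#' @param mua absorption coefficient, 1/mm.
#' @param mus scattering coefficient, 1/mm.
#' @param g scattering anisotropy.
#' @param n refractive index (carried along, unused by the infinite-medium
#'   solution).
#' @return list with `mua`, `musp`, `n`, `D`, `mueff`.
#' @export
diffusion_params <- function(mua, mus, g, n = 1) {
  musp <- mus * (1 - g)
  D <- 1 / (3 * (mua + musp))
  list(mua = mua, musp = musp, n = n, D = D,
       mueff = sqrt(3 * mua * (mua + musp)))
}

#' Infinite-medium CW diffusion Green's function
#'
#' Fluence per unit source power at distance `r` from an isotropic point
#' source in an infinite homogeneous medium:
#' `exp(-mueff * r) / (4 * pi * D * r)`.
#'
#' @param r distance from the source, mm (> 0).
#' @param p parameters from [diffusion_params()].
#' @return fluence, 1/mm^2, vectorized over `r`.
#' @export
infinite_cw_fluence <- function(r, p) {
  if (any(r <= 0))
    vmc_error("the point-source Green's function requires r > 0",
              "oracle_domain_error")
  exp(-p$mueff * r) / (4 * pi * p$D * r)
}

#' Compare simulated CW fluence against the diffusion Green's function
#'
#' Shell-averages the CW fluence of a homogeneous (cyclic or large-domain)
#' run in 1 mm radial bins around the source and compares each shell with
#' the analytic infinite-medium solution. Shells closer than 3 transport
#' mean free paths (`3 / (mua + musp)`) are excluded, where diffusion
#' theory is invalid; shells with fewer deposition events than
#' `min_events` are flagged as having insufficient statistics rather than
#' compared.
#'
#' @param result a normalized `voxmc_result` from a homogeneous run.
#' @param p optional [diffusion_params()]; derived from the config's
#'   medium 1 when omitted.
#' @param r_range radii (mm) to compare over, default `c(5, 15)`.
#' @param min_events deposition-event threshold per shell (default 1000).
#' @return list with `profile` (a data.frame of shell radius, MC and
#'   analytic fluence, relative error, event count) and `max_rel_err`
#'   (maximum relative error over adequately sampled shells in range;
#'   `NA` if none qualify).
#' @export
compare_to_oracle <- function(result, p = NULL, r_range = c(5, 15),
                              min_events = 1000) {
  stopifnot(inherits(result, "voxmc_result"))
  cfg <- result$config
  if (is.null(p)) {
    m <- cfg$domain$media[2, ]
    p <- diffusion_params(m[["mua"]], m[["mus"]], m[["g"]], m[["n"]])
  }
  phi <- cw_fluence(result)
  unit <- cfg$domain$length_unit
  d <- cfg$domain$dim
  srcpos <- cfg$source$pos
  cx <- (seq_len(d[1]) - 0.5 - srcpos[1]) * unit
  cy <- (seq_len(d[2]) - 0.5 - srcpos[2]) * unit
  cz <- (seq_len(d[3]) - 0.5 - srcpos[3]) * unit
  r <- sqrt(outer(outer(cx^2, cy^2, "+"), cz^2, "+"))

  ltr <- 1 / (p$mua + p$musp)
  rmin <- max(r_range[1], 3 * ltr)
  shell <- floor(r)
  ks <- seq(floor(rmin), ceiling(r_range[2]) - 1)
  prof <- do.call(rbind, lapply(ks, function(k) {
    sel <- shell == k & r > 0
    mc <- mean(phi[sel])
    an <- mean(infinite_cw_fluence(r[sel], p))
    ev <- sum(result$nevents[sel])
    data.frame(r = k + 0.5, mc = mc, analytic = an,
               rel_err = abs(mc - an) / an, events = ev,
               adequate = ev >= min_events)
  }))
  ok <- prof$adequate & prof$r >= rmin & prof$r <= r_range[2]
  list(profile = prof,
       max_rel_err = if (any(ok)) max(prof$rel_err[ok]) else NA_real_)
}
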