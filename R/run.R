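# Top-level simulation driver: worker splitting, disjoint substreams,
# merging, and normalization.

split_photons <- function(n, workers) {
  base <- n %/% workers
  counts <- rep(base, workers)
  extra <- n %% workers
  if (extra > 0) counts[seq_len(extra)] <- counts[seq_len(extra)] + 1
  counts
}

#' Run a simulation
#'
#' Validates and parses the input (when given a file path or document),
#' rasterizes shapes into the label volume if needed, splits the photon
#' budget as evenly as possible across `workers` logical workers with
#' disjoint per-photon random substreams, transports the photons, merges
#' the parts, and (by default) normalizes deposited energy to fluence
#' rate. Identical `(input, seed, workers)` yields bit-identical results.
#'
#' @param input a file path, JSON string, document list, or parsed
#'   `voxmc_config`.
#' @param photons override of `Session.Photons`.
#' @param seed override of `Session.RNGSeed`.
#' @param workers number of logical workers (default 1). Worker `i` draws
#'   its photons from substreams keyed by `(seed, i-1)`, so different
#'   worker counts give statistically independent but individually
#'   reproducible runs.
#' @param normalize override of `Session.DoNormalize`.
#' @param roulette_threshold weight fraction of the initial packet weight
#'   below which Russian roulette is played (default `1e-4`).
#' @param roulette_p survival probability of the roulette (default 0.1);
#'   survivors are reweighted by `1/roulette_p`, keeping the expectation
#'   unbiased.
#' @return a `voxmc_result`: the time-gated fluence array `flux`
#'   (x, y, z, gate), the detected-photon matrix `detp`, the weight ledger
#'   (`absorbed`, `escaped`, `expired`, `roulette_net`, `launched`), and
#'   the realized config.
#' @export
#' @examples
#' doc <- make_fixture("homogeneous_cube", photons = 1000)
#' res <- run_simulation(doc, seed = 7)
#' res
run_simulation <- function(input, photons = NULL, seed = NULL,
                           workers = 1L, normalize = NULL,
                           roulette_threshold = 1e-4, roulette_p = 0.1) {
  cfg <- if (inherits(input, "voxmc_config")) input else parse_config(input)
  if (!is.null(photons)) cfg$session$photons <- photons
  if (!is.null(seed)) cfg$session$seed <- as.integer(seed)
  if (!is.null(normalize)) cfg$session$do_normalize <- isTRUE(normalize)
  cfg <- realize_volume(cfg)

  n <- cfg$session$photons
  workers <- as.integer(workers)
  stopifnot(workers >= 1, n >= 1)
  counts <- split_photons(n, workers)
  parts <- lapply(seq_len(workers), function(i) {
    if (counts[i] < 1) return(NULL)
    run_photons(cfg, counts[i], cfg$session$seed, worker = i - 1L,
                roulette_threshold = roulette_threshold,
                roulette_p = roulette_p)
  })
  parts <- Filter(Negate(is.null), parts)
  res <- merge_results(parts)
  res$workers <- workers
  res$worker_photons <- counts
  if (cfg$session$do_normalize) res <- normalize_fluence(res)
  res
}

#' Continuous-wave fluence from a time-gated result
#'
#' Sums the normalized fluence rate over time gates and multiplies by the
#' gate width, giving the CW (time-integrated) fluence in 1/mm^2 per unit
#' delivered energy.
#'
#' @param result a normalized `voxmc_result`.
#' @return 3D array of CW fluence.
#' @export
cw_fluence <- function(result) {
  stopifnot(inherits(result, "voxmc_result"))
  if (!isTRUE(result$normalized))
    vmc_error("CW fluence requires a normalized result",
              "normalize_state_error")
  d <- dim(result$flux)
  out <- array(0, d[1:3])
  for (g in seq_len(d[4])) out <- out + result$flux[, , , g]
  out * result$config$forward$dt
}
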