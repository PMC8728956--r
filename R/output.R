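# Result assembly: merging worker parts, fluence normalization, and the
# JSON/JData output writers and readers.

#' Merge partial simulation results
#'
#' Adds raw energy grids, concatenates detected-photon tables, and sums the
#' weight ledger. Parts must come from the same config (photon counts and
#' worker substreams may differ) and must not be normalized yet;
#' normalization is applied after merging.
#'
#' @param parts list of `voxmc_result` objects (raw).
#' @return a single raw `voxmc_result`.
#' @export
merge_results <- function(parts) {
  stopifnot(length(parts) >= 1)
  for (p in parts) {
    if (!inherits(p, "voxmc_result"))
      vmc_error("merge expects voxmc_result parts", "merge_error")
    if (isTRUE(p$normalized))
      vmc_error("cannot merge normalized results; merge raw parts first",
                "merge_error")
  }
  h <- vapply(parts, function(p) vmc_hash(serialize_config(p$config)),
              character(1))
  if (length(unique(h)) != 1)
    vmc_error("parts were produced from different configs", "merge_error")
  rr <- unique(lapply(parts, function(p) p$roulette))
  if (length(rr) != 1)
    vmc_error("parts were run with different roulette settings",
              "merge_error")
  out <- parts[[1]]
  if (length(parts) == 1) return(out)
  for (p in parts[-1]) {
    out$flux <- out$flux + p$flux
    out$nevents <- out$nevents + p$nevents
    out$detp <- if (length(out$detp) && length(p$detp)) {
      rbind(out$detp, p$detp)
    } else if (length(p$detp)) p$detp else out$detp
    for (f in c("absorbed", "escaped", "expired", "roulette_net",
                "launched", "nphoton"))
      out[[f]] <- out[[f]] + p[[f]]
    out$worker_ids <- c(out$worker_ids, p$worker_ids)
  }
  out$workers <- length(out$worker_ids)
  out
}

# per-voxel absorption map (per mm) from the realized config
voxel_mua <- function(cfg) {
  dom <- cfg$domain
  if (dom$media_format == "muamus_float") {
    array(dom$volume[1, , , ], dom$dim)
  } else {
    array(dom$media[as.vector(dom$volume) + 1L, "mua"], dom$dim)
  }
}

#' Normalize raw deposited energy into fluence rate
#'
#' Converts the per-voxel, per-gate deposited energy `E` into fluence rate
#' `E / (mua * V_voxel * Dt * W_launched)` (1/mm^2/s per unit delivered
#' energy). Voxels with `mua = 0` accumulate weighted pathlength (mm)
#' instead of energy during transport and are normalized as
#' `sum(w*l) / (V_voxel * Dt * W_launched)`, which is the same estimator
#' in the limit.
#'
#' @param result a raw `voxmc_result`.
#' @return the result with `flux` in fluence-rate units and
#'   `normalized = TRUE`.
#' @export
normalize_fluence <- function(result) {
  stopifnot(inherits(result, "voxmc_result"))
  if (isTRUE(result$normalized))
    vmc_error("result is already normalized", "normalize_state_error")
  cfg <- result$config
  mua <- voxel_mua(cfg)                       # per mm
  vvox <- cfg$domain$length_unit^3            # mm^3
  denom <- cfg$forward$dt * result$launched * vvox
  scale <- array(1 / denom, dim(mua))
  pos <- mua > 0
  scale[pos] <- scale[pos] / mua[pos]
  G <- dim(result$flux)[4]
  for (g in seq_len(G))
    result$flux[, , , g] <- result$flux[, , , g] * scale
  result$normalized <- TRUE
  result
}

#' Write simulation outputs as JSON/JData files
#'
#' Writes two pure-JSON files: `<basename>.jnii`, a minimal JNIfTI-style
#' volume (header object plus the zlib-compressed JData 4D fluence array),
#' and `<basename>_detp.json` with the detected-photon table and its
#' column metadata. Partial pathlengths are recorded in mm. Both files
#' re-read bit-exactly via [read_jnii()] and [read_detp()] (up to the
#' declared output element type).
#'
#' @param result a `voxmc_result` (normalized or raw; the header records
#'   which).
#' @param basename output path prefix.
#' @return invisibly, the paths written.
#' @export
write_outputs <- function(result, basename) {
  stopifnot(inherits(result, "voxmc_result"))
  cfg <- result$config
  hdr <- list(
    Dim = dim(result$flux),
    VoxelSize = rep(cfg$domain$length_unit, 3),
    LengthUnit = "mm",
    TimeStart = cfg$forward$t0,
    TimeGateWidth = cfg$forward$dt,
    TimeGates = cfg$forward$gates,
    Normalized = isTRUE(result$normalized),
    FluenceUnit = if (isTRUE(result$normalized))
      "1/mm^2/s per unit delivered energy" else "deposited energy",
    Photons = result$nphoton,
    Seed = result$seed,
    Workers = result$workers
  )
  vol_path <- paste0(basename, ".jnii")
  jsonlite::write_json(
    list(NIFTIHeader = hdr,
         NIFTIData = jd_encode(result$flux, cfg$session$out_dtype,
                               compress = TRUE)),
    vol_path, auto_unbox = TRUE, digits = I(17))

  detp_path <- paste0(basename, "_detp.json")
  nmedia <- nrow(cfg$domain$media) - 1L
  dobj <- list(
    DetectorInfo = list(
      Columns = detp_colnames(nmedia),
      Media = nmedia,
      PathlengthUnit = "mm",
      Detected = if (length(result$detp)) nrow(result$detp) else 0L
    )
  )
  if (length(result$detp))
    dobj$DetectorData <- jd_encode(unname(result$detp), "double",
                                   compress = TRUE)
  jsonlite::write_json(dobj, detp_path, auto_unbox = TRUE, digits = I(17))
  invisible(c(vol_path, detp_path))
}

#' Read a JNIfTI-style fluence volume written by [write_outputs()]
#'
#' @param path the `.jnii` file path.
#' @return list with `header` and the decoded 4D `data` array.
#' @export
read_jnii <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  list(header = doc$NIFTIHeader, data = jd_decode(doc$NIFTIData))
}

#' Read a detected-photon table written by [write_outputs()]
#'
#' @param path the `_detp.json` file path.
#' @return matrix with named columns (zero rows when nothing was detected).
#' @export
read_detp <- function(path) {
  doc <- jsonlite::read_json(path, simplifyVector = FALSE)
  cols <- unlist(doc$DetectorInfo$Columns)
  if (is.null(doc$DetectorData))
    return(matrix(numeric(0), 0, length(cols),
                  dimnames = list(NULL, cols)))
  m <- jd_decode(doc$DetectorData)
  attr(m, "jd_dtype") <- NULL
  colnames(m) <- cols
  m
}

#' @export
print.voxmc_result <- function(x, ...) {
  cat("voxmc simulation result\n")
  cat(sprintf("  photons: %g across %d worker(s), seed %d\n",
              x$nphoton, x$workers, x$seed))
  cat(sprintf("  fluence grid: %s (%s)\n",
              paste(dim(x$flux), collapse = "x"),
              if (isTRUE(x$normalized)) "normalized fluence rate"
              else "raw deposited energy"))
  bal <- x$absorbed + x$escaped + x$expired + x$roulette_net
  cat(sprintf(
    "  weight ledger: absorbed %.4g, escaped %.4g, expired %.4g, roulette %.4g\n",
    x$absorbed, x$escaped, x$expired, x$roulette_net))
  cat(sprintf("  conservation: |ledger - launched|/launched = %.3g\n",
              abs(bal - x$launched) / x$launched))
  cat(sprintf("  detected photons: %d\n",
              if (length(x$detp)) nrow(x$detp) else 0L))
  invisible(x)
}
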