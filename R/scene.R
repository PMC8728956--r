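# Simulation description: JSON dialect validation and parsing.
#
# Top-level sections follow the Session/Forward/Optode/Domain/Shapes layout.
# Coordinates are continuous grid units with voxel (i,j,k) spanning the
# half-open box [i,i+1)x[j,j+1)x[k,k+1), 0-based. Optical coefficients are
# per mm; LengthUnit (mm per grid unit) converts them internally.

vmc_source_types <- c("pencil", "isotropic", "cone", "gaussian", "planar",
                      "pattern", "fourier", "disk", "line", "slit",
                      "pattern3d")

vmc_shape_kinds <- c("grid", "sphere", "box", "cylinder",
                     "xlayers", "ylayers", "zlayers")

# boundary-condition letters, faces ordered x-,x+,y-,y+,z-,z+
vmc_bc_codes <- c(a = 0L, r = 1L, m = 2L, c = 3L)

num1 <- function(x) {
  v <- suppressWarnings(as.numeric(unlist(x, use.names = FALSE)))
  if (length(v) == 1 && !is.na(v)) v else NA_real_
}
numv <- function(x) suppressWarnings(as.numeric(unlist(x, use.names = FALSE)))

#' Path to the shipped JSON Schema for the input dialect
#'
#' The schema documents the accepted structure of simulation JSON files
#' (sections, key names, types, enums and ranges). [validate_config()]
#' enforces the same rules.
#'
#' @return file path of the schema JSON.
#' @export
vmc_schema_path <- function() {
  system.file("schema", "voxmc-input.schema.json", package = "voxmc",
              mustWork = TRUE)
}

#' Validate a simulation JSON document
#'
#' Checks a parsed JSON document against the input dialect rules shipped in
#' the package schema: required sections and keys, types, enum membership
#' and numeric ranges. Violations are returned, not thrown, so callers can
#' report all of them at once. Unknown keys produce warnings only.
#'
#' @param doc a list as returned by `jsonlite::read_json(..., simplifyVector
#'   = FALSE)`, a JSON string, or a file path.
#' @return character vector of violations, each `"<json path>: <rule>"`;
#'   empty when the document conforms.
#' @export
validate_config <- function(doc) {
  doc <- load_doc(doc)
  v <- character(0)
  bad <- function(path, rule) v <<- c(v, paste0(path, ": ", rule))

  known <- c("Session", "Forward", "Optode", "Domain", "Shapes")
  extra <- setdiff(names(doc), known)
  if (length(extra))
    warning("ignoring unknown top-level keys: ",
            paste(extra, collapse = ", "), call. = FALSE)

  for (key in c("Session", "Forward", "Domain", "Optode"))
    if (is.null(doc[[key]])) bad(paste0("/", key), "required section missing")

  ses <- doc$Session
  if (!is.null(ses)) {
    ph <- num1(ses$Photons)
    if (is.null(ses$Photons) || is.na(ph) || ph < 1)
      bad("/Session/Photons", "photon count must be a number >= 1")
    if (!is.null(ses$RNGSeed) && is.na(num1(ses$RNGSeed)))
      bad("/Session/RNGSeed", "seed must be a number")
    for (flag in c("DoMismatch", "DoNormalize")) {
      f <- ses[[flag]]
      if (!is.null(f) && !(isTRUE(f) || isFALSE(f) || num1(f) %in% c(0, 1)))
        bad(paste0("/Session/", flag), "flag must be 0/1 or boolean")
    }
    if (!is.null(ses$OutDtype) &&
        !identical(as.character(ses$OutDtype), "single") &&
        !identical(as.character(ses$OutDtype), "double"))
      bad("/Session/OutDtype", "must be 'single' or 'double'")
  }

  fwd <- doc$Forward
  if (!is.null(fwd)) {
    t0 <- num1(fwd$T0); t1 <- num1(fwd$T1); dt <- num1(fwd$Dt)
    if (is.na(t0)) bad("/Forward/T0", "required number")
    if (is.na(t1)) bad("/Forward/T1", "required number")
    if (is.na(dt) || (!is.na(dt) && dt <= 0))
      bad("/Forward/Dt", "required number > 0")
    if (!is.na(t0) && !is.na(t1) && t0 >= t1)
      bad("/Forward/T0", "T0 must be < T1")
    if (!is.na(t0) && !is.na(t1) && !is.na(dt) && dt > 0) {
      g <- (t1 - t0) / dt
      if (abs(g - round(g)) > 1e-6 * max(1, g))
        bad("/Forward/Dt", "(T1 - T0) must be an integer multiple of Dt")
    }
  }

  opt <- doc$Optode
  if (!is.null(opt)) {
    src <- opt$Source
    if (is.null(src)) {
      bad("/Optode/Source", "required section missing")
    } else {
      ty <- as.character(src$Type %||% "")
      if (!ty %in% vmc_source_types)
        bad("/Optode/Source/Type",
            paste0("must be one of: ", paste(vmc_source_types,
                                             collapse = ", ")))
      pos <- numv(src$Pos)
      if (length(pos) != 3 || any(is.na(pos)))
        bad("/Optode/Source/Pos", "must be a 3-vector of numbers")
      dirv <- numv(src$Dir)
      if (length(dirv) != 3 || any(is.na(dirv)) ||
          sum(dirv^2) < 1e-12)
        bad("/Optode/Source/Dir", "must be a nonzero 3-vector")
      if (ty %in% c("pattern", "pattern3d") && !jd_is_array(src$Pattern))
        bad("/Optode/Source/Pattern",
            "pattern sources require a JData-encoded Pattern array")
      if (ty %in% c("planar", "pattern", "fourier")) {
        p1 <- numv(src$Param1); p2 <- numv(src$Param2)
        if (length(p1) < 3 || sum(p1[1:3]^2) == 0 ||
            length(p2) < 3 || sum(p2[1:3]^2) == 0)
          bad("/Optode/Source/Param1",
              "planar-type sources need nonzero edge vectors in Param1/Param2")
      }
    }
    dets <- opt$Detector
    if (!is.null(dets)) {
      for (i in seq_along(dets)) {
        d <- dets[[i]]
        if (length(numv(d$Pos)) != 3)
          bad(sprintf("/Optode/Detector/%d/Pos", i - 1),
              "must be a 3-vector")
        if (is.na(num1(d$R)) || num1(d$R) <= 0)
          bad(sprintf("/Optode/Detector/%d/R", i - 1),
              "radius must be > 0")
      }
    }
  }

  dom <- doc$Domain
  has_volume <- FALSE
  if (!is.null(dom)) {
    dm <- numv(dom$Dim)
    if (length(dm) != 3 || any(is.na(dm)) || any(dm < 1) ||
        any(dm != round(dm)))
      bad("/Domain/Dim", "must be 3 integer extents >= 1")
    if (!is.null(dom$LengthUnit) &&
        (is.na(num1(dom$LengthUnit)) || num1(dom$LengthUnit) <= 0))
      bad("/Domain/LengthUnit", "must be a number > 0")
    med <- dom$Media
    if (is.null(med) || length(med) < 1) {
      bad("/Domain/Media", "at least one medium entry is required")
    } else {
      for (i in seq_along(med)) {
        m <- med[[i]]
        p <- sprintf("/Domain/Media/%d", i - 1)
        if (is.na(num1(m$mua)) || num1(m$mua) < 0)
          bad(paste0(p, "/mua"), "absorption must be a number >= 0")
        if (is.na(num1(m$mus)) || num1(m$mus) < 0)
          bad(paste0(p, "/mus"), "scattering must be a number >= 0")
        g <- num1(m$g)
        if (is.na(g) || g < -1 || g > 1)
          bad(paste0(p, "/g"), "anisotropy must lie in [-1, 1]")
        if (is.na(num1(m$n)) || num1(m$n) < 1)
          bad(paste0(p, "/n"), "refractive index must be >= 1")
      }
    }
    bcs <- dom$BoundaryCondition
    if (!is.null(bcs)) {
      s <- as.character(bcs)
      if (nchar(s) != 6 ||
          !all(strsplit(s, "")[[1]] %in% names(vmc_bc_codes)))
        bad("/Domain/BoundaryCondition",
            "must be 6 characters from {a, r, m, c}")
    }
    if (!is.null(dom$MediaFormat) &&
        !as.character(dom$MediaFormat) %in% c("labels", "muamus_float"))
      bad("/Domain/MediaFormat", "must be 'labels' or 'muamus_float'")
    if (!is.null(dom$Volume)) {
      has_volume <- TRUE
      if (!jd_is_array(dom$Volume))
        bad("/Domain/Volume", "must be a JData array annotation")
    }
  }

  shp <- doc$Shapes
  has_shapes <- FALSE
  if (!is.null(shp)) {
    if (jd_is_array(shp)) {
      if (has_volume)
        bad("/Shapes", "volume given in both Shapes and Domain.Volume")
      has_volume <- TRUE
    } else if (is.list(shp)) {
      has_shapes <- length(shp) > 0
      for (i in seq_along(shp)) {
        s <- shp[[i]]
        kind <- tolower(names(s)[1] %||% "")
        if (!kind %in% vmc_shape_kinds)
          bad(sprintf("/Shapes/%d", i - 1),
              paste0("unknown shape kind; expected one of: ",
                     paste(vmc_shape_kinds, collapse = ", ")))
      }
    } else {
      bad("/Shapes", "must be a shape list or a JData array")
    }
  }
  if (!is.null(dom) && !has_volume && !has_shapes &&
      !identical(as.character(dom$MediaFormat %||% "labels"),
                 "muamus_float"))
    bad("/Shapes", "exactly one of Shapes or Domain.Volume must define the medium")
  if (has_volume && has_shapes)
    bad("/Shapes", "Shapes and Domain.Volume are mutually exclusive")

  v
}

load_doc <- function(doc) {
  if (is.character(doc) && length(doc) == 1) {
    doc <- if (file.exists(doc)) {
      jsonlite::read_json(doc, simplifyVector = FALSE)
    } else {
      jsonlite::parse_json(doc, simplifyVector = FALSE)
    }
  }
  if (!is.list(doc))
    vmc_error("input must be a JSON object", "config_parse_error")
  doc
}

#' Parse a validated simulation document into a config object
#'
#' Applies the documented defaults (refractive-index mismatch physics off,
#' absorbing boundaries on all faces, `LengthUnit = 1` mm, single-precision
#' output), normalizes the source direction, decodes any JData-encoded
#' volume or source pattern, and converts boundary-condition letters to
#' face codes.
#'
#' @param doc as in [validate_config()]; must validate cleanly.
#' @return an object of class `voxmc_config`.
#' @export
parse_config <- function(doc) {
  doc <- load_doc(doc)
  viol <- withCallingHandlers(validate_config(doc),
                              warning = function(w) invokeRestart("muffleWarning"))
  if (length(viol))
    vmc_error(paste0("invalid simulation document:\n  ",
                     paste(viol, collapse = "\n  ")),
              "config_invalid_error")

  ses <- doc$Session %||% list()
  as_flag <- function(x, default) {
    if (is.null(x)) return(default)
    isTRUE(x) || identical(num1(x), 1)
  }
  session <- list(
    id = as.character(ses$ID %||% "voxmc"),
    photons = num1(ses$Photons),
    seed = as.integer(num1(ses$RNGSeed %||% 1)),
    do_mismatch = as_flag(ses$DoMismatch, FALSE),
    do_normalize = as_flag(ses$DoNormalize, TRUE),
    out_dtype = as.character(ses$OutDtype %||% "single")
  )

  fwd <- doc$Forward
  t0 <- num1(fwd$T0); t1 <- num1(fwd$T1); dt <- num1(fwd$Dt)
  forward <- list(t0 = t0, t1 = t1, dt = dt,
                  gates = as.integer(round((t1 - t0) / dt)))

  src <- doc$Optode$Source
  dirv <- numv(src$Dir)
  dirv <- dirv / sqrt(sum(dirv^2))
  pad4 <- function(x) {
    x <- numv(x)
    c(x, rep(0, 4))[1:4]
  }
  pattern <- NULL
  if (jd_is_array(src$Pattern)) pattern <- jd_decode(src$Pattern)
  source <- list(
    type = as.character(src$Type),
    pos = numv(src$Pos),
    dir = dirv,
    param1 = pad4(src$Param1),
    param2 = pad4(src$Param2),
    focus = num1(src$Focus %||% Inf),
    pattern = pattern
  )
  if (is.na(source$focus)) source$focus <- Inf

  dets <- doc$Optode$Detector %||% list()
  detectors <- matrix(numeric(0), ncol = 4,
                      dimnames = list(NULL, c("x", "y", "z", "r")))
  if (length(dets)) {
    detectors <- do.call(rbind, lapply(dets, function(d)
      c(numv(d$Pos), num1(d$R))))
    colnames(detectors) <- c("x", "y", "z", "r")
  }

  dom <- doc$Domain
  media <- do.call(rbind, lapply(dom$Media, function(m)
    c(mua = num1(m$mua), mus = num1(m$mus), g = num1(m$g), n = num1(m$n))))
  bc_string <- as.character(dom$BoundaryCondition %||% "aaaaaa")
  bc <- unname(vmc_bc_codes[strsplit(bc_string, "")[[1]]])
  dim3 <- as.integer(numv(dom$Dim))
  media_format <- as.character(dom$MediaFormat %||% "labels")

  volume <- NULL
  vol_src <- if (!is.null(dom$Volume)) dom$Volume
             else if (jd_is_array(doc$Shapes)) doc$Shapes
  if (!is.null(vol_src)) {
    volume <- tryCatch(jd_decode(vol_src), voxmc_error = function(e)
      vmc_error(paste0("corrupt volume payload: ", conditionMessage(e)),
                "config_volume_error"))
    vdim <- dim(volume) %||% length(volume)
    expect_dim <- if (media_format == "muamus_float") c(2L, dim3) else dim3
    if (!identical(as.integer(vdim), as.integer(expect_dim)))
      vmc_error(sprintf(
        "volume dimensions [%s] do not match Domain.Dim [%s]",
        paste(vdim, collapse = ","), paste(expect_dim, collapse = ",")),
        "config_volume_error")
    if (media_format == "labels") {
      storage.mode(volume) <- "integer"
      check_media_coverage(volume, media)
    }
  }

  shapes <- NULL
  if (!jd_is_array(doc$Shapes) && !is.null(doc$Shapes) &&
      length(doc$Shapes)) shapes <- canonical_shapes(doc$Shapes)

  cfg <- structure(list(
    session = session, forward = forward, source = source,
    detectors = detectors,
    domain = list(dim = dim3,
                  length_unit = num1(dom$LengthUnit %||% 1),
                  media = media,
                  boundary = as.integer(bc),
                  boundary_string = bc_string,
                  media_format = media_format,
                  volume = volume),
    shapes = shapes
  ), class = "voxmc_config")
  cfg
}

# normalize shape geometry to plain numeric vectors so a config compares
# equal no matter whether it came from R lists or parsed JSON
canonical_shapes <- function(shapes) {
  lapply(shapes, function(s) {
    kind <- names(s)[1]
    spec <- s[[1]]
    out <- if (tolower(kind) %in% c("xlayers", "ylayers", "zlayers")) {
      lapply(spec, function(l) as.numeric(unlist(l)))
    } else {
      sp <- spec
      for (f in c("O", "Size", "C0", "C1"))
        if (!is.null(sp[[f]])) sp[[f]] <- as.numeric(unlist(sp[[f]]))
      if (!is.null(sp$R)) sp$R <- as.numeric(unlist(sp$R))
      if (!is.null(sp$Tag)) sp$Tag <- as.integer(unlist(sp$Tag))
      sp
    }
    stats::setNames(list(out), kind)
  })
}

check_media_coverage <- function(volume, media) {
  labs <- sort(unique(as.vector(volume)))
  labs <- labs[labs > 0]
  if (length(labs) && max(labs) > nrow(media) - 1)
    vmc_error(sprintf(
      "volume labels up to %d but only %d media entries (labels 0..%d)",
      max(labs), nrow(media), nrow(media) - 1), "config_media_error")
  invisible(TRUE)
}

#' Read and parse a simulation JSON file
#'
#' @param path file path of the input JSON.
#' @return a `voxmc_config` object.
#' @export
read_config <- function(path) parse_config(load_doc(path))

#' Serialize a config object back to the JSON document form
#'
#' Inverse of [parse_config()]: `parse_config(serialize_config(cfg))`
#' reproduces `cfg`. Volumes and patterns are re-encoded as compressed
#' JData annotations.
#'
#' @param cfg a `voxmc_config` object.
#' @param path optional file to write the JSON document to.
#' @return the document list, invisibly when `path` is given.
#' @export
serialize_config <- function(cfg, path = NULL) {
  stopifnot(inherits(cfg, "voxmc_config"))
  src <- list(Type = cfg$source$type,
              Pos = cfg$source$pos,
              Dir = cfg$source$dir,
              Param1 = cfg$source$param1,
              Param2 = cfg$source$param2)
  if (is.finite(cfg$source$focus)) src$Focus <- cfg$source$focus
  if (!is.null(cfg$source$pattern))
    src$Pattern <- jd_encode(cfg$source$pattern, "double", compress = TRUE)
  opt <- list(Source = src)
  if (nrow(cfg$detectors))
    opt$Detector <- lapply(seq_len(nrow(cfg$detectors)), function(i)
      list(Pos = unname(cfg$detectors[i, 1:3]),
           R = unname(cfg$detectors[i, 4])))
  dom <- list(
    Dim = cfg$domain$dim,
    LengthUnit = cfg$domain$length_unit,
    Media = lapply(seq_len(nrow(cfg$domain$media)), function(i)
      as.list(cfg$domain$media[i, ])),
    MediaFormat = cfg$domain$media_format,
    BoundaryCondition = cfg$domain$boundary_string
  )
  if (!is.null(cfg$domain$volume)) {
    vdt <- if (cfg$domain$media_format == "labels") {
      if (max(cfg$domain$volume) < 256) "uint8" else "int32"
    } else "single"
    dom$Volume <- jd_encode(cfg$domain$volume, vdt, compress = TRUE)
  }
  doc <- list(
    Session = list(ID = cfg$session$id,
                   Photons = cfg$session$photons,
                   RNGSeed = cfg$session$seed,
                   DoMismatch = as.integer(cfg$session$do_mismatch),
                   DoNormalize = as.integer(cfg$session$do_normalize),
                   OutDtype = cfg$session$out_dtype),
    Forward = list(T0 = cfg$forward$t0, T1 = cfg$forward$t1,
                   Dt = cfg$forward$dt),
    Optode = opt,
    Domain = dom
  )
  if (!is.null(cfg$shapes)) doc$Shapes <- cfg$shapes
  if (!is.null(path)) {
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = I(17),
                         pretty = TRUE)
    return(invisible(doc))
  }
  doc
}

#' @export
print.voxmc_config <- function(x, ...) {
  cat("voxmc simulation config\n")
  cat(sprintf("  session: %s, %g photons, seed %d\n",
              x$session$id, x$session$photons, x$session$seed))
  cat(sprintf("  domain: %s voxels, %g mm/voxel, %d media, BC '%s'\n",
              paste(x$domain$dim, collapse = "x"), x$domain$length_unit,
              nrow(x$domain$media), x$domain$boundary_string))
  cat(sprintf("  source: %s at (%s); %d detector(s)\n", x$source$type,
              paste(signif(x$source$pos, 4), collapse = ", "),
              nrow(x$detectors)))
  cat(sprintf("  time: [%g, %g] s in %d gate(s) of %g s\n",
              x$forward$t0, x$forward$t1, x$forward$gates, x$forward$dt))
  invisible(x)
}
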