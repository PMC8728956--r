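# CSG shape rasterization into a label volume.
#
# Membership is tested at the voxel center (i+0.5, j+0.5, k+0.5); boundary
# ties (center exactly on a surface) resolve to inside via closed
# inequalities. Shapes are applied in list order: the last shape containing
# a voxel center writes its label. Layer ranges are 0-based inclusive voxel
# index ranges [start, end].

#' Rasterize a CSG shape list into a label volume
#'
#' @param shapes list of single-key shape objects (`Grid`, `Sphere`, `Box`,
#'   `Cylinder`, `XLayers`, `YLayers`, `ZLayers`), applied in order.
#' @param dim 3 integer grid extents; may be omitted when the first shape
#'   is a `Grid` carrying a `Size`.
#' @param default_tag label for voxels no shape touches (default 0,
#'   the background medium).
#' @return integer 3D array of media labels, dim `dim`.
#' @export
#' @examples
#' shapes <- list(
#'   list(Grid = list(Tag = 1, Size = c(20, 20, 20))),
#'   list(Sphere = list(O = c(10, 10, 10), R = 5, Tag = 2))
#' )
#' vol <- rasterize_shapes(shapes)
#' table(vol)
rasterize_shapes <- function(shapes, dim = NULL, default_tag = 0L) {
  if (is.null(dim)) {
    first <- shapes[[1]]
    if (identical(tolower(names(first)[1]), "grid")) {
      dim <- as.integer(unlist(first[[1]]$Size))
    } else {
      vmc_error("grid extents unknown: give dim or start with a Grid shape",
                "shape_grid_error")
    }
  }
  dim <- as.integer(dim)
  stopifnot(length(dim) == 3, all(dim >= 1))
  nx <- dim[1]; ny <- dim[2]; nz <- dim[3]
  vol <- array(as.integer(default_tag), dim)
  cx <- seq_len(nx) - 0.5
  cy <- seq_len(ny) - 0.5
  cz <- seq_len(nz) - 0.5

  clip_warn <- function(kind) {
    warning(sprintf("%s extends outside the grid; clipped", kind),
            call. = FALSE)
  }

  for (s in shapes) {
    kind <- tolower(names(s)[1])
    spec <- s[[1]]
    tag <- as.integer(spec$Tag %||% 1L)
    switch(kind,
      grid = {
        sz <- as.integer(unlist(spec$Size %||% dim))
        if (!identical(sz, dim)) clip_warn("Grid")
        vol[] <- tag
      },
      sphere = {
        O <- as.numeric(unlist(spec$O)); R <- as.numeric(spec$R)
        if (any(O - R < 0) || any(O + R > dim)) clip_warn("Sphere")
        d2 <- outer(outer((cx - O[1])^2, (cy - O[2])^2, "+"),
                    (cz - O[3])^2, "+")
        vol[d2 <= R^2] <- tag
      },
      box = {
        O <- as.numeric(unlist(spec$O))
        Sz <- as.numeric(unlist(spec$Size))
        if (any(O < 0) || any(O + Sz > dim)) clip_warn("Box")
        vol[cx >= O[1] & cx <= O[1] + Sz[1],
            cy >= O[2] & cy <= O[2] + Sz[2],
            cz >= O[3] & cz <= O[3] + Sz[3]] <- tag
      },
      cylinder = {
        C0 <- as.numeric(unlist(spec$C0))
        C1 <- as.numeric(unlist(spec$C1))
        R <- as.numeric(spec$R)
        ax <- C1 - C0
        L2 <- sum(ax^2)
        if (L2 == 0)
          vmc_error("cylinder axis endpoints coincide", "shape_geom_error")
        X <- array(cx, dim)
        Y <- array(rep(cy, each = nx), dim)
        Z <- array(rep(cz, each = nx * ny), dim)
        tt <- ((X - C0[1]) * ax[1] + (Y - C0[2]) * ax[2] +
               (Z - C0[3]) * ax[3]) / L2
        dx <- X - (C0[1] + tt * ax[1])
        dy <- Y - (C0[2] + tt * ax[2])
        dz <- Z - (C0[3] + tt * ax[3])
        vol[tt >= 0 & tt <= 1 & dx^2 + dy^2 + dz^2 <= R^2] <- tag
      },
      xlayers = ,
      ylayers = ,
      zlayers = {
        axis <- match(substr(kind, 1, 1), c("x", "y", "z"))
        nax <- dim[axis]
        for (layer in spec) {
          l <- as.numeric(unlist(layer))
          lo <- l[1]; hi <- l[2]; ltag <- as.integer(l[3])
          if (lo < 0 || hi > nax - 1) {
            clip_warn(paste0(toupper(substr(kind, 1, 1)), "Layers"))
            lo <- max(lo, 0); hi <- min(hi, nax - 1)
          }
          if (hi < lo) next
          idx <- (lo:hi) + 1L
          if (axis == 1) vol[idx, , ] <- ltag
          else if (axis == 2) vol[, idx, ] <- ltag
          else vol[, , idx] <- ltag
        }
      },
      vmc_error(sprintf("unsupported shape kind '%s'", names(s)[1]),
                "shape_kind_error")
    )
  }
  vol
}

# resolve the config's medium definition to a concrete volume
realize_volume <- function(cfg) {
  if (is.null(cfg$domain$volume)) {
    if (is.null(cfg$shapes))
      vmc_error("config defines neither a volume nor shapes",
                "config_volume_error")
    cfg$domain$volume <- rasterize_shapes(cfg$shapes, cfg$domain$dim)
    check_media_coverage(cfg$domain$volume, cfg$domain$media)
  }
  cfg
}
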