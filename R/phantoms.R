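# Synthetic-data generator: parametric port templates, the wax-slab and
# breast-balloon irradiation scenes, voxelization, synthetic CT with metal
# artifacts, and the analysis contours.
#
# All lengths are mm. The beam at gantry 0 travels along +y (anterior ->
# posterior); port magnets are discs with their axis along y.

TTE_MODELS <- c("DermaSpan", "AlloX2", "AlloX2-Pro")

## canonical port dimensions (mm). Magnet thicknesses and the AlloX2-Pro
## magnet diameter are the vendor-quoted values; casing dimensions are
## canonical defaults (outer dimensions are not published) chosen so that
## the DermaSpan/AlloX2 magnets are about three times wider than the
## AlloX2-Pro magnet and the single-port DermaSpan carries a somewhat
## heavier titanium dome than the thin-walled dual AlloX2 ports.
.port_dims <- function(model) {
  switch(model,
    "DermaSpan" = list(magnet_t = 2.41, magnet_r = 15.6, wall = 0.8,
                       casing = "titanium", n_ports = 1, port_dz = 0),
    "AlloX2" = list(magnet_t = 2.50, magnet_r = 13.0, wall = 0.4,
                    casing = "titanium", n_ports = 2, port_dz = 16),
    "AlloX2-Pro" = list(magnet_t = 7.14, magnet_r = 5.2, wall = 1.0,
                        casing = "peek", n_ports = 2, port_dz = 15,
                        port_r = 13, port_h = 9.14),
    stop("unknown model '", model, "'; expected one of ",
         paste(TTE_MODELS, collapse = ", ")))
}

.solid <- function(shape, material, center, ..., density = NULL) {
  c(list(shape = shape, material = material, center = center,
         density = density), list(...))
}

#' Parametric port template for a tissue-expander model
#'
#' Builds the injection/drain port assembly of one of the three expander
#' models as an ordered list of solid primitives (later solids override
#' earlier ones when voxelized). DermaSpan: a single titanium casing with
#' one NdFeB magnet (2.41 mm thick). AlloX2: two titanium ports, one
#' magnet each (2.50 mm). AlloX2-Pro: two PEEK ports with a single central
#' magnet, 7.14 mm thick and 10.4 mm maximum lateral extent. The template
#' frame is centered on the assembly; the magnet disc axis is y.
#'
#' @param model one of "DermaSpan", "AlloX2", "AlloX2-Pro".
#' @param magnet_density magnet density (g/cm^3); default 7.4.
#' @return object of class `port_template` with fields `model`, `solids`,
#'   `magnet_ids`, `ref_point`.
#' @export
#' @examples
#' tpl <- port_template("AlloX2-Pro")
#' port_magnet_thickness(tpl)    # 7.14 mm
port_template <- function(model, magnet_density = 7.4) {
  model <- match.arg(model, TTE_MODELS)
  p <- .port_dims(model)
  solids <- list()
  magnet_ids <- integer(0)
  if (model == "AlloX2-Pro") {
    for (dz in c(-p$port_dz, p$port_dz))
      solids <- c(solids, list(
        .solid("cylinder", "peek", c(0, 0, dz), radius = p$port_r,
               half_height = p$port_h / 2, axis = "y")))
    ## thin PEEK sleeve around the central magnet
    solids <- c(solids, list(
      .solid("cylinder", "peek", c(0, 0, 0), radius = p$magnet_r + p$wall,
             half_height = p$magnet_t / 2 + p$wall, axis = "y"),
      .solid("cylinder", "ndfeb", c(0, 0, 0), radius = p$magnet_r,
             half_height = p$magnet_t / 2, axis = "y",
             density = magnet_density)))
    magnet_ids <- length(solids)
  } else {
    offsets <- if (p$n_ports == 1) 0 else c(-p$port_dz, p$port_dz)
    for (dz in offsets) {
      solids <- c(solids, list(
        .solid("cylinder", p$casing, c(0, 0, dz),
               radius = p$magnet_r + p$wall,
               half_height = p$magnet_t / 2 + p$wall, axis = "y"),
        .solid("cylinder", "ndfeb", c(0, 0, dz), radius = p$magnet_r,
               half_height = p$magnet_t / 2, axis = "y",
               density = magnet_density)))
      magnet_ids <- c(magnet_ids, length(solids))
    }
  }
  out <- structure(list(model = model, solids = solids,
                        magnet_ids = magnet_ids, ref_point = c(0, 0, 0),
                        dims = p),
                   class = "port_template")
  validate_port_template(out)
  out
}

#' @rdname port_template
#' @export
validate_port_template <- function(tpl) {
  stopifnot(inherits(tpl, "port_template"))
  n_mag <- length(tpl$magnet_ids)
  expected <- if (tpl$model == "AlloX2") 2L else 1L
  if (n_mag != expected)
    stop(tpl$model, ": expected ", expected, " magnet(s), got ", n_mag)
  for (id in tpl$magnet_ids) {
    s <- tpl$solids[[id]]
    if (s$material != "ndfeb") stop("magnet solid must be ndfeb")
  }
  invisible(tpl)
}

#' @rdname port_template
#' @export
port_magnet_thickness <- function(tpl) {
  2 * tpl$solids[[tpl$magnet_ids[1]]]$half_height
}

#' @rdname port_template
#' @export
port_magnet_extent <- function(tpl) {
  2 * max(vapply(tpl$magnet_ids,
                 function(id) tpl$solids[[id]]$radius, 0))
}

#' @export
print.port_template <- function(x, ...) {
  cat("<port_template>", x$model, "-", length(x$solids), "solids,",
      length(x$magnet_ids), "magnet(s),",
      sprintf("magnet %.2f mm thick x %.1f mm wide\n",
              port_magnet_thickness(x), port_magnet_extent(x)))
  invisible(x)
}

## translate template solids into world coordinates
.place_template <- function(tpl, at) {
  lapply(tpl$solids, function(s) { s$center <- s$center + at; s })
}

#' Wax-slab irradiation scene
#'
#' The AP-field benchmark geometry: a 30 x 30 x 1.7 cm^3 wax slab with the
#' port assembly embedded at its center, stacked between 1.5 cm of
#' water-equivalent plastic upstream and 10 cm downstream. The beam enters
#' at y = 0 travelling along +y. Probe planes (the film positions) sit at
#' the upstream surface, the two slab interfaces and in the distal falloff.
#'
#' @param model expander model.
#' @param margin_mm air margin around the stack in the voxel bounding box.
#' @param magnet_density magnet density (g/cm^3).
#' @return object of class `tte_scene`.
#' @export
wax_slab_scene <- function(model, margin_mm = 6, magnet_density = 7.4) {
  model <- match.arg(model, TTE_MODELS)
  tpl <- port_template(model, magnet_density = magnet_density)
  slab_c <- 15 + 17 / 2      # slab spans y in [15, 32] mm
  ## abutting slabs are extended into their downstream neighbour (which is
  ## composited later and overrides), so no background leaks into seams
  solids <- list(
    .solid("box", "plastic_water", c(0, 8.5, 0), half = c(150, 8.5, 150)),
    .solid("box", "wax", c(0, slab_c + 1, 0), half = c(150, 9.5, 150)),
    .solid("box", "plastic_water", c(0, 82, 0), half = c(150, 50, 150)))
  n0 <- length(solids)
  solids <- c(solids, .place_template(tpl, c(0, slab_c, 0)))
  structure(list(
    name = "wax_slab", model = model, solids = solids,
    port_solid_idx = n0 + seq_along(tpl$solids),
    magnet_solid_idx = n0 + tpl$magnet_ids,
    template = tpl,
    medium = "wax",                      # what replaces the port
    background = "air",
    bbox = list(x = c(-152, 152), y = c(-margin_mm, 132 + margin_mm),
                z = c(-152, 152)),
    iso = c(0, slab_c, 0),
    surface_y = 0, slab_y = c(15, 32),
    probe_planes_y = c(0, 15, 32, 52, 82),
    profile_point = c(0, slab_c,
                      if (model == "AlloX2") .port_dims(model)$port_dz else 0)
  ), class = "tte_scene")
}

#' Breast tissue-expander irradiation scene
#'
#' The partial-arc geometry: a water-filled silicone balloon (about 1 mm
#' shell) truncated posteriorly where it rests in a wax holder, the port
#' assembly inside the balloon near its anterior apex, and a 5 mm wax bolus
#' on top. Supported for the dual-port models only (the arc study is
#' defined for AlloX2 and AlloX2-Pro). The isocenter is the port assembly
#' center; anterior is -y (beam-facing at gantry 0), posterior +y
#' (holder-facing).
#'
#' @param model "AlloX2" or "AlloX2-Pro".
#' @param half_axes balloon ellipsoid half-axes (x, y, z) in mm.
#' @param base_y posterior truncation plane (mm, balloon frame).
#' @param magnet_density magnet density (g/cm^3).
#' @return object of class `tte_scene`.
#' @export
breast_scene <- function(model, half_axes = c(24, 52, 42), base_y = 28,
                         magnet_density = 7.4) {
  model <- match.arg(model, TTE_MODELS)
  if (model == "DermaSpan")
    stop("DermaSpan is not supported for the arc study (dual-port models only)")
  tpl <- port_template(model, magnet_density = magnet_density)
  shell <- 1
  port_at <- c(0, -30, 0)
  ## the arc isocenter sits on the magnet the analysis profile traverses:
  ## the drain-port magnet for AlloX2 (offset along z), the central magnet
  ## for AlloX2-Pro -- the worst case where the port stays in-beam over
  ## the whole arc
  iso_at <- port_at + c(0, 0, if (model == "AlloX2") .port_dims(model)$port_dz else 0)
  solids <- list(
    ## wax holder below the balloon (bag base rests on it; extends up into
    ## the bag region, which is composited later and overrides)
    .solid("box", "wax", c(0, (base_y + shell - 2 + 46) / 2, 0),
           half = c(52, (46 - base_y - shell + 2) / 2, 52)),
    ## silicone shell = outer ellipsoid, interior water overrides
    ## 5 mm wax bolus on top of the dome; reaches 2 mm into the bag
    ## region so no air seam forms (the bag solids override it)
    .solid("box", "wax", c(0, -(half_axes[2] + shell + 1.5), 0),
           half = c(46, 3.5, 52)),
    .solid("ellipsoid", "silicone", c(0, 0, 0),
           half = half_axes + shell, clip_y = c(-Inf, base_y + shell)),
    .solid("ellipsoid", "water", c(0, 0, 0),
           half = half_axes, clip_y = c(-Inf, base_y)))
  n0 <- length(solids)
  solids <- c(solids, .place_template(tpl, port_at))
  structure(list(
    name = "breast", model = model, solids = solids,
    port_solid_idx = n0 + seq_along(tpl$solids),
    magnet_solid_idx = n0 + tpl$magnet_ids,
    template = tpl,
    medium = "water",
    background = "air",
    bbox = list(x = c(-56, 56), y = c(-(half_axes[2] + 10), 50),
                z = c(-56, 56)),
    iso = iso_at,
    balloon = list(half_axes = half_axes, base_y = base_y, shell = shell),
    probe_planes_y = c(-half_axes[2] - shell, -30, 0, base_y),
    profile_point = c(0, 0,
                      if (model == "AlloX2") .port_dims(model)$port_dz else 0)
  ), class = "tte_scene")
}

#' @export
print.tte_scene <- function(x, ...) {
  cat("<tte_scene>", x$name, "/", x$model, "-", length(x$solids), "solids\n")
  invisible(x)
}

## fractional 1-D overlap of [lo, hi] with voxels centered at `centers`
.overlap1d <- function(centers, half_vox, lo, hi) {
  pmax(0, pmin(centers + half_vox, hi) - pmax(centers - half_vox, lo)) /
    (2 * half_vox)
}

## per-voxel volume coverage of one solid on the grid (0..1), restricted to
## the solid's bounding box; mass-conserving rasterization.
.solid_coverage <- function(s, origin, spacing, dims) {
  ax <- lapply(1:3, function(a) origin[a] + (seq_len(dims[a]) - 0.5) * spacing[a])
  hv <- spacing / 2
  cl <- s$clip_y
  if (is.null(cl)) cl <- c(-Inf, Inf) else cl <- cl + s$center[2]
  if (s$shape == "box") {
    lo <- s$center - s$half; hi <- s$center + s$half
    lo[2] <- max(lo[2], cl[1]); hi[2] <- min(hi[2], cl[2])
    fx <- .overlap1d(ax[[1]], hv[1], lo[1], hi[1])
    fy <- .overlap1d(ax[[2]], hv[2], lo[2], hi[2])
    fz <- .overlap1d(ax[[3]], hv[3], lo[3], hi[3])
    idx <- list(which(fx > 0), which(fy > 0), which(fz > 0))
    cov <- outer(outer(fx[idx[[1]]], fy[idx[[2]]]), fz[idx[[3]]])
    return(list(idx = idx, cov = cov))
  }
  if (s$shape == "cylinder") {
    lo_y <- max(s$center[2] - s$half_height, cl[1])
    hi_y <- min(s$center[2] + s$half_height, cl[2])
    fy <- .overlap1d(ax[[2]], hv[2], lo_y, hi_y)
    ix <- which(abs(ax[[1]] - s$center[1]) <= s$radius + hv[1])
    iz <- which(abs(ax[[3]] - s$center[3]) <= s$radius + hv[3])
    iy <- which(fy > 0)
    if (!length(ix) || !length(iy) || !length(iz))
      return(list(idx = list(ix, iy, iz),
                  cov = array(0, c(length(ix), length(iy), length(iz)))))
    ## disc cross-section coverage by 5x5 subsampling of the voxel square
    off <- (seq_len(5) - 3) / 5
    area <- matrix(0, length(ix), length(iz))
    for (ox in off) for (oz in off) {
      px <- ax[[1]][ix] + ox * spacing[1] - s$center[1]
      pz <- ax[[3]][iz] + oz * spacing[3] - s$center[3]
      area <- area + (outer(px^2, pz^2, `+`) <= s$radius^2)
    }
    area <- area / 25
    cov <- outer(area, fy[iy])           # (x, z, y) -> reorder
    cov <- aperm(cov, c(1, 3, 2))
    return(list(idx = list(ix, iy, iz), cov = cov))
  }
  if (s$shape == "ellipsoid") {
    ix <- which(abs(ax[[1]] - s$center[1]) <= s$half[1] + hv[1])
    iy <- which(ax[[2]] - s$center[2] >= -s$half[2] - hv[2] &
                ax[[2]] <= min(s$center[2] + s$half[2], cl[2]) + hv[2])
    iz <- which(abs(ax[[3]] - s$center[3]) <= s$half[3] + hv[3])
    cov <- array(0, c(length(ix), length(iy), length(iz)))
    off <- (seq_len(3) - 2) / 3
    for (ox in off) for (oy in off) for (oz in off) {
      px <- (ax[[1]][ix] + ox * spacing[1] - s$center[1]) / s$half[1]
      py <- ax[[2]][iy] + oy * spacing[2]
      pz <- (ax[[3]][iz] + oz * spacing[3] - s$center[3]) / s$half[3]
      pyn <- (py - s$center[2]) / s$half[2]
      inside <- outer(outer(px^2, pyn^2, `+`), pz^2, `+`) <= 1
      okc <- py >= cl[1] & py <= cl[2]
      if (!all(okc)) inside <- sweep(inside, 2, okc, `&`)
      cov <- cov + inside
    }
    return(list(idx = list(ix, iy, iz), cov = cov / 27))
  }
  stop("unknown shape ", s$shape)
}

## composite a list of solids onto density/label arrays (later overrides
## earlier, proportionally to volume coverage; labels switch at >= 50%)
.rasterize_solids <- function(solids, origin, spacing, dims,
                              density, labels, materials) {
  for (s in solids) {
    sc <- .solid_coverage(s, origin, spacing, dims)
    if (!all(lengths(sc$idx) > 0)) next
    rho <- if (is.null(s$density)) tte_material(s$material)$density else s$density
    code <- match(s$material, materials)
    if (is.na(code)) { materials <- c(materials, s$material); code <- length(materials) }
    sub <- density[sc$idx[[1]], sc$idx[[2]], sc$idx[[3]], drop = FALSE]
    density[sc$idx[[1]], sc$idx[[2]], sc$idx[[3]]] <-
      sc$cov * rho + (1 - sc$cov) * sub
    lsub <- labels[sc$idx[[1]], sc$idx[[2]], sc$idx[[3]], drop = FALSE]
    lsub[sc$cov >= 0.5] <- code
    labels[sc$idx[[1]], sc$idx[[2]], sc$idx[[3]]] <- lsub
  }
  list(density = density, labels = labels, materials = materials)
}

## vectorized point-in-solid test on coordinate arrays (mm)
.solid_mask <- function(s, X, Y, Z) {
  cx <- s$center[1]; cy <- s$center[2]; cz <- s$center[3]
  m <- switch(s$shape,
    box = abs(X - cx) <= s$half[1] & abs(Y - cy) <= s$half[2] &
          abs(Z - cz) <= s$half[3],
    cylinder = {
      if (!identical(s$axis, "y")) stop("only y-axis cylinders supported")
      (X - cx)^2 + (Z - cz)^2 <= s$radius^2 & abs(Y - cy) <= s$half_height
    },
    ellipsoid = ((X - cx) / s$half[1])^2 + ((Y - cy) / s$half[2])^2 +
                ((Z - cz) / s$half[3])^2 <= 1,
    stop("unknown shape ", s$shape))
  if (!is.null(s$clip_y)) m <- m & Y >= s$clip_y[1] + cy & Y <= s$clip_y[2] + cy
  m
}

#' Voxelize a scene
#'
#' Rasterizes the scene's solids in priority order (later solids override
#' earlier ones: the port casing overrides the slab/balloon, the magnet
#' overrides the casing) on a regular grid. Rasterization is
#' mass-conserving: per-voxel densities are composited by the solid's
#' fractional volume coverage (exact per-axis overlaps for boxes and
#' cylinder heights, subsampled coverage for disc cross-sections and
#' ellipsoids), so that radiological path lengths through thin, dense
#' structures like the 2.4 mm port magnets are preserved on the 2 mm dose
#' grid; material labels follow majority (>= 50%) coverage. Produces the
#' geometric ground truth used by both dose engines.
#'
#' @param scene a [wax_slab_scene()] or [breast_scene()].
#' @param spacing voxel spacing in mm (scalar or length-3); default the
#'   2 mm dose-grid resolution.
#' @return object of class `voxel_phantom`: `density` and `labels`
#'   [tte_volume()]s, `materials` (label code -> material name), and the
#'   scene description.
#' @export
voxelize <- function(scene, spacing = 2) {
  stopifnot(inherits(scene, "tte_scene"))
  if (length(spacing) == 1L) spacing <- rep(spacing, 3L)
  if (any(spacing <= 0)) stop("spacing must be > 0")
  if (!length(scene$solids)) stop("scene is empty")
  bb <- scene$bbox
  lo <- c(bb$x[1], bb$y[1], bb$z[1])
  n <- pmax(1L, as.integer(ceiling(c(diff(bb$x), diff(bb$y), diff(bb$z)) / spacing)))
  mats <- scene$background
  labels <- array(1L, n)
  density <- array(tte_material(scene$background)$density, n)
  ras <- .rasterize_solids(scene$solids, lo, spacing, n,
                           density, labels, mats)
  density <- ras$density; labels <- ras$labels; mats <- ras$materials
  structure(list(
    density = tte_volume(density, lo, spacing),
    labels = tte_volume(labels, lo, spacing),
    materials = mats,
    scene = scene, spacing = spacing, origin = lo,
    provenance = list(scene = scene$name, model = scene$model,
                      spacing = spacing)),
    class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$density$data)
  cat(sprintf("<voxel_phantom> %s/%s, %d x %d x %d @ %s mm\n",
              x$scene$name, x$scene$model, d[1], d[2], d[3],
              paste(signif(x$spacing, 3), collapse = "x")))
  invisible(x)
}

## logical mask of port-material voxels
.port_mask <- function(phantom) {
  port_mats <- c("titanium", "ndfeb", "peek")
  codes <- which(phantom$materials %in% port_mats)
  array(phantom$labels$data %in% codes, dim(phantom$labels$data))
}

.magnet_mask <- function(phantom) {
  code <- match("ndfeb", phantom$materials)
  phantom$labels$data == code
}

#' Synthetic CT of a phantom
#'
#' Emulates the CT appearance of the phantom: densities are mapped to
#' Hounsfield units through a piecewise-linear curve (air -1000, water 0,
#' 1000 HU per g/cm^3 above water) that saturates at the maximum density of
#' the scanner's conversion table (default 2.5 g/cm^3) -- metal voxels
#' therefore read back at the saturation density, not their true density.
#' With `bloom = TRUE` the bright footprint of titanium-encased magnets is
#' dilated along the beam axis so the apparent artifact is about three
#' times the magnet thickness; the PEEK-encased AlloX2-Pro magnet (no
#' saturating casing) keeps an artifact of about its own thickness.
#' Optional seeded low-amplitude streaks can be added outside the port.
#'
#' @param phantom a [voxelize()]d phantom.
#' @param saturation saturation density, g/cm^3 (> 0).
#' @param bloom logical, enlarge the Ti-encased artifact footprint.
#' @param streaks logical, add seeded radial HU perturbations.
#' @param seed integer seed for the streak noise.
#' @return object of class `synthetic_ct`: `hu` [tte_volume()], conversion
#'   `curve` (data.frame hu/density), `saturation`, and the source scene.
#' @export
synthesize_ct <- function(phantom, saturation = 2.5, bloom = TRUE,
                          streaks = FALSE, seed = 1L) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (saturation <= 0) stop("saturation must be > 0")
  dens <- phantom$density$data
  hu_cap <- 1000 * (saturation - 1)
  hu <- pmin(round(1000 * (dens - 1)), hu_cap)

  artifact <- dens > saturation
  if (bloom && any(artifact)) {
    tpl <- phantom$scene$template
    casing <- tpl$dims$casing
    if (identical(casing, "titanium")) {
      t_mag <- port_magnet_thickness(tpl)
      metal_t <- t_mag + 2 * tpl$dims$wall
      pad_mm <- (3 * t_mag - metal_t) / 2
      ky <- max(0L, as.integer(round(pad_mm / phantom$spacing[2])))
      ## bloom acts along the beam axis (the dimension the CT artifact is
      ## observed to exaggerate); dual-port models stay separable
      artifact <- .dilate_mask(artifact, c(0L, ky, 0L))
      hu[artifact] <- hu_cap
    }
    ## PEEK casing: no saturating metal besides the magnet; footprint stays
  }
  if (streaks) {
    set.seed(seed)
    nz <- which(!artifact & dens > 0.5)
    hu[nz] <- hu[nz] + as.integer(round(stats::rnorm(length(nz), 0, 15)))
  }
  curve <- data.frame(hu = c(-1000, 0, hu_cap),
                      density = c(tte_material("air")$density, 1, saturation))
  structure(list(
    hu = tte_volume(hu, phantom$origin, phantom$spacing,
                    meta = list(model = phantom$scene$model)),
    curve = curve, saturation = saturation,
    artifact = artifact,
    scene = phantom$scene, spacing = phantom$spacing,
    origin = phantom$origin,
    provenance = c(phantom$provenance,
                   list(saturation = saturation, bloom = bloom,
                        streaks = streaks))),
    class = "synthetic_ct")
}

#' @export
print.synthetic_ct <- function(x, ...) {
  cat(sprintf("<synthetic_ct> %s/%s, saturation %.2f g/cm^3\n",
              x$scene$name, x$scene$model, x$saturation))
  invisible(x)
}

#' Convert HU to density through a CT conversion curve
#' @param ct a [synthesize_ct()] object.
#' @return numeric array of densities (g/cm^3), capped at the saturation
#'   density.
#' @export
ct_density <- function(ct) {
  cv <- ct$curve
  d <- stats::approx(cv$hu, cv$density, xout = pmin(pmax(ct$hu$data, min(cv$hu)),
                                                    max(cv$hu)),
                     rule = 2)$y
  array(d, dim(ct$hu$data))
}

## integer box dilation of a logical mask (radius per axis, voxels)
.dilate_mask <- function(mask, k) {
  if (all(k == 0L)) return(mask)
  d <- dim(mask)
  out <- mask
  shift_axis <- function(m, axis, by) {
    idx <- rep(list(quote(expr = )), 3)
    src <- seq_len(d[axis]) - by
    src[src < 1L] <- 1L; src[src > d[axis]] <- d[axis]
    ## out-of-range shifts clamp to edge: acceptable for interior artifacts
    idx[[axis]] <- src
    do.call(`[`, c(list(m), idx, list(drop = FALSE)))
  }
  for (axis in 1:3) {
    if (k[axis] == 0L) next
    acc <- out
    for (by in seq_len(k[axis])) {
      acc <- acc | shift_axis(out, axis, by) | shift_axis(out, axis, -by)
    }
    out <- acc
  }
  out
}

#' Analysis contours for the breast scene
#'
#' Builds the silicone-bag mask and a 3 mm outward expansion of the bag
#' wall split into four 90-degree azimuthal sectors about the bag centroid
#' in the axial (x-y) plane: C_Anterior (beam-facing, -y), C_Posterior
#' (holder-facing, +y), C_Left (+x) and C_Right (-x).
#'
#' @param phantom a voxelized [breast_scene()] phantom.
#' @return list with `bag` and contours `C_Anterior`, `C_Posterior`,
#'   `C_Left`, `C_Right`, each of class `tte_contour` (logical volume +
#'   volume in cc).
#' @export
make_shell_contours <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (!identical(phantom$scene$name, "breast"))
    stop("shell contours are defined for the breast scene")
  mats <- phantom$materials
  bag_codes <- which(mats %in% c("water", "silicone", "titanium", "ndfeb", "peek"))
  bag <- array(phantom$labels$data %in% bag_codes, dim(phantom$labels$data))
  if (!any(bag)) stop("no bag found in phantom")
  sp <- phantom$spacing
  dist <- cpp_dist_transform(bag, dim(bag), sp)
  shell <- !bag & dist <= 3.0 + 1e-9
  ## centroid of the bag in the axial plane
  idx <- which(bag, arr.ind = TRUE)
  cx <- phantom$origin[1] + (mean(idx[, 1]) - 0.5) * sp[1]
  cy <- phantom$origin[2] + (mean(idx[, 2]) - 0.5) * sp[2]
  sid <- which(shell, arr.ind = TRUE)
  px <- phantom$origin[1] + (sid[, 1] - 0.5) * sp[1] - cx
  py <- phantom$origin[2] + (sid[, 2] - 0.5) * sp[2] - cy
  ang <- atan2(px, -py)  # 0 = anterior (-y), +pi/2 = left (+x)
  sector <- character(nrow(sid))
  sector[abs(ang) <= pi / 4] <- "C_Anterior"
  sector[abs(ang) >= 3 * pi / 4] <- "C_Posterior"
  sector[ang > pi / 4 & ang < 3 * pi / 4] <- "C_Left"
  sector[ang < -pi / 4 & ang > -3 * pi / 4] <- "C_Right"
  vox_cc <- prod(sp) / 1000
  mk <- function(name, mask) {
    structure(list(name = name,
                   mask = tte_volume(mask, phantom$origin, sp),
                   volume_cc = sum(mask) * vox_cc),
              class = "tte_contour")
  }
  out <- list(bag = mk("bag", bag))
  lin <- (sid[, 3] - 1L) * prod(dim(bag)[1:2]) +
         (sid[, 2] - 1L) * dim(bag)[1] + sid[, 1]
  for (nm in c("C_Anterior", "C_Posterior", "C_Left", "C_Right")) {
    m <- array(FALSE, dim(bag))
    m[lin[sector == nm]] <- TRUE
    out[[nm]] <- mk(nm, m)
  }
  out
}

#' @export
print.tte_contour <- function(x, ...) {
  cat(sprintf("<tte_contour> %s: %.1f cc\n", x$name, x$volume_cc))
  invisible(x)
}
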