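# RS1 (window-level threshold + unity override) and RS2 (rigid template
# registration + material assignment) density-override strategies, plus the
# ground-truth and port-substituted grids.

.new_density_grid <- function(density, matid, materials, strategy, iso, meta) {
  structure(list(density = density, matid = matid, materials = materials,
                 strategy = strategy, iso = iso, meta = meta),
            class = "tte_density_grid")
}

#' @export
print.tte_density_grid <- function(x, ...) {
  d <- dim(x$density$data)
  cat(sprintf("<tte_density_grid> strategy %s, %d x %d x %d\n",
              x$strategy, d[1], d[2], d[3]))
  invisible(x)
}

#' Ground-truth density grid of a phantom
#' @param phantom a [voxelize()]d phantom.
#' @return a `tte_density_grid` with strategy tag "truth".
#' @export
truth_grid <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  .new_density_grid(phantom$density, phantom$labels$data, phantom$materials,
                    "truth", phantom$scene$iso,
                    list(scene = phantom$scene$name, model = phantom$scene$model))
}

#' Port-substituted ("no port") density grid
#'
#' Replaces every port voxel (casing and magnet) by the enclosing medium --
#' wax in the slab scene, water in the breast scene -- leaving all other
#' voxels untouched. This is the reference configuration against which the
#' dosimetric impact of the port is measured.
#'
#' @param phantom a [voxelize()]d phantom containing a port.
#' @return a `tte_density_grid` with strategy tag "no-port".
#' @export
no_port_grid <- function(phantom) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (!length(phantom$scene$port_solid_idx))
    stop("no port present in phantom")
  ## re-rasterize the scene without the port solids, so partial-volume
  ## boundary voxels revert exactly to the enclosing medium
  scene2 <- phantom$scene
  scene2$solids <- scene2$solids[-scene2$port_solid_idx]
  scene2$port_solid_idx <- integer(0)
  scene2$magnet_solid_idx <- integer(0)
  ph2 <- voxelize(scene2, phantom$spacing)
  .new_density_grid(
    ph2$density, ph2$labels$data, ph2$materials, "no-port",
    phantom$scene$iso,
    list(scene = phantom$scene$name, model = phantom$scene$model))
}

#' No-port baseline in the planning (override) context
#'
#' The counterpart of [no_port_grid()] for strategy comparisons on a
#' synthetic CT: the whole override region is set to unity density (no
#' port template, no retained artifact), voxels outside keep their
#' CT-converted densities. Differencing an RS1 or RS2 run against this
#' baseline isolates the dosimetric effect of the port representation
#' itself, with the override context held fixed.
#'
#' @inheritParams rs1_override
#' @return a `tte_density_grid` with strategy tag "no-port".
#' @export
no_port_override <- function(ct, threshold_hu = NULL, region = NULL) {
  stopifnot(inherits(ct, "synthetic_ct"))
  if (is.null(threshold_hu)) threshold_hu <- 1000 * (2.0 - 1)
  if (is.null(region)) {
    am <- .artifact_mask(ct, threshold_hu,
                         .expected_components(ct$scene$model))
    region <- .default_region(ct, am)
  }
  dens <- ct_density(ct)
  dens[region] <- 1.0
  .new_density_grid(
    tte_volume(dens, ct$origin, ct$spacing),
    array(1L, dim(dens)), "water", "no-port", ct$scene$iso,
    list(scene = ct$scene$name, model = ct$scene$model,
         threshold_hu = threshold_hu))
}

## default override region: the artifact bounding box grown by `margin_mm`
## for the slab scene, the bag + margin for the breast scene.
.default_region <- function(ct, artifact_mask, margin_mm = 10) {
  d <- dim(ct$hu$data)
  if (identical(ct$scene$name, "breast")) {
    ## approximate bag: everything inside the balloon outer ellipsoid
    sp <- ct$spacing
    k <- as.integer(ceiling(margin_mm / sp))
    b <- ct$scene$balloon
    n <- d
    xs <- ct$origin[1] + (seq_len(n[1]) - 0.5) * sp[1]
    ys <- ct$origin[2] + (seq_len(n[2]) - 0.5) * sp[2]
    zs <- ct$origin[3] + (seq_len(n[3]) - 0.5) * sp[3]
    X <- array(rep(xs, times = n[2] * n[3]), n)
    Y <- array(rep(rep(ys, each = n[1]), times = n[3]), n)
    Z <- array(rep(zs, each = n[1] * n[2]), n)
    ax <- b$half_axes + b$shell + margin_mm
    (X / ax[1])^2 + (Y / ax[2])^2 + (Z / ax[3])^2 <= 1 &
      Y <= b$base_y + b$shell + margin_mm
  } else {
    idx <- which(artifact_mask, arr.ind = TRUE)
    k <- as.integer(ceiling(margin_mm / ct$spacing))
    lo <- pmax(1L, apply(idx, 2, min) - k)
    hi <- pmin(d, apply(idx, 2, max) + k)
    m <- array(FALSE, d)
    m[lo[1]:hi[1], lo[2]:hi[2], lo[3]:hi[3]] <- TRUE
    m
  }
}

## threshold segmentation of the CT, keeping the n largest components
.artifact_mask <- function(ct, threshold_hu, n_components) {
  hu <- ct$hu$data
  if (threshold_hu > max(hu)) stop("threshold above the CT maximum: empty artifact mask")
  raw <- hu >= threshold_hu
  lab <- cpp_label_components(as.vector(raw), dim(hu))
  ncomp <- attr(lab, "n_components")
  if (ncomp == 0) stop("empty artifact mask at this threshold")
  keep <- order(tabulate(lab[lab > 0], nbins = ncomp),
                decreasing = TRUE)[seq_len(min(n_components, ncomp))]
  array(lab %in% keep, dim(hu))
}

## expected number of bright CT components per model: the titanium-encased
## models show one bright blob per port; for AlloX2-Pro only the magnet
## saturates (PEEK stays dark).
.expected_components <- function(model) {
  switch(model, "DermaSpan" = 1L, "AlloX2" = 2L, "AlloX2-Pro" = 1L)
}

#' RS1: window-level threshold density override
#'
#' Clinical strategy 1: the metal is identified by thresholding the CT at a
#' window level showing only the brightest region (default: the HU value of
#' 2.0 g/cm^3 on the conversion curve), keeping the largest connected
#' components up to the model's port count. Artifact voxels keep their
#' CT-converted (saturation-capped) density; every other voxel inside the
#' override region is set to unity density; voxels outside the region keep
#' their CT densities. All voxels are transported as density-scaled water,
#' as a treatment planning system does after a density override.
#'
#' @param ct a [synthesize_ct()] object.
#' @param threshold_hu segmentation threshold (HU).
#' @param region logical array: the override region (contour enclosing the
#'   artifact); default: artifact bounding box + 1 cm (slab scene) or the
#'   bag + 1 cm margin (breast scene).
#' @param n_components number of bright components to keep; default per
#'   model.
#' @return a `tte_density_grid` (strategy "RS1") with the artifact mask in
#'   `meta$artifact`.
#' @export
rs1_override <- function(ct, threshold_hu = NULL, region = NULL,
                         n_components = NULL) {
  stopifnot(inherits(ct, "synthetic_ct"))
  if (is.null(threshold_hu)) threshold_hu <- 1000 * (2.0 - 1)
  if (is.null(n_components))
    n_components <- .expected_components(ct$scene$model)
  am <- .artifact_mask(ct, threshold_hu, n_components)
  if (is.null(region)) region <- .default_region(ct, am)
  dens <- ct_density(ct)
  dens[region & !am] <- 1.0
  .new_density_grid(
    tte_volume(dens, ct$origin, ct$spacing),
    array(1L, dim(dens)), "water", "RS1", ct$scene$iso,
    list(scene = ct$scene$name, model = ct$scene$model,
         threshold_hu = threshold_hu, artifact = am, region = region))
}

#' RS2: rigid template registration density override
#'
#' Clinical strategy 2: the vendor port template is registered rigidly to
#' the CT artifact and voxelized with its true materials and densities (the
#' magnet keeps 7.4 g/cm^3 regardless of CT saturation); every other voxel
#' inside the override region is set to unity density. The pose is
#' initialized at the artifact centroid and refined by an exhaustive local
#' search (translations up to +/-3 voxels, in-plane rotation +/-10 degrees
#' in 1 degree steps about the y axis) maximizing the Dice overlap between
#' the template's high-density footprint and the artifact mask;
#' deterministic, ties broken towards the smallest translation then the
#' smallest rotation.
#'
#' @inheritParams rs1_override
#' @param template the [port_template()] matching the scanned model.
#' @param search_vox translation search radius, voxels.
#' @param search_rot_deg rotation search half-range, degrees.
#' @param min_overlap minimum acceptable Dice overlap (registration
#'   failure below it).
#' @return list with `grid` (a `tte_density_grid`, strategy "RS2") and
#'   `pose` (class `rigid_pose`: translation mm, rotation rad, dice).
#' @export
rs2_register <- function(ct, template, threshold_hu = NULL, region = NULL,
                         search_vox = 3L, search_rot_deg = 10,
                         min_overlap = 0.2) {
  stopifnot(inherits(ct, "synthetic_ct"), inherits(template, "port_template"))
  if (!identical(template$model, ct$scene$model))
    stop("template model ", template$model, " does not match scene model ",
         ct$scene$model)
  if (is.null(threshold_hu)) threshold_hu <- 1000 * (2.0 - 1)
  am <- .artifact_mask(ct, threshold_hu,
                       .expected_components(ct$scene$model))
  if (is.null(region)) region <- .default_region(ct, am)
  d <- dim(ct$hu$data)
  sp <- ct$spacing

  ## artifact centroid (mm, world)
  idx <- which(am, arr.ind = TRUE)
  centroid <- ct$origin + (colMeans(idx) - 0.5) * sp

  ## high-density footprint of the template (solids with density > 2)
  hi_solids <- Filter(function(s) {
    dens <- if (is.null(s$density)) tte_material(s$material)$density else s$density
    dens > 2
  }, template$solids)

  xs <- ct$origin[1] + (seq_len(d[1]) - 0.5) * sp[1]
  ys <- ct$origin[2] + (seq_len(d[2]) - 0.5) * sp[2]
  zs <- ct$origin[3] + (seq_len(d[3]) - 0.5) * sp[3]
  X <- array(rep(xs, times = d[2] * d[3]), d)
  Y <- array(rep(rep(ys, each = d[1]), times = d[3]), d)
  Z <- array(rep(zs, each = d[1] * d[2]), d)

  footprint_at <- function(translation, rot) {
    ## rotate about y through the template reference, then translate
    cr <- cos(rot); sr <- sin(rot)
    at <- centroid + translation
    m <- array(FALSE, d)
    for (s in hi_solids) {
      cx <- cr * s$center[1] + sr * s$center[3]
      cz <- -sr * s$center[1] + cr * s$center[3]
      s2 <- s; s2$center <- c(cx + at[1], s$center[2] + at[2], cz + at[3])
      m <- m | .solid_mask(s2, X, Y, Z)
    }
    m
  }
  dice <- function(a, b) {
    i <- sum(a & b); 2 * i / (sum(a) + sum(b))
  }
  shifts <- expand.grid(ix = -search_vox:search_vox,
                        iy = -search_vox:search_vox,
                        iz = -search_vox:search_vox)
  rots <- seq(-search_rot_deg, search_rot_deg, by = 1) * pi / 180
  best <- list(dice = -1, tr = c(0, 0, 0), rot = 0)
  for (r in rots) {
    base <- footprint_at(c(0, 0, 0), r)
    bi <- which(base)
    if (!length(bi)) next
    arr <- which(base, arr.ind = TRUE)
    for (k in seq_len(nrow(shifts))) {
      sh <- c(shifts$ix[k], shifts$iy[k], shifts$iz[k])
      ii <- arr[, 1] + sh[1]; jj <- arr[, 2] + sh[2]; kk <- arr[, 3] + sh[3]
      ok <- ii >= 1 & ii <= d[1] & jj >= 1 & jj <= d[2] & kk >= 1 & kk <= d[3]
      lin <- ii[ok] + (jj[ok] - 1L) * d[1] + (kk[ok] - 1L) * d[1] * d[2]
      inter <- sum(am[lin])
      dc <- 2 * inter / (sum(ok) + sum(am))
      better <- dc > best$dice + 1e-12 ||
        (abs(dc - best$dice) <= 1e-12 &&
         (sum((sh * sp)^2) < sum(best$tr^2) - 1e-9 ||
          (abs(sum((sh * sp)^2) - sum(best$tr^2)) <= 1e-9 &&
           abs(r) < abs(best$rot))))
      if (better) best <- list(dice = dc, tr = sh * sp, rot = r)
    }
  }
  if (best$dice < min_overlap)
    stop(sprintf("registration failure: best overlap %.3f below floor %.3f",
                 best$dice, min_overlap))
  rot <- ((best$rot + pi) %% (2 * pi)) - pi
  pose <- structure(list(translation = best$tr, rotation = rot,
                         dice = best$dice,
                         anchor = centroid + best$tr),
                    class = "rigid_pose")

  ## voxelize the full template at the registered pose with true material
  ## densities (mass-conserving compositing, as in voxelize()); the
  ## override region is grown to cover the registered template footprint
  at <- pose$anchor
  cr <- cos(rot); sr <- sin(rot)
  solids2 <- lapply(template$solids, function(s) {
    cx <- cr * s$center[1] + sr * s$center[3]
    cz <- -sr * s$center[1] + cr * s$center[3]
    s$center <- c(cx + at[1], s$center[2] + at[2], cz + at[3])
    s
  })
  for (s2 in solids2) {
    sc2 <- .solid_coverage(s2, ct$origin, sp, d)
    if (all(lengths(sc2$idx) > 0))
      region[sc2$idx[[1]], sc2$idx[[2]], sc2$idx[[3]]] <-
        region[sc2$idx[[1]], sc2$idx[[2]], sc2$idx[[3]]] | (sc2$cov > 0)
  }
  dens <- ct_density(ct)
  dens[region] <- 1.0
  matid <- array(1L, d)
  materials <- "water"
  ras <- .rasterize_solids(solids2, ct$origin, sp, d, dens, matid, materials)
  dens <- ras$density; matid <- ras$labels; materials <- ras$materials
  grid <- .new_density_grid(
    tte_volume(dens, ct$origin, sp), matid, materials, "RS2", ct$scene$iso,
    list(scene = ct$scene$name, model = ct$scene$model,
         threshold_hu = threshold_hu, artifact = am, pose = pose,
         region = region))
  list(grid = grid, pose = pose)
}

#' @export
print.rigid_pose <- function(x, ...) {
  cat(sprintf("<rigid_pose> t = (%.1f, %.1f, %.1f) mm, rot = %.1f deg, Dice %.3f\n",
              x$translation[1], x$translation[2], x$translation[3],
              x$rotation * 180 / pi, x$dice))
  invisible(x)
}
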