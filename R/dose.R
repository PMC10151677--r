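# Beam models, the two dose engines (voxel Monte Carlo and analytic
# primary-beam raytracer), calibration, and the exponential PDD fit.

#' Static beam specification
#'
#' A rectangular open field from a point source. The field is defined at
#' `field_dist` cm from the source (100 cm for both the SSD-100 AP setup
#' and the SAD-100 arc control points). Gantry angle rotates the source
#' about the z axis through `ref`: gantry 0 has the source at -y (anterior)
#' with the beam travelling +y; positive angles move the source towards +x.
#'
#' @param field field size c(x, z) in cm at the definition plane.
#' @param mu monitor units delivered by this beam.
#' @param spectrum a [spectrum_6mv()] object.
#' @param ssd source-to-reference distance in cm; the source sits `ssd`
#'   upstream of `ref` along the beam axis.
#' @param gantry gantry angle, degrees.
#' @param ref reference point (mm, world): the surface point for an SSD
#'   setup or the isocenter for a SAD setup.
#' @return object of class `tte_beam`.
#' @export
beam_spec <- function(field = c(15, 10), mu = 500, spectrum = spectrum_6mv(),
                      ssd = 100, gantry = 0, ref = c(0, 0, 0)) {
  stopifnot(length(field) == 2L, all(field > 0), ssd > 0, mu > 0)
  g <- gantry * pi / 180
  axis <- c(sin(g), cos(g), 0)            # unit vector source -> ref
  e_x <- c(cos(g), -sin(g), 0)
  e_z <- c(0, 0, 1)
  src <- ref - ssd * 10 * axis            # mm
  structure(list(field = field, mu = mu, spectrum = spectrum, ssd = ssd,
                 gantry = gantry, ref = ref, src = src, axis = axis,
                 e_x = e_x, e_z = e_z, field_dist = ssd),
            class = "tte_beam")
}

#' Arc specification
#'
#' A conformal arc as a sequence of static control points with the total
#' monitor units split equally. The default 90 to 270 degrees
#' counterclockwise passes through gantry 0 (anterior), i.e. the couch is
#' never entered; both endpoints (the parallel-opposed lateral fields) are
#' included.
#'
#' @param start,stop gantry angles, degrees.
#' @param direction "ccw" or "cw".
#' @param spacing control-point spacing, degrees (must divide the span).
#' @param field field size c(x, z) cm at the isocenter.
#' @param mu total monitor units.
#' @param spectrum source spectrum.
#' @param sad source-axis distance, cm.
#' @return object of class `tte_arc`.
#' @export
arc_spec <- function(start = 90, stop = 270, direction = "ccw", spacing = 2,
                     field = c(3, 3), mu = 355, spectrum = spectrum_6mv(),
                     sad = 100) {
  direction <- match.arg(direction, c("ccw", "cw"))
  span <- if (direction == "ccw") (start - stop) %% 360 else (stop - start) %% 360
  if (span == 0) span <- 360
  if (span > 360) stop("arc span must be <= 360 degrees")
  if (abs(span / spacing - round(span / spacing)) > 1e-9)
    stop("control-point spacing must divide the arc span")
  k <- 0:round(span / spacing)
  angles <- if (direction == "ccw") (start - k * spacing) %% 360
            else (start + k * spacing) %% 360
  structure(list(start = start, stop = stop, direction = direction,
                 spacing = spacing, angles = angles, field = field, mu = mu,
                 spectrum = spectrum, sad = sad),
            class = "tte_arc")
}

## -- per-material cross-section tables on the grid nodes ------------------

.mat_tables <- function(materials) {
  xs <- xs_tables()
  eg <- xs$energies
  key <- paste(materials, collapse = "|")
  if (!is.null(.ttedose$mat_tab[[key]])) return(.ttedose$mat_tab[[key]])
  nmat <- length(materials)
  mk <- function() matrix(0, length(eg), nmat)
  out <- list(egrid = eg, pe = mk(), inc = mk(), pair = mk(), tr = mk())
  for (j in seq_len(nmat)) {
    m <- tte_material(materials[j])
    out$pe[, j] <- mixture_mu_rho(m, eg, "photoelectric")
    out$inc[, j] <- mixture_mu_rho(m, eg, "compton")
    out$pair[, j] <- mixture_mu_rho(m, eg, "pair")
    out$tr[, j] <- mu_tr_over_rho(m, eg)
  }
  if (is.null(.ttedose$mat_tab)) .ttedose$mat_tab <- list()
  .ttedose$mat_tab[[key]] <- out
  out
}

## construct the dose object from kernel output
.make_dose <- function(res, grid, engine, histories, seed, nbatch, meta) {
  nb <- res$nbatch
  mean_b <- res$sum / nb
  var_b <- pmax(0, (res$sumsq - nb * mean_b^2) / max(1, nb - 1))
  se <- sqrt(var_b / nb)
  rel <- ifelse(mean_b > 0, se / mean_b, 0)
  d <- dim(grid$density$data)
  structure(list(
    dose = tte_volume(array(res$sum / histories, d), grid$density$origin,
                      grid$density$spacing),
    relunc = tte_volume(array(rel, d), grid$density$origin,
                        grid$density$spacing),
    engine = engine, histories = histories, seed = seed, nbatch = nbatch,
    e_launched = res$e_launched, e_transferred = res$e_transferred,
    e_escaped = res$e_escaped,
    calibrated = FALSE, meta = meta),
    class = "tte_dose")
}

#' @export
print.tte_dose <- function(x, ...) {
  cat(sprintf("<tte_dose> engine %s, %g histories, seed %s%s\n", x$engine,
              x$histories, format(x$seed),
              if (isTRUE(x$calibrated)) ", calibrated (cGy)" else " (raw)"))
  invisible(x)
}

#' Monte Carlo dose calculation
#'
#' Voxel photon transport on a density grid: source photons are sampled
#' from the beam spectrum across the field aperture; free flights use
#' Woodcock delta tracking against the grid's energy-dependent majorant
#' (exact optical-depth ray marching below `wk_min`, where the
#' magnet-driven majorant would make delta tracking inefficient);
#' interactions are photoelectric absorption, Klein-Nishina Compton
#' scattering and pair production (two tracked 511 keV annihilation
#' photons). Dose is scored with a track-length collision-kerma estimator;
#' statistical uncertainties come from `nbatch` independent batches.
#' Runs are bit-reproducible for a fixed seed.
#'
#' @param grid a density grid ([truth_grid()], [no_port_grid()],
#'   [rs1_override()], [rs2_register()] result, ...).
#' @param beam a [beam_spec()].
#' @param histories number of primary photon histories (>= 1).
#' @param seed integer seed.
#' @param nbatch number of statistical batches (>= 2, default 10).
#' @param cutoff photon cutoff energy, MeV (absorbed locally below it).
#' @param wk_min minimum energy for Woodcock tracking, MeV.
#' @param use_woodcock logical; FALSE forces ray marching at all energies.
#' @param majorant_from optional density grid (or list of grids) whose
#'   materials and densities are folded into the Woodcock majorant: paired
#'   runs that share a seed and a majorant follow identical photon
#'   histories wherever their geometries agree, which strongly reduces the
#'   variance of difference profiles (correlated sampling).
#' @return object of class `tte_dose` with per-voxel dose (raw kerma per
#'   history until [apply_calibration()]), relative uncertainty, and the
#'   analog energy ledger (`e_launched`, `e_transferred`, `e_escaped`).
#' @export
mc_dose <- function(grid, beam, histories = 1e6, seed = 1L, nbatch = 10L,
                    cutoff = 0.01, wk_min = 0.3, use_woodcock = TRUE,
                    majorant_from = NULL) {
  stopifnot(inherits(grid, "tte_density_grid"), inherits(beam, "tte_beam"))
  if (histories < 1) stop("histories must be >= 1")
  d <- dim(grid$density$data)
  if (prod(d) == 0) stop("empty grid")
  ## paired-run support: computing the majorant over the union of this
  ## grid's materials and a reference grid's keeps the delta-tracking
  ## random-number stream identical between the two runs wherever the
  ## geometries agree (correlated sampling for difference profiles)
  if (!is.null(majorant_from) && inherits(majorant_from, "tte_density_grid"))
    majorant_from <- list(majorant_from)
  mats <- grid$materials
  for (g in majorant_from) mats <- union(mats, g$materials)
  tab <- .mat_tables(mats)
  rmax_of <- function(g, m) {
    j <- match(m, g$materials)
    if (is.na(j)) return(0)
    sel <- g$matid == j
    if (any(sel)) max(g$density$data[sel]) else 0
  }
  rho_max <- vapply(mats, function(m) {
    r <- rmax_of(grid, m)
    for (g in majorant_from) r <- max(r, rmax_of(g, m))
    r
  }, 0)
  res <- cpp_mc_dose(
    dims = d, origin = grid$density$origin / 10,
    spacing = grid$density$spacing / 10,
    density = as.vector(grid$density$data),
    matid = as.integer(grid$matid) - 1L,
    egrid = tab$egrid, mu_pe = tab$pe, mu_inc = tab$inc, mu_pair = tab$pair,
    mu_tr = tab$tr, rho_max = rho_max,
    spec_e = beam$spectrum$energy, spec_w = beam$spectrum$weights,
    src = beam$src / 10, e_axis = beam$axis, e_x = beam$e_x, e_z = beam$e_z,
    field_half_x = beam$field[1] / 2, field_half_z = beam$field[2] / 2,
    field_dist = beam$field_dist,
    histories = histories, nbatch = as.integer(nbatch), seed = seed,
    cutoff = cutoff, wk_min = wk_min, use_woodcock = use_woodcock)
  .make_dose(res, grid, "mc", histories, seed, nbatch,
             meta = list(beam = beam, strategy = grid$strategy))
}

#' Analytic primary-beam raytracer
#'
#' The deterministic stand-in for a treatment-planning dose algorithm:
#' per-voxel dose proportional to `exp(-optical depth) * (SAD/r)^2 *
#' B(d_eff) * (1 + k_s * d_eff)`, with the optical depth accumulated by
#' Siddon-style voxel traversal at the spectrum's effective energy, a
#' buildup factor `B(d) = 1 - exp(-beta d)` and a linear scatter-buildup
#' term commissioned against the package's own Monte Carlo water
#' depth-dose curve.
#'
#' @inheritParams mc_dose
#' @param beta buildup coefficient, 1/cm.
#' @param k_scatter linear scatter-buildup coefficient, 1/cm.
#' @return a `tte_dose` (zero statistical uncertainty).
#' @export
raytrace_dose <- function(grid, beam, beta = 2.7, k_scatter = 0.024) {
  stopifnot(inherits(grid, "tte_density_grid"), inherits(beam, "tte_beam"))
  d <- dim(grid$density$data)
  eff <- beam$spectrum$effective_energy
  mu_mass <- vapply(grid$materials,
                    function(m) mixture_mu_rho(tte_material(m), eff), 0)
  mu_w <- mixture_mu_rho(tte_material("water"), eff)
  out <- cpp_raytrace(
    dims = d, origin = grid$density$origin / 10,
    spacing = grid$density$spacing / 10,
    density = as.vector(grid$density$data),
    matid = as.integer(grid$matid) - 1L,
    mu_mass = unname(mu_mass), mu_water = mu_w,
    src = beam$src / 10, e_axis = beam$axis, e_x = beam$e_x, e_z = beam$e_z,
    field_half_x = beam$field[1] / 2, field_half_z = beam$field[2] / 2,
    field_dist = beam$field_dist, beta = beta, k_scatter = k_scatter)
  res <- list(sum = out, sumsq = out^2, nbatch = 1L,
              e_launched = NA_real_, e_transferred = NA_real_,
              e_escaped = NA_real_)
  dd <- .make_dose(res, grid, "raytrace", 1, NA_integer_, 1L,
                   meta = list(beam = beam, strategy = grid$strategy))
  dd$relunc$data[] <- 0
  dd
}

#' Arc dose by control-point superposition
#'
#' Runs the chosen engine at every control point of the arc (equal MU and
#' history split; per-control-point seeds derived from `seed`) and sums the
#' doses; batch variances add across control points.
#'
#' @param grid density grid.
#' @param arc an [arc_spec()].
#' @param engine "mc" or "raytrace".
#' @param histories total histories, divided across control points.
#' @param seed integer seed.
#' @param ... passed to the engine.
#' @return a `tte_dose`; `histories` is the total over control points.
#' @export
arc_dose <- function(grid, arc, engine = c("mc", "raytrace"),
                     histories = 4e6, seed = 1L, ...) {
  engine <- match.arg(engine)
  stopifnot(inherits(arc, "tte_arc"))
  iso <- grid$iso
  if (is.null(iso)) stop("grid has no isocenter; set grid$iso")
  ncp <- length(arc$angles)
  h_cp <- floor(histories / ncp)
  acc_dose <- NULL; acc_var <- NULL
  ledger <- c(e_launched = 0, e_transferred = 0, e_escaped = 0)
  for (i in seq_len(ncp)) {
    b <- beam_spec(field = arc$field, mu = arc$mu / ncp,
                   spectrum = arc$spectrum, ssd = arc$sad,
                   gantry = arc$angles[i], ref = iso)
    h_i <- if (i == ncp) histories - h_cp * (ncp - 1) else h_cp
    dd <- if (engine == "mc")
      mc_dose(grid, b, histories = h_i, seed = seed + 7919 * i, ...)
    else raytrace_dose(grid, b, ...)
    w <- dd$dose$data          # per-history raw; rescale to per-cp total
    scale <- h_i / histories   # so the sum is per-history of the whole arc
    if (is.null(acc_dose)) {
      acc_dose <- w * scale
      acc_var <- (dd$relunc$data * w * scale)^2
    } else {
      acc_dose <- acc_dose + w * scale
      acc_var <- acc_var + (dd$relunc$data * w * scale)^2
    }
    if (engine == "mc")
      ledger <- ledger + c(dd$e_launched, dd$e_transferred, dd$e_escaped)
  }
  rel <- ifelse(acc_dose > 0, sqrt(acc_var) / acc_dose, 0)
  structure(list(
    dose = tte_volume(acc_dose, grid$density$origin, grid$density$spacing),
    relunc = tte_volume(rel, grid$density$origin, grid$density$spacing),
    engine = paste0(engine, "-arc"), histories = histories, seed = seed,
    nbatch = NA_integer_,
    e_launched = ledger[[1]], e_transferred = ledger[[2]],
    e_escaped = ledger[[3]],
    calibrated = FALSE,
    meta = list(arc = arc, strategy = grid$strategy)),
    class = "tte_dose")
}

## -- calibration -----------------------------------------------------------

#' Engine calibration to 1 cGy/MU
#'
#' Runs the reference geometry -- a 10 x 10 cm^2 field at 100 cm SSD on a
#' water phantom -- and records the dose per history at the depth of
#' maximum dose on the central axis (1 x 1 cm^2 probe, lightly smoothed).
#' Dose grids are then scaled so that the reference setup delivers
#' 1 cGy/MU at dmax, with a fluence-area correction for other field sizes.
#' The central-axis curve is also summarized by the exponential fit over
#' 5-15 cm depth ([fit_pdd_exponential()]).
#'
#' @param spectrum source spectrum.
#' @param engine "mc" or "raytrace".
#' @param histories histories for the reference run (MC).
#' @param seed seed for the reference run.
#' @return object of class `tte_calibration`.
#' @export
calibrate_engine <- function(spectrum = spectrum_6mv(),
                             engine = c("mc", "raytrace"),
                             histories = 2e6, seed = 20260930) {
  engine <- match.arg(engine)
  key <- config_hash(list(engine = engine, h = histories, seed = seed,
                          spec = spectrum[c("energy", "weights")]))
  if (!is.null(.ttedose$calib[[key]])) return(.ttedose$calib[[key]])
  grid <- water_box_grid(lateral_mm = 220, depth_mm = 320,
                         spacing = c(4, 2, 4))
  beam <- beam_spec(field = c(10, 10), mu = 1, spectrum = spectrum,
                    ssd = 100, gantry = 0, ref = c(0, 0, 0))
  dd <- if (engine == "mc") mc_dose(grid, beam, histories = histories,
                                    seed = seed)
        else raytrace_dose(grid, beam)
  prof <- extract_profile(dd, axis = "y", through = c(0, 0, 0),
                          lateral_avg_mm = 10)
  sm <- stats::filter(prof$dose, rep(1 / 3, 3), sides = 2)
  sm[is.na(sm)] <- prof$dose[is.na(sm)]
  imax <- which.max(sm)
  fit <- fit_pdd_exponential(prof$position / 10, prof$dose,
                             fit_range = c(5, 15), at = 10)
  out <- structure(list(engine = engine, spectrum = spectrum,
                        raw_dmax_per_history = as.numeric(sm[imax]),
                        dmax_mm = prof$position[imax],
                        ref_area_cm2 = 100,
                        d10_fit = fit, pdd = prof,
                        histories = histories, seed = seed),
                   class = "tte_calibration")
  if (is.null(.ttedose$calib)) .ttedose$calib <- list()
  .ttedose$calib[[key]] <- out
  out
}

#' @export
print.tte_calibration <- function(x, ...) {
  cat(sprintf("<tte_calibration> %s: dmax %.0f mm, D(10 cm)/Dmax %.3f\n",
              x$engine, x$dmax_mm,
              x$d10_fit$value / x$raw_dmax_per_history))
  invisible(x)
}

#' @rdname calibrate_engine
#' @param dose a `tte_dose` from the same engine family.
#' @param cal a `tte_calibration`.
#' @return `apply_calibration`: the dose object rescaled to cGy.
#' @export
apply_calibration <- function(dose, cal) {
  stopifnot(inherits(dose, "tte_dose"), inherits(cal, "tte_calibration"))
  if (isTRUE(dose$calibrated)) return(dose)
  beam <- dose$meta$beam
  if (is.null(beam)) {
    arc <- dose$meta$arc
    area <- prod(arc$field); mu <- arc$mu
  } else {
    area <- prod(beam$field); mu <- beam$mu
  }
  f <- mu * (area / cal$ref_area_cm2) / cal$raw_dmax_per_history
  dose$dose$data <- dose$dose$data * f
  dose$calibrated <- TRUE
  dose$meta$calibration <- list(cgy_per_raw = f, dmax_mm = cal$dmax_mm)
  dose
}

#' Water reference phantom grid
#'
#' A homogeneous water box with its entrance surface at y = 0 (beam enters
#' along +y), used for calibration and engine benchmarks.
#'
#' @param lateral_mm lateral extent (x and z), mm.
#' @param depth_mm depth along y, mm.
#' @param spacing voxel spacing, mm (length 1 or 3).
#' @return a `tte_density_grid`.
#' @export
water_box_grid <- function(lateral_mm = 200, depth_mm = 350, spacing = 2) {
  if (length(spacing) == 1L) spacing <- rep(spacing, 3)
  n <- as.integer(ceiling(c(lateral_mm, depth_mm, lateral_mm) / spacing))
  origin <- c(-lateral_mm / 2, 0, -lateral_mm / 2)
  dens <- array(1.0, n)
  structure(list(
    density = tte_volume(dens, origin, spacing),
    matid = array(1L, n), materials = "water",
    strategy = "truth", iso = c(0, 0, 0), meta = list(scene = "water_box")),
    class = "tte_density_grid")
}

#' Exponential fit of a depth-dose curve
#'
#' Least-squares fit of `A * exp(-b * d)` (linear regression on the log
#' dose) over `fit_range`, used to read the absorbed dose at a stated
#' depth from a noisy PDD, as in linac output calibration.
#'
#' @param depth depths, cm.
#' @param dose dose values (> 0 within the fit range).
#' @param fit_range depth range c(lo, hi) in cm.
#' @param at depth (cm) at which the fitted dose is evaluated.
#' @return list with `value` (fitted dose at `at`), `A`, `b`, `r_squared`,
#'   `n`, and `monotone` (FALSE triggers a warning: the fit range should
#'   lie beyond the buildup region).
#' @export
fit_pdd_exponential <- function(depth, dose, fit_range = c(5, 15), at = 10) {
  sel <- depth >= fit_range[1] & depth <= fit_range[2]
  if (sum(sel) < 5) stop("need at least 5 points inside the fit range")
  d <- depth[sel]; v <- dose[sel]
  if (any(v <= 0)) stop("nonpositive dose inside the fit range")
  monotone <- all(diff(v[order(d)]) <= 0)
  if (!monotone)
    warning("depth-dose curve is not monotone within the fit range")
  fit <- stats::lm(log(v) ~ d)
  A <- exp(stats::coef(fit)[[1]]); b <- -stats::coef(fit)[[2]]
  ss_tot <- sum((log(v) - mean(log(v)))^2)
  r2 <- if (ss_tot > 0) 1 - sum(stats::residuals(fit)^2) / ss_tot else 1
  list(value = A * exp(-b * at), A = A, b = b,
       r_squared = r2, n = sum(sel), monotone = monotone)
}
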