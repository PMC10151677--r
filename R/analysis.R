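# Comparison machinery: 1-D profiles, gamma index, DVH parameters,
# port-effect differencing and the strategy-difference report.

#' Extract a 1-D dose profile
#'
#' Dose versus position along one axis through a stated point, optionally
#' averaged over a square lateral window (the film-probe analogue: the
#' measurement films are 1 x 1 cm^2) with uncertainties combined in
#' quadrature, and optionally normalized to the value at a stated position.
#'
#' @param dose a `tte_dose`.
#' @param axis "x", "y" or "z".
#' @param through point (mm, world) the profile passes through.
#' @param lateral_avg_mm side length of the averaging window perpendicular
#'   to the profile (0 = single voxel column).
#' @param normalize_at if non-NULL, position (mm) whose value is scaled
#'   to 100.
#' @return data.frame with `position` (mm), `dose`, `relunc`.
#' @export
extract_profile <- function(dose, axis = "y", through = c(0, 0, 0),
                            lateral_avg_mm = 0, normalize_at = NULL) {
  stopifnot(inherits(dose, "tte_dose"))
  a <- match(axis, c("x", "y", "z"))
  if (is.na(a)) stop("axis must be x, y or z")
  vol <- dose$dose
  d <- dim(vol$data)
  others <- setdiff(1:3, a)
  sel <- vector("list", 3)
  sel[[a]] <- seq_len(d[a])
  for (o in others) {
    centers <- voxel_centers(vol, o)
    if (through[o] < min(centers) - vol$spacing[o] / 2 ||
        through[o] > max(centers) + vol$spacing[o] / 2)
      stop("profile point outside grid on axis ", c("x", "y", "z")[o])
    if (lateral_avg_mm > 0) {
      half <- lateral_avg_mm / 2
      idx <- which(abs(centers - through[o]) <= half + 1e-9)
    } else idx <- which.min(abs(centers - through[o]))
    sel[[o]] <- idx
  }
  sub <- do.call(`[`, c(list(vol$data), sel, list(drop = FALSE)))
  subu <- do.call(`[`, c(list(dose$relunc$data), sel, list(drop = FALSE)))
  val <- apply(sub, a, mean)
  nlat <- prod(dim(sub)[others])
  ## quadrature of per-voxel standard errors of the averaged voxels
  unc <- sqrt(apply((subu * sub)^2, a, sum)) / nlat
  rel <- ifelse(val > 0, unc / val, 0)
  out <- data.frame(position = voxel_centers(vol, a), dose = val, relunc = rel)
  if (!is.null(normalize_at)) {
    ref <- out$dose[which.min(abs(out$position - normalize_at))]
    if (ref <= 0) stop("normalization value is nonpositive")
    out$dose <- 100 * out$dose / ref
  }
  out
}

#' Gamma index of two dose curves or volumes
#'
#' The combined dose-difference / distance-to-agreement metric: for each
#' reference point, the minimum over the evaluated distribution of
#' `sqrt((dD/crit_D)^2 + (dx/crit_d)^2)`. Dose differences are normalized
#' globally to the reference maximum (local normalization behind the
#' `local` flag). For curves the evaluated distribution is interpolated
#' linearly and the minimum over each segment is solved in closed form
#' (exact minimization of the quadratic) over the whole evaluated curve.
#' For volumes a brute-force neighborhood search (three times the distance
#' criterion) with
#' sub-voxel trilinear refinement is used (intended for small grids or
#' masked regions).
#'
#' @param reference,evaluated data.frames with `position` (mm) and `dose`,
#'   or `tte_dose` objects on commensurable lattices.
#' @param dose_crit dose criterion, percent of the normalization dose.
#' @param dist_crit distance-to-agreement criterion, mm.
#' @param local logical: normalize dose differences to the local reference
#'   dose instead of the global maximum.
#' @param mask optional logical array restricting the volume comparison.
#' @param threshold low-dose threshold (fraction of reference max) below
#'   which reference points are excluded from the pass rate.
#' @return object of class `tte_gamma`: `gamma` values, `pass_rate`,
#'   `criteria`.
#' @export
gamma_index <- function(reference, evaluated, dose_crit = 2, dist_crit = 1,
                        local = FALSE, mask = NULL, threshold = 0.1) {
  if (inherits(reference, "tte_dose"))
    return(.gamma_volume(reference, evaluated, dose_crit, dist_crit, local,
                         mask, threshold))
  .gamma_curve(reference, evaluated, dose_crit, dist_crit, local, threshold)
}

.gamma_curve <- function(ref, ev, dose_crit, dist_crit, local, threshold) {
  stopifnot(is.data.frame(ref), is.data.frame(ev))
  dmax <- max(ref$dose)
  if (dmax <= 0) stop("reference maximum dose is zero")
  n <- nrow(ref)
  g <- numeric(n)
  xs <- ev$position; vs <- ev$dose
  for (i in seq_len(n)) {
    x0 <- ref$position[i]; v0 <- ref$dose[i]
    dnorm <- if (local) max(v0, 1e-12 * dmax) else dmax
    dd <- dose_crit / 100 * dnorm
    ## candidate: every evaluated sample point
    best <- min(sqrt(((vs - v0) / dd)^2 + ((xs - x0) / dist_crit)^2))
    ## candidate: interior minima on each linear segment (exact quadratic)
    for (j in seq_len(length(xs) - 1)) {
      xa <- xs[j]; xb <- xs[j + 1]
      L <- xb - xa
      if (L == 0) next
      va <- vs[j]; m <- (vs[j + 1] - va) / L
      ## minimize ((va + m s - v0)/dd)^2 + ((xa + s - x0)/dc)^2 over s
      A <- (m / dd)^2 + (1 / dist_crit)^2
      B <- 2 * (m * (va - v0) / dd^2 + (xa - x0) / dist_crit^2)
      s <- -B / (2 * A)
      s <- min(max(s, 0), L)
      best <- min(best, sqrt(((va + m * s - v0) / dd)^2 +
                             ((xa + s - x0) / dist_crit)^2))
    }
    g[i] <- best
  }
  eval_pts <- ref$dose >= threshold * dmax
  structure(list(gamma = g, position = ref$position,
                 pass_rate = mean(g[eval_pts] <= 1),
                 evaluated = eval_pts,
                 criteria = c(dose_pct = dose_crit, dist_mm = dist_crit),
                 local = local),
            class = "tte_gamma")
}

.gamma_volume <- function(ref, ev, dose_crit, dist_crit, local, mask,
                          threshold) {
  stopifnot(inherits(ev, "tte_dose"),
            all(dim(ref$dose$data) == dim(ev$dose$data)))
  rd <- ref$dose$data; ed <- ev$dose$data
  dmax <- max(rd)
  if (dmax <= 0) stop("reference maximum dose is zero")
  sp <- ref$dose$spacing
  d <- dim(rd)
  if (is.null(mask)) mask <- array(TRUE, d)
  pts <- which(mask)
  g <- array(NA_real_, d)
  win <- ceiling(3 * dist_crit / sp)
  sub <- 3L  # sub-voxel refinement factor
  for (p in pts) {
    iz <- (p - 1) %/% (d[1] * d[2]) + 1
    iy <- ((p - 1) %/% d[1]) %% d[2] + 1
    ix <- (p - 1) %% d[1] + 1
    v0 <- rd[ix, iy, iz]
    dnorm <- if (local) max(v0, 1e-12 * dmax) else dmax
    dd <- dose_crit / 100 * dnorm
    best <- Inf
    for (dxs in seq(-win[1] * sub, win[1] * sub)) {
      jx <- ix + dxs / sub
      if (jx < 1 || jx > d[1]) next
      for (dys in seq(-win[2] * sub, win[2] * sub)) {
        jy <- iy + dys / sub
        if (jy < 1 || jy > d[2]) next
        for (dzs in seq(-win[3] * sub, win[3] * sub)) {
          jz <- iz + dzs / sub
          if (jz < 1 || jz > d[3]) next
          r2 <- sum(((c(dxs, dys, dzs) / sub) * sp)^2) / dist_crit^2
          if (r2 > 9 && best < Inf) next
          ## trilinear interpolation of the evaluated dose
          fx <- floor(jx); fy <- floor(jy); fz <- floor(jz)
          cx <- min(fx + 1, d[1]); cy <- min(fy + 1, d[2]); cz <- min(fz + 1, d[3])
          tx <- jx - fx; ty <- jy - fy; tz <- jz - fz
          val <-
            ed[fx, fy, fz] * (1-tx)*(1-ty)*(1-tz) + ed[cx, fy, fz] * tx*(1-ty)*(1-tz) +
            ed[fx, cy, fz] * (1-tx)*ty*(1-tz)     + ed[fx, fy, cz] * (1-tx)*(1-ty)*tz +
            ed[cx, cy, fz] * tx*ty*(1-tz)         + ed[cx, fy, cz] * tx*(1-ty)*tz +
            ed[fx, cy, cz] * (1-tx)*ty*tz         + ed[cx, cy, cz] * tx*ty*tz
          best <- min(best, sqrt(((val - v0) / dd)^2 + r2))
        }
      }
    }
    g[p] <- best
  }
  eval_pts <- !is.na(g) & rd >= threshold * dmax
  structure(list(gamma = g, pass_rate = mean(g[eval_pts] <= 1),
                 evaluated = eval_pts,
                 criteria = c(dose_pct = dose_crit, dist_mm = dist_crit),
                 local = local),
            class = "tte_gamma")
}

#' @export
print.tte_gamma <- function(x, ...) {
  cat(sprintf("<tte_gamma> %g%%/%g mm, pass rate %.1f%%\n",
              x$criteria[1], x$criteria[2], 100 * x$pass_rate))
  invisible(x)
}

#' DVH parameters of a contoured volume
#'
#' D_x is the minimum dose received by the hottest x% of the contoured
#' volume, i.e. the (100 - x)-th percentile of the voxel-dose distribution,
#' computed by linear interpolation of the empirical cumulative
#' dose-volume curve (quantile type 7). The mean is the arithmetic mean
#' over contour voxels; the quoted relative uncertainty is the standard
#' error of the contour mean dose (quadrature of per-voxel standard
#' errors), used as the run-level figure for every DVH parameter.
#'
#' @param dose a `tte_dose`.
#' @param contour a `tte_contour` (or logical array on the same lattice).
#' @param dx percentages x for D_x (default 1 and 10).
#' @return object of class `dvh_result`: `D` (named vector, e.g. D1, D10),
#'   `mean`, `volume_cc`, `relunc`.
#' @export
dvh_parameters <- function(dose, contour, dx = c(1, 10)) {
  stopifnot(inherits(dose, "tte_dose"))
  mask <- if (inherits(contour, "tte_contour")) contour$mask$data else contour
  if (!any(mask)) stop("empty contour mask")
  v <- dose$dose$data[mask]
  q <- stats::quantile(v, probs = 1 - dx / 100, names = FALSE, type = 7)
  ## run-level uncertainty of the contour statistics: standard error of the
  ## contour mean dose under a voxel-independence approximation
  se <- dose$relunc$data[mask] * v
  ru <- if (sum(v) > 0) sqrt(sum(se^2)) / sum(v) else 0
  structure(list(
    D = stats::setNames(q, paste0("D", dx)),
    mean = mean(v),
    volume_cc = sum(mask) * prod(dose$dose$spacing) / 1000,
    relunc = ru,
    name = if (inherits(contour, "tte_contour")) contour$name else "mask"),
    class = "dvh_result")
}

#' @export
print.dvh_result <- function(x, ...) {
  cat(sprintf("<dvh_result> %s (%.1f cc): %s, mean %.3g\n", x$name,
              x$volume_cc,
              paste(names(x$D), signif(x$D, 4), collapse = ", "), x$mean))
  invisible(x)
}

#' Port-effect difference profile
#'
#' Percentage dose difference `100 * (D_ref - D_test) / D_ref` along an
#' axis at matched positions (reference first: positive values mean the
#' reference -- normally the no-port run -- is hotter, i.e. the port
#' causes an underdose). Uncertainties are propagated in quadrature from
#' both runs. The profile is averaged laterally over the film-probe window
#' and smoothed along the axis with a short moving average before the
#' extrema are read off.
#'
#' @param dose_ref,dose_test `tte_dose` objects on the same lattice with
#'   the same beam and MU.
#' @param axis profile axis.
#' @param through profile point (mm).
#' @param lateral_avg_mm lateral probe size (mm).
#' @param smooth moving-average window (points; 1 = none).
#' @return object of class `tte_port_effect`: data.frame `profile`
#'   (`position`, `diff_pct`, `unc_pct`) plus the inputs' metadata.
#' @export
port_effect <- function(dose_ref, dose_test, axis = "y", through = c(0, 0, 0),
                        lateral_avg_mm = 10, smooth = 3L) {
  stopifnot(inherits(dose_ref, "tte_dose"), inherits(dose_test, "tte_dose"))
  if (!all(dim(dose_ref$dose$data) == dim(dose_test$dose$data)))
    stop("dose lattices do not match")
  pr <- extract_profile(dose_ref, axis, through, lateral_avg_mm)
  pt <- extract_profile(dose_test, axis, through, lateral_avg_mm)
  ok <- pr$dose > 0
  diff <- ifelse(ok, 100 * (pr$dose - pt$dose) / pr$dose, NA_real_)
  unc <- ifelse(ok, 100 * (pt$dose / pr$dose) *
                  sqrt(pr$relunc^2 + pt$relunc^2), NA_real_)
  if (smooth > 1L) {
    k <- rep(1 / smooth, smooth)
    sm <- stats::filter(diff, k, sides = 2)
    diff <- ifelse(is.na(sm), diff, as.numeric(sm))
    unc <- unc / sqrt(smooth)   # neighbor averaging (approximate)
  }
  structure(list(
    profile = data.frame(position = pr$position, diff_pct = diff,
                         unc_pct = unc),
    axis = axis, through = through,
    ref = dose_ref$meta$strategy, test = dose_test$meta$strategy),
    class = "tte_port_effect")
}

#' @rdname port_effect
#' @param pe a `tte_port_effect`.
#' @param region position window c(lo, hi) in mm to search.
#' @return `max_underdose` / `max_overdose`: list with `value` (percent,
#'   positive), `position` (mm) and `unc` (percent).
#' @export
max_underdose <- function(pe, region) {
  p <- pe$profile
  sel <- which(p$position >= region[1] & p$position <= region[2] &
               !is.na(p$diff_pct))
  if (!length(sel)) stop("empty search region")
  i <- sel[which.max(p$diff_pct[sel])]
  list(value = p$diff_pct[i], position = p$position[i], unc = p$unc_pct[i])
}

#' @rdname port_effect
#' @export
max_overdose <- function(pe, region) {
  p <- pe$profile
  sel <- which(p$position >= region[1] & p$position <= region[2] &
               !is.na(p$diff_pct))
  if (!length(sel)) stop("empty search region")
  i <- sel[which.min(p$diff_pct[sel])]
  list(value = -p$diff_pct[i], position = p$position[i], unc = p$unc_pct[i])
}

#' @export
print.tte_port_effect <- function(x, ...) {
  cat(sprintf("<tte_port_effect> %s vs %s along %s, %d points\n",
              x$ref, x$test, x$axis, nrow(x$profile)))
  invisible(x)
}

#' Strategy-difference DVH report
#'
#' For every contour and each of D1, D10 and mean dose, the percentage
#' differences (no-port - RS1), (no-port - RS2) and (RS1 - RS2), each
#' normalized to the first-named run's value (positive entries mean the
#' first-named run is hotter) with combined statistical uncertainties
#' (quadrature of the run-level contour uncertainties).
#'
#' @param runs named list of `tte_dose` objects; must contain `noport`,
#'   `rs1`, `rs2` on matched lattices.
#' @param contours named list of `tte_contour`s.
#' @return data.frame in the layout contour x (volume, then one column per
#'   pair and metric), class `tte_dvh_report`.
#' @export
dvh_difference_report <- function(runs, contours) {
  need <- c("noport", "rs1", "rs2")
  if (!all(need %in% names(runs)))
    stop("runs must contain ", paste(need, collapse = ", "))
  dims <- lapply(runs[need], function(r) dim(r$dose$data))
  if (!all(vapply(dims, identical, TRUE, dims[[1]])))
    stop("run lattices do not match")
  pairs <- list(c("noport", "rs1"), c("noport", "rs2"), c("rs1", "rs2"))
  metrics <- c("D1", "D10", "mean")
  rows <- lapply(names(contours), function(cn) {
    ct <- contours[[cn]]
    dv <- lapply(runs[need], dvh_parameters, contour = ct)
    row <- list(contour = cn, volume_cc = dv[[1]]$volume_cc)
    for (pr in pairs) {
      a <- dv[[pr[1]]]; b <- dv[[pr[2]]]
      unc <- 100 * sqrt(a$relunc^2 + b$relunc^2)
      for (m in metrics) {
        va <- if (m == "mean") a$mean else a$D[[m]]
        vb <- if (m == "mean") b$mean else b$D[[m]]
        nm <- paste0(pr[1], "_minus_", pr[2], "_", m)
        row[[nm]] <- 100 * (va - vb) / va
        row[[paste0(nm, "_unc")]] <- unc
      }
    }
    as.data.frame(row)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("tte_dvh_report", class(out))
  attr(out, "normalization") <- "percent of the first-named run's value"
  out
}
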