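# Material definitions, photon cross sections and the 6 MV source model.
# All mass attenuation coefficients are in cm^2/g, energies in MeV.

.ttedose <- new.env(parent = emptyenv())

MEC2 <- 0.51099895  # electron rest energy, MeV

#' Define a material
#'
#' A material is a mass density plus an elemental composition by mass
#' fraction. Mass fractions must sum to one (tolerance 1e-6) and every
#' element must be present in the bundled cross-section tables.
#'
#' @param name material name.
#' @param density mass density in g/cm^3 (> 0).
#' @param composition named numeric vector of mass fractions, names are
#'   element symbols (e.g. `c(H = 0.112, O = 0.888)`).
#' @return an object of class `tte_material`.
#' @export
#' @examples
#' material("water", 1.0, c(H = 0.111894, O = 0.888106))
material <- function(name, density, composition) {
  stopifnot(is.character(name), length(name) == 1L)
  if (!is.numeric(density) || length(density) != 1L || density <= 0)
    stop("density must be a positive scalar (g/cm^3)")
  if (is.null(names(composition)) || any(names(composition) == ""))
    stop("composition must be a named vector of mass fractions")
  if (abs(sum(composition) - 1) > 1e-6)
    stop("mass fractions must sum to 1 (got ", sum(composition), ")")
  unknown <- setdiff(names(composition), xs_tables()$elements)
  if (length(unknown))
    stop("unknown element(s): ", paste(unknown, collapse = ", "))
  structure(list(name = name, density = density,
                 composition = composition[composition > 0]),
            class = "tte_material")
}

#' @export
print.tte_material <- function(x, ...) {
  cat("<tte_material>", x$name, sprintf("(%.4g g/cm^3)\n", x$density))
  comp <- paste(sprintf("%s %.4f", names(x$composition), x$composition),
                collapse = ", ")
  cat("  composition:", comp, "\n")
  invisible(x)
}

#' Built-in materials
#'
#' The materials used by the phantom generators. Compositions: water;
#' paraffin wax C25H52; titanium; sintered Nd2Fe14B (the port magnet alloy,
#' density configurable because vendor figures quote both 7.6 and 7.4
#' g/cm^3; 7.4 is the default used for dose physics); PEEK C19H12O3;
#' silicone (polydimethylsiloxane); dry air. "plastic_water" is treated as
#' water-equivalent.
#'
#' @param name one of `r paste(names(.tte_builtin_materials()), collapse = ", ")`.
#' @param density optional density override in g/cm^3.
#' @return a [material()] object.
#' @export
#' @examples
#' tte_material("ndfeb")           # 7.4 g/cm^3 default
#' tte_material("ndfeb", 7.6)      # vendor-quoted density
tte_material <- function(name, density = NULL) {
  reg <- .tte_builtin_materials()
  if (!name %in% names(reg))
    stop("unknown material '", name, "'; available: ",
         paste(names(reg), collapse = ", "))
  m <- reg[[name]]
  material(name, if (is.null(density)) m$density else density, m$composition)
}

.tte_builtin_materials <- function() {
  list(
    water = list(density = 1.0,
                 composition = c(H = 0.111894, O = 0.888106)),
    plastic_water = list(density = 1.0,
                 composition = c(H = 0.111894, O = 0.888106)),
    wax = list(density = 0.92,   # paraffin C25H52
                 composition = c(C = 0.851394, H = 0.148606)),
    titanium = list(density = 4.54, composition = c(Ti = 1)),
    ndfeb = list(density = 7.4,  # Nd2Fe14B
                 composition = c(Nd = 0.266838, Fe = 0.723162, B = 0.010000)),
    peek = list(density = 1.3,   # C19H12O3
                 composition = c(C = 0.791565, H = 0.041956, O = 0.166479)),
    silicone = list(density = 1.1,  # PDMS C2H6OSi
                 composition = c(C = 0.323943, H = 0.081559,
                                 O = 0.215751, Si = 0.378747)),
    air = list(density = 0.0012,
                 composition = c(N = 0.755, O = 0.232, Ar = 0.013))
  )
}

#' Bundled photon cross-section tables
#'
#' Per-element mass attenuation coefficients partitioned into
#' photoelectric, incoherent (Compton) and pair-production channels on a
#' common 0.01-10 MeV grid. Generated from analytic parameterizations
#' (exact free-electron Klein-Nishina; anchored photoelectric power law;
#' water-anchored pair curve scaled by Z(Z+1)/A); coherent scattering is
#' excluded throughout.
#'
#' @return a list with `energies`, `elements`, and per-channel matrices
#'   (`pe`, `incoh`, `pair`, `total`), energies by rows.
#' @export
xs_tables <- function() {
  if (!is.null(.ttedose$xs)) return(.ttedose$xs)
  path <- system.file("extdata", "xs_photon.csv", package = "ttedose")
  if (path == "") path <- file.path("inst", "extdata", "xs_photon.csv")
  tab <- utils::read.csv(path, stringsAsFactors = FALSE)
  els <- unique(tab$element)
  energies <- sort(unique(tab$energy_mev))
  shape <- function(col) {
    m <- vapply(els, function(e) {
      sub <- tab[tab$element == e, ]
      sub[[col]][order(sub$energy_mev)]
    }, numeric(length(energies)))
    dimnames(m) <- list(NULL, els)
    m
  }
  .ttedose$xs <- list(
    energies = energies, elements = els,
    Z = vapply(els, function(e) tab$Z[tab$element == e][1], 0),
    A = vapply(els, function(e) tab$A[tab$element == e][1], 0),
    pe = shape("mu_pe"), incoh = shape("mu_incoh"),
    pair = shape("mu_pair"), total = shape("mu_total"))
  .ttedose$xs
}

## log-log interpolation of a columnwise table at arbitrary energies;
## zero values (pair below threshold) are handled linearly.
.interp_loglog <- function(egrid, values, energy) {
  if (any(energy < egrid[1] - 1e-12) || any(energy > egrid[length(egrid)] + 1e-9))
    stop("energy out of table range [", egrid[1], ", ", egrid[length(egrid)],
         "] MeV")
  energy <- pmin(pmax(energy, egrid[1]), egrid[length(egrid)])
  i <- findInterval(energy, egrid, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(egrid) - 1L)
  e0 <- egrid[i]; e1 <- egrid[i + 1L]
  v0 <- values[i]; v1 <- values[i + 1L]
  t <- log(energy / e0) / log(e1 / e0)
  out <- ifelse(v0 > 0 & v1 > 0,
                exp(log(v0) + t * (log(v1) - log(v0))),
                v0 + t * (v1 - v0))
  out
}

#' Mass attenuation coefficient of a material
#'
#' Mixture rule: the material coefficient is the mass-fraction-weighted sum
#' of the element coefficients, interpolated log-log between table grid
#' energies.
#'
#' @param mat a [material()].
#' @param energy photon energy (MeV), vectorized; must lie within the table
#'   range (0.01-10 MeV).
#' @param channel one of "total", "photoelectric", "compton", "pair".
#' @return mass attenuation coefficient(s), cm^2/g.
#' @export
#' @examples
#' mixture_mu_rho(tte_material("water"), 2.0)  # ~0.0493 cm^2/g
mixture_mu_rho <- function(mat, energy, channel = "total") {
  stopifnot(inherits(mat, "tte_material"))
  xs <- xs_tables()
  key <- switch(match.arg(channel, c("total", "photoelectric", "compton", "pair")),
                total = "total", photoelectric = "pe", compton = "incoh",
                pair = "pair")
  vals <- numeric(length(energy))
  for (el in names(mat$composition)) {
    vals <- vals + mat$composition[[el]] *
      .interp_loglog(xs$energies, xs[[key]][, el], energy)
  }
  vals
}

#' Narrow-beam transmission through a material slab
#'
#' `exp(-(mu/rho) * rho * t)` at the given photon energy; the complement
#' `1 - transmission` is the attenuation. Scattering build-up is ignored
#' (narrow-beam / "ideal conditions" geometry).
#'
#' @param mat a [material()].
#' @param thickness slab thickness in cm (>= 0), vectorized.
#' @param energy photon energy in MeV.
#' @return transmitted fraction in (0, 1].
#' @export
#' @examples
#' # port magnet: ~5-7% attenuation for MV photons
#' 1 - transmission(tte_material("ndfeb"), 0.241, 2.0)
transmission <- function(mat, thickness, energy) {
  if (any(thickness < 0)) stop("thickness must be >= 0")
  mu <- mixture_mu_rho(mat, energy, "total")
  exp(-mu * mat$density * thickness)
}

#' Sample photon interaction channels
#'
#' Draws interaction channels with probabilities proportional to the
#' partial mass attenuation coefficients of the material at that energy.
#'
#' @param energy photon energy (MeV).
#' @param mat a [material()].
#' @param n number of draws.
#' @return factor with levels photoelectric/compton/pair.
#' @export
sample_interaction <- function(energy, mat, n = 1L) {
  p <- interaction_probabilities(energy, mat)
  factor(sample(names(p), n, replace = TRUE, prob = p),
         levels = c("photoelectric", "compton", "pair"))
}

#' @rdname sample_interaction
#' @export
interaction_probabilities <- function(energy, mat) {
  parts <- c(photoelectric = mixture_mu_rho(mat, energy, "photoelectric"),
             compton = mixture_mu_rho(mat, energy, "compton"),
             pair = mixture_mu_rho(mat, energy, "pair"))
  parts / sum(parts)
}

#' Klein-Nishina differential cross section
#'
#' Free-electron Klein-Nishina angular differential cross section
#' d(sigma)/d(Omega) (arbitrary normalization) for incident energy
#' `energy` at scattering angle `theta`.
#'
#' @param energy incident photon energy (MeV).
#' @param theta polar scattering angle (rad).
#' @return unnormalized differential cross section.
#' @export
klein_nishina_pdf <- function(energy, theta) {
  a <- energy / MEC2
  r <- 1 / (1 + a * (1 - cos(theta)))  # E'/E
  r^2 * (r + 1 / r - sin(theta)^2)
}

#' Sample Compton scattering kinematics
#'
#' Rejection sampling of the free-electron Klein-Nishina angular
#' distribution; the scattered energy follows from the Compton relation
#' `E' = E / (1 + (E/me c^2)(1 - cos theta))`.
#'
#' @param energy incident photon energy (MeV), scalar.
#' @param n number of samples.
#' @return list with `energy` (scattered photon, MeV), `angle` (polar, rad)
#'   and `electron` (energy transferred to the electron, MeV).
#' @export
sample_compton <- function(energy, n = 1L) {
  stopifnot(energy > 0)
  a <- energy / MEC2
  out_ct <- numeric(0)
  ## envelope: uniform in cos(theta), bounded by the theta=0 value (=2)
  while (length(out_ct) < n) {
    m <- max(64L, 2L * (n - length(out_ct)))
    ct <- stats::runif(m, -1, 1)
    r <- 1 / (1 + a * (1 - ct))
    f <- r^2 * (r + 1 / r - (1 - ct^2))
    keep <- stats::runif(m) * 2 <= f
    out_ct <- c(out_ct, ct[keep])
  }
  ct <- out_ct[seq_len(n)]
  eprime <- energy / (1 + a * (1 - ct))
  list(energy = eprime, angle = acos(ct), electron = energy - eprime)
}

## mean fraction of the photon energy transferred to the Compton electron
compton_transfer_fraction <- function(energy) {
  vapply(energy, function(E) {
    ct <- seq(-1, 1, length.out = 2001)
    a <- E / MEC2
    r <- 1 / (1 + a * (1 - ct))
    f <- r^2 * (r + 1 / r - (1 - ct^2))    # dsigma/dcos(theta) (unnorm.)
    w <- f / sum(f)
    1 - sum(w * r)
  }, 0)
}

#' Energy-transfer coefficient of a material
#'
#' Mass energy-transfer coefficient mu_tr/rho: the photoelectric channel
#' transfers the full photon energy, the Compton channel the Klein-Nishina
#' mean electron fraction, and the pair channel `E - 1.022` MeV. Used by
#' the collision-kerma dose estimator.
#'
#' @inheritParams mixture_mu_rho
#' @return mu_tr/rho in cm^2/g.
#' @export
mu_tr_over_rho <- function(mat, energy) {
  fc <- compton_transfer_fraction(energy)
  fp <- ifelse(energy > 2 * MEC2, 1 - 2 * MEC2 / energy, 0)
  mixture_mu_rho(mat, energy, "photoelectric") +
    fc * mixture_mu_rho(mat, energy, "compton") +
    fp * mixture_mu_rho(mat, energy, "pair")
}

#' 6 MV photon source spectrum
#'
#' A documented piecewise parameterization of a flattened 6 MV linac
#' spectrum: fluence density phi(E) proportional to E * exp(-E / T) between
#' `e_min` and `e_max`, discretized on `n_bins` bins. With the default
#' spectral temperature `T = 0.9` MeV the fluence-weighted mean (the
#' "effective energy" used by the raytracer) is about 1.8 MeV, in line with
#' published 6 MV spectra. A monoenergetic override is available for
#' benchmarking.
#'
#' @param n_bins number of energy bins.
#' @param e_min,e_max spectrum support (MeV); `e_max` <= 6 for a 6 MV beam.
#' @param temperature spectral falloff parameter T (MeV).
#' @param mono if non-NULL, a single energy (MeV): returns a
#'   monoenergetic spectrum at that energy.
#' @return object of class `tte_spectrum`: `energy` (bin centers),
#'   `weights` (normalized fluence weights), `effective_energy`.
#' @export
#' @examples
#' s <- spectrum_6mv(); s$effective_energy
spectrum_6mv <- function(n_bins = 48L, e_min = 0.25, e_max = 6,
                         temperature = 0.9, mono = NULL) {
  if (!is.null(mono)) {
    stopifnot(mono > 0, mono <= 6)
    out <- list(energy = mono, weights = 1, effective_energy = mono)
    class(out) <- "tte_spectrum"
    return(out)
  }
  stopifnot(e_max <= 6, e_min > 0, e_min < e_max)
  edges <- seq(e_min, e_max, length.out = n_bins + 1L)
  mid <- (edges[-1] + edges[-length(edges)]) / 2
  w <- mid * exp(-mid / temperature) * diff(edges)
  w <- w / sum(w)
  out <- list(energy = mid, weights = w,
              effective_energy = sum(w * mid))
  class(out) <- "tte_spectrum"
  out
}

#' @export
print.tte_spectrum <- function(x, ...) {
  cat(sprintf("<tte_spectrum> %d bins, %.3g-%.3g MeV, effective %.3f MeV\n",
              length(x$energy), min(x$energy), max(x$energy),
              x$effective_energy))
  invisible(x)
}
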