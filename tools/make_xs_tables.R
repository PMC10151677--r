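# Generates inst/extdata/xs_photon.csv: per-element photon mass attenuation
# coefficients (cm^2/g) partitioned into photoelectric / incoherent / pair
# channels on a log energy grid, 0.01-10 MeV.
#
# The tables are computed from standard analytic physics rather than copied
# from a database:
#   * incoherent: exact free-electron Klein-Nishina total cross section
#     times the electron density N_A * Z / A;
#   * photoelectric: two-term parameterization C*Z^4.6/E^3.25 + D*Z^5/E
#     (per-atom, cm^2; E in MeV) anchored on the classic water value at
#     10-100 keV and the high-Z MeV-range tail;
#   * pair (nuclear + triplet): universal energy curve obtained as the
#     residual of the classic Hubbell water attenuation totals minus the
#     Klein-Nishina incoherent part, scaled between elements by Z(Z+1)/A.
# Coherent (Rayleigh) scattering is deliberately excluded everywhere.
# Absorption-edge structure is not modeled (lowest grid energy 10 keV).

suppressWarnings(dir.create("inst/extdata", recursive = TRUE, showWarnings = FALSE))

elements <- data.frame(
  symbol = c("H", "B", "C", "N", "O", "Ar", "Si", "Ti", "Fe", "Nd"),
  Z      = c(1, 5, 6, 7, 8, 18, 14, 22, 26, 60),
  A      = c(1.008, 10.811, 12.011, 14.007, 15.999, 39.948, 28.086,
             47.867, 55.845, 144.242),
  stringsAsFactors = FALSE
)

NA_AVO <- 6.02214076e23
RE2    <- 7.940787e-26   # classical electron radius squared, cm^2
MEC2   <- 0.51099895     # MeV

## exact Klein-Nishina total cross section per electron (cm^2)
kn_sigma <- function(E) {
  a <- E / MEC2
  t1 <- (1 + a) / a^2 * (2 * (1 + a) / (1 + 2 * a) - log(1 + 2 * a) / a)
  t2 <- log(1 + 2 * a) / (2 * a)
  t3 <- (1 + 3 * a) / (1 + 2 * a)^2
  2 * pi * RE2 * (t1 + t2 - t3)
}

## photoelectric per-atom cross section (cm^2), parameterized
PE_C <- 3.25e-33
PE_D <- 2.70e-34
pe_sigma <- function(Z, E) PE_C * Z^4.6 / E^3.25 + PE_D * Z^5 / E

## universal pair-production curve: water residual / water Z(Z+1)/A sum.
## Classic water mass attenuation totals (coherent excluded; negligible
## above 1 MeV) at anchor energies:
pair_anchor_E <- c(1.022, 1.25, 1.5, 2, 3, 4, 5, 6, 8, 10)
water_total   <- c(NA, 0.06323, 0.05754, 0.04942, 0.03969, 0.03403,
                   0.03031, 0.02770, 0.02429, 0.02219)
w_frac_water  <- c(H = 0.111894, O = 0.888106)
ne_water      <- NA_AVO * (w_frac_water[["H"]] * 1 / 1.008 +
                           w_frac_water[["O"]] * 8 / 15.999)
zz_over_a <- function(Z, A) Z * (Z + 1) / A
zz_water  <- w_frac_water[["H"]] * zz_over_a(1, 1.008) +
             w_frac_water[["O"]] * zz_over_a(8, 15.999)

pe_water <- function(E) {
  (w_frac_water[["H"]] * pe_sigma(1, E) / 1.008 +
   w_frac_water[["O"]] * pe_sigma(8, E) / 15.999) * NA_AVO
}
pair_water_anchor <- pmax(0, water_total - kn_sigma(pair_anchor_E) * ne_water -
                             pe_water(pair_anchor_E))
pair_water_anchor[1] <- 0  # threshold

## smooth monotone interpolation of the universal curve vs energy
pair_universal <- function(E) {
  f <- numeric(length(E))
  ok <- E > 1.022
  if (any(ok)) {
    f[ok] <- stats::splinefun(pair_anchor_E, pair_water_anchor / zz_water,
                              method = "hyman")(pmin(E[ok], 10))
    ## linear continuation above 10 MeV not needed (grid capped at 10)
    f[ok] <- pmax(0, f[ok])
  }
  f
}

energies <- exp(seq(log(0.01), log(10), length.out = 48))
## make sure classic anchor points land exactly on the grid for tests
energies <- sort(unique(signif(c(energies, 0.03, 0.1, 1.25, 2, 6), 6)))

rows <- do.call(rbind, lapply(seq_len(nrow(elements)), function(i) {
  el <- elements[i, ]
  inc  <- kn_sigma(energies) * NA_AVO * el$Z / el$A
  pe   <- pe_sigma(el$Z, energies) * NA_AVO / el$A
  pair <- pair_universal(energies) * zz_over_a(el$Z, el$A)
  data.frame(element = el$symbol, Z = el$Z, A = el$A,
             energy_mev = energies,
             mu_pe = signif(pe, 6), mu_incoh = signif(inc, 6),
             mu_pair = signif(pair, 6),
             mu_total = signif(pe + inc + pair, 6))
}))

write.csv(rows, "inst/extdata/xs_photon.csv", row.names = FALSE, quote = FALSE)
cat("wrote", nrow(rows), "rows;",
    "water@2MeV =",
    signif(0.111894 * rows$mu_total[rows$element == "H" & rows$energy_mev == 2] +
           0.888106 * rows$mu_total[rows$element == "O" & rows$energy_mev == 2], 4),
    "cm^2/g\n")
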