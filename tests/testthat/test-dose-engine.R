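## beams, the MC kernel, the raytracer, calibration and the PDD fit

test_that("beam and arc specifications validate their geometry", {
  b <- beam_spec(field = c(15, 10), mu = 500, gantry = 0)
  expect_equal(b$src, c(0, -1000, 0))
  expect_equal(sum(b$axis * b$e_x), 0)
  expect_error(beam_spec(field = c(-1, 10)), "field")
  a <- arc_spec(start = 90, stop = 270, direction = "ccw", spacing = 2)
  expect_length(a$angles, 91)                        # endpoints included
  expect_true(all(c(90, 0, 270) %in% a$angles))      # passes anterior
  expect_error(arc_spec(spacing = 7), "divide")
})

test_that("raytracer dose falls off monotonically and scales with density", {
  g <- small_water_grid()
  b <- beam_spec(field = c(10, 10), mu = 100)
  d <- raytrace_dose(g, b)
  p <- extract_profile(d, "y", c(0, 0, 0), lateral_avg_mm = 10)
  beyond <- p$dose[p$position > 20 & p$position < 190]
  expect_true(all(diff(beyond) < 0))                 # monotone falloff
  ## peak near the buildup depth, then decrease
  expect_gt(which.max(p$dose), 1)
  ## doubling density halves the depth of an iso-transmission surface
  g2 <- small_water_grid()
  g2$density$data[] <- 2
  d2 <- raytrace_dose(g2, b)
  p2 <- extract_profile(d2, "y", c(0, 0, 0), lateral_avg_mm = 10)
  ## compare radiological attenuation with inverse-square removed
  isq <- ((1000 + p$position) / 1000)^2
  a1 <- -log(p$dose * isq / max(p$dose * isq))
  a2 <- -log(p2$dose * isq / max(p2$dose * isq))
  i40 <- which(p$position == 81); i20 <- which(p$position == 41)
  expect_equal(a2[i20], a1[i40], tolerance = 0.08)
})

test_that("inserting the magnet slab reproduces closed-form transmission", {
  ## raytracer primary attenuation vs the transmission() closed form
  sp <- spectrum_6mv(mono = 2)
  g0 <- small_water_grid(lateral = 80, depth = 120, spacing = 2)
  g1 <- small_water_grid(lateral = 80, depth = 120, spacing = 2)
  nd <- tte_material("ndfeb")
  iy <- which(voxel_centers(g1$density, 2) > 30 &
              voxel_centers(g1$density, 2) <= 32.41)
  g1$materials <- c("water", "ndfeb")
  g1$matid[, iy, ] <- 2L
  g1$density$data[, iy, ] <- 7.4 * 2.41 / (2 * length(iy))  # conserve mass
  b <- beam_spec(field = c(6, 6), mu = 1, spectrum = sp)
  ## primary beam only: disable the commissioned scatter-buildup term
  d0 <- raytrace_dose(g0, b, k_scatter = 0)
  d1 <- raytrace_dose(g1, b, k_scatter = 0)
  deep <- voxel_centers(d0$dose, 2) > 60
  ratio <- mean(d1$dose$data[20, deep, 20] / d0$dose$data[20, deep, 20])
  ## closed form: magnet transmission over the displaced water's
  expect_equal(ratio,
               transmission(nd, 0.241, 2) /
                 transmission(tte_material("water"), 0.2 * length(iy), 2),
               tolerance = 0.005)
})

test_that("Woodcock tracking equals direct exponential sampling", {
  d <- ttedose:::cpp_woodcock_depths(30000, 0.05, 0.4, 11)
  ks <- suppressWarnings(stats::ks.test(d, "pexp", 0.05))
  expect_gt(ks$p.value, 0.001)
  expect_equal(mean(d), 20, tolerance = 3 * 20 / sqrt(30000) / 20 + 0.02)
})

test_that("MC transmission through a homogeneous slab matches Beer-Lambert", {
  ## narrow-beam geometry: a pencil beam whose full cross-section fits in
  ## the probe window, so the probe-average kerma decays at the primary
  ## attenuation rate (small scatter build-up tolerated)
  sp <- spectrum_6mv(mono = 2)
  g <- slab_grid("water", depth = 200, spacing = c(8, 2, 8))
  b <- beam_spec(field = c(0.5, 0.5), mu = 1, spectrum = sp)
  d <- cached("mc_mono_water", mc_dose(g, b, histories = 2e5, seed = 3))
  ## energy conservation ledger is exact
  expect_lt(abs(d$e_launched - d$e_transferred - d$e_escaped) /
            d$e_launched, 1e-3)
  p <- extract_profile(d, "y", c(0, 0, 0), lateral_avg_mm = 8)
  mu <- mixture_mu_rho(tte_material("water"), 2)
  i0 <- which(p$position == 11)
  sel <- which(p$position > 11 & p$position <= 110)
  ratio <- p$dose[sel] / p$dose[i0]
  expected <- exp(-mu * (p$position[sel] - 11) / 10)
  expect_equal(ratio, expected, tolerance = 0.04)
})

test_that("MC runs are bit-reproducible for a fixed seed", {
  g <- small_water_grid(lateral = 80, depth = 100, spacing = 8)
  b <- beam_spec(field = c(5, 5), mu = 1)
  d1 <- mc_dose(g, b, histories = 2e4, seed = 77)
  d2 <- mc_dose(g, b, histories = 2e4, seed = 77)
  expect_identical(d1$dose$data, d2$dose$data)
  expect_identical(d1$relunc$data, d2$relunc$data)
  d3 <- mc_dose(g, b, histories = 2e4, seed = 78)
  expect_false(identical(d1$dose$data, d3$dose$data))
})

test_that("batch uncertainty scales like one over root histories", {
  g <- small_water_grid(lateral = 80, depth = 100, spacing = 8)
  b <- beam_spec(field = c(5, 5), mu = 1)
  hs <- c(1e4, 4e4, 1.6e5)
  med <- vapply(hs, function(h) {
    d <- mc_dose(g, b, histories = h, seed = 5)
    hi <- d$dose$data > 0.5 * max(d$dose$data)
    stats::median(d$relunc$data[hi])
  }, 0)
  fit <- stats::lm(log(med) ~ log(hs))
  expect_equal(unname(stats::coef(fit)[2]), -0.5, tolerance = 0.1)
})

test_that("raytracer matches MC on water depth dose beyond buildup", {
  g <- cached("pdd_grid", water_box_grid(160, 250, c(4, 2, 4)))
  b <- beam_spec(field = c(10, 10), mu = 100)
  dmc <- cached("pdd_mc", mc_dose(g, b, histories = 6e5, seed = 5))
  drt <- raytrace_dose(g, b)
  pm <- extract_profile(dmc, "y", c(0, 0, 0), lateral_avg_mm = 10)
  pr <- extract_profile(drt, "y", c(0, 0, 0), lateral_avg_mm = 10)
  sel <- pm$position >= 20 & pm$position <= 200
  i0 <- which(pm$position == 21)
  ratio <- (pm$dose[sel] / pm$dose[i0]) / (pr$dose[sel] / pr$dose[i0])
  expect_lt(max(abs(ratio - 1)), 0.03 + 3 * max(pm$relunc[sel]))
})

test_that("arc with a single control point equals the static beam", {
  g <- small_water_grid(lateral = 80, depth = 100, spacing = 8)
  g$iso <- c(0, 50, 0)
  a <- arc_spec(start = 0, stop = 0, direction = "cw", spacing = 360,
                field = c(5, 5), mu = 100)
  expect_length(a$angles, 2)  # degenerate full-span declaration
  ## use an explicit single angle instead
  a$angles <- 0
  da <- arc_dose(g, a, engine = "mc", histories = 2e4, seed = 9)
  b <- beam_spec(field = c(5, 5), mu = 100, ssd = 100, gantry = 0,
                 ref = g$iso)
  db <- mc_dose(g, b, histories = 2e4, seed = 9 + 7919)
  expect_identical(da$dose$data, db$dose$data)
})

test_that("lateral shells receive symmetric dose under the partial arc", {
  ## a water cylinder about the rotation axis: the 90-270 arc must give
  ## left and right flanks the same dose within noise
  sc <- breast_scene("AlloX2-Pro", half_axes = c(30, 30, 30), base_y = 29)
  sc$solids <- sc$solids[2:3]      # balloon only, no holder/bolus/ports
  sc$port_solid_idx <- integer(0); sc$magnet_solid_idx <- integer(0)
  ph <- voxelize(sc, 4)
  g <- truth_grid(ph)
  g$iso <- c(0, 0, 0)
  a <- arc_spec(start = 90, stop = 270, direction = "ccw", spacing = 10,
                field = c(4, 4), mu = 100)
  d <- arc_dose(g, a, engine = "mc", histories = 4e5, seed = 21)
  xpos <- voxel_centers(d$dose, 1)
  left <- d$dose$data[which(abs(xpos - 20) < 6), 14:16, 14:16]
  right <- d$dose$data[which(abs(xpos + 20) < 6), 14:16, 14:16]
  expect_equal(mean(left), mean(right), tolerance = 0.04)
})

test_that("calibration delivers 1 cGy per MU at dmax and preserves ratios", {
  cal <- cached("cal_mc", calibrate_engine(spectrum_6mv(), "mc",
                                           histories = 3e5, seed = 99))
  g <- cached("pdd_grid", water_box_grid(160, 250, c(4, 2, 4)))
  b <- beam_spec(field = c(10, 10), mu = 100, spectrum = spectrum_6mv())
  d <- cached("pdd_mc", mc_dose(g, b, histories = 6e5, seed = 5))
  dc <- apply_calibration(d, cal)
  ## the reference geometry delivers ~1 cGy/MU at dmax (same field, 100 MU)
  p <- extract_profile(dc, "y", c(0, 0, 0), lateral_avg_mm = 10)
  expect_equal(max(p$dose), 100, tolerance = 0.03)
  ## scaling preserves all dose ratios
  expect_equal(dc$dose$data / sum(dc$dose$data),
               d$dose$data / sum(d$dose$data), tolerance = 1e-12)
})

test_that("exponential PDD fit recovers exact and noisy curves", {
  d <- seq(2, 20, 0.5)
  v <- 80 * exp(-0.046 * d)
  f <- fit_pdd_exponential(d, v)
  expect_equal(f$A, 80, tolerance = 1e-10)
  expect_equal(f$b, 0.046, tolerance = 1e-10)
  expect_equal(f$value, 80 * exp(-0.46), tolerance = 1e-10)
  ## 0.5% multiplicative noise: value at 10 cm within 1%
  set.seed(31)
  vn <- v * (1 + stats::rnorm(length(v), 0, 0.005))
  fn <- fit_pdd_exponential(d, vn)
  expect_equal(fn$value, 80 * exp(-0.46), tolerance = 0.01)
  ## diagnostics: non-monotone input warns, nonpositive input errors
  vb <- v; vb[20] <- vb[19] * 1.2
  expect_warning(fit_pdd_exponential(d, vb), "not monotone")
  vz <- v; vz[20] <- -1
  expect_error(fit_pdd_exponential(d, vz), "nonpositive")
  expect_error(fit_pdd_exponential(d[1:4], v[1:4]), "at least 5")
})
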