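## port templates, scenes, voxelization, synthetic CT and contours

test_that("port templates carry the vendor-quoted magnet dimensions", {
  d <- port_template("DermaSpan")
  expect_equal(port_magnet_thickness(d), 2.41)
  expect_length(d$magnet_ids, 1)
  a <- port_template("AlloX2")
  expect_equal(port_magnet_thickness(a), 2.50)
  expect_length(a$magnet_ids, 2)          # two ports, one magnet each
  p <- port_template("AlloX2-Pro")
  expect_equal(port_magnet_thickness(p), 7.14)
  expect_equal(port_magnet_extent(p), 10.4)
  expect_length(p$magnet_ids, 1)
  ## Ti casing for the commercial models, PEEK for the novel one
  expect_equal(d$solids[[1]]$material, "titanium")
  expect_equal(a$solids[[1]]$material, "titanium")
  expect_equal(p$solids[[1]]$material, "peek")
  ## lateral extent about three times the AlloX2-Pro magnet
  expect_gt(port_magnet_extent(d) / port_magnet_extent(p), 2.2)
  expect_lt(port_magnet_extent(d) / port_magnet_extent(p), 3.5)
  expect_error(port_template("NoSuch"))
})

test_that("wax slab scene has the published stack dimensions", {
  sc <- wax_slab_scene("DermaSpan")
  expect_equal(diff(sc$slab_y), 17)                 # 1.7 cm wax
  expect_equal(sc$slab_y[1] - sc$surface_y, 15)     # 1.5 cm upstream
  ## total stack 1.5 + 1.7 + 10 = 13.2 cm
  expect_equal(132 - sc$surface_y, 132)
  ph <- voxelize(sc, 4)
  wax_code <- match("wax", ph$materials)
  wax_vox <- sum(ph$labels$data == wax_code)
  ## 30 x 30 x 1.7 cm^3 of wax (port removes a little)
  expect_equal(wax_vox * prod(ph$spacing) / 1000, 30 * 30 * 1.7 / 0.001 / 1000,
               tolerance = 0.06)
  expect_equal(tte_material("wax")$density, 0.92)
})

test_that("breast scene holds the dual-port models only", {
  expect_error(breast_scene("DermaSpan"), "dual-port")
  sc <- breast_scene("AlloX2-Pro")
  bol <- sc$solids[[2]]
  expect_equal(bol$material, "wax")
  ## the bolus slab is 5 mm thick above the dome (2 mm overridden by bag)
  expect_equal(2 * bol$half[2] - 2, 5)
  expect_equal(sc$balloon$shell, 1)                 # ~1 mm silicone shell
  ph <- voxelize(sc, 4)
  expect_true("water" %in% ph$materials)            # water fill, not saline
  expect_true("silicone" %in% ph$materials)
})

test_that("voxelization respects priority and conserves magnet mass", {
  sc <- wax_slab_scene("AlloX2-Pro")
  ph <- voxelize(sc, 2)
  ## voxel at the magnet center carries the magnet label and density
  ctr <- sc$iso
  ij <- vapply(1:3, function(a)
    which.min(abs(voxel_centers(ph$density, a) - ctr[a])), 0L)
  expect_equal(ph$materials[ph$labels$data[ij[1], ij[2], ij[3]]], "ndfeb")
  expect_equal(ph$density$data[ij[1], ij[2], ij[3]], 7.4)
  ## magnet mass within 15% of the analytic solid at 0.5 mm spacing, and
  ## voxelized mass error shrinks with refinement (template-only scene so
  ## the fine grid stays small)
  tpl <- sc$template
  tsc <- structure(list(name = "template", model = "AlloX2-Pro",
                        solids = tpl$solids, background = "air",
                        bbox = list(x = c(-16, 16), y = c(-6, 6),
                                    z = c(-30, 30)),
                        iso = c(0, 0, 0), medium = "air",
                        port_solid_idx = seq_along(tpl$solids),
                        magnet_solid_idx = tpl$magnet_ids,
                        template = tpl), class = "tte_scene")
  vol_true <- pi * (10.4 / 2)^2 * 7.14                   # mm^3
  err <- vapply(c(2, 1, 0.5), function(sp) {
    phx <- voxelize(tsc, sp)
    code <- match("ndfeb", phx$materials)
    v <- sum(phx$labels$data == code) * prod(phx$spacing)
    abs(v / vol_true - 1)
  }, 0)
  expect_lt(err[3], 0.15)
  expect_true(err[3] <= err[1] + 1e-9)
})

test_that("synthetic CT saturates metal and blooms Ti-encased artifacts", {
  sc <- wax_slab_scene("DermaSpan")
  ph <- voxelize(sc, 2)
  ct <- synthesize_ct(ph, saturation = 2.5, bloom = TRUE)
  dens <- ct_density(ct)
  mag <- ph$labels$data == match("ndfeb", ph$materials)
  ## magnet voxels read back the saturation density, not 7.4
  expect_equal(unique(dens[mag]), 2.5)
  expect_error(synthesize_ct(ph, saturation = -1), "saturation")
  ## bloom off: artifact equals the voxelized high-density footprint
  ct0 <- synthesize_ct(ph, bloom = FALSE)
  expect_equal(ct0$artifact, ph$density$data > 2.5)
  ## artifact thickness about three times the magnet thickness
  iz <- which.min(abs(voxel_centers(ph$density, 3)))
  ix <- which.min(abs(voxel_centers(ph$density, 1)))
  t_art <- sum(ct$artifact[ix, , iz]) * ph$spacing[2]
  ratio <- t_art / port_magnet_thickness(sc$template)
  expect_gte(ratio, 2.5); expect_lte(ratio, 3.5)
  ## AlloX2-Pro: artifact thickness about the magnet thickness itself
  scp <- wax_slab_scene("AlloX2-Pro")
  php <- voxelize(scp, 2)
  ctp <- synthesize_ct(php, bloom = TRUE)
  t_artp <- sum(ctp$artifact[ix, , iz]) * php$spacing[2]
  expect_lt(t_artp / 7.14, 1.5)
  expect_gte(t_artp / 7.14, 0.8)
})

test_that("CT round trip recovers density where the curve is invertible", {
  sc <- wax_slab_scene("AlloX2")
  ph <- voxelize(sc, 4)
  ct <- synthesize_ct(ph, saturation = 2.5, bloom = FALSE)
  dens <- ct_density(ct)
  ok <- ph$density$data <= 2.5    # below saturation the curve is invertible
  ## 1 HU quantization ~ 0.001 g/cm^3
  expect_lt(max(abs(dens[ok] - ph$density$data[ok])), 0.002)
})

test_that("shell contours tile the 3 mm expansion in four sectors", {
  sc <- breast_scene("AlloX2")
  ph <- voxelize(sc, 2)
  co <- make_shell_contours(ph)
  sect <- c("C_Anterior", "C_Posterior", "C_Left", "C_Right")
  masks <- lapply(co[sect], function(x) x$mask$data)
  ## pairwise disjoint
  for (i in 1:3) for (j in (i + 1):4)
    expect_false(any(masks[[i]] & masks[[j]]))
  ## union is the full 3 mm shell: every shell voxel within 3 mm of the bag
  un <- Reduce(`|`, masks)
  dist <- ttedose:::cpp_dist_transform(co$bag$mask$data, dim(un), ph$spacing)
  expect_true(all(dist[un] <= 3 + 1e-9))
  expect_true(all(un[!co$bag$mask$data & dist <= 3]))
  ## volumes in line with the published contour volumes (within 20%)
  expect_equal(co$C_Posterior$volume_cc, 15.4, tolerance = 0.2)
  expect_equal(co$C_Anterior$volume_cc, 17.6, tolerance = 0.2)
  ## volume field consistent with the mask
  expect_equal(co$bag$volume_cc,
               sum(co$bag$mask$data) * prod(ph$spacing) / 1000)
})
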