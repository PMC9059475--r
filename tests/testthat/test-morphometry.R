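test_that("VOI selection implements the half-open growth-plate rule", {
  lab <- array(1L, dim = c(4, 4, 350))
  vol <- voxel_volume(lab, spacing = 10, growth_plate_z = 0)
  voi <- select_voi(vol)             # defaults: 1 mm below, 2 mm extent
  expect_equal(dim(voi$labels)[3], 200)          # slices [100, 300)
  expect_equal(voi$origin[3], 1.0)

  full <- select_voi(voxel_volume(lab, 10, growth_plate_z = 0),
                     offset = 0, extent = 3.5)
  expect_equal(dim(full$labels)[3], 350)         # identity crop
  expect_error(select_voi(vol, offset = 10),
               class = "osteomech_range_error")
  expect_error(select_voi(voxel_volume(lab, 10), offset = 1),
               class = "osteomech_range_error")
})

test_that("global metrics: counting, complement, and surface oracle", {
  slab <- array(FALSE, dim = c(20, 20, 20))
  slab[, , 1:10] <- TRUE
  gm <- global_metrics(slab, 10)
  expect_equal(gm$bvtv, 0.5)
  # complement partition
  expect_equal(global_metrics(!slab, 10)$bvtv, 0.5)

  solid <- array(TRUE, dim = c(12, 12, 12))
  gm2 <- global_metrics(solid, 10)
  expect_equal(gm2$bvtv, 1)
  expect_lt(gm2$bstv, 1e-9)    # open VOI faces carry no surface

  sph <- digital_sphere(50)
  area <- osteomech:::phase_surface_area(sph, 10)   # mm^2 at 10 um voxels
  expect_lt(abs(area / (4 * pi * (50 * 0.01)^2) - 1), 0.03)
})

test_that("local thickness recovers plates and rods within a voxel", {
  plate <- digital_plate(10)               # 100 um at 10 um spacing
  th <- local_thickness(plate, 10)
  expect_lt(abs(th$mean - 0.100), 0.010 + 1e-9)

  rod <- digital_cylinder(4, 60)           # 80 um diameter
  thr <- local_thickness(rod, 10)
  expect_lt(abs(thr$mean - 0.080), 0.010 + 1e-9)

  # map never exceeds the bounding dimension of the phase
  expect_lte(max(th$map), 0.100 + 0.010)
  expect_error(local_thickness(array(FALSE, c(4, 4, 4)), 10),
               class = "osteomech_undefined_metric")
})

test_that("lattice phantom thickness/separation match the design", {
  blk <- rod_lattice_block(120, s_vox = 24, t_vox = 6)  # 60 um / 240 um at 10 um
  th <- local_thickness(blk, 10)
  expect_lt(abs(th$mean - 0.060), 0.011)
  sp <- local_thickness(!blk, 10)
  # pore inscribed diameter: sqrt(2) * pitch - diameter
  expect_lt(abs(sp$mean - (sqrt(2) * 0.24 - 0.06)), 0.035)
})

test_that("trabecular number follows the direct 3D convention", {
  expect_equal(trabecular_number(0.06, 0.19), 4)
  expect_lt(trabecular_number(0.06, 100), 0.01)    # tb_sp -> inf limit
  expect_error(trabecular_number(0, 0),
               class = "osteomech_undefined_metric")
})

test_that("SMI distinguishes plates, rods and spheres", {
  expect_lt(abs(structure_model_index(digital_plate(20, nxy = 50), 10)),
            0.3)
  expect_lt(abs(structure_model_index(digital_cylinder(10, 80), 10) - 3),
            0.3)
  expect_lt(abs(structure_model_index(digital_sphere(40), 10) - 4), 0.3)
  expect_error(structure_model_index(array(FALSE, c(4, 4, 4)), 10),
               class = "osteomech_undefined_metric")
})

test_that("cortical thickness measures the annulus wall", {
  ph <- make_prism_phantom("annulus", list(ro = 0.6, ri = 0.4), length = 2,
                           spacing = 20)
  expect_lt(abs(cortical_thickness(ph$volume) - 0.2), 0.020 + 1e-9)
  empty <- voxel_volume(array(0L, c(4, 4, 4)), 20)
  expect_error(cortical_thickness(empty),
               class = "osteomech_undefined_metric")
})

test_that("morphometry indices are invariant to 90-degree rotations", {
  set.seed(7)
  ph <- make_femur_phantom(phantom_params(voxel_spacing = 22.5, seed = 7))
  voi <- select_voi(ph$volume)
  bone <- voi$labels == 2L
  rot <- aperm(bone[, dim(bone)[2]:1, ], c(2, 1, 3))   # 90 deg about z
  expect_equal(sum(rot), sum(bone))
  th1 <- local_thickness(bone, 22.5)$mean
  th2 <- local_thickness(rot, 22.5)$mean
  expect_equal(th1, th2, tolerance = 1e-12)
  s1 <- osteomech:::phase_surface_area(bone, 22.5)
  s2 <- osteomech:::phase_surface_area(rot, 22.5)
  expect_equal(s1, s2, tolerance = 5e-3)   # tetrahedral split orientation
})

test_that("full report reproduces phantom design values", {
  ph <- make_femur_phantom(phantom_params(seed = 1))
  rep <- morphometry_report(ph$volume)
  gt <- ph$ground_truth
  expect_lt(abs(rep$bvtv - gt$true_bvtv), 0.01)
  expect_lt(abs(rep$tb_th - gt$true_strut_thickness), 0.01125 + 1e-9)
  expect_lt(abs(rep$ct_th - gt$cortical_thickness), 0.01125 + 1e-9)
  expect_gte(rep$bvtv, 0)
  expect_lte(rep$bvtv, 1)
})
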