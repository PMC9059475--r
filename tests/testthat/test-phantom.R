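test_that("Hertz forward model satisfies the contact relation", {
  expect_equal(hertz_force(1, E = 1, nu = 0, R = 1), 4 / 3)
  expect_equal(hertz_force(0, E = 5, nu = 0.3, R = 300), 0)
  cv <- synth_indentation_curve(E = 5, nu = 0.3, R = 300, depth_max = 50,
                                noise_sd = 0)
  # every sample lies on the Hertz curve and force is strictly increasing
  expect_equal(cv$force, hertz_force(cv$depth, 5, 0.3, 300))
  expect_true(all(diff(cv$force) > 0))
  expect_error(synth_indentation_curve(E = 5, depth_max = -1),
               class = "osteomech_parameter_error")
})

test_that("frequency sweep follows E(f) = a + b ln f", {
  sw <- synth_frequency_sweep(a = 10, b = 2, freqs = c(1, 10, 100),
                              noise_sd = 0)
  fits <- vapply(sw, function(cv) fit_hertz(cv)$modulus_e, numeric(1))
  expect_equal(fits, 10 + 2 * log(c(1, 10, 100)), tolerance = 1e-8)
  # ln 1 = 0 so the first curve is generated exactly at modulus a
  expect_equal(fits[1], 10, tolerance = 1e-8)
  flat <- synth_frequency_sweep(a = 4, b = 0, freqs = c(1, 10, 100),
                                noise_sd = 0)
  expect_equal(flat[[1]]$force, flat[[3]]$force)
  expect_error(synth_frequency_sweep(a = 1, b = -2, freqs = c(1, 10)),
               class = "osteomech_parameter_error")
})

test_that("bending generator honors stiffness and peak force", {
  bc <- synth_bending_curve(noise_sd = 0)
  sl <- diff(bc$force) / diff(bc$displacement)
  expect_lt(abs(max(sl) / 120 - 1), 0.01)
  expect_equal(max(bc$force), 25)
  expect_error(synth_bending_curve(yield_load = 30, ultimate_load = 25),
               class = "osteomech_parameter_error")
  expect_error(synth_bending_curve(fracture_disp = 0.01),
               class = "osteomech_parameter_error")
})

test_that("calcein generator encodes MAR and MS/BS ground truth", {
  ls <- synth_calcein_dataset(mar_true = 1, msbs_true = 0.5, n_fields = 200,
                              noise_frac = 0, seed = 1)
  expect_equal(mean(ls$distances), 7)
  z <- synth_calcein_dataset(mar_true = 1, msbs_true = 0, n_fields = 10,
                             seed = 1)
  expect_equal(sum(z$fields$dl_surface), 0)
  expect_equal(sum(z$fields$sl_surface), 0)
  expect_error(synth_calcein_dataset(1, msbs_true = 1.5),
               class = "osteomech_parameter_error")
})

test_that("prism phantoms carry closed-form section ground truth", {
  circ <- make_prism_phantom("circle", list(r = 0.5), length = 2,
                             spacing = 25)
  expect_equal(circ$ground_truth$imax, pi * 0.5^4 / 4)
  ann <- make_prism_phantom("annulus", list(ro = 0.6, ri = 0.4), length = 2,
                            spacing = 25)
  expect_equal(ann$ground_truth$imax, pi * (0.6^4 - 0.4^4) / 4)
  sq <- make_prism_phantom("square", list(a = 1), length = 2, spacing = 25)
  expect_equal(sq$ground_truth$imax, 1 / 12)
  expect_error(make_prism_phantom("hexagon", list(a = 1), 2, 25),
               class = "osteomech_parameter_error")
})

test_that("femur phantom hits the BV/TV target and is deterministic", {
  p <- phantom_params(trabecular_target_bvtv = 0.12, seed = 1)
  ph <- make_femur_phantom(p)
  voi <- select_voi(ph$volume)
  bone <- voi$labels == 2
  comp <- bone | voi$labels == 3
  bvtv <- sum(bone) / sum(comp)
  expect_gte(bvtv, 0.11)
  expect_lte(bvtv, 0.13)
  expect_equal(abs(bvtv - 0.12) < 0.01 + 1e-12, TRUE)

  ph2 <- make_femur_phantom(p)
  expect_identical(ph$volume$labels, ph2$volume$labels)

  empty <- make_femur_phantom(phantom_params(trabecular_target_bvtv = 0,
                                             seed = 1))
  expect_equal(sum(select_voi(empty$volume)$labels == 2), 0)

  expect_error(phantom_params(strut_thickness = 0.3, strut_spacing = 0.2),
               class = "osteomech_parameter_error")
  expect_error(phantom_params(strut_thickness = 0.01),
               class = "osteomech_parameter_error")
})

test_that("cortical shell is a closed ring in every slice", {
  ph <- make_femur_phantom(phantom_params(seed = 2))
  lab <- ph$volume$labels
  # no interior (trabecular/marrow) voxel may touch exterior background
  shift <- function(a, di, dj) {
    n <- dim(a)
    out <- array(FALSE, n)
    si <- max(1, 1 + di):min(n[1], n[1] + di)
    sj <- max(1, 1 + dj):min(n[2], n[2] + dj)
    out[si, sj, ] <- a[si - di, sj - dj, , drop = FALSE]
    out
  }
  interior <- lab == 2L | lab == 3L
  exterior <- lab == 0L
  leak <- FALSE
  for (dd in list(c(1, 0), c(-1, 0), c(0, 1), c(0, -1)))
    leak <- leak || any(interior & shift(exterior, dd[1], dd[2]))
  expect_false(leak)
})

test_that("voxelization refinement moves BV/TV toward the target", {
  bv <- vapply(c(22.5, 11.25), function(sp) {
    ph <- make_femur_phantom(phantom_params(voxel_spacing = sp, seed = 3))
    voi <- select_voi(ph$volume)
    sum(voi$labels == 2) / sum(voi$labels %in% c(2, 3))
  }, numeric(1))
  expect_lt(abs(bv[2] - 0.12), abs(bv[1] - 0.12))
})

test_that("volume and curve containers validate their invariants", {
  expect_error(voxel_volume(array(5L, c(2, 2, 2)), 10),
               class = "osteomech_parameter_error")
  expect_error(force_indentation_curve(1:5, 1:5),
               class = "osteomech_parameter_error")
  expect_error(load_displacement_curve(c(0, 0.2, 0.1, seq(0.3, 2, 0.1)),
                                       rep(1, 21)),
               class = "osteomech_data_error")
})

test_that("volumes and curves survive file round trips", {
  ph <- make_prism_phantom("annulus", list(ro = 0.5, ri = 0.3), length = 2,
                           spacing = 50)
  path <- tempfile(fileext = ".mha")
  write_volume_mha(ph$volume, path)
  back <- read_volume_mha(path)
  expect_identical(back$labels, ph$volume$labels)
  expect_equal(back$spacing, ph$volume$spacing)
  expect_equal(back$origin, ph$volume$origin)

  cv <- synth_indentation_curve(E = 5, noise_sd = 0.1, seed = 2)
  pc <- tempfile(fileext = ".csv")
  write_indentation_csv(cv, pc)
  cv2 <- read_indentation_csv(pc)
  expect_equal(cv2$force, cv$force)
  expect_equal(cv2$probe_radius, cv$probe_radius)

  bc <- synth_bending_curve(noise_sd = 0.05, seed = 3)
  pb <- tempfile(fileext = ".csv")
  write_bending_csv(bc, pb)
  bc2 <- read_bending_csv(pb)
  expect_equal(bc2$displacement, bc$displacement)
  expect_equal(bc2$span, bc$span)
})
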