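test_that("hex element stiffness has the right null space and symmetry", {
  K <- osteomech:::hex_stiffness(1000, 0.3, 0.05)
  expect_equal(K, t(K), tolerance = 1e-12)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)   # six rigid-body modes
  expect_true(all(ev > -1e-8 * max(ev)))
  # rigid translation produces no force
  u_rigid <- rep(c(1, 0, 0), 8)
  expect_lt(max(abs(K %*% u_rigid)), 1e-9 * max(abs(K)))
})

test_that("material assignment covers labels and flags gaps", {
  ph <- make_femur_phantom(phantom_params(voxel_spacing = 45, seed = 1,
                                          strut_thickness = 0.09,
                                          trabecular_target_bvtv = 0.12,
                                          shaft_length = 0.5,
                                          metaphysis_extent = 1,
                                          growth_plate_position = 0.1))
  mats <- material_map(cortical_E = 10000, trabecular_E = 7000)
  model <- assign_materials(ph$volume, mats)
  expect_equal(nrow(model$elem_nodes), sum(ph$volume$labels != 0))
  # marrow defaults
  marrow <- model$materials[["3"]]
  expect_equal(unname(marrow["E"]), 20)
  expect_equal(unname(marrow["nu"]), 0.499)
  expect_error(assign_materials(ph$volume, mats[c("1", "3")]),
               class = "osteomech_config_error")
  # excluding marrow shrinks the mesh to bone voxels
  mb <- assign_materials(ph$volume, mats, include_marrow = FALSE)
  expect_equal(nrow(mb$elem_nodes), sum(ph$volume$labels %in% 1:2))
})

test_that("floating voxels are reported as disconnected", {
  lab <- array(0L, c(10, 10, 10))
  lab[2:4, 2:4, 2:4] <- 1L
  lab[7:9, 7:9, 7:9] <- 1L      # separate island
  vol <- voxel_volume(lab, 100)
  expect_error(assign_materials(vol, material_map(cortical_E = 1000)),
               class = "osteomech_solver_error")
})

test_that("solid beam: linearity, symmetry, reactions, beam theory", {
  ph <- make_prism_phantom("square", list(a = 0.4), length = 4.4,
                           spacing = 50)
  model <- assign_materials(ph$volume, material_map(cortical_E = 10000))
  sol <- fe_bending_solve(model, span = 4, load = 5)

  # reaction balance
  expect_lt(abs(sol$reaction_balance) / 5, 1e-6)
  # exact linearity in the load
  sol2 <- fe_bending_solve(model, span = 4, load = 10)
  expect_equal(sol2$u, 2 * sol$u, tolerance = 1e-9)
  expect_equal(sol2$von_mises_stress, 2 * sol$von_mises_stress,
               tolerance = 1e-9)
  # mirror symmetry about midspan
  uy <- sol$u[, "uy"]
  co <- model$coords
  zmid <- mean(range(co[, "z"]))
  i_lo <- which(abs(co[, "z"] - (zmid - 1)) < 1e-9)
  i_hi <- which(abs(co[, "z"] - (zmid + 1)) < 1e-9)
  o_lo <- i_lo[order(co[i_lo, "x"], co[i_lo, "y"])]
  o_hi <- i_hi[order(co[i_hi, "x"], co[i_hi, "y"])]
  expect_equal(uy[o_lo], uy[o_hi], tolerance = 1e-6)
  # strain energy consistency with the single load
  expect_equal(sol$strain_energy, 0.5 * 5 * sol$midspan_deflection,
               tolerance = 0.02)
  # Euler-Bernoulli ballpark for a moderately slender solid beam
  sec <- section_properties(ph$volume$labels[, , 5] == 1, 50)
  delta_eb <- 5 * 4^3 / (48 * 10000 * sec$imin)
  expect_lt(abs(sol$midspan_deflection / delta_eb - 1), 0.08)

  # zero load gives the zero field
  sol0 <- fe_bending_solve(model, span = 4, load = 0)
  expect_equal(max(abs(sol0$u)), 0)
})

test_that("von Mises invariants", {
  uni <- matrix(c(7, 0, 0, 0, 0, 0), 1)
  expect_equal(von_mises_stress(uni), 7)
  hydro <- matrix(c(5, 5, 5, 0, 0, 0), 1)
  expect_equal(von_mises_stress(hydro), 0)
  shear <- matrix(c(0, 0, 0, 3, 0, 0), 1)
  expect_equal(von_mises_stress(shear), sqrt(3) * 3)
  # uniaxial strain state (nu = 0 material): e = (e, 0, 0)
  e <- matrix(c(0.01, 0, 0, 0, 0, 0), 1)
  expect_equal(von_mises_strain(e), 0.01 * 2 / 3, tolerance = 1e-12)
})

test_that("uniform modulus scaling: stresses fixed, strains scaled", {
  ph <- make_prism_phantom("square", list(a = 0.3), length = 3,
                           spacing = 60)
  m1 <- assign_materials(ph$volume, material_map(cortical_E = 10000))
  m2 <- assign_materials(ph$volume, material_map(cortical_E = 5000))
  s1 <- fe_bending_solve(m1, span = 2.6, load = 5)
  s2 <- fe_bending_solve(m2, span = 2.6, load = 5)
  expect_equal(s2$von_mises_stress, s1$von_mises_stress, tolerance = 1e-9)
  expect_equal(s2$von_mises_strain, 2 * s1$von_mises_strain,
               tolerance = 1e-9)
  cmp <- compare_groups(s2, s1)
  expect_lt(max(abs(cmp$percent_difference[
    cmp$quantity %in% c("peak_vm_stress", "p95_vm_stress")])), 1e-6)
  expect_equal(
    cmp$percent_difference[cmp$quantity == "peak_vm_strain"], 100,
    tolerance = 1e-6)
  same <- compare_groups(s1, s1)
  expect_true(all(same$percent_difference == 0))
  s3 <- fe_bending_solve(m1, span = 2.6, load = 2)
  expect_error(compare_groups(s1, s3),
               class = "osteomech_comparison_error")
})
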