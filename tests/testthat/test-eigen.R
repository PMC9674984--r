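test_that("buckling pressures scale linearly with the moduli", {
  mesh <- gv_mesh(gv_capsule(85, 300), target_edge = 12)
  m1 <- gv_material()
  m2 <- gv_material(E_axial = 2 * m1$E_axial, E_circ = 2 * m1$E_circ,
                    shear = 2 * m1$G)
  p1 <- linear_buckling(gv_model(mesh, m1), n_modes = 2)$pressure_kPa
  p2 <- linear_buckling(gv_model(mesh, m2), n_modes = 2)$pressure_kPa
  expect_equal(p2, 2 * p1, tolerance = 1e-6)
})

test_that("long isotropic cylinder matches the hydrostatic ring closed form", {
  matiso <- gv_material(E_axial = 1, E_circ = 1, nu = 0.3,
                        shear = 1 / (2 * 1.3))
  mesh <- gv_mesh(gv_capsule(85, 1800), target_edge = 10) # L/D > 20
  model <- gv_model(mesh, matiso, bc = "apex")
  lba <- linear_buckling(model, n_modes = 1, follower = TRUE)
  pring <- ring_buckling_pressure(1, 0.3, 2.4, 85)
  expect_lt(abs(lba$pressure_kPa[1] - pring) / pring, 0.05)
})

test_that("frequencies halve when the density quadruples", {
  mesh <- gv_mesh(gv_capsule(85, 300), target_edge = 12)
  f1 <- modal_frequencies(gv_model(mesh, gv_material()), n_modes = 2)
  f2 <- modal_frequencies(gv_model(mesh, gv_material(density = 4 * 1350)),
                          n_modes = 2)
  expect_equal(f2$frequency_MHz, f1$frequency_MHz / 2, tolerance = 1e-6)
})

test_that("the imaging drive sits far below the lowest resonance", {
  f1 <- baseline_modal()$frequency_MHz[1]
  expect_gt(f1 / 11.4, 10)
})

test_that("first buckling mode is lobed, not breathing", {
  lba <- baseline_lba()
  expect_gte(gvbuckle:::mode_wavenumber(lba, 1), 2)
})

test_that("buckling and modal results are ordered and well-formed", {
  lba <- baseline_lba()
  expect_true(all(diff(lba$pressure_kPa) >= -1e-9))
  expect_true(all(lba$pressure_kPa > 0))
  md <- baseline_modal()
  expect_true(all(diff(md$frequency_MHz) >= -1e-9))
  expect_true(all(md$frequency_MHz > 0))
})

test_that("mode export writes readable VTK files with displacement fields", {
  lba <- cached("small_lba", linear_buckling(small_model(), n_modes = 2))
  dir <- withr::local_tempdir()
  files <- mode_export(lba, dir)
  expect_length(files, 2)
  back <- read_vtk(files[1])
  expect_identical(nrow(back$nodes), nrow(small_model()$mesh$nodes))
  expect_true("displacement" %in% names(back$point_vectors))
})

test_that("tidy and glance summarize eigen results", {
  lba <- baseline_lba()
  td <- tidy(lba)
  expect_s3_class(td, "tbl_df")
  expect_named(td, c("mode", "pressure_kPa"))
  gl <- glance(lba)
  expect_equal(gl$threshold_kPa, lba$pressure_kPa[1])
  md <- baseline_modal()
  expect_equal(glance(md)$f1_MHz, md$frequency_MHz[1])
})

test_that("taller cone caps stiffen both buckling and vibration", {
  # sensitivity of the acknowledged free cone-shape parameter: the follower
  # (live-load) buckling pencil and the lowest resonance both rise steeply
  # with the cap height (values documented in the methods vignette)
  vals <- vapply(c(0.5, 1.0), function(cr) {
    model <- gv_model(gv_mesh(gv_capsule(85, 500, cone_height_ratio = cr),
                              target_edge = 5))
    c(linear_buckling(model, n_modes = 1, follower = TRUE)$pressure_kPa[1],
      modal_frequencies(model, n_modes = 1)$frequency_MHz[1])
  }, numeric(2))
  expect_equal(vals[1, 1], 252.1, tolerance = 0.02)
  expect_equal(vals[1, 2], 330.7, tolerance = 0.02)
  expect_equal(vals[2, 1], 331.6, tolerance = 0.02)
  expect_equal(vals[2, 2], 379.2, tolerance = 0.02)
})
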