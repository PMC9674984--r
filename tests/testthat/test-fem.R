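test_that("rigid-body motions lie in the null space of the stiffness", {
  model <- small_model()
  K <- assemble_stiffness(model)
  kmax <- max(abs(K))
  n <- nrow(model$mesh$nodes)
  # translations
  for (tr in list(c(1, 0, 0), c(0, 0, 1))) {
    u <- as.vector(t(cbind(matrix(tr, n, 3, byrow = TRUE), matrix(0, n, 3))))
    expect_lt(max(abs(K %*% u)), 1e-8 * kmax)
  }
  # rotation about z: u = omega x x, theta = omega
  p <- model$mesh$nodes
  u <- as.vector(t(cbind(-p[, 2], p[, 1], 0, 0, 0, 1)))
  expect_lt(max(abs(K %*% u)) / max(abs(p)), 1e-8 * kmax)
})

test_that("assembled operators are symmetric", {
  model <- small_model()
  K <- assemble_stiffness(model)
  expect_lt(max(abs(K - Matrix::t(K))), 1e-12 * max(abs(K)))
  pre <- solve_prestress(model, 1)
  Kg <- geometric_stiffness(model, pre)
  expect_lt(max(abs(Kg - Matrix::t(Kg))), 1e-12 * max(abs(Kg)) + 1e-300)
  Kp <- pressure_load_stiffness(model, 1)
  expect_lt(max(abs(Kp - Matrix::t(Kp))), 1e-12 * max(abs(Kp)) + 1e-300)
})

test_that("lumped mass conserves the wall mass and scales with thickness", {
  model <- small_model()
  M <- assemble_mass(model)
  total <- sum(M[seq(1, length(M), by = 6)]) # x-translation entries
  rho_t <- model$material$rho_internal * model$material$thickness
  expect_equal(total, rho_t * mesh_area(model$mesh), tolerance = 1e-10)
  m2 <- gv_material(thickness = 2 * model$material$thickness)
  model2 <- gv_model(model$mesh, m2)
  M2 <- assemble_mass(model2)
  expect_equal(sum(M2[seq(1, length(M2), by = 6)]), 2 * total, tolerance = 1e-10)
})

test_that("zero net pressure produces identically zero prestress", {
  model <- small_model()
  pre <- solve_prestress(model, 0)
  expect_true(all(pre$N_circ == 0))
  expect_true(all(attr(pre, "displacement") == 0))
})

test_that("mid-cylinder prestress approaches the thin-shell closed form", {
  model <- cached("prestress_model",
                  gv_model(gv_mesh(gv_capsule(85, 500), target_edge = 8),
                           bc = "apex"))
  pre <- solve_prestress(model, 1) # 1 kPa external
  mesh <- model$mesh
  zc <- mesh$geometry$Lc / 2
  cent <- (mesh$nodes[mesh$tris[, 1], 3] + mesh$nodes[mesh$tris[, 2], 3] +
             mesh$nodes[mesh$tris[, 3], 3]) / 3
  mid <- abs(cent) < zc * 0.3
  R <- 42.5
  p_int <- 1e-3 # MPa
  expect_equal(mean(pre$N_circ[mid]), -p_int * R, tolerance = 0.02)
  expect_equal(mean(pre$N_axial[mid]), -p_int * R / 2, tolerance = 0.05)
  # external overpressure is compressive
  expect_true(all(pre$N_circ[mid] < 0))
})

test_that("geometric stiffness is linear in the prestress and zero without", {
  model <- small_model()
  pre1 <- solve_prestress(model, 1)
  pre2 <- pre1
  pre2[c("N11", "N22", "N12")] <- pre1[c("N11", "N22", "N12")] * 3
  Kg1 <- geometric_stiffness(model, pre1)
  Kg3 <- geometric_stiffness(model, pre2)
  expect_lt(max(abs(Kg3 - 3 * Kg1)), 1e-10 * max(abs(Kg1)))
  pre0 <- solve_prestress(model, 0)
  expect_equal(max(abs(geometric_stiffness(model, pre0))), 0)
})

test_that("constrained stiffness is positive definite", {
  model <- small_model()
  K <- assemble_stiffness(model)
  Kff <- apply_bc(model, K)
  # Cholesky succeeds only for PD matrices
  expect_silent(Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE))
  # apex boundary condition: exactly 3 translations per pinned node
  model2 <- gv_model(model$mesh, model$material, bc = "apex")
  apex_dofs <- sort(as.vector(vapply(model2$mesh$apex, function(a)
    6L * (a - 1L) + 1:3, integer(3))))
  expect_true(all(apex_dofs %in% model2$fixed_dofs))
})

test_that("membrane patch test: affine stretch reproduces constant stress", {
  pl <- flat_plate()
  sec <- gv_section(gv_material())
  # affine in-plane displacement: exx = 1e-3, eyy = -4e-4, gxy = 6e-4
  exx <- 1e-3; eyy <- -4e-4; gxy <- 6e-4
  n <- nrow(pl$nodes)
  u6 <- matrix(0, n, 6)
  u6[, 1] <- exx * pl$nodes[, 1] + gxy / 2 * pl$nodes[, 2]
  u6[, 2] <- eyy * pl$nodes[, 2] + gxy / 2 * pl$nodes[, 1]
  N <- gvbuckle:::cpp_membrane_stress(pl$nodes, pl$tris, sec$Cm, sec$Db,
                                      c(1, 0, 0), as.vector(t(u6)))
  # compare in the common material frame (columns 4:6); the element-local
  # frames differ in orientation between triangles
  exp_N <- sec$Cm %*% c(exx, eyy, gxy)
  for (k in 1:3) {
    expect_equal(N[, k + 3], rep(exp_N[k], nrow(N)), tolerance = 1e-8)
  }
})

test_that("bending patch test: constant curvature energy is exact", {
  pl <- flat_plate()
  sec <- gv_section(gv_material())
  K <- shell_K(pl$nodes, pl$tris, sec, axis = c(1, 0, 0))
  Db <- sec$Db
  for (kap in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(0.3, -0.7, 0.5))) {
    k11 <- kap[1]; k22 <- kap[2]; k12 <- kap[3]
    w <- 0.5 * (k11 * pl$nodes[, 1]^2 + k22 * pl$nodes[, 2]^2) +
      k12 * pl$nodes[, 1] * pl$nodes[, 2]
    rx <- k22 * pl$nodes[, 2] + k12 * pl$nodes[, 1]
    ry <- -(k11 * pl$nodes[, 1] + k12 * pl$nodes[, 2])
    u <- as.vector(t(cbind(0, 0, w, rx, ry, 0)))
    E <- 0.5 * as.numeric(t(u) %*% (K %*% u))
    Ean <- pl$area / 2 * (Db[1, 1] * k11^2 + Db[2, 2] * k22^2 +
                            2 * Db[1, 2] * k11 * k22 + 4 * Db[3, 3] * k12^2)
    expect_equal(E, Ean, tolerance = 1e-8)
  }
})

test_that("degenerate elements are reported by element id", {
  mesh <- gv_mesh(gv_capsule(85, 300), target_edge = 12)
  bad <- mesh
  bad$nodes[bad$tris[5, 2], ] <- bad$nodes[bad$tris[5, 1], ]
  sec <- gv_section(gv_material())
  expect_error(
    gvbuckle:::cpp_shell_triplets(bad$nodes, bad$tris, sec$Cm, sec$Db,
                                  c(0, 0, 1), 1e-6),
    "degenerate")
})
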