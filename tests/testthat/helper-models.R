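# Shared fixtures, built once per test run and cached across test files.
.gv_test_cache <- new.env(parent = emptyenv())

cached <- function(key, expr) {
  if (!exists(key, envir = .gv_test_cache)) {
    assign(key, force(expr), envir = .gv_test_cache)
  }
  get(key, envir = .gv_test_cache)
}

# small baseline-shaped model for cheap unit tests
small_model <- function() {
  cached("small_model", gv_model(gv_mesh(gv_capsule(85, 300), target_edge = 12)))
}

# default-resolution baseline model (the reported-threshold geometry)
baseline_model <- function() {
  cached("baseline_model", gv_model(gv_mesh(gv_capsule(85, 500), target_edge = 5)))
}

baseline_lba <- function() {
  cached("baseline_lba", linear_buckling(baseline_model(), n_modes = 4))
}

baseline_modal <- function() {
  cached("baseline_modal", modal_frequencies(baseline_model(), n_modes = 4))
}

# reduced-resolution model used for explicit-dynamics work
dynamics_model <- function() {
  cached("dynamics_model", gv_model(gv_mesh(gv_capsule(85, 500), target_edge = 12)))
}

# full ramp + bisection threshold search on the reduced model (expensive;
# computed once and shared between the acceptance criteria that need it)
dynamics_threshold <- function() {
  cached("dynamics_threshold", find_threshold(dynamics_model(), duration = 1))
}

# diameter sweep at the default resolution and its power-law fit
diameter_sweep <- function() {
  cached("diameter_sweep", sweep_thresholds("diameter", 500))
}

diameter_fit <- function() {
  cached("diameter_fit", fit_power_law(diameter_sweep()))
}

# default synthetic population with thresholds from the real diameter fit
calibrated_population <- function(n = 20000, seed = 42) {
  key <- paste0("pop_", n, "_", seed)
  cached(key, {
    pop <- sample_population(n, seed = seed)
    pop <- assign_thresholds(pop, diameter_fit(), 1)
    ratio <- calibrate_collapse_ratio(pop)
    assign_thresholds(pop, diameter_fit(), ratio)
  })
}

# flat rectangular plate (open mesh) for element-level patch tests
flat_plate <- function(nx = 7, ny = 6, Lx = 8, Ly = 6) {
  xs <- seq(0, Lx, length.out = nx)
  ys <- seq(0, Ly, length.out = ny)
  g <- expand.grid(x = xs, y = ys)
  nodes <- cbind(g$x, g$y, 0)
  id <- function(i, j) (j - 1) * nx + i
  tris <- NULL
  for (j in 1:(ny - 1)) for (i in 1:(nx - 1)) {
    a <- id(i, j); b <- id(i + 1, j); c <- id(i, j + 1); d <- id(i + 1, j + 1)
    tris <- rbind(tris, c(a, b, d), c(a, d, c))
  }
  storage.mode(tris) <- "integer"
  list(nodes = nodes, tris = tris, area = Lx * Ly)
}

shell_K <- function(nodes, tris, section, axis = c(0, 0, 1), drill = 1e-6) {
  tm <- gvbuckle:::cpp_shell_triplets(nodes, tris, section$Cm, section$Db,
                                      axis, drill)
  ndof <- 6 * nrow(nodes)
  K <- Matrix::sparseMatrix(i = tm$i, j = tm$j, x = tm$x, dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}
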