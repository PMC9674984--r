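# Sparse symmetric eigenanalysis of the constrained shell system:
# linear buckling (K u = lambda (-Kg) u) and modal frequencies
# (K u = omega^2 M u), both through a sparse Cholesky factor of K and
# Lanczos iteration on the symmetrized operator.

chol_ops <- function(Kff) {
  ch <- Matrix::Cholesky(Kff, LDL = FALSE, perm = TRUE)
  list(
    ch = ch,
    # x = P' L^-T y  (maps Lanczos coordinates back to dof space)
    back = function(y) {
      z <- Matrix::solve(ch, y, system = "Lt")
      as.numeric(Matrix::solve(ch, z, system = "Pt"))
    },
    # y = L^-1 P x
    fwd = function(x) {
      z <- Matrix::solve(ch, x, system = "P")
      as.numeric(Matrix::solve(ch, z, system = "L"))
    },
    solveA = function(b) as.numeric(Matrix::solve(ch, b, system = "A"))
  )
}

#' Linear buckling analysis (LBA)
#'
#' Computes threshold buckling pressures and mode shapes of the constrained
#' shell under a unit external overpressure reference load. The membrane
#' prestress of the reference load enters a geometric stiffness `Kg`, and the
#' generalized symmetric eigenproblem `K u = lambda (-Kg) u` is solved by
#' Lanczos iteration on the Cholesky-symmetrized operator; the eigenvalues
#' `lambda` scale the reference overpressure to the threshold pressures.
#' Modes that would require internal (negative) overpressure are discarded.
#'
#' @param model A [gv_model()], or a [gv_mesh()] (a default material is bound).
#' @param n_modes Number of buckling modes requested (default 10).
#' @param reference_kpa Reference overpressure, kPa (default 1; thresholds
#'   are linear in it, so the default reports eigenvalues directly in kPa).
#' @param follower If `TRUE`, include the load-stiffness term of the
#'   follower (always-normal) pressure in the buckling pencil. The default
#'   `FALSE` treats the reference pressure as a dead load, the convention
#'   under which the reported thresholds of the average stripped vesicle are
#'   reproduced; the hydrostatic ring-buckling closed form
#'   `P = 2 E t^3 / ((1 - nu^2) D^3)` corresponds to `follower = TRUE`.
#' @return A `gv_buckling` object: tibble of `mode`, `pressure_kPa` with the
#'   mode shapes (columns of attribute `"modes"`, free-dof displacement
#'   fields expanded to full dof vectors, unit-normalized) and the model in
#'   attributes.
#' @examples
#' \donttest{
#' model <- gv_model(gv_mesh(gv_capsule(85, 500), target_edge = 8))
#' lba <- linear_buckling(model, n_modes = 4)
#' lba$pressure_kPa[1]
#' }
#' @export
linear_buckling <- function(model, n_modes = 10, reference_kpa = 1,
                            follower = FALSE) {
  if (inherits(model, "gv_mesh")) model <- gv_model(model)
  stopifnot(inherits(model, "gv_model"))
  pre <- solve_prestress(model, net_pressure_kpa = reference_kpa)
  K <- assemble_stiffness(model)
  Kg <- geometric_stiffness(model, pre)
  if (follower) Kg <- Kg + pressure_load_stiffness(model, reference_kpa)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Kff <- K[free, free]
  Kgff <- Kg[free, free]
  ops <- chol_ops(Kff)
  nfree <- length(free)
  Afun <- function(y, args) {
    x <- ops$back(y)
    w <- as.numeric(Kgff %*% x)
    -ops$fwd(w)
  }
  k <- min(n_modes + 4, nfree - 1)
  es <- RSpectra::eigs_sym(Afun, k = k, which = "LA", n = nfree,
                           opts = list(retvec = TRUE, tol = 1e-8))
  if (es$nconv < 1) stop("buckling eigen-solver did not converge")
  mu <- es$values
  pos <- which(mu > 1e-12)
  if (!length(pos)) stop("no positive buckling eigenvalue found")
  lambda <- 1 / mu[pos]
  ord <- order(lambda)
  lambda <- lambda[ord]
  take <- seq_len(min(n_modes, length(lambda)))
  lambda <- lambda[take]
  vecs <- es$vectors[, pos[ord][take], drop = FALSE]
  modes <- matrix(0, model$ndof, length(take))
  for (j in seq_along(take)) {
    u <- ops$back(vecs[, j])
    u <- u / sqrt(sum(u^2))
    modes[free, j] <- u
  }
  out <- tibble::tibble(mode = seq_along(lambda),
                        pressure_kPa = lambda * reference_kpa)
  attr(out, "modes") <- modes
  attr(out, "model") <- model
  attr(out, "reference_kpa") <- reference_kpa
  class(out) <- c("gv_buckling", class(out))
  out
}

#' Modal (natural frequency) analysis
#'
#' Solves `K u = omega^2 M u` on the constrained system with the lumped mass
#' and returns the lowest natural frequencies in MHz with M-orthonormal mode
#' shapes. The ultrasound drive used for buckling studies (11.4 MHz) sits far
#' below the lowest shell resonance, which is why the quasi-static buckling
#' picture applies.
#'
#' @param model A [gv_model()] (or a [gv_mesh()]).
#' @param n_modes Number of modes (default 4).
#' @return A `gv_modal` tibble with `mode`, `frequency_MHz`; mode shapes in
#'   attribute `"modes"`.
#' @export
modal_frequencies <- function(model, n_modes = 4) {
  if (inherits(model, "gv_mesh")) model <- gv_model(model)
  stopifnot(inherits(model, "gv_model"))
  K <- assemble_stiffness(model)
  free <- setdiff(seq_len(model$ndof), model$fixed_dofs)
  Kff <- K[free, free]
  mfull <- assemble_mass(model)
  msq <- sqrt(mfull[free])
  ops <- chol_ops(Kff)
  Afun <- function(y, args) msq * ops$solveA(msq * y)
  k <- min(n_modes + 4, length(free) - 1)
  es <- RSpectra::eigs_sym(Afun, k = k, which = "LA", n = length(free),
                           opts = list(retvec = TRUE, tol = 1e-8))
  if (es$nconv < 1) stop("modal eigen-solver did not converge")
  mu <- es$values
  keep <- which(mu > 0)
  om2 <- 1 / mu[keep]
  ord <- order(om2)
  take <- seq_len(min(n_modes, length(ord)))
  om2 <- om2[ord][take]
  freq <- sqrt(om2) / (2 * pi) # rad/us -> MHz
  vecs <- es$vectors[, keep[ord][take], drop = FALSE]
  modes <- matrix(0, model$ndof, length(take))
  for (j in seq_along(take)) {
    y <- vecs[, j]
    u <- y / msq # M-orthonormal displacement mode
    modes[free, j] <- u
  }
  out <- tibble::tibble(mode = seq_along(freq), frequency_MHz = freq)
  attr(out, "modes") <- modes
  attr(out, "model") <- model
  class(out) <- c("gv_modal", class(out))
  out
}

#' Export eigenmode shapes as VTK files
#'
#' Writes one legacy-VTK file per mode with the displacement field attached
#' as point vectors, for inspection in ParaView and the like.
#'
#' @param result A `gv_buckling` or `gv_modal` object.
#' @param path Directory to write into (created if missing).
#' @param prefix File-name prefix.
#' @return Invisibly, the written file paths.
#' @export
mode_export <- function(result, path, prefix = "mode") {
  model <- attr(result, "model")
  modes <- attr(result, "modes")
  if (is.null(model) || is.null(modes)) stop("result carries no mode shapes")
  if (!dir.exists(path)) dir.create(path, recursive = TRUE)
  files <- character(ncol(modes))
  for (j in seq_len(ncol(modes))) {
    u <- mode_displacement(model, modes[, j])
    files[j] <- file.path(path, sprintf("%s_%02d.vtk", prefix, j))
    write_vtk(model$mesh, files[j], point_vectors = list(displacement = u))
  }
  invisible(files)
}

# Circumferential wavenumber of a buckling/modal shape: dominant Fourier
# harmonic of the radial displacement sampled on the ring of nodes nearest
# the equator.

# Translational (u) part of a 6-dof mode vector, as an n x 3 matrix.
mode_displacement <- function(model, mode_vec) {
  um <- matrix(mode_vec, ncol = 6, byrow = TRUE)
  um[, 1:3, drop = FALSE]
}

mode_wavenumber <- function(result, mode = 1) {
  model <- attr(result, "model")
  modes <- attr(result, "modes")
  p <- model$mesh$nodes
  u <- mode_displacement(model, modes[, mode])
  zc <- abs(p[, 3])
  ring <- which(zc < min(zc) + 1e-6)
  if (length(ring) < 8) { # fall back to the widest ring of nodes
    ring <- which(abs(p[, 3] - median(p[, 3])) < model$mesh$edge_target / 2)
  }
  theta <- atan2(p[ring, 2], p[ring, 1])
  r_hat <- cbind(cos(theta), sin(theta))
  ur <- rowSums(u[ring, 1:2, drop = FALSE] * r_hat)
  ord <- order(theta)
  ur <- ur[ord]
  n <- length(ur)
  amp <- Mod(stats::fft(ur))[1:(n %/% 2)]
  which.max(amp[-1]) # skip the breathing (m = 0) term; index = wavenumber
}
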