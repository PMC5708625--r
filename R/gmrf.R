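#' Specification of the spatial GMRF random-field term
#'
#' The spatial engine represents a continuous Gaussian random field by a
#' Gaussian Markov random field on a regular lattice mesh aggregated from
#' the analysis grid. `mesh_cutoff` is the node spacing in degrees: smaller
#' cut-off, finer mesh, more flexible spatial term. The decay hyperparameter
#' `kappa` controls the effective correlation range (about `sqrt(8)/kappa`)
#' and `tau` the field precision; both are selected by empirical Bayes on a
#' log-scale grid unless fixed.
#'
#' @param mesh_cutoff Node spacing in degrees (default 4; conventional
#'   sweep range 0.5-8).
#' @param prior_sd_beta Gaussian prior sd for the fixed effects (default 10).
#' @param n_grid Hyperparameter grid resolution per axis (default 5).
#' @param grid_span Log-scale half-width of the grid: multipliers
#'   `exp(seq(-grid_span, grid_span, length.out = n_grid))` (default 2).
#' @param kappa_fixed,tau_fixed Optional fixed values; when both are given
#'   the grid search is skipped.
#' @param pc_range Penalised-complexity prior on the effective range:
#'   `c(rho0, p)` meaning `P(range < rho0) = p`. `rho0 = NA` (default)
#'   resolves at fit time to a fifth of the short landscape side. Set to
#'   `NULL` for a flat hyperprior (pure marginal-likelihood selection).
#' @param pc_sigma Penalised-complexity prior on the field standard
#'   deviation: `c(sigma0, p)` meaning `P(sd > sigma0) = p` (default
#'   `c(1, 0.05)`). `NULL` for flat. Without these penalties the marginal
#'   likelihood tends to run to landscape-scale, high-variance fields that
#'   are confounded with smooth covariates.
#' @return A list of class `gmrf_spec`.
#' @export
gmrf_spec <- function(mesh_cutoff = 4, prior_sd_beta = 10, n_grid = 5,
                      grid_span = 2, kappa_fixed = NULL, tau_fixed = NULL,
                      pc_range = c(NA, 0.5), pc_sigma = c(1, 0.05)) {
  if (!is.numeric(mesh_cutoff) || mesh_cutoff <= 0) {
    stop("`mesh_cutoff` must be > 0", call. = FALSE)
  }
  structure(list(mesh_cutoff = mesh_cutoff, prior_sd_beta = prior_sd_beta,
                 n_grid = as.integer(n_grid), grid_span = grid_span,
                 kappa_fixed = kappa_fixed, tau_fixed = tau_fixed,
                 pc_range = pc_range, pc_sigma = pc_sigma),
            class = "gmrf_spec")
}

# Log hyperprior density in (log range, log sd) coordinates: exponential
# PC-style penalties P(range < rho0) = p_r, P(sd > sigma0) = p_s.
log_hyper_prior <- function(kappa, tau, spec, rho0_default) {
  lp <- 0
  rho <- sqrt(8) / kappa
  sigma <- 1 / sqrt(4 * pi * kappa^2 * tau)
  if (!is.null(spec$pc_range)) {
    rho0 <- spec$pc_range[1]
    if (is.na(rho0)) rho0 <- rho0_default
    lam_r <- -log(spec$pc_range[2]) * rho0
    lp <- lp + log(lam_r) - log(rho) - lam_r / rho
  }
  if (!is.null(spec$pc_sigma)) {
    lam_s <- -log(spec$pc_sigma[2]) / spec$pc_sigma[1]
    lp <- lp + log(lam_s) + log(sigma) - lam_s * sigma
  }
  lp
}

# Regular lattice mesh covering the grid extent at roughly `cutoff` spacing.
build_mesh <- function(grid, cutoff) {
  ext <- grid_extent(grid)
  w <- ext["xmax"] - ext["xmin"]
  h <- ext["ymax"] - ext["ymin"]
  nx <- max(2L, as.integer(ceiling(w / cutoff)) + 1L)
  ny <- max(2L, as.integer(ceiling(h / cutoff)) + 1L)
  if (nx * ny < 4L) stop("mesh has fewer than 4 nodes", call. = FALSE)
  list(nx = nx, ny = ny,
       dx = as.numeric(w / (nx - 1)), dy = as.numeric(h / (ny - 1)),
       x0 = as.numeric(ext["xmin"]), y0 = as.numeric(ext["ymin"]),
       n_nodes = nx * ny)
}

# Lattice stiffness matrix (anisotropic 5-point stencil) and node areas.
mesh_matrices <- function(mesh) {
  nx <- mesh$nx; ny <- mesh$ny; m <- nx * ny
  idx <- function(i, j) (j - 1L) * nx + i
  ii <- integer(0); jj <- integer(0); wts <- numeric(0)
  # horizontal edges: conductance dy/dx; vertical: dx/dy
  i <- rep(seq_len(nx - 1L), times = ny)
  j <- rep(seq_len(ny), each = nx - 1L)
  ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i + 1L, j))
  wts <- c(wts, rep(mesh$dy / mesh$dx, length(i)))
  i <- rep(seq_len(nx), times = ny - 1L)
  j <- rep(seq_len(ny - 1L), each = nx)
  ii <- c(ii, idx(i, j)); jj <- c(jj, idx(i, j + 1L))
  wts <- c(wts, rep(mesh$dx / mesh$dy, length(i)))
  W <- Matrix::sparseMatrix(i = c(ii, jj), j = c(jj, ii), x = c(wts, wts),
                            dims = c(m, m))
  G <- Matrix::Diagonal(m, Matrix::rowSums(W)) - W
  C <- Matrix::Diagonal(m, mesh$dx * mesh$dy)
  list(G = G, C = C)
}

#' Build the sparse GMRF precision matrix on the mesh
#'
#' SPDE-style (smoothness order 2) lattice precision
#' `Q = tau * (kappa^4 C + 2 kappa^2 G + G C^{-1} G)` with `C` the diagonal
#' node-area matrix and `G` the lattice stiffness (graph Laplacian with
#' anisotropy-corrected edge conductances). `Q` is symmetric positive
#' definite and sparse.
#'
#' @param grid A [grid_spec()].
#' @param mesh_cutoff Node spacing in degrees.
#' @param kappa,tau Positive hyperparameters (spatial decay; precision
#'   scale).
#' @return A `dsCMatrix` sparse precision matrix with attribute `mesh`.
#' @export
build_gmrf_precision <- function(grid, mesh_cutoff, kappa, tau) {
  stopifnot(inherits(grid, "grid_spec"))
  if (kappa <= 0 || tau <= 0) {
    stop("`kappa` and `tau` must be > 0", call. = FALSE)
  }
  mesh <- build_mesh(grid, mesh_cutoff)
  mm <- mesh_matrices(mesh)
  Q <- tau * (kappa^4 * mm$C + 2 * kappa^2 * mm$G +
                mm$G %*% Matrix::solve(mm$C, mm$G))
  Q <- Matrix::forceSymmetric(Q)
  attr(Q, "mesh") <- mesh
  Q
}

# Sparse bilinear projector from mesh nodes to point locations (n x m).
mesh_projector <- function(mesh, x, y) {
  fx <- (x - mesh$x0) / mesh$dx
  fy <- (y - mesh$y0) / mesh$dy
  i0 <- pmin(pmax(floor(fx), 0), mesh$nx - 2L)
  j0 <- pmin(pmax(floor(fy), 0), mesh$ny - 2L)
  tx <- pmin(pmax(fx - i0, 0), 1)
  ty <- pmin(pmax(fy - j0, 0), 1)
  node <- function(i, j) (j) * mesh$nx + i + 1L
  n <- length(x)
  rows <- rep(seq_len(n), 4L)
  cols <- c(node(i0, j0), node(i0 + 1L, j0), node(i0, j0 + 1L),
            node(i0 + 1L, j0 + 1L))
  vals <- c((1 - tx) * (1 - ty), tx * (1 - ty), (1 - tx) * ty, tx * ty)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals,
                       dims = c(n, mesh$n_nodes))
}

# Draw one realisation of the mean-zero field with precision Q (dense chol;
# meshes here are small).
simulate_gmrf <- function(Q, rng_seed) {
  R <- chol(as.matrix(Q))
  z <- withr::with_seed(rng_seed, stats::rnorm(nrow(Q)))
  backsolve(R, z)
}
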