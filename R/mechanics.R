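#' Mechanical tissue parameters
#'
#' Tissue-specific linear-elastic constants and the two coupling constants
#' linking mechanics to the tumor model: `lambda1` (1/kPa) damps the cell
#' diffusion coefficient with von Mises stress, and `lambda2` (kPa) scales
#' the tumor-gradient body force in the equilibrium equation.
#'
#' @param G Named numeric vector of shear moduli (kPa) per tissue label;
#'   defaults to 2.1 (white), 2.6 (gray), 2.1 (other).
#' @param nu Named numeric vector of Poisson ratios per tissue label,
#'   strictly inside `(0, 0.5)`.
#' @param lambda1 Stress-diffusion coupling constant (1/kPa), default 0.25.
#' @param lambda2 Growth-forcing coupling constant (kPa), default 1.
#' @return An object of class `mechanical_params`.
#' @export
mechanical_params <- function(G = c(white = 2.1, gray = 2.6, other = 2.1),
                              nu = c(white = 0.45, gray = 0.45, other = 0.45),
                              lambda1 = 0.25, lambda2 = 1) {
  if (any(G <= 0)) stop("shear moduli must be positive")
  if (any(nu <= 0) || any(nu >= 0.5)) stop("Poisson ratios must lie in (0, 0.5)")
  if (lambda1 < 0) stop("lambda1 must be nonnegative")
  structure(list(G = G, nu = nu, lambda1 = lambda1, lambda2 = lambda2),
            class = "mechanical_params")
}

tissue_values <- function(par, grid) {
  lab <- grid$tissue_labels[grid$brain_mask]
  v <- par[lab]
  v[is.na(v)] <- par[["other"]]
  as.numeric(v)
}

# Precomputed neighbour bookkeeping restricted to the brain mask.
mask_topology <- function(grid) {
  dims <- grid_dims(grid)
  mask <- grid$brain_mask
  idx <- which(mask)
  id <- array(0L, dims)
  id[idx] <- seq_along(idx)
  nb <- vector("list", 3)
  for (axis in 1:3) {
    plus <- shift_index(dims, axis, 1L)[idx]
    minus <- shift_index(dims, axis, -1L)[idx]
    p <- ifelse(is.na(plus), 0L, id[pmax(plus, 1L)])
    m <- ifelse(is.na(minus), 0L, id[pmax(minus, 1L)])
    nb[[axis]] <- list(plus = p, minus = m)
  }
  list(idx = idx, id = id, nb = nb, n = length(idx), dims = dims,
       h = grid_spacings(grid))
}

# Central-difference operator along `axis` on mask voxels. Where a neighbour
# is outside the mask a ghost value of `ghost * f(p)` is used: ghost = 1
# mirrors the field (zero normal derivative), ghost = -1 reflects it through
# zero (zero boundary value), as required by the slip condition.
diff_operator <- function(topo, axis, ghost = 1) {
  n <- topo$n
  h2 <- 2 * topo$h[axis]
  p <- topo$nb[[axis]]$plus
  m <- topo$nb[[axis]]$minus
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  hasp <- p > 0L; hasm <- m > 0L
  rows <- c(which(hasp), which(hasm))
  cols <- c(p[hasp], m[hasm])
  vals <- c(rep(1 / h2, sum(hasp)), rep(-1 / h2, sum(hasm)))
  diagv <- numeric(n)
  diagv[!hasp] <- diagv[!hasp] + ghost / h2
  diagv[!hasm] <- diagv[!hasm] - ghost / h2
  rows <- c(rows, seq_len(n)); cols <- c(cols, seq_len(n)); vals <- c(vals, diagv)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

# Conservative variable-coefficient Laplacian sum_a d/dxa (G d/dxa) with
# harmonic face averaging; `ghost` is a length-3 vector of per-axis ghost
# signs for missing neighbours (1: zero flux, -1: antisymmetric, which adds
# -2 G f / h^2 on the diagonal).
lap_operator <- function(topo, Gv, ghost = c(1, 1, 1)) {
  n <- topo$n
  rows <- integer(0); cols <- integer(0); vals <- numeric(0)
  diagv <- numeric(n)
  for (axis in 1:3) {
    ih2 <- 1 / topo$h[axis]^2
    for (side in c("plus", "minus")) {
      nb <- topo$nb[[axis]][[side]]
      has <- nb > 0L
      Gf <- numeric(n)
      Gf[has] <- 2 * Gv[has] * Gv[nb[has]] / (Gv[has] + Gv[nb[has]])
      rows <- c(rows, which(has)); cols <- c(cols, nb[has]); vals <- c(vals, Gf[has] * ih2)
      diagv[has] <- diagv[has] - Gf[has] * ih2
      if (ghost[axis] == -1) diagv[!has] <- diagv[!has] - 2 * Gv[!has] * ih2
    }
  }
  rows <- c(rows, seq_len(n)); cols <- c(cols, seq_len(n)); vals <- c(vals, diagv)
  Matrix::sparseMatrix(i = rows, j = cols, x = vals, dims = c(n, n))
}

#' Assemble (and factorize) the elasticity operator
#'
#' Discretizes the quasi-static isotropic equilibrium equation
#' `div(G grad u) + grad(G/(1-2nu) div u) = lambda2 grad phi_T` on the brain
#' mask with a slip boundary condition (zero normal displacement, free
#' tangential motion) and returns the assembled sparse operator together with
#' its cached LU factorization, the gradient operators used for forcing and
#' strain evaluation, and index bookkeeping. The operator depends only on
#' grid, mask and tissue constants, so one factorization serves every solve
#' of a simulation or calibration run.
#'
#' @param grid A [grid3d()].
#' @param mech A [mechanical_params()].
#' @return An object of class `elasticity_operator`.
#' @export
elasticity_operator <- function(grid, mech) {
  topo <- mask_topology(grid)
  Gv <- tissue_values(mech$G, grid)
  nuv <- tissue_values(mech$nu, grid)
  beta <- Gv / (1 - 2 * nuv)
  n <- topo$n

  D_sym <- lapply(1:3, function(a) diff_operator(topo, a, ghost = 1))
  D_anti <- lapply(1:3, function(a) diff_operator(topo, a, ghost = -1))
  Bd <- Matrix::Diagonal(n, beta)

  blocks <- vector("list", 9)
  for (c in 1:3) for (d in 1:3) {
    ghost <- c(1, 1, 1); ghost[c] <- -1
    blk <- D_sym[[c]] %*% Bd %*% D_anti[[d]]
    if (c == d) blk <- blk + lap_operator(topo, Gv, ghost = ghost)
    blocks[[(c - 1) * 3 + d]] <- blk
  }
  A <- rbind(cbind(blocks[[1]], blocks[[2]], blocks[[3]]),
             cbind(blocks[[4]], blocks[[5]], blocks[[6]]),
             cbind(blocks[[7]], blocks[[8]], blocks[[9]]))
  A <- methods::as(A, "CsparseMatrix")
  # the assembled operator is symmetric negative definite; a permuted sparse
  # Cholesky of -A is far cheaper than an LU of A
  solve_fun <- tryCatch({
    ch <- Matrix::Cholesky(Matrix::forceSymmetric(-A), LDL = FALSE, perm = TRUE)
    function(b) -as.numeric(Matrix::solve(ch, b))
  }, error = function(e) {
    lu <- Matrix::lu(A)
    function(b) as.numeric(Matrix::solve(lu, b))
  })
  structure(list(A = A, solve_fun = solve_fun, topo = topo, D_sym = D_sym,
                 D_anti = D_anti, Gv = Gv, nuv = nuv, grid = grid, mech = mech),
            class = "elasticity_operator")
}

# one-slot cache: repeated calibrations / forecasts on the same grid and
# tissue constants reuse the factorized operator
.op_cache <- new.env(parent = emptyenv())

op_cache_key <- function(grid, mech) {
  paste(paste(grid_dims(grid), collapse = "x"),
        paste(grid_spacings(grid), collapse = "x"),
        sum(grid$brain_mask), sum(which(grid$brain_mask)),
        paste(mech$G, collapse = ","), paste(mech$nu, collapse = ","),
        sep = "|")
}

cached_elasticity_operator <- function(grid, mech) {
  key <- op_cache_key(grid, mech)
  if (!identical(.op_cache$key, key)) {
    .op_cache$key <- key
    .op_cache$op <- elasticity_operator(grid, mech)
  }
  .op_cache$op
}

#' Solve for quasi-static tissue displacement
#'
#' Solves the discrete linear-elastic equilibrium equation forced by the
#' gradient of the tumor volume fraction. The returned displacement field
#' satisfies zero normal displacement with free tangential slip on the
#' brain-mask boundary.
#'
#' @param phi_T Tumor volume-fraction field (3D array).
#' @param mech A [mechanical_params()].
#' @param grid A [grid3d()].
#' @param op Optional precomputed [elasticity_operator()] (reused across
#'   repeated solves).
#' @param tol Relative residual tolerance for the discrete solve.
#' @return List of class `displacement_field` with full-grid arrays
#'   `ux`, `uy`, `uz` (mm) and the operator used.
#' @export
solve_displacement <- function(phi_T, mech, grid, op = NULL, tol = 1e-8) {
  if (is.null(op)) op <- elasticity_operator(grid, mech)
  topo <- op$topo
  phi <- check_field(phi_T, grid, "phi_T")[topo$idx]
  b <- c(as.numeric(op$D_sym[[1]] %*% phi),
         as.numeric(op$D_sym[[2]] %*% phi),
         as.numeric(op$D_sym[[3]] %*% phi)) * mech$lambda2
  if (max(abs(b)) == 0) {
    u <- numeric(3 * topo$n)
  } else {
    u <- op$solve_fun(b)
    res <- sqrt(sum((as.numeric(op$A %*% u) - b)^2)) / sqrt(sum(b^2))
    if (!is.finite(res) || res > tol)
      stop(sprintf("elasticity solve did not converge: relative residual %.3g", res))
  }
  dims <- grid_dims(grid)
  out <- lapply(1:3, function(c) {
    f <- array(0, dims)
    f[topo$idx] <- u[((c - 1) * topo$n + 1):(c * topo$n)]
    f
  })
  structure(list(ux = out[[1]], uy = out[[2]], uz = out[[3]], op = op),
            class = "displacement_field")
}

#' Von Mises stress of a displacement field
#'
#' Evaluates the deviatoric part of the isotropic linear-elastic stress
#' tensor from central-difference strains of the displacement field and
#' returns its von Mises norm (kPa), a nonnegative scalar summary of shear
#' stress used to damp cell diffusion.
#'
#' @param u A `displacement_field` from [solve_displacement()].
#' @param mech A [mechanical_params()].
#' @param grid A [grid3d()].
#' @param op Optional precomputed [elasticity_operator()].
#' @return Nonnegative 3D array (kPa), zero outside the brain mask.
#' @export
von_mises <- function(u, mech, grid, op = NULL) {
  if (is.null(op)) op <- if (!is.null(u$op)) u$op else elasticity_operator(grid, mech)
  topo <- op$topo
  comp <- list(u$ux[topo$idx], u$uy[topo$idx], u$uz[topo$idx])
  # grad[[a]][[c]] = d u_c / d x_a with slip-consistent ghosts
  grad <- vector("list", 3)
  for (a in 1:3) {
    grad[[a]] <- vector("list", 3)
    for (c in 1:3) {
      D <- if (a == c) op$D_anti[[a]] else op$D_sym[[a]]
      grad[[a]][[c]] <- as.numeric(D %*% comp[[c]])
    }
  }
  Gv <- op$Gv
  lamL <- 2 * Gv * op$nuv / (1 - 2 * op$nuv)
  eps <- function(i, j) 0.5 * (grad[[i]][[j]] + grad[[j]][[i]])
  tr <- eps(1, 1) + eps(2, 2) + eps(3, 3)
  s2 <- 0
  for (i in 1:3) for (j in 1:3) {
    sig <- 2 * Gv * eps(i, j) + if (i == j) lamL * tr else 0
    dev <- sig - if (i == j) (2 * Gv + 3 * lamL) * tr / 3 else 0
    s2 <- s2 + dev^2
  }
  vm <- sqrt(pmax(1.5 * s2, 0))
  out <- array(0, grid_dims(grid))
  out[topo$idx] <- vm
  out
}

#' Stress-damped diffusion coefficient
#'
#' Damps a baseline diffusion coefficient exponentially with the local von
#' Mises stress: `D = D0 * exp(-lambda1 * sigma_vm)`. With `lambda1 = 0` the
#' field is identically `D0`; increasing stress strictly decreases it.
#'
#' @param D0 Baseline diffusion coefficient (mm^2/day), nonnegative scalar.
#' @param lambda1 Coupling constant (1/kPa).
#' @param sigma_vm Von Mises stress field (kPa).
#' @return Field with values in `(0, D0]`.
#' @export
damp_diffusion <- function(D0, lambda1, sigma_vm) {
  if (D0 < 0) stop("D0 must be nonnegative")
  D0 * exp(-lambda1 * sigma_vm)
}
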