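# P1 (linear triangle) finite-element primitives shared by all field solvers.
# Scalar operators are n x n with row i <-> node i; vector (displacement)
# operators are 2n x 2n with dofs [1..n] = x-components, [n+1..2n] = y.

#' @import Matrix
NULL

#' Precompute element geometry for assembly
#'
#' Computes, once per mesh, the constant P1 shape-function gradients, element
#' areas and diameters, and the triplet index vectors reused by every
#' assembly call.
#'
#' @param mesh a `wall_mesh`.
#' @return list with `G1`, `G2` (m x 3 gradient components), `areas`,
#'   `diam` (longest edge per element), `n_nodes`, and triplet indices.
#' @export
fem_precompute <- function(mesh) {
  tri <- mesh$triangles
  nd <- mesh$nodes
  x <- matrix(nd[tri, 1L], ncol = 3L)
  y <- matrix(nd[tri, 2L], ncol = 3L)
  A <- mesh$element_areas
  # grad phi_i = (y_j - y_k, x_k - x_j) / (2A), (i,j,k) cyclic
  G1 <- cbind(y[, 2L] - y[, 3L], y[, 3L] - y[, 1L], y[, 1L] - y[, 2L]) / (2 * A)
  G2 <- cbind(x[, 3L] - x[, 2L], x[, 1L] - x[, 3L], x[, 2L] - x[, 1L]) / (2 * A)
  e1 <- sqrt((x[, 2L] - x[, 1L])^2 + (y[, 2L] - y[, 1L])^2)
  e2 <- sqrt((x[, 3L] - x[, 2L])^2 + (y[, 3L] - y[, 2L])^2)
  e3 <- sqrt((x[, 1L] - x[, 3L])^2 + (y[, 1L] - y[, 3L])^2)
  idx <- rep(1:3, each = 3L)
  jdx <- rep(1:3, times = 3L)
  list(tri = tri, areas = A, G1 = G1, G2 = G2,
       diam = pmax(e1, e2, e3), n_nodes = nrow(nd),
       ii = as.vector(tri[, idx]), jj = as.vector(tri[, jdx]),
       idx = idx, jdx = jdx, memo = new.env(parent = emptyenv()))
}

fem_cache <- function(mesh) {
  if (is.null(mesh$fem)) fem_precompute(mesh) else mesh$fem
}

#' Attach precomputed FEM data to a mesh
#' @param mesh a `wall_mesh`.
#' @return the mesh with a `fem` field holding [fem_precompute()] output.
#' @export
fem_attach <- function(mesh) {
  mesh$fem <- fem_precompute(mesh)
  mesh
}

assemble_from_xx <- function(fem, xx) {
  sparseMatrix(i = fem$ii, j = fem$jj, x = as.vector(xx),
               dims = c(fem$n_nodes, fem$n_nodes))
}

#' Assemble a P1 mass matrix
#'
#' Consistent mass matrix with a constant or element-wise coefficient:
#' element contribution `coeff * A/12 * (1 + I)`.
#'
#' @param mesh a `wall_mesh` (optionally with [fem_attach()] data).
#' @param coefficient scalar or per-element vector, >= 0.
#' @return sparse symmetric n x n matrix (`dgCMatrix`).
#' @export
assemble_mass <- function(mesh, coefficient = 1) {
  fem <- fem_cache(mesh)
  if (any(coefficient < 0)) stop("mass coefficient must be non-negative")
  if (length(coefficient) == 1L) {
    # unit mass matrix is memoized per mesh; scaling is cheap
    if (is.null(fem$memo$M1)) {
      xx <- outer_elem(fem$areas / 12, ifelse(fem$idx == fem$jdx, 2, 1))
      fem$memo$M1 <- assemble_from_xx(fem, xx)
    }
    return(if (coefficient == 1) fem$memo$M1 else coefficient * fem$memo$M1)
  }
  cA <- coefficient * fem$areas / 12
  xx <- outer_elem(cA, ifelse(fem$idx == fem$jdx, 2, 1))
  assemble_from_xx(fem, xx)
}

# m-vector `a` times a length-9 pattern -> m x 9 matrix of triplet values
outer_elem <- function(a, pat) matrix(a, nrow = length(a), ncol = 9L) *
  matrix(pat, nrow = length(a), ncol = 9L, byrow = TRUE)

#' Assemble a P1 diffusion (stiffness) matrix
#'
#' `K[i,j] = sum_e A_e * grad(phi_i)' D grad(phi_j)`.  Symmetric positive
#' semi-definite with the constant field in its null space.
#'
#' @param mesh a `wall_mesh`.
#' @param diffusivity scalar, per-element vector, or symmetric 2 x 2 tensor.
#' @return sparse n x n matrix.
#' @export
assemble_diffusion <- function(mesh, diffusivity = 1) {
  fem <- fem_cache(mesh)
  if (!is.matrix(diffusivity) && length(diffusivity) == 1L) {
    if (is.null(fem$memo$K1)) fem$memo$K1 <- assemble_diffusion_raw(fem, 1)
    return(if (diffusivity == 1) fem$memo$K1 else diffusivity * fem$memo$K1)
  }
  assemble_diffusion_raw(fem, diffusivity)
}

assemble_diffusion_raw <- function(fem, diffusivity) {
  if (is.matrix(diffusivity)) {
    D <- diffusivity
    if (!isTRUE(all.equal(D, t(D))))
      stop("diffusivity tensor must be symmetric")
    dxx <- D[1L, 1L]; dyy <- D[2L, 2L]; dxy <- D[1L, 2L]
  } else {
    dxx <- dyy <- diffusivity; dxy <- 0
  }
  xx <- matrix(0, nrow(fem$G1), 9L)
  for (k in seq_len(9L)) {
    i <- fem$idx[k]; j <- fem$jdx[k]
    xx[, k] <- fem$areas *
      (dxx * fem$G1[, i] * fem$G1[, j] + dyy * fem$G2[, i] * fem$G2[, j] +
       dxy * (fem$G1[, i] * fem$G2[, j] + fem$G2[, i] * fem$G1[, j]))
  }
  assemble_from_xx(fem, xx)
}

#' Assemble SUPG-stabilized advection
#'
#' Conservative-form Galerkin advection (integrated by parts, consistent
#' with a zero-total-flux boundary) plus streamline-diffusion stabilization
#' `tau_e (v . grad phi_i)(v . grad phi_j)` with
#' `tau_e = h_e / (2|v_e|) * min(1, Pe_e / 3)`, `Pe_e = |v_e| h_e / (2 D)`
#' and `h_e` the element diameter; `tau_e = 0` where the velocity vanishes,
#' so the operator reduces to pure Galerkin (and to the zero matrix for a
#' globally zero velocity).
#'
#' @param mesh a `wall_mesh`.
#' @param velocity m x 2 matrix of element-wise velocities (cm/h).
#' @param diffusivity scalar physical diffusivity used in the element Peclet
#'   number.
#' @return sparse n x n matrix (nonsymmetric).
#' @export
assemble_advection_supg <- function(mesh, velocity, diffusivity) {
  fem <- fem_cache(mesh)
  v1 <- velocity[, 1L]; v2 <- velocity[, 2L]
  if (any(!is.finite(v1)) || any(!is.finite(v2)))
    stop("advection velocity must be finite on every element")
  vn <- sqrt(v1^2 + v2^2)
  pe <- ifelse(diffusivity > 0, vn * fem$diam / (2 * diffusivity), Inf)
  tau <- ifelse(vn > 0, fem$diam / (2 * vn) * pmin(1, pe / 3), 0)
  # vg[, i] = v . grad(phi_i), constant per element
  vg <- v1 * fem$G1 + v2 * fem$G2
  xx <- matrix(0, length(vn), 9L)
  for (k in seq_len(9L)) {
    i <- fem$idx[k]; j <- fem$jdx[k]
    xx[, k] <- -vg[, i] * fem$areas / 3 +          # -(u v, grad w)
      tau * fem$areas * vg[, i] * vg[, j]          # streamline diffusion
  }
  assemble_from_xx(fem, xx)
}

#' Assemble the vector elasticity operator
#'
#' Default form follows the displacement equation
#' `(lambda_s + mu_s) grad(div U) + mu_s lap U`, i.e.
#' `(lambda+mu) (div U, div W) + mu (grad U, grad W)`.
#' `form = "full_stress"` instead discretizes the divergence of the full
#' symmetric stress `lambda tr(eps) I + 2 mu eps(U)`; the two coincide for
#' smooth fields but differ at the discrete level.
#'
#' @param mesh a `wall_mesh`.
#' @param lambda_s,mu_s Lame parameters (any consistent pressure unit;
#'   internally mmHg).
#' @param form `"grad_div"` (default) or `"full_stress"`.
#' @return sparse symmetric 2n x 2n matrix.
#' @export
assemble_vector_elasticity <- function(mesh, lambda_s, mu_s,
                                       form = c("grad_div", "full_stress")) {
  form <- match.arg(form)
  if (!(mu_s > 0) || !(lambda_s + mu_s > 0))
    stop("non-physical moduli: require mu_s > 0 and lambda_s + mu_s > 0")
  fem <- fem_cache(mesh)
  n <- fem$n_nodes
  m <- nrow(fem$tri)
  # 6 local dofs per element: (ux1, ux2, ux3, uy1, uy2, uy3)
  gdof <- cbind(fem$tri, fem$tri + n)
  B1 <- cbind(fem$G1, matrix(0, m, 3L))   # d/dx of x-comp rows
  B2 <- cbind(matrix(0, m, 3L), fem$G2)   # d/dy of y-comp rows
  Bdiv <- B1 + B2
  Gx <- cbind(fem$G1, fem$G1)             # gradient pieces reused below
  Gy <- cbind(fem$G2, fem$G2)
  Bxy <- 0.5 * cbind(fem$G2, fem$G1)      # eps_xy row

  ii <- jj <- xx <- vector("list", 36L)
  k <- 0L
  for (a in seq_len(6L)) for (b in seq_len(6L)) {
    k <- k + 1L
    if (form == "grad_div") {
      val <- (lambda_s + mu_s) * Bdiv[, a] * Bdiv[, b]
      # (grad U, grad W): block-diagonal scalar stiffness per component
      same_comp <- (a <= 3L) == (b <= 3L)
      if (same_comp)
        val <- val + mu_s * (Gx[, a] * Gx[, b] + Gy[, a] * Gy[, b])
    } else {
      val <- lambda_s * Bdiv[, a] * Bdiv[, b] +
        2 * mu_s * (B1[, a] * B1[, b] + B2[, a] * B2[, b] +
                      2 * Bxy[, a] * Bxy[, b])
    }
    ii[[k]] <- gdof[, a]; jj[[k]] <- gdof[, b]; xx[[k]] <- val * fem$areas
  }
  sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
               dims = c(2L * n, 2L * n))
}

#' Apply Dirichlet constraints by symmetric elimination
#'
#' Moves the known values to the right-hand side, zeroes the constrained
#' rows and columns and places 1 on the diagonal, so the solution satisfies
#' the constraints exactly and a symmetric operator stays symmetric.
#'
#' @param op sparse operator matrix.
#' @param rhs right-hand-side vector.
#' @param dofs integer indices of constrained rows (for vector problems use
#'   dof indexing, x-components 1..n and y-components n+1..2n).
#' @param values prescribed values, recycled to `length(dofs)`.
#' @return list with elements `op` and `rhs`.
#' @export
apply_dirichlet <- function(op, rhs, dofs, values = 0) {
  if (length(dofs) == 0L) return(list(op = op, rhs = rhs))
  if (any(dofs < 1L) || any(dofs > nrow(op))) stop("constrained dofs out of range")
  values <- rep_len(values, length(dofs))
  if (anyDuplicated(dofs)) {
    agg <- tapply(values, dofs, function(v) diff(range(v)))
    if (any(agg > 0)) stop("conflicting duplicate Dirichlet prescriptions")
    keep <- !duplicated(dofs)
    dofs <- dofs[keep]; values <- values[keep]
  }
  full <- numeric(nrow(op)); full[dofs] <- values
  rhs <- rhs - as.vector(op %*% full)
  keepmask <- rep(TRUE, nrow(op)); keepmask[dofs] <- FALSE
  op[dofs, ] <- 0
  op[, dofs] <- 0
  op <- op + sparseMatrix(i = dofs, j = dofs, x = 1, dims = dim(op))
  rhs[dofs] <- values
  list(op = op, rhs = rhs)
}

#' Solve a sparse linear system
#'
#' Sparse direct solve: Cholesky for symmetric systems (falling back to LU
#' when the matrix is not positive definite), LU otherwise, with a residual
#' check `|A x - b| <= 1e-10 (|b| + 1)`.
#'
#' @param op sparse matrix.
#' @param rhs numeric vector.
#' @param name label used in error messages.
#' @return solution vector.
#' @export
solve_linear_system <- function(op, rhs, name = "operator") {
  symm <- isSymmetric(op, tol = 1e-12)
  x <- tryCatch({
    if (symm) solve(forceSymmetric(op), rhs) else solve(op, rhs)
  }, error = function(e) {
    if (symm) tryCatch(solve(as(op, "generalMatrix"), rhs),
                       error = function(e2) NULL)
    else NULL
  })
  if (is.null(x) || any(!is.finite(x)))
    stop(sprintf("singular or ill-posed linear system in %s", name))
  x <- as.vector(x)
  res <- sqrt(sum((as.vector(op %*% x) - rhs)^2))
  if (res > 1e-10 * (sqrt(sum(rhs^2)) + 1))
    stop(sprintf("linear solve for %s did not converge (residual %.3e)", name, res))
  x
}

# Lumped (row-sum) mass weights w_i = sum_e A_e/3 over elements touching
# node i; the nodal quadrature used for the time-derivative and reaction
# terms of the field steps (keeps them M-matrices, hence positivity).
lumped_mass_weights <- function(fem) {
  if (!is.null(fem$memo$wlump)) return(fem$memo$wlump)
  w <- numeric(fem$n_nodes)
  for (k in 1:3) {
    s <- rowsum(fem$areas / 3, fem$tri[, k])
    ix <- as.integer(rownames(s))
    w[ix] <- w[ix] + s[, 1L]
  }
  fem$memo$wlump <- w
  w
}

# Cached Cholesky factorization for SPD operators whose sparsity pattern is
# fixed across time steps (numeric-only refactorization via update()).
fem_factor_spd <- function(op) Cholesky(forceSymmetric(op), LDL = FALSE, perm = TRUE)
fem_refactor_spd <- function(fac, op) update(fac, forceSymmetric(op))
fem_solve_spd <- function(fac, rhs) as.vector(solve(fac, rhs, system = "A"))
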