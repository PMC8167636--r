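# Constant-strain tetrahedron (tet4) linear elasticity.
#
# Consistent mm-N-MPa unit system: coordinates in mm, forces in N, moduli and
# stresses in MPa (1 N/mm^2 = 1 MPa), displacements in mm. Three
# translational degrees of freedom per node; element stress is constant.

#' Isotropic linear-elastic material
#'
#' @param young_modulus_MPa Young's modulus E > 0 (MPa).
#' @param poisson_ratio Poisson's ratio in (0, 0.5).
#' @return object of class `material`.
#' @export
material <- function(young_modulus_MPa, poisson_ratio) {
  if (!is.numeric(young_modulus_MPa) || young_modulus_MPa <= 0)
    stop("Young's modulus must be positive")
  if (!is.numeric(poisson_ratio) || poisson_ratio <= 0 || poisson_ratio >= 0.5)
    stop("Poisson's ratio must lie in (0, 0.5)")
  structure(list(E = young_modulus_MPa, nu = poisson_ratio),
            class = "material")
}

#' Reference material set for the dentition model
#'
#' Isotropic homogeneous constants: tooth (dentin/enamel aggregate)
#' E = 20300 MPa, nu = 0.26; periodontal ligament E = 68.90 MPa, nu = 0.45;
#' splint PMMA E = 2200 MPa, nu = 0.35.
#'
#' @return named list of [material()] objects: `tooth`, `pdl`, `splint`.
#' @export
default_materials <- function() {
  list(tooth = material(20300, 0.26),
       pdl = material(68.90, 0.45),
       splint = material(2200, 0.35))
}

# Map region labels (FDI codes, pdl_*, splint) to a material list.
region_materials <- function(regions, materials) {
  out <- vector("list", length(regions))
  names(out) <- regions
  for (r in regions) {
    out[[r]] <- if (grepl("^pdl", r)) materials$pdl
    else if (r == "splint") materials$splint
    else if (grepl("^[34][1-7]$", r)) materials$tooth
    else materials[[r]]
    if (is.null(out[[r]])) stop("no material for region '", r, "'")
  }
  out
}

#' Isotropic elasticity matrix (Voigt notation)
#'
#' 6x6 matrix D relating stress (sxx, syy, szz, sxy, syz, szx) to engineering
#' strain.
#'
#' @param E Young's modulus (MPa).
#' @param nu Poisson's ratio.
#' @return 6x6 numeric matrix (MPa).
#' @export
elastic_D <- function(E, nu) {
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))
  D <- matrix(0, 6, 6)
  D[1:3, 1:3] <- lam
  diag(D)[1:3] <- lam + 2 * mu
  diag(D)[4:6] <- mu
  D
}

# Shape-function gradients of a tet4: 4 x 3 matrix; row a = grad N_a.
# Derived from the cross products of the edge vectors.
tet_gradients <- function(coords) {
  a <- coords[2, ] - coords[1, ]
  b <- coords[3, ] - coords[1, ]
  cc <- coords[4, ] - coords[1, ]
  cr <- function(u, v) c(u[2] * v[3] - u[3] * v[2],
                         u[3] * v[1] - u[1] * v[3],
                         u[1] * v[2] - u[2] * v[1])
  det <- sum(a * cr(b, cc))
  g2 <- cr(b, cc) / det
  g3 <- cr(cc, a) / det
  g4 <- cr(a, b) / det
  rbind(-(g2 + g3 + g4), g2, g3, g4)
}

#' Strain-displacement matrix of a tet4 element
#'
#' @param coords 4x3 matrix of node coordinates (mm).
#' @return 6x12 matrix B (constant over the element).
#' @export
tet_B <- function(coords) {
  g <- tet_gradients(coords)
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    cA <- 3 * (a - 1)
    B[1, cA + 1] <- g[a, 1]
    B[2, cA + 2] <- g[a, 2]
    B[3, cA + 3] <- g[a, 3]
    B[4, cA + 1] <- g[a, 2]; B[4, cA + 2] <- g[a, 1]
    B[5, cA + 2] <- g[a, 3]; B[5, cA + 3] <- g[a, 2]
    B[6, cA + 1] <- g[a, 3]; B[6, cA + 3] <- g[a, 1]
  }
  B
}

#' Element stiffness matrix of a constant-strain tetrahedron
#'
#' K_e = V B' D B with the isotropic D(E, nu); symmetric 12x12 with exactly
#' six rigid-body zero-energy modes.
#'
#' @param coords 4x3 matrix of node coordinates (mm).
#' @param mat a [material()].
#' @return 12x12 numeric matrix (N/mm).
#' @export
element_stiffness <- function(coords, mat) {
  a <- coords[2, ] - coords[1, ]
  b <- coords[3, ] - coords[1, ]
  cc <- coords[4, ] - coords[1, ]
  vol <- (a[1] * (b[2] * cc[3] - b[3] * cc[2]) -
            a[2] * (b[1] * cc[3] - b[3] * cc[1]) +
            a[3] * (b[1] * cc[2] - b[2] * cc[1])) / 6
  if (vol <= 0) stop("degenerate tetrahedron (non-positive volume)")
  B <- tet_B(coords)
  D <- elastic_D(mat$E, mat$nu)
  vol * t(B) %*% D %*% B
}

#' Assemble the global sparse stiffness matrix
#'
#' Vectorised tet4 assembly over all elements. Because adjacent regions share
#' nodes on the background grid, bonded (tied) contact is realised by node
#' sharing; no constraint equations are needed for conforming meshes.
#'
#' @param model a `dentition_model`.
#' @param materials either a named list of [material()] per region label, or
#'   a list with `tooth`/`pdl`/`splint` entries (see [default_materials()]).
#' @return sparse symmetric matrix (`Matrix::dgCMatrix`) of size
#'   `3 n_nodes x 3 n_nodes`.
#' @export
assemble <- function(model, materials = default_materials()) {
  regions <- unique(model$region)
  mats <- region_materials(regions, materials)
  E <- vapply(mats, function(m) m$E, 1)[model$region]
  nu <- vapply(mats, function(m) m$nu, 1)[model$region]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))

  p <- model$nodes; e <- model$elements
  m <- nrow(e)
  a <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  b <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cc <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n2 <- cr(b, cc); n3 <- cr(cc, a); n4 <- cr(a, b)
  det <- rowSums(a * n2)
  if (any(det <= 0)) stop("degenerate tetrahedron (non-positive volume)")
  vol <- det / 6
  # gradients g[[a]][, i]
  g <- list(-(n2 + n3 + n4) / det, n2 / det, n3 / det, n4 / det)

  ii <- vector("list", 144); jj <- vector("list", 144); xx <- vector("list", 144)
  idx <- 1L
  for (A in 1:4) for (Bn in 1:4) {
    dot_ab <- rowSums(g[[A]] * g[[Bn]])
    for (i in 1:3) for (j in 1:3) {
      val <- vol * (lam * g[[A]][, i] * g[[Bn]][, j] +
                      mu * g[[A]][, j] * g[[Bn]][, i] +
                      (if (i == j) mu * dot_ab else 0))
      ii[[idx]] <- 3L * (e[, A] - 1L) + i
      jj[[idx]] <- 3L * (e[, Bn] - 1L) + j
      xx[[idx]] <- val
      idx <- idx + 1L
    }
  }
  ndof <- 3L * nrow(p)
  K <- Matrix::sparseMatrix(i = unlist(ii), j = unlist(jj), x = unlist(xx),
                            dims = c(ndof, ndof))
  Matrix::forceSymmetric((K + Matrix::t(K)) / 2)
}

#' Construct a load case
#'
#' @param fixed_nodes integer node indices whose three translational DOFs are
#'   fixed (zero unless `fixed_values` given).
#' @param nodal_forces n x 3 matrix of nodal forces (N), or `NULL`.
#' @param fixed_values optional matrix (length(fixed_nodes) x 3) of
#'   prescribed displacements (mm) for the fixed nodes.
#' @param dof_constraints optional data frame with columns `node`, `dof`
#'   (1 = x, 2 = y, 3 = z), `value` for per-component Dirichlet conditions
#'   (used e.g. for symmetry rollers); combined with `fixed_nodes`.
#' @return object of class `load_case`.
#' @export
load_case <- function(fixed_nodes = integer(0), nodal_forces = NULL,
                      fixed_values = NULL, dof_constraints = NULL) {
  if (length(fixed_nodes) == 0 && is.null(dof_constraints))
    stop("load case needs at least one constrained node (singular system otherwise)")
  structure(list(fixed_nodes = as.integer(fixed_nodes),
                 nodal_forces = nodal_forces,
                 fixed_values = fixed_values,
                 dof_constraints = dof_constraints),
            class = "load_case")
}

#' Apply an evenly distributed occlusal load on a node set
#'
#' The total force is split equally between the nodes of the named set and
#' applied along the given direction (default vertical, -z).
#'
#' @param model a `dentition_model`.
#' @param set_name name of a node set (e.g. `"occlusal_36"`,
#'   `"occlusal_splint"`).
#' @param total_force_N total force magnitude (N).
#' @param direction unit 3-vector (normalised internally if close to unit).
#' @param forces optional existing n x 3 force matrix to add to.
#' @return n x 3 nodal force matrix.
#' @export
apply_occlusal_load <- function(model, set_name, total_force_N,
                                direction = c(0, 0, -1), forces = NULL) {
  set <- model$node_sets[[set_name]]
  if (is.null(set) || length(set) == 0)
    stop("empty or unknown node set: ", set_name)
  nrm <- sqrt(sum(direction^2))
  if (abs(nrm - 1) > 1e-6) {
    if (nrm == 0) stop("direction must be a nonzero vector")
    direction <- direction / nrm
  }
  if (is.null(forces)) forces <- matrix(0, nrow(model$nodes), 3)
  per <- total_force_N / length(set)
  forces[set, ] <- forces[set, , drop = FALSE] +
    matrix(per * direction, length(set), 3, byrow = TRUE)
  forces
}

#' Consistent nodal forces for a uniform traction on boundary faces
#'
#' Distributes a uniform traction over selected boundary faces with the
#' consistent tet4 lumping (one third of each face's force to each node),
#' which reproduces uniform stress states exactly.
#'
#' @param model a `dentition_model`.
#' @param face_select function taking the face-geometry list (`area`,
#'   `normal`, `centroid`) and returning a logical vector.
#' @param traction length-3 traction vector (MPa = N/mm^2).
#' @param region optional region label to restrict the boundary.
#' @param forces optional force matrix to add to.
#' @return n x 3 nodal force matrix.
#' @export
apply_face_traction <- function(model, face_select, traction, region = NULL,
                                forces = NULL) {
  el <- if (is.null(region)) seq_len(nrow(model$elements))
        else which(model$region == region)
  bf <- boundary_faces(model$elements[el, , drop = FALSE], nrow(model$nodes))
  fg <- face_geometry(model$nodes, bf$faces)
  sel <- which(face_select(fg))
  if (length(sel) == 0) stop("no boundary faces selected")
  if (is.null(forces)) forces <- matrix(0, nrow(model$nodes), 3)
  for (k in sel) {
    f <- fg$area[k] * traction / 3
    for (nd in bf$faces[k, ])
      forces[nd, ] <- forces[nd, ] + f
  }
  forces
}

#' Solve the constrained linear-elastic system
#'
#' Eliminates the Dirichlet DOFs, solves the reduced system by sparse
#' Cholesky (falling back to a Jacobi-preconditioned conjugate-gradient
#' iteration with relative tolerance 1e-10 if the factorisation fails),
#' verifies the relative residual, and recovers reactions at constrained
#' DOFs.
#'
#' @param K global sparse stiffness from [assemble()].
#' @param case a [load_case()].
#' @param model the `dentition_model` (for stress recovery and sizes).
#' @param materials materials used in assembly (for stress recovery).
#' @return object of class `fe_solution`: `displacements` (n x 3 mm),
#'   `element_stress` (m x 6 MPa, Voigt), `von_mises` (m, MPa), `reactions`
#'   (named rows for constrained DOFs, N), `residual` (relative), `applied`
#'   (copy of the force matrix).
#' @export
fe_solve <- function(K, case, model, materials = default_materials()) {
  n <- nrow(model$nodes)
  ndof <- 3L * n
  f <- if (is.null(case$nodal_forces)) matrix(0, n, 3) else case$nodal_forces
  fvec <- as.numeric(t(f))

  cdof <- integer(0); cval <- numeric(0)
  if (length(case$fixed_nodes) > 0) {
    base <- rep(3L * (case$fixed_nodes - 1L), each = 3) + 1:3
    vals <- if (is.null(case$fixed_values)) numeric(length(base))
            else as.numeric(t(case$fixed_values))
    cdof <- c(cdof, base); cval <- c(cval, vals)
  }
  if (!is.null(case$dof_constraints)) {
    cdof <- c(cdof, 3L * (case$dof_constraints$node - 1L) + case$dof_constraints$dof)
    cval <- c(cval, case$dof_constraints$value)
  }
  if (length(cdof) == 0)
    stop("singular system: no fixed nodes or DOF constraints given")
  dup <- !duplicated(cdof)
  cdof <- cdof[dup]; cval <- cval[dup]
  free <- setdiff(seq_len(ndof), cdof)

  Kff <- Matrix::forceSymmetric(K[free, free, drop = FALSE])
  Kfc <- K[free, cdof, drop = FALSE]
  rhs <- fvec[free] - as.numeric(Kfc %*% cval)

  uf <- tryCatch(
    as.numeric(Matrix::solve(Kff, rhs)),
    error = function(e) {
      if (grepl("not positive definite|singular|Cholmod", e$message, ignore.case = TRUE))
        pcg_solve(Kff, rhs, tol = 1e-10)
      else stop(e)
    })

  denom <- max(sqrt(sum(rhs^2)), .Machine$double.eps)
  residual <- sqrt(sum((as.numeric(Kff %*% uf) - rhs)^2)) / denom
  if (!is.finite(residual) || residual > 1e-8)
    stop(sprintf("solver failed: relative residual %.3g (singular or ill-conditioned system; check that the model is constrained)", residual))

  u <- numeric(ndof)
  u[free] <- uf
  u[cdof] <- cval
  umat <- matrix(u, ncol = 3, byrow = TRUE)

  # reactions at constrained DOFs
  r <- as.numeric(K[cdof, , drop = FALSE] %*% u) - fvec[cdof]
  reactions <- cbind(dof = cdof, reaction_N = r)

  st <- recover_stress(model, umat, materials)
  structure(list(displacements = umat,
                 element_stress = st$stress,
                 von_mises = st$von_mises,
                 reactions = reactions,
                 residual = residual,
                 applied = f),
            class = "fe_solution")
}

# Jacobi-preconditioned conjugate gradients (fallback solver).
pcg_solve <- function(A, b, tol = 1e-10, maxit = 20000L) {
  d <- Matrix::diag(A)   # diagonal of the sparse matrix
  if (any(d <= 0)) stop("singular system: non-positive diagonal in stiffness")
  x <- numeric(length(b))
  r <- b
  z <- r / d
  p <- z
  rz <- sum(r * z)
  nb <- sqrt(sum(b^2))
  for (it in seq_len(maxit)) {
    Ap <- as.numeric(A %*% p)
    alpha <- rz / sum(p * Ap)
    x <- x + alpha * p
    r <- r - alpha * Ap
    if (sqrt(sum(r^2)) <= tol * nb) return(x)
    z <- r / d
    rz_new <- sum(r * z)
    p <- z + (rz_new / rz) * p
    rz <- rz_new
  }
  stop("conjugate-gradient solver did not converge; system may be singular")
}

# Element stresses from nodal displacements (vectorised).
recover_stress <- function(model, umat, materials) {
  regions <- unique(model$region)
  mats <- region_materials(regions, materials)
  E <- vapply(mats, function(m) m$E, 1)[model$region]
  nu <- vapply(mats, function(m) m$nu, 1)[model$region]
  lam <- E * nu / ((1 + nu) * (1 - 2 * nu))
  mu <- E / (2 * (1 + nu))

  p <- model$nodes; e <- model$elements
  a <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  b <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cc <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cr <- function(u, v) cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
                             u[, 3] * v[, 1] - u[, 1] * v[, 3],
                             u[, 1] * v[, 2] - u[, 2] * v[, 1])
  n2 <- cr(b, cc); n3 <- cr(cc, a); n4 <- cr(a, b)
  det <- rowSums(a * n2)
  g <- list(-(n2 + n3 + n4) / det, n2 / det, n3 / det, n4 / det)

  eps <- matrix(0, nrow(e), 6)   # exx eyy ezz gxy gyz gzx
  for (A in 1:4) {
    uA <- umat[e[, A], , drop = FALSE]
    gA <- g[[A]]
    eps[, 1] <- eps[, 1] + gA[, 1] * uA[, 1]
    eps[, 2] <- eps[, 2] + gA[, 2] * uA[, 2]
    eps[, 3] <- eps[, 3] + gA[, 3] * uA[, 3]
    eps[, 4] <- eps[, 4] + gA[, 2] * uA[, 1] + gA[, 1] * uA[, 2]
    eps[, 5] <- eps[, 5] + gA[, 3] * uA[, 2] + gA[, 2] * uA[, 3]
    eps[, 6] <- eps[, 6] + gA[, 3] * uA[, 1] + gA[, 1] * uA[, 3]
  }
  tr <- eps[, 1] + eps[, 2] + eps[, 3]
  stress <- cbind(lam * tr + 2 * mu * eps[, 1],
                  lam * tr + 2 * mu * eps[, 2],
                  lam * tr + 2 * mu * eps[, 3],
                  mu * eps[, 4],
                  mu * eps[, 5],
                  mu * eps[, 6])
  colnames(stress) <- c("sxx", "syy", "szz", "sxy", "syz", "szx")
  list(stress = stress, von_mises = von_mises(stress))
}

#' Von Mises equivalent stress
#'
#' sqrt(0.5 [(sxx-syy)^2 + (syy-szz)^2 + (szz-sxx)^2] + 3 (sxy^2 + syz^2 + szx^2)).
#'
#' @param stress either a length-6 Voigt vector (sxx, syy, szz, sxy, syz,
#'   szx), an m x 6 matrix of such rows, or a 3x3 symmetric tensor.
#' @return von Mises stress (scalar or vector), MPa.
#' @export
von_mises <- function(stress) {
  if (is.matrix(stress) && all(dim(stress) == c(3, 3))) {
    stress <- c(stress[1, 1], stress[2, 2], stress[3, 3],
                stress[1, 2], stress[2, 3], stress[3, 1])
  }
  if (!is.matrix(stress)) stress <- matrix(stress, ncol = 6)
  sqrt(0.5 * ((stress[, 1] - stress[, 2])^2 +
                (stress[, 2] - stress[, 3])^2 +
                (stress[, 3] - stress[, 1])^2) +
         3 * (stress[, 4]^2 + stress[, 5]^2 + stress[, 6]^2))
}

#' @export
print.fe_solution <- function(x, ...) {
  cat(sprintf("FE solution: %d nodes, max |u| = %.4g mm, max von Mises = %.4g MPa, residual %.2e\n",
              nrow(x$displacements),
              max(sqrt(rowSums(x$displacements^2))),
              max(x$von_mises), x$residual))
  invisible(x)
}

#' Global equilibrium check
#'
#' Sum of reactions plus sum of applied forces, relative to the applied load
#' magnitude.
#'
#' @param solution an `fe_solution`.
#' @return relative equilibrium error (dimensionless).
#' @export
equilibrium_error <- function(solution) {
  applied <- colSums(solution$applied)
  dof <- ((solution$reactions[, "dof"] - 1) %% 3) + 1
  reac <- vapply(1:3, function(d)
    sum(solution$reactions[dof == d, "reaction_N"]), 1)
  tot <- sqrt(sum((applied + reac)^2))
  tot / max(sqrt(sum(applied^2)), .Machine$double.eps)
}
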