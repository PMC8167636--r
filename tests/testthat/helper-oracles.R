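# Independent reference implementations used to cross-check the package.
# These deliberately take different computational routes than the package
# (shape functions via a 4x4 linear solve instead of edge cross products;
# dense assembly and base::solve instead of sparse Cholesky; queue-based
# flood fill instead of label propagation).

# Elasticity matrix written out entry by entry (textbook form).
oracle_D <- function(E, nu) {
  f <- E / ((1 + nu) * (1 - 2 * nu))
  D <- matrix(0, 6, 6)
  D[1, 1] <- D[2, 2] <- D[3, 3] <- f * (1 - nu)
  D[1, 2] <- D[2, 1] <- D[1, 3] <- D[3, 1] <- D[2, 3] <- D[3, 2] <- f * nu
  D[4, 4] <- D[5, 5] <- D[6, 6] <- f * (1 - 2 * nu) / 2
  D
}

# Tet4 stiffness via the coefficient matrix of the linear shape functions:
# N_a(x) = alpha_a + beta_a x + gamma_a y + delta_a z, coefficients from
# solving C %*% coef = I with C = [1 | coords].
oracle_element_stiffness <- function(coords, E, nu) {
  C <- cbind(1, coords)
  vol <- det(C) / 6
  stopifnot(vol > 0)
  coef <- solve(C, diag(4))   # column a = coefficients of N_a
  B <- matrix(0, 6, 12)
  for (a in 1:4) {
    bx <- coef[2, a]; by <- coef[3, a]; bz <- coef[4, a]
    c0 <- 3 * (a - 1)
    B[1, c0 + 1] <- bx
    B[2, c0 + 2] <- by
    B[3, c0 + 3] <- bz
    B[4, c0 + 1] <- by; B[4, c0 + 2] <- bx
    B[5, c0 + 2] <- bz; B[5, c0 + 3] <- by
    B[6, c0 + 1] <- bz; B[6, c0 + 3] <- bx
  }
  vol * t(B) %*% oracle_D(E, nu) %*% B
}

# Dense global stiffness by an explicit element loop.
oracle_dense_stiffness <- function(model, materials) {
  n <- nrow(model$nodes)
  K <- matrix(0, 3 * n, 3 * n)
  for (k in seq_len(nrow(model$elements))) {
    en <- model$elements[k, ]
    reg <- model$region[k]
    mat <- if (grepl("^pdl", reg)) materials$pdl
           else if (reg == "splint") materials$splint
           else if (grepl("^[34][1-7]$", reg)) materials$tooth
           else materials[[reg]]
    Ke <- oracle_element_stiffness(model$nodes[en, ], mat$E, mat$nu)
    dofs <- as.vector(vapply(en, function(nd) 3L * (nd - 1L) + 1:3, integer(3)))
    K[dofs, dofs] <- K[dofs, dofs] + Ke
  }
  K
}

# Dense constrained solve with base::solve.
oracle_dense_solve <- function(model, materials, fixed_nodes, forces) {
  K <- oracle_dense_stiffness(model, materials)
  n <- nrow(model$nodes)
  fvec <- as.numeric(t(forces))
  cdof <- as.vector(vapply(as.integer(fixed_nodes), function(nd) 3L * (nd - 1L) + 1:3,
                           integer(3)))
  free <- setdiff(seq_len(3 * n), cdof)
  u <- numeric(3 * n)
  u[free] <- solve(K[free, free], fvec[free])
  matrix(u, ncol = 3, byrow = TRUE)
}

# Queue-based 26-connectivity flood fill on a 3-D binary mask.
oracle_flood_fill <- function(mask) {
  d <- dim(mask)
  lab <- array(0L, dim = d)
  cur <- 0L
  idx <- which(mask != 0)
  shifts <- as.matrix(expand.grid(-1:1, -1:1, -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, ]
  for (start in idx) {
    if (lab[start] != 0L) next
    cur <- cur + 1L
    queue <- start
    lab[start] <- cur
    while (length(queue) > 0) {
      v <- queue[length(queue)]
      queue <- queue[-length(queue)]
      k <- v - 1L
      x <- k %% d[1] + 1L
      y <- (k %/% d[1]) %% d[2] + 1L
      z <- k %/% (d[1] * d[2]) + 1L
      for (s in seq_len(nrow(shifts))) {
        nx <- x + shifts[s, 1]; ny <- y + shifts[s, 2]; nz <- z + shifts[s, 3]
        if (nx < 1 || ny < 1 || nz < 1 || nx > d[1] || ny > d[2] || nz > d[3]) next
        ni <- (nz - 1L) * d[1] * d[2] + (ny - 1L) * d[1] + nx
        if (mask[ni] != 0 && lab[ni] == 0L) {
          lab[ni] <- cur
          queue <- c(queue, ni)
        }
      }
    }
  }
  list(labels = lab, component_count = cur)
}

# Small fixed-geometry dentition specs used across tests.
toy_spec <- function(n = 2, seed = 1L) {
  dentition_spec(n_teeth = n, random_seed = seed)
}
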