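test_that("element stiffness is symmetric with six rigid-body modes", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness(co, material(1, 1e-9))
  expect_lt(max(abs(K - t(K))) / max(abs(K)), 1e-10)
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-9 * max(ev)), 6)
  for (dir in list(c(1, 0, 0), c(0, 1, 0), c(0, 0, 1), c(1, -2, 3))) {
    u <- rep(dir, 4)
    expect_lt(max(abs(K %*% u)), 1e-12 * max(abs(K)))
  }
  expect_error(element_stiffness(co[c(1, 2, 3, 3), ], material(1, 0.3)),
               "degenerate")
  # reversed orientation has negative volume
  expect_error(element_stiffness(co[c(1, 3, 2, 4), ], material(1, 0.3)),
               "degenerate")
})

test_that("element stiffness matches the independent shape-function oracle", {
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  K <- element_stiffness(co, material(1, 1e-9))
  Ko <- oracle_element_stiffness(co, 1, 1e-9)
  expect_equal(as.numeric(K), as.numeric(Ko), tolerance = 1e-12)
  set.seed(5)
  for (rep in 1:5) {
    co <- matrix(runif(12, -1, 1), 4, 3)
    if (det(cbind(1, co)) < 0.05) next   # skip near-degenerate draws
    E <- runif(1, 10, 30000); nu <- runif(1, 0.05, 0.45)
    expect_equal(as.numeric(element_stiffness(co, material(E, nu))),
                 as.numeric(oracle_element_stiffness(co, E, nu)),
                 tolerance = 1e-10)
  }
})

test_that("assembly matches the dense oracle and keeps rigid modes", {
  # single element: assembly equals the element matrix
  co <- rbind(c(0, 0, 0), c(1, 0, 0), c(0, 1, 0), c(0, 0, 1))
  one <- structure(list(nodes = co, elements = matrix(1:4, 1),
                        region = "part", node_sets = list(), cell_mm = 1),
                   class = "dentition_model")
  mats <- list(part = material(200, 0.3))
  expect_equal(as.matrix(assemble(one, mats)),
               unname(element_stiffness(co, mats$part)), tolerance = 1e-12)

  # two stacked cubes: 6 zero-energy modes before constraints
  m <- mesh_regions(list(a = box_solid(c(0, 0, 0), c(1, 1, 1)),
                         b = box_solid(c(0, 0, 1), c(1, 1, 2))), cell_mm = 1)
  mats2 <- list(a = material(100, 0.3), b = material(50, 0.2))
  K <- as.matrix(assemble(m, mats2))
  ev <- eigen(K, symmetric = TRUE, only.values = TRUE)$values
  expect_equal(sum(abs(ev) < 1e-8 * max(ev)), 6)

  # dense-oracle agreement on a 24-element mesh (matrix-vector products)
  m24 <- mesh_regions(list(bar = box_solid(c(0, 0, 0), c(2, 2, 1))), cell_mm = 1)
  expect_equal(nrow(m24$elements), 24)
  mats3 <- list(bar = material(2200, 0.35))
  Ks <- assemble(m24, mats3)
  Kd <- oracle_dense_stiffness(m24, mats3)
  set.seed(2)
  for (rep in 1:3) {
    x <- rnorm(ncol(Kd))
    expect_equal(as.numeric(Ks %*% x), as.numeric(Kd %*% x),
                 tolerance = 1e-10)
  }
  expect_error(assemble(m24, list(unrelated = material(1, 0.3))), "material")
})

test_that("occlusal loads are conserved and additive", {
  m <- mesh_dentition(toy_spec(n = 2))
  f <- apply_occlusal_load(m, "occlusal_31", 44.3)
  expect_equal(sum(f), -44.3, tolerance = 1e-12)
  set <- m$node_sets$occlusal_31
  expect_true(all(abs(f[set, 3] + 44.3 / length(set)) < 1e-12))
  f2 <- apply_occlusal_load(m, "occlusal_41", 10, forces = f)
  expect_equal(sum(f2), -54.3, tolerance = 1e-12)
  expect_error(apply_occlusal_load(m, "occlusal_99", 1), "unknown")
  expect_error(apply_occlusal_load(m, "occlusal_31", 1, direction = c(0, 0, 0)),
               "nonzero")
})

test_that("axial bar reproduces the closed-form elongation", {
  bar <- mesh_regions(list(bar = box_solid(c(0, 0, 0), c(10, 1, 1))),
                      cell_mm = 0.5)
  mats <- list(bar = material(2200, 0.35))   # PMMA constants
  K <- assemble(bar, mats)
  nd <- bar$nodes
  rollers <- rbind(
    data.frame(node = which(abs(nd[, 1]) < 1e-9), dof = 1, value = 0),
    data.frame(node = which(abs(nd[, 2]) < 1e-9), dof = 2, value = 0),
    data.frame(node = which(abs(nd[, 3]) < 1e-9), dof = 3, value = 0))
  f <- apply_face_traction(bar, function(fg)
    fg$centroid[, 1] > 10 - 1e-9 & fg$normal[, 1] > 0.99, traction = c(22, 0, 0))
  sol <- fe_solve(K, load_case(dof_constraints = rollers, nodal_forces = f),
                  bar, mats)
  tip <- sol$displacements[nd[, 1] > 10 - 1e-9, 1]
  expect_lt(max(abs(tip - 0.1)) / 0.1, 1e-6)   # delta = FL/EA
  expect_lt(sol$residual, 1e-8)
  expect_lt(equilibrium_error(sol), 1e-6)
  # uniform uniaxial stress state
  expect_equal(unname(range(sol$element_stress[, "sxx"])), c(22, 22),
               tolerance = 1e-9)
})

test_that("an irregular patch reproduces a prescribed linear field", {
  m <- mesh_regions(list(cube = box_solid(c(0, 0, 0), c(1, 1, 1))),
                    cell_mm = 0.5)
  interior <- which(apply(m$nodes, 1, function(p) all(p > 1e-9 & p < 1 - 1e-9)))
  expect_length(interior, 1)
  m$nodes[interior, ] <- m$nodes[interior, ] + c(0.07, -0.05, 0.04)
  expect_true(all(tet_volumes(m) > 0))
  A <- matrix(c(1e-3, 2e-4, -1e-4, 3e-4, -5e-4, 2e-4, 1e-4, 4e-4, 6e-4), 3, 3)
  ufield <- m$nodes %*% t(A)
  bnd <- setdiff(seq_len(nrow(m$nodes)), interior)
  mats <- list(cube = material(500, 0.3))
  sol <- fe_solve(assemble(m, mats),
                  load_case(fixed_nodes = bnd, fixed_values = ufield[bnd, ]),
                  m, mats)
  expect_lt(max(abs(sol$displacements - ufield)), 1e-8)
  # constant-strain elements: stress is spatially constant over the patch
  expect_lt(max(apply(sol$element_stress, 2, function(s) diff(range(s)))),
            1e-8)
})

test_that("solution scales linearly in load and inversely in stiffness", {
  m <- mesh_dentition(toy_spec(n = 1))
  mats <- default_materials()
  K <- assemble(m, mats)
  f <- apply_occlusal_load(m, names(m$node_sets)[1], 10)
  case <- load_case(fixed_nodes = m$node_sets$pdl_outer, nodal_forces = f)
  sol <- fe_solve(K, case, m, mats)
  sol2 <- fe_solve(K, load_case(fixed_nodes = m$node_sets$pdl_outer,
                                nodal_forces = 2 * f), m, mats)
  expect_equal(sol2$displacements, 2 * sol$displacements, tolerance = 1e-9)
  half <- list(tooth = material(mats$tooth$E / 2, mats$tooth$nu),
               pdl = material(mats$pdl$E / 2, mats$pdl$nu),
               splint = mats$splint)
  solh <- fe_solve(assemble(m, half), case, m, half)
  expect_equal(solh$displacements, 2 * sol$displacements, tolerance = 1e-9)
})

test_that("unconstrained systems are rejected with a clear error", {
  m <- mesh_regions(list(cube = box_solid(c(0, 0, 0), c(1, 1, 1))), cell_mm = 1)
  mats <- list(cube = material(100, 0.3))
  K <- assemble(m, mats)
  expect_error(load_case(fixed_nodes = integer(0)), "constrained node")
  f <- matrix(0, nrow(m$nodes), 3); f[8, 3] <- -1
  # constraints that still admit a rigid motion must fail at solve time
  cs <- data.frame(node = 1L, dof = 1L, value = 0)
  expect_error(fe_solve(K, load_case(dof_constraints = cs, nodal_forces = f),
                        m, mats), "singular|converge|residual")
})

test_that("sparse solution matches the dense oracle on a small mesh", {
  m <- mesh_regions(list(bar = box_solid(c(0, 0, 0), c(1, 1, 2))), cell_mm = 1)
  expect_lte(nrow(m$elements), 50)
  mats <- list(bar = material(300, 0.25))
  fixed <- which(abs(m$nodes[, 3]) < 1e-9)
  f <- matrix(0, nrow(m$nodes), 3)
  top <- which(abs(m$nodes[, 3] - 2) < 1e-9)
  f[top, ] <- matrix(c(0.3, -0.1, -1), length(top), 3, byrow = TRUE)
  sol <- fe_solve(assemble(m, mats), load_case(fixed_nodes = fixed,
                                               nodal_forces = f), m, mats)
  uo <- oracle_dense_solve(m, mats, fixed, f)
  expect_lt(max(abs(sol$displacements - uo)) / max(abs(uo)), 1e-9)
})

test_that("cantilever tip deflection converges monotonically with refinement", {
  L <- 20; E <- 2200; I <- 1 / 12; F <- 1
  euler <- F * L^3 / (3 * E * I)
  tips <- vapply(c(1, 0.5, 0.25), function(h) {
    m <- mesh_regions(list(bar = box_solid(c(0, 0, 0), c(L, 1, 1))), cell_mm = h)
    mats <- list(bar = material(E, 0.0001))
    fixed <- which(abs(m$nodes[, 1]) < 1e-9)
    f <- matrix(0, nrow(m$nodes), 3)
    tipn <- which(abs(m$nodes[, 1] - L) < 1e-9)
    f[tipn, 3] <- -F / length(tipn)
    sol <- fe_solve(assemble(m, mats),
                    load_case(fixed_nodes = fixed, nodal_forces = f), m, mats)
    max(abs(sol$displacements[tipn, 3]))
  }, 1)
  err <- abs(tips - euler) / euler
  expect_true(all(diff(err) < 0))   # strictly decreasing error
  expect_true(all(tips < euler))    # CST is overstiff, converges from below
})

test_that("von Mises closed forms and invariants hold", {
  expect_equal(von_mises(c(5, 0, 0, 0, 0, 0)), 5)
  expect_equal(von_mises(c(3, 3, 3, 0, 0, 0)), 0)
  expect_equal(von_mises(c(0, 0, 0, 1, 0, 0)), sqrt(3))
  # 3x3 tensor input agrees with Voigt input
  s <- matrix(c(2, 1, 0, 1, -1, 0.5, 0, 0.5, 3), 3, 3)
  expect_equal(von_mises(s), von_mises(c(2, -1, 3, 1, 0.5, 0)))
  set.seed(9)
  rnd <- matrix(rnorm(60), ncol = 6)
  expect_true(all(von_mises(rnd) >= 0))
  # pressure invariance: adding a hydrostatic state changes nothing
  p <- rnd; p[, 1:3] <- p[, 1:3] + 7
  expect_equal(von_mises(p), von_mises(rnd), tolerance = 1e-12)
})
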