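# Scenario tests run on toy dentitions (1-3 teeth) so each solve stays small.

test_that("scenario loads match the calibrated measurement totals", {
  spec <- toy_spec(n = 2)
  model1 <- mesh_dentition(spec, splint = FALSE)
  model3 <- mesh_dentition(spec, splint = TRUE)

  # the toy dentition only carries teeth 31 and 41; restrict the shares
  mk <- function(raw, shares) occlusal_measurement("toy", raw, shares)
  m1 <- mk(11873, c("31" = 60, "41" = 40))
  sc1 <- build_scenario(scenario_config(1, m1, spec), model = model1)
  expect_equal(sum(abs(sc1$case$nodal_forces[, 3])), raw_to_newton(11873),
               tolerance = 1e-9)
  # per-tooth load proportion: tooth 41 carries 40% of the total
  nd41 <- model1$node_sets$occlusal_41
  expect_equal(sum(-sc1$case$nodal_forces[nd41, 3]),
               0.40 * raw_to_newton(11873), tolerance = 1e-9)

  m3 <- mk(7801, c("31" = 50, "41" = 50))
  sc3 <- build_scenario(scenario_config(3, m3, spec), model = model3)
  expect_equal(sum(abs(sc3$case$nodal_forces[, 3])), raw_to_newton(7801),
               tolerance = 1e-9)
  # options 2/3 load the splint top only
  loaded <- which(rowSums(abs(sc3$case$nodal_forces)) > 0)
  expect_true(all(loaded %in% model3$node_sets$occlusal_splint))
  # a splint option demands a splint region
  expect_error(build_scenario(scenario_config(2, m3, spec), model = model1),
               "splint")
})

test_that("without a splint the teeth are mechanically independent", {
  spec <- toy_spec(n = 3)
  model <- mesh_dentition(spec, splint = FALSE)
  mats <- default_materials()
  K <- assemble(model, mats)
  fixed <- model$node_sets$pdl_outer
  teeth <- grep("^occlusal_[34]", names(model$node_sets), value = TRUE)
  # load one tooth: the others must not move at all
  f <- apply_occlusal_load(model, teeth[1], 30)
  sol <- fe_solve(K, load_case(fixed_nodes = fixed, nodal_forces = f),
                  model, mats)
  loaded_lbl <- sub("occlusal_", "", teeth[1])
  for (lbl in setdiff(sub("occlusal_", "", teeth), loaded_lbl)) {
    u <- sol$displacements[region_nodes(model, lbl), ]
    expect_lt(max(abs(u)), 1e-12)
  }
  # superposition: solving all teeth jointly equals per-tooth solves summed
  fall <- NULL
  for (tn in teeth) fall <- apply_occlusal_load(model, tn, 30, forces = fall)
  sol_joint <- fe_solve(K, load_case(fixed_nodes = fixed, nodal_forces = fall),
                        model, mats)
  u_sum <- 0
  for (tn in teeth) {
    fi <- apply_occlusal_load(model, tn, 30)
    u_sum <- u_sum + fe_solve(K, load_case(fixed_nodes = fixed,
                                           nodal_forces = fi),
                              model, mats)$displacements
  }
  expect_equal(sol_joint$displacements, u_sum, tolerance = 1e-9)
})

test_that("the splint couples teeth and redistributes load", {
  spec <- toy_spec(n = 2)
  model <- mesh_dentition(spec, splint = TRUE)
  mats <- default_materials()
  K <- assemble(model, mats)
  fixed <- model$node_sets$pdl_outer
  # load applied over tooth 31's occlusal nodes only
  f <- apply_occlusal_load(model, "occlusal_31", 30)
  sol <- fe_solve(K, load_case(fixed_nodes = fixed, nodal_forces = f),
                  model, mats)
  u41 <- sol$displacements[region_nodes(model, "41"), ]
  expect_gt(max(sqrt(rowSums(u41^2))), 1e-6)   # unloaded tooth moves
  s <- summarize_solution(sol, model)
  expect_gt(s$max_vm_MPa[s$region == "41"], 0)  # ... and carries stress
})

test_that("scenario runs are deterministic", {
  spec <- toy_spec(n = 2)
  meas <- occlusal_measurement("toy", 5000, c("31" = 55, "41" = 45))
  cfg <- scenario_config(1, meas, spec)
  r1 <- run_option(cfg)
  r2 <- run_option(cfg)
  expect_identical(r1$summary$max_disp_mm, r2$summary$max_disp_mm)
  expect_identical(r1$summary$max_vm_MPa, r2$summary$max_vm_MPa)
})

test_that("summaries report per-region maxima with invariances", {
  spec <- toy_spec(n = 2)
  model <- mesh_dentition(spec, splint = FALSE)
  mats <- default_materials()
  K <- assemble(model, mats)
  fixed <- model$node_sets$pdl_outer
  # zero load -> all maxima zero
  sol0 <- fe_solve(K, load_case(fixed_nodes = fixed), model, mats)
  s0 <- summarize_solution(sol0, model)
  expect_true(all(s0$max_disp_mm == 0))
  expect_true(all(s0$max_vm_MPa == 0))

  f <- apply_occlusal_load(model, "occlusal_31", 25)
  sol <- fe_solve(K, load_case(fixed_nodes = fixed, nodal_forces = f),
                  model, mats)
  s <- summarize_solution(sol, model)

  # permutation invariance: relabel the nodes and re-summarise
  set.seed(4)
  perm <- sample(nrow(model$nodes))
  inv <- integer(length(perm)); inv[perm] <- seq_along(perm)
  model2 <- model
  model2$nodes <- model$nodes[perm, ]
  model2$elements <- matrix(inv[model$elements], ncol = 4)
  model2$node_sets <- lapply(model$node_sets, function(s) sort(inv[s]))
  sol2 <- sol
  sol2$displacements <- sol$displacements[perm, ]
  s2 <- summarize_solution(sol2, model2)
  expect_equal(s$max_disp_mm, s2$max_disp_mm, tolerance = 1e-14)
  expect_equal(s$max_vm_MPa, s2$max_vm_MPa, tolerance = 1e-14)
})

test_that("under a muscle-vector load the tooth stress peaks at the root", {
  spec <- toy_spec(n = 2)
  model <- mesh_dentition(spec, splint = FALSE)
  mats <- default_materials()
  K <- assemble(model, mats)
  dir <- c(0.3, 0, -1); dir <- dir / sqrt(sum(dir^2))
  f <- apply_occlusal_load(model, "occlusal_31", 50, direction = dir)
  sol <- fe_solve(K, load_case(fixed_nodes = model$node_sets$pdl_outer,
                               nodal_forces = f), model, mats)
  s <- summarize_solution(sol, model)
  expect_equal(s$stress_location[s$region == "31"], "root_interface")
})

test_that("option comparisons form ratios with safe degenerate handling", {
  a <- data.frame(region = c("31", "41"), max_disp_mm = c(0.01, 0.002),
                  max_vm_MPa = c(2, 0.5), stress_location = "root_interface")
  expect_equal(compare_options(a, a)$disp_ratio, c(1, 1))
  b <- a; b$max_disp_mm <- 2 * a$max_disp_mm; b$max_vm_MPa <- 2 * a$max_vm_MPa
  cmp <- compare_options(a, b)
  expect_equal(cmp$disp_ratio, c(2, 2))
  expect_equal(cmp$vm_ratio, c(2, 2))
  # published periodontal maxima: 0.53 MPa (no splint) vs 1.25 MPa (ground splint)
  expect_equal(round_half_up(1.25 / 0.53, 2), 2.36)
  z <- a; z$max_vm_MPa <- c(0, 1)
  expect_true(is.na(compare_options(z, b)$vm_ratio[1]))
  bad <- a; bad$region <- c("31", "36")
  expect_error(compare_options(a, bad), "different region")
})

test_that("safety checks apply the published thresholds", {
  th <- safety_thresholds()
  sm <- data.frame(
    region = c("35", "pdl_35", "splint"),
    max_disp_mm = c(0.01, 0.002, 0.02),
    max_vm_MPa = c(10, 1.25, 2.70),
    stress_location = "root_interface")
  rep <- safety_check(sm, th)
  splint_row <- rep[rep$region == "splint", ]
  expect_true(splint_row$safe)
  expect_equal(splint_row$margin, 32.00 / 2.70, tolerance = 1e-12)
  pdl_row <- rep[rep$check == "pdl_stress", ]
  expect_true(pdl_row$safe)            # 1.25 MPa vs premolar limit 1.40 MPa
  expect_equal(pdl_row$threshold, 1.40)
  # boundary equality is conservative: exactly 0.03 mm is unsafe, margin 1
  sm2 <- sm; sm2$max_disp_mm[1] <- 0.03
  rep2 <- safety_check(sm2, th)
  mob <- rep2[rep2$check == "mobility", ]
  expect_false(mob$safe)
  expect_equal(mob$margin, 1)
  # monotone: scaling all observations down never flips safe -> unsafe
  sm3 <- sm; sm3$max_disp_mm <- sm$max_disp_mm / 2
  sm3$max_vm_MPa <- sm$max_vm_MPa / 2
  rep3 <- safety_check(sm3, th)
  expect_true(all(rep3$safe >= rep$safe))
  expect_error(safety_thresholds(mobility_limit_mm = -1), "positive")
})

test_that("tooth classes map FDI codes as in the threshold table", {
  expect_equal(tooth_class(c(31, 32, 33, 34, 35, 36, 37)),
               c("incisor", "incisor", "canine", "premolar", "premolar",
                 "molar", "molar"))
  expect_equal(tooth_class("45"), "premolar")
  expect_error(tooth_class(38), "unknown tooth class")
})
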