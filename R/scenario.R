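# Scenario assembly and post-processing for the three splint design options:
# option 1 - dentition without splint, per-tooth occlusal loads;
# option 2 - splint as manufactured, total load on the splint top;
# option 3 - splint after corrective grinding, total load on the splint top.
# Options 2 and 3 differ only in the occlusal measurement driving the load:
# the grinding is represented by the changed measured force distribution.

#' Scenario configuration
#'
#' @param option design option: 1 (no splint), 2 (splint as manufactured) or
#'   3 (splint after grinding).
#' @param measurement an [occlusal_measurement()]; conventionally measurement
#'   1 with option 1, measurement 2 with option 2, measurement 3 with
#'   option 3.
#' @param spec a [dentition_spec()].
#' @param direction load direction unit vector; default vertical `-z`. The
#'   direction is exposed so an oblique (muscle-vector) reading of the load
#'   can be run as well.
#' @return object of class `scenario_config`.
#' @export
scenario_config <- function(option, measurement, spec = dentition_spec(),
                            direction = c(0, 0, -1)) {
  if (!option %in% 1:3) stop("option must be 1, 2 or 3")
  stopifnot(inherits(measurement, "occlusal_measurement"),
            inherits(spec, "dentition_spec"))
  structure(list(option = as.integer(option),
                 measurement = measurement,
                 spec = spec,
                 direction = direction),
            class = "scenario_config")
}

#' Build the model and load case of a scenario
#'
#' Option 1 applies each tooth's calibrated force evenly over that tooth's
#' occlusal node set; options 2/3 include the splint region (bonded to the
#' crowns by the shared conforming mesh) and apply the calibrated total
#' evenly over the splint-top node set. All degrees of freedom are fixed on
#' the PDL outer surface (the interface towards the alveolar bone, which is
#' not modelled).
#'
#' @param config a [scenario_config()].
#' @param model optional pre-built `dentition_model` (must match the option's
#'   splint requirement); meshed from the spec when omitted.
#' @return list with `model` (a `dentition_model`), `case` (a [load_case()]),
#'   and `total_force_N`.
#' @export
build_scenario <- function(config, model = NULL) {
  stopifnot(inherits(config, "scenario_config"))
  needs_splint <- config$option %in% c(2, 3)
  if (is.null(model)) {
    model <- mesh_dentition(config$spec, splint = needs_splint)
  } else if (needs_splint && !"splint" %in% model$region) {
    stop("option ", config$option, " requires a splint region in the model")
  }
  total <- raw_to_newton(config$measurement$raw_sum)
  dist <- distribute_force(total, config$measurement)
  forces <- NULL
  if (config$option == 1) {
    for (t in names(dist$per_tooth_N)) {
      if (dist$per_tooth_N[[t]] == 0) next
      forces <- apply_occlusal_load(model, paste0("occlusal_", t),
                                    dist$per_tooth_N[[t]],
                                    direction = config$direction,
                                    forces = forces)
    }
  } else {
    forces <- apply_occlusal_load(model, "occlusal_splint", total,
                                  direction = config$direction)
  }
  case <- load_case(fixed_nodes = model$node_sets$pdl_outer,
                    nodal_forces = forces)
  list(model = model, case = case, total_force_N = total)
}

#' Run one design option end to end
#'
#' Meshes (or reuses) the model, assembles, solves, and reports basic run
#' statistics.
#'
#' @param config a [scenario_config()].
#' @param model optional pre-built model (see [build_scenario()]).
#' @param materials material set (default [default_materials()]).
#' @param verbose print a per-stage log line?
#' @return list with `model`, `solution` (an `fe_solution`), `summary`
#'   (see [summarize_solution()]), `total_force_N`, `option`.
#' @export
run_option <- function(config, model = NULL,
                       materials = default_materials(), verbose = FALSE) {
  sc <- build_scenario(config, model)
  if (verbose)
    message(sprintf("option %d: %d nodes, %d elements, total load %.1f N",
                    config$option, nrow(sc$model$nodes),
                    nrow(sc$model$elements), sc$total_force_N))
  K <- assemble(sc$model, materials)
  sol <- fe_solve(K, sc$case, sc$model, materials)
  if (verbose)
    message(sprintf("option %d: residual %.2e, max |u| %.4g mm",
                    config$option, sol$residual,
                    max(sqrt(rowSums(sol$displacements^2)))))
  list(model = sc$model, solution = sol,
       summary = summarize_solution(sol, sc$model),
       total_force_N = sc$total_force_N, option = config$option)
}

#' Per-region maxima of a solved scenario
#'
#' For every tooth, PDL shell and the splint: the maximum total displacement
#' (Euclidean norm of the nodal displacement) over the region's nodes and the
#' maximum von Mises stress over the region's (constant-stress) elements --
#' no nodal averaging, so maxima are element values. Each stress maximum is
#' also classified by location: `"root_interface"` if the peak element shares
#' a node with the tooth's PDL shell (the constrained root region),
#' `"crown_contact"` if it shares a node with the splint, otherwise
#' `"interior"`.
#'
#' @param solution an `fe_solution`.
#' @param model the matching `dentition_model`.
#' @return data frame with columns `region`, `max_disp_mm`, `max_vm_MPa`,
#'   `stress_location`.
#' @export
summarize_solution <- function(solution, model) {
  unorm <- sqrt(rowSums(solution$displacements^2))
  regions <- sort(unique(model$region))
  teeth <- regions[grepl("^[34][1-7]$", regions)]
  pdl_nodes_of <- function(t) {
    lbl <- paste0("pdl_", t)
    if (lbl %in% regions) region_nodes(model, lbl) else integer(0)
  }
  splint_nodes <- if ("splint" %in% regions) region_nodes(model, "splint") else integer(0)
  rows <- lapply(regions, function(r) {
    el <- which(model$region == r)
    nd <- sort(unique(as.vector(model$elements[el, , drop = FALSE])))
    vm <- solution$von_mises[el]
    kmax <- el[which.max(vm)]
    loc <- "interior"
    if (r %in% teeth) {
      pn <- pdl_nodes_of(r)
      if (any(model$elements[kmax, ] %in% pn)) loc <- "root_interface"
      else if (any(model$elements[kmax, ] %in% splint_nodes)) loc <- "crown_contact"
    }
    data.frame(region = r,
               max_disp_mm = max(unorm[nd]),
               max_vm_MPa = max(vm),
               stress_location = loc,
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Compare per-region maxima between two options
#'
#' @param summary_a,summary_b data frames from [summarize_solution()]; must
#'   cover the same regions.
#' @param names optional length-2 labels.
#' @return data frame with per-region ratios `b / a` for displacement and
#'   stress maxima; a zero denominator yields `NA` (undefined), not an error.
#' @export
compare_options <- function(summary_a, summary_b, names = c("a", "b")) {
  if (!setequal(summary_a$region, summary_b$region))
    stop("summaries cover different region sets")
  b <- summary_b[match(summary_a$region, summary_b$region), ]
  ratio <- function(num, den) ifelse(den == 0, NA_real_, num / den)
  data.frame(region = summary_a$region,
             disp_ratio = ratio(b$max_disp_mm, summary_a$max_disp_mm),
             vm_ratio = ratio(b$max_vm_MPa, summary_a$max_vm_MPa),
             stringsAsFactors = FALSE)
}

#' Physiological and material safety thresholds
#'
#' Defaults: physiological tooth mobility 0.03 mm; dentin ultimate tensile
#' strength 44.40-97.80 MPa (the conservative lower bound is the default
#' comparison value) and compressive strength 297.20 MPa; PDL allowable
#' stress by tooth class (incisors 1.50, canines 1.60, premolars 1.40,
#' molars 1.20 MPa -- lower bounds of the published per-class ranges); PMMA
#' minimum tensile fracture stress 32.00 MPa.
#'
#' @param mobility_limit_mm tooth displacement limit.
#' @param dentin_tensile_min_MPa,dentin_tensile_max_MPa,dentin_compressive_MPa
#'   dentin strength values.
#' @param pdl_limit_MPa named per-class PDL limits.
#' @param pmma_fracture_MPa splint material limit.
#' @return object of class `safety_thresholds`.
#' @export
safety_thresholds <- function(mobility_limit_mm = 0.03,
                              dentin_tensile_min_MPa = 44.40,
                              dentin_tensile_max_MPa = 97.80,
                              dentin_compressive_MPa = 297.20,
                              pdl_limit_MPa = c(incisor = 1.50, canine = 1.60,
                                                premolar = 1.40, molar = 1.20),
                              pmma_fracture_MPa = 32.00) {
  vals <- c(mobility_limit_mm, dentin_tensile_min_MPa, dentin_tensile_max_MPa,
            dentin_compressive_MPa, pdl_limit_MPa, pmma_fracture_MPa)
  if (any(vals <= 0)) stop("all thresholds must be positive")
  structure(list(mobility_limit_mm = mobility_limit_mm,
                 dentin_tensile_min_MPa = dentin_tensile_min_MPa,
                 dentin_tensile_max_MPa = dentin_tensile_max_MPa,
                 dentin_compressive_MPa = dentin_compressive_MPa,
                 pdl_limit_MPa = pdl_limit_MPa,
                 pmma_fracture_MPa = pmma_fracture_MPa),
            class = "safety_thresholds")
}

#' Safety checks of a scenario summary
#'
#' Compares each region's maxima against the thresholds: tooth displacement
#' vs physiological mobility; tooth von Mises vs the conservative dentin
#' tensile bound; PDL von Mises vs the class-specific limit; splint von Mises
#' vs the PMMA fracture stress. Verdicts use strict inequality: a value equal
#' to its threshold is reported unsafe (margin 1.0), a conservative
#' convention.
#'
#' @param summary data frame from [summarize_solution()].
#' @param thresholds a [safety_thresholds()].
#' @return data frame of class `safety_report`: `region`, `check`,
#'   `observed`, `threshold`, `margin` (threshold/observed), `safe`.
#' @export
safety_check <- function(summary, thresholds = safety_thresholds()) {
  rows <- list()
  add <- function(region, check, observed, threshold) {
    rows[[length(rows) + 1]] <<- data.frame(
      region = region, check = check, observed = observed,
      threshold = threshold,
      margin = ifelse(observed > 0, threshold / observed, Inf),
      safe = observed < threshold,
      stringsAsFactors = FALSE)
  }
  for (i in seq_len(nrow(summary))) {
    r <- summary$region[i]
    if (grepl("^[34][1-7]$", r)) {
      add(r, "mobility", summary$max_disp_mm[i], thresholds$mobility_limit_mm)
      add(r, "dentin_tensile", summary$max_vm_MPa[i],
          thresholds$dentin_tensile_min_MPa)
    } else if (grepl("^pdl_", r)) {
      cls <- tooth_class(sub("^pdl_", "", r))
      lim <- thresholds$pdl_limit_MPa[[cls]]
      if (is.null(lim)) stop("no PDL limit for tooth class ", cls)
      add(r, "pdl_stress", summary$max_vm_MPa[i], lim)
    } else if (r == "splint") {
      add(r, "pmma_fracture", summary$max_vm_MPa[i],
          thresholds$pmma_fracture_MPa)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("safety_report", class(out))
  out
}

#' @export
print.safety_report <- function(x, ...) {
  n_unsafe <- sum(!x$safe)
  cat(sprintf("Safety report: %d checks, %d unsafe\n", nrow(x), n_unsafe))
  print.data.frame(x, digits = 4, row.names = FALSE)
  invisible(x)
}
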