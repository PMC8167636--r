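# Voxel Hounsfield-unit phantom and threshold segmentation.
#
# The phantom emulates a cone-beam CT of the mandibular dentition: tooth
# voxels near enamel density (~3000 HU), a bone-like body under the gum line
# (150-1800 HU), everything else soft tissue (< 150 HU). It exists so the
# segmentation step can be exercised without patient DICOM data.

#' Generate a voxel Hounsfield phantom of a dentition
#'
#' Rasterises the dentition solids on a regular voxel grid and assigns
#' Hounsfield units per tissue: tooth interiors draw uniformly from
#' [2700, 3000] HU (enamel-like, always above the 1800 HU bone ceiling),
#' a bone-like band below the gum line draws from [150, 1800], and the
#' remainder is soft tissue below 150 HU. Deterministic for a fixed
#' `random_seed` in the spec.
#'
#' @param spec a [dentition_spec()].
#' @return an object of class `voxel_phantom` with fields `hu_values`
#'   (3-D array), `voxel_size_mm`, `origin_mm`.
#' @export
generate_phantom <- function(spec) {
  stopifnot(inherits(spec, "dentition_spec"))
  h <- spec$voxel_size_mm
  if (any(h <= 0)) stop("voxel size must be positive")
  teeth <- arch_teeth(spec)
  for (tt in teeth) {
    if (tooth_volume_analytic(tt) <= 0) stop("degenerate (zero-volume) tooth")
  }
  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
               lapply(teeth, function(t) t$bbox))
  margin <- 2
  lo <- bb[1, ] - margin; hi <- bb[2, ] + margin
  n <- ceiling((hi - lo) / h)
  xs <- lo[1] + (seq_len(n[1]) - 0.5) * h[1]
  ys <- lo[2] + (seq_len(n[2]) - 0.5) * h[2]
  zs <- lo[3] + (seq_len(n[3]) - 0.5) * h[3]
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))

  in_tooth <- rep(FALSE, nrow(pts))
  in_pdl <- rep(FALSE, nrow(pts))
  for (tt in teeth) {
    in_tooth <- in_tooth | tt$inside(pts)
    sh <- build_pdl_shell(tt, spec$pdl_thickness_mm)
    in_pdl <- in_pdl | sh$inside(pts)
  }
  # bone-like body: below the gum line, within the arch region, not tooth/PDL
  centers <- t(vapply(teeth, function(x) x$center, c(0, 0)))
  dmin <- rep(Inf, nrow(pts))
  for (i in seq_len(nrow(centers)))
    dmin <- pmin(dmin, sqrt((pts[, 1] - centers[i, 1])^2 +
                              (pts[, 2] - centers[i, 2])^2))
  in_bone <- pts[, 3] < 0 & dmin <= max(spec$crown_width_mm) + 2 &
    !in_tooth & !in_pdl

  old_seed <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(spec$random_seed)
  hu <- stats::runif(nrow(pts), min = -80, max = 140)      # soft tissue < 150
  hu[in_bone] <- stats::runif(sum(in_bone), 150, 1800)     # bone band
  hu[in_tooth] <- stats::runif(sum(in_tooth), 2700, 3000)  # enamel/dentin

  structure(list(hu_values = array(hu, dim = n),
                 voxel_size_mm = h,
                 origin_mm = lo),
            class = "voxel_phantom")
}

#' @export
print.voxel_phantom <- function(x, ...) {
  d <- dim(x$hu_values)
  cat(sprintf("Voxel phantom: %d x %d x %d voxels @ %.2f mm, HU range [%.0f, %.0f]\n",
              d[1], d[2], d[3], x$voxel_size_mm[1],
              min(x$hu_values), max(x$hu_values)))
  invisible(x)
}

#' Threshold segmentation of a voxel phantom
#'
#' Selects voxels with HU inside the window `[lo, hi]` and labels connected
#' components under 26-connectivity. The defaults mirror the raised tooth
#' window (1000-3000 HU) used to exclude soft tissue when segmenting
#' dentition CTs; note that trabecular/cortical bone (150-1800 HU) partially
#' overlaps that window, so isolating individual teeth in the presence of a
#' bone band requires a higher lower limit (e.g. 2000 HU).
#'
#' @param phantom a `voxel_phantom`.
#' @param lo,hi HU window bounds (lo < hi).
#' @return an object of class `segmentation_result` with `label_grid`
#'   (integer array, 0 = background), `component_count`, `hu_window`.
#' @export
segment_phantom <- function(phantom, lo = 1000, hi = 3000) {
  stopifnot(inherits(phantom, "voxel_phantom"))
  if (lo >= hi) stop("lo must be below hi")
  fg <- phantom$hu_values >= lo & phantom$hu_values <= hi
  lab <- label_components_3d(array(as.integer(fg), dim = dim(phantom$hu_values)))
  structure(list(label_grid = lab$labels,
                 component_count = lab$component_count,
                 hu_window = c(lo, hi)),
            class = "segmentation_result")
}

#' @export
print.segmentation_result <- function(x, ...) {
  cat(sprintf("Segmentation: window [%g, %g] HU, %d component(s), %d foreground voxel(s)\n",
              x$hu_window[1], x$hu_window[2], x$component_count,
              sum(x$label_grid > 0)))
  invisible(x)
}

#' Label connected components of a 3-D binary mask
#'
#' 26-connectivity labelling by iterative minimum-label propagation over the
#' 26 neighbour shifts until a fixed point, then relabelling to consecutive
#' integers 1..k. Fully vectorised; cost scales with mask size times the
#' largest component diameter.
#'
#' @param mask 3-D integer/logical array; nonzero = foreground.
#' @return list with `labels` (integer array, 0 background) and
#'   `component_count`.
#' @export
label_components_3d <- function(mask) {
  d <- dim(mask)
  if (length(d) != 3) stop("mask must be a 3-D array")
  fg <- mask != 0
  nfg <- sum(fg)
  if (nfg == 0)
    return(list(labels = array(0L, dim = d), component_count = 0L))
  lab <- array(0, dim = d)
  lab[fg] <- seq_len(nfg)
  shifts <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  shifts <- shifts[rowSums(abs(shifts)) > 0, , drop = FALSE]
  shift_arr <- function(a, s) {
    # shift array by s, padding with Inf (no label influence)
    out <- array(Inf, dim = d)
    src_x <- max(1, 1 - s[1]):min(d[1], d[1] - s[1])
    src_y <- max(1, 1 - s[2]):min(d[2], d[2] - s[2])
    src_z <- max(1, 1 - s[3]):min(d[3], d[3] - s[3])
    out[src_x + s[1], src_y + s[2], src_z + s[3]] <- a[src_x, src_y, src_z]
    out
  }
  work <- array(Inf, dim = d)
  work[fg] <- lab[fg]
  repeat {
    newmin <- work
    for (i in seq_len(nrow(shifts))) {
      sh <- shift_arr(work, shifts[i, ])
      newmin <- pmin(newmin, sh)
    }
    newmin[!fg] <- Inf
    if (all(newmin[fg] == work[fg])) break
    work <- newmin
  }
  labs <- work[fg]
  u <- sort(unique(labs))
  out <- array(0L, dim = d)
  out[fg] <- as.integer(match(labs, u))
  list(labels = out, component_count = length(u))
}
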