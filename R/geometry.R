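# Implicit-solid geometry for the synthetic dentition.
#
# Solids are lists with an `inside(pts)` predicate (pts: n x 3 matrix, mm)
# and an axis-aligned bounding box `bbox` (2 x 3: min row, max row).
# The z axis is the occlusal (vertical) direction; the gum line of every
# tooth sits at z = 0, crowns extend upward, roots downward.

#' Specification of a synthetic dentition
#'
#' Parameters of the parametric stand-in for a patient mandibular dentition:
#' tooth count and sizes, arch layout, periodontal-ligament (PDL) shell
#' thickness, splint thickness, and mesh edge-length targets. The default
#' geometry is a reduced-scale idealisation (small parametric teeth) sized so
#' the conforming background-grid mesh of the full 14-tooth arch stays around
#' 5e4 elements; the PDL thickness keeps its physiological 0.25 mm.
#'
#' @param n_teeth number of teeth (default 14, a full mandibular arch).
#' @param crown_height_mm crown height above the gum line.
#' @param root_length_mm root length below the gum line.
#' @param crown_width_mm named per-class crown widths (mm) for incisor,
#'   canine, premolar, molar.
#' @param cervical_ratio cervical (gum-line) radius as a fraction of the
#'   crown-top radius.
#' @param root_taper root tip radius as a fraction of the cervical radius.
#' @param gap_mm free gap between adjacent crowns along the arch.
#' @param pdl_thickness_mm PDL shell thickness (mm).
#' @param splint_thickness_mm occlusal splint thickness (mm).
#' @param splint_wall_frac fraction of the crown height embraced by the
#'   splint side walls.
#' @param max_edge_mm named per-region maximum tetrahedron edge lengths
#'   (tooth, pdl, splint); the shared background grid uses the smallest.
#' @param voxel_size_mm voxel pitch of the Hounsfield phantom.
#' @param random_seed seed for the phantom's HU noise.
#' @return an object of class `dentition_spec`.
#' @export
dentition_spec <- function(n_teeth = 14,
                           crown_height_mm = 2.2,
                           root_length_mm = 3.6,
                           crown_width_mm = c(incisor = 1.7, canine = 1.8,
                                              premolar = 1.9, molar = 2.2),
                           cervical_ratio = 0.8,
                           root_taper = 0.2,
                           gap_mm = 0.6,
                           pdl_thickness_mm = 0.25,
                           splint_thickness_mm = 0.5,
                           splint_wall_frac = 0.6,
                           max_edge_mm = c(tooth = 0.45, pdl = 0.45, splint = 0.45),
                           voxel_size_mm = c(0.20, 0.20, 0.20),
                           random_seed = 1L) {
  if (n_teeth < 1 || n_teeth > 14) stop("n_teeth must be in 1..14")
  lens <- c(crown_height_mm, root_length_mm, crown_width_mm, gap_mm,
            pdl_thickness_mm, splint_thickness_mm, max_edge_mm, voxel_size_mm)
  if (any(lens <= 0)) stop("all lengths must be positive")
  if (cervical_ratio <= 0 || cervical_ratio > 1) stop("cervical_ratio in (0,1]")
  if (root_taper <= 0 || root_taper >= 1) stop("root_taper in (0,1)")
  structure(list(n_teeth = as.integer(n_teeth),
                 crown_height_mm = crown_height_mm,
                 root_length_mm = root_length_mm,
                 crown_width_mm = crown_width_mm,
                 cervical_ratio = cervical_ratio,
                 root_taper = root_taper,
                 gap_mm = gap_mm,
                 pdl_thickness_mm = pdl_thickness_mm,
                 splint_thickness_mm = splint_thickness_mm,
                 splint_wall_frac = splint_wall_frac,
                 max_edge_mm = max_edge_mm,
                 voxel_size_mm = rep(voxel_size_mm, length.out = 3),
                 random_seed = as.integer(random_seed)),
            class = "dentition_spec")
}

#' @export
print.dentition_spec <- function(x, ...) {
  cat(sprintf("Dentition spec: %d teeth, crown %.1f mm / root %.1f mm, PDL %.2f mm, splint %.2f mm\n",
              x$n_teeth, x$crown_height_mm, x$root_length_mm,
              x$pdl_thickness_mm, x$splint_thickness_mm))
  invisible(x)
}

#' Tooth class from an FDI code
#'
#' Maps the position digit to the anatomical class: 1,2 incisor; 3 canine;
#' 4,5 premolar; 6,7 molar.
#'
#' @param fdi integer or character FDI code(s).
#' @return character vector of classes.
#' @export
tooth_class <- function(fdi) {
  pos <- as.integer(fdi) %% 10
  if (any(is.na(pos)) || any(pos < 1 | pos > 7)) stop("unknown tooth class for FDI code")
  c("incisor", "incisor", "canine", "premolar", "premolar",
    "molar", "molar")[pos]
}

#' Build a single parametric tooth solid
#'
#' Crown: conical frustum widening from the cervical radius at the gum line
#' (z = 0) to the full crown radius at the occlusal surface (z = crown
#' height). Root: tapered cone from the cervical radius down to a blunt tip.
#' The crown-top surface is the analytic disc z = crown height, which makes
#' occlusal node sets well defined.
#'
#' @param center_xy tooth axis position (x, y) in mm.
#' @param crown_height_mm,root_length_mm,crown_width_mm tooth dimensions.
#' @param cervical_ratio,root_taper shape ratios, see [dentition_spec()].
#' @param fdi optional FDI label carried along.
#' @return an implicit solid of class `tooth_solid`.
#' @export
tooth_solid <- function(center_xy, crown_height_mm, root_length_mm,
                        crown_width_mm, cervical_ratio = 0.8,
                        root_taper = 0.2, fdi = NA_integer_) {
  if (any(c(crown_height_mm, root_length_mm, crown_width_mm) <= 0))
    stop("tooth dimensions must be positive")
  r_crown <- crown_width_mm / 2
  r_cerv <- cervical_ratio * r_crown
  r_tip <- root_taper * r_cerv
  hc <- crown_height_mm; lr <- root_length_mm
  cx <- center_xy[1]; cy <- center_xy[2]
  radius_at <- function(z) {
    r <- rep(NA_real_, length(z))
    cr <- z >= 0 & z <= hc
    rt <- z >= -lr & z < 0
    r[cr] <- r_cerv + (r_crown - r_cerv) * z[cr] / hc
    r[rt] <- r_cerv + (r_cerv - r_tip) * z[rt] / lr
    r
  }
  inside <- function(pts) {
    z <- pts[, 3]
    rho <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    ok <- z >= -lr & z <= hc
    r <- radius_at(pmin(pmax(z, -lr), hc))
    ok & !is.na(r) & rho <= r
  }
  rmax <- max(r_crown, r_cerv)
  bbox <- rbind(c(cx - rmax, cy - rmax, -lr), c(cx + rmax, cy + rmax, hc))
  structure(list(inside = inside, bbox = bbox, kind = "tooth",
                 center = c(cx, cy), crown_height = hc, root_length = lr,
                 r_crown = r_crown, r_cerv = r_cerv, r_tip = r_tip,
                 radius_at = radius_at, fdi = as.integer(fdi)),
            class = c("tooth_solid", "implicit_solid"))
}

#' Build the periodontal-ligament shell of a tooth
#'
#' The shell is the set of points at outward distance (0, thickness] from the
#' root surface only (the crown is excluded: the shell spans z <= 0). The
#' lateral offset is corrected by the cosine of the root taper angle so the
#' normal distance to the cone surface never exceeds the thickness; below the
#' tip the exact distance to the tip disc is used.
#'
#' @param tooth a [tooth_solid()].
#' @param thickness_mm shell thickness (default 0.25 mm, the physiological
#'   PDL width).
#' @param neighbours optional list of other tooth solids; an error is raised
#'   if the shell would intersect any of them.
#' @return an implicit solid of class `pdl_shell`.
#' @export
build_pdl_shell <- function(tooth, thickness_mm = 0.25, neighbours = NULL) {
  stopifnot(inherits(tooth, "tooth_solid"))
  if (thickness_mm <= 0) stop("thickness must be positive")
  t <- thickness_mm
  lr <- tooth$root_length
  cos_a <- lr / sqrt(lr^2 + (tooth$r_cerv - tooth$r_tip)^2)
  cx <- tooth$center[1]; cy <- tooth$center[2]
  inside <- function(pts) {
    z <- pts[, 3]
    rho <- sqrt((pts[, 1] - cx)^2 + (pts[, 2] - cy)^2)
    out <- rep(FALSE, nrow(pts))
    lat <- z <= 0 & z >= -lr
    if (any(lat)) {
      d <- (rho[lat] - tooth$radius_at(z[lat])) * cos_a
      out[lat] <- d > 0 & d <= t
    }
    below <- z < -lr & z >= -lr - t
    if (any(below)) {
      dz <- -lr - z[below]
      dr <- pmax(rho[below] - tooth$r_tip, 0)
      out[below] <- sqrt(dz^2 + dr^2) <= t & sqrt(dz^2 + dr^2) > 0
    }
    out
  }
  rmax <- tooth$r_cerv + t / cos_a
  bbox <- rbind(c(cx - rmax, cy - rmax, -lr - t), c(cx + rmax, cy + rmax, 0))
  shell <- structure(list(inside = inside, bbox = bbox, kind = "pdl",
                          tooth = tooth, thickness = t),
                     class = c("pdl_shell", "implicit_solid"))
  if (!is.null(neighbours)) {
    pts <- sample_surface_points(shell, n_z = 24, n_theta = 32)
    for (nb in neighbours) {
      if (any(nb$inside(pts)))
        stop(sprintf("PDL shell of tooth %s intersects a neighbouring tooth; reduce thickness",
                     tooth$fdi))
    }
  }
  shell
}

# Sample points on/near the outer shell surface, used by intersection checks.
sample_surface_points <- function(shell, n_z = 16, n_theta = 24) {
  tooth <- shell$tooth
  zs <- seq(-tooth$root_length, 0, length.out = n_z)
  th <- seq(0, 2 * pi, length.out = n_theta + 1)[-1]
  grid <- expand.grid(z = zs, th = th)
  r <- tooth$radius_at(grid$z) + shell$thickness * 0.99
  cbind(tooth$center[1] + r * cos(grid$th),
        tooth$center[2] + r * sin(grid$th),
        grid$z)
}

#' Lay out the tooth solids of a dentition along the arch
#'
#' Teeth are placed on a semicircular arch (a simplified mandibular arch
#' form), spaced by half-widths plus a fixed free gap, spanning the full
#' semicircle. The 14-tooth layout runs 37..31, 41..47 from left to right;
#' smaller dentitions take the central subset of that sequence.
#'
#' @param spec a [dentition_spec()].
#' @return named list of `tooth_solid` objects, names = FDI codes.
#' @export
arch_teeth <- function(spec) {
  n <- spec$n_teeth
  # smaller dentitions take the n central teeth of the full sequence
  start <- (14 - n) %/% 2 + 1
  fdi <- FDI_MANDIBLE[start:(start + n - 1)]
  widths <- spec$crown_width_mm[tooth_class(fdi)]
  gaps <- spec$gap_mm
  s <- numeric(n)
  s[1] <- widths[1] / 2
  if (n > 1) for (i in 2:n) s[i] <- s[i - 1] + (widths[i - 1] + widths[i]) / 2 + gaps
  total <- s[n] + widths[n] / 2
  if (n == 1) {
    centers <- cbind(0, 0)
  } else {
    R <- total / pi
    theta <- pi - s / total * pi
    centers <- cbind(R * cos(theta), R * sin(theta))
  }
  teeth <- lapply(seq_len(n), function(i) {
    tooth_solid(centers[i, ], spec$crown_height_mm, spec$root_length_mm,
                widths[i], spec$cervical_ratio, spec$root_taper, fdi = fdi[i])
  })
  names(teeth) <- fdi
  teeth
}

#' Build the occlusal splint solid over a dentition
#'
#' The splint is a single connected solid: an occlusal slab of the given
#' thickness resting directly on the flat crown-top plane (zero gap), plus
#' side walls that embrace each crown by a radial offset of the same
#' thickness and fill the embrasures between adjacent crowns. The inner
#' surface coincides with the crown surfaces.
#'
#' @param teeth named list of [tooth_solid()] objects (>= 2 teeth).
#' @param thickness_mm splint thickness (mm).
#' @param wall_frac fraction of the crown height covered by the side walls.
#' @return an implicit solid of class `splint_solid`.
#' @export
build_splint_solid <- function(teeth, thickness_mm, wall_frac = 0.6) {
  if (length(teeth) < 2) stop("a splint needs at least 2 teeth")
  if (thickness_mm <= 0) stop("thickness must be positive")
  hc <- unique(vapply(teeth, function(t) t$crown_height, 1))
  if (length(hc) != 1) stop("splint requires a common crown-top plane")
  t <- thickness_mm
  centers <- t(vapply(teeth, function(x) x$center, c(0, 0)))
  halfwidth <- max(vapply(teeth, function(x) x$r_crown, 1))
  z_wall <- hc * (1 - wall_frac)
  dist_to_polyline <- function(pts) {
    d <- rep(Inf, nrow(pts))
    if (nrow(centers) == 1)
      return(sqrt((pts[, 1] - centers[1, 1])^2 + (pts[, 2] - centers[1, 2])^2))
    for (i in seq_len(nrow(centers) - 1)) {
      a <- centers[i, ]; b <- centers[i + 1, ]
      ab <- b - a
      len2 <- sum(ab^2)
      u <- pmin(pmax(((pts[, 1] - a[1]) * ab[1] + (pts[, 2] - a[2]) * ab[2]) / len2, 0), 1)
      px <- a[1] + u * ab[1]; py <- a[2] + u * ab[2]
      d <- pmin(d, sqrt((pts[, 1] - px)^2 + (pts[, 2] - py)^2))
    }
    d
  }
  inside <- function(pts) {
    z <- pts[, 3]
    in_any_tooth <- rep(FALSE, nrow(pts))
    min_excess <- rep(Inf, nrow(pts))
    crown_band <- z >= z_wall & z <= hc
    for (tt in teeth) {
      in_any_tooth <- in_any_tooth | tt$inside(pts)
      if (any(crown_band)) {
        rho <- sqrt((pts[, 1] - tt$center[1])^2 + (pts[, 2] - tt$center[2])^2)
        rc <- tt$radius_at(pmin(pmax(z, 0), hc))
        ex <- rho - rc
        min_excess[crown_band] <- pmin(min_excess[crown_band], ex[crown_band])
      }
    }
    dpoly <- dist_to_polyline(pts)
    slab <- z > hc & z <= hc + t & dpoly <= halfwidth + t
    walls <- crown_band & !in_any_tooth &
      (min_excess <= t | dpoly <= halfwidth)
    slab | walls
  }
  pad <- halfwidth + t
  bbox <- rbind(c(min(centers[, 1]) - pad, min(centers[, 2]) - pad, z_wall),
                c(max(centers[, 1]) + pad, max(centers[, 2]) + pad, hc + t))
  splint <- structure(list(inside = inside, bbox = bbox, kind = "splint",
                           thickness = t, crown_top = hc, z_wall = z_wall),
                      class = c("splint_solid", "implicit_solid"))
  if (!splint_connected(splint)) stop("splint solid is disconnected")
  splint
}

# Coarse voxel connectivity check (26-connectivity) for an implicit solid.
splint_connected <- function(solid, h = 0.3) {
  g <- voxelize_solid(solid, h)
  if (sum(g$mask) == 0) return(FALSE)
  lab <- label_components_3d(array(as.integer(g$mask), dim = g$dim))
  lab$component_count == 1
}

# Rasterise an implicit solid on a regular grid of pitch h (voxel centres).
voxelize_solid <- function(solid, h) {
  lo <- solid$bbox[1, ] - h; hi <- solid$bbox[2, ] + h
  n <- pmax(ceiling((hi - lo) / h), 1)
  xs <- lo[1] + (seq_len(n[1]) - 0.5) * h
  ys <- lo[2] + (seq_len(n[2]) - 0.5) * h
  zs <- lo[3] + (seq_len(n[3]) - 0.5) * h
  pts <- as.matrix(expand.grid(x = xs, y = ys, z = zs))
  mask <- solid$inside(pts)
  list(mask = mask, dim = n, origin = lo, h = h,
       centers = pts)
}

#' Volume of an implicit solid by voxel counting
#'
#' @param solid an implicit solid.
#' @param h voxel pitch in mm (default 0.1).
#' @return volume in mm^3.
#' @export
solid_volume <- function(solid, h = 0.1) {
  g <- voxelize_solid(solid, h)
  sum(g$mask) * h^3
}

#' Analytic volume of a parametric tooth
#'
#' Sum of the crown frustum and root frustum volumes,
#' V = pi h / 3 (r1^2 + r1 r2 + r2^2) for each part.
#'
#' @param tooth a [tooth_solid()].
#' @return volume in mm^3.
#' @export
tooth_volume_analytic <- function(tooth) {
  fr <- function(h, r1, r2) pi * h / 3 * (r1^2 + r1 * r2 + r2^2)
  fr(tooth$crown_height, tooth$r_cerv, tooth$r_crown) +
    fr(tooth$root_length, tooth$r_cerv, tooth$r_tip)
}

#' Assemble all solids of a dentition
#'
#' Builds the tooth solids on the arch, one PDL shell per tooth (checked
#' against neighbouring teeth), and optionally the splint.
#'
#' @param spec a [dentition_spec()].
#' @param splint logical; include the splint solid?
#' @return named list of implicit solids; names are FDI codes for teeth,
#'   `pdl_<FDI>` for shells, `"splint"` for the splint.
#' @export
build_dentition_solids <- function(spec, splint = FALSE) {
  teeth <- arch_teeth(spec)
  solids <- teeth
  for (nm in names(teeth)) {
    nb <- teeth[setdiff(names(teeth), nm)]
    solids[[paste0("pdl_", nm)]] <-
      build_pdl_shell(teeth[[nm]], spec$pdl_thickness_mm, neighbours = nb)
  }
  if (splint)
    solids[["splint"]] <- build_splint_solid(teeth, spec$splint_thickness_mm,
                                             spec$splint_wall_frac)
  solids
}

#' Axis-aligned box solid
#'
#' Convenience solid for benchmarks and tests.
#'
#' @param lo,hi numeric length-3 corner coordinates (mm).
#' @return an implicit solid.
#' @export
box_solid <- function(lo, hi) {
  if (any(hi <= lo)) stop("box must have positive extent")
  inside <- function(pts) {
    pts[, 1] >= lo[1] & pts[, 1] <= hi[1] &
      pts[, 2] >= lo[2] & pts[, 2] <= hi[2] &
      pts[, 3] >= lo[3] & pts[, 3] <= hi[3]
  }
  structure(list(inside = inside, bbox = rbind(lo, hi), kind = "box"),
            class = "implicit_solid")
}
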