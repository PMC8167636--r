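# Structured background-grid tetrahedralization.
#
# Every region is rasterised on ONE shared cubic grid; each grid cell whose
# centroid lies inside a region is split into the fixed 6-tetrahedron Kuhn
# pattern (all tets share the cell's main diagonal). Because all regions use
# the same grid and the same pattern, meshes of adjacent regions are
# node-conforming at their interfaces by construction, and bonded contact
# reduces to shared nodes. All tetrahedra have positive signed volume.

# Kuhn subdivision of the unit cube: the 6 permutation paths from corner
# (0,0,0) to (1,1,1). Corner indexing: 1 + ix + 2*iy + 4*iz.
# Node orderings below give positive signed volume.
KUHN_TETS <- matrix(c(
  1, 2, 4, 8,   # x, y, z
  1, 4, 3, 8,   # y, x, z
  1, 3, 7, 8,   # y, z, x
  1, 7, 5, 8,   # z, y, x
  1, 5, 6, 8,   # z, x, y
  1, 6, 2, 8    # x, z, y
), ncol = 4, byrow = TRUE)

#' Mesh implicit solids on a shared background grid
#'
#' @param solids named list of implicit solids; names are region labels
#'   (FDI codes for teeth, `pdl_<FDI>`, `"splint"`, or arbitrary labels).
#'   When several solids overlap, earlier entries take precedence.
#' @param max_edge maximum tetrahedron edge length, either a single value or
#'   a named vector per region; the grid cell size is
#'   `min(max_edge)/sqrt(3)` so that no edge (the cell diagonal being the
#'   longest) exceeds the smallest requested bound.
#' @param grid_origin optional length-3 origin of the grid; defaults to the
#'   joint bounding-box minimum.
#' @param cell_mm optional explicit cell size overriding `max_edge`.
#' @return an object of class `dentition_model`: `nodes` (n x 3 matrix, mm),
#'   `elements` (m x 4 integer matrix), `region` (character per element),
#'   `node_sets` (named list of integer vectors), `cell_mm`.
#' @export
mesh_regions <- function(solids, max_edge = 0.45, grid_origin = NULL,
                         cell_mm = NULL) {
  if (length(solids) == 0) stop("no solids to mesh")
  if (is.null(names(solids)) || any(names(solids) == ""))
    stop("solids must be a named list")
  if (any(max_edge <= 0)) stop("max_edge must be positive")
  h <- if (!is.null(cell_mm)) cell_mm else min(max_edge) / sqrt(3)

  bb <- Reduce(function(a, b) rbind(pmin(a[1, ], b[1, ]), pmax(a[2, ], b[2, ])),
               lapply(solids, function(s) s$bbox))
  lo <- if (is.null(grid_origin)) bb[1, ] else grid_origin
  n <- pmax(ceiling((bb[2, ] - lo) / h - 1e-9), 1L)

  # classify cell centroids; first matching solid wins
  nx <- n[1]; ny <- n[2]; nz <- n[3]
  region_id <- integer(nx * ny * nz)   # 0 = outside
  cell_ix <- rep(seq_len(nx), times = ny * nz)
  cell_iy <- rep(rep(seq_len(ny), each = nx), times = nz)
  cell_iz <- rep(seq_len(nz), each = nx * ny)
  cx <- lo[1] + (cell_ix - 0.5) * h
  cy <- lo[2] + (cell_iy - 0.5) * h
  cz <- lo[3] + (cell_iz - 0.5) * h
  for (si in seq_along(solids)) {
    s <- solids[[si]]
    cand <- which(region_id == 0L &
                    cx >= s$bbox[1, 1] - h & cx <= s$bbox[2, 1] + h &
                    cy >= s$bbox[1, 2] - h & cy <= s$bbox[2, 2] + h &
                    cz >= s$bbox[1, 3] - h & cz <= s$bbox[2, 3] + h)
    if (length(cand) == 0) next
    ins <- s$inside(cbind(cx[cand], cy[cand], cz[cand]))
    region_id[cand[ins]] <- si
  }
  keep <- which(region_id > 0L)
  if (length(keep) == 0) stop("all regions empty after meshing")
  for (si in seq_along(solids)) {
    if (!any(region_id == si))
      stop(sprintf("region '%s' is empty after meshing", names(solids)[si]))
  }

  # global vertex ids on the (nx+1)(ny+1)(nz+1) lattice
  vx <- nx + 1L; vy <- ny + 1L
  vid <- function(ix, iy, iz) (iz - 1L) * (vx * vy) + (iy - 1L) * vx + ix
  ix0 <- cell_ix[keep]; iy0 <- cell_iy[keep]; iz0 <- cell_iz[keep]
  corner <- matrix(0L, nrow = length(keep), ncol = 8)
  k <- 1L
  for (dz in 0:1) for (dy in 0:1) for (dx in 0:1) {
    corner[, 1L + dx + 2L * dy + 4L * dz] <- vid(ix0 + dx, iy0 + dy, iz0 + dz)
    k <- k + 1L
  }
  elements_global <- do.call(rbind, lapply(seq_len(6), function(tt)
    corner[, KUHN_TETS[tt, ], drop = FALSE]))
  region <- rep(names(solids)[region_id[keep]], times = 6)
  # interleave so the 6 tets of each cell are contiguous
  ord <- order(rep(seq_along(keep), times = 6))
  elements_global <- elements_global[ord, , drop = FALSE]
  region <- rep(names(solids)[region_id[keep]], each = 6)

  used <- sort(unique(as.vector(elements_global)))
  elements <- matrix(match(as.vector(elements_global), used),
                     nrow = nrow(elements_global))
  g_iz <- (used - 1L) %/% (vx * vy)
  rem <- (used - 1L) %% (vx * vy)
  g_iy <- rem %/% vx
  g_ix <- rem %% vx
  nodes <- cbind(lo[1] + g_ix * h, lo[2] + g_iy * h, lo[3] + g_iz * h)

  model <- structure(list(nodes = nodes,
                          elements = elements,
                          region = region,
                          node_sets = list(),
                          cell_mm = h,
                          max_edge = max_edge),
                     class = "dentition_model")
  model$node_sets <- build_node_sets(model, solids)
  model
}

#' @export
print.dentition_model <- function(x, ...) {
  cat(sprintf("Dentition model: %d nodes, %d tet4 elements, %d region(s), cell %.3f mm\n",
              nrow(x$nodes), nrow(x$elements), length(unique(x$region)),
              x$cell_mm))
  cat("  regions:", paste(sort(unique(x$region)), collapse = ", "), "\n")
  cat("  node sets:", paste(names(x$node_sets), collapse = ", "), "\n")
  invisible(x)
}

#' Signed volumes of the tetrahedra of a model
#'
#' @param model a `dentition_model`.
#' @return numeric vector of signed volumes (mm^3); positive under the
#'   package's node-ordering convention.
#' @export
tet_volumes <- function(model) {
  p <- model$nodes; e <- model$elements
  a <- p[e[, 2], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  b <- p[e[, 3], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  cc <- p[e[, 4], , drop = FALSE] - p[e[, 1], , drop = FALSE]
  (a[, 1] * (b[, 2] * cc[, 3] - b[, 3] * cc[, 2]) -
     a[, 2] * (b[, 1] * cc[, 3] - b[, 3] * cc[, 1]) +
     a[, 3] * (b[, 1] * cc[, 2] - b[, 2] * cc[, 1])) / 6
}

# The 4 faces of a tet, each opposite one node, oriented outward for a
# positively oriented tet.
TET_FACES <- matrix(c(2, 3, 4,
                      1, 4, 3,
                      1, 2, 4,
                      1, 3, 2), ncol = 3, byrow = TRUE)

# All 4m faces of m elements with owner element indices and an
# orientation-independent numeric key per face (sorted node triple packed
# into a double; exact for meshes below ~2e5 nodes).
collect_faces <- function(elements, n_nodes = max(elements)) {
  m <- nrow(elements)
  faces <- matrix(0L, nrow = 4 * m, ncol = 3)
  owner <- integer(4 * m)
  for (f in 1:4) {
    idx <- seq(f, by = 4, length.out = m)
    faces[idx, ] <- elements[, TET_FACES[f, ], drop = FALSE]
    owner[idx] <- seq_len(m)
  }
  a <- faces[, 1]; b <- faces[, 2]; cc <- faces[, 3]
  lo <- pmin(a, b, cc); hi <- pmax(a, b, cc)
  mid <- a + b + cc - lo - hi
  nn <- as.numeric(n_nodes) + 1
  key <- (as.numeric(lo) * nn + mid) * nn + hi
  list(faces = faces, owner = owner, key = key)
}

# Boundary faces of a set of elements: faces whose sorted key appears once.
boundary_faces <- function(elements, n_nodes = max(elements)) {
  cf <- collect_faces(elements, n_nodes)
  # interior faces appear exactly twice, boundary faces once
  sel <- !(duplicated(cf$key) | duplicated(cf$key, fromLast = TRUE))
  list(faces = cf$faces[sel, , drop = FALSE], owner = cf$owner[sel],
       key = cf$key[sel])
}

# Geometry of oriented triangular faces: area, unit normal, centroid.
face_geometry <- function(nodes, faces) {
  a <- nodes[faces[, 1], , drop = FALSE]
  b <- nodes[faces[, 2], , drop = FALSE]
  cc <- nodes[faces[, 3], , drop = FALSE]
  u <- b - a; v <- cc - a
  nrm <- cbind(u[, 2] * v[, 3] - u[, 3] * v[, 2],
               u[, 3] * v[, 1] - u[, 1] * v[, 3],
               u[, 1] * v[, 2] - u[, 2] * v[, 1])
  area2 <- sqrt(rowSums(nrm^2))
  list(area = area2 / 2,
       normal = nrm / pmax(area2, .Machine$double.eps),
       centroid = (a + b + cc) / 3)
}

# Build the named node sets from the meshed regions and the analytic solids.
build_node_sets <- function(model, solids) {
  sets <- list()
  regions <- unique(model$region)
  teeth_labels <- regions[grepl("^[34][1-7]$", regions)]
  has_splint <- "splint" %in% regions
  cos30 <- cos(pi / 6)
  h <- model$cell_mm
  nn <- nrow(model$nodes)

  all_bf <- boundary_faces(model$elements, nn)   # global mesh boundary
  global_keys <- all_bf$key

  region_elements <- function(lbl) which(model$region == lbl)

  for (lbl in teeth_labels) {
    el <- region_elements(lbl)
    bf <- boundary_faces(model$elements[el, , drop = FALSE], nn)
    fg <- face_geometry(model$nodes, bf$faces)
    hc <- solids[[lbl]]$crown_height
    occl <- fg$normal[, 3] > cos30 & fg$centroid[, 3] > hc - 2 * h
    sets[[paste0("occlusal_", lbl)]] <-
      sort(unique(as.vector(bf$faces[occl, , drop = FALSE])))
    crown <- fg$centroid[, 3] > 0 & !occl
    sets[[paste0("crown_outer_", lbl)]] <-
      sort(unique(as.vector(bf$faces[crown, , drop = FALSE])))
  }

  pdl_labels <- regions[grepl("^pdl_", regions)]
  pdl_outer <- integer(0)
  for (lbl in pdl_labels) {
    el <- region_elements(lbl)
    bf <- boundary_faces(model$elements[el, , drop = FALSE], nn)
    on_global <- bf$key %in% global_keys
    pdl_outer <- c(pdl_outer, as.vector(bf$faces[on_global, , drop = FALSE]))
  }
  sets[["pdl_outer"]] <- sort(unique(pdl_outer))

  if (has_splint) {
    el <- region_elements("splint")
    bf <- boundary_faces(model$elements[el, , drop = FALSE], nn)
    fg <- face_geometry(model$nodes, bf$faces)
    top <- fg$normal[, 3] > cos30 & bf$key %in% global_keys
    sets[["occlusal_splint"]] <-
      sort(unique(as.vector(bf$faces[top, , drop = FALSE])))
    # splint_inner: splint nodes shared with any tooth region
    tooth_nodes <- sort(unique(as.vector(
      model$elements[model$region %in% teeth_labels, , drop = FALSE])))
    splint_nodes <- sort(unique(as.vector(
      model$elements[el, , drop = FALSE])))
    sets[["splint_inner"]] <- intersect(splint_nodes, tooth_nodes)
  }
  sets
}

#' Nodes belonging to a region
#'
#' @param model a `dentition_model`.
#' @param label region label.
#' @return sorted integer vector of node indices.
#' @export
region_nodes <- function(model, label) {
  el <- model$region == label
  if (!any(el)) stop("unknown region: ", label)
  sort(unique(as.vector(model$elements[el, , drop = FALSE])))
}

#' Connected components of a region (element connectivity via shared nodes)
#'
#' @param model a `dentition_model`.
#' @param label region label.
#' @return integer component id per element of the region.
#' @export
region_components <- function(model, label) {
  el <- which(model$region == label)
  elems <- model$elements[el, , drop = FALSE]
  m <- nrow(elems)
  # union-find over elements joined by shared nodes
  parent <- seq_len(m)
  find <- function(i) {
    while (parent[i] != i) {
      parent[i] <<- parent[parent[i]]
      i <- parent[i]
    }
    i
  }
  node_first <- integer(max(elems))
  for (i in seq_len(m)) {
    for (nd in elems[i, ]) {
      if (node_first[nd] == 0L) node_first[nd] <- i
      else {
        ri <- find(i); rj <- find(node_first[nd])
        if (ri != rj) parent[ri] <- rj
      }
    }
  }
  roots <- vapply(seq_len(m), find, 1L)
  match(roots, unique(roots))
}

#' Extract the boundary surface triangles of a region
#'
#' @param model a `dentition_model`.
#' @param label region label (or `NULL` for the whole-mesh boundary).
#' @return list with `vertices` (v x 3) and `triangles` (t x 3 indices),
#'   oriented outward.
#' @export
region_surface <- function(model, label = NULL) {
  el <- if (is.null(label)) seq_len(nrow(model$elements))
        else which(model$region == label)
  if (length(el) == 0) stop("unknown or empty region")
  bf <- boundary_faces(model$elements[el, , drop = FALSE])
  used <- sort(unique(as.vector(bf$faces)))
  tri <- matrix(match(as.vector(bf$faces), used), ncol = 3)
  list(vertices = model$nodes[used, , drop = FALSE], triangles = tri)
}

#' Mesh the full synthetic dentition
#'
#' Convenience wrapper: builds the solids from a spec (optionally with the
#' splint) and meshes them on the shared background grid. Checks that the
#' splint meshes as a single connected component and that every PDL shell is
#' non-empty (the model must be constrainable at the PDL outer surface).
#'
#' @param spec a [dentition_spec()].
#' @param splint include the splint region?
#' @return a `dentition_model`.
#' @export
mesh_dentition <- function(spec, splint = FALSE) {
  solids <- build_dentition_solids(spec, splint = splint)
  model <- mesh_regions(solids, max_edge = spec$max_edge_mm)
  if (length(model$node_sets$pdl_outer) == 0)
    stop("pdl_outer node set is empty; the model cannot be constrained")
  if (splint) {
    comp <- region_components(model, "splint")
    if (max(comp) != 1)
      stop("splint region meshed into ", max(comp), " disconnected components")
  }
  model
}
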