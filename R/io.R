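# File formats: measurement CSV/JSON, summary CSV, binary STL, legacy VTK,
# YAML scenario configs, and run manifests.

#' Read an occlusal measurement from CSV
#'
#' Format: leading comment lines `# key: value` carrying `measurement_id` and
#' `raw_sum`, then a `tooth_id,share_pct` table.
#'
#' @param path file path.
#' @return an [occlusal_measurement()].
#' @export
read_measurement_csv <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty measurement file: ", path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (l in hdr) {
    kv <- strsplit(sub("^#\\s*", "", l), ":\\s*")[[1]]
    if (length(kv) == 2) meta[[trimws(kv[1])]] <- trimws(kv[2])
  }
  if (is.null(meta$raw_sum)) stop("missing '# raw_sum:' header in ", path)
  body <- lines[!grepl("^#", lines)]
  if (length(body) < 2) stop("no measurement rows in ", path)
  df <- utils::read.csv(text = paste(body, collapse = "\n"),
                        stringsAsFactors = FALSE)
  if (!all(c("tooth_id", "share_pct") %in% names(df)))
    stop("measurement CSV must have columns tooth_id, share_pct")
  bad <- which(is.na(df$tooth_id) | is.na(df$share_pct))
  if (length(bad) > 0)
    stop("malformed measurement row at line ", bad[1] + 1)
  shares <- stats::setNames(as.numeric(df$share_pct), df$tooth_id)
  occlusal_measurement(measurement_id = meta$measurement_id %||% basename(path),
                       raw_sum = as.numeric(meta$raw_sum),
                       shares = shares)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read an occlusal measurement from JSON
#'
#' JSON object with fields `measurement_id`, `raw_sum`, `shares` (map from
#' FDI code to percentage).
#'
#' @param path file path.
#' @return an [occlusal_measurement()].
#' @export
read_measurement_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  occlusal_measurement(x$measurement_id %||% basename(path),
                       x$raw_sum, unlist(x$shares))
}

#' Write a calibrated force report as CSV
#'
#' One row per tooth with the percentage share and the absolute force at
#' one-decimal (printed) precision, plus side and group shares in comment
#' headers.
#'
#' @param dist a `force_distribution`.
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_force_csv <- function(dist, path) {
  rd <- round_distribution(dist)
  sides <- side_shares(rd)
  hdr <- c(sprintf("# total_force_N: %.1f", rd$total_force_N),
           sprintf("# left_share_pct: %.1f", round_half_up(sides["left"], 1)),
           sprintf("# right_share_pct: %.1f", round_half_up(sides["right"], 1)))
  df <- data.frame(tooth_id = names(dist$per_tooth_N),
                   force_N = round_half_up(dist$per_tooth_N, 1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(df, con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write per-region maxima summaries as CSV
#'
#' @param summaries named list of data frames from [summarize_solution()];
#'   names are the option numbers ("1", "2", "3").
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_summary_csv <- function(summaries, path) {
  if (length(summaries) == 0) stop("no summaries to write")
  if (is.null(names(summaries))) names(summaries) <- seq_along(summaries)
  rows <- do.call(rbind, lapply(names(summaries), function(opt) {
    s <- summaries[[opt]]
    cbind(option = as.integer(opt), s)
  }))
  rows$max_disp_mm <- signif(rows$max_disp_mm, 6)
  rows$max_vm_MPa <- signif(rows$max_vm_MPa, 6)
  utils::write.csv(rows, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a summary CSV written by [write_summary_csv()]
#'
#' @param path file path.
#' @return named list of per-option data frames.
#' @export
read_summary_csv <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  df$region <- as.character(df$region)
  split_cols <- setdiff(names(df), "option")
  out <- lapply(split(df[split_cols], df$option), function(d) {
    rownames(d) <- NULL
    d
  })
  out
}

#' Export a triangulated surface as binary STL
#'
#' @param surface list with `vertices` (v x 3) and `triangles` (t x 3
#'   indices), e.g. from [region_surface()].
#' @param path output path.
#' @param name solid name written to the 80-byte header.
#' @return the path, invisibly.
#' @export
export_stl <- function(surface, path, name = "splintfea") {
  v <- surface$vertices; tri <- surface$triangles
  if (nrow(tri) == 0) stop("empty surface")
  # warn (but still write) if the surface is not edge-manifold
  ek <- c(paste(pmin(tri[, 1], tri[, 2]), pmax(tri[, 1], tri[, 2])),
          paste(pmin(tri[, 2], tri[, 3]), pmax(tri[, 2], tri[, 3])),
          paste(pmin(tri[, 3], tri[, 1]), pmax(tri[, 3], tri[, 1])))
  if (any(table(ek) > 2))
    warning("surface is non-manifold; STL written anyway")
  con <- file(path, "wb")
  on.exit(close(con))
  hdr <- charToRaw(sprintf("%-80s", substr(name, 1, 79)))
  writeBin(hdr[1:80], con)
  writeBin(as.integer(nrow(tri)), con, size = 4, endian = "little")
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  cc <- v[tri[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  len <- sqrt(rowSums(nrm^2))
  nrm <- nrm / pmax(len, .Machine$double.eps)
  for (i in seq_len(nrow(tri))) {
    writeBin(as.numeric(c(nrm[i, ], a[i, ], b[i, ], cc[i, ])), con,
             size = 4, endian = "little")
    writeBin(as.integer(0), con, size = 2, endian = "little")
  }
  invisible(path)
}

#' Import a binary STL file
#'
#' @param path file path.
#' @return list with `vertices` (3t x 3, one triple per triangle corner) and
#'   `triangles` (t x 3 indices into `vertices`).
#' @export
import_stl <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  invisible(readBin(con, "raw", n = 80))
  nt <- readBin(con, "integer", size = 4, endian = "little")
  if (!length(nt) || nt < 0) stop("unreadable STL file: ", path)
  verts <- matrix(0, 3 * nt, 3)
  for (i in seq_len(nt)) {
    rec <- readBin(con, "numeric", n = 12, size = 4, endian = "little")
    if (length(rec) < 12) stop("truncated STL file: ", path)
    verts[3 * i - 2, ] <- rec[4:6]
    verts[3 * i - 1, ] <- rec[7:9]
    verts[3 * i, ] <- rec[10:12]
    invisible(readBin(con, "raw", n = 2))
  }
  list(vertices = verts,
       triangles = matrix(seq_len(3 * nt), ncol = 3, byrow = TRUE))
}

#' Total area of a triangulated surface
#'
#' @param surface list with `vertices` and `triangles`.
#' @return area (mm^2).
#' @export
surface_area <- function(surface) {
  v <- surface$vertices; tri <- surface$triangles
  a <- v[tri[, 1], , drop = FALSE]
  b <- v[tri[, 2], , drop = FALSE]
  cc <- v[tri[, 3], , drop = FALSE]
  u <- b - a; w <- cc - a
  nrm <- cbind(u[, 2] * w[, 3] - u[, 3] * w[, 2],
               u[, 3] * w[, 1] - u[, 1] * w[, 3],
               u[, 1] * w[, 2] - u[, 2] * w[, 1])
  sum(sqrt(rowSums(nrm^2))) / 2
}

#' Export a solved model as legacy ASCII VTK
#'
#' Unstructured grid with point displacement vectors and cell von Mises
#' stress, viewable in ParaView.
#'
#' @param model a `dentition_model`.
#' @param solution an `fe_solution` (optional; mesh-only file if `NULL`).
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_vtk <- function(model, solution = NULL, path) {
  n <- nrow(model$nodes); m <- nrow(model$elements)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("# vtk DataFile Version 3.0",
               "splintfea dentition model", "ASCII",
               "DATASET UNSTRUCTURED_GRID",
               sprintf("POINTS %d double", n)), con)
  utils::write.table(format(model$nodes, scientific = TRUE, digits = 9),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELLS %d %d", m, 5 * m), con)
  utils::write.table(cbind(4L, model$elements - 1L), con,
                     row.names = FALSE, col.names = FALSE, quote = FALSE)
  writeLines(sprintf("CELL_TYPES %d", m), con)
  writeLines(as.character(rep(10L, m)), con)
  region_id <- as.integer(factor(model$region))
  writeLines(c(sprintf("CELL_DATA %d", m),
               "SCALARS region int 1", "LOOKUP_TABLE default"), con)
  writeLines(as.character(region_id), con)
  if (!is.null(solution)) {
    writeLines(c("SCALARS von_mises double 1", "LOOKUP_TABLE default"), con)
    writeLines(format(solution$von_mises, scientific = TRUE, digits = 9), con)
    writeLines(c(sprintf("POINT_DATA %d", n),
                 "VECTORS displacement double"), con)
    utils::write.table(format(solution$displacements, scientific = TRUE,
                              digits = 9),
                       con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  }
  invisible(path)
}

#' Read or write a scenario configuration as YAML
#'
#' @param path file path.
#' @return for `read_scenario_yaml`, a list with `option`, `measurement`
#'   (path or inline), `direction`, and dentition-spec overrides.
#' @export
read_scenario_yaml <- function(path) {
  yaml::read_yaml(path)
}

#' @rdname read_scenario_yaml
#' @param config list to serialise.
#' @export
write_scenario_yaml <- function(config, path) {
  yaml::write_yaml(config, path)
  invisible(path)
}

#' Run manifest
#'
#' Provenance record for a pipeline run: a reproducible hash of the
#' configuration bytes, the seed, package/R versions, per-stage timings and
#' the output file inventory.
#'
#' @param config_path path of the configuration file (hashed), or `NULL`.
#' @param seed integer seed used for the run.
#' @param timings named numeric vector of per-stage elapsed seconds.
#' @param outputs character vector of output file paths (must exist).
#' @return list of class `run_manifest`.
#' @export
run_manifest <- function(config_path = NULL, seed = NA_integer_,
                         timings = numeric(0), outputs = character(0)) {
  missing <- outputs[!file.exists(outputs)]
  if (length(missing) > 0)
    stop("manifest lists missing output file(s): ",
         paste(missing, collapse = ", "))
  hash <- if (!is.null(config_path)) unname(tools::md5sum(config_path))
          else NA_character_
  structure(list(config_hash = hash,
                 seed = seed,
                 versions = list(
                   splintfea = as.character(utils::packageVersion("splintfea")),
                   R = paste(R.version$major, R.version$minor, sep = ".")),
                 timings_s = as.list(timings),
                 outputs = as.list(outputs)),
            class = "run_manifest")
}

#' Write a run manifest as JSON
#'
#' @param manifest a [run_manifest()].
#' @param path output path.
#' @return the path, invisibly.
#' @export
write_manifest <- function(manifest, path) {
  jsonlite::write_json(unclass(manifest), path, auto_unbox = TRUE,
                       pretty = TRUE, digits = NA)
  invisible(path)
}
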