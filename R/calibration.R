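# FDI codes for a full mandibular dentition (quadrant 3 = lower left,
# quadrant 4 = lower right), ordered left second molar -> right second molar.
FDI_MANDIBLE <- c(37L, 36L, 35L, 34L, 33L, 32L, 31L,
                  41L, 42L, 43L, 44L, 45L, 46L, 47L)

#' Round half away from zero
#'
#' Decimal rounding with ties going up (the convention of printed clinical
#' tables), as opposed to [round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 1) {
  p <- 10^digits
  sign(x) * floor(abs(x) * p + 0.5 + 1e-12) / p
}

#' Construct an occlusal measurement
#'
#' One T-Scan acquisition: the dimensionless relative force total ("raw sum")
#' and the per-tooth percentage shares of the total.
#'
#' @param measurement_id character label.
#' @param raw_sum non-negative relative occlusal force total.
#' @param shares named numeric vector of percentage shares; names are
#'   two-digit FDI codes in quadrants 3 and 4 (31..37, 41..47).
#' @return an object of class `occlusal_measurement`.
#' @export
occlusal_measurement <- function(measurement_id, raw_sum, shares) {
  if (!is.numeric(raw_sum) || length(raw_sum) != 1 || is.na(raw_sum) || raw_sum < 0)
    stop("raw_sum must be a single non-negative number")
  if (length(shares) == 0) stop("shares must be non-empty")
  ids <- suppressWarnings(as.integer(names(shares)))
  if (any(is.na(ids)) || !all(ids %in% FDI_MANDIBLE))
    stop("tooth IDs must be FDI codes in {31..37, 41..47}")
  if (anyDuplicated(ids)) stop("duplicated tooth ID in shares")
  if (any(shares < 0 | shares > 100)) stop("shares must lie in [0, 100]")
  s <- sum(shares)
  if (s < 95 || s > 105)
    stop(sprintf("shares sum to %.1f; expected within [95, 105]", s))
  structure(list(measurement_id = as.character(measurement_id),
                 raw_sum = as.numeric(raw_sum),
                 shares = shares[order(match(ids, FDI_MANDIBLE))]),
            class = "occlusal_measurement")
}

#' @export
print.occlusal_measurement <- function(x, ...) {
  cat(sprintf("Occlusal measurement '%s': raw sum %g, %d teeth, shares sum %.1f%%\n",
              x$measurement_id, x$raw_sum, length(x$shares), sum(x$shares)))
  invisible(x)
}

#' Convert a relative T-Scan raw sum to an absolute force
#'
#' Linear calibration of the dimensionless T-Scan total against absolute
#' occlusal force: F = 0.021 x raw_sum + 8.022 (Newtons). The returned value
#' is unrounded; presentation layers round to one decimal.
#'
#' @param raw_sum non-negative relative force (may be a vector).
#' @return force in Newtons.
#' @examples
#' raw_to_newton(11873)  # ~257.4 N
#' @export
raw_to_newton <- function(raw_sum) {
  if (!is.numeric(raw_sum) || any(is.na(raw_sum)) || any(raw_sum < 0))
    stop("raw_sum must be non-negative")
  0.021 * raw_sum + 8.022
}

#' Distribute a total occlusal force over the teeth
#'
#' Applies the percentage shares of a measurement to a total force. Shares
#' are used as printed (no renormalisation when they do not sum exactly to
#' 100); internal values stay unrounded.
#'
#' @param total total force in Newtons (> 0).
#' @param measurement an [occlusal_measurement()] (or a named share vector).
#' @return an object of class `force_distribution` with fields
#'   `total_force_N` and `per_tooth_N` (named, tooth order preserved).
#' @export
distribute_force <- function(total, measurement) {
  shares <- if (inherits(measurement, "occlusal_measurement")) measurement$shares else measurement
  if (length(shares) == 0) stop("shares must be non-empty")
  if (any(shares < 0 | shares > 100)) stop("shares must lie in [0, 100]")
  if (!is.numeric(total) || length(total) != 1 || total <= 0)
    stop("total force must be a single positive number")
  structure(list(total_force_N = total,
                 per_tooth_N = total * shares / 100),
            class = "force_distribution")
}

#' @export
print.force_distribution <- function(x, ...) {
  cat(sprintf("Force distribution: total %.1f N over %d teeth\n",
              x$total_force_N, length(x$per_tooth_N)))
  print(round_half_up(x$per_tooth_N, 1))
  invisible(x)
}

#' Round a force distribution to printed precision
#'
#' Presentation layer: per-tooth forces and the total are rounded half-up to
#' one decimal, matching published occlusal-force tables. Group shares
#' recomputed from the rounded table reproduce published side percentages.
#'
#' @param dist a `force_distribution`.
#' @return a `force_distribution` with one-decimal values.
#' @export
round_distribution <- function(dist) {
  stopifnot(inherits(dist, "force_distribution"))
  structure(list(total_force_N = round_half_up(dist$total_force_N, 1),
                 per_tooth_N = round_half_up(dist$per_tooth_N, 1)),
            class = "force_distribution")
}

#' Percentage of the total force carried by a group of teeth
#'
#' @param dist a `force_distribution`.
#' @param teeth integer (or character) FDI codes; all must be present.
#' @return percentage (0-100), unrounded.
#' @export
group_share <- function(dist, teeth) {
  stopifnot(inherits(dist, "force_distribution"))
  teeth <- as.character(teeth)
  missing <- setdiff(teeth, names(dist$per_tooth_N))
  if (length(missing) > 0)
    stop("unknown tooth ID(s): ", paste(missing, collapse = ", "))
  100 * sum(dist$per_tooth_N[teeth]) / dist$total_force_N
}

#' Left/right side shares of a force distribution
#'
#' Left side = FDI quadrant 3 (31-37), right side = quadrant 4 (41-47).
#'
#' @param dist a `force_distribution`.
#' @return named numeric vector `c(left = ..., right = ...)` in percent.
#' @export
side_shares <- function(dist) {
  ids <- as.integer(names(dist$per_tooth_N))
  left <- names(dist$per_tooth_N)[ids %/% 10 == 3]
  right <- names(dist$per_tooth_N)[ids %/% 10 == 4]
  c(left = if (length(left)) group_share(dist, left) else 0,
    right = if (length(right)) group_share(dist, right) else 0)
}

#' Ratio of two measurement totals
#'
#' @param a,b `force_distribution` objects (or single positive totals).
#' @return `total(a) / total(b)`.
#' @export
measurement_ratio <- function(a, b) {
  ta <- if (inherits(a, "force_distribution")) a$total_force_N else a
  tb <- if (inherits(b, "force_distribution")) b$total_force_N else b
  if (ta <= 0 || tb <= 0) stop("totals must be positive")
  ta / tb
}

#' Bundled T-Scan measurements
#'
#' Loads one of the three packaged occlusal measurements (1: no splint,
#' 2: splint as manufactured, 3: splint after corrective grinding).
#'
#' @param n measurement number, 1, 2 or 3.
#' @return an `occlusal_measurement`.
#' @export
tscan_measurement <- function(n) {
  stopifnot(n %in% 1:3)
  path <- system.file("extdata", sprintf("measurement%d.csv", n),
                      package = "splintfea", mustWork = TRUE)
  read_measurement_csv(path)
}
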