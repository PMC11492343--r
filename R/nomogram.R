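# Institutional seed-ordering nomogram: prostate volume + prescribed dose
# -> average number of I-125 seeds required (0.36 mCi per seed), and the
# classification of the manually ordered number against it.

#' Build a seed nomogram table
#'
#' @param isotope Isotope name.
#' @param activity_per_seed Source activity per seed, mCi.
#' @param dose_levels Supported prescription dose levels, Gy.
#' @param volumes Tabulated prostate volumes, cm\\u00b3 (strictly increasing).
#' @param seeds Numeric matrix, one column per dose level, one row per
#'   volume; seed counts must be non-decreasing in volume within each
#'   column.
#' @return An object of class `nomogram_table`.
#' @export
nomogram_table <- function(isotope, activity_per_seed, dose_levels, volumes,
                           seeds) {
  seeds <- as.matrix(seeds)
  stopifnot(length(volumes) == nrow(seeds),
            length(dose_levels) == ncol(seeds))
  if (any(diff(volumes) <= 0))
    stop("nomogram volumes must be strictly increasing")
  if (any(apply(seeds, 2, function(col) any(diff(col) < 0))))
    stop("nomogram seed counts must be non-decreasing in volume")
  colnames(seeds) <- as.character(dose_levels)
  structure(list(isotope = isotope, activity_per_seed = activity_per_seed,
                 dose_levels = dose_levels, volumes = volumes,
                 seeds = seeds),
            class = "nomogram_table")
}

#' The bundled institutional nomogram
#'
#' Average number of I-125 seeds (0.36 mCi each) required per prostate
#' volume, tabulated from 10 to 80 cm\\u00b3 in 5 cm\\u00b3 steps at the two
#' prescription dose levels used for PSI: 110 Gy (boost after 45 Gy EBRT)
#' and 145 Gy (definitive).
#'
#' @return A [nomogram_table()].
#' @export
default_nomogram <- function() {
  nomogram_table(
    isotope = "I-125",
    activity_per_seed = 0.36,
    dose_levels = c(110, 145),
    volumes = seq(10, 80, by = 5),
    seeds = cbind(
      c(31, 38, 45, 52, 59, 66, 73, 80, 87, 93, 100, 107, 114, 121, 128),
      c(43, 50, 57, 64, 71, 78, 85, 92, 99, 106, 113, 120, 127, 134, 141)))
}

#' Load a nomogram from a YAML config file
#'
#' Expected keys: `isotope`, `activity_per_seed`, `dose_levels`, and `rows`
#' (a list of `volume` plus one seed count per dose level, keyed by dose).
#' With `config_path = NULL` the bundled default is returned.
#'
#' @param config_path Path to YAML config or `NULL`.
#' @return A [nomogram_table()].
#' @export
load_nomogram <- function(config_path = NULL) {
  if (is.null(config_path)) return(default_nomogram())
  cfg <- tryCatch(yaml::read_yaml(config_path), error = function(e) {
    stop("nomogram config error: cannot parse ", config_path, ": ",
         conditionMessage(e))
  })
  for (key in c("isotope", "activity_per_seed", "dose_levels", "rows"))
    if (is.null(cfg[[key]]))
      stop("nomogram config error: missing key '", key, "'")
  doses <- as.numeric(unlist(cfg$dose_levels))
  volumes <- vapply(cfg$rows, function(r) as.numeric(r$volume), numeric(1))
  seeds <- t(vapply(cfg$rows, function(r) {
    vapply(as.character(doses), function(d) {
      v <- r[[d]]
      if (is.null(v)) stop("nomogram config error: row for volume ",
                           r$volume, " lacks dose level ", d)
      as.numeric(v)
    }, numeric(1))
  }, numeric(length(doses))))
  nomogram_table(cfg$isotope, as.numeric(cfg$activity_per_seed), doses,
                 volumes, seeds)
}

#' Write a nomogram to a YAML config file
#'
#' @param table A [nomogram_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
save_nomogram <- function(table, path) {
  rows <- lapply(seq_along(table$volumes), function(i) {
    row <- list(volume = table$volumes[i])
    for (j in seq_along(table$dose_levels))
      row[[as.character(table$dose_levels[j])]] <- table$seeds[i, j]
    row
  })
  yaml::write_yaml(list(isotope = table$isotope,
                        activity_per_seed = table$activity_per_seed,
                        dose_levels = as.list(table$dose_levels),
                        rows = rows), path)
  invisible(path)
}

#' Seeds required for a prostate volume at a dose level
#'
#' Returns the tabulated value exactly at tabulated volumes and a linear
#' interpolation between adjacent rows otherwise. Volumes outside the
#' tabulated span are outside institutional nomogram scope: no
#' extrapolation is attempted and an error condition carrying a
#' manual-review flag is signalled.
#'
#' @param volume Prostate volume, cm\\u00b3.
#' @param dose Prescription dose, Gy; must be one of the table's dose
#'   levels.
#' @param table A [nomogram_table()].
#' @return Real-valued seed count (not rounded).
#' @export
seeds_required <- function(volume, dose, table = default_nomogram()) {
  col <- match(dose, table$dose_levels)
  if (is.na(col))
    stop("dose ", dose, " Gy is not a nomogram dose level (",
         paste(table$dose_levels, collapse = ", "), ")")
  if (!is.numeric(volume) || length(volume) != 1 || is.na(volume))
    stop("volume must be a single number")
  lo <- min(table$volumes)
  hi <- max(table$volumes)
  if (volume < lo || volume > hi) {
    cond <- structure(
      class = c("psichart_nomogram_domain_error", "error", "condition"),
      list(message = sprintf(
        paste0("prostate volume %g cm³ outside nomogram range ",
               "[%g, %g]: manual review required"), volume, lo, hi),
        call = sys.call(-1), manual_review = TRUE))
    stop(cond)
  }
  stats::approx(table$volumes, table$seeds[, col], xout = volume,
                method = "linear")$y
}

#' Classify a manually entered seed order against the nomogram
#'
#' Computes `d = manual - seeds_required(volume, dose)` on the unrounded
#' nomogram value and applies the institutional tolerance of 5 seeds:
#' a manual number more than `tolerance` above the nomogram yields a
#' warning prompting physicist verification; more than `tolerance` below
#' yields an error for immediate attention and investigation; a difference
#' of `tolerance` or less (in magnitude) passes.
#'
#' @param manual Seed count entered by the physician (integer, >= 0).
#' @param volume Prostate volume, cm\\u00b3.
#' @param dose Prescription dose, Gy.
#' @param table A [nomogram_table()].
#' @param tolerance Tolerance in seeds (default 5).
#' @return A list of class `seed_difference_verdict`: `manual`, `computed`,
#'   `difference`, `severity` (`"pass"`, `"warning"`, `"error"`), `message`.
#' @export
classify_order <- function(manual, volume, dose, table = default_nomogram(),
                           tolerance = 5) {
  stopifnot(is.numeric(manual), length(manual) == 1, manual >= 0)
  computed <- seeds_required(volume, dose, table)
  d <- manual - computed
  if (d > tolerance) {
    severity <- "warning"
    message <- sprintf(
      paste0("manual seed number %d exceeds nomogram value %.1f by %.1f ",
             "(> %g): physicist verification required"),
      as.integer(manual), computed, d, tolerance)
  } else if (d < -tolerance) {
    severity <- "error"
    message <- sprintf(
      paste0("manual seed number %d below nomogram value %.1f by %.1f ",
             "(> %g): immediate attention and investigation required"),
      as.integer(manual), computed, -d, tolerance)
  } else {
    severity <- "pass"
    message <- sprintf(
      "manual seed number %d within %g of nomogram value %.1f",
      as.integer(manual), tolerance, computed)
  }
  structure(list(manual = as.integer(manual), computed = computed,
                 difference = d, severity = severity, message = message),
            class = "seed_difference_verdict")
}

#' Round a seed quantity to the ordering increment
#'
#' Seed orders are placed in increments of 5; the quantity is always
#' rounded up (the smallest multiple of 5 at or above the computed count)
#' so that an order is never short.
#'
#' @param seeds Non-negative real seed count.
#' @return Integer multiple of 5.
#' @export
round_order_quantity <- function(seeds) {
  stopifnot(is.numeric(seeds), all(seeds >= 0))
  as.integer(5 * ceiling(seeds / 5))
}
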