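#' Longitudinal ultrasonic velocity in an elastic solid
#'
#' Plane-wave longitudinal velocity of a homogeneous isotropic solid,
#' `v = sqrt( (E/rho) * (1 - sigma) / ((1 + sigma) * (1 - 2*sigma)) )`.
#' For a stem whose elastic modulus and Poisson's ratio stay roughly
#' constant, water uptake raises the density and therefore lowers the
#' velocity -- the mechanism that lets echo timing track water content.
#'
#' @param E Modulus of elasticity, Pa.
#' @param rho Density, kg/m^3.
#' @param sigma Poisson's ratio, in `[0, 0.5)`.
#'
#' @return Velocity in m/s.
#' @export
#' @examples
#' longitudinal_velocity(10e9, 600, 0.3)
longitudinal_velocity <- function(E, rho, sigma) {
  if (any(E <= 0)) stop("modulus of elasticity must be positive")
  if (any(rho <= 0)) stop("density must be positive")
  if (any(sigma < 0) || any(sigma >= 0.5)) {
    stop("Poisson's ratio must lie in [0, 0.5); the expression diverges at 0.5")
  }
  sqrt((E / rho) * (1 - sigma) / ((1 + sigma) * (1 - 2 * sigma)))
}

#' Pulse-echo velocity from the primary-echo time
#'
#' `v = 2 * D / t`: the echo travels to the far interface and back, so the
#' round-trip path is twice the half-path length `D`.
#'
#' @param D Half-path length (probe to reflecting interface), m.
#' @param t Primary-echo time, s.
#'
#' @return Velocity in m/s.
#' @export
velocity_from_echo <- function(D, t) {
  if (any(D <= 0) || any(t <= 0)) stop("path length and echo time must be positive")
  2 * D / t
}

#' Sample volume from its geometry
#'
#' @param shape `"cylinder"` (dims = diameter, height) or `"cuboid"`
#'   (dims = three edges), all in cm.
#' @param dims Numeric vector of dimensions in cm.
#'
#' @return Volume in cm^3.
#' @export
#' @examples
#' sample_volume("cylinder", c(6, 6))     # pi * 9 * 6
#' sample_volume("cuboid", c(2, 4, 10))   # 80
sample_volume <- function(shape = c("cylinder", "cuboid"), dims) {
  shape <- match.arg(shape)
  if (any(dims <= 0)) stop("dimensions must be positive")
  if (shape == "cylinder") {
    if (length(dims) != 2L) stop("a cylinder needs diameter and height")
    pi * (dims[1L] / 2)^2 * dims[2L]
  } else {
    if (length(dims) != 3L) stop("a cuboid needs three edge lengths")
    prod(dims)
  }
}

#' Bulk density
#'
#' @param mass_g Mass in g.
#' @param volume_cm3 Volume in cm^3.
#' @return Density in g/cm^3.
#' @export
bulk_density <- function(mass_g, volume_cm3) {
  if (any(mass_g <= 0) || any(volume_cm3 <= 0)) {
    stop("mass and volume must be positive")
  }
  mass_g / volume_cm3
}

#' Volumetric moisture content from soaking masses
#'
#' `theta = (mA - mB) / (beta * V)`: mass of absorbed water divided by the
#' water density times the sample volume, i.e. the volume fraction taken up
#' by the absorbed water.
#'
#' @param mA Mass after soaking, g.
#' @param mB Mass before soaking, g.
#' @param beta Density of water, g/cm^3 (default 1).
#' @param V Sample volume, cm^3.
#'
#' @return Moisture content as a fraction.
#' @export
#' @examples
#' volumetric_moisture(173.60, 102.60, 1, sample_volume("cylinder", c(6, 6)))
volumetric_moisture <- function(mA, mB, beta = 1, V) {
  if (any(mB <= 0)) stop("initial mass must be positive")
  if (any(mA < mB)) stop("mass after soaking cannot be below the initial mass")
  if (any(beta <= 0) || any(V <= 0)) stop("beta and V must be positive")
  (mA - mB) / (beta * V)
}

#' Wet-basis mass moisture content
#'
#' `(mA - mB) / mA`: absorbed water mass relative to the wet mass.
#'
#' @inheritParams volumetric_moisture
#' @return Moisture content as a fraction.
#' @export
mass_moisture <- function(mA, mB) {
  if (any(mB <= 0)) stop("initial mass must be positive")
  if (any(mA < mB)) stop("mass after soaking cannot be below the initial mass")
  (mA - mB) / mA
}

fit_result <- function(coefficients, correlation, n_points) {
  if (n_points < 4L) stop("a quadratic fit needs at least 4 points")
  if (!is.finite(correlation)) stop("fit correlation is not finite")
  structure(
    list(coefficients = as.numeric(coefficients),
         correlation = as.numeric(correlation),
         n_points = as.integer(n_points)),
    class = "fit_result"
  )
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> v = %.4g %+.4g*theta %+.4g*theta^2  (r = %.4f, n = %d)\n",
              x$coefficients[1L], x$coefficients[2L], x$coefficients[3L],
              x$correlation, x$n_points))
  invisible(x)
}

#' Read an immersion-experiment table
#'
#' Expects a CSV with columns `sample_id`, `shape`, `dim1_cm`, `dim2_cm`,
#' `dim3_cm` (may be empty for cylinders), `timepoint_min`, `mass_g` and
#' `velocity_m_s`. Timepoints must be strictly increasing within each
#' sample.
#'
#' @param path CSV file path.
#' @return A data frame.
#' @export
read_immersion <- function(path) {
  if (!file.exists(path)) stop("immersion table not found: ", path)
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  need <- c("sample_id", "shape", "dim1_cm", "dim2_cm", "timepoint_min",
            "mass_g")
  missing <- setdiff(need, names(df))
  if (length(missing) > 0L) {
    stop("immersion table lacks columns: ", paste(missing, collapse = ", "))
  }
  for (col in c("dim1_cm", "dim2_cm", "timepoint_min", "mass_g")) {
    if (!is.numeric(df[[col]])) {
      bad <- which(is.na(suppressWarnings(as.numeric(df[[col]]))))[1L]
      stop(sprintf("non-numeric value in column '%s', row %d of %s",
                   col, bad, path))
    }
  }
  if (any(df$mass_g <= 0)) {
    stop("non-positive mass at row ", which(df$mass_g <= 0)[1L], " of ", path)
  }
  for (sid in unique(df$sample_id)) {
    tp <- df$timepoint_min[df$sample_id == sid]
    if (is.unsorted(tp, strictly = TRUE)) {
      stop("timepoints for sample '", sid, "' are not strictly increasing")
    }
  }
  df
}

#' Bundled immersion reference table
#'
#' The packaged water-immersion data set: three cylindrical stem samples
#' (6, 7 and 10 cm diameter, height equal to diameter) weighed and measured
#' for pulse-echo velocity at 15 timepoints from the start of soaking out
#' to nine days.
#'
#' @return A data frame in the [read_immersion()] schema.
#' @export
#' @examples
#' head(table2_immersion())
table2_immersion <- function() {
  read_immersion(system.file("extdata", "immersion_table2.csv",
                             package = "stemecho", mustWork = TRUE))
}

#' Derived quantities and velocity--moisture fits for an immersion series
#'
#' For every record computes the bulk density, wet-basis mass moisture and
#' volumetric moisture (relative to the sample's mass at its first
#' timepoint). For every sample with measured velocities it then fits a
#' quadratic polynomial of velocity on volumetric moisture by least
#' squares and reports the Pearson correlation between fitted and observed
#' velocities; the summary correlation is the unweighted mean across
#' samples.
#'
#' @param records Data frame in the [read_immersion()] schema (or the
#'   bundled [table2_immersion()] table).
#' @param beta Water density in g/cm^3 (default 1).
#'
#' @return An object of class `immersion_analysis`: list with `table` (the
#'   records plus `volume_cm3`, `density_g_cm3`, `mass_mc`, `vol_mc`),
#'   `fits` (named list of per-sample fit results) and `mean_correlation`.
#' @export
#' @examples
#' res <- immersion_analysis(table2_immersion())
#' res$mean_correlation
immersion_analysis <- function(records, beta = 1) {
  if (beta <= 0) stop("beta must be positive")
  records <- records[order(match(records$sample_id, unique(records$sample_id)),
                           records$timepoint_min), ]
  tabs <- list()
  fits <- list()
  for (sid in unique(records$sample_id)) {
    rec <- records[records$sample_id == sid, ]
    dims <- c(rec$dim1_cm[1L], rec$dim2_cm[1L])
    if (identical(rec$shape[1L], "cuboid")) dims <- c(dims, rec$dim3_cm[1L])
    V <- sample_volume(rec$shape[1L], dims)
    mB <- rec$mass_g[1L]
    rec$volume_cm3 <- V
    rec$density_g_cm3 <- bulk_density(rec$mass_g, V)
    rec$mass_mc <- mass_moisture(rec$mass_g, mB)
    rec$vol_mc <- volumetric_moisture(rec$mass_g, mB, beta, V)
    tabs[[sid]] <- rec

    if (nrow(rec) < 4L || is.null(rec$velocity_m_s) ||
        anyNA(rec$velocity_m_s)) {
      warning("sample '", sid, "' excluded from the fit (needs >= 4 ",
              "timepoints with measured velocities)")
      next
    }
    fit <- stats::lm(velocity_m_s ~ vol_mc + I(vol_mc^2), data = rec)
    r <- stats::cor(stats::fitted(fit), rec$velocity_m_s)
    fits[[sid]] <- fit_result(stats::coef(fit), r, nrow(rec))
  }
  if (length(fits) == 0L) stop("no sample had enough points for a fit")
  structure(
    list(table = do.call(rbind, c(tabs, make.row.names = FALSE)),
         fits = fits,
         mean_correlation = mean(vapply(fits, `[[`, 1, "correlation"))),
    class = "immersion_analysis"
  )
}

#' @export
print.immersion_analysis <- function(x, ...) {
  cat("<immersion_analysis> ", length(x$fits), " sample(s), ",
      nrow(x$table), " records\n", sep = "")
  for (sid in names(x$fits)) {
    cat(sprintf("  %-6s r = %.4f (n = %d)\n", sid,
                x$fits[[sid]]$correlation, x$fits[[sid]]$n_points))
  }
  cat(sprintf("  mean correlation: %.4f\n", x$mean_correlation))
  invisible(x)
}

#' Correlation between echo-position and covariate time series
#'
#' Aligns a series of echo picks with an environmental covariate (soil
#' moisture, air temperature, ...) by exact timestamp match, optionally
#' restricted to a time window, and returns the Pearson correlation of the
#' aligned pairs.
#'
#' @param picks Data frame with columns `timestamp` and `onset_pu`.
#' @param covariate Data frame whose first column is `timestamp` and whose
#'   second column is the covariate value.
#' @param window Optional numeric length-2 vector `c(from, to)`; only
#'   timestamps inside the closed interval are used.
#'
#' @return Pearson correlation in `[-1, 1]`.
#' @export
track_correlation <- function(picks, covariate, window = NULL) {
  if (!all(c("timestamp", "onset_pu") %in% names(picks))) {
    stop("picks need columns 'timestamp' and 'onset_pu'")
  }
  if (ncol(covariate) < 2L || names(covariate)[1L] != "timestamp") {
    stop("covariate needs a 'timestamp' first column and a value column")
  }
  m <- merge(picks[c("timestamp", "onset_pu")],
             stats::setNames(covariate[1:2], c("timestamp", "covariate")),
             by = "timestamp")
  if (!is.null(window)) {
    if (length(window) != 2L) stop("window must be c(from, to)")
    m <- m[m$timestamp >= window[1L] & m$timestamp <= window[2L], ]
  }
  if (nrow(m) < 3L) {
    stop("no aligned points: need >= 3 matching timestamps",
         if (!is.null(window)) " inside the window" else "")
  }
  if (stats::sd(m$onset_pu) == 0 || stats::sd(m$covariate) == 0) {
    stop("undefined correlation: one series has zero variance")
  }
  stats::cor(m$onset_pu, m$covariate)
}
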