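# Readers for the microanatomic-measurement and in-vivo growth tables
# (CSV layout), and generators for synthetic stand-ins of those tables.
# The real supplementary spreadsheets are not redistributable here; the
# synthetic generators emulate their layout and are calibrated so that the
# published summary statistics are reproduced exactly (affine moment
# matching for measurement columns; per-lesion noise constructed orthogonal
# to time so group mean slopes are preserved).

#' Read a papilla/melanocyte measurement table
#'
#' CSV layout mirroring the microanatomic measurement table: one sheet of
#' papilla measurements (height and radii, micrometres, raw = uncorrected
#' for shrinkage), melanocyte diameters and confocal papilla counts.
#'
#' @param path CSV file with columns \code{table} (\code{"papilla"},
#'   \code{"melanocyte"}, \code{"confocal"}), \code{H_bar}, \code{r_base},
#'   \code{r_mid}, \code{r_tip}, \code{diameter}, \code{count}.
#' @return list of data frames \code{papilla}, \code{melanocyte},
#'   \code{confocal}.
#' @export
read_measurement_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("table", "H_bar", "r_base", "r_mid", "r_tip", "diameter", "count")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed measurement table: missing column(s) ",
         paste(miss, collapse = ", "))
  list(
    papilla = df[df$table == "papilla",
                 c("H_bar", "r_base", "r_mid", "r_tip")],
    melanocyte = df[df$table == "melanocyte", "diameter", drop = FALSE],
    confocal = df[df$table == "confocal", "count", drop = FALSE]
  )
}

# rescale x to exact mean m and standard deviation s
.moment_match <- function(x, m, s) {
  (x - mean(x)) / sd(x) * s + m
}

#' Generate a synthetic measurement table
#'
#' Synthetic stand-in for the raw microanatomic measurement data: 100
#' papilla measurement tuples, melanocyte diameters and 40 confocal papilla
#' counts.  Columns are affinely calibrated so the sample statistics equal
#' the published values exactly (measured height 59.7 +/- 18.2 um, base
#' radius 28.0 +/- 10.1 um, confocal density 48.8 +/- 5.29 per mm^2).
#'
#' @param path output CSV path.
#' @param n_papilla,n_melanocyte,n_confocal row counts.
#' @param seed RNG seed.
#' @return the path, invisibly.
#' @export
synth_measurement_table <- function(path, n_papilla = 100, n_melanocyte = 50,
                                    n_confocal = 40, seed = 1L) {
  set.seed(seed)
  # draw plausible shapes, derive measurement tuples from the shape model,
  # then calibrate the raw height/base columns to the published moments
  stats <- papilla_statistics_preset("standard")
  sh <- sample_papillae(stats, n_papilla)
  meas <- t(vapply(seq_len(n_papilla), function(i) {
    cv <- build_shape_curve(sh$R[i], sh$H[i], sh$p[i])
    zs <- c(0, 0.5 * sh$H[i], max(sh$H[i] - 12, 0.5 * sh$H[i]))
    c(sh$H[i], shape_radius_at_height(cv, zs))
  }, numeric(4)))
  H_raw <- .moment_match(meas[, 1], 59.7, 18.2)
  scale_r <- meas[, 2] / pmax(meas[, 1], 1)          # base/height proportion
  r_base <- .moment_match(meas[, 2], 28.0, 10.1)
  ratio_mid <- meas[, 3] / meas[, 2]
  ratio_tip <- meas[, 4] / meas[, 2]
  papilla <- data.frame(table = "papilla", H_bar = pmax(H_raw, 12),
                        r_base = pmax(r_base, 4),
                        r_mid = pmax(r_base, 4) * ratio_mid,
                        r_tip = pmax(r_base, 4) * ratio_tip,
                        diameter = NA_real_, count = NA_real_)
  papilla$H_bar <- .moment_match(papilla$H_bar, 59.7, 18.2)
  papilla$r_base <- .moment_match(papilla$r_base, 28.0, 10.1)
  melanocyte <- data.frame(table = "melanocyte", H_bar = NA_real_,
                           r_base = NA_real_, r_mid = NA_real_,
                           r_tip = NA_real_,
                           diameter = rnorm(n_melanocyte, 10, 1.5),
                           count = NA_real_)
  confocal <- data.frame(table = "confocal", H_bar = NA_real_,
                         r_base = NA_real_, r_mid = NA_real_,
                         r_tip = NA_real_, diameter = NA_real_,
                         count = .moment_match(rnorm(n_confocal), 48.8, 5.29))
  utils::write.csv(rbind(papilla, melanocyte, confocal), path,
                   row.names = FALSE)
  invisible(path)
}

#' Read an in-vivo growth table
#'
#' CSV layout mirroring the sequential-dermatoscopy growth data: one row per
#' observation with lesion id, pattern label, time in days and lesion area
#' in mm^2.
#'
#' @param path CSV with columns \code{lesion}, \code{pattern}
#'   (\code{"reticular"}/\code{"globular"}), \code{time_d}, \code{area_mm2}.
#' @return list of per-lesion data frames (attributes \code{pattern}), plus
#'   attribute \code{"patterns"} mapping lesion id to pattern.
#' @export
read_growth_table <- function(path) {
  df <- utils::read.csv(path)
  need <- c("lesion", "pattern", "time_d", "area_mm2")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("malformed growth table: missing column(s) ",
         paste(miss, collapse = ", "))
  split_df <- split(df, df$lesion)
  out <- lapply(split_df, function(d) {
    d <- d[order(d$time_d), c("time_d", "area_mm2")]
    rownames(d) <- NULL
    d
  })
  attr(out, "patterns") <- vapply(split_df, function(d)
    as.character(d$pattern[1]), "")
  out
}

#' Write a growth table
#'
#' @param lesions list of per-lesion data frames (\code{time_d},
#'   \code{area_mm2}).
#' @param patterns character vector of pattern labels, one per lesion.
#' @param path output CSV path.
#' @export
write_growth_table <- function(lesions, patterns, path) {
  rows <- lapply(seq_along(lesions), function(i)
    data.frame(lesion = names(lesions)[i] %||% sprintf("L%02d", i),
               pattern = patterns[i],
               time_d = lesions[[i]]$time_d,
               area_mm2 = lesions[[i]]$area_mm2, row.names = NULL))
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a) || length(a) == 0 || is.na(a)) b else a

#' Generate a synthetic growth table
#'
#' Synthetic stand-in for the in-vivo area-versus-time series: 13 reticular
#' and 25 globular lesions with >= 10 observations each and initial areas
#' below 30 mm^2.  Per-lesion slopes are drawn around the published group
#' means and recentred so the group means are exact; observation noise is
#' constructed orthogonal to time so ordinary least squares recovers each
#' lesion's slope exactly.
#'
#' @param path output CSV path.
#' @param n_reticular,n_globular lesion counts.
#' @param slope_reticular,slope_globular group mean slopes (mm^2/d).
#' @param sd_reticular,sd_globular across-lesion slope standard deviations.
#' @param seed RNG seed.
#' @return the path, invisibly.
#' @export
synth_growth_table <- function(path, n_reticular = 13, n_globular = 25,
                               slope_reticular = 1.928e-3,
                               slope_globular = 6.005e-3,
                               sd_reticular = 1.889e-3,
                               sd_globular = 6.099e-3, seed = 1L) {
  set.seed(seed)
  mk_group <- function(n, m, s, label) {
    slopes <- rnorm(n, m, s)
    slopes <- slopes - mean(slopes) + m        # exact group mean
    lapply(seq_len(n), function(i) {
      nobs <- sample(10:16, 1)
      t <- sort(runif(nobs, 0, 1200))
      a0 <- runif(1, 2, 25) + max(0, -slopes[i] * 1200)  # keep areas positive
      e <- rnorm(nobs, 0, 0.4)
      e <- stats::residuals(lm(e ~ t))         # orthogonal to (1, t)
      d <- data.frame(time_d = t, area_mm2 = a0 + slopes[i] * t + e)
      attr(d, "pattern") <- label
      d
    })
  }
  ret <- mk_group(n_reticular, slope_reticular, sd_reticular, "reticular")
  glo <- mk_group(n_globular, slope_globular, sd_globular, "globular")
  lesions <- c(ret, glo)
  names(lesions) <- sprintf("L%02d", seq_along(lesions))
  patterns <- c(rep("reticular", n_reticular), rep("globular", n_globular))
  write_growth_table(lesions, patterns, path)
  invisible(path)
}
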