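.eval_poly <- function(beta, lat, lon) {
  beta[1] + beta[2] * lat + beta[3] * lon + beta[4] * lat^2 +
    beta[5] * lon^2 + beta[6] * lat * lon
}

#' Binary quadratic trend-surface regression
#'
#' Ordinary least squares of a trait on the six-term quadratic basis in
#' geographic coordinates,
#' \eqn{Z = \beta_0 + \beta_1 x + \beta_2 y + \beta_3 x^2 + \beta_4 y^2 +
#' \beta_5 xy}, with x = latitude (deg N) and y = longitude (deg E), on raw
#' (uncentered) coordinates. Observations are individual trees or wood
#' samples tagged with their provenance's coordinates, so the fit has the
#' trial's full residual scatter and R-squared (the "fitting coefficient")
#' is small even when the surface is highly significant. The p-value is the
#' overall regression F-test with (5, n - 6) degrees of freedom.
#'
#' @param observations `data.frame` with columns `latitude`, `longitude`,
#'   and `value` (or supply `trait` to name another response column).
#' @param trait Response column name (default `"value"`).
#' @return An object of class `trend_surface`: `coefficients` (b0..b5),
#'   `r2`, `p_value`, `n`, `fitted`, `residuals`.
#' @export
fit_trend_surface <- function(observations, trait = "value") {
  z <- observations[[trait]]
  x <- observations$latitude
  y <- observations$longitude
  keep <- stats::complete.cases(z, x, y)
  z <- z[keep]; x <- x[keep]; y <- y[keep]
  n <- length(z)
  if (n < 7) stop("need at least 7 observations for the 6-term surface",
                  call. = FALSE)
  if (nrow(unique(cbind(x, y))) < 3) {
    stop("need at least 3 distinct locations", call. = FALSE)
  }
  M <- cbind(1, x, y, x^2, y^2, x * y)
  colnames(M) <- paste0("b", 0:5)
  if (qr(M)$rank < 6) {
    stop("rank-deficient quadratic basis (collinear coordinates)", call. = FALSE)
  }
  kappa_val <- kappa(M, exact = FALSE)
  if (kappa_val > 1e10) {
    warning(sprintf("ill-conditioned basis (condition number %.2e); consider the coordinate range", kappa_val),
            call. = FALSE)
  }
  fit <- stats::lm(z ~ M - 1)
  beta <- stats::setNames(as.numeric(stats::coef(fit)), colnames(M))
  fitted <- drop(M %*% beta)
  res <- z - fitted
  ss_tot <- sum((z - mean(z))^2)
  ss_res <- sum(res^2)
  if (ss_tot <= 0) {
    r2 <- 0; p <- 1
  } else {
    r2 <- 1 - ss_res / ss_tot
    df2 <- n - 6
    f <- (r2 / 5) / ((1 - r2) / df2)
    p <- if (r2 <= 0) 1 else stats::pf(f, 5, df2, lower.tail = FALSE)
  }
  structure(list(coefficients = beta, r2 = r2, p_value = p, n = n,
                 fitted = fitted, residuals = res,
                 bbox = c(lat_min = min(x), lat_max = max(x),
                          lon_min = min(y), lon_max = max(y))),
            class = "trend_surface")
}

#' @export
print.trend_surface <- function(x, ...) {
  b <- signif(x$coefficients, 4)
  cat(sprintf("Trend surface (n = %d): Z = %g + %g x + %g y + %g x^2 + %g y^2 + %g xy\n",
              x$n, b[1], b[2], b[3], b[4], b[5], b[6]))
  cat(sprintf("Fitting coefficient R^2 = %.4f, F-test p = %.3g\n",
              x$r2, x$p_value))
  invisible(x)
}

#' Evaluate a trend surface on points or a lattice
#'
#' Evaluates the quadratic polynomial pointwise. With `lat`/`lon` vectors it
#' returns predictions at those points; with `grid_n` it builds a regular
#' lattice over the fit's bounding box padded by `pad` degrees and returns a
#' long-format lattice table suitable for contouring.
#'
#' @param fit A `trend_surface` object, or a length-6 coefficient vector
#'   (b0..b5).
#' @param lat,lon Optional point coordinates (equal length).
#' @param grid_n Lattice resolution per axis (default 100) when `lat`/`lon`
#'   are not given.
#' @param pad Padding in degrees around the data hull (default 0.5).
#' @param bbox Optional `c(lat_min, lat_max, lon_min, lon_max)` overriding
#'   the fit's bounding box.
#' @return A numeric vector (points) or a `data.frame` with `latitude`,
#'   `longitude`, `value` (lattice).
#' @export
evaluate_surface <- function(fit, lat = NULL, lon = NULL, grid_n = 100,
                             pad = 0.5, bbox = NULL) {
  beta <- if (inherits(fit, "trend_surface")) fit$coefficients else {
    stopifnot(length(fit) == 6)
    as.numeric(fit)
  }
  if (!is.null(lat)) {
    stopifnot(length(lat) == length(lon))
    return(.eval_poly(beta, lat, lon))
  }
  if (is.null(bbox)) {
    if (!inherits(fit, "trend_surface")) {
      stop("bbox required when evaluating bare coefficients on a lattice",
           call. = FALSE)
    }
    bbox <- c(fit$bbox["lat_min"] - pad, fit$bbox["lat_max"] + pad,
              fit$bbox["lon_min"] - pad, fit$bbox["lon_max"] + pad)
  }
  lats <- seq(bbox[1], bbox[2], length.out = grid_n)
  lons <- seq(bbox[3], bbox[4], length.out = grid_n)
  g <- expand.grid(latitude = lats, longitude = lons)
  g$value <- .eval_poly(beta, g$latitude, g$longitude)
  g
}

#' Attach provenance coordinates to trial records
#'
#' Tags each tree or wood sample with its provenance's latitude/longitude so
#' individual observations can enter [fit_trend_surface()].
#'
#' @param records Growth- or wood-schema records.
#' @param locations Provenance table with `code`, `latitude`, `longitude`.
#' @return `records` with `latitude` and `longitude` columns.
#' @export
attach_coordinates <- function(records, locations) {
  i <- match(records$provenance, locations$code)
  if (anyNA(i)) {
    stop("provenance code(s) without coordinates: ",
         paste(unique(records$provenance[is.na(i)]), collapse = ", "),
         call. = FALSE)
  }
  records$latitude <- locations$latitude[i]
  records$longitude <- locations$longitude[i]
  records
}
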