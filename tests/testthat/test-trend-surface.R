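make_surface_data <- function(n = 60, beta = c(2, 0.5, -0.3, 0.02, -0.01, 0.005),
                              sd = 0, seed = 1) {
  set.seed(seed)
  lat <- runif(n, 20, 26)
  lon <- runif(n, 97, 114)
  z <- beta[1] + beta[2] * lat + beta[3] * lon + beta[4] * lat^2 +
    beta[5] * lon^2 + beta[6] * lat * lon + rnorm(n, sd = sd)
  data.frame(latitude = lat, longitude = lon, value = z)
}

test_that("noiseless quadratic data are recovered exactly", {
  beta <- c(2, 0.5, -0.3, 0.02, -0.01, 0.005)
  d <- make_surface_data(beta = beta, sd = 0)
  fit <- suppressWarnings(fit_trend_surface(d))
  expect_equal(unname(fit$coefficients), beta, tolerance = 1e-6)
  expect_equal(fit$r2, 1, tolerance = 1e-9)
})

test_that("a constant response gives zero fit and p-value one", {
  d <- make_surface_data()
  d$value <- 4.2
  fit <- suppressWarnings(fit_trend_surface(d))
  expect_equal(fit$r2, 0)
  expect_equal(fit$p_value, 1)
})

test_that("OLS matches a brute-force normal-equations oracle", {
  for (s in 1:5) {
    d <- make_surface_data(n = 50, sd = 1.5, seed = s)
    fit <- suppressWarnings(fit_trend_surface(d))
    M <- with(d, cbind(1, latitude, longitude, latitude^2, longitude^2,
                       latitude * longitude))
    beta_o <- solve(crossprod(M), crossprod(M, d$value))
    # the raw quadratic basis is ill-conditioned, so coefficient agreement
    # between QR and the squared normal equations is limited by the oracle
    expect_equal(unname(fit$coefficients), unname(drop(beta_o)),
                 tolerance = 1e-6)
    # the well-conditioned summaries agree to near machine precision
    res <- d$value - drop(M %*% beta_o)
    r2_o <- 1 - sum(res^2) / sum((d$value - mean(d$value))^2)
    expect_equal(fit$r2, r2_o, tolerance = 1e-10)
    f_o <- (r2_o / 5) / ((1 - r2_o) / (nrow(d) - 6))
    expect_equal(fit$p_value, pf(f_o, 5, nrow(d) - 6, lower.tail = FALSE),
                 tolerance = 1e-10)
  }
})

test_that("fitted values at training points reproduce the R-squared split", {
  d <- make_surface_data(n = 80, sd = 2, seed = 3)
  fit <- suppressWarnings(fit_trend_surface(d))
  pred <- evaluate_surface(fit, lat = d$latitude, lon = d$longitude)
  rss <- sum((d$value - pred)^2)
  tss <- sum((d$value - mean(d$value))^2)
  expect_equal(rss, (1 - fit$r2) * tss, tolerance = 1e-8)
})

test_that("adding a constant shifts only the intercept", {
  d <- make_surface_data(n = 50, sd = 1, seed = 4)
  f1 <- suppressWarnings(fit_trend_surface(d))
  d$value <- d$value + 11
  f2 <- suppressWarnings(fit_trend_surface(d))
  expect_equal(f2$coefficients[-1], f1$coefficients[-1], tolerance = 1e-8)
  expect_equal(unname(f2$coefficients[1] - f1$coefficients[1]), 11,
               tolerance = 1e-8)
  expect_equal(f2$r2, f1$r2, tolerance = 1e-9)
})

test_that("degenerate geometries are rejected", {
  d <- make_surface_data(n = 5)
  expect_error(fit_trend_surface(d), "at least 7")
  d <- data.frame(latitude = rep(c(20, 21, 22), 4),
                  longitude = rep(c(100, 101, 102), 4))
  d$value <- rnorm(12)
  # three collinear locations: quadratic basis is rank deficient
  expect_error(fit_trend_surface(d), "rank-deficient|distinct")
})

test_that("surface evaluation reproduces the published growth surface", {
  ref <- reference_table("trend_surface")
  dbh <- ref[ref$trait == "DBH", ]
  beta <- as.numeric(dbh[, c("b0", "b1", "b2", "b3", "b4", "b5")])
  val <- evaluate_surface(beta, lat = 22.85, lon = 108.40)
  expect_lt(abs(val - 13.05), 0.01)

  expect_equal(evaluate_surface(rep(0, 6), lat = c(20, 25), lon = c(100, 110)),
               c(0, 0))
  g <- evaluate_surface(c(3, 0, 0, 0, 0, 0), grid_n = 7,
                        bbox = c(20, 26, 97, 114))
  expect_equal(nrow(g), 49)
  expect_true(all(g$value == 3))
})

test_that("coordinates attach by provenance code", {
  loc <- reference_table("locations")
  rec <- data.frame(provenance = c("GXNN", "YNMS"), tree = 1:2)
  out <- attach_coordinates(rec, loc)
  expect_equal(out$latitude, c(22.85, 24.20))
  rec$provenance[1] <- "ZZZZ"
  expect_error(attach_coordinates(rec, loc), "ZZZZ")
})
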