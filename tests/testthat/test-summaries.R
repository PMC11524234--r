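test_that("descriptive statistics match hand computation", {
  rec <- data.frame(provenance = rep("A", 3), tree = 1:3, y = c(1, 2, 3))
  d <- provenance_descriptives(rec, "y")
  a <- d[d$provenance == "A", ]
  expect_equal(a$mean, 2)
  expect_equal(a$cv, 50)
  expect_equal(a$se, 1 / sqrt(3), tolerance = 1e-10)
  expect_equal(c(a$min, a$max), c(1, 3))
})

test_that("constant traits give zero CV and degenerate range", {
  rec <- data.frame(provenance = rep(c("A", "B"), each = 4), tree = 1,
                    y = 7)
  d <- provenance_descriptives(rec, "y")
  expect_true(all(d$cv[d$provenance != "Overall"] == 0))
  expect_true(all(d$min == 7 & d$max == 7))
})

test_that("descriptives are invariant to record order and use provenance means overall", {
  rec <- make_growth_records(p = 4, b = 3, n = 3, seed = 8, survival = 0.9)
  d1 <- provenance_descriptives(rec, "dbh")
  d2 <- provenance_descriptives(rec[sample(nrow(rec)), ], "dbh")
  expect_equal(d1, d2)
  ov <- d1[d1$provenance == "Overall", ]
  pm <- d1$mean[d1$provenance != "Overall"]
  expect_equal(ov$mean, mean(pm))
  expect_equal(ov$se, sd(pm) / sqrt(length(pm)))
})

test_that("variation summary averages CVs and finds the widest fold", {
  d <- data.frame(provenance = c("A", "B"), n = 5, mean = c(10, 20),
                  se = 1, min = c(2, 5), max = c(8, 30),
                  cv = c(10, 30), flagged = FALSE)
  s <- trait_variation_summary(d)
  expect_equal(s$mean_cv, 20)
  # B has the widest absolute range (25 vs 6) -> fold 30/5
  expect_equal(s$fold_ratio, 6)
  expect_equal(s$widest_range_provenance, "B")

  d1 <- d[1, ]
  expect_equal(trait_variation_summary(d1)$mean_cv, 10)

  d$min[2] <- 0
  expect_warning(s2 <- trait_variation_summary(d), "skipped")
  expect_equal(s2$widest_range_provenance, "A")
})

test_that("Duncan letters collapse for identical means and split clear ones", {
  rec <- data.frame(provenance = rep(c("A", "B", "C"), each = 4), tree = 1,
                    y = rep(5, 12) + rep(c(0.001, -0.001, 0), 4))
  out <- duncan_mrt(rec, "y")
  expect_true(all(out$table$letters == "a"))

  set.seed(1)
  rec2 <- data.frame(provenance = rep(c("A", "B"), each = 40), tree = 1,
                     y = c(rnorm(40, 10), rnorm(40, 20)))
  out2 <- duncan_mrt(rec2, "y")
  expect_equal(length(unique(out2$table$letters)), 2)
})

test_that("the two-group Duncan decision equals the pooled t-test", {
  # q*(alpha, 2, df) = t(alpha/2, df) * sqrt(2), so at k = 2 the range test
  # is algebraically a pooled two-sample t-test at level alpha
  for (s in 1:40) {
    set.seed(s)
    n1 <- sample(4:9, 1); n2 <- sample(4:9, 1)
    y1 <- rnorm(n1, 0); y2 <- rnorm(n2, 0.8)
    rec <- data.frame(provenance = rep(c("A", "B"), c(n1, n2)), tree = 1,
                      y = c(y1, y2))
    out <- duncan_mrt(rec, "y", alpha = 0.05)
    split <- length(unique(out$table$letters)) == 2
    # pooled t-test with the harmonic-mean n convention used by the MRT
    p_t <- t.test(y1, y2, var.equal = TRUE)$p.value
    ms_e <- ((n1 - 1) * var(y1) + (n2 - 1) * var(y2)) / (n1 + n2 - 2)
    n_e <- 2 / (1 / n1 + 1 / n2)
    t_stat <- abs(mean(y1) - mean(y2)) / sqrt(2 * ms_e / n_e)
    split_t <- t_stat > qt(0.975, n1 + n2 - 2)
    expect_identical(split, split_t)
    if (n1 == n2) expect_identical(split, p_t < 0.05)
  }
})

test_that("Duncan letters are contiguous over the ranked means", {
  for (s in 1:20) {
    set.seed(100 + s)
    p <- sample(3:7, 1)
    rec <- data.frame(provenance = rep(letters[1:p], each = 6), tree = 1,
                      y = rnorm(6 * p) + rep(runif(p, 0, 3), each = 6))
    out <- duncan_mrt(rec, "y")
    tab <- out$table
    for (ch in unique(strsplit(paste(tab$letters, collapse = ""), "")[[1]])) {
      has <- grepl(ch, tab$letters)
      expect_true(all(diff(which(has)) == 1))  # one contiguous run
    }
    expect_true(all(nchar(tab$letters) >= 1))
  }
})
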