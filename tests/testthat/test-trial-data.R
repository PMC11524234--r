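test_that("growth tables read with dead trees retained and validated", {
  f <- tempfile(fileext = ".csv")
  write_growth_fixture(f)
  rec <- read_trial_table(f, "growth")
  expect_equal(nrow(rec), 4)
  expect_equal(sum(rec$alive), 3)
  expect_true(all(is.na(rec$dbh[!rec$alive])))
  expect_identical(attr(rec, "schema"), "growth")
})

test_that("read/write round-trip is the identity for all three schemas", {
  f <- tempfile(fileext = ".csv")

  g <- write_growth_fixture(f)
  rec <- read_trial_table(f, "growth")
  f2 <- tempfile(fileext = ".csv")
  write_trial_table(rec, f2)
  rec2 <- read_trial_table(f2, "growth")
  expect_equal(rec2, rec, ignore_attr = TRUE)

  wood <- data.frame(provenance = c("AA", "BB"), tree = 1:2,
                     fl = c(1500, 1400), fd = c(33, 31),
                     vl = c(700, 650), vd = c(170, 160),
                     wbd = c(0.33, 0.35), cr = c(50, 52))
  write_trial_table(wood, f)
  w1 <- read_trial_table(f, "wood")
  write_trial_table(w1, f2)
  expect_equal(read_trial_table(f2, "wood"), w1, ignore_attr = TRUE)

  prov <- data.frame(code = c("AA", "BB"), latitude = c(22.4, 24.1),
                     longitude = c(106.8, 98.9), altitude = c(269, 913))
  write_trial_table(prov, f)
  p1 <- read_trial_table(f, "provenance")
  write_trial_table(p1, f2)
  expect_equal(read_trial_table(f2, "provenance"), p1, ignore_attr = TRUE)
})

test_that("tab-separated input is accepted on read", {
  f <- tempfile(fileext = ".tsv")
  writeLines(c("provenance\tblock\ttree\talive\tdbh\theight",
               "AA\t1\t1\tTRUE\t10.5\t9.2"), f)
  rec <- read_trial_table(f, "growth")
  expect_equal(rec$dbh, 10.5)
})

test_that("schema violations raise informative errors", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("provenance,block,tree,alive,dbh,height",
               "AA,1,1,TRUE,10.2,9.1",
               "AA,2,1,TRUE,abc,10.0"), f)
  expect_error(read_trial_table(f, "growth"), "line 3")
  expect_error(read_trial_table(f, "growth"), "dbh")

  writeLines(c("provenance,block,tree,alive,dbh",
               "AA,1,1,TRUE,10.2"), f)
  expect_error(read_trial_table(f, "growth"), "height")

  write_growth_fixture(f)
  prov <- data.frame(code = "ZZ", latitude = 20, longitude = 100)
  expect_error(read_trial_table(f, "growth", provenances = prov),
               "AA")
})

test_that("live trees must carry positive measurements", {
  f <- tempfile(fileext = ".csv")
  writeLines(c("provenance,block,tree,alive,dbh,height",
               "AA,1,1,TRUE,10.2,9.1",
               "AA,2,1,TRUE,NA,10.0"), f)
  expect_error(read_trial_table(f, "growth"), "line 3")
})

test_that("validate_trial tabulates the unbalanced design", {
  rec <- expand.grid(tree = 1:3, block = 1:2, provenance = c("AA", "BB"),
                     stringsAsFactors = FALSE)
  rec$alive <- TRUE
  rec$dbh <- 10; rec$height <- 9
  des <- validate_trial(rec)
  expect_equal(des$p, 2)
  expect_equal(des$b, 2)
  expect_true(all(des$n_ij == 3))

  rec$alive[1] <- FALSE
  des2 <- validate_trial(rec)
  expect_equal(sort(as.vector(des2$n_ij)), c(2, 3, 3, 3))
  expect_equal(des2$n, 3)

  # counts are invariant to record order
  des3 <- validate_trial(rec[sample(nrow(rec)), ])
  expect_equal(des3$n_ij, des2$n_ij)
})

test_that("a provenance alive in a single block is flagged", {
  rec <- data.frame(provenance = c("AA", "AA", "BB", "BB"),
                    block = c(1, 2, 1, 2), tree = 1,
                    alive = c(TRUE, TRUE, TRUE, FALSE),
                    dbh = c(10, 11, 9, NA), height = c(9, 9, 8, NA))
  expect_warning(des <- validate_trial(rec), "BB")
  expect_equal(des$single_block_provenances, "BB")
})

test_that("mean surviving plot count matches the binomial expectation", {
  counts <- vapply(1:25, function(s) {
    rec <- simulate_trial(simulation_config(seed = s))$records
    mean(validate_trial(rec)$n_ij)
  }, numeric(1))
  expect_equal(mean(counts), 4, tolerance = 0.02)
})
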