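test_that("container validation rejects degenerate and non-integer input", {
  expect_error(count_table_2x2(0, 0, 0, 0), "total")
  expect_error(count_table_2x2(-1, 0, 0, 5), "non-negative")
  expect_error(count_table_2x2(1.5, 0, 0, 5), "integers")
  expect_error(ordinal_counts(c(1, 2), c(0, 0)), "positive")
  expect_error(ordinal_counts(5, 4), "k >= 2")
  expect_error(verification_counts(c(1, 2), c(1, 2), 0), "equal length")
  expect_error(score_set(c(1, 2), c(1, 1)), "per disease label")
  expect_error(score_set(c(1, Inf), c(1, 0)), "finite")
})

test_that("read_table parses each schema and flags malformed files", {
  p <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("#dtabayes schema: 2x2", "test,disease,count",
               "0,0,327", "0,1,208", "1,0,115", "1,1,818"), p)
  tab <- read_table(p)
  expect_s3_class(tab, "count_table_2x2")
  expect_equal(as.vector(t(tab$counts)), c(327, 208, 115, 818))

  writeLines(c("#dtabayes schema: 2x2", "test,disease,count",
               "0,0,0", "0,1,0", "1,0,0", "1,1,0"), p)
  expect_error(read_table(p), "total")

  writeLines(c("#dtabayes schema: 2x2", "test,disease,count",
               "0,0,1", "0,1,2", "1,1,3"), p)
  expect_error(read_table(p), "cell")

  writeLines(c("#dtabayes schema: 2x2", "wrong,cols", "1,2"), p)
  expect_error(read_table(p), "lacks column")

  expect_error(read_table(file.path(tempdir(), "nope.csv")), "no such file")
})

test_that("mammogram fixture matches its published ordinal counts", {
  x <- load_fixture("mammogram")
  expect_equal(x$k, 5)
  expect_equal(x$diseased, c(1, 0, 6, 11, 12))
  expect_equal(x$nondiseased, c(9, 2, 11, 8, 0))
})

test_that("write/read round-trip reproduces every container exactly", {
  fixtures <- list_fixtures()
  for (nm in fixtures) {
    x <- load_fixture(nm)
    p <- withr::local_tempfile(fileext = ".csv")
    write_table(x, p)
    y <- read_table(p)
    attributes(x)[c("provenance", "derived")] <- NULL
    expect_equal(y, x, info = nm)
  }
})

test_that("bundled fixtures re-validate against their study totals", {
  expect_equal(sum(load_fixture("est_cad")$counts), 1468)
  expect_equal(sum(load_fixture("scintigraphy")$m), 670)
  expect_equal(sum(load_fixture("mammography_verification")$m), 1509)
  expect_equal(sum(load_fixture("strongyloides")$counts), 162)
  lung <- load_fixture("lung_ct_mri")
  expect_equal(sum(lung$diseased), 995)
  expect_equal(sum(lung$nondiseased), 435)
  sten <- load_fixture("stenosis")
  expect_equal(sum(sten$diseased), 58)
  expect_equal(sum(sten$nondiseased), 236)
  diab <- load_fixture("diabetes")
  expect_equal(sum(diab$labels == 1), 59)
  expect_equal(sum(diab$labels == 0), 19)
  # the 59/19 split reproduces the published group means
  expect_equal(mean(diab$values[diab$labels == 0]), 107.5, tolerance = 1e-3)
  expect_equal(mean(diab$values[diab$labels == 1]) -
                 mean(diab$values[diab$labels == 0]), 16.13, tolerance = 1e-2)
})

test_that("unknown fixture names raise a lookup error listing options", {
  expect_error(load_fixture("nonexistent"), "available")
  expect_true("est_cad" %in% list_fixtures())
  expect_match(attr(load_fixture("scintigraphy"), "provenance"), "scintigraphy",
               ignore.case = TRUE)
})

test_that("the reconstructed stenosis non-diseased cells are the unique
           non-negative table reproducing the published posterior means", {
  # search over the plausible ranges implied by loose bounds on the
  # published means, then require agreement within half a printed unit
  target <- c(fpf1 = 0.2918, fpf2 = 0.1668, fpf_bn = 0.1627, fpf_bp = 0.2959)
  hits <- NULL
  for (n11 in 30:45) for (n01 in 0:8) for (n10 in 20:40) {
    n00 <- 236 - n11 - n01 - n10
    if (n00 < 0) next
    a <- c(n00, n01, n10, n11) + 1
    v <- c((a[3] + a[4]) / 240, (a[2] + a[4]) / 240,
           a[4] / 240, (a[2] + a[3] + a[4]) / 240)
    if (all(abs(v - target) < 0.0025)) hits <- rbind(hits, c(n00, n01, n10, n11))
  }
  expect_equal(nrow(hits), 1)
  expect_equal(as.vector(hits), c(168, 0, 30, 38))
  sten <- load_fixture("stenosis")
  expect_equal(as.vector(t(sten$nondiseased)), c(168, 0, 30, 38))
  expect_true(attr(sten, "derived"))
})
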