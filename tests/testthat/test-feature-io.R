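test_that("a plain CSV feature list parses into a validated table", {
  path <- withr::local_tempfile(fileext = ".csv")
  areas <- matrix(round(runif(36, 1e3, 1e5)), 3, 12,
                  dimnames = list(NULL, paste0("S", 1:12)))
  df <- data.frame(mz = c(339.07, 679.15, 121.03), rt = c(5.1, 5.1, 2.2),
                   annotation = c("a", "", "c"))
  write.csv(cbind(df, areas), path, row.names = FALSE)
  ft <- readFeatureTable(path, mode = "negative")
  expect_s4_class(ft, "FeatureTable")
  expect_equal(dim(ft), c(3L, 12L))
  expect_equal(unname(mz(ft)), df$mz)
  expect_equal(ionMode(ft), "negative")
  expect_equal(colnames(ft), paste0("S", 1:12))
})

test_that("defective rows are rejected with row-indexed diagnostics", {
  path <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(mz = c(100, 200, -5, 400), rt = c(1, 2, 3, 4),
                       S1 = c(10, -3, 10, 10), S2 = c(5, 5, 5, 5)),
            path, row.names = FALSE)
  expect_warning(ft <- readFeatureTable(path, mode = "positive"),
                 "row 2 \\(negative area\\).*row 3 \\(m/z must be > 0\\)")
  expect_equal(nrow(ft), 2L)

  # missing mandatory column is a format error naming the column
  path2 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(mass = 100, rt = 1, S1 = 5), path2, row.names = FALSE)
  expect_error(readFeatureTable(path2, mode = "positive"), "'mz' not found")

  # duplicated m/z + RT rows are kept, with a warning
  path3 <- withr::local_tempfile(fileext = ".csv")
  write.csv(data.frame(mz = c(100, 100), rt = c(1, 1), S1 = c(5, 6),
                       S2 = c(2, 3), S3 = c(1, 1)), path3, row.names = FALSE)
  expect_warning(ft3 <- readFeatureTable(path3, mode = "positive"),
                 "duplicated")
  expect_equal(nrow(ft3), 2L)

  # blank area cells read as zero
  path4 <- withr::local_tempfile(fileext = ".csv")
  writeLines(c("mz,rt,S1,S2,S3", "100,1,,5,7"), path4)
  ft4 <- readFeatureTable(path4, mode = "positive")
  expect_equal(unname(areas(ft4)[1, ]), c(0, 5, 7))
})

test_that("read -> write -> read is the identity on generator output", {
  ds <- makeSyntheticDataset(syntheticSpec(nMetabolites = 6, seed = 42,
                                           areaNoiseCv = 0.1))
  dir <- withr::local_tempdir()
  paths <- writeSyntheticDataset(ds, dir)
  ft1 <- readFeatureTable(paths[["features"]], mode = "negative")
  path2 <- file.path(dir, "again.csv")
  writeFeatureTable(ft1, path2)
  ft2 <- readFeatureTable(path2, mode = "negative")
  expect_equal(featureIds(ft2), featureIds(ft1))
  expect_equal(mz(ft2), mz(ft1))
  expect_equal(rt(ft2), rt(ft1))
  expect_equal(areas(ft2), areas(ft1))
  expect_equal(annotations(ft2), annotations(ft1))
  # and the first read matches the in-memory generator output
  expect_equal(unname(mz(ft1)), unname(mz(ds$table)))
})

test_that("minimum-area filter keeps max-area >= threshold, inclusively", {
  areas <- rbind(c(8999, 10), c(9000, 1), c(9001, 0.5))
  ft <- simpleTable(mz = c(100, 200, 300), rt = c(1, 2, 3), areas = areas)
  expect_equal(nrow(filterMinArea(ft, 9000)), 2L)
  expect_equal(featureIds(filterMinArea(ft, 9000)), c("F0002", "F0003"))
  expect_equal(filterMinArea(ft, 0), ft)       # identity at 0

  # idempotent, monotone, equal to a brute-force scan on a random fixture
  set.seed(7)
  big <- simpleTable(mz = runif(40, 100, 900), rt = runif(40, 0, 10),
                     areas = matrix(rexp(40 * 6, 1e-4), 40, 6))
  thr <- 9000
  once <- filterMinArea(big, thr)
  expect_equal(featureIds(filterMinArea(once, thr)), featureIds(once))
  expect_equal(featureIds(once),
               featureIds(big)[apply(areas(big), 1, max) >= thr])
  for (t2 in c(2e4, 5e4))
    expect_true(all(featureIds(filterMinArea(big, t2)) %in% featureIds(once)))
})

test_that("invalid tables are refused by the validity method", {
  expect_error(FeatureTable(mz = -1, rt = 1, areas = matrix(1, 1, 3),
                            mode = "positive"), "m/z")
  expect_error(FeatureTable(mz = 100, rt = -1, areas = matrix(1, 1, 3),
                            mode = "positive"), "retention")
  expect_error(FeatureTable(mz = 100, rt = 1, areas = matrix(0, 1, 3),
                            mode = "positive"), "positive area")
  expect_error(FeatureTable(mz = c(1, 2), rt = c(1, 2), ids = c("a", "a"),
                            areas = matrix(1, 2, 3), mode = "positive"),
               "unique")
})
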