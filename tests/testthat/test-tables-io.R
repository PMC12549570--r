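toyFeatures <- function() {
  list(features = data.frame(
         feature_id = c("F1", "F2", "F3"),
         mz = c(400.1234, 512.5, 633.3),
         charge = c(2L, 3L, 2L),
         rt = c(12.5, 30.1, 44.9),
         has_msms = c(TRUE, TRUE, FALSE),
         sequence = c("PEPTIDEK", NA, NA),
         stringsAsFactors = FALSE),
       abundance = matrix(c(1e5, NA, 3e5, 2e5, 4e4, NA),
                          nrow = 3,
                          dimnames = list(c("F1", "F2", "F3"),
                                          c("S1", "S2"))))
}

test_that("feature tables round-trip through CSV and TSV", {
  toy <- toyFeatures()
  for (ext in c(".csv", ".tsv")) {
    path <- tempfile(fileext = ext)
    writeFeatureTable(toy$features, toy$abundance, path)
    back <- readFeatureTable(path)
    expect_equal(back$features, toy$features)
    expect_equal(back$abundance, toy$abundance)
  }
})

test_that("missing abundances stay NA, never zero", {
  toy <- toyFeatures()
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(toy$features, toy$abundance, path)
  back <- readFeatureTable(path)
  expect_true(is.na(back$abundance["F2", "S1"]))
  expect_false(any(back$abundance == 0, na.rm = TRUE))
})

test_that("a vendor-style dialect maps onto canonical columns", {
  toy <- toyFeatures()
  wide <- cbind(toy$features, as.data.frame(toy$abundance))
  names(wide)[1:4] <- c("Compound", "m/z", "Charge", "Retention time (min)")
  path <- tempfile(fileext = ".csv")
  write.csv(wide, path, row.names = FALSE, na = "")
  back <- readFeatureTable(path, dialect = c(
    feature_id = "Compound", mz = "m/z", charge = "Charge",
    rt = "Retention time (min)"))
  expect_equal(back$features$feature_id, toy$features$feature_id)
  expect_equal(back$abundance, toy$abundance)
  expect_error(readFeatureTable(path, dialect = c(feature_id = "Nope")),
               "dialect column")
})

test_that("feature validation rejects malformed input", {
  toy <- toyFeatures()
  path <- tempfile(fileext = ".csv")
  bad <- toy$features; bad$mz[1] <- -5
  writeFeatureTable(bad, toy$abundance, path)
  expect_error(readFeatureTable(path), "non-positive m/z")
  bad <- toy$features; bad$rt[2] <- -1
  writeFeatureTable(bad, toy$abundance, path)
  expect_error(readFeatureTable(path), "negative retention")
  ab <- toy$abundance; ab[1, 1] <- -10
  writeFeatureTable(toy$features, ab, path)
  expect_error(readFeatureTable(path), "negative abundance")
  dup <- toy$features; dup$feature_id <- c("F1", "F1", "F3")
  ab2 <- toy$abundance; rownames(ab2) <- dup$feature_id
  writeFeatureTable(dup, ab2, path)
  expect_error(readFeatureTable(path), "duplicate feature")
  writeLines("feature_id,mz\nF1,400", path)
  expect_error(readFeatureTable(path), "required column")
  expect_error(readFeatureTable(tempfile()), "not found")
})

test_that("sample reconciliation against metadata is enforced", {
  toy <- toyFeatures()
  path <- tempfile(fileext = ".csv")
  writeFeatureTable(toy$features, toy$abundance, path)
  meta <- data.frame(sample_id = c("S1", "S2"),
                     group = c("RFposCCPpos_RA", "RFneg_control"),
                     experiment_id = "e1", stringsAsFactors = FALSE)
  expect_silent(readFeatureTable(path, samples = meta))
  expect_error(readFeatureTable(path, samples = meta[1, , drop = FALSE]),
               "reconciliation error")
})

test_that("identification tables validate engine/score consistency", {
  path <- tempfile(fileext = ".csv")
  ok <- data.frame(feature_id = c("F1", "F2"),
                   sequence = c("PEPTIDEK", "SLSPGERATL"),
                   engine = c("database_search", "de_novo"),
                   score = c(45.2, NA), alc = c(NA, 92.1),
                   protein_accessions = c("IGHV3-11", ""),
                   stringsAsFactors = FALSE)
  write.csv(ok, path, row.names = FALSE, na = "")
  back <- readIdentTable(path)
  expect_equal(back$score, c(45.2, NA))
  expect_equal(back$alc, c(NA, 92.1))
  bad <- ok; bad$engine[1] <- "mascot"
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readIdentTable(path), "unknown engine")
  bad <- ok; bad$score[1] <- NA
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readIdentTable(path), "engine/score mismatch")
  bad <- ok; bad$alc[1] <- 50
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readIdentTable(path), "exactly one")
  bad <- ok; bad$alc[2] <- 140
  write.csv(bad, path, row.names = FALSE, na = "")
  expect_error(readIdentTable(path), "ALC")
})

test_that("sample metadata validates the group enumeration", {
  path <- tempfile(fileext = ".csv")
  meta <- data.frame(sample_id = c("S1", "S2"),
                     group = c("RFposCCPpos_RA", "RFneg_control"),
                     stringsAsFactors = FALSE)
  write.csv(meta, path, row.names = FALSE)
  back <- readSampleMeta(path)
  expect_equal(back$experiment_id, c("exp1", "exp1"))
  meta$group[2] <- "healthy"
  write.csv(meta, path, row.names = FALSE)
  expect_error(readSampleMeta(path), "unknown group")
  meta$group[2] <- "RFneg_control"; meta$sample_id[2] <- "S1"
  write.csv(meta, path, row.names = FALSE)
  expect_error(readSampleMeta(path), "duplicate sample")
})

test_that("buildExperiment assembles a coherent SummarizedExperiment", {
  toy <- toyFeatures()
  meta <- data.frame(sample_id = c("S1", "S2"),
                     group = c("RFposCCPpos_RA", "RFneg_control"),
                     experiment_id = "e1", stringsAsFactors = FALSE)
  se <- buildExperiment(toy$features, toy$abundance, meta)
  expect_s4_class(se, "SummarizedExperiment")
  expect_equal(dim(se), c(3L, 2L))
  expect_equal(SummarizedExperiment::assay(se, "abundance"),
               toy$abundance)
  expect_equal(SummarizedExperiment::colData(se)$group,
               meta$group)
  expect_error(buildExperiment(toy$features, toy$abundance, meta[1, ]),
               "reconciliation error")
})

test_that("writeResultTables writes one CSV per table", {
  dir <- tempfile()
  paths <- writeResultTables(dir, list(a = data.frame(x = 1:3),
                                       b = data.frame(y = "s")))
  expect_true(all(file.exists(file.path(dir, c("a.csv", "b.csv")))))
})
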