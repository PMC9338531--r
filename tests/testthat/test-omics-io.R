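# readers, filters, imputation, pairing

write_toy_tsv <- function(lines) {
  f <- withr::local_tempfile(fileext = ".tsv", .local_envir = parent.frame())
  writeLines(lines, f)
  f
}

test_that("read_omics_matrix parses values, missing cells, and rejects bad input", {
  f <- write_toy_tsv(c("gene\ts1\ts2", "g1\t1.5\t2", "g2\tNA\t4"))
  m <- read_omics_matrix(f, "mrna")
  expect_equal(m$values["g1", ], c(s1 = 1.5, s2 = 2))
  expect_true(is.na(m$values["g2", "s1"]))

  fdup <- write_toy_tsv(c("gene\ts1", "g1\t1", "g1\t2"))
  expect_error(read_omics_matrix(fdup, "mrna"), "g1")

  fbad <- write_toy_tsv(c("gene\ts1", "g1\tabc"))
  expect_error(read_omics_matrix(fbad, "mrna"), "non-numeric")

  fragged <- write_toy_tsv(c("gene\ts1\ts2", "g1\t1\t2", "g2\t3"))
  expect_error(read_omics_matrix(fragged, "mrna"))
})

test_that("transform_abundance applies the layer transforms once", {
  v <- matrix(c(3, 7, 0, 15), 2, 2,
              dimnames = list(c("g1", "g2"), c("s1", "s2")))
  mr <- transform_abundance(omics_matrix(v, "mrna"))
  expect_equal(mr$values, log2(v + 1))
  expect_identical(transform_abundance(mr)$values, mr$values)
  pv <- matrix(c(2, 8, 4, 16), 2, 2, dimnames = dimnames(v))
  expect_equal(transform_abundance(omics_matrix(pv, "protein"))$values,
               log2(pv))
})

test_that("filter_low_abundance drops features below the median threshold", {
  v <- matrix(c(0, 0, 0, 5, 6, 7, 1, 1, 2, 10, 20, 30, 0.5, 0.6, 3), 5, 3,
              byrow = TRUE,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:3)))
  m <- omics_matrix(v, "mrna")
  expect_identical(rownames(filter_low_abundance(m, 0)$values),
                   rownames(v))
  f1 <- filter_low_abundance(m, 1)  # drops g1 (median 0) and g5 (median 0.6)
  expect_setequal(rownames(f1$values), c("g2", "g3", "g4"))
  # threshold at the 40th percentile of medians: brute-force check
  meds <- apply(v, 1, median)
  thr <- unname(quantile(meds, 0.4))
  fq <- filter_low_abundance(m, thr)
  expect_setequal(rownames(fq$values), names(meds)[meds >= thr])
  expect_error(filter_low_abundance(m, 100), "every feature")
})

test_that("filter_and_impute drops >20%-missing features and imputes by KNN mean", {
  # feature missing in 3/10 samples at max_missing_frac = 0.2 -> dropped
  v <- matrix(rnorm(50), 5, 10,
              dimnames = list(paste0("g", 1:5), paste0("s", 1:10)))
  v[1, 1:3] <- NA
  out <- filter_and_impute(omics_matrix(v, "protein", log2 = TRUE),
                           k_neighbors = 3)
  expect_false("g1" %in% rownames(out$values))
  expect_false(anyNA(out$values))
})

test_that("KNN imputation equals the hand-computed nearest-sample mean", {
  # 4 samples; s1 missing g1; distances computed on jointly observed rows
  v <- rbind(g1 = c(NA, 1, 5, 2),
             g2 = c(1, 1.1, 9, 1.3),
             g3 = c(2, 2.2, 7, 2.1),
             g4 = c(3, 2.9, 1, 3.2))
  colnames(v) <- paste0("s", 1:4)
  out <- filter_and_impute(omics_matrix(v, "protein", log2 = TRUE),
                           max_missing_frac = 0.3, k_neighbors = 2)
  # exhaustive distances from s1 on g2..g4: s2 and s4 are the two nearest
  d <- sapply(2:4, function(j) mean((v[2:4, 1] - v[2:4, j])^2))
  expect_equal(order(d)[1:2], c(1, 3))  # s2, s4
  expect_equal(out$values["g1", "s1"], mean(c(1, 2)))
  # identity when nothing is missing, idempotent on own output
  expect_identical(filter_and_impute(out, k_neighbors = 2)$values, out$values)
  expect_error(filter_and_impute(omics_matrix(v, "protein", log2 = TRUE),
                                 k_neighbors = 4), "k_neighbors")
})

test_that("build_paired_cohort intersects genes and samples", {
  p <- matrix(1, 3, 2, dimnames = list(c("A", "B", "C"), c("s1", "s2")))
  m <- matrix(2, 3, 3, dimnames = list(c("B", "C", "D"), c("s1", "s2", "s3")))
  meta <- data.frame(sample = c("s1", "s2", "s3"),
                     group = c("tumor", "normal", "normal"))
  co <- build_paired_cohort(p, m, meta)
  expect_setequal(co$genes, c("B", "C"))
  expect_setequal(co$samples, c("s1", "s2"))
  expect_equal(attr(co, "n_dropped_genes"), 2L)
  p2 <- matrix(1, 2, 2, dimnames = list(c("X", "Y"), c("s1", "s2")))
  expect_error(build_paired_cohort(p2, m, meta), "no shared genes")
})

test_that("rMATS tables parse IncLevel lists with NA and validate ranges", {
  f <- write_toy_tsv(c(
    paste("ID", "GeneID", "geneSymbol", "IncLevel1", "IncLevel2",
          "IncLevelDifference", "PValue", "FDR", sep = "\t"),
    paste("SE_1", "G1", "G1", "0.1,0.2,NA", "0.5,0.6", "-0.4", "0.01", "0.02",
          sep = "\t")))
  tab <- read_rmats_table(f, "SE")
  expect_equal(unname(tab$psi["SE_1", 1:3]), c(0.1, 0.2, NA))
  expect_equal(unname(tab$psi["SE_1", 4:5]), c(0.5, 0.6))
  expect_equal(unname(tab$groups),
               c("tumor", "tumor", "tumor", "control", "control"))

  fhdr <- write_toy_tsv(paste("ID", "GeneID", "geneSymbol", "IncLevel1",
                              "IncLevel2", "IncLevelDifference", "PValue",
                              "FDR", sep = "\t"))
  expect_equal(nrow(read_rmats_table(fhdr, "SE")$info), 0L)

  fbad <- write_toy_tsv(c(
    paste("ID", "GeneID", "geneSymbol", "IncLevel1", "IncLevel2",
          "IncLevelDifference", "PValue", "FDR", sep = "\t"),
    paste("SE_1", "G1", "G1", "0.1,oops", "0.5", "-0.4", "0.01", "0.02",
          sep = "\t")))
  expect_error(read_rmats_table(fbad, "SE"), "malformed")

  frange <- write_toy_tsv(c(
    paste("ID", "GeneID", "geneSymbol", "IncLevel1", "IncLevel2",
          "IncLevelDifference", "PValue", "FDR", sep = "\t"),
    paste("SE_1", "G1", "G1", "1.2", "0.5", "0.7", "0.01", "0.02",
          sep = "\t")))
  expect_error(read_rmats_table(frange, "SE"), "\\[0, 1\\]")
})

test_that("GMT and splicing-factor lists read and validate", {
  f <- write_toy_tsv(c("setA\tdesc\tg1\tg2\tg3", "setB\tdesc\tg4"))
  sets <- read_gmt(f)
  expect_equal(sets$setA, c("g1", "g2", "g3"))
  expect_equal(sets$setB, "g4")
  fdup <- write_toy_tsv(c("setA\td\tg1", "setA\td\tg2"))
  expect_error(read_gmt(fdup), "duplicate")
  fempty <- write_toy_tsv(c("setA\td\tg1", "setB\td"))
  expect_error(read_gmt(fempty), "empty")

  fsf <- write_toy_tsv(c("SF1", "SF2", "SF1", ""))
  expect_warning(sf <- read_sf_list(fsf), "1 duplicate")
  expect_equal(sf, c("SF1", "SF2"))
})
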