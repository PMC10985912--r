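test_that("asv_table validates and round-trips through TSV", {
  m <- toy_counts(matrix(c(3, 0, 1, 2, 5, 4), nrow = 3), prefix = "F")
  tab <- asv_table(m, "fungi")
  expect_s3_class(tab, "asv_table")
  expect_equal(dim(tab$counts), c(3L, 2L))

  path <- withr::local_tempfile(fileext = ".tsv")
  write_asv_table(tab, path)
  back <- read_asv_table(path, "fungi")
  expect_identical(back$counts, tab$counts)

  # transposed writing is recovered via the orientation flag
  tpath <- withr::local_tempfile(fileext = ".tsv")
  df <- data.frame(asv_id = colnames(m), t(m), check.names = FALSE)
  write.table(df, tpath, sep = "\t", quote = FALSE, row.names = FALSE)
  back_t <- read_asv_table(tpath, "fungi", orientation = "asvs_rows")
  expect_identical(back_t$counts, tab$counts)
})

test_that("invalid tables are rejected and zero columns dropped with warning", {
  m <- toy_counts(matrix(c(1, 2, 0, 0), nrow = 2))
  expect_warning(tab <- asv_table(m, "bacteria"), "all-zero")
  expect_identical(asv_ids(tab), "A001")

  bad <- toy_counts(matrix(c(-1, 2, 3, 4), nrow = 2))
  expect_error(asv_table(bad, "fungi"), "negative")
  frac <- matrix(c(1.5, 2, 3, 4), nrow = 2,
                 dimnames = list(c("S1", "S2"), c("A001", "A002")))
  expect_error(asv_table(frac, "fungi"), "integer")
  dup <- toy_counts(matrix(1:4, nrow = 2))
  rownames(dup) <- c("S1", "S1")
  expect_error(asv_table(dup, "fungi"), "duplicate sample")
  expect_error(asv_table(matrix(numeric(0), 0, 0), "fungi"), "empty")
})

test_that("core_asvs returns exactly the ASVs detected in every location", {
  # 10 ASVs, 4 seeded into all three locations; brute-force oracle check
  set.seed(11)
  n <- 9L
  meta <- toy_meta(n, conditions = "snow_free")
  m <- matrix(0L, n, 10L)
  core_idx <- c(1L, 4L, 7L, 9L)
  for (j in core_idx) m[c(1, 2, 3), j] <- 1L  # S1..S3 cover L1, L2, L3
  m[4, 2] <- 5L; m[5, 3] <- 2L; m[7, 5] <- 1L  # partial-location ASVs
  m <- toy_counts(m)
  tab <- suppressWarnings(asv_table(m, "fungi"))

  oracle <- colnames(m)[vapply(seq_len(ncol(m)), function(j) {
    all(vapply(unique(meta$location), function(loc) {
      any(m[meta$location == loc, j] > 0)
    }, logical(1)))
  }, logical(1))]
  oracle <- intersect(oracle, asv_ids(tab))
  expect_setequal(core_asvs(tab, meta), oracle)
  expect_setequal(core_asvs(tab, meta), colnames(m)[core_idx])

  # ASV present in 2 of 3 locations is not core
  expect_false("A002" %in% core_asvs(tab, meta))

  meta1 <- meta; meta1$location <- "L1"
  expect_error(core_asvs(tab, meta1), "single location")
})

test_that("core set is monotone under added counts", {
  set.seed(12)
  meta <- toy_meta(12L)
  m <- toy_counts(matrix(rbinom(12 * 8, 3, 0.25), 12L))
  tab <- suppressWarnings(asv_table(m, "fungi"))
  core0 <- core_asvs(tab, meta)
  m2 <- tab$counts
  m2[2, 3] <- m2[2, 3] + 5L   # adding counts never removes core status
  tab2 <- asv_table(m2, "fungi")
  expect_true(all(core0 %in% core_asvs(tab2, meta)))
})

test_that("relative abundance rows sum to one and errors name the sample", {
  tab <- asv_table(toy_counts(rbind(c(2, 2, 0), c(1, 2, 7))), "fungi")
  ra <- relative_abundance(tab)
  expect_equal(unname(rowSums(ra)), c(1, 1), tolerance = 1e-9)
  expect_equal(unname(ra[1, ]), c(0.5, 0.5, 0))
  expect_equal(unname(ra[2, ]), c(0.1, 0.2, 0.7))

  z <- toy_counts(rbind(c(1, 1, 1), c(0, 0, 0)))
  tabz <- asv_table(z, "fungi")
  expect_error(relative_abundance(tabz), "S2")
})

test_that("abundant_asvs_per_group follows the group-mean threshold", {
  n <- 12L
  meta <- toy_meta(n, locations = c("L1", "L2"))
  m <- matrix(90L, n, 1L)                 # ASV 1 fixed at 10% in all samples
  m <- cbind(m, matrix(270L, n, 3L))      # three ASVs at 30%
  m[, 1] <- 100L; m[, 2:4] <- 300L
  m <- toy_counts(m)
  tab <- asv_table(m, "fungi")

  res <- suppressWarnings(abundant_asvs_per_group(tab, meta, 0.07))
  expect_true(all(vapply(res, function(ids) "A001" %in% ids, logical(1))))

  res0 <- suppressWarnings(abundant_asvs_per_group(tab, meta, 0))
  expect_true(all(vapply(res0, function(ids) setequal(ids, asv_ids(tab)),
                         logical(1))))
  # threshold zero is a superset of any positive threshold
  expect_true(all(mapply(function(lo, hi) all(hi %in% lo), res0, res)))

  res1 <- suppressWarnings(abundant_asvs_per_group(tab, meta, 1.0))
  expect_true(all(lengths(res1) == 0L))
})

test_that("condition-exclusive core partitioning matches planted pattern", {
  n <- 12L
  meta <- toy_meta(n, locations = c("L1", "L2"))
  sf <- meta$condition == "snow_free"
  m <- matrix(0L, n, 5L)
  m[sf, 1] <- 3L; m[sf, 2] <- 1L       # snow-free only
  m[!sf, 3] <- 2L                      # snow-covered only
  m[, 4] <- 1L; m[, 5] <- 2L           # both
  m <- toy_counts(m)
  tab <- asv_table(m, "fungi")
  core <- asv_ids(tab)
  part <- condition_exclusive_core(tab, meta, core)
  expect_setequal(part$asv_id[part$exclusivity == "snow_free_only"],
                  c("A001", "A002"))
  expect_identical(part$asv_id[part$exclusivity == "snow_covered_only"],
                   "A003")
  expect_setequal(part$asv_id[part$exclusivity == "both"], c("A004", "A005"))
  expect_equal(part$n_snow_free[part$asv_id == "A001"], sum(sf))
  expect_error(condition_exclusive_core(tab, meta, c(core, "NOPE")),
               "not in the table")
})

test_that("taxonomy and metadata readers normalise input", {
  tf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("asv_id\tphylum\tgenus",
               "F001\tAscomycota\t",
               "F002\tBasidiomycota\tRussula"), tf)
  tax <- read_taxonomy(tf)
  expect_true(is.na(tax$genus[1]))
  expect_true(all(c("class", "species") %in% names(tax)))

  mf <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("sample_id\tlocation\tcondition",
               "S1\tL1\tsnow-free",
               "S2\tL2\tsnow covered"), mf)
  meta <- read_sample_metadata(mf)
  expect_equal(as.character(meta$condition), c("snow_free", "snow_covered"))
  writeLines(c("sample_id\tlocation\tcondition", "S1\tL1\tslush"), mf)
  expect_error(read_sample_metadata(mf), "unknown condition")
})
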