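make_tiny_ds <- function() {
  vals <- matrix(c(1, 2, 3, 4, 5, 6), nrow = 2, byrow = TRUE,
                 dimnames = list(c("s1", "s2"), c("A", "B", "C")))
  npx_dataset(vals, lod = c(A = 0, B = 0, C = 0), batch = c("P1", "P1"))
}

test_that("long CSV round trip preserves the dataset", {
  co <- two_group_cohort(seed = 9, n = 15, n_proteins = 6)
  dir <- withr_local_tempdir()
  path <- file.path(dir, "npx.csv")
  write_npx_long(co$dataset, path)
  back <- read_npx_long(path)
  expect_equal(back$values, co$dataset$values, tolerance = 1e-12)
  expect_equal(as.numeric(back$lod), as.numeric(co$dataset$lod),
               tolerance = 1e-12)
  expect_identical(back$batch, co$dataset$batch)
  expect_identical(back$qc_pass, co$dataset$qc_pass)
  expect_identical(back$below_lod, co$dataset$below_lod)
})

test_that("read_npx_long validates its input", {
  dir <- withr_local_tempdir()
  df <- data.frame(SampleID = c("s1", "s1", "s2"), Assay = c("A", "B", "A"),
                   NPX = c(1, 2, 3), LOD = 0, PlateID = "P1",
                   QC_Warning = "Pass")
  p <- file.path(dir, "ok.csv"); write.csv(df, p, row.names = FALSE)
  ds <- read_npx_long(p)
  expect_equal(dim(ds), c(2L, 2L))
  expect_true(is.na(ds$values["s2", "B"]))

  bad <- df; names(bad)[3] <- "Value"
  pb <- file.path(dir, "bad.csv"); write.csv(bad, pb, row.names = FALSE)
  expect_error(read_npx_long(pb), "missing required column")

  dup <- rbind(df, df[1, ])
  pd <- file.path(dir, "dup.csv"); write.csv(dup, pd, row.names = FALSE)
  expect_error(read_npx_long(pd), "duplicate")
})

test_that("a value exactly at the LOD is not flagged below LOD", {
  vals <- matrix(c(1, 2), 1, 2, dimnames = list("s1", c("A", "B")))
  ds <- npx_dataset(vals, lod = c(A = 1, B = 3), batch = "P1")
  expect_false(ds$below_lod[1, "A"])  # NPX == LOD: strict inequality
  expect_true(ds$below_lod[1, "B"])
})

test_that("apply_qc keeps passing samples and reports removals", {
  ds <- make_tiny_ds()
  expect_identical(apply_qc(ds)$values, ds$values)

  co <- generate_cohort(synthetic_config(
    group_sizes = c(UC = 250, CD_L1 = 250),
    group_positions = c(UC = 0, CD_L1 = 1), n_proteins = 5, n_signal = 2,
    qc_fail_rate = 0.1, seed = 21))
  out <- apply_qc(co$dataset)
  expect_setequal(attr(out, "removed"), co$truth$qc_fail_ids)
  expect_equal(nrow(out$values), 500 - length(co$truth$qc_fail_ids))
})

test_that("exclude_assays removes named proteins, warns on unknown", {
  co <- two_group_cohort(seed = 2, n = 10, n_proteins = 12)
  out <- exclude_assays(co$dataset, c("PROT_01", "PROT_02", "PROT_03",
                                      "PROT_04"))
  expect_equal(ncol(out$values), 8)
  expect_identical(exclude_assays(co$dataset, character(0))$values,
                   co$dataset$values)
  expect_warning(out2 <- exclude_assays(co$dataset, "NOT_THERE"),
                 "not in panel")
  expect_identical(out2$values, co$dataset$values)
})

test_that("exclude_below_lod applies the strict >90% rule", {
  co <- two_group_cohort(seed = 13, n = 50, n_proteins = 10, n_signal = 0)
  ds <- plant_lod_violations(co$dataset, c("PROT_01", "PROT_06", "PROT_10"),
                             fraction = 0.91)
  out <- exclude_below_lod(ds)
  expect_setequal(attr(out, "removed"), c("PROT_01", "PROT_06", "PROT_10"))
  expect_equal(ncol(out$values), 7)
  # idempotent
  expect_identical(exclude_below_lod(out)$values, out$values)

  # exactly 90% below LOD: retained
  n <- 50
  vals <- matrix(rnorm(n), n, 1, dimnames = list(sprintf("s%02d", 1:n), "A"))
  lod <- c(A = sort(vals)[45] + 1e-9)  # 45/50 = 90% strictly below
  ds90 <- npx_dataset(vals, lod, batch = rep("P1", n))
  expect_equal(mean(ds90$below_lod), 0.9)
  expect_equal(ncol(exclude_below_lod(ds90)$values), 1)

  # untouched mask: identity
  clean <- exclude_below_lod(co$dataset)
  expect_identical(clean$values, co$dataset$values)
})

test_that("missing values are excluded from LOD-fraction denominators", {
  vals <- matrix(c(0, 0, NA, NA, NA, NA, NA, NA, NA, 5), 10, 1,
                 dimnames = list(sprintf("s%02d", 1:10), "A"))
  ds <- npx_dataset(vals, lod = c(A = 1), batch = rep("P1", 10))
  # 2 of 3 non-missing below LOD = 66.7% <= 90%: retained
  expect_equal(ncol(exclude_below_lod(ds)$values), 1)
  # 2 of 2 non-missing below LOD would exceed it
  vals2 <- vals; vals2[10, 1] <- NA
  ds2 <- npx_dataset(vals2, lod = c(A = 1), batch = rep("P1", 10))
  expect_equal(ncol(exclude_below_lod(ds2)$values), 0)
})

test_that("median_center batch adjustment aligns medians and is idempotent", {
  co <- two_group_cohort(seed = 5, n = 30, n_proteins = 6)
  ds <- co$dataset
  # single batch: unchanged up to numerical tolerance
  adj0 <- adjust_batches(ds, "median_center")
  expect_equal(adj0$values, ds$values, tolerance = 1e-12)

  # two batches differing by +2 on every protein
  ds2 <- ds
  ds2$batch <- rep(c("B1", "B2"), length.out = nrow(ds$values))
  shift <- ifelse(ds2$batch == "B2", 2, 0)
  ds2$values <- ds2$values + shift
  adj <- adjust_batches(ds2, "median_center")
  meds <- sapply(c("B1", "B2"), function(b) {
    apply(adj$values[adj$batch == b, ], 2, median)
  })
  expect_lt(max(abs(meds[, 1] - meds[, 2])), 1e-9)

  # idempotent
  adj2 <- adjust_batches(adj, "median_center")
  expect_equal(adj2$values, adj$values, tolerance = 1e-9)

  # within-batch rank order preserved
  for (b in c("B1", "B2")) {
    expect_identical(apply(adj$values[adj$batch == b, ], 2, order),
                     apply(ds2$values[ds2$batch == b, ], 2, order))
  }
})

test_that("batch adjustment shrinks between-batch variance on synthetic data", {
  spread <- function(ds) {
    meds <- sapply(unique(ds$batch), function(b) {
      apply(ds$values[ds$batch == b, , drop = FALSE], 2, median)
    })
    mean(apply(meds, 1, var))
  }
  ratios <- vapply(1:20, function(s) {
    co <- generate_cohort(synthetic_config(
      group_sizes = c(UC = 60, CD_L1 = 60),
      group_positions = c(UC = 0, CD_L1 = 1), n_proteins = 8, n_signal = 0,
      n_batches = 3, batch_sd = 1.0, residual_sd = 0.5, qc_fail_rate = 0,
      covariate_effects = c(age = 0, sex = 0, duration = 0), seed = s))
    adj <- adjust_batches(co$dataset, "median_center")
    spread(adj) / spread(co$dataset)
  }, numeric(1))
  expect_lt(mean(ratios), 0.10)
})

test_that("reference and location-scale methods behave", {
  co <- two_group_cohort(seed = 8, n = 40, n_proteins = 5)
  ds <- co$dataset
  ds$batch <- rep(c("B1", "B2"), each = 40)
  ds$values[ds$batch == "B2", ] <- ds$values[ds$batch == "B2", ] * 2 + 3
  expect_error(adjust_batches(ds, "reference_align", reference_batch = "NOPE"),
               "reference batch")
  ra <- adjust_batches(ds, "reference_align", reference_batch = "B1")
  meds <- sapply(c("B1", "B2"), function(b)
    apply(ra$values[ra$batch == b, ], 2, median))
  expect_lt(max(abs(meds[, 1] - meds[, 2])), 1e-9)
  ls <- adjust_batches(ds, "location_scale", reference_batch = "B1")
  mads <- sapply(c("B1", "B2"), function(b)
    apply(ls$values[ls$batch == b, ], 2, mad))
  expect_lt(max(abs(mads[, 1] - mads[, 2])), 1e-6)

  dsw <- ds
  dsw$batch[1] <- "TINY"
  expect_warning(adjust_batches(dsw, "median_center"), "<3 samples")
})

test_that("assign_groups maps Montreal phenotypes deterministically", {
  meta <- data.frame(
    SampleID = paste0("s", 1:7),
    Diagnosis = c("UC", "CD", "CD", "CD", "HC", "IBD-U", "CD"),
    Location = c(NA, "L2", "L1", "L3+L4", NA, NA, "L4"),
    Behavior = c(NA, "B1", "B1", "B2", NA, NA, "B1"),
    Extent = c("E2", NA, NA, NA, NA, NA, NA),
    Age = 30, Sex = "F", DurationYears = 5, PriorSurgery = FALSE,
    TreatmentNaive = FALSE, Cohort = "A", stringsAsFactors = FALSE)
  expect_warning(g <- assign_groups(meta), "isolated L4")
  expect_equal(unname(g[c("s1", "s2", "s3", "s4", "s5", "s6")]),
               c("UC", "CD_L2", "CD_L1", "CD_L3", "HC", "IBDU"))
  expect_true(is.na(g[["s7"]]))

  meta$Location[2] <- NA
  expect_error(suppressWarnings(assign_groups(meta)), "missing Montreal location")

  expect_setequal(expand_group("COLONIC_IBD"), c("UC", "CD_L2"))
  grp <- c(a = "UC", b = "CD_L2", c = "CD_L1")
  expect_equal(npxspectrum:::group_index(grp, "COLONIC_IBD"), c(1L, 2L))
})

test_that("filtering preserves sample and protein order", {
  co <- two_group_cohort(seed = 17, n = 20, n_proteins = 8)
  ds <- co$dataset
  ds$qc_pass[c(3, 11)] <- FALSE
  out <- apply_qc(ds)
  expect_identical(rownames(out$values),
                   setdiff(rownames(ds$values), rownames(ds$values)[c(3, 11)]))
  out2 <- exclude_assays(ds, "PROT_04")
  expect_identical(colnames(out2$values),
                   setdiff(colnames(ds$values), "PROT_04"))
})

test_that("metadata validation enforces the Montreal contract", {
  co <- two_group_cohort(seed = 1, n = 6)
  meta <- co$meta
  expect_silent(validate_sample_meta(meta))
  bad <- meta; bad$Age[1] <- 15
  expect_error(validate_sample_meta(bad), "18")
  bad2 <- meta; bad2$Extent[bad2$Diagnosis == "CD"][1] <- "E1"
  expect_error(validate_sample_meta(bad2), "extent")
  dir <- withr_local_tempdir()
  p <- file.path(dir, "meta.csv")
  write_sample_meta(meta, p)
  expect_equal(read_sample_meta(p), meta, tolerance = 1e-12)
})
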