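test_that("variant merging dedups across callers on (sample, gene, pos, alt)", {
  a <- toyVariantTable("mutect2")
  b <- toyVariantTable("varscan2")
  merged <- mergeVariantCallers(list(a, b))
  expect_equal(nrow(merged), nrow(a))
  expect_true(all(merged$caller == "mutect2,varscan2"))
  # single caller: identity with caller list of length 1
  single <- mergeVariantCallers(list(a))
  expect_equal(nrow(single), nrow(a))
  expect_true(all(single$caller == "mutect2"))
  # records lacking position/alt fall back to (sample, gene, class)
  c1 <- a; c1$position <- NA; c1$alt <- NA
  c2 <- b; c2$position <- NA; c2$alt <- NA
  expect_equal(nrow(mergeVariantCallers(list(c1, c2))), nrow(a))
  # empty input
  empty <- a[0, ]
  expect_equal(nrow(mergeVariantCallers(list(empty, empty))), 0L)
})

test_that("mutation burden counts records per sample with zeros for absentees", {
  v <- toyVariantTable()
  burden <- mutationBurden(v, c("S1", "S2", "S3"))
  expect_identical(burden, c(S1 = 3L, S2 = 1L, S3 = 0L))
  expect_equal(sum(burden), nrow(v))
})

test_that("fusion burden applies the high-confidence filter to the Arriba caller only", {
  f <- toyFusionTable()
  burden <- fusionBurden(f, c("S1", "S2", "S3", "S4"))
  # S1: 2 high arriba kept, 1 low arriba dropped
  # S3: medium arriba dropped, high starfusion kept (not filtered)
  expect_identical(burden, c(S1 = 2L, S2 = 1L, S3 = 1L, S4 = 0L))
  kept <- filterHighConfidence(f)
  expect_false(any(kept$caller == "arriba" & kept$confidence != "high"))
})

test_that("copy-number gain/loss counts match hand counts and bounds", {
  cn <- matrix(c(2L, 1L, 0L, -1L, -2L,
                 0L, 0L, 0L, 0L, 0L,
                 1L, 1L, 1L, -2L, 0L), 5, 3,
               dimnames = list(paste0("g", 1:5), paste0("S", 1:3)))
  out <- cnGainLossCounts(cn)
  expect_equal(out$genes_gained, c(2L, 0L, 3L))
  expect_equal(out$genes_lost, c(2L, 0L, 1L))
  expect_true(all(out$genes_gained + out$genes_lost <= nrow(cn)))
  bad <- cn; bad[1, 1] <- 5L
  expect_error(cnGainLossCounts(bad), "-2..2")
})

test_that("fusion frequency is partner-agnostic percent of carriers per group", {
  f <- filterHighConfidence(toyFusionTable())
  groups <- c(S1 = "gbm", S2 = "lgg", S3 = "gbm", S4 = "gbm",
              S5 = "gbm", S6 = "gbm", S7 = "gbm", S8 = "gbm",
              S9 = "gbm", S10 = "lgg")
  freq <- fusionFrequencyByGroup(f, groups, "EGFR")
  # 1 of 8 gbm samples carries an EGFR fusion (S1; S3's was medium)
  expect_equal(unname(freq["gbm"]), 100 * 1 / 8)
  expect_equal(unname(freq["lgg"]), 0)
  # 3' partner matches count too
  freq_braf <- fusionFrequencyByGroup(f, groups, "BRAF")
  expect_equal(unname(freq_braf["lgg"]), 50)
  # absent gene: zero everywhere, all values bounded
  none <- fusionFrequencyByGroup(f, groups, "NOTAGENE")
  expect_true(all(none == 0))
  expect_true(all(freq >= 0 & freq <= 100))
  expect_error(fusionFrequencyByGroup(f, character(0), "EGFR"),
               "empty group")
})

test_that("counts are invariant to input row order", {
  v <- toyVariantTable()
  f <- toyFusionTable()
  set.seed(3)
  expect_identical(mutationBurden(v[sample(nrow(v)), ], c("S1", "S2")),
                   mutationBurden(v, c("S1", "S2")))
  expect_identical(fusionBurden(f[sample(nrow(f)), ], paste0("S", 1:4)),
                   fusionBurden(f, paste0("S", 1:4)))
})

test_that("gene panels join expression, variants, CN and fusions per sample", {
  v <- matrix(c(5, 1, 9, 2, 3, 4), 2, 3,
              dimnames = list(c("EGFR", "PTEN"), c("S1", "S2", "S3")))
  x <- BrainExpression(v, unit = "LOG2TPM")
  cn <- matrix(c(2L, -1L, 0L, 0L), 2, 2,
               dimnames = list(c("EGFR", "PTEN"), c("S1", "S2")))
  pan <- genePanel("EGFR", x, toyVariantTable(),
                   filterHighConfidence(toyFusionTable()), cn)
  expect_equal(nrow(pan), 3L)
  s1 <- pan[pan$sample_id == "S1", ]
  expect_equal(s1$expression, 5)
  expect_true(s1$mutated)
  expect_equal(s1$cn_call, 2L)
  expect_true(s1$fused)
  s3 <- pan[pan$sample_id == "S3", ]
  expect_false(s3$mutated)
  expect_equal(s3$cn_call, 0L)
  expect_false(s3$covered_cn)
  expect_error(genePanel("NOPE", x, NULL, NULL, NULL), "absent")
})
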