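recDF <- function(time, event, subtype = "G", dataset = "D",
                  ids = sprintf("S%03d", seq_along(time))) {
  data.frame(sample_id = ids, patient_id = ids, time_years = time,
             event = event, subtype = subtype, dataset = dataset,
             stringsAsFactors = FALSE)
}

test_that("primary/unique filter removes non-primary and duplicate samples", {
  rec <- recDF(c(1, 2, 3, 4, 5), rep(TRUE, 5),
               ids = c("S2", "S1", "R1", "N1", "S9"))
  rec$patient_id <- c("P1", "P1", "P2", "P3", "P4")
  meta <- data.frame(
    sample_id = c("S2", "S1", "R1", "N1", "S9"),
    patient_id = rec$patient_id, dataset = "D", disease_label = "g",
    sample_type = c("primary", "primary", "recurrent", "normal",
                    "primary"),
    stringsAsFactors = FALSE)
  out <- filterPrimaryUnique(rec, meta)
  # recurrent and normal dropped; P1 keeps lexicographically smallest S1
  expect_setequal(out$sample_id, c("S1", "S9"))
  expect_equal(max(table(out$patient_id)), 1L)
})

test_that("all-unique primary records pass the filter unchanged", {
  rec <- recDF(1:4, rep(TRUE, 4))
  meta <- data.frame(sample_id = rec$sample_id,
                     patient_id = rec$patient_id, dataset = "D",
                     disease_label = "g", sample_type = "primary",
                     stringsAsFactors = FALSE)
  expect_setequal(filterPrimaryUnique(rec, meta)$sample_id,
                  rec$sample_id)
})

test_that("KM curve steps match the product-limit closed form", {
  # 10 uncensored events at 1..10: S steps down by 1/10 each time
  cv <- kmCurve(recDF(1:10, rep(TRUE, 10)))
  expect_equal(cv@surv, seq(0.9, 0, by = -0.1))
  expect_equal(kmMedian(cv), 5)

  # all censored: S stays 1, median undefined
  cens <- kmCurve(recDF(1:5, rep(FALSE, 5)))
  expect_true(all(cens@surv == 1))
  expect_identical(kmMedian(cens), NA_real_)

  # censored middle record: S(1) = 2/3, S(3) = 0
  mixed <- kmCurve(recDF(c(1, 2, 3), c(TRUE, FALSE, TRUE)))
  ev <- mixed@nEvent > 0
  expect_equal(mixed@surv[ev], c(2 / 3, 0))
})

test_that("KM estimate matches the hand product-limit oracle on a fixed censored example", {
  time <- c(1, 2, 2, 3, 4, 4, 5, 6)
  event <- c(TRUE, FALSE, TRUE, TRUE, FALSE, TRUE, FALSE, TRUE)
  cv <- kmCurve(recDF(time, event))
  oracle <- handKM(time, event)
  ev <- cv@nEvent > 0
  expect_equal(cv@time[ev], oracle$time)
  expect_equal(cv@surv[ev], oracle$surv, tolerance = 1e-12)
  # frozen hand values: 7/8, 7/8*6/7, then *4/5, *3/4, *0
  expect_equal(oracle$surv, c(0.875, 0.75, 0.6, 0.45, 0),
               tolerance = 1e-12)
  expect_equal(kmMedian(cv), 4)
  expect_equal(handKMMedian(time, event), 4)
})

test_that("single uncensored event defines the median at that time", {
  cv <- kmCurve(recDF(3, TRUE))
  expect_equal(kmMedian(cv), 3)
})

test_that("NN annotation follows the radius/fraction/min-cohort rules", {
  # 41 same-(subtype,dataset) samples on a tight grid, times 0..40
  set.seed(8)
  n <- 41
  rec <- recDF(0:40, rep(TRUE, n))
  co <- matrix(runif(2 * n, 0, 0.5), n, 2,
               dimnames = list(rec$sample_id, c("x", "y")))
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  ann <- nnSurvivalAnnotate(e, rec)
  # every sample: N = 41, k = round(0.25*41) = 10 >= min_cohort
  expect_false(any(is.na(ann$median_survival_years)))
  # cross-check one sample against explicit neighbor sort + hand KM
  d1 <- sqrt(colSums((t(co[-1, ]) - co[1, ])^2))
  cohort <- order(d1)[1:10] + 1
  expect_equal(ann$median_survival_years[1],
               handKMMedian(rec$time_years[cohort],
                            rec$event[cohort]))
})

test_that("samples with fewer than min_cohort qualifying neighbors stay unannotated", {
  # only 9 candidates within radius -> below the 10 minimum
  n <- 10
  rec <- recDF(seq_len(n), rep(TRUE, n))
  co <- cbind(seq(0, 0.9, length.out = n), 0)
  rownames(co) <- rec$sample_id
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  ann <- nnSurvivalAnnotate(e, rec,
                            nnSurvivalParams(cohort_fraction = 1))
  expect_true(all(is.na(ann$median_survival_years)))
})

test_that("degenerate cohorts with one shared time annotate that time", {
  n <- 30
  rec <- recDF(rep(7.5, n), rep(TRUE, n))
  co <- matrix(runif(2 * n), n, 2,
               dimnames = list(rec$sample_id, NULL))
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  ann <- nnSurvivalAnnotate(e, rec,
                            nnSurvivalParams(min_cohort = 5))
  expect_true(all(ann$median_survival_years == 7.5))
})

test_that("NN annotation equals the brute-force oracle across seeded landscapes", {
  for (seed in 1:8) {
    L <- randomSurvivalLandscape(seed, n_per_group = 55)
    ann <- nnSurvivalAnnotate(L$embedding, L$records)
    oracle <- oracleNNAnnotate(embeddingCoords(L$embedding), L$records)
    expect_equal(ann$median_survival_years, oracle)
  }
})

test_that("annotation is invariant under rigid translation of the embedding", {
  L <- randomSurvivalLandscape(99, n_per_group = 50)
  ann <- nnSurvivalAnnotate(L$embedding, L$records)
  co2 <- embeddingCoords(L$embedding) + matrix(c(13, -7),
           nrow(embeddingCoords(L$embedding)), 2, byrow = TRUE)
  e2 <- new("LandscapeEmbedding", coords = co2, seed = 1L,
            params = embedParams())
  ann2 <- nnSurvivalAnnotate(e2, L$records)
  expect_equal(ann2$median_survival_years, ann$median_survival_years)
})

test_that("records missing from the embedding are an error", {
  L <- randomSurvivalLandscape(1, n_per_group = 12)
  rec <- L$records
  rec$sample_id[1] <- "GHOST"
  expect_error(nnSurvivalAnnotate(L$embedding, rec), "GHOST")
})

test_that("the two neighbor-selection orders coincide", {
  # the cohort is the min(k, #within-radius) nearest in-radius points in
  # both orders, so radius-then-k and k-then-radius must agree exactly
  for (seed in c(17, 18)) {
    set.seed(seed)
    n <- 60
    rec <- recDF(rexp(n, log(2) / 3), runif(n) < 0.7)
    co <- matrix(runif(2 * n, 0, 6), n, 2,
                 dimnames = list(rec$sample_id, NULL))
    e <- new("LandscapeEmbedding", coords = co, seed = 1L,
             params = embedParams())
    a1 <- nnSurvivalAnnotate(e, rec, nnSurvivalParams(
      cohort_fraction = 0.5, min_cohort = 5, order = "radius_then_k"))
    a2 <- nnSurvivalAnnotate(e, rec, nnSurvivalParams(
      cohort_fraction = 0.5, min_cohort = 5, order = "k_then_radius"))
    expect_equal(a1$median_survival_years, a2$median_survival_years)
  }
})
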