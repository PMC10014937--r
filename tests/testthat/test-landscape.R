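gaussianClusters <- function(seed, k = 5, n_each = 60, d = 50,
                             sep = 10) {
  set.seed(seed)
  centers <- matrix(rnorm(k * d), k, d)
  centers <- centers / sqrt(rowSums(centers^2)) * sep *
    seq_len(k)  # distinct radii keep centers apart
  v <- do.call(rbind, lapply(seq_len(k), function(i)
    sweep(matrix(rnorm(n_each * d), n_each, d), 2, centers[i, ], "+")))
  lab <- rep(paste0("C", seq_len(k)), each = n_each)
  x <- t(v) - min(v)  # nonnegative, genes x samples
  rownames(x) <- sprintf("g%03d", seq_len(d))
  colnames(x) <- sprintf("s%03d", seq_len(k * n_each))
  list(x = BrainExpression(x, unit = "LOG2TPM"), labels = lab)
}

test_that("embedding is deterministic given input, params and seed", {
  gc <- gaussianClusters(1, k = 3, n_each = 20, d = 10)
  e1 <- embedLandscape(gc$x, seed = 42)
  e2 <- embedLandscape(gc$x, seed = 42)
  expect_identical(embeddingCoords(e1), embeddingCoords(e2))
  expect_identical(embeddingSamples(e1), colnames(gc$x))
})

test_that("3-component embeddings have three coordinates", {
  gc <- gaussianClusters(2, k = 2, n_each = 20, d = 10)
  e <- embedLandscape(gc$x, params = embedParams(n_components = 3),
                      seed = 1)
  expect_identical(colnames(embeddingCoords(e)), c("x", "y", "z"))
})

test_that("well-separated Gaussian clusters are recovered in 2-D", {
  skip_if_not_installed("mclust")
  gc <- gaussianClusters(3)
  e <- embedLandscape(gc$x, seed = 11)
  set.seed(12)
  km <- kmeans(embeddingCoords(e), centers = 5, nstart = 25)
  ari <- mclust::adjustedRandIndex(km$cluster, gc$labels)
  expect_gte(ari, 0.9)
})

test_that("too few samples or non-finite input are rejected", {
  gc <- gaussianClusters(4, k = 1, n_each = 10, d = 5)
  expect_error(embedLandscape(gc$x, params = embedParams(n_neighbors = 15)),
               "n_neighbors")
})

test_that("unanimous neighborhoods transfer their label", {
  co <- rbind(matrix(rnorm(20, mean = 0, sd = 0.1), 10, 2),
              matrix(rnorm(20, mean = 5, sd = 0.1), 10, 2),
              c(0.05, 0.05))
  rownames(co) <- sprintf("s%02d", 1:21)
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  labels <- setNames(rep(c("SHH", "WNT"), each = 10),
                     sprintf("s%02d", 1:20))
  out <- knnLabelImpute(e, labels, k = 5)
  expect_identical(unname(out["s21"]), "SHH")
  expect_identical(out[names(labels)], labels)
})

test_that("k-NN ties resolve to the single nearest neighbor's label", {
  # constructed 2-2 tie at k = 4: nearest labeled point carries "B"
  co <- rbind(c(0, 0),
              c(0, 1), c(0, 2),      # B at distances 1, 2
              c(1.5, 0), c(2.5, 0))  # A at distances 1.5, 2.5
  rownames(co) <- c("q", "b1", "b2", "a1", "a2")
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  labels <- c(b1 = "B", b2 = "B", a1 = "A", a2 = "A")
  out <- knnLabelImpute(e, labels, k = 4)
  expect_identical(unname(out["q"]), "B")
})

test_that("label transfer requires labeled samples and valid k", {
  co <- matrix(rnorm(10), 5, 2,
               dimnames = list(paste0("s", 1:5), NULL))
  e <- new("LandscapeEmbedding", coords = co, seed = 1L,
           params = embedParams())
  expect_error(knnLabelImpute(e, character(0), k = 1), "no labeled")
  expect_error(knnLabelImpute(e, c(s1 = "A"), k = 5), "k must be")
})

test_that("label transfer matches the brute-force implementation", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- 120
    co <- matrix(runif(2 * n, 0, 10), n, 2,
                 dimnames = list(sprintf("s%03d", 1:n), NULL))
    e <- new("LandscapeEmbedding", coords = co, seed = 1L,
             params = embedParams())
    lab_idx <- sample(n, 40)
    labels <- setNames(sample(c("X", "Y", "Z"), 40, replace = TRUE),
                       rownames(co)[lab_idx])
    k <- sample(c(1, 5, 15), 1)
    expect_identical(knnLabelImpute(e, labels, k),
                     oracleKnnImpute(co, labels, k))
  }
})

test_that("embedding CSV + sidecar round trip", {
  gc <- gaussianClusters(5, k = 2, n_each = 15, d = 8)
  e <- embedLandscape(gc$x, seed = 3)
  pth <- withr::local_tempfile(fileext = ".csv")
  writeEmbedding(e, pth)
  back <- readEmbedding(pth)
  expect_equal(embeddingCoords(back), embeddingCoords(e),
               tolerance = 1e-12)
  expect_identical(back@seed, 3L)
})
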