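writeGmtLines <- function(lines) {
  pth <- withr::local_tempfile(fileext = ".gmt",
                               .local_envir = parent.frame())
  writeLines(lines, pth)
  pth
}

nullScores <- function(seed, p = 100, n = 40) {
  set.seed(seed)
  matrix(rnorm(p * n), p, n,
         dimnames = list(sprintf("pw%03d", seq_len(p)),
                         sprintf("s%02d", seq_len(n))))
}

test_that("GMT parsing handles sets, dedup and malformed lines", {
  pth <- writeGmtLines(c("SET1\tdesc1\tG1\tG2",
                         "SET2\tdesc2\tG1\tG1"))
  sets <- readGmt(pth)
  expect_identical(sets$SET1, c("G1", "G2"))
  expect_identical(sets$SET2, "G1")
  expect_identical(unname(attr(sets, "description")["SET1"]), "desc1")
  expect_error(readGmt(writeGmtLines("SET1\tdesc")), "3 fields")
  expect_error(readGmt(writeGmtLines(c("A\td\tG1", "A\td\tG2"))),
               "duplicate set")
})

plantedMatrix <- function(seed, p = 200, n = 20, shift = 3) {
  set.seed(seed)
  m <- matrix(rnorm(p * n), p, n,
              dimnames = list(sprintf("g%03d", seq_len(p)),
                              sprintf("s%02d", seq_len(n))))
  m[1:10, 1] <- m[1:10, 1] + shift
  m
}

test_that("scores are bounded in [-1, 1] and respect the size filter", {
  m <- plantedMatrix(1)
  sets <- list(UP = sprintf("g%03d", 1:10),
               MID = sprintf("g%03d", 50:80),
               TINY = c("g001", "g002"),
               ALIEN = c("x1", "x2", "x3", "x4", "x5", "x6"))
  expect_message(sc <- gsvaScores(m, sets), "size window")
  s <- pathwayScores(sc)
  expect_setequal(rownames(s), c("UP", "MID"))
  expect_true(all(s >= -1 & s <= 1))
})

test_that("a planted up-shifted set scores highest in the planted sample", {
  for (seed in 1:3) {
    m <- plantedMatrix(seed)
    sc <- pathwayScores(gsvaScores(m, list(UP = sprintf("g%03d", 1:10))))
    expect_gt(sc["UP", "s01"], 0)
    expect_identical(names(which.max(sc["UP", ])), "s01")
  }
})

test_that("negating the planted shift flips the sign of the top score", {
  m <- plantedMatrix(5, shift = -3)
  sc <- pathwayScores(gsvaScores(m, list(UP = sprintf("g%03d", 1:10))))
  expect_lt(sc["UP", "s01"], 0)
  expect_identical(names(which.min(sc["UP", ])), "s01")
})

test_that("scores are invariant to gene and sample order", {
  m <- plantedMatrix(7, p = 80, n = 10)
  sets <- list(A = sprintf("g%03d", 1:10), B = sprintf("g%03d", 30:45))
  s1 <- pathwayScores(gsvaScores(m, sets))
  set.seed(8)
  m2 <- m[sample(nrow(m)), sample(ncol(m))]
  s2 <- pathwayScores(gsvaScores(m2, sets))
  expect_equal(s2[rownames(s1), colnames(s1)], s1, tolerance = 1e-12)
})

test_that("the planted signal is confirmed by an independent rank statistic", {
  # mean within-set rank of expression in the planted sample must exceed
  # the mean over the other samples (a model-free check on the same data)
  m <- plantedMatrix(9)
  ranks <- apply(m, 2, rank)
  in_set <- rownames(m) %in% sprintf("g%03d", 1:10)
  mean_rank <- colMeans(ranks[in_set, ])
  expect_identical(names(which.max(mean_rank)), "s01")
})

test_that("degenerate scoring inputs are rejected", {
  m <- plantedMatrix(2, n = 2)
  expect_error(gsvaScores(m, list(A = sprintf("g%03d", 1:10))),
               "3 samples")
  m3 <- plantedMatrix(2, n = 5)
  expect_error(suppressMessages(
    gsvaScores(m3, list(TINY = c("g001", "g002")))), "size filter")
})

test_that("with d0 = 0 the moderated t equals the ordinary pooled t", {
  s <- nullScores(1, p = 50)
  ga <- sprintf("s%02d", 1:20); gb <- sprintf("s%02d", 21:40)
  tb <- moderatedTTest(s, ga, gb, d0 = 0)
  ref <- apply(s, 1, function(x)
    t.test(x[ga], x[gb], var.equal = TRUE)$statistic)
  expect_equal(tb$t, unname(ref), tolerance = 1e-12)
  expect_equal(tb$df, rep(38, 50))
})

test_that("identical groups give zero difference, t = 0 and p = 1", {
  s <- nullScores(2, p = 20, n = 8)
  s[1, ] <- rep(c(0.3, -0.1, 0.2, 0.4), 2)  # identical in both groups
  ga <- sprintf("s%02d", 1:4); gb <- sprintf("s%02d", 5:8)
  s[, gb] <- s[, ga]
  tb <- moderatedTTest(s, ga, gb)
  expect_equal(tb$mean_diff, rep(0, 20))
  expect_equal(tb$t, rep(0, 20))
  expect_equal(tb$p_value, rep(1, 20))
})

test_that("null pathway scores give calibrated raw p-values", {
  s <- nullScores(11, p = 1000, n = 40)
  tb <- moderatedTTest(s, sprintf("s%02d", 1:20),
                       sprintf("s%02d", 21:40))
  expect_lt(abs(mean(tb$p_value < 0.05) - 0.05), 0.02)
  expect_true(all(tb$adj_p_value >= tb$p_value))
})

test_that("d0 = Inf pins every posterior variance at s0^2", {
  s <- nullScores(3, p = 30)
  ga <- sprintf("s%02d", 1:20); gb <- sprintf("s%02d", 21:40)
  tb <- moderatedTTest(s, ga, gb, d0 = Inf, s02 = 0.7)
  diff <- rowMeans(s[, ga]) - rowMeans(s[, gb])
  expect_equal(tb$t, unname(diff / sqrt(0.7 * (1 / 20 + 1 / 20))),
               tolerance = 1e-12)
})

test_that("moderated t agrees with the limma cross-check on shared data", {
  skip_if_not_installed("limma")
  set.seed(13)
  p <- 200
  # heteroscedastic pathways so shrinkage actually matters
  sds <- sqrt(1 / rgamma(p, shape = 4, rate = 4))
  s <- matrix(rnorm(p * 30, sd = rep(sds, 30)), p, 30,
              dimnames = list(sprintf("pw%03d", 1:p),
                              sprintf("s%02d", 1:30)))
  ga <- sprintf("s%02d", 1:15); gb <- sprintf("s%02d", 16:30)
  tb <- moderatedTTest(s, ga, gb)
  design <- cbind(1, c(rep(1, 15), rep(0, 15)))
  fit <- limma::eBayes(limma::lmFit(s[, c(ga, gb)], design))
  expect_gt(cor(tb$t, fit$t[, 2]), 0.999)
  expect_equal(attr(tb, "d0"), fit$df.prior, tolerance = 0.25)
})

test_that("group contracts are enforced", {
  s <- nullScores(4, p = 10, n = 6)
  expect_error(moderatedTTest(s, c("s01", "s02"), c("s02", "s03")),
               "overlap")
  expect_error(moderatedTTest(s, "s01", c("s02", "s03")),
               "at least 2")
  expect_error(moderatedTTest(s, c("s01", "zz"), c("s02", "s03")),
               "not in score matrix")
})

test_that("BH adjustment preserves the raw p ordering", {
  s <- nullScores(5, p = 300)
  tb <- moderatedTTest(s, sprintf("s%02d", 1:20),
                       sprintf("s%02d", 21:40))
  ord <- order(tb$p_value)
  expect_true(all(diff(tb$adj_p_value[ord]) >= -1e-12))
})

test_that("consensus pathways intersect significant same-direction calls", {
  mkTable <- function(pw, padj, dir) {
    data.frame(pathway = pw, mean_diff = ifelse(dir == "up", 1, -1),
               t = 1, df = 10, p_value = padj, adj_p_value = padj,
               direction = dir, stringsAsFactors = FALSE)
  }
  t1 <- mkTable(c("A", "B", "C"), c(0.01, 0.01, 0.01), "up")
  t2 <- mkTable(c("B", "C"), c(0.01, 0.01), "up")
  t3 <- mkTable(c("B", "Z"), c(0.01, 0.2), "up")
  expect_identical(consensusPathways(list(t1, t2, t3), 0.05, "up"), "B")
  expect_identical(consensusPathways(list(t1, t1), 0.05, "up"),
                   c("A", "B", "C"))
  t_empty <- mkTable("A", 0.9, "up")
  expect_length(consensusPathways(list(t1, t_empty), 0.05, "up"), 0)
})
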