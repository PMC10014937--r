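#' Read a GMT gene-set file
#'
#' One set per tab-separated line: name, description, then gene symbols.
#' Duplicate genes within a line are deduplicated; duplicate set names
#' or lines with fewer than three fields are errors.
#'
#' @param path GMT path.
#' @return named list of character vectors (gene symbols); per-set
#'   descriptions in `attr(x, "description")`.
#' @export
readGmt <- function(path) {
  if (!file.exists(path)) stop("GMT file not found: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  short <- which(lengths(fields) < 3L)
  if (length(short))
    stop("malformed GMT line(s) with < 3 fields: line ",
         paste(short, collapse = ", "))
  nm <- vapply(fields, `[[`, character(1), 1L)
  if (anyDuplicated(nm))
    stop("duplicate set name(s): ",
         paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  names(sets) <- nm
  attr(sets, "description") <- stats::setNames(
    vapply(fields, `[[`, character(1), 2L), nm)
  sets
}

#' Single-sample gene-set variation scores
#'
#' Computes per-set, per-sample enrichment scores with the gene-set
#' variation analysis (GSVA) statistic:
#' \enumerate{
#'   \item per gene, an expression-level statistic is computed as a
#'     kernel estimate of the gene's cumulative distribution across
#'     samples (Gaussian kernel, bandwidth = per-gene sd / 4);
#'   \item per sample, genes are ranked by this statistic and the ranks
#'     are symmetrized around the middle of the list, so genes at either
#'     expression extreme carry the largest weight;
#'   \item per set and sample, a Kolmogorov-Smirnov-like weighted random
#'     walk (weight exponent tau = 1) descends the ranked gene list, and
#'     the score is the maximum positive deviation plus the maximum
#'     negative deviation of the walk ("max deviation difference").
#' }
#' Scores are bounded in \[-1, 1\]: near 1 the set's genes concentrate
#' among the sample's most expressed genes, near -1 among the least.
#' Sets are first restricted to genes present in the matrix and filtered
#' by the size window.
#'
#' @param x a [BrainExpression-class] object (typically `"LOG2TPM"`) or
#'   a numeric genes x samples matrix.
#' @param sets named list of gene-symbol vectors (see [readGmt()]).
#' @param min_size,max_size size window applied to `|set intersect
#'   genes|` (defaults 5 and 500).
#' @param tau weight exponent of the random walk (default 1).
#' @return A [PathwayScores-class] object (filtered sets x samples).
#' @export
gsvaScores <- function(x, sets, min_size = 5L, max_size = 500L, tau = 1) {
  v <- if (is(x, "BrainExpression")) exprValues(x) else as.matrix(x)
  if (ncol(v) < 3L) stop("need at least 3 samples, got ", ncol(v))
  genes <- rownames(v)
  idx_sets <- lapply(sets, function(s) which(genes %in% s))
  sizes <- lengths(idx_sets)
  keep <- sizes >= min_size & sizes <= max_size
  if (any(!keep))
    message(sum(!keep), " gene set(s) outside size window [",
            min_size, ", ", max_size, "] excluded")
  if (!any(keep)) stop("no gene set survives the size filter")
  idx_sets <- idx_sets[keep]

  z <- .kcdfStat(v)
  p <- nrow(v); n <- ncol(v)
  w_pos <- abs(p / 2 - seq_len(p))^tau
  scores <- matrix(NA_real_, length(idx_sets), n,
                   dimnames = list(names(idx_sets), colnames(v)))
  for (j in seq_len(n)) {
    ord <- order(z[, j], decreasing = TRUE)
    pos_of_gene <- integer(p)
    pos_of_gene[ord] <- seq_len(p)
    for (s in seq_along(idx_sets)) {
      scores[s, j] <- .ksWalkScore(pos_of_gene[idx_sets[[s]]], w_pos, p)
    }
  }
  new("PathwayScores", scores = scores)
}

# Gaussian-kernel CDF statistic: z_ij = mean_k Phi((x_ij - x_ik) / h_i),
# h_i = sd_i / 4 (constant genes get z = 0.5 throughout)
.kcdfStat <- function(v) {
  p <- nrow(v)
  z <- v
  for (i in seq_len(p)) {
    x <- v[i, ]
    h <- stats::sd(x) / 4
    if (!is.finite(h) || h <= 0) { z[i, ] <- 0.5; next }
    z[i, ] <- rowMeans(stats::pnorm(outer(x, x, "-") / h))
  }
  z
}

# weighted KS random walk, max positive + max negative deviation
.ksWalkScore <- function(set_pos, w_pos, p) {
  m <- length(set_pos)
  ind <- logical(p)
  ind[set_pos] <- TRUE
  win <- sum(w_pos[set_pos])
  if (win <= 0) return(0)
  walk <- cumsum(ifelse(ind, w_pos / win, -1 / (p - m)))
  max(walk, 0) + min(walk, 0)
}

#' Moderated-t differential pathway test
#'
#' Two-group comparison of enrichment scores per pathway with an
#' empirical-Bayes moderated t-statistic: the per-pathway pooled
#' residual variance \eqn{s_g^2} (df \eqn{d = n_a + n_b - 2}) is shrunk
#' toward a prior variance \eqn{s_0^2} with prior degrees of freedom
#' \eqn{d_0}, giving the posterior variance
#' \eqn{\tilde{s}_g^2 = (d_0 s_0^2 + d s_g^2) / (d_0 + d)} and
#' \eqn{t_g = \bar{\Delta}_g / (\tilde{s}_g \sqrt{1/n_a + 1/n_b})} on
#' \eqn{d_0 + d} degrees of freedom. The hyperprior \eqn{(d_0, s_0^2)}
#' is estimated by matching the first two moments of \eqn{\log s_g^2}
#' under the scaled-F model (trigamma inversion for \eqn{d_0}).
#' P-values are Benjamini-Hochberg adjusted across pathways.
#'
#' @param scores a [PathwayScores-class] object or pathways x samples
#'   matrix.
#' @param group_a,group_b disjoint character vectors of sample ids, each
#'   of size >= 2. The reported difference and direction are for
#'   `group_a` relative to `group_b`.
#' @param d0,s02 optional hyperprior overrides; `d0 = 0` gives the
#'   ordinary pooled two-sample t, `d0 = Inf` fixes every posterior
#'   variance at `s02`.
#' @return data.frame with columns `pathway`, `mean_diff`, `t`, `df`,
#'   `p_value`, `adj_p_value`, `direction` (`"up"`/`"down"` in group A);
#'   the fitted hyperprior in attributes `d0` and `s02`.
#' @export
moderatedTTest <- function(scores, group_a, group_b, d0 = NULL,
                           s02 = NULL) {
  s <- if (is(scores, "PathwayScores")) pathwayScores(scores)
       else as.matrix(scores)
  if (length(intersect(group_a, group_b)))
    stop("groups overlap")
  if (length(group_a) < 2L || length(group_b) < 2L)
    stop("each group needs at least 2 samples")
  miss <- setdiff(c(group_a, group_b), colnames(s))
  if (length(miss)) stop("sample(s) not in score matrix: ",
                         paste(miss, collapse = ", "))
  a <- s[, group_a, drop = FALSE]
  b <- s[, group_b, drop = FALSE]
  na <- ncol(a); nb <- ncol(b); d <- na + nb - 2
  ma <- rowMeans(a); mb <- rowMeans(b)
  diff <- ma - mb
  s2 <- (rowSums((a - ma)^2) + rowSums((b - mb)^2)) / d

  if (is.null(d0) || is.null(s02)) {
    fit <- .fitVariancePrior(s2, d)
    if (is.null(d0)) d0 <- fit$d0
    if (is.null(s02)) s02 <- fit$s02
  }
  post <- if (is.infinite(d0)) rep(s02, length(s2))
          else (d0 * s02 + d * s2) / (d0 + d)
  se <- sqrt(post * (1 / na + 1 / nb))
  t <- ifelse(se > 0, diff / se, ifelse(diff == 0, 0, sign(diff) * Inf))
  df_t <- d0 + d
  p <- 2 * stats::pt(-abs(t), df = df_t)
  p[se == 0 & diff == 0] <- 1
  out <- data.frame(pathway = rownames(s), mean_diff = diff, t = t,
                    df = df_t, p_value = p,
                    adj_p_value = stats::p.adjust(p, method = "BH"),
                    direction = ifelse(diff < 0, "down", "up"),
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "d0") <- d0
  attr(out, "s02") <- s02
  out
}

# moment-matching of (d0, s0^2) on log s_g^2 under s_g^2 ~ s0^2 F(d, d0)
.fitVariancePrior <- function(s2, d) {
  ok <- is.finite(s2) & s2 > 0
  if (sum(ok) < 2L) return(list(d0 = Inf, s02 = max(mean(s2), 1e-12)))
  z <- log(s2[ok])
  evar <- stats::var(z) - trigamma(d / 2)
  if (evar > 1e-10) {
    d0 <- 2 * .trigammaInverse(evar)
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2) +
                 digamma(d0 / 2) - log(d0 / 2))
  } else {
    d0 <- Inf
    s02 <- exp(mean(z) - digamma(d / 2) + log(d / 2))
  }
  list(d0 = d0, s02 = s02)
}

.trigammaInverse <- function(y) {
  if (y > trigamma(1e-6)) return(1e-6)
  if (y < trigamma(1e8)) return(1e8)
  stats::uniroot(function(x) trigamma(x) - y,
                 interval = c(1e-6, 1e8), tol = 1e-10)$root
}

#' Pathways consistently significant across comparisons
#'
#' Intersection, over a list of differential tables, of pathways with
#' BH-adjusted p at or below `alpha` and the stated direction -- e.g.
#' the pathways up-regulated in every glioma subtype versus normal
#' brain.
#'
#' @param tables list of data.frames from [moderatedTTest()].
#' @param alpha adjusted-p threshold (default 0.05).
#' @param direction `"up"` or `"down"` (in each comparison's group A).
#' @return character vector of pathway names (sorted).
#' @export
consensusPathways <- function(tables, alpha = 0.05,
                              direction = c("up", "down")) {
  direction <- match.arg(direction)
  stopifnot(length(tables) >= 1L)
  hits <- lapply(tables, function(tb)
    tb$pathway[tb$adj_p_value <= alpha & tb$direction == direction])
  sort(Reduce(intersect, hits))
}

#' Write a pathway score matrix as TSV (pathway x sample)
#'
#' @param x a [PathwayScores-class] object.
#' @param path output TSV path.
#' @return `path`, invisibly.
#' @export
writePathwayScores <- function(x, path) {
  s <- pathwayScores(x)
  df <- data.frame(pathway = rownames(s), s, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
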