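#' Z-score a feature/RT pair and remove outlying trials
#'
#' Both variables are z-scored across trials; trials with |z| > 3 on
#' either variable are removed and the remaining pairs returned without
#' re-standardization.
#'
#' @param feature per-trial feature values.
#' @param rts per-trial reaction times.
#' @return list with `x`, `y` (retained z-scored pairs) and `keep`
#'   (logical over trials).
#' @export
zscore_clean <- function(feature, rts) {
  n <- length(feature)
  if (n < 3L || length(rts) != n)
    stop("invalid argument: need >= 3 paired trials")
  sx <- stats::sd(feature); sy <- stats::sd(rts)
  if (!is.finite(sx) || sx == 0 || !is.finite(sy) || sy == 0)
    stop("degenerate input: zero variance")
  zx <- (feature - mean(feature)) / sx
  zy <- (rts - mean(rts)) / sy
  keep <- abs(zx) <= 3 & abs(zy) <= 3
  list(x = zx[keep], y = zy[keep], keep = keep)
}

# slope/intercept/R^2 of OLS y ~ x on already-cleaned z-scored pairs
ols_fit <- function(x, y) {
  vx <- sum((x - mean(x))^2)
  if (length(x) < 3L || vx == 0)
    return(c(slope = NA_real_, intercept = NA_real_, r2 = NA_real_))
  slope <- sum((x - mean(x)) * (y - mean(y))) / vx
  intercept <- mean(y) - slope * mean(x)
  pred <- intercept + slope * x
  ssr <- sum((y - pred)^2)
  sst <- sum((y - mean(y))^2)
  r2 <- if (sst > 0) 1 - ssr / sst else NA_real_
  c(slope = slope, intercept = intercept, r2 = r2)
}

#' Time-resolved single-trial regression of RTs on a feature
#'
#' Per time point, pairs the single-trial feature with reaction times,
#' z-scores and outlier-cleans them ([zscore_clean()]), and fits ordinary
#' least squares (slope, intercept, R^2). On z-scored pairs the slope
#' equals the Pearson correlation.
#'
#' @param feature numeric matrix, trials x times.
#' @param rts per-trial reaction times.
#' @return a `regression_timecourse`: list with `slope`, `intercept`,
#'   `r2` (per time point), `max_r2`, `n_retained` (per time point).
#' @export
regress_timecourse <- function(feature, rts) {
  nt <- ncol(feature)
  slope <- intercept <- r2 <- nret <- numeric(nt)
  for (ti in seq_len(nt)) {
    z <- zscore_clean(feature[, ti], rts)
    fit <- ols_fit(z$x, z$y)
    slope[ti] <- fit[["slope"]]
    intercept[ti] <- fit[["intercept"]]
    r2[ti] <- fit[["r2"]]
    nret[ti] <- length(z$x)
  }
  structure(list(slope = slope, intercept = intercept, r2 = r2,
                 max_r2 = if (all(is.na(r2))) NA_real_ else max(r2, na.rm = TRUE),
                 n_retained = nret),
            class = "regression_timecourse")
}

#' Shuffled-correspondence null slope time course
#'
#' Permutes the assignment of reaction times to trials `n_shuffles` times
#' and recomputes the regression slope time course, returning the mean
#' across shuffles (the per-participant null).
#'
#' @param feature numeric matrix, trials x times.
#' @param rts per-trial reaction times.
#' @param n_shuffles number of random reassignments.
#' @param seed integer RNG seed.
#' @return numeric vector of mean null slopes per time point.
#' @export
shuffled_null <- function(feature, rts, n_shuffles = 100, seed = 1L) {
  set.seed(seed)
  acc <- matrix(0, n_shuffles, ncol(feature))
  for (s in seq_len(n_shuffles)) {
    perm <- sample.int(length(rts))
    acc[s, ] <- regress_timecourse(feature, rts[perm])$slope
  }
  colMeans(acc)
}

# clusters of contiguous same-sign supra-threshold t values;
# returns list of (indices, stat = sum of t)
find_clusters <- function(tvals, tcrit) {
  state <- integer(length(tvals))
  state[tvals > tcrit] <- 1L
  state[tvals < -tcrit] <- -1L
  out <- list()
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  for (j in which(r$values != 0L)) {
    idx <- starts[j]:ends[j]
    out[[length(out) + 1L]] <- list(indices = idx, stat = sum(tvals[idx]))
  }
  out
}

# pointwise paired t values from a subjects x bins difference matrix,
# vectorized over sign-flip permutations (sum of squares is flip-invariant)
paired_t_matrix <- function(D, signs) {
  n <- nrow(D)
  m <- crossprod(signs, D) / n              # n_perm x bins means
  ss <- matrix(colSums(D^2), nrow(m), ncol(m), byrow = TRUE)
  v <- (ss - n * m^2) / (n - 1)
  v[v < .Machine$double.eps] <- .Machine$double.eps
  m / sqrt(v / n)
}

#' Cluster-based permutation test for paired conditions
#'
#' Pointwise paired t-test over bins (time points or frequencies); bins
#' exceeding the two-tailed critical t at `alpha_cluster` form clusters
#' of contiguous same-sign runs; each cluster's statistic is the sum of
#' its t values. The null distribution is the maximum absolute cluster
#' statistic over `n_perm` random per-subject sign flips, and
#' Monte-Carlo p-values use the +1 correction. Cohen's d per cluster is
#' computed from the cluster-averaged per-subject differences.
#'
#' @param A,B numeric matrices, subjects x bins (paired conditions).
#' @param n_perm number of sign-flip permutations.
#' @param alpha_cluster cluster-forming alpha (two-tailed).
#' @param seed integer RNG seed.
#' @return a `cluster_test`: list with `t` (pointwise), `clusters` (list
#'   of index vectors), `stats`, `p` (per cluster), `d` (per cluster),
#'   `min_p` (1 when no clusters form), `n_perm`.
#' @export
cluster_permutation_test <- function(A, B, n_perm = 1000,
                                     alpha_cluster = 0.05, seed = 1L) {
  if (!is.matrix(A) || !is.matrix(B) || any(dim(A) != dim(B)))
    stop("invalid argument: A and B must be subjects x bins matrices of equal size")
  n <- nrow(A)
  if (n < 2L) stop("invalid argument: need at least 2 subjects")
  D <- A - B
  tcrit <- stats::qt(1 - alpha_cluster / 2, df = n - 1)
  tvals <- as.numeric(paired_t_matrix(D, matrix(1, n, 1L)))
  cl <- find_clusters(tvals, tcrit)
  if (length(cl) == 0L)
    return(structure(list(t = tvals, clusters = list(), stats = numeric(0),
                          p = numeric(0), d = numeric(0), min_p = 1,
                          n_perm = n_perm),
                     class = "cluster_test"))
  set.seed(seed)
  signs <- matrix(sample(c(-1, 1), n * n_perm, replace = TRUE), n, n_perm)
  Tperm <- paired_t_matrix(D, signs)
  maxstat <- numeric(n_perm)
  for (s in seq_len(n_perm)) {
    pc <- find_clusters(Tperm[s, ], tcrit)
    maxstat[s] <- if (length(pc)) max(abs(vapply(pc, `[[`, numeric(1L), "stat")))
    else 0
  }
  stats_ <- vapply(cl, `[[`, numeric(1L), "stat")
  # tie comparison with a relative tolerance: the identity sign flip must
  # reproduce the observed statistic up to floating-point summation order
  p <- vapply(stats_, function(s)
    (1 + sum(maxstat >= abs(s) * (1 - 1e-10))) / (n_perm + 1),
    numeric(1L))
  d <- vapply(cl, function(c) cohens_d_cluster(D, c$indices), numeric(1L))
  structure(list(t = tvals, clusters = lapply(cl, `[[`, "indices"),
                 stats = stats_, p = p, d = d, min_p = min(p),
                 n_perm = n_perm),
            class = "cluster_test")
}

#' Cohen's d for a cluster of bins
#'
#' Per subject, the condition difference is averaged over the cluster's
#' bins; d is the mean of those averages divided by their (n-1) standard
#' deviation across subjects.
#'
#' @param D subjects x bins difference matrix (A - B).
#' @param cluster integer vector of bin indices (nonempty).
#' @return Cohen's d (NA with a warning when the between-subject SD is 0).
#' @export
cohens_d_cluster <- function(D, cluster) {
  if (length(cluster) == 0L) stop("invalid argument: empty cluster")
  m <- rowMeans(D[, cluster, drop = FALSE])
  s <- stats::sd(m)
  if (!is.finite(s) || s == 0) {
    if (isTRUE(all(m == 0))) return(0)
    warning("zero between-subject SD; Cohen's d undefined")
    return(NA_real_)
  }
  mean(m) / s
}

#' Median split of trials by reaction time
#'
#' Trials with RT strictly below the median are "fast"; trials at or
#' above it are "slow". Deterministic; all-identical RTs put every trial
#' in the slow half with a warning.
#'
#' @param rts per-trial reaction times (>= 2 trials).
#' @return list with integer index vectors `fast` and `slow`.
#' @export
median_split <- function(rts) {
  if (length(rts) < 2L) stop("invalid argument: need >= 2 trials")
  med <- stats::median(rts)
  fast <- which(rts < med)
  slow <- which(rts >= med)
  if (length(fast) == 0L)
    warning("all reaction times identical; every trial assigned to the slow half")
  list(fast = fast, slow = slow)
}

#' Paired group-level contrast
#'
#' Two-tailed paired t-test or Wilcoxon signed-rank (normal
#' approximation) on per-subject values, with Cohen's d of the paired
#' differences.
#'
#' @param a,b per-subject values (paired, >= 3 subjects).
#' @param method `"t"` or `"wilcoxon"`.
#' @return list with `statistic` (t or z), `p`, `d`, `df` (t only),
#'   `method`. Zero-variance differences flag d and the t statistic NA.
#' @export
paired_contrast <- function(a, b, method = c("t", "wilcoxon")) {
  method <- match.arg(method)
  if (length(a) != length(b) || length(a) < 3L)
    stop("invalid argument: need >= 3 paired subjects")
  diffs <- a - b
  sdd <- stats::sd(diffs)
  d <- if (sdd > 0) mean(diffs) / sdd else if (all(diffs == 0)) 0 else NA_real_
  if (method == "t") {
    if (sdd == 0 && all(diffs == 0))
      return(list(statistic = 0, p = 1, d = 0, df = length(a) - 1L,
                  method = "t"))
    if (sdd == 0) {
      warning("zero variance of differences; t undefined")
      return(list(statistic = NA_real_, p = NA_real_, d = d,
                  df = length(a) - 1L, method = "t"))
    }
    tt <- stats::t.test(a, b, paired = TRUE)
    list(statistic = unname(tt$statistic), p = tt$p.value, d = d,
         df = unname(tt$parameter), method = "t")
  } else {
    nz <- diffs[diffs != 0]
    n <- length(nz)
    if (n == 0L) {
      warning("all paired differences zero; Wilcoxon undefined")
      return(list(statistic = NA_real_, p = NA_real_, d = d, method = "wilcoxon"))
    }
    rk <- rank(abs(nz))
    V <- sum(rk[nz > 0])
    mu <- n * (n + 1) / 4
    ties <- table(rk)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(ties^3 - ties) / 48
    z <- (V - mu) / sqrt(sig2)
    list(statistic = z, p = 2 * stats::pnorm(-abs(z)), d = d,
         method = "wilcoxon")
  }
}
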