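#' Two-sided Wilcoxon rank-sum test
#'
#' Two-group comparison of a pipeline read-out. The p-value is exact
#' (by enumeration of rank assignments) when the smaller sample has at
#' most `exact_max` observations and the pooled data are tie-free;
#' otherwise the normal approximation with tie correction (and
#' continuity correction) is used.
#'
#' @param x,y Numeric samples, each of length >= 1.
#' @param exact_max Largest min(n) for which the exact null
#'   distribution is enumerated.
#' @return A list of class `dtc_test`: `statistic` (rank-sum W),
#'   `p_value`, `method`.
#' @export
ranksum_test <- function(x, y, exact_max = 8) {
  x <- as.numeric(x); y <- as.numeric(y)
  stopifnot(length(x) >= 1, length(y) >= 1)
  if (length(unique(c(x, y))) == 1L) {
    return(new_dtc_test(statistic = length(x) * length(y) / 2,
                        p_value = 1, method = "wilcoxon-ranksum"))
  }
  ties <- anyDuplicated(c(x, y)) > 0L
  exact <- !ties && min(length(x), length(y)) <= exact_max
  wt <- suppressWarnings(
    wilcox.test(x, y, alternative = "two.sided", exact = exact,
                correct = TRUE))
  new_dtc_test(statistic = unname(wt$statistic), p_value = wt$p.value,
               method = if (exact) "wilcoxon-ranksum-exact"
                        else "wilcoxon-ranksum-normal")
}

#' Kruskal-Wallis test across three or more groups
#'
#' Tie-corrected H statistic with the chi-square approximation.
#'
#' @param groups A named list of numeric vectors (>= 3 groups, each
#'   non-empty), or a data frame with columns `group` and `value`.
#' @return A `dtc_test` with `statistic` (H), `p_value`, `df`.
#' @export
kruskal_wallis <- function(groups) {
  g <- as_group_list(groups)
  if (length(g) < 3L) stop("need >= 3 groups", call. = FALSE)
  if (any(lengths(g) == 0L)) stop("empty group", call. = FALSE)
  kt <- kruskal.test(g)
  out <- new_dtc_test(statistic = unname(kt$statistic),
                      p_value = kt$p.value, method = "kruskal-wallis")
  out$df <- unname(kt$parameter)
  out
}

#' Dwass-Steel-Critchlow-Fligner pairwise comparisons, Monte-Carlo
#'
#' All-pairs nonparametric multiple comparison following a
#' Kruskal-Wallis test. For every pair of groups the standardized
#' pairwise rank-sum statistic (mid-ranks, tie-corrected variance) is
#' computed on the two groups' pooled data. Family-wise adjusted
#' p-values come from a Monte-Carlo permutation scheme: the group
#' labels of the full pooled sample are permuted `n_iter` times, the
#' maximum absolute pairwise statistic is recorded for each
#' permutation, and each pair's p-value is
#' `(1 + #{max_null >= |observed|}) / (n_iter + 1)` (so the smallest
#' attainable p is `1/(n_iter + 1)`). Fixed seed gives identical
#' p-values across runs.
#'
#' @param groups A named list of numeric vectors (>= 3 groups), or a
#'   data frame with columns `group` and `value`.
#' @param n_iter Number of Monte-Carlo label permutations.
#' @param seed Integer seed.
#' @return A `dtc_test` with a `pairwise` data frame (`group1`,
#'   `group2`, `statistic`, `p_value`), plus `n_iterations` and
#'   `seed`.
#' @export
dscf_montecarlo <- function(groups, n_iter = 10000, seed = 1L) {
  g <- as_group_list(groups)
  if (length(g) < 3L) stop("need >= 3 groups", call. = FALSE)
  if (any(lengths(g) < 1L)) stop("empty group", call. = FALSE)
  k <- length(g)
  nms <- names(g)
  sizes <- lengths(g)
  pooled <- unlist(g, use.names = FALSE)
  lab <- rep.int(seq_len(k), sizes)
  prs <- utils::combn(k, 2)
  obs <- pairwise_dscf_stats(pooled, lab, k, prs)
  old_seed <- get0(".Random.seed", globalenv(), inherits = FALSE)
  on.exit({
    if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv())
  })
  set.seed(seed)
  max_null <- numeric(n_iter)
  for (it in seq_len(n_iter)) {
    pl <- lab[sample.int(length(lab))]
    max_null[it] <- max(abs(pairwise_dscf_stats(pooled, pl, k, prs)))
  }
  pv <- vapply(abs(obs), function(t0) {
    (1 + sum(max_null >= t0 - 1e-12)) / (n_iter + 1)
  }, numeric(1))
  out <- new_dtc_test(statistic = max(abs(obs)),
                      p_value = min(pv), method = "dscf-montecarlo")
  out$pairwise <- data.frame(group1 = nms[prs[1, ]],
                             group2 = nms[prs[2, ]],
                             statistic = obs, p_value = pv)
  out$n_iterations <- n_iter
  out$seed <- seed
  out
}

# Standardized pairwise rank-sum statistics for all group pairs.
# For pair (i, j): rank only x_i, x_j pooled (mid-ranks); W = rank sum
# of group i; z = (W - E[W]) / sd(W) with tie-corrected variance.
pairwise_dscf_stats <- function(pooled, lab, k, prs) {
  vapply(seq_len(ncol(prs)), function(c) {
    i <- prs[1, c]; j <- prs[2, c]
    xi <- pooled[lab == i]; xj <- pooled[lab == j]
    ni <- length(xi); nj <- length(xj)
    r <- rank(c(xi, xj))
    W <- sum(r[seq_len(ni)])
    n <- ni + nj
    mu <- ni * (n + 1) / 2
    tie <- table(c(xi, xj))
    sig2 <- ni * nj / 12 * ((n + 1) - sum(tie^3 - tie) / (n * (n - 1)))
    if (sig2 <= 0) return(0)
    (W - mu) / sqrt(sig2)
  }, numeric(1))
}

new_dtc_test <- function(statistic, p_value, method) {
  structure(list(statistic = statistic, p_value = p_value,
                 method = method),
            class = "dtc_test")
}

#' @export
print.dtc_test <- function(x, ...) {
  cat(sprintf("%s: statistic = %.4g, p = %.4g\n",
              x$method, x$statistic, x$p_value))
  if (!is.null(x$pairwise)) {
    print(x$pairwise, row.names = FALSE)
  }
  invisible(x)
}

as_group_list <- function(groups) {
  if (is.data.frame(groups)) {
    stopifnot(all(c("group", "value") %in% names(groups)))
    groups <- split(groups$value, groups$group)
  }
  if (!is.list(groups)) stop("`groups` must be a list or data frame",
                             call. = FALSE)
  if (is.null(names(groups))) {
    names(groups) <- paste0("g", seq_along(groups))
  }
  lapply(groups, as.numeric)
}

#' Boxplot-style summary of groups
#'
#' Median, quartiles and whiskers at 1.5 x the interquartile range,
#' one row per group -- the elements used in standard boxplot
#' reporting of these read-outs.
#'
#' @param groups A named list of numeric vectors or a `group`/`value`
#'   data frame.
#' @return A data frame: `group`, `n`, `median`, `q1`, `q3`,
#'   `whisker_low`, `whisker_high`, `n_outliers`.
#' @export
group_summary <- function(groups) {
  g <- as_group_list(groups)
  out <- lapply(names(g), function(nm) {
    v <- g[[nm]]
    q <- quantile(v, c(0.25, 0.5, 0.75), names = FALSE, type = 7)
    iqr <- q[3] - q[1]
    lo <- q[1] - 1.5 * iqr; hi <- q[3] + 1.5 * iqr
    inl <- v[v >= lo & v <= hi]
    data.frame(group = nm, n = length(v), median = q[2],
               q1 = q[1], q3 = q[3],
               whisker_low = if (length(inl)) min(inl) else NA_real_,
               whisker_high = if (length(inl)) max(inl) else NA_real_,
               n_outliers = sum(v < lo | v > hi))
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
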