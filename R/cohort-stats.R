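#' G-test with Williams' correction
#'
#' Likelihood-ratio test of goodness of fit or of independence, with Williams'
#' (1976) correction for the chi-square approximation in small samples. The
#' statistic is G = 2 * sum(O * ln(O/E)), with zero observed cells
#' contributing 0; G is divided by the Williams factor q > 1 and referred to a
#' chi-square upper tail.
#'
#' For goodness of fit on k cells with total N,
#' q = 1 + (k^2 - 1) / (6 N (k - 1)); for an r x c independence table,
#' q = 1 + (N * sum(1/row) - 1)(N * sum(1/col) - 1) / (6 N (r-1)(c-1)).
#'
#' @param observed For `mode = "gof"`, a vector of k >= 2 non-negative integer
#'   counts; for `mode = "independence"`, an r x c matrix of counts.
#' @param expected_prop Expected proportions under the null (gof only);
#'   defaults to equal proportions. Must sum to 1.
#' @param mode `"gof"` or `"independence"`.
#' @return A `g_test` object: list with `G`, `q_williams`, `G_adj`, `df`,
#'   `p.value`, `mode`.
#' @examples
#' # sex balance of 89 females vs 86 males against a 50:50 null
#' g_test(c(89, 86))$p.value   # 0.821
#' @export
g_test <- function(observed, expected_prop = NULL,
                   mode = c("gof", "independence")) {
  mode <- match.arg(mode)
  if (any(observed < 0) || anyNA(observed)) stop("counts must be non-negative")
  N <- sum(observed)
  if (N == 0) stop("total count is zero")
  if (mode == "gof") {
    observed <- as.numeric(observed)
    k <- length(observed)
    if (k < 2L) stop("goodness-of-fit needs >= 2 cells")
    if (is.null(expected_prop)) expected_prop <- rep(1 / k, k)
    if (abs(sum(expected_prop) - 1) > 1e-8)
      stop("expected proportions must sum to 1")
    E <- N * expected_prop
    if (any(E == 0)) stop("zero expected cell")
    df <- k - 1L
    q <- 1 + (k^2 - 1) / (6 * N * (k - 1))
  } else {
    if (!is.matrix(observed) || nrow(observed) < 2L || ncol(observed) < 2L)
      stop("independence mode needs an r x c matrix with r, c >= 2")
    rs <- rowSums(observed); cs <- colSums(observed)
    if (any(rs == 0) || any(cs == 0)) stop("zero row or column margin")
    E <- outer(rs, cs) / N
    df <- (nrow(observed) - 1L) * (ncol(observed) - 1L)
    q <- 1 + (N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1) /
      (6 * N * (nrow(observed) - 1) * (ncol(observed) - 1))
  }
  term <- ifelse(observed > 0, observed * log(observed / E), 0)
  G <- 2 * sum(term)
  G_adj <- G / q
  structure(
    list(G = G, q_williams = q, G_adj = G_adj, df = df,
         p.value = stats::pchisq(G_adj, df, lower.tail = FALSE), mode = mode),
    class = "g_test"
  )
}

#' @export
print.g_test <- function(x, ...) {
  cat(sprintf("G-test (%s, Williams-corrected): G = %.4f, q = %.4f, df = %d, p = %.3f\n",
              x$mode, x$G, x$q_williams, x$df, x$p.value))
  invisible(x)
}

#' Multiple-comparison alpha threshold
#'
#' Bonferroni-style division of the base significance level by the number of
#' pairwise comparisons: alpha/3 = .017 for a three-way comparison, alpha/2 =
#' .025 for a two-way one. The reported value is rounded to 3 decimals; the
#' unrounded value is what decisions use.
#'
#' @param n_way Number of comparisons (>= 1).
#' @param base Base significance level (default .05).
#' @return List with `alpha` (exact) and `reported` (3 dp).
#' @export
alpha_threshold <- function(n_way, base = 0.05) {
  if (n_way < 1) stop("n_way must be >= 1")
  a <- base / n_way
  list(alpha = a, reported = round(a, 3L))
}

#' Kruskal-Wallis rank-sum test
#'
#' Tie-corrected H statistic referred to chi-square at (groups - 1) df. Thin
#' wrapper over [stats::kruskal.test()] returning the pieces the reporting
#' layer uses; all values identical across groups gives H = 0, p = 1 rather
#' than an error.
#'
#' @param groups List of >= 2 numeric vectors, each with >= 2 values.
#' @return List with `H`, `df`, `p.value`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  if (any(lengths(groups) < 2L)) stop("each group needs >= 2 values")
  if (length(unique(unlist(groups))) == 1L)
    return(list(H = 0, df = length(groups) - 1L, p.value = 1))
  kt <- stats::kruskal.test(groups)
  list(H = unname(kt$statistic), df = unname(kt$parameter),
       p.value = kt$p.value)
}

#' Normality-dispatched group comparison
#'
#' Applies the Shapiro-Wilk test to each group at alpha = .05; when every
#' group is consistent with normality the parametric branch is used (ANOVA for
#' 3+ groups, equal-variance t-test for 2), otherwise the nonparametric branch
#' (Kruskal-Wallis / Wilcoxon rank-sum). Groups too small for Shapiro-Wilk
#' (n < 3) force the nonparametric branch, with a message.
#'
#' @param groups List of >= 2 numeric vectors.
#' @param shapiro_alpha Normality alpha (default .05).
#' @return List with `test` (label of the chosen test), `branch`
#'   (`"parametric"`/`"nonparametric"`), `statistic`, `p.value`,
#'   `shapiro_p` (per-group, NA where not computable).
#' @export
dispatch_test <- function(groups, shapiro_alpha = 0.05) {
  if (length(groups) < 2L) stop("need >= 2 groups")
  shapiro_p <- vapply(groups, function(g) {
    if (length(g) < 3L || length(unique(g)) == 1L) return(NA_real_)
    stats::shapiro.test(g)$p.value
  }, numeric(1L))
  if (anyNA(shapiro_p)) {
    message("dispatch_test: group too small for Shapiro-Wilk; using nonparametric branch")
    normal <- FALSE
  } else {
    normal <- all(shapiro_p >= shapiro_alpha)
  }
  two <- length(groups) == 2L
  if (normal) {
    if (two) {
      tt <- stats::t.test(groups[[1L]], groups[[2L]], var.equal = TRUE)
      res <- list(test = "t-test (equal variances)", branch = "parametric",
                  statistic = unname(tt$statistic), p.value = tt$p.value)
    } else {
      values <- unlist(groups)
      g <- factor(rep(seq_along(groups), lengths(groups)))
      fit <- stats::aov(values ~ g)
      sm <- summary(fit)[[1L]]
      res <- list(test = "one-way ANOVA", branch = "parametric",
                  statistic = sm[["F value"]][1L], p.value = sm[["Pr(>F)"]][1L])
    }
  } else {
    if (two) {
      wt <- rank_sum_test(groups[[1L]], groups[[2L]])
      res <- list(test = "Wilcoxon rank-sum", branch = "nonparametric",
                  statistic = wt$statistic, p.value = wt$p.value)
    } else {
      kw <- kruskal_wallis(groups)
      res <- list(test = "Kruskal-Wallis", branch = "nonparametric",
                  statistic = kw$H, p.value = kw$p.value)
    }
  }
  res$shapiro_p <- shapiro_p
  res
}

#' Spearman rank correlation
#'
#' Mid-rank ties, Pearson correlation on the ranks, p-value from the t
#' approximation at n - 2 degrees of freedom (via
#' [stats::cor.test()] with `exact = FALSE`). Zero rank variance in either
#' vector leaves rho undefined and is an explicit error.
#'
#' @param x,y Numeric vectors of equal length >= 3.
#' @return List with `rho`, `p.value`, `n`.
#' @export
spearman_cor <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  if (length(x) < 3L) stop("need >= 3 complete pairs")
  if (stats::var(rank(x)) == 0 || stats::var(rank(y)) == 0)
    stop("zero rank variance: rho undefined")
  ct <- suppressWarnings(
    stats::cor.test(x, y, method = "spearman", exact = FALSE))
  list(rho = unname(ct$estimate), p.value = ct$p.value, n = length(x))
}

#' Distribution-free confidence interval for a median
#'
#' Order-statistic (binomial) interval: the largest j with
#' P(Bin(n, 1/2) < j) <= (1 - level)/2 gives the lower bound as the j-th order
#' statistic and the upper as the (n + 1 - j)-th; the achieved coverage
#' 1 - 2 P(Bin(n, 1/2) <= j - 1) is at least the nominal level. When no such
#' j >= 1 exists (tiny n), the widest interval (min, max) is returned with
#' `attained = FALSE` and its (sub-nominal) coverage.
#'
#' @param values Numeric vector, n >= 1.
#' @param level Nominal confidence level (default .95).
#' @return A list with `median`, `lower`, `upper`, `j`, `k`, `coverage`,
#'   `attained`, `n`.
#' @export
median_ci <- function(values, level = 0.95) {
  values <- values[!is.na(values)]
  n <- length(values)
  if (n < 1L) stop("need at least one value")
  s <- sort(values)
  tail_p <- (1 - level) / 2
  j_candidates <- which(stats::pbinom(seq_len(n) - 1L, n, 0.5) <= tail_p)
  if (length(j_candidates) == 0L || n < 2L) {
    j <- 1L; k <- n
    attained <- FALSE
  } else {
    j <- max(j_candidates); k <- n + 1L - j
    attained <- TRUE
  }
  coverage <- 1 - 2 * stats::pbinom(j - 1L, n, 0.5)
  if (coverage < level) attained <- FALSE
  list(median = stats::median(s), lower = s[j], upper = s[k], j = j, k = k,
       coverage = coverage, attained = attained, n = n)
}
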