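#' Wilcoxon-Mann-Whitney rank-sum test
#'
#' Two-sided test of location shift. For small samples (total n <= 12) the
#' permutation distribution of the U statistic is enumerated exactly over all
#' choose(n, n_a) rank assignments, which remains valid under ties because the
#' enumeration operates on the pooled mid-ranks. Larger samples use the normal
#' approximation with tie-corrected variance and continuity correction (via
#' [stats::wilcox.test()]).
#'
#' @param group_a,group_b Numeric vectors, each with >= 2 values.
#' @param exact_max Total-sample-size cutoff for exact enumeration (default 12).
#' @return List with `statistic` (U for group_a), `p.value`, `method`.
#' @export
rank_sum_test <- function(group_a, group_b, exact_max = 12L) {
  na <- length(group_a); nb <- length(group_b)
  if (na < 2L || nb < 2L)
    stop("each group needs >= 2 values (got ", na, " and ", nb, ")")
  pooled <- c(group_a, group_b)
  r <- rank(pooled)
  u_obs <- sum(r[seq_len(na)]) - na * (na + 1) / 2
  if (na + nb <= exact_max) {
    combos <- utils::combn(na + nb, na)
    u_all <- colSums(matrix(r[combos], nrow = na)) - na * (na + 1) / 2
    mu <- na * nb / 2
    p <- mean(abs(u_all - mu) >= abs(u_obs - mu) - 1e-12)
    list(statistic = u_obs, p.value = p, method = "exact enumeration")
  } else {
    wt <- suppressWarnings(
      stats::wilcox.test(group_a, group_b, exact = FALSE, correct = TRUE))
    list(statistic = u_obs, p.value = wt$p.value,
         method = "normal approximation (tie-corrected, continuity-corrected)")
  }
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment (q-values) via [stats::p.adjust()]; output is in the
#' input order and every q is in [0, 1].
#'
#' @param pvalues Numeric vector of p-values in [0, 1].
#' @return Numeric vector of BH-adjusted q-values, same order as input.
#' @export
bh_fdr <- function(pvalues) {
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE) || anyNA(pvalues))
    stop("p-values must lie in [0, 1] with no missing values")
  stats::p.adjust(pvalues, method = "BH")
}

#' Call differentially expressed genes for one cohort contrast
#'
#' Tests every gene with a valid control reference, cohort patients versus
#' healthy controls, with the rank-sum test; adjusts across all tested genes
#' with Benjamini-Hochberg; and flags DEGs by the joint rule
#' q < `q_threshold` and |signed FC| >= `fc_threshold`. The cohort-level
#' signed fold change is the cohort median patient value against the control
#' reference.
#'
#' @param matrix Expression matrix (genes x samples).
#' @param meta Sample metadata.
#' @param cohort Character vector of patient sample ids forming the contrast
#'   (e.g. one FGF21 stratum).
#' @param reference A [control_reference()] object.
#' @param fc_threshold Fold-change filter (default 1.5).
#' @param q_threshold FDR filter (default .05).
#' @return data.frame with columns `gene`, `statistic`, `fc`, `p`, `q`,
#'   `is_deg`.
#' @export
call_degs <- function(matrix, meta, cohort, reference,
                      fc_threshold = 1.5, q_threshold = 0.05) {
  cohort <- intersect(cohort, colnames(matrix))
  if (length(cohort) < 2L) stop("cohort needs >= 2 patients")
  controls <- intersect(colnames(matrix),
                        meta$sample_id[meta$group == "control"])
  genes <- names(reference$values)
  pat <- matrix[genes, cohort, drop = FALSE]
  ctl <- matrix[genes, controls, drop = FALSE]
  stat <- numeric(length(genes)); p <- numeric(length(genes))
  for (i in seq_along(genes)) {
    res <- rank_sum_test(pat[i, ], ctl[i, ])
    stat[i] <- res$statistic; p[i] <- res$p.value
  }
  med <- apply(pat, 1L, stats::median)
  fc <- signed_fc(med, reference$values)
  q <- bh_fdr(p)
  data.frame(gene = genes, statistic = stat, fc = as.numeric(fc), p = p, q = q,
             is_deg = q < q_threshold & abs(fc) >= fc_threshold,
             row.names = NULL)
}

#' Per-patient direction concordance of cohort DEGs
#'
#' For each cohort-level DEG, the fraction of cohort patients whose individual
#' direction call carries the same sign as the cohort DEG (zero calls count as
#' discordant). The summary is the fraction of DEGs whose per-gene concordance
#' exceeds 0.5 — i.e. the share of DEGs regulated in the same direction in the
#' majority of patients.
#'
#' @param deg_table Output of [call_degs()].
#' @param calls Direction-call matrix from [direction_calls()].
#' @param cohort Patient sample ids of the cohort.
#' @return List with `per_gene` (data.frame: `gene`, `direction`,
#'   `concordance`) and `summary` (scalar fraction; `NA` if no DEGs).
#' @export
concordance <- function(deg_table, calls, cohort) {
  cohort <- intersect(cohort, colnames(calls))
  degs <- deg_table[deg_table$is_deg, , drop = FALSE]
  if (nrow(degs) == 0L) {
    warning("no DEGs; empty concordance summary")
    return(list(per_gene = data.frame(gene = character(),
                                      direction = integer(),
                                      concordance = numeric()),
                summary = NA_real_))
  }
  degs <- degs[degs$gene %in% rownames(calls), , drop = FALSE]
  dir <- ifelse(degs$fc >= 0, 1L, -1L)
  sub <- calls[degs$gene, cohort, drop = FALSE]
  frac <- rowMeans(sub == dir)   # dir recycles down columns (one per gene row)
  per_gene <- data.frame(gene = degs$gene, direction = dir,
                         concordance = as.numeric(frac), row.names = NULL)
  list(per_gene = per_gene, summary = mean(frac > 0.5))
}
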