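#' Build a ranked gene list
#'
#' Orders genes by a real-valued score (signed fold change or test statistic),
#' descending, with a deterministic tie-break on the gene identifier
#' (ascending) so that runs are reproducible regardless of input order.
#'
#' @param scores Named numeric vector (names are gene ids).
#' @return Named numeric vector sorted by (score desc, gene id asc).
#' @export
ranked_list <- function(scores) {
  if (is.null(names(scores)) || anyDuplicated(names(scores)))
    stop("scores must be named with unique gene ids")
  if (anyNA(scores)) stop("scores must not contain missing values")
  scores[order(-scores, names(scores))]
}

#' Weighted Kolmogorov-Smirnov enrichment score
#'
#' Walks the ranked list; positions in the gene set ("hits") increment the
#' running sum by |score|^weight normalised by the total hit weight, positions
#' outside it decrement by 1/(N - N_h). The enrichment score is the running
#' sum's maximum deviation from zero, signed. With weight = 0 the statistic is
#' the classic (unweighted) KS form and the walk returns to 0.
#'
#' @param ranked A [ranked_list()].
#' @param gene_set Character vector of member gene ids.
#' @param weight Exponent on |score| for hit increments (default 1).
#' @return List with `es`, `running` (the N-step running sum) and `hits`
#'   (logical vector along the ranking).
#' @export
enrichment_score <- function(ranked, gene_set, weight = 1) {
  genes <- names(ranked)
  hits <- genes %in% gene_set
  nh <- sum(hits)
  if (nh == 0L) stop("gene set has no overlap with the ranked list")
  if (nh == length(genes))
    stop("gene set covers the whole ranked list; miss decrement undefined")
  w <- abs(ranked)^weight
  hit_total <- sum(w[hits])
  inc <- ifelse(hits,
                if (hit_total > 0) w / hit_total else 1 / nh,
                -1 / (length(genes) - nh))
  if (hit_total == 0) inc[!hits] <- -1 / (length(genes) - nh)
  running <- cumsum(inc)
  # ties in |running| (exact or within fp jitter) resolve to the earliest
  # position, so the sign of ES is deterministic
  peak <- which(abs(running) >= max(abs(running)) - 1e-12)[1L]
  list(es = running[peak], running = running, hits = hits)
}

#' Permutation-normalised enrichment score and p-value
#'
#' Calibrates an observed enrichment score against a gene-label permutation
#' null: random sets of the same size drawn from the ranked universe. The
#' normalised enrichment score divides the observed ES by the mean |ES| of
#' same-sign permutations, and the p-value is the add-one-smoothed fraction of
#' same-sign permutations at least as extreme. Two pass flags are computed:
#' `pass_abs` (p < .05 and |NES| > 1, the pathway rule) and `pass_signed`
#' (p < .05 and NES > 1, the immune-marker rule).
#'
#' @inheritParams enrichment_score
#' @param n_perm Number of permutations (>= 100; default 1000).
#' @param seed Integer seed for the permutation stream.
#' @return An `enrichment_result` data.frame row: `set`, `size`, `es`, `nes`,
#'   `p.value`, `n_perm`, `pass_abs`, `pass_signed`.
#' @export
nes_and_p <- function(ranked, gene_set, weight = 1, n_perm = 1000L,
                      seed = 1L) {
  if (n_perm < 100L) stop("n_perm must be >= 100")
  obs <- enrichment_score(ranked, gene_set, weight)$es
  nh <- sum(names(ranked) %in% gene_set)
  n <- length(ranked)
  perm_es <- withr_seed(seed, {
    vapply(seq_len(n_perm), function(i) {
      idx <- sample.int(n, nh)
      enrichment_score(ranked, names(ranked)[idx], weight)$es
    }, numeric(1L))
  })
  same <- perm_es[sign(perm_es) == sign(obs)]
  if (length(same) == 0L || obs == 0) {
    warning("no same-sign permutation ES; NES undefined for this set")
    nes <- NA_real_; p <- 1
  } else {
    nes <- obs / mean(abs(same))
    p <- (1 + sum(abs(same) >= abs(obs))) / (1 + length(same))
  }
  res <- data.frame(set = NA_character_, size = nh, es = obs, nes = nes,
                    p.value = p, n_perm = as.integer(n_perm),
                    pass_abs = !is.na(nes) && p < 0.05 && abs(nes) > 1,
                    pass_signed = !is.na(nes) && p < 0.05 && nes > 1,
                    row.names = NULL)
  class(res) <- c("enrichment_result", "data.frame")
  res
}

# evaluate expr under a temporary RNG state seeded with `seed`
#' @keywords internal
withr_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Gene-set / marker-set enrichment over a collection
#'
#' Runs the weighted-KS enrichment with permutation NES for every set in a
#' collection against one ranking. Which pass flag applies is decided by the
#' collection's category: `pathway` collections use the |NES| > 1 rule,
#' `immune_marker` ones the signed NES > 1 rule; both flags are always
#' reported. Sets with no overlap with the ranked universe are reported with
#' an `error` note rather than a zero enrichment.
#'
#' @param ranking Named numeric vector of ranking scores (gene-level signed FC
#'   or test statistic); will be ordered by [ranked_list()].
#' @param collection A `gene_set_collection`.
#' @inheritParams nes_and_p
#' @return data.frame with one row per set: `set`, `size`, `es`, `nes`,
#'   `p.value`, `n_perm`, `pass_abs`, `pass_signed`, `pass` (the applicable
#'   rule), `note`.
#' @export
enrich_collection <- function(ranking, collection, weight = 1,
                              n_perm = 1000L, seed = 1L) {
  ranked <- ranked_list(ranking)
  rows <- lapply(seq_along(collection$sets), function(i) {
    nm <- names(collection$sets)[i]
    res <- tryCatch(
      nes_and_p(ranked, collection$sets[[i]], weight, n_perm, seed + i),
      error = function(e) {
        data.frame(set = nm, size = 0L, es = NA_real_, nes = NA_real_,
                   p.value = NA_real_, n_perm = as.integer(n_perm),
                   pass_abs = FALSE, pass_signed = FALSE,
                   note = conditionMessage(e))
      })
    res$set <- nm
    if (is.null(res$note)) res$note <- ""
    res
  })
  out <- do.call(rbind, rows)
  out$pass <- if (collection$category == "immune_marker") out$pass_signed else out$pass_abs
  rownames(out) <- NULL
  out
}

#' Immune-cell marker enrichment
#'
#' Convenience wrapper of [enrich_collection()] for LM22-style marker-set
#' collections (category `immune_marker`), where a cell type counts as
#' enriched when p < .05 and the signed NES exceeds 1.
#'
#' @inheritParams enrich_collection
#' @param marker_sets A `gene_set_collection` tagged `immune_marker`.
#' @return As [enrich_collection()].
#' @export
marker_enrichment <- function(ranking, marker_sets, weight = 1,
                              n_perm = 1000L, seed = 1L) {
  if (marker_sets$category != "immune_marker")
    stop("marker_sets must be tagged 'immune_marker'")
  enrich_collection(ranking, marker_sets, weight, n_perm, seed)
}

#' Annotate genes with panel categories
#'
#' Maps each gene to the panel(s) containing it (e.g. the matrisome scheme:
#' collagens, proteoglycans and glycoproteins forming the core matrisome,
#' plus matrisome-associated categories); genes in no panel are labelled
#' `unannotated`.
#'
#' @param genes Character vector of gene ids.
#' @param panels A `gene_set_collection` of categorical panels.
#' @return List with `labels` (data.frame: `gene`, `panel`; one row per
#'   membership, `unannotated` rows for orphans) and `counts` (named integer
#'   vector per panel).
#' @export
annotate_panels <- function(genes, panels) {
  rows <- lapply(names(panels$sets), function(nm) {
    members <- intersect(genes, panels$sets[[nm]])
    if (length(members) == 0L) return(NULL)
    data.frame(gene = members, panel = nm)
  })
  df <- do.call(rbind, rows)
  annotated <- if (is.null(df)) character() else unique(df$gene)
  orphans <- setdiff(genes, annotated)
  if (length(orphans))
    df <- rbind(df, data.frame(gene = orphans, panel = "unannotated"))
  rownames(df) <- NULL
  counts <- table(factor(df$panel, levels = c(names(panels$sets), "unannotated")))
  list(labels = df, counts = c(counts))
}
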