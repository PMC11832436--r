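test_that("ranked lists order by score descending with deterministic tie-break", {
  scores <- c(b = 2, a = 2, d = 5, c = 1)
  expect_equal(names(ranked_list(scores)), c("d", "a", "b", "c"))
  expect_error(ranked_list(c(1, 2)), "named")
  expect_error(ranked_list(c(a = 1, a = 2)), "named")
})

test_that("enrichment score matches frozen small-case values and the oracle", {
  r4 <- ranked_list(c(g1 = 4, g2 = 3, g3 = 2, g4 = 1))
  # single hit at the top drives the running sum straight to +1
  expect_equal(enrichment_score(r4, "g1")$es, 1)
  # single hit at the bottom, unweighted: running sum -1/3, -2/3, -1, 0
  bottom <- enrichment_score(r4, "g4", weight = 0)
  expect_equal(bottom$es, -1)
  expect_equal(bottom$es, oracle_es(r4, "g4", weight = 0))
  expect_equal(bottom$running, c(-1 / 3, -2 / 3, -1, 0), ignore_attr = TRUE,
               tolerance = 1e-12)
  # 5-gene list, hits at ranks 1 and 3, weight 1: frozen from the oracle
  r5 <- ranked_list(c(a = 5, b = 4, c = 3, d = 2, e = 1))
  expect_equal(oracle_es(r5, c("a", "c")), 2 / 3)
  expect_equal(enrichment_score(r5, c("a", "c"))$es, 2 / 3)
  expect_error(enrichment_score(r4, c("g1", "g2", "g3", "g4")), "whole")
  expect_error(enrichment_score(r4, "zzz"), "no overlap")
})

test_that("enrichment score agrees with fgsea on random instances", {
  set.seed(42)
  for (i in 1:20) {
    n <- sample(5:40, 1L)
    scores <- sort(rnorm(n), decreasing = TRUE)
    names(scores) <- sprintf("g%02d", seq_len(n))
    idx <- sort(sample(n, sample(1:(n - 1L), 1L)))
    for (w in c(0, 1)) {
      mine <- enrichment_score(scores, names(scores)[idx], weight = w)$es
      ref <- fgsea::calcGseaStat(scores, selectedStats = idx, gseaParam = w)
      expect_equal(mine, ref, tolerance = 1e-10)
    }
  }
})

test_that("ES stays in [-1, 1] and the unweighted walk returns to zero", {
  set.seed(7)
  for (i in 1:50) {
    n <- sample(4:30, 1L)
    scores <- ranked_list(setNames(rnorm(n), sprintf("g%02d", seq_len(n))))
    set <- sample(names(scores), sample(1:(n - 1L), 1L))
    for (w in c(0, 1)) {
      res <- enrichment_score(scores, set, weight = w)
      expect_true(abs(res$es) <= 1 + 1e-12)
      expect_true(all(abs(res$running) <= 1 + 1e-12))
      if (w == 0) expect_equal(res$running[n], 0, tolerance = 1e-12)
    }
  }
})

test_that("permutation NES handles the degenerate null and planted signal", {
  # k = 1 hit in a 2-gene list: every same-sign permutation ES equals |obs|
  r2 <- ranked_list(c(a = 2, b = 1))
  res <- nes_and_p(r2, "a", n_perm = 200L, seed = 3L)
  expect_equal(res$nes, 1)
  expect_equal(res$p.value, 1)
  expect_false(res$pass_abs)
  # planted top-loaded set is detected
  set.seed(11)
  scores <- setNames(c(rnorm(20, 4, 0.3), rnorm(180)), sprintf("g%03d", 1:200))
  r <- ranked_list(scores)
  hit <- nes_and_p(r, sprintf("g%03d", 1:20), n_perm = 500L, seed = 4L)
  expect_true(hit$pass_abs)
  expect_gt(hit$nes, 1)
  expect_lt(hit$p.value, 0.05)
})

test_that("decoy sets stay near the nominal false-positive rate on null rankings", {
  set.seed(15)
  passes <- 0L
  n_sets <- 40L
  scores <- ranked_list(setNames(rnorm(300), sprintf("g%03d", 1:300)))
  for (i in seq_len(n_sets)) {
    set <- sample(names(scores), 15L)
    res <- nes_and_p(scores, set, n_perm = 200L, seed = 1000L + i)
    passes <- passes + res$pass_abs
  }
  # binomial(40, .05) stays at or below 7 with probability > 0.999
  expect_lte(passes, 7L)
})

test_that("collection enrichment separates planted programs from decoys", {
  cfg <- strong_config(seed = 23L, n_genes = 150L, n_up = 30L, n_down = 30L,
                       n_unchanged = 10L)
  sim <- generate_cohort(cfg)
  ref <- control_reference(sim$expression, sim$metadata)
  up_ids <- names(which(sim$truth$stratum == "up"))
  deg <- call_degs(sim$expression, sim$metadata, up_ids, ref)
  ranking <- setNames(deg$fc, deg$gene)
  gs <- generate_gene_sets(cfg)
  res <- enrich_collection(ranking, gs, n_perm = 300L, seed = 2L)
  expect_true(res$pass[res$set == "stress_regulators"])
  expect_false(res$pass[res$set == "decoy_stress_regulators_1"])
  expect_equal(res$pass, res$pass_abs)  # pathway collection uses the |NES| rule
})

test_that("marker enrichment demands the immune_marker tag and flags disjoint sets", {
  pathway <- gene_set_collection(list(s = c("g1", "g2")), category = "pathway")
  expect_error(marker_enrichment(c(g1 = 1, g2 = 0.5, g3 = -1), pathway),
               "immune_marker")
  markers <- gene_set_collection(list(macro = c("g1", "g2"),
                                      ghost = c("zz1", "zz2")),
                                 category = "immune_marker")
  set.seed(2)
  ranking <- setNames(c(3, 2.5, rnorm(40)), c("g1", "g2", sprintf("h%02d", 1:40)))
  res <- marker_enrichment(ranking, markers, n_perm = 200L, seed = 6L)
  expect_equal(res$pass, res$pass_signed)
  expect_match(res$note[res$set == "ghost"], "no overlap")
  expect_true(is.na(res$es[res$set == "ghost"]))
})

test_that("panel annotation maps genes to categories and conserves counts", {
  panels <- gene_set_collection(
    list(collagens = c("COL1A1", "COL3A1"), glycoproteins = c("FN1", "COL1A1")),
    category = "matrisome")
  ann <- annotate_panels(c("COL1A1", "FN1", "ALB"), panels)
  lab <- ann$labels
  expect_setequal(lab$panel[lab$gene == "COL1A1"],
                  c("collagens", "glycoproteins"))
  expect_equal(lab$panel[lab$gene == "ALB"], "unannotated")
  expect_equal(sum(ann$counts), nrow(lab))
  expect_equal(unname(ann$counts["collagens"]), 1L)
})
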