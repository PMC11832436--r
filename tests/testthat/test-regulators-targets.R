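fake_stratification <- function(up, down, unchanged = character()) {
  data.frame(sample_id = c(up, down, unchanged),
             status = rep(c("up", "down", "unchanged"),
                          c(length(up), length(down), length(unchanged))))
}

test_that("the recurrence filter admits candidates at exactly 10 patients", {
  up_pat <- sprintf("u%02d", 1:20)
  down_pat <- sprintf("d%02d", 1:15)
  calls <- matrix(0L, 3L, 35L,
                  dimnames = list(c("tf10", "tf9", "tfdown"),
                                  c(up_pat, down_pat)))
  calls["tf10", up_pat[1:10]] <- 1L
  calls["tf9", up_pat[1:9]] <- 1L
  calls["tfdown", down_pat[1:12]] <- -1L
  strata <- fake_stratification(up_pat, down_pat)
  rec <- recurrence_filter(calls, strata, c("tf10", "tf9", "tfdown"))
  up_rows <- rec[rec$stratum == "up", ]
  expect_true(up_rows$pass_up[up_rows$gene == "tf10"])
  expect_false(up_rows$pass_up[up_rows$gene == "tf9"])
  down_rows <- rec[rec$stratum == "down", ]
  expect_true(down_rows$pass_down[down_rows$gene == "tfdown"])
  expect_equal(down_rows$n_down[down_rows$gene == "tfdown"], 12L)
  # pooled counting merges the strata before applying the threshold
  pooled <- recurrence_filter(calls, strata, "tf9", pooled = TRUE)
  expect_equal(pooled$stratum, "pooled")
  expect_equal(pooled$n_up, 9L)
  expect_error(recurrence_filter(calls, strata, "absent"), "absent")
  expect_warning(empty <- recurrence_filter(calls, strata, character()), "empty")
  expect_equal(nrow(empty), 0L)
})

test_that("the recurrence pass set shrinks monotonically with min_patients", {
  set.seed(44)
  pat <- sprintf("p%03d", 1:60)
  calls <- matrix(sample(c(-1L, 0L, 1L), 40L * 60L, replace = TRUE,
                         prob = c(.2, .6, .2)),
                  40L, 60L, dimnames = list(sprintf("g%02d", 1:40), pat))
  strata <- fake_stratification(pat[1:30], pat[31:60])
  genes <- rownames(calls)
  prev <- NULL
  for (m in c(3L, 6L, 9L, 12L)) {
    rec <- recurrence_filter(calls, strata, genes, min_patients = m)
    passed <- paste(rec$gene, rec$stratum)[rec$pass_up | rec$pass_down]
    if (!is.null(prev)) expect_true(all(passed %in% prev))
    prev <- passed
  }
})

test_that("planted regulators are exactly the genes that survive the filter", {
  cfg <- strong_config(seed = 29L, n_genes = 150L, n_up = 30L, n_down = 30L,
                       n_unchanged = 10L)
  sim <- generate_cohort(cfg)
  ref <- control_reference(sim$expression, sim$metadata)
  calls <- direction_calls(sim$expression, sim$metadata, ref)
  st <- stratify(sim$expression, sim$metadata, "FGF21")
  candidates <- setdiff(rownames(calls), "FGF21")
  rec <- recurrence_filter(calls, st, candidates)
  pr <- sim$truth$programs
  up_expect <- pr$gene[pr$stratum == "up" & pr$direction == 1L]
  up_got <- rec$gene[rec$stratum == "up" & rec$pass_up]
  expect_setequal(up_got, up_expect)
  down_expect <- pr$gene[pr$stratum == "down" & pr$direction == -1L]
  down_got <- rec$gene[rec$stratum == "down" & rec$pass_down]
  expect_setequal(down_got, down_expect)
})

test_that("null recurrence counts match the binomial-tail oracle", {
  # homogeneous null calls: per-patient call probability is known, so the
  # expected number of passing genes is n_genes * P(Bin(n_pat, p) >= m)
  set.seed(55)
  n_genes <- 400L; n_pat <- 40L; p_call <- 0.15; m <- 10L
  pat <- sprintf("p%03d", seq_len(n_pat))
  calls <- matrix(rbinom(n_genes * n_pat, 1L, p_call), n_genes, n_pat,
                  dimnames = list(sprintf("g%03d", seq_len(n_genes)), pat))
  strata <- fake_stratification(pat, character())
  rec <- recurrence_filter(calls, strata, rownames(calls), min_patients = m,
                           strata_used = "up")
  observed <- sum(rec$pass_up)
  expected <- n_genes * pbinom(m - 1L, n_pat, p_call, lower.tail = FALSE)
  sd_pass <- sqrt(expected * (1 - expected / n_genes))
  expect_lt(abs(observed - expected), 4 * sd_pass + 1)
})

test_that("proportion comparison flags differences at the two-way alpha", {
  # exactly proportional counts carry no evidence
  even <- proportion_compare(c(30, 30), c(120, 120))
  expect_equal(even$p.value, 1)
  expect_false(even$significant)
  expect_equal(even$alpha, 0.025)
  # synthetic counts, checked against a direct evaluation of the formulas
  res <- proportion_compare(c(30, 5), c(117, 159))
  tab <- rbind(c(30, 5), c(87, 154))
  E <- outer(rowSums(tab), colSums(tab)) / sum(tab)
  G <- 2 * sum(tab * log(tab / E))
  q <- 1 + (sum(tab) * sum(1 / rowSums(tab)) - 1) *
    (sum(tab) * sum(1 / colSums(tab)) - 1) / (6 * sum(tab))
  p_direct <- pchisq(G / q, 1L, lower.tail = FALSE)
  expect_equal(res$p.value, p_direct, tolerance = 1e-12)
  expect_equal(res$significant, p_direct < 0.025)
  # column swap symmetry
  swapped <- proportion_compare(c(5, 30), c(159, 117))
  expect_equal(swapped$p.value, res$p.value)
  expect_error(proportion_compare(c(117, 159), c(117, 159)), "margin")
})

test_that("target-ledger overlap arithmetic reproduces the published percentages", {
  fix <- synthetic_target_fixture()
  led <- target_ledger(animal_models = fix$animal_models,
                       patient_regulated = fix$patient_regulated)
  rep <- validate_targets(led, reference = fix$master)
  expect_equal(rep$pct_of_reference[rep$set == "animal_models"], 46.3)
  expect_equal(rep$n_overlap[rep$set == "animal_models"], 87L)
  expect_equal(rep$pct_of_reference[rep$set == "patient_regulated"], 77.7)
  expect_gt(rep$pct_of_reference[rep$set == "patient_regulated"], 77)
  # disjoint evidence scores zero
  led2 <- target_ledger(none = c("X1", "X2"))
  expect_equal(validate_targets(led2, reference = fix$master)$pct_of_reference, 0)
  # the percentage is relative to the reference set, so unequal sets are asymmetric
  a <- sprintf("A%02d", 1:40); b <- c(a[1:10], sprintf("B%02d", 1:10))
  ab <- validate_targets(target_ledger(b = b), reference = a)$pct_of_reference
  ba <- validate_targets(target_ledger(a = a), reference = b)$pct_of_reference
  expect_equal(ab, 25)
  expect_equal(ba, 50)
})
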