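test_that("alleles are grouped by cohort sharing", {
  alleles <- tibble::tibble(
    pos = c(100, 200, 300), ref = "A", alt = "G",
    case_ids = list(1:2, 1, integer(0)),
    ctrl_ids = list(1:3, integer(0), 2:4))
  obs <- make_cohort_obs(alleles)
  g <- assign_groups(obs)
  expect_equal(g$group[g$pos == 100], "shared")
  expect_equal(g$group[g$pos == 200], "case_only")
  expect_equal(g$group[g$pos == 300], "control_only")
  expect_equal(g$case_carriers[g$pos == 100], 2L)
  expect_equal(g$control_carriers[g$pos == 300], 3L)
  # group constraints
  expect_true(all(g$control_carriers[g$group == "case_only"] == 0))
  expect_true(all(g$case_carriers[g$group == "control_only"] == 0))
})

test_that("group sizes equal a set-algebra oracle on random cohorts", {
  set.seed(11)
  for (rep in 1:10) {
    n_sites <- 40
    alleles <- tibble::tibble(
      pos = sample(16000, n_sites), ref = "A", alt = "G",
      case_ids = lapply(seq_len(n_sites), function(i) {
        k <- sample(0:3, 1); if (k) sample(5, k) else integer(0)
      }),
      ctrl_ids = lapply(seq_len(n_sites), function(i) {
        k <- sample(0:3, 1); if (k) sample(8, k) else integer(0)
      }))
    seen <- lengths(alleles$case_ids) + lengths(alleles$ctrl_ids) > 0
    alleles <- alleles[seen, ]
    g <- assign_groups(make_cohort_obs(alleles, 5, 8))
    case_set <- alleles$pos[lengths(alleles$case_ids) > 0]
    ctrl_set <- alleles$pos[lengths(alleles$ctrl_ids) > 0]
    expect_setequal(g$pos[g$group == "shared"], intersect(case_set, ctrl_set))
    expect_setequal(g$pos[g$group == "case_only"], setdiff(case_set, ctrl_set))
    expect_setequal(g$pos[g$group == "control_only"], setdiff(ctrl_set, case_set))
    expect_equal(nrow(g), length(union(case_set, ctrl_set)))
  }
})

test_that("enrichment test reproduces documented cohort p-values", {
  r1 <- carrier_enrichment_test(10, 52, 0, 104)
  expect_equal(r1$method, "fisher_exact")
  expect_equal(r1$p_value, 9.03e-6, tolerance = 5e-3)
  r2 <- carrier_enrichment_test(0, 52, 25, 104)
  expect_equal(r2$method, "chi_square")
  expect_equal(r2$p_value, 1.14e-4, tolerance = 5e-3)
  r3 <- carrier_enrichment_test(40, 52, 69, 104)
  expect_equal(r3$method, "chi_square")
  expect_equal(r3$p_value, 0.175, tolerance = 5e-3)
  # equal proportions: zero statistic, p = 1
  r4 <- carrier_enrichment_test(26, 52, 52, 104, rule = "chi_square")
  expect_equal(r4$statistic, 0)
  expect_equal(r4$p_value, 1)
})

test_that("the expected-count rule switches between exact and chi-square", {
  # 14 of 52 vs 0 of 104: smallest expected count 14*52/156 = 4.67 -> exact
  expect_equal(carrier_enrichment_test(14, 52, 0, 104)$method, "fisher_exact")
  # 15 of 52 vs 0 of 104: smallest expected count 5 -> chi-square
  expect_equal(carrier_enrichment_test(15, 52, 0, 104)$method, "chi_square")
})

test_that("Fisher branch is symmetric and matches complete enumeration", {
  set.seed(3)
  for (i in 1:40) {
    n1 <- sample(2:20, 1); n2 <- sample(2:20, 1)
    k1 <- sample(0:n1, 1); k2 <- sample(0:n2, 1)
    p <- carrier_enrichment_test(k1, n1, k2, n2, rule = "fisher_exact")$p_value
    p_swap <- carrier_enrichment_test(k2, n2, k1, n1,
                                      rule = "fisher_exact")$p_value
    expect_equal(p, p_swap, tolerance = 1e-10)
    expect_equal(p, fisher_enumeration_oracle(k1, n1, k2, n2),
                 tolerance = 1e-9)
    expect_true(p > 0 && p <= 1)
  }
})

test_that("enrichment_table builds per-gene per-group carrier tests", {
  set.seed(21)
  co <- generate_cohort(simulation_config(seed = 21, n_pool = 120,
                                          private_rate = 1))
  tab <- enrichment_table(co$observations)
  expect_true(all(c("gene", "group", "p_value", "method") %in% names(tab)))
  expect_true(all(tab$p_value > 0 & tab$p_value <= 1))
  expect_true("MT-TRNA" %in% tab$gene)        # pooled tRNA region
  expect_false(any(grepl("^MT-T[A-Z]$", tab$gene)))
  # carrier counts are bounded by cohort sizes
  expect_true(all(tab$case_carriers <= 52 & tab$control_carriers <= 104))
})

test_that("per-individual burden comparison is calibrated under the null", {
  set.seed(31)
  pvals <- replicate(200, {
    counts_case <- rpois(26, 3)
    counts_ctrl <- rpois(52, 3)
    rows <- tibble::tibble(
      sample_id = c(sprintf("case%02d", rep(seq_len(26), counts_case)),
                    sprintf("ctrl%02d", rep(seq_len(52), counts_ctrl))),
      cohort = rep(c("case", "control"), c(sum(counts_case), sum(counts_ctrl))),
      pos = sample(3307:4262, sum(counts_case) + sum(counts_ctrl),
                   replace = FALSE),
      ref = "A", alt = "G")
    out <- burden_per_individual(make_obs(rows))
    out$p_value[out$region == "MT-ND1"]
  })
  rate <- mean(pvals < 0.05)
  expect_gt(rate, 0.011)   # 95% binomial interval around 0.05, n = 200
  expect_lt(rate, 0.096)
})

test_that("a uniform +5 allele shift per individual is detected", {
  set.seed(32)
  counts_case <- rpois(26, 3) + 5
  counts_ctrl <- rpois(52, 3)
  rows <- tibble::tibble(
    sample_id = c(sprintf("case%02d", rep(seq_len(26), counts_case)),
                  sprintf("ctrl%02d", rep(seq_len(52), counts_ctrl))),
    cohort = rep(c("case", "control"), c(sum(counts_case), sum(counts_ctrl))),
    pos = sample(3307:4262, sum(counts_case) + sum(counts_ctrl)),
    ref = "A", alt = "G")
  out <- burden_per_individual(make_obs(rows))
  expect_lt(out$p_value[out$region == "MT-ND1"], 1e-6)
  expect_gt(out$mean_case[out$region == "MT-ND1"],
            out$mean_control[out$region == "MT-ND1"])
})
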