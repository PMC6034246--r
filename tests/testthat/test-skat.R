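test_that("burden ratio partitions alleles with strict > 1 rule", {
  g <- tibble::tibble(pos = 1:3, ref = "A", alt = "G",
                      case_carriers = c(5L, 2L, 2L),
                      control_carriers = c(5L, 0L, 4L))
  out <- gene_burden_partition(g, n_case = 50, n_ctrl = 100)
  expect_equal(out$ratio, c(2, Inf, 1))
  expect_equal(out$allele_set, c("positive", "positive", "negative"))
  g_bad <- tibble::tibble(case_carriers = 0L, control_carriers = 0L)
  expect_error(gene_burden_partition(g_bad, 50, 100), "absent")
})

test_that("genotype matrix encodes carrier status and HF dosage", {
  obs <- make_obs(tibble::tibble(
    sample_id = c("case01", "case01", "ctrl01"), cohort = c("case", "case", "control"),
    pos = c(100, 100, 200), ref = "A", alt = "G",
    mutant_reads = c(50L, 80L, 100L), total_reads = 100L)) |> compute_hf()
  alleles <- tibble::tibble(pos = c(100, 200), ref = "A", alt = "G")
  Gc <- genotype_matrix(obs, alleles, "carrier")
  expect_equal(unname(Gc["case01", ]), c(1, 0))
  expect_equal(unname(Gc["ctrl01", ]), c(0, 1))
  Gh <- genotype_matrix(obs, alleles, "hf")
  expect_equal(unname(Gh["case01", 1]), 0.8)   # per-sample maximum HF
  expect_equal(attr(Gc, "cohort"), c("case", "control"))
})

test_that("an all-zero genotype matrix gives Q = 0, p = 1", {
  y <- rep(c(1, 0), c(10, 20))
  res <- suppressWarnings(skat_test(matrix(0, 30, 4), y))
  expect_equal(res$Q, 0)
  expect_equal(res$p_value, 1)
})

test_that("single-column SKAT equals the logistic score test", {
  set.seed(101)
  for (i in 1:5) {
    n <- 120
    y <- rbinom(n, 1, 0.35)
    g <- rbinom(n, 1, runif(1, 0.05, 0.3))
    if (var(g) == 0) next
    res <- skat_test(matrix(g, ncol = 1), y, weights = 1, method = "eigen")
    mu <- mean(y); r <- y - mu; v <- mu * (1 - mu)
    U <- sum(g * r)
    varU <- v * sum(g^2) - v * sum(g)^2 / n
    p_closed <- pchisq(U^2 / varU, df = 1, lower.tail = FALSE)
    expect_equal(res$p_value, p_closed, tolerance = 1e-6)
  }
})

test_that("null residuals are orthogonal to the intercept", {
  set.seed(5)
  y <- rep(c(1, 0), c(52, 104))
  G <- matrix(rbinom(156 * 4, 1, 0.1), 156, 4)
  X <- rep(1, 156)
  mu <- rep(mean(y), 156)
  expect_equal(sum((y - mu) * X), 0, tolerance = 1e-10)
  # and so Q is invariant to adding a constant to a column's dosages
  res1 <- skat_test(G, y, weights = 1)
  expect_equal(res1$Q, sum((crossprod(G, y - mu))^2), tolerance = 1e-8)
})

test_that("moment-matching p agrees with a 2000-permutation oracle", {
  set.seed(202)
  n <- 156
  y <- rep(c(1, 0), c(52, 104))
  freq <- runif(5, 0.05, 0.2)
  G <- matrix(rbinom(n * 5, 1, rep(freq, each = n)), n, 5)
  # induce a modest association in 5 causal columns
  flip <- which(y == 1 & runif(n) < 0.15)
  G[flip, sample(5, 1)] <- 1
  pm <- skat_test(G, y, method = "moment")$p_value
  pp <- skat_test(G, y, method = "permutation", B = 2000, seed = 7)$p_value
  mc_se <- sqrt(pp * (1 - pp) / 2000)
  expect_lt(abs(pm - pp), 4 * mc_se + 0.01)
})

test_that("moment and eigen p-values agree on random instances", {
  set.seed(303)
  for (i in 1:8) {
    n <- sample(c(100, 156, 220), 1)
    p <- sample(3:12, 1)
    y <- rbinom(n, 1, 0.35)
    G <- matrix(rbinom(n * p, 1, rep(runif(p, 0.05, 0.25), each = n)), n, p)
    m <- suppressWarnings(skat_test(G, y, method = "moment"))$p_value
    e <- suppressWarnings(skat_test(G, y, method = "eigen"))$p_value
    expect_lt(abs(m - e) / e, 0.10)
  }
})

test_that("permutation p-values respect the 1/(B+1) floor", {
  set.seed(404)
  n <- 100
  y <- rep(c(1, 0), each = 50)
  G <- matrix(c(y, rbinom(n, 1, 0.1)), n, 2)  # first column = phenotype
  res <- skat_test(G, y, method = "permutation", B = 99, seed = 1)
  expect_gte(res$p_value, 1 / 100)
})

test_that("zero-variance columns are dropped with a warning", {
  y <- rep(c(1, 0), c(20, 40))
  G <- cbind(rbinom(60, 1, 0.2), 0)
  expect_warning(res <- skat_test(G, y), "zero-variance")
  expect_equal(res$n_alleles, 1L)
})

test_that("skat_by_gene stratifies by allele set and excludes synonymous", {
  set.seed(9)
  co <- generate_cohort(simulation_config(seed = 9, n_pool = 150,
                                          private_rate = 1))
  res <- skat_by_gene(co$observations, reference = co$reference)
  expect_true(all(res$allele_set %in% c("positive", "negative")))
  expect_true(all(res$p_value > 0 & res$p_value <= 1))
  expect_true(all(res$Q >= 0))
  # synonymous protein alleles are excluded from the tested sets
  cons <- call_consequence(
    add_gene(dplyr::distinct(co$observations, pos, ref, alt)) |>
      dplyr::filter(gene_class == "protein"),
    co$reference, on_incomplete = "drop")
  n_syn <- sum(cons$consequence == "synonymous")
  res_all <- skat_by_gene(co$observations, reference = NULL)
  expect_equal(sum(res_all$n_alleles) - sum(res$n_alleles), n_syn)
})

test_that("SKAT detects a causal gene planted by the generator", {
  set.seed(55)
  ps <- replicate(20, {
    s <- sample.int(1e6, 1)
    co <- generate_cohort(simulation_config(
      seed = s, n_pool = 150, private_rate = 1,
      causal_genes = "MT-ND5", causal_or = 3))
    res <- skat_by_gene(co$observations, genes = "MT-ND5")
    pv <- res$p_value[res$allele_set == "positive"]
    if (length(pv) == 0) NA_real_ else min(pv)
  })
  expect_lt(median(ps, na.rm = TRUE), 0.1)  # well below the null median of 0.5
})

test_that("interaction test: type-I calibration, power, degeneracy", {
  set.seed(66)
  n <- 156
  y0 <- rep(c(1, 0), c(52, 104))
  # null: independent genes, no phenotype link
  p_null <- replicate(400, {
    G1 <- matrix(rbinom(n * 4, 1, 0.15), n, 4)
    G2 <- matrix(rbinom(n * 4, 1, 0.15), n, 4)
    interaction_test(G1, G2, sample(y0))$p_value
  })
  rate <- mean(p_null < 0.05)
  expect_gt(rate, 0.028); expect_lt(rate, 0.078)  # binomial interval, n = 400

  # power: phenotype generated with a positive product-term log-odds
  p_alt <- replicate(60, {
    G1 <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
    G2 <- matrix(rbinom(n * 4, 1, 0.3), n, 4)
    b1 <- rowSums(G1); b2 <- rowSums(G2)
    eta <- -1 + 1.2 * scale(b1) * scale(b2)
    y <- rbinom(n, 1, plogis(eta))
    if (sum(y) < 5 || sum(y) > n - 5) return(NA_real_)
    interaction_test(G1, G2, y)$p_value
  })
  expect_lt(median(p_alt, na.rm = TRUE), 0.05)

  # identical matrices are degenerate
  G1 <- matrix(rbinom(n * 4, 1, 0.2), n, 4)
  expect_error(interaction_test(G1, G1, y0), "collinear|degenerate")
})

test_that("tidy and glance methods summarise SKAT fits", {
  set.seed(77)
  y <- rep(c(1, 0), c(30, 60))
  G <- matrix(rbinom(90 * 3, 1, 0.2), 90, 3)
  fit <- skat_test(G, y)
  td <- generics::tidy(fit)
  expect_equal(nrow(td), 1)
  expect_equal(td$p.value, fit$p_value)
  gl <- generics::glance(fit)
  expect_equal(gl$n, 90)
})
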