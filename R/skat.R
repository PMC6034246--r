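#' Partition a gene's alleles by burden ratio
#'
#' The gene burden ratio of an allele is its case allele frequency divided
#' by its control allele frequency; alleles with ratio strictly greater
#' than 1 are `positive` (positively associated), all others `negative`.
#' An allele present in cases but absent from controls has infinite ratio
#' and is positive.  Frequency is the carrier fraction by default; an
#' HF-weighted dosage frequency is available.
#'
#' @param groups Grouped-allele tibble from [assign_groups()] (optionally
#'   with a `gene` column to restrict by).
#' @param n_case,n_ctrl Cohort sizes.
#' @param gene Optional gene symbol to restrict to (requires a `gene`
#'   column).
#' @return `groups` with `case_freq`, `control_freq`, `ratio` and
#'   `allele_set` (`"positive"`/`"negative"`) columns.
#' @export
gene_burden_partition <- function(groups, n_case, n_ctrl, gene = NULL) {
  stopifnot(all(c("case_carriers", "control_carriers") %in% names(groups)))
  if (!is.null(gene)) {
    stopifnot("gene" %in% names(groups))
    groups <- filter(groups, .data$gene == !!gene)
  }
  if (any(groups$case_carriers == 0 & groups$control_carriers == 0)) {
    abort("allele absent from both cohorts: no burden ratio")
  }
  groups |>
    mutate(case_freq = .data$case_carriers / n_case,
           control_freq = .data$control_carriers / n_ctrl,
           ratio = if_else(.data$control_freq == 0, Inf,
                           .data$case_freq / .data$control_freq),
           allele_set = if_else(.data$ratio > 1, "positive", "negative"))
}

#' Build a sample-by-allele dosage matrix
#'
#' @param obs Observation tibble (`sample_id`, `cohort`, `pos`, `ref`,
#'   `alt`, and `hf` when `dosage = "hf"`).
#' @param alleles Tibble of alleles to include (columns `pos`, `ref`,
#'   `alt`).
#' @param dosage `"carrier"` for 0/1 carrier status or `"hf"` for
#'   heteroplasmic fraction / 100 (the sample's maximum when an allele is
#'   observed more than once).
#' @return Numeric matrix with samples as rows (ordered cases first, then
#'   controls, alphabetically within cohort) and alleles as columns named
#'   `pos_ref>alt`; sample cohort is kept in `attr(, "cohort")`.
#' @export
genotype_matrix <- function(obs, alleles, dosage = c("carrier", "hf")) {
  dosage <- match.arg(dosage)
  roster <- obs |>
    distinct(.data$sample_id, .data$cohort) |>
    arrange(desc(.data$cohort == "case"), .data$sample_id)
  key <- paste0(alleles$pos, "_", alleles$ref, ">", alleles$alt)
  G <- matrix(0, nrow(roster), length(key),
              dimnames = list(roster$sample_id, key))
  hit <- obs |>
    mutate(k = paste0(.data$pos, "_", .data$ref, ">", .data$alt)) |>
    filter(.data$k %in% key)
  if (nrow(hit) > 0) {
    val <- if (dosage == "hf") {
      stopifnot("hf" %in% names(hit))
      hit$hf / 100
    } else 1
    hit$val <- val
    agg <- hit |>
      group_by(.data$sample_id, .data$k) |>
      summarise(val = max(.data$val), .groups = "drop")
    G[cbind(match(agg$sample_id, roster$sample_id), match(agg$k, key))] <- agg$val
  }
  attr(G, "cohort") <- roster$cohort
  G
}

#' Beta-density variant weights on carrier frequency
#'
#' @param freq Carrier frequencies in \[0, 1\].
#' @param shape Two Beta shape parameters; the default (1, 25) upweights
#'   rare alleles, the conventional choice for rare-variant kernel tests.
#' @return Non-negative weights.
#' @export
beta_weights <- function(freq, shape = c(1, 25)) {
  dbeta(pmin(pmax(freq, 1e-8), 1 - 1e-8), shape[1], shape[2])
}

fit_null_binomial <- function(y, X) {
  fit <- suppressWarnings(glm.fit(X, y, family = binomial()))
  mu <- fit$fitted.values
  if (!fit$converged || any(mu < 1e-10) || any(mu > 1 - 1e-10)) {
    abort(paste0("null logistic model did not converge cleanly (possible ",
                 "separation); drop covariates or use method = \"permutation\""))
  }
  list(mu = mu, X = X)
}

#' @importFrom stats glm.fit
skat_lambda <- function(G, W, mu, X) {
  # eigenvalues of W G' P0 G W, P0 = V - V X (X'VX)^-1 X'V, V = diag(v)
  v <- mu * (1 - mu)
  GW <- sweep(G, 2, W, `*`)           # G W
  VG <- GW * v                        # V G W
  XtVX <- crossprod(X, X * v)
  B <- crossprod(X, VG)               # X' V G W
  A <- crossprod(GW, VG) - t(B) %*% solve(XtVX, B)  # W G' P0 G W
  ev <- eigen((A + t(A)) / 2, symmetric = TRUE, only.values = TRUE)$values
  ev[ev > max(ev) * 1e-10]
}

# Liu et al. moment-matching approximation to P(sum lambda_i chi2_1 > q)
p_liu <- function(q, lambda) {
  c1 <- sum(lambda); c2 <- sum(lambda^2)
  c3 <- sum(lambda^3); c4 <- sum(lambda^4)
  s1 <- c3 / c2^1.5; s2 <- c4 / c2^2
  if (s1^2 > s2) {
    a <- 1 / (s1 - sqrt(s1^2 - s2))
    d <- s1 * a^3 - a^2
    l <- a^2 - 2 * d
  } else {
    a <- 1 / s1; d <- 0; l <- 1 / s1^2
  }
  muQ <- c1; sigmaQ <- sqrt(2 * c2)
  muX <- l + d; sigmaX <- sqrt(2) * a
  tstar <- (q - muQ) / sigmaQ
  p <- pchisq(tstar * sigmaX + muX, df = l, ncp = d, lower.tail = FALSE)
  min(max(p, .Machine$double.xmin), 1)
}

# Imhof's characteristic-function inversion for the same tail probability
p_imhof <- function(q, lambda) {
  integrand <- function(u) {
    theta <- 0.5 * colSums(atan(outer(lambda, u))) - q * u / 2
    rho <- exp(0.25 * colSums(log1p(outer(lambda^2, u^2))))
    sin(theta) / (u * rho)
  }
  val <- tryCatch(
    integrate(integrand, 0, Inf, subdivisions = 2000L, rel.tol = 1e-9)$value,
    error = function(e) NA_real_)
  if (is.na(val)) return(p_liu(q, lambda))
  p <- 0.5 + val / pi
  min(max(p, .Machine$double.xmin), 1)
}

#' Sequence kernel association test for a set of mtDNA alleles
#'
#' A variance-component score test aggregating the alleles of a gene (or
#' any allele set) against a binary phenotype.  A null logistic model
#' (intercept plus optional covariates) is fitted by iteratively reweighted
#' least squares; the score statistic is
#' `Q = (y - mu)' G W^2 G' (y - mu)` with per-allele weights `W` (linear
#' weighted kernel).  Under the null, Q is a weighted sum of 1-df
#' chi-squares whose weights are the eigenvalues of the projected kernel;
#' the p-value is computed by four-moment matching (`"moment"`), by
#' numerical inversion of the characteristic function (`"eigen"`), or by
#' phenotype permutation (`"permutation"`, p = (1 + #{Q* >= Q})/(B + 1)).
#'
#' @param G Sample-by-allele dosage matrix (entries in \[0, 1\]), e.g. from
#'   [genotype_matrix()].
#' @param phenotype Binary vector (1 = case), length `nrow(G)`.
#' @param covariates Optional numeric matrix/data frame of covariates.
#' @param weights Per-allele weights; default Beta(1, 25) density evaluated
#'   at the carrier frequency.  Use `weights = 1` for a flat kernel.
#' @param weight_shape Beta shape parameters for the default weights.
#' @param method `"moment"`, `"eigen"` or `"permutation"`.
#' @param B Number of permutations (permutation method).
#' @param seed Optional seed for the permutation draw, recorded in the
#'   result.
#' @return An object of class `mito_skat`: list with `Q`, `p_value`,
#'   `method`, `lambda`, `n`, `n_alleles`, `weights`, `B`, `seed` and
#'   `perm_Q` (permutation method only).  Supports [generics::tidy()],
#'   [generics::glance()] and [ggplot2::autoplot()].
#' @export
skat_test <- function(G, phenotype, covariates = NULL, weights = NULL,
                      weight_shape = c(1, 25),
                      method = c("moment", "eigen", "permutation"),
                      B = 2000, seed = NULL) {
  method <- match.arg(method)
  G <- as.matrix(G)
  y <- as.numeric(phenotype)
  stopifnot(length(y) == nrow(G), all(y %in% c(0, 1)))
  if (ncol(G) == 0) abort("genotype matrix has no allele columns")
  keep <- apply(G, 2, function(z) var(z) > 0)
  if (!all(keep)) {
    warn(paste0("dropping ", sum(!keep), " zero-variance allele column(s)"))
    G <- G[, keep, drop = FALSE]
  }
  if (is.null(weights)) {
    weights <- beta_weights(colMeans(G > 0), weight_shape)
  } else if (length(weights) == 1) {
    weights <- rep(weights, ncol(G))
  } else {
    weights <- weights[keep]
  }
  if (ncol(G) == 0) {
    res <- list(Q = 0, p_value = 1, method = method, lambda = numeric(0),
                n = length(y), n_alleles = 0L, weights = numeric(0),
                B = NA_integer_, seed = seed, perm_Q = NULL)
    class(res) <- "mito_skat"
    return(res)
  }
  X <- cbind(`(Intercept)` = rep(1, length(y)),
             if (!is.null(covariates)) as.matrix(covariates))
  null <- fit_null_binomial(y, X)
  r <- y - null$mu
  S <- as.numeric(crossprod(G, r)) * weights   # W G' r
  Q <- sum(S^2)
  perm_Q <- NULL
  if (method == "permutation") {
    if (!is.null(seed)) set.seed(seed)
    M <- t(sweep(G, 2, weights, `*`))          # W G', p x n
    perm_Q <- vapply(seq_len(B), function(b) {
      rp <- r[sample.int(length(r))]
      sum((M %*% rp)^2)
    }, numeric(1))
    p <- (1 + sum(perm_Q >= Q - 1e-12)) / (B + 1)
    lambda <- numeric(0)
  } else {
    lambda <- skat_lambda(G, weights, null$mu, X)
    p <- if (length(lambda) == 0) 1
         else if (method == "moment") p_liu(Q, lambda)
         else p_imhof(Q, lambda)
  }
  res <- list(Q = Q, p_value = p, method = method, lambda = lambda,
              n = length(y), n_alleles = ncol(G), weights = weights,
              B = if (method == "permutation") B else NA_integer_,
              seed = seed, perm_Q = perm_Q)
  class(res) <- "mito_skat"
  res
}

#' @export
print.mito_skat <- function(x, ...) {
  cat("Sequence kernel association test\n")
  cat(sprintf("  n = %d samples, %d allele column(s)\n", x$n, x$n_alleles))
  cat(sprintf("  Q = %.4g, p = %.4g (%s)\n", x$Q, x$p_value, x$method))
  invisible(x)
}

#' Per-gene SKAT stratified by burden-ratio allele set
#'
#' For each gene region, partitions its alleles into positively and
#' negatively associated sets by gene burden ratio and runs [skat_test()]
#' on each non-empty set against case/control status.  Protein genes are
#' restricted to nonsynonymous alleles when a reference sequence is
#' supplied; rRNA and tRNA genes use all their alleles.
#'
#' @param obs Observation tibble (`sample_id`, `cohort`, `pos`, `ref`,
#'   `alt`; `hf` needed for `dosage = "hf"`).
#' @param reference Optional reference sequence; when given, synonymous
#'   protein alleles are excluded from the tested sets.
#' @inheritParams enrichment_table
#' @inheritParams skat_test
#' @inheritParams genotype_matrix
#' @param genes Optional character vector restricting the genes tested.
#' @return Tibble with one row per gene x allele set: `gene`,
#'   `allele_set`, `n_alleles`, `Q`, `p_value`, `method`.
#' @export
skat_by_gene <- function(obs, gene_map = mt_genes(), reference = NULL,
                         pool_trna = FALSE, dosage = c("carrier", "hf"),
                         method = c("moment", "eigen", "permutation"),
                         weights = NULL, weight_shape = c(1, 25),
                         B = 2000, seed = NULL, genes = NULL) {
  dosage <- match.arg(dosage); method <- match.arg(method)
  groups <- assign_groups(obs)
  n_case <- n_distinct(obs$sample_id[obs$cohort == "case"])
  n_ctrl <- n_distinct(obs$sample_id[obs$cohort == "control"])
  part <- gene_burden_partition(groups, n_case, n_ctrl) |> add_gene(gene_map)
  part <- filter(part, .data$gene != "noncoding")
  if (!is.null(reference)) {
    prot <- filter(part, .data$gene_class == "protein")
    if (nrow(prot) > 0) {
      cons <- call_consequence(prot, reference, gene_map,
                               on_incomplete = "drop")
      drop <- cons |> filter(.data$consequence == "synonymous") |>
        mutate(k = paste0(.data$pos, "_", .data$ref, ">", .data$alt, "@", .data$gene))
      part <- filter(part, !(paste0(.data$pos, "_", .data$ref, ">", .data$alt,
                                    "@", .data$gene) %in% drop$k))
    }
  }
  if (pool_trna) {
    part <- mutate(part, gene = if_else(.data$gene_class == "tRNA",
                                        "MT-TRNA", .data$gene))
  }
  if (!is.null(genes)) part <- filter(part, .data$gene %in% genes)
  y <- NULL
  out <- part |>
    group_by(.data$gene, .data$allele_set) |>
    group_map(function(d, key) {
      G <- genotype_matrix(obs, d, dosage)
      yv <- as.numeric(attr(G, "cohort") == "case")
      fit <- tryCatch(
        skat_test(G, yv, method = method, weights = weights,
                  weight_shape = weight_shape, B = B, seed = seed),
        error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      tibble(gene = key$gene, allele_set = key$allele_set,
             n_alleles = nrow(d), Q = fit$Q, p_value = fit$p_value,
             method = fit$method)
    }) |>
    list_rbind()
  arrange(out, .data$allele_set, .data$p_value)
}

#' Score test for interaction between two gene burdens
#'
#' Collapses each gene's alleles to a weighted burden score, fits the null
#' logistic model `y ~ burden1 + burden2`, and score-tests the added
#' product term `burden1 * burden2`.  This burden-by-burden score test is
#' one specific interpretation of "gene-gene interaction" for allele-set
#' data; see the methods vignette.
#'
#' @param G1,G2 Dosage matrices for the two genes (same sample order).
#' @param phenotype Binary vector (1 = case).
#' @param weights1,weights2 Optional per-allele weights (default
#'   Beta(1, 25) on carrier frequency).
#' @param method `"score"` for the 1-df chi-square score test,
#'   `"permutation"` for a permutation p-value of the score statistic.
#' @param B,seed Permutation settings.
#' @return Object of class `mito_interaction` with `statistic`, `p_value`,
#'   `method`, `n`.
#' @export
interaction_test <- function(G1, G2, phenotype, weights1 = NULL,
                             weights2 = NULL, method = c("score", "permutation"),
                             B = 2000, seed = NULL) {
  method <- match.arg(method)
  G1 <- as.matrix(G1); G2 <- as.matrix(G2)
  y <- as.numeric(phenotype)
  stopifnot(nrow(G1) == nrow(G2), length(y) == nrow(G1), all(y %in% c(0, 1)))
  w1 <- weights1 %||% beta_weights(colMeans(G1 > 0))
  w2 <- weights2 %||% beta_weights(colMeans(G2 > 0))
  b1 <- as.numeric(G1 %*% w1)
  b2 <- as.numeric(G2 %*% w2)
  if (var(b1) == 0 || var(b2) == 0) abort("degenerate (constant) gene burden")
  if (abs(stats::cor(b1, b2)) > 1 - 1e-8) {
    abort("degenerate interaction: the two gene burdens are collinear")
  }
  z <- scale(b1, scale = FALSE) * scale(b2, scale = FALSE)
  X <- cbind(1, b1, b2)
  null <- fit_null_binomial(y, X)
  r <- y - null$mu
  v <- null$mu * (1 - null$mu)
  U <- sum(z * r)
  XtVX <- crossprod(X, X * v)
  zVX <- crossprod(z, X * v)
  varU <- sum(z^2 * v) - zVX %*% solve(XtVX, t(zVX))
  stat <- as.numeric(U^2 / varU)
  if (method == "score") {
    p <- pchisq(stat, df = 1, lower.tail = FALSE)
  } else {
    if (!is.null(seed)) set.seed(seed)
    perm <- vapply(seq_len(B), function(b) {
      rp <- r[sample.int(length(r))]
      sum(z * rp)^2
    }, numeric(1))
    p <- (1 + sum(perm >= U^2 - 1e-12)) / (B + 1)
  }
  res <- list(statistic = stat, p_value = p, method = method, n = length(y),
              B = if (method == "permutation") B else NA_integer_, seed = seed)
  class(res) <- "mito_interaction"
  res
}

#' @export
print.mito_interaction <- function(x, ...) {
  cat("Burden-by-burden interaction score test\n")
  cat(sprintf("  n = %d, statistic = %.4g, p = %.4g (%s)\n",
              x$n, x$statistic, x$p_value, x$method))
  invisible(x)
}
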