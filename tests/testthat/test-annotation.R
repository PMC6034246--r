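test_that("rating combination averages and rounds", {
  expect_equal(combine_ratings(2, 2, 3), 2L)   # mean 2.333 -> 2
  expect_equal(combine_ratings(3, 3, 3), 3L)
  expect_equal(combine_ratings(1, 2, 3), 2L)   # exact mean
  expect_equal(combine_ratings(1, 1, 2), 1L)   # mean 1.333 -> 1
  expect_error(combine_ratings(0, 2, 3), "1, 2, 3")
  expect_error(combine_ratings(2, NA, 3))
})

test_that("rating combination is symmetric and monotone; halves configurable", {
  trip <- expand.grid(a = 1:3, b = 1:3, c = 1:3)
  for (i in seq_len(nrow(trip))) {
    r <- combine_ratings(trip$a[i], trip$b[i], trip$c[i])
    expect_equal(r, combine_ratings(trip$c[i], trip$a[i], trip$b[i]))
    expect_gte(combine_ratings(min(trip$a[i] + 1, 3), trip$b[i], trip$c[i]), r)
  }
  # (1, 2, 2) has no half; halves only arise at mean x.5, e.g. (1, 2, x)?
  # mean of three integers is k/3, so exact halves occur at k = 7.5: never.
  # The rule still matters for even divisors if ratings are pre-averaged:
  expect_equal(combine_ratings(1, 2, 2), 2L)   # 1.667 -> 2 under half-up
})

test_that("conservation index counts wild-type rows", {
  ref <- synthetic_reference(1)
  panel <- generate_conservation_panel(ref, 5587, 5655,
                                       tibble::tibble(pos = c(5628, 5600),
                                                      k = c(16, 17)))
  expect_equal(conservation_index(panel, 5628), 94.12)
  expect_equal(conservation_index(panel, 5600), 100.00)
})

test_that("CI is recovered exactly and is always a multiple of 100/17", {
  ref <- synthetic_reference(2)
  set.seed(12)
  ks <- sample(1:17, 30, replace = TRUE)
  targets <- tibble::tibble(pos = 1000 + seq_len(30), k = ks)
  panel <- generate_conservation_panel(ref, 1000, 1060, targets)
  ci <- conservation_index(panel, targets$pos)
  expect_equal(ci, round(100 * ks / 17, 2))
  # direct counting oracle on the alignment matrix
  for (i in seq_len(nrow(targets))) {
    col <- panel$aln[, targets$pos[i] - 1000 + 1]
    expect_equal(ci[i], round(100 * sum(col == col[1]) / 17, 2))
  }
})

test_that("gapped human rows and uncovered positions are errors", {
  panel <- read_alignment_panel(c(human = "AC-GT", sp1 = "ACTGT",
                                  sp2 = "ACTGA"), human_start = 100)
  expect_error(conservation_index(panel, 500), "not covered")
  # position 102 maps past the gap; make a gap column explicit
  panel2 <- read_alignment_panel(c(human = "A-C", sp1 = "AGC"), 1)
  expect_equal(unname(panel2$pos_to_col[["2"]]), 3L)
})

test_that("panel frequency criterion is strict at 1%", {
  expect_true(panel_frequency_check(4, 2704))    # 0.15%
  expect_false(panel_frequency_check(31, 2704))  # 1.15%
  expect_false(panel_frequency_check(27, 2700))  # exactly 1.00%
  expect_true(panel_frequency_check(0, 2704))
})

test_that("stem Watson-Crick disruptions are alterations, loops are not", {
  ref <- synthetic_reference(1)
  st <- trna_structure("MT-TA", reference = ref)
  # m.5628 T>C sits at conventional number 31 in the anticodon stem (L
  # strand: gene-strand A>G) and breaks an A-U pair
  sa <- structural_assessment(
    tibble::tibble(pos = 5628, ref = "T", alt = "C"), st)
  expect_equal(sa$trna_number, 31)
  expect_equal(sa$region, "anticodon stem")
  expect_true(sa$alteration)
  expect_false(sa$anticodon_loop)

  # T-loop positions are never structural alterations
  st_tt <- trna_structure("MT-TT", reference = ref)
  tpos <- st_tt$pos[st_tt$region == "T-loop"][1]
  b <- substring(ref, tpos, tpos)
  sa2 <- structural_assessment(
    tibble::tibble(pos = tpos, ref = b,
                   alt = setdiff(c("A", "C", "G", "T"), b)[1]), st_tt)
  expect_false(sa2$alteration)

  # anticodon-loop positions carry the functional flag only
  apos <- st_tt$pos[st_tt$region == "anticodon loop"][1]
  ab <- substring(ref, apos, apos)
  sa3 <- structural_assessment(
    tibble::tibble(pos = apos, ref = ab,
                   alt = setdiff(c("A", "C", "G", "T"), ab)[1]), st_tt)
  expect_true(sa3$anticodon_loop)
  expect_false(sa3$alteration)

  expect_error(structural_assessment(
    tibble::tibble(pos = 100, ref = "A", alt = "G"), st), "absent")
})

test_that("creating a G-U wobble from G-C counts as an alteration", {
  # hand-built two-position stem: 5' G pairs 3' C on an H-strand gene
  st <- tibble::tibble(
    gene = "MT-TX", pos = c(1001L, 1002L), strand = "H",
    trna_number = c(31, 39), region = "anticodon stem",
    partner_number = c(39, 31), partner_pos = c(1002L, 1001L),
    gene_strand_base = c("G", "C"))
  # C -> T at the 3' side: G-C becomes G-U (wobble, non-Watson-Crick)
  sa <- structural_assessment(
    tibble::tibble(pos = 1002, ref = "C", alt = "T"), st)
  expect_true(sa$alteration)
  # G -> A at the 5' side: G-C becomes A-C, also an alteration
  sa2 <- structural_assessment(
    tibble::tibble(pos = 1001, ref = "G", alt = "A"), st)
  expect_true(sa2$alteration)
})

test_that("loop positions never report alterations across all tRNAs", {
  ref <- synthetic_reference(3)
  st <- trna_structures(reference = ref)
  loops <- st[st$region %in% c("D-loop", "T-loop", "variable region",
                               "linker"), ]
  pick <- loops[seq(1, nrow(loops), by = 13), ]
  alleles <- tibble::tibble(
    pos = pick$pos,
    ref = ifelse(pick$strand == "L",
                 chartr("ACGT", "TGCA", pick$gene_strand_base),
                 pick$gene_strand_base))
  alleles$alt <- vapply(alleles$ref, function(b)
    setdiff(c("A", "C", "G", "T"), b)[1], character(1))
  sa <- structural_assessment(alleles, st)
  expect_false(any(sa$alteration))
})

test_that("tRNA verdicts are the conjunction of the three criteria", {
  # documented examples
  v <- classify_trna(tibble::tibble(
    allele = c("m.5628T>C", "m.12178C>T", "m.12172A>G"),
    absent_in_controls = c(TRUE, TRUE, TRUE),
    panel_count = c(4L, 0L, 31L),   # 0.15%, 0.00%, 1.15% of 2704
    ci = c(94.12, 64.71, 88.24),
    alteration = c(TRUE, TRUE, FALSE)))
  expect_equal(v$pathogenic, c(TRUE, FALSE, FALSE))

  # randomized conjunction oracle
  set.seed(8)
  rv <- tibble::tibble(
    absent_in_controls = sample(c(TRUE, FALSE), 60, replace = TRUE),
    panel_ok = sample(c(TRUE, FALSE), 60, replace = TRUE),
    ci = runif(60, 0, 100),
    alteration = sample(c(TRUE, FALSE), 60, replace = TRUE))
  out <- classify_trna(rv)
  expect_equal(out$pathogenic,
               rv$absent_in_controls & rv$panel_ok & (rv$ci > 75) &
                 rv$alteration)

  expect_error(classify_trna(tibble::tibble(absent_in_controls = TRUE,
                                            alteration = TRUE)),
               "panel")
  expect_error(classify_trna(tibble::tibble(absent_in_controls = TRUE,
                                            alteration = TRUE,
                                            panel_ok = TRUE,
                                            ci = NA_real_)),
               "ci")
})

test_that("protein shortlist keeps stars >= 2 with HF above threshold", {
  tab2 <- tibble::tibble(
    allele = c("m.9438G>A", "m.9490C>T", "m.9755G>C", "m.9856T>C",
               "m.9957T>C"),
    stars = c(2L, 2L, 1L, 2L, 2L),
    hf = c(42.05, 99.23, 99.59, 99.71, 99.35))
  out <- protein_shortlist(tab2)
  expect_setequal(out$allele,
                  c("m.9438G>A", "m.9490C>T", "m.9856T>C", "m.9957T>C"))
  expect_equal(nrow(protein_shortlist(
    tibble::tibble(stars = c(1L, 1L), hf = c(99, 99)))), 0)
  expect_equal(nrow(protein_shortlist(
    tibble::tibble(stars = 3L, hf = 39))), 0)
})
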