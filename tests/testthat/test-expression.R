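make_ct <- function(genotype, treatment, gene, bio_rep, tech_rep, ct) {
  data.frame(genotype = genotype, treatment = treatment, gene = gene,
             bio_rep = bio_rep, tech_rep = tech_rep, ct = ct,
             stringsAsFactors = FALSE)
}

test_that("technical replicates collapse to cell means", {
  d <- make_ct("g", "c", "x", 1, 1:2, c(20, 20))
  expect_equal(collapse_technical(d)$ct, 20)
  d2 <- make_ct("g", "c", "x", 1, 1:2, c(19.8, 20.2))
  expect_equal(collapse_technical(d2)$ct, 20)
  set.seed(9)
  d3 <- expand.grid(genotype = c("a", "b"), treatment = c("c", "s"),
                    gene = c("t", "ref"), bio_rep = 1:2, tech_rep = 1:3,
                    KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
  d3$ct <- runif(nrow(d3), 18, 30)
  got <- collapse_technical(d3)
  for (i in seq_len(nrow(got))) {
    sub <- d3$ct[d3$genotype == got$genotype[i] &
                 d3$treatment == got$treatment[i] &
                 d3$gene == got$gene[i] & d3$bio_rep == got$bio_rep[i]]
    expect_equal(got$ct[i], mean(sub))
  }
})

test_that("CT validation flags out-of-range and non-finite values", {
  expect_warning(collapse_technical(make_ct("g", "c", "x", 1, 1, 3)),
                 "outside the usual")
  expect_error(collapse_technical(make_ct("g", "c", "x", 1, 1, NA)),
               "non-finite CT")
  expect_error(collapse_technical(data.frame(ct = 1)), "missing column")
})

test_that("delta-CT and fold change follow the Livak identities", {
  expect_equal(delta_ct(25, 20), 5)
  expect_equal(delta_ct(20, 20), 0)
  expect_equal(delta_ct(18.3, 20.1), -1.8)
  expect_equal(fold_change(2, 2), 1)       # calibrator identity
  expect_equal(fold_change(1, 2), 2)       # ddCT = -1 doubles
  expect_equal(fold_change(-3.645 + 1, 1), 2^3.645, tolerance = 1e-12)
  expect_equal(2^3.645, 12.51, tolerance = 1e-3)  # severe-stress dehydrin scale
  # chaining and monotonicity
  set.seed(2)
  dct <- rnorm(3, 0, 3)
  expect_equal(fold_change(dct[1], dct[3]),
               fold_change(dct[1], dct[2]) * fold_change(dct[2], dct[3]),
               tolerance = 1e-12)
  dd <- sort(rnorm(20))
  expect_true(all(diff(2^-dd) < 0))
})

test_that("relative_expression normalizes, calibrates and reports folds", {
  # two treatments, flat reference at 20, target induced by 2 cycles
  d <- rbind(
    make_ct("g", "control_90_95FC", "ref", 1, 1, 20),
    make_ct("g", "control_90_95FC", "tgt", 1, 1, 25),
    make_ct("g", "stress", "ref", 1, 1, 20),
    make_ct("g", "stress", "tgt", 1, 1, 23)
  )
  rel <- relative_expression(d, reference = "ref")
  expect_equal(rel$dct, c(5, 3))
  expect_equal(rel$ddct, c(0, -2))
  expect_equal(rel$fold_change, c(1, 4))
  sm <- summarize_expression(rel)
  expect_equal(sm$fold_change[sm$treatment == "control_90_95FC"], 1)
  expect_error(relative_expression(d, reference = "nope"),
               "reference gene")
  expect_error(relative_expression(d, reference = "ref",
                                   calibrator = "nope"), "calibrator")
  # missing reference cell is a structured error naming the cell
  expect_error(relative_expression(d[-3, ], reference = "ref"),
               "reference gene missing for cell")
})

test_that("configured expression shifts round-trip through the generator", {
  cfg <- sim_config(seed = 4, ct_noise_sd = 0, ct_bio_sd = 0)
  ct <- sim_ct_table(cfg)
  rel <- relative_expression(ct, reference = cfg$reference_gene)
  sm <- summarize_expression(rel)
  shift <- default_log2_shift()
  for (cl in c("tolerant", "sensitive")) {
    geno <- unique(ct$genotype[ct$class == cl])
    for (g in rownames(shift[[cl]])) for (tr in colnames(shift[[cl]])) {
      got <- sm$fold_change[sm$genotype == geno & sm$gene == g &
                            sm$treatment == tr]
      expect_equal(got, 2^shift[[cl]][g, tr], tolerance = 1e-9)
    }
  }
  # the flagship induction: 12.51-fold dehydrin under severe stress
  expect_equal(sm$fold_change[sm$genotype == "G-tol" & sm$gene == "Dhn1" &
                              sm$treatment == "severe_25_30FC"],
               12.51, tolerance = 1e-9)
})

test_that("noisy synthetic CTs recover the configured mean log2 shift", {
  cfg <- sim_config(seed = 21)
  ct <- sim_ct_table(cfg)
  sm <- summarize_expression(relative_expression(ct))
  want <- default_log2_shift()$tolerant["Dhn1", "severe_25_30FC"]
  got <- -sm$ddct[sm$genotype == "G-tol" & sm$gene == "Dhn1" &
                  sm$treatment == "severe_25_30FC"]
  # bio sd 0.25 on two bio reps of target and reference -> generous band
  expect_lt(abs(got - want), 1.5)
})

test_that("primer efficiency is recovered from a standard curve", {
  # perfect doubling: slope -1/log10(2)
  lg <- c(0, -1, -2, -3)
  eff <- primer_efficiency(lg, 20 - (1 / log10(2)) * lg)
  expect_equal(eff$efficiency, 1, tolerance = 1e-9)
  expect_equal(eff$slope, -1 / log10(2), tolerance = 1e-9)
  # forward-simulated 90% efficiency, zero noise
  e09 <- primer_efficiency(lg, 25 - (1 / log10(1.9)) * lg)
  expect_equal(e09$efficiency, 0.9, tolerance = 1e-9)
  expect_equal(e09$r_squared, 1, tolerance = 1e-9)
  expect_error(primer_efficiency(lg, rep(20, 4)), "degenerate")
  expect_error(primer_efficiency(c(0, -1), c(20, 23)), "at least 3")
})
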