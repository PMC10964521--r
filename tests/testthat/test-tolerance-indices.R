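test_that("hand-evaluated index examples are reproduced", {
  # yp=4, ys=1 in a trial with mean yp 2, mean ys 1 (SI = 0.5)
  y <- data.frame(genotype = 1, yp = 4, ys = 1)
  idx <- stress_indices(y, mean_yp = 2, mean_ys = 1)
  expect_equal(idx$tol, 3)
  expect_equal(idx$mp, 2.5)
  expect_equal(idx$gmp, 2)
  expect_equal(idx$hm, 1.6)
  expect_equal(idx$sti, 1.0)
  expect_equal(idx$ssi, 1.5)
  expect_equal(attr(idx, "trial")$stress_intensity, 0.5)

  # equal yields: no loss, symmetric means
  y2 <- data.frame(genotype = 1, yp = 3, ys = 3)
  idx2 <- stress_indices(y2, mean_yp = 4, mean_ys = 2)
  expect_equal(idx2$tol, 0)
  expect_equal(idx2$ssi, 0)
  expect_equal(idx2$mp, 3)
  expect_equal(idx2$gmp, 3)
  expect_equal(idx2$hm, 3)
})

test_that("indices match the brute-force oracle on random trials", {
  set.seed(42)
  for (trial in 1:100) {
    y <- random_yields(5)
    got <- stress_indices(y)
    want <- oracle_indices(y, mean(y$yp), mean(y$ys))
    for (col in c("ssi", "tol", "mp", "gmp", "sti", "hm"))
      expect_equal(got[[col]], want[[col]], tolerance = 1e-12)
  }
})

test_that("index identities and AM-GM-HM ordering hold on random yields", {
  set.seed(7)
  y <- random_yields(200)
  idx <- stress_indices(y)
  myp <- mean(y$yp)
  expect_true(all(idx$mp >= idx$gmp & idx$gmp >= idx$hm))
  expect_equal(idx$gmp^2, y$yp * y$ys, tolerance = 1e-9)
  expect_equal(idx$sti, idx$gmp^2 / myp^2, tolerance = 1e-9)
  # equality of the three means iff yp == ys
  eq <- data.frame(genotype = 1, yp = 2.5, ys = 2.5)
  ieq <- stress_indices(eq, mean_yp = 3, mean_ys = 2)
  expect_equal(ieq$mp, ieq$gmp)
  expect_equal(ieq$gmp, ieq$hm)
})

test_that("a genotype with the population's relative loss has SSI exactly 1", {
  y <- data.frame(genotype = 1:3, yp = c(2, 4, 6), ys = c(1.2, 2.4, 3.6))
  idx <- stress_indices(y)  # every ys/yp = mean_ys/mean_yp = 0.6
  expect_equal(idx$ssi, rep(1, 3), tolerance = 1e-12)
})

test_that("invalid yield tables are rejected with informative errors", {
  expect_error(stress_indices(data.frame(genotype = 1, yp = 0, ys = 1)),
               "non-positive yp")
  expect_error(stress_indices(data.frame(genotype = 1, yp = -2, ys = 1)),
               "non-positive yp")
  expect_error(stress_indices(data.frame(genotype = c(1, 1),
                                         yp = c(2, 3), ys = c(1, 1))),
               "duplicate genotype")
  expect_error(stress_indices(data.frame(genotype = 1, yp = 3, ys = 3)),
               "stress intensity is zero")
  expect_error(stress_indices(data.frame(genotype = 1, yp = 3)),
               "missing column")
})

test_that("sensitivity slope: closed forms and least-squares oracle", {
  # a genotype tracking the environment means one-to-one has slope 1
  b <- fw_slope(data.frame(genotype = 1:2, yp = c(4, 3), ys = c(2, 1)))
  expect_equal(unname(b), c(1, 1))
  # two environments: (yp - ys) / (mean_yp - mean_ys)
  y <- data.frame(genotype = 1:3, yp = c(4, 2, 6), ys = c(2, 2, 1))
  b2 <- fw_slope(y)
  expect_equal(unname(b2), (y$yp - y$ys) / (mean(y$yp) - mean(y$ys)))
  # flat genotype has slope 0
  yf <- data.frame(genotype = 1:2, e1 = c(5, 1), e2 = c(5, 9),
                   e3 = c(5, 2), e4 = c(5, 8))
  expect_equal(unname(fw_slope(yf))[1], 0)
  # 4-environment random tables against the normal-equations oracle
  set.seed(11)
  for (trial in 1:25) {
    Y <- matrix(runif(24, 1, 10), nrow = 6)
    tab <- data.frame(genotype = 1:6, Y)
    expect_equal(unname(fw_slope(tab)), oracle_slope(Y), tolerance = 1e-10)
  }
  expect_error(fw_slope(data.frame(genotype = 1, e1 = 2)), "at least two")
  expect_error(fw_slope(data.frame(genotype = 1:2, e1 = c(1, 3),
                                   e2 = c(3, 1))),
               "environment means are all equal")
})

test_that("STS is the signed sum of its seven components", {
  comp <- data.frame(gmp = 2, sti = 0.5, hm = 1.6, mp = 2.5,
                     tol = 3, ssi = 1, b = 0.8)
  expect_equal(sts_score(comp)$sts, 1.8)
  zero <- as.data.frame(as.list(setNames(rep(0, 7),
           c("gmp", "sti", "hm", "mp", "tol", "ssi", "b"))))
  expect_equal(sts_score(zero)$sts, 0)
  # chained hand evaluation from the yp=4/ys=1 example with a stated
  # two-environment summary (mean_yp 2, mean_ys 1 -> b = 3)
  y <- data.frame(genotype = 1, yp = 4, ys = 1)
  idx <- stress_indices(y, mean_yp = 2, mean_ys = 1)
  idx$b <- (4 - 1) / (2 - 1)
  expect_equal(sts_score(idx)$sts, 2 + 1 + 1.6 + 2.5 - 3 - 1.5 - 3)
  expect_error(sts_score(data.frame(gmp = 1)), "missing component")
  comp$b <- NA
  expect_error(sts_score(comp), "non-finite")
})

test_that("ranking is a deterministic bijection with documented ties", {
  idx <- data.frame(genotype = c(5, 3, 9), sts = c(2, 2, 7))
  rk <- rank_genotypes(idx)
  expect_equal(rk$rank[rk$genotype == 9], 1)
  expect_equal(rk$rank[rk$genotype == 3], 2)  # tie broken by smaller id
  expect_equal(rk$rank[rk$genotype == 5], 3)
  expect_equal(rank_genotypes(data.frame(genotype = 1, sts = 0))$rank, 1)
  empty <- rank_genotypes(data.frame(genotype = numeric(0),
                                     sts = numeric(0)))
  expect_equal(nrow(empty), 0)
  # permutation invariance of the genotype -> rank map
  set.seed(3)
  big <- data.frame(genotype = 1:50, sts = rnorm(50))
  r1 <- rank_genotypes(big)
  shuf <- big[sample(50), ]
  r2 <- rank_genotypes(shuf)
  m <- match(r1$genotype, r2$genotype)
  expect_equal(r1$rank, r2$rank[m])
  expect_setequal(r1$rank, 1:50)
})

test_that("extreme classification takes k from each end, ordered outward", {
  idx <- rank_genotypes(data.frame(genotype = 1:5,
                                   sts = c(5, 3, 9, 1, 7)))
  ex <- classify_extremes(idx, k_tolerant = 2, k_sensitive = 2)
  expect_equal(ex$tolerant, c(3, 5))       # best first
  expect_equal(ex$sensitive, c(4, 2))      # worst first
  expect_length(classify_extremes(idx, 0, 0)$tolerant, 0)
  expect_error(classify_extremes(idx, 4, 2), "between 0 and")
})

test_that("sts_table pipeline is consistent with its parts", {
  set.seed(5)
  y <- random_yields(20)
  tab <- sts_table(y)
  idx <- stress_indices(y)
  expect_equal(tab$gmp, idx$gmp)
  expect_equal(tab$b, unname(fw_slope(y)), ignore_attr = TRUE)
  expect_equal(tab$sts,
               tab$gmp + tab$sti + tab$hm + tab$mp - tab$tol - tab$ssi -
                 tab$b, tolerance = 1e-12)
  expect_setequal(tab$rank, 1:20)
})
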