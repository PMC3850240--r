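test_that("base simulation has Binomial(2, 0.5) genotype marginals and a bimodal phenotype", {
  st <- sim_setting("high", n = 1000, p = 2000, seed = 7)
  sim <- simulate_base(st)
  G <- sim$genotypes$values
  freqs <- c(mean(G == 0), mean(G == 1), mean(G == 2))
  expect_equal(freqs, c(0.25, 0.5, 0.25), tolerance = 0.01)
  # per-column allele frequency within 3 SE of 0.5
  af <- colMeans(G) / 2
  se <- sqrt(0.5 * 0.5 / (2 * 1000))
  expect_gt(mean(abs(af - 0.5) < 3 * se), 0.99)
  y <- sim$phenotype
  expect_length(y, 1000)
  expect_equal(mean(y), 0, tolerance = 0.2)
  expect_equal(mean(y[1:500]), 2, tolerance = 0.2)
  expect_equal(mean(y[501:1000]), -2, tolerance = 0.2)
})

test_that("simulation is deterministic given the seed", {
  a <- make_setting("mixed", p = 500, n_causal = 25, seed = 11, n = 200)
  b <- make_setting("mixed", p = 500, n_causal = 25, seed = 11, n = 200)
  expect_identical(a$genotypes$values, b$genotypes$values)
  expect_identical(a$phenotype, b$phenotype)
  expect_identical(a$causal, b$causal)
  c <- make_setting("mixed", p = 500, n_causal = 25, seed = 12, n = 200)
  expect_false(identical(a$genotypes$values, c$genotypes$values))
})

test_that("causal embedding preserves each column's value multiset and targets the high half", {
  st <- sim_setting("high", n = 400, p = 100, seed = 3)
  sim <- simulate_base(st)
  before <- sim$genotypes$values[, 5:9]
  G <- embed_causal_block(sim$genotypes, sim$phenotype, 5:9)
  after <- G$values[, 5:9]
  for (k in 1:5) {
    expect_identical(tabulate(before[, k] + 1L, 3L),
                     tabulate(after[, k] + 1L, 3L))
    # all 2s in the top half, all 0s in the bottom half
    expect_true(all(which(after[, k] == 2) <= 200))
    expect_true(all(which(after[, k] == 0) > 200))
  }
  # non-causal columns untouched
  expect_identical(G$values[, 20], sim$genotypes$values[, 20])
})

test_that("causal SNPs correlate with the phenotype component, not its exact rank", {
  d <- make_setting("high", p = 2000, n_causal = 25, seed = 5)
  r_y <- mean(cor(d$genotypes$values[, d$causal$index], d$phenotype))
  # analytic value: cov(x, y) = 1, var(x) = 1/2, var(y) = 5 => r = 1/sqrt(2.5)
  expect_equal(r_y, 1 / sqrt(2.5), tolerance = 0.03)
})

test_that("mean pairwise causal correlation hits the high/mixed/low targets over seeds", {
  seeds <- 1:20
  r <- sapply(seeds, function(s) {
    sapply(c("high", "mixed", "low"), function(nm) {
      d <- make_setting(nm, p = 1000, n_causal = 25, seed = s)
      mean_pairwise_cor(d$genotypes, d$causal$index)
    })
  })
  m <- rowMeans(r)
  expect_gt(m["high"], 0.95); expect_lt(m["high"], 0.99)
  expect_gt(m["mixed"], 0.74); expect_lt(m["mixed"], 0.82)
  expect_gt(m["low"], 0.50); expect_lt(m["low"], 0.60)
})

test_that("degrade_ld leaves the matrix unchanged at fraction 0 and scales correlation as (1-f)^2", {
  d <- make_setting("high", p = 500, n_causal = 25, seed = 2)
  same <- degrade_ld(d$genotypes, d$causal$index, 0, seed = 1)
  expect_identical(same$values, d$genotypes$values)
  r0 <- mean_pairwise_cor(d$genotypes, d$causal$index)
  f <- 0.4
  rs <- sapply(1:10, function(s)
    mean_pairwise_cor(degrade_ld(d$genotypes, d$causal$index, f, seed = s),
                      d$causal$index))
  expect_equal(mean(rs), (1 - f)^2 * r0, tolerance = 0.03)
})

test_that("full permutation of causal columns destroys the phenotype association", {
  rr <- sapply(1:20, function(s) {
    d <- make_setting("high", p = 200, n_causal = 25, seed = s)
    Gp <- degrade_ld(d$genotypes, d$causal$index, 1, seed = s + 999)
    mean(abs(cor(Gp$values[, d$causal$index], d$phenotype)))
  })
  expect_lt(mean(rr), 0.05)
})

test_that("block layout follows the scaled centers and errors are raised for bad input", {
  d <- make_setting("high", p = 50000, n_causal = 25, seed = 1, n = 10)
  centers <- c(1000, 10000, 20000, 30000, 40000)
  expected <- sort(as.integer(outer(-2:2, centers, `+`)))
  expect_identical(d$causal$index, expected)
  d2 <- make_setting("high", p = 5000, n_causal = 25, seed = 1, n = 10)
  expect_identical(unique(diff(d2$causal$index))[1], 1L)
  expect_equal(d2$causal$index[3 + 5 * (0:4)], round(centers / 10))
  expect_error(sim_setting("high", n = 999), "even")
  expect_error(sim_setting("high", p = 20, n = 10), "too small")
  expect_error(degrade_ld(d2$genotypes, 1:2, 1.5, 1), "fraction")
  expect_error(embed_causal_block(d2$genotypes, d2$phenotype, 99999),
               "out of range")
})

test_that("mixed setting degrades exactly the first and last causal blocks", {
  d <- make_setting("mixed", p = 2000, n_causal = 25, seed = 4)
  cls <- d$causal$ld_class
  expect_identical(cls[1:5], rep("partially_permuted", 5))
  expect_identical(cls[21:25], rep("partially_permuted", 5))
  expect_identical(cls[6:20], rep("sorted", 15))
  dl <- make_setting("low", p = 2000, n_causal = 25, seed = 4)
  expect_true(all(dl$causal$ld_class == "partially_permuted"))
})

test_that("genotype_matrix validates entries and dimensions", {
  expect_error(genotype_matrix(matrix(c(0, 1, 3, 2), 2)), "row 1, column 2")
  expect_error(genotype_matrix(matrix(0:1, 2, 2),
                               snp_ids = c("a", "a")), "unique")
  g <- genotype_matrix(matrix(c(0, 1, NA, 2), 2))
  expect_identical(dim(g), c(2L, 2L))
})
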