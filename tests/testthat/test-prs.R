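# PRS construction: p-value thresholding, LD clumping, region exclusion,
# panel scoring.

test_that("p-value filter keeps the boundary and warns on empty result", {
  ss <- toy_sumstats(beta = c(0.3, 0.1, 0.05), se = 0.1)
  ss$p <- c(0.005, 0.02, 0.5)
  expect_equal(pvalue_filter(ss, 0.01)$p, 0.005)
  ss$p <- c(0.01, 0.02, 0.5)
  expect_equal(nrow(pvalue_filter(ss, 0.01)), 1)      # p == threshold kept
  expect_equal(nrow(pvalue_filter(ss, 1.0)), 3)
  expect_warning(out <- pvalue_filter(ss, 1e-6), "no variants")
  expect_equal(nrow(out), 0)
})

test_that("greedy clumping follows the hand-traced example", {
  set.seed(5)
  n <- 400
  x1 <- rbinom(n, 2, 0.3)
  # x2 strongly correlated with x1, x3 nearly independent
  x2 <- ifelse(runif(n) < 0.85, x1, rbinom(n, 2, 0.3))
  x3 <- rbinom(n, 2, 0.4)
  panel <- toy_panel(list(x1, x2, x3), pos = c(1e5, 2e5, 3e5))
  expect_gt(cor(x1, x2)^2, 0.1)
  expect_lt(cor(x1, x3)^2, 0.1)
  ss <- toy_sumstats(beta = c(0.5, 0.4, 0.3), se = c(0.088, 0.082, 0.0775),
                     pos = c(1e5, 2e5, 3e5))
  expect_true(all(diff(ss$p) > 0))
  cl <- ld_clump(ss, panel, r2_cutoff = 0.1, radius_bp = 1e6)
  expect_equal(sort(cl$index_variants$id), c("rs1", "rs3"))
  expect_equal(unname(cl$removed["rs2"]), "rs1")
})

test_that("clumping respects the radius and breaks p ties by position", {
  x <- rbinom(300, 2, 0.4)
  panel <- toy_panel(list(x, x), pos = c(1e6, 3e6))   # r^2 = 1, 2 Mb apart
  ss <- toy_sumstats(beta = c(0.5, 0.5), se = 0.1, pos = c(1e6, 3e6))
  cl <- ld_clump(ss, panel, 0.1, 1e6)
  expect_equal(nrow(cl$index_variants), 2)            # outside the radius

  panel2 <- toy_panel(list(x, x), pos = c(1e6, 1.5e6))
  ss2 <- toy_sumstats(beta = c(0.5, 0.5), se = 0.1, pos = c(1e6, 1.5e6))
  cl2 <- ld_clump(ss2, panel2, 0.1, 1e6)
  expect_equal(cl2$index_variants$id, "rs1")          # equal p: lower pos wins

  miss <- toy_sumstats(beta = 0.1, se = 0.1, pos = 7e6)
  expect_error(ld_clump(miss, panel, 0.1, 1e6), "absent from panel")
})

test_that("clumping matches the naive reference on random instances", {
  set.seed(6)
  for (rep in 1:25) {
    m <- sample(5:50, 1)
    n <- 150
    cfg <- sim_config(n_individuals = n, n_variants = m, ld_block_size = 5,
                      within_block_corr = 0.7, seed = 6000 + rep)
    panel <- sim_genotypes(cfg)
    b <- rnorm(m); s2 <- runif(m, 0.05, 0.3)
    ss <- sumstats(panel$variants, beta = b, se = s2, z = b / s2, n = n)
    r2 <- runif(1, 0.05, 0.6)
    radius <- sample(c(5e3, 2e4, 1e6), 1)
    got <- ld_clump(ss, panel, r2, radius)
    want <- reference_clump(as.data.frame(ss),
                            panel$dosages[, match(variant_key(ss),
                                                  variant_key(panel$variants))],
                            r2, radius)
    expect_setequal(got$index_variants$id, want)
    expect_setequal(c(got$index_variants$id, names(got$removed)), ss$id)
  }
})

test_that("degenerate cutoffs behave as limits dictate", {
  cfg <- sim_config(n_individuals = 200, n_variants = 30, ld_block_size = 30,
                    within_block_corr = 0.9, seed = 77)
  panel <- sim_genotypes(cfg)
  m <- 30
  b <- rnorm(m)
  ss <- sumstats(panel$variants, beta = b, se = 0.1, z = b / 0.1, n = 200)
  # cutoff near 1: nothing removed
  expect_equal(nrow(ld_clump(ss, panel, 1 - 1e-9, 1e6)$index_variants), m)
  # tiny cutoff, huge radius: one index per chromosome
  cl <- ld_clump(ss, panel, 1e-12, 1e9)
  expect_equal(nrow(cl$index_variants), length(unique(ss$chrom)))
})

test_that("clumping is invariant to input row order", {
  sim <- small_sim(seed = 13, n = 250, m = 40)
  ss <- sim$ss
  cl1 <- ld_clump(ss, sim$panel, 0.2, 1e6)
  shuf <- as.data.frame(ss)[sample(nrow(ss)), ]
  ss2 <- sumstats(shuf[VARIANT_COLS], beta = shuf$beta, se = shuf$se,
                  z = shuf$z, p = shuf$p, n = shuf$n)
  cl2 <- ld_clump(ss2, sim$panel, 0.2, 1e6)
  expect_setequal(cl1$index_variants$id, cl2$index_variants$id)
})

test_that("build_prs composes filter and clump; weights are the betas", {
  set.seed(7)
  n <- 400
  x1 <- rbinom(n, 2, 0.3)
  x2 <- ifelse(runif(n) < 0.9, x1, rbinom(n, 2, 0.3))   # tags x1
  x3 <- rbinom(n, 2, 0.4)
  x4 <- rbinom(n, 2, 0.2)
  x5 <- rbinom(n, 2, 0.5)
  panel <- toy_panel(list(x1, x2, x3, x4, x5), pos = (1:5) * 1e5)
  beta <- c(0.6, 0.5, -0.4, 0.05, 0.02)
  se <- c(0.1, 0.1, 0.1, 0.1, 0.1)
  ss <- toy_sumstats(beta = beta, se = se, pos = (1:5) * 1e5)
  # p: rs1-rs3 well below 0.01; rs4, rs5 clearly above
  w <- build_prs(ss, panel, p_threshold = 0.01, r2_cutoff = 0.1,
                 radius_bp = 1e6)
  expect_setequal(w$variants$id, c("rs1", "rs3"))
  expect_equal(unname(w$weights[order(w$variants$id), 1]),
               beta[c(1, 3)])
  expect_false(isTRUE(attr(w, "standardized_weight")))

  # z-only summary statistics fall back to z weights, flagged
  zz <- sumstats(ss[VARIANT_COLS], z = ss$z, p = ss$p, n = 400)
  wz <- build_prs(zz, panel)
  expect_true(attr(wz, "standardized_weight"))
  expect_equal(sort(unname(wz$weights[, 1])), sort(zz$z[c(1, 3)]))

  hopeless <- toy_sumstats(beta = 0.01, se = 0.1)
  expect_warning(w0 <- build_prs(hopeless, panel), "threshold")
  expect_equal(nrow(w0$variants), 0)
})

test_that("region exclusion respects printed APOE boundaries inclusively", {
  apoe <- read_regions("19:45147340-45594595")
  pos <- c(45147339, 45147340, 45200000, 45594595, 45594596)
  w <- weight_matrix(toy_variants(5, chrom = "19", pos = pos),
                     matrix(1, 5, 1, dimnames = list(NULL, "t")))
  out <- exclude_region(w, apoe)
  expect_setequal(out$variants$pos, c(45147339, 45594596))

  # excluding a union equals sequential exclusion
  r1 <- region_set("19", 45147340, 45300000)
  r2 <- region_set("19", 45300001, 45594595)
  both <- region_set(rep("19", 2), c(45147340, 45300001),
                     c(45300000, 45594595))
  expect_equal(exclude_region(w, both),
               exclude_region(exclude_region(w, r1), r2))
  expect_equal(exclude_region(w, region_set()), w)
})

test_that("panel scoring is the dosage-weight product with allele flips", {
  panel <- toy_panel(list(c(0, 1, 2)))
  w <- weight_matrix(toy_variants(1), matrix(2, 1, 1, dimnames = list(NULL, "t")))
  expect_equal(unname(score_panel(w, panel)[, 1]), c(0, 2, 4))

  # 3 x 2 hand multiplication
  p2 <- toy_panel(list(c(0, 1, 2), c(2, 0, 1)), pos = c(1e4, 2e4))
  w2 <- weight_matrix(toy_variants(2), matrix(c(1, -0.5, 0, 2), 2,
                                              dimnames = list(NULL, c("u", "v"))))
  expect_equal(unname(score_panel(w2, p2)),
               cbind(c(0 - 1, 1 - 0, 2 - 0.5), c(4, 0, 2)),
               ignore_attr = TRUE)

  # swapped alleles in the panel count the other allele: dosage 2 - d
  p3 <- toy_panel(list(c(0, 1, 2)), a1 = "G", a2 = "A")
  expect_equal(unname(score_panel(w, p3)[, 1]), 2 * c(2, 1, 0))

  wz <- weight_matrix(toy_variants(1), matrix(0, 1, 1, dimnames = list(NULL, "t")))
  expect_warning(sz <- score_panel(wz, panel), "no usable variants")
  expect_equal(unname(sz[, 1]), c(0, 0, 0))
})
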