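test_that("HWE priors are binomial and respect the Vandermonde identity", {
  expect_equal(hwe_prior(0.5, 2, 0), c(0.25, 0.5, 0.25))
  expect_equal(hwe_prior(0.5, 4, 0), c(1, 4, 6, 4, 1) / 16)
  for (k in c(2, 4, 6, 8)) {
    for (p in c(0.1, 0.37, 0.8)) {
      expect_equal(hwe_prior(p, k, 0), dbinom(0:k, k, p))
    }
  }
  # subgenome convolution equals the merged binomial
  for (hyp in list(c(2, 2), c(2, 2, 2), c(4, 4))) {
    for (p in c(0.2, 0.5, 0.7)) {
      expect_equal(hwe_prior(p, hyp, 0), hwe_prior(p, sum(hyp), 0),
                   tolerance = 1e-12)
    }
  }
})

test_that("full selfing removes heterozygotes at the diploid fixed point", {
  expect_equal(hwe_prior(0.5, 2, 1), c(0.5, 0, 0.5), tolerance = 1e-8)
  expect_equal(hwe_prior(0.2, 2, 1), c(0.8, 0, 0.2), tolerance = 1e-8)
})

test_that("selfing redistributes but never shifts the prior mean", {
  for (k in c(2, 4, 6)) {
    for (p in seq(0.1, 0.9, by = 0.1)) {
      for (s in c(0, 0.3, 0.7, 1)) {
        pr <- hwe_prior(p, k, s)
        expect_equal(sum(pr), 1, tolerance = 1e-9)
        expect_true(all(pr >= 0))
        expect_equal(sum(pr * 0:k), k * p, tolerance = 1e-7)
      }
    }
  }
  # partial selfing raises homozygosity relative to HWE
  pr0 <- hwe_prior(0.5, 4, 0)
  pr5 <- hwe_prior(0.5, 4, 0.5)
  expect_gt(pr5[1] + pr5[5], pr0[1] + pr0[5])
})

test_that("allele-frequency updates are pmg means renormalized per locus", {
  x <- toy_rad()
  pmg <- matrix(rep(c(2 * 0.3, 2 * 0.7), each = 4), 4, 2)
  pmg <- cbind(pmg, pmg)
  dimnames(pmg) <- list(x$taxa, x$alleles)
  p <- update_allele_freqs(pmg, x, 2)
  expect_equal(unname(p), c(0.3, 0.7, 0.3, 0.7))
  # raw means 0.2 and 0.9 renormalize to 2/11, 9/11
  pmg2 <- pmg
  pmg2[, 1] <- 2 * 0.2; pmg2[, 2] <- 2 * 0.9
  p2 <- update_allele_freqs(pmg2, x, 2)
  expect_equal(unname(p2[1:2]), c(0.2, 0.9) / 1.1)
  # truth genotypes give the exact sample frequency
  set.seed(8)
  sim <- simulate_raddata(sim_config(30, 8, ploidy = 2))
  pt <- update_allele_freqs(sim$truth, sim$data, 2)
  expect_equal(unname(pt), unname(colMeans(sim$truth) / 2))
})

test_that("structure frequencies recover per-cluster truth in a split panel", {
  set.seed(91)
  nt <- 100; nl <- 40; k <- 2
  sub <- rep(1:2, each = nt / 2)
  p1 <- runif(nl, 0.05, 0.45)
  p2 <- runif(nl, 0.55, 0.95)
  g <- matrix(0L, nt, nl)
  g[sub == 1, ] <- rbinom(nt / 2 * nl, k, rep(p1, each = nt / 2))
  g[sub == 2, ] <- rbinom(nt / 2 * nl, k, rep(p2, each = nt / 2))
  cfg <- sim_config(nt, nl, ploidy = k, locus_depth_shape = 8,
                    locus_depth_scale = 5)  # mean depth 40
  loci <- sprintf("loc%d", 1:nl)
  alleles <- as.vector(rbind(paste0(loci, "_A"), paste0(loci, "_B")))
  geno <- matrix(0L, nt, 2 * nl,
                 dimnames = list(sprintf("i%03d", 1:nt), alleles))
  geno[, seq(1, 2 * nl, 2)] <- g
  geno[, seq(2, 2 * nl, 2)] <- k - g
  x <- simulate_depths(geno, cfg, locus = setNames(rep(loci, each = 2),
                                                   alleles))
  fit <- iterate_hwe(x, k)
  indf <- popstruct_individual_freqs(fitted(fit), x, k, n_axes = 1)
  csub <- rbind(colMeans(g[sub == 1, ]) / k, colMeans(g[sub == 2, ]) / k)
  err <- abs(indf[, seq(1, 2 * nl, 2)] - csub[sub, ])
  expect_lt(mean(err), 0.1)
})

test_that("structure frequencies degrade to the global mean without variance", {
  x <- toy_rad()
  pmg <- matrix(rep(c(0.8, 1.2, 1.4, 0.6), each = 4), 4, 4,
                dimnames = list(x$taxa, x$alleles))
  indf <- popstruct_individual_freqs(pmg, x, 2, n_axes = 1)
  for (t in 1:4) expect_equal(unname(indf[t, ]), unname(indf[1, ]))
  # per-locus normalization keeps frequency sums at 1
  expect_equal(unname(rowSums(indf[, 1:2])), rep(1, 4))
  # clamping: fitted values at 0 map to the clamp floor
  pmg0 <- pmg; pmg0[, 1] <- 0; pmg0[, 2] <- 2
  indf0 <- popstruct_individual_freqs(pmg0, x, 2, n_axes = 1,
                                      clamp_eps = 0.01)
  expect_true(all(indf0[, 1] >= 0.01 / (0.01 + 0.99) - 1e-12))
  expect_error(popstruct_individual_freqs(pmg, x, 2, n_axes = 5),
               "individuals")
})

test_that("LD priors fall back to the base prior without neighbors", {
  set.seed(14)
  sim <- simulate_raddata(sim_config(20, 6, ploidy = 2))
  fit <- iterate_hwe(sim$data, 2)
  base <- fit$fits[[1]]$prior
  # loci are 10 kb apart; a 1 bp window finds nothing
  out <- ld_adjusted_priors(base, fitted(fit), fit$data,
                            ld_config(1), 2)
  expect_equal(out, base, ignore_attr = TRUE)
  # zero mixture weight is also the identity
  out0 <- ld_adjusted_priors(base, fitted(fit), fit$data,
                             ld_config(5e4, mix_weight = 0), 2)
  expect_equal(out0, base, ignore_attr = TRUE, tolerance = 1e-12)
  # positions are required
  xnp <- rad_data(sim$data$depth, locus = unname(sim$data$locus))
  expect_error(ld_adjusted_priors(base, fitted(fit), xnp,
                                  ld_config(5e4), 2), "positions")
})

test_that("a perfectly linked high-depth locus imputes a zero-depth locus", {
  set.seed(19)
  panel <- make_ld_panel(120, 20, depth_shape = 10, depth_scale = 5)
  fit <- iterate_hwe(panel$data, 2, use_ld = TRUE,
                     ld_cfg = ld_config(1000))
  masked <- panel$zero_mask
  r <- cor(as.vector(fitted(fit)[masked]),
           as.vector(panel$truth[masked]))
  expect_gt(r, 0.9)
})

test_that("mapping priors reproduce Mendelian F1 segregation", {
  set.seed(5)
  # diploid Aa x Aa with well-covered parents
  nl <- 4
  pd <- matrix(1L, 2, nl)
  cfg <- sim_config(20, nl, ploidy = 2, population = "f1",
                    parent_dosage = pd)
  truth <- simulate_truth_genotypes(cfg)
  x <- simulate_depths(truth, cfg)
  dep <- x$depth
  dep[1:2, ] <- as.integer(round(100 * truth[1:2, ] / 2))
  x <- rad_data(dep, locus = unname(x$locus))
  model <- pop_model(setNames(rep(0.5, ncol(dep)), colnames(dep)),
                     c = 0.001, d = 9)
  pr <- mapping_priors(x, cross_design("parent1", "parent2"), 2, model)
  expect_equal(unname(pr["prog001", 1, ]), c(0.25, 0.5, 0.25))
  expect_equal(attr(pr, "flagged"), character(0))
})

test_that("tetraploid AAAB x AAAA priors come from gamete enumeration", {
  dep <- matrix(0L, 3, 2,
                dimnames = list(c("P1", "P2", "prog"), c("L_B", "L_A")))
  # parent 1 has 1 copy of B (AAAB), parent 2 none (AAAA)
  dep["P1", ] <- c(50L, 150L)
  dep["P2", ] <- c(0L, 200L)
  dep["prog", ] <- c(1L, 3L)
  x <- rad_data(dep, locus = c("L", "L"))
  model <- pop_model(c(L_B = 0.125, L_A = 0.875), c = 0.001, d = 9)
  pr <- mapping_priors(x, cross_design("P1", "P2"), 4, model)
  expect_equal(unname(pr["prog", "L_B", ]), c(0.5, 0.5, 0, 0, 0))
  # monomorphic cross: AA x AA for the A allele gives a point prior
  expect_equal(unname(pr["prog", "L_A", ]), c(0, 0, 0, 0.5, 0.5))
})

test_that("F1 priors match the exhaustive gamete-pair oracle", {
  for (k in c(2, 4)) {
    ploidy <- ploidy_hypothesis(k)
    for (g1 in 0:k) {
      for (g2 in 0:k) {
        got <- dosecall:::conv(dosecall:::gamete_dist(g1, ploidy),
                               dosecall:::gamete_dist(g2, ploidy))
        expect_equal(got, f1_oracle(g1, g2, k), tolerance = 1e-12,
                     label = sprintf("k=%d g1=%d g2=%d", k, g1, g2))
      }
    }
  }
})

test_that("non-segregating loci fall back to HWE priors", {
  dep <- matrix(c(0L, 100L,
                  0L, 100L,
                  20L, 20L),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "prog"), c("L_B", "L_A")))
  x <- rad_data(dep, locus = c("L", "L"))
  # both parents called homozygous A, yet progeny minor freq is 0.5
  model <- pop_model(c(L_B = 0.5, L_A = 0.5), c = 0.001, d = 9)
  pr <- mapping_priors(x, cross_design("P1", "P2"), 2, model)
  expect_equal(attr(pr, "flagged"), "L")
  expect_equal(unname(pr["prog", "L_B", ]), dbinom(0:2, 2, 0.5))
  # a parent with zero depth also flags the locus
  dep0 <- dep; dep0["P1", ] <- 0L
  x0 <- rad_data(dep0, locus = c("L", "L"))
  pr0 <- mapping_priors(x0, cross_design("P1", "P2"), 2, model)
  expect_equal(attr(pr0, "flagged"), "L")
})

test_that("later generations shift the segregation distribution", {
  # F2 = F1 selfed once: Aa x Aa then selfing gives more homozygotes
  dep <- matrix(c(50L, 50L, 50L, 50L, 5L, 5L),
                nrow = 3, byrow = TRUE,
                dimnames = list(c("P1", "P2", "prog"), c("L_A", "L_B")))
  x <- rad_data(dep, locus = c("L", "L"))
  model <- pop_model(c(L_A = 0.5, L_B = 0.5), c = 0.001, d = 9)
  d_f1 <- cross_design("P1", "P2")
  d_f2 <- cross_design("P1", "P2", generations_selfing = 1)
  pr1 <- mapping_priors(x, d_f1, 2, model)["prog", "L_A", ]
  pr2 <- mapping_priors(x, d_f2, 2, model)["prog", "L_A", ]
  expect_equal(unname(pr1), c(0.25, 0.5, 0.25))
  expect_equal(unname(pr2), c(0.375, 0.25, 0.375))
  # backcross to P1 (Aa) from an Aa x AA cross
  dep2 <- dep; dep2["P2", ] <- c(100L, 0L)
  x2 <- rad_data(dep2, locus = c("L", "L"))
  d_bc <- cross_design("P1", "P2", generations_backcross = 1,
                       recurrent = "P1")
  pr_bc <- mapping_priors(x2, d_bc, 2, model)["prog", "L_A", ]
  # hand enumeration: F1 of Aa x AA is (0, 1/2, 1/2); its gametes carry A
  # with prob 3/4; crossing back to Aa gives (1/8, 1/2, 3/8)
  expect_equal(unname(pr_bc), c(0.125, 0.5, 0.375))
  # multi-subgenome hypotheses only support the F1 itself
  expect_error(mapping_priors(x, d_f2, c(2, 2), model),
               "single-subgenome")
})

test_that("every prior-producing operation yields normalized vectors", {
  set.seed(33)
  sim <- simulate_raddata(sim_config(25, 10, ploidy = 4))
  fit <- iterate_popstruct(sim$data, 4)
  pr <- fit$fits[[1]]$prior
  sums <- rowSums(pr, dims = 2)
  expect_true(all(abs(sums - 1) < 1e-9))
  expect_true(all(pr >= 0))
})
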