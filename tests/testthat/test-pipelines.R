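test_that("an infinite tolerance stops after exactly one iteration", {
  set.seed(6)
  sim <- simulate_raddata(sim_config(15, 8, ploidy = 2))
  fit <- iterate_hwe(sim$data, 2, tol = Inf)
  expect_equal(fit$n_iterations, 1L)
  expect_true(fit$converged)
  expect_s3_class(fit, "rad_fit")
})

test_that("non-convergence warns but still returns a result", {
  set.seed(6)
  sim <- simulate_raddata(sim_config(15, 8, ploidy = 2))
  expect_warning(fit <- iterate_hwe(sim$data, 2, tol = 0, max_iter = 2),
                 "converge")
  expect_false(fit$converged)
  expect_equal(fit$n_iterations, 2L)
})

test_that("a monomorphic locus drives posteriors to the full dosage", {
  dep <- matrix(c(9L, 0L, 14L, 0L, 6L, 0L),
                nrow = 3, byrow = TRUE,
                dimnames = list(paste0("t", 1:3), c("L_A", "L_B")))
  x <- rad_data(dep, locus = c("L", "L"))
  fit <- iterate_hwe(x, 2)
  expect_true(all(fit$fits[[1]]$posterior[, "L_A", "2"] > 0.99))
  expect_true(all(fit$discrete[, "L_A"] == 2L))
})

test_that("zero-depth genotypes take their posterior from the prior", {
  set.seed(23)
  sim <- simulate_raddata(sim_config(30, 10, ploidy = 2))
  dep <- sim$data$depth
  dep[1:5, ] <- 0L  # five individuals with no reads at all
  x <- rad_data(dep, locus = unname(sim$data$locus),
                chrom = sim$data$loci$chrom, pos = sim$data$loci$pos)
  for (fit in list(iterate_hwe(x, 2), iterate_popstruct(x, 2))) {
    f <- fit$fits[[1]]
    expect_equal(f$posterior[1:5, , ], f$prior[1:5, , ],
                 tolerance = 1e-12)
  }
})

test_that("the fitted object exposes genotypes and frequencies", {
  set.seed(7)
  sim <- simulate_raddata(sim_config(20, 6, ploidy = 2))
  fit <- iterate_hwe(sim$data, 2)
  expect_identical(fitted(fit), fit$pmg)
  expect_identical(coef(fit), fit$freq)
  expect_true(all(fitted(fit) >= 0 & fitted(fit) <= 2))
  # locus rows of pmg sum to k
  for (loc in fit$data$loci$locus) {
    j <- which(fit$data$locus == loc)
    expect_equal(unname(rowSums(fit$pmg[, j])),
                 rep(2, length(fit$data$taxa)), tolerance = 1e-6)
  }
  expect_output(print(fit), "hwe pipeline")
  expect_output(summary(fit), "heterozygous")
  # memory trimming drops the large arrays but keeps genotypes
  fit2 <- iterate_hwe(sim$data, 2, keep_arrays = FALSE)
  expect_null(fit2$fits[[1]]$prior)
  expect_equal(fit2$pmg, fit$pmg)
})

test_that("frequency recovery is nearly unbiased on model-matched data", {
  sim <- simulate_raddata(sim_config(300, 60, ploidy = 2,
                                     locus_depth_shape = 4,
                                     locus_depth_scale = 5, seed = 61))
  xf <- filter_markers(sim$data, 150, 5)
  fit <- iterate_hwe(xf, 2, c = 0.001, d = 9)
  err <- coef(fit) - sim$freq[names(coef(fit))]
  expect_lt(abs(mean(err)), 0.02)
})

test_that("mapping pipeline imputes zero-read F1 genotypes from segregation", {
  set.seed(44)
  nl <- 20
  pd <- matrix(1L, 2, nl)  # Aa x Aa everywhere
  cfg <- sim_config(50, nl, ploidy = 2, population = "f1",
                    parent_dosage = pd)
  truth <- simulate_truth_genotypes(cfg)
  x <- simulate_depths(truth, cfg)
  dep <- x$depth
  dep[1:2, ] <- as.integer(round(200 * truth[1:2, ] / 2))
  x <- rad_data(dep, locus = unname(x$locus))
  fit <- run_mapping(x, cross_design("parent1", "parent2"), 2)
  expect_equal(fit$n_iterations, 1L)
  # parents recovered exactly at depth 200
  expect_equal(fit$discrete[c("parent1", "parent2"), ],
               truth[1:2, ], ignore_attr = TRUE)
  # zero-read progeny genotypes sit at the prior mean of 1
  ld <- dosecall:::locus_depth(x)
  zero <- which(ld == 0, arr.ind = TRUE)
  zero <- zero[zero[, 1] > 2, , drop = FALSE]
  if (nrow(zero) > 0) {
    pmgA <- fit$pmg[, seq(1, 2 * nl, 2)]
    vals <- pmgA[cbind(zero[, 1], zero[, 2])]
    expect_equal(vals, rep(1, length(vals)), tolerance = 1e-9)
  }
  # beats the naive ratio estimator
  nv <- naive_genotypes(x, 2, setNames(colMeans(truth) / 2,
                                       colnames(truth)))
  expect_lt(rmse(fitted(fit), truth), rmse(nv, truth))
  expect_error(run_mapping(x, cross_design("absent", "parent2"), 2),
               "not found")
})

test_that("ploidy selection prefers the generating ploidy at high depth", {
  sim <- simulate_raddata(sim_config(100, 40, ploidy = 2,
                                     locus_depth_shape = 8,
                                     locus_depth_scale = 5, seed = 77))
  fit <- iterate_hwe(sim$data, list(2, 4))
  expect_gte(mean(fit$ploidy_choice == 1), 0.8)
  # single hypothesis: identity
  fit1 <- iterate_hwe(sim$data, 2)
  expect_true(all(fit1$ploidy_choice == 1L))
  # auto vs allo tetraploid are identical under HWE: tie goes first
  fit2 <- iterate_hwe(sim$data, list(4, c(2, 2)))
  expect_true(all(fit2$ploidy_choice == 1L))
})

test_that("genotype error shrinks with read depth", {
  sim <- simulate_raddata(sim_config(200, 60, ploidy = 2, seed = 88))
  xf <- filter_markers(sim$data, 100, 5)
  fit <- iterate_hwe(xf, 2, c = 0.001, d = 9)
  tr <- sim$truth[fit$data$taxa, names(coef(fit))]
  ld <- dosecall:::locus_depth(xf)[, match(xf$locus, xf$loci$locus)]
  bins <- list(c(0, 4), c(5, 9), c(10, 19), c(20, Inf))
  err <- vapply(bins, function(b) {
    m <- ld >= b[1] & ld <= b[2]
    sqrt(mean((fitted(fit)[m] - tr[m])^2))
  }, 0)
  expect_true(all(diff(err) <= 0))
})
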