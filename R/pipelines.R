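#' @name pipelines
#' @title Genotype-calling pipelines
#' @description End-to-end estimation of genotype posteriors: iterative
#'   pipelines for diversity panels (Hardy-Weinberg or population
#'   structure priors, optionally linkage-aware) and a one-pass pipeline
#'   for biparental mapping populations. Each returns a fitted
#'   `rad_fit` object.
NULL

# initial allele frequencies from raw depth ratios over non-blank taxa,
# floored and renormalized per locus
init_freqs <- function(x, k) {
  ld <- locus_depth(x)
  tot <- colSums(ld)[match(x$locus, x$loci$locus)]
  p <- colSums(x$depth) / pmax(tot, 1)
  p <- pmax(p, 1 / (2 * length(x$taxa) * k))
  for (j in locus_alleles(x)) p[j] <- p[j] / sum(p[j])
  stats::setNames(p, x$alleles)
}

# replicate an alleles x (k+1) prior matrix across taxa
expand_prior <- function(prior_mat, nt) {
  ka <- ncol(prior_mat)
  out <- array(NA_real_, dim = c(nt, nrow(prior_mat), ka))
  for (i in seq_len(ka))
    out[, , i] <- matrix(prior_mat[, i], nt, nrow(prior_mat), byrow = TRUE)
  attr(out, "kind") <- "prior"
  out
}

# per-individual binomial (selfing-adjusted) priors from an individual
# frequency matrix
ind_prior_array <- function(ind_freq, ploidy, s) {
  nt <- nrow(ind_freq)
  na <- ncol(ind_freq)
  k <- ploidy$k
  pm <- hwe_prior_mat(as.vector(ind_freq), ploidy, s)
  out <- array(pm, dim = c(nt, na, k + 1L))
  attr(out, "kind") <- "prior"
  out
}

run_one_iterative <- function(x, ploidy, model_args, structure_prior,
                              n_axes, tol, max_iter, use_ld, ld_cfg,
                              verbose) {
  k <- ploidy$k
  nt <- length(x$taxa)
  p <- init_freqs(x, k)
  pmg <- NULL
  trace <- data.frame(iteration = integer(), max_dp = numeric(),
                      mean_pmg_shift = numeric())
  converged <- FALSE
  it <- 0L
  repeat {
    it <- it + 1L
    if (structure_prior && !is.null(pmg)) {
      # fix the axis count at the first structure iteration: letting it
      # float re-creates spurious axes from the priors they induced
      if (is.null(n_axes)) n_axes <- default_n_axes(pmg, x, k)
      indf <- popstruct_individual_freqs(pmg, x, ploidy, n_axes = n_axes)
      model <- pop_model(p, c = model_args$c, d = model_args$d,
                         s = model_args$s, ind_freq = indf)
      priors <- ind_prior_array(indf, ploidy, model_args$s)
    } else {
      model <- pop_model(p, c = model_args$c, d = model_args$d,
                         s = model_args$s)
      priors <- expand_prior(hwe_prior_mat(p, ploidy, model_args$s), nt)
    }
    dimnames(priors) <- list(x$taxa, x$alleles, 0:k)
    if (use_ld && !is.null(pmg))
      priors <- ld_adjusted_priors(priors, pmg, x, ld_cfg, ploidy)
    lik <- genotype_likelihoods(x, ploidy, model)
    post <- posterior(priors, lik)
    pmg_new <- posterior_mean(post)
    p_new <- update_allele_freqs(pmg_new, x, ploidy)
    max_dp <- max(abs(p_new - p))
    shift <- if (is.null(pmg)) NA_real_ else mean(abs(pmg_new - pmg))
    trace <- rbind(trace, data.frame(iteration = it, max_dp = max_dp,
                                     mean_pmg_shift = shift))
    if (verbose)
      message(sprintf("iteration %d: max |dp| = %.3g, mean pmg shift = %.3g",
                      it, max_dp, shift))
    p <- p_new
    pmg <- pmg_new
    if (max_dp < tol) {
      converged <- TRUE
      break
    }
    if (it >= max_iter) break
  }
  list(ploidy = ploidy, prior = priors, likelihood = lik,
       posterior = post, pmg = pmg, discrete = most_probable(post),
       freq = p, model = model, n_iterations = it,
       converged = converged, trace = trace)
}

# per-locus log marginal likelihood of each hypothesis fit
locus_log_marginal <- function(x, fits) {
  vapply(fits, function(f) {
    marg <- rowSums(f$prior * f$likelihood, dims = 2L)
    marg[marg <= 0] <- .Machine$double.xmin
    lm_al <- colSums(log(marg))
    vapply(locus_alleles(x), function(j) sum(lm_al[j]), 0)
  }, numeric(nrow(x$loci)))
}

#' Select the best inheritance hypothesis per locus
#'
#' Given fits of the same data under several ploidy hypotheses, chooses
#' for each locus the hypothesis with the largest log marginal likelihood
#' (summed over individuals and the locus's alleles); ties go to the
#' first hypothesis listed. Note that under pure Hardy-Weinberg priors
#' with no selfing, auto- and allopolyploid hypotheses of equal total
#' ploidy yield identical priors and are indistinguishable; the choice is
#' only discriminative with mapping designs or selfing.
#'
#' @param x A [rad_data] object.
#' @param fits List of per-hypothesis fit components, each containing
#'   `prior` and `likelihood` arrays.
#' @return Integer vector (one per locus, named) indexing the chosen
#'   hypothesis, with the per-locus log marginal likelihood matrix as
#'   attribute `log_marginal`.
#' @export
select_ploidy <- function(x, fits) {
  lm_mat <- locus_log_marginal(x, fits)
  if (nrow(x$loci) == 1L) lm_mat <- matrix(lm_mat, nrow = 1L)
  choice <- max.col(lm_mat, ties.method = "first")
  names(choice) <- x$loci$locus
  attr(choice, "log_marginal") <- lm_mat
  choice
}

assemble_fit <- function(x, fits, method, keep_arrays, call) {
  choice <- if (length(fits) > 1L) select_ploidy(x, fits)
  else stats::setNames(rep(1L, nrow(x$loci)), x$loci$locus)
  al_choice <- choice[match(x$locus, x$loci$locus)]
  pmg <- fits[[1L]]$pmg
  disc <- fits[[1L]]$discrete
  freq <- fits[[1L]]$freq
  for (h in seq_along(fits)[-1L]) {
    sel <- al_choice == h
    pmg[, sel] <- fits[[h]]$pmg[, sel]
    disc[, sel] <- fits[[h]]$discrete[, sel]
    freq[sel] <- fits[[h]]$freq[sel]
  }
  attr(pmg, "discrete") <- FALSE
  attr(disc, "discrete") <- TRUE
  if (!keep_arrays) {
    fits <- lapply(fits, function(f) {
      f$prior <- NULL
      f$likelihood <- NULL
      f
    })
  }
  structure(list(call = call, method = method, data = x, fits = fits,
                 ploidies = lapply(fits, `[[`, "ploidy"),
                 ploidy_choice = choice, pmg = pmg, discrete = disc,
                 freq = freq,
                 model = fits[[which.max(tabulate(choice,
                                                  length(fits)))]]$model,
                 n_iterations = max(vapply(fits, `[[`, 0L,
                                           "n_iterations")),
                 converged = all(vapply(fits, `[[`, TRUE, "converged"))),
            class = "rad_fit")
}

#' Iterative genotype calling under Hardy-Weinberg priors
#'
#' For diversity panels without strong population structure. Allele
#' frequencies are initialized from raw depth ratios, then priors,
#' likelihoods, posteriors and posterior mean genotypes are re-estimated
#' iteratively until the largest allele-frequency change falls below
#' `tol` (or `max_iter` is reached, in which case the result is returned
#' with `converged = FALSE` and a warning). Blank control taxa are
#' excluded before fitting. With `use_ld = TRUE`, priors are additionally
#' informed by correlated alleles at nearby loci from the second
#' iteration onward.
#'
#' @param x A [rad_data] object (already filtered, see
#'   [filter_markers()]).
#' @param ploidies One or several ploidy hypotheses (integer vectors or
#'   [ploidy_hypothesis] objects, in a list when several); with several,
#'   the best hypothesis is chosen per locus by [select_ploidy()].
#' @param c Cross-contamination rate; see [estimate_contamination()].
#' @param d Beta-binomial overdispersion; see [test_overdispersion()].
#' @param s Self-fertilization rate.
#' @param tol Convergence tolerance on the maximum allele-frequency
#'   change between iterations.
#' @param max_iter Maximum number of iterations.
#' @param use_ld Use linkage-aware priors (requires genomic positions).
#' @param ld_cfg An [ld_config]; required when `use_ld = TRUE`.
#' @param keep_arrays Keep the full prior and likelihood arrays in the
#'   result (set `FALSE` to trim memory; posterior and genotypes are
#'   always kept).
#' @param verbose Log one line per iteration.
#' @return A [rad_fit] object.
#' @export
iterate_hwe <- function(x, ploidies = 2L, c = 0.001, d = 9, s = 0,
                        tol = 1e-3, max_iter = 50L, use_ld = FALSE,
                        ld_cfg = NULL, keep_arrays = TRUE,
                        verbose = FALSE) {
  cl <- match.call()
  x <- subset_taxa(x, non_blank(x))
  if (use_ld && is.null(ld_cfg)) stop("use_ld = TRUE requires ld_cfg")
  fits <- lapply(as_ploidy_list(ploidies), function(pl)
    run_one_iterative(x, pl, list(c = c, d = d, s = s),
                      structure_prior = FALSE, n_axes = NULL, tol = tol,
                      max_iter = max_iter, use_ld = use_ld,
                      ld_cfg = ld_cfg, verbose = verbose))
  res <- assemble_fit(x, fits, if (use_ld) "hwe_ld" else "hwe",
                      keep_arrays, cl)
  if (!res$converged)
    warning("allele frequencies did not converge within max_iter")
  res
}

#' Iterative genotype calling with population-structure priors
#'
#' For diversity panels with population structure. The first iteration
#' uses Hardy-Weinberg priors to obtain initial posterior mean genotypes;
#' subsequent iterations derive individual-specific allele frequencies
#' from a principal components decomposition of the current genotypes
#' (see [popstruct_individual_freqs()]) and use per-individual binomial
#' priors, so that each individual's prior reflects its own ancestry.
#'
#' @inheritParams iterate_hwe
#' @param n_axes Number of principal axes for the structure model;
#'   `NULL` (default) selects axes by the broken-stick criterion.
#' @return A [rad_fit] object.
#' @export
iterate_popstruct <- function(x, ploidies = 2L, c = 0.001, d = 9, s = 0,
                              n_axes = NULL, tol = 1e-3, max_iter = 50L,
                              use_ld = FALSE, ld_cfg = NULL,
                              keep_arrays = TRUE, verbose = FALSE) {
  cl <- match.call()
  x <- subset_taxa(x, non_blank(x))
  if (use_ld && is.null(ld_cfg)) stop("use_ld = TRUE requires ld_cfg")
  fits <- lapply(as_ploidy_list(ploidies), function(pl)
    run_one_iterative(x, pl, list(c = c, d = d, s = s),
                      structure_prior = TRUE, n_axes = n_axes, tol = tol,
                      max_iter = max_iter, use_ld = use_ld,
                      ld_cfg = ld_cfg, verbose = verbose))
  res <- assemble_fit(x, fits,
                      if (use_ld) "popstruct_ld" else "popstruct",
                      keep_arrays, cl)
  if (!res$converged)
    warning("allele frequencies did not converge within max_iter")
  res
}

#' One-pass genotype calling for a biparental mapping population
#'
#' Parents are genotyped by maximum likelihood from their own depth,
#' progeny priors follow the segregation distribution of the cross (see
#' [mapping_priors()]), and posteriors are computed in a single pass:
#' allele frequencies are estimated once from progeny depth ratios and
#' not iterated.
#'
#' @inheritParams iterate_hwe
#' @param design A [cross_design] naming the parents.
#' @return A [rad_fit] object with `n_iterations = 1`.
#' @export
run_mapping <- function(x, design, ploidies = 2L, c = 0.001, d = 9,
                        keep_arrays = TRUE) {
  cl <- match.call()
  stopifnot(inherits(design, "cross_design"))
  for (par in c(design$parent1, design$parent2))
    if (!par %in% x$taxa) stop("parent not found in data set: ", par)
  x <- subset_taxa(x, non_blank(x))
  progeny <- setdiff(x$taxa, c(design$parent1, design$parent2))
  xp <- subset_taxa(x, progeny)
  fits <- lapply(as_ploidy_list(ploidies), function(pl) {
    p <- init_freqs(xp, pl$k)
    model <- pop_model(p, c = c, d = d)
    priors <- mapping_priors(x, design, pl, model)
    lik <- genotype_likelihoods(x, pl, model)
    post <- posterior(priors, lik)
    pmg <- posterior_mean(post)
    list(ploidy = pl, prior = priors, likelihood = lik, posterior = post,
         pmg = pmg, discrete = most_probable(post), freq = p,
         model = model, flagged = attr(priors, "flagged"),
         n_iterations = 1L, converged = TRUE,
         trace = data.frame(iteration = 1L, max_dp = NA_real_,
                            mean_pmg_shift = NA_real_))
  })
  assemble_fit(x, fits, "mapping", keep_arrays, cl)
}

#' @rdname pipelines
#' @param x,object A `rad_fit` object.
#' @param ... Unused.
#' @export
print.rad_fit <- function(x, ...) {
  cat(sprintf("Genotype calls (%s pipeline)\n", x$method))
  cat(sprintf("  %d taxa, %d alleles at %d loci\n", length(x$data$taxa),
              length(x$data$alleles), nrow(x$data$loci)))
  ks <- vapply(x$ploidies, `[[`, 0L, "k")
  cat(sprintf("  ploidy hypotheses: %s\n",
              paste(vapply(x$ploidies, function(p)
                paste(p$subgenomes, collapse = "+"), ""),
                collapse = ", ")))
  cat(sprintf("  %d iteration(s), converged: %s\n", x$n_iterations,
              x$converged))
  invisible(x)
}

#' @rdname pipelines
#' @export
summary.rad_fit <- function(object, ...) {
  print(object)
  cat(sprintf("  mean posterior-mean dosage: %.3f\n", mean(object$pmg)))
  het <- mean(object$discrete > 0 &
                object$discrete < vapply(object$ploidies, `[[`, 0L,
                                         "k")[1])
  cat(sprintf("  fraction of calls heterozygous: %.3f\n", het))
  if (length(object$fits) == 1L) {
    tr <- object$fits[[1L]]$trace
    if (nrow(tr) > 0)
      cat(sprintf("  final max |dp| = %.3g\n", tr$max_dp[nrow(tr)]))
  }
  invisible(object)
}

#' @rdname pipelines
#' @export
fitted.rad_fit <- function(object, ...) object$pmg

#' @rdname pipelines
#' @export
coef.rad_fit <- function(object, ...) object$freq
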