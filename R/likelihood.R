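#' Probability that a read matches a given allele
#'
#' Under the contamination model, each read at a locus is a Bernoulli
#' trial: with probability `1 - c` it comes from the individual's own
#' template, where the chance of drawing the allele is its genotype
#' fraction `i / k`, and with probability `c` it is a cross-sample
#' contaminant drawn at the population allele frequency `p`.
#'
#' @param i Allele copy number (0..k); vectorized.
#' @param k Total ploidy.
#' @param p Population allele frequency in `[0, 1]`; vectorized.
#' @param c Cross-contamination rate in `[0, 1)`.
#' @return `(1 - c) * i / k + c * p`, a probability.
#' @export
read_success_prob <- function(i, k, p, c) {
  if (any(i < 0 | i > k)) stop("copy number i must lie in 0..k")
  if (any(p < 0 | p > 1)) stop("allele frequency p must lie in [0, 1]")
  if (any(c < 0 | c >= 1)) stop("contamination rate c must lie in [0, 1)")
  (1 - c) * i / k + c * p
}

# beta-binomial pmf for a successes out of a+b trials, mean probability
# pi and overdispersion d (beta parameters d*pi, d*(1-pi)); log-space,
# fully vectorized. Degenerate pi (0 or 1) is evaluated as the point-mass
# limit of the distribution.
dbetabinom <- function(a, b, pi, d) {
  n <- length(a <- as.numeric(a))
  arg <- cbind(a, b = as.numeric(b), pi = as.numeric(pi),
               d = as.numeric(d))
  a <- arg[, "a"]; b <- arg[, "b"]; pi <- arg[, "pi"]; d <- arg[, "d"]
  out <- numeric(length(a))
  lo <- pi <= 0
  hi <- pi >= 1
  out[lo] <- as.numeric(a[lo] == 0)
  out[hi] <- as.numeric(b[hi] == 0)
  ok <- !lo & !hi
  if (any(ok)) {
    la <- lchoose(a[ok] + b[ok], a[ok]) +
      lbeta(d[ok] * pi[ok] + a[ok], d[ok] * (1 - pi[ok]) + b[ok]) -
      lbeta(d[ok] * pi[ok], d[ok] * (1 - pi[ok]))
    out[ok] <- exp(la)
  }
  out
}

#' Beta-binomial likelihood of allelic read depth
#'
#' Likelihood of observing `a` reads of an allele and `b` reads of the
#' other alleles at a locus, when the expected allelic fraction is `pi`
#' and read counts are overdispersed relative to the binomial. The count
#' of allele reads follows a beta-binomial with beta parameters
#' `d * pi` and `d * (1 - pi)`; smaller `d` means more overdispersion and
#' as `d` grows the distribution converges to the binomial.
#'
#' Degenerate allelic fractions, which arise for a zero- or full-dosage
#' genotype when the contamination rate is exactly zero, are evaluated as
#' the limiting point masses: `pi = 0` gives likelihood 1 when `a = 0`
#' and 0 otherwise, and symmetrically for `pi = 1`.
#'
#' @param a,b Non-negative integer read counts (vectorized).
#' @param pi Expected allelic fraction, see [read_success_prob()].
#' @param d Overdispersion parameter, `> 0`.
#' @return Likelihood value(s) in `[0, 1]`.
#' @examples
#' betabinom_likelihood(1, 1, 0.5, 9)   # 0.45
#' @export
betabinom_likelihood <- function(a, b, pi, d) {
  if (any(a < 0) || any(b < 0) || any(a != round(a)) || any(b != round(b)))
    stop("read counts a and b must be non-negative integers")
  if (any(pi < 0 | pi > 1)) stop("pi must lie in [0, 1]")
  if (any(d <= 0)) stop("overdispersion d must be positive")
  dbetabinom(a, b, pi, d)
}

#' Population model parameters
#'
#' Bundles the parameters of the read-depth model: per-allele frequencies,
#' the genome-wide cross-contamination rate `c`, the beta-binomial
#' overdispersion `d`, the self-fertilization rate `s`, and optionally a
#' taxa x alleles matrix of individual-specific allele frequencies (used
#' by the population-structure prior).
#'
#' @param freq Named numeric vector of allele frequencies; within each
#'   locus the frequencies must sum to 1.
#' @param c Contamination rate in `[0, 0.5)`.
#' @param d Overdispersion, `> 0`. The default of 9 reflects the level of
#'   overdispersion typical of GBS/RAD-seq libraries.
#' @param s Self-fertilization rate in `[0, 1]`.
#' @param ind_freq Optional taxa x alleles matrix of individual allele
#'   frequencies in `(0, 1)`.
#' @return Object of class `pop_model`.
#' @export
pop_model <- function(freq, c = 0.001, d = 9, s = 0, ind_freq = NULL) {
  stopifnot(is.numeric(freq), all(freq >= 0), all(freq <= 1))
  if (c < 0 || c >= 0.5) stop("contamination rate c must lie in [0, 0.5)")
  if (d <= 0) stop("overdispersion d must be positive")
  if (s < 0 || s > 1) stop("selfing rate s must lie in [0, 1]")
  structure(list(freq = freq, c = c, d = d, s = s, ind_freq = ind_freq),
            class = "pop_model")
}

# check model$freq sums to 1 per locus of the data set
check_model_freqs <- function(x, model, tol = 1e-6) {
  if (!all(x$alleles %in% names(model$freq)))
    stop("model frequencies do not cover all alleles")
  p <- model$freq[x$alleles]
  sums <- vapply(locus_alleles(x), function(j) sum(p[j]), 0)
  if (any(abs(sums - 1) > tol))
    stop("allele frequencies must sum to 1 within each locus")
  invisible(TRUE)
}

#' Genotype likelihoods for every individual, allele and copy number
#'
#' Evaluates the beta-binomial likelihood of each individual's allelic
#' read depth for every possible copy number `i = 0..k` of every allele.
#' Genotypes with zero reads at a locus receive a flat likelihood of 1
#' for every copy number, so their posteriors will equal their priors.
#'
#' @param x A [rad_data] object.
#' @param ploidy A [ploidy_hypothesis] (or integer coercible to one).
#' @param model A [pop_model]; if `ind_freq` is present those frequencies
#'   are used in place of the global ones when computing the expected
#'   allelic fraction.
#' @return A taxa x alleles x (k+1) array of likelihoods with attribute
#'   `kind = "likelihood"`.
#' @export
genotype_likelihoods <- function(x, ploidy, model) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  check_model_freqs(x, model)
  ld <- locus_depth(x)
  nt <- length(x$taxa)
  out <- array(NA_real_,
               dim = c(nt, length(x$alleles), k + 1L),
               dimnames = list(x$taxa, x$alleles, 0:k))
  use_ind <- !is.null(model$ind_freq)
  for (al in seq_along(x$alleles)) {
    a <- x$depth[, al]
    b <- ld[, x$locus[[al]]] - a
    p <- if (use_ind) model$ind_freq[, al] else
      rep(model$freq[[x$alleles[al]]], nt)
    for (i in 0:k) {
      pi <- read_success_prob(i, k, p, model$c)
      out[, al, i + 1L] <- dbetabinom(a, b, pi, model$d)
    }
  }
  attr(out, "kind") <- "likelihood"
  out
}

#' Estimate the cross-contamination rate from blank barcodes
#'
#' A no-template (blank) negative control receives reads only through
#' cross-sample contamination during library preparation, so the ratio of
#' its read depth to the mean depth of true samples estimates the
#' contamination rate `c`.
#'
#' @param x A [rad_data] object with at least one blank taxon flagged
#'   (see [set_blank_taxa()]).
#' @return Contamination rate, clamped to `[1e-6, 0.5)`.
#' @export
estimate_contamination <- function(x) {
  stopifnot(inherits(x, "rad_data"))
  if (length(x$blanks) == 0L)
    stop("no blank taxa are flagged; either call set_blank_taxa() or ",
         "supply the contamination rate c directly")
  tot <- rowSums(x$depth)
  cc <- mean(tot[x$blanks]) / mean(tot[non_blank(x)])
  min(max(cc, 1e-6), 0.5 - 1e-9)
}

# beta-binomial CDF at a (scalar), n trials
pbetabinom_scalar <- function(a, n, pi, d) {
  if (a < 0) return(0)
  sum(dbetabinom(0:min(a, n), n - 0:min(a, n), pi, d))
}

#' Choose the overdispersion parameter from the data
#'
#' For each candidate overdispersion value `d`, assigns every scored
#' genotype its most-likely copy number under that `d`, then computes a
#' randomized quantile of the observed allele count under the implied
#' beta-binomial distribution (a uniform draw within the discrete
#' probability step makes the quantiles continuous). If `d` matches the
#' overdispersion truly present in the data, these quantiles are uniform
#' on (0, 1); each candidate is therefore scored by the Kolmogorov-Smirnov
#' distance of its quantiles from the uniform distribution, and the
#' candidate with the smallest distance is selected (ties favour the
#' smaller, i.e. more conservative, `d`).
#'
#' Only genotypes with at least `min_depth` reads are scored: at low
#' depth the maximum-likelihood copy number simply tracks the observed
#' allelic ratio, absorbing the very overdispersion being measured and
#' biasing the selection toward large `d`. Ten reads is enough for the
#' assigned copy number to be driven by the genotype rather than by
#' sampling noise.
#'
#' @param x A [rad_data] object.
#' @param ploidy A [ploidy_hypothesis].
#' @param model A [pop_model] with converged allele frequencies; its `d`
#'   slot is ignored.
#' @param candidates Numeric vector of candidate `d` values, all `> 0`.
#' @param min_depth Minimum locus read depth for a genotype to be scored.
#' @param max_genotypes Maximum number of genotypes to score (sampled
#'   without replacement when more are available).
#' @return Object of class `overdispersion_report`: list with
#'   `candidates`, `scores` and `selected_d`.
#' @export
test_overdispersion <- function(x, ploidy, model, candidates,
                                min_depth = 10L,
                                max_genotypes = 10000L) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  if (length(candidates) == 0L || any(candidates <= 0))
    stop("candidates must be a non-empty vector of positive values")
  candidates <- sort(unique(as.numeric(candidates)))
  ld <- locus_depth(x)
  nb <- non_blank(x)
  # sufficiently covered (taxon, allele) pairs among non-blank taxa
  loc_of <- match(x$locus, x$loci$locus)
  nmat <- ld[nb, loc_of, drop = FALSE]
  idx <- which(nmat >= max(min_depth, 1L), arr.ind = TRUE)
  if (nrow(idx) == 0L)
    stop("no genotypes with read depth >= ", max(min_depth, 1L))
  if (nrow(idx) > max_genotypes)
    idx <- idx[sample.int(nrow(idx), max_genotypes), , drop = FALSE]
  a <- x$depth[nb, , drop = FALSE][idx]
  n <- nmat[idx]
  p <- model$freq[x$alleles][idx[, 2]]
  scores <- vapply(candidates, function(d) {
    # most-likely copy number per genotype under this d
    likmat <- vapply(0:k, function(i)
      dbetabinom(a, n - a, read_success_prob(i, k, p, model$c), d),
      numeric(length(a)))
    ihat <- max.col(likmat, ties.method = "first") - 1L
    pihat <- read_success_prob(ihat, k, p, model$c)
    u <- vapply(seq_along(a), function(g) {
      pbetabinom_scalar(a[g] - 1, n[g], pihat[g], d) +
        stats::runif(1) * dbetabinom(a[g], n[g] - a[g], pihat[g], d)
    }, 0)
    u <- pmin(pmax(u, 0), 1)
    as.numeric(suppressWarnings(
      stats::ks.test(u, "punif"))$statistic)
  }, 0)
  structure(list(candidates = candidates, scores = scores,
                 selected_d = candidates[which.min(scores)]),
            class = "overdispersion_report")
}

#' @export
print.overdispersion_report <- function(x, ...) {
  cat("Overdispersion selection\n")
  print(data.frame(d = x$candidates, ks_distance = round(x$scores, 4)))
  cat(sprintf("selected d = %g\n", x$selected_d))
  invisible(x)
}
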