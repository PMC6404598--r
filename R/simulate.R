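#' Simulation configuration
#'
#' Parameters of the read-depth simulator. The depth model mirrors the
#' behaviour of restriction-enzyme-based protocols, where depth varies
#' strongly from locus to locus: overall locus depth is Gamma(shape =
#' `locus_depth_shape`, scale = `locus_depth_scale`) (defaults 2 and 5,
#' i.e. mean 10), the total depth of one individual at one locus is a
#' rounded Gamma with shape equal to the locus depth divided by 10 and
#' scale `ind_depth_scale` (default 10), and allelic counts within that
#' total follow the same beta-binomial contamination/overdispersion model
#' used for inference.
#'
#' @param n_taxa,n_loci Numbers of individuals and loci.
#' @param ploidy A [ploidy_hypothesis] (or integer).
#' @param population One of `"hwe"`, `"structured"`, `"selfing"`, `"f1"`.
#' @param n_subpops,fst Structured population: number of subpopulations
#'   and target differentiation (Balding-Nichols Beta model).
#' @param s Selfing rate for `population = "selfing"`.
#' @param parent_dosage Optional 2 x n_loci matrix of parental dosages of
#'   the first allele for `population = "f1"`; drawn binomially from the
#'   locus frequency when `NULL`.
#' @param allele_freq_sampler Function of `n` returning ancestral allele
#'   frequencies in (0, 1); default uniform on (0.05, 0.95), a typical
#'   range after minor-allele filtering.
#' @param locus_depth_shape,locus_depth_scale,ind_depth_scale Gamma depth
#'   parameters, see above.
#' @param d,c Overdispersion and contamination used when sampling allelic
#'   counts.
#' @param seed Optional integer seed applied by [simulate_raddata()].
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_taxa, n_loci, ploidy = 2L, population = "hwe",
                       n_subpops = 2L, fst = 0.3, s = 0.5,
                       parent_dosage = NULL,
                       allele_freq_sampler = function(n)
                         stats::runif(n, 0.05, 0.95),
                       locus_depth_shape = 2, locus_depth_scale = 5,
                       ind_depth_scale = 10, d = 9, c = 0.001,
                       seed = NULL) {
  stopifnot(n_taxa >= 1, n_loci >= 1, locus_depth_shape > 0,
            locus_depth_scale > 0, ind_depth_scale > 0, d > 0,
            c >= 0, c < 0.5)
  population <- match.arg(population,
                          c("hwe", "structured", "selfing", "f1"))
  structure(list(n_taxa = as.integer(n_taxa),
                 n_loci = as.integer(n_loci),
                 ploidy = ploidy_hypothesis(ploidy),
                 population = population,
                 n_subpops = as.integer(n_subpops), fst = fst, s = s,
                 parent_dosage = parent_dosage,
                 allele_freq_sampler = allele_freq_sampler,
                 locus_depth_shape = locus_depth_shape,
                 locus_depth_scale = locus_depth_scale,
                 ind_depth_scale = ind_depth_scale,
                 d = d, c = c, seed = seed),
            class = "sim_config")
}

sim_locus_names <- function(n) sprintf("loc%d", seq_len(n))

#' Simulate true genotypes
#'
#' Draws biallelic truth dosages under the configured population model:
#' binomial sampling at the locus frequency under HWE; hierarchical
#' Balding-Nichols subpopulation frequencies followed by within-
#' subpopulation binomial sampling for structured populations; the
#' partial-selfing equilibrium distribution (see [hwe_prior()]) for
#' selfing populations; and the cross's segregation distribution for F1
#' populations (whose first two rows are the parents).
#'
#' @param cfg A [sim_config].
#' @return Integer taxa x alleles dosage matrix (two alleles per locus,
#'   rows summing to the ploidy within each locus), with attributes
#'   `locus` (allele -> locus map), `freq` (true per-allele frequencies)
#'   and, when relevant, `subpop` or `parent_dosage`.
#' @export
simulate_truth_genotypes <- function(cfg) {
  k <- cfg$ploidy$k
  nl <- cfg$n_loci
  nt <- cfg$n_taxa
  p <- cfg$allele_freq_sampler(nl)
  loci <- sim_locus_names(nl)
  alleles <- as.vector(rbind(paste0(loci, "_A"), paste0(loci, "_B")))
  locus <- rep(loci, each = 2L)
  subpop <- NULL
  pd <- NULL
  taxa <- sprintf("ind%03d", seq_len(nt))
  g1 <- switch(cfg$population,
    hwe = matrix(stats::rbinom(nt * nl, k, rep(p, each = nt)), nt, nl),
    structured = {
      subpop <- rep(seq_len(cfg$n_subpops), length.out = nt)
      shp <- (1 - cfg$fst) / cfg$fst
      psub <- matrix(stats::rbeta(cfg$n_subpops * nl,
                                  rep(p, each = cfg$n_subpops) * shp,
                                  (1 - rep(p, each = cfg$n_subpops)) * shp),
                     cfg$n_subpops, nl)
      pmat <- psub[cbind(rep(subpop, times = nl),
                         rep(seq_len(nl), each = nt))]
      matrix(stats::rbinom(nt * nl, k, pmat), nt, nl)
    },
    selfing = {
      g <- matrix(0L, nt, nl)
      for (l in seq_len(nl)) {
        pr <- hwe_prior(p[l], cfg$ploidy, cfg$s)
        g[, l] <- sample(0:k, nt, replace = TRUE, prob = pr)
      }
      g
    },
    f1 = {
      pd <- cfg$parent_dosage
      if (is.null(pd))
        pd <- matrix(stats::rbinom(2L * nl, k, rep(p, each = 2L)), 2L, nl)
      taxa <- c("parent1", "parent2",
                sprintf("prog%03d", seq_len(max(nt - 2L, 0L))))
      g <- matrix(0L, nt, nl)
      g[1L, ] <- pd[1L, ]
      g[2L, ] <- pd[2L, ]
      for (l in seq_len(nl)) {
        seg <- conv(gamete_dist(pd[1L, l], cfg$ploidy),
                    gamete_dist(pd[2L, l], cfg$ploidy))
        if (nt > 2L)
          g[3:nt, l] <- sample(0:k, nt - 2L, replace = TRUE, prob = seg)
      }
      g
    })
  geno <- matrix(0L, nt, 2L * nl, dimnames = list(taxa, alleles))
  geno[, seq(1L, 2L * nl, by = 2L)] <- g1
  geno[, seq(2L, 2L * nl, by = 2L)] <- k - g1
  freq <- numeric(2L * nl)
  freq[seq(1L, 2L * nl, by = 2L)] <- colMeans(g1) / k
  freq[seq(2L, 2L * nl, by = 2L)] <- 1 - colMeans(g1) / k
  structure(geno, locus = stats::setNames(locus, alleles),
            freq = stats::setNames(freq, alleles), subpop = subpop,
            parent_dosage = pd)
}

# beta-binomial sampler, vectorized; boundary pi gives the point mass
rbetabinom <- function(n, size, pi, d) {
  out <- integer(n)
  lo <- pi <= 0
  hi <- pi >= 1
  out[hi] <- size[hi]
  ok <- !lo & !hi & size > 0
  if (any(ok)) {
    q <- stats::rbeta(sum(ok), d * pi[ok], d * (1 - pi[ok]))
    out[ok] <- stats::rbinom(sum(ok), size[ok], q)
  }
  out
}

#' Simulate allelic read depth for given true genotypes
#'
#' Applies the depth model described in [sim_config()]: Gamma locus
#' depth, rounded Gamma individual depth, then allelic counts partitioned
#' by sequential conditional beta-binomials so that for biallelic loci
#' the count of each allele follows exactly the beta-binomial read-depth
#' model with the genotype's expected allelic fraction.
#'
#' @param genotypes Taxa x alleles integer dosage matrix (e.g. from
#'   [simulate_truth_genotypes()]); must carry a `locus` attribute or be
#'   accompanied by `locus`.
#' @param cfg A [sim_config].
#' @param locus Optional allele -> locus map overriding the attribute.
#' @param freq Optional per-allele population frequencies (used in the
#'   contamination term); defaults to the attribute or the realized
#'   frequencies.
#' @param chrom,pos Optional per-locus positions to attach.
#' @return A [rad_data] object.
#' @export
simulate_depths <- function(genotypes, cfg, locus = NULL, freq = NULL,
                            chrom = NULL, pos = NULL) {
  if (is.null(locus)) locus <- attr(genotypes, "locus")
  if (is.null(freq)) freq <- attr(genotypes, "freq")
  if (is.null(freq)) freq <- colMeans(genotypes) / cfg$ploidy$k
  k <- cfg$ploidy$k
  nt <- nrow(genotypes)
  loci <- unique(unname(locus))
  nl <- length(loci)
  if (is.null(chrom)) chrom <- rep("chr1", nl)
  if (is.null(pos)) pos <- (seq_len(nl) - 1L) * 10000L
  depth <- matrix(0L, nt, ncol(genotypes),
                  dimnames = dimnames(genotypes))
  d_locus <- stats::rgamma(nl, shape = cfg$locus_depth_shape,
                           scale = cfg$locus_depth_scale)
  for (l in seq_len(nl)) {
    j <- which(unname(locus) == loci[l])
    n_ti <- as.integer(round(stats::rgamma(
      nt, shape = max(d_locus[l] / 10, 1e-6),
      scale = cfg$ind_depth_scale)))
    remaining <- n_ti
    pis <- vapply(j, function(al)
      read_success_prob(genotypes[, al], k, freq[al], cfg$c),
      numeric(nt))
    for (jj in seq_along(j)[-length(j)]) {
      tail_sum <- rowSums(pis[, jj:length(j), drop = FALSE])
      cond <- ifelse(tail_sum > 0, pis[, jj] / tail_sum, 0)
      a <- rbetabinom(nt, remaining, cond, cfg$d)
      depth[, j[jj]] <- a
      remaining <- remaining - a
    }
    depth[, j[length(j)]] <- remaining
  }
  rad_data(depth, locus = unname(locus), chrom = chrom, pos = pos)
}

#' Simulate a complete read-depth data set with known truth
#'
#' Convenience wrapper: seeds the random number generator from the
#' configuration, draws true genotypes and read depths, and returns both
#' together.
#'
#' @param cfg A [sim_config].
#' @return Object of class `rad_sim`: list with `truth` (dosage matrix),
#'   `data` (a [rad_data]), `freq` (true allele frequencies) and
#'   `config`.
#' @export
simulate_raddata <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  truth <- simulate_truth_genotypes(cfg)
  data <- simulate_depths(truth, cfg)
  structure(list(truth = truth, data = data,
                 freq = attr(truth, "freq"), config = cfg),
            class = "rad_sim")
}

#' @export
print.rad_sim <- function(x, ...) {
  cat(sprintf("Simulated data set: %d taxa, %d loci, k = %d (%s)\n",
              x$config$n_taxa, x$config$n_loci, x$config$ploidy$k,
              x$config$population))
  print(x$data)
  invisible(x)
}

#' Naive depth-ratio genotype estimator
#'
#' The baseline estimator `k * a / (a + b)`; genotypes with zero reads
#' are set to the frequency-based expectation `k * p`.
#'
#' @param x A [rad_data] object.
#' @param ploidy A [ploidy_hypothesis].
#' @param freq Per-allele frequencies used for zero-depth genotypes.
#' @return Taxa x alleles numeric matrix.
#' @export
naive_genotypes <- function(x, ploidy, freq) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  ld <- locus_depth(x)[, match(x$locus, x$loci$locus), drop = FALSE]
  out <- ifelse(ld > 0, k * x$depth / pmax(ld, 1), NA_real_)
  fallback <- matrix(k * freq[x$alleles], nrow(out), ncol(out),
                     byrow = TRUE)
  out[is.na(out)] <- fallback[is.na(out)]
  dimnames(out) <- dimnames(x$depth)
  out
}

#' Root mean squared genotyping error
#'
#' RMSE between estimated and true numeric genotypes (both on the 0..k
#' dosage scale); lower is more accurate. Optionally computed per marker
#' (allele column) and/or separately for genotypes with zero and nonzero
#' read depth.
#'
#' @param estimates,truth Numeric matrices of identical shape.
#' @param per_marker Return one value per column instead of the overall
#'   value.
#' @param zero_read_mask Optional logical matrix (`TRUE` where the
#'   genotype had zero reads); when supplied, results are returned
#'   separately for the nonzero- and zero-read subsets.
#' @return A number, a per-marker vector, or a named list/matrix split by
#'   read-depth class.
#' @export
rmse <- function(estimates, truth, per_marker = FALSE,
                 zero_read_mask = NULL) {
  if (!identical(dim(estimates), dim(truth)))
    stop("estimates and truth must have the same shape")
  sq <- (estimates - truth)^2
  agg <- function(m) {
    if (per_marker) sqrt(colMeans(m, na.rm = TRUE))
    else sqrt(mean(m, na.rm = TRUE))
  }
  if (is.null(zero_read_mask)) return(agg(sq))
  if (!identical(dim(zero_read_mask), dim(truth)))
    stop("zero_read_mask must have the same shape as truth")
  sq_nz <- sq; sq_nz[zero_read_mask] <- NA
  sq_z <- sq; sq_z[!zero_read_mask] <- NA
  list(nonzero = agg(sq_nz), zero = agg(sq_z))
}
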