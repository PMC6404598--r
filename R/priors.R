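#' @name priors
#' @title Genotype prior probabilities
#' @description Priors over allele copy number under Hardy-Weinberg
#'   equilibrium (with optional partial selfing), population structure,
#'   linkage disequilibrium, and biparental mapping designs.
NULL

# open discrete convolution of two probability vectors
conv <- function(x, y) {
  out <- numeric(length(x) + length(y) - 1L)
  for (j in seq_along(y)) {
    out[j:(j + length(x) - 1L)] <- out[j:(j + length(x) - 1L)] + x * y[j]
  }
  out
}

# polysomic gamete distribution: k/2 chromosomes drawn without
# replacement from a genotype carrying g copies out of k (no double
# reduction)
gamete_poly <- function(g, k) {
  if (k %% 2L != 0L) stop("gametes require an even ploidy")
  stats::dhyper(0:(k / 2L), g, k - g, k / 2L)
}

# selfing transition matrix: column g holds the offspring dosage
# distribution of a selfed genotype with dosage g (two independent
# polysomic gametes from the same parent)
self_transition <- function(k) {
  vapply(0:k, function(g) {
    gam <- gamete_poly(g, k)
    conv(gam, gam)
  }, numeric(k + 1L))
}

hwe_prior_single <- function(p, k, s, tol = 1e-9, max_iter = 100L) {
  base <- stats::dbinom(0:k, k, p)
  if (s <= 0) return(base)
  if (k %% 2L != 0L)
    stop("selfing-adjusted priors require an even ploidy")
  S <- self_transition(k)
  v <- base
  for (it in seq_len(max_iter)) {
    v_new <- (1 - s) * base + s * drop(S %*% v)
    if (max(abs(v_new - v)) < tol) {
      v <- v_new
      break
    }
    v <- v_new
  }
  v / sum(v)
}

#' Hardy-Weinberg genotype prior, optionally adjusted for selfing
#'
#' With no selfing the prior over the copy number of an allele with
#' frequency `p` is Binomial(k, p); for a multi-subgenome hypothesis the
#' per-subgenome binomials are convolved, which by the Vandermonde
#' identity equals the single Binomial(k, p). With partial selfing at
#' rate `s`, the prior is the stationary genotype distribution of a
#' population in which a fraction `s` of offspring arise by
#' self-fertilization (one generation of selfing draws two independent
#' polysomic gametes from the same parent) and a fraction `1 - s` by
#' random mating; it is computed as the fixed point of
#' `v <- (1 - s) * Binomial(k, p) + s * Self(v)`. Selfing redistributes
#' probability toward homozygous dosages but never shifts the mean,
#' which stays at `k * p`.
#'
#' @param p Allele frequency in `[0, 1]`.
#' @param ploidy A [ploidy_hypothesis].
#' @param s Selfing rate in `[0, 1]`.
#' @return Numeric probability vector of length `k + 1` over copy numbers
#'   `0..k`, summing to 1.
#' @examples
#' hwe_prior(0.5, 2, 0)  # (0.25, 0.5, 0.25)
#' hwe_prior(0.5, 2, 1)  # (0.5, 0, 0.5): full selfing removes heterozygotes
#' @export
hwe_prior <- function(p, ploidy, s = 0) {
  ploidy <- ploidy_hypothesis(ploidy)
  stopifnot(p >= 0, p <= 1, s >= 0, s <= 1)
  vecs <- lapply(ploidy$subgenomes, function(ks) hwe_prior_single(p, ks, s))
  Reduce(conv, vecs)
}

# priors for a vector of frequencies: length(p) x (k+1) matrix; memoizes
# over rounded p when the selfing fixed point is needed
hwe_prior_mat <- function(p, ploidy, s = 0) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  if (s <= 0) {
    out <- vapply(0:k, function(i) stats::dbinom(i, k, p),
                  numeric(length(p)))
    if (length(p) == 1L) out <- matrix(out, nrow = 1L)
    return(out)
  }
  pr <- round(p, 5)
  uq <- unique(pr)
  tab <- vapply(uq, function(q) hwe_prior(q, ploidy, s), numeric(k + 1L))
  t(tab[, match(pr, uq), drop = FALSE])
}

#' Re-estimate allele frequencies from posterior mean genotypes
#'
#' The frequency of each allele is the mean of its posterior mean
#' genotype across individuals divided by the ploidy, renormalized within
#' each locus so that locus frequencies sum to 1.
#'
#' @param pmg Taxa x alleles matrix of posterior mean genotypes.
#' @param x A [rad_data] object (for the allele-to-locus map).
#' @param ploidy A [ploidy_hypothesis].
#' @return Named numeric vector of allele frequencies.
#' @export
update_allele_freqs <- function(pmg, x, ploidy) {
  ploidy <- ploidy_hypothesis(ploidy)
  p <- colMeans(pmg) / ploidy$k
  for (j in locus_alleles(x)) {
    tot <- sum(p[j])
    p[j] <- if (tot > 0) p[j] / tot else 1 / length(j)
  }
  stats::setNames(p, x$alleles)
}

# parallel-analysis (Horn) axis count: keep leading axes whose variance
# exceeds what column-permuted data (structure destroyed, margins kept)
# produce; robust to the non-spherical noise of estimated genotypes
choose_n_axes <- function(X, cap = 10L, n_perm = 3L) {
  ev <- stats::prcomp(X, center = TRUE)$sdev^2
  m <- min(length(ev), cap + 1L)
  perm_ev <- vapply(seq_len(n_perm), function(r) {
    Xp <- apply(X, 2L, sample)
    (stats::prcomp(Xp, center = TRUE)$sdev[seq_len(m)])^2
  }, numeric(m))
  thr <- apply(perm_ev, 1L, max)
  keep <- ev[seq_len(m)] > thr
  # leading run only: a later axis above threshold without its
  # predecessors is noise
  n <- if (all(keep)) m else which(!keep)[1L] - 1L
  min(n, cap)
}

# default axis count for a genotype matrix, dropping each locus's
# redundant first allele column
default_n_axes <- function(pmg, x, k) {
  nonred <- unlist(lapply(locus_alleles(x), function(j) j[-1L]))
  choose_n_axes(pmg[, nonred, drop = FALSE] / k)
}

#' Individual-specific allele frequencies from population structure
#'
#' Estimates, for every individual, a personal expected allele frequency
#' that reflects its position in the population's genetic structure.
#' Posterior mean genotypes scaled to `[0, 1]` are decomposed by
#' principal components analysis; each allele's scaled genotype is then
#' regressed on the leading axis scores and the fitted values, clamped
#' away from 0 and 1 and renormalized within each locus, serve as
#' individual allele frequencies for a structure-aware binomial prior.
#'
#' @param pmg Taxa x alleles matrix of posterior mean genotypes from the
#'   previous iteration.
#' @param x A [rad_data] object.
#' @param ploidy A [ploidy_hypothesis].
#' @param n_axes Number of principal axes; the default chooses the
#'   leading axes whose variance exceeds a column-permutation (parallel
#'   analysis) threshold, capped at 10, which guards against fitting the
#'   noise axes that estimated genotypes at low depth inevitably carry.
#' @param clamp_eps Lower/upper clamp for fitted frequencies; default
#'   `1 / (2 * n_taxa * k)`.
#' @return Taxa x alleles matrix of individual allele frequencies.
#' @export
popstruct_individual_freqs <- function(pmg, x, ploidy, n_axes = NULL,
                                       clamp_eps = NULL) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  nt <- nrow(pmg)
  X <- pmg / k
  # PCA on one allele per locus: a locus's alleles sum to k, so keeping
  # all of them adds perfectly anti-correlated duplicate columns that
  # distort the spectrum and the axis count
  nonred <- unlist(lapply(locus_alleles(x), function(j) j[-1L]))
  pc <- stats::prcomp(X[, nonred, drop = FALSE], center = TRUE,
                      scale. = FALSE)
  if (is.null(n_axes)) n_axes <- choose_n_axes(X[, nonred, drop = FALSE])
  if (nt < n_axes + 1L)
    stop("need at least n_axes + 1 individuals for the structure model")
  if (is.null(clamp_eps)) clamp_eps <- 1 / (2 * nt * k)
  if (n_axes >= 1L && ncol(pc$x) >= 1L) {
    scores <- pc$x[, seq_len(min(n_axes, ncol(pc$x))), drop = FALSE]
    fit <- stats::lm.fit(cbind(1, scores), X)
    fitted <- as.matrix(fit$fitted.values)
  } else {
    fitted <- matrix(colMeans(X), nt, ncol(X), byrow = TRUE)
  }
  fitted <- pmin(pmax(fitted, clamp_eps), 1 - clamp_eps)
  for (j in locus_alleles(x)) {
    rs <- rowSums(fitted[, j, drop = FALSE])
    fitted[, j] <- fitted[, j, drop = FALSE] / rs
  }
  dimnames(fitted) <- dimnames(pmg)
  fitted
}

#' Linkage configuration
#'
#' @param ld_distance Basepair window within which alleles at other loci
#'   are considered as predictors.
#' @param max_neighbors Maximum number of predictor alleles per target.
#' @param mix_weight Weight in `[0, 1]` of the linkage-informed component
#'   in the final prior mixture.
#' @return Object of class `ld_config`.
#' @export
ld_config <- function(ld_distance, max_neighbors = 10L, mix_weight = 0.5) {
  stopifnot(ld_distance > 0, max_neighbors >= 1,
            mix_weight >= 0, mix_weight <= 1)
  structure(list(ld_distance = as.numeric(ld_distance),
                 max_neighbors = as.integer(max_neighbors),
                 mix_weight = mix_weight),
            class = "ld_config")
}

#' Adjust genotype priors using linkage disequilibrium
#'
#' For each allele, finds up to `max_neighbors` alleles at *other* loci
#' within `ld_distance` basepairs whose posterior mean genotypes are most
#' strongly correlated with the target allele's, predicts the target
#' dosage by least squares from those neighbors, and mixes a binomial
#' prior centred on the predicted frequency with the base prior:
#' `(1 - w) * base + w * Binomial(k, q)`. Alleles with no eligible
#' neighbor keep their base prior unchanged. This lets high-depth linked
#' markers inform (and impute) low- or zero-depth genotypes.
#'
#' @param base_priors Taxa x alleles x (k+1) prior array.
#' @param pmg Taxa x alleles posterior mean genotypes from the previous
#'   iteration.
#' @param x A [rad_data] object with genomic positions.
#' @param cfg An [ld_config].
#' @param ploidy A [ploidy_hypothesis].
#' @return Prior array of the same shape, `kind = "prior"`.
#' @export
ld_adjusted_priors <- function(base_priors, pmg, x, cfg, ploidy) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  if (all(is.na(x$loci$chrom)))
    stop("linkage-aware priors need genomic positions; use a pipeline ",
         "without LD for position-free data")
  loc_i <- match(x$locus, x$loci$locus)
  chrom <- x$loci$chrom[loc_i]
  pos <- x$loci$pos[loc_i]
  eps <- 1 / (2 * nrow(pmg) * k)
  out <- base_priors
  cors <- suppressWarnings(stats::cor(pmg))
  ld_cov <- locus_depth(x)
  for (al in seq_along(x$alleles)) {
    cand <- which(x$locus != x$locus[al] &
                    !is.na(chrom) & chrom == chrom[al] &
                    abs(pos - pos[al]) <= cfg$ld_distance)
    if (length(cand) == 0L) next
    r <- abs(cors[al, cand])
    cand <- cand[!is.na(r)]
    r <- r[!is.na(r)]
    if (length(cand) == 0L) next
    nb <- cand[order(r, decreasing = TRUE)][seq_len(min(cfg$max_neighbors,
                                                        length(cand)))]
    # train on individuals with reads at the target locus (their pmg
    # carry data, not just the prior), then predict for everyone --
    # zero-depth genotypes included
    covered <- ld_cov[, loc_i[al]] > 0
    X <- cbind(1, pmg[, nb, drop = FALSE])
    if (sum(covered) >= ncol(X) + 2L) {
      fit <- stats::lm.fit(X[covered, , drop = FALSE], pmg[covered, al])
      beta <- ifelse(is.na(fit$coefficients), 0, fit$coefficients)
      pred <- drop(X %*% beta)
    } else {
      fit <- stats::lm.fit(X, pmg[, al])
      pred <- fit$fitted.values
    }
    q <- pmin(pmax(pred / k, eps), 1 - eps)
    ldprior <- vapply(0:k, function(i) stats::dbinom(i, k, q),
                      numeric(length(q)))
    out[, al, ] <- (1 - cfg$mix_weight) * base_priors[, al, ] +
      cfg$mix_weight * ldprior
  }
  attr(out, "kind") <- "prior"
  out
}

#' Mapping-population cross design
#'
#' Describes a biparental population: an F1 by default, with optional
#' further generations of backcrossing (to a named recurrent parent),
#' intermating among progeny, and self-fertilization, applied in that
#' order.
#'
#' @param parent1,parent2 Taxon identifiers of the two parents.
#' @param generations_selfing,generations_backcross,generations_intermating
#'   Non-negative generation counts; all zero gives an F1.
#' @param recurrent Taxon id of the recurrent parent (required when
#'   `generations_backcross > 0`; must be one of the two parents).
#' @return Object of class `cross_design`.
#' @export
cross_design <- function(parent1, parent2, generations_selfing = 0L,
                         generations_backcross = 0L, recurrent = NULL,
                         generations_intermating = 0L) {
  stopifnot(generations_selfing >= 0, generations_backcross >= 0,
            generations_intermating >= 0)
  if (generations_backcross > 0) {
    if (is.null(recurrent) || !recurrent %in% c(parent1, parent2))
      stop("backcrossing requires 'recurrent' to be one of the parents")
  }
  structure(list(parent1 = parent1, parent2 = parent2,
                 generations_selfing = as.integer(generations_selfing),
                 generations_backcross = as.integer(generations_backcross),
                 recurrent = recurrent,
                 generations_intermating =
                   as.integer(generations_intermating)),
            class = "cross_design")
}

# gamete dosage distribution of a parent carrying g copies of an allele,
# under the given inheritance hypothesis; for allopolyploids the g copies
# are assigned to subgenomes in every consistent way (no phasing
# information), each assignment contributing its convolved per-subgenome
# disomic gametes with equal weight
gamete_dist <- function(g, ploidy) {
  sub <- ploidy$subgenomes
  if (length(sub) == 1L) return(gamete_poly(g, sub))
  ks <- sub[1L]
  grid <- expand.grid(rep(list(0:ks), length(sub)))
  grid <- grid[rowSums(grid) == g, , drop = FALSE]
  gams <- apply(grid, 1, function(gs)
    Reduce(conv, lapply(gs, function(gg) gamete_poly(gg, ks))))
  rowMeans(matrix(gams, ncol = nrow(grid)))
}

# gamete distribution of a population with genotype distribution v
gamete_from_dist <- function(v, k) {
  gams <- vapply(0:k, function(g) gamete_poly(g, k), numeric(k / 2L + 1L))
  drop(gams %*% v)
}

# advance an F1 genotype distribution through later generations
apply_generations <- function(v, design, ploidy, g_recurrent) {
  if (design$generations_backcross + design$generations_selfing +
      design$generations_intermating == 0L) return(v)
  if (length(ploidy$subgenomes) > 1L)
    stop("generations beyond the F1 are supported for single-subgenome ",
         "(polysomic) hypotheses only")
  k <- ploidy$k
  for (i in seq_len(design$generations_backcross))
    v <- conv(gamete_from_dist(v, k), gamete_poly(g_recurrent, k))
  for (i in seq_len(design$generations_intermating)) {
    gd <- gamete_from_dist(v, k)
    v <- conv(gd, gd)
  }
  if (design$generations_selfing > 0L) {
    S <- self_transition(k)
    for (i in seq_len(design$generations_selfing)) v <- drop(S %*% v)
  }
  v / sum(v)
}

#' Genotype priors for a biparental mapping population
#'
#' Calls each parent's allele dosage by maximum likelihood from its own
#' read depth (uniform prior, so no population information leaks into the
#' parental calls), then derives the progeny genotype distribution of the
#' cross: for an F1 the convolution of the two parents' gamete
#' distributions (polysomic gametes without double reduction, or
#' per-subgenome disomic gametes averaged over consistent assignments of
#' parental copies to subgenomes), with any further backcross,
#' intermating and selfing generations applied as transitions on the
#' genotype distribution. The same prior applies to every progeny
#' individual; parents receive flat priors.
#'
#' Loci where a parent has zero depth, and loci whose called parental
#' genotypes are inconsistent with the progeny allele frequencies (both
#' parents homozygous for the same allele yet the progeny minor-allele
#' frequency exceeds `3 * c`, i.e. more minor reads than contamination
#' can explain), are flagged and fall back to Hardy-Weinberg priors from
#' the progeny frequencies.
#'
#' @param x A [rad_data] object containing parents and progeny.
#' @param design A [cross_design].
#' @param ploidy A [ploidy_hypothesis].
#' @param model A [pop_model] whose `freq` are progeny allele frequencies.
#' @return Taxa x alleles x (k+1) prior array (`kind = "prior"`) with
#'   attribute `flagged`, the identifiers of fallback loci.
#' @export
mapping_priors <- function(x, design, ploidy, model) {
  ploidy <- ploidy_hypothesis(ploidy)
  k <- ploidy$k
  for (par in c(design$parent1, design$parent2))
    if (!par %in% x$taxa) stop("parent not found in data set: ", par)
  check_model_freqs(x, model)
  ld <- locus_depth(x)
  nt <- length(x$taxa)
  out <- array(NA_real_, dim = c(nt, length(x$alleles), k + 1L),
               dimnames = list(x$taxa, x$alleles, 0:k))
  parents <- c(design$parent1, design$parent2)
  progeny <- setdiff(non_blank(x), parents)
  flagged <- character()
  # ML parental dosage per allele
  call_parent <- function(par, al) {
    a <- x$depth[par, al]
    b <- ld[par, x$locus[[al]]] - a
    p <- model$freq[[x$alleles[al]]]
    lik <- vapply(0:k, function(i)
      dbetabinom(a, b, read_success_prob(i, k, p, model$c), model$d), 0)
    which.max(lik) - 1L
  }
  for (li in seq_len(nrow(x$loci))) {
    loc <- x$loci$locus[li]
    als <- which(x$locus == loc)
    zero_parent <- any(ld[parents, loc] == 0)
    for (al in als) {
      p_prog <- model$freq[[x$alleles[al]]]
      fallback <- FALSE
      if (zero_parent) {
        fallback <- TRUE
      } else {
        g1 <- call_parent(design$parent1, al)
        g2 <- call_parent(design$parent2, al)
        minor <- min(p_prog, 1 - p_prog)
        if (((g1 == 0L && g2 == 0L) || (g1 == k && g2 == k)) &&
            minor > 3 * model$c)
          fallback <- TRUE
      }
      if (fallback) {
        prior <- hwe_prior(p_prog, ploidy, 0)
        if (!loc %in% flagged) flagged <- c(flagged, loc)
      } else {
        v <- conv(gamete_dist(g1, ploidy), gamete_dist(g2, ploidy))
        g_rec <- if (!is.null(design$recurrent)) {
          if (design$recurrent == design$parent1) g1 else g2
        } else 0L
        prior <- apply_generations(v, design, ploidy, g_rec)
      }
      out[progeny, al, ] <- matrix(prior, length(progeny), k + 1L,
                                   byrow = TRUE)
      out[parents, al, ] <- 1 / (k + 1L)
      blanks <- x$blanks
      if (length(blanks)) out[blanks, al, ] <- 1 / (k + 1L)
    }
  }
  attr(out, "kind") <- "prior"
  attr(out, "flagged") <- flagged
  out
}
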