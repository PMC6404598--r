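#' Posterior genotype probabilities by Bayes' theorem
#'
#' Combines genotype priors with read-depth likelihoods: for each
#' individual and allele the posterior probability of copy number `i` is
#' the normalized product of prior and likelihood. Genotypes whose prior
#' mass lies entirely on likelihood-zero copy numbers (an inconsistency,
#' e.g. a contaminated outlier in a mapping population with a degenerate
#' prior) keep their prior, with a warning.
#'
#' @param priors,likelihoods Taxa x alleles x (k+1) arrays of the same
#'   shape; priors normalized per genotype.
#' @return Posterior array of the same shape (`kind = "posterior"`), each
#'   genotype's vector summing to 1.
#' @export
posterior <- function(priors, likelihoods) {
  stopifnot(identical(dim(priors), dim(likelihoods)))
  prod <- priors * likelihoods
  den <- rowSums(prod, dims = 2L)
  bad <- den <= 0
  if (any(bad)) {
    warning(sum(bad), " genotype(s) inconsistent with their prior; ",
            "posterior set to the prior")
    den[bad] <- 1
  }
  out <- prod / as.vector(den)
  if (any(bad)) {
    idx <- which(bad, arr.ind = TRUE)
    for (r in seq_len(nrow(idx)))
      out[idx[r, 1], idx[r, 2], ] <- priors[idx[r, 1], idx[r, 2], ]
  }
  dimnames(out) <- dimnames(priors)
  attr(out, "kind") <- "posterior"
  out
}

#' Posterior mean genotypes
#'
#' The expected allele copy number under the posterior: each copy number
#' `i = 0..k` is weighted by its posterior probability. This continuous
#' value in `[0, k]` carries genotype uncertainty into downstream
#' analyses instead of forcing a hard call.
#'
#' @param post Taxa x alleles x (k+1) posterior array.
#' @return Taxa x alleles numeric matrix with attribute
#'   `discrete = FALSE`.
#' @examples
#' p <- array(c(0.6, 0.4, 0), dim = c(1, 1, 3))
#' posterior_mean(p)  # 0.4
#' @export
posterior_mean <- function(post) {
  k <- dim(post)[3] - 1L
  w <- array(rep(0:k, each = prod(dim(post)[1:2])), dim = dim(post))
  out <- rowSums(post * w, dims = 2L)
  dimnames(out) <- dimnames(post)[1:2]
  attr(out, "discrete") <- FALSE
  out
}

#' Most probable genotypes
#'
#' The posterior mode of the allele copy number; ties are broken toward
#' the smaller copy number.
#'
#' @param post Taxa x alleles x (k+1) posterior array.
#' @return Taxa x alleles integer matrix with attribute `discrete = TRUE`.
#' @export
most_probable <- function(post) {
  k <- dim(post)[3] - 1L
  flat <- matrix(post, nrow = prod(dim(post)[1:2]), ncol = k + 1L)
  # which.max-style first maximum = smaller copy number on ties
  best <- apply(flat, 1L, which.max) - 1L
  out <- matrix(as.integer(best), dim(post)[1], dim(post)[2])
  dimnames(out) <- dimnames(post)[1:2]
  attr(out, "discrete") <- TRUE
  out
}
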