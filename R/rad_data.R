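#' Allelic read-depth data set
#'
#' Container for the individuals x alleles read-count matrix produced by
#' reduced-representation sequencing (GBS / RAD-seq) pipelines, together
#' with the allele-to-locus mapping, optional genomic positions, and the
#' names of any no-template (blank barcode) control samples.
#'
#' Alleles belonging to the same locus are mutually exclusive sequence
#' variants (SNP alleles or tag haplotypes); for any individual the reads
#' at a locus are partitioned among its alleles. Every locus must carry at
#' least two alleles, so that the "reads of other alleles" count used by
#' the likelihood model is well defined.
#'
#' @param depth Integer matrix of read counts, individuals in rows and
#'   alleles in columns. Row and column names are used as taxon and allele
#'   identifiers; unnamed dimensions get default identifiers.
#' @param locus Character vector, one entry per allele (column of `depth`),
#'   giving the locus each allele belongs to.
#' @param chrom Optional character vector of chromosome names, one per
#'   locus (in the order loci first appear in `locus`).
#' @param pos Optional integer vector of 0-based basepair positions, one
#'   per locus.
#' @param blanks Character vector of taxa that are no-template controls.
#'
#' @return An object of class `rad_data`: a list with elements `depth`
#'   (integer matrix), `taxa`, `alleles`, `locus` (allele -> locus map),
#'   `loci` (data frame with `locus`, `chrom`, `pos`), and `blanks`.
#' @examples
#' dep <- matrix(c(5L, 2L, 0L, 7L), nrow = 2, byrow = TRUE,
#'               dimnames = list(c("ind1", "ind2"), c("L1_A", "L1_B")))
#' rd <- rad_data(dep, locus = c("L1", "L1"))
#' counts_for_allele(rd, "ind1", "L1_A")
#' @export
rad_data <- function(depth, locus, chrom = NULL, pos = NULL,
                     blanks = character()) {
  if (!is.matrix(depth)) depth <- as.matrix(depth)
  if (is.null(rownames(depth)))
    rownames(depth) <- paste0("taxon", seq_len(nrow(depth)))
  if (is.null(colnames(depth)))
    colnames(depth) <- paste0("allele", seq_len(ncol(depth)))
  if (length(locus) != ncol(depth))
    stop("'locus' must have one entry per allele (column of 'depth')")
  storage.mode(depth) <- "integer"
  locus <- as.character(locus)
  loci <- unique(locus)
  loci_df <- data.frame(locus = loci,
                        chrom = if (is.null(chrom)) NA_character_ else
                          as.character(chrom),
                        pos = if (is.null(pos)) NA_integer_ else
                          as.integer(pos),
                        stringsAsFactors = FALSE)
  x <- structure(list(depth = depth,
                      taxa = rownames(depth),
                      alleles = colnames(depth),
                      locus = stats::setNames(locus, colnames(depth)),
                      loci = loci_df,
                      blanks = as.character(blanks)),
                 class = "rad_data")
  validate_rad_data(x)
  x
}

validate_rad_data <- function(x) {
  d <- x$depth
  if (anyNA(d) || any(d < 0L))
    stop("read depths must be non-negative integers with no missing values")
  if (anyDuplicated(x$taxa)) stop("duplicated taxon identifiers")
  if (anyDuplicated(x$alleles)) stop("duplicated allele identifiers")
  n_per_locus <- table(x$locus)
  if (any(n_per_locus < 2L))
    stop("every locus needs at least two alleles; offending loci: ",
         paste(names(n_per_locus)[n_per_locus < 2L], collapse = ", "))
  if (!all(x$blanks %in% x$taxa))
    stop("blank taxa not present in the data set: ",
         paste(setdiff(x$blanks, x$taxa), collapse = ", "))
  has_chrom <- !is.na(x$loci$chrom)
  if (any(has_chrom & (is.na(x$loci$pos) | x$loci$pos < 0L)))
    stop("loci with a chromosome need a non-negative basepair position")
  invisible(x)
}

#' @export
print.rad_data <- function(x, ...) {
  cat("Allelic read-depth data set\n")
  cat(sprintf("  %d taxa (%d blanks), %d alleles at %d loci\n",
              length(x$taxa), length(x$blanks), length(x$alleles),
              nrow(x$loci)))
  if (any(!is.na(x$loci$chrom))) cat("  genomic positions present\n")
  nz <- mean(x$depth > 0)
  cat(sprintf("  mean depth %.1f, %.0f%% of entries non-zero\n",
              mean(x$depth), 100 * nz))
  invisible(x)
}

# indices of alleles per locus, in locus order
locus_alleles <- function(x) {
  split(seq_along(x$alleles), factor(x$locus, levels = x$loci$locus))
}

# taxa x loci matrix of total read depth per locus
locus_depth <- function(x) {
  idx <- locus_alleles(x)
  out <- vapply(idx, function(j) rowSums(x$depth[, j, drop = FALSE]),
                numeric(length(x$taxa)))
  if (length(x$taxa) == 1L) out <- matrix(out, nrow = 1L)
  dimnames(out) <- list(x$taxa, x$loci$locus)
  out
}

non_blank <- function(x) setdiff(x$taxa, x$blanks)

#' Reads supporting an allele versus other alleles of its locus
#'
#' Returns the pair (a, b) used by the beta-binomial read-depth model:
#' `a` is the read count of the given allele in the given individual and
#' `b` is the summed count of all other alleles at the same locus.
#'
#' @param x A [rad_data] object.
#' @param taxon,allele Single taxon and allele identifiers.
#' @return Named numeric vector `c(a = , b = )`.
#' @export
counts_for_allele <- function(x, taxon, allele) {
  if (!taxon %in% x$taxa) stop("unknown taxon: ", taxon)
  if (!allele %in% x$alleles) stop("unknown allele: ", allele)
  sib <- names(x$locus)[x$locus == x$locus[[allele]]]
  a <- x$depth[taxon, allele]
  b <- sum(x$depth[taxon, setdiff(sib, allele)])
  c(a = as.numeric(a), b = as.numeric(b))
}

#' Flag no-template control samples
#'
#' Marks taxa as blank-barcode negative controls. Blanks are excluded from
#' marker filtering counts and from all model estimation except the
#' contamination-rate estimate of [estimate_contamination()].
#'
#' @param x A [rad_data] object.
#' @param taxa Character vector of taxon identifiers.
#' @return The modified `rad_data` object.
#' @export
set_blank_taxa <- function(x, taxa) {
  stopifnot(inherits(x, "rad_data"))
  if (!all(taxa %in% x$taxa))
    stop("blank taxa not present in the data set: ",
         paste(setdiff(taxa, x$taxa), collapse = ", "))
  x$blanks <- as.character(taxa)
  x
}

#' Filter markers on call rate and minor-allele support
#'
#' Retains a locus if at least `min_ind_with_reads` non-blank individuals
#' have more than zero reads of it; within retained loci, drops any allele
#' seen in fewer than `min_ind_with_minor_allele` non-blank individuals.
#' Loci left with fewer than two alleles are removed. The filter is applied
#' to a fixed point, so that applying it twice with the same thresholds
#' changes nothing.
#'
#' @param x A [rad_data] object.
#' @param min_ind_with_reads Minimum number of non-blank individuals with
#'   nonzero depth at the locus.
#' @param min_ind_with_minor_allele Minimum number of non-blank individuals
#'   with nonzero reads of each allele.
#' @return A filtered [rad_data] object; may contain zero loci (with a
#'   warning) when the thresholds cannot be met.
#' @export
filter_markers <- function(x, min_ind_with_reads = 0,
                           min_ind_with_minor_allele = 0) {
  stopifnot(inherits(x, "rad_data"),
            min_ind_with_reads >= 0, min_ind_with_minor_allele >= 0)
  nb <- non_blank(x)
  repeat {
    if (length(x$alleles) == 0L) break
    ld <- locus_depth(x)[nb, , drop = FALSE]
    keep_loci <- x$loci$locus[colSums(ld > 0) >= min_ind_with_reads]
    keep_al <- x$alleles[x$locus %in% keep_loci]
    nz <- colSums(x$depth[nb, keep_al, drop = FALSE] > 0)
    keep_al <- keep_al[nz >= min_ind_with_minor_allele]
    tab <- table(x$locus[keep_al])
    keep_al <- keep_al[x$locus[keep_al] %in% names(tab)[tab >= 2L]]
    if (identical(keep_al, x$alleles)) break
    x <- subset_alleles(x, keep_al)
  }
  if (length(x$alleles) == 0L)
    warning("no loci passed the filtering thresholds")
  x
}

# keep the given alleles (and their loci), preserving order
subset_alleles <- function(x, alleles) {
  j <- match(alleles, x$alleles)
  loci <- unique(unname(x$locus[j]))
  li <- match(loci, x$loci$locus)
  out <- x
  out$depth <- x$depth[, j, drop = FALSE]
  out$alleles <- alleles
  out$locus <- x$locus[j]
  out$loci <- x$loci[li, , drop = FALSE]
  rownames(out$loci) <- NULL
  out
}

# drop taxa (used by pipelines to exclude blanks)
subset_taxa <- function(x, taxa) {
  i <- match(taxa, x$taxa)
  out <- x
  out$depth <- x$depth[i, , drop = FALSE]
  out$taxa <- taxa
  out$blanks <- intersect(x$blanks, taxa)
  out
}
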