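#' Import allelic read depth from a VCF file
#'
#' Reads any VCF (plain or bgzipped) carrying a per-sample allelic depth
#' (`AD`) FORMAT field, such as output by common GBS/RAD-seq callers.
#' Each VCF record becomes one locus whose REF and ALT alleles become the
#' locus's alleles; missing `AD` entries become zero depth. Records with
#' a malformed `AD` arity are skipped with a warning. Positions are
#' stored 0-based internally (VCF is 1-based).
#'
#' @param path Path to the VCF file.
#' @param min_ind_with_reads,min_ind_with_minor_allele Filtering
#'   thresholds passed to [filter_markers()].
#' @return A [rad_data] object.
#' @export
read_vcf_ad <- function(path, min_ind_with_reads = 0,
                        min_ind_with_minor_allele = 0) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fmt <- vcf@gt[, 1L]
  if (!any(grepl("(^|:)AD(:|$)", fmt)))
    stop("VCF has no AD (allelic depth) FORMAT field")
  ad <- vcfR::extract.gt(vcf, element = "AD")
  taxa <- colnames(ad)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L,
                                       dimnames = list(NULL, names(fix)))
  depth_cols <- list()
  locus <- character()
  loci <- character(); chrom <- character(); pos <- integer()
  for (r in seq_len(nrow(fix))) {
    alts <- strsplit(fix[r, "ALT"], ",", fixed = TRUE)[[1L]]
    alts <- alts[alts != "."]
    als <- c(fix[r, "REF"], alts)
    n_al <- length(als)
    if (n_al < 2L) next
    counts <- matrix(0L, length(taxa), n_al)
    vals <- ad[r, ]
    has <- !is.na(vals) & vals != "."
    if (any(has)) {
      parts <- strsplit(vals[has], ",", fixed = TRUE)
      arity_ok <- lengths(parts) == n_al
      if (!all(arity_ok)) {
        warning("record ", r, ": AD arity mismatch; record skipped")
        next
      }
      num <- suppressWarnings(
        matrix(as.integer(unlist(parts)), ncol = n_al, byrow = TRUE))
      num[is.na(num)] <- 0L
      counts[has, ] <- num
    }
    loc <- fix[r, "ID"]
    if (is.na(loc) || loc == ".")
      loc <- paste0(fix[r, "CHROM"], "_", fix[r, "POS"])
    if (loc %in% loci) loc <- paste0(loc, "_", r)
    depth_cols[[length(depth_cols) + 1L]] <- counts
    locus <- c(locus, rep(loc, n_al))
    loci <- c(loci, loc)
    chrom <- c(chrom, fix[r, "CHROM"])
    pos <- c(pos, as.integer(fix[r, "POS"]) - 1L)
    names(depth_cols)[length(depth_cols)] <-
      paste(paste0(loc, "_", als), collapse = ";")
  }
  if (length(depth_cols) == 0L) stop("no usable records in VCF")
  depth <- do.call(cbind, depth_cols)
  colnames(depth) <- unlist(strsplit(names(depth_cols), ";", fixed = TRUE))
  rownames(depth) <- taxa
  x <- rad_data(depth, locus = locus, chrom = chrom, pos = pos)
  filter_markers(x, min_ind_with_reads, min_ind_with_minor_allele)
}

#' Import allelic read depth from CSV
#'
#' Reads a read-count matrix (taxa in rows, first column taxon
#' identifiers, remaining columns alleles) and a two-column allele-to-
#' locus map (`allele,locus`). No genomic positions are attached.
#'
#' @param path Path to the depth CSV.
#' @param locus_map_path Path to the allele-to-locus CSV map.
#' @return A [rad_data] object.
#' @export
read_depth_csv <- function(path, locus_map_path) {
  tab <- utils::read.csv(path, check.names = FALSE,
                         stringsAsFactors = FALSE)
  if (nrow(tab) == 0L || ncol(tab) < 2L)
    stop("depth CSV is empty or has no allele columns")
  taxa <- as.character(tab[[1L]])
  if (anyDuplicated(taxa))
    stop("duplicated taxon rows in depth CSV: ",
         paste(unique(taxa[duplicated(taxa)]), collapse = ", "))
  depth <- as.matrix(tab[, -1L, drop = FALSE])
  rownames(depth) <- taxa
  map <- utils::read.csv(locus_map_path, stringsAsFactors = FALSE)
  missing <- setdiff(colnames(depth), map[[1L]])
  if (length(missing))
    stop("alleles absent from the locus map: ",
         paste(missing, collapse = ", "))
  locus <- map[[2L]][match(colnames(depth), map[[1L]])]
  rad_data(depth, locus = locus)
}

#' Write a read-depth data set
#'
#' `write_depth_csv()` writes the depth matrix plus the allele-to-locus
#' map as CSV; `write_vcf_ad()` writes a VCF 4.2 file with per-sample
#' `AD` (one record per locus, the first allele as REF), usable as input
#' to [read_vcf_ad()]. Loci without positions get synthetic coordinates.
#'
#' @param x A [rad_data] object.
#' @param path Output file path (for CSV, the locus map is written next
#'   to it with suffix `_loci.csv`).
#' @return The path, invisibly.
#' @export
write_depth_csv <- function(x, path) {
  df <- data.frame(taxon = x$taxa, x$depth, check.names = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  map <- data.frame(allele = x$alleles, locus = unname(x$locus))
  utils::write.csv(map, sub("\\.csv$", "_loci.csv", path),
                   row.names = FALSE)
  invisible(path)
}

vcf_header <- function(taxa, extra_format) {
  c("##fileformat=VCFv4.2",
    "##source=dosecall",
    extra_format,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
            "INFO", "FORMAT", taxa), collapse = "\t"))
}

# synthetic alphabet alleles A, B, C... for loci without sequence alleles
vcf_allele_codes <- function(n) LETTERS[seq_len(n)]

#' @rdname write_depth_csv
#' @export
write_vcf_ad <- function(x, path) {
  idx <- locus_alleles(x)
  chrom <- ifelse(is.na(x$loci$chrom), "chrUn", x$loci$chrom)
  pos <- ifelse(is.na(x$loci$pos), seq_len(nrow(x$loci)) * 1000L,
                x$loci$pos) + 1L
  lines <- vcf_header(
    x$taxa,
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">")
  for (l in seq_along(idx)) {
    j <- idx[[l]]
    codes <- vcf_allele_codes(length(j))
    samples <- apply(x$depth[, j, drop = FALSE], 1L, paste,
                     collapse = ",")
    lines <- c(lines, paste(c(chrom[l], pos[l], x$loci$locus[l],
                              codes[1L],
                              paste(codes[-1L], collapse = ","),
                              ".", ".", ".", "AD", samples),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}

# dosage -> VCF GT string, e.g. dosage 3 of the alt allele at k = 4 gives
# "0/1/1/1"; for multiallelic loci dosages per alt allele are laid out in
# allele order
gt_string <- function(dosages, k) {
  alleles <- integer(0)
  for (j in seq_along(dosages))
    alleles <- c(alleles, rep(j, dosages[j]))
  alleles <- c(rep(0L, k - length(alleles)), alleles)
  paste(sort(alleles), collapse = "/")
}

#' Export called genotypes
#'
#' Writes genotypes from a fitted pipeline. Modes `"continuous"` and
#' `"discrete"` write a taxa x alleles CSV of posterior-mean or
#' most-probable dosages; within each locus the first (reference) allele
#' column is dropped, since locus dosages sum to the ploidy and the
#' column would be redundant (and make downstream design matrices rank
#' deficient). Mode `"vcf"` writes one record per locus with `GT` (the
#' most probable genotype, ploidy-many alleles) and `DS` (posterior mean
#' dosage of each alternate allele).
#'
#' @param fit A [rad_fit] object.
#' @param path Output path.
#' @param mode `"continuous"`, `"discrete"` or `"vcf"`.
#' @return The path, invisibly.
#' @export
write_genotypes <- function(fit, path,
                            mode = c("continuous", "discrete", "vcf")) {
  mode <- match.arg(mode)
  stopifnot(inherits(fit, "rad_fit"))
  x <- fit$data
  if (mode %in% c("continuous", "discrete")) {
    keep <- unlist(lapply(locus_alleles(x), function(j) j[-1L]))
    mat <- if (mode == "continuous") fit$pmg else fit$discrete
    message("dropping the first allele of each locus from the export (",
            length(x$alleles) - length(keep), " columns)")
    df <- data.frame(taxon = x$taxa,
                     round(mat[, keep, drop = FALSE], 4),
                     check.names = FALSE)
    utils::write.csv(df, path, row.names = FALSE)
    return(invisible(path))
  }
  idx <- locus_alleles(x)
  chrom <- ifelse(is.na(x$loci$chrom), "chrUn", x$loci$chrom)
  pos <- ifelse(is.na(x$loci$pos), seq_len(nrow(x$loci)) * 1000L,
                x$loci$pos) + 1L
  lines <- vcf_header(x$taxa, c(
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste0("##FORMAT=<ID=DS,Number=A,Type=Float,Description=",
           "\"Posterior mean dosage of each ALT allele\">")))
  for (l in seq_along(idx)) {
    j <- idx[[l]]
    k <- fit$ploidies[[fit$ploidy_choice[l]]]$k
    codes <- vcf_allele_codes(length(j))
    samples <- vapply(seq_along(x$taxa), function(t) {
      gt <- gt_string(fit$discrete[t, j[-1L]], k)
      ds <- paste(sprintf("%.4f", fit$pmg[t, j[-1L]]), collapse = ",")
      paste0(gt, ":", ds)
    }, "")
    lines <- c(lines, paste(c(chrom[l], pos[l], x$loci$locus[l],
                              codes[1L],
                              paste(codes[-1L], collapse = ","),
                              ".", ".", ".", "GT:DS", samples),
                            collapse = "\t"))
  }
  writeLines(lines, path)
  invisible(path)
}
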