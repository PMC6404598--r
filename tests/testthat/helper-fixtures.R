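# fixtures and independent oracles shared across test files

# small data set: 4 individuals, 2 biallelic loci
toy_rad <- function() {
  dep <- matrix(c(5L, 2L, 7L, 0L,
                  0L, 0L, 3L, 3L,
                  4L, 4L, 0L, 0L,
                  1L, 0L, 2L, 8L),
                nrow = 4, byrow = TRUE,
                dimnames = list(paste0("t", 1:4),
                                c("L1_A", "L1_B", "L2_A", "L2_B")))
  rad_data(dep, locus = c("L1", "L1", "L2", "L2"))
}

# beta-binomial pmf by explicit rising products -- independent of the
# log-gamma implementation: B(x+a, y+b)/B(x, y) =
#   prod_{j<a}(x+j) * prod_{j<b}(y+j) / prod_{j<a+b}(x+y+j)
bb_oracle <- function(a, b, pi, d) {
  x <- d * pi
  y <- d * (1 - pi)
  num <- prod(x + seq_len(a) - 1) * prod(y + seq_len(b) - 1)
  den <- prod(x + y + seq_len(a + b) - 1)
  choose(a + b, a) * num / den
}

# exhaustive F1 segregation oracle: enumerate all C(k, k/2) chromosome
# subsets of each parent's genotype, pair every gamete of parent 1 with
# every gamete of parent 2, tally offspring dosage
f1_oracle <- function(g1, g2, k) {
  gametes <- function(g) {
    chroms <- c(rep(1L, g), rep(0L, k - g))
    subs <- utils::combn(k, k / 2)
    apply(subs, 2, function(j) sum(chroms[j]))
  }
  gam1 <- gametes(g1)
  gam2 <- gametes(g2)
  off <- outer(gam1, gam2, "+")
  tabulate(as.vector(off) + 1L, nbins = k + 1L) / length(off)
}

# perfect-LD panel: loci come in adjacent pairs sharing the same true
# genotypes; the first locus of each pair is zeroed out for the first
# half of the individuals
make_ld_panel <- function(nt, n_pairs, k = 2, depth_shape = 2,
                          depth_scale = 5) {
  cfg <- sim_config(nt, 2 * n_pairs, ploidy = k,
                    locus_depth_shape = depth_shape,
                    locus_depth_scale = depth_scale)
  p <- stats::runif(n_pairs, 0.2, 0.8)
  g <- matrix(stats::rbinom(nt * n_pairs, k, rep(p, each = nt)), nt,
              n_pairs)
  g2 <- matrix(0L, nt, 2 * n_pairs)
  g2[, seq(1, 2 * n_pairs, 2)] <- g
  g2[, seq(2, 2 * n_pairs, 2)] <- g
  loci <- sprintf("loc%d", seq_len(2 * n_pairs))
  alleles <- as.vector(rbind(paste0(loci, "_A"), paste0(loci, "_B")))
  geno <- matrix(0L, nt, 4 * n_pairs,
                 dimnames = list(sprintf("ind%03d", seq_len(nt)),
                                 alleles))
  geno[, seq(1, 4 * n_pairs, 2)] <- g2
  geno[, seq(2, 4 * n_pairs, 2)] <- k - g2
  locmap <- stats::setNames(rep(loci, each = 2), alleles)
  freq <- stats::setNames(
    as.vector(rbind(colMeans(g2) / k, 1 - colMeans(g2) / k)), alleles)
  pos <- as.integer(rep((seq_len(n_pairs) - 1) * 1e6, each = 2) +
                      rep(c(0L, 500L), n_pairs))
  x <- simulate_depths(geno, cfg, locus = locmap, freq = freq,
                       chrom = rep("chr1", 2 * n_pairs), pos = pos)
  dep <- x$depth
  mask_ind <- seq_len(nt %/% 2)
  odd_loci <- seq(1, 2 * n_pairs, by = 2)
  zero_cols <- sort(c(2 * odd_loci - 1, 2 * odd_loci))
  dep[mask_ind, zero_cols] <- 0L
  zm <- matrix(FALSE, nt, 4 * n_pairs)
  zm[mask_ind, zero_cols] <- TRUE
  list(data = rad_data(dep, locus = unname(locmap),
                       chrom = rep("chr1", 2 * n_pairs), pos = pos),
       truth = geno, freq = freq, zero_mask = zm)
}

# plain-text VCF fixture with AD depths; `records` is a list of lists
# with chrom, pos, ref, alt (comma string), ad (character per sample)
write_vcf_fixture <- function(path, samples, records) {
  lines <- c("##fileformat=VCFv4.2",
             paste0("##FORMAT=<ID=AD,Number=R,Type=Integer,",
                    "Description=\"Allelic depths\">"),
             paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL",
                     "FILTER", "INFO", "FORMAT", samples),
                   collapse = "\t"))
  for (r in records) {
    lines <- c(lines, paste(c(r$chrom, r$pos, ".", r$ref, r$alt, ".",
                              ".", ".", "AD", r$ad), collapse = "\t"))
  }
  writeLines(lines, path)
  path
}
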