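#' Linkage-disequilibrium filter against the anchor map
#'
#' Every true variant should be in strong local LD with nearby trusted
#' markers. For each candidate site the LD with every anchor site is
#' measured as the two-sided Fisher exact P-value of the 2 x 2 table of
#' haplotype counts (AB, Ab, aB, ab); heterozygous genotypes are counted as
#' minor-allele homozygotes so each taxon contributes at most one haplotype,
#' and at multiallelic sites all non-major alleles are collapsed into the
#' minor class. A pair of sites is testable only when (i) they are at least
#' \code{min_bp} apart (2500 bp; different chromosomes always qualify),
#' (ii) at least \code{min_taxa} (40) taxa are nonmissing at both sites, and
#' (iii) at least \code{min_minor} (2) of those taxa carry the minor allele
#' at each site. The up-to-20 best (lowest-P) hits are collected; a site is
#' rejected when the best P-value exceeds 1e-6 or when none of the best hits
#' is local (same chromosome, within 1 Mb, P within 10x of the best P);
#' otherwise it passes with the LLD flag. Sites with no testable anchor pair
#' pass unassessed, without the flag.
#'
#' @name ldfilter
NULL

# two-sided Fisher exact P for a 2x2 table (point-probability method),
# computed from hypergeometric point masses; vectorised over tables
.fet2 <- function(n11, n10, n01, n00) {
  vapply(seq_along(n11), function(i) {
    m <- n11[i] + n10[i]      # row 1 total
    n <- n01[i] + n00[i]      # row 2 total
    k <- n11[i] + n01[i]      # column 1 total
    lo <- max(0L, k - n); hi <- min(k, m)
    supp <- lo:hi
    d <- stats::dhyper(supp, m, n, k)
    pobs <- stats::dhyper(n11[i], m, n, k)
    sum(d[d <= pobs * (1 + 1e-7)])
  }, 0)
}

# minor-carrier haplotype vector for a genotype-code vector: 1 = carries a
# non-major allele (het counted as minor homozygote), 0 = major homozygote,
# NA = missing. Major allele = most frequent allele among called genotypes.
.hap_minor <- function(geno) {
  ok <- !is.na(geno)
  if (!any(ok)) return(rep(NA_integer_, length(geno)))
  ac <- colSums(.geno_counts[geno[ok], , drop = FALSE])
  major <- which.max(ac)
  h <- rep(NA_integer_, length(geno))
  h[ok] <- as.integer(.geno_counts[geno[ok], major] < 2L)
  h
}

#' LD P-value between two sites
#'
#' @param geno_a,geno_b genotype-code vectors over the same taxa
#' @param chrom_a,chrom_b,pos_a,pos_b coordinates of the two sites
#' @param min_bp minimum separation in bp on the same chromosome
#'   (default 2500)
#' @param min_taxa minimum jointly nonmissing taxa (default 40)
#' @param min_minor minimum minor-carrying taxa at each site, within the
#'   jointly nonmissing set (default 2)
#' @return the two-sided Fisher exact P-value, or NA when the pair is
#'   untestable
#' @export
ld_pvalue <- function(geno_a, geno_b, chrom_a, pos_a, chrom_b, pos_b,
                      min_bp = 2500, min_taxa = 40, min_minor = 2) {
  if (length(geno_a) != length(geno_b)) stop("genotype vectors differ in length")
  if (chrom_a == chrom_b && abs(pos_a - pos_b) < min_bp) return(NA_real_)
  ha <- .hap_minor(geno_a); hb <- .hap_minor(geno_b)
  ok <- !is.na(ha) & !is.na(hb)
  if (sum(ok) < min_taxa) return(NA_real_)
  ha <- ha[ok]; hb <- hb[ok]
  if (sum(ha) < min_minor || sum(hb) < min_minor) return(NA_real_)
  .fet2(sum(ha == 1 & hb == 1), sum(ha == 1 & hb == 0),
        sum(ha == 0 & hb == 1), sum(ha == 0 & hb == 0))
}

.anchor_hap_matrix <- function(anchor) {
  H <- t(apply(anchor$geno, 1L, .hap_minor))
  if (nrow(anchor$geno) == 1L) H <- matrix(H, nrow = 1L)
  H
}

#' Precompute anchor haplotype vectors for repeated LD filtering
#'
#' @param anchor an [anchor_map()]
#' @return the anchor with the minor-carrier matrix cached
#' @export
prepare_anchor_ld <- function(anchor) {
  stopifnot(inherits(anchor, "hap_anchor"))
  attr(anchor, "hap_cache") <- .anchor_hap_matrix(anchor)
  anchor
}

#' Apply the LD filter to one candidate site
#'
#' @param geno genotype codes of the candidate site over all taxa
#' @param chrom,pos candidate coordinates
#' @param anchor an [anchor_map()] over the same taxa
#' @param max_hits best hits collected (default 20)
#' @param best_p_max rejection threshold on the best hit (default 1e-6)
#' @param local_radius bp radius defining a local hit (default 1e6)
#' @param local_factor a local hit must have P within this factor of the
#'   best P (default 10)
#' @param min_bp,min_taxa,min_minor testability conditions, see
#'   [ld_pvalue()]
#' @return list with \code{status} in "lld", "unassessed", "reject", and
#'   \code{hits}: a data.frame of the collected best hits (anchor index,
#'   chrom, pos, pvalue, local flag)
#' @export
ld_filter <- function(geno, chrom, pos, anchor, max_hits = 20,
                      best_p_max = 1e-6, local_radius = 1e6,
                      local_factor = 10, min_bp = 2500, min_taxa = 40,
                      min_minor = 2) {
  stopifnot(inherits(anchor, "hap_anchor"),
            length(geno) == length(anchor$taxa))
  h <- .hap_minor(geno)
  hn <- !is.na(h)
  # anchor minor-carrier matrix; precompute once via prepare_anchor_ld()
  # when filtering many candidate sites against the same anchor
  H <- attr(anchor, "hap_cache")
  if (is.null(H)) H <- .anchor_hap_matrix(anchor)
  Hn <- !is.na(H)
  h1 <- as.numeric(h == 1 & hn); h0 <- as.numeric(h == 0 & hn)
  h1[is.na(h1)] <- 0; h0[is.na(h0)] <- 0
  M1 <- H == 1 & Hn; M0 <- H == 0 & Hn
  M1[is.na(M1)] <- FALSE; M0[is.na(M0)] <- FALSE
  n11 <- as.vector(M1 %*% h1); n10 <- as.vector(M1 %*% h0)
  n01 <- as.vector(M0 %*% h1); n00 <- as.vector(M0 %*% h0)
  far <- anchor$sites$chrom != chrom |
    abs(anchor$sites$pos - pos) >= min_bp
  testable <- far & (n11 + n10 + n01 + n00) >= min_taxa &
    (n11 + n01) >= min_minor & (n11 + n10) >= min_minor
  if (!any(testable)) {
    return(list(status = "unassessed",
                hits = data.frame(anchor = integer(0), chrom = character(0),
                                  pos = integer(0), pvalue = numeric(0),
                                  local = logical(0))))
  }
  ti <- which(testable)
  p <- .fet2(n11[ti], n10[ti], n01[ti], n00[ti])
  ord <- order(p, anchor$sites$chrom[ti], anchor$sites$pos[ti])
  top <- head(ord, max_hits)
  hits <- data.frame(anchor = ti[top],
                     chrom = anchor$sites$chrom[ti[top]],
                     pos = anchor$sites$pos[ti[top]],
                     pvalue = p[top], stringsAsFactors = FALSE)
  best_p <- hits$pvalue[1]
  hits$local <- hits$chrom == chrom & abs(hits$pos - pos) <= local_radius &
    hits$pvalue <= local_factor * best_p
  status <- if (best_p > best_p_max) {
    "reject"
  } else if (any(hits$local)) {
    "lld"
  } else {
    "reject"
  }
  list(status = status, hits = hits)
}
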