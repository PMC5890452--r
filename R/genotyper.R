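#' Likelihood genotype calling and tentative site discovery
#'
#' Genotypes are called per taxon from the six-allele depth vector under a
#' multinomial read model with a uniform error rate \code{eps} (default 1\%):
#' a read drawn from homozygote a/a shows allele x with probability
#' \code{1 - eps} if x = a and \code{eps/5} otherwise; under heterozygote
#' a/b each of a and b is seen with probability \code{(1-eps)/2 + eps/10}
#' and any other allele with \code{eps/5}. The maximum-likelihood genotype
#' over the 21 unordered pairs is returned, with ties broken toward the
#' homozygote of the deeper allele and then by allele order; a taxon with no
#' reads is missing.
#'
#' @name genotyper
NULL

# 6 x 21 matrix of per-read log emission probabilities for a given eps
.geno_logp <- function(eps) {
  p <- matrix(eps / 5, 6, 21)
  for (k in 1:21) {
    a <- .geno_pairs[k, 1]; b <- .geno_pairs[k, 2]
    if (a == b) {
      p[a, k] <- 1 - eps
    } else {
      p[a, k] <- (1 - eps) / 2 + eps / 10
      p[b, k] <- (1 - eps) / 2 + eps / 10
    }
  }
  log(p)
}

# resolve ML genotype codes for a taxa x 6 depth matrix; returns integer codes
.call_geno_matrix <- function(dep, eps) {
  lp <- .geno_logp(eps)
  ll <- dep %*% lp                      # taxa x 21 log-likelihoods
  out <- rep(NA_integer_, nrow(dep))
  tot <- rowSums(dep)
  ok <- tot > 0
  if (!any(ok)) return(out)
  mx <- apply(ll[ok, , drop = FALSE], 1L, max)
  rows <- which(ok)
  for (r in seq_along(rows)) {
    i <- rows[r]
    cand <- which(ll[i, ] >= mx[r] - 1e-9 * abs(mx[r]) - 1e-12)
    if (length(cand) == 1L) {
      out[i] <- cand
    } else {
      # ties: prefer homozygote of the deeper allele, then allele order
      hom <- cand[!.geno_is_het[cand]]
      if (length(hom)) {
        d <- dep[i, .geno_pairs[hom, 1]]
        out[i] <- hom[order(-d, .geno_pairs[hom, 1])][1]
      } else {
        out[i] <- min(cand)
      }
    }
  }
  out
}

#' Call a genotype from a six-allele depth vector
#'
#' @param depths numeric vector of length 6 (A, C, G, T, I, D read depths)
#' @param error_rate uniform per-read error rate in (0, 0.5)
#' @return integer genotype code (see [geno_code()]), or NA when all depths
#'   are zero
#' @examples
#' geno_label(call_genotype(c(10, 0, 0, 0, 0, 0)))
#' geno_label(call_genotype(c(5, 5, 0, 0, 0, 0)))
#' @export
call_genotype <- function(depths, error_rate = 0.01) {
  stopifnot(length(depths) == 6L, all(depths >= 0))
  if (error_rate <= 0 || error_rate >= 0.5) {
    stop("error_rate must lie in (0, 0.5)")
  }
  .call_geno_matrix(matrix(as.numeric(depths), 1L, 6L), error_rate)[1]
}

#' Evaluate one genomic position for tentative variation
#'
#' A position yields a tentative site only when at least \code{min_covered_taxa}
#' taxa have any coverage, some non-reference allele is present in the reads,
#' and not every called genotype is a reference homozygote. Alternative
#' alleles are ranked by their total read depth across taxa and at most the
#' two most abundant are kept (final retention is decided downstream by the
#' segregation test).
#'
#' @param dep numeric \code{taxa x 6} depth matrix for the position
#' @param ref_allele reference allele symbol, one of A, C, G, T
#' @param min_covered_taxa minimum number of taxa with coverage (default 10)
#' @param error_rate genotyping error rate (default 0.01)
#' @param chrom,pos coordinates carried into the result
#' @param qual optional \code{taxa x 6} mean base-quality matrix
#' @return a \code{hap_site} list (ref, alts, genotype codes, allele depth
#'   totals, mean quals) or NULL when the position is not tentatively variant
#' @export
discover_site <- function(dep, ref_allele, min_covered_taxa = 10,
                          error_rate = 0.01, chrom = "chr1", pos = 1L,
                          qual = NULL) {
  ref <- match(ref_allele, HAP_ALLELES)
  if (is.na(ref)) stop("unknown reference allele: ", ref_allele)
  dep <- as.matrix(dep)
  stopifnot(ncol(dep) == 6L)
  covered <- rowSums(dep) > 0
  if (sum(covered) < min_covered_taxa) return(NULL)
  allele_depth <- colSums(dep)
  alt_present <- which(allele_depth > 0 & seq_len(6) != ref)
  if (length(alt_present) == 0) return(NULL)
  geno <- .call_geno_matrix(dep, error_rate)
  ref_hom <- geno_code(ref, ref)
  called <- geno[!is.na(geno)]
  if (length(called) == 0 || all(called == ref_hom)) return(NULL)
  # alleles actually carried by non-reference calls, ranked by read depth
  alt_used <- alt_present[order(-allele_depth[alt_present], alt_present)]
  alts <- head(alt_used, 2L)
  aq <- if (is.null(qual)) rep(0, 6) else {
    qs <- colSums(qual * dep)
    ifelse(allele_depth > 0, qs / allele_depth, 0)
  }
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alts = as.integer(alts), geno = geno,
                 allele_depth = allele_depth, mean_qual = aq,
                 taxon_depth = dep),
            class = "hap_site")
}

#' @export
#' @method print hap_site
print.hap_site <- function(x, ...) {
  cat(sprintf("<hap_site> %s:%d ref %s alt %s; %d/%d taxa called\n",
              x$chrom, x$pos, HAP_ALLELES[x$ref],
              paste(HAP_ALLELES[x$alts], collapse = ","),
              sum(!is.na(x$geno)), length(x$geno)))
  invisible(x)
}

#' The ">1, >2" minor-depth filter
#'
#' A site is accepted when the read support of its minor (alternative)
#' alleles is greater than 1 in at least one taxon and greater than 2 summed
#' across all taxa. With two alternative alleles, each is tested on its own
#' per-taxon depths; alleles failing the rule are dropped, and the site
#' fails when no alternative allele survives.
#'
#' @param site a \code{hap_site} from [discover_site()] (needs per-taxon
#'   depths)
#' @return list with \code{pass} (logical) and \code{kept_alts} (integer
#'   allele indices that satisfy the rule)
#' @export
minor_depth_filter <- function(site) {
  stopifnot(inherits(site, "hap_site"))
  keep <- integer(0)
  for (a in site$alts) {
    d <- site$taxon_depth[, a]
    if (max(d) > 1 && sum(d) > 2) keep <- c(keep, a)
  }
  list(pass = length(keep) > 0, kept_alts = keep)
}
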