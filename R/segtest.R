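#' Segregation test on 2 x N allelic depth tables
#'
#' For a pair of alleles at a site, the per-taxon read depths form a 2 x N
#' contingency table (one column per taxon). In a panel of inbred lines the
#' two alleles of a real variant are concentrated in roughly disjoint taxon
#' subsets, whereas sequencing/alignment errors scatter the minor depths at
#' random; the test's P-value measures that randomness. Since exact Fisher
#' P-values for 2 x N tables are expensive, a hybrid scheme is used: the
#' Pearson chi-square P-value is computed first and returned as-is when it
#' is at least \code{chisq_gate} (0.2), exploiting the empirical observation
#' that in that regime it is a de facto lower bound on the exact P-value;
#' otherwise a Monte-Carlo estimate of the Fisher exact P-value is computed
#' by sampling \code{B} tables with the observed margins (Patefield
#' algorithm via [stats::r2dtable()]) and scoring tables whose
#' log-probability does not exceed the observed one:
#' P = (1 + #{sims <= obs}) / (B + 1).
#'
#' @name segtest
NULL

# run code with a private, seeded RNG stream, restoring global state
.with_seed <- function(seed, code) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  if (!is.null(seed)) set.seed(seed)
  force(code)
}

# deterministic per-site stream id derived from a master seed and coordinates
.site_seed <- function(seed, chrom, pos) {
  h <- sum(utf8ToInt(as.character(chrom)) * 131L %% 7919L)
  as.integer((as.numeric(seed) * 48271 + h * 2097593 + as.numeric(pos) * 69621) %%
               2147483562) + 1L
}

#' Segregation-test P-value for a 2 x N depth table
#'
#' @param tab numeric matrix with 2 rows (allele depths) and one column per
#'   taxon; columns with zero totals are dropped before testing
#' @param B Monte-Carlo replicates (default 2000)
#' @param seed RNG seed for the Monte-Carlo stage; the global RNG state is
#'   left untouched
#' @param chisq_gate chi-square P-value above which no simulation is run
#'   (default 0.2; set to > 1 to force simulation)
#' @return a P-value in (0, 1]; degenerate tables (a zero row, or fewer than
#'   two non-empty columns) give 1 by convention
#' @export
seg_pvalue <- function(tab, B = 2000, seed = NULL, chisq_gate = 0.2) {
  tab <- as.matrix(tab)
  stopifnot(nrow(tab) == 2L, all(tab >= 0))
  tab <- tab[, colSums(tab) > 0, drop = FALSE]
  if (ncol(tab) < 2L || any(rowSums(tab) == 0)) return(1)
  chi <- suppressWarnings(stats::chisq.test(tab, correct = FALSE))$p.value
  if (is.na(chi)) chi <- 1
  if (chi >= chisq_gate) return(chi)
  sr <- as.integer(round(rowSums(tab)))
  sc <- as.integer(round(colSums(tab)))
  obs <- -sum(lfactorial(tab))
  almost1 <- 1 + 64 * .Machine$double.eps
  .with_seed(seed, {
    sims <- stats::r2dtable(B, sr, sc)
    stat <- -colSums(matrix(lfactorial(unlist(sims)), nrow = length(tab)))
    (1 + sum(stat <= obs / almost1)) / (B + 1)
  })
}

#' Segregation-test filter for a tentative site
#'
#' Builds the 2 x N depth table for every unordered pair of site alleles
#' (reference plus alternatives), computes [seg_pvalue()] for each, and
#' keeps an alternative allele when at least one table involving it has a
#' P-value at or below \code{alpha}. The site is skipped when no
#' alternative survives.
#'
#' @param site a \code{hap_site} from [discover_site()]
#' @param alpha retention threshold on the P-value (default 0.01)
#' @param B,chisq_gate passed to [seg_pvalue()]
#' @param seed master seed; the per-site stream is derived from
#'   (seed, chrom, pos) so results do not depend on processing order
#' @return list with \code{pass}, \code{kept_alts}, \code{pvalue} (the
#'   smallest P over all tables) and \code{allele_p} (per-alt minimum P)
#' @export
st_filter <- function(site, alpha = 0.01, B = 2000, seed = NULL,
                      chisq_gate = 0.2) {
  stopifnot(inherits(site, "hap_site"))
  alleles <- c(site$ref, site$alts)
  sseed <- if (is.null(seed)) NULL else .site_seed(seed, site$chrom, site$pos)
  np <- length(alleles)
  allele_p <- stats::setNames(rep(Inf, length(site$alts)),
                              HAP_ALLELES[site$alts])
  pmin_all <- Inf
  for (i in seq_len(np - 1L)) {
    for (j in seq((i + 1L), np)) {
      tab <- rbind(site$taxon_depth[, alleles[i]],
                   site$taxon_depth[, alleles[j]])
      p <- seg_pvalue(tab, B = B, seed = sseed, chisq_gate = chisq_gate)
      pmin_all <- min(pmin_all, p)
      for (a in intersect(alleles[c(i, j)], site$alts)) {
        k <- match(a, site$alts)
        allele_p[k] <- min(allele_p[k], p)
      }
    }
  }
  kept <- site$alts[allele_p <= alpha]
  list(pass = length(kept) > 0, kept_alts = kept,
       pvalue = if (is.finite(pmin_all)) pmin_all else 1,
       allele_p = allele_p)
}
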