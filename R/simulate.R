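#' Synthetic inbred-cohort simulator
#'
#' Generates a cohort of (mostly) inbred taxa descended from a small number
#' of founders, together with the read-depth observations and a trusted
#' anchor map, so that every pipeline stage can be exercised against known
#' truth. Each taxon's genome is a mosaic of founder segments (breakpoints
#' follow a Poisson process with mean segment length
#' \code{founder_block_bp}), which creates identity-by-descent between taxa
#' sharing a founder over a window and local linkage disequilibrium at the
#' block scale. Site classes:
#' \describe{
#'   \item{true}{a real variant; founders carry the minor allele with the
#'     site's MAF, taxa are homozygous for their founder's allele apart
#'     from planted residual heterozygosity; a configurable fraction are
#'     indels (I/D alleles).}
#'   \item{error_only}{monomorphic reference; minor alleles appear only
#'     through sequencing error.}
#'   \item{paralog}{a collapsed paralogous locus: taxa whose founder
#'     carries the hidden paralog allele receive a 50/50 read mixture,
#'     producing systematic heterozygous calls.}
#'   \item{translocated}{the genotype pattern is copied from a donor site
#'     in a distant genomic region, mimicking a mismapped marker whose
#'     genetic position disagrees with its physical one.}
#' }
#' Read depths are Poisson(\code{coverage_mean}) per taxon and site; each
#' read reports a genotype allele, replaced with probability
#' \code{seq_error_rate} by one of the other five alleles uniformly. The
#' anchor map is a subsample of high-MAF true SNP sites more than 5 bp from
#' any indel, with genotypes masked at rate \code{anchor_missing_rate}.
#' Everything is reproducible from \code{seed}.
#'
#' @name simcohort
NULL

#' Simulation configuration
#'
#' @param n_taxa number of taxa (default 50)
#' @param n_founders number of founder haplotypes (default 5)
#' @param chrom_lengths named vector of chromosome lengths in bp
#' @param n_true_sites planted true variants (default 2000)
#' @param maf_distribution function(n) drawing n minor allele frequencies
#'   (default a folded-SFS-like 0.5 * Beta(1, 3))
#' @param coverage_mean mean per-taxon read depth (default 4)
#' @param seq_error_rate per-read error probability (default 0.005)
#' @param het_residual_rate per-genotype residual heterozygosity
#'   (default 0.01)
#' @param n_paralog_sites,n_translocated_sites,n_error_only_sites counts of
#'   artifact site classes (default 0)
#' @param indel_fraction fraction of true sites whose minor allele is I or
#'   D (default 0.05)
#' @param founder_block_bp mean founder-segment length in bp (default 4e6;
#'   use a value far above the chromosome length for clone-like taxa)
#' @param founder_assignment "random" draws every founder segment iid;
#'   "balanced" assigns the first segment of each chromosome from a
#'   balanced permutation across taxa (equal-sized clone groups in the
#'   clone-cohort limit, as in a deliberately balanced validation panel)
#' @param paralog_freq founder frequency of the hidden paralog allele
#'   (default 0.3)
#' @param anchor_density fraction of eligible true SNP sites included in
#'   the anchor map (default 0.5)
#' @param anchor_min_maf minimum realized MAF for anchor eligibility
#'   (default 0.05)
#' @param anchor_missing_rate missing-genotype rate in the anchor map
#'   (default 0.05)
#' @param base_qual phred base quality attached to simulated reads
#'   (default 30)
#' @param seed mandatory RNG seed
#' @return a \code{sim_config} list
#' @export
sim_config <- function(n_taxa = 50, n_founders = 5,
                       chrom_lengths = c(chr1 = 1e7, chr2 = 1e7),
                       n_true_sites = 2000,
                       maf_distribution = function(n) 0.5 * stats::rbeta(n, 1, 3),
                       coverage_mean = 4, seq_error_rate = 0.005,
                       het_residual_rate = 0.01, n_paralog_sites = 0,
                       n_translocated_sites = 0, n_error_only_sites = 0,
                       indel_fraction = 0.05, founder_block_bp = 4e6,
                       founder_assignment = c("random", "balanced"),
                       paralog_freq = 0.3, anchor_density = 0.5,
                       anchor_min_maf = 0.05, anchor_missing_rate = 0.05,
                       base_qual = 30, seed) {
  if (missing(seed)) stop("sim_config: seed is mandatory")
  stopifnot(n_taxa > 0, n_founders > 0, all(chrom_lengths > 0),
            n_true_sites >= 0, n_paralog_sites >= 0,
            n_translocated_sites >= 0, n_error_only_sites >= 0,
            coverage_mean >= 0, seq_error_rate >= 0, seq_error_rate <= 1,
            het_residual_rate >= 0, het_residual_rate <= 1,
            anchor_density >= 0, anchor_density <= 1)
  founder_assignment <- match.arg(founder_assignment)
  if (is.null(names(chrom_lengths))) {
    names(chrom_lengths) <- paste0("chr", seq_along(chrom_lengths))
  }
  structure(as.list(environment()), class = "sim_config")
}

# vectorised multinomial draws: n_vec trials each, shared probability p6
.rmultinom_rows <- function(n_vec, p6) {
  m <- matrix(0, length(n_vec), 6L)
  rem <- n_vec
  prem <- 1
  for (a in 1:5) {
    pa <- if (prem > 0) min(p6[a] / prem, 1) else 0
    m[, a] <- stats::rbinom(length(rem), rem, pa)
    rem <- rem - m[, a]
    prem <- prem - p6[a]
  }
  m[, 6] <- rem
  m
}

# read-emission probability over the 6 alleles for a genotype code
.emission_p <- function(code, eps) {
  a <- .geno_pairs[code, ]
  p <- rep(eps / 5, 6)
  if (a[1] == a[2]) {
    p[a[1]] <- 1 - eps
  } else {
    p[a[1]] <- (1 - eps) / 2 + eps / 10
    p[a[2]] <- (1 - eps) / 2 + eps / 10
  }
  p
}

#' Simulate a cohort
#'
#' @param cfg a [sim_config()]
#' @return list with \code{depths} (named list of [depth_matrix()] per
#'   chromosome), \code{anchor} (an [anchor_map()]), and \code{truth}: a
#'   list holding the site table (chrom, pos, label, ref, alt, maf), the
#'   true genotype matrix, the founder-assignment matrix, the anchor site
#'   indices, and the taxon names
#' @export
simulate_cohort <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  set.seed(cfg$seed)
  taxa <- sprintf("tx%03d", seq_len(cfg$n_taxa))
  n_all <- cfg$n_true_sites + cfg$n_paralog_sites +
    cfg$n_translocated_sites + cfg$n_error_only_sites
  chroms <- names(cfg$chrom_lengths)
  # allocate site counts per chromosome proportionally to length
  frac <- cfg$chrom_lengths / sum(cfg$chrom_lengths)
  n_per <- floor(n_all * frac)
  while (sum(n_per) < n_all) {
    i <- which.max(frac - n_per / n_all)
    n_per[i] <- n_per[i] + 1L
  }
  site_chrom <- rep(chroms, n_per)
  site_pos <- unlist(lapply(seq_along(chroms), function(i) {
    sort(sample.int(cfg$chrom_lengths[i], n_per[i]))
  }), use.names = FALSE)
  labels <- sample(rep(c("true", "paralog", "translocated", "error_only"),
                       c(cfg$n_true_sites, cfg$n_paralog_sites,
                         cfg$n_translocated_sites, cfg$n_error_only_sites)))
  ref <- sample.int(4L, n_all, replace = TRUE)
  alt <- rep(NA_integer_, n_all)
  maf <- rep(NA_real_, n_all)
  is_true <- labels == "true"
  n_true <- sum(is_true)
  if (n_true > 0) {
    maf[is_true] <- cfg$maf_distribution(n_true)
    indel <- stats::runif(n_true) < cfg$indel_fraction
    alt_t <- integer(n_true)
    alt_t[indel] <- sample(5:6, sum(indel), replace = TRUE)
    alt_t[!indel] <- vapply(ref[is_true][!indel], function(r) {
      sample(setdiff(1:4, r), 1)
    }, 0L)
    alt[is_true] <- alt_t
  }
  is_par <- labels == "paralog"
  if (any(is_par)) {
    alt[is_par] <- vapply(ref[is_par], function(r) {
      sample(setdiff(1:4, r), 1)
    }, 0L)
  }
  # founder mosaics: founder id per (site, taxon)
  founder <- matrix(0L, n_all, cfg$n_taxa)
  for (ci in seq_along(chroms)) {
    rows <- which(site_chrom == chroms[ci])
    L <- cfg$chrom_lengths[ci]
    first_ids <- if (cfg$founder_assignment == "balanced") {
      sample(rep_len(seq_len(cfg$n_founders), cfg$n_taxa))
    } else {
      sample.int(cfg$n_founders, cfg$n_taxa, replace = TRUE)
    }
    for (t in seq_len(cfg$n_taxa)) {
      bp <- 0
      brk <- numeric(0)
      while (TRUE) {
        bp <- bp + stats::rexp(1, 1 / cfg$founder_block_bp)
        if (bp >= L) break
        brk <- c(brk, bp)
      }
      seg <- findInterval(site_pos[rows], brk) + 1L
      ids <- c(first_ids[t],
               sample.int(cfg$n_founders, length(brk), replace = TRUE))
      founder[rows, t] <- ids[seg]
    }
  }
  # founder alleles at true sites (TRUE = minor); paralog carrier founders
  fall <- matrix(FALSE, n_all, cfg$n_founders)
  if (n_true > 0) {
    fall[is_true, ] <- stats::runif(n_true * cfg$n_founders) <
      maf[is_true]
  }
  if (any(is_par)) {
    fall[is_par, ] <- stats::runif(sum(is_par) * cfg$n_founders) <
      cfg$paralog_freq
  }
  # true genotypes
  geno <- matrix(NA_integer_, n_all, cfg$n_taxa)
  ref_hom <- geno_code(ref, ref)
  for (s in which(is_true)) {
    carrier <- fall[s, founder[s, ]]
    g <- ifelse(carrier, geno_code(alt[s], alt[s]), ref_hom[s])
    het <- stats::runif(cfg$n_taxa) < cfg$het_residual_rate
    g[het] <- geno_code(ref[s], alt[s])
    geno[s, ] <- g
  }
  geno[labels == "error_only", ] <-
    ref_hom[labels == "error_only"]
  geno[is_par, ] <- ref_hom[is_par]    # primary locus truly monomorphic
  # translocated sites copy a donor pattern from a distant region
  donor <- rep(NA_integer_, n_all)
  tr <- which(labels == "translocated")
  true_idx <- which(is_true)
  for (s in tr) {
    far <- true_idx[site_chrom[true_idx] != site_chrom[s] |
                      abs(site_pos[true_idx] - site_pos[s]) >
                        3 * cfg$founder_block_bp]
    # only segregating donors make a meaningful translocated pattern: a
    # pattern copied from a (near-)monomorphic site is untestable by LD
    if (length(far)) {
      carr <- vapply(far, function(d) {
        sum(geno_carries(geno[d, ], alt[d]), na.rm = TRUE)
      }, 0L)
      far <- far[carr >= pmax(2, round(0.1 * cfg$n_taxa))]
    }
    if (length(far) == 0) stop("no distant donor site available; enlarge genome")
    d <- far[sample.int(length(far), 1)]
    donor[s] <- d
    a <- sample(setdiff(1:4, ref[s]), 1)
    alt[s] <- a
    carrier <- geno_carries(geno[d, ], alt[d]) & !is.na(geno[d, ])
    g <- ifelse(carrier, geno_code(a, a), ref_hom[s])
    geno[s, ] <- g
  }
  # emission genotype: true genotype except at paralog sites, where carrier
  # taxa emit a 50/50 ref/alt mixture
  emit <- geno
  for (s in which(is_par)) {
    carrier <- fall[s, founder[s, ]]
    emit[s, carrier] <- geno_code(ref[s], alt[s])
  }
  # depth emission per chromosome
  depths <- list()
  for (ci in seq_along(chroms)) {
    rows <- which(site_chrom == chroms[ci])
    ns <- length(rows)
    dep <- array(0, c(ns, cfg$n_taxa, 6L))
    n_reads <- matrix(stats::rpois(ns * cfg$n_taxa, cfg$coverage_mean),
                      ns, cfg$n_taxa)
    ecode <- emit[rows, , drop = FALSE]
    for (cd in sort(unique(as.vector(ecode)))) {
      cells <- which(ecode == cd & n_reads > 0)
      if (length(cells) == 0) next
      p <- .emission_p(cd, cfg$seq_error_rate)
      counts <- .rmultinom_rows(n_reads[cells], p)
      for (a in 1:6) {
        slab <- matrix(0, ns, cfg$n_taxa)
        slab[cells] <- counts[, a]
        dep[, , a] <- dep[, , a] + slab
      }
    }
    qual <- array(0, c(ns, cfg$n_taxa, 6L))
    qual[dep > 0] <- cfg$base_qual
    depths[[chroms[ci]]] <- depth_matrix(chroms[ci], site_pos[rows], taxa,
                                         dep, qual, ref = ref[rows])
  }
  # anchor: high-MAF true SNP sites away from indels
  realized_maf <- vapply(seq_len(n_all), function(s) .site_maf(geno[s, ]), 0)
  indel_sites <- which(!is.na(alt) & alt >= 5L)
  near_indel <- rep(FALSE, n_all)
  for (ch in chroms) {
    rows <- which(site_chrom == ch)
    ip <- site_pos[intersect(rows, indel_sites)]
    if (length(ip)) {
      near_indel[rows] <- vapply(site_pos[rows], function(p) {
        any(abs(ip - p) <= 5)
      }, TRUE)
    }
  }
  eligible <- which(is_true & !is.na(alt) & alt <= 4L &
                      realized_maf >= cfg$anchor_min_maf & !near_indel)
  n_anchor <- floor(cfg$anchor_density * length(eligible))
  anchor_idx <- sort(sample(eligible, n_anchor))
  ag <- geno[anchor_idx, , drop = FALSE]
  ag[matrix(stats::runif(length(ag)) < cfg$anchor_missing_rate,
            nrow(ag), ncol(ag))] <- NA_integer_
  anchor <- anchor_map(
    sites = data.frame(chrom = site_chrom[anchor_idx],
                       pos = site_pos[anchor_idx],
                       ref = ref[anchor_idx], alt = alt[anchor_idx],
                       stringsAsFactors = FALSE),
    geno = ag, taxa = taxa)
  truth <- list(
    sites = data.frame(chrom = site_chrom, pos = site_pos, label = labels,
                       ref = ref, alt = alt, maf = maf,
                       realized_maf = realized_maf, donor = donor,
                       stringsAsFactors = FALSE),
    geno = geno, founder = founder, anchor_idx = anchor_idx, taxa = taxa)
  list(depths = depths, anchor = anchor, truth = truth)
}

#' Ground-truth IBD pairs per anchor window
#'
#' A pair of taxa is truly IBD in a window when their founder assignment is
#' identical at every anchor site of the window.
#'
#' @param cohort a [simulate_cohort()] result
#' @param window_sites anchor sites per window (must match the value used
#'   with [find_ibd_pairs()]; default 2000)
#' @return list, per window, of a two-column matrix of taxon index pairs
#' @export
truth_ibd_pairs <- function(cohort, window_sites = 2000) {
  tr <- cohort$truth
  out <- list(); w <- 0L
  for (ch in unique(cohort$anchor$sites$chrom)) {
    idx <- which(cohort$anchor$sites$chrom == ch)
    wins <- .anchor_windows_1chrom(length(idx), window_sites)
    for (r in seq_len(nrow(wins))) {
      w <- w + 1L
      rows <- tr$anchor_idx[idx[wins[r, "start"]:wins[r, "end"]]]
      f <- tr$founder[rows, , drop = FALSE]
      nt <- ncol(f)
      prs <- which(upper.tri(matrix(0, nt, nt)), arr.ind = TRUE)
      same <- vapply(seq_len(nrow(prs)), function(i) {
        all(f[, prs[i, 1]] == f[, prs[i, 2]])
      }, TRUE)
      out[[w]] <- prs[same, , drop = FALSE]
    }
  }
  out
}
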