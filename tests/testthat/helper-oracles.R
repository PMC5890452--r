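# Independent brute-force oracles used to validate the implementation.
# These deliberately re-derive each quantity from first principles and avoid
# the package's internal code paths.

# exact Fisher P for a 2xN table by full enumeration of tables with the
# observed margins, scoring by table probability (hypergeometric convention)
enum_exact_p <- function(tab) {
  sr <- rowSums(tab)
  sc <- colSums(tab)
  n <- sum(sr)
  A <- as.matrix(expand.grid(lapply(sc, function(cc) 0:cc)))
  A <- A[rowSums(A) == sr[1], , drop = FALSE]
  logp <- apply(A, 1, function(a) sum(lchoose(sc, a)) - lchoose(n, sr[1]))
  stats <- apply(A, 1, function(a) -sum(lfactorial(c(a, sc - a))))
  obs <- -sum(lfactorial(tab))
  min(1, sum(exp(logp)[stats <= obs / (1 + 64 * .Machine$double.eps)]))
}

# genotype likelihood by literal per-read products over all 21 genotypes;
# returns log-likelihood vector indexed by genotype code
oracle_geno_loglik <- function(depths, eps) {
  ll <- numeric(21)
  k <- 0
  for (i in 1:6) for (j in i:6) {
    k <- k + 1
    p <- rep(eps / 5, 6)
    if (i == j) p[i] <- 1 - eps else {
      p[i] <- (1 - eps) / 2 + eps / 10
      p[j] <- (1 - eps) / 2 + eps / 10
    }
    l <- 0
    for (a in 1:6) if (depths[a] > 0) l <- l + depths[a] * log(p[a])
    ll[k] <- l
  }
  ll
}

# allele indices carried by a genotype code (explicit, no lookup tables)
oracle_carried <- function(code) {
  k <- 0
  for (i in 1:6) for (j in i:6) {
    k <- k + 1
    if (k == code) return(unique(c(i, j)))
  }
  stop("bad code")
}

# IBD filter by explicit loops over pairs and alleles
oracle_ibd_filter <- function(geno, pairs, min_ratio = 2, min_alleles = 2) {
  match <- mismatch <- rep(0, 6)
  seen <- rep(FALSE, 6)
  if (nrow(pairs)) {
    for (r in seq_len(nrow(pairs))) {
      ga <- geno[pairs$taxon_a[r]]
      gb <- geno[pairs$taxon_b[r]]
      if (is.na(ga) || is.na(gb)) next
      ca <- oracle_carried(ga)
      cb <- oracle_carried(gb)
      for (a in 1:6) {
        ina <- a %in% ca
        inb <- a %in% cb
        if (ina && inb) match[a] <- match[a] + 1
        if (xor(ina, inb)) mismatch[a] <- mismatch[a] + 1
        if (ina || inb) seen[a] <- TRUE
      }
    }
  }
  n_conf <- sum(match > 0 & match >= min_ratio * mismatch)
  if (n_conf >= min_alleles) "confirmed"
  else if (sum(seen) <= 1) "ibd1"
  else "fail"
}

# inbreeding coefficient by direct accumulation
oracle_inbreeding <- function(geno, maf) {
  O <- 0; N <- 0; E <- 0
  for (k in seq_along(geno)) {
    if (is.na(geno[k])) next
    N <- N + 1
    a <- oracle_carried(geno[k])
    if (length(a) == 1) O <- O + 1
    E <- E + (1 - 2 * maf[k] * (1 - maf[k]))
  }
  if (N == E) return(NA_real_)
  (O - E) / (N - E)
}

# random genotype vector over a biallelic site (codes in the global space)
random_site_geno <- function(n, ref, alt, maf = 0.2, het = 0.05,
                             miss = 0.1) {
  g <- integer(n)
  for (t in 1:n) {
    u <- runif(1)
    g[t] <- if (u < miss) NA_integer_
    else if (u < miss + het) geno_code(ref, alt)
    else if (u < miss + het + maf) geno_code(alt, alt)
    else geno_code(ref, ref)
  }
  g
}

# a small hand-built tentative site (bypasses discovery) for filter tests
make_site <- function(taxon_depth, ref, alts, geno = NULL, chrom = "chr1",
                      pos = 1000L) {
  if (is.null(geno)) geno <- rep(geno_code(ref, ref), nrow(taxon_depth))
  structure(list(chrom = chrom, pos = as.integer(pos), ref = ref,
                 alts = as.integer(alts), geno = geno,
                 allele_depth = colSums(taxon_depth),
                 mean_qual = rep(30, 6), taxon_depth = taxon_depth),
            class = "hap_site")
}

# hand-built IBD pair structure with a single window spanning a chromosome
make_ibd <- function(pairs_df, chrom = "chr1", start = 1L, end = 1e9) {
  structure(list(
    windows = data.frame(chrom = chrom, start_pos = start, end_pos = end,
                         first_site = 1L, last_site = 1L,
                         stringsAsFactors = FALSE),
    pairs = list(pairs_df), taxa = NULL), class = "hap_ibd")
}
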