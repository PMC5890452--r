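#' Per-site and per-taxon summary statistics and VCF output
#'
#' Each emitted site carries an INFO annotation set: total depth DP, number
#' of called genotypes NZ, allelic depths AD, alternative allele counts AC,
#' average allele base qualities AQ, genotype-class counts GN, heterozygote
#' count HT, the excess-heterozygosity ratio
#' EF = het_frequency / (presence_frequency * minor_allele_frequency),
#' segregation-test P-value PV, minor allele frequency MAF (summed over all
#' alternative alleles), pre-imputation MAF0, the heterozygote fraction FH
#' within the high-coverage taxon subset, imputation accuracies, and the
#' flags IBD1, LLD, NI5 (indel or within 5 bp of a putative indel), FH2
#' (FH > 2\%), DUP (heterozygote frequency > 3\%) and INHMP311 (site also in
#' the strict route's output).
#'
#' @name annotate
NULL

#' Per-taxon inbreeding coefficient
#'
#' F = (O - E) / (N - E), where O is the observed number of homozygous
#' genotypes of the taxon, N the number of sites at which it is genotyped,
#' and E = sum over those sites of (1 - 2 p q) the expected homozygote count
#' given per-site minor allele frequencies p (q = 1 - p).
#'
#' @param geno integer genotype codes of one taxon over sites (NA missing)
#' @param maf per-site minor allele frequencies, computed from all taxa
#'   with nonmissing genotypes at the site
#' @return F, or NA when N = E
#' @export
inbreeding_coefficient <- function(geno, maf) {
  stopifnot(length(geno) == length(maf))
  ok <- !is.na(geno)
  if (!any(ok)) stop("taxon has no genotyped sites")
  N <- sum(ok)
  O <- sum(!geno_is_het(geno[ok]))
  p <- maf[ok]
  E <- sum(1 - 2 * p * (1 - p))
  if (abs(N - E) < .Machine$double.eps^0.5) return(NA_real_)
  (O - E) / (N - E)
}

#' Inbreeding coefficients for every taxon of a genotype matrix
#'
#' @param geno integer genotype matrix \code{sites x taxa}
#' @return numeric vector of per-taxon F values (site MAFs computed from
#'   the matrix itself)
#' @export
inbreeding_coefficients <- function(geno) {
  maf <- apply(geno, 1L, .site_maf)
  vapply(seq_len(ncol(geno)), function(t) {
    inbreeding_coefficient(geno[, t], maf)
  }, 0)
}

#' High-coverage taxon subset
#'
#' Taxa with strictly more than \code{min_presence} nonmissing genotypes on
#' the designated chromosome.
#'
#' @param geno genotype matrix \code{sites x taxa}
#' @param site_chrom chromosome of each site
#' @param chrom the designated chromosome
#' @param min_presence presence fraction that must be exceeded (default 0.5)
#' @return integer taxon indices
#' @export
highcov_taxa <- function(geno, site_chrom, chrom, min_presence = 0.5) {
  rows <- site_chrom == chrom
  if (!any(rows)) return(integer(0))
  pres <- colMeans(!is.na(geno[rows, , drop = FALSE]))
  which(pres > min_presence)
}

#' Heterozygote fraction within the high-coverage subset
#'
#' @param geno_site genotype codes of all taxa at one site
#' @param subset taxon indices from [highcov_taxa()]
#' @return FH = heterozygotes / nonmissing genotypes within the subset, or
#'   NA when the subset is empty or has no data at the site
#' @export
fraction_het_highcov <- function(geno_site, subset) {
  if (length(subset) == 0) return(NA_real_)
  g <- geno_site[subset]
  nz <- sum(!is.na(g))
  if (nz == 0) return(NA_real_)
  sum(geno_is_het(g), na.rm = TRUE) / nz
}

# genotype-class counts in VCF order: AA,AB,BB for 1 alt; AA,AB,AC,BB,BC,CC
# for 2 alts (A = ref, B/C = alts)
.gn_counts <- function(geno_site, alleles) {
  na <- length(alleles)
  combos <- list()
  for (i in seq_len(na)) for (j in i:na) {
    combos[[length(combos) + 1L]] <- geno_code(alleles[i], alleles[j])
  }
  # VCF class order: AA, AB, AC, BB, BC, CC <=> pairs (1,1),(1,2),(1,3),
  # (2,2),(2,3),(3,3) which is exactly the enumeration above
  codes <- unlist(combos)
  vapply(codes, function(cd) sum(geno_site == cd, na.rm = TRUE), 0L)
}

#' Annotate a set of sites
#'
#' @param sites data.frame with columns chrom, pos, ref, alt1, alt2
#'   (allele indices; alt2 NA at biallelic sites)
#' @param geno integer genotype matrix \code{sites x taxa}
#' @param allele_depth optional \code{sites x 6} summed read depths
#' @param mean_qual optional \code{sites x 6} depth-weighted mean base
#'   qualities
#' @param pv optional per-site segregation-test P-values
#' @param ibd1,lld,inhmp311 optional logical flag vectors
#' @param imp optional data.frame(MAF0, ImpHomoAccuracy, ImpMinorAccuracy)
#' @param fh_chrom chromosome designating the high-coverage subset; NULL
#'   skips FH/FH2
#' @param dup_het_max heterozygote frequency above which DUP is set
#'   (default 0.03)
#' @param fh2_max FH above which FH2 is set (default 0.02)
#' @param ni5_radius putative-indel proximity for NI5 (default 5 bp)
#' @return data.frame of annotations, one row per site (AD/AC/AQ/GN as
#'   comma-joined strings, flags logical)
#' @export
annotate_sites <- function(sites, geno, allele_depth = NULL,
                           mean_qual = NULL, pv = NULL, ibd1 = NULL,
                           lld = NULL, inhmp311 = NULL, imp = NULL,
                           fh_chrom = NULL, dup_het_max = 0.03,
                           fh2_max = 0.02, ni5_radius = 5) {
  ns <- nrow(sites); nt <- ncol(geno)
  stopifnot(nrow(geno) == ns)
  join <- function(x) paste(x, collapse = ",")
  fmt <- function(x) ifelse(is.na(x), NA_character_,
                            sub("e-0", "e-", sprintf("%.4g", x)))
  out <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    stringsAsFactors = FALSE)
  site_alleles <- lapply(seq_len(ns), function(s) {
    a <- c(sites$ref[s], sites$alt1[s], sites$alt2[s])
    a[!is.na(a)]
  })
  nz <- rowSums(!is.na(geno))
  ht <- rowSums(matrix(geno_is_het(geno), ns, nt), na.rm = TRUE)
  maf <- vapply(seq_len(ns), function(s) {
    g <- geno[s, ]
    ok <- !is.na(g)
    if (!any(ok)) return(NA_real_)
    ac <- colSums(.geno_counts[g[ok], , drop = FALSE])
    alt <- setdiff(site_alleles[[s]], sites$ref[s])
    sum(ac[alt]) / sum(ac[site_alleles[[s]]])
  }, 0)
  out$NZ <- as.integer(nz)
  out$HT <- as.integer(ht)
  out$MAF <- maf
  het_freq <- ifelse(nz > 0, ht / nz, NA_real_)
  pres_freq <- nz / nt
  out$EF <- ifelse(!is.na(maf) & maf > 0 & pres_freq > 0,
                   het_freq / (pres_freq * maf), NA_real_)
  if (!is.null(allele_depth)) {
    out$DP <- as.integer(round(rowSums(allele_depth)))
    out$AD <- vapply(seq_len(ns), function(s) {
      join(as.integer(round(allele_depth[s, site_alleles[[s]]])))
    }, "")
  }
  if (!is.null(mean_qual)) {
    out$AQ <- vapply(seq_len(ns), function(s) {
      join(as.integer(round(mean_qual[s, site_alleles[[s]]])))
    }, "")
  }
  out$AC <- vapply(seq_len(ns), function(s) {
    g <- geno[s, ]
    ok <- !is.na(g)
    ac <- if (any(ok)) colSums(.geno_counts[g[ok], , drop = FALSE]) else
      rep(0L, 6)
    alt <- setdiff(site_alleles[[s]], sites$ref[s])
    join(as.integer(ac[alt]))
  }, "")
  out$GN <- vapply(seq_len(ns), function(s) {
    join(.gn_counts(geno[s, ], site_alleles[[s]]))
  }, "")
  if (!is.null(pv)) out$PV <- pv
  if (!is.null(imp)) {
    out$MAF0 <- imp$MAF0
    out$ImpHomoAccuracy <- imp$ImpHomoAccuracy
    out$ImpMinorAccuracy <- imp$ImpMinorAccuracy
  }
  if (!is.null(fh_chrom)) {
    sub <- highcov_taxa(geno, sites$chrom, fh_chrom)
    out$FH <- vapply(seq_len(ns), function(s) {
      fraction_het_highcov(geno[s, ], sub)
    }, 0)
    out$FH2 <- !is.na(out$FH) & out$FH > fh2_max
  }
  # putative indels: any site whose allele set includes I or D
  is_indel <- vapply(site_alleles, function(a) any(a >= 5L), TRUE)
  out$NI5 <- is_indel
  for (ch in unique(sites$chrom)) {
    rows <- which(sites$chrom == ch)
    ip <- sites$pos[rows[is_indel[rows]]]
    if (length(ip)) {
      near <- vapply(sites$pos[rows], function(p) {
        any(abs(ip - p) <= ni5_radius)
      }, TRUE)
      out$NI5[rows] <- out$NI5[rows] | near
    }
  }
  out$DUP <- !is.na(het_freq) & het_freq > dup_het_max
  if (!is.null(ibd1)) out$IBD1 <- ibd1
  if (!is.null(lld)) out$LLD <- lld
  if (!is.null(inhmp311)) out$INHMP311 <- inhmp311
  out
}

.vcf_info_defs <- c(
  DP = '##INFO=<ID=DP,Number=1,Type=Integer,Description="Total read depth at the site">',
  NZ = '##INFO=<ID=NZ,Number=1,Type=Integer,Description="Number of taxa with called genotypes">',
  AD = '##INFO=<ID=AD,Number=.,Type=Integer,Description="Allelic depths (reference, alternative in order listed in ALT field)">',
  AC = '##INFO=<ID=AC,Number=.,Type=Integer,Description="Numbers of alternative alleles in order listed in ALT field">',
  AQ = '##INFO=<ID=AQ,Number=.,Type=Integer,Description="Average allele base qualities (reference, alternative in order listed in ALT field)">',
  GN = '##INFO=<ID=GN,Number=.,Type=Integer,Description="Numbers of genotypes (AA,AB,BB or AA,AB,AC,BB,BC,CC if 2 alt alleles present)">',
  HT = '##INFO=<ID=HT,Number=1,Type=Integer,Description="Number of heterozygotes">',
  EF = '##INFO=<ID=EF,Number=1,Type=Float,Description="het_frequency/(presence_frequency*minor_allele_frequency)">',
  PV = '##INFO=<ID=PV,Number=1,Type=Float,Description="P-value from segregation test">',
  MAF = '##INFO=<ID=MAF,Number=1,Type=Float,Description="Minor allele frequency (summed up over all alternative alleles)">',
  MAF0 = '##INFO=<ID=MAF0,Number=1,Type=Float,Description="Minor allele frequency before imputation">',
  FH = '##INFO=<ID=FH,Number=1,Type=Float,Description="Fraction of heterozygous taxa among high-coverage taxa">',
  FH2 = '##INFO=<ID=FH2,Number=0,Type=Flag,Description="Site with FH greater than 2%">',
  IBD1 = '##INFO=<ID=IBD1,Number=0,Type=Flag,Description="Only 1 allele present in IBD contrasts">',
  LLD = '##INFO=<ID=LLD,Number=0,Type=Flag,Description="Site in local LD with anchor map">',
  NI5 = '##INFO=<ID=NI5,Number=0,Type=Flag,Description="Indel or site within 5 bp of a putative indel">',
  INHMP311 = '##INFO=<ID=INHMP311,Number=0,Type=Flag,Description="Site present in the strict-route variant set">',
  ImpHomoAccuracy = '##INFO=<ID=ImpHomoAccuracy,Number=1,Type=Float,Description="Fraction of homozygotes imputed back into homozygotes">',
  ImpMinorAccuracy = '##INFO=<ID=ImpMinorAccuracy,Number=1,Type=Float,Description="Fraction of minor allele homozygotes imputed back into minor allele homozygotes">',
  DUP = '##INFO=<ID=DUP,Number=0,Type=Flag,Description="Site with heterozygote frequency >3%">'
)

.vcf_num <- function(x) {
  ifelse(is.na(x), ".", sub("e-0", "e-", sprintf("%.4g", x)))
}

#' Write sites, annotations and genotypes to a VCF file
#'
#' Emits a VCF 4.2 text file. Indel alleles are written with the pipeline's
#' collapsed symbols I and D in REF/ALT. The INFO keys emitted are those
#' present in \code{ann} (among the supported set); flags are written when
#' TRUE.
#'
#' @param path output path
#' @param sites data.frame chrom, pos, ref, alt1, alt2 (allele indices)
#' @param geno integer genotype matrix \code{sites x taxa}
#' @param ann annotation data.frame from [annotate_sites()]
#' @param taxa taxon names
#' @return invisibly, the path
#' @export
write_vcf <- function(path, sites, geno, ann, taxa) {
  ns <- nrow(sites)
  keys <- intersect(names(.vcf_info_defs), names(ann))
  hdr <- c("##fileformat=VCFv4.2",
           "##source=hapforge",
           .vcf_info_defs[keys],
           '##FORMAT=<ID=GT,Number=1,Type=String,Description="Genotype">',
           paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", "FORMAT", taxa), collapse = "\t"))
  flag_keys <- c("FH2", "IBD1", "LLD", "NI5", "INHMP311", "DUP")
  int_keys <- c("DP", "NZ", "HT")
  rows <- character(ns)
  for (s in seq_len(ns)) {
    alleles <- c(sites$ref[s], sites$alt1[s], sites$alt2[s])
    alleles <- alleles[!is.na(alleles)]
    alt_str <- if (length(alleles) > 1) {
      paste(HAP_ALLELES[alleles[-1]], collapse = ",")
    } else "."
    info <- character(0)
    for (k in keys) {
      v <- ann[[k]][s]
      if (k %in% flag_keys) {
        if (isTRUE(v)) info <- c(info, k)
      } else if (is.na(v)) {
        next
      } else if (k %in% int_keys) {
        info <- c(info, paste0(k, "=", as.integer(v)))
      } else if (is.character(v)) {
        info <- c(info, paste0(k, "=", v))
      } else {
        info <- c(info, paste0(k, "=", .vcf_num(v)))
      }
    }
    g <- geno[s, ]
    al <- geno_alleles(g)
    i1 <- match(al[, 1], alleles) - 1L
    i2 <- match(al[, 2], alleles) - 1L
    gt <- ifelse(is.na(g) | is.na(i1) | is.na(i2), "./.",
                 paste0(pmin(i1, i2), "/", pmax(i1, i2)))
    info_str <- if (length(info)) paste(info, collapse = ";") else "."
    rows[s] <- paste(c(sites$chrom[s], sites$pos[s], ".",
                       HAP_ALLELES[sites$ref[s]], alt_str, ".", "PASS",
                       info_str, "GT", gt), collapse = "\t")
  }
  writeLines(c(hdr, rows), path)
  invisible(path)
}

#' Read a pipeline VCF back into sites, genotypes and annotations
#'
#' Uses \pkg{vcfR} for parsing. Only the INFO keys written by [write_vcf()]
#' are interpreted.
#'
#' @param path VCF path
#' @return list with \code{sites}, \code{geno}, \code{ann}, \code{taxa}
#' @export
read_vcf <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- v@fix
  ns <- nrow(fix)
  ref <- match(fix[, "REF"], HAP_ALLELES)
  alts <- strsplit(ifelse(is.na(fix[, "ALT"]), "", fix[, "ALT"]), ",",
                   fixed = TRUE)
  alt1 <- vapply(alts, function(a) {
    if (length(a) >= 1) match(a[1], HAP_ALLELES) else NA_integer_
  }, 0L)
  alt2 <- vapply(alts, function(a) {
    if (length(a) >= 2) match(a[2], HAP_ALLELES) else NA_integer_
  }, 0L)
  sites <- data.frame(chrom = fix[, "CHROM"],
                      pos = as.integer(fix[, "POS"]),
                      ref = ref, alt1 = alt1, alt2 = alt2,
                      stringsAsFactors = FALSE)
  gt <- v@gt[, -1, drop = FALSE]
  if (ns == 1 && is.null(dim(gt))) gt <- matrix(gt, nrow = 1)
  taxa <- colnames(gt)
  geno <- matrix(NA_integer_, ns, length(taxa))
  for (s in seq_len(ns)) {
    alleles <- c(sites$ref[s], sites$alt1[s], sites$alt2[s])
    alleles <- alleles[!is.na(alleles)]
    parts <- strsplit(gt[s, ], "[/|]")
    geno[s, ] <- vapply(parts, function(p) {
      if (length(p) != 2 || any(p == ".")) return(NA_integer_)
      geno_code(alleles[as.integer(p[1]) + 1L], alleles[as.integer(p[2]) + 1L])
    }, 0L)
  }
  info_kv <- strsplit(ifelse(is.na(fix[, "INFO"]), "", fix[, "INFO"]), ";",
                      fixed = TRUE)
  parse_info <- function(key, numeric = TRUE) {
    pre <- paste0(key, "=")
    val <- vapply(info_kv, function(kv) {
      hit <- kv[startsWith(kv, pre)]
      if (length(hit)) substring(hit[1], nchar(pre) + 1L) else NA_character_
    }, "")
    if (numeric) suppressWarnings(as.numeric(val)) else val
  }
  has_flag <- function(key) {
    vapply(info_kv, function(kv) key %in% kv, TRUE)
  }
  ann <- data.frame(chrom = sites$chrom, pos = sites$pos,
                    stringsAsFactors = FALSE)
  for (k in c("DP", "NZ", "HT")) {
    ann[[k]] <- as.integer(parse_info(k, numeric = TRUE))
  }
  for (k in c("EF", "PV", "MAF", "MAF0", "FH",
              "ImpHomoAccuracy", "ImpMinorAccuracy")) {
    ann[[k]] <- parse_info(k, numeric = TRUE)
  }
  for (k in c("AD", "AC", "AQ", "GN")) {
    ann[[k]] <- parse_info(k, numeric = FALSE)
  }
  for (k in c("FH2", "IBD1", "LLD", "NI5", "INHMP311", "DUP")) {
    ann[[k]] <- has_flag(k)
  }
  list(sites = sites, geno = geno, ann = ann, taxa = taxa)
}
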