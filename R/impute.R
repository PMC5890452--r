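#' LD-KNN genotype imputation
#'
#' Missing genotypes are filled by a K-nearest-neighbour vote in which the
#' neighbours of a taxon are chosen by genetic distance computed over sites
#' in good local LD with the target site. For each target site, up to 70
#' surrounding sites within 600 kb with heterozygosity below 3\% and more
#' than 50\% nonmissing taxa are ranked by r-squared with the target and
#' kept as the LD site list. For each taxon, up to 30 neighbours are taken
#' among taxa that are nonmissing at the target site, have at most 50\%
#' missing data at the LD sites, at least 10 sites comparable with the
#' target taxon, and IBS distance at most 0.1 over those sites. Each
#' candidate genotype g gets the weight \code{w_g = sum_i 1/(1 + 70 d_i)}
#' over neighbours i with genotype g; the top-weight genotype is imputed
#' when its weight is at least 10 times the runner-up's, otherwise the
#' imputation is inconclusive ("unknown"). Unknown imputations at sites
#' with pre-imputation MAF below 1\% become major-allele homozygotes. Every
#' genotype (missing or not) is test-imputed to build the transition matrix
#' and the per-site accuracy statistics, but only originally missing
#' entries change in the output.
#'
#' @name imputeknn
NULL

# minor-dosage coding for one site: 0 major hom, 0.5 het(-like), 1 minor hom
# (number of non-major alleles / 2); NA for missing
.minor_dosage <- function(geno) {
  ok <- !is.na(geno)
  out <- rep(NA_real_, length(geno))
  if (!any(ok)) return(out)
  ac <- colSums(.geno_counts[geno[ok], , drop = FALSE])
  major <- which.max(ac)
  out[ok] <- (2 - .geno_counts[geno[ok], major]) / 2
  out
}

# per-site minor allele frequency (summed over all non-major alleles)
.site_maf <- function(geno) {
  ok <- !is.na(geno)
  if (!any(ok)) return(NA_real_)
  ac <- colSums(.geno_counts[geno[ok], , drop = FALSE])
  1 - max(ac) / sum(ac)
}

.site_major_hom <- function(geno) {
  ok <- !is.na(geno)
  if (!any(ok)) return(NA_integer_)
  ac <- colSums(.geno_counts[geno[ok], , drop = FALSE])
  major <- which.max(ac)
  geno_code(major, major)
}

# per-site LD-eligibility and dosage, computed once per matrix
.ld_site_profile <- function(geno, het_max, presence_min) {
  nt <- ncol(geno)
  nz <- rowSums(!is.na(geno))
  nhet <- rowSums(matrix(geno_is_het(geno), nrow(geno), nt), na.rm = TRUE)
  elig <- nz > presence_min * nt & ifelse(nz > 0, nhet / nz, 0) < het_max
  dosage <- t(vapply(seq_len(nrow(geno)),
                     function(s) .minor_dosage(geno[s, ]),
                     numeric(nt)))
  list(elig = elig, dosage = dosage)
}

.select_ld_core <- function(target, pos, window_bp, max_sites, prof) {
  cand <- which(abs(pos - pos[target]) <= window_bp &
                  seq_along(pos) != target & prof$elig)
  if (length(cand) == 0) return(integer(0))
  y <- prof$dosage[target, ]
  r <- suppressWarnings(
    stats::cor(y, t(prof$dosage[cand, , drop = FALSE]),
               use = "pairwise.complete.obs"))
  r2 <- as.vector(r)^2
  # fewer than 2 jointly informative taxa, or a constant site, give NA
  r2[is.na(r2)] <- 0
  cand[order(-r2, cand)][seq_len(min(max_sites, length(cand)))]
}

#' Select the LD site list for a target site
#'
#' @param target index of the target site
#' @param geno integer genotype matrix \code{sites x taxa}
#' @param pos site positions (bp); all sites assumed on one chromosome
#' @param window_bp candidate window, +/- around the target (default 6e5)
#' @param max_sites list cap (default 70)
#' @param het_max maximum heterozygote fraction among called genotypes
#'   (default 0.03, strict)
#' @param presence_min sites qualify with more than this fraction of
#'   nonmissing taxa (default 0.5)
#' @return integer site indices ranked by decreasing r-squared with the
#'   target (possibly empty)
#' @export
select_ld_sites <- function(target, geno, pos, window_bp = 6e5,
                            max_sites = 70, het_max = 0.03,
                            presence_min = 0.5) {
  prof <- .ld_site_profile(geno, het_max, presence_min)
  .select_ld_core(target, pos, window_bp, max_sites, prof)
}

# pairwise IBS distances and comparable-site counts over a set of LD sites;
# d is NA where no comparable sites exist
.ld_distances <- function(geno, ld_sites) {
  nt <- ncol(geno)
  g <- geno[ld_sites, , drop = FALSE]
  g[is.na(g)] <- 22L
  ii <- rep(seq_len(nt), times = nt)
  jj <- rep(seq_len(nt), each = nt)
  v <- .geno_dist_pad[cbind(as.vector(g[, ii]), as.vector(g[, jj]))]
  v <- matrix(v, nrow = nrow(g))
  n <- colSums(!is.na(v))
  d <- ifelse(n > 0, colSums(v, na.rm = TRUE) / pmax(n, 1L), NA_real_)
  list(d = matrix(d, nt, nt), n = matrix(n, nt, nt))
}

.neighbors_from_dist <- function(target_taxon, dd, miss_frac, target_geno,
                                 max_d, min_common, max_missing, k) {
  nt <- ncol(dd$d)
  cand <- seq_len(nt)[-target_taxon]
  d <- dd$d[target_taxon, cand]
  n <- dd$n[target_taxon, cand]
  keep <- !is.na(d) & d <= max_d & n >= min_common &
    !is.na(target_geno[cand]) & miss_frac[cand] <= max_missing
  cand <- cand[keep]; d <- d[keep]
  sel <- head(order(d, cand), k)
  data.frame(taxon = cand[sel], distance = d[sel])
}

#' Nearest-neighbour taxa for one target taxon at one site
#'
#' @param target_taxon taxon index
#' @param ld_sites LD site indices from [select_ld_sites()]
#' @param geno genotype matrix \code{sites x taxa}
#' @param target_geno genotypes of all taxa at the target site (neighbours
#'   must be nonmissing there)
#' @param max_d maximum neighbour distance (default 0.1)
#' @param min_common minimum comparable LD sites (default 10)
#' @param max_missing maximum fraction of missing genotypes at the LD sites
#'   (default 0.5)
#' @param k neighbours kept (default 30)
#' @return data.frame \code{taxon}, \code{distance}, ordered by distance
#'   then taxon index
#' @export
neighbor_distances <- function(target_taxon, ld_sites, geno, target_geno,
                               max_d = 0.1, min_common = 10,
                               max_missing = 0.5, k = 30) {
  if (length(ld_sites) == 0) {
    return(data.frame(taxon = integer(0), distance = numeric(0)))
  }
  dd <- .ld_distances(geno, ld_sites)
  miss_frac <- colMeans(is.na(geno[ld_sites, , drop = FALSE]))
  .neighbors_from_dist(target_taxon, dd, miss_frac, target_geno,
                       max_d, min_common, max_missing, k)
}

#' Weighted KNN genotype vote
#'
#' @param neighbors data.frame from [neighbor_distances()]
#' @param target_geno genotypes of all taxa at the target site
#' @param weight_scale the 70 in \code{1/(1 + 70 d)}
#' @param dominance required ratio of best to second-best weight
#'   (default 10)
#' @return the imputed genotype code, or NA when the vote is inconclusive
#'   or no neighbours exist
#' @export
knn_vote <- function(neighbors, target_geno, weight_scale = 70,
                     dominance = 10) {
  if (nrow(neighbors) == 0) return(NA_integer_)
  g <- target_geno[neighbors$taxon]
  w <- 1 / (1 + weight_scale * neighbors$distance)
  ws <- vapply(split(w, g), sum, 0)
  codes <- as.integer(names(ws))
  ord <- order(-ws, codes)
  best <- ws[ord[1]]
  second <- if (length(ord) > 1) ws[ord[2]] else 0
  if (best >= dominance * second) codes[ord[1]] else NA_integer_
}

.geno_class <- function(code, major_hom) {
  ifelse(is.na(code), "unimputed",
    ifelse(.geno_counts[code, 5] + .geno_counts[code, 6] > 0, "indel",
      ifelse(code == major_hom, "major_hom",
        ifelse(.geno_is_het[code], "het", "minor_hom"))))
}

.impute_classes <- c("major_hom", "het", "minor_hom", "indel")

#' Impute a genotype matrix and collect self-imputation statistics
#'
#' @param geno integer genotype matrix \code{sites x taxa}, NA missing
#' @param pos site positions in bp (one chromosome)
#' @param maf_fallback unknown imputations at sites with pre-imputation MAF
#'   below this become major-allele homozygotes (default 0.01)
#' @param window_bp,max_ld_sites,het_max,presence_min passed to
#'   [select_ld_sites()]
#' @param max_d,min_common,max_missing,k passed to [neighbor_distances()]
#' @param weight_scale,dominance passed to [knn_vote()]
#' @return list with \code{geno} (imputed matrix; only originally missing
#'   entries differ), \code{transition} (original class x imputed class
#'   counts over originally nonmissing genotypes; classes major_hom, het,
#'   minor_hom, indel, plus an "unimputed" outcome), \code{site_stats}
#'   (per-site MAF0, ImpHomoAccuracy, ImpMinorAccuracy) and
#'   \code{test_imputed} (test-imputation results for every entry)
#' @export
impute_matrix <- function(geno, pos, maf_fallback = 0.01, window_bp = 6e5,
                          max_ld_sites = 70, het_max = 0.03,
                          presence_min = 0.5, max_d = 0.1, min_common = 10,
                          max_missing = 0.5, k = 30, weight_scale = 70,
                          dominance = 10) {
  ns <- nrow(geno); nt <- ncol(geno)
  stopifnot(length(pos) == ns)
  out <- geno
  test_imp <- matrix(NA_integer_, ns, nt)
  trans <- matrix(0L, 4, 5,
                  dimnames = list(.impute_classes,
                                  c(.impute_classes, "unimputed")))
  prof <- .ld_site_profile(geno, het_max, presence_min)
  maf0 <- vapply(seq_len(ns), function(s) .site_maf(geno[s, ]), 0)
  imp_homo <- imp_minor <- rep(NA_real_, ns)
  for (s in seq_len(ns)) {
    ld <- .select_ld_core(s, pos, window_bp, max_ld_sites, prof)
    tg <- geno[s, ]
    major_hom <- .site_major_hom(tg)
    if (length(ld) > 0) {
      dd <- .ld_distances(geno, ld)
      miss_frac <- colMeans(is.na(geno[ld, , drop = FALSE]))
      for (t in seq_len(nt)) {
        nb <- .neighbors_from_dist(t, dd, miss_frac, tg, max_d,
                                   min_common, max_missing, k)
        if (nrow(nb)) {
          test_imp[s, t] <- knn_vote(nb, tg, weight_scale, dominance)
        }
      }
    }
    if (!is.na(major_hom)) {
      orig_cls <- .geno_class(tg, major_hom)
      imp_cls <- .geno_class(test_imp[s, ], major_hom)
      known <- !is.na(tg)
      for (oc in .impute_classes) {
        sel <- known & orig_cls == oc
        if (any(sel)) {
          tb <- table(factor(imp_cls[sel], levels = colnames(trans)))
          trans[oc, ] <- trans[oc, ] + as.integer(tb)
        }
      }
      # per-site accuracies over successfully test-imputed genotypes
      hom_sel <- known & orig_cls %in% c("major_hom", "minor_hom") &
        !is.na(test_imp[s, ])
      if (any(hom_sel)) {
        imp_homo[s] <- mean(imp_cls[hom_sel] %in% c("major_hom", "minor_hom"))
      }
      min_sel <- known & orig_cls == "minor_hom" & !is.na(test_imp[s, ])
      if (any(min_sel)) {
        imp_minor[s] <- mean(imp_cls[min_sel] == "minor_hom")
      }
      # fill originally missing entries
      fill <- is.na(tg)
      if (any(fill)) {
        v <- test_imp[s, fill]
        if (!is.na(maf0[s]) && maf0[s] < maf_fallback) {
          v[is.na(v)] <- major_hom
        }
        out[s, fill] <- v
      }
    }
  }
  list(geno = out, transition = trans,
       site_stats = data.frame(MAF0 = maf0, ImpHomoAccuracy = imp_homo,
                               ImpMinorAccuracy = imp_minor),
       test_imputed = test_imp)
}
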