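#' Pipeline configuration and orchestration
#'
#' Two published filtering routes are supported, starting from the same
#' discovery + segregation-test + IBD-filtered site set:
#' \describe{
#'   \item{strict}{adds the linkage-disequilibrium filter (sites in weak or
#'     only-nonlocal LD with the anchor map are rejected) and annotates
#'     LLD/IBD1/NI5/FH/FH2.}
#'   \item{permissive}{adds the ">1, >2" minor-depth filter instead, then
#'     LD-KNN imputation, annotating DUP/MAF0/Imp* and marking membership
#'     in the strict set with INHMP311.}
#' }
#'
#' @name pipeline
NULL

#' Default pipeline configuration
#'
#' All thresholds default to the published values: base quality 10, mapping
#' quality 30 (applied upstream at pileup extraction), at least 10 covered
#' taxa, genotyping error rate 1\%, segregation-test alpha 0.01 with
#' chi-square gate 0.2, IBD windows of 2000 anchor sites with distance
#' threshold 0.02 and 200 comparable sites, match/mismatch ratio 2 for 2
#' alleles, LD testability 2500 bp / 40 taxa / 2 minor carriers with 20
#' hits, best-P cutoff 1e-6, 1 Mb local radius and factor 10, the ">1, >2"
#' depth rule, and KNN imputation with 70 LD sites in 600 kb (het < 3\%,
#' presence > 50\%), 30 neighbours, distance cap 0.1, at least 10 common
#' sites, weight scale 70, dominance 10 and MAF fallback 1\%.
#'
#' @param route "strict", "permissive" or "both"
#' @param seed master RNG seed; per-site segregation-test streams are
#'   derived from it and the site coordinates
#' @param ... overrides for individual entries (partial lists are merged)
#' @return nested configuration list
#' @export
pipeline_config <- function(route = "both", seed = 1L, ...) {
  cfg <- list(
    route = route,
    seed = as.integer(seed),
    discovery = list(min_covered_taxa = 10, error_rate = 0.01),
    st = list(alpha = 0.01, chisq_gate = 0.2, replicates = 2000),
    ibd = list(window_sites = 2000, threshold = 0.02, min_comparable = 200,
               min_ratio = 2, min_alleles = 2),
    ld = list(max_hits = 20, best_p_max = 1e-6, local_radius_bp = 1e6,
              local_factor = 10, min_bp = 2500, min_taxa = 40,
              min_minor = 2),
    impute = list(window_bp = 6e5, max_ld_sites = 70, het_max = 0.03,
                  presence_min = 0.5, max_d = 0.1, min_common = 10, k = 30,
                  weight_scale = 70, dominance = 10, maf_fallback = 0.01),
    annotate = list(fh_chrom = NULL, dup_het_max = 0.03, fh2_max = 0.02,
                    ni5_radius = 5))
  dots <- list(...)
  for (k in names(dots)) {
    if (is.list(dots[[k]]) && is.list(cfg[[k]])) {
      cfg[[k]][names(dots[[k]])] <- dots[[k]]
    } else {
      cfg[[k]] <- dots[[k]]
    }
  }
  if (!cfg$route %in% c("strict", "permissive", "both")) {
    stop("route must be one of strict, permissive, both")
  }
  cfg
}

# drop genotypes that carry alleles outside the retained set
.mask_foreign_geno <- function(geno, alleles) {
  keep_code <- outer(alleles, alleles, function(a, b) geno_code(a, b))
  geno[!is.na(geno) & !(geno %in% keep_code)] <- NA_integer_
  geno
}

.sites_df <- function(site_list) {
  data.frame(
    chrom = vapply(site_list, `[[`, "", "chrom"),
    pos = vapply(site_list, function(s) s$pos, 0L),
    ref = vapply(site_list, function(s) s$ref, 0L),
    alt1 = vapply(site_list, function(s) s$alts[1], 0L),
    alt2 = vapply(site_list, function(s) {
      if (length(s$alts) > 1) s$alts[2] else NA_integer_
    }, 0L),
    stringsAsFactors = FALSE)
}

#' Run the discovery + filtering pipeline
#'
#' @param depths a [depth_matrix()] or named list of them (one per
#'   chromosome); reference alleles must be present
#' @param anchor an [anchor_map()] over the same taxa (required for the IBD
#'   and LD stages)
#' @param config a [pipeline_config()]
#' @param out_dir optional directory; when given, the route VCFs and the
#'   attrition report are written there
#' @return list with \code{strict} and/or \code{permissive} results (each:
#'   sites, geno, ann, taxa), and \code{report}: per-stage site counts
#'   (stage, sites_in, sites_out, rejected)
#' @export
run_pipeline <- function(depths, anchor, config = pipeline_config(),
                         out_dir = NULL) {
  if (inherits(depths, "hap_depths")) depths <- list(depths)
  stopifnot(length(depths) > 0)
  if (is.null(anchor) || !inherits(anchor, "hap_anchor")) {
    stop("configuration error: the IBD and LD stages require an anchor map")
  }
  taxa <- depths[[1]]$taxa
  for (d in depths) stopifnot(identical(d$taxa, taxa))
  if (!identical(anchor$taxa, taxa)) {
    stop("configuration error: anchor taxa do not match depth-store taxa")
  }
  report <- list()
  log_stage <- function(route, stage, n_in, n_out) {
    report[[length(report) + 1L]] <<- data.frame(
      route = route, stage = stage, sites_in = n_in, sites_out = n_out,
      rejected = n_in - n_out, stringsAsFactors = FALSE)
  }

  # --- discovery -----------------------------------------------------------
  tentative <- list()
  n_positions <- 0L
  for (d in depths) {
    n_positions <- n_positions + length(d$positions)
    for (i in seq_along(d$positions)) {
      if (is.na(d$ref[i])) next
      st <- discover_site(matrix(d$depth[i, , ], ncol = 6L),
                          HAP_ALLELES[d$ref[i]],
                          min_covered_taxa = config$discovery$min_covered_taxa,
                          error_rate = config$discovery$error_rate,
                          chrom = d$chrom, pos = d$positions[i],
                          qual = matrix(d$qual[i, , ], ncol = 6L))
      if (!is.null(st)) tentative[[length(tentative) + 1L]] <- st
    }
  }
  log_stage("common", "discovery", n_positions, length(tentative))

  # --- segregation test ----------------------------------------------------
  st_sites <- list()
  for (s in tentative) {
    res <- st_filter(s, alpha = config$st$alpha, B = config$st$replicates,
                     seed = config$seed, chisq_gate = config$st$chisq_gate)
    if (res$pass) {
      s$alts <- res$kept_alts
      s$pv <- res$pvalue
      s$geno <- .mask_foreign_geno(s$geno, c(s$ref, s$alts))
      st_sites[[length(st_sites) + 1L]] <- s
    }
  }
  log_stage("common", "segregation_test", length(tentative), length(st_sites))

  # --- IBD filter ----------------------------------------------------------
  ibd <- find_ibd_pairs(anchor, window_sites = config$ibd$window_sites,
                        threshold = config$ibd$threshold,
                        min_comparable = config$ibd$min_comparable)
  ibd_sites <- list()
  for (s in st_sites) {
    res <- ibd_filter(s$geno, ibd, s$chrom, s$pos,
                      min_ratio = config$ibd$min_ratio,
                      min_alleles = config$ibd$min_alleles)
    if (res$status %in% c("confirmed", "ibd1")) {
      s$ibd1 <- res$status == "ibd1"
      ibd_sites[[length(ibd_sites) + 1L]] <- s
    }
  }
  log_stage("common", "ibd_filter", length(st_sites), length(ibd_sites))

  out <- list()
  fh_chrom <- config$annotate$fh_chrom
  if (is.null(fh_chrom)) fh_chrom <- depths[[1]]$chrom

  build_mats <- function(site_list) {
    if (length(site_list) == 0) {
      return(list(sites = data.frame(chrom = character(0), pos = integer(0),
                                     ref = integer(0), alt1 = integer(0),
                                     alt2 = integer(0)),
                  geno = matrix(NA_integer_, 0, length(taxa)),
                  ad = matrix(0, 0, 6), aq = matrix(0, 0, 6),
                  pv = numeric(0), ibd1 = logical(0)))
    }
    sites <- .sites_df(site_list)
    geno <- do.call(rbind, lapply(site_list, `[[`, "geno"))
    ad <- do.call(rbind, lapply(site_list, `[[`, "allele_depth"))
    aq <- do.call(rbind, lapply(site_list, `[[`, "mean_qual"))
    pv <- vapply(site_list, function(s) s$pv, 0)
    ibd1 <- vapply(site_list, function(s) isTRUE(s$ibd1), TRUE)
    list(sites = sites, geno = geno, ad = ad, aq = aq, pv = pv, ibd1 = ibd1)
  }

  # --- strict route: LD filter --------------------------------------------
  strict_keys <- NULL
  strict_lld_keys <- NULL
  if (config$route %in% c("strict", "both")) {
    anchor_p <- prepare_anchor_ld(anchor)
    kept <- list(); lld <- logical(0)
    for (s in ibd_sites) {
      res <- ld_filter(s$geno, s$chrom, s$pos, anchor_p,
                       max_hits = config$ld$max_hits,
                       best_p_max = config$ld$best_p_max,
                       local_radius = config$ld$local_radius_bp,
                       local_factor = config$ld$local_factor,
                       min_bp = config$ld$min_bp,
                       min_taxa = config$ld$min_taxa,
                       min_minor = config$ld$min_minor)
      if (res$status != "reject") {
        kept[[length(kept) + 1L]] <- s
        lld <- c(lld, res$status == "lld")
      }
    }
    log_stage("strict", "ld_filter", length(ibd_sites), length(kept))
    m <- build_mats(kept)
    ann <- annotate_sites(m$sites, m$geno, allele_depth = m$ad,
                          mean_qual = m$aq, pv = m$pv, ibd1 = m$ibd1,
                          lld = lld, fh_chrom = fh_chrom,
                          fh2_max = config$annotate$fh2_max,
                          ni5_radius = config$annotate$ni5_radius)
    ann$LLD <- lld
    ann$DUP <- NULL                       # DUP is a permissive-route flag
    out$strict <- list(sites = m$sites, geno = m$geno, ann = ann,
                       taxa = taxa)
    strict_keys <- paste(m$sites$chrom, m$sites$pos)
    strict_lld_keys <- strict_keys[lld]
  }

  # --- permissive route: ">1,>2" + imputation ------------------------------
  if (config$route %in% c("permissive", "both")) {
    kept <- list()
    for (s in ibd_sites) {
      res <- minor_depth_filter(s)
      if (res$pass) {
        if (!identical(sort(res$kept_alts), sort(s$alts))) {
          s$alts <- res$kept_alts
          s$geno <- .mask_foreign_geno(s$geno, c(s$ref, s$alts))
        }
        kept[[length(kept) + 1L]] <- s
      }
    }
    log_stage("permissive", "minor_depth_filter", length(ibd_sites),
              length(kept))
    m <- build_mats(kept)
    # impute per chromosome
    imp_geno <- m$geno
    imp_stats <- data.frame(MAF0 = rep(NA_real_, nrow(m$sites)),
                            ImpHomoAccuracy = NA_real_,
                            ImpMinorAccuracy = NA_real_)
    trans <- NULL
    for (ch in unique(m$sites$chrom)) {
      rows <- which(m$sites$chrom == ch)
      im <- impute_matrix(m$geno[rows, , drop = FALSE], m$sites$pos[rows],
                          maf_fallback = config$impute$maf_fallback,
                          window_bp = config$impute$window_bp,
                          max_ld_sites = config$impute$max_ld_sites,
                          het_max = config$impute$het_max,
                          presence_min = config$impute$presence_min,
                          max_d = config$impute$max_d,
                          min_common = config$impute$min_common,
                          k = config$impute$k,
                          weight_scale = config$impute$weight_scale,
                          dominance = config$impute$dominance)
      imp_geno[rows, ] <- im$geno
      imp_stats[rows, ] <- im$site_stats
      trans <- if (is.null(trans)) im$transition else trans + im$transition
    }
    log_stage("permissive", "imputation", length(kept), length(kept))
    keys <- paste(m$sites$chrom, m$sites$pos)
    inhmp <- if (is.null(strict_keys)) NULL else keys %in% strict_keys
    # LLD is carried over from the strict-route LD assessment when available
    lld_perm <- if (is.null(strict_lld_keys)) NULL else
      keys %in% strict_lld_keys
    # DUP is judged on the unimputed genotypes
    ann <- annotate_sites(m$sites, m$geno, allele_depth = m$ad,
                          mean_qual = m$aq, pv = m$pv, ibd1 = m$ibd1,
                          lld = lld_perm, inhmp311 = inhmp, imp = imp_stats,
                          dup_het_max = config$annotate$dup_het_max,
                          ni5_radius = config$annotate$ni5_radius)
    # genotype-derived counts in the emitted VCF reflect imputed genotypes
    ann_imp <- annotate_sites(m$sites, imp_geno, allele_depth = m$ad,
                              mean_qual = m$aq, pv = m$pv, ibd1 = m$ibd1,
                              lld = lld_perm, inhmp311 = inhmp,
                              imp = imp_stats,
                              dup_het_max = config$annotate$dup_het_max,
                              ni5_radius = config$annotate$ni5_radius)
    ann_imp$DUP <- ann$DUP
    out$permissive <- list(sites = m$sites, geno = imp_geno, ann = ann_imp,
                           unimputed_geno = m$geno, transition = trans,
                           taxa = taxa)
  }

  out$report <- do.call(rbind, report)
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    if (!is.null(out$strict)) {
      write_vcf(file.path(out_dir, "strict.vcf"), out$strict$sites,
                out$strict$geno, out$strict$ann, taxa)
    }
    if (!is.null(out$permissive)) {
      write_vcf(file.path(out_dir, "permissive_imputed.vcf"),
                out$permissive$sites, out$permissive$geno,
                out$permissive$ann, taxa)
    }
    utils::write.table(out$report, file.path(out_dir, "report.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  out
}
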