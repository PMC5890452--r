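#' Identity-by-descent detection and the IBD genotype filter
#'
#' A trusted anchor map (a matrix of reliable SNP genotypes, the analogue of
#' a GBS anchor) is used to find pairs of taxa that are identical by descent
#' within genomic windows: the genome is cut into consecutive windows of
#' \code{window_sites} anchor sites (2000 by default, trailing remainders
#' merged into the previous window), the identity-by-state distance is
#' computed for every taxon pair within each window, and pairs at distance
#' at most 0.02 with at least 200 comparable sites are declared IBD. A
#' candidate site then passes the IBD filter when the genotypes of IBD pairs
#' at the site confirm its alleles (match/mismatch ratio at least 2 for at
#' least two alleles), is weakly passed with the IBD1 flag when at most one
#' allele appears in the IBD contrasts, and fails otherwise.
#'
#' @name ibd
NULL

#' Anchor map constructor
#'
#' @param sites data.frame with columns \code{chrom}, \code{pos},
#'   \code{ref}, \code{alt} (allele indices 1..6), sorted by chrom and pos
#' @param geno integer matrix \code{sites x taxa} of genotype codes (NA
#'   missing)
#' @param taxa taxon names
#' @return object of class \code{hap_anchor}
#' @export
anchor_map <- function(sites, geno, taxa) {
  stopifnot(nrow(sites) == nrow(geno), length(taxa) == ncol(geno))
  for (ch in unique(sites$chrom)) {
    p <- sites$pos[sites$chrom == ch]
    if (is.unsorted(p, strictly = TRUE)) {
      stop("anchor sites must be strictly sorted by position within chromosome")
    }
  }
  colnames(geno) <- taxa
  structure(list(sites = sites, geno = geno, taxa = taxa),
            class = "hap_anchor")
}

#' @export
#' @method print hap_anchor
print.hap_anchor <- function(x, ...) {
  cat(sprintf("<hap_anchor> %d sites x %d taxa on %d chromosome(s)\n",
              nrow(x$sites), length(x$taxa), length(unique(x$sites$chrom))))
  invisible(x)
}

#' Identity-by-state distance between two genotype vectors
#'
#' Distance is the mean over comparable sites (both genotypes nonmissing)
#' of \code{1 - shared_alleles/2}: 0 for identical genotypes, 0.5 for a
#' heterozygote against a homozygote sharing one allele, 1 for opposite
#' homozygotes.
#'
#' @param gi,gj integer genotype-code vectors over the same sites
#' @param min_comparable minimum comparable sites for the distance to be
#'   defined (default 200)
#' @return distance in [0, 1], or NA when too few sites are comparable
#' @export
ibs_distance <- function(gi, gj, min_comparable = 200) {
  if (length(gi) != length(gj)) stop("genotype vectors differ in length")
  ok <- !is.na(gi) & !is.na(gj)
  if (sum(ok) < min_comparable) return(NA_real_)
  mean(.geno_dist[cbind(gi[ok], gj[ok])])
}

# window index ranges over anchor sites of one chromosome
.anchor_windows_1chrom <- function(n_sites, window_sites) {
  if (n_sites == 0L) return(NULL)
  n_full <- n_sites %/% window_sites
  if (n_full == 0L) {
    return(cbind(start = 1L, end = n_sites))
  }
  starts <- (seq_len(n_full) - 1L) * window_sites + 1L
  ends <- starts + window_sites - 1L
  ends[n_full] <- n_sites           # merge trailing remainder into last window
  cbind(start = starts, end = ends)
}

#' Find IBD taxon pairs in anchor windows
#'
#' @param anchor a [anchor_map()]
#' @param window_sites anchor sites per window (default 2000)
#' @param threshold IBS distance at or below which a pair is IBD
#'   (default 0.02)
#' @param min_comparable minimum comparable sites per pair (default 200)
#' @return object of class \code{hap_ibd}: \code{windows} (data.frame chrom,
#'   start_pos, end_pos, index range) and \code{pairs} (list, per window, of
#'   a data.frame taxon_a, taxon_b, distance with taxa as column indices)
#' @export
find_ibd_pairs <- function(anchor, window_sites = 2000, threshold = 0.02,
                           min_comparable = 200) {
  stopifnot(inherits(anchor, "hap_anchor"))
  nt <- length(anchor$taxa)
  win_rows <- list(); pair_list <- list(); w <- 0L
  for (ch in unique(anchor$sites$chrom)) {
    idx <- which(anchor$sites$chrom == ch)
    wins <- .anchor_windows_1chrom(length(idx), window_sites)
    for (r in seq_len(nrow(wins))) {
      w <- w + 1L
      rows <- idx[wins[r, "start"]:wins[r, "end"]]
      g <- anchor$geno[rows, , drop = FALSE]
      # accumulate pairwise distances via the padded lookup
      gm <- g; gm[is.na(gm)] <- 22L
      ii <- rep(seq_len(nt), times = nt)
      jj <- rep(seq_len(nt), each = nt)
      v <- .geno_dist_pad[cbind(as.vector(gm[, ii]), as.vector(gm[, jj]))]
      v <- matrix(v, nrow = nrow(g))
      cmp <- colSums(!is.na(v))
      d <- colSums(v, na.rm = TRUE) / pmax(cmp, 1L)
      dmat <- matrix(d, nt, nt)
      cmat <- matrix(cmp, nt, nt)
      sel <- which(upper.tri(dmat) & cmat >= min_comparable &
                     dmat <= threshold, arr.ind = TRUE)
      win_rows[[w]] <- data.frame(
        chrom = ch,
        start_pos = anchor$sites$pos[rows[1]],
        end_pos = anchor$sites$pos[rows[length(rows)]],
        first_site = rows[1], last_site = rows[length(rows)],
        stringsAsFactors = FALSE)
      pair_list[[w]] <- data.frame(taxon_a = sel[, 1], taxon_b = sel[, 2],
                                   distance = dmat[sel])
    }
  }
  structure(list(windows = do.call(rbind, win_rows), pairs = pair_list,
                 taxa = anchor$taxa),
            class = "hap_ibd")
}

#' @export
#' @method print hap_ibd
print.hap_ibd <- function(x, ...) {
  cat(sprintf("<hap_ibd> %d windows; IBD pairs per window: %s\n",
              nrow(x$windows),
              paste(vapply(x$pairs, nrow, 0L), collapse = ", ")))
  invisible(x)
}

#' Window containing a genomic position
#'
#' Positions outside the anchored span of a chromosome map to the first or
#' last window of that chromosome; a chromosome absent from the anchor map
#' yields NA.
#'
#' @param ibd a [find_ibd_pairs()] result
#' @param chrom,pos coordinates
#' @return window index (row of \code{ibd$windows}) or NA
#' @export
ibd_window_of <- function(ibd, chrom, pos) {
  rows <- which(ibd$windows$chrom == chrom)
  if (length(rows) == 0) return(NA_integer_)
  w <- rows[pos >= ibd$windows$start_pos[rows] &
              pos <= ibd$windows$end_pos[rows]]
  if (length(w)) return(w[1])
  if (pos < ibd$windows$start_pos[rows[1]]) rows[1] else rows[length(rows)]
}

#' Apply the IBD filter to one site
#'
#' Over all IBD pairs of the site's window with both genotypes nonmissing:
#' for each allele, a pair where both genotypes carry the allele identically
#' counts as a match, a pair where exactly one genotype carries it counts as
#' a mismatch (a heterozygote carries each of its two alleles). The site is
#' confirmed when at least two alleles reach a match/mismatch ratio of 2
#' (infinite ratio when mismatch = 0 and match > 0); failing that it passes
#' weakly, flagged IBD1, when at most one allele appears among the IBD
#' contrast genotypes; otherwise it fails.
#'
#' @param geno integer genotype codes of all taxa at the site
#' @param ibd a [find_ibd_pairs()] result
#' @param chrom,pos site coordinates (select the window)
#' @param min_ratio confirmation ratio (default 2)
#' @param min_alleles alleles that must reach the ratio (default 2)
#' @return list with \code{status} one of "confirmed", "ibd1", "fail" (or
#'   "no_window" when the chromosome has no anchor window), \code{match} and
#'   \code{mismatch} per-allele counts
#' @export
ibd_filter <- function(geno, ibd, chrom, pos, min_ratio = 2,
                       min_alleles = 2) {
  w <- ibd_window_of(ibd, chrom, pos)
  if (is.na(w)) {
    return(list(status = "no_window", match = rep(0L, 6),
                mismatch = rep(0L, 6)))
  }
  pr <- ibd$pairs[[w]]
  match <- mismatch <- rep(0L, 6)
  seen <- rep(FALSE, 6)
  if (nrow(pr)) {
    ga <- geno[pr$taxon_a]; gb <- geno[pr$taxon_b]
    ok <- !is.na(ga) & !is.na(gb)
    ga <- ga[ok]; gb <- gb[ok]
    if (length(ga)) {
      ca <- .geno_counts[ga, , drop = FALSE] > 0L   # pairs x 6 carrier flags
      cb <- .geno_counts[gb, , drop = FALSE] > 0L
      match <- as.integer(colSums(ca & cb))
      mismatch <- as.integer(colSums(xor(ca, cb)))
      seen <- colSums(ca | cb) > 0L
    }
  }
  conf <- sum(match > 0L & match >= min_ratio * mismatch)
  status <- if (conf >= min_alleles) {
    "confirmed"
  } else if (sum(seen) <= 1L) {
    "ibd1"
  } else {
    "fail"
  }
  list(status = status, match = match, mismatch = mismatch)
}
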