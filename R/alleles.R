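#' @title The six-allele space and genotype codes
#' @description Internal constants shared by every pipeline stage. All
#'   insertions are collapsed to the single symbol "I" and all deletions to
#'   "D", regardless of indel length or sequence, so each site lives in the
#'   fixed, ordered allele space A, C, G, T, I, D. Diploid genotypes are
#'   unordered allele pairs and are stored as integer codes 1..21 indexing
#'   the pairs (1,1),(1,2),...,(1,6),(2,2),...,(6,6); NA means missing.
#' @name allele-space
#' @keywords internal
#' @importFrom utils head
NULL

#' Ordered allele symbols used throughout the pipeline
#' @export
HAP_ALLELES <- c("A", "C", "G", "T", "I", "D")

.geno_pairs <- local({
  p <- matrix(0L, nrow = 21L, ncol = 2L)
  k <- 0L
  for (i in 1:6) for (j in i:6) {
    k <- k + 1L
    p[k, ] <- c(i, j)
  }
  colnames(p) <- c("a1", "a2")
  p
})

.geno_code_lut <- local({
  m <- matrix(NA_integer_, 6, 6)
  for (k in 1:21) {
    m[.geno_pairs[k, 1], .geno_pairs[k, 2]] <- k
    m[.geno_pairs[k, 2], .geno_pairs[k, 1]] <- k
  }
  m
})

# allele multiplicity per genotype code: 21 x 6 matrix of 0/1/2
.geno_counts <- local({
  m <- matrix(0L, 21, 6)
  for (k in 1:21) {
    m[k, .geno_pairs[k, 1]] <- m[k, .geno_pairs[k, 1]] + 1L
    m[k, .geno_pairs[k, 2]] <- m[k, .geno_pairs[k, 2]] + 1L
  }
  colnames(m) <- HAP_ALLELES
  m
})

.geno_is_het <- .geno_pairs[, 1] != .geno_pairs[, 2]

# shared-allele count between genotype codes (IBS): sum over alleles of
# min(multiplicity), in {0,1,2}
.geno_shared <- local({
  s <- matrix(0L, 21, 21)
  for (i in 1:21) for (j in 1:21) {
    s[i, j] <- sum(pmin(.geno_counts[i, ], .geno_counts[j, ]))
  }
  s
})

# IBS mismatch distance between genotype codes: 0 identical, 0.5 het vs hom
# sharing one allele, 1 opposite homozygotes
.geno_dist <- 1 - .geno_shared / 2

# distance lookup padded with a 22nd "missing" state mapping to NA, so that
# vectorised pairwise lookups can index missing genotypes directly
.geno_dist_pad <- local({
  m <- rbind(cbind(.geno_dist, NA_real_), NA_real_)
  m
})

#' Genotype code for an unordered allele pair
#'
#' @param a1,a2 integer allele indices in 1..6 (order irrelevant)
#' @return integer code in 1..21
#' @export
geno_code <- function(a1, a2) {
  stopifnot(all(a1 %in% 1:6), all(a2 %in% 1:6))
  .geno_code_lut[cbind(a1, a2)]
}

#' Allele indices of a genotype code
#'
#' @param code integer genotype code(s) in 1..21 (NA allowed)
#' @return two-column integer matrix (a1 <= a2)
#' @export
geno_alleles <- function(code) {
  out <- matrix(NA_integer_, length(code), 2L)
  ok <- !is.na(code)
  out[ok, ] <- .geno_pairs[code[ok], , drop = FALSE]
  colnames(out) <- c("a1", "a2")
  out
}

#' Does a genotype code carry a given allele?
#'
#' @param code genotype code(s); NA gives NA
#' @param allele allele index in 1..6
#' @return logical vector
#' @export
geno_carries <- function(code, allele) {
  out <- rep(NA, length(code))
  ok <- !is.na(code)
  out[ok] <- .geno_counts[code[ok], allele] > 0L
  out
}

#' Is a genotype code heterozygous?
#' @param code genotype code(s); NA gives NA
#' @return logical vector
#' @export
geno_is_het <- function(code) {
  out <- rep(NA, length(code))
  ok <- !is.na(code)
  out[ok] <- .geno_is_het[code[ok]]
  out
}

#' Human-readable genotype labels ("A/C" style)
#' @param code genotype code(s)
#' @return character vector, NA for missing
#' @export
geno_label <- function(code) {
  out <- rep(NA_character_, length(code))
  ok <- !is.na(code)
  out[ok] <- paste(HAP_ALLELES[.geno_pairs[code[ok], 1]],
                   HAP_ALLELES[.geno_pairs[code[ok], 2]], sep = "/")
  out
}
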