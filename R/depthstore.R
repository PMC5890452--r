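#' Per-taxon allelic depth matrices and on-disk stores
#'
#' An allelic depth matrix holds, for one chromosome, the read depth and the
#' mean base quality of each of the six alleles (A, C, G, T, I, D) for every
#' covered site and taxon. On disk it is split into one store file per taxon
#' per chromosome; within a file only sites with non-zero total coverage for
#' that taxon are kept, and every depth and quality goes through the
#' one-byte codec (see [encode_count()]).
#'
#' @name depthstore
NULL

#' Construct an allelic depth matrix
#'
#' @param chrom chromosome identifier (single string)
#' @param positions sorted, strictly increasing 1-based coordinates
#' @param taxa character vector of taxon names
#' @param depth numeric array \code{sites x taxa x 6} of read depths
#' @param qual numeric array \code{sites x taxa x 6} of mean phred base
#'   qualities (0 where no reads)
#' @param ref optional integer vector of reference allele indices (1..4)
#'   per site; NA when unknown
#' @return object of class \code{hap_depths}
#' @export
depth_matrix <- function(chrom, positions, taxa, depth, qual, ref = NULL) {
  positions <- as.integer(positions)
  if (is.unsorted(positions, strictly = TRUE)) {
    stop("positions must be strictly increasing within a chromosome")
  }
  dm <- c(length(positions), length(taxa), 6L)
  stopifnot(identical(dim(depth), dm), identical(dim(qual), dm))
  if (is.null(ref)) ref <- rep(NA_integer_, length(positions))
  stopifnot(length(ref) == length(positions))
  structure(list(chrom = as.character(chrom), positions = positions,
                 taxa = as.character(taxa),
                 depth = depth, qual = qual, ref = as.integer(ref)),
            class = "hap_depths")
}

#' @export
#' @method print hap_depths
print.hap_depths <- function(x, ...) {
  cat(sprintf("<hap_depths> chrom %s: %d sites x %d taxa (6-allele space)\n",
              x$chrom, length(x$positions), length(x$taxa)))
  invisible(x)
}

.store_magic <- charToRaw("HFDS")

.store_path <- function(dir, taxon, chrom) {
  file.path(dir, paste0(taxon, "_", chrom, ".hds"))
}

#' Save an allelic depth matrix as per-taxon depth stores
#'
#' Writes one binary store file per taxon (for the matrix's chromosome) under
#' \code{dir}. Each file holds the covered positions and the byte-coded
#' \code{sites x 6} depth and quality arrays; sites with zero total depth for
#' the taxon are dropped.
#'
#' @param m a [depth_matrix()] object
#' @param dir output directory (created if needed)
#' @return invisibly, the paths written
#' @export
save_depth_store <- function(m, dir) {
  stopifnot(inherits(m, "hap_depths"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character(0)
  for (t in seq_along(m$taxa)) {
    dep <- matrix(m$depth[, t, ], ncol = 6L)
    qua <- matrix(m$qual[, t, ], ncol = 6L)
    keep <- rowSums(dep) > 0
    dep <- dep[keep, , drop = FALSE]
    qua <- qua[keep, , drop = FALSE]
    pos <- m$positions[keep]
    path <- .store_path(dir, m$taxa[t], m$chrom)
    con <- file(path, "wb")
    on.exit(close(con), add = TRUE)
    writeBin(.store_magic, con)
    writeBin(1L, con, size = 4, endian = "little")          # version
    for (s in c(m$chrom, m$taxa[t])) {
      writeBin(nchar(s, type = "bytes"), con, size = 4, endian = "little")
      writeBin(charToRaw(s), con)
    }
    writeBin(length(pos), con, size = 4, endian = "little")
    writeBin(pos, con, size = 4, endian = "little")
    ref <- m$ref[keep]
    ref[is.na(ref)] <- 0L
    writeBin(as.raw(ref), con)
    # one byte per code: 0..182 as-is, negative codes in two's complement
    # (-1 -> 255 ... -73 -> 183), filling the byte range exactly
    writeBin(as.raw(encode_count(as.vector(dep)) %% 256L), con)
    writeBin(as.raw(encode_count(as.vector(qua)) %% 256L), con)
    close(con)
    on.exit()
    paths <- c(paths, path)
  }
  invisible(paths)
}

.read_store_file <- function(path) {
  if (!file.exists(path)) stop("depth store not found: ", path)
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readBin(con, "raw", 4)
  if (!identical(magic, .store_magic)) {
    stop("corrupt depth store (bad magic): ", path)
  }
  version <- readBin(con, "integer", 1, size = 4, endian = "little")
  if (!identical(version, 1L)) stop("unsupported depth store version: ", path)
  rd_str <- function() {
    n <- readBin(con, "integer", 1, size = 4, endian = "little")
    rawToChar(readBin(con, "raw", n))
  }
  chrom <- rd_str()
  taxon <- rd_str()
  n <- readBin(con, "integer", 1, size = 4, endian = "little")
  pos <- readBin(con, "integer", n, size = 4, endian = "little")
  ref <- as.integer(readBin(con, "raw", n))
  ref[ref == 0L] <- NA_integer_
  rd_codes <- function() {
    b <- as.integer(readBin(con, "raw", n * 6L))
    decode_count(ifelse(b > 182L, b - 256L, b))
  }
  dep <- rd_codes()
  qua <- rd_codes()
  list(chrom = chrom, taxon = taxon, positions = pos, ref = ref,
       depth = matrix(dep, ncol = 6L), qual = matrix(qua, ncol = 6L))
}

#' Load per-taxon depth stores back into an allelic depth matrix
#'
#' @param dir directory holding \code{.hds} store files
#' @param chrom optional chromosome to restrict to (required when the
#'   directory holds stores for several chromosomes)
#' @param taxa optional taxon names (default: every store found)
#' @return a [depth_matrix()] over the union of covered positions
#' @export
load_depth_store <- function(dir, chrom = NULL, taxa = NULL) {
  files <- list.files(dir, pattern = "\\.hds$", full.names = TRUE)
  if (length(files) == 0) stop("no depth store files under: ", dir)
  parts <- lapply(files, .read_store_file)
  chroms <- vapply(parts, `[[`, "", "chrom")
  if (is.null(chrom)) {
    if (length(unique(chroms)) > 1L) {
      stop("stores for several chromosomes present; pass chrom=")
    }
    chrom <- chroms[1]
  }
  parts <- parts[chroms == chrom]
  if (length(parts) == 0) stop("no stores for chromosome ", chrom)
  names(parts) <- vapply(parts, `[[`, "", "taxon")
  if (!is.null(taxa)) {
    miss <- setdiff(taxa, names(parts))
    if (length(miss)) stop("missing stores for taxa: ",
                           paste(miss, collapse = ", "))
    parts <- parts[taxa]
  }
  all_pos <- sort(unique(unlist(lapply(parts, `[[`, "positions"))))
  nt <- length(parts)
  dep <- array(0, dim = c(length(all_pos), nt, 6L))
  qua <- array(0, dim = c(length(all_pos), nt, 6L))
  ref <- rep(NA_integer_, length(all_pos))
  for (t in seq_len(nt)) {
    idx <- match(parts[[t]]$positions, all_pos)
    dep[idx, t, ] <- parts[[t]]$depth
    qua[idx, t, ] <- parts[[t]]$qual
    ref[idx] <- ifelse(is.na(ref[idx]), parts[[t]]$ref, ref[idx])
  }
  depth_matrix(chrom, all_pos, names(parts), dep, qua, ref = ref)
}

#' Load every chromosome's depth stores from a directory
#'
#' @param dir directory holding \code{.hds} store files for one or more
#'   chromosomes
#' @return named list of [depth_matrix()] objects, one per chromosome
#' @export
load_depth_store_all <- function(dir) {
  files <- list.files(dir, pattern = "\\.hds$", full.names = TRUE)
  if (length(files) == 0) stop("no depth store files under: ", dir)
  chroms <- unique(vapply(files, function(f) .read_store_file(f)$chrom, ""))
  stats::setNames(lapply(chroms, function(ch) {
    load_depth_store(dir, chrom = ch)
  }), chroms)
}

#' Extract six-allele depths from samtools mpileup text
#'
#' Parses single-sample pileup text for one taxon and one chromosome into an
#' allelic depth matrix. Insertions (\code{+n...}) and deletions
#' (\code{-n...}) are collapsed to the I and D alleles; the quality assigned
#' to an indel is the quality of the read base directly preceding it. Bases
#' with quality below \code{baseq_min} are not counted (mapping-quality
#' filtering is assumed to have been applied upstream, e.g. via
#' \code{samtools mpileup -q}). Supported pileup features: match/mismatch,
#' read start \code{^} / end \code{$}, indels, the deleted-base placeholder
#' \code{*} (consumes a quality, counts toward no allele) and \code{N}
#' (skipped). Reference skips (\code{<}, \code{>}) and any other character
#' raise an error rather than miscounting.
#'
#' @param lines character vector of pileup lines, or a path to a pileup file
#'   (optionally gzip-compressed) when \code{is_path = TRUE}
#' @param taxon taxon name to record
#' @param baseq_min minimum phred base quality for a base to count
#'   (default 10)
#' @param is_path treat \code{lines} as a file path
#' @return a [depth_matrix()] with one column (taxon)
#' @export
depths_from_pileup <- function(lines, taxon = "taxon1", baseq_min = 10,
                               is_path = FALSE) {
  if (is_path) {
    con <- if (grepl("\\.gz$", lines)) gzfile(lines, "rt") else file(lines, "rt")
    on.exit(close(con))
    lines <- readLines(con)
  }
  lines <- lines[nzchar(lines)]
  n <- length(lines)
  chroms <- character(n); pos <- integer(n)
  dep <- matrix(0, n, 6L); qsum <- matrix(0, n, 6L)
  for (li in seq_len(n)) {
    f <- strsplit(lines[li], "\t", fixed = TRUE)[[1]]
    if (length(f) < 6L) {
      stop(sprintf("malformed pileup line %d: expected >= 6 fields", li))
    }
    chroms[li] <- f[1]
    pos[li] <- suppressWarnings(as.integer(f[2]))
    if (is.na(pos[li])) stop(sprintf("malformed pileup line %d: bad position", li))
    ref <- toupper(f[3])
    ref_idx <- match(ref, HAP_ALLELES[1:4])
    bases <- strsplit(f[5], "")[[1]]
    quals <- utf8ToInt(f[6]) - 33L
    i <- 1L; qi <- 0L
    last_qual <- NA_integer_
    while (i <= length(bases)) {
      ch <- bases[i]
      if (ch == "^") {
        i <- i + 2L
      } else if (ch == "$") {
        i <- i + 1L
      } else if (ch %in% c("+", "-")) {
        j <- i + 1L
        while (j <= length(bases) && grepl("[0-9]", bases[j])) j <- j + 1L
        len <- as.integer(paste(bases[(i + 1L):(j - 1L)], collapse = ""))
        if (is.na(len)) {
          stop(sprintf("malformed pileup line %d: bad indel length", li))
        }
        a <- if (ch == "+") 5L else 6L     # I or D
        if (is.na(last_qual)) {
          stop(sprintf("malformed pileup line %d: indel with no preceding base",
                       li))
        }
        if (last_qual >= baseq_min) {
          dep[li, a] <- dep[li, a] + 1
          qsum[li, a] <- qsum[li, a] + last_qual
        }
        i <- j + len
      } else {
        qi <- qi + 1L
        if (qi > length(quals)) {
          stop(sprintf("malformed pileup line %d: quality string too short", li))
        }
        q <- quals[qi]
        last_qual <- q
        if (ch %in% c(".", ",")) {
          if (is.na(ref_idx)) {
            stop(sprintf("pileup line %d: reference match with non-ACGT ref", li))
          }
          if (q >= baseq_min) {
            dep[li, ref_idx] <- dep[li, ref_idx] + 1
            qsum[li, ref_idx] <- qsum[li, ref_idx] + q
          }
        } else if (toupper(ch) %in% HAP_ALLELES[1:4]) {
          a <- match(toupper(ch), HAP_ALLELES[1:4])
          if (q >= baseq_min) {
            dep[li, a] <- dep[li, a] + 1
            qsum[li, a] <- qsum[li, a] + q
          }
        } else if (toupper(ch) == "N" || ch == "*") {
          # consumes a quality, counts toward no allele
        } else {
          stop(sprintf("pileup line %d: unsupported pileup character '%s'",
                       li, ch))
        }
        i <- i + 1L
      }
    }
  }
  if (length(unique(chroms)) > 1L) {
    stop("pileup spans several chromosomes; split input per chromosome")
  }
  ord <- order(pos)
  if (anyDuplicated(pos)) stop("duplicated positions in pileup input")
  qmean <- matrix(0, n, 6L)
  nz <- dep > 0
  qmean[nz] <- round(qsum[nz] / dep[nz])
  refs <- match(toupper(vapply(strsplit(lines, "\t", fixed = TRUE),
                               `[[`, "", 3L)), HAP_ALLELES[1:4])
  depth_matrix(chroms[1], pos[ord], taxon,
               array(dep[ord, , drop = FALSE], c(n, 1L, 6L)),
               array(qmean[ord, , drop = FALSE], c(n, 1L, 6L)),
               ref = refs[ord])
}
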