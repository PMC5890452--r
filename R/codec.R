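#' One-byte depth/quality codec
#'
#' Allelic depths and mean base qualities are persisted one byte per value.
#' Integers 0..182 are represented exactly by the non-negative codes 0..182.
#' The 73 negative codes -1..-73 form a geometric grid: code -k stands for
#' \code{round(183 * b^k)} with \code{b = (10000/183)^(1/73)} (about 1.0563),
#' so counts up to 10000 are stored with at most ~3\% relative error; larger
#' counts saturate at the top grid point (10000). Encoding maps a count to
#' the nearest representable value (ties toward the smaller code), which
#' makes the decode(encode(x)) round-trip error minimal and the encoder
#' monotone non-decreasing.
#'
#' @name depth-codec
NULL

.codec <- local({
  n_neg <- 73L
  max_exact <- 182L
  max_depth <- 10000L
  b <- (max_depth / (max_exact + 1))^(1 / n_neg)
  grid <- as.integer(round((max_exact + 1) * b^(1:n_neg)))
  # all representable values in increasing order; index i maps to code
  # codes_in_order[i]
  values <- c(0:max_exact, grid)
  codes <- c(0:max_exact, -(1:n_neg))
  # decode lookup by code: index = code+1 for >=0, 183 + k for -k
  list(n_neg = n_neg, max_exact = max_exact, max_depth = max_depth,
       b = b, grid = grid, values = values, codes = codes)
})

#' Encode a non-negative count as a one-byte code
#'
#' @param x integer vector of counts, all >= 0
#' @return integer vector of byte codes in [-73, 182]
#' @seealso [decode_count()]
#' @examples
#' encode_count(c(0, 182, 183, 10000))
#' @export
encode_count <- function(x) {
  if (any(is.na(x)) || any(x < 0)) {
    stop("encode_count: counts must be non-negative and non-missing")
  }
  x <- as.numeric(x)
  out <- integer(length(x))
  exact <- x <= .codec$max_exact
  out[exact] <- as.integer(x[exact])
  if (any(!exact)) {
    xx <- pmin(x[!exact], .codec$max_depth)
    # nearest representable value among {182} U grid; ties -> smaller code
    vals <- c(.codec$max_exact, .codec$grid)
    idx <- findInterval(xx, vals)            # vals[idx] <= xx < vals[idx+1]
    lo <- vals[idx]
    hi <- vals[pmin(idx + 1L, length(vals))]
    pick_hi <- (xx - lo) > (hi - xx)          # strict: ties go to lower value
    j <- idx + as.integer(pick_hi)            # index into vals
    code <- ifelse(j == 1L, .codec$max_exact, -(j - 1L))
    out[!exact] <- as.integer(code)
  }
  out
}

#' Decode a one-byte code back to a count
#'
#' Exact inverse of [encode_count()] on 0..182; negative codes decode to
#' their geometric grid value.
#'
#' @param code integer vector of codes in [-73, 182]
#' @return integer vector of counts
#' @examples
#' decode_count(encode_count(5000))
#' @export
decode_count <- function(code) {
  if (any(is.na(code)) || any(code < -.codec$n_neg) ||
      any(code > .codec$max_exact)) {
    stop("decode_count: codes must lie in [-73, 182]")
  }
  out <- integer(length(code))
  neg <- code < 0L
  out[!neg] <- as.integer(code[!neg])
  out[neg] <- .codec$grid[-code[neg]]
  out
}

#' Codec parameters
#'
#' @return list with the exact range limit, number of negative codes, the
#'   geometric base, the grid of negative-code values and the saturation
#'   depth
#' @export
codec_info <- function() {
  list(max_exact = .codec$max_exact, n_negative = .codec$n_neg,
       base = .codec$b, grid = .codec$grid, max_depth = .codec$max_depth)
}
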