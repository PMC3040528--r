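# Row-key codec: order-preserving, fixed-width encoding of (contig_index,
# position). Lexicographic byte order of encoded keys must equal numeric
# order of the tuples, so range scans over the flat store are genomic scans.

ROW_KEY_BYTES <- 12L   # 4 bytes contig index + 8 bytes position, big-endian
ROW_KEY_HEX <- 24L

# Positions are held in doubles; beyond 2^53 a double can no longer represent
# every integer exactly, so that is the hard upper bound here.
MAX_POSITION <- 2^53

#' Encode a genomic locus as a fixed-width, order-preserving row key
#'
#' The row key is 12 bytes: a 4-byte big-endian contig index followed by an
#' 8-byte big-endian position. Sorting keys bytewise is identical to sorting
#' `(contig_index, position)` numerically, which is what makes range scans
#' over the flat store equivalent to genomic-order traversal.
#'
#' @param contig_index Dense integer index of the contig in the store's
#'   contig dictionary (0-based, `< 2^31`).
#' @param position 0-based base offset on the contig (`0 <= position < 2^53`;
#'   positions are carried in doubles, which are exact up to 2^53).
#' @return A `raw` vector of 12 bytes.
#' @seealso [decode_row_key()]
#' @export
encode_row_key <- function(contig_index, position) {
  check_row_key_parts(contig_index, position)
  hex_to_raw(row_key_hex(contig_index, position))
}

#' Decode a row key back to (contig_index, position)
#'
#' Inverse of [encode_row_key()].
#'
#' @param key A raw vector of exactly 12 bytes (or a 24-character lowercase
#'   hex string).
#' @return A list with elements `contig_index` and `position`.
#' @export
decode_row_key <- function(key) {
  hex <- if (is.raw(key)) {
    if (length(key) != ROW_KEY_BYTES) {
      stop("row key must be exactly ", ROW_KEY_BYTES, " bytes, got ",
           length(key), call. = FALSE)
    }
    raw_to_hex(key)
  } else if (is.character(key) && length(key) == 1L && nchar(key) == ROW_KEY_HEX) {
    key
  } else {
    stop("row key must be a 12-byte raw vector or 24-char hex string",
         call. = FALSE)
  }
  list(contig_index = strtoi(substr(hex, 1L, 8L), 16L),
       position = hex_to_pos(substr(hex, 9L, 24L)))
}

check_row_key_parts <- function(contig_index, position) {
  if (any(is.na(contig_index)) || any(contig_index < 0) ||
      any(contig_index >= 2^31)) {
    stop("contig_index out of range [0, 2^31)", call. = FALSE)
  }
  if (any(is.na(position)) || any(position < 0) || any(position >= MAX_POSITION) ||
      any(position != floor(position))) {
    stop("position out of range [0, 2^53) or not an integer", call. = FALSE)
  }
  invisible(TRUE)
}

# Vectorised hex form of the row key; the store works in hex internally
# (lowercase hex sorts bytewise under radix sort, same order as the raw keys).
row_key_hex <- function(contig_index, position) {
  hi <- position %/% 2^32
  lo <- position %% 2^32
  sprintf("%08x%04x%04x%04x%04x",
          as.integer(contig_index),
          as.integer(hi %/% 65536), as.integer(hi %% 65536),
          as.integer(lo %/% 65536), as.integer(lo %% 65536))
}

hex_to_pos <- function(hex16) {
  strtoi(substr(hex16, 1L, 4L), 16L) * 2^48 +
    strtoi(substr(hex16, 5L, 8L), 16L) * 2^32 +
    strtoi(substr(hex16, 9L, 12L), 16L) * 2^16 +
    strtoi(substr(hex16, 13L, 16L), 16L)
}

hex_to_raw <- function(hex) {
  n <- nchar(hex)
  as.raw(strtoi(substring(hex, seq(1L, n, 2L), seq(2L, n, 2L)), 16L))
}

raw_to_hex <- function(r) paste(sprintf("%02x", as.integer(r)), collapse = "")
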