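# Generic object persistence over the cell store ("generic methods to read
# and write the full range of data types"): importers and exporters go
# through these, never through put_cell directly, so a different backend
# could be swapped in behind the same surface.

next_version <- function(store, row_hex, family, label) {
  cells <- get_cells(store, "primary", row_hex, family, label = label)
  if (length(cells) == 0L) return(1L)
  max(vapply(cells, `[[`, 0L, "version")) + 1L
}

#' Write a variant to the store and tag-index it
#'
#' Writes the serialised variant into the `variant` family at its locus row
#' and adds one secondary-index entry per tag. With `auto_version = TRUE`
#' (the default) the version is assigned as one more than the highest
#' version already stored at `(locus, genome)` — load-order numbering
#' starting at 1.
#'
#' @param store A `qe_store`.
#' @param v A [variant()].
#' @param auto_version Assign the next free version at the locus.
#' @return The variant with its final version, invisibly.
#' @export
write_variant <- function(store, v, auto_version = TRUE) {
  ci <- contig_index(store, v$contig, register = TRUE)
  rk <- row_key_hex(ci, v$position)
  if (auto_version) v$version <- next_version(store, rk, "variant", v$genome_label)
  put_cell(store, cell_address("primary", rk, "variant", v$genome_label,
                               v$version),
           encode_variant(v))
  index_object(store, v$tags, variant_id(v), "primary", rk, v$genome_label)
  invisible(v)
}

#' Write a feature to the store and tag-index it
#' @inheritParams write_variant
#' @param ft A [feature()].
#' @return The feature with its final version, invisibly.
#' @export
write_feature <- function(store, ft, auto_version = TRUE) {
  ci <- contig_index(store, ft$contig, register = TRUE)
  rk <- row_key_hex(ci, ft$position)
  if (auto_version) ft$version <- next_version(store, rk, "feature", ft$genome_label)
  put_cell(store, cell_address("primary", rk, "feature", ft$genome_label,
                               ft$version),
           encode_feature(ft))
  index_object(store, ft$tags,
               charToRaw(paste("feature",
                               object_id_string(ft$contig, ft$position,
                                                ft$genome_label, ft$version),
                               sep = "\t")),
               "primary", rk, ft$genome_label)
  invisible(ft)
}

#' Write a coding consequence to the store and tag-index it
#'
#' The consequence's `variant_version` back-reference must resolve to a
#' stored variant at the same locus and genome unless `check_ref = FALSE`.
#'
#' @inheritParams write_variant
#' @param cq A [consequence()].
#' @param check_ref Verify the back-referenced variant exists.
#' @return The consequence with its final version, invisibly.
#' @export
write_consequence <- function(store, cq, check_ref = TRUE, auto_version = TRUE) {
  ci <- contig_index(store, cq$contig, register = TRUE)
  rk <- row_key_hex(ci, cq$position)
  if (check_ref) {
    vcells <- get_cells(store, "primary", rk, "variant", label = cq$genome_label)
    if (!any(vapply(vcells, `[[`, 0L, "version") == cq$variant_version)) {
      stop("consequence back-reference does not resolve: no variant v",
           cq$variant_version, " at ", cq$contig, ":", format_pos(cq$position),
           " in ", cq$genome_label, call. = FALSE)
    }
  }
  if (auto_version) {
    cq$version <- next_version(store, rk, "consequence", cq$genome_label)
  }
  put_cell(store, cell_address("primary", rk, "consequence", cq$genome_label,
                               cq$version),
           encode_consequence(cq))
  index_object(store, cq$tags,
               charToRaw(paste("consequence",
                               object_id_string(cq$contig, cq$position,
                                                cq$genome_label, cq$version),
                               sep = "\t")),
               "primary", rk, cq$genome_label)
  invisible(cq)
}

#' Write a coverage block
#'
#' @inheritParams write_variant
#' @param cb A [coverage_block()].
#' @return The block, invisibly.
#' @export
write_coverage_block <- function(store, cb, auto_version = TRUE) {
  ci <- contig_index(store, cb$contig, register = TRUE)
  rk <- row_key_hex(ci, cb$block_start)
  version <- if (auto_version) next_version(store, rk, "coverage", cb$genome_label) else 1L
  put_cell(store, cell_address("primary", rk, "coverage", cb$genome_label,
                               version),
           encode_coverage(cb))
  invisible(cb)
}

#' Read the variants stored at one locus
#'
#' @param store A `qe_store`.
#' @param contig,position Locus (0-based).
#' @param genome_label Optional genome restriction.
#' @return A list of `qe_variant`, ordered by (label, version).
#' @export
variants_at <- function(store, contig, position, genome_label = NULL) {
  idx <- store$contigs[[contig]]
  if (is.null(idx)) return(list())
  cells <- get_cells(store, "primary", row_key_hex(idx, position), "variant",
                     label = genome_label)
  lapply(cells, function(c) decode_variant(c$value))
}
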