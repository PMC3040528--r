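# Secondary (tag) index: one index table per genome. The index key is the
# tag key plus the object ID, separated by a 0x01 byte so that tag "a"
# can never prefix-collide with tag "ab"; the value locates the row in the
# primary table. This is what lets tag queries avoid walking the whole
# primary table.

index_table_name <- function(genome_label) paste0("idx:", genome_label)

#' Add secondary-index entries for an object's tags
#'
#' Called by the persistence layer after the object itself has been written:
#' one index entry per tag key, keyed `tag || 0x01 || object_id`, in the
#' per-genome index table. The index keys on the tag key only; tag-value
#' filtering happens client-side after lookup.
#'
#' @param store A `qe_store`.
#' @param tags Named character vector of tags (see [variant()]).
#' @param object_id Opaque object ID (raw, from [variant_id()], or string).
#' @param target_table,target_row_key Locator of the object's primary-table
#'   row.
#' @param genome_label Genome whose index table receives the entries.
#' @return Number of entries written, invisibly.
#' @export
index_object <- function(store, tags, object_id, target_table,
                         target_row_key, genome_label) {
  tags <- as_tag_map(tags)
  if (length(tags) == 0L) return(invisible(0L))
  oid <- if (is.raw(object_id)) rawToChar(object_id) else object_id
  tname <- index_table_name(genome_label)
  rhex <- row_key_to_hex(target_row_key)
  for (tg in names(tags)) {
    put_cell(store,
             cell_address(tname, paste0(tg, INDEX_SEP, oid), "index",
                          genome_label),
             paste(target_table, rhex, sep = "\t"))
  }
  invisible(length(tags))
}

#' Look up primary-table rows by tag
#'
#' Prefix scan over the per-genome index table: yields exactly the entries
#' whose tag key equals `tag`, ordered by object ID, without touching the
#' primary table.
#'
#' @param store A `qe_store`.
#' @param tag Tag key to look up.
#' @param genome_label Genome whose index to search.
#' @return A list of entries `list(target_table, target_row_key = <raw>,
#'   object_id = <raw>)`.
#' @export
lookup_by_tag <- function(store, tag, genome_label) {
  assert_open(store)
  assert_genome(store, genome_label)
  if (grepl("[\x01-\x1f]", tag)) {
    stop("tag keys may not contain control bytes", call. = FALSE)
  }
  te <- table_env(store, index_table_name(genome_label))
  if (is.null(te)) return(list())
  keys <- sorted_keys(te)
  prefix <- paste0(tag, INDEX_SEP)
  keys <- keys[startsWith(keys, prefix)]
  out <- vector("list", length(keys))
  kept <- 0L
  for (k in keys) {
    cells <- te$cells[[k]]
    loc <- strsplit(cells[[1L]]$value, "\t", fixed = TRUE)[[1L]]
    rhex <- loc[2]
    # skip (and warn about) dangling entries whose target row vanished
    pe <- table_env(store, loc[1])
    present <- !is.null(pe) &&
      (!is.null(pe$cells[[paste0(rhex, GROUP_SEP, "variant")]]) ||
         !is.null(pe$cells[[paste0(rhex, GROUP_SEP, "feature")]]) ||
         !is.null(pe$cells[[paste0(rhex, GROUP_SEP, "consequence")]]))
    if (!present) {
      warning("dangling tag-index entry skipped for tag '", tag, "'",
              call. = FALSE)
      next
    }
    kept <- kept + 1L
    out[[kept]] <- list(target_table = loc[1],
                        target_row_key = hex_to_raw(rhex),
                        object_id = charToRaw(substr(k, nchar(prefix) + 1L,
                                                     nchar(k))))
  }
  out[seq_len(kept)]
}
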