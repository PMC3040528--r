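# Map-reduce-style traversal over the primary table, and the two analysis
# tools built on it: variant-type counting and tumor/normal somatic
# subtraction. The "framework" is an in-process contract, not a distributed
# runtime: map functions are pure per-row transforms, emissions are grouped
# by key (values kept in emission order), reduced per key, and the result
# is independent of how rows were partitioned.

#' Map-reduce traversal of a table
#'
#' Semantically: scan all rows in genomic order, apply `map_fn` to each,
#' group the emitted (key, value) pairs by key, and apply `reduce_fn` per
#' key. Rows are internally processed in `partitions` contiguous chunks;
#' because grouping happens across partitions and values stay in emission
#' order, the result is the same for any partition count — that invariance
#' is part of the contract and is what makes the traversal trivially
#' parallelisable on a real cluster backend.
#'
#' @param store A `qe_store`.
#' @param map_fn `function(row_key, cells)` returning a list of emissions,
#'   each `list(key = <string>, value = <anything>)` (or an empty list).
#' @param reduce_fn `function(key, values)` reducing the list of values
#'   emitted under one key. Both functions must be pure.
#' @param table Table to traverse (default `"primary"`).
#' @param partitions Number of contiguous row chunks (default 4).
#' @return A named list, one reduced result per key, keys in sorted order.
#' @export
map_reduce <- function(store, map_fn, reduce_fn, table = "primary",
                       partitions = 4L) {
  assert_open(store)
  rows <- scan_range(store, table)
  groups <- new.env(parent = emptyenv())
  key_order <- character(0)
  chunks <- if (length(rows)) {
    size <- ceiling(length(rows) / max(1L, partitions))
    split(seq_along(rows), ceiling(seq_along(rows) / size))
  } else list()
  for (chunk in chunks) {
    for (i in chunk) {
      row <- rows[[i]]
      emissions <- tryCatch(
        map_fn(row$row_key, row$cells),
        error = function(e) {
          d <- decode_row_key(row$row_key)
          stop("map function failed at row (contig ", d$contig_index, ", ",
               "position ", format_pos(d$position), "): ",
               conditionMessage(e), call. = FALSE)
        })
      for (em in emissions) {
        k <- em$key
        cur <- groups[[k]]
        if (is.null(cur)) {
          key_order <- c(key_order, k)
          groups[[k]] <- list(em$value)
        } else {
          cur[[length(cur) + 1L]] <- em$value
          groups[[k]] <- cur
        }
      }
    }
  }
  keys <- sort(key_order, method = "radix")
  out <- vector("list", length(keys))
  names(out) <- keys
  for (k in keys) {
    out[[k]] <- tryCatch(
      reduce_fn(k, groups[[k]]),
      error = function(e) stop("reduce function failed for key '", k, "': ",
                               conditionMessage(e), call. = FALSE))
  }
  out
}

#' Count stored variants by type
#'
#' A map-reduce traversal emitting one count per variant cell of the genome;
#' the counts over all five variant types sum to the total number of stored
#' variants.
#'
#' @param store A `qe_store`.
#' @param genome_label Genome to count.
#' @return Named integer vector over
#'   `r paste(VARIANT_TYPES, collapse = ", ")` (zero where absent).
#' @export
count_variant_types <- function(store, genome_label) {
  assert_open(store)
  assert_genome(store, genome_label)
  res <- map_reduce(
    store,
    map_fn = function(row_key, cells) {
      out <- list()
      for (cell in cells) {
        if (cell$family != "variant" || cell$label != genome_label) next
        v <- decode_variant(cell$value)
        out[[length(out) + 1L]] <- list(key = v$type, value = 1L)
      }
      out
    },
    reduce_fn = function(key, values) sum(unlist(values)))
  counts <- structure(integer(length(VARIANT_TYPES)), names = VARIANT_TYPES)
  for (k in names(res)) counts[[k]] <- as.integer(res[[k]])
  counts
}

#' Quality criteria for somatic calling
#'
#' User-specified map-phase criteria for the somatic detector. Loads are
#' deliberately unfiltered (every allele observed once or more is stored),
#' so any normal-sample evidence for the same allele vetoes a call; the
#' defaults here are explicit stand-ins exposed because "good coverage" has
#' no canonical numeric value.
#'
#' @param min_tumor_observations Minimum reads supporting the tumor allele.
#' @param min_tumor_fraction Minimum `observation_count / depth` in the
#'   tumor.
#' @param min_normal_coverage Minimum normal depth at the locus for the
#'   absence of a normal call to be believable.
#' @param max_p_value Optional upper bound on the tumor call p-value.
#' @return A `qe_somatic_criteria`.
#' @export
somatic_criteria <- function(min_tumor_observations = 4L,
                             min_tumor_fraction = 0.1,
                             min_normal_coverage = 10L,
                             max_p_value = NULL) {
  if (min_tumor_observations < 1) {
    stop("min_tumor_observations must be >= 1", call. = FALSE)
  }
  if (min_tumor_fraction < 0 || min_tumor_fraction > 1) {
    stop("min_tumor_fraction must lie in [0, 1]", call. = FALSE)
  }
  if (min_normal_coverage < 0) {
    stop("min_normal_coverage must be >= 0", call. = FALSE)
  }
  structure(list(min_tumor_observations = as.integer(min_tumor_observations),
                 min_tumor_fraction = min_tumor_fraction,
                 min_normal_coverage = as.integer(min_normal_coverage),
                 max_p_value = max_p_value),
            class = "qe_somatic_criteria")
}

#' Detect putative somatic mutations in a tumor/normal pair
#'
#' Both genomes must be loaded into the same table, so that identical
#' variants sit in the same row and the subtraction is a per-row operation.
#' Map phase: every tumor variant that passes the quality criteria and has
#' no normal-genome variant of the same type and alleles at the same locus
#' is emitted (any normal observation count >= 1 vetoes). Reduce phase: the
#' normal's per-base coverage at the locus is looked up and the call is
#' `PUTATIVE_SOMATIC` iff that depth reaches `min_normal_coverage` —
#' otherwise the absence of a normal call proves nothing
#' (`REJECTED_LOW_NORMAL_COVERAGE`).
#'
#' @param store A `qe_store`.
#' @param tumor_label,normal_label Genome labels of the pair.
#' @param criteria A [somatic_criteria()].
#' @param report_rejected Also return rejected calls with their rejection
#'   status (`REJECTED_QUALITY`, `REJECTED_PRESENT_IN_NORMAL`,
#'   `REJECTED_LOW_NORMAL_COVERAGE`).
#' @return A list of `qe_somatic_call`
#'   (`list(variant, normal_depth_at_locus, status)`) in genomic order.
#' @export
detect_somatic <- function(store, tumor_label, normal_label,
                           criteria = somatic_criteria(),
                           report_rejected = FALSE) {
  assert_open(store)
  assert_genome(store, tumor_label)
  assert_genome(store, normal_label)
  res <- map_reduce(
    store,
    map_fn = function(row_key, cells) {
      tumor <- list(); normal <- list()
      for (cell in cells) {
        if (cell$family != "variant") next
        if (cell$label == tumor_label) {
          tumor[[length(tumor) + 1L]] <- decode_variant(cell$value)
        } else if (cell$label == normal_label) {
          normal[[length(normal) + 1L]] <- decode_variant(cell$value)
        }
      }
      out <- list()
      for (tv in tumor) {
        status <- NA_character_
        if (tv$observation_count < criteria$min_tumor_observations ||
            (tv$depth > 0 &&
             tv$observation_count / tv$depth < criteria$min_tumor_fraction) ||
            (!is.null(criteria$max_p_value) &&
             (is.na(tv$p_value) || tv$p_value > criteria$max_p_value))) {
          status <- "REJECTED_QUALITY"
        } else {
          for (nv in normal) {
            if (nv$type == tv$type && nv$ref_allele == tv$ref_allele &&
                nv$alt_allele == tv$alt_allele) {
              status <- "REJECTED_PRESENT_IN_NORMAL"
              break
            }
          }
        }
        out[[length(out) + 1L]] <- list(
          key = paste(tv$contig, format_pos(tv$position), tv$version,
                      sep = "\t"),
          value = list(variant = tv, status = status))
      }
      out
    },
    reduce_fn = function(key, values) values[[1L]])
  calls <- list()
  for (item in res) {
    tv <- item$variant
    ndepth <- normal_depth_at(store, normal_label, tv$contig, tv$position)
    status <- item$status
    if (is.na(status)) {
      status <- if (ndepth >= criteria$min_normal_coverage) "PUTATIVE_SOMATIC"
                else "REJECTED_LOW_NORMAL_COVERAGE"
    }
    if (!report_rejected && status != "PUTATIVE_SOMATIC") next
    calls[[length(calls) + 1L]] <-
      structure(list(variant = tv, normal_depth_at_locus = ndepth,
                     status = status),
                class = "qe_somatic_call")
  }
  vs <- lapply(calls, `[[`, "variant")
  o <- order(match(vapply(vs, `[[`, "", "contig"), store$contig_names),
             vapply(vs, `[[`, 0, "position"),
             vapply(vs, `[[`, 0L, "version"))
  calls[o]
}

normal_depth_at <- function(store, normal_label, contig, position) {
  ci <- store$contigs[[contig]]
  if (is.null(ci)) return(0L)
  bs <- store$block_size
  bstart <- (position %/% bs) * bs
  cells <- get_cells(store, "primary", row_key_hex(ci, bstart), "coverage",
                     label = normal_label)
  if (length(cells) == 0L) return(0L)
  best <- cells[[length(cells)]]   # cells ordered by version; take highest
  cb <- decode_coverage(best$value)
  hit <- match(position - bstart, cb$offsets)
  if (is.na(hit)) 0L else cb$depths[hit]
}

#' @export
print.qe_somatic_call <- function(x, ...) {
  v <- x$variant
  cat(sprintf("<somatic call %s %s:%s %s>%s obs=%d/%d normal_depth=%d %s>\n",
              v$type, v$contig, format_pos(v$position),
              if (nzchar(v$ref_allele)) v$ref_allele else "-",
              if (nzchar(v$alt_allele)) v$alt_allele else "-",
              v$observation_count, v$depth, x$normal_depth_at_locus,
              x$status))
  invisible(x)
}
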