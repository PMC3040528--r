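# Embedded byte-ordered key-value store with the column-family cell model:
# one primary table per reference genome build, rows keyed by genomic start
# position, four fixed column families, dynamic per-genome labels, and
# integer cell versions to distinguish co-located values. A flat ordered
# map stands in for a distributed BigTable-style backend: the physical key
# is row-key-hex "/" family, each slot holding the (label, version, value)
# cells of that row/family. Lowercase hex sorts bytewise under radix sort,
# so sorted physical keys are in genomic order.
#
# Single-writer contract: one process opens a store for writing at a time;
# readers see a consistent snapshot once flushed.

GROUP_SEP <- "/"
INDEX_SEP <- "\x01"   # tag index key separator; tags may not contain it

#' Create a new variant store
#'
#' Lays out a store directory for one reference genome build: a config file,
#' a contig dictionary mapping contig names to dense integer indices (the
#' total order that makes row keys sortable), the primary table and one tag
#' index table per genome. Contigs may be declared up front or registered
#' automatically, in order of first appearance, as data is loaded.
#'
#' @param path Directory to create (must not already contain a store).
#' @param reference_name Name of the reference genome build, e.g. `"hg18"`.
#' @param contigs Optional character vector fixing the contig dictionary
#'   order up front.
#' @param block_size Coverage block width in bases (default 1000).
#' @return A `qe_store` handle, open for reading and writing.
#' @export
store_create <- function(path, reference_name, contigs = character(),
                         block_size = 1000L) {
  if (file.exists(file.path(path, "config.json"))) {
    stop("a store already exists at ", path, call. = FALSE)
  }
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(path, "tables"), showWarnings = FALSE)
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$reference_name <- reference_name
  st$block_size <- as.integer(block_size)
  st$contigs <- new.env(parent = emptyenv())   # name -> 0-based index
  st$contig_names <- character(0)
  st$genomes <- new.env(parent = emptyenv())
  st$tables <- new.env(parent = emptyenv())
  st$open <- TRUE
  class(st) <- "qe_store"
  for (ct in contigs) contig_index(st, ct, register = TRUE)
  store_flush(st)
  st
}

#' Open an existing store
#'
#' @param path Store directory created by [store_create()].
#' @return A `qe_store` handle.
#' @export
store_open <- function(path) {
  cfg_path <- file.path(path, "config.json")
  if (!file.exists(cfg_path)) stop("no store at ", path, call. = FALSE)
  cfg <- jsonlite::read_json(cfg_path)
  st <- new.env(parent = emptyenv())
  st$path <- path
  st$reference_name <- cfg$reference_name
  st$block_size <- as.integer(cfg$block_size)
  st$contigs <- new.env(parent = emptyenv())
  st$contig_names <- character(0)
  st$genomes <- new.env(parent = emptyenv())
  st$tables <- new.env(parent = emptyenv())
  st$open <- TRUE
  class(st) <- "qe_store"
  ct_path <- file.path(path, "contigs.tsv")
  if (file.exists(ct_path)) {
    lines <- readLines(ct_path)
    for (ln in lines) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      idx <- as.integer(f[1])
      assign(f[2], idx, envir = st$contigs)
      st$contig_names[idx + 1L] <- f[2]
    }
  }
  for (g in unlist(cfg$genomes)) assign(g, TRUE, envir = st$genomes)
  for (tf in list.files(file.path(path, "tables"), pattern = "\\.tab$")) {
    tname <- table_name_from_file(tf)
    te <- table_env(st, tname, create = TRUE)
    lines <- readLines(file.path(path, "tables", tf))
    if (length(lines)) {
      sep <- regexpr("\x02", lines, fixed = TRUE)
      keys <- substr(lines, 1L, sep - 1L)
      vals <- substr(lines, sep + 1L, nchar(lines))
      for (i in seq_along(lines)) {
        k <- keys[i]
        cell <- decode_stored_cell(vals[i])
        cur <- te$cells[[k]]
        te$cells[[k]] <- if (is.null(cur)) list(cell) else c(cur, list(cell))
      }
      te$dirty <- TRUE
    }
  }
  st
}

#' Flush a store to disk
#'
#' Persists config, contig dictionary and all tables as plain-text files.
#' Values never contain newlines (serialisation escapes them), so each cell
#' is one line.
#'
#' @param store A `qe_store`.
#' @return The store, invisibly.
#' @export
store_flush <- function(store) {
  assert_open(store)
  cfg <- list(format = "varkv-store-1",
              reference_name = store$reference_name,
              block_size = store$block_size,
              genomes = as.list(sort(ls(store$genomes))))
  jsonlite::write_json(cfg, file.path(store$path, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  if (length(store$contig_names)) {
    writeLines(paste(seq_along(store$contig_names) - 1L, store$contig_names,
                     sep = "\t"),
               file.path(store$path, "contigs.tsv"))
  }
  for (tname in ls(store$tables)) {
    te <- store$tables[[tname]]
    keys <- ls(te$cells)
    con <- file(file.path(store$path, "tables", table_file_name(tname)), "w")
    tryCatch({
      for (chunk in split_chunks(keys, 50000L)) {
        lines <- unlist(lapply(chunk, function(k) {
          paste0(k, "\x02", vapply(te$cells[[k]], encode_stored_cell, ""))
        }), use.names = FALSE)
        if (length(lines)) writeLines(lines, con)
      }
    }, finally = close(con))
  }
  invisible(store)
}

#' Close a store, flushing it first
#' @param store A `qe_store`.
#' @export
store_close <- function(store) {
  store_flush(store)
  store$open <- FALSE
  invisible(NULL)
}

#' @export
print.qe_store <- function(x, ...) {
  cat(sprintf("<varkv store %s: reference=%s, %d contig(s), genomes: %s>\n",
              x$path, x$reference_name, length(x$contig_names),
              paste(sort(ls(x$genomes)), collapse = ", ")))
  invisible(x)
}

#' Genomes present in a store
#' @param store A `qe_store`.
#' @return Sorted character vector of genome labels.
#' @export
store_genomes <- function(store) sort(ls(store$genomes))

#' Contig dictionary of a store
#' @param store A `qe_store`.
#' @return Character vector of contig names in dictionary (index) order.
#' @export
store_contigs <- function(store) store$contig_names

assert_open <- function(store) {
  if (!isTRUE(store$open)) stop("store is closed", call. = FALSE)
  invisible(TRUE)
}

assert_genome <- function(store, label) {
  if (!exists(label, envir = store$genomes, inherits = FALSE)) {
    stop("unknown genome label '", label, "'; known: ",
         paste(store_genomes(store), collapse = ", "), call. = FALSE)
  }
  invisible(TRUE)
}

register_genome <- function(store, label) {
  check_label(label)
  assign(label, TRUE, envir = store$genomes)
  invisible(NULL)
}

contig_index <- function(store, contig, register = FALSE) {
  idx <- store$contigs[[contig]]
  if (is.null(idx)) {
    if (!register) {
      stop("unknown contig '", contig, "'", call. = FALSE)
    }
    check_contig(contig)
    idx <- length(store$contig_names)
    assign(contig, idx, envir = store$contigs)
    store$contig_names[idx + 1L] <- contig
  }
  idx
}

# table files: ':' is awkward in filenames, encode it
table_file_name <- function(tname) paste0(gsub(":", "%3a", tname, fixed = TRUE), ".tab")
table_name_from_file <- function(f) gsub("%3a", ":", sub("\\.tab$", "", f), fixed = TRUE)

table_env <- function(store, tname, create = FALSE) {
  te <- store$tables[[tname]]
  if (is.null(te)) {
    if (!create) return(NULL)
    te <- new.env(parent = emptyenv())
    te$cells <- new.env(parent = emptyenv())
    te$dirty <- TRUE
    te$sorted <- character(0)
    assign(tname, te, envir = store$tables)
  }
  te
}

sorted_keys <- function(te) {
  if (te$dirty) {
    te$sorted <- sort(ls(te$cells), method = "radix")
    te$dirty <- FALSE
  }
  te$sorted
}

# one stored cell per line fragment: version \x03 label \x03 value
encode_stored_cell <- function(cell) {
  paste(cell$version, cell$label, cell$value, sep = "\x03")
}

decode_stored_cell <- function(s) {
  p1 <- regexpr("\x03", s, fixed = TRUE)
  rest <- substr(s, p1 + 1L, nchar(s))
  p2 <- regexpr("\x03", rest, fixed = TRUE)
  list(label = substr(rest, 1L, p2 - 1L),
       version = as.integer(substr(s, 1L, p1 - 1L)),
       value = substr(rest, p2 + 1L, nchar(rest)))
}

check_family <- function(table, family) {
  ok <- if (startsWith(table, "idx:")) "index" else PRIMARY_FAMILIES
  if (!family %in% ok) {
    stop("unknown column family '", family, "' for table '", table,
         "'; families are fixed at table creation (", paste(ok, collapse = ", "),
         ")", call. = FALSE)
  }
  invisible(TRUE)
}

#' Address of a single cell in the store
#'
#' @param table Table name: `"primary"` for the main table, or a per-genome
#'   tag index table `"idx:<label>"`.
#' @param row_key Row key as returned by [encode_row_key()] (raw or hex), or,
#'   for index tables, an arbitrary key string.
#' @param family Column family: one of variant, coverage, feature,
#'   consequence for the primary table; index for tag tables.
#' @param label Genome label (column qualifier), e.g. `"genome7"`.
#' @param version Cell version, integer `>= 1`.
#' @return A `qe_cell_address`.
#' @export
cell_address <- function(table, row_key, family, label, version = 1L) {
  check_family(table, family)
  check_label(label)
  if (version < 1) stop("cell version must be >= 1", call. = FALSE)
  structure(list(table = table, row_key = row_key, family = family,
                 label = label, version = as.integer(version)),
            class = "qe_cell_address")
}

row_key_to_hex <- function(row_key) {
  if (is.raw(row_key)) {
    if (length(row_key) != ROW_KEY_BYTES) {
      stop("row key must be ", ROW_KEY_BYTES, " bytes", call. = FALSE)
    }
    raw_to_hex(row_key)
  } else if (is.character(row_key) && length(row_key) == 1L) {
    row_key
  } else {
    stop("row_key must be raw or a hex string", call. = FALSE)
  }
}

#' Write one cell
#'
#' Writes `value` at `(table, row, family, label, version)`. Writing to an
#' existing version replaces its value; distinct versions accumulate, which
#' is how co-located variants in one genome are kept apart.
#'
#' @param store A `qe_store`.
#' @param addr A [cell_address()].
#' @param value Cell value: a single-line string (serialised record).
#' @return The store, invisibly.
#' @export
put_cell <- function(store, addr, value) {
  assert_open(store)
  check_family(addr$table, addr$family)
  te <- table_env(store, addr$table, create = TRUE)
  k <- if (addr$family == "index") addr$row_key else
    paste0(row_key_to_hex(addr$row_key), GROUP_SEP, addr$family)
  cell <- list(label = addr$label, version = as.integer(addr$version),
               value = value)
  cur <- te$cells[[k]]
  if (is.null(cur)) {
    te$cells[[k]] <- list(cell)
    te$dirty <- TRUE
  } else {
    hit <- FALSE
    for (i in seq_along(cur)) {
      if (cur[[i]]$label == cell$label && cur[[i]]$version == cell$version) {
        cur[[i]] <- cell; hit <- TRUE; break
      }
    }
    if (!hit) cur[[length(cur) + 1L]] <- cell
    te$cells[[k]] <- cur
  }
  if (addr$table == "primary") register_genome(store, addr$label)
  invisible(store)
}

#' Read the cells of one row/family
#'
#' @inheritParams put_cell
#' @param table,row_key,family As in [cell_address()].
#' @param label Optional genome label; when given only that genome's cells
#'   are returned.
#' @return A list of cells `list(label, version, value)`, ordered by
#'   `(label, version)`; empty when the row is absent.
#' @export
get_cells <- function(store, table, row_key, family, label = NULL) {
  assert_open(store)
  check_family(table, family)
  te <- table_env(store, table)
  if (is.null(te)) return(list())
  k <- if (family == "index") row_key else
    paste0(row_key_to_hex(row_key), GROUP_SEP, family)
  cells <- te$cells[[k]]
  if (is.null(cells)) return(list())
  if (!is.null(label)) {
    cells <- Filter(function(c) c$label == label, cells)
  }
  if (length(cells) > 1L) {
    o <- order(vapply(cells, `[[`, "", "label"),
               vapply(cells, `[[`, 0L, "version"), method = "radix")
    cells <- cells[o]
  }
  cells
}

#' Range scan over a table in genomic order
#'
#' Yields exactly the rows with `start_key <= row_key < end_key`, each once,
#' in ascending byte (= genomic) order. Both bounds may be `NULL` for an
#' unbounded scan.
#'
#' @inheritParams get_cells
#' @param start_key,end_key Row-key bounds (raw or hex), half-open.
#' @param family Optional family restriction.
#' @return A list of rows, each `list(row_key = <raw>, cells = <list>)`
#'   where every cell is `list(family, label, version, value)`.
#' @export
scan_range <- function(store, table = "primary", start_key = NULL,
                       end_key = NULL, family = NULL) {
  idx <- scan_group_keys(store, table, start_key, end_key, family)
  if (length(idx$keys) == 0L) return(list())
  te <- idx$te
  rows_hex <- substr(idx$keys, 1L, ROW_KEY_HEX)
  r <- rle(rows_hex)
  out <- vector("list", length(r$values))
  pos <- 1L
  for (i in seq_along(r$values)) {
    ks <- idx$keys[pos:(pos + r$lengths[i] - 1L)]
    pos <- pos + r$lengths[i]
    cells <- list()
    for (k in ks) {
      fam <- substr(k, ROW_KEY_HEX + 2L, nchar(k))
      for (cell in te$cells[[k]]) {
        cells[[length(cells) + 1L]] <-
          list(family = fam, label = cell$label, version = cell$version,
               value = cell$value)
      }
    }
    out[[i]] <- list(row_key = hex_to_raw(r$values[i]), cells = cells)
  }
  out
}

# Shared scan plumbing: sorted physical keys of a table restricted to a
# half-open row range and (optionally) one family. Bounds are compared
# numerically after decoding, avoiding locale-dependent string collation.
scan_group_keys <- function(store, table, start_key, end_key, family = NULL) {
  assert_open(store)
  if (!is.null(start_key) && !is.null(end_key)) {
    s <- row_key_to_hex(start_key); e <- row_key_to_hex(end_key)
    if (key_gt(s, e)) stop("scan start key exceeds end key", call. = FALSE)
  }
  te <- table_env(store, table)
  if (is.null(te)) return(list(te = NULL, keys = character(0)))
  keys <- sorted_keys(te)
  if (length(keys) == 0L) return(list(te = te, keys = keys))
  if (!is.null(family)) {
    check_family(table, family)
    keys <- keys[endsWith(keys, paste0(GROUP_SEP, family))]
  }
  if (!is.null(start_key) || !is.null(end_key)) {
    ci <- strtoi(substr(keys, 1L, 8L), 16L)
    po <- hex_to_pos(substr(keys, 9L, 24L))
    keep <- rep(TRUE, length(keys))
    if (!is.null(start_key)) {
      d <- decode_row_key(row_key_to_hex(start_key))
      keep <- keep & (ci > d$contig_index |
                        (ci == d$contig_index & po >= d$position))
    }
    if (!is.null(end_key)) {
      d <- decode_row_key(row_key_to_hex(end_key))
      keep <- keep & (ci < d$contig_index |
                        (ci == d$contig_index & po < d$position))
    }
    keys <- keys[keep]
  }
  list(te = te, keys = keys)
}

key_gt <- function(a_hex, b_hex) {
  a <- decode_row_key(a_hex); b <- decode_row_key(b_hex)
  a$contig_index > b$contig_index ||
    (a$contig_index == b$contig_index && a$position > b$position)
}

split_chunks <- function(x, size) {
  if (length(x) == 0L) return(list())
  split(x, (seq_along(x) - 1L) %/% size)
}
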