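# Cell-value encoding. The store treats values as opaque single-line
# strings; each record carries a schema tag ("VAR1", "COV1", ...) so values
# are self-describing and the layout can evolve. Fields are tab-separated
# and free-text fields are percent-escaped, which keeps both directions
# vectorisable — the encoder/decoder run over millions of records in one
# call on the bulk paths.

esc_field <- function(x) {
  x <- gsub("%", "%25", x, fixed = TRUE)
  x <- gsub("\t", "%09", x, fixed = TRUE)
  x <- gsub("\n", "%0a", x, fixed = TRUE)
  x <- gsub("\r", "%0d", x, fixed = TRUE)
  x
}

unesc_field <- function(x) {
  x <- gsub("%0d", "\r", x, fixed = TRUE)
  x <- gsub("%0a", "\n", x, fixed = TRUE)
  x <- gsub("%09", "\t", x, fixed = TRUE)
  x <- gsub("%25", "%", x, fixed = TRUE)
  x
}

esc_tag_part <- function(x) {
  x <- esc_field(x)
  x <- gsub("=", "%3d", x, fixed = TRUE)
  x <- gsub(",", "%2c", x, fixed = TRUE)
  x
}

unesc_tag_part <- function(x) {
  x <- gsub("%2c", ",", x, fixed = TRUE)
  x <- gsub("%3d", "=", x, fixed = TRUE)
  unesc_field(x)
}

encode_tags <- function(tags) {
  if (length(tags) == 0L) return("")
  paste(paste0(esc_tag_part(names(tags)), "=", esc_tag_part(unname(tags))),
        collapse = ",")
}

decode_tags <- function(s) {
  if (is.na(s) || !nzchar(s)) return(structure(character(0), names = character(0)))
  parts <- strsplit(s, ",", fixed = TRUE)[[1]]
  eq <- regexpr("=", parts, fixed = TRUE)
  keys <- unesc_tag_part(substr(parts, 1L, eq - 1L))
  vals <- unesc_tag_part(substr(parts, eq + 1L, nchar(parts)))
  structure(vals, names = keys)
}

na_dot <- function(x) ifelse(is.na(x), ".", as.character(x))
dot_na <- function(x) ifelse(x == ".", NA, x)

encode_variant <- function(v) {
  encode_variant_vec(v$type, v$contig, v$position, v$stop, v$ref_allele,
                     v$alt_allele, v$observation_count, v$depth, v$p_value,
                     encode_tags(v$tags), v$genome_label, v$version)
}

# Vectorised over parallel columns; tags_enc is the already-encoded tag field.
encode_variant_vec <- function(type, contig, position, stop, ref, alt,
                               obs, depth, p_value, tags_enc, label, version) {
  paste("VAR1", type, esc_field(contig), format_pos(position),
        format_pos(stop), esc_field(ref), esc_field(alt), obs, depth,
        na_dot(p_value), tags_enc, esc_field(label), version, sep = "\t")
}

decode_variant <- function(value) {
  f <- strsplit(value, "\t", fixed = TRUE)[[1]]
  if (f[1] != "VAR1" || length(f) != 13L) {
    stop("not a VAR1 record: ", substr(value, 1, 40), call. = FALSE)
  }
  structure(list(contig = unesc_field(f[3]), position = as.numeric(f[4]),
                 stop = as.numeric(f[5]), type = f[2],
                 ref_allele = unesc_field(f[6]), alt_allele = unesc_field(f[7]),
                 observation_count = as.integer(f[8]), depth = as.integer(f[9]),
                 p_value = as.numeric(dot_na(f[10])), tags = decode_tags(f[11]),
                 genome_label = unesc_field(f[12]), version = as.integer(f[13])),
            class = "qe_variant")
}

# Column-wise decode of many VAR1 values at once (bulk export path). Tags
# are left encoded; callers that need them decode per record.
decode_variant_cols <- function(values) {
  f <- strsplit(values, "\t", fixed = TRUE)
  m <- matrix(unlist(f, use.names = FALSE), nrow = 13L)
  list(type = m[2, ], contig = unesc_field(m[3, ]),
       position = as.numeric(m[4, ]), stop = as.numeric(m[5, ]),
       ref_allele = unesc_field(m[6, ]), alt_allele = unesc_field(m[7, ]),
       observation_count = as.integer(m[8, ]), depth = as.integer(m[9, ]),
       p_value = as.numeric(dot_na(m[10, ])), tags_enc = m[11, ],
       genome_label = unesc_field(m[12, ]), version = as.integer(m[13, ]))
}

encode_coverage <- function(cb) {
  paste("COV1", esc_field(cb$contig), format_pos(cb$block_start),
        cb$block_size, paste(cb$offsets, collapse = ","),
        paste(cb$depths, collapse = ","), esc_field(cb$genome_label),
        sep = "\t")
}

decode_coverage <- function(value) {
  f <- strsplit(value, "\t", fixed = TRUE)[[1]]
  if (f[1] != "COV1" || length(f) != 7L) {
    stop("not a COV1 record: ", substr(value, 1, 40), call. = FALSE)
  }
  offs <- if (nzchar(f[5])) as.integer(strsplit(f[5], ",", fixed = TRUE)[[1]]) else integer(0)
  deps <- if (nzchar(f[6])) as.integer(strsplit(f[6], ",", fixed = TRUE)[[1]]) else integer(0)
  structure(list(contig = unesc_field(f[2]), block_start = as.numeric(f[3]),
                 block_size = as.integer(f[4]), offsets = offs, depths = deps,
                 genome_label = unesc_field(f[7])),
            class = "qe_coverage_block")
}

encode_feature <- function(ft) {
  paste("FEA1", esc_field(ft$contig), format_pos(ft$position),
        format_pos(ft$stop), esc_field(ft$name), na_dot(ft$score), ft$strand,
        encode_tags(ft$tags), esc_field(ft$genome_label), ft$version,
        sep = "\t")
}

decode_feature <- function(value) {
  f <- strsplit(value, "\t", fixed = TRUE)[[1]]
  if (f[1] != "FEA1" || length(f) != 10L) {
    stop("not a FEA1 record: ", substr(value, 1, 40), call. = FALSE)
  }
  structure(list(contig = unesc_field(f[2]), position = as.numeric(f[3]),
                 stop = as.numeric(f[4]), name = unesc_field(f[5]),
                 score = as.numeric(dot_na(f[6])), strand = f[7],
                 tags = decode_tags(f[8]), genome_label = unesc_field(f[9]),
                 version = as.integer(f[10])),
            class = "qe_feature")
}

encode_consequence <- function(cq) {
  paste("CSQ1", esc_field(cq$contig), format_pos(cq$position),
        esc_field(cq$effect), na_dot(esc_field(cq$gene)), cq$variant_version,
        encode_tags(cq$tags), esc_field(cq$genome_label), cq$version,
        sep = "\t")
}

decode_consequence <- function(value) {
  f <- strsplit(value, "\t", fixed = TRUE)[[1]]
  if (f[1] != "CSQ1" || length(f) != 9L) {
    stop("not a CSQ1 record: ", substr(value, 1, 40), call. = FALSE)
  }
  structure(list(contig = unesc_field(f[2]), position = as.numeric(f[3]),
                 effect = unesc_field(f[4]),
                 gene = unesc_field(dot_na(f[5])),
                 variant_version = as.integer(f[6]), tags = decode_tags(f[7]),
                 genome_label = unesc_field(f[8]), version = as.integer(f[9])),
            class = "qe_consequence")
}

decode_value <- function(value) {
  switch(substr(value, 1L, 4L),
         VAR1 = decode_variant(value),
         COV1 = decode_coverage(value),
         FEA1 = decode_feature(value),
         CSQ1 = decode_consequence(value),
         stop("unknown record schema tag: ", substr(value, 1, 8), call. = FALSE))
}
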