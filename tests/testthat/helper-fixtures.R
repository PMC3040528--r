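# Shared fixtures, memoised per test run, and the independent brute-force
# oracles the store-backed paths are checked against. Oracles operate on
# plain data frames and never touch store internals.

.fix <- new.env(parent = emptyenv())

memo <- function(name, build) {
  if (is.null(.fix[[name]])) .fix[[name]] <- build()
  .fix[[name]]
}

# 10k tagged random variants in a store, plus the truth frame
query_fixture <- function() {
  memo("query10k", function() {
    df <- generate_variants(10000, contig_lengths = c(chr1 = 2e6, chr2 = 1e6),
                            genome_label = "genome1", seed = 101)
    st <- store_create(tempfile("qfix"), "fixref",
                       contigs = c("chr1", "chr2"))
    write_variant_frame(st, df)
    df$tag_names <- lapply(df$tags, function(s) names(varkv:::decode_tags(s)))
    df$tag_map <- lapply(df$tags, varkv:::decode_tags)
    list(store = st, df = df)
  })
}

# canonical one-line form of a variant, for set comparisons
canon_variant <- function(contig, position, type, ref, alt, obs) {
  sprintf("%s:%.0f:%s:%s>%s:%d", contig, as.numeric(position),
          type, toupper(ref), toupper(alt), as.integer(obs))
}

canon_from_objects <- function(vs) {
  vapply(vs, function(v) canon_variant(v$contig, v$position, v$type,
                                       v$ref_allele, v$alt_allele,
                                       v$observation_count), "")
}

# brute-force in-memory filter over the truth frame: the oracle for
# query_variants. Returns the canonical strings, sorted.
oracle_query <- function(df, region = NULL, filter = variant_filter()) {
  keep <- rep(TRUE, nrow(df))
  if (!is.null(region)) {
    m <- regmatches(region, regexec("^([^:]+):([0-9]+)-([0-9]+)$", region))[[1]]
    if (length(m) == 4L) {
      keep <- keep & df$contig == m[2] &
        df$position >= as.numeric(m[3]) & df$position < as.numeric(m[4])
    } else {
      keep <- keep & df$contig == region
    }
  }
  if (!is.null(filter$min_observations)) {
    keep <- keep & df$observation_count >= filter$min_observations
  }
  if (!is.null(filter$min_depth)) keep <- keep & df$depth >= filter$min_depth
  if (!is.null(filter$max_p_value)) {
    keep <- keep & !is.na(df$p_value) & df$p_value <= filter$max_p_value
  }
  if (!is.null(filter$variant_types)) {
    keep <- keep & df$type %in% filter$variant_types
  }
  if (!is.null(filter$tag)) {
    keep <- keep & vapply(df$tag_names, function(tn) filter$tag %in% tn, FALSE)
    if (!is.null(filter$tag_value)) {
      keep <- keep & vapply(df$tag_map, function(tm) {
        filter$tag %in% names(tm) && tm[[filter$tag]] == filter$tag_value
      }, FALSE)
    }
  }
  sort(canon_variant(df$contig[keep], df$position[keep], df$type[keep],
                     df$ref_allele[keep], df$alt_allele[keep],
                     df$observation_count[keep]))
}

# the 100 kb study-condition pileup (seed 42) loaded into a store
roundtrip_fixture <- function() {
  memo("roundtrip", function() {
    ref <- generate_reference(c(chrT = 100000L), seed = 42L)
    gp <- generate_pileup(ref, mean_depth = 20, snv_rate = 1e-3,
                          indel_rate = 1e-4, error_rate = 0, seed = 42L)
    st <- store_create(tempfile("rt"), "synth-ref")
    report <- load_pileup(st, gp$lines, "genomeA", min_observations = 1L)
    list(store = st, gp = gp, report = report, reference = ref)
  })
}

somatic_fixture <- function(error_rate = 0) {
  key <- paste0("somatic", error_rate)
  memo(key, function() {
    ref <- memo("somref", function() generate_reference(c(chrS = 100000L),
                                                        seed = 11L))
    tn <- generate_tumor_normal(ref, germline_n = 200L, somatic_n = 50L,
                                mean_depth = 30, seed = 42L,
                                normal_floor = 10L, error_rate = error_rate)
    st <- store_create(tempfile("tn"), "synth-ref")
    load_pileup(st, tn$tumor_lines, "tumor")
    load_pileup(st, tn$normal_lines, "normal")
    list(store = st, tn = tn)
  })
}

# grammar-directed random pileup base-string fuzzer; returns the string for
# a given ref base and depth (token count is depth by construction)
fuzz_bases <- function(ref, depth) {
  others <- setdiff(c("A", "C", "G", "T"), toupper(ref))
  parts <- character(0)
  for (i in seq_len(depth)) {
    call <- {
      r <- runif(1)
      if (r < 0.62) sample(c(".", ","), 1)
      else if (r < 0.92) {
        b <- sample(others, 1)
        if (runif(1) < 0.5) tolower(b) else b
      }
      else "*"
    }
    if (runif(1) < 0.1) {
      call <- paste0("^", sample(c("!", "I", "~", "5", "a"), 1), call)
    }
    if (runif(1) < 0.08) {
      len <- sample(c(1:4, 9:12), 1)
      seq <- paste(sample(c("A", "C", "G", "T", "a", "c", "g", "t"), len,
                          replace = TRUE), collapse = "")
      call <- paste0(call, sample(c("+", "-"), 1), len, seq)
    }
    if (runif(1) < 0.08) call <- paste0(call, "$")
    parts <- c(parts, call)
  }
  paste(parts, collapse = "")
}

# independent sequential oracle for map_reduce: plain scan + group + reduce
sequential_mr_oracle <- function(store, map_fn, reduce_fn) {
  rows <- scan_range(store, "primary")
  em_keys <- character(0); em_vals <- list()
  for (row in rows) {
    for (em in map_fn(row$row_key, row$cells)) {
      em_keys <- c(em_keys, em$key)
      em_vals[[length(em_vals) + 1L]] <- em$value
    }
  }
  out <- list()
  for (k in sort(unique(em_keys), method = "radix")) {
    out[[k]] <- reduce_fn(k, em_vals[em_keys == k])
  }
  out
}

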