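test_that("row-key codec round-trips and rejects out-of-range input", {
  k <- encode_row_key(3, 12345)
  expect_length(k, 12)
  expect_equal(decode_row_key(k), list(contig_index = 3L, position = 12345))
  expect_equal(decode_row_key(encode_row_key(0, 0)),
               list(contig_index = 0L, position = 0))
  expect_error(encode_row_key(-1, 0), "contig_index")
  expect_error(encode_row_key(0, -5), "position")
  expect_error(encode_row_key(0, 2^53), "position")
  expect_error(decode_row_key(as.raw(1:5)), "12 bytes")
})

test_that("byte order of encoded keys equals numeric order of loci", {
  # brute-force oracle: sort tuples numerically, sort hex keys bytewise
  set.seed(4)
  n <- 1000
  ci <- sample(0:50, n, replace = TRUE)
  po <- sample(c(0:100, sample.int(2^31, 50)), n, replace = TRUE)
  hex <- varkv:::row_key_hex(ci, po)
  by_bytes <- order(hex, method = "radix")
  by_tuple <- order(ci, po)
  expect_identical(hex[by_bytes], hex[by_tuple])
  # fuzz: decode-then-re-encode is the identity on key bytes
  for (i in sample(n, 50)) {
    d <- decode_row_key(encode_row_key(ci[i], po[i]))
    expect_identical(varkv:::raw_to_hex(encode_row_key(d$contig_index,
                                                       d$position)), hex[i])
  }
})

test_that("put/get honours the cell model: families, labels, versions", {
  st <- store_create(tempfile("kv"), "ref1", contigs = "chr1")
  rk <- varkv:::row_key_hex(0L, 500)
  expect_equal(get_cells(st, "primary", rk, "variant"), list())   # absent row

  put_cell(st, cell_address("primary", rk, "variant", "genome7", 1), "val-a")
  put_cell(st, cell_address("primary", rk, "variant", "genome7", 2), "val-b")
  put_cell(st, cell_address("primary", rk, "variant", "genome8", 1), "val-c")

  # both versions of one genome, ascending
  g7 <- get_cells(st, "primary", rk, "variant", label = "genome7")
  expect_equal(vapply(g7, `[[`, 0L, "version"), c(1L, 2L))
  expect_equal(vapply(g7, `[[`, "", "value"), c("val-a", "val-b"))
  # both genome labels when label unset, ordered by (label, version)
  all_cells <- get_cells(st, "primary", rk, "variant")
  expect_equal(vapply(all_cells, `[[`, "", "label"),
               c("genome7", "genome7", "genome8"))
  # overwriting an existing version replaces its value
  put_cell(st, cell_address("primary", rk, "variant", "genome7", 2), "val-b2")
  g7 <- get_cells(st, "primary", rk, "variant", label = "genome7")
  expect_equal(vapply(g7, `[[`, "", "value"), c("val-a", "val-b2"))

  expect_error(put_cell(st, cell_address("primary", rk, "bogus", "g", 1), "x"),
               "family")
  expect_error(cell_address("primary", rk, "index", "g", 1), "family")
})

test_that("scan_range yields exactly the half-open row range in genomic order", {
  st <- store_create(tempfile("kv2"), "ref1", contigs = c("c1", "c2"))
  set.seed(7)
  loci <- unique(data.frame(ci = sample(0:1, 200, replace = TRUE),
                            po = sample.int(5000, 200, replace = TRUE)))
  for (i in seq_len(nrow(loci))) {
    put_cell(st, cell_address("primary",
                              varkv:::row_key_hex(loci$ci[i], loci$po[i]),
                              "variant", "g", 1),
             paste0("v", i))
  }
  rows <- scan_range(st, "primary")
  expect_equal(length(rows), nrow(loci))
  dec <- lapply(rows, function(r) decode_row_key(r$row_key))
  ci <- vapply(dec, `[[`, 0L, "contig_index")
  po <- vapply(dec, `[[`, 0, "position")
  expect_false(is.unsorted(order(ci, po)))
  expect_identical(order(ci, po), seq_along(rows))   # already genomic order
  # visits every inserted row exactly once
  expect_setequal(paste(ci, po), paste(loci$ci, loci$po))

  # half-open interval semantics
  some <- loci[loci$ci == 0, ]
  some <- some[order(some$po), ]
  a <- some$po[2]; b <- some$po[5]
  sub <- scan_range(st, "primary", encode_row_key(0, a), encode_row_key(0, b))
  dec <- vapply(sub, function(r) decode_row_key(r$row_key)$position, 0)
  expect_equal(dec, some$po[some$po >= a & some$po < b])
  expect_equal(scan_range(st, "primary", encode_row_key(0, a),
                          encode_row_key(0, a)), list())
  expect_error(scan_range(st, "primary", encode_row_key(0, b),
                          encode_row_key(0, a)), "exceeds")
  # empty store scans empty
  st2 <- store_create(tempfile("kv3"), "ref1")
  expect_equal(scan_range(st2, "primary"), list())
})

test_that("a flushed store reopens with identical contents", {
  dir <- tempfile("persist")
  st <- store_create(dir, "hg-synth", contigs = c("chr1", "chr2"),
                     block_size = 500)
  v <- variant("chr2", 777, 778, "SNV", "G", "T", 3, 9,
               tags = c(dbSNP = "rs99"), genome_label = "genomeX")
  write_variant(st, v)
  write_coverage_block(st, coverage_block("chr1", 0, 500, c(1, 2), c(5, 6),
                                          "genomeX"))
  store_close(st)
  expect_error(put_cell(st, cell_address("primary", "x", "variant", "g", 1),
                        "y"), "closed")

  st2 <- store_open(dir)
  expect_equal(st2$reference_name, "hg-synth")
  expect_equal(st2$block_size, 500L)
  expect_equal(store_contigs(st2), c("chr1", "chr2"))
  expect_equal(store_genomes(st2), "genomeX")
  got <- variants_at(st2, "chr2", 777, "genomeX")
  expect_length(got, 1)
  expect_equal(got[[1]]$alt_allele, "T")
  expect_equal(got[[1]]$tags, c(dbSNP = "rs99"))
  cov <- query_coverage(st2, "genomeX", "chr1:0-500")
  expect_equal(cov$depth, c(5L, 6L))
  # the tag index survived too
  hits <- lookup_by_tag(st2, "dbSNP", "genomeX")
  expect_length(hits, 1)
})
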