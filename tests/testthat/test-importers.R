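test_that("parse_pileup_line splits classic pileup and rejects other shapes", {
  r <- parse_pileup_line("chr1\t100\tA\t5\t..,,.\tIIIII")
  expect_equal(r$contig, "chr1")
  expect_equal(r$position, 100)
  expect_equal(r$ref_base, "A")
  expect_equal(r$depth, 5L)
  expect_equal(r$read_bases, "..,,.")
  expect_error(parse_pileup_line("chr1\t100\tA\t5\t..,,."), "6")
  expect_error(parse_pileup_line("chr1\tx\tA\t5\t..,,.\tIIIII"), "position")
  expect_error(parse_pileup_line("chr1\t100\tA\tz\t..,,.\tIIIII"), "depth")
  # CRLF endings handled identically to LF
  r2 <- parse_pileup_line("chr1\t100\tA\t5\t..,,.\tIIIII\r")
  expect_equal(r2$base_qualities, "IIIII")
})

test_that("count_alleles tokenizes the pileup grammar exactly", {
  # all-reference marks
  c1 <- count_alleles(parse_pileup_line("chr1\t100\tA\t5\t..,,.\tIIIII"))
  expect_equal(c1$ref_count, 5L)
  expect_length(c1$snv_counts, 0)
  # hand-tokenized: ". C , c . ^~ ." -> 4 ref, C twice (case-folded)
  c2 <- count_alleles(parse_pileup_line("chr1\t100\tA\t6\t.C,c.^~.\tIIIIII"))
  expect_equal(c2$ref_count, 4L)
  expect_equal(c2$snv_counts, c(C = 2L))
  # hand-tokenized: indels attach to the preceding ref calls
  c3 <- count_alleles(parse_pileup_line("chr1\t100\tG\t3\t.+2AT.,-1c\tIII"))
  expect_equal(c3$ref_count, 3L)
  expect_equal(c3$insertion_counts, c(AT = 1L))
  expect_equal(c3$deletion_counts, c(c = 1L))
  # '*' placeholders count as call tokens but not as ref
  c4 <- count_alleles(parse_pileup_line("chr1\t100\tA\t4\t.*.,\tIIII"))
  expect_equal(c4$ref_count, 3L)
  expect_equal(c4$deletion_placeholders, 1L)
  # token conservation violation is a consistency error naming the locus
  expect_error(count_alleles(parse_pileup_line("chr1\t100\tA\t9\t..,\tIII")),
               "token conservation.*chr1:100")
})

test_that("token conservation holds for grammar-valid fuzzed base strings", {
  set.seed(31)
  for (i in 1:500) {
    d <- sample(1:40, 1)
    ref <- sample(c("A", "C", "G", "T"), 1)
    rec <- structure(list(contig = "f", position = i, ref_base = ref,
                          depth = d, read_bases = fuzz_bases(ref, d),
                          base_qualities = strrep("I", d)),
                     class = "qe_pileup_record")
    counts <- count_alleles(rec)   # errors if conservation fails
    expect_equal(counts$ref_count + sum(counts$snv_counts) +
                   counts$deletion_placeholders, d)
  }
})

test_that("call_variants applies thresholds and deterministic version order", {
  rec <- parse_pileup_line("chr1\t100\tA\t6\t.CC.TC\tIIIIII")
  cts <- count_alleles(rec)
  expect_equal(cts$snv_counts, c(C = 3L, T = 1L))
  vs <- call_variants(rec, cts, min_observations = 1, genome_label = "g")
  expect_length(vs, 2)
  expect_equal(vapply(vs, `[[`, "", "alt_allele"), c("C", "T"))
  expect_equal(vapply(vs, `[[`, 0L, "version"), c(1L, 2L))  # SNVs by base
  expect_equal(vs[[1]]$position, 99)                        # 0-based
  expect_equal(vs[[1]]$observation_count, 3L)
  # threshold prunes
  vs3 <- call_variants(rec, cts, min_observations = 3, genome_label = "g")
  expect_length(vs3, 1)
  vs9 <- call_variants(rec, cts, min_observations = 9, genome_label = "g")
  expect_length(vs9, 0)
  # SNVs, then insertions, then deletions
  rec2 <- parse_pileup_line("chr1\t50\tG\t5\t.T.+1A.-2cc.\tIIIII")
  vs2 <- call_variants(rec2, count_alleles(rec2), 1, "g")
  expect_equal(vapply(vs2, `[[`, "", "type"),
               c("SNV", "INSERTION", "DELETION"))
  expect_equal(vapply(vs2, `[[`, 0L, "version"), 1:3)
  expect_equal(vs2[[3]]$ref_allele, "CC")   # deletion allele upper-cased
  expect_equal(vs2[[3]]$stop, 49 + 1 + 2)
})

test_that("load_pileup writes the truth variants and exact per-base coverage", {
  ref <- generate_reference(c(mini = 4000L), seed = 3L)
  gp <- generate_pileup(ref, mean_depth = 12, snv_rate = 3e-3,
                        indel_rate = 5e-4, seed = 8L)
  st <- store_create(tempfile("lp"), "r", block_size = 250)
  rep <- load_pileup(st, gp$lines, "gA")
  expect_equal(rep$lines_read, length(gp$lines))
  expect_equal(rep$variants_written, nrow(gp$truth$variants))
  got <- canon_from_objects(query_variants(st, "gA"))
  tv <- gp$truth$variants
  want <- canon_variant(tv$contig, tv$position, tv$type, tv$ref, tv$alt,
                        tv$observation_count)
  expect_setequal(got, want)
  # brute-force per-base depth oracle: every covered base in exactly one
  # block with the right depth
  cov <- query_coverage(st, "gA", "mini:0-4000")
  dm <- gp$truth$depth_map$mini
  expect_equal(cov$position, which(dm >= 1) - 1)
  expect_equal(cov$depth, dm[dm >= 1])
  expect_equal(anyDuplicated(cov$position), 0L)
  # empty stream loads nothing
  st0 <- store_create(tempfile("lp0"), "r")
  rep0 <- load_pileup(st0, character(0), "gA")
  expect_equal(rep0, list(variants_written = 0L, blocks_written = 0L,
                          lines_read = 0L))
})

test_that("unsorted or malformed pileup input aborts with the offending line", {
  st <- store_create(tempfile("bad"), "r")
  lines <- c("c1\t10\tA\t1\t.\tI", "c1\t5\tA\t1\t.\tI")
  expect_error(load_pileup(st, lines, "g"), "unsorted.*line 2")
  lines2 <- c("c1\t10\tA\t1\t.\tI", "c2\t1\tA\t1\t.\tI", "c1\t20\tA\t1\t.\tI")
  expect_error(load_pileup(st, lines2, "g"), "unsorted")
  expect_error(load_pileup(st, "c1\t10\tA\t3\t.\tIII", "g"),
               "token conservation")
  expect_error(load_pileup(st, "c1\t10\tA\t1\t.\tI\textra\tcols", "g"), "6")
})

test_that("BED loader keeps 0-based half-open coordinates and skips headers", {
  st <- store_create(tempfile("bed"), "r")
  n <- load_bed_features(st, c("track name=test", "browser position chr1",
                               "# comment",
                               "chr1\t10\t20\tpromoter\t3.5\t+",
                               "chr1\t40\t45"),
                         "gB")
  expect_equal(n, 2L)
  rows <- scan_range(st, "primary", family = "feature")
  f1 <- varkv:::decode_feature(rows[[1]]$cells[[1]]$value)
  expect_equal(f1$position, 10)
  expect_equal(f1$stop, 20)
  expect_equal(f1$name, "promoter")
  expect_equal(f1$score, 3.5)
  expect_equal(f1$strand, "+")
  expect_equal(f1$tags, c(name = "promoter"))
  # named features are reachable through the tag index
  expect_length(lookup_by_tag(st, "name", "gB"), 1)
  expect_error(load_bed_features(st, "chr1\t20\t10", "gB"), "coordinates")
})

test_that("GFF loader converts 1-based inclusive and parses attributes", {
  st <- store_create(tempfile("gff"), "r")
  n <- load_gff_features(st, c("# gff",
                               "chr1\tsrc\tgene\t1\t1\t.\t+\t.\tID=x;Note=y",
                               "chr1\tsrc\texon\t100\t200\t0.9\t-\t.\t."),
                         "gC")
  expect_equal(n, 2L)
  rows <- scan_range(st, "primary", family = "feature")
  f1 <- varkv:::decode_feature(rows[[1]]$cells[[1]]$value)
  expect_equal(f1$position, 0)   # start=1,end=1 -> [0,1)
  expect_equal(f1$stop, 1)
  expect_equal(f1$tags, c(ID = "x", Note = "y"))
  expect_equal(f1$name, "x")
  f2 <- varkv:::decode_feature(rows[[2]]$cells[[1]]$value)
  expect_equal(f2$position, 99)
  expect_equal(f2$stop, 200)
  expect_equal(f2$strand, "-")
  expect_error(load_gff_features(st, "chr1\tsrc\tgene\t1\t5", "gC"), "9")
})

test_that("plugin registry dispatches, lists formats, and rejects duplicates", {
  expect_setequal(intersect(c("pileup", "bed", "gff", "consequence-kv"),
                            loader_formats()),
                  c("pileup", "bed", "gff", "consequence-kv"))
  st <- store_create(tempfile("plug"), "r")
  # a custom 3-column tab format: contig, pos0, alt
  toy_loader <- function(store, input, genome_label, ...) {
    k <- 0L
    for (ln in input) {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      write_variant(store, variant(f[1], as.numeric(f[2]),
                                   as.numeric(f[2]) + 1, "SNV", "A", f[3],
                                   1, 1, genome_label = genome_label))
      k <- k + 1L
    }
    k
  }
  register_loader("toy-tab", toy_loader)
  expect_error(register_loader("toy-tab", toy_loader), "already registered")
  n <- load_with_plugin("toy-tab", st, c("c1\t5\tC", "c1\t9\tG"), "gP")
  expect_equal(n, 2L)
  got <- query_variants(st, "gP")
  expect_equal(vapply(got, `[[`, 0, "position"), c(5, 9))
  expect_error(load_with_plugin("nope", st, "x", "gP"),
               "known formats.*pileup")
})

test_that("consequence loader links to stored variants and rejects danglers", {
  st <- store_create(tempfile("csq"), "r")
  write_variant(st, variant("chr1", 99, 100, "SNV", "A", "C", 2, 6,
                            genome_label = "gQ"))
  n <- load_consequences_kv(st, "chr1\t100\t1\tmissense\tTP53\tsource=synthetic",
                            "gQ")
  expect_equal(n, 1L)
  pairs <- query_consequences(st, "gQ")
  expect_length(pairs, 1)
  expect_equal(pairs[[1]]$consequence$effect, "missense")
  expect_equal(pairs[[1]]$consequence$gene, "TP53")
  expect_equal(pairs[[1]]$variant$alt_allele, "C")
  expect_error(load_consequences_kv(st, "chr1\t100\t9\tmissense\t.", "gQ"),
               "does not resolve")
})
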