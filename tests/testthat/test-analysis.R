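test_that("map_reduce equals the sequential oracle for arbitrary pure functions", {
  st <- store_create(tempfile("mrprop"), "r")
  write_variant_frame(st, generate_variants(800, c(cM = 5e5),
                                            genome_label = "g", seed = 33))
  # a small combinator family generates random pure map/reduce pairs
  set.seed(77)
  key_fns <- list(
    function(rk, cell, v) v$type,
    function(rk, cell, v) v$contig,
    function(rk, cell, v) as.character(v$depth %% 7L),
    function(rk, cell, v) paste0(v$type, ":", v$observation_count %% 3L))
  val_fns <- list(
    function(v) 1L,
    function(v) v$observation_count,
    function(v) as.numeric(v$depth))
  red_fns <- list(
    function(k, vals) sum(unlist(vals)),
    function(k, vals) length(vals),
    function(k, vals) max(unlist(vals)),
    function(k, vals) unlist(vals)[1])
  for (case in 1:25) {
    kf <- sample(key_fns, 1)[[1]]
    vf <- sample(val_fns, 1)[[1]]
    rf <- sample(red_fns, 1)[[1]]
    parts <- sample(1:7, 1)
    map_fn <- function(rk, cells) {
      out <- list()
      for (cell in cells) {
        if (cell$family != "variant") next
        v <- varkv:::decode_variant(cell$value)
        out[[length(out) + 1L]] <- list(key = kf(rk, cell, v),
                                        value = vf(v))
      }
      out
    }
    expect_identical(map_reduce(st, map_fn, rf, partitions = parts),
                     sequential_mr_oracle(st, map_fn, rf),
                     info = paste("case", case, "partitions", parts))
  }
})

test_that("map_reduce handles identity counting, empties, and error context", {
  st <- store_create(tempfile("mr"), "r", contigs = "c1")
  expect_equal(map_reduce(st, function(rk, cells) list(),
                          function(k, v) NULL), structure(list(),
                                                          names = character(0)))
  for (p in c(3, 7, 11)) {
    write_variant(st, variant("c1", p, p + 1, "SNV", "A", "C", 1, 1,
                              genome_label = "g"))
  }
  n <- map_reduce(st,
                  function(rk, cells) list(list(key = "n", value = 1L)),
                  function(k, vals) length(vals))
  expect_equal(n$n, 3L)
  expect_error(map_reduce(st, function(rk, cells) stop("boom"),
                          function(k, v) v),
               "map function failed at row.*position")
  expect_error(map_reduce(st,
                          function(rk, cells) list(list(key = "k", value = 1)),
                          function(k, v) stop("crunch")),
               "reduce function failed for key 'k'")
})

test_that("variant-type counts are exact and agree with the query path", {
  st <- store_create(tempfile("cnt"), "r")
  df <- generate_variants(800, c(cA = 1e5), genome_label = "g", seed = 12)
  write_variant_frame(st, df)
  counts <- count_variant_types(st, "g")
  expect_equal(sum(counts), 800L)
  truth <- table(df$type)
  for (ty in names(truth)) expect_equal(unname(counts[ty]),
                                        as.integer(truth[[ty]]))
  # dual-path equivalence via the iterator
  vs <- query_variants(st, "g")
  tab <- table(factor(vapply(vs, `[[`, "", "type"),
                      levels = names(counts)))
  expect_equal(as.integer(tab), unname(as.integer(counts)))
  # empty genome: all zeros
  st2 <- store_create(tempfile("cnt2"), "r")
  write_variant(st2, variant("c", 1, 2, "SNV", "A", "C", 1, 1,
                             genome_label = "other"))
  varkv:::register_genome(st2, "empty")
  expect_true(all(count_variant_types(st2, "empty") == 0L))
  expect_error(count_variant_types(st, "nosuch"), "unknown genome")
})

test_that("somatic rules: quality veto, normal veto, coverage check", {
  st <- store_create(tempfile("som"), "r", contigs = "c1", block_size = 100)
  crit <- somatic_criteria(min_tumor_observations = 4,
                           min_tumor_fraction = 0.1,
                           min_normal_coverage = 10)
  # normal coverage 15 at locus 5 and 18 at locus 30, none at locus 205
  write_coverage_block(st, coverage_block("c1", 0, 100, c(5, 30), c(15, 18),
                                          "normal"))
  varkv:::register_genome(st, "normal")
  # tumor SNV 8/20 at locus 5, no normal variant -> PUTATIVE
  write_variant(st, variant("c1", 5, 6, "SNV", "A", "C", 8, 20,
                            genome_label = "tumor"))
  # same allele present in normal at locus 30 -> vetoed
  write_variant(st, variant("c1", 30, 31, "SNV", "G", "T", 9, 20,
                            genome_label = "tumor"))
  write_variant(st, variant("c1", 30, 31, "SNV", "G", "T", 1, 18,
                            genome_label = "normal"))
  # low observations -> quality reject
  write_variant(st, variant("c1", 60, 61, "SNV", "C", "A", 2, 40,
                            genome_label = "tumor"))
  # no normal coverage at locus 205 -> low-coverage reject
  write_variant(st, variant("c1", 205, 206, "SNV", "T", "G", 12, 22,
                            genome_label = "tumor"))
  calls <- detect_somatic(st, "tumor", "normal", crit)
  expect_length(calls, 1)
  expect_equal(calls[[1]]$variant$position, 5)
  expect_equal(calls[[1]]$status, "PUTATIVE_SOMATIC")
  expect_equal(calls[[1]]$normal_depth_at_locus, 15L)
  all_calls <- detect_somatic(st, "tumor", "normal", crit,
                              report_rejected = TRUE)
  expect_length(all_calls, 4)
  status_by_pos <- setNames(vapply(all_calls, `[[`, "", "status"),
                            vapply(all_calls, function(x) x$variant$position,
                                   0))
  expect_equal(unname(status_by_pos[c("5", "30", "60", "205")]),
               c("PUTATIVE_SOMATIC", "REJECTED_PRESENT_IN_NORMAL",
                 "REJECTED_QUALITY", "REJECTED_LOW_NORMAL_COVERAGE"))
  expect_error(detect_somatic(st, "tumor", "nope"), "unknown genome")
})

test_that("a different alt allele in the normal does not veto the tumor call", {
  st <- store_create(tempfile("som2"), "r", contigs = "c1", block_size = 100)
  write_variant(st, variant("c1", 9, 10, "SNV", "A", "C", 10, 20,
                            genome_label = "tumor"))
  write_variant(st, variant("c1", 9, 10, "SNV", "A", "G", 3, 25,
                            genome_label = "normal"))
  write_coverage_block(st, coverage_block("c1", 0, 100, 9, 25, "normal"))
  calls <- detect_somatic(st, "tumor", "normal")
  expect_length(calls, 1)
  expect_equal(calls[[1]]$variant$alt_allele, "C")
})

test_that("somatic detection on the planted pair is exact and symmetric-safe", {
  fx <- somatic_fixture(error_rate = 0)
  calls <- detect_somatic(fx$store, "tumor", "normal")
  got <- vapply(calls, function(x) {
    v <- x$variant
    canon_variant(v$contig, v$position, v$type, v$ref_allele, v$alt_allele, 0)
  }, "")
  ss <- fx$tn$truth$somatic_subset
  want <- canon_variant(ss$contig, ss$position, ss$type, ss$ref, ss$alt, 0)
  expect_setequal(got, want)         # precision and recall both 1
  # germline variants never appear among somatic calls
  gs <- fx$tn$truth$germline_subset
  germ <- canon_variant(gs$contig, gs$position, gs$type, gs$ref, gs$alt, 0)
  expect_length(intersect(got, germ), 0)
  # swapping tumor and normal yields the reciprocal difference: nothing,
  # since every normal variant is a germline variant also in the tumor
  rev_calls <- detect_somatic(fx$store, "normal", "tumor")
  expect_length(rev_calls, 0)
})
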