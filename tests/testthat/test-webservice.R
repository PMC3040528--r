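ws_store <- function() {
  memo("wsstore", function() {
    st <- store_create(tempfile("ws"), "synth-ref", contigs = "chrW",
                       block_size = 100)
    df <- generate_variants(400, c(chrW = 50000), genome_label = "genomeA",
                            seed = 21)
    write_variant_frame(st, df)
    write_variant(st, variant("chrW", 7, 8, "SNV", "A", "G", 3, 9,
                              genome_label = "genomeB"))
    write_coverage_block(st, coverage_block("chrW", 0, 100, 0:49,
                                            rep(5:9, 10), "genomeA"))
    write_coverage_block(st, coverage_block("chrW", 100, 100, 0:9, 1:10,
                                            "genomeA"))
    st
  })
}

test_that("the genome listing is well-formed XML and its URLs all resolve", {
  st <- ws_store()
  resp <- handle_request(st, "/genomes")
  expect_equal(resp$status, 200L)
  doc <- xml2::read_xml(resp$body)   # parse failure = malformed
  genomes <- xml2::xml_find_all(doc, "//genome")
  expect_length(genomes, 2)
  expect_setequal(xml2::xml_attr(genomes, "label"), c("genomeA", "genomeB"))
  urls <- xml2::xml_attr(xml2::xml_find_all(doc, "//resource"), "url")
  expect_gt(length(urls), 0)
  for (u in urls) {   # crawl: every advertised URL answers 200
    tgt <- varkv:::parse_request_target(u)
    r <- handle_request(st, tgt$path, tgt$query)
    expect_equal(r$status, 200L, info = u)
  }
})

test_that("unknown genomes, malformed filters and unknown params are rejected", {
  st <- ws_store()
  expect_equal(handle_request(st, "/genomes/nope/variants")$status, 404L)
  expect_equal(handle_request(st, "/nothere")$status, 404L)
  expect_equal(handle_request(st, "/genomes/genomeA/variants",
                              list(filter.minObs = "abc"))$status, 400L)
  expect_equal(handle_request(st, "/genomes/genomeA/variants",
                              list(bogus = "1"))$status, 400L)  # not ignored
  expect_equal(handle_request(st, "/genomes/genomeA/variants",
                              list(region = "chrW:9-2"))$status, 400L)
  expect_equal(handle_request(st, "/genomes/genomeA/coverage",
                              list(format = "wig"))$status, 400L)  # no region
  expect_equal(handle_request(st, "/genomes/genomeA/variants",
                              list(format = "vcf"))$status, 400L)
})

test_that("service bodies are byte-identical to library exports", {
  st <- ws_store()
  set.seed(99)
  for (i in 1:20) {
    a <- sort(sample.int(50000, 2) - 1)
    region <- sprintf("chrW:%d-%d", a[1], a[2])
    minobs <- sample(0:5, 1)
    resp <- handle_request(st, "/genomes/genomeA/variants",
                           list(region = region, format = "bed",
                                filter.minObs = as.character(minobs)))
    expect_equal(resp$status, 200L)
    vs <- query_variants(st, "genomeA", region = region,
                         filter = variant_filter(min_observations = minobs))
    lib_body <- varkv:::paste_body(export_bed(vs, NULL))
    expect_identical(resp$body, lib_body, info = region)
  }
  # coverage: wig and wig-block
  resp <- handle_request(st, "/genomes/genomeA/coverage",
                         list(region = "chrW:0-150", format = "wig"))
  cov <- query_coverage(st, "genomeA", "chrW:0-150")
  expect_identical(resp$body,
                   varkv:::paste_body(export_wig(cov, NULL, "per_base")))
  respb <- handle_request(st, "/genomes/genomeA/coverage",
                          list(region = "chrW:0-150", format = "wig-block"))
  expect_identical(respb$body,
                   varkv:::paste_body(export_wig(cov, NULL, "block_average",
                                                 block_size = 100)))
  # tags listing matches nonredundant_tags
  respt <- handle_request(st, "/genomes/genomeA/variants",
                          list(format = "tags"))
  all_vs <- query_variants(st, "genomeA")
  expect_identical(respt$body, varkv:::paste_body(
    varkv:::format_tags_body(nonredundant_tags(all_vs))))
})

test_that("identical requests return identical bytes (statelessness)", {
  st <- ws_store()
  reqs <- list(list(path = "/genomes", query = list()),
               list(path = "/genomes/genomeA/variants",
                    query = list(format = "bed", region = "chrW:0-30000")),
               list(path = "/genomes/genomeA/variants",
                    query = list(format = "xml", limit = "10")),
               list(path = "/genomes/genomeA/coverage",
                    query = list(region = "chrW:0-120", format = "wig")))
  for (rq in reqs) {
    r1 <- handle_request(st, rq$path, rq$query)
    r2 <- handle_request(st, rq$path, rq$query)
    expect_identical(r1, r2)
  }
})

test_that("variants XML carries result metadata and honours offset/limit", {
  st <- ws_store()
  resp <- handle_request(st, "/genomes/genomeA/variants",
                         list(format = "xml", offset = "5", limit = "7"))
  doc <- xml2::read_xml(resp$body)
  root <- xml2::xml_find_first(doc, "/variants")
  expect_equal(xml2::xml_attr(root, "genome"), "genomeA")
  total <- as.integer(xml2::xml_attr(root, "total"))
  expect_equal(total, 400L)
  expect_equal(as.integer(xml2::xml_attr(root, "returned")), 7L)
  entries <- xml2::xml_find_all(doc, "//variant")
  expect_length(entries, 7)
})

test_that("browser links percent-encode the service URL recoverably", {
  inner <- "http://localhost:8470/genomes/genomeA/variants?format=bed&region=chrW:0-100"
  u <- browser_link("ucsc", inner)
  expect_match(u, "^https://genome.ucsc.edu/cgi-bin/hgTracks\\?hgct_customText=")
  enc <- sub(".*hgct_customText=", "", u)
  expect_identical(utils::URLdecode(enc), inner)
  g <- browser_link("igv", inner)
  expect_match(g, "^http://localhost:60151/load\\?file=")
  expect_identical(utils::URLdecode(sub(".*file=", "", g)), inner)
  expect_error(browser_link("ensembl", inner))
})

test_that("the socket server answers a real HTTP GET with handler bytes", {
  st <- ws_store()
  port <- 30000 + sample.int(20000, 1)
  dir <- st$path
  store_flush(st)
  script <- sprintf(
    "library(varkv); st <- store_open('%s'); qe_serve(st, port = %d, max_requests = 2, quiet = TRUE)",
    dir, port)
  system2(file.path(R.home("bin"), "Rscript"), c("-e", shQuote(script)),
          wait = FALSE)
  body <- NULL
  path <- "/genomes/genomeA/variants?format=bed&region=chrW%3A0-30000"
  for (try in 1:50) {
    Sys.sleep(0.2)
    body <- tryCatch({
      con <- socketConnection("127.0.0.1", port, open = "r+", blocking = TRUE,
                              timeout = 5)
      writeLines(c(paste("GET", path, "HTTP/1.1"), "Host: localhost",
                   "Connection: close", ""), con, sep = "\r\n")
      resp <- readLines(con, warn = FALSE)
      close(con)
      resp
    }, error = function(e) NULL, warning = function(w) NULL)
    if (!is.null(body) && length(body)) break
  }
  expect_false(is.null(body))
  expect_match(body[1], "HTTP/1.1 200 OK")
  blank <- which(body == "")[1]
  payload <- paste0(paste(body[(blank + 1):length(body)], collapse = "\n"),
                    "\n")
  expected <- handle_request(st, "/genomes/genomeA/variants",
                             list(format = "bed",
                                  region = "chrW:0-30000"))$body
  expect_identical(payload, expected)
  # second allowed request lets the server exit cleanly
  tryCatch({
    con <- socketConnection("127.0.0.1", port, open = "r+", blocking = TRUE,
                            timeout = 2)
    writeLines(c("GET / HTTP/1.1", ""), con, sep = "\r\n")
    readLines(con, warn = FALSE); close(con)
  }, error = function(e) NULL, warning = function(w) NULL)
})
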