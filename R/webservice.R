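# Stateless HTTP front-end over the query layer. Every query is a
# bookmarkable URL: the handler is a pure function of (store, path, query
# parameters), so identical requests against an unchanged store return
# identical bytes. A minimal single-threaded HTTP/1.1 loop over base-R
# server sockets serves the handler; the handler itself is the tested
# surface and is also what the CLI `serve` command runs.
#
# Routes (frozen interface):
#   GET /                                   HTML index
#   GET /genomes                            XML: genomes, data types, formats
#   GET /genomes/{label}/variants           ?region&format=bed|xml|tags
#                                           &tag&tag.value&filter.minObs
#                                           &filter.minDepth&filter.maxP
#                                           &filter.type&offset&limit
#   GET /genomes/{label}/consequences       ?region&format=xml + filter.*
#   GET /genomes/{label}/coverage           ?region&format=wig|wig-block
# Unknown parameters are rejected (400), not ignored.

http_response <- function(status, content_type, body) {
  list(status = as.integer(status), content_type = content_type, body = body)
}

http_error <- function(status, message) {
  http_response(status, "text/plain", paste0("error: ", message, "\n"))
}

VARIANT_PARAMS <- c("region", "format", "tag", "tag.value", "filter.minObs",
                    "filter.minDepth", "filter.maxP", "filter.type",
                    "offset", "limit")
COVERAGE_PARAMS <- c("region", "format")

#' Handle one query-service request
#'
#' The stateless core of the web service: maps a resource path plus query
#' parameters to a response, calling the same query/export functions the
#' CLI uses, so service and library output are byte-identical by
#' construction.
#'
#' @param store A `qe_store`.
#' @param path Resource path, e.g. `"/genomes/genome1/variants"`.
#' @param query Named list/vector of query parameters (decoded).
#' @return A list `(status, content_type, body)`; `body` is a single string.
#' @export
handle_request <- function(store, path, query = list()) {
  query <- as.list(query)
  tryCatch({
    if (path == "/" || path == "/index.html") {
      return(http_response(200, "text/html", service_index_html(store)))
    }
    if (path == "/genomes") {
      return(http_response(200, "text/xml", genomes_xml(store)))
    }
    m <- regmatches(path, regexec(
      "^/genomes/([^/]+)/(variants|consequences|coverage)$", path))[[1]]
    if (length(m) != 3L) return(http_error(404, "no such resource"))
    label <- utils::URLdecode(m[2]); kind <- m[3]
    if (!(label %in% store_genomes(store))) {
      return(http_error(404, paste0("unknown genome '", label, "'")))
    }
    allowed <- if (kind == "coverage") COVERAGE_PARAMS else VARIANT_PARAMS
    unknown <- setdiff(names(query), allowed)
    if (length(unknown)) {
      return(http_error(400, paste0("unknown parameter(s): ",
                                    paste(unknown, collapse = ", "))))
    }
    switch(kind,
           variants = serve_variants(store, label, query),
           consequences = serve_consequences(store, label, query),
           coverage = serve_coverage(store, label, query))
  }, error = function(e) http_error(400, conditionMessage(e)))
}

parse_int_param <- function(query, name) {
  x <- query[[name]]
  if (is.null(x)) return(NULL)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v) || v < 0 || v != floor(v)) {
    stop("parameter ", name, " must be a non-negative integer", call. = FALSE)
  }
  v
}

parse_num_param <- function(query, name) {
  x <- query[[name]]
  if (is.null(x)) return(NULL)
  v <- suppressWarnings(as.numeric(x))
  if (is.na(v)) stop("parameter ", name, " must be numeric", call. = FALSE)
  v
}

filter_from_query <- function(query) {
  types <- if (!is.null(query$filter.type)) {
    strsplit(query$filter.type, ",", fixed = TRUE)[[1]]
  } else NULL
  variant_filter(min_observations = parse_int_param(query, "filter.minObs"),
                 min_depth = parse_int_param(query, "filter.minDepth"),
                 max_p_value = parse_num_param(query, "filter.maxP"),
                 variant_types = types,
                 tag = query$tag, tag_value = query$tag.value)
}

serve_variants <- function(store, label, query) {
  fmt <- if (is.null(query$format)) "bed" else query$format
  if (!fmt %in% c("bed", "xml", "tags")) {
    stop("unsupported variants format '", fmt, "'", call. = FALSE)
  }
  vs <- query_variants(store, label, region = query$region,
                       filter = filter_from_query(query))
  if (fmt == "bed") {
    lines <- export_bed(vs, con = NULL)
    return(http_response(200, "text/plain", paste_body(lines)))
  }
  if (fmt == "tags") {
    lines <- format_tags_body(nonredundant_tags(vs))
    return(http_response(200, "text/plain", paste_body(lines)))
  }
  offset <- parse_int_param(query, "offset")
  limit <- parse_int_param(query, "limit")
  http_response(200, "text/xml",
                variants_xml(store, label, vs, query, offset, limit))
}

serve_consequences <- function(store, label, query) {
  fmt <- if (is.null(query$format)) "xml" else query$format
  if (fmt != "xml") {
    stop("unsupported consequences format '", fmt, "'", call. = FALSE)
  }
  pairs <- query_consequences(store, label, region = query$region,
                              filter = filter_from_query(query))
  http_response(200, "text/xml", consequences_xml(label, pairs))
}

serve_coverage <- function(store, label, query) {
  if (is.null(query$region)) {
    stop("coverage queries require a region parameter", call. = FALSE)
  }
  fmt <- if (is.null(query$format)) "wig" else query$format
  if (!fmt %in% c("wig", "wig-block")) {
    stop("unsupported coverage format '", fmt, "'", call. = FALSE)
  }
  cov <- query_coverage(store, label, region = query$region)
  lines <- if (fmt == "wig") {
    export_wig(cov, con = NULL, mode = "per_base")
  } else {
    export_wig(cov, con = NULL, mode = "block_average",
               block_size = store$block_size)
  }
  http_response(200, "text/plain", paste_body(lines))
}

paste_body <- function(lines) {
  if (length(lines) == 0L) "" else paste0(paste(lines, collapse = "\n"), "\n")
}

service_index_html <- function(store) {
  paste0("<!DOCTYPE html>\n<html><head><title>varkv query engine</title>",
         "</head>\n<body><h1>varkv query engine</h1>\n",
         "<p>Reference: ", store$reference_name, "</p>\n",
         "<p>See <a href=\"/genomes\">/genomes</a> for the XML resource ",
         "listing.</p>\n</body></html>\n")
}

genomes_xml <- function(store) {
  doc <- xml2::xml_new_root("queryEngine", schemaVersion = "1",
                            reference = store$reference_name)
  for (g in store_genomes(store)) {
    gn <- xml2::xml_add_child(doc, "genome", label = g)
    for (kind in c("variants", "consequences", "coverage")) {
      formats <- switch(kind, variants = c("bed", "xml", "tags"),
                        consequences = "xml",
                        coverage = c("wig", "wig-block"))
      for (fmt in formats) {
        url <- paste0("/genomes/", utils::URLencode(g, reserved = TRUE), "/",
                      kind, "?format=", fmt)
        if (kind == "coverage") {
          ct <- store_contigs(store)
          if (length(ct) == 0L) next
          url <- paste0(url, "&region=",
                        utils::URLencode(paste0(ct[1], ":0-1000"),
                                         reserved = TRUE))
        }
        xml2::xml_add_child(gn, "resource", type = kind, format = fmt,
                            url = url)
      }
    }
  }
  as.character(doc)
}

variants_xml <- function(store, label, vs, query, offset = NULL,
                         limit = NULL) {
  total <- length(vs)
  from <- if (is.null(offset)) 0L else as.integer(offset)
  vs <- if (from < total) vs[(from + 1L):total] else list()
  if (!is.null(limit) && length(vs) > limit) vs <- vs[seq_len(limit)]
  doc <- xml2::xml_new_root("variants", genome = label,
                            region = if (is.null(query$region)) "" else query$region,
                            total = as.character(total),
                            offset = as.character(from),
                            returned = as.character(length(vs)))
  for (v in vs) {
    xml2::xml_add_child(doc, "variant", contig = v$contig,
                        position = format_pos(v$position),
                        stop = format_pos(v$stop), type = v$type,
                        ref = v$ref_allele, alt = v$alt_allele,
                        observations = as.character(v$observation_count),
                        depth = as.character(v$depth),
                        pValue = if (is.na(v$p_value)) "" else as.character(v$p_value),
                        version = as.character(v$version),
                        tags = encode_tags(v$tags))
  }
  as.character(doc)
}

consequences_xml <- function(label, pairs) {
  doc <- xml2::xml_new_root("consequences", genome = label,
                            returned = as.character(length(pairs)))
  for (p in pairs) {
    cq <- p$consequence; v <- p$variant
    xml2::xml_add_child(doc, "consequence", contig = cq$contig,
                        position = format_pos(cq$position),
                        effect = cq$effect,
                        gene = if (is.na(cq$gene)) "" else cq$gene,
                        variantVersion = as.character(cq$variant_version),
                        variantType = v$type,
                        variantObservations = as.character(v$observation_count))
  }
  as.character(doc)
}

#' Build a genome-browser link embedding a service query URL
#'
#' Wraps a variants (BED) or coverage (WIG) query URL as a custom-track
#' parameter for the UCSC browser (`hgct_customText`) or a load URL for
#' IGV's remote-control endpoint. The inner URL is percent-encoded so that
#' decoding the parameter recovers it exactly.
#'
#' @param kind `"ucsc"` or `"igv"`.
#' @param query_url Absolute service URL of the query to embed.
#' @return The browser link as a string.
#' @export
browser_link <- function(kind = c("ucsc", "igv"), query_url) {
  kind <- match.arg(kind)
  enc <- utils::URLencode(query_url, reserved = TRUE)
  switch(kind,
         ucsc = paste0("https://genome.ucsc.edu/cgi-bin/hgTracks?",
                       "hgct_customText=", enc),
         igv = paste0("http://localhost:60151/load?file=", enc))
}

# ---- socket loop -----------------------------------------------------------

parse_request_target <- function(target) {
  qpos <- regexpr("?", target, fixed = TRUE)
  if (qpos < 0) return(list(path = target, query = list()))
  path <- substr(target, 1L, qpos - 1L)
  qs <- substr(target, qpos + 1L, nchar(target))
  query <- list()
  if (nzchar(qs)) {
    for (pair in strsplit(qs, "&", fixed = TRUE)[[1]]) {
      eq <- regexpr("=", pair, fixed = TRUE)
      if (eq < 0) {
        query[[utils::URLdecode(pair)]] <- ""
      } else {
        query[[utils::URLdecode(substr(pair, 1L, eq - 1L))]] <-
          utils::URLdecode(substr(pair, eq + 1L, nchar(pair)))
      }
    }
  }
  list(path = path, query = query)
}

#' Serve the query engine over HTTP
#'
#' A minimal single-threaded HTTP/1.1 loop over base-R server sockets,
#' dispatching GET requests to [handle_request()]. Binds to localhost by
#' default; there is no authentication. Intended for desk-scale use and for
#' driving genome browsers — not as a hardened public server.
#'
#' @param store A `qe_store`.
#' @param port TCP port to listen on.
#' @param max_requests Stop after this many requests (default `Inf`; handy
#'   for scripted use).
#' @param quiet Suppress the startup message.
#' @return Invisibly, the number of requests served.
#' @export
qe_serve <- function(store, port = 8470L, max_requests = Inf, quiet = FALSE) {
  srv <- serverSocket(port)
  on.exit(close(srv), add = TRUE)
  if (!quiet) message("varkv query service listening on 127.0.0.1:", port)
  served <- 0L
  while (served < max_requests) {
    con <- socketAccept(srv, blocking = TRUE, open = "r+b")
    served <- served + tryCatch(serve_one(store, con), error = function(e) 0L)
    tryCatch(close(con), error = function(e) NULL)
  }
  invisible(served)
}

serve_one <- function(store, con) {
  req <- readLines(con, n = 1L)
  if (length(req) == 0L) return(0L)
  # drain headers
  repeat {
    h <- readLines(con, n = 1L)
    if (length(h) == 0L || !nzchar(gsub("\r", "", h))) break
  }
  parts <- strsplit(trimws(req), " +")[[1]]
  resp <- if (length(parts) < 2L || parts[1] != "GET") {
    http_error(405, "only GET is supported")
  } else {
    tgt <- parse_request_target(parts[2])
    handle_request(store, tgt$path, tgt$query)
  }
  body <- charToRaw(resp$body)
  status_text <- c(`200` = "OK", `400` = "Bad Request", `404` = "Not Found",
                   `405` = "Method Not Allowed")[[as.character(resp$status)]]
  header <- sprintf(paste0("HTTP/1.1 %d %s\r\nContent-Type: %s\r\n",
                           "Content-Length: %d\r\nConnection: close\r\n\r\n"),
                    resp$status, status_text, resp$content_type, length(body))
  writeBin(c(charToRaw(header), body), con)
  1L
}
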