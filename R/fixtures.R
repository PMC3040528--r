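# Deterministic synthetic-data generator: reference contigs, pileup streams
# with planted variants and logged sequencing-error alleles, tumor/normal
# pairs, and random tagged variant sets — each with a machine-readable truth
# set, so every other module is testable without downloading anything.
# Everything is reproducible byte-for-byte from (parameters, seed).

with_seed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Generate random reference contigs
#'
#' Uniform ACGT sequences, deterministic for a fixed seed.
#'
#' @param contigs Named integer vector: contig name -> length in bases.
#' @param seed RNG seed.
#' @return Named list of single strings, one per contig.
#' @export
generate_reference <- function(contigs = c(chrT = 100000L), seed = 42L) {
  stopifnot(all(contigs >= 1))
  with_seed(seed, {
    out <- lapply(contigs, function(L) {
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = "")
    })
    names(out) <- names(contigs)
    out
  })
}

# Build the pileup lines of one contig. `planted` is a data frame with
# columns pos0, type (SNV/INSERTION/DELETION), ref, alt, count; depth is the
# final per-base depth vector (callers have already floored it so that
# depth >= count at planted loci). Sequencing-error alleles are injected at
# non-planted covered positions at `error_rate` per read and logged.
build_contig_pileup <- function(contig, seq, depth, planted, error_rate,
                                decorate = TRUE) {
  L <- nchar(seq)
  refv <- strsplit(seq, "")[[1]]
  snv_alt <- character(L); snv_n <- integer(L)
  var_tok <- character(L)                    # ".+2AT"-style repeated token
  var_tok_n <- integer(L)
  if (nrow(planted)) {
    for (i in seq_len(nrow(planted))) {
      p <- planted$pos0[i] + 1L
      if (planted$type[i] == "SNV") {
        snv_alt[p] <- planted$alt[i]; snv_n[p] <- planted$count[i]
      } else if (planted$type[i] == "INSERTION") {
        var_tok[p] <- paste0(".+", nchar(planted$alt[i]), planted$alt[i])
        var_tok_n[p] <- planted$count[i]
      } else {
        var_tok[p] <- paste0(".-", nchar(planted$ref[i]), planted$ref[i])
        var_tok_n[p] <- planted$count[i]
      }
    }
  }
  is_planted <- snv_n > 0L | var_tok_n > 0L
  err_n <- integer(L)
  err_alt <- character(L)
  if (error_rate > 0) {
    elig <- which(depth >= 1L & !is_planted)
    if (length(elig)) {
      en <- stats::rbinom(length(elig), depth[elig], error_rate)
      hit <- en > 0L
      if (any(hit)) {
        idx <- elig[hit]
        err_n[idx] <- en[hit]
        err_alt[idx] <- vapply(refv[idx], function(r) {
          sample(setdiff(c("A", "C", "G", "T"), r), 1L)
        }, "")
      }
    }
  }
  n_ref <- depth - snv_n - var_tok_n - err_n
  stopifnot(all(n_ref >= 0))
  covered <- which(depth >= 1L)
  if (length(covered) == 0L) {
    return(list(lines = character(0),
                error_log = data.frame(contig = character(0),
                                       position = numeric(0),
                                       alt = character(0),
                                       count = integer(0))))
  }
  nr <- n_ref[covered]
  bases <- paste0(strrep(".", ceiling(nr / 2)), strrep(",", nr %/% 2),
                  strrep(snv_alt[covered], ceiling(snv_n[covered] / 2)),
                  strrep(tolower(snv_alt[covered]), snv_n[covered] %/% 2),
                  strrep(var_tok[covered], var_tok_n[covered]),
                  strrep(err_alt[covered], err_n[covered]))
  if (decorate) {
    starts <- stats::runif(length(covered)) < 0.15
    ends <- stats::runif(length(covered)) < 0.15
    bases <- paste0(ifelse(starts, "^!", ""), bases, ifelse(ends, "$", ""))
  }
  lines <- sprintf("%s\t%s\t%s\t%d\t%s\t%s", contig,
                   format_pos(covered),   # covered is already 1-based
                   refv[covered], depth[covered], bases,
                   strrep("I", depth[covered]))
  elog <- which(err_n > 0L)
  list(lines = lines,
       error_log = data.frame(contig = rep(contig, length(elog)),
                              position = as.numeric(elog - 1L),
                              alt = err_alt[elog], count = err_n[elog]))
}

# Draw planted variants for one contig: SNVs at snv_rate, indels at
# indel_rate (split evenly, insertions of 1-3 random bases, deletions of
# 1-2 reference bases), at most one variant per locus.
draw_planted <- function(seq, depth, snv_rate, indel_rate, min_count = 1L,
                         allele_fraction = 0.5) {
  L <- nchar(seq)
  refv <- strsplit(seq, "")[[1]]
  u <- stats::runif(L)
  snv_at <- which(u < snv_rate)
  ind_at <- which(u >= snv_rate & u < snv_rate + indel_rate & seq_len(L) < L - 3L)
  rows <- list()
  for (p in snv_at) {
    alt <- sample(setdiff(c("A", "C", "G", "T"), refv[p]), 1L)
    rows[[length(rows) + 1L]] <- list(pos0 = p - 1, type = "SNV",
                                      ref = refv[p], alt = alt)
  }
  for (p in ind_at) {
    if (stats::runif(1) < 0.5) {
      ins <- paste(sample(c("A", "C", "G", "T"),
                          sample(1:3, 1L), replace = TRUE), collapse = "")
      rows[[length(rows) + 1L]] <- list(pos0 = p - 1, type = "INSERTION",
                                        ref = "", alt = ins)
    } else {
      dlen <- sample(1:2, 1L)
      del <- substr(seq, p + 1L, p + dlen)
      rows[[length(rows) + 1L]] <- list(pos0 = p - 1, type = "DELETION",
                                        ref = del, alt = "")
    }
  }
  if (length(rows) == 0L) {
    return(data.frame(pos0 = numeric(0), type = character(0),
                      ref = character(0), alt = character(0),
                      count = integer(0)))
  }
  df <- do.call(rbind, lapply(rows, function(r) {
    data.frame(pos0 = r$pos0, type = r$type, ref = r$ref, alt = r$alt)
  }))
  d <- pmax(depth[df$pos0 + 1L], 2L)
  cnt <- pmax(min_count, stats::rbinom(nrow(df), d, allele_fraction))
  df$count <- pmin(cnt, d)
  df
}

#' Generate a pileup stream with a known truth set
#'
#' Per-base depths are Poisson around `mean_depth` (floored at 1 where a
#' variant is planted); SNVs are planted at `snv_rate` and short indels at
#' `indel_rate` per base with supporting-read counts drawn binomially at
#' `allele_fraction`; sequencing-error alleles are injected at `error_rate`
#' per read at non-variant positions and logged. Emitted lines satisfy the
#' pileup grammar and the token-conservation invariant, including read
#' start (`^X`) and end (`$`) decorations.
#'
#' @param reference Named list of contig sequences ([generate_reference()]).
#' @param mean_depth Mean per-base read depth.
#' @param snv_rate,indel_rate Per-base planting probabilities.
#' @param error_rate Per-read error probability at non-variant positions.
#' @param seed RNG seed.
#' @param allele_fraction Expected fraction of reads carrying a planted
#'   allele.
#' @return A list: `lines` (the pileup, sorted by contig and position) and
#'   `truth` with `variants` (data frame: contig, position (0-based), type,
#'   ref, alt, observation_count), `depth_map` (per-contig integer vector,
#'   0 = uncovered) and `error_log` (contig, position, alt, count).
#' @export
generate_pileup <- function(reference, mean_depth = 20, snv_rate = 1e-3,
                            indel_rate = 1e-4, error_rate = 0, seed = 42L,
                            allele_fraction = 0.5) {
  stopifnot(mean_depth >= 1, snv_rate >= 0, snv_rate < 1,
            indel_rate >= 0, indel_rate < 1, error_rate >= 0, error_rate < 1)
  with_seed(seed, {
    all_lines <- character(0)
    truth_vars <- list(); depth_map <- list(); elogs <- list()
    for (ct in names(reference)) {
      seq <- reference[[ct]]
      L <- nchar(seq)
      depth <- stats::rpois(L, mean_depth)
      planted <- draw_planted(seq, depth, snv_rate, indel_rate,
                              allele_fraction = allele_fraction)
      if (nrow(planted)) {
        depth[planted$pos0 + 1L] <- pmax(depth[planted$pos0 + 1L],
                                         planted$count)
      }
      built <- build_contig_pileup(ct, seq, depth, planted, error_rate)
      all_lines <- c(all_lines, built$lines)
      if (nrow(planted)) {
        truth_vars[[ct]] <- data.frame(contig = ct,
                                       position = planted$pos0,
                                       type = planted$type,
                                       ref = planted$ref, alt = planted$alt,
                                       observation_count = planted$count)
      }
      depth_map[[ct]] <- depth
      elogs[[ct]] <- built$error_log
    }
    variants <- if (length(truth_vars)) do.call(rbind, truth_vars) else
      data.frame(contig = character(0), position = numeric(0),
                 type = character(0), ref = character(0), alt = character(0),
                 observation_count = integer(0))
    rownames(variants) <- NULL
    elog <- do.call(rbind, elogs)
    rownames(elog) <- NULL
    list(lines = all_lines,
         truth = list(variants = variants, depth_map = depth_map,
                      error_log = elog))
  })
}

#' Generate a tumor/normal pileup pair with known somatic truth
#'
#' Plants `germline_n` variants present in both genomes and `somatic_n`
#' present only in the tumor, at distinct loci (80% SNVs, the rest split
#' between short insertions and deletions). Planted supporting-read counts
#' satisfy the default [somatic_criteria()] by construction (count >= 4 and
#' allele fraction >= 0.1), and the normal's depth at every somatic locus is
#' floored at `normal_floor` so that detector completeness is testable.
#'
#' @param reference Named list of contig sequences.
#' @param germline_n,somatic_n Numbers of planted variants.
#' @param mean_depth Mean per-base depth in both genomes.
#' @param seed RNG seed.
#' @param normal_floor Minimum normal depth at somatic loci.
#' @param error_rate Per-read error probability (both genomes).
#' @return A list: `normal_lines`, `tumor_lines`, and `truth` with
#'   `variants` (with a `subset` column, `"germline"` or `"somatic"`),
#'   `somatic_subset`, `germline_subset`, per-genome `depth_map` and
#'   `error_log` entries.
#' @export
generate_tumor_normal <- function(reference, germline_n = 200L,
                                  somatic_n = 50L, mean_depth = 30,
                                  seed = 42L, normal_floor = 10L,
                                  error_rate = 0) {
  stopifnot(germline_n >= 0, somatic_n >= 0)
  with_seed(seed, {
    # lay all planted loci out across contigs, distinct and clear of ends
    lens <- vapply(reference, nchar, 0)
    total <- germline_n + somatic_n
    ct_of <- sample(rep(names(reference), ceiling(total * lens / sum(lens)) + 1L),
                    total)
    planted_all <- list()
    used <- lapply(reference, function(x) integer(0))
    for (i in seq_len(total)) {
      ct <- ct_of[i]
      repeat {
        p <- sample.int(lens[[ct]] - 4L, 1L)
        if (!(p %in% used[[ct]])) break
      }
      used[[ct]] <- c(used[[ct]], p)
      refv <- substr(reference[[ct]], p, p)
      r <- stats::runif(1)
      if (r < 0.8) {
        row <- list(type = "SNV", ref = refv,
                    alt = sample(setdiff(c("A", "C", "G", "T"), refv), 1L))
      } else if (r < 0.9) {
        row <- list(type = "INSERTION", ref = "",
                    alt = paste(sample(c("A", "C", "G", "T"),
                                       sample(1:2, 1L), replace = TRUE),
                                collapse = ""))
      } else {
        row <- list(type = "DELETION",
                    ref = substr(reference[[ct]], p + 1L, p + sample(1:2, 1L)),
                    alt = "")
      }
      planted_all[[i]] <- data.frame(contig = ct, pos0 = p - 1,
                                     type = row$type, ref = row$ref,
                                     alt = row$alt,
                                     subset = if (i <= germline_n) "germline"
                                              else "somatic")
    }
    planted_all <- if (total) do.call(rbind, planted_all) else
      data.frame(contig = character(0), pos0 = numeric(0),
                 type = character(0), ref = character(0), alt = character(0),
                 subset = character(0))

    build_genome <- function(which_subsets, floor_at = NULL) {
      lines <- character(0); dmap <- list(); elog <- list()
      counts <- numeric(nrow(planted_all))
      for (ct in names(reference)) {
        L <- lens[[ct]]
        depth <- stats::rpois(L, mean_depth)
        sel <- planted_all$contig == ct & planted_all$subset %in% which_subsets
        pl <- planted_all[sel, , drop = FALSE]
        if (nrow(pl)) {
          d <- pmax(depth[pl$pos0 + 1L], 8L)
          cnt <- pmax(pmax(4L, ceiling(0.12 * d)),
                      stats::rbinom(nrow(pl), d, 0.5))
          pl$count <- pmin(cnt, d)
          depth[pl$pos0 + 1L] <- pmax(d, pl$count)
          counts[which(sel)] <- pl$count
        } else {
          pl$count <- integer(0)
        }
        if (!is.null(floor_at)) {
          fl <- planted_all$contig == ct & !(planted_all$subset %in% which_subsets)
          depth[planted_all$pos0[fl] + 1L] <-
            pmax(depth[planted_all$pos0[fl] + 1L], floor_at)
        }
        built <- build_contig_pileup(ct, reference[[ct]], depth, pl,
                                     error_rate)
        lines <- c(lines, built$lines)
        dmap[[ct]] <- depth
        elog[[ct]] <- built$error_log
      }
      list(lines = lines, depth_map = dmap,
           error_log = do.call(rbind, elog), counts = counts)
    }

    tumor <- build_genome(c("germline", "somatic"))
    normal <- build_genome("germline", floor_at = normal_floor)

    variants <- data.frame(contig = planted_all$contig,
                           position = planted_all$pos0,
                           type = planted_all$type, ref = planted_all$ref,
                           alt = planted_all$alt,
                           subset = planted_all$subset,
                           tumor_count = tumor$counts,
                           normal_count = normal$counts)
    rownames(variants) <- NULL
    list(normal_lines = normal$lines, tumor_lines = tumor$lines,
         truth = list(
           variants = variants,
           somatic_subset = variants[variants$subset == "somatic", , drop = FALSE],
           germline_subset = variants[variants$subset == "germline", , drop = FALSE],
           depth_map = list(tumor = tumor$depth_map,
                            normal = normal$depth_map),
           error_log = list(tumor = tumor$error_log,
                            normal = normal$error_log)))
  })
}

#' Generate a random tagged variant set
#'
#' Variants at distinct loci with random types, alleles, depths, p-values
#' and tags drawn from a small annotation-style pool — the fixture behind
#' query/filter, tag-index and capacity exercises. Returned as a data frame
#' ready for [write_variant_frame()].
#'
#' @param n Number of variants.
#' @param contig_lengths Named vector of contig lengths.
#' @param genome_label Genome label for the set.
#' @param seed RNG seed.
#' @param tag_pool Tag keys to draw from.
#' @param mean_tags Mean number of tags per variant (Poisson).
#' @return A data frame with one row per variant; `tags` holds the encoded
#'   tag map (see [write_variant_frame()]).
#' @export
generate_variants <- function(n, contig_lengths = c(chr1 = 1e6, chr2 = 1e6),
                              genome_label = "genome1", seed = 1L,
                              tag_pool = c("dbSNP", "genic", "missense",
                                           "validated", "repeat"),
                              mean_tags = 1.2) {
  with_seed(seed, {
    ct <- sample(names(contig_lengths), n, replace = TRUE,
                 prob = contig_lengths / sum(contig_lengths))
    draw_pos <- function(cts) floor(stats::runif(length(cts)) *
                                      contig_lengths[cts])
    pos <- draw_pos(ct)
    key <- paste0(ct, ":", pos)
    while (anyDuplicated(key)) {          # distinct loci
      dup <- duplicated(key)
      pos[dup] <- draw_pos(ct[dup])
      key <- paste0(ct, ":", pos)
    }
    type <- sample(c("SNV", "INSERTION", "DELETION"), n, replace = TRUE,
                   prob = c(0.85, 0.08, 0.07))
    bases <- c("A", "C", "G", "T")
    ref <- sample(bases, n, replace = TRUE)
    alt <- bases[(match(ref, bases) - 1L + sample(1:3, n, replace = TRUE)) %% 4L + 1L]
    ins <- type == "INSERTION"; del <- type == "DELETION"
    ref[ins] <- ""
    alt[del] <- ""
    depth <- stats::rpois(n, 25) + 1L
    obs <- pmin(depth, pmax(1L, stats::rbinom(n, depth, 0.4)))
    pval <- signif(stats::runif(n), 4)
    ntags <- if (mean_tags > 0) stats::rpois(n, mean_tags) else integer(n)
    tags <- character(n)
    for (i in which(ntags > 0L)) {
      k <- sample(tag_pool, min(ntags[i], length(tag_pool)))
      tags[i] <- encode_tags(structure(
        ifelse(stats::runif(length(k)) < 0.5, "",
               as.character(sample(1:99, length(k), replace = TRUE))),
        names = sort(k)))
    }
    stp <- pos + 1
    stp[del] <- pos[del] + 2
    data.frame(contig = ct, position = pos, stop = stp, type = type,
               ref_allele = ref, alt_allele = alt, observation_count = obs,
               depth = depth, p_value = pval, tags = tags,
               genome_label = genome_label, version = 1L,
               stringsAsFactors = FALSE)
  })
}

#' Write a variant data frame through the store interface
#'
#' Each row becomes a [variant()] written with [write_variant()] (tags are
#' decoded from the frame's encoded `tags` column). With `fast = TRUE` rows
#' are bulk-encoded and written with the same key layout, record encoding
#' and index entries as the per-object path, skipping per-object
#' construction — the path used for capacity-scale loads. Rows must then be
#' at distinct loci per genome (versions are all 1).
#'
#' @param store A `qe_store`.
#' @param df A frame from [generate_variants()].
#' @param fast Use the vectorised bulk path.
#' @return Number of variants written, invisibly.
#' @export
write_variant_frame <- function(store, df, fast = FALSE) {
  if (!fast) {
    for (i in seq_len(nrow(df))) {
      v <- variant(contig = df$contig[i], position = df$position[i],
                   stop = df$stop[i], type = df$type[i],
                   ref_allele = df$ref_allele[i], alt_allele = df$alt_allele[i],
                   observation_count = df$observation_count[i],
                   depth = df$depth[i], p_value = df$p_value[i],
                   tags = decode_tags(df$tags[i]),
                   genome_label = df$genome_label[i],
                   version = df$version[i])
      write_variant(store, v, auto_version = TRUE)
    }
    return(invisible(nrow(df)))
  }
  # bulk path: vectorised encode, direct slot assignment, version 1
  assert_open(store)
  for (ct in unique(df$contig)) contig_index(store, ct, register = TRUE)
  for (lb in unique(df$genome_label)) register_genome(store, lb)
  ci <- vapply(df$contig, function(ct) store$contigs[[ct]], 0L)
  rhex <- row_key_hex(ci, df$position)
  gkeys <- paste0(rhex, GROUP_SEP, "variant")
  if (anyDuplicated(paste0(gkeys, "\x01", df$genome_label))) {
    stop("bulk write requires distinct loci per genome", call. = FALSE)
  }
  values <- encode_variant_vec(df$type, df$contig, df$position, df$stop,
                               df$ref_allele, df$alt_allele,
                               df$observation_count, df$depth, df$p_value,
                               df$tags, df$genome_label, 1L)
  te <- table_env(store, "primary", create = TRUE)
  cells <- te$cells
  labels <- df$genome_label
  for (i in seq_along(gkeys)) {
    k <- gkeys[i]
    cell <- list(label = labels[i], version = 1L, value = values[i])
    cur <- cells[[k]]
    cells[[k]] <- if (is.null(cur)) list(cell) else c(cur, list(cell))
  }
  te$dirty <- TRUE
  tagged <- which(nzchar(df$tags))
  for (i in tagged) {
    index_object(store, decode_tags(df$tags[i]),
                 object_id_string(df$contig[i], df$position[i], labels[i], 1L),
                 "primary", rhex[i], labels[i])
  }
  invisible(nrow(df))
}
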