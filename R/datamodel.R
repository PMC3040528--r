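# Domain types. Plain classed lists (as in most Bioconductor-era tooling the
# hot paths construct millions of these, so construction stays cheap);
# invariants are enforced here and nowhere else.

VARIANT_TYPES <- c("SNV", "INSERTION", "DELETION", "SV", "TRANSLOCATION")
PRIMARY_FAMILIES <- c("variant", "coverage", "feature", "consequence")

#' Reference locus
#'
#' A contig name plus a 0-based base offset; the source of every row key.
#' All internal coordinates in the package are 0-based, half-open. Pileup
#' (1-based), GFF (1-based inclusive) and WIG (1-based) are converted at the
#' I/O boundary; BED is already 0-based half-open.
#'
#' @param contig Contig name; non-empty, no tab, newline or NUL byte.
#' @param position 0-based base offset, `>= 0`.
#' @return An object of class `qe_locus`.
#' @export
reference_locus <- function(contig, position) {
  check_contig(contig)
  if (!is.numeric(position) || length(position) != 1L || is.na(position) ||
      position < 0 || position != floor(position)) {
    stop("position must be a single non-negative integer", call. = FALSE)
  }
  structure(list(contig = contig, position = as.numeric(position)),
            class = "qe_locus")
}

check_contig <- function(contig) {
  if (!is.character(contig) || length(contig) != 1L || is.na(contig) ||
      !nzchar(contig) || grepl("[\t\n\r]", contig)) {
    stop("contig must be a non-empty string without tab/newline", call. = FALSE)
  }
  invisible(TRUE)
}

check_label <- function(label) {
  if (!is.character(label) || length(label) != 1L || is.na(label) ||
      !nzchar(label) || grepl("[\t\n\r\x01]", label)) {
    stop("genome label must be a non-empty string without control characters",
         call. = FALSE)
  }
  invisible(TRUE)
}

# Tag maps are named character vectors: names are tag keys, values tag
# values. A bare tag is a key with an empty-string value. An unnamed
# character vector is promoted to bare tags.
as_tag_map <- function(tags) {
  if (is.null(tags) || length(tags) == 0L) return(structure(character(0), names = character(0)))
  if (!is.character(tags)) stop("tags must be a (named) character vector", call. = FALSE)
  if (is.null(names(tags))) {
    tags <- structure(rep("", length(tags)), names = tags)
  } else if (any(!nzchar(names(tags)))) {
    # entries with empty names are bare tags given positionally
    nm <- names(tags)
    bare <- !nzchar(nm)
    nm[bare] <- tags[bare]
    tags[bare] <- ""
    names(tags) <- nm
  }
  if (any(!nzchar(names(tags))) ||
      any(grepl("[\x01-\x1f]", names(tags)))) {
    stop("tag keys must be non-empty and contain no control bytes", call. = FALSE)
  }
  if (anyDuplicated(names(tags))) stop("duplicate tag keys", call. = FALSE)
  tags
}

#' Construct a variant record
#'
#' A typed variant call (SNV, insertion, deletion, structural variant or
#' translocation breakend) with its supporting read counts, optional call
#' p-value, and free-form tags. `(locus, genome_label, version)` uniquely
#' identifies a stored variant; co-located variants in one genome are told
#' apart by `version` (the cell-version analogue of a BigTable timestamp).
#' Translocations are stored one record per breakend; name the partner in a
#' `mate` tag.
#'
#' @param contig,position Locus (0-based).
#' @param stop 0-based exclusive end; for an SNV this must be `position + 1`.
#' @param type One of `r paste(VARIANT_TYPES, collapse = ", ")`.
#' @param ref_allele,alt_allele Reference and alternate alleles; `alt_allele`
#'   is empty for a pure deletion, `ref_allele` empty for a pure insertion.
#' @param observation_count Reads supporting the alternate allele.
#' @param depth Total reads at the locus; `>= observation_count`.
#' @param p_value Call p-value in `[0, 1]`, or `NA` when absent.
#' @param tags Named character vector of tag key/value pairs (values may be
#'   empty; a bare unnamed string becomes a bare tag).
#' @param genome_label Genome the call belongs to (column-family label).
#' @param version Integer `>= 1`; assigned in load order when written via
#'   [write_variant()] with `auto_version = TRUE`.
#' @return An object of class `qe_variant`.
#' @export
variant <- function(contig, position, stop = position + 1, type = "SNV",
                    ref_allele, alt_allele, observation_count, depth,
                    p_value = NA_real_, tags = character(),
                    genome_label, version = 1L) {
  check_contig(contig); check_label(genome_label)
  type <- match.arg(type, VARIANT_TYPES)
  if (position < 0 || position != floor(position)) {
    stop("position must be a non-negative integer", call. = FALSE)
  }
  if (type %in% c("SNV")) {
    if (stop != position + 1) stop("SNV must have stop == position + 1", call. = FALSE)
    if (nchar(ref_allele) != 1L || nchar(alt_allele) != 1L) {
      stop("SNV alleles must be single bases", call. = FALSE)
    }
    if (toupper(ref_allele) == toupper(alt_allele)) {
      stop("SNV alt allele must differ from the reference base", call. = FALSE)
    }
  } else if (stop <= position && type != "INSERTION") {
    stop("stop must exceed position for ranged variant types", call. = FALSE)
  }
  if (observation_count < 0) stop("observation_count must be >= 0", call. = FALSE)
  if (depth < observation_count) {
    stop("depth must be >= observation_count", call. = FALSE)
  }
  if (!is.na(p_value) && (p_value < 0 || p_value > 1)) {
    stop("p_value must lie in [0, 1]", call. = FALSE)
  }
  if (version < 1) stop("version must be >= 1", call. = FALSE)
  structure(list(contig = contig, position = as.numeric(position),
                 stop = as.numeric(stop), type = type,
                 ref_allele = ref_allele, alt_allele = alt_allele,
                 observation_count = as.integer(observation_count),
                 depth = as.integer(depth), p_value = as.numeric(p_value),
                 tags = as_tag_map(tags), genome_label = genome_label,
                 version = as.integer(version)),
            class = "qe_variant")
}

#' Construct a per-base coverage block
#'
#' Coverage is stored as sparse per-base depths over fixed-width genomic
#' windows ("a user-defined range of bases"), one block per
#' `(window, genome)`. Uncovered bases are simply absent — never stored as 0.
#'
#' @param contig Contig name.
#' @param block_start 0-based window start; must be a multiple of `block_size`.
#' @param block_size Window width in bases.
#' @param offsets Integer in-block offsets (`0 <= offset < block_size`) of
#'   covered bases.
#' @param depths Read depths (`>= 1`), parallel to `offsets`.
#' @param genome_label Genome the coverage belongs to.
#' @return An object of class `qe_coverage_block`.
#' @export
coverage_block <- function(contig, block_start, block_size, offsets, depths,
                           genome_label) {
  check_contig(contig); check_label(genome_label)
  if (block_start %% block_size != 0) {
    stop("block_start must be a multiple of block_size", call. = FALSE)
  }
  offsets <- as.integer(offsets); depths <- as.integer(depths)
  if (length(offsets) != length(depths)) {
    stop("offsets and depths must be parallel vectors", call. = FALSE)
  }
  if (length(offsets) && (any(offsets < 0) || any(offsets >= block_size))) {
    stop("offsets must lie in [0, block_size)", call. = FALSE)
  }
  if (any(depths < 1)) stop("stored depths must be >= 1 (omit uncovered bases)", call. = FALSE)
  if (anyDuplicated(offsets)) stop("duplicate offsets in coverage block", call. = FALSE)
  o <- order(offsets)
  structure(list(contig = contig, block_start = as.numeric(block_start),
                 block_size = as.integer(block_size),
                 offsets = offsets[o], depths = depths[o],
                 genome_label = genome_label),
            class = "qe_coverage_block")
}

#' Construct a genomic feature
#'
#' Any location-based annotation on the genome (BED/GFF intervals and the
#' like): a half-open interval with a name, optional score and strand, and
#' free-form tags.
#'
#' @inheritParams variant
#' @param name Feature name.
#' @param score Numeric score or `NA`.
#' @param strand `"+"`, `"-"` or `"."` (unknown).
#' @return An object of class `qe_feature`.
#' @export
feature <- function(contig, position, stop, name = "", score = NA_real_,
                    strand = ".", tags = character(), genome_label,
                    version = 1L) {
  check_contig(contig); check_label(genome_label)
  if (stop <= position) stop("feature stop must exceed position", call. = FALSE)
  strand <- match.arg(strand, c(".", "+", "-"))
  structure(list(contig = contig, position = as.numeric(position),
                 stop = as.numeric(stop), name = name,
                 score = as.numeric(score), strand = strand,
                 tags = as_tag_map(tags), genome_label = genome_label,
                 version = as.integer(version)),
            class = "qe_feature")
}

#' Construct a coding-consequence annotation
#'
#' A consequence (e.g. missense, synonymous) that links back to the variant
#' it reports on via the `(locus, genome_label, variant_version)` triple.
#'
#' @inheritParams variant
#' @param effect Consequence class, e.g. `"missense"`.
#' @param gene Gene symbol or `NA`.
#' @param variant_version Version of the annotated variant at the same locus
#'   and genome label.
#' @return An object of class `qe_consequence`.
#' @export
consequence <- function(contig, position, effect, gene = NA_character_,
                        variant_version = 1L, tags = character(),
                        genome_label, version = 1L) {
  check_contig(contig); check_label(genome_label)
  if (!nzchar(effect)) stop("effect must be non-empty", call. = FALSE)
  structure(list(contig = contig, position = as.numeric(position),
                 effect = effect, gene = gene,
                 variant_version = as.integer(variant_version),
                 tags = as_tag_map(tags), genome_label = genome_label,
                 version = as.integer(version)),
            class = "qe_consequence")
}

#' Opaque, stable identifier of a stored variant
#'
#' Deterministic and injective over `(locus, genome_label, version)`: used as
#' the object-ID component of secondary (tag) index keys. The encoding joins
#' the four components with a tab, which neither contigs nor labels may
#' contain, so distinct triples can never collide.
#'
#' @param v A `qe_variant` (or any object with `contig`, `position`,
#'   `genome_label` and `version` fields).
#' @return A raw vector (byte string).
#' @export
variant_id <- function(v) {
  if (is.null(v$contig) || is.null(v$position) || is.null(v$genome_label) ||
      is.null(v$version)) {
    stop("variant_id requires locus, genome_label and version to be set",
         call. = FALSE)
  }
  charToRaw(object_id_string(v$contig, v$position, v$genome_label, v$version))
}

# Character form used internally for index keys (R strings cannot hold NUL,
# raw keys live only at the API edge).
object_id_string <- function(contig, position, label, version) {
  paste(contig, format_pos(position), label, version, sep = "\t")
}

format_pos <- function(p) {
  # positions are doubles; print without scientific notation
  formatC(p, format = "f", digits = 0)
}

#' @export
print.qe_variant <- function(x, ...) {
  cat(sprintf("<variant %s %s:%s %s>%s obs=%d depth=%d genome=%s v%d\n",
              x$type, x$contig, format_pos(x$position),
              if (nzchar(x$ref_allele)) x$ref_allele else "-",
              if (nzchar(x$alt_allele)) x$alt_allele else "-",
              x$observation_count, x$depth, x$genome_label, x$version))
  invisible(x)
}

#' @export
print.qe_coverage_block <- function(x, ...) {
  cat(sprintf("<coverage block %s:%s (+%d bases) %d covered, genome=%s>\n",
              x$contig, format_pos(x$block_start), x$block_size,
              length(x$offsets), x$genome_label))
  invisible(x)
}
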