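# Core data containers: genome_record, feature_location, feature_instance.
# Coordinates are 1-based inclusive everywhere (GenBank convention); any
# half-open conversion is confined to the geometry code.

#' Construct a feature location
#'
#' A location is an ordered set of `(start, end)` parts on one strand.
#' Within each part `start <= end`; a feature that spans the sequence
#' origin of a circular record is represented as two or more parts with
#' `wraps_origin = TRUE` (the later parts restart at position 1).
#'
#' @param parts Two-column integer matrix (start, end), one row per part.
#' @param strand `"+"` or `"-"`.
#' @param wraps_origin Logical; `TRUE` when the parts run across the
#'   sequence origin.
#' @return An object of class `feature_location`.
#' @export
feature_location <- function(parts, strand = "+", wraps_origin = FALSE) {
  parts <- matrix(as.integer(parts), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  stopifnot(nrow(parts) >= 1L, strand %in% c("+", "-"))
  bad <- parts[, 1L] > parts[, 2L]
  if (any(bad)) {
    orgmapr_stop("orgmapr_parse_error",
                 sprintf("location part %d has start > end", which(bad)[1L]))
  }
  if (wraps_origin && nrow(parts) < 2L) {
    orgmapr_stop("orgmapr_parse_error",
                 "an origin-spanning location needs >= 2 parts")
  }
  structure(list(parts = parts, strand = strand,
                 wraps_origin = isTRUE(wraps_origin)),
            class = "feature_location")
}

#' Total span length of a location in bp
#'
#' Sum of `end - start + 1` over all parts (exonic length, gaps excluded).
#'
#' @param loc A [feature_location()].
#' @return Integer number of bases covered by the parts.
#' @export
location_span <- function(loc) {
  sum(loc$parts[, 2L] - loc$parts[, 1L] + 1L)
}

# genomic extent actually drawn: first start to last end, through the
# origin when the location wraps
location_extent <- function(loc, length_bp) {
  s <- loc$parts[1L, 1L]
  e <- loc$parts[nrow(loc$parts), 2L]
  len <- if (loc$wraps_origin) (length_bp - s + 1L) + e else e - s + 1L
  list(start = s, end = e, length = as.integer(len))
}

#' Construct a feature instance
#'
#' One drawable GenBank annotation: its feature key, optional gene and
#' product names, location and raw qualifiers.
#'
#' @param key GenBank feature key (e.g. `gene`, `CDS`, `tRNA`, `D-loop`).
#' @param location A [feature_location()].
#' @param gene Optional gene name (from the `/gene` qualifier).
#' @param product Optional product name.
#' @param qualifiers Named character vector of raw qualifiers.
#' @return An object of class `feature_instance`.
#' @export
feature_instance <- function(key, location, gene = NULL, product = NULL,
                             qualifiers = character()) {
  stopifnot(is.character(key), nzchar(key))
  stopifnot(inherits(location, "feature_location"))
  structure(list(key = key, gene = gene, product = product,
                 location = location, qualifiers = qualifiers),
            class = "feature_instance")
}

#' Construct a genome record
#'
#' One parsed GenBank record. `topology` and `source_category` are always
#' resolved (never unknown); `sequence` may be the empty string for
#' records without an ORIGIN block, in which case sequence-dependent
#' operations (GC profile, restriction scan, de novo repeat search)
#' refuse to run.
#'
#' @param accession Accession or locus name.
#' @param length_bp Sequence length in bp.
#' @param sequence Nucleotide string over the IUPAC alphabet (may be `""`).
#' @param topology `"circular"` or `"linear"`.
#' @param source_category `"plastid"`, `"mitochondrial"` or `"other"`.
#' @param features List of [feature_instance()] objects, in file order.
#' @param organism,definition Free-text metadata.
#' @return An object of class `genome_record`.
#' @export
genome_record <- function(accession, length_bp, sequence = "",
                          topology = c("linear", "circular"),
                          source_category = c("other", "plastid",
                                              "mitochondrial"),
                          features = list(), organism = "",
                          definition = "") {
  topology <- match.arg(topology)
  source_category <- match.arg(source_category)
  length_bp <- as.integer(length_bp)
  stopifnot(length_bp >= 1L)
  if (nzchar(sequence) && nchar(sequence) != length_bp) {
    orgmapr_stop("orgmapr_parse_error", sprintf(
      "sequence length (%d) disagrees with declared length (%d) for %s",
      nchar(sequence), length_bp, accession))
  }
  for (f in features) {
    if (any(f$location$parts < 1L) || any(f$location$parts > length_bp)) {
      orgmapr_stop("orgmapr_parse_error", sprintf(
        "feature '%s' has coordinates outside [1, %d] in %s",
        f$key, length_bp, accession))
    }
  }
  structure(list(accession = accession, organism = organism,
                 definition = definition, length_bp = length_bp,
                 topology = topology, source_category = source_category,
                 sequence = sequence, features = features),
            class = "genome_record")
}

#' @export
print.genome_record <- function(x, ...) {
  cat(sprintf("<genome_record> %s: %s bp, %s, %s, %d features\n",
              x$accession, format(x$length_bp, big.mark = ","),
              x$topology, x$source_category, length(x$features)))
  invisible(x)
}

#' @export
print.feature_instance <- function(x, ...) {
  parts <- apply(x$location$parts, 1L,
                 function(p) sprintf("%d..%d", p[1L], p[2L]))
  cat(sprintf("<feature> %s %s [%s] strand %s%s\n", x$key,
              x$gene %||% "", paste(parts, collapse = ","),
              x$location$strand,
              if (x$location$wraps_origin) " (wraps origin)" else ""))
  invisible(x)
}
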