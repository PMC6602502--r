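# Feature classification: map each drawable annotation onto exactly one
# feature class of the active configuration.

#' Classify a single feature
#'
#' The class is chosen by first match in configuration order: a per-gene
#' override or an explicit gene-name pattern wins; otherwise the feature
#' key decides (tRNA -> trna, rRNA -> rrna, D-loop -> dloop,
#' prim_transcript/operon -> operon, intron -> intron); otherwise the
#' catch-all `other` class. The display name is the tidied gene name,
#' suffixed with `*` when the gene contains an intron and the intron
#' style is `asterisk`. A feature is `suppressed` when its class is
#' disabled, when tidy-up rejected its name, or (transcript mode with a
#' per-gene selection) when its gene is deselected.
#'
#' @param feature A [feature_instance()].
#' @param config A [default_config()] (possibly overridden).
#' @param has_intron Whether the owning gene has an intron (computed by
#'   [classify_features()] from the record context).
#' @return An object of class `classified_feature` with fields
#'   `feature`, `class_id`, `color`, `display_name`, `has_intron`,
#'   `suppressed`.
#' @export
classify_feature <- function(feature, config, has_intron = FALSE) {
  tid <- tidy_gene_name(feature$gene %||% NA_character_,
                        tidy_up = config$tidy_up,
                        max_len = config$tidy_max_len)
  name <- tid$name
  class_id <- NULL
  color <- NULL
  display <- if (!is.na(name)) name else ""

  ov <- if (!is.na(name)) config$gene_overrides[[name]] else NULL
  if (!is.null(ov)) {
    if (!is.null(ov$class)) class_id <- ov$class
    if (!is.null(ov$color)) color <- toupper(ov$color)
    if (!is.null(ov$product)) display <- ov$product
  }

  if (is.null(class_id) && !is.na(name) && nzchar(name)) {
    for (cls in config$classes) {
      if (length(cls$patterns) &&
          any(vapply(cls$patterns, grepl, logical(1L), x = name))) {
        class_id <- cls$class_id
        break
      }
    }
  }
  if (is.null(class_id)) {
    for (cls in config$classes) {
      if (feature$key %in% cls$keys) {
        class_id <- cls$class_id
        break
      }
    }
  }
  if (is.null(class_id)) class_id <- "other"
  cls <- config$classes[[class_id]]
  if (is.null(color)) color <- if (!is.null(cls)) cls$color else "#D3D3D3"

  if (has_intron && identical(config$intron_style, "asterisk") &&
      nzchar(display)) {
    display <- paste0(display, "*")
  }

  suppressed <- tid$rejected ||
    (!is.null(cls) && !cls$enabled) ||
    (identical(config$mode, "transcript") && !is.null(config$enabled_genes) &&
       !is.na(name) && !(name %in% config$enabled_genes))

  structure(list(feature = feature, class_id = class_id, color = color,
                 gene = if (is.na(name)) NULL else name,
                 display_name = display, has_intron = has_intron,
                 suppressed = suppressed),
            class = "classified_feature")
}

# keys that are drawn on their own even without a gene name
STANDALONE_KEYS <- c("D-loop", "D_loop", "prim_transcript", "operon",
                     "rep_origin", "oriC", "misc_feature", "mRNA", "CDS",
                     "tRNA", "rRNA")

#' Classify all drawable features of a record
#'
#' Groups annotations by gene name (the `gene` feature supplies the
#' drawn extent, a `CDS`/`tRNA`/`rRNA` child supplies the key and exon
#' structure), detects introns (a gene has an intron iff its
#' CDS/tRNA/rRNA location has two or more parts, or an `intron` feature
#' lies within its extent), and classifies stand-alone features
#' (D-loop, operons, origins, and any key the configuration makes
#' drawable). `source` and bare `intron`/`repeat_region` features
#' produce no drawable element of their own.
#'
#' @param record A [genome_record()].
#' @param config A [default_config()] (possibly overridden).
#' @return List of `classified_feature` objects in coordinate order.
#' @export
classify_features <- function(record, config) {
  feats <- record$features
  if (length(feats) == 0L) return(list())
  keys <- vapply(feats, `[[`, character(1L), "key")
  genes <- vapply(feats, function(f) f$gene %||% NA_character_, character(1L))

  drawable_keys <- unique(c(unlist(lapply(config$classes, `[[`, "keys")),
                            STANDALONE_KEYS))
  out <- list()

  intron_feats <- feats[keys == "intron"]

  seen_genes <- character()
  for (i in seq_along(feats)) {
    f <- feats[[i]]
    if (f$key %in% c("source", "intron", "repeat_region")) next
    g <- genes[i]
    if (!is.na(g)) {
      if (g %in% seen_genes) next
      seen_genes <- c(seen_genes, g)
      group <- feats[!is.na(genes) & genes == g]
      gkeys <- vapply(group, `[[`, character(1L), "key")
      # standalone transcription-unit keys are classified on their own
      if (all(gkeys %in% c("operon", "prim_transcript", "D-loop", "D_loop"))) {
        rep_feat <- group[[1L]]
        out[[length(out) + 1L]] <- classify_feature(rep_feat, config)
        next
      }
      gene_feat <- group[gkeys == "gene"]
      specific <- group[gkeys %in% c("CDS", "tRNA", "rRNA", "mRNA")]
      loc_owner <- if (length(gene_feat)) gene_feat[[1L]] else group[[1L]]
      key_owner <- if (length(specific)) specific[[1L]] else loc_owner
      # keep the exon structure when the child feature has one (for
      # intron-gap drawing); the overall extent is the same
      if (length(specific) && nrow(specific[[1L]]$location$parts) >= 2L) {
        loc_owner <- specific[[1L]]
      }
      has_intron <- any(vapply(specific, function(s) nrow(s$location$parts) >= 2L,
                               logical(1L))) ||
        any(vapply(intron_feats, function(ir) {
          within_extent(ir$location, loc_owner$location, record$length_bp)
        }, logical(1L)))
      merged <- feature_instance(key = key_owner$key,
                                 location = loc_owner$location,
                                 gene = g, product = key_owner$product,
                                 qualifiers = key_owner$qualifiers)
      out[[length(out) + 1L]] <- classify_feature(merged, config, has_intron)
    } else if (f$key %in% drawable_keys) {
      out[[length(out) + 1L]] <- classify_feature(f, config)
    }
  }
  out
}

# is location `a` contained in the drawn extent of `b`?
within_extent <- function(a, b, length_bp) {
  ea <- location_extent(a, length_bp)
  eb <- location_extent(b, length_bp)
  pos_in <- function(p) {
    if (eb$start <= eb$end && !b$wraps_origin) p >= eb$start && p <= eb$end
    else p >= eb$start || p <= eb$end
  }
  pos_in(ea$start) && pos_in(ea$end)
}
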