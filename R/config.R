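# Map configuration: built-in class tables per source category, and the
# XML override format (see inst/extdata/ogconfig.xsd).

.orgmapr_cache <- new.env(parent = emptyenv())

read_class_table <- function(source_category) {
  key <- paste0("classes_", source_category)
  if (!is.null(.orgmapr_cache[[key]])) return(.orgmapr_cache[[key]])
  file <- switch(source_category,
                 plastid = "classes_plastid.tsv",
                 mitochondrial = "classes_mitochondrial.tsv",
                 "classes_generic.tsv")
  tab <- utils::read.delim(extdata_path(file), stringsAsFactors = FALSE,
                           colClasses = "character")
  classes <- lapply(seq_len(nrow(tab)), function(i) {
    feature_class(
      class_id = tab$class_id[i], label = tab$label[i],
      color = tab$color[i],
      keys = strsplit(tab$keys[i], ";", fixed = TRUE)[[1L]],
      patterns = strsplit(tab$patterns[i], ";", fixed = TRUE)[[1L]],
      enabled = as.logical(tab$enabled[i]))
  })
  names(classes) <- tab$class_id
  .orgmapr_cache[[key]] <- classes
  classes
}

#' Gene-name lexicon shipped with the package
#'
#' Canonical organellar gene names with their category (plastid or
#' mitochondrial) and feature class; used by the name tidy-up, the
#' classifier and the synthetic-genome generator.
#'
#' @return Data frame with columns `name`, `category`, `class_id`.
#' @export
gene_lexicon <- function() {
  if (is.null(.orgmapr_cache$lexicon)) {
    .orgmapr_cache$lexicon <- utils::read.delim(
      extdata_path("gene_lexicon.tsv"), stringsAsFactors = FALSE)
  }
  .orgmapr_cache$lexicon
}

#' Construct a feature class
#'
#' @param class_id Unique identifier (e.g. `photosystem_I`, `trna`).
#' @param label Legend label.
#' @param color Fill colour as `#RRGGBB`.
#' @param keys GenBank feature keys assigned to this class.
#' @param patterns Gene-name regular expressions assigned to this class.
#' @param enabled Whether features of this class are drawn.
#' @return An object of class `feature_class`.
#' @export
feature_class <- function(class_id, label = class_id, color = "#D3D3D3",
                          keys = character(), patterns = character(),
                          enabled = TRUE) {
  stopifnot(is.character(class_id), nzchar(class_id))
  if (!is_hex_color(color)) {
    orgmapr_stop("orgmapr_config_error",
                 sprintf("class '%s': color '%s' is not #RRGGBB", class_id, color))
  }
  structure(list(class_id = class_id, label = label, color = toupper(color),
                 keys = keys, patterns = patterns, enabled = isTRUE(enabled)),
            class = "feature_class")
}

#' Built-in default map configuration
#'
#' Returns the standard drawing configuration for a source category:
#' the built-in feature-class table (photosystems, cytochrome complex,
#' ATP synthase, ... for plastids; respiratory complexes I-V, D-loop,
#' ... for mitochondria; a generic table otherwise), tidy-up on,
#' asterisk intron style, annotation-based IR detection, GC graph on,
#' SVG output at 300 dpi. Deterministic: repeated calls give identical
#' configurations.
#'
#' @param source_category `"plastid"`, `"mitochondrial"` or `"other"`.
#' @return An object of class `map_config`.
#' @export
default_config <- function(source_category = c("other", "plastid",
                                               "mitochondrial")) {
  source_category <- match.arg(source_category)
  structure(list(
    mode = "standard",
    classes = read_class_table(source_category),
    tidy_up = TRUE,
    tidy_max_len = 20L,
    intron_style = "asterisk",
    ir_method = "annotation",
    enzymes = character(),
    show_gc = TRUE,
    gc_window_bp = NULL,         # NULL = ~1/240 of the genome, >= 50 bp
    zoom = NULL,
    stretch_factor = NULL,       # NULL = fill the canvas exactly
    up_color = "#D7301F",
    down_color = "#2166AC",
    output_formats = "svg",
    dpi = 300L,
    enabled_genes = NULL,        # transcript mode: per-gene selection
    gene_overrides = list()      # per-gene color/product/class from XML
  ), class = "map_config")
}

#' @export
print.map_config <- function(x, ...) {
  cat(sprintf("<map_config> mode=%s, %d classes, tidy_up=%s, ir=%s, gc=%s\n",
              x$mode, length(x$classes), x$tidy_up, x$ir_method, x$show_gc))
  invisible(x)
}

#' Apply an XML configuration override
#'
#' Reads an `ogconfig` XML document (schema shipped at
#' `inst/extdata/ogconfig.xsd`) and applies it over a base
#' configuration: `<class id color label enabled>` overrides or adds a
#' class, `<gene name color product class>` sets per-gene overrides,
#' `<featurekey key class>` attaches an extra GenBank feature key
#' (e.g. `misc_feature`) to a class. Everything unspecified inherits
#' from `base`; applying overrides is associative.
#'
#' @param xml Path to an XML file, or a string of XML text.
#' @param base Base [default_config()] to override.
#' @return The overridden `map_config`.
#' @export
load_xml_config <- function(xml, base = default_config()) {
  doc <- tryCatch(xml2::read_xml(xml), error = function(e) {
    orgmapr_stop("orgmapr_config_error",
                 sprintf("XML syntax error: %s", conditionMessage(e)))
  })
  root <- xml2::xml_name(doc)
  if (root != "ogconfig") {
    orgmapr_stop("orgmapr_config_error",
                 sprintf("unknown document element </%s>: expected <ogconfig>", root))
  }
  cfg <- base
  for (node in xml2::xml_children(doc)) {
    el <- xml2::xml_name(node)
    attrs <- xml2::xml_attrs(node)
    path <- paste0("/ogconfig/", el)
    check_attrs <- function(allowed, required) {
      unknown <- setdiff(names(attrs), allowed)
      if (length(unknown)) {
        orgmapr_stop("orgmapr_config_error",
                     sprintf("%s: unknown attribute '%s'", path, unknown[1L]))
      }
      missing <- setdiff(required, names(attrs))
      if (length(missing)) {
        orgmapr_stop("orgmapr_config_error",
                     sprintf("%s: missing attribute '%s'", path, missing[1L]))
      }
    }
    check_color <- function(value) {
      if (!is_hex_color(value)) {
        orgmapr_stop("orgmapr_config_error",
                     sprintf("%s: color '%s' is not #RRGGBB", path, value))
      }
    }
    if (el == "class") {
      check_attrs(c("id", "color", "label", "enabled"), "id")
      id <- attrs[["id"]]
      cls <- cfg$classes[[id]] %||%
        feature_class(id, label = id, color = "#D3D3D3")
      if ("color" %in% names(attrs)) {
        check_color(attrs[["color"]])
        cls$color <- toupper(attrs[["color"]])
      }
      if ("label" %in% names(attrs)) cls$label <- attrs[["label"]]
      if ("enabled" %in% names(attrs)) {
        cls$enabled <- tolower(attrs[["enabled"]]) %in% c("true", "1")
      }
      cfg$classes[[id]] <- cls
    } else if (el == "gene") {
      check_attrs(c("name", "color", "product", "class"), "name")
      if ("color" %in% names(attrs)) check_color(attrs[["color"]])
      ov <- cfg$gene_overrides[[attrs[["name"]]]] %||% list()
      for (a in intersect(c("color", "product", "class"), names(attrs))) {
        ov[[a]] <- attrs[[a]]
      }
      cfg$gene_overrides[[attrs[["name"]]]] <- ov
    } else if (el == "featurekey") {
      check_attrs(c("key", "class"), c("key", "class"))
      id <- attrs[["class"]]
      if (is.null(cfg$classes[[id]])) {
        orgmapr_stop("orgmapr_config_error",
                     sprintf("%s: class '%s' does not exist", path, id))
      }
      cfg$classes[[id]]$keys <- union(cfg$classes[[id]]$keys, attrs[["key"]])
    } else {
      orgmapr_stop("orgmapr_config_error",
                   sprintf("/ogconfig: unknown element <%s>", el))
    }
  }
  cfg
}
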