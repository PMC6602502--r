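# Transcript mode: per-gene expression tables and the up/down colour
# ramp overlaying the map.

#' Read a gene-expression table
#'
#' Two-column tab- or comma-delimited text: gene name, signed value
#' (e.g. a log2 fold-change). An optional header row is skipped when
#' its second field is not numeric. Duplicate gene names keep the last
#' value with a warning; a non-numeric value is an error naming the
#' row.
#'
#' @param x File path or a string of table text.
#' @param dataset_label Free-text label for the dataset.
#' @return An object of class `expression_dataset`: `values` (named
#'   numeric vector, gene -> value) and `dataset_label`.
#' @export
read_expression_table <- function(x, dataset_label = "expression") {
  lines <- if (length(x) > 1L) {
    x
  } else if (file.exists(x)) {
    readLines(x, warn = FALSE)
  } else if (grepl("[\t,\n]", x)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("expression file not found: %s", x))
  }
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    orgmapr_stop("orgmapr_parse_error", "expression table is empty")
  }
  fields <- strsplit(lines, "[\t,]")
  ncols <- lengths(fields)
  if (any(ncols < 2L)) {
    orgmapr_stop("orgmapr_parse_error",
                 sprintf("expression table row %d has fewer than 2 columns",
                         which(ncols < 2L)[1L]))
  }
  start <- 1L
  if (suppressWarnings(is.na(as.numeric(fields[[1L]][2L])))) {
    start <- 2L   # header row
    if (length(lines) < 2L) {
      orgmapr_stop("orgmapr_parse_error", "expression table has a header but no rows")
    }
  }
  genes <- character(); vals <- numeric()
  for (i in start:length(fields)) {
    g <- trimws(fields[[i]][1L])
    v <- suppressWarnings(as.numeric(trimws(fields[[i]][2L])))
    if (is.na(v)) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("expression table row %d: value '%s' is not numeric",
                           i, fields[[i]][2L]))
    }
    if (!nzchar(g)) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("expression table row %d: empty gene name", i))
    }
    if (g %in% genes) {
      orgmapr_warn(sprintf("duplicate gene '%s' in expression table: last value wins", g))
      vals[match(g, genes)] <- v
    } else {
      genes <- c(genes, g)
      vals <- c(vals, v)
    }
  }
  names(vals) <- genes
  structure(list(values = vals, dataset_label = dataset_label),
            class = "expression_dataset")
}

NEUTRAL_GREY <- "#BEBEBE"

#' Colour for an expression value
#'
#' Positive values ramp from white toward `up_color`, negative values
#' symmetrically toward `down_color`; saturation is `min(|v|/max_abs,
#' 1)`, so `v = +max_abs` gives exactly `up_color`, `v = 0` gives a
#' neutral grey. Monotone in `|v|` and symmetric in sign.
#'
#' @param value Signed expression value.
#' @param up_color,down_color Endpoint colours as `#RRGGBB`.
#' @param max_abs Scaling anchor (> 0); values beyond it saturate.
#' @return A `#RRGGBB` string.
#' @export
expression_color <- function(value, up_color = "#D7301F",
                             down_color = "#2166AC", max_abs = 1) {
  stopifnot(max_abs > 0)
  if (value == 0) return(NEUTRAL_GREY)
  base <- if (value > 0) up_color else down_color
  s <- min(abs(value) / max_abs, 1)
  rgb <- grDevices::col2rgb(base)[, 1L]
  mixed <- round(255 + s * (rgb - 255))
  toupper(grDevices::rgb(mixed[1L], mixed[2L], mixed[3L],
                         maxColorValue = 255))
}

#' Overlay expression values on a layout
#'
#' Adds one `expression_box` per gene element, coloured by
#' [expression_color()]; genes absent from the dataset get a
#' neutral-grey box. Geometry is never altered — only overlay elements
#' are appended. Genes deselected in the configuration
#' (`enabled_genes`) produce no box.
#'
#' @param layout A placed `map_layout`.
#' @param dataset An [read_expression_table()] result.
#' @param config A `map_config` with `mode = "transcript"`.
#' @param max_abs Scaling anchor; defaults to the dataset's largest
#'   absolute value (1 when the dataset is empty of matches).
#' @return The layout with expression overlay elements appended.
#' @export
apply_expression <- function(layout, dataset, config,
                             max_abs = NULL) {
  if (!identical(config$mode, "transcript")) {
    orgmapr_stop("orgmapr_input_error",
                 "apply_expression requires a transcript-mode configuration")
  }
  if (is.null(max_abs)) {
    max_abs <- if (length(dataset$values)) max(abs(dataset$values)) else 1
    if (max_abs == 0) max_abs <- 1
  }
  el <- layout$elements
  gene_rows <- which(el$kind %in% c("feature_arc", "feature_box") &
                       nzchar(el$text))
  rows <- list()
  for (i in gene_rows) {
    gene <- sub("\\*$", "", el$text[i])
    if (!is.null(config$enabled_genes) && !(gene %in% config$enabled_genes)) next
    col <- if (gene %in% names(dataset$values)) {
      expression_color(dataset$values[[gene]], config$up_color,
                       config$down_color, max_abs)
    } else {
      NEUTRAL_GREY
    }
    rows[[length(rows) + 1L]] <- element_row(
      kind = "expression_box", class_id = "expression", color = col,
      side = el$side[i], a0 = el$a0[i], ext = el$ext[i],
      x0 = el$x0[i], x1 = el$x1[i], text = gene)
  }
  if (length(rows)) {
    layout$elements <- rbind(el, bind_elements(rows))
  }
  layout
}
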