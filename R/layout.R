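# Geometry resolution: convert a classified, analyzed record plus its
# configuration into resolution-independent map geometry. Circular maps
# measure angles in degrees clockwise from 3 o'clock (position 1 = 0
# degrees); linear maps measure x in abstract map units. All functions
# here are pure: identical inputs give element-for-element identical
# layouts.

CANVAS_W <- 1000
CANVAS_H <- 1000
CANVAS_H_LINEAR <- 320
LABEL_CHAR_W <- 7          # map units per character at the label font size
LABEL_TIER_STEP <- 26      # radial/vertical distance between label tiers
LABEL_R0 <- 380            # tier-0 label radius on circular maps

#' Map a sequence position to a map angle
#'
#' Position 1 maps to 0 degrees (3 o'clock); angles grow clockwise, so
#' `angle = 360 * (pos - 1) / length`.
#'
#' @param pos 1-based position in `[1, length]`.
#' @param length Sequence length in bp.
#' @return Angle in degrees in `[0, 360)`.
#' @export
position_to_angle <- function(pos, length) {
  if (any(pos < 1L) || any(pos > length)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("position out of range [1, %d]", length))
  }
  360 * (pos - 1) / length
}

# largest interval from {1,2,5} x 10^k that yields 8-20 ruler ticks
scale_interval <- function(length_bp) {
  cand <- as.vector(outer(c(1, 2, 5), 10^(0:8)))
  counts <- floor(length_bp / cand)
  ok <- cand[counts >= 8 & counts <= 20]
  if (length(ok)) max(ok) else max(1, 10^floor(log10(max(length_bp, 10) / 10)))
}

empty_elements <- function() {
  data.frame(kind = character(), class_id = character(), color = character(),
             side = character(), a0 = numeric(), ext = numeric(),
             x0 = numeric(), x1 = numeric(), text = character(),
             width = numeric(), tier = integer(), leader = logical(),
             clipped = logical(), stringsAsFactors = FALSE)
}

element_row <- function(kind, class_id = "other", color = "#D3D3D3",
                        side = "inner", a0 = NA_real_, ext = NA_real_,
                        x0 = NA_real_, x1 = NA_real_, text = "",
                        width = NA_real_, tier = NA_integer_,
                        leader = FALSE, clipped = FALSE) {
  list(kind = kind, class_id = class_id, color = color, side = side,
       a0 = a0, ext = ext, x0 = x0, x1 = x1, text = text,
       width = width, tier = tier, leader = leader, clipped = clipped)
}

# build the element table in one pass (one data.frame() call, not one
# per element)
bind_elements <- function(rows) {
  if (!length(rows)) return(empty_elements())
  chr <- function(f) vapply(rows, `[[`, character(1L), f)
  num <- function(f) vapply(rows, function(r) as.numeric(r[[f]]), numeric(1L))
  int <- function(f) vapply(rows, function(r) as.integer(r[[f]]), integer(1L))
  lgl <- function(f) vapply(rows, `[[`, logical(1L), f)
  data.frame(kind = chr("kind"), class_id = chr("class_id"),
             color = chr("color"), side = chr("side"), a0 = num("a0"),
             ext = num("ext"), x0 = num("x0"), x1 = num("x1"),
             text = chr("text"), width = num("width"), tier = int("tier"),
             leader = lgl("leader"), clipped = lgl("clipped"),
             stringsAsFactors = FALSE)
}

new_layout <- function(shape, elements, rings, title, legend, canvas,
                       length_bp, stretch = NA_real_, window = NULL) {
  structure(list(shape = shape, elements = elements, rings = rings,
                 title = title, legend = legend, canvas = canvas,
                 length_bp = length_bp, stretch = stretch, window = window),
            class = "map_layout")
}

#' @export
print.map_layout <- function(x, ...) {
  cat(sprintf("<map_layout> %s, %d elements, rings: %s\n", x$shape,
              nrow(x$elements),
              if (length(x$rings)) paste(names(x$rings), collapse = ", ")
              else "none"))
  invisible(x)
}

layout_legend <- function(classified, config) {
  used <- unique(vapply(Filter(function(cf) !cf$suppressed, classified),
                        `[[`, character(1L), "class_id"))
  keep <- Filter(function(cls) cls$enabled && cls$class_id %in% used,
                 config$classes)
  data.frame(label = vapply(keep, `[[`, character(1L), "label"),
             color = vapply(keep, `[[`, character(1L), "color"),
             stringsAsFactors = FALSE)
}

feature_kind <- function(cf) {
  key <- cf$feature$key
  if (key %in% c("operon", "prim_transcript") || cf$class_id == "operon") {
    "operon_bar"
  } else if (key %in% c("D-loop", "D_loop") || cf$class_id == "dloop") {
    "dloop_arc"
  } else {
    "feature_arc"
  }
}

#' Resolve circular map geometry
#'
#' Places plus-strand features on the inner side of the circle
#' (transcribed clockwise) and minus-strand features outside,
#' origin-spanning features as one continuous arc across 0 degrees,
#' operons/primary transcripts as spanning bars, the D-loop as its own
#' arc, the inverted-repeat pair as a bracket ring with IR_A on the
#' right half (ending at the map origin), the GC profile as a ring with
#' a reference circle at 50%, and restriction sites as labelled radial
#' ticks. Labels are placed deterministically (see [place_labels()]).
#'
#' @param record A [genome_record()].
#' @param classified Output of [classify_features()].
#' @param analyses Optional named list: `gc` ([gc_profile()]), `ir`
#'   ([find_inverted_repeats()]), `cuts` ([scan_restriction_sites()]).
#' @param config A [default_config()].
#' @return A `map_layout` with placed labels.
#' @export
layout_circular <- function(record, classified, analyses = list(),
                            config = default_config()) {
  if (!is.null(config$zoom)) {
    orgmapr_stop("orgmapr_input_error",
                 "zoom is only available for linear maps")
  }
  L <- record$length_bp
  rows <- list()
  for (cf in classified) {
    if (cf$suppressed) next
    loc <- cf$feature$location
    ext <- location_extent(loc, L)
    a0 <- position_to_angle(ext$start, L)
    adeg <- 360 * ext$length / L
    side <- if (loc$strand == "+") "inner" else "outer"
    rows[[length(rows) + 1L]] <- element_row(
      kind = feature_kind(cf), class_id = cf$class_id, color = cf$color,
      side = side, a0 = a0, ext = adeg, text = cf$display_name)
    if (identical(config$intron_style, "box") && cf$has_intron &&
        nrow(loc$parts) >= 2L && !loc$wraps_origin) {
      p <- loc$parts
      for (g in seq_len(nrow(p) - 1L)) {
        gs <- p[g, 2L] + 1L
        ge <- p[g + 1L, 1L] - 1L
        if (ge >= gs) {
          rows[[length(rows) + 1L]] <- element_row(
            kind = "intron_gap", class_id = "intron", color = "#FFFFFF",
            side = side, a0 = position_to_angle(gs, L),
            ext = 360 * (ge - gs + 1) / L)
        }
      }
    }
    if (nzchar(cf$display_name)) {
      rows[[length(rows) + 1L]] <- element_row(
        kind = "label", class_id = cf$class_id, color = "#000000",
        side = side, a0 = (a0 + adeg / 2) %% 360, text = cf$display_name,
        width = nchar(cf$display_name) * LABEL_CHAR_W)
    }
  }

  rings <- list()
  interval <- scale_interval(L)
  tick_pos <- seq.int(0L, L - 1L, by = interval) + 1L
  rings$scale <- list(interval = interval,
                      ticks = data.frame(pos = tick_pos,
                                         angle = position_to_angle(tick_pos, L),
                                         label = format_bp(tick_pos - 1L)))
  gc <- analyses$gc
  if (isTRUE(config$show_gc) && !is.null(gc)) {
    rings$gc <- list(reference = 0.5,
                     values = data.frame(
                       angle = position_to_angle(gc$values$window_center, L),
                       gc_fraction = gc$values$gc_fraction))
  }
  ir <- analyses$ir
  if (!is.null(ir)) {
    rings$ir_bracket <- list(
      ir_a = c(a0 = position_to_angle(ir$ir_a[1L], L),
               ext = 360 * (ir$ir_a[2L] - ir$ir_a[1L] + 1) / L),
      ir_b = c(a0 = position_to_angle(ir$ir_b[1L], L),
               ext = 360 * (ir$ir_b[2L] - ir$ir_b[1L] + 1) / L),
      method = ir$method)
  }
  cuts <- analyses$cuts
  if (!is.null(cuts) && nrow(cuts)) {
    for (i in seq_len(nrow(cuts))) {
      rows[[length(rows) + 1L]] <- element_row(
        kind = "cut_tick", class_id = "cutsite", color = "#333333",
        side = "outer", a0 = position_to_angle(cuts$position[i], L),
        ext = 0, text = cuts$enzyme[i])
    }
  }

  layout <- new_layout(
    shape = "circular", elements = bind_elements(rows), rings = rings,
    title = sprintf("%s  %s  (%s bp)", record$accession, record$organism,
                    format(record$length_bp, big.mark = ",")),
    legend = layout_legend(classified, config),
    canvas = c(width = CANVAS_W, height = CANVAS_H), length_bp = L)
  place_labels(layout)
}

format_bp <- function(x) {
  ifelse(x >= 1000 & x %% 1000 == 0, paste0(x / 1000, " kb"), as.character(x))
}

#' Resolve linear map geometry
#'
#' Maps position `pos` to `x = stretch * (pos - window_start)`; the
#' stretch factor defaults to `canvas_width / window_length` so the
#' drawn window fills the canvas exactly, and can be overridden via
#' `config$stretch_factor`. Features are clipped to the zoom window
#' (the whole record when unset) with clipped edges marked; plus-strand
#' features sit above the axis, minus-strand below, mirroring the
#' circular inner/outer convention.
#'
#' @inheritParams layout_circular
#' @return A `map_layout` with placed labels.
#' @export
layout_linear <- function(record, classified, analyses = list(),
                          config = default_config()) {
  L <- record$length_bp
  window <- config$zoom %||% c(1L, L)
  if (window[1L] < 1L || window[2L] > L || window[1L] >= window[2L]) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("zoom window %d:%d outside [1, %d] or inverted",
                         window[1L], window[2L], L))
  }
  wlen <- window[2L] - window[1L] + 1L
  stretch <- config$stretch_factor %||% (CANVAS_W / wlen)
  xof <- function(pos) stretch * (pos - window[1L])

  rows <- list()
  for (cf in classified) {
    if (cf$suppressed) next
    loc <- cf$feature$location
    # an origin-wrapping feature is drawn as one box per run on a
    # linear axis (it genuinely occupies both ends of the sequence)
    spans <- if (loc$wraps_origin) {
      brk <- which(diff(loc$parts[, 1L]) < 0L)[1L]
      list(c(loc$parts[1L, 1L], loc$parts[brk, 2L]),
           c(loc$parts[brk + 1L, 1L], loc$parts[nrow(loc$parts), 2L]))
    } else {
      e <- location_extent(loc, L)
      list(c(e$start, e$end))
    }
    side <- if (loc$strand == "+") "inner" else "outer"
    for (sp in spans) {
      s <- max(sp[1L], window[1L])
      e <- min(sp[2L], window[2L])
      if (s > e) next
      clipped <- s != sp[1L] || e != sp[2L]
      rows[[length(rows) + 1L]] <- element_row(
        kind = if (feature_kind(cf) == "feature_arc") "feature_box"
               else feature_kind(cf),
        class_id = cf$class_id, color = cf$color, side = side,
        x0 = xof(s), x1 = xof(e + 1L), text = cf$display_name,
        clipped = clipped)
      if (nzchar(cf$display_name)) {
        rows[[length(rows) + 1L]] <- element_row(
          kind = "label", class_id = cf$class_id, color = "#000000",
          side = side, x0 = (xof(s) + xof(e + 1L)) / 2,
          text = cf$display_name,
          width = nchar(cf$display_name) * LABEL_CHAR_W)
      }
    }
  }
  interval <- scale_interval(wlen)
  first <- ceiling((window[1L] - 1L) / interval) * interval
  tick_pos <- seq.int(first, window[2L] - 1L, by = interval) + 1L
  rings <- list(scale = list(interval = interval,
                             ticks = data.frame(pos = tick_pos,
                                                x = xof(tick_pos),
                                                label = format_bp(tick_pos - 1L))))
  cuts <- analyses$cuts
  if (!is.null(cuts) && nrow(cuts)) {
    keep <- cuts$position >= window[1L] & cuts$position <= window[2L]
    for (i in which(keep)) {
      rows[[length(rows) + 1L]] <- element_row(
        kind = "cut_tick", class_id = "cutsite", color = "#333333",
        side = "outer", x0 = xof(cuts$position[i]), x1 = xof(cuts$position[i]),
        text = cuts$enzyme[i])
    }
  }
  layout <- new_layout(
    shape = "linear", elements = bind_elements(rows), rings = rings,
    title = sprintf("%s  %s  (%s bp)", record$accession, record$organism,
                    format(record$length_bp, big.mark = ",")),
    legend = layout_legend(classified, config),
    canvas = c(width = CANVAS_W, height = CANVAS_H_LINEAR),
    length_bp = L, stretch = stretch, window = window)
  place_labels(layout)
}

circ_angle_dist <- function(a, b) {
  d <- abs(a - b) %% 360
  pmin(d, 360 - d)
}

#' Place map labels without overlap
#'
#' Deterministic greedy pass in coordinate order: each label starts at
#' tier 0 (closest to its feature) and is pushed outward (circular) or
#' to a higher stack tier (linear) until it no longer collides with any
#' already-placed label of that tier; pushed labels get a leader line.
#' No label is ever dropped.
#'
#' @param layout A `map_layout` from [layout_circular()] or
#'   [layout_linear()].
#' @return The layout with `tier` and `leader` filled in for all label
#'   elements.
#' @export
place_labels <- function(layout) {
  el <- layout$elements
  idx <- which(el$kind == "label")
  if (!length(idx)) return(layout)
  anchors <- if (layout$shape == "circular") el$a0[idx] else el$x0[idx]
  ord <- idx[order(anchors, idx)]
  tiers <- list()  # per tier: matrix of placed (center, half_width)
  for (i in ord) {
    center <- if (layout$shape == "circular") el$a0[i] else el$x0[i]
    t <- 0L
    repeat {
      half <- label_half_width(el$width[i], layout$shape, t)
      placed <- tiers[[as.character(t)]]
      clash <- FALSE
      if (!is.null(placed)) {
        d <- if (layout$shape == "circular") {
          circ_angle_dist(placed[, 1L], center)
        } else {
          abs(placed[, 1L] - center)
        }
        clash <- any(d < placed[, 2L] + half)
      }
      if (!clash) break
      t <- t + 1L
    }
    tiers[[as.character(t)]] <- rbind(tiers[[as.character(t)]], c(center, half))
    el$tier[i] <- t
    el$leader[i] <- t > 0L
  }
  layout$elements <- el
  layout
}

# half extent of a label in the tier's own coordinate: degrees at the
# tier radius on circular maps, map units on linear maps
label_half_width <- function(width_units, shape, tier) {
  if (shape == "circular") {
    r <- LABEL_R0 + tier * LABEL_TIER_STEP
    (width_units / (2 * pi * r)) * 360 / 2
  } else {
    width_units / 2
  }
}
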