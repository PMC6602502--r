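# Rendering: a deterministic SVG writer plus PDF/PostScript and raster
# output through R's graphics devices. All formats are drawn from the
# same resolved MapLayout by shared geometry, so the formats agree
# visually; the SVG text is byte-deterministic (stable element order,
# fixed 3-decimal float formatting, no timestamps).

fmt3 <- function(x) {
  out <- sprintf("%.3f", x)
  bad <- out == "-0.000"
  if (any(bad)) out[bad] <- "0.000"
  out
}

svg_tag <- function(name, attrs = character(), content = NULL) {
  a <- if (length(attrs)) {
    paste0(" ", paste0(names(attrs), "=\"", attrs, "\"", collapse = " "))
  } else ""
  if (is.null(content)) {
    paste0("<", name, a, "/>")
  } else {
    paste0("<", name, a, ">", content, "</", name, ">")
  }
}

xml_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  gsub(">", "&gt;", x, fixed = TRUE)
}

# point on the map circle: angle in degrees clockwise from 3 o'clock
circ_xy <- function(a_deg, r, cx = 500, cy = 500) {
  rad <- a_deg * pi / 180
  c(cx + r * cos(rad), cy + r * sin(rad))
}

# SVG path for an annulus sector [r0, r1] over [a0, a0+ext] degrees
sector_path <- function(a0, ext, r0, r1) {
  if (ext >= 360) {
    return(paste(sector_path(a0, 180, r0, r1),
                 sector_path(a0 + 180, 180, r0, r1)))
  }
  a1 <- a0 + ext
  p1 <- circ_xy(a0, r1); p2 <- circ_xy(a1, r1)
  p3 <- circ_xy(a1, r0); p4 <- circ_xy(a0, r0)
  laf <- if (ext > 180) 1 else 0
  sprintf("M %s %s A %s %s 0 %d 1 %s %s L %s %s A %s %s 0 %d 0 %s %s Z",
          fmt3(p1[1]), fmt3(p1[2]), fmt3(r1), fmt3(r1), laf,
          fmt3(p2[1]), fmt3(p2[2]), fmt3(p3[1]), fmt3(p3[2]),
          fmt3(r0), fmt3(r0), laf, fmt3(p4[1]), fmt3(p4[2]))
}

# radial band per element kind on circular maps (r0, r1)
RADII <- list(feature_inner = c(300, 330), feature_outer = c(330, 360),
              operon = c(268, 292), expression = c(240, 264),
              gc = c(150, 230), ir = 372, cut = c(360, 382))

element_band <- function(kind, side) {
  switch(kind,
         operon_bar = RADII$operon,
         expression_box = RADII$expression,
         if (side == "inner") RADII$feature_inner else RADII$feature_outer)
}

#' Serialize a layout to SVG text
#'
#' Produces one SVG element per drawn map element plus the scale ring
#' or axis, GC ring with its 50% reference circle, IR brackets, legend
#' and title. Output is byte-deterministic for a given layout.
#'
#' @param layout A placed `map_layout`.
#' @return A single string containing an SVG 1.1 document.
#' @export
render_svg <- function(layout) {
  w <- layout$canvas[["width"]]
  h <- layout$canvas[["height"]]
  out <- c(
    "<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
    sprintf(paste0("<svg xmlns=\"http://www.w3.org/2000/svg\" version=\"1.1\" ",
                   "width=\"%d\" height=\"%d\" viewBox=\"0 0 %d %d\" ",
                   "font-family=\"Helvetica, Arial, sans-serif\">"),
            w, h, w, h),
    svg_tag("title", content = xml_escape(layout$title)),
    svg_tag("rect", c(x = "0", y = "0", width = w, height = h,
                      fill = "#FFFFFF")),
    svg_tag("text", c(x = fmt3(w / 2), y = "22", `text-anchor` = "middle",
                      `font-size` = "16"), xml_escape(layout$title)))
  out <- c(out,
           if (layout$shape == "circular") svg_circular_body(layout)
           else svg_linear_body(layout),
           svg_legend(layout), "</svg>")
  paste(out, collapse = "\n")
}

svg_circular_body <- function(layout) {
  out <- character()
  rings <- layout$rings
  # backbone circle and ruler
  out <- c(out, svg_tag("circle", c(cx = "500", cy = "500", r = "330",
                                    fill = "none", stroke = "#000000",
                                    `stroke-width` = "1.2", class = "backbone")))
  if (!is.null(rings$scale)) {
    tk <- rings$scale$ticks
    for (i in seq_len(nrow(tk))) {
      p1 <- circ_xy(tk$angle[i], 330); p2 <- circ_xy(tk$angle[i], 338)
      pt <- circ_xy(tk$angle[i], 350)
      out <- c(out,
               svg_tag("line", c(x1 = fmt3(p1[1]), y1 = fmt3(p1[2]),
                                 x2 = fmt3(p2[1]), y2 = fmt3(p2[2]),
                                 stroke = "#000000", `stroke-width` = "0.8")),
               svg_tag("text", c(x = fmt3(pt[1]), y = fmt3(pt[2]),
                                 `text-anchor` = "middle", `font-size` = "8",
                                 class = "ruler"), xml_escape(tk$label[i])))
    }
  }
  if (!is.null(rings$gc)) {
    gv <- rings$gc$values
    r_of <- function(f) RADII$gc[1] + diff(RADII$gc) * f
    # filled radial histogram between the baseline and each window value
    for (i in seq_len(nrow(gv))) {
      a0 <- gv$angle[i]
      ext <- if (i < nrow(gv)) gv$angle[i + 1] - a0 else 360 + gv$angle[1] - a0
      if (ext <= 0) ext <- ext + 360
      out <- c(out, svg_tag("path", c(
        d = sector_path(a0, ext, RADII$gc[1], r_of(gv$gc_fraction[i])),
        fill = "#8F8F8F", stroke = "none", class = "gc-bar")))
    }
    out <- c(out, svg_tag("circle", c(
      cx = "500", cy = "500", r = fmt3(r_of(rings$gc$reference)),
      fill = "none", stroke = "#000000", `stroke-width` = "0.6",
      `stroke-dasharray` = "3 2", class = "gc-ref",
      `data-gc` = fmt3(rings$gc$reference))))
  }
  if (!is.null(rings$ir_bracket)) {
    for (nm in c("ir_a", "ir_b")) {
      br <- rings$ir_bracket[[nm]]
      lab <- if (nm == "ir_a") "IR_A" else "IR_B"
      mid <- circ_xy(br[["a0"]] + br[["ext"]] / 2, RADII$ir + 12)
      out <- c(out,
               svg_tag("path", c(d = arc_path(br[["a0"]], br[["ext"]], RADII$ir),
                                 fill = "none", stroke = "#555555",
                                 `stroke-width` = "4", class = paste0("ir ", lab))),
               svg_tag("text", c(x = fmt3(mid[1]), y = fmt3(mid[2]),
                                 `text-anchor` = "middle", `font-size` = "11",
                                 class = "ir-label"), lab))
    }
  }
  el <- layout$elements
  for (i in seq_len(nrow(el))) {
    e <- lapply(el, `[[`, i)   # plain list row: much cheaper than df subset
    out <- c(out, switch(
      e$kind,
      feature_arc = , dloop_arc = , operon_bar = , expression_box = ,
      intron_gap = {
        band <- element_band(e$kind, e$side)
        cls <- if (e$kind == "intron_gap") "intron-gap" else e$kind
        svg_tag("path", c(d = sector_path(e$a0, e$ext, band[1], band[2]),
                          fill = e$color, stroke = "#000000",
                          `stroke-width` = "0.5", class = cls))
      },
      cut_tick = {
        p1 <- circ_xy(e$a0, RADII$cut[1]); p2 <- circ_xy(e$a0, RADII$cut[2])
        pt <- circ_xy(e$a0, RADII$cut[2] + 8)
        paste(svg_tag("line", c(x1 = fmt3(p1[1]), y1 = fmt3(p1[2]),
                                x2 = fmt3(p2[1]), y2 = fmt3(p2[2]),
                                stroke = e$color, `stroke-width` = "0.8",
                                class = "cut-tick")),
              svg_tag("text", c(x = fmt3(pt[1]), y = fmt3(pt[2]),
                                `text-anchor` = "middle", `font-size` = "7",
                                class = "cut-label"), xml_escape(e$text)),
              sep = "\n")
      },
      label = {
        r <- LABEL_R0 + e$tier * LABEL_TIER_STEP
        pt <- circ_xy(e$a0, r)
        lead <- if (isTRUE(e$leader)) {
          p0 <- circ_xy(e$a0, 364)
          p1 <- circ_xy(e$a0, r - 8)
          paste0(svg_tag("line", c(x1 = fmt3(p0[1]), y1 = fmt3(p0[2]),
                                   x2 = fmt3(p1[1]), y2 = fmt3(p1[2]),
                                   stroke = "#888888", `stroke-width` = "0.4",
                                   class = "leader")), "\n")
        } else ""
        paste0(lead,
               svg_tag("text", c(x = fmt3(pt[1]), y = fmt3(pt[2]),
                                 `text-anchor` = "middle", `font-size` = "10",
                                 class = "gene-label"), xml_escape(e$text)))
      },
      NULL))
  }
  out
}

# open arc (stroke only) at radius r
arc_path <- function(a0, ext, r) {
  if (ext >= 360) ext <- 359.99
  p1 <- circ_xy(a0, r); p2 <- circ_xy(a0 + ext, r)
  sprintf("M %s %s A %s %s 0 %d 1 %s %s", fmt3(p1[1]), fmt3(p1[2]),
          fmt3(r), fmt3(r), if (ext > 180) 1 else 0, fmt3(p2[1]), fmt3(p2[2]))
}

svg_linear_body <- function(layout) {
  out <- character()
  y_axis <- 160
  out <- c(out, svg_tag("line", c(x1 = "0", y1 = fmt3(y_axis),
                                  x2 = fmt3(layout$canvas[["width"]]),
                                  y2 = fmt3(y_axis), stroke = "#000000",
                                  `stroke-width` = "1.2", class = "backbone")))
  tk <- layout$rings$scale$ticks
  for (i in seq_len(nrow(tk))) {
    out <- c(out,
             svg_tag("line", c(x1 = fmt3(tk$x[i]), y1 = fmt3(y_axis),
                               x2 = fmt3(tk$x[i]), y2 = fmt3(y_axis + 8),
                               stroke = "#000000", `stroke-width` = "0.8")),
             svg_tag("text", c(x = fmt3(tk$x[i]), y = fmt3(y_axis + 20),
                               `text-anchor` = "middle", `font-size` = "8",
                               class = "ruler"), xml_escape(tk$label[i])))
  }
  el <- layout$elements
  for (i in seq_len(nrow(el))) {
    e <- lapply(el, `[[`, i)
    above <- e$side == "inner"
    out <- c(out, switch(
      e$kind,
      feature_box = , dloop_arc = , operon_bar = , expression_box = ,
      intron_gap = {
        yy <- if (e$kind == "operon_bar") {
          if (above) c(98, 112) else c(208, 222)
        } else if (e$kind == "expression_box") {
          if (above) c(80, 94) else c(226, 240)
        } else {
          if (above) c(118, 152) else c(168, 202)
        }
        cls <- if (e$kind == "intron_gap") "intron-gap" else e$kind
        dash <- if (isTRUE(e$clipped)) c(`stroke-dasharray` = "3 2") else character()
        svg_tag("rect", c(x = fmt3(e$x0), y = fmt3(yy[1]),
                          width = fmt3(e$x1 - e$x0), height = fmt3(diff(yy)),
                          fill = e$color, stroke = "#000000",
                          `stroke-width` = "0.5", dash, class = cls))
      },
      cut_tick = {
        paste(svg_tag("line", c(x1 = fmt3(e$x0), y1 = fmt3(y_axis - 6),
                                x2 = fmt3(e$x0), y2 = fmt3(y_axis + 6),
                                stroke = e$color, `stroke-width` = "0.8",
                                class = "cut-tick")),
              svg_tag("text", c(x = fmt3(e$x0), y = fmt3(y_axis + 32),
                                `text-anchor` = "middle", `font-size` = "7",
                                class = "cut-label"), xml_escape(e$text)),
              sep = "\n")
      },
      label = {
        y <- if (above) 108 - e$tier * 16 else 252 + e$tier * 16
        svg_tag("text", c(x = fmt3(e$x0), y = fmt3(y),
                          `text-anchor` = "middle", `font-size` = "10",
                          class = "gene-label"), xml_escape(e$text))
      },
      NULL))
  }
  out
}

svg_legend <- function(layout) {
  lg <- layout$legend
  if (is.null(lg) || nrow(lg) == 0L) return(character())
  h <- layout$canvas[["height"]]
  out <- character()
  y0 <- h - 14 * nrow(lg) - 6
  for (i in seq_len(nrow(lg))) {
    y <- y0 + 14 * (i - 1)
    out <- c(out,
             svg_tag("rect", c(x = "8", y = fmt3(y), width = "12",
                               height = "10", fill = lg$color[i],
                               stroke = "#000000", `stroke-width` = "0.4",
                               class = "legend-swatch")),
             svg_tag("text", c(x = "24", y = fmt3(y + 9), `font-size` = "9",
                               class = "legend-label"), xml_escape(lg$label[i])))
  }
  out
}
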