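# File output: write the SVG, draw PDF/PostScript and raster formats
# through R graphics devices from the same layout geometry, and bundle
# batches into a store-only zip archive with fixed timestamps (so
# re-running a job reproduces the archive byte for byte).

SUPPORTED_FORMATS <- c("svg", "pdf", "ps", "png", "tiff", "jpeg")
UNITS_PER_INCH <- 100   # map units per inch when resolving raster sizes

#' Describe a render job
#'
#' @param layout A placed `map_layout`.
#' @param formats Subset of `svg`, `pdf`, `ps`, `png`, `tiff`, `jpeg`.
#' @param dpi Raster resolution in dots per inch (>= 30).
#' @param output_basename Output path without extension.
#' @return An object of class `render_job`.
#' @export
render_job <- function(layout, formats = "svg", dpi = 300L,
                       output_basename = "map") {
  if (length(formats) == 0L) {
    orgmapr_stop("orgmapr_input_error", "no output formats requested")
  }
  bad <- setdiff(formats, SUPPORTED_FORMATS)
  if (length(bad)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("unsupported format '%s'; supported: %s", bad[1L],
                         paste(SUPPORTED_FORMATS, collapse = ", ")))
  }
  dpi <- as.integer(dpi)
  if (dpi < 30L) {
    orgmapr_stop("orgmapr_input_error", "dpi must be >= 30")
  }
  structure(list(layout = layout, formats = unique(formats), dpi = dpi,
                 output_basename = output_basename),
            class = "render_job")
}

#' Render a layout to files
#'
#' Writes one file per requested format, named
#' `<output_basename>.<ext>`. The SVG comes from [render_svg()]; PDF
#' and PostScript are vector drawings of the same geometry; PNG, TIFF
#' (lossless) and JPEG (quality 92) are rasterized at `dpi`, so the
#' pixel width is `canvas_width_inches * dpi`.
#'
#' @param job A [render_job()].
#' @return Character vector of written file paths.
#' @export
render_all <- function(job) {
  stopifnot(inherits(job, "render_job"))
  dir <- dirname(job$output_basename)
  if (!dir.exists(dir)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("output directory does not exist: %s", dir))
  }
  layout <- job$layout
  w_in <- layout$canvas[["width"]] / UNITS_PER_INCH
  h_in <- layout$canvas[["height"]] / UNITS_PER_INCH
  written <- character()
  for (fmt in job$formats) {
    path <- paste0(job$output_basename, ".", fmt)
    switch(fmt,
      svg = {
        con <- file(path, open = "wb")
        writeBin(charToRaw(paste0(render_svg(layout), "\n")), con)
        close(con)
      },
      pdf = {
        grDevices::pdf(path, width = w_in, height = h_in, useDingbats = FALSE)
        on.exit(grDevices::dev.off(), add = TRUE, after = FALSE)
        draw_layout(layout)
        grDevices::dev.off()
        on.exit()
      },
      ps = {
        grDevices::postscript(path, width = w_in, height = h_in,
                              paper = "special", horizontal = FALSE)
        draw_layout(layout)
        grDevices::dev.off()
      },
      png = {
        grDevices::png(path, width = w_in * job$dpi, height = h_in * job$dpi,
                       res = job$dpi, type = "cairo")
        draw_layout(layout)
        grDevices::dev.off()
      },
      tiff = {
        grDevices::tiff(path, width = w_in * job$dpi, height = h_in * job$dpi,
                        res = job$dpi, compression = "lzw", type = "cairo")
        draw_layout(layout)
        grDevices::dev.off()
      },
      jpeg = {
        grDevices::jpeg(path, width = w_in * job$dpi, height = h_in * job$dpi,
                        res = job$dpi, quality = 92, type = "cairo")
        draw_layout(layout)
        grDevices::dev.off()
      })
    written <- c(written, path)
  }
  written
}

# shared vector drawing used by all non-SVG devices
draw_layout <- function(layout) {
  w <- layout$canvas[["width"]]
  h <- layout$canvas[["height"]]
  op <- graphics::par(mar = c(0, 0, 0, 0))
  on.exit(graphics::par(op), add = TRUE)
  graphics::plot.new()
  graphics::plot.window(xlim = c(0, w), ylim = c(h, 0), asp = 1,
                        xaxs = "i", yaxs = "i")
  graphics::text(w / 2, 22, layout$title, cex = 1.1)
  if (layout$shape == "circular") draw_circular(layout) else draw_linear(layout)
  lg <- layout$legend
  if (!is.null(lg) && nrow(lg)) {
    y0 <- h - 14 * nrow(lg) - 6
    for (i in seq_len(nrow(lg))) {
      y <- y0 + 14 * (i - 1)
      graphics::rect(8, y + 10, 20, y, col = lg$color[i], border = "#000000")
      graphics::text(24, y + 6, lg$label[i], adj = c(0, 0.5), cex = 0.6)
    }
  }
}

sector_poly <- function(a0, ext, r0, r1, cx = 500, cy = 500) {
  n <- max(2L, ceiling(ext))
  ang <- (a0 + seq(0, ext, length.out = n)) * pi / 180
  x <- c(cx + r1 * cos(ang), rev(cx + r0 * cos(ang)))
  y <- c(cy + r1 * sin(ang), rev(cy + r0 * sin(ang)))
  list(x = x, y = y)
}

draw_circular <- function(layout) {
  rings <- layout$rings
  th <- seq(0, 2 * pi, length.out = 361)
  graphics::lines(500 + 330 * cos(th), 500 + 330 * sin(th))
  if (!is.null(rings$scale)) {
    tk <- rings$scale$ticks
    for (i in seq_len(nrow(tk))) {
      p1 <- circ_xy(tk$angle[i], 330); p2 <- circ_xy(tk$angle[i], 338)
      pt <- circ_xy(tk$angle[i], 350)
      graphics::segments(p1[1], p1[2], p2[1], p2[2])
      graphics::text(pt[1], pt[2], tk$label[i], cex = 0.5)
    }
  }
  if (!is.null(rings$gc)) {
    gv <- rings$gc$values
    r_of <- function(f) RADII$gc[1] + diff(RADII$gc) * f
    for (i in seq_len(nrow(gv))) {
      a0 <- gv$angle[i]
      ext <- if (i < nrow(gv)) gv$angle[i + 1] - a0 else 360 + gv$angle[1] - a0
      if (ext <= 0) ext <- ext + 360
      p <- sector_poly(a0, ext, RADII$gc[1], r_of(gv$gc_fraction[i]))
      graphics::polygon(p$x, p$y, col = "#8F8F8F", border = NA)
    }
    rr <- r_of(rings$gc$reference)
    graphics::lines(500 + rr * cos(th), 500 + rr * sin(th), lty = 2, lwd = 0.6)
  }
  if (!is.null(rings$ir_bracket)) {
    for (nm in c("ir_a", "ir_b")) {
      br <- rings$ir_bracket[[nm]]
      ang <- (br[["a0"]] + seq(0, br[["ext"]], length.out = 90)) * pi / 180
      graphics::lines(500 + RADII$ir * cos(ang), 500 + RADII$ir * sin(ang),
                      lwd = 3, col = "#555555")
      mid <- circ_xy(br[["a0"]] + br[["ext"]] / 2, RADII$ir + 12)
      graphics::text(mid[1], mid[2], toupper(sub("ir_", "IR_", nm)), cex = 0.7)
    }
  }
  el <- layout$elements
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    if (e$kind %in% c("feature_arc", "dloop_arc", "operon_bar",
                      "expression_box", "intron_gap")) {
      band <- element_band(e$kind, e$side)
      p <- sector_poly(e$a0, e$ext, band[1], band[2])
      graphics::polygon(p$x, p$y, col = e$color, border = "#000000",
                        lwd = 0.4)
    } else if (e$kind == "cut_tick") {
      p1 <- circ_xy(e$a0, RADII$cut[1]); p2 <- circ_xy(e$a0, RADII$cut[2])
      graphics::segments(p1[1], p1[2], p2[1], p2[2], col = e$color)
      pt <- circ_xy(e$a0, RADII$cut[2] + 8)
      graphics::text(pt[1], pt[2], e$text, cex = 0.45)
    } else if (e$kind == "label") {
      r <- LABEL_R0 + e$tier * LABEL_TIER_STEP
      pt <- circ_xy(e$a0, r)
      if (isTRUE(e$leader)) {
        p0 <- circ_xy(e$a0, 364); p1 <- circ_xy(e$a0, r - 8)
        graphics::segments(p0[1], p0[2], p1[1], p1[2], col = "#888888",
                           lwd = 0.4)
      }
      graphics::text(pt[1], pt[2], e$text, cex = 0.65)
    }
  }
}

draw_linear <- function(layout) {
  y_axis <- 160
  graphics::segments(0, y_axis, layout$canvas[["width"]], y_axis)
  tk <- layout$rings$scale$ticks
  graphics::segments(tk$x, y_axis, tk$x, y_axis + 8)
  graphics::text(tk$x, y_axis + 20, tk$label, cex = 0.5)
  el <- layout$elements
  for (i in seq_len(nrow(el))) {
    e <- el[i, ]
    above <- e$side == "inner"
    if (e$kind %in% c("feature_box", "dloop_arc", "operon_bar",
                      "expression_box", "intron_gap")) {
      yy <- if (above) c(118, 152) else c(168, 202)
      graphics::rect(e$x0, yy[2], e$x1, yy[1], col = e$color,
                     border = "#000000", lwd = 0.4)
    } else if (e$kind == "cut_tick") {
      graphics::segments(e$x0, y_axis - 6, e$x0, y_axis + 6, col = e$color)
      graphics::text(e$x0, y_axis + 32, e$text, cex = 0.45)
    } else if (e$kind == "label") {
      y <- if (above) 108 - e$tier * 16 else 252 + e$tier * 16
      graphics::text(e$x0, y, e$text, cex = 0.65)
    }
  }
}

# ---- store-only zip writer (fixed timestamps => deterministic bytes) ----

crc32_table <- function() {
  tab <- .orgmapr_cache$crc_tab
  if (!is.null(tab)) return(tab)
  tab <- integer(256L)
  for (n in 0:255) {
    c <- n
    for (k in 1:8) {
      c <- if (bitwAnd(c, 1L) != 0L) {
        bitwXor(bitwShiftR(c, 1L), -306674912L)  # 0xEDB88320
      } else {
        bitwShiftR(c, 1L)
      }
    }
    tab[n + 1L] <- c
  }
  .orgmapr_cache$crc_tab <- tab
  tab
}

crc32 <- function(raw_bytes) {
  tab <- crc32_table()
  c <- -1L  # 0xFFFFFFFF
  for (b in as.integer(raw_bytes)) {
    c <- bitwXor(tab[bitwAnd(bitwXor(c, b), 255L) + 1L],
                 bitwShiftR(c, 8L))
  }
  bitwXor(c, -1L)
}

pack_u <- function(x, bytes) {
  x <- as.numeric(x) %% 2^(8 * bytes)
  as.raw((x %/% 256^(seq_len(bytes) - 1L)) %% 256)
}

#' Bundle files into a zip archive
#'
#' Minimal store-only (uncompressed) ZIP writer with fixed entry
#' timestamps, so identical inputs always produce a byte-identical
#' archive. Entries are stored under their base names.
#'
#' @param zipfile Output archive path.
#' @param files Character vector of existing files to include.
#' @return `zipfile`, invisibly.
#' @export
write_zip <- function(zipfile, files) {
  missing <- files[!file.exists(files)]
  if (length(missing)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("cannot zip missing file: %s", missing[1L]))
  }
  con <- file(zipfile, open = "wb")
  on.exit(close(con))
  offsets <- numeric(length(files))
  centrals <- vector("list", length(files))
  offset <- 0
  for (i in seq_along(files)) {
    data <- readBin(files[i], "raw", n = file.info(files[i])$size)
    name <- charToRaw(basename(files[i]))
    crc <- crc32(data)
    local <- c(charToRaw("PK\x03\x04"), pack_u(20, 2), pack_u(0, 2),
               pack_u(0, 2), pack_u(0x0000, 2), pack_u(0x0021, 2),
               pack_u(crc, 4), pack_u(length(data), 4),
               pack_u(length(data), 4), pack_u(length(name), 2),
               pack_u(0, 2), name)
    writeBin(local, con)
    writeBin(data, con)
    offsets[i] <- offset
    centrals[[i]] <- c(charToRaw("PK\x01\x02"), pack_u(20, 2), pack_u(20, 2),
                       pack_u(0, 2), pack_u(0, 2), pack_u(0x0000, 2),
                       pack_u(0x0021, 2), pack_u(crc, 4),
                       pack_u(length(data), 4), pack_u(length(data), 4),
                       pack_u(length(name), 2), pack_u(0, 2), pack_u(0, 2),
                       pack_u(0, 2), pack_u(0, 2), pack_u(0, 4),
                       pack_u(offset, 4), name)
    offset <- offset + length(local) + length(data)
  }
  cd_start <- offset
  for (cen in centrals) writeBin(cen, con)
  cd_size <- sum(vapply(centrals, length, integer(1L)))
  end <- c(charToRaw("PK\x05\x06"), pack_u(0, 2), pack_u(0, 2),
           pack_u(length(files), 2), pack_u(length(files), 2),
           pack_u(cd_size, 4), pack_u(cd_start, 4), pack_u(0, 2))
  writeBin(end, con)
  invisible(zipfile)
}

#' List the entry names of a zip archive
#'
#' Reads the central directory of an archive written by [write_zip()]
#' (or any standard zip file) and returns the stored entry names.
#'
#' @param zipfile Archive path.
#' @return Character vector of entry names.
#' @export
zip_entries <- function(zipfile) {
  data <- readBin(zipfile, "raw", n = file.info(zipfile)$size)
  sig <- c(0x50, 0x4b, 0x01, 0x02)
  hits <- which(as.integer(data) == sig[1L])
  hits <- hits[hits + 3L <= length(data) &
                 as.integer(data[hits + 1L]) == sig[2L] &
                 as.integer(data[hits + 2L]) == sig[3L] &
                 as.integer(data[hits + 3L]) == sig[4L]]
  vapply(hits, function(h) {
    nlen <- as.integer(data[h + 28L]) + 256L * as.integer(data[h + 29L])
    rawToChar(data[(h + 46L):(h + 45L + nlen)])
  }, character(1L))
}
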