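# Seeded synthetic-genome generator: emits GenBank flat-file text with
# fully known ground truth (planted inverted repeats, introns,
# origin-spanning features, D-loops, operons, IUPAC noise), so every
# other module is testable without any external data.

#' Describe a synthetic genome
#'
#' The defaults emulate realistic study material: a quadripartite
#' plastome (LSC + IR + SSC + reverse-complemented IR, 150 kb with
#' 25 kb repeats), a compact metazoan-style mitogenome (16.5 kb with an
#' origin-spanning D-loop), or a small generic replicon. The seed fully
#' determines the output; the generator never touches the caller's RNG
#' stream.
#'
#' Planted inverted repeats are made maximal by construction (the bases
#' flanking the pair are forced to break the repeat), so "exact
#' boundary recovery" by the de novo detector is well defined.
#'
#' @param kind `"plastome_like"`, `"mitogenome_like"` or `"generic"`.
#' @param length_bp Genome length in bp.
#' @param ir_len Length of each inverted-repeat copy (plastome only;
#'   `0` disables the repeat). Must be `< length_bp / 2`.
#' @param n_genes Number of genes to plant.
#' @param plant_introns Give some protein-coding genes a two-exon
#'   structure?
#' @param wrap_origin_feature Plant a feature spanning the sequence
#'   origin (the D-loop on mitogenome-like records)?
#' @param include_operon Plant one `operon` feature over a gene run?
#' @param iupac_noise_frac Fraction of positions replaced by IUPAC
#'   ambiguity codes (never inside a planted repeat).
#' @param ir_noise_frac Fraction of positions of one repeat copy
#'   mutated to a different standard base (boundaries unchanged).
#' @param seed Integer seed.
#' @return An object of class `fixture_spec`.
#' @export
fixture_spec <- function(kind = c("plastome_like", "mitogenome_like", "generic"),
                         length_bp = NULL, ir_len = NULL, n_genes = NULL,
                         plant_introns = kind == "plastome_like",
                         wrap_origin_feature = kind == "mitogenome_like",
                         include_operon = FALSE,
                         iupac_noise_frac = 0, ir_noise_frac = 0, seed = 1L) {
  kind <- match.arg(kind)
  length_bp <- as.integer(length_bp %||% switch(kind, plastome_like = 150000L,
                                                mitogenome_like = 16500L,
                                                generic = 10000L))
  ir_len <- as.integer(ir_len %||% if (kind == "plastome_like") {
    min(25000L, length_bp %/% 6L)
  } else 0L)
  n_genes <- as.integer(n_genes %||% switch(kind, plastome_like = 45L,
                                            mitogenome_like = 30L,
                                            generic = 12L))
  if (ir_len > 0L && 2L * ir_len >= length_bp) {
    orgmapr_stop("orgmapr_input_error", "ir_len must be < length_bp / 2")
  }
  if (iupac_noise_frac < 0 || iupac_noise_frac > 1) {
    orgmapr_stop("orgmapr_input_error", "iupac_noise_frac must be in [0, 1]")
  }
  structure(list(kind = kind, length_bp = length_bp, ir_len = ir_len,
                 n_genes = n_genes, plant_introns = isTRUE(plant_introns),
                 wrap_origin_feature = isTRUE(wrap_origin_feature),
                 include_operon = isTRUE(include_operon),
                 iupac_noise_frac = iupac_noise_frac,
                 ir_noise_frac = ir_noise_frac, seed = as.integer(seed)),
            class = "fixture_spec")
}

BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")
AMBIG <- c("N", "R", "Y", "S", "W", "K", "M")

random_bases <- function(n) sample(BASES, n, replace = TRUE)

#' Generate a synthetic GenBank record
#'
#' Builds the sequence and feature table described by a
#' [fixture_spec()] and renders it as valid GenBank flat-file text
#' (LOCUS / FEATURES / ORIGIN / `//`) that round-trips through
#' [read_genbank()]. The accompanying ground truth lists every planted
#' feature and the exact repeat boundaries for assertions.
#'
#' @param spec A [fixture_spec()].
#' @return List with elements `text` (GenBank flat-file text), `truth`
#'   (accession, topology, source category, planted features with
#'   parts/strand, `ir` boundaries, `dloop` bounds) and `spec`.
#' @export
make_fixture <- function(spec) {
  stopifnot(inherits(spec, "fixture_spec"))
  with_seed(spec$seed, build_fixture(spec))
}

build_fixture <- function(spec) {
  L <- spec$length_bp
  ir <- spec$ir_len
  chars <- random_bases(L)
  truth <- list(topology = "circular", ir = NULL, dloop = NULL)

  if (spec$kind == "plastome_like" && ir > 0L) {
    lsc <- as.integer(round((L - 2L * ir) * 0.8))
    ssc <- L - 2L * ir - lsc
    irb_rng <- c(lsc + 1L, lsc + ir)
    ira_rng <- c(L - ir + 1L, L)
    chars[ira_rng[1L]:ira_rng[2L]] <-
      rev(COMP[chars[irb_rng[1L]:irb_rng[2L]]])
    # enforce repeat maximality: the first SSC base must not equal the
    # complement of the last SSC base, or the pair would extend further
    ssc_first <- irb_rng[2L] + 1L
    ssc_last <- ira_rng[1L] - 1L
    if (chars[ssc_first] == COMP[chars[ssc_last]]) {
      chars[ssc_first] <- BASES[match(COMP[chars[ssc_last]], BASES) %% 4L + 1L]
    }
    if (spec$ir_noise_frac > 0) {
      n_mut <- max(1L, floor(spec$ir_noise_frac * ir))
      at <- irb_rng[1L] + sample.int(ir - 2L, n_mut) # keep the ends intact
      chars[at] <- vapply(chars[at], function(b) {
        sample(setdiff(BASES, b), 1L)
      }, character(1L))
    }
    truth$ir <- list(ir_a = ira_rng, ir_b = irb_rng, length_bp = ir)
    regions <- list(c(2L, lsc - 1L), c(ssc_first + 1L, ssc_last - 1L))
  } else {
    regions <- list(c(2L, L - 1L))
  }

  feats <- list()
  add_feat <- function(key, parts, strand, gene = NULL, quals = character(),
                       wraps = FALSE) {
    feats[[length(feats) + 1L]] <<- list(key = key, parts = parts,
                                         strand = strand, gene = gene,
                                         quals = quals, wraps = wraps)
  }

  if (spec$kind == "mitogenome_like" && spec$wrap_origin_feature) {
    dl_tail <- max(2L, L - 549L)
    dl_head <- 450L
    truth$dloop <- list(tail = c(dl_tail, L), head = c(1L, dl_head))
    add_feat("D-loop", rbind(c(dl_tail, L), c(1L, dl_head)), "+",
             wraps = TRUE)
    regions <- list(c(dl_head + 2L, dl_tail - 2L))
  }

  lex <- gene_lexicon()
  pool <- switch(spec$kind,
                 plastome_like = lex[lex$category == "plastid", ],
                 mitogenome_like = lex[lex$category == "mitochondrial", ],
                 NULL)
  reg_len <- vapply(regions, function(r) r[2L] - r[1L] + 1L, integer(1L))
  n_genes <- spec$n_genes
  n_genes <- min(n_genes, max(1L, sum(reg_len) %/% 150L))
  if (!is.null(pool)) n_genes <- min(n_genes, nrow(pool))
  names_draw <- if (is.null(pool)) {
    paste0("orf", seq_len(n_genes))
  } else {
    pool$name[sample.int(nrow(pool), n_genes)]
  }
  slots_per <- pmax(0L, as.integer(round(n_genes * reg_len / sum(reg_len))))
  while (sum(slots_per) < n_genes) slots_per[1L] <- slots_per[1L] + 1L
  while (sum(slots_per) > n_genes) {
    i <- which(slots_per > 0L)[1L]
    slots_per[i] <- slots_per[i] - 1L
  }

  gi <- 0L
  for (ri in seq_along(regions)) {
    r <- regions[[ri]]
    ns <- slots_per[ri]
    if (ns == 0L) next
    slot_w <- (r[2L] - r[1L] + 1L) %/% ns
    for (s in seq_len(ns)) {
      gi <- gi + 1L
      gname <- names_draw[gi]
      s0 <- r[1L] + (s - 1L) * slot_w
      s1 <- min(r[1L] + s * slot_w - 10L, r[2L])
      is_trna <- grepl("^trn", gname)
      is_rrna <- grepl("^rrn", gname)
      glen <- if (is_trna) 74L
              else if (is_rrna) min(1500L, s1 - s0 - 10L)
              else sample(300:1500, 1L)
      glen <- max(30L, min(glen, s1 - s0 - 5L))
      gs <- s0 + sample.int(max(1L, s1 - s0 - glen), 1L)
      ge <- min(gs + glen - 1L, r[2L])
      if (ge - gs + 1L < 30L) next
      glen <- ge - gs + 1L
      strand <- if (stats::runif(1) < 0.5) "+" else "-"
      key <- if (is_trna) "tRNA" else if (is_rrna) "rRNA" else "CDS"
      with_intron <- spec$plant_introns && key == "CDS" && glen >= 600L &&
        stats::runif(1) < 0.3
      parts <- if (with_intron) {
        e1 <- gs + as.integer(glen * 0.3)
        i2 <- e1 + as.integer(glen * 0.3)
        rbind(c(gs, e1), c(i2, ge))
      } else {
        rbind(c(gs, ge))
      }
      add_feat("gene", rbind(c(gs, ge)), strand, gene = gname)
      add_feat(key, parts, strand, gene = gname,
               quals = c(product = paste(gname, "product")))
    }
  }

  if (spec$include_operon && gi >= 2L) {
    g1 <- feats[[which(vapply(feats, function(f) f$key == "gene", logical(1L)))[1L]]]
    span <- c(g1$parts[1L, 1L], min(L, g1$parts[1L, 2L] + 2000L))
    add_feat("operon", rbind(span), g1$strand,
             quals = c(note = "polycistronic transcription unit"))
  }
  if (!is.null(truth$ir)) {
    add_feat("repeat_region", rbind(truth$ir$ir_b), "+",
             quals = c(note = "inverted repeat B"))
    add_feat("repeat_region", rbind(truth$ir$ir_a), "-",
             quals = c(note = "inverted repeat A"))
  }

  if (spec$iupac_noise_frac > 0) {
    n_noise <- max(1L, floor(spec$iupac_noise_frac * L))
    allowed <- unlist(lapply(regions, function(r) r[1L]:r[2L]))
    at <- allowed[sample.int(length(allowed), min(n_noise, length(allowed)))]
    chars[at] <- sample(AMBIG, length(at), replace = TRUE)
  }

  # stable file order: by first coordinate, wrapping features first
  ord <- order(vapply(feats, function(f) if (f$wraps) 0L else f$parts[1L, 1L],
                      integer(1L)))
  feats <- feats[ord]

  accession <- sprintf("SYN%s%06d",
                       switch(spec$kind, plastome_like = "P",
                              mitogenome_like = "M", generic = "G"),
                       spec$seed %% 1000000L)
  organism <- switch(spec$kind,
                     plastome_like = "Synthetica plastophila",
                     mitogenome_like = "Synthetica animalis",
                     generic = "Synthetica generica")
  definition <- switch(spec$kind,
    plastome_like = sprintf("%s chloroplast, complete genome.", organism),
    mitogenome_like = sprintf("%s mitochondrion, complete genome.", organism),
    generic = sprintf("%s plasmid, complete sequence.", organism))
  organelle <- switch(spec$kind, plastome_like = "plastid:chloroplast",
                      mitogenome_like = "mitochondrion", generic = NULL)

  sequence <- chars_to_str(chars)
  text <- render_genbank(accession, organism, definition, sequence, L,
                         "circular", organelle, feats)
  truth$accession <- accession
  truth$length_bp <- L
  truth$source_category <- switch(spec$kind, plastome_like = "plastid",
                                  mitogenome_like = "mitochondrial",
                                  generic = "other")
  truth$features <- feats
  truth$sequence <- sequence
  list(text = text, truth = truth, spec = spec)
}

location_text <- function(parts, strand) {
  rngs <- apply(parts, 1L, function(p) {
    if (p[1L] == p[2L]) as.character(p[1L]) else sprintf("%d..%d", p[1L], p[2L])
  })
  body <- if (length(rngs) > 1L) {
    sprintf("join(%s)", paste(rngs, collapse = ","))
  } else {
    rngs
  }
  if (strand == "-") sprintf("complement(%s)", body) else body
}

render_genbank <- function(accession, organism, definition, sequence, L,
                           topology, organelle, feats) {
  lines <- c(
    sprintf("LOCUS       %-17s%d bp    DNA     %-9s PLN 01-JAN-2020",
            accession, L, topology),
    sprintf("DEFINITION  %s", definition),
    sprintf("ACCESSION   %s", accession),
    sprintf("SOURCE      %s", organism),
    sprintf("  ORGANISM  %s", organism),
    "FEATURES             Location/Qualifiers",
    sprintf("     %-16s%s", "source", sprintf("1..%d", L)),
    sprintf("                     /organism=\"%s\"", organism))
  if (!is.null(organelle)) {
    lines <- c(lines,
               sprintf("                     /organelle=\"%s\"", organelle))
  }
  for (f in feats) {
    lines <- c(lines, sprintf("     %-16s%s", f$key,
                              location_text(f$parts, f$strand)))
    if (!is.null(f$gene)) {
      lines <- c(lines, sprintf("                     /gene=\"%s\"", f$gene))
    }
    if (length(f$quals)) {
      lines <- c(lines, sprintf("                     /%s=\"%s\"",
                                names(f$quals), f$quals))
    }
  }
  lines <- c(lines, "ORIGIN", origin_block(sequence, L), "//")
  paste(lines, collapse = "\n")
}

origin_block <- function(sequence, L) {
  starts <- seq.int(1L, L, by = 60L)
  chunks <- substring(tolower(sequence), starts, pmin(starts + 59L, L))
  spaced <- gsub("(.{10})", "\\1 ", chunks)
  sprintf("%9d %s", starts, trimws(spaced, which = "right"))
}

#' Write a fixture to disk
#'
#' @param fixture A [make_fixture()] result.
#' @param path Output file path (GenBank flat file).
#' @return `path`, invisibly.
#' @export
write_fixture <- function(fixture, path) {
  writeLines(fixture$text, path)
  invisible(path)
}
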