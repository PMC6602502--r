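# GenBank flat-file reader. Hand-written against the NCBI flat-file
# grammar (LOCUS / DEFINITION / FEATURES / ORIGIN / "//"), because the
# installed sequence packages either fetch records over the network or
# ignore the feature table. Supports concatenated multi-record files,
# join/complement locations, origin-spanning features and IUPAC
# ambiguity characters in ORIGIN.

#' Read one or more GenBank records
#'
#' Parses a GenBank flat file (single- or multi-record) into a list of
#' [genome_record()] objects in file order. Compound locations
#' (`join`, `order`, `complement`) are resolved into location parts;
#' fuzzy positions (`<`, `>`) are clamped to their numeric bounds with a
#' warning; IUPAC ambiguity characters in ORIGIN are preserved verbatim.
#' Records without an ORIGIN block get an empty sequence and
#' sequence-dependent operations will refuse to run on them.
#' Topology and source category are resolved per record via
#' [resolve_topology_and_source()].
#'
#' @param x A file path, a single string containing the flat-file text,
#'   or a character vector of lines.
#' @return List of `genome_record` objects, one per LOCUS...// block.
#' @seealso [make_fixture()] to generate records for experimentation.
#' @export
read_genbank <- function(x) {
  lines <- genbank_lines(x)
  locus_at <- grep("^LOCUS", lines)
  if (length(locus_at) == 0L) {
    orgmapr_stop("orgmapr_parse_error", "no LOCUS line found: not a GenBank flat file")
  }
  end_at <- grep("^//\\s*$", lines)
  records <- vector("list", length(locus_at))
  for (k in seq_along(locus_at)) {
    li <- locus_at[k]
    ti <- end_at[end_at > li]
    if (length(ti) == 0L) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("record %d (line %d) is unterminated: no '//' found", k, li),
                   record = k, line = li)
    }
    ti <- ti[1L]
    if (k < length(locus_at) && locus_at[k + 1L] < ti) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("record %d (line %d) is unterminated before the next LOCUS", k, li),
                   record = k, line = li)
    }
    records[[k]] <- parse_gb_record(lines[li:ti], k, li - 1L)
  }
  lapply(records, resolve_topology_and_source)
}

genbank_lines <- function(x) {
  if (length(x) > 1L) return(x)
  stopifnot(is.character(x), length(x) == 1L)
  if (grepl("\n", x, fixed = TRUE)) {
    strsplit(x, "\n", fixed = TRUE)[[1L]]
  } else {
    if (!file.exists(x)) {
      orgmapr_stop("orgmapr_input_error", sprintf("input file not found: %s", x))
    }
    readLines(x, warn = FALSE)
  }
}

parse_gb_record <- function(lines, rec_idx, offset) {
  m <- regmatches(lines[1L],
                  regexec("^LOCUS\\s+(\\S+)\\s+(\\d+)\\s+bp\\b", lines[1L]))[[1L]]
  if (length(m) == 0L) {
    orgmapr_stop("orgmapr_parse_error",
                 sprintf("record %d: malformed LOCUS line at line %d", rec_idx, offset + 1L),
                 record = rec_idx, line = offset + 1L)
  }
  locus_name <- m[2L]
  length_bp <- as.integer(m[3L])
  topology <- if (grepl("\\bcircular\\b", lines[1L], ignore.case = TRUE)) {
    "circular"
  } else {
    "linear"
  }

  definition <- keyword_text(lines, "DEFINITION")
  accession <- keyword_text(lines, "ACCESSION")
  accession <- if (nzchar(accession)) strsplit(accession, "\\s+")[[1L]][1L] else locus_name
  organism <- ""
  oi <- grep("^ {1,3}ORGANISM", lines)
  if (length(oi)) organism <- trimws(sub("^ {1,3}ORGANISM\\s*", "", lines[oi[1L]]))
  source_line <- keyword_text(lines, "SOURCE")

  fstart <- grep("^FEATURES", lines)
  feats <- list()
  if (length(fstart)) {
    fstart <- fstart[1L]
    stops <- grep("^(ORIGIN|BASE COUNT|CONTIG|//)", lines)
    fend <- min(stops[stops > fstart])
    if (fend > fstart + 1L) {
      feats <- parse_feature_table(lines[(fstart + 1L):(fend - 1L)],
                                   rec_idx, offset + fstart)
    }
  }

  sequence <- ""
  ostart <- grep("^ORIGIN", lines)
  if (length(ostart)) {
    ostart <- ostart[1L]
    n <- length(lines)
    if (n - 1L >= ostart + 1L) {
      body <- paste(lines[(ostart + 1L):(n - 1L)], collapse = "")
      sequence <- toupper(gsub("[^A-Za-z]", "", body))
    }
  }

  rec <- genome_record(accession = accession, length_bp = length_bp,
                       sequence = sequence, topology = topology,
                       source_category = "other", features = feats,
                       organism = organism,
                       definition = paste(definition, source_line))
  if (topology == "linear" &&
      any(vapply(feats, function(f) f$location$wraps_origin, logical(1L)))) {
    orgmapr_warn(sprintf(
      "%s: LOCUS says linear but a feature wraps the origin; keeping LOCUS topology",
      accession))
  }
  rec
}

keyword_text <- function(lines, keyword) {
  i <- grep(paste0("^", keyword, "\\b"), lines)
  if (length(i) == 0L) return("")
  i <- i[1L]
  out <- sub(paste0("^", keyword, "\\s*"), "", lines[i])
  j <- i + 1L
  while (j <= length(lines) && grepl("^ ", lines[j]) &&
         !grepl("^ {1,3}[A-Z]", lines[j])) {
    out <- paste(out, trimws(lines[j]))
    j <- j + 1L
  }
  trimws(out)
}

parse_feature_table <- function(flines, rec_idx, offset) {
  feats <- list()
  cur_key <- NULL
  cur_loc <- ""
  cur_line <- 0L
  quals <- character()
  qual_name <- NULL
  qual_open <- FALSE
  qual_val <- ""

  close_qual <- function() {
    if (!is.null(qual_name)) {
      # first occurrence wins for the names we consume (gene, product)
      if (!qual_name %in% names(quals)) quals[qual_name] <<- qual_val
      qual_name <<- NULL
      qual_open <<- FALSE
      qual_val <<- ""
    }
  }
  flush_feature <- function() {
    close_qual()
    if (!is.null(cur_key)) {
      loc <- parse_gb_location(cur_loc, rec_idx, cur_line)
      feats[[length(feats) + 1L]] <<- feature_instance(
        key = cur_key, location = loc,
        gene = if ("gene" %in% names(quals)) unname(quals["gene"]) else NULL,
        product = if ("product" %in% names(quals)) unname(quals["product"]) else NULL,
        qualifiers = quals)
      cur_key <<- NULL
      quals <<- character()
    }
  }

  for (i in seq_along(flines)) {
    line <- flines[i]
    if (!nzchar(trimws(line))) next
    if (grepl("^ {5}\\S", line) && !grepl("^ {6}", line)) {
      flush_feature()
      mm <- regmatches(line, regexec("^ {5}(\\S+)\\s*(.*)$", line))[[1L]]
      cur_key <- mm[2L]
      cur_loc <- mm[3L]
      cur_line <- offset + i
      next
    }
    content <- trimws(line)
    if (is.null(cur_key)) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("record %d: feature table continuation without a feature at line %d",
                           rec_idx, offset + i),
                   record = rec_idx, line = offset + i)
    }
    if (qual_open) {
      qual_val <- paste(qual_val, content)
      if (grepl("\"$", content)) {
        qual_val <- sub("\"$", "", qual_val)
        qual_open <- FALSE
        close_qual()
      }
      next
    }
    if (startsWith(content, "/")) {
      close_qual()
      mm <- regmatches(content,
                       regexec("^/([A-Za-z_0-9]+)(=(.*))?$", content))[[1L]]
      if (length(mm) == 0L) {
        orgmapr_stop("orgmapr_parse_error",
                     sprintf("record %d: malformed qualifier at line %d",
                             rec_idx, offset + i),
                     record = rec_idx, line = offset + i)
      }
      qual_name <- mm[2L]
      val <- mm[4L]
      if (identical(mm[3L], "")) {            # flag qualifier, no value
        qual_val <- "TRUE"
        close_qual()
      } else if (startsWith(val, "\"")) {
        val <- sub("^\"", "", val)
        if (grepl("\"$", val)) {
          qual_val <- sub("\"$", "", val)
          close_qual()
        } else {
          qual_val <- val
          qual_open <- TRUE
        }
      } else {
        qual_val <- val
        close_qual()
      }
      next
    }
    # continuation of a multi-line location
    cur_loc <- paste0(cur_loc, content)
  }
  flush_feature()
  feats
}

# split "a,b,c" at top-level commas (ignoring commas inside parentheses)
split_top_level <- function(txt) {
  chars <- str_to_chars(txt)
  depth <- cumsum((chars == "(") - (chars == ")"))
  cuts <- which(chars == "," & depth == 0L)
  starts <- c(1L, cuts + 1L)
  ends <- c(cuts - 1L, length(chars))
  mapply(function(s, e) chars_to_str(chars[s:e]), starts, ends,
         USE.NAMES = FALSE)
}

parse_gb_location <- function(txt, rec_idx, line_no) {
  txt <- gsub("\\s", "", txt)
  if (!nzchar(txt)) {
    orgmapr_stop("orgmapr_parse_error",
                 sprintf("record %d: empty feature location at line %d", rec_idx, line_no),
                 record = rec_idx, line = line_no)
  }
  strand <- "+"
  if (grepl("^complement\\(", txt)) {
    strand <- "-"
    txt <- sub("^complement\\((.*)\\)$", "\\1", txt)
  }
  if (grepl("^(join|order)\\(", txt)) {
    txt <- sub("^(join|order)\\((.*)\\)$", "\\2", txt)
  }
  pieces <- split_top_level(txt)
  fuzzy <- FALSE
  parts <- matrix(0L, nrow = length(pieces), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  for (i in seq_along(pieces)) {
    p <- pieces[i]
    if (grepl("^complement\\(", p)) {
      strand <- "-"
      p <- sub("^complement\\((.*)\\)$", "\\1", p)
    }
    if (grepl("[<>]", p)) {
      fuzzy <- TRUE
      p <- gsub("[<>]", "", p)
    }
    p <- sub("\\^", "..", p)                  # between-base site -> range
    mm <- regmatches(p, regexec("^(\\d+)(\\.\\.(\\d+))?$", p))[[1L]]
    if (length(mm) == 0L) {
      orgmapr_stop("orgmapr_parse_error",
                   sprintf("record %d: cannot parse location '%s' at line %d",
                           rec_idx, pieces[i], line_no),
                   record = rec_idx, line = line_no)
    }
    s <- as.integer(mm[2L])
    e <- if (nzchar(mm[3L])) as.integer(mm[4L]) else s
    parts[i, ] <- c(s, e)
  }
  if (fuzzy) {
    orgmapr_warn(sprintf("record %d: fuzzy position clamped to numeric bounds (line %d)",
                         rec_idx, line_no))
  }
  wraps <- nrow(parts) >= 2L && any(diff(parts[, 1L]) < 0L)
  feature_location(parts, strand = strand, wraps_origin = wraps)
}

#' Resolve topology and sequence source of a record
#'
#' Topology comes from the LOCUS line token (`circular`/`linear`,
#' defaulting to linear); the source category is inferred from, in
#' order: the `/organelle` qualifier of the `source` feature, then a
#' case-insensitive keyword scan of DEFINITION and SOURCE text
#' (`chloroplast`/`plastid` -> plastid; `mitochondrion`/`mitochondrial`
#' -> mitochondrial), else `other`. Both fields can be forced by the
#' caller.
#'
#' @param record A [genome_record()].
#' @param topology Optional override (`"circular"` or `"linear"`).
#' @param source_category Optional override.
#' @return The record with both fields resolved.
#' @export
resolve_topology_and_source <- function(record, topology = NULL,
                                        source_category = NULL) {
  stopifnot(inherits(record, "genome_record"))
  if (!is.null(topology)) {
    record$topology <- match.arg(topology, c("circular", "linear"))
  }
  if (!is.null(source_category)) {
    record$source_category <- match.arg(source_category,
                                        c("plastid", "mitochondrial", "other"))
    return(record)
  }
  record$source_category <- infer_source_category(record)
  record
}

infer_source_category <- function(record) {
  for (f in record$features) {
    if (f$key == "source" && "organelle" %in% names(f$qualifiers)) {
      org <- tolower(f$qualifiers[["organelle"]])
      if (grepl("mitochond", org)) return("mitochondrial")
      if (grepl("plastid|chloroplast", org)) return("plastid")
    }
  }
  text <- tolower(paste(record$definition, record$organism))
  if (grepl("chloroplast|plastid", text)) return("plastid")
  if (grepl("mitochondrion|mitochondrial", text)) return("mitochondrial")
  "other"
}
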