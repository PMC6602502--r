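# Sequence-level computations: circular coordinate arithmetic,
# sliding-window GC content, inverted-repeat detection and degenerate
# restriction-site scanning.

#' Shortest distance between two positions
#'
#' On a linear molecule this is `|b - a|`; on a circular molecule the
#' shorter way around, `min(|b - a|, length - |b - a|)`.
#'
#' @param a,b 1-based positions in `[1, length]`.
#' @param length Molecule length in bp.
#' @param topology `"circular"` or `"linear"`.
#' @return Distance in bp.
#' @export
circular_distance <- function(a, b, length, topology = c("circular", "linear")) {
  topology <- match.arg(topology)
  if (any(c(a, b) < 1L) || any(c(a, b) > length)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("positions must lie in [1, %d]", length))
  }
  d <- abs(b - a)
  if (topology == "circular") pmin(d, length - d) else d
}

require_sequence <- function(record, what) {
  if (!nzchar(record$sequence)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("sequence required: record %s has no ORIGIN block, cannot compute %s",
                         record$accession, what))
  }
}

#' Sliding-window GC content
#'
#' Windows start every `step_bp` bases; on circular records they wrap
#' the origin and there are exactly `ceiling(length / step_bp)` windows.
#' The GC fraction counts G, C and S in the numerator and only
#' unambiguously counting bases (A, C, G, T, U, S, W) in the
#' denominator; all other IUPAC ambiguity codes are excluded from both.
#' A window with no counting bases reports 0.
#'
#' @param record A [genome_record()] with sequence.
#' @param window_bp Window width in bp.
#' @param step_bp Step between window starts in bp.
#' @return An object of class `gc_profile`: `window_bp`, `step_bp`, and
#'   a data frame `values` with columns `window_center` (position) and
#'   `gc_fraction` in `[0, 1]`.
#' @export
gc_profile <- function(record, window_bp = 500L, step_bp = window_bp) {
  require_sequence(record, "the GC profile")
  window_bp <- as.integer(window_bp)
  step_bp <- as.integer(step_bp)
  stopifnot(window_bp >= 1L, step_bp >= 1L)
  chars <- str_to_chars(record$sequence)
  L <- record$length_bp
  is_gc <- chars %in% c("G", "C", "S")
  is_ct <- chars %in% c("A", "C", "G", "T", "U", "S", "W")
  circular <- record$topology == "circular"
  if (circular) {
    starts <- seq.int(1L, L, by = step_bp)
    w <- min(window_bp, L)
    if (w > 1L) {
      is_gc <- c(is_gc, is_gc[seq_len(w - 1L)])
      is_ct <- c(is_ct, is_ct[seq_len(w - 1L)])
    }
  } else {
    w <- min(window_bp, L)
    starts <- seq.int(1L, max(1L, L - w + 1L), by = step_bp)
  }
  cs_gc <- c(0, cumsum(is_gc))
  cs_ct <- c(0, cumsum(is_ct))
  num <- cs_gc[starts + w] - cs_gc[starts]
  den <- cs_ct[starts + w] - cs_ct[starts]
  frac <- ifelse(den > 0, num / den, 0)
  centers <- ((starts - 1L + (w - 1L) %/% 2L) %% L) + 1L
  structure(list(window_bp = window_bp, step_bp = step_bp,
                 values = data.frame(window_center = centers,
                                     gc_fraction = frac)),
            class = "gc_profile")
}

#' Shipped restriction-enzyme table
#'
#' A curated table of common type II enzymes (name, IUPAC recognition
#' sequence, cut offset), shipped as a plain-text file and extensible
#' via [options()]-free arguments in the CLI.
#'
#' @param extra_file Optional path to a user table with the same three
#'   columns, appended to the shipped one (later entries win).
#' @return Data frame with columns `name`, `site`, `cut_offset`.
#' @export
enzyme_table <- function(extra_file = NULL) {
  tab <- .orgmapr_cache$enzymes
  if (is.null(tab)) {
    tab <- utils::read.delim(extdata_path("enzymes.tsv"),
                             stringsAsFactors = FALSE)
    .orgmapr_cache$enzymes <- tab
  }
  if (!is.null(extra_file)) {
    extra <- utils::read.delim(extra_file, stringsAsFactors = FALSE)
    tab <- rbind(tab[!tab$name %in% extra$name, ], extra)
  }
  tab
}

iupac_to_regex <- function(pattern) {
  sets <- IUPAC_SETS[str_to_chars(toupper(pattern))]
  if (anyNA(names(sets)) || any(vapply(sets, is.null, logical(1L)))) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("recognition sequence '%s' contains a non-IUPAC character", pattern))
  }
  paste(vapply(sets, function(s) {
    if (length(s) == 1L) s else paste0("[", paste(s, collapse = ""), "]")
  }, character(1L)), collapse = "")
}

regex_positions <- function(subject, regex) {
  m <- gregexpr(paste0("(?=", regex, ")"), subject, perl = TRUE)[[1L]]
  if (m[1L] == -1L) integer() else as.integer(m)
}

#' Scan restriction sites
#'
#' Finds all matches of each enzyme's recognition sequence on both
#' strands. IUPAC degeneracy is expanded on the pattern side only:
#' ambiguity codes in the genome never satisfy a match. On circular
#' records, sites spanning the origin are reported at their wrapped
#' start position. Palindromic sites are reported once, on the plus
#' strand. The position of a minus-strand site is the genome coordinate
#' of its leftmost base.
#'
#' @param record A [genome_record()] with sequence.
#' @param enzymes Character vector of enzyme names from [enzyme_table()].
#' @param table Enzyme table (defaults to the shipped one).
#' @return Data frame with columns `enzyme`, `position`, `strand`,
#'   sorted by position.
#' @export
scan_restriction_sites <- function(record, enzymes, table = enzyme_table()) {
  require_sequence(record, "restriction sites")
  unknown <- setdiff(enzymes, table$name)
  if (length(unknown)) {
    orgmapr_stop("orgmapr_input_error",
                 sprintf("unknown enzyme '%s'; valid names: %s",
                         unknown[1L], paste(sort(table$name), collapse = ", ")))
  }
  L <- record$length_bp
  out <- list()
  for (enz in enzymes) {
    site <- table$site[match(enz, table$name)]
    m <- nchar(site)
    subject <- record$sequence
    if (record$topology == "circular" && m > 1L && L >= m) {
      subject <- paste0(subject, substr(subject, 1L, m - 1L))
    }
    pats <- list(`+` = site)
    rc <- revcomp(site)
    if (!identical(rc, toupper(site))) pats$`-` <- rc
    for (strand in names(pats)) {
      pos <- regex_positions(subject, iupac_to_regex(pats[[strand]]))
      pos <- pos[pos <= L]
      if (length(pos)) {
        out[[length(out) + 1L]] <- data.frame(
          enzyme = enz, position = pos, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(out)) {
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  res <- do.call(rbind, out)
  res <- res[order(res$position, res$enzyme, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Construct an inverted-repeat pair
#'
#' Orders the two copies by the drawing convention: `ir_a` is the copy
#' immediately upstream (counter-clockwise) of position 1 — the one
#' drawn on the right half of a circular map, ending at the map origin.
#'
#' @param seg1,seg2 `(start, end)` of the two copies, 1-based inclusive.
#' @param length_bp Genome length (for the ordering rule).
#' @param method `"annotation"` or `"self_comparison"`.
#' @param n_mismatch Mismatch count between the copies (de novo method).
#' @return Object of class `repeat_pair` with fields `ir_a`, `ir_b`,
#'   `length_bp`, `method`, `n_mismatch`.
#' @export
repeat_pair <- function(seg1, seg2, length_bp, method, n_mismatch = 0L) {
  gap <- function(seg) (length_bp - seg[2L]) %% length_bp
  if (gap(seg2) < gap(seg1)) {
    tmp <- seg1; seg1 <- seg2; seg2 <- tmp
  }
  structure(list(ir_a = as.integer(seg1), ir_b = as.integer(seg2),
                 length_bp = as.integer(seg1[2L] - seg1[1L] + 1L),
                 method = method, n_mismatch = as.integer(n_mismatch)),
            class = "repeat_pair")
}

#' @export
print.repeat_pair <- function(x, ...) {
  cat(sprintf("<repeat_pair> IR_A %d..%d, IR_B %d..%d (%s bp, %s, %d mismatches)\n",
              x$ir_a[1L], x$ir_a[2L], x$ir_b[1L], x$ir_b[2L],
              format(x$length_bp, big.mark = ","), x$method, x$n_mismatch))
  invisible(x)
}

#' Locate the large inverted repeat of a genome
#'
#' Two detection methods. `annotation`: pair the two annotated repeat
#' features (feature key `repeat_region`, or any feature whose `/note`
#' or `/rpt_type` mentions an inverted repeat / IRa / IRb).
#' `self_comparison` (de novo): seed-and-extend between the forward
#' sequence and its reverse complement — exact 21-mer seeds at a stride
#' that guarantees a seed inside any repeat of at least `min_len`,
#' exact extension when `max_mismatch_frac = 0`, otherwise x-drop
#' extension trimmed so the reported pair's mismatch fraction stays
#' within budget. The longest pair of disjoint segments of at least
#' `min_len` is returned; `NULL` when nothing qualifies or
#' `method = "none"`. The returned `ir_a` is always the copy ending at
#' the map origin (drawn on the right).
#'
#' @param record A [genome_record()].
#' @param method `"annotation"`, `"self_comparison"` or `"none"`.
#' @param min_len Minimum repeat length in bp (default 1000).
#' @param max_mismatch_frac Mismatch budget as a fraction of repeat
#'   length (default 0.01).
#' @return A [repeat_pair()] or `NULL`.
#' @export
find_inverted_repeats <- function(record,
                                  method = c("annotation", "self_comparison", "none"),
                                  min_len = 1000L, max_mismatch_frac = 0.01) {
  method <- match.arg(method)
  if (method == "none") return(NULL)
  if (method == "annotation") {
    if (length(record$features) == 0L) {
      orgmapr_stop("orgmapr_input_error",
                   "annotation-based IR detection needs features, record has none")
    }
    return(ir_from_annotation(record))
  }
  require_sequence(record, "de novo inverted-repeat detection")
  ir_self_comparison(record, as.integer(min_len), max_mismatch_frac)
}

IR_NOTE_REGEX <- "inverted[ _-]?repeat|\\bIR[ _-]?[AaBb]\\b"

ir_from_annotation <- function(record) {
  cand <- Filter(function(f) {
    notes <- paste(f$qualifiers[names(f$qualifiers) %in% c("note", "rpt_type")],
                   collapse = " ")
    f$key == "repeat_region" ||
      grepl(IR_NOTE_REGEX, notes, ignore.case = TRUE)
  }, record$features)
  if (length(cand) < 2L) return(NULL)
  ext <- lapply(cand, function(f) location_extent(f$location, record$length_bp))
  lens <- vapply(ext, `[[`, integer(1L), "length")
  pick <- order(lens, decreasing = TRUE)[1:2]
  e1 <- ext[[pick[1L]]]; e2 <- ext[[pick[2L]]]
  repeat_pair(c(e1$start, e1$end), c(e2$start, e2$end),
              record$length_bp, method = "annotation")
}

ir_self_comparison <- function(record, min_len, frac) {
  k <- 21L
  if (min_len < k) min_len <- k
  L <- record$length_bp
  if (L < 2L * min_len) return(NULL)
  seq <- record$sequence
  rc <- revcomp(seq)
  sraw <- charToRaw(seq)
  rcraw <- charToRaw(rc)
  stride <- max(1L, min_len - k)
  seeds <- seq.int(1L, L - k + 1L, by = stride)
  best <- NULL
  found <- matrix(numeric(0), ncol = 2L)  # genome intervals already explained
  for (i in seeds) {
    if (nrow(found) &&
        any(i >= found[, 1L] & (i + k - 1L) <= found[, 2L])) next
    kmer <- substr(seq, i, i + k - 1L)
    hits <- gregexpr(kmer, rc, fixed = TRUE)[[1L]]
    if (hits[1L] == -1L) next
    for (j in utils::head(as.integer(hits), 4L)) {
      pair <- extend_ir_match(sraw, rcraw, i, i + k - 1L, j, j + k - 1L, frac)
      a1 <- pair$a1; b1 <- pair$b1
      # map the reverse-complement segment back to genome coordinates
      s2 <- L - pair$b2 + 1L
      e2 <- L - pair$a2 + 1L
      if (a1 <= e2 && s2 <= b1) next            # overlapping: a palindrome, not an IR
      len <- b1 - a1 + 1L
      if (len < min_len) next
      found <- rbind(found, c(a1, b1), c(s2, e2))
      if (is.null(best) || len > best$len) {
        best <- list(seg1 = c(a1, b1), seg2 = c(s2, e2), len = len,
                     mm = pair$mm)
      }
    }
  }
  if (is.null(best)) return(NULL)
  repeat_pair(best$seg1, best$seg2, L, method = "self_comparison",
              n_mismatch = best$mm)
}

# Extend an exact k-mer match (seq[i1..i2] == rc[j1..j2]) in both
# directions. frac == 0: stop at the first mismatch. frac > 0: x-drop
# scoring (+1 match / -2 mismatch, drop threshold 20), then trim so the
# final mismatch fraction is <= frac.
extend_ir_match <- function(sraw, rcraw, i1, i2, j1, j2, frac) {
  L <- length(sraw)
  xdrop <- 20L

  extend_dir <- function(tmax, idx_s, idx_r) {
    if (tmax <= 0L) return(list(ext = 0L, mmpos = integer()))
    neq <- sraw[idx_s] != rcraw[idx_r]
    if (frac == 0) {
      first <- which(neq)[1L]
      ext <- if (is.na(first)) tmax else first - 1L
      return(list(ext = ext, mmpos = integer()))
    }
    score <- cumsum(ifelse(neq, -2L, 1L))
    cm <- cummax(score)
    stop_at <- which(score < cm - xdrop)[1L]
    limit <- if (is.na(stop_at)) tmax else stop_at
    ext <- which.max(score[seq_len(limit)])
    if (score[ext] <= 0L) ext <- 0L
    list(ext = ext, mmpos = which(neq[seq_len(max(ext, 0L))]))
  }

  tr <- min(L - i2, L - j2)
  right <- extend_dir(tr, if (tr > 0L) (i2 + 1L):(i2 + tr) else integer(),
                      if (tr > 0L) (j2 + 1L):(j2 + tr) else integer())
  tl <- min(i1 - 1L, j1 - 1L)
  left <- extend_dir(tl, if (tl > 0L) (i1 - 1L):(i1 - tl) else integer(),
                     if (tl > 0L) (j1 - 1L):(j1 - tl) else integer())

  ext_r <- right$ext; mm_r <- right$mmpos
  ext_l <- left$ext;  mm_l <- left$mmpos
  core <- i2 - i1 + 1L
  repeat {
    len <- core + ext_l + ext_r
    mm <- length(mm_l) + length(mm_r)
    if (mm <= frac * len) break
    # trim the cheaper end: the one whose outermost mismatch is closest
    # to its tip (removing the fewest matching bases per mismatch shed)
    cost_r <- if (length(mm_r)) ext_r - max(mm_r) + 1L else Inf
    cost_l <- if (length(mm_l)) ext_l - max(mm_l) + 1L else Inf
    if (cost_r <= cost_l) {
      ext_r <- max(mm_r) - 1L
      mm_r <- mm_r[mm_r < max(mm_r)]
    } else {
      ext_l <- max(mm_l) - 1L
      mm_l <- mm_l[mm_l < max(mm_l)]
    }
  }
  list(a1 = i1 - ext_l, b1 = i2 + ext_r,
       a2 = j1 - ext_l, b2 = j2 + ext_r,
       mm = length(mm_l) + length(mm_r))
}
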