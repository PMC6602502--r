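# Independent brute-force oracles, deliberately written without reusing
# any package internals: naive position-by-position IUPAC matching, a
# direct per-window GC counter, and a stepwise circular walk.

ORACLE_IUPAC <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

oracle_revcomp <- function(x) {
  map <- c(A = "T", C = "G", G = "C", T = "A", R = "Y", Y = "R", S = "S",
           W = "W", K = "M", M = "K", B = "V", V = "B", D = "H", H = "D",
           N = "N")
  paste(rev(map[strsplit(toupper(x), "")[[1]]]), collapse = "")
}

# all plus-strand match positions of an IUPAC pattern: brute force over
# every alignment, one comparison per pattern offset; genome ambiguity
# codes never match (their letter is not in any pattern set of ACGT)
oracle_match_positions <- function(seq, pattern, circular = FALSE) {
  p <- strsplit(toupper(pattern), "")[[1]]
  m <- length(p)
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  subject <- if (circular && m > 1) c(s, s[seq_len(m - 1)]) else s
  npos <- length(subject) - m + 1
  if (npos < 1) return(integer())
  ok <- rep(TRUE, npos)
  for (off in seq_len(m)) {
    ok <- ok & (subject[off:(off + npos - 1)] %in% ORACLE_IUPAC[[p[off]]])
  }
  hits <- which(ok)
  hits[hits <= L]
}

# full both-strand site table matching the scanner's reporting rules
oracle_scan <- function(seq, enzymes, table, circular = FALSE) {
  rows <- list()
  for (enz in enzymes) {
    site <- table$site[match(enz, table$name)]
    pats <- list(`+` = site)
    rc <- oracle_revcomp(site)
    if (!identical(rc, toupper(site))) pats$`-` <- rc
    for (strand in names(pats)) {
      for (pos in oracle_match_positions(seq, pats[[strand]], circular)) {
        rows[[length(rows) + 1]] <- data.frame(
          enzyme = enz, position = pos, strand = strand,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!length(rows)) {
    return(data.frame(enzyme = character(), position = integer(),
                      strand = character(), stringsAsFactors = FALSE))
  }
  out <- do.call(rbind, rows)
  out <- out[order(out$position, out$enzyme, out$strand), , drop = FALSE]
  rownames(out) <- NULL
  out
}

oracle_gc <- function(seq, window, step, circular = TRUE) {
  s <- strsplit(toupper(seq), "")[[1]]
  L <- length(s)
  w <- min(window, L)
  starts <- if (circular) seq(1, L, by = step) else seq(1, max(1, L - w + 1), by = step)
  vapply(starts, function(st) {
    idx <- st:(st + w - 1)
    if (circular) idx <- ((idx - 1) %% L) + 1
    win <- s[idx]
    num <- sum(win %in% c("G", "C", "S"))
    den <- sum(win %in% c("A", "C", "G", "T", "U", "S", "W"))
    if (den > 0) num / den else 0
  }, numeric(1))
}

# shortest-path distance found by literally walking both ways
oracle_walk_distance <- function(a, b, L, topology) {
  if (topology == "linear") return(abs(b - a))
  fwd <- 0; p <- a
  while (p != b) {
    p <- if (p == L) 1 else p + 1
    fwd <- fwd + 1
  }
  bwd <- 0; p <- a
  while (p != b) {
    p <- if (p == 1) L else p - 1
    bwd <- bwd + 1
  }
  min(fwd, bwd)
}

# pairwise label-overlap check recomputed from the layout fields alone
oracle_label_overlaps <- function(layout) {
  el <- layout$elements
  lab <- el[el$kind == "label", , drop = FALSE]
  n <- nrow(lab)
  if (n < 2) return(0L)
  count <- 0L
  for (i in 1:(n - 1)) {
    for (j in (i + 1):n) {
      if (lab$tier[i] != lab$tier[j]) next
      if (layout$shape == "circular") {
        r <- 380 + lab$tier[i] * 26
        half_i <- (lab$width[i] / (2 * pi * r)) * 360 / 2
        half_j <- (lab$width[j] / (2 * pi * r)) * 360 / 2
        d <- abs(lab$a0[i] - lab$a0[j]) %% 360
        d <- min(d, 360 - d)
        if (d < half_i + half_j) count <- count + 1L
      } else {
        d <- abs(lab$x0[i] - lab$x0[j])
        if (d < (lab$width[i] + lab$width[j]) / 2) count <- count + 1L
      }
    }
  }
  count
}

# boolean variant for bulk checks (one expectation per batch, not per
# feature)
features_match_truth <- function(record, truth) {
  parsed <- Filter(function(f) f$key != "source", record$features)
  if (length(parsed) != length(truth$features)) return(FALSE)
  for (k in seq_along(parsed)) {
    pf <- parsed[[k]]
    tf <- truth$features[[k]]
    ok <- identical(pf$key, tf$key) &&
      identical(pf$gene %||% NULL, tf$gene) &&
      identical(pf$location$strand, tf$strand) &&
      isTRUE(all(pf$location$parts == tf$parts)) &&
      identical(pf$location$wraps_origin, tf$wraps)
    if (!ok) return(FALSE)
  }
  identical(record$accession, truth$accession) &&
    identical(record$length_bp, truth$length_bp) &&
    identical(record$topology, truth$topology) &&
    identical(record$source_category, truth$source_category)
}

expect_features_match_truth <- function(record, truth) {
  parsed <- Filter(function(f) f$key != "source", record$features)
  expect_length(parsed, length(truth$features))
  for (k in seq_along(parsed)) {
    pf <- parsed[[k]]
    tf <- truth$features[[k]]
    expect_identical(pf$key, tf$key)
    expect_identical(pf$gene %||% NULL, tf$gene)
    expect_identical(pf$location$strand, tf$strand)
    expect_equal(unname(pf$location$parts), unname(tf$parts))
    expect_identical(pf$location$wraps_origin, tf$wraps)
  }
  expect_identical(record$accession, truth$accession)
  expect_identical(record$length_bp, truth$length_bp)
  expect_identical(record$topology, truth$topology)
  expect_identical(record$source_category, truth$source_category)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
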