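# Hand-rolled miniature GenBank records for parser edge-case tests.

mini_gb <- function(accession = "TST00001", length_bp = NULL,
                    topology = "circular", definition = "Test record.",
                    feature_lines = character(), sequence = "ACGTACGTACGT",
                    origin = TRUE) {
  length_bp <- length_bp %||% nchar(sequence)
  lines <- c(
    sprintf("LOCUS       %-12s %d bp    DNA     %s  UNA 01-JAN-2020",
            accession, length_bp, topology),
    sprintf("DEFINITION  %s", definition),
    sprintf("ACCESSION   %s", accession),
    "FEATURES             Location/Qualifiers",
    feature_lines)
  if (origin) {
    starts <- seq(1, nchar(sequence), by = 60)
    chunks <- substring(tolower(sequence), starts,
                        pmin(starts + 59, nchar(sequence)))
    lines <- c(lines, "ORIGIN", sprintf("%9d %s", starts, chunks))
  }
  paste(c(lines, "//"), collapse = "\n")
}

feat_line <- function(key, loc, ...) {
  quals <- c(...)
  c(sprintf("     %-16s%s", key, loc),
    if (length(quals)) {
      sprintf("                     /%s=\"%s\"", names(quals), quals)
    })
}
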