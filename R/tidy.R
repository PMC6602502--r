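# Gene-name tidy-up: reject over-long free-text names and reformat
# names that violate organellar nomenclature conventions (lower-case
# locus stem + capital suffix letter; trnX-ANT for tRNAs). The
# canonical-name table ships as inst/extdata/gene_lexicon.tsv so users
# can extend it.

#' Normalize a gene name (tidy-up)
#'
#' With `tidy_up = FALSE` the name is returned unchanged. With
#' `tidy_up = TRUE`: names longer than `max_len` characters (after
#' stripping quotes and outer whitespace) are rejected as probable
#' annotation errors; otherwise the name is normalized — stray quotes,
#' whitespace and underscores removed, tRNA names brought to the
#' canonical `trnX-ANT` form (one-letter amino acid, hyphen, upper-case
#' RNA-alphabet anticodon), known loci restored to their canonical
#' casing via the shipped lexicon, and unknown locus-tag-shaped names
#' given a lower-case stem with capital suffix letter. The
#' transformation is deterministic, idempotent and never lengthens a
#' name.
#'
#' @param raw Gene-qualifier text (may be empty).
#' @param tidy_up Apply normalization and rejection? Default `TRUE`.
#' @param max_len Rejection threshold in characters (default 20).
#' @return `list(name =, rejected =)`; `name` is `NA_character_` when
#'   rejected.
#' @examples
#' tidy_gene_name("PSBA")         # "psbA"
#' tidy_gene_name("trnh_gug")     # "trnH-GUG"
#' tidy_gene_name("PSBA", tidy_up = FALSE)  # unchanged
#' @export
tidy_gene_name <- function(raw, tidy_up = TRUE, max_len = 20L) {
  if (is.null(raw) || is.na(raw)) return(list(name = NA_character_, rejected = FALSE))
  if (!tidy_up) return(list(name = raw, rejected = FALSE))
  name <- trimws(gsub("[\"']", "", raw))
  if (nchar(name) > max_len) {
    return(list(name = NA_character_, rejected = TRUE))
  }
  if (!nzchar(name)) return(list(name = "", rejected = FALSE))

  # canonical tRNA form: trnX-ANT (requires an existing separator so the
  # rewrite never lengthens the name)
  m <- regmatches(name,
                  regexec("^[Tt][Rr][Nn]([A-Za-z])[-_ ]([AaCcGgTtUu]{3})$", name))[[1L]]
  if (length(m)) {
    return(list(name = sprintf("trn%s-%s", toupper(m[2L]),
                               chartr("T", "U", toupper(m[3L]))),
                rejected = FALSE))
  }

  # known locus: restore canonical casing from the lexicon
  lex <- gene_lexicon()
  hit <- match(tolower(name), tolower(lex$name))
  if (!is.na(hit)) return(list(name = lex$name[hit], rejected = FALSE))

  # locus-tag shape: 3-letter stem (+ optional capital suffix) (+ digits)
  if (grepl("^[A-Za-z]{4}$", name)) {
    name <- paste0(tolower(substr(name, 1L, 3L)), toupper(substr(name, 4L, 4L)))
  } else if (grepl("^[A-Za-z]{3}[0-9.]+$", name)) {
    name <- paste0(tolower(substr(name, 1L, 3L)), substring(name, 4L))
  } else if (grepl("^[A-Za-z]{4}[0-9]+$", name)) {
    name <- paste0(tolower(substr(name, 1L, 3L)), toupper(substr(name, 4L, 4L)),
                   substring(name, 5L))
  }
  list(name = name, rejected = FALSE)
}
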