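# Shared low-level helpers: IUPAC alphabet handling, reverse complement,
# structured error conditions, and a seed-scoped RNG guard.

IUPAC_CHARS <- c("A", "C", "G", "T", "U", "R", "Y", "S", "W", "K", "M",
                 "B", "D", "H", "V", "N")

# expansion of every IUPAC code into the set of standard bases it stands for
IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T", U = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("G", "C"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Reverse complement of a nucleotide string
#'
#' Complements all IUPAC ambiguity codes (R<->Y, K<->M, B<->V, D<->H;
#' S, W and N are self-complementary) and reverses the string.
#'
#' @param x A single nucleotide string (upper or lower case).
#' @return The reverse complement, case preserved.
#' @examples
#' revcomp("GAATTC")   # palindrome
#' revcomp("ATGNNR")
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  comp <- chartr("ACGTURYSWKMBVDHNacgturyswkmbvdhn",
                 "TGCAAYRSWMKVBHDNtgcaayrswmkvbhdn", x)
  intToUtf8(rev(utf8ToInt(comp)))
}

str_to_chars <- function(x) strsplit(x, "", fixed = TRUE)[[1L]]
chars_to_str <- function(x) paste(x, collapse = "")

# stop() with a classed condition so callers can catch structured errors
orgmapr_stop <- function(class, msg, ...) {
  info <- list(...)
  cond <- structure(
    class = c(class, "orgmapr_error", "error", "condition"),
    list(message = msg, call = sys.call(-1), info = info)
  )
  stop(cond)
}

orgmapr_warn <- function(msg) {
  warning(warningCondition(msg, class = "orgmapr_warning"))
}

# Run `expr` under a temporary RNG state seeded with `seed`; the caller's
# global RNG stream is restored afterwards, so generators never leak
# random state.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

is_hex_color <- function(x) {
  is.character(x) & grepl("^#[0-9A-Fa-f]{6}$", x)
}

extdata_path <- function(file) {
  p <- system.file("extdata", file, package = "orgmapr")
  if (!nzchar(p)) {
    # during development (pkgload) fall back to the source tree
    p <- file.path("inst", "extdata", file)
  }
  p
}
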