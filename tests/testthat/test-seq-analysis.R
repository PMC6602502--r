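test_that("circular distance matches a literal stepwise walk", {
  expect_identical(circular_distance(1, 1, 10000, "circular"), 0)
  expect_identical(circular_distance(9990, 10, 10000, "circular"), 20)
  expect_identical(circular_distance(1, 5001, 10000, "circular"),
                   oracle_walk_distance(1, 5001, 10000, "circular"))
  expect_error(circular_distance(0, 5, 10, "circular"),
               class = "orgmapr_input_error")
  set.seed(42)
  for (i in 1:25) {
    L <- sample(10:500, 1)
    a <- sample(L, 1); b <- sample(L, 1)
    top <- sample(c("circular", "linear"), 1)
    expect_equal(circular_distance(a, b, L, top),
                 oracle_walk_distance(a, b, L, top))
  }
})

gb_rec <- function(seq, topology = "circular", acc = "SEQ00001") {
  genome_record(acc, nchar(seq), sequence = seq, topology = topology)
}

test_that("GC profile hits the degenerate endpoints and the naive counter", {
  all_gc <- gb_rec(strrep("GGCC", 250))
  expect_true(all(gc_profile(all_gc, 100, 100)$values$gc_fraction == 1))
  all_at <- gb_rec(strrep("ATAT", 250))
  expect_true(all(gc_profile(all_at, 100, 100)$values$gc_fraction == 0))

  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 10000, TRUE), collapse = "")
  rec <- gb_rec(seq)
  gp <- gc_profile(rec, 100, 100)
  expect_identical(nrow(gp$values), as.integer(ceiling(10000 / 100)))
  expect_equal(gp$values$gc_fraction, oracle_gc(seq, 100, 100))
})

test_that("GC windows wrap the origin and handle IUPAC codes per the stated rule", {
  # 20 bp circular: window 8 starting at 17 wraps around to position 4
  seq <- paste0(strrep("G", 10), strrep("A", 10))
  gp <- gc_profile(gb_rec(seq), 8, 4)
  expect_equal(gp$values$gc_fraction, oracle_gc(seq, 8, 4))
  # S counts as GC, W as AT; N/R/Y are excluded from both sides
  mixed <- gb_rec("SSWWNNRRYY")
  gp2 <- gc_profile(mixed, 10, 10)
  expect_equal(gp2$values$gc_fraction, 2 / 4)
})

test_that("GC profile is rotation-invariant up to index relabeling", {
  set.seed(9)
  seq <- paste(sample(c("A", "C", "G", "T"), 1200, TRUE), collapse = "")
  shift <- 300   # a multiple of the step
  rotated <- paste0(substring(seq, shift + 1), substring(seq, 1, shift))
  v1 <- gc_profile(gb_rec(seq), 100, 100)$values$gc_fraction
  v2 <- gc_profile(gb_rec(rotated), 100, 100)$values$gc_fraction
  k <- shift / 100
  expect_equal(v2, c(v1[-(1:k)], v1[1:k]))
})

test_that("restriction scanning matches the worked examples", {
  lin <- gb_rec("GGAATTCC", topology = "linear")
  hits <- scan_restriction_sites(lin, "EcoRI")
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$position, 2L)
  expect_identical(hits$strand, "+")

  circ <- gb_rec("TCGGGGGGGAAT")   # GAAT|TC wraps the origin
  hits2 <- scan_restriction_sites(circ, "EcoRI")
  expect_identical(nrow(hits2), 1L)
  expect_identical(hits2$position, 9L)

  expect_error(scan_restriction_sites(lin, "NotAnEnzyme"),
               class = "orgmapr_input_error")
})

test_that("genome-side ambiguity codes never satisfy a recognition pattern", {
  rec <- gb_rec("GGANTTCC", topology = "linear")   # N inside would-be EcoRI
  expect_identical(nrow(scan_restriction_sites(rec, "EcoRI")), 0L)
  # but pattern-side degeneracy expands: HinfI = GANTC matches any base
  rec2 <- gb_rec("TGACTCT", topology = "linear")
  hits <- scan_restriction_sites(rec2, "HinfI")
  expect_identical(hits$position, 2L)
})

test_that("the scanner agrees with the naive position-by-position oracle", {
  enz <- c("EcoRI", "HinfI", "BstXI", "AluI", "AccI", "NotI")
  tab <- enzyme_table()
  set.seed(11)
  for (i in 1:20) {
    L <- sample(500:2000, 1)
    chars <- sample(c("A", "C", "G", "T"), L, TRUE)
    chars[sample(L, 5)] <- sample(c("N", "R", "S"), 5, TRUE)
    seq <- paste(chars, collapse = "")
    top <- sample(c("circular", "linear"), 1)
    rec <- gb_rec(seq, topology = top)
    got <- scan_restriction_sites(rec, enz)
    want <- oracle_scan(seq, enz, tab, circular = top == "circular")
    expect_equal(got, want)
  }
})

test_that("scanning the reverse complement mirrors positions and swaps strands", {
  set.seed(13)
  seq <- paste(sample(c("A", "C", "G", "T"), 3000, TRUE), collapse = "")
  for (enz in c("BsaI", "FokI", "SapI")) {
    m <- nchar(enzyme_table()$site[match(enz, enzyme_table()$name)])
    fwd <- scan_restriction_sites(gb_rec(seq, "linear"), enz)
    rev <- scan_restriction_sites(gb_rec(revcomp(seq), "linear"), enz)
    L <- nchar(seq)
    mirrored <- data.frame(
      enzyme = as.character(fwd$enzyme),
      position = as.integer(L - fwd$position - m + 2L),
      strand = as.character(ifelse(fwd$strand == "+", "-", "+")),
      stringsAsFactors = FALSE)
    mirrored <- mirrored[order(mirrored$position, mirrored$enzyme,
                               mirrored$strand), ]
    rownames(mirrored) <- NULL
    expect_equal(rev, mirrored)
  }
})

test_that("planted inverted repeats are recovered exactly, IR_A ending at the origin", {
  for (seed in 1:12) {
    fx <- make_fixture(fixture_spec("plastome_like", length_bp = 24000L,
                                    ir_len = 2500L, seed = seed))
    rec <- read_genbank(fx$text)[[1]]
    ir <- find_inverted_repeats(rec, "self_comparison", min_len = 1000,
                                max_mismatch_frac = 0)
    expect_false(is.null(ir))
    expect_identical(ir$ir_a, as.integer(fx$truth$ir$ir_a))
    expect_identical(ir$ir_b, as.integer(fx$truth$ir$ir_b))
    expect_identical(ir$ir_a[2], rec$length_bp)   # right repeat convention
    # the detected copies really are reverse complements of each other
    s_a <- substring(rec$sequence, ir$ir_a[1], ir$ir_a[2])
    s_b <- substring(rec$sequence, ir$ir_b[1], ir$ir_b[2])
    expect_identical(s_a, revcomp(s_b))
  }
})

test_that("repeat-free sequences yield no repeat pair", {
  fx <- make_fixture(fixture_spec("generic", length_bp = 8000L, seed = 5))
  rec <- read_genbank(fx$text)[[1]]
  expect_null(find_inverted_repeats(rec, "self_comparison", min_len = 1000))
  expect_null(find_inverted_repeats(rec, "none"))
})

test_that("annotation-based detection passes the annotated coordinates through", {
  fx <- make_fixture(fixture_spec("plastome_like", length_bp = 24000L,
                                  ir_len = 2500L, seed = 3))
  rec <- read_genbank(fx$text)[[1]]
  ir <- find_inverted_repeats(rec, "annotation")
  expect_identical(ir$method, "annotation")
  expect_identical(ir$ir_a, as.integer(fx$truth$ir$ir_a))
  expect_identical(ir$ir_b, as.integer(fx$truth$ir$ir_b))
})

test_that("noisy repeats are recovered within the mismatch budget", {
  for (seed in 1:4) {
    fx <- make_fixture(fixture_spec("plastome_like", length_bp = 40000L,
                                    ir_len = 5000L, ir_noise_frac = 0.01,
                                    seed = seed))
    rec <- read_genbank(fx$text)[[1]]
    ir <- find_inverted_repeats(rec, "self_comparison", min_len = 1000,
                                max_mismatch_frac = 0.01)
    expect_false(is.null(ir))
    truth <- fx$truth$ir
    # reported pair respects the budget and covers the planted repeat
    expect_lte(ir$n_mismatch / ir$length_bp, 0.01)
    cover <- function(got, want) {
      inter <- min(got[2], want[2]) - max(got[1], want[1]) + 1
      inter / (want[2] - want[1] + 1)
    }
    expect_gte(cover(ir$ir_a, truth$ir_a), 0.95)
    expect_gte(cover(ir$ir_b, truth$ir_b), 0.95)
    expect_lte(abs(ir$ir_a[1] - truth$ir_a[1]), 0.02 * truth$length_bp)
    expect_lte(abs(ir$ir_b[2] - truth$ir_b[2]), 0.02 * truth$length_bp)
  }
})
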