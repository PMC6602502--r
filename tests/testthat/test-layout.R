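test_that("positions map to angles clockwise from 3 o'clock", {
  expect_equal(position_to_angle(1, 16569), 0)
  expect_equal(position_to_angle(5001, 10000), 180)
  expect_equal(position_to_angle(2501, 10000), 90)
  expect_error(position_to_angle(0, 100), class = "orgmapr_input_error")
  expect_error(position_to_angle(101, 100), class = "orgmapr_input_error")
})

simple_record <- function(L = 10000, genes = list(list(gene = "abcA",
                                                       start = 1, end = 2500,
                                                       strand = "+"))) {
  feats <- list()
  for (g in genes) {
    feats[[length(feats) + 1]] <- feature_instance(
      "gene", feature_location(rbind(c(g$start, g$end)), strand = g$strand),
      gene = g$gene)
    feats[[length(feats) + 1]] <- feature_instance(
      "CDS", feature_location(rbind(c(g$start, g$end)), strand = g$strand),
      gene = g$gene)
  }
  genome_record("LAY00001", L, topology = "circular", features = feats)
}

test_that("a plus-strand gene spanning the first quarter draws 0..90 deg inside", {
  rec <- simple_record()
  cfg <- default_config("other")
  ly <- layout_circular(rec, classify_features(rec, cfg), config = cfg)
  arc <- ly$elements[ly$elements$kind == "feature_arc", ]
  expect_identical(nrow(arc), 1L)
  expect_identical(arc$side, "inner")
  expect_equal(arc$a0, 0)
  expect_equal(arc$ext, 90)
})

test_that("arc extents equal 360 * span / length to 1e-9 relative tolerance", {
  fx <- make_fixture(fixture_spec("plastome_like", length_bp = 30000L,
                                  ir_len = 3000L, seed = 2))
  rec <- read_genbank(fx$text)[[1]]
  cfg <- default_config("plastid")
  cl <- classify_features(rec, cfg)
  ly <- layout_circular(rec, cl, config = cfg)
  arcs <- ly$elements[ly$elements$kind %in%
                        c("feature_arc", "dloop_arc", "operon_bar"), ]
  spans <- vapply(Filter(function(cf) !cf$suppressed, cl), function(cf) {
    location_extent(cf$feature$location, rec$length_bp)$length
  }, integer(1))
  expect_equal(arcs$ext, 360 * spans / rec$length_bp, tolerance = 1e-9)
})

test_that("rotating all coordinates rotates every arc correspondingly", {
  L <- 12000
  base_genes <- list(list(gene = "abcA", start = 100, end = 700, strand = "+"),
                     list(gene = "defB", start = 3000, end = 4200, strand = "-"),
                     list(gene = "ghiC", start = 9000, end = 9600, strand = "+"))
  delta <- 1500
  rot_genes <- lapply(base_genes, function(g) {
    g$start <- g$start + delta; g$end <- g$end + delta; g
  })
  cfg <- default_config("other")
  r1 <- simple_record(L, base_genes)
  r2 <- simple_record(L, rot_genes)
  a1 <- layout_circular(r1, classify_features(r1, cfg), config = cfg)
  a2 <- layout_circular(r2, classify_features(r2, cfg), config = cfg)
  f1 <- a1$elements[a1$elements$kind == "feature_arc", ]
  f2 <- a2$elements[a2$elements$kind == "feature_arc", ]
  expect_equal((f1$a0 + 360 * delta / L) %% 360, f2$a0 %% 360)
  expect_equal(f1$ext, f2$ext)
})

test_that("an origin-wrapping feature is one continuous arc across 0 degrees", {
  feats <- list(feature_instance(
    "D-loop", feature_location(rbind(c(9500, 10000), c(1, 400)),
                               wraps_origin = TRUE)))
  rec <- genome_record("MITO0001", 10000, topology = "circular",
                       source_category = "mitochondrial", features = feats)
  cfg <- default_config("mitochondrial")
  ly <- layout_circular(rec, classify_features(rec, cfg), config = cfg)
  dl <- ly$elements[ly$elements$kind == "dloop_arc", ]
  expect_identical(nrow(dl), 1L)
  expect_equal(dl$a0, position_to_angle(9500, 10000))
  expect_equal(dl$ext, 360 * 901 / 10000)
  expect_gt(dl$a0 + dl$ext, 360)   # crosses the map origin
})

test_that("zoom is rejected on circular maps and validated on linear maps", {
  rec <- simple_record()
  cfg <- default_config("other")
  cl <- classify_features(rec, cfg)
  cfg$zoom <- c(100, 200)
  expect_error(layout_circular(rec, cl, config = cfg),
               class = "orgmapr_input_error")
  cfg$zoom <- c(200, 100)
  expect_error(layout_linear(rec, cl, config = cfg),
               class = "orgmapr_input_error")
  cfg$zoom <- c(1, 20000)
  expect_error(layout_linear(rec, cl, config = cfg),
               class = "orgmapr_input_error")
})

test_that("linear maps fill the canvas: stretch = canvas / window", {
  rec <- simple_record(10000, list(list(gene = "abcA", start = 1, end = 1000,
                                        strand = "+")))
  cfg <- default_config("other")
  ly <- layout_linear(rec, classify_features(rec, cfg), config = cfg)
  expect_equal(ly$stretch, ly$canvas[["width"]] / 10000)
  box <- ly$elements[ly$elements$kind == "feature_box", ]
  expect_equal(box$x0, 0)
  expect_equal(box$x1, ly$canvas[["width"]] * 1000 / 10000)
})

test_that("zoomed windows re-translate coordinates and clip features", {
  rec <- simple_record(10000, list(
    list(gene = "inwin", start = 2501, end = 2600, strand = "+"),
    list(gene = "edges", start = 1500, end = 2500, strand = "-")))
  cfg <- default_config("other")
  cfg$zoom <- c(2001, 3000)
  ly <- layout_linear(rec, classify_features(rec, cfg), config = cfg)
  W <- ly$canvas[["width"]]
  box <- ly$elements[ly$elements$kind == "feature_box" &
                       ly$elements$text == "inwin", ]
  expect_equal(box$x0, W * 0.5)
  expect_equal(box$x1, W * 0.6)
  clip <- ly$elements[ly$elements$kind == "feature_box" &
                        ly$elements$text == "edges", ]
  expect_true(clip$clipped)
  expect_equal(clip$x0, 0)

  # the zoomed layout equals the full layout clipped and re-translated
  cfg_full <- default_config("other")
  full <- layout_linear(rec, classify_features(rec, cfg_full),
                        config = cfg_full)
  fb <- full$elements[full$elements$kind == "feature_box" &
                        full$elements$text == "inwin", ]
  shift <- (2001 - 1) * full$stretch
  expect_equal((fb$x0 - shift) / full$stretch * ly$stretch, box$x0)
})

test_that("the drawn span ends exactly at the canvas width", {
  set.seed(21)
  for (i in 1:10) {
    L <- sample(2000:50000, 1)
    rec <- simple_record(L, list(list(gene = "abcA", start = L - 99, end = L,
                                      strand = "+")))
    cfg <- default_config("other")
    ly <- layout_linear(rec, classify_features(rec, cfg), config = cfg)
    box <- ly$elements[ly$elements$kind == "feature_box", ]
    expect_equal(box$x1, ly$canvas[["width"]], tolerance = 1e-6)
  }
})

test_that("label placement is greedy, deterministic and overlap-free", {
  # non-overlapping anchors stay at tier 0
  rec <- simple_record(10000, list(
    list(gene = "farA", start = 1, end = 200, strand = "+"),
    list(gene = "farB", start = 5000, end = 5200, strand = "+")))
  cfg <- default_config("other")
  ly <- layout_circular(rec, classify_features(rec, cfg), config = cfg)
  labs <- ly$elements[ly$elements$kind == "label", ]
  expect_true(all(labs$tier == 0))
  expect_false(any(labs$leader))

  # identical anchors force tier 1 with a leader line
  rec2 <- simple_record(10000, list(
    list(gene = "twinA", start = 100, end = 300, strand = "+"),
    list(gene = "twinB", start = 100, end = 300, strand = "-")))
  ly2 <- layout_circular(rec2, classify_features(rec2, cfg), config = cfg)
  labs2 <- ly2$elements[ly2$elements$kind == "label", ]
  expect_setequal(labs2$tier, c(0, 1))
  expect_true(labs2$leader[labs2$tier == 1])

  # dense random labels: zero pairwise overlaps after the pass
  set.seed(31)
  genes <- lapply(1:50, function(i) {
    s <- sample(9500, 1)
    list(gene = sprintf("gn%02d", i), start = s, end = s + 120,
         strand = sample(c("+", "-"), 1))
  })
  rec3 <- simple_record(10000, genes)
  ly3 <- layout_circular(rec3, classify_features(rec3, cfg), config = cfg)
  expect_identical(oracle_label_overlaps(ly3), 0L)
  ly3lin <- layout_linear(rec3, classify_features(rec3, cfg), config = cfg)
  expect_identical(oracle_label_overlaps(ly3lin), 0L)
})

test_that("layout is a pure function of its inputs", {
  fx <- make_fixture(fixture_spec("mitogenome_like", seed = 4))
  rec <- read_genbank(fx$text)[[1]]
  cfg <- default_config("mitochondrial")
  cl <- classify_features(rec, cfg)
  an <- analyze_record(rec, cfg)
  l1 <- layout_circular(rec, cl, an, cfg)
  l2 <- layout_circular(rec, cl, an, cfg)
  expect_identical(l1, l2)
})

test_that("the IR bracket puts IR_A in the right half of the map", {
  fx <- make_fixture(fixture_spec("plastome_like", length_bp = 30000L,
                                  ir_len = 3000L, seed = 6))
  rec <- read_genbank(fx$text)[[1]]
  cfg <- default_config("plastid")
  ly <- draw_genome_map(rec, cfg)
  br <- ly$rings$ir_bracket
  expect_false(is.null(br))
  # IR_A ends exactly at the map origin (0/360 degrees)
  expect_equal((br$ir_a[["a0"]] + br$ir_a[["ext"]]) %% 360, 0)
  mid <- (br$ir_a[["a0"]] + br$ir_a[["ext"]] / 2) %% 360
  expect_true(mid > 270 && mid < 360)   # right upper quadrant: x > 0
})
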