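test_that("tidy-up normalizes names to organellar nomenclature", {
  expect_identical(tidy_gene_name("PSBA"), list(name = "psbA", rejected = FALSE))
  expect_identical(tidy_gene_name("rbcl"), list(name = "rbcL", rejected = FALSE))
  expect_identical(tidy_gene_name("RPOC1"), list(name = "rpoC1", rejected = FALSE))
  expect_identical(tidy_gene_name("trnh_gug"),
                   list(name = "trnH-GUG", rejected = FALSE))
  expect_identical(tidy_gene_name("TRNH-GTG"),
                   list(name = "trnH-GUG", rejected = FALSE))
  expect_identical(tidy_gene_name(" \"psbA\" "),
                   list(name = "psbA", rejected = FALSE))
})

test_that("over-long names are rejected; tidy-up off is the identity", {
  long <- "a 41-character-long free-text description!"
  expect_true(tidy_gene_name(long)$rejected)
  expect_identical(tidy_gene_name(long, tidy_up = FALSE),
                   list(name = long, rejected = FALSE))
  expect_identical(tidy_gene_name("psbA", tidy_up = FALSE),
                   list(name = "psbA", rejected = FALSE))
})

test_that("tidy-up is idempotent and never lengthens a name", {
  corpus <- c(gene_lexicon()$name,
              toupper(gene_lexicon()$name),
              "PSBA", "ndhb", "Trnf-Gaa", "ycf15", "ORF1234", "atp6",
              "trnL-uaa", "cox1", "NAD4L", "some gene", "x")
  for (raw in corpus) {
    once <- tidy_gene_name(raw)
    if (once$rejected) next
    twice <- tidy_gene_name(once$name)
    expect_identical(twice, once)
    expect_lte(nchar(once$name), nchar(trimws(gsub("[\"']", "", raw))))
  }
})

test_that("features classify by gene-name pattern first, then feature key", {
  cfg <- default_config("plastid")
  trna <- feature_instance("tRNA", feature_location(rbind(c(100, 173))),
                           gene = "trnH-GUG")
  expect_identical(classify_feature(trna, cfg)$class_id, "trna")

  unknown <- feature_instance("CDS", feature_location(rbind(c(1, 300))),
                              gene = "zzz9")
  expect_identical(classify_feature(unknown, cfg)$class_id, "other")

  op <- feature_instance("operon", feature_location(rbind(c(1, 5000))))
  expect_identical(classify_feature(op, cfg)$class_id, "operon")
  pt <- feature_instance("prim_transcript", feature_location(rbind(c(1, 5000))))
  expect_identical(classify_feature(pt, cfg)$class_id, "operon")

  psb <- feature_instance("gene", feature_location(rbind(c(1, 900))),
                          gene = "psbB")
  expect_identical(classify_feature(psb, cfg)$class_id, "photosystem_II")
})

test_that("intron-containing genes get an asterisk, or gap boxes in box style", {
  txt <- mini_gb("INTR0001", sequence = strrep("ACGT", 500),
                 feature_lines = c(
                   feat_line("gene", "101..900", gene = "atpF"),
                   feat_line("CDS", "join(101..400,601..900)", gene = "atpF")))
  rec <- read_genbank(txt)[[1]]
  cfg <- default_config("plastid")
  cl <- classify_features(rec, cfg)
  expect_length(cl, 1L)
  expect_true(cl[[1]]$has_intron)
  expect_identical(cl[[1]]$display_name, "atpF*")

  cfg$intron_style <- "box"
  cl2 <- classify_features(rec, cfg)
  expect_identical(cl2[[1]]$display_name, "atpF")
  ly <- layout_circular(rec, cl2, config = cfg)
  expect_identical(sum(ly$elements$kind == "intron_gap"), 1L)
  ly_star <- layout_circular(rec, cl, config = default_config("plastid"))
  expect_identical(sum(ly_star$elements$kind == "intron_gap"), 0L)
  expect_true("atpF*" %in% ly_star$elements$text)
})

test_that("classification is total over generated fixtures", {
  for (seed in 1:6) {
    fx <- make_fixture(fixture_spec("plastome_like", length_bp = 30000L,
                                    ir_len = 3000L, seed = seed))
    rec <- read_genbank(fx$text)[[1]]
    cfg <- default_config(rec$source_category)
    cl <- classify_features(rec, cfg)
    ids <- names(cfg$classes)
    for (cf in cl) {
      expect_true(cf$class_id %in% ids)
    }
  }
})

test_that("default configurations are deterministic and category-specific", {
  p1 <- default_config("plastid")
  p2 <- default_config("plastid")
  expect_identical(p1, p2)
  expect_true(all(c("trna", "rrna") %in% names(p1$classes)))
  expect_false(p1$classes$trna$color == p1$classes$rrna$color)
  m <- default_config("mitochondrial")
  expect_true("dloop" %in% names(m$classes))
  expect_true(m$classes$dloop$enabled)
  cols <- vapply(p1$classes, `[[`, "", "color")
  expect_true(all(grepl("^#[0-9A-F]{6}$", cols)))
})

test_that("XML configuration overrides apply over the base config", {
  base <- default_config("plastid")
  cfg <- load_xml_config('<ogconfig><class id="trna" color="#00AA00"/></ogconfig>',
                         base)
  expect_identical(cfg$classes$trna$color, "#00AA00")
  cfg_same <- cfg
  cfg_same$classes$trna <- base$classes$trna
  expect_identical(cfg_same, base)

  expect_identical(load_xml_config("<ogconfig/>", base), base)

  cfg2 <- load_xml_config(
    '<ogconfig><featurekey key="misc_feature" class="other"/></ogconfig>', base)
  expect_true("misc_feature" %in% cfg2$classes$other$keys)
  misc <- feature_instance("misc_feature", feature_location(rbind(c(5, 50))))
  expect_identical(classify_feature(misc, cfg2)$class_id, "other")
})

test_that("XML override application is associative", {
  base <- default_config("plastid")
  x <- '<ogconfig><class id="trna" color="#111111"/><gene name="psbA" product="PSII D1"/></ogconfig>'
  y <- '<ogconfig><class id="trna" color="#222222"/><class id="rrna" label="rRNAs"/></ogconfig>'
  lhs <- load_xml_config(x, load_xml_config(y, base))
  expect_identical(lhs$classes$trna$color, "#111111")   # x wins over y
  expect_identical(lhs$classes$rrna$label, "rRNAs")     # y preserved
  expect_identical(lhs$gene_overrides$psbA$product, "PSII D1")
})

test_that("malformed XML configurations give structured errors with paths", {
  base <- default_config("plastid")
  expect_error(load_xml_config("<ogconfig><bogus/></ogconfig>", base),
               class = "orgmapr_config_error")
  expect_error(load_xml_config("<wrong/>", base),
               class = "orgmapr_config_error")
  err <- tryCatch(
    load_xml_config('<ogconfig><class id="trna" color="green"/></ogconfig>', base),
    error = function(e) e)
  expect_s3_class(err, "orgmapr_config_error")
  expect_match(conditionMessage(err), "green")
  err2 <- tryCatch(
    load_xml_config('<ogconfig><class id="trna" hue="#000000"/></ogconfig>', base),
    error = function(e) e)
  expect_match(conditionMessage(err2), "/ogconfig/class")
})

test_that("disabling a class suppresses exactly its elements end-to-end", {
  fx <- make_fixture(fixture_spec("plastome_like", length_bp = 30000L,
                                  ir_len = 3000L, seed = 11))
  rec <- read_genbank(fx$text)[[1]]
  cfg <- default_config("plastid")
  full <- draw_genome_map(rec, cfg)
  cfg_off <- load_xml_config(
    '<ogconfig><class id="trna" enabled="false"/></ogconfig>', cfg)
  off <- draw_genome_map(rec, cfg_off)
  expect_gt(sum(full$elements$class_id == "trna"), 0)
  expect_identical(sum(off$elements$class_id == "trna"), 0L)
  keep <- full$elements[full$elements$class_id != "trna", ]
  also <- off$elements[off$elements$class_id != "trna", ]
  expect_identical(keep$kind, also$kind)
  expect_identical(keep$a0, also$a0)
})
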