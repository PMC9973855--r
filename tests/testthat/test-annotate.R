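ref_table <- function() {
  data.frame(accession = c("TDB001", "TDB002", "TDB003"),
             family = c("ABC", "ABC", "MFS"),
             subfamily = c("CUT1", NA, NA),
             tc_number = c("3.A.1.1.1", "3.A.1.2.1", "2.A.1.1.1"),
             substrate_class = c("sugars", "sugars", NA),
             substrate = c("maltose", NA, NA))
}

hit_row <- function(subject, bitscore, evalue = 1e-50, identity = 85,
                    coverage = 90, track = "curated_tdb") {
  data.frame(query_id = "p1", subject_id = subject,
             percent_identity = identity, alignment_length = 100,
             mismatches = 10, gap_opens = 0, qstart = 1, qend = 100,
             sstart = 1, send = 100, evalue = evalue, bitscore = bitscore,
             query_coverage = coverage, subject_description = "",
             source_track = track)
}

bundle_with_hits <- function(hits, doms = NULL) {
  pr <- data.frame(protein_id = "p1", description = "",
                   sequence = paste(rep("A", 60), collapse = ""))
  build_bundles(pr, hits, doms)$p1
}

test_that("best reference hit maximizes bitscore with documented tie-breaks", {
  b <- bundle_with_hits(rbind(hit_row("TDB001", 300),
                              hit_row("TDB002", 250)))
  expect_equal(best_reference_hit(b, ref_table())$hit$subject_id, "TDB001")
  # tie on bitscore and evalue: lexicographically smaller subject wins
  b <- bundle_with_hits(rbind(hit_row("TDB002", 300),
                              hit_row("TDB001", 300)))
  expect_equal(best_reference_hit(b, ref_table())$hit$subject_id, "TDB001")
  # unresolvable and sub-threshold hits yield no best hit
  b <- bundle_with_hits(hit_row("UNKNOWN", 300))
  expect_null(best_reference_hit(b, ref_table()))
  b <- bundle_with_hits(hit_row("TDB001", 300, evalue = 0.1))
  expect_null(best_reference_hit(b, ref_table()))
  # NR hits never feed homology transfer
  b <- bundle_with_hits(hit_row("TDB001", 300, track = "nr"))
  expect_null(best_reference_hit(b, ref_table()))
})

test_that("classification copies from the reference or falls back to profiles", {
  b <- bundle_with_hits(hit_row("TDB001", 300))
  best <- best_reference_hit(b, ref_table())
  cls <- assign_classification(b, best)
  expect_equal(cls$family, "ABC")
  expect_equal(cls$subfamily, "CUT1")
  expect_equal(cls$tc_number, "3.A.1.1.1")
  # profile fallback: PF00005 maps to ABC with no TC number
  doms <- data.frame(query_id = "p1", model_accession = "PF00005",
                     model_name = "ABC_tran", domain_evalue = 1e-10,
                     score = 100, env_start = 1L, env_end = 50L)
  b2 <- bundle_with_hits(NULL, doms)
  cls2 <- assign_classification(b2, NULL)
  expect_equal(cls2$family, "ABC")
  expect_true(is.na(cls2$tc_number))
  # nothing resolvable at all
  b3 <- bundle_with_hits(NULL)
  expect_equal(assign_classification(b3, NULL)$family, "unclassified")
})

test_that("substrate transfer is tiered with abstention", {
  tiers <- transfer_tiers()
  mk_best <- function(identity, coverage, acc = "TDB001") {
    b <- bundle_with_hits(hit_row(acc, 300, identity = identity,
                                  coverage = coverage))
    best_reference_hit(b, ref_table())
  }
  s <- predict_substrate(mk_best(85, 95), tiers)
  expect_equal(s, list(substrate_class = "sugars", substrate = "maltose"))
  s <- predict_substrate(mk_best(40, 80), tiers)
  expect_equal(s, list(substrate_class = "sugars",
                       substrate = NA_character_))
  s <- predict_substrate(mk_best(25, 95), tiers)
  expect_true(is.na(s$substrate_class) && is.na(s$substrate))
  expect_true(is.na(predict_substrate(NULL, tiers)$substrate))
  # missing reference fields propagate as abstention at that level
  s <- predict_substrate(mk_best(85, 95, acc = "TDB002"), tiers)
  expect_equal(s$substrate_class, "sugars")
  expect_true(is.na(s$substrate))
  # unknown coverage fails every coverage floor
  b <- bundle_with_hits(hit_row("TDB001", 300, coverage = NA))
  expect_true(is.na(predict_substrate(best_reference_hit(b, ref_table()),
                                      tiers)$substrate_class))
})

test_that("raising the specific-identity floor never adds specific calls", {
  d <- file.path(tempdir(), "fx-tiers")
  fb <- generate_fixtures(fixture_spec(seed = 5L), d)
  floors <- c(40, 60, 80, 96)
  n_specific <- vapply(floors, function(fl) {
    ann <- annotate_fixture_dir(
      d, tiers = transfer_tiers(specific_min_identity = fl))
    sum(!is.na(ann$substrate))
  }, numeric(1))
  expect_true(all(diff(n_specific) <= 0))
})

test_that("the engineered tier mixture yields the exact abstention split", {
  d <- file.path(tempdir(), "fx-mix")
  spec <- fixture_spec(n_abc = 50L, n_mfs = 0L, n_uvra = 0L, n_cbs = 0L,
                       n_cpa3 = 0L, n_membrane_subunits = 0L,
                       n_background = 0L, seed = 13L,
                       tier_mix = c(specific = 0.6, class = 0.2,
                                    abstain = 0.2))
  fb <- generate_fixtures(spec, d)
  ann <- annotate_fixture_dir(d)
  expect_equal(sum(!is.na(ann$substrate)), 30)                      # specific
  expect_equal(sum(is.na(ann$substrate) & !is.na(ann$substrate_class)), 10)
  expect_equal(sum(is.na(ann$substrate_class)), 10)                 # abstained
})

test_that("annotation is invariant to input hit order and repeatable", {
  d <- file.path(tempdir(), "fx-order")
  fb <- generate_fixtures(fixture_spec(seed = 17L), d)
  proteome <- read_fasta(fb$paths[["proteome"]])
  hits <- do.call(rbind, lapply(c("curated_tdb", "tcdb", "nr"), function(tr)
    read_tabular_hits(fb$paths[[tr]], tr, proteome)))
  doms <- read_domain_table(fb$paths[["domains"]])
  cogs <- read_cog_hits(fb$paths[["cogs"]])
  topo <- read_tm_short(fb$paths[["tm"]])
  ref <- read_reference_table(fb$paths[["reference"]])
  a1 <- annotate_proteome(proteome, hits, doms, cogs, topo, ref)
  set.seed(23)
  a2 <- annotate_proteome(proteome, hits[sample(nrow(hits)), ],
                          doms[sample(nrow(doms)), ],
                          cogs[sample(nrow(cogs)), ], topo, ref)
  rownames(a2) <- NULL
  expect_equal(a1, a2, ignore_attr = TRUE)
  f1 <- tempfile(); f2 <- tempfile()
  write_annotations(a1, f1)
  write_annotations(a2, f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("every retained annotation names at least one passing track", {
  d <- file.path(tempdir(), "fx-track")
  generate_fixtures(fixture_spec(seed = 19L), d)
  ann <- annotate_fixture_dir(d)
  ret <- ann[ann$status == "retained", ]
  expect_true(all(nzchar(ret$evidence_summary)))
  expect_true(all(vapply(strsplit(ret$evidence_summary, ","), length,
                         integer(1)) >= 1))
})

test_that("confidence tiers follow the evidence strength", {
  d <- file.path(tempdir(), "fx-conf")
  fb <- generate_fixtures(fixture_spec(seed = 29L), d)
  ann <- annotate_fixture_dir(d)
  m <- fb$manifest[match(ann$protein_id, fb$manifest$protein_id), ]
  ret <- ann$status == "retained"
  expect_true(all(ann$confidence[ret & m$tier %in% "specific"] == "high",
                  na.rm = TRUE))
  expect_true(all(ann$confidence[ret & m$tier %in% "class" &
                                   m$category == "cpa3_confusable"] ==
                    "medium"))
})

test_that("an empty proteome annotates to an empty table", {
  pr <- data.frame(protein_id = character(), description = character(),
                   sequence = character())
  ann <- annotate_proteome(pr)
  expect_equal(nrow(ann), 0)
})
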