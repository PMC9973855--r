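tmp <- function(ext = "") tempfile(fileext = ext)

test_that("FASTA records map deflines to id, description and sequence", {
  fa <- tmp(".faa")
  writeLines(c(">p1 desc", "MKT", ">p2", "GALA", "VINE"), fa)
  pr <- read_fasta(fa)
  expect_equal(pr$protein_id, c("p1", "p2"))
  expect_equal(pr$description, c("desc", ""))
  expect_equal(pr$sequence, c("MKT", "GALAVINE"))
})

test_that("FASTA reader rejects duplicates, empty files and illegal residues", {
  fa <- tmp(".faa")
  writeLines(c(">p1", "MKT", ">p1", "GAL"), fa)
  expect_error(read_fasta(fa), "duplicate.*p1")
  writeLines(character(0), fa)
  expect_error(read_fasta(fa), class = "transannot_parse_error")
  writeLines(c(">p1", "MK1T"), fa)
  expect_error(read_fasta(fa), class = "transannot_parse_error")
  expect_error(read_fasta(tmp()), class = "transannot_missing_input")
})

test_that("tabular hit lines map to standardized fields", {
  f <- tmp(".tsv")
  writeLines("q1\tTDB0001\t85.0\t200\t30\t0\t1\t200\t1\t200\t1e-80\t300", f)
  h <- read_tabular_hits(f, "curated_tdb")
  expect_equal(h$evalue, 1e-80)
  expect_equal(h$bitscore, 300)
  expect_equal(h$percent_identity, 85)
  expect_equal(h$source_track, "curated_tdb")
  expect_true(is.na(h$query_coverage))  # no column 13, no proteome
  # coverage computed from qstart/qend when the proteome is supplied
  proteome <- data.frame(protein_id = "q1", description = "",
                         sequence = paste(rep("A", 250), collapse = ""))
  h2 <- read_tabular_hits(f, "curated_tdb", proteome)
  expect_equal(h2$query_coverage, 100 * 200 / 250)
  writeLines(character(0), f)
  expect_equal(nrow(read_tabular_hits(f, "nr")), 0)
  writeLines("q1\tS\tnot_a_number\t1\t1\t1\t1\t1\t1\t1\t1\t1", f)
  expect_error(read_tabular_hits(f, "nr"), class = "transannot_parse_error")
})

test_that("random tabular hits round-trip through write-then-read unchanged", {
  set.seed(11)
  n <- 1000
  hits <- data.frame(
    query_id = sprintf("q%04d", sample(500, n, replace = TRUE)),
    subject_id = sprintf("S%05d", sample(1e5, n, replace = TRUE)),
    percent_identity = round(runif(n, 10, 100), 2),
    alignment_length = as.numeric(sample(30:900, n, replace = TRUE)),
    mismatches = as.numeric(sample(0:200, n, replace = TRUE)),
    gap_opens = as.numeric(sample(0:10, n, replace = TRUE)),
    qstart = as.numeric(sample(1:50, n, replace = TRUE)),
    qend = as.numeric(sample(100:900, n, replace = TRUE)),
    sstart = as.numeric(sample(1:50, n, replace = TRUE)),
    send = as.numeric(sample(100:900, n, replace = TRUE)),
    evalue = 10^runif(n, -180, 1),
    bitscore = round(runif(n, 20, 2000), 1),
    query_coverage = round(runif(n, 1, 100), 1),
    subject_description = sample(c("ABC transporter", "MFS permease",
                                   "hypothetical protein"), n, TRUE),
    source_track = "tcdb")
  f <- tmp(".tsv")
  write_tabular_hits(hits, f)
  back <- read_tabular_hits(f, "tcdb")
  expect_identical(back, hits)
  f2 <- tmp(".tsv")
  write_tabular_hits(back, f2)
  expect_identical(readLines(f), readLines(f2))
})

test_that("domain tables parse with version stripping and accession surrogates", {
  f <- tmp(".tbl")
  pad <- function(acc, q, ev)
    sprintf("ABC_tran %s 200 %s - 400 %s 80 0.1 1 1 %s %s 80 0.1 1 180 5 180 5 180 0.95 desc text", acc, q, ev, ev, ev)
  writeLines(c("# comment", pad("PF00005.27", "p1", "1e-20"),
               pad("-", "p2", "1e-8")), f)
  d <- read_domain_table(f)
  expect_equal(d$model_accession, c("PF00005", "ABC_tran"))
  expect_equal(d$domain_evalue, c(1e-20, 1e-8))
  expect_equal(d$env_start, c(5L, 5L))
  writeLines("# only comments", f)
  expect_equal(nrow(read_domain_table(f)), 0)
})

test_that("a generated domain table parses to exactly the planted hits", {
  set.seed(3)
  n <- 50
  doms <- data.frame(
    query_id = sprintf("p%03d", 1:n),
    model_accession = sample(c("PF00005", "PF07690", "TIGR00972"), n, TRUE),
    model_name = "model", domain_evalue = 10^runif(n, -40, -2),
    score = round(runif(n, 20, 300), 1),
    env_start = sample(1:20, n, TRUE), env_end = sample(100:300, n, TRUE))
  f <- tmp(".tbl")
  write_domain_table(doms, f)
  back <- read_domain_table(f)
  expect_equal(nrow(back), n)
  expect_identical(back[names(doms)], doms)
})

test_that("COG accessions are extracted from plain and embedded subjects", {
  f <- tmp(".tsv")
  line <- function(q, s) sprintf("%s\t%s\t30\t100\t70\t0\t1\t100\t1\t100\t1e-20\t150", q, s)
  writeLines(c(line("q1", "COG0178"),
               line("q2", "gnl|CDD|223256 COG0178"),
               line("q3", "no_cog_here")), f)
  warnings <- character(0)
  cogs <- withCallingHandlers(read_cog_hits(f),
                              warning = function(w) {
                                warnings <<- c(warnings, conditionMessage(w))
                                invokeRestart("muffleWarning")
                              })
  expect_equal(cogs$cog_id, c("COG0178", "COG0178"))
  expect_equal(cogs$query_id, c("q1", "q2"))
  expect_length(warnings, 1)
  expect_match(warnings, "no_cog_here")
})

test_that("a 20-line COG fixture with 2 bad subjects yields 18 hits and 2 warnings", {
  set.seed(9)
  f <- tmp(".tsv")
  subj <- c(sprintf("COG%04d", sample(100:999, 18)), "junk|a", "plain")
  lines <- sprintf("q%02d\t%s\t30\t100\t70\t0\t1\t100\t1\t100\t1e-9\t120",
                   1:20, subj)
  writeLines(lines, f)
  warnings <- 0
  cogs <- withCallingHandlers(read_cog_hits(f),
                              warning = function(w) {
                                warnings <<- warnings + 1
                                invokeRestart("muffleWarning")
                              })
  expect_equal(nrow(cogs), 18)
  expect_equal(warnings, 2)
})

test_that("TMHMM short lines parse counts and 1-based inclusive segments", {
  f <- tmp(".txt")
  writeLines(c("p1\tlen=450\tExpAA=110.2\tFirst60=0.1\tPredHel=2\tTopology=i12-34o56-78i",
               "p2\tlen=200\tExpAA=0.0\tFirst60=0.0\tPredHel=0\tTopology=o"), f)
  tp <- read_tm_short(f)
  expect_equal(tp$p1$tm_count, 2)
  expect_equal(unname(tp$p1$segments[1, ]), c(12L, 34L))
  expect_equal(unname(tp$p1$segments[2, ]), c(56L, 78L))
  expect_equal(tp$p2$tm_count, 0)
  expect_equal(nrow(tp$p2$segments), 0)
  writeLines("p3 len=100 ExpAA=1 First60=0 Topology=o", f)
  expect_error(read_tm_short(f), "PredHel")
})

test_that("annotations round-trip and abstentions serialize as dashes", {
  ann <- data.frame(
    protein_id = c("a", "b"), status = c("retained", "excluded"),
    family = c("ABC", NA), subfamily = c("CUT1", NA),
    tc_number = c("3.A.1.1.1", NA), substrate_class = c("sugars", NA),
    substrate = c(NA_character_, NA_character_),
    confidence = c("medium", NA),
    tm_count = c(0L, 3L), evidence_summary = c("curated_tdb,hmm", "hmm"),
    excluded_by = c(NA, "abc_nontransporter_cogs"))
  f <- tmp(".tsv")
  write_annotations(ann, f, provenance = c(tool = "test"))
  lines <- readLines(f)
  expect_match(lines[1], "^# tool: test")
  # abstained substrate serializes as "-"
  expect_match(lines[3], "\tsugars\t-\t")
  back <- read_annotations(f)
  expect_identical(back, ann)
  # empty annotation set gives a header-only file
  write_annotations(ann[0, ], f)
  expect_equal(readLines(f), paste(names(ann), collapse = "\t"))
})

test_that("reference tables validate accessions and TC numbers", {
  f <- tmp(".tsv")
  ref <- data.frame(accession = c("TDB1", "TDB2"),
                    family = c("ABC", "CPA3"), subfamily = c("CUT1", NA),
                    tc_number = c("3.A.1.1.1", "2.A.63"),
                    substrate_class = c("sugars", NA),
                    substrate = c("maltose", NA))
  write_reference_table(ref, f)
  expect_identical(read_reference_table(f), ref)
  bad <- ref; bad$accession <- c("X", "X")
  write_reference_table(bad, f)
  expect_error(read_reference_table(f), "duplicate")
  bad <- ref; bad$tc_number <- c("3.A.1.1.1", "notatc")
  write_reference_table(bad, f)
  expect_error(read_reference_table(f), "TC number")
})
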