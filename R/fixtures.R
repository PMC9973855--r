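# Deterministic synthetic-fixture generator.  Produces a proteome, a
# curated reference table, a gold standard and consistent evidence files
# in every supported format, with planted true transporters and planted
# decoys exercising each default negative rule and each failure mode the
# pipeline is known for: non-transporter ATPases sharing the ATP-binding
# cassette profile (exclusion by COG or NR keyword), CPA3-family
# antiporters whose subunits resemble NADH:ubiquinone oxidoreductase
# (retained false positives — the default ruleset cannot touch them), and
# low-identity ABC membrane subunits with no passing evidence (false
# negatives).  Evidence values are planted directly rather than produced
# by running search engines: realism is at the format and distribution
# level, which is what the pipeline consumes.  E-values are sampled
# log-uniform inside pass/fail bands separated from the thresholds by a
# factor-of-10 guard margin so no fixture ever sits on a boundary.

POLAR_POOL <- c("A", "G", "S", "T", "D", "E", "K", "R", "N", "Q",
                "P", "H", "Y")
HYDRO_POOL <- c("I", "L", "V")
SUBSTRATE_POOL <- c("maltose", "galactose", "ribose", "xylose",
                    "arabinose", "trehalose")

rand_seq <- function(n, pool = POLAR_POOL)
  paste(sample(pool, n, replace = TRUE), collapse = "")

rlunif <- function(n, lo, hi) 10^runif(n, log10(lo), log10(hi))

# Membrane-protein sequence: n_segs hydrophobic runs of `run` residues
# separated (and flanked) by polar linkers; returns the sequence and the
# planted 1-based segment coordinates.
tm_sequence <- function(n_segs, run = 25L, linker = 25L) {
  parts <- character(0)
  segs <- matrix(integer(), ncol = 2)
  pos <- 0L
  for (i in seq_len(n_segs)) {
    parts <- c(parts, rand_seq(linker), rand_seq(run, HYDRO_POOL))
    start <- pos + linker + 1L
    segs <- rbind(segs, c(start, start + run - 1L))
    pos <- pos + linker + run
  }
  parts <- c(parts, rand_seq(linker))
  list(sequence = paste(parts, collapse = ""), segments = segs)
}

#' Fixture specification
#'
#' Counts per planted scenario class, the generator seed, and the mix of
#' homology-transfer tiers among the planted ABC transporters.
#'
#' @param n_abc ABC transporters (ATP-binding subunits with curated
#'   reference hits; tier per \code{tier_mix}).
#' @param n_mfs MFS-like 12-helix transporters with specific-tier TCDB
#'   hits.
#' @param n_uvra UvrA-type decoys (ATP-binding cassette profile +
#'   excinuclease COG/keywords) — excluded by the default COG rule.
#' @param n_cbs CBS-domain decoys — half carry the exclusion COG, half
#'   only the NR keyword.
#' @param n_cpa3 CPA3-family antiporter subunits with
#'   oxidoreductase-style NR descriptions — retained (the shipped rules
#'   cannot exclude them).
#' @param n_membrane_subunits Low-identity ABC membrane subunits: only
#'   sub-threshold hits plus 5 transmembrane helices — missed entirely.
#' @param n_background Proteins with no passing evidence and no
#'   membrane-spanning runs.
#' @param seed Integer generator seed; identical seeds give
#'   byte-identical outputs.
#' @param tier_mix Fractions of specific / class / abstain tier
#'   identities among the ABC transporters; must sum to 1.
#' @param cpa3_in_gold Whether the gold standard lists the CPA3 subunits
#'   as true transporters (set FALSE to reproduce the retained-CPA3
#'   false-positive anatomy in evaluation).
#' @return Object of class \code{fixture_spec}.
#' @export
fixture_spec <- function(n_abc = 50L, n_mfs = 10L, n_uvra = 10L,
                         n_cbs = 5L, n_cpa3 = 5L,
                         n_membrane_subunits = 5L, n_background = 30L,
                         seed = 42L,
                         tier_mix = c(specific = 0.6, class = 0.2,
                                      abstain = 0.2),
                         cpa3_in_gold = TRUE) {
  counts <- c(n_abc, n_mfs, n_uvra, n_cbs, n_cpa3, n_membrane_subunits,
              n_background)
  if (any(counts < 0)) stop("fixture counts must be non-negative")
  if (abs(sum(tier_mix) - 1) > 1e-9) stop("tier_mix must sum to 1")
  structure(list(n_abc = as.integer(n_abc), n_mfs = as.integer(n_mfs),
                 n_uvra = as.integer(n_uvra), n_cbs = as.integer(n_cbs),
                 n_cpa3 = as.integer(n_cpa3),
                 n_membrane_subunits = as.integer(n_membrane_subunits),
                 n_background = as.integer(n_background),
                 seed = as.integer(seed), tier_mix = tier_mix,
                 cpa3_in_gold = isTRUE(cpa3_in_gold)),
            class = "fixture_spec")
}

# Deterministic tier quotas: cumulative rounding guarantees the engineered
# fractions are met exactly for any n.
tier_quota <- function(n, mix) {
  counts <- diff(round(cumsum(c(0, mix)) * n))
  rep(c("specific", "class", "abstain"), counts)
}

tier_identity <- function(tier) {
  switch(tier,
         specific = round(runif(1, 70, 95), 1),
         class = round(runif(1, 35, 55), 1),
         abstain = round(runif(1, 8, 25), 1))
}

FIXTURE_FILES <- c(proteome = "proteome.faa", reference = "reference.tsv",
                   gold = "gold.tsv", curated_tdb = "hits_curated_tdb.tsv",
                   tcdb = "hits_tcdb.tsv", nr = "hits_nr.tsv",
                   domains = "domains.tbl", cogs = "cogs.tsv",
                   tm = "tm_short.txt", manifest = "manifest.tsv")

# Internal accumulator shared by generate_fixtures() and worked_example().
new_builder <- function() {
  env <- new.env(parent = emptyenv())
  env$proteins <- list(); env$hits <- list(); env$domains <- list()
  env$cogs <- list(); env$topologies <- list(); env$reference <- list()
  env$gold <- list(); env$manifest <- list()
  env
}

bld_protein <- function(b, id, description, sequence, segments = NULL) {
  b$proteins[[id]] <- data.frame(protein_id = id, description = description,
                                 sequence = sequence,
                                 stringsAsFactors = FALSE)
  segs <- if (is.null(segments)) matrix(integer(), ncol = 2) else segments
  b$topologies[[id]] <- tm_topology(segs)
}

bld_hit <- function(b, id, subject, track, identity, coverage, evalue,
                    bitscore, description = "") {
  len <- nchar(b$proteins[[id]]$sequence)
  alen <- max(1L, round(len * coverage / 100))
  b$hits[[length(b$hits) + 1L]] <- data.frame(
    query_id = id, subject_id = subject, percent_identity = identity,
    alignment_length = alen,
    mismatches = round(alen * (100 - identity) / 100), gap_opens = 0,
    qstart = 1, qend = alen, sstart = 1, send = alen,
    evalue = evalue, bitscore = bitscore, query_coverage = coverage,
    subject_description = description, source_track = track,
    stringsAsFactors = FALSE)
}

bld_domain <- function(b, id, accession, name, evalue, score = 80) {
  len <- nchar(b$proteins[[id]]$sequence)
  b$domains[[length(b$domains) + 1L]] <- data.frame(
    query_id = id, model_accession = strip_version(accession),
    model_name = name, domain_evalue = evalue, score = score,
    env_start = 5L, env_end = min(len, 180L), stringsAsFactors = FALSE)
}

bld_cog <- function(b, id, cog, evalue, bitscore = 150) {
  b$cogs[[length(b$cogs) + 1L]] <- data.frame(
    query_id = id, cog_id = cog, evalue = evalue, bitscore = bitscore,
    stringsAsFactors = FALSE)
}

bld_reference <- function(b, accession, family, subfamily, tc, class,
                          substrate) {
  b$reference[[accession]] <- data.frame(
    accession = accession, family = family, subfamily = subfamily,
    tc_number = tc, substrate_class = class, substrate = substrate,
    stringsAsFactors = FALSE)
}

bld_manifest <- function(b, id, category, tier, expected_status,
                         expected_rule, expected_substrate,
                         expected_class, true_substrate, reference_acc,
                         tm_planted, in_gold) {
  b$manifest[[id]] <- data.frame(
    protein_id = id, category = category, tier = tier,
    expected_status = expected_status, expected_rule = expected_rule,
    expected_substrate = expected_substrate,
    expected_substrate_class = expected_class,
    true_substrate = true_substrate, reference_accession = reference_acc,
    tm_planted = tm_planted, in_gold = in_gold, stringsAsFactors = FALSE)
  if (in_gold)
    b$gold[[id]] <- data.frame(protein_id = id, substrate = true_substrate,
                               stringsAsFactors = FALSE)
}

bld_write <- function(b, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- setNames(file.path(out_dir, FIXTURE_FILES), names(FIXTURE_FILES))
  proteome <- do.call(rbind, c(unname(b$proteins),
                               list(make.row.names = FALSE)))
  hits <- do.call(rbind, c(b$hits, list(make.row.names = FALSE)))
  if (is.null(hits)) hits <- empty_hits()
  write_fasta(proteome, paths[["proteome"]])
  reference <- do.call(rbind, c(unname(b$reference),
                                list(make.row.names = FALSE)))
  if (is.null(reference))
    reference <- data.frame(accession = character(), family = character(),
                            subfamily = character(), tc_number = character(),
                            substrate_class = character(),
                            substrate = character())
  write_reference_table(reference, paths[["reference"]])
  gold <- do.call(rbind, c(unname(b$gold), list(make.row.names = FALSE)))
  if (is.null(gold))
    gold <- data.frame(protein_id = character(), substrate = character())
  write_gold_standard(gold, paths[["gold"]])
  for (tr in VALID_TRACKS)
    write_tabular_hits(hits[hits$source_track == tr, , drop = FALSE],
                       paths[[tr]])
  domains <- do.call(rbind, c(b$domains, list(make.row.names = FALSE)))
  if (is.null(domains))
    domains <- data.frame(query_id = character(),
                          model_accession = character(),
                          model_name = character(),
                          domain_evalue = numeric(), score = numeric(),
                          env_start = integer(), env_end = integer())
  write_domain_table(domains, paths[["domains"]])
  cogs <- do.call(rbind, c(b$cogs, list(make.row.names = FALSE)))
  if (is.null(cogs))
    cogs <- data.frame(query_id = character(), cog_id = character(),
                       evalue = numeric(), bitscore = numeric())
  write_cog_hits(cogs, paths[["cogs"]])
  write_tm_short(b$topologies, paths[["tm"]],
                 lengths = setNames(nchar(proteome$sequence),
                                    proteome$protein_id))
  manifest <- do.call(rbind, c(unname(b$manifest),
                               list(make.row.names = FALSE)))
  utils::write.table(manifest, paths[["manifest"]], sep = "\t",
                     quote = FALSE, row.names = FALSE, na = "-")
  structure(list(paths = paths, manifest = manifest, proteome = proteome),
            class = "fixture_bundle")
}

# pass/fail E-value bands (thresholds 1e-5 blast/cog, 1e-4 hmm; bands keep
# a x10 guard margin on each side)
ev_pass_blast <- function() rlunif(1, 1e-30, 1e-6)
ev_fail_blast <- function() rlunif(1, 1e-3, 1e-1)
ev_pass_hmm <- function() rlunif(1, 1e-25, 1e-5)
ev_fail_hmm <- function() rlunif(1, 1e-2, 1e-1)
ev_pass_cog <- function() rlunif(1, 1e-30, 1e-6)

#' Generate a synthetic fixture bundle
#'
#' Writes a proteome, reference table, gold standard, evidence files in
#' every supported format, and a manifest recording the planted truth per
#' protein.  Identical seeds give byte-identical outputs.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Output directory (created if needed).
#' @return Object of class \code{fixture_bundle}: list with \code{paths}
#'   (named file paths), \code{manifest} (planted-truth data frame) and
#'   \code{proteome}.
#' @export
generate_fixtures <- function(spec = fixture_spec(), out_dir) {
  set.seed(spec$seed)
  b <- new_builder()
  tiers <- tier_quota(spec$n_abc, spec$tier_mix)

  for (i in seq_len(spec$n_abc)) {
    id <- sprintf("abc_%03d", i)
    acc <- sprintf("TDB%04d", i)
    substrate <- sample(SUBSTRATE_POOL, 1)
    bld_reference(b, acc, "ABC", "CUT1", "3.A.1.1.1", "sugars", substrate)
    bld_protein(b, id, "ABC transporter ATP-binding protein",
                rand_seq(sample(280:340, 1)))
    tier <- tiers[i]
    ident <- tier_identity(tier)
    cov <- round(runif(1, 80, 95), 1)
    bld_hit(b, id, acc, "curated_tdb", ident, cov, ev_pass_blast(),
            round(runif(1, 200, 400)), "ABC-type sugar transport ATPase")
    bld_hit(b, id, "WP_900001.1", "nr", round(runif(1, 60, 90), 1),
            round(runif(1, 80, 95), 1), ev_pass_blast(),
            round(runif(1, 150, 350)),
            "ABC transporter ATP-binding protein")
    bld_domain(b, id, "PF00005.27", "ABC_tran", ev_pass_hmm())
    bld_cog(b, id, "COG1129", ev_pass_cog())
    bld_manifest(b, id, "abc", tier, "retained", NA_character_,
                 if (tier == "specific") substrate else NA_character_,
                 if (tier != "abstain") "sugars" else NA_character_,
                 substrate, acc, 0L, TRUE)
  }

  for (i in seq_len(spec$n_mfs)) {
    id <- sprintf("mfs_%03d", i)
    acc <- sprintf("TCDB%04d", i)
    substrate <- sample(SUBSTRATE_POOL, 1)
    bld_reference(b, acc, "MFS", NA_character_, "2.A.1.1.1", "sugars",
                  substrate)
    ts <- tm_sequence(12L)
    bld_protein(b, id, "MFS sugar transporter", ts$sequence, ts$segments)
    bld_hit(b, id, acc, "tcdb", round(runif(1, 70, 95), 1),
            round(runif(1, 80, 95), 1), ev_pass_blast(),
            round(runif(1, 250, 450)), "MFS permease")
    bld_hit(b, id, "WP_900002.1", "nr", round(runif(1, 60, 90), 1),
            round(runif(1, 80, 95), 1), ev_pass_blast(),
            round(runif(1, 150, 350)), "MFS transporter")
    bld_domain(b, id, "PF07690.17", "MFS_1", ev_pass_hmm())
    bld_cog(b, id, "COG0477", ev_pass_cog())
    bld_manifest(b, id, "mfs", "specific", "retained", NA_character_,
                 substrate, "sugars", substrate, acc, 12L, TRUE)
  }

  for (i in seq_len(spec$n_uvra)) {
    id <- sprintf("uvra_%03d", i)
    bld_protein(b, id, "excinuclease ABC subunit A",
                rand_seq(sample(380:420, 1)))
    bld_domain(b, id, "PF00005.27", "ABC_tran", ev_pass_hmm())
    bld_cog(b, id, "COG0178", ev_pass_cog())
    bld_hit(b, id, "WP_910001.1", "nr", round(runif(1, 70, 95), 1),
            round(runif(1, 85, 98), 1), ev_pass_blast(),
            round(runif(1, 300, 500)), "excinuclease ABC subunit A")
    bld_manifest(b, id, "uvra_decoy", NA_character_, "excluded",
                 "abc_nontransporter_cogs", NA_character_, NA_character_,
                 NA_character_, NA_character_, 0L, FALSE)
  }

  for (i in seq_len(spec$n_cbs)) {
    id <- sprintf("cbs_%03d", i)
    via_cog <- i <= ceiling(spec$n_cbs / 2)
    bld_protein(b, id, "CBS domain protein", rand_seq(sample(220:280, 1)))
    bld_domain(b, id, "PF00005.27", "ABC_tran", ev_pass_hmm())
    if (via_cog) {
      bld_cog(b, id, "COG0517", ev_pass_cog())
      bld_hit(b, id, "WP_920001.1", "nr", round(runif(1, 60, 90), 1),
              round(runif(1, 80, 95), 1), ev_pass_blast(),
              round(runif(1, 150, 300)), "signal transduction protein")
      rule <- "abc_nontransporter_cogs"
    } else {
      bld_hit(b, id, "WP_920002.1", "nr", round(runif(1, 60, 90), 1),
              round(runif(1, 80, 95), 1), ev_pass_blast(),
              round(runif(1, 150, 300)), "CBS domain containing protein")
      rule <- "abc_nr_keywords"
    }
    bld_manifest(b, id, "cbs_decoy", NA_character_, "excluded", rule,
                 NA_character_, NA_character_, NA_character_,
                 NA_character_, 0L, FALSE)
  }

  for (i in seq_len(spec$n_cpa3)) {
    id <- sprintf("cpa3_%03d", i)
    acc <- sprintf("TDBCPA%03d", i)
    bld_reference(b, acc, "CPA3", NA_character_, "2.A.63.1.1", "cations",
                  "sodium")
    ts <- tm_sequence(8L)
    bld_protein(b, id, "monovalent cation:proton antiporter subunit",
                ts$sequence, ts$segments)
    bld_hit(b, id, acc, "curated_tdb", round(runif(1, 35, 55), 1),
            round(runif(1, 80, 95), 1), ev_pass_blast(),
            round(runif(1, 120, 250)), "CPA3 antiporter subunit")
    bld_hit(b, id, "WP_930001.1", "nr", round(runif(1, 40, 70), 1),
            round(runif(1, 80, 95), 1), ev_pass_blast(),
            round(runif(1, 120, 250)),
            "NADH-quinone oxidoreductase subunit N")
    bld_manifest(b, id, "cpa3_confusable", "class", "retained",
                 NA_character_, NA_character_, "cations", "sodium", acc,
                 8L, spec$cpa3_in_gold)
  }

  for (i in seq_len(spec$n_membrane_subunits)) {
    id <- sprintf("msub_%03d", i)
    # 5 helices: below the standalone TM criterion; every hit sub-threshold
    ts <- tm_sequence(5L)
    bld_protein(b, id, "ABC transporter permease (divergent)", ts$sequence,
                ts$segments)
    bld_hit(b, id, "TDBX001", "curated_tdb", round(runif(1, 15, 24), 1),
            round(runif(1, 40, 60), 1), ev_fail_blast(),
            round(runif(1, 30, 60)), "ABC transporter permease")
    bld_domain(b, id, "PF00005.27", "ABC_tran", ev_fail_hmm(), score = 8)
    bld_manifest(b, id, "membrane_subunit", NA_character_,
                 "never_candidate", NA_character_, NA_character_,
                 NA_character_, NA_character_, NA_character_, 5L, TRUE)
  }

  for (i in seq_len(spec$n_background)) {
    id <- sprintf("bg_%03d", i)
    bld_protein(b, id, "hypothetical protein",
                rand_seq(sample(150:350, 1)))
    bld_hit(b, id, "WP_940001.1", "nr", round(runif(1, 20, 35), 1),
            round(runif(1, 30, 60), 1), ev_fail_blast(),
            round(runif(1, 30, 60)), "hypothetical protein")
    bld_manifest(b, id, "background", NA_character_, "never_candidate",
                 NA_character_, NA_character_, NA_character_,
                 NA_character_, NA_character_, 0L, FALSE)
  }

  bld_write(b, out_dir)
}

#' Minimal six-protein worked example
#'
#' A deterministic bundle used in documentation and smoke tests: one
#' MalK-like ABC transporter (retained, specific-tier maltose transfer),
#' one UvrA decoy (excluded by the COG rule), one keyword decoy (excluded
#' by the NR-keyword rule), one CPA3 confusable (retained — the shipped
#' rules cannot exclude it), one TM-only protein (retained at low
#' confidence), one background protein (never a candidate).
#'
#' @param out_dir Output directory.
#' @param cpa3_in_gold Whether the gold standard counts the CPA3
#'   confusable as a true transporter (default FALSE: evaluating against
#'   this gold reproduces the one-false-positive anatomy).
#' @return A \code{fixture_bundle}.
#' @export
worked_example <- function(out_dir, cpa3_in_gold = FALSE) {
  set.seed(7L)
  b <- new_builder()
  bld_reference(b, "TDB0001", "ABC", "CUT1", "3.A.1.1.1", "sugars",
                "maltose")
  bld_reference(b, "TDB0002", "CPA3", NA_character_, "2.A.63.1.1",
                "cations", "sodium")

  bld_protein(b, "malK_like", "maltose ABC transporter ATP-binding protein",
              rand_seq(360))
  bld_hit(b, "malK_like", "TDB0001", "curated_tdb", 85, 92, 1e-80, 310,
          "maltose ABC transporter ATPase MalK")
  bld_hit(b, "malK_like", "WP_900001.1", "nr", 82, 90, 1e-75, 290,
          "ABC transporter ATP-binding protein")
  bld_domain(b, "malK_like", "PF00005.27", "ABC_tran", 1e-20)
  bld_cog(b, "malK_like", "COG1129", 1e-30)
  bld_manifest(b, "malK_like", "abc", "specific", "retained",
               NA_character_, "maltose", "sugars", "maltose", "TDB0001",
               0L, TRUE)

  bld_protein(b, "uvrA_decoy", "excinuclease ABC subunit A",
              rand_seq(400))
  bld_domain(b, "uvrA_decoy", "PF00005.27", "ABC_tran", 1e-15)
  bld_cog(b, "uvrA_decoy", "COG0178", 1e-40)
  bld_hit(b, "uvrA_decoy", "WP_910001.1", "nr", 90, 95, 1e-120, 450,
          "excinuclease ABC subunit A")
  bld_manifest(b, "uvrA_decoy", "uvra_decoy", NA_character_, "excluded",
               "abc_nontransporter_cogs", NA_character_, NA_character_,
               NA_character_, NA_character_, 0L, FALSE)

  bld_protein(b, "keyword_decoy", "UvrABC system protein", rand_seq(380))
  bld_domain(b, "keyword_decoy", "PF00005.27", "ABC_tran", 1e-12)
  bld_hit(b, "keyword_decoy", "WP_910002.1", "nr", 88, 94, 1e-110, 420,
          "excinuclease ABC subunit A")
  bld_manifest(b, "keyword_decoy", "keyword_decoy", NA_character_,
               "excluded", "abc_nr_keywords", NA_character_,
               NA_character_, NA_character_, NA_character_, 0L, FALSE)

  ts <- tm_sequence(8L)
  bld_protein(b, "cpa3_confusable",
              "cation:proton antiporter subunit", ts$sequence, ts$segments)
  bld_hit(b, "cpa3_confusable", "TDB0002", "curated_tdb", 45, 85, 1e-25,
          160, "CPA3 antiporter subunit")
  bld_hit(b, "cpa3_confusable", "WP_930001.1", "nr", 55, 88, 1e-35, 200,
          "NADH-quinone oxidoreductase subunit N")
  bld_manifest(b, "cpa3_confusable", "cpa3_confusable", "class",
               "retained", NA_character_, NA_character_, "cations",
               "sodium", "TDB0002", 8L, cpa3_in_gold)

  ts <- tm_sequence(7L)
  bld_protein(b, "tm_only", "uncharacterized membrane protein",
              ts$sequence, ts$segments)
  bld_manifest(b, "tm_only", "tm_only", NA_character_, "retained",
               NA_character_, NA_character_, NA_character_, NA_character_,
               NA_character_, 7L, TRUE)

  bld_protein(b, "background_1", "hypothetical protein", rand_seq(240))
  bld_hit(b, "background_1", "WP_940001.1", "nr", 28, 45, 0.02, 40,
          "hypothetical protein")
  bld_manifest(b, "background_1", "background", NA_character_,
               "never_candidate", NA_character_, NA_character_,
               NA_character_, NA_character_, NA_character_, 0L, FALSE)

  bld_write(b, out_dir)
}

#' Run the full pipeline on a fixture bundle directory
#'
#' Reads every file of a generated bundle with the package readers and
#' annotates the proteome with the supplied (default) configuration.
#'
#' @param dir Directory written by [generate_fixtures()] or
#'   [worked_example()].
#' @param use_tm_file Use the bundled TMHMM-short file (TRUE, default)
#'   or the built-in hydropathy predictor (FALSE).
#' @param ... Passed on to [annotate_proteome()].
#' @return A \code{transannot_annotations} data frame.
#' @export
annotate_fixture_dir <- function(dir, use_tm_file = TRUE, ...) {
  p <- setNames(file.path(dir, FIXTURE_FILES), names(FIXTURE_FILES))
  proteome <- read_fasta(p[["proteome"]])
  hits <- do.call(rbind, lapply(VALID_TRACKS, function(tr)
    read_tabular_hits(p[[tr]], tr, proteome)))
  topo <- if (use_tm_file) read_tm_short(p[["tm"]]) else NULL
  annotate_proteome(proteome, hits,
                    domain_hits = read_domain_table(p[["domains"]]),
                    cog_hits = read_cog_hits(p[["cogs"]]),
                    topologies = topo,
                    reference = read_reference_table(p[["reference"]]),
                    ...)
}
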