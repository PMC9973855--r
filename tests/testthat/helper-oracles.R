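# Independent brute-force oracles and random-input builders.  Each oracle
# recomputes a quantity with plain loops, sharing no code path with the
# implementation it checks.

KD_ORACLE <- c(A =  1.8, R = -4.5, N = -3.5, D = -3.5, C =  2.5,
               Q = -3.5, E = -3.5, G = -0.4, H = -3.2, I =  4.5,
               L =  3.8, K = -3.9, M =  1.9, F =  2.8, P = -1.6,
               S = -0.8, T = -0.7, W = -0.9, Y = -1.3, V =  4.2)

# windowed mean by direct recomputation at every position
oracle_windowed_mean <- function(sequence, window) {
  chars <- strsplit(sequence, "")[[1]]
  s <- KD_ORACLE[chars]
  s[is.na(s)] <- 0
  n <- length(s)
  h <- window %/% 2
  out <- numeric(n)
  for (i in seq_len(n)) {
    w <- s[max(1, i - h):min(n, i + h)]
    out[i] <- sum(w) / length(w)
  }
  out
}

# run-finding by explicit position scan: supra-threshold runs, merge
# short gaps, drop short merged runs
oracle_call_runs <- function(profile, threshold, min_len, merge_gap) {
  above <- profile >= threshold
  runs <- list()
  i <- 1
  while (i <= length(above)) {
    if (above[i]) {
      j <- i
      while (j < length(above) && above[j + 1]) j <- j + 1
      runs[[length(runs) + 1]] <- c(i, j)
      i <- j + 1
    } else i <- i + 1
  }
  if (length(runs) == 0) return(matrix(integer(), ncol = 2))
  merged <- list(runs[[1]])
  for (r in runs[-1]) {
    last <- merged[[length(merged)]]
    if (r[1] - last[2] - 1 <= merge_gap) {
      merged[[length(merged)]] <- c(last[1], r[2])
    } else merged[[length(merged) + 1]] <- r
  }
  keep <- Filter(function(r) r[2] - r[1] + 1 >= min_len, merged)
  if (length(keep) == 0) return(matrix(integer(), ncol = 2))
  do.call(rbind, keep)
}

# per-track pass predicate recomputed from the raw evidence tables
oracle_track_pass <- function(id, blast, domains, cogs, topologies, th) {
  pass <- c(curated_tdb = FALSE, tcdb = FALSE, nr = FALSE, hmm = FALSE,
            cog = FALSE, tm = FALSE)
  for (tr in c("curated_tdb", "tcdb", "nr")) {
    for (k in seq_len(nrow(blast))) {
      if (blast$query_id[k] == id && blast$source_track[k] == tr &&
          blast$evalue[k] <= th$blast_evalue_max[[tr]])
        pass[[tr]] <- TRUE
    }
  }
  for (k in seq_len(nrow(domains))) {
    if (domains$query_id[k] == id &&
        domains$domain_evalue[k] <= th$hmm_domain_evalue_max)
      pass[["hmm"]] <- TRUE
  }
  for (k in seq_len(nrow(cogs))) {
    if (cogs$query_id[k] == id && cogs$evalue[k] <= th$cog_evalue_max &&
        cogs$cog_id[k] %in% th$cog_allowlist)
      pass[["cog"]] <- TRUE
  }
  topo <- topologies[[id]]
  if (!is.null(topo) && topo$tm_count >= th$tm_standalone_min)
    pass[["tm"]] <- TRUE
  pass
}

# independent reading of the negative-rule semantics: armed by a passing
# scope domain, fired by a passing payload COG or a keyword substring in
# the top-k NR descriptions
oracle_apply_rules <- function(bundle, candidate, rs) {
  if (!candidate$is_candidate) return(list(status = "never_candidate",
                                           excluded_by = NA_character_))
  doms <- bundle$domain_hits
  passing_doms <- character(0)
  for (k in seq_len(nrow(doms)))
    if (doms$passes[k]) passing_doms <- c(passing_doms,
                                          doms$model_accession[k])
  cogs <- bundle$cog_hits
  passing_cogs <- character(0)
  for (k in seq_len(nrow(cogs)))
    if (cogs$passes[k]) passing_cogs <- c(passing_cogs, cogs$cog_id[k])
  nr <- bundle$blast_hits$nr
  ord <- order(-nr$bitscore, nr$evalue, nr$subject_id)
  descs <- nr$subject_description[ord][seq_len(min(rs$nr_top_k, nrow(nr)))]
  for (r in rs$rules) {
    armed <- FALSE
    for (sc in r$scope_accessions) if (sc %in% passing_doms) armed <- TRUE
    if (!armed) next
    if (r$rule_kind == "cog_exclusion") {
      for (p in r$payload) {
        if (p %in% passing_cogs)
          return(list(status = "excluded", excluded_by = r$rule_id))
      }
    } else {
      for (p in r$payload) {
        for (d in descs) {
          if (grepl(tolower(p), tolower(d), fixed = TRUE))
            return(list(status = "excluded", excluded_by = r$rule_id))
        }
      }
    }
  }
  list(status = "retained", excluded_by = NA_character_)
}

random_protein_ids <- function(n) sprintf("rp_%04d", seq_len(n))

# random raw evidence over a synthetic proteome, exercising scope domains,
# payload COGs, allowlist COGs, exclusion keywords and sub-threshold hits
random_evidence <- function(n, seed) {
  set.seed(seed)
  ids <- random_protein_ids(n)
  proteome <- data.frame(protein_id = ids, description = "",
                         sequence = vapply(seq_len(n), function(i)
                           paste(sample(c("A", "G", "S", "T", "D", "E"),
                                        60, replace = TRUE), collapse = ""),
                           character(1)))
  descs <- c("ABC transporter ATP-binding protein",
             "excinuclease ABC subunit A", "CBS domain containing protein",
             "chromosome partition protein Smc",
             "cytochrome c biogenesis protein", "hypothetical protein",
             "NADH-quinone oxidoreductase subunit N",
             "RNase L inhibitor homolog")
  payload_cogs <- c("COG0178", "COG0517", "COG1196", "COG1192")
  other_cogs <- c("COG1129", "COG0477", "COG9999", "COG1234")
  blast <- list(); domains <- list(); cogs <- list()
  for (i in seq_len(n)) {
    id <- ids[i]
    for (k in seq_len(sample(0:3, 1))) {
      blast[[length(blast) + 1]] <- data.frame(
        query_id = id, subject_id = sprintf("S%05d", sample(1e5, 1)),
        percent_identity = round(runif(1, 15, 95), 1),
        alignment_length = 100, mismatches = 10, gap_opens = 0,
        qstart = 1, qend = 50, sstart = 1, send = 50,
        evalue = 10^runif(1, -40, 1), bitscore = round(runif(1, 30, 400)),
        query_coverage = round(runif(1, 20, 100), 1),
        subject_description = sample(descs, 1),
        source_track = sample(c("curated_tdb", "tcdb", "nr"), 1))
    }
    for (k in seq_len(sample(0:2, 1))) {
      domains[[length(domains) + 1]] <- data.frame(
        query_id = id,
        model_accession = sample(c("PF00005", "PF07690", "PF00361"), 1),
        model_name = "dom", domain_evalue = 10^runif(1, -30, 0),
        score = round(runif(1, 10, 200)), env_start = 1L, env_end = 50L)
    }
    for (k in seq_len(sample(0:2, 1))) {
      cogs[[length(cogs) + 1]] <- data.frame(
        query_id = id,
        cog_id = sample(c(payload_cogs, other_cogs), 1),
        evalue = 10^runif(1, -40, 0), bitscore = round(runif(1, 30, 300)))
    }
  }
  list(proteome = proteome,
       blast = if (length(blast)) do.call(rbind, blast) else NULL,
       domains = if (length(domains)) do.call(rbind, domains) else NULL,
       cogs = if (length(cogs)) do.call(rbind, cogs) else NULL)
}

random_bundles <- function(n, seed) {
  ev <- random_evidence(n, seed)
  build_bundles(ev$proteome, ev$blast, ev$domains, ev$cogs)
}
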