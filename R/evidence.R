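# Per-protein evidence aggregation: group all hits by track, apply the
# per-track thresholds, and nominate candidates by the mutually inclusive
# union over tracks (any passing homology/domain/COG track, or a strong
# standalone transmembrane topology).

EVIDENCE_TRACKS <- c("curated_tdb", "tcdb", "nr", "hmm", "cog", "tm")

# COGs that may act as POSITIVE transporter evidence.  Kept deliberately
# small and user-extensible: the exclusion COGs of the default negative
# ruleset must never themselves nominate candidates.
DEFAULT_COG_ALLOWLIST <- c("COG0477",  # MFS permease
                           "COG1129",  # ABC-type sugar transport ATPase
                           "COG1175",  # ABC-type sugar permease
                           "COG0395")  # ABC-type sugar permease component

#' Evidence thresholds
#'
#' E-value ceilings per search track plus the standalone transmembrane
#' criterion.  A hit passes its track iff its E-value is at or below the
#' ceiling; the tm track passes iff the predicted helix count reaches
#' \code{tm_standalone_min}.  Only COGs in \code{cog_allowlist} count as
#' positive evidence (exclusion COGs are consumed by the rule engine
#' regardless of the allowlist).
#'
#' @param blast_evalue_max Named numeric ceilings for the three alignment
#'   tracks (\code{curated_tdb}, \code{tcdb}, \code{nr}).
#' @param hmm_domain_evalue_max Per-domain independent E-value ceiling.
#' @param cog_evalue_max COG hit E-value ceiling.
#' @param tm_standalone_min Minimum helix count for TM-only candidacy.
#' @param cog_allowlist COG accessions accepted as positive evidence.
#' @return Object of class \code{transannot_thresholds}.
#' @export
transannot_thresholds <- function(blast_evalue_max = c(curated_tdb = 1e-5,
                                                       tcdb = 1e-5,
                                                       nr = 1e-5),
                                  hmm_domain_evalue_max = 1e-4,
                                  cog_evalue_max = 1e-5,
                                  tm_standalone_min = 6L,
                                  cog_allowlist = DEFAULT_COG_ALLOWLIST) {
  blast_evalue_max <- blast_evalue_max[VALID_TRACKS]
  if (anyNA(blast_evalue_max))
    stop("blast_evalue_max must name all of: ",
         paste(VALID_TRACKS, collapse = ", "))
  if (any(c(blast_evalue_max, hmm_domain_evalue_max, cog_evalue_max) <= 0))
    stop("all E-value ceilings must be > 0")
  if (tm_standalone_min < 1L) stop("tm_standalone_min must be positive")
  structure(list(blast_evalue_max = blast_evalue_max,
                 hmm_domain_evalue_max = hmm_domain_evalue_max,
                 cog_evalue_max = cog_evalue_max,
                 tm_standalone_min = as.integer(tm_standalone_min),
                 cog_allowlist = cog_allowlist),
            class = "transannot_thresholds")
}

#' Build one evidence bundle per protein
#'
#' Collects all evidence for each proteome member, sorts each track
#' (alignment hits by descending bitscore, domain and COG hits by
#' ascending E-value), flags per-hit threshold passes, and computes the
#' per-track pass table.  Evidence whose query id is not in the proteome
#' is dropped with a warning.
#'
#' @param proteome Proteome data frame (see [read_fasta()]).
#' @param blast_hits Data frame of alignment hits across all three tracks
#'   (column \code{source_track}), or a list of such frames.
#' @param domain_hits Data frame of profile-HMM domain hits (may be NULL).
#' @param cog_hits Data frame of COG hits (may be NULL).
#' @param topologies Named list of [tm_topology()] objects; when NULL the
#'   built-in hydropathy predictor is run with \code{tm_params}.
#' @param thresholds A [transannot_thresholds()] object.
#' @param tm_params A [hydropathy_params()] object for the built-in
#'   predictor.
#' @return Named list of \code{evidence_bundle} objects, in proteome
#'   order.
#' @export
build_bundles <- function(proteome, blast_hits = NULL, domain_hits = NULL,
                          cog_hits = NULL, topologies = NULL,
                          thresholds = transannot_thresholds(),
                          tm_params = hydropathy_params()) {
  if (is.list(blast_hits) && !is.data.frame(blast_hits))
    blast_hits <- do.call(rbind, blast_hits)
  if (is.null(blast_hits)) blast_hits <- empty_hits()
  ids <- proteome$protein_id

  drop_unknown <- function(df, what) {
    if (is.null(df) || nrow(df) == 0L) return(df)
    unknown <- !(df$query_id %in% ids)
    if (any(unknown)) {
      warning(sprintf("%d %s hit(s) with unknown query id dropped (e.g. '%s')",
                      sum(unknown), what, df$query_id[unknown][1]),
              call. = FALSE)
      df <- df[!unknown, , drop = FALSE]
    }
    df
  }
  blast_hits <- drop_unknown(blast_hits, "alignment")
  domain_hits <- drop_unknown(domain_hits, "domain")
  cog_hits <- drop_unknown(cog_hits, "COG")

  if (is.null(topologies))
    topologies <- predict_topologies(proteome, tm_params)

  lapply_named <- function(f) setNames(lapply(seq_along(ids), f), ids)
  lapply_named(function(i) {
    id <- ids[i]
    by_track <- lapply(setNames(VALID_TRACKS, VALID_TRACKS), function(tr) {
      h <- blast_hits[blast_hits$query_id == id &
                        blast_hits$source_track == tr, , drop = FALSE]
      h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
      h$passes <- h$evalue <= thresholds$blast_evalue_max[[tr]]
      h
    })
    dh <- if (is.null(domain_hits)) NULL
          else domain_hits[domain_hits$query_id == id, , drop = FALSE]
    if (is.null(dh)) {
      dh <- data.frame(query_id = character(), model_accession = character(),
                       model_name = character(), domain_evalue = numeric(),
                       score = numeric(), env_start = integer(),
                       env_end = integer(), stringsAsFactors = FALSE)
    }
    dh <- dh[order(dh$domain_evalue, dh$model_accession), , drop = FALSE]
    dh$passes <- dh$domain_evalue <= thresholds$hmm_domain_evalue_max
    ch <- if (is.null(cog_hits)) NULL
          else cog_hits[cog_hits$query_id == id, , drop = FALSE]
    if (is.null(ch)) {
      ch <- data.frame(query_id = character(), cog_id = character(),
                       evalue = numeric(), bitscore = numeric(),
                       stringsAsFactors = FALSE)
    }
    ch <- ch[order(ch$evalue, ch$cog_id), , drop = FALSE]
    ch$passes <- ch$evalue <= thresholds$cog_evalue_max
    ch$positive <- ch$passes & ch$cog_id %in% thresholds$cog_allowlist
    topo <- topologies[[id]] %||% tm_topology()

    track_pass <- c(
      curated_tdb = any(by_track$curated_tdb$passes),
      tcdb = any(by_track$tcdb$passes),
      nr = any(by_track$nr$passes),
      hmm = any(dh$passes),
      cog = any(ch$positive),
      tm = topo$tm_count >= thresholds$tm_standalone_min)

    structure(list(protein_id = id, blast_hits = by_track,
                   domain_hits = dh, cog_hits = ch, topology = topo,
                   track_pass = track_pass, thresholds = thresholds),
              class = "evidence_bundle")
  })
}

#' @export
print.evidence_bundle <- function(x, ...) {
  cat(sprintf("evidence_bundle for '%s'\n", x$protein_id))
  cat(sprintf("  alignment hits: curated_tdb %d, tcdb %d, nr %d\n",
              nrow(x$blast_hits$curated_tdb), nrow(x$blast_hits$tcdb),
              nrow(x$blast_hits$nr)))
  cat(sprintf("  domain hits: %d; COG hits: %d; TM segments: %d\n",
              nrow(x$domain_hits), nrow(x$cog_hits), x$topology$tm_count))
  pass <- names(x$track_pass)[x$track_pass]
  cat("  passing tracks:",
      if (length(pass)) paste(pass, collapse = ", ") else "(none)", "\n")
  invisible(x)
}

#' Candidate status under the mutually inclusive union
#'
#' A protein is a candidate transporter iff any homology, domain or COG
#' track passes its threshold, or the transmembrane track passes
#' standalone.  TM-only candidates are later annotated at the lowest
#' confidence tier.
#'
#' @param bundle An \code{evidence_bundle}.
#' @return List with \code{is_candidate} (logical) and
#'   \code{triggering_tracks} (character vector of passing tracks).
#' @export
flag_candidate <- function(bundle) {
  trig <- names(bundle$track_pass)[bundle$track_pass]
  list(is_candidate = length(trig) > 0L, triggering_tracks = trig)
}
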