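# Homology transfer of family / subfamily / TC number and tiered substrate
# predictions from a curated reference table.  Specific-substrate calls
# ("maltose") require a stronger best hit than class-level calls
# ("sugars"); when neither tier is met the prediction abstains.

#' Substrate transfer tiers
#'
#' Identity/coverage floors for the two prediction tiers.  A best
#' reference hit at or above the specific tier transfers both the named
#' substrate and its class; a hit reaching only the class tier transfers
#' the class alone; anything weaker abstains on both.  Unknown coverage
#' fails every coverage floor (conservative).
#'
#' @param specific_min_identity,specific_min_coverage Floors (percent)
#'   for specific-substrate transfer.
#' @param class_min_identity,class_min_coverage Floors (percent) for
#'   substrate-class transfer; must not exceed the specific floors.
#' @return Object of class \code{transfer_tiers}.
#' @export
transfer_tiers <- function(specific_min_identity = 60,
                           specific_min_coverage = 70,
                           class_min_identity = 30,
                           class_min_coverage = 50) {
  if (specific_min_identity < class_min_identity ||
      specific_min_coverage < class_min_coverage)
    stop("specific tier floors must be >= class tier floors")
  structure(list(specific_min_identity = specific_min_identity,
                 specific_min_coverage = specific_min_coverage,
                 class_min_identity = class_min_identity,
                 class_min_coverage = class_min_coverage),
            class = "transfer_tiers")
}

# Minimal, user-extensible map from transporter-family profile accessions
# to family names, used when no reference hit resolves.
DEFAULT_PROFILE_FAMILY_MAP <- c(PF00005 = "ABC")

#' Best resolvable reference hit for a retained protein
#'
#' The highest-bitscore threshold-passing hit on the curated or TCDB
#' tracks whose subject accession resolves in the reference table; ties
#' broken by lower E-value, then lexicographic subject id.
#'
#' @param bundle An \code{evidence_bundle}.
#' @param reference Reference data frame (see [read_reference_table()]).
#' @return List with \code{hit} (one-row data frame) and \code{entry}
#'   (one-row reference entry), or \code{NULL} when no resolvable passing
#'   hit exists.
#' @export
best_reference_hit <- function(bundle, reference) {
  h <- rbind(bundle$blast_hits$curated_tdb, bundle$blast_hits$tcdb)
  h <- h[h$passes & h$subject_id %in% reference$accession, , drop = FALSE]
  if (nrow(h) == 0L) return(NULL)
  h <- h[order(-h$bitscore, h$evalue, h$subject_id), , drop = FALSE]
  best <- h[1, , drop = FALSE]
  entry <- reference[reference$accession == best$subject_id, , drop = FALSE]
  list(hit = best, entry = entry)
}

#' Transfer family / subfamily / TC number
#'
#' Copies classification from the best reference entry when one resolves;
#' otherwise falls back to the profile-to-family map over
#' threshold-passing domain hits; otherwise \code{"unclassified"}.
#'
#' @param bundle An \code{evidence_bundle}.
#' @param best Result of [best_reference_hit()] (or NULL).
#' @param profile_family_map Named character vector mapping profile
#'   accessions to family names.
#' @return List with \code{family}, \code{subfamily}, \code{tc_number}
#'   (absent values are \code{NA}).
#' @export
assign_classification <- function(bundle, best,
                                  profile_family_map = DEFAULT_PROFILE_FAMILY_MAP) {
  if (!is.null(best)) {
    e <- best$entry
    return(list(family = e$family, subfamily = e$subfamily,
                tc_number = e$tc_number))
  }
  passing <- bundle$domain_hits[bundle$domain_hits$passes, , drop = FALSE]
  mapped <- passing$model_accession[passing$model_accession %in%
                                      names(profile_family_map)]
  if (length(mapped))
    return(list(family = unname(profile_family_map[mapped[1]]),
                subfamily = NA_character_, tc_number = NA_character_))
  list(family = "unclassified", subfamily = NA_character_,
       tc_number = NA_character_)
}

#' Tiered substrate prediction with abstention
#'
#' @param best Result of [best_reference_hit()] (or NULL).
#' @param tiers A [transfer_tiers()] object.
#' @return List with \code{substrate_class} and \code{substrate}
#'   (\code{NA} = abstained).  Missing reference fields propagate as
#'   abstention at that level.
#' @export
predict_substrate <- function(best, tiers = transfer_tiers()) {
  abstain <- list(substrate_class = NA_character_, substrate = NA_character_)
  if (is.null(best)) return(abstain)
  id <- best$hit$percent_identity
  cov <- best$hit$query_coverage
  cov_ok <- function(floor) !is.na(cov) && cov >= floor
  e <- best$entry
  if (id >= tiers$specific_min_identity && cov_ok(tiers$specific_min_coverage))
    return(list(substrate_class = e$substrate_class, substrate = e$substrate))
  if (id >= tiers$class_min_identity && cov_ok(tiers$class_min_coverage))
    return(list(substrate_class = e$substrate_class,
                substrate = NA_character_))
  abstain
}

substrate_tier <- function(best, tiers) {
  if (is.null(best)) return("none")
  id <- best$hit$percent_identity
  cov <- best$hit$query_coverage
  if (id >= tiers$specific_min_identity &&
      !is.na(cov) && cov >= tiers$specific_min_coverage) return("specific")
  if (id >= tiers$class_min_identity &&
      !is.na(cov) && cov >= tiers$class_min_coverage) return("class")
  "none"
}

evidence_summary <- function(call) {
  paste(call$triggering_tracks, collapse = ",")
}

#' Annotate a proteome end to end
#'
#' Full composition: evidence bundling, candidate nomination, negative
#' decision tree, classification transfer and tiered substrate
#' prediction.  Output order equals proteome order and the result is
#' deterministic for identical inputs.
#'
#' Confidence tiers: \code{high} = curated/TCDB best hit at the specific
#' substrate tier; \code{medium} = class-tier best hit or
#' transporter-profile-only evidence; \code{low} = anything weaker
#' (including TM-only candidates).
#'
#' @param proteome Proteome data frame (see [read_fasta()]).
#' @param blast_hits,domain_hits,cog_hits,topologies Evidence, as for
#'   [build_bundles()].
#' @param reference Reference data frame (see [read_reference_table()]).
#' @param rs A [ruleset()]; defaults to [default_ruleset()].
#' @param thresholds A [transannot_thresholds()] object.
#' @param tiers A [transfer_tiers()] object.
#' @param tm_params A [hydropathy_params()] object.
#' @param profile_family_map Profile-to-family fallback map.
#' @return Data frame of class \code{transannot_annotations}, one row per
#'   protein, with the columns of [write_annotations()] plus
#'   \code{matched_payload}.
#' @export
annotate_proteome <- function(proteome, blast_hits = NULL,
                              domain_hits = NULL, cog_hits = NULL,
                              topologies = NULL, reference = NULL,
                              rs = default_ruleset(),
                              thresholds = transannot_thresholds(),
                              tiers = transfer_tiers(),
                              tm_params = hydropathy_params(),
                              profile_family_map = DEFAULT_PROFILE_FAMILY_MAP) {
  if (is.null(reference))
    reference <- data.frame(accession = character(), family = character(),
                            subfamily = character(), tc_number = character(),
                            substrate_class = character(),
                            substrate = character(), stringsAsFactors = FALSE)
  bundles <- build_bundles(proteome, blast_hits, domain_hits, cog_hits,
                           topologies, thresholds, tm_params)
  rows <- lapply(bundles, function(b) {
    cand <- flag_candidate(b)
    call <- apply_rules(b, cand, rs)
    row <- list(protein_id = b$protein_id, status = call$status,
                family = NA_character_, subfamily = NA_character_,
                tc_number = NA_character_, substrate_class = NA_character_,
                substrate = NA_character_, confidence = NA_character_,
                tm_count = b$topology$tm_count,
                evidence_summary = evidence_summary(call),
                excluded_by = call$excluded_by,
                matched_payload = call$matched_payload)
    if (call$status == "retained") {
      best <- best_reference_hit(b, reference)
      cls <- assign_classification(b, best, profile_family_map)
      sub <- predict_substrate(best, tiers)
      tier <- substrate_tier(best, tiers)
      profile_backed <- any(b$domain_hits$passes &
                              b$domain_hits$model_accession %in%
                                names(profile_family_map))
      row$family <- cls$family
      row$subfamily <- cls$subfamily
      row$tc_number <- cls$tc_number
      row$substrate_class <- sub$substrate_class
      row$substrate <- sub$substrate
      row$confidence <- if (tier == "specific") "high"
                        else if (tier == "class" || profile_backed) "medium"
                        else "low"
    }
    as.data.frame(row, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out)) out <- as.data.frame(
    setNames(rep(list(character()), length(ANNOTATION_COLUMNS) + 1L),
             c(ANNOTATION_COLUMNS, "matched_payload")))
  class(out) <- c("transannot_annotations", "data.frame")
  attr(out, "thresholds") <- thresholds
  attr(out, "tiers") <- tiers
  out
}

#' @export
print.transannot_annotations <- function(x, ...) {
  n <- table(factor(x$status,
                    levels = c("retained", "excluded", "never_candidate")))
  cat(sprintf("transannot annotations: %d protein(s)\n", nrow(x)))
  cat(sprintf("  retained %d | excluded %d | never_candidate %d\n",
              n[["retained"]], n[["excluded"]], n[["never_candidate"]]))
  ret <- x[x$status == "retained", , drop = FALSE]
  if (nrow(ret)) {
    cat(sprintf("  specific substrate calls: %d; class-only: %d; abstained: %d\n",
                sum(!is.na(ret$substrate)),
                sum(is.na(ret$substrate) & !is.na(ret$substrate_class)),
                sum(is.na(ret$substrate_class))))
  }
  invisible(x)
}

#' @export
summary.transannot_annotations <- function(object, ...) {
  ret <- object[object$status == "retained", , drop = FALSE]
  out <- list(n = nrow(object),
              by_status = table(object$status),
              by_family = if (nrow(ret)) table(ret$family) else table(character()),
              by_confidence = if (nrow(ret)) table(ret$confidence)
                              else table(character()),
              abstained = sum(is.na(ret$substrate)))
  class(out) <- "summary.transannot_annotations"
  out
}

#' @export
print.summary.transannot_annotations <- function(x, ...) {
  cat(sprintf("%d protein(s):\n", x$n))
  print(x$by_status)
  cat("retained by family:\n"); print(x$by_family)
  cat("retained by confidence:\n"); print(x$by_confidence)
  cat(sprintf("specific-substrate abstentions among retained: %d\n",
              x$abstained))
  invisible(x)
}
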