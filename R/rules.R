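# Negative decision tree: declarative post-filters that delete
# false-positive candidates.  A rule is "armed" by a threshold-passing
# domain hit in its scope (e.g. PF00005, the ATP-binding cassette profile
# that also matches UvrA/Smc/RecF-type ATPases and CBS-domain proteins);
# an armed rule "fires" on its payload — exclusion COGs, or keywords in
# the descriptions of the top NR hits.  Rules run in order; the first
# firing rule wins.

#' Construct a negative rule
#'
#' @param rule_id Unique rule identifier.
#' @param scope_accessions Profile accessions that arm the rule.
#' @param rule_kind \code{"cog_exclusion"} or \code{"keyword_exclusion"}.
#' @param payload COG accessions (cog_exclusion) or keyword strings
#'   (keyword_exclusion); must be non-empty.
#' @param description Free-text rationale.
#' @return Object of class \code{negative_rule}.
#' @export
negative_rule <- function(rule_id, scope_accessions, rule_kind, payload,
                          description = "") {
  rule_kind <- match.arg(rule_kind, c("cog_exclusion", "keyword_exclusion"))
  if (length(payload) == 0L) stop("rule payload must be non-empty")
  if (rule_kind == "cog_exclusion" && !all(grepl(COG_PATTERN, payload)))
    stop("cog_exclusion payload must be COG accessions")
  structure(list(rule_id = rule_id,
                 scope_accessions = as.character(scope_accessions),
                 rule_kind = rule_kind, payload = as.character(payload),
                 description = description),
            class = "negative_rule")
}

#' Construct a ruleset
#'
#' @param rules Ordered list of [negative_rule()] objects with unique ids.
#' @param nr_top_k How many top NR hits (by bitscore) the keyword scan
#'   inspects.
#' @return Object of class \code{transannot_ruleset}.
#' @export
ruleset <- function(rules = list(), nr_top_k = 5L) {
  ids <- vapply(rules, `[[`, character(1), "rule_id")
  if (anyDuplicated(ids)) stop("duplicate rule_id in ruleset")
  if (nr_top_k < 1L) stop("nr_top_k must be positive")
  structure(list(rules = rules, nr_top_k = as.integer(nr_top_k)),
            class = "transannot_ruleset")
}

#' The shipped default negative ruleset (ABC/ATP-binding cassette)
#'
#' Two rules scoped to PF00005, the conserved ATP-binding cassette
#' profile, which also matches non-transporter ATPases (UvrA, Smc, RecF,
#' SbcC, Soj, Mrp) and CBS-domain regulators: (1) exclusion by positive
#' hits to the twelve COGs representing those non-transporters; (2)
#' exclusion by eight keywords in the descriptions of the top NR hits.
#'
#' @param nr_top_k How many top NR hits the keyword scan inspects.
#' @return A [ruleset()] with the two ABC rules.
#' @export
default_ruleset <- function(nr_top_k = 5L) {
  ruleset(list(
    negative_rule(
      rule_id = "abc_nontransporter_cogs",
      scope_accessions = "PF00005",
      rule_kind = "cog_exclusion",
      payload = c("COG0178", "COG1196", "COG1106", "COG1195", "COG0419",
                  "COG3910", "COG1192", "COG0489", "COG2524", "COG2905",
                  "COG4109", "COG0517"),
      description = paste("ATP-binding cassette candidates also hitting",
                          "COGs of non-transporter ATPases (UvrA, Smc,",
                          "RecF, SbcC, Soj, Mrp) or CBS-domain proteins",
                          "are deleted")),
    negative_rule(
      rule_id = "abc_nr_keywords",
      scope_accessions = "PF00005",
      rule_kind = "keyword_exclusion",
      payload = c("cAMP-binding", "CBS domain", "Chromosome partition",
                  "Cytochrome c assembly", "Cytochrome c biogenesis",
                  "Excinuclease", "RNase L inhibitor", "UvrABC"),
      description = paste("ATP-binding cassette candidates whose top NR",
                          "hits carry non-transporter keywords are",
                          "deleted"))),
    nr_top_k = nr_top_k)
}

#' Write a ruleset to a YAML file
#'
#' @param rs A [ruleset()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_ruleset <- function(rs, path) {
  obj <- list(nr_top_k = rs$nr_top_k,
              rules = lapply(rs$rules, function(r)
                list(rule_id = r$rule_id,
                     scope = as.list(r$scope_accessions),
                     kind = r$rule_kind,
                     payload = as.list(r$payload),
                     description = r$description)))
  yaml::write_yaml(obj, path)
  invisible(path)
}

#' Read a ruleset from a YAML file
#'
#' @param path Path to a ruleset file written by [write_ruleset()] (or
#'   hand-authored in the same layout).
#' @return A [ruleset()].
#' @export
read_ruleset <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  obj <- yaml::read_yaml(path)
  rules <- lapply(obj$rules, function(r)
    negative_rule(r$rule_id, unlist(r$scope), r$kind, unlist(r$payload),
                  r$description %||% ""))
  ruleset(rules, nr_top_k = obj$nr_top_k %||% 5L)
}

#' Apply the negative decision tree to one candidate
#'
#' Non-candidates pass through untouched (\code{never_candidate}).  For a
#' candidate, each rule in order is armed iff any of its scope accessions
#' appears among the bundle's threshold-passing domain hits; an armed
#' cog_exclusion fires iff any payload COG appears among the
#' threshold-passing COG hits; an armed keyword_exclusion fires iff any
#' payload keyword occurs (case-insensitive substring) in the subject
#' description of any of the top \code{nr_top_k} NR hits by bitscore.
#' The first firing rule excludes the protein.
#'
#' @param bundle An \code{evidence_bundle}.
#' @param candidate Result of [flag_candidate()] for the same protein.
#' @param rs A [ruleset()].
#' @return A \code{transporter_call}: list with \code{protein_id},
#'   \code{status} (\code{retained}/\code{excluded}/\code{never_candidate}),
#'   \code{triggering_tracks}, \code{excluded_by}, \code{matched_payload}.
#' @export
apply_rules <- function(bundle, candidate = flag_candidate(bundle),
                        rs = default_ruleset()) {
  call <- list(protein_id = bundle$protein_id, status = "retained",
               triggering_tracks = candidate$triggering_tracks,
               excluded_by = NA_character_, matched_payload = NA_character_)
  if (!candidate$is_candidate) {
    call$status <- "never_candidate"
    call$triggering_tracks <- character()
    return(structure(call, class = "transporter_call"))
  }
  passing_doms <- bundle$domain_hits$model_accession[bundle$domain_hits$passes]
  passing_cogs <- bundle$cog_hits$cog_id[bundle$cog_hits$passes]
  nr <- bundle$blast_hits$nr
  top_nr_desc <- head(nr$subject_description, rs$nr_top_k)
  for (r in rs$rules) {
    if (!any(r$scope_accessions %in% passing_doms)) next
    matched <- NA_character_
    if (r$rule_kind == "cog_exclusion") {
      hit <- r$payload[r$payload %in% passing_cogs]
      if (length(hit)) matched <- hit[1]
    } else {
      for (kw in r$payload) {
        if (any(grepl(tolower(kw), tolower(top_nr_desc), fixed = TRUE))) {
          matched <- kw
          break
        }
      }
    }
    if (!is.na(matched)) {
      call$status <- "excluded"
      call$excluded_by <- r$rule_id
      call$matched_payload <- matched
      break
    }
  }
  structure(call, class = "transporter_call")
}

#' @export
print.transannot_ruleset <- function(x, ...) {
  cat(sprintf("transannot ruleset: %d rule(s), keyword scan over top %d NR hits\n",
              length(x$rules), x$nr_top_k))
  for (r in x$rules)
    cat(sprintf("  [%s] %s scoped to {%s}: %d payload item(s)\n",
                r$rule_id, r$rule_kind,
                paste(r$scope_accessions, collapse = ","),
                length(r$payload)))
  invisible(x)
}
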