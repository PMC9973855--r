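# Readers and writers for every external format the pipeline touches.
# All coordinates are 1-based inclusive; "-" serializes an absent value.
# Parse failures are hard errors naming the file and line; lines that a
# reader is allowed to skip (COG subjects with no extractable accession)
# are skipped with a warning, never silently.

VALID_TRACKS <- c("curated_tdb", "tcdb", "nr")
AA_ALLOWED <- strsplit("ACDEFGHIKLMNPQRSTVWYXBZU", "")[[1]]

# Shortest decimal representation that parses back to the same double:
# keeps the evidence files readable without breaking round-trip identity.
fmt_g <- function(x) {
  vapply(x, function(v) {
    if (is.na(v)) return("-")
    s <- sprintf("%.15g", v)
    if (as.numeric(s) != v) s <- sprintf("%.17g", v)
    s
  }, character(1))
}

split_fields <- function(path, sep = "\t") {
  lines <- readLines(path, warn = FALSE)
  lines <- sub("\r$", "", lines)
  keep <- which(nzchar(trimws(lines)) & !startsWith(trimws(lines), "#"))
  list(fields = strsplit(lines[keep], sep, fixed = (sep == "\t")),
       lineno = keep)
}

as_num_or_stop <- function(x, path, line, what) {
  v <- suppressWarnings(as.numeric(x))
  if (anyNA(v)) stop_parse(path, line, sprintf("non-numeric %s field: '%s'", what, x))
  v
}

#' Read a protein FASTA file
#'
#' Parses a protein FASTA into one record per defline.  The protein id is
#' the first whitespace-delimited token after \code{">"}; the remainder of
#' the defline becomes the description.  Sequences are upper-cased and
#' restricted to the 20 standard amino acids plus X, B, Z and U.
#'
#' @param path Path to a FASTA file.
#' @return A data frame with columns \code{protein_id}, \code{description}
#'   and \code{sequence}, in file order.
#' @examples
#' fa <- tempfile(fileext = ".faa")
#' writeLines(c(">p1 maltose ABC transporter", "MKTAYIAK"), fa)
#' read_fasta(fa)
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  # validate residue characters up front: the FASTA parser would silently
  # drop invalid one-letter codes, and readers must never drop content
  raw <- readLines(path, warn = FALSE)
  seq_lines <- which(!startsWith(trimws(raw), ">"))
  pat <- sprintf("[^%s[:space:]]", paste(AA_ALLOWED, collapse = ""))
  bad_line <- seq_lines[grepl(pat, toupper(raw[seq_lines]))]
  if (length(bad_line))
    stop_parse(path, bad_line[1], "illegal residue character in sequence")
  aa <- tryCatch(Biostrings::readAAStringSet(path), error = function(e) {
    stop_parse(path, "?", conditionMessage(e))
  })
  if (length(aa) == 0L)
    stop_parse(path, 1, "empty FASTA file (no records)")
  deflines <- names(aa)
  ids <- sub("\\s.*$", "", deflines)
  desc <- ifelse(grepl("\\s", deflines),
                 sub("^\\S+\\s+", "", deflines), "")
  if (any(!nzchar(ids)))
    stop_parse(path, "?", "record with empty identifier")
  if (anyDuplicated(ids)) {
    dup <- ids[duplicated(ids)][1]
    transannot_error(sprintf("duplicate protein_id in %s: '%s'", path, dup),
                     "transannot_parse_error")
  }
  seqs <- toupper(as.character(aa))
  if (any(nchar(seqs) < 1L))
    transannot_error(sprintf("zero-length sequence in %s", path),
                     "transannot_parse_error")
  data.frame(protein_id = ids, description = desc, sequence = unname(seqs),
             stringsAsFactors = FALSE)
}

#' Write a protein FASTA file
#'
#' @param proteome Data frame as returned by [read_fasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_fasta <- function(proteome, path) {
  x <- Biostrings::AAStringSet(proteome$sequence)
  names(x) <- ifelse(nzchar(proteome$description),
                     paste(proteome$protein_id, proteome$description),
                     proteome$protein_id)
  Biostrings::writeXStringSet(x, path)
  invisible(path)
}

empty_hits <- function() {
  data.frame(query_id = character(), subject_id = character(),
             percent_identity = numeric(), alignment_length = numeric(),
             mismatches = numeric(), gap_opens = numeric(),
             qstart = numeric(), qend = numeric(),
             sstart = numeric(), send = numeric(),
             evalue = numeric(), bitscore = numeric(),
             query_coverage = numeric(), subject_description = character(),
             source_track = character(), stringsAsFactors = FALSE)
}

#' Read tabular protein alignment hits (12+-column BLAST dialect)
#'
#' Columns 1--12 follow the standard tabular order (qseqid sseqid pident
#' length mismatch gapopen qstart qend sstart send evalue bitscore);
#' column 13 (query coverage percentage) and column 14 (subject title) are
#' optional.  When column 13 is absent, coverage is computed as
#' \code{100 * (qend - qstart + 1) / query_length} if a proteome is
#' supplied, else recorded as unknown (\code{NA}) and treated downstream
#' as failing any coverage threshold.
#'
#' @param path Path to the tab-separated hit table. Lines starting with
#'   \code{#} are skipped.
#' @param source_track One of \code{"curated_tdb"}, \code{"tcdb"},
#'   \code{"nr"} — the search track these hits belong to.
#' @param proteome Optional proteome data frame (for coverage computation).
#' @return Data frame of hits with standardized column names, including
#'   \code{query_coverage}, \code{subject_description} and
#'   \code{source_track}.
#' @export
read_tabular_hits <- function(path, source_track, proteome = NULL) {
  source_track <- match.arg(source_track, VALID_TRACKS)
  if (!file.exists(path)) stop_missing(path)
  sf <- split_fields(path)
  if (length(sf$fields) == 0L) return(empty_hits())
  rows <- vector("list", length(sf$fields))
  for (i in seq_along(sf$fields)) {
    f <- sf$fields[[i]]
    ln <- sf$lineno[i]
    if (length(f) < 12L)
      stop_parse(path, ln, sprintf("expected >= 12 tab-separated columns, found %d", length(f)))
    num <- as_num_or_stop(f[3:12], path, ln, "alignment")
    cov <- if (length(f) >= 13L) as_num_or_stop(f[13], path, ln, "qcovs") else NA_real_
    rows[[i]] <- data.frame(
      query_id = f[1], subject_id = f[2],
      percent_identity = num[1], alignment_length = num[2],
      mismatches = num[3], gap_opens = num[4],
      qstart = num[5], qend = num[6], sstart = num[7], send = num[8],
      evalue = num[9], bitscore = num[10],
      query_coverage = cov,
      subject_description = if (length(f) >= 14L) f[14] else "",
      stringsAsFactors = FALSE)
  }
  hits <- do.call(rbind, rows)
  if (!is.null(proteome)) {
    miss <- is.na(hits$query_coverage)
    if (any(miss)) {
      len <- setNames(nchar(proteome$sequence), proteome$protein_id)
      ql <- len[hits$query_id[miss]]
      hits$query_coverage[miss] <-
        100 * (hits$qend[miss] - hits$qstart[miss] + 1) / ql
    }
  }
  bad <- which(hits$evalue < 0 | hits$percent_identity < 0 |
                 hits$percent_identity > 100)
  if (length(bad))
    stop_parse(path, sf$lineno[bad[1]], "evalue or percent identity out of range")
  hits$source_track <- source_track
  hits
}

#' Write tabular alignment hits
#'
#' Emits the 12 mandatory columns, plus query coverage (column 13) and
#' subject description (column 14) when coverage is known for every row.
#'
#' @param hits Data frame as returned by [read_tabular_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_tabular_hits <- function(hits, path) {
  if (nrow(hits) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  base <- cbind(hits$query_id, hits$subject_id,
                fmt_g(hits$percent_identity), fmt_g(hits$alignment_length),
                fmt_g(hits$mismatches), fmt_g(hits$gap_opens),
                fmt_g(hits$qstart), fmt_g(hits$qend),
                fmt_g(hits$sstart), fmt_g(hits$send),
                fmt_g(hits$evalue), fmt_g(hits$bitscore))
  if (nrow(hits) > 0 && !anyNA(hits$query_coverage)) {
    base <- cbind(base, fmt_g(hits$query_coverage), hits$subject_description)
  }
  writeLines(apply(base, 1, paste, collapse = "\t"), path)
  invisible(path)
}

strip_version <- function(acc) sub("\\.\\d+$", "", acc)

#' Read a HMMER3 per-domain table (domtblout dialect)
#'
#' Whitespace-delimited with \code{#} comment lines; the description field
#' is everything after the 22 fixed columns.  The model accession has any
#' version suffix (\code{.N}) stripped; when the accession column is
#' \code{"-"} the model name is used as accession surrogate.  The
#' independent (i-)E-value is used as the per-domain E-value.
#'
#' @param path Path to a domtblout file.
#' @return Data frame with columns \code{query_id}, \code{model_accession},
#'   \code{model_name}, \code{domain_evalue}, \code{score},
#'   \code{env_start}, \code{env_end}.
#' @export
read_domain_table <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  sf <- split_fields(path, sep = "[[:space:]]+")
  empty <- data.frame(query_id = character(), model_accession = character(),
                      model_name = character(), domain_evalue = numeric(),
                      score = numeric(), env_start = integer(),
                      env_end = integer(), stringsAsFactors = FALSE)
  if (length(sf$fields) == 0L) return(empty)
  rows <- vector("list", length(sf$fields))
  for (i in seq_along(sf$fields)) {
    f <- sf$fields[[i]]
    ln <- sf$lineno[i]
    if (length(f) < 22L)
      stop_parse(path, ln, sprintf("expected >= 22 whitespace-delimited columns, found %d", length(f)))
    ieval <- as_num_or_stop(f[13], path, ln, "i-Evalue")
    score <- as_num_or_stop(f[14], path, ln, "domain score")
    env <- as_num_or_stop(f[20:21], path, ln, "env coordinate")
    if (ieval < 0) stop_parse(path, ln, "negative i-Evalue")
    if (env[1] < 1 || env[2] < env[1])
      stop_parse(path, ln, "invalid env coordinates")
    acc <- if (f[2] == "-") f[1] else strip_version(f[2])
    rows[[i]] <- data.frame(query_id = f[4], model_accession = acc,
                            model_name = f[1], domain_evalue = ieval,
                            score = score, env_start = as.integer(env[1]),
                            env_end = as.integer(env[2]),
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Write a HMMER3-style per-domain table
#'
#' @param domains Data frame as returned by [read_domain_table()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_domain_table <- function(domains, path) {
  hdr <- "# target name accession tlen query name accession qlen E-value score bias # of c-Evalue i-Evalue score bias hmm_from hmm_to ali_from ali_to env_from env_to acc description"
  lines <- character(nrow(domains))
  for (i in seq_len(nrow(domains))) {
    d <- domains[i, ]
    span <- d$env_end - d$env_start + 1L
    lines[i] <- paste(
      d$model_name, d$model_accession, span, d$query_id, "-",
      d$env_end + 10L, fmt_g(d$domain_evalue), fmt_g(d$score), "0.0",
      1, 1, fmt_g(d$domain_evalue), fmt_g(d$domain_evalue), fmt_g(d$score),
      "0.0", 1, span, d$env_start, d$env_end, d$env_start, d$env_end,
      "0.95", "-")
  }
  writeLines(c(hdr, lines), path)
  invisible(path)
}

COG_PATTERN <- "COG\\d{4}"

#' Read COG hits from a tabular alignment file
#'
#' Same tabular dialect as [read_tabular_hits()]; the COG accession is
#' extracted from the subject field, either directly (\code{"COG0178"}) or
#' from any embedded token containing it
#' (\code{"gnl|CDD|223256 COG0178"}).  Lines with no extractable COG
#' accession are skipped with a warning.
#'
#' @param path Path to the tabular COG hit file.
#' @return Data frame with columns \code{query_id}, \code{cog_id},
#'   \code{evalue}, \code{bitscore}.
#' @export
read_cog_hits <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  sf <- split_fields(path)
  empty <- data.frame(query_id = character(), cog_id = character(),
                      evalue = numeric(), bitscore = numeric(),
                      stringsAsFactors = FALSE)
  if (length(sf$fields) == 0L) return(empty)
  rows <- list()
  for (i in seq_along(sf$fields)) {
    f <- sf$fields[[i]]
    ln <- sf$lineno[i]
    if (length(f) < 12L)
      stop_parse(path, ln, sprintf("expected >= 12 tab-separated columns, found %d", length(f)))
    m <- regmatches(f[2], regexpr(COG_PATTERN, f[2]))
    if (length(m) == 0L) {
      warning(sprintf("%s:%d: no COG accession in subject '%s'; line skipped",
                      path, ln, f[2]), call. = FALSE)
      next
    }
    rows[[length(rows) + 1L]] <- data.frame(
      query_id = f[1], cog_id = m,
      evalue = as_num_or_stop(f[11], path, ln, "evalue"),
      bitscore = as_num_or_stop(f[12], path, ln, "bitscore"),
      stringsAsFactors = FALSE)
  }
  if (length(rows) == 0L) return(empty)
  do.call(rbind, rows)
}

#' Write COG hits as a 12-column tabular file
#'
#' @param cogs Data frame as returned by [read_cog_hits()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_cog_hits <- function(cogs, path) {
  lines <- sprintf("%s\t%s\t30\t100\t70\t0\t1\t100\t1\t100\t%s\t%s",
                   cogs$query_id, cogs$cog_id,
                   fmt_g(cogs$evalue), fmt_g(cogs$bitscore))
  writeLines(lines, path)
  invisible(path)
}

parse_topology_string <- function(topo) {
  m <- gregexpr("(\\d+)-(\\d+)", topo)[[1]]
  if (m[1] == -1L) return(matrix(integer(), ncol = 2,
                                 dimnames = list(NULL, c("start", "end"))))
  spans <- regmatches(topo, gregexpr("(\\d+)-(\\d+)", topo))[[1]]
  parts <- do.call(rbind, strsplit(spans, "-", fixed = TRUE))
  matrix(as.integer(parts), ncol = 2, dimnames = list(NULL, c("start", "end")))
}

#' Read a TMHMM "short" one-line-per-protein summary
#'
#' Lines of the form
#' \code{"<id> len=<n> ExpAA=<x> First60=<y> PredHel=<k> Topology=<topo>"}.
#' The helix count is \code{PredHel}; segments are parsed from the
#' topology string (\code{"i12-34o56-78i"} gives intervals 12--34 and
#' 56--78, 1-based inclusive).
#'
#' @param path Path to the TMHMM short-format file.
#' @return Named list of [tm_topology()] objects, keyed by protein id.
#' @export
read_tm_short <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  sf <- split_fields(path, sep = "[[:space:]]+")
  out <- list()
  for (i in seq_along(sf$fields)) {
    f <- sf$fields[[i]]
    ln <- sf$lineno[i]
    id <- f[1]
    line <- paste(f, collapse = " ")
    ph <- regmatches(line, regexpr("PredHel=(\\d+)", line))
    if (length(ph) == 0L)
      stop_parse(path, ln, "missing PredHel field")
    k <- as.integer(sub("PredHel=", "", ph))
    topo <- regmatches(line, regexpr("Topology=(\\S*)", line))
    segs <- if (length(topo)) parse_topology_string(sub("Topology=", "", topo))
            else matrix(integer(), ncol = 2)
    if (nrow(segs) != k)
      stop_parse(path, ln, sprintf("PredHel=%d but topology string has %d segments", k, nrow(segs)))
    out[[id]] <- tm_topology(segs)
  }
  out
}

#' Write topologies in TMHMM short format
#'
#' @param topologies Named list of [tm_topology()] objects.
#' @param path Output path.
#' @param lengths Optional named integer vector of sequence lengths.
#' @return Invisibly, `path`.
#' @export
write_tm_short <- function(topologies, path, lengths = NULL) {
  lines <- vapply(names(topologies), function(id) {
    tp <- topologies[[id]]
    segs <- tp$segments
    topo <- "o"
    if (nrow(segs) > 0) {
      sides <- rep(c("i", "o"), length.out = nrow(segs) + 1L)
      topo <- paste0(paste0(sides[seq_len(nrow(segs))],
                            segs[, 1], "-", segs[, 2], collapse = ""),
                     sides[nrow(segs) + 1L])
    }
    len <- if (!is.null(lengths) && id %in% names(lengths)) lengths[[id]]
           else if (nrow(segs)) max(segs[, 2]) + 10L else 300L
    exp_aa <- sum(segs[, 2] - segs[, 1] + 1L)
    sprintf("%s\tlen=%d\tExpAA=%.2f\tFirst60=%.2f\tPredHel=%d\tTopology=%s",
            id, len, as.numeric(exp_aa), 0, tp$tm_count, topo)
  }, character(1))
  writeLines(unname(lines), path)
  invisible(path)
}

ANNOTATION_COLUMNS <- c("protein_id", "status", "family", "subfamily",
                        "tc_number", "substrate_class", "substrate",
                        "confidence", "tm_count", "evidence_summary",
                        "excluded_by")

#' Write annotations as a tab-delimited table
#'
#' Fixed header (protein_id, status, family, subfamily, tc_number,
#' substrate_class, substrate, confidence, tm_count, evidence_summary,
#' excluded_by); absent values are written as \code{"-"}; rows keep input
#' order.  Optional provenance is written as leading \code{#} comment
#' lines.
#'
#' @param annotations Annotation data frame (see [annotate_proteome()]).
#' @param path Output path.
#' @param provenance Optional named character vector recorded as
#'   \code{# key: value} header lines.
#' @return Invisibly, `path`.
#' @export
write_annotations <- function(annotations, path, provenance = NULL) {
  con <- file(path, "wb")  # binary mode: LF endings on every platform
  on.exit(close(con))
  if (!is.null(provenance))
    writeLines(sprintf("# %s: %s", names(provenance), provenance), con)
  writeLines(paste(ANNOTATION_COLUMNS, collapse = "\t"), con)
  if (nrow(annotations) > 0) {
    chr <- annotations[, ANNOTATION_COLUMNS]
    chr$tm_count <- as.character(chr$tm_count)
    cells <- vapply(ANNOTATION_COLUMNS, function(cn) na_dash(chr[[cn]]),
                    character(nrow(annotations)))
    if (nrow(annotations) == 1L) cells <- matrix(cells, nrow = 1)
    writeLines(apply(cells, 1, paste, collapse = "\t"), con)
  }
  invisible(path)
}

#' Read an annotation table written by [write_annotations()]
#'
#' @param path Path to the annotation TSV.
#' @return Annotation data frame; \code{"-"} cells become \code{NA}.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  df <- utils::read.delim(path, comment.char = "#",
                          colClasses = "character", check.names = FALSE)
  if (!identical(names(df), ANNOTATION_COLUMNS))
    stop_parse(path, 1, "unexpected annotation header")
  for (cn in setdiff(ANNOTATION_COLUMNS, c("protein_id", "status")))
    df[[cn]] <- dash_na(df[[cn]])
  df$tm_count <- as.integer(df$tm_count)
  df
}

TC_PATTERN <- "^\\d+\\.[A-Za-z]\\.\\d+(\\.\\d+(\\.\\d+)?)?$"

#' Read the curated reference metadata table
#'
#' TSV with header \code{accession, family, subfamily, tc_number,
#' substrate_class, substrate}; \code{"-"} marks absent values.  TC
#' numbers, when present, must match the TC-system pattern
#' (e.g. \code{3.A.1.1.1}, \code{2.A.63}).
#'
#' @param path Path to the reference TSV.
#' @return Data frame keyed by unique \code{accession}.
#' @export
read_reference_table <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  need <- c("accession", "family", "subfamily", "tc_number",
            "substrate_class", "substrate")
  if (!all(need %in% names(df)))
    stop_parse(path, 1, "reference table missing required columns")
  df <- df[, need]
  for (cn in need[-1]) df[[cn]] <- dash_na(df[[cn]])
  if (anyDuplicated(df$accession))
    transannot_error(sprintf("duplicate reference accession: '%s'",
                             df$accession[duplicated(df$accession)][1]),
                     "transannot_parse_error")
  bad <- !is.na(df$tc_number) & !grepl(TC_PATTERN, df$tc_number)
  if (any(bad))
    transannot_error(sprintf("malformed TC number: '%s'", df$tc_number[bad][1]),
                     "transannot_parse_error")
  df
}

#' Write a reference metadata table
#' @param reference Reference data frame (see [read_reference_table()]).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_reference_table <- function(reference, path) {
  out <- reference
  for (cn in setdiff(names(out), "accession")) out[[cn]] <- na_dash(out[[cn]])
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a gold-standard annotation table
#'
#' TSV with header \code{protein_id, substrate}; every listed id is a
#' manually confirmed transporter; \code{"-"} marks an unknown substrate.
#'
#' @param path Path to the gold-standard TSV.
#' @return Data frame with columns \code{protein_id}, \code{substrate}.
#' @export
read_gold_standard <- function(path) {
  if (!file.exists(path)) stop_missing(path)
  df <- utils::read.delim(path, colClasses = "character", check.names = FALSE)
  if (!all(c("protein_id", "substrate") %in% names(df)))
    stop_parse(path, 1, "gold standard missing required columns")
  if (anyDuplicated(df$protein_id))
    transannot_error("duplicate protein_id in gold standard",
                     "transannot_parse_error")
  df$substrate <- dash_na(df$substrate)
  df[, c("protein_id", "substrate")]
}

#' Write a gold-standard annotation table
#' @param gold Data frame with columns \code{protein_id}, \code{substrate}.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_gold_standard <- function(gold, path) {
  out <- data.frame(protein_id = gold$protein_id,
                    substrate = na_dash(gold$substrate))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
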