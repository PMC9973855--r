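# Benchmark arithmetic: concordance between a predicted transporter set
# and a manual gold standard.  False positives are predicted-only ids
# (rate over the predicted count); false negatives are manual-only ids
# (rate over the manual count) — the only denominators consistent with
# rates like 7/364 ~ 2% and 1/358 ~ 0.3%.

#' Compare a predicted transporter set with a gold standard
#'
#' @param predicted_ids Character vector of predicted transporter ids
#'   (duplicates ignored).
#' @param gold Gold standard: data frame with a \code{protein_id} column
#'   (see [read_gold_standard()]) or a plain character vector of ids.
#' @param substrate_corrections Optional pre-computed correction count to
#'   embed in the report.
#' @return Object of class \code{transannot_eval} with fields
#'   \code{n_predicted}, \code{n_manual}, \code{n_confirmed}, \code{fp},
#'   \code{fn}, \code{fp_pct}, \code{fn_pct},
#'   \code{substrate_corrections}.
#' @examples
#' # a benchmark where 357 of 364 predictions are manually confirmed
#' compare_sets(sprintf("p%03d", 1:364),
#'              sprintf("p%03d", c(1:357, 900)))
#' @export
compare_sets <- function(predicted_ids, gold,
                         substrate_corrections = NA_integer_) {
  gold_ids <- if (is.data.frame(gold)) gold$protein_id else gold
  predicted_ids <- unique(as.character(predicted_ids))
  gold_ids <- unique(as.character(gold_ids))
  n_pred <- length(predicted_ids)
  n_man <- length(gold_ids)
  n_conf <- length(intersect(predicted_ids, gold_ids))
  fp <- n_pred - n_conf
  fn <- n_man - n_conf
  structure(list(
    n_predicted = n_pred, n_manual = n_man, n_confirmed = n_conf,
    fp = fp, fn = fn,
    fp_pct = if (n_pred == 0L) 0 else 100 * fp / n_pred,
    fn_pct = if (n_man == 0L) 0 else 100 * fn / n_man,
    substrate_corrections = substrate_corrections),
    class = "transannot_eval")
}

norm_substrate <- function(x) tolower(trimws(x))

#' Count substrate-prediction corrections
#'
#' Among confirmed proteins (predicted and in the gold standard), counts
#' those where a specific substrate was predicted and differs from the
#' gold substrate after normalization (case-fold, trim).  Abstentions are
#' never corrections, nor are confirmed proteins without a gold
#' substrate.
#'
#' @param predictions Annotation data frame (see [annotate_proteome()]).
#' @param gold Gold standard data frame with \code{protein_id} and
#'   \code{substrate}.
#' @return Integer count.
#' @export
substrate_corrections <- function(predictions, gold) {
  ret <- predictions[predictions$status == "retained", , drop = FALSE]
  m <- merge(ret[, c("protein_id", "substrate")], gold, by = "protein_id",
             suffixes = c("_pred", "_gold"))
  sum(!is.na(m$substrate_pred) & !is.na(m$substrate_gold) &
        norm_substrate(m$substrate_pred) != norm_substrate(m$substrate_gold))
}

#' Evaluate annotations against a gold standard
#'
#' Convenience wrapper: the retained set is compared with the gold ids
#' and substrate corrections are counted among confirmed proteins.
#'
#' @param predictions Annotation data frame (see [annotate_proteome()]).
#' @param gold Gold standard data frame.
#' @return A \code{transannot_eval} report.
#' @export
evaluate_annotations <- function(predictions, gold) {
  retained <- predictions$protein_id[predictions$status == "retained"]
  compare_sets(retained, gold,
               substrate_corrections = substrate_corrections(predictions, gold))
}

#' Render an evaluation report
#'
#' False-positive rate is printed to the nearest integer percent and the
#' false-negative rate to one decimal.
#'
#' @param report A \code{transannot_eval} object.
#' @return Character vector of report lines.
#' @export
format_report <- function(report) {
  c(sprintf("Predicted transporters   %d", report$n_predicted),
    sprintf("Manual annotation        %d", report$n_manual),
    sprintf("Confirmed                %d", report$n_confirmed),
    sprintf("False positives          %d (%.0f%%)", report$fp, report$fp_pct),
    sprintf("False negatives          %d (%.1f%%)", report$fn, report$fn_pct),
    if (!is.na(report$substrate_corrections))
      sprintf("Substrate corrections    %d", report$substrate_corrections))
}

#' @export
print.transannot_eval <- function(x, ...) {
  writeLines(format_report(x))
  invisible(x)
}

#' @export
as.data.frame.transannot_eval <- function(x, ...) {
  data.frame(n_predicted = x$n_predicted, n_manual = x$n_manual,
             n_confirmed = x$n_confirmed, fp = x$fp, fn = x$fn,
             fp_pct = x$fp_pct, fn_pct = x$fn_pct,
             substrate_corrections = x$substrate_corrections)
}

#' Write an evaluation report as TSV
#' @param report A \code{transannot_eval} object.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_report_tsv <- function(report, path) {
  utils::write.table(as.data.frame(report), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
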