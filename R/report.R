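#' Human-readable summary report of a pipeline run
#'
#' Formats the run's result tables as plain text: per-round descriptor
#' means and SDs (with an overall column), the descriptor-ADG rank
#' correlation table, the quartile-group comparison, and the final
#' model's coefficient table. Regenerating the report from the same
#' artifacts gives identical text.
#'
#' @param run a `broileract_run` object from [run_pipeline()].
#' @param file optional path; when given the report is also written
#'   there.
#' @return character vector of report lines (invisibly when `file` is
#'   given).
#' @export
make_report <- function(run, file = NULL) {
  stopifnot(inherits(run, "broileract_run"))
  m <- run$merged
  desc_cols <- c(md = "Mean distance (m/h)", skew = "Skewness",
                 rmse = "RMSE (m/h)", ac = "Autocorrelation",
                 ent = "Entropy")
  rounds <- sort(unique(m$round_id))
  fmt <- function(x) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return("NA")
    sprintf("%.2f (%.2f)", mean(x), if (length(x) > 1) sd(x) else 0)
  }

  lines <- c("Activity descriptors and average daily gain", "")
  header <- sprintf("%-22s %-16s %s", "Descriptor", "Overall",
                    paste(sprintf("%-16s", paste0("Round ", rounds)),
                          collapse = " "))
  lines <- c(lines, "Per-round descriptor means (SD):", header)
  for (d in names(desc_cols)) {
    by_round <- vapply(rounds, function(r) fmt(m[[d]][m$round_id == r]),
                       character(1))
    lines <- c(lines, sprintf("%-22s %-16s %s", desc_cols[d], fmt(m[[d]]),
                              paste(sprintf("%-16s", by_round),
                                    collapse = " ")))
  }
  lines <- c(lines, sprintf("%-22s %-16s %s", "ADG (g/day)", fmt(m$adg),
                            paste(sprintf("%-16s",
                                          vapply(rounds, function(r)
                                            fmt(m$adg[m$round_id == r]),
                                            character(1))),
                                  collapse = " ")))

  lines <- c(lines, "", "Rank correlations with ADG (Kendall tau-b, bootstrap 95% CI):",
             sprintf("%-12s %8s %18s %8s %8s %6s",
                     "Descriptor", "tau", "95% CI", "z", "P", "n"))
  co <- run$correlations
  for (i in seq_len(nrow(co))) {
    lines <- c(lines, sprintf("%-12s %8.3f %18s %8.3f %8.3f %6d",
                              co$descriptor[i], co$tau[i],
                              sprintf("[%.3f, %.3f]", co$ci_lower[i],
                                      co$ci_upper[i]),
                              co$z[i], co$p[i], co$n[i]))
  }

  lines <- c(lines, "", "Low vs high ADG quartile groups (Wilcoxon rank sum):")
  qc <- run$quartile_comparison
  if (all(is.na(qc$W))) {
    lines <- c(lines, "  [warning] degenerate or empty quartile groups; comparison skipped")
  } else {
    lines <- c(lines, sprintf("%-12s %10s %10s %8s %8s",
                              "Descriptor", "mean(low)", "mean(high)", "W", "P"))
    for (i in seq_len(nrow(qc))) {
      if (is.na(qc$W[i])) next
      lines <- c(lines, sprintf("%-12s %10.3f %10.3f %8.1f %8.3f",
                                qc$descriptor[i], qc$mean_low[i],
                                qc$mean_high[i], qc$W[i], qc$p[i]))
    }
  }

  lines <- c(lines, "", "Linear model of ADG (sum-to-zero round contrasts):")
  if (is.null(run$model)) {
    lines <- c(lines, "  [warning] model could not be fitted")
  } else {
    lines <- c(lines, utils::capture.output(print(run$model)))
  }

  if (!is.null(file)) {
    writeLines(lines, file)
    return(invisible(lines))
  }
  lines
}
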