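#' Full group-comparison report from a per-animal summary table
#'
#' Recomputes every group-level comparison of the packaged study from a
#' per-animal summary table (the packaged fixture by default, or the
#' summaries of a simulated cohort): young-versus-aged Mann-Whitney tests
#' for training days, PD and PDR sessions/trials to criterion, both
#' perseveration measures and the latency controls, the within-young sex
#' contrasts, and the Spearman correlation between individual PD and PDR
#' trials to criterion.
#'
#' Exclusions follow the study design: subjects flagged by the
#' first-PD-session stimulus-bias screen are excluded from the PD
#' comparisons and from the PD-PDR correlation, but retained for training,
#' PDR and perseveration comparisons. Sex contrasts within the aged group
#' are computed but marked underpowered. No multiple-testing correction is
#' applied (none is applied in the study this mirrors); p-values are
#' two-sided and exact whenever `n_a * n_b <= exact_limit`.
#'
#' @param summaries per-animal summary data frame with the fixture's
#'   columns (see [load_table1()]); `age_group` and `bias_flag` are derived
#'   when absent.
#' @param exact_limit passed to [mann_whitney_u()].
#' @return A list of class `pdr_report`: `comparisons` (data frame with
#'   medians, ranges, U, p, method, note), `correlation`
#'   (a [spearman_rho()] result), `excluded` (bias-flagged subject ids) and
#'   `n` (group sizes).
#' @examples
#' rep <- replicate_paper_report(load_table1())
#' subset(rep$comparisons, measure == "pdr_trials")$U # 54.5
#' @export
replicate_paper_report <- function(summaries = load_table1(),
                                   exact_limit = 400L) {
  req <- c("subject_id", "sex", "age_years", "training_days", "pd_sessions",
           "pd_trials", "pd_response_latency", "pd_reward_latency",
           "pdr_sessions", "pdr_trials", "pdr_response_latency",
           "pdr_reward_latency", "persev_errors_binomial",
           "persev_errors_50", "trials_to_50")
  missing_cols <- setdiff(req, names(summaries))
  if (length(missing_cols)) {
    stop("summary table lacks columns: ", paste(missing_cols, collapse = ", "))
  }
  df <- summaries
  if (is.null(df$age_group)) {
    df$age_group <- ifelse(df$age_years < 5, "young", "aged")
  }
  if (is.null(df$bias_flag)) {
    df$bias_flag <- if (!is.null(df$bias_image)) !is.na(df$bias_image) else FALSE
  }
  unb <- df[!df$bias_flag, , drop = FALSE]

  rows <- list()
  cmp <- function(measure, data, split_var, a, b, subset_label, note = "") {
    va <- data[[measure]][data[[split_var]] == a]
    vb <- data[[measure]][data[[split_var]] == b]
    va <- va[!is.na(va)]; vb <- vb[!is.na(vb)]
    if (length(va) == 0L || length(vb) == 0L) return(invisible(NULL))
    m <- mann_whitney_u(va, vb, exact_limit = exact_limit,
                        measure = measure, group_a = a, group_b = b)
    rows[[length(rows) + 1L]] <<- data.frame(
      measure = measure, subset = subset_label, group_a = a, group_b = b,
      n_a = m$n_a, n_b = m$n_b, median_a = m$median_a, median_b = m$median_b,
      min_a = m$range_a[1], max_a = m$range_a[2],
      min_b = m$range_b[1], max_b = m$range_b[2],
      U = m$U, p = m$p, method = m$method, note = note,
      stringsAsFactors = FALSE)
  }

  for (msr in c("pd_sessions", "pd_trials", "pd_response_latency",
                "pd_reward_latency")) {
    cmp(msr, unb, "age_group", "young", "aged", "unbiased")
  }
  for (msr in c("training_days", "pdr_sessions", "pdr_trials",
                "pdr_response_latency", "pdr_reward_latency",
                "persev_errors_binomial", "persev_errors_50",
                "trials_to_50")) {
    cmp(msr, df, "age_group", "young", "aged", "all")
  }
  yu <- unb[unb$age_group == "young", , drop = FALSE]
  for (msr in c("pd_trials", "pd_response_latency", "pd_reward_latency")) {
    cmp(msr, yu, "sex", "m", "f", "young unbiased")
  }
  ya <- df[df$age_group == "young", , drop = FALSE]
  for (msr in c("pdr_trials", "pdr_response_latency", "pdr_reward_latency",
                "persev_errors_binomial", "persev_errors_50",
                "trials_to_50")) {
    cmp(msr, ya, "sex", "m", "f", "young")
  }
  ag <- df[df$age_group == "aged", , drop = FALSE]
  cmp("pdr_trials", ag, "sex", "m", "f", "aged",
      note = "underpowered: small aged-male sample")

  corr <- spearman_rho(unb$pd_trials, unb$pdr_trials)

  structure(list(
    comparisons = do.call(rbind, rows),
    correlation = corr,
    excluded = df$subject_id[df$bias_flag],
    n = c(young = sum(df$age_group == "young"),
          aged = sum(df$age_group == "aged")),
    note = "two-sided p-values, no multiple-testing correction"
  ), class = "pdr_report")
}

#' @export
print.pdr_report <- function(x, ...) {
  cat("Group-comparison report:", x$n[["young"]], "young /",
      x$n[["aged"]], "aged;", length(x$excluded),
      "subjects excluded from PD comparisons (stimulus bias):",
      paste(x$excluded, collapse = ", "), "\n\n")
  cc <- x$comparisons
  for (i in seq_len(nrow(cc))) {
    cat(sprintf(
      "%-24s [%s] %s (n=%d, med %.5g) vs %s (n=%d, med %.5g): U = %g, p = %.4g%s\n",
      cc$measure[i], cc$subset[i], cc$group_a[i], cc$n_a[i], cc$median_a[i],
      cc$group_b[i], cc$n_b[i], cc$median_b[i], cc$U[i], cc$p[i],
      if (nzchar(cc$note[i])) paste0("  (", cc$note[i], ")") else ""))
  }
  cat(sprintf(
    "\nPD vs PDR trials to criterion: Spearman rho = %.2f (n = %d, p = %.2g)\n",
    x$correlation$rho, x$correlation$n, x$correlation$p))
  cat(x$note, "\n")
  invisible(x)
}

#' Write a group-comparison report as JSON
#'
#' @param report a `pdr_report` from [replicate_paper_report()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_report_json <- function(report, path) {
  stopifnot(inherits(report, "pdr_report"))
  out <- list(
    n = as.list(report$n),
    excluded = report$excluded,
    comparisons = report$comparisons,
    correlation = list(n = report$correlation$n, rho = report$correlation$rho,
                       p = report$correlation$p),
    note = report$note
  )
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "rows")
  invisible(path)
}
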