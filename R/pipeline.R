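# End-to-end study pipeline: score a cohort of scenario records on the
# deviation checklist and the rubric, compute CPR metrics, and run the
# stratified two-group comparison (item frequencies with exact Fisher tests
# and proportion differences; times and CPR metrics with Wilcoxon /
# Hodges-Lehmann; optional dual-rater concordance). The output mirrors the
# three descriptive/comparative tables of a simulation study report.

#' Times to individual resuscitation tasks for one record
#'
#' First-occurrence times (seconds from scenario start) of the eight timed
#' tasks tracked by the pipeline; `NA` when the task never happened.
#'
#' @param record A [scenario_record()].
#' @return Named numeric vector: `pulse_check`, `start_cc`, `start_ekg`,
#'   `call_help`, `bag_mask`, `establish_iv_io`, `adrenaline`,
#'   `repeat_adrenaline`.
#' @export
task_times <- function(record) {
  ev <- record$events
  f <- function(a) { t <- ev$t[ev$action == a]; if (length(t)) min(t) else NA_real_ }
  adm <- sort(ev$t[ev$action == "administer_adrenaline"])
  c(pulse_check = f("pulse_check"),
    start_cc = f("start_compressions"),
    start_ekg = f("start_ekg_monitor"),
    call_help = f("call_help"),
    bag_mask = f("start_bag_mask"),
    establish_iv_io = f("establish_iv_io"),
    adrenaline = if (length(adm) >= 1) adm[1] else NA_real_,
    repeat_adrenaline = if (length(adm) >= 2) adm[2] else NA_real_)
}

.mdn_cell <- function(x) {
  x <- x[!is.na(x)]
  if (!length(x)) return(list(n = 0L, median = NA_real_, q1 = NA_real_, q3 = NA_real_))
  q <- median_iqr(x)
  list(n = length(x), median = unname(q["median"]),
       q1 = unname(q["q1"]), q3 = unname(q["q3"]))
}

# one quantitative comparison row: medians/IQRs overall and per group plus
# HL shift (aid - no_aid) and rank-sum p when both groups are comparable
.quant_row <- function(variable, x_all, x_no, x_aid, compare) {
  a <- .mdn_cell(x_all); n0 <- .mdn_cell(x_no); n1 <- .mdn_cell(x_aid)
  row <- data.frame(variable = variable,
                    n = a$n, median = a$median, q1 = a$q1, q3 = a$q3,
                    n_no_aid = n0$n, median_no_aid = n0$median,
                    q1_no_aid = n0$q1, q3_no_aid = n0$q3,
                    n_aid = n1$n, median_aid = n1$median,
                    q1_aid = n1$q1, q3_aid = n1$q3,
                    hl_diff = NA_real_, hl_lo = NA_real_, hl_hi = NA_real_,
                    p_value = NA_real_)
  x_no <- x_no[!is.na(x_no)]; x_aid <- x_aid[!is.na(x_aid)]
  if (compare && length(x_no) >= 2 && length(x_aid) >= 2) {
    hl <- hodges_lehmann(x_no, x_aid)
    row$hl_diff <- hl$estimate; row$hl_lo <- hl$ci_low; row$hl_hi <- hl$ci_high
    row$p_value <- wilcoxon_rank_sum(x_no, x_aid)$p_value
  }
  row
}

#' Run the stratified study analysis on a cohort
#'
#' Scores every record with [score_team()] and [score_cpt()], computes
#' [compute_metrics()] where a compression stream and recognition anchor
#' exist (teams without compressions still contribute checklist scores),
#' and assembles the three report tables: per-item frequencies with group
#' difference and exact Fisher p (the checklist-item table), times to tasks
#' and CPR quality with Hodges-Lehmann shifts and rank-sum p-values, and
#' overall score descriptives. Group comparison columns are left `NA`, with
#' a warning, when either group has fewer than two teams.
#'
#' @param records List of [scenario_record()]s with unique `team_id`s.
#' @param rubric Rubric for the performance score; default
#'   [default_cpt_rubric()].
#' @param raters Optional list of two equal-length numeric vectors (paired
#'   per-team totals from two raters) for the concordance analysis.
#' @param n_resamples Bootstrap resamples for the CCC CI, default 2000.
#' @param seed Seed for the bootstrap, default 1.
#' @return Object of class `cohort_report`: list with `descriptives`,
#'   `item_table`, `time_table`, `cpr_table`, `cpr_flag_table`,
#'   `agreement` (NULL without rater data) and `meta`.
#' @export
run_study <- function(records, rubric = default_cpt_rubric(), raters = NULL,
                      n_resamples = 2000, seed = 1) {
  stopifnot(is.list(records), length(records) >= 1,
            all(vapply(records, inherits, logical(1), "scenario_record")))
  ids <- vapply(records, `[[`, character(1), "team_id")
  if (anyDuplicated(ids))
    stop("duplicate team_id(s): ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  grp <- vapply(records, `[[`, character(1), "group")
  compare <- min(table(factor(grp, levels = c("aid_not_used", "aid_used")))) >= 2
  if (!compare)
    warning("fewer than two teams in a group: descriptives only, no group comparison")

  cdev <- lapply(records, score_team)
  cpt <- lapply(records, score_cpt, rubric = rubric)
  cdev_tot <- vapply(cdev, `[[`, numeric(1), "total")
  cpt_tot <- vapply(cpt, `[[`, numeric(1), "total")
  is_aid <- grp == "aid_used"

  metrics <- lapply(records, function(r) {
    if (!nrow(r$compressions) || is.na(recognition_time(r))) return(NULL)
    compute_metrics(r)
  })

  descriptives <- rbind(
    .quant_row("cdev15plus_total", cdev_tot, cdev_tot[!is_aid],
               cdev_tot[is_aid], compare),
    .quant_row("cpt_total", cpt_tot, cpt_tot[!is_aid], cpt_tot[is_aid],
               compare))

  # checklist-item table --------------------------------------------------
  devm <- vapply(cdev, function(s) s$items$deviation, integer(15))
  corr <- 1L - devm                      # 15 x n matrix of correct indicators
  item_table <- cdev15_items()
  n <- length(records); n0 <- sum(!is_aid); n1 <- sum(is_aid)
  item_table$n_correct <- rowSums(corr)
  item_table$pct_correct <- 100 * item_table$n_correct / n
  item_table$pct_deviation <- 100 - item_table$pct_correct
  item_table$n_correct_no_aid <- rowSums(corr[, !is_aid, drop = FALSE])
  item_table$pct_correct_no_aid <- 100 * item_table$n_correct_no_aid / max(n0, 1)
  item_table$n_correct_aid <- rowSums(corr[, is_aid, drop = FALSE])
  item_table$pct_correct_aid <- 100 * item_table$n_correct_aid / max(n1, 1)
  item_table$diff_pct <- NA_real_
  item_table$diff_lo <- NA_real_
  item_table$diff_hi <- NA_real_
  item_table$fisher_p <- NA_real_
  if (compare) {
    for (i in 1:15) {
      k0 <- item_table$n_correct_no_aid[i]; k1 <- item_table$n_correct_aid[i]
      pd <- proportion_difference(k0, n0, k1, n1)
      item_table$diff_pct[i] <- pd$estimate
      item_table$diff_lo[i] <- pd$ci_low
      item_table$diff_hi[i] <- pd$ci_high
      tab <- matrix(c(k0, n0 - k0, k1, n1 - k1), nrow = 2, byrow = TRUE)
      item_table$fisher_p[i] <- fisher_exact(tab)$p_value
    }
  }

  # time-to-task table -----------------------------------------------------
  tmat <- t(vapply(records, task_times, numeric(8)))
  time_table <- do.call(rbind, lapply(colnames(tmat), function(task)
    .quant_row(task, tmat[, task], tmat[!is_aid, task], tmat[is_aid, task],
               compare)))

  # CPR quality tables ------------------------------------------------------
  mval <- function(field) vapply(metrics, function(m)
    if (is.null(m)) NA_real_ else m[[field]], numeric(1))
  rate <- mval("mean_rate_per_min"); depth <- mval("mean_depth_cm")
  recoil <- mval("recoil_complete_fraction"); nffv <- mval("no_flow_fraction")
  cpr_table <- rbind(
    .quant_row("mean_cc_rate_per_min", rate, rate[!is_aid], rate[is_aid], compare),
    .quant_row("mean_cc_depth_cm", depth, depth[!is_aid], depth[is_aid], compare),
    .quant_row("complete_recoil_pct", recoil, recoil[!is_aid], recoil[is_aid], compare),
    .quant_row("no_flow_fraction", nffv, nffv[!is_aid], nffv[is_aid], compare))

  fval <- function(flag) vapply(metrics, function(m)
    if (is.null(m)) NA else m$flags[[flag]], logical(1))
  flag_names <- c("rate_in_100_120", "depth_in_5_6cm", "recoil_gt_50pct",
                  "nff_lt_20pct")
  cpr_flag_table <- do.call(rbind, lapply(flag_names, function(fn) {
    v <- fval(fn)
    ok <- !is.na(v)
    row <- data.frame(flag = fn, n = sum(ok), n_true = sum(v[ok]),
                      pct_true = 100 * mean(v[ok]),
                      diff_pct = NA_real_, fisher_p = NA_real_)
    if (compare) {
      k0 <- sum(v[ok & !is_aid]); m0 <- sum(ok & !is_aid)
      k1 <- sum(v[ok & is_aid]); m1 <- sum(ok & is_aid)
      if (m0 >= 2 && m1 >= 2) {
        row$diff_pct <- proportion_difference(k0, m0, k1, m1)$estimate
        row$fisher_p <- fisher_exact(matrix(c(k0, m0 - k0, k1, m1 - k1),
                                            nrow = 2, byrow = TRUE))$p_value
      }
    }
    row
  }))

  agreement <- NULL
  if (!is.null(raters)) {
    stopifnot(is.list(raters), length(raters) == 2)
    ccc <- bootstrap_ci(function(x, y) lin_ccc(x, y)$estimate,
                        as.numeric(raters[[1]]), as.numeric(raters[[2]]),
                        n_resamples = n_resamples, seed = seed)
    agreement <- list(ccc = ccc$estimate, ci_low = ccc$ci_low,
                      ci_high = ccc$ci_high, method = ccc$method)
  }

  meta <- list(n_teams = n, n_no_aid = n0, n_aid = n1,
               thresholds = records[[1]]$config$thresholds,
               rubric = rubric$name, rubric_max_score = rubric$max_score,
               quantile_type = 2,
               proportion_ci_method = "wald",
               fisher_method = "full enumeration, point-probability rule",
               bootstrap = list(n_resamples = n_resamples, seed = seed),
               package_version = as.character(utils::packageVersion("resusdev")))

  structure(list(descriptives = descriptives, item_table = item_table,
                 time_table = time_table, cpr_table = cpr_table,
                 cpr_flag_table = cpr_flag_table, agreement = agreement,
                 meta = meta),
            class = "cohort_report")
}

#' @export
print.cohort_report <- function(x, ...) {
  d <- x$descriptives
  cat(sprintf("<cohort_report> %d teams (%d no-aid / %d aid)\n",
              x$meta$n_teams, x$meta$n_no_aid, x$meta$n_aid))
  for (i in seq_len(nrow(d)))
    cat(sprintf("  %s: median %g (IQR %g-%g)\n", d$variable[i], d$median[i],
                d$q1[i], d$q3[i]))
  if (!is.null(x$agreement))
    cat(sprintf("  rater agreement CCC %.3f (%.3f-%.3f)\n",
                x$agreement$ccc, x$agreement$ci_low, x$agreement$ci_high))
  invisible(x)
}

.md_table <- function(df, digits = 3) {
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(v) ifelse(is.na(v), "", format(round(v, digits))))
  df[] <- lapply(df, as.character)
  hdr <- paste0("| ", paste(names(df), collapse = " | "), " |")
  sep <- paste0("|", paste(rep("---", ncol(df)), collapse = "|"), "|")
  rows <- apply(df, 1, function(r) paste0("| ", paste(r, collapse = " | "), " |"))
  c(hdr, sep, rows)
}

#' Render a cohort report to files
#'
#' JSON output is lossless (full precision, reloadable with
#' [read_report()]); CSV writes one file per table; markdown renders the
#' three table analogues with percentages shown to one decimal and
#' p-values to three (full precision always lives in the JSON).
#'
#' @param report A [run_study()] result.
#' @param dir Output directory (created if missing).
#' @param format One of `"json"`, `"csv"`, `"markdown"`.
#' @return Character vector of the files written, invisibly.
#' @export
render_report <- function(report, dir, format = c("json", "csv", "markdown")) {
  stopifnot(inherits(report, "cohort_report"))
  format <- match.arg(format)
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  tables <- c("descriptives", "item_table", "time_table", "cpr_table",
              "cpr_flag_table")
  if (format == "json") {
    path <- file.path(dir, "report.json")
    jsonlite::write_json(unclass(report), path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", dataframe = "rows")
    files <- path
  } else if (format == "csv") {
    files <- vapply(tables, function(tb) {
      p <- file.path(dir, paste0(tb, ".csv"))
      utils::write.csv(report[[tb]], p, row.names = FALSE)
      p
    }, character(1))
  } else {
    lines <- c("# Cohort report", "",
               sprintf("%d teams (%d without / %d with the cognitive aid)",
                       report$meta$n_teams, report$meta$n_no_aid,
                       report$meta$n_aid), "",
               "## Score descriptives", "",
               .md_table(report$descriptives, 1), "",
               "## Checklist items (correct counts and group comparison)", "",
               .md_table(report$item_table[, c("item", "label", "n_correct",
                                               "pct_correct", "pct_deviation",
                                               "diff_pct", "fisher_p")], 3), "",
               "## Times to resuscitation tasks (s)", "",
               .md_table(report$time_table, 1), "",
               "## CPR quality", "",
               .md_table(report$cpr_table, 2), "",
               .md_table(report$cpr_flag_table, 3))
    if (!is.null(report$agreement))
      lines <- c(lines, "",
                 sprintf("Rater agreement: CCC %.3f (95%% CI %.3f to %.3f)",
                         report$agreement$ccc, report$agreement$ci_low,
                         report$agreement$ci_high))
    path <- file.path(dir, "report.md")
    writeLines(lines, path)
    files <- path
  }
  invisible(files)
}

#' Reload a JSON cohort report
#'
#' @param path Path to a `report.json` written by [render_report()].
#' @return A `cohort_report` (tables as data.frames).
#' @export
read_report <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  for (tb in c("descriptives", "item_table", "time_table", "cpr_table",
               "cpr_flag_table"))
    obj[[tb]] <- as.data.frame(obj[[tb]])
  structure(obj, class = "cohort_report")
}
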