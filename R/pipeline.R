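#' Study configuration
#'
#' Declares a full study run for [run_study()]: where the cohort comes
#' from (simulated with known ground truth, or ingested from a directory
#' of CSVs), which analysis blocks to run, and the statistical knobs.
#'
#' @param mode `"simulate"` or `"ingest"`.
#' @param cohort A [cohort_config()] (simulate mode).
#' @param path Cohort directory (ingest mode; layout of [write_cohort()]).
#' @param repeatability,pols_correlations,fasting Analysis toggles.
#' @param alpha Significance level used by normality gates and screen
#'   flags.
#' @param n_perm Permutations for the factorial ANOVA.
#' @param n_boot Bootstrap resamples for the ICC.
#' @param seed Master seed (mandatory in simulate mode).
#' @param outdir Output directory, or NULL to skip writing.
#' @return An object of class `study_config`.
#' @export
study_config <- function(mode = c("simulate", "ingest"),
                         cohort = cohort_config(), path = NULL,
                         repeatability = TRUE, pols_correlations = TRUE,
                         fasting = TRUE, alpha = 0.05,
                         n_perm = 10000, n_boot = 1000,
                         seed = NULL, outdir = NULL) {
  mode <- match.arg(mode)
  if (mode == "simulate" && is.null(seed))
    stop("simulate mode requires a seed", call. = FALSE)
  if (mode == "ingest" && is.null(path))
    stop("ingest mode requires a cohort path", call. = FALSE)
  structure(
    list(mode = mode, cohort = cohort, path = path,
         repeatability = isTRUE(repeatability),
         pols_correlations = isTRUE(pols_correlations),
         fasting = isTRUE(fasting), alpha = alpha,
         n_perm = n_perm, n_boot = n_boot, seed = seed, outdir = outdir),
    class = "study_config"
  )
}

row_or_null <- function(df) if (is.null(df) || nrow(df) == 0) NULL else df

cell_split <- function(df) {
  split(df, paste(df$sex, df$strain, sep = ":"), drop = TRUE)
}

#' Analyze a cohort
#'
#' Runs the full analysis battery on a cohort (simulated or ingested):
#' respirometry QC and routine metabolic rate, behavioral metrics and the
#' boldness index, then the report blocks — day-to-day repeatability
#' (Pearson + bootstrap ICC per sex), mass-consumption correlations per
#' sex-by-strain, the sex-by-strain permutation ANOVA on RMR, the
#' correlation screen (boldness index and each behavioral measure against
#' RMR per sex-by-strain), and the fasting comparisons appropriate to the
#' design (paired tests and feed-by-sex ANOVAs for a crossover;
#' fed-versus-unfed behavioral comparisons with Cohen's d for a
#' between-groups design).
#'
#' @param cohort A `cohort` from [generate_cohort()] or [read_cohort()].
#' @param alpha Significance level.
#' @param n_perm Permutations for factorial ANOVAs.
#' @param n_boot Bootstrap resamples for the ICC.
#' @param seed Seed for the stochastic procedures (permutation,
#'   bootstrap); analysis is deterministic given (cohort, seed).
#' @return An object of class `study_report`: list of tidy data-frame
#'   blocks plus run metadata (method, n after QC and exclusions named on
#'   every row).
#' @export
analyze_cohort <- function(cohort, alpha = 0.05, n_perm = 10000,
                           n_boot = 1000, seed = 1L) {
  stopifnot(inherits(cohort, "cohort"))
  seeds <- derive_seeds(seed, 4)

  resp <- compute_rmr(cohort$respirometry)
  meta_cols <- c("fish_id", "strain", "sex", "feed_state", "mass_g")
  resp <- merge(resp, cohort$metadata[, c("fish_id", "strain", "sex")],
                by = "fish_id", sort = TRUE)
  excluded <- resp[!resp$qc_pass, c("fish_id", "session_day", "qc_reason")]
  resp_ok <- resp[resp$qc_pass, , drop = FALSE]

  # day-1 fed measurements are the cross-sectional RMR of each fish
  fed1 <- resp_ok[resp_ok$session_day == 1, , drop = FALSE]
  if ("feed_state" %in% names(fed1) &&
      any(fed1$feed_state == "unfed")) {
    # crossover: take each fish's fed session whichever day it fell on
    fed1 <- resp_ok[resp_ok$feed_state == "fed", , drop = FALSE]
    fed1 <- fed1[!duplicated(fed1$fish_id), , drop = FALSE]
  }

  report <- list()
  two_days <- length(unique(resp_ok$session_day)) >= 2
  crossover <- "feed_state" %in% names(resp_ok) &&
    length(unique(resp_ok$feed_state)) > 1 && two_days

  ## repeatability block (Fig 1A analog): per sex, both days, same feed
  if (two_days && !crossover) {
    rows <- lapply(split(resp_ok, resp_ok$sex), function(d) {
      paired <- pair_sessions(d, value = "o2_consumed")
      if (nrow(paired) < 5) return(NULL)
      cr <- correlation_auto(paired$day1, paired$day2, alpha)
      icc <- icc_oneway(paired$day1, paired$day2, n_boot = n_boot,
                        seed = seeds[1])
      data.frame(sex = d$sex[1], method = cr$method,
                 r = cr$coefficient, r_p_value = cr$p_value,
                 icc = icc$estimate, icc_ci_low = icc$ci_low,
                 icc_ci_high = icc$ci_high, n = nrow(paired),
                 n_dropped = length(attr(paired, "dropped")),
                 stringsAsFactors = FALSE)
    })
    report$repeatability <- row_or_null(do.call(rbind, rows))
  }

  ## mass-consumption block (Fig 1B analog)
  rows <- lapply(cell_split(fed1), function(d) {
    if (nrow(d) < 4) return(NULL)
    cr <- correlation_auto(d$mass_g, d$o2_consumed, alpha)
    data.frame(sex = d$sex[1], strain = d$strain[1], method = cr$method,
               coefficient = cr$coefficient, p_value = cr$p_value,
               n = cr$n, stringsAsFactors = FALSE)
  })
  report$mass_consumption <- row_or_null(do.call(rbind, rows))

  ## sex x strain permutation ANOVA on RMR (Fig 1C analog)
  if (length(unique(fed1$sex)) == 2 &&
      length(unique(fed1$strain)) == 2 &&
      all(table(fed1$sex, fed1$strain) >= 2)) {
    pa <- perm_anova_2x2(fed1$rmr, fed1$sex, fed1$strain,
                         n_perm = n_perm, seed = seeds[2])
    tt <- pa$terms
    tt$term <- c("sex", "strain", "sex:strain")
    tt$effect_label <- vapply(tt$eta_squared, function(v)
      classify_effect("eta_squared", min(v, 1))$label, "")
    tt$n <- pa$n
    report$sex_strain_anova <- tt
  }

  ## behavioral metrics + boldness index
  metrics <- NULL
  if (!is.null(cohort$trajectories)) {
    metrics <- behavior_metrics_table(cohort$trajectories)
    metrics <- merge(metrics, cohort$metadata[, meta_cols], by = "fish_id",
                     sort = TRUE)
    bold <- boldness_index(metrics, metrics[, c("sex", "strain")])
    metrics <- merge(metrics, bold, by = "fish_id", sort = TRUE)
  }

  ## correlation screen (Fig 2 analog)
  if (!is.null(metrics)) {
    screen_vars <- c("boldness_index", "bottom_distance",
                     "center_distance", "distance_traveled",
                     "percent_explored", "percent_immobile",
                     "max_velocity")
    scr <- merge(metrics,
                 fed1[, c("fish_id", "rmr")], by = "fish_id", sort = TRUE)
    rows <- lapply(cell_split(scr), function(d) {
      do.call(rbind, lapply(screen_vars, function(v) {
        ok <- complete.cases(d[[v]], d$rmr)
        if (sum(ok) < 4) return(NULL)
        cr <- correlation_auto(d[[v]][ok], d$rmr[ok], alpha)
        data.frame(sex = d$sex[1], strain = d$strain[1], variable = v,
                   method = cr$method, coefficient = cr$coefficient,
                   p_value = cr$p_value, n = cr$n,
                   significant = cr$p_value < alpha,
                   stringsAsFactors = FALSE)
      }))
    })
    report$correlation_screen <- row_or_null(do.call(rbind, rows))
  }

  ## fasting blocks (Fig 3 analog)
  if (crossover) {
    # feed-state x sex permutation ANOVA within strain
    rows <- lapply(split(resp_ok, resp_ok$strain), function(d) {
      if (length(unique(d$feed_state)) != 2 ||
          length(unique(d$sex)) != 2) return(NULL)
      pa <- perm_anova_2x2(d$rmr, d$feed_state, d$sex,
                           n_perm = n_perm, seed = seeds[3])
      tt <- pa$terms
      tt$term <- c("feed_state", "sex", "feed_state:sex")
      tt$strain <- d$strain[1]
      tt$effect_label <- vapply(tt$eta_squared, function(v)
        classify_effect("eta_squared", min(v, 1))$label, "")
      tt$n <- pa$n
      tt
    })
    report$fasting_anova <- row_or_null(do.call(rbind, rows))

    # paired fed vs unfed within each sex x strain cell
    rows <- lapply(cell_split(resp_ok), function(d) {
      fed <- d[d$feed_state == "fed", c("fish_id", "rmr")]
      unf <- d[d$feed_state == "unfed", c("fish_id", "rmr")]
      m <- merge(fed, unf, by = "fish_id", suffixes = c("_fed", "_unfed"))
      if (nrow(m) < 5) return(NULL)
      tg <- two_group_test(m$rmr_fed, m$rmr_unfed, paired = TRUE, alpha)
      data.frame(sex = d$sex[1], strain = d$strain[1],
                 method = tg$method, statistic = tg$statistic,
                 p_value = tg$p_value, n = nrow(m),
                 stringsAsFactors = FALSE)
    })
    report$fasting_paired <- row_or_null(do.call(rbind, rows))
  }

  if (!is.null(metrics) && any(metrics$feed_state == "unfed")) {
    # between-groups behavioral comparisons, fed vs unfed per cell
    behav_vars <- c("bottom_distance", "center_distance",
                    "distance_traveled", "percent_explored")
    rows <- lapply(cell_split(metrics), function(d) {
      fed <- d[d$feed_state == "fed", , drop = FALSE]
      unf <- d[d$feed_state == "unfed", , drop = FALSE]
      if (nrow(fed) < 3 || nrow(unf) < 3) return(NULL)
      do.call(rbind, lapply(behav_vars, function(v) {
        tg <- two_group_test(fed[[v]], unf[[v]], paired = FALSE, alpha)
        data.frame(sex = d$sex[1], strain = d$strain[1], variable = v,
                   method = tg$method, statistic = tg$statistic,
                   p_value = tg$p_value, cohen_d = tg$cohen_d,
                   effect_label = classify_effect("cohen_d",
                                                  tg$cohen_d)$label,
                   n_fed = nrow(fed), n_unfed = nrow(unf),
                   stringsAsFactors = FALSE)
      }))
    })
    report$fasting_behavior <- row_or_null(do.call(rbind, rows))
  }

  ## ground-truth recovery appendix (simulate mode only)
  if (!is.null(cohort$ground_truth)) {
    gt <- cohort$ground_truth
    rec <- data.frame(quantity = "rho_true", truth = gt$rho_true,
                      estimate = NA_real_, stringsAsFactors = FALSE)
    if (!is.null(report$correlation_screen)) {
      bi <- report$correlation_screen
      bi <- bi[bi$variable == "boldness_index", , drop = FALSE]
      # pooled via mean Fisher z of the per-cell estimates
      z <- atanh(pmax(pmin(bi$coefficient, 0.999999), -0.999999))
      rec$estimate[1] <- tanh(mean(z))
    }
    if (crossover && !is.null(report$fasting_anova)) {
      fed <- resp_ok[resp_ok$feed_state == "fed", ]
      unf <- resp_ok[resp_ok$feed_state == "unfed", ]
      m <- merge(fed[, c("fish_id", "rmr")], unf[, c("fish_id", "rmr")],
                 by = "fish_id", suffixes = c("_fed", "_unfed"))
      rec <- rbind(rec, data.frame(
        quantity = "fasting_rmr_multiplier",
        truth = gt$fasting_rmr_multiplier,
        estimate = mean(m$rmr_unfed / m$rmr_fed)))
    }
    report$recovery <- rec
  }

  report$qc <- data.frame(
    n_records = nrow(resp), n_pass = sum(resp$qc_pass),
    n_excluded = sum(!resp$qc_pass))
  report$exclusions <- excluded
  report$metrics <- metrics
  report$rmr <- resp
  report$meta <- list(alpha = alpha, n_perm = n_perm, n_boot = n_boot,
                      seed = seed,
                      package_version = as.character(
                        utils::packageVersion("polscope")))
  class(report) <- "study_report"
  report
}

#' @export
print.study_report <- function(x, ...) {
  cat("<study_report>\n")
  for (nm in setdiff(names(x), c("metrics", "rmr", "meta", "exclusions"))) {
    blk <- x[[nm]]
    if (is.data.frame(blk)) {
      cat(sprintf("\n-- %s --\n", nm))
      print(blk, row.names = FALSE, digits = 3)
    }
  }
  invisible(x)
}

#' Run a full study
#'
#' Simulates or ingests a cohort per the [study_config()], analyzes it
#' with [analyze_cohort()], and (when `outdir` is set) writes the report
#' blocks as CSVs plus a combined `report.json`, the intermediate metric
#' and RMR tables, a plain-text log of every gate decision, and — in
#' simulate mode — the ground truth and a recovery appendix. Byte-for-byte
#' deterministic given (config, seed).
#'
#' @param config A [study_config()].
#' @return The `study_report`, invisibly when writing to disk.
#' @export
run_study <- function(config) {
  stopifnot(inherits(config, "study_config"))
  if (config$mode == "simulate") {
    cohort <- generate_cohort(config$cohort, seed = config$seed)
  } else {
    issues <- validate_inputs(config$path)
    if (nrow(issues))
      stop(paste0("input validation failed:\n",
                  paste(sprintf("  %s [%s]: %s", issues$file,
                                issues$column, issues$issue),
                        collapse = "\n")), call. = FALSE)
    cohort <- read_cohort(config$path)
  }
  report <- analyze_cohort(cohort, alpha = config$alpha,
                           n_perm = config$n_perm,
                           n_boot = config$n_boot,
                           seed = if (is.null(config$seed)) 1L
                                  else config$seed)
  if (!is.null(config$outdir))
    write_study_report(report, config$outdir, cohort = cohort,
                       write_ground_truth = config$mode == "simulate")
  if (is.null(config$outdir)) report else invisible(report)
}

#' @rdname run_study
#' @param report A `study_report`.
#' @param outdir Output directory.
#' @param cohort Optional cohort, for ground-truth serialization.
#' @param write_ground_truth Write `ground_truth.json` alongside the
#'   report.
#' @export
write_study_report <- function(report, outdir, cohort = NULL,
                               write_ground_truth = FALSE) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  blocks <- c("repeatability", "mass_consumption", "sex_strain_anova",
              "correlation_screen", "fasting_anova", "fasting_paired",
              "fasting_behavior", "recovery", "qc", "exclusions",
              "metrics", "rmr")
  json <- list(meta = report$meta)
  log_lines <- c(sprintf("polscope study report (seed %s)",
                         report$meta$seed))
  for (nm in blocks) {
    blk <- report[[nm]]
    if (is.null(blk) || !is.data.frame(blk)) next
    write.csv(blk, file.path(outdir, paste0(nm, ".csv")),
              row.names = FALSE, quote = FALSE)
    json[[nm]] <- blk
    if ("method" %in% names(blk))
      log_lines <- c(log_lines, sprintf(
        "%s: %s", nm,
        paste(unique(blk$method), collapse = ", ")))
  }
  # gate decisions: which screens fell back to Spearman
  scr <- report$correlation_screen
  if (!is.null(scr)) {
    sp <- scr[scr$method == "spearman", , drop = FALSE]
    log_lines <- c(log_lines, sprintf(
      "correlation_screen: %d/%d cells gated to spearman", nrow(sp),
      nrow(scr)))
  }
  jsonlite::write_json(json, file.path(outdir, "report.json"),
                       auto_unbox = TRUE, digits = NA, na = "null",
                       dataframe = "columns")
  writeLines(log_lines, file.path(outdir, "run.log"))
  if (write_ground_truth && !is.null(cohort$ground_truth))
    jsonlite::write_json(cohort$ground_truth,
                         file.path(outdir, "ground_truth.json"),
                         auto_unbox = TRUE, digits = NA,
                         dataframe = "columns")
  invisible(outdir)
}

#' Validate an on-disk cohort directory
#'
#' Schema checks for the [write_cohort()] layout: required columns per
#' file, duplicate (fish, day) records, and id cross-references (every
#' fish in the respirometry and trajectory files must appear in the
#' metadata, and vice versa).
#'
#' @param path Cohort directory.
#' @return Data frame of issues (`file`, `column`, `issue`); zero rows
#'   when the layout is well-formed.
#' @export
validate_inputs <- function(path) {
  issues <- data.frame(file = character(), column = character(),
                       issue = character(), stringsAsFactors = FALSE)
  add <- function(file, column, issue)
    rbind(issues, data.frame(file = file, column = column, issue = issue,
                             stringsAsFactors = FALSE))
  meta_path <- file.path(path, "metadata.csv")
  resp_path <- file.path(path, "respirometry.csv")
  if (!file.exists(meta_path))
    return(add("metadata.csv", "", "file missing"))
  meta <- read.csv(meta_path, stringsAsFactors = FALSE)
  for (col in c("fish_id", "strain", "sex", "feed_state", "mass_g"))
    if (!col %in% names(meta))
      issues <- add("metadata.csv", col, "column missing")
  if (anyDuplicated(meta$fish_id))
    issues <- add("metadata.csv", "fish_id", "duplicate fish_id")

  if (file.exists(resp_path)) {
    resp <- read.csv(resp_path, stringsAsFactors = FALSE)
    need <- c("fish_id", "session_day", "o2_fish_t1", "o2_fish_t2",
              "o2_blank_t1", "o2_blank_t2", "duration_min", "mass_g")
    for (col in need)
      if (!col %in% names(resp))
        issues <- add("respirometry.csv", col, "column missing")
    if (all(c("fish_id", "session_day") %in% names(resp))) {
      dup <- duplicated(resp[, c("fish_id", "session_day",
                                 intersect("feed_state", names(resp)))])
      if (any(dup))
        issues <- add("respirometry.csv", "fish_id",
                      sprintf("duplicate (fish_id, session_day): %s",
                              paste(resp$fish_id[dup], collapse = ", ")))
    }
    o2_cols <- intersect(need[3:6], names(resp))
    if (length(o2_cols)) {
      bad <- !complete.cases(resp[, o2_cols, drop = FALSE])
      if (any(bad))
        issues <- add("respirometry.csv", paste(o2_cols, collapse = "|"),
                      sprintf("missing O2 reading for fish: %s",
                              paste(unique(resp$fish_id[bad]),
                                    collapse = ", ")))
    }
    if ("fish_id" %in% names(resp) && "fish_id" %in% names(meta)) {
      orphan <- setdiff(resp$fish_id, meta$fish_id)
      if (length(orphan))
        issues <- add("respirometry.csv", "fish_id",
                      sprintf("fish not in metadata: %s",
                              paste(orphan, collapse = ", ")))
    }
  }
  tdir <- file.path(path, "trajectories")
  if (dir.exists(tdir) && "fish_id" %in% names(meta)) {
    traj_ids <- sub("\\.csv$", "",
                    list.files(tdir, pattern = "\\.csv$"))
    missing_traj <- setdiff(meta$fish_id, traj_ids)
    if (length(missing_traj))
      issues <- add("trajectories/", "fish_id",
                    sprintf("metadata fish without trajectory: %s",
                            paste(missing_traj, collapse = ", ")))
    orphan <- setdiff(traj_ids, meta$fish_id)
    if (length(orphan))
      issues <- add("trajectories/", "fish_id",
                    sprintf("trajectory fish not in metadata: %s",
                            paste(orphan, collapse = ", ")))
  }
  issues
}
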