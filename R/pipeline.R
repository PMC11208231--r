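## End-to-end orchestration: raw sessions -> MEP records -> motor maps ->
## clinical scores -> group-difference and association models, with
## cohort/missing-data accounting and CSV round-trip IO.

#' Build the per-subject per-muscle map table from raw sessions
#'
#' Runs MEP extraction ([process_epochs()]) and map summarization
#' ([summarize_map()]) over every session of a cohort, then mirrors
#' left-hemisphere X coordinates so hemispheres pool ("more lateral" keeps
#' one sign, see [pool_hemispheres()]).
#'
#' @param cohort a `synthetic_cohort` with raw sessions, or a nested list
#'   `[[subject]][[muscle]]` of `tms_session` objects plus a `subjects`
#'   data.frame passed separately.
#' @param subjects subject table (`subject`, `group`, `hemisphere`); taken
#'   from the cohort when omitted.
#' @param method,alpha area method forwarded to [summarize_map()].
#' @param mirror mirror left-hemisphere maps before pooling (default TRUE).
#' @return data.frame, one row per subject x muscle: `subject`, `group`,
#'   `hemisphere`, `muscle`, `cog_x`, `cog_y`, `cog_z`, `area`, `n_sites`,
#'   `missing`, `degenerate`.
#' @export
build_map_table <- function(cohort, subjects = NULL,
                            method = c("alpha_shape", "convex_hull"),
                            alpha = 15, mirror = TRUE) {
  method <- match.arg(method)
  sessions <- if (inherits(cohort, "synthetic_cohort")) cohort$sessions
              else cohort
  if (is.null(sessions)) {
    stop("cohort carries no raw TMS sessions", call. = FALSE)
  }
  if (is.null(subjects)) subjects <- cohort$subjects
  rows <- list()
  for (s in names(sessions)) {
    srow <- subjects[subjects$subject == s, ]
    for (m in names(sessions[[s]])) {
      ses <- sessions[[s]][[m]]
      epochs <- lapply(seq_len(nrow(ses$epochs)),
                       function(i) ses$epochs[i, ])
      recs <- process_epochs(epochs, ses$sampling_rate,
                             stim_ids = ses$sites$stim_id, muscle = m)
      mp <- summarize_map(m, recs, ses$sites, method = method,
                          alpha = alpha)
      rows[[length(rows) + 1L]] <- data.frame(
        subject = s, group = as.character(srow$group),
        hemisphere = srow$hemisphere, muscle = m,
        cog_x = mp$cog[["x"]], cog_y = mp$cog[["y"]],
        cog_z = mp$cog[["z"]], area = mp$area,
        n_sites = mp$n_sites, missing = mp$missing,
        degenerate = mp$degenerate, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  if (mirror) out <- pool_hemispheres(out)
  out
}

#' Missing-data accounting from per-muscle counts
#'
#' @param missing_counts named integer vector, missing outcomes per muscle.
#' @param n_subjects total number of subjects.
#' @param n_muscles number of muscles (default the number of counts).
#' @return list: `per_muscle`, `n_missing`, `total_slots`, `missing_pct`
#'   (one decimal).
#' @export
missing_summary <- function(missing_counts, n_subjects,
                            n_muscles = length(missing_counts)) {
  total <- n_subjects * n_muscles
  n_missing <- sum(missing_counts)
  list(per_muscle = missing_counts,
       n_missing = n_missing,
       total_slots = total,
       missing_pct = round(100 * n_missing / total, 1))
}

#' Cohort missing-data accounting from a map table
#'
#' Counts the muscle outcomes that could not be measured (no accepted
#' MEPs) per muscle and overall. A subject x muscle slot must appear
#' exactly once.
#'
#' @param map_table output of [build_map_table()].
#' @return as [missing_summary()], plus `n_subjects_missing_any`.
#' @export
account_missing <- function(map_table) {
  key <- paste(map_table$subject, map_table$muscle)
  if (anyDuplicated(key)) {
    stop("duplicate subject x muscle rows in map table", call. = FALSE)
  }
  miss <- if ("missing" %in% names(map_table)) map_table$missing
          else is.na(map_table$cog_x)
  muscles <- unique(map_table$muscle)
  per_muscle <- vapply(muscles, function(m) {
    sum(miss[map_table$muscle == m])
  }, integer(1))
  out <- missing_summary(per_muscle,
                         n_subjects = length(unique(map_table$subject)),
                         n_muscles = length(muscles))
  out$n_subjects_missing_any <-
    length(unique(map_table$subject[miss]))
  out
}

#' Score a cohort's clinical and tracking outcomes
#'
#' Applies the QST scorers to each subject's raw records and the tracking
#' outcomes to the (non-practice) test trial. The first tracking trial is a
#' practice trial and is excluded from analysis by default.
#'
#' @param cohort a `synthetic_cohort`.
#' @param q,r tracking analysis parameters (defaults 90% and 0.9 deg).
#' @param include_practice score the practice trial instead of dropping it.
#' @return wide data.frame keyed by `subject` with `group` and one column
#'   per test (`ts`, `ppt`, `cpm_abs`, `cpm_rel`, `vibration`,
#'   `graphaesthesia`, `tpd`, `angular_near`, `time_near`, `path`).
#'   Graphaesthesia is carried on the percentage scale (error rate x 100)
#'   so the modelled tests share interpretable coefficient magnitudes.
#' @export
score_cohort <- function(cohort, q = 90, r = 0.9,
                         include_practice = FALSE) {
  stopifnot(inherits(cohort, "synthetic_cohort"))
  rows <- lapply(cohort$subjects$subject, function(s) {
    qrow <- score_qst(cohort$qst[[s]])
    trial <- if (include_practice) cohort$tracking[[s]]$practice
             else cohort$tracking[[s]]$test
    trow <- score_tracking_trial(trial, q = q, r = r)
    cbind(data.frame(subject = s, stringsAsFactors = FALSE), qrow, trow)
  })
  out <- do.call(rbind, rows)
  out$graphaesthesia <- out$graphaesthesia * 100
  out <- merge(cohort$subjects[, c("subject", "group")], out,
               by = "subject", sort = TRUE)
  rownames(out) <- NULL
  out
}

#' Long map-feature table for one model family
#'
#' @param map_table from [build_map_table()].
#' @param feature one of `"area"`, `"cog_x"`, `"cog_y"`, `"cog_z"` (the
#'   medio-lateral, posterior-anterior and vertical CoG axes).
#' @return long data.frame `subject`, `group`, `test` (= muscle), `value`;
#'   missing maps dropped.
#' @export
map_long <- function(map_table,
                     feature = c("area", "cog_x", "cog_y", "cog_z")) {
  feature <- match.arg(feature)
  out <- data.frame(subject = map_table$subject,
                    group = factor(map_table$group,
                                   levels = c("control", "LBP")),
                    test = factor(map_table$muscle,
                                  levels = unique(map_table$muscle)),
                    value = map_table[[feature]],
                    stringsAsFactors = FALSE)
  out <- out[!is.na(out$value) & !map_table$missing, , drop = FALSE]
  rownames(out) <- NULL
  out
}

MAP_FAMILIES <- c(area = "area", cog_ml = "cog_x", cog_ap = "cog_y",
                  cog_vert = "cog_z")

#' Run the full study analysis
#'
#' End to end: simulate (or ingest) the cohort, extract MEPs and motor
#' maps, do the missing-data accounting, score the clinical battery and
#' tracking, fit the group-difference models (four map families with
#' muscles as the Test variable, three clinical families), fit the
#' association models between each map family and each clinical test, and
#' refit significant associations within each group (the stratified gate).
#' With the same configuration and seed, the result is bit-identical.
#'
#' @param cfg a [sim_config()] (synthetic mode), or a list
#'   `list(clinical = <path>, map_table = <path>)` of CSVs written by
#'   [write_study_csvs()] (files mode: pre-scored tables are ingested and
#'   only the modelling stages run).
#' @param outdir optional output directory; when given, all result tables
#'   are written as CSV plus a `provenance.json` carrying the
#'   configuration and its hash.
#' @param q,r tracking analysis parameters.
#' @param area_method,area_alpha map-area options.
#' @param var_by_test use per-test residual variances in the clinical
#'   family models (default TRUE: those families stack tests with
#'   incommensurable units and scales). Map families always share one
#'   residual variance across muscles, which share units.
#' @param alpha_sig significance threshold gating the stratified
#'   association follow-up (default 0.05).
#' @param associations fit the association models (default TRUE; the
#'   group-difference analysis always runs).
#' @return list of class `study_result`: `subjects`, `map_table`,
#'   `accounting`, `clinical`, `group_estimates`,
#'   `association_estimates`, `stratified_estimates`, `config_hash`.
#' @export
run_study <- function(cfg, outdir = NULL, q = 90, r = 0.9,
                      area_method = "alpha_shape", area_alpha = 15,
                      var_by_test = TRUE, alpha_sig = 0.05,
                      associations = TRUE) {
  if (inherits(cfg, "sim_config")) {
    cohort <- simulate_cohort(cfg)
    map_table <- build_map_table(cohort, method = area_method,
                                 alpha = area_alpha)
    clinical <- score_cohort(cohort, q = q, r = r)
    subjects <- cohort$subjects
  } else if (is.list(cfg) && all(c("clinical", "map_table") %in%
                                 names(cfg))) {
    clinical <- utils::read.csv(cfg$clinical, stringsAsFactors = FALSE)
    map_table <- utils::read.csv(cfg$map_table, stringsAsFactors = FALSE)
    need <- c("subject", "group", "muscle", "cog_x", "cog_y", "cog_z",
              "area", "missing")
    miss_cols <- setdiff(need, names(map_table))
    if (length(miss_cols) > 0L) {
      stop(sprintf("map_table file lacks column(s): %s",
                   paste(miss_cols, collapse = ", ")), call. = FALSE)
    }
    clinical$group <- factor(clinical$group, levels = c("control", "LBP"))
    subjects <- unique(clinical[, c("subject", "group")])
  } else {
    stop("cfg must be a sim_config or list(clinical=, map_table=)",
         call. = FALSE)
  }

  accounting <- account_missing(map_table)

  ## group-difference models
  group_rows <- list()
  for (famname in names(MAP_FAMILIES)) {
    long <- map_long(map_table, MAP_FAMILIES[[famname]])
    fit <- fit_group_model(long)
    est <- estimates(fit)
    est$family <- famname
    est$singular <- fit$singular
    group_rows[[famname]] <- est
  }
  clin_fams <- clinical_families()
  for (famname in names(clin_fams)) {
    tests <- intersect(clin_fams[[famname]], names(clinical))
    long <- stack_long(clinical, tests, family = famname)
    fit <- fit_group_model(long, var_by_test = var_by_test)
    est <- estimates(fit)
    est$family <- famname
    est$singular <- fit$singular
    group_rows[[famname]] <- est
  }
  group_estimates <- do.call(rbind, group_rows)
  rownames(group_estimates) <- NULL

  association_estimates <- NULL
  stratified_estimates <- NULL
  if (associations) {
    assoc_rows <- list()
    strat_rows <- list()
    predictors <- clinical
    pred_tests <- setdiff(names(clinical), c("subject", "group"))
    for (famname in names(MAP_FAMILIES)) {
      long <- map_long(map_table, MAP_FAMILIES[[famname]])
      for (p in pred_tests) {
        fit <- fit_association_model(long, predictors, p)
        est <- estimates(fit)
        est$family <- famname
        est$predictor <- p
        est$stratum <- "all"
        assoc_rows[[paste(famname, p)]] <- est
        sig <- est$test[!is.na(est$p) & est$p < alpha_sig]
        if (length(sig) > 0L) {          # gate: only then stratify
          for (g in levels(subjects$group)) {
            sest <- tryCatch({
              sfit <- stratified_association(long, predictors, p,
                                             subjects, g)
              estimates(sfit)
            }, error = function(e) {
              warning(sprintf(
                "stratified refit skipped (%s / %s in %s): %s",
                famname, p, g, conditionMessage(e)), call. = FALSE)
              NULL
            })
            if (is.null(sest)) next
            sest$family <- famname
            sest$predictor <- p
            sest$stratum <- g
            strat_rows[[paste(famname, p, g)]] <- sest
          }
        }
      }
    }
    association_estimates <- do.call(rbind, assoc_rows)
    if (length(strat_rows) > 0L) {
      stratified_estimates <- do.call(rbind, strat_rows)
      rownames(stratified_estimates) <- NULL
    }
    if (!is.null(association_estimates)) {
      rownames(association_estimates) <- NULL
    }
  }

  hash <- config_hash(cfg)
  res <- structure(list(
    subjects = subjects, map_table = map_table, accounting = accounting,
    clinical = clinical, group_estimates = group_estimates,
    association_estimates = association_estimates,
    stratified_estimates = stratified_estimates,
    config_hash = hash
  ), class = "study_result")
  if (!is.null(outdir)) write_study_csvs(res, cfg, outdir)
  res
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf(
    "<study_result> %d subjects; %.1f%% missing map outcomes (%d/%d)\n",
    nrow(x$subjects), x$accounting$missing_pct, x$accounting$n_missing,
    x$accounting$total_slots))
  cat(sprintf("  %d group-difference estimates, %d association estimates\n",
              nrow(x$group_estimates),
              if (is.null(x$association_estimates)) 0L
              else nrow(x$association_estimates)))
  invisible(x)
}

#' Deterministic hash of a run configuration
#'
#' @param cfg any serializable configuration object.
#' @return 8-hex-digit character hash.
#' @export
config_hash <- function(cfg) {
  key <- paste(deparse(cfg), collapse = "\n")
  sprintf("%08x", substream_seed(0L, key))
}

#' Write the study result tables
#'
#' Writes `subjects.csv`, `map_table.csv`, `clinical.csv`,
#' `group_estimates.csv`, `association_estimates.csv` (when present),
#' `stratified_estimates.csv` (when present), `accounting.json` and
#' `provenance.json` (configuration, its hash, file list) to `outdir`.
#' CSVs are UTF-8, comma-separated, header row, `.` decimal separator.
#'
#' @param res a `study_result`.
#' @param cfg the configuration that produced it.
#' @param outdir output directory (created if needed).
#' @return invisibly, the vector of files written.
#' @export
write_study_csvs <- function(res, cfg, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  hash <- res$config_hash
  files <- character(0)
  wr <- function(df, name) {
    df$config_hash <- hash
    path <- file.path(outdir, name)
    utils::write.csv(df, path, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(res$subjects, "subjects.csv")
  wr(res$map_table, "map_table.csv")
  wr(res$clinical, "clinical.csv")
  wr(res$group_estimates, "group_estimates.csv")
  if (!is.null(res$association_estimates)) {
    wr(res$association_estimates, "association_estimates.csv")
  }
  if (!is.null(res$stratified_estimates)) {
    wr(res$stratified_estimates, "stratified_estimates.csv")
  }
  acc <- res$accounting
  acc$config_hash <- hash
  jsonlite::write_json(acc, file.path(outdir, "accounting.json"),
                       auto_unbox = TRUE, digits = NA)
  prov <- list(config_hash = hash,
               config = if (inherits(cfg, "sim_config"))
                 unclass(cfg) else cfg,
               files = basename(c(files, "accounting.json")))
  jsonlite::write_json(prov, file.path(outdir, "provenance.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(c(files, file.path(outdir, c("accounting.json",
                                         "provenance.json"))))
}

## ---------------------------------------------------------------------------
## CSV round-trip IO for the raw-data schemas

#' Write/read stimulation-site coordinates
#'
#' Schema: `stim_id`, `x`, `y`, `z` (mm, template space).
#' @param sites data.frame in the schema above.
#' @param path CSV path.
#' @return `read_sites_csv` returns the data.frame.
#' @export
write_sites_csv <- function(sites, path) {
  utils::write.csv(sites[, c("stim_id", "x", "y", "z")], path,
                   row.names = FALSE)
  invisible(path)
}

#' @rdname write_sites_csv
#' @export
read_sites_csv <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE)
}

#' Write/read per-stimulation EMG epochs
#'
#' Long schema: `stim_id`, `sample_index`, `uv`; the sampling rate travels
#' in a JSON sidecar (`<path>.json`).
#'
#' @param epochs matrix, one row per stimulation.
#' @param sampling_rate Hz.
#' @param path CSV path.
#' @return `read_epochs_csv` returns `list(epochs, sampling_rate)`.
#' @export
write_epochs_csv <- function(epochs, sampling_rate, path) {
  long <- data.frame(
    stim_id = rep(seq_len(nrow(epochs)), each = ncol(epochs)),
    sample_index = rep(seq_len(ncol(epochs)), times = nrow(epochs)),
    uv = as.vector(t(epochs)))
  utils::write.csv(long, path, row.names = FALSE)
  jsonlite::write_json(list(sampling_rate = sampling_rate),
                       paste0(path, ".json"), auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_epochs_csv
#' @export
read_epochs_csv <- function(path) {
  long <- utils::read.csv(path)
  hdr <- jsonlite::read_json(paste0(path, ".json"))
  ids <- unique(long$stim_id)
  n_samp <- max(long$sample_index)
  epochs <- matrix(NA_real_, nrow = length(ids), ncol = n_samp)
  for (i in seq_along(ids)) {
    sub <- long[long$stim_id == ids[i], ]
    epochs[i, sub$sample_index] <- sub$uv
  }
  list(epochs = epochs, sampling_rate = hdr$sampling_rate)
}

#' Write/read a tracking trial
#'
#' Schema: `t`, `target_x`, `target_y`, `actual_x`, `actual_y` (degrees).
#' @param trial tracking trial data.frame.
#' @param path CSV path.
#' @return `read_tracking_csv` returns the data.frame.
#' @export
write_tracking_csv <- function(trial, path) {
  utils::write.csv(
    trial[, c("t", "target_x", "target_y", "actual_x", "actual_y")],
    path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tracking_csv
#' @export
read_tracking_csv <- function(path) {
  utils::read.csv(path)
}
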