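#' Load and validate a cohort table from CSV
#'
#' Expects one row per participant with the five trait columns and the
#' three `ki_<roi>` columns (a column mapping can rename them). Influx
#' rates must be numeric, finite, and positive where present; per-measure
#' missingness is allowed, and logical `excl_<trait>` columns blank out the
#' flagged measure for that row.
#'
#' @param path CSV file with a header.
#' @param column_map optional named character vector mapping file columns
#'   to canonical names, e.g. `c(DS_total = "digit_span")`.
#' @return a `cohort` data frame.
#' @export
load_cohort <- function(path, column_map = NULL) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (!is.null(column_map))
    names(d)[match(names(column_map), names(d))] <- unname(column_map)
  ki_cols <- paste0("ki_", roi_names())
  expected <- c(trait_names(), ki_cols)
  missing_cols <- setdiff(expected, names(d))
  if (length(missing_cols))
    stop("cohort file lacks column(s) ", paste(missing_cols, collapse = ", "),
         "; available columns: ", paste(names(d), collapse = ", "))
  if (!"participant_id" %in% names(d))
    d$participant_id <- sprintf("sub-%03d", seq_len(nrow(d)))
  if (anyDuplicated(d$participant_id)) stop("participant ids must be unique")
  for (cc in ki_cols) {
    v <- d[[cc]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(v))) & !is.na(v) & v != "")
      stop(sprintf("non-numeric value in column %s, row %d", cc, bad[1]))
    }
    if (any(!is.na(v) & (v <= 0 | !is.finite(v))))
      stop("influx rates in ", cc, " must be finite and positive")
  }
  for (tr in trait_names()) {
    flag <- paste0("excl_", tr)
    if (flag %in% names(d)) d[[tr]][as.logical(d[[flag]]) %in% TRUE] <- NA
  }
  message(sprintf("loaded cohort: %d participants, %d columns; missing per trait: %s",
                  nrow(d), ncol(d),
                  paste(sprintf("%s=%d", trait_names(),
                                vapply(trait_names(),
                                       function(tr) sum(is.na(d[[tr]])),
                                       integer(1))),
                        collapse = ", ")))
  class(d) <- c("cohort", "data.frame")
  d
}

#' Trait-by-ROI correlation table (frequentist + Bayesian)
#'
#' Runs [corr_test()] for every trait across the three striatal ROIs and
#' stacks the rows: Pearson r, one-sided p, Holm-adjusted p (family = the
#' three ROIs within a trait), and BF01 under the flat (0, 1) and (-1, 1)
#' priors. Alternatively reproduces the table from printed (r, n)
#' summaries via `summary_df`.
#'
#' @param cohort a cohort data frame (ignored when `summary_df` is given).
#' @param traits trait columns to analyse.
#' @param rois ROI names.
#' @param width Bayes-factor prior width.
#' @param summary_df optional data frame with columns `trait`, `roi`, `r`,
#'   `n` ("summary mode").
#' @param path optional CSV output path.
#' @return the correlation table (data frame).
#' @export
run_table1 <- function(cohort = NULL, traits = trait_names(),
                       rois = roi_names(), width = 1, summary_df = NULL,
                       path = NULL) {
  tab <- if (!is.null(summary_df)) {
    corr_test_summary(summary_df, width)
  } else {
    do.call(rbind, lapply(traits, function(tr)
      corr_test(cohort, tr, rois, width)))
  }
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Trait-by-ROI cross-validated predictive accuracy table
#'
#' Per trait x ROI pair: repeated k-fold cross-validation of the simple
#' regression of influx rate on the trait, with a permutation null —
#' mean, standard error, and permutation p for both out-of-sample R2 and
#' RMSE.
#'
#' @param cohort a cohort data frame.
#' @param traits,rois columns to analyse.
#' @param cfg a [cv_config()]; each pair consumes a deterministic
#'   sub-seed derived from `cfg$seed`.
#' @param path optional CSV output path.
#' @return data frame with one row per trait x ROI.
#' @export
run_table2 <- function(cohort, traits = trait_names(), rois = roi_names(),
                       cfg = cv_config(), path = NULL) {
  rows <- list()
  for (ti in seq_along(traits)) {
    for (ri in seq_along(rois)) {
      sub_cfg <- cfg
      sub_cfg$seed <- cfg$seed + 1000L * ti + ri
      pt <- permutation_test(cohort[[traits[ti]]],
                             cohort[[paste0("ki_", rois[ri])]], sub_cfg)
      obs <- pt$observed
      rows[[length(rows) + 1L]] <-
        data.frame(trait = traits[ti], roi = rois[ri], n = obs$n,
                   r2_mean = obs$r2_mean, r2_stderr = obs$r2_stderr,
                   r2_perm_p = pt$perm_p_r2,
                   rmse_mean = obs$rmse_mean, rmse_stderr = obs$rmse_stderr,
                   rmse_perm_p = pt$perm_p_rmse)
    }
  }
  tab <- do.call(rbind, rows)
  if (!is.null(path)) utils::write.csv(tab, path, row.names = FALSE)
  tab
}

#' Run configuration for the full report
#'
#' @param cohort_path cohort CSV (NULL to simulate a null cohort).
#' @param traits,rois columns to analyse.
#' @param cv a [cv_config()].
#' @param bf_widths prior-width grid for the robustness curves.
#' @param subsample_sizes sizes for the subsample-variability curves.
#' @param subsample_draws resamples per size.
#' @param seed master seed; stochastic stages draw named sub-seeds from it.
#' @param out_dir output directory.
#' @return object of class `run_config`.
#' @export
run_config <- function(cohort_path = NULL, traits = trait_names(),
                       rois = roi_names(), cv = cv_config(),
                       bf_widths = seq(0.1, 2, by = 0.1),
                       subsample_sizes = c(15, 25, 50, 94),
                       subsample_draws = 1000, seed = 1,
                       out_dir = "results") {
  structure(list(cohort_path = cohort_path, traits = traits, rois = rois,
                 cv = cv, bf_widths = bf_widths,
                 subsample_sizes = subsample_sizes,
                 subsample_draws = subsample_draws, seed = seed,
                 out_dir = out_dir),
            class = "run_config")
}

#' Read a run configuration from YAML
#'
#' Top-level keys mirror the arguments of [run_config()]; `cv` may be a
#' mapping with `k`, `repeats`, `n_permutations`.
#'
#' @param path YAML file.
#' @return a [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  cv_args <- y$cv %||% list()
  cv <- do.call(cv_config, c(cv_args,
                             if (is.null(cv_args$seed)) list(seed = y$seed %||% 1)))
  args <- y[setdiff(names(y), "cv")]
  do.call(run_config, c(args, list(cv = cv)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Produce the full report directory
#'
#' End-to-end orchestration: loads (or simulates) the cohort, then writes
#' `table1.csv` (correlations + Bayes factors), `table2.csv`
#' (cross-validated accuracy), `robustness_curves.csv` (BF01 by prior
#' width per trait x ROI), `subsample_curves.csv`, and `run_log.txt`
#' (seed, sizes, package/R versions). Per-trait failures are collected and
#' re-raised together after all outputs that could be produced are
#' written.
#'
#' @param config a [run_config()].
#' @return invisibly, named vector of output paths.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  dir.create(config$out_dir, showWarnings = FALSE, recursive = TRUE)
  cohort <- if (is.null(config$cohort_path)) {
    simulate_cohort(cohort_spec(seed = config$seed))
  } else load_cohort(config$cohort_path)
  unknown <- setdiff(config$traits, names(cohort))
  if (length(unknown))
    stop("unknown trait column(s): ", paste(unknown, collapse = ", "))
  paths <- c(table1 = file.path(config$out_dir, "table1.csv"),
             table2 = file.path(config$out_dir, "table2.csv"),
             robustness = file.path(config$out_dir, "robustness_curves.csv"),
             subsample = file.path(config$out_dir, "subsample_curves.csv"),
             log = file.path(config$out_dir, "run_log.txt"))
  errors <- character()
  collect <- function(tag, expr) {
    tryCatch(expr, error = function(e) {
      errors <<- c(errors, sprintf("%s: %s", tag, conditionMessage(e)))
      NULL
    })
  }
  t1 <- collect("table1", run_table1(cohort, config$traits, config$rois,
                                     path = paths["table1"]))
  collect("table2", run_table2(cohort, config$traits, config$rois,
                               config$cv, path = paths["table2"]))
  collect("robustness", {
    rc <- do.call(rbind, lapply(seq_len(nrow(t1)), function(i) {
      cbind(trait = t1$trait[i], roi = t1$roi[i],
            bf_robustness_curve(t1$r[i], t1$n[i], c(0, 1), config$bf_widths))
    }))
    utils::write.csv(rc, paths["robustness"], row.names = FALSE)
  })
  collect("subsample", {
    sizes <- config$subsample_sizes
    sc <- do.call(rbind, lapply(config$traits, function(tr) {
      do.call(rbind, lapply(config$rois, function(roi) {
        ok <- stats::complete.cases(cohort[[tr]],
                                    cohort[[paste0("ki_", roi)]])
        cbind(trait = tr, roi = roi,
              subsample_variability(cohort[[tr]][ok],
                                    cohort[[paste0("ki_", roi)]][ok],
                                    sizes[sizes <= sum(ok)],
                                    config$subsample_draws,
                                    seed = config$seed))
      }))
    }))
    utils::write.csv(sc, paths["subsample"], row.names = FALSE)
  })
  writeLines(c(sprintf("seed: %s", config$seed),
               sprintf("n_participants: %d", nrow(cohort)),
               sprintf("cv: k=%d repeats=%d permutations=%d",
                       config$cv$k, config$cv$repeats,
                       config$cv$n_permutations),
               sprintf("R: %s", R.version.string),
               sprintf("dopaproxy: %s",
                       as.character(utils::packageVersion("dopaproxy")))),
             paths["log"])
  if (length(errors))
    stop("run_all finished with errors:\n", paste(errors, collapse = "\n"))
  invisible(paths)
}
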