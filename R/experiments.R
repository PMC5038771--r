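# Config-driven experiment presets reproducing the analysis designs
# end-to-end: attribute subset, decision attribute, decision binning,
# discretization, cross-validated classification and metric reporting.

#' Experiment presets
#'
#' Named condition-attribute/decision configurations:
#' * `E1` — four-bin UPDRS total from patient, age, session and saccade
#'   duration/latency/amplitude.
#' * `E2` — session number from clinical attributes only (no eye movements).
#' * `E3` — session number with eye-movement attributes, UPDRS III and
#'   Hoehn-Yahr.
#' * `E4a` — `E1` plus the PDQ-39, AIMS and Epworth well-being scales.
#' * `E4b` — session number with the extended set including PDQ-39.
#' * `E5_III` / `E5_II` — four-bin UPDRS III (resp. II) from the companion
#'   subscale, session, latency and PDQ-39.
#'
#' @param name Preset name.
#' @return List with `name`, `decision`, `conditions`, `decision_bins`
#'   (NULL for a nominal decision).
#' @export
experiment_preset <- function(name = c("E1", "E2", "E3", "E4a", "E4b",
                                       "E5_III", "E5_II")) {
  name <- match.arg(name)
  switch(name,
    E1 = list(name = name, decision = "UPDRS", decision_bins = 4L,
              conditions = c("Pat", "age", "Sess", "SccDur", "SccLat",
                             "SccAmp")),
    E2 = list(name = name, decision = "Sess", decision_bins = NULL,
              conditions = c("Pat", "age", "t_dur", "SEngs", "UPDRS_III",
                             "UPDRS_IV", "UPDRS")),
    E3 = list(name = name, decision = "Sess", decision_bins = NULL,
              conditions = c("Pat", "age", "SccVel", "UPDRS_III", "HYsc",
                             "SccDur", "SccLat", "SccAmp")),
    E4a = list(name = name, decision = "UPDRS", decision_bins = 4L,
               conditions = c("Pat", "age", "Sess", "SccDur", "SccLat",
                              "SccAmp", "PDQ39", "AIMS", "Epworth")),
    E4b = list(name = name, decision = "Sess", decision_bins = NULL,
               conditions = c("Pat", "UPDRS_III", "SEngs", "SccLat", "SccDur",
                              "SccAmp", "PDQ39")),
    E5_III = list(name = name, decision = "UPDRS_III", decision_bins = 4L,
                  conditions = c("Pat", "UPDRS_II", "Sess", "SccLat",
                                 "PDQ39")),
    E5_II = list(name = name, decision = "UPDRS_II", decision_bins = 4L,
                 conditions = c("Pat", "UPDRS_III", "Sess", "SccLat",
                                "PDQ39")))
}

#' Discretize a decision table for an experiment
#'
#' Bins a numeric decision by equal-frequency quantile cuts, selects
#' condition cuts (maximal-discernibility or equal-frequency) and applies
#' them. Discretization is computed once on the full table; see
#' `cuts_per_fold` in [run_experiment()] for the leakage-free variant.
#'
#' @param dt A `decisiontable`.
#' @param discretizer `"md"` or `"eqfreq"`.
#' @param decision_bins Bins for a numeric decision (ignored for nominal).
#' @param eq_bins Bins per condition attribute for `"eqfreq"`.
#' @param dialect Interval label dialect.
#' @return A `disctable`.
#' @export
discretize_table <- function(dt, discretizer = c("md", "eqfreq"),
                             decision_bins = 4L, eq_bins = 4L,
                             dialect = "rses") {
  discretizer <- match.arg(discretizer)
  dcuts <- if (is.numeric(dt$data[[dt$decision]]))
    equal_frequency_cuts(dt, dt$decision, decision_bins) else NULL
  cuts <- if (discretizer == "md") md_select_cuts(dt, decision_cuts = dcuts)
          else equal_frequency_cutset(dt, eq_bins, decision_cuts = dcuts)
  apply_cuts(dt, cuts, dialect = dialect)
}

#' Run a preset experiment end-to-end
#'
#' Projects the input to the preset's attributes, forms the decision table
#' (the patient number is included as a nominal condition unless
#' `include_patient = FALSE`), optionally oversamples, discretizes, and
#' cross-validates over the given fold seeds. Returns the cut set, starred
#' attributes, the rules induced on the full discretized table, per-seed
#' confusion matrices and the multi-seed metric summary; optionally writes
#' the bundle to `out_dir`.
#'
#' @param x An `infotable` (e.g. a generated cohort or [load_table()] result).
#' @param preset Preset name or an [experiment_preset()] list.
#' @param folds Folds per run (`"loo"` for leave-one-out).
#' @param seeds Fold seeds; the headline metrics are means over these.
#' @param classifier `"decomposition-tree"`, `"rough-rules"`, or a baseline
#'   kind (`"naive-bayes"`, `"decision-tree"`, `"decision-table-majority"`,
#'   `"tree-ensemble"`).
#' @param discretizer `"md"` (decision-aware) or `"eqfreq"`.
#' @param dialect Interval label dialect.
#' @param smote Oversample (SMOTE, 3 nearest neighbors, factor 3)?
#' @param cuts_per_fold Recompute cuts on each training fold (leakage-free)
#'   instead of once globally.
#' @param min_leaf Decomposition-tree leaf threshold.
#' @param include_patient Keep the patient number as a condition attribute.
#' @param stratified Stratify folds on the decision label.
#' @param out_dir Optional output directory.
#' @return Results bundle (list).
#' @export
run_experiment <- function(x, preset = "E1", folds = 6L, seeds = 1:10,
                           classifier = "decomposition-tree",
                           discretizer = "md", dialect = "rses",
                           smote = FALSE, cuts_per_fold = FALSE,
                           min_leaf = 3L, include_patient = TRUE,
                           stratified = FALSE, out_dir = NULL) {
  pr <- if (is.character(preset)) experiment_preset(preset) else preset
  conds <- pr$conditions
  if (!include_patient) conds <- setdiff(conds, "Pat")
  needed <- unique(c(conds, pr$decision))
  absent <- setdiff(needed, x$schema$name)
  if (length(absent))
    stop("input schema lacks attribute(s) required by preset ", pr$name, ": ",
         paste(absent, collapse = ", "),
         " (available: ", paste(x$schema$name, collapse = ", "), ")")
  dt <- as_decision_table(project(x, needed), pr$decision, conditions = conds)
  if (smote) dt <- smote_oversample(dt, k_neighbors = 3L, factor = 3L,
                                    seed = seeds[1L])
  baseline_kinds <- c("naive-bayes", "decision-tree",
                      "decision-table-majority", "tree-ensemble")
  cv_args <- if (classifier %in% baseline_kinds) {
    list(classifier = "baseline", baseline = baseline_spec(classifier))
  } else {
    list(classifier = classifier)
  }
  if (cuts_per_fold) {
    res <- cv_per_fold_cuts(dt, folds, seeds, discretizer, pr$decision_bins,
                            dialect, cv_args, min_leaf, stratified)
    disc <- NULL
  } else {
    disc <- discretize_table(dt, discretizer,
                             decision_bins = pr$decision_bins %||% 4L,
                             dialect = dialect)
    res <- do.call(cv_multi_seed,
                   c(list(x = disc, k = folds, seeds = seeds,
                          stratified = stratified, min_leaf = min_leaf),
                     cv_args))
  }
  bundle <- list(
    preset = pr, folds = folds, seeds = seeds, classifier = classifier,
    discretizer = discretizer, dialect = dialect, smote = smote,
    cuts_per_fold = cuts_per_fold, min_leaf = min_leaf,
    cuts = if (!is.null(disc)) disc$cuts else NULL,
    starred = if (!is.null(disc)) disc$cuts$starred else NULL,
    rules = if (!is.null(disc)) induce_rules(disc) else NULL,
    metrics = res$mean, metrics_sd = res$sd, per_seed = res$per_seed,
    cms = res$cms,
    version = as.character(utils::packageVersion("roughpd")))
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

# Leakage-free variant: per fold, decision bins and condition cuts come from
# the training part only; class bookkeeping uses bin indices since interval
# labels differ across folds.
cv_per_fold_cuts <- function(dt, k, seeds, discretizer, decision_bins,
                             dialect, cv_args, min_leaf, stratified) {
  d_raw <- decision_values(dt)
  numeric_dec <- is.numeric(d_raw)
  nb <- decision_bins %||% 4L
  classes <- if (numeric_dec) paste0("bin", seq_len(nb)) else
    sort(unique(as.character(d_raw)))
  rows <- list(); cms <- list()
  for (s in seeds) {
    fp <- make_folds(n_objects(dt), k, seed = s,
                     labels = as.character(d_raw), stratified = stratified)
    cm <- new_cm(classes, fp$k)
    for (f in seq_len(fp$k)) {
      tr <- filter_objects(dt, dt$ids[fp$assignment != f])
      te_pos <- which(fp$assignment == f)
      dcuts <- if (numeric_dec) equal_frequency_cuts(tr, dt$decision, nb)
               else NULL
      cuts <- if (discretizer == "md") md_select_cuts(tr, decision_cuts = dcuts)
              else equal_frequency_cutset(tr, 4L, decision_cuts = dcuts)
      tr_disc <- apply_cuts(tr, cuts, dialect = dialect)
      te_disc <- apply_cuts(filter_objects(dt, dt$ids[te_pos]), cuts,
                            dialect = dialect)
      predict_one <- if (identical(cv_args$classifier, "baseline")) {
        model <- train_baseline(cv_args$baseline, tr_disc, seed = s + f)
        function(obj) predict_baseline(model, obj)
      } else if (identical(cv_args$classifier, "rough-rules")) {
        rules <- induce_rules(tr_disc)
        function(obj) classify_rules(rules, obj)
      } else {
        tree <- build_tree(tr_disc, min_leaf = min_leaf)
        function(obj) classify_tree(tree, obj)
      }
      lab_to_class <- function(lab, raw_value) {
        if (!numeric_dec) return(lab)
        paste0("bin", findInterval(raw_value, dcuts) + 1L)
      }
      conds <- condition_attrs(te_disc)
      for (i in seq_len(n_objects(te_disc))) {
        obj <- as_record(te_disc, i, conds)
        pred <- predict_one(obj)
        cm$total <- cm$total + 1L
        if (!is.na(pred)) {
          cm$covered <- cm$covered + 1L
          actual <- if (numeric_dec)
            paste0("bin", findInterval(d_raw[te_pos[i]], dcuts) + 1L)
          else as.character(d_raw[te_pos[i]])
          pred_cls <- if (numeric_dec) {
            # map the predicted interval label back to its bin index
            mids <- c(dcuts[1] - 1,
                      if (length(dcuts) > 1) (dcuts[-length(dcuts)] + dcuts[-1]) / 2,
                      dcuts[length(dcuts)] + 1)
            labs <- interval_label(mids, dcuts, dialect)
            paste0("bin", match(pred, labs))
          } else pred
          if (!is.na(pred_cls) && pred_cls %in% classes)
            cm$counts[actual, pred_cls] <- cm$counts[actual, pred_cls] + 1L
        }
      }
    }
    g <- global_metrics(cm)
    rows[[length(rows) + 1L]] <-
      data.frame(seed = s, accuracy = g[["accuracy"]],
                 coverage = g[["coverage"]], mcc = mcc(cm),
                 kappa = cohen_kappa(cm))
    cms[[length(cms) + 1L]] <- cm
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed, mean = colMeans(per_seed[, -1L]),
       sd = vapply(per_seed[, -1L], stats::sd, numeric(1)), cms = cms)
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  if (!is.null(bundle$cuts))
    cutset_to_json(bundle$cuts, file.path(out_dir, "cuts.json"))
  if (!is.null(bundle$rules))
    write_rules(bundle$rules, file.path(out_dir, "rules.txt"),
                file.path(out_dir, "rules.json"))
  for (i in seq_along(bundle$cms))
    write_cm(bundle$cms[[i]],
             file.path(out_dir, sprintf("confusion_seed%02d.csv", i)))
  metrics <- list(preset = bundle$preset$name, classifier = bundle$classifier,
                  folds = bundle$folds, seeds = bundle$seeds,
                  metrics_mean = as.list(bundle$metrics),
                  metrics_sd = as.list(bundle$metrics_sd),
                  version = bundle$version)
  writeLines(jsonlite::toJSON(metrics, auto_unbox = TRUE, digits = NA),
             file.path(out_dir, "metrics.json"))
  log_lines <- c(
    sprintf("preset: %s", bundle$preset$name),
    sprintf("decision: %s", bundle$preset$decision),
    sprintf("conditions: %s", paste(bundle$preset$conditions, collapse = ", ")),
    sprintf("classifier: %s", bundle$classifier),
    sprintf("folds: %s, seeds: %s", bundle$folds,
            paste(bundle$seeds, collapse = ",")),
    sprintf("discretizer: %s, dialect: %s, smote: %s, cuts_per_fold: %s",
            bundle$discretizer, bundle$dialect, bundle$smote,
            bundle$cuts_per_fold),
    sprintf("version: %s", bundle$version))
  writeLines(log_lines, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
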