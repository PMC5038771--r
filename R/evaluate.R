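# Cross-validation with abstention-aware bookkeeping, fold-averaged confusion
# matrices, global/per-class metrics, MCC, Cohen's kappa and SMOTE-style
# oversampling.

# Run code under a temporary RNG state seeded with `seed`, restoring the
# caller's stream afterwards.
rpd_with_seed <- function(seed, code) {
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    stats::runif(1)
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()))
  set.seed(as.integer(seed))
  code
}

#' Plan cross-validation folds
#'
#' Seeded shuffle followed by round-robin assignment; fold sizes differ by at
#' most one. Stratified mode balances decision labels across folds. `k = n`
#' gives leave-one-out.
#'
#' @param n Number of objects.
#' @param k Number of folds (2..n), or `"loo"`.
#' @param seed Integer seed (same seed, same assignment).
#' @param labels Decision labels, required for `stratified = TRUE`.
#' @param stratified Balance labels across folds?
#' @return Object of class `foldplan`: `k`, `seed`, `assignment` (fold index
#'   per object position), `stratified`.
#' @export
make_folds <- function(n, k, seed, labels = NULL, stratified = FALSE) {
  if (identical(k, "loo")) k <- n
  k <- as.integer(k)
  if (k > n) stop("k = ", k, " exceeds number of objects n = ", n)
  if (k < 2L) stop("k must be at least 2")
  assignment <- integer(n)
  rpd_with_seed(seed, {
    if (stratified) {
      if (is.null(labels) || length(labels) != n)
        stop("stratified folds require one label per object")
      perm <- sample.int(n)
      counter <- 0L
      for (grp in split(perm, as.character(labels)[perm])) {
        for (i in grp) {
          assignment[i] <- counter %% k + 1L
          counter <- counter + 1L
        }
      }
    } else {
      perm <- sample.int(n)
      assignment[perm] <- rep_len(seq_len(k), n)
    }
  })
  structure(list(k = k, seed = as.integer(seed), assignment = assignment,
                 stratified = stratified),
            class = "foldplan")
}

new_cm <- function(classes, k) {
  counts <- matrix(0L, length(classes), length(classes),
                   dimnames = list(actual = classes, predicted = classes))
  structure(list(classes = classes, counts = counts, k = k,
                 covered = 0L, total = 0L),
            class = "rough_cm")
}

#' Fold-averaged entries of a confusion matrix
#'
#' Accumulated integer counts divided by the number of folds, the convention
#' under which every printed entry times `k` is an integer.
#' @param cm A `rough_cm`.
#' @export
cm_averaged <- function(cm) cm$counts / cm$k

#' @export
print.rough_cm <- function(x, digits = 2, ...) {
  avg <- round(cm_averaged(x), digits)
  per <- per_class_metrics(x)
  disp <- cbind(as.data.frame(avg), ACC = round(per$ACC, digits))
  disp <- rbind(disp, TPR = c(round(per$TPR, digits), NA))
  print(disp)
  g <- global_metrics(x)
  cat(sprintf("global accuracy %.3f, global coverage %.3f (k = %d folds)\n",
              g[["accuracy"]], g[["coverage"]], x$k))
  invisible(x)
}

#' Write a confusion matrix as CSV (predicted columns, actual rows)
#'
#' Layout mirrors the published tables: fold-averaged entries, a trailing
#' `ACC` column and a trailing `TPR` row.
#' @param cm A `rough_cm`.
#' @param path Output path.
#' @export
write_cm <- function(cm, path) {
  avg <- cm_averaged(cm)
  per <- per_class_metrics(cm)
  out <- cbind(as.data.frame(avg), ACC = per$ACC)
  out <- rbind(out, TPR = c(per$TPR, NA))
  utils::write.csv(out, path, row.names = TRUE)
  invisible(path)
}

#' Cross-validate a classifier on a discretized decision table
#'
#' Per fold: train on the remaining folds, classify the held-out objects, and
#' accumulate integer counts over covered objects (abstentions never enter
#' the matrix). Final matrix entries are accumulated counts divided by `k`;
#' all metrics are computed from the accumulated (pre-division) counts.
#'
#' @param x A `disctable` (for rule classifiers and discrete baselines).
#' @param folds A [make_folds()] plan over `n_objects(x)`.
#' @param classifier `"decomposition-tree"`, `"rough-rules"` or `"baseline"`.
#' @param baseline A [baseline_spec()] when `classifier = "baseline"`.
#' @param min_leaf Decomposition-tree leaf threshold.
#' @param vote Rule voting scheme.
#' @param rule_attrs Rule induction method: `"minimal"` (object-wise minimal
#'   consistent rules, the default), `"reducts"` (rules over every exhaustive
#'   reduct) or `"all"` (full non-starred antecedents).
#' @param seed Seed for stochastic baselines (defaults to the fold seed).
#' @return A `rough_cm`.
#' @export
cross_validate <- function(x, folds,
                           classifier = c("decomposition-tree", "rough-rules",
                                          "baseline"),
                           baseline = NULL, min_leaf = 3L, vote = "weighted",
                           rule_attrs = c("minimal", "reducts", "all"),
                           seed = folds$seed) {
  classifier <- match.arg(classifier)
  rule_attrs <- match.arg(rule_attrs)
  n <- n_objects(x)
  stopifnot(length(folds$assignment) == n)
  classes <- decision_classes(x)
  cm <- new_cm(classes, folds$k)
  d <- as.character(decision_values(x))
  conds <- condition_attrs(x)
  for (f in seq_len(folds$k)) {
    tr_pos <- which(folds$assignment != f)
    te_pos <- which(folds$assignment == f)
    if (!length(te_pos)) next
    train <- filter_objects(x, x$ids[tr_pos])
    if (!all(unique(d[te_pos]) %in% d[tr_pos]))
      message("fold ", f, ": decision class absent from training; ",
              "held-out objects of that class may abstain")
    predict_one <- switch(
      classifier,
      "decomposition-tree" = {
        tree <- build_tree(train, min_leaf = min_leaf,
                           rule_method = if (rule_attrs == "reducts")
                             "reducts" else "minimal")
        function(obj) classify_tree(tree, obj, scheme = vote)
      },
      "rough-rules" = {
        rules <- switch(rule_attrs,
                        minimal = minimal_rules(train),
                        reducts = reduct_rules(train),
                        all = induce_rules(train))
        function(obj) classify_rules(rules, obj, scheme = vote)
      },
      "baseline" = {
        if (is.null(baseline)) stop("baseline spec required")
        model <- train_baseline(baseline, train, seed = seed + f)
        function(obj) predict_baseline(model, obj)
      })
    for (i in te_pos) {
      obj <- as_record(x, i, conds)
      pred <- predict_one(obj)
      cm$total <- cm$total + 1L
      if (!is.na(pred)) {
        cm$covered <- cm$covered + 1L
        if (!pred %in% classes) next # cannot happen for rule classifiers
        cm$counts[d[i], pred] <- cm$counts[d[i], pred] + 1L
      }
    }
  }
  cm
}

#' Global accuracy and coverage
#'
#' Coverage is the fraction of tested objects any rule covered; accuracy is
#' the fraction correct among covered objects (abstentions excluded), so the
#' two are reported separately.
#'
#' @param cm A `rough_cm`.
#' @return Named numeric `c(accuracy, coverage)` (empty denominators give 0).
#' @export
global_metrics <- function(cm) {
  correct <- sum(diag(cm$counts))
  acc <- if (cm$covered > 0L) correct / cm$covered else 0
  cov <- if (cm$total > 0L) cm$covered / cm$total else 0
  c(accuracy = acc, coverage = cov)
}

#' Per-class true-positive rate and accuracy
#'
#' `TPR(c)` normalizes the diagonal entry by its predicted-class column sum;
#' `ACC(c)` by its actual-class row sum (the published table layout). Empty
#' denominators give 0.
#'
#' @param cm A `rough_cm`.
#' @return Data frame with `class`, `TPR`, `ACC`.
#' @export
per_class_metrics <- function(cm) {
  dg <- diag(cm$counts)
  cs <- colSums(cm$counts)
  rs <- rowSums(cm$counts)
  data.frame(class = cm$classes,
             TPR = ifelse(cs > 0, dg / cs, 0),
             ACC = ifelse(rs > 0, dg / rs, 0),
             row.names = NULL)
}

#' Matthews correlation coefficient
#'
#' Computed from the accumulated counts; for more than two classes the
#' generalized (covariance) form is used, which reduces to the familiar
#' `(TP*TN - FP*FN) / sqrt(...)` for a 2x2 matrix. A zero denominator yields
#' 0 with a warning.
#'
#' @param cm A `rough_cm` or plain count matrix.
#' @return Value in `[-1, 1]`.
#' @export
mcc <- function(cm) {
  C <- if (inherits(cm, "rough_cm")) cm$counts else as.matrix(cm)
  s <- sum(C)
  trace <- sum(diag(C))
  pk <- colSums(C) # predicted per class
  tk <- rowSums(C) # actual per class
  num <- trace * s - sum(pk * tk)
  den <- sqrt(s^2 - sum(pk^2)) * sqrt(s^2 - sum(tk^2))
  if (den == 0) {
    warning("MCC denominator is zero; returning 0")
    return(0)
  }
  num / den
}

#' Cohen's kappa
#'
#' Chance-corrected agreement between actual and predicted labels, from the
#' accumulated counts. A degenerate denominator yields 0 with a warning.
#'
#' @param cm A `rough_cm` or plain count matrix.
#' @export
cohen_kappa <- function(cm) {
  C <- if (inherits(cm, "rough_cm")) cm$counts else as.matrix(cm)
  s <- sum(C)
  if (s == 0) {
    warning("empty confusion matrix; returning 0")
    return(0)
  }
  po <- sum(diag(C)) / s
  pe <- sum(colSums(C) * rowSums(C)) / s^2
  if (abs(1 - pe) < 1e-12) {
    warning("kappa denominator is zero; returning 0")
    return(0)
  }
  (po - pe) / (1 - pe)
}

#' SMOTE-style oversampling of a raw decision table
#'
#' Every record spawns `factor - 1` synthetic records interpolated toward a
#' randomly chosen one of its `k_neighbors` nearest same-class neighbors
#' (Euclidean distance on standardized numeric condition attributes); nominal
#' and identifier attributes are copied from the seed record. A class with
#' fewer members than `k_neighbors + 1` uses all available neighbors (with a
#' warning); a singleton class duplicates itself.
#'
#' @param x A `decisiontable` with numeric condition attributes.
#' @param k_neighbors Number of nearest neighbors (>= 1).
#' @param factor Oversampling factor (3 triples the table).
#' @param seed Integer seed.
#' @return A `decisiontable` with `n * factor` records (new ids appended).
#' @export
smote_oversample <- function(x, k_neighbors = 3L, factor = 3L, seed = 1L) {
  stopifnot(inherits(x, "decisiontable"), k_neighbors >= 1L, factor >= 1L)
  if (factor == 1L) return(x)
  conds <- condition_attrs(x)
  kinds <- x$schema$kind[match(conds, x$schema$name)]
  num_attrs <- conds[kinds == "numeric"]
  n <- n_objects(x)
  d <- as.character(decision_values(x))
  Z <- sapply(num_attrs, function(a) {
    v <- x$data[[a]]
    s <- stats::sd(v, na.rm = TRUE)
    if (is.na(s) || s == 0) rep(0, n) else (v - mean(v, na.rm = TRUE)) / s
  })
  Z[is.na(Z)] <- 0
  Z <- matrix(Z, nrow = n)
  new_rows <- list()
  warned <- FALSE
  rpd_with_seed(seed, {
    for (i in seq_len(n)) {
      same <- setdiff(which(d == d[i]), i)
      if (!length(same)) same <- i # singleton class: zero interpolation span
      kk <- min(k_neighbors, length(same))
      if (kk < k_neighbors && !warned) {
        warning("class '", d[i], "' has fewer than k_neighbors + 1 members; ",
                "using all available neighbors")
        warned <- TRUE
      }
      dist2 <- colSums((t(Z[same, , drop = FALSE]) - Z[i, ])^2)
      nb <- same[order(dist2)][seq_len(kk)]
      for (s in seq_len(factor - 1L)) {
        j <- nb[sample.int(kk, 1L)]
        u <- stats::runif(1)
        row <- x$data[i, , drop = FALSE]
        for (a in num_attrs) {
          vi <- x$data[[a]][i]; vj <- x$data[[a]][j]
          row[[a]] <- if (is.na(vi) || is.na(vj)) vi else vi + u * (vj - vi)
        }
        new_rows[[length(new_rows) + 1L]] <- row
      }
    }
  })
  aug <- rbind(x$data, do.call(rbind, new_rows))
  ids <- c(x$ids, max(x$ids) + seq_len(length(new_rows)))
  out <- information_table(aug, x$schema, ids = ids)
  out$decision <- x$decision
  class(out) <- class(x)
  out
}

#' Cross-validate over several seeds
#'
#' Repeats [cross_validate()] with a fresh fold plan per seed and reports the
#' per-seed global metrics plus their mean and standard deviation; single-run
#' results are seed-dependent, so multi-seed means are the headline numbers.
#'
#' @param x A `disctable`.
#' @param k Folds per run.
#' @param seeds Integer vector of fold seeds (default 10 seeds).
#' @param stratified Stratify folds on the decision?
#' @param ... Passed to [cross_validate()].
#' @return List with `per_seed` (data frame), `mean`, `sd`, and `cms` (the
#'   per-seed confusion matrices).
#' @export
cv_multi_seed <- function(x, k, seeds = 1:10, stratified = FALSE, ...) {
  d <- as.character(decision_values(x))
  rows <- list(); cms <- list()
  for (s in seeds) {
    fp <- make_folds(n_objects(x), k, seed = s, labels = d,
                     stratified = stratified)
    cm <- cross_validate(x, fp, ...)
    g <- global_metrics(cm)
    rows[[length(rows) + 1L]] <-
      data.frame(seed = s, accuracy = g[["accuracy"]],
                 coverage = g[["coverage"]], mcc = mcc(cm),
                 kappa = cohen_kappa(cm))
    cms[[length(cms) + 1L]] <- cm
  }
  per_seed <- do.call(rbind, rows)
  list(per_seed = per_seed,
       mean = colMeans(per_seed[, -1L]),
       sd = vapply(per_seed[, -1L], stats::sd, numeric(1)),
       cms = cms)
}
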