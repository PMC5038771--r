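# Reference classifiers mirroring the comparison set: categorical naive
# Bayes (default probability 0, 20-value cap per attribute), a gini decision
# tree (rpart, min node size 2, no pruning), a majority decision table over a
# selected attribute subset, and a bagged tree ensemble with per-tree
# square-root attribute sampling. Unlike the rule classifiers, baselines
# always emit a label (coverage 1).

#' Baseline classifier specification
#'
#' @param kind One of `"naive-bayes"`, `"decision-tree"`,
#'   `"decision-table-majority"`, `"tree-ensemble"`.
#' @param ... Hyperparameters: naive-bayes takes `default_prob` (0) and
#'   `max_nominal` (20); decision-tree takes `minsplit` (2) and `cp` (0, no
#'   pruning); decision-table-majority takes `attrs` (default: greedy reduct);
#'   tree-ensemble takes `n_trees` (100), `mtry` (default floor(sqrt(p))) and
#'   `bootstrap` (TRUE).
#' @export
baseline_spec <- function(kind = c("naive-bayes", "decision-tree",
                                   "decision-table-majority", "tree-ensemble"),
                          ...) {
  kind <- match.arg(kind)
  hp <- list(...)
  defaults <- switch(kind,
    "naive-bayes" = list(default_prob = 0, max_nominal = 20L),
    "decision-tree" = list(minsplit = 2L, cp = 0),
    "decision-table-majority" = list(attrs = NULL),
    "tree-ensemble" = list(n_trees = 100L, mtry = NULL, bootstrap = TRUE))
  unknown <- setdiff(names(hp), names(defaults))
  if (length(unknown))
    stop("unknown hyperparameter(s) for ", kind, ": ",
         paste(unknown, collapse = ", "))
  hp <- utils::modifyList(defaults, hp)
  structure(list(kind = kind, hp = hp), class = "baseline_spec")
}

prep_factor_frame <- function(x, conds, class_levels = NULL) {
  df <- x$data[, conds, drop = FALSE]
  for (a in conds) df[[a]] <- factor(as.character(df[[a]]))
  df
}

#' Train a baseline classifier
#'
#' @param spec A [baseline_spec()].
#' @param x A discretized (or otherwise discrete-valued) `decisiontable`.
#' @param seed Seed for stochastic kinds (tree ensemble bootstrap/sampling).
#' @return A `baseline_model`.
#' @export
train_baseline <- function(spec, x, seed = 1L) {
  stopifnot(inherits(spec, "baseline_spec"), inherits(x, "decisiontable"))
  conds <- condition_attrs(x)
  d <- as.character(decision_values(x))
  classes <- decision_classes(x)
  majority <- classes[which.max(vapply(classes, function(cl) sum(d == cl), 0L))]
  fit <- switch(
    spec$kind,
    "naive-bayes" = {
      counts <- lapply(conds, function(a) {
        v <- as.character(x$data[[a]])
        vals <- unique(v[!is.na(v)])
        if (length(vals) > spec$hp$max_nominal)
          stop("attribute '", a, "' has ", length(vals),
               " nominal values, over the cap of ", spec$hp$max_nominal)
        table(factor(d[!is.na(v)], levels = classes),
              factor(v[!is.na(v)], levels = vals))
      })
      names(counts) <- conds
      list(priors = table(factor(d, levels = classes)) / length(d),
           counts = counts)
    },
    "decision-tree" = {
      df <- prep_factor_frame(x, conds)
      df$.dec <- factor(d, levels = classes)
      rpart::rpart(.dec ~ ., data = df, method = "class",
                   parms = list(split = "gini"),
                   control = rpart::rpart.control(
                     minsplit = spec$hp$minsplit, minbucket = 1L,
                     cp = spec$hp$cp, xval = 0L))
    },
    "decision-table-majority" = {
      attrs <- spec$hp$attrs %||% reduct_greedy(x)$attrs
      if (!length(attrs)) attrs <- conds
      key <- ind_key(x, attrs)
      lookup <- tapply(d, key, function(lab) {
        tt <- table(factor(lab, levels = classes))
        classes[which.max(tt)]
      })
      list(attrs = attrs, lookup = lookup)
    },
    "tree-ensemble" = {
      p <- length(conds)
      mtry <- spec$hp$mtry %||% max(1L, floor(sqrt(p)))
      df <- prep_factor_frame(x, conds)
      df$.dec <- factor(d, levels = classes)
      n <- nrow(df)
      rpd_with_seed(seed, {
        trees <- lapply(seq_len(spec$hp$n_trees), function(b) {
          rows <- if (spec$hp$bootstrap) sample.int(n, n, replace = TRUE)
                  else seq_len(n)
          feats <- sort(sample(conds, mtry))
          fit <- rpart::rpart(
            .dec ~ ., data = df[rows, c(feats, ".dec"), drop = FALSE],
            method = "class", parms = list(split = "gini"),
            control = rpart::rpart.control(minsplit = 2L, minbucket = 1L,
                                           cp = 0, xval = 0L))
          list(fit = fit, feats = feats)
        })
        trees
      })
    })
  structure(list(kind = spec$kind, hp = spec$hp, fit = fit, conds = conds,
                 classes = classes, majority = majority, decision = x$decision),
            class = "baseline_model")
}

predict_baseline_one <- function(model, object) {
  classes <- model$classes
  switch(
    model$kind,
    "naive-bayes" = {
      # default probability 0 for unseen values; MISSING attributes skipped;
      # an all-zero posterior falls back to the majority class
      post <- as.numeric(model$fit$priors)
      for (a in model$conds) {
        v <- object[[a]]
        if (is.na(v)) next
        tab <- model$fit$counts[[a]]
        lk <- if (v %in% colnames(tab)) {
          cc <- tab[, v]
          tot <- rowSums(tab)
          ifelse(tot > 0, cc / tot, model$hp$default_prob)
        } else rep(model$hp$default_prob, length(classes))
        post <- post * as.numeric(lk)
      }
      if (all(post == 0)) model$majority else classes[which.max(post)]
    },
    "decision-tree" = {
      nd <- as.data.frame(lapply(object[model$conds], function(v) v),
                          stringsAsFactors = FALSE)
      names(nd) <- model$conds
      for (a in model$conds) {
        lev <- attr(model$fit, "xlevels")[[a]] %||%
          levels(model$fit$model[[a]])
        nd[[a]] <- factor(nd[[a]], levels = lev %||% unique(nd[[a]]))
      }
      pr <- predict(model$fit, newdata = nd, type = "prob")
      cls <- colnames(pr)[which.max(pr[1L, ])]
      cls
    },
    "decision-table-majority" = {
      v <- object[model$fit$attrs]
      v[is.na(v)] <- NA_KEY
      key <- paste(v, collapse = "\r")
      hit <- model$fit$lookup[key]
      if (is.na(hit)) model$majority else unname(hit)
    },
    "tree-ensemble" = {
      votes <- stats::setNames(rep(0, length(classes)), classes)
      for (tr in model$fit) {
        nd <- as.data.frame(as.list(object[tr$feats]), stringsAsFactors = FALSE)
        names(nd) <- tr$feats
        for (a in tr$feats) {
          lev <- attr(tr$fit, "xlevels")[[a]]
          nd[[a]] <- factor(nd[[a]], levels = lev %||% unique(nd[[a]]))
        }
        pr <- predict(tr$fit, newdata = nd, type = "prob")
        cls <- colnames(pr)[which.max(pr[1L, ])]
        votes[cls] <- votes[cls] + 1
      }
      classes[which.max(votes[classes])]
    })
}

#' Predict with a baseline classifier
#'
#' Baselines always produce a label (never abstain); comparisons against the
#' rule classifiers therefore contrast accuracy-on-all with
#' accuracy-on-covered.
#'
#' @param model A `baseline_model`.
#' @param newdata A named character vector (one labelled record), a data
#'   frame of labels, or a table object.
#' @return Character vector of predicted labels.
#' @export
predict_baseline <- function(model, newdata) {
  if (is.character(newdata) && !is.null(names(newdata)))
    return(predict_baseline_one(model, newdata))
  df <- if (inherits(newdata, "infotable")) newdata$data else newdata
  vapply(seq_len(nrow(df)), function(i) {
    obj <- vapply(model$conds, function(a) as.character(df[[a]][i]), character(1))
    names(obj) <- model$conds
    predict_baseline_one(model, obj)
  }, character(1))
}
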