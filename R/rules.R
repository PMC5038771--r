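# Decision-rule induction, rule rendering/parsing, voting classification,
# templates and the decomposition-tree classifier.

#' Construct a decision rule
#'
#' @param antecedent Named character vector: attribute -> required label.
#' @param consequent Decision label.
#' @param support Count of training objects matching the antecedent.
#' @param confidence Fraction of antecedent-matching objects carrying the
#'   consequent decision (in (0, 1]).
#' @param decision Decision attribute name.
#' @export
decision_rule <- function(antecedent, consequent, support = NA_integer_,
                          confidence = NA_real_, decision = "D") {
  structure(list(antecedent = antecedent, consequent = consequent,
                 support = support, confidence = confidence,
                 decision = decision),
            class = "decisionrule")
}

#' @export
print.decisionrule <- function(x, ...) {
  cat(format_rule(x), sprintf(" [support %s, confidence %.3g]\n",
                              x$support, x$confidence))
  invisible(x)
}

# A labelled record: named character vector over (a subset of) attributes.
as_record <- function(x, i, attrs = NULL) {
  if (is.null(attrs)) attrs <- setdiff(names(x$data), character(0))
  r <- vapply(attrs, function(a) as.character(x$data[[a]][i]), character(1))
  names(r) <- attrs
  r
}

match_antecedent <- function(antecedent, records) {
  # records: data.frame of labels; returns logical vector (NA never matches)
  if (!length(antecedent)) return(rep(TRUE, nrow(records)))
  ok <- rep(TRUE, nrow(records))
  for (a in names(antecedent)) {
    v <- as.character(records[[a]])
    ok <- ok & !is.na(v) & v == antecedent[[a]]
  }
  ok
}

#' Induce decision rules from a discretized table
#'
#' One candidate rule per distinct antecedent pattern over `attrs` (starred
#' and MISSING descriptors are dropped); identical antecedents are merged;
#' an inconsistent antecedent yields one rule per decision label, each with
#' its own confidence. Support and confidence are recomputed over the whole
#' training table.
#'
#' @param x A `disctable` (or decision table with discrete values).
#' @param attrs Condition attributes to describe with (typically a reduct or
#'   all non-starred conditions, the default).
#' @return List of [decision_rule()] objects.
#' @export
induce_rules <- function(x, attrs = NULL) {
  if (is.null(attrs)) attrs <- non_starred_conditions(x)
  if (!length(attrs)) stop("attrs must be nonempty")
  n <- n_objects(x)
  if (n == 0L) return(list())
  d <- as.character(decision_values(x))
  recs <- x$data[, attrs, drop = FALSE]
  ants <- lapply(seq_len(n), function(i) {
    r <- vapply(attrs, function(a) as.character(recs[[a]][i]), character(1))
    r <- r[!is.na(r) & r != "*"]
    r
  })
  keys <- vapply(ants, function(a)
    paste(names(a), a, sep = "\r=", collapse = "\r&"), character(1))
  first <- !duplicated(keys)
  rules <- list()
  for (i in which(first)) {
    ant <- ants[[i]]
    m <- match_antecedent(ant, recs)
    support <- sum(m)
    tab <- table(d[m])
    labs <- names(tab)[order(-as.integer(tab), match(names(tab), d[m]))]
    for (lab in labs) {
      rules[[length(rules) + 1L]] <-
        decision_rule(ant, lab, support = support,
                      confidence = as.integer(tab[[lab]]) / support,
                      decision = x$decision)
    }
  }
  rules
}

non_starred_conditions <- function(x) {
  conds <- condition_attrs(x)
  starred <- if (!is.null(x$cuts)) x$cuts$starred else
    conds[vapply(conds, function(a) all(x$data[[a]] == "*"), logical(1))]
  setdiff(conds, starred)
}

#' Classify a labelled record by rule voting
#'
#' Rules whose antecedent matches the record vote for their consequent with
#' weight support x confidence (`scheme = "weighted"`, the standard vote) or
#' one vote each (`scheme = "simple"`). The label with the highest total wins;
#' ties break by the larger maximum rule support, then by first-seen rule
#' order. A record matching no rule is uncovered and yields `NA` (ABSTAIN).
#'
#' @param rules List of [decision_rule()]s.
#' @param object Named character vector of labels (same cuts as training).
#' @param scheme `"weighted"` or `"simple"`.
#' @return Decision label, or `NA_character_` for ABSTAIN.
#' @export
classify_rules <- function(rules, object, scheme = c("weighted", "simple")) {
  scheme <- match.arg(scheme)
  if (!length(rules)) return(NA_character_)
  hit <- vapply(rules, function(r) {
    v <- object[names(r$antecedent)]
    length(r$antecedent) == 0L ||
      (!anyNA(v) && all(v == r$antecedent))
  }, logical(1))
  if (!any(hit)) return(NA_character_)
  mr <- rules[hit]
  labs <- vapply(mr, function(r) r$consequent, character(1))
  w <- if (scheme == "weighted")
    vapply(mr, function(r) r$support * r$confidence, numeric(1))
  else rep(1, length(mr))
  tot <- tapply(w, factor(labs, levels = unique(labs)), sum)
  best <- max(tot)
  tied <- names(tot)[tot >= best - 1e-12]
  if (length(tied) > 1L) {
    sup <- vapply(tied, function(L)
      max(vapply(mr[labs == L], function(r) r$support, numeric(1))), numeric(1))
    tied <- tied[sup == max(sup)]
  }
  tied[1L] # first-seen order preserved by unique(labs) levels
}

#' Render a rule in conjunctive normal text form
#'
#' Produces `('attr' = value) & ... => ('decision' = label)`; interval labels
#' are double-quoted, nominal values printed plain. An empty antecedent
#' renders as the degenerate `=> (...)` form.
#'
#' @param rule A [decision_rule()].
#' @export
format_rule <- function(rule) {
  fmt_val <- function(v) {
    if (grepl("^[\\(\\[]", v)) paste0("\"", v, "\"") else v
  }
  lhs <- if (length(rule$antecedent)) {
    paste(vapply(names(rule$antecedent), function(a)
      sprintf("('%s' = %s)", a, fmt_val(rule$antecedent[[a]])), character(1)),
      collapse = " & ")
  } else ""
  rhs <- sprintf("('%s' = %s)", rule$decision, fmt_val(rule$consequent))
  if (nzchar(lhs)) paste(lhs, "=>", rhs) else paste("=>", rhs)
}

#' Parse a rule rendered by [format_rule()]
#'
#' Inverse of [format_rule()] up to support/confidence (not serialized in the
#' text form).
#'
#' @param text One rule string.
#' @export
parse_rule <- function(text) {
  parts <- strsplit(text, "=>", fixed = TRUE)[[1L]]
  if (length(parts) != 2L) stop("malformed rule text: ", text)
  scan_desc <- function(s) {
    m <- gregexpr("\\('([^']+)' = (\"[^\"]*\"|[^)]*)\\)", s)[[1L]]
    if (m[1L] == -1L) return(stats::setNames(character(0), character(0)))
    out <- character(0)
    for (k in seq_along(m)) {
      frag <- substr(s, m[k], m[k] + attr(m, "match.length")[k] - 1L)
      nm <- sub("^\\('([^']+)'.*$", "\\1", frag)
      val <- sub("^\\('[^']+' = (.*)\\)$", "\\1", frag)
      val <- sub("^\"(.*)\"$", "\\1", val)
      out[nm] <- val
    }
    out
  }
  ant <- scan_desc(parts[1L])
  con <- scan_desc(parts[2L])
  if (length(con) != 1L) stop("malformed rule consequent: ", text)
  decision_rule(ant, con[[1L]], decision = names(con))
}

#' Write rules to a text file (one per line) and optionally JSON
#'
#' @param rules List of rules.
#' @param path Text file path.
#' @param json_path Optional JSON path carrying support/confidence.
#' @export
write_rules <- function(rules, path, json_path = NULL) {
  writeLines(vapply(rules, format_rule, character(1)), path)
  if (!is.null(json_path)) {
    obj <- lapply(rules, function(r)
      list(antecedent = as.list(r$antecedent), consequent = r$consequent,
           support = r$support, confidence = r$confidence,
           decision = r$decision))
    writeLines(jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA), json_path)
  }
  invisible(path)
}

#' Best splitting template for a set of objects
#'
#' A template is a conjunction of attribute = label descriptors; its fitness
#' is the number of objects matching every descriptor. The template is grown
#' greedily one descriptor at a time, maximizing fitness subject to splitting
#' the object set into two nonempty parts; ties prefer fewer descriptors, then
#' schema attribute order, then the lexicographically smaller label. Returns
#' `NULL` when no descriptor splits the set (degenerate: stop splitting).
#'
#' @param x A `disctable`.
#' @param ids Object ids to split (default all).
#' @return `list(descriptors, fitness)` of class `template`, or `NULL`.
#' @export
best_template <- function(x, ids = NULL) {
  if (is.null(ids)) ids <- x$ids
  sub <- filter_objects(x, ids)
  n <- n_objects(sub)
  attrs <- condition_attrs(sub)
  grow_best <- function(current) {
    # best single-descriptor extension of `current` by fitness
    base_ok <- match_antecedent(current, sub$data)
    best <- NULL
    for (a in setdiff(attrs, names(current))) {
      v <- as.character(sub$data[[a]])
      for (lab in sort(unique(v[!is.na(v) & v != "*"]))) {
        fit <- sum(base_ok & !is.na(v) & v == lab)
        if (fit >= 1L && fit <= n - 1L &&
            (is.null(best) || fit > best$fitness)) {
          cand <- current; cand[a] <- lab
          best <- list(descriptors = cand, fitness = fit)
        }
      }
    }
    best
  }
  tpl <- grow_best(stats::setNames(character(0), character(0)))
  if (is.null(tpl)) return(NULL)
  repeat {
    ext <- grow_best(tpl$descriptors)
    if (is.null(ext) || ext$fitness <= tpl$fitness) break # fewer descriptors win ties
    tpl <- ext
  }
  structure(tpl, class = "template")
}

#' Reduct-based rule set for a (sub)table
#'
#' The rule set a trained rough-set classifier carries: rules induced over
#' every exhaustive reduct of the table (greedy fallback past the capacity
#' limit), deduplicated. A single-class table yields the degenerate
#' empty-antecedent rule `=> class`, which matches everything routed to it.
#' Minimal (reduct-length) antecedents are what give the classifier coverage
#' beyond literal row duplicates.
#'
#' @param x A `disctable` (or discrete decision table).
#' @param attr_sets Optional list of attribute sets (reducts) to induce over;
#'   by default the exhaustive reducts of `x` itself. Decomposition-tree
#'   leaves pass the reducts of their full training table so that leaf rules
#'   stay selective even when the leaf is decision-pure.
#' @return List of [decision_rule()]s.
#' @export
reduct_rules <- function(x, attr_sets = NULL) {
  if (is.null(attr_sets)) {
    reds <- tryCatch(reducts_exhaustive(x),
                     error = function(e) list(reduct_greedy(x)))
    attr_sets <- unique(lapply(reds, `[[`, "attrs"))
  }
  rules <- list()
  for (s in attr_sets) {
    aa <- intersect(non_starred_conditions(x), s)
    if (!length(aa)) next
    rules <- c(rules, induce_rules(x, aa))
  }
  if (!length(rules)) {
    # no usable reduct attributes (e.g. a single-class table): the
    # degenerate empty-antecedent rule carries the majority decision
    d <- as.character(decision_values(x))
    tab <- sort(table(d), decreasing = TRUE)
    return(list(decision_rule(stats::setNames(character(0), character(0)),
                              names(tab)[1L], support = n_objects(x),
                              confidence = unname(tab[1L]) / n_objects(x),
                              decision = x$decision)))
  }
  keys <- vapply(rules, function(r)
    paste0(paste(names(r$antecedent), r$antecedent, sep = "=", collapse = "&"),
           "=>", r$consequent), character(1))
  rules[!duplicated(keys)]
}

#' Minimal consistent decision rules (object-wise local reducts)
#'
#' For every object, all shortest antecedents (subsets of its non-starred
#' descriptor set) whose pattern is decision-pure over the reference table
#' `within` become rules; an object with no consistent antecedent (an
#' inconsistent row) contributes its full-length antecedent with fractional
#' confidence. Support and confidence are recounted over `within`. These
#' maximally general consistent rules are what give a trained rough-set
#' classifier its coverage on unseen objects.
#'
#' @param x A `disctable` (the objects to describe, e.g. a tree leaf).
#' @param within Reference table for consistency and recounting (defaults to
#'   `x`; a leaf passes its full training table).
#' @param max_len Antecedent length cap (default: all condition attributes).
#' @return Deduplicated list of [decision_rule()]s.
#' @export
minimal_rules <- function(x, within = x, max_len = NULL) {
  attrs <- non_starred_conditions(within)
  if (!length(attrs)) return(induce_rules(within))
  d_within <- as.character(decision_values(within))
  recs <- within$data[, attrs, drop = FALSE]
  n <- n_objects(x)
  rules <- list(); keys <- character(0)
  add_rule <- function(ant, lab, support, confidence) {
    key <- paste0(paste(names(ant), ant, sep = "=", collapse = "&"),
                  "=>", lab)
    if (!key %in% keys) {
      keys[[length(keys) + 1L]] <<- key
      rules[[length(rules) + 1L]] <<-
        decision_rule(ant, lab, support = support, confidence = confidence,
                      decision = within$decision)
    }
  }
  max_len <- max_len %||% length(attrs)
  for (i in seq_len(n)) {
    full <- vapply(attrs, function(a) as.character(x$data[[a]][i]), character(1))
    full <- full[!is.na(full) & full != "*"]
    if (!length(full)) next
    di <- as.character(decision_values(x))[i]
    found <- FALSE
    for (len in seq_len(min(max_len, length(full)))) {
      for (sel in utils::combn(names(full), len, simplify = FALSE)) {
        ant <- full[sel]
        m <- match_antecedent(ant, recs)
        if (all(d_within[m] == di)) {
          add_rule(ant, di, sum(m), 1)
          found <- TRUE
        }
      }
      if (found) break # only the shortest consistent antecedents
    }
    if (!found) { # inconsistent even on the full descriptor set
      m <- match_antecedent(full, recs)
      tab <- table(d_within[m])
      add_rule(full, di, sum(m), as.integer(tab[[di]]) / sum(m))
    }
  }
  rules
}

match_template <- function(template, object) {
  v <- object[names(template$descriptors)]
  !anyNA(v) && all(v == template$descriptors)
}

#' Build a decomposition-tree classifier
#'
#' A binary tree whose internal nodes are labelled by templates; objects
#' matching the node template descend the match branch, others the no-match
#' branch. Splitting recurses until a node holds at most `min_leaf` objects or
#' no splitting template exists. Each leaf stores the reduct-based rules of
#' its object subtable (see [reduct_rules()]); with `min_leaf >= n` the tree
#' degenerates to the flat reduct-rule classifier.
#'
#' @param x A `disctable`.
#' @param min_leaf Leaf size threshold (>= 1).
#' @return Object of class `decomptree`.
#' @export
build_tree <- function(x, min_leaf = 3L,
                       rule_method = c("minimal", "reducts")) {
  stopifnot(min_leaf >= 1L)
  rule_method <- match.arg(rule_method)
  attrs <- non_starred_conditions(x)
  global_sets <- if (length(attrs) && rule_method == "reducts") {
    reds <- tryCatch(reducts_exhaustive(x),
                     error = function(e) list(reduct_greedy(x)))
    unique(lapply(reds, `[[`, "attrs"))
  } else list()
  grow <- function(ids) {
    make_leaf <- function() {
      sub <- filter_objects(x, ids)
      list(kind = "leaf", ids = ids,
           rules = if (!length(attrs)) list()
                   else if (rule_method == "minimal")
                     minimal_rules(sub, within = x)
                   else reduct_rules(sub, global_sets))
    }
    if (length(ids) <= min_leaf) return(make_leaf())
    tpl <- best_template(x, ids)
    if (is.null(tpl)) return(make_leaf())
    sub <- filter_objects(x, ids)
    hits <- match_antecedent(tpl$descriptors, sub$data)
    list(kind = "node", template = tpl,
         match = grow(ids[hits]), nomatch = grow(ids[!hits]))
  }
  structure(list(root = grow(x$ids), min_leaf = min_leaf,
                 decision = x$decision, attrs = attrs),
            class = "decomptree")
}

#' Classify a labelled record with a decomposition tree
#'
#' The record is routed by template matches from the root to a leaf, where
#' the leaf's rules vote (see [classify_rules()]); a record matching no leaf
#' rule abstains.
#'
#' @param tree A [build_tree()] result.
#' @param object Named character label vector.
#' @param scheme Voting scheme passed to [classify_rules()].
#' @return Decision label or `NA_character_` (ABSTAIN).
#' @export
classify_tree <- function(tree, object, scheme = "weighted") {
  node <- tree$root
  while (node$kind == "node") {
    node <- if (match_template(node$template, object)) node$match else node$nomatch
  }
  classify_rules(node$rules, object, scheme)
}

#' Leaf object-id sets of a decomposition tree
#' @param tree A `decomptree`.
#' @return List of id vectors, one per leaf (they partition the training set).
#' @export
tree_leaves <- function(tree) {
  out <- list()
  walk <- function(node, path) {
    if (node$kind == "leaf") {
      out[[length(out) + 1L]] <<- list(ids = node$ids, path = path)
    } else {
      walk(node$match, c(path, list(list(template = node$template, branch = TRUE))))
      walk(node$nomatch, c(path, list(list(template = node$template, branch = FALSE))))
    }
  }
  walk(tree$root, list())
  out
}
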