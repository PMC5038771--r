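# Indiscernibility relation, elementary granules, lower/upper approximations,
# positive region, dependency degree, discernibility matrix and reducts.
#
# Throughout, MISSING (NA) equals only MISSING, so the indiscernibility
# relation remains an equivalence relation even with incomplete data.

NA_KEY <- "\rMISSING\r"

ind_key <- function(x, B) {
  n <- n_objects(x)
  if (!length(B)) return(rep("", n))
  cols <- lapply(B, function(a) {
    v <- as.character(x$data[[a]])
    v[is.na(v)] <- NA_KEY
    v
  })
  do.call(paste, c(cols, sep = "\r"))
}

#' Partition a table into B-elementary granules
#'
#' Two objects fall in the same granule iff they carry equal values on every
#' attribute of `B` (MISSING equals only MISSING). The empty attribute set
#' yields a single granule holding the whole universe.
#'
#' @param x A `decisiontable` or `disctable`.
#' @param B Attribute names (subset of condition and decision attributes).
#' @return List of granules, each a list with `attrs`, `signature` (named
#'   labels) and `members` (object ids), ordered by first member occurrence.
#' @export
partition <- function(x, B) {
  unknown <- setdiff(B, x$schema$name)
  if (length(unknown))
    stop("unknown attribute(s): ", paste(unknown, collapse = ", "))
  key <- ind_key(x, B)
  first <- !duplicated(key)
  ord_keys <- key[first]
  groups <- split(seq_len(n_objects(x)), factor(key, levels = ord_keys))
  lapply(seq_along(groups), function(g) {
    rows <- groups[[g]]
    sig <- if (length(B)) {
      vapply(B, function(a) as.character(x$data[[a]][rows[1L]]), character(1))
    } else {
      stats::setNames(character(0), character(0))
    }
    structure(list(attrs = B, signature = sig, members = x$ids[rows]),
              class = "granule")
  })
}

#' Lower and upper approximation of a concept
#'
#' The lower approximation is the union of B-granules wholly contained in the
#' concept `X`; the upper approximation is the union of granules intersecting
#' `X`; their difference is the boundary region. `X` is crisp with respect to
#' `B` iff the boundary is empty.
#'
#' @param x A `decisiontable` or `disctable`.
#' @param B Attribute names.
#' @param X Set of object ids (subset of `x$ids`).
#' @return Object of class `approximation`: `concept`, `lower`, `upper`,
#'   `boundary`, `crisp`.
#' @export
approximate <- function(x, B, X) {
  bad <- setdiff(X, x$ids)
  if (length(bad)) stop("unknown object id(s): ", paste(bad, collapse = ", "))
  gr <- partition(x, B)
  lower <- integer(0); upper <- integer(0)
  for (g in gr) {
    inX <- g$members %in% X
    if (any(inX)) upper <- c(upper, g$members)
    if (all(inX)) lower <- c(lower, g$members)
  }
  lower <- sort(lower); upper <- sort(upper)
  structure(list(concept = sort(unique(X)), lower = lower, upper = upper,
                 boundary = setdiff(upper, lower),
                 crisp = identical(lower, upper)),
            class = "approximation")
}

#' @export
print.approximation <- function(x, ...) {
  cat(sprintf("<approximation> |X| = %d, |lower| = %d, |upper| = %d, %s\n",
              length(x$concept), length(x$lower), length(x$upper),
              if (x$crisp) "crisp" else "rough"))
  invisible(x)
}

#' Positive region of the decision with respect to attributes B
#'
#' Union over decision classes of their B-lower approximations: the objects
#' whose B-granule is decision-pure.
#'
#' @param x A `decisiontable` or `disctable` with a discrete decision.
#' @param B Condition attribute names.
#' @return Sorted vector of object ids.
#' @export
positive_region <- function(x, B) {
  d <- as.character(decision_values(x))
  gr <- partition(x, B)
  pos <- integer(0)
  for (g in gr) {
    rows <- match(g$members, x$ids)
    if (length(unique(d[rows])) == 1L) pos <- c(pos, g$members)
  }
  sort(pos)
}

#' Dependency degree of the decision on attributes B
#'
#' `|POS_B(D)| / |U|`, in `[0, 1]`; 1 means the table is consistent on `B`.
#'
#' @inheritParams positive_region
#' @export
dependency <- function(x, B) {
  n <- n_objects(x)
  if (n == 0L) return(0)
  length(positive_region(x, B)) / n
}

#' Decision-relative discernibility matrix
#'
#' For every object pair with different decisions in which at least one member
#' lies in the positive region of the full condition set, the set of condition
#' attributes on which the pair differs (MISSING differs from any value but
#' equals MISSING).
#'
#' @param x A `decisiontable` or `disctable`.
#' @param attrs Condition attributes to consider (default all).
#' @return List with `pairs` (two-column id matrix) and `attrs` (list of
#'   character vectors, parallel to the rows of `pairs`).
#' @export
discernibility_matrix <- function(x, attrs = condition_attrs(x)) {
  d <- as.character(decision_values(x))
  n <- n_objects(x)
  pos <- x$ids %in% positive_region(x, attrs)
  cols <- lapply(attrs, function(a) {
    v <- as.character(x$data[[a]])
    v[is.na(v)] <- NA_KEY
    v
  })
  pair_i <- integer(0); pair_j <- integer(0); ent <- list()
  for (i in seq_len(max(0L, n - 1L))) {
    for (j in seq.int(i + 1L, n)) {
      if (d[i] == d[j]) next
      if (!pos[i] && !pos[j]) next
      diff_attrs <- attrs[vapply(cols, function(v) v[i] != v[j], logical(1))]
      if (length(diff_attrs)) {
        pair_i <- c(pair_i, x$ids[i]); pair_j <- c(pair_j, x$ids[j])
        ent[[length(ent) + 1L]] <- diff_attrs
      }
    }
  }
  list(pairs = cbind(i = pair_i, j = pair_j), attrs = ent)
}

verify_reduct <- function(x, attrs, full_dep) {
  if (!isTRUE(all.equal(dependency(x, attrs), full_dep))) return(FALSE)
  for (a in attrs)
    if (dependency(x, setdiff(attrs, a)) >= full_dep - 1e-12) return(FALSE)
  TRUE
}

#' All exhaustive reducts
#'
#' Minimal condition-attribute subsets preserving the positive region of the
#' full condition set, found as minimal hitting sets of the decision-relative
#' discernibility matrix (enumeration by increasing subset size with
#' absorption pruning). Every returned subset passes a verification pass:
#' its dependency equals the full dependency and dropping any single member
#' strictly lowers it.
#'
#' @param x A `decisiontable` or `disctable`.
#' @param max_attrs Capacity limit for exhaustive search (default 20).
#' @return List of reducts, each `list(attrs, kind = "exhaustive")`.
#' @export
reducts_exhaustive <- function(x, max_attrs = 20L) {
  conds <- condition_attrs(x)
  p <- length(conds)
  if (p > max_attrs)
    stop("exhaustive reduct search over ", max_attrs,
         " condition attributes; use reduct_greedy()")
  full_dep <- dependency(x, conds)
  dm <- discernibility_matrix(x)
  entries <- unique(lapply(dm$attrs, sort))
  # absorption: keep only minimal entries
  if (length(entries) > 1L) {
    keep <- rep(TRUE, length(entries))
    for (a in seq_along(entries)) for (b in seq_along(entries)) {
      if (a != b && keep[a] && keep[b] &&
          all(entries[[b]] %in% entries[[a]]) &&
          length(entries[[b]]) < length(entries[[a]])) keep[a] <- FALSE
    }
    entries <- entries[keep]
  }
  universe <- sort(unique(unlist(entries)))
  if (!length(entries)) {
    return(list(list(attrs = character(0), kind = "exhaustive")))
  }
  found <- list()
  for (size in seq_len(length(universe))) {
    combos <- utils::combn(universe, size, simplify = FALSE)
    for (s in combos) {
      if (length(found) &&
          any(vapply(found, function(r) all(r %in% s), logical(1)))) next
      hits <- all(vapply(entries, function(e) any(e %in% s), logical(1)))
      if (hits) found[[length(found) + 1L]] <- s
    }
  }
  found <- Filter(function(s) verify_reduct(x, s, full_dep), found)
  lapply(found, function(s) list(attrs = s, kind = "exhaustive"))
}

#' Greedy reduct
#'
#' Forward selection adding the attribute with the largest dependency gain
#' (ties by schema order) until the full-attribute dependency is reached,
#' followed by a pruning pass dropping attributes whose removal preserves the
#' dependency. The result is a superset-minimal reduct.
#'
#' @param x A `decisiontable` or `disctable`.
#' @return `list(attrs, kind = "greedy")`.
#' @export
reduct_greedy <- function(x) {
  conds <- condition_attrs(x)
  full_dep <- dependency(x, conds)
  sel <- character(0)
  cur <- dependency(x, sel)
  while (cur < full_dep - 1e-12) {
    gains <- vapply(setdiff(conds, sel),
                    function(a) dependency(x, c(sel, a)), numeric(1))
    pick <- names(gains)[which.max(gains)] # ties: first in schema order
    sel <- c(sel, pick)
    cur <- dependency(x, sel)
  }
  for (a in sel) {
    if (length(sel) > 1L &&
        dependency(x, setdiff(sel, a)) >= full_dep - 1e-12)
      sel <- setdiff(sel, a)
  }
  list(attrs = sel, kind = "greedy")
}
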