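# Supervised (maximal-discernibility) and equal-frequency discretization.
#
# A cut set maps every numeric condition attribute to a strictly increasing
# vector of cut points; numeric attributes that receive no cuts are "starred"
# (excluded as non-significant) and render as "*" for every object. Nominal
# condition attributes never take part in the cut search and are always kept
# with their raw values.

#' Construct a cut set
#'
#' @param cuts Named list: numeric attribute name -> increasing numeric vector
#'   of cut points (possibly empty).
#' @param starred Character vector of numeric attributes excluded from the
#'   discretized table (those with zero cuts).
#' @param kept Character vector of nominal attributes passed through unchanged.
#' @param decision_cuts Optional cuts used to bin a numeric decision attribute.
#' @return An object of class `cutset`.
#' @export
cutset <- function(cuts = list(), starred = character(),
                   kept = character(), decision_cuts = NULL) {
  cuts <- lapply(cuts, function(cc) {
    cc <- sort(unique(as.numeric(cc)))
    stopifnot(all(is.finite(cc)))
    cc
  })
  structure(list(cuts = cuts, starred = starred, kept = kept,
                 decision_cuts = decision_cuts),
            class = "cutset")
}

#' @export
print.cutset <- function(x, ...) {
  cat("<cutset>\n")
  for (a in names(x$cuts))
    cat(" ", a, ":", paste(x$cuts[[a]], collapse = ", "), "\n")
  if (length(x$starred)) cat("  starred:", paste(x$starred, collapse = ", "), "\n")
  if (length(x$kept)) cat("  kept nominal:", paste(x$kept, collapse = ", "), "\n")
  if (length(x$decision_cuts))
    cat("  decision cuts:", paste(x$decision_cuts, collapse = ", "), "\n")
  invisible(x)
}

#' Serialize a cut set to JSON
#'
#' Starred attributes are encoded as the string `"*"`, others as arrays of
#' cut points.
#' @param x A `cutset`.
#' @param path Optional file to write to.
#' @export
cutset_to_json <- function(x, path = NULL) {
  obj <- c(x$cuts, stats::setNames(as.list(rep("*", length(x$starred))), x$starred))
  txt <- jsonlite::toJSON(obj, auto_unbox = FALSE, digits = NA)
  if (!is.null(path)) writeLines(txt, path)
  txt
}

#' Candidate boundary cuts for one numeric attribute
#'
#' Midpoints between consecutive distinct sorted values whose adjacent
#' value-groups contain objects of more than one decision class. A constant
#' attribute yields an empty candidate set.
#'
#' @param x A `decisiontable`.
#' @param attr Numeric attribute name.
#' @param dec Optional discrete decision vector (one label per object); by
#'   default the decision column is used, which must then be discrete.
#' @return Numeric vector of candidate cut points (possibly empty).
#' @export
candidate_cuts <- function(x, attr, dec = NULL) {
  v <- x$data[[attr]]
  if (is.null(v)) stop("unknown attribute: ", attr)
  if (!is.numeric(v)) stop("candidate_cuts requires a numeric attribute")
  if (is.null(dec)) dec <- discrete_decision(x)
  keep <- !is.na(v)
  v2 <- v[keep]
  d2 <- dec[keep]
  vals <- sort(unique(v2))
  if (length(vals) < 2L) return(numeric(0))
  grp <- match(v2, vals)
  sets <- split(d2, grp)
  out <- numeric(0)
  for (i in seq_len(length(vals) - 1L)) {
    u <- unique(c(sets[[i]], sets[[i + 1L]]))
    if (length(u) > 1L) out <- c(out, (vals[i] + vals[i + 1L]) / 2)
  }
  out
}

# Decision column as discrete labels; errors if numeric and unbinned.
discrete_decision <- function(x, decision_cuts = NULL) {
  d <- decision_values(x)
  if (is.numeric(d)) {
    if (is.null(decision_cuts))
      stop("numeric decision attribute must be binned first ",
           "(pass decision_cuts, e.g. from equal_frequency_cuts)")
    as.character(findInterval(d, decision_cuts))
  } else {
    as.character(d)
  }
}

#' Greedy maximal-discernibility cut selection
#'
#' Decision-aware supervised discretization: at each step the candidate cut
#' (over any numeric condition attribute) discerning the largest number of
#' not-yet-discerned object pairs with different decisions is selected. Ties
#' are broken by attribute order in the schema, then by the smaller cut value.
#' Selection stops when every discernible pair is discerned or no cut adds
#' discernment. Numeric attributes ending with zero cuts are starred; nominal
#' condition attributes are always kept and already discern pairs on which
#' they differ.
#'
#' Pairs in which one object is MISSING on an attribute cannot be discerned by
#' a cut on that attribute; missingness itself is handled downstream by the
#' indiscernibility relation (MISSING equals only MISSING).
#'
#' @param x A `decisiontable`.
#' @param decision_cuts Cuts binning a numeric decision attribute (required
#'   when the decision is numeric).
#' @return A [cutset()].
#' @export
md_select_cuts <- function(x, decision_cuts = NULL) {
  dec <- discrete_decision(x, decision_cuts)
  conds <- condition_attrs(x)
  kinds <- x$schema$kind[match(conds, x$schema$name)]
  num_attrs <- conds[kinds == "numeric"]
  nom_attrs <- conds[kinds == "nominal"]
  n <- n_objects(x)
  chosen <- stats::setNames(lapply(num_attrs, function(a) numeric(0)), num_attrs)
  if (n > 1L && length(num_attrs)) {
    pr <- which(outer(dec, dec, "!="), arr.ind = TRUE)
    pr <- pr[pr[, 1L] < pr[, 2L], , drop = FALSE]
    iv <- pr[, 1L]; jv <- pr[, 2L]
    npairs <- length(iv)
    if (npairs > 0L) {
      # every cross-decision pair is a target: cuts must carry the
      # discernment themselves (nominal attributes are rendered as raw
      # values but do not absolve the cut search)
      remaining <- rep(TRUE, npairs)
      cand <- lapply(num_attrs, function(a) candidate_cuts(x, a, dec))
      names(cand) <- num_attrs
      lo <- hi <- list()
      for (a in num_attrs) {
        va <- x$data[[a]]
        lo[[a]] <- pmin(va[iv], va[jv])
        hi[[a]] <- pmax(va[iv], va[jv])
      }
      while (any(remaining)) {
        best_attr <- NA_character_; best_cut <- NA_real_; best_cnt <- 0L
        for (a in num_attrs) {
          cc <- setdiff(cand[[a]], chosen[[a]])
          if (!length(cc)) next
          la <- lo[[a]]; ha <- hi[[a]]
          for (cv in cc) {
            cnt <- sum(remaining & !is.na(la) & la < cv & cv <= ha)
            if (cnt > best_cnt) {
              best_attr <- a; best_cut <- cv; best_cnt <- cnt
            }
          }
        }
        if (best_cnt == 0L) break
        chosen[[best_attr]] <- sort(c(chosen[[best_attr]], best_cut))
        la <- lo[[best_attr]]; ha <- hi[[best_attr]]
        remaining <- remaining &
          !(!is.na(la) & la < best_cut & best_cut <= ha)
      }
    }
  }
  n_cuts <- vapply(chosen, length, 0L)
  cutset(cuts = chosen[n_cuts > 0L],
         starred = num_attrs[n_cuts == 0L],
         kept = nom_attrs,
         decision_cuts = decision_cuts)
}

#' Equal-frequency cuts for one numeric attribute
#'
#' Unsupervised binning into `k` groups of (near-)equal counts; the `k - 1`
#' cuts are midpoints between the order statistics flanking each bin boundary.
#' With fewer distinct values than bins the bin count is reduced with a
#' warning. A constant attribute yields no cuts.
#'
#' @param x An `infotable` or `decisiontable`.
#' @param attr Numeric attribute name.
#' @param k Number of bins (>= 2).
#' @return Numeric vector of cuts (length `k - 1` or fewer).
#' @export
equal_frequency_cuts <- function(x, attr, k) {
  v <- x$data[[attr]]
  if (!is.numeric(v)) stop("equal_frequency_cuts requires a numeric attribute")
  stopifnot(k >= 2L)
  v <- sort(v[!is.na(v)])
  nv <- length(v)
  distinct <- unique(v)
  if (length(distinct) < 2L) return(numeric(0))
  if (length(distinct) < k) {
    warning(sprintf("attribute '%s' has %d distinct values < k = %d; reducing bins",
                    attr, length(distinct), k))
    k <- length(distinct)
  }
  cuts <- numeric(0)
  for (j in seq_len(k - 1L)) {
    pos <- j * nv / k
    i <- max(1L, min(nv - 1L, floor(pos)))
    if (pos > i) i <- min(nv - 1L, ceiling(pos) - 1L) # boundary inside a run
    cand <- (v[i] + v[i + 1L]) / 2
    # midpoint must separate distinct values; walk forward if inside a tie run
    while (i < nv - 1L && v[i] == v[i + 1L]) {
      i <- i + 1L
      cand <- (v[i] + v[i + 1L]) / 2
    }
    if (v[i] < v[i + 1L]) cuts <- c(cuts, cand)
  }
  sort(unique(cuts))
}

#' Equal-frequency cut set over all numeric condition attributes
#'
#' @param x A `decisiontable`.
#' @param k Bins per attribute.
#' @param decision_cuts Optional cuts binning a numeric decision.
#' @return A [cutset()]; constant attributes are starred.
#' @export
equal_frequency_cutset <- function(x, k, decision_cuts = NULL) {
  conds <- condition_attrs(x)
  kinds <- x$schema$kind[match(conds, x$schema$name)]
  num_attrs <- conds[kinds == "numeric"]
  cuts <- lapply(num_attrs, function(a) equal_frequency_cuts(x, a, k))
  names(cuts) <- num_attrs
  n_cuts <- vapply(cuts, length, 0L)
  cutset(cuts = cuts[n_cuts > 0L], starred = num_attrs[n_cuts == 0L],
         kept = conds[kinds == "nominal"], decision_cuts = decision_cuts)
}

# Numeric rendering used in interval labels: whole numbers get one decimal
# ("55.0"), fractional cuts print in full ("45.5", "259.695").
fmt_cut <- function(x) {
  vapply(x, function(z) {
    if (z == round(z)) sprintf("%.1f", z)
    else format(z, trim = TRUE, scientific = FALSE)
  }, character(1))
}

fmt_plain <- function(x) format(x, trim = TRUE, scientific = FALSE)

#' Interval labels for numeric values under a cut vector
#'
#' Membership follows the half-open convention: a value equal to a cut belongs
#' to the upper interval. Two rendering dialects are supported:
#' `"rses"` renders open-looking labels `"(-Inf, c1)"`, `"(ci, cj)"`,
#' `"(cm, Inf)"`; `"bracket"` renders `"[min, c1]"`, `"(ci, cj]"`, `"(cm, max]"`
#' using the observed data range for the outer endpoints.
#'
#' @param v Numeric vector.
#' @param cuts Increasing cut vector (may be empty: single interval).
#' @param dialect `"rses"` or `"bracket"`.
#' @param range Observed (min, max), used by the bracket dialect.
#' @return Character labels (`NA` propagates for MISSING values).
#' @export
interval_label <- function(v, cuts, dialect = c("rses", "bracket"),
                           range = NULL) {
  dialect <- match.arg(dialect)
  cuts <- sort(unique(cuts))
  m <- length(cuts)
  bin <- findInterval(v, cuts) # v >= cut -> upper interval
  if (dialect == "rses") {
    lo <- c("-Inf", fmt_cut(cuts))
    hi <- c(fmt_cut(cuts), "Inf")
    lab <- paste0("(", lo[bin + 1L], ", ", hi[bin + 1L], ")")
  } else {
    if (is.null(range)) range <- range(v, na.rm = TRUE)
    lo <- c(fmt_plain(range[1L]), fmt_plain(cuts))
    hi <- c(fmt_plain(cuts), fmt_plain(range[2L]))
    open <- c("[", rep("(", m))
    lab <- paste0(open[bin + 1L], lo[bin + 1L], ", ", hi[bin + 1L], "]")
  }
  lab[is.na(v)] <- NA_character_
  lab
}

#' Apply a cut set, producing a discretized decision table
#'
#' Every non-starred numeric condition value is replaced by its interval
#' label; starred attributes render `"*"` for all objects; nominal attributes
#' keep their raw values; MISSING propagates as MISSING. A numeric decision is
#' binned by its own cuts (`cuts$decision_cuts`).
#'
#' @param x A `decisiontable`.
#' @param cuts A [cutset()].
#' @param dialect Interval rendering dialect (see [interval_label()]).
#' @return An object of class `disctable` (also a `decisiontable`): label
#'   data plus the generating cut set.
#' @export
apply_cuts <- function(x, cuts, dialect = c("rses", "bracket")) {
  dialect <- match.arg(dialect)
  stopifnot(inherits(x, "decisiontable"), inherits(cuts, "cutset"))
  conds <- condition_attrs(x)
  kinds <- x$schema$kind[match(conds, x$schema$name)]
  out <- x$data
  for (idx in seq_along(conds)) {
    a <- conds[idx]
    v <- x$data[[a]]
    if (kinds[idx] == "nominal") {
      out[[a]] <- as.character(v)
    } else if (a %in% names(cuts$cuts) && length(cuts$cuts[[a]])) {
      out[[a]] <- interval_label(v, cuts$cuts[[a]], dialect)
    } else {
      lab <- rep("*", length(v))
      out[[a]] <- lab
    }
  }
  dv <- x$data[[x$decision]]
  if (is.numeric(dv)) {
    if (is.null(cuts$decision_cuts))
      stop("numeric decision requires cuts$decision_cuts")
    out[[x$decision]] <- interval_label(dv, cuts$decision_cuts, dialect)
  } else {
    out[[x$decision]] <- as.character(dv)
  }
  # identifier columns are carried along as character for traceability
  idc <- x$schema$name[x$schema$role == "identifier"]
  for (a in idc) out[[a]] <- as.character(x$data[[a]])
  sch <- x$schema
  sch$kind <- "nominal"
  tab <- information_table(out, sch, ids = x$ids)
  tab$decision <- x$decision
  tab$cuts <- cuts
  tab$dialect <- dialect
  class(tab) <- c("disctable", "decisiontable", "infotable")
  tab
}

#' Order of decision class labels in a discretized table
#'
#' Interval labels of a binned numeric decision are ordered by interval
#' position; nominal decisions sort by value.
#' @param x A `disctable` (or decision table with discrete decision).
#' @export
decision_classes <- function(x) {
  d <- decision_values(x)
  u <- unique(d[!is.na(d)])
  if (!is.null(x$cuts) && !is.null(x$cuts$decision_cuts)) {
    dc <- x$cuts$decision_cuts
    # one representative value per bin, in ascending interval order
    mids <- c(dc[1] - 1, if (length(dc) > 1) (dc[-length(dc)] + dc[-1]) / 2,
              dc[length(dc)] + 1)
    ordered <- interval_label(mids, dc, x$dialect %||% "rses")
    return(ordered[ordered %in% u])
  }
  sort(u)
}
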