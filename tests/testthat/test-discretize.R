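# Oracle used below: a candidate cut is the midpoint of two adjacent distinct
# values whose value-groups jointly contain more than one decision class;
# enumeration is done directly here, independent of the package's search.
enumerate_candidates <- function(v, d) {
  vals <- sort(unique(v))
  out <- numeric(0)
  for (i in seq_len(length(vals) - 1)) {
    cls <- unique(c(d[v == vals[i]], d[v == vals[i + 1]]))
    if (length(cls) > 1) out <- c(out, (vals[i] + vals[i + 1]) / 2)
  }
  out
}

one_attr_table <- function(v, d) {
  sch <- schema(attribute_spec("x", "numeric"),
                attribute_spec("dec", "nominal", "decision"))
  as_decision_table(information_table(data.frame(x = v, dec = d), sch), "dec")
}

test_that("candidate cuts are decision-boundary midpoints", {
  expect_equal(candidate_cuts(one_attr_table(c(12, 16), c("lo", "hi")), "x"),
               14.0)
  expect_equal(candidate_cuts(one_attr_table(c(12, 16, 20), rep("same", 3)), "x"),
               numeric(0))
  expect_equal(candidate_cuts(one_attr_table(c(5, 5, 5), c("a", "b", "a")), "x"),
               numeric(0)) # constant attribute
  # the eight UPDRS values with their own four-bin labels as decision
  v <- c(58, 40, 40, 16, 49, 22, 37, 12)
  d <- as.character(findInterval(v, c(14, 22.5, 55)))
  got <- candidate_cuts(one_attr_table(v, d), "x")
  expect_equal(got, sort(enumerate_candidates(v, d)))
  expect_true(14.0 %in% got)
})

test_that("greedy MD selection stars the non-significant attributes of the worked example", {
  md <- md_select_cuts(example_decision_table(), decision_cuts = c(14, 22.5, 55))
  expect_setequal(md$starred, c("t_dur", "HYsc", "SccAmp"))
  expect_true(all(c("age", "SccDur", "SccLat") %in% names(md$cuts)))
  expect_setequal(md$kept, c("Pat", "Sess"))
  # selected cuts discern every cross-bin pair discernible by numeric values
  disc <- apply_cuts(example_decision_table(), md)
  d <- decision_values(disc)
  num <- c("age", "t_dur", "HYsc", "SccDur", "SccLat", "SccAmp")
  raw <- example_decision_table()$data
  for (i in 1:7) for (j in (i + 1):8) {
    if (d[i] == d[j]) next
    if (all(raw[i, num] == raw[j, num])) next
    expect_false(all(disc$data[i, num] == disc$data[j, num]),
                 label = sprintf("pair (%d, %d) discerned", i, j))
  }
})

test_that("a single separating cut is selected exactly", {
  dt <- one_attr_table(c(1, 2, 3, 10, 11, 12), rep(c("a", "b"), each = 3))
  md <- md_select_cuts(dt)
  expect_equal(md$cuts, list(x = 6.5))
  expect_length(md$starred, 0L)
})

test_that("greedy MD matches the exhaustive minimum on a small two-attribute table", {
  sch <- schema(attribute_spec("x", "numeric"), attribute_spec("y", "numeric"),
                attribute_spec("dec", "nominal", "decision"))
  df <- data.frame(x = c(1, 2, 3, 4, 5, 6), y = c(2, 1, 2, 1, 2, 1),
                   dec = c("a", "a", "b", "b", "a", "b"))
  dt <- as_decision_table(information_table(df, sch), "dec")
  md <- md_select_cuts(dt)
  n_md <- length(unlist(md$cuts))
  # brute force: smallest set of candidate cuts discerning all cross-class pairs
  cand <- list(x = enumerate_candidates(df$x, df$dec),
               y = enumerate_candidates(df$y, df$dec))
  all_cuts <- rbind(data.frame(attr = "x", cut = cand$x),
                    data.frame(attr = "y", cut = cand$y))
  pairs <- which(outer(df$dec, df$dec, "!="), arr.ind = TRUE)
  pairs <- pairs[pairs[, 1] < pairs[, 2], , drop = FALSE]
  discerns <- function(rows) {
    apply(pairs, 1, function(pr) {
      any(vapply(rows, function(r) {
        v1 <- df[[all_cuts$attr[r]]][pr[1]]; v2 <- df[[all_cuts$attr[r]]][pr[2]]
        min(v1, v2) < all_cuts$cut[r] & all_cuts$cut[r] <= max(v1, v2)
      }, logical(1)))
    })
  }
  best <- Inf
  for (size in seq_len(nrow(all_cuts))) {
    for (s in utils::combn(nrow(all_cuts), size, simplify = FALSE)) {
      if (all(discerns(s))) { best <- size; break }
    }
    if (is.finite(best)) break
  }
  expect_equal(n_md, best)
  # and the greedy set does discern everything
  disc <- apply_cuts(dt, md)
  for (k in seq_len(nrow(pairs)))
    expect_false(all(disc$data[pairs[k, 1], c("x", "y")] ==
                     disc$data[pairs[k, 2], c("x", "y")]))
})

test_that("equal-frequency cuts sit at quantile midpoints", {
  dt <- one_attr_table(1:8, rep("a", 8))
  expect_equal(equal_frequency_cuts(dt, "x", 4), c(2.5, 4.5, 6.5))
  lat <- c(402, 297, 227, 198, 285, 217, 380, 187)
  cut2 <- equal_frequency_cuts(one_attr_table(lat, rep("a", 8)), "x", 2)
  expect_length(cut2, 1L)
  expect_gt(cut2, 227); expect_lt(cut2, 285)
  expect_warning(equal_frequency_cuts(one_attr_table(c(1, 1, 2, 2), rep("a", 4)),
                                      "x", 4),
                 "distinct values")
  sch <- schema(attribute_spec("x", "numeric"),
                attribute_spec("c", "numeric"),
                attribute_spec("dec", "nominal", "decision"))
  dt2 <- as_decision_table(information_table(
    data.frame(x = 1:4, c = rep(7, 4), dec = c("a", "a", "b", "b")), sch), "dec")
  cs <- equal_frequency_cutset(dt2, 2)
  expect_equal(cs$starred, "c") # constant column starred
})

test_that("applying the printed cuts reproduces all printed interval labels", {
  disc <- example_disctable()
  expected <- data.frame(
    Pat = c("28", "28", "28", "28", "38", "38", "38", "38"),
    age = c(rep("(-Inf, 55.0)", 4), rep("(55.0, Inf)", 4)),
    t_dur = rep("*", 8),
    Sess = c("1", "2", "2", "4", "1", "2", "3", "4"),
    HYsc = rep("*", 8),
    SccDur = c("(-Inf, 45.5)", "(45.5, Inf)", "(45.5, Inf)", "(45.5, Inf)",
               "(-Inf, 45.5)", "(45.5, Inf)", "(-Inf, 45.5)", "(-Inf, 45.5)"),
    SccLat = c("(260.0, Inf)", "(260.0, Inf)", "(-Inf, 260.0)", "(-Inf, 260.0)",
               "(260.0, Inf)", "(-Inf, 260.0)", "(260.0, Inf)", "(-Inf, 260.0)"),
    SccAmp = c("(10.5, Inf)", "(10.5, Inf)", "(-Inf, 10.5)", "(-Inf, 10.5)",
               "(10.5, Inf)", "(10.5, Inf)", "(10.5, Inf)", "(-Inf, 10.5)"),
    UPDRS = c("(55.0, Inf)", "(22.5, 55.0)", "(22.5, 55.0)", "(14.0, 22.5)",
              "(22.5, 55.0)", "(14.0, 22.5)", "(22.5, 55.0)", "(-Inf, 14.0)"),
    stringsAsFactors = FALSE)
  expect_identical(disc$data, expected)
})

test_that("MISSING propagates and an empty cut set collapses to one granule", {
  sch <- schema(attribute_spec("x", "numeric"),
                attribute_spec("dec", "nominal", "decision"))
  dt <- as_decision_table(information_table(
    data.frame(x = c(1, NA, 3), dec = c("a", "b", "a")), sch), "dec")
  disc <- apply_cuts(dt, cutset(cuts = list(x = 2)))
  expect_identical(disc$data$x, c("(-Inf, 2.0)", NA, "(2.0, Inf)"))
  disc0 <- apply_cuts(dt, cutset(starred = "x"))
  expect_true(all(disc0$data$x == "*"))
  expect_length(partition(disc0, "x"), 1L)
})

test_that("interval labelling is monotone and respects the v >= cut convention", {
  cuts <- c(2, 5, 9)
  v <- c(-3, 1.99, 2, 2.01, 5, 8.5, 9, 12)
  labs <- interval_label(v, cuts)
  bins <- findInterval(v, cuts)
  expect_true(all(diff(bins) >= 0))
  expect_equal(labs[3], "(2.0, 5.0)") # boundary value goes up
  expect_equal(labs[1], "(-Inf, 2.0)")
  expect_equal(labs[8], "(9.0, Inf)")
  expect_equal(unique(labs[order(v)]), unique(labs)) # label order follows value order
})

test_that("bracket dialect renders closed outer intervals from the data range", {
  v <- c(6, 20, 30, 45, 60, 94)
  labs <- interval_label(v, c(25, 40, 55), dialect = "bracket")
  expect_equal(labs[1], "[6, 25]")
  expect_equal(labs[3], "(25, 40]")
  expect_equal(labs[6], "(55, 94]")
})

test_that("MD discretization preserves discernibility on consistent tables", {
  for (seed in 1:5) {
    dt <- random_numeric_table(15, p = 3, classes = 3, seed = seed)
    disc <- apply_cuts(dt, md_select_cuts(dt))
    d <- decision_values(disc)
    raw <- dt$data
    conds <- condition_attrs(dt)
    for (i in seq_len(14)) for (j in seq.int(i + 1, 15)) {
      if (d[i] == d[j]) next
      if (all(raw[i, conds] == raw[j, conds])) next # already indiscernible
      expect_false(all(disc$data[i, conds] == disc$data[j, conds]),
                   label = sprintf("seed %d pair (%d, %d)", seed, i, j))
    }
  }
})

test_that("cut sets serialize to JSON with stars", {
  js <- cutset_to_json(example_cuts())
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$age, 55)
  expect_equal(parsed$t_dur, "*")
  expect_equal(parsed$SccLat, 260)
})
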