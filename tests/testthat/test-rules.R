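e1_disctable <- function() {
  it <- project(example_table(),
                c("Pat", "age", "Sess", "SccDur", "SccLat", "SccAmp", "UPDRS"))
  apply_cuts(as_decision_table(it, "UPDRS"), example_cuts())
}

test_that("row-wise induction reproduces the published worked-example rule", {
  disc <- e1_disctable()
  rules <- induce_rules(disc)
  r8 <- induce_rules(filter_objects(disc, 8L))[[1]]
  expect_equal(r8$support, 1L)
  expect_equal(r8$confidence, 1)
  expect_equal(r8$consequent, "(-Inf, 14.0)")
  expect_equal(
    format_rule(r8),
    paste0("('Pat' = 38) & ('age' = \"(55.0, Inf)\") & ('Sess' = 4) & ",
           "('SccDur' = \"(-Inf, 45.5)\") & ('SccLat' = \"(-Inf, 260.0)\") & ",
           "('SccAmp' = \"(-Inf, 10.5)\") => ('UPDRS' = \"(-Inf, 14.0)\")"))
  # the same rule arises from whole-table induction with full confidence
  whole <- Filter(function(r) r$consequent == "(-Inf, 14.0)", rules)
  expect_true(any(vapply(whole, function(r) r$confidence == 1, logical(1))))
})

test_that("identical rows merge and inconsistent rows split confidence", {
  sch <- schema(attribute_spec("a", "nominal"),
                attribute_spec("dec", "nominal", "decision"))
  same <- as_decision_table(information_table(
    data.frame(a = c("x", "x"), dec = c("p", "p")), sch), "dec")
  r <- induce_rules(same, "a")
  expect_length(r, 1L)
  expect_equal(r[[1]]$support, 2L)
  expect_equal(r[[1]]$confidence, 1)
  clash <- as_decision_table(information_table(
    data.frame(a = c("x", "x"), dec = c("p", "q")), sch), "dec")
  r2 <- induce_rules(clash, "a")
  expect_length(r2, 2L)
  expect_equal(vapply(r2, `[[`, numeric(1), "confidence"), c(0.5, 0.5))
  expect_setequal(vapply(r2, `[[`, character(1), "consequent"), c("p", "q"))
  # confidences per antecedent sum to one over decision labels
  expect_equal(sum(vapply(r2, `[[`, numeric(1), "confidence")), 1)
  expect_error(induce_rules(same, character(0)), "nonempty")
})

test_that("rule voting weights support x confidence, abstains when uncovered", {
  disc <- e1_disctable()
  rules <- induce_rules(disc)
  obj8 <- c(Pat = "38", age = "(55.0, Inf)", Sess = "4",
            SccDur = "(-Inf, 45.5)", SccLat = "(-Inf, 260.0)",
            SccAmp = "(-Inf, 10.5)")
  expect_equal(classify_rules(rules, obj8), "(-Inf, 14.0)")
  nowhere <- c(Pat = "99", age = "(55.0, Inf)", Sess = "1",
               SccDur = "(45.5, Inf)", SccLat = "(260.0, Inf)",
               SccAmp = "(10.5, Inf)")
  expect_true(is.na(classify_rules(rules, nowhere)))
  # hand-built vote: weight 2.0 beats 1.0; equal weights break by support
  r_heavy <- decision_rule(c(a = "x"), "P", support = 2L, confidence = 1)
  r_light <- decision_rule(c(b = "y"), "Q", support = 1L, confidence = 1)
  expect_equal(classify_rules(list(r_heavy, r_light), c(a = "x", b = "y")), "P")
  r_q2 <- decision_rule(c(b = "y"), "Q", support = 4L, confidence = 0.5)
  # totals tie at 2.0; Q wins on larger single-rule support
  expect_equal(classify_rules(list(r_heavy, r_q2), c(a = "x", b = "y")), "Q")
  # simple scheme ignores weights: first-seen label wins ties via support tie-break
  expect_equal(classify_rules(list(r_heavy, r_light), c(a = "x", b = "y"),
                              scheme = "simple"), "P")
})

test_that("rule text round-trips through parse", {
  disc <- e1_disctable()
  for (r in induce_rules(disc)) {
    back <- parse_rule(format_rule(r))
    expect_equal(back$antecedent, r$antecedent)
    expect_equal(back$consequent, r$consequent)
    expect_equal(back$decision, r$decision)
  }
  degenerate <- decision_rule(setNames(character(0), character(0)), "(-Inf, 14.0)",
                              decision = "UPDRS")
  expect_match(format_rule(degenerate), "^=> \\('UPDRS'")
  expect_equal(parse_rule(format_rule(degenerate))$consequent, "(-Inf, 14.0)")
})

test_that("minimal rules carry the shortest consistent antecedents", {
  sch <- schema(attribute_spec("a", "nominal"), attribute_spec("b", "nominal"),
                attribute_spec("dec", "nominal", "decision"))
  df <- data.frame(a = c("x", "x", "y", "y"), b = c("u", "v", "u", "v"),
                   dec = c("P", "P", "Q", "Q"))
  dt <- as_decision_table(information_table(df, sch), "dec")
  rules <- minimal_rules(dt)
  # `a` alone decides; `b` values mix classes, so every antecedent is {a}
  expect_true(all(vapply(rules, function(r)
    identical(names(r$antecedent), "a"), logical(1))))
  expect_setequal(vapply(rules, `[[`, character(1), "consequent"), c("P", "Q"))
  expect_true(all(vapply(rules, `[[`, numeric(1), "support") == 2))
  expect_true(all(vapply(rules, `[[`, numeric(1), "confidence") == 1))
  # an inconsistent pair falls back to a full-length fractional rule
  df2 <- data.frame(a = c("x", "x"), b = c("u", "u"), dec = c("P", "Q"))
  dt2 <- as_decision_table(information_table(df2, sch), "dec")
  r2 <- minimal_rules(dt2)
  expect_setequal(vapply(r2, `[[`, numeric(1), "confidence"), c(0.5, 0.5))
  expect_true(all(lengths(lapply(r2, `[[`, "antecedent")) == 2))
  # consistency can be judged against an enclosing table: a pure subset of an
  # impure universe still needs a discriminating antecedent
  sub <- filter_objects(dt, 1:2)
  r3 <- minimal_rules(sub, within = dt)
  expect_true(all(lengths(lapply(r3, `[[`, "antecedent")) >= 1))
})

test_that("the best template is the fittest splitting descriptor", {
  sch <- schema(attribute_spec("a", "nominal"),
                attribute_spec("dec", "nominal", "decision"))
  dt <- as_decision_table(information_table(
    data.frame(a = c(rep("x", 5), rep("y", 3)), dec = rep("p", 8)), sch), "dec")
  tpl <- best_template(dt)
  expect_equal(tpl$descriptors, c(a = "x"))
  expect_equal(tpl$fitness, 5L)
  # worked example: template fitness equals the maximum over all descriptors
  disc <- e1_disctable()
  tpl2 <- best_template(disc)
  counts <- unlist(lapply(condition_attrs(disc), function(a) {
    v <- disc$data[[a]]
    tab <- table(v[v != "*" & !is.na(v)])
    tab[tab < n_objects(disc)]
  }))
  expect_equal(tpl2$fitness, max(counts))
  # all-identical rows: degenerate
  dt_same <- as_decision_table(information_table(
    data.frame(a = rep("x", 4), dec = rep("p", 4)), sch), "dec")
  expect_null(best_template(dt_same))
})

test_that("decomposition-tree leaves match their path templates", {
  disc <- e1_disctable()
  tree <- build_tree(disc, min_leaf = 2L)
  leaves <- tree_leaves(tree)
  expect_setequal_ids(unlist(lapply(leaves, `[[`, "ids")), disc$ids)
  expect_equal(sum(lengths(lapply(leaves, `[[`, "ids"))), 8L) # a partition
  for (lf in leaves) {
    for (step in lf$path) {
      for (id in lf$ids) {
        obj <- roughpd:::as_record(disc, match(id, disc$ids),
                                   condition_attrs(disc))
        hit <- roughpd:::match_template(step$template, obj)
        expect_equal(hit, step$branch,
                     label = sprintf("leaf obj %d follows its branch", id))
      }
    }
  }
})

test_that("training-set reclassification of a consistent table is perfect", {
  disc <- e1_disctable()
  tree <- build_tree(disc, min_leaf = 1L)
  preds <- vapply(seq_len(8), function(i) {
    classify_tree(tree, roughpd:::as_record(disc, i, condition_attrs(disc)))
  }, character(1))
  expect_equal(preds, decision_values(disc)) # 100% accuracy, 100% coverage
})

test_that("a single-leaf tree equals the flat rule classifier on every object", {
  disc <- e1_disctable()
  tree <- build_tree(disc, min_leaf = n_objects(disc))
  rules <- minimal_rules(disc)
  for (i in seq_len(8)) {
    obj <- roughpd:::as_record(disc, i, condition_attrs(disc))
    expect_identical(classify_tree(tree, obj), classify_rules(rules, obj))
  }
  # also on unseen perturbed objects (including abstentions)
  set.seed(42)
  for (rep in 1:10) {
    obj <- vapply(condition_attrs(disc), function(a)
      sample(unique(disc$data[[a]]), 1), character(1))
    expect_identical(classify_tree(tree, obj), classify_rules(rules, obj))
  }
})
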