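# Shared fixtures: the eight-record two-patient worked example (patients 28
# and 38 across sessions), its printed cut set, and random-table generators
# for property-style tests.

example_schema <- function() {
  schema(
    attribute_spec("Pat", "nominal", "condition"),
    attribute_spec("age", "numeric", "condition", "years"),
    attribute_spec("sex", "nominal", "condition"),
    attribute_spec("t_dur", "numeric", "condition", "years"),
    attribute_spec("Sess", "nominal", "condition"),
    attribute_spec("UPDRS", "numeric", "condition", "score points"),
    attribute_spec("HYsc", "numeric", "condition", "stage"),
    attribute_spec("SccDur", "numeric", "condition", "ms"),
    attribute_spec("SccLat", "numeric", "condition", "ms"),
    attribute_spec("SccAmp", "numeric", "condition", "deg"),
    attribute_spec("SccVel", "numeric", "condition", "deg/s"))
}

example_records <- function() {
  data.frame(
    Pat = c("28", "28", "28", "28", "38", "38", "38", "38"),
    age = c(54, 54, 54, 54, 56, 56, 56, 56),
    sex = c("1", "1", "1", "1", "0", "0", "0", "0"),
    t_dur = c(8, 8, 8, 8, 11, 11, 11, 11),
    Sess = c("1", "2", "2", "4", "1", "2", "3", "4"),
    UPDRS = c(58, 40, 40, 16, 49, 22, 37, 12),
    HYsc = c(2.0, 1.0, 1.0, 1.0, 2.5, 1.5, 2.5, 1.5),
    SccDur = c(43, 46, 49, 47, 42, 48, 43, 45),
    SccLat = c(402, 297, 227, 198, 285, 217, 380, 187),
    SccAmp = c(12, 11, 10, 9, 14, 12, 14, 10),
    SccVel = c(566.9, 474.5, 431.2, 376.2, 675.2, 509.7, 638.9, 482.6),
    stringsAsFactors = FALSE)
}

example_table <- function() information_table(example_records(), example_schema())

# The printed cut set of the worked example (UPDRS as four-bin decision).
example_cuts <- function() {
  cutset(cuts = list(age = 55.0, SccDur = 45.5, SccLat = 260.0, SccAmp = 10.5),
         starred = c("t_dur", "HYsc"), kept = c("Pat", "Sess"),
         decision_cuts = c(14.0, 22.5, 55.0))
}

# Decision table over the worked example's nine discretization attributes.
example_decision_table <- function() {
  it <- project(example_table(),
                c("Pat", "age", "t_dur", "Sess", "HYsc",
                  "SccDur", "SccLat", "SccAmp", "UPDRS"))
  as_decision_table(it, "UPDRS")
}

example_disctable <- function() apply_cuts(example_decision_table(), example_cuts())

# Random discrete decision table: n objects, p condition attributes with
# `levels` labels each, `classes` decision labels.
random_disc_table <- function(n, p = 5L, levels = 3L, classes = 2L,
                              seed = 1L) {
  set.seed(seed)
  df <- as.data.frame(lapply(seq_len(p), function(j)
    sample(letters[seq_len(levels)], n, replace = TRUE)),
    col.names = paste0("a", seq_len(p)))
  df$dec <- sample(LETTERS[seq_len(classes)], n, replace = TRUE)
  sch <- do.call(schema, c(
    lapply(paste0("a", seq_len(p)), attribute_spec, kind = "nominal"),
    list(attribute_spec("dec", "nominal", "decision"))))
  as_decision_table(information_table(df, sch), "dec")
}

# Random numeric decision table for discretization tests.
random_numeric_table <- function(n, p = 2L, classes = 2L, seed = 1L) {
  set.seed(seed)
  df <- as.data.frame(lapply(seq_len(p), function(j) round(runif(n, 0, 10), 1)),
                      col.names = paste0("x", seq_len(p)))
  df$dec <- sample(LETTERS[seq_len(classes)], n, replace = TRUE)
  sch <- do.call(schema, c(
    lapply(paste0("x", seq_len(p)), attribute_spec, kind = "numeric"),
    list(attribute_spec("dec", "nominal", "decision"))))
  as_decision_table(information_table(df, sch), "dec")
}

expect_setequal_ids <- function(a, b) expect_setequal(as.integer(a), as.integer(b))
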