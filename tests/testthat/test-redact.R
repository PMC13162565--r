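mkRows <- function(texts) {
  n <- length(texts)
  data.frame(index = seq_len(n), speaker = "SPEAKER_00",
             start_ms = as.integer(seq(0, by = 400, length.out = n)),
             end_ms = as.integer(seq(300, by = 400, length.out = n)),
             text = texts, confidence = 1, stringsAsFactors = FALSE)
}

test_that("a name-lexicon token is detected and replaced by its placeholder", {
  rows <- mkRows(c("Margaret,", "it's", "nice", "to", "meet", "you."))
  rules <- redactionRules(nameLexicon = "margaret")
  spans <- detectPhi(rows, rules)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$category, "NAME")
  expect_equal(spans$word_start_index, 1)
  red <- applyRedaction(rows, spans, rules)
  expect_equal(red$rows$text[1], "[NAME]")
  expect_identical(red$rows$start_ms, rows$start_ms)
  expect_identical(red$rows$end_ms, rows$end_ms)
})

test_that("placeholder style is configurable", {
  rows <- mkRows(c("Margaret", "hello"))
  rules <- redactionRules(nameLexicon = "margaret",
                          placeholderStyle = "**{CATEGORY}**")
  red <- applyRedaction(rows, detectPhi(rows, rules), rules)
  expect_equal(red$rows$text[1], "**NAME**")
})

test_that("clean rows produce no spans and redaction is the identity", {
  rows <- mkRows(c("we", "are", "back", "again"))
  rules <- redactionRules(nameLexicon = "margaret")
  spans <- detectPhi(rows, rules)
  expect_equal(nrow(spans), 0)
  red <- applyRedaction(rows, spans, rules)
  expect_identical(red$rows, rows)
})

test_that("pattern categories match punctuation-stripped tokens", {
  rows <- mkRows(c("seen", "on", "03/14/2019,", "mrn", "MRN483920",
                   "call", "555-0147", "87-year-old"))
  rules <- redactionRules()
  spans <- detectPhi(rows, rules)
  expect_setequal(spans$category, c("DATE", "ID", "CONTACT", "AGE"))
  expect_equal(spans$word_start_index[spans$category == "DATE"], 3)
  expect_equal(spans$matched_text[spans$category == "DATE"], "03/14/2019,")
})

test_that("safe lexicon suppresses every other rule", {
  rows <- mkRows(c("Springfield", "General"))
  rules <- redactionRules(locationLexicon = "springfield",
                          safeLexicon = "springfield")
  expect_equal(nrow(detectPhi(rows, rules)), 0)
  # safe beats patterns too
  rows2 <- mkRows(c("03/14/2019"))
  rules2 <- redactionRules(safeLexicon = "03/14/2019")
  expect_equal(nrow(detectPhi(rows2, rules2)), 0)
})

test_that("longest match wins and multi-word spans cover several rows", {
  rows <- mkRows(c("she", "lives", "in", "New", "York", "City"))
  rules <- redactionRules(locationLexicon = c("new york city", "york"))
  spans <- detectPhi(rows, rules)
  expect_equal(nrow(spans), 1)
  expect_equal(spans$word_start_index, 4)
  expect_equal(spans$word_end_index, 6)
  red <- applyRedaction(rows, spans, rules)
  expect_equal(red$rows$text[4:6], rep("[LOCATION]", 3))
})

test_that("patterns outrank lexicons on equal-length conflicts", {
  rows <- mkRows(c("MRN483920"))
  rules <- redactionRules(nameLexicon = "mrn483920")
  spans <- detectPhi(rows, rules)
  expect_equal(spans$category, "ID")
  expect_equal(spans$rule_id, "mrn")
})

test_that("redaction is idempotent", {
  spec <- fixtureSpec(seed = 5, durationS = 10)
  tr <- genTranscript(spec)
  rows <- flattenTranscript(tr$transcript)
  rules <- fixtureRedactionRules(tr$plan)
  red <- applyRedaction(rows, detectPhi(rows, rules), rules)
  expect_equal(nrow(detectPhi(red$rows, rules)), 0)
})

test_that("invalid regex fails at rule construction, not detection", {
  pats <- data.frame(id = "broken", regex = "([", category = "ID",
                     stringsAsFactors = FALSE)
  expect_error(redactionRules(patterns = pats), "invalid regex")
})

test_that("span set equals an exhaustive n-gram scan on synthetic lines", {
  rules <- redactionRules(
    nameLexicon = c("margaret", "okafor", "anna maria"),
    locationLexicon = c("springfield", "new york city"),
    safeLexicon = "york")
  texts <- c("well", "Margaret", "and", "Anna", "Maria", "flew", "to",
             "New", "York", "City", "on", "03/14/2019", "then",
             "Springfield", "called", "555-0147", "about", "MRN483920",
             "for", "a", "87-year-old")
  for (seed in 1:10) {
    set.seed(seed)
    rows <- mkRows(sample(texts, 20, replace = TRUE))
    got <- detectPhi(rows, rules)
    want <- bruteForcePhi(rows, rules)
    expect_identical(got[, c("word_start_index", "word_end_index",
                             "category")],
                     want, label = paste("seed", seed))
  }
})

test_that("rule files load from YAML with inline lexicons", {
  f <- withr::local_tempfile(fileext = ".yaml")
  yaml::write_yaml(list(name_lexicon = list("margaret"),
                        location_lexicon = list("springfield"),
                        safe_lexicon = list(),
                        placeholder_style = "[{CATEGORY}]"), f)
  rules <- readRedactionRules(f)
  expect_s4_class(rules, "RedactionRules")
  expect_equal(rules@nameLexicon, "margaret")
  # default patterns attached when the file names none
  expect_true("mrn" %in% rules@patterns$id)
})

test_that("spans referencing absent word indices error in applyRedaction", {
  rows <- mkRows(c("hello", "there"))
  rules <- redactionRules(nameLexicon = "x")
  spans <- data.frame(word_start_index = 5L, word_end_index = 5L,
                      category = "NAME", matched_text = "x",
                      rule_id = "name_lexicon", stringsAsFactors = FALSE)
  expect_error(applyRedaction(rows, spans, rules), "outside")
})
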