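#' Redaction rule set
#'
#' A PHI rule engine configuration: case-folded name and location lexicons
#' (single tokens or multi-word phrases), a safe lexicon that always
#' suppresses a match, an ordered list of regex patterns for the
#' pattern-shaped categories (DATE, ID, CONTACT, AGE), and a placeholder
#' template.
#'
#' Precedence at detection time is safe lexicon > patterns > lexicons;
#' overlapping candidates are resolved longest-match-first with ties broken
#' by evaluation order.
#'
#' @slot nameLexicon case-folded name tokens/phrases
#' @slot locationLexicon case-folded location tokens/phrases
#' @slot safeLexicon tokens never redacted, whatever else matches
#' @slot patterns data.frame with columns id, regex, category (ordered)
#' @slot placeholderStyle template rendered per category; `{CATEGORY}` is
#'   substituted, e.g. the default `"[{CATEGORY}]"` renders `"[NAME]"`
#' @export
setClass("RedactionRules",
  representation(nameLexicon = "character", locationLexicon = "character",
                 safeLexicon = "character", patterns = "data.frame",
                 placeholderStyle = "character"))

PHI_CATEGORIES <- c("NAME", "DATE", "LOCATION", "ID", "CONTACT", "AGE")

setValidity("RedactionRules", function(object) {
  p <- object@patterns
  if (nrow(p) && !all(c("id", "regex", "category") %in% names(p)))
    return("patterns must have columns id, regex, category")
  if (nrow(p) && !all(p$category %in% PHI_CATEGORIES))
    return(paste("pattern categories must be among:",
                 paste(PHI_CATEGORIES, collapse = ", ")))
  for (i in seq_len(nrow(p))) {
    ok <- tryCatch({ grepl(p$regex[i], "probe", perl = TRUE); TRUE },
                   error = function(e) FALSE, warning = function(e) FALSE)
    if (!ok) return(sprintf("invalid regex in pattern '%s'", p$id[i]))
  }
  if (length(object@placeholderStyle) != 1)
    return("placeholderStyle must be a single template string")
  TRUE
})

#' Construct a redaction rule set
#'
#' @param nameLexicon,locationLexicon,safeLexicon character vectors; folded
#'   to lower case on construction
#' @param patterns data.frame (id, regex, category) evaluated in row order;
#'   regexes are matched case-insensitively against punctuation-stripped
#'   word tokens. Invalid regexes error here, at configuration time.
#' @param placeholderStyle placeholder template; `{CATEGORY}` is replaced by
#'   the category name
#' @return a [RedactionRules-class]
#' @export
redactionRules <- function(nameLexicon = character(),
                           locationLexicon = character(),
                           safeLexicon = character(),
                           patterns = defaultPhiPatterns(),
                           placeholderStyle = "[{CATEGORY}]") {
  if (is.null(patterns))
    patterns <- data.frame(id = character(), regex = character(),
                           category = character(), stringsAsFactors = FALSE)
  new("RedactionRules",
      nameLexicon = unique(tolower(trimws(nameLexicon))),
      locationLexicon = unique(tolower(trimws(locationLexicon))),
      safeLexicon = unique(tolower(trimws(safeLexicon))),
      patterns = patterns, placeholderStyle = placeholderStyle)
}

#' Default patterns for pattern-shaped PHI categories
#'
#' Dates (numeric m/d/y forms), medical record numbers, phone-style contact
#' numbers, and spelled ages ("87-year-old"). Deliberately small: a starting
#' point users extend per institution, not a full Safe Harbor rule base.
#' @return data.frame with columns id, regex, category
#' @export
defaultPhiPatterns <- function() {
  data.frame(
    id = c("date_numeric", "mrn", "phone", "age_hyphenated"),
    regex = c("^\\d{1,2}[/-]\\d{1,2}[/-]\\d{2,4}$",
              "^mrn[-#]?\\d{4,}$",
              "^\\(?\\d{3}\\)?[-. ]?\\d{3}[-.]\\d{4}$|^\\d{3}[-.]\\d{4}$",
              "^\\d{1,3}-year-old$"),
    category = c("DATE", "ID", "CONTACT", "AGE"),
    stringsAsFactors = FALSE)
}

#' Read a rule set from YAML or JSON
#'
#' Keys: `name_lexicon`, `location_lexicon`, `safe_lexicon` (inline lists or
#' paths to one-token-per-line files, relative to the rule file),
#' `patterns` (list of `{id, regex, category}`), `placeholder_style`.
#' @param path rule file (.yaml/.yml/.json)
#' @return a [RedactionRules-class]
#' @export
readRedactionRules <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE))
    yaml::read_yaml(path) else jsonlite::fromJSON(path, simplifyVector = FALSE)
  lex <- function(x) {
    if (is.null(x)) return(character())
    x <- unlist(x, use.names = FALSE)
    if (length(x) == 1 && file.exists(file.path(dirname(path), x)))
      x <- readLines(file.path(dirname(path), x), warn = FALSE)
    as.character(x)
  }
  pats <- if (is.null(raw$patterns)) defaultPhiPatterns() else
    do.call(rbind, lapply(raw$patterns, function(p)
      data.frame(id = p$id, regex = p$regex, category = p$category,
                 stringsAsFactors = FALSE)))
  redactionRules(nameLexicon = lex(raw$name_lexicon),
                 locationLexicon = lex(raw$location_lexicon),
                 safeLexicon = lex(raw$safe_lexicon),
                 patterns = pats,
                 placeholderStyle = raw$placeholder_style %||% "[{CATEGORY}]")
}

#' Render the placeholder for a category
#' @param rules a [RedactionRules-class]
#' @param category PHI category name
#' @export
renderPlaceholder <- function(rules, category) {
  gsub("{CATEGORY}", category, rules@placeholderStyle, fixed = TRUE)
}

# Strip leading/trailing punctuation from a token; internal punctuation
# (dates "03/14/2019", phones "555-0147") is preserved.
stripPunct <- function(x) gsub("^[[:punct:]]+|[[:punct:]]+$", "", x)

matchToken <- function(x) tolower(stripPunct(x))

#' Detect PHI spans in a flattened word table
#'
#' Scans word n-grams against the name/location lexicons and each word's
#' punctuation-stripped token against the regex patterns. Candidates whose
#' phrase, or any constituent token, appears in the safe lexicon are
#' suppressed. Overlaps are resolved deterministically: longer spans win;
#' among equal lengths patterns precede lexicons, then earlier pattern /
#' lexicon order, then earlier start. Tokens that already equal a rendered
#' placeholder are skipped, which makes redaction idempotent.
#'
#' @param rows flattened word table ([flattenTranscript()])
#' @param rules a [RedactionRules-class]
#' @return data.frame of spans: word_start_index, word_end_index, category,
#'   matched_text, rule_id; sorted by word_start_index, non-overlapping
#' @export
detectPhi <- function(rows, rules) {
  stopifnot(is(rules, "RedactionRules"))
  empty <- data.frame(word_start_index = integer(), word_end_index = integer(),
                      category = character(), matched_text = character(),
                      rule_id = character(), stringsAsFactors = FALSE)
  n <- nrow(rows)
  if (!n) return(empty)
  if (!identical(order(rows$index), seq_len(n)))
    stop("rows must be in word order", call. = FALSE)

  toks <- matchToken(rows$text)
  placeholders <- tolower(vapply(PHI_CATEGORIES, renderPlaceholder,
                                 "", rules = rules))
  skip <- tolower(rows$text) %in% placeholders
  safe <- function(phraseToks) {
    paste(phraseToks, collapse = " ") %in% rules@safeLexicon ||
      any(phraseToks %in% rules@safeLexicon)
  }

  cand <- list(); k <- 0L
  # Pattern candidates: single-word, in pattern order (priority class 1).
  for (pi in seq_len(nrow(rules@patterns))) {
    hits <- which(!skip & toks != "" &
                  grepl(rules@patterns$regex[pi], toks,
                        perl = TRUE, ignore.case = TRUE))
    for (i in hits) {
      if (safe(toks[i])) next
      k <- k + 1L
      cand[[k]] <- data.frame(
        word_start_index = rows$index[i], word_end_index = rows$index[i],
        category = rules@patterns$category[pi], matched_text = rows$text[i],
        rule_id = rules@patterns$id[pi], priorityClass = 1L, rulePos = pi,
        stringsAsFactors = FALSE)
    }
  }
  # Lexicon candidates: n-grams up to the longest phrase in either lexicon
  # (priority class 2; name lexicon evaluated before location).
  lexes <- list(list(set = rules@nameLexicon, category = "NAME",
                     id = "name_lexicon", pos = 1L),
                list(set = rules@locationLexicon, category = "LOCATION",
                     id = "location_lexicon", pos = 2L))
  for (lx in lexes) {
    if (!length(lx$set)) next
    maxLen <- max(lengths(strsplit(lx$set, "\\s+")))
    for (len in seq_len(maxLen)) {
      if (len > n) break
      for (i in seq_len(n - len + 1L)) {
        span <- i:(i + len - 1L)
        if (any(skip[span]) || any(toks[span] == "")) next
        phrase <- paste(toks[span], collapse = " ")
        if (!(phrase %in% lx$set) || safe(toks[span])) next
        k <- k + 1L
        cand[[k]] <- data.frame(
          word_start_index = rows$index[i],
          word_end_index = rows$index[i + len - 1L],
          category = lx$category,
          matched_text = paste(rows$text[span], collapse = " "),
          rule_id = lx$id, priorityClass = 2L, rulePos = lx$pos,
          stringsAsFactors = FALSE)
      }
    }
  }
  if (!k) return(empty)
  cand <- do.call(rbind, cand)
  len <- cand$word_end_index - cand$word_start_index
  ord <- order(-len, cand$priorityClass, cand$rulePos, cand$word_start_index)
  cand <- cand[ord, , drop = FALSE]
  len <- len[ord]
  taken <- rep(FALSE, n)
  keep <- logical(nrow(cand))
  pos <- match(cand$word_start_index, rows$index)
  for (ci in seq_len(nrow(cand))) {
    span <- pos[ci]:(pos[ci] + len[ci])
    if (any(taken[span])) next
    taken[span] <- TRUE
    keep[ci] <- TRUE
  }
  out <- cand[keep, c("word_start_index", "word_end_index", "category",
                      "matched_text", "rule_id"), drop = FALSE]
  out <- out[order(out$word_start_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Apply PHI spans to a flattened word table
#'
#' Replaces the text of every word inside each span with the rendered
#' placeholder; timestamps, indices and speakers are untouched. Returns the
#' redacted rows and a redaction map recording span -> placeholder.
#'
#' @param rows flattened word table
#' @param spans spans from [detectPhi()] on the same rows
#' @param rules a [RedactionRules-class]
#' @return list with elements `rows` (redacted table) and `map` (data.frame:
#'   span fields plus placeholder)
#' @export
applyRedaction <- function(rows, spans, rules) {
  out <- rows
  map <- cbind(spans,
               placeholder = vapply(spans$category, renderPlaceholder, "",
                                    rules = rules),
               stringsAsFactors = FALSE)
  rownames(map) <- NULL
  for (si in seq_len(nrow(spans))) {
    pos <- match(spans$word_start_index[si]:spans$word_end_index[si],
                 rows$index)
    if (anyNA(pos))
      stop(sprintf("span %d references word indices outside the table", si),
           call. = FALSE)
    out$text[pos] <- map$placeholder[si]
  }
  list(rows = out, map = map)
}
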