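#' Parse a diarized transcript JSON document
#'
#' Reads the WhisperX-compatible schema: top-level `language`, `duration_ms`
#' and `segments`, each segment carrying second-valued `start`/`end`, `text`,
#' `speaker` and a `words` list with per-word `word`, `start`, `end`,
#' `score`. Second-valued timestamps are converted to integer milliseconds by
#' half-up rounding; global word indices are assigned in document order.
#'
#' A word missing its `score` receives confidence 1.0 with a warning (some
#' ASR backends omit per-word scores). Negative or reversed timestamps are
#' rejected with an error naming the offending word.
#'
#' @param x path to a JSON file, or a JSON string
#' @return a [Transcript-class] object
#' @export
parseTranscript <- function(x) {
  txt <- if (length(x) == 1 && !grepl("[{\\[]", substr(x, 1, 1)) &&
             file.exists(x)) paste(readLines(x, warn = FALSE), collapse = "\n")
         else paste(x, collapse = "\n")
  doc <- tryCatch(jsonlite::fromJSON(txt, simplifyVector = FALSE),
                  error = function(e)
                    stop("malformed transcript JSON: ", conditionMessage(e),
                         call. = FALSE))
  if (is.null(doc$segments))
    stop("transcript document has no 'segments' field", call. = FALSE)
  lang <- if (!is.null(doc$language)) as.character(doc$language) else "en"

  wordRows <- list(); segRows <- list(); idx <- 0L; missingScore <- 0L
  for (si in seq_along(doc$segments)) {
    seg <- doc$segments[[si]]
    spk <- if (!is.null(seg$speaker)) as.character(seg$speaker) else "SPEAKER_00"
    segRows[[si]] <- data.frame(
      segment = si, speaker = spk,
      start_ms = secToMs(as.numeric(seg$start)),
      end_ms = secToMs(as.numeric(seg$end)),
      text = if (!is.null(seg$text)) as.character(seg$text) else "",
      stringsAsFactors = FALSE)
    for (w in seg$words) {
      idx <- idx + 1L
      if (is.null(w$word) || is.null(w$start) || is.null(w$end))
        stop(sprintf("word %d in segment %d lacks word/start/end", idx, si),
             call. = FALSE)
      sc <- if (is.null(w$score)) { missingScore <- missingScore + 1L; 1.0 }
            else as.numeric(w$score)
      wordRows[[idx]] <- data.frame(
        index = idx, segment = si, speaker = spk,
        start_ms = secToMs(as.numeric(w$start)),
        end_ms = secToMs(as.numeric(w$end)),
        text = as.character(w$word), confidence = sc,
        stringsAsFactors = FALSE)
    }
  }
  if (missingScore > 0)
    warning(sprintf("%d word(s) lacked a confidence score; defaulted to 1.0",
                    missingScore))
  words <- if (length(wordRows)) do.call(rbind, wordRows) else emptyWordTable()
  segs <- if (length(segRows)) do.call(rbind, segRows) else emptySegmentTable()
  dur <- if (!is.null(doc$duration_ms)) as.integer(doc$duration_ms)
         else if (nrow(words)) max(words$end_ms) else 0L
  # Widen any segment that under-covers its words (defensive; keeps the
  # covering invariant when upstream sentence bounds are loose).
  if (nrow(words)) {
    for (si in seq_len(nrow(segs))) {
      ws <- words[words$segment == segs$segment[si], ]
      if (nrow(ws)) {
        segs$start_ms[si] <- min(segs$start_ms[si], min(ws$start_ms))
        segs$end_ms[si] <- max(segs$end_ms[si], max(ws$end_ms))
      }
    }
  }
  validateWordOrder(words)
  new("Transcript", words = words, segments = segs, language = lang,
      durationMs = dur)
}

validateWordOrder <- function(words) {
  if (!nrow(words)) return(invisible(TRUE))
  bad <- which(words$end_ms < words$start_ms)
  if (length(bad))
    stop(sprintf("word %d ('%s') has end before start (%d < %d ms)",
                 words$index[bad[1]], words$text[bad[1]],
                 words$end_ms[bad[1]], words$start_ms[bad[1]]), call. = FALSE)
  bad <- which(words$start_ms < 0)
  if (length(bad))
    stop(sprintf("word %d ('%s') has negative start time",
                 words$index[bad[1]], words$text[bad[1]]), call. = FALSE)
  if (!identical(order(words$start_ms, words$index), seq_len(nrow(words))))
    stop("words are not in start-time order", call. = FALSE)
  invisible(TRUE)
}

#' Build a Transcript from a word table
#'
#' Convenience constructor used by the synthetic generator and tests. Segment
#' bounds are widened to cover their words; segment text defaults to the
#' concatenated word text.
#'
#' @param words data.frame with columns segment, speaker, start_ms, end_ms,
#'   text, confidence (index is assigned from row order)
#' @param language language tag
#' @param durationMs source audio duration in ms (default: last word end)
#' @return a [Transcript-class]
#' @export
transcriptFromWords <- function(words, language = "en", durationMs = NULL) {
  if (!nrow(words)) {
    return(new("Transcript", words = emptyWordTable(),
               segments = emptySegmentTable(), language = language,
               durationMs = as.integer(durationMs %||% 0L)))
  }
  words <- words[order(words$start_ms), , drop = FALSE]
  words$index <- seq_len(nrow(words))
  rownames(words) <- NULL
  segs <- do.call(rbind, lapply(unique(words$segment), function(g) {
    ws <- words[words$segment == g, ]
    data.frame(segment = g, speaker = ws$speaker[1],
               start_ms = min(ws$start_ms), end_ms = max(ws$end_ms),
               text = paste(ws$text, collapse = " "),
               stringsAsFactors = FALSE)
  }))
  rownames(segs) <- NULL
  dur <- as.integer(durationMs %||% max(words$end_ms))
  new("Transcript", words = words[, WORD_COLUMNS], segments = segs,
      language = language, durationMs = dur)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Serialize a Transcript to its JSON document form
#'
#' Inverse of [parseTranscript()]: emits the WhisperX-compatible schema with
#' second-valued timestamps. Byte-stable: serializing the same Transcript
#' twice yields identical text, and `parseTranscript(serializeTranscript(t))`
#' reproduces `t` on the retained field set.
#'
#' @param t a [Transcript-class]
#' @param path optional file to write; when NULL the JSON string is returned
#' @return JSON string (invisibly, when `path` is given)
#' @export
serializeTranscript <- function(t, path = NULL) {
  stopifnot(is(t, "Transcript"))
  segs <- lapply(seq_len(nSegments(t)), function(si) {
    seg <- t@segments[si, ]
    ws <- t@words[t@words$segment == seg$segment, , drop = FALSE]
    list(start = seg$start_ms / 1000, end = seg$end_ms / 1000,
         text = seg$text, speaker = seg$speaker,
         words = lapply(seq_len(nrow(ws)), function(wi) {
           list(word = ws$text[wi], start = ws$start_ms[wi] / 1000,
                end = ws$end_ms[wi] / 1000, score = ws$confidence[wi])
         }))
  })
  doc <- list(language = t@language, duration_ms = t@durationMs,
              segments = segs)
  json <- jsonlite::toJSON(doc, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  if (!is.null(path)) {
    writeLines(json, path, useBytes = TRUE)
    return(invisible(as.character(json)))
  }
  as.character(json)
}

#' Flatten a Transcript to one row per word
#'
#' Produces the word-order table consumed by the redaction engine:
#' `index, speaker, start_ms, end_ms, text, confidence`. Lossless with
#' respect to those fields; row count equals the word count.
#'
#' @param t a [Transcript-class]
#' @return data.frame in global word order
#' @export
flattenTranscript <- function(t) {
  stopifnot(is(t, "Transcript"))
  out <- t@words[, c("index", "speaker", "start_ms", "end_ms", "text",
                     "confidence"), drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Write/read the flattened word table as CSV
#'
#' RFC-4180 quoting, UTF-8, header `index,speaker,start_ms,end_ms,text,confidence`.
#' @param rows flattened word table
#' @param path CSV file path
#' @export
writeFlattened <- function(rows, path) {
  utils::write.csv(rows, path, row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname writeFlattened
#' @export
readFlattened <- function(path) {
  utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8",
                  colClasses = c(index = "integer", speaker = "character",
                                 start_ms = "integer", end_ms = "integer",
                                 text = "character", confidence = "numeric"))
}
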