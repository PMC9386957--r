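## End-to-end driver: parse -> arc diagram -> shape -> fold -> classify ->
## factorize -> minimize -> generator tracking, assembled into a report.

.detectFormat <- function(input) {
  joined <- paste(input, collapse = "\n")
  if (grepl(":", joined, fixed = TRUE)) return("invariant")
  lines <- trimws(unlist(strsplit(joined, "\n")))
  lines <- lines[nzchar(lines)]
  if (length(lines) > 0L &&
      all(grepl("^[0-9]+[[:space:]]+\\S+[[:space:]]+[0-9]+$", lines)))
    return("bpseq")
  "dotbracket"
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e) {
    stop(sprintf("pipeline stage '%s' failed: %s", name, conditionMessage(e)),
         call. = FALSE)
  })
}

#' Run the full structure-to-factorization pipeline
#'
#' Accepts an RNA secondary structure in (extended) dot-bracket notation, a
#' BPSEQ listing, or a raw tangle invariant string, and carries it through
#' parsing, flattening, shape reduction, book-folding, classification,
#' factorization, rewriting minimization and generator tracking.
#'
#' @param input Character input: a structure/invariant string, or the lines
#'   of a file.
#' @param format One of \code{"auto"}, \code{"dotbracket"}, \code{"bpseq"},
#'   \code{"invariant"}.
#' @param maxStates Rewriting search budget, see [minimizeWord()].
#' @param trace Keep the rewrite trace in the report?
#' @return A [TangleReport-class].
#' @examples
#' runPipeline("1:1',2:4,3:5',5:4',2':3'")
#' @export
runPipeline <- function(input, format = c("auto", "dotbracket", "bpseq",
                                          "invariant"),
                        maxStates = 1e5, trace = FALSE) {
  format <- match.arg(format)
  if (format == "auto") format <- .detectFormat(input)
  structure <- NULL
  shape <- NULL
  posMap <- data.frame(dot = character(0), position = integer(0))
  if (format == "invariant") {
    tangle <- .stage("parse", parseInvariant(paste(input, collapse = "")))
  } else {
    structure <- .stage("parse", switch(format,
      dotbracket = if (length(input) > 1L) readDotBracket(input)
                   else parseDotBracket(input),
      bpseq = parseBpseq(input)))
    flat <- .stage("arc diagram", toArcDiagram(structure))
    shape <- .stage("shape reduction", reduceToShape(flat))
    folded <- .stage("fold", foldToTangle(shape))
    tangle <- folded$tangle
    posMap <- folded$positionMap
  }
  cls <- classifyTangle(tangle)
  raw <- .stage("factorize", factorizeTangle(tangle, minimize = FALSE))
  minimized <- .stage("minimize", minimizeWord(raw))
  gens <- .stage("generator tracking", trackGenerators(minimized$word))
  new("TangleReport",
      input = paste(input, collapse = "\n"), format = format,
      structure = structure, shape = shape, positionMap = posMap,
      tangle = tangle, tangleClass = cls, rawWord = raw,
      minimizedWord = minimized$word,
      certifiedMinimal = minimized$certified,
      crossingNumber = crossingNumber(tangle), generators = gens,
      trace = if (trace) minimized$trace else
        data.frame(rule = character(0), pos = integer(0),
                   before = character(0), after = character(0)))
}

#' Serialize a report as JSON
#'
#' Schema-stable JSON rendering of a [TangleReport-class]: byte-identical
#' across runs for identical input.
#'
#' @param report A [TangleReport-class].
#' @param pretty Indent the output?
#' @return A JSON character scalar.
#' @export
reportToJSON <- function(report, pretty = FALSE) {
  stopifnot(is(report, "TangleReport"))
  genList <- lapply(report@generators, function(df) {
    lapply(seq_len(nrow(df)), function(r)
      list(position = df$position[r], kind = df$kind[r], index = df$index[r]))
  })
  wordList <- function(w) {
    lapply(seq_along(w@kind), function(k)
      list(kind = w@kind[k], i = w@index[k]))
  }
  obj <- list(
    input = report@input,
    format = report@format,
    shape = if (is.null(report@shape)) NULL else
      unname(apply(report@shape@arcs, 1L, identity, simplify = FALSE)),
    tangle = list(n = report@tangle@n,
                  invariant = formatInvariant(report@tangle)),
    class = report@tangleClass,
    crossing_number = report@crossingNumber,
    raw_word = formatWord(report@rawWord),
    minimized_word = formatWord(report@minimizedWord),
    minimized_factors = wordList(report@minimizedWord),
    certified_minimal = report@certifiedMinimal,
    generators = genList,
    trace = if (nrow(report@trace)) report@trace else NULL
  )
  as.character(jsonlite::toJSON(obj, auto_unbox = TRUE, null = "null",
                                pretty = pretty, digits = NA))
}
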