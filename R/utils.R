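#' @keywords internal
"_PACKAGE"

#' @importFrom stats setNames
#' @importFrom utils read.csv write.csv head
NULL

`%||%` <- function(x, y) if (is.null(x) || length(x) == 0) y else x

#' Normalize a term surface
#'
#' Lower-cases, trims, and collapses internal whitespace to single spaces.
#' All dictionary comparisons are performed on this normal form, so that
#' e.g. "LVEF", "lvef" and "LV  EF" reduce to comparable strings.
#'
#' @param x character vector of surfaces.
#' @return character vector of normalized surfaces.
#' @export
#' @examples
#' normalize_term("  Left   Ventricular EF ")
normalize_term <- function(x) {
  x <- tolower(as.character(x))
  x <- gsub("\\s+", " ", x)
  trimws(x)
}

# Tokenize a normalized surface on whitespace.
term_tokens <- function(x) {
  if (!nzchar(x)) return(character(0))
  strsplit(x, " ", fixed = TRUE)[[1]]
}

# Connective tokens that carry no content for token-overlap scoring.
STOP_TOKENS <- c("of", "the", "at", "a", "an", "to", "and")

# Connector tokens allowed between words merged by the concept builder.
BUILDER_CONNECTORS <- c("of", "the", "at", "a", "an", "and")

# Maximum number of lexicon words in a single built term; prevents runaway
# merging across clauses.
BUILDER_MAX_WORDS <- 8L

ORIGIN_PRIORITY <- c(PHRASE = 3L, ABBREVIATION = 2L, BUILT = 1L)

# Escape regex metacharacters in a literal surface.
escape_regex <- function(x) gsub("([][{}()+*^$|\\\\?.])", "\\\\\\1", x)

# Turn a normalized surface into a regex fragment: literal characters with
# flexible internal whitespace.
surface_fragment <- function(surface) {
  gsub(" ", "\\\\s+", escape_regex(surface))
}

# Wrap a regex body with token-boundary guards: no match may start or end
# inside a longer alphanumeric run.
with_boundaries <- function(body) {
  paste0("(?<![[:alnum:]])(?:", body, ")(?![[:alnum:]])")
}

# Locate all matches of a perl regex; returns a data.frame with 1-based
# inclusive start/end and the matched text.
locate_all <- function(text, pattern, ignore_case = TRUE) {
  if (!nzchar(text)) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  if (ignore_case) pattern <- paste0("(?i)", pattern)
  m <- gregexpr(pattern, text, perl = TRUE)[[1]]
  if (m[1] == -1) {
    return(data.frame(start = integer(0), end = integer(0),
                      text = character(0), stringsAsFactors = FALSE))
  }
  start <- as.integer(m)
  len <- attr(m, "match.length")
  end <- start + len - 1L
  data.frame(start = start, end = end,
             text = substring(text, start, end),
             stringsAsFactors = FALSE)
}

# Build an alternation regex over a set of surfaces, longest first so that
# the regex engine prefers the longest surface at any position.
surfaces_alternation <- function(surfaces) {
  surfaces <- surfaces[nzchar(surfaces)]
  if (length(surfaces) == 0) return(NULL)
  surfaces <- surfaces[order(-nchar(surfaces), surfaces)]
  with_boundaries(paste(vapply(surfaces, surface_fragment, ""), collapse = "|"))
}

# Read a headerless comma-delimited resource file, skipping blank lines and
# '#' comments; returns list(fields = list of character vectors, line = ints).
read_resource_lines <- function(path) {
  if (!file.exists(path)) {
    stop("resource file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(!grepl("^\\s*(#|$)", raw))
  fields <- lapply(raw[keep], function(ln) {
    scan(text = ln, what = character(), sep = ",", quote = "\"",
         quiet = TRUE, strip.white = TRUE)
  })
  list(fields = fields, line = keep)
}

# Split a ';'-separated multi-value field into a character vector.
split_multi <- function(x) {
  if (is.na(x) || !nzchar(x)) return(character(0))
  trimws(strsplit(x, ";", fixed = TRUE)[[1]])
}

empty_df <- function(...) {
  cols <- list(...)
  out <- lapply(cols, function(cl) vector(cl, 0))
  names(out) <- names(cols)
  as.data.frame(out, stringsAsFactors = FALSE)
}
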