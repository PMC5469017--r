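# Loading and validation of the knowledge resources: concept inventory,
# term dictionary, anatomy/measure word lexicon, qualitative-value lexicon,
# unit table, and mutual-exclusion constraint groups.

#' Load the measurement concept inventory
#'
#' Reads `concepts.csv` with columns concept_id, label, value_kind, units,
#' anatomy_tags, measure_tags (the last three `;`-separated). The shipped
#' inventory contains 27 cardiac structure and function concepts.
#'
#' @param path path to a concepts CSV file.
#' @return data.frame with columns `concept_id`, `label`, `value_kind`
#'   (one of QUANTITATIVE, QUALITATIVE, BOTH) and list-columns `units`,
#'   `anatomy_tags`, `measure_tags`.
#' @export
load_concepts <- function(path) {
  res <- read_resource_lines(path)
  rows <- lapply(seq_along(res$fields), function(i) {
    f <- res$fields[[i]]
    if (length(f) != 6) {
      stop("concepts: line ", res$line[i], ": expected 6 fields, got ",
           length(f), call. = FALSE)
    }
    f
  })
  if (length(rows) == 0) {
    out <- empty_df(concept_id = "character", label = "character",
                    value_kind = "character")
    out$units <- list(); out$anatomy_tags <- list(); out$measure_tags <- list()
    return(out)
  }
  out <- data.frame(
    concept_id = vapply(rows, `[[`, "", 1),
    label = vapply(rows, `[[`, "", 2),
    value_kind = vapply(rows, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  bad_kind <- !out$value_kind %in% c("QUANTITATIVE", "QUALITATIVE", "BOTH")
  if (any(bad_kind)) {
    stop("concepts: invalid value_kind at line ",
         res$line[which(bad_kind)[1]], call. = FALSE)
  }
  if (anyDuplicated(out$concept_id)) {
    stop("concepts: duplicate concept_id: ",
         out$concept_id[duplicated(out$concept_id)][1], call. = FALSE)
  }
  out$units <- lapply(rows, function(f) split_multi(f[4]))
  out$anatomy_tags <- lapply(rows, function(f) split_multi(f[5]))
  out$measure_tags <- lapply(rows, function(f) split_multi(f[6]))
  out
}

#' Load the term dictionary
#'
#' The dictionary lists one `term,concept_id` pair per line (`#` comments
#' allowed, quotes honored for surfaces containing commas). Surfaces are
#' normalized with [normalize_term()] at load time.
#'
#' @param path path to a dictionary CSV file.
#' @param concepts concept inventory from [load_concepts()]; entries naming
#'   an unknown concept are a resource error. Pass `NULL` to skip the check.
#' @return data.frame with columns `surface`, `concept_id`, `line`.
#' @export
load_dictionary <- function(path, concepts = NULL) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) {
    return(empty_df(surface = "character", concept_id = "character",
                    line = "integer"))
  }
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 2) {
      stop("dictionary: line ", res$line[i],
           ": expected 2 comma-delimited fields, got ",
           length(res$fields[[i]]), call. = FALSE)
    }
  }
  out <- data.frame(
    surface = normalize_term(vapply(res$fields, `[[`, "", 1)),
    concept_id = vapply(res$fields, `[[`, "", 2),
    line = res$line,
    stringsAsFactors = FALSE
  )
  if (any(!nzchar(out$surface))) {
    stop("dictionary: line ", out$line[which(!nzchar(out$surface))[1]],
         ": empty term surface", call. = FALSE)
  }
  if (!is.null(concepts)) {
    unknown <- !out$concept_id %in% concepts$concept_id
    if (any(unknown)) {
      stop("dictionary: line ", out$line[which(unknown)[1]],
           ": unknown concept_id '", out$concept_id[which(unknown)[1]], "'",
           call. = FALSE)
    }
  }
  # A surface maps to exactly one concept; exact duplicates are collapsed,
  # conflicting duplicates are a resource error.
  split_map <- split(out$concept_id, out$surface)
  conflict <- names(split_map)[vapply(split_map, function(x)
    length(unique(x)) > 1, TRUE)]
  if (length(conflict) > 0) {
    stop("dictionary: surface '", conflict[1],
         "' maps to multiple concepts", call. = FALSE)
  }
  out[!duplicated(out$surface), , drop = FALSE]
}

#' Load the anatomy/measure word lexicon
#'
#' Reads `words.csv` with columns surface, category (ANATOMY or MEASURE)
#' and group (the canonical semantic group shared by variants and
#' misspellings of the same word).
#'
#' @param path path to a words CSV file.
#' @return data.frame with columns `surface`, `category`, `group_id`.
#' @export
load_word_lexicon <- function(path) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) {
    return(empty_df(surface = "character", category = "character",
                    group_id = "character"))
  }
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 3) {
      stop("words: line ", res$line[i], ": expected 3 fields", call. = FALSE)
    }
  }
  out <- data.frame(
    surface = normalize_term(vapply(res$fields, `[[`, "", 1)),
    category = toupper(vapply(res$fields, `[[`, "", 2)),
    group_id = vapply(res$fields, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  bad <- !out$category %in% c("ANATOMY", "MEASURE")
  if (any(bad)) {
    stop("words: line ", res$line[which(bad)[1]],
         ": category must be ANATOMY or MEASURE", call. = FALSE)
  }
  key <- split(paste(out$category, out$group_id), out$surface)
  conflict <- names(key)[vapply(key, function(x) length(unique(x)) > 1, TRUE)]
  if (length(conflict) > 0) {
    stop("words: surface '", conflict[1],
         "' assigned to more than one category/group", call. = FALSE)
  }
  out[!duplicated(out$surface), , drop = FALSE]
}

#' Load mutual-exclusion constraint pairs
#'
#' Each row declares an unordered pair of semantic groups that cannot both
#' describe the same measurement concept (e.g. atrium vs. ventricle, volume
#' vs. pressure). Exclusion is symmetric; self-exclusion is an error.
#'
#' @param path path to a constraints CSV file.
#' @return data.frame with columns `group_a`, `group_b`.
#' @export
load_constraints <- function(path) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) return(empty_df(group_a = "character", group_b = "character"))
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 2) {
      stop("constraints: line ", res$line[i], ": expected 2 fields",
           call. = FALSE)
    }
  }
  out <- data.frame(
    group_a = vapply(res$fields, `[[`, "", 1),
    group_b = vapply(res$fields, `[[`, "", 2),
    stringsAsFactors = FALSE
  )
  if (any(out$group_a == out$group_b)) {
    stop("constraints: a group cannot exclude itself", call. = FALSE)
  }
  out
}

#' Load the unit table
#'
#' Reads `units.csv` with columns unit_id, surfaces (`;`-separated variants)
#' and dimension. Surface variants must be unique across units after
#' normalization.
#'
#' @param path path to a units CSV file.
#' @return data.frame with columns `unit_id`, `dimension` and list-column
#'   `surfaces`.
#' @export
load_units <- function(path) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) {
    out <- empty_df(unit_id = "character", dimension = "character")
    out$surfaces <- list()
    return(out)
  }
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 3) {
      stop("units: line ", res$line[i], ": expected 3 fields", call. = FALSE)
    }
  }
  out <- data.frame(
    unit_id = vapply(res$fields, `[[`, "", 1),
    dimension = vapply(res$fields, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
  out$surfaces <- lapply(res$fields, function(f) normalize_term(split_multi(f[2])))
  all_surf <- unlist(out$surfaces)
  if (anyDuplicated(all_surf)) {
    stop("units: surface '", all_surf[duplicated(all_surf)][1],
         "' appears under more than one unit", call. = FALSE)
  }
  out
}

#' Load the qualitative-value lexicon
#'
#' Reads `qualitative.csv` with columns surface, grade_rank. Ranks impose a
#' total severity order (normal = 0 upward) so qualitative ranges such as
#' "low to moderate" always satisfy low <= high.
#'
#' @param path path to a qualitative CSV file.
#' @return data.frame with columns `surface`, `grade_rank`.
#' @export
load_qualitative <- function(path) {
  res <- read_resource_lines(path)
  n <- length(res$fields)
  if (n == 0) {
    return(empty_df(surface = "character", grade_rank = "integer"))
  }
  for (i in seq_len(n)) {
    if (length(res$fields[[i]]) != 2) {
      stop("qualitative: line ", res$line[i], ": expected 2 fields",
           call. = FALSE)
    }
  }
  out <- data.frame(
    surface = normalize_term(vapply(res$fields, `[[`, "", 1)),
    grade_rank = as.integer(vapply(res$fields, `[[`, "", 2)),
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$grade_rank))) {
    stop("qualitative: non-integer grade_rank", call. = FALSE)
  }
  if (anyDuplicated(out$surface)) {
    stop("qualitative: duplicate surface '",
         out$surface[duplicated(out$surface)][1], "'", call. = FALSE)
  }
  out
}

#' Load abbreviation patterns
#'
#' One regular expression per line (`#` comments allowed). Patterns are
#' applied case-insensitively with token-boundary guards added by the
#' recognizer.
#'
#' @param path path to an abbreviations text file.
#' @return character vector of regex patterns.
#' @export
load_abbreviations <- function(path) {
  if (!file.exists(path)) {
    stop("resource file not found: ", path, call. = FALSE)
  }
  raw <- readLines(path, encoding = "UTF-8", warn = FALSE)
  raw <- raw[!grepl("^\\s*(#|$)", raw)]
  trimws(raw)
}

#' Load all extraction resources from a directory
#'
#' Expects `concepts.csv`, `dictionary.csv`, `words.csv`, `constraints.csv`,
#' `units.csv`, `qualitative.csv`, `abbreviations.txt` and `patterns.cfg`
#' in `dir`. With no argument, loads the resources shipped with the package.
#'
#' @param dir resource directory.
#' @param unit_mismatch what to do with a pair whose unit is incompatible
#'   with the concept: `"warn"` keeps the pair with `unit_ok = FALSE`
#'   (default), `"drop"` discards it.
#' @return an object of class `echo_resources`.
#' @export
#' @examples
#' res <- load_resources()
#' nrow(res$concepts)
load_resources <- function(dir = system.file("extdata", "resources",
                                             package = "echopairs"),
                           unit_mismatch = c("warn", "drop")) {
  unit_mismatch <- match.arg(unit_mismatch)
  concepts <- load_concepts(file.path(dir, "concepts.csv"))
  out <- list(
    concepts = concepts,
    dictionary = load_dictionary(file.path(dir, "dictionary.csv"), concepts),
    words = load_word_lexicon(file.path(dir, "words.csv")),
    constraints = load_constraints(file.path(dir, "constraints.csv")),
    units = load_units(file.path(dir, "units.csv")),
    qualitative = load_qualitative(file.path(dir, "qualitative.csv")),
    abbreviations = load_abbreviations(file.path(dir, "abbreviations.txt")),
    patterns = load_patterns(file.path(dir, "patterns.cfg")),
    unit_mismatch = unit_mismatch,
    dir = dir
  )
  class(out) <- "echo_resources"
  out
}

#' @export
print.echo_resources <- function(x, ...) {
  cat("<echo_resources>\n")
  cat("  concepts:    ", nrow(x$concepts), "\n")
  cat("  dictionary:  ", nrow(x$dictionary), "terms\n")
  cat("  word lexicon:", nrow(x$words), "words\n")
  cat("  constraints: ", nrow(x$constraints), "exclusion pairs\n")
  cat("  units:       ", nrow(x$units), "\n")
  cat("  qualitative: ", nrow(x$qualitative), "grades\n")
  cat("  patterns:    ", nrow(x$patterns), "rules\n")
  invisible(x)
}

#' Validate loaded resources for internal consistency
#'
#' Checks cross-references between the loaded resources. Errors: constraint
#' pairs naming groups absent from the word lexicon or concept tags; unit
#' surface collisions; dictionary surfaces whose concept candidates are
#' discarded by the semantic constraints derived from their own words.
#' Warnings (informational): concepts with no dictionary term; dictionary
#' surfaces containing words absent from the word lexicon.
#'
#' @param resources an `echo_resources` object.
#' @return list with elements `ok` (TRUE iff zero errors), `errors`,
#'   `warnings` (character vectors of findings).
#' @export
validate_resources <- function(resources) {
  errors <- character(0)
  warnings <- character(0)

  known_groups <- unique(c(resources$words$group_id,
                           unlist(resources$concepts$anatomy_tags),
                           unlist(resources$concepts$measure_tags)))
  cg <- unique(c(resources$constraints$group_a, resources$constraints$group_b))
  bad_groups <- setdiff(cg, known_groups)
  if (length(bad_groups) > 0) {
    errors <- c(errors, paste0("constraint references unknown group: ",
                               bad_groups))
  }

  all_unit_surf <- unlist(resources$units$surfaces)
  if (anyDuplicated(all_unit_surf)) {
    errors <- c(errors, paste0("unit surface collision: ",
                               unique(all_unit_surf[duplicated(all_unit_surf)])))
  }

  no_terms <- setdiff(resources$concepts$concept_id,
                      resources$dictionary$concept_id)
  if (length(no_terms) > 0) {
    warnings <- c(warnings, paste0("concept has no dictionary term: ", no_terms))
  }

  lex_words <- resources$words$surface
  for (i in seq_len(nrow(resources$dictionary))) {
    toks <- setdiff(term_tokens(resources$dictionary$surface[i]), STOP_TOKENS)
    missing <- setdiff(toks[grepl("^[a-z]{3,}$", toks)], lex_words)
    if (length(missing) > 0) {
      warnings <- c(warnings,
                    paste0("dictionary surface '",
                           resources$dictionary$surface[i],
                           "' has words outside the word lexicon: ",
                           paste(missing, collapse = ", ")))
    }
    # A surface must survive its own semantic constraints, otherwise it can
    # never map to its declared concept.
    mres <- map_surface(resources$dictionary$surface[i], resources)
    if (!identical(mres$status, "MAPPED") ||
        !identical(mres$concept_id, resources$dictionary$concept_id[i])) {
      errors <- c(errors,
                  paste0("dictionary surface '",
                         resources$dictionary$surface[i],
                         "' does not map to its own concept (got ",
                         mres$status, ")"))
    }
  }

  list(ok = length(errors) == 0, errors = errors, warnings = warnings)
}

#' Write resources back to CSV files
#'
#' Serializes the dictionary, word lexicon, constraints and qualitative
#' lexicon in the same dialect read by the loaders, so that a load/write/load
#' round trip is the identity on content.
#'
#' @param resources an `echo_resources` object.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_resources <- function(resources, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  writeLines(paste(resources$dictionary$surface,
                   resources$dictionary$concept_id, sep = ","),
             file.path(dir, "dictionary.csv"))
  writeLines(paste(resources$words$surface, resources$words$category,
                   resources$words$group_id, sep = ","),
             file.path(dir, "words.csv"))
  writeLines(paste(resources$constraints$group_a,
                   resources$constraints$group_b, sep = ","),
             file.path(dir, "constraints.csv"))
  writeLines(paste(resources$qualitative$surface,
                   resources$qualitative$grade_rank, sep = ","),
             file.path(dir, "qualitative.csv"))
  invisible(dir)
}
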