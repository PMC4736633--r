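# SMARTS-dictionary fingerprints. A dictionary is an ordered list of bits,
# each defined either by a SMARTS pattern or by an element-count rule
# ("N>=2"). Two curated dictionaries ship with the package (see
# inst/extdata): a PubChem-style subset and a substructure-key subset that
# together cover all the published toxicity-alert bits plus generic
# functional-group chemistry. A full 881-bit PubChem dictionary can be
# loaded from a user-supplied file in the same format.

.element_numbers <- c(H = 1, B = 5, C = 6, N = 7, O = 8, F = 9, Si = 14,
                      P = 15, S = 16, Cl = 17, As = 33, Se = 34, Br = 35,
                      I = 53)

# Parse a count rule like "N>=2"; NULL when the pattern is plain SMARTS.
.parse_count_rule <- function(pattern) {
  m <- regmatches(pattern,
                  regexec("^([A-Z][a-z]?)>=([0-9]+)$", pattern))[[1L]]
  if (length(m) == 0L) return(NULL)
  el <- m[2L]
  .check(el %in% names(.element_numbers),
         sprintf("count rule with unknown element: %s", pattern))
  list(element = el, min_count = as.integer(m[3L]),
       smarts = sprintf("[#%d]", .element_numbers[[el]]))
}

#' Read a fingerprint dictionary file
#'
#' Plain-text, tab-separated: bit index, SMARTS-or-count-rule, description;
#' lines starting with '#' are comments. Count rules have the form
#' \code{"N>=2"} (element symbol, minimum count). Bit indices must be
#' contiguous from 0. Every SMARTS is compiled (matched against methane)
#' at load time so malformed patterns fail fast.
#'
#' @param path file path.
#' @param name dictionary name (defaults to the file base name).
#' @return An object of class \code{"fp_dictionary"}: data.frame with
#'   columns \code{bit}, \code{pattern}, \code{description}, \code{type}
#'   (\code{"smarts"}/\code{"count"}), \code{feature} (column name used in
#'   feature tables).
#' @export
read_fingerprint_dictionary <- function(path, name = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  .check(length(lines) > 0, "empty fingerprint dictionary")
  parts <- strsplit(lines, "\t", fixed = TRUE)
  .check(all(lengths(parts) >= 3),
         "dictionary lines must be: index<TAB>pattern<TAB>description")
  df <- data.frame(
    bit = as.integer(vapply(parts, `[[`, "", 1L)),
    pattern = vapply(parts, `[[`, "", 2L),
    description = vapply(parts, `[[`, "", 3L),
    stringsAsFactors = FALSE)
  .check(identical(df$bit, seq_len(nrow(df)) - 1L),
         "bit indices must be contiguous from 0")
  df$type <- ifelse(vapply(df$pattern,
                           function(p) is.null(.parse_count_rule(p)),
                           logical(1)), "smarts", "count")
  if (is.null(name)) name <- sub("\\.[^.]*$", "", basename(path))
  # feature name: leading token of the description when it looks like an
  # identifier ("SubFP294: ..."), else dictionary name + bit index
  lead <- sub(":.*$", "", df$description)
  df$feature <- ifelse(grepl("^[A-Za-z][A-Za-z0-9_]*$", lead) &
                         grepl(":", df$description),
                       lead, sprintf("%s%03d", name, df$bit))
  .check(!anyDuplicated(df$feature), "duplicate feature names in dictionary")
  attr(df, "name") <- name
  class(df) <- c("fp_dictionary", "data.frame")
  .compile_dictionary(df)
  df
}

# Fail fast on SMARTS OpenBabel cannot compile.
.compile_dictionary <- function(dict) {
  pats <- dict$pattern[dict$type == "smarts"]
  if (!length(pats)) return(invisible(TRUE))
  res <- ChemmineOB::forEachMol("SMILES", "C probe", function(m) {
    vapply(pats, function(p) {
      tryCatch(ChemmineOB::smartsSearch_OB(list(m), p)[[1L]],
               error = function(e) NA_integer_)
    }, integer(1))
  })[[1L]]
  bad <- pats[is.na(res)]
  .check(length(bad) == 0,
         sprintf("SMARTS failed to compile: %s",
                 paste(utils::head(bad, 5), collapse = " ; ")))
  invisible(TRUE)
}

#' Load a bundled fingerprint dictionary
#'
#' @param name \code{"substructure"} (substructure-key subset, includes the
#'   published SubFP alert bits) or \code{"pubchem"} (PubChem-style subset,
#'   includes the published PubchemFP alert bits and element-count bits),
#'   or a path to a dictionary file.
#' @return An \code{"fp_dictionary"}.
#' @export
load_fingerprint_dictionary <- function(name) {
  builtin <- c(substructure = "substructure_subset.tsv",
               pubchem = "pubchem_subset.tsv")
  if (name %in% names(builtin)) {
    path <- system.file("extdata", builtin[[name]], package = "rvmtox",
                        mustWork = TRUE)
    read_fingerprint_dictionary(path, name = name)
  } else {
    read_fingerprint_dictionary(name)
  }
}

#' Compute dictionary fingerprints
#'
#' Bit i is 1 iff SMARTS pattern i matches the molecule at least once, or
#' the count rule is satisfied. Bits are invariant to SMILES atom-order
#' permutations of the same molecule because matching operates on the
#' parsed structure.
#'
#' @param smiles character vector of parseable SMILES.
#' @param dict an \code{"fp_dictionary"}.
#' @return Integer 0/1 matrix, molecules x bits, columns named by
#'   \code{dict$feature}.
#' @export
compute_fingerprint <- function(smiles, dict) {
  .check(inherits(dict, "fp_dictionary"),
         "compute_fingerprint: need an fp_dictionary")
  rules <- lapply(dict$pattern, .parse_count_rule)
  match_smarts <- ifelse(dict$type == "count",
                         vapply(rules, function(r)
                           if (is.null(r)) "" else r$smarts, ""),
                         dict$pattern)
  min_count <- ifelse(dict$type == "count",
                      vapply(rules, function(r)
                        if (is.null(r)) 1L else r$min_count, 1L), 1L)
  counts <- .smarts_count_matrix(smiles, stats::setNames(match_smarts,
                                                         dict$feature))
  bits <- sweep(counts, 2L, min_count, ">=") + 0L
  rownames(bits) <- NULL
  bits
}
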