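#' Compile an Aho-Corasick keyword trie
#'
#' Builds the multi-keyword automaton used for exact tag matching. The
#' automaton reports every occurrence (including overlapping occurrences)
#' of every keyword in a target in a single left-to-right pass; search
#' time is linear in target length plus the number of matches.
#'
#' @param keywords Character vector of distinct ACGT keywords.
#' @return An object of class `ac_trie`.
#' @export
build_trie <- function(keywords) {
  keywords <- as.character(keywords)
  if (anyDuplicated(keywords))
    stop("duplicate keywords: ",
         paste(unique(keywords[duplicated(keywords)]), collapse = ", "))
  structure(list(ptr = .ac_build(keywords), keywords = keywords),
            class = "ac_trie")
}

# XPtr objects do not survive serialization; rebuild lazily if needed.
.trie_ptr <- function(trie) {
  if (is.null(trie$ptr) ||
      isTRUE(tryCatch({.ac_n_keywords(trie$ptr); FALSE},
                      error = function(e) TRUE)))
    trie$ptr <- .ac_build(trie$keywords)
  trie$ptr
}

#' Search targets for all keyword occurrences
#'
#' @param trie An `ac_trie` from [build_trie()].
#' @param targets Character vector of target sequences.
#' @return A data.frame with one row per hit: `target` (index into
#'   `targets`), `keyword` (index into the trie's keyword list), `start`
#'   (1-based start of the occurrence).
#' @export
trie_search <- function(trie, targets) {
  stopifnot(inherits(trie, "ac_trie"))
  .ac_search(.trie_ptr(trie), as.character(targets))
}

#' @export
print.ac_trie <- function(x, ...) {
  cat("<ac_trie> ", length(x$keywords), " keywords\n", sep = "")
  invisible(x)
}
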