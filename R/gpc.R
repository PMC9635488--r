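#' Grapheme-phoneme correspondence rule sets
#'
#' A rule maps a grapheme (one or more letters) to a phoneme, optionally
#' restricted to a position class (onset/vowel/coda/any). The serial route
#' scans a spelling left to right, at each position firing the rule with
#' the longest matching grapheme among those eligible for the current slot.
#'
#' @param rules data.frame with columns `rule_index` (stable 0-based or
#'   1-based integers, unique), `grapheme`, `phoneme`, `position_class`
#'   (onset/vowel/coda/any)
#' @return object of class `gpc_ruleset`
#' @export
gpc_ruleset <- function(rules) {
  need <- c("rule_index", "grapheme", "phoneme", "position_class")
  if (!all(need %in% names(rules)))
    stop("rules need columns: ", paste(need, collapse = ", "))
  rules$grapheme <- tolower(rules$grapheme)
  if (any(!nzchar(rules$grapheme))) stop("empty grapheme in rule set")
  if (anyDuplicated(rules$rule_index)) stop("duplicate rule_index")
  if (!all(rules$position_class %in% c("onset", "vowel", "coda", "any")))
    stop("position_class must be onset, vowel, coda or any")
  key <- paste(rules$grapheme, rules$position_class)
  if (anyDuplicated(key))
    stop("duplicate (grapheme, position_class): ",
         paste(unique(key[duplicated(key)]), collapse = "; "))
  rules <- rules[order(rules$rule_index), , drop = FALSE]
  rownames(rules) <- NULL
  structure(list(rules = rules), class = "gpc_ruleset")
}

#' @export
length.gpc_ruleset <- function(x) nrow(x$rules)

slot_order <- c(onset = 1L, vowel = 2L, coda = 3L)

#' Apply the GPC route to a spelling
#'
#' Serial left-to-right scan: at each position the rule with the longest
#' grapheme matching there is fired (largest-to-smallest search), its
#' phoneme emitted, and the scan advances past the grapheme. Eligibility by
#' slot: the scan starts in the onset slot; onset-class rules may fire only
#' before a vowel-class rule has fired; vowel-class rules before any
#' coda-class rule; coda-class rules only at or after the vowel; "any"
#' rules always. Among equal-length matches a slot-specific rule beats
#' "any", and a rule matching the current slot beats a later slot.
#'
#' @param spelling non-empty letter string
#' @param ruleset a [gpc_ruleset()]
#' @return object of class `gpc_trace`: data.frame(start, end, grapheme,
#'   rule_index, phoneme, class)
#' @export
apply_gpc <- function(spelling, ruleset) {
  spelling <- tolower(spelling)
  if (!nzchar(spelling)) stop("empty spelling")
  rl <- ruleset$rules
  pos <- 1L
  state <- 1L
  rows <- list()
  n <- nchar(spelling)
  while (pos <= n) {
    rest <- substring(spelling, pos)
    cand <- rl[startsWith(rest, rl$grapheme), , drop = FALSE]
    if (nrow(cand)) {
      cls_ord <- slot_order[cand$position_class]
      eligible <- cand$position_class == "any" |
        (cls_ord >= state & !(cand$position_class == "coda" & state == 1L))
      cand <- cand[eligible, , drop = FALSE]
    }
    if (!nrow(cand))
      stop("unpronounceable input '", spelling, "': no rule matches at position ", pos)
    len <- nchar(cand$grapheme)
    cand <- cand[len == max(len), , drop = FALSE]
    if (nrow(cand) > 1L) {
      # prefer slot-specific over "any", then the earliest eligible slot
      pr <- ifelse(cand$position_class == "any", 99L, slot_order[cand$position_class])
      pr <- ifelse(pr != 99L & pr == state, 0L, pr)
      cand <- cand[order(pr), , drop = FALSE][1L, , drop = FALSE]
    }
    g <- cand$grapheme[1L]
    cls <- cand$position_class[1L]
    rows[[length(rows) + 1L]] <- data.frame(
      start = pos, end = pos + nchar(g) - 1L, grapheme = g,
      rule_index = cand$rule_index[1L], phoneme = cand$phoneme[1L],
      class = cls, stringsAsFactors = FALSE)
    if (cls != "any") state <- max(state, slot_order[[cls]])
    pos <- pos + nchar(g)
  }
  tr <- do.call(rbind, rows)
  stopifnot(tr$start[1L] == 1L, tr$end[nrow(tr)] == n,
            all(tr$start[-1L] == tr$end[-nrow(tr)] + 1L))  # span cover
  structure(tr, class = c("gpc_trace", "data.frame"))
}

#' Pronunciation of a spelling under the rule route
#' @inheritParams apply_gpc
#' @return character vector of phonemes in output order
#' @export
gpc_pronounce <- function(spelling, ruleset) apply_gpc(spelling, ruleset)$phoneme

#' Rule-activation representation of a lexicon
#'
#' Row i has a 1 at the index of every rule fired for word i and 0
#' elsewhere (binary set semantics: a rule fired twice is still coded once;
#' graded activation magnitudes are out of scope, hook via `value`).
#'
#' @param lex a [lexicon()] (or character vector of spellings with names)
#' @param ruleset a [gpc_ruleset()]
#' @param value activation recorded for a fired rule (default 1)
#' @return matrix n_stimuli x n_rules, rownames = word ids
#' @export
gpc_representation <- function(lex, ruleset, value = 1) {
  spellings <- if (inherits(lex, "lexicon")) {
    setNames(vapply(lex$entries, `[[`, character(1), "spelling"), word_ids(lex))
  } else {
    if (is.null(names(lex))) names(lex) <- lex
    lex
  }
  nr <- length(ruleset)
  idx_of <- setNames(seq_len(nr), as.character(ruleset$rules$rule_index))
  m <- matrix(0, length(spellings), nr,
              dimnames = list(names(spellings),
                              as.character(ruleset$rules$rule_index)))
  for (i in seq_along(spellings)) {
    tr <- apply_gpc(spellings[[i]], ruleset)
    m[i, idx_of[as.character(unique(tr$rule_index))]] <- value
  }
  m
}

#' Localist lexical-route extension
#'
#' One-hot orthographic and phonological lexicon blocks: row i is the
#' concatenation of two length-n one-hot vectors with the 1 in position i.
#' Concatenated with the GPC representation this gives
#' n_rules + 2 * n_words columns (8,029 at the standard scale of 2,033
#' rules and 2,998 words).
#'
#' @param lex a [lexicon()], a character vector of word ids, or an integer
#'   word count
#' @return sparse matrix (dgCMatrix) n_words x 2*n_words
#' @export
lexical_extension <- function(lex) {
  ids <- if (inherits(lex, "lexicon")) word_ids(lex)
         else if (is.character(lex)) lex
         else paste0("w", seq_len(lex))
  n <- length(ids)
  Matrix::sparseMatrix(i = rep(seq_len(n), 2L),
                       j = c(seq_len(n), n + seq_len(n)), x = 1,
                       dims = c(n, 2L * n),
                       dimnames = list(ids, c(paste0("olex:", ids),
                                              paste0("plex:", ids))))
}

#' Rule-set TSV round trip
#'
#' Columns: rule_index, grapheme, phoneme, position_class.
#' @param ruleset a [gpc_ruleset()]
#' @param path file path
#' @export
write_rules_tsv <- function(ruleset, path) {
  write.table(ruleset$rules, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rules_tsv
#' @export
read_rules_tsv <- function(path) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = c(rule_index = "integer", grapheme = "character",
                                  phoneme = "character",
                                  position_class = "character"))
  gpc_ruleset(df)
}

#' Derive a rule set from a lexicon by majority vote
#'
#' For every (grapheme, slot) pair occurring in the lexicon with a 1:1
#' grapheme-phoneme alignment, the most frequent mapped phoneme (ties
#' broken alphabetically) becomes a rule with that slot as its position
#' class. On a fully regular lexicon the derived rules pronounce every word
#' correctly; planted exception words mismatch on their deviant mapping.
#'
#' @param lex a [lexicon()]
#' @return a [gpc_ruleset()]
#' @export
generate_rules <- function(lex) {
  votes <- list()
  for (e in lex$entries) {
    for (g in c("onset", "vowel", "coda")) {
      gs <- e[[g]]; ps <- e[[paste0("p_", g)]]
      if (length(gs) != length(ps)) next  # alignment unavailable
      for (k in seq_along(gs)) {
        key <- paste(g, gs[k], sep = "\r")
        votes[[key]] <- c(votes[[key]], ps[k])
      }
    }
  }
  if (!length(votes)) stop("no alignable grapheme-phoneme pairs in lexicon")
  keys <- sort(names(votes))
  rows <- do.call(rbind, lapply(seq_along(keys), function(i) {
    parts <- strsplit(keys[i], "\r", fixed = TRUE)[[1]]
    tab <- sort(table(votes[[keys[i]]]), decreasing = TRUE)
    best <- names(tab)[tab == max(tab)]
    data.frame(rule_index = i - 1L, grapheme = parts[2], phoneme = sort(best)[1],
               position_class = parts[1], stringsAsFactors = FALSE)
  }))
  gpc_ruleset(rows)
}
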