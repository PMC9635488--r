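#' Lexicon entries and lexicons
#'
#' A lexicon entry is a monosyllabic word with its spelling pre-segmented
#' into onset/vowel/coda grapheme sequences, its pronunciation segmented
#' into the matching phoneme sequences, and an occurrences-per-million
#' frequency. A lexicon bundles entries with the grapheme and phoneme
#' schemes under which they are encodable.
#'
#' @param word_id unique token
#' @param onset,vowel,coda character vectors of graphemes (may be empty)
#' @param p_onset,p_vowel,p_coda character vectors of phonemes
#' @param freq occurrences per million, positive
#' @return object of class `lexicon_entry`
#' @export
lexicon_entry <- function(word_id, onset = character(), vowel = character(),
                          coda = character(), p_onset = character(),
                          p_vowel = character(), p_coda = character(), freq) {
  if (!is.numeric(freq) || length(freq) != 1L || !is.finite(freq) || freq <= 0)
    stop("entry '", word_id, "': frequency must be a positive number")
  structure(list(word_id = as.character(word_id),
                 onset = tolower(onset), vowel = tolower(vowel),
                 coda = tolower(coda),
                 p_onset = p_onset, p_vowel = p_vowel, p_coda = p_coda,
                 spelling = paste0(c(tolower(onset), tolower(vowel),
                                     tolower(coda)), collapse = ""),
                 freq = freq),
            class = "lexicon_entry")
}

validate_entry <- function(entry, ortho_scheme, phon_scheme) {
  for (g in c("onset", "vowel", "coda")) {
    miss <- setdiff(entry[[g]], ortho_scheme[[g]])
    if (length(miss))
      stop("entry '", entry$word_id, "': grapheme(s) ",
           paste(miss, collapse = ", "), " not in ", g, " group")
    pm <- setdiff(entry[[paste0("p_", g)]], phon_scheme[[g]])
    if (length(pm))
      stop("entry '", entry$word_id, "': phoneme(s) ",
           paste(pm, collapse = ", "), " not in ", g, " group")
  }
  invisible(entry)
}

#' Construct a lexicon
#' @param entries list of [lexicon_entry()] objects
#' @param ortho_scheme a [grapheme_scheme()]
#' @param phon_scheme a [phoneme_scheme()]
#' @return object of class `lexicon`
#' @export
lexicon <- function(entries, ortho_scheme, phon_scheme) {
  ids <- vapply(entries, `[[`, character(1), "word_id")
  if (anyDuplicated(ids))
    stop("duplicate word_id: ", paste(unique(ids[duplicated(ids)]), collapse = ", "))
  for (e in entries) validate_entry(e, ortho_scheme, phon_scheme)
  structure(list(entries = entries, ortho_scheme = ortho_scheme,
                 phon_scheme = phon_scheme),
            class = "lexicon")
}

#' @export
length.lexicon <- function(x) length(x$entries)

#' @export
word_ids <- function(lex) vapply(lex$entries, `[[`, character(1), "word_id")

#' @export
frequencies <- function(lex) vapply(lex$entries, `[[`, numeric(1), "freq")

#' @export
print.lexicon <- function(x, ...) {
  cat("lexicon:", length(x), "words,",
      n_units(x$ortho_scheme), "orthographic units,",
      n_units(x$phon_scheme), "phonological units\n")
  invisible(x)
}

encode_slots <- function(used_by_group, scheme, constituents_of) {
  v <- setNames(integer(n_units(scheme)), unit_labels(scheme))
  for (g in c("onset", "vowel", "coda")) {
    for (sym in used_by_group[[g]]) {
      if (!sym %in% scheme[[g]])
        stop("symbol '", sym, "' not in ", g, " group of scheme")
      v[paste0(g, ":", sym)] <- 1L
      # multi-symbol rule: activate same-group constituents as well
      for (cst in constituents_of(sym)) {
        if (cst %in% scheme[[g]]) v[paste0(g, ":", cst)] <- 1L
      }
    }
  }
  v
}

#' Encode a word's spelling as a binary slot vector
#'
#' Each used grapheme sets its unit to 1; a multi-letter grapheme (e.g.
#' "ph") additionally sets the units of its constituent single letters that
#' belong to the same slot group. All other units are 0.
#'
#' @param entry a [lexicon_entry()]
#' @param scheme a [grapheme_scheme()]
#' @return named integer vector of 0/1, length `n_units(scheme)`
#' @export
encode_orthography <- function(entry, scheme) {
  encode_slots(list(onset = entry$onset, vowel = entry$vowel, coda = entry$coda),
               scheme,
               function(sym) if (nchar(sym) > 1L) strsplit(sym, "")[[1]] else character())
}

#' Encode a word's pronunciation as a binary slot vector
#'
#' Compound phonemes (e.g. /ps/) activate both the compound unit and its
#' constituent units in the same group.
#'
#' @param entry a [lexicon_entry()]
#' @param scheme a [phoneme_scheme()]
#' @return named integer vector of 0/1
#' @export
encode_phonology <- function(entry, scheme) {
  encode_slots(list(onset = entry$p_onset, vowel = entry$p_vowel,
                    coda = entry$p_coda),
               scheme,
               function(sym) scheme$compound_map[[sym]] %||% character())
}

#' Encode a whole lexicon as a binary feature matrix
#'
#' @param lex a [lexicon()]
#' @param channel "orthography" or "phonology"
#' @return integer matrix, stimuli (rows, named by word_id) by units
#' @export
encode_lexicon <- function(lex, channel = c("orthography", "phonology")) {
  channel <- match.arg(channel)
  rows <- lapply(lex$entries, function(e) {
    tryCatch(
      if (channel == "orthography") encode_orthography(e, lex$ortho_scheme)
      else encode_phonology(e, lex$phon_scheme),
      error = function(err) stop("word '", e$word_id, "': ", conditionMessage(err)))
  })
  m <- do.call(rbind, rows)
  rownames(m) <- word_ids(lex)
  m
}

#' Lexicon TSV round trip
#'
#' Columns: word_id, spelling, onset, vowel, coda, p_onset, p_vowel,
#' p_coda, freq_per_million; grapheme/phoneme sequences are `+`-delimited
#' (empty string for an empty slot). The spelling column must equal the
#' concatenated graphemes.
#'
#' @param lex a [lexicon()]
#' @param path file path
#' @export
write_lexicon_tsv <- function(lex, path) {
  j <- function(x) paste(x, collapse = "+")
  df <- do.call(rbind, lapply(lex$entries, function(e)
    data.frame(word_id = e$word_id, spelling = e$spelling,
               onset = j(e$onset), vowel = j(e$vowel), coda = j(e$coda),
               p_onset = j(e$p_onset), p_vowel = j(e$p_vowel),
               p_coda = j(e$p_coda), freq_per_million = e$freq,
               stringsAsFactors = FALSE)))
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

split_plus <- function(s) if (is.na(s) || !nzchar(s)) character() else strsplit(s, "+", fixed = TRUE)[[1]]

#' @rdname write_lexicon_tsv
#' @param ortho_scheme,phon_scheme schemes the entries must be encodable under
#' @export
read_lexicon_tsv <- function(path, ortho_scheme, phon_scheme) {
  df <- read.delim(path, stringsAsFactors = FALSE, na.strings = NULL,
                   colClasses = c(freq_per_million = "numeric"))
  need <- c("word_id", "spelling", "onset", "vowel", "coda",
            "p_onset", "p_vowel", "p_coda", "freq_per_million")
  if (!all(need %in% names(df)))
    stop("lexicon TSV missing column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  entries <- lapply(seq_len(nrow(df)), function(i) {
    r <- df[i, ]
    e <- tryCatch(
      lexicon_entry(r$word_id, split_plus(r$onset), split_plus(r$vowel),
                    split_plus(r$coda), split_plus(r$p_onset),
                    split_plus(r$p_vowel), split_plus(r$p_coda),
                    r$freq_per_million),
      error = function(err) stop("line ", i + 1L, ": ", conditionMessage(err)))
    if (e$spelling != tolower(r$spelling))
      stop("line ", i + 1L, ": concatenated graphemes '", e$spelling,
           "' do not spell '", r$spelling, "'")
    e
  })
  lexicon(entries, ortho_scheme, phon_scheme)
}

#' Greedy longest-match grapheme segmenter
#'
#' Splits a spelling into onset/vowel/coda grapheme sequences by scanning
#' left to right, preferring the longest grapheme that matches at the
#' current position in the current slot (onset until the first vowel
#' grapheme, then vowel, then coda). Intended for synthetic lexicon
#' construction; analysis-path lexicons arrive pre-segmented.
#'
#' @param spelling letter string
#' @param scheme a [grapheme_scheme()]
#' @return list(onset=, vowel=, coda=) or NULL if unsegmentable
#' @export
segment_graphemes <- function(spelling, scheme) {
  spelling <- tolower(spelling)
  pos <- 1L
  state <- 1L  # 1 onset, 2 vowel, 3 coda
  out <- list(onset = character(), vowel = character(), coda = character())
  slots <- c("onset", "vowel", "coda")
  while (pos <= nchar(spelling)) {
    best <- NULL; best_slot <- NA_integer_
    for (s in state:3L) {
      if (s == 3L && state == 1L) next  # no coda before the vowel
      cand <- scheme[[slots[s]]]
      for (g in cand[order(-nchar(cand))]) {
        if (startsWith(substring(spelling, pos), g)) {
          if (is.null(best) || nchar(g) > nchar(best)) { best <- g; best_slot <- s }
          break
        }
      }
    }
    if (is.null(best)) return(NULL)
    out[[slots[best_slot]]] <- c(out[[slots[best_slot]]], best)
    state <- max(state, best_slot)
    pos <- pos + nchar(best)
  }
  if (length(out$vowel) == 0L) return(NULL)
  out
}
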