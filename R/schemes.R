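#' Slot schemes for orthographic and phonological codes
#'
#' Monosyllables are segmented into onset, vowel and coda slots. A grapheme
#' scheme lists, per slot, the graphemes that may occupy it; each grapheme
#' owns one binary unit, and the units of a slot form a contiguous block in
#' group order (onset block first, then vowel, then coda). A phoneme scheme
#' is analogous, with an explicit map from compound phonemes (e.g. /ps/) to
#' their constituents.
#'
#' @param onset,vowel,coda character vectors of symbols, one per unit
#' @return an object of class `grapheme_scheme`
#' @export
grapheme_scheme <- function(onset, vowel, coda) {
  groups <- list(onset = tolower(onset), vowel = tolower(vowel), coda = tolower(coda))
  for (g in names(groups)) {
    if (anyDuplicated(groups[[g]]))
      stop("duplicate grapheme in ", g, " group: ",
           paste(groups[[g]][duplicated(groups[[g]])], collapse = ", "))
    if (any(!nzchar(groups[[g]]))) stop("empty grapheme in ", g, " group")
  }
  structure(list(onset = groups$onset, vowel = groups$vowel, coda = groups$coda),
            class = "grapheme_scheme")
}

#' @rdname grapheme_scheme
#' @param compound_map named list mapping a compound phoneme symbol to a
#'   character vector of constituent symbols (same slot group)
#' @export
phoneme_scheme <- function(onset, vowel, coda, compound_map = list()) {
  sch <- structure(list(onset = onset, vowel = vowel, coda = coda,
                        compound_map = compound_map),
                   class = "phoneme_scheme")
  for (g in c("onset", "vowel", "coda"))
    if (anyDuplicated(sch[[g]]))
      stop("duplicate phoneme in ", g, " group")
  for (cp in names(compound_map)) {
    grp <- scheme_group_of(sch, cp)
    if (is.na(grp)) stop("compound phoneme ", cp, " not in any group")
    miss <- setdiff(compound_map[[cp]], sch[[grp]])
    if (length(miss))
      stop("constituents of compound ", cp, " missing from ", grp,
           " group: ", paste(miss, collapse = ", "))
  }
  sch
}

scheme_group_of <- function(scheme, symbol) {
  for (g in c("onset", "vowel", "coda")) if (symbol %in% scheme[[g]]) return(g)
  NA_character_
}

#' @export
n_units <- function(scheme) UseMethod("n_units")
#' @export
n_units.grapheme_scheme <- function(scheme)
  length(scheme$onset) + length(scheme$vowel) + length(scheme$coda)
#' @export
n_units.phoneme_scheme <- n_units.grapheme_scheme

#' Unit labels of a scheme, block by block
#' @param scheme a grapheme or phoneme scheme
#' @return character vector, `<slot>:<symbol>`
#' @export
unit_labels <- function(scheme) {
  c(paste0("onset:", scheme$onset), paste0("vowel:", scheme$vowel),
    paste0("coda:", scheme$coda))
}

#' Small toy schemes for examples and tests
#' @return list with `ortho` and `phon` schemes
#' @export
toy_schemes <- function() {
  list(
    ortho = grapheme_scheme(
      onset = c("b", "c", "h", "p", "t", "ch", "ph"),
      vowel = c("a", "e", "i", "ea"),
      coda = c("n", "s", "t", "p", "ps", "st")),
    phon = phoneme_scheme(
      onset = c("b", "k", "h", "p", "t", "C", "f"),
      vowel = c("a", "e", "i", "E"),
      coda = c("n", "s", "t", "p", "ps"),
      compound_map = list(ps = c("p", "s")))
  )
}

#' Synthetic paper-scale schemes
#'
#' A stand-in inventory with the standard dimensionalities: 105 grapheme
#' units (30 onset, 27 vowel, 48 coda) and 61 phoneme units split into
#' onset/vowel/coda, with the compound coda phonemes /ps/, /ks/ and /ts/
#' activating their constituents. The actual symbol inventory of the
#' published slot coding is not redistributable, so this is a synthetic
#' English-like reconstruction with the same block structure.
#'
#' @return list with `ortho` (105 units) and `phon` (61 units) schemes
#' @export
paper_scale_schemes <- function() {
  onset_g <- c("b", "c", "d", "f", "g", "h", "j", "k", "l", "m", "n", "p",
               "q", "r", "s", "t", "v", "w", "x", "y", "z",
               "ch", "ph", "sh", "th", "wh", "qu", "kn", "wr", "gn")   # 30
  vowel_g <- c("a", "e", "i", "o", "u", "y",
               "ai", "ay", "au", "aw", "ea", "ee", "ei", "ew", "ey",
               "ie", "oa", "oe", "oi", "oo", "ou", "ow", "oy", "ue",
               "ui", "igh", "eigh")                                    # 27
  coda_g <- c("b", "c", "d", "f", "g", "h", "k", "l", "m", "n", "p", "r",
              "s", "t", "v", "w", "x", "y", "z",
              "ch", "ck", "ff", "gh", "ll", "ng", "nk", "ph", "sh", "ss",
              "th", "tch", "zz", "mb", "mn", "ps", "ts", "ks", "lk", "lm",
              "nd", "nt", "st", "sk", "sp", "ld", "rd", "rn", "rt")    # 48
  onset_p <- c("p", "b", "t", "d", "k", "g", "f", "v", "s", "z", "S", "Z",
               "tS", "dZ", "h", "m", "n", "l", "r", "w", "j", "T", "D") # 23
  vowel_p <- c("i", "I", "e", "E", "a", "A", "o", "O", "u", "U", "@",
               "aI", "aU", "oI")                                        # 14
  coda_p <- c("p", "b", "t", "d", "k", "g", "f", "v", "s", "z", "S", "Z",
              "m", "n", "N", "l", "r", "T", "D", "tS", "dZ",
              "ps", "ks", "ts")                                         # 24
  list(
    ortho = grapheme_scheme(onset_g, vowel_g, coda_g),
    phon = phoneme_scheme(onset_p, vowel_p, coda_p,
                          compound_map = list(ps = c("p", "s"),
                                              ks = c("k", "s"),
                                              ts = c("t", "s")))
  )
}

#' Read or write a scheme as TSV
#'
#' Columns: `group` (onset/vowel/coda), `symbol`, `constituents`
#' (`+`-delimited, empty for simple symbols). Grapheme schemes ignore the
#' constituents column on read (constituents of multi-letter graphemes are
#' their letters).
#'
#' @param scheme a scheme object
#' @param path file path
#' @param type "grapheme" or "phoneme"
#' @export
write_scheme_tsv <- function(scheme, path) {
  rows <- do.call(rbind, lapply(c("onset", "vowel", "coda"), function(g) {
    syms <- scheme[[g]]
    cons <- vapply(syms, function(s) {
      cm <- scheme$compound_map[[s]]
      if (is.null(cm)) "" else paste(cm, collapse = "+")
    }, character(1))
    data.frame(group = g, symbol = syms, constituents = cons,
               stringsAsFactors = FALSE)
  }))
  write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_scheme_tsv
#' @export
read_scheme_tsv <- function(path, type = c("grapheme", "phoneme")) {
  type <- match.arg(type)
  df <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c("character", "character", "character"))
  if (!all(c("group", "symbol", "constituents") %in% names(df)))
    stop("scheme TSV must have columns group, symbol, constituents")
  gs <- function(g) df$symbol[df$group == g]
  if (type == "grapheme") return(grapheme_scheme(gs("onset"), gs("vowel"), gs("coda")))
  comp <- df[nzchar(df$constituents), ]
  cm <- lapply(strsplit(comp$constituents, "+", fixed = TRUE), identity)
  names(cm) <- comp$symbol
  phoneme_scheme(gs("onset"), gs("vowel"), gs("coda"), compound_map = cm)
}
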