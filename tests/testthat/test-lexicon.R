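test_that("orthographic encoding activates graphemes and same-group constituents", {
  s <- grapheme_scheme(onset = c("p", "h", "ph", "b"), vowel = c("a", "e"),
                       coda = c("t", "s"))
  e <- lexicon_entry("phat", onset = "ph", vowel = "a", coda = "t", freq = 1)
  v <- encode_orthography(e, s)
  expect_equal(sum(v), 5)  # ph + constituents p, h + a + t
  expect_equal(unname(v[c("onset:p", "onset:h", "onset:ph", "vowel:a", "coda:t")]),
               c(1, 1, 1, 1, 1))

  # constituent not in the same group is not activated
  s2 <- grapheme_scheme(onset = c("b", "c", "ch"), vowel = c("a", "e"),
                        coda = c("t", "s"))
  e2 <- lexicon_entry("chat", onset = "ch", vowel = "a", coda = "t", freq = 1)
  v2 <- encode_orthography(e2, s2)
  expect_equal(sum(v2), 4)  # ch, c, a, t ("h" is not an onset grapheme)
  expect_setequal(names(v2)[v2 == 1],
                  c("onset:ch", "onset:c", "vowel:a", "coda:t"))

  # single-feature case
  e3 <- lexicon_entry("a", vowel = "a", p_vowel = "a", freq = 1)
  v3 <- encode_orthography(e3, s)
  expect_equal(sum(v3), 1)
  expect_equal(unname(v3["vowel:a"]), 1)

  expect_error(
    encode_orthography(lexicon_entry("x", onset = "z", vowel = "a", freq = 1), s),
    "'z'.*onset")
})

test_that("phonological encoding activates compounds plus constituents", {
  s <- toy_schemes()$phon
  e <- lexicon_entry("hips", onset = "h", vowel = "i", coda = "ps",
                     p_onset = "h", p_vowel = "i", p_coda = "ps", freq = 1)
  v <- encode_phonology(e, s)
  expect_equal(unname(v[c("coda:ps", "coda:p", "coda:s")]), c(1, 1, 1))
  expect_equal(sum(v), 5)  # h, i + ps/p/s

  # simple phonemes only: active count = number of phonemes
  e2 <- lexicon_entry("pat", onset = "p", vowel = "a", coda = "t",
                      p_onset = "p", p_vowel = "a", p_coda = "t", freq = 1)
  expect_equal(sum(encode_phonology(e2, s)), 3)
})

test_that("encoding matches a brute-force set-union oracle on random toy schemes", {
  for (seed in 1:10) {
    sch <- withr::with_seed(seed, {
      letters10 <- letters[1:10]
      onset <- c(sample(letters10, 4),
                 paste0(sample(letters10, 1), sample(letters10, 1)))
      grapheme_scheme(onset = unique(onset),
                      vowel = unique(c("a", "e", sample(c("ai", "ea"), 1))),
                      coda = unique(sample(letters10, 5)))
    })
    gs <- withr::with_seed(seed + 100, list(
      onset = sample(sch$onset, 1), vowel = sample(sch$vowel, 1),
      coda = sample(sch$coda, 1)))
    e <- lexicon_entry("w", gs$onset, gs$vowel, gs$coda, freq = 1)
    v <- encode_orthography(e, sch)
    # oracle: union of used graphemes and their same-group letters
    expected <- character()
    for (g in c("onset", "vowel", "coda")) {
      for (sym in gs[[g]]) {
        expected <- c(expected, paste0(g, ":", sym))
        for (l in strsplit(sym, "")[[1]])
          if (l %in% sch[[g]]) expected <- c(expected, paste0(g, ":", l))
      }
    }
    expect_setequal(names(v)[v == 1], unique(expected))
  }
})

test_that("lexicon encoding composes rows and validates ids", {
  lex <- toy_lex()
  M <- encode_lexicon(lex, "orthography")
  expect_equal(dim(M), c(3L, n_units(lex$ortho_scheme)))
  expect_equal(M["chat", ], encode_orthography(lex$entries[[1]], lex$ortho_scheme))
  expect_equal(M["pea", ], encode_orthography(lex$entries[[2]], lex$ortho_scheme))

  s <- paper_scale_schemes()
  expect_equal(n_units(s$ortho), 105L)
  expect_equal(n_units(s$phon), 61L)
  e <- lexicon_entry("phat", onset = "ph", vowel = "a", coda = "t",
                     p_onset = "f", p_vowel = "a", p_coda = "t", freq = 1)
  expect_length(encode_orthography(e, s$ortho), 105L)

  expect_error(lexicon(list(lex$entries[[1]], lex$entries[[1]]),
                       lex$ortho_scheme, lex$phon_scheme), "duplicate word_id")
})

test_that("permuting a lexicon permutes encoding rows identically", {
  lex <- learnable_lex(12)
  perm <- withr::with_seed(9, sample(length(lex)))
  lex2 <- lexicon(lex$entries[perm], lex$ortho_scheme, lex$phon_scheme)
  for (ch in c("orthography", "phonology"))
    expect_identical(encode_lexicon(lex, ch)[perm, ], encode_lexicon(lex2, ch))
})

test_that("lexicon TSV round trip is lossless and validates rows", {
  lex <- toy_lex()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_lexicon_tsv(lex, f)
  lex2 <- read_lexicon_tsv(f, lex$ortho_scheme, lex$phon_scheme)
  expect_equal(length(lex2), length(lex))
  for (i in seq_along(lex$entries))
    expect_equal(lex2$entries[[i]], lex$entries[[i]])

  # zero frequency rejected, with line number
  tx <- readLines(f)
  tx[2] <- sub("120", "0", tx[2])
  writeLines(tx, f)
  expect_error(read_lexicon_tsv(f, lex$ortho_scheme, lex$phon_scheme),
               "line 2.*positive")

  # graphemes must spell the spelling column
  write_lexicon_tsv(lex, f)
  tx <- readLines(f)
  tx[3] <- sub("\tpea\t", "\tpeat\t", tx[3])
  writeLines(tx, f)
  expect_error(read_lexicon_tsv(f, lex$ortho_scheme, lex$phon_scheme),
               "do not spell")
})

test_that("scheme TSV round trip preserves groups and compound maps", {
  s <- toy_schemes()
  f <- withr::local_tempfile(fileext = ".tsv")
  write_scheme_tsv(s$phon, f)
  p2 <- read_scheme_tsv(f, "phoneme")
  expect_equal(p2$onset, s$phon$onset)
  expect_equal(p2$compound_map, s$phon$compound_map)
  write_scheme_tsv(s$ortho, f)
  o2 <- read_scheme_tsv(f, "grapheme")
  expect_equal(o2$coda, s$ortho$coda)
})

test_that("scheme invariants are enforced", {
  expect_error(grapheme_scheme(c("b", "b"), "a", "t"), "duplicate")
  expect_error(phoneme_scheme("p", "a", c("s", "ps"),
                              compound_map = list(ps = c("p", "s"))),
               "missing from")
})
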