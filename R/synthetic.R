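#' Specification of a synthetic artificial lexicon
#'
#' The generator emulates a monosyllabic training corpus: words are
#' onset+vowel+coda grapheme draws from a slot scheme, pronounced by a
#' canonical grapheme-to-phoneme map except for a planted fraction of
#' exception words whose vowel receives a deviant mapping; frequencies are
#' Zipf-distributed occurrences per million, assigned so that word length
#' and log frequency stay decorrelated.
#'
#' @param n_words number of words (default 200; 2998 is the paper-scale
#'   option)
#' @param p_exception proportion of exception words (exact count by
#'   construction)
#' @param zipf_exponent exponent of the rank-frequency law (default 1)
#' @param p_empty_onset,p_empty_coda probability of an empty slot
#' @param schemes list(ortho=, phon=) as from [paper_scale_schemes()]
#' @param seed integer seed
#' @return object of class `synth_lexicon_spec`
#' @export
synth_lexicon_spec <- function(n_words = 200L, p_exception = 0.1,
                               zipf_exponent = 1, p_empty_onset = 0.15,
                               p_empty_coda = 0.15,
                               schemes = paper_scale_schemes(), seed = 1L) {
  stopifnot(n_words >= 2L, p_exception >= 0, p_exception <= 1,
            zipf_exponent > 0)
  structure(list(n_words = as.integer(n_words), p_exception = p_exception,
                 zipf_exponent = zipf_exponent,
                 p_empty_onset = p_empty_onset, p_empty_coda = p_empty_coda,
                 schemes = schemes, seed = as.integer(seed)),
            class = "synth_lexicon_spec")
}

#' Canonical grapheme-to-phoneme map of a scheme pair
#'
#' Letter-faithful deterministic assignment, emulating the broad
#' consistency of natural orthographies: a grapheme maps to the same-named
#' phoneme of its slot when one exists (b -> /b/), otherwise to the
#' same-named phoneme of its first such constituent letter (ck -> /k/,
#' ai -> /a/), otherwise to a slot phoneme picked by deterministic cycling.
#' Distinct graphemes may share a phoneme (homophony), as in real spelling
#' systems; what matters for the reading models is that each grapheme's
#' mapping is consistent. The deviant (exception) mapping of a vowel
#' grapheme is the next vowel phoneme after its canonical one.
#' @keywords internal
canonical_gp_map <- function(schemes) {
  out <- list()
  for (g in c("onset", "vowel", "coda")) {
    gs <- schemes$ortho[[g]]
    ps <- schemes$phon[[g]]
    fallback <- 0L
    out[[g]] <- setNames(vapply(gs, function(gr) {
      if (gr %in% ps) return(gr)
      for (letter in strsplit(gr, "")[[1]]) {
        if (letter %in% ps) return(letter)
      }
      fallback <<- fallback + 1L
      ps[(fallback - 1L) %% length(ps) + 1L]
    }, character(1)), gs)
  }
  out
}

deviant_vowel <- function(grapheme, gp, schemes) {
  ps <- schemes$phon$vowel
  i <- match(gp$vowel[[grapheme]], ps)
  ps[i %% length(ps) + 1L]
}

#' Generate a synthetic lexicon
#'
#' See [synth_lexicon_spec()] for the generative model. The exception words
#' are flagged in the returned lexicon's `exception` attribute; the
#' length-frequency decorrelation target (|r| < 0.15 between letter length
#' and log frequency) is enforced by re-permuting the frequency assignment
#' up to 20 times.
#'
#' @param spec a [synth_lexicon_spec()]
#' @return a [lexicon()] with attributes `exception` (logical vector) and
#'   `gp_map`
#' @export
generate_lexicon <- function(spec) {
  schemes <- spec$schemes
  gp <- canonical_gp_map(schemes)
  with_seed(substream_seed(spec$seed, "lexicon"), {
    seen <- character()
    words <- vector("list", spec$n_words)
    i <- 1L
    guard <- 0L
    while (i <= spec$n_words) {
      guard <- guard + 1L
      if (guard > 200L * spec$n_words) stop("cannot draw enough unique spellings")
      on <- if (runif(1) < spec$p_empty_onset) character() else
        sample(schemes$ortho$onset, 1L)
      vo <- sample(schemes$ortho$vowel, 1L)
      co <- if (length(on) && runif(1) < spec$p_empty_coda) character() else
        sample(schemes$ortho$coda, 1L)
      sp <- paste0(c(on, vo, co), collapse = "")
      if (sp %in% seen) next
      # keep only words whose greedy slot parse recovers the intended
      # segmentation, so the serial rule route never misparses a regular
      # word (the study's stimuli were likewise selection-controlled)
      seg <- segment_graphemes(sp, schemes$ortho)
      if (is.null(seg) ||
          !identical(seg, list(onset = on, vowel = vo, coda = co))) next
      seen <- c(seen, sp)
      words[[i]] <- list(onset = on, vowel = vo, coda = co)
      i <- i + 1L
    }
    n_exc <- round(spec$p_exception * spec$n_words)
    exc <- rep(FALSE, spec$n_words)
    if (n_exc > 0L) {
      # exceptions stay a strict minority within every vowel grapheme so
      # that majority-vote rule derivation always recovers the canonical
      # mapping
      vowels <- vapply(words, `[[`, character(1), "vowel")
      counts <- table(vowels)
      cap <- setNames(pmax(0L, ceiling(as.integer(counts) / 2L) - 1L),
                      names(counts))
      taken <- setNames(integer(length(counts)), names(counts))
      for (k in sample.int(spec$n_words)) {
        if (sum(exc) >= n_exc) break
        v <- vowels[k]
        if (taken[[v]] < cap[[v]]) {
          exc[k] <- TRUE
          taken[[v]] <- taken[[v]] + 1L
        }
      }
      if (sum(exc) < n_exc)
        warning("placed only ", sum(exc), " of ", n_exc,
                " exception words under the per-vowel minority cap")
    }
    # Zipf frequencies over a random rank permutation; the corpus is
    # treated as the top slice of a nominal 30,000-word vocabulary so
    # per-million values are realistic (top word ~ 10^5 per million)
    H <- sum(seq_len(30000L)^(-spec$zipf_exponent))
    ranks <- sample.int(spec$n_words)
    freqs <- 1e6 * ranks^(-spec$zipf_exponent) / H
    lens <- vapply(words, function(w)
      nchar(paste0(c(w$onset, w$vowel, w$coda), collapse = "")), numeric(1))
    tries <- 0L
    while (abs(cor(lens, log(freqs))) >= 0.15 && tries < 20L) {
      ranks <- sample.int(spec$n_words)
      freqs <- 1e6 * ranks^(-spec$zipf_exponent) / H
      tries <- tries + 1L
    }
    if (tries == 20L)
      warning("length-frequency decorrelation target not met after 20 permutations")
    entries <- lapply(seq_len(spec$n_words), function(k) {
      w <- words[[k]]
      pv <- if (exc[k]) deviant_vowel(w$vowel, gp, schemes) else gp$vowel[[w$vowel]]
      lexicon_entry(
        word_id = sprintf("w%03d", k),
        onset = w$onset, vowel = w$vowel, coda = w$coda,
        p_onset = unname(gp$onset[w$onset]), p_vowel = pv,
        p_coda = unname(gp$coda[w$coda]),
        freq = freqs[k])
    })
    lex <- lexicon(entries, schemes$ortho, schemes$phon)
    attr(lex, "exception") <- exc
    attr(lex, "gp_map") <- gp
    lex
  })
}

#' Generate a nonword test set
#'
#' Nonwords are onset+vowel+coda combinations over the lexicon's grapheme
#' inventory whose spelling does not occur in the lexicon. Each nonword's
#' acceptable pronunciations are the canonical (regular) mapping plus, when
#' its vowel grapheme has an attested exception mapping somewhere in the
#' lexicon, each such deviant-vowel alternative.
#'
#' @param lex a lexicon from [generate_lexicon()]
#' @param n number of nonwords (default 50)
#' @param seed integer seed
#' @return object of class `nonword_set`: list of items with `spelling`,
#'   slot segments, and `acceptable` (list of p_onset/p_vowel/p_coda
#'   triples)
#' @export
generate_nonwords <- function(lex, n = 50L, seed = 1L) {
  stopifnot(n >= 1L)
  gp <- attr(lex, "gp_map")
  if (is.null(gp)) stop("lexicon lacks a gp_map attribute (not synthetic?)")
  schemes <- list(ortho = lex$ortho_scheme, phon = lex$phon_scheme)
  known <- vapply(lex$entries, `[[`, character(1), "spelling")
  # vowel grapheme -> attested deviant vowel phonemes in the lexicon
  attested <- list()
  for (e in lex$entries) {
    canon <- unname(gp$vowel[e$vowel])
    if (!identical(e$p_vowel, canon))
      attested[[e$vowel]] <- union(attested[[e$vowel]], e$p_vowel)
  }
  # nonwords recombine graphemes attested in the lexicon, so every
  # correspondence they require has been trainable
  inv <- list(
    onset = unique(unlist(lapply(lex$entries, `[[`, "onset"))),
    vowel = unique(unlist(lapply(lex$entries, `[[`, "vowel"))),
    coda = unique(unlist(lapply(lex$entries, `[[`, "coda"))))
  with_seed(substream_seed(seed, "nonwords"), {
    items <- list()
    seen <- character()
    guard <- 0L
    while (length(items) < n) {
      guard <- guard + 1L
      if (guard > 2000L * n) stop("cannot draw enough nonwords")
      on <- if (runif(1) < 0.1) character() else sample(inv$onset, 1L)
      vo <- sample(inv$vowel, 1L)
      co <- sample(inv$coda, 1L)
      sp <- paste0(c(on, vo, co), collapse = "")
      if (sp %in% known || sp %in% seen) next
      seen <- c(seen, sp)
      acc <- list(list(p_onset = unname(gp$onset[on]),
                       p_vowel = unname(gp$vowel[[vo]]),
                       p_coda = unname(gp$coda[co])))
      for (alt in attested[[vo]] %||% character())
        acc[[length(acc) + 1L]] <- list(p_onset = unname(gp$onset[on]),
                                        p_vowel = alt,
                                        p_coda = unname(gp$coda[co]))
      items[[length(items) + 1L]] <- list(spelling = sp, onset = on,
                                          vowel = vo, coda = co,
                                          acceptable = acc)
    }
    structure(list(items = items, phon_scheme = lex$phon_scheme,
                   ortho_scheme = lex$ortho_scheme), class = "nonword_set")
  })
}

#' @export
length.nonword_set <- function(x) length(x$items)

#' Encode a nonword set for network testing
#'
#' @param nw a [generate_nonwords()] set
#' @return list: `X` (orthographic matrix), `pool` (matrix of all distinct
#'   acceptable pronunciation vectors across the set), `acceptable_idx`
#'   (per item, rows of `pool` acceptable for it), `target_idx` (per item,
#'   the row of its canonical pronunciation), `freq` (nominal test
#'   frequency, 1 per million)
#' @export
encode_nonwords <- function(nw) {
  ents <- lapply(seq_along(nw$items), function(i) {
    it <- nw$items[[i]]
    lexicon_entry(sprintf("nw%03d", i), it$onset, it$vowel, it$coda,
                  it$acceptable[[1]]$p_onset, it$acceptable[[1]]$p_vowel,
                  it$acceptable[[1]]$p_coda, freq = 1)
  })
  X <- do.call(rbind, lapply(ents, encode_orthography, scheme = nw$ortho_scheme))
  rownames(X) <- vapply(ents, `[[`, character(1), "word_id")
  pool <- NULL
  pool_keys <- character()
  acceptable_idx <- vector("list", length(nw$items))
  target_idx <- integer(length(nw$items))
  for (i in seq_along(nw$items)) {
    it <- nw$items[[i]]
    idxs <- integer()
    for (a in it$acceptable) {
      e <- lexicon_entry("tmp", it$onset, it$vowel, it$coda,
                         a$p_onset, a$p_vowel, a$p_coda, freq = 1)
      v <- encode_phonology(e, nw$phon_scheme)
      key <- paste(v, collapse = "")
      j <- match(key, pool_keys)
      if (is.na(j)) {
        pool <- rbind(pool, v)
        pool_keys <- c(pool_keys, key)
        j <- length(pool_keys)
      }
      idxs <- c(idxs, j)
    }
    acceptable_idx[[i]] <- unique(idxs)
    target_idx[i] <- idxs[1L]
  }
  rownames(pool) <- NULL
  list(X = X, pool = pool, acceptable_idx = acceptable_idx,
       target_idx = target_idx, freq = rep(1, length(nw$items)))
}

#' Default ellipsoidal gray-matter stand-in mask
#'
#' An ellipsoid with semi-axes (9, 8, 7) voxels centred in the grid:
#' large enough to exercise sphere truncation at mask edges, small enough
#' for minutes-scale tests (~2,100 voxels on the default 24^3 grid).
#'
#' @param grid a [volume_grid()]
#' @param semi_axes ellipsoid semi-axes in voxels
#' @return logical 3-D array
#' @export
ellipsoid_mask <- function(grid, semi_axes = c(9, 8, 7)) {
  d <- grid$dim
  ctr <- (d + 1) / 2
  x <- (seq_len(d[1]) - ctr[1]) / semi_axes[1]
  y <- (seq_len(d[2]) - ctr[2]) / semi_axes[2]
  z <- (seq_len(d[3]) - ctr[3]) / semi_axes[3]
  outer(outer(x^2, y^2, `+`), z^2, `+`) <= 1
}

#' Planted-region specification for synthetic beta series
#'
#' @param center voxel coordinate (1-based) of the region center
#' @param radius region radius in voxels (default 3, the 123-voxel sphere)
#' @param source name of the feature matrix embedded there (e.g.
#'   "ann_hidden", "gpc", "orthography", "phonology")
#' @param gain signal gain multiplying the embedded patterns (default 2)
#' @return object of class `planted_roi_spec`
#' @export
planted_roi_spec <- function(center, radius = 3, source, gain = 2) {
  stopifnot(gain >= 0, radius >= 0)
  structure(list(center = as.integer(center), radius = radius,
                 source = source, gain = gain), class = "planted_roi_spec")
}

#' Generate multi-subject beta series with planted geometry
#'
#' Inside each planted region, beta(stimulus, voxel) = gain * (random
#' linear projection of the z-scored source features onto the region's
#' voxels, drawn fresh per subject) + Gaussian noise; outside the regions
#' the betas are pure Gaussian noise. RSA is invariant to the voxel basis,
#' so a linear embedding is exactly the structure the method assumes;
#' hemodynamics and noise autocorrelation are deliberately not simulated.
#'
#' @param features named list of stimuli x feature matrices (rownames =
#'   stimulus labels, shared across sources)
#' @param grid a [volume_grid()]
#' @param mask logical 3-D array
#' @param rois list of [planted_roi_spec()]
#' @param n_subjects number of subjects (default 18)
#' @param noise_sd Gaussian noise sd (default 1)
#' @param seed integer seed
#' @return list: `subjects` (list of [beta_series()]), `roi_masks` (named
#'   list of logical arrays), `labels`
#' @export
generate_beta_series <- function(features, grid, mask, rois,
                                 n_subjects = 18L, noise_sd = 1, seed = 1L) {
  stopifnot(noise_sd > 0, n_subjects >= 1L)
  labels <- rownames(features[[1L]])
  for (f in features) stopifnot(identical(rownames(f), labels))
  n_stim <- length(labels)
  nvox <- sum(mask)
  lin_mask <- which(mask)
  roi_masks <- list()
  roi_cols <- list()
  for (i in seq_along(rois)) {
    r <- rois[[i]]
    off <- sphere_offsets(r$radius)
    pts <- sweep(off, 2L, r$center, `+`)
    ok <- pts[, 1] >= 1 & pts[, 2] >= 1 & pts[, 3] >= 1 &
      pts[, 1] <= grid$dim[1] & pts[, 2] <= grid$dim[2] & pts[, 3] <= grid$dim[3]
    pts <- pts[ok, , drop = FALSE]
    lin <- pts[, 1] + grid$dim[1] * (pts[, 2] - 1L) +
      grid$dim[1] * grid$dim[2] * (pts[, 3] - 1L)
    lin <- lin[mask[lin]]
    if (length(lin) == 0L) stop("planted region ", i, " lies outside the mask")
    rm_ <- array(FALSE, grid$dim)
    rm_[lin] <- TRUE
    nm <- names(rois)[i] %||% paste0("roi", i)
    if (is.null(names(rois)) || !nzchar(nm)) nm <- paste0("roi", i)
    roi_masks[[nm]] <- rm_
    roi_cols[[nm]] <- match(lin, lin_mask)
  }
  Z <- lapply(features, zscore_features)
  subjects <- vector("list", n_subjects)
  for (s in seq_len(n_subjects)) {
    noise <- with_seed(substream_seed(seed, paste0("noise_s", s)),
                       matrix(rnorm(n_stim * nvox, sd = noise_sd), n_stim, nvox))
    dat <- noise
    for (i in seq_along(rois)) {
      r <- rois[[i]]
      if (r$gain == 0) next
      nm <- names(roi_masks)[i]
      cols <- roi_cols[[nm]]
      Zi <- Z[[r$source]]
      W <- with_seed(substream_seed(seed, paste0("proj_s", s, "_", nm)),
                     matrix(rnorm(ncol(Zi) * length(cols)), ncol(Zi), length(cols)))
      dat[, cols] <- dat[, cols] + r$gain * (Zi %*% W) / sqrt(ncol(Zi))
    }
    subjects[[s]] <- beta_series(sprintf("sub-%02d", s), grid, labels, dat, mask)
  }
  list(subjects = subjects, roi_masks = roi_masks, labels = labels)
}

#' Build and write a complete synthetic dataset
#'
#' Orchestrates lexicon, nonwords, rule derivation, model representations
#' and beta-series generation, writing every artifact in the pipeline's
#' input formats (TSV, NIfTI, JSON) under `dir`.
#'
#' @param dir output directory (created if missing)
#' @param lexicon_spec a [synth_lexicon_spec()]
#' @param n_nonwords nonword count
#' @param grid a [volume_grid()] (default 24^3 at 3 mm)
#' @param rois list of [planted_roi_spec()]; sources must name entries of
#'   `features` (or the built-ins "orthography"/"phonology")
#' @param features optional named list of extra source feature matrices
#'   (e.g. ann_hidden, gpc)
#' @param n_subjects,noise_sd,seed see [generate_beta_series()]
#' @return (invisibly) list with all in-memory components
#' @export
make_dataset <- function(dir, lexicon_spec = synth_lexicon_spec(),
                         n_nonwords = 50L,
                         grid = volume_grid(c(24L, 24L, 24L)),
                         rois = list(), features = list(),
                         n_subjects = 18L, noise_sd = 1, seed = 1L) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  lex <- generate_lexicon(lexicon_spec)
  nw <- generate_nonwords(lex, n_nonwords, seed = seed)
  rules <- generate_rules(lex)
  write_lexicon_tsv(lex, file.path(dir, "lexicon.tsv"))
  write_rules_tsv(rules, file.path(dir, "rules.tsv"))
  write_nonwords_tsv(nw, file.path(dir, "nonwords.tsv"))
  feats <- c(list(orthography = encode_lexicon(lex, "orthography"),
                  phonology = encode_lexicon(lex, "phonology")), features)
  mask <- ellipsoid_mask(grid)
  write_nifti(array(as.numeric(mask), grid$dim), file.path(dir, "mask.nii"),
              voxdim_mm = grid$voxdim_mm, origin_mm = grid$origin_mm)
  betas <- NULL
  if (length(rois)) {
    betas <- generate_beta_series(feats, grid, mask, rois, n_subjects,
                                  noise_sd, seed)
    for (s in seq_along(betas$subjects))
      write_beta_series(betas$subjects[[s]],
                        file.path(dir, sprintf("sub-%02d_beta", s)))
    for (nm in names(betas$roi_masks))
      write_nifti(array(as.numeric(betas$roi_masks[[nm]]), grid$dim),
                  file.path(dir, paste0("roi_", nm, ".nii")),
                  voxdim_mm = grid$voxdim_mm, origin_mm = grid$origin_mm)
    gt <- lapply(seq_along(rois), function(i)
      list(name = names(betas$roi_masks)[i], source = rois[[i]]$source,
           center = rois[[i]]$center, radius = rois[[i]]$radius,
           gain = rois[[i]]$gain))
    jsonlite::write_json(gt, file.path(dir, "ground_truth.json"),
                         auto_unbox = TRUE)
  }
  invisible(list(lexicon = lex, nonwords = nw, rules = rules, grid = grid,
                 mask = mask, betas = betas, features = feats))
}

#' Nonword TSV round trip
#'
#' Columns: nonword_id, spelling, onset, vowel, coda, then one row per
#' acceptable pronunciation (alt index, p_onset, p_vowel, p_coda).
#' @param nw a [generate_nonwords()] set
#' @param path file path
#' @export
write_nonwords_tsv <- function(nw, path) {
  rows <- list()
  for (i in seq_along(nw$items)) {
    it <- nw$items[[i]]
    for (a in seq_along(it$acceptable)) {
      p <- it$acceptable[[a]]
      rows[[length(rows) + 1L]] <- data.frame(
        nonword_id = sprintf("nw%03d", i), spelling = it$spelling,
        onset = paste(it$onset, collapse = "+"),
        vowel = paste(it$vowel, collapse = "+"),
        coda = paste(it$coda, collapse = "+"), alt = a,
        p_onset = paste(p$p_onset, collapse = "+"),
        p_vowel = paste(p$p_vowel, collapse = "+"),
        p_coda = paste(p$p_coda, collapse = "+"), stringsAsFactors = FALSE)
    }
  }
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}
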