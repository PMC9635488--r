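# Shared fixtures: all built in code, no files.

toy_lex <- function() {
  s <- toy_schemes()
  lexicon(list(
    lexicon_entry("chat", onset = "ch", vowel = "a", coda = "t",
                  p_onset = "C", p_vowel = "a", p_coda = "t", freq = 120),
    lexicon_entry("pea", onset = "p", vowel = "ea",
                  p_onset = "p", p_vowel = "E", freq = 40),
    lexicon_entry("hips", onset = "h", vowel = "i", coda = "ps",
                  p_onset = "h", p_vowel = "i", p_coda = "ps", freq = 7)
  ), s$ortho, s$phon)
}

# small learnable lexicon: one grapheme per slot, fully regular
learnable_lex <- function(n = 20L, seed = 42L) {
  spec <- synth_lexicon_spec(n_words = n, p_exception = 0,
                             schemes = paper_scale_schemes(), seed = seed)
  generate_lexicon(spec)
}

rand_features <- function(n_stim, n_feat, seed) {
  withr::with_seed(seed,
    matrix(rnorm(n_stim * n_feat), n_stim, n_feat,
           dimnames = list(paste0("s", seq_len(n_stim)), NULL)))
}

rand_rdm <- function(n_stim, seed, n_feat = 8L)
  compute_rdm(rand_features(n_stim, n_feat, seed))

# independent manual Pearson (no stats::cor)
pearson_manual <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

# reference connected components by breadth-first flood fill
flood_fill_oracle <- function(bin, conn) {
  d <- dim(bin)
  lab <- array(0L, d)
  nb <- expand.grid(dx = -1:1, dy = -1:1, dz = -1:1)
  nb <- nb[rowSums(abs(nb)) > 0, ]
  nb <- switch(as.character(conn),
               "6" = nb[rowSums(abs(nb)) == 1, ],
               "18" = nb[rowSums(abs(nb)) <= 2, ],
               "26" = nb)
  nxt <- 0L
  for (start in which(bin)) {
    if (lab[start] != 0L) next
    nxt <- nxt + 1L
    queue <- start
    lab[start] <- nxt
    while (length(queue)) {
      cur <- queue[1]; queue <- queue[-1]
      co <- arrayInd(cur, d)
      for (r in seq_len(nrow(nb))) {
        p <- co + as.integer(nb[r, ])
        if (any(p < 1) || any(p > d)) next
        li <- p[1] + d[1] * (p[2] - 1) + d[1] * d[2] * (p[3] - 1)
        if (bin[li] && lab[li] == 0L) {
          lab[li] <- nxt
          queue <- c(queue, li)
        }
      }
    }
  }
  lab
}

# do two labelings induce the same partition of foreground voxels?
same_partition <- function(a, b) {
  ka <- paste(a[a > 0], b[a > 0])
  length(unique(ka)) == max(a) && max(a) == max(b)
}

# average-tie ranks by sorting (no rank())
rank_manual <- function(v) {
  o <- order(v)
  r <- numeric(length(v))
  i <- 1
  while (i <= length(v)) {
    j <- i
    while (j < length(v) && v[o[j + 1]] == v[o[i]]) j <- j + 1
    r[o[i:j]] <- mean(i:j)
    i <- j + 1
  }
  r
}
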