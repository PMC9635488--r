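#' Configuration of the feedforward reading network
#'
#' A fully connected 105-100-61 logistic network mapping slot-coded
#' orthography to slot-coded phonology, trained by online backpropagation
#' (cross-entropy loss). Output units whose target is 1 receive an
#' additional external input that ramps up over training as a function of
#' log-compressed word frequency, a stand-in for a growing semantic
#' contribution to phonology.
#'
#' @param n_input,n_hidden,n_output layer sizes
#' @param epochs passes over the word set
#' @param learning_rate SGD step size
#' @param weight_init_halfwidth weights start uniform on +/- this value
#' @param seed RNG seed for initialization and epoch shuffling
#' @param ramp_gain multiplier g of the external input; 0 disables it
#' @param ramp_halflife k, in epochs: ramp(e) = e / (e + k)
#' @param freq_compression "log1p" (default): ln(1 + f) / ln(1 + freq_ref),
#'   a log compression normalized so the most frequent plausible word
#'   (freq_ref per million) compresses to 1; or "none" (raw frequency)
#' @param freq_ref normalization constant of the log compression, in
#'   occurrences per million (default 1e5)
#' @return object of class `ann_config`
#' @export
ann_config <- function(n_input = 105L, n_hidden = 100L, n_output = 61L,
                       epochs = 400L, learning_rate = 0.1,
                       weight_init_halfwidth = 0.1, seed = 1L,
                       ramp_gain = 2, ramp_halflife = 100,
                       freq_compression = c("log1p", "none"),
                       freq_ref = 1e5) {
  freq_compression <- match.arg(freq_compression)
  stopifnot(n_input >= 1, n_hidden >= 1, n_output >= 1, epochs >= 1,
            learning_rate >= 0, weight_init_halfwidth >= 0,
            ramp_gain >= 0, ramp_halflife > 0, freq_ref > 0)
  structure(list(n_input = as.integer(n_input), n_hidden = as.integer(n_hidden),
                 n_output = as.integer(n_output), epochs = as.integer(epochs),
                 learning_rate = learning_rate,
                 weight_init_halfwidth = weight_init_halfwidth,
                 seed = as.integer(seed), ramp_gain = ramp_gain,
                 ramp_halflife = ramp_halflife,
                 freq_compression = freq_compression, freq_ref = freq_ref),
            class = "ann_config")
}

compress_freq <- function(freq, config) {
  if (any(!is.finite(freq)) || any(freq <= 0)) stop("frequencies must be positive")
  switch(config$freq_compression,
         log1p = log1p(freq) / log1p(config$freq_ref),
         none = freq)
}

#' Initialize network weights
#'
#' All weights and biases i.i.d. uniform on
#' [-weight_init_halfwidth, +weight_init_halfwidth], reproducible from the
#' config seed.
#'
#' @param config an [ann_config()]
#' @return object of class `ann_model`: W1 (hidden x input), b1, W2
#'   (output x hidden), b2, config
#' @export
initialize_model <- function(config) {
  h <- config$weight_init_halfwidth
  with_seed(config$seed, {
    structure(list(
      W1 = matrix(runif(config$n_hidden * config$n_input, -h, h),
                  config$n_hidden, config$n_input),
      b1 = runif(config$n_hidden, -h, h),
      W2 = matrix(runif(config$n_output * config$n_hidden, -h, h),
                  config$n_output, config$n_hidden),
      b2 = runif(config$n_output, -h, h),
      config = config), class = "ann_model")
  })
}

ramp_value <- function(epoch, config) epoch / (epoch + config$ramp_halflife)

#' External input to target phoneme units
#'
#' g * ramp(epoch) * compress(frequency); zero at epoch 0, nondecreasing in
#' epoch, approaching g * compress(frequency). During training the value at
#' epoch e is added to the pre-activation of every output unit whose target
#' is 1 for the presented word.
#'
#' @param frequency occurrences per million (> 0)
#' @param epoch epoch index, starting at 0
#' @param config an [ann_config()]
#' @return nonnegative scalar (vectorized over `frequency`)
#' @export
external_phoneme_input <- function(frequency, epoch, config) {
  stopifnot(epoch >= 0)
  config$ramp_gain * ramp_value(epoch, config) * compress_freq(frequency, config)
}

#' Forward pass
#'
#' hidden = logistic(W1 x + b1); output = logistic(W2 h + b2 + e), where e
#' is the external-input vector (typically `ext * target`). The rounded
#' output is the elementwise nearest whole number (0 or 1).
#'
#' @param model an `ann_model`
#' @param input binary input vector, length n_input
#' @param external external-input vector, length n_output (default zeros)
#' @return list(hidden, output, rounded) of class `reading_output`
#' @export
ann_forward <- function(model, input, external = NULL) {
  cfg <- model$config
  if (length(input) != cfg$n_input)
    stop("input length ", length(input), " != n_input ", cfg$n_input)
  if (is.null(external)) external <- numeric(cfg$n_output)
  if (length(external) != cfg$n_output)
    stop("external-input length ", length(external), " != n_output ", cfg$n_output)
  h <- plogis(drop(model$W1 %*% input) + model$b1)
  y <- plogis(drop(model$W2 %*% h) + model$b2 + external)
  # nearest whole number; the 0.5 tie goes up, matching the compiled scorer
  structure(list(hidden = h, output = y, rounded = as.integer(y >= 0.5)),
            class = "reading_output")
}

#' Train the network
#'
#' Online gradient descent on the cross-entropy error, one pass over the
#' full word set per epoch, presentation order reshuffled every epoch under
#' the config seed. Records per-epoch mean error and training-word accuracy
#' (rounded output identical to target, with that epoch's external input).
#'
#' @param model an initialized `ann_model`
#' @param X orthographic matrix (stimuli x n_input)
#' @param Tmat phonological target matrix (stimuli x n_output)
#' @param freq frequency per million for each stimulus
#' @return list(model=, history=data.frame(epoch, mean_error, accuracy))
#' @export
ann_train <- function(model, X, Tmat, freq) {
  cfg <- model$config
  stopifnot(ncol(X) == cfg$n_input, ncol(Tmat) == cfg$n_output,
            nrow(X) == nrow(Tmat), length(freq) == nrow(X))
  cf <- compress_freq(freq, cfg)
  fit <- with_seed(cfg$seed + 1L,
    cpp_ann_train(model$W1, model$b1, model$W2, model$b2,
                  X * 1.0, Tmat * 1.0, cf, cfg$epochs, cfg$learning_rate,
                  cfg$ramp_gain, cfg$ramp_halflife))
  trained <- structure(list(W1 = fit$W1, b1 = drop(fit$b1), W2 = fit$W2,
                            b2 = drop(fit$b2), config = cfg),
                       class = "ann_model")
  history <- data.frame(epoch = seq_len(cfg$epochs),
                        mean_error = drop(fit$mean_loss),
                        accuracy = drop(fit$accuracy))
  list(model = trained, history = history)
}

#' End-of-training external input per stimulus
#' @keywords internal
final_external <- function(freq, config)
  external_phoneme_input(freq, config$epochs, config)

#' Batch forward pass with per-stimulus external input on target units
#'
#' @param model trained `ann_model`
#' @param X stimuli x n_input
#' @param Tmat stimuli x n_output targets (define where external input lands)
#' @param freq frequencies; external input at its end-of-training value
#' @return list(hidden, output, rounded) matrices
#' @export
ann_read <- function(model, X, Tmat, freq) {
  cfg <- model$config
  ext <- final_external(freq, cfg)
  out <- cpp_ann_forward(model$W1, model$b1, model$W2, model$b2,
                         X * 1.0, ext, Tmat * 1.0)
  rounded <- (out$output >= 0.5) * 1
  dimnames(out$hidden) <- list(rownames(X), NULL)
  dimnames(rounded) <- dimnames(Tmat)
  list(hidden = out$hidden, output = out$output, rounded = rounded)
}

#' Hidden-layer stimulus representations
#'
#' Row i is the hidden activation vector for stimulus i (forward pass with
#' the external input at its end-of-training magnitude on that word's
#' target units; the hidden layer itself is upstream of the external input,
#' which affects only the output layer).
#'
#' @inheritParams ann_read
#' @return numeric matrix, stimuli x n_hidden
#' @export
hidden_representations <- function(model, X, Tmat, freq)
  ann_read(model, X, Tmat, freq)$hidden

#' Exact-match word scoring
#'
#' A rounded output is correct iff it is identical to the target vector.
#' @param rounded,target equal-length binary vectors
#' @return logical
#' @export
score_word <- function(rounded, target) {
  if (length(rounded) != length(target)) stop("length mismatch")
  all(rounded == target)
}

#' Jaccard similarity of two binary vectors
#'
#' |a AND b| / |a OR b|; defined as 1 when both vectors are empty, so an
#' all-zero output is never closer to a target than that target is to
#' itself.
#'
#' @param a,b equal-length binary vectors
#' @return numeric in [0, 1]
#' @export
jaccard_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("length mismatch")
  u <- sum(a | b)
  if (u == 0) return(1)
  sum(a & b) / u
}

#' Score a nonword pronunciation
#'
#' Under the `jaccard` criterion the rounded output is correct iff its
#' maximum Jaccard similarity over the whole pool of pronunciation vectors
#' is attained by a member of the item's acceptable set and strictly
#' exceeds the similarity to every non-member (a tie with a non-member is
#' incorrect). Under the `exact` criterion it is correct iff it equals some
#' acceptable vector.
#'
#' @param rounded rounded output vector
#' @param acceptable_idx indices (rows of `pool`) of acceptable pronunciations
#' @param pool matrix of all pronunciation vectors in the test set
#' @param criterion "jaccard" or "exact"
#' @return logical
#' @export
score_nonword <- function(rounded, acceptable_idx, pool,
                          criterion = c("jaccard", "exact")) {
  criterion <- match.arg(criterion)
  if (length(acceptable_idx) == 0L) stop("acceptable set is empty")
  if (any(acceptable_idx < 1L | acceptable_idx > nrow(pool)))
    stop("acceptable set is not a subset of the pool")
  if (criterion == "exact") {
    return(any(vapply(acceptable_idx, function(i)
      all(rounded == pool[i, ]), logical(1))))
  }
  sims <- vapply(seq_len(nrow(pool)), function(i)
    jaccard_similarity(rounded, pool[i, ]), numeric(1))
  best_acc <- max(sims[acceptable_idx])
  others <- setdiff(seq_len(nrow(pool)), acceptable_idx)
  if (length(others) == 0L) return(TRUE)
  best_acc > max(sims[others])
}

#' Analytic single-sample gradients (for gradient checking)
#' @param model an `ann_model`
#' @param x input vector
#' @param t target vector
#' @param ext scalar external input applied to target-1 units
#' @return list(loss, hidden, output, gW1, gb1, gW2, gb2)
#' @export
ann_gradients <- function(model, x, t, ext = 0)
  cpp_ann_grad(model$W1, model$b1, model$W2, model$b2, x, t, ext)

#' Cross-entropy loss of one sample (for finite-difference oracles)
#' @inheritParams ann_gradients
#' @return scalar loss
#' @export
ann_loss <- function(model, x, t, ext = 0) {
  h <- plogis(drop(model$W1 %*% x) + model$b1)
  y <- plogis(drop(model$W2 %*% h) + model$b2 + ext * t)
  eps <- 1e-12
  -sum(t * log(y + eps) + (1 - t) * log(1 - y + eps))
}
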