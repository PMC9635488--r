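#' Representational dissimilarity matrices
#'
#' An RDM is a symmetric stimuli-by-stimuli matrix of correlation distances
#' (1 - Pearson's r between feature rows), zero on the diagonal, entries in
#' [0, 2]. RDMs are the common representational space in which model and
#' neural codes are compared.
#'
#' @param mat square numeric matrix
#' @param labels stimulus labels (defaults to rownames)
#' @param check validate invariants (symmetry, zero diagonal, range)
#' @return object of class `rdm` (a labeled matrix)
#' @export
rdm <- function(mat, labels = rownames(mat), check = TRUE) {
  mat <- as.matrix(mat)
  if (is.null(labels)) labels <- paste0("s", seq_len(nrow(mat)))
  if (check) {
    if (nrow(mat) != ncol(mat)) stop("RDM must be square")
    if (any(!is.finite(mat))) stop("RDM entries must be finite")
    if (max(abs(mat - t(mat))) > 1e-8) stop("RDM must be symmetric")
    if (max(abs(diag(mat))) > 1e-8) stop("RDM diagonal must be zero")
    if (min(mat) < -1e-8 || max(mat) > 2 + 1e-8)
      stop("correlation-distance entries must lie in [0, 2]")
  }
  mat <- (mat + t(mat)) / 2
  diag(mat) <- 0
  dimnames(mat) <- list(labels, labels)
  structure(mat, class = c("rdm", "matrix", "array"))
}

#' @export
print.rdm <- function(x, ...) {
  cat("RDM over", nrow(x), "stimuli\n")
  print(unclass(x)[seq_len(min(6L, nrow(x))), seq_len(min(6L, ncol(x)))])
  invisible(x)
}

#' Column-wise z-scoring of a feature matrix
#'
#' Each column is centred and scaled to unit (sample) variance.
#' Zero-variance columns carry no pairwise information and would produce
#' NaNs; they are dropped with a warning.
#'
#' @param X stimuli x features matrix
#' @return matrix with standardized, informative columns
#' @export
zscore_features <- function(X) {
  X <- as.matrix(X) * 1.0
  if (nrow(X) < 2L) stop("need at least 2 stimuli")
  s <- apply(X, 2L, sd)
  drop <- !is.finite(s) | s == 0
  if (any(drop)) {
    warning(sum(drop), " zero-variance feature column(s) dropped")
    X <- X[, !drop, drop = FALSE]
    s <- s[!drop]
  }
  scale(X, center = TRUE, scale = s)[, , drop = FALSE]
}

#' Correlation-distance RDM of a feature matrix
#'
#' Entry (i, j) = 1 - Pearson correlation of feature rows i and j.
#'
#' @param X stimuli (rows) x features matrix, rownames used as labels
#' @return an [rdm()]
#' @export
compute_rdm <- function(X) {
  X <- as.matrix(X) * 1.0
  if (nrow(X) < 2L) stop("need at least 2 stimuli")
  if (ncol(X) < 2L) stop("need at least 2 features")
  rs <- apply(X, 1L, sd)
  if (any(rs == 0)) {
    bad <- rownames(X)[rs == 0] %||% which(rs == 0)
    stop("stimulus with zero feature variance: ", paste(bad, collapse = ", "))
  }
  D <- 1 - cor(t(X))
  rdm(D, labels = rownames(X))
}

#' Elementwise mean of RDMs
#' @param rdms list of [rdm()]s with identical labels
#' @return an [rdm()]
#' @export
average_rdms <- function(rdms) {
  stopifnot(length(rdms) >= 1L)
  lab <- rownames(rdms[[1]])
  for (r in rdms)
    if (!identical(rownames(r), lab)) stop("RDM labels differ")
  rdm(Reduce(`+`, lapply(rdms, unclass)) / length(rdms), labels = lab)
}

#' Upper-triangle vector of an RDM (diagonal excluded)
#' @param x an [rdm()]
#' @return numeric vector of length n(n-1)/2, column-major order
#' @export
upper_tri_vec <- function(x) {
  m <- unclass(x)
  m[upper.tri(m)]
}

check_labels <- function(a, b) {
  if (!identical(rownames(a), rownames(b))) stop("RDM labels do not match")
}

#' Rank-based second-order correlation of two RDMs
#'
#' Spearman correlation over the strictly-upper triangles (average ranks
#' for ties).
#'
#' @param a,b [rdm()]s with matching labels
#' @return list of class `rdm_comparison`: rho, n_pairs, method
#' @export
rdm_spearman <- function(a, b) {
  check_labels(a, b)
  ua <- upper_tri_vec(a); ub <- upper_tri_vec(b)
  structure(list(rho = cor(ua, ub, method = "spearman"),
                 n_pairs = length(ua), method = "spearman", control = NULL),
            class = "rdm_comparison")
}

#' Rank-based partial correlation of two RDMs given a third
#'
#' All three upper-triangle vectors are rank-transformed; the partial
#' correlation of target with model controlling for control is
#' (r_tm - r_tc r_mc) / sqrt((1 - r_tc^2)(1 - r_mc^2)) on the ranks
#' (equivalently, the correlation of the rank residuals).
#'
#' @param target,model,control [rdm()]s with matching labels
#' @return `rdm_comparison` with method "partial_spearman"
#' @export
rdm_partial_spearman <- function(target, model, control) {
  check_labels(target, model); check_labels(target, control)
  rt <- rank(upper_tri_vec(target))
  rm_ <- rank(upper_tri_vec(model))
  rc <- rank(upper_tri_vec(control))
  r_tm <- cor(rt, rm_); r_tc <- cor(rt, rc); r_mc <- cor(rm_, rc)
  if (!is.finite(r_mc) || abs(r_mc) >= 1 - 1e-12)
    stop("model and control RDMs are rank-identical; partial correlation undefined")
  if (abs(r_tc) >= 1 - 1e-12) {
    # the control exhausts the target's rank variance; nothing remains for
    # the model to explain
    rho <- 0
  } else {
    rho <- (r_tm - r_tc * r_mc) / sqrt((1 - r_tc^2) * (1 - r_mc^2))
  }
  structure(list(rho = rho, n_pairs = length(rt), method = "partial_spearman",
                 control = "control"), class = "rdm_comparison")
}

#' @export
print.rdm_comparison <- function(x, ...) {
  cat(x$method, "rho =", format(x$rho, digits = 4),
      "over", x$n_pairs, "pairs\n")
  invisible(x)
}

#' Pairwise correlation table of named RDMs
#'
#' Mirrors the usual model-RDM correlation-matrix report: symmetric with
#' unit diagonal. `method = "pearson"` (default) correlates the distance
#' vectors directly; `"spearman"` uses the rank-based second-order
#' correlation.
#'
#' @param rdms named list of [rdm()]s (>= 2)
#' @param method "pearson" or "spearman"
#' @return matrix with model labels, class `rdm_correlation_table`
#' @export
build_correlation_table <- function(rdms, method = c("pearson", "spearman")) {
  method <- match.arg(method)
  stopifnot(length(rdms) >= 2L, !is.null(names(rdms)))
  k <- length(rdms)
  out <- diag(k)
  dimnames(out) <- list(names(rdms), names(rdms))
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    check_labels(rdms[[i]], rdms[[j]])
    v <- cor(upper_tri_vec(rdms[[i]]), upper_tri_vec(rdms[[j]]),
             method = method)
    out[i, j] <- out[j, i] <- v
  }
  structure(out, class = c("rdm_correlation_table", "matrix", "array"))
}

#' RDM TSV round trip (header row/column of labels)
#' @param x an [rdm()]
#' @param path file path
#' @export
write_rdm_tsv <- function(x, path) {
  df <- data.frame(label = rownames(x), unclass(x), check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rdm_tsv
#' @export
read_rdm_tsv <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  lab <- as.character(df$label)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rdm(m, labels = lab)
}
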