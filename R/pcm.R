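#' Pairwise comparison matrix
#'
#' Construct and validate a reciprocal judgment matrix on the Saaty 1-9
#' scale for one node of a criteria hierarchy. Entry `a[i, j]` states how
#' much more important element i is than element j; the diagonal is 1 and
#' `a[i, j] * a[j, i] == 1`.
#'
#' Inputs may supply only the upper triangle (lower triangle `NA` or 0);
#' missing lower-triangle entries are filled with reciprocals. Full
#' matrices are validated for reciprocity to a relative tolerance of 1e-6.
#'
#' @param entries Square numeric matrix (n >= 2) of positive judgments.
#' @param node Optional name of the hierarchy node the matrix belongs to.
#' @param permissive If `TRUE`, entries outside \[1/9, 9\] are admitted with
#'   a warning instead of an error.
#' @return An object of class `pcm`: the validated matrix with attributes
#'   `node`.
#' @export
#' @examples
#' m <- pcm(rbind(c(1, 2, 4), c(NA, 1, 2), c(NA, NA, 1)))
#' ahp_weights(m)
pcm <- function(entries, node = NULL, permissive = FALSE) {
  if (!is.matrix(entries) || !is.numeric(entries)) {
    abort_mcda("`entries` must be a numeric matrix")
  }
  n <- nrow(entries)
  if (n < 2L || ncol(entries) != n) {
    abort_mcda("judgment matrix must be square with n >= 2")
  }
  m <- entries
  m[m == 0] <- NA_real_
  # fill lower triangle from upper where absent
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i > j && is.na(m[i, j]) && !is.na(m[j, i])) m[i, j] <- 1 / m[j, i]
      if (i < j && is.na(m[i, j]) && !is.na(m[j, i])) m[i, j] <- 1 / m[j, i]
    }
  }
  diag(m)[is.na(diag(m))] <- 1
  if (anyNA(m)) {
    idx <- which(is.na(m), arr.ind = TRUE)[1, ]
    abort_mcda(sprintf("judgment missing at cell (%d, %d) with no reciprocal",
                       idx[1], idx[2]))
  }
  if (any(m <= 0)) {
    idx <- which(m <= 0, arr.ind = TRUE)[1, ]
    abort_mcda(sprintf("non-positive judgment at cell (%d, %d)", idx[1], idx[2]))
  }
  bad_diag <- which(abs(diag(m) - 1) > 1e-9)
  if (length(bad_diag)) {
    abort_mcda(sprintf("diagonal entry (%d, %d) must be 1, got %g",
                       bad_diag[1], bad_diag[1], diag(m)[bad_diag[1]]))
  }
  recip <- m * t(m)
  bad <- which(abs(recip - 1) > 1e-6, arr.ind = TRUE)
  if (nrow(bad)) {
    abort_mcda(sprintf(
      "reciprocity violated at cells (%d, %d)/(%d, %d): a_ij * a_ji = %.8g",
      bad[1, 1], bad[1, 2], bad[1, 2], bad[1, 1], recip[bad[1, 1], bad[1, 2]]))
  }
  out_of_scale <- which(m < 1 / 9 - 1e-9 | m > 9 + 1e-9, arr.ind = TRUE)
  if (nrow(out_of_scale)) {
    msg <- sprintf("judgment at cell (%d, %d) = %g outside the [1/9, 9] scale",
                   out_of_scale[1, 1], out_of_scale[1, 2],
                   m[out_of_scale[1, 1], out_of_scale[1, 2]])
    if (permissive) warning(msg, call. = FALSE) else abort_mcda(msg)
  }
  if (!is.null(rownames(m)) && anyDuplicated(rownames(m))) {
    abort_mcda("duplicate element names in judgment matrix")
  }
  structure(m, class = c("pcm", "matrix", "array"), node = node)
}

#' @export
print.pcm <- function(x, ...) {
  node <- attr(x, "node")
  cat(sprintf("Pairwise comparison matrix (%d x %d)%s\n",
              nrow(x), ncol(x),
              if (is.null(node)) "" else paste0(" for node '", node, "'")))
  print(round(unclass(x), 4))
  invisible(x)
}

#' Build a perfectly consistent judgment matrix from a weight vector
#'
#' Returns the matrix with `a[i, j] = w[i] / w[j]`, which is consistent by
#' construction; `ahp_weights()` recovers `w` (normalized) exactly up to
#' numerical tolerance. Mainly used to seed simulations and tests.
#'
#' @param w Positive numeric weight vector (length >= 2); need not sum to 1.
#' @param node Optional hierarchy node name.
#' @param snap If `TRUE`, entries are snapped to the nearest Saaty value
#'   (the matrix is then only approximately consistent).
#' @return A `pcm` object.
#' @export
consistent_pcm <- function(w, node = NULL, snap = FALSE) {
  stopifnot(is.numeric(w), length(w) >= 2, all(w > 0))
  m <- outer(w, w, "/")
  if (snap) {
    up <- upper.tri(m)
    m[up] <- snap_to_saaty(m[up])
    m[lower.tri(m)] <- 1 / t(m)[lower.tri(m)]
    diag(m) <- 1
  }
  if (!is.null(names(w))) dimnames(m) <- list(names(w), names(w))
  pcm(m, node = node, permissive = TRUE)
}
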