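#' AHP priority weights from a pairwise comparison matrix
#'
#' Computes the priority vector of a reciprocal judgment matrix. The
#' default method is the principal right eigenvector, found by power
#' iteration (tolerance 1e-10, at most 10,000 iterations); the
#' row-geometric-mean method is available as a cross-check and coincides
#' with the eigenvector on perfectly consistent matrices.
#'
#' @param matrix A `pcm` object (or a matrix accepted by [pcm()]).
#' @param method `"eigen"` (principal eigenvector, default) or
#'   `"geometric"` (row geometric means).
#' @param tol Convergence tolerance for power iteration.
#' @param max_iter Maximum number of power-iteration sweeps.
#' @return A list with `weights` (nonnegative, summing to 1, named after
#'   the matrix rows) and `lambda_max` (the dominant eigenvalue; for the
#'   geometric method, the Perron value of the matrix evaluated at the
#'   geometric-mean vector).
#' @export
#' @examples
#' m <- pcm(rbind(c(1, 2, 4), c(1/2, 1, 2), c(1/4, 1/2, 1)))
#' ahp_weights(m)$weights  # 4/7, 2/7, 1/7
ahp_weights <- function(matrix, method = c("eigen", "geometric"),
                        tol = 1e-10, max_iter = 10000L) {
  method <- match.arg(method)
  if (!inherits(matrix, "pcm")) matrix <- pcm(matrix)
  a <- unclass(matrix)
  n <- nrow(a)
  if (method == "geometric") {
    w <- exp(rowMeans(log(a)))
    w <- w / sum(w)
    lambda <- mean((a %*% w) / w)
    return(list(weights = stats::setNames(w, rownames(a)), lambda_max = lambda))
  }
  w <- rep(1 / n, n)
  lambda <- n
  for (it in seq_len(max_iter)) {
    v <- as.vector(a %*% w)
    w_new <- v / sum(v)
    lambda <- sum(v)                       # Rayleigh-type estimate on the simplex
    if (max(abs(w_new - w)) < tol) {
      lambda <- mean((a %*% w_new) / w_new)
      return(list(weights = stats::setNames(w_new, rownames(a)),
                  lambda_max = lambda))
    }
    w <- w_new
  }
  abort_mcda(sprintf("power iteration did not converge in %d iterations", max_iter))
}

#' Saaty random index table
#'
#' Random consistency indices for matrix orders 1 through 15, used to scale
#' the consistency index into the consistency ratio. Orders 1 and 2 have
#' RI = 0 (reciprocal matrices of those orders are always consistent).
#'
#' @return Named numeric vector, names `"1"` to `"15"`.
#' @export
random_index <- function() {
  c(`1` = 0, `2` = 0, `3` = 0.58, `4` = 0.90, `5` = 1.12, `6` = 1.24,
    `7` = 1.32, `8` = 1.41, `9` = 1.45, `10` = 1.49, `11` = 1.51,
    `12` = 1.48, `13` = 1.56, `14` = 1.57, `15` = 1.59)
}

#' Consistency diagnostics for a judgment matrix
#'
#' Computes the principal eigenvalue, consistency index
#' CI = (lambda_max - n) / (n - 1), consistency ratio CR = CI / RI and the
#' acceptability flag CR < threshold. For n = 2 the CR is defined as 0: a
#' reciprocal 2x2 matrix is always consistent.
#'
#' @param matrix A `pcm` object (2 <= n <= 15).
#' @param threshold Acceptability threshold on CR (default 0.1).
#' @return A list of class `ahp_consistency` with fields `n`, `lambda_max`,
#'   `consistency_index`, `random_index`, `consistency_ratio`, `acceptable`.
#' @export
ahp_consistency <- function(matrix, threshold = 0.1) {
  if (!inherits(matrix, "pcm")) matrix <- pcm(matrix)
  n <- nrow(matrix)
  ri_tab <- random_index()
  if (n > length(ri_tab)) {
    abort_mcda(sprintf("no random index tabulated for order n = %d (max %d)",
                       n, length(ri_tab)))
  }
  lambda <- ahp_weights(matrix)$lambda_max
  if (n == 2L) {
    ci <- 0; cr <- 0
  } else {
    ci <- (lambda - n) / (n - 1)
    cr <- ci / ri_tab[[as.character(n)]]
  }
  structure(list(n = n, lambda_max = lambda, consistency_index = ci,
                 random_index = ri_tab[[as.character(n)]],
                 consistency_ratio = cr,
                 acceptable = cr < threshold),
            class = "ahp_consistency")
}

#' @export
print.ahp_consistency <- function(x, ...) {
  cat(sprintf("AHP consistency (n = %d): lambda_max = %.6f, CI = %.6f, CR = %.6f (%s)\n",
              x$n, x$lambda_max, x$consistency_index, x$consistency_ratio,
              if (x$acceptable) "acceptable" else "NOT acceptable"))
  invisible(x)
}

#' Aggregate expert judgment matrices
#'
#' Combines several experts' judgment matrices for the same hierarchy node
#' into one group matrix by the element-wise (optionally weighted)
#' geometric mean: entry ij of the result is
#' `(prod a_ij^u_k)^(1 / sum u_k)` with `u_k = 1` by default or the
#' expert's authority coefficient when `expert_weights` is supplied.
#' Reciprocity of the result is exact by construction.
#'
#' @param matrices List of `pcm` objects of equal order (same node).
#' @param expert_weights Optional positive numeric vector, one weight per
#'   expert (e.g. authority coefficients Cr).
#' @return A `pcm` object.
#' @export
aggregate_judgments <- function(matrices, expert_weights = NULL) {
  if (!is.list(matrices) || length(matrices) == 0L) {
    abort_mcda("`matrices` must be a non-empty list of judgment matrices")
  }
  matrices <- lapply(matrices, function(m) if (inherits(m, "pcm")) m else pcm(m))
  n <- nrow(matrices[[1]])
  if (any(vapply(matrices, nrow, 1L) != n)) {
    abort_mcda("all judgment matrices must have the same order")
  }
  k <- length(matrices)
  u <- if (is.null(expert_weights)) rep(1, k) else expert_weights
  if (length(u) != k || any(!is.finite(u)) || any(u <= 0)) {
    abort_mcda("`expert_weights` must be positive, one per expert")
  }
  u <- u / sum(u)
  logm <- Reduce(`+`, Map(function(m, w) w * log(unclass(m)), matrices, as.list(u)))
  g <- exp(logm)
  # enforce exact reciprocity against floating-point drift
  g[lower.tri(g)] <- 1 / t(g)[lower.tri(g)]
  diag(g) <- 1
  dimnames(g) <- dimnames(matrices[[1]])
  pcm(g, node = attr(matrices[[1]], "node"), permissive = TRUE)
}

#' Expert authority coefficient
#'
#' The authority coefficient Cr of an expert is the arithmetic mean of the
#' influence coefficient Ca and the familiarity coefficient Cs, both on
#' \[0, 1\]: Cr = (Ca + Cs) / 2. Values above 0.8 are conventionally taken
#' to indicate an authoritative judgment.
#'
#' @param ca Influence coefficient(s) in \[0, 1\].
#' @param cs Familiarity coefficient(s) in \[0, 1\]; recycled against `ca`.
#' @return Numeric vector of authority coefficients.
#' @export
#' @examples
#' authority_coefficient(0.9, 0.8)  # 0.85
authority_coefficient <- function(ca, cs) {
  if (!is.numeric(ca) || !is.numeric(cs) || anyNA(ca) || anyNA(cs) ||
      any(ca < 0 | ca > 1) || any(cs < 0 | cs > 1)) {
    abort_mcda("`ca` and `cs` must be numeric in [0, 1]")
  }
  (ca + cs) / 2
}

#' Panel authority summary
#'
#' Computes each expert's authority coefficient and flags whether the whole
#' panel exceeds the conventional 0.8 acceptability bar.
#'
#' @param roster Data frame with columns `expert_id`, `ca`, `cs`.
#' @param bar Acceptability bar on Cr (default 0.8, exclusive).
#' @return The roster with a `cr` column, plus attribute `authoritative`
#'   (`TRUE` when every Cr > `bar`).
#' @export
panel_authority <- function(roster, bar = 0.8) {
  need <- c("expert_id", "ca", "cs")
  if (!is.data.frame(roster) || !all(need %in% names(roster))) {
    abort_mcda("`roster` must be a data frame with columns expert_id, ca, cs")
  }
  roster$cr <- authority_coefficient(roster$ca, roster$cs)
  attr(roster, "authoritative") <- all(roster$cr > bar)
  roster
}
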