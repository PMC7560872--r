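#' Jensen-Shannon distance between two compositions
#'
#' The square root of the Jensen-Shannon divergence, computed with base-2
#' logarithms so the distance lies in \[0, 1\]. sqrt-JSD is a true metric on
#' the probability simplex, which makes it a suitable definition of the
#' compositional phase space.
#'
#' @param p,q numeric vectors of equal length: non-negative, each summing to
#'   1 within `1e-6`.
#' @return A scalar in \[0, 1\]; 0 iff `p == q`, 1 for disjoint supports.
#' @examples
#' js_distance(c(1, 0), c(0, 1))      # 1
#' js_distance(c(1, 0), c(0.5, 0.5))  # ~0.5579
#' @export
js_distance <- function(p, q) {
  if (length(p) != length(q))
    stop("compositions differ in length (", length(p), " vs ", length(q), ")")
  .check_composition(p, "p")
  .check_composition(q, "q")
  sqrt(js_divergence(p, q))
}

.check_composition <- function(x, name) {
  if (any(!is.finite(x)) || any(x < 0))
    stop("'", name, "' is not a valid composition (negative or non-finite)")
  if (abs(sum(x) - 1) > 1e-6)
    stop("'", name, "' does not sum to 1 (sum = ", format(sum(x)), ")")
  invisible(TRUE)
}

#' Jensen-Shannon divergence (base-2)
#'
#' `JSD(p, q) = H(m) - (H(p) + H(q))/2` with `m = (p + q)/2` and Shannon
#' entropy `H` in bits. Zero cells contribute zero (the `0 log 0 = 0`
#' convention).
#'
#' @inheritParams js_distance
#' @return A scalar in \[0, 1\].
#' @export
js_divergence <- function(p, q) {
  m <- (p + q) / 2
  d <- .entropy2(m) - (.entropy2(p) + .entropy2(q)) / 2
  # clamp tiny negative round-off so sqrt() stays real
  max(d, 0)
}

.entropy2 <- function(x) {
  x <- x[x > 0]
  -sum(x * log2(x))
}

#' Pairwise sample distances in compositional phase space
#'
#' Builds the full symmetric distance matrix over samples, using either the
#' Jensen-Shannon distance (default; base-2, entries in \[0, 1\]) or the
#' Aitchison distance (Euclidean distance between centered-log-ratio
#' transforms). Taxa absent from every sample are dropped first (they cannot
#' affect either metric).
#'
#' @param t an [abundance_table()], already normalized (rows sum to 1).
#' @param metric `"js"` or `"aitchison"`.
#' @param pseudocount for `"aitchison"` only: `NULL` (default) errors on any
#'   zero entry; `"auto"` uses 0.5 x the smallest nonzero relative abundance;
#'   a positive number is used as given. Rows are renormalized after the
#'   pseudocount is added.
#' @return A symmetric numeric matrix with zero diagonal and sample IDs as
#'   dimnames.
#' @export
pairwise_distances <- function(t, metric = c("js", "aitchison"),
                               pseudocount = NULL) {
  stopifnot(inherits(t, "abundance_table"))
  metric <- match.arg(metric)
  t <- drop_empty_taxa(t)
  P <- t$values
  rs <- rowSums(P)
  if (any(abs(rs - 1) > 1e-6))
    stop("table is not normalized; call to_relative_abundance() first")
  n <- nrow(P)
  if (metric == "js") {
    hp <- apply(P, 1, .entropy2)
    d <- matrix(0, n, n, dimnames = list(rownames(P), rownames(P)))
    for (i in seq_len(max(n - 1, 0))) {
      js <- seq.int(i + 1L, n)
      M <- (P[rep(i, length(js)), , drop = FALSE] + P[js, , drop = FALSE]) / 2
      Mh <- apply(M, 1, .entropy2)
      v <- sqrt(pmax(Mh - (hp[i] + hp[js]) / 2, 0))
      d[i, js] <- v
      d[js, i] <- v
    }
  } else {
    if (any(P == 0)) {
      if (is.null(pseudocount))
        stop("Aitchison distance undefined with zero entries; ",
             "set pseudocount = \"auto\" or a positive number")
      eps <- if (identical(pseudocount, "auto"))
        0.5 * min(P[P > 0]) else as.numeric(pseudocount)
      if (!is.finite(eps) || eps <= 0) stop("pseudocount must be positive")
      P <- P + eps
      P <- P / rowSums(P)
    }
    clr <- log(P) - rowMeans(log(P))
    d <- as.matrix(stats::dist(clr))
    dimnames(d) <- list(rownames(P), rownames(P))
  }
  d
}

#' Write / read a square distance matrix as TSV
#'
#' Plain-text interchange format: header row and first column carry sample
#' IDs.
#'
#' @param d symmetric numeric matrix with dimnames.
#' @param path output file.
#' @return `write_distance_matrix` returns `path` invisibly;
#'   `read_distance_matrix` returns the matrix.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(sample_id = rownames(d), d, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_distance_matrix
#' @export
read_distance_matrix <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t", row.names = 1,
                          check.names = FALSE)
  d <- as.matrix(df)
  validate_distance_matrix(d)
  d
}

#' Validate a distance matrix
#'
#' Checks symmetry, zero diagonal and non-negativity.
#'
#' @param d matrix to check.
#' @param tol numeric tolerance for symmetry.
#' @return `d`, invisibly, or an error.
#' @export
validate_distance_matrix <- function(d, tol = 1e-9) {
  if (!is.matrix(d) || nrow(d) != ncol(d))
    stop("distance matrix must be square")
  if (is.null(rownames(d))) stop("distance matrix must carry sample IDs")
  if (any(d < 0)) stop("negative distances")
  if (any(abs(diag(d)) > tol)) stop("nonzero diagonal")
  if (max(abs(d - t(d))) > tol) stop("matrix not symmetric")
  invisible(d)
}
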