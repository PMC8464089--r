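#' Multi-class ReliefF feature weighting
#'
#' Standard multi-class ReliefF (Kononenko): for each evaluated instance
#' `R`, the `k` nearest same-class neighbours (hits) and, for every other
#' class `c`, the `k` nearest neighbours in `c` (misses) are found under
#' Manhattan distance on range-normalized features.  Each feature weight
#' is updated by
#' \deqn{W[f] \mathrel{-}= \overline{\mathrm{diff}}(f, R, \mathrm{hits})/n
#'   \;+\; \sum_{c \ne \mathrm{class}(R)}
#'   \frac{P(c)}{1 - P(\mathrm{class}(R))}
#'   \overline{\mathrm{diff}}(f, R, \mathrm{misses}_c)/n,}
#' with `diff(f, a, b) = |a_f - b_f| / range_f`.  Features that separate
#' classes accumulate positive weight; features independent of the labels
#' hover near zero; constant features get exactly zero.
#'
#' Ties in the final ordering are broken by original column order, and
#' with `n_samples = NULL` (all instances, the default) the result is
#' fully deterministic regardless of `seed`.
#'
#' @param x Numeric matrix or data frame of features (rows = instances).
#' @param labels Class labels, one per row; at least two classes.
#' @param k_neighbors Number of hits/misses per class (default 10); must
#'   be smaller than the smallest class size.
#' @param n_samples Number of instances to evaluate (sampled without
#'   replacement using `seed`), or `NULL` for all.
#' @param seed Seed for the optional subsampling.
#' @return Object of class `feature_ranking`: list with `weights` (named,
#'   in column order) and `order` (feature names by descending weight).
#' @examples
#' x <- cbind(sig = rep(0:1, each = 10), noise = rep(1, 20))
#' r <- relieff_rank(x, rep(c("a", "b"), each = 10), k_neighbors = 3)
#' r$order[1]
#' @export
relieff_rank <- function(x, labels, k_neighbors = 10, n_samples = NULL,
                         seed = 0) {
  x <- as.matrix(as.data.frame(x, check.names = FALSE))
  storage.mode(x) <- "double"
  if (anyNA(x)) stop("relieff_rank: feature matrix contains missing values")
  labels <- factor(labels)
  labels <- droplevels(labels)
  if (nlevels(labels) < 2L)
    stop("relieff_rank: need at least two classes")
  if (nrow(x) != length(labels))
    stop("relieff_rank: labels must match rows")
  cls_sizes <- table(labels)
  k_neighbors <- as.integer(k_neighbors)
  if (k_neighbors < 1L || k_neighbors >= min(cls_sizes))
    stop("relieff_rank: k_neighbors must be >= 1 and smaller than the ",
         "smallest class size (", min(cls_sizes), ")")
  n <- nrow(x); nf <- ncol(x)
  rng <- apply(x, 2, max) - apply(x, 2, min)
  live <- rng > 0
  xn <- x
  xn[, live] <- sweep(xn[, live, drop = FALSE], 2, rng[live], "/")
  xn[, !live] <- 0                      # zero-range features carry no signal
  prior <- as.numeric(cls_sizes) / n
  names(prior) <- names(cls_sizes)

  eval_idx <- seq_len(n)
  if (!is.null(n_samples)) {
    n_samples <- as.integer(n_samples)
    if (n_samples < 1L || n_samples > n)
      stop("relieff_rank: n_samples out of range")
    eval_idx <- with_seed(seed, sort(sample.int(n, n_samples)))
  }
  w <- numeric(nf)
  n_used <- length(eval_idx)
  lvls <- levels(labels)
  for (i in eval_idx) {
    d_feat <- abs(sweep(xn, 2, xn[i, ]))  # n x nf, normalized diffs
    d <- rowSums(d_feat)
    cls_i <- as.character(labels[i])
    for (cl in lvls) {
      members <- which(labels == cl)
      members <- members[members != i]
      nb <- members[order(d[members], members)][seq_len(k_neighbors)]
      mean_diff <- colMeans(d_feat[nb, , drop = FALSE])
      if (cl == cls_i) {
        w <- w - mean_diff / n_used
      } else {
        w <- w + (prior[[cl]] / (1 - prior[[cls_i]])) * mean_diff / n_used
      }
    }
  }
  names(w) <- colnames(x) %||% paste0("f", seq_len(nf))
  ord <- order(-w, seq_len(nf))
  structure(list(weights = w, order = names(w)[ord]),
            class = "feature_ranking")
}

#' @export
print.feature_ranking <- function(x, n = 10, ...) {
  cat("<feature_ranking>", length(x$order), "features\n")
  top <- utils::head(x$order, n)
  for (i in seq_along(top))
    cat(sprintf("  %2d. %-28s %+.4f\n", i, top[i], x$weights[[top[i]]]))
  if (length(x$order) > n) cat("  ...\n")
  invisible(x)
}

#' Top-ranked feature names
#'
#' @param ranking A [relieff_rank()] result.
#' @param n Number of leading features, `1 <= n <= length(ranking$order)`.
#' @return Character vector of the first `n` feature names.
#' @export
top_n <- function(ranking, n) {
  if (!inherits(ranking, "feature_ranking"))
    stop("top_n: ranking must be a feature_ranking")
  n <- as.integer(n)
  if (n < 1L || n > length(ranking$order))
    stop("top_n: n must be between 1 and ", length(ranking$order))
  ranking$order[seq_len(n)]
}
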