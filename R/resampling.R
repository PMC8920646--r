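# Imbalance resampling: SMOTE oversampling, Tomek-link undersampling, and
# the Tomek-first hybrid that balances the classes exactly. Distances are
# Euclidean on z-scored features (the 16 descriptors span several orders of
# magnitude, so unscaled Euclidean distance would be dominated by the
# largest-scale feature).

zscore <- function(X) {
  mu <- colMeans(X)
  sd_ <- apply(X, 2L, stats::sd)
  sd_[sd_ == 0] <- 1
  sweep(sweep(X, 2L, mu), 2L, sd_, "/")
}

#' SMOTE minority oversampling
#'
#' Synthesizes minority-class samples by interpolation: a minority base
#' sample is chosen round-robin, one of its `T_neighbors` nearest minority
#' neighbors (Euclidean on z-scored features) is drawn uniformly, and the
#' synthetic point is `base + lambda * (neighbor - base)` with
#' `lambda ~ Uniform[0, 1]`. Enough points are synthesized to bring the
#' minority up to `target_count` (default: the majority count).
#'
#' @param X numeric feature matrix (rows = samples)
#' @param y factor/character labels with two classes
#' @param T_neighbors nearest-neighbor pool size (default 5); reduced with a
#'   warning when the minority class is too small
#' @param target_count minority size after oversampling (default: majority
#'   count, i.e. full balance)
#' @param seed integer seed; fixed seed gives identical output
#' @return list of class `resample_result`: `X`, `y`, `provenance`
#'   (`"original"`/`"synthetic"` per row), `seed`
#' @export
smote <- function(X, y, T_neighbors = 5L, target_count = NULL, seed = 1L) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2L) stopf("need exactly two classes")
  minority <- names(tab)[which.min(tab)]
  min_idx <- which(y == minority)
  d <- length(min_idx)
  if (d < 2L) stopf("minority class must have at least 2 members")
  target_count <- target_count %||% max(tab)
  if (target_count < d) stopf("target_count (%d) below current minority count (%d)",
                              target_count, d)
  if (T_neighbors > d - 1L) {
    warnf("T reduced from %d to %d (minority size %d)", T_neighbors, d - 1L, d)
    T_neighbors <- d - 1L
  }
  n_syn <- target_count - d
  prov <- rep("original", nrow(X))
  if (n_syn == 0L)
    return(structure(list(X = X, y = y, provenance = prov, seed = seed),
                     class = "resample_result"))
  Z <- zscore(X)[min_idx, , drop = FALSE]
  D <- as.matrix(stats::dist(Z))
  diag(D) <- Inf
  ord <- apply(D, 1L, function(r) order(r)[seq_len(T_neighbors)])
  nn <- if (T_neighbors == 1L) matrix(ord, ncol = 1L) else t(ord)
  set.seed(seed)
  base <- rep_len(seq_len(d), n_syn)          # round-robin base cycling
  pick <- sample.int(T_neighbors, n_syn, replace = TRUE)
  lambda <- stats::runif(n_syn)
  Xb <- X[min_idx[base], , drop = FALSE]
  Xn <- X[min_idx[nn[cbind(base, pick)]], , drop = FALSE]
  synth <- Xb + lambda * (Xn - Xb)
  structure(list(X = rbind(X, synth),
                 y = c(y, rep(minority, n_syn)),
                 provenance = c(prov, rep("synthetic", n_syn)),
                 seed = seed),
            class = "resample_result")
}

#' Find Tomek links and undersample the majority class
#'
#' An opposite-class pair (b, a) forms a Tomek link when no other sample is
#' strictly closer to either member than they are to each other
#' (mutual-nearest-neighbor condition, Euclidean on z-scored features).
#' In undersampler mode the majority member of every link is removed.
#'
#' @param X numeric feature matrix
#' @param y two-class labels
#' @return list of class `resample_result` with `X`, `y`, `provenance`,
#'   `removed_indices` (row indices of removed majority samples) and
#'   `links` (two-column matrix of linked row indices, minority first)
#' @export
tomek_links <- function(X, y) {
  X <- as.matrix(X)
  y <- as.character(y)
  tab <- table(y)
  if (length(tab) != 2L) stopf("need exactly two classes")
  majority <- names(tab)[which.max(tab)]
  D <- as.matrix(stats::dist(zscore(X)))
  diag(D) <- Inf
  nnd <- apply(D, 1L, min)
  eps <- 1e-12
  links <- NULL
  n <- nrow(X)
  for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
    if (y[i] == y[j]) next
    if (D[i, j] <= nnd[i] + eps && D[i, j] <= nnd[j] + eps) {
      pair <- if (y[i] == majority) c(j, i) else c(i, j)  # minority first
      links <- rbind(links, pair)
    }
  }
  removed <- if (is.null(links)) integer(0) else unique(links[, 2L])
  keep <- setdiff(seq_len(n), removed)
  structure(list(X = X[keep, , drop = FALSE], y = y[keep],
                 provenance = rep("original", length(keep)),
                 removed_indices = removed,
                 links = links, keep = keep),
            class = "resample_result")
}

#' Hybrid SMOTE-Tomek resampling
#'
#' Default order (`"tomek_first"`): majority members of Tomek links are
#' removed first, then SMOTE raises the minority to the reduced majority
#' count, leaving the classes exactly balanced (104 benign / 26 malignant
#' with 11 links removed becomes 93 / 93). The alternative order
#' (`"smote_first"`) oversamples to balance and then removes the majority
#' members of any links among the resampled data.
#'
#' @inheritParams smote
#' @param order stage order
#' @return `resample_result` with balanced classes (tomek_first)
#' @export
smote_tomek <- function(X, y, T_neighbors = 5L, seed = 1L,
                        order = c("tomek_first", "smote_first")) {
  order <- match.arg(order)
  if (order == "tomek_first") {
    st <- tomek_links(X, y)
    tab <- table(st$y)
    out <- smote(st$X, st$y, T_neighbors, target_count = max(tab), seed = seed)
    out$removed_indices <- st$removed_indices
    out
  } else {
    sm <- smote(X, y, T_neighbors, seed = seed)
    st <- tomek_links(sm$X, sm$y)
    st$provenance <- sm$provenance[st$keep]
    st
  }
}
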