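# Gain-ratio (C4.5-style) decision trees and discrete AdaBoost ensembles.
# Two classifier configurations are supported: boosted unpruned gain-ratio
# trees ("boosted J48", base = "tree") and boosted depth-1 stumps (classic
# AdaBoost, base = "stump"). Multi-class boosting follows SAMME.

#' Shannon entropy of class counts
#'
#' `-sum p log2 p` over classes with positive count, in bits.
#'
#' @param counts non-negative class counts (or weights), total > 0.
#' @return entropy in bits.
#' @export
entropy <- function(counts) {
  tot <- sum(counts)
  if (length(counts) == 0L || tot <= 0) stop("empty class counts")
  p <- counts / tot
  -sum(plogp(p))
}

#' Split information of a partition
#'
#' `-sum (|Ti|/|T|) log2 (|Ti|/|T|)` over the subset sizes of a partition;
#' for a binary split this is the entropy of the split proportions.
#'
#' @param sizes positive subset sizes.
#' @return split information in bits.
#' @export
split_info <- function(sizes) {
  if (any(sizes <= 0)) stop("all subset sizes must be positive")
  entropy(sizes)
}

#' Best gain-ratio split of a weighted sample set
#'
#' For each attribute, candidate thresholds are the midpoints between
#' consecutive distinct sorted values; the weighted information gain and
#' split information are evaluated for every candidate and the candidate
#' maximising the gain ratio among those with positive gain and positive
#' split information is returned. Ties break to the lowest attribute index,
#' then the lowest threshold.
#'
#' @param X numeric matrix (samples x attributes).
#' @param y class labels (character/factor).
#' @param weights optional non-negative sample weights (default uniform);
#'   normalised internally.
#' @param min_leaf minimum number of samples required on each side.
#' @return list with `attribute`, `threshold`, `gain`, `split_info`,
#'   `gain_ratio` (class `split_candidate`), or `NULL` when no admissible
#'   split exists.
#' @export
best_split <- function(X, y, weights = NULL, min_leaf = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n < 2L) return(NULL)
  y <- as.character(y)
  classes <- sort(unique(y))
  if (length(classes) < 2L) return(NULL)
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  yi <- match(y, classes)

  tot_w <- vapply(seq_along(classes), function(c) sum(w[yi == c]), numeric(1))
  h_parent <- entropy(tot_w)

  best <- NULL
  for (j in seq_len(ncol(X))) {
    ord <- order(X[, j])
    xs <- X[ord, j]
    cw <- vapply(seq_along(classes),
                 function(c) cumsum(w[ord] * (yi[ord] == c)),
                 numeric(n))
    if (!is.matrix(cw)) cw <- matrix(cw, nrow = n)
    pos <- which(diff(xs) > 0)
    if (min_leaf > 1L)
      pos <- pos[pos >= min_leaf & (n - pos) >= min_leaf]
    if (length(pos) == 0L) next

    cl <- cw[pos, , drop = FALSE]                 # left class weights
    cr <- matrix(tot_w, length(pos), length(classes), byrow = TRUE) - cl
    wl <- rowSums(cl); wr <- 1 - wl
    # H(side) = -[ (sum_c cw log2 cw)/W - log2 W ]
    hl <- ifelse(wl > 0, -(rowSums(plogp(cl)) / wl - log2(pmax(wl, 1e-300))), 0)
    hr <- ifelse(wr > 0, -(rowSums(plogp(cr)) / wr - log2(pmax(wr, 1e-300))), 0)
    gain <- h_parent - (wl * hl + wr * hr)
    si <- -(plogp(wl) + plogp(wr))
    ok <- gain > 1e-12 & si > 0
    if (!any(ok)) next
    gr <- rep(-Inf, length(pos))
    gr[ok] <- gain[ok] / si[ok]
    # ties (within numerical tolerance) break to the lowest threshold,
    # then to the lowest attribute index
    tol <- 1e-9
    i <- which(gr >= max(gr) - tol)[1]
    if (is.null(best) || gr[i] > best$gain_ratio + tol) {
      best <- structure(list(
        attribute = j,
        threshold = (xs[pos[i]] + xs[pos[i] + 1]) / 2,
        gain = gain[i],
        split_info = si[i],
        gain_ratio = gr[i]), class = "split_candidate")
    }
  }
  best
}

#' Grow a gain-ratio decision tree
#'
#' Recursive partitioning with [best_split()]: internal nodes test
#' `attribute <= threshold` (left) vs `>` (right); recursion stops at node
#' purity, `max_depth`, `min_leaf`, or when no split with positive gain and
#' split information exists. Leaf labels are the weighted majority class,
#' ties broken toward the lexicographically smaller label.
#'
#' @param X numeric matrix (samples x attributes).
#' @param y class labels.
#' @param weights optional sample weights.
#' @param max_depth maximum tree depth (`Inf` = unlimited; 1 = stump).
#' @param min_leaf minimum samples per leaf.
#' @return object of class `gain_ratio_tree`.
#' @export
grow_tree <- function(X, y, weights = NULL, max_depth = Inf, min_leaf = 1L) {
  X <- as.matrix(X)
  n <- nrow(X)
  if (n == 0L) stop("empty training set")
  y <- as.character(y)
  classes <- sort(unique(y))
  w <- weights %||% rep(1, n)
  w <- w / sum(w)
  yi <- match(y, classes)

  make_leaf <- function(idx) {
    cw <- vapply(seq_along(classes),
                 function(c) sum(w[idx][yi[idx] == c]), numeric(1))
    list(leaf = TRUE, label = which.max(cw), probs = cw / sum(cw))
  }
  build <- function(idx, depth) {
    if (length(unique(yi[idx])) == 1L || depth >= max_depth ||
        length(idx) < 2L * min_leaf)
      return(make_leaf(idx))
    s <- best_split(X[idx, , drop = FALSE], y[idx], w[idx], min_leaf)
    if (is.null(s)) return(make_leaf(idx))
    go_left <- X[idx, s$attribute] <= s$threshold
    list(leaf = FALSE, attribute = s$attribute, threshold = s$threshold,
         left = build(idx[go_left], depth + 1L),
         right = build(idx[!go_left], depth + 1L))
  }
  structure(list(node = build(seq_len(n), 0L),
                 classes = classes,
                 feature_names = colnames(X)),
            class = "gain_ratio_tree")
}

#' Predict class labels with a gain-ratio tree
#'
#' @param tree a `gain_ratio_tree`.
#' @param X numeric matrix of samples.
#' @return character vector of predicted labels.
#' @export
predict_tree <- function(tree, X) {
  X <- as.matrix(X)
  out <- integer(nrow(X))
  descend <- function(node, idx) {
    if (length(idx) == 0L) return()
    if (node$leaf) { out[idx] <<- node$label; return() }
    go_left <- X[idx, node$attribute] <= node$threshold
    descend(node$left, idx[go_left])
    descend(node$right, idx[!go_left])
  }
  descend(tree$node, seq_len(nrow(X)))
  tree$classes[out]
}

#' Train a boosted ensemble of gain-ratio trees
#'
#' Discrete AdaBoost: starting from uniform weights, each round grows a base
#' learner on the current weights, computes its weighted error `eps`, gives
#' it stage weight `alpha = 0.5 * log((1 - eps)/eps)` (two classes) or
#' `alpha = log((1 - eps)/eps) + log(n_classes - 1)` (SAMME, multi-class),
#' multiplies the weights of misclassified samples by `exp(alpha)` and
#' renormalises. The loop stops early when a learner is perfect (`eps` is
#' floored at 1e-10 so its alpha stays finite, and the learner is kept) or
#' no better than chance (`eps >= 1 - 1/n_classes`, learner rejected).
#'
#' @param X numeric matrix (samples x features).
#' @param y class labels (2 or 3 classes).
#' @param K maximum boosting rounds (>= 1).
#' @param base `"tree"` (unpruned gain-ratio tree, the boosted-J48
#'   configuration) or `"stump"` (depth-1, classic AdaBoost).
#' @param max_depth depth cap for `base = "tree"` (default unlimited).
#' @param min_leaf minimum samples per leaf.
#' @param positive label of the positive (fall) class for 2-class margins;
#'   defaults to `"fall"` when present, otherwise the lexicographically
#'   largest label.
#' @param seed accepted for interface stability; training is deterministic
#'   (no subsampling), so it has no effect.
#' @return object of class `boosted_ensemble` with fields `alphas`, `trees`,
#'   `classes`, `positive`, `base`.
#' @export
train_boosted <- function(X, y, K = 10L,
                          base = c("tree", "stump"),
                          max_depth = Inf, min_leaf = 1L,
                          positive = NULL, seed = NULL) {
  base <- match.arg(base)
  if (K < 1L) stop("K must be >= 1")
  X <- as.matrix(X)
  y <- as.character(y)
  classes <- sort(unique(y))
  nc <- length(classes)
  if (nc < 2L) stop("training labels contain a single class")
  if (is.null(positive))
    positive <- if ("fall" %in% classes) "fall" else classes[nc]
  depth <- if (base == "stump") 1L else max_depth

  n <- nrow(X)
  w <- rep(1 / n, n)
  alphas <- numeric(0)
  trees <- list()
  for (k in seq_len(K)) {
    tr <- grow_tree(X, y, w, max_depth = depth, min_leaf = min_leaf)
    pred <- predict_tree(tr, X)
    miss <- pred != y
    eps <- sum(w[miss])
    if (eps >= 1 - 1 / nc) {
      if (length(trees) == 0L) {
        warning("first base learner no better than chance; ",
                "keeping it with unit weight")
        alphas <- 1; trees <- list(tr)
      }
      break
    }
    perfect <- eps <= 0
    if (perfect) eps <- 1e-10
    alpha <- if (nc == 2L) 0.5 * log((1 - eps) / eps)
             else log((1 - eps) / eps) + log(nc - 1)
    alphas <- c(alphas, alpha)
    trees <- c(trees, list(tr))
    if (perfect) break
    w <- w * exp(alpha * miss)
    w <- w / sum(w)
  }
  structure(list(alphas = alphas, trees = trees, classes = classes,
                 positive = positive, base = base,
                 feature_names = colnames(X)),
            class = "boosted_ensemble")
}

#' Predict with a boosted ensemble
#'
#' Two classes: the decision is the sign of the alpha-weighted vote
#' `F(x) = sum alpha_k * phi_k(x)` with `phi_k(x)` in `{-1, +1}` (+1 = the
#' positive/fall class); `sign(0)` resolves to the positive class. The
#' signed sum is returned as `margin` and serves as the ROC score.
#' Multi-class: argmax of the alpha-weighted votes per class, ties to the
#' lexicographically smaller label; `margin` is `NA`.
#'
#' @param object a `boosted_ensemble`.
#' @param newdata numeric matrix or data.frame of feature vectors.
#' @param ... unused.
#' @return data.frame with columns `label` and `margin`.
#' @export
predict.boosted_ensemble <- function(object, newdata, ...) {
  X <- as.matrix(newdata)
  n <- nrow(X)
  preds <- vapply(object$trees, function(tr) predict_tree(tr, X), character(n))
  if (!is.matrix(preds)) preds <- matrix(preds, nrow = n)
  if (length(object$classes) == 2L) {
    signs <- ifelse(preds == object$positive, 1, -1)
    margin <- as.numeric(signs %*% object$alphas)
    neg <- setdiff(object$classes, object$positive)
    label <- ifelse(margin >= 0, object$positive, neg)
  } else {
    votes <- matrix(0, n, length(object$classes),
                    dimnames = list(NULL, object$classes))
    for (k in seq_along(object$trees))
      for (cl in object$classes)
        votes[, cl] <- votes[, cl] + object$alphas[k] * (preds[, k] == cl)
    label <- object$classes[max.col(votes, ties.method = "first")]
    margin <- rep(NA_real_, n)
  }
  data.frame(label = label, margin = margin, stringsAsFactors = FALSE)
}

# --- model serialization (JSON) ---------------------------------------------

node_to_list <- function(node) {
  if (node$leaf)
    list(leaf = TRUE, label = node$label, probs = as.list(node$probs))
  else
    list(leaf = FALSE, attribute = node$attribute, threshold = node$threshold,
         left = node_to_list(node$left), right = node_to_list(node$right))
}

node_from_list <- function(lst) {
  if (isTRUE(lst$leaf))
    list(leaf = TRUE, label = as.integer(lst$label),
         probs = as.numeric(unlist(lst$probs)))
  else
    list(leaf = FALSE, attribute = as.integer(lst$attribute),
         threshold = as.numeric(lst$threshold),
         left = node_from_list(lst$left), right = node_from_list(lst$right))
}

#' Write a boosted ensemble to a JSON model file
#'
#' Thresholds and stage weights are stored at full double precision, so a
#' written-and-reloaded model produces bit-identical predictions.
#'
#' @param ensemble a `boosted_ensemble`.
#' @param path output file path.
#' @param metadata optional named list stored verbatim (e.g. window length,
#'   feature names, training provenance).
#' @return `path`, invisibly.
#' @export
write_model <- function(ensemble, path, metadata = list()) {
  obj <- list(
    format = "fallvar-boosted-ensemble",
    version = 1L,
    base = ensemble$base,
    classes = ensemble$classes,
    positive = ensemble$positive,
    feature_names = ensemble$feature_names,
    alphas = ensemble$alphas,
    trees = lapply(ensemble$trees, function(tr) node_to_list(tr$node)),
    metadata = metadata)
  # digits = I(17): full round-trip precision for thresholds and alphas
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = I(17),
                       pretty = TRUE)
  invisible(path)
}

#' Read a boosted ensemble from a JSON model file
#'
#' @param path model file written by [write_model()].
#' @return a `boosted_ensemble` (with the stored metadata attached as
#'   attribute `"metadata"`).
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "fallvar-boosted-ensemble"))
    stop("not a fallvar model file: ", path)
  classes <- as.character(unlist(obj$classes))
  fn <- if (length(obj$feature_names)) as.character(unlist(obj$feature_names))
  trees <- lapply(obj$trees, function(t)
    structure(list(node = node_from_list(t), classes = classes,
                   feature_names = fn),
              class = "gain_ratio_tree"))
  ens <- structure(list(alphas = as.numeric(unlist(obj$alphas)),
                        trees = trees, classes = classes,
                        positive = as.character(obj$positive),
                        base = as.character(obj$base),
                        feature_names = fn),
                   class = "boosted_ensemble")
  attr(ens, "metadata") <- obj$metadata
  ens
}

#' @export
print.boosted_ensemble <- function(x, ...) {
  cat(sprintf("Boosted gain-ratio ensemble (base = %s): %d member(s), classes: %s\n",
              x$base, length(x$trees), paste(x$classes, collapse = ", ")))
  cat(sprintf("  stage weights: %s\n",
              paste(signif(x$alphas, 4), collapse = ", ")))
  invisible(x)
}
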