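# A small, seeded random-forest classifier (CART trees with Gini splits,
# bootstrap resampling, mtry feature subsampling) providing the
# mean-decrease-in-Gini variable importance used by the scenario-discovery
# step. Written in-package because the environment ships no R random-forest
# implementation; the feature set is deliberately minimal (binary or
# multiclass classification, numeric and one-hot-encoded categorical
# predictors, importance and majority-vote prediction).

# ---- feature encoding ----

# data.frame -> numeric matrix; factors/characters become one-hot columns.
# Returns the matrix and a map from columns back to source variables so that
# importances can be re-aggregated per original variable.
encode_features <- function(df) {
  cols <- list(); src <- character()
  for (nm in names(df)) {
    v <- df[[nm]]
    if (is.numeric(v)) {
      cols[[nm]] <- as.numeric(v); src <- c(src, nm)
    } else {
      f <- factor(v)
      for (lv in levels(f)) {
        cn <- paste0(nm, "=", lv)
        cols[[cn]] <- as.numeric(f == lv); src <- c(src, nm)
      }
    }
  }
  list(x = do.call(cbind, cols), source = src)
}

gini_impurity <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

# best Gini split of `idx` on feature column `xf`; returns NULL or
# list(threshold, gain) with gain = n*G(parent) - nl*G(l) - nr*G(r)
best_split_feature <- function(xf, yint, idx, n_class) {
  v <- xf[idx]
  o <- order(v)
  v <- v[o]; yo <- yint[idx][o]
  n <- length(v)
  if (v[1L] == v[n]) return(NULL)
  # cumulative class counts at each prefix
  cum <- matrix(0L, n, n_class)
  cum[cbind(seq_len(n), yo)] <- 1L
  cum <- apply(cum, 2L, cumsum)
  tot <- cum[n, ]
  g_parent <- n * gini_impurity(tot)
  cut_ok <- which(v[-n] < v[-1L])   # splits between distinct values
  if (!length(cut_ok)) return(NULL)
  nl <- cut_ok
  nr <- n - nl
  gl <- nl - rowSums(cum[cut_ok, , drop = FALSE]^2) / nl
  gr <- nr - rowSums((matrix(tot, length(cut_ok), n_class, byrow = TRUE) -
                        cum[cut_ok, , drop = FALSE])^2) / nr
  gain <- g_parent - gl - gr
  b <- which.max(gain)
  if (gain[b] <= 1e-12) return(NULL)
  list(threshold = (v[cut_ok[b]] + v[cut_ok[b] + 1L]) / 2, gain = gain[b])
}

build_tree <- function(x, yint, n_class, boot_idx, mtry, min_node, importance_env) {
  p <- ncol(x)
  n_root <- length(boot_idx)
  feature <- integer(); threshold <- numeric()
  left <- integer(); right <- integer(); pred <- integer()
  new_node <- function() {
    feature[length(feature) + 1L] <<- 0L
    threshold[length(threshold) + 1L] <<- NA_real_
    left[length(left) + 1L] <<- 0L; right[length(right) + 1L] <<- 0L
    pred[length(pred) + 1L] <<- 0L
    length(feature)
  }
  grow <- function(idx) {
    node <- new_node()
    counts <- tabulate(yint[idx], n_class)
    pred[node] <<- which.max(counts)
    if (length(idx) < 2L * min_node || gini_impurity(counts) == 0)
      return(node)
    feats <- sample.int(p, mtry)
    best <- NULL; best_f <- NA_integer_
    for (f in feats) {
      s <- best_split_feature(x[, f], yint, idx, n_class)
      if (!is.null(s) && (is.null(best) || s$gain > best$gain)) {
        best <- s; best_f <- f
      }
    }
    if (is.null(best)) return(node)
    importance_env$imp[best_f] <- importance_env$imp[best_f] +
      best$gain / n_root
    lidx <- idx[x[idx, best_f] <= best$threshold]
    ridx <- idx[x[idx, best_f] > best$threshold]
    feature[node] <<- best_f; threshold[node] <<- best$threshold
    left[node] <<- grow(lidx)
    right[node] <<- grow(ridx)
    node
  }
  grow(boot_idx)
  list(feature = feature, threshold = threshold, left = left, right = right,
       pred = pred)
}

#' Random-forest classifier with Gini importance
#'
#' Fits `ntree` CART trees on bootstrap resamples, each split chosen among
#' `mtry` randomly subsampled feature columns by Gini impurity decrease.
#' Categorical predictors are one-hot encoded; their importance is summed
#' back to the source variable. Reproducible given `seed`.
#'
#' @param data data.frame of predictors (numeric, factor or character).
#' @param y binary or multiclass label (factor, logical or character), with
#'   at least two classes present.
#' @param ntree number of trees.
#' @param mtry features sampled per split; default `floor(sqrt(p))` over
#'   encoded columns.
#' @param min_node minimum node size eligible for splitting.
#' @param seed integer seed.
#' @return object of class `gini_forest` with `importance` (mean decrease in
#'   Gini per original variable, normalized by the bootstrap-root size and
#'   averaged over trees), `trees`, and the encoding map.
#' @export
gini_forest <- function(data, y, ntree = 500L, mtry = NULL, min_node = 5L,
                        seed = 1L) {
  stopifnot(is.data.frame(data), nrow(data) >= 2L)
  yf <- factor(y)
  if (nlevels(yf) < 2L)
    stop("gini_forest: the label has a single class; importance is undefined")
  if (length(yf) != nrow(data))
    stop("gini_forest: label length does not match data")
  enc <- encode_features(data)
  x <- enc$x
  yint <- as.integer(yf)
  n_class <- nlevels(yf)
  p <- ncol(x)
  if (is.null(mtry)) mtry <- max(1L, floor(sqrt(p)))
  mtry <- min(as.integer(mtry), p)
  set.seed(substream_seed(seed, 0L, stream_id("gini_forest")))
  imp_env <- new.env()
  imp_env$imp <- numeric(p)
  trees <- vector("list", ntree)
  n <- nrow(x)
  for (t in seq_len(ntree)) {
    boot <- sample.int(n, n, replace = TRUE)
    trees[[t]] <- build_tree(x, yint, n_class, boot, mtry, min_node, imp_env)
  }
  col_imp <- imp_env$imp / ntree
  importance <- vapply(split(col_imp, enc$source), sum, numeric(1))
  importance <- importance[unique(names(data))]
  structure(list(importance = importance, trees = trees, encoding = enc,
                 classes = levels(yf), ntree = ntree, mtry = mtry,
                 min_node = min_node, seed = seed),
            class = "gini_forest")
}

#' @export
predict.gini_forest <- function(object, newdata, ...) {
  enc <- encode_features(newdata)
  miss <- setdiff(colnames(object$encoding$x), colnames(enc$x))
  x <- enc$x
  for (m in miss) {
    x <- cbind(x, 0)
    colnames(x)[ncol(x)] <- m
  }
  x <- x[, colnames(object$encoding$x), drop = FALSE]
  n <- nrow(x)
  votes <- matrix(0L, n, length(object$classes))
  route <- function(tree, node, idx) {
    if (tree$feature[node] == 0L) {
      votes[cbind(idx, tree$pred[node])] <<- votes[cbind(idx, tree$pred[node])] + 1L
      return(invisible())
    }
    go_l <- x[idx, tree$feature[node]] <= tree$threshold[node]
    if (any(go_l)) route(tree, tree$left[node], idx[go_l])
    if (any(!go_l)) route(tree, tree$right[node], idx[!go_l])
  }
  for (tree in object$trees) route(tree, 1L, seq_len(n))
  factor(object$classes[max.col(votes)], levels = object$classes)
}
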