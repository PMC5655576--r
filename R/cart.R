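# Classification-tree view of the rating data.
#
# A CART fit on the rated scenarios is the diagnostic that exposes the
# non-compensatory structure: when level-3 IGF-I or tumor status
# dominates the decision, those splits surface at the top of the tree
# with (near-)pure S-DA leaves. The tree is grown with rpart -
# binary splits, Gini impurity - with the severity levels treated as
# ordered so every split is of the form {1} vs {2,3} or {1,2} vs {3}.

#' Fit a classification tree to rated scenarios
#'
#' @param levels Level vectors (one row per rated presentation).
#' @param class Observed rating per row (`S`, `M-DA`, `S-DA`).
#' @param min_leaf Minimum observations in a leaf (rpart `minbucket`);
#'   default 20.
#' @return Object of class `activity_cart` wrapping the `rpart` fit.
#' @seealso [cart_top_splits()]
#' @export
fit_cart <- function(levels, class, min_leaf = 20L) {
  m <- as_level_matrix(levels)
  class <- as.character(class)
  if (nrow(m) == 0L) abort_invalid("cannot fit a tree to empty data")
  if (length(class) != nrow(m)) abort_invalid("levels and class sizes disagree")
  if (!all(class %in% RATING_LEVELS)) {
    abort_invalid("class must be one of S, M-DA, S-DA")
  }
  df <- as.data.frame(m)
  df$.class <- factor(class, levels = RATING_LEVELS)
  fit <- rpart::rpart(
    .class ~ igf + tumor + comorbidity + symptoms + qol,
    data = df, method = "class",
    parms = list(split = "gini"),
    control = rpart::rpart.control(
      minbucket = min_leaf, minsplit = 2L * min_leaf,
      cp = 0, xval = 0, maxsurrogate = 0, maxcompete = 0
    )
  )
  structure(list(rpart = fit, min_leaf = as.integer(min_leaf)),
            class = "activity_cart")
}

#' Splits along the leftmost-first spine of a fitted tree
#'
#' Returns the split sequence from the root downwards following the
#' node order of the tree frame, i.e. the root split first. Useful for
#' checking which parameters dominate the decision.
#'
#' @param tree An [fit_cart()] object.
#' @param n Number of top splits to return.
#' @return Data frame with columns `var` (parameter split on) and
#'   `threshold` (levels above go right).
#' @export
cart_top_splits <- function(tree, n = 2L) {
  if (!inherits(tree, "activity_cart")) {
    abort_invalid("`tree` must come from fit_cart()")
  }
  frame <- tree$rpart$frame
  splits_idx <- which(frame$var != "<leaf>")
  if (length(splits_idx) == 0L) {
    return(data.frame(var = character(0), threshold = numeric(0)))
  }
  splits_idx <- utils::head(splits_idx, n)
  sp <- tree$rpart$splits
  # one primary split per internal node, in frame order
  data.frame(
    var = as.character(frame$var[splits_idx]),
    threshold = sp[seq_along(splits_idx), "index"]
  )
}

#' Predict classes from a fitted tree
#'
#' @param object An [fit_cart()] object.
#' @param newdata Level vectors.
#' @param ... Unused.
#' @return Character vector of predicted classes.
#' @export
predict.activity_cart <- function(object, newdata, ...) {
  df <- as.data.frame(as_level_matrix(newdata))
  as.character(predict(object$rpart, df, type = "class"))
}

#' @export
print.activity_cart <- function(x, ...) {
  print(x$rpart)
  invisible(x)
}
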