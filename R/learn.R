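# Threshold re-derivation by axis-aligned recursive partitioning.
#
# The published rule has exactly one cut per feature (RDW and glucose gap),
# so the learner fits a depth-2 partition and extracts the root split plus
# the best second-level split on the other feature. Splits maximize the Gini
# impurity decrease over all midpoints between consecutive sorted unique
# feature values. Genotype-positives are a ~10-15% minority, so by default
# each node's split re-balances the two classes to equal total weight
# ("balanced"); without it the Gini criterion favours trivial splits that
# ignore the minority class.

#' Configuration for the threshold learner
#'
#' @param max_depth Maximum partition depth (the rule extractor uses 2:
#'   one cut per feature).
#' @param min_leaf Minimum number of observations on each side of a split.
#' @param class_weight `"balanced"` re-weights the classes to equal total
#'   weight within the node being split; `"uniform"` uses raw counts.
#' @return A list of class `learner_config`.
#' @export
learner_config <- function(max_depth = 2, min_leaf = 20,
                           class_weight = c("balanced", "uniform")) {
  class_weight <- match.arg(class_weight)
  if (!is.numeric(max_depth) || max_depth < 1) abort_invalid("`max_depth` must be >= 1.")
  if (!is.numeric(min_leaf) || min_leaf < 1) abort_invalid("`min_leaf` must be >= 1.")
  structure(
    list(max_depth = as.integer(max_depth), min_leaf = as.integer(min_leaf),
         class_weight = class_weight),
    class = "learner_config"
  )
}

# Per-observation weights for a node: balanced gives each class total weight
# n/2 within the node; uniform gives every observation weight 1.
node_weights <- function(y, class_weight) {
  n <- length(y)
  if (class_weight == "uniform") {
    return(rep(1, n))
  }
  n_pos <- sum(y)
  n_neg <- n - n_pos
  w <- numeric(n)
  w[y] <- n / (2 * n_pos)
  w[!y] <- n / (2 * n_neg)
  w
}

#' Best axis-aligned split of a single feature
#'
#' Exhaustively evaluates every midpoint between consecutive sorted unique
#' feature values, maximizing the weighted Gini impurity decrease
#' \eqn{\Delta = G(parent) - \frac{W_L}{W} G(L) - \frac{W_R}{W} G(R)}.
#' Ties are broken toward the smaller threshold. A split is returned even if
#' the best impurity decrease is 0 (the caller prunes); `NULL` (a no-split
#' signal) is returned only when the feature is constant or no candidate
#' satisfies `min_leaf`.
#'
#' @param x Numeric feature vector.
#' @param y Logical labels (`TRUE` = positive class).
#' @param weights Optional per-observation weights (default 1).
#' @param min_leaf Minimum observations required on each side.
#' @return `NULL`, or a list with `threshold`, `direction` (`"<="` if the
#'   left side is the positive-enriched side, else `">="`),
#'   `impurity_decrease`, `n_left`, `n_right`.
#' @export
best_split <- function(x, y, weights = NULL, min_leaf = 1) {
  check_numeric_finite(x, "x")
  if (!is.logical(y) || length(y) != length(x)) {
    abort_invalid("`y` must be a logical vector matching `x`.")
  }
  n <- length(x)
  if (is.null(weights)) weights <- rep(1, n)
  ord <- order(x)
  xs <- x[ord]
  ys <- y[ord]
  ws <- weights[ord]

  # candidate boundaries: positions i where xs[i] < xs[i+1]
  boundary <- which(diff(xs) > 0)
  boundary <- boundary[boundary >= min_leaf & (n - boundary) >= min_leaf]
  if (length(boundary) == 0L) {
    return(NULL)
  }

  cum_wp <- cumsum(ws * ys)
  cum_wn <- cumsum(ws * !ys)
  Wp <- cum_wp[n]
  Wn <- cum_wn[n]
  W <- Wp + Wn
  gini <- function(wp, wn) {
    w <- wp + wn
    ifelse(w <= 0, 0, 1 - (wp / w)^2 - (wn / w)^2)
  }
  g_parent <- gini(Wp, Wn)

  wl_p <- cum_wp[boundary]
  wl_n <- cum_wn[boundary]
  wr_p <- Wp - wl_p
  wr_n <- Wn - wl_n
  WL <- wl_p + wl_n
  WR <- wr_p + wr_n
  decrease <- g_parent - (WL / W) * gini(wl_p, wl_n) - (WR / W) * gini(wr_p, wr_n)

  best <- which.max(decrease) # first max = smallest threshold (xs ascending)
  i <- boundary[best]
  list(
    threshold = (xs[i] + xs[i + 1L]) / 2,
    direction = if ((wl_p[best] / WL[best]) >= (wr_p[best] / WR[best])) "<=" else ">=",
    impurity_decrease = decrease[best],
    n_left = i,
    n_right = n - i
  )
}

#' Learn RDW and glucose-gap thresholds by recursive partitioning
#'
#' Fits a depth-2 axis-aligned partition of (RDW, glucose gap) against
#' genotype-positive labels and extracts one threshold per feature: the root
#' split (whichever feature gives the larger impurity decrease) and the best
#' second-level split on the other feature, taken from whichever child yields
#' the larger weight-scaled decrease. The fit is deterministic given the
#' inputs and configuration. The learner reports thresholds for inspection;
#' it does not silently replace the published defaults in
#' [decision_criteria()].
#'
#' @param rdw,gg Numeric feature vectors.
#' @param labels Logical genotype-positive labels; both classes must be
#'   present.
#' @param config A [learner_config()].
#' @return An object of class `g6pd_rule_fit`: a list with `rdw_threshold`,
#'   `rdw_direction`, `gg_threshold`, `gg_direction`, `root_feature`,
#'   `criteria` (a [decision_criteria()] built from the learned cuts), and
#'   the fitted partition used by [predict.g6pd_rule_fit()].
#' @export
learn_rule <- function(rdw, gg, labels, config = learner_config()) {
  check_numeric_finite(rdw, "rdw")
  check_numeric_finite(gg, "gg")
  if (!is.logical(labels) || length(labels) != length(rdw) ||
      length(gg) != length(rdw)) {
    abort_invalid("`rdw`, `gg`, and logical `labels` must have matching lengths.")
  }
  n <- length(labels)
  n_pos <- sum(labels)
  if (n_pos == 0L || n_pos == n) {
    abort_degenerate("both classes must be present to learn thresholds.")
  }
  if (n < 2 * config$min_leaf) {
    abort_invalid(sprintf("need at least %d observations (2 * min_leaf).",
                          2 * config$min_leaf))
  }

  features <- list(rdw = rdw, gg = gg)
  w_root <- node_weights(labels, config$class_weight)
  root_cands <- lapply(features, best_split, y = labels, weights = w_root,
                       min_leaf = config$min_leaf)
  usable <- !vapply(root_cands, is.null, logical(1))
  if (!any(usable)) {
    abort_invalid("no admissible root split (both features constant or min_leaf too large).")
  }
  decreases <- vapply(root_cands, function(s) if (is.null(s)) -Inf else s$impurity_decrease,
                      numeric(1))
  root_feature <- names(features)[which.max(decreases)] # tie -> rdw (first)
  root <- root_cands[[root_feature]]
  other_feature <- setdiff(names(features), root_feature)

  left_idx <- features[[root_feature]] <= root$threshold
  child_split <- function(idx) {
    y <- labels[idx]
    if (sum(idx) < 2 * config$min_leaf || length(unique(y)) < 2L) {
      return(NULL)
    }
    s <- best_split(features[[other_feature]][idx], y,
                    weights = node_weights(y, config$class_weight),
                    min_leaf = config$min_leaf)
    if (!is.null(s)) s$scaled_decrease <- s$impurity_decrease * sum(idx) / n
    s
  }
  child_left <- child_split(left_idx)
  child_right <- child_split(!left_idx)
  second <- NULL
  if (!is.null(child_left) || !is.null(child_right)) {
    dl <- if (is.null(child_left)) -Inf else child_left$scaled_decrease
    dr <- if (is.null(child_right)) -Inf else child_right$scaled_decrease
    second <- if (dl >= dr) child_left else child_right
  }

  thresholds <- stats::setNames(c(NA_real_, NA_real_), c("rdw", "gg"))
  directions <- stats::setNames(c(NA_character_, NA_character_), c("rdw", "gg"))
  thresholds[root_feature] <- root$threshold
  directions[root_feature] <- root$direction
  if (!is.null(second)) {
    thresholds[other_feature] <- second$threshold
    directions[other_feature] <- second$direction
  }

  # Scoring partition: split both children of the root on the other feature,
  # leaves scored by their raw positive fraction.
  leaf_frac <- function(idx) if (sum(idx) == 0L) NA_real_ else mean(labels[idx])
  tree <- list(root_feature = root_feature, root_threshold = root$threshold,
               other_feature = other_feature, children = list())
  for (side in c("left", "right")) {
    idx <- if (side == "left") left_idx else !left_idx
    s <- child_split(idx)
    if (is.null(s)) {
      tree$children[[side]] <- list(threshold = NA_real_, score = leaf_frac(idx))
    } else {
      sub <- features[[other_feature]] <= s$threshold
      tree$children[[side]] <- list(
        threshold = s$threshold,
        score_low = leaf_frac(idx & sub),
        score_high = leaf_frac(idx & !sub)
      )
    }
  }

  criteria <- NULL
  if (!anyNA(thresholds)) {
    criteria <- decision_criteria(rdw_threshold = thresholds[["rdw"]],
                                  gg_threshold = thresholds[["gg"]])
  }
  structure(
    list(
      rdw_threshold = unname(thresholds[["rdw"]]),
      rdw_direction = unname(directions[["rdw"]]),
      gg_threshold = unname(thresholds[["gg"]]),
      gg_direction = unname(directions[["gg"]]),
      root_feature = root_feature,
      root_impurity_decrease = root$impurity_decrease,
      second_impurity_decrease = if (is.null(second)) NA_real_ else second$impurity_decrease,
      criteria = criteria,
      tree = tree,
      config = config,
      n = n,
      n_positive = n_pos
    ),
    class = "g6pd_rule_fit"
  )
}

#' @export
print.g6pd_rule_fit <- function(x, ...) {
  cat("Recursive-partitioning threshold fit\n")
  cat(sprintf("  n = %d (%d genotype-positive)\n", x$n, x$n_positive))
  cat(sprintf("  root: %s, threshold %.3f (Gini decrease %.4f)\n",
              x$root_feature, if (x$root_feature == "rdw") x$rdw_threshold else x$gg_threshold,
              x$root_impurity_decrease))
  cat(sprintf("  learned rule: rdw %s %.3f, gg %s %.3f\n",
              x$rdw_direction, x$rdw_threshold, x$gg_direction, x$gg_threshold))
  invisible(x)
}

#' Leaf-score predictions from a fitted partition
#'
#' Scores new observations by the positive fraction of the depth-2 partition
#' leaf they fall in — the natural continuous score of a recursive-partitioning
#' model, suitable for rank-based AUROC evaluation with [auroc()].
#'
#' @param object A `g6pd_rule_fit` from [learn_rule()].
#' @param rdw,gg Numeric vectors of new observations.
#' @param ... Unused.
#' @return Numeric vector of leaf positive fractions in \[0, 1\].
#' @export
predict.g6pd_rule_fit <- function(object, rdw, gg, ...) {
  check_numeric_finite(rdw, "rdw")
  check_numeric_finite(gg, "gg")
  tree <- object$tree
  root_x <- if (tree$root_feature == "rdw") rdw else gg
  other_x <- if (tree$root_feature == "rdw") gg else rdw
  left <- root_x <= tree$root_threshold
  score <- numeric(length(root_x))
  for (side in c("left", "right")) {
    idx <- if (side == "left") left else !left
    child <- tree$children[[side]]
    if (is.na(child$threshold)) {
      score[idx] <- child$score
    } else {
      low <- other_x <= child$threshold
      score[idx & low] <- child$score_low
      score[idx & !low] <- child$score_high
    }
  }
  score
}
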