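## Retraining machinery: class-weighted recursive partitioning with a
## beam-search lookahead, cost-complexity pruning, grouped Monte Carlo
## cross-validation, and ROC bookkeeping.
##
## The trainer grows a binary tree by weighted-Gini impurity reduction.
## At each node the top `lookahead_alternatives` candidate splits are
## evaluated not only by their immediate impurity but by the impurity of
## a greedy depth-`lookahead_depth` expansion beneath them (a beam of
## width 1 per candidate); the candidate with the lowest lookahead
## impurity wins. Categorical descriptors are handled by ordering their
## levels by weighted hotspot fraction (optimal for binary outcomes).

POS_CLASS <- "hotspot"
NEG_CLASS <- "non-hotspot"

weighted_gini <- function(wpos, wneg) {
  tot <- wpos + wneg
  if (tot <= 0) return(0)
  tot * (1 - (wpos / tot)^2 - (wneg / tot)^2)
}

## Best split of one numeric feature; returns NULL or
## list(param, op="le", value, impurity) (impurity = sum of child Ginis).
best_numeric_split <- function(x, y, w) {
  ok <- !is.na(x)
  x <- x[ok]; y <- y[ok]; w <- w[ok]
  if (length(x) < 2) return(NULL)
  o <- order(x)
  x <- x[o]; y <- y[o]; w <- w[o]
  wpos <- cumsum(w * y)
  wneg <- cumsum(w * (1 - y))
  n <- length(x)
  tp <- wpos[n]; tn <- wneg[n]
  cut_ok <- which(x[-n] < x[-1]) # candidate boundaries between runs
  if (length(cut_ok) == 0) return(NULL)
  lp <- wpos[cut_ok]; ln <- wneg[cut_ok]
  rp <- tp - lp; rn <- tn - ln
  ltot <- lp + ln; rtot <- rp + rn
  imp <- ifelse(ltot > 0, ltot * (1 - (lp / ltot)^2 - (ln / ltot)^2), 0) +
    ifelse(rtot > 0, rtot * (1 - (rp / rtot)^2 - (rn / rtot)^2), 0)
  k <- which.min(imp)
  list(
    op = "le", value = (x[cut_ok[k]] + x[cut_ok[k] + 1]) / 2,
    impurity = imp[k]
  )
}

## Categorical feature: order levels by weighted positive fraction and
## scan prefix subsets; returns list(op="in", value=<level set>, impurity).
best_categorical_split <- function(x, y, w) {
  ok <- !is.na(x)
  x <- as.character(x[ok]); y <- y[ok]; w <- w[ok]
  lv <- unique(x)
  if (length(lv) < 2) return(NULL)
  frac <- vapply(lv, function(l) {
    sel <- x == l
    wp <- sum(w[sel] * y[sel])
    wp / max(sum(w[sel]), 1e-12)
  }, numeric(1))
  lv <- lv[order(frac)]
  wpos_l <- vapply(lv, function(l) sum(w[x == l] * y[x == l]), numeric(1))
  wtot_l <- vapply(lv, function(l) sum(w[x == l]), numeric(1))
  cp <- cumsum(wpos_l); ct <- cumsum(wtot_l)
  tp <- cp[length(lv)]; tt <- ct[length(lv)]
  best <- NULL
  for (k in seq_len(length(lv) - 1)) {
    lp <- cp[k]; ln <- ct[k] - cp[k]
    rp <- tp - lp; rn <- (tt - ct[k]) - rp
    imp <- weighted_gini(lp, ln) + weighted_gini(rp, rn)
    if (is.null(best) || imp < best$impurity) {
      best <- list(op = "in", value = lv[seq_len(k)], impurity = imp)
    }
  }
  best
}

## Top-k candidate splits at a node across all features.
candidate_splits <- function(data, features, y, w, k) {
  cands <- list()
  for (f in features) {
    x <- data[[f]]
    s <- if (is.numeric(x)) {
      best_numeric_split(x, y, w)
    } else {
      best_categorical_split(x, y, w)
    }
    if (!is.null(s)) {
      s$param <- f
      cands[[length(cands) + 1]] <- s
    }
  }
  if (length(cands) == 0) return(list())
  imps <- vapply(cands, function(s) s$impurity, numeric(1))
  cands[order(imps)][seq_len(min(k, length(cands)))]
}

apply_split <- function(data, s) {
  x <- data[[s$param]]
  cond <- if (s$op == "le") {
    !is.na(x) & x <= s$value
  } else {
    !is.na(x) & as.character(x) %in% s$value
  }
  cond
}

## Greedy lookahead rollout: total weighted impurity of the leaves of a
## depth-limited greedy expansion beneath a candidate split.
rollout_impurity <- function(data, features, y, w, depth, min_n) {
  node_imp <- weighted_gini(sum(w * y), sum(w * (1 - y)))
  if (depth <= 0 || length(y) < min_n || node_imp <= 1e-12) {
    return(node_imp)
  }
  s <- candidate_splits(data, features, y, w, 1)
  if (length(s) == 0 || s[[1]]$impurity >= node_imp - 1e-12) {
    return(node_imp)
  }
  cond <- apply_split(data, s[[1]])
  if (all(cond) || !any(cond)) return(node_imp)
  rollout_impurity(data[cond, , drop = FALSE], features, y[cond],
    w[cond], depth - 1, min_n
  ) +
    rollout_impurity(data[!cond, , drop = FALSE], features, y[!cond],
      w[!cond], depth - 1, min_n
    )
}

make_leaf <- function(y, w) {
  wp <- sum(w * y)
  wn <- sum(w * (1 - y))
  cls <- if (wp > wn) POS_CLASS else NEG_CLASS
  prob <- max(wp, wn) / max(wp + wn, 1e-12)
  leaf <- tree_leaf(cls, max(0.5, min(1, prob)))
  # bookkeeping for pruning: weighted misclassification risk and counts
  leaf$risk <- min(wp, wn)
  leaf$n <- length(y)
  leaf
}

grow_tree <- function(data, features, y, w, depth, cfg) {
  node_imp <- weighted_gini(sum(w * y), sum(w * (1 - y)))
  if (depth >= cfg$max_depth || length(y) < cfg$min_n ||
    node_imp <= 1e-12) {
    return(make_leaf(y, w))
  }
  cands <- candidate_splits(data, features, y, w, cfg$alternatives)
  cands <- Filter(function(s) s$impurity < node_imp - 1e-12, cands)
  if (length(cands) == 0) return(make_leaf(y, w))
  # the lookahead arbitrates among candidates whose immediate gain is
  # within tolerance of the best; a clearly superior immediate split
  # stands (deep greedy rollouts are too noisy to overrule it)
  best_imm <- min(vapply(cands, function(s) s$impurity, numeric(1)))
  cands <- Filter(
    function(s) s$impurity <= best_imm + cfg$tie_tol * node_imp, cands
  )
  scores <- vapply(cands, function(s) {
    cond <- apply_split(data, s)
    if (all(cond) || !any(cond)) return(Inf)
    rollout_impurity(data[cond, , drop = FALSE], features, y[cond],
      w[cond], cfg$lookahead - 1, cfg$min_n
    ) +
      rollout_impurity(data[!cond, , drop = FALSE], features, y[!cond],
        w[!cond], cfg$lookahead - 1, cfg$min_n
      )
  }, numeric(1))
  if (all(!is.finite(scores))) return(make_leaf(y, w))
  s <- cands[[which.min(scores)]]
  cond <- apply_split(data, s)
  node <- tree_split(
    s$param, s$op, s$value,
    yes = grow_tree(data[cond, , drop = FALSE], features, y[cond],
      w[cond], depth + 1, cfg
    ),
    no = grow_tree(data[!cond, , drop = FALSE], features, y[!cond],
      w[!cond], depth + 1, cfg
    )
  )
  node$risk <- min(sum(w * y), sum(w * (1 - y)))
  node$n <- length(y)
  node
}

## ---- cost-complexity pruning ----

subtree_stats <- function(node) {
  if (node$type == "leaf") {
    list(risk = node$risk, leaves = 1L)
  } else {
    a <- subtree_stats(node$yes)
    b <- subtree_stats(node$no)
    list(risk = a$risk + b$risk, leaves = a$leaves + b$leaves)
  }
}

## weakest link: the internal node with the smallest per-leaf risk gain.
weakest_link <- function(node, path = integer(0)) {
  if (node$type == "leaf") return(NULL)
  st <- subtree_stats(node)
  g <- (node$risk - st$risk) / max(st$leaves - 1L, 1L)
  best <- list(g = g, path = path)
  for (side in c("yes", "no")) {
    cand <- weakest_link(node[[side]],
      c(path, if (side == "yes") 1L else 2L)
    )
    if (!is.null(cand) && cand$g < best$g) best <- cand
  }
  best
}

collapse_at <- function(node, path) {
  if (length(path) == 0) {
    return(node$as_leaf)
  }
  side <- if (path[1] == 1L) "yes" else "no"
  node[[side]] <- collapse_at(node[[side]], path[-1])
  node
}

## Annotate every internal node with the leaf it would collapse to.
store_collapse_leaves <- function(node, y, w, data, features) {
  if (node$type == "leaf") return(node)
  node$as_leaf <- make_leaf(y, w)
  cond <- apply_split(data, node)
  node$yes <- store_collapse_leaves(node$yes, y[cond], w[cond],
    data[cond, ], features
  )
  node$no <- store_collapse_leaves(node$no, y[!cond], w[!cond],
    data[!cond, ], features
  )
  node
}

prune_to_level <- function(root, level) {
  if (level <= 1 || root$type == "leaf") return(root)
  for (i in seq_len(level - 1)) {
    if (root$type == "leaf") break
    wl <- weakest_link(root)
    root <- collapse_at(root, wl$path)
  }
  root
}

#' Train a class-weighted lookahead decision tree
#'
#' Grows a binary recursive-partitioning tree over numeric and categorical
#' descriptors using weighted Gini impurity, with a lookahead: the top
#' `lookahead_alternatives` candidate splits at each node are compared by
#' the impurity of a greedy expansion `lookahead_depth` levels deep, not
#' just by their immediate gain. The grown tree is then reduced by
#' cost-complexity (weakest-link) pruning; `pruning_level` selects the
#' n-th tree in the pruning sequence (1 = unpruned).
#'
#' Class weights default to the inverse class frequency, which re-balances
#' the strongly skewed hotspot/non-hotspot data.
#'
#' @param data A data frame of descriptors plus a label column.
#' @param label_col Name of the label column (values `"hotspot"` /
#'   `"non-hotspot"`, or logical).
#' @param features Descriptor columns to consider; default: all numeric
#'   and character/factor columns except labels and bookkeeping ids.
#' @param class_weights `"inverse"` (inverse class frequency), or a named
#'   numeric vector `c(hotspot = , "non-hotspot" = )`.
#' @param lookahead_depth,lookahead_alternatives Lookahead depth and beam
#'   width (published settings: 4 and 7).
#' @param pruning_level Position in the pruning sequence (published: 4).
#' @param min_n Minimum rows to attempt a split.
#' @param max_depth Maximum tree depth.
#' @return An `fv_tree` (with `$unpruned` kept as an attribute-like field
#'   for inspection).
#' @export
train_tree <- function(data, label_col = "label", features = NULL,
                       class_weights = "inverse", lookahead_depth = 4,
                       lookahead_alternatives = 7, pruning_level = 4,
                       min_n = 5, max_depth = 10) {
  data <- as_tibble(data)
  lab <- data[[label_col]]
  if (is.logical(lab)) lab <- ifelse(lab, POS_CLASS, NEG_CLASS)
  y <- as.integer(lab == POS_CLASS)
  if (length(unique(y)) < 2) {
    warn("single-class dataset: returning a single-leaf tree")
    leaf <- make_leaf(y, rep(1, length(y)))
    return(new_fv_tree(leaf, aa = "any", name = "trained"))
  }
  if (is.null(features)) {
    drop <- c(
      label_col, "group_id", "name", "model_index", "ordinal", "resno",
      "is_terminal", "open_n", "open_c", "motif"
    )
    features <- setdiff(names(data), drop)
    keep <- vapply(features, function(f) {
      is.numeric(data[[f]]) || is.character(data[[f]]) ||
        is.factor(data[[f]])
    }, logical(1))
    features <- features[keep]
  }
  if (identical(class_weights, "inverse")) {
    freq <- c(mean(y == 1), mean(y == 0))
    class_weights <- c(1 / freq[1], 1 / freq[2])
    names(class_weights) <- c(POS_CLASS, NEG_CLASS)
  }
  w <- ifelse(y == 1, class_weights[[POS_CLASS]],
    class_weights[[NEG_CLASS]]
  )
  cfg <- list(
    alternatives = lookahead_alternatives, lookahead = lookahead_depth,
    min_n = min_n, max_depth = max_depth, tie_tol = 0.05
  )
  df <- as.data.frame(data[, features, drop = FALSE])
  root <- grow_tree(df, features, y, w, 0L, cfg)
  root <- store_collapse_leaves(root, y, w, df, features)
  pruned <- prune_to_level(root, pruning_level)
  tree <- new_fv_tree(pruned, aa = "any", name = "trained")
  tree$unpruned <- new_fv_tree(root, aa = "any", name = "trained_full")
  tree$features <- features
  tree$class_weights <- class_weights
  tree
}

#' ROC coordinates from confusion counts
#'
#' @param tp,p True positives and total positives.
#' @param fp,n False positives and total negatives.
#' @return A one-row tibble `tpr`, `fpr` (`NA` when a denominator is 0).
#' @export
roc_point <- function(tp, p, fp, n) {
  tibble(
    tpr = if (p > 0) tp / p else NA_real_,
    fpr = if (n > 0) fp / n else NA_real_
  )
}

#' Hotspot class balance of a labelled dataset
#'
#' Fraction of hotspot residues at the ensemble-group level, as a
#' percentage (each group of up to five ensemble members counts once).
#'
#' @param data Data frame with `group_id` and `label` columns.
#' @return Percentage of hotspot groups.
#' @export
class_balance <- function(data) {
  g <- distinct(as_tibble(data), .data$group_id, .data$label)
  100 * mean(g$label == POS_CLASS)
}

#' Grouped Monte Carlo cross-validation
#'
#' Repeatedly samples a random train fraction of the *groups* (ensembles
#' stay together), trains a classifier, and evaluates residue-level
#' confusion counts on the held-out groups after applying the
#' at-least-one-member aggregation rule. Repeats in which a class is
#' absent from the training split are resampled (with a message).
#'
#' @param data Labelled descriptor data with `group_id` and `label`.
#' @param n_repeats Number of random splits (published protocol: 40).
#' @param train_fraction Fraction of groups in training (published: 0.75).
#' @param trainer `function(train_data) -> fv_tree`; default trains with
#'   [train_tree()] defaults.
#' @param seed Integer seed for reproducible splits.
#' @return An `fv_cv` object: tibble of per-repeat counts (`tp`, `fn`,
#'   `fp`, `tn`, `tpr`, `fpr`) with the mean row available via
#'   [glance.fv_cv()].
#' @export
monte_carlo_cv <- function(data, n_repeats = 40, train_fraction = 0.75,
                           trainer = NULL, seed = 1) {
  data <- as_tibble(data)
  if (is.null(trainer)) trainer <- function(d) train_tree(d)
  set.seed(seed)
  groups <- distinct(data, .data$group_id, .data$label)
  n_train <- max(1, round(train_fraction * nrow(groups)))
  res <- list()
  for (r in seq_len(n_repeats)) {
    repeat {
      tr_groups <- sample(groups$group_id, n_train)
      tr <- filter(data, .data$group_id %in% tr_groups)
      if (length(unique(tr$label)) == 2) break
      inform("resampling a split that left one class empty in training")
    }
    te <- filter(data, !.data$group_id %in% tr_groups)
    if (nrow(te) == 0) next
    tree <- trainer(tr)
    # residue-level evaluation with the >=1-member rule
    te_groups <- distinct(te, .data$group_id, .data$label)
    calls <- vapply(te_groups$group_id, function(g) {
      rows <- filter(te, .data$group_id == g)
      member <- vapply(seq_len(nrow(rows)), function(k) {
        classify_residue(rows[k, ], tree)$class
      }, character(1))
      if (any(member == POS_CLASS)) POS_CLASS else NEG_CLASS
    }, character(1))
    truth <- te_groups$label
    tp <- sum(calls == POS_CLASS & truth == POS_CLASS)
    fn <- sum(calls == NEG_CLASS & truth == POS_CLASS)
    fp <- sum(calls == POS_CLASS & truth == NEG_CLASS)
    tn <- sum(calls == NEG_CLASS & truth == NEG_CLASS)
    rp <- roc_point(tp, tp + fn, fp, fp + tn)
    res[[r]] <- tibble(
      repeat_id = r, tp = tp, fn = fn, fp = fp, tn = tn,
      tpr = rp$tpr, fpr = rp$fpr
    )
  }
  out <- bind_rows(res)
  structure(list(repeats = out, n_repeats = n_repeats,
    train_fraction = train_fraction, seed = seed), class = "fv_cv")
}

#' @export
print.fv_cv <- function(x, ...) {
  g <- glance(x)
  cat(
    "<fv_cv> ", nrow(x$repeats), " repeats: mean TPR ",
    round(g$tpr_mean, 3), ", mean FPR ", round(g$fpr_mean, 3), "\n",
    sep = ""
  )
  invisible(x)
}

#' Per-repeat cross-validation results
#'
#' @param x An `fv_cv`.
#' @param ... Unused.
#' @return Tibble with one row per repeat (`tp`, `fn`, `fp`, `tn`, `tpr`,
#'   `fpr`).
#' @export
tidy.fv_cv <- function(x, ...) x$repeats

#' One-row cross-validation summary
#'
#' Mean confusion counts across repeats and the ROC point they imply
#' (mean true positives over mean positives, as in the published
#' averaged-count reporting), plus the SD of the per-repeat rates.
#'
#' @param x An `fv_cv`.
#' @param ... Unused.
#' @return One-row tibble.
#' @export
glance.fv_cv <- function(x, ...) {
  r <- x$repeats
  mean_rp <- roc_point(
    mean(r$tp), mean(r$tp + r$fn), mean(r$fp), mean(r$fp + r$tn)
  )
  tibble(
    n_repeats = nrow(r),
    tp_mean = mean(r$tp), fn_mean = mean(r$fn),
    fp_mean = mean(r$fp), tn_mean = mean(r$tn),
    tpr_mean = mean_rp$tpr, fpr_mean = mean_rp$fpr,
    tpr_sd = sd(r$tpr), fpr_sd = sd(r$fpr)
  )
}

#' ROC-style plot of cross-validation repeats
#'
#' @param object An `fv_cv`.
#' @param ... Unused.
#' @return A ggplot: per-repeat (FPR, TPR) points with the mean marked.
#' @export
autoplot.fv_cv <- function(object, ...) {
  r <- object$repeats
  g <- glance(object)
  ggplot2::ggplot(r, ggplot2::aes(x = .data$fpr, y = .data$tpr)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::annotate("point",
      x = g$fpr_mean, y = g$tpr_mean,
      colour = "red", size = 3, shape = 17
    ) +
    ggplot2::coord_cartesian(xlim = c(0, 1), ylim = c(0, 1)) +
    ggplot2::labs(
      x = "false positive rate", y = "true positive rate",
      title = "Monte Carlo cross-validation (mean in red)"
    ) +
    ggplot2::theme_minimal()
}
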