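# A small low-cost trainer configuration for CV tests.
fast_trainer <- function(d) {
  train_tree(d, lookahead_depth = 1, lookahead_alternatives = 1,
    pruning_level = 1, max_depth = 4)
}

sep_dataset <- function(n = 60, seed = 1) {
  # perfectly separable 1-D problem: hotspot iff x > 5
  set.seed(seed)
  x <- c(runif(n / 2, 0, 4.5), runif(n / 2, 5.5, 10))
  tibble::tibble(
    x = x,
    label = ifelse(x > 5, "hotspot", "non-hotspot"),
    group_id = seq_len(n)
  )
}

test_that("a separable 1-D dataset yields one split in the margin", {
  d <- sep_dataset()
  tr <- train_tree(d, features = "x", pruning_level = 1)
  expect_equal(tr$root$param, "x")
  expect_gt(tr$root$value, 4.5)
  expect_lt(tr$root$value, 5.5)
  expect_equal(tr$root$yes$type, "leaf")
  expect_equal(tr$root$no$type, "leaf")
  # rpart as an independent cross-check on the same data
  rp <- rpart::rpart(factor(label) ~ x, data = d,
    control = rpart::rpart.control(minsplit = 5, cp = 0.01)
  )
  rp_cut <- rp$splits[1, "index"]
  expect_gt(rp_cut, 4.5)
  expect_lt(rp_cut, 5.5)
})

test_that("single-class data gives a single-leaf tree with a warning", {
  d <- tibble::tibble(
    x = 1:10, label = rep("non-hotspot", 10), group_id = 1:10
  )
  expect_warning(tr <- train_tree(d, features = "x"), "single-class")
  expect_equal(tr$root$type, "leaf")
})

test_that("training is reproducible and deterministic", {
  d <- simulate_labelled_dataset(60, rule_tree = published_asp_tree(),
    noise = 0.05, seed = 21)
  t1 <- train_tree(d, lookahead_depth = 2, lookahead_alternatives = 3,
    pruning_level = 2)
  t2 <- train_tree(d, lookahead_depth = 2, lookahead_alternatives = 3,
    pruning_level = 2)
  expect_equal(tidy(t1), tidy(t2))
})

test_that("pruning yields subtrees with monotone size", {
  d <- simulate_labelled_dataset(80, rule_tree = published_asp_tree(),
    noise = 0.1, seed = 5)
  sizes <- vapply(c(1, 2, 4, 99), function(lvl) {
    tr <- train_tree(d, lookahead_depth = 1, lookahead_alternatives = 1,
      pruning_level = lvl)
    nrow(tidy(tr))
  }, numeric(1))
  expect_true(all(diff(sizes) <= 0))
  expect_equal(sizes[4], 1) # maximal pruning reaches the root
  # a pruned tree is a subtree of the unpruned one: every pruned split
  # (param, value) appears in the unpruned split set
  tr4 <- train_tree(d, lookahead_depth = 1, lookahead_alternatives = 1,
    pruning_level = 3)
  full <- tidy(tr4$unpruned)
  pruned <- tidy(tr4)
  full_splits <- paste(full$param, vapply(full$value, function(v) {
    paste(v, collapse = ",")
  }, character(1)))
  pruned_splits <- paste(pruned$param, vapply(pruned$value, function(v) {
    paste(v, collapse = ",")
  }, character(1)))
  expect_true(all(pruned_splits[pruned$type == "split"] %in%
    full_splits[full$type == "split"]))
})

test_that("k-fold duplication of the minority class equals inverse weighting", {
  set.seed(8)
  n_pos <- 10
  n_neg <- 40 # ratio 4: duplicate positives 4x
  d <- tibble::tibble(
    x = c(rnorm(n_pos, 7), rnorm(n_neg, 3)),
    z = rnorm(n_pos + n_neg),
    label = c(rep("hotspot", n_pos), rep("non-hotspot", n_neg)),
    group_id = seq_len(n_pos + n_neg)
  )
  dup <- dplyr::bind_rows(d, d[rep(1:n_pos, 3), ])
  t_w <- train_tree(d, features = c("x", "z"), class_weights = "inverse",
    lookahead_depth = 1, lookahead_alternatives = 1, pruning_level = 1)
  t_d <- train_tree(dup, features = c("x", "z"),
    class_weights = c("hotspot" = 1, "non-hotspot" = 1),
    lookahead_depth = 1, lookahead_alternatives = 1, pruning_level = 1)
  expect_equal(t_w$root$param, t_d$root$param)
  expect_equal(t_w$root$value, t_d$root$value, tolerance = 1e-9)
})

test_that("roc_point reproduces the averaged-count worked examples", {
  expect_equal(round(roc_point(7.5, 8, 6.6, 285)$tpr, 2), 0.94)
  expect_equal(round(roc_point(7.5, 8, 6.6, 285)$fpr, 2), 0.02)
  expect_equal(round(roc_point(11 - 0.6, 11, 8.1, 188)$tpr, 2), 0.95)
  expect_equal(round(roc_point(11 - 0.6, 11, 8.1, 188)$fpr, 2), 0.04)
  expect_equal(roc_point(0, 8, 0, 285), tibble::tibble(tpr = 0, fpr = 0))
  expect_true(is.na(roc_point(0, 0, 1, 10)$tpr))
})

test_that("class_balance reproduces the dataset compositions", {
  asp <- tibble::tibble(
    group_id = 1:1465,
    label = c(rep("hotspot", 40), rep("non-hotspot", 1425))
  )
  expect_equal(round(class_balance(asp), 1), 2.7)
  asn <- tibble::tibble(
    group_id = 1:995,
    label = c(rep("hotspot", 55), rep("non-hotspot", 940))
  )
  expect_equal(round(class_balance(asn), 1), 5.5)
  even <- tibble::tibble(group_id = 1:2, label = c("hotspot", "non-hotspot"))
  expect_equal(class_balance(even), 50)
  # rows of one group count once
  asp5 <- asp[rep(1:1465, each = 5), ]
  expect_equal(class_balance(asp5), class_balance(asp))
})

test_that("grouped CV never splits a group across train and test", {
  d <- simulate_labelled_dataset(40, rule_tree = published_asp_tree(),
    seed = 3)
  seen <- new.env()
  spy_trainer <- function(train) {
    key <- paste(sort(unique(train$group_id)), collapse = ",")
    assign(paste0("k", length(ls(seen))), list(
      train_groups = unique(train$group_id)
    ), envir = seen)
    fast_trainer(train)
  }
  cv <- monte_carlo_cv(d, n_repeats = 5, trainer = spy_trainer, seed = 2)
  expect_equal(nrow(tidy(cv)), 5)
  for (nm in ls(seen)) {
    tr_groups <- get(nm, envir = seen)$train_groups
    # per repeat: groups in train have all 5 rows in train
    n_rows <- table(d$group_id[d$group_id %in% tr_groups])
    expect_true(all(n_rows == 5))
  }
  # confusion counts partition the held-out groups
  r <- tidy(cv)
  expect_true(all(r$tp + r$fn + r$fp + r$tn == 10)) # 25% of 40 groups
})

test_that("CV of a constant non-hotspot classifier gives TPR 0, FPR 0", {
  d <- simulate_labelled_dataset(30, rule_tree = published_asp_tree(),
    seed = 6)
  const_trainer <- function(train) {
    fvhotspots:::new_fv_tree(
      fvhotspots:::tree_leaf("non-hotspot", 1), "any", "const"
    )
  }
  cv <- monte_carlo_cv(d, n_repeats = 3, trainer = const_trainer, seed = 1)
  g <- glance(cv)
  expect_equal(g$tpr_mean, 0)
  expect_equal(g$fpr_mean, 0)
})

test_that("separable data cross-validates to TPR 1, FPR 0", {
  d <- sep_dataset(n = 80, seed = 2)
  trainer <- function(train) train_tree(train, features = "x",
    lookahead_depth = 1, lookahead_alternatives = 1, pruning_level = 1)
  cv <- monte_carlo_cv(d, n_repeats = 10, trainer = trainer, seed = 3)
  g <- glance(cv)
  expect_equal(g$tpr_mean, 1)
  expect_equal(g$fpr_mean, 0)
  # identical seeds give identical splits
  cv2 <- monte_carlo_cv(d, n_repeats = 10, trainer = trainer, seed = 3)
  expect_equal(tidy(cv2), tidy(cv))
})

test_that("cv tidiers and autoplot expose the repeat table", {
  d <- sep_dataset(n = 40, seed = 5)
  cv <- monte_carlo_cv(d, n_repeats = 4, trainer = fast_trainer, seed = 1)
  expect_s3_class(tidy(cv), "tbl_df")
  expect_named(
    glance(cv),
    c("n_repeats", "tp_mean", "fn_mean", "fp_mean", "tn_mean",
      "tpr_mean", "fpr_mean", "tpr_sd", "fpr_sd")
  )
  p <- autoplot(cv)
  expect_s3_class(p, "ggplot")
})
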