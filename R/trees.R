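## Decision-tree representation shared by the published classifiers and
## the trainer. A tree is a recursive list of nodes:
##   split node: list(type="split", param, op ("le"|"gt"|"lt"|"in"),
##               value (threshold or category set), yes, no)
##   leaf:       list(type="leaf", class ("hotspot"|"non-hotspot"),
##               prob (majority-class probability in [0.5, 1]),
##               hotspot_class (1-3 or NA))
## The `yes` child is taken when the condition holds.

tree_split <- function(param, op, value, yes, no) {
  stopifnot(op %in% c("le", "lt", "gt", "in"))
  list(type = "split", param = param, op = op, value = value,
    yes = yes, no = no)
}

tree_leaf <- function(class, prob = 1.0, hotspot_class = NA_integer_) {
  stopifnot(class %in% c("hotspot", "non-hotspot"), prob >= 0.5, prob <= 1)
  list(type = "leaf", class = class, prob = prob,
    hotspot_class = as.integer(hotspot_class))
}

new_fv_tree <- function(root, aa, name) {
  structure(list(root = root, aa = aa, name = name), class = "fv_tree")
}

## Thresholds the published narrative leaves open, with their admissible
## intervals. The large-successor cuts must fall between the successor
## sizes of the last "small" and first "large" amino-acid type:
##   Asp tree: between Asp (110.21) and Pro (111.53)  -> 110.9
##   Asn tree: between Asn (113.19) and Val (124.24)  -> 118.7
ASP_SUCCESSOR_CUT <- 110.9
ASN_SUCCESSOR_BIG_CUT <- 118.7

#' The published aspartate isomerization decision tree
#'
#' Encodes the published Asp classifier: inflexible residues
#' (RMSD <= 0.145) and residues with a large successor are non-hotspots;
#' among flexible residues with a small successor (Gly/Ala/Ser/Cys/Asp),
#' very high flexibility (RMSD > 0.485) gives hotspot class 1; moderate
#' flexibility with a change in C-terminal secondary structure within
#' fewer than 3 residues gives class 2; otherwise an Asp-Gly motif gives
#' class 3, and everything else is a non-hotspot. Leaf probabilities are
#' the residue-count purities of the published leaf compositions (class 1:
#' 5/7, class 2: 3/3, class 3: 2/3); unreported leaves carry 1.0.
#'
#' @return An `fv_tree`.
#' @export
published_asp_tree <- function() {
  root <- tree_split(
    "rmsd", "le", 0.145,
    yes = tree_leaf("non-hotspot", 1.0),
    no = tree_split(
      "successor_size", "gt", ASP_SUCCESSOR_CUT,
      yes = tree_leaf("non-hotspot", 1.0),
      no = tree_split(
        "rmsd", "gt", 0.485,
        yes = tree_leaf("hotspot", 5 / 7, 1L),
        no = tree_split(
          "next_diff_ss_c", "lt", 3,
          yes = tree_leaf("hotspot", 1.0, 2L),
          no = tree_split(
            "succ_aa", "in", "G",
            yes = tree_leaf("hotspot", 2 / 3, 3L),
            no = tree_leaf("non-hotspot", 1.0)
          )
        )
      )
    )
  )
  new_fv_tree(root, aa = "D", name = "published_asp")
}

#' The published asparagine deamidation decision tree
#'
#' Encodes the published Asn classifier: residues with a big successor
#' (successor size > 118.7, i.e. anything larger than Asn itself) or
#' inflexible residues (RMSD <= 0.01) are non-hotspots. Flexible residues
#' with successor size above 102.7 (Asp/Pro/Thr/Asn successors) are
#' hotspot class 1 when located in CDR loop 1. Residues with successor
#' size at most 102.7 (Gly/Ala/Ser/Cys) are class 2 when phi < -75.2
#' degrees, and class 3 when phi >= -75.2 with high solvent exposure
#' (SASA > 89.4) and a change in N-terminal secondary structure more than
#' 3 residues away. Leaf probabilities from the published compositions:
#' class 1 3/3, class 2 6/10, class 3 4/6.
#'
#' @return An `fv_tree`.
#' @export
published_asn_tree <- function() {
  root <- tree_split(
    "successor_size", "gt", ASN_SUCCESSOR_BIG_CUT,
    yes = tree_leaf("non-hotspot", 1.0),
    no = tree_split(
      "rmsd", "le", 0.01,
      yes = tree_leaf("non-hotspot", 1.0),
      no = tree_split(
        "successor_size", "gt", 102.7,
        yes = tree_split(
          "cdr_loop", "in", 1,
          yes = tree_leaf("hotspot", 1.0, 1L),
          no = tree_leaf("non-hotspot", 1.0)
        ),
        no = tree_split(
          "phi", "lt", -75.2,
          yes = tree_leaf("hotspot", 6 / 10, 2L),
          no = tree_split(
            "res_sasa", "gt", 89.4,
            yes = tree_split(
              "next_diff_ss_n", "gt", 3,
              yes = tree_leaf("hotspot", 4 / 6, 3L),
              no = tree_leaf("non-hotspot", 1.0)
            ),
            no = tree_leaf("non-hotspot", 1.0)
          )
        )
      )
    )
  )
  new_fv_tree(root, aa = "N", name = "published_asn")
}

split_condition <- function(node, value) {
  switch(node$op,
    le = value <= node$value,
    lt = value < node$value,
    gt = value > node$value,
    `in` = value %in% node$value
  )
}

#' Classify one descriptor vector with a decision tree
#'
#' Deterministic leaf assignment. Every split parameter used on the path
#' must be present and non-missing; a missing value raises an error naming
#' the field.
#'
#' @param vector A named list or one-row data frame of descriptor values.
#' @param tree An `fv_tree` ([published_asp_tree()], [published_asn_tree()]
#'   or a trained tree).
#' @return A list `class`, `prob` (majority-class probability at the
#'   leaf), `hotspot_class` (1-3 or `NA`), `p_hotspot` (probability of the
#'   hotspot class: `prob` at a hotspot leaf, `1 - prob` otherwise).
#' @export
classify_residue <- function(vector, tree) {
  if (is.data.frame(vector)) vector <- as.list(vector[1, ])
  node <- tree$root
  while (node$type == "split") {
    v <- vector[[node$param]]
    if (is.null(v) || length(v) == 0 || is.na(v)) {
      abort(paste0(
        "missing value for split parameter '", node$param, "'"
      ))
    }
    node <- if (split_condition(node, v)) node$yes else node$no
  }
  p_hot <- if (node$class == "hotspot") node$prob else 1 - node$prob
  list(
    class = node$class, prob = node$prob,
    hotspot_class = node$hotspot_class, p_hotspot = p_hot
  )
}

## Flat node table of a tree (depth-first), used by tidy() and JSON IO.
flatten_tree <- function(node, id = 1L, depth = 0L) {
  if (node$type == "leaf") {
    return(tibble(
      id = id, depth = depth, type = "leaf", param = NA_character_,
      op = NA_character_, value = list(NULL), class = node$class,
      prob = node$prob, hotspot_class = node$hotspot_class,
      yes = NA_integer_, no = NA_integer_
    ))
  }
  yes_tb <- flatten_tree(node$yes, id + 1L, depth + 1L)
  no_tb <- flatten_tree(node$no, max(yes_tb$id) + 1L, depth + 1L)
  bind_rows(
    tibble(
      id = id, depth = depth, type = "split", param = node$param,
      op = node$op, value = list(node$value), class = NA_character_,
      prob = NA_real_, hotspot_class = NA_integer_,
      yes = id + 1L, no = max(yes_tb$id) + 1L
    ),
    yes_tb, no_tb
  )
}

#' @export
print.fv_tree <- function(x, ...) {
  cat("<fv_tree> ", x$name, " (", x$aa, ")\n", sep = "")
  show <- function(node, indent) {
    pad <- strrep("  ", indent)
    if (node$type == "leaf") {
      cat(pad, "* ", node$class,
        if (!is.na(node$hotspot_class)) paste0(" [class ", node$hotspot_class, "]"),
        " p=", round(node$prob, 3), "\n",
        sep = ""
      )
    } else {
      op <- c(le = "<=", lt = "<", gt = ">", `in` = "in")[node$op]
      cat(pad, node$param, " ", op, " ",
        paste(node$value, collapse = ","), "?\n",
        sep = ""
      )
      show(node$yes, indent + 1)
      show(node$no, indent + 1)
    }
  }
  show(x$root, 1)
  invisible(x)
}

#' Tidy a decision tree into a node table
#'
#' @param x An `fv_tree`.
#' @param ... Unused.
#' @return A tibble with one row per node (`id`, `depth`, `type`, `param`,
#'   `op`, `value` list-column, leaf `class`/`prob`/`hotspot_class`, child
#'   ids `yes`/`no`).
#' @export
tidy.fv_tree <- function(x, ...) {
  flatten_tree(x$root)
}

## ---- JSON serialization (schema mirrors the node structure) ----

node_to_list <- function(node) {
  if (node$type == "leaf") {
    out <- list(type = "leaf", class = node$class, prob = node$prob)
    if (!is.na(node$hotspot_class)) out$hotspot_class <- node$hotspot_class
    out
  } else {
    list(
      type = "split", param = node$param, op = node$op,
      value = as.list(node$value),
      yes = node_to_list(node$yes), no = node_to_list(node$no)
    )
  }
}

list_to_node <- function(lst) {
  if (lst$type == "leaf") {
    hc <- lst$hotspot_class
    if (is.null(hc) || length(hc) == 0) hc <- NA_integer_
    tree_leaf(lst$class, lst$prob, hc)
  } else {
    value <- unlist(lst$value)
    tree_split(
      lst$param, lst$op, value,
      yes = list_to_node(lst$yes), no = list_to_node(lst$no)
    )
  }
}

#' Serialize / load a decision tree as JSON
#'
#' Trained and published trees share one JSON schema, so trees written by
#' the trainer can be re-loaded and applied by the classifier.
#'
#' @param tree An `fv_tree`.
#' @param path File path.
#' @return `path` invisibly (writer); an `fv_tree` (reader).
#' @export
write_tree_json <- function(tree, path) {
  obj <- list(name = tree$name, aa = tree$aa, root = node_to_list(tree$root))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_tree_json
#' @export
read_tree_json <- function(path) {
  obj <- jsonlite::read_json(path)
  new_fv_tree(list_to_node(obj$root), aa = obj$aa, name = obj$name)
}
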