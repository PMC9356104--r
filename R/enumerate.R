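# Redundancy-free enumeration of operator configurations, and stochastic
# sampling of random configurations.
#
# The enumerator realises the count N(p,k) = p (3p-2)^(k-2) constructively.
# A tree over regulators g1..gk is encoded by a choice vector: one of p
# operators for the initial pair (g1, g2), then for each further regulator
# g_j one of 3p-2 extensions of the current tree (root operator o):
#   * join at the root with operator o'       (p ways; o' = o is the
#     associative flatten, appending g_j to the root run, and keeps the tree
#     maximally left-heavy),
#   * pair g_j with the root's left subtree via o' != o   (p-1 ways),
#   * pair g_j with the root's right subtree via o' != o  (p-1 ways).
# All extensions of all distinct trees yield canonically distinct trees, so
# the enumeration is duplicate-free and its size is exactly the closed form.
# Mirror images are never generated: the new leaf always sits on the right.
# The all-zero choice vector is the maximally left-heavy tree, and the choice
# for the outermost (root-level) join varies fastest, so cheap operator
# changes near the root come before deep rearrangements.

.tree_from_choices <- function(regulators, opnames, choices) {
  k <- length(regulators)
  p <- length(opnames)
  if (k == 1) return(tree_leaf(regulators[1]))
  tree <- tree_node(opnames[choices[1] + 1L],
                    tree_leaf(regulators[1]), tree_leaf(regulators[2]))
  if (k == 2) return(tree)
  for (j in 3:k) {
    c <- choices[j - 1L]
    g <- tree_leaf(regulators[j])
    o <- tree$op
    others <- setdiff(opnames, o)
    if (c < p) {
      tree <- tree_node(opnames[c + 1L], tree, g)
    } else if (c < p + (p - 1L)) {
      o2 <- others[c - p + 1L]
      tree <- tree_node(o, tree_node(o2, tree$left, g), tree$right)
    } else {
      o2 <- others[c - (2L * p - 1L) + 1L]
      tree <- tree_node(o, tree$left, tree_node(o2, tree$right, g))
    }
  }
  tree
}

#' Enumerate expression trees for one target gene
#'
#' Streams all `N(p, k)` operator expression trees over the given regulators
#' that are distinct up to commutativity and associativity (see
#' [count_configs()] for the count). The first tree is the maximally
#' left-heavy chain in the first operator; root-level operator changes are
#' cycled before deeper rearrangements.
#'
#' @param regulators Character vector of input gene names (length >= 1).
#' @param ops An `operator_set`.
#' @return An iterator object with elements
#'   `$next_tree()` (returns the next tree, or NULL when exhausted),
#'   `$reset()`, and `$size` (the total count, double).
#' @examples
#' it <- exhaustive_configurations(c("A", "B", "C"), operator_preset("bar"))
#' while (!is.null(tr <- it$next_tree())) cat(format_tree(tr), "\n")
#' @export
exhaustive_configurations <- function(regulators, ops) {
  regulators <- as.character(regulators)
  k <- length(regulators)
  if (k < 1) stop("need at least one regulator")
  opnames <- names(ops)
  p <- length(opnames)
  radix <- if (k <= 1) integer() else c(p, rep(3L * p - 2L, max(0L, k - 2L)))
  nd <- length(radix)
  env <- new.env()
  env$choices <- rep(0L, nd)
  env$done <- FALSE
  advance <- function() {
    # odometer with the LAST digit (outermost, root-level join) fastest
    i <- nd
    repeat {
      if (i == 0L) { env$done <- TRUE; return(invisible()) }
      env$choices[i] <- env$choices[i] + 1L
      if (env$choices[i] < radix[i]) return(invisible())
      env$choices[i] <- 0L
      i <- i - 1L
    }
  }
  list(
    size = count_configs(p, k),
    reset = function() { env$choices <- rep(0L, nd); env$done <- FALSE },
    next_tree = function() {
      if (env$done) return(NULL)
      tree <- .tree_from_choices(regulators, opnames, env$choices)
      if (nd == 0L) env$done <- TRUE else advance()
      tree
    }
  )
}

#' Enumerate whole-network configurations
#'
#' Cartesian product of the per-target tree enumerators of
#' [exhaustive_configurations()]; genes without inputs get the empty tree.
#' Targets are ordered by ascending in-degree, the smallest trees advancing
#' outermost (slowest). Iteration is deterministic and restartable.
#'
#' @param grn A `grn`.
#' @param ops An `operator_set`.
#' @param guard Refuse search spaces larger than this many configurations
#'   (default 1e7) unless raised explicitly.
#' @return An iterator with `$next_config()` (a named list target -> tree, or
#'   NULL when exhausted), `$reset()` and `$size`.
#' @export
exhaustive_search_space <- function(grn, ops, guard = 1e7) {
  total <- total_configs(grn, length(ops))
  tot_num <- suppressWarnings(as.numeric(as.character(total)))
  if (!is.finite(tot_num) || tot_num > guard) {
    stop("search space has ", as.character(total),
         " configurations, above the guard of ", format(guard, scientific = FALSE),
         "; raise `guard` to proceed or use stochastic search")
  }
  deg <- in_degrees(grn)
  targets <- grn$genes[deg >= 1]
  targets <- targets[order(deg[deg >= 1])]   # smallest trees outermost
  fixed <- grn$genes[deg == 0]
  its <- lapply(targets, function(g) {
    exhaustive_configurations(regulators(grn, g)$source, ops)
  })
  names(its) <- targets
  env <- new.env()
  start <- function() {
    for (it in its) it$reset()
    env$current <- lapply(its, function(it) it$next_tree())
    env$done <- FALSE
  }
  start()
  empty <- stats::setNames(vector("list", length(fixed)), fixed)
  list(
    size = tot_num,
    reset = start,
    next_config = function() {
      if (env$done) return(NULL)
      if (length(its) == 0) {
        env$done <- TRUE
        return(empty[grn$genes])
      }
      out <- c(env$current, empty)[grn$genes]
      # advance: innermost = last (largest) target
      i <- length(its)
      repeat {
        nx <- its[[i]]$next_tree()
        if (!is.null(nx)) { env$current[[i]] <- nx; break }
        its[[i]]$reset()
        env$current[[i]] <- its[[i]]$next_tree()
        i <- i - 1L
        if (i == 0L) { env$done <- TRUE; break }
      }
      out
    }
  )
}

#' Draw one random configuration
#'
#' For each multi-input target, draws a random full binary tree: the shape by
#' recursive uniform splitting (the split point of each internal node uniform
#' over the possible left-subtree sizes), a uniformly random assignment of
#' regulators to leaves, and independent uniformly random operator labels.
#' Single-input targets get the single leaf tree and input-free genes the
#' empty tree.
#'
#' @param grn A `grn`.
#' @param ops An `operator_set`.
#' @return A configuration: named list target gene -> tree (or NULL).
#' @note Uses the current RNG stream; call `set.seed()` for reproducibility.
#' @export
sample_configuration <- function(grn, ops) {
  opnames <- names(ops)
  rshape <- function(leaves) {
    k <- length(leaves)
    if (k == 1) return(tree_leaf(leaves[1]))
    m <- if (k == 2) 1L else sample.int(k - 1L, 1L)
    tree_node(sample(opnames, 1L),
              rshape(leaves[seq_len(m)]),
              rshape(leaves[(m + 1L):k]))
  }
  out <- stats::setNames(vector("list", n_genes(grn)), grn$genes)
  for (g in grn$genes) {
    rr <- regulators(grn, g)$source
    if (length(rr) == 0) next
    out[[g]] <- rshape(sample(rr))
  }
  out
}

#' Format / parse whole configurations
#'
#' A configuration serializes as a JSON object mapping each target gene to
#' the s-expression of its tree (empty string for input-free genes).
#'
#' @param config Named list target -> tree.
#' @return `format_configuration()`: named character vector.
#' @export
format_configuration <- function(config) {
  vapply(config, format_tree, "")
}

#' @rdname format_configuration
#' @param strings Named character vector or list of s-expressions.
#' @param ops Optional `operator_set` for validation.
#' @export
parse_configuration <- function(strings, ops = NULL) {
  lapply(strings, parse_tree, ops = ops)
}

#' @rdname format_configuration
#' @param path JSON file path.
#' @export
read_configuration <- function(path, ops = NULL) {
  parse_configuration(jsonlite::fromJSON(path), ops = ops)
}

#' @rdname format_configuration
#' @export
write_configuration <- function(config, path) {
  jsonlite::write_json(as.list(format_configuration(config)), path,
                       auto_unbox = TRUE)
  invisible(path)
}
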