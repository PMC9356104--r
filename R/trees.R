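# Expression trees: binary trees whose leaves are a target gene's regulators
# and whose internal nodes are three-valued operators. A tree evaluates to the
# combined regulatory effect on its target in a given cell state.

#' Build tree nodes
#'
#' `tree_leaf(gene)` is a reference to one input gene; `tree_node(op, left,
#' right)` combines two subtrees with a binary operator (given as an operator
#' name, resolved against the configuration's operator set at evaluation).
#'
#' @param gene Gene name.
#' @return A tree (nested list).
#' @export
tree_leaf <- function(gene) list(gene = as.character(gene))

#' @rdname tree_leaf
#' @param op Operator name.
#' @param left,right Subtrees.
#' @export
tree_node <- function(op, left, right) {
  list(op = as.character(op), left = left, right = right)
}

is_leaf <- function(tree) !is.null(tree$gene)

#' Leaf genes of a tree
#' @param tree A tree, or NULL (the empty tree of an input-free gene).
#' @return Character vector of leaf gene names (left-to-right).
#' @export
tree_leaves <- function(tree) {
  if (is.null(tree)) return(character())
  if (is_leaf(tree)) return(tree$gene)
  c(tree_leaves(tree$left), tree_leaves(tree$right))
}

#' Parse and format trees as s-expressions
#'
#' Syntax: a leaf is a bare gene name; an internal node is
#' `(OP lhs rhs)` with `OP` an operator name, e.g.
#' `"(AND_HI (OR_HI Stat3 Esrrb) Klf4)"`. `format_tree()` inverts
#' `parse_tree()` up to whitespace; round-tripping preserves the canonical
#' form exactly.
#'
#' @param text S-expression string.
#' @param ops Optional `operator_set` used to validate operator names.
#' @return `parse_tree()`: a tree. `format_tree()`: a string (empty string
#'   for `NULL`, the empty tree).
#' @export
parse_tree <- function(text, ops = NULL) {
  text <- trimws(text)
  if (text == "") return(NULL)
  toks <- regmatches(text, gregexpr("[()]|[^()[:space:]]+", text))[[1]]
  pos <- 1L
  parse1 <- function() {
    if (pos > length(toks)) stop("unexpected end of expression")
    tok <- toks[pos]; pos <<- pos + 1L
    if (tok == "(") {
      op <- toks[pos]; pos <<- pos + 1L
      if (op %in% c("(", ")")) stop("expected operator name after '('")
      if (!is.null(ops) && !op %in% names(ops)) stop("unknown operator: ", op)
      args <- list()
      while (pos <= length(toks) && toks[pos] != ")") {
        args[[length(args) + 1L]] <- parse1()
      }
      if (pos > length(toks)) stop("missing ')'")
      pos <<- pos + 1L
      if (length(args) != 2) stop("operator ", op, " must have exactly 2 arguments")
      tree_node(op, args[[1]], args[[2]])
    } else if (tok == ")") {
      stop("unexpected ')'")
    } else {
      tree_leaf(tok)
    }
  }
  out <- parse1()
  if (pos <= length(toks)) stop("trailing input after expression")
  out
}

#' @rdname parse_tree
#' @param tree A tree or NULL.
#' @export
format_tree <- function(tree) {
  if (is.null(tree)) return("")
  if (is_leaf(tree)) return(tree$gene)
  paste0("(", tree$op, " ", format_tree(tree$left), " ",
         format_tree(tree$right), ")")
}

#' Canonical form of a tree under commutativity and associativity
#'
#' Maximal same-operator runs are flattened into one multiset node and
#' children are sorted by (subtree leaf count, lexicographic form). Two trees
#' are equivalent up to commutativity and associativity iff their canonical
#' forms are equal.
#'
#' @param tree A tree.
#' @return A string, e.g. `"(AND_HI A B C)"`.
#' @export
canonical_form <- function(tree) {
  if (is.null(tree)) return("")
  rec <- function(t) {
    if (is_leaf(t)) return(list(n = 1L, s = t$gene))
    kids <- list()
    collect <- function(x) {
      if (!is_leaf(x) && x$op == t$op) { collect(x$left); collect(x$right) }
      else kids[[length(kids) + 1L]] <<- rec(x)
    }
    collect(t$left); collect(t$right)
    ord <- order(vapply(kids, `[[`, 1L, "n"), vapply(kids, `[[`, "", "s"))
    kids <- kids[ord]
    list(n = sum(vapply(kids, `[[`, 1L, "n")),
         s = paste0("(", t$op, " ",
                    paste(vapply(kids, `[[`, "", "s"), collapse = " "), ")"))
  }
  rec(tree)$s
}

# Vectorized evaluation of a tree's effect over many states at once.
# bits: states x genes 0/1 matrix with gene-name columns; signs: named +-1
# vector over the tree's leaf genes; tabs: named list of 3x3 operator tables.
.tree_effects <- function(tree, bits, signs, tabs) {
  if (is.null(tree)) return(rep(0L, nrow(bits)))
  if (is_leaf(tree)) {
    sg <- signs[[tree$gene]]
    if (is.null(sg)) stop("leaf gene ", tree$gene, " is not a regulator here")
    return(bits[, tree$gene] * sg)
  }
  tab <- tabs[[tree$op]]
  if (is.null(tab)) stop("unknown operator: ", tree$op)
  a <- .tree_effects(tree$left, bits, signs, tabs)
  b <- .tree_effects(tree$right, bits, signs, tabs)
  tab[cbind(a + 2L, b + 2L)]
}

#' Evaluate a tree's combined regulatory effect in one cell state
#'
#' Each leaf maps its gene's expression to an effect: OFF is always neutral
#' (0); ON is +1 for an activating edge and -1 for a repressing edge, with
#' the sign taken from the network edge (leaf gene -> `target`). Internal
#' nodes combine their children's effects with their operator. The empty
#' tree (a gene with no inputs, e.g. a medium) evaluates to 0.
#'
#' @param tree A tree or NULL.
#' @param state State index, or 0/1 bit vector in gene order.
#' @param grn A `grn`.
#' @param target The target gene the tree belongs to (defines edge signs).
#' @param ops Operator set (default all six built-ins).
#' @return An effect in \{-1, 0, +1\}.
#' @export
evaluate_tree <- function(tree, state, grn, target, ops = builtin_operators()) {
  n <- n_genes(grn)
  bits <- if (length(state) == 1) {
    decode_state(state, n)
  } else {
    if (length(state) != n) stop("state must be an index or a length-", n, " bit vector")
    matrix(as.integer(state), 1L, n)
  }
  colnames(bits) <- grn$genes
  regs <- regulators(grn, target)
  signs <- stats::setNames(as.list(regs$sign), regs$source)
  lv <- tree_leaves(tree)
  if (!setequal(lv, regs$source) || anyDuplicated(lv)) {
    stop("tree leaves must be exactly the regulators of ", target)
  }
  tabs <- lapply(ops, `[[`, "table")
  as.integer(.tree_effects(tree, bits, signs, tabs))
}

#' Number of distinct operator configurations for one target gene
#'
#' With `p` available operators and `k` regulators the number of expression
#' trees distinct under commutativity and associativity that the enumeration
#' scheme generates is `N(p,1) = 1`, `N(p,2) = p` and
#' `N(p,k) = p (3p-2)^(k-2)` for `k > 2` (each additional regulator
#' multiplies the count by `3p - 2`).
#'
#' @param p Number of operators (>= 1).
#' @param k In-degree of the target (>= 0; 0 and 1 both give 1).
#' @param exact If TRUE return a [bigint()] (needed when the value exceeds
#'   2^53); otherwise a double.
#' @return A number (or `bigint`).
#' @examples
#' count_configs(2, 3)  # 8
#' count_configs(6, 4)  # 1536
#' @export
count_configs <- function(p, k, exact = FALSE) {
  p <- as.integer(p); k <- as.integer(k)
  if (p < 1 || k < 0) stop("need p >= 1 and k >= 0")
  if (exact) {
    if (k <= 1) return(bigint(1))
    return(bigint_mul(bigint(p), bigint_pow(bigint(3L * p - 2L), k - 2L)))
  }
  if (k <= 1) return(1)
  v <- p * (3 * p - 2)^(k - 2)
  if (v >= 2^53) stop("count exceeds exact double range; use exact = TRUE")
  v
}

#' Total number of operator configurations of a network
#'
#' The product over all target genes of [count_configs()] at their
#' in-degrees, computed in exact integer arithmetic (the 14-node
#' reprogramming network already needs 26 digits).
#'
#' @param grn A `grn`.
#' @param p Number of available operators.
#' @return A [bigint()]; use `as.character()` for the digit string.
#' @export
total_configs <- function(grn, p) {
  out <- bigint(1)
  for (k in in_degrees(grn)) {
    out <- bigint_mul(out, count_configs(p, k, exact = TRUE))
  }
  out
}
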