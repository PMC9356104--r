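# Shared helpers: independent, deliberately naive reference implementations
# used as oracles against the package's vectorized code paths.

# Scalar, per-state landscape computation: materializes each gene's truth
# table over its regulators by scalar recursion, then sums tau per Eq.-style
# agreement scoring. Shares no code with compute_landscape().
naive_landscape <- function(grn, config, ops = builtin_operators(),
                            L = -1, H = 1) {
  n <- n_genes(grn)
  eval_scalar <- function(tree, bits, target) {
    if (is.null(tree)) return(0L)
    if (!is.null(tree$gene)) {
      e <- grn$edges[grn$edges$source == tree$gene & grn$edges$target == target, ]
      expr <- bits[match(tree$gene, grn$genes)]
      return(if (expr == 0L) 0L else as.integer(e$sign))
    }
    a <- eval_scalar(tree$left, bits, target)
    b <- eval_scalar(tree$right, bits, target)
    apply_operator(ops[[tree$op]], a, b)
  }
  T <- numeric(2^n)
  for (s in 0:(2^n - 1)) {
    bits <- as.integer(decode_state(s, n))
    tot <- 0
    for (gi in seq_len(n)) {
      g <- grn$genes[gi]
      F <- eval_scalar(config[[g]], bits, g)
      tot <- tot + if (F == 0L) (L + H) / 2 else if (bits[gi] == (F > 0L)) L else H
    }
    T[s + 1] <- tot
  }
  T
}

# Brute-force set of all canonical forms over `leaves`: every fully
# parenthesized binary tree with every operator labeling, canonicalized.
all_canonical_forms <- function(leaves, opnames) {
  gen <- function(lv) {
    k <- length(lv)
    if (k == 1) return(list(tree_leaf(lv[1])))
    out <- list()
    for (m in 1:(k - 1)) {
      for (lc in utils::combn(k, m, simplify = FALSE)) {
        for (L in gen(lv[lc])) for (R in gen(lv[-lc])) for (o in opnames) {
          out[[length(out) + 1L]] <- tree_node(o, L, R)
        }
      }
    }
    out
  }
  unique(vapply(gen(leaves), canonical_form, ""))
}

# random tree over given leaves with ops, for property tests
random_tree <- function(leaves, opnames) {
  k <- length(leaves)
  if (k == 1) return(tree_leaf(leaves[1]))
  m <- if (k == 2) 1L else sample.int(k - 1L, 1L)
  tree_node(sample(opnames, 1L),
            random_tree(leaves[seq_len(m)], opnames),
            random_tree(leaves[(m + 1L):k], opnames))
}

# random configuration for a GRN (independent of sample_configuration)
random_config <- function(grn, opnames) {
  out <- stats::setNames(vector("list", n_genes(grn)), grn$genes)
  for (g in grn$genes) {
    rr <- regulators(grn, g)$source
    if (length(rr)) out[[g]] <- random_tree(sample(rr), opnames)
  }
  out
}
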