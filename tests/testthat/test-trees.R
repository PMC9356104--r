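test_that("trees parse, format and round-trip as s-expressions", {
  t1 <- parse_tree("(AND_HI (OR_HI Stat3 Esrrb) Klf4)")
  expect_identical(sort(tree_leaves(t1)), c("Esrrb", "Klf4", "Stat3"))
  expect_identical(format_tree(t1), "(AND_HI (OR_HI Stat3 Esrrb) Klf4)")
  expect_identical(parse_tree("Klf4"), tree_leaf("Klf4"))
  expect_null(parse_tree(""))
  expect_identical(format_tree(NULL), "")
  expect_identical(format_tree(parse_tree(format_tree(t1))), format_tree(t1))
  expect_error(parse_tree("(AND_HI A)"), "exactly 2")
  expect_error(parse_tree("(AND_HI A B C)"), "exactly 2")
  expect_error(parse_tree("(NOPE A B)", ops = builtin_operators()), "unknown operator")
  expect_error(parse_tree("(AND_HI A B"), "missing")
})

test_that("leaf evaluation maps expression to effect through the edge sign", {
  g <- grn(c("A", "B", "C", "E"),
           data.frame(source = c("B", "E", "A"), target = c("C", "C", "B"),
                      sign = c(1L, 1L, -1L)))
  # activator leaf ON -> +1; OFF -> 0
  expect_identical(evaluate_tree(tree_leaf("A"), c(1, 0, 0, 0), g, "B"), -1L)
  expect_identical(evaluate_tree(tree_leaf("A"), c(0, 0, 0, 0), g, "B"), 0L)
  # (B OR_HI E) with both ON -> +1
  tr <- parse_tree("(OR_HI B E)")
  expect_identical(evaluate_tree(tr, c(0, 1, 0, 1), g, "C"), 1L)
  # empty tree (no inputs) is neutral
  expect_identical(evaluate_tree(NULL, 0L, g, "A"), 0L)
  # leaves must be exactly the target's regulators
  expect_error(evaluate_tree(tree_leaf("B"), 0L, g, "B"), "exactly the regulators")
})

test_that("configuration counts follow the closed form and its recursion", {
  expect_identical(count_configs(6, 1), 1)
  expect_identical(count_configs(6, 2), 6)
  expect_identical(count_configs(2, 3), 8)
  expect_identical(count_configs(6, 4), 1536)
  for (p in 2:6) for (k in 3:6) {
    expect_identical(count_configs(p, k), count_configs(p, k - 1) * (3 * p - 2))
  }
  expect_error(count_configs(0, 2), "p >= 1")
  expect_identical(as.character(count_configs(6, 5, exact = TRUE)), "24576")
})

test_that("network-wide totals use exact integer arithmetic", {
  expect_identical(as.character(total_configs(fixture("mef_ipsc")$grn, 6)),
                   "26142282979403407520956416")
  expect_identical(as.character(total_configs(fixture("pluripotency")$grn, 6)),
                   "28179280429056")
  # every in-degree <= 1 collapses the space to a single configuration
  chain <- grn(c("A", "B"), data.frame(source = "A", target = "B", sign = 1))
  expect_identical(as.character(total_configs(chain, 6)), "1")
})

test_that("big integer helpers multiply exactly", {
  expect_identical(as.character(bigint_mul(bigint("99999999999999999"), 10)),
                   "999999999999999990")
  expect_identical(as.character(bigint_pow(bigint(2), 100)),
                   "1267650600228229401496703205376")
  expect_true(bigint("26142282979403407520956416") ==
              bigint_mul(bigint("26142282979403407520956416"), 1))
})

test_that("the enumerator yields the closed-form count with no duplicates", {
  opsall <- builtin_operators()
  for (p in 2:6) {
    ops <- operator_set(opsall[seq_len(p)])
    for (k in 1:5) {
      it <- exhaustive_configurations(LETTERS[1:k], ops)
      forms <- character()
      while (!is.null(tr <- it$next_tree())) {
        forms[length(forms) + 1L] <- canonical_form(tr)
      }
      expect_identical(length(forms), as.integer(count_configs(p, k)),
                       label = sprintf("count p=%d k=%d", p, k))
      expect_identical(anyDuplicated(forms), 0L,
                       label = sprintf("duplicates p=%d k=%d", p, k))
    }
  }
})

test_that("enumerated trees are genuine canonical forms of the full space", {
  # for small cases, every yielded form appears in the brute-force set of
  # all fully parenthesized labeled trees, canonicalized
  for (p in 2:3) for (k in 2:4) {
    opnames <- names(builtin_operators())[seq_len(p)]
    oracle <- all_canonical_forms(LETTERS[1:k], opnames)
    it <- exhaustive_configurations(LETTERS[1:k], operator_set(builtin_operators()[seq_len(p)]))
    forms <- character()
    while (!is.null(tr <- it$next_tree())) forms[length(forms) + 1L] <- canonical_form(tr)
    expect_true(all(forms %in% oracle), label = sprintf("p=%d k=%d", p, k))
    # at three leaves the enumeration covers the whole space
    if (k <= 3) expect_setequal(forms, oracle)
  }
})

test_that("the two-operator three-regulator case lists the published eight", {
  it <- exhaustive_configurations(c("A", "B", "C"), operator_preset("bar"))
  forms <- character()
  while (!is.null(tr <- it$next_tree())) forms[length(forms) + 1L] <- canonical_form(tr)
  expect_setequal(forms, c(
    "(AND_HI A B C)", "(OR_HI A B C)",
    "(OR_HI C (AND_HI A B))", "(OR_HI B (AND_HI A C))", "(OR_HI A (AND_HI B C))",
    "(AND_HI C (OR_HI A B))", "(AND_HI B (OR_HI A C))", "(AND_HI A (OR_HI B C))"))
  # first yielded tree is the maximally left-heavy chain in the first operator
  it$reset()
  expect_identical(format_tree(it$next_tree()), "(AND_HI (AND_HI A B) C)")
})

test_that("tree evaluation is invariant under swap and re-association", {
  g <- grn(c("T", "R1", "R2", "R3", "R4"),
           data.frame(source = c("R1", "R2", "R3", "R4"),
                      target = rep("T", 4), sign = c(1L, -1L, 1L, -1L)))
  opnames <- names(builtin_operators())
  set.seed(7)
  for (rep_i in 1:25) {
    tr <- random_tree(sample(c("R1", "R2", "R3", "R4")), opnames)
    # commutative swap at the root
    swapped <- tree_node(tr$op, tr$right, tr$left)
    # re-associate when the left child shares the root operator
    reassoc <- if (!is.null(tr$left$op) && tr$left$op == tr$op) {
      tree_node(tr$op, tr$left$left, tree_node(tr$op, tr$left$right, tr$right))
    } else tr
    for (s in sample(0:31, 8)) {
      v <- evaluate_tree(tr, s, g, "T")
      expect_identical(evaluate_tree(swapped, s, g, "T"), v)
      expect_identical(evaluate_tree(reassoc, s, g, "T"), v)
    }
  }
})

test_that("whole-network enumeration is the product of per-target spaces", {
  g <- grn(c("T1", "T2", "A", "B", "C"),
           data.frame(source = c("A", "B", "A", "B", "C"),
                      target = c("T1", "T1", "T2", "T2", "T2"),
                      sign = 1L))
  it <- exhaustive_search_space(g, operator_preset("bar"))
  expect_identical(it$size, 16)
  seen <- character()
  while (!is.null(cfg <- it$next_config())) {
    expect_identical(sort(names(cfg)), sort(g$genes))
    expect_null(cfg$A)
    seen[length(seen) + 1L] <- paste(format_configuration(cfg), collapse = ";")
  }
  expect_length(seen, 16)
  expect_identical(anyDuplicated(seen), 0L)
  # restartable and deterministic
  it$reset()
  again <- character()
  while (!is.null(cfg <- it$next_config())) {
    again[length(again) + 1L] <- paste(format_configuration(cfg), collapse = ";")
  }
  expect_identical(again, seen)
  # all in-degrees <= 1: a single configuration
  chain <- grn(c("A", "B"), data.frame(source = "A", target = "B", sign = 1))
  itc <- exhaustive_search_space(chain, operator_preset("all"))
  n_cfg <- 0L
  while (!is.null(itc$next_config())) n_cfg <- n_cfg + 1L
  expect_identical(n_cfg, 1L)
})

test_that("the exhaustive guard refuses oversized spaces", {
  expect_error(exhaustive_search_space(fixture("pluripotency")$grn,
                                       operator_preset("all")),
               "guard")
})

test_that("random configurations are reproducible and well-formed", {
  fx <- fixture("toy")
  ops <- operator_preset("all")
  set.seed(123); c1 <- sample_configuration(fx$grn, ops)
  set.seed(123); c2 <- sample_configuration(fx$grn, ops)
  expect_identical(format_configuration(c1), format_configuration(c2))
  for (g in fx$grn$genes) {
    expect_setequal(tree_leaves(c1[[g]]), regulators(fx$grn, g)$source)
  }
  # single-regulator targets always get the single leaf
  expect_identical(format_tree(c1$E), "C")
})

test_that("operator labels in sampled two-leaf trees are close to uniform", {
  g <- grn(c("T", "A", "B"),
           data.frame(source = c("A", "B"), target = "T", sign = 1L))
  ops <- operator_preset("all")
  set.seed(42)
  draws <- replicate(6000, sample_configuration(g, ops)$T$op)
  counts <- table(factor(draws, levels = names(ops)))
  chi <- sum((counts - 1000)^2 / 1000)
  # chi-square with 5 df: 99.9th percentile ~ 20.5
  expect_lt(chi, 20.5)
})

test_that("configuration files round-trip through JSON", {
  fx <- fixture("toy")
  set.seed(5)
  cfg <- sample_configuration(fx$grn, operator_preset("all"))
  path <- withr::local_tempfile(fileext = ".json")
  write_configuration(cfg, path)
  back <- read_configuration(path, ops = operator_preset("all"))
  expect_identical(format_configuration(back[fx$grn$genes]),
                   format_configuration(cfg))
})
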