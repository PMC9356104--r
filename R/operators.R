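# Three-valued operator algebra: the effect space E = {-1, 0, +1}, binary
# operators E x E -> E represented as 3x3 tables, and brute-force enumeration
# of all 3^9 tables under algebraic constraints.

EFFECTS <- c(-1L, 0L, 1L)

#' Construct a three-valued operator
#'
#' An operator combines two regulatory effects (repressive -1, neutral 0,
#' activating +1) into one. It is stored as a 3x3 result table with rows and
#' columns ordered -1, 0, +1: `table[i+2, j+2]` is the result of combining
#' effects `i` and `j`.
#'
#' @param name Short identifier, e.g. `"AND_HI"`.
#' @param table Integer 3x3 matrix with entries in \{-1, 0, +1\}, row/column
#'   order -1, 0, +1.
#' @return An object of class `operator`.
#' @seealso [builtin_operators()], [apply_operator()], [operator_properties()]
#' @export
operator <- function(name, table) {
  table <- matrix(as.integer(table), 3L, 3L)
  if (!all(table %in% EFFECTS)) {
    stop("operator table entries must lie in {-1, 0, +1}")
  }
  structure(list(name = as.character(name), table = table), class = "operator")
}

#' @export
print.operator <- function(x, ...) {
  cat("<operator ", x$name, ">\n", sep = "")
  tab <- x$table
  dimnames(tab) <- list(c("-1", "0", "+1"), c("-1", "0", "+1"))
  print(tab)
  invisible(x)
}

#' @export
format.operator <- function(x, ...) x$name

# Tables of the six canonical operators. AND-like operators require both
# inputs active; the HI/LO variants send the mixed pair (+1, -1) to +1 or -1.
# OR-like operators fire on either input; MAX/MIN return the extreme value.
.builtin_tables <- function() {
  list(
    AND_HI = matrix(c(-1L, 0L, 1L,  0L, 0L, 0L,  1L, 0L, 1L), 3, 3, byrow = TRUE),
    AND_LO = matrix(c(-1L, 0L, -1L, 0L, 0L, 0L, -1L, 0L, 1L), 3, 3, byrow = TRUE),
    OR_HI  = matrix(c(-1L, -1L, 1L, -1L, 0L, 1L, 1L, 1L, 1L), 3, 3, byrow = TRUE),
    OR_LO  = matrix(c(-1L, -1L, -1L, -1L, 0L, 1L, -1L, 1L, 1L), 3, 3, byrow = TRUE),
    MAX    = matrix(c(-1L, 0L, 1L,  0L, 0L, 1L,  1L, 1L, 1L), 3, 3, byrow = TRUE),
    MIN    = matrix(c(-1L, -1L, -1L, -1L, 0L, 0L, -1L, 0L, 1L), 3, 3, byrow = TRUE)
  )
}

#' The six canonical three-valued operators
#'
#' Returns the six non-trivial idempotent, commutative and associative
#' operators on the effect space:
#' * `AND_HI`, `AND_LO`: AND analogues; both inputs must be non-neutral to
#'   produce a signal, and the mixed-sign pair maps to +1 (`AND_HI`) or -1
#'   (`AND_LO`).
#' * `OR_HI`, `OR_LO`: OR analogues; either non-neutral input produces a
#'   signal, mixed signs map to +1 or -1 respectively.
#' * `MAX`, `MIN`: return the maximum / minimum input value, hybrids of AND
#'   and OR.
#'
#' Three further operators satisfy the same algebraic constraints but are
#' constant except where idempotence forces the diagonal; they are available
#' through [enumerate_operators()].
#'
#' @return An object of class `operator_set`: an ordered list of `operator`
#'   objects. The order is fixed and defines enumeration order elsewhere.
#' @examples
#' ops <- builtin_operators()
#' apply_operator(ops$MAX, -1, 1)   # +1
#' @export
builtin_operators <- function() {
  tabs <- .builtin_tables()
  operator_set(mapply(operator, names(tabs), tabs, SIMPLIFY = FALSE))
}

#' Bundle operators into an ordered set
#'
#' @param ops List of `operator` objects with distinct tables.
#' @return An `operator_set`.
#' @export
operator_set <- function(ops) {
  stopifnot(length(ops) >= 1, all(vapply(ops, inherits, TRUE, "operator")))
  keys <- vapply(ops, function(o) paste(o$table, collapse = ","), "")
  if (anyDuplicated(keys)) stop("duplicate operator tables in set")
  names(ops) <- vapply(ops, function(o) o$name, "")
  structure(ops, class = c("operator_set", "list"))
}

#' @export
print.operator_set <- function(x, ...) {
  cat("<operator_set: ", paste(names(x), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Named preset operator sets
#'
#' The three balanced two-operator pairs plus the full six-operator set:
#' `"bar"` = \{AND_HI, OR_HI\}, `"underbar"` = \{AND_LO, OR_LO\},
#' `"maxmin"` = \{MAX, MIN\}, `"all"` = all six.
#'
#' @param name One of `"bar"`, `"underbar"`, `"maxmin"`, `"all"`.
#' @return An `operator_set`.
#' @export
operator_preset <- function(name = c("all", "bar", "underbar", "maxmin")) {
  name <- match.arg(name)
  all6 <- builtin_operators()
  switch(name,
    all      = all6,
    bar      = operator_set(all6[c("AND_HI", "OR_HI")]),
    underbar = operator_set(all6[c("AND_LO", "OR_LO")]),
    maxmin   = operator_set(all6[c("MAX", "MIN")])
  )
}

#' Apply an operator to two effects
#'
#' @param op An `operator`.
#' @param a,b Effects in \{-1, 0, +1\} (vectorized; recycled to common length).
#' @return Integer vector of combined effects.
#' @export
apply_operator <- function(op, a, b) {
  a <- as.integer(a); b <- as.integer(b)
  if (!all(a %in% EFFECTS) || !all(b %in% EFFECTS)) {
    stop("effects must lie in {-1, 0, +1}")
  }
  op$table[cbind(a + 2L, b + 2L)]
}

#' The forcing function: effect to target expression
#'
#' A net activating effect forces the target ON (1), a net repressive effect
#' forces it OFF (0). A neutral effect imposes no forcing and is deliberately
#' undefined here; callers must branch on neutrality before forcing.
#'
#' @param e Effect vector with entries in \{-1, +1\}.
#' @return Integer vector in \{0, 1\}.
#' @export
forcing <- function(e) {
  e <- as.integer(e)
  if (any(e == 0L)) stop("forcing is undefined for the neutral effect 0")
  if (!all(e %in% c(-1L, 1L))) stop("effects must lie in {-1, +1}")
  as.integer(e == 1L)
}

#' Algebraic properties of an operator
#'
#' Checks idempotence (q(i,i) = i), commutativity (q(i,j) = q(j,i)) and
#' associativity (q(i, q(j,k)) = q(q(i,j), k), all 27 triples) by direct
#' evaluation of the table.
#'
#' @param op An `operator`.
#' @return Named logical vector `c(idempotent=, commutative=, associative=)`.
#' @export
operator_properties <- function(op) {
  tab <- op$table
  idem <- all(diag(tab) == EFFECTS)
  comm <- identical(tab, t(tab))
  asso <- TRUE
  for (i in 1:3) for (j in 1:3) for (k in 1:3) {
    if (tab[i, tab[j, k] + 2L] != tab[tab[i, j] + 2L, k]) {
      asso <- FALSE
      break
    }
  }
  c(idempotent = idem, commutative = comm, associative = asso)
}

#' Combine a list of effects with one associative operator
#'
#' Left fold of the binary table; the result is order-independent only for
#' associative (and commutative) operators, which is all the built-ins.
#'
#' @param op An `operator`.
#' @param effects Integer vector of effects, length >= 1.
#' @return A single effect.
#' @export
fold_effects <- function(op, effects) {
  effects <- as.integer(effects)
  Reduce(function(a, b) apply_operator(op, a, b), effects)
}

#' Brute-force enumeration of three-valued operators
#'
#' Enumerates all 3^9 = 19683 tables over the effect space and filters them by
#' the requested algebraic properties. The order is deterministic:
#' lexicographic on the flattened table (row-major, rows/columns -1, 0, +1,
#' values ordered -1 < 0 < +1).
#'
#' @param idempotent,commutative,associative Logical; require the property.
#' @param as_operators If `TRUE` (default) return a list of `operator`
#'   objects named `Q1`, `Q2`, ...; if `FALSE` return the count only (cheaper
#'   when only the count is wanted).
#' @return List of operators, or an integer count.
#' @examples
#' enumerate_operators(as_operators = FALSE)                      # 19683
#' enumerate_operators(TRUE, TRUE, TRUE, as_operators = FALSE)    # 9
#' enumerate_operators(FALSE, TRUE, TRUE, as_operators = FALSE)   # 63
#' @export
enumerate_operators <- function(idempotent = FALSE, commutative = FALSE,
                                associative = FALSE, as_operators = TRUE) {
  keep <- .filter_tables(.all_tables_3x3(), idempotent, commutative, associative)
  if (!as_operators) return(sum(keep))
  tabs <- .all_tables_3x3()[keep, , drop = FALSE]
  lapply(seq_len(nrow(tabs)), function(r) {
    operator(paste0("Q", r), matrix(tabs[r, ], 3, 3, byrow = TRUE))
  })
}

# 19683 x 9 matrix of row-major flattened tables in lexicographic order.
# expand.grid varies its first factor fastest, so reversing the columns puts
# the slowest-varying digit first: rows come out lexicographically sorted.
.all_tables_3x3 <- function() {
  m <- as.matrix(expand.grid(rep(list(EFFECTS), 9)))[, 9:1]
  dimnames(m) <- NULL
  m
}

.filter_tables <- function(tabs, idempotent, commutative, associative) {
  # column index of entry q(i, j) in the row-major flattened table
  cl <- function(i, j) (i + 1L) * 3L + (j + 2L)
  keep <- rep(TRUE, nrow(tabs))
  if (idempotent) {
    for (i in EFFECTS) keep <- keep & tabs[, cl(i, i)] == i
  }
  if (commutative) {
    for (i in EFFECTS) for (j in EFFECTS) {
      if (i < j) keep <- keep & tabs[, cl(i, j)] == tabs[, cl(j, i)]
    }
  }
  if (associative) {
    rows <- seq_len(nrow(tabs))
    for (i in EFFECTS) for (j in EFFECTS) for (k in EFFECTS) {
      qjk <- tabs[, cl(j, k)]
      lhs <- tabs[cbind(rows, cl(i, -1L) + qjk + 1L)]
      qij <- tabs[, cl(i, j)]
      rhs <- tabs[cbind(rows, cl(-1L, k) + (qij + 1L) * 3L)]
      keep <- keep & lhs == rhs
    }
  }
  keep
}

#' Enumerate two-valued (Boolean) operators under the same constraints
#'
#' All 2^4 = 16 Boolean binary operators, filtered by idempotence,
#' commutativity and associativity. With all three constraints only AND and
#' OR survive, which motivates the three-valued generalisation.
#'
#' @inheritParams enumerate_operators
#' @return A list of 2x2 integer tables (rows/cols ordered 0, 1), or a count.
#' @export
enumerate_boolean_operators <- function(idempotent = FALSE, commutative = FALSE,
                                        associative = FALSE, as_operators = TRUE) {
  g <- as.matrix(expand.grid(rep(list(0:1), 4)))[, 4:1]  # cols q(0,0),q(0,1),q(1,0),q(1,1)
  cl <- function(i, j) i * 2L + j + 1L
  keep <- rep(TRUE, nrow(g))
  if (idempotent) keep <- keep & g[, cl(0, 0)] == 0L & g[, cl(1, 1)] == 1L
  if (commutative) keep <- keep & g[, cl(0, 1)] == g[, cl(1, 0)]
  if (associative) {
    rows <- seq_len(nrow(g))
    for (i in 0:1) for (j in 0:1) for (k in 0:1) {
      keep <- keep & g[cbind(rows, cl(i, 0L) + g[, cl(j, k)])] ==
                     g[cbind(rows, cl(0L, k) + 2L * g[, cl(i, j)])]
    }
  }
  if (!as_operators) return(sum(keep))
  tabs <- g[keep, , drop = FALSE]
  lapply(seq_len(nrow(tabs)), function(r) matrix(tabs[r, ], 2, 2, byrow = TRUE))
}

#' Serialize / deserialize an operator as JSON
#'
#' The JSON form is `{"name": ..., "table": [[...],[...],[...]]}` with
#' row/column order -1, 0, +1.
#'
#' @param op An `operator`.
#' @return `operator_to_json()`: a JSON string; `operator_from_json()`: an
#'   `operator`.
#' @export
operator_to_json <- function(op) {
  jsonlite::toJSON(list(name = op$name,
                        table = unname(split(op$table, row(op$table)))),
                   auto_unbox = TRUE)
}

#' @rdname operator_to_json
#' @param json JSON string produced by `operator_to_json()`.
#' @export
operator_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  tab <- x$table
  if (is.list(tab)) tab <- do.call(rbind, tab)
  operator(x$name, matrix(as.integer(tab), 3, 3))
}
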