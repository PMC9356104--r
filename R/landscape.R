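# Discrete energy landscape over all 2^N cell states, attractor detection
# with degenerate-plateau semantics, basins of attraction, constraint
# checking, and configuration-search drivers.

#' Compute the discrete energy landscape
#'
#' For each state s and each gene g, the gene's regulators are combined by
#' the gene's expression tree into a resulting effect F. The gene contributes
#' `L` (agreement) if its expression equals the forced value f(F), `H`
#' (disagreement) if it differs, and the neutral energy `(L+H)/2` if F = 0
#' (which includes all genes without inputs, e.g. media). The state energy
#' is the sum of the per-gene contributions, so with the defaults
#' `L = -1, H = +1` it is an integer in `[-N, +N]`; -N means every gene
#' agrees with its input signal.
#'
#' @param grn A `grn`.
#' @param config Configuration: named list target gene -> tree (NULL for
#'   input-free genes), covering every gene of the network.
#' @param ops Operator set resolving the operator names in the trees.
#' @param L,H Agreement / disagreement energies (defaults -1, +1).
#' @return An object of class `energy_landscape`: list with `T` (numeric
#'   vector of length 2^N, state s at position s+1), `n`, `genes`, `L`, `H`,
#'   and `config` (the formatted configuration, for provenance).
#' @examples
#' g <- grn(c("A", "B"), data.frame(source = "B", target = "A", sign = 1))
#' land <- compute_landscape(g, list(A = tree_leaf("B"), B = NULL))
#' land$T  # (0, 0, 1, -1): the worked single-activator motif
#' @export
compute_landscape <- function(grn, config, ops = builtin_operators(),
                              L = -1, H = 1) {
  n <- n_genes(grn)
  missing <- setdiff(grn$genes, names(config))
  if (length(missing)) stop("configuration misses gene(s): ",
                            paste(missing, collapse = ", "))
  bits <- decode_state(0:(2^n - 1), n)
  colnames(bits) <- grn$genes
  tabs <- lapply(ops, `[[`, "table")
  neutral <- (L + H) / 2
  T <- numeric(2^n)
  for (g in grn$genes) {
    regs <- regulators(grn, g)
    tree <- config[[g]]
    lv <- tree_leaves(tree)
    if (!setequal(lv, regs$source) || anyDuplicated(lv)) {
      stop("tree for ", g, " must use exactly its regulators {",
           paste(regs$source, collapse = ", "), "}")
    }
    if (length(regs$source) == 0) {
      T <- T + neutral
      next
    }
    signs <- stats::setNames(as.list(regs$sign), regs$source)
    F <- .tree_effects(tree, bits, signs, tabs)
    a <- bits[, g]
    T <- T + ifelse(F == 0L, neutral, ifelse(a == (F > 0L), L, H))
  }
  structure(list(T = T, n = n, genes = grn$genes, L = L, H = H,
                 config = format_configuration(config)),
            class = "energy_landscape")
}

#' @export
print.energy_landscape <- function(x, ...) {
  cat("<energy_landscape: ", x$n, " genes, ", length(x$T), " states, energies [",
      min(x$T), ", ", max(x$T), "]>\n", sep = "")
  invisible(x)
}

#' Construct a landscape directly from an energy vector
#'
#' Mostly for tests and worked examples where `T` is given by hand.
#'
#' @param T Numeric vector of length 2^n.
#' @param genes Optional gene names (defaults to `g1..gn`).
#' @param L,H Agreement / disagreement energies recorded on the object.
#' @return An `energy_landscape`.
#' @export
landscape_from_T <- function(T, genes = NULL, L = -1, H = 1) {
  n <- round(log2(length(T)))
  if (2^n != length(T)) stop("length of T must be a power of two")
  if (is.null(genes)) genes <- paste0("g", seq_len(n))
  structure(list(T = as.numeric(T), n = as.integer(n), genes = genes,
                 L = L, H = H, config = NULL),
            class = "energy_landscape")
}

# For every state: is it a member of an attractor plateau? A state is
# excluded iff its maximal connected equal-energy plateau contains some state
# with a strictly lower-energy neighbor; computed by propagating "bad" flags
# across flat edges until fixpoint (vectorized over all states).
.attractor_member <- function(land) {
  T <- land$T; n <- land$n
  nb <- .neighbor_matrix(n)
  bad <- rep(FALSE, length(T))
  flat <- matrix(FALSE, length(T), n)
  for (i in seq_len(n)) {
    Tn <- T[nb[, i]]
    bad <- bad | Tn < T
    flat[, i] <- Tn == T
  }
  repeat {
    spread <- rep(FALSE, length(T))
    for (i in seq_len(n)) spread <- spread | (flat[, i] & bad[nb[, i]])
    new_bad <- bad | spread
    if (identical(new_bad, bad)) break
    bad <- new_bad
  }
  !bad
}

#' Find the attractors of a landscape
#'
#' An attractor is a maximal connected (under Hamming-1 adjacency)
#' equal-energy plateau none of whose members has a strictly lower-energy
#' neighbor. Single-state plateaus are ordinary minima; multi-state plateaus
#' are degenerate attractors (the genes that differ across the plateau do
#' not affect the energy of that cell type).
#'
#' @param land An `energy_landscape`.
#' @return A list of attractors, each a list with `states` (integer state
#'   indices, ascending), `energy`, and `degenerate` (TRUE if > 1 state).
#'   Ordered by energy, then by smallest member state.
#' @export
find_attractors <- function(land) {
  member <- .attractor_member(land)
  idx <- which(member) - 1L
  if (length(idx) == 0) return(list())
  # connect members through flat edges (members of one plateau share energy)
  nb <- .neighbor_matrix(land$n)
  edges <- NULL
  for (i in seq_len(land$n)) {
    to <- nb[idx + 1L, i] - 1L
    keep <- member[to + 1L] & land$T[to + 1L] == land$T[idx + 1L] & idx < to
    if (any(keep)) edges <- rbind(edges, cbind(idx[keep], to[keep]))
  }
  g <- igraph::make_empty_graph(n = length(idx), directed = FALSE)
  if (!is.null(edges)) {
    g <- igraph::add_edges(g, rbind(match(edges[, 1], idx), match(edges[, 2], idx)))
  }
  comp <- igraph::components(g)
  split_states <- split(idx, comp$membership)
  atts <- lapply(split_states, function(ss) {
    ss <- sort(ss)
    list(states = ss, energy = land$T[ss[1] + 1L], degenerate = length(ss) > 1L)
  })
  ord <- order(vapply(atts, `[[`, 0, "energy"),
               vapply(atts, function(a) a$states[1], 0L))
  unname(atts[ord])
}

#' Basins of attraction
#'
#' State s belongs to the basin of attractor A iff some path of
#' non-increasing-energy steps leads from s into A; equal-energy (flat) steps
#' are traversable in both directions, matching the dashed lines of the
#' landscape plots. With `strict = TRUE` only strictly decreasing steps are
#' allowed (flat steps only inside the attractor itself), which yields
#' subsets of the default basins.
#'
#' @param land An `energy_landscape`.
#' @param attractors Result of [find_attractors()].
#' @param strict Disallow flat moves outside attractors (default FALSE).
#' @return A logical matrix `2^n x n_attractors`; entry (s+1, a) says state
#'   s can reach attractor a.
#' @export
basins <- function(land, attractors, strict = FALSE) {
  T <- land$T; n <- land$n
  nb <- .neighbor_matrix(n)
  out <- matrix(FALSE, length(T), length(attractors))
  for (a in seq_along(attractors)) {
    inb <- rep(FALSE, length(T))
    inb[attractors[[a]]$states + 1L] <- TRUE
    # reverse reachability: expand to states that can step into the set
    repeat {
      reach <- rep(FALSE, length(T))
      for (i in seq_len(n)) {
        Tn <- T[nb[, i]]
        ok <- if (strict) {
          inb[nb[, i]] & (Tn < T | (Tn == T & inb))   # flat only if already in
        } else {
          inb[nb[, i]] & Tn <= T
        }
        reach <- reach | ok
      }
      new_in <- inb | reach
      if (identical(new_in, inb)) break
      inb <- new_in
    }
    out[, a] <- inb
  }
  colnames(out) <- paste0("A", seq_along(attractors))
  out
}

#' Check attractor constraints against found attractors
#'
#' A constraint is satisfied iff some attractor contains a state matching its
#' pattern (full patterns pin one state; partial patterns match any state
#' agreeing on the mentioned genes; membership in a degenerate attractor
#' counts). Surplus attractors are reported, not rejected: a configuration
#' is valid when every required state is present, whatever else the
#' landscape contains.
#'
#' @param attractors Result of [find_attractors()].
#' @param constraints A `constraint_set`.
#' @param grn The `grn` the patterns refer to.
#' @return List with `ok` (all constraints met), `matches` (per constraint,
#'   the index of the first matching attractor, NA if none) and `surplus`
#'   (attractor indices matching no constraint).
#' @export
satisfies_constraints <- function(attractors, constraints, grn) {
  matches <- stats::setNames(rep(NA_integer_, length(constraints$states)),
                             names(constraints$states))
  used <- logical(length(attractors))
  for (ci in seq_along(constraints$states)) {
    targets <- constraint_states(grn, constraints$states[[ci]])
    for (ai in seq_along(attractors)) {
      if (any(attractors[[ai]]$states %in% targets)) {
        matches[ci] <- ai
        used[ai] <- TRUE
        break
      }
    }
  }
  list(ok = !anyNA(matches), matches = matches, surplus = which(!used))
}

# fast validity test used in search loops: is every (full or partial)
# constraint pattern contained in some attractor plateau? Checks membership
# of the pattern states directly instead of partitioning the whole landscape.
.constraints_met <- function(land, member, target_sets) {
  for (ts in target_sets) {
    if (!any(member[ts + 1L])) return(FALSE)
  }
  TRUE
}

#' Search operator configurations against constraints
#'
#' Iterates configurations (exhaustively via [exhaustive_search_space()] or
#' stochastically via [sample_configuration()]), computes each landscape and
#' records which configurations satisfy all constraints, plus per-state
#' minimum prevalence: the fraction of tested landscapes in which each state
#' is an attractor member (a state belongs to at most one attractor, so it
#' is counted once per landscape). Streaming; memory does not grow with the
#' budget.
#'
#' @param grn A `grn`.
#' @param ops An `operator_set`.
#' @param constraints A `constraint_set` (NULL records prevalence only).
#' @param mode `"exhaustive"` or `"stochastic"`.
#' @param budget Number of configurations to test (stochastic mode).
#' @param seed Integer seed (stochastic mode).
#' @param L,H Energy parameters.
#' @param guard Exhaustive-mode guard, see [exhaustive_search_space()].
#' @param max_valid Stop storing formatted configurations beyond this many
#'   valid ones (they are still counted).
#' @param progress_every Print a progress line every this many landscapes
#'   (0 = silent).
#' @return List with `n_tested`, `n_valid`, `valid` (list of formatted
#'   configurations), and `prevalence` (numeric vector over states).
#' @export
search_configurations <- function(grn, ops, constraints = NULL,
                                  mode = c("exhaustive", "stochastic"),
                                  budget = NULL, seed = NULL,
                                  L = -1, H = 1, guard = 1e7,
                                  max_valid = 1000L, progress_every = 0) {
  mode <- match.arg(mode)
  target_sets <- if (is.null(constraints)) list() else {
    lapply(constraints$states, function(p) constraint_states(grn, p))
  }
  counts <- numeric(2^n_genes(grn))
  n_tested <- 0L
  n_valid <- 0L
  valid <- list()
  consume <- function(config) {
    land <- compute_landscape(grn, config, ops, L = L, H = H)
    member <- .attractor_member(land)
    counts <<- counts + member
    n_tested <<- n_tested + 1L
    if (length(target_sets) && .constraints_met(land, member, target_sets)) {
      n_valid <<- n_valid + 1L
      if (n_valid <= max_valid) valid[[n_valid]] <<- format_configuration(config)
    }
    if (progress_every > 0 && n_tested %% progress_every == 0) {
      message(n_tested, " landscapes tested, ", n_valid, " valid")
    }
  }
  if (mode == "exhaustive") {
    it <- exhaustive_search_space(grn, ops, guard = guard)
    while (!is.null(cfg <- it$next_config())) consume(cfg)
  } else {
    if (is.null(budget) || is.null(seed)) {
      stop("stochastic mode requires `budget` and `seed`")
    }
    old <- .save_rng(); on.exit(.restore_rng(old))
    set.seed(as.integer(seed))
    for (b in seq_len(budget)) consume(sample_configuration(grn, ops))
  }
  list(n_tested = n_tested, n_valid = n_valid, valid = valid,
       prevalence = counts / max(n_tested, 1L))
}

#' Dump a landscape as TSV
#'
#' Columns `index`, `bits` (most significant bit first), `energy`.
#'
#' @param land An `energy_landscape`.
#' @param path Output path.
#' @export
write_landscape <- function(land, path) {
  df <- data.frame(index = 0:(2^land$n - 1),
                   bits = state_label(0:(2^land$n - 1), land$n),
                   energy = land$T)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attractor report as JSON
#'
#' @param attractors Result of [find_attractors()].
#' @param land The landscape (for bit labels).
#' @param check Optional result of [satisfies_constraints()].
#' @param path Output path.
#' @export
write_attractor_report <- function(attractors, land, path, check = NULL) {
  rep_atts <- lapply(seq_along(attractors), function(i) {
    a <- attractors[[i]]
    m <- if (!is.null(check)) {
      hit <- names(check$matches)[which(check$matches == i)]
      if (length(hit)) hit[1] else NULL
    }
    list(states = a$states, bits = state_label(a$states, land$n),
         energy = a$energy, degenerate = a$degenerate,
         matched_constraint = m)
  })
  out <- list(attractors = rep_atts,
              surplus = if (is.null(check)) integer() else check$surplus)
  jsonlite::write_json(out, path, auto_unbox = TRUE, null = "null")
  invisible(path)
}
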