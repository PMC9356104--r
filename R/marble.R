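# Boltzmann-weighted random walks ("marble simulations") on the discrete
# landscape. From state s a marble either flips one gene or stays, with
# probability softmax(-beta * deltaE) over the N+1 options; it has arrived
# when its state is unchanged over `stop_repeats` consecutive updates.

#' Marble simulation settings
#'
#' @param beta Noise parameter (>= 0). The move logits are `-beta * deltaE`,
#'   so larger beta means colder, more deterministic descent; decreasing
#'   beta increases the noise level and uphill moves become likelier.
#' @param n_marbles Marbles per initial state.
#' @param n_replicates Independent repetitions (means and standard
#'   deviations are reported across replicates).
#' @param stop_repeats Consecutive unchanged updates that count as arrival
#'   (>= 2; default 3).
#' @param max_steps Safety cap on updates per marble; walks still moving are
#'   censored and credited to "Other". Default `10 * n * stop_repeats` is
#'   set at simulation time if NULL.
#' @param frozen_genes Character vector (or integer bit positions) of genes
#'   that can never flip, e.g. media components.
#' @param seed Master seed; every (initial state, replicate) pair derives
#'   its own substream so results are reproducible and order-independent.
#' @return An object of class `marble_config`.
#' @export
marble_config <- function(beta = 1.0, n_marbles = 1000L, n_replicates = 3L,
                          stop_repeats = 3L, max_steps = NULL,
                          frozen_genes = character(), seed = 1L) {
  if (beta < 0) stop("beta must be >= 0")
  if (stop_repeats < 2) stop("stop_repeats must be >= 2")
  structure(list(beta = beta, n_marbles = as.integer(n_marbles),
                 n_replicates = as.integer(n_replicates),
                 stop_repeats = as.integer(stop_repeats),
                 max_steps = max_steps, frozen_genes = frozen_genes,
                 seed = as.integer(seed)),
            class = "marble_config")
}

# resolve frozen genes to 1-based bit columns
.frozen_cols <- function(land, frozen) {
  if (length(frozen) == 0) return(integer())
  if (is.numeric(frozen)) return(as.integer(frozen) + 1L)
  m <- match(frozen, land$genes)
  if (anyNA(m)) stop("unknown frozen gene(s): ",
                     paste(frozen[is.na(m)], collapse = ", "))
  m
}

#' Transition probabilities from one state
#'
#' The Boltzmann weights `exp(-beta * (E_mu - E_s))` over the N single-gene
#' flips plus the stay option (deltaE = 0), normalized to sum to 1. Frozen
#' genes get probability 0 before normalization, so the remaining moves are
#' renormalized rather than folded into the stay probability.
#'
#' @param land An `energy_landscape`.
#' @param s State index.
#' @param beta Noise parameter.
#' @param frozen Genes that cannot flip (names or 0-based bit positions).
#' @return Numeric vector of length n+1: flip gene 1..n, then stay.
#' @export
transition_probabilities <- function(land, s, beta, frozen = character()) {
  n <- land$n
  dE <- land$T[hamming_neighbors(s, n) + 1L] - land$T[s + 1L]
  w <- exp(-beta * c(dE, 0))
  w[.frozen_cols(land, frozen)] <- 0
  w / sum(w)
}

#' Select a move by inverse-CDF sampling
#'
#' Picks the smallest index mu with `cumsum(probs)[mu] > r`; move order is
#' gene/bit order with "stay" last.
#'
#' @param probs Normalized probability vector.
#' @param r Uniform random number in `[0, 1)` (defaults to one draw from the
#'   current RNG).
#' @return The chosen index.
#' @export
step_choice <- function(probs, r = stats::runif(1)) {
  which(cumsum(probs) > r)[1]
}

# precompute the (2^n) x (n+1) cumulative transition matrix for a landscape;
# logits are shifted by the row maximum before exponentiation so very large
# beta stays finite (greedy-descent limit)
.cdf_matrix <- function(land, beta, frozen = character()) {
  n <- land$n
  nb <- .neighbor_matrix(n)
  logits <- matrix(-beta * (land$T[nb] - land$T), ncol = n)
  logits <- cbind(logits, 0)                   # stay: deltaE = 0
  frozen_cols <- .frozen_cols(land, frozen)
  logits[, frozen_cols] <- -Inf
  shift <- apply(logits, 1, max)
  W <- exp(logits - shift)
  P <- W / rowSums(W)
  t(apply(P, 1, cumsum))
}

#' Run a single marble walk
#'
#' @param land An `energy_landscape`.
#' @param start Initial state index.
#' @param config A [marble_config()]. The walk uses the current RNG stream;
#'   seed management happens in [simulate_ensemble()].
#' @return List with `final` (state index), `steps` (updates performed) and
#'   `censored` (TRUE if `max_steps` was hit before arrival).
#' @export
run_marble <- function(land, start, config) {
  n <- land$n
  max_steps <- if (is.null(config$max_steps)) 10L * n * config$stop_repeats
               else config$max_steps
  cdf <- .cdf_matrix(land, config$beta, config$frozen_genes)
  s <- as.integer(start)
  same <- 0L
  steps <- 0L
  while (steps < max_steps) {
    steps <- steps + 1L
    mu <- which(cdf[s + 1L, ] > stats::runif(1))[1]
    s_new <- if (mu <= n) bitwXor(s, bitwShiftL(1L, mu - 1L)) else s
    same <- if (s_new == s) same + 1L else 0L
    s <- s_new
    if (same >= config$stop_repeats) {
      return(list(final = s, steps = steps, censored = FALSE))
    }
  }
  list(final = s, steps = steps, censored = TRUE)
}

# Vectorized ensemble walk: m marbles from one start state, shared CDF.
# Returns final states (censored walks get NA).
.walk_batch <- function(cdf, n, start, m, stop_repeats, max_steps) {
  s <- rep(as.integer(start), m)
  same <- integer(m)
  active <- rep(TRUE, m)
  for (step in seq_len(max_steps)) {
    idx <- which(active)
    if (length(idx) == 0) break
    r <- stats::runif(length(idx))
    # smallest mu with cumulative > r  ==  #(cumulative <= r) + 1
    mu <- rowSums(cdf[s[idx] + 1L, , drop = FALSE] <= r) + 1L
    stay <- mu > n
    flips <- bitwXor(s[idx][!stay], bitwShiftL(1L, mu[!stay] - 1L))
    s[idx][!stay] <- flips
    same[idx] <- ifelse(stay, same[idx] + 1L, 0L)
    done <- same[idx] >= stop_repeats
    active[idx[done]] <- FALSE
  }
  s[active] <- NA_integer_
  s
}

#' Ensemble marble simulation
#'
#' Releases `n_marbles` marbles at each initial state (times
#' `n_replicates`), records where each stops, and credits terminal states to
#' attractors: a terminal state inside a degenerate attractor credits that
#' attractor (member probabilities are pooled), anything outside every
#' attractor (including censored walks) is "Other".
#'
#' @param land An `energy_landscape`.
#' @param attractors Result of [find_attractors()]; names are taken from
#'   `names(attractors)` if set, else `A1`, `A2`, ...
#' @param config A [marble_config()].
#' @param initial_states Integer vector of start states (default all 2^n).
#' @return An object of class `probability_table`: list with `mean` and
#'   `sd` (matrices initial state x attractor+Other), `replicates` (3-d
#'   array), `initial_states`, `config`.
#' @export
simulate_ensemble <- function(land, attractors, config,
                              initial_states = 0:(2^land$n - 1)) {
  n <- land$n
  max_steps <- if (is.null(config$max_steps)) 10L * n * config$stop_repeats
               else config$max_steps
  labels <- names(attractors)
  if (is.null(labels)) labels <- paste0("A", seq_along(attractors))
  state2att <- rep(NA_integer_, 2^n)
  for (a in seq_along(attractors)) state2att[attractors[[a]]$states + 1L] <- a
  cdf <- .cdf_matrix(land, config$beta, config$frozen_genes)
  cols <- c(labels, "Other")
  reps <- array(0, dim = c(length(initial_states), length(cols), config$n_replicates),
                dimnames = list(NULL, cols, NULL))
  old <- .save_rng(); on.exit(.restore_rng(old))
  for (si in seq_along(initial_states)) {
    for (rep_i in seq_len(config$n_replicates)) {
      # independent substream per (state, replicate): reproducible and
      # insensitive to evaluation order
      set.seed(as.integer((as.numeric(config$seed) * 1009 +
                           as.numeric(initial_states[si]) * 131 + rep_i) %%
                          2147483647))
      fin <- .walk_batch(cdf, n, initial_states[si], config$n_marbles,
                         config$stop_repeats, max_steps)
      att <- ifelse(is.na(fin), NA_integer_, state2att[fin + 1L])
      tab <- tabulate(att, nbins = length(attractors))
      other <- config$n_marbles - sum(tab)
      reps[si, , rep_i] <- c(tab, other) / config$n_marbles
    }
  }
  structure(list(mean = apply(reps, c(1, 2), mean),
                 sd = apply(reps, c(1, 2), stats::sd),
                 replicates = reps,
                 initial_states = initial_states,
                 attractor_labels = labels,
                 config = config),
            class = "probability_table")
}

#' @export
print.probability_table <- function(x, ...) {
  cat("<probability_table: ", length(x$initial_states), " initial states x ",
      ncol(x$mean), " outcomes, ", dim(x$replicates)[3], " replicates>\n", sep = "")
  invisible(x)
}

#' Basin-strength summary for composition plots
#'
#' Assigns each initial state its dominating attractor (maximum mean
#' probability over the named attractors, ties broken by attractor order),
#' groups states by dominating attractor, and orders states within each
#' segment by increasing dominating probability. This is the ordering used
#' by [plot_basin_strengths()].
#'
#' @param table A `probability_table` over all states.
#' @return List with `order` (permutation of row indices), `dominating`
#'   (attractor label per state, in original row order), `segments` (runs of
#'   the ordered states per dominating attractor), and the reordered `mean`
#'   and `sd` matrices.
#' @export
basin_strength_summary <- function(table) {
  att_cols <- seq_along(table$attractor_labels)
  pm <- table$mean[, att_cols, drop = FALSE]
  dom <- max.col(pm, ties.method = "first")
  dom_p <- pm[cbind(seq_len(nrow(pm)), dom)]
  ord <- order(dom, dom_p)
  seg <- table(factor(table$attractor_labels[dom],
                      levels = table$attractor_labels))
  list(order = ord,
       dominating = table$attractor_labels[dom],
       segments = seg,
       mean = table$mean[ord, , drop = FALSE],
       sd = table$sd[ord, , drop = FALSE],
       initial_states = table$initial_states[ord])
}

#' Attractor-to-attractor transition ("reprogramming") matrix
#'
#' Marbles start inside each attractor (split evenly over the member states
#' of a degenerate attractor) and the probability of ending in each
#' attractor is recorded. Rows sum to 1.
#'
#' @param land An `energy_landscape`.
#' @param attractors Result of [find_attractors()].
#' @param config A [marble_config()].
#' @return List with `mean` and `sd` matrices (initial attractor x terminal
#'   attractor + Other).
#' @export
reprogramming_matrix <- function(land, attractors, config) {
  labels <- names(attractors)
  if (is.null(labels)) labels <- paste0("A", seq_along(attractors))
  cols <- c(labels, "Other")
  out_mean <- matrix(0, length(attractors), length(cols),
                     dimnames = list(labels, cols))
  out_sd <- out_mean
  for (a in seq_along(attractors)) {
    ss <- attractors[[a]]$states
    per <- .split_marbles(config$n_marbles, length(ss))
    parts <- vector("list", length(ss))
    for (k in seq_along(ss)) {
      cfg_k <- config
      cfg_k$n_marbles <- per[k]
      tab <- simulate_ensemble(land, attractors, cfg_k, initial_states = ss[k])
      parts[[k]] <- tab$replicates[1, , , drop = FALSE] * per[k]
    }
    pooled <- Reduce(`+`, parts) / sum(per)   # 1 x cols x reps
    out_mean[a, ] <- apply(pooled[1, , , drop = FALSE], 2, mean)
    out_sd[a, ] <- apply(pooled[1, , , drop = FALSE], 2, stats::sd)
  }
  list(mean = out_mean, sd = out_sd)
}

# near-even split of m marbles over k states
.split_marbles <- function(m, k) {
  base <- m %/% k
  extra <- m %% k
  base + c(rep(1L, extra), rep(0L, k - extra))
}

#' Media-transfer simulations on frozen sub-landscapes
#'
#' Emulates transferring a stable cell colony into another medium: for each
#' assignment of the media genes, every initial attractor state is projected
#' into that medium (media bits overwritten) and simulated with the media
#' genes frozen, so marbles explore only the disconnected sub-landscape of
#' that medium.
#'
#' @param land An `energy_landscape`.
#' @param media_genes Character vector of media gene names.
#' @param attractors Result of [find_attractors()].
#' @param config A [marble_config()].
#' @param media_assignments Optional integer matrix (rows = assignments,
#'   columns = media genes, 0/1); default all 2^m combinations.
#' @return List of results per media assignment: each has `medium` (named
#'   0/1 vector), and `table` (matrix initial attractor x terminal
#'   attractor + Other of mean probabilities).
#' @export
media_transfer <- function(land, media_genes, attractors, config,
                           media_assignments = NULL) {
  mcols <- match(media_genes, land$genes)
  if (anyNA(mcols)) stop("unknown media gene(s)")
  m <- length(media_genes)
  if (is.null(media_assignments)) {
    media_assignments <- as.matrix(expand.grid(rep(list(0:1), m)))
    colnames(media_assignments) <- media_genes
  }
  labels <- names(attractors)
  if (is.null(labels)) labels <- paste0("A", seq_along(attractors))
  cols <- c(labels, "Other")
  out <- vector("list", nrow(media_assignments))
  for (mi in seq_len(nrow(media_assignments))) {
    assign_bits <- media_assignments[mi, ]
    tabm <- matrix(0, length(attractors), length(cols),
                   dimnames = list(labels, cols))
    for (a in seq_along(attractors)) {
      ss <- attractors[[a]]$states
      # overwrite media bits
      proj <- ss
      for (j in seq_len(m)) {
        bit <- bitwShiftL(1L, mcols[j] - 1L)
        proj <- ifelse(assign_bits[j] == 1,
                       bitwOr(proj, bit), bitwAnd(proj, bitwNot(bit)))
      }
      proj <- unique(as.integer(proj))
      cfg <- config
      cfg$frozen_genes <- union(config$frozen_genes, media_genes)
      per <- .split_marbles(config$n_marbles, length(proj))
      acc <- numeric(length(cols))
      for (k in seq_along(proj)) {
        cfg_k <- cfg
        cfg_k$n_marbles <- per[k]
        tab <- simulate_ensemble(land, attractors, cfg_k, initial_states = proj[k])
        acc <- acc + tab$mean[1, ] * per[k]
      }
      tabm[a, ] <- acc / sum(per)
    }
    out[[mi]] <- list(medium = stats::setNames(as.integer(assign_bits), media_genes),
                      table = tabm)
  }
  out
}

#' Write a probability table as TSV
#'
#' One row per initial state and replicate, with the state bits, the
#' probability of each attractor and of "Other".
#'
#' @param table A `probability_table`.
#' @param land The landscape (for bit labels).
#' @param path Output path.
#' @export
write_probability_table <- function(table, land, path) {
  reps <- table$replicates
  rows <- list()
  for (r in seq_len(dim(reps)[3])) {
    df <- data.frame(state_index = table$initial_states,
                     bits = state_label(table$initial_states, land$n))
    df <- cbind(df, as.data.frame(reps[, , r, drop = FALSE][, , 1]))
    df$n <- table$config$n_marbles
    df$replicate <- r
    rows[[r]] <- df
  }
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
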