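# Gene regulatory network data model, binary state encoding, and file I/O.
#
# The bit convention is global and owned by this file: the gene at position i
# of grn$genes owns bit i-1 (the least significant bit is the first gene), so
# a state index is s = sum_i 2^(i-1) * g_i. Binary strings in reports are
# printed most-significant-bit first, so a 5-gene state (0,1,1,0,1) prints as
# "10110" and encodes to 22.

#' Construct a gene regulatory network
#'
#' @param genes Character vector of unique gene names. List position defines
#'   the bit position of each gene (first gene = least significant bit).
#' @param edges Data frame with columns `source`, `target`, `sign`
#'   (+1 activation, -1 repression). Zero-row data frames are allowed.
#' @param media Character vector of genes that are external inputs (media
#'   components such as LIF). Media genes must have in-degree 0; by default
#'   all in-degree-0 genes whose name suggests nothing are left unflagged, so
#'   pass `media` explicitly.
#' @return An object of class `grn`.
#' @export
grn <- function(genes, edges = NULL, media = character()) {
  genes <- as.character(genes)
  if (anyDuplicated(genes)) stop("duplicate gene names")
  if (is.null(edges) || nrow(edges) == 0) {
    edges <- data.frame(source = character(), target = character(),
                        sign = integer(), stringsAsFactors = FALSE)
  } else {
    edges <- data.frame(source = as.character(edges$source),
                        target = as.character(edges$target),
                        sign = as.integer(edges$sign), stringsAsFactors = FALSE)
  }
  bad <- setdiff(unique(c(edges$source, edges$target)), genes)
  if (length(bad)) stop("edge endpoint(s) not in gene list: ", paste(bad, collapse = ", "))
  if (!all(edges$sign %in% c(-1L, 1L))) stop("edge signs must be +1 or -1")
  if (anyDuplicated(edges[, c("source", "target")])) {
    stop("duplicate (source, target) edge")
  }
  media <- as.character(media)
  if (length(setdiff(media, genes))) stop("unknown media gene")
  indeg_media <- edges$target %in% media
  if (any(indeg_media)) {
    stop("media genes must have in-degree 0: ",
         paste(unique(edges$target[indeg_media]), collapse = ", "))
  }
  structure(list(genes = genes, edges = edges, media = media), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat("<grn: ", length(x$genes), " genes, ", nrow(x$edges), " edges",
      if (length(x$media)) paste0(", media = ", paste(x$media, collapse = "+")),
      ">\n", sep = "")
  invisible(x)
}

#' Number of genes in a network
#' @param grn A `grn`.
#' @return Integer.
#' @export
n_genes <- function(grn) length(grn$genes)

#' Regulators of a target gene
#'
#' @param grn A `grn`.
#' @param target Gene name.
#' @return Data frame with columns `source` and `sign`, in edge-file order.
#' @export
regulators <- function(grn, target) {
  e <- grn$edges[grn$edges$target == target, c("source", "sign")]
  rownames(e) <- NULL
  e
}

#' In-degrees of all genes
#' @param grn A `grn`.
#' @return Named integer vector, in gene order.
#' @export
in_degrees <- function(grn) {
  vapply(grn$genes, function(g) sum(grn$edges$target == g), 0L)
}

#' Encode a bit vector as a state index
#'
#' The state index is \eqn{s = \sum_i 2^i g_i} with the first gene at bit 0.
#'
#' @param bits Vector of 0/1 expression values, one per gene (bit 0 first).
#' @return Integer state index in `[0, 2^N)`.
#' @examples
#' encode_state(c(0, 1, 1, 0, 1))  # 22
#' @export
encode_state <- function(bits) {
  bits <- as.integer(bits)
  if (!all(bits %in% c(0L, 1L))) stop("state bits must be 0 or 1")
  if (length(bits) > 30) stop("more than 30 genes: state index overflows integer")
  as.integer(sum(bits * 2^(seq_along(bits) - 1L)))
}

#' Decode a state index into a bit vector
#' @param s State index (vectorized).
#' @param n Number of genes.
#' @return Integer matrix, one row per state, column i = gene i's bit.
#' @export
decode_state <- function(s, n) {
  s <- as.integer(s)
  if (any(s < 0 | s >= 2^n)) stop("state index out of range")
  m <- vapply(seq_len(n) - 1L, function(i) bitwAnd(bitwShiftR(s, i), 1L),
              integer(length(s)))
  matrix(m, nrow = length(s), ncol = n)
}

#' Print a state as a binary string, most significant bit first
#' @param s State index.
#' @param n Number of genes.
#' @return Character vector like `"10110"` (for s = 22, n = 5).
#' @export
state_label <- function(s, n) {
  b <- decode_state(s, n)
  apply(b[, n:1, drop = FALSE], 1, paste, collapse = "")
}

#' Hamming-distance-1 neighbors of a state
#'
#' @param s State index in `[0, 2^N)`.
#' @param n Number of genes.
#' @return Integer vector of the `n` neighbor indices, in bit order
#'   (bit 0 flipped first).
#' @export
hamming_neighbors <- function(s, n) {
  s <- as.integer(s)
  if (s < 0 || s >= 2^n) stop("state index out of range")
  bitwXor(s, bitwShiftL(1L, seq_len(n) - 1L))
}

# neighbor index matrix for all states: 2^n rows, column i = flip bit i-1.
# 1-based rows for direct R indexing.
.neighbor_matrix <- function(n) {
  s <- 0:(2^n - 1)
  m <- vapply(seq_len(n) - 1L, function(i) bitwXor(s, bitwShiftL(1L, i)), s)
  matrix(m + 1L, nrow = 2^n, ncol = n)
}

#' Read / write a network file
#'
#' Tab-separated file with a header `source<TAB>target<TAB>sign`; `sign` may
#' be `+1`/`1`/`activate` or `-1`/`repress`. Lines starting with `#` are
#' comments. An optional directive line `!genes: A B C ...` fixes the gene
#' order (and may list isolated genes); otherwise gene order is
#' first-appearance order in the edge list. An optional `!media: LIF ...`
#' directive flags external inputs.
#'
#' @param path File path.
#' @return `read_network()`: a `grn`. `write_network()`: invisibly, `path`.
#' @export
read_network <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path, warn = FALSE)
  genes_order <- NULL
  media <- character()
  body <- character()
  body_ln <- integer()
  for (ln in seq_along(lines)) {
    line <- trimws(lines[ln])
    if (line == "" || startsWith(line, "#")) next
    if (startsWith(line, "!genes:")) {
      genes_order <- strsplit(trimws(sub("^!genes:", "", line)), "[ \t]+")[[1]]
    } else if (startsWith(line, "!media:")) {
      media <- strsplit(trimws(sub("^!media:", "", line)), "[ \t]+")[[1]]
    } else {
      body <- c(body, line)
      body_ln <- c(body_ln, ln)
    }
  }
  if (length(body) == 0 && is.null(genes_order)) {
    stop("empty network file: ", path)
  }
  edges <- NULL
  if (length(body)) {
    parts <- strsplit(body, "\t")
    # a conventional header line is allowed and skipped
    if (identical(tolower(parts[[1]]), c("source", "target", "sign"))) {
      parts <- parts[-1]; body_ln <- body_ln[-1]
    }
    if (length(parts)) {
      nfield <- lengths(parts)
      if (any(nfield != 3)) {
        stop("line ", body_ln[which(nfield != 3)[1]], ": expected 3 tab-separated fields")
      }
      src <- vapply(parts, `[`, "", 1)
      tgt <- vapply(parts, `[`, "", 2)
      sgn_tok <- vapply(parts, `[`, "", 3)
      sgn <- ifelse(sgn_tok %in% c("+1", "1", "activate"), 1L,
             ifelse(sgn_tok %in% c("-1", "repress"), -1L, NA_integer_))
      if (anyNA(sgn)) {
        stop("line ", body_ln[which(is.na(sgn))[1]], ": unknown sign token '",
             sgn_tok[which(is.na(sgn))[1]], "'")
      }
      dup <- duplicated(paste(src, tgt, sep = "\r"))
      if (any(dup)) {
        stop("line ", body_ln[which(dup)[1]], ": duplicate edge ",
             src[which(dup)[1]], " -> ", tgt[which(dup)[1]])
      }
      edges <- data.frame(source = src, target = tgt, sign = sgn,
                          stringsAsFactors = FALSE)
    }
  }
  genes <- genes_order
  if (is.null(genes)) {
    genes <- unique(c(rbind(edges$source, edges$target)))
  } else {
    extra <- setdiff(unique(c(edges$source, edges$target)), genes)
    if (length(extra)) stop("gene(s) in edges but not in !genes: header: ",
                            paste(extra, collapse = ", "))
  }
  grn(genes, edges, media)
}

#' @rdname read_network
#' @param grn A `grn` object.
#' @export
write_network <- function(grn, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("!genes: ", paste(grn$genes, collapse = " ")), con)
  if (length(grn$media)) {
    writeLines(paste0("!media: ", paste(grn$media, collapse = " ")), con)
  }
  writeLines("source\ttarget\tsign", con)
  if (nrow(grn$edges)) {
    writeLines(sprintf("%s\t%s\t%+d", grn$edges$source, grn$edges$target,
                       grn$edges$sign), con)
  }
  invisible(path)
}

#' Attractor constraint sets
#'
#' A constraint set names binarized expression patterns (e.g. "iPSC") that
#' must appear as attractor states of a landscape. Patterns may be partial:
#' genes not mentioned match either value, and a partial pattern is satisfied
#' by any attractor state agreeing on the mentioned genes.
#'
#' @param states Named list; each element is a named vector of 0/1 expression
#'   values, keyed by gene name.
#' @param media Optional character vector naming the media context.
#' @return An object of class `constraint_set`.
#' @export
constraint_set <- function(states, media = character()) {
  stopifnot(is.list(states), length(names(states)) == length(states))
  states <- lapply(states, function(s) {
    v <- as.integer(s)
    if (!all(v %in% c(0L, 1L))) stop("constraint values must be 0 or 1")
    names(v) <- names(s)
    v
  })
  structure(list(states = states, media = as.character(media)),
            class = "constraint_set")
}

#' @export
print.constraint_set <- function(x, ...) {
  cat("<constraint_set: ", paste(names(x$states), collapse = ", "), ">\n", sep = "")
  invisible(x)
}

#' Read / write constraints as JSON
#'
#' Format: `{"attractors": {"iPSC": {"Oct4": 1, ...}, ...}, "media": ["LIF"]}`.
#'
#' @param path File path.
#' @return `read_constraints()`: a `constraint_set`.
#' @export
read_constraints <- function(path) {
  x <- jsonlite::fromJSON(path)
  constraint_set(lapply(x$attractors, unlist),
                 media = if (is.null(x$media)) character() else x$media)
}

#' @rdname read_constraints
#' @param constraints A `constraint_set`.
#' @export
write_constraints <- function(constraints, path) {
  jsonlite::write_json(list(attractors = lapply(constraints$states, as.list),
                            media = constraints$media),
                       path, auto_unbox = TRUE)
  invisible(path)
}

#' Resolve a constraint pattern against a network
#'
#' Full patterns resolve to a unique state index; partial patterns resolve to
#' the set of matching indices.
#'
#' @param grn A `grn`.
#' @param pattern Named 0/1 vector keyed by gene name.
#' @return Integer vector of matching state indices.
#' @export
constraint_states <- function(grn, pattern) {
  unknown <- setdiff(names(pattern), grn$genes)
  if (length(unknown)) stop("constraint names unknown gene(s): ",
                            paste(unknown, collapse = ", "))
  n <- n_genes(grn)
  fixed_bits <- match(names(pattern), grn$genes) - 1L
  base <- sum(as.integer(pattern) * 2^fixed_bits)
  free <- setdiff(0:(n - 1L), fixed_bits)
  if (length(free) == 0) return(as.integer(base))
  combos <- as.matrix(expand.grid(rep(list(0:1), length(free))))
  as.integer(base + combos %*% 2^free)
}

#' Random network generator
#'
#' Draws `n_edges` distinct directed edges (no self-loops unless
#' `allow_self_loops`) uniformly at random and assigns repression signs with
#' probability `repress_fraction`. Intended as a test-input generator.
#'
#' @param n_genes Number of genes (named `G1`, `G2`, ...).
#' @param n_edges Number of edges.
#' @param repress_fraction Probability an edge is repressive.
#' @param seed Integer seed; the draw is reproducible.
#' @param allow_self_loops Allow a gene to regulate itself (default FALSE).
#' @return A `grn`.
#' @export
random_grn <- function(n_genes, n_edges, repress_fraction = 0.3, seed = 1L,
                       allow_self_loops = FALSE) {
  genes <- paste0("G", seq_len(n_genes))
  pairs <- expand.grid(source = seq_len(n_genes), target = seq_len(n_genes))
  if (!allow_self_loops) pairs <- pairs[pairs$source != pairs$target, ]
  if (n_edges > nrow(pairs)) stop("infeasible edge count: at most ", nrow(pairs))
  old <- .save_rng(); on.exit(.restore_rng(old))
  set.seed(as.integer(seed))
  pick <- pairs[sample.int(nrow(pairs), n_edges), ]
  sign <- ifelse(stats::runif(n_edges) < repress_fraction, -1L, 1L)
  grn(genes, data.frame(source = genes[pick$source], target = genes[pick$target],
                        sign = sign, stringsAsFactors = FALSE))
}

# save/restore the global RNG state so seeded helpers don't disturb callers
.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
}
.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  } else {
    assign(".Random.seed", old, envir = globalenv())
  }
}
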