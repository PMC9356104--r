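# Flattened-hypercube visualization of discrete energy landscapes: each of
# the 2^n states is a corner of an n-cube, drawn as concentric copies of the
# (n-1)-cube layout; nodes are pie glyphs showing gene expression, edges are
# arrows toward lower energy (dashed when flat), with optional basin rings.

#' 2D layout of the n-dimensional hypercube
#'
#' The layout for n genes is two copies of the layout for n-1: states with
#' the highest bit clear form the inner copy and states with it set the
#' outer copy, scaled by a constant factor, with corresponding corners
#' joined. The base cases are a vertical pair (n = 1) and a rounded square
#' (n = 2). Deterministic.
#'
#' @param n Number of genes, 1..7 (beyond seven the plot is too cluttered;
#'   merge genes with [merge_genes()] or fix some with [slice_landscape()]).
#' @return An object of class `hypercube_layout`: list with `n`, `coords`
#'   (2^n x 2 matrix, row s+1 = state s) and `edges` (n 2^(n-1) x 2 matrix
#'   of state index pairs at Hamming distance 1).
#' @export
hypercube_layout <- function(n) {
  if (n < 1 || n > 7) {
    stop("hypercube layout supports 1..7 genes; merge genes into shared ",
         "dimensions (merge_genes) or plot a slice (slice_landscape) instead")
  }
  coords <- matrix(c(0, -0.5, 0, 0.5), 2, 2, byrow = TRUE)
  if (n >= 2) {
    # rounded square for n = 2
    coords <- matrix(c(-1, -1, 1, -1, -1, 1, 1, 1), 4, 2, byrow = TRUE)
    if (n > 2) {
      for (k in 3:n) {
        # scale factor grows with k so outer shells keep clearance
        coords <- rbind(coords, coords * (1.9 + 0.12 * k))
      }
    }
  }
  s <- 0:(2^n - 1)
  edges <- NULL
  for (i in seq_len(n) - 1L) {
    to <- bitwXor(s, bitwShiftL(1L, i))
    keep <- s < to
    edges <- rbind(edges, cbind(s[keep], to[keep]))
  }
  structure(list(n = n, coords = coords, edges = edges),
            class = "hypercube_layout")
}

#' @export
print.hypercube_layout <- function(x, ...) {
  cat("<hypercube_layout: n = ", x$n, ", ", nrow(x$coords), " nodes, ",
      nrow(x$edges), " edges>\n", sep = "")
  invisible(x)
}

# diverging palette symmetric about zero energy
.energy_colors <- function(T) {
  lim <- max(abs(T), 1)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  pal[round((T + lim) / (2 * lim) * 100) + 1]
}

.draw_pie <- function(x, y, r, bits, cols = NULL, border = "grey30") {
  n <- length(bits)
  a0 <- pi / 2
  for (i in seq_len(n)) {
    th <- seq(a0 - 2 * pi * (i) / n, a0 - 2 * pi * (i - 1) / n, length.out = 24)
    graphics::polygon(c(x, x + r * cos(th)), c(y, y + r * sin(th)),
                      col = if (bits[i] == 1) (if (is.null(cols)) "grey25" else cols[i]) else "white",
                      border = border, lwd = 0.5)
  }
}

.draw_ring <- function(x, y, r0, r1, cols) {
  k <- length(cols)
  for (i in seq_len(k)) {
    th <- seq(2 * pi * (i - 1) / k, 2 * pi * i / k, length.out = 32)
    graphics::polygon(c(x + r1 * cos(th), x + r0 * rev(cos(th))),
                      c(y + r1 * sin(th), y + r0 * rev(sin(th))),
                      col = cols[i], border = NA)
  }
}

#' Plot an energy landscape on the flattened hypercube
#'
#' Each state is a pie glyph (one sector per gene, filled iff ON, bit 0 at
#' twelve o'clock moving clockwise); node color encodes energy through a
#' diverging palette symmetric about zero. Edges connect Hamming-1 neighbors
#' as arrows pointing toward the lower energy with width proportional to
#' |deltaE|; equal-energy neighbors are joined by dashed lines. Attractor
#' states are outlined in their label color and an optional outer ring shows
#' which basins a state belongs to.
#'
#' @param land An `energy_landscape`.
#' @param layout A [hypercube_layout()] of matching dimension (default
#'   built on the fly).
#' @param attractors Optional result of [find_attractors()].
#' @param basin_map Optional result of [basins()]; draws the basin rings.
#' @param file Optional output path; `.pdf` or `.svg` choose the device,
#'   anything else plots to the active device.
#' @param max_lwd Arrow width at the largest |deltaE| (linear scale).
#' @param node_scale Pie radius as a fraction of the layout extent.
#' @return Invisibly, the file path (or NULL when drawn on a live device).
#' @export
plot_landscape <- function(land, layout = hypercube_layout(land$n),
                           attractors = NULL, basin_map = NULL,
                           file = NULL, max_lwd = 4, node_scale = 0.030) {
  if (layout$n != land$n) stop("layout dimension does not match landscape")
  dev_open <- FALSE
  if (!is.null(file)) {
    if (grepl("\\.pdf$", file)) grDevices::pdf(file, width = 9, height = 8)
    else if (grepl("\\.svg$", file)) grDevices::svg(file, width = 9, height = 8)
    else grDevices::pdf(file)
    dev_open <- TRUE
    on.exit(grDevices::dev.off())
  }
  co <- layout$coords
  ext <- max(abs(co)) * 1.15 + 1
  r <- ext * node_scale * 2
  graphics::par(mar = c(1, 1, 2, 6), xpd = NA)
  graphics::plot(NA, xlim = c(-ext, ext * 1.25), ylim = c(-ext, ext),
                 axes = FALSE, xlab = "", ylab = "", asp = 1)
  T <- land$T
  dmax <- max(abs(T[layout$edges[, 1] + 1] - T[layout$edges[, 2] + 1]), 1e-9)
  att_col <- NULL
  att_of_state <- rep(NA_integer_, length(T))
  if (!is.null(attractors) && length(attractors)) {
    att_col <- grDevices::hcl.colors(max(3, length(attractors)), "Dark 3")[seq_along(attractors)]
    for (a in seq_along(attractors)) att_of_state[attractors[[a]]$states + 1] <- a
  }
  for (e in seq_len(nrow(layout$edges))) {
    a <- layout$edges[e, 1]; b <- layout$edges[e, 2]
    dE <- T[b + 1] - T[a + 1]
    p1 <- co[a + 1, ]; p2 <- co[b + 1, ]
    # shrink endpoints to the glyph boundary
    v <- p2 - p1; L <- sqrt(sum(v^2)); u <- v / max(L, 1e-9)
    q1 <- p1 + u * r * 1.4; q2 <- p2 - u * r * 1.4
    if (dE == 0) {
      graphics::segments(q1[1], q1[2], q2[1], q2[2], lty = 2, col = "grey40")
    } else {
      if (dE > 0) { tmp <- q1; q1 <- q2; q2 <- tmp }   # arrow points downhill
      head_state <- if (dE > 0) a else b
      colr <- if (!is.na(att_of_state[head_state + 1])) att_col[att_of_state[head_state + 1]] else "grey25"
      graphics::arrows(q1[1], q1[2], q2[1], q2[2],
                       lwd = 0.4 + max_lwd * abs(dE) / dmax,
                       length = 0.07, col = colr)
    }
  }
  ecol <- .energy_colors(T)
  bits <- decode_state(0:(2^land$n - 1), land$n)
  for (s in 0:(2^land$n - 1)) {
    if (!is.null(basin_map) && !is.null(att_col) && any(basin_map[s + 1, ])) {
      inb <- which(basin_map[s + 1, ])
      .draw_ring(co[s + 1, 1], co[s + 1, 2], r * 1.15, r * 1.4, att_col[inb])
    }
    graphics::symbols(co[s + 1, 1], co[s + 1, 2], circles = r, inches = FALSE,
                      add = TRUE, bg = ecol[s + 1],
                      fg = if (!is.na(att_of_state[s + 1])) att_col[att_of_state[s + 1]] else "grey30")
    .draw_pie(co[s + 1, 1], co[s + 1, 2], r * 0.85, bits[s + 1, ])
  }
  # legend glyph naming the sectors, and a color bar
  lx <- ext * 1.12; ly <- ext * 0.85
  .draw_pie(lx, ly, r * 1.6, rep(1, land$n))
  for (i in seq_len(land$n)) {
    ang <- pi / 2 - 2 * pi * (i - 0.5) / land$n
    graphics::text(lx + r * 2.4 * cos(ang), ly + r * 2.4 * sin(ang),
                   land$genes[i], cex = 0.7)
  }
  ticks <- pretty(range(T))
  bar_y <- seq(-ext * 0.6, ext * 0.4, length.out = 101)
  lim <- max(abs(T), 1)
  pal <- grDevices::colorRampPalette(c("#2166ac", "#f7f7f7", "#b2182b"))(101)
  graphics::rect(lx, bar_y[-101], lx + ext * 0.05, bar_y[-1],
                 col = pal[round((seq(min(bar_y), max(bar_y), length.out = 100) -
                                  min(bar_y)) / diff(range(bar_y)) * 100) + 1],
                 border = NA)
  graphics::text(lx + ext * 0.1,
                 seq(-ext * 0.6, ext * 0.4, length.out = length(ticks)),
                 labels = round(seq(-lim, lim, length.out = length(ticks)), 1),
                 cex = 0.7, adj = 0)
  graphics::title(main = sprintf("Energy landscape (%d genes, %d states)",
                                 land$n, length(T)))
  invisible(file)
}

#' Merge gene groups into shared plot dimensions
#'
#' Keeps only the full states in which every gene of a group shares one
#' value and maps each group to a single reduced bit, producing a lower-
#' dimensional landscape for plotting. Reduced neighbors are generally NOT
#' Hamming-1 neighbors of the full landscape, so merged minima may differ
#' from true attractors; the returned object carries this caveat and
#' plotting it must keep the caveat visible.
#'
#' @param land An `energy_landscape`.
#' @param groups Named list of character vectors partitioning (a subset of)
#'   the genes; genes not mentioned become singleton groups.
#' @return An `energy_landscape` over the reduced dimensions with attributes
#'   `full_states` (the selected full-state index per reduced state) and
#'   `caveat`.
#' @export
merge_genes <- function(land, groups) {
  genes <- land$genes
  named <- unlist(groups)
  if (anyDuplicated(named)) stop("groups overlap")
  if (length(setdiff(named, genes))) stop("unknown gene in groups")
  singles <- setdiff(genes, named)
  all_groups <- c(groups, stats::setNames(as.list(singles), singles))
  # preserve bit order by each group's first gene
  first_bit <- vapply(all_groups, function(g) match(g[1], genes), 0L)
  all_groups <- all_groups[order(first_bit)]
  m <- length(all_groups)
  combos <- decode_state(0:(2^m - 1), m)
  full_states <- integer(2^m)
  Tred <- numeric(2^m)
  for (rs in 0:(2^m - 1)) {
    bits <- integer(length(genes))
    for (gi in seq_len(m)) {
      bits[match(all_groups[[gi]], genes)] <- combos[rs + 1, gi]
    }
    fs <- encode_state(bits)
    full_states[rs + 1] <- fs
    Tred[rs + 1] <- land$T[fs + 1]
  }
  out <- landscape_from_T(Tred, genes = names(all_groups), L = land$L, H = land$H)
  attr(out, "full_states") <- full_states
  attr(out, "caveat") <- paste(
    "merged landscape: reduced neighbors are not Hamming-1 neighbors of the",
    "full landscape; minima shown here may differ from true attractors")
  out
}

#' Fix some genes and plot the remaining hyperplane
#'
#' @param land An `energy_landscape`.
#' @param fixed Named 0/1 vector of genes to pin.
#' @return An `energy_landscape` over the free genes, with attribute
#'   `full_states`.
#' @export
slice_landscape <- function(land, fixed) {
  genes <- land$genes
  if (length(setdiff(names(fixed), genes))) stop("unknown gene in `fixed`")
  free <- setdiff(genes, names(fixed))
  m <- length(free)
  if (m < 1) stop("no free genes left")
  combos <- decode_state(0:(2^m - 1), m)
  full_states <- integer(2^m)
  for (rs in 0:(2^m - 1)) {
    bits <- integer(length(genes))
    bits[match(names(fixed), genes)] <- as.integer(fixed)
    bits[match(free, genes)] <- combos[rs + 1, ]
    full_states[rs + 1] <- encode_state(bits)
  }
  out <- landscape_from_T(land$T[full_states + 1], genes = free,
                          L = land$L, H = land$H)
  attr(out, "full_states") <- full_states
  out
}

#' Stacked composition plot of basin strengths
#'
#' Draws the probability of reaching each attractor for every initial state
#' as a stacked area over a continuous, unlabeled state axis, ordered and
#' segmented by dominating attractor ([basin_strength_summary()]); "Other"
#' is the topmost band and segment boundaries are marked.
#'
#' @param summary Result of [basin_strength_summary()].
#' @param file Optional `.pdf`/`.svg` output path.
#' @param colors Optional colors per attractor (+ grey for Other).
#' @return Invisibly, the file path.
#' @export
plot_basin_strengths <- function(summary, file = NULL, colors = NULL) {
  if (!is.null(file)) {
    if (grepl("\\.svg$", file)) grDevices::svg(file, width = 8, height = 4.5)
    else grDevices::pdf(file, width = 8, height = 4.5)
    on.exit(grDevices::dev.off())
  }
  pm <- summary$mean
  k <- ncol(pm)
  n_states <- nrow(pm)
  if (is.null(colors)) {
    colors <- c(grDevices::hcl.colors(max(3, k - 1), "Dark 3")[seq_len(k - 1)], "grey70")
  }
  graphics::par(mar = c(2.5, 4, 2, 8), xpd = NA)
  graphics::plot(NA, xlim = c(0, n_states), ylim = c(0, 1), xaxt = "n",
                 xlab = "", ylab = "probability of reaching attractor",
                 main = "Basin strengths")
  x <- seq_len(n_states) - 0.5
  cum <- rbind(0, apply(t(pm), 2, cumsum))
  for (i in seq_len(k)) {
    graphics::polygon(c(x, rev(x)), c(cum[i, ], rev(cum[i + 1, ])),
                      col = colors[i], border = NA)
  }
  seg_ends <- cumsum(summary$segments)
  graphics::abline(v = seg_ends[-length(seg_ends)], col = "white", lwd = 1.5)
  graphics::mtext("initial states (ordered within segment)", side = 1, line = 1)
  graphics::legend(n_states * 1.02, 1, legend = colnames(pm), fill = colors,
                   bty = "n", cex = 0.8)
  invisible(file)
}
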