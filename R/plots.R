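# Scalable visualizations of multi-set intersection statistics: matrix
# (UpSet-style) and circular layouts for all combinations, and pairwise
# heatmap / network views.  Base graphics; every plot function invisibly
# returns the geometry it drew so proportionality is testable.

## colour intensity encodes -log10(adjusted p), capped so astronomically
## small p-values do not flatten the palette; NA (untested records) is grey
p_intensity_colors <- function(log10_p_adjusted, cap = 10,
                               palette = c("#E8F5E9", "#00441B")) {
  ramp <- grDevices::colorRampPalette(palette)(101L)
  vapply(log10_p_adjusted, function(l) {
    if (is.na(l)) return("grey80")
    ramp[1L + round(100 * min(-l, cap) / cap)]
  }, character(1))
}

select_records <- function(fit, degree = NULL, sort.by = "size") {
  rec <- fit$records
  if (!is.null(degree)) rec <- rec[rec$degree %in% degree, , drop = FALSE]
  if (!nrow(rec)) stop("no records in the requested degree range")
  sort_records(rec, by = sort.by)
}

#' Plot a multi-set intersection analysis
#'
#' Four layouts for an [mset_test()] fit.  `"matrix"` draws an UpSet-style
#' chart: a panel of filled/empty membership markers (one row per set, one
#' column per combination, set sizes at the right) below bars whose heights
#' are proportional to the observed intersection sizes and whose fill
#' intensity encodes `-log10` of the adjusted p-value.  `"circular"` arranges
#' the same information radially: one presence/absence track per set and an
#' outer bar ring, sectors starting at 12 o'clock and proceeding clockwise.
#' `"heatmap"` shows the `t x t` pairwise significance matrix (diagonal
#' annotated with set sizes) and `"network"` one node per set (area
#' proportional to log set size) with an edge per overlapping pair (width
#' proportional to overlap, colour intensity to significance; deterministic
#' Fruchterman-Reingold layout from `seed`).
#'
#' @param x An `"msetest"` object.
#' @param type One of `"matrix"`, `"circular"`, `"heatmap"`, `"network"`.
#' @param degree Integer vector of combination degrees to display (matrix and
#'   circular layouts); default degrees 2 and above.
#' @param sort.by Column order for matrix/circular layouts, see
#'   [sort_records()].
#' @param color.cap Ceiling on `-log10(adjusted p)` for the colour scale;
#'   values at or above the cap share the deepest colour.
#' @param seed Layout seed for the network view.
#' @param ... Further arguments passed to the underlying graphics calls.
#' @return Invisibly, a data frame (or list for `"network"`) describing the
#'   drawn geometry: for matrix/circular layouts one row per combination with
#'   its barcode, observed size and bar length in user coordinates.
#' @export
plot.msetest <- function(x, type = c("matrix", "circular", "heatmap", "network"),
                         degree = NULL, sort.by = "size", color.cap = 10,
                         seed = 1L, ...) {
  type <- match.arg(type)
  switch(type,
    matrix = plot_mset_matrix(x, degree = degree, sort.by = sort.by,
                              color.cap = color.cap, ...),
    circular = plot_mset_circular(x, degree = degree, sort.by = sort.by,
                                  color.cap = color.cap, ...),
    heatmap = plot_mset_heatmap(x, color.cap = color.cap, ...),
    network = plot_mset_network(x, color.cap = color.cap, seed = seed, ...)
  )
}

plot_mset_matrix <- function(fit, degree = NULL, sort.by = "size",
                             color.cap = 10, ...) {
  if (is.null(degree)) degree <- 2:length(fit$set_sizes)
  rec <- select_records(fit, degree, sort.by)
  t <- length(fit$set_sizes)
  k <- nrow(rec)
  maxobs <- max(rec$observed, 1L)
  bar_span <- t * 1.2                       # vertical user units for the bars
  heights <- rec$observed / maxobs * bar_span
  cols <- p_intensity_colors(rec$log10_p_adjusted, cap = color.cap)
  op <- graphics::par(mar = c(1, 1, 2, 5))
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(0.5, k + 0.5),
                        ylim = c(0.5, t + 0.7 + bar_span * 1.15))
  y0 <- t + 0.7
  ## membership matrix
  for (j in seq_len(t)) {
    bits <- substr(rec$barcode, j, j) == "1"
    graphics::points(seq_len(k), rep(t - j + 1, k), pch = 21,
                     bg = ifelse(bits, "#00441B", "white"),
                     col = "grey40", cex = min(1.4, 30 / k))
    graphics::text(k + 0.6, t - j + 1,
                   sprintf("%s (%d)", names(fit$set_sizes)[j], fit$set_sizes[j]),
                   adj = 0, xpd = NA, cex = 0.8)
  }
  ## bars
  graphics::rect(seq_len(k) - 0.4, y0, seq_len(k) + 0.4, y0 + heights,
                 col = cols, border = NA)
  graphics::text(seq_len(k), y0 + heights, rec$observed, pos = 3,
                 cex = min(0.8, 25 / k), xpd = NA)
  graphics::title(main = "Multi-set intersections", adj = 0)
  invisible(data.frame(barcode = rec$barcode, observed = rec$observed,
                       height = heights, color = cols,
                       stringsAsFactors = FALSE))
}

## arc polygon between radii r0..r1 over angles a0..a1 (radians)
draw_sector <- function(a0, a1, r0, r1, col, steps = 8L) {
  aa <- seq(a0, a1, length.out = steps)
  graphics::polygon(c(r0 * cos(aa), rev(r1 * cos(aa))),
                    c(r0 * sin(aa), rev(r1 * sin(aa))),
                    col = col, border = NA)
}

plot_mset_circular <- function(fit, degree = NULL, sort.by = "size",
                               color.cap = 10, track_colors = NULL, ...) {
  if (is.null(degree)) degree <- 2:length(fit$set_sizes)
  rec <- select_records(fit, degree, sort.by)
  t <- length(fit$set_sizes)
  k <- nrow(rec)
  if (is.null(track_colors)) {
    track_colors <- grDevices::hcl.colors(t, "Dark 3")
  }
  maxobs <- max(rec$observed, 1L)
  r_in <- 0.25; r_tracks <- 0.55; r_bar0 <- 0.6; bar_span <- 0.35
  dr <- (r_tracks - r_in) / t
  gap <- 0.12 * 2 * pi / k
  op <- graphics::par(mar = c(0.5, 0.5, 2, 0.5), pty = "s")
  on.exit(graphics::par(op))
  graphics::plot.new()
  graphics::plot.window(xlim = c(-1.15, 1.15), ylim = c(-1.15, 1.15), asp = 1)
  heights <- rec$observed / maxobs * bar_span
  cols <- p_intensity_colors(rec$log10_p_adjusted, cap = color.cap)
  for (i in seq_len(k)) {
    ## sector i: start at 12 o'clock, clockwise
    a1 <- pi / 2 - (i - 1) * 2 * pi / k - gap / 2
    a0 <- pi / 2 - i * 2 * pi / k + gap / 2
    for (j in seq_len(t)) {
      present <- substr(rec$barcode[i], j, j) == "1"
      draw_sector(a0, a1, r_in + (j - 1) * dr, r_in + j * dr - 0.004,
                  if (present) track_colors[j] else "grey90")
    }
    draw_sector(a0, a1, r_bar0, r_bar0 + heights[i], cols[i])
    am <- (a0 + a1) / 2
    graphics::text(1.02 * cos(am), 1.02 * sin(am), rec$observed[i],
                   cex = min(0.7, 20 / k), xpd = NA)
  }
  graphics::legend("topleft",
                   legend = sprintf("%s (%d)", names(fit$set_sizes), fit$set_sizes),
                   fill = track_colors, bty = "n", cex = 0.7)
  graphics::title(main = "Multi-set intersections (circular)", adj = 0)
  invisible(data.frame(barcode = rec$barcode, observed = rec$observed,
                       height = heights, color = cols,
                       stringsAsFactors = FALSE))
}

plot_mset_heatmap <- function(fit, color.cap = 10, ...) {
  t <- length(fit$set_sizes)
  if (t < 2L) stop("heatmap needs at least two sets")
  pairs <- fit$records[fit$records$degree == 2L, , drop = FALSE]
  mat <- matrix(NA_real_, t, t, dimnames = list(names(fit$set_sizes),
                                                names(fit$set_sizes)))
  for (r in seq_len(nrow(pairs))) {
    idx <- which(strsplit(pairs$barcode[r], "")[[1L]] == "1")
    v <- min(-pairs$log10_p_adjusted[r], color.cap)
    mat[idx[1L], idx[2L]] <- v
    mat[idx[2L], idx[1L]] <- v
  }
  ramp <- grDevices::colorRampPalette(c("#E8F5E9", "#00441B"))(100L)
  op <- graphics::par(mar = c(5, 5, 2, 1))
  on.exit(graphics::par(op))
  graphics::image(seq_len(t), seq_len(t), t(mat[t:1, , drop = FALSE]),
                  zlim = c(0, color.cap), col = ramp, axes = FALSE,
                  xlab = "", ylab = "")
  graphics::axis(1, at = seq_len(t), labels = colnames(mat), las = 2, tick = FALSE)
  graphics::axis(2, at = seq_len(t), labels = rev(rownames(mat)), las = 2, tick = FALSE)
  for (i in seq_len(t)) {
    graphics::text(i, t - i + 1, fit$set_sizes[i], cex = 0.8)
  }
  graphics::title(main = expression("Pairwise intersection significance, " *
                                    -log[10] ~ "adjusted P"), adj = 0)
  invisible(mat)
}

plot_mset_network <- function(fit, color.cap = 10, seed = 1L, ...) {
  t <- length(fit$set_sizes)
  if (t < 2L) stop("network needs at least two sets")
  pairs <- fit$records[fit$records$degree == 2L & fit$records$observed > 0L, ,
                       drop = FALSE]
  ends <- t(vapply(pairs$barcode,
                   function(b) which(strsplit(b, "")[[1L]] == "1"),
                   integer(2)))
  g <- igraph::make_empty_graph(n = t, directed = FALSE)
  igraph::V(g)$name <- names(fit$set_sizes)
  if (nrow(pairs)) g <- igraph::add_edges(g, t(ends))
  set.seed(seed)
  coords <- igraph::layout_with_fr(g)
  vsize <- 12 * log10(pmax(fit$set_sizes, 2)) / max(log10(pmax(fit$set_sizes, 2)))
  ewidth <- if (nrow(pairs)) 1 + 6 * pairs$observed / max(pairs$observed) else numeric(0)
  ecol <- p_intensity_colors(pairs$log10_p_adjusted, cap = color.cap,
                             palette = c("#C8E6C9", "#00441B"))
  igraph::plot.igraph(g, layout = coords, vertex.size = vsize,
                      vertex.color = "#A5D6A7", vertex.frame.color = "grey40",
                      vertex.label.color = "black", vertex.label.cex = 0.8,
                      edge.width = ewidth, edge.color = ecol, ...)
  graphics::title(main = "Pairwise intersection network", adj = 0)
  invisible(list(coords = coords, edges = ends,
                 observed = pairs$observed, edge_color = ecol))
}
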