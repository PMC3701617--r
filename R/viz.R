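# Grid images (red -> yellow heatmaps), dendrograms and matrix export.
#
# All plotting is side-effect-only: rendering never mutates the numerical
# results, and every plot builder returns the ggplot object so that tests
# can assert on the mapped data rather than on pixels.

matrix_to_long <- function(m) {
  labs <- rownames(m) %||% as.character(seq_len(nrow(m)))
  idx <- expand.grid(i = seq_len(nrow(m)), j = seq_len(ncol(m)))
  tibble(
    form1 = factor(labs[idx$i], levels = labs),
    form2 = factor(labs[idx$j], levels = rev(labs)),
    value = m[cbind(idx$i, idx$j)],
    diagonal = idx$i == idx$j
  )
}

#' Grid image of a form-comparison matrix
#'
#' Renders an n x n matrix of pairwise comparison counts (or fractions)
#' as a grid of coloured rectangles with forms on both axes. The colour
#' scale is linear from red (minimum, zero common items) to yellow
#' (maximum); diagonal cells (self-comparison) are drawn in neutral grey
#' and excluded from the scale so they do not swamp the off-diagonal
#' contrast.
#'
#' @param m Square matrix with form OIDs as dimnames.
#' @param mode `"absolute"` (scale spans the observed off-diagonal range)
#'   or `"relative"` (scale fixed to \[0, 1\]).
#' @param title Optional plot title.
#' @param path Optional output file (written with [ggplot2::ggsave()],
#'   PNG/SVG/PDF by extension); rendering is deterministic for fixed
#'   input.
#' @param width,height Device size in inches when `path` is given.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
grid_image <- function(m, mode = c("absolute", "relative"), title = NULL,
                       path = NULL, width = 7, height = 6) {
  mode <- match.arg(mode)
  if (!is.matrix(m) || nrow(m) != ncol(m)) {
    abort("Grid images require a square matrix.", class = "fc_usage_error")
  }
  long <- matrix_to_long(m)
  off <- long[!long$diagonal, ]
  limits <- if (mode == "relative") c(0, 1) else {
    if (nrow(off) > 0L) range(off$value) else c(0, 1)
  }
  if (limits[1] == limits[2]) limits[2] <- limits[1] + 1  # constant matrix
  p <- ggplot2::ggplot(off, ggplot2::aes(x = .data$form1, y = .data$form2,
                                         fill = .data$value)) +
    ggplot2::geom_tile(color = "grey30") +
    ggplot2::geom_tile(data = long[long$diagonal, , drop = FALSE],
                       fill = "grey80", color = "grey30") +
    ggplot2::scale_fill_gradient(
      low = "red", high = "yellow", limits = limits,
      name = if (mode == "relative") "fraction" else "items"
    ) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = title, x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @export
#' @rdname grid_image
#' @param object A `form_set_result`.
#' @param matrix_name Which matrix to plot: `"identical"`, `"matching"` or
#'   `"similar"`.
#' @param relative Plot the size-normalised fractions instead of absolute
#'   counts.
#' @param ... Unused.
autoplot.form_set_result <- function(object,
                                     matrix_name = c("identical", "matching", "similar"),
                                     relative = FALSE, ...) {
  matrix_name <- match.arg(matrix_name)
  m <- object$matrices[[matrix_name]]
  if (relative) {
    m <- relative_matrix(m, object$coded_sizes,
                         diagonal = if (matrix_name == "identical") "one" else "zero")
  }
  grid_image(m, mode = if (relative) "relative" else "absolute",
             title = sprintf("%s items (%s)", matrix_name,
                             if (relative) "relative" else "absolute"))
}

# Segment coordinates of an hclust dendrogram: leaves at x = 1..n in
# hc$order; each merge draws two vertical risers and one horizontal bar.
dendrogram_segments <- function(hc) {
  n <- length(hc$order)
  leaf_x <- integer(n); leaf_x[hc$order] <- seq_len(n)
  node_x <- numeric(max(1L, n - 1L))
  segs <- list()
  child_xy <- function(id, k) {
    if (id < 0) c(leaf_x[-id], 0) else c(node_x[id], hc$height[id])
  }
  for (k in seq_len(n - 1L)) {
    a <- child_xy(hc$merge[k, 1L]); b <- child_xy(hc$merge[k, 2L])
    h <- hc$height[k]
    node_x[k] <- mean(c(a[1L], b[1L]))
    segs[[length(segs) + 1L]] <- tibble(
      x = c(a[1L], b[1L], a[1L]), xend = c(a[1L], b[1L], b[1L]),
      y = c(a[2L], b[2L], h), yend = c(h, h, h)
    )
  }
  bind_rows(segs)
}

#' Dendrogram plot of a form cluster tree
#'
#' Draws the hierarchical clustering of forms with leaf labels on the
#' x-axis and merge height (form distance) on the y-axis: the longer the
#' lines joining two forms, the fewer items they have in common.
#'
#' @param tree An `hclust`/`form_cluster` tree (see [cluster_forms()]).
#' @param title Optional plot title.
#' @param path Optional output image file.
#' @param width,height Device size in inches when `path` is given.
#' @return The ggplot object, invisibly when `path` is given.
#' @export
dendrogram_plot <- function(tree, title = NULL, path = NULL,
                            width = 7, height = 5) {
  hc <- stats::as.hclust(tree)
  n <- length(hc$order)
  segs <- dendrogram_segments(hc)
  leaves <- tibble(x = seq_len(n), label = hc$labels[hc$order])
  p <- ggplot2::ggplot() +
    ggplot2::geom_segment(data = segs,
                          ggplot2::aes(x = .data$x, xend = .data$xend,
                                       y = .data$y, yend = .data$yend)) +
    ggplot2::scale_x_continuous(breaks = leaves$x, labels = leaves$label) +
    ggplot2::labs(title = title, x = NULL, y = "distance (merge height)") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1),
                   panel.grid.major.x = ggplot2::element_blank())
  if (!is.null(path)) {
    ggplot2::ggsave(path, p, width = width, height = height, dpi = 150)
    return(invisible(p))
  }
  p
}

#' @export
#' @param object,... See [dendrogram_plot()].
#' @rdname dendrogram_plot
autoplot.form_cluster <- function(object, ...) dendrogram_plot(object, ...)

#' Export form-set matrices as CSV
#'
#' Writes `identical.csv`, `matching.csv` and `similar.csv` (OID header
#' row and column) into a directory; values round-trip losslessly through
#' [utils::read.csv()] with `row.names = 1`.
#'
#' @param result A `form_set_result`.
#' @param out_dir Output directory (created if missing).
#' @return Named character vector of the three file paths, invisibly.
#' @export
export_matrices <- function(result, out_dir) {
  stopifnot(inherits(result, "form_set_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  paths <- vapply(names(result$matrices), function(cat) {
    p <- file.path(out_dir, paste0(cat, ".csv"))
    write.csv(result$matrices[[cat]], p)
    p
  }, character(1))
  invisible(paths)
}

#' Write the full image set for a form-set comparison
#'
#' For each of the three matrices (identical, matching, similar) this
#' writes an absolute grid image, a relative grid image and a dendrogram
#' of the clustering on the distance derived from that matrix -- nine
#' images in total, named `<matrix>_<mode>.png` -- plus one Newick file
#' per matrix.
#'
#' @param result A `form_set_result`.
#' @param out_dir Output directory (created if missing).
#' @param linkage Linkage for [cluster_forms()].
#' @return Character vector of all files written, invisibly.
#' @export
save_form_set_images <- function(result, out_dir, linkage = "complete") {
  stopifnot(inherits(result, "form_set_result"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  files <- character()
  for (cat in names(result$matrices)) {
    m <- result$matrices[[cat]]
    abs_p <- file.path(out_dir, paste0(cat, "_absolute.png"))
    rel_p <- file.path(out_dir, paste0(cat, "_relative.png"))
    den_p <- file.path(out_dir, paste0(cat, "_dendrogram.png"))
    nwk_p <- file.path(out_dir, paste0(cat, "_tree.nwk"))
    grid_image(m, "absolute", title = paste(cat, "items (absolute)"),
               path = abs_p)
    rel <- relative_matrix(m, result$coded_sizes,
                           diagonal = if (cat == "identical") "one" else "zero")
    grid_image(rel, "relative", title = paste(cat, "items (relative)"),
               path = rel_p)
    tree <- cluster_forms(withCallingHandlers(
      to_distance(m), warning = function(w) invokeRestart("muffleWarning")),
      linkage = linkage)
    dendrogram_plot(tree, title = paste("clustering on", cat, "items"),
                    path = den_p)
    newick_export(tree, nwk_p)
    files <- c(files, abs_p, rel_p, den_p, nwk_p)
  }
  invisible(files)
}
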