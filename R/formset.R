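# Pairwise comparison of a set of forms: three count matrices, relative
# normalisation, distance derivation and hierarchical clustering.

as_form_list <- function(forms) {
  if (inherits(forms, "odm_study")) forms <- forms$forms
  if (inherits(forms, "odm_form")) forms <- list(forms)
  stopifnot(is.list(forms), all(map_lgl(forms, is.data.frame)))
  forms
}

#' Compare every pair in a set of forms
#'
#' Runs [match_items()] once per unordered pair of forms and stores the
#' identical, matching and similar counts in three symmetric n x n
#' matrices (mirrored, which is output-equivalent to comparing all ordered
#' pairs because category counts are symmetric). The diagonal of the
#' identical matrix holds each form's coded-item count (a form is
#' identical to itself on every coded item); the matching and similar
#' diagonals are zero.
#'
#' @param forms List of `odm_form` objects (or an [odm_study()]); at
#'   least 2 forms with unique OIDs.
#' @return A `form_set_result`: list with `form_oids`, `form_names`,
#'   `sizes` (item counts), `coded_sizes`, and `matrices` (named list of
#'   the three integer matrices with OID dimnames). [tidy()] returns the
#'   long count table; [glance()] the set summary.
#' @examples
#' set <- gen_form_set(sizes = c(10, 10, 8),
#'                     overlaps = data.frame(form1 = 1, form2 = 2, identical = 4,
#'                                           matching = 0, similar = 0),
#'                     seed = 1)
#' res <- compare_form_set(set)
#' res$matrices$identical
#' @export
compare_form_set <- function(forms) {
  forms <- as_form_list(forms)
  n <- length(forms)
  if (n < 2L) abort("Need at least 2 forms.", class = "fc_usage_error")
  oids <- unname(map_chr(forms, form_oid))
  if (anyDuplicated(oids)) {
    abort(sprintf("Duplicate form OIDs: %s",
                  paste(unique(oids[duplicated(oids)]), collapse = ", ")),
          class = "fc_invalid_study")
  }
  sizes <- unname(map_int(forms, nrow))
  coded_sizes <- unname(map_int(forms, ~ sum(lengths(.x$codes) > 0L)))

  mats <- lapply(c(identical = 1, matching = 2, similar = 3), function(i) {
    m <- matrix(0L, n, n, dimnames = list(oids, oids))
    m
  })
  for (i in seq_len(n - 1L)) {
    for (j in seq(i + 1L, n)) {
      cnt <- match_items(forms[[i]], forms[[j]])$counts
      for (cat in names(mats)) {
        mats[[cat]][i, j] <- mats[[cat]][j, i] <- unname(cnt[[cat]])
      }
    }
  }
  diag(mats$identical) <- coded_sizes

  structure(list(form_oids = oids, form_names = unname(map_chr(forms, form_name)),
                 sizes = sizes, coded_sizes = coded_sizes, matrices = mats),
            class = "form_set_result")
}

#' @export
print.form_set_result <- function(x, ...) {
  cat(sprintf("<form_set_result> %d forms, %d items (%d coded)\n",
              length(x$form_oids), sum(x$sizes), sum(x$coded_sizes)))
  cat("Identical-item matrix:\n")
  print(x$matrices$identical)
  invisible(x)
}

#' @export
#' @rdname compare_form_set
#' @param x,object A `form_set_result`.
#' @param ... Unused.
tidy.form_set_result <- function(x, ...) {
  n <- length(x$form_oids)
  idx <- expand.grid(i = seq_len(n), j = seq_len(n))
  bind_rows(lapply(names(x$matrices), function(cat) {
    tibble(category = cat,
           form1 = x$form_oids[idx$i], form2 = x$form_oids[idx$j],
           count = x$matrices[[cat]][cbind(idx$i, idx$j)])
  }))
}

#' @export
#' @rdname compare_form_set
glance.form_set_result <- function(x, ...) {
  tibble(n_forms = length(x$form_oids), total_items = sum(x$sizes),
         mean_items = round(mean(x$sizes)), min_items = min(x$sizes),
         max_items = max(x$sizes))
}

#' Normalise a count matrix by the smaller form size
#'
#' Absolute common-item counts under-represent small forms: a small form
#' can share at most as many items as it has. The relative matrix divides
#' each off-diagonal entry by the smaller of the two forms' coded-item
#' counts, giving fractions in \[0, 1\].
#'
#' @param m Symmetric count matrix (one of the `form_set_result`
#'   matrices).
#' @param coded_sizes Coded-item count per form, in matrix order.
#' @param diagonal `"one"` for the identical matrix (a form shares all its
#'   coded items with itself), `"zero"` otherwise.
#' @return Numeric matrix with entries in \[0, 1\]. Rows/columns of forms
#'   with zero coded items are set to 0 with a warning.
#' @export
relative_matrix <- function(m, coded_sizes, diagonal = c("zero", "one")) {
  diagonal <- match.arg(diagonal)
  n <- nrow(m)
  stopifnot(n == ncol(m), length(coded_sizes) == n)
  denom <- outer(coded_sizes, coded_sizes, pmin)
  zero <- coded_sizes == 0L
  if (any(zero)) {
    warn(sprintf("%d form(s) have zero coded items; their relative entries are set to 0.",
                 sum(zero)))
    denom[denom == 0L] <- 1L
  }
  out <- m / denom
  out[zero, ] <- 0; out[, zero] <- 0
  diag(out) <- if (diagonal == "one") as.numeric(!zero) else 0
  dimnames(out) <- dimnames(m)
  out
}

#' Derive a distance matrix from common-item counts
#'
#' The distance between two forms is defined by the number of items they
#' have in common: `d(i, j) = C - common(i, j)` with `C` the largest
#' off-diagonal common count in the set. Pairs sharing the most items are
#' closest; pairs sharing none attain the maximum distance `C`. The
#' diagonal (self-comparison) is excluded from `C` and set to zero.
#'
#' @param common Symmetric non-negative count matrix.
#' @return A symmetric `dist`-compatible numeric matrix with zero
#'   diagonal. If all off-diagonal counts are zero the distances collapse
#'   to zero and a degenerate-clustering warning is emitted.
#' @export
to_distance <- function(common) {
  n <- nrow(common)
  stopifnot(n == ncol(common))
  off <- common; diag(off) <- NA
  C <- if (n > 1L) max(off, na.rm = TRUE) else 0
  if (C == 0) {
    warn("All off-diagonal common-item counts are zero; distances are degenerate (all 0).")
  }
  d <- C - common
  diag(d) <- 0
  dimnames(d) <- dimnames(common)
  d
}

#' Hierarchically cluster forms from a distance matrix
#'
#' Agglomerative clustering of forms via [stats::hclust()]; merge heights
#' follow the chosen linkage (complete by default). Leaf labels are the
#' form OIDs taken from the distance-matrix dimnames.
#'
#' @param d Symmetric distance matrix with zero diagonal (see
#'   [to_distance()]).
#' @param linkage `"complete"`, `"average"` or `"single"`.
#' @return An object of class `form_cluster`/`hclust`.
#' @export
cluster_forms <- function(d, linkage = c("complete", "average", "single")) {
  linkage <- match.arg(linkage)
  if (nrow(d) < 2L) abort("Clustering needs at least 2 forms.",
                          class = "fc_usage_error")
  hc <- hclust(as.dist(d), method = linkage)
  class(hc) <- c("form_cluster", class(hc))
  hc
}

#' Export a cluster tree in Newick format
#'
#' Branch lengths are derived from the merge heights (via
#' [ape::as.phylo()]), so the exported tree is readable by any standard
#' phylogenetics tool.
#'
#' @param tree An `hclust`/`form_cluster` tree.
#' @param path Optional output file; when `NULL` the Newick string is
#'   returned.
#' @return The Newick string (invisibly when written to `path`).
#' @export
newick_export <- function(tree, path = NULL) {
  phy <- ape::as.phylo(stats::as.hclust(tree))
  txt <- ape::write.tree(phy)
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}

#' Summary statistics of a form set
#'
#' @param forms List of `odm_form` objects or an [odm_study()].
#' @return One-row tibble with `n_forms`, `total_items`, `mean_items`
#'   (rounded to the nearest integer), `mean_items_exact`, `min_items`,
#'   `max_items`.
#' @examples
#' summary_stats(evaluation_form_set(seed = 1))
#' @export
summary_stats <- function(forms) {
  forms <- as_form_list(forms)
  stopifnot(length(forms) >= 1L)
  sizes <- map_int(forms, nrow)
  tibble(n_forms = length(forms), total_items = sum(sizes),
         mean_items = round(mean(sizes)), mean_items_exact = mean(sizes),
         min_items = min(sizes), max_items = max(sizes))
}
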