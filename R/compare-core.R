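# Item-pair classification and best-fit comparison of two forms.
#
# Category definitions, on items represented as (name, concept codes,
# value domain):
#   identical -- name, codes and value domain all equal;
#   matching  -- codes and value domain equal, names different;
#   similar   -- codes equal, value domains different;
#   differing -- concept codes differ.
# Items without any concept code ("uncoded") cannot be compared
# automatically and are reported separately.

#' Canonicalise an item name for comparison
#'
#' Names are compared after Unicode NFC normalisation, trimming,
#' collapsing internal whitespace runs to single spaces and case folding.
#' Raw names are preserved for reporting; only comparisons use this form.
#'
#' @param raw Character vector of item names.
#' @return Character vector of normalised names.
#' @examples
#' normalize_name("  Date of   Birth ")  # "date of birth"
#' @export
normalize_name <- function(raw) {
  x <- stringi::stri_trans_nfc(as.character(raw))
  x <- gsub("[[:space:]]+", " ", trimws(x))
  stringi::stri_trans_tolower(x)
}

code_sets_equal <- function(a, b) {
  length(a) > 0L && length(b) > 0L && setequal(a, b)
}

code_lists_equivalent <- function(a, b) {
  if (is.null(a) && is.null(b)) return(TRUE)
  if (is.null(a) || is.null(b)) return(FALSE)
  if (!setequal(a$coded_value, b$coded_value)) return(FALSE)
  # Where both sides annotate an entry, its concept codes must agree;
  # display texts are language-dependent and ignored.
  for (cv in a$coded_value) {
    ca <- a$codes[[match(cv, a$coded_value)]]
    cb <- b$codes[[match(cv, b$coded_value)]]
    if (length(ca) > 0L && length(cb) > 0L && !setequal(ca, cb)) return(FALSE)
  }
  TRUE
}

#' Test two value domains for equality
#'
#' Two value domains are equal iff their data types are equal, their
#' measurement units are equal (both absent counts as equal), and their
#' code lists are equivalent: same set of coded values and, where both
#' sides annotate an entry with concept codes, the same codes per value
#' (display texts are ignored as language-dependent). The classic
#' counter-example is a laboratory item recorded in mg/dl in one form and
#' mmol/l in another: same concept, different domain.
#'
#' @param a,b Items (one-row tibbles from [odm_item()] or lists) with
#'   elements `data_type`, `unit`, `code_list`.
#' @return `TRUE` or `FALSE`; symmetric in its arguments.
#' @export
value_domains_equal <- function(a, b) {
  vd_equal_row(as_item_row(a), as_item_row(b))
}

vd_equal_row <- function(a, b) {
  if (!identical(a$data_type, b$data_type)) return(FALSE)
  ua <- a$unit; ub <- b$unit
  units_eq <- (is.na(ua) && is.na(ub)) || (!is.na(ua) && !is.na(ub) && ua == ub)
  if (!units_eq) return(FALSE)
  code_lists_equivalent(a$code_list, b$code_list)
}

# Accept both one-row tibbles and plain lists; unwrap list-columns.
as_item_row <- function(x) {
  if (is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    list(oid = x$oid, name = x$name, codes = x$codes[[1L]],
         data_type = x$data_type, unit = x$unit,
         code_list = x$code_list[[1L]])
  } else {
    x$unit <- x$unit %||% NA_character_
    x
  }
}

#' Classify a pair of coded items
#'
#' Applies the four-category rule to one item from each form. Both items
#' must carry concept codes; uncoded items are never classified (they are
#' routed to the uncoded lists by [match_items()]). Concept-code sets are
#' compared by exact set equality (postcoordinated items must share all
#' codes); names via [normalize_name()]; value domains via
#' [value_domains_equal()]. The function is symmetric.
#'
#' @param a,b Items ([odm_item()] rows or equivalent lists).
#' @return One of `"identical"`, `"matching"`, `"similar"`, `"differing"`.
#' @examples
#' a <- odm_item("I.1", "birth date", codes = "C2004062", data_type = "date")
#' b <- odm_item("I.2", "date of birth", codes = "C2004062", data_type = "date")
#' classify_pair(a, b)  # "matching"
#' @export
classify_pair <- function(a, b) {
  a <- as_item_row(a); b <- as_item_row(b)
  if (length(a$codes) == 0L || length(b$codes) == 0L) {
    abort("classify_pair() requires coded items; uncoded items are excluded from automatic comparison.",
          class = "fc_uncoded")
  }
  if (!code_sets_equal(a$codes, b$codes)) return("differing")
  if (!vd_equal_row(a, b)) return("similar")
  if (normalize_name(a$name) == normalize_name(b$name)) "identical" else "matching"
}

# Plain-list view of an item table, with names pre-normalised, so the
# O(n1 * n2) classification loop avoids repeated tibble slicing.
items_as_rows <- function(items) {
  if (nrow(items) == 0L) return(list())
  norm <- normalize_name(items$name)
  lapply(seq_len(nrow(items)), function(i) {
    list(oid = items$oid[[i]], name = items$name[[i]], norm_name = norm[[i]],
         codes = items$codes[[i]], data_type = items$data_type[[i]],
         unit = items$unit[[i]], code_list = items$code_list[[i]])
  })
}

classify_row <- function(a, b) {
  if (!code_sets_equal(a$codes, b$codes)) return("differing")
  if (!vd_equal_row(a, b)) return("similar")
  if (a$norm_name == b$norm_name) "identical" else "matching"
}

# Maximum-cardinality bipartite matching (Kuhn's augmenting-path
# algorithm). `elig` is an n1 x n2 logical matrix; left vertices are
# processed in row order and neighbours in column order, which makes the
# returned matching deterministic (document-order tie-breaking). Returns
# for each left vertex the matched right index or NA.
kuhn_match <- function(elig) {
  n1 <- nrow(elig); n2 <- ncol(elig)
  match2 <- rep(NA_integer_, n2)  # right -> left
  augment <- function(u, visited) {
    for (v in which(elig[u, ])) {
      if (visited[v]) next
      visited[v] <- TRUE
      if (is.na(match2[v]) || Recall(match2[v], visited)) {
        match2[v] <<- u
        return(TRUE)
      }
    }
    FALSE
  }
  for (u in seq_len(n1)) {
    if (any(elig[u, ])) augment(u, visited = rep(FALSE, n2))
  }
  match1 <- rep(NA_integer_, n1)
  match1[match2[!is.na(match2)]] <- which(!is.na(match2))
  match1
}

empty_items <- function() odm_item("I.0", "x")[0, ]

#' Compare two forms by best-fit item matching
#'
#' Computes the aggregated comparison report for two forms. Uncoded items
#' are set aside first. Among coded items a one-to-one pairing is built in
#' three priority passes -- identical, then matching, then similar -- each
#' pass taking a maximum-cardinality matching over the still-unpaired
#' eligible pairs (ties broken by document order, so output is
#' deterministic). Coded items left unpaired are reported as differing.
#' Category counts are invariant under swapping the two forms.
#'
#' @param items1,items2 `odm_form` objects (or plain item tibbles).
#' @param oid1,oid2 Form OIDs for the report header; default to the forms'
#'   own attributes.
#' @return A `form_comparison` object: list with `pairs` (tibble of
#'   classified pairs), `differing1`, `differing2`, `uncoded1`, `uncoded2`
#'   (item tibbles), `counts` (named integer vector) and the form
#'   OIDs/names. Use [glance()] for the one-row count summary, [tidy()]
#'   for the per-item long table and [render_report()] (or `print()`) for
#'   the human-readable report.
#' @examples
#' pair <- worked_example_pair()
#' rep <- match_items(pair$forms[[1]], pair$forms[[2]])
#' glance(rep)
#' @export
match_items <- function(items1, items2,
                        oid1 = form_oid(items1), oid2 = form_oid(items2)) {
  items1 <- as_tibble(items1); items2 <- as_tibble(items2)
  coded1 <- lengths(items1$codes) > 0L
  coded2 <- lengths(items2$codes) > 0L
  c1 <- items1[coded1, ]; c2 <- items2[coded2, ]
  n1 <- nrow(c1); n2 <- nrow(c2)

  rows1 <- items_as_rows(c1); rows2 <- items_as_rows(c2)
  cat_m <- matrix("differing", n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) {
      cat_m[i, j] <- classify_row(rows1[[i]], rows2[[j]])
    }
  }

  used1 <- rep(FALSE, n1); used2 <- rep(FALSE, n2)
  pair_rows <- list()
  for (category in c("identical", "matching", "similar")) {
    elig <- (cat_m == category) & outer(!used1, !used2, "&")
    if (!any(elig)) next
    m1 <- kuhn_match(elig)
    for (i in which(!is.na(m1))) {
      j <- m1[[i]]
      used1[i] <- TRUE; used2[j] <- TRUE
      pair_rows[[length(pair_rows) + 1L]] <- tibble(
        category = category,
        form1_oid = c1$oid[[i]], form1_name = c1$name[[i]],
        form2_oid = c2$oid[[j]], form2_name = c2$name[[j]],
        form1_row = i, form2_row = j
      )
    }
  }
  pairs <- if (length(pair_rows)) bind_rows(pair_rows) else
    tibble(category = character(), form1_oid = character(),
           form1_name = character(), form2_oid = character(),
           form2_name = character(), form1_row = integer(),
           form2_row = integer())
  pairs <- pairs[order(match(pairs$category, c("identical", "matching", "similar")),
                       pairs$form1_row), ]

  res <- structure(list(
    form1_oid = oid1 %||% NA_character_, form2_oid = oid2 %||% NA_character_,
    form1_name = form_name(items1), form2_name = form_name(items2),
    pairs = pairs,
    identical_pairs = pairs[pairs$category == "identical", ],
    matching_pairs = pairs[pairs$category == "matching", ],
    similar_pairs = pairs[pairs$category == "similar", ],
    differing1 = c1[!used1, , drop = FALSE],
    differing2 = c2[!used2, , drop = FALSE],
    uncoded1 = items1[!coded1, , drop = FALSE],
    uncoded2 = items2[!coded2, , drop = FALSE],
    items1 = items1, items2 = items2,
    n_items1 = nrow(items1), n_items2 = nrow(items2),
    n_coded1 = n1, n_coded2 = n2
  ), class = "form_comparison")
  res$counts <- c(
    identical = sum(pairs$category == "identical"),
    matching = sum(pairs$category == "matching"),
    similar = sum(pairs$category == "similar"),
    differing_form1 = nrow(res$differing1),
    differing_form2 = nrow(res$differing2),
    uncoded_form1 = nrow(res$uncoded1),
    uncoded_form2 = nrow(res$uncoded2)
  )
  res
}

#' @export
#' @rdname match_items
#' @param x,object A `form_comparison`.
#' @param ... Unused.
glance.form_comparison <- function(x, ...) {
  tibble(
    form1_oid = x$form1_oid, form2_oid = x$form2_oid,
    n_identical = unname(x$counts[["identical"]]),
    n_matching = unname(x$counts[["matching"]]),
    n_similar = unname(x$counts[["similar"]]),
    n_differing_form1 = unname(x$counts[["differing_form1"]]),
    n_differing_form2 = unname(x$counts[["differing_form2"]]),
    n_uncoded_form1 = unname(x$counts[["uncoded_form1"]]),
    n_uncoded_form2 = unname(x$counts[["uncoded_form2"]]),
    n_items_form1 = x$n_items1, n_items_form2 = x$n_items2
  )
}

#' @export
#' @rdname match_items
tidy.form_comparison <- function(x, ...) {
  paired <- x$pairs[, c("category", "form1_oid", "form1_name",
                        "form2_oid", "form2_name")]
  one_sided <- function(items, category, side) {
    if (nrow(items) == 0L) {
      return(paired[0, ])
    }
    out <- tibble(category = category,
                  form1_oid = NA_character_, form1_name = NA_character_,
                  form2_oid = NA_character_, form2_name = NA_character_,
                  .rows = nrow(items))
    out[[paste0(side, "_oid")]] <- items$oid
    out[[paste0(side, "_name")]] <- items$name
    out
  }
  bind_rows(
    paired,
    one_sided(x$differing1, "differing", "form1"),
    one_sided(x$differing2, "differing", "form2"),
    one_sided(x$uncoded1, "uncoded", "form1"),
    one_sided(x$uncoded2, "uncoded", "form2")
  )
}

item_line <- function(items, row) {
  it <- as_item_row(items[row, ])
  vd <- it$data_type
  if (!is.na(it$unit)) vd <- paste0(vd, " [", it$unit, "]")
  if (!is.null(it$code_list)) {
    vd <- paste0(vd, " {", paste(it$code_list$coded_value, collapse = "|"), "}")
  }
  codes <- if (length(it$codes)) paste(it$codes, collapse = ", ") else "-"
  sprintf("  %-12s %-45s %-22s %s", it$oid, it$name, vd, codes)
}

#' Render a comparison report as plain text
#'
#' Produces the human-readable aggregated report: one section per
#' category listing each item's OID, name, value-domain summary and
#' concept codes; uncoded items are listed separately with a note that
#' they cannot be compared automatically; a footer gives the counts.
#'
#' @param report A `form_comparison` from [match_items()].
#' @return Character vector of report lines, invisibly printed by
#'   `print.form_comparison()`.
#' @export
render_report <- function(report) {
  stopifnot(inherits(report, "form_comparison"))
  hdr <- sprintf("  %-12s %-45s %-22s %s", "OID", "Name", "Value domain",
                 "Concept codes")
  out <- c(
    sprintf("Comparison of forms '%s' (form 1) and '%s' (form 2)",
            report$form1_oid, report$form2_oid),
    sprintf("Form 1: %d items (%d coded); form 2: %d items (%d coded)",
            report$n_items1, report$n_coded1, report$n_items2, report$n_coded2),
    ""
  )
  pair_section <- function(title, pairs) {
    lines <- c(sprintf("%s (%d):", title, nrow(pairs)))
    if (nrow(pairs) > 0L) lines <- c(lines, hdr)
    for (k in seq_len(nrow(pairs))) {
      lines <- c(lines,
                 paste0(pair_item_line(report, pairs$form1_oid[[k]], 1L)),
                 paste0(pair_item_line(report, pairs$form2_oid[[k]], 2L)),
                 "")
    }
    c(lines, "")
  }
  single_section <- function(title, items, note = NULL) {
    lines <- c(sprintf("%s (%d):", title, nrow(items)))
    if (!is.null(note)) lines <- c(lines, paste0("  (", note, ")"))
    if (nrow(items) > 0L) lines <- c(lines, hdr)
    for (k in seq_len(nrow(items))) lines <- c(lines, item_line(items, k))
    c(lines, "")
  }
  out <- c(out,
           pair_section("Identical items", report$identical_pairs),
           pair_section("Matching items", report$matching_pairs),
           pair_section("Similar items", report$similar_pairs),
           single_section("Differing items in form 1", report$differing1),
           single_section("Differing items in form 2", report$differing2),
           single_section("Uncoded items in form 1", report$uncoded1,
                          "no concept code assigned; automatic comparison not possible"),
           single_section("Uncoded items in form 2", report$uncoded2,
                          "no concept code assigned; automatic comparison not possible"),
           sprintf("Summary: %d identical, %d matching, %d similar; %d/%d differing; %d/%d uncoded (form 1/form 2)",
                   report$counts[["identical"]], report$counts[["matching"]],
                   report$counts[["similar"]], report$counts[["differing_form1"]],
                   report$counts[["differing_form2"]], report$counts[["uncoded_form1"]],
                   report$counts[["uncoded_form2"]]))
  out
}

# Locate the stored item row behind a pair entry and format it.
pair_item_line <- function(report, oid, side) {
  items <- if (side == 1L) report$items1 else report$items2
  item_line(items, match(oid, items$oid))
}

#' @export
print.form_comparison <- function(x, ...) {
  cat(render_report(x), sep = "\n")
  invisible(x)
}
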