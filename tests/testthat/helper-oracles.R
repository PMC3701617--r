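# Independent oracles and small random-input builders used across tests.

# All permutations of a vector (n <= 6 in tests).
all_perms <- function(v) {
  if (length(v) <= 1L) return(list(v))
  out <- list()
  for (i in seq_along(v)) {
    for (p in all_perms(v[-i])) out[[length(out) + 1L]] <- c(v[[i]], p)
  }
  out
}

lex_greater <- function(a, b) {
  for (k in seq_along(a)) {
    if (a[k] != b[k]) return(a[k] > b[k])
  }
  FALSE
}

# Brute-force oracle for the best-fit pairing: enumerate every injective
# pairing between the coded items of two forms and maximise the
# (identical, matching, similar) count triple lexicographically.
# Independent of the three-pass implementation: only classify_pair is
# shared, whose truth table is itself tested exhaustively.
oracle_best_counts <- function(items1, items2) {
  c1 <- items1[lengths(items1$codes) > 0L, ]
  c2 <- items2[lengths(items2$codes) > 0L, ]
  n1 <- nrow(c1); n2 <- nrow(c2)
  if (n1 == 0L || n2 == 0L) return(c(identical = 0L, matching = 0L, similar = 0L))
  cat_m <- matrix("differing", n1, n2)
  for (i in seq_len(n1)) {
    for (j in seq_len(n2)) cat_m[i, j] <- classify_pair(c1[i, ], c2[j, ])
  }
  m <- if (n1 <= n2) cat_m else t(cat_m)
  k <- nrow(m); N <- ncol(m)
  best <- c(identical = 0L, matching = 0L, similar = 0L)
  targets <- utils::combn(N, k, simplify = FALSE)
  for (tg in targets) {
    for (p in all_perms(tg)) {
      cats <- m[cbind(seq_len(k), p)]
      cnt <- c(identical = sum(cats == "identical"),
               matching = sum(cats == "matching"),
               similar = sum(cats == "similar"))
      if (lex_greater(cnt, best)) best <- cnt
    }
  }
  best
}

# Naive agglomerative clustering: repeatedly merge the closest pair of
# clusters (lowest-index tie-break) under the requested linkage and
# record merge heights. Used to validate stats::hclust-based results.
naive_agglomerative_heights <- function(d, linkage = "complete") {
  link_fun <- switch(linkage, complete = max, single = min, average = mean)
  clusters <- as.list(seq_len(nrow(d)))
  heights <- numeric()
  while (length(clusters) > 1L) {
    best <- c(NA, NA); best_d <- Inf
    for (a in seq_len(length(clusters) - 1L)) {
      for (b in seq(a + 1L, length(clusters))) {
        dd <- link_fun(d[clusters[[a]], clusters[[b]]])
        if (dd < best_d) { best_d <- dd; best <- c(a, b) }
      }
    }
    heights <- c(heights, best_d)
    clusters[[best[1L]]] <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters[[best[2L]]] <- NULL
  }
  sort(heights)
}

# Small adversarial forms: codes, names and domains drawn from tiny pools
# so that same-code collisions (and hence non-trivial pairings) are
# frequent. Uncoded items included with probability `p_uncoded`.
random_small_form <- function(n, oid, p_uncoded = 0.15) {
  code_pool <- c("CT01", "CT02", "CT03")
  name_pool <- c("alpha", "beta", "gamma")
  dom_pool <- list(
    list(data_type = "integer", unit = NA_character_, code_list = NULL),
    list(data_type = "float", unit = "mg/dl", code_list = NULL),
    list(data_type = "string", unit = NA_character_,
         code_list = code_list(c("A", "B")))
  )
  rows <- lapply(seq_len(n), function(i) {
    dom <- dom_pool[[sample(3L, 1L)]]
    codes <- if (stats::runif(1) < p_uncoded) character() else
      sample(code_pool, 1L)
    odm_item(sprintf("%s.I%d", oid, i), sample(name_pool, 1L), codes = codes,
             data_type = dom$data_type, unit = dom$unit,
             code_list = dom$code_list)
  })
  odm_form(oid, paste("Form", oid), dplyr::bind_rows(rows))
}

random_symmetric_count_matrix <- function(n, max_count = 20L) {
  m <- matrix(0L, n, n)
  m[upper.tri(m)] <- sample(0:max_count, sum(upper.tri(m)), replace = TRUE)
  m <- m + t(m)
  dimnames(m) <- list(sprintf("F.%d", seq_len(n)), sprintf("F.%d", seq_len(n)))
  m
}

random_feasible_spec <- function(seed) {
  set.seed(seed)
  ni <- sample(0:5, 1); nm <- sample(0:5, 1); ns <- sample(0:5, 1)
  nu1 <- sample(0:3, 1); nu2 <- sample(0:3, 1)
  overlap_spec(
    n1 = ni + nm + ns + nu1 + sample(0:8, 1),
    n2 = ni + nm + ns + nu2 + sample(0:8, 1),
    n_identical = ni, n_matching = nm, n_similar = ns,
    n_uncoded1 = nu1, n_uncoded2 = nu2, seed = seed
  )
}

expect_counts <- function(report, identical, matching, similar) {
  expect_equal(unname(report$counts[["identical"]]), identical)
  expect_equal(unname(report$counts[["matching"]]), matching)
  expect_equal(unname(report$counts[["similar"]]), similar)
}
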