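# Synthetic ODM fixtures with planted, exactly recoverable comparison
# structure. The generators are first-class package code: every planted
# identical/matching/similar pair uses its own concept code, and all
# remaining coded items draw from disjoint code pools, so the comparator
# must recover the planted counts exactly -- the module's core validation
# property.
#
# Placeholder concept codes use the reserved prefix "CX" to make clear
# they are not real UMLS CUIs; the only real CUI used is C1516879 in the
# worked example pair.

# Restore the RNG state afterwards so generators do not perturb callers.
with_seed <- function(seed, code) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", globalenv(), inherits = FALSE))
        rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

SYNTH_WORDS <- c(
  "blood", "pressure", "heart", "rate", "tumor", "stage", "grade", "biopsy",
  "serum", "glucose", "weight", "height", "pain", "score", "therapy", "dose",
  "response", "relapse", "margin", "lymph", "node", "count", "onset", "date",
  "history", "smoking", "alcohol", "allergy", "medication", "surgery",
  "pathology", "imaging", "marker", "antigen", "volume", "diameter", "status",
  "follow", "consent", "screening"
)

SYNTH_UNITS <- c("mg/dl", "mmol/l", "cm", "kg", "ml", "mmHg", "U/l")

# Unique human-readable names: word pair plus a running index, so no two
# generated names collide after normalisation.
make_name_gen <- function() {
  k <- 0L
  function() {
    k <<- k + 1L
    paste(paste(sample(SYNTH_WORDS, 2L), collapse = " "), k)
  }
}

random_domain <- function() {
  dt <- sample(c("boolean", "date", "time", "string", "float", "integer"), 1L)
  unit <- if (dt %in% c("float", "integer") && stats::runif(1) < 0.4)
    sample(SYNTH_UNITS, 1L) else NA_character_
  cl <- NULL
  if (dt == "string" && stats::runif(1) < 0.4) {
    k <- sample(2:4, 1L)
    vals <- paste0("V", seq_len(k))
    cl <- code_list(vals, paste0("value ", seq_len(k)))
  }
  list(data_type = dt, unit = unit, code_list = cl)
}

# Change exactly one aspect of a value domain so the result compares
# unequal: data type, measurement unit, or code-list membership.
perturb_domain <- function(dom) {
  mode <- sample(c("type", "unit", "codelist"), 1L)
  if (mode == "codelist" && is.null(dom$code_list)) mode <- "type"
  if (mode == "type") {
    pool <- setdiff(c("boolean", "date", "time", "string", "float", "integer"),
                    dom$data_type)
    dom$data_type <- sample(pool, 1L)
    if (!dom$data_type %in% c("float", "integer")) dom$unit <- NA_character_
    if (dom$data_type != "string") dom$code_list <- NULL
  } else if (mode == "unit") {
    pool <- if (is.na(dom$unit)) SYNTH_UNITS else setdiff(SYNTH_UNITS, dom$unit)
    if (!dom$data_type %in% c("float", "integer")) dom$data_type <- "float"
    dom$unit <- sample(pool, 1L)
  } else {
    cl <- dom$code_list
    dom$code_list <- code_list(c(cl$coded_value, "VX"),
                               c(cl$display_text, "extra value"))
  }
  dom
}

domain_item <- function(oid, name, codes, dom) {
  odm_item(oid, name, codes = codes, data_type = dom$data_type,
           unit = dom$unit, code_list = dom$code_list)
}

#' Reconstruction of the worked 8-item example form pair
#'
#' Two small forms of 8 data items each, built to exercise every category
#' of the comparison: one identical pair ("Willingness to participate in
#' clinical trials", shared CUI C1516879, boolean domain), two matching
#' pairs ("Date of Birth" vs "Birth date"; "Gender" vs "Sex" with a
#' shared sex code list), two similar pairs ("Serum creatinine" recorded
#' in mg/dl vs mmol/l; "Age" as integer vs free text), three uncoded
#' free-text items in form 1, and three form-2 items coded with unshared
#' codes. Comparing the two forms therefore yields 1 identical, 2
#' matching and 2 similar items, with 3 uncoded items in form 1.
#'
#' All concept codes except C1516879 are fixed synthetic placeholders
#' (prefix `CX`), not real UMLS CUIs. The function is deterministic:
#' repeated calls produce byte-identical ODM via [write_odm()].
#'
#' @return An [odm_study()] with forms `F.COMPARE1` and `F.COMPARE2`.
#' @examples
#' glance(match_items(worked_example_pair()$forms[[1]],
#'                    worked_example_pair()$forms[[2]]))
#' @export
worked_example_pair <- function() {
  sex_cl <- code_list(c("M", "F"), c("male", "female"),
                      codes = list("CX0010", "CX0011"), oid = "CL.SEX")
  f1 <- odm_form("F.COMPARE1", "Example form 1", bind_rows(
    odm_item("I1.1", "Willingness to participate in clinical trials",
             codes = "C1516879", data_type = "boolean"),
    odm_item("I1.2", "Date of Birth", codes = "CX0002", data_type = "date"),
    odm_item("I1.3", "Gender", codes = "CX0003", data_type = "string",
             code_list = sex_cl),
    odm_item("I1.4", "Serum creatinine", codes = "CX0004",
             data_type = "float", unit = "mg/dl"),
    odm_item("I1.5", "Age", codes = "CX0005", data_type = "integer"),
    odm_item("I1.6", "Comments", data_type = "string"),
    odm_item("I1.7", "Examination notes", data_type = "string"),
    odm_item("I1.8", "Other findings", data_type = "string")
  ))
  f2 <- odm_form("F.COMPARE2", "Example form 2", bind_rows(
    odm_item("I2.1", "Willingness to participate in clinical trials",
             codes = "C1516879", data_type = "boolean"),
    odm_item("I2.2", "Birth date", codes = "CX0002", data_type = "date"),
    odm_item("I2.3", "Sex", codes = "CX0003", data_type = "string",
             code_list = sex_cl),
    odm_item("I2.4", "Serum creatinine", codes = "CX0004",
             data_type = "float", unit = "mmol/l"),
    odm_item("I2.5", "Age", codes = "CX0005", data_type = "string"),
    odm_item("I2.6", "Smoking status", codes = "CX0101", data_type = "string"),
    odm_item("I2.7", "Height", codes = "CX0102", data_type = "float",
             unit = "cm"),
    odm_item("I2.8", "Weight", codes = "CX0103", data_type = "float",
             unit = "kg")
  ))
  odm_study(list(f1, f2))
}

#' Specify the planted overlap structure of a synthetic form pair
#'
#' @param n1,n2 Total item counts of the two forms.
#' @param n_identical,n_matching,n_similar Planted pair counts.
#' @param n_uncoded1,n_uncoded2 Planted uncoded item counts per form.
#' @param seed Integer seed; generation is fully reproducible.
#' @return An `overlap_spec` list, validated: planted counts must fit in
#'   both forms and all counts be non-negative.
#' @export
overlap_spec <- function(n1, n2, n_identical = 0, n_matching = 0,
                         n_similar = 0, n_uncoded1 = 0, n_uncoded2 = 0,
                         seed = 1) {
  s <- list(n1 = as.integer(n1), n2 = as.integer(n2),
            n_identical = as.integer(n_identical),
            n_matching = as.integer(n_matching),
            n_similar = as.integer(n_similar),
            n_uncoded1 = as.integer(n_uncoded1),
            n_uncoded2 = as.integer(n_uncoded2), seed = as.integer(seed))
  if (any(unlist(s[1:7]) < 0L)) {
    abort("Overlap-spec counts must be non-negative.", class = "fc_usage_error")
  }
  planted <- s$n_identical + s$n_matching + s$n_similar
  if (planted + s$n_uncoded1 > s$n1) {
    abort(sprintf("Infeasible spec: %d planted + %d uncoded items exceed n1 = %d.",
                  planted, s$n_uncoded1, s$n1), class = "fc_usage_error")
  }
  if (planted + s$n_uncoded2 > s$n2) {
    abort(sprintf("Infeasible spec: %d planted + %d uncoded items exceed n2 = %d.",
                  planted, s$n_uncoded2, s$n2), class = "fc_usage_error")
  }
  structure(s, class = "overlap_spec")
}

#' Generate a form pair with planted comparison structure
#'
#' Builds two ODM-writable forms whose comparison by [match_items()]
#' recovers the planted counts exactly: identical pairs share name,
#' concept code and value domain; matching pairs share code and domain
#' under different names; similar pairs share a code but have a perturbed
#' domain (changed data type, measurement unit or code list); all
#' remaining coded items carry globally unique unshared codes and are
#' therefore differing; uncoded items carry empty code sets. Item order
#' within each form is shuffled (seeded), so recovery does not depend on
#' item placement.
#'
#' @param spec An [overlap_spec()].
#' @param oid1,oid2,name1,name2 Form OIDs and names.
#' @return An [odm_study()] with the two forms.
#' @examples
#' pair <- gen_overlap_pair(overlap_spec(21, 31, n_identical = 4,
#'                                       n_matching = 5, n_similar = 3))
#' glance(match_items(pair$forms[[1]], pair$forms[[2]]))
#' @export
gen_overlap_pair <- function(spec, oid1 = "F.A", oid2 = "F.B",
                             name1 = "Synthetic form A",
                             name2 = "Synthetic form B") {
  stopifnot(inherits(spec, "overlap_spec"))
  with_seed(spec$seed, {
    built <- build_planted_pair(spec, code_prefix = "CX")
    f1 <- finalize_form(built$items1, oid1, name1, oid_prefix = "F1.I")
    f2 <- finalize_form(built$items2, oid2, name2, oid_prefix = "F2.I")
    odm_study(list(f1, f2))
  })
}

# Shared worker: emits the two item lists (without OIDs/order) for one
# planted pair block. Codes are made unique via `code_prefix`.
build_planted_pair <- function(spec, code_prefix) {
  name_gen <- make_name_gen()
  items1 <- list(); items2 <- list()
  code_i <- 0L
  next_code <- function(kind) {
    code_i <<- code_i + 1L
    sprintf("%s%s%04d", code_prefix, kind, code_i)
  }
  for (k in seq_len(spec$n_identical)) {
    nm <- name_gen(); code <- next_code("S"); dom <- random_domain()
    items1[[length(items1) + 1L]] <- list(name = nm, codes = code, dom = dom)
    items2[[length(items2) + 1L]] <- list(name = nm, codes = code, dom = dom)
  }
  for (k in seq_len(spec$n_matching)) {
    code <- next_code("S"); dom <- random_domain()
    items1[[length(items1) + 1L]] <- list(name = name_gen(), codes = code, dom = dom)
    items2[[length(items2) + 1L]] <- list(name = name_gen(), codes = code, dom = dom)
  }
  for (k in seq_len(spec$n_similar)) {
    code <- next_code("S"); dom <- random_domain()
    items1[[length(items1) + 1L]] <- list(name = name_gen(), codes = code, dom = dom)
    items2[[length(items2) + 1L]] <- list(name = name_gen(), codes = code,
                                          dom = perturb_domain(dom))
  }
  n_planted <- spec$n_identical + spec$n_matching + spec$n_similar
  for (k in seq_len(spec$n1 - n_planted - spec$n_uncoded1)) {
    items1[[length(items1) + 1L]] <- list(name = name_gen(),
                                          codes = next_code("A"),
                                          dom = random_domain())
  }
  for (k in seq_len(spec$n2 - n_planted - spec$n_uncoded2)) {
    items2[[length(items2) + 1L]] <- list(name = name_gen(),
                                          codes = next_code("B"),
                                          dom = random_domain())
  }
  for (k in seq_len(spec$n_uncoded1)) {
    items1[[length(items1) + 1L]] <- list(name = name_gen(),
                                          codes = character(),
                                          dom = random_domain())
  }
  for (k in seq_len(spec$n_uncoded2)) {
    items2[[length(items2) + 1L]] <- list(name = name_gen(),
                                          codes = character(),
                                          dom = random_domain())
  }
  list(items1 = items1, items2 = items2)
}

finalize_form <- function(item_list, oid, name, oid_prefix) {
  if (length(item_list) == 0L) return(odm_form(oid, name))
  item_list <- item_list[sample(length(item_list))]
  rows <- lapply(seq_along(item_list), function(i) {
    it <- item_list[[i]]
    item <- domain_item(sprintf("%s%03d", oid_prefix, i), it$name, it$codes,
                        it$dom)
    # code-list OIDs must be unique per item to avoid cross-form clashes
    if (!is.null(item$code_list[[1L]])) {
      item$code_list_oid <- paste0("CL.", item$oid)
    }
    item
  })
  odm_form(oid, name, bind_rows(rows))
}

#' Generate a set of forms with planted pairwise overlap
#'
#' Builds `length(sizes)` forms whose [compare_form_set()] matrices equal
#' the requested pairwise targets exactly. Each listed form pair draws
#' its shared items from a pair-specific concept-code pool used by no
#' other pair (pairwise-independent overlap), and all remaining coded
#' items get globally unique codes; unlisted pairs therefore share
#' nothing.
#'
#' @param sizes Integer vector of per-form item counts.
#' @param overlaps Data frame with columns `form1`, `form2` (form
#'   indices) and planted counts `identical`, `matching`, `similar`
#'   (missing columns default to 0); at most one row per unordered pair.
#' @param seed Integer seed.
#' @param form_oids,form_names Optional identifiers (defaults `F.1` ...).
#' @param n_uncoded Integer vector of planted uncoded items per form.
#' @return An [odm_study()] of the generated forms.
#' @export
gen_form_set <- function(sizes, overlaps = NULL, seed = 1,
                         form_oids = sprintf("F.%d", seq_along(sizes)),
                         form_names = sprintf("Synthetic form %d", seq_along(sizes)),
                         n_uncoded = rep(0L, length(sizes))) {
  n <- length(sizes)
  stopifnot(n >= 1L, length(form_oids) == n, length(form_names) == n,
            length(n_uncoded) == n)
  if (is.null(overlaps)) {
    overlaps <- data.frame(form1 = integer(), form2 = integer())
  }
  overlaps <- as_tibble(overlaps)
  for (col in c("identical", "matching", "similar")) {
    if (is.null(overlaps[[col]])) overlaps[[col]] <- rep(0L, nrow(overlaps))
  }
  if (nrow(overlaps) > 0L) {
    swap <- overlaps$form1 > overlaps$form2
    tmp <- overlaps$form1[swap]
    overlaps$form1[swap] <- overlaps$form2[swap]
    overlaps$form2[swap] <- tmp
    if (any(overlaps$form1 == overlaps$form2) ||
        any(overlaps$form1 < 1L | overlaps$form2 > n)) {
      abort("Overlap targets must reference two distinct forms within the set.",
            class = "fc_usage_error")
    }
    key <- paste(overlaps$form1, overlaps$form2)
    if (anyDuplicated(key)) {
      abort("At most one overlap target per form pair is supported.",
            class = "fc_usage_error")
    }
  }
  load <- n_uncoded
  for (r in seq_len(nrow(overlaps))) {
    planted <- overlaps$identical[r] + overlaps$matching[r] + overlaps$similar[r]
    load[overlaps$form1[r]] <- load[overlaps$form1[r]] + planted
    load[overlaps$form2[r]] <- load[overlaps$form2[r]] + planted
  }
  bad <- which(load > sizes)
  if (length(bad) > 0L) {
    abort(sprintf(
      "Infeasible overlap system: form %d needs %d planted/uncoded items but has size %d.",
      bad[1L], load[bad[1L]], sizes[bad[1L]]), class = "fc_usage_error")
  }

  with_seed(seed, {
    pools <- rep(list(list()), n)  # per-form lists of item prototypes
    for (r in seq_len(nrow(overlaps))) {
      ps <- overlap_spec(
        n1 = overlaps$identical[r] + overlaps$matching[r] + overlaps$similar[r],
        n2 = overlaps$identical[r] + overlaps$matching[r] + overlaps$similar[r],
        n_identical = overlaps$identical[r], n_matching = overlaps$matching[r],
        n_similar = overlaps$similar[r], seed = 0
      )
      blk <- build_planted_pair(ps, code_prefix = sprintf("CXP%03d.", r))
      i <- overlaps$form1[r]; j <- overlaps$form2[r]
      pools[[i]] <- c(pools[[i]], blk$items1)
      pools[[j]] <- c(pools[[j]], blk$items2)
    }
    name_gen <- make_name_gen()
    forms <- lapply(seq_len(n), function(f) {
      items <- pools[[f]]
      n_fill <- sizes[f] - length(items) - n_uncoded[f]
      for (k in seq_len(n_fill)) {
        items[[length(items) + 1L]] <- list(
          name = name_gen(), codes = sprintf("CXU%03d.%04d", f, k),
          dom = random_domain())
      }
      for (k in seq_len(n_uncoded[f])) {
        items[[length(items) + 1L]] <- list(name = name_gen(),
                                            codes = character(),
                                            dom = random_domain())
      }
      finalize_form(items, form_oids[f], form_names[f],
                    oid_prefix = sprintf("F%d.I", f))
    })
    odm_study(forms)
  })
}

#' Seven-form synthetic set shaped like the evaluation form set
#'
#' A preset of 7 prostate-cancer-themed synthetic forms with 285 items in
#' total (minimum 5, maximum 87, mean 41 after rounding) and two planted
#' overlaps: 48 identical items between the medical-history and
#' pathological-report forms and 18 between the epidemiological-registry
#' and quality-management forms; the remaining pairs share nothing. This
#' mirrors the summary shape of a real evaluation corpus that cannot be
#' redistributed; all content here is synthetic.
#'
#' @param seed Integer seed.
#' @return An [odm_study()] of 7 forms.
#' @export
evaluation_form_set <- function(seed = 1) {
  gen_form_set(
    sizes = c(87L, 64L, 48L, 35L, 27L, 19L, 5L),
    overlaps = data.frame(form1 = c(1L, 3L), form2 = c(2L, 4L),
                          identical = c(48L, 18L), matching = 0L, similar = 0L),
    seed = seed,
    form_oids = sprintf("F.%d", 1:7),
    form_names = c("Medical history", "Pathological report",
                   "Epidemiological cancer registry",
                   "Quality management: cancer documentation",
                   "Quality management: follow-up",
                   "Routine care: admission", "Routine care: discharge")
  )
}

#' Two-group form set with planted cluster structure
#'
#' Two groups of forms with high within-group and zero between-group
#' overlap, for validating that hierarchical clustering separates the
#' groups.
#'
#' @param seed Integer seed.
#' @param group_size Forms per group.
#' @param n_items Items per form.
#' @param overlap Identical items planted per within-group pair.
#' @return An [odm_study()] of `2 * group_size` forms; the first
#'   `group_size` form OIDs are prefixed `F.A`, the rest `F.B`.
#' @export
two_group_form_set <- function(seed = 1, group_size = 3, n_items = 24,
                               overlap = 8) {
  n <- 2L * group_size
  within <- function(offset) {
    idx <- utils::combn(seq_len(group_size) + offset, 2L)
    data.frame(form1 = idx[1, ], form2 = idx[2, ], identical = overlap,
               matching = 0L, similar = 0L)
  }
  gen_form_set(
    sizes = rep(as.integer(n_items), n),
    overlaps = rbind(within(0L), within(group_size)),
    seed = seed,
    form_oids = c(sprintf("F.A%d", seq_len(group_size)),
                  sprintf("F.B%d", seq_len(group_size)))
  )
}
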