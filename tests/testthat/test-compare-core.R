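test_that("name normalisation trims, collapses whitespace, folds case and Unicode form", {
  expect_equal(normalize_name("  Date of   Birth "), "date of birth")
  expect_equal(normalize_name(""), "")
  composed <- "Größe"                 # o-umlaut as one code point
  decomposed <- "Größe"              # o + combining diaeresis
  expect_equal(normalize_name(composed), normalize_name(decomposed))
  expect_equal(normalize_name(c("A\tB", " x ")), c("a b", "x"))
})

test_that("value-domain equality covers types, units and code lists symmetrically", {
  mgdl <- odm_item("I.1", "serum creatinine", codes = "C1", data_type = "float",
                   unit = "mg/dl")
  mmoll <- odm_item("I.2", "serum creatinine", codes = "C1", data_type = "float",
                    unit = "mmol/l")
  expect_false(value_domains_equal(mgdl, mmoll))   # the creatinine case
  expect_true(value_domains_equal(mgdl, mgdl))     # reflexive
  expect_equal(value_domains_equal(mgdl, mmoll), value_domains_equal(mmoll, mgdl))

  no_unit <- odm_item("I.3", "x", codes = "C1", data_type = "float")
  expect_true(value_domains_equal(no_unit, no_unit))
  expect_false(value_domains_equal(no_unit, mgdl))

  int_item <- odm_item("I.4", "x", codes = "C1", data_type = "integer")
  expect_false(value_domains_equal(no_unit, int_item))
})

test_that("code lists compare as sets, by coded value and entry codes, ignoring display text", {
  base <- code_list(c("M", "F"), c("male", "female"),
                    codes = list("C0024554", "C0015780"))
  permuted <- code_list(c("F", "M"), c("Frau", "Mann"),
                        codes = list("C0015780", "C0024554"))
  a <- odm_item("I.1", "sex", codes = "C1", data_type = "string", code_list = base)
  b <- odm_item("I.2", "sex", codes = "C1", data_type = "string", code_list = permuted)
  expect_true(value_domains_equal(a, b))

  # random permutations of larger generated code lists
  set.seed(42)
  for (k in 1:10) {
    vals <- paste0("V", sample(20, sample(2:6, 1)))
    cl1 <- code_list(vals, paste0("d", seq_along(vals)))
    perm <- sample(length(vals))
    cl2 <- code_list(vals[perm], paste0("e", seq_along(vals)))
    x <- odm_item("I.1", "x", codes = "C1", data_type = "string", code_list = cl1)
    y <- odm_item("I.2", "x", codes = "C1", data_type = "string", code_list = cl2)
    expect_true(value_domains_equal(x, y))
  }

  other_vals <- odm_item("I.3", "sex", codes = "C1", data_type = "string",
                         code_list = code_list(c("M", "F", "U")))
  expect_false(value_domains_equal(a, other_vals))
  no_cl <- odm_item("I.4", "sex", codes = "C1", data_type = "string")
  expect_false(value_domains_equal(a, no_cl))
  # same values but conflicting entry annotations
  conflict <- code_list(c("M", "F"), codes = list("C0024554", "CXXXX"))
  c_item <- odm_item("I.5", "sex", codes = "C1", data_type = "string",
                     code_list = conflict)
  expect_false(value_domains_equal(a, c_item))
  # one side unannotated: codes are not required to agree
  bare <- odm_item("I.6", "sex", codes = "C1", data_type = "string",
                   code_list = code_list(c("M", "F")))
  expect_true(value_domains_equal(a, bare))
})

test_that("pair classification follows the four-category truth table", {
  dom_a <- list(data_type = "date", unit = NA_character_, code_list = NULL)
  dom_b <- list(data_type = "string", unit = NA_character_, code_list = NULL)
  mk <- function(name, codes, dom) {
    odm_item("I.x", name, codes = codes, data_type = dom$data_type,
             unit = dom$unit, code_list = dom$code_list)
  }
  a <- mk("birth date", "C2004062", dom_a)
  # exhaustive over (codes equal, domains equal, names equal)
  for (codes_eq in c(TRUE, FALSE)) {
    for (dom_eq in c(TRUE, FALSE)) {
      for (name_eq in c(TRUE, FALSE)) {
        b <- mk(if (name_eq) "Birth  Date" else "date of birth",
                if (codes_eq) "C2004062" else "C9999999",
                if (dom_eq) dom_a else dom_b)
        expected <- if (!codes_eq) "differing"
          else if (!dom_eq) "similar"
          else if (name_eq) "identical" else "matching"
        expect_equal(classify_pair(a, b), expected)
        expect_equal(classify_pair(b, a), expected)  # symmetric
      }
    }
  }
})

test_that("the birth-date and creatinine textbook examples classify as stated", {
  bd <- odm_item("I.1", "birth date", codes = "C2004062", data_type = "date")
  dob <- odm_item("I.2", "date of birth", codes = "C2004062", data_type = "date")
  expect_equal(classify_pair(bd, dob), "matching")

  cr1 <- odm_item("I.3", "serum creatinine", codes = "C0201976",
                  data_type = "float", unit = "mg/dl")
  cr2 <- odm_item("I.4", "serum creatinine", codes = "C0201976",
                  data_type = "float", unit = "mmol/l")
  expect_equal(classify_pair(cr1, cr2), "similar")
})

test_that("any coded item is identical to itself; uncoded items are refused", {
  it <- odm_item("I.1", "age", codes = c("C0001779", "C0011900"),
                 data_type = "integer")
  expect_equal(classify_pair(it, it), "identical")
  uncoded <- odm_item("I.2", "comments")
  expect_error(classify_pair(it, uncoded), class = "fc_uncoded")
})

test_that("postcoordinated code sets compare by exact set equality", {
  ab <- odm_item("I.1", "x", codes = c("C1", "C2"), data_type = "string")
  ba <- odm_item("I.2", "x", codes = c("C2", "C1"), data_type = "string")
  a_only <- odm_item("I.3", "x", codes = "C1", data_type = "string")
  expect_equal(classify_pair(ab, ba), "identical")
  expect_equal(classify_pair(ab, a_only), "differing")  # no partial credit
})

test_that("the worked example pair aggregates to 1 identical, 2 matching, 2 similar, 3 uncoded", {
  pair <- worked_example_pair()
  rep <- match_items(pair$forms[[1]], pair$forms[[2]])
  expect_counts(rep, identical = 1L, matching = 2L, similar = 2L)
  expect_equal(unname(rep$counts[["uncoded_form1"]]), 3L)
  expect_equal(unname(rep$counts[["differing_form2"]]), 3L)
  expect_equal(unname(rep$counts[["differing_form1"]]), 0L)
})

test_that("a form compared with itself is identical on every coded item", {
  form <- gen_overlap_pair(overlap_spec(12, 12, n_identical = 3, n_uncoded1 = 2,
                                        seed = 5))$forms[[1]]
  rep <- match_items(form, form)
  n_coded <- sum(coded_mask(form))
  expect_counts(rep, identical = n_coded, matching = 0L, similar = 0L)
  expect_equal(unname(rep$counts[["differing_form1"]]), 0L)
})

test_that("two items sharing one code against a single counterpart yield one pair plus one leftover", {
  f1 <- odm_form("F.1", "f1", dplyr::bind_rows(
    odm_item("I.1", "first", codes = "C1", data_type = "string"),
    odm_item("I.2", "second", codes = "C1", data_type = "string")
  ))
  f2 <- odm_form("F.2", "f2",
                 odm_item("J.1", "third", codes = "C1", data_type = "string"))
  rep <- match_items(f1, f2)
  expect_counts(rep, identical = 0L, matching = 1L, similar = 0L)
  expect_equal(unname(rep$counts[["differing_form1"]]), 1L)
  expect_equal(unname(rep$counts[["differing_form2"]]), 0L)
  # deterministic document-order tie-break: the first form-1 item is taken
  expect_equal(rep$matching_pairs$form1_oid, "I.1")
})

test_that("empty item lists yield an all-empty report", {
  e <- odm_form("F.E", "empty")
  rep <- match_items(e, e)
  expect_true(all(rep$counts == 0L))
  expect_equal(nrow(tidy(rep)), 0L)
})

test_that("the rendered report lists OIDs, names, domains, codes and counts", {
  pair <- worked_example_pair()
  rep <- match_items(pair$forms[[1]], pair$forms[[2]])
  txt <- render_report(rep)
  expect_true(any(grepl("C1516879", txt)))
  expect_true(any(grepl("Identical items \\(1\\)", txt)))
  expect_true(any(grepl("Matching items \\(2\\)", txt)))
  expect_true(any(grepl("Similar items \\(2\\)", txt)))
  expect_true(any(grepl("Uncoded items in form 1 \\(3\\)", txt)))
  expect_true(any(grepl("mg/dl", txt)))
  for (oid in rep$uncoded1$oid) expect_true(any(grepl(oid, txt, fixed = TRUE)))

  empty <- match_items(odm_form("F.E", "e"), odm_form("F.F", "f"))
  etxt <- render_report(empty)
  expect_true(any(grepl("Identical items \\(0\\)", etxt)))
})

test_that("tidy() accounts for every item exactly once", {
  pair <- gen_overlap_pair(overlap_spec(10, 14, n_identical = 2, n_matching = 3,
                                        n_similar = 1, n_uncoded1 = 2,
                                        n_uncoded2 = 1, seed = 9))
  rep <- match_items(pair$forms[[1]], pair$forms[[2]])
  td <- tidy(rep)
  oids1 <- td$form1_oid[!is.na(td$form1_oid)]
  oids2 <- td$form2_oid[!is.na(td$form2_oid)]
  expect_setequal(oids1, pair$forms[[1]]$oid)
  expect_setequal(oids2, pair$forms[[2]]$oid)
  expect_false(anyDuplicated(oids1) > 0)
  expect_false(anyDuplicated(oids2) > 0)
  g <- glance(rep)
  expect_equal(g$n_identical + g$n_matching + g$n_similar +
                 g$n_differing_form1 + g$n_uncoded_form1, g$n_items_form1)
})
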