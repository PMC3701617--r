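test_that("the worked example fixture parses into two 8-item forms in stable order", {
  f <- write_tmp_xml("")  # placeholder path; overwritten by write_odm
  write_odm(worked_example_pair(), f)
  study <- parse_odm(f)
  expect_length(study$forms, 2L)
  expect_equal(unname(vapply(study$forms, nrow, 1L)), c(8L, 8L))
  expect_equal(form_oid(study$forms[[1]]), "F.COMPARE1")
  expect_equal(study$forms[[1]]$name[1],
               "Willingness to participate in clinical trials")
  expect_equal(study$forms[[1]]$codes[[1]], "C1516879")

  again <- parse_odm(f)
  expect_identical(lapply(again$forms, function(x) x$oid),
                   lapply(study$forms, function(x) x$oid))
})

test_that("a document with zero FormDefs yields an empty study", {
  path <- write_tmp_xml(odm_doc(""))
  study <- parse_odm(path)
  expect_length(study$forms, 0L)
})

test_that("concept codes are harvested from Alias elements with trimming and de-duplication", {
  item <- paste0(
    '<ItemDef OID="I.1" Name="x" DataType="boolean">',
    '<Alias Context="UMLS" Name=" C1516879 "/>',
    '<Alias Context="UMLS" Name="C1516879"/>',
    '<Alias Context="UMLS" Name="C0001779"/>',
    '<Alias Context="SNOMED" Name="12345"/>',
    '</ItemDef>'
  )
  study <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item))))
  # postcoordination: two UMLS codes, duplicate collapsed, other context ignored
  expect_setequal(study$forms[[1]]$codes[[1]], c("C1516879", "C0001779"))

  snomed <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item))),
                      contexts = c("SNOMED"))
  expect_equal(snomed$forms[[1]]$codes[[1]], "12345")

  node <- xml2::xml_find_first(xml2::xml_ns_strip(xml2::read_xml(paste0(
    "<root>", item, "</root>"))), ".//ItemDef")
  expect_setequal(extract_concept_codes(node), c("C1516879", "C0001779"))
  expect_equal(extract_concept_codes(node, contexts = "MeSH"), character())
})

test_that("items without annotations parse as uncoded, a legal state", {
  item <- '<ItemDef OID="I.1" Name="Comments" DataType="string"/>'
  study <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item))))
  expect_equal(study$forms[[1]]$codes[[1]], character())
  expect_false(any(coded_mask(study$forms[[1]])))
})

test_that("namespaced and namespace-free documents parse identically", {
  item <- paste0('<ItemDef OID="I.1" Name="x" DataType="integer">',
                 '<Alias Context="UMLS" Name="C1"/></ItemDef>')
  with_ns <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item), xmlns = TRUE)))
  without_ns <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item), xmlns = FALSE)))
  expect_equal(as.data.frame(with_ns$forms[[1]]),
               as.data.frame(without_ns$forms[[1]]))
})

test_that("unresolvable references are structural errors naming the OID", {
  missing_item <- paste0(
    '<FormDef OID="F.1" Name="f" Repeating="No">',
    '<ItemGroupRef ItemGroupOID="IG.1" Mandatory="No"/></FormDef>',
    '<ItemGroupDef OID="IG.1" Name="g" Repeating="No">',
    '<ItemRef ItemOID="I.MISSING" Mandatory="No"/></ItemGroupDef>'
  )
  expect_error(parse_odm(write_tmp_xml(odm_doc(missing_item))),
               "I.MISSING", class = "fc_structure_error")

  dangling_cl <- one_item_mdv(paste0(
    '<ItemDef OID="I.1" Name="x" DataType="string">',
    '<CodeListRef CodeListOID="CL.MISSING"/></ItemDef>'))
  expect_error(parse_odm(write_tmp_xml(odm_doc(dangling_cl))),
               "CL.MISSING", class = "fc_structure_error")

  missing_group <- '<FormDef OID="F.1" Name="f" Repeating="No">
     <ItemGroupRef ItemGroupOID="IG.MISSING" Mandatory="No"/></FormDef>'
  expect_error(parse_odm(write_tmp_xml(odm_doc(missing_group))),
               "IG.MISSING", class = "fc_structure_error")
})

test_that("malformed XML and missing files raise parse errors", {
  expect_error(parse_odm(write_tmp_xml("<ODM><unclosed>")),
               class = "fc_parse_error")
  expect_error(parse_odm(file.path(tempdir(), "does-not-exist.xml")),
               class = "fc_parse_error")
})

test_that("unknown data types map to 'other' with a warning, not an error", {
  item <- '<ItemDef OID="I.1" Name="x" DataType="partialDatetime"/>'
  expect_warning(
    study <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item)))),
    "partialDatetime")
  expect_equal(study$forms[[1]]$data_type[1], "other")
})

test_that("only the first of several MeasurementUnitRefs is used, with a warning", {
  bd <- paste0(
    '<BasicDefinitions>',
    '<MeasurementUnit OID="MU.1" Name="mg/dl"><Symbol>',
    '<TranslatedText xml:lang="en">mg/dl</TranslatedText></Symbol></MeasurementUnit>',
    '<MeasurementUnit OID="MU.2" Name="mmol/l"><Symbol>',
    '<TranslatedText xml:lang="en">mmol/l</TranslatedText></Symbol></MeasurementUnit>',
    '</BasicDefinitions>')
  item <- paste0('<ItemDef OID="I.1" Name="x" DataType="float">',
                 '<MeasurementUnitRef MeasurementUnitOID="MU.1"/>',
                 '<MeasurementUnitRef MeasurementUnitOID="MU.2"/></ItemDef>')
  expect_warning(
    study <- parse_odm(write_tmp_xml(odm_doc(one_item_mdv(item), basic_defs = bd))),
    "MeasurementUnitRef")
  expect_equal(study$forms[[1]]$unit[1], "mg/dl")
})

test_that("item order follows group order then OrderNumber within groups", {
  mdv <- paste0(
    '<FormDef OID="F.1" Name="f" Repeating="No">',
    '<ItemGroupRef ItemGroupOID="IG.1" Mandatory="No" OrderNumber="2"/>',
    '<ItemGroupRef ItemGroupOID="IG.2" Mandatory="No" OrderNumber="1"/>',
    '</FormDef>',
    '<ItemGroupDef OID="IG.1" Name="g1" Repeating="No">',
    '<ItemRef ItemOID="I.1" Mandatory="No" OrderNumber="2"/>',
    '<ItemRef ItemOID="I.2" Mandatory="No" OrderNumber="1"/></ItemGroupDef>',
    '<ItemGroupDef OID="IG.2" Name="g2" Repeating="No">',
    '<ItemRef ItemOID="I.3" Mandatory="No"/></ItemGroupDef>',
    '<ItemDef OID="I.1" Name="a" DataType="string"/>',
    '<ItemDef OID="I.2" Name="b" DataType="string"/>',
    '<ItemDef OID="I.3" Name="c" DataType="string"/>'
  )
  study <- parse_odm(write_tmp_xml(odm_doc(mdv)))
  expect_equal(study$forms[[1]]$oid, c("I.3", "I.2", "I.1"))
  # item accounting: one parsed row per reachable ItemRef
  expect_equal(nrow(study$forms[[1]]), 3L)
})

test_that("write -> parse round trip preserves items, codes and value domains", {
  study <- gen_overlap_pair(overlap_spec(9, 11, n_identical = 2, n_matching = 2,
                                         n_similar = 2, n_uncoded1 = 1,
                                         n_uncoded2 = 2, seed = 1))
  path <- write_tmp_xml("")
  write_odm(study, path)
  back <- parse_odm(path)
  expect_equal(names(back$forms), names(study$forms))
  for (k in seq_along(study$forms)) {
    a <- study$forms[[k]]; b <- back$forms[[k]]
    expect_equal(b$oid, a$oid)
    expect_equal(b$name, a$name)
    expect_equal(b$codes, a$codes)
    expect_equal(b$data_type, a$data_type)
    expect_equal(b$unit, a$unit)
    for (i in seq_len(nrow(a))) {
      ca <- a$code_list[[i]]; cb <- b$code_list[[i]]
      expect_equal(is.null(ca), is.null(cb))
      if (!is.null(ca)) {
        expect_equal(cb$coded_value, ca$coded_value)
        expect_equal(cb$codes, ca$codes)
      }
    }
  }
})

test_that("a study containing an empty form round trips", {
  study <- odm_study(list(
    odm_form("F.E", "Empty form"),
    odm_form("F.X", "One item", odm_item("I.1", "x", codes = "C1"))
  ))
  path <- write_tmp_xml("")
  write_odm(study, path)
  back <- parse_odm(path)
  expect_equal(nrow(back$forms[["F.E"]]), 0L)
  expect_equal(nrow(back$forms[["F.X"]]), 1L)
})

test_that("duplicate OIDs are rejected before writing", {
  expect_error(
    odm_study(list(odm_form("F.1", "a"), odm_form("F.1", "b"))),
    class = "fc_invalid_study")
  dup_items <- odm_study(list(
    odm_form("F.1", "a", odm_item("I.1", "x")),
    odm_form("F.2", "b", odm_item("I.1", "y"))
  ))
  expect_error(write_odm(dup_items, tempfile(fileext = ".xml")),
               class = "fc_invalid_study")
})
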