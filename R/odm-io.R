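# ODM 1.3 study-metadata I/O.
#
# Forms are represented as tibbles with one row per data item and the
# columns documented in `odm_item()`; concept codes and code lists live in
# list-columns so that postcoordinated items (several codes) and enumerated
# value domains need no auxiliary tables.

#' Construct a single ODM data item
#'
#' Builds a one-row tibble describing one data item of a form: its OID, its
#' human-readable name, its concept-code annotations and its value domain
#' (data type, optional measurement unit, optional code list). An item with
#' an empty `codes` vector is \emph{uncoded} and is excluded from automatic
#' comparison.
#'
#' @param oid Item OID, unique within a study.
#' @param name Human-readable item name (non-empty).
#' @param codes Character vector of concept codes (e.g. UMLS CUIs such as
#'   `"C1516879"`). Whitespace is trimmed and duplicates dropped; may be
#'   empty (uncoded item).
#' @param data_type One of `"boolean"`, `"date"`, `"time"`, `"string"`,
#'   `"float"`, `"integer"`, `"other"`.
#' @param unit Optional measurement-unit label (e.g. `"mg/dl"`); `NA` for
#'   none.
#' @param code_list Optional code list created with [code_list()]; `NULL`
#'   for none.
#' @return A one-row tibble with columns `oid`, `name`, `codes`
#'   (list-column), `data_type`, `unit`, `code_list` (list-column),
#'   `code_list_oid`.
#' @examples
#' odm_item("I.1", "Willingness to participate in clinical trials",
#'          codes = "C1516879", data_type = "boolean")
#' @export
odm_item <- function(oid, name, codes = character(), data_type = "string",
                     unit = NA_character_, code_list = NULL) {
  stopifnot(is.character(oid), length(oid) == 1L)
  if (!is.character(name) || length(name) != 1L || !nzchar(name)) {
    abort("`name` must be a non-empty string.", class = "fc_invalid_item")
  }
  data_type <- tolower(data_type)
  if (!data_type %in% ODM_DATA_TYPES) {
    warn(sprintf("Unknown data type '%s' for item '%s'; mapped to 'other'.",
                 data_type, oid))
    data_type <- "other"
  }
  codes <- unique(trimws(as.character(codes)))
  codes <- codes[nzchar(codes)]
  if (!is.null(code_list)) {
    stopifnot(is.data.frame(code_list))
    if (nrow(code_list) == 0L) {
      abort("A code list, when present, must be non-empty.",
            class = "fc_invalid_item")
    }
  }
  cl_oid <- if (is.null(code_list)) NA_character_ else
    attr(code_list, "code_list_oid") %||% paste0("CL.", oid)
  tibble(
    oid = oid, name = name, codes = list(codes),
    data_type = data_type, unit = as.character(unit),
    code_list = list(code_list), code_list_oid = cl_oid
  )
}

#' Construct a code list (enumerated value domain)
#'
#' @param coded_values Character vector of stored values (unique).
#' @param display_texts Optional decode labels, same length.
#' @param codes Optional list of concept-code character vectors, one per
#'   entry (annotation of the permissible values themselves).
#' @param oid Optional code-list OID used when writing ODM.
#' @return A tibble with columns `coded_value`, `display_text`, `codes`,
#'   carrying attribute `code_list_oid`.
#' @examples
#' code_list(c("M", "F"), c("male", "female"))
#' @export
code_list <- function(coded_values, display_texts = coded_values,
                      codes = NULL, oid = NULL) {
  coded_values <- as.character(coded_values)
  if (anyDuplicated(coded_values)) {
    abort("Coded values must be unique within a code list.",
          class = "fc_invalid_item")
  }
  if (is.null(codes)) codes <- rep(list(character()), length(coded_values))
  cl <- tibble(coded_value = coded_values,
               display_text = as.character(display_texts),
               codes = map(codes, ~ unique(trimws(as.character(.x)))))
  attr(cl, "code_list_oid") <- oid
  cl
}

#' Assemble items into a form
#'
#' @param oid Form OID.
#' @param name Form name.
#' @param items Tibble of item rows, usually `dplyr::bind_rows()` of
#'   [odm_item()] calls; may have zero rows (degenerate form).
#' @return An `odm_form`: the item tibble with attributes `form_oid` and
#'   `form_name`.
#' @export
odm_form <- function(oid, name, items = odm_item("I.0", "x")[0, ]) {
  stopifnot(is.data.frame(items))
  if (anyDuplicated(items$oid)) {
    abort(sprintf("Duplicate item OIDs in form '%s': %s", oid,
                  paste(unique(items$oid[duplicated(items$oid)]), collapse = ", ")),
          class = "fc_invalid_study")
  }
  items <- as_tibble(items)
  attr(items, "form_oid") <- oid
  attr(items, "form_name") <- name
  class(items) <- c("odm_form", class(items))
  items
}

#' @export
print.odm_form <- function(x, ...) {
  cat(sprintf("<odm_form> %s (%s): %d items, %d coded\n",
              form_oid(x), form_name(x), nrow(x), sum(coded_mask(x))))
  NextMethod()
}

#' Form accessors
#'
#' `form_oid()` and `form_name()` read the identifying attributes of an
#' `odm_form`; `coded_mask()` flags items carrying at least one concept
#' code.
#' @param form An `odm_form`.
#' @return A string, or a logical vector for `coded_mask()`.
#' @export
form_oid <- function(form) attr(form, "form_oid") %||% NA_character_

#' @rdname form_oid
#' @export
form_name <- function(form) attr(form, "form_name") %||% NA_character_

#' @rdname form_oid
#' @export
coded_mask <- function(form) lengths(form$codes) > 0L

#' Bundle forms into a study
#'
#' @param forms List of `odm_form` objects with unique form OIDs.
#' @param source_path Provenance string (file path for parsed studies).
#' @return An `odm_study` (list with elements `forms`, `source_path`).
#' @export
odm_study <- function(forms, source_path = NA_character_) {
  oids <- map_chr(forms, form_oid)
  if (anyDuplicated(oids)) {
    abort(sprintf("Duplicate form OIDs in study: %s",
                  paste(unique(oids[duplicated(oids)]), collapse = ", ")),
          class = "fc_invalid_study")
  }
  structure(list(forms = setNames(forms, oids), source_path = source_path),
            class = "odm_study")
}

#' @export
print.odm_study <- function(x, ...) {
  cat(sprintf("<odm_study> %d form(s)%s\n", length(x$forms),
              if (is.na(x$source_path)) "" else paste0(" from ", x$source_path)))
  for (f in x$forms) {
    cat(sprintf("  %s (%s): %d items\n", form_oid(f), form_name(f), nrow(f)))
  }
  invisible(x)
}

# ---------------------------------------------------------------------------
# Parsing

# Namespace-agnostic child lookup: ODM exports differ in whether they declare
# the CDISC namespace, so all matching is on local element names.
xml_children_named <- function(node, name) {
  kids <- xml2::xml_children(node)
  kids[xml2::xml_name(kids) == name]
}

xml_find_local <- function(node, name) {
  xml2::xml_find_all(node, sprintf(".//*[local-name()='%s']", name))
}

translated_text <- function(node) {
  tt <- xml2::xml_find_first(node, ".//*[local-name()='TranslatedText']")
  if (inherits(tt, "xml_missing")) NA_character_ else trimws(xml2::xml_text(tt))
}

#' Extract concept codes from an ODM item element
#'
#' Concept codes are read from ODM `Alias` children whose `Context`
#' attribute is one of `contexts` (the standard ODM extension point for
#' external vocabularies). Codes are whitespace-trimmed and de-duplicated;
#' an element without such annotations yields an empty set (an uncoded
#' item, a legal state).
#'
#' @param item_element An `xml2` node for an `ItemDef` (or any element
#'   carrying `Alias` children, e.g. a `CodeListItem`).
#' @param contexts Character vector of annotation-context labels to accept
#'   (default `"UMLS"`).
#' @return Character vector of concept codes (possibly empty).
#' @export
extract_concept_codes <- function(item_element, contexts = "UMLS") {
  aliases <- xml_children_named(item_element, "Alias")
  if (length(aliases) == 0L) return(character())
  ctx <- xml2::xml_attr(aliases, "Context")
  nm <- xml2::xml_attr(aliases, "Name")
  out <- trimws(nm[!is.na(ctx) & trimws(ctx) %in% contexts & !is.na(nm)])
  unique(out[nzchar(out)])
}

# Order a node-set of *Ref elements by OrderNumber when all carry one,
# otherwise keep document order (both are legal ODM).
order_refs <- function(refs) {
  if (length(refs) == 0L) return(refs)
  ord <- suppressWarnings(as.numeric(xml2::xml_attr(refs, "OrderNumber")))
  if (!anyNA(ord)) refs <- refs[order(ord)]
  refs
}

parse_code_list <- function(cl_node, contexts) {
  entries <- xml2::xml_children(cl_node)
  entries <- entries[xml2::xml_name(entries) %in% c("CodeListItem", "EnumeratedItem")]
  if (length(entries) == 0L) {
    abort(sprintf("CodeList '%s' has no entries.", xml2::xml_attr(cl_node, "OID")),
          class = "fc_structure_error")
  }
  code_list(
    coded_values = xml2::xml_attr(entries, "CodedValue"),
    display_texts = map_chr(entries, function(e) {
      dt <- translated_text(e)
      if (is.na(dt)) xml2::xml_attr(e, "CodedValue") else dt
    }),
    codes = map(entries, extract_concept_codes, contexts = contexts),
    oid = xml2::xml_attr(cl_node, "OID")
  )
}

parse_item_def <- function(node, code_lists, units, contexts) {
  oid <- xml2::xml_attr(node, "OID")
  nm <- xml2::xml_attr(node, "Name")
  dt_raw <- xml2::xml_attr(node, "DataType")
  if (is.na(dt_raw)) dt_raw <- "string"
  dt <- tolower(dt_raw)
  if (!dt %in% ODM_DATA_TYPES) {
    warn(sprintf("ItemDef '%s': unknown DataType '%s' mapped to 'other'.",
                 oid, dt_raw))
    dt <- "other"
  }

  mu_refs <- xml_children_named(node, "MeasurementUnitRef")
  unit <- NA_character_
  if (length(mu_refs) > 0L) {
    if (length(mu_refs) > 1L) {
      warn(sprintf("ItemDef '%s' has %d MeasurementUnitRefs; using the first.",
                   oid, length(mu_refs)))
    }
    mu_oid <- xml2::xml_attr(mu_refs[[1L]], "MeasurementUnitOID")
    unit <- units[[mu_oid]] %||% mu_oid
  }

  cl <- NULL
  cl_ref <- xml_children_named(node, "CodeListRef")
  if (length(cl_ref) > 0L) {
    cl_oid <- xml2::xml_attr(cl_ref[[1L]], "CodeListOID")
    cl <- code_lists[[cl_oid]]
    if (is.null(cl)) {
      abort(sprintf("ItemDef '%s' references missing CodeList '%s'.", oid, cl_oid),
            class = "fc_structure_error")
    }
  }

  odm_item(oid, nm, codes = extract_concept_codes(node, contexts),
           data_type = dt, unit = unit, code_list = cl)
}

#' Parse a CDISC ODM 1.3 document into a study
#'
#' Reads study metadata from an ODM 1.3 XML file and exposes every
#' `FormDef` as an ordered item table: `ItemGroupRef` and `ItemRef`
#' indirections are resolved in document order (honouring `OrderNumber`
#' when given), concept codes are harvested from `Alias` annotations, and
#' each item's value domain is assembled from its `DataType`, the
#' referenced `CodeList` and the first `MeasurementUnitRef` (resolved to
#' the unit's `Symbol` where a `MeasurementUnit` definition exists).
#'
#' Unresolvable `ItemRef`/`ItemGroupRef`/`CodeListRef` targets raise a
#' structural error naming the OID rather than being dropped silently;
#' malformed XML raises the parser error (which names the offending line).
#' Namespaces are ignored: elements are matched on local names, so
#' documents with or without the CDISC namespace parse identically.
#'
#' @param path Path to an ODM XML file (UTF-8).
#' @param contexts Annotation contexts accepted as concept codes, see
#'   [extract_concept_codes()].
#' @return An [odm_study()].
#' @examples
#' f <- tempfile(fileext = ".xml")
#' write_odm(worked_example_pair(), f)
#' study <- parse_odm(f)
#' study
#' @export
parse_odm <- function(path, contexts = "UMLS") {
  if (!file.exists(path)) {
    abort(sprintf("No such file: '%s'", path), class = "fc_parse_error")
  }
  doc <- tryCatch(
    xml2::read_xml(path, encoding = "UTF-8"),
    error = function(e) abort(sprintf("Malformed XML in '%s': %s",
                                      path, conditionMessage(e)),
                              class = "fc_parse_error")
  )
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "ODM") {
    abort(sprintf("Root element of '%s' is <%s>, expected <ODM>.",
                  path, xml2::xml_name(root)), class = "fc_parse_error")
  }

  units <- list()
  for (mu in xml_find_local(root, "MeasurementUnit")) {
    sym <- translated_text(mu)
    units[[xml2::xml_attr(mu, "OID")]] <-
      if (is.na(sym)) xml2::xml_attr(mu, "Name") else sym
  }

  code_lists <- list()
  for (cl in xml_find_local(root, "CodeList")) {
    code_lists[[xml2::xml_attr(cl, "OID")]] <- parse_code_list(cl, contexts)
  }

  item_nodes <- xml_find_local(root, "ItemDef")
  item_defs <- setNames(as.list(item_nodes), xml2::xml_attr(item_nodes, "OID"))
  group_nodes <- xml_find_local(root, "ItemGroupDef")
  groups <- setNames(as.list(group_nodes), xml2::xml_attr(group_nodes, "OID"))

  parsed_items <- new.env(parent = emptyenv())  # memoise per ItemDef OID
  get_item <- function(ioid, where) {
    hit <- get0(ioid, envir = parsed_items, inherits = FALSE)
    if (!is.null(hit)) return(hit)
    node <- item_defs[[ioid]]
    if (is.null(node)) {
      abort(sprintf("%s references missing ItemDef '%s'.", where, ioid),
            class = "fc_structure_error")
    }
    parsed_items[[ioid]] <- parse_item_def(node, code_lists, units, contexts)
    parsed_items[[ioid]]
  }

  forms <- list()
  for (fd in xml_find_local(root, "FormDef")) {
    foid <- xml2::xml_attr(fd, "OID")
    rows <- list()
    for (igr in order_refs(xml_children_named(fd, "ItemGroupRef"))) {
      goid <- xml2::xml_attr(igr, "ItemGroupOID")
      grp <- groups[[goid]]
      if (is.null(grp)) {
        abort(sprintf("FormDef '%s' references missing ItemGroupDef '%s'.",
                      foid, goid), class = "fc_structure_error")
      }
      for (ir in order_refs(xml_children_named(grp, "ItemRef"))) {
        rows[[length(rows) + 1L]] <-
          get_item(xml2::xml_attr(ir, "ItemOID"),
                   sprintf("ItemGroupDef '%s'", goid))
      }
    }
    items <- if (length(rows)) bind_rows(rows) else odm_item("I.0", "x")[0, ]
    forms[[length(forms) + 1L]] <-
      odm_form(foid, xml2::xml_attr(fd, "Name") %||% foid, items)
  }

  odm_study(forms, source_path = path)
}

# ---------------------------------------------------------------------------
# Writing

add_aliases <- function(parent, codes, context) {
  for (code in codes) {
    xml2::xml_add_child(parent, "Alias", Context = context, Name = code)
  }
}

#' Write a study as a CDISC ODM 1.3 document
#'
#' Emits schema-shaped ODM 1.3: one `ItemGroupDef` per form holding the
#' form's `ItemRef`s in order, `ItemDef`s with `Alias` concept-code
#' annotations, `CodeList` definitions, and `MeasurementUnit` definitions
#' under `BasicDefinitions` referenced via `MeasurementUnitRef`. The output
#' is deterministic (fixed `CreationDateTime`), so writing the same study
#' twice yields byte-identical files, and
#' `parse_odm(write_odm(s))` reproduces a study whose comparison behaviour
#' is indistinguishable from `s`.
#'
#' @param study An [odm_study()] (or a single `odm_form`).
#' @param path Output file path.
#' @param context Annotation context label to write on concept-code
#'   `Alias` elements.
#' @return `path`, invisibly.
#' @export
write_odm <- function(study, path, context = "UMLS") {
  if (inherits(study, "odm_form")) study <- odm_study(list(study))
  stopifnot(inherits(study, "odm_study"))
  all_items <- bind_rows(lapply(study$forms, as_tibble))
  if (anyDuplicated(all_items$oid)) {
    abort(sprintf("Duplicate item OIDs across study: %s",
                  paste(unique(all_items$oid[duplicated(all_items$oid)]),
                        collapse = ", ")),
          class = "fc_invalid_study")
  }

  doc <- xml2::xml_new_root(
    "ODM",
    xmlns = "http://www.cdisc.org/ns/odm/v1.3",
    FileType = "Snapshot", FileOID = "FC.ODM.1",
    ODMVersion = "1.3", CreationDateTime = "2013-01-01T00:00:00"
  )
  st <- xml2::xml_add_child(doc, "Study", OID = "ST.1")
  gv <- xml2::xml_add_child(st, "GlobalVariables")
  xml2::xml_add_child(gv, "StudyName", "formcompare study")
  xml2::xml_add_child(gv, "StudyDescription", "Generated by formcompare")
  xml2::xml_add_child(gv, "ProtocolName", "formcompare")

  units <- sort(unique(all_items$unit[!is.na(all_items$unit)]))
  if (length(units) > 0L) {
    bd <- xml2::xml_add_child(st, "BasicDefinitions")
    for (i in seq_along(units)) {
      mu <- xml2::xml_add_child(bd, "MeasurementUnit",
                                OID = paste0("MU.", i), Name = units[[i]])
      sym <- xml2::xml_add_child(mu, "Symbol")
      xml2::xml_add_child(sym, "TranslatedText", units[[i]], "xml:lang" = "en")
    }
  }
  unit_oid <- setNames(paste0("MU.", seq_along(units)), units)

  mdv <- xml2::xml_add_child(st, "MetaDataVersion", OID = "MDV.1",
                             Name = "Metadata version 1")
  for (k in seq_along(study$forms)) {
    form <- study$forms[[k]]
    fd <- xml2::xml_add_child(mdv, "FormDef", OID = form_oid(form),
                              Name = form_name(form), Repeating = "No")
    xml2::xml_add_child(fd, "ItemGroupRef", ItemGroupOID = paste0("IG.", k),
                        Mandatory = "No", OrderNumber = "1")
  }
  for (k in seq_along(study$forms)) {
    form <- study$forms[[k]]
    ig <- xml2::xml_add_child(mdv, "ItemGroupDef", OID = paste0("IG.", k),
                              Name = paste0(form_name(form), " items"),
                              Repeating = "No")
    for (i in seq_len(nrow(form))) {
      xml2::xml_add_child(ig, "ItemRef", ItemOID = form$oid[[i]],
                          Mandatory = "No", OrderNumber = as.character(i))
    }
  }

  emitted_cls <- character()
  cl_nodes <- list()
  for (i in seq_len(nrow(all_items))) {
    it <- all_items[i, ]
    idef <- xml2::xml_add_child(mdv, "ItemDef", OID = it$oid,
                                Name = it$name, DataType = it$data_type)
    q <- xml2::xml_add_child(idef, "Question")
    xml2::xml_add_child(q, "TranslatedText", it$name, "xml:lang" = "en")
    if (!is.na(it$unit)) {
      xml2::xml_add_child(idef, "MeasurementUnitRef",
                          MeasurementUnitOID = unname(unit_oid[[it$unit]]))
    }
    cl <- it$code_list[[1L]]
    if (!is.null(cl)) {
      cl_oid <- it$code_list_oid
      xml2::xml_add_child(idef, "CodeListRef", CodeListOID = cl_oid)
      if (!cl_oid %in% emitted_cls) {
        emitted_cls <- c(emitted_cls, cl_oid)
        cl_nodes[[cl_oid]] <- cl
      }
    }
    add_aliases(idef, it$codes[[1L]], context)
  }

  for (cl_oid in emitted_cls) {
    cl <- cl_nodes[[cl_oid]]
    cln <- xml2::xml_add_child(mdv, "CodeList", OID = cl_oid,
                               Name = cl_oid, DataType = "string")
    for (j in seq_len(nrow(cl))) {
      cli <- xml2::xml_add_child(cln, "CodeListItem",
                                 CodedValue = cl$coded_value[[j]])
      dec <- xml2::xml_add_child(cli, "Decode")
      xml2::xml_add_child(dec, "TranslatedText", cl$display_text[[j]],
                          "xml:lang" = "en")
      add_aliases(cli, cl$codes[[j]], context)
    }
  }

  xml2::write_xml(doc, path, encoding = "UTF-8")
  invisible(path)
}
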