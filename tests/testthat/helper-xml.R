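# Hand-built ODM XML snippets written to temp files for parser tests.

odm_doc <- function(mdv_body, basic_defs = "", xmlns = TRUE) {
  ns <- if (xmlns) ' xmlns="http://www.cdisc.org/ns/odm/v1.3"' else ""
  paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<ODM', ns, ' FileType="Snapshot" FileOID="T.1" ODMVersion="1.3"',
    ' CreationDateTime="2013-01-01T00:00:00">',
    '<Study OID="S.1"><GlobalVariables><StudyName>t</StudyName>',
    '<StudyDescription>t</StudyDescription><ProtocolName>t</ProtocolName>',
    '</GlobalVariables>', basic_defs,
    '<MetaDataVersion OID="MDV.1" Name="v1">', mdv_body,
    '</MetaDataVersion></Study></ODM>'
  )
}

write_tmp_xml <- function(text) {
  path <- withr::local_tempfile(fileext = ".xml",
                                .local_envir = parent.frame())
  writeLines(text, path)
  path
}

one_item_mdv <- function(item_def) {
  paste0(
    '<FormDef OID="F.1" Name="Form 1" Repeating="No">',
    '<ItemGroupRef ItemGroupOID="IG.1" Mandatory="No"/></FormDef>',
    '<ItemGroupDef OID="IG.1" Name="g" Repeating="No">',
    '<ItemRef ItemOID="I.1" Mandatory="No"/></ItemGroupDef>',
    item_def
  )
}
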