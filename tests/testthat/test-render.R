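test_that("severity options render as None, Mild, Moderate, Severe under '3;*'", {
  rendered <- toy_rendered()
  rec <- Filter(function(r) r$question_iri == bp_iri("RightSeverityQuestion"),
                rendered$manifest)[[1]]
  expect_equal(vapply(rec$options, function(v) v$label, ""),
               c("None", "Mild", "Moderate", "Severe"))
  # and the HTML lists them in that order
  pos <- vapply(c("None", "Mild", "Moderate", "Severe"), function(lab) {
    m <- regexpr(paste0("value=\"[^\"]*\"/>", lab, "</label>"), rendered$html)
    as.integer(m)
  }, 0L)
  expect_true(all(diff(pos) > 0))
})

test_that("rendered options equal the alphabetical list permuted by the order spec", {
  fx <- toy()
  base_labels <- c("Mild", "Moderate", "None", "Severe")
  for (spec_str in all_order_specs(4)) {
    cfg <- fx$config
    cfg$sections[[2]]$lists[[1]]$questions[[1]]$subquestion_lists[[1]]$questions[[1]]$option_order <- spec_str
    rendered <- render_form(cfg, fx$spec)
    rec <- Filter(function(r) r$question_iri == bp_iri("RightSeverityQuestion"),
                  rendered$manifest)[[1]]
    expect_equal(vapply(rec$options, function(v) v$label, ""),
                 base_labels[oracle_option_order(spec_str, 4)],
                 info = spec_str)
  }
})

test_that("show-trigger sub-questions start hidden and carry the trigger wiring", {
  rendered <- toy_rendered()
  ctrl <- fld(bp_iri("RadiculopathyQuestion"))
  blk <- regmatches(rendered$html,
                    regexpr(paste0('<div class="of-subq"[^>]*data-controller="',
                                   ctrl, '"[^>]*>'), rendered$html))
  expect_length(blk, 1L)
  expect_match(blk, 'style="display:none"')
  expect_match(blk, paste0('data-trigger-answer="', cfa_iri("Yes"), '"'))
  expect_match(blk, 'data-trigger-kind="show"')
  # the behaviour script clears inputs when a block is re-hidden
  expect_match(rendered$html, "clearInputs", fixed = TRUE)
})

test_that("repeat copies get distinct field names and repeat indices", {
  rendered <- toy_rendered()
  cond <- Filter(function(r) r$question_iri %in%
                   bp_iri(c("ConditionNameQuestion", "ConditionDateQuestion",
                            "ConditionICDQuestion")), rendered$manifest)
  expect_length(cond, 6L)
  expect_setequal(vapply(cond, function(r) r$repeat_index, 0L), c(1L, 2L))
  expect_equal(anyDuplicated(vapply(cond, function(r) r$field_name, "")), 0L)
})

test_that("numbering skips unnumbered elements without consuming a label", {
  xml <- paste0(
    "<configuration><input><ontology>s</ontology></input>",
    "<form><iri>http://x/f</iri>",
    "<section numbered=\"true\"><iri>http://x/s1</iri><questionList>",
    "<question numbered=\"true\"><iri>http://x/q1</iri></question>",
    "<question><iri>http://x/q2</iri></question>",
    "<question numbered=\"true\"><iri>http://x/q3</iri></question>",
    "</questionList></section>",
    "<section><iri>http://x/s2</iri></section>",
    "<section numbered=\"true\"><iri>http://x/s3</iri><questionList>",
    "<question numbered=\"true\"><iri>http://x/q4</iri></question>",
    "</questionList></section>",
    "</form></configuration>")
  labels <- number_elements(parse_config(xml))
  expect_equal(labels[["http://x/s1#1"]], "A")
  expect_false("http://x/s2#1" %in% names(labels))
  expect_equal(labels[["http://x/s3#1"]], "B")
  expect_equal(labels[["http://x/q1#1"]], "1")
  expect_false("http://x/q2#1" %in% names(labels))
  expect_equal(labels[["http://x/q3#1"]], "2")
  expect_equal(labels[["http://x/q4#1"]], "1")  # counter resets per section
})

test_that("rendering is deterministic and the manifest matches the HTML fields", {
  fx <- toy()
  r1 <- render_form(fx$config, fx$spec)
  r2 <- render_form(fx$config, fx$spec)
  expect_identical(r1$html, r2$html)
  markup <- sub("<script>.*", "", r1$html)  # behaviour script quotes 'name=' too
  html_names <- unique(unlist(regmatches(markup,
                                         gregexpr('name="[^"]+"', markup))))
  html_names <- sub('^name="', "", sub('"$', "", html_names))
  manifest_names <- vapply(r1$manifest, function(r) r$field_name, "")
  expect_setequal(html_names, manifest_names)
  expect_equal(anyDuplicated(manifest_names), 0L)
})

test_that("rendering fails fast on a question missing from the specification", {
  fx <- toy()
  cfg <- fx$config
  cfg$sections[[2]]$lists[[1]]$questions[[1]]$iri <- "http://x/ghost"
  expect_error(render_form(cfg, fx$spec), "not defined in the form specification")
})

test_that("widget types map to their HTML input elements", {
  g <- build_datamodel_ontology()
  add_q <- function(g, iri, values = paste0("http://x/v", 1:2)) {
    g <- rdf_add(g, iri, ontoforms:::RDF_TYPE, dm_iri("Question"))
    g <- rdf_add(g, iri, dm_iri("hasText"), iri, lit = TRUE)
    for (v in values) {
      g <- rdf_add(g, v, ontoforms:::RDF_TYPE, dm_iri("Value"))
      g <- rdf_add(g, v, ontoforms:::RDFS_LABEL, sub(".*/", "", v), lit = TRUE)
    }
    rdf_add(g, iri, dm_iri("hasPossibleValue"), values)
  }
  for (q in paste0("http://x/q_", c("text", "textarea", "radio", "checkbox",
                                    "checkbox-horizontal", "dropdown")))
    g <- add_q(g, q)
  g <- rdf_add(g, "http://x/sec", ontoforms:::RDF_TYPE, dm_iri("Section"))
  g <- rdf_add(g, "http://x/f", ontoforms:::RDF_TYPE, dm_iri("Form"))
  xml <- paste0(
    "<configuration><input><ontology>s</ontology></input>",
    "<form><iri>http://x/f</iri><section><iri>http://x/sec</iri><questionList>",
    paste0(vapply(c("text", "textarea", "radio", "checkbox",
                    "checkbox-horizontal", "dropdown"), function(w) paste0(
      "<question type=\"", w, "\"><iri>http://x/q_", w, "</iri></question>"), ""),
      collapse = ""),
    "</questionList></section></form></configuration>")
  rendered <- render_form(parse_config(xml), extract_form_spec(g))
  expect_match(rendered$html, sprintf('<input type="text" name="%s"',
                                      fld("http://x/q_text")))
  expect_match(rendered$html, sprintf('<textarea name="%s"', fld("http://x/q_textarea")))
  expect_match(rendered$html, sprintf('<input type="radio" name="%s"', fld("http://x/q_radio")))
  expect_match(rendered$html, sprintf('<input type="checkbox" name="%s"', fld("http://x/q_checkbox")))
  expect_match(rendered$html, '<div class="of-options horizontal">')
  expect_match(rendered$html, sprintf('<select name="%s"', fld("http://x/q_dropdown")))
})
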