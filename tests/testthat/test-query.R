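# Seeded 5-submission demo dataset merged with the ontologies.
demo_dataset <- function(seed = 7L) {
  key <- paste0("demo_", seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  fx <- toy()
  subs <- generate_submissions(submission_model(seed = seed), fx$config, fx$spec, 5)
  acqs <- lapply(seq_along(subs), function(k)
    process_submission(subs[[k]], fx$config, fx$spec, toy_rendered()$manifest,
                       submission_id = paste0("d", k)))
  merged <- rdf_merge(merge_submissions(acqs), fx$graph)
  .cache[[key]] <- list(fixture = fx, submissions = subs, acquired = acqs,
                        graph = merged)
  .cache[[key]]
}

# brute-force scan over Observation individuals, no SPARQL involved
scan_observations <- function(g, pred) {
  obs <- rdf_instances(g, dm_iri("Observation"))
  obs[vapply(obs, pred, TRUE)]
}

test_that("observation count over the demo dataset matches the answer count", {
  d <- demo_dataset()
  res <- run_sparql(d$graph, packaged_query("all_observations"))
  n_answered <- sum(vapply(d$acquired, function(a)
    length(rdf_instances(a$graph, dm_iri("Observation"))), 0L))
  expect_equal(nrow(res$rows), n_answered)
  expect_true(run_sparql(d$graph, sprintf(
    "PREFIX dm: <%s> ASK { ?o dm:hasFocus ?f }", dm_iri("")))$ask)
})

test_that("focus retrieval equals a brute-force scan and is seed-determined", {
  d <- demo_dataset()
  res <- observations_by_focus(d$graph, cfa_iri("RadiculopathySignsSymptoms"))
  oracle <- scan_observations(d$graph, function(o)
    cfa_iri("RadiculopathySignsSymptoms") %in% rdf_objects(d$graph, o, dm_iri("hasFocus")))
  expect_setequal(res$rows$obs, oracle)
  # ground truth by construction from the generated answers
  f <- fld(bp_iri("RadiculopathyQuestion"))
  n_answered <- sum(vapply(d$submissions, function(s) !is.null(s$answers[[f]]), TRUE))
  expect_equal(nrow(res$rows), n_answered)
  # the packaged radiculopathy query restricted to affirmative answers
  yes <- run_sparql(d$graph, packaged_query("radiculopathy_observations"))
  n_yes <- sum(vapply(d$submissions, function(s)
    identical(s$answers[[f]], cfa_iri("Yes")), TRUE))
  expect_equal(sum(yes$rows$value == cfa_iri("Yes")), n_yes)
})

test_that("a focus with no annotated questions returns nothing", {
  d <- demo_dataset()
  res <- observations_by_focus(d$graph, cfa_iri("ConditionHistoryNever"))
  expect_equal(nrow(res$rows), 0L)
})

test_that("two questions sharing a focus are aggregated by one query", {
  fx <- toy()
  g <- fx$graph
  # second instrument: a differently-worded question with the same focus
  q2 <- "http://x/other-form#RadiculopathyPresent"
  g <- rdf_add(g, q2, ontoforms:::RDF_TYPE, dm_iri("Question"))
  g <- rdf_add(g, q2, dm_iri("hasText"), "Radiculopathy present?", lit = TRUE)
  g <- rdf_add(g, q2, dm_iri("hasPossibleValue"), c(cfa_iri("Yes"), cfa_iri("No")))
  g <- rdf_add(g, q2, dm_iri("isAbout"), cfa_iri("RadiculopathySignsSymptoms"))
  g <- rdf_add(g, "http://x/other-form#F", ontoforms:::RDF_TYPE, dm_iri("Form"))
  g <- rdf_add(g, "http://x/other-form#S", ontoforms:::RDF_TYPE, dm_iri("Section"))
  spec2 <- extract_form_spec(g, fx$config$bindings)
  cfg2 <- parse_config(paste0(
    "<configuration><input><ontology>s</ontology></input>",
    "<form><iri>http://x/other-form#F</iri><section><iri>http://x/other-form#S</iri>",
    "<questionList><question type=\"radio\"><iri>", q2, "</iri></question>",
    "</questionList></section></form></configuration>"))
  a1 <- process_submission(
    new_submission(fx$config$form_iri, toy_answers_yes()),
    fx$config, fx$spec, submission_id = "share1")
  ans2 <- list()
  ans2[[fld(q2)]] <- cfa_iri("Yes")
  a2 <- process_submission(new_submission("http://x/other-form#F", ans2),
                           cfg2, spec2, submission_id = "share2")
  merged <- rdf_merge(merge_submissions(list(a1, a2)), g)
  res <- observations_by_focus(merged, cfa_iri("RadiculopathySignsSymptoms"))
  expect_equal(nrow(res$rows), 2L)
})

test_that("description queries aggregate left and right lower-extremity foci", {
  d <- demo_dataset()
  res <- observations_by_description(
    d$graph, fn = cfa_iri("PainInBodyPart"),
    location_class = cfa_iri("LowerExtremityStructure"),
    value = cfa_iri("Severe"))
  oracle <- scan_observations(d$graph, function(o) {
    foci <- rdf_objects(d$graph, o, dm_iri("hasFocus"))
    if (length(foci) == 0L) return(FALSE)
    f <- foci[[1]]
    if (!cfa_iri("PainInBodyPart") %in% rdf_objects(d$graph, f, cfa_iri("hasAssessedFunction")))
      return(FALSE)
    locs <- rdf_objects(d$graph, f, cfa_iri("hasAnatomicalLocation"))
    loc_ok <- any(vapply(locs, function(l) {
      tys <- rdf_objects(d$graph, l, ontoforms:::RDF_TYPE)
      up <- tys
      repeat {
        more <- unique(c(up, unlist(lapply(up, function(t)
          rdf_objects(d$graph, t, ontoforms:::RDFS_SUBCLASSOF)))))
        if (length(more) == length(up)) break
        up <- more
      }
      cfa_iri("LowerExtremityStructure") %in% up
    }, TRUE))
    loc_ok && cfa_iri("Severe") %in% rdf_objects(d$graph, o, dm_iri("hasValue"))
  })
  expect_setequal(res$rows$obs, oracle)
  # the packaged query file gives the same result
  packaged <- run_sparql(d$graph, packaged_query("severe_pain_lower_extremity"))
  expect_setequal(packaged$rows$obs, oracle)
  # both lateralities contribute to the aggregation when present
  sides <- vapply(res$rows$obs, function(o) {
    f <- rdf_objects(d$graph, o, dm_iri("hasFocus"))[[1]]
    rdf_objects(d$graph, f, cfa_iri("hasLaterality"))[[1]]
  }, "")
  expect_true(length(unique(sides)) >= 1L)
})

test_that("attribute-only description pattern equals the brute-force scan", {
  d <- demo_dataset()
  res <- observations_by_description(d$graph, attribute = cfa_iri("Severity"))
  oracle <- scan_observations(d$graph, function(o) {
    foci <- rdf_objects(d$graph, o, dm_iri("hasFocus"))
    length(foci) > 0L &&
      cfa_iri("Severity") %in% rdf_objects(d$graph, foci[[1]],
                                           cfa_iri("hasAssessedAttribute"))
  })
  expect_setequal(res$rows$obs, oracle)
  # an unknown location yields nothing
  none <- observations_by_description(d$graph,
                                      location_class = cfa_iri("CervicalSpine"))
  expect_equal(nrow(none$rows), 0L)
})

test_that("adding a submission never removes focus-query rows", {
  d <- demo_dataset()
  partial <- rdf_merge(merge_submissions(d$acquired[1:3]), d$fixture$graph)
  full <- d$graph
  for (focus in cfa_iri(c("RadiculopathySignsSymptoms",
                          "SeverityConstantPainRightLowerExtremity",
                          "SeverityConstantPainLeftLowerExtremity"))) {
    before <- observations_by_focus(partial, focus)$rows$obs
    after <- observations_by_focus(full, focus)$rows$obs
    expect_true(all(before %in% after), info = focus)
  }
})

test_that("class-based focus retrieval matches foci typed by any subclass", {
  d <- demo_dataset()
  res <- observations_by_focus(d$graph, class_iri = cfa_iri("Finding"))
  oracle <- scan_observations(d$graph, function(o) {
    foci <- rdf_objects(d$graph, o, dm_iri("hasFocus"))
    length(foci) > 0L  # every shipped focus is typed under Finding
  })
  expect_setequal(res$rows$obs, oracle)
})

test_that("query results export as CSV and SPARQL-JSON", {
  d <- demo_dataset()
  res <- run_sparql(d$graph, packaged_query("radiculopathy_observations"))
  tmp <- withr::local_tempdir()
  write_query_result(res, file.path(tmp, "r.csv"), "csv")
  expect_equal(nrow(utils::read.csv(file.path(tmp, "r.csv"))), nrow(res$rows))
  write_query_result(res, file.path(tmp, "r.json"), "json")
  doc <- jsonlite::read_json(file.path(tmp, "r.json"))
  expect_equal(unlist(doc$head$vars), c("obs", "value"))
  expect_length(doc$results$bindings, nrow(res$rows))
  expect_equal(doc$results$bindings[[1]]$obs$type, "uri")
})
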