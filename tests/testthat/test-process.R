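toy_acquired <- function(answers = toy_answers_yes(), id = "t1") {
  fx <- toy()
  process_submission(new_submission(fx$config$form_iri, answers,
                                    timestamp = "2017-08-01T00:00:00Z"),
                     fx$config, fx$spec, toy_rendered()$manifest,
                     submission_id = id)
}

test_that("answers become observations with value and focus assertions", {
  acq <- toy_acquired()
  g <- acq$graph
  radio_obs <- rdf_subjects(g, dm_iri("sourceQuestion"), bp_iri("RadiculopathyQuestion"))
  expect_length(radio_obs, 1L)
  expect_equal(rdf_objects(g, radio_obs, dm_iri("hasValue")), cfa_iri("Yes"))
  expect_equal(rdf_objects(g, radio_obs, dm_iri("hasFocus")),
               cfa_iri("RadiculopathySignsSymptoms"))
  # focus-less question: no hasFocus
  date_obs <- rdf_subjects(g, dm_iri("sourceQuestion"), bp_iri("ConditionDateQuestion"))
  expect_length(date_obs, 2L)
  for (o in date_obs) expect_length(rdf_objects(g, o, dm_iri("hasFocus")), 0L)
  # free text stored as a literal, not an object value
  expect_length(rdf_objects(g, date_obs[1], dm_iri("hasValue")), 0L)
  expect_length(rdf_objects(g, date_obs[1], dm_iri("hasTextValue")), 1L)
})

test_that("a question's answered sub-questions hang off its observation", {
  acq <- toy_acquired()
  g <- acq$graph
  radio_obs <- rdf_subjects(g, dm_iri("sourceQuestion"), bp_iri("RadiculopathyQuestion"))
  kids <- rdf_objects(g, radio_obs, dm_iri("hasComponent"))
  expect_length(kids, 2L)
  kid_sources <- unlist(lapply(kids, rdf_objects, g = g, p = dm_iri("sourceQuestion")))
  expect_setequal(kid_sources,
                  bp_iri(c("RightSeverityQuestion", "LeftSeverityQuestion")))
})

test_that("the patient info list aggregates into one subject-information individual", {
  acq <- toy_acquired()
  g <- acq$graph
  si <- rdf_instances(g, dm_iri("SubjectInformation"))
  expect_length(si, 1L)
  expect_equal(rdf_objects(g, si, cfa_iri("hasName")), "Ada")
  expect_equal(rdf_objects(g, si, cfa_iri("hasID")), "123")
  # reachable from the form data root via hasComponent
  reach <- acq$form_data_iri
  repeat {
    nxt <- unique(c(reach, rdf_match(g, s = reach, p = dm_iri("hasComponent"))$o))
    if (length(nxt) == length(reach)) break
    reach <- nxt
  }
  expect_true(si %in% reach)
})

test_that("the component digraph is a tree rooted at the form data individual", {
  acq <- toy_acquired()
  edges <- rdf_match(acq$graph, p = dm_iri("hasComponent"))
  expect_equal(anyDuplicated(edges$o), 0L)          # every node has one parent
  expect_false(acq$form_data_iri %in% edges$o)      # root has none
  nodes <- unique(c(edges$s, edges$o))
  expect_equal(length(edges$o), length(nodes) - 1L) # |E| = |V| - 1
  expect_length(rdf_instances(acq$graph, dm_iri("FormData")), 1L)
})

test_that("validation rejects missing required answers, bad values, and trigger-bypass", {
  fx <- toy()
  manifest <- toy_rendered()$manifest
  mk <- function(answers) new_submission(fx$config$form_iri, answers)
  ans <- toy_answers_yes()
  dropped <- ans[setdiff(names(ans), fld(bp_iri("PatientNameInfo")))]
  expect_error(process_submission(mk(dropped), fx$config, fx$spec, manifest),
               "missing required field")
  bad <- toy_answers_yes()
  bad[[fld(bp_iri("RightSeverityQuestion"))]] <- cfa_iri("Left")
  expect_error(process_submission(mk(bad), fx$config, fx$spec, manifest),
               "not among the possible values")
  sneaky <- toy_answers_yes()
  sneaky[[fld(bp_iri("RadiculopathyQuestion"))]] <- cfa_iri("No")
  expect_error(process_submission(mk(sneaky), fx$config, fx$spec, manifest),
               "trigger condition is not met")
  ghost <- toy_answers_yes()
  ghost[["deadbeef__r1"]] <- "x"
  expect_error(process_submission(mk(ghost), fx$config, fx$spec, manifest),
               "unknown field")
})

test_that("unanswered optional questions create no observation", {
  ans <- toy_answers_yes()
  ans[[fld(bp_iri("ConditionICDQuestion"), 2L)]] <- NULL
  acq <- toy_acquired(ans)
  expect_length(rdf_instances(acq$graph, dm_iri("Observation")),
                length(grep("__r", names(ans))) - 2L)  # minus the two info fields
})

test_that("serializations agree: CSV rows, Turtle round-trip, OWL header-only delta", {
  acq <- toy_acquired()
  tmp <- withr::local_tempdir()
  csv_path <- file.path(tmp, "out.csv")
  serialize_acquired(acq, "csv", csv_path)
  csv <- utils::read.csv(csv_path, stringsAsFactors = FALSE)
  expect_equal(nrow(csv), length(rdf_instances(acq$graph, dm_iri("Observation"))))
  expect_equal(sort(names(csv)),
               sort(c("submission", "question_iri", "repeat_index", "value", "focus_iri")))

  ttl_path <- file.path(tmp, "out.ttl")
  serialize_acquired(acq, "rdf", ttl_path)
  expect_true(graph_isomorphic(read_turtle(ttl_path), acq$graph))

  owl_path <- file.path(tmp, "out.owl")
  serialize_acquired(acq, "owl", owl_path)
  owl_g <- read_rdfxml(owl_path)
  extra <- setdiff(ontoforms:::triple_keys(owl_g$triples),
                   ontoforms:::triple_keys(acq$graph$triples))
  expect_length(setdiff(ontoforms:::triple_keys(acq$graph$triples),
                        ontoforms:::triple_keys(owl_g$triples)), 0L)
  expect_true(all(grepl("owl#(Ontology|imports)", extra)))
  expect_true(any(grepl("datamodel", extra)))
})

test_that("merging submissions keeps one FormData per submission and detects collisions", {
  fx <- toy()
  subs <- generate_submissions(submission_model(seed = 3), fx$config, fx$spec, 5)
  acqs <- lapply(seq_along(subs), function(k)
    process_submission(subs[[k]], fx$config, fx$spec, toy_rendered()$manifest,
                       submission_id = paste0("m", k)))
  merged <- merge_submissions(acqs)
  expect_length(rdf_instances(merged, dm_iri("FormData")), 5L)
  forms <- unique(rdf_match(merged, p = dm_iri("sourceForm"))$o)
  expect_equal(forms, fx$config$form_iri)
  expect_equal(rdf_size(merge_submissions(list())), 0L)
  expect_true(graph_isomorphic(merge_submissions(acqs[1]), acqs[[1]]$graph))
  expect_error(merge_submissions(list(acqs[[1]], acqs[[1]])), "collision")
})

test_that("renaming question texts changes no non-provenance triple", {
  fx <- toy()
  acq1 <- toy_acquired(id = "p1")
  # rewrite every question text in the ontology, re-extract, reprocess
  g2 <- fx$graph
  idx <- g2$triples$p == dm_iri("hasText")
  g2$triples$o[idx] <- paste0("REWORDED: ", g2$triples$o[idx])
  spec2 <- extract_form_spec(g2, fx$config$bindings)
  acq2 <- process_submission(
    new_submission(fx$config$form_iri, toy_answers_yes(),
                   timestamp = "2017-08-01T00:00:00Z"),
    fx$config, spec2, submission_id = "p1")
  expect_true(graph_isomorphic(acq1$graph, acq2$graph))
})
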