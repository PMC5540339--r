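test_that("datamodel asserts the form-structure and data hierarchies", {
  g <- build_datamodel_ontology()
  sub <- function(a, b) nrow(rdf_match(g, s = a, p = ontoforms:::RDFS_SUBCLASSOF, o = b)) == 1L
  expect_true(sub(dm_iri("Question"), dm_iri("FormStructure")))
  expect_true(sub(dm_iri("Form"), dm_iri("FormStructure")))
  expect_true(sub(dm_iri("Section"), dm_iri("FormStructure")))
  expect_true(sub(dm_iri("Observation"), dm_iri("Data")))
  expect_true(sub(dm_iri("FormData"), dm_iri("Data")))
  expect_true(sub(dm_iri("SubjectInformation"), dm_iri("Data")))
  for (p in c("hasComponent", "hasFocus", "hasValue", "hasPossibleValue", "isAbout"))
    expect_true(dm_iri(p) %in% rdf_instances(g, ontoforms:::OWL_OBJPROP), info = p)
})

test_that("datamodel class graph has no subclass cycles", {
  g <- build_datamodel_ontology()
  edges <- rdf_match(g, p = ontoforms:::RDFS_SUBCLASSOF)
  # brute-force reachability: no class may reach itself
  reach <- function(from, seen = character()) {
    nxt <- edges$o[edges$s == from]
    for (x in nxt) {
      if (x %in% seen) next
      seen <- reach(x, c(seen, x))
    }
    seen
  }
  for (cls in unique(edges$s))
    expect_false(cls %in% reach(cls), info = cls)
})

test_that("domain ontology composes foci from attribute, function, location, laterality", {
  g <- build_toy_domain_ontology()
  right <- cfa_iri("SeverityConstantPainRightLowerExtremity")
  left <- cfa_iri("SeverityConstantPainLeftLowerExtremity")
  expect_equal(rdf_objects(g, right, cfa_iri("hasAssessedAttribute")), cfa_iri("Severity"))
  expect_equal(rdf_objects(g, right, cfa_iri("hasTemporalQuality")), cfa_iri("Constant"))
  expect_equal(rdf_objects(g, right, cfa_iri("hasLaterality")), cfa_iri("Right"))
  # left/right counterparts differ only in laterality and location
  comps <- function(f) {
    tr <- rdf_match(g, s = f)
    tr <- tr[!tr$p %in% c(cfa_iri("hasLaterality"), cfa_iri("hasAnatomicalLocation"),
                          ontoforms:::RDFS_LABEL), c("p", "o")]
    tr[order(tr$p, tr$o), ]
  }
  expect_equal(comps(right)$o, comps(left)$o)
  expect_false(identical(rdf_objects(g, right, cfa_iri("hasLaterality")),
                         rdf_objects(g, left, cfa_iri("hasLaterality"))))
})

test_that("assessment findings split by result type and values are typed", {
  g <- build_toy_domain_ontology()
  sub <- function(a, b) nrow(rdf_match(g, s = a, p = ontoforms:::RDFS_SUBCLASSOF, o = b)) == 1L
  expect_true(sub(cfa_iri("Assessment"), cfa_iri("Finding")))
  expect_true(sub(cfa_iri("Measurement"), cfa_iri("Finding")))
  expect_true(sub(cfa_iri("Finding"), dm_iri("DataElementDescription")))
  value_classes <- c(cfa_iri("Value"),
                     rdf_subjects(g, ontoforms:::RDFS_SUBCLASSOF, cfa_iri("Value")))
  for (v in c("Mild", "Moderate", "NoneSeverity", "Severe", "Yes", "No",
              "Right", "Left", "Constant", "Intermittent")) {
    types <- rdf_objects(g, cfa_iri(v), ontoforms:::RDF_TYPE)
    expect_true(any(types %in% value_classes), info = v)
  }
})

test_that("external terminology references carry source and code", {
  g <- build_toy_domain_ontology()
  expect_equal(rdf_objects(g, cfa_iri("PainInBodyPart"), cfa_iri("codeSource")), "ICF")
  expect_equal(rdf_objects(g, cfa_iri("PainInBodyPart"), cfa_iri("codeValue")), "b2801")
  expect_equal(rdf_objects(g, cfa_iri("RightLowerExtremity"), cfa_iri("codeValue")), "s750")
})

test_that("the example form mirrors its specification and validates cleanly", {
  fx <- toy()
  expect_equal(validate_config_against_spec(fx$config, fx$spec), character(0))
  radio_q <- fx$spec$questions[[bp_iri("RadiculopathyQuestion")]]
  expect_setequal(vapply(radio_q$possible_values, function(v) v$iri, ""),
                  c(cfa_iri("Yes"), cfa_iri("No")))
  expect_equal(fx$spec$questions[[bp_iri("RightSeverityQuestion")]]$focus,
               cfa_iri("SeverityConstantPainRightLowerExtremity"))
  # repeating inline list of three text questions
  cond_list <- fx$config$sections[[2]]$lists[[1]]$questions[[2]]$subquestion_lists[[1]]
  expect_equal(cond_list$repeat_n, 2L)
  expect_equal(cond_list$layout, "inline")
  expect_length(cond_list$questions, 3L)
})

test_that("synthetic submissions are reproducible and complete under seed", {
  fx <- toy()
  m <- submission_model(seed = 11, completion_rate = 1)
  s1 <- generate_submissions(m, fx$config, fx$spec, 3)
  s2 <- generate_submissions(m, fx$config, fx$spec, 3)
  expect_identical(lapply(s1, function(s) s$answers),
                   lapply(s2, function(s) s$answers))
  # completion_rate = 1: every visible field answered
  rendered <- toy_rendered()
  tree <- ontoforms:::build_instance_tree(fx$config, fx$spec)
  for (s in s1) {
    for (node in ontoforms:::tree_instances(tree)) {
      if (is.na(node$field)) next
      visible <- !identical(node$kind, "question") ||
        ontoforms:::instance_visible(node, s$answers)
      if (visible) expect_false(is.null(s$answers[[node$field]]),
                                info = node$field)
    }
  }
})

test_that("uniform answers on a two-option question are binomially balanced", {
  fx <- toy()
  m <- submission_model(seed = 99, completion_rate = 1)
  subs <- generate_submissions(m, fx$config, fx$spec, 100)
  f <- fld(bp_iri("RadiculopathyQuestion"))
  yes <- sum(vapply(subs, function(s) identical(s$answers[[f]], cfa_iri("Yes")), TRUE))
  # 3 sigma around 50 for Binomial(100, 1/2)
  expect_gt(yes, 50 - 3 * sqrt(25))
  expect_lt(yes, 50 + 3 * sqrt(25))
})

test_that("every synthetic submission is accepted by the processor", {
  for (seed in c(1, 7, 23, 57)) {
    fx <- random_form_fixture(seed = seed)
    subs <- generate_submissions(submission_model(seed = seed, completion_rate = 0.6),
                                 fx$config, fx$spec, 25)
    for (k in seq_along(subs)) {
      expect_no_error(process_submission(subs[[k]], fx$config, fx$spec,
                                         submission_id = paste0("s", seed, "_", k)))
    }
  }
})
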