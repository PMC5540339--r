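# Shipped ontologies: the generic form/data model, and a small clinical
# functional-assessment style domain ontology with composed focus
# individuals (assessed attribute / assessed function with temporal
# qualifier / anatomical location with laterality). External terminologies
# (ICF, SNOMED CT) are referenced by source/code string pairs on internal
# individuals, never imported.

DM_ONT_IRI  <- "http://example.org/ontoforms/datamodel"
CFA_ONT_IRI <- "http://example.org/ontoforms/cfa"
BP_ONT_IRI  <- "http://example.org/ontoforms/backpain-form"

decl_class <- function(g, iri, super = NULL, label = NULL) {
  g <- rdf_add(g, iri, RDF_TYPE, OWL_CLASS)
  if (!is.null(super)) g <- rdf_add(g, iri, RDFS_SUBCLASSOF, super)
  if (!is.null(label)) g <- rdf_add(g, iri, RDFS_LABEL, label, lit = TRUE)
  g
}

decl_prop <- function(g, iri, kind = OWL_OBJPROP, domain = NULL, range = NULL) {
  g <- rdf_add(g, iri, RDF_TYPE, kind)
  if (!is.null(domain)) g <- rdf_add(g, iri, RDFS_DOMAIN, domain)
  if (!is.null(range)) g <- rdf_add(g, iri, RDFS_RANGE, range)
  g
}

decl_ind <- function(g, iri, type, label = NULL) {
  g <- rdf_add(g, iri, RDF_TYPE, OWL_NAMEDIND)
  g <- rdf_add(g, iri, RDF_TYPE, type)
  if (!is.null(label)) g <- rdf_add(g, iri, RDFS_LABEL, label, lit = TRUE)
  g
}

coded_ref <- function(g, iri, source, code) {
  g <- rdf_add(g, iri, cfa("codeSource"), source, lit = TRUE)
  rdf_add(g, iri, cfa("codeValue"), code, lit = TRUE)
}

#' Build the form/data model ontology
#'
#' The generic, context-free vocabulary of form structures and the data they
#' generate: `Form`, `Section` and `Question` as kinds of `FormStructure`;
#' `FormData`, `Observation`, `SubjectInformation`, `EvaluatorInformation`
#' and `Certification` as kinds of `Data`; and the properties linking them
#' (`hasComponent`, `hasValue`, `hasPossibleValue`, `isAbout`, `hasFocus`).
#' Property domains and ranges are asserted conservatively.
#'
#' @return An `rdf_graph` of the datamodel ontology.
#' @export
build_datamodel_ontology <- function() {
  g <- rdf_graph()
  g <- rdf_add(g, DM_ONT_IRI, RDF_TYPE, OWL_ONTOLOGY)
  g <- decl_class(g, dm("FormStructure"), label = "Form structure")
  g <- decl_class(g, dm("Form"), dm("FormStructure"), "Form")
  g <- decl_class(g, dm("Section"), dm("FormStructure"), "Section")
  g <- decl_class(g, dm("SubjectInfoSection"), dm("Section"), "Subject information section")
  g <- decl_class(g, dm("Question"), dm("FormStructure"), "Question")
  g <- decl_class(g, dm("Data"), label = "Data")
  g <- decl_class(g, dm("FormData"), dm("Data"), "Form data")
  g <- decl_class(g, dm("Observation"), dm("Data"), "Observation")
  g <- decl_class(g, dm("SubjectInformation"), dm("Data"), "Subject information")
  g <- decl_class(g, dm("EvaluatorInformation"), dm("Data"), "Evaluator information")
  g <- decl_class(g, dm("Certification"), dm("Data"), "Certification")
  # anchors for the domain-ontology hooks
  g <- decl_class(g, dm("DataElementDescription"), label = "Data element description")
  g <- decl_class(g, dm("Value"), label = "Value")

  g <- decl_prop(g, dm("hasComponent"), OWL_OBJPROP, dm("Data"), dm("Data"))
  g <- decl_prop(g, dm("hasValue"), OWL_OBJPROP, dm("Observation"), dm("Value"))
  g <- decl_prop(g, dm("hasPossibleValue"), OWL_OBJPROP, dm("Question"), dm("Value"))
  g <- decl_prop(g, dm("isAbout"), OWL_OBJPROP, dm("Question"), dm("DataElementDescription"))
  g <- decl_prop(g, dm("hasFocus"), OWL_OBJPROP, dm("Observation"), dm("DataElementDescription"))
  # provenance and display properties
  g <- decl_prop(g, dm("sourceQuestion"), OWL_OBJPROP, dm("Data"), dm("Question"))
  g <- decl_prop(g, dm("sourceSection"), OWL_OBJPROP, dm("Data"), dm("Section"))
  g <- decl_prop(g, dm("sourceForm"), OWL_OBJPROP, dm("FormData"), dm("Form"))
  g <- decl_prop(g, dm("hasText"), OWL_DATAPROP, dm("FormStructure"))
  g <- decl_prop(g, dm("hasHeading"), OWL_DATAPROP, dm("Section"))
  g <- decl_prop(g, dm("hasTextValue"), OWL_DATAPROP, dm("Observation"))
  g <- decl_prop(g, dm("repeatIndex"), OWL_DATAPROP, dm("Data"))
  g <- decl_prop(g, dm("submissionTimestamp"), OWL_DATAPROP, dm("FormData"))
  g
}

#' Build the toy functional-assessment domain ontology
#'
#' A small clinical functional-assessment style ontology providing the
#' domain hooks the form pipeline needs: a `Finding` hierarchy under the
#' datamodel's `DataElementDescription` anchor (split into `Assessment` for
#' non-numeric results and `Measurement` for numeric ones), value sets
#' (severity scale, yes/no, laterality, temporal quality), an anatomical
#' location taxonomy in which right and left lower-extremity structures
#' share a common superclass, and composed focus individuals such as
#' "severity of constant pain in the right lower extremity". ICF and
#' SNOMED CT terms are referenced via source/code string pairs.
#'
#' @return An `rdf_graph` of the domain ontology.
#' @export
build_toy_domain_ontology <- function() {
  g <- rdf_graph()
  g <- rdf_add(g, CFA_ONT_IRI, RDF_TYPE, OWL_ONTOLOGY)
  g <- rdf_add(g, CFA_ONT_IRI, OWL_IMPORTS, DM_ONT_IRI)

  g <- decl_class(g, cfa("Finding"), dm("DataElementDescription"), "Finding")
  g <- decl_class(g, cfa("Assessment"), cfa("Finding"), "Assessment")
  g <- decl_class(g, cfa("Measurement"), cfa("Finding"), "Measurement")
  g <- decl_class(g, cfa("FunctionalFinding"), cfa("Finding"), "Functional finding")
  g <- decl_class(g, cfa("FunctionalAssessment"), cfa("Assessment"), "Functional assessment")

  g <- decl_class(g, cfa("Value"), dm("Value"), "Value")
  g <- decl_class(g, cfa("SeverityScaleValue"), cfa("Value"), "Severity scale value")
  g <- decl_class(g, cfa("YesNoValue"), cfa("Value"), "Yes/no value")
  g <- decl_class(g, cfa("LateralityValue"), cfa("Value"), "Laterality value")
  g <- decl_class(g, cfa("TemporalQualityValue"), cfa("Value"), "Temporal quality value")

  g <- decl_class(g, cfa("SubjectMatterConcept"), label = "Subject matter concept")
  g <- decl_class(g, cfa("BodyFunction"), cfa("SubjectMatterConcept"), "Body function")
  g <- decl_class(g, cfa("AssessmentAttribute"), cfa("SubjectMatterConcept"), "Assessment attribute")
  g <- decl_class(g, cfa("BodyStructure"), cfa("SubjectMatterConcept"), "Body structure")
  g <- decl_class(g, cfa("LowerExtremityStructure"), cfa("BodyStructure"),
                  "Structure of lower extremity")
  g <- decl_class(g, cfa("RightLowerExtremityStructure"), cfa("LowerExtremityStructure"),
                  "Structure of right lower extremity")
  g <- decl_class(g, cfa("LeftLowerExtremityStructure"), cfa("LowerExtremityStructure"),
                  "Structure of left lower extremity")

  g <- decl_prop(g, cfa("hasAssessedAttribute"), OWL_OBJPROP, cfa("Finding"),
                 cfa("AssessmentAttribute"))
  g <- decl_prop(g, cfa("hasAssessedFunction"), OWL_OBJPROP, cfa("Finding"),
                 cfa("SubjectMatterConcept"))
  g <- decl_prop(g, cfa("hasTemporalQuality"), OWL_OBJPROP, cfa("Finding"),
                 cfa("TemporalQualityValue"))
  g <- decl_prop(g, cfa("hasAnatomicalLocation"), OWL_OBJPROP, cfa("Finding"),
                 cfa("BodyStructure"))
  g <- decl_prop(g, cfa("hasLaterality"), OWL_OBJPROP, cfa("Finding"),
                 cfa("LateralityValue"))
  g <- decl_prop(g, cfa("codeSource"), OWL_DATAPROP)
  g <- decl_prop(g, cfa("codeValue"), OWL_DATAPROP)
  g <- decl_prop(g, cfa("hasName"), OWL_DATAPROP)
  g <- decl_prop(g, cfa("hasID"), OWL_DATAPROP)

  # value individuals
  g <- decl_ind(g, cfa("Mild"), cfa("SeverityScaleValue"), "Mild")
  g <- decl_ind(g, cfa("Moderate"), cfa("SeverityScaleValue"), "Moderate")
  g <- decl_ind(g, cfa("NoneSeverity"), cfa("SeverityScaleValue"), "None")
  g <- decl_ind(g, cfa("Severe"), cfa("SeverityScaleValue"), "Severe")
  g <- decl_ind(g, cfa("Yes"), cfa("YesNoValue"), "Yes")
  g <- decl_ind(g, cfa("No"), cfa("YesNoValue"), "No")
  g <- decl_ind(g, cfa("Right"), cfa("LateralityValue"), "Right")
  g <- decl_ind(g, cfa("Left"), cfa("LateralityValue"), "Left")
  g <- decl_ind(g, cfa("Constant"), cfa("TemporalQualityValue"), "Constant")
  g <- decl_ind(g, cfa("Intermittent"), cfa("TemporalQualityValue"), "Intermittent")

  # subject-matter individuals with external terminology references
  g <- decl_ind(g, cfa("Severity"), cfa("AssessmentAttribute"), "Severity")
  g <- decl_ind(g, cfa("Presence"), cfa("AssessmentAttribute"), "Presence")
  g <- decl_ind(g, cfa("PainInBodyPart"), cfa("BodyFunction"), "icf:b2801 Pain in body part")
  g <- coded_ref(g, cfa("PainInBodyPart"), "ICF", "b2801")
  g <- decl_ind(g, cfa("Radiculopathy"), cfa("SubjectMatterConcept"), "Radiculopathy")
  g <- coded_ref(g, cfa("Radiculopathy"), "SNOMED CT", "72274001")
  g <- decl_ind(g, cfa("RightLowerExtremity"), cfa("RightLowerExtremityStructure"),
                "Right lower extremity")
  g <- coded_ref(g, cfa("RightLowerExtremity"), "ICF", "s750")
  g <- decl_ind(g, cfa("LeftLowerExtremity"), cfa("LeftLowerExtremityStructure"),
                "Left lower extremity")
  g <- coded_ref(g, cfa("LeftLowerExtremity"), "ICF", "s750")

  # composed focus individuals
  g <- decl_ind(g, cfa("SeverityConstantPainRightLowerExtremity"),
                cfa("FunctionalAssessment"),
                "Severity of constant pain in the right lower extremity")
  g <- rdf_add(g, cfa("SeverityConstantPainRightLowerExtremity"),
               cfa("hasAssessedAttribute"), cfa("Severity"))
  g <- rdf_add(g, cfa("SeverityConstantPainRightLowerExtremity"),
               cfa("hasAssessedFunction"), cfa("PainInBodyPart"))
  g <- rdf_add(g, cfa("SeverityConstantPainRightLowerExtremity"),
               cfa("hasTemporalQuality"), cfa("Constant"))
  g <- rdf_add(g, cfa("SeverityConstantPainRightLowerExtremity"),
               cfa("hasAnatomicalLocation"), cfa("RightLowerExtremity"))
  g <- rdf_add(g, cfa("SeverityConstantPainRightLowerExtremity"),
               cfa("hasLaterality"), cfa("Right"))

  g <- decl_ind(g, cfa("SeverityConstantPainLeftLowerExtremity"),
                cfa("FunctionalAssessment"),
                "Severity of constant pain in the left lower extremity")
  g <- rdf_add(g, cfa("SeverityConstantPainLeftLowerExtremity"),
               cfa("hasAssessedAttribute"), cfa("Severity"))
  g <- rdf_add(g, cfa("SeverityConstantPainLeftLowerExtremity"),
               cfa("hasAssessedFunction"), cfa("PainInBodyPart"))
  g <- rdf_add(g, cfa("SeverityConstantPainLeftLowerExtremity"),
               cfa("hasTemporalQuality"), cfa("Constant"))
  g <- rdf_add(g, cfa("SeverityConstantPainLeftLowerExtremity"),
               cfa("hasAnatomicalLocation"), cfa("LeftLowerExtremity"))
  g <- rdf_add(g, cfa("SeverityConstantPainLeftLowerExtremity"),
               cfa("hasLaterality"), cfa("Left"))

  g <- decl_ind(g, cfa("RadiculopathySignsSymptoms"), cfa("FunctionalAssessment"),
                "Presence of signs or symptoms due to radiculopathy")
  g <- rdf_add(g, cfa("RadiculopathySignsSymptoms"),
               cfa("hasAssessedAttribute"), cfa("Presence"))
  g <- rdf_add(g, cfa("RadiculopathySignsSymptoms"),
               cfa("hasAssessedFunction"), cfa("Radiculopathy"))

  g <- decl_ind(g, cfa("ConditionHistory"), cfa("Finding"),
                "Previously diagnosed condition")
  g <- rdf_add(g, cfa("ConditionHistory"), cfa("hasAssessedAttribute"), cfa("Presence"))
  g
}

#' Build the example back-pain form specification
#'
#' A compact form specification exercising every layout feature: a subject
#' information section with an inline info list (required patient name,
#' optional ID bound to a data property); a question section with a
#' radio yes/no question about radiculopathy whose "Yes" answer triggers two
#' severity sub-questions (one of which overrides alphabetical option order
#' with `optionOrder="3;*"` so the severity scale reads None, Mild,
#' Moderate, Severe); and a container question holding an inline,
#' twice-repeated list of three free-text questions about diagnosed
#' conditions.
#'
#' @param ontology_path Value written into the configuration's
#'   `<input><ontology>` element (a path the CLI resolves relative to the
#'   configuration file).
#' @return List with `graph` (the form-specification `rdf_graph`) and
#'   `config_xml` (the matching XML configuration as a string).
#' @export
build_toy_form_spec <- function(ontology_path = "backpain-form.ttl") {
  g <- rdf_graph()
  g <- rdf_add(g, BP_ONT_IRI, RDF_TYPE, OWL_ONTOLOGY)
  g <- rdf_add(g, BP_ONT_IRI, OWL_IMPORTS, DM_ONT_IRI)
  g <- rdf_add(g, BP_ONT_IRI, OWL_IMPORTS, CFA_ONT_IRI)

  g <- decl_ind(g, bp("BackPainForm"), dm("Form"), "Back Conditions Assessment")

  g <- decl_ind(g, bp("PatientInfoSection"), dm("SubjectInfoSection"))
  g <- rdf_add(g, bp("PatientInfoSection"), dm("hasHeading"),
               "Patient Information", lit = TRUE)
  g <- decl_ind(g, bp("SymptomSection"), dm("Section"))
  g <- rdf_add(g, bp("SymptomSection"), dm("hasHeading"),
               "Back and Lower Extremity Symptoms", lit = TRUE)

  q <- function(g, iri, text, values = character(), focus = NULL) {
    g <- decl_ind(g, iri, dm("Question"))
    g <- rdf_add(g, iri, dm("hasText"), text, lit = TRUE)
    if (length(values) > 0L) g <- rdf_add(g, iri, dm("hasPossibleValue"), values)
    if (!is.null(focus)) g <- rdf_add(g, iri, dm("isAbout"), focus)
    g
  }
  g <- q(g, bp("PatientNameInfo"), "Patient Name")
  g <- q(g, bp("PatientIDInfo"), "Patient ID")
  g <- q(g, bp("RadiculopathyQuestion"),
         "Does the patient have any signs or symptoms due to radiculopathy?",
         c(cfa("Yes"), cfa("No")), cfa("RadiculopathySignsSymptoms"))
  severity_values <- c(cfa("Mild"), cfa("Moderate"), cfa("NoneSeverity"), cfa("Severe"))
  g <- q(g, bp("RightSeverityQuestion"),
         "Severity of constant pain, right lower extremity",
         severity_values, cfa("SeverityConstantPainRightLowerExtremity"))
  g <- q(g, bp("LeftSeverityQuestion"),
         "Severity of constant pain, left lower extremity",
         severity_values, cfa("SeverityConstantPainLeftLowerExtremity"))
  g <- q(g, bp("ConditionsQuestion"),
         "Previously diagnosed back conditions")
  g <- q(g, bp("ConditionNameQuestion"), "Condition", focus = cfa("ConditionHistory"))
  g <- q(g, bp("ConditionDateQuestion"), "Date of diagnosis")
  g <- q(g, bp("ConditionICDQuestion"), "ICD code")

  config_xml <- paste0(
    '<?xml version="1.0" encoding="UTF-8"?>\n',
    '<configuration>\n',
    '  <input>\n',
    '    <ontology>', ontology_path, '</ontology>\n',
    '    <imports>\n',
    '      <ontology iri="', DM_ONT_IRI, '" path="datamodel.ttl"/>\n',
    '      <ontology iri="', CFA_ONT_IRI, '" path="cfa.ttl"/>\n',
    '    </imports>\n',
    '  </input>\n',
    '  <output>\n',
    '    <file title="Back Conditions Assessment"/>\n',
    '    <cssStyle>default</cssStyle>\n',
    '  </output>\n',
    '  <form>\n',
    '    <iri>', bp("BackPainForm"), '</iri>\n',
    '    <section type="subject_section">\n',
    '      <iri>', bp("PatientInfoSection"), '</iri>\n',
    '      <infoList type="inline">\n',
    '        <info type="text" required="true" property="', cfa("hasName"), '">\n',
    '          <iri>', bp("PatientNameInfo"), '</iri>\n',
    '        </info>\n',
    '        <info type="text" property="', cfa("hasID"), '">\n',
    '          <iri>', bp("PatientIDInfo"), '</iri>\n',
    '        </info>\n',
    '      </infoList>\n',
    '    </section>\n',
    '    <section type="question_section" numbered="true">\n',
    '      <iri>', bp("SymptomSection"), '</iri>\n',
    '      <questionList>\n',
    '        <question type="radio" numbered="true" required="true" ',
    'showSubquestionsForAnswer="', cfa("Yes"), '">\n',
    '          <iri>', bp("RadiculopathyQuestion"), '</iri>\n',
    '          <questionList>\n',
    '            <question type="radio" numbered="true" optionOrder="3;*">\n',
    '              <iri>', bp("RightSeverityQuestion"), '</iri>\n',
    '            </question>\n',
    '            <question type="radio" numbered="true" optionOrder="3;*">\n',
    '              <iri>', bp("LeftSeverityQuestion"), '</iri>\n',
    '            </question>\n',
    '          </questionList>\n',
    '        </question>\n',
    '        <question type="none" numbered="true">\n',
    '          <iri>', bp("ConditionsQuestion"), '</iri>\n',
    '          <questionList type="inline" repeat="2">\n',
    '            <question type="text">\n',
    '              <iri>', bp("ConditionNameQuestion"), '</iri>\n',
    '            </question>\n',
    '            <question type="text">\n',
    '              <iri>', bp("ConditionDateQuestion"), '</iri>\n',
    '            </question>\n',
    '            <question type="text">\n',
    '              <iri>', bp("ConditionICDQuestion"), '</iri>\n',
    '            </question>\n',
    '          </questionList>\n',
    '        </question>\n',
    '      </questionList>\n',
    '    </section>\n',
    '  </form>\n',
    '</configuration>\n')

  list(graph = g, config_xml = config_xml)
}

#' Assemble the full toy fixture set
#'
#' Convenience wrapper building the datamodel, domain ontology, form
#' specification and parsed configuration, with the merged graph and the
#' extracted `form_spec` ready for rendering and processing.
#'
#' @return List with `config` (`form_config`), `spec` (`form_spec`),
#'   `graph` (merged ontology graph) and the three component graphs.
#' @export
toy_fixture <- function() {
  dm_g <- build_datamodel_ontology()
  cfa_g <- build_toy_domain_ontology()
  form <- build_toy_form_spec()
  merged <- rdf_merge(dm_g, cfa_g, form$graph)
  config <- parse_config(form$config_xml)
  spec <- extract_form_spec(merged, config$bindings)
  list(config = config, spec = spec, graph = merged,
       datamodel = dm_g, domain = cfa_g, formspec = form$graph,
       config_xml = form$config_xml)
}

#' Write the shipped fixture files
#'
#' Serializes the datamodel, domain and form-specification ontologies as
#' Turtle next to the XML configuration, producing a self-contained example
#' directory for the command-line interface.
#'
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_files <- function(dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_turtle(build_datamodel_ontology(), file.path(dir, "datamodel.ttl"))
  write_turtle(build_toy_domain_ontology(), file.path(dir, "cfa.ttl"))
  form <- build_toy_form_spec()
  write_turtle(form$graph, file.path(dir, "backpain-form.ttl"))
  writeLines(form$config_xml, file.path(dir, "backpain-config.xml"), sep = "")
  invisible(dir)
}
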