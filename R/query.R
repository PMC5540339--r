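# Retrieval idioms over acquired data merged with the ontologies:
# focus-individual lookup (instrument-independent: any question annotated
# with the same description contributes) and description-component matching
# with anatomical subsumption over the asserted class hierarchy.

#' Observations with a given focus
#'
#' Returns the observations whose `hasFocus` points at the given
#' data-element description individual — regardless of which question (or
#' which form) produced them. With `class_iri` instead of `focus_iri`,
#' observations whose focus is typed by the class or any asserted subclass
#' are returned.
#'
#' @param graph Merged `rdf_graph` of acquired data plus ontologies.
#' @param focus_iri IRI of a description individual.
#' @param class_iri Alternatively, IRI of a description class; matching is
#'   up to asserted `rdfs:subClassOf` subsumption.
#' @return A `query_result` with variable `obs`.
#' @export
observations_by_focus <- function(graph, focus_iri = NULL, class_iri = NULL) {
  stopifnot(xor(is.null(focus_iri), is.null(class_iri)))
  q <- if (!is.null(focus_iri)) sprintf(
    "PREFIX dm: <%s>
     SELECT DISTINCT ?obs WHERE {
       ?obs a dm:Observation .
       ?obs dm:hasFocus <%s> .
     }", DM_NS, focus_iri)
  else sprintf(
    "PREFIX dm: <%s> PREFIX rdfs: <%s>
     SELECT DISTINCT ?obs WHERE {
       ?obs a dm:Observation .
       ?obs dm:hasFocus ?focus .
       ?focus a ?cls .
       ?cls rdfs:subClassOf* <%s> .
     }", DM_NS, RDFS_NS, class_iri)
  run_sparql(graph, q)
}

#' Observations matching a description pattern
#'
#' Retrieves observations whose focus description carries all the supplied
#' components: assessed attribute, assessed function, temporal quality and
#' laterality are matched exactly; the anatomical location is matched up to
#' subsumption (an observation located in the right or left lower extremity
#' matches a query for the lower extremity, because both location
#' individuals are typed by subclasses of the common structure class). A
#' `value` constraint additionally restricts the observation's selected
#' answer.
#'
#' @param graph Merged `rdf_graph` of acquired data plus ontologies.
#' @param attribute,fn,temporal,laterality Optional IRIs of description
#'   component individuals (assessed attribute, assessed function, temporal
#'   quality, laterality).
#' @param location_class Optional IRI of an anatomical structure class;
#'   matched via `rdf:type`/`rdfs:subClassOf*` on the focus location.
#' @param value Optional IRI restricting the observation's `hasValue`.
#' @return A `query_result` with variable `obs`.
#' @export
observations_by_description <- function(graph, attribute = NULL, fn = NULL,
                                        location_class = NULL, temporal = NULL,
                                        laterality = NULL, value = NULL) {
  clauses <- c("?obs a dm:Observation .", "?obs dm:hasFocus ?focus .")
  if (!is.null(attribute))
    clauses <- c(clauses, sprintf("?focus cfa:hasAssessedAttribute <%s> .", attribute))
  if (!is.null(fn))
    clauses <- c(clauses, sprintf("?focus cfa:hasAssessedFunction <%s> .", fn))
  if (!is.null(temporal))
    clauses <- c(clauses, sprintf("?focus cfa:hasTemporalQuality <%s> .", temporal))
  if (!is.null(laterality))
    clauses <- c(clauses, sprintf("?focus cfa:hasLaterality <%s> .", laterality))
  if (!is.null(location_class))
    clauses <- c(clauses,
                 "?focus cfa:hasAnatomicalLocation ?loc .",
                 "?loc a ?loctype .",
                 sprintf("?loctype rdfs:subClassOf* <%s> .", location_class))
  if (!is.null(value))
    clauses <- c(clauses, sprintf("?obs dm:hasValue <%s> .", value))
  q <- sprintf(
    "PREFIX dm: <%s> PREFIX cfa: <%s> PREFIX rdfs: <%s>
     SELECT DISTINCT ?obs WHERE {
       %s
     }", DM_NS, CFA_NS, RDFS_NS, paste(clauses, collapse = "\n       "))
  run_sparql(graph, q)
}

#' Path to a packaged example query
#'
#' The package ships example SPARQL queries under `inst/queries`:
#' `all_observations.rq`, `radiculopathy_observations.rq` (focus-based
#' retrieval) and `severe_pain_lower_extremity.rq` (description-component
#' retrieval aggregating left and right laterality).
#'
#' @param name Query file name (with or without the `.rq` extension);
#'   omit to list available queries.
#' @return File path, or a character vector of available query names.
#' @export
packaged_query <- function(name = NULL) {
  dir <- system.file("queries", package = "ontoforms")
  if (is.null(name)) return(list.files(dir, pattern = "\\.rq$"))
  if (!grepl("\\.rq$", name)) name <- paste0(name, ".rq")
  path <- file.path(dir, name)
  if (!file.exists(path))
    stop("no packaged query '", name, "'; available: ",
         paste(list.files(dir, pattern = "\\.rq$"), collapse = ", "),
         call. = FALSE)
  path
}
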