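# Form-specification ontology loading and content extraction.

#' Load an ontology with its imports
#'
#' Reads the form-specification ontology and merges it with the supplied
#' import documents. Formats are detected from content/extension: Turtle
#' (`.ttl`) and RDF/XML (`.rdf`, `.owl`, `.xml`). `owl:imports` declarations
#' whose IRIs are not covered by a supplied local document are reported with
#' a warning, not an error, so that specifications referring to remote
#' ontologies still load from local copies.
#'
#' @param source Path (or document string) of the main ontology.
#' @param imports Character vector of additional paths to merge in.
#' @return The merged `rdf_graph`.
#' @export
load_ontology <- function(source, imports = character()) {
  graphs <- lapply(c(source, imports), read_ontology_document)
  merged <- rdf_merge(graphs)
  declared <- rdf_match(merged, p = OWL_IMPORTS)$o
  loaded_onts <- rdf_instances(merged, OWL_ONTOLOGY)
  missing <- setdiff(declared, loaded_onts)
  if (length(missing) > 0L)
    warning("owl:imports not resolved locally (merge a local copy to include them): ",
            paste(missing, collapse = ", "), call. = FALSE)
  merged
}

read_ontology_document <- function(source) {
  is_path <- length(source) == 1L && !grepl("\n", source) && file.exists(source)
  if (is_path) {
    ext <- tolower(tools::file_ext(source))
    txt <- paste(readLines(source, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  } else {
    ext <- ""
    txt <- source
  }
  looks_xml <- grepl("^\\s*<\\?xml|^\\s*<rdf:RDF", txt)
  g <- tryCatch({
    if (ext %in% c("rdf", "owl", "xml") || (ext == "" && looks_xml))
      read_rdfxml(txt)
    else
      read_turtle(txt)
  }, error = function(e) {
    stop("failed to load ontology document '",
         if (is_path) source else "<inline>", "': ", conditionMessage(e),
         call. = FALSE)
  })
  g
}

#' Extract form content from an ontology graph
#'
#' Collects, for every individual asserted to be a `dm:Question`, its
#' displayable text (via the bound text property), its possible answer
#' values (via the bound possible-value property, labelled via the bound
#' label property and sorted alphabetically — the default presentation
#' order), and its semantic focus (via the bound focus property, normally
#' `dm:isAbout`). Section headings and form individuals are collected the
#' same way. Questions without a text assertion are skipped with a warning.
#'
#' @param graph Merged ontology graph from [load_ontology()].
#' @param bindings Named list of property IRIs (`question_text`,
#'   `section_heading`, `focus`, `possible_value`, `value_label`); defaults
#'   come from the datamodel vocabulary.
#' @return A `form_spec` object: `questions` and `sections` keyed by IRI,
#'   plus the set of `form_individuals`.
#' @export
extract_form_spec <- function(graph, bindings = default_bindings()) {
  b <- default_bindings()
  b[names(bindings)] <- bindings
  question_iris <- sort(rdf_instances(graph, dm("Question")))
  questions <- list()
  for (qi in question_iris) {
    text <- pick_literal(graph, qi, b$question_text)
    if (is.na(text)) {
      warning("question ", qi, " has no text (property <", b$question_text,
              ">); skipped", call. = FALSE)
      next
    }
    value_iris <- rdf_objects(graph, qi, b$possible_value)
    values <- lapply(value_iris, function(vi) {
      lab <- pick_literal(graph, vi, b$value_label)
      list(iri = vi, label = if (is.na(lab)) iri_local_name(vi) else lab)
    })
    values <- sort_values_alphabetically(values)
    focus <- rdf_objects(graph, qi, b$focus)
    questions[[qi]] <- list(iri = qi, text = text,
                            possible_values = values,
                            focus = if (length(focus) > 0L) focus[[1]] else NA_character_)
  }
  section_iris <- sort(unique(c(rdf_instances(graph, dm("Section")),
                                rdf_instances(graph, dm("SubjectInfoSection")))))
  sections <- list()
  for (si in section_iris) {
    heading <- pick_literal(graph, si, b$section_heading)
    sections[[si]] <- list(iri = si,
                           heading = if (is.na(heading)) "" else heading)
  }
  structure(list(ontology_iri = first_or_na(rdf_instances(graph, OWL_ONTOLOGY)),
                 questions = questions,
                 sections = sections,
                 form_individuals = sort(rdf_instances(graph, dm("Form"))),
                 bindings = b),
            class = "form_spec")
}

first_or_na <- function(x) if (length(x) > 0L) x[[1]] else NA_character_

# untagged literal preferred, then "en", then any
pick_literal <- function(graph, s, p) {
  tr <- rdf_match(graph, s = s, p = p)
  tr <- tr[tr$lit, , drop = FALSE]
  if (nrow(tr) == 0L) return(NA_character_)
  tr <- tr[order(match(tr$lang, c("", "en"), nomatch = 3L), tr$o), , drop = FALSE]
  tr$o[[1]]
}

# case-insensitive alphabetical by label; ties broken by IRI string order
sort_values_alphabetically <- function(values) {
  if (length(values) == 0L) return(values)
  labels <- vapply(values, function(v) v$label, "")
  iris <- vapply(values, function(v) v$iri, "")
  if (anyDuplicated(labels))
    warning("duplicate answer labels within one question: ",
            paste(unique(labels[duplicated(labels)]), collapse = ", "),
            call. = FALSE)
  values[order(tolower(labels), iris, method = "radix")]
}

#' @export
print.form_spec <- function(x, ...) {
  cat(sprintf("<form_spec: %d question(s), %d section(s), %d form individual(s)>\n",
              length(x$questions), length(x$sections), length(x$form_individuals)))
  invisible(x)
}
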