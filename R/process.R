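# Submission processing: answers -> semantically enriched data graph.
#
# Each answered question instance yields one Observation; the hasComponent
# partonomy mirrors the configuration nesting (form data -> section grouping
# node -> observations -> sub-question observations); info lists aggregate
# their answers as data-property assertions on a single individual; every
# observation inherits the focus of its source question.

#' Construct a submission
#'
#' @param form_iri IRI of the form individual the answers belong to.
#' @param answers Named list: form field name (see [render_form()] manifest)
#'   -> character vector of selected value IRIs or entered text.
#' @param timestamp ISO-8601 timestamp string.
#' @return A `form_submission` object.
#' @export
new_submission <- function(form_iri, answers,
                           timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%SZ", tz = "UTC")) {
  stopifnot(is.list(answers))
  if (length(answers) > 0L && is.null(names(answers)))
    stop("answers must be a named list keyed by form field name", call. = FALSE)
  answers <- answers[vapply(answers, length, 0L) > 0L]
  structure(list(form_iri = form_iri, answers = answers, timestamp = timestamp),
            class = "form_submission")
}

#' @export
print.form_submission <- function(x, ...) {
  cat(sprintf("<form_submission: %s, %d answered field(s)>\n",
              x$form_iri, length(x$answers)))
  invisible(x)
}

ENUM_WIDGETS <- c("radio", "checkbox", "checkbox-horizontal", "dropdown")

# is an instance visible given the submitted answers and its trigger chain?
instance_visible <- function(node, answers) {
  conds <- node$visible_if
  if (is.null(conds) || length(conds) == 0L) return(TRUE)
  for (cond in conds) {
    selected <- cond$answer %in% (answers[[cond$field]] %||% character(0))
    if (cond$kind == "show" && !selected) return(FALSE)
    if (cond$kind == "hide" && selected) return(FALSE)
  }
  TRUE
}

`%||%` <- function(a, b) if (is.null(a)) b else a

validate_submission <- function(submission, tree, manifest) {
  answers <- submission$answers
  problems <- character(0)
  known_fields <- vapply(manifest, function(r) r$field_name, "")
  unknown <- setdiff(names(answers), known_fields)
  if (length(unknown) > 0L)
    problems <- c(problems, paste0("unknown field(s): ", paste(unknown, collapse = ", ")))
  for (node in tree_instances(tree)) {
    f <- node$field
    if (is.na(f)) next
    ans <- answers[[f]]
    visible <- if (identical(node$kind, "question")) instance_visible(node, answers) else TRUE
    if (!visible && !is.null(ans))
      problems <- c(problems, paste0(
        "answer given for field ", f, " (question ", node$iri,
        ") whose trigger condition is not met"))
    if (visible && node$required && is.null(ans))
      problems <- c(problems, paste0("missing required field ", f,
                                     " (", node$iri, ")"))
    if (!is.null(ans) && node$widget_type %in% ENUM_WIDGETS) {
      allowed <- vapply(node$options, function(v) v$iri, "")
      bad <- setdiff(ans, allowed)
      if (length(bad) > 0L)
        problems <- c(problems, paste0(
          "answer(s) ", paste(bad, collapse = ", "),
          " not among the possible values of question ", node$iri))
      if (node$widget_type %in% c("radio", "dropdown") && length(ans) > 1L)
        problems <- c(problems, paste0("multiple answers for single-valued field ", f))
    }
  }
  problems
}

#' Process a submission into an acquired-data graph
#'
#' Validates the answers against the widget manifest (required fields,
#' allowed values, trigger conditions — re-checked server-side even though
#' the rendered form clears suppressed inputs) and creates the data
#' individuals: one `FormData` root, one grouping `Data` individual per
#' section, one `Observation` per answered question instance (with
#' `hasValue` assertions to selected value IRIs, a literal text value for
#' free-text answers, and `hasFocus` copied from the question's `isAbout`
#' description), and one aggregated individual per answered info-list copy
#' carrying its data-property assertions.
#'
#' @param submission A `form_submission`.
#' @param config A `form_config`.
#' @param spec A `form_spec`.
#' @param manifest Manifest from [render_form()]; rebuilt from the
#'   configuration when omitted.
#' @param submission_id Identifier used to mint data-individual IRIs
#'   (`<data namespace>/<submission id>/<type>/<counter>`); supply one for
#'   reproducible output, otherwise a timestamp-derived id is used.
#' @return An `acquired_graph`: list with `graph` (`rdf_graph`),
#'   `form_data_iri`, `submission_id` and `imports`.
#' @export
process_submission <- function(submission, config, spec, manifest = NULL,
                               submission_id = NULL) {
  stopifnot(inherits(submission, "form_submission"))
  tree <- build_instance_tree(config, spec)
  if (is.null(manifest)) manifest <- build_manifest(tree)
  problems <- validate_submission(submission, tree, manifest)
  if (length(problems) > 0L)
    stop("invalid submission:\n  - ", paste(problems, collapse = "\n  - "),
         call. = FALSE)
  if (is.null(submission_id))
    submission_id <- paste0("s", format(as.numeric(Sys.time()) * 1000, scientific = FALSE))

  ns <- paste0(DATA_NS, submission_id, "/")
  counters <- new.env(parent = emptyenv())
  mint <- function(type) {
    k <- (counters[[type]] %||% 0L) + 1L
    counters[[type]] <- k
    paste0(ns, type, "/", k)
  }
  g <- rdf_graph()
  answers <- submission$answers

  form_data <- paste0(ns, "formdata/1")
  g <- rdf_add(g, form_data, RDF_TYPE, dm("FormData"))
  g <- rdf_add(g, form_data, dm("sourceForm"), submission$form_iri)
  g <- rdf_add(g, form_data, dm("submissionTimestamp"), submission$timestamp,
               lit = TRUE)

  process_question <- function(node, parent_iri) {
    ans <- if (is.na(node$field)) NULL else answers[[node$field]]
    answered <- !is.na(node$field) && !is.null(ans) &&
      instance_visible(node, answers)
    attach_to <- parent_iri
    if (answered) {
      obs <- mint("observation")
      g <<- rdf_add(g, obs, RDF_TYPE, dm("Observation"))
      g <<- rdf_add(g, parent_iri, dm("hasComponent"), obs)
      g <<- rdf_add(g, obs, dm("sourceQuestion"), node$iri)
      g <<- rdf_add(g, obs, dm("repeatIndex"), as.character(node$repeat_index),
                    lit = TRUE, dtype = paste0(XSD_NS, "integer"))
      if (node$widget_type %in% ENUM_WIDGETS) {
        g <<- rdf_add(g, obs, dm("hasValue"), ans)
      } else {
        g <<- rdf_add(g, obs, dm("hasTextValue"), ans, lit = TRUE)
      }
      if (!is.na(node$focus)) g <<- rdf_add(g, obs, dm("hasFocus"), node$focus)
      attach_to <- obs
    }
    for (sl in node$sublists)
      for (child in sl$nodes) process_question(child, attach_to)
  }

  for (sec in tree$sections) {
    sec_node <- mint("sectiondata")
    g <- rdf_add(g, sec_node, RDF_TYPE, dm("Data"))
    g <- rdf_add(g, sec_node, dm("sourceSection"), sec$iri)
    g <- rdf_add(g, form_data, dm("hasComponent"), sec_node)
    for (item in sec$items) {
      if (item$kind == "qlist") {
        for (node in item$nodes) process_question(node, sec_node)
      } else {
        for (grp in item$groups) {
          answered_fields <- Filter(function(f) !is.null(answers[[f$field]]),
                                    grp$fields)
          if (length(answered_fields) == 0L) next
          ind <- if (identical(grp$individual, "new")) mint("info") else grp$individual
          type <- switch(grp$section_type,
                         subject_section = dm("SubjectInformation"),
                         evaluator_section = dm("EvaluatorInformation"),
                         dm("Data"))
          g <- rdf_add(g, ind, RDF_TYPE, type)
          g <- rdf_add(g, ind, dm("repeatIndex"), as.character(grp$repeat_index),
                       lit = TRUE, dtype = paste0(XSD_NS, "integer"))
          g <- rdf_add(g, sec_node, dm("hasComponent"), ind)
          for (f in answered_fields) {
            vals <- answers[[f$field]]
            if (f$widget_type %in% ENUM_WIDGETS) {
              g <- rdf_add(g, ind, f$data_property, vals)
            } else {
              g <- rdf_add(g, ind, f$data_property, vals, lit = TRUE)
            }
            g <- rdf_add(g, ind, dm("sourceQuestion"), f$iri)
          }
        }
      }
    }
  }
  structure(list(graph = g, form_data_iri = form_data,
                 submission_id = submission_id,
                 imports = unique(c(DM_ONT_IRI, config$import_iris))),
            class = "acquired_graph")
}

#' @export
print.acquired_graph <- function(x, ...) {
  n_obs <- length(rdf_instances(x$graph, dm("Observation")))
  cat(sprintf("<acquired_graph: %s; %d observation(s), %d triple(s)>\n",
              x$form_data_iri, n_obs, rdf_size(x$graph)))
  invisible(x)
}

#' Observations of an acquired graph as a data frame
#'
#' One row per observation: submission id, source question IRI, repeat
#' index, selected value(s) (IRIs or entered text, `|`-joined when
#' multi-valued) and focus IRI.
#'
#' @param acquired An `acquired_graph`, or a merged `rdf_graph`.
#' @param submission_id Id recorded in the `submission` column when a bare
#'   graph is given.
#' @return data.frame with columns `submission`, `question_iri`,
#'   `repeat_index`, `value`, `focus_iri`.
#' @export
observations_df <- function(acquired, submission_id = NA_character_) {
  g <- if (inherits(acquired, "acquired_graph")) acquired$graph else acquired
  if (inherits(acquired, "acquired_graph")) submission_id <- acquired$submission_id
  obs <- rdf_instances(g, dm("Observation"))
  rows <- lapply(obs, function(o) {
    vals <- c(rdf_objects(g, o, dm("hasValue")),
              rdf_objects(g, o, dm("hasTextValue")))
    ri <- rdf_objects(g, o, dm("repeatIndex"))
    sid <- submission_id
    if (is.na(sid)) {
      m <- regmatches(o, regexec(paste0("^", DATA_NS, "([^/]+)/"), o))[[1]]
      if (length(m) == 2L) sid <- m[2]
    }
    data.frame(submission = sid,
               question_iri = first_or_na(rdf_objects(g, o, dm("sourceQuestion"))),
               repeat_index = as.integer(first_or_na(ri)),
               value = paste(sort(vals), collapse = "|"),
               focus_iri = first_or_na(rdf_objects(g, o, dm("hasFocus"))),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, c(rows, list(make.row.names = FALSE)))
  if (is.null(out))
    out <- data.frame(submission = character(), question_iri = character(),
                      repeat_index = integer(), value = character(),
                      focus_iri = character(), stringsAsFactors = FALSE)
  out[order(out$submission, out$question_iri, out$repeat_index), , drop = FALSE]
}

#' Serialize an acquired-data graph
#'
#' @param acquired An `acquired_graph`.
#' @param format `"csv"` (one row per observation, RFC 4180), `"rdf"`
#'   (Turtle of the data graph) or `"owl"` (RDF/XML with an ontology header
#'   importing the datamodel and domain ontologies so a reasoner can
#'   interpret the data).
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
serialize_acquired <- function(acquired, format = c("csv", "rdf", "owl"), path) {
  stopifnot(inherits(acquired, "acquired_graph"))
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(observations_df(acquired), path, row.names = FALSE)
  } else if (format == "rdf") {
    write_turtle(acquired$graph, path)
  } else {
    write_rdfxml(acquired$graph, path,
                 ontology_iri = paste0(DATA_NS, acquired$submission_id),
                 imports = acquired$imports)
  }
  invisible(path)
}

#' Merge acquired-data graphs
#'
#' @param graphs List of `acquired_graph` objects (or bare `rdf_graph`s).
#' @return The union `rdf_graph`. Minted data individuals must be disjoint
#'   across submissions; a collision raises an error since it indicates an
#'   IRI-minting bug.
#' @export
merge_submissions <- function(graphs) {
  stopifnot(is.list(graphs))
  gs <- lapply(graphs, function(x)
    if (inherits(x, "acquired_graph")) x$graph else x)
  minted <- lapply(gs, function(g)
    unique(g$triples$s[startsWith(g$triples$s, DATA_NS)]))
  all_minted <- unlist(minted)
  if (anyDuplicated(all_minted) > 0L)
    stop("individual IRI collision across submissions: ",
         paste(unique(all_minted[duplicated(all_minted)]), collapse = ", "),
         call. = FALSE)
  if (length(gs) == 0L) return(rdf_graph())
  rdf_merge(gs)
}
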