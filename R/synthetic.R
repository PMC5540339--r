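# Seeded synthetic data: submission generation for any configured form, and
# a random form-fixture generator used to exercise the pipeline over many
# layout shapes. Both are deterministic under their seed.

#' Synthetic submission model
#'
#' Describes how synthetic answers are drawn: every visible required field
#' is always answered; visible optional fields are answered with probability
#' `completion_rate`; enumerated answers are drawn from the question's
#' possible values (uniformly unless per-question weights are supplied);
#' free-text answers are short plausible strings from a fixed word pool.
#'
#' @param seed Integer seed; identical seeds reproduce identical submissions.
#' @param completion_rate Probability in `[0, 1]` that a visible optional
#'   field is answered (default 1: complete submissions).
#' @param answer_weights Optional named list: question IRI -> numeric vector
#'   of weights over that question's presented options.
#' @return A `submission_model` object.
#' @export
submission_model <- function(seed = 1L, completion_rate = 1,
                             answer_weights = list()) {
  stopifnot(completion_rate >= 0, completion_rate <= 1)
  structure(list(seed = as.integer(seed), completion_rate = completion_rate,
                 answer_weights = answer_weights),
            class = "submission_model")
}

TEXT_WORDS <- c("chronic", "acute", "lumbar", "thoracic", "strain", "sprain",
                "stenosis", "arthritis", "2014-03-02", "2016-11-20", "M54.5",
                "M51.2", "S33.5", "follow-up", "stable", "improving")

#' Generate synthetic submissions for a form
#'
#' Walks the rendered layout top-down, drawing answers field by field.
#' Sub-questions behind a show/hide trigger are answered only when the
#' drawn controlling answer makes them visible, so every generated
#' submission is accepted by [process_submission()].
#'
#' @param model A [submission_model()].
#' @param config A `form_config`.
#' @param spec A `form_spec`.
#' @param n Number of submissions.
#' @return List of `n` `form_submission` objects.
#' @export
generate_submissions <- function(model, config, spec, n) {
  stopifnot(inherits(model, "submission_model"), n >= 1L)
  tree <- build_instance_tree(config, spec)
  instances <- tree_instances(tree)
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(model$seed)
  out <- vector("list", n)
  for (i in seq_len(n)) {
    answers <- list()
    for (node in instances) {
      if (is.na(node$field)) next
      visible <- !identical(node$kind, "question") || instance_visible(node, answers)
      if (!visible) next
      answer_it <- node$required || stats::runif(1) < model$completion_rate
      if (!answer_it) next
      if (node$widget_type %in% ENUM_WIDGETS) {
        opts <- vapply(node$options, function(v) v$iri, "")
        if (length(opts) == 0L) next
        w <- model$answer_weights[[node$iri]]
        if (is.null(w) || length(w) != length(opts)) w <- rep(1, length(opts))
        if (node$widget_type %in% c("checkbox", "checkbox-horizontal")) {
          k <- 1L + stats::rbinom(1, length(opts) - 1L, 0.25)
          picked <- sample(seq_along(opts), k, prob = w)
        } else {
          picked <- sample(seq_along(opts), 1L, prob = w)
        }
        answers[[node$field]] <- opts[sort(picked)]
      } else {
        answers[[node$field]] <- paste(
          TEXT_WORDS[sample(seq_along(TEXT_WORDS), 2L)], collapse = " ")
      }
    }
    out[[i]] <- new_submission(config$form_iri, answers,
                               timestamp = sprintf("2017-08-01T00:00:%02dZ", i %% 60))
  }
  out
}

#' Generate a random form fixture
#'
#' Builds a random configuration tree (nested sections, question lists with
#' repeats, show/hide triggers, all widget types) together with a matching
#' form-specification graph, for property-style testing of the pipeline
#' over many layout shapes.
#'
#' @param seed Integer seed.
#' @param max_depth Maximum question-nesting depth (default 4).
#' @param max_questions Maximum number of question individuals (default 30).
#' @param max_repeat Maximum list repeat count (default 3).
#' @param p_trigger Probability that a radio question with sub-questions
#'   gets a show/hide trigger.
#' @return List with `config` (`form_config`), `spec` (`form_spec`),
#'   `graph` (merged datamodel + fixture graph) and `config_xml`.
#' @export
random_form_fixture <- function(seed, max_depth = 4L, max_questions = 30L,
                                max_repeat = 3L, p_trigger = 0.5) {
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(seed)
  rf_ns <- "http://example.org/ontoforms/random-fixture#"
  rf <- function(x) paste0(rf_ns, x)

  g <- rdf_graph(namespaces = c(of_namespaces(), rf = rf_ns))
  # small value and focus pools
  value_pool <- paste0("Value", 1:6)
  value_labels <- c("Absent", "Mild", "Moderate", "Severe", "Unknown", "Worse")
  for (k in seq_along(value_pool)) {
    g <- rdf_add(g, rf(value_pool[k]), RDF_TYPE, dm("Value"))
    g <- rdf_add(g, rf(value_pool[k]), RDFS_LABEL, value_labels[k], lit = TRUE)
  }
  focus_pool <- paste0("Focus", 1:4)
  for (f in focus_pool) {
    g <- rdf_add(g, rf(f), RDF_TYPE, dm("DataElementDescription"))
    g <- rdf_add(g, rf(f), RDFS_LABEL, paste("Description", f), lit = TRUE)
  }

  q_count <- 0L
  new_question <- function(widget) {
    q_count <<- q_count + 1L
    iri <- rf(paste0("Q", q_count))
    g <<- rdf_add(g, iri, RDF_TYPE, dm("Question"))
    g <<- rdf_add(g, iri, dm("hasText"),
                  paste("Question", q_count), lit = TRUE)
    n_opts <- 0L
    if (widget %in% ENUM_WIDGETS) {
      n_opts <- sample(2:4, 1L)
      picked <- sample(value_pool, n_opts)
      g <<- rdf_add(g, iri, dm("hasPossibleValue"), rf(picked))
    }
    if (stats::runif(1) < 0.5)
      g <<- rdf_add(g, iri, dm("isAbout"), rf(sample(focus_pool, 1L)))
    list(iri = iri, n_opts = n_opts)
  }

  gen_question_xml <- function(depth) {
    widget <- sample(c("radio", "radio", "checkbox", "dropdown", "text",
                       "textarea", "none"), 1L)
    if (widget == "none" && (depth >= max_depth || q_count + 2L > max_questions))
      widget <- "text"
    q <- new_question(widget)
    attrs <- sprintf(' type="%s"', widget)
    if (stats::runif(1) < 0.5) attrs <- paste0(attrs, ' numbered="true"')
    if (widget != "none" && stats::runif(1) < 0.5)
      attrs <- paste0(attrs, ' required="true"')
    n_sub <- 0L
    if (depth < max_depth && q_count < max_questions &&
        (widget == "none" || stats::runif(1) < 0.3))
      n_sub <- sample(1:2, 1L)
    subs <- if (n_sub > 0L) gen_qlist_xml(depth + 1L, n_sub) else ""
    if (widget == "radio" && nzchar(subs) && stats::runif(1) < p_trigger) {
      opts <- rdf_objects(g, q$iri, dm("hasPossibleValue"))
      kind <- if (stats::runif(1) < 0.8) "showSubquestionsForAnswer"
              else "hideSubquestionsForAnswer"
      attrs <- paste0(attrs, sprintf(' %s="%s"', kind, sample(opts, 1L)))
    }
    paste0("<question", attrs, "><iri>", q$iri, "</iri>", subs, "</question>")
  }

  gen_qlist_xml <- function(depth, n_q = NULL) {
    if (is.null(n_q)) n_q <- sample(1:4, 1L)
    n_q <- min(n_q, max_questions - q_count)
    if (n_q < 1L) return("")
    rep_n <- sample(c(1L, 1L, 1L, seq_len(max_repeat)), 1L)
    layout <- sample(c("normal", "inline"), 1L)
    qs <- vapply(seq_len(n_q), function(i) gen_question_xml(depth), "")
    sprintf('<questionList type="%s" repeat="%d">%s</questionList>',
            layout, rep_n, paste(qs, collapse = ""))
  }

  n_sections <- sample(1:2, 1L)
  section_xml <- character(0)
  for (s in seq_len(n_sections)) {
    sec_iri <- rf(paste0("Section", s))
    g <- rdf_add(g, sec_iri, RDF_TYPE, dm("Section"))
    g <- rdf_add(g, sec_iri, dm("hasHeading"), paste("Section", s), lit = TRUE)
    n_lists <- sample(1:2, 1L)
    lists <- vapply(seq_len(n_lists), function(i) gen_qlist_xml(1L), "")
    numbered <- if (stats::runif(1) < 0.5) ' numbered="true"' else ""
    section_xml <- c(section_xml,
                     sprintf('<section type="question_section"%s><iri>%s</iri>%s</section>',
                             numbered, sec_iri, paste(lists, collapse = "")))
  }
  form_iri <- rf("Form")
  g <- rdf_add(g, form_iri, RDF_TYPE, dm("Form"))
  config_xml <- paste0(
    "<configuration><input><ontology>inline</ontology></input>",
    "<output><file title=\"Random fixture\"/></output>",
    "<form><iri>", form_iri, "</iri>",
    paste(section_xml, collapse = ""),
    "</form></configuration>")

  merged <- rdf_merge(build_datamodel_ontology(), g)
  config <- parse_config(config_xml)
  spec <- extract_form_spec(merged, config$bindings)
  list(config = config, spec = spec, graph = merged, config_xml = config_xml)
}

#' Demo cohort submission model
#'
#' The submission model used for the packaged five-patient demo dataset:
#' complete submissions whose severity answers are skewed toward the severe
#' end of the scale (weights 1:1:1:3 over the presented options), emulating
#' a symptomatic cohort so that description-level queries have matches on
#' both lateralities.
#'
#' @param seed Integer seed.
#' @return A [submission_model()].
#' @export
demo_submission_model <- function(seed = 7L) {
  w <- list()
  w[[bp("RightSeverityQuestion")]] <- c(1, 1, 1, 3)
  w[[bp("LeftSeverityQuestion")]] <- c(1, 1, 1, 3)
  submission_model(seed = seed, completion_rate = 1, answer_weights = w)
}
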