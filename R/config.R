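# XML form-configuration parsing and validation.
#
# The configuration document drives form generation: input/output locations,
# bindings to ontology properties, and the layout tree of sections, question
# lists, questions (with sub-question lists) and info lists. The grammar is
# enforced explicitly so that misplaced elements, unknown attributes and bad
# enum values are reported with the offending node's path.

WIDGET_TYPES <- c("text", "textarea", "radio", "checkbox",
                  "checkbox-horizontal", "dropdown", "none")
SECTION_TYPES <- c("question_section", "subject_section", "evaluator_section")

default_bindings <- function() {
  list(question_text   = dm("hasText"),
       section_heading = dm("hasHeading"),
       focus           = dm("isAbout"),
       possible_value  = dm("hasPossibleValue"),
       value_label     = RDFS_LABEL)
}

config_error <- function(msg, node = NULL) {
  loc <- if (!is.null(node)) paste0(" at ", xml2::xml_path(node)) else ""
  stop("configuration error: ", msg, loc, call. = FALSE)
}

check_attrs <- function(node, allowed) {
  attrs <- names(xml2::xml_attrs(node))
  bad <- setdiff(attrs, allowed)
  if (length(bad) > 0L)
    config_error(paste0("unknown attribute(s) ", paste(sQuote(bad), collapse = ", "),
                        " on <", xml2::xml_name(node), ">"), node)
}

check_children <- function(node, allowed) {
  kids <- xml2::xml_name(xml2::xml_children(node))
  bad <- setdiff(kids, allowed)
  if (length(bad) > 0L)
    config_error(paste0("unknown element(s) ", paste(sQuote(bad), collapse = ", "),
                        " inside <", xml2::xml_name(node), ">"), node)
}

attr_or <- function(node, name, default) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) default else v
}

attr_bool <- function(node, name, default = FALSE) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  if (!v %in% c("true", "false"))
    config_error(paste0("attribute '", name, "' must be 'true' or 'false', got '", v, "'"), node)
  v == "true"
}

attr_enum <- function(node, name, allowed, default) {
  v <- xml2::xml_attr(node, name)
  if (is.na(v)) return(default)
  if (!v %in% allowed)
    config_error(paste0("attribute '", name, "' has value '", v,
                        "'; allowed: ", paste(allowed, collapse = ", ")), node)
  v
}

child_iri <- function(node) {
  iri_nodes <- xml2::xml_find_all(node, "./iri")
  if (length(iri_nodes) != 1L)
    config_error(paste0("<", xml2::xml_name(node), "> requires exactly one <iri> child"), node)
  iri <- trimws(xml2::xml_text(iri_nodes[[1]]))
  if (!is_valid_iri(iri))
    config_error(paste0("'", iri, "' is not a valid IRI"), node)
  iri
}

#' Parse an XML form configuration
#'
#' Reads the layout configuration into a validated tree: input/output
#' options, property bindings, and the ordered section/list/question
#' structure. Element order in the result equals XML document order; absent
#' attributes take their documented defaults (`repeat` 1, `numbered` and
#' `required` false, list layout `normal`).
#'
#' @param xml_text Configuration document as a string, or a file path.
#' @return A `form_config` object; see the vignette for the tree structure.
#' @export
parse_config <- function(xml_text) {
  doc <- tryCatch(xml2::read_xml(xml_text),
                  error = function(e) stop("XML parse error: ",
                                           conditionMessage(e), call. = FALSE))
  root <- xml2::xml_root(doc)
  if (xml2::xml_name(root) != "configuration")
    config_error("root element must be <configuration>", root)
  check_children(root, c("input", "output", "bindings", "form"))

  input_node <- xml2::xml_find_first(root, "./input")
  if (is.na(input_node) || length(input_node) == 0L)
    config_error("missing <input> element", root)
  check_children(input_node, c("ontology", "imports"))
  ont_node <- xml2::xml_find_first(input_node, "./ontology")
  if (inherits(ont_node, "xml_missing"))
    config_error("missing <input>/<ontology>", input_node)
  input_ontology <- trimws(xml2::xml_text(ont_node))
  import_iris <- character(0)
  import_paths <- character(0)
  imports_node <- xml2::xml_find_first(input_node, "./imports")
  if (!inherits(imports_node, "xml_missing")) {
    check_children(imports_node, "ontology")
    for (imp in xml2::xml_find_all(imports_node, "./ontology")) {
      check_attrs(imp, c("iri", "path"))
      iri <- xml2::xml_attr(imp, "iri")
      if (is.na(iri)) config_error("import <ontology> requires an 'iri' attribute", imp)
      import_iris <- c(import_iris, iri)
      import_paths <- c(import_paths, attr_or(imp, "path", NA_character_))
    }
  }

  output_title <- ""
  output_path <- NULL
  css_style <- "default"
  output_node <- xml2::xml_find_first(root, "./output")
  if (!inherits(output_node, "xml_missing")) {
    check_children(output_node, c("file", "cssStyle"))
    file_node <- xml2::xml_find_first(output_node, "./file")
    if (!inherits(file_node, "xml_missing")) {
      check_attrs(file_node, c("title", "path"))
      output_title <- attr_or(file_node, "title", "")
      p <- xml2::xml_attr(file_node, "path")
      if (!is.na(p)) output_path <- p
    }
    css_node <- xml2::xml_find_first(output_node, "./cssStyle")
    if (!inherits(css_node, "xml_missing")) css_style <- trimws(xml2::xml_text(css_node))
  }

  bindings <- default_bindings()
  bindings_node <- xml2::xml_find_first(root, "./bindings")
  if (!inherits(bindings_node, "xml_missing")) {
    allowed <- c(questionText = "question_text", sectionHeading = "section_heading",
                 focus = "focus", possibleValue = "possible_value",
                 valueLabel = "value_label")
    check_children(bindings_node, names(allowed))
    for (b in xml2::xml_children(bindings_node)) {
      check_attrs(b, "iri")
      iri <- xml2::xml_attr(b, "iri")
      if (is.na(iri) || !is_valid_iri(iri))
        config_error("binding requires a valid 'iri' attribute", b)
      bindings[[allowed[[xml2::xml_name(b)]]]] <- iri
    }
  }

  form_node <- xml2::xml_find_first(root, "./form")
  if (inherits(form_node, "xml_missing"))
    config_error("missing <form> element", root)
  check_children(form_node, c("iri", "section"))
  form_iri <- child_iri(form_node)
  section_nodes <- xml2::xml_find_all(form_node, "./section")
  if (length(section_nodes) == 0L)
    config_error("<form> must contain at least one <section>", form_node)
  sections <- lapply(section_nodes, parse_section_node)

  structure(list(form_iri = form_iri,
                 input_ontology = input_ontology,
                 import_iris = import_iris,
                 import_paths = import_paths,
                 output_title = output_title,
                 output_path = output_path,
                 css_style = css_style,
                 bindings = bindings,
                 sections = sections),
            class = "form_config")
}

parse_section_node <- function(node) {
  check_attrs(node, c("type", "numbered"))
  check_children(node, c("iri", "questionList", "infoList"))
  lists <- lapply(xml2::xml_find_all(node, "./questionList|./infoList"),
                  function(ln) {
                    if (xml2::xml_name(ln) == "questionList") parse_question_list_node(ln)
                    else parse_info_list_node(ln)
                  })
  list(iri = child_iri(node),
       section_type = attr_enum(node, "type", SECTION_TYPES, "question_section"),
       numbered = attr_bool(node, "numbered"),
       lists = lists)
}

parse_repeat <- function(node) {
  v <- xml2::xml_attr(node, "repeat")
  if (is.na(v)) return(1L)
  r <- suppressWarnings(as.integer(v))
  if (is.na(r) || r < 1L)
    config_error(paste0("'repeat' must be a positive integer, got '", v, "'"), node)
  r
}

parse_question_list_node <- function(node) {
  check_attrs(node, c("type", "repeat"))
  check_children(node, "question")
  qnodes <- xml2::xml_find_all(node, "./question")
  list(kind = "questionList",
       layout = attr_enum(node, "type", c("inline", "normal"), "normal"),
       repeat_n = parse_repeat(node),
       questions = lapply(qnodes, parse_question_node))
}

parse_question_node <- function(node) {
  check_attrs(node, c("type", "numbered", "required", "optionOrder",
                      "showSubquestionsForAnswer", "hideSubquestionsForAnswer"))
  check_children(node, c("iri", "questionList"))
  show_trigger <- attr_or(node, "showSubquestionsForAnswer", NA_character_)
  hide_trigger <- attr_or(node, "hideSubquestionsForAnswer", NA_character_)
  list(kind = "question",
       iri = child_iri(node),
       widget_type = attr_enum(node, "type", WIDGET_TYPES, "text"),
       numbered = attr_bool(node, "numbered"),
       required = attr_bool(node, "required"),
       option_order = attr_or(node, "optionOrder", NA_character_),
       show_trigger = show_trigger,
       hide_trigger = hide_trigger,
       subquestion_lists = lapply(xml2::xml_find_all(node, "./questionList"),
                                  parse_question_list_node))
}

parse_info_list_node <- function(node) {
  check_attrs(node, c("type", "repeat", "individual"))
  check_children(node, "info")
  inodes <- xml2::xml_find_all(node, "./info")
  if (length(inodes) == 0L)
    config_error("<infoList> must contain at least one <info>", node)
  list(kind = "infoList",
       layout = attr_enum(node, "type", c("inline", "normal"), "normal"),
       repeat_n = parse_repeat(node),
       individual = attr_or(node, "individual", "new"),
       infos = lapply(inodes, parse_info_node))
}

parse_info_node <- function(node) {
  check_attrs(node, c("type", "required", "optionOrder", "property"))
  check_children(node, "iri")
  prop <- xml2::xml_attr(node, "property")
  if (is.na(prop) || !is_valid_iri(prop))
    config_error("<info> requires a valid 'property' attribute", node)
  wt <- attr_enum(node, "type", setdiff(WIDGET_TYPES, "none"), "text")
  list(kind = "info",
       iri = child_iri(node),
       data_property_iri = prop,
       widget_type = wt,
       required = attr_bool(node, "required"),
       option_order = attr_or(node, "optionOrder", NA_character_))
}

#' @export
print.form_config <- function(x, ...) {
  nq <- length(config_questions(x))
  cat(sprintf("<form_config: %s; %d section(s), %d question(s)>\n",
              x$form_iri, length(x$sections), nq))
  invisible(x)
}

# All question configs in document order (depth-first, including sub-questions).
config_questions <- function(config) {
  out <- list()
  walk_ql <- function(ql) {
    for (q in ql$questions) {
      out[[length(out) + 1L]] <<- q
      for (sub in q$subquestion_lists) walk_ql(sub)
    }
  }
  for (sec in config$sections)
    for (ln in sec$lists)
      if (ln$kind == "questionList") walk_ql(ln)
  out
}

config_infos <- function(config) {
  out <- list()
  for (sec in config$sections)
    for (ln in sec$lists)
      if (ln$kind == "infoList")
        for (inf in ln$infos) out[[length(out) + 1L]] <- inf
  out
}

#' Resolve an option-order specification
#'
#' Answer options are presented alphabetically by default; an order spec such
#' as `"3;*"` overrides this: positions listed before `"*"` come first (in
#' listed order), `"*"` expands to all unlisted positions in ascending order,
#' and positions listed after `"*"` come last. Positions are 1-based indices
#' into the default alphabetical order.
#'
#' @param order_spec Semicolon-separated positive integers with at most one
#'   `"*"`, e.g. `"3;*"`, `"*;4"`, `"2;*;4"`.
#' @param n Number of options.
#' @return An integer permutation of `1:n` giving the presentation order.
#' @examples
#' resolve_option_order("3;*", 4)    # c(3, 1, 2, 4)
#' resolve_option_order("2;*;4", 5)  # c(2, 1, 3, 5, 4)
#' @export
resolve_option_order <- function(order_spec, n) {
  stopifnot(is.character(order_spec), length(order_spec) == 1L,
            n >= 1L, n == as.integer(n))
  parts <- strsplit(order_spec, ";", fixed = TRUE)[[1]]
  parts <- trimws(parts)
  if (length(parts) == 0L || any(!nzchar(parts)))
    stop("invalid optionOrder '", order_spec, "': empty segment", call. = FALSE)
  star_at <- which(parts == "*")
  if (length(star_at) > 1L)
    stop("invalid optionOrder '", order_spec, "': multiple '*'", call. = FALSE)
  nums <- parts[parts != "*"]
  if (length(nums) > 0L && any(!grepl("^[0-9]+$", nums)))
    stop("invalid optionOrder '", order_spec, "': segments must be positive integers or '*'",
         call. = FALSE)
  idx <- as.integer(nums)
  if (any(idx < 1L) || any(idx > n))
    stop("invalid optionOrder '", order_spec, "': index out of range 1..", n, call. = FALSE)
  if (anyDuplicated(idx))
    stop("invalid optionOrder '", order_spec, "': duplicate index", call. = FALSE)
  if (length(star_at) == 0L) {
    before <- idx
    after <- integer(0)
  } else {
    npart <- cumsum(parts == "*")
    before <- as.integer(parts[parts != "*" & npart == 0L])
    after <- as.integer(parts[parts != "*" & npart == 1L])
  }
  rest <- setdiff(seq_len(n), c(before, after))
  out <- c(before, rest, after)
  stopifnot(length(out) == n)
  out
}

#' Cross-validate a configuration against a form specification
#'
#' Checks that every IRI the configuration refers to resolves to an
#' individual of the expected class in the form-specification ontology, that
#' trigger answers appear among the question's possible values, and that no
#' question carries both show and hide triggers.
#'
#' @param config A `form_config` from [parse_config()].
#' @param spec A `form_spec` from [extract_form_spec()].
#' @return Character vector of issue descriptions; empty when fully
#'   consistent. Issues are returned, never raised.
#' @export
validate_config_against_spec <- function(config, spec) {
  issues <- character(0)
  note <- function(msg) issues <<- c(issues, msg)
  if (!config$form_iri %in% spec$form_individuals)
    note(paste0("unresolved form IRI: ", config$form_iri))
  for (sec in config$sections) {
    if (!sec$iri %in% names(spec$sections))
      note(paste0("unresolved section IRI: ", sec$iri))
  }
  for (q in config_questions(config)) {
    qs <- spec$questions[[q$iri]]
    if (is.null(qs)) {
      note(paste0("unresolved question IRI: ", q$iri))
      next
    }
    if (!is.na(q$show_trigger) && !is.na(q$hide_trigger))
      note(paste0("question ", q$iri,
                  " sets both showSubquestionsForAnswer and hideSubquestionsForAnswer"))
    pv <- vapply(qs$possible_values, function(v) v$iri, "")
    for (trig in c(q$show_trigger, q$hide_trigger)) {
      if (!is.na(trig) && !trig %in% pv)
        note(paste0("trigger answer ", trig, " is not a possible value of question ", q$iri))
    }
    if (!is.na(q$option_order)) {
      ok <- tryCatch({resolve_option_order(q$option_order, length(pv)); TRUE},
                     error = function(e) {note(conditionMessage(e)); FALSE})
    }
    has_trigger <- !is.na(q$show_trigger) || !is.na(q$hide_trigger)
    if (has_trigger && length(q$subquestion_lists) == 0L)
      note(paste0("question ", q$iri, " has a trigger but no sub-questions"))
    if (q$widget_type %in% c("radio", "checkbox", "checkbox-horizontal", "dropdown") &&
        length(pv) == 0L)
      note(paste0("question ", q$iri, " has widget '", q$widget_type,
                  "' but no possible values in the specification"))
  }
  for (inf in config_infos(config)) {
    if (!inf$iri %in% names(spec$questions))
      note(paste0("unresolved info IRI: ", inf$iri))
  }
  issues
}
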