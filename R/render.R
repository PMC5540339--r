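# HTML form generation.
#
# A single deterministic walk over the configuration ("instance tree")
# underlies rendering, submission validation/processing, and synthetic
# submission generation, so the partonomy of acquired data mirrors the
# rendered layout by construction. Each repeat copy of a question becomes
# one instance with its own form field name.

field_name_for <- function(iri, repeat_index) {
  h <- substr(digest::digest(iri, algo = "sha1", serialize = FALSE), 1L, 8L)
  paste0(h, "__r", repeat_index)
}

# Ordered option list for a question: alphabetical default permuted by the
# configured optionOrder.
question_options <- function(qspec, option_order) {
  vals <- qspec$possible_values
  if (length(vals) == 0L) return(list())
  if (!is.na(option_order)) {
    perm <- resolve_option_order(option_order, length(vals))
    vals <- vals[perm]
  }
  vals
}

# Build the instance tree: sections -> item lists -> question/info instances
# across repeat copies. When `spec` is NULL only structure and numbering are
# computed (options and texts need the ontology).
build_instance_tree <- function(config, spec = NULL) {
  counters <- new.env(parent = emptyenv())
  next_index <- function(iri) {
    k <- if (is.null(counters[[iri]])) 1L else counters[[iri]] + 1L
    counters[[iri]] <- k
    k
  }
  section_letter <- 0L
  qnum <- 0L

  inst_question <- function(q, triggers) {
    ri <- next_index(q$iri)
    qspec <- if (!is.null(spec)) spec$questions[[q$iri]] else NULL
    if (!is.null(spec) && is.null(qspec))
      stop("render error: question ", q$iri,
           " is not defined in the form specification", call. = FALSE)
    answerable <- q$widget_type != "none"
    label <- NA_character_
    if (q$numbered) {
      qnum <<- qnum + 1L
      label <- as.character(qnum)
    }
    node <- list(kind = "question",
                 iri = q$iri,
                 repeat_index = ri,
                 field = if (answerable) field_name_for(q$iri, ri) else NA_character_,
                 widget_type = q$widget_type,
                 required = q$required,
                 numbered = q$numbered,
                 number_label = label,
                 text = if (!is.null(qspec)) qspec$text else NA_character_,
                 focus = if (!is.null(qspec)) qspec$focus else NA_character_,
                 options = if (!is.null(qspec)) question_options(qspec, q$option_order) else list(),
                 trigger = if (!is.na(q$show_trigger)) list(kind = "show", answer = q$show_trigger)
                           else if (!is.na(q$hide_trigger)) list(kind = "hide", answer = q$hide_trigger)
                           else NULL,
                 visible_if = triggers)
    sub_triggers <- triggers
    if (!is.null(node$trigger) && answerable)
      sub_triggers <- c(sub_triggers,
                        list(list(field = node$field, answer = node$trigger$answer,
                                  kind = node$trigger$kind)))
    node$sublists <- lapply(q$subquestion_lists, function(ql)
      inst_qlist(ql, sub_triggers))
    node
  }

  inst_qlist <- function(ql, triggers) {
    nodes <- list()
    for (r in seq_len(ql$repeat_n))
      for (q in ql$questions)
        nodes[[length(nodes) + 1L]] <- inst_question(q, triggers)
    list(kind = "qlist", layout = ql$layout, nodes = nodes)
  }

  inst_infolist <- function(il, section_type) {
    groups <- list()
    for (r in seq_len(il$repeat_n)) {
      fields <- lapply(il$infos, function(inf) {
        ri <- next_index(inf$iri)
        ispec <- if (!is.null(spec)) spec$questions[[inf$iri]] else NULL
        if (!is.null(spec) && is.null(ispec))
          stop("render error: info field ", inf$iri,
               " is not defined in the form specification", call. = FALSE)
        list(kind = "info",
             iri = inf$iri,
             repeat_index = ri,
             field = field_name_for(inf$iri, ri),
             data_property = inf$data_property_iri,
             widget_type = inf$widget_type,
             required = inf$required,
             text = if (!is.null(ispec)) ispec$text else NA_character_,
             options = if (!is.null(ispec)) question_options(ispec, inf$option_order) else list())
      })
      groups[[length(groups) + 1L]] <-
        list(kind = "infogroup", repeat_index = r,
             individual = il$individual, section_type = section_type,
             fields = fields)
    }
    list(kind = "infolist", layout = il$layout, groups = groups)
  }

  sections <- lapply(config$sections, function(sec) {
    qnum <<- 0L
    label <- NA_character_
    if (sec$numbered) {
      section_letter <<- section_letter + 1L
      label <- LETTERS[section_letter]
    }
    heading <- ""
    if (!is.null(spec) && sec$iri %in% names(spec$sections))
      heading <- spec$sections[[sec$iri]]$heading
    items <- lapply(sec$lists, function(ln) {
      if (ln$kind == "questionList") inst_qlist(ln, list())
      else inst_infolist(ln, sec$section_type)
    })
    list(kind = "section", iri = sec$iri, section_type = sec$section_type,
         numbered = sec$numbered, number_label = label,
         heading = heading, items = items)
  })
  list(sections = sections)
}

# flat list of question/info instance nodes in document order
tree_instances <- function(tree) {
  out <- list()
  add_q <- function(node) {
    out[[length(out) + 1L]] <<- node
    for (sl in node$sublists)
      for (child in sl$nodes) add_q(child)
  }
  for (sec in tree$sections)
    for (item in sec$items) {
      if (item$kind == "qlist") for (node in item$nodes) add_q(node)
      else for (grp in item$groups) for (f in grp$fields) out[[length(out) + 1L]] <- f
    }
  out
}

#' Display numbering of form elements
#'
#' Assigns hierarchical display labels: numbered sections are lettered
#' A, B, ... in document order, numbered question instances within a section
#' are numbered 1, 2, ... in depth-first document order. Non-numbered
#' elements are skipped without consuming a label, so inserting one never
#' shifts the others.
#'
#' @param config A `form_config`.
#' @return Named character vector: `"<iri>#<repeat index>"` -> label, with
#'   one entry per numbered element instance.
#' @export
number_elements <- function(config) {
  tree <- build_instance_tree(config, spec = NULL)
  out <- character(0)
  for (sec in tree$sections)
    if (sec$numbered) out[paste0(sec$iri, "#1")] <- sec$number_label
  for (node in tree_instances(tree))
    if (identical(node$kind, "question") && node$numbered)
      out[paste0(node$iri, "#", node$repeat_index)] <- node$number_label
  out
}

html_escape <- function(x) {
  x <- gsub("&", "&amp;", x, fixed = TRUE)
  x <- gsub("<", "&lt;", x, fixed = TRUE)
  x <- gsub(">", "&gt;", x, fixed = TRUE)
  gsub("\"", "&quot;", x, fixed = TRUE)
}

DEFAULT_CSS <- paste(
  "body.default { font-family: sans-serif; margin: 2em; }",
  ".of-section { border: 1px solid #999; margin: 1em 0; padding: 1em; }",
  ".of-section h2 { margin-top: 0; }",
  ".of-inline { display: flex; gap: 1em; flex-wrap: wrap; }",
  ".of-question, .of-info { margin: 0.5em 0; }",
  ".of-options.horizontal label { display: inline-block; margin-right: 1em; }",
  ".of-required { color: #a00; }",
  ".of-subq { margin-left: 2em; border-left: 2px solid #ccc; padding-left: 1em; }",
  sep = "\n")

TRIGGER_SCRIPT <- paste(
  "document.querySelectorAll('.of-subq').forEach(function (blk) {",
  "  var field = blk.getAttribute('data-controller');",
  "  var answer = blk.getAttribute('data-trigger-answer');",
  "  var kind = blk.getAttribute('data-trigger-kind');",
  "  var inputs = document.querySelectorAll('[name=\"' + field + '\"]');",
  "  function selected() {",
  "    var vals = [];",
  "    inputs.forEach(function (el) {",
  "      if ((el.type === 'radio' || el.type === 'checkbox')) {",
  "        if (el.checked) vals.push(el.value);",
  "      } else if (el.tagName === 'SELECT') { vals.push(el.value); }",
  "    });",
  "    return vals;",
  "  }",
  "  function clearInputs() {",
  "    blk.querySelectorAll('input, textarea, select').forEach(function (el) {",
  "      if (el.type === 'radio' || el.type === 'checkbox') el.checked = false;",
  "      else el.value = '';",
  "    });",
  "  }",
  "  function update() {",
  "    var hit = selected().indexOf(answer) >= 0;",
  "    var show = (kind === 'show') ? hit : !hit;",
  "    if (!show) clearInputs();",
  "    blk.style.display = show ? '' : 'none';",
  "  }",
  "  inputs.forEach(function (el) { el.addEventListener('change', update); });",
  "  update();",
  "});",
  sep = "\n")

render_widget <- function(node) {
  f <- html_escape(node$field)
  req <- if (node$required) " required" else ""
  horizontal <- identical(node$widget_type, "checkbox-horizontal")
  itype <- switch(node$widget_type,
                  radio = "radio", checkbox = "checkbox",
                  "checkbox-horizontal" = "checkbox", NULL)
  if (node$widget_type == "text")
    return(sprintf('<input type="text" name="%s"%s/>', f, req))
  if (node$widget_type == "textarea")
    return(sprintf('<textarea name="%s"%s></textarea>', f, req))
  if (node$widget_type == "dropdown") {
    opts <- vapply(node$options, function(v)
      sprintf('<option value="%s">%s</option>',
              html_escape(v$iri), html_escape(v$label)), "")
    return(sprintf('<select name="%s"%s><option value=""></option>%s</select>',
                   f, req, paste(opts, collapse = "")))
  }
  opts <- vapply(node$options, function(v)
    sprintf('<label><input type="%s" name="%s" value="%s"/>%s</label>',
            itype, f, html_escape(v$iri), html_escape(v$label)), "")
  sprintf('<div class="of-options%s">%s</div>',
          if (horizontal) " horizontal" else "", paste(opts, collapse = "\n"))
}

render_question_node <- function(node) {
  parts <- character(0)
  label <- if (!is.na(node$number_label)) paste0(node$number_label, ". ") else ""
  req_mark <- if (node$required) ' <span class="of-required">*</span>' else ""
  head <- sprintf('<div class="of-question" id="qb_%s"><label>%s%s</label>%s',
                  html_escape(if (is.na(node$field)) paste0("x", node$repeat_index,
                                                            "_", iri_local_name(node$iri))
                              else node$field),
                  html_escape(paste0(label, node$text)), req_mark, "")
  parts <- c(parts, head)
  if (node$widget_type != "none") parts <- c(parts, render_widget(node))
  for (sl in node$sublists) {
    inner <- vapply(sl$nodes, render_question_node, "")
    cls <- paste0("of-subq", if (sl$layout == "inline") " of-inline" else "")
    if (!is.null(node$trigger) && !is.na(node$field)) {
      hidden <- if (node$trigger$kind == "show") ' style="display:none"' else ""
      parts <- c(parts, sprintf(
        '<div class="%s" data-controller="%s" data-trigger-answer="%s" data-trigger-kind="%s"%s>\n%s\n</div>',
        cls, html_escape(node$field), html_escape(node$trigger$answer),
        node$trigger$kind, hidden, paste(inner, collapse = "\n")))
    } else {
      parts <- c(parts, sprintf('<div class="%s">\n%s\n</div>',
                                sub("of-subq", "of-qlist", cls),
                                paste(inner, collapse = "\n")))
    }
  }
  parts <- c(parts, "</div>")
  paste(parts, collapse = "\n")
}

render_info_field <- function(f) {
  req_mark <- if (f$required) ' <span class="of-required">*</span>' else ""
  sprintf('<div class="of-info"><label>%s</label>%s\n%s</div>',
          html_escape(f$text), req_mark, render_widget(f))
}

#' Render a form as HTML
#'
#' Generates a self-contained HTML5 document (inline stylesheet and
#' behaviour script, no external dependencies) from the parsed configuration
#' and the extracted form specification, together with the widget manifest
#' mapping each form field name back to its question IRI and repeat index.
#' Sub-questions governed by a `showSubquestionsForAnswer` trigger start
#' hidden and are revealed by the script when the trigger answer is
#' selected (symmetrically for hide triggers); de-selecting the trigger
#' re-hides the block and clears its inputs so suppressed answers are never
#' submitted.
#'
#' @param config A `form_config` from [parse_config()].
#' @param spec A `form_spec` from [extract_form_spec()].
#' @return A `rendered_form`: list with `html` (string) and `manifest`
#'   (list of widget records; see [manifest_df()]).
#' @export
render_form <- function(config, spec) {
  tree <- build_instance_tree(config, spec)
  body <- character(0)
  for (sec in tree$sections) {
    head_label <- if (!is.na(sec$number_label)) paste0(sec$number_label, ". ") else ""
    body <- c(body, sprintf('<section class="of-section" id="sec_%s">',
                            html_escape(iri_local_name(sec$iri))))
    if (nzchar(sec$heading))
      body <- c(body, sprintf("<h2>%s</h2>", html_escape(paste0(head_label, sec$heading))))
    for (item in sec$items) {
      if (item$kind == "qlist") {
        cls <- paste0("of-qlist", if (item$layout == "inline") " of-inline" else "")
        inner <- vapply(item$nodes, render_question_node, "")
        body <- c(body, sprintf('<div class="%s">\n%s\n</div>', cls,
                                paste(inner, collapse = "\n")))
      } else {
        cls <- paste0("of-infolist", if (item$layout == "inline") " of-inline" else "")
        for (grp in item$groups) {
          inner <- vapply(grp$fields, render_info_field, "")
          body <- c(body, sprintf('<div class="%s">\n%s\n</div>', cls,
                                  paste(inner, collapse = "\n")))
        }
      }
    }
    body <- c(body, "</section>")
  }
  html <- paste0(
    "<!DOCTYPE html>\n<html>\n<head>\n<meta charset=\"utf-8\"/>\n",
    "<title>", html_escape(config$output_title), "</title>\n",
    "<style>\n", DEFAULT_CSS, "\n</style>\n</head>\n",
    "<body class=\"", html_escape(config$css_style), "\">\n",
    "<h1>", html_escape(config$output_title), "</h1>\n",
    "<form id=\"ontoform\" method=\"POST\" action=\"#\">\n",
    paste(body, collapse = "\n"),
    "\n<p><button type=\"submit\">Submit</button></p>\n</form>\n",
    "<script>\n", TRIGGER_SCRIPT, "\n</script>\n</body>\n</html>\n")
  manifest <- build_manifest(tree)
  structure(list(html = html, manifest = manifest, tree = tree),
            class = "rendered_form")
}

build_manifest <- function(tree) {
  records <- list()
  for (node in tree_instances(tree)) {
    if (identical(node$kind, "question") && node$widget_type == "none") next
    records[[length(records) + 1L]] <- structure(
      list(field_name = node$field,
           question_iri = node$iri,
           repeat_index = node$repeat_index,
           widget_type = node$widget_type,
           options = node$options,
           required = node$required,
           kind = node$kind,
           data_property = if (identical(node$kind, "info")) node$data_property else NA_character_,
           visible_if = if (identical(node$kind, "question")) node$visible_if else list()),
      class = "widget_record")
  }
  records
}

#' Manifest as a data frame
#'
#' @param x A `rendered_form` or a manifest list.
#' @return data.frame with one row per form field: `field_name`,
#'   `question_iri`, `repeat_index`, `widget_type`, `required`, `kind`,
#'   `n_options`.
#' @export
manifest_df <- function(x) {
  records <- if (inherits(x, "rendered_form")) x$manifest else x
  do.call(rbind, lapply(records, function(r)
    data.frame(field_name = r$field_name, question_iri = r$question_iri,
               repeat_index = r$repeat_index, widget_type = r$widget_type,
               required = r$required, kind = r$kind,
               n_options = length(r$options), stringsAsFactors = FALSE)))
}

#' @export
print.rendered_form <- function(x, ...) {
  cat(sprintf("<rendered_form: %d field(s), %d characters of HTML>\n",
              length(x$manifest), nchar(x$html)))
  invisible(x)
}
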