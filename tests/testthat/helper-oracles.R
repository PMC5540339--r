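# Shared fixtures and independent oracles for the test suite.

.cache <- new.env(parent = emptyenv())

toy <- function() {
  if (is.null(.cache$toy)) .cache$toy <- toy_fixture()
  .cache$toy
}

toy_rendered <- function() {
  if (is.null(.cache$toy_rendered)) {
    fx <- toy()
    .cache$toy_rendered <- render_form(fx$config, fx$spec)
  }
  .cache$toy_rendered
}

# field name for a question instance (same pure convention the renderer uses)
fld <- function(iri, k = 1L) ontoforms:::field_name_for(iri, k)

bp_iri <- function(x) paste0("http://example.org/ontoforms/backpain-form#", x)
cfa_iri <- function(x) paste0("http://example.org/ontoforms/cfa#", x)
dm_iri <- function(x) paste0("http://example.org/ontoforms/datamodel#", x)

# A complete, hand-written submission for the toy back-pain form.
toy_answers_yes <- function() {
  ans <- list()
  ans[[fld(bp_iri("PatientNameInfo"))]] <- "Ada"
  ans[[fld(bp_iri("PatientIDInfo"))]] <- "123"
  ans[[fld(bp_iri("RadiculopathyQuestion"))]] <- cfa_iri("Yes")
  ans[[fld(bp_iri("RightSeverityQuestion"))]] <- cfa_iri("Severe")
  ans[[fld(bp_iri("LeftSeverityQuestion"))]] <- cfa_iri("Mild")
  ans[[fld(bp_iri("ConditionNameQuestion"), 1L)]] <- "lumbar strain"
  ans[[fld(bp_iri("ConditionDateQuestion"), 1L)]] <- "2014-03-02"
  ans[[fld(bp_iri("ConditionICDQuestion"), 1L)]] <- "M54.5"
  ans[[fld(bp_iri("ConditionNameQuestion"), 2L)]] <- "spinal stenosis"
  ans[[fld(bp_iri("ConditionDateQuestion"), 2L)]] <- "2016-11-20"
  ans[[fld(bp_iri("ConditionICDQuestion"), 2L)]] <- "M48.0"
  ans
}

# ---- option-order oracle --------------------------------------------------
# Brute force: among all permutations of 1..n, find the unique one where the
# positions listed before "*" form the prefix in listed order, positions
# listed after "*" form the suffix in listed order, and the remaining
# positions sit in between in ascending order.
oracle_option_order <- function(order_spec, n) {
  parts <- strsplit(order_spec, ";", fixed = TRUE)[[1]]
  star <- which(parts == "*")
  stopifnot(length(star) <= 1L)
  if (length(star) == 0L) {
    before <- as.integer(parts)
    after <- integer(0)
  } else {
    before <- as.integer(parts[seq_len(star - 1L)])
    after <- if (star < length(parts)) as.integer(parts[(star + 1L):length(parts)])
             else integer(0)
  }
  pm <- perm_matrix(n)
  keep <- rep(TRUE, nrow(pm))
  for (j in seq_along(before)) keep <- keep & pm[, j] == before[j]
  for (j in seq_along(after))
    keep <- keep & pm[, n - length(after) + j] == after[j]
  mid_cols <- setdiff(seq_len(n), c(seq_along(before),
                                    if (length(after)) (n - length(after) + 1L):n))
  if (length(mid_cols) > 1L) {
    mid <- pm[, mid_cols, drop = FALSE]
    for (j in seq_len(length(mid_cols) - 1L))
      keep <- keep & mid[, j] < mid[, j + 1L]
  }
  hits <- which(keep)
  if (length(hits) != 1L) return(NULL)  # semantics must pick a unique order
  pm[hits, ]
}

perm_matrix <- function(n) {
  key <- paste0("perms_", n)
  if (is.null(.cache[[key]]))
    .cache[[key]] <- do.call(rbind, all_permutations(n))
  .cache[[key]]
}

all_permutations <- function(n) {
  n <- as.integer(n)
  if (n == 1L) return(list(1L))
  sub <- all_permutations(n - 1L)
  out <- list()
  for (p in sub)
    for (k in seq_len(n))
      out[[length(out) + 1L]] <- append(p, n, after = k - 1L)
  out
}

# all valid order specs over n options (every ordered selection of distinct
# positions, with '*' inserted at every possible slot or absent)
all_order_specs <- function(n) {
  specs <- character(0)
  sels <- list(integer(0))
  for (len in seq_len(n)) {
    new_sels <- list()
    for (sel in sels[vapply(sels, length, 0L) == len - 1L]) {
      for (k in setdiff(seq_len(n), sel))
        new_sels[[length(new_sels) + 1L]] <- c(sel, k)
    }
    sels <- c(sels, new_sels)
  }
  for (sel in sels) {
    if (length(sel) > 0L)
      specs <- c(specs, paste(sel, collapse = ";"))
    for (slot in 0:length(sel)) {
      parts <- append(as.character(sel), "*", after = slot)
      specs <- c(specs, paste(parts, collapse = ";"))
    }
  }
  unique(specs)
}

# ---- partonomy oracle -----------------------------------------------------
# Canonical form of the hasComponent tree in an acquired graph, derived only
# from the output triples.
graph_partonomy_canonical <- function(acquired) {
  g <- acquired$graph
  edges <- rdf_match(g, p = dm_iri("hasComponent"))
  children <- split(edges$o, edges$s)
  label_of <- function(iri) {
    types <- rdf_objects(g, iri, paste0(ontoforms:::RDF_NS, "type"))
    if (dm_iri("FormData") %in% types) return("FORM")
    if (dm_iri("Observation") %in% types)
      return(paste0("Q[", rdf_objects(g, iri, dm_iri("sourceQuestion"))[1], "#",
                    rdf_objects(g, iri, dm_iri("repeatIndex"))[1], "]"))
    src <- rdf_objects(g, iri, dm_iri("sourceSection"))
    if (length(src) > 0L) return(paste0("SEC[", src[1], "]"))
    "INFO"
  }
  canon <- function(iri) {
    kids <- children[[iri]]
    inner <- if (is.null(kids)) "" else
      paste(sort(vapply(kids, canon, "")), collapse = ",")
    paste0(label_of(iri), "(", inner, ")")
  }
  canon(acquired$form_data_iri)
}

# Expected canonical partonomy, walked directly over the parsed configuration
# and the raw answers (independent of build_instance_tree / the processor).
expected_partonomy_canonical <- function(config, answers) {
  counters <- new.env(parent = emptyenv())
  nxt <- function(iri) {
    k <- (if (is.null(counters[[iri]])) 0L else counters[[iri]]) + 1L
    counters[[iri]] <- k
    k
  }
  visible <- function(triggers) {
    for (tg in triggers) {
      sel <- tg$answer %in% (answers[[tg$field]] %||% character(0))
      if (tg$kind == "show" && !sel) return(FALSE)
      if (tg$kind == "hide" && sel) return(FALSE)
    }
    TRUE
  }
  `%||%` <- function(a, b) if (is.null(a)) b else a
  walk_q <- function(q, triggers) {
    k <- nxt(q$iri)
    f <- ontoforms:::field_name_for(q$iri, k)
    answered <- q$widget_type != "none" && !is.null(answers[[f]]) &&
      visible(triggers)
    sub_triggers <- triggers
    if (q$widget_type != "none" &&
        (!is.na(q$show_trigger) || !is.na(q$hide_trigger))) {
      kind <- if (!is.na(q$show_trigger)) "show" else "hide"
      ansr <- if (!is.na(q$show_trigger)) q$show_trigger else q$hide_trigger
      sub_triggers <- c(triggers, list(list(field = f, answer = ansr, kind = kind)))
    }
    kid_labels <- character(0)
    for (ql in q$subquestion_lists)
      for (r in seq_len(ql$repeat_n))
        for (sq in ql$questions)
          kid_labels <- c(kid_labels, walk_q(sq, sub_triggers))
    if (answered) {
      paste0("Q[", q$iri, "#", k, "](",
             paste(sort(kid_labels), collapse = ","), ")")
    } else {
      kid_labels  # unanswered: children attach to this node's parent
    }
  }
  sec_labels <- character(0)
  for (sec in config$sections) {
    kid_labels <- character(0)
    for (ln in sec$lists) {
      if (ln$kind == "questionList") {
        for (r in seq_len(ln$repeat_n))
          for (q in ln$questions)
            kid_labels <- c(kid_labels, walk_q(q, list()))
      } else {
        for (r in seq_len(ln$repeat_n)) {
          any_answered <- FALSE
          for (inf in ln$infos) {
            k <- nxt(inf$iri)
            if (!is.null(answers[[ontoforms:::field_name_for(inf$iri, k)]]))
              any_answered <- TRUE
          }
          if (any_answered) kid_labels <- c(kid_labels, "INFO()")
        }
      }
    }
    sec_labels <- c(sec_labels,
                    paste0("SEC[", sec$iri, "](",
                           paste(sort(kid_labels), collapse = ","), ")"))
  }
  paste0("FORM(", paste(sort(sec_labels), collapse = ","), ")")
}

# ---- random-corpus cache --------------------------------------------------
# One shared corpus of random fixtures with complete seeded submissions,
# reused by the partonomy, focus-enrichment and conservation suites.
random_corpus <- function(n = 200L, base_seed = 1000L) {
  key <- paste0("corpus_", n, "_", base_seed)
  if (!is.null(.cache[[key]])) return(.cache[[key]])
  corpus <- vector("list", n)
  for (i in seq_len(n)) {
    fx <- random_form_fixture(seed = base_seed + i)
    model <- submission_model(seed = base_seed + i, completion_rate = 1)
    sub <- generate_submissions(model, fx$config, fx$spec, 1L)[[1]]
    acq <- process_submission(sub, fx$config, fx$spec,
                              submission_id = sprintf("c%d", i))
    corpus[[i]] <- list(fixture = fx, submission = sub, acquired = acq)
  }
  .cache[[key]] <- corpus
  corpus
}

# ---- rdflib oracle --------------------------------------------------------
# Independent cross-check through Python rdflib (present in the runtime
# image): parse a Turtle document and run a SPARQL query, returning the
# sorted set of row term-tuples.
rdflib_available <- function() {
  if (is.null(.cache$rdflib)) {
    st <- suppressWarnings(system2("python", c("-c", shQuote("import rdflib")),
                                   stdout = FALSE, stderr = FALSE))
    .cache$rdflib <- identical(st, 0L)
  }
  .cache$rdflib
}

rdflib_select <- function(turtle_text, query) {
  ttl <- tempfile(fileext = ".ttl")
  writeLines(turtle_text, ttl, sep = "")
  rq <- tempfile(fileext = ".rq")
  writeLines(query, rq)
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "q = open(sys.argv[2]).read()",
    "for row in g.query(q):",
    "    print('\\t'.join(str(x) for x in row))"), script)
  out <- system2("python", c(script, ttl, rq), stdout = TRUE)
  sort(out)
}

rdflib_ntriples <- function(turtle_text) {
  ttl <- tempfile(fileext = ".ttl")
  writeLines(turtle_text, ttl, sep = "")
  script <- tempfile(fileext = ".py")
  writeLines(c(
    "import sys, rdflib",
    "g = rdflib.Graph(); g.parse(sys.argv[1], format='turtle')",
    "for s, p, o in g:",
    "    print('\\t'.join([str(s), str(p), o.n3()]))"), script)
  sort(system2("python", c(script, ttl), stdout = TRUE))
}
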