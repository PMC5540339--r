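# SPARQL 1.1 subset evaluator.
#
# Supported: PREFIX prologue, SELECT [DISTINCT] ?v... | *, ASK, a single
# WHERE group of triple patterns and FILTER constraints, the 'a' keyword,
# property paths built from IRI steps with '/' sequencing and '*'/'+'
# closure, FILTER expressions over =, !=, !, &&, || and parentheses.
# This covers the retrieval idioms the package ships (focus lookup and
# description-component matching with subclass subsumption) without a
# triple-store dependency.

# -- term encoding: IRIs as "<iri>", literals as "\"lex\"" [@lang | ^^<dt>] --

enc_iri <- function(iri) {
  if (length(iri) == 0L) return(character(0))
  paste0("<", iri, ">")
}
enc_lit <- function(lex, lang = "", dtype = "") {
  if (length(lex) == 0L) return(character(0))
  out <- paste0("\"", lex, "\"")
  if (nzchar(lang)) out <- paste0(out, "@", lang)
  else if (nzchar(dtype)) out <- paste0(out, "^^<", dtype, ">")
  out
}
enc_term_row <- function(o, lit, lang, dtype) {
  if (length(o) == 0L) return(character(0))
  ifelse(lit, mapply(enc_lit, o, lang, dtype, USE.NAMES = FALSE), enc_iri(o))
}
dec_term <- function(x) {
  iri <- startsWith(x, "<")
  out <- x
  out[iri] <- substr(x[iri], 2L, nchar(x[iri]) - 1L)
  litv <- !iri
  out[litv] <- sub("^\"((?:[^\"\\\\]|\\\\.)*)\".*$", "\\1", x[litv])
  out
}

sparql_error <- function(msg, pos = NA) {
  if (!is.na(pos)) msg <- sprintf("%s (near token %d)", msg, pos)
  stop("SPARQL syntax error: ", msg, call. = FALSE)
}

# -- parser -----------------------------------------------------------------

parse_sparql <- function(query) {
  toks <- tokenize_rdf(query)
  n <- length(toks)
  i <- 1L
  peek <- function() if (i <= n) toks[i] else ""
  kw <- function(x) toupper(peek()) == x
  expect <- function(x) {
    if (toupper(peek()) != toupper(x)) sparql_error(paste0("expected '", x, "'"), i)
    i <<- i + 1L
  }
  prefixes <- character()
  while (kw("PREFIX")) {
    i <- i + 1L
    pfx_tok <- peek()
    if (!grepl("^[A-Za-z_][A-Za-z0-9_.-]*:$", pfx_tok))
      sparql_error("bad PREFIX declaration", i)
    i <- i + 1L
    iri_tok <- peek()
    if (!tok_is_iriref(iri_tok)) sparql_error("bad PREFIX IRI", i)
    prefixes[sub(":$", "", pfx_tok)] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
    i <- i + 1L
  }
  parse_term <- function() {
    t <- peek()
    if (tok_is_var(t)) { i <<- i + 1L; return(list(kind = "var", name = substring(t, 2L))) }
    if (tok_is_iriref(t)) { i <<- i + 1L
      return(list(kind = "const", enc = enc_iri(substr(t, 2L, nchar(t) - 1L)))) }
    if (tok_is_string(t)) {
      lex <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      i <<- i + 1L
      lang <- ""; dtype <- ""
      if (startsWith(peek(), "@")) { lang <- substring(peek(), 2L); i <<- i + 1L }
      else if (peek() == "^^") {
        i <<- i + 1L
        dt <- peek()
        dtype <- if (tok_is_iriref(dt)) substr(dt, 2L, nchar(dt) - 1L)
                 else expand_pname(dt, prefixes)
        i <<- i + 1L
      }
      return(list(kind = "const", enc = enc_lit(lex, lang, dtype)))
    }
    if (tok_is_pname(t)) { i <<- i + 1L
      return(list(kind = "const", enc = enc_iri(expand_pname(t, prefixes)))) }
    if (grepl("^[0-9]", t)) { i <<- i + 1L
      dt <- if (grepl("\\.", t)) paste0(XSD_NS, "decimal") else paste0(XSD_NS, "integer")
      return(list(kind = "const", enc = enc_lit(t, "", dt))) }
    sparql_error(paste0("unexpected token '", t, "'"), i)
  }
  parse_path <- function() {
    if (tok_is_var(peek())) {
      nm <- substring(peek(), 2L)
      i <<- i + 1L
      return(list(kind = "pvar", name = nm))
    }
    steps <- list()
    repeat {
      t <- peek()
      iri <- if (t == "a") { i <<- i + 1L; RDF_TYPE }
             else if (tok_is_iriref(t)) { i <<- i + 1L; substr(t, 2L, nchar(t) - 1L) }
             else if (tok_is_pname(t)) { i <<- i + 1L; expand_pname(t, prefixes) }
             else sparql_error(paste0("expected predicate, got '", t, "'"), i)
      mod <- ""
      if (peek() %in% c("*", "+")) { mod <- peek(); i <<- i + 1L }
      steps[[length(steps) + 1L]] <- list(iri = iri, mod = mod)
      if (peek() == "/") { i <<- i + 1L; next }
      break
    }
    steps
  }
  parse_filter_expr <- function() {
    parse_or <- function() {
      left <- parse_and()
      while (peek() == "||") { i <<- i + 1L; left <- list(op = "or", l = left, r = parse_and()) }
      left
    }
    parse_and <- function() {
      left <- parse_unary()
      while (peek() == "&&") { i <<- i + 1L; left <- list(op = "and", l = left, r = parse_unary()) }
      left
    }
    parse_unary <- function() {
      if (peek() == "!") { i <<- i + 1L; return(list(op = "not", l = parse_unary())) }
      if (peek() == "(") { i <<- i + 1L; e <- parse_or(); expect(")"); return(e) }
      l <- parse_term()
      op <- peek()
      if (!op %in% c("=", "!=")) sparql_error("expected '=' or '!=' in FILTER", i)
      i <<- i + 1L
      r <- parse_term()
      list(op = op, l = l, r = r)
    }
    parse_or()
  }
  qtype <- toupper(peek())
  if (!qtype %in% c("SELECT", "ASK"))
    sparql_error("only SELECT and ASK queries are supported", i)
  i <- i + 1L
  distinct <- FALSE
  vars <- NULL
  if (qtype == "SELECT") {
    if (kw("DISTINCT")) { distinct <- TRUE; i <- i + 1L }
    if (peek() == "*") { vars <- "*"; i <- i + 1L }
    else {
      vars <- character(0)
      while (tok_is_var(peek())) { vars <- c(vars, substring(peek(), 2L)); i <- i + 1L }
      if (length(vars) == 0L) sparql_error("SELECT requires variables or *", i)
    }
  }
  if (kw("WHERE")) i <- i + 1L
  expect("{")
  patterns <- list()
  filters <- list()
  repeat {
    if (peek() == "}") { i <- i + 1L; break }
    if (toupper(peek()) == "FILTER") {
      i <- i + 1L
      expect("(")
      filters[[length(filters) + 1L]] <- parse_filter_expr()
      expect(")")
      if (peek() == ".") i <- i + 1L
      next
    }
    s <- parse_term()
    repeat {
      path <- parse_path()
      repeat {
        o <- parse_term()
        patterns[[length(patterns) + 1L]] <- list(s = s, path = path, o = o)
        if (peek() == ",") { i <- i + 1L; next }
        break
      }
      if (peek() == ";") {
        i <- i + 1L
        if (peek() %in% c(".", "}")) break
        next
      }
      break
    }
    if (peek() == ".") i <- i + 1L
  }
  list(type = qtype, distinct = distinct, vars = vars,
       patterns = patterns, filters = filters)
}

# -- evaluation -------------------------------------------------------------

# pairs (from,to) of the relation denoted by a path over the graph
path_pairs <- function(g, path) {
  tr <- g$triples
  step_pairs <- function(step) {
    rel <- tr[tr$p == step$iri, , drop = FALSE]
    pairs <- data.frame(from = enc_iri(rel$s),
                        to = enc_term_row(rel$o, rel$lit, rel$lang, rel$dtype),
                        stringsAsFactors = FALSE)
    if (step$mod == "") return(unique(pairs))
    # closure only over IRI nodes
    pairs <- pairs[startsWith(pairs$to, "<"), , drop = FALSE]
    closed <- unique(pairs)
    repeat {
      nxt <- merge(closed, pairs, by.x = "to", by.y = "from")
      nxt <- unique(data.frame(from = nxt$from, to = nxt$to.y,
                               stringsAsFactors = FALSE))
      grown <- rbind(closed, nxt)
      grown <- grown[!duplicated(paste(grown$from, grown$to)), , drop = FALSE]
      if (nrow(grown) == nrow(closed)) break
      closed <- grown
    }
    if (step$mod == "*") {
      universe <- unique(c(enc_iri(tr$s),
                           enc_term_row(tr$o, tr$lit, tr$lang, tr$dtype)))
      universe <- universe[startsWith(universe, "<")]
      closed <- rbind(closed, data.frame(from = universe, to = universe,
                                         stringsAsFactors = FALSE))
      closed <- closed[!duplicated(paste(closed$from, closed$to)), , drop = FALSE]
    }
    closed
  }
  out <- step_pairs(path[[1]])
  for (step in path[-1]) {
    nxt <- step_pairs(step)
    out <- merge(out, nxt, by.x = "to", by.y = "from")
    out <- unique(data.frame(from = out$from, to = out$to.y,
                             stringsAsFactors = FALSE))
  }
  unique(out)
}

# zero-length-path special case: ?x p* ?x matches terms outside the relation
# too when an endpoint is a constant; path_pairs already includes identity
# over all graph IRIs, and constants bound outside the graph are handled here.
augment_star_identity <- function(pairs, path, const_terms) {
  only_star <- all(vapply(path, function(st) st$mod == "*", TRUE))
  if (!only_star || length(const_terms) == 0L) return(pairs)
  extra <- data.frame(from = const_terms, to = const_terms,
                      stringsAsFactors = FALSE)
  out <- rbind(pairs, extra)
  out[!duplicated(paste(out$from, out$to)), , drop = FALSE]
}

join_solutions <- function(sols, match_df) {
  shared <- intersect(names(sols), names(match_df))
  if (nrow(sols) == 0L) return(sols[0, , drop = FALSE])
  if (length(shared) == 0L) {
    if (ncol(sols) == 0L) return(match_df)
    sols$..k <- 1L
    match_df$..k <- 1L
    out <- merge(sols, match_df, by = "..k")
    out$..k <- NULL
    return(out)
  }
  merge(sols, match_df, by = shared)
}

eval_filter <- function(expr, sols) {
  val_of <- function(t) {
    if (t$kind == "var") {
      if (!t$name %in% names(sols)) return(rep(NA_character_, nrow(sols)))
      sols[[t$name]]
    } else rep(t$enc, nrow(sols))
  }
  if (!is.null(expr$op) && expr$op %in% c("and", "or", "not")) {
    l <- eval_filter(expr$l, sols)
    if (expr$op == "not") return(!l)
    r <- eval_filter(expr$r, sols)
    if (expr$op == "and") return(l & r) else return(l | r)
  }
  l <- val_of(expr$l)
  r <- val_of(expr$r)
  res <- if (expr$op == "=") l == r else l != r
  res & !is.na(l) & !is.na(r)
}

#' Run a SPARQL query over a graph
#'
#' Evaluates the supported SPARQL 1.1 subset (see the package vignette):
#' `SELECT`/`ASK` with one basic graph pattern group, `FILTER`, and property
#' paths with `/`, `*`, `+` over IRI steps.
#'
#' @param graph An `rdf_graph`.
#' @param query SPARQL query string, or path to a `.rq` file.
#' @return A `query_result`: list with `variables` (character), `rows`
#'   (data.frame of decoded values; IRIs as plain strings) and, for ASK
#'   queries, `ask` (logical).
#' @export
run_sparql <- function(graph, query) {
  stopifnot(is_rdf_graph(graph))
  if (length(query) == 1L && !grepl("[{\n]", query) && file.exists(query))
    query <- paste(readLines(query, warn = FALSE, encoding = "UTF-8"),
                   collapse = "\n")
  q <- parse_sparql(query)
  sols <- data.frame(row.names = 1L)  # one empty solution
  for (pat in q$patterns) {
    if (identical(pat$path$kind, "pvar")) {
      tr <- graph$triples
      pairs <- data.frame(from = enc_iri(tr$s),
                          pred = enc_iri(tr$p),
                          to = enc_term_row(tr$o, tr$lit, tr$lang, tr$dtype),
                          stringsAsFactors = FALSE)
      if (pat$s$kind == "const") pairs <- pairs[pairs$from == pat$s$enc, , drop = FALSE]
      if (pat$o$kind == "const") pairs <- pairs[pairs$to == pat$o$enc, , drop = FALSE]
      cols <- list()
      if (pat$s$kind == "var") cols[[pat$s$name]] <- pairs$from
      cols[[pat$path$name]] <- pairs$pred
      if (pat$o$kind == "var") cols[[pat$o$name]] <- pairs$to
      match_df <- unique(as.data.frame(cols, stringsAsFactors = FALSE))
      sols <- join_solutions(sols, match_df)
      next
    }
    pairs <- path_pairs(graph, pat$path)
    consts <- c(if (pat$s$kind == "const") pat$s$enc,
                if (pat$o$kind == "const") pat$o$enc)
    pairs <- augment_star_identity(pairs, pat$path, consts)
    if (pat$s$kind == "const") pairs <- pairs[pairs$from == pat$s$enc, , drop = FALSE]
    if (pat$o$kind == "const") pairs <- pairs[pairs$to == pat$o$enc, , drop = FALSE]
    cols <- list()
    if (pat$s$kind == "var") cols[[pat$s$name]] <- pairs$from
    if (pat$o$kind == "var") cols[[pat$o$name]] <- pairs$to
    if (length(cols) == 0L) {
      # fully ground pattern: acts as an existence test
      if (nrow(pairs) == 0L) sols <- sols[0, , drop = FALSE]
      next
    }
    match_df <- unique(as.data.frame(cols, stringsAsFactors = FALSE))
    if (pat$s$kind == "var" && pat$o$kind == "var" && pat$s$name == pat$o$name)
      match_df <- unique(data.frame(
        stats::setNames(list(pairs$from[pairs$from == pairs$to]), pat$s$name),
        stringsAsFactors = FALSE))
    sols <- join_solutions(sols, match_df)
  }
  for (f in q$filters) {
    if (nrow(sols) > 0L) sols <- sols[eval_filter(f, sols), , drop = FALSE]
  }
  if (q$type == "ASK") {
    return(structure(list(variables = character(0),
                          rows = data.frame(),
                          ask = nrow(sols) > 0L),
                     class = "query_result"))
  }
  vars <- if (identical(q$vars, "*")) names(sols) else q$vars
  out <- sols[, intersect(vars, names(sols)), drop = FALSE]
  for (v in setdiff(vars, names(out))) out[[v]] <- NA_character_
  out <- out[, vars, drop = FALSE]
  if (q$distinct) out <- unique(out)
  for (v in names(out)) out[[v]] <- dec_term(out[[v]])
  rownames(out) <- NULL
  structure(list(variables = vars, rows = out, ask = NULL),
            class = "query_result")
}

#' @export
print.query_result <- function(x, ...) {
  if (!is.null(x$ask)) {
    cat("ASK ->", x$ask, "\n")
  } else {
    cat(sprintf("<query_result: %d rows over [%s]>\n",
                nrow(x$rows), paste(x$variables, collapse = ", ")))
    if (nrow(x$rows) > 0L) print(utils::head(x$rows, 20L))
  }
  invisible(x)
}

#' Export a query result
#'
#' @param result A `query_result` from [run_sparql()].
#' @param path Output file path.
#' @param format `"csv"` (RFC 4180) or `"json"` (SPARQL 1.1 results JSON).
#' @return `path`, invisibly.
#' @export
write_query_result <- function(result, path, format = c("csv", "json")) {
  format <- match.arg(format)
  if (format == "csv") {
    utils::write.csv(result$rows, path, row.names = FALSE)
  } else {
    bindings <- lapply(seq_len(nrow(result$rows)), function(i) {
      row <- result$rows[i, , drop = FALSE]
      b <- list()
      for (v in result$variables) {
        val <- row[[v]]
        if (is.na(val)) next
        ty <- if (grepl("^[A-Za-z][A-Za-z0-9+.-]*:", val)) "uri" else "literal"
        b[[v]] <- list(type = ty, value = val)
      }
      b
    })
    doc <- list(head = list(vars = result$variables),
                results = list(bindings = bindings))
    if (!is.null(result$ask)) doc <- list(head = list(), boolean = result$ask)
    jsonlite::write_json(doc, path, auto_unbox = TRUE)
  }
  invisible(path)
}
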