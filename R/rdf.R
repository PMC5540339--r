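# Well-known vocabulary IRIs ------------------------------------------------

RDF_NS  <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
RDFS_NS <- "http://www.w3.org/2000/01/rdf-schema#"
OWL_NS  <- "http://www.w3.org/2002/07/owl#"
XSD_NS  <- "http://www.w3.org/2001/XMLSchema#"

RDF_TYPE        <- paste0(RDF_NS, "type")
RDFS_LABEL      <- paste0(RDFS_NS, "label")
RDFS_SUBCLASSOF <- paste0(RDFS_NS, "subClassOf")
RDFS_DOMAIN     <- paste0(RDFS_NS, "domain")
RDFS_RANGE      <- paste0(RDFS_NS, "range")
RDFS_COMMENT    <- paste0(RDFS_NS, "comment")
OWL_CLASS       <- paste0(OWL_NS, "Class")
OWL_OBJPROP     <- paste0(OWL_NS, "ObjectProperty")
OWL_DATAPROP    <- paste0(OWL_NS, "DatatypeProperty")
OWL_ANNPROP     <- paste0(OWL_NS, "AnnotationProperty")
OWL_NAMEDIND    <- paste0(OWL_NS, "NamedIndividual")
OWL_ONTOLOGY    <- paste0(OWL_NS, "Ontology")
OWL_IMPORTS     <- paste0(OWL_NS, "imports")

#' Default namespace table
#'
#' Prefix-to-IRI mappings used throughout the package: the RDF/RDFS/OWL/XSD
#' standard namespaces, the form/data model vocabulary (`dm`), the shipped
#' functional-assessment style domain ontology (`cfa`), the example back-pain
#' form specification (`bp`), and the namespace under which acquired-data
#' individuals are minted (`data`).
#'
#' @return Named character vector mapping prefixes to namespace IRIs.
#' @export
of_namespaces <- function() {
  c(rdf  = RDF_NS,
    rdfs = RDFS_NS,
    owl  = OWL_NS,
    xsd  = XSD_NS,
    dm   = "http://example.org/ontoforms/datamodel#",
    cfa  = "http://example.org/ontoforms/cfa#",
    bp   = "http://example.org/ontoforms/backpain-form#",
    data = "http://example.org/ontoforms/data/")
}

DM_NS   <- "http://example.org/ontoforms/datamodel#"
CFA_NS  <- "http://example.org/ontoforms/cfa#"
BP_NS   <- "http://example.org/ontoforms/backpain-form#"
DATA_NS <- "http://example.org/ontoforms/data/"

dm  <- function(x) paste0(DM_NS, x)
cfa <- function(x) paste0(CFA_NS, x)
bp  <- function(x) paste0(BP_NS, x)

#' Create an empty RDF graph
#'
#' The package's in-memory triple container: a set of (subject, predicate,
#' object) triples over IRIs and literals, with no blank nodes. Objects are
#' literals when `lit` is `TRUE` and may carry a language tag or datatype IRI.
#'
#' @param namespaces Named character vector of prefix-to-IRI mappings used
#'   when serializing; defaults to [of_namespaces()].
#' @return An object of class `rdf_graph`.
#' @seealso [rdf_add()], [rdf_match()], [read_turtle()], [write_turtle()]
#' @export
rdf_graph <- function(namespaces = of_namespaces()) {
  structure(
    list(triples = data.frame(s = character(), p = character(),
                              o = character(), lit = logical(),
                              lang = character(), dtype = character(),
                              stringsAsFactors = FALSE),
         namespaces = namespaces),
    class = "rdf_graph")
}

is_rdf_graph <- function(x) inherits(x, "rdf_graph")

#' Add triples to a graph
#'
#' @param g An `rdf_graph`.
#' @param s Subject IRI (recycled over `o`).
#' @param p Predicate IRI (recycled over `o`).
#' @param o Character vector of object IRIs or literal lexical forms.
#' @param lit Logical; `TRUE` when `o` holds literals.
#' @param lang Optional language tag for literal objects.
#' @param dtype Optional datatype IRI for literal objects.
#' @return The graph with the triples appended (duplicates are dropped).
#' @export
rdf_add <- function(g, s, p, o, lit = FALSE, lang = "", dtype = "") {
  stopifnot(is_rdf_graph(g))
  if (length(o) == 0L) return(g)
  add <- data.frame(s = rep_len(as.character(s), length(o)),
                    p = rep_len(as.character(p), length(o)),
                    o = as.character(o),
                    lit = rep_len(lit, length(o)),
                    lang = rep_len(lang, length(o)),
                    dtype = rep_len(dtype, length(o)),
                    stringsAsFactors = FALSE)
  g$triples <- rbind(g$triples, add)
  g$triples <- g$triples[!duplicated(triple_keys(g$triples)), , drop = FALSE]
  rownames(g$triples) <- NULL
  g
}

triple_keys <- function(tr) {
  obj <- ifelse(tr$lit,
                paste0("\"", tr$o, "\"@", tr$lang, "^^", tr$dtype),
                paste0("<", tr$o, ">"))
  paste(tr$s, tr$p, obj, sep = "\r")
}

#' Number of triples in a graph
#' @param g An `rdf_graph`.
#' @return Integer triple count.
#' @export
rdf_size <- function(g) nrow(g$triples)

#' Match triples by pattern
#'
#' @param g An `rdf_graph`.
#' @param s,p,o Optional subject/predicate/object values to filter on
#'   (`NULL` = wildcard). `o` matches IRIs and literal lexical forms alike.
#' @return The matching rows of the triple table.
#' @export
rdf_match <- function(g, s = NULL, p = NULL, o = NULL) {
  tr <- g$triples
  keep <- rep(TRUE, nrow(tr))
  if (!is.null(s)) keep <- keep & tr$s %in% s
  if (!is.null(p)) keep <- keep & tr$p %in% p
  if (!is.null(o)) keep <- keep & tr$o %in% o
  tr[keep, , drop = FALSE]
}

#' Objects of triples with a given subject and predicate
#' @inheritParams rdf_match
#' @return Character vector of object values (IRIs or literal forms).
#' @export
rdf_objects <- function(g, s, p) rdf_match(g, s = s, p = p)$o

#' Subjects of triples with a given predicate and object
#' @inheritParams rdf_match
#' @return Character vector of subject IRIs.
#' @export
rdf_subjects <- function(g, p, o) unique(rdf_match(g, p = p, o = o)$s)

rdf_has <- function(g, s, p, o) nrow(rdf_match(g, s, p, o)) > 0L

#' Instances of a class (asserted types only)
#' @param g An `rdf_graph`.
#' @param class_iri Class IRI.
#' @return Character vector of individual IRIs with an asserted `rdf:type`.
#' @export
rdf_instances <- function(g, class_iri) rdf_subjects(g, RDF_TYPE, class_iri)

#' Merge RDF graphs
#'
#' @param ... `rdf_graph` objects, or a single list of them.
#' @return The union graph (duplicate triples removed; namespace tables merged,
#'   first binding of a prefix wins).
#' @export
rdf_merge <- function(...) {
  gs <- list(...)
  if (length(gs) == 1L && !is_rdf_graph(gs[[1]]) && is.list(gs[[1]])) gs <- gs[[1]]
  out <- rdf_graph(namespaces = character())
  nss <- character()
  for (g in gs) {
    stopifnot(is_rdf_graph(g))
    out$triples <- rbind(out$triples, g$triples)
    new <- setdiff(names(g$namespaces), names(nss))
    nss <- c(nss, g$namespaces[new])
  }
  if (length(nss) == 0L) nss <- of_namespaces()
  out$namespaces <- nss
  out$triples <- out$triples[!duplicated(triple_keys(out$triples)), , drop = FALSE]
  rownames(out$triples) <- NULL
  out
}

#' Test two graphs for equality
#'
#' The package mints full IRIs for every individual and emits no blank nodes,
#' so RDF graph isomorphism reduces to set equality of triples.
#'
#' @param g1,g2 `rdf_graph` objects.
#' @return `TRUE` when the graphs contain exactly the same triples.
#' @export
graph_isomorphic <- function(g1, g2) {
  setequal(triple_keys(g1$triples), triple_keys(g2$triples))
}

#' @export
print.rdf_graph <- function(x, ...) {
  cat(sprintf("<rdf_graph: %d triples, %d namespaces>\n",
              nrow(x$triples), length(x$namespaces)))
  invisible(x)
}

# IRI helpers ---------------------------------------------------------------

#' Check that a string is a plausible absolute IRI
#' @param x Character vector.
#' @return Logical vector; `TRUE` for strings with a scheme, no spaces and no
#'   angle brackets.
#' @export
is_valid_iri <- function(x) {
  grepl("^[A-Za-z][A-Za-z0-9+.-]*:", x) & !grepl("[ <>\"{}|\\\\^`]", x)
}

shorten_iri <- function(iri, namespaces) {
  for (pfx in names(namespaces)) {
    ns <- namespaces[[pfx]]
    hit <- startsWith(iri, ns)
    loc <- substring(iri, nchar(ns) + 1L)
    ok <- hit & grepl("^[A-Za-z0-9_.-]*$", loc) & !startsWith(loc, "-") &
      !startsWith(loc, ".") & !endsWith(loc, ".")
    iri <- ifelse(ok, paste0(pfx, ":", loc), iri)
  }
  iri
}

iri_local_name <- function(iri) sub(".*[#/]", "", iri)

# Turtle serialization ------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  x <- gsub("\r", "\\r", x, fixed = TRUE)
  x <- gsub("\t", "\\t", x, fixed = TRUE)
  x
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    chars <- strsplit(x[[i]], "", fixed = TRUE)[[1]]
    res <- character(0)
    j <- 1L
    while (j <= length(chars)) {
      if (chars[j] == "\\" && j < length(chars)) {
        nxt <- chars[j + 1L]
        res <- c(res, switch(nxt, n = "\n", r = "\r", t = "\t",
                             "\"" = "\"", "\\" = "\\", nxt))
        j <- j + 2L
      } else {
        res <- c(res, chars[j])
        j <- j + 1L
      }
    }
    out[i] <- paste0(res, collapse = "")
  }
  out
}

term_turtle <- function(o, lit, lang, dtype, namespaces) {
  if (!lit) {
    short <- shorten_iri(o, namespaces)
    if (short != o) return(short)
    return(paste0("<", o, ">"))
  }
  t <- paste0("\"", escape_literal(o), "\"")
  if (nzchar(lang)) t <- paste0(t, "@", lang)
  else if (nzchar(dtype)) t <- paste0(t, "^^", term_turtle(dtype, FALSE, "", "", namespaces))
  t
}

#' Serialize a graph as Turtle
#'
#' Output is canonical: prefixes sorted, one triple per line, triples sorted
#' lexicographically, so equal graphs produce byte-identical documents.
#'
#' @param g An `rdf_graph`.
#' @param path Optional file path; when `NULL` the document is returned as a
#'   single string.
#' @return The Turtle document (invisibly when written to `path`).
#' @export
write_turtle <- function(g, path = NULL) {
  ns <- g$namespaces[order(names(g$namespaces))]
  header <- sprintf("@prefix %s: <%s> .", names(ns), unname(ns))
  tr <- g$triples
  lines <- character(0)
  if (nrow(tr) > 0L) {
    subj <- vapply(tr$s, function(s) term_turtle(s, FALSE, "", "", ns), "")
    pred <- ifelse(tr$p == RDF_TYPE, "a",
                   vapply(tr$p, function(p) term_turtle(p, FALSE, "", "", ns), ""))
    obj <- mapply(term_turtle, tr$o, tr$lit, tr$lang, tr$dtype,
                  MoreArgs = list(namespaces = ns), USE.NAMES = FALSE)
    lines <- sort(paste0(subj, " ", pred, " ", obj, " ."))
  }
  doc <- paste0(paste(c(header, "", lines), collapse = "\n"), "\n")
  if (is.null(path)) return(doc)
  writeLines(doc, path, sep = "")
  invisible(doc)
}

# Turtle / SPARQL shared tokenizer ------------------------------------------

TOKEN_REGEX <- paste0(
  "#[^\n]*",                                   # comment
  "|<[^<>\"{}|^`\\\\ ]*>",                     # IRIREF
  "|\"(?:[^\"\\\\]|\\\\.)*\"",                 # string literal
  "|@[A-Za-z][A-Za-z0-9-]*",                   # langtag or @prefix/@base
  "|\\^\\^",                                   # datatype marker
  "|[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*", # prefixed name (possibly pfx:)
  "|\\?[A-Za-z_][A-Za-z0-9_]*",                # SPARQL variable
  "|[0-9]+(?:\\.[0-9]+)?",                     # numeric literal
  "|&&|\\|\\||!=",                             # SPARQL operators
  "|[A-Za-z_][A-Za-z0-9_]*",                   # bare word / keyword / 'a'
  "|[.;,{}()*+/=!]"                            # punctuation
)

tokenize_rdf <- function(text) {
  m <- gregexpr(TOKEN_REGEX, text, perl = TRUE)[[1]]
  if (m[1] == -1L) return(character(0))
  toks <- regmatches(text, gregexpr(TOKEN_REGEX, text, perl = TRUE))[[1]]
  toks[!startsWith(toks, "#")]
}

tok_is_iriref <- function(t) startsWith(t, "<") & endsWith(t, ">")
tok_is_string <- function(t) startsWith(t, "\"")
tok_is_pname  <- function(t) grepl("^[A-Za-z_][A-Za-z0-9_.-]*:[A-Za-z0-9_.-]*$", t)
tok_is_var    <- function(t) startsWith(t, "?")

expand_pname <- function(tok, prefixes) {
  i <- regexpr(":", tok, fixed = TRUE)
  pfx <- substr(tok, 1L, i - 1L)
  loc <- substring(tok, i + 1L)
  if (!pfx %in% names(prefixes))
    stop("undefined prefix '", pfx, ":' in '", tok, "'", call. = FALSE)
  paste0(prefixes[[pfx]], loc)
}

# Minimal Turtle parser: @prefix directives, IRI/prefixed-name subjects and
# predicates ('a' allowed), IRI/literal objects, ';' and ',' continuations.
# Blank nodes and collections are outside the supported subset.

#' Parse a Turtle document
#'
#' Supports the Turtle subset the package emits (and common ontology-editor
#' output): `@prefix` directives, IRI and prefixed-name terms, the `a`
#' keyword, string literals with language tags or datatypes, numeric
#' literals, and `;`/`,` predicate/object list continuations. Blank nodes are
#' not supported.
#'
#' @param text Turtle document as a string, or a file path.
#' @return An `rdf_graph`.
#' @export
read_turtle <- function(text) {
  if (length(text) == 1L && !grepl("[\n@<]", text) && file.exists(text))
    text <- paste(readLines(text, warn = FALSE, encoding = "UTF-8"), collapse = "\n")
  toks <- tokenize_rdf(text)
  prefixes <- character()
  g <- rdf_graph(namespaces = character())
  rows <- list()
  i <- 1L
  n <- length(toks)
  term_at <- function(i) {
    if (i > n) stop("Turtle parse error: unexpected end of input", call. = FALSE)
    t <- toks[i]
    if (tok_is_iriref(t)) {
      list(v = substr(t, 2L, nchar(t) - 1L), lit = FALSE, lang = "", dtype = "", nxt = i + 1L)
    } else if (tok_is_string(t)) {
      val <- unescape_literal(substr(t, 2L, nchar(t) - 1L))
      lang <- ""; dtype <- ""; j <- i + 1L
      if (j <= n && startsWith(toks[j], "@") && tolower(toks[j]) != "@prefix") {
        lang <- substring(toks[j], 2L); j <- j + 1L
      } else if (j + 1L <= n && toks[j] == "^^") {
        dt <- term_at(j + 1L); dtype <- dt$v; j <- dt$nxt
      }
      list(v = val, lit = TRUE, lang = lang, dtype = dtype, nxt = j)
    } else if (tok_is_pname(t)) {
      list(v = expand_pname(t, prefixes), lit = FALSE, lang = "", dtype = "", nxt = i + 1L)
    } else if (grepl("^[0-9]", t)) {
      dt <- if (grepl("\\.", t)) paste0(XSD_NS, "decimal") else paste0(XSD_NS, "integer")
      list(v = t, lit = TRUE, lang = "", dtype = dt, nxt = i + 1L)
    } else if (t %in% c("true", "false")) {
      list(v = t, lit = TRUE, lang = "", dtype = paste0(XSD_NS, "boolean"), nxt = i + 1L)
    } else {
      stop("Turtle parse error: unexpected token '", t, "'", call. = FALSE)
    }
  }
  while (i <= n) {
    t <- toks[i]
    if (tolower(t) %in% c("@prefix", "prefix")) {
      pfx_tok <- toks[i + 1L]
      if (!grepl(":$", pfx_tok)) stop("Turtle parse error: bad prefix declaration", call. = FALSE)
      iri_tok <- toks[i + 2L]
      if (!tok_is_iriref(iri_tok)) stop("Turtle parse error: bad prefix IRI", call. = FALSE)
      pfx <- sub(":$", "", pfx_tok)
      prefixes[pfx] <- substr(iri_tok, 2L, nchar(iri_tok) - 1L)
      i <- i + 3L
      if (i <= n && toks[i] == ".") i <- i + 1L
      next
    }
    subj <- term_at(i)
    if (subj$lit) stop("Turtle parse error: literal subject", call. = FALSE)
    i <- subj$nxt
    repeat {
      pt <- toks[i]
      p <- if (pt == "a") RDF_TYPE else {
        pr <- term_at(i)
        if (pr$lit) stop("Turtle parse error: literal predicate", call. = FALSE)
        pr$v
      }
      i <- if (pt == "a") i + 1L else term_at(i)$nxt
      repeat {
        ob <- term_at(i)
        rows[[length(rows) + 1L]] <-
          data.frame(s = subj$v, p = p, o = ob$v, lit = ob$lit,
                     lang = ob$lang, dtype = ob$dtype, stringsAsFactors = FALSE)
        i <- ob$nxt
        if (i <= n && toks[i] == ",") { i <- i + 1L; next }
        break
      }
      if (i <= n && toks[i] == ";") {
        i <- i + 1L
        if (i <= n && toks[i] == ".") break  # trailing ; before .
        next
      }
      break
    }
    if (i > n || toks[i] != ".")
      stop("Turtle parse error: expected '.' near token ", i, call. = FALSE)
    i <- i + 1L
  }
  if (length(rows) > 0L) g$triples <- do.call(rbind, rows)
  g$triples <- g$triples[!duplicated(triple_keys(g$triples)), , drop = FALSE]
  rownames(g$triples) <- NULL
  std <- of_namespaces()
  add_pfx <- prefixes[setdiff(names(prefixes), "")]
  miss <- setdiff(names(std), names(add_pfx))
  g$namespaces <- c(add_pfx, std[miss])
  g
}

# RDF/XML -------------------------------------------------------------------

#' Serialize a graph as RDF/XML
#'
#' @param g An `rdf_graph`.
#' @param path Optional output file path.
#' @param ontology_iri Optional IRI for an `owl:Ontology` header node.
#' @param imports Character vector of ontology IRIs to declare as
#'   `owl:imports` on the header.
#' @return The RDF/XML document string (invisibly when written to `path`).
#' @export
write_rdfxml <- function(g, path = NULL, ontology_iri = NULL, imports = character()) {
  ns <- g$namespaces
  # all property-element namespaces must be declared on the root up front
  std <- c(rdf = RDF_NS, rdfs = RDFS_NS, owl = OWL_NS, xsd = XSD_NS)
  pred_ns <- unique(vapply(unique(g$triples$p), function(p) {
    loc <- iri_local_name(p)
    substr(p, 1L, nchar(p) - nchar(loc))
  }, ""))
  extra <- setdiff(pred_ns, std)
  extra_attrs <- list()
  for (nsiri in extra) {
    pfx <- names(ns)[match(nsiri, ns)]
    if (is.na(pfx) || pfx %in% names(std))
      pfx <- paste0("ns", substr(digest::digest(nsiri, algo = "sha1",
                                                serialize = FALSE), 1L, 6L))
    extra_attrs[[paste0("xmlns:", pfx)]] <- nsiri
  }
  root_attrs <- c(list("xmlns:rdf" = RDF_NS, "xmlns:rdfs" = RDFS_NS,
                       "xmlns:owl" = OWL_NS, "xmlns:xsd" = XSD_NS),
                  extra_attrs)
  doc <- do.call(xml2::xml_new_root, c(list("rdf:RDF"), root_attrs))
  qname_tbl <- c(std, vapply(names(extra_attrs), function(a)
    extra_attrs[[a]], ""))
  names(qname_tbl) <- c(names(std), sub("^xmlns:", "", names(extra_attrs)))
  if (!is.null(ontology_iri)) {
    onode <- xml2::xml_add_child(doc, "owl:Ontology", "rdf:about" = ontology_iri)
    for (imp in imports)
      xml2::xml_add_child(onode, "owl:imports", "rdf:resource" = imp)
  }
  tr <- g$triples
  ord <- order(tr$s, tr$p, tr$o)
  tr <- tr[ord, , drop = FALSE]
  for (s in unique(tr$s)) {
    node <- xml2::xml_add_child(doc, "rdf:Description", "rdf:about" = s)
    sub <- tr[tr$s == s, , drop = FALSE]
    for (k in seq_len(nrow(sub))) {
      pname <- rdfxml_qname(sub$p[k], qname_tbl)
      if (sub$lit[k]) {
        child <- xml2::xml_add_child(node, pname, sub$o[k])
        if (nzchar(sub$lang[k])) xml2::xml_set_attr(child, "xml:lang", sub$lang[k])
        if (nzchar(sub$dtype[k])) xml2::xml_set_attr(child, "rdf:datatype", sub$dtype[k])
      } else {
        xml2::xml_add_child(node, pname, "rdf:resource" = sub$o[k])
      }
    }
  }
  out <- as.character(doc)
  if (is.null(path)) return(out)
  writeLines(out, path, sep = "")
  invisible(out)
}

# RDF/XML property elements need a QName; the prefix table is prepared (and
# declared on the root) by write_rdfxml before any property is emitted.
rdfxml_qname <- function(iri, qname_tbl) {
  loc <- iri_local_name(iri)
  nsiri <- substr(iri, 1L, nchar(iri) - nchar(loc))
  pfx <- names(qname_tbl)[match(nsiri, qname_tbl)]
  if (is.na(pfx))
    stop("internal error: undeclared RDF/XML namespace ", nsiri, call. = FALSE)
  paste0(pfx, ":", loc)
}

#' Parse an RDF/XML document
#'
#' Handles the flat RDF/XML profile the package writes and that ontology
#' editors commonly emit: `rdf:Description` or typed resource elements with
#' `rdf:about`, property elements with `rdf:resource` or literal content,
#' `xml:lang` and `rdf:datatype` attributes, and one level of nested resource
#' elements. RDF containers and reification are not supported.
#'
#' @param source RDF/XML document string or file path.
#' @return An `rdf_graph`.
#' @export
read_rdfxml <- function(source) {
  doc <- xml2::read_xml(source)
  if (xml2::xml_name(doc, xml2::xml_ns(doc)) != "rdf:RDF" &&
      xml2::xml_name(doc) != "RDF")
    stop("not an RDF/XML document (root is not rdf:RDF)", call. = FALSE)
  g <- rdf_graph()
  rows <- list()
  nsmap <- xml2::xml_ns(doc)
  node_iri <- function(node) {
    about <- xml2::xml_attr(node, "about")
    if (is.na(about)) about <- xml2::xml_attr(node, "ID")
    about
  }
  elem_iri <- function(node) {
    # expand the element QName to a full IRI using the document namespace map
    qn <- xml2::xml_name(node, nsmap)
    if (grepl(":", qn, fixed = TRUE)) {
      parts <- strsplit(qn, ":", fixed = TRUE)[[1]]
      paste0(nsmap[[parts[1]]], parts[2])
    } else qn
  }
  emit <- function(s, p, o, lit, lang = "", dtype = "") {
    rows[[length(rows) + 1L]] <<-
      data.frame(s = s, p = p, o = o, lit = lit, lang = lang, dtype = dtype,
                 stringsAsFactors = FALSE)
  }
  handle_resource <- function(node) {
    s <- node_iri(node)
    if (is.na(s)) stop("RDF/XML parse error: resource node without rdf:about",
                       call. = FALSE)
    ei <- elem_iri(node)
    if (ei != paste0(RDF_NS, "Description")) emit(s, RDF_TYPE, ei, FALSE)
    for (prop in xml2::xml_children(node)) {
      p <- elem_iri(prop)
      res <- xml2::xml_attr(prop, "resource")
      if (!is.na(res)) { emit(s, p, res, FALSE); next }
      kids <- xml2::xml_children(prop)
      if (length(kids) > 0L) {
        for (kid in kids) {
          o <- handle_resource(kid)
          emit(s, p, o, FALSE)
        }
      } else {
        lang <- xml2::xml_attr(prop, "lang")
        dtype <- xml2::xml_attr(prop, "datatype")
        emit(s, p, xml2::xml_text(prop), TRUE,
             ifelse(is.na(lang), "", lang), ifelse(is.na(dtype), "", dtype))
      }
    }
    s
  }
  for (top in xml2::xml_children(doc)) handle_resource(top)
  if (length(rows) > 0L) {
    g$triples <- do.call(rbind, rows)
    g$triples <- g$triples[!duplicated(triple_keys(g$triples)), , drop = FALSE]
    rownames(g$triples) <- NULL
  }
  g
}
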