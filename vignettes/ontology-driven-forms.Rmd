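---
title: "Ontology-driven forms: model, design decisions, and what the tests show"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Ontology-driven forms: model, design decisions, and what the tests show}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ontoforms)
```

## The model

`ontoforms` implements a two-stage pipeline for structured data acquisition.

**Stage 1 — form generation.** An XML configuration is parsed into a layout
tree (`parse_config()`), the form-specification ontology and its imports
are loaded and merged (`load_ontology()`), and per-element content is
extracted (`extract_form_spec()`): question text, the enumerated answer
values reachable through `hasPossibleValue`, and the optional semantic
focus reachable through `isAbout`. `render_form()` then emits a
self-contained HTML document plus a *widget manifest* mapping each form
field name to its question IRI and repeat index.

**Stage 2 — input handling.** `process_submission()` validates the answers
against the manifest and creates data individuals following the form/data
model ontology: every submission yields one `FormData` individual; every
answered question instance yields one `Observation` carrying `hasValue`
assertions (IRIs of the selected values) or a literal text value; the
`hasComponent` relation reproduces the configured nesting, so a question
configured with two answered sub-questions yields an observation with two
outgoing `hasComponent` edges. Observations inherit their question's focus
as `hasFocus`; after that step the data depend on the domain descriptions
only — question wordings matter solely for provenance, which is kept in
separate `sourceQuestion`/`sourceSection`/`sourceForm` assertions.

Two retrieval idioms are packaged (`inst/queries/*.rq`). Focus retrieval
(`observations_by_focus()`) selects observations by their description
individual — instrument-independent by construction. Description retrieval
(`observations_by_description()`) matches the *components* of the focus:
assessed attribute, assessed function, temporal quality, laterality, and an
anatomical location matched up to `rdfs:subClassOf` subsumption, so a query
for the lower extremity aggregates right- and left-side observations.

## Vocabulary and shipped ontologies

The form/data model ontology (`build_datamodel_ontology()`) declares
`Form`, `Section`, `SubjectInfoSection` and `Question` as kinds of
`FormStructure`; `FormData`, `Observation`, `SubjectInformation`,
`EvaluatorInformation` and `Certification` as kinds of `Data`; and the
properties `hasComponent`, `hasValue`, `hasPossibleValue`, `isAbout` and
`hasFocus`. Domains and ranges are asserted conservatively (`hasComponent`:
Data→Data; `hasValue`: Observation→Value; `hasFocus`:
Observation→DataElementDescription; `isAbout`:
Question→DataElementDescription; `hasPossibleValue`: Question→Value).
`Certification` and `EvaluatorInformation` are declared but unused by the
example form; they exist so evaluator sections type their aggregates
sensibly.

The domain ontology (`build_toy_domain_ontology()`) provides the anchors a
functional-assessment vocabulary needs: a `Finding` hierarchy under
`DataElementDescription`, split into `Assessment` (non-numeric results) and
`Measurement` (numeric results); value sets for a severity scale, yes/no,
laterality and temporal quality; an anatomical taxonomy in which the right
and left lower-extremity structure classes share a common superclass; and
composed focus individuals such as *severity of constant pain in the right
lower extremity* (assessed attribute Severity, assessed function
pain-in-body-part qualified as Constant, location right lower extremity
with laterality Right). External terminology bindings (ICF, SNOMED CT) are
represented as source/code string pairs on the internal individuals rather
than as ontology imports, keeping the package fully offline.

## Parameters that matter

* **`optionOrder`** (per question, string): answer options default to
  case-insensitive alphabetical order by label (ties broken by IRI, so the
  order is total and platform-independent). An order spec permutes
  *positions in that default order*: entries before `*` go first in listed
  order, `*` expands to the unlisted positions ascending, entries after `*`
  go last. `"3;*"` over {Mild, Moderate, None, Severe} yields
  None, Mild, Moderate, Severe — a proper clinical scale.
* **`repeat`** (per list, positive integer, default 1): renders N copies of
  the list contents; each copy's fields get a distinct repeat index and the
  acquired sub-trees stay disjoint.
* **triggers** (`showSubquestionsForAnswer`/`hideSubquestionsForAnswer`,
  answer IRI): sub-questions start hidden (shown, for hide-triggers) and
  toggle when the controlling answer is selected. At most one of the two
  may be set per question; this is enforced at validation time.
* **`completion_rate`** (synthetic model, probability, default 1): chance
  that a visible optional field is answered. Required fields are always
  answered; trigger-hidden fields never.
* **`submission_id`** (processing): data individuals are minted as
  `<data-ns>/<submission id>/<type>/<counter>`. Supplying the id makes
  output graphs reproducible; omitting it derives one from the clock.

## Design decisions

* **Configuration grammar.** The XML schema is enforced as an explicit
  grammar (root `configuration` with `input`/`output`/`bindings`/`form`;
  `form` → `iri` + `section`+; `section` → `iri` +
  (`questionList`|`infoList`)\*; `question` → `iri` + `questionList`\*;
  `infoList` → `info`+) with errors naming the offending node path.
  Explicit validation beats permissive parsing: configuration mistakes
  surface before a form is ever rendered.
* **Field names.** HTML field names are the first 8 hex digits of the
  SHA-1 of the question IRI plus a repeat suffix (`ab12cd34__r2`), since
  IRIs contain characters illegal in field names. The manifest is the
  authoritative reverse map.
* **One shared layout walk.** Rendering, validation, processing and
  synthetic generation all traverse the same instance tree
  (configuration × repeats × triggers), which is what makes the acquired
  partonomy mirror the rendered layout by construction rather than by
  coincidence.
* **Section grouping.** Each rendered section contributes one grouping
  `Data` individual under `FormData`; observations and info aggregates hang
  off it. Whether intermediate per-section individuals exist at all was an
  open choice; grouping keeps the partonomy aligned with the visible layout
  at every level. Info-list aggregates (not the grouping node) carry the
  semantic type — `SubjectInformation` in subject sections,
  `EvaluatorInformation` in evaluator sections — so a patient-info section
  produces exactly one `SubjectInformation` individual.
* **Checkbox questions** produce one observation with several `hasValue`
  assertions, preserving the one-observation-per-question correspondence.
  Free-text answers use a literal-valued property (`hasTextValue`) distinct
  from the object property `hasValue`.
* **Unanswered optional questions** create no observation: absence of an
  answer is open-world absence, not an empty-valued individual.
* **Trigger hygiene.** The rendered script clears inputs inside a re-hidden
  block, so suppressed answers are never submitted; the processor
  nevertheless re-validates trigger conditions server-side and rejects
  answers whose trigger is unmet.
* **Reasoning scope.** Instance checks at extraction time use asserted
  types only; subsumption enters only in the query layer, as SPARQL
  property paths over asserted `rdfs:subClassOf` edges. On the shipped
  ontologies, where all class memberships are asserted, this coincides
  with what a DL classifier would conclude, at a fraction of the
  machinery. Consequences of axioms that are *not* asserted (e.g.
  membership implied by property restrictions) are out of scope.
* **RDF stack.** The triple container, Turtle and RDF/XML serializers and
  parsers, and the SPARQL subset evaluator are implemented in the package.
  The supported SPARQL subset is SELECT/ASK over one basic graph pattern
  group with FILTER (`=`, `!=`, `!`, `&&`, `||`) and property paths
  (`/`, `*`, `+` over IRI steps); the Turtle reader covers the subset the
  package emits plus common editor output (no blank nodes). The test suite
  cross-checks both against an independent engine (Python `rdflib`) on the
  shipped ontologies.
* **Label language.** Untagged literals are preferred, then `"en"`, then
  anything; multilingual forms are out of scope.

## The synthetic generator, and what passing tests show

`generate_submissions()` emulates form filling: it walks the layout
top-down, always answers visible required fields, answers visible optional
fields with probability `completion_rate`, draws enumerated answers from
the presented options (uniformly, or with per-question weights), and
answers text fields with short clinical-flavoured strings. The demo cohort
(`demo_submission_model()`) consists of five complete submissions whose
severity answers are weighted 1:1:1:3 toward the severe end, emulating a
symptomatic clinic population so that description-level queries have
matches on both lateralities.

`random_form_fixture()` generates random configurations (nested sections,
lists with repeats up to 3, nesting depth up to 4, up to 30 questions, all
widget types, show/hide triggers) with matching specification graphs. The
acceptance suite processes complete submissions over 200 such fixtures and
checks three properties against brute-force oracles: the `hasComponent`
tree is isomorphic to the answered-question nesting tree; `hasFocus`
appears on exactly the observations whose question carries `isAbout`; and
the observation count equals the answered answerable-question count.

What this does *not* show: the generator produces syntactically clean,
honest answers. Real submissions arrive with adversarial input, encoding
issues, concurrent edits and partially saved states, none of which are
modelled. The synthetic text fields are short tokens, not realistic
clinical narratives; and the domain ontology is a deliberately small stand-in
— conclusions about query behaviour over a full terminology (thousands of
classes, deep hierarchies, non-tree subsumption) should not be drawn from
these fixtures.

## Numerical and degenerate-input choices

Alphabetical sorting lowercases then compares by codepoint, with IRI
tie-breaks — reproducible across locales. Graph equality is set equality of
triples (the package mints full IRIs and emits no blank nodes, so this *is*
RDF isomorphism here). Turtle output is canonical (sorted prefixes and
triples), making equal graphs byte-identical on disk. Empty cases are
defined, not errors: a form with no answered optional questions produces a
`FormData` with empty section groups; merging zero graphs yields the empty
graph; a SPARQL query over the empty graph yields zero rows. Problem sizes
in the shipped suites (200-fixture corpus, exhaustive option-order specs
for up to 6 options, 5-patient demo) were chosen so the full suite and the
acceptance script each run in a couple of minutes on one CPU while still
exercising every layout feature; they are configuration, not limits.

## Known limitations

* No demo web server: the pipeline is file-based (JSON submissions in,
  CSV/Turtle/RDF-XML out) and the CLI wraps it; live HTTP acquisition would
  be a thin layer over the same functions.
* OWL functional syntax is not read; use Turtle or RDF/XML.
* No DL reasoner: classification-dependent queries beyond asserted
  subsumption are out of scope, as is SWRL.
* The complete source questionnaire is not reproduced; the example form is
  a compact analogue exercising every configuration feature.
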