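# ontoforms

Ontology-driven Web form generation and semantic data acquisition in R.

Structured data acquisition — in the motivating case, clinical functional
assessment instruments such as disability questionnaires — usually produces
opaque key–value records: the meaning of "question 12b" lives only in the
form's wording. `ontoforms` takes the ontology-driven route instead. A form
is specified twice, by design:

* an **OWL form specification** holds the content: `Question`, `Section` and
  `Form` individuals with their display text, enumerated answer `Value`s,
  and — crucially — an `isAbout` link from each question to a
  *data-element description* in a domain ontology (e.g. "severity of
  constant pain in the right lower extremity", composed from an assessed
  attribute, an assessed function with a temporal qualifier, and an
  anatomical location with laterality);
* an **XML configuration** holds the layout and behaviour: sections,
  question lists (inline or vertical, optionally repeated), widget types
  (`text`, `textarea`, `radio`, `checkbox`, `checkbox-horizontal`,
  `dropdown`, `none`), numbering, required flags, presentation order of
  answer options (`optionOrder="3;*"`), and answer-triggered sub-questions
  (`showSubquestionsForAnswer` / `hideSubquestionsForAnswer`).

From these the package renders a self-contained HTML form, and converts each
submission into an RDF graph of data individuals: one `FormData` root per
submission, one `Observation` per answered question (with `hasValue`
assertions to the selected value IRIs, or a literal for free text), a
`hasComponent` partonomy that mirrors the layout nesting, info-list answers
aggregated onto a single individual (e.g. one `SubjectInformation` per
patient), and every observation enriched with the `hasFocus` description
inherited from its question. Because the acquired data reference domain
descriptions rather than question wordings, queries are
instrument-independent: all observations about radiculopathy are one
`hasFocus` lookup away, regardless of which form (or which phrasing)
produced them, and a description-level query for "severe pain anywhere in
the lower extremity" aggregates left- and right-side observations through
the anatomical class hierarchy.

The package is self-contained: it ships the generic form/data model
ontology, a small functional-assessment style domain ontology, an example
back-pain form, a seeded synthetic-submission generator, an RDF triple store
with Turtle and RDF/XML I/O, and a SPARQL subset engine (basic graph
patterns, `FILTER`, property paths) — no triple-store server or network
access required.

## Worked example

```r
library(ontoforms)

fx <- toy_fixture()          # ontologies + parsed XML config + extracted spec
validate_config_against_spec(fx$config, fx$spec)
#> character(0)              # every IRI resolves, triggers are consistent

rendered <- render_form(fx$config, fx$spec)
rendered
#> <rendered_form: 11 field(s), 5000 characters of HTML>

# alphabetical order would put "None" inside the severity scale;
# optionOrder="3;*" moves it first:
sev <- Filter(function(r) grepl("RightSeverityQuestion", r$question_iri),
              rendered$manifest)[[1]]
vapply(sev$options, `[[`, "", "label")
#> [1] "None"     "Mild"     "Moderate" "Severe"

# five synthetic patients, processed to RDF and merged
subs <- generate_submissions(demo_submission_model(seed = 7), fx$config, fx$spec, 5)
acqs <- lapply(seq_along(subs), function(k)
  process_submission(subs[[k]], fx$config, fx$spec, rendered$manifest,
                     submission_id = paste0("demo", k)))
merged <- rdf_merge(merge_submissions(acqs), fx$graph)

# instrument-independent retrieval by focus
run_sparql(merged, packaged_query("radiculopathy_observations"))$rows$value
#> [1] ".../cfa#No"  ".../cfa#Yes" ".../cfa#Yes" ".../cfa#Yes" ".../cfa#No"

# description-level retrieval, aggregating left and right laterality
nrow(run_sparql(merged, packaged_query("severe_pain_lower_extremity"))$rows)
#> [1] 4
```

The three printed lines say: the severity scale presents in clinical order;
three of the five demo patients reported radiculopathy signs or symptoms;
and four observations across both lower extremities recorded severe pain.

A command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli", "ontoforms", package = "ontoforms"))')
Rscript -e 'ontoforms::write_fixture_files("example")'
Rscript "$CLI" generate --config example/backpain-config.xml --out form.html
Rscript "$CLI" process  --config example/backpain-config.xml --synthetic 5 \
                        --seed 7 --formats csv,rdf,owl --out-dir out --merge
Rscript "$CLI" query    --data out/merged.ttl --data example/cfa.ttl \
                        --data example/datamodel.ttl \
                        --query "$(Rscript -e 'cat(ontoforms::packaged_query("radiculopathy_observations"))')"
```

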