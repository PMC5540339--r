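# All observations where the patient presented signs or symptoms due to
# radiculopathy, via the focus individual — independent of the assessment
# instrument and of the particular formulation of the question.
PREFIX dm:  <http://example.org/ontoforms/datamodel#>
PREFIX cfa: <http://example.org/ontoforms/cfa#>

SELECT DISTINCT ?obs ?value
WHERE {
  ?obs a dm:Observation .
  ?obs dm:hasFocus cfa:RadiculopathySignsSymptoms .
  ?obs dm:hasValue ?value .
}
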