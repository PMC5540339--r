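# Observations of severe pain anywhere in the lower extremity: the focus
# must assess pain in a body part located in a structure of the lower
# extremity (right and left both match, via the asserted class hierarchy)
# and the selected answer must be the Severe scale value.
PREFIX dm:   <http://example.org/ontoforms/datamodel#>
PREFIX cfa:  <http://example.org/ontoforms/cfa#>
PREFIX rdfs: <http://www.w3.org/2000/01/rdf-schema#>

SELECT DISTINCT ?obs
WHERE {
  ?obs a dm:Observation .
  ?obs dm:hasFocus ?focus .
  ?focus cfa:hasAssessedFunction cfa:PainInBodyPart .
  ?focus cfa:hasAnatomicalLocation ?loc .
  ?loc a ?loctype .
  ?loctype rdfs:subClassOf* cfa:LowerExtremityStructure .
  ?obs dm:hasValue cfa:Severe .
}
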