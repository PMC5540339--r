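PREFIX dm: <http://example.org/ontoforms/datamodel#>

SELECT DISTINCT ?obs
WHERE {
  ?obs a dm:Observation .
}
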