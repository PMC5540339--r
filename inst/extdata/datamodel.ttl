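@prefix bp: <http://example.org/ontoforms/backpain-form#> .
@prefix cfa: <http://example.org/ontoforms/cfa#> .
@prefix data: <http://example.org/ontoforms/data/> .
@prefix dm: <http://example.org/ontoforms/datamodel#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

<http://example.org/ontoforms/datamodel> a owl:Ontology .
dm:Certification a owl:Class .
dm:Certification rdfs:label "Certification" .
dm:Certification rdfs:subClassOf dm:Data .
dm:Data a owl:Class .
dm:Data rdfs:label "Data" .
dm:DataElementDescription a owl:Class .
dm:DataElementDescription rdfs:label "Data element description" .
dm:EvaluatorInformation a owl:Class .
dm:EvaluatorInformation rdfs:label "Evaluator information" .
dm:EvaluatorInformation rdfs:subClassOf dm:Data .
dm:Form a owl:Class .
dm:Form rdfs:label "Form" .
dm:Form rdfs:subClassOf dm:FormStructure .
dm:FormData a owl:Class .
dm:FormData rdfs:label "Form data" .
dm:FormData rdfs:subClassOf dm:Data .
dm:FormStructure a owl:Class .
dm:FormStructure rdfs:label "Form structure" .
dm:hasComponent a owl:ObjectProperty .
dm:hasComponent rdfs:domain dm:Data .
dm:hasComponent rdfs:range dm:Data .
dm:hasFocus a owl:ObjectProperty .
dm:hasFocus rdfs:domain dm:Observation .
dm:hasFocus rdfs:range dm:DataElementDescription .
dm:hasHeading a owl:DatatypeProperty .
dm:hasHeading rdfs:domain dm:Section .
dm:hasPossibleValue a owl:ObjectProperty .
dm:hasPossibleValue rdfs:domain dm:Question .
dm:hasPossibleValue rdfs:range dm:Value .
dm:hasText a owl:DatatypeProperty .
dm:hasText rdfs:domain dm:FormStructure .
dm:hasTextValue a owl:DatatypeProperty .
dm:hasTextValue rdfs:domain dm:Observation .
dm:hasValue a owl:ObjectProperty .
dm:hasValue rdfs:domain dm:Observation .
dm:hasValue rdfs:range dm:Value .
dm:isAbout a owl:ObjectProperty .
dm:isAbout rdfs:domain dm:Question .
dm:isAbout rdfs:range dm:DataElementDescription .
dm:Observation a owl:Class .
dm:Observation rdfs:label "Observation" .
dm:Observation rdfs:subClassOf dm:Data .
dm:Question a owl:Class .
dm:Question rdfs:label "Question" .
dm:Question rdfs:subClassOf dm:FormStructure .
dm:repeatIndex a owl:DatatypeProperty .
dm:repeatIndex rdfs:domain dm:Data .
dm:Section a owl:Class .
dm:Section rdfs:label "Section" .
dm:Section rdfs:subClassOf dm:FormStructure .
dm:sourceForm a owl:ObjectProperty .
dm:sourceForm rdfs:domain dm:FormData .
dm:sourceForm rdfs:range dm:Form .
dm:sourceQuestion a owl:ObjectProperty .
dm:sourceQuestion rdfs:domain dm:Data .
dm:sourceQuestion rdfs:range dm:Question .
dm:sourceSection a owl:ObjectProperty .
dm:sourceSection rdfs:domain dm:Data .
dm:sourceSection rdfs:range dm:Section .
dm:SubjectInformation a owl:Class .
dm:SubjectInformation rdfs:label "Subject information" .
dm:SubjectInformation rdfs:subClassOf dm:Data .
dm:SubjectInfoSection a owl:Class .
dm:SubjectInfoSection rdfs:label "Subject information section" .
dm:SubjectInfoSection rdfs:subClassOf dm:Section .
dm:submissionTimestamp a owl:DatatypeProperty .
dm:submissionTimestamp rdfs:domain dm:FormData .
dm:Value a owl:Class .
dm:Value rdfs:label "Value" .
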