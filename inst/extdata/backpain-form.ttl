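@prefix bp: <http://example.org/ontoforms/backpain-form#> .
@prefix cfa: <http://example.org/ontoforms/cfa#> .
@prefix data: <http://example.org/ontoforms/data/> .
@prefix dm: <http://example.org/ontoforms/datamodel#> .
@prefix owl: <http://www.w3.org/2002/07/owl#> .
@prefix rdf: <http://www.w3.org/1999/02/22-rdf-syntax-ns#> .
@prefix rdfs: <http://www.w3.org/2000/01/rdf-schema#> .
@prefix xsd: <http://www.w3.org/2001/XMLSchema#> .

<http://example.org/ontoforms/backpain-form> a owl:Ontology .
<http://example.org/ontoforms/backpain-form> owl:imports <http://example.org/ontoforms/cfa> .
<http://example.org/ontoforms/backpain-form> owl:imports <http://example.org/ontoforms/datamodel> .
bp:BackPainForm a dm:Form .
bp:BackPainForm a owl:NamedIndividual .
bp:BackPainForm rdfs:label "Back Conditions Assessment" .
bp:ConditionDateQuestion a dm:Question .
bp:ConditionDateQuestion a owl:NamedIndividual .
bp:ConditionDateQuestion dm:hasText "Date of diagnosis" .
bp:ConditionICDQuestion a dm:Question .
bp:ConditionICDQuestion a owl:NamedIndividual .
bp:ConditionICDQuestion dm:hasText "ICD code" .
bp:ConditionNameQuestion a dm:Question .
bp:ConditionNameQuestion a owl:NamedIndividual .
bp:ConditionNameQuestion dm:hasText "Condition" .
bp:ConditionNameQuestion dm:isAbout cfa:ConditionHistory .
bp:ConditionsQuestion a dm:Question .
bp:ConditionsQuestion a owl:NamedIndividual .
bp:ConditionsQuestion dm:hasText "Previously diagnosed back conditions" .
bp:LeftSeverityQuestion a dm:Question .
bp:LeftSeverityQuestion a owl:NamedIndividual .
bp:LeftSeverityQuestion dm:hasPossibleValue cfa:Mild .
bp:LeftSeverityQuestion dm:hasPossibleValue cfa:Moderate .
bp:LeftSeverityQuestion dm:hasPossibleValue cfa:NoneSeverity .
bp:LeftSeverityQuestion dm:hasPossibleValue cfa:Severe .
bp:LeftSeverityQuestion dm:hasText "Severity of constant pain, left lower extremity" .
bp:LeftSeverityQuestion dm:isAbout cfa:SeverityConstantPainLeftLowerExtremity .
bp:PatientIDInfo a dm:Question .
bp:PatientIDInfo a owl:NamedIndividual .
bp:PatientIDInfo dm:hasText "Patient ID" .
bp:PatientInfoSection a dm:SubjectInfoSection .
bp:PatientInfoSection a owl:NamedIndividual .
bp:PatientInfoSection dm:hasHeading "Patient Information" .
bp:PatientNameInfo a dm:Question .
bp:PatientNameInfo a owl:NamedIndividual .
bp:PatientNameInfo dm:hasText "Patient Name" .
bp:RadiculopathyQuestion a dm:Question .
bp:RadiculopathyQuestion a owl:NamedIndividual .
bp:RadiculopathyQuestion dm:hasPossibleValue cfa:No .
bp:RadiculopathyQuestion dm:hasPossibleValue cfa:Yes .
bp:RadiculopathyQuestion dm:hasText "Does the patient have any signs or symptoms due to radiculopathy?" .
bp:RadiculopathyQuestion dm:isAbout cfa:RadiculopathySignsSymptoms .
bp:RightSeverityQuestion a dm:Question .
bp:RightSeverityQuestion a owl:NamedIndividual .
bp:RightSeverityQuestion dm:hasPossibleValue cfa:Mild .
bp:RightSeverityQuestion dm:hasPossibleValue cfa:Moderate .
bp:RightSeverityQuestion dm:hasPossibleValue cfa:NoneSeverity .
bp:RightSeverityQuestion dm:hasPossibleValue cfa:Severe .
bp:RightSeverityQuestion dm:hasText "Severity of constant pain, right lower extremity" .
bp:RightSeverityQuestion dm:isAbout cfa:SeverityConstantPainRightLowerExtremity .
bp:SymptomSection a dm:Section .
bp:SymptomSection a owl:NamedIndividual .
bp:SymptomSection dm:hasHeading "Back and Lower Extremity Symptoms" .
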