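<?xml version="1.0" encoding="UTF-8"?>
<configuration>
  <input>
    <ontology>backpain-form.ttl</ontology>
    <imports>
      <ontology iri="http://example.org/ontoforms/datamodel" path="datamodel.ttl"/>
      <ontology iri="http://example.org/ontoforms/cfa" path="cfa.ttl"/>
    </imports>
  </input>
  <output>
    <file title="Back Conditions Assessment"/>
    <cssStyle>default</cssStyle>
  </output>
  <form>
    <iri>http://example.org/ontoforms/backpain-form#BackPainForm</iri>
    <section type="subject_section">
      <iri>http://example.org/ontoforms/backpain-form#PatientInfoSection</iri>
      <infoList type="inline">
        <info type="text" required="true" property="http://example.org/ontoforms/cfa#hasName">
          <iri>http://example.org/ontoforms/backpain-form#PatientNameInfo</iri>
        </info>
        <info type="text" property="http://example.org/ontoforms/cfa#hasID">
          <iri>http://example.org/ontoforms/backpain-form#PatientIDInfo</iri>
        </info>
      </infoList>
    </section>
    <section type="question_section" numbered="true">
      <iri>http://example.org/ontoforms/backpain-form#SymptomSection</iri>
      <questionList>
        <question type="radio" numbered="true" required="true" showSubquestionsForAnswer="http://example.org/ontoforms/cfa#Yes">
          <iri>http://example.org/ontoforms/backpain-form#RadiculopathyQuestion</iri>
          <questionList>
            <question type="radio" numbered="true" optionOrder="3;*">
              <iri>http://example.org/ontoforms/backpain-form#RightSeverityQuestion</iri>
            </question>
            <question type="radio" numbered="true" optionOrder="3;*">
              <iri>http://example.org/ontoforms/backpain-form#LeftSeverityQuestion</iri>
            </question>
          </questionList>
        </question>
        <question type="none" numbered="true">
          <iri>http://example.org/ontoforms/backpain-form#ConditionsQuestion</iri>
          <questionList type="inline" repeat="2">
            <question type="text">
              <iri>http://example.org/ontoforms/backpain-form#ConditionNameQuestion</iri>
            </question>
            <question type="text">
              <iri>http://example.org/ontoforms/backpain-form#ConditionDateQuestion</iri>
            </question>
            <question type="text">
              <iri>http://example.org/ontoforms/backpain-form#ConditionICDQuestion</iri>
            </question>
          </questionList>
        </question>
      </questionList>
    </section>
  </form>
</configuration>
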