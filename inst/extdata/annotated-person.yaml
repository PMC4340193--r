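# The annotated Person bean model: equivalent to the external TestedSubject
# class, someValuesFrom a string-value range on firstname, cardinality 1 on
# dateofBirth and minimum cardinality 1 on researchGroups.
classes:
  - name: Person
    package: cz.zcu.kiv
    annotations:
      - marker: EquivalentClass
        resource: http://cz.zcu.kiv/TestedSubject
    fields:
      - name: id
        type: integer
        id: true
      - name: firstname
        type: string
        annotations:
          - marker: SomeValuesFrom
            string_values:
              - http://cz.zcu.kiv/GivenNames
      - name: dateofBirth
        type: date
        annotations:
          - marker: Cardinality
            number: 1
      - name: researchGroups
        type: ResearchGroup
        collection: true
        annotations:
          - marker: MinCardinality
            number: 1
  - name: ResearchGroup
    package: cz.zcu.kiv
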