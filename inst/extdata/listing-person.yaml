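# The plain Person/ResearchGroup bean model: an integer identifier, an
# atomic string field and a collection-valued association.
classes:
  - name: Person
    package: cz.zcu.kiv
    fields:
      - name: id
        type: integer
        id: true
      - name: firstname
        type: string
      - name: researchGroups
        type: ResearchGroup
        collection: true
  - name: ResearchGroup
    package: cz.zcu.kiv
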