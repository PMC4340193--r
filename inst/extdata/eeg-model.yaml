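classes:
- name: Gender
  package: cz.zcu.kiv
  enum:
  - MALE
  - FEMALE
- name: ResearchGroup
  package: cz.zcu.kiv
  fields:
  - name: title
    type: string
  - name: groupDescription
    type: string
- name: Person
  package: cz.zcu.kiv
  fields:
  - name: id
    type: integer
    id: yes
  - name: firstname
    type: string
    annotations:
    - marker: SomeValuesFrom
      string_values:
      - http://cz.zcu.kiv/GivenNames
  - name: surname
    type: string
    annotations:
    - marker: EquivalentProperty
      resource: http://cz.zcu.kiv/family_name
  - name: dateofBirth
    type: date
    annotations:
    - marker: Cardinality
      number: 1
  - name: laterality
    type: string
  - name: age
    type: integer
  - name: gender
    type: Gender
    annotations:
    - marker: MaxCardinality
      number: 1
  - name: colleagues
    type: Person
    collection: yes
    annotations:
    - marker: Symmetric
  - name: supervisor
    type: Person
    annotations:
    - marker: Transitive
    - marker: Inverse
      resource: http://cz.zcu.kiv/supervises
  - name: researchGroups
    type: ResearchGroup
    collection: yes
    annotations:
    - marker: MinCardinality
      number: 1
    - marker: AllValuesFrom
      resource: http://cz.zcu.kiv/ResearchGroups
  annotations:
  - marker: EquivalentClass
    resource: http://cz.zcu.kiv/TestedSubject
  - marker: SameAs
    resource: http://cz.zcu.kiv/Participant
  - marker: DifferentFrom
    resource: http://cz.zcu.kiv/Experiment
  - marker: AllDifferent
    resource: http://cz.zcu.kiv/AllDifferent
- name: Activity
  package: cz.zcu.kiv
  fields:
  - name: stimulation
    type: string
  - name: instructions
    type: string
  - name: stimuliDescription
    type: string
- name: Environment
  package: cz.zcu.kiv
  fields:
  - name: weather
    type: string
  - name: daytime
    type: string
  - name: roomTemperature
    type: decimal
- name: Equipment
  package: cz.zcu.kiv
  fields:
  - name: producer
    type: string
- name: HardwareEquipment
  package: cz.zcu.kiv
  extends: Equipment
  fields:
  - name: hardwareType
    type: string
  - name: serialNumber
    type: string
- name: SoftwareEquipment
  package: cz.zcu.kiv
  extends: Equipment
  fields:
  - name: softwareName
    type: string
  - name: version
    type: string
- name: Electrode
  package: cz.zcu.kiv
  fields:
  - name: electrodeType
    type: string
  - name: impedance
    type: decimal
  - name: location
    type: string
  - name: fixation
    type: string
- name: DataDigitalization
  package: cz.zcu.kiv
  fields:
  - name: filtration
    type: string
  - name: samplingFrequency
    type: decimal
  - name: bandPass
    type: string
- name: SignalAnalysis
  package: cz.zcu.kiv
  fields:
  - name: preStimulusMs
    type: integer
  - name: postStimulusMs
    type: integer
  - name: epochCount
    type: integer
  - name: procedureDescription
    type: string
- name: DataPresentation
  package: cz.zcu.kiv
  fields:
  - name: averagedWaves
    type: string
  - name: grandAverages
    type: string
  - name: rawDataLink
    type: string
- name: SignalArtifact
  package: cz.zcu.kiv
  fields:
  - name: compensationMethod
    type: string
  - name: removalDescription
    type: string
  - name: uselessSignalConditions
    type: string
- name: Scenario
  package: cz.zcu.kiv
  fields:
  - name: title
    type: string
  - name: scenarioDescription
    type: string
  - name: scenarioLength
    type: integer
- name: Data
  package: cz.zcu.kiv
  fields:
  - name: filename
    type: string
  - name: filesize
    type: decimal
- name: Experiment
  package: cz.zcu.kiv
  fields:
  - name: startTime
    type: datetime
  - name: testedSubject
    type: Person
  - name: scenario
    type: Scenario
  - name: hardware
    type: HardwareEquipment
  - name: experimentData
    type: Data
  - name: usedSoftware
    type: SoftwareEquipment
    collection: yes
  - name: usedElectrodes
    type: Electrode
    collection: yes
  - name: digitalization
    type: DataDigitalization
  - name: analyses
    type: SignalAnalysis
    collection: yes
  - name: presentation
    type: DataPresentation
  - name: artifacts
    type: SignalArtifact
    collection: yes
  - name: activity
    type: Activity
  - name: environment
    type: Environment

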