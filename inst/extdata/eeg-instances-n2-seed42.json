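[
  {
    "class": "Person",
    "id": "person1",
    "values": {
      "id": 1,
      "firstname": "Jan",
      "surname": "Prochazka",
      "dateofBirth": "1950-09-10",
      "laterality": "RIGHT_HANDED",
      "age": 75,
      "gender": "MALE"
    }
  },
  {
    "class": "Scenario",
    "id": "scenario1",
    "values": {
      "title": "Resting state",
      "scenarioDescription": "Synthetic scenario 1",
      "scenarioLength": 29
    }
  },
  {
    "class": "HardwareEquipment",
    "id": "hardware1",
    "values": {
      "hardwareType": "EEG amplifier",
      "producer": "Biosemi",
      "serialNumber": "SN-96666"
    }
  },
  {
    "class": "Data",
    "id": "data1",
    "values": {
      "filename": "experiment_001.avg",
      "filesize": 287.11
    }
  },
  {
    "class": "Experiment",
    "id": "experiment1",
    "values": {
      "startTime": "2013-03-09T16:26:00",
      "testedSubject": "person1",
      "scenario": "scenario1",
      "hardware": "hardware1",
      "experimentData": "data1"
    }
  },
  {
    "class": "Person",
    "id": "person2",
    "values": {
      "id": 2,
      "firstname": "Roman",
      "surname": "Prochazka",
      "dateofBirth": "1980-05-20",
      "laterality": "RIGHT_HANDED",
      "age": 45,
      "gender": "FEMALE"
    }
  },
  {
    "class": "Scenario",
    "id": "scenario2",
    "values": {
      "title": "Visual N400",
      "scenarioDescription": "Synthetic scenario 2",
      "scenarioLength": 37
    }
  },
  {
    "class": "HardwareEquipment",
    "id": "hardware2",
    "values": {
      "hardwareType": "A/D converter",
      "producer": "g.tec",
      "serialNumber": "SN-90411"
    }
  },
  {
    "class": "Data",
    "id": "data2",
    "values": {
      "filename": "experiment_002.avg",
      "filesize": 223.397
    }
  },
  {
    "class": "Experiment",
    "id": "experiment2",
    "values": {
      "startTime": "2013-06-26T15:35:00",
      "testedSubject": "person2",
      "scenario": "scenario2",
      "hardware": "hardware2",
      "experimentData": "data2"
    }
  }
]
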