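# Bundled EEG/ERP experiment-metadata model and seeded instance generator.
#
# The model mirrors the metadata groups collected around an
# electroencephalography / event-related-potential experiment: the
# experimental protocol (Activity), recording conditions (Environment), the
# tested subject (Person), recording hardware and software, electrodes,
# digitalization parameters, signal analysis and presentation, and artifact
# handling, tied together by the Experiment / Scenario / Data hub classes.
# Attribute value pools in the generator are synthetic fixture content; only
# the class structure and linkage are domain-constrained.

eeg_ns <- "http://cz.zcu.kiv/"

#' Build the EEG/ERP experiment-metadata model
#'
#' Returns the bundled domain model: one class per metadata semantic group
#' (Activity, Environment, Person -- the tested subject --, HardwareEquipment,
#' SoftwareEquipment, Electrode, DataDigitalization, SignalAnalysis,
#' DataPresentation, SignalArtifact) plus the Experiment, Scenario, Data,
#' ResearchGroup, Equipment and Gender support classes.  Experiment references
#' Person, Scenario, HardwareEquipment and Data.  Person carries the complete
#' supported marker set, one of each, including its equivalence to the
#' external TestedSubject class, a someValuesFrom constraint on `firstname`,
#' cardinality 1 on `dateofBirth` and minimum cardinality 1 on
#' `researchGroups`.
#'
#' @return List of [class_model()] objects; passes [validate_model()] with an
#'   empty report.
#' @examples
#' m <- build_domain_model()
#' nrow(validate_model(m)) == 0
#' @export
build_domain_model <- function() {
  pkg <- "cz.zcu.kiv"
  cls <- function(name, ...) class_model(name, paste0(pkg, ".", name), ...)
  af <- function(name, kind, ...) field_model(name, "atomic", atomic_kind = kind, ...)

  list(
    class_model("Gender", paste0(pkg, ".Gender"), is_enumeration = TRUE,
                enum_literals = c("MALE", "FEMALE")),
    cls("ResearchGroup", fields = list(
      af("title", "string"),
      af("groupDescription", "string")
    )),
    cls("Person",
      annotations = list(
        semantic_annotation("EquivalentClass", resource = paste0(eeg_ns, "TestedSubject")),
        semantic_annotation("SameAs", resource = paste0(eeg_ns, "Participant")),
        semantic_annotation("DifferentFrom", resource = paste0(eeg_ns, "Experiment")),
        semantic_annotation("AllDifferent", resource = paste0(eeg_ns, "AllDifferent"))
      ),
      fields = list(
        af("id", "integer", is_identifier = TRUE),
        af("firstname", "string", annotations = list(
          semantic_annotation("SomeValuesFrom",
                              string_values = paste0(eeg_ns, "GivenNames")))),
        af("surname", "string", annotations = list(
          semantic_annotation("EquivalentProperty",
                              resource = paste0(eeg_ns, "family_name")))),
        af("dateofBirth", "date", annotations = list(
          semantic_annotation("Cardinality", number = 1))),
        af("laterality", "string"),
        af("age", "integer"),
        field_model("gender", "reference", target_class = "Gender",
                    annotations = list(
                      semantic_annotation("MaxCardinality", number = 1))),
        field_model("colleagues", "collection", target_class = "Person",
                    annotations = list(semantic_annotation("Symmetric"))),
        field_model("supervisor", "reference", target_class = "Person",
                    annotations = list(
                      semantic_annotation("Transitive"),
                      semantic_annotation("Inverse",
                                          resource = paste0(eeg_ns, "supervises")))),
        field_model("researchGroups", "collection", target_class = "ResearchGroup",
                    annotations = list(
                      semantic_annotation("MinCardinality", number = 1),
                      semantic_annotation("AllValuesFrom",
                                          resource = paste0(eeg_ns, "ResearchGroups"))))
      )),
    cls("Activity", fields = list(
      af("stimulation", "string"),
      af("instructions", "string"),
      af("stimuliDescription", "string")
    )),
    cls("Environment", fields = list(
      af("weather", "string"),
      af("daytime", "string"),
      af("roomTemperature", "decimal")
    )),
    cls("Equipment", fields = list(
      af("producer", "string")
    )),
    cls("HardwareEquipment", superclass = "Equipment", fields = list(
      af("hardwareType", "string"),
      af("serialNumber", "string")
    )),
    cls("SoftwareEquipment", superclass = "Equipment", fields = list(
      af("softwareName", "string"),
      af("version", "string")
    )),
    cls("Electrode", fields = list(
      af("electrodeType", "string"),
      af("impedance", "decimal"),
      af("location", "string"),
      af("fixation", "string")
    )),
    cls("DataDigitalization", fields = list(
      af("filtration", "string"),
      af("samplingFrequency", "decimal"),
      af("bandPass", "string")
    )),
    cls("SignalAnalysis", fields = list(
      af("preStimulusMs", "integer"),
      af("postStimulusMs", "integer"),
      af("epochCount", "integer"),
      af("procedureDescription", "string")
    )),
    cls("DataPresentation", fields = list(
      af("averagedWaves", "string"),
      af("grandAverages", "string"),
      af("rawDataLink", "string")
    )),
    cls("SignalArtifact", fields = list(
      af("compensationMethod", "string"),
      af("removalDescription", "string"),
      af("uselessSignalConditions", "string")
    )),
    cls("Scenario", fields = list(
      af("title", "string"),
      af("scenarioDescription", "string"),
      af("scenarioLength", "integer")
    )),
    cls("Data", fields = list(
      af("filename", "string"),
      af("filesize", "decimal")
    )),
    cls("Experiment", fields = list(
      af("startTime", "datetime"),
      field_model("testedSubject", "reference", target_class = "Person"),
      field_model("scenario", "reference", target_class = "Scenario"),
      field_model("hardware", "reference", target_class = "HardwareEquipment"),
      field_model("experimentData", "reference", target_class = "Data"),
      field_model("usedSoftware", "collection", target_class = "SoftwareEquipment"),
      field_model("usedElectrodes", "collection", target_class = "Electrode"),
      field_model("digitalization", "reference", target_class = "DataDigitalization"),
      field_model("analyses", "collection", target_class = "SignalAnalysis"),
      field_model("presentation", "reference", target_class = "DataPresentation"),
      field_model("artifacts", "collection", target_class = "SignalArtifact"),
      field_model("activity", "reference", target_class = "Activity"),
      field_model("environment", "reference", target_class = "Environment")
    ))
  )
}

# synthetic value pools (fixture content, not domain data)
fixture_pools <- function() {
  list(
    firstnames = c("Jan", "Petr", "Eva", "Roman", "Lucie", "Marek", "Hana", "Tomas"),
    surnames = c("Novak", "Svoboda", "Dvorak", "Cerny", "Prochazka", "Vesela"),
    lateralities = c("LEFT_HANDED", "RIGHT_HANDED", "AMBIDEXTROUS"),
    genders = c("MALE", "FEMALE"),
    scenario_titles = c("P300 oddball", "Auditory attention", "Visual N400",
                        "Resting state", "Flanker task"),
    hardware_types = c("EEG amplifier", "A/D converter", "Stimulator",
                       "Response pad"),
    producers = c("BrainProducts", "Biosemi", "NeuroScan", "g.tec")
  )
}

#' Generate synthetic experiment instances
#'
#' Produces `n` Experiment records, each linked to one fresh Person, Scenario,
#' HardwareEquipment and Data record -- five records per experiment, the
#' linkage shape used for scaling runs -- with atomic values drawn from
#' seeded pseudo-random pools.  The same seed always yields identical
#' records, and every record of a class populates the same fields, so mapped
#' triple counts are exactly affine in `n`.
#'
#' @param n Number of experiments (>= 0).
#' @param seed Integer seed for the value pools.
#' @return List of `5 * n` [instance_record()] objects, valid against
#'   [build_domain_model()].
#' @examples
#' length(generate_instances(2, seed = 42)) == 10
#' @export
generate_instances <- function(n, seed = 1L) {
  if (!is.numeric(n) || length(n) != 1L || is.na(n) || n < 0) {
    stop("`n` must be a non-negative count of experiments")
  }
  n <- as.integer(n)
  if (n == 0L) return(list())

  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit({
    if (is.null(old_seed)) {
      if (exists(".Random.seed", globalenv())) rm(".Random.seed", envir = globalenv())
    } else assign(".Random.seed", old_seed, envir = globalenv())
  })
  set.seed(as.integer(seed))

  pools <- fixture_pools()
  pick <- function(pool) pool[[sample.int(length(pool), 1L)]]
  records <- vector("list", 5L * n)
  for (i in seq_len(n)) {
    pid <- sprintf("person%d", i)
    sid <- sprintf("scenario%d", i)
    hid <- sprintf("hardware%d", i)
    did <- sprintf("data%d", i)
    eid <- sprintf("experiment%d", i)
    records[[5L * i - 4L]] <- instance_record("Person", pid, list(
      id = i,
      firstname = pick(pools$firstnames),
      surname = pick(pools$surnames),
      dateofBirth = sprintf("19%02d-%02d-%02d", sample(50:99, 1L),
                            sample(1:12, 1L), sample(1:28, 1L)),
      laterality = pick(pools$lateralities),
      age = sample(18:80, 1L),
      gender = pick(pools$genders)
    ))
    records[[5L * i - 3L]] <- instance_record("Scenario", sid, list(
      title = pick(pools$scenario_titles),
      scenarioDescription = sprintf("Synthetic scenario %d", i),
      scenarioLength = sample(5:60, 1L)
    ))
    records[[5L * i - 2L]] <- instance_record("HardwareEquipment", hid, list(
      hardwareType = pick(pools$hardware_types),
      producer = pick(pools$producers),
      serialNumber = sprintf("SN-%05d", sample.int(99999L, 1L))
    ))
    records[[5L * i - 1L]] <- instance_record("Data", did, list(
      filename = sprintf("experiment_%03d.avg", i),
      filesize = round(stats::runif(1L, 0.5, 512), 3)
    ))
    records[[5L * i]] <- instance_record("Experiment", eid, list(
      startTime = sprintf("2013-%02d-%02dT%02d:%02d:00", sample(1:12, 1L),
                          sample(1:28, 1L), sample(8:18, 1L), sample(0:59, 1L)),
      testedSubject = pid,
      scenario = sid,
      hardware = hid,
      experimentData = did
    ))
  }
  records
}
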