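# The shipped terminology for Alzheimer's-disease clinical data: the study
# model (subjects, events, visits, exams, sites, diagnoses), the
# neuropsychological-test taxonomy, the item-scope taxonomy, and the fully
# modelled MMSE item set with its double classification (test-item family x
# cognitive scope).

#' Build the Alzheimer's-disease clinical data ontology (TBox)
#'
#' Constructs the full terminology: the high-level study model, the
#' neuropsychological test taxonomy (behavioural / cognitive / functional,
#' with the concrete ADNI instruments as leaves), the scope taxonomy of the
#' psychological sub-domains an item can address, and the 30 Mini-Mental
#' State Exam item classes. Each MMSE item class is classified twice: under
#' its test-item family (`MMSEItem`) and under the scope it evaluates
#' (orientation, registration, attention and calculation, recall, language
#' and praxis). The 30 items split 10/3/5/3/9 across those five groups.
#'
#' Properties follow the study model: a `Subject` `undergoes` an `Event`;
#' events have a date, a visit code and a site; a test `hasTestItem` its
#' items, which carry a `verbatimAnswer` (String) and an `itemScore` (Float),
#' with `0_1_score` as a subproperty of `itemScore` for binary-scored items.
#' An `owl:allValuesFrom` restriction per instrument confines `hasTestItem`
#' to that instrument's own item family (e.g. an MMSE session may only be
#' linked to `MMSEItem` individuals). The `MMSE` class is aligned by
#' `owl:sameAs` to the NCI Thesaurus OBO term `NCIT_C74982`.
#'
#' @param namespace IRI prefix for the ontology; defaults to
#'   [ado_namespace()].
#' @return An `ontology_schema`.
#' @examples
#' schema <- build_ad_onto()
#' length(subclass_closure(schema, "MMSEItem")) - 1  # 30 item classes
#' @export
build_ad_onto <- function(namespace = ado_namespace()) {
  classes <- list()
  cls <- function(name, parents = character(), labels = name) {
    classes[[length(classes) + 1L]] <<-
      list(uri = paste0(namespace, name),
           labels = labels,
           parents = if (length(parents)) paste0(namespace, parents) else character())
  }

  # high-level study model
  for (top in c("Subject", "MedicalHistory", "FamilyHistory", "Enrollment",
                "Event", "Site", "Diagnosis"))
    cls(top)
  cls("Visit", "Event")
  cls("Exam", "Event")
  for (ex in c("BiospecimenExam", "ImageExam", "ClinicalExam"))
    cls(ex, "Exam")
  cls("NeuropsychologicalTest", "Exam")

  # test taxonomy
  cls("BehaviouralTest", "NeuropsychologicalTest")
  cls("CognitiveTest", "NeuropsychologicalTest")
  cls("FunctionalTest", "NeuropsychologicalTest")
  tests <- list(
    GDS = list(parent = "BehaviouralTest", labels = c("GDS", "Geriatric Depression Scale")),
    NPI = list(parent = "BehaviouralTest", labels = c("NPI", "Neuropsychiatric Inventory")),
    `NPI-Q` = list(parent = "BehaviouralTest",
                   labels = c("NPI-Q", "Neuropsychiatric Inventory Questionnaire")),
    ADAS = list(parent = "CognitiveTest",
                labels = c("ADAS", "Alzheimer's Disease Assessment Scale")),
    CCI = list(parent = "CognitiveTest", labels = c("CCI", "Cognitive Change Index")),
    CDR = list(parent = "CognitiveTest", labels = c("CDR", "Clinical Dementia Rating")),
    MMSE = list(parent = "CognitiveTest",
                labels = c("MMSE", "Mini-Mental State Examination")),
    MoCA = list(parent = "CognitiveTest",
                labels = c("MoCA", "Montreal Cognitive Assessment")),
    NeuropsychologicalBattery = list(parent = "CognitiveTest",
                                     labels = c("NeuropsychologicalBattery",
                                                "Neuropsychological Battery")),
    FAQ = list(parent = "FunctionalTest",
               labels = c("FAQ", "Functional Activity Questionnaire")),
    `FCI-SF` = list(parent = "FunctionalTest",
                    labels = c("FCI-SF", "Financial Capacity Instrument - Short Form")))
  for (t in names(tests)) cls(t, tests[[t]]$parent, tests[[t]]$labels)

  # items: one generic item class (with its synonym), one family per test
  cls("TestItem", labels = c("TestItem", "NeuropsychologicalItem"))
  for (t in names(tests)) cls(paste0(t, "Item"), "TestItem")

  # scope taxonomy: the psychological sub-domain an item evaluates; scope
  # classes are themselves item categories, hence live under TestItem
  scopes <- list(
    DailyFunctioning = c("ActivitiesOfDailyLiving", "HomeAndHobbies", "PersonalCare"),
    ExecutiveFunction = c("CognitiveFlexibility", "JudgmentAndProblemSolving",
                          "ProcessionSpeed", "AttentionAndCalculation"),
    Language = c("Reading", "VerbalFluency", "Comprehension", "Naming",
                 "Repetition", "Writing"),
    MemoryItem = c("Learning", "LogicalMemory", "Long-TermMemory", "Registration",
                   "SemanticMemory", "Short-TermMemory", "WorkingMemory", "MemoryLoss"),
    Orientation = c("PlaceOrientation", "TimeOrientation"),
    PsychiatricDomain = c("Disinhibition", "Anxiety", "Apathy_Indifference",
                          "Depression", "Dysphoria", "Agitation_Aggression",
                          "EatingDisorders", "Elation_Euphoria", "Hallucinations",
                          "SleepDisorders", "Delusion", "Irritability_Lability"),
    SocialFunctioning = "CommunityAffair",
    `Visuo-SpatialAbility` = "VisualConstruction")
  slash_labels <- c(Apathy_Indifference = "Apathy/Indifference",
                    Agitation_Aggression = "Agitation/Aggression",
                    Elation_Euphoria = "Elation/Euphoria",
                    Irritability_Lability = "Irritability/Lability")
  cls("MemoryItem", "TestItem", labels = c("MemoryItem", "Memory"))
  for (top in setdiff(names(scopes), "MemoryItem")) cls(top, "TestItem")
  for (top in names(scopes)) {
    for (s in scopes[[top]]) {
      lab <- if (s %in% names(slash_labels)) c(s, unname(slash_labels[s])) else s
      cls(s, top, labels = lab)
    }
  }

  # the 30 MMSE item classes, doubly classified
  item <- function(name, scope) cls(name, c("MMSEItem", scope))
  for (k in 1:5)  item(paste0("MMSE_OrientationItem_", k), "TimeOrientation")
  for (k in 6:10) item(paste0("MMSE_OrientationItem_", k), "PlaceOrientation")
  for (k in 1:3)  item(paste0("MMSE_RegistrationItem_", k), "Registration")
  for (k in 1:5)  item(paste0("MMSE_AttentionAndCalculationItem_", k),
                       "AttentionAndCalculation")
  for (k in 1:3)  item(paste0("MMSE_RecallItem_", k), "MemoryItem")
  for (k in 1:9)  item(paste0("MMSE_LanguageAndPraxisItem_", k), "Language")

  properties <- list()
  prop <- function(name, kind, domain, range, sub = NA_character_) {
    properties[[length(properties) + 1L]] <<-
      list(uri = paste0(namespace, name), kind = kind,
           domain = paste0(namespace, domain),
           range = if (kind == "object") paste0(namespace, range) else range,
           subproperty_of = if (is.na(sub)) NA_character_ else paste0(namespace, sub))
  }
  prop("undergoes", "object", "Subject", "Event")
  prop("takesPlaceIn", "object", "Event", "Site")
  prop("supportedBy", "object", "Diagnosis", "Exam")
  prop("hasTestItem", "object", "NeuropsychologicalTest", "TestItem")
  prop("hasDate", "datatype", "Event", "Date")
  prop("hasVisitCode", "datatype", "Event", "String")
  prop("verbatimAnswer", "datatype", "TestItem", "String")
  prop("itemScore", "datatype", "TestItem", "Float")
  prop("0_1_score", "datatype", "TestItem", "Float", sub = "itemScore")

  restrictions <- data.frame(
    on_class = paste0(namespace, names(tests)),
    on_property = paste0(namespace, "hasTestItem"),
    all_values_from = paste0(namespace, names(tests), "Item"),
    stringsAsFactors = FALSE)

  alignments <- data.frame(
    local_uri = paste0(namespace, "MMSE"),
    external_uri = paste0(OBO_NS, "NCIT_C74982"),
    stringsAsFactors = FALSE)

  ontology_schema(namespace = namespace, classes = classes,
                  properties = properties, restrictions = restrictions,
                  alignments = alignments)
}

#' MMSE item classes and their scope group
#'
#' Walks the built is-a graph: the MMSE item classes are the proper subclass
#' closure of `MMSEItem`; each item's scope group is determined from its
#' non-family parent's position in the scope taxonomy (never from the item's
#' name).
#'
#' @param schema an `ontology_schema` from [build_ad_onto()].
#' @return A data.frame with columns `item` (class IRI) and `group`, where
#'   `group` is one of `orientation`, `registration`,
#'   `attention_calculation`, `recall`, `language_praxis`.
#' @export
mmse_item_groups <- function(schema) {
  ns <- schema$namespace
  family <- paste0(ns, "MMSEItem")
  items <- setdiff(subclass_closure(schema, family), family)
  closure <- function(name) subclass_closure(schema, paste0(ns, name))
  in_orient <- closure("Orientation")
  in_reg <- closure("Registration")
  in_attn <- closure("AttentionAndCalculation")
  in_lang <- closure("Language")
  in_mem <- closure("MemoryItem")
  group <- vapply(items, function(it) {
    sc <- setdiff(schema$classes[[it]]$parents, family)
    if (any(sc %in% in_orient)) "orientation"
    else if (any(sc %in% in_reg)) "registration"
    else if (any(sc %in% in_attn)) "attention_calculation"
    else if (any(sc %in% in_lang)) "language_praxis"
    else if (any(sc %in% in_mem)) "recall"
    else NA_character_
  }, character(1), USE.NAMES = FALSE)
  data.frame(item = items, group = group, stringsAsFactors = FALSE)
}
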