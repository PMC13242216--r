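test_that("axiom TSV parsing infers the signature and validates the DAG", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tkind\trelation\tobject",
               "A\tSubClassOf\t-\tROOT",
               "B\tSubClassOf\t-\tROOT"), path)
  ont <- parseOntology(path)
  expect_setequal(ontologyClasses(ont), c("A", "B", "ROOT"))
  expect_equal(nrow(axioms(ont)), 2L)

  writeLines(c("subject\tkind\trelation\tobject",
               "A\tSubClassOf\t-\tB",
               "broken line without tabs"), path)
  expect_error(parseOntology(path), "line 3")

  writeLines(c("subject\tkind\trelation\tobject",
               "A\tSubClassOf\t-\tB",
               "B\tSubClassOf\t-\tA"), path)
  expect_error(parseOntology(path), "cycle")
})

test_that("OBO subset stanzas map to the three axiom kinds", {
  path <- withr::local_tempfile(fileext = ".obo")
  writeLines(c("[Term]", "id: MP:0000001", "name: root-ish",
               "is_a: MP:0000000 ! parent",
               "relationship: has_part MP:0000002",
               "equivalent_to: HP:0000001"), path)
  ont <- parseOntology(path)
  ax <- axioms(ont)
  expect_setequal(ax$kind, c("SubClassOf", "SubClassOfSome", "EquivalentTo"))
  expect_equal(ax$relation[ax$kind == "SubClassOfSome"], "has_part")
  expect_true("has_part" %in% ontologyRoles(ont))

  writeLines(c("[Term]", "id: MP:0000001",
               "intersection_of: MP:0000002"), path)
  expect_error(parseOntology(path), "unsupported OBO construct")
})

test_that("reserved relation names cannot be ontology roles", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("subject\tkind\trelation\tobject",
               "A\tSubClassOfSome\thas_phenotype\tB"), path)
  expect_error(parseOntology(path), "reserved")
})

test_that("association axioms are added, filtered and leave input intact", {
  ont <- toyOntology()
  before <- axioms(ont)
  assoc <- associationTable("has_phenotype", list(g1 = "P_A1"))
  ont2 <- addAssociationAxioms(ont, assoc)
  added <- axioms(ont2)[nrow(axioms(ont2)), ]
  expect_equal(added$subject, "g1")
  expect_equal(added$kind, "SubClassOfSome")
  expect_equal(added$relation, "has_phenotype")
  expect_equal(added$object, "P_A1")
  expect_true("g1" %in% ontologyClasses(ont2))
  expect_identical(axioms(ont), before)

  expect_identical(addAssociationAxioms(ont, associationTable("has_symptom")),
                   ont)

  expect_message(
    ont3 <- addAssociationAxioms(
      ont, associationTable("has_symptom",
                            list(d1 = c("P_A2", "P_UNKNOWN")))),
    "dropping 1")
  ax3 <- axioms(ont3)
  expect_equal(sum(ax3$kind == "SubClassOfSome"), 1L)
  expect_equal(ax3$object[ax3$kind == "SubClassOfSome"], "P_A2")
})

test_that("projection applies the structural rules deterministically", {
  ont <- ontology(data.frame(subject = "A", kind = "SubClassOf",
                             relation = NA_character_, object = "B",
                             stringsAsFactors = FALSE))
  expect_equal(graphEdges(projectGraph(ont)),
               data.frame(head = "A", relation = "subClassOf", tail = "B"))

  ont2 <- ontology(data.frame(subject = "g1", kind = "SubClassOfSome",
                              relation = "has_phenotype", object = "P_A1",
                              stringsAsFactors = FALSE))
  expect_equal(graphEdges(projectGraph(ont2)),
               data.frame(head = "g1", relation = "has_phenotype",
                          tail = "P_A1"))

  ont3 <- ontology(data.frame(subject = "A", kind = "EquivalentTo",
                              relation = NA_character_, object = "B",
                              stringsAsFactors = FALSE))
  ed <- graphEdges(projectGraph(ont3))
  expect_equal(nrow(ed), 2L)
  expect_true(all(ed$relation == "subClassOf"))
  expect_setequal(paste(ed$head, ed$tail), c("A B", "B A"))

  phe <- generatePhenome(synthConfig(seed = 3))
  expect_identical(graphEdges(projectGraph(phe$ontology)),
                   graphEdges(projectGraph(phe$ontology)))
})

test_that("ontology round-trips through the axiom TSV dialect", {
  phe <- generatePhenome(synthConfig(seed = 5))
  path <- withr::local_tempfile(fileext = ".tsv")
  writeOntologyTSV(phe$ontology, path)
  back <- parseOntology(path)
  key <- function(o) {
    ax <- axioms(o)
    sort(paste(ax$subject, ax$kind, ifelse(is.na(ax$relation), "-",
                                           ax$relation), ax$object))
  }
  expect_identical(key(back), key(phe$ontology))
})

test_that("graph variants nest monotonically and respect inductivity", {
  fx <- variantFixture()
  test <- "d3"
  build <- function(v) buildGraphVariant(fx$ont, fx$gene, fx$disease,
                                         fx$gda, v, testDiseases = test)
  gs <- lapply(c(G1 = "G1", G2 = "G2", G3 = "G3", G4 = "G4",
                 G3T = "G3T", G4T = "G4T"), build)
  ekey <- function(g) with(graphEdges(g), paste(head, relation, tail))
  expect_true(all(ekey(gs$G1) %in% ekey(gs$G2)))
  expect_true(all(ekey(gs$G2) %in% ekey(gs$G3)))
  expect_true(all(ekey(gs$G3) %in% ekey(gs$G4)))
  expect_true(all(ekey(gs$G3) %in% ekey(gs$G3T)))
  expect_true(all(ekey(gs$G4) %in% ekey(gs$G4T)))

  ## G1 carries no gene or disease identifiers at all
  expect_false(any(c("g1", "g2", "d1", "d2", "d3") %in% graphNodes(gs$G1)))

  ## G4 minus G3 is exactly the training gene-disease edges
  diff <- setdiff(ekey(gs$G4), ekey(gs$G3))
  expect_setequal(diff, c("d1 associated_with g1", "d2 associated_with g2"))

  ## the held-out disease is absent from every inductive variant but
  ## present (with phenotype edges only) in the transductive ones
  for (v in c("G1", "G2", "G3", "G4"))
    expect_false(test %in% graphNodes(gs[[v]]))
  expect_true(test %in% graphNodes(gs$G3T))
  t3 <- setdiff(ekey(gs$G3T), ekey(gs$G3))
  expect_setequal(t3, "d3 has_symptom P2")
  expect_false(any(grepl("associated_with", setdiff(ekey(gs$G4T),
                                                    ekey(gs$G4)))))
})

test_that("a test-disease gene association is a hard error for any variant", {
  fx <- variantFixture()
  for (v in c("G1", "G2", "G3", "G4", "G3T", "G4T"))
    expect_error(buildGraphVariant(fx$ont, fx$gene, fx$disease, fx$gda, v,
                                   testDiseases = "d1"),
                 "leakage")
})

test_that("graph TSV writer and reader round-trip edge sets", {
  fx <- variantFixture()
  g <- buildGraphVariant(fx$ont, fx$gene, fx$disease, fx$gda, "G4")
  path <- withr::local_tempfile(fileext = ".tsv")
  writeGraphTSV(g, path)
  back <- readGraphTSV(path)
  expect_identical(graphEdges(back), graphEdges(g))
})
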