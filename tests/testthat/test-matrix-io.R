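test_that("the fixture matrix round-trips through CSV byte-stably", {
  s <- fx_study()
  csv <- write_matrix(s, "csv")
  s2 <- read_matrix(csv, "csv")
  expect_identical(coding_set(s2), coding_set(s))
  expect_identical(write_matrix(s2, "csv"), csv)
  expect_identical(nrow(s2$characters), 43L)
})

test_that("the fixture matrix round-trips through NEXUS with polymorphism", {
  s <- fx_study()
  nx <- write_matrix(s, "nexus")
  expect_match(nx, "DIMENSIONS NCHAR=43")
  expect_match(nx, "\\{01\\}")  # the two polymorphic cells
  s2 <- read_matrix(nx, "nexus")
  expect_identical(coding_set(s2), coding_set(s))
})

test_that("NEXUS export refuses characters beyond the symbol limit", {
  base <- "http://example.com/study/"
  chars <- data.frame(id = paste0(base, "character/1"),
                      label = "Hypervariable thing", body_region = "body",
                      template_category = "unannotated",
                      stringsAsFactors = FALSE)
  states <- data.frame(id = paste0(base, "state/", 1:40),
                       character_id = chars$id,
                       label = paste0("s", 1:40), stringsAsFactors = FALSE)
  s <- study(characters = chars, states = states,
             otus = data.frame(id = paste0(base, "otu/1"),
                               taxon_name = "T", material = "",
                               stringsAsFactors = FALSE))
  expect_error(write_matrix(s, "nexus"), "Hypervariable thing")
  expect_silent(write_matrix(s, "csv"))
})

test_that("matrix round trips hold on fuzzed synthetic studies", {
  for (seed in c(101, 102, 103)) {
    g <- generate_study(synth_config(seed = seed, polymorphism_rate = 0.3))
    s <- g$study
    expect_identical(coding_set(read_matrix(write_matrix(s, "csv"),
                                            "csv")), coding_set(s))
    expect_identical(coding_set(read_matrix(write_matrix(s, "nexus"),
                                            "nexus")), coding_set(s))
    csv <- write_matrix(s, "csv")
    expect_identical(write_matrix(read_matrix(csv, "csv"), "csv"), csv)
  }
})

test_that("study RDF export round-trips and feeds the reasoner", {
  s <- fx_study_annotated()
  g <- study_to_rdf(s)
  s2 <- rdf_to_study(g)
  expect_identical(nrow(s2$characters), nrow(s$characters))
  expect_identical(nrow(s2$states), nrow(s$states))
  expect_identical(nrow(s2$otus), nrow(s$otus))
  expect_identical(nrow(s2$codings), nrow(s$codings))
  expect_identical(nrow(s2$specimens), nrow(s$specimens))
  expect_identical(length(s2$annotations), length(s$annotations))
  expect_identical(coding_set(s2), coding_set(s))
  expect_true(graph_isomorphic(study_to_rdf(s2), g))
})

test_that("a minimal one-of-everything study materializes one denotes edge", {
  base <- "http://example.com/study/"
  chars <- data.frame(id = paste0(base, "character/1"), label = "C1",
                      body_region = "head",
                      template_category = "qualitative",
                      stringsAsFactors = FALSE)
  states <- data.frame(id = paste0(base, "state/1"),
                       character_id = chars$id, label = "curved",
                       stringsAsFactors = FALSE)
  otus <- data.frame(id = paste0(base, "otu/1"), taxon_name = "T1",
                     material = "", stringsAsFactors = FALSE)
  codings <- data.frame(otu_id = otus$id, character_id = chars$id,
                        state_id = states$id, stringsAsFactors = FALSE)
  specimens <- data.frame(catalog_urn = "urn:catalog:X:X:1",
                          otu_id = otus$id, repository_coden = "X",
                          country = "", subdivision = "", role = "other",
                          sex = "unknown", verbatim = "",
                          stringsAsFactors = FALSE)
  s <- study(chars, states, otus, codings, specimens)
  s <- annotate_state(s, states$id,
                      compose_qualitative(hao("wing"), pato("curved")))
  out <- study_propagate(s)
  expect_identical(nrow(out), 1L)
  expect_identical(out$specimen, "urn:catalog:X:X:1")
  # empty study exports an empty graph
  expect_identical(nrow(study_to_rdf(study())), 0L)
})
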