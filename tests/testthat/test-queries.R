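test_that("usage counts distinct classes per source ontology", {
  s <- fx_study()
  s <- annotate_state(s, "Eye color: blue",
                      compose_qualitative(hao("eye"), pato("blue")))
  s <- annotate_state(s, "Eye color: gray-silver",
                      compose_qualitative(hao("eye"), pato("gray-silver")))
  u <- usage_counts(s)
  expect_identical(u$counts[["HAO"]], 1L)   # eye, counted once
  expect_identical(u$counts[["PATO"]], 2L)  # blue, gray-silver
  # duplicating annotations leaves distinct-class counts unchanged
  s2 <- annotate_state(s, "Eye color: blue",
                       compose_qualitative(hao("eye"), pato("blue")),
                       replace = TRUE)
  expect_identical(usage_counts(s2)$counts, u$counts)
  # unknown namespaces are reported, not dropped
  s3 <- annotate_state(s, "Nucha presence: present",
                       ce_some(PR$has_part, ce_named("urn:odd:class")))
  expect_identical(usage_counts(s3)$counts[["unknown"]], 1L)
})

test_that("usage comparison obeys inclusion-exclusion", {
  s <- fx_study_annotated()
  u <- usage_counts(s)
  self <- usage_compare(u, u)
  expect_identical(self$union, self$intersection)
  expect_identical(self$union, self$a)
  # fuzzed pairs
  set.seed(31)
  for (i in seq_len(20)) {
    g1 <- generate_study(synth_config(seed = 200 + i))
    g2 <- generate_study(synth_config(seed = 300 + i))
    ua <- usage_counts(g1$study)
    ub <- usage_counts(g2$study)
    cmp <- usage_compare(ua, ub)
    expect_identical(cmp$union, cmp$a + cmp$b - cmp$intersection)
    expect_true(all(cmp$intersection <= pmin(cmp$a, cmp$b)))
    expect_true(all(pmax(cmp$a, cmp$b) <= cmp$union))
  }
  expect_error(usage_compare(u, usage_counts(s, namespace_map = c(
    structure("X", names = "urn:")))), "different namespace maps")
})

test_that("entity partition reproduces the two-disjunct query semantics", {
  # 4 characters, 2 about parts of the mesosoma -> 50%
  base <- "http://example.com/study/"
  chars <- data.frame(
    id = paste0(base, "character/", 1:4),
    label = paste("Char", 1:4), body_region = "mesosoma",
    template_category = "qualitative", stringsAsFactors = FALSE)
  states <- data.frame(id = paste0(base, "state/", 1:4),
                       character_id = chars$id,
                       label = paste0("s", 1:4), stringsAsFactors = FALSE)
  otus <- data.frame(id = paste0(base, "otu/1"), taxon_name = "T",
                     material = "", stringsAsFactors = FALSE)
  s <- study(chars, states, otus)
  s <- annotate_state(s, states$id[[1]],
                      compose_qualitative(hao("notaulus"),
                                          pato("sigmoid")))
  s <- annotate_state(s, states$id[[2]],
                      compose_qualitative(hao("ventro_lateral_region"),
                                          pato("foveate")))
  s <- annotate_state(s, states$id[[3]],
                      compose_qualitative(hao("eye"), pato("blue")))
  s <- annotate_state(s, states$id[[4]],
                      compose_qualitative(hao("petiole"), pato("smooth")))
  tbx <- fx_tbox()
  r <- partition_by_entity(s, hao("mesosoma"), tbx)
  expect_identical(r$count, 2L)
  expect_equal(r$percentage, 50)
  # the quality partition: 1 of 4 characters uses a shape subtype
  rq <- partition_by_quality(s, pato("shape"), tbx)
  expect_identical(rq$count, 1L)
  expect_equal(rq$percentage, 25)
  # the top quality counts every qualitative character here
  rtop <- partition_by_quality(s, pato("quality"), tbx)
  expect_identical(rtop$count, 4L)
  # the whole body is an upper bound for every entity query
  rbody <- partition_by_entity(s, hao("body"), tbx)
  expect_true(rbody$count >= r$count)
  # an unused entity counts nothing; an unknown one errors
  expect_identical(partition_by_entity(s, hao("tooth"), tbx)$count, 0L)
  expect_error(partition_by_entity(s, "urn:nowhere", tbx), "unknown")
})

test_that("partition counts are monotone along part_of", {
  s <- fx_study_annotated()
  tbx <- fx_tbox()
  o <- fx_ontology()
  # every declared 'A part_of B' pair: count(B) >= count(A)
  for (ax in o$axioms) {
    if (ax$type == "subclass" && ax$sub$kind == "named" &&
        ax$sup$kind == "some" && ax$sup$property == PR$part_of) {
      ca <- partition_by_entity(s, ax$sub$iri, tbx)$count
      cb <- partition_by_entity(s, ax$sup$filler$iri, tbx)$count
      expect_true(cb >= ca,
                  info = sprintf("%s part_of %s", ax$sub$iri,
                                 ax$sup$filler$iri))
    }
  }
})

test_that("template tally recovers generator mixes and fixture categories", {
  g <- generate_study(synth_config(seed = 9, n_qualitative = 10,
                                   n_presence = 5, n_count = 2,
                                   n_relative = 3))
  t <- template_tally(g$study)
  expect_identical(t[["qualitative"]], 10L)
  expect_identical(t[["presence_absence"]], 5L)
  expect_identical(t[["count"]], 2L)
  expect_identical(t[["relative_measurement"]], 3L)
  expect_identical(sum(t) - t[["unannotated"]], 20L)
  # empty study: all zeros
  expect_true(all(template_tally(study()) == 0L))
  # name-based fixture categories (pre-reconciliation)
  tf <- template_tally(fx_study())
  expect_identical(tf[["count"]], 1L)
  expect_identical(tf[["presence_absence"]], 14L)
  expect_identical(tf[["unannotated"]], 1L)
  expect_identical(sum(tf), 43L)
  # overrides win over the name heuristic
  ov <- data.frame(character_label = "Body length",
                   template_category = "nonstandard",
                   stringsAsFactors = FALSE)
  expect_identical(template_tally(fx_study(), overrides = ov)[[
    "nonstandard"]], 1L)
})

test_that("partition reports format percentages to one decimal", {
  s <- fx_study_annotated()
  rep <- partition_report(s, entities = hao("mesosoma"),
                          qualities = pato("texture"), tbox = fx_tbox())
  expect_identical(nrow(rep), 2L)
  expect_match(rep$percentage, "^[0-9]+\\.[0-9]$")
  # byte-stable across runs
  rep2 <- partition_report(s, entities = hao("mesosoma"),
                           qualities = pato("texture"), tbox = fx_tbox())
  expect_identical(rep, rep2)
})
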