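test_that("the qualitative composer nests locator chains as published", {
  e <- compose_qualitative(hao("wing"), pato("curved"))
  expect_true(ce_equal(e, ce_some(PR$has_part,
                                  ce_and(ce_named(hao("wing")),
                                         ce_some(PR$bearer_of,
                                                 ce_named(pato("curved")))))))
  e2 <- compose_qualitative(c(hao("mesosoma"),
                              hao("ventro_lateral_region")),
                            pato("foveate"))
  expect_identical(e2$filler$args[[1]]$iri, hao("mesosoma"))
  inner <- e2$filler$args[[2]]
  expect_identical(inner$filler$args[[1]]$iri,
                   hao("ventro_lateral_region"))
  expect_identical(classify_template(e2), "qualitative")
  expect_error(compose_qualitative(character(0), pato("curved")),
               "non-empty")
})

test_that("presence and absence compose without negation", {
  p1 <- compose_presence_absence(hao("nucha"), TRUE)
  expect_true(ce_equal(p1, ce_some(PR$has_part, ce_named(hao("nucha")))))
  a1 <- compose_presence_absence(c(hao("mesosoma"), hao("speculum")),
                                 FALSE)
  # references the absent quality on the container; no negation node,
  # and the missing part is recorded machine-readably
  expect_identical(classify_template(a1), "presence_absence")
  expect_true(PR$absent %in% ce_classes(a1))
  expect_false(hao("speculum") %in% ce_classes(a1))
  expect_identical(attr(a1, "absent_part"), hao("speculum"))
  # chain of length 1: the organism itself bears 'absent'
  a2 <- compose_presence_absence(hao("nucha"), FALSE)
  expect_true(ce_equal(a2, ce_some(PR$bearer_of, ce_named(PR$absent))))
  expect_identical(classify_template(a2), "presence_absence")
})

test_that("count composer and boundary cases", {
  e <- compose_count(hao("mandible"), hao("tooth"), 3)
  expect_identical(classify_template(e), "count")
  expect_identical(e$filler$args[[2]]$n, 3L)
  e4 <- compose_count(hao("mandible"), hao("tooth"), 4)
  expect_identical(e4$filler$args[[2]]$n, 4L)
  e0 <- compose_count(hao("mandible"), hao("tooth"), 0)
  expect_identical(classify_template(e0), "count")
  expect_error(compose_count(hao("mandible"), hao("tooth"), -1),
               "non-negative")
})

test_that("relative-measurement composer emits the five-atom rule", {
  r <- compose_relative(hao("antenna"), pato("length"), hao("eye"),
                        "increased")
  expect_identical(classify_template(r$expression),
                   "relative_measurement")
  expect_length(r$rule$body, 5L)
  expect_identical(r$rule$head$var, "o")
  kinds <- vapply(r$rule$body, `[[`, character(1), "type")
  expect_identical(sum(kinds == "property"), 3L)
  expect_identical(sum(kinds == "class"), 2L)
  expect_false(r$degenerate)
  # mesopectus/metapectus form from the printed character
  r2 <- compose_relative(hao("mesopectus"), pato("length"),
                         hao("metapectus"), "decreased")
  expect_identical(classify_template(r2$expression),
                   "relative_measurement")
  # degenerate self-comparison accepted and flagged
  r3 <- compose_relative(hao("eye"), pato("length"), hao("eye"), "equal")
  expect_true(r3$degenerate)
  expect_error(compose_relative(hao("eye"), pato("length"), hao("eye"),
                                "increased"), "distinct entities")
})

test_that("classification inverts every composer on 500 seeded inputs", {
  anat <- hao(c("body", "head", "mesosoma", "eye", "antenna", "wing",
                "mandible", "tooth", "petiole", "leg"))
  quals <- pato(c("curved", "blue", "foveate", "smooth", "length"))
  set.seed(500)
  for (i in seq_len(500)) {
    which_t <- sample(c("qualitative", "presence_absence", "count",
                        "relative_measurement"), 1L)
    chain <- sample(anat, sample(1:3, 1L))
    got <- switch(which_t,
      qualitative = classify_template(
        compose_qualitative(chain, sample(quals, 1L))),
      presence_absence = classify_template(
        compose_presence_absence(chain, stats::runif(1) < 0.5)),
      count = classify_template(
        compose_count(chain, sample(anat, 1L), sample(0:5, 1L))),
      relative_measurement = classify_template(
        compose_relative(anat[[1]], pato("length"), anat[[2]],
                         sample(c("increased", "decreased"),
                                1L))$expression)
    )
    expect_identical(got, which_t,
                     info = sprintf("case %d (%s)", i, which_t))
  }
})

test_that("hand-built unions fall outside the four templates", {
  q1 <- compose_qualitative(hao("wing"), pato("curved"))
  q2 <- compose_qualitative(hao("eye"), pato("blue"))
  expect_identical(classify_template(ce_or(q1, q2)), "nonstandard")
  expect_identical(classify_template(ce_named(hao("wing"))),
                   "nonstandard")
})

test_that("annotation mints stable subclass axioms and refuses doubles", {
  s <- fx_study()
  st <- "Eye color: blue"
  defn <- compose_qualitative(hao("eye"), pato("blue"))
  s1 <- annotate_state(s, st, defn, ontology = fx_ontology())
  sid <- names(s1$annotations)[[1]]
  a <- s1$annotations[[sid]]
  expect_identical(a$phenotype, paste0(sid, "#phenotype"))
  expect_length(a$axioms, 2L)
  expect_identical(a$axioms[[1]]$type, "subclass")  # never equivalence
  expect_true(ce_equal(a$axioms[[1]]$sub, ce_named(a$phenotype)))
  expect_identical(a$axioms[[2]]$type, "class_assertion")
  expect_identical(a$axioms[[2]]$expr$kind, "only")
  expect_error(annotate_state(s1, st, defn), "already annotated")
  expect_silent(annotate_state(s1, st, defn, replace = TRUE))
  # undeclared classes are rejected when an ontology is supplied
  expect_error(
    annotate_state(s, st, ce_named("urn:mystery:class"),
                   ontology = fx_ontology()),
    "undeclared classes")
})

test_that("annotated states classify coded specimens end to end", {
  s <- fx_study()
  s <- annotate_state(s, "Eye color: blue",
                      compose_qualitative(hao("eye"), pato("blue")))
  out <- study_propagate(s, tbox = fx_tbox())
  sid <- names(s$annotations)[[1]]
  ea <- s$otus$id[s$otus$taxon_name == "Evania appendigaster"]
  ea_specs <- s$specimens$catalog_urn[s$specimens$otu_id == ea]
  got <- out$specimen[out$phenotype == paste0(sid, "#phenotype")]
  expect_setequal(got, ea_specs)  # only the blue-eyed species
})

test_that("composed expressions stay inside the reasoned fragment", {
  # never Only, never negation; Only enters via annotate_state alone
  set.seed(77)
  anat <- hao(c("head", "eye", "wing"))
  for (i in seq_len(50)) {
    e <- switch(sample(3, 1L),
      compose_qualitative(sample(anat, 2L), pato("curved")),
      compose_presence_absence(sample(anat, 1L), FALSE),
      compose_count(sample(anat, 1L), hao("tooth"), 2))
    walk <- function(x) {
      expect_false(x$kind == "only")
      switch(x$kind, and = , or = lapply(x$args, walk),
             some = , exactly = walk(x$filler), NULL)
    }
    walk(e)
  }
})
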