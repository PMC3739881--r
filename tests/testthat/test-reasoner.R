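test_that("structural subsumption handles the anatomy partition patterns", {
  tbx <- tiny_tbox()
  # reflexivity
  x <- ce_some(PR$has_part, ce_named(hao("antenna")))
  expect_true(is_subsumed(x, x, tbx))
  # the two-disjunct partition query finds a part through its declared
  # part_of superclass
  sub <- ce_some(PR$has_part,
                 ce_and(ce_named(hao("ventro_lateral_region")),
                        ce_some(PR$bearer_of, ce_named(pato("foveate")))))
  sup <- ce_or(ce_some(PR$has_part, ce_named(hao("mesosoma"))),
               ce_some(PR$has_part,
                       ce_some(PR$part_of, ce_named(hao("mesosoma")))))
  expect_true(is_subsumed(sub, sup, tbx))
  # quality query generalizes through the quality hierarchy
  sub2 <- ce_some(PR$has_part,
                  ce_and(ce_named(hao("antenna")),
                         ce_some(PR$bearer_of, ce_named(pato("curved")))))
  sup2 <- ce_some(PR$has_part,
                  ce_some(PR$bearer_of, ce_named(pato("shape"))))
  expect_true(is_subsumed(sub2, sup2, tbx))
  expect_false(is_subsumed(sup2, sub2, tbx))
  # top subsumes everything
  expect_true(is_subsumed(sub2, ce_named(tbx$top), tbx))
})

test_that("transitivity, Or handling and Only/Exactly structure", {
  tbx <- tiny_tbox()
  # transitive has_part folds nested existentials
  deep <- ce_some(PR$has_part, ce_some(PR$has_part,
                                       ce_named(hao("eye"))))
  expect_true(is_subsumed(deep, ce_some(PR$has_part,
                                        ce_named(hao("eye"))), tbx))
  # Or in sub position: all disjuncts must hold
  sub <- ce_some(PR$has_part, ce_or(ce_named(hao("eye")),
                                    ce_named(hao("wing"))))
  sup <- ce_or(ce_some(PR$has_part, ce_named(hao("eye"))),
               ce_some(PR$has_part, ce_named(hao("wing"))))
  expect_true(is_subsumed(sub, sup, tbx))
  expect_false(is_subsumed(sub, ce_some(PR$has_part,
                                        ce_named(hao("eye"))), tbx))
  # Only compared structurally, filler monotone
  o1 <- ce_only(PR$denotes, ce_named(pato("curved")))
  o2 <- ce_only(PR$denotes, ce_named(pato("shape")))
  expect_true(is_subsumed(o1, o2, tbx))
  expect_false(is_subsumed(o2, o1, tbx))
  # Exactly: same cardinality and equivalent filler only; n >= 1
  # additionally entails the existential
  e3 <- ce_exactly(PR$has_part, 3, ce_named(hao("eye")))
  expect_true(is_subsumed(e3, e3, tbx))
  expect_false(is_subsumed(e3, ce_exactly(PR$has_part, 2,
                                          ce_named(hao("eye"))), tbx))
  expect_true(is_subsumed(e3, ce_some(PR$has_part, ce_named(hao("eye"))),
                          tbx))
  expect_false(is_subsumed(ce_exactly(PR$has_part, 0,
                                      ce_named(hao("eye"))),
                           ce_some(PR$has_part, ce_named(hao("eye"))),
                           tbx))
})

test_that("is_subsumed is reflexive and transitive on random expressions", {
  o <- tiny_ontology()
  tbx <- tiny_tbox()
  classes <- o$classes$iri
  props <- c(PR$has_part, PR$part_of, PR$bearer_of)
  set.seed(7)
  exprs <- lapply(seq_len(30), function(i) {
    random_expression(classes, props, max_depth = 3L, el_only = TRUE)
  })
  for (e in exprs) expect_true(is_subsumed(e, e, tbx))
  for (i in seq_len(60)) {
    trio <- sample(exprs, 3L)
    if (is_subsumed(trio[[1]], trio[[2]], tbx) &&
        is_subsumed(trio[[2]], trio[[3]], tbx)) {
      expect_true(is_subsumed(trio[[1]], trio[[3]], tbx))
    }
  }
})

test_that("oracle guards its fragment and resource caps", {
  o <- tiny_ontology()
  expect_error(oracle_subsumed(ce_only(PR$denotes, ce_named(hao("eye"))),
                               ce_named(hao("eye")), o),
               "EL core")
  expect_error(ce_and(list()), "two operands")
  deep <- ce_named(hao("eye"))
  for (i in 1:8) deep <- ce_some(PR$has_part, deep)
  expect_error(oracle_subsumed(deep, deep, o), "resource guard")
  # top subsumes all
  expect_true(oracle_subsumed(ce_named(hao("eye")),
                              ce_named(iri_expand("owl:Thing",
                                                  cfg$prefixes)), o))
})

test_that("the canonical model realizes the has_part chain claim", {
  # the nested template's locator is reachable from the root along
  # has_part edges, i.e. it is modelled as part of the same organism
  o <- tiny_ontology()
  expr <- ce_some(PR$has_part,
                  ce_and(ce_named(hao("mesosoma")),
                         ce_some(PR$has_part,
                                 ce_and(ce_named(hao("ventro_lateral_region")),
                                        ce_some(PR$bearer_of,
                                                ce_named(pato("foveate")))))))
  expect_true(oracle_subsumed(expr,
                              ce_some(PR$has_part,
                                      ce_named(hao("ventro_lateral_region"))),
                              o))
})

test_that("materialize derives transitive closures and the denotes chain", {
  tbx <- tiny_tbox()
  ab <- abox_graph(s = c("urn:a", "urn:b"), p = rep(PR$part_of, 2),
                   o = c("urn:b", "urn:c"))
  m <- materialize(ab, tbx)
  inferred <- m$edges[m$edges$inferred, , drop = FALSE]
  expect_identical(inferred$s, "urn:a")
  expect_identical(inferred$o, "urn:c")
  expect_match(inferred$derivation, "chain")
  # fixed point
  expect_identical(materialize(m, tbx)$edges, m$edges)
  # the Fig-2-style coding pattern: state -> coding -> TU -> specimen
  chain_cfg <- sempheno_config()
  props <- rbind(ont_property(PR$state_of), ont_property(PR$belongs_to_tu),
                 ont_property(PR$denotes))
  chains <- chain_cfg$chains
  o <- ontology(properties = props, chains = chains)
  tb2 <- build_tbox(o)
  ab2 <- abox_graph(
    s = c("urn:state1", "_:coding_2222", "urn:otu1"),
    p = c(PR$state_of, PR$belongs_to_tu, PR$denotes),
    o = c("_:coding_2222", "urn:otu1", "urn:catalog:NCSU:NCSU:34852")
  )
  m2 <- materialize(ab2, tb2)
  hit <- m2$edges[m2$edges$s == "urn:state1" & m2$edges$p == PR$denotes, ]
  expect_identical(hit$o, "urn:catalog:NCSU:NCSU:34852")
  expect_true(hit$inferred)
  # empty graph maps to itself
  empty <- abox_graph()
  expect_identical(nrow(materialize(empty, tb2)$edges), 0L)
})

test_that("propagate_phenotypes classifies specimens through denotes-only", {
  chain_cfg <- sempheno_config()
  props <- rbind(ont_property(PR$state_of), ont_property(PR$belongs_to_tu),
                 ont_property(PR$denotes))
  o <- ontology(properties = props, chains = chain_cfg$chains)
  tb <- build_tbox(o)
  ab <- abox_graph(
    s = c("urn:state1", "_:c1", "urn:otu1"),
    p = c(PR$state_of, PR$belongs_to_tu, PR$denotes),
    o = c("_:c1", "urn:otu1", "urn:catalog:NCSU:NCSU:34852"),
    assertions = list(list(individual = "urn:state1",
                           expr = ce_only(PR$denotes,
                                          ce_named("urn:P"))))
  )
  m <- materialize(ab, tb)
  out <- propagate_phenotypes(m, data.frame(state = "urn:state1",
                                            phenotype = "urn:P"))
  expect_identical(out$specimen, "urn:catalog:NCSU:NCSU:34852")
  expect_identical(out$phenotype, "urn:P")
  expect_error(
    propagate_phenotypes(m, data.frame(state = "urn:ghost",
                                       phenotype = "urn:P")),
    "unknown state")
})

test_that("polymorphic codings propagate both states' phenotypes", {
  s <- fx_study()
  pr <- PR
  st <- s$states[s$states$character_id ==
                   s$characters$id[s$characters$label ==
                                     "Female metatibial spines presence"], ]
  expr_absent <- compose_presence_absence(c(hao("leg"),
                                            hao("metatibial_spine")),
                                          FALSE)
  expr_present <- compose_presence_absence(c(hao("leg"),
                                             hao("metatibial_spine")),
                                           TRUE)
  s <- annotate_state(s, st$id[st$label == "absent"], expr_absent)
  s <- annotate_state(s, st$id[st$label == "present"], expr_present)
  out <- study_propagate(s)
  lv <- s$otus$id[s$otus$taxon_name == "Szepligetella levipetiolata"]
  spec <- s$specimens$catalog_urn[s$specimens$otu_id == lv][[1]]
  got <- out$phenotype[out$specimen == spec]
  # both states denote the same specimens: no clash, two classes
  expect_setequal(got, paste0(st$id, "#phenotype"))
})

test_that("materialize is monotone on fuzzed graphs", {
  tbx <- tiny_tbox()
  set.seed(11)
  for (rep in seq_len(10)) {
    n <- 12L
    nodes <- sprintf("urn:n%d", seq_len(8))
    s <- sample(nodes, n, replace = TRUE)
    o <- sample(nodes, n, replace = TRUE)
    p <- sample(c(PR$part_of, PR$has_part, PR$bearer_of), n,
                replace = TRUE)
    full <- materialize(abox_graph(s, p, o), tbx)
    keep <- sample.int(n, n - 3L)
    partial <- materialize(abox_graph(s[keep], p[keep], o[keep]), tbx)
    key <- function(e) paste(e$s, e$p, e$o)
    expect_true(all(key(partial$edges) %in% key(full$edges)))
  }
})
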