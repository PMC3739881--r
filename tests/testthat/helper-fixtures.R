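# Shared fixtures, built once per test run.

fixture_env <- new.env(parent = emptyenv())

memo <- function(name, builder) {
  if (!exists(name, fixture_env)) {
    assign(name, builder(), envir = fixture_env)
  }
  get(name, fixture_env)
}

fx_study <- function() memo("study", function() evaniid_study())
fx_study_annotated <- function() {
  memo("study_annotated", function() evaniid_study(annotate = TRUE))
}
fx_ontology <- function() memo("ontology", function() mini_ontology())
fx_tbox <- function() memo("tbox", function() build_tbox(fx_ontology()))
fx_key <- function() memo("key", function() evaniid_key())
fx_labels <- function() memo("labels", function() {
  ontology_labels(fx_ontology())
})

cfg <- sempheno_config()
PR <- cfg$properties

hao <- function(x) paste0(cfg$prefixes[["hao"]], x)
pato <- function(x) paste0(cfg$prefixes[["pato"]], x)

# a tiny hand-built ontology for reasoner unit tests
tiny_ontology <- function() {
  memo("tiny_ontology", function() {
    classes <- do.call(rbind, lapply(
      c(hao(c("mesosoma", "ventro_lateral_region", "antenna", "eye",
              "wing")),
        pato(c("quality", "shape", "curved", "foveate"))), ont_class))
    props <- rbind(ont_property(PR$has_part, transitive = TRUE),
                   ont_property(PR$part_of, transitive = TRUE),
                   ont_property(PR$bearer_of),
                   ont_property(PR$denotes))
    axioms <- list(
      axiom_subclass(ce_named(pato("curved")), ce_named(pato("shape"))),
      axiom_subclass(ce_named(pato("shape")), ce_named(pato("quality"))),
      axiom_subclass(ce_named(pato("foveate")), ce_named(pato("quality"))),
      axiom_subclass(ce_named(hao("ventro_lateral_region")),
                     ce_some(PR$part_of, ce_named(hao("mesosoma"))))
    )
    ontology(classes, props, axioms)
  })
}

tiny_tbox <- function() memo("tiny_tbox", function() build_tbox(tiny_ontology()))

# canonical multiset of codings at the label level, for round-trip checks
coding_set <- function(s) {
  sort(paste(
    s$otus$taxon_name[match(s$codings$otu_id, s$otus$id)],
    s$characters$label[match(s$codings$character_id, s$characters$id)],
    s$states$label[match(s$codings$state_id, s$states$id)],
    sep = " | "
  ))
}
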