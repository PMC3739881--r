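test_that("generation is deterministic under a fixed seed", {
  a <- generate_study(synth_config(seed = 1))
  b <- generate_study(synth_config(seed = 1))
  expect_identical(write_matrix(a$study, "csv"),
                   write_matrix(b$study, "csv"))
  expect_identical(a$truth, b$truth)
  c <- generate_study(synth_config(seed = 2))
  expect_false(identical(write_matrix(a$study, "csv"),
                         write_matrix(c$study, "csv")))
})

test_that("generated studies satisfy the study invariants", {
  g <- generate_study(synth_config(seed = 5, polymorphism_rate = 0.4))
  expect_s3_class(g$study, "sempheno_study")
  expect_silent(sempheno:::validate_study(g$study))
  # every state annotated; every annotation classifies as constructed
  expect_identical(length(g$study$annotations), nrow(g$study$states))
  for (sid in names(g$study$annotations)) {
    a <- g$study$annotations[[sid]]
    ch <- g$study$states$character_id[g$study$states$id == sid]
    expect_identical(classify_template(a$definition),
                     unname(g$truth$templates[[ch]]))
  }
  # rules accompany exactly the relative-measurement states
  has_rule <- vapply(g$study$annotations, function(a) !is.null(a$rule),
                     logical(1))
  rel_states <- g$study$states$character_id %in%
    names(g$truth$templates)[g$truth$templates == "relative_measurement"]
  expect_identical(unname(has_rule[g$study$states$id]),
                   unname(rel_states))
})

test_that("requested template mixes are recovered exactly", {
  g <- generate_study(synth_config(seed = 12, n_qualitative = 7,
                                   n_presence = 4, n_count = 1,
                                   n_relative = 2))
  t <- template_tally(g$study)
  expect_identical(unname(t[c("qualitative", "presence_absence", "count",
                              "relative_measurement")]),
                   c(7L, 4L, 1L, 2L))
})

test_that("generator ground truth matches the inference pipeline", {
  for (seed in c(21, 22, 23, 24, 25)) {
    g <- generate_study(synth_config(seed = seed))
    got <- study_propagate(g$study)
    expect_identical(got$specimen, g$truth$propagation$specimen)
    expect_identical(got$phenotype, g$truth$propagation$phenotype)
    tbx <- build_tbox(g$ontology)
    ep <- g$truth$entity_partition
    for (i in seq_len(nrow(ep))) {
      expect_identical(
        partition_by_entity(g$study, ep$class[[i]], tbx)$count,
        ep$count[[i]], info = sprintf("seed %d, %s", seed, ep$class[[i]]))
    }
    qp <- g$truth$quality_partition
    for (i in seq_len(nrow(qp))) {
      expect_identical(
        partition_by_quality(g$study, qp$class[[i]], tbx)$count,
        qp$count[[i]], info = sprintf("seed %d, %s", seed, qp$class[[i]]))
    }
  }
})

test_that("infeasible configurations are rejected", {
  expect_error(synth_config(n_anatomy = 2), "anatomy")
  expect_error(synth_config(n_quality = 2), "quality")
  expect_error(synth_config(n_otus = 0), "OTU")
})
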