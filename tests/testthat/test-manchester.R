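test_that("parsing covers the expression forms used in annotations", {
  labs <- fx_labels()
  e <- parse_manchester("wing and bearer_of some curved", cfg$prefixes,
                        labs)
  expect_true(ce_equal(e, ce_and(ce_named(labs[["wing"]]),
                                 ce_some(PR$bearer_of,
                                         ce_named(labs[["curved"]])))))
  expect_true(ce_equal(parse_manchester("mesosoma", cfg$prefixes, labs),
                       ce_named(labs[["mesosoma"]])))
  nested <- paste0("has_part some (mesosoma and has_part some ",
                   "('ventro-lateral region' and bearer_of some foveate))")
  e2 <- parse_manchester(nested, cfg$prefixes, labs)
  expect_identical(e2$kind, "some")
  expect_identical(e2$filler$args[[2]]$filler$args[[1]]$iri,
                   labs[["ventro-lateral region"]])
  # canonical re-rendering round-trips the nested expression
  r <- render_manchester(e2, cfg$prefixes, labs)
  expect_true(ce_equal(parse_manchester(r, cfg$prefixes, labs), e2))
  expect_identical(
    render_manchester(parse_manchester(r, cfg$prefixes, labs),
                      cfg$prefixes, labs), r)
})

test_that("parser reports errors instead of guessing", {
  labs <- fx_labels()
  expect_error(parse_manchester("not wing", cfg$prefixes, labs),
               "unsupported construct 'not'")
  expect_error(parse_manchester("wing and", cfg$prefixes, labs),
               "Manchester syntax error")
  expect_error(parse_manchester("nosuch:thing", cfg$prefixes, labs),
               "unresolvable prefix")
  expect_error(parse_manchester("totally unknown words", cfg$prefixes,
                                labs),
               "cannot resolve")
  expect_error(parse_manchester("has_part exactly wing tooth",
                                cfg$prefixes, labs),
               "non-negative integer")
  expect_error(parse_manchester("", cfg$prefixes, labs), "non-empty")
})

test_that("rendering is canonical and quotes multiword labels", {
  labs <- fx_labels()
  e <- ce_and(ce_named(labs[["wing"]]),
              ce_some(PR$bearer_of, ce_named(labs[["curved"]])))
  expect_identical(render_manchester(e, cfg$prefixes, labs),
                   "wing and (bearer_of some curved)")
  expect_identical(
    render_manchester(ce_exactly(PR$has_part, 3,
                                 ce_named(labs[["tooth"]])),
                      cfg$prefixes, labs),
    "has_part exactly 3 tooth")
  e2 <- ce_some(PR$has_part, ce_named(labs[["ventro-lateral region"]]))
  expect_identical(render_manchester(e2, cfg$prefixes, labs),
                   "has_part some 'ventro-lateral region'")
  # unknown IRI without a prefix falls back to angle brackets
  e3 <- ce_named("urn:uuid:1234")
  expect_identical(render_manchester(e3, character(0)), "<urn:uuid:1234>")
})

test_that("parse o render is the identity on 1000 seeded random ASTs", {
  labs <- fx_labels()
  classes <- unname(labs[!grepl("_of$|_part$|towards|denotes|state|TU|magnitude",
                                names(labs))])
  props <- unname(c(PR$has_part, PR$part_of, PR$bearer_of, PR$towards))
  set.seed(2026)
  for (i in seq_len(1000)) {
    e <- random_expression(classes, props, max_depth = 4L)
    r <- render_manchester(e, cfg$prefixes, labs)
    expect_true(ce_equal(parse_manchester(r, cfg$prefixes, labs), e),
                info = sprintf("seeded case %d: %s", i, r))
    if (!ce_equal(parse_manchester(r, cfg$prefixes, labs), e)) break
  }
})

test_that("expression constructors enforce their invariants", {
  expect_error(ce_and(ce_named("urn:a")), "two operands")
  expect_error(ce_or(list(ce_named("urn:a"))), "two operands")
  expect_error(ce_exactly("urn:p", -1, ce_named("urn:a")),
               "non-negative")
  expect_error(ce_named(""), "IRI")
  expect_silent(ce_exactly("urn:p", 0, ce_named("urn:a")))
})
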