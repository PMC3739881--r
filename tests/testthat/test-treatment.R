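test_that("treatment sentences parse with sections and polymorphism", {
  txt <- paste("Testus specius", "", "Head.",
               "Mandibular teeth count: 3.",
               "Eye color: blue.", "", "Mesosoma.",
               "Female metatibial spines presence: absent; present.",
               sep = "\n")
  p <- parse_treatment(txt)
  expect_identical(p$taxon_name, "Testus specius")
  teeth <- p$codings[p$codings$character_label == "Mandibular teeth count", ]
  expect_identical(teeth$state_label, "3")
  expect_identical(teeth$body_region, "head")
  spines <- p$codings[p$codings$character_label ==
                        "Female metatibial spines presence", ]
  expect_setequal(spines$state_label, c("absent", "present"))
  expect_identical(unique(spines$body_region), "mesosoma")
})

test_that("malformed treatments are rejected", {
  expect_error(parse_treatment(""), "non-empty")
  expect_error(parse_treatment("Taxon\n\nHead.\nno colon here.\n"),
               "malformed sentence")
  expect_error(parse_treatment(
    "Taxon\n\nHead.\nEye color: blue.\nEye color: red.\n"),
    "duplicate character")
  expect_error(parse_treatment("Taxon\n\nstray text before a header\n"),
               "unknown section header")
})

test_that("the packaged treatments merge to one 43-character set", {
  s <- fx_study()
  expect_identical(nrow(s$characters), 43L)
  expect_identical(nrow(s$otus), 5L)
  cells <- unique(paste(s$codings$otu_id, s$codings$character_id))
  expect_identical(length(cells), 5L * 43L)
  # section structure as printed: 1 body + 13 head + 25 mesosoma + 4 metasoma
  expect_identical(as.integer(table(s$characters$body_region)[
    c("body", "head", "mesosoma", "metasoma")]),
    c(1L, 13L, 25L, 4L))
})

test_that("render o parse is the identity on fixture codings", {
  s <- fx_study()
  for (i in seq_len(nrow(s$otus))) {
    txt <- render_treatment(s, s$otus$id[[i]])
    p <- parse_treatment(txt)
    got <- sort(paste(p$codings$character_label, p$codings$state_label,
                      sep = " | "))
    want <- sort(paste(
      s$characters$label[match(
        s$codings$character_id[s$codings$otu_id == s$otus$id[[i]]],
        s$characters$id)],
      s$states$label[match(
        s$codings$state_id[s$codings$otu_id == s$otus$id[[i]]],
        s$states$id)], sep = " | "))
    expect_identical(got, want, info = s$otus$taxon_name[[i]])
  }
  # fixture content spot check
  ea <- render_treatment(s, "Evania appendigaster")
  expect_match(ea, "Eye color: blue.", fixed = TRUE)
  expect_error(render_treatment(s, "No such taxon"), "absent from study")
})

test_that("an OTU with no codings renders headers only", {
  s <- study(otus = data.frame(id = "urn:o1", taxon_name = "Empty taxon",
                               material = "", stringsAsFactors = FALSE))
  txt <- render_treatment(s, "Empty taxon")
  expect_match(txt, "Head\\.")
  expect_false(grepl(":", sub("^Empty taxon", "", txt)))
})

test_that("material examined parsing is lenient but captures localities", {
  s <- fx_study()
  dc <- s$specimens[s$specimens$otu_id ==
                      s$otus$id[s$otus$taxon_name ==
                                  "Szepligetella deercreeki"], ]
  expect_identical(nrow(dc), 5L)  # holotype + 4 paratypes
  expect_identical(sum(dc$role == "holotype"), 1L)
  expect_identical(sum(dc$role == "paratype"), 4L)
  expect_true(all(dc$subdivision == "New Caledonia"))
  expect_true("urn:catalog:NCSU:NCSU:49530" %in% dc$catalog_urn)  # range
  # unparseable museum-type strings are retained, not rejected
  lv <- s$specimens[s$specimens$otu_id ==
                      s$otus$id[s$otus$taxon_name ==
                                  "Szepligetella levipetiolata"], ]
  expect_true(any(grepl("B.M.TYPE", lv$catalog_urn, fixed = TRUE)))
})

test_that("occurrence filtering matches the published distributions", {
  s <- fx_study()
  nc <- filter_occurrence(s, "New Caledonia")
  expect_setequal(nc$taxon_name,
                  c("Evania appendigaster", "Szepligetella deercreeki",
                    "Szepligetella irwini", "Szepligetella levipetiolata"))
  expect_true("Szepligetella sericea" %in%
                filter_occurrence(s, "Hawaii")$taxon_name)
  expect_identical(nrow(filter_occurrence(s, "Atlantis")), 0L)
  # case-insensitive substring
  expect_identical(nrow(filter_occurrence(s, "new caledonia")), 4L)
})
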