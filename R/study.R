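# Study: character matrix (characters, states, OTUs, codings), specimens,
# phenotype annotations and prefix map. Matrix elements are minted IRIs
# under a configurable base namespace so every data element has its own
# global identifier.

body_regions <- c("body", "head", "mesosoma", "metasoma")
template_categories <- c("qualitative", "presence_absence", "count",
                         "relative_measurement", "nonstandard", "unannotated")

empty_study_tables <- function() {
  list(
    characters = data.frame(id = character(0), label = character(0),
                            body_region = character(0),
                            template_category = character(0),
                            stringsAsFactors = FALSE),
    states = data.frame(id = character(0), character_id = character(0),
                        label = character(0), stringsAsFactors = FALSE),
    otus = data.frame(id = character(0), taxon_name = character(0),
                      material = character(0), stringsAsFactors = FALSE),
    codings = data.frame(otu_id = character(0), character_id = character(0),
                         state_id = character(0), stringsAsFactors = FALSE),
    specimens = data.frame(catalog_urn = character(0), otu_id = character(0),
                           repository_coden = character(0),
                           country = character(0), subdivision = character(0),
                           role = character(0), sex = character(0),
                           verbatim = character(0), stringsAsFactors = FALSE)
  )
}

#' Assemble a study
#'
#' @param characters data.frame (id, label, body_region, template_category).
#' @param states data.frame (id, character_id, label).
#' @param otus data.frame (id, taxon_name, material).
#' @param codings data.frame (otu_id, character_id, state_id); several rows
#'   for one (otu, character) encode polymorphism.
#' @param specimens data.frame (catalog_urn, otu_id, repository_coden,
#'   country, subdivision, role, sex, verbatim).
#' @param annotations named list keyed by state id; each element a
#'   phenotype record (see [annotate_state()]).
#' @param prefixes prefix map.
#' @param metadata list (title, source).
#' @return an object of class `sempheno_study`.
#' @export
study <- function(characters = NULL, states = NULL, otus = NULL,
                  codings = NULL, specimens = NULL, annotations = list(),
                  prefixes = sempheno_prefixes(), metadata = list()) {
  e <- empty_study_tables()
  s <- structure(
    list(characters = characters %||% e$characters,
         states = states %||% e$states,
         otus = otus %||% e$otus,
         codings = codings %||% e$codings,
         specimens = specimens %||% e$specimens,
         annotations = annotations, prefixes = prefixes,
         metadata = metadata),
    class = "sempheno_study"
  )
  validate_study(s)
  s
}

validate_study <- function(s) {
  assert_that(!anyDuplicated(s$characters$id), "duplicate character ids")
  assert_that(!anyDuplicated(s$characters$label),
              "character labels must be unique within a study")
  assert_that(!anyDuplicated(s$states$id), "duplicate state ids")
  assert_that(!anyDuplicated(paste(s$states$character_id, s$states$label)),
              "state labels must be unique within their character")
  assert_that(!anyDuplicated(s$otus$id), "duplicate OTU ids")
  assert_that(all(nzchar(s$otus$taxon_name)), "OTU taxon names required")
  assert_that(!anyDuplicated(s$specimens$catalog_urn),
              "specimen catalog URNs must be unique")
  assert_that(all(s$codings$otu_id %in% s$otus$id),
              "codings reference unknown OTUs")
  assert_that(all(s$codings$character_id %in% s$characters$id),
              "codings reference unknown characters")
  assert_that(all(s$codings$state_id %in% s$states$id),
              "codings reference unknown states")
  assert_that(all(s$states$character_id %in% s$characters$id),
              "states reference unknown characters")
  assert_that(all(s$specimens$otu_id %in% s$otus$id),
              "specimens reference unknown OTUs")
  assert_that(!anyDuplicated(paste(s$codings$otu_id, s$codings$character_id,
                                   s$codings$state_id)),
              "duplicate coding rows")
  assert_that(all(s$characters$body_region %in% body_regions),
              "unknown body region")
  assert_that(all(s$characters$template_category %in% template_categories),
              "unknown template category")
  assert_that(all(names(s$annotations) %in% s$states$id),
              "annotations reference unknown states")
  invisible(s)
}

#' @export
print.sempheno_study <- function(x, ...) {
  cat(sprintf(paste0("<study> %d OTUs x %d characters (%d states, ",
                     "%d codings, %d specimens, %d annotated states)\n"),
              nrow(x$otus), nrow(x$characters), nrow(x$states),
              nrow(x$codings), nrow(x$specimens), length(x$annotations)))
  invisible(x)
}

study_state_labels <- function(s, otu_id, character_id) {
  st <- s$codings$state_id[s$codings$otu_id == otu_id &
                             s$codings$character_id == character_id]
  s$states$label[match(st, s$states$id)]
}

otu_by_name <- function(s, taxon_name) {
  i <- match(taxon_name, s$otus$taxon_name)
  assert_that(!is.na(i), sprintf("OTU '%s' absent from study", taxon_name))
  s$otus[i, , drop = FALSE]
}

#' ABox graph of a study (CDAO-role edges)
#'
#' Builds the asserted edges of the study's instance graph: coding cells
#' linked to their states (`has_state`, with the inverse `state_of`
#' asserted explicitly so the denotes chain can fire) and to their OTUs
#' (`belongs_to_TU`), and `denotes` edges from each OTU to each of its
#' specimens (one edge per member specimen of the denoted set).
#'
#' @param s a study.
#' @param config a [sempheno_config()].
#' @return an [abox_graph()].
#' @export
study_abox <- function(s, config = sempheno_config()) {
  pr <- config$properties
  cell <- paste(s$codings$otu_id, s$codings$character_id)
  cell_id <- if (nrow(s$codings)) {
    paste0("_:coding_", match(cell, unique(cell)))
  } else {
    character(0)
  }
  ss <- pp <- oo <- character(0)
  add <- function(a, b, c) {
    ss <<- c(ss, a); pp <<- c(pp, b); oo <<- c(oo, c)
  }
  for (i in seq_len(nrow(s$codings))) {
    add(cell_id[[i]], pr$has_state, s$codings$state_id[[i]])
    add(s$codings$state_id[[i]], pr$state_of, cell_id[[i]])
    add(cell_id[[i]], pr$belongs_to_tu, s$codings$otu_id[[i]])
  }
  for (i in seq_len(nrow(s$specimens))) {
    add(s$specimens$otu_id[[i]], pr$denotes, s$specimens$catalog_urn[[i]])
  }
  assertions <- lapply(names(s$annotations), function(st) {
    list(individual = st,
         expr = ce_only(pr$denotes, ce_named(s$annotations[[st]]$phenotype)))
  })
  abox_graph(ss, pp, oo, assertions = assertions)
}

#' Run the denotes chain and propagate phenotypes for a whole study
#'
#' Convenience wrapper: builds the study ABox, materializes the configured
#' chains and propagates annotated states' phenotype classes to specimens.
#'
#' @param s an annotated study.
#' @param config a [sempheno_config()].
#' @param tbox optional TBox for entailed superclasses.
#' @return see [propagate_phenotypes()].
#' @export
study_propagate <- function(s, config = sempheno_config(), tbox = NULL) {
  chain_props <- data.frame(
    iri = unique(c(unlist(config$chains), names(config$chains),
                   unlist(config$properties[c("has_state", "denotes")]))),
    stringsAsFactors = FALSE
  )
  chain_props$label <- vapply(chain_props$iri, local_name, character(1))
  chain_props$transitive <- FALSE
  chain_ont <- ontology(properties = chain_props, chains = config$chains,
                        prefixes = config$prefixes)
  chain_tbox <- build_tbox(chain_ont)
  g <- materialize(study_abox(s, config), chain_tbox)
  ann <- data.frame(
    state = names(s$annotations),
    phenotype = vapply(s$annotations, function(a) a$phenotype, character(1)),
    stringsAsFactors = FALSE
  )
  propagate_phenotypes(g, ann, tbox = tbox,
                       denotes = config$properties$denotes)
}
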