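# Packaged fixtures: the five printed ensign-wasp treatments, the
# identification key, a synthetic mini ontology standing in for
# HAO/PATO/BSPO content, and a demonstrative annotation table.
#
# The key fixture encodes the couplet reading consistent with the
# companion descriptions (each couplet's two leads are the paired
# alternatives); two typeset conflicts between key and descriptions are
# resolved in favour of the descriptions, and the missing terminal leaf
# label is restored (see the methods vignette).

fixture_path <- function(...) {
  p <- system.file("extdata", ..., package = "sempheno", mustWork = FALSE)
  if (!nzchar(p)) {
    # during development, resolve against the source tree
    p <- file.path("inst", "extdata", ...)
  }
  assert_that(file.exists(p), sprintf("fixture not found: %s",
                                      file.path(...)))
  p
}

#' Paths or texts of the five packaged treatments
#'
#' @param as_text return the file contents rather than paths.
#' @return named character vector in publication order.
#' @export
evaniid_treatments <- function(as_text = TRUE) {
  files <- c(
    "Evania appendigaster" = "evania_appendigaster.txt",
    "Szepligetella deercreeki" = "szepligetella_deercreeki.txt",
    "Szepligetella irwini" = "szepligetella_irwini.txt",
    "Szepligetella levipetiolata" = "szepligetella_levipetiolata.txt",
    "Szepligetella sericea" = "szepligetella_sericea.txt"
  )
  paths <- vapply(files, function(f) fixture_path("treatments", f),
                  character(1))
  if (!as_text) return(paths)
  vapply(paths, function(p) {
    paste(readLines(p, encoding = "UTF-8", warn = FALSE), collapse = "\n")
  }, character(1))
}

#' The packaged five-species study
#'
#' Parses the five treatments into one study: 43 characters merged by
#' exact label, a complete 5 x 43 matrix (two polymorphic cells) and the
#' specimen records extracted from the Material Examined sections.
#'
#' @param annotate when TRUE, apply the demonstrative EQ annotation table
#'   ([evaniid_annotations()]) against the mini ontology.
#' @param config a [sempheno_config()].
#' @return a [study()].
#' @export
evaniid_study <- function(annotate = FALSE, config = sempheno_config()) {
  s <- build_study(evaniid_treatments(), prefixes = config$prefixes,
                   metadata = list(title = "Ensign wasps of New Caledonia"))
  if (annotate) {
    s <- annotate_states_table(s, evaniid_annotations(),
                               config = config,
                               ontology = mini_ontology())
  }
  s
}

#' The packaged identification key
#'
#' @return a [key()] over the five packaged species.
#' @export
evaniid_key <- function() {
  read_key(fixture_path("key_new_caledonia.json"))
}

#' The packaged mini ontology (synthetic HAO/PATO/BSPO stand-in)
#'
#' Anatomy classes under a transitive part_of hierarchy, qualities under
#' shape/size/color/texture, a few spatial-region classes, the model
#' properties and the denotes property chain. The content is synthetic:
#' it emulates the structure of the real ontologies at fixture scale and
#' carries none of their terms' definitions.
#'
#' @return an [ontology()].
#' @export
mini_ontology <- function() {
  load_rdf(fixture_path("ontology", "mini_ontology.ttl"), "turtle")
}

#' The demonstrative annotation table
#'
#' EQ expressions (Manchester subset) for a subset of the packaged
#' study's states, written against the mini ontology's labels.
#'
#' @return data.frame with columns state, expression.
#' @export
evaniid_annotations <- function() {
  utils::read.delim(fixture_path("annotations_demo.tsv"),
                    colClasses = "character", check.names = FALSE)
}

#' Path of the packaged template-category override table
#'
#' Ships empty: reconciling the name-based template categories against
#' the study's full published annotation set requires that external data
#' set, and the overrides belong there when available.
#'
#' @return file path.
#' @export
category_overrides_path <- function() {
  fixture_path("category_overrides.csv")
}
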