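# Natural-language treatment parsing and rendering.
#
# A treatment is plain text: the taxon name, then sections headed
# "Body length." / "Head." / "Mesosoma." / "Metasoma." containing
# "Character name: state[; state2]." sentences (two states = polymorphism),
# and optionally a lenient "Material Examined." section.

section_headers <- c("Body length" = "body", "Head" = "head",
                     "Mesosoma" = "mesosoma", "Metasoma" = "metasoma")

#' Parse a treatment text
#'
#' @param text treatment text (a single string or character vector of
#'   lines).
#' @return a list with `taxon_name`, `codings` (data.frame character_label,
#'   body_region, state_label with one row per state; polymorphic sentences
#'   contribute several rows), `characters` (label, body_region),
#'   `states` (character_label, state_label) and `material` (verbatim
#'   Material Examined text, possibly empty).
#' @export
parse_treatment <- function(text) {
  if (length(text) > 1L) text <- paste(text, collapse = "\n")
  assert_that(is_string(text) && nzchar(trimws(text)),
              "treatment text must be non-empty")
  lines <- strsplit(text, "\n", fixed = TRUE)[[1]]
  lines <- trimws(lines)
  lines <- lines[nzchar(lines)]
  taxon <- lines[[1]]
  assert_that(!grepl(":", taxon, fixed = TRUE),
              "first line must be the taxon name")
  region <- NA_character_
  material_lines <- character(0)
  in_material <- FALSE
  rows <- list()
  seen <- character(0)
  for (ln in lines[-1]) {
    hdr <- sub("\\.$", "", ln)
    if (hdr %in% names(section_headers)) {
      region <- section_headers[[hdr]]
      in_material <- FALSE
      next
    }
    if (identical(hdr, "Material Examined")) {
      in_material <- TRUE
      next
    }
    if (in_material) {
      material_lines <- c(material_lines, ln)
      next
    }
    if (is.na(region)) {
      stop(sprintf("unknown section header or stray text: '%s'", ln),
           call. = FALSE)
    }
    for (sentence in split_sentences(ln)) {
      m <- regmatches(sentence, regexec("^(.+?): (.+)\\.$", sentence))[[1]]
      if (length(m) != 3L) {
        stop(sprintf("malformed sentence (expected 'Name: state.'): '%s'",
                     sentence), call. = FALSE)
      }
      label <- m[[2]]
      if (label %in% seen) {
        stop(sprintf("duplicate character '%s' within one treatment", label),
             call. = FALSE)
      }
      seen <- c(seen, label)
      states <- strsplit(m[[3]], "; ", fixed = TRUE)[[1]]
      rows[[length(rows) + 1L]] <- data.frame(
        character_label = label, body_region = region, state_label = states,
        stringsAsFactors = FALSE
      )
    }
  }
  codings <- if (length(rows)) do.call(rbind, rows) else
    data.frame(character_label = character(0), body_region = character(0),
               state_label = character(0), stringsAsFactors = FALSE)
  characters <- unique(codings[c("character_label", "body_region")])
  rownames(characters) <- NULL
  states <- unique(codings[c("character_label", "state_label")])
  rownames(states) <- NULL
  list(taxon_name = taxon, codings = codings, characters = characters,
       states = states,
       material = paste(material_lines, collapse = " "))
}

# Split a paragraph into "Name: state." sentences: a period followed by
# whitespace and an upper-case letter or digit ends a sentence. State
# labels may contain internal periods ("0.5 of compound eye height").
split_sentences <- function(x) {
  out <- strsplit(x, "(?<=\\.)\\s+(?=[A-Z0-9'(])", perl = TRUE)[[1]]
  trimws(out)
}

#' Render a treatment for one OTU
#'
#' Deterministic inverse of [parse_treatment()]: sections in the order
#' Body length, Head, Mesosoma, Metasoma; characters in stored study
#' order; polymorphic states joined by `"; "`; one sentence per line. An
#' OTU with no codings renders headers only.
#'
#' @param s a study.
#' @param otu an OTU taxon name or id.
#' @return the treatment text as a single string.
#' @export
render_treatment <- function(s, otu) {
  i <- match(otu, s$otus$id)
  if (is.na(i)) i <- match(otu, s$otus$taxon_name)
  assert_that(!is.na(i), sprintf("OTU '%s' absent from study", otu))
  otu_id <- s$otus$id[[i]]
  out <- c(s$otus$taxon_name[[i]], "")
  for (hdr in names(section_headers)) {
    region <- section_headers[[hdr]]
    chars <- s$characters[s$characters$body_region == region, , drop = FALSE]
    out <- c(out, paste0(hdr, "."))
    for (j in seq_len(nrow(chars))) {
      labs <- study_state_labels(s, otu_id, chars$id[[j]])
      if (!length(labs)) next
      out <- c(out, sprintf("%s: %s.", chars$label[[j]],
                            paste(labs, collapse = "; ")))
    }
    out <- c(out, "")
  }
  mat <- s$otus$material[[i]]
  if (!is.na(mat) && nzchar(mat)) {
    out <- c(out, "Material Examined.", mat, "")
  }
  paste(out, collapse = "\n")
}

#' Build a study from treatment texts
#'
#' Characters are merged across treatments by exact label (the treatments
#' are machine-rendered and label-stable); state labels are scoped to their
#' character. IRIs for characters, states and OTUs are minted under
#' `base_iri`. Specimens are extracted from each Material Examined section
#' with the lenient grammar of [parse_material()].
#'
#' @param texts character vector of treatment texts (or a list).
#' @param base_iri namespace for minted matrix-element IRIs.
#' @param prefixes prefix map stored on the study.
#' @param metadata study metadata list.
#' @return a [study()].
#' @export
build_study <- function(texts, base_iri = sempheno_prefixes()[["ex"]],
                        prefixes = sempheno_prefixes(), metadata = list()) {
  parsed <- lapply(texts, parse_treatment)
  char_labels <- character(0)
  char_region <- character(0)
  for (p in parsed) {
    for (j in seq_len(nrow(p$characters))) {
      lab <- p$characters$character_label[[j]]
      reg <- p$characters$body_region[[j]]
      k <- match(lab, char_labels)
      if (is.na(k)) {
        char_labels <- c(char_labels, lab)
        char_region <- c(char_region, reg)
      } else {
        assert_that(identical(char_region[[k]], reg),
                    sprintf("character '%s' appears under two regions", lab))
      }
    }
  }
  characters <- data.frame(
    id = sprintf("%scharacter/%d", base_iri, seq_along(char_labels)),
    label = char_labels, body_region = char_region,
    template_category = classify_character_label(char_labels),
    stringsAsFactors = FALSE
  )
  state_key <- character(0)
  state_char <- character(0)
  state_lab <- character(0)
  for (p in parsed) {
    for (j in seq_len(nrow(p$states))) {
      key <- paste0(p$states$character_label[[j]], "\r",
                    p$states$state_label[[j]])
      if (!key %in% state_key) {
        state_key <- c(state_key, key)
        state_char <- c(state_char, p$states$character_label[[j]])
        state_lab <- c(state_lab, p$states$state_label[[j]])
      }
    }
  }
  states <- data.frame(
    id = sprintf("%sstate/%d", base_iri, seq_along(state_key)),
    character_id = characters$id[match(state_char, characters$label)],
    label = state_lab, stringsAsFactors = FALSE
  )
  otus <- data.frame(
    id = sprintf("%sotu/%d", base_iri, seq_along(parsed)),
    taxon_name = vapply(parsed, `[[`, character(1), "taxon_name"),
    material = vapply(parsed, `[[`, character(1), "material"),
    stringsAsFactors = FALSE
  )
  codings <- list()
  specimens <- list()
  for (i in seq_along(parsed)) {
    p <- parsed[[i]]
    if (nrow(p$codings)) {
      key <- paste0(p$codings$character_label, "\r", p$codings$state_label)
      codings[[length(codings) + 1L]] <- data.frame(
        otu_id = otus$id[[i]],
        character_id = characters$id[match(p$codings$character_label,
                                           characters$label)],
        state_id = states$id[match(key, state_key)],
        stringsAsFactors = FALSE
      )
    }
    if (nzchar(p$material)) {
      sp <- parse_material(p$material, otus$id[[i]])
      if (nrow(sp)) specimens[[length(specimens) + 1L]] <- sp
    }
  }
  codings <- if (length(codings)) do.call(rbind, codings) else NULL
  specimens <- if (length(specimens)) {
    sp <- do.call(rbind, specimens)
    sp[!duplicated(sp$catalog_urn), , drop = FALSE]
  } else NULL
  study(characters = characters, states = states, otus = otus,
        codings = codings, specimens = specimens, prefixes = prefixes,
        metadata = metadata)
}

# Name-based template heuristic; reconciliation against a supplementary
# annotation set happens through the category-overrides table (see
# template_tally). "Body length" is stored unannotated by default.
classify_character_label <- function(labels) {
  vapply(labels, function(lab) {
    if (identical(lab, "Body length")) return("unannotated")
    if (grepl(" presence$", lab)) return("presence_absence")
    if (grepl(" count$", lab)) return("count")
    if (grepl("length( versus | )", lab) || grepl(" length$", lab)) {
      return("relative_measurement")
    }
    "qualitative"
  }, character(1), USE.NAMES = FALSE)
}
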