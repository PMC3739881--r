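# Lenient "Material Examined" grammar:
#   [Role [sex]:] COUNTRY: region[: subregion]: counts. catalog numbers
#   (coden); ...
# Unparseable fragments are retained verbatim on the specimen rows rather
# than rejected; the occurrence filter matches against both the structured
# locality and the verbatim chunk, so records like
# "FRANCE: New Caledonia, B.M.TYPE.HYM. 3a.287 (BMNH)" still count.

#' Parse a Material Examined section into specimen rows
#'
#' @param text the section text.
#' @param otu_id the owning OTU's IRI.
#' @return data.frame with the specimen columns of [study()].
#' @export
parse_material <- function(text, otu_id) {
  chunks <- strsplit(text, "(?<=\\.)\\s+(?=[A-Z{])", perl = TRUE)[[1]]
  chunks <- trimws(chunks)
  chunks <- chunks[nzchar(chunks)]
  country <- subdivision <- ""
  role <- "other"
  sex <- "unknown"
  rows <- list()
  for (chunk in chunks) {
    if (grepl("^(Holotype|Paratype)", chunk)) role <- tolower(
      sub("^(Holotype|Paratype).*", "\\1", chunk))
    else if (grepl("Syntype|syntype", chunk)) role <- "syntype"
    else if (grepl("^Other material", chunk)) role <- "other"
    if (grepl("\\bfemale", chunk) && !grepl("\\bmale", sub("female", "",
                                                           chunk))) {
      sex <- "female"
    } else if (grepl("\\bmale", chunk) && !grepl("\\bfemale", chunk)) {
      sex <- "male"
    } else if (grepl("male", chunk) && grepl("female", chunk)) {
      sex <- "unknown"
    }
    m <- regexec("\\b([A-Z][A-Z]+(?: [A-Z][A-Z]+)*): ?(.*)$", chunk)
    m <- regmatches(chunk, m)[[1]]
    if (length(m) == 3L && !m[[2]] %in% c("NCSU", "LINN")) {
      country <- m[[2]]
      tail <- m[[3]]
      segs <- strsplit(tail, ": ", fixed = TRUE)[[1]]
      subdivision <- if (length(segs) > 1L) {
        paste(segs[-length(segs)], collapse = ": ")
      } else {
        ""
      }
    }
    for (urn_coden in extract_catalog(chunk)) {
      rows[[length(rows) + 1L]] <- data.frame(
        catalog_urn = urn_coden[[1]], otu_id = otu_id,
        repository_coden = urn_coden[[2]], country = country,
        subdivision = subdivision, role = role, sex = sex,
        verbatim = chunk, stringsAsFactors = FALSE
      )
    }
  }
  if (!length(rows)) {
    return(empty_study_tables()$specimens)
  }
  out <- do.call(rbind, rows)
  out[!duplicated(out$catalog_urn), , drop = FALSE]
}

# Catalog-number extraction: "NCSU 12345", "LINN 2719", bare 4-6 digit
# numbers and en-dash ranges, museum-type strings like
# "B.M.TYPE.HYM. 3a.287". The repository coden is the nearest following
# "(CODEN)" group.
extract_catalog <- function(chunk) {
  out <- list()
  # positions of coden groups
  coden_g <- gregexpr("\\(([A-Z]{2,6})\\)", chunk)
  coden_m <- coden_g[[1]]
  codens <- if (coden_m[[1]] > 0L) {
    data.frame(pos = as.integer(coden_m),
               coden = gsub("[()]", "", regmatches(chunk, coden_g)[[1]]),
               stringsAsFactors = FALSE)
  } else {
    data.frame(pos = integer(0), coden = character(0))
  }
  coden_at <- function(pos) {
    after <- codens$coden[codens$pos > pos]
    if (length(after)) after[[1]] else
      if (nrow(codens)) codens$coden[[nrow(codens)]] else ""
  }
  add <- function(urn, coden) out[[length(out) + 1L]] <<- list(urn, coden)
  # museum type strings
  tg <- gregexpr("B\\.M\\.TYPE\\.HYM\\. ?[0-9A-Za-z.]+[0-9A-Za-z]", chunk)
  tm <- tg[[1]]
  if (tm[[1]] > 0L) {
    tvals <- regmatches(chunk, tg)[[1]]
    for (k in seq_along(tvals)) {
      add(paste0("urn:catalog:", coden_at(tm[[k]]), ":",
                 gsub(" ", "", tvals[[k]])), coden_at(tm[[k]]))
    }
  }
  # LINN numbers
  lg <- gregexpr("LINN ([0-9]{3,5})", chunk)
  lm <- lg[[1]]
  if (lm[[1]] > 0L) {
    lvals <- regmatches(chunk, lg)[[1]]
    for (k in seq_along(lvals)) {
      v <- sub("LINN ", "", lvals[[k]])
      add(paste0("urn:catalog:", coden_at(lm[[k]]), ":LINN:", v),
          coden_at(lm[[k]]))
    }
  }
  # NCSU-style numbers and ranges (with or without the NCSU prefix)
  masked <- gsub("B\\.M\\.TYPE\\.HYM\\. ?[0-9A-Za-z.]+[0-9A-Za-z]", "",
                 chunk)
  masked <- gsub("LINN [0-9]+", "", masked)
  ng <- gregexpr("[0-9]{4,6}(–[0-9]{4,6})?", masked)
  nm <- ng[[1]]
  if (nm[[1]] > 0L) {
    vals <- regmatches(masked, ng)[[1]]
    for (k in seq_along(vals)) {
      coden <- coden_at(nm[[k]])
      parts <- strsplit(vals[[k]], "–", fixed = TRUE)[[1]]
      nums <- if (length(parts) == 2L) {
        seq(as.integer(parts[[1]]), as.integer(parts[[2]]))
      } else {
        as.integer(parts[[1]])
      }
      for (n in nums) {
        add(sprintf("urn:catalog:NCSU:NCSU:%d", n), coden)
      }
    }
  }
  out
}

#' Filter OTUs by occurrence locality
#'
#' Returns the OTUs having at least one specimen whose locality matches
#' the query token (case-insensitive substring over country, subdivision
#' and the verbatim record fragment).
#'
#' @param s a study.
#' @param country_or_region query token, e.g. `"New Caledonia"`.
#' @return the matching rows of the study's `otus` table (possibly empty).
#' @export
filter_occurrence <- function(s, country_or_region) {
  assert_that(is_string(country_or_region), "query token required")
  hay <- tolower(paste(s$specimens$country, s$specimens$subdivision,
                       s$specimens$verbatim))
  hit <- grepl(tolower(country_or_region), hay, fixed = TRUE)
  ids <- unique(s$specimens$otu_id[hit])
  out <- s$otus[s$otus$id %in% ids, , drop = FALSE]
  rownames(out) <- NULL
  out
}
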