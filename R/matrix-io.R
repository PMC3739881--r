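# Matrix interchange: NEXUS CHARACTERS block (standard data, per-character
# state symbols, polymorphism as {..}) and CSV (one row per OTU, states
# joined by "; "). Both re-readable losslessly at the coding level. The
# NEXUS dialect is written by hand: the installed phylogenetics packages
# do not round-trip polymorphic standard-category matrices.

nexus_symbols <- strsplit("0123456789ABCDEFGHIJKLMNOPQRSTUV", "")[[1]]

nexus_quote <- function(x) paste0("'", gsub("'", "''", x), "'")

#' Write a study matrix
#'
#' @param s a study.
#' @param format `"nexus"` or `"csv"`.
#' @param path optional output file.
#' @return the serialized text (invisibly when `path` is given).
#' @export
write_matrix <- function(s, format = c("nexus", "csv"), path = NULL) {
  format <- match.arg(format)
  txt <- if (format == "nexus") write_matrix_nexus(s) else
    write_matrix_csv(s)
  if (!is.null(path)) {
    writeLines(txt, path, sep = "", useBytes = TRUE)
    return(invisible(txt))
  }
  txt
}

write_matrix_nexus <- function(s) {
  ntax <- nrow(s$otus)
  nchar_ <- nrow(s$characters)
  over <- vapply(s$characters$id, function(ch) {
    sum(s$states$character_id == ch) > length(nexus_symbols)
  }, logical(1))
  if (any(over)) {
    stop(sprintf("character '%s' has more than %d states (NEXUS symbol limit)",
                 s$characters$label[over][[1]], length(nexus_symbols)),
         call. = FALSE)
  }
  lab_lines <- vapply(seq_len(nchar_), function(j) {
    ch <- s$characters$id[[j]]
    st <- s$states[s$states$character_id == ch, , drop = FALSE]
    sprintf("    %d %s / %s", j, nexus_quote(s$characters$label[[j]]),
            paste(nexus_quote(st$label), collapse = " "))
  }, character(1))
  rows <- vapply(seq_len(ntax), function(i) {
    otu <- s$otus$id[[i]]
    cells <- vapply(seq_len(nchar_), function(j) {
      ch <- s$characters$id[[j]]
      st <- s$states[s$states$character_id == ch, , drop = FALSE]
      coded <- s$codings$state_id[s$codings$otu_id == otu &
                                    s$codings$character_id == ch]
      if (!length(coded)) return("?")
      syms <- nexus_symbols[match(coded, st$id)]
      syms <- sort_c(syms)
      if (length(syms) == 1L) syms else
        paste0("{", paste(syms, collapse = ""), "}")
    }, character(1))
    sprintf("    %s %s", nexus_quote(s$otus$taxon_name[[i]]),
            paste(cells, collapse = ""))
  }, character(1))
  paste0(paste(c(
    "#NEXUS",
    "BEGIN TAXA;",
    sprintf("  DIMENSIONS NTAX=%d;", ntax),
    sprintf("  TAXLABELS %s;",
            paste(nexus_quote(s$otus$taxon_name), collapse = " ")),
    "END;",
    "BEGIN CHARACTERS;",
    sprintf("  DIMENSIONS NCHAR=%d;", nchar_),
    sprintf("  FORMAT DATATYPE=STANDARD SYMBOLS=\"%s\" MISSING=? GAP=-;",
            paste(nexus_symbols, collapse = "")),
    "  CHARSTATELABELS",
    paste(lab_lines, collapse = ",\n"),
    "  ;",
    "  MATRIX",
    rows,
    "  ;",
    "END;"
  ), collapse = "\n"), "\n")
}

csv_quote <- function(x) paste0("\"", gsub("\"", "\"\"", x), "\"")

write_matrix_csv <- function(s) {
  header <- paste(csv_quote(c("taxon", s$characters$label)), collapse = ",")
  rows <- vapply(seq_len(nrow(s$otus)), function(i) {
    otu <- s$otus$id[[i]]
    cells <- vapply(s$characters$id, function(ch) {
      paste(study_state_labels(s, otu, ch), collapse = "; ")
    }, character(1))
    paste(csv_quote(c(s$otus$taxon_name[[i]], cells)), collapse = ",")
  }, character(1))
  paste0(paste(c(header, rows), collapse = "\n"), "\n")
}

#' Read a study matrix written by [write_matrix()]
#'
#' Reconstructs the coding-level content (characters, states, OTUs,
#' codings); specimen and annotation data are not part of either format.
#'
#' @param x text or path to a file.
#' @param format `"nexus"` or `"csv"`.
#' @param base_iri namespace for re-minted IRIs.
#' @return a [study()].
#' @export
read_matrix <- function(x, format = c("nexus", "csv"),
                        base_iri = sempheno_prefixes()[["ex"]]) {
  format <- match.arg(format)
  if (length(x) == 1L && !grepl("\n", x) && file.exists(x)) {
    x <- paste(readLines(x, encoding = "UTF-8", warn = FALSE),
               collapse = "\n")
  }
  if (format == "csv") read_matrix_csv(x, base_iri) else
    read_matrix_nexus(x, base_iri)
}

read_matrix_csv <- function(text, base_iri) {
  df <- utils::read.csv(text = text, check.names = FALSE,
                        colClasses = "character")
  labels <- colnames(df)[-1]
  chars <- data.frame(
    id = sprintf("%scharacter/%d", base_iri, seq_along(labels)),
    label = labels, body_region = "body",
    template_category = "unannotated", stringsAsFactors = FALSE
  )
  otus <- data.frame(
    id = sprintf("%sotu/%d", base_iri, seq_len(nrow(df))),
    taxon_name = df[[1]], material = "", stringsAsFactors = FALSE
  )
  states <- list()
  codings <- list()
  for (j in seq_along(labels)) {
    seenj <- character(0)
    for (i in seq_len(nrow(df))) {
      cell <- df[[j + 1L]][[i]]
      if (!nzchar(cell)) next
      for (lab in strsplit(cell, "; ", fixed = TRUE)[[1]]) {
        if (!lab %in% seenj) seenj <- c(seenj, lab)
        codings[[length(codings) + 1L]] <- data.frame(
          otu_id = otus$id[[i]], character_id = chars$id[[j]],
          state_label = lab, stringsAsFactors = FALSE
        )
      }
    }
    if (length(seenj)) {
      states[[length(states) + 1L]] <- data.frame(
        character_id = chars$id[[j]], label = seenj,
        stringsAsFactors = FALSE
      )
    }
  }
  assemble_matrix_study(chars, states, otus, codings, base_iri)
}

assemble_matrix_study <- function(chars, states, otus, codings, base_iri) {
  states <- if (length(states)) do.call(rbind, states) else
    data.frame(character_id = character(0), label = character(0),
               stringsAsFactors = FALSE)
  states$id <- sprintf("%sstate/%d", base_iri, seq_len(nrow(states)))
  skey <- paste0(states$character_id, "\r", states$label)
  codings <- if (length(codings)) {
    cd <- do.call(rbind, codings)
    data.frame(otu_id = cd$otu_id, character_id = cd$character_id,
               state_id = states$id[match(paste0(cd$character_id, "\r",
                                                 cd$state_label), skey)],
               stringsAsFactors = FALSE)
  } else NULL
  study(characters = chars, states = states[c("id", "character_id",
                                              "label")],
        otus = otus, codings = codings)
}

nexus_tokens <- function(text) {
  n <- nchar(text)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "'") {
      j <- i + 1L
      buf <- ""
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "'") {
          if (substr(text, j + 1L, j + 1L) == "'") {
            buf <- paste0(buf, "'"); j <- j + 2L; next
          }
          break
        }
        buf <- paste0(buf, cj); j <- j + 1L
      }
      toks <- c(toks, paste0("'", buf))
      i <- j + 1L
      next
    }
    if (ch %in% c(";", ",", "/", "{", "}", "=")) {
      toks <- c(toks, ch); i <- i + 1L; next
    }
    m <- regexpr("^[^\\s;,/{}=']+", substr(text, i, n), perl = TRUE)
    tok <- regmatches(substr(text, i, n), m)
    toks <- c(toks, tok)
    i <- i + nchar(tok)
  }
  toks
}

read_matrix_nexus <- function(text, base_iri) {
  toks <- nexus_tokens(text)
  unq <- function(t) sub("^'", "", t)
  is_quoted <- function(t) startsWith(t, "'")
  find_kw <- function(kw, from = 1L) {
    idx <- which(toupper(toks) == toupper(kw))
    idx <- idx[idx >= from]
    assert_that(length(idx) > 0L, sprintf("NEXUS: '%s' not found", kw))
    idx[[1]]
  }
  # taxa
  ti <- find_kw("TAXLABELS")
  taxa <- character(0)
  k <- ti + 1L
  while (toks[[k]] != ";") { taxa <- c(taxa, unq(toks[[k]])); k <- k + 1L }
  otus <- data.frame(
    id = sprintf("%sotu/%d", base_iri, seq_along(taxa)),
    taxon_name = taxa, material = "", stringsAsFactors = FALSE
  )
  # charstatelabels
  ci <- find_kw("CHARSTATELABELS")
  k <- ci + 1L
  chars <- list()
  states <- list()
  state_syms <- list()
  repeat {
    if (toks[[k]] == ";") break
    if (toks[[k]] == ",") { k <- k + 1L; next }
    idx <- as.integer(toks[[k]]); k <- k + 1L
    lab <- unq(toks[[k]]); k <- k + 1L
    assert_that(identical(toks[[k]], "/"), "NEXUS: expected '/'")
    k <- k + 1L
    st <- character(0)
    while (!toks[[k]] %in% c(",", ";")) {
      st <- c(st, unq(toks[[k]])); k <- k + 1L
    }
    cid <- sprintf("%scharacter/%d", base_iri, idx)
    chars[[idx]] <- data.frame(id = cid, label = lab, body_region = "body",
                               template_category = "unannotated",
                               stringsAsFactors = FALSE)
    states[[idx]] <- data.frame(character_id = cid, label = st,
                                stringsAsFactors = FALSE)
    state_syms[[idx]] <- st
  }
  chars <- do.call(rbind, chars)
  # matrix
  mi <- find_kw("MATRIX")
  k <- mi + 1L
  codings <- list()
  while (toks[[k]] != ";") {
    taxon <- unq(toks[[k]]); k <- k + 1L
    otu_id <- otus$id[match(taxon, otus$taxon_name)]
    cells <- list()
    while (length(cells) < nrow(chars)) {
      if (toks[[k]] == "{") {
        k <- k + 1L
        syms <- ""
        while (toks[[k]] != "}") {
          syms <- paste0(syms, toks[[k]]); k <- k + 1L
        }
        k <- k + 1L
        cells[[length(cells) + 1L]] <- strsplit(syms, "")[[1]]
      } else {
        run <- toks[[k]]; k <- k + 1L
        for (sym in strsplit(run, "")[[1]]) {
          cells[[length(cells) + 1L]] <- sym
        }
      }
    }
    for (j in seq_along(cells)) {
      for (sym in cells[[j]]) {
        if (sym == "?") next
        pos <- match(sym, nexus_symbols)
        codings[[length(codings) + 1L]] <- data.frame(
          otu_id = otu_id, character_id = chars$id[[j]],
          state_label = state_syms[[j]][[pos]], stringsAsFactors = FALSE
        )
      }
    }
  }
  assemble_matrix_study(chars, states, otus, codings, base_iri)
}
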