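# Minimal RDF triple graph with Turtle and RDF/XML serialization.
#
# No RDF library ships in the installed R stack, so the (deliberately
# restricted) dialects this package emits are parsed and written here:
# plain and typed literals, IRIs, labelled blank nodes, @prefix lines,
# ';'/',' predicate-object lists. That covers everything the package
# serializes; it is not a general-purpose Turtle parser.

#' Construct an RDF graph
#'
#' @param s,p,o character vectors: subject (IRI or `_:label` blank),
#'   predicate IRI, object.
#' @param otype object type per triple: `"iri"`, `"blank"` or `"literal"`.
#' @param dt optional datatype IRI per literal object (NA otherwise).
#' @return a data.frame of class `sempheno_graph` with columns
#'   s, p, o, otype, dt.
#' @export
rdf_graph <- function(s = character(0), p = character(0), o = character(0),
                      otype = character(0), dt = NA_character_) {
  n <- length(s)
  df <- data.frame(s = s, p = p, o = o,
                   otype = if (n && length(otype) == 0L) "iri" else otype,
                   dt = rep_len(dt, n), stringsAsFactors = FALSE)
  class(df) <- c("sempheno_graph", "data.frame")
  df
}

graph_bind <- function(...) {
  parts <- Filter(function(x) !is.null(x) && nrow(x) > 0L, list(...))
  if (!length(parts)) return(rdf_graph())
  out <- do.call(rbind, lapply(parts, function(x) {
    class(x) <- "data.frame"
    x
  }))
  out <- unique(out)
  rownames(out) <- NULL
  class(out) <- c("sempheno_graph", "data.frame")
  out
}

is_blank <- function(x) startsWith(x, "_:")

graph_canonical_strings <- function(g) {
  sort_c(sprintf("%s|%s|%s|%s|%s", g$s, g$p, g$o, g$otype,
                 ifelse(is.na(g$dt), "", g$dt)))
}

graph_equal <- function(a, b) {
  identical(graph_canonical_strings(a), graph_canonical_strings(b))
}

# --- Turtle -----------------------------------------------------------------

escape_literal <- function(x) {
  x <- gsub("\\", "\\\\", x, fixed = TRUE)
  x <- gsub("\"", "\\\"", x, fixed = TRUE)
  x <- gsub("\n", "\\n", x, fixed = TRUE)
  gsub("\r", "\\r", x, fixed = TRUE)
}

unescape_literal <- function(x) {
  out <- character(length(x))
  for (i in seq_along(x)) {
    s <- x[[i]]
    s <- gsub("\\n", "\n", s, fixed = TRUE)
    s <- gsub("\\r", "\r", s, fixed = TRUE)
    s <- gsub("\\\"", "\"", s, fixed = TRUE)
    s <- gsub("\\\\", "\\", s, fixed = TRUE)
    out[[i]] <- s
  }
  out
}

ttl_term <- function(value, type, dt, prefixes) {
  if (type == "literal") {
    lit <- paste0("\"", escape_literal(value), "\"")
    if (!is.na(dt)) lit <- paste0(lit, "^^", iri_compact(dt, prefixes))
    return(lit)
  }
  if (type == "blank" || is_blank(value)) return(value)
  iri_compact(value, prefixes)
}

#' Serialize an RDF graph to Turtle
#'
#' @param g an [rdf_graph()].
#' @param prefixes prefix map used both for `@prefix` headers and to
#'   compact IRIs.
#' @return a single string of Turtle text.
#' @export
write_turtle <- function(g, prefixes) {
  validate_prefix_map(prefixes)
  used <- sort_c(names(prefixes))
  header <- sprintf("@prefix %s: <%s> .", used, unlist(prefixes[used]))
  if (nrow(g) == 0L) return(paste(c(header, ""), collapse = "\n"))
  lines <- character(0)
  subj_key <- ifelse(is_blank(g$s), paste0("~", g$s), g$s)
  for (s in sort_c(unique(subj_key))) {
    rows <- g[subj_key == s, , drop = FALSE]
    subj <- rows$s[[1]]
    sterm <- if (is_blank(subj)) subj else iri_compact(subj, prefixes)
    rows <- sort_df(rows, c("p", "o", "otype"))
    po <- vapply(seq_len(nrow(rows)), function(i) {
      paste(iri_compact(rows$p[[i]], prefixes),
            ttl_term(rows$o[[i]], rows$otype[[i]], rows$dt[[i]], prefixes))
    }, character(1))
    lines <- c(lines, paste0(sterm, " ", paste(po, collapse = " ;\n    "),
                             " ."))
  }
  paste(c(header, "", lines, ""), collapse = "\n")
}

ttl_tokenize <- function(text) {
  n <- nchar(text)
  toks <- character(0)
  i <- 1L
  while (i <= n) {
    ch <- substr(text, i, i)
    if (grepl("^\\s$", ch)) { i <- i + 1L; next }
    if (ch == "#") {
      nl <- regexpr("\n", substr(text, i, n), fixed = TRUE)
      if (nl < 0L) break
      i <- i + nl
      next
    }
    if (ch == "\"") {
      j <- i + 1L
      while (j <= n) {
        cj <- substr(text, j, j)
        if (cj == "\\") { j <- j + 2L; next }
        if (cj == "\"") break
        j <- j + 1L
      }
      assert_that(j <= n, "unterminated literal in Turtle input")
      tok <- substr(text, i, j)
      # attach ^^datatype if present
      if (substr(text, j + 1L, j + 2L) == "^^") {
        rest <- substr(text, j + 3L, n)
        m <- regexpr("^\\S+?(?=[\\s;,.]|$)", rest, perl = TRUE)
        dt <- regmatches(rest, m)
        tok <- paste0(tok, "^^", dt)
        j <- j + 2L + attr(m, "match.length")
      }
      toks <- c(toks, tok)
      i <- j + 1L
      next
    }
    if (ch == "<") {
      close <- regexpr(">", substr(text, i, n), fixed = TRUE)
      assert_that(close > 0L, "unterminated IRI in Turtle input")
      toks <- c(toks, substr(text, i, i + close - 1L))
      i <- i + close
      next
    }
    if (ch %in% c(";", ",", ".")) { toks <- c(toks, ch); i <- i + 1L; next }
    m <- regexpr("^[^\\s;,]+", substr(text, i, n), perl = TRUE)
    tok <- regmatches(substr(text, i, n), m)
    adv <- nchar(tok)
    # a trailing '.' terminates the statement; it is not part of the token
    if (nchar(tok) > 1L && endsWith(tok, ".") && !grepl("^[0-9.]+$", tok)) {
      tok <- substr(tok, 1L, nchar(tok) - 1L)
      toks <- c(toks, tok, ".")
    } else {
      toks <- c(toks, tok)
    }
    i <- i + adv
    next
  }
  toks
}

#' Parse Turtle text (the dialect written by [write_turtle()])
#'
#' @param text Turtle text.
#' @return list with elements `graph` (an [rdf_graph()]) and `prefixes`.
#' @export
read_turtle <- function(text) {
  lines_all <- strsplit(text, "\n", fixed = TRUE)[[1]]
  pfx_lines <- grep("^\\s*@prefix", lines_all, value = TRUE)
  prefixes <- character(0)
  for (pl in pfx_lines) {
    m <- regmatches(pl, regexec("@prefix\\s+([^:]*):\\s+<([^>]*)>", pl))[[1]]
    prefixes[m[[2]]] <- m[[3]]
  }
  body <- paste(grep("^\\s*@prefix", lines_all, invert = TRUE, value = TRUE),
                collapse = "\n")
  toks <- ttl_tokenize(body)
  resolve_tok <- function(tok) {
    if (startsWith(tok, "_:")) return(list(v = tok, type = "blank", dt = NA))
    if (startsWith(tok, "<")) {
      return(list(v = substr(tok, 2L, nchar(tok) - 1L), type = "iri",
                  dt = NA))
    }
    if (startsWith(tok, "\"")) {
      dt <- NA_character_
      lit <- tok
      caret <- regexpr("\"^^", tok, fixed = TRUE)
      if (caret > 0L) {
        lit <- substr(tok, 1L, caret)
        dt_tok <- substr(tok, caret + 3L, nchar(tok))
        dt <- resolve_tok(dt_tok)$v
      }
      return(list(v = unescape_literal(substr(lit, 2L, nchar(lit) - 1L)),
                  type = "literal", dt = dt))
    }
    if (tok == "a") {
      return(list(v = paste0(prefixes[["rdf"]] %||%
                               "http://www.w3.org/1999/02/22-rdf-syntax-ns#",
                             "type"), type = "iri", dt = NA))
    }
    list(v = iri_expand(tok, prefixes), type = "iri", dt = NA)
  }
  s <- p <- o <- ot <- dt <- character(0)
  i <- 1L
  while (i <= length(toks)) {
    subj <- resolve_tok(toks[[i]])
    i <- i + 1L
    repeat {
      pred <- resolve_tok(toks[[i]])
      i <- i + 1L
      repeat {
        obj <- resolve_tok(toks[[i]])
        i <- i + 1L
        s <- c(s, subj$v); p <- c(p, pred$v); o <- c(o, obj$v)
        ot <- c(ot, obj$type); dt <- c(dt, obj$dt)
        if (i > length(toks) || toks[[i]] != ",") break
        i <- i + 1L
      }
      if (i > length(toks) || toks[[i]] != ";") break
      i <- i + 1L
      if (i <= length(toks) && toks[[i]] == ".") break   # dangling ';'
    }
    if (i <= length(toks) && toks[[i]] == ".") i <- i + 1L
  }
  list(graph = rdf_graph(s, p, o, ot, dt), prefixes = prefixes)
}

# --- RDF/XML ----------------------------------------------------------------

split_iri <- function(iri) {
  m <- regexpr("[#/][^#/]*$", iri)
  assert_that(m > 0L, sprintf("cannot split IRI '%s' for RDF/XML", iri))
  list(ns = substr(iri, 1L, m), local = substr(iri, m + 1L, nchar(iri)))
}

#' Serialize an RDF graph to RDF/XML
#'
#' Generic description-based serialization (one `rdf:Description` per
#' subject). Predicate IRIs must split into namespace + XML NCName.
#'
#' @param g an [rdf_graph()].
#' @param prefixes prefix map; every predicate namespace must be covered.
#' @return a single string of RDF/XML.
#' @export
write_rdfxml <- function(g, prefixes) {
  validate_prefix_map(prefixes)
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  nsmap <- c(structure(names(prefixes), names = unlist(prefixes)))
  attrs <- paste0("xmlns:", names(prefixes), "=\"",
                  unlist(prefixes), "\"", collapse = " ")
  out <- c("<?xml version=\"1.0\" encoding=\"UTF-8\"?>",
           paste0("<rdf:RDF ", attrs, ">"))
  esc <- function(x) {
    x <- gsub("&", "&amp;", x, fixed = TRUE)
    x <- gsub("<", "&lt;", x, fixed = TRUE)
    gsub(">", "&gt;", x, fixed = TRUE)
  }
  subj_key <- ifelse(is_blank(g$s), paste0("~", g$s), g$s)
  for (s in sort_c(unique(subj_key))) {
    rows <- sort_df(g[subj_key == s, , drop = FALSE], c("p", "o", "otype"))
    subj <- rows$s[[1]]
    open <- if (is_blank(subj)) {
      sprintf("  <rdf:Description rdf:nodeID=\"%s\">",
              substr(subj, 3L, nchar(subj)))
    } else {
      sprintf("  <rdf:Description rdf:about=\"%s\">", esc(subj))
    }
    out <- c(out, open)
    for (i in seq_len(nrow(rows))) {
      parts <- split_iri(rows$p[[i]])
      pfx <- nsmap[[parts$ns]]
      assert_that(!is.null(pfx),
                  sprintf("no prefix for predicate namespace '%s'", parts$ns))
      tag <- paste0(pfx, ":", parts$local)
      ot <- rows$otype[[i]]
      ov <- rows$o[[i]]
      line <- if (ot == "iri") {
        sprintf("    <%s rdf:resource=\"%s\"/>", tag, esc(ov))
      } else if (ot == "blank") {
        sprintf("    <%s rdf:nodeID=\"%s\"/>", tag,
                substr(ov, 3L, nchar(ov)))
      } else if (!is.na(rows$dt[[i]])) {
        sprintf("    <%s rdf:datatype=\"%s\">%s</%s>", tag,
                esc(rows$dt[[i]]), esc(ov), tag)
      } else {
        sprintf("    <%s>%s</%s>", tag, esc(ov), tag)
      }
      out <- c(out, line)
    }
    out <- c(out, "  </rdf:Description>")
  }
  paste(c(out, "</rdf:RDF>", ""), collapse = "\n")
}

#' Parse RDF/XML (the description-based form written by [write_rdfxml()])
#'
#' @param text RDF/XML text.
#' @return list with elements `graph` and `prefixes`.
#' @export
read_rdfxml <- function(text) {
  doc <- xml2::read_xml(text)
  ns <- xml2::xml_ns(doc)
  prefixes <- structure(as.character(ns), names = sub("^d[0-9]+$", "",
                                                      names(ns)))
  prefixes <- prefixes[nzchar(names(prefixes))]
  prefixes <- prefixes[!duplicated(names(prefixes))]
  rdf_ns <- "http://www.w3.org/1999/02/22-rdf-syntax-ns#"
  s <- p <- o <- ot <- dt <- character(0)
  for (desc in xml2::xml_children(doc)) {
    about <- xml2::xml_attr(desc, "about")
    nodeid <- xml2::xml_attr(desc, "nodeID")
    subj <- if (!is.na(about)) about else paste0("_:", nodeid)
    for (child in xml2::xml_children(desc)) {
      q <- xml2::xml_name(child, ns = ns)  # "pfx:local" using doc namespaces
      colon <- regexpr(":", q, fixed = TRUE)
      pfx <- substr(q, 1L, colon - 1L)
      pred <- paste0(ns[[pfx]], substr(q, colon + 1L, nchar(q)))
      res <- xml2::xml_attr(child, "resource")
      nid <- xml2::xml_attr(child, "nodeID")
      dty <- xml2::xml_attr(child, "datatype")
      if (!is.na(res)) {
        s <- c(s, subj); p <- c(p, pred); o <- c(o, res)
        ot <- c(ot, "iri"); dt <- c(dt, NA_character_)
      } else if (!is.na(nid)) {
        s <- c(s, subj); p <- c(p, pred); o <- c(o, paste0("_:", nid))
        ot <- c(ot, "blank"); dt <- c(dt, NA_character_)
      } else {
        s <- c(s, subj); p <- c(p, pred); o <- c(o, xml2::xml_text(child))
        ot <- c(ot, "literal"); dt <- c(dt, if (is.na(dty)) NA_character_
                                            else dty)
      }
    }
  }
  list(graph = rdf_graph(s, p, o, ot, dt), prefixes = prefixes)
}

# --- graph isomorphism (blank-node renaming) --------------------------------

blank_signatures <- function(g, colors) {
  sigs <- lapply(names(colors), function(b) {
    outg <- g[g$s == b, , drop = FALSE]
    ing <- g[g$otype == "blank" & g$o == b, , drop = FALSE]
    oside <- sprintf("out|%s|%s", outg$p,
                     ifelse(outg$otype == "blank",
                            paste0("C", colors[outg$o]), outg$o))
    iside <- sprintf("in|%s|%s", ing$p,
                     ifelse(is_blank(ing$s), paste0("C", colors[ing$s]),
                            ing$s))
    paste(sort_c(c(oside, iside)), collapse = "&")
  })
  structure(unlist(sigs), names = names(colors))
}

refine_colors <- function(g, blanks) {
  colors <- structure(rep("0", length(blanks)), names = blanks)
  repeat {
    sigs <- blank_signatures(g, colors)
    new_colors <- structure(as.character(match(sigs, sort_c(unique(sigs)))),
                            names = names(colors))
    if (identical(new_colors, colors)) return(list(colors = colors,
                                                   sigs = sigs))
    colors <- new_colors
  }
}

#' Test whether two RDF graphs are isomorphic up to blank-node renaming
#'
#' Colour refinement on blank nodes followed by backtracking within colour
#' classes. Intended for the package's fixture-scale graphs.
#'
#' @param a,b graphs from [rdf_graph()].
#' @return `TRUE` or `FALSE`.
#' @export
graph_isomorphic <- function(a, b) {
  a <- unique(as.data.frame(a)); b <- unique(as.data.frame(b))
  if (nrow(a) != nrow(b)) return(FALSE)
  blanks_a <- sort_c(unique(c(a$s[is_blank(a$s)],
                              a$o[a$otype == "blank"])))
  blanks_b <- sort_c(unique(c(b$s[is_blank(b$s)],
                              b$o[b$otype == "blank"])))
  if (length(blanks_a) != length(blanks_b)) return(FALSE)
  ground <- function(g) {
    gg <- g[!is_blank(g$s) & g$otype != "blank", , drop = FALSE]
    graph_canonical_strings(rdf_graph(gg$s, gg$p, gg$o, gg$otype, gg$dt))
  }
  if (!identical(ground(a), ground(b))) return(FALSE)
  if (length(blanks_a) == 0L) return(TRUE)
  ra <- refine_colors(a, blanks_a)
  rb <- refine_colors(b, blanks_b)
  if (!identical(unname(sort_c(unname(ra$sigs))),
                 unname(sort_c(unname(rb$sigs))))) {
    return(FALSE)
  }
  # backtracking assignment within equal-signature groups
  target <- graph_canonical_strings(rdf_graph(b$s, b$p, b$o, b$otype, b$dt))
  cand <- lapply(blanks_a, function(x) {
    names(rb$sigs)[rb$sigs == ra$sigs[[x]]]
  })
  names(cand) <- blanks_a
  ordering <- blanks_a[order(vapply(cand, length, integer(1)))]
  assign_try <- function(idx, map, used) {
    if (idx > length(ordering)) {
      s2 <- ifelse(is_blank(a$s), unname(map[a$s]), a$s)
      o2 <- ifelse(a$otype == "blank", unname(map[a$o]), a$o)
      return(identical(graph_canonical_strings(
        rdf_graph(s2, a$p, o2, a$otype, a$dt)), target))
    }
    x <- ordering[[idx]]
    for (y in cand[[x]]) {
      if (y %in% used) next
      map2 <- map; map2[[x]] <- y
      if (assign_try(idx + 1L, map2, c(used, y))) return(TRUE)
    }
    FALSE
  }
  assign_try(1L, structure(character(0)), character(0))
}
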