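# Seeded synthetic-study generator and random-structure helpers for
# property-based testing. The generator states a small but realistic
# world: a mini anatomy with a part_of tree a few levels deep, a quality
# tree under shape/size/color/texture, a handful of OTUs with one to a
# few specimens each, and a character mix dominated by qualitative
# characters - mirroring the proportions seen in morphological matrices
# of this kind. Ground truth (template per character, partition counts,
# propagation pairs) is computed independently during generation, never
# by calling the reasoner.

#' Configuration for the synthetic-study generator
#'
#' Defaults follow the character-mix proportions of a typical annotated
#' hymenopteran matrix (mostly qualitative characters, a substantial
#' presence/absence share, few counts, some relative measurements),
#' scaled down for test speed.
#'
#' @param seed integer seed fixing all randomness.
#' @param n_qualitative,n_presence,n_count,n_relative characters per
#'   template category.
#' @param n_otus number of OTUs.
#' @param polymorphism_rate probability a cell receives two states.
#' @param n_anatomy anatomy classes in the part_of tree (>= 3).
#' @param anatomy_depth maximum part_of depth below the root.
#' @param n_quality quality leaf classes (>= 4).
#' @param n_specimens_per_otu specimens minted per OTU.
#' @return a list of class `sempheno_synth_config`.
#' @export
synth_config <- function(seed = 1L, n_qualitative = 10L, n_presence = 5L,
                         n_count = 2L, n_relative = 3L, n_otus = 4L,
                         polymorphism_rate = 0.1, n_anatomy = 12L,
                         anatomy_depth = 3L, n_quality = 8L,
                         n_specimens_per_otu = 2L) {
  cfg <- list(seed = as.integer(seed), n_qualitative = n_qualitative,
              n_presence = n_presence, n_count = n_count,
              n_relative = n_relative, n_otus = n_otus,
              polymorphism_rate = polymorphism_rate,
              n_anatomy = n_anatomy, anatomy_depth = anatomy_depth,
              n_quality = n_quality,
              n_specimens_per_otu = n_specimens_per_otu)
  for (f in setdiff(names(cfg), "polymorphism_rate")) {
    assert_that(cfg[[f]] >= 0L, sprintf("'%s' must be >= 0", f))
  }
  assert_that(n_anatomy >= 3L, "need at least 3 anatomy classes")
  assert_that(n_quality >= 4L, "need at least 4 quality leaves")
  assert_that(n_otus >= 1L, "need at least one OTU")
  structure(cfg, class = "sempheno_synth_config")
}

with_seed <- function(seed, code) {
  if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())),
            add = TRUE)
  }
  set.seed(seed)
  force(code)
}

#' Generate a synthetic annotated study with ground truth
#'
#' Builds a random mini anatomy (part_of tree) and quality tree, composes
#' phenotypes per the requested template mix, codes every OTU for every
#' character (polymorphic with the configured rate), mints specimens with
#' localities from a small pool and annotates every state. Ground truth
#' is derived from the construction itself: the template of each
#' character, the (specimen, phenotype) propagation pairs implied by the
#' codings, and the entity/quality partition counts implied by the
#' locator chains and the generated part_of tree.
#'
#' @param cfg a [synth_config()].
#' @param config a [sempheno_config()].
#' @return list with `study`, `ontology`, `truth` (elements `templates`,
#'   `propagation`, `entity_partition`, `quality_partition`) and `cfg`.
#' @export
generate_study <- function(cfg = synth_config(),
                           config = sempheno_config()) {
  with_seed(cfg$seed, generate_study_impl(cfg, config))
}

generate_study_impl <- function(cfg, config) {
  pfx <- config$prefixes
  pr <- config$properties
  anat_iri <- function(i) sprintf("%sanat_%02d", pfx[["hao"]], i)
  qual_iri <- function(x) paste0(pfx[["pato"]], x)

  # anatomy part_of tree: node 1 is the body root
  parent <- rep(NA_integer_, cfg$n_anatomy)
  depth <- rep(0L, cfg$n_anatomy)
  for (i in seq(2L, cfg$n_anatomy)) {
    cand <- which(depth[seq_len(i - 1L)] < cfg$anatomy_depth)
    parent[[i]] <- cand[[sample.int(length(cand), 1L)]]
    depth[[i]] <- depth[[parent[[i]]]] + 1L
  }
  anat_classes <- do.call(rbind, lapply(seq_len(cfg$n_anatomy),
                                        function(i) ont_class(anat_iri(i))))
  anat_axioms <- lapply(seq(2L, cfg$n_anatomy), function(i) {
    axiom_subclass(ce_named(anat_iri(i)),
                   ce_some(pr$part_of, ce_named(anat_iri(parent[[i]]))))
  })
  anc_of <- function(i) {  # part_of ancestors (IRIs), excluding self
    out <- integer(0)
    while (!is.na(parent[[i]])) {
      i <- parent[[i]]
      out <- c(out, i)
    }
    anat_iri(out)
  }

  # quality tree: quality -> {shape,size,color,texture} -> leaves; absent
  branches <- c("shape", "size", "color", "texture")
  leaves <- sprintf("qual_%02d", seq_len(cfg$n_quality))
  leaf_branch <- branches[(seq_len(cfg$n_quality) - 1L) %% 4L + 1L]
  qual_classes <- do.call(rbind, lapply(c("quality", branches, leaves,
                                          "absent"), function(x) {
    ont_class(qual_iri(x))
  }))
  qual_axioms <- c(
    lapply(branches, function(b) {
      axiom_subclass(ce_named(qual_iri(b)), ce_named(qual_iri("quality")))
    }),
    lapply(seq_along(leaves), function(i) {
      axiom_subclass(ce_named(qual_iri(leaves[[i]])),
                     ce_named(qual_iri(leaf_branch[[i]])))
    }),
    list(axiom_subclass(ce_named(qual_iri("absent")),
                        ce_named(qual_iri("quality"))))
  )
  qual_anc <- function(leaf) {  # quality ancestors incl. self
    i <- match(leaf, leaves)
    c(qual_iri(leaf), qual_iri(leaf_branch[[i]]), qual_iri("quality"))
  }

  props <- rbind(
    ont_property(pr$has_part, transitive = TRUE),
    ont_property(pr$part_of, transitive = TRUE),
    ont_property(pr$bearer_of),
    ont_property(pr$towards),
    ont_property(pr$increased), ont_property(pr$decreased),
    ont_property(pr$equal)
  )
  o <- ontology(classes = rbind(anat_classes, qual_classes),
                properties = props,
                axioms = c(anat_axioms, qual_axioms), prefixes = pfx)

  pick_chain <- function() {
    node <- sample.int(cfg$n_anatomy - 1L, 1L) + 1L  # never the root
    if (!is.na(parent[[node]]) && parent[[node]] != 1L &&
        stats::runif(1) < 0.5) {
      c(anat_iri(parent[[node]]), anat_iri(node))
    } else {
      anat_iri(node)
    }
  }
  templates <- c(rep("qualitative", cfg$n_qualitative),
                 rep("presence_absence", cfg$n_presence),
                 rep("count", cfg$n_count),
                 rep("relative_measurement", cfg$n_relative))
  n_char <- length(templates)
  base <- pfx[["ex"]]
  characters <- data.frame(
    id = sprintf("%scharacter/%d", base, seq_len(n_char)),
    label = sprintf("Character %02d (%s)", seq_len(n_char), templates),
    body_region = sample(body_regions, n_char, replace = TRUE),
    template_category = templates, stringsAsFactors = FALSE
  )
  states <- list()
  state_defs <- list()   # state id -> list(expr, rule)
  entity_sets <- list()  # character id -> has_part-reachable entity IRIs
  quality_sets <- list() # character id -> borne quality IRIs (with anc)
  for (j in seq_len(n_char)) {
    chain <- pick_chain()
    cid <- characters$id[[j]]
    mk_state <- function(k, lab) {
      sprintf("%sstate/%d_%d", base, j, k)
    }
    tpl <- templates[[j]]
    if (tpl == "qualitative") {
      qs <- sample(leaves, 2L)
      defs <- lapply(qs, function(q) {
        list(expr = compose_qualitative(chain, qual_iri(q), config),
             rule = NULL)
      })
      labs <- qs
      ent <- c(chain, unlist(lapply(chain, function(x) {
        anc_of(match(x, anat_iri(seq_len(cfg$n_anatomy))))
      })))
      qual <- unique(c(qual_anc(qs[[1]]), qual_anc(qs[[2]])))
    } else if (tpl == "presence_absence") {
      defs <- list(
        list(expr = compose_presence_absence(chain, TRUE, config),
             rule = NULL),
        list(expr = compose_presence_absence(chain, FALSE, config),
             rule = NULL)
      )
      labs <- c("present", "absent")
      # the present state reaches every chain class; the absent state
      # only the containers. The character-level set is the union.
      ent <- c(chain, unlist(lapply(chain, function(x) {
        anc_of(match(x, anat_iri(seq_len(cfg$n_anatomy))))
      })))
      # the absent state bears 'absent' on a container only when the
      # chain has one; a length-1 chain yields a bare bearer_of with no
      # has_part step, which the quality query cannot reach
      qual <- if (length(chain) >= 2L) {
        c(qual_iri("absent"), qual_iri("quality"))
      } else {
        character(0)
      }
    } else if (tpl == "count") {
      counted <- anat_iri(sample.int(cfg$n_anatomy - 1L, 1L) + 1L)
      n0 <- sample.int(4L, 1L)
      defs <- lapply(c(n0, n0 + 1L), function(n) {
        list(expr = compose_count(chain, counted, n, config), rule = NULL)
      })
      labs <- as.character(c(n0, n0 + 1L))
      ent <- c(chain, counted,
               unlist(lapply(c(chain, counted), function(x) {
                 anc_of(match(x, anat_iri(seq_len(cfg$n_anatomy))))
               })))
      qual <- character(0)
    } else {
      pair <- sample.int(cfg$n_anatomy - 1L, 2L, replace = FALSE) + 1L
      q <- sample(leaves[leaf_branch == "size"], 1L)
      defs <- lapply(c("increased", "decreased"), function(dir) {
        r <- compose_relative(anat_iri(pair[[1]]), qual_iri(q),
                              anat_iri(pair[[2]]), dir, config)
        list(expr = r$expression, rule = r$rule)
      })
      labs <- c("longer", "shorter")
      ent <- c(anat_iri(pair[[1]]), anc_of(pair[[1]]))
      qual <- qual_anc(q)
    }
    for (k in seq_along(defs)) {
      sid <- mk_state(k, labs[[k]])
      states[[length(states) + 1L]] <- data.frame(
        id = sid, character_id = cid, label = labs[[k]],
        stringsAsFactors = FALSE
      )
      state_defs[[sid]] <- defs[[k]]
    }
    entity_sets[[cid]] <- unique(ent)
    quality_sets[[cid]] <- unique(qual)
  }
  states <- do.call(rbind, states)

  otus <- data.frame(
    id = sprintf("%sotu/%d", base, seq_len(cfg$n_otus)),
    taxon_name = sprintf("Taxon %02d", seq_len(cfg$n_otus)),
    material = "", stringsAsFactors = FALSE
  )
  localities <- data.frame(
    country = c("FRANCE", "USA", "FIJI", "INDONESIA"),
    subdivision = c("New Caledonia", "Hawaii", "", ""),
    stringsAsFactors = FALSE
  )
  specimens <- list()
  for (i in seq_len(cfg$n_otus)) {
    for (k in seq_len(cfg$n_specimens_per_otu)) {
      loc <- localities[sample.int(nrow(localities), 1L), ]
      specimens[[length(specimens) + 1L]] <- data.frame(
        catalog_urn = sprintf("urn:catalog:SYN:SYN:%d",
                              (i - 1L) * cfg$n_specimens_per_otu + k),
        otu_id = otus$id[[i]], repository_coden = "SYN",
        country = loc$country, subdivision = loc$subdivision,
        role = if (k == 1L) "holotype" else "other",
        sex = sample(c("male", "female", "unknown"), 1L),
        verbatim = "", stringsAsFactors = FALSE
      )
    }
  }
  specimens <- if (length(specimens)) do.call(rbind, specimens) else NULL

  codings <- list()
  for (i in seq_len(cfg$n_otus)) {
    for (j in seq_len(n_char)) {
      st <- states[states$character_id == characters$id[[j]], , drop = FALSE]
      k <- if (stats::runif(1) < cfg$polymorphism_rate &&
               nrow(st) >= 2L) {
        sample.int(nrow(st), 2L)
      } else {
        sample.int(nrow(st), 1L)
      }
      for (kk in sort(k)) {
        codings[[length(codings) + 1L]] <- data.frame(
          otu_id = otus$id[[i]], character_id = characters$id[[j]],
          state_id = st$id[[kk]], stringsAsFactors = FALSE
        )
      }
    }
  }
  codings <- if (length(codings)) do.call(rbind, codings) else NULL

  s <- study(characters = characters, states = states, otus = otus,
             codings = codings, specimens = specimens, prefixes = pfx)
  for (sid in names(state_defs)) {
    s <- annotate_state(s, sid, state_defs[[sid]]$expr, config = config,
                        rule = state_defs[[sid]]$rule)
  }

  # ground truth, computed from the construction only
  truth_templates <- stats::setNames(templates, characters$id)
  prop_rows <- list()
  if (!is.null(codings) && !is.null(specimens)) {
    for (r in seq_len(nrow(codings))) {
      sp <- specimens$catalog_urn[specimens$otu_id == codings$otu_id[[r]]]
      for (x in sp) {
        prop_rows[[length(prop_rows) + 1L]] <- data.frame(
          specimen = x,
          phenotype = paste0(codings$state_id[[r]], "#phenotype"),
          stringsAsFactors = FALSE
        )
      }
    }
  }
  propagation <- if (length(prop_rows)) {
    sort_df(unique(do.call(rbind, prop_rows)), c("specimen", "phenotype"))
  } else {
    data.frame(specimen = character(0), phenotype = character(0),
               stringsAsFactors = FALSE)
  }
  entity_partition <- data.frame(
    class = anat_iri(seq_len(cfg$n_anatomy)),
    count = vapply(anat_iri(seq_len(cfg$n_anatomy)), function(e) {
      sum(vapply(characters$id, function(cid) {
        e %in% entity_sets[[cid]]
      }, logical(1)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  quality_partition <- data.frame(
    class = c(qual_iri(c("quality", branches, "absent")),
              qual_iri(leaves)),
    count = vapply(c(qual_iri(c("quality", branches, "absent")),
                     qual_iri(leaves)), function(q) {
      sum(vapply(characters$id, function(cid) {
        q %in% quality_sets[[cid]]
      }, logical(1)))
    }, integer(1)),
    stringsAsFactors = FALSE
  )
  list(study = s, ontology = o,
       truth = list(templates = truth_templates,
                    propagation = propagation,
                    entity_partition = entity_partition,
                    quality_partition = quality_partition),
       cfg = cfg)
}

# --- random structures for fuzzing -----------------------------------------

#' Random class expression (full grammar)
#'
#' Draws from the current RNG state; wrap in a seeded context for
#' reproducibility. Used by the parse/render round-trip properties.
#'
#' @param classes,properties IRI vocabularies to draw from.
#' @param max_depth maximum nesting depth.
#' @param el_only when TRUE, restrict to the EL core (no only/exactly).
#' @return a class expression.
#' @export
random_expression <- function(classes, properties, max_depth = 4L,
                              el_only = FALSE) {
  kinds <- if (max_depth <= 1L) {
    "named"
  } else if (el_only) {
    c("named", "and", "or", "some")
  } else {
    c("named", "and", "or", "some", "only", "exactly")
  }
  kind <- sample(kinds, 1L,
                 prob = switch(as.character(length(kinds)),
                               "1" = 1,
                               "4" = c(0.35, 0.2, 0.15, 0.3),
                               c(0.3, 0.2, 0.12, 0.25, 0.05, 0.08)))
  switch(kind,
    named = ce_named(sample(classes, 1L)),
    and = ce_and(lapply(seq_len(sample(2:3, 1L)), function(i) {
      random_expression(classes, properties, max_depth - 1L, el_only)
    })),
    or = ce_or(lapply(seq_len(2L), function(i) {
      random_expression(classes, properties, max_depth - 1L, el_only)
    })),
    some = ce_some(sample(properties, 1L),
                   random_expression(classes, properties, max_depth - 1L,
                                     el_only)),
    only = ce_only(sample(properties, 1L),
                   random_expression(classes, properties, max_depth - 1L,
                                     el_only)),
    exactly = ce_exactly(sample(properties, 1L), sample(0:3, 1L),
                         random_expression(classes, properties,
                                           max_depth - 1L, el_only))
  )
}

#' Random mini ontology for subsumption fuzzing
#'
#' A random named-class hierarchy, a part_of tree over a subset of the
#' classes (told complex superclasses), transitive has_part/part_of, and
#' optionally the has_part-over-part_of folding chain.
#'
#' @param n_classes number of classes.
#' @param config a [sempheno_config()].
#' @param fold_chain include `has_part o part_of -> has_part`.
#' @return an [ontology()].
#' @export
random_ontology <- function(n_classes = 10L, config = sempheno_config(),
                            fold_chain = FALSE) {
  pfx <- config$prefixes
  pr <- config$properties
  cls <- sprintf("%sc%02d", pfx[["hao"]], seq_len(n_classes))
  classes <- do.call(rbind, lapply(cls, ont_class))
  axioms <- list()
  for (i in seq(2L, n_classes)) {
    if (stats::runif(1) < 0.6) {  # named subclass edge to an earlier class
      axioms[[length(axioms) + 1L]] <-
        axiom_subclass(ce_named(cls[[i]]),
                       ce_named(cls[[sample.int(i - 1L, 1L)]]))
    }
    if (stats::runif(1) < 0.4) {  # part_of a random other class
      axioms[[length(axioms) + 1L]] <-
        axiom_subclass(ce_named(cls[[i]]),
                       ce_some(pr$part_of,
                               ce_named(cls[[sample.int(i - 1L, 1L)]])))
    }
  }
  props <- rbind(ont_property(pr$has_part, transitive = TRUE),
                 ont_property(pr$part_of, transitive = TRUE),
                 ont_property(pr$bearer_of))
  chains <- list()
  if (fold_chain) {
    chains[[pr$has_part]] <- c(pr$has_part, pr$part_of)
  }
  ontology(classes = classes, properties = props, axioms = axioms,
           prefixes = pfx, chains = chains)
}
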