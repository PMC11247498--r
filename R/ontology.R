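# Merged phenotype ontology: OBO parsing, ancestor closure, information
# content and most-informative common ancestors.

new_ontology <- function(terms, parents, ancestors, roots, topo) {
  structure(
    list(terms = terms, parents = parents, ancestors = ancestors,
         roots = roots, topo = topo),
    class = "phen_ontology"
  )
}

infer_namespace <- function(id) {
  prefix <- sub(":.*$", "", id)
  ifelse(prefix == "HP", "human-phenotype",
         ifelse(prefix == "MP", "mammalian-phenotype", "shared"))
}

#' Parse a merged phenotype ontology from OBO flat-file text
#'
#' Reads OBO 1.2/1.4 `[Term]` stanzas and builds a rooted directed acyclic
#' graph of phenotype terms. Only the `id`, `name`, `namespace`, `is_a` and
#' `is_obsolete` tags are interpreted; `is_a` targets become parent edges
#' (any trailing `! comment` is stripped) and all other relationship types
#' are ignored. Obsolete terms are dropped at parse time, so annotations to
#' them fail loudly downstream rather than being silently remapped.
#'
#' The reflexive ancestor closure of every term is precomputed in topological
#' order; acyclicity and resolvability of every `is_a` target are verified on
#' every parse.
#'
#' @param x OBO text: either a single string (possibly with embedded
#'   newlines) or a character vector of lines.
#' @return A `phen_ontology` object: a list with `terms` (tibble of `id`,
#'   `name`, `namespace`), `parents` (named list of parent-id vectors),
#'   `ancestors` (named list of reflexive ancestor-id vectors), `roots`
#'   (ids with no parents) and `topo` (a topological order, roots first).
#' @examples
#' ont <- parse_obo(c(
#'   "[Term]", "id: A", "name: root", "",
#'   "[Term]", "id: B", "name: child", "is_a: A ! root"
#' ))
#' term_ancestors(ont, "B")
#' @seealso [read_obo()] to parse from a file path.
#' @export
parse_obo <- function(x) {
  if (length(x) == 1L && grepl("\n", x, fixed = TRUE)) {
    x <- strsplit(x, "\n", fixed = TRUE)[[1L]]
  }
  lines <- sub("\r$", "", as.character(x))

  header_idx <- grep("^\\[[^]]+\\]\\s*$", lines)
  if (!length(header_idx)) {
    stop("no [Term] stanzas found in OBO input", call. = FALSE)
  }
  header_tag <- sub("^\\[([^]]+)\\]\\s*$", "\\1", lines[header_idx])
  stanza_end <- c(header_idx[-1L] - 1L, length(lines))

  ids <- character(0)
  names_ <- character(0)
  namespaces <- character(0)
  parents <- list()

  for (k in seq_along(header_idx)) {
    if (header_tag[k] != "Term") next
    body <- lines[seq(header_idx[k] + 1L, length.out = stanza_end[k] - header_idx[k])]
    body <- body[nzchar(body)]
    tags <- sub("^([A-Za-z_]+):.*$", "\\1", body)
    vals <- trimws(sub("^[A-Za-z_]+:", "", body))

    id <- vals[tags == "id"][1L]
    if (is.na(id) || !nzchar(id)) {
      stop("OBO [Term] stanza without an id tag", call. = FALSE)
    }
    obs <- vals[tags == "is_obsolete"]
    if (length(obs) && any(tolower(obs) == "true")) next

    if (id %in% ids) {
      stop("duplicate term id in OBO input: ", id, call. = FALSE)
    }
    nm <- vals[tags == "name"][1L]
    ns <- vals[tags == "namespace"][1L]
    isa <- vals[tags == "is_a"]
    isa <- trimws(sub("\\s*!.*$", "", isa))
    isa <- unique(isa[nzchar(isa)])

    ids <- c(ids, id)
    names_ <- c(names_, if (is.na(nm)) id else nm)
    namespaces <- c(namespaces, if (is.na(ns)) infer_namespace(id) else ns)
    parents[[id]] <- isa
  }

  if (!length(ids)) stop("OBO input contains no non-obsolete terms", call. = FALSE)

  all_parents <- unique(unlist(parents, use.names = FALSE))
  missing <- setdiff(all_parents, ids)
  if (length(missing)) {
    stop("is_a target not defined in ontology: ", missing[1L], call. = FALSE)
  }

  # Kahn's algorithm over parent edges: a term is ready once all its parents
  # have been emitted, so the returned order has roots first.
  n_unmet <- vapply(parents, length, integer(1L))[ids]
  n_unmet[is.na(n_unmet)] <- 0L
  names(n_unmet) <- ids
  children <- split(
    rep(ids, vapply(parents[ids], length, integer(1L))),
    unlist(parents[ids], use.names = FALSE)
  )
  queue <- ids[n_unmet == 0L]
  topo <- character(length(ids))
  n_done <- 0L
  while (length(queue)) {
    t <- queue[1L]
    queue <- queue[-1L]
    n_done <- n_done + 1L
    topo[n_done] <- t
    for (ch in children[[t]]) {
      n_unmet[ch] <- n_unmet[ch] - 1L
      if (n_unmet[ch] == 0L) queue <- c(queue, ch)
    }
  }
  if (n_done < length(ids)) {
    cyc <- ids[n_unmet > 0L]
    stop("cyclic is_a structure in ontology involving term: ", cyc[1L],
         call. = FALSE)
  }

  ancestors <- vector("list", length(ids))
  names(ancestors) <- ids
  for (t in topo) {
    ps <- parents[[t]]
    ancestors[[t]] <- if (length(ps)) {
      unique(c(t, unlist(ancestors[ps], use.names = FALSE)))
    } else {
      t
    }
  }

  roots <- ids[vapply(ids, function(t) length(parents[[t]]) == 0L, logical(1L))]
  terms <- tibble::tibble(id = ids, name = names_, namespace = namespaces)
  new_ontology(terms, parents, ancestors, roots, topo)
}

#' Read a merged phenotype ontology from an OBO file
#'
#' @param path Path to an OBO 1.2/1.4 flat file (UTF-8).
#' @return A `phen_ontology`; see [parse_obo()].
#' @export
read_obo <- function(path) {
  parse_obo(readLines(path, encoding = "UTF-8", warn = FALSE))
}

#' @export
print.phen_ontology <- function(x, ...) {
  ns <- table(x$terms$namespace)
  cat("<phen_ontology> ", nrow(x$terms), " terms (",
      paste(names(ns), as.integer(ns), sep = ": ", collapse = ", "),
      "), ", length(x$roots), " root(s)\n", sep = "")
  invisible(x)
}

assert_term <- function(ont, t) {
  bad <- setdiff(t, names(ont$ancestors))
  if (length(bad)) {
    stop("unknown ontology term: ", bad[1L], call. = FALSE)
  }
  invisible(TRUE)
}

#' Reflexive ancestor set of a term
#'
#' Returns the reflexive transitive closure over `is_a` parent edges: the
#' term itself plus every term reachable by following parents. Reflexivity
#' means identical terms attain a Jaccard similarity of 1 in
#' [term_similarity()].
#'
#' @param ont A `phen_ontology`.
#' @param t A term id present in `ont`.
#' @return Character vector of ancestor term ids (including `t`).
#' @export
term_ancestors <- function(ont, t) {
  stopifnot(length(t) == 1L)
  assert_term(ont, t)
  ont$ancestors[[t]]
}

#' Annotation-based information content
#'
#' Computes, for every ontology term, the information content
#' \eqn{IC(t) = -\ln(count(t)/N)} where `count(t)` is the number of distinct
#' corpus entities annotated to `t` or to any of its descendants and `N` is
#' the corpus size. Terms annotated to no entity receive the maximum
#' \eqn{\ln N} (treated as frequency 1, bounded rather than infinite), and
#' every root receives IC 0 by construction, since all annotated entities
#' propagate to the roots.
#'
#' The corpus is typically the union of all disease HPO annotation sets and
#' all model MP annotation sets in a study; see [build_ic_corpus()].
#'
#' @param ont A `phen_ontology`.
#' @param corpus A list of character vectors, one per annotated entity,
#'   each giving the entity's directly annotated term ids. Must be
#'   non-empty; every term must exist in `ont`.
#' @return A `phen_ic` object: list with `ic` (named numeric over all
#'   ontology terms, natural-log units) and `corpus_size`.
#' @export
information_content <- function(ont, corpus) {
  if (!is.list(corpus) || length(corpus) == 0L) {
    stop("corpus must be a non-empty list of annotation sets", call. = FALSE)
  }
  used <- unique(unlist(corpus, use.names = FALSE))
  assert_term(ont, used)

  anc_hits <- unlist(
    lapply(corpus, function(ts) {
      unique(unlist(ont$ancestors[unique(ts)], use.names = FALSE))
    }),
    use.names = FALSE
  )
  counts <- table(anc_hits)
  n <- length(corpus)

  ic <- rep(log(n), nrow(ont$terms))
  names(ic) <- ont$terms$id
  ic[names(counts)] <- -log(as.numeric(counts) / n)
  ic[ic < 0] <- 0 # guard against -log(1) returning -0
  ic[ont$roots] <- 0
  structure(list(ic = ic, corpus_size = n), class = "phen_ic")
}

#' @export
print.phen_ic <- function(x, ...) {
  cat("<phen_ic> ", length(x$ic), " terms, corpus of ", x$corpus_size,
      " entities, max IC ", format(max(x$ic), digits = 4), "\n", sep = "")
  invisible(x)
}

#' Write an information-content table as two-column TSV
#'
#' @param ic A `phen_ic` object.
#' @param path Output path; columns `term_id`, `ic`.
#' @export
write_ic <- function(ic, path) {
  readr::write_tsv(
    tibble::tibble(term_id = names(ic$ic), ic = unname(ic$ic)),
    path
  )
  invisible(path)
}

#' Most-informative common ancestor of two terms
#'
#' Intersects the reflexive ancestor sets of the two terms and returns the
#' common ancestor with maximal information content. Ties on IC are broken
#' by the lexicographically smallest term id, so the returned term is
#' deterministic; the IC value is unique regardless of ties. If the terms
#' share no ancestor (disconnected graph) the sentinel
#' `list(term = NA, ic = 0)` is returned.
#'
#' @param ont A `phen_ontology`.
#' @param ic A `phen_ic` from [information_content()].
#' @param t1,t2 Term ids.
#' @return List with `term` (id or `NA_character_`) and `ic` (numeric).
#' @export
mica <- function(ont, ic, t1, t2) {
  assert_term(ont, c(t1, t2))
  common <- intersect(ont$ancestors[[t1]], ont$ancestors[[t2]])
  if (!length(common)) {
    return(list(term = NA_character_, ic = 0))
  }
  vals <- ic$ic[common]
  best <- max(vals)
  list(term = sort(common[vals == best])[1L], ic = unname(best))
}

#' Does a single root subsume terms from both species namespaces?
#'
#' Convenience check for the cross-species connectivity a merged ontology
#' must provide for HPO--MP comparison to be informative.
#'
#' @param ont A `phen_ontology`.
#' @return Logical scalar.
#' @export
has_cross_species_root <- function(ont) {
  ns <- stats::setNames(ont$terms$namespace, ont$terms$id)
  for (r in ont$roots) {
    desc <- ont$terms$id[vapply(ont$terms$id,
                                function(t) r %in% ont$ancestors[[t]],
                                logical(1L))]
    if (any(ns[desc] == "human-phenotype") &&
        any(ns[desc] == "mammalian-phenotype")) {
      return(TRUE)
    }
  }
  FALSE
}
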