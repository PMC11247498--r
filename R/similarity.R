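# PhenoDigm-style similarity: pairwise HPO--MP term similarity, per-query
# best matches, and the percentage score normalised by the disease
# self-comparison optimum.

#' Pairwise similarity of two phenotype terms
#'
#' Computes \eqn{\sqrt{J(t_q, t_h) \times IC(MICA)}} where \eqn{J} is the
#' Jaccard index of the two terms' reflexive ancestor sets and \eqn{IC(MICA)}
#' the information content of their most-informative common ancestor. The
#' form is symmetric in its arguments and equals 0 exactly when the only
#' shared ancestor is a zero-IC root (or none at all). Alternative pairwise
#' forms (IC-only, Jaccard-only) are available via `form`; the geometric
#' mean of Jaccard and IC is the default, fixed for reproducibility.
#'
#' @param ont A `phen_ontology`.
#' @param ic A `phen_ic`.
#' @param t_query,t_hit Term ids (typically an HPO query and an MP hit, but
#'   any terms of the merged graph are accepted).
#' @param form Pairwise functional form: `"geometric"` (default),
#'   `"ic"` or `"jaccard"`.
#' @return Non-negative numeric scalar.
#' @export
term_similarity <- function(ont, ic, t_query, t_hit,
                            form = c("geometric", "ic", "jaccard")) {
  form <- match.arg(form)
  assert_term(ont, c(t_query, t_hit))
  a <- ont$ancestors[[t_query]]
  b <- ont$ancestors[[t_hit]]
  common <- intersect(a, b)
  if (!length(common)) return(0)
  j <- length(common) / (length(a) + length(b) - length(common))
  m <- max(ic$ic[common])
  switch(form,
         geometric = sqrt(j * m),
         ic = m,
         jaccard = j)
}

#' Best cross-species hit for every query term
#'
#' For each query (disease HPO) term, finds the hit (model MP) term with
#' maximal pairwise similarity. Ties are broken by the lexicographically
#' smallest hit id. When a query term has no positive similarity with any
#' hit, the match is recorded with `hit_term = NA`, `pair_score = 0`.
#'
#' @inheritParams term_similarity
#' @param query_terms,hit_terms Non-empty character vectors of term ids.
#' @return Tibble with one row per query term: `query_term`, `hit_term`,
#'   `pair_score`, `subsumer` (the MICA term id, `NA` for zero scores).
#' @export
best_matches <- function(ont, ic, query_terms, hit_terms,
                         form = "geometric") {
  query_terms <- unique(as.character(query_terms))
  hit_terms <- unique(as.character(hit_terms))
  if (!length(query_terms)) stop("query term set is empty", call. = FALSE)
  if (!length(hit_terms)) stop("hit term set is empty", call. = FALSE)
  assert_term(ont, c(query_terms, hit_terms))

  hit_terms <- sort(hit_terms)
  rows <- lapply(query_terms, function(q) {
    sims <- vapply(hit_terms, function(h) {
      term_similarity(ont, ic, q, h, form = form)
    }, numeric(1L))
    best <- max(sims)
    if (best <= 0) {
      return(tibble::tibble(query_term = q, hit_term = NA_character_,
                            pair_score = 0, subsumer = NA_character_))
    }
    h <- hit_terms[sims == best][1L] # hit_terms sorted: smallest id wins ties
    tibble::tibble(query_term = q, hit_term = h, pair_score = best,
                   subsumer = mica(ont, ic, q, h)$term)
  })
  dplyr::bind_rows(rows)
}

#' Disease self-comparison optimum
#'
#' The score a hypothetical mouse model perfectly mimicking every disease
#' phenotype would achieve: the maximum and mean over the disease terms of
#' their self-similarities \eqn{\sqrt{1 \times IC(t)}}.
#'
#' @inheritParams term_similarity
#' @param disease_terms Non-empty character vector of term ids.
#' @return Named list with `opt_max` and `opt_mean`.
#' @export
optimal_self <- function(ont, ic, disease_terms) {
  disease_terms <- unique(as.character(disease_terms))
  if (!length(disease_terms)) stop("disease term set is empty", call. = FALSE)
  assert_term(ont, disease_terms)
  s <- sqrt(pmax(ic$ic[disease_terms], 0))
  list(opt_max = max(s), opt_mean = mean(s))
}

#' PhenoDigm percentage score for one model--disease pair
#'
#' The disease's HPO terms are the queries (the default, anchored direction);
#' each is matched against the model's MP terms with [best_matches()]. The
#' raw maximum and mean of the per-query best scores are each normalised by
#' the disease self-comparison optimum from [optimal_self()] and averaged
#' with equal weight:
#' \deqn{percentage = 100 \times \frac{raw\_max/opt\_max +
#'   raw\_mean/opt\_mean}{2}}
#' clamped to \[0, 100\]. A degenerate disease annotated only to zero-IC
#' roots (opt_max = 0) scores 0. Setting `bidirectional = TRUE` averages the
#' score with the reverse-direction score (model MP terms as queries against
#' their own self-optimum); the default is query-only and the two directions
#' are not required to be equal.
#'
#' @inheritParams term_similarity
#' @param disease_terms,model_terms Non-empty character vectors of term ids.
#' @param model_id,disease_id Optional identifiers carried into the result.
#' @param bidirectional Average with the reversed-role score (default FALSE).
#' @return A `phenodigm_score` object: list with `model_id`, `disease_id`,
#'   `raw_max`, `raw_mean`, `percentage` and `matches` (the [best_matches()]
#'   tibble).
#' @examples
#' ont <- parse_obo(c(
#'   "[Term]", "id: R", "",
#'   "[Term]", "id: HP:0000001", "is_a: R", "",
#'   "[Term]", "id: MP:0000001", "is_a: R"
#' ))
#' ic <- information_content(ont, list(d = "HP:0000001", m = "MP:0000001"))
#' phenodigm_score(ont, ic, "HP:0000001", "MP:0000001")$percentage
#' @export
phenodigm_score <- function(ont, ic, disease_terms, model_terms,
                            model_id = NA_character_,
                            disease_id = NA_character_,
                            form = "geometric", bidirectional = FALSE) {
  b <- best_matches(ont, ic, disease_terms, model_terms, form = form)
  raw_max <- max(b$pair_score)
  raw_mean <- mean(b$pair_score)
  opt <- optimal_self(ont, ic, disease_terms)
  pct <- if (opt$opt_max <= 0) {
    0
  } else {
    100 * (raw_max / opt$opt_max + raw_mean / opt$opt_mean) / 2
  }
  if (bidirectional) {
    rev_b <- best_matches(ont, ic, model_terms, disease_terms, form = form)
    rev_opt <- optimal_self(ont, ic, model_terms)
    rev_pct <- if (rev_opt$opt_max <= 0) {
      0
    } else {
      100 * (max(rev_b$pair_score) / rev_opt$opt_max +
               mean(rev_b$pair_score) / rev_opt$opt_mean) / 2
    }
    pct <- (pct + rev_pct) / 2
  }
  structure(
    list(model_id = model_id, disease_id = disease_id,
         raw_max = raw_max, raw_mean = raw_mean,
         percentage = min(max(pct, 0), 100), matches = b),
    class = "phenodigm_score"
  )
}

#' @export
print.phenodigm_score <- function(x, ...) {
  cat("<phenodigm_score> ", x$model_id, " vs ", x$disease_id, ": ",
      sprintf("%.2f%%", x$percentage),
      " (raw max ", format(x$raw_max, digits = 4),
      ", raw mean ", format(x$raw_mean, digits = 4), ")\n", sep = "")
  invisible(x)
}

# Scalar pairwise similarity with memoisation over an environment keyed by
# "query\rhit". Used by score_pairs to avoid recomputing the (few) distinct
# term pairs a study touches many times.
memo_similarity <- function(ont, ic, memo, q, h, form) {
  key <- paste0(q, "\r", h)
  v <- memo[[key]]
  if (is.null(v)) {
    v <- term_similarity(ont, ic, q, h, form = form)
    memo[[key]] <- v
  }
  v
}

#' Score a table of model--disease pairs
#'
#' Vectorised driver over the pairs produced by [eligible_pairs()]:
#' computes [phenodigm_score()] for each pair, memoising pairwise term
#' similarities and per-disease self-optima across the study.
#'
#' @inheritParams term_similarity
#' @param pairs Tibble with columns `model_id`, `disease_id`, `mouse_gene`,
#'   `human_gene` (see [eligible_pairs()]).
#' @param models,diseases Catalogue tibbles as returned by [read_models()]
#'   and [read_diseases()] (list-columns `mp_terms` / `hpo_terms`).
#' @return `pairs` with columns `raw_max`, `raw_mean`, `percentage` and
#'   `is_match` appended. Percentages are kept at full precision here;
#'   writers round to 2 decimals.
#' @export
score_pairs <- function(ont, ic, pairs, models, diseases,
                        form = "geometric") {
  mp_by_model <- stats::setNames(models$mp_terms, models$model_id)
  hpo_by_disease <- stats::setNames(diseases$hpo_terms, diseases$disease_id)
  memo <- new.env(hash = TRUE, parent = emptyenv())
  opt_memo <- new.env(hash = TRUE, parent = emptyenv())

  n <- nrow(pairs)
  raw_max <- raw_mean <- pct <- numeric(n)
  for (i in seq_len(n)) {
    qs <- unique(hpo_by_disease[[pairs$disease_id[i]]])
    hs <- unique(mp_by_model[[pairs$model_id[i]]])
    best <- vapply(qs, function(q) {
      max(vapply(hs, function(h) {
        memo_similarity(ont, ic, memo, q, h, form)
      }, numeric(1L)))
    }, numeric(1L))
    raw_max[i] <- max(best)
    raw_mean[i] <- mean(best)
    opt <- opt_memo[[pairs$disease_id[i]]]
    if (is.null(opt)) {
      opt <- optimal_self(ont, ic, qs)
      opt_memo[[pairs$disease_id[i]]] <- opt
    }
    pct[i] <- if (opt$opt_max <= 0) {
      0
    } else {
      min(max(100 * (raw_max[i] / opt$opt_max +
                       raw_mean[i] / opt$opt_mean) / 2, 0), 100)
    }
  }
  dplyr::mutate(pairs, raw_max = raw_max, raw_mean = raw_mean,
                percentage = pct, is_match = pct > 0)
}
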