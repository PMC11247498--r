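# Pipeline orchestration: eligibility, match calling, gene-level
# aggregation, novelty vs an external catalogue, lethality rescue, and the
# end-to-end driver with file writers.

#' Eligible model--disease pairs
#'
#' The scorer requires MP-encoded phenotypes for the mouse knockout and
#' HPO-encoded phenotypes for the associated disease. Eligible pairs are
#' all (model, disease) combinations where the model's mouse gene maps to
#' the disease's human gene under the one-to-one ortholog map, the model
#' has at least one MP term and the disease at least one HPO term.
#'
#' @param models,diseases Catalogue tibbles ([read_models()],
#'   [read_diseases()]).
#' @param ortholog_map Bijective mapping tibble from
#'   [one_to_one_orthologs()].
#' @return Tibble with columns `model_id`, `disease_id`, `mouse_gene`,
#'   `human_gene`, ordered by (`model_id`, `disease_id`).
#' @export
eligible_pairs <- function(models, diseases, ortholog_map) {
  m <- dplyr::filter(models, lengths(.data$mp_terms) > 0L)
  d <- dplyr::filter(diseases, lengths(.data$hpo_terms) > 0L)
  pairs <- dplyr::inner_join(
    dplyr::select(m, "model_id", "mouse_gene"),
    ortholog_map,
    by = "mouse_gene"
  )
  pairs <- dplyr::inner_join(
    pairs,
    dplyr::select(d, "disease_id", "human_gene"),
    by = "human_gene",
    relationship = "many-to-many"
  )
  dplyr::arrange(
    dplyr::select(pairs, "model_id", "disease_id", "mouse_gene",
                  "human_gene"),
    .data$model_id, .data$disease_id
  )
}

#' Call a PhenoDigm match
#'
#' A pair (or gene) is a match when its percentage score is strictly
#' greater than 0, which implies at least one informative HPO--MP term
#' match. The boundary value 0 is excluded.
#'
#' @param score A `phenodigm_score` object or a numeric percentage vector.
#' @return Logical vector.
#' @export
call_match <- function(score) {
  if (inherits(score, "phenodigm_score")) score <- score$percentage
  as.numeric(score) > 0
}

#' Aggregate pair scores to gene level
#'
#' Multiple mouse models may exist for a gene (embryo/adult,
#' heterozygous/homozygous) and several disorders may be associated with
#' its human ortholog; the gene-level result keeps the best-scoring pair.
#' Ties on the maximum percentage are broken by the lexicographically
#' smallest (`model_id`, `disease_id`) pair for determinism.
#'
#' @param pair_scores Tibble from [score_pairs()].
#' @return Tibble with one row per human gene: `human_gene`, `mouse_gene`,
#'   `best_percentage`, `best_model_id`, `best_disease_id`, `is_match`,
#'   `rescue` (initialised to `"none"`), `n_models_scored`,
#'   `n_diseases_scored`.
#' @export
aggregate_gene <- function(pair_scores) {
  ordered <- dplyr::arrange(pair_scores, .data$model_id, .data$disease_id)
  out <- dplyr::summarise(
    dplyr::group_by(ordered, .data$human_gene, .data$mouse_gene),
    best_percentage = max(.data$percentage),
    best_model_id = .data$model_id[which.max(.data$percentage)],
    best_disease_id = .data$disease_id[which.max(.data$percentage)],
    n_models_scored = dplyr::n_distinct(.data$model_id),
    n_diseases_scored = dplyr::n_distinct(.data$disease_id),
    .groups = "drop"
  )
  out <- dplyr::mutate(out,
                       is_match = .data$best_percentage > 0,
                       rescue = "none")
  dplyr::arrange(
    dplyr::select(out, "human_gene", "mouse_gene", "best_percentage",
                  "best_model_id", "best_disease_id", "is_match", "rescue",
                  "n_models_scored", "n_diseases_scored"),
    .data$human_gene
  )
}

#' Genes whose model is novel versus an external catalogue
#'
#' A matched gene is novel when the external (MGI-style) catalogue has no
#' model for the gene at all, or none of its external models achieves a
#' positive percentage against the associated disease phenotypes.
#'
#' @param gene_results Tibble from [aggregate_gene()].
#' @param external_scores Tibble with columns `human_gene`,
#'   `best_percentage` giving each gene's best external-model score; genes
#'   may be absent.
#' @return Character vector of novel human genes.
#' @export
novel_vs_external <- function(gene_results, external_scores) {
  matched <- gene_results$human_gene[gene_results$is_match]
  ext <- stats::setNames(external_scores$best_percentage,
                         external_scores$human_gene)
  has_ext_match <- !is.na(ext[matched]) & ext[matched] > 0
  sort(matched[!has_ext_match])
}

#' Lethality-based rescue of non-matched genes
#'
#' Genes without a phenotype match can still be called by comparing
#' preweaning lethality in the mouse with curated reports of early death in
#' the human clinical records: a non-matched gene is rescued when any of
#' its models is preweaning lethal and any associated disease carries a
#' `pre_infant` early-death annotation; with `include_childhood = TRUE`,
#' `childhood` annotations also rescue. Matched genes are never relabelled,
#' so rescues are additive to, not overlapping with, phenotype matches.
#'
#' @param gene_results Tibble from [aggregate_gene()].
#' @param models,diseases Catalogue tibbles.
#' @param include_childhood Also rescue on childhood death (default FALSE).
#' @return `gene_results` with the `rescue` column updated to
#'   `"pre_infant"` or `"childhood"` where the rule applies.
#' @export
lethality_rescue <- function(gene_results, models, diseases,
                             include_childhood = FALSE) {
  lethal_genes <- unique(models$mouse_gene[models$preweaning_lethal])
  death_by_gene <- function(level) {
    unique(diseases$human_gene[diseases$early_death == level])
  }
  pre_infant_genes <- death_by_gene("pre_infant")
  childhood_genes <- death_by_gene("childhood")

  eligible <- !gene_results$is_match &
    gene_results$mouse_gene %in% lethal_genes
  rescue <- gene_results$rescue
  rescue[eligible & gene_results$human_gene %in% pre_infant_genes] <-
    "pre_infant"
  if (include_childhood) {
    idx <- eligible & rescue == "none" &
      gene_results$human_gene %in% childhood_genes
    rescue[idx] <- "childhood"
  }
  gene_results$rescue <- rescue
  gene_results
}

#' Best external-model percentage per gene
#'
#' Scores an external (MGI-style) model catalogue against the study
#' diseases with the same ontology, IC table and scorer used for the
#' primary models, and keeps each gene's best percentage.
#'
#' @inheritParams score_pairs
#' @param external External model tibble ([read_external_models()]).
#' @param diseases Disease catalogue tibble.
#' @param ortholog_map Bijection from [one_to_one_orthologs()].
#' @return Tibble with columns `human_gene`, `best_percentage`.
#' @export
score_external <- function(ont, ic, external, diseases, ortholog_map,
                           form = "geometric") {
  pairs <- eligible_pairs(
    dplyr::mutate(external,
                  zygosity = "homozygous", life_stage = "early_adult",
                  viability = "unknown", n_procedures = 0L,
                  preweaning_lethal = FALSE),
    diseases, ortholog_map
  )
  if (!nrow(pairs)) {
    return(tibble::tibble(human_gene = character(0),
                          best_percentage = numeric(0)))
  }
  scored <- score_pairs(ont, ic, pairs, external, diseases, form = form)
  dplyr::summarise(dplyr::group_by(scored, .data$human_gene),
                   best_percentage = max(.data$percentage),
                   .groups = "drop")
}

#' Default information-content corpus for a study
#'
#' The union of all disease HPO annotation sets and all model MP annotation
#' sets (entities with empty annotation sets are dropped; they carry no
#' frequency information).
#'
#' @param models,diseases Catalogue tibbles.
#' @return Named list of character vectors, one entry per annotated entity.
#' @export
build_ic_corpus <- function(models, diseases) {
  c(
    stats::setNames(diseases$hpo_terms, diseases$disease_id)[
      lengths(diseases$hpo_terms) > 0L],
    stats::setNames(models$mp_terms, models$model_id)[
      lengths(models$mp_terms) > 0L]
  )
}

#' Run the full disease-model identification pipeline
#'
#' Applies the one-to-one ortholog filter, builds the IC table over the
#' study corpus (unless one is supplied), scores every eligible
#' model--disease pair, aggregates to gene level, flags genes novel versus
#' the external catalogue (when given) and applies the lethality-rescue
#' rule.
#'
#' @param ont A `phen_ontology`.
#' @param models,diseases,orthologs Catalogue tibbles.
#' @param external Optional external model tibble
#'   ([read_external_models()]).
#' @param include_childhood Passed to [lethality_rescue()].
#' @param ic Optional pre-computed `phen_ic`; default is built from
#'   [build_ic_corpus()].
#' @param min_support Ortholog support threshold (default 5).
#' @param form Pairwise similarity form; see [term_similarity()].
#' @return A `phenomatch_run`: list with `pair_scores`, `gene_results`
#'   (including `novel_vs_external` when `external` is given),
#'   `external_scores`, `ic` and `summary` (counts of genes scored,
#'   matches, rescues and novel genes).
#' @export
run_pipeline <- function(ont, models, diseases, orthologs, external = NULL,
                         include_childhood = FALSE, ic = NULL,
                         min_support = 5L, form = "geometric") {
  ortholog_map <- one_to_one_orthologs(orthologs, min_support = min_support)
  if (is.null(ic)) {
    ic <- information_content(ont, build_ic_corpus(models, diseases))
  }
  pairs <- eligible_pairs(models, diseases, ortholog_map)
  pair_scores <- score_pairs(ont, ic, pairs, models, diseases, form = form)
  gene_results <- aggregate_gene(pair_scores)

  external_scores <- NULL
  if (!is.null(external) && nrow(external)) {
    external_scores <- score_external(ont, ic, external, diseases,
                                      ortholog_map, form = form)
    novel <- novel_vs_external(gene_results, external_scores)
    gene_results$novel_vs_external <-
      gene_results$is_match & gene_results$human_gene %in% novel
  }
  gene_results <- lethality_rescue(gene_results, models, diseases,
                                   include_childhood = include_childhood)

  summary <- list(
    n_pairs_scored = nrow(pair_scores),
    n_genes_scored = nrow(gene_results),
    n_matches = sum(gene_results$is_match),
    match_rate = if (nrow(gene_results)) {
      mean(gene_results$is_match)
    } else {
      NA_real_
    },
    n_rescued = sum(gene_results$rescue != "none"),
    n_novel = if (is.null(external_scores)) {
      NA_integer_
    } else {
      sum(gene_results$novel_vs_external)
    }
  )
  structure(
    list(pair_scores = pair_scores, gene_results = gene_results,
         external_scores = external_scores, ic = ic, summary = summary),
    class = "phenomatch_run"
  )
}

#' @export
print.phenomatch_run <- function(x, ...) {
  s <- x$summary
  cat("<phenomatch_run> ", s$n_pairs_scored, " pairs over ",
      s$n_genes_scored, " genes; ", s$n_matches, " matched genes (",
      sprintf("%.1f%%", 100 * s$match_rate), "), ", s$n_rescued,
      " rescued", if (!is.na(s$n_novel)) {
        paste0(", ", s$n_novel, " novel vs external")
      } else {
        ""
      }, "\n", sep = "")
  invisible(x)
}

#' Write pipeline outputs
#'
#' Writes `pair_scores.tsv` (one row per scored pair; percentages reported
#' to 2 decimals), `gene_results.tsv` and `summary.json` into `dir`.
#'
#' @param run A `phenomatch_run` from [run_pipeline()].
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_pipeline_outputs <- function(run, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ps <- dplyr::mutate(run$pair_scores,
                      raw_max = round(.data$raw_max, 6),
                      raw_mean = round(.data$raw_mean, 6),
                      percentage = round(.data$percentage, 2))
  readr::write_tsv(ps, file.path(dir, "pair_scores.tsv"))
  gr <- dplyr::mutate(run$gene_results,
                      best_percentage = round(.data$best_percentage, 2))
  readr::write_tsv(gr, file.path(dir, "gene_results.tsv"))
  jsonlite::write_json(run$summary, file.path(dir, "summary.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(dir)
}
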