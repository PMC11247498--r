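# Tabular catalogue readers/writers and the one-to-one ortholog filter.
#
# Schemas (tab-separated, header row required; term lists are
# semicolon-delimited within one column):
#   models.tsv:    model_id, mouse_gene, zygosity, life_stage, viability,
#                  mp_terms, n_procedures, preweaning_lethal
#   diseases.tsv:  disease_id, human_gene, hpo_terms, moi, category,
#                  early_death, evidence
#   orthologs.tsv: human_gene_symbol, mouse_gene_symbol, support_count
#   external.tsv:  model_id, mouse_gene, mp_terms

ZYGOSITY_LEVELS <- c("homozygous", "heterozygous", "hemizygous")
LIFE_STAGE_LEVELS <- c("embryo", "early_adult")
VIABILITY_LEVELS <- c("lethal", "subviable", "viable", "unknown")
MOI_LEVELS <- c("AD", "AR", "AD&AR", "other")
EARLY_DEATH_LEVELS <- c("none", "pre_infant", "childhood")
EVIDENCE_LEVELS <- c("green", "amber", "red")

#' Default high-level disease categories
#'
#' The declared label set for disease records, modelled on high-level
#' (PanelApp level-2-style) disease classes. [read_diseases()] validates
#' against this set unless another is supplied.
#'
#' @return Character vector of category labels.
#' @export
disease_categories <- function() {
  c("cardiovascular", "dysmorphic and congenital", "endocrine",
    "haematology and immunology", "metabolic",
    "neurology and neurodevelopmental", "ophthalmological",
    "renal and urinary tract", "respiratory", "skeletal")
}

TERM_ID_REGEX <- "^(HP|MP):[0-9]{7}$"

split_terms <- function(x) {
  lapply(x, function(cell) {
    if (is.na(cell) || !nzchar(cell)) return(character(0))
    unique(trimws(strsplit(cell, ";", fixed = TRUE)[[1L]]))
  })
}

collapse_terms <- function(x) {
  vapply(x, paste, character(1L), collapse = ";")
}

check_enum <- function(x, levels, column) {
  bad <- which(!(x %in% levels))
  if (length(bad)) {
    stop("invalid ", column, " value \"", x[bad[1L]], "\" in row ", bad[1L],
         " (allowed: ", paste(levels, collapse = ", "), ")", call. = FALSE)
  }
}

check_terms <- function(terms, column) {
  for (i in seq_along(terms)) {
    bad <- terms[[i]][!grepl(TERM_ID_REGEX, terms[[i]])]
    if (length(bad)) {
      stop("malformed term id \"", bad[1L], "\" in ", column, ", row ", i,
           call. = FALSE)
    }
  }
}

check_columns <- function(df, required, what) {
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(what, " is missing required column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }
}

#' Read a mouse model catalogue
#'
#' One row per mutant line: gene, zygosity, life stage, homozygote
#' viability, the significant MP terms called by the phenotyping pipeline
#' (semicolon-delimited; may be empty, which makes the record ineligible
#' for scoring), the number of phenotyping procedures completed and a
#' preweaning-lethality flag. Validation errors name the offending row.
#'
#' @param path Path to a models TSV.
#' @return Tibble with `mp_terms` as a list-column of character vectors.
#' @export
read_models <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      model_id = readr::col_character(),
      mouse_gene = readr::col_character(),
      zygosity = readr::col_character(),
      life_stage = readr::col_character(),
      viability = readr::col_character(),
      mp_terms = readr::col_character(),
      n_procedures = readr::col_integer(),
      preweaning_lethal = readr::col_logical()
    ),
    progress = FALSE
  )
  check_columns(df, c("model_id", "mouse_gene", "zygosity", "life_stage",
                      "viability", "mp_terms", "n_procedures",
                      "preweaning_lethal"), "models table")
  check_enum(df$zygosity, ZYGOSITY_LEVELS, "zygosity")
  check_enum(df$life_stage, LIFE_STAGE_LEVELS, "life_stage")
  check_enum(df$viability, VIABILITY_LEVELS, "viability")
  if (any(bad <- df$n_procedures < 0L, na.rm = TRUE)) {
    stop("negative n_procedures in row ", which(bad)[1L], call. = FALSE)
  }
  bad <- which(df$viability == "lethal" & !df$preweaning_lethal)
  if (length(bad)) {
    stop("viability \"lethal\" requires preweaning_lethal TRUE (row ",
         bad[1L], ")", call. = FALSE)
  }
  terms <- split_terms(df$mp_terms)
  check_terms(terms, "mp_terms")
  df$mp_terms <- terms
  df
}

#' Read a Mendelian disease catalogue
#'
#' One row per disorder: OMIM/Orphanet-style id, the associated human gene,
#' HPO terms (semicolon-delimited; may be empty, making the record
#' ineligible), mode of inheritance, high-level disease category, a curated
#' early-death annotation and the evidence grade for the gene--disease
#' association.
#'
#' @param path Path to a diseases TSV.
#' @param categories Declared category label set (default
#'   [disease_categories()]).
#' @return Tibble with `hpo_terms` as a list-column.
#' @export
read_diseases <- function(path, categories = disease_categories()) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      disease_id = readr::col_character(),
      human_gene = readr::col_character(),
      hpo_terms = readr::col_character(),
      moi = readr::col_character(),
      category = readr::col_character(),
      early_death = readr::col_character(),
      evidence = readr::col_character()
    ),
    progress = FALSE
  )
  check_columns(df, c("disease_id", "human_gene", "hpo_terms", "moi",
                      "category", "early_death", "evidence"),
                "diseases table")
  check_enum(df$moi, MOI_LEVELS, "moi")
  check_enum(df$category, categories, "category")
  check_enum(df$early_death, EARLY_DEATH_LEVELS, "early_death")
  check_enum(df$evidence, EVIDENCE_LEVELS, "evidence")
  terms <- split_terms(df$hpo_terms)
  check_terms(terms, "hpo_terms")
  df$hpo_terms <- terms
  df
}

#' Read an ortholog prediction table
#'
#' Columns follow the GenTaR-style export: `human_gene_symbol`,
#' `mouse_gene_symbol` and `support_count`, the number of orthology
#' prediction services (0--12) agreeing on the pair.
#'
#' @param path Path to an orthologs TSV.
#' @return Tibble with columns `human_gene`, `mouse_gene`, `support`.
#' @export
read_orthologs <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      human_gene_symbol = readr::col_character(),
      mouse_gene_symbol = readr::col_character(),
      support_count = readr::col_integer()
    ),
    progress = FALSE
  )
  check_columns(df, c("human_gene_symbol", "mouse_gene_symbol",
                      "support_count"), "orthologs table")
  bad <- which(df$support_count < 0L | df$support_count > 12L)
  if (length(bad)) {
    stop("support_count out of range 0-12 in row ", bad[1L], call. = FALSE)
  }
  tibble::tibble(human_gene = df$human_gene_symbol,
                 mouse_gene = df$mouse_gene_symbol,
                 support = df$support_count)
}

#' Read an external (MGI-style) model catalogue
#'
#' Non-IMPC mouse models with their MP annotations, used as the
#' "previous model" baseline for novelty calling.
#'
#' @param path Path to an external models TSV.
#' @return Tibble with `mp_terms` as a list-column.
#' @export
read_external_models <- function(path) {
  df <- readr::read_tsv(
    path,
    col_types = readr::cols(
      model_id = readr::col_character(),
      mouse_gene = readr::col_character(),
      mp_terms = readr::col_character()
    ),
    progress = FALSE
  )
  check_columns(df, c("model_id", "mouse_gene", "mp_terms"),
                "external models table")
  terms <- split_terms(df$mp_terms)
  check_terms(terms, "mp_terms")
  df$mp_terms <- terms
  df
}

#' Bidirectional one-to-one ortholog filter
#'
#' Drops ortholog predictions supported by fewer than `min_support` of the
#' 12 prediction services, then keeps only pairs that are one-to-one in
#' both directions among the surviving records: the human gene maps to
#' exactly one mouse gene and that mouse gene maps back to exactly one
#' human gene. The threshold is applied before the bijectivity test, so a
#' low-support paralog cannot veto a high-support one-to-one pair. The
#' result is a bijection on its domain (possibly empty).
#'
#' @param orthologs Tibble with columns `human_gene`, `mouse_gene`,
#'   `support` (see [read_orthologs()]).
#' @param min_support Minimum number of agreeing prediction services
#'   (default 5; "five or more of the 12").
#' @return Tibble with columns `human_gene`, `mouse_gene`.
#' @export
one_to_one_orthologs <- function(orthologs, min_support = 5L) {
  kept <- dplyr::distinct(
    dplyr::filter(orthologs, .data$support >= min_support),
    .data$human_gene, .data$mouse_gene
  )
  kept <- dplyr::add_count(kept, .data$human_gene, name = "n_mouse")
  kept <- dplyr::add_count(kept, .data$mouse_gene, name = "n_human")
  out <- dplyr::filter(kept, .data$n_mouse == 1L, .data$n_human == 1L)
  dplyr::select(out, "human_gene", "mouse_gene")
}

#' @rdname read_models
#' @param models Tibble as returned by [read_models()].
#' @param path Output path.
#' @export
write_models <- function(models, path) {
  models$mp_terms <- collapse_terms(models$mp_terms)
  readr::write_tsv(models, path)
  invisible(path)
}

#' @rdname read_diseases
#' @param diseases Tibble as returned by [read_diseases()].
#' @export
write_diseases <- function(diseases, path) {
  diseases$hpo_terms <- collapse_terms(diseases$hpo_terms)
  readr::write_tsv(diseases, path)
  invisible(path)
}

#' @rdname read_orthologs
#' @param orthologs Tibble with columns `human_gene`, `mouse_gene`,
#'   `support`.
#' @export
write_orthologs <- function(orthologs, path) {
  readr::write_tsv(
    tibble::tibble(human_gene_symbol = orthologs$human_gene,
                   mouse_gene_symbol = orthologs$mouse_gene,
                   support_count = orthologs$support),
    path
  )
  invisible(path)
}

#' @rdname read_external_models
#' @param external Tibble as returned by [read_external_models()].
#' @export
write_external_models <- function(external, path) {
  external$mp_terms <- collapse_terms(external$mp_terms)
  readr::write_tsv(external, path)
  invisible(path)
}
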