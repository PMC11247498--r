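# Association layer: per-category enrichment of matches, bivariate
# comparisons, correlations, and the logistic regression of match status
# on model/gene/disease features.

# Two-sided Fisher exact p for one 2x2 table; thin wrapper kept as a named
# unit so the enrichment loop and the enumeration-oracle tests share one
# entry point.
fisher_p <- function(a, b, c, d) {
  stats::fisher.test(matrix(c(a, b, c, d), nrow = 2L, byrow = TRUE),
                     alternative = "two.sided")$p.value
}

#' Per-category enrichment of phenotype matches
#'
#' For each disease category, builds the 2x2 table of matched / non-matched
#' genes inside versus outside the category, computes the sample odds ratio
#' `ad/bc` with a Wald log confidence interval, a two-sided Fisher exact
#' p-value, and Benjamini-Hochberg q-values over the family of categories
#' tested. Genes annotated to several categories contribute to each
#' category's table; out-of-category cells count distinct genes not in the
#' category.
#'
#' The odds ratio is `Inf` when `bc = 0` with `a, d > 0`, and `NA` when a
#' margin is empty (undefined). The Wald CI is reported only when all four
#' cells are positive.
#'
#' @param gene_table Tibble with columns `gene`, `category`, `is_match`
#'   (one row per gene-category pair; a gene's match status must be
#'   constant across its rows).
#' @param conf_level Confidence level for the Wald interval (default 0.95).
#' @return Tibble with one row per category: `category`, `a`, `b`, `c`,
#'   `d`, `odds_ratio`, `ci_low`, `ci_high`, `p_value`, `q_value`.
#' @export
category_enrichment <- function(gene_table, conf_level = 0.95) {
  stopifnot(all(c("gene", "category", "is_match") %in% names(gene_table)))
  cats <- sort(unique(gene_table$category))
  if (length(cats) < 2L) {
    stop("category enrichment requires at least two categories",
         call. = FALSE)
  }
  match_by_gene <- tapply(gene_table$is_match, gene_table$gene, any)
  genes <- names(match_by_gene)

  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  rows <- lapply(cats, function(ct) {
    in_cat <- genes %in% gene_table$gene[gene_table$category == ct]
    a <- sum(in_cat & match_by_gene)
    b <- sum(in_cat & !match_by_gene)
    c_ <- sum(!in_cat & match_by_gene)
    d <- sum(!in_cat & !match_by_gene)
    or <- if ((a + b) == 0L || (c_ + d) == 0L ||
              (a + c_) == 0L || (b + d) == 0L) {
      NA_real_
    } else if (b * c_ == 0) {
      if (a > 0 && d > 0) Inf else NA_real_
    } else {
      (a * d) / (b * c_)
    }
    if (!is.na(or) && is.finite(or) && min(a, b, c_, d) > 0L) {
      se <- sqrt(1 / a + 1 / b + 1 / c_ + 1 / d)
      ci_low <- exp(log(or) - z * se)
      ci_high <- exp(log(or) + z * se)
    } else {
      ci_low <- ci_high <- NA_real_
    }
    tibble::tibble(category = ct, a = a, b = b, c = c_, d = d,
                   odds_ratio = or, ci_low = ci_low, ci_high = ci_high,
                   p_value = fisher_p(a, b, c_, d))
  })
  out <- dplyr::bind_rows(rows)
  out$q_value <- stats::p.adjust(out$p_value, method = "BH")
  out
}

#' Compare annotation counts between matches and non-matches
#'
#' Two-sided Wilcoxon rank-sum test, used to compare the number of HPO or
#' MP terms between phenotype matches and non-matches. Small untied
#' samples use the exact distribution; ties or samples above 50 per group
#' fall back to the midrank normal approximation (the default behaviour of
#' [stats::wilcox.test()]).
#'
#' @param x,y Non-empty numeric vectors (e.g. term counts in matches and
#'   in non-matches).
#' @return Two-sided p-value.
#' @export
compare_counts <- function(x, y) {
  if (!length(x) || !length(y)) {
    stop("both samples must be non-empty", call. = FALSE)
  }
  suppressWarnings(stats::wilcox.test(x, y, alternative = "two.sided",
                                      exact = NULL)$p.value)
}

#' Pearson correlation
#'
#' Standard product-moment coefficient, with explicit validation of the
#' degenerate inputs that would otherwise return `NA` silently.
#'
#' @param x,y Numeric vectors of equal length >= 3 with non-zero variance.
#' @return Pearson r in \[-1, 1\].
#' @export
correlate <- function(x, y) {
  if (length(x) != length(y)) stop("x and y must have equal length",
                                   call. = FALSE)
  if (length(x) < 3L) stop("correlation requires at least 3 observations",
                           call. = FALSE)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stop("zero variance input", call. = FALSE)
  }
  stats::cor(x, y, method = "pearson")
}

#' Pair-level feature table for the regression layer
#'
#' Joins model features (zygosity, viability, procedures completed, number
#' of significant MP terms) and disease features (number of HPO terms,
#' category, early-death annotation, mode of inheritance) onto the scored
#' pairs; the regression's unit of analysis is the model--disease pair.
#'
#' @param pair_scores Tibble from [score_pairs()].
#' @param models,diseases Catalogue tibbles.
#' @return Tibble with one row per scored pair and the feature columns
#'   used by [fit_match_model()].
#' @export
pair_feature_table <- function(pair_scores, models, diseases) {
  m <- dplyr::mutate(
    dplyr::select(models, "model_id", "zygosity", "life_stage",
                  "viability", "n_procedures", mp = "mp_terms"),
    n_mp_terms = lengths(.data$mp)
  )
  d <- dplyr::mutate(
    dplyr::select(diseases, "disease_id", "moi", "category", "early_death",
                  hpo = "hpo_terms"),
    n_hpo_terms = lengths(.data$hpo)
  )
  out <- dplyr::left_join(pair_scores, dplyr::select(m, -"mp"),
                          by = "model_id")
  out <- dplyr::left_join(out, dplyr::select(d, -"hpo"), by = "disease_id")
  out
}

#' Logistic regression of match status on model, gene and disease features
#'
#' Maximum-likelihood logistic fit (no penalty) of the binary match
#' indicator on the supplied features, with Wald 95% confidence intervals.
#' Continuous covariates are standardised to z-scores before fitting, so
#' their coefficients are comparable per-standard-deviation effects.
#' Categorical features are one-hot encoded against a declared reference
#' level: heterozygous for zygosity (hemizygous is pooled with homozygous),
#' viable for viability, the alphabetically first category for the disease
#' class, `AR` for mode of inheritance; `early_death` enters as a binary
#' indicator (any early death vs none).
#'
#' Convergence failure and (quasi-)complete separation are flagged as
#' errors rather than silently returning unstable estimates.
#'
#' @param pair_table Tibble such as from [pair_feature_table()] (or any
#'   table with the outcome and feature columns).
#' @param outcome Name of the logical/binary outcome column (default
#'   `"is_match"`).
#' @param features Character vector of feature columns to use; default is
#'   every recognised feature present in `pair_table`.
#' @param conf_level Wald interval level (default 0.95).
#' @return A `phen_logit`: list with `coefficients` (tibble of `term`,
#'   `estimate`, `se`, `ci_low`, `ci_high`, `p_value`), `n`, `converged`,
#'   `features` and the underlying `fit`.
#' @export
fit_match_model <- function(pair_table, outcome = "is_match",
                            features = NULL, conf_level = 0.95) {
  known <- c("n_procedures", "n_mp_terms", "n_hpo_terms", "zygosity",
             "viability", "category", "early_death", "moi")
  if (is.null(features)) features <- intersect(known, names(pair_table))
  missing <- setdiff(c(outcome, features), names(pair_table))
  if (length(missing)) {
    stop("pair_table is missing column(s): ",
         paste(missing, collapse = ", "), call. = FALSE)
  }

  y <- as.integer(as.logical(pair_table[[outcome]]))
  keep <- !is.na(y)
  for (f in features) keep <- keep & !is.na(pair_table[[f]])
  df <- pair_table[keep, features, drop = FALSE]
  y <- y[keep]
  if (length(unique(y)) < 2L) {
    stop("outcome must contain both classes", call. = FALSE)
  }

  X <- list()
  for (f in features) {
    v <- df[[f]]
    if (is.numeric(v)) {
      if (stats::sd(v) == 0) {
        stop("feature '", f, "' is constant", call. = FALSE)
      }
      X[[f]] <- as.numeric(scale(v))
    } else if (f == "zygosity") {
      X[["homozygous"]] <- as.integer(v %in% c("homozygous", "hemizygous"))
    } else if (f == "early_death") {
      X[["early_death"]] <- as.integer(v != "none")
    } else if (f == "viability") {
      for (lv in setdiff(sort(unique(v)), "viable")) {
        X[[paste0("viability_", lv)]] <- as.integer(v == lv)
      }
    } else if (f == "moi") {
      for (lv in setdiff(sort(unique(v)), "AR")) {
        X[[paste0("moi_", make.names(lv))]] <- as.integer(v == lv)
      }
    } else { # category and any other factor-like feature
      lvs <- sort(unique(as.character(v)))
      for (lv in lvs[-1L]) {
        X[[paste0(f, "_", make.names(lv))]] <- as.integer(v == lv)
      }
    }
  }
  mm <- do.call(cbind, X)
  const <- apply(mm, 2L, function(col) stats::sd(col) == 0)
  if (any(const)) {
    stop("feature '", colnames(mm)[const][1L],
         "' is constant after encoding", call. = FALSE)
  }

  dat <- data.frame(.y = y, mm, check.names = FALSE)
  sep_warning <- FALSE
  fit <- withCallingHandlers(
    stats::glm(.y ~ ., data = dat, family = stats::binomial()),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("fitted probabilities numerically 0 or 1", msg) ||
          grepl("algorithm did not converge", msg)) {
        sep_warning <<- TRUE
        invokeRestart("muffleWarning")
      }
    }
  )
  est <- stats::coef(fit)
  if (sep_warning && any(abs(est[-1L]) > 10)) {
    stop("complete or quasi-complete separation detected; remove the ",
         "offending feature or use a penalised fit", call. = FALSE)
  }
  if (!fit$converged) {
    stop("logistic fit did not converge", call. = FALSE)
  }

  sm <- summary(fit)$coefficients
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  coefs <- tibble::tibble(
    term = rownames(sm),
    estimate = sm[, "Estimate"],
    se = sm[, "Std. Error"],
    ci_low = sm[, "Estimate"] - z * sm[, "Std. Error"],
    ci_high = sm[, "Estimate"] + z * sm[, "Std. Error"],
    p_value = sm[, "Pr(>|z|)"]
  )
  structure(
    list(coefficients = coefs, n = length(y), converged = fit$converged,
         features = features, fit = fit),
    class = "phen_logit"
  )
}

#' @export
print.phen_logit <- function(x, ...) {
  cat("<phen_logit> n = ", x$n, ", converged: ", x$converged, "\n",
      sep = "")
  print(as.data.frame(x$coefficients), digits = 3)
  invisible(x)
}

#' Write enrichment and regression tables
#'
#' Writes `enrichment.tsv` (category, 2x2 cells, OR, CI, p, q) and
#' `regression.tsv` (feature, estimate, ci_low, ci_high) into `dir`.
#'
#' @param enrichment Tibble from [category_enrichment()].
#' @param regression A `phen_logit` from [fit_match_model()], or `NULL`.
#' @param dir Output directory (created if absent).
#' @return `dir`, invisibly.
#' @export
write_stats_outputs <- function(enrichment, regression, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  enr <- dplyr::mutate(enrichment, dplyr::across(
    c("odds_ratio", "ci_low", "ci_high", "p_value", "q_value"),
    ~ round(.x, 6)
  ))
  readr::write_tsv(enr, file.path(dir, "enrichment.tsv"))
  if (!is.null(regression)) {
    reg <- dplyr::mutate(
      dplyr::select(regression$coefficients, feature = "term", "estimate",
                    "ci_low", "ci_high"),
      dplyr::across(c("estimate", "ci_low", "ci_high"), ~ round(.x, 6))
    )
    readr::write_tsv(reg, file.path(dir, "regression.tsv"))
  }
  invisible(dir)
}
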