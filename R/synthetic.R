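# Seeded synthetic-study generator: merged toy ontology with mirrored
# cross-species subtrees, and model/disease/ortholog/external catalogues
# with planted statistical structure (category enrichment, logistic match
# propensity, viability mix) so the whole pipeline is testable without the
# real consortium downloads.

derive_seed <- function(seed, k) {
  as.integer((as.numeric(seed) %% 1048576 * 1000003 + k * 7919) %% 2147483629)
}

sample_vec <- function(x, size, replace = FALSE, prob = NULL) {
  x[sample.int(length(x), size, replace = replace, prob = prob)]
}

#' Synthetic-study configuration
#'
#' The generator's stated world. Defaults follow the marginal statistics of
#' a large knockout-phenotyping study of rare-disease genes: ~2400
#' disease-associated genes, a gene-level phenotype-match rate of 55%, a
#' homozygote viability mix of 24% lethal / 8% subviable / 68% viable, an
#' endocrine-like category with strongly elevated match odds and a
#' respiratory-like category with reduced odds, and planted logistic
#' effects of procedures completed, mouse/human annotation counts,
#' zygosity and early death on match propensity (log-odds per standard
#' deviation for the continuous features).
#'
#' @param seed Integer seed governing every draw; per-table sub-seeds are
#'   derived from it so partial regeneration is stable.
#' @param n_systems Number of shared "phenotype system" ancestors bridging
#'   the two species namespaces.
#' @param subtree_depth,branching Depth and branching factor of the
#'   mirrored per-system subtrees; each namespace contributes
#'   `branching^subtree_depth` leaves per system.
#' @param n_genes Number of disease-associated genes.
#' @param target_match_rate Gene-level match rate the planted logistic
#'   model is calibrated to (0 disables matching entirely).
#' @param category_weights Named sampling weights for the disease
#'   categories.
#' @param category_odds Named odds multipliers planted on match propensity
#'   (categories not named get 1).
#' @param beta Planted logistic coefficients for `n_procedures`,
#'   `n_mp_terms`, `n_hpo_terms` (per SD, continuous) and the
#'   `homozygous`, `early_death` indicators.
#' @param viability_probs Probabilities of lethal/subviable/viable.
#' @param moi_probs Mode-of-inheritance distribution.
#' @param early_death_probs Distribution of curated early-death
#'   annotations per disease.
#' @param hpo_range,mp_range Inclusive ranges for HPO terms per disease
#'   and MP terms per model.
#' @param p_second_disease Probability a gene has a second associated
#'   disorder.
#' @param p_hemizygous Probability a viable gene's model is hemizygous
#'   rather than homozygous.
#' @param external_coverage Fraction of genes with an external (MGI-style)
#'   model.
#' @param external_match Fraction of external models whose phenotypes
#'   overlap the disease systems (positive external score).
#' @param mirror_copy Calibration mode: every model is annotated with the
#'   exact cross-species image of its disease's term set (the merged
#'   graph's shared terms), so every scored pair attains 100.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       n_systems = 20L,
                       subtree_depth = 2L,
                       branching = 3L,
                       n_genes = 2400L,
                       target_match_rate = 0.55,
                       category_weights = c(
                         "neurology and neurodevelopmental" = 0.22,
                         "metabolic" = 0.12,
                         "dysmorphic and congenital" = 0.12,
                         "cardiovascular" = 0.10,
                         "endocrine" = 0.08,
                         "ophthalmological" = 0.08,
                         "skeletal" = 0.08,
                         "renal and urinary tract" = 0.07,
                         "haematology and immunology" = 0.07,
                         "respiratory" = 0.06),
                       category_odds = c("endocrine" = 3,
                                         "respiratory" = 0.75),
                       beta = c(n_procedures = 0.35, n_mp_terms = 0.8,
                                n_hpo_terms = -0.45, homozygous = 0.4,
                                early_death = 0.6),
                       viability_probs = c(lethal = 0.24, subviable = 0.08,
                                           viable = 0.68),
                       moi_probs = c(AD = 0.35, AR = 0.45, "AD&AR" = 0.08,
                                     other = 0.12),
                       early_death_probs = c(none = 0.82,
                                             pre_infant = 0.10,
                                             childhood = 0.08),
                       hpo_range = c(3L, 12L),
                       mp_range = c(1L, 10L),
                       p_second_disease = 0.12,
                       p_hemizygous = 0.02,
                       external_coverage = 0.7,
                       external_match = 0.6,
                       mirror_copy = FALSE) {
  stopifnot(
    length(seed) == 1L, is.finite(seed),
    n_systems >= 1L, subtree_depth >= 1L, branching >= 1L, n_genes >= 1L,
    target_match_rate >= 0, target_match_rate < 1,
    length(hpo_range) == 2L, hpo_range[1L] >= 1L,
    hpo_range[2L] >= hpo_range[1L],
    length(mp_range) == 2L, mp_range[1L] >= 1L,
    mp_range[2L] >= mp_range[1L],
    p_second_disease >= 0, p_second_disease <= 1,
    external_coverage >= 0, external_coverage <= 1,
    external_match >= 0, external_match <= 1
  )
  check_probs <- function(p, what) {
    if (any(p < 0) || abs(sum(p) - 1) > 1e-8) {
      stop(what, " must be non-negative and sum to 1", call. = FALSE)
    }
  }
  check_probs(viability_probs, "viability_probs")
  check_probs(moi_probs, "moi_probs")
  check_probs(early_death_probs, "early_death_probs")
  check_probs(category_weights, "category_weights")
  if (!all(names(category_weights) %in% disease_categories())) {
    stop("category_weights names must be drawn from disease_categories()",
         call. = FALSE)
  }
  structure(
    list(seed = as.integer(seed), n_systems = as.integer(n_systems),
         subtree_depth = as.integer(subtree_depth),
         branching = as.integer(branching), n_genes = as.integer(n_genes),
         target_match_rate = target_match_rate,
         category_weights = category_weights,
         category_odds = category_odds, beta = beta,
         viability_probs = viability_probs, moi_probs = moi_probs,
         early_death_probs = early_death_probs,
         hpo_range = as.integer(hpo_range), mp_range = as.integer(mp_range),
         p_second_disease = p_second_disease,
         p_hemizygous = p_hemizygous,
         external_coverage = external_coverage,
         external_match = external_match, mirror_copy = mirror_copy),
    class = "sim_config"
  )
}

#' Generate the merged cross-species toy ontology
#'
#' Builds a single-rooted DAG: under the root, `n_systems` shared
#' "phenotype system" terms; under each system, two mirrored subtrees of
#' the stated depth and branching -- one of HP-namespace terms, one of
#' MP-namespace terms with identical numeric ids -- so every HP leaf has
#' an MP counterpart with an informative shared ancestor (the system
#' term). Terms from different systems share only the zero-IC root, which
#' is what makes "no informative overlap" constructible. The structure is
#' fully determined by the configuration, so the OBO text is byte-stable.
#'
#' @param cfg A [sim_config()].
#' @return A `sim_ontology`: list with `ontology` (a `phen_ontology`),
#'   `obo_text` (character vector of lines), `leaves` (tibble of `system`,
#'   `hp_id`, `mp_id` mirror pairs) and `leaves_per_system`.
#' @export
generate_ontology <- function(cfg) {
  b <- cfg$branching
  d <- cfg$subtree_depth
  root_id <- "CP:0000001"
  lines <- c(
    "format-version: 1.2",
    "ontology: phenomatch/merged-synthetic",
    "",
    "[Term]",
    paste0("id: ", root_id),
    "name: phenotypic abnormality (cross-species root)",
    "namespace: shared",
    ""
  )
  stanza <- function(id, name, ns, parent_id, parent_name) {
    c("[Term]", paste0("id: ", id), paste0("name: ", name),
      paste0("namespace: ", ns),
      paste0("is_a: ", parent_id, " ! ", parent_name), "")
  }

  leaves <- list()
  n_local <- sum(b^seq_len(d))
  offsets <- c(0L, cumsum(b^seq_len(d)))
  for (s in seq_len(cfg$n_systems)) {
    sys_id <- sprintf("CP:%07d", 1L + s)
    sys_name <- paste0("phenotype system ", s)
    lines <- c(lines, stanza(sys_id, sys_name, "shared", root_id,
                             "phenotypic abnormality (cross-species root)"))
    for (prefix in c("HP", "MP")) {
      ns <- if (prefix == "HP") "human-phenotype" else "mammalian-phenotype"
      for (lvl in seq_len(d)) {
        for (j in seq_len(b^lvl)) {
          idx <- offsets[lvl] + j
          id <- sprintf("%s:%07d", prefix, s * 10000L + idx)
          name <- paste0(tolower(prefix), " phenotype ", s, ".", idx)
          if (lvl == 1L) {
            pid <- sys_id
            pname <- sys_name
          } else {
            pidx <- offsets[lvl - 1L] + ((j - 1L) %/% b) + 1L
            pid <- sprintf("%s:%07d", prefix, s * 10000L + pidx)
            pname <- paste0(tolower(prefix), " phenotype ", s, ".", pidx)
          }
          lines <- c(lines, stanza(id, name, ns, pid, pname))
        }
      }
    }
    leaf_idx <- offsets[d] + seq_len(b^d)
    leaves[[s]] <- tibble::tibble(
      system = s,
      hp_id = sprintf("HP:%07d", s * 10000L + leaf_idx),
      mp_id = sprintf("MP:%07d", s * 10000L + leaf_idx)
    )
  }
  structure(
    list(ontology = parse_obo(lines), obo_text = lines,
         leaves = dplyr::bind_rows(leaves), leaves_per_system = b^d),
    class = "sim_ontology"
  )
}

#' @export
print.sim_ontology <- function(x, ...) {
  cat("<sim_ontology> ", nrow(x$ontology$terms), " terms, ",
      nrow(x$leaves), " mirrored leaf pairs\n", sep = "")
  invisible(x)
}

# Round-robin allocation of `total` mirror slots across matched diseases,
# one guaranteed slot each, capped by each disease's HPO set size.
allocate_mirrors <- function(total, caps) {
  k <- length(caps)
  alloc <- rep(1L, k)
  spare <- total - k
  while (spare > 0L && any(alloc < caps)) {
    for (i in seq_len(k)) {
      if (spare > 0L && alloc[i] < caps[i]) {
        alloc[i] <- alloc[i] + 1L
        spare <- spare - 1L
      }
    }
  }
  alloc
}

#' Generate a complete synthetic study
#'
#' Draws the model, disease, ortholog and external catalogues with the
#' planted structure described in [sim_config()], plus a ground-truth
#' table for recovery tests. Match labels are drawn from the planted
#' logistic model (intercept calibrated so the expected gene-level match
#' rate equals `target_match_rate`); for matched pairs the model's MP set
#' includes mirror images of the disease's HPO terms (guaranteeing an
#' informative overlap), while unmatched pairs draw all their MP terms
#' from phenotype systems disjoint from the gene's diseases (sharing only
#' the zero-IC root), so the realised pipeline match reproduces the
#' planted label exactly.
#'
#' Lethal genes contribute a homozygous embryo model plus a heterozygous
#' early-adult model; viable and subviable genes one homozygous (rarely
#' hemizygous) early-adult model.
#'
#' @param cfg A [sim_config()].
#' @param sim_ont A `sim_ontology` from [generate_ontology()] (built from
#'   `cfg` if omitted).
#' @param annotations When `FALSE`, skip drawing the MP annotation sets
#'   and the external catalogue (they are left empty); feature draws,
#'   propensities and truth labels are identical to the full run because
#'   every table uses its own derived sub-seed. Used by recovery
#'   simulations that only need the truth table.
#' @return List of tibbles: `models`, `diseases`, `orthologs`, `external`,
#'   `truth` (per pair: ids, `true_match`, `propensity` and the features
#'   that entered the planted propensity) and `coefficients` (planted
#'   intercept, feature betas and per-category log-odds).
#' @export
generate_study <- function(cfg, sim_ont = generate_ontology(cfg),
                           annotations = TRUE) {
  leaves <- sim_ont$leaves
  lps <- sim_ont$leaves_per_system
  if (cfg$hpo_range[2L] > 2L * lps) {
    stop("hpo_range exceeds the ", 2L * lps,
         " HP leaves available per disease (2 systems)", call. = FALSE)
  }
  if (cfg$n_systems < 5L ||
      cfg$mp_range[2L] > (cfg$n_systems - 4L) * lps) {
    stop("mp_range infeasible: not enough free phenotype systems for ",
         "non-matching annotation draws", call. = FALSE)
  }
  hp_by_system <- split(leaves$hp_id, leaves$system)
  mp_by_system <- split(leaves$mp_id, leaves$system)
  mirror <- stats::setNames(leaves$mp_id, leaves$hp_id)

  n <- cfg$n_genes
  human <- sprintf("GENE%05d", seq_len(n))
  mouse <- sprintf("Gene%05d", seq_len(n))

  set.seed(derive_seed(cfg$seed, 11L))
  category <- sample_vec(names(cfg$category_weights), n, replace = TRUE,
                         prob = cfg$category_weights)
  moi <- sample_vec(names(cfg$moi_probs), n, replace = TRUE,
                    prob = cfg$moi_probs)
  viability <- sample_vec(names(cfg$viability_probs), n, replace = TRUE,
                          prob = cfg$viability_probs)
  evidence <- sample_vec(EVIDENCE_LEVELS, n, replace = TRUE,
                         prob = c(0.7, 0.2, 0.1))
  n_dis <- 1L + stats::rbinom(n, 1L, cfg$p_second_disease)

  # Diseases: each uses 2 phenotype systems; the systems of a gene's
  # diseases are mutually disjoint so mirror and filler draws never
  # collide.
  set.seed(derive_seed(cfg$seed, 12L))
  total_dis <- sum(n_dis)
  d_gene <- rep(seq_len(n), n_dis)
  gene_systems <- vector("list", n)
  d_systems <- vector("list", total_dis)
  d_hpo <- vector("list", total_dis)
  d_early <- character(total_dis)
  n_hpo_span <- cfg$hpo_range[2L] - cfg$hpo_range[1L] + 1L
  k <- 0L
  for (i in seq_len(n)) {
    sys_g <- sample_vec(seq_len(cfg$n_systems), 2L * n_dis[i])
    gene_systems[[i]] <- sys_g
    for (j in seq_len(n_dis[i])) {
      k <- k + 1L
      systems <- sys_g[c(2L * j - 1L, 2L * j)]
      n_hpo <- sample.int(n_hpo_span, 1L) + cfg$hpo_range[1L] - 1L
      pool <- unlist(hp_by_system[as.character(systems)],
                     use.names = FALSE)
      d_systems[[k]] <- systems
      d_hpo[[k]] <- sample_vec(pool, n_hpo)
      d_early[k] <- sample_vec(names(cfg$early_death_probs), 1L,
                               prob = cfg$early_death_probs)
    }
  }
  diseases <- tibble::tibble(
    disease_id = sprintf("OMIM:%06d", 100000L + seq_len(total_dis)),
    human_gene = human[d_gene],
    hpo_terms = d_hpo,
    moi = moi[d_gene],
    category = category[d_gene],
    early_death = d_early,
    evidence = evidence[d_gene],
    systems = d_systems
  )

  # Models: feature draws first (sizes enter the planted propensity); term
  # sets are filled in after labels are known.
  set.seed(derive_seed(cfg$seed, 13L))
  lethal_idx <- which(viability == "lethal")
  other_idx <- which(viability != "lethal")
  zyg_other <- ifelse(stats::runif(length(other_idx)) < cfg$p_hemizygous,
                      "hemizygous", "homozygous")
  models <- dplyr::bind_rows(
    tibble::tibble(
      model_id = paste0(mouse[lethal_idx], "_hom_em"),
      mouse_gene = mouse[lethal_idx],
      zygosity = "homozygous", life_stage = "embryo",
      viability = "lethal",
      n_procedures = 2L + stats::rpois(length(lethal_idx), 7),
      preweaning_lethal = TRUE
    ),
    tibble::tibble(
      model_id = paste0(mouse[lethal_idx], "_het_ea"),
      mouse_gene = mouse[lethal_idx],
      zygosity = "heterozygous", life_stage = "early_adult",
      viability = "lethal",
      n_procedures = 3L + stats::rpois(length(lethal_idx), 14),
      preweaning_lethal = TRUE
    ),
    tibble::tibble(
      model_id = paste0(mouse[other_idx], "_",
                        substr(zyg_other, 1L, 3L), "_ea"),
      mouse_gene = mouse[other_idx],
      zygosity = zyg_other, life_stage = "early_adult",
      viability = viability[other_idx],
      n_procedures = 3L + stats::rpois(length(other_idx), 14),
      preweaning_lethal = FALSE
    )
  )
  models <- dplyr::arrange(models, .data$model_id)
  models$mp_size <- pmin(
    cfg$mp_range[2L],
    pmax(cfg$mp_range[1L],
         1L + stats::rbinom(nrow(models), pmin(models$n_procedures, 20L),
                            0.3))
  )

  # Pair table and planted propensity.
  pairs <- dplyr::inner_join(
    dplyr::select(models, "model_id", "mouse_gene", "zygosity",
                  "n_procedures", "mp_size"),
    dplyr::mutate(
      dplyr::select(diseases, "disease_id", "human_gene", "category",
                    "early_death", "hpo_terms"),
      mouse_gene = mouse[match(.data$human_gene, human)],
      n_hpo = lengths(.data$hpo_terms)
    ),
    by = "mouse_gene", relationship = "many-to-many"
  )
  pairs <- dplyr::arrange(pairs, .data$model_id, .data$disease_id)

  zsc <- function(v) {
    s <- stats::sd(v)
    if (s == 0) rep(0, length(v)) else (v - mean(v)) / s
  }
  cat_logodds <- log(ifelse(is.na(cfg$category_odds[pairs$category]), 1,
                            cfg$category_odds[pairs$category]))
  eta <- cfg$beta[["n_procedures"]] * zsc(pairs$n_procedures) +
    cfg$beta[["n_mp_terms"]] * zsc(pairs$mp_size) +
    cfg$beta[["n_hpo_terms"]] * zsc(pairs$n_hpo) +
    cfg$beta[["homozygous"]] *
      (pairs$zygosity %in% c("homozygous", "hemizygous")) +
    cfg$beta[["early_death"]] * (pairs$early_death != "none") +
    as.numeric(cat_logodds)

  gene_of_pair <- pairs$human_gene
  if (cfg$target_match_rate <= 0) {
    b0 <- -Inf
    propensity <- rep(0, nrow(pairs))
  } else {
    gene_rate <- function(b0) {
      p <- stats::plogis(b0 + eta)
      mean(tapply(1 - p, gene_of_pair, prod))
    }
    b0 <- stats::uniroot(
      function(b0) (1 - gene_rate(b0)) - cfg$target_match_rate,
      interval = c(-30, 30), tol = 1e-10
    )$root
    propensity <- stats::plogis(b0 + eta)
  }

  set.seed(derive_seed(cfg$seed, 14L))
  true_match <- stats::runif(nrow(pairs)) < propensity
  if (cfg$mirror_copy) {
    true_match <- rep(TRUE, nrow(pairs))
    propensity <- rep(1, nrow(pairs))
  }

  # Fill MP term sets so the realised phenotype overlap equals the label.
  set.seed(derive_seed(cfg$seed, 15L))
  hpo_by_disease <- stats::setNames(diseases$hpo_terms,
                                    diseases$disease_id)
  systems_by_gene <- stats::setNames(gene_systems, human)
  pair_by_model <- split(seq_len(nrow(pairs)), pairs$model_id)
  mp_sets <- vector("list", nrow(models))
  names(mp_sets) <- models$model_id
  all_systems <- seq_len(cfg$n_systems)
  for (mi in if (annotations) seq_len(nrow(models)) else integer(0)) {
    mid <- models$model_id[mi]
    idx <- pair_by_model[[mid]]
    gene <- pairs$human_gene[idx[1L]]
    if (cfg$mirror_copy) {
      mp_sets[[mi]] <- unique(unlist(
        hpo_by_disease[pairs$disease_id[idx]], use.names = FALSE
      ))
      next
    }
    matched <- pairs$disease_id[idx][true_match[idx]]
    m <- max(models$mp_size[mi], length(matched))
    mirrors <- character(0)
    if (length(matched)) {
      caps <- lengths(hpo_by_disease[matched])
      alloc <- allocate_mirrors(m, caps)
      mirrors <- unlist(lapply(seq_along(matched), function(j) {
        unname(mirror[sample_vec(hpo_by_disease[[matched[j]]], alloc[j])])
      }), use.names = FALSE)
    }
    n_fill <- m - length(mirrors)
    if (n_fill > 0L) {
      free <- setdiff(all_systems, systems_by_gene[[gene]])
      pool <- unlist(mp_by_system[as.character(free)], use.names = FALSE)
      mp_sets[[mi]] <- c(mirrors, sample_vec(pool, n_fill))
    } else {
      mp_sets[[mi]] <- mirrors
    }
  }
  if (!annotations) mp_sets <- rep(list(character(0)), nrow(models))
  models$mp_terms <- unname(mp_sets)
  models <- dplyr::select(models, "model_id", "mouse_gene", "zygosity",
                          "life_stage", "viability", "mp_terms",
                          "n_procedures", "preweaning_lethal")

  # Orthologs: every study gene well-supported, plus decoys exercising the
  # threshold and bijectivity rules (their genes occur in no other table).
  set.seed(derive_seed(cfg$seed, 16L))
  orthologs <- tibble::tibble(
    human_gene = c(human, "DECOYH1", "DECOYH2", "DECOYH2", "DECOYH3",
                   "DECOYH4"),
    mouse_gene = c(mouse, "DecoyM1", "DecoyM2a", "DecoyM2b", "DecoyM3",
                   "DecoyM3"),
    support = c(sample_vec(5:12, n, replace = TRUE), 4L, 9L, 9L, 9L, 9L)
  )

  # External MGI-style catalogue.
  set.seed(derive_seed(cfg$seed, 17L))
  ext_idx <- if (annotations) {
    which(stats::runif(n) < cfg$external_coverage)
  } else {
    integer(0)
  }
  ext_size <- sample.int(7L, length(ext_idx), replace = TRUE) + 1L
  ext_overlap <- stats::runif(length(ext_idx)) < cfg$external_match
  ext_mp <- vector("list", length(ext_idx))
  for (k in seq_along(ext_idx)) {
    i <- ext_idx[k]
    pool_systems <- if (ext_overlap[k]) {
      gene_systems[[i]][1:2]
    } else {
      setdiff(all_systems, gene_systems[[i]])
    }
    pool <- unlist(mp_by_system[as.character(pool_systems)],
                   use.names = FALSE)
    ext_mp[[k]] <- sample_vec(pool, min(ext_size[k], length(pool)))
  }
  external <- tibble::tibble(
    model_id = sprintf("MGI:%07d", 5000000L + ext_idx),
    mouse_gene = mouse[ext_idx],
    mp_terms = ext_mp
  )

  # The truth table carries the features that entered the planted
  # propensity (n_mp_terms is the drawn target size), so recovery
  # simulations can fit the regression without re-deriving them.
  truth <- tibble::tibble(
    model_id = pairs$model_id, disease_id = pairs$disease_id,
    human_gene = pairs$human_gene, mouse_gene = pairs$mouse_gene,
    true_match = true_match, propensity = propensity,
    n_procedures = pairs$n_procedures, n_mp_terms = pairs$mp_size,
    n_hpo_terms = pairs$n_hpo, zygosity = pairs$zygosity,
    early_death = pairs$early_death, category = pairs$category
  )
  coefficients <- tibble::tibble(
    feature = c("(Intercept)", names(cfg$beta),
                paste0("category_logodds_",
                       make.names(names(cfg$category_weights)))),
    value = c(b0, unname(cfg$beta),
              log(ifelse(is.na(cfg$category_odds[
                names(cfg$category_weights)]), 1,
                cfg$category_odds[names(cfg$category_weights)])))
  )

  list(models = models,
       diseases = dplyr::select(diseases, -"systems"),
       orthologs = orthologs, external = external, truth = truth,
       coefficients = coefficients)
}

#' Simulate a study and write all inputs to disk
#'
#' Runs [generate_ontology()] and [generate_study()] and writes
#' `merged.obo`, `models.tsv`, `diseases.tsv`, `orthologs.tsv`,
#' `external.tsv`, `truth.tsv` and `truth_coefficients.tsv` into `dir`.
#' Outputs are byte-identical across runs with the same configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if absent).
#' @return Invisibly, a list with the `sim_ontology`, the study tables and
#'   the output directory.
#' @export
simulate_study <- function(cfg = sim_config(), dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sim_ont <- generate_ontology(cfg)
  study <- generate_study(cfg, sim_ont)
  writeLines(sim_ont$obo_text, file.path(dir, "merged.obo"))
  write_models(study$models, file.path(dir, "models.tsv"))
  write_diseases(study$diseases, file.path(dir, "diseases.tsv"))
  write_orthologs(study$orthologs, file.path(dir, "orthologs.tsv"))
  write_external_models(study$external, file.path(dir, "external.tsv"))
  truth <- dplyr::mutate(study$truth,
                         propensity = round(.data$propensity, 8))
  readr::write_tsv(truth, file.path(dir, "truth.tsv"))
  readr::write_tsv(
    dplyr::mutate(study$coefficients, value = round(.data$value, 8)),
    file.path(dir, "truth_coefficients.tsv")
  )
  invisible(list(ontology = sim_ont, study = study, dir = dir))
}
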