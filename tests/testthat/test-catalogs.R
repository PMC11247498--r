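write_lines_tmp <- function(lines) {
  path <- withr::local_tempfile(fileext = ".tsv",
                                .local_envir = parent.frame())
  writeLines(lines, path)
  path
}

test_that("catalogue readers round-trip well-formed tables", {
  mp <- write_lines_tmp(c(
    "model_id\tmouse_gene\tzygosity\tlife_stage\tviability\tmp_terms\tn_procedures\tpreweaning_lethal",
    "m1\tGeneA\thomozygous\tearly_adult\tviable\tMP:0000001;MP:0000002\t10\tFALSE",
    "m2\tGeneB\theterozygous\tearly_adult\tlethal\t\t5\tTRUE"
  ))
  models <- read_models(mp)
  expect_equal(nrow(models), 2L)
  expect_equal(models$mp_terms[[1L]], c("MP:0000001", "MP:0000002"))
  expect_equal(models$mp_terms[[2L]], character(0)) # ineligible downstream

  dp <- write_lines_tmp(c(
    "disease_id\thuman_gene\thpo_terms\tmoi\tcategory\tearly_death\tevidence",
    "OMIM:100001\tGENEA\tHP:0000001\tAD\tendocrine\tnone\tgreen",
    "ORPHA:2002\tGENEB\tHP:0000002;HP:0000003\tAD&AR\trespiratory\tchildhood\tamber"
  ))
  diseases <- read_diseases(dp)
  expect_equal(nrow(diseases), 2L)
  expect_equal(lengths(diseases$hpo_terms), c(1L, 2L))

  # writers reproduce the readable schema
  m2 <- write_lines_tmp("x")
  write_models(models, m2)
  expect_equal(read_models(m2)$mp_terms, models$mp_terms)
  d2 <- write_lines_tmp("x")
  write_diseases(diseases, d2)
  expect_equal(read_diseases(d2), diseases)
})

test_that("validation errors name the offending row and value", {
  bad_zyg <- write_lines_tmp(c(
    "model_id\tmouse_gene\tzygosity\tlife_stage\tviability\tmp_terms\tn_procedures\tpreweaning_lethal",
    "m1\tGeneA\thom\tearly_adult\tviable\tMP:0000001\t10\tFALSE"
  ))
  expect_error(read_models(bad_zyg), "zygosity.*\"hom\".*row 1")

  bad_term <- write_lines_tmp(c(
    "model_id\tmouse_gene\tzygosity\tlife_stage\tviability\tmp_terms\tn_procedures\tpreweaning_lethal",
    "m1\tGeneA\thomozygous\tearly_adult\tviable\tMP:1\t10\tFALSE"
  ))
  expect_error(read_models(bad_term), "malformed term id.*MP:1")

  # lethal lines must carry the preweaning flag
  bad_flag <- write_lines_tmp(c(
    "model_id\tmouse_gene\tzygosity\tlife_stage\tviability\tmp_terms\tn_procedures\tpreweaning_lethal",
    "m1\tGeneA\thomozygous\tearly_adult\tlethal\tMP:0000001\t10\tFALSE"
  ))
  expect_error(read_models(bad_flag), "preweaning")

  missing_col <- write_lines_tmp(c(
    "disease_id\thuman_gene\thpo_terms\tmoi\tcategory\tearly_death",
    "OMIM:1\tG\tHP:0000001\tAD\tendocrine\tnone"
  ))
  expect_error(suppressWarnings(read_diseases(missing_col)), "evidence")

  bad_support <- write_lines_tmp(c(
    "human_gene_symbol\tmouse_gene_symbol\tsupport_count",
    "H1\tM1\t13"
  ))
  expect_error(read_orthologs(bad_support), "support_count.*row 1")
})

test_that("one-to-one filter applies the support-5 threshold then bijectivity", {
  tab <- function(...) {
    m <- matrix(c(...), ncol = 3L, byrow = TRUE)
    tibble::tibble(human_gene = m[, 1L], mouse_gene = m[, 2L],
                   support = as.integer(m[, 3L]))
  }
  # support 5 passes ("five or more of the 12 prediction services")
  expect_equal(nrow(one_to_one_orthologs(tab("H1", "M1", 5))), 1L)
  # support 4 is below threshold
  expect_equal(nrow(one_to_one_orthologs(tab("H1", "M1", 4))), 0L)
  # one-to-many and many-to-one both fail in either direction
  expect_equal(nrow(one_to_one_orthologs(
    tab("H1", "M1", 8, "H1", "M2", 8))), 0L)
  expect_equal(nrow(one_to_one_orthologs(
    tab("H1", "M1", 8, "H2", "M1", 8))), 0L)
  # a low-support paralog cannot veto a high-support one-to-one pair
  # (threshold applied before the bijectivity test)
  kept <- one_to_one_orthologs(tab("H1", "M1", 9, "H1", "M2", 3))
  expect_equal(kept$mouse_gene, "M1")
})

test_that("the filter output is always a bijection on random tables", {
  set.seed(2024)
  for (rep in 1:20) {
    n <- 60L
    tab <- tibble::tibble(
      human_gene = sprintf("H%02d", sample.int(25L, n, replace = TRUE)),
      mouse_gene = sprintf("M%02d", sample.int(25L, n, replace = TRUE)),
      support = sample.int(12L, n, replace = TRUE)
    )
    for (thr in c(3L, 5L, 8L, 11L)) {
      out <- one_to_one_orthologs(tab, min_support = thr)
      expect_false(anyDuplicated(out$human_gene) > 0)
      expect_false(anyDuplicated(out$mouse_gene) > 0)
    }
  }
})

test_that("raising min_support shrinks the mapping on paralog-free tables", {
  # With the threshold applied before the bijectivity test, dropping a
  # low-support paralog can legitimately ADD a previously vetoed pair, so
  # global monotonicity cannot hold; on tables whose gene pairs are
  # already unique the filter reduces to thresholding and is monotone.
  set.seed(31)
  for (rep in 1:10) {
    n <- 30L
    tab <- tibble::tibble(
      human_gene = sprintf("H%02d", sample(100L, n)),
      mouse_gene = sprintf("M%02d", sample(100L, n)),
      support = sample.int(12L, n, replace = TRUE)
    )
    sizes <- vapply(1:12, function(thr) {
      nrow(one_to_one_orthologs(tab, min_support = thr))
    }, integer(1L))
    expect_true(all(diff(sizes) <= 0L))
  }
  # the de-vetoing counter-example itself
  tab <- tibble::tibble(human_gene = c("H1", "H1"),
                        mouse_gene = c("M1", "M2"),
                        support = c(9L, 6L))
  expect_equal(nrow(one_to_one_orthologs(tab, min_support = 5L)), 0L)
  expect_equal(one_to_one_orthologs(tab, min_support = 8L)$mouse_gene, "M1")
})
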