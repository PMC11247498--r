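test_that("term similarity evaluates the closed form sqrt(J x IC(MICA))", {
  # hand-built toy: R -> A -> {X, Y}; IC fixed by hand so the expected
  # values are direct evaluations of the stated form
  ont <- parse_obo(c(
    "[Term]", "id: R", "",
    "[Term]", "id: A", "is_a: R", "",
    "[Term]", "id: X", "is_a: A", "",
    "[Term]", "id: Y", "is_a: A"
  ))
  ic <- structure(list(ic = c(R = 0, A = 1, X = 2, Y = 2),
                       corpus_size = 8L), class = "phen_ic")
  # self: J = 1, IC = 2 -> sqrt(2)
  expect_equal(term_similarity(ont, ic, "X", "X"), sqrt(2))
  # siblings: 3 reflexive ancestors each, intersection {A, R}, union 4,
  # MICA = A with IC 1 -> sqrt(0.5)
  expect_equal(term_similarity(ont, ic, "X", "Y"), sqrt(0.5))
  # symmetry
  expect_equal(term_similarity(ont, ic, "Y", "X"),
               term_similarity(ont, ic, "X", "Y"))
  # disjoint branches sharing only a zero-IC root
  ont2 <- fixture_ontology()
  ic2 <- fixture_ic(ont2)
  expect_equal(term_similarity(ont2, ic2, "HP:0000011", "MP:0000021"), 0)
})

test_that("best_matches picks the argmax hit with lexicographic ties", {
  ont <- fixture_ontology()
  ic <- fixture_ic(ont)
  # HP:0000011's best hit is its mirror's system sibling; both MP leaves
  # under system 1 tie (same ancestors), so the smaller id wins
  b <- best_matches(ont, ic, "HP:0000011", c("MP:0000012", "MP:0000011"))
  expect_equal(b$hit_term, "MP:0000011")
  expect_equal(b$subsumer, "CP:0000002")
  # shared-namespace identity: each query matches itself at sqrt(IC)
  b2 <- best_matches(ont, ic, c("HP:0000011", "HP:0000012"),
                     c("HP:0000011", "HP:0000012"))
  expect_equal(b2$hit_term, b2$query_term)
  expect_equal(b2$pair_score, sqrt(unname(ic$ic[b2$query_term])))
  # a query with no informative hit gets a zero score and NA hit
  b3 <- best_matches(ont, ic, "HP:0000021", c("MP:0000011"))
  expect_equal(b3$pair_score, 0)
  expect_true(is.na(b3$hit_term))
  expect_error(best_matches(ont, ic, character(0), "MP:0000011"), "empty")
  expect_error(best_matches(ont, ic, "HP:0000011", character(0)), "empty")
})

test_that("best_matches equals the exhaustive double-loop oracle on random sets", {
  set.seed(77)
  for (rep in 1:20) {
    parents <- random_dag(sample(10:40, 1L))
    ont <- parse_obo(obo_from_parents(parents))
    ids <- names(parents)
    corpus <- random_corpus(ids)
    ic <- information_content(ont, corpus)
    qs <- ids[sample.int(length(ids), sample(1:4, 1L))]
    hs <- ids[sample.int(length(ids), sample(1:4, 1L))]
    b <- best_matches(ont, ic, qs, hs)
    for (i in seq_len(nrow(b))) {
      sims <- vapply(unique(hs), function(h) {
        oracle_term_sim(parents, ic$ic, b$query_term[i], h)
      }, numeric(1L))
      expect_equal(b$pair_score[i], max(sims))
    }
  }
})

test_that("optimal_self returns the self-similarity ceiling", {
  ont <- parse_obo(c("[Term]", "id: R", "", "[Term]", "id: L",
                     "is_a: R"))
  ic <- structure(list(ic = c(R = 0, L = 4), corpus_size = 60L),
                  class = "phen_ic")
  opt <- optimal_self(ont, ic, "L")
  expect_equal(opt$opt_max, 2)
  expect_equal(opt$opt_mean, 2)
  # degenerate: only zero-IC roots
  expect_equal(optimal_self(ont, ic, "R"), list(opt_max = 0, opt_mean = 0))
  # max dominates mean
  opt2 <- optimal_self(ont, ic, c("R", "L"))
  expect_gte(opt2$opt_max, opt2$opt_mean)
  expect_error(optimal_self(ont, ic, character(0)), "empty")
})

test_that("phenodigm_score hits its boundary cases", {
  ont <- fixture_ontology()
  ic <- fixture_ic(ont)
  d <- c("HP:0000011", "HP:0000012")
  # exact image of the disease set (shared terms of the merged graph)
  expect_equal(phenodigm_score(ont, ic, d, d)$percentage, 100)
  # no informative overlap: model annotated in the other system
  s0 <- phenodigm_score(ont, ic, d, c("MP:0000021", "MP:0000022"))
  expect_equal(s0$percentage, 0)
  expect_equal(s0$raw_max, 0)
  # degenerate disease annotated only to the zero-IC root
  expect_equal(phenodigm_score(ont, ic, "CP:0000001", "MP:0000011")$percentage, 0)
  # partial mirror match lands strictly between
  s <- phenodigm_score(ont, ic, d, "MP:0000011")
  expect_true(s$percentage > 0 && s$percentage < 100)
})

test_that("score is monotone under augmenting the model with a better hit", {
  set.seed(901)
  for (rep in 1:15) {
    parents <- random_dag(sample(15:40, 1L))
    ont <- parse_obo(obo_from_parents(parents))
    ids <- names(parents)
    ic <- information_content(ont, random_corpus(ids))
    qs <- ids[sample.int(length(ids), sample(2:4, 1L))]
    hs <- ids[sample.int(length(ids), sample(1:3, 1L))]
    extra <- ids[sample.int(length(ids), 1L)]
    p1 <- phenodigm_score(ont, ic, qs, hs)$percentage
    p2 <- phenodigm_score(ont, ic, qs, unique(c(hs, extra)))$percentage
    expect_gte(p2 + 1e-9, p1)
  }
})

test_that("the score is intentionally asymmetric in disease and model roles", {
  ont <- fixture_ontology()
  ic <- fixture_ic(ont)
  a <- phenodigm_score(ont, ic, c("HP:0000011", "HP:0000021"),
                       "MP:0000011")$percentage
  b <- phenodigm_score(ont, ic, "MP:0000011",
                       c("HP:0000011", "HP:0000021"))$percentage
  # not required to be equal; both remain in range
  expect_true(all(c(a, b) >= 0 & c(a, b) <= 100))
  # the bidirectional variant averages the two directions
  s_bi <- phenodigm_score(ont, ic, c("HP:0000011", "HP:0000021"),
                          "MP:0000011", bidirectional = TRUE)$percentage
  expect_equal(s_bi, (a + b) / 2)
})
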