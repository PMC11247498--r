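# Small fixtures built in code.

# A fixture ontology: root, two shared system ancestors, mirrored HP/MP
# leaves under system 1 and 2 (two leaves each per namespace).
fixture_obo <- function() {
  c("[Term]", "id: CP:0000001", "name: root", "namespace: shared", "",
    "[Term]", "id: CP:0000002", "name: system 1", "namespace: shared",
    "is_a: CP:0000001", "",
    "[Term]", "id: CP:0000003", "name: system 2", "namespace: shared",
    "is_a: CP:0000001", "",
    "[Term]", "id: HP:0000011", "is_a: CP:0000002", "",
    "[Term]", "id: HP:0000012", "is_a: CP:0000002", "",
    "[Term]", "id: MP:0000011", "is_a: CP:0000002", "",
    "[Term]", "id: MP:0000012", "is_a: CP:0000002", "",
    "[Term]", "id: HP:0000021", "is_a: CP:0000003", "",
    "[Term]", "id: HP:0000022", "is_a: CP:0000003", "",
    "[Term]", "id: MP:0000021", "is_a: CP:0000003", "",
    "[Term]", "id: MP:0000022", "is_a: CP:0000003", "")
}

fixture_ontology <- function() parse_obo(fixture_obo())

# IC table over the fixture: diseases annotated in system 1, models in
# system 1 and 2, so both system ancestors are informative but the root
# is not.
fixture_ic <- function(ont = fixture_ontology()) {
  information_content(ont, list(
    d1 = c("HP:0000011", "HP:0000012"),
    d2 = c("HP:0000021"),
    m1 = c("MP:0000011"),
    m2 = c("MP:0000021", "MP:0000022")
  ))
}

fixture_models <- function() {
  tibble::tibble(
    model_id = c("mA_hom_ea", "mB_hom_em", "mB_het_ea", "mC_hom_ea"),
    mouse_gene = c("GeneA", "GeneB", "GeneB", "GeneC"),
    zygosity = c("homozygous", "homozygous", "heterozygous", "homozygous"),
    life_stage = c("early_adult", "embryo", "early_adult", "early_adult"),
    viability = c("viable", "lethal", "lethal", "viable"),
    mp_terms = list(c("MP:0000011", "MP:0000012"), "MP:0000021",
                    "MP:0000021", character(0)),
    n_procedures = c(12L, 5L, 14L, 9L),
    preweaning_lethal = c(FALSE, TRUE, TRUE, FALSE)
  )
}

fixture_diseases <- function() {
  tibble::tibble(
    disease_id = c("OMIM:100001", "OMIM:100002", "OMIM:100003"),
    human_gene = c("GENEA", "GENEB", "GENEC"),
    hpo_terms = list(c("HP:0000011", "HP:0000012"), "HP:0000021",
                     character(0)),
    moi = c("AD", "AR", "AR"),
    category = c("endocrine", "neurology and neurodevelopmental",
                 "respiratory"),
    early_death = c("none", "pre_infant", "childhood"),
    evidence = c("green", "green", "amber")
  )
}

fixture_orthologs <- function() {
  tibble::tibble(
    human_gene = c("GENEA", "GENEB", "GENEC"),
    mouse_gene = c("GeneA", "GeneB", "GeneC"),
    support = c(9L, 7L, 12L)
  )
}

small_cfg <- function(seed = 1L, n_genes = 150L, ...) {
  sim_config(seed = seed, n_genes = n_genes, n_systems = 8L, ...)
}
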