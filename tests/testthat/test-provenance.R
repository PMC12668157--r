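test_that("HTAN ids parse into center/participant/suffix", {
  p <- parse_htan_id("HTA13_1_101")
  expect_equal(p$center_id, "HTA13")
  expect_equal(p$participant_id, "HTA13_1")
  expect_equal(p$local_suffix, "101")

  bare <- parse_htan_id("HTA7_1")
  expect_true(is.na(bare$local_suffix))
  expect_equal(bare$participant_id, "HTA7_1")

  expect_error(parse_htan_id("XYZ_1"), "position 1")
  expect_error(parse_htan_id("HTA6_"), "malformed")
  expect_error(parse_htan_id("HTAx_1"), "position 4")
})

toy_graph <- function() {
  provenance_graph(data.frame(
    htan_id = c("HTA1_1", "HTA1_1_1", "HTA1_1_2", "HTA1_1_1_f1",
                "HTA1_1_2_f2"),
    node_kind = c("participant", "biospecimen", "biospecimen", "file",
                  "file"),
    parent_ids = c("", "HTA1_1", "HTA1_1", "HTA1_1_1", "HTA1_1_2"),
    drs_uri = c(NA, NA, NA, "drs://dg.4DFC:abc", "http://nope"),
    center = "HTA1", assay_type = c(NA, NA, NA, "H&E", "MxIF"),
    level = c(NA, NA, NA, "2", "2")))
}

test_that("lineage walks the provenance chain both ways", {
  g <- toy_graph()
  expect_equal(lineage(g, "HTA1_1_1_f1", "ancestors"),
               c("HTA1_1", "HTA1_1_1"))
  expect_equal(lineage(g, "HTA1_1", "descendants"),
               c("HTA1_1_1", "HTA1_1_1_f1", "HTA1_1_2", "HTA1_1_2_f2"))
  expect_error(lineage(g, "HTA9_9", "ancestors"), "not in")

  # ancestors/descendants are mutually consistent on a random DAG
  set.seed(6)
  md <- gen_metadata(cohort_scenario(precancer = c(A = 3, C = 3, none = 4),
                                     seed = 6))
  rg <- provenance_graph(md$nodes)
  ids <- sample(md$nodes$htan_id, 8)
  for (a in ids) {
    for (b in lineage(rg, a, "ancestors")) {
      expect_true(a %in% lineage(rg, b, "descendants"))
    }
  }
})

test_that("provenance graph validation catches broken structure", {
  base <- data.frame(htan_id = c("HTA1_1", "HTA1_1_1"),
                     node_kind = c("participant", "biospecimen"),
                     parent_ids = c("", "HTA1_1"))
  expect_error(provenance_graph(rbind(base, data.frame(
    htan_id = "HTA1_1_f", node_kind = "file", parent_ids = "HTA1_9"))),
    "not present")
  # a file hanging directly off a participant has no biospecimen ancestor
  expect_error(provenance_graph(rbind(base, data.frame(
    htan_id = "HTA1_1_f", node_kind = "file", parent_ids = "HTA1_1"))),
    "biospecimen")
  cyc <- data.frame(htan_id = c("a", "b"), node_kind = "participant",
                    parent_ids = c("b", "a"))
  expect_error(provenance_graph(cyc), "cycle")
})

test_that("organ cohorts roll tissue terms up to whole organs", {
  clinical <- data.frame(
    participant_id = c("HTA1_1", "HTA1_2", "HTA1_3", "HTA1_4"),
    tissue_or_organ_of_origin = c("Breast, NOS", "  breast,  nos ",
                                  "Upper lobe, lung", "Mystery site"))
  map <- c("Breast, NOS" = "Breast", "Upper lobe, lung" = "Lung")
  expect_warning(got <- organ_cohort(clinical, map, "Breast"), "skipped")
  expect_equal(got, c("HTA1_1", "HTA1_2"))   # case/whitespace-insensitive
  expect_error(suppressWarnings(organ_cohort(clinical, map, "Kidney")),
               "not a category")
})

test_that("morphology codes canonicalize across dialects", {
  expect_equal(canonicalize_morphology(c("M82110", "8220/0", "82630",
                                         "82-x", "M8211")),
               c("8211/0", "8220/0", "8263/0", NA, NA))
  expect_equal(canonicalize_morphology(" M82130 "), "8213/0")
})

test_that("the precancer union combines four criteria with per-criterion flags", {
  clinical <- data.frame(
    participant_id = c("HTA1_1", "HTA6_2", "HTA6_3", "HTA6_4"),
    center = c("HTA1", "HTA6", "HTA6", "HTA6"),
    age_at_diagnosis = c(0, 54, 61, 70),
    primary_diagnosis = c("Not Reported", "Ductal Carcinoma in situ",
                          "Adenocarcinoma, NOS", "Adenocarcinoma, NOS"))
  biospecimens <- data.frame(
    biospecimen_id = c("HTA6_2_1", "HTA6_3_1", "HTA6_4_1"),
    participant_id = c("HTA6_2", "HTA6_3", "HTA6_4"),
    tumor_tissue_type = c("Premalignant", "Primary", "Primary"),
    histologic_morphology_code = c("", "M82110", "8500/3"))
  cfg <- precancer_config("HTA1")
  rep <- precancer_union(clinical, biospecimens, cfg)
  expect_equal(rep$participant_id, c("HTA1_1", "HTA6_2", "HTA6_3"))
  expect_equal(rep$by_age_sentinel, c(TRUE, FALSE, FALSE))
  # one row per participant even when two criteria hit (union dedup)
  expect_equal(rep$by_diagnosis, c(FALSE, TRUE, FALSE))
  expect_equal(rep$by_tissue_type, c(FALSE, TRUE, FALSE))
  expect_equal(rep$by_morphology, c(FALSE, FALSE, TRUE))
  expect_error(precancer_union(clinical[, -2], biospecimens, cfg),
               "center")
})

test_that("union size obeys the inclusion bound on planted overlaps", {
  # disjoint criteria: union size equals the sum
  md1 <- gen_metadata(cohort_scenario(precancer = c(A = 4, B = 3, C = 2,
                                                    D = 2, none = 5),
                                      seed = 11))
  rep1 <- precancer_union(md1$clinical, md1$biospecimens, md1$config)
  expect_equal(nrow(rep1), 4 + 3 + 2 + 2)
  # overlapping criteria: union is strictly smaller than the sum
  md2 <- gen_metadata(cohort_scenario(precancer = c(A = 4, B = 3, AB = 3,
                                                    none = 5), seed = 12))
  rep2 <- precancer_union(md2$clinical, md2$biospecimens, md2$config)
  expect_equal(nrow(rep2), 10)
  expect_lt(nrow(rep2), sum(rep2$by_age_sentinel) + sum(rep2$by_diagnosis))
})

test_that("cross-modal matching requires both released modalities", {
  fm <- data.frame(
    center = "HTA1",
    parent_biospecimen_id = c("B1", "B1", "B2", "B3", "B3"),
    assay_type = c("H&E", "MxIF", "H&E", "H&E", "MxIF"),
    data_release = c("R1", "R1", "R1", NA, NA))
  expect_equal(cross_modal_match(fm, "H&E", "MxIF"), "B1")
  expect_error(cross_modal_match(fm, "H&E", "MIBI"), "unknown modality")
})

test_that("manifests carry valid DRS URIs and report rejects", {
  g <- toy_graph()
  mf <- build_manifest(g, c("HTA1_1_1_f1", "HTA1_1_2_f2", "HTA1_1_1",
                            "HTA9_9"))
  expect_equal(mf$manifest$htan_id, "HTA1_1_1_f1")
  expect_equal(mf$manifest$drs_uri, "drs://dg.4DFC:abc")
  expect_equal(nrow(mf$rejects), 3L)
  expect_setequal(mf$rejects$reason,
                  c("malformed drs_uri", "not a file node",
                    "not in provenance graph"))

  # determinism: same inputs give byte-stable output
  set.seed(2)
  md <- gen_metadata(cohort_scenario(seed = 2))
  rg <- provenance_graph(md$nodes)
  ids <- sample(md$file_metadata$htan_id)
  m1 <- build_manifest(rg, sort(ids))
  m2 <- build_manifest(rg, ids)
  expect_identical(m1$manifest, m2$manifest)
})
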