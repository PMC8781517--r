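simple_map <- function() {
  data.frame(
    entity_id   = c("T1", "T1", "T2", "C1", "C2", "C2"),
    entity_kind = c("transcript_hit", "transcript_hit", "transcript_hit",
                    "compound", "compound", "compound"),
    pathway_id  = c("p1", "p2", "p2", "p2", "p3", "p2"),
    pathway_name = "x", system = c("sysA", "sysB", "sysB", "sysB", "sysA",
                                   "sysB"),
    stringsAsFactors = FALSE)
}

test_that("entity annotation partitions ids and computes coverage", {
  map <- simple_map()
  a <- annotate_entities(c("T1", "T2", "T9"), "transcript_hit", map)
  expect_equal(a$annotated, c("T1", "T2"))
  expect_equal(a$unannotated, "T9")
  expect_equal(a$coverage, 2 / 3)
  expect_equal(a$pathways, c("p1", "p2"))
  expect_equal(a$pathway_entities$p2, c("T1", "T2"))

  none <- annotate_entities(c("X1", "X2"), "compound", map)
  expect_equal(none$coverage, 0)
  expect_equal(none$pathways, character(0))

  empty <- annotate_entities(character(0), "compound", map)
  expect_true(is.na(empty$coverage))

  # 3 of 10 mapped
  ten <- annotate_entities(c("C1", "C2", sprintf("Z%d", 1:8)), "compound",
                           map)
  expect_equal(ten$coverage, 0.2)
})

test_that("multi-pathway entities yield the brute-force pathway union", {
  for (s in 1:10) {
    map <- random_pathway_map(seed = 900 + s)
    ids <- sprintf("e%02d", 1:12)
    a <- annotate_entities(ids, "transcript_hit", map)
    want <- sort(unique(map$pathway_id[map$entity_kind == "transcript_hit" &
                                         map$entity_id %in% ids]))
    expect_equal(a$pathways, want)
  }
})

test_that("shared core is the pathway intersection with entity restriction", {
  map <- simple_map()
  ta <- annotate_entities(c("T1", "T2"), "transcript_hit", map)
  ca <- annotate_entities(c("C1", "C2"), "compound", map)
  core <- shared_core(ta, ca, map)
  expect_equal(core$shared, "p2")
  expect_equal(core$union, c("p1", "p2", "p3"))
  expect_equal(core$transcripts, c("T1", "T2"))
  expect_equal(core$compounds, c("C1", "C2"))
  expect_equal(core$systems, "sysB")

  # inclusion-exclusion on a |T|=5, |C|=4, overlap-2 construction
  mk <- function(pws, kind, ent) data.frame(
    entity_id = ent, entity_kind = kind, pathway_id = pws,
    pathway_name = "x", system = "s1", stringsAsFactors = FALSE)
  map2 <- rbind(mk(sprintf("p%d", 1:5), "transcript_hit", "T1"),
                mk(sprintf("p%d", 4:7), "compound", "C1"))
  core2 <- shared_core(annotate_entities("T1", "transcript_hit", map2),
                       annotate_entities("C1", "compound", map2))
  expect_equal(length(core2$shared), 2L)
  expect_equal(length(core2$union), 7L)

  ca_disjoint <- annotate_entities("C2", "compound",
                                   simple_map()[5, , drop = FALSE])
  expect_warning(core3 <- shared_core(ta, ca_disjoint), "no pathways shared")
  expect_equal(core3$shared, character(0))
  expect_equal(core3$transcripts, character(0))
})

test_that("shared-core set identities hold on random maps", {
  for (s in 1:40) {
    map <- random_pathway_map(seed = 1200 + s)
    ids <- sprintf("e%02d", 1:12)
    ta <- annotate_entities(ids, "transcript_hit", map)
    ca <- annotate_entities(ids, "compound", map)
    core <- suppressWarnings(shared_core(ta, ca, map))
    expect_setequal(core$shared, intersect(ta$pathways, ca$pathways))
    expect_true(all(core$shared %in% core$union))
    expect_equal(length(core$union),
                 length(ta$pathways) + length(ca$pathways) -
                   length(core$shared))
    for (e in core$transcripts)
      expect_true(any(map$entity_id == e & map$pathway_id %in% core$shared &
                        map$entity_kind == "transcript_hit"))
  }
})

test_that("the tripartite network wires entities, pathways and systems", {
  map <- simple_map()
  ta <- annotate_entities(c("T1", "T2"), "transcript_hit", map)
  ca <- annotate_entities(c("C1", "C2"), "compound", map)
  core <- shared_core(ta, ca, map)
  net <- build_network(core, map)
  # 2 transcripts + 2 compounds on 1 shared pathway in 1 system
  expect_equal(igraph::vcount(net), 6L)
  expect_equal(igraph::ecount(net), 5L)
  kinds <- igraph::V(net)$kind
  expect_equal(sum(kinds == "pathway"), 1L)
  expect_equal(sum(kinds == "system"), 1L)
  # entity nodes only touch shared pathways; pathway touches its one system
  pw <- igraph::V(net)[kinds == "pathway"]
  expect_equal(igraph::degree(net, pw), 5, ignore_attr = TRUE)

  empty_core <- suppressWarnings(
    shared_core(annotate_entities("T1", "transcript_hit",
                                  map[1, , drop = FALSE]),
                annotate_entities("C2", "compound", map[5, , drop = FALSE])))
  expect_equal(igraph::vcount(build_network(empty_core, map)), 0L)

  bad_map <- map[map$pathway_id != "p2" | map$entity_kind != "compound", ]
  bad_core <- core
  bad_core$shared <- c("p2", "p99")
  expect_error(build_network(bad_core, map), "p99")
})

test_that("network degree sequence matches the incidence construction", {
  pm <- simulate_pathway_map(sprintf("T%02d", 1:10), sprintf("C%02d", 1:8),
                             n_shared = 5, n_transcript_only = 3,
                             n_compound_only = 3,
                             symptom_blocks = list(
                               pain = c(pathways = 2, transcripts = 4,
                                        compounds = 3)),
                             seed = 31)
  ta <- annotate_entities(sprintf("T%02d", 1:10), "transcript_hit", pm$map)
  ca <- annotate_entities(sprintf("C%02d", 1:8), "compound", pm$map)
  core <- shared_core(ta, ca, pm$map)
  net <- build_network(core, pm$map)
  inc <- pm$map[pm$map$pathway_id %in% core$shared, ]
  inc <- inc[!duplicated(inc[c("entity_id", "pathway_id")]), ]
  for (e in unique(inc$entity_id))
    expect_equal(unname(igraph::degree(net, e)),
                 sum(inc$entity_id == e))
  for (p in core$shared)
    expect_equal(unname(igraph::degree(net, p)),
                 sum(inc$pathway_id == p) + 1L)  # + its system edge
  expect_true(all(igraph::degree(net) >= 1))     # no orphan nodes
})

test_that("symptom clusters are induced subnetworks with exact membership", {
  pm <- simulate_pathway_map(sprintf("T%02d", 1:10), sprintf("C%02d", 1:8),
                             n_shared = 6, n_transcript_only = 2,
                             n_compound_only = 2,
                             symptom_blocks = list(
                               pain = c(pathways = 3, transcripts = 5,
                                        compounds = 4)),
                             seed = 77)
  ta <- annotate_entities(sprintf("T%02d", 1:10), "transcript_hit", pm$map)
  ca <- annotate_entities(sprintf("C%02d", 1:8), "compound", pm$map)
  net <- build_network(shared_core(ta, ca, pm$map), pm$map)

  sc <- extract_symptom_cluster(net, "pain", pm$symptoms$pain)
  expect_equal(unname(sc$counts["pathways"]), 3L)
  expect_equal(sort(sc$transcripts), pm$manifest$blocks$pain$transcripts)
  expect_equal(sort(sc$compounds), pm$manifest$blocks$pain$compounds)
  # every member is adjacent to a listed pathway inside the subnetwork
  for (e in c(sc$transcripts, sc$compounds)) {
    nb <- igraph::V(sc$subnetwork)$name[
      unlist(igraph::adjacent_vertices(sc$subnetwork, e))]
    expect_true(any(nb %in% sc$pathways))
  }

  none <- extract_symptom_cluster(net, "none", character(0))
  expect_equal(unname(none$counts), c(0L, 0L, 0L, 0L))

  expect_warning(sk <- extract_symptom_cluster(net, "pain",
                                               c(pm$symptoms$pain, "pw_zz")),
                 "pw_zz")
  expect_equal(sk$counts, sc$counts)

  # inducing over the full pathway list reproduces the whole network
  all_pw <- igraph::V(net)$name[igraph::V(net)$kind == "pathway"]
  whole <- extract_symptom_cluster(net, "all", all_pw)
  expect_equal(igraph::vcount(whole$subnetwork), igraph::vcount(net))
  expect_equal(igraph::ecount(whole$subnetwork), igraph::ecount(net))
})

test_that("one pathway with three adjacent entities gives a 3-member cluster", {
  map <- data.frame(entity_id = c("T1", "T2", "C1"),
                    entity_kind = c("transcript_hit", "transcript_hit",
                                    "compound"),
                    pathway_id = "p1", pathway_name = "P", system = "s1",
                    stringsAsFactors = FALSE)
  ta <- annotate_entities(c("T1", "T2"), "transcript_hit", map)
  ca <- annotate_entities("C1", "compound", map)
  net <- build_network(shared_core(ta, ca, map), map)
  sc <- extract_symptom_cluster(net, "x", "p1")
  expect_equal(unname(sc$counts["transcripts"] + sc$counts["compounds"]), 3L)
})
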