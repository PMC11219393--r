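matrix_row <- function(species, gene, status = "intact",
                       category = NA_integer_, group = NA_character_) {
  data.frame(species = species, gene = gene, status = status,
             category = category, shared_group = group)
}

test_that("a duplicate shared by a clade gets one stem birth, not per-lineage births", {
  tr <- six_tip_tree()
  # duplicated state (category 1) in A..D; single copy in E, F
  m <- rbind(matrix_row(c("A", "B", "C", "D"), "g", category = 1L),
             matrix_row(c("E", "F"), "g"))
  ev <- place_births(m, tr)
  expect_equal(nrow(ev), 1)
  expect_equal(ev$branch_id, branch_of_node(tr, mrca_node(tr, c("A", "D"))))
  # duplicate observed in one terminal only
  m2 <- rbind(matrix_row("A", "g", category = 2L),
              matrix_row(c("B", "C"), "g"))
  ev2 <- place_births(m2, tr)
  expect_equal(ev2$branch_id, branch_of_node(tr, mrca_node(tr, "A")))
  # category 4 contributes no births
  m3 <- matrix_row(c("A", "B"), "g", category = 4L)
  expect_equal(nrow(place_births(m3, tr)), 0)
})

test_that("family births land on the stem of all bearing species; errors on none", {
  tr <- six_tip_tree()
  fam <- data.frame(family = "F", gene = c("anc", "derived"),
                    ancestral = c(TRUE, FALSE))
  m <- rbind(matrix_row(c("A", "B", "C", "D", "E", "F"), "anc"),
             matrix_row(c("A", "B", "C", "D", "E", "F"), "derived"))
  ev <- place_births(m, tr, fam)
  root_stem <- branch_of_node(tr, length(tr$phy$tip.label) + 1L)
  expect_equal(ev$gene, "derived")
  expect_equal(ev$branch_id, root_stem)
  m_none <- rbind(matrix_row("A", "anc"),
                  matrix_row("A", "derived", status = "absent"))
  expect_error(place_births(m_none, tr, fam), "no bearing species")
})

test_that("parsimony placements equal the exhaustive minimum on all 4-leaf patterns", {
  tr <- four_tip_tree()
  tips <- tr$phy$tip.label
  fam <- data.frame(family = "F", gene = c("anc", "g"),
                    ancestral = c(TRUE, FALSE))
  for (mask in 1:15) {                    # every non-empty presence pattern
    present <- tips[as.logical(bitwAnd(mask, c(1, 2, 4, 8)))]
    m <- rbind(matrix_row(tips, "anc"),
               matrix_row(present, "g"),
               if (length(setdiff(tips, present)))
                 matrix_row(setdiff(tips, present), "g", status = "absent"))
    births <- place_births(m, tr, fam)
    deaths <- place_deaths(m, tr, births)
    got <- nrow(births) + sum(deaths$gene == "g")
    expect_equal(got, oracle_min_events(tr, present),
                 info = paste("pattern", paste(present, collapse = "")))
  }
})

test_that("death placement: stem losses, independent vs shared disruptions", {
  tr <- six_tip_tree()
  root_stem <- branch_of_node(tr, length(tr$phy$tip.label) + 1L)
  ef_stem <- branch_of_node(tr, mrca_node(tr, c("E", "F")))
  # gene absent in the (E,F) clade only: one stem loss
  m <- rbind(matrix_row(c("A", "B", "C", "D"), "g"),
             matrix_row(c("E", "F"), "g", status = "absent"))
  births <- data.frame(branch_id = root_stem, type = "birth", gene = "g",
                       provenance = "prior")
  d <- place_deaths(m, tr, births)
  expect_equal(nrow(d), 1)
  expect_equal(d$type, "loss")
  expect_equal(d$branch_id, ef_stem)
  # different disruptive mutations: independent terminal events
  m2 <- rbind(matrix_row(c("A", "B", "C", "D"), "g"),
              matrix_row(c("E", "F"), "g", status = "disrupted"))
  d2 <- place_deaths(m2, tr, births)
  expect_setequal(d2$branch_id,
                  branch_of_node(tr, match(c("E", "F"), tr$phy$tip.label)))
  # the same mutation (shared group): one ancestral disruption
  m3 <- rbind(matrix_row(c("A", "B", "C", "D"), "g"),
              matrix_row(c("E", "F"), "g", status = "disrupted",
                         group = "mut1"))
  d3 <- place_deaths(m3, tr, births)
  expect_equal(nrow(d3), 1)
  expect_equal(d3$branch_id, ef_stem)
  # intact everywhere: no deaths; segregating: no deaths
  expect_equal(nrow(place_deaths(matrix_row(tr$phy$tip.label, "g"), tr,
                                 births)), 0)
  m4 <- rbind(matrix_row(c("A", "B", "C", "D", "E"), "g"),
              matrix_row("F", "g", status = "segregating"))
  expect_equal(nrow(place_deaths(m4, tr, births)), 0)
  # presence above the birth branch is inconsistent
  births_low <- data.frame(branch_id = ef_stem, type = "birth", gene = "g",
                           provenance = "prior")
  expect_error(place_deaths(m, tr, births_low), "above its birth")
})

test_that("prior merging appends, permits same-branch birth+loss, flags conflicts", {
  inferred <- data.frame(branch_id = 2L, type = "birth", gene = "g",
                         provenance = "inferred")
  expect_identical(merge_prior(inferred, NULL), inferred)
  prior <- data.frame(branch_id = c(1L, 1L), type = c("birth", "loss"),
                      gene = "ghost", note = "earlier work")
  out <- merge_prior(inferred, prior)
  expect_equal(nrow(out), 3)
  expect_setequal(out$provenance, c("inferred", "prior"))
  # net branch effect of an invisible birth+loss pair is zero
  cnt <- count_branch_events(out[out$gene == "ghost", ],
                             matrix_row("A", "other"))
  expect_equal(cnt$births - cnt$deaths, 0)
  clash <- data.frame(branch_id = 1L, type = "birth", gene = "g")
  expect_error(merge_prior(inferred, clash), "conflict")
  won <- merge_prior(inferred, clash, override = TRUE)
  expect_equal(won$branch_id[won$gene == "g"], 1L)
  expect_equal(won$provenance[won$gene == "g"], "prior")
})

test_that("death weights follow the category rules (-2, -1, 0)", {
  led <- function(type) data.frame(branch_id = 10L, type = type, gene = "g",
                                   provenance = "inferred")
  # category 1, all sequences disrupted: -2
  m_cat1 <- matrix_row("A", "g", status = "disrupted", category = 1L)
  expect_equal(count_branch_events(led("disruption"), m_cat1)$deaths, 2)
  # category 3 mixed intact and disrupted: -1
  m_cat3 <- matrix_row("A", "g", status = "intact_and_disrupted",
                       category = 3L)
  expect_equal(count_branch_events(led("disruption"), m_cat3)$deaths, 1)
  # category 4 mixed: 0
  m_cat4 <- matrix_row("A", "g", status = "intact_and_disrupted",
                       category = 4L)
  expect_equal(count_branch_events(led("disruption"), m_cat4)$deaths, 0)
  # single locus: -1; unknown inferred gene rejected
  m_single <- matrix_row("A", "g", status = "disrupted")
  expect_equal(count_branch_events(led("disruption"), m_single)$deaths, 1)
  expect_error(count_branch_events(led("loss"), matrix_row("A", "other")),
               "unknown gene")
})

test_that("ancestral totals do parent + births - deaths and reject negatives", {
  tr <- six_tip_tree()
  root_stem <- branch_of_node(tr, length(tr$phy$tip.label) + 1L)
  counts <- data.frame(branch_id = c(root_stem, 2L),
                       births = c(3L, 0L), deaths = c(0L, 4L))
  tot <- ancestral_counts(32, counts, tr)
  root_node <- length(tr$phy$tip.label) + 1L
  expect_equal(tot$intact[tot$node == root_node], 35)
  kid <- bitterfam:::node_children(tr, root_node)[1]
  expect_equal(tot$intact[tot$branch_id == 2], 31)
  bad <- data.frame(branch_id = root_stem, births = 0L, deaths = 40L)
  expect_error(ancestral_counts(32, bad, tr), "negative")
})

test_that("replayed simulated histories satisfy the conservation identity", {
  tr <- six_tip_tree()
  for (s in 1:25) {
    cfg <- simulation_config(seed = s, birth_rate = 0.04,
                             disruption_rate = 0.06, loss_rate = 0.04,
                             conversion_rate = 0.1,
                             root_repertoire_size = 6,
                             emit_sequences = FALSE)
    sim <- simulate_history(tr, cfg)
    led <- history_ledger(sim)
    m <- bitterfam:::truth_status_matrix(sim)
    counts <- count_branch_events(led, m, tr)
    tot <- ancestral_counts(6, counts, tr)
    for (sp in names(sim$repertoires)) {
      truth <- sum(sim$repertoires[[sp]]$genes$state %in%
                     c("intact", "segregating"))
      expect_equal(tot$intact[tot$label == sp], truth,
                   info = paste("seed", s, sp))
    }
  }
})

test_that("stem duplications are recovered without spurious per-lineage births", {
  tr <- six_tip_tree()
  recovered <- 0; eligible <- 0
  for (s in 1:40) {
    cfg <- simulation_config(seed = 1000 + s, birth_rate = 0.05,
                             disruption_rate = 0, loss_rate = 0,
                             conversion_rate = 0.5,
                             root_repertoire_size = 3,
                             emit_sequences = FALSE)
    sim <- simulate_history(tr, cfg)
    h <- sim$history
    int <- h[h$event == "birth" & h$branch_id <= 5, ]  # internal branches
    if (nrow(int) == 0) next
    m <- bitterfam:::truth_status_matrix(sim)
    births <- place_births(m, tr, bitterfam:::truth_families(sim))
    for (i in seq_len(nrow(int))) {
      g <- int$gene_id[i]
      bearing <- m$species[m$gene == g & m$status != "absent"]
      below <- tips_below(tr, node_of_branch(tr, int$branch_id[i]))
      if (!setequal(bearing, below)) next  # copy lost somewhere: out of scope
      eligible <- eligible + 1
      got <- births[births$gene == g, ]
      recovered <- recovered +
        (nrow(got) == 1 && got$branch_id == int$branch_id[i])
    }
  }
  expect_gt(eligible, 0)
  expect_equal(recovered, eligible)
})

test_that("the ancestral set rule covers inclusion, rescue and exclusion", {
  inv <- data.frame(
    gene = rep(c("gA", "gB", "gC"), each = 2),
    database = rep(c("db1", "db2"), 3),
    status = c("intact", "disrupted",    # gA: intact in one db
               "disrupted", "disrupted", # gB: disrupted everywhere
               "disrupted", "absent"))   # gC: disrupted/absent everywhere
  cap <- data.frame(gene = c("gB", "gC"), species = c("sp1", "sp1"),
                    status = c("intact", "disrupted"))
  set <- build_ancestral_set(inv, cap)
  expect_setequal(as.character(set), c("gA", "gB"))
  expect_equal(attr(set, "excluded"), "gC")
  # copy suffixes collapse to the base gene
  cap2 <- data.frame(gene = "gB-2", species = "sp1", status = "intact")
  expect_true("gB" %in% build_ancestral_set(inv, cap2))
})
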