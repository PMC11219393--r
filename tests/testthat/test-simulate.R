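test_that("zero rates give every leaf the intact root repertoire and no events", {
  tr <- six_tip_tree()
  cfg <- simulation_config(seed = 3, birth_rate = 0, disruption_rate = 0,
                           loss_rate = 0, conversion_rate = 0,
                           root_repertoire_size = 32,
                           emit_sequences = FALSE)
  sim <- simulate_history(tr, cfg)
  expect_equal(nrow(sim$history), 0)
  for (rep_ in sim$repertoires) {
    expect_equal(nrow(rep_$genes), 32)
    expect_true(all(rep_$genes$state == "intact"))
  }
})

test_that("parameter validation rejects negative rates and missing seeds", {
  expect_error(simulation_config(seed = 1, birth_rate = -0.1), "rates")
  expect_error(simulation_config(seed = 1, seg_pseudo_prob = 1.5),
               "probabilities")
  expect_error(simulation_config(), "seed")
})

test_that("pure-birth event counts match the Yule closed form over 2000 seeds", {
  tr <- species_tree(ape::read.tree(text = "(A:2,B:0):0;"))
  b <- 0.3
  n <- vapply(1:2000, function(s) {
    cfg <- simulation_config(seed = s, birth_rate = b, disruption_rate = 0,
                             loss_rate = 0, conversion_rate = 0,
                             root_repertoire_size = 1,
                             emit_sequences = FALSE)
    nrow(simulate_history(tr, cfg)$repertoires$A$genes)
  }, numeric(1))
  expected <- exp(b * 2)          # E[N(t)] of a Yule process from one gene
  se <- sd(n) / sqrt(length(n))
  expect_lt(abs(mean(n) - expected), 3 * se)
})

test_that("a loss on an internal branch propagates Dollo-style to all tips below", {
  # force a loss on the (A,B) stem by simulating until one occurs there
  found <- FALSE
  for (s in 1:60) {
    cfg <- simulation_config(seed = s, birth_rate = 0, disruption_rate = 0,
                             loss_rate = 0.08, conversion_rate = 0,
                             root_repertoire_size = 6,
                             emit_sequences = FALSE)
    tr <- six_tip_tree()
    sim <- simulate_history(tr, cfg)
    ab_stem <- branch_of_node(tr, mrca_node(tr, c("A", "B")))
    ev <- sim$history[sim$history$event == "loss" &
                      sim$history$branch_id == ab_stem, ]
    if (nrow(ev)) {
      g <- ev$gene_id[1]
      expect_false(g %in% sim$repertoires$A$genes$gene_id)
      expect_false(g %in% sim$repertoires$B$genes$gene_id)
      # present in at least one tip outside the clade (not lost elsewhere
      # in every lineage for these rates and seeds)
      outside <- c("C", "D", "E", "F")
      present_outside <- vapply(outside, function(sp)
        g %in% sim$repertoires[[sp]]$genes$gene_id, logical(1))
      lost_again <- sim$history$gene_id == g &
        sim$history$event == "loss" & sim$history$branch_id != ab_stem
      expect_true(any(present_outside) || any(lost_again))
      found <- TRUE
      break
    }
  }
  expect_true(found)
})

test_that("fixed seed reproduces history, repertoires and emission bit-identically", {
  tr <- six_tip_tree()
  cfg <- simulation_config(seed = 99, root_repertoire_size = 6)
  s1 <- simulate_history(tr, cfg)
  s2 <- simulate_history(tr, cfg)
  expect_identical(s1$history, s2$history)
  expect_identical(s1$repertoires, s2$repertoires)
  e1 <- emit_capture(s1, cfg, sex = "male", n_nr_a = 10, n_nr_x = 2)
  e2 <- emit_capture(s2, cfg, sex = "male", n_nr_a = 10, n_nr_x = 2)
  expect_identical(e1$records, e2$records)
  expect_identical(e1$per_site, e2$per_site)
})

test_that("conversion changes sequences but never copy number", {
  for (s in 1:40) {
    cfg <- simulation_config(seed = s, birth_rate = 0.08,
                             disruption_rate = 0, loss_rate = 0,
                             conversion_rate = 1, root_repertoire_size = 4,
                             emit_sequences = FALSE)
    sim <- simulate_history(six_tip_tree(), cfg)
    h <- sim$history
    if (!any(h$event == "conversion")) next
    # copy number at any tip = root size + births on its root path
    for (sp in names(sim$repertoires)) {
      tr <- sim$tree
      path <- integer(0)
      node <- match(sp, tr$phy$tip.label)
      repeat {
        path <- c(path, branch_of_node(tr, node))
        if (node == length(tr$phy$tip.label) + 1L) break
        node <- tr$phy$edge[match(node, tr$phy$edge[, 2]), 1]
      }
      births <- sum(h$event == "birth" & h$branch_id %in% path)
      # births of copies later present; conversions contribute nothing
      expect_equal(nrow(sim$repertoires[[sp]]$genes), 4 + births)
    }
    return(invisible(NULL))
  }
  skip("no conversion event drawn in 40 seeds (unexpected)")
})

test_that("an unmutated simulated gene passes ORF and 7-TM tests", {
  tpl <- gene_template(900)
  v <- sequence_verdict(tpl)
  expect_equal(v$orf_length, 897)
  expect_equal(v$tm_count, 7)
  expect_equal(v$status, "intact")
})

test_that("emitted depth is proportional to copy number (slope within 5%)", {
  cfg <- simulation_config(seed = 21, depth_mean = 800)
  rep_ <- synth_repertoire(21, n_single = 40, divergence = 0.03, cfg = cfg)
  em <- emit_capture(rep_, cfg, sex = "male", n_nr_a = 5, n_nr_x = 0)
  g <- em$records[em$records$kind == "gene", ]
  fit <- lm(mean_depth ~ 0 + copy_number, data = g)
  slope <- coef(fit)[[1]]
  expect_lt(abs(slope - cfg$depth_mean / 2) / (cfg$depth_mean / 2), 0.05)
})

test_that("male X depth is halved, female is not, and labels are validated", {
  cfg <- simulation_config(seed = 5, depth_mean = 1000)
  nr <- emit_neutral_reference_set(83, 3, NULL, cfg, sex = "male")
  r <- nr$records
  ratio <- mean(r$mean_depth[r$kind == "NR-X"]) /
    mean(r$mean_depth[r$kind == "NR-A"])
  expect_gt(ratio, 0.4)
  expect_lt(ratio, 0.6)
  nrf <- emit_neutral_reference_set(83, 3, NULL, cfg, sex = "female",
                                    reseed = TRUE)
  rf <- nrf$records
  ratio_f <- mean(rf$mean_depth[rf$kind == "NR-X"]) /
    mean(rf$mean_depth[rf$kind == "NR-A"])
  expect_gt(ratio_f, 0.9)
  expect_lt(ratio_f, 1.1)
  expect_error(emit_neutral_reference_set(5, 1, NULL, cfg, sex = "robot"),
               "sex")
  expect_error(emit_capture(synth_repertoire(1, 2), cfg, sex = "unknown"),
               "sex")
})

test_that("neutral reference defaults give 83 NR-A + 3 NR-X and n_x = 0 works", {
  cfg <- simulation_config(seed = 8)
  nr <- emit_neutral_reference_set(cfg = cfg)
  expect_equal(sum(nr$records$kind == "NR-A"), 83)
  expect_equal(sum(nr$records$kind == "NR-X"), 3)
  expect_true(all(nr$records$mapped_length >= 1000))
  nr0 <- emit_neutral_reference_set(n_autosomal = 10, n_x = 0, cfg = cfg)
  expect_equal(sum(nr0$records$kind == "NR-X"), 0)
})

test_that("identical paralogs share every window; congregated loci sum depth", {
  cfg <- simulation_config(seed = 31, depth_mean = 1500)
  rep_ <- synth_repertoire(31, n_single = 10, divergence = 0, cfg = cfg)
  # divergence 0 -> identical pair
  em <- emit_capture(rep_, cfg, sex = "male", n_nr_a = 5, n_nr_x = 0)
  g01 <- em$records[em$records$locus_id == "G01", ]
  expect_equal(g01$shared_fraction, 1.0)
  expect_equal(g01$n_genes, 2)
  singles <- em$records[em$records$kind == "gene" & em$records$n_genes == 1, ]
  expect_lt(abs(g01$mean_depth / mean(singles$mean_depth) - 2), 0.25)
})

test_that("neutral SNP density stochastically dominates intact-gene density", {
  cfg <- simulation_config(seed = 13, gene_rate_multiplier = 0.4)
  tr <- six_tip_tree()
  sim <- simulate_history(tr, cfg <- simulation_config(seed = 13,
    root_repertoire_size = 10, birth_rate = 0, disruption_rate = 0,
    loss_rate = 0, conversion_rate = 0))
  em <- emit_capture(sim, cfg, sex = "male", n_nr_a = 40, n_nr_x = 0)
  r <- em$records
  gene_med <- median(r$snp_density[r$kind == "gene"])
  nr_med <- median(r$snp_density[r$kind == "NR-A"])
  expect_gt(nr_med, gene_med)
})
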