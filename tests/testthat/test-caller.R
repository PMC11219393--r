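test_that("boxplot summary matches the brute-force oracle and handles degenerate spread", {
  b <- boxplot_stats(c(5, 5, 5, 5))
  expect_equal(b$q1, 5)
  expect_equal(b$q3, 5)
  expect_equal(b$median, 5)
  expect_equal(b$iqr, 0)
  expect_equal(b$lower_whisker, 5)
  expect_equal(b$upper_whisker, 5)

  cases <- list(c(1:10, 100), c(2, 9, 4), 7, c(1, 1, 2, 100, 100),
                rnorm(25), rnorm(26), rexp(51), rexp(52))
  set.seed(4)
  for (i in 1:30) cases[[length(cases) + 1]] <- rlnorm(sample(1:80, 1))
  for (v in cases) {
    got <- boxplot_stats(v)
    want <- oracle_boxplot(v)
    for (f in names(want)) expect_equal(got[[f]], want[[f]], info = f)
    perm <- boxplot_stats(v[sample.int(length(v))])
    expect_equal(unclass(got)[names(want)], unclass(perm)[names(want)])
    # whiskers are data points inside the fences
    expect_true(got$lower_whisker %in% v && got$upper_whisker %in% v)
  }
  expect_error(boxplot_stats(numeric(0)), "non-empty")
})

test_that("snp density is per kilobase and rejects zero lengths", {
  expect_equal(snp_density(5, 1000), 5)
  expect_equal(snp_density(3, 600), 5)
  expect_equal(snp_density(0, 123), 0)
  expect_error(snp_density(1, 0), "mapped_length")
})

test_that("round-2 absence uses mean depth < 10, strictly", {
  expect_equal(screen_absent_round2(rep(9.9, 100)), "absent")
  expect_equal(screen_absent_round2(rep(10, 100)), "retained")
  expect_equal(screen_absent_round2(rep(0, 50)), "absent")
  expect_error(screen_absent_round2(numeric(0)), "non-empty")
})

test_that("round-3 screen applies length and whisker rules per locus class", {
  gbox <- boxplot_stats(c(90, 100, 100, 110, 120))
  abox <- boxplot_stats(c(95, 100, 105, 110))
  recs <- data.frame(
    locus_id = c("g_short", "g_low", "g_ok", "nr_short", "nr_dup", "nr_ok"),
    kind = c("gene", "gene", "gene", "NR-A", "NR-A", "NR-A"),
    mapped_length = c(749, 900, 900, 999, 1500, 1500),
    mean_depth = c(100, 0.4 * gbox$lower_whisker, 0.6 * gbox$lower_whisker,
                   100, 1.6 * abox$upper_whisker, 100))
  excl <- screen_round3(recs, gbox, abox)
  expect_setequal(excl$locus_id, c("g_short", "g_low", "nr_short", "nr_dup"))
  expect_equal(excl$reason[excl$locus_id == "g_short"], "short")
  expect_equal(excl$reason[excl$locus_id == "nr_dup"], "duplicated")
  expect_error(screen_round3(data.frame(locus_id = "x", kind = "mystery",
                                        mapped_length = 1, mean_depth = 1),
                             gbox, abox), "kind")
})

test_that("candidate flagging is strict at the whisker and splits three ways", {
  dbox <- boxplot_stats(c(90, 100, 110, 120, 130))
  sbox <- boxplot_stats(c(1, 2, 3, 4, 5))
  recs <- data.frame(
    locus_id = c("at_whisker", "depth_hi", "snp_hi", "both_hi"),
    mean_depth = c(dbox$upper_whisker, dbox$upper_whisker * 1.5, 100,
                   dbox$upper_whisker * 2),
    snp_density = c(sbox$upper_whisker, 2, sbox$upper_whisker * 2,
                    sbox$upper_whisker * 2))
  out <- flag_duplication_candidates(recs, dbox, sbox)
  expect_equal(out$flag,
               c("single_locus", "candidate", "high_snp_only", "candidate"))
})

test_that("candidate resolution reproduces the four category outcomes", {
  dbox <- boxplot_stats(c(900, 1000, 1000, 1100, 1200))
  sbox <- boxplot_stats(c(1, 2, 3, 4, 5))
  # shared fraction above threshold: congregated, category 1, round 4
  r1 <- resolve_candidate("X", shared_fraction = 0.5,
                          depth_boxplot = dbox, snp_boxplot = sbox)
  expect_equal(r1$call, "duplicated_congregated")
  expect_equal(r1$category, 1L)
  expect_equal(r1$round_decided, 4L)
  expect_equal(r1$children, "")
  # separable children within whiskers: category 2 with -1/-2 children
  kids <- data.frame(locus_id = c("X-1", "X-2"),
                     mean_depth = c(1000, 1050),
                     snp_sites = c(2, 3), mapped_length = c(1000, 1000))
  r2 <- resolve_candidate("X", shared_fraction = 0.02, post_split = kids,
                          depth_boxplot = dbox, snp_boxplot = sbox)
  expect_equal(r2$call[1], "split_single_locus")
  expect_equal(r2$category[1], 2L)
  expect_equal(r2$children[1], "X-1,X-2")
  expect_true(all(r2$call[-1] == "single_locus"))
  # a child still above the depth whisker: category 3 at round 5
  kids$mean_depth[2] <- dbox$upper_whisker * 1.4
  r3 <- resolve_candidate("X", shared_fraction = 0.02, post_split = kids,
                          depth_boxplot = dbox, snp_boxplot = sbox)
  expect_equal(r3$category[r3$locus_id == "X-2"], 3L)
  expect_equal(r3$round_decided[r3$locus_id == "X-2"], 5L)
  # a child with only SNP excess: category 4
  kids$mean_depth[2] <- 1000
  kids$snp_sites[2] <- 40
  r4 <- resolve_candidate("X", shared_fraction = 0.02, post_split = kids,
                          depth_boxplot = dbox, snp_boxplot = sbox)
  expect_equal(r4$category[r4$locus_id == "X-2"], 4L)
  # missing haplotypes when the fraction must be computed
  expect_error(resolve_candidate("X", shared_fraction = NA,
                                 depth_boxplot = dbox, snp_boxplot = sbox),
               "haplotype")
})

test_that("every candidate ends in exactly one category or split children", {
  cfg <- simulation_config(seed = 77, depth_mean = 600)
  rep_ <- synth_repertoire(77, n_single = 35, divergence = 0.04, cfg = cfg)
  em <- emit_capture(rep_, cfg, sex = "male", n_nr_a = 20, n_nr_x = 2)
  calls <- call_loci(em)
  cand <- calls$calls[calls$calls$call != "absent", ]
  decided <- cand$call %in% c("single_locus", "duplicated_congregated",
                              "split_single_locus", "high_snp_only")
  expect_true(all(decided))
  with_cat <- cand[cand$call %in% c("duplicated_congregated",
                                    "high_snp_only",
                                    "split_single_locus"), ]
  expect_true(all(with_cat$category %in% 1:4))
})

test_that("false-positive candidate rate on single-copy loci stays below 10%", {
  fp <- 0; total <- 0
  for (s in 1:20) {
    cfg <- simulation_config(seed = 400 + s, depth_mean = 600)
    rep_ <- synth_repertoire(400 + s, n_single = 35, cfg = cfg)
    em <- emit_capture(rep_, cfg, sex = "male", n_nr_a = 12, n_nr_x = 0)
    calls <- call_loci(em)
    g <- calls$calls[calls$calls$call != "absent" &
                     !grepl("-", calls$calls$locus_id), ]
    fp <- fp + sum(g$call != "single_locus")
    total <- total + nrow(g)
  }
  expect_lt(fp / total, 0.10)
})

test_that("raising true copy number never turns a duplicated call into single-locus", {
  cfg <- simulation_config(seed = 55, depth_mean = 800)
  dbox <- boxplot_stats(c(700, 800, 800, 850, 900))
  sbox <- boxplot_stats(c(1, 2, 3, 4, 5))
  rec1 <- data.frame(locus_id = "X", mean_depth = 800, snp_density = 3)
  rec2 <- data.frame(locus_id = "X", mean_depth = 1600, snp_density = 3)
  f1 <- flag_duplication_candidates(rec1, dbox, sbox)$flag
  f2 <- flag_duplication_candidates(rec2, dbox, sbox)$flag
  expect_equal(f1, "single_locus")
  expect_equal(f2, "candidate")
})
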