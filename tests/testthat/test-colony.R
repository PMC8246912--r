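make_colony <- function(n_ba, n_mc, n_other, n_dead = 0) {
  lo <- 30; hi <- 3000
  rows <- rbind(
    if (n_ba) cbind(cKit = rep(lo, n_ba), FceRI = hi, CD49b = hi),
    if (n_mc) cbind(cKit = rep(hi, n_mc), FceRI = hi, CD49b = lo),
    if (n_other) cbind(cKit = rep(lo, n_other), FceRI = lo, CD49b = lo),
    if (n_dead) cbind(cKit = rep(lo, n_dead), FceRI = lo, CD49b = lo))
  event_table(rows,
              kinds = c(cKit = "fluorescent", FceRI = "fluorescent",
                        CD49b = "fluorescent"),
              population = rep(c("live", "dead"),
                               c(n_ba + n_mc + n_other, n_dead)))
}

test_that("colony classification enforces the 20-event and 5-event rules", {
  # 25 live, 6 in Ba gate, 2 in MC gate -> classified, Ba only
  rec <- classify_colony(make_colony(6, 2, 17), colony_id = "c1")
  expect_true(rec$classified)
  expect_equal(rec$lineage_calls, "Ba")
  expect_equal(rec$type, "Ba")
  expect_equal(rec$n_live_events, 25)

  # 15 live events -> unclassified
  rec2 <- classify_colony(make_colony(10, 5, 0), colony_id = "c2")
  expect_false(rec2$classified)
  expect_length(rec2$lineage_calls, 0)
  expect_true(is.na(rec2$type))

  # 0 live events -> size 1, unclassified
  rec3 <- classify_colony(make_colony(0, 0, 0, n_dead = 8), colony_id = "c3")
  expect_equal(rec3$size, 1L)
  expect_false(rec3$classified)

  # both gates at threshold -> mixed
  rec4 <- classify_colony(make_colony(5, 5, 10), colony_id = "c4")
  expect_equal(rec4$type, "mixed")

  # classified but no gate reaches 5 events
  rec5 <- classify_colony(make_colony(4, 4, 14), colony_id = "c5")
  expect_equal(rec5$type, "none")

  bad_gate <- list(Zz = list(nope = c(0, 1)))
  expect_error(classify_colony(make_colony(6, 2, 17), gates = bad_gate),
               "unknown parameter")
})

test_that("colony summaries compute proportions and SEM correctly", {
  recs <- list(classify_colony(make_colony(6, 0, 19), colony_id = "a"),
               classify_colony(make_colony(7, 0, 18), colony_id = "b"),
               classify_colony(make_colony(0, 6, 19), colony_id = "c"),
               classify_colony(make_colony(6, 6, 13), colony_id = "d"))
  s1 <- summarize_colony_output(recs, rep("P1", 4))
  expect_equal(s1$mean_fraction[s1$type == "Ba"], 0.5)
  expect_equal(s1$mean_fraction[s1$type == "MC"], 0.25)
  expect_equal(s1$mean_fraction[s1$type == "mixed"], 0.25)
  expect_true(all(is.na(s1$sem)))
  # proportions over types sum to 1 per population
  expect_equal(sum(s1$mean_fraction), 1)

  # two identical experiments: SEM 0
  s2 <- summarize_colony_output(c(recs, recs), rep("P1", 8),
                                experiments = rep(c("e1", "e2"), each = 4))
  expect_equal(s2$sem, rep(0, 4))

  # textbook s / sqrt(n) on a 3-replicate hand case: Ba fractions 1, 0.5, 0
  recs3 <- list(classify_colony(make_colony(6, 0, 19), colony_id = "x1"),
                classify_colony(make_colony(6, 0, 19), colony_id = "x2"),
                classify_colony(make_colony(0, 6, 19), colony_id = "x3"),
                classify_colony(make_colony(0, 6, 19), colony_id = "x4"))
  s3 <- summarize_colony_output(recs3, rep("P1", 4),
                                experiments = c("e1", "e2", "e2", "e3"))
  expect_equal(s3$sem[s3$type == "Ba"], sd(c(1, 0.5, 0)) / sqrt(3))

  # a population with only unclassified colonies is missing, not zero
  un <- list(classify_colony(make_colony(2, 0, 2), colony_id = "u"))
  s4 <- summarize_colony_output(c(recs, un), c(rep("P1", 4), "MCgate"))
  expect_false("MCgate" %in% s4$population)
})

test_that("colony overlays join projections with outcomes one-to-one", {
  set.seed(6)
  ref <- simulate_flow_events(c("a", "b"), c(40, 40), n_fluor = 3,
                              n_scatter = 0, seed = 2)
  colnames(ref$rows) <- c("cKit", "FceRI", "CD49b")
  names(ref$kinds) <- c("cKit", "FceRI", "CD49b")
  model <- fit_pca(ref)
  idx <- event_table(ref$rows[1:3, ], ref$kinds,
                     population = rep("P1", 3),
                     cell_ids = c("i1", "i2", "i3"))
  recs <- list(classify_colony(make_colony(6, 0, 19), colony_id = "k1",
                               origin_cell_id = "i1", size = 1),
               classify_colony(make_colony(0, 6, 19), colony_id = "k2",
                               origin_cell_id = "i2", size = 1000),
               classify_colony(make_colony(5, 5, 15), colony_id = "k3",
                               origin_cell_id = "i3"))
  ov <- overlay_colonies(model, idx, recs)
  expect_equal(nrow(ov), 3)
  expect_equal(ov$log10_size, c(0, 3, log10(25)))
  expect_equal(ov$type, c("Ba", "MC", "mixed"))
  # coordinates equal the direct projection of the founding cells
  expect_equal(as.numeric(ov$PC1), as.numeric(project_pca(model, idx)[, 1]))

  bad <- list(classify_colony(make_colony(6, 0, 19), colony_id = "k9",
                              origin_cell_id = "zz"))
  expect_error(overlay_colonies(model, idx, bad), "zz")
})
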