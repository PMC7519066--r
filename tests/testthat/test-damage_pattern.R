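test_that("direct breakage probability is the published linear ramp", {
  expect_equal(direct_break_prob(5), 0)
  expect_equal(direct_break_prob(37.5), 1)
  expect_equal(direct_break_prob(21.25), 0.5)
  expect_equal(direct_break_prob(c(0, 3, 100)), c(0, 0, 1))
  # linear in between
  e <- seq(5, 37.5, by = 2.5)
  expect_equal(direct_break_prob(e), (e - 5) / 32.5)
  expect_error(direct_break_prob(-1), class = "iondamage_validation_error")
})

test_that("indirect breakage probability is the constant 0.65", {
  expect_identical(indirect_break_prob(), 0.65)
  ev <- deposition_events(position = seq_len(1e5), strand = 0,
                          kind = "OH_ATTACK")
  b <- sample_breaks(ev, seed = 1)
  expect_equal(nrow(b) / 1e5, 0.65, tolerance = 0.005 / 0.65)
})

test_that("sample_breaks honours the per-event probabilities", {
  # certain and impossible events
  sure <- deposition_events(1:50, strand = 1, kind = "ENERGY",
                            energy_ev = 40)
  expect_equal(nrow(sample_breaks(sure, seed = 1)), 50L)
  never <- deposition_events(1:50, strand = 1, kind = "ENERGY",
                             energy_ev = 4.9)
  expect_equal(nrow(sample_breaks(never, seed = 1)), 0L)

  # mixed stream: counts within 3 sigma of the binomial expectation
  n <- 1e4
  ev <- deposition_events(
    position = seq_len(2 * n), strand = rep(0:1, n),
    kind = rep(c("ENERGY", "OH_ATTACK"), each = n),
    energy_ev = c(rep(21.25, n), rep(NA, n)))
  b <- sample_breaks(ev, seed = 42)
  n_dir <- sum(b$mechanism == "direct")
  n_ind <- sum(b$mechanism == "indirect")
  expect_lt(abs(n_dir - 0.5 * n), 3 * sqrt(n * 0.25))
  expect_lt(abs(n_ind - 0.65 * n), 3 * sqrt(n * 0.65 * 0.35))

  # seeded reproducibility
  expect_identical(sample_breaks(ev, seed = 9), sample_breaks(ev, seed = 9))
  expect_error(deposition_events(1, 0, "ENERGY", energy_ev = 0),
               class = "iondamage_validation_error")
})

test_that("classifier worked micro-examples score exactly", {
  mk <- function(pos, strand, mech = "direct") {
    data.frame(position = pos, strand = strand, mechanism = mech,
               stringsAsFactors = FALSE)
  }
  t1 <- classify_breaks(mk(c(100, 105), c(0, 1)))
  expect_equal(t1$n_dsb, 1L)
  expect_equal(t1$n_ssb, 0L)
  expect_equal(t1$n_dsb_sites, 1L)
  expect_equal(t1$n_dsb_clusters, 0L)
  expect_equal(t1$dsb_channels[["direct"]], 1L)

  t2 <- classify_breaks(mk(c(100, 115), c(0, 1)))
  expect_equal(t2$n_dsb, 0L)
  expect_equal(t2$n_ssb, 2L)

  # exactly 10 bp apart is still a DSB ("within 10 bp" is inclusive)
  t10 <- classify_breaks(mk(c(100, 110), c(0, 1)))
  expect_equal(t10$n_dsb, 1L)

  # two DSBs 20 bp apart: one cluster, one site
  t3 <- classify_breaks(mk(c(100, 102, 120, 121), c(0, 1, 0, 1)))
  expect_equal(t3$n_dsb, 2L)
  expect_equal(t3$n_dsb_clusters, 1L)
  expect_equal(t3$n_dsb_sites, 1L)
  expect_equal(t3$n_dsb_per_cluster_mean, 2)

  # hybrid channel: one direct + one indirect break
  th <- classify_breaks(mk(c(100, 105), c(0, 1), c("direct", "indirect")))
  expect_equal(th$dsb_channels[["hybrid"]], 1L)
})

test_that("coincident direct+indirect breaks count once in totals, twice in channels", {
  b <- data.frame(position = c(200, 200), strand = c(0, 0),
                  mechanism = c("direct", "indirect"),
                  stringsAsFactors = FALSE)
  t <- classify_breaks(b)
  expect_equal(t$n_sb_total, 1L)
  expect_equal(t$n_ssb, 1L)
  expect_equal(t$sb_channels[["direct"]], 1L)
  expect_equal(t$sb_channels[["indirect"]], 1L)
  # a dual-mechanism break in a DSB makes the DSB hybrid
  b2 <- rbind(b, data.frame(position = 205, strand = 1,
                            mechanism = "direct"))
  t2 <- classify_breaks(b2)
  expect_equal(t2$n_dsb, 1L)
  expect_equal(t2$dsb_channels[["hybrid"]], 1L)
})

test_that("conservation and ordering invariants hold on random patterns", {
  for (seed in 1:60) {
    br <- generate_break_pattern(n_tracks = 20, breaks_per_track = 3,
                                 clustering_scale = 4, span = 2000,
                                 seed = seed)
    t <- classify_breaks(br)
    n_dedup <- nrow(unique(br[c("position", "strand")]))
    expect_identical(t$n_sb_total, n_dedup)
    expect_identical(t$n_sb_total, t$n_ssb + 2L * t$n_dsb)
    expect_lte(t$n_dsb_sites, t$n_dsb)
    expect_lte(t$n_dsb_clusters, t$n_dsb_sites)
    expect_gte(t$n_ssb, 0L)
    expect_identical(sum(t$dsb_channels), t$n_dsb)
    # sites = isolated DSBs + clusters
    expect_identical(t$n_dsb_sites,
                     (t$n_dsb_sites - t$n_dsb_clusters) + t$n_dsb_clusters)
  }
})

test_that("classification is invariant under translation and strand swap", {
  for (seed in 1:20) {
    br <- generate_break_pattern(n_tracks = 10, breaks_per_track = 3,
                                 clustering_scale = 3, span = 500,
                                 seed = seed)
    t0 <- classify_breaks(br)
    shifted <- br; shifted$position <- shifted$position + 1000L
    swapped <- br; swapped$strand <- 1L - swapped$strand
    drop_pos <- function(x) x[setdiff(names(x), "dsb_positions")]
    expect_equal(drop_pos(unclass(classify_breaks(shifted))),
                 drop_pos(unclass(t0)))
    expect_equal(drop_pos(unclass(classify_breaks(swapped))),
                 drop_pos(unclass(t0)))
  }
})

test_that("greedy pairing matches the exhaustive maximum-pairing oracle", {
  # scaled-down in-suite version (200 instances); the acceptance test
  # runs 1000
  for (seed in 1:200) {
    br <- random_dense_breaks(seed)
    t <- classify_breaks(br)
    orc <- oracle_classifier(br)
    expect_identical(t$n_sb_total, orc$n_dedup, info = paste("seed", seed))
    expect_identical(t$n_dsb, orc$n_dsb_max, info = paste("seed", seed))
    got <- c(n_dsb = t$n_dsb, n_clusters = t$n_dsb_clusters,
             n_sites = t$n_dsb_sites)
    ok <- any(vapply(orc$tallies, function(tt) all(tt == got), logical(1)))
    expect_true(ok, info = paste("seed", seed))
  }
})

test_that("generated patterns behave in the sparse and dense limits", {
  # sparse, uniform-like: essentially no DSBs
  sparse <- generate_break_pattern(n_tracks = 40, breaks_per_track = 1,
                                   clustering_scale = 1e5, span = 1e7,
                                   seed = 1)
  t_sparse <- classify_breaks(sparse)
  expect_lte(t_sparse$n_dsb, 1L)

  # tight clusters: most tracks yield a DSB
  dense <- generate_break_pattern(n_tracks = 200, breaks_per_track = 4,
                                  clustering_scale = 2, span = 1e6,
                                  seed = 2)
  t_dense <- classify_breaks(dense)
  expect_gt(t_dense$n_dsb, 50L)

  # seed reproducibility
  expect_identical(
    generate_break_pattern(10, seed = 3),
    generate_break_pattern(10, seed = 3))
})

test_that("break-list TSV reader validates its schema", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("# fixture", "position_bp\tstrand\tmechanism",
               "100\t0\tdirect", "105\t1\tindirect"), path)
  b <- read_breaks(path)
  expect_equal(b$position, c(100L, 105L))
  t <- classify_breaks(b)
  expect_equal(t$n_dsb, 1L)
  expect_equal(t$dsb_channels[["hybrid"]], 1L)
  expect_error(read_breaks("/nope.tsv"), class = "iondamage_io_error")
  bad <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("a\tb", "1\t2"), bad)
  expect_error(read_breaks(bad), class = "iondamage_validation_error")
})
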