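db <- builtin_db()

test_that("evaluation agrees with the straight-transcription oracle", {
  lets <- c(0.2, 1, 5, 10, 20, 50, 100, 200, 500)
  for (i in seq_len(nrow(db))) {
    row <- db[i, ]
    par <- query_params(db, row$ion, row$damage_class, row$channel)
    got <- eval_yield(par, lets)
    want <- vapply(lets, function(L) oracle_eval_row(row, L), numeric(1))
    expect_equal(got, want, tolerance = 1e-12,
                 info = paste(row$damage_class, row$ion, row$channel))
  }
})

test_that("frozen worked examples reproduce to 1e-12 relative", {
  # values computed once with independent high-precision arithmetic
  expect_equal(eval_yield(query_params(db, "H", "DSB"), 10),
               8.589132251527015, tolerance = 1e-12)
  expect_equal(eval_yield(query_params(db, "C", "DSB_SITE"), 150),
               14.609148283691416, tolerance = 1e-12)
  # at L = p5 the dip log term is exactly zero, so the dip equals p4
  expect_equal(eval_yield(query_params(db, "Li", "SSB"), 8.993),
               139.04279538010046, tolerance = 1e-12)
})

test_that("low-LET limit equals p1: exactly at 0, within 1% at 1e-6", {
  for (i in seq_len(nrow(db))) {
    row <- db[i, ]
    par <- query_params(db, row$ion, row$damage_class, row$channel)
    expect_identical(low_let_limit(par), row$p1)
    expect_equal(eval_yield(par, 0), row$p1)
    expect_equal(eval_yield(par, 1e-6), row$p1, tolerance = 0.01,
                 info = paste(row$damage_class, row$ion, row$channel))
  }
})

test_that("dip term is p4 at L = p5, p4/2 at L = p5*e, symmetric in log", {
  par <- query_params(db, "Li", "SSB")
  p <- par$p
  dip_at <- function(L) {
    p[["p1"]] - (p[["p2"]] * L)^p[["p3"]] - eval_yield(par, L)
  }
  expect_equal(dip_at(p[["p5"]]), p[["p4"]], tolerance = 1e-12)
  expect_equal(dip_at(p[["p5"]] * exp(1)), p[["p4"]] / 2,
               tolerance = 1e-12)
  for (t in c(0.3, 1.7, 2.5)) {
    expect_equal(dip_at(p[["p5"]] * exp(t)), dip_at(p[["p5"]] * exp(-t)),
                 tolerance = 1e-12)
  }
})

test_that("overkill form is monotone without the p4/p5 term, else peaked", {
  lets <- exp(seq(log(0.2), log(600), length.out = 400))
  no_ok <- query_params(db, "H", "DSB")
  expect_true(all(diff(eval_yield(no_ok, lets)) > 0))
  with_ok <- query_params(db, "C", "DSB_SITE")
  y <- eval_yield(with_ok, lets)
  expect_true(any(diff(y) < 0))          # eventually decreasing
  expect_gt(which.max(y), 1)             # interior maximum
  expect_lt(which.max(y), length(y))
})

test_that("clamp policy returns raw negatives by default, 0 on opt-in", {
  par <- query_params(db, "Ne", "SSB")   # decreasing, no dip term
  raw <- eval_yield(par, 1e4)
  expect_lt(raw, 0)
  det <- eval_yield(par, 1e4, clamp = TRUE, details = TRUE)
  expect_equal(det$value, 0)
  expect_true(det$clamped)
  expect_false(det$in_validity_range)
  det2 <- eval_yield(par, 10, details = TRUE)
  expect_false(det2$clamped)
  expect_true(det2$in_validity_range)
})

test_that("evaluation rejects invalid LET and peak_yield the wrong form", {
  par <- query_params(db, "H", "DSB")
  expect_error(eval_yield(par, -1), class = "iondamage_validation_error")
  expect_error(peak_yield(query_params(db, "H", "SSB"), c(1, 300)),
               class = "iondamage_validation_error")
  expect_error(peak_yield(par, c(300, 1)),
               class = "iondamage_validation_error")
})

test_that("peak_yield matches a dense brute-force scan", {
  par <- query_params(db, "C", "DSB_SITE")
  pk <- peak_yield(par, c(1, 300))
  grid <- exp(seq(log(1), log(300), length.out = 2e5))
  brute <- max(eval_yield(par, grid))
  expect_equal(pk$yield, brute, tolerance = 1e-9)
  expect_false(pk$at_boundary)
  expect_true(pk$yield >= 14 && pk$yield <= 16)

  # monotone model peaks at the window edge with the boundary flag
  pk2 <- peak_yield(query_params(db, "H", "DSB"), c(1, 300))
  expect_true(pk2$at_boundary)
  expect_equal(pk2$let, 300, tolerance = 1e-6)

  # tiny window: peak stays inside it
  pk3 <- peak_yield(par, c(50, 50.5))
  expect_true(pk3$let >= 50 && pk3$let <= 50.5)
})

test_that("yield_table equals pointwise evaluation and handles empties", {
  specs <- data.frame(ion = c("H", "C"), damage_class = c("DSB", "SSB"),
                      stringsAsFactors = FALSE)
  lets <- c(1, 10, 100)
  tab <- yield_table(db, specs, lets)
  expect_equal(dim(tab), c(3L, 3L))
  expect_equal(tab$DSB.H.TOTAL,
               eval_yield(query_params(db, "H", "DSB"), lets))
  expect_equal(tab$SSB.C.TOTAL,
               eval_yield(query_params(db, "C", "SSB"), lets))
  empty <- yield_table(db, specs, numeric(0))
  expect_equal(nrow(empty), 0L)
  expect_named(empty, c("let", "DSB.H.TOTAL", "SSB.C.TOTAL"))
  expect_error(yield_table(db, data.frame(ion = "Xx",
                                          damage_class = "DSB"), 1),
               class = "iondamage_validation_error")
})

test_that("RBE is yield over hydrogen low-LET reference", {
  expect_equal(rbe(db, "H", "DSB", let = 0), 1)
  # frozen: carbon DSB at 150 keV/um against hydrogen p1 = 6.8
  expect_equal(rbe(db, "C", "DSB", let = 150), 2.2910383179678296,
               tolerance = 1e-9)
  # interior RBE maximum (overkill) for carbon DSB sites
  lets <- exp(seq(log(1), log(300), length.out = 300))
  r <- rbe(db, "C", "DSB_SITE", lets)
  expect_gt(which.max(r), 1)
  expect_lt(which.max(r), length(r))
  # alternative reference: hydrogen at a stated LET
  ref <- rbe_reference("at_let", let = 2)
  expect_equal(rbe(db, "C", "DSB", 150, reference = ref),
               eval_yield(query_params(db, "C", "DSB"), 150) /
                 eval_yield(query_params(db, "H", "DSB"), 2))
})

test_that("per-cell conversion is bilinear with the 6.6 Gbp default", {
  expect_equal(per_cell_yield(6.8, dose = 1), 44.88)
  expect_equal(per_cell_yield(12.3, dose = 0), 0)
  expect_equal(per_cell_yield(3.1, dose = 2 * 1.7),
               2 * per_cell_yield(3.1, dose = 1.7))
  expect_equal(per_cell_yield(3.1, 1, genome_gbp = 2 * 6.6),
               2 * per_cell_yield(3.1, 1))
  expect_error(per_cell_yield(1, dose = -1),
               class = "iondamage_validation_error")
  expect_warning(per_cell_yield(1, dose = 500), "additivity")
})
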