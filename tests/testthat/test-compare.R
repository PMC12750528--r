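quota_tbl <- function(metal, mean, sd = 0, strain = "S1", n = 3L) {
  tibble::tibble(strain = strain, metal = metal, mean_quota = mean,
                 sd = sd, n = as.integer(n))
}

profile_tbl <- function(metal, abundance, sd = NA_real_, group = "G1") {
  tibble::tibble(group = group, metal = metal, abundance = abundance,
                 sd = sd, n = 3L, n_proteins = 1L)
}

test_that("log-log correlation is exact for proportional inputs, matches a
           closed-form oracle, and ignores profile scaling", {
  metals <- c("Mg", "Fe", "Zn", "Mn", "Cu", "Mo")
  q <- quota_tbl(metals, c(100, 10, 8, 2, 0.5, 0.05))
  prop <- profile_tbl(metals, 0.003 * q$mean_quota)
  r <- correlate_metallome(q, prop)
  expect_equal(r$r_squared, 1, tolerance = 1e-12)
  expect_equal(r$n_points, 6)

  # hand-entered 4-point pairs against the closed-form Pearson sums
  q4 <- quota_tbl(c("Fe", "Zn", "Mn", "Cu"), c(12, 5, 1.2, 0.3))
  p4 <- profile_tbl(c("Fe", "Zn", "Mn", "Cu"), c(0.8, 0.9, 0.05, 0.04))
  r4 <- correlate_metallome(q4, p4)
  expect_equal(
    r4$r_squared,
    oracle_r_squared(log10(q4$mean_quota), log10(p4$abundance)),
    tolerance = 1e-12
  )

  # arbitrary units: rescaling the profile leaves r^2 unchanged
  r4b <- correlate_metallome(q4, dplyr::mutate(p4, abundance = abundance * 570))
  expect_equal(r4b$r_squared, r4$r_squared, tolerance = 1e-12)

  expect_error(
    correlate_metallome(q4[1:2, ], p4),
    "fewer than 3"
  )
})

test_that("metals unmatched between quota and proteome are reported, not
           dropped", {
  q <- quota_tbl(c("Ca", "Fe", "Zn", "Mn", "Cu"), c(5000, 10, 8, 2, 0.5))
  p <- profile_tbl(c("Fe", "Zn", "Mn", "Cu", "W"), c(1, 0.8, 0.2, 0.05, 0.01))
  r <- correlate_metallome(q, p)
  expect_equal(r$n_points, 4)
  expect_setequal(r$excluded$metal, c("Ca", "W"))
  td <- tidy(r)
  expect_equal(nrow(td), 6)
  expect_equal(sum(!td$included), 2)
  g <- glance(r)
  expect_equal(g$n.metals, 4)
  expect_equal(g$space, "log10")
})

test_that("strain ratios propagate SD by the delta method and are exact on
           degenerate inputs", {
  a <- quota_tbl(c("Fe", "Zn"), c(2, 7), sd = c(0, 0))
  b <- quota_tbl(c("Fe", "Zn"), c(4, 7), sd = c(0, 0))
  r <- strain_ratio(b, a)
  expect_equal(r$ratio[r$metal == "Fe"], 2)
  expect_equal(r$sd[r$metal == "Fe"], 0)

  # identical inputs -> all ratios exactly 1
  same <- quota_tbl(c("Fe", "Zn", "Cu"), c(3, 5, 9), sd = c(0.3, 0.5, 0.9))
  rs <- strain_ratio(same, same)
  expect_equal(rs$ratio, rep(1, 3))
  expect_equal(rs$sd, sqrt(2) * c(0.3 / 3, 0.9 / 9, 0.5 / 5),
               tolerance = 1e-12)

  # delta-method SD vs a Monte-Carlo oracle at CV 0.1; the first-order
  # formula undershoots the exact ratio SD by a few percent at this CV
  num <- quota_tbl("Fe", 20, sd = 2)
  den <- quota_tbl("Fe", 10, sd = 1)
  delta_sd <- strain_ratio(num, den)$sd
  expect_equal(delta_sd, 2 * sqrt(0.01 + 0.01), tolerance = 1e-12)
  set.seed(88)
  mc <- sd(rnorm(1e5, 20, 2) / rnorm(1e5, 10, 1))
  expect_lt(abs(delta_sd - mc) / mc, 0.05)
  # and the two converge as the CV shrinks
  mc_small <- sd(rnorm(1e5, 20, 0.2) / rnorm(1e5, 10, 0.1))
  delta_small <- 2 * sqrt(2) * 0.01
  expect_lt(abs(delta_small - mc_small) / mc_small, 0.02)

  # zero denominator -> skipped with warning
  z <- quota_tbl(c("Fe", "Zn"), c(1e-12, 5))
  z$mean_quota[1] <- 0
  expect_warning(rz <- strain_ratio(b, z), "skipped")
  expect_equal(rz$metal, "Zn")
})

test_that("differential expression matches the textbook pooled t-test and
           behaves symmetrically", {
  q <- quant_tbl(
    list(a1 = c(1, 10), a2 = c(2, 11), a3 = c(3, 12),
         b1 = c(4, 10), b2 = c(5, 11), b3 = c(6, 12)),
    proteins = c("pd", "ps"),
    groups = c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  )
  de <- differential_expression(q, "A", "B", normalize = FALSE)
  pd <- de[de$protein_id == "pd", ]
  orc <- oracle_pooled_t(c(1, 2, 3), c(4, 5, 6))
  expect_equal(pd$statistic, orc$statistic, tolerance = 1e-10)
  expect_equal(pd$p, orc$p, tolerance = 1e-10)
  expect_equal(pd$log2fc, log2(5 / 2), tolerance = 1e-12)

  # identical vectors across groups: zero t, p = 1
  ps <- de[de$protein_id == "ps", ]
  expect_equal(ps$statistic, 0)
  expect_equal(ps$p, 1)
  expect_equal(ps$log2fc, 0)

  # swapping groups negates log2fc and leaves p unchanged
  sw <- differential_expression(q, "B", "A", normalize = FALSE)
  expect_equal(sw$log2fc, -de$log2fc, tolerance = 1e-12)
  expect_equal(sw$p, de$p, tolerance = 1e-12)

  expect_error(differential_expression(q, "A", "nope"), "absent")
})

test_that("proteins with under two detected replicates get undefined
           p-values and annotations attach metal lists", {
  q <- quant_tbl(
    list(a1 = c(1, NA), a2 = c(2, NA), b1 = c(2, 5), b2 = c(3, 6)),
    proteins = c("ok", "thin"),
    groups = c(a1 = "A", a2 = "A", b1 = "B", b2 = "B")
  )
  ann <- ann_tbl(c("ok", "ok"), c("Zn", "Fe"), 1)
  de <- differential_expression(q, "A", "B", annotations = ann,
                                normalize = FALSE)
  thin <- de[de$protein_id == "thin", ]
  expect_true(is.na(thin$p))
  expect_equal(thin$n_a, 0L)
  expect_equal(de$metals[de$protein_id == "ok"][[1]], c("Fe", "Zn"))
  expect_equal(de$metals[de$protein_id == "thin"][[1]], character())

  g <- glance(de)
  expect_equal(g$n.tested, 1L)
  td <- tidy(de)
  expect_equal(td$metals[td$protein_id == "ok"], "Fe,Zn")
})

test_that("Welch and BH-adjusted variants differ from the defaults in the
           expected direction", {
  q <- quant_tbl(
    list(a1 = c(1, 1), a2 = c(1.1, 1.2), a3 = c(0.9, 1.1),
         b1 = c(5, 1.2), b2 = c(9, 0.8), b3 = c(2, 1.1)),
    proteins = c("p1", "p2"),
    groups = c(a1 = "A", a2 = "A", a3 = "A", b1 = "B", b2 = "B", b3 = "B")
  )
  student <- differential_expression(q, "A", "B", normalize = FALSE)
  welch <- differential_expression(q, "A", "B", normalize = FALSE,
                                   var_equal = FALSE)
  expect_false(isTRUE(all.equal(student$p[1], welch$p[1])))

  bh <- differential_expression(q, "A", "B", normalize = FALSE,
                                p_adjust = "BH")
  expect_true(all(bh$p_adj >= bh$p, na.rm = TRUE))
})

test_that("the metal roll-up test compares replicate profiles per metal", {
  sim <- simulate_metallome_study(
    n_proteins = 200, n_templates = 20, seed = 17, sigma_log = 0.05,
    missing_rate = 0, group_effects = list(OA16 = c(Cu = 2))
  )
  store <- annotate_templates(sim$paths$structures)
  ann <- transfer_annotations(filter_matches(sim$matches), store)
  reps <- metallome_by_sample(normalize_total(sim$quant, by = "sample"), ann)
  rt <- metal_rollup_test(reps, "OA1", "OA16")
  cu <- rt[rt$metal == "Cu", ]
  expect_true(cu$significant)
  expect_gt(cu$ratio, 1.5)

  # identical groups -> p = 1
  reps_same <- dplyr::bind_rows(
    tibble::tibble(group = "A", sample_id = paste0("a", 1:3),
                   metal = "Zn", abundance = c(1, 2, 3), n_proteins = 2L),
    tibble::tibble(group = "B", sample_id = paste0("b", 1:3),
                   metal = "Zn", abundance = c(1, 2, 3), n_proteins = 2L)
  )
  same <- metal_rollup_test(reps_same, "A", "B")
  expect_equal(same$p, 1)
  expect_equal(same$ratio, 1)

  # one replicate per group: ratio defined, p undefined
  solo <- dplyr::bind_rows(
    tibble::tibble(group = "A", sample_id = "a1", metal = "Zn",
                   abundance = 2, n_proteins = 1L),
    tibble::tibble(group = "B", sample_id = "b1", metal = "Zn",
                   abundance = 4, n_proteins = 1L)
  )
  rs <- metal_rollup_test(solo, "A", "B")
  expect_equal(rs$ratio, 2)
  expect_true(is.na(rs$p))

  expect_error(metal_rollup_test(solo, "A", "nope"), "absent")
})

test_that("quota tables read from TSV validate their invariants", {
  f <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    strain = "OA1", metal = c("Fe", "Zn"),
    mean_mmol_per_molC = c(1.5, 8), sd = c(0.2, 1), n = c(3L, 3L)
  ), f)
  q <- read_quota_table(f)
  expect_equal(q$mean_quota, c(1.5, 8))

  bad <- withr::local_tempfile(fileext = ".tsv")
  readr::write_tsv(tibble::tibble(
    strain = "OA1", metal = "Fe", mean_mmol_per_molC = -1, sd = 0.1, n = 3L
  ), bad)
  expect_error(read_quota_table(bad), "positive")
})
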