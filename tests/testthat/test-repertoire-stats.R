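fake_groups <- function(sizes) {
  dplyr::tibble(
    group_id = sprintf("g%02d", seq_along(sizes)),
    paired_identifier = sprintf("id%02d", seq_along(sizes)),
    size = as.integer(sizes),
    cells = lapply(seq_along(sizes), function(i) {
      sprintf("g%02d_cell%d", i, seq_len(sizes[i]))
    })
  )
}

test_that("clonal size summary separates repeated clonotypes from singletons", {
  sizes <- clonal_size_distribution(fake_groups(c(3, 1, 1)))
  expect_equal(sizes$size, c(3L, 1L, 1L))
  g <- glance(sizes)
  expect_equal(g$n_repeated, 1L)
  expect_equal(g$n_singletons, 2L)
  expect_equal(g$n_cells, 5L)
})

test_that("clonal size summary agrees with brute-force counting on random pools", {
  set.seed(55)
  sizes <- sample(1:6, 40, replace = TRUE)
  g <- glance(clonal_size_distribution(fake_groups(sizes)))
  expect_equal(g$n_singletons, sum(sizes == 1))
  expect_equal(g$n_repeated, sum(sizes > 1))
  expect_equal(g$n_cells, sum(sizes))
})

test_that("pool intersection is exact and symmetric", {
  a <- fake_groups(c(2, 1)); b <- fake_groups(c(1, 1, 1))
  b$paired_identifier <- c("id01", "zz1", "zz2")
  expect_equal(shared_clonotypes(a, b), "id01")
  expect_equal(shared_clonotypes(a, b), shared_clonotypes(b, a))
  b$paired_identifier <- c("q1", "q2", "q3")
  expect_length(shared_clonotypes(a, b), 0L)
})

test_that("usage counts chains per pool with pool totals as denominators", {
  calls <- dplyr::tibble(
    pool = rep("R2", 10), chain = "alpha",
    v_name = c(rep("TRAV5D-4", 4), rep("TRAV2", 6)),
    j_name = "TRAJ18"
  )
  u <- vj_usage(calls, "TRAV5D-4", "alpha", "V")
  expect_equal(u$used, 4L)
  expect_equal(u$total, 10L)
  expect_error(vj_usage(calls, "TRAV99", "alpha", "V"),
               class = "tr1kit_lookup_error")
})

test_that("chi-square on published usage counts is overwhelmingly significant", {
  for (el in c("TRAV5D-4", "TRAJ18", "TRBV1")) {
    res <- chi_square_independence(dplyr::filter(insb_vj_usage(), element == el))
    expect_lt(res$p_value, 1e-4)
    expect_equal(res$df, 3L)
  }
})

test_that("identical proportions give statistic 0 and p = 1", {
  u <- dplyr::tibble(pool = c("A", "B", "C"), used = c(10L, 20L, 30L),
                     total = c(50L, 100L, 150L))
  res <- chi_square_independence(u)
  expect_equal(res$statistic, 0)
  expect_equal(res$p_value, 1)
})

test_that("the 2x2 statistic equals the closed form N(ad-bc)^2/(margins)", {
  a <- 18L; b <- 12L; c <- 7L; d <- 23L
  u <- dplyr::tibble(pool = c("P", "Q"), used = c(a, c), total = c(a + b, c + d))
  res <- chi_square_independence(u)
  n <- a + b + c + d
  closed <- n * (a * d - b * c)^2 /
    ((a + b) * (c + d) * (a + c) * (b + d))
  expect_equal(res$statistic, closed)
})

test_that("scaling all counts by k multiplies the statistic by k", {
  u <- dplyr::tibble(pool = c("A", "B"), used = c(12L, 30L), total = c(40L, 60L))
  r1 <- chi_square_independence(u)
  u3 <- dplyr::mutate(u, used = used * 3L, total = total * 3L)
  r3 <- chi_square_independence(u3)
  expect_equal(r3$statistic, 3 * r1$statistic)
  expect_lte(r3$p_value, r1$p_value)
})

test_that("small expected counts in a 2-pool table fall back to Fisher", {
  u <- dplyr::tibble(pool = c("A", "B"), used = c(1L, 0L), total = c(4L, 5L))
  res <- chi_square_independence(u)
  expect_equal(res$method, "fisher")
  expect_error(chi_square_independence(dplyr::tibble(pool = "A", used = 1L,
                                                     total = 2L)),
               class = "tr1kit_input_error")
  expect_error(chi_square_independence(dplyr::tibble(pool = c("A", "B"),
                                                     used = c(0L, 0L),
                                                     total = c(0L, 5L))),
               class = "tr1kit_input_error")
})

test_that("CDR3 length summaries report mean and SEM with the singleton rule", {
  cdr3 <- dplyr::tibble(pool = c("R1", "R1", "R2"), chain = "beta",
                        cdr3_aa = c(strrep("A", 12), strrep("A", 14),
                                    strrep("C", 9)))
  s <- cdr3_length_summary(cdr3)
  r1 <- s[s$pool == "R1", ]
  expect_equal(r1$mean_length, 13)
  expect_equal(r1$sem, 1)
  expect_equal(s$sem[s$pool == "R2"], 0)  # documented singleton convention
  expect_error(cdr3_length_summary(dplyr::tibble(pool = character(),
                                                 chain = character(),
                                                 cdr3_aa = character())),
               class = "tr1kit_input_error")
})

test_that("a residue fixed in one pool is enriched by one over its background", {
  # pool X: D at position 2 in all 4 sequences; other pools give D background 0.25
  cdr3 <- dplyr::tibble(
    pool = rep(c("X", "Y"), each = 4),
    cdr3_aa = c(rep("CDSSGF", 4), "CASSGF", "CGSSGF", "CTSSGF", "CWSSGF")
  )
  em <- positional_residue_enrichment(cdr3, background = "combined")
  d2 <- em[em$pool == "X" & em$position == 2 & em$residue == "D", ]
  expect_equal(d2$background_freq, 0.5)  # 4 of 8 sequences have D at P2
  expect_equal(d2$enrichment, 2.0)       # 1.0 / 0.5
})

test_that("a pool identical to its background has all enrichment entries 1", {
  cdr3 <- dplyr::tibble(pool = "only",
                        cdr3_aa = c("CASSLF", "CDEGHF", "CWYKRF"))
  em <- positional_residue_enrichment(cdr3, background = "combined")
  expect_true(all(abs(em$enrichment - 1) < 1e-12))
  em_pool <- positional_residue_enrichment(
    dplyr::tibble(pool = rep(c("a", "b"), each = 3),
                  cdr3_aa = rep(c("CASSLF", "CDEGHF", "CWYKRF"), 2)),
    background = "pool")
  expect_true(all(abs(em_pool$enrichment - 1) < 1e-12))
})

test_that("enrichment frequencies match brute-force counting on random pools", {
  set.seed(66)
  rand_cdr3 <- function(n) {
    vapply(seq_len(n), function(i) {
      paste(c("C", sample(strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]],
                          sample(4:8, 1), replace = TRUE)), collapse = "")
    }, character(1))
  }
  cdr3 <- dplyr::tibble(pool = rep(c("p1", "p2"), times = c(12, 18)),
                        cdr3_aa = rand_cdr3(30))
  em <- positional_residue_enrichment(cdr3, n_positions = 6)
  # brute-force one entry
  row <- em[em$pool == "p2" & em$position == 3, ][1, ]
  p2_res <- substr(cdr3$cdr3_aa[cdr3$pool == "p2"], 3, 3)
  p2_res <- p2_res[p2_res != ""]
  expect_equal(row$pool_freq, mean(p2_res == row$residue))
  all_res <- substr(cdr3$cdr3_aa, 3, 3)
  all_res <- all_res[all_res != ""]
  expect_equal(row$background_freq, mean(all_res == row$residue))
})

test_that("charged P2/P3 fractions count distinct clonotypes", {
  # exactly one of two qualifies (D at P2); numbering starts at the Cys
  res <- charged_p2p3_fraction(c("CDSSG", "CSSSG"))
  expect_equal(res$fraction, 0.5)
  # duplicates collapse to one clonotype
  res2 <- charged_p2p3_fraction(c("CDSSG", "CDSSG", "CSSSG"))
  expect_equal(res2$fraction, 0.5)
  # short sequences leave the denominator, with a message
  expect_message(res3 <- charged_p2p3_fraction(c("CDSSG", "CS")), "excluded")
  expect_equal(res3$n_excluded, 1L)
  expect_equal(res3$fraction, 1)
  expect_error(suppressMessages(charged_p2p3_fraction(c("CD"))),
               class = "tr1kit_input_error")
})
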