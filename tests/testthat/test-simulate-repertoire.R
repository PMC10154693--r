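germ <- test_germline()

test_that("all-singleton clone-size distribution yields one clone per cell", {
  cfg <- repertoire_config(n_cells = c(R1 = 20), clone_size_mean = c(R1 = 1),
                           leak_rate = 0)
  rep <- simulate_repertoire(germ, cfg, seed = 3)
  expect_equal(nrow(rep$clones), 20L)
  expect_true(all(rep$clones$size == 1L))
  expect_equal(nrow(rep$cells), 20L)
})

test_that("clone sizes always sum to the requested pool sizes", {
  cfg <- repertoire_config(n_cells = c(Tconv = 37, R2 = 53), leak_rate = 0)
  rep <- simulate_repertoire(germ, cfg, seed = 11)
  sums <- tapply(rep$cells$cell_id, rep$cells$pool, length)
  expect_equal(as.integer(sums[c("Tconv", "R2")]), c(37L, 53L))
})

test_that("error-free contigs are exact V + junction + J concatenations", {
  cfg <- repertoire_config(n_cells = c(R1 = 15), error_rate = 0)
  rep <- simulate_repertoire(germ, cfg, seed = 5)
  seq_of <- stats::setNames(germ$sequence, germ$name)
  rebuilt <- paste0(seq_of[rep$clone_chains$v_name],
                    rep$clone_chains$junction_nt,
                    seq_of[rep$clone_chains$j_name])
  expect_equal(unname(rebuilt), rep$clone_chains$sequence)
  # productive chains: junction in frame with the V cysteine
  expect_true(all(nchar(rep$clone_chains$junction_nt) %% 3 == 0))
})

test_that("forced charged motif puts D/E at CDR3beta P2 or P3 in every clone", {
  cfg <- repertoire_config(n_cells = c(R3 = 30),
                           charged_motif_prob = c(R3 = 1), error_rate = 0)
  rep <- simulate_repertoire(germ, cfg, seed = 6)
  beta <- rep$clone_chains[rep$clone_chains$chain == "beta", ]
  p23 <- substr(vapply(beta$junction_nt, oracle_translate, character(1)), 1, 2)
  expect_true(all(grepl("[DE]", p23)))

  cfg0 <- repertoire_config(n_cells = c(R3 = 30),
                            charged_motif_prob = c(R3 = 0), error_rate = 0)
  rep0 <- simulate_repertoire(germ, cfg0, seed = 6)
  beta0 <- rep0$clone_chains[rep0$clone_chains$chain == "beta", ]
  p23_0 <- substr(vapply(beta0$junction_nt, oracle_translate, character(1)), 1, 2)
  expect_false(any(grepl("[DE]", p23_0)))
})

test_that("skewed V usage matches the configured weight within a binomial CI", {
  lead_p <- 10 / 12  # 10:1 against the two other alpha V segments
  cfg <- repertoire_config(
    n_cells = c(R1 = 200), clone_size_mean = c(R1 = 1),
    lead_usage = list(v_alpha = c(R1 = lead_p)), leak_rate = 0
  )
  rep <- simulate_repertoire(germ, cfg, seed = 8)
  alpha <- rep$clone_chains[rep$clone_chains$chain == "alpha", ]
  n_lead <- sum(alpha$v_name == "TRAV5D-4")
  # independent binomial oracle: exact 99% acceptance interval
  lo <- qbinom(0.005, nrow(alpha), lead_p)
  hi <- qbinom(0.995, nrow(alpha), lead_p)
  expect_gte(n_lead, lo)
  expect_lte(n_lead, hi)
})

test_that("low-avidity leak copies whole repeated clonotypes into Tconv", {
  cfg <- repertoire_config(n_cells = c(Tconv = 20, R2 = 60),
                           clone_size_mean = c(Tconv = 1, R2 = 5),
                           leak_rate = 1, leak_cells = 2L)
  rep <- simulate_repertoire(germ, cfg, seed = 9)
  repeated_r2 <- rep$clones$true_identifier[rep$clones$pool == "R2" &
                                              rep$clones$size > 2L]
  tconv_ids <- rep$clones$true_identifier[
    rep$clones$clone_id %in% rep$cells$clone_id[rep$cells$pool == "Tconv"]]
  expect_gt(length(intersect(repeated_r2, tconv_ids)), 0L)
})

test_that("the simulator is a pure function of (germline, config, seed)", {
  cfg <- repertoire_config(n_cells = c(Tconv = 10, R1 = 10))
  r1 <- simulate_repertoire(germ, cfg, seed = 42)
  r2 <- simulate_repertoire(germ, cfg, seed = 42)
  expect_identical(r1$contigs, r2$contigs)
  expect_identical(r1$clones, r2$clones)
  r3 <- simulate_repertoire(germ, cfg, seed = 43)
  expect_false(identical(r1$contigs$sequence, r3$contigs$sequence))
})

test_that("bad inputs are rejected", {
  expect_error(simulate_repertoire(dplyr::tibble(), repertoire_config(), 1),
               class = "tr1kit_config_error")
  expect_error(repertoire_config(leak_rate = 1.5),
               class = "tr1kit_parameter_error")
})
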