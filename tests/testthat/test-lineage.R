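mk_groups <- function(spec) {
  # spec: named list clonotype -> character vector of member cells
  dplyr::tibble(
    group_id = names(spec),
    paired_identifier = paste0("id_", names(spec)),
    size = lengths(spec),
    cells = unname(spec)
  )
}

test_that("the cluster table counts member cells per cluster", {
  groups <- mk_groups(list(g1 = c("a1", "a2", "a3"), g2 = "b1"))
  labels <- dplyr::tibble(cell_id = c("a1", "a2", "a3", "b1"),
                          cluster = c(1L, 2L, 2L, 0L))
  tab <- clonotype_cluster_table(groups, labels)
  expect_equal(nrow(tab), 1L)  # only the repeated clonotype
  expect_equal(tab$cluster_0, 0L)
  expect_equal(tab$cluster_1, 1L)
  expect_equal(tab$cluster_2, 2L)
})

test_that("an all-singleton repertoire yields an empty table with a warning", {
  groups <- mk_groups(list(g1 = "a", g2 = "b"))
  labels <- dplyr::tibble(cell_id = c("a", "b"), cluster = c(0L, 1L))
  expect_warning(tab <- clonotype_cluster_table(groups, labels),
                 "no repeated clonotypes")
  expect_equal(nrow(tab), 0L)
})

test_that("the table matches generator bookkeeping on simulated data", {
  germ <- test_germline()
  cfg <- repertoire_config(n_cells = c(R2 = 60), clone_size_mean = c(R2 = 4),
                           error_rate = 0, leak_rate = 0)
  rep <- simulate_repertoire(germ, cfg, seed = 71)
  groups <- rep$cells |>
    dplyr::left_join(rep$clones[c("clone_id", "true_identifier")], by = "clone_id") |>
    dplyr::group_by(paired_identifier = true_identifier) |>
    dplyr::summarise(size = dplyr::n(), cells = list(cell_id)) |>
    dplyr::mutate(group_id = paired_identifier)
  labels <- dplyr::tibble(cell_id = rep$cells$cell_id,
                          cluster = rep$cells$true_cluster)
  tab <- clonotype_cluster_table(groups, labels)
  # conservation: entries sum to clustered cells of repeated clonotypes
  repeated_cells <- sum(groups$size[groups$size > 1])
  expect_equal(sum(tab$n_cells), repeated_cells)
  # brute-force one row
  g <- tab$group_id[1]
  members <- groups$cells[[match(g, groups$group_id)]]
  truth <- table(factor(rep$cells$true_cluster[rep$cells$cell_id %in% members],
                        levels = 0:2))
  expect_equal(as.integer(truth),
               as.integer(tab[1, c("cluster_0", "cluster_1", "cluster_2")]))
})

test_that("sharing summary classifies by membership in clusters 1 and 2", {
  tab <- dplyr::tibble(
    group_id = c("g1", "g2", "g3"),
    paired_identifier = c("a", "b", "c"),
    cluster_0 = c(0L, 0L, 0L),
    cluster_1 = c(2L, 1L, 0L),
    cluster_2 = c(3L, 0L, 4L),
    n_cells = c(5, 1, 4)
  )
  ss <- sharing_summary(tab)
  expect_equal(ss$n_clonotypes, c(1L, 1L, 1L))
  expect_equal(sum(ss$n_cells), 10)
  expect_equal(sum(ss$fraction), 1)
})

test_that("sharing fractions always sum to one and cover every clonotype", {
  set.seed(72)
  n <- 25
  tab <- dplyr::tibble(
    group_id = sprintf("g%02d", 1:n),
    paired_identifier = sprintf("i%02d", 1:n),
    cluster_0 = rpois(n, 1),
    cluster_1 = rpois(n, 1.5),
    cluster_2 = rpois(n, 2)
  )
  tab$n_cells <- tab$cluster_0 + tab$cluster_1 + tab$cluster_2
  ss <- sharing_summary(tab)
  in_12 <- sum(tab$cluster_1 + tab$cluster_2 > 0)
  expect_equal(sum(ss$n_clonotypes) + attr(ss, "n_excluded"), n)
  expect_equal(sum(ss$n_clonotypes), in_12)
  expect_equal(sum(ss$fraction), 1)
})

test_that("a generator with known sharing probability is recovered within CI", {
  set.seed(73)
  p_shared <- 0.8
  n <- 200
  shared <- runif(n) < p_shared
  tab <- dplyr::tibble(
    group_id = sprintf("g%03d", 1:n),
    paired_identifier = sprintf("i%03d", 1:n),
    cluster_0 = 0L,
    cluster_1 = ifelse(shared, 1L, rbinom(n, 1, 0.5)),
    cluster_2 = 1L
  )
  tab$cluster_2[!shared & tab$cluster_1 == 1L] <- 0L
  tab$n_cells <- tab$cluster_0 + tab$cluster_1 + tab$cluster_2
  ss <- sharing_summary(tab)
  obs <- ss$n_clonotypes[ss$category == "shared"]
  ci <- qbinom(c(0.005, 0.995), n, p_shared)
  expect_gte(obs, ci[1])
  expect_lte(obs, ci[2])
})

test_that("proportionality p-values follow the exact binomial", {
  tab <- dplyr::tibble(group_id = "g1", paired_identifier = "a",
                       cluster_0 = 0L, cluster_1 = 6L, cluster_2 = 3L,
                       n_cells = 9)
  # cluster sizes 2:1 -> null proportion 1/3; 6:3 is exactly proportional
  res <- proportionality_check(tab, cluster_sizes = c("1" = 100, "2" = 50))
  expect_equal(res$p_value, 1)
  # closed form: 10:0 against p0 = 0.5 gives 2 * 0.5^10
  tab2 <- dplyr::tibble(group_id = "g2", paired_identifier = "b",
                        cluster_0 = 0L, cluster_1 = 10L, cluster_2 = 0L,
                        n_cells = 10)
  res2 <- proportionality_check(tab2, cluster_sizes = c("1" = 50, "2" = 50))
  expect_equal(res2$p_value, 2 * 0.5^10)
})

test_that("proportional allocation is called consistent for most clonotypes", {
  set.seed(74)
  reps <- 40
  size1 <- 60; size2 <- 140
  p0 <- size2 / (size1 + size2)
  tab <- dplyr::tibble(
    group_id = sprintf("g%02d", 1:reps),
    paired_identifier = sprintf("i%02d", 1:reps),
    cluster_0 = 0L,
    total = 4L + rpois(reps, 6)
  )
  tab$cluster_2 <- rbinom(reps, tab$total, p0)
  tab$cluster_1 <- tab$total - tab$cluster_2
  tab$n_cells <- tab$total
  res <- proportionality_check(tab[, -4],
                               cluster_sizes = c("1" = size1, "2" = size2))
  expect_gte(glance(res)$fraction_consistent, 0.9)
})
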