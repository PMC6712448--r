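test_that("Fisher p reproduces the cohort sex comparisons", {
  # published cohort counts: men/women 494/349 (NH), 29/28 (CH), 9/1 (PC)
  expect_equal(round(fisher_exact_2x2(494, 9, 349, 1)$p_value, 3), 0.054)
  expect_equal(round(fisher_exact_2x2(29, 9, 28, 1)$p_value, 3), 0.035)
})

test_that("a balanced table gives p = 1", {
  expect_equal(fisher_exact_2x2(5, 5, 5, 5)$p_value, 1)
})

test_that("Fisher p equals the enumeration oracle on random tables", {
  set.seed(41)
  for (i in 1:200) {
    n <- sample(4:200, 1)
    cells <- as.numeric(stats::rmultinom(1, n, stats::runif(4, 0.05, 1)))
    p <- fisher_exact_2x2(cells[1], cells[2], cells[3], cells[4])$p_value
    p_oracle <- fisher_enum_oracle(cells[1], cells[2], cells[3], cells[4])
    expect_equal(p, p_oracle, tolerance = 1e-10)
  }
})

test_that("Fisher p agrees with the stats reference implementation", {
  set.seed(42)
  for (i in 1:50) {
    cells <- as.numeric(stats::rmultinom(1, sample(10:150, 1),
                                         stats::runif(4, 0.05, 1)))
    m <- matrix(cells, 2)
    expect_equal(fisher_exact_2x2(m[1, 1], m[1, 2], m[2, 1], m[2, 2])$p_value,
                 stats::fisher.test(m)$p.value, tolerance = 1e-7)
  }
})

test_that("Fisher p is invariant to transposition and row/column swaps", {
  set.seed(43)
  for (i in 1:50) {
    x <- sample(0:30, 4, replace = TRUE)
    if (sum(x) == 0) next
    p <- fisher_exact_2x2(x[1], x[2], x[3], x[4])$p_value
    expect_equal(fisher_exact_2x2(x[1], x[3], x[2], x[4])$p_value, p,
                 tolerance = 1e-12)  # transpose
    expect_equal(fisher_exact_2x2(x[4], x[3], x[2], x[1])$p_value, p,
                 tolerance = 1e-12)  # both rows and columns swapped
  }
})

test_that("Fisher rejects degenerate input", {
  expect_error(fisher_exact_2x2(0, 0, 0, 0), "empty")
  expect_error(fisher_exact_2x2(-1, 2, 3, 4), "nonnegative")
  expect_error(fisher_exact_2x2(1.5, 2, 3, 4), "nonnegative")
})

test_that("Mann-Whitney: exact closed form on fully separated triples", {
  res <- mann_whitney_u(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$U, 0)
  expect_equal(res$p_value, 0.1)   # 2 / choose(6, 3)
  expect_equal(res$method, "exact")
})

test_that("Mann-Whitney: identical samples give p near 1", {
  x <- c(3.2, 5.5, 7.1, 2.2, 9.9)
  res <- mann_whitney_u(x, x)
  expect_gte(res$p_value, 0.99)
})

test_that("Mann-Whitney approximation agrees with the exact distribution", {
  set.seed(44)
  for (i in 1:20) {
    x <- stats::rnorm(15); y <- stats::rnorm(15, 0.5)
    exact <- mann_whitney_u(x, y, exact_max = 15)
    approx <- mann_whitney_u(x, y, exact_max = 0)
    expect_lt(abs(approx$p_value - exact$p_value), 0.01)
  }
})

test_that("Mann-Whitney agrees with a permutation oracle", {
  set.seed(45)
  x <- stats::rnorm(15); y <- stats::rnorm(15, 1)
  p <- mann_whitney_u(x, y)$p_value
  p_perm <- mw_permutation_oracle(x, y, n_perm = 20000)
  expect_lt(abs(p - p_perm), 0.01)
})

test_that("large shifted samples are detected at extreme significance", {
  set.seed(46)
  x <- stats::rnorm(100); y <- stats::rnorm(100, 1)
  expect_lt(mann_whitney_u(x, y)$p_value, 1e-6)
})

test_that("Mann-Whitney rejects empty groups", {
  expect_error(mann_whitney_u(numeric(0), 1:3), "empty")
})

test_that("75th-percentile normalization behaves by construction", {
  set.seed(47)
  raw <- stats::rlnorm(200, 5, 1)
  norm <- normalize_expression(raw)
  expect_equal(stats::quantile(norm, 0.75, names = FALSE), 0)
  expect_equal(norm, log2(raw) - stats::quantile(log2(raw), 0.75,
                                                 names = FALSE))
  # constant sample normalizes to all zeros
  expect_equal(normalize_expression(rep(7, 10)), rep(0, 10))
  # global scale factors cancel
  expect_equal(normalize_expression(raw * 3.7), norm, tolerance = 1e-12)
  expect_error(normalize_expression(c(1, -2)), "positive")
})

test_that("expression comparison recovers engineered shifts", {
  set.seed(48)
  labels <- c(stats::setNames(rep("nonhypermutator", 200), paste0("N", 1:200)),
              stats::setNames(rep("common_hypermutator", 40), paste0("C", 1:40)),
              stats::setNames(rep("pole_category", 10), paste0("P", 1:10)))
  effects <- list(genes = c("PD-L1", "CTLA-4"),
                  nonhypermutator = c(0, 0),
                  common_hypermutator = c(1.5, 0),
                  pole_category = c(1.5, 0))
  records <- simulate_expression(labels, effects, sd = 1)
  res <- compare_expression_by_group(records, labels, "PD-L1")
  expect_lt(res$p_values[["NH_vs_CH"]], 0.05)
  expect_lt(res$p_values[["NH_vs_PC"]], 0.05)
  expect_gt(res$p_values[["CH_vs_PC"]], 0.05)

  # identical distributions: all p comfortably nonsignificant
  flat <- records
  flat$fold_change <- 0
  res_flat <- compare_expression_by_group(flat, labels, "PD-L1")
  expect_true(all(res_flat$p_values > 0.9))

  expect_error(compare_expression_by_group(records, labels, "CD8A"),
               "absent")
})

test_that("the three-group comparison reproduces published p-values from
           marginal counts", {
  clin <- expand_group_counts()
  profiles <- data.frame(tumor_id = clin$tumor_id, label = clin$label,
                         stringsAsFactors = FALSE)
  rep <- build_group_comparison(profiles,
                                clin[, setdiff(names(clin), "label")])
  expect_equal(unname(rep$groups),
               c(843L, 57L, 10L))
  tab <- rep$table
  p_of <- function(var) tab[tab$variable == var &
                              !is.na(tab$p_NH_vs_PC),
                            c("p_NH_vs_PC", "p_CH_vs_PC")][1, ]
  expect_equal(unlist(p_of("sex"), use.names = FALSE), c(0.054, 0.035))
  expect_equal(unlist(p_of("location"), use.names = FALSE), c(0.489, 0.069))
  expect_equal(unlist(p_of("histology"), use.names = FALSE), c(0.076, 0.717))
  expect_equal(unlist(p_of("pT"), use.names = FALSE), c(1.000, 1.000))
  expect_equal(unlist(p_of("pStage"), use.names = FALSE), c(0.052, 0.487))
  expect_equal(unlist(p_of("lymphatic_invasion"), use.names = FALSE),
               c(0.538, 0.299))
  expect_equal(unlist(p_of("vessel_invasion"), use.names = FALSE),
               c(0.320, 1.000))
  # formatted percentage cells match the published style
  expect_equal(tab$nonhypermutator[tab$variable == "sex" &
                                     tab$level == "man"], "494 (58.6)")
})

test_that("single-group cohorts report counts with comparisons not computable", {
  clin <- expand_group_counts()
  nh <- clin[clin$label == "nonhypermutator", ]
  profiles <- data.frame(tumor_id = nh$tumor_id, label = nh$label,
                         stringsAsFactors = FALSE)
  rep <- build_group_comparison(profiles,
                                nh[, setdiff(names(nh), "label")])
  expect_true(all(is.na(rep$table$p_NH_vs_PC)))
  expect_true(all(rep$table$pole_category == "-"))
})

test_that("unjoinable tumor ids are reported", {
  clin <- expand_group_counts()[1:5, ]
  profiles <- data.frame(tumor_id = c(clin$tumor_id, "GHOST"),
                         label = "nonhypermutator",
                         stringsAsFactors = FALSE)
  expect_error(
    build_group_comparison(profiles,
                           clin[, setdiff(names(clin), "label")]),
    "GHOST")
})
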