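make_gene_table <- function(groups) {
  # build a gene table whose classification should equal `groups`
  phen <- list(
    DL = "embryonic lethality", DV = "abnormal gait",
    L = "prenatal lethality", V = "small body size",
    DU = character(), NONDISEASE_UNKNOWN = character()
  )
  tibble::tibble(
    gene_id = sprintf("g%03d", seq_along(groups)),
    mouse_ortholog = sprintf("m%03d", seq_along(groups)),
    ko_phenotypes = lapply(groups, function(g) phen[[g]]),
    is_disease = groups %in% c("DL", "DV", "DU"),
    is_housekeeping = FALSE
  )
}

test_that("lethality calls follow the any-lethal-wins substring rule", {
  expect_identical(is_lethal("embryonic lethality, complete penetrance"), "lethal")
  expect_identical(is_lethal(character()), "unknown")
  expect_identical(is_lethal(c("abnormal gait", "prenatal lethality")), "lethal")
  expect_identical(is_lethal(c("abnormal gait", "small body size")), "viable")
  expect_identical(is_lethal("PERINATAL LETHALITY"), "lethal")
  expect_identical(is_lethal("lethargy", lethal_terms = "lethality"), "viable")
})

test_that("classification assigns the six groups per definition", {
  groups <- c(rep("DL", 4), rep("DV", 2), rep("DU", 3), rep("L", 2), "V")
  cl <- classify_essentiality(make_gene_table(groups))
  expect_identical(cl$group, groups)
  tab <- tabulate_groups(cl)
  expect_identical(tab$n[match(c("DL", "DV", "DU", "L", "V"), tab$group)],
                   c(4L, 2L, 3L, 2L, 1L))
})

test_that("headline shares reproduce the known ratios and guard empty denominators", {
  # 673/793 lethal among known-essentiality disease genes; 1299/1971 overall
  groups <- c(rep("DL", 673), rep("DV", 120), rep("L", 1299 - 673),
              rep("V", 672 - 120), rep("DU", 1172))
  sh <- glance(tabulate_groups(classify_essentiality(make_gene_table(groups))))
  expect_identical(sh$lethal_share_known_pct, 85)
  expect_identical(sh$lethal_share_knockouts_pct, 66)
  expect_identical(sh$dl_share_of_disease_pct, 34)
  expect_identical(sh$dv_share_of_disease_pct, 6)

  sh0 <- glance(tabulate_groups(classify_essentiality(make_gene_table(c("DU", "DU")))))
  expect_true(is.na(sh0$lethal_share_known_pct))
  expect_true(is.na(sh0$lethal_share_knockouts_pct))
})

test_that("housekeeping overlap builds the genome-level 2x2", {
  groups <- c(rep("DU", 1172), rep("DL", 673), rep("DV", 120),
              rep("L", 626), rep("V", 552))
  gt <- make_gene_table(groups)
  du_idx <- which(groups == "DU")
  other_idx <- which(groups != "DU")
  gt$is_housekeeping[c(du_idx[1:64], other_idx[1:545])] <- TRUE
  cl <- classify_essentiality(gt)
  hk <- housekeeping_overlap(cl, genome_size = 24789)
  expect_identical(unname(as.vector(t(hk$table))), c(64, 1108, 545, 23072))
  expect_identical(hk$group_pct, 5.5)
  expect_identical(hk$genome_pct, 2.5)
  expect_lt(hk$test$p_value, 0.05)

  expect_error(housekeeping_overlap(cl, genome_size = 100), "smaller than")

  gt$is_housekeeping <- FALSE
  hk0 <- housekeeping_overlap(classify_essentiality(gt), genome_size = 24789)
  expect_identical(hk0$group_pct, 0)
  expect_true(is.na(hk0$odds_ratio))
})

test_that("housekeeping percentages equal brute-force counts on random tables", {
  withr::local_seed(7)
  for (rep in 1:5) {
    groups <- sample(c("DL", "DV", "DU", "L", "V", "NONDISEASE_UNKNOWN"),
                     200, replace = TRUE)
    gt <- make_gene_table(groups)
    gt$is_housekeeping <- sample(c(TRUE, FALSE), 200, replace = TRUE, prob = c(.1, .9))
    cl <- classify_essentiality(gt)
    hk <- housekeeping_overlap(cl, genome_size = 500)
    a <- sum(groups == "DU" & gt$is_housekeeping)
    n_du <- sum(groups == "DU")
    expect_equal(hk$group_pct,
                 floor(1000 * a / n_du + 0.5) / 10)
    expect_equal(sum(hk$table), 500)
    expect_equal(hk$table[1, 1], a)
  }
})

test_that("groups partition the universe and reclassification is local", {
  withr::local_seed(11)
  groups <- sample(c("DL", "DV", "DU", "L", "V", "NONDISEASE_UNKNOWN"),
                   60, replace = TRUE)
  groups[[1]] <- "DU"
  gt <- make_gene_table(groups)
  cl <- classify_essentiality(gt)
  expect_identical(sum(table(cl$group)), 60L)
  expect_true(all(cl$group[cl$is_disease] %in% c("DL", "DV", "DU")))

  # adding a lethal report to a DU gene makes it DL and changes nothing else
  du <- which(cl$group == "DU")[1]
  gt2 <- gt
  gt2$ko_phenotypes[[du]] <- "embryonic lethality"
  cl2 <- classify_essentiality(gt2)
  expect_identical(cl2$group[[du]], "DL")
  expect_identical(cl2$group[-du], cl$group[-du])
})

test_that("tabulation is invariant to row order", {
  groups <- c(rep("DL", 5), rep("DV", 3), rep("DU", 2), "L", "V")
  cl <- classify_essentiality(make_gene_table(groups))
  perm <- cl[sample(nrow(cl)), ]
  t1 <- tabulate_groups(cl)
  t2 <- tabulate_groups(perm)
  expect_equal(as.data.frame(t1), as.data.frame(t2))
  expect_identical(glance(t1), glance(t2))
})
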