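test_that("a single biallelic SNP yields root plus two leaves with allele counts", {
  g <- make_gt(matrix(rep(c(0L, 1L), c(6, 4))), rep(c(1L, 2L), 5))
  tree <- build_tree(g)
  expect_equal(nrow(tree$nodes), 3L)
  expect_equal(tree$nodes$size, c(10L, 6L, 4L))
  expect_equal(tree$nodes$branch[2:3], c("wild", "mutant"))
  expect_equal(tree$nodes$parent[2:3], c(1L, 1L))
  expect_setequal(tree$leaves, 2:3)
})

test_that("hand-enumerated 3-SNP tree matches the constructed topology exactly", {
  # SNPs A, B, C at MAFs 0.4, 0.3, 0.1 (split order A, B, C); haplotypes:
  # i1,i2=110; i3=101; i4=100; i5=010; i6..i10=000
  geno <- rbind(c(1,1,0), c(1,1,0), c(1,0,1), c(1,0,0), c(0,1,0),
                matrix(0L, 5, 3))
  g <- make_gt(matrix(as.integer(geno), 10, 3), rep(c(2L, 1L), 5))
  tree <- build_tree(g)
  nd <- tree$nodes
  expect_equal(nrow(nd), 9L)
  expect_equal(nd$parent, c(NA, 1L, 1L, 2L, 2L, 3L, 3L, 6L, 6L))
  expect_equal(nd$branch[-1],
               c("wild", "mutant", "wild", "mutant", "wild", "mutant",
                 "wild", "mutant"))
  expect_equal(nd$snp[-1], c(1L, 1L, 2L, 2L, 2L, 2L, 3L, 3L))
  expect_identical(tree$members[[3]], c(1L, 2L, 3L, 4L))   # A mutants
  expect_identical(tree$members[[7]], c(1L, 2L))           # A+B mutants
  expect_identical(tree$members[[9]], 3L)                  # A,C mutant
  expect_setequal(tree$leaves, c(4L, 5L, 7L, 8L, 9L))      # 5 distinct haplotypes
  # count conservation: children partition their parent at every node
  for (id in nd$id) {
    kids <- nd$id[!is.na(nd$parent) & nd$parent == id]
    if (length(kids))
      expect_setequal(unlist(tree$members[kids]), tree$members[[id]])
    expect_equal(nd$n_cases[id] + nd$n_controls[id], nd$size[id])
  }
})

test_that("monomorphic SNPs contribute no node", {
  g <- make_gt(cbind(rep(c(0L, 1L), 5), 0L), rep(c(1L, 2L), 5))
  tree <- build_tree(g)
  expect_equal(nrow(tree$nodes), 3L)  # only the polymorphic SNP splits
})

test_that("build_tree enforces the zero-missingness contract", {
  g <- make_gt(matrix(c(0L, 1L, NA, 0L), 4, 1), rep(c(1L, 2L), 2))
  expect_error(build_tree(g), "missing genotypes")
})

test_that("node chi-square matches the closed 2x2 form and the stats oracle", {
  expect_equal(chisq_2x2(10, 40, 40, 10), 36)
  # balanced node: case fraction inside equals outside -> statistic 0
  expect_equal(chisq_2x2(10, 40, 10, 40), 0)
  # margin-zero convention
  expect_equal(chisq_2x2(0, 0, 10, 20), 0)
  set.seed(404)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 30) + 1, 2)
    expect_equal(chisq_2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2]),
                 unname(stats::chisq.test(tab, correct = FALSE)$statistic),
                 tolerance = 1e-12)
  }
})

test_that("node statistics carry the right direction and margins", {
  g <- make_gt(matrix(rep(c(1L, 0L), c(4, 6))), rep(c(2L, 1L), c(5, 5)))
  tree <- build_tree(g)
  st <- node_statistics(tree)
  expect_false(1L %in% st$node_id)  # root excluded
  mut <- st[st$node_id == 3L, ]     # 4 mutants, all cases
  expect_equal(mut$direction, "risk")
  expect_equal(mut$cases_in + mut$cases_out, 5L)
  expect_equal(mut$controls_in + mut$controls_out, 5L)
  wld <- st[st$node_id == 2L, ]
  expect_equal(wld$direction, "protective")
  expect_equal(wld$statistic, mut$statistic)  # complement symmetry at the root split
})

test_that("greedy antichain selection follows the ancestor-exclusion rule", {
  # chain root -> a -> b with stats a=5, b=3: only a selected
  chain <- structure(list(nodes = data.frame(id = 1:3, parent = c(NA, 1L, 2L),
                                             depth = 0:2), root_id = 1L),
                     class = "haplotype_tree")
  stats <- data.frame(node_id = 2:3, statistic = c(5, 3), depth = 1:2)
  out <- tree_statistic(stats, chain)
  expect_equal(out$selected_nodes$node_id, 2L)
  expect_equal(out$S, 5)
  # five sibling leaves: a ready-made antichain, all selected
  sib <- structure(list(nodes = data.frame(id = 1:6,
                                           parent = c(NA, rep(1L, 5)),
                                           depth = c(0, rep(1, 5))),
                        root_id = 1L), class = "haplotype_tree")
  stats <- data.frame(node_id = 2:6, statistic = 1:5, depth = 1)
  out <- tree_statistic(stats, sib)
  expect_equal(out$S, 15)
  expect_setequal(out$selected_nodes$node_id, 2:6)
})

test_that("greedy selection equals an independent brute-force on random trees", {
  set.seed(777)
  for (rep in 1:60) {
    n_nodes <- sample(3:12, 1)
    tree <- random_tree_skeleton(n_nodes)
    stats <- data.frame(node_id = 2:n_nodes,
                        statistic = round(runif(n_nodes - 1, 0, 3), 1),
                        depth = tree$nodes$depth[-1])
    out <- tree_statistic(stats, tree)
    expect_identical(out$selected_nodes$node_id,
                     oracle_greedy(tree$nodes, stats))
    # the selection is an antichain by explicit ancestor check
    sel <- out$selected_nodes$node_id
    anc <- function(id) {
      p <- tree$nodes$parent[id]; out <- integer(0)
      while (!is.na(p)) { out <- c(out, p); p <- tree$nodes$parent[p] }
      out
    }
    for (x in sel) expect_false(any(setdiff(sel, x) %in% c(anc(x))) ||
                                  any(vapply(setdiff(sel, x),
                                             function(y) x %in% anc(y), TRUE)))
  }
})

test_that("permutation p-value respects its definitional bounds and determinism", {
  g <- simulate_cohort(planted_sim_config(seed = 2, n_cases = 150L,
                                          n_controls = 150L))
  tt1 <- run_tree_test(g, n_perm = 199, seed = 5)
  tt2 <- run_tree_test(g, n_perm = 199, seed = 5)
  expect_identical(tt1$result$p_perm, tt2$result$p_perm)
  expect_gte(tt1$result$p_perm, 1 / 200)
  expect_lte(tt1$result$p_perm, 1)
  # S_obs is reproduced by the permutation-route arithmetic under the
  # identity labelling
  tree <- tt1$tree
  ids <- tree$nodes$id[-1]
  n_case <- tree$nodes$n_cases[1]; n <- tree$nodes$size[1]
  lab <- as.numeric(tree$case)
  a <- vapply(ids, function(id) sum(lab[tree$members[[id]]]), 0)
  size <- tree$nodes$size[-1]
  stat <- chisq_2x2(a, n_case - a, size - a, (n - n_case) - (size - a))
  st <- node_statistics(tree)
  expect_equal(stat[match(st$node_id, ids)], st$statistic, tolerance = 1e-12)
})

test_that("a perfectly balanced tree gives permutation p of 1", {
  geno <- rep(c(0L, 1L), each = 8)
  phen <- rep(c(1L, 2L), 8)  # case fraction identical inside both branches
  g <- make_gt(matrix(geno), phen)
  tree <- build_tree(g)
  res <- permutation_test(tree, n_perm = 99, seed = 1)
  expect_equal(res$S, 0)
  expect_equal(res$p_perm, 1)
})

test_that("adding balanced case/control pairs to a node never raises its chi-square", {
  for (tab in list(c(10, 40, 5, 45), c(3, 7, 1, 9), c(25, 25, 10, 40))) {
    stats <- vapply(0:30, function(t)
      chisq_2x2(tab[1] + t, tab[2], tab[3] + t, tab[4]), 0)
    expect_true(all(diff(stats) <= 1e-9))
  }
})

test_that("run_tree_test composes QC and testing with a coherent ledger", {
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 120L,
                                  n_controls = 120L, n_neutral_snps = 6L,
                                  snp_missing_rate = 0.02,
                                  phenotype_missing_rate = 0.02,
                                  baseline_odds = 0.2, seed = 41))
  tt <- run_tree_test(g, n_perm = 99, seed = 2)
  expect_equal(tt$report$stages$stage[1], "missing_phenotype")
  expect_equal(tt$report$final_n,
               n_samples(g) - sum(tt$report$stages$individuals_removed))
  expect_equal(tt$report$final_n, tt$tree$nodes$size[1])
  expect_lte(nrow(tt$result$selected_nodes), 5L)
})

test_that("relabelling two halves of one control population is not significant", {
  # same-source "cases" and "controls": calibration analogue of comparing
  # two healthy control cohorts
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 1L,
                                  n_controls = 400L, n_neutral_snps = 6L,
                                  baseline_odds = 0.02, seed = 53))
  ctl <- gt_subset(g, samples = g$phenotype == 1L)
  ctl$phenotype <- rep(c(1L, 2L), length.out = n_samples(ctl))
  tt <- run_tree_test(ctl, n_perm = 199, seed = 7)
  expect_gt(tt$result$p_perm, 0.01)
})

test_that("newick export is parseable and mirrors the leaf count", {
  g <- simulate_cohort(sim_config(clades = demo_clades(), n_cases = 80L,
                                  n_controls = 80L, n_neutral_snps = 4L,
                                  baseline_odds = 0.3, seed = 19))
  qc <- lextree_qc(g)
  tree <- build_tree(qc$table)
  nwk <- export_tree_newick(tree)
  phy <- ape::read.tree(text = nwk)
  expect_equal(length(phy$tip.label), length(tree$leaves))
})
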