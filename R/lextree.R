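#' Build the lexical haplotype tree
#'
#' All individuals start at the root. SNPs are processed in decreasing order
#' of minor allele frequency (ties broken by ascending rCRS position); at
#' each SNP every current leaf is split into a wild-type (reference allele)
#' left child and a mutant right child, but only when both classes are
#' non-empty — otherwise the leaf's haplotype prefix simply extends without
#' creating nodes. Leaves end up in bijection with the distinct haplotypes.
#' Because a node is only ever created by a true split, every node's member
#' set is distinct, so membership-identical single-child chains cannot arise.
#'
#' @param g a \code{\link{genotype_table}} with zero missing genotypes and no
#'   missing phenotypes (the lexical-QC post-condition).
#' @return an object of class \code{haplotype_tree}: a node table (id,
#'   parent, snp, branch, depth, size, n_cases, n_controls), per-node member
#'   index lists, the case indicator vector, and the SNP processing order.
#' @export
build_tree <- function(g) {
  if (anyNA(g$geno))
    abort("missing genotypes present; run lextree_qc first")
  if (anyNA(g$phenotype))
    abort("missing phenotypes present; prune them first")
  n <- n_samples(g)
  case <- g$phenotype == 2L
  maf <- snp_maf(g)
  snp_order <- order(-maf, g$snp_meta$pos)

  id <- 1L; parent <- NA_integer_; snp <- NA_integer_
  branch <- NA_character_; depth <- 0L
  members <- list(seq_len(n))
  leaves <- 1L
  for (j in snp_order) {
    new_leaves <- integer(0)
    for (lf in leaves) {
      mem <- members[[lf]]
      gj <- g$geno[mem, j]
      mut <- mem[gj == 1L]; wt <- mem[gj == 0L]
      if (length(mut) > 0L && length(wt) > 0L) {
        for (br in c("wild", "mutant")) {
          id <- c(id, length(id) + 1L)
          parent <- c(parent, lf)
          snp <- c(snp, j)
          branch <- c(branch, br)
          depth <- c(depth, depth[lf] + 1L)
          members <- c(members, list(if (br == "wild") wt else mut))
        }
        new_leaves <- c(new_leaves, id[length(id) - 1L], id[length(id)])
      } else {
        new_leaves <- c(new_leaves, lf)
      }
    }
    leaves <- new_leaves
  }
  size <- lengths(members)
  n_cases <- vapply(members, function(mem) sum(case[mem]), 0L)
  structure(list(
    nodes = data.frame(id = id, parent = parent, snp = snp, branch = branch,
                       depth = depth, size = size, n_cases = n_cases,
                       n_controls = size - n_cases, stringsAsFactors = FALSE),
    members = members, case = case, leaves = leaves,
    snp_order = snp_order, snp_meta = g$snp_meta, root_id = 1L),
    class = "haplotype_tree")
}

#' @export
print.haplotype_tree <- function(x, ...) {
  cat(sprintf(
    "haplotype_tree: %d nodes (%d leaves = distinct haplotypes), %d individuals (%d cases / %d controls), %d SNPs\n",
    nrow(x$nodes), length(x$leaves), x$nodes$size[1],
    x$nodes$n_cases[1], x$nodes$n_controls[1], length(x$snp_order)))
  invisible(x)
}

# internal: ancestor id vector for a node (excluding itself, including root)
node_ancestors <- function(tree, id) {
  out <- integer(0)
  p <- tree$nodes$parent[id]
  while (!is.na(p)) { out <- c(out, p); p <- tree$nodes$parent[p] }
  out
}

# internal: symmetric node-comparability matrix (TRUE when one node is an
# ancestor of the other); used by the antichain selection
conflict_matrix <- function(tree) {
  k <- nrow(tree$nodes)
  conf <- matrix(FALSE, k, k)
  for (i in seq_len(k)) {
    anc <- node_ancestors(tree, i)
    conf[i, anc] <- TRUE
    conf[anc, i] <- TRUE
  }
  conf
}

#' Per-node 2x2 case/control statistics
#'
#' For every non-root node, the Pearson chi-square (1 df, no continuity
#' correction) of the table (in-node vs out-of-node) x (case vs control),
#' with direction "risk" when the in-node case odds exceed the out-of-node
#' odds and "protective" otherwise ("none" at independence).
#'
#' @param tree a \code{\link{build_tree}} result.
#' @return data.frame with one row per non-root node: \code{node_id},
#'   \code{statistic}, \code{direction}, the 2x2 counts and \code{depth}.
#' @export
node_statistics <- function(tree) {
  tot_cases <- tree$nodes$n_cases[tree$root_id]
  tot_ctls  <- tree$nodes$n_controls[tree$root_id]
  if (tot_cases == 0L || tot_ctls == 0L)
    abort("cohort must contain both cases and controls")
  nd <- tree$nodes[tree$nodes$id != tree$root_id, , drop = FALSE]
  a <- nd$n_cases            # cases in node
  b <- tot_cases - a         # cases out
  c_ <- nd$n_controls        # controls in
  d <- tot_ctls - c_         # controls out
  stat <- chisq_2x2(a, b, c_, d)
  cross <- a * d - b * c_
  data.frame(node_id = nd$id, statistic = stat,
             direction = ifelse(cross > 0, "risk",
                                ifelse(cross < 0, "protective", "none")),
             cases_in = a, cases_out = b, controls_in = c_, controls_out = d,
             depth = nd$depth, stringsAsFactors = FALSE)
}

# internal greedy antichain selection. stat/depth/ids aligned vectors;
# conflict indexed by node id. Ties: larger stat, then shallower depth,
# then smaller id.
greedy_antichain <- function(stat, depth, ids, conflict, k = 5L) {
  o <- order(-stat, depth, ids)
  sel <- integer(0)
  for (i in o) {
    if (!any(conflict[ids[i], ids[sel]])) {
      sel <- c(sel, i)
      if (length(sel) == k) break
    }
  }
  sel
}

#' Whole-tree statistic: sum of the five largest non-nested node values
#'
#' Greedy selection: node statistics are visited in decreasing order (ties
#' broken by shallower depth, then smaller node id); a node is accepted iff
#' it is neither an ancestor nor a descendant of any node already accepted;
#' selection stops after \code{k} nodes or exhaustion. The whole-tree
#' statistic S is the sum of the accepted statistics.
#'
#' @param stats result of \code{\link{node_statistics}}.
#' @param tree the \code{haplotype_tree} the statistics were computed on.
#' @param k maximum number of selected nodes (default 5).
#' @return list with \code{selected_nodes} (rows of \code{stats}, an
#'   antichain) and \code{S}.
#' @export
tree_statistic <- function(stats, tree, k = 5L) {
  if (nrow(stats) == 0) abort("no node statistics")
  conf <- conflict_matrix(tree)
  sel <- greedy_antichain(stats$statistic, stats$depth, stats$node_id, conf, k)
  list(selected_nodes = stats[sel, , drop = FALSE],
       S = sum(stats$statistic[sel]))
}

#' Permutation test of the whole-tree statistic
#'
#' The tree topology and node memberships stay fixed; case/control labels are
#' permuted uniformly \code{n_perm} times; per permutation the node 2x2
#' counts are recomputed from the memberships and the whole-tree statistic S
#' re-derived by the same greedy antichain rule. The p-value uses the add-one
#' estimator \code{(1 + #\{S_perm >= S_obs\}) / (1 + n_perm)}, which never
#' reports zero. Deterministic given \code{seed}.
#'
#' @param tree a \code{\link{build_tree}} result (carries the phenotypes).
#' @param n_perm number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param k antichain size (default 5).
#' @return an object of class \code{tree_test_result}: \code{selected_nodes},
#'   \code{S}, \code{n_perm}, \code{p_perm}, and the permutation statistics
#'   \code{perm_S}.
#' @export
permutation_test <- function(tree, n_perm, seed = 1L, k = 5L) {
  stopifnot(n_perm >= 1)
  obs_stats <- node_statistics(tree)
  obs <- tree_statistic(obs_stats, tree, k)

  n <- tree$nodes$size[tree$root_id]
  n_case <- tree$nodes$n_cases[tree$root_id]
  nonroot <- tree$nodes$id != tree$root_id
  ids <- tree$nodes$id[nonroot]
  depth <- tree$nodes$depth[nonroot]
  size <- tree$nodes$size[nonroot]
  conf <- conflict_matrix(tree)
  # node membership indicator (non-root nodes x individuals)
  M <- matrix(0, length(ids), n)
  for (r in seq_along(ids)) M[r, tree$members[[ids[r]]]] <- 1

  set.seed(seed)
  perm_S <- numeric(n_perm)
  tot_ctl <- n - n_case
  for (b in seq_len(n_perm)) {
    lab <- numeric(n)
    lab[sample.int(n, n_case)] <- 1
    a  <- as.vector(M %*% lab)       # cases in node
    ci <- size - a                   # controls in node
    stat <- chisq_2x2(a, n_case - a, ci, tot_ctl - ci)
    sel <- greedy_antichain(stat, depth, ids, conf, k)
    perm_S[b] <- sum(stat[sel])
  }
  p_perm <- (1 + sum(perm_S >= obs$S)) / (1 + n_perm)
  structure(list(selected_nodes = obs$selected_nodes, S = obs$S,
                 n_perm = as.integer(n_perm), p_perm = p_perm,
                 perm_S = perm_S),
            class = "tree_test_result")
}

#' @export
print.tree_test_result <- function(x, ...) {
  cat(sprintf("tree_test_result: S = %.4f, p_perm = %.4g (%d permutations)\n",
              x$S, x$p_perm, x$n_perm))
  cat("selected nodes:\n")
  print(x$selected_nodes, row.names = FALSE)
  invisible(x)
}

#' Run the full lexical-tree analysis on a raw case-control table
#'
#' Prunes missing-phenotype individuals (ledger stage "missing_phenotype"),
#' applies \code{\link{lextree_qc}}, builds the tree, scores nodes, forms the
#' whole-tree statistic and runs the permutation test.
#'
#' @param g a raw \code{\link{genotype_table}}.
#' @param t a \code{\link{qc_thresholds}}.
#' @param n_perm number of permutations.
#' @param seed integer RNG seed.
#' @param k antichain size.
#' @return list with \code{report} (qc_report including the phenotype-pruning
#'   stage), \code{tree}, and \code{result} (a \code{tree_test_result}).
#' @export
run_tree_test <- function(g, t = qc_thresholds(), n_perm = 999L, seed = 1L,
                          k = 5L) {
  keep <- !is.na(g$phenotype)
  pre <- new_qc_report(n_samples(g), n_snps(g))
  pre <- add_stage(pre, "missing_phenotype", ind = sum(!keep))
  g <- gt_subset(g, samples = keep)
  qc <- lextree_qc(g, t = t)
  rep <- pre
  for (i in seq_len(nrow(qc$report$stages)))
    rep <- add_stage(rep, qc$report$stages$stage[i],
                     qc$report$stages$individuals_removed[i],
                     qc$report$stages$snps_removed[i])
  gq <- qc$table
  if (n_samples(gq) == 0 || n_snps(gq) == 0)
    abort("no data left after lexical QC")
  if (!any(is_case(gq)) || !any(is_control(gq)))
    abort("post-QC cohort lacks cases or controls")
  tree <- build_tree(gq)
  res <- permutation_test(tree, n_perm = n_perm, seed = seed, k = k)
  list(report = rep, tree = tree, result = res)
}

#' Export the per-node table as TSV
#'
#' One row per non-root node: id, parent, defining SNP and branch, counts,
#' statistic, direction and whether the node is in the selected antichain.
#'
#' @param tree a \code{haplotype_tree}.
#' @param result a \code{tree_test_result} for the same tree.
#' @param path output file (NULL to just return the data.frame).
#' @return the node table, invisibly when written.
#' @export
export_node_table <- function(tree, result, path = NULL) {
  stats <- node_statistics(tree)
  nd <- tree$nodes[match(stats$node_id, tree$nodes$id), ]
  out <- data.frame(
    node_id = stats$node_id, parent = nd$parent,
    snp_id = tree$snp_meta$id[nd$snp], branch = nd$branch,
    n_cases = stats$cases_in, n_controls = stats$controls_in,
    statistic = stats$statistic, direction = stats$direction,
    selected = stats$node_id %in% result$selected_nodes$node_id,
    stringsAsFactors = FALSE)
  if (!is.null(path)) {
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
    return(invisible(out))
  }
  out
}

#' Export the skeletal tree in Newick format
#'
#' Node labels carry the node id and case/control counts
#' (\code{n<ID>_<cases>c_<controls>k}), suitable for plotting with standard
#' phylogenetics tools.
#'
#' @param tree a \code{haplotype_tree}.
#' @param path output file (NULL to return the Newick string).
#' @return the Newick string, invisibly when written.
#' @export
export_tree_newick <- function(tree, path = NULL) {
  kids <- split(tree$nodes$id[-1], tree$nodes$parent[-1])
  lab <- sprintf("n%d_%dc_%dk", tree$nodes$id, tree$nodes$n_cases,
                 tree$nodes$n_controls)
  rec <- function(id) {
    ch <- kids[[as.character(id)]]
    if (is.null(ch)) return(lab[id])
    paste0("(", paste(vapply(ch, rec, ""), collapse = ","), ")", lab[id])
  }
  nwk <- paste0(rec(tree$root_id), ";")
  if (!is.null(path)) {
    writeLines(nwk, path)
    return(invisible(nwk))
  }
  nwk
}
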