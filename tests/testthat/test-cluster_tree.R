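test_that("pairwise identity follows the min-length denominator", {
  expect_equal(pairwise_identity("MKYLV", "MKYLV"), 1.0)
  expect_equal(pairwise_identity("ACDEF", "ACDEG"), 4 / 5)
  # disjoint alphabet subsets: no identical aligned pairs
  expect_equal(pairwise_identity("AAAAA", "WWWWW"), 0.0)
  # shorter sequence fully contained: min-length denominator gives 1.0
  expect_equal(pairwise_identity("MKYLVACDEF", "MKYLV"), 1.0)
})

test_that("greedy clustering recovers synthetic families and is order-invariant", {
  set.seed(61)
  fams <- make_families(n_fam = 5, fam_size = 4, len = 120, n_mut = 6)
  cl <- greedy_cluster(fams[, c("id", "seq")], 0.75)
  expect_length(cl$clusters, 5L)
  # memberships exactly match family labels
  for (cluster in cl$clusters) {
    fam_of <- fams$family[match(cluster$members, fams$id)]
    expect_length(unique(fam_of), 1L)
  }

  shuffled <- fams[sample(nrow(fams)), c("id", "seq")]
  cl2 <- greedy_cluster(shuffled, 0.75)
  expect_equal(cl2$membership[names(cl$membership)], cl$membership)

  # n identical copies -> one cluster; threshold 1 on distinct -> singletons
  same <- data.frame(id = sprintf("s%d", 1:6), seq = rep("MKYLVMKYLV", 6))
  expect_length(greedy_cluster(same, 0.9)$clusters, 1L)
  set.seed(62)
  distinct <- data.frame(id = sprintf("d%d", 1:5),
                         seq = replicate(5, random_protein(60)))
  expect_length(greedy_cluster(distinct, 1.0)$clusters, 5L)
})

test_that("cluster count is monotone in threshold and under set combination", {
  set.seed(63)
  fams <- make_families(n_fam = 4, fam_size = 3, len = 100, n_mut = 8)
  counts <- vapply(c(0.95, 0.85, 0.7, 0.5, 0.3), function(th) {
    length(greedy_cluster(fams[, c("id", "seq")], th)$clusters)
  }, numeric(1))
  expect_true(all(diff(counts) <= 0))  # lower threshold, fewer-or-equal

  # combining two sets never yields fewer clusters than the larger set alone
  set.seed(64)
  other <- make_families(n_fam = 3, fam_size = 3, len = 100, n_mut = 8)
  other$id <- paste0("x_", other$id)
  n_a <- length(greedy_cluster(fams[, c("id", "seq")], 0.75)$clusters)
  n_b <- length(greedy_cluster(other[, c("id", "seq")], 0.75)$clusters)
  n_ab <- length(greedy_cluster(rbind(fams, other)[, c("id", "seq")],
                                0.75)$clusters)
  expect_gte(n_ab, max(n_a, n_b))
})

test_that("neighbor joining is exact on additive distances", {
  # two taxa: a single edge split evenly
  D2 <- matrix(c(0, 3, 3, 0), 2, dimnames = list(c("A", "B"), c("A", "B")))
  t2 <- nj_tree(D2)
  expect_equal(sum(t2$edge.length), 3)

  # three taxa: closed-form three-point branch lengths
  D3 <- matrix(0, 3, 3, dimnames = list(c("A", "B", "C"), c("A", "B", "C")))
  D3["A", "B"] <- D3["B", "A"] <- 5
  D3["A", "C"] <- D3["C", "A"] <- 7
  D3["B", "C"] <- D3["C", "B"] <- 8
  t3 <- nj_tree(D3)
  bl <- setNames(t3$edge.length, t3$tip.label[t3$edge[, 2]])
  expect_equal(bl[["A"]], (5 + 7 - 8) / 2)
  expect_equal(bl[["B"]], (5 + 8 - 7) / 2)
  expect_equal(bl[["C"]], (7 + 8 - 5) / 2)

  # additive matrices from random 4-8 taxon trees reconstruct exactly
  set.seed(65)
  for (n in c(4, 6, 8)) {
    true_tree <- ape::rtree(n, br = function(k) runif(k, 0.2, 2))
    D <- ape::cophenetic.phylo(true_tree)
    t_hat <- nj_tree(D)
    expect_equal(ape::dist.topo(ape::unroot(true_tree), t_hat)[1], 0)
    expect_equal(ape::cophenetic.phylo(t_hat)[rownames(D), colnames(D)], D,
                 tolerance = 1e-8)
  }

  Dbad <- matrix(c(0, 1, 2, 0), 2, 2,
                 dimnames = list(c("A", "B"), c("A", "B")))
  expect_error(nj_tree(Dbad), "symmetric")
})

test_that("Poisson-corrected protein distances cap at p = 0.95", {
  prot <- data.frame(id = c("a", "b"), seq = c("AAAAAAAA", "WWWWWWWW"))
  D <- protein_distances(prot)
  expect_equal(D["a", "b"], -log(1 - 0.95))
  expect_equal(diag(D), c(a = 0, b = 0))
})

test_that("clade delineation matches the brute-force enumeration oracle", {
  # all-metagenome tree: one call at the root
  t1 <- read_newick(text = "((A:2,B:2):2,(C:2,D:2):2);")
  org1 <- setNames(rep("metagenome", 4), c("A", "B", "C", "D"))
  r1 <- delineate_clades(t1, org1)
  expect_equal(nrow(r1$calls), 1L)
  expect_equal(r1$calls$rule, "monophyly")
  expect_length(r1$unassigned, 0L)

  # all-reference deep tree: zero calls
  org2 <- setNames(rep("reference", 4), c("A", "B", "C", "D"))
  r2 <- delineate_clades(t1, org2)
  expect_equal(nrow(r2$calls), 0L)
  expect_setequal(r2$unassigned, c("A", "B", "C", "D"))

  # deep mixed tree with one shallow mixed subtree and one pure-metagenome
  # deep subtree: exactly two accepted calls
  t3 <- read_newick(text = paste0(
    "(((M1:2,M2:2):1,(R1:0.3,M3:0.3):0.2):1,(R2:2,R3:2):1);"))
  org3 <- c(M1 = "metagenome", M2 = "metagenome", M3 = "metagenome",
            R1 = "reference", R2 = "reference", R3 = "reference")
  r3 <- delineate_clades(t3, org3)
  expect_equal(nrow(r3$calls), 2L)
  expect_setequal(r3$calls$rule, c("monophyly", "shallow"))

  # randomized trees against the oracle
  set.seed(66)
  for (trial in 1:25) {
    n <- sample(5:50, 1)
    tr <- ape::rtree(n, br = function(k) runif(k, 0.05, 1.5))
    org <- setNames(sample(c("metagenome", "reference"), n, replace = TRUE,
                           prob = c(0.6, 0.4)), tr$tip.label)
    got <- delineate_clades(tr, org)
    expect_equal(sort(got$calls$node), oracle_clades(tr, org))
  }

  expect_error(delineate_clades(t1, org1[-1]), "unlabeled leaf")
})
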