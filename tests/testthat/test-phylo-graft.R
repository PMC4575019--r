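qx_tree <- function() {
  tax_tree(ape::read.tree(text = "((Qa:10,Qb:10):5,X:15);"),
           data.frame(species = c("Qa", "Qb", "X"),
                      genus = c("Q", "Q", "Xg"),
                      family = c("Qf", "Qf", "Xf"), stringsAsFactors = FALSE))
}

test_that("grafting at a genus MRCA preserves ultrametricity and ages", {
  tt <- qx_tree()
  res <- graft_species(tt, "Q_new", genus = "Q", family = "Qf")
  expect_equal(res$report$attachment_level, "genus")
  expect_equal(res$report$attachment_node_age, 10)
  expect_equal(res$report$assigned_branch_length, 10)
  expect_equal(length(res$tree$tree$tip.label), 4L)
  expect_lt(ultrametric_spread(res$tree), 1e-6)
  expect_equal(patristic_distance(res$tree, "Q_new", "Qa"), 20)
})

test_that("sequential congener grafts build a polytomy, staying ultrametric", {
  tt <- qx_tree()
  for (sp in c("Q1", "Q2", "Q3")) {
    res <- graft_species(tt, sp, genus = "Q", family = "Qf")
    tt <- res$tree
    expect_lt(ultrametric_spread(tt), 1e-6)
  }
  node <- ape::getMRCA(tt$tree, c("Qa", "Qb"))
  expect_equal(sum(tt$tree$edge[, 1] == node), 5L)  # polytomy of 5 children
  # two species grafted at the same node of age t sit exactly 2t apart
  expect_equal(patristic_distance(tt, "Q1", "Q2"), 20)
})

test_that("single-congener grafts attach at the stem; family is the fallback", {
  tt <- qx_tree()
  res <- graft_species(tt, "X_new", genus = "Xg", family = "Xf")
  expect_equal(res$report$attachment_level, "genus")
  # X's parent is the root (age 15): stem attachment makes a root polytomy
  expect_equal(res$report$attachment_node_age, 15)
  expect_equal(patristic_distance(res$tree, "X_new", "X"), 30)
  expect_lt(ultrametric_spread(res$tree), 1e-6)

  fam <- graft_species(tt, "Qc_new", genus = "Qz", family = "Qf")
  expect_equal(fam$report$attachment_level, "family")
  expect_equal(fam$report$attachment_node_age, 10)

  fail <- graft_species(tt, "alien", genus = "nix", family = "nixf")
  expect_equal(fail$report$attachment_level, "failed")
  expect_identical(ape::write.tree(fail$tree$tree), ape::write.tree(tt$tree))
})

test_that("patristic distances match hand sums and metric properties hold", {
  tt <- abc_tree()
  expect_equal(patristic_distance(tt, "A", "B"), 2)
  expect_equal(patristic_distance(tt, "A", "A"), 0)
  expect_equal(patristic_distance(tt, "A", "C"), 4)
  expect_equal(patristic_distance(tt, "C", "A"), 4)
  expect_error(patristic_distance(tt, "A", "Z"), "unknown tip")

  set.seed(31)
  for (rep in 1:3) {
    tt <- simulate_tree(25, birth_rate = 0.15, seed = 300 + rep)
    dm <- patristic_matrix(tt)
    h <- max(ape::node.depth.edgelength(tt$tree))
    expect_true(isSymmetric(dm))
    expect_true(all(diag(dm) == 0))
    expect_true(all(dm[upper.tri(dm)] > 0))
    expect_true(all(dm <= 2 * h + 1e-8))
    # triangle inequality on a sample of triples
    tri <- replicate(30, sample(nrow(dm), 3))
    for (k in seq_len(ncol(tri))) {
      i <- tri[1, k]; j <- tri[2, k]; l <- tri[3, k]
      expect_lte(dm[i, j], dm[i, l] + dm[l, j] + 1e-8)
    }
  }
})

test_that("graft_all covers a dataset and is order-invariant", {
  tt <- simulate_tree(40, seed = 77)
  tax <- tt$taxonomy
  # invent 8 unplaced species spread across existing genera/families
  set.seed(8)
  extra <- data.frame(
    species = paste0("new", 1:8),
    genus = sample(tax$genus, 8),
    family = NA, stringsAsFactors = FALSE)
  extra$family <- tax$family[match(extra$genus, tax$genus)]
  extra$genus[7:8] <- paste0("nogenus", 1:2)  # force family-level grafts
  m <- diag(8); m[1, ] <- 1
  a <- make_assemblage(m, origins = rep(c("native", "exotic"), 4),
                       plant_names = extra$species,
                       genus = extra$genus, family = extra$family)
  res <- graft_all(tt, list(a))
  expect_setequal(res$report$species, extra$species)
  expect_equal(sum(res$report$attachment_level == "genus"), 6L)
  expect_equal(sum(res$report$attachment_level == "family"), 2L)
  expect_true(all(extra$species %in% res$tree$tree$tip.label))
  expect_lt(ultrametric_spread(res$tree), 1e-6)

  # permuting the graft order leaves all pairwise distances unchanged
  for (perm_seed in 1:2) {
    set.seed(perm_seed)
    tt2 <- tt
    for (i in sample(nrow(extra))) {
      tt2 <- graft_species(tt2, extra$species[i], genus = extra$genus[i],
                           family = extra$family[i])$tree
    }
    dm1 <- patristic_matrix(res$tree)
    dm2 <- patristic_matrix(tt2)
    expect_equal(dm2[rownames(dm1), colnames(dm1)], dm1, tolerance = 1e-10)
  }

  # nothing missing: identity
  res2 <- graft_all(res$tree, list(a))
  expect_equal(nrow(res2$report), 0L)
  expect_identical(ape::write.tree(res2$tree$tree),
                   ape::write.tree(res$tree$tree))
})

test_that("phylo_isolation averages distances to natives with self-exclusion", {
  tt <- abc_tree()
  m <- matrix(1, 3, 2)
  a <- make_assemblage(m, origins = c("native", "native", "exotic"),
                       plant_names = c("A", "B", "C"))
  expect_equal(phylo_isolation(tt, a, "C")$phylo_isolation, 4)     # (4+4)/2
  rec <- phylo_isolation(tt, a, "A")
  expect_equal(rec$phylo_isolation, 2)  # self excluded, mean over {B}
  expect_equal(rec$n_comparators, 1L)
  # opting out of self-exclusion deflates the native mean
  expect_equal(phylo_isolation(tt, a, "A", exclude_self = FALSE)$phylo_isolation, 1)
  # no comparators after self-exclusion is an error
  a2 <- make_assemblage(m, origins = c("native", "exotic", "exotic"),
                        plant_names = c("A", "B", "C"))
  expect_error(phylo_isolation(tt, a2, "A"), "no native comparators")
  expect_equal(phylo_isolation(tt, a2, "B")$phylo_isolation, 2)
})

test_that("deeper attachment never decreases phylogenetic isolation", {
  # same species grafted at the (shallow) genus node vs the (deep) family
  # node: isolation vs fixed natives must not decrease
  tt <- simulate_tree(40, seed = 101)
  tax <- tt$taxonomy
  counts <- table(tax$genus)
  g <- names(counts)[counts >= 2][1]
  fam <- tax$family[match(g, tax$genus)]
  expect_gt(sum(tax$family == fam), sum(tax$genus == g))  # deep node exists
  shallow <- graft_species(tt, "probe", genus = g, family = fam)$tree
  deep <- graft_species(tt, "probe", genus = "nothere", family = fam)$tree
  set.seed(5)
  natives <- sample(setdiff(tt$tree$tip.label, "probe"), 6)
  m <- matrix(1, 7, 2)
  mk <- function(ttx) make_assemblage(
    m, origins = c(rep("native", 6), "exotic"),
    plant_names = c(natives, "probe"))
  iso_s <- phylo_isolation(shallow, mk(shallow), "probe")$phylo_isolation
  iso_d <- phylo_isolation(deep, mk(deep), "probe")$phylo_isolation
  expect_gte(iso_d, iso_s - 1e-9)
})

test_that("ultrametricity is validated and can be forced by tip extension", {
  bad <- ape::read.tree(text = "((A:1,B:2):1,C:2);")
  tax <- data.frame(species = c("A", "B", "C"), genus = "g", family = "f")
  expect_error(tax_tree(bad, tax), "not ultrametric")
  fixed <- tax_tree(bad, tax, force_ultrametric = TRUE)
  expect_lt(ultrametric_spread(fixed), 1e-12)
  expect_true(is_ultrametric_tree(fixed))
})
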