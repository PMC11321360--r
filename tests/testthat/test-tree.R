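test_that("labelled Newick parsing infers ages and validates input", {
  tr <- parse_labeled_newick("((A:1,B:1):1,(C:1,D:1):1);",
                             c(A = 1, B = 1, C = 0, D = 0))
  expect_identical(length(tr$labels), 4L)
  expect_identical(sum(tr$labels), 2L)
  expect_equal(tr$ages[tr$root], 2)
  expect_equal(unname(tr$ages[1:4]), rep(0, 4))
  expect_error(parse_labeled_newick("((A:1,B:1):1,(C:1,D:1):1);",
                                    c(A = 1, B = 1, C = 0)), "label.*D")
  expect_error(parse_labeled_newick("((A:1,B:1,C:1):1,D:2);",
                                    c(A = 1, B = 1, C = 0, D = 0)), "binary")
  # a shorter tip branch is an ancient leaf, not an error
  tr2 <- parse_labeled_newick("((A:1,B:0.5):1,(C:1,D:1):1);",
                              c(A = 1, B = 1, C = 0, D = 0))
  expect_equal(unname(tr2$ages[2]), 0.5)
})

test_that("minimum leaf flips restore the infinite-sites clade property", {
  nwk <- "((A:1,B:1):1,(C:1,D:1):1);"
  r0 <- repair_infinite_sites(parse_labeled_newick(nwk, c(A = 1, B = 1, C = 0, D = 0)))
  expect_equal(r0$flips, 0)
  expect_identical(r0$tree$labels, c(1L, 1L, 0L, 0L))
  r1 <- repair_infinite_sites(parse_labeled_newick(nwk, c(A = 1, B = 0, C = 1, D = 0)))
  expect_equal(r1$flips, 1)
  rall <- repair_infinite_sites(parse_labeled_newick(nwk, c(A = 1, B = 1, C = 1, D = 1)))
  expect_equal(rall$flips, 0)
  expect_identical(sort(rall$clade), 1:4)
  expect_error(repair_infinite_sites(
    parse_labeled_newick(nwk, c(A = 0, B = 0, C = 0, D = 0))), "segregate")
})

test_that("flip counts are optimal against exhaustive clade enumeration", {
  set.seed(14)
  for (rep in 1:8) {
    n <- sample(5:12, 1)
    phy <- ape::rtree(n)
    nwk <- ape::write.tree(phy)
    labs <- stats::setNames(sample(0:1, n, replace = TRUE), phy$tip.label)
    if (sum(labs) == 0) labs[1] <- 1
    tr <- parse_labeled_newick(nwk, labs)
    got <- repair_infinite_sites(tr)
    # independent enumeration: cost of every possible derived clade
    pp <- ape::prop.part(tr$phylo)
    clades <- c(lapply(seq_len(n), identity), lapply(pp, as.integer))
    costs <- vapply(clades, function(cl) {
      sum(tr$labels[cl] == 0) + sum(tr$labels[-cl] == 1)
    }, numeric(1))
    expect_equal(got$flips, min(costs))
    # result satisfies the clade property
    ev <- extract_coalescent_events(got$tree)
    expect_true(inherits(ev, "tree_events"))
  }
})

test_that("event extraction follows the branch-labelling rules", {
  tr <- parse_labeled_newick("((D1:1,D2:1):3,(A1:2,A2:2):2);",
                             c(D1 = 1, D2 = 1, A1 = 0, A2 = 0))
  ev <- extract_coalescent_events(tr)
  expect_equal(ev$der_coal, 1)
  expect_equal(ev$anc_coal, c(2, 4))
  expect_equal(ev$mixed_age, 4)   # parent of the oldest derived coalescence
  expect_identical(ev$n_der_modern, 2L)
  expect_identical(ev$n_anc_modern, 2L)
  # single derived leaf: no derived coalescences; its parent is mixed
  tr1 <- parse_labeled_newick("((D1:1,A3:1):3,(A1:2,A2:2):2);",
                              c(D1 = 1, A3 = 0, A1 = 0, A2 = 0))
  ev1 <- extract_coalescent_events(tr1)
  expect_identical(length(ev1$der_coal), 0L)
  expect_equal(ev1$mixed_age, 1)
  # derived leaves count minus derived coalescences equals 1 (mixed lineage)
  expect_identical(ev$n_der_modern + length(ev$der_leaves) - length(ev$der_coal), 1L)
  expect_error(extract_coalescent_events(
    parse_labeled_newick("((A:1,B:1):1,(C:1,D:1):1);",
                         c(A = 1, B = 0, C = 1, D = 0))), "clade")
})

test_that("extraction is invariant to leaf-order rotation of the Newick string", {
  a <- extract_coalescent_events(parse_labeled_newick(
    "((D1:1,D2:1):3,(A1:2,A2:2):2);", c(D1 = 1, D2 = 1, A1 = 0, A2 = 0)))
  b <- extract_coalescent_events(parse_labeled_newick(
    "((A2:2,A1:2):2,(D2:1,D1:1):3);", c(D1 = 1, D2 = 1, A1 = 0, A2 = 0)))
  expect_equal(sort(a$der_coal), sort(b$der_coal))
  expect_equal(sort(a$anc_coal), sort(b$anc_coal))
  expect_equal(a$mixed_age, b$mixed_age)
})

test_that("importance-sample files round-trip and are validated", {
  s1 <- tree_events(der_coal = c(1.25, 3.5), anc_coal = c(2, 7.75),
                    mixed_age = 7.75, der_leaves = 1.5, anc_leaves = c(2.5, 4),
                    n_der_modern = 2, n_anc_modern = 3)
  s2 <- tree_events(der_coal = c(0.5, 2.25), anc_coal = c(1, 5),
                    mixed_age = 5, der_leaves = 1.5, anc_leaves = c(2.5, 4),
                    n_der_modern = 2, n_anc_modern = 3)
  path <- tempfile()
  write_importance_samples(list(s1, s2), path)
  back <- read_importance_samples(path)
  expect_length(back, 2)
  expect_equal(back[[1]]$der_coal, s1$der_coal)
  expect_equal(back[[2]]$anc_coal, s2$anc_coal)
  expect_equal(back[[1]]$mixed_age, 7.75)
  expect_identical(back[[2]]$n_anc_modern, 3L)
  # unsorted times are sorted with a warning
  p2 <- tempfile()
  writeLines(c("SAMPLE 1", "Modern: 3 2", "DerCoals: 3 1", "AncCoals: 5",
               "Mixed: 5", "DerLeaves:", "AncLeaves:"), p2)
  expect_warning(b2 <- read_importance_samples(p2), "sorted")
  expect_equal(b2[[1]]$der_coal, c(1, 3))
  # inconsistent modern counts across samples
  p3 <- tempfile()
  writeLines(c("SAMPLE 1", "Modern: 2 2", "DerCoals: 1", "AncCoals: 5",
               "Mixed: 5", "DerLeaves:", "AncLeaves:",
               "SAMPLE 2", "Modern: 3 2", "DerCoals: 1 2", "AncCoals: 5",
               "Mixed: 5", "DerLeaves:", "AncLeaves:"), p3)
  expect_error(read_importance_samples(p3), "disagree")
})

test_that("simulated trees re-extract to their own event lists", {
  set.seed(33)
  nh <- pop_size_history(0, 400)
  traj <- simulate_trajectory_backward(0.6, selection_schedule(0), nh, 400)
  traj[traj > 0 & seq_along(traj) > 300] <- 0  # guarantee mutation origin
  sim <- suppressMessages(simulate_structured_coalescent(
    traj, n_modern_derived = 4, n_modern_ancestral = 3,
    ancient_derived = 5.5, ancient_ancestral = 12.5, N_history = nh))
  expect_true(sim$complete)
  tr <- parse_labeled_newick(sim$newick, sim$labels)
  rep <- repair_infinite_sites(tr)
  expect_equal(rep$flips, 0)      # construction guarantees the clade property
  ev <- extract_coalescent_events(tr)
  expect_equal(sort(ev$der_coal), sort(sim$events$der_coal), tolerance = 1e-6)
  expect_equal(sort(ev$anc_coal), sort(sim$events$anc_coal), tolerance = 1e-6)
  expect_equal(ev$mixed_age, sim$events$mixed_age, tolerance = 1e-6)
  expect_equal(ev$der_leaves, 5.5, tolerance = 1e-6)
})
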