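test_that("perfect-linkage bins follow the same-scaffold and cross-scaffold rules", {
  v <- rep(c(1L, 0L), 11)
  v_na <- v; v_na[5] <- NA
  seg <- rbind(v, v, v, 1L - v, v_na, v_na)
  ms <- make_markers(seg, scaffold = c("s1", "s2", "s3", "s4", "s5", "s5"))
  b <- perfect_linkage_bins(ms)
  # complete identical (s1, s2, s3) and complementary (s4) vectors merge;
  # the incomplete vector on s5 merges only with its same-scaffold twin
  expect_equal(nrow(b$bins), 2L)
  big <- which(b$bins$n_scaffolds == 4L)
  expect_setequal(b$scaffolds[[big]], c("s1", "s2", "s3", "s4"))
  expect_setequal(b$scaffolds[[3 - big]], "s5")
  expect_equal(b$bins$n_markers[big], 4L)

  # a single missing entry blocks cross-scaffold merging
  ms2 <- make_markers(rbind(v_na, v_na), scaffold = c("sA", "sB"))
  expect_equal(nrow(perfect_linkage_bins(ms2)$bins), 2L)

  # classes are never binned together
  ms3 <- make_markers(rbind(v, v), class = c("maternal", "paternal"),
                      scaffold = c("sA", "sB"))
  expect_equal(nrow(perfect_linkage_bins(ms3)$bins), 2L)
})

# Hand-built fixtures for the propagation rules: a bins object and sibling
# clusterings over its bin ids.
make_bins <- function(scaffold_sets, class = "maternal") {
  ids <- sprintf("bin%05d", seq_along(scaffold_sets))
  names(scaffold_sets) <- ids
  structure(list(
    bins = data.frame(bin_id = ids, class = class,
                      n_markers = lengths(scaffold_sets),
                      n_scaffolds = lengths(scaffold_sets)),
    seg = matrix(1L, length(ids), 2), members = as.list(ids),
    scaffolds = scaffold_sets, offspring = c("o1", "o2")),
    class = "linkage_bins")
}
make_clustering <- function(bin_groups, threshold) {
  groups <- lapply(bin_groups, identity)
  names(groups) <- sprintf("LG%02d", seq_along(groups))
  structure(list(groups = groups, sizes = lengths(groups),
                 threshold = threshold), class = "linkage_groups")
}

test_that("the vote-ratio rules assign, refuse and log as specified", {
  # sibling cluster: 10 scaffolds on LG1, 1 on LG2, 1 unknown -> all LG1
  core <- assignment_state(c(sprintf("k%02d", 1:10), "k11"),
                           c(rep("LG1", 10), "LG2"))
  bins <- make_bins(as.list(c(sprintf("k%02d", 1:10), "k11", "unk")))
  clus <- make_clustering(list(bins$bins$bin_id), 6.1)
  cfg <- propagation_config(lod_ladder = 6.1)
  out <- propagate(core, list(`6.1` = clus), bins, cfg)
  a <- out$assignments
  expect_equal(a$group[a$scaffold == "unk"], "LG1")
  expect_equal(a$provenance[a$scaffold == "unk"], "group_rule")

  # bin with tallies {LG1: 2, LG2: 1}: 2 < 3 x 1, no assignment, conflict logged
  core2 <- assignment_state(c("a", "b", "c"), c("LG1", "LG1", "LG2"))
  bins2 <- make_bins(list(c("a", "b", "c", "unk")))
  clus2 <- make_clustering(list(character(0)), 6.1)
  out2 <- propagate(core2, list(`6.1` = clus2), bins2, cfg)
  expect_false("unk" %in% out2$assignments$scaffold)
  expect_gt(nrow(out2$conflicts), 0L)

  # unanimous single vote: 1 >= 3 x 0 -> assigned
  core3 <- assignment_state("a", "LG1")
  bins3 <- make_bins(list(c("a", "unk")))
  out3 <- propagate(core3, list(`6.1` = clus2), bins3, cfg)
  a3 <- out3$assignments
  expect_equal(a3$group[a3$scaffold == "unk"], "LG1")
  expect_equal(a3$provenance[a3$scaffold == "unk"], "bin_rule")

  # exact ratio is accepted (3 vs 1 with ratio 3)
  core4 <- assignment_state(c("a", "b", "c", "d"),
                            c("LG1", "LG1", "LG1", "LG2"))
  bins4 <- make_bins(list(c("a", "b", "c", "d", "unk")))
  out4 <- propagate(core4, list(`6.1` = clus2), bins4, cfg)
  expect_equal(out4$assignments$group[out4$assignments$scaffold == "unk"],
               "LG1")

  # top tie yields no assignment
  core5 <- assignment_state(c("a", "b"), c("LG1", "LG2"))
  bins5 <- make_bins(list(c("a", "b", "unk")))
  out5 <- propagate(core5, list(`6.1` = clus2), bins5, cfg)
  expect_false("unk" %in% out5$assignments$scaffold)

  # missing ladder clustering is rejected
  expect_error(propagate(core3, list(`9.9` = clus2), bins3, cfg), "ladder")
})

test_that("propagation chains across bins within a ladder step", {
  # s1 known; bin1 = {s1, s2}; bin2 = {s2, s3}: s3 reachable only after s2
  core <- assignment_state("s1", "LG1")
  bins <- make_bins(list(c("s1", "s2"), c("s2", "s3")))
  clus <- make_clustering(list(character(0)), 6.0)
  out <- propagate(core, list(`6.0` = clus), bins,
                   propagation_config(lod_ladder = 6.0))
  a <- out$assignments
  expect_setequal(a$scaffold, c("s1", "s2", "s3"))
  expect_true(all(a$group == "LG1"))
})

test_that("propagation is a fixpoint, keeps core labels, and ignores unit order", {
  core <- assignment_state(c("a", "b", "c", "x"),
                           c("LG1", "LG1", "LG1", "LG2"))
  bins <- make_bins(list(c("a", "u1"), c("b", "u2"), c("u2", "u3"),
                         c("x", "u4")))
  clus <- make_clustering(list(c("bin00001", "bin00002")), 6.0)
  cfg <- propagation_config(lod_ladder = 6.0)
  once <- propagate(core, list(`6.0` = clus), bins, cfg)
  twice <- propagate(once, list(`6.0` = clus), bins, cfg)
  expect_identical(once$assignments, twice$assignments)
  # core labels survive untouched
  a <- once$assignments
  expect_equal(a$group[match(c("a", "b", "c", "x"), a$scaffold)],
               c("LG1", "LG1", "LG1", "LG2"))
  expect_true(all(a$provenance[match(c("a", "b", "c", "x"), a$scaffold)] ==
                    "core"))
  # the assigned set only grows and unit order does not matter at the fixpoint
  perm_bins <- make_bins(list(c("x", "u4"), c("u2", "u3"), c("b", "u2"),
                              c("a", "u1")))
  perm <- propagate(core, list(`6.0` = clus), perm_bins, cfg)
  m1 <- stats::setNames(once$assignments$group, once$assignments$scaffold)
  m2 <- stats::setNames(perm$assignments$group, perm$assignments$scaffold)
  expect_identical(m1[sort(names(m1))], m2[sort(names(m2))])
})

test_that("assignments accumulate across ladder steps and are never revoked", {
  core <- assignment_state(c("a", "b"), c("LG1", "LG2"))
  bins <- make_bins(list(c("a", "u1"), c("b", "u2")))
  # u1 reachable at 6.1 only, u2 at 6.0 only
  clusA <- make_clustering(list("bin00001"), 6.1)
  clusB <- make_clustering(list("bin00002"), 6.0)
  cfg <- propagation_config(lod_ladder = c(6.1, 6.0))
  out <- propagate(core, list(`6.1` = clusA, `6.0` = clusB), bins, cfg)
  a <- out$assignments
  expect_equal(a$group[a$scaffold == "u1"], "LG1")
  expect_equal(a$group[a$scaffold == "u2"], "LG2")
  expect_equal(a$ladder[a$scaffold == "u1"], 6.1)
})

test_that("assignment summaries count scaffolds and megabases", {
  empty <- summarize_assignments(assignment_state(character(0), character(0)),
                                 c(s = 1))
  expect_equal(nrow(empty), 0L)

  st <- assignment_state(c("s1", "s2"), c("LG1", "LG2"))
  out <- summarize_assignments(st, c(s1 = 1000, s2 = 1000))
  expect_equal(sum(out$total_bp), 2000)
  expect_equal(out$n_scaffolds, c(1L, 1L))
  expect_equal(unname(attr(out, "totals")["total_bp"]), 2000)
})

test_that("zero-error propagation matches simulator truth everywhere", {
  ky <- karyotype_config(n_chromosomes = 4, physical_length_bp = 2e6,
                         scaffold_length = c(2e4, 6e4))
  pd <- pedigree_config(n_offspring = 44, family_sizes = c(22, 22),
                        genotype_error_rate = 0, missing_rate = 0.05,
                        mean_depth = 40, seed = 29)
  st <- simulate_pedigree(ky, pd, marker_density = 120)
  tab <- apply_confidence_mask(st$genotypes, 15)
  core_ms <- pick_one_snp_per_scaffold(
    select_maternal_testcross(tab, cfg = filter_config(12, 0.30, 15)))
  lg <- cluster_markers(core_ms, 8.4)
  core <- core_assignments(lg, core_ms)

  fam <- st$families$individual[st$families$family == 1]
  sib_tab <- apply_confidence_mask(st$genotypes, 20)
  sib <- select_sibling_informative(sib_tab, family_ids = fam,
                                    cfg = filter_config(5, 4, 20))
  bins <- perfect_linkage_bins(sib)
  ladders <- c(6.1, 6.0, 5.5)
  clus <- lapply(ladders, function(l) cluster_markers(bins, l))
  names(clus) <- as.character(ladders)
  out <- propagate(core, clus, bins, propagation_config(lod_ladder = ladders))

  prop <- out$assignments[out$assignments$provenance != "core", ]
  expect_gt(nrow(prop), 0L)
  truth_chr <- stats::setNames(st$scaffolds$chromosome, st$scaffolds$scaffold)
  # every group maps to one true chromosome; propagated scaffolds match it
  grp_chr <- tapply(truth_chr[core$assignments$scaffold],
                    core$assignments$group,
                    function(x) as.integer(names(sort(-table(x)))[1]))
  expect_true(all(truth_chr[prop$scaffold] == grp_chr[prop$group]))
})
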