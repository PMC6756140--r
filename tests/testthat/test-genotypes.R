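test_that("confidence mask keeps calls only when both alternatives are unlikely", {
  calls <- matrix(c(1L, 1L, 1L), 1, 3)
  pl <- array(0, c(1, 3, 3))
  pl[1, 1, ] <- c(40, 0, 60)   # both alternatives >= 15: retained
  pl[1, 2, ] <- c(10, 0, 60)   # one alternative below 15: masked
  pl[1, 3, ] <- c(14, 0, 60)
  tab <- make_table(calls, pl)
  out <- apply_confidence_mask(tab, 15)
  expect_identical(unname(out$calls[1, ]), c(1L, NA_integer_, NA_integer_))
  # threshold 0 is a vacuous mask
  expect_identical(apply_confidence_mask(tab, 0)$calls, tab$calls)
  # tables without likelihoods pass through
  expect_identical(apply_confidence_mask(make_table(calls), 15)$calls,
                   make_table(calls)$calls)
})

test_that("maternal-testcross selection applies the whole-cohort scheme", {
  n <- 90
  mk_row <- function(mother, off) matrix(c(mother, off), 1)
  cfg <- filter_config(24, 27, 15)
  # mother het, 45/45 split: retained
  t1 <- make_table(mk_row(1L, rep(c(1L, 0L), 45)))
  expect_equal(nrow(select_maternal_testcross(t1, cfg = cfg)$info), 1L)
  # mother homozygous: dropped regardless of offspring
  t2 <- make_table(mk_row(0L, rep(c(1L, 0L), 45)))
  expect_equal(nrow(select_maternal_testcross(t2, cfg = cfg)$info), 0L)
  # minor genotype 20 < 24: dropped
  t3 <- make_table(mk_row(1L, c(rep(1L, 70), rep(0L, 20))))
  expect_equal(nrow(select_maternal_testcross(t3, cfg = cfg)$info), 0L)
  # third genotype class: fathers cannot share one allele -> dropped
  t4 <- make_table(mk_row(1L, c(rep(1L, 45), rep(0L, 44), 2L)))
  expect_equal(nrow(select_maternal_testcross(t4, cfg = cfg)$info), 0L)
  # missing above 30% of 90: dropped
  t5 <- make_table(mk_row(1L, c(rep(c(1L, 0L), 31), rep(NA_integer_, 28))))
  expect_equal(nrow(select_maternal_testcross(t5, cfg = cfg)$info), 0L)
  # segregation vector binarised to het/hom over the offspring
  ms <- select_maternal_testcross(t1, cfg = cfg)
  expect_identical(unname(ms$seg[1, ]), rep(c(1L, 0L), 45))
  expect_identical(ms$info$class, "maternal")
  # fractional and count max_missing agree (30% of 90 = 27)
  cfg_frac <- filter_config(24, 0.30, 15)
  t6 <- make_table(mk_row(1L, c(rep(c(1L, 0L), 32), rep(NA_integer_, 26))))
  expect_equal(nrow(select_maternal_testcross(t6, cfg = cfg_frac)$info), 1L)
  expect_error(select_maternal_testcross(t1, mother_id = "nope"), "mother")
})

test_that("sibling selection infers the informative parent within a family", {
  cfg <- filter_config(5, 4, 20)
  fam <- sprintf("off%03d", 1:22)
  mk_tab <- function(mother, off22) make_table(matrix(c(mother, off22), 1))
  # mother homozygous, sibs 11 het / 11 hom-ref: paternal-informative
  tA <- mk_tab(0L, rep(c(1L, 0L), 11))
  msA <- select_sibling_informative(tA, family_ids = fam, cfg = cfg)
  expect_equal(msA$info$class, "paternal")
  # mother het, sibs segregate het/hom-alt: maternal-informative
  tB <- mk_tab(1L, rep(c(1L, 2L), 11))
  msB <- select_sibling_informative(tB, family_ids = fam, cfg = cfg)
  expect_equal(msB$info$class, "maternal")
  # all three classes present: both parents het -> dropped
  tC <- mk_tab(1L, c(rep(0L, 6), rep(1L, 10), rep(2L, 6)))
  expect_equal(nrow(select_sibling_informative(tC, family_ids = fam,
                                               cfg = cfg)$info), 0L)
  # mother hom-ref but hom-alt sibs appear: incompatible -> dropped
  tD <- mk_tab(0L, c(rep(1L, 11), rep(2L, 11)))
  expect_equal(nrow(select_sibling_informative(tD, family_ids = fam,
                                               cfg = cfg)$info), 0L)
  # five missing of 22 exceeds the cap of four
  tE <- mk_tab(0L, c(rep(c(1L, 0L), 8), 1L, rep(NA_integer_, 5)))
  expect_equal(nrow(select_sibling_informative(tE, family_ids = fam,
                                               cfg = cfg)$info), 0L)
  # four missing passes
  tF <- mk_tab(0L, c(rep(c(1L, 0L), 9), rep(NA_integer_, 4)))
  expect_equal(nrow(select_sibling_informative(tF, family_ids = fam,
                                               cfg = cfg)$info), 1L)
  # minor genotype below five: dropped
  tG <- mk_tab(0L, c(rep(1L, 4), rep(0L, 18)))
  expect_equal(nrow(select_sibling_informative(tG, family_ids = fam,
                                               cfg = cfg)$info), 0L)
  expect_error(select_sibling_informative(tA, family_ids = character(0)),
               "non-empty")
})

test_that("one SNP per scaffold prefers complete then balanced then leftmost", {
  seg <- rbind(c(1L, 0L, 1L, 0L, NA, NA, 1L, 0L, 1L, 0L),
               rep(c(1L, 0L), 5),
               c(rep(1L, 8), 0L, 0L),
               c(rep(1L, 6), rep(0L, 4)))
  ms <- make_markers(seg, scaffold = c("s1", "s1", "s2", "s2"))
  ms$info$position <- c(10L, 50L, 5L, 9L)
  out <- pick_one_snp_per_scaffold(ms)
  # s1: fewest missing wins; s2: equal missing, larger minor count wins
  expect_identical(out$info$marker_id, c("mk002", "mk004"))

  # position breaks exact ties
  seg2 <- rbind(rep(c(1L, 0L), 5), rep(c(0L, 1L), 5))
  ms2 <- make_markers(seg2, scaffold = c("s1", "s1"))
  ms2$info$position <- c(70L, 30L)
  expect_identical(pick_one_snp_per_scaffold(ms2)$info$marker_id, "mk002")

  # idempotent when already one per scaffold
  one <- make_markers(seg2, scaffold = c("s1", "s2"))
  expect_identical(pick_one_snp_per_scaffold(one)$info, one$info)
})

test_that("filters are order-stable and monotone in their thresholds", {
  ky <- karyotype_config(n_chromosomes = 2, physical_length_bp = 2e6)
  pd <- pedigree_config(n_offspring = 40, family_sizes = c(22, 18), seed = 21)
  st <- simulate_pedigree(ky, pd, marker_density = 50)
  tab <- apply_confidence_mask(st$genotypes, 15)

  base <- select_maternal_testcross(tab, cfg = filter_config(10, 0.30, 15))
  # permuting marker order leaves the selected set unchanged
  perm <- sample(nrow(tab$markers))
  tab_p <- genotype_table(tab$individuals, tab$markers[perm, ],
                          tab$calls[perm, , drop = FALSE],
                          tab$pl[perm, , , drop = FALSE])
  out_p <- select_maternal_testcross(tab_p, cfg = filter_config(10, 0.30, 15))
  expect_setequal(out_p$info$marker_id, base$info$marker_id)

  # stricter thresholds never add markers
  tighter <- select_maternal_testcross(tab, cfg = filter_config(15, 0.30, 15))
  expect_true(all(tighter$info$marker_id %in% base$info$marker_id))
  less_missing <- select_maternal_testcross(tab, cfg = filter_config(10, 0.1, 15))
  expect_true(all(less_missing$info$marker_id %in% base$info$marker_id))
})

test_that("zero-error simulations recover exactly the truth maternal markers", {
  ky <- karyotype_config(n_chromosomes = 2, physical_length_bp = 2e6)
  pd <- pedigree_config(n_offspring = 90, family_sizes = c(50, 40),
                        genotype_error_rate = 0, missing_rate = 0,
                        mean_depth = 40, seed = 13)
  st <- simulate_pedigree(ky, pd, marker_density = 60)
  ms <- select_maternal_testcross(apply_confidence_mask(st$genotypes, 15),
                                  cfg = filter_config(24, 0.30, 15))
  truth <- st$markers$marker_id[st$markers$class == "maternal"]
  # count thresholds: drop truth markers whose minor class is < 24
  seg_true <- st$truth$genotype[st$markers$class == "maternal", -1L]
  minor <- pmin(rowSums(seg_true == 1L), rowSums(seg_true == 0L))
  expect_setequal(ms$info$marker_id, truth[minor >= 24])
})

test_that("VCF loading rejects bad mother ids and drops non-SNP records", {
  path <- tempfile(fileext = ".vcf")
  writeLines(c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "mom", "kid", sep = "\t"),
    paste("s1", "10", "v1", "A", "T", ".", "PASS", ".", "GT", "0/1", "1/1",
          sep = "\t"),
    paste("s1", "20", "v2", "A", "AT", ".", "PASS", ".", "GT", "0/1", "0/0",
          sep = "\t"),
    paste("s1", "30", "v3", "A", "T,G", ".", "PASS", ".", "GT", "0/1", "0/0",
          sep = "\t")), path)
  tab <- load_genotypes(path, mother_id = "mom")
  expect_equal(nrow(tab$markers), 1L)           # indel and multiallelic dropped
  expect_equal(attr(tab, "dropped_records"), 2L)
  expect_identical(unname(tab$calls[1, ]), c(1L, 2L))
  expect_error(load_genotypes(path, mother_id = "granny"), "mother")
  # mother is moved to the front
  tab2 <- load_genotypes(path, mother_id = "kid")
  expect_identical(tab2$individuals[1], "kid")
})
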