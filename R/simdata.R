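#' Karyotype configuration for the pedigree simulator
#'
#' Describes the simulated genome: chromosome number, genetic and physical
#' chromosome lengths, and the scaffold length distribution used to tile each
#' chromosome with non-overlapping scaffolds.  The default chromosome number
#' follows the gametic count of the milkweed/coffee karyotype (x = n = 11,
#' 2n = 22); physical lengths are scaled down so that desk-scale simulations
#' stay fast while marker counts remain realistic.
#'
#' @param n_chromosomes Number of chromosomes (>= 1).
#' @param genetic_length_cM Genetic length of each chromosome in centimorgans;
#'   recycled to `n_chromosomes`.  A length of 0 forbids crossovers.
#' @param physical_length_bp Physical length of each chromosome in bp;
#'   recycled to `n_chromosomes`.
#' @param scaffold_length Numeric pair `c(min, max)`: scaffold lengths are
#'   drawn uniformly from this range and tiled left to right without gaps,
#'   so every scaffold lies on exactly one chromosome.
#' @return An object of class `karyotype_config`.
#' @export
karyotype_config <- function(n_chromosomes = 11,
                             genetic_length_cM = 60,
                             physical_length_bp = 5e6,
                             scaffold_length = c(2e4, 1e5)) {
  stopifnot(n_chromosomes >= 1)
  genetic_length_cM <- rep_len(genetic_length_cM, n_chromosomes)
  physical_length_bp <- rep_len(physical_length_bp, n_chromosomes)
  if (any(genetic_length_cM < 0) || any(physical_length_bp < 0))
    stop("chromosome lengths must be non-negative")
  if (length(scaffold_length) != 2L || scaffold_length[1] > scaffold_length[2] ||
      scaffold_length[1] < 1)
    stop("scaffold_length must be c(min, max) with 1 <= min <= max")
  structure(list(n_chromosomes = as.integer(n_chromosomes),
                 genetic_length_cM = genetic_length_cM,
                 physical_length_bp = physical_length_bp,
                 scaffold_length = scaffold_length),
            class = "karyotype_config")
}

#' Pedigree configuration for the simulator
#'
#' Emulates the study design of an open-pollinated maternal plant whose
#' offspring fall into full-sib families, each family sired by a single
#' pollen donor.  The defaults mirror a 96-offspring cohort in six families
#' with the largest family holding 22 full sibs.
#'
#' @param n_offspring Total number of offspring.
#' @param family_sizes Integer vector of full-sib family sizes; must sum to
#'   `n_offspring`.  One paternal donor per family.
#' @param genotype_error_rate Probability that an observed call is flipped to
#'   a uniformly chosen other genotype.
#' @param missing_rate Probability that a call is reported missing.
#' @param mean_depth Mean per-site sequencing depth (reads/site) of the
#'   Poisson read-depth model used to generate Phred-scaled genotype
#'   likelihoods.
#' @param seed Integer seed; identical configurations and seeds give
#'   bitwise-identical simulations.
#' @return An object of class `pedigree_config`.
#' @export
pedigree_config <- function(n_offspring = 96,
                            family_sizes = c(22, 17, 16, 15, 14, 12),
                            genotype_error_rate = 0.02,
                            missing_rate = 0.10,
                            mean_depth = 20,
                            seed = 1) {
  if (any(family_sizes <= 0)) stop("family sizes must be positive")
  if (sum(family_sizes) != n_offspring)
    stop("family_sizes must sum to n_offspring")
  if (genotype_error_rate < 0 || genotype_error_rate > 1 ||
      missing_rate < 0 || missing_rate > 1)
    stop("error and missing rates must lie in [0, 1]")
  if (mean_depth < 0) stop("mean_depth must be non-negative")
  structure(list(n_offspring = as.integer(n_offspring),
                 family_sizes = as.integer(family_sizes),
                 n_fathers = length(family_sizes),
                 genotype_error_rate = genotype_error_rate,
                 missing_rate = missing_rate,
                 mean_depth = mean_depth,
                 seed = as.integer(seed)),
            class = "pedigree_config")
}

# One gamete: crossover count ~ Poisson(map length in Morgans), uniform
# crossover placement on the genetic map, no interference (Haldane model).
# chrom_index: list of marker indices per chromosome; gpos: genetic positions.
.meiosis_gamete <- function(h1, h2, chrom_index, gpos, genetic_length_cM) {
  allele <- integer(length(h1))
  for (ch in seq_along(chrom_index)) {
    idx <- chrom_index[[ch]]
    if (!length(idx)) next
    L <- genetic_length_cM[ch]
    nco <- if (L > 0) stats::rpois(1L, L / 100) else 0L
    start <- sample.int(2L, 1L)
    if (nco > 0L) {
      xo <- sort(stats::runif(nco, 0, L))
      seg <- (start - 1L + findInterval(gpos[idx], xo)) %% 2L
    } else {
      seg <- rep.int(start - 1L, length(idx))
    }
    allele[idx] <- ifelse(seg == 0L, h1[idx], h2[idx])
  }
  allele
}

# Phred-scaled genotype likelihoods from a Poisson-depth binomial read model.
# Alt-read counts are drawn conditional on the (possibly corrupted) observed
# call so the likelihood triplet is consistent with the emitted genotype; the
# triplet is then normalised so the called genotype has PL 0, other entries
# clamped at 0.  Sequencing base error is 1%.
.simulate_pl <- function(calls, mean_depth) {
  M <- nrow(calls); N <- ncol(calls)
  pl <- array(0, dim = c(M, N, 3L))
  obs <- as.vector(calls)
  keep <- !is.na(obs)
  depth <- stats::rpois(sum(keep), mean_depth)
  p_alt <- c(0.01, 0.5, 0.99)
  alt <- stats::rbinom(length(depth), depth, p_alt[obs[keep] + 1L])
  ll <- cbind(stats::dbinom(alt, depth, p_alt[1], log = TRUE),
              stats::dbinom(alt, depth, p_alt[2], log = TRUE),
              stats::dbinom(alt, depth, p_alt[3], log = TRUE)) / log(10)
  raw <- -10 * (ll - apply(ll, 1L, max))
  called <- raw[cbind(seq_len(nrow(raw)), obs[keep] + 1L)]
  norm <- pmax(raw - called, 0)
  for (g in 1:3) {
    slice <- matrix(0, M, N)
    slice[keep] <- norm[, g]
    pl[, , g] <- slice
  }
  # depth-0 sites carry no information: mark the call missing
  zero <- keep
  zero[keep] <- depth == 0L
  calls[matrix(zero, M, N)] <- NA_integer_
  list(pl = pl, calls = calls)
}

#' Simulate a pseudo-testcross mapping pedigree
#'
#' Generates a full synthetic study: a scaffolded genome, parental
#' haplotypes, offspring produced by a Haldane (no-interference) crossover
#' process, and an observed genotype matrix corrupted by genotyping error and
#' missingness, with Phred-scaled genotype likelihoods from a Poisson-depth
#' binomial read model.
#'
#' Marker classes follow the pseudo-testcross design: at maternal-informative
#' markers the mother is heterozygous and every father is homozygous for the
#' shared reference allele; at paternal-informative markers the mother is
#' homozygous and exactly one father is heterozygous.
#'
#' @param karyotype A [karyotype_config()].
#' @param pedigree A [pedigree_config()].
#' @param marker_density Markers per Mbp (total over both parental classes).
#' @param prop_maternal Proportion of markers that are maternal-informative.
#' @param markers Optional data frame `(chromosome, pos_bp, class[, father])`
#'   fixing marker placement exactly; overrides `marker_density`.  Useful for
#'   controlled experiments (e.g. two markers a known map distance apart).
#' @return An object of class `sim_study` with components:
#'   `genotypes` (a [genotype_table()], mother first), `markers` (the marker
#'   catalog: scaffold, 1-based position within scaffold, chromosome,
#'   genetic position, parental class, informative father), `scaffolds`
#'   (scaffold -> chromosome truth table with start/end/length), `families`
#'   (individual -> family/father), and `truth` (uncorrupted genotype
#'   matrix and maternal phase).
#' @export
simulate_pedigree <- function(karyotype, pedigree, marker_density = 25,
                              prop_maternal = 0.5, markers = NULL) {
  stopifnot(inherits(karyotype, "karyotype_config"),
            inherits(pedigree, "pedigree_config"))
  if (is.null(markers) && marker_density <= 0)
    stop("marker_density must be positive")
  set.seed(pedigree$seed)
  K <- karyotype$n_chromosomes

  # --- scaffolds tile each chromosome left to right, no gaps ---
  sc <- vector("list", K)
  for (ch in seq_len(K)) {
    plen <- karyotype$physical_length_bp[ch]
    lens <- integer(0)
    while (sum(lens) < plen) {
      lens <- c(lens, round(stats::runif(32L, karyotype$scaffold_length[1],
                                         karyotype$scaffold_length[2])))
    }
    cut <- which(cumsum(lens) >= plen)[1]
    lens <- lens[seq_len(cut)]
    lens[cut] <- plen - sum(lens[-cut])
    lens <- lens[lens > 0]
    end <- cumsum(lens)
    sc[[ch]] <- data.frame(chromosome = ch,
                           start = c(0, end[-length(end)]) + 1,
                           end = end, length = lens)
  }
  scaffolds <- do.call(rbind, sc)
  scaffolds$scaffold <- sprintf("scf%05d", seq_len(nrow(scaffolds)))
  scaffolds <- scaffolds[, c("scaffold", "chromosome", "start", "end", "length")]

  # --- marker placement ---
  if (is.null(markers)) {
    mk <- vector("list", K)
    for (ch in seq_len(K)) {
      plen <- karyotype$physical_length_bp[ch]
      n_mk <- round(marker_density * plen / 1e6)
      if (n_mk == 0L) next
      if (plen <= 0) stop("chromosome with zero physical length cannot carry markers")
      pos <- sort(sample.int(plen, n_mk))
      cls <- ifelse(stats::runif(n_mk) < prop_maternal, "maternal", "paternal")
      fa <- ifelse(cls == "paternal",
                   sample.int(pedigree$n_fathers, n_mk, replace = TRUE),
                   NA_integer_)
      mk[[ch]] <- data.frame(chromosome = ch, pos_bp = pos, class = cls,
                             father = fa)
    }
    markers <- do.call(rbind, mk)
    if (is.null(markers) || !nrow(markers)) stop("no markers generated")
  } else {
    markers <- as.data.frame(markers)
    if (is.null(markers$father)) markers$father <- NA_integer_
    markers$father[markers$class == "paternal" & is.na(markers$father)] <- 1L
    if (any(karyotype$physical_length_bp[markers$chromosome] <= 0))
      stop("chromosome with zero physical length cannot carry markers")
    markers <- markers[order(markers$chromosome, markers$pos_bp), ]
  }
  M <- nrow(markers)
  markers$marker_id <- sprintf("mk%05d", seq_len(M))
  markers$genetic_cM <- karyotype$genetic_length_cM[markers$chromosome] *
    markers$pos_bp / karyotype$physical_length_bp[markers$chromosome]
  # scaffold lookup
  markers$scaffold <- NA_character_
  markers$position <- NA_integer_
  for (ch in seq_len(K)) {
    i <- which(markers$chromosome == ch)
    if (!length(i)) next
    schi <- scaffolds[scaffolds$chromosome == ch, ]
    j <- findInterval(markers$pos_bp[i], schi$start)
    markers$scaffold[i] <- schi$scaffold[j]
    markers$position[i] <- as.integer(markers$pos_bp[i] - schi$start[j] + 1)
  }
  markers$position <- as.integer(markers$position)

  # --- parental haplotypes ---
  m_phase <- ifelse(markers$class == "maternal",
                    sample(0:1, M, replace = TRUE), NA_integer_)
  mh1 <- ifelse(!is.na(m_phase), m_phase, 0L)
  mh2 <- ifelse(!is.na(m_phase), 1L - m_phase, 0L)
  f_h1 <- matrix(0L, pedigree$n_fathers, M)
  f_h2 <- matrix(0L, pedigree$n_fathers, M)
  pat <- which(markers$class == "paternal")
  if (length(pat)) {
    f_phase <- sample(0:1, length(pat), replace = TRUE)
    f_h1[cbind(markers$father[pat], pat)] <- f_phase
    f_h2[cbind(markers$father[pat], pat)] <- 1L - f_phase
  }

  # --- meiosis ---
  chrom_index <- split(seq_len(M), factor(markers$chromosome, levels = seq_len(K)))
  n_off <- pedigree$n_offspring
  fam_of <- rep(seq_along(pedigree$family_sizes), pedigree$family_sizes)
  G <- matrix(0L, M, n_off + 1L)
  G[, 1L] <- mh1 + mh2
  for (i in seq_len(n_off)) {
    mg <- .meiosis_gamete(mh1, mh2, chrom_index, markers$genetic_cM,
                          karyotype$genetic_length_cM)
    pg <- .meiosis_gamete(f_h1[fam_of[i], ], f_h2[fam_of[i], ], chrom_index,
                          markers$genetic_cM, karyotype$genetic_length_cM)
    G[, i + 1L] <- mg + pg
  }
  individuals <- c("mother", sprintf("off%03d", seq_len(n_off)))

  # --- observation model: error flips, missingness, Phred likelihoods ---
  obs <- G
  n_cell <- length(obs)
  flip <- stats::runif(n_cell) < pedigree$genotype_error_rate
  if (any(flip)) {
    shift <- sample(1:2, sum(flip), replace = TRUE)
    obs[flip] <- (obs[flip] + shift) %% 3L
  }
  miss <- stats::runif(n_cell) < pedigree$missing_rate
  obs[miss] <- NA_integer_
  sim <- .simulate_pl(obs, pedigree$mean_depth)
  gt <- genotype_table(individuals = individuals,
                       markers = data.frame(marker_id = markers$marker_id,
                                            scaffold = markers$scaffold,
                                            position = markers$position),
                       calls = sim$calls, pl = sim$pl,
                       mother_id = "mother")

  families <- data.frame(individual = individuals[-1L],
                         family = fam_of, father = fam_of)
  catalog <- markers[, c("marker_id", "scaffold", "position", "chromosome",
                         "pos_bp", "genetic_cM", "class", "father")]
  rownames(catalog) <- NULL
  dimnames(G) <- list(markers$marker_id, individuals)
  structure(list(genotypes = gt, markers = catalog, scaffolds = scaffolds,
                 families = families,
                 truth = list(genotype = G, maternal_phase = m_phase),
                 karyotype = karyotype, pedigree = pedigree),
            class = "sim_study")
}

#' @export
print.sim_study <- function(x, ...) {
  cat("Simulated pedigree study\n")
  cat(sprintf("  %d chromosomes, %d scaffolds, %d markers (%d maternal / %d paternal)\n",
              x$karyotype$n_chromosomes, nrow(x$scaffolds), nrow(x$markers),
              sum(x$markers$class == "maternal"),
              sum(x$markers$class == "paternal")))
  cat(sprintf("  %d offspring in %d full-sib families (largest %d)\n",
              x$pedigree$n_offspring, length(x$pedigree$family_sizes),
              max(x$pedigree$family_sizes)))
  invisible(x)
}

#' Write genotypes to a VCF file
#'
#' Emits one VCFv4.2 record per marker with `CHROM` set to the scaffold id,
#' `POS` to the 1-based offset within the scaffold, and per-sample `GT:PL`
#' fields (mother first).  Missing calls are written as `./.`.  The output
#' round-trips losslessly through [load_genotypes()].
#'
#' @param x A `sim_study` or [genotype_table()].
#' @param path Destination file path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(x, path) {
  gt <- if (inherits(x, "sim_study")) x$genotypes else x
  stopifnot(inherits(gt, "genotype_table"))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("##fileformat=VCFv4.2",
               "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
               paste0("##FORMAT=<ID=PL,Number=G,Type=Integer,",
                      "Description=\"Phred-scaled genotype likelihoods\">"),
               paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                       "INFO", "FORMAT", gt$individuals), collapse = "\t")),
             con)
  gt_str <- c("0/0", "0/1", "1/1")
  M <- nrow(gt$markers)
  calls <- gt$calls
  pl <- gt$pl
  body <- character(M)
  for (m in seq_len(M)) {
    cells <- vapply(seq_along(gt$individuals), function(j) {
      g <- calls[m, j]
      if (is.na(g)) return("./.")
      sprintf("%s:%d,%d,%d", gt_str[g + 1L],
              as.integer(round(pl[m, j, 1L])),
              as.integer(round(pl[m, j, 2L])),
              as.integer(round(pl[m, j, 3L])))
    }, character(1))
    body[m] <- paste(c(gt$markers$scaffold[m], gt$markers$position[m],
                       gt$markers$marker_id[m], "A", "T", ".", "PASS", ".",
                       "GT:PL", cells), collapse = "\t")
  }
  writeLines(body, con)
  invisible(path)
}

#' Simulate assembler-bubble probe candidates
#'
#' Fabricates bubble-like probe candidates: random sequences with a SNP
#' offset, a home scaffold, and mapping counts at the 90% and 95% identity
#' thresholds.  A configurable fraction of candidates is emitted as
#' near-identical pairs (>= 90% identity) carrying a truth duplicate flag,
#' for exercising [dedupe_candidates()].
#'
#' @param n Number of candidates to generate.
#' @param scaffold_lengths Named numeric vector of scaffold lengths (bp);
#'   candidates are assigned to scaffolds uniformly.
#' @param duplicate_fraction Fraction of candidates belonging to a
#'   near-identical pair.
#' @param multimap_distribution Probability vector over mapping counts
#'   1, 2, 3, ... at 90% identity; the 95%-identity count is a thinned copy.
#' @param seed Integer seed.
#' @param candidate_length Length of generated bubble sequences (>= 80).
#' @return A [probe_candidates()] data frame with a logical truth column
#'   `is_duplicate`.
#' @export
simulate_probe_candidates <- function(n, scaffold_lengths,
                                      duplicate_fraction = 0.1,
                                      multimap_distribution =
                                        c(0.70, 0.10, 0.05, 0.05, 0.04,
                                          0.03, 0.02, 0.01),
                                      seed = 1, candidate_length = 120) {
  stopifnot(n >= 0, duplicate_fraction >= 0, duplicate_fraction <= 1,
            candidate_length >= 80)
  set.seed(seed)
  empty <- probe_candidates(id = character(0), sequence = character(0),
                            snp_offset = integer(0), scaffold_id = character(0),
                            scaffold_length = numeric(0),
                            map_count_90 = integer(0), map_count_95 = integer(0))
  empty$is_duplicate <- logical(0)
  if (n == 0L) return(empty)
  if (is.null(names(scaffold_lengths)))
    names(scaffold_lengths) <- sprintf("scf%05d", seq_along(scaffold_lengths))
  n_dup_pairs <- floor(n * duplicate_fraction / 2)
  n_base <- n - n_dup_pairs
  bases <- c("A", "C", "G", "T")
  seqs <- vapply(seq_len(n_base), function(i)
    paste(sample(bases, candidate_length, replace = TRUE), collapse = ""),
    character(1))
  scf <- sample(names(scaffold_lengths), n_base, replace = TRUE)
  probs <- multimap_distribution / sum(multimap_distribution)
  mc90 <- sample.int(length(probs), n_base, replace = TRUE, prob = probs)
  mc95 <- 1L + stats::rbinom(n_base, mc90 - 1L, 0.5)
  cand <- probe_candidates(
    id = sprintf("bub%05d", seq_len(n_base)),
    sequence = seqs,
    snp_offset = sample.int(candidate_length, n_base, replace = TRUE) - 1L,
    scaffold_id = scf,
    scaffold_length = unname(scaffold_lengths[scf]),
    map_count_90 = mc90, map_count_95 = mc95)
  cand$is_duplicate <- FALSE
  if (n_dup_pairs > 0L) {
    src <- sample.int(n_base, n_dup_pairs, replace = FALSE)
    mutated <- vapply(cand$sequence[src], function(s) {
      v <- strsplit(s, "")[[1]]
      k <- max(1L, round(length(v) * 0.05))
      at <- sample.int(length(v), k)
      v[at] <- vapply(v[at], function(b) sample(setdiff(bases, b), 1L),
                      character(1))
      paste(v, collapse = "")
    }, character(1), USE.NAMES = FALSE)
    dup <- cand[src, ]
    dup$id <- sprintf("bub%05d", n_base + seq_len(n_dup_pairs))
    dup$sequence <- mutated
    cand$is_duplicate[src] <- TRUE
    dup$is_duplicate <- TRUE
    cand <- rbind(cand, dup)
  }
  rownames(cand) <- NULL
  cand
}

#' Simulate a diploid k-mer depth histogram
#'
#' Generates a histogram of distinct k-mer species by depth under a
#' two-component diploid mixture: with per-base heterozygosity `h`, a
#' fraction `q = 1 - (1 - h)^k` of k-mer loci overlap a heterozygous site
#' and contribute two distinct species at roughly half depth, while the
#' remaining loci contribute one species at full depth.  Depths are Poisson;
#' a low-depth error component of spurious species is added.
#'
#' @param genome_size Haploid genome size in bp.
#' @param heterozygosity Per-base heterozygosity rate in `[0, 1)`.
#' @param k K-mer length (default 17).
#' @param mean_depth Mean depth of the homozygous component.
#' @param seed Integer seed.
#' @param error_species_fraction Number of error k-mer species as a fraction
#'   of `genome_size`; these sit at depth ~1.
#' @return A [kmer_hist()] object.
#' @export
simulate_kmer_histogram <- function(genome_size, heterozygosity = 0.01,
                                    k = 17, mean_depth = 84, seed = 1,
                                    error_species_fraction = 0.3) {
  stopifnot(genome_size >= 1, heterozygosity >= 0, heterozygosity < 1, k >= 1,
            mean_depth > 0, error_species_fraction >= 0)
  set.seed(seed)
  q <- 1 - (1 - heterozygosity)^k
  n_hom <- round((1 - q) * genome_size)
  n_het <- round(2 * q * genome_size)
  n_err <- round(error_species_fraction * genome_size)
  depths <- c(stats::rpois(n_hom, mean_depth),
              stats::rpois(n_het, mean_depth / 2),
              1L + stats::rpois(n_err, 0.25))
  depths <- depths[depths > 0L]
  kmer_hist(k = k, count = tabulate(depths))
}
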