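#' Genotype table
#'
#' Container for a markers-by-individuals call matrix with per-call
#' Phred-scaled genotype likelihood triplets.  Calls are coded
#' `0` = homozygous reference, `1` = heterozygous, `2` = homozygous
#' alternate, `NA` = missing.  The mother is always the first individual.
#'
#' @param individuals Character vector of sample ids, mother first.
#' @param markers Data frame with columns `marker_id`, `scaffold`,
#'   `position` (1-based within scaffold).
#' @param calls Integer matrix (markers x individuals) over `{0, 1, 2, NA}`.
#' @param pl Numeric array (markers x individuals x 3) of Phred-scaled
#'   genotype likelihoods normalised so the called genotype has PL 0, or
#'   `NULL` when likelihoods are unavailable (calls then count as fully
#'   confident).
#' @param mother_id Sample id of the maternal parent; must be
#'   `individuals[1]`.
#' @return An object of class `genotype_table`.
#' @export
genotype_table <- function(individuals, markers, calls, pl = NULL,
                           mother_id = individuals[1]) {
  stopifnot(is.character(individuals), length(individuals) >= 1,
            nrow(calls) == nrow(markers),
            ncol(calls) == length(individuals))
  if (!identical(mother_id, individuals[1]))
    stop("mother must be the first individual")
  if (!is.null(pl))
    stopifnot(length(dim(pl)) == 3, dim(pl)[1] == nrow(calls),
              dim(pl)[2] == ncol(calls), dim(pl)[3] == 3)
  storage.mode(calls) <- "integer"
  dimnames(calls) <- list(markers$marker_id, individuals)
  structure(list(individuals = individuals, mother_id = mother_id,
                 markers = as.data.frame(markers), calls = calls, pl = pl),
            class = "genotype_table")
}

#' @export
print.genotype_table <- function(x, ...) {
  cat(sprintf("Genotype table: %d markers x %d individuals (mother: %s)%s\n",
              nrow(x$markers), length(x$individuals), x$mother_id,
              if (is.null(x$pl)) ", no likelihoods" else ""))
  invisible(x)
}

#' Load genotypes from a VCF file
#'
#' Reads GT (and, when present, PL) fields from a VCF and returns a
#' [genotype_table()].  Only biallelic SNP records are kept; multiallelic
#' and indel records are dropped and their count reported in the
#' `dropped_records` attribute.  1-based positions are preserved.
#'
#' @param path Path to a VCF file.
#' @param mother_id Sample id of the maternal parent.  Defaults to the first
#'   sample in the VCF; an id absent from the file is an error.  The table
#'   is reordered so the mother comes first.
#' @return A [genotype_table()].
#' @export
load_genotypes <- function(path, mother_id = NULL) {
  vcf <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1,
                                       dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]; alt <- fix[, "ALT"]
  snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T")
  n_drop <- sum(!snp)
  if (!any(snp)) stop("no biallelic SNP records in ", path)
  gt_raw <- vcfR::extract.gt(vcf, element = "GT")
  gt_raw <- gt_raw[snp, , drop = FALSE]
  samples <- colnames(gt_raw)
  if (is.null(mother_id)) mother_id <- samples[1]
  if (!mother_id %in% samples)
    stop("mother sample id '", mother_id, "' not present in VCF")
  ord <- c(mother_id, setdiff(samples, mother_id))
  gt_raw <- gt_raw[, ord, drop = FALSE]
  code <- function(g) {
    g <- gsub("|", "/", g, fixed = TRUE)
    out <- rep(NA_integer_, length(g))
    out[g %in% c("0/0")] <- 0L
    out[g %in% c("0/1", "1/0")] <- 1L
    out[g %in% c("1/1")] <- 2L
    out
  }
  calls <- matrix(code(gt_raw), nrow = nrow(gt_raw),
                  dimnames = dimnames(gt_raw))
  ids <- fix[snp, "ID"]
  if (all(is.na(ids)) || any(ids == "."))
    ids <- sprintf("%s_%s", fix[snp, "CHROM"], fix[snp, "POS"])
  markers <- data.frame(marker_id = ids, scaffold = fix[snp, "CHROM"],
                        position = as.integer(fix[snp, "POS"]))
  pl <- NULL
  if ("PL" %in% vcfR::vcf_field_names(vcf, tag = "FORMAT")$ID) {
    pl_raw <- vcfR::extract.gt(vcf, element = "PL")
    pl_raw <- pl_raw[snp, ord, drop = FALSE]
    split3 <- function(s) {
      out <- matrix(NA_real_, length(s), 3L)
      ok <- !is.na(s)
      if (any(ok)) {
        parts <- strsplit(s[ok], ",", fixed = TRUE)
        keep <- lengths(parts) == 3L
        if (any(keep))
          out[which(ok)[keep], ] <- matrix(
            as.numeric(unlist(parts[keep])), ncol = 3L, byrow = TRUE)
      }
      out
    }
    flat <- split3(as.vector(pl_raw))
    pl <- array(flat, dim = c(nrow(pl_raw), ncol(pl_raw), 3L))
    pl[is.na(pl)] <- 0
  }
  out <- genotype_table(individuals = ord, markers = markers, calls = calls,
                        pl = pl, mother_id = mother_id)
  attr(out, "dropped_records") <- n_drop
  out
}

#' Filter configuration for marker selection
#'
#' Bundles the thresholds of a SNP filtering scheme: the minimum abundance of
#' the minor genotype class, the maximum number (or fraction) of missing
#' individuals per locus, and the Phred confidence-mask threshold.  The
#' whole-cohort maternal-testcross scheme uses (24, 30%, 15); the
#' single-family sibling scheme uses (5, 4, 20).
#'
#' @param min_minor_genotype Minimum count of the minor genotype class.
#' @param max_missing Maximum missing individuals: an integer count, or a
#'   fraction of the cohort when `< 1`.
#' @param phred_mask_threshold Phred threshold used by
#'   [apply_confidence_mask()].
#' @return An object of class `filter_config`.
#' @export
filter_config <- function(min_minor_genotype = 24, max_missing = 0.30,
                          phred_mask_threshold = 15) {
  stopifnot(min_minor_genotype >= 0, max_missing >= 0,
            phred_mask_threshold >= 0)
  structure(list(min_minor_genotype = min_minor_genotype,
                 max_missing = max_missing,
                 phred_mask_threshold = phred_mask_threshold),
            class = "filter_config")
}

.max_missing_count <- function(max_missing, n) {
  if (max_missing < 1) floor(max_missing * n) else max_missing
}

#' Mask genotype calls of low confidence
#'
#' A call is retained only when both non-called genotypes in its normalised
#' Phred likelihood triplet score at or above `threshold` -- i.e. one
#' genotype is clearly most probable and the two alternatives are clearly
#' less probable.  Calls failing the rule are set to missing; retained call
#' values are never altered.  Tables without likelihoods pass unchanged.
#'
#' @param table A [genotype_table()].
#' @param threshold Phred units; 0 retains everything.
#' @return A [genotype_table()] with low-confidence calls set to missing.
#' @export
apply_confidence_mask <- function(table, threshold) {
  stopifnot(inherits(table, "genotype_table"), threshold >= 0)
  if (is.null(table$pl) || threshold == 0) return(table)
  calls <- table$calls
  idx <- which(!is.na(calls), arr.ind = TRUE)
  if (nrow(idx)) {
    g <- calls[idx]
    pls <- cbind(table$pl[cbind(idx, 1L)], table$pl[cbind(idx, 2L)],
                 table$pl[cbind(idx, 3L)])
    ok <- logical(nrow(idx))
    for (r in 1:3) {
      sel <- g == r - 1L
      if (any(sel)) {
        others <- pls[sel, -r, drop = FALSE]
        ok[sel] <- others[, 1L] >= threshold & others[, 2L] >= threshold
      }
    }
    calls[idx[!ok, , drop = FALSE]] <- NA_integer_
  }
  table$calls <- calls
  table
}

#' Marker set
#'
#' A set of informative markers with parental class and binary segregation
#' vectors over the offspring cohort: `1` = informative heterozygote,
#' `0` = informative homozygote, `NA` = missing.
#'
#' @param info Data frame with columns `marker_id`, `scaffold`, `position`,
#'   `class` (`"maternal"` or `"paternal"`).
#' @param seg Integer matrix (markers x offspring) over `{0, 1, NA}`.
#' @param offspring Character vector of offspring ids (cohort order).
#' @return An object of class `marker_set`.
#' @export
marker_set <- function(info, seg, offspring) {
  stopifnot(nrow(info) == nrow(seg), ncol(seg) == length(offspring),
            all(info$class %in% c("maternal", "paternal")))
  storage.mode(seg) <- "integer"
  dimnames(seg) <- list(info$marker_id, offspring)
  rownames(info) <- NULL
  structure(list(info = as.data.frame(info), seg = seg,
                 offspring = offspring),
            class = "marker_set")
}

#' @export
print.marker_set <- function(x, ...) {
  cat(sprintf("Marker set: %d markers (%d maternal / %d paternal) x %d offspring\n",
              nrow(x$info), sum(x$info$class == "maternal"),
              sum(x$info$class == "paternal"), length(x$offspring)))
  invisible(x)
}

# Class tallies over offspring calls, one row per marker.
.class_counts <- function(calls) {
  cbind(n0 = rowSums(calls == 0L, na.rm = TRUE),
        n1 = rowSums(calls == 1L, na.rm = TRUE),
        n2 = rowSums(calls == 2L, na.rm = TRUE),
        miss = rowSums(is.na(calls)))
}

#' Select maternal-testcross markers
#'
#' Retains markers segregating as Aa (mother) x aa (all fathers): the mother
#' is heterozygous and the offspring exhibit exactly the two genotype
#' classes of a testcross (heterozygotes plus one homozygous class; a third
#' class among non-missing calls rejects the locus, since the unsampled
#' fathers cannot then share one homozygous allele).  Loci must further meet
#' the minor-genotype and missingness thresholds of `cfg`.  Apply
#' [apply_confidence_mask()] first.
#'
#' @param table A [genotype_table()] (confidence mask already applied).
#' @param mother_id Maternal sample id; must be present in the table.
#' @param cfg A [filter_config()].
#' @return A [marker_set()] of maternal-informative markers with segregation
#'   vectors binarised over the offspring cohort.
#' @export
select_maternal_testcross <- function(table, mother_id = table$mother_id,
                                      cfg = filter_config()) {
  stopifnot(inherits(table, "genotype_table"))
  if (!mother_id %in% table$individuals)
    stop("mother sample id '", mother_id, "' not present")
  off <- setdiff(table$individuals, mother_id)
  oc <- table$calls[, off, drop = FALSE]
  mc <- table$calls[, mother_id]
  n_off <- length(off)
  max_miss <- .max_missing_count(cfg$max_missing, n_off)
  cc <- .class_counts(oc)
  hom <- pmax(cc[, "n0"], cc[, "n2"])
  keep <- !is.na(mc) & mc == 1L &
    !(cc[, "n0"] > 0L & cc[, "n2"] > 0L) &          # no third class
    cc[, "n1"] > 0L & hom > 0L &                    # both testcross classes
    pmin(cc[, "n1"], hom) >= cfg$min_minor_genotype &
    cc[, "miss"] <= max_miss
  seg <- oc[keep, , drop = FALSE]
  seg[] <- ifelse(is.na(seg), NA_integer_, ifelse(seg == 1L, 1L, 0L))
  info <- data.frame(marker_id = table$markers$marker_id[keep],
                     scaffold = table$markers$scaffold[keep],
                     position = table$markers$position[keep],
                     class = rep("maternal", sum(keep)))
  marker_set(info, seg, off)
}

#' Select single-parent-informative markers within one full-sib family
#'
#' Within a full-sib family, retains loci at which exactly one parent is
#' heterozygous.  When the mother is heterozygous the offspring must
#' segregate as Aa x aa (maternal class); when the mother is homozygous and
#' the sibs segregate into her homozygous class plus heterozygotes, the
#' (unsampled) father is inferred heterozygous (paternal class).  Loci
#' showing three genotype classes, or classes incompatible with a single
#' heterozygous parent, are dropped.  Count thresholds are applied within
#' the family.
#'
#' @param table A [genotype_table()] with the confidence mask already
#'   applied at `cfg$phred_mask_threshold`.
#' @param mother_id Maternal sample id.
#' @param family_ids Offspring ids of the full-sib family (non-empty, all
#'   present in the table).
#' @param cfg A [filter_config()]; the sibling scheme defaults are
#'   `filter_config(5, 4, 20)`.
#' @return A [marker_set()] over the family offspring with per-marker
#'   parental class.
#' @export
select_sibling_informative <- function(table, mother_id = table$mother_id,
                                       family_ids,
                                       cfg = filter_config(5, 4, 20)) {
  stopifnot(inherits(table, "genotype_table"))
  if (!length(family_ids)) stop("family_ids must be non-empty")
  if (!all(family_ids %in% table$individuals))
    stop("family_ids must all be present in the table")
  if (!mother_id %in% table$individuals)
    stop("mother sample id '", mother_id, "' not present")
  oc <- table$calls[, family_ids, drop = FALSE]
  mc <- table$calls[, mother_id]
  max_miss <- .max_missing_count(cfg$max_missing, length(family_ids))
  cc <- .class_counts(oc)
  hom <- pmax(cc[, "n0"], cc[, "n2"])
  # mother het: offspring must show het + exactly one homozygous class
  keep_mat <- !is.na(mc) & mc == 1L &
    !(cc[, "n0"] > 0L & cc[, "n2"] > 0L) &          # both parents het
    cc[, "n1"] > 0L & hom > 0L &
    pmin(cc[, "n1"], hom) >= cfg$min_minor_genotype
  # mother homozygous: sibs segregate her class + hets => father het
  same <- ifelse(!is.na(mc) & mc == 2L, cc[, "n2"], cc[, "n0"])
  other <- ifelse(!is.na(mc) & mc == 2L, cc[, "n0"], cc[, "n2"])
  keep_pat <- !is.na(mc) & mc != 1L &
    other == 0L &                                   # incompatible with mother
    cc[, "n1"] > 0L & same > 0L &
    pmin(cc[, "n1"], same) >= cfg$min_minor_genotype
  ok_miss <- cc[, "miss"] <= max_miss
  keep <- (keep_mat | keep_pat) & ok_miss
  cls <- ifelse(keep_mat, "maternal", "paternal")
  seg <- oc[keep, , drop = FALSE]
  seg[] <- ifelse(is.na(seg), NA_integer_, ifelse(seg == 1L, 1L, 0L))
  info <- data.frame(marker_id = table$markers$marker_id[keep],
                     scaffold = table$markers$scaffold[keep],
                     position = table$markers$position[keep],
                     class = cls[keep])
  marker_set(info, seg, family_ids)
}

#' Keep one SNP per scaffold
#'
#' Selects, for each scaffold, the marker with the fewest missing calls;
#' ties are broken by the most balanced segregation (minor-class count
#' closest to half the cohort), then by lowest position.
#'
#' @param markers A [marker_set()].
#' @return A [marker_set()] with exactly one marker per scaffold.
#' @export
pick_one_snp_per_scaffold <- function(markers) {
  stopifnot(inherits(markers, "marker_set"))
  if (!nrow(markers$info)) return(markers)
  n_miss <- rowSums(is.na(markers$seg))
  n_het <- rowSums(markers$seg == 1L, na.rm = TRUE)
  n_hom <- rowSums(markers$seg == 0L, na.rm = TRUE)
  minor <- pmin(n_het, n_hom)
  ord <- order(markers$info$scaffold, n_miss, -minor, markers$info$position)
  first <- ord[!duplicated(markers$info$scaffold[ord])]
  first <- sort(first)
  marker_set(markers$info[first, , drop = FALSE],
             markers$seg[first, , drop = FALSE], markers$offspring)
}
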