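#' K-mer depth histogram
#'
#' Distribution of distinct k-mer species over their depth (number of
#' occurrences in a read set).  In a diploid read set the histogram is
#' bimodal: heterozygous regions contribute species at roughly half the
#' depth of homozygous regions, and sequencing errors pile up at depth ~1.
#'
#' @param k K-mer length.
#' @param count Numeric vector: `count[d]` is the number of distinct k-mer
#'   species observed at depth `d` (depths are the indices, starting at 1).
#' @return An object of class `kmer_hist`.
#' @export
kmer_hist <- function(k, count) {
  stopifnot(k >= 1, all(count >= 0))
  structure(list(k = as.integer(k), count = as.numeric(count)),
            class = "kmer_hist")
}

#' @export
print.kmer_hist <- function(x, ...) {
  cat(sprintf("%d-mer histogram: %d depth bins, %.3g species, %.3g instances\n",
              x$k, length(x$count), sum(x$count),
              sum(seq_along(x$count) * x$count)))
  invisible(x)
}

#' Count canonical k-mers in reads
#'
#' Counts every k-mer of the reads exactly, collapsing strands: a k-mer and
#' its reverse complement are the same species (the lexicographically
#' smaller string represents both).  K-mers containing non-ACGT characters
#' are skipped; reads shorter than k are skipped and counted in the
#' `short_reads` attribute.  Exact counting on in-memory strings -- intended
#' for desk-scale read sets, not production sequencing volumes.
#'
#' @param reads A FASTQ/FASTA file path, a `Biostrings::DNAStringSet`, or a
#'   character vector of read sequences.
#' @param k K-mer length (default 17).
#' @return A [kmer_hist()].
#' @export
kmer_histogram <- function(reads, k = 17) {
  stopifnot(k >= 1)
  if (is.character(reads) && length(reads) == 1L && file.exists(reads)) {
    fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", reads)) "fastq" else "fasta"
    reads <- Biostrings::readDNAStringSet(reads, format = fmt)
  }
  if (methods::is(reads, "XStringSet")) reads <- as.character(reads)
  if (!length(reads)) stop("no reads supplied")
  reads <- toupper(reads)
  n <- nchar(reads)
  short <- sum(n < k)
  reads <- reads[n >= k]
  n <- n[n >= k]
  if (!length(reads)) stop("all reads shorter than k")
  kmers <- unlist(lapply(seq_along(reads), function(i)
    substring(reads[i], 1:(n[i] - k + 1L), k:n[i])), use.names = FALSE)
  kmers <- kmers[!grepl("[^ACGT]", kmers)]
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  canon <- pmin(kmers, rc)
  species_depth <- table(canon)
  out <- kmer_hist(k, tabulate(as.integer(species_depth)))
  attr(out, "short_reads") <- short
  out
}

#' Locate error valley and diploid peaks in a k-mer histogram
#'
#' Smooths the species counts with a centred moving average (window 5) and
#' locates: the error valley (first local minimum after depth 1, separating
#' the sequencing-error pile-up from genomic k-mers), the homozygous peak
#' (global maximum of depth x smoothed count beyond the valley -- weighting
#' by depth keeps the taller half-depth heterozygous peak from capturing
#' it), and the heterozygous peak (the smoothed local maximum nearest half
#' the homozygous depth, searched within 25% of that half-depth).  A missing
#' heterozygous peak (no candidate local maximum in the band, or only
#' negligible ones) is reported as `NA` and downstream heterozygosity is 0.
#'
#' @param hist A [kmer_hist()].
#' @return A list `error_valley_depth`, `het_peak_depth` (possibly `NA`),
#'   `hom_peak_depth`.
#' @export
find_peaks <- function(hist) {
  stopifnot(inherits(hist, "kmer_hist"))
  cnt <- hist$count
  if (length(cnt) < 3 || sum(cnt) == 0) stop("histogram is degenerate")
  pad <- c(0, 0, cnt, 0, 0)
  s <- vapply(seq_along(cnt), function(d) mean(pad[d:(d + 4)]), numeric(1))
  n <- length(s)
  # error valley: first (weak) local minimum of the smoothed series after 1
  valley <- 0L
  for (d in 2:(n - 1L)) {
    if (s[d] <= s[d - 1L] && s[d] <= s[d + 1L]) { valley <- d; break }
    if (s[d] > s[d - 1L] && d == 2L) { valley <- 1L; break }  # no error mode
  }
  beyond <- seq_len(n) > valley
  if (!any(beyond & s > 0)) stop("no peak beyond the error valley")
  weighted <- seq_len(n) * s
  hom <- which.max(ifelse(beyond, weighted, -Inf))
  if (s[hom] <= 0) stop("no peak beyond the error valley")
  # candidate heterozygous peaks: interior local maxima near hom/2 (within
  # 25% of the homozygous depth) with non-negligible mass; jitter on the
  # shoulder of a unimodal histogram otherwise fakes a peak
  cand <- which(seq_len(n) > valley & seq_len(n) < hom &
                  s >= c(-Inf, s[-n]) & s >= c(s[-1], -Inf))
  cand <- cand[abs(cand - hom / 2) <= 0.25 * hom / 2 &
                 s[cand] >= 0.05 * s[hom]]
  het <- if (length(cand)) cand[which.min(abs(cand - hom / 2))] else NA_integer_
  list(error_valley_depth = valley, het_peak_depth = het,
       hom_peak_depth = hom)
}

#' Estimate genome size and heterozygosity from a k-mer histogram
#'
#' Two-component diploid estimate.  Genome size is the total k-mer instance
#' mass beyond the error valley divided by the homozygous peak depth.  The
#' fraction `f` of genomic species falling below the midpoint of the two
#' peaks (and above the valley) estimates the heterozygous share of
#' species; since a heterozygous k-mer locus contributes two species and a
#' homozygous one, `f = 2q / (1 + q)` where `q` is the per-k-mer
#' heterozygosity, so `q = f / (2 - f)` and the per-base rate is
#' `1 - (1 - q)^(1/k)`.  With no heterozygous peak, heterozygosity is 0.
#'
#' @param hist A [kmer_hist()].
#' @param peaks Result of [find_peaks()] (computed when omitted).
#' @return An object of class `genome_profile`: `genome_size`,
#'   `heterozygosity`, `het_peak_depth`, `hom_peak_depth`,
#'   `error_valley_depth`.
#' @export
estimate_genome <- function(hist, peaks = find_peaks(hist)) {
  stopifnot(inherits(hist, "kmer_hist"))
  valley <- peaks$error_valley_depth
  hom <- peaks$hom_peak_depth
  if (valley >= hom) stop("error valley at or beyond the homozygous peak")
  cnt <- hist$count
  d <- seq_along(cnt)
  genomic <- d > valley
  genome_size <- sum(d[genomic] * cnt[genomic]) / hom
  if (is.na(peaks$het_peak_depth)) {
    f <- 0
  } else {
    mid <- (peaks$het_peak_depth + hom) / 2
    f <- sum(cnt[genomic & d <= mid]) / sum(cnt[genomic])
  }
  q <- f / (2 - f)
  het <- 1 - (1 - q)^(1 / hist$k)
  structure(list(genome_size = genome_size, heterozygosity = het,
                 het_peak_depth = peaks$het_peak_depth,
                 hom_peak_depth = hom, error_valley_depth = valley),
            class = "genome_profile")
}

#' @export
print.genome_profile <- function(x, ...) {
  cat(sprintf(paste0("Genome profile: size %.3g bp, heterozygosity %.4f\n",
                     "  peaks: het %s x, hom %d x (valley %d)\n"),
              x$genome_size, x$heterozygosity,
              ifelse(is.na(x$het_peak_depth), "-", x$het_peak_depth),
              x$hom_peak_depth, x$error_valley_depth))
  invisible(x)
}

#' Read and write k-mer histogram TSV files
#'
#' Two-column tab-separated format (`depth`, `count`), compatible with
#' common k-mer counter dump formats.
#'
#' @param path File path.
#' @param k K-mer length to attach on read (not stored in the file).
#' @return [read_kmer_histogram()] returns a [kmer_hist()];
#'   [write_kmer_histogram()] returns `path` invisibly.
#' @export
read_kmer_histogram <- function(path, k = 17) {
  tab <- utils::read.delim(path, header = FALSE,
                           col.names = c("depth", "count"))
  cnt <- numeric(max(tab$depth))
  cnt[tab$depth] <- tab$count
  kmer_hist(k, cnt)
}

#' @rdname read_kmer_histogram
#' @param hist A [kmer_hist()] to write.
#' @export
write_kmer_histogram <- function(hist, path) {
  stopifnot(inherits(hist, "kmer_hist"))
  keep <- hist$count > 0
  utils::write.table(data.frame(depth = seq_along(hist$count)[keep],
                                count = hist$count[keep]),
                     path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
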