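# Build a genotype table from a plain call matrix (markers x individuals,
# mother first).  Optional pl: markers x individuals x 3 array.
make_table <- function(calls, pl = NULL, individuals = NULL) {
  M <- nrow(calls)
  if (is.null(individuals))
    individuals <- c("mother", sprintf("off%03d", seq_len(ncol(calls) - 1L)))
  markers <- data.frame(marker_id = sprintf("mk%03d", seq_len(M)),
                        scaffold = sprintf("scf%03d", seq_len(M)),
                        position = rep(100L, M))
  genotype_table(individuals, markers, calls, pl = pl)
}

# Marker set straight from a segregation matrix (rows = markers).
make_markers <- function(seg, class = "maternal", scaffold = NULL) {
  M <- nrow(seg)
  if (is.null(scaffold)) scaffold <- sprintf("scf%03d", seq_len(M))
  info <- data.frame(marker_id = sprintf("mk%03d", seq_len(M)),
                     scaffold = scaffold, position = rep(1L, M),
                     class = rep_len(class, M))
  marker_set(info, seg, sprintf("off%03d", seq_len(ncol(seg))))
}

# A random DNA string.
random_dna <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                       replace = TRUE), collapse = "")

# Mutate exactly k positions of a DNA string (always to a different base).
mutate_dna <- function(s, at) {
  v <- strsplit(s, "")[[1]]
  v[at] <- vapply(v[at], function(b)
    sample(setdiff(c("A", "C", "G", "T"), b), 1L), character(1))
  paste(v, collapse = "")
}

# Fabricated best-hit table from simulator truth: each scaffold hits the
# pseudochromosome matching its true chromosome at its true midpoint, except
# a noise fraction redirected to a random other pseudochromosome.
truth_hits <- function(scaffolds, noise = 0, seed = 1) {
  set.seed(seed)
  chrom <- paste0("C", scaffolds$chromosome)
  if (noise > 0) {
    flip <- runif(nrow(scaffolds)) < noise
    pool <- unique(chrom)
    chrom[flip] <- vapply(chrom[flip], function(cc)
      sample(setdiff(pool, cc), 1L), character(1))
  }
  data.frame(scaffold = scaffolds$scaffold, chromosome = chrom,
             position = (scaffolds$start + scaffolds$end) / 2,
             score = 100)
}

# Independent maximal monotone-run decomposition: extends each run point by
# point, testing strict monotonicity of the full slice each time.
runs_oracle <- function(y) {
  n <- length(y)
  out <- data.frame(start = integer(0), length = integer(0),
                    direction = character(0))
  strictly_mono <- function(z) {
    d <- diff(z)
    all(d > 0) || all(d < 0)
  }
  i <- 1L
  while (i <= n) {
    len <- 1L
    while (i + len <= n && strictly_mono(y[i:(i + len)])) len <- len + 1L
    dir <- if (len == 1L) "single"
    else if (y[i + 1L] > y[i]) "increasing" else "decreasing"
    out <- rbind(out, data.frame(start = i, length = len, direction = dir))
    i <- i + len
  }
  out
}
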