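# Independent brute-force oracles and small fixture builders shared across
# the suite. Oracles deliberately use the most naive correct algorithm.

# all 4^k k-mers, lexicographic
all_kmers <- function(k) {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(rev(rep(list(b), k)), stringsAsFactors = FALSE)
  sort(do.call(paste0, rev(g)))
}

hamming <- function(a, b)
  sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])

min_hamming <- function(x, members)
  min(vapply(members, function(m) hamming(x, m), 0))

# hypergeometric one-sided tail by direct summation over the support
hyper_tail_ge <- function(k_set, n_set, k_rest, n_rest) {
  K <- k_set + k_rest          # total successes
  N <- n_set + n_rest
  supp <- max(0, K - n_rest):min(K, n_set)
  pr <- choose(n_set, supp) * choose(n_rest, K - supp) / choose(N, K)
  sum(pr[supp >= k_set])
}

# exact one-sided Wilcoxon rank-sum p by enumeration of all assignments
ranksum_enum <- function(x, y, side = c("greater", "less")) {
  side <- match.arg(side)
  all <- c(x, y)
  r <- rank(all)
  obs <- sum(r[seq_along(x)])
  combos <- combn(length(all), length(x))
  stats <- apply(combos, 2, function(i) sum(r[i]))
  if (side == "greater") mean(stats >= obs) else mean(stats <= obs)
}

# naive windowed distinct-promoter counts: loop promoters x windows
windowed_counts_naive <- function(seqs, upstream, motif, w, p_lo, p_hi) {
  k <- nchar(motif)
  starts <- p_lo:p_hi
  vals <- integer(length(starts))
  for (s in seqs) {
    L <- nchar(s)
    occ <- integer(0)
    for (i in seq_len(L - k + 1))
      if (substr(s, i, i + k - 1) == motif) occ <- c(occ, i - upstream - 1)
    dmax <- L - upstream - 1
    for (j in seq_along(starts)) {
      p <- starts[j]
      if (p + w - 1 > dmax) next                 # promoter must cover window
      if (any(occ >= p & occ <= p + w - 1)) vals[j] <- vals[j] + 1L
    }
  }
  vals
}

# brute-force seeds: every closed neighbourhood checked against all pairs
seeds_naive <- function(counts, core_threshold = 200) {
  motifs <- names(counts)
  core <- counts >= core_threshold
  is_seed <- logical(length(motifs))
  for (i in seq_along(motifs)) {
    if (!core[i]) next
    ok <- TRUE
    for (j in seq_along(motifs)) {
      if (i == j) next
      if (hamming(motifs[i], motifs[j]) != 1) next
      if (!(core[i] || core[j])) next            # edge absent
      if (counts[j] >= counts[i]) { ok <- FALSE; break }
    }
    is_seed[i] <- ok
  }
  sort(motifs[is_seed])
}

# tiny promoter set from explicit sequences
mini_set <- function(seqs, upstream, ids = NULL) {
  if (is.null(ids)) ids <- sprintf("m%02d", seq_along(seqs))
  promoter_set(ids, seqs, upstream)
}

# background-free promoter: motif planted in a run of 'fill' bases
flat_promoter <- function(len, upstream, motif = NULL, at = NULL,
                          fill = "G") {
  s <- strrep(fill, len)
  if (!is.null(motif)) {
    i <- at + upstream + 1
    substr(s, i, i + nchar(motif) - 1) <- motif
  }
  s
}

# small scan config so background-free fixtures stay light
mini_config <- function(upstream = 120,
                        learn = c(-120, -60), search = c(-60, 40),
                        ...) {
  scan_config(learn = learn, search = search, ...)
}
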