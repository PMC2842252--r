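# Motif algebra: degenerate pattern expansion, Hamming rings, overlap pairs,
# shared cores. All patterns are exact strings over the IUPAC alphabet; no
# probabilistic motif models.

.IUPAC <- c(A = "A", C = "C", G = "G", T = "T",
            R = "AG", Y = "CT", S = "CG", W = "AT", K = "GT", M = "AC",
            B = "CGT", D = "AGT", H = "ACT", V = "ACG", N = "ACGT")

.pattern_sets <- function(pattern) {
  ch <- strsplit(toupper(pattern), "")[[1L]]
  bad <- !(ch %in% names(.IUPAC))
  if (any(bad))
    stop("unsupported IUPAC code(s) in pattern '", pattern, "': ",
         paste(unique(ch[bad]), collapse = ", "))
  lapply(.IUPAC[ch], function(s) strsplit(s, "")[[1L]])
}

#' Expand a degenerate IUPAC pattern into concrete motifs
#'
#' The expansion is the Cartesian product of the per-position code sets, in
#' lexicographic order; a fully concrete pattern expands to itself.
#'
#' @param pattern A string over IUPAC nucleotide codes (e.g. `"TATAWA"`).
#' @return Character vector of concrete DNA motifs, sorted.
#' @examples
#' expand_pattern("TATAWA")  # TATAAA, TATATA
#' expand_pattern("YR")      # the four initiator dinucleotides
#' @export
expand_pattern <- function(pattern) {
  sets <- .pattern_sets(pattern)
  grid <- expand.grid(rev(sets), stringsAsFactors = FALSE)
  out <- do.call(paste0, rev(grid))
  sort(out)
}

.str_mat <- function(x) {
  # rows = strings, cols = positions
  matrix(unlist(strsplit(x, ""), use.names = FALSE),
         nrow = length(x), byrow = TRUE)
}

.min_dist_to <- function(x, members) {
  # minimum Hamming distance from each string in x to the member set
  xm <- .str_mat(x)
  d <- matrix(Inf, length(x), length(members))
  mm <- .str_mat(members)
  for (j in seq_along(members))
    d[, j] <- rowSums(xm != matrix(mm[j, ], nrow(xm), ncol(xm), byrow = TRUE))
  apply(d, 1L, min)
}

#' Concrete motifs at an exact minimum Hamming distance from a pattern
#'
#' Returns every concrete k-mer whose minimum Hamming distance to any member
#' of `expand_pattern(pattern)` is exactly `d`. Rings over `d = 0..k`
#' partition the 4^k k-mer space; the distance-0 ring is the expansion
#' itself. For the canonical TATA-box pattern `TATAWA` the distance-1 ring
#' has 32 members.
#'
#' @param pattern IUPAC pattern of length k.
#' @param d Integer distance, `0 <= d <= k`.
#' @return Sorted character vector of concrete k-mers.
#' @export
hamming_ring <- function(pattern, d) {
  sets <- .pattern_sets(pattern)
  k <- length(sets)
  d <- as.integer(d)
  if (is.na(d) || d < 0L || d > k)
    stop("'d' must be between 0 and the pattern length (", k, ")")
  members <- expand_pattern(pattern)
  if (d == 0L) return(members)
  bases <- c("A", "C", "G", "T")
  cand <- character(0)
  pos_sets <- utils::combn(k, d, simplify = FALSE)
  for (m in members) {
    mch <- strsplit(m, "")[[1L]]
    for (ps in pos_sets) {
      alts <- lapply(ps, function(i) setdiff(bases, mch[i]))
      grid <- expand.grid(alts, stringsAsFactors = FALSE)
      for (r in seq_len(nrow(grid))) {
        v <- mch
        v[ps] <- unlist(grid[r, ], use.names = FALSE)
        cand <- c(cand, paste(v, collapse = ""))
      }
    }
  }
  cand <- unique(cand)
  sort(cand[.min_dist_to(cand, members) == d])
}

#' Ordered suffix/prefix overlap pairs among equal-length motifs
#'
#' Pair `(A, B)` is reported when the last `overlap` bases of `A` equal the
#' first `overlap` bases of `B`; self-pairs (e.g. homopolymers, or the
#' self-overlapping TC trinucleotide repeats) are included.
#'
#' @param motifs Character vector of k-mers, all the same length.
#' @param overlap Overlap length, `1 <= overlap < k`; default `k - 1`
#'   (consecutive-base overlap of hexamers as used for the TC-element trio).
#' @return A data.frame with columns `from`, `to`.
#' @export
overlap_pairs <- function(motifs, overlap = NULL) {
  motifs <- unique(as.character(motifs))
  if (!length(motifs)) return(data.frame(from = character(), to = character()))
  k <- unique(nchar(motifs))
  if (length(k) != 1L) stop("motifs must all have the same length")
  if (is.null(overlap)) overlap <- k - 1L
  overlap <- as.integer(overlap)
  if (overlap < 1L || overlap >= k) stop("'overlap' must be in [1, k-1]")
  suf <- substring(motifs, k - overlap + 1L, k)
  pre <- substring(motifs, 1L, overlap)
  hits <- which(outer(suf, pre, "=="), arr.ind = TRUE)
  out <- data.frame(from = motifs[hits[, 1L]], to = motifs[hits[, 2L]],
                    stringsAsFactors = FALSE)
  out <- out[order(out$from, out$to), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Count motifs containing each length-`core_len` substring
#'
#' For every substring of length `core_len` present in at least one motif,
#' the number of distinct motifs containing it. Used to identify shared
#' core trinucleotides (e.g. CTC/TCT/CTT within the TC-elements).
#'
#' @param motifs Character vector of k-mers.
#' @param core_len Core length (default 3).
#' @return Named integer vector (cores as names), sorted by decreasing count
#'   then name.
#' @export
substring_cores <- function(motifs, core_len = 3) {
  motifs <- unique(as.character(motifs))
  core_len <- as.integer(core_len)
  if (!length(motifs)) return(structure(integer(0), names = character(0)))
  if (any(nchar(motifs) < core_len)) stop("'core_len' exceeds a motif length")
  per <- lapply(motifs, function(m) {
    st <- seq_len(nchar(m) - core_len + 1L)
    unique(substring(m, st, st + core_len - 1L))
  })
  tab <- table(unlist(per, use.names = FALSE))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(-out, names(out))]
}
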