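# Distance profiles between [-39,-26]-class PLM matches and downstream
# initiator (YR) dinucleotides.

#' First-base distances from a PLM match to a downstream dinucleotide
#'
#' Distances are counted first base to first base: a distance of 8 between
#' `TATAAA` and `CA` corresponds to the sequence `TATAAANNCA`. Distances
#' smaller than the PLM length (dinucleotide overlapping the PLM match) are
#' included, as the definition is purely positional.
#'
#' @param sequence A DNA string.
#' @param plm_start 1-based index of the PLM match in `sequence` (an error
#'   if the PLM is not there).
#' @param plm The PLM motif.
#' @param dinucleotide A 2-mer.
#' @param max_distance Maximal distance reported (default 70).
#' @return Integer vector of distances in `[1, max_distance]`.
#' @examples
#' first_base_distances("TATAAAGGCA", 1, "TATAAA", "CA")  # 8
#' @export
first_base_distances <- function(sequence, plm_start, plm, dinucleotide,
                                 max_distance = 70) {
  sequence <- toupper(sequence); plm <- toupper(plm)
  dinucleotide <- toupper(dinucleotide)
  plm_start <- as.integer(plm_start)
  if (substr(sequence, plm_start, plm_start + nchar(plm) - 1L) != plm)
    stop("'", plm, "' does not occur at index ", plm_start)
  d <- seq_len(min(max_distance,
                   nchar(sequence) - plm_start - nchar(dinucleotide) + 1L))
  if (!length(d)) return(integer(0))
  at <- plm_start + d
  d[substring(sequence, at, at + 1L) == dinucleotide]
}

#' Distance profile between a PLM class and the YR dinucleotides
#'
#' For every promoter and every match of a record's motif with its first
#' base inside the record's functional window, counts the dinucleotide
#' occurrences at each first-base-to-first-base distance `1..max_distance`
#' downstream. Every (promoter, match, distance) triple contributes one
#' count; with `per_promoter = TRUE` each (promoter, distance) pair counts
#' once per dinucleotide regardless of the number of matches.
#'
#' @param set A `promoter_set`.
#' @param records A `plm_record` or list of records of one PLM class,
#'   computed on `set`.
#' @param dinucleotides 2-mers to profile (default the YR set CA, TA, TG,
#'   CG).
#' @param max_distance Maximal distance (default 70).
#' @param per_promoter Count promoters rather than occurrences.
#' @param class_label Label stored in the output (default the first
#'   record's motif).
#' @return An object of class `distance_profile`: a data.frame `class`,
#'   `dinucleotide`, `distance`, `count` covering every distance
#'   `1..max_distance`.
#' @export
distance_profile <- function(set, records,
                             dinucleotides = c("CA", "TA", "TG", "CG"),
                             max_distance = 70, per_promoter = FALSE,
                             class_label = NULL) {
  stopifnot(inherits(set, "promoter_set"))
  if (inherits(records, "plm_record")) records <- list(records)
  if (!length(records)) stop("no records supplied")
  if (is.null(class_label))
    class_label <- if (length(records) == 1L) records[[1L]]$motif else "class"
  dinucleotides <- toupper(dinucleotides)

  # PLM matches inside their functional windows: (prom, pos)
  mp <- ms <- integer(0)
  for (r in records) {
    occ <- .occ(set, r$motif)
    keep <- occ$pos >= r$functional_window[1] &
      occ$pos <= r$functional_window[2]
    mp <- c(mp, occ$prom[keep]); ms <- c(ms, occ$pos[keep])
  }
  out <- list()
  for (dn in dinucleotides) {
    docc <- .occ(set, dn)
    counts <- integer(max_distance)
    if (length(mp) && length(docc$prom)) {
      dsp <- split(docc$pos, docc$prom)
      hits_p <- integer(0); hits_d <- integer(0)
      for (j in seq_along(mp)) {
        dp <- dsp[[as.character(mp[j])]]
        if (is.null(dp)) next
        dd <- dp - ms[j]
        dd <- dd[dd >= 1L & dd <= max_distance]
        if (length(dd)) {
          hits_p <- c(hits_p, rep.int(mp[j], length(dd)))
          hits_d <- c(hits_d, dd)
        }
      }
      if (per_promoter && length(hits_d)) {
        u <- !duplicated(paste(hits_p, hits_d))
        hits_d <- hits_d[u]
      }
      if (length(hits_d)) counts <- tabulate(hits_d, max_distance)
    }
    out[[dn]] <- data.frame(class = class_label, dinucleotide = dn,
                            distance = seq_len(max_distance),
                            count = counts, stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  structure(res, class = c("distance_profile", "data.frame"),
            max_distance = max_distance)
}

#' Plot a distance profile
#'
#' One line per dinucleotide (CA red, TG orange, TA blue, CG green, others
#' grey), count against first-base-to-first-base distance.
#'
#' @param x A `distance_profile`.
#' @param ... Passed to [matplot()].
#' @return Invisibly, `x`.
#' @export
plot.distance_profile <- function(x, ...) {
  dns <- unique(x$dinucleotide)
  wide <- sapply(dns, function(dn) x$count[x$dinucleotide == dn])
  cols <- c(CA = "red3", TG = "orange2", TA = "blue3", CG = "green4")
  col <- ifelse(dns %in% names(cols), cols[dns], "grey50")
  matplot(seq_len(attr(x, "max_distance")), wide, type = "l", lty = 1,
          col = col, xlab = "distance (bases)", ylab = "count",
          main = unique(x$class)[1L], ...)
  legend("topright", legend = dns, col = col, lty = 1, bty = "n")
  invisible(x)
}
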