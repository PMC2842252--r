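# Greedy one-base extension of a PLM under the SMS-improvement rule.

# evaluate a motif at a fixed window size; returns a plm_record-like list
# or NULL (not a PLM at this window size)
.eval_at_w <- function(set, motif, w, config) {
  occ <- .occ(set, motif)
  occ$motif <- toupper(motif)
  dmax <- set$downstream - 1L
  wc <- .windowed_counts(occ, dmax, w, config$learn[1], config$search[2])
  dist <- structure(list(motif = occ$motif, window_size = w,
                         starts = wc$starts, values = wc$values,
                         coverage = wc$coverage, k = occ$k,
                         n_promoters = length(set),
                         learn = config$learn, search = config$search),
                    class = "plm_dist")
  model <- tryCatch(fit_background(dist, config), error = function(e) NULL)
  if (is.null(model)) return(NULL)
  i <- .peak_index(dist, config)
  if (is.na(i)) return(NULL)
  p_star <- dist$starts[i]
  base <- predict(model, p_star, "baseline")
  upper <- predict(model, p_star, "upper")
  if (upper - base <= 0) return(NULL)
  sms <- (dist$values[i] - base) / (upper - base)
  if (!(dist$values[i] > upper) || !(sms > config$sms_min)) return(NULL)
  # refined preferential position inside the above-bound run
  in_search <- dist$starts >= config$search[1] &
    dist$starts <= config$search[2] & dist$coverage > 0L
  sidx <- which(in_search)
  above <- dist$values[sidx] > predict(model, dist$starts[sidx], "upper")
  j <- which(sidx == i)
  lo <- j; hi <- j
  while (lo > 1L && above[lo - 1L] && sidx[lo - 1L] == sidx[lo] - 1L) lo <- lo - 1L
  while (hi < length(sidx) && above[hi + 1L] && sidx[hi + 1L] == sidx[hi] + 1L) hi <- hi + 1L
  fw <- c(dist$starts[sidx[lo]], dist$starts[sidx[hi]] + w - 1L)
  in_peak <- occ$pos >= p_star & occ$pos <= p_star + w - 1L
  if (!any(in_peak)) return(NULL)
  tab <- table(occ$pos[in_peak])
  pref <- as.integer(names(tab))[max(which(tab == max(tab)))]
  inside <- occ$pos >= fw[1] & occ$pos <= fw[2]
  if (!any(inside)) return(NULL)
  list(motif = occ$motif, window_size = w, preferential_position = pref,
       functional_window = fw, sms = sms,
       n_promoters = length(unique(occ$prom[inside])))
}

#' Greedy one-base extension of a PLM
#'
#' Starting from a detected PLM, evaluates at each round the 8 motifs
#' obtained by adding one base (4 bases, upstream or downstream). A
#' candidate qualifies when it is itself a PLM with a preferential position
#' inside `config$target` and an SMS at least `factor` times the current
#' motif's SMS; the highest-SMS qualifying candidate (ties broken
#' lexicographically) is accepted and the round repeats, stopping when no
#' candidate qualifies. SMS values along the chain are all evaluated at the
#' starting PLM's sliding-window size, so that scores of motifs of different
#' lengths are compared on one distribution scale (see vignette).
#'
#' @param set A `promoter_set`.
#' @param start A concrete motif already detected as a PLM in `set`
#'   (otherwise an error).
#' @param config A [scan_config()].
#' @param factor Required SMS improvement per accepted step (default 1.1).
#' @return An object of class `plm_extension`: `chain` (data.frame motif /
#'   length / sms / position per accepted element, starting motif first),
#'   `final` motif, and the window size used.
#' @export
extend_plm <- function(set, start, config = scan_config(), factor = 1.1) {
  stopifnot(inherits(set, "promoter_set"))
  if (length(set) == 0L) stop("empty promoter set")
  start <- toupper(start)
  rec0 <- detect_plm(set, start, config)
  if (is.null(rec0))
    stop("'", start, "' is not a PLM in this promoter set")
  w <- rec0$window_size
  cur <- .eval_at_w(set, start, w, config)
  if (is.null(cur))
    stop("'", start, "' is not a PLM at its detected window size")
  chain <- list(cur)
  bases <- c("A", "C", "G", "T")
  repeat {
    cand_motifs <- c(paste0(bases, cur$motif), paste0(cur$motif, bases))
    best <- NULL
    for (m in sort(cand_motifs)) {
      ev <- .eval_at_w(set, m, w, config)
      if (is.null(ev)) next
      if (ev$preferential_position < config$target[1] ||
          ev$preferential_position > config$target[2]) next
      if (ev$sms < factor * cur$sms) next
      if (is.null(best) || ev$sms > best$sms) best <- ev
    }
    if (is.null(best)) break
    chain[[length(chain) + 1L]] <- best
    cur <- best
  }
  df <- data.frame(
    motif = vapply(chain, `[[`, "", "motif"),
    length = vapply(chain, function(x) nchar(x$motif), 0L),
    sms = vapply(chain, `[[`, 0, "sms"),
    position = vapply(chain, `[[`, 0L, "preferential_position"),
    n_promoters = vapply(chain, `[[`, 0L, "n_promoters"),
    stringsAsFactors = FALSE)
  structure(list(start = start, chain = df, final = cur$motif,
                 window_size = w, factor = factor),
            class = "plm_extension")
}

#' @export
print.plm_extension <- function(x, ...) {
  cat(sprintf("PLM extension from %s (window %d, factor %.2f):\n",
              x$start, x$window_size, x$factor))
  print(x$chain, row.names = FALSE)
  cat("final motif:", x$final, "\n")
  invisible(x)
}
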