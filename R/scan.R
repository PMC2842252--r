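# The PLM detector: positional counting in a sliding window, background
# regression over the distal learning region, family-wise upper prediction
# bound, adaptive window escalation, peak/functional-window detection and
# SMS scoring.

#' Scan configuration for PLM detection
#'
#' @param learn Closed position interval used to learn the background model
#'   (default `c(-1000, -300)`); must be fully upstream of the TSS.
#' @param search Closed position interval searched for peaks (default
#'   `c(-300, 500)`).
#' @param ci_level Confidence level of the upper bound (default 0.99). The
#'   bound is family-wise over the searched windows: a peak is called only
#'   when it exceeds what the maximum of the background windows would reach
#'   at this level (see the package vignette).
#' @param max_window Maximal sliding-window size (default 100).
#' @param sms_min Minimal SMS for a PLM; peaks with SMS `<= sms_min` are
#'   rejected (default 1, i.e. the peak must clear the upper bound).
#' @param target Closed interval of the TATA-like topological constraint
#'   (default `c(-39, -26)`), used by the cascade and extension steps.
#' @return An object of class `scan_config`.
#' @export
scan_config <- function(learn = c(-1000, -300), search = c(-300, 500),
                        ci_level = 0.99, max_window = 100, sms_min = 1,
                        target = c(-39, -26)) {
  learn <- as.integer(learn); search <- as.integer(search)
  stopifnot(length(learn) == 2L, length(search) == 2L,
            learn[1] < learn[2], search[1] < search[2])
  if (learn[2] > search[1])
    stop("learn and search regions may share at most their boundary")
  if (learn[2] >= 0L) stop("the learning region must lie upstream of the TSS")
  if (!(ci_level > 0 && ci_level < 1)) stop("'ci_level' must be in (0, 1)")
  if (max_window < 1L) stop("'max_window' must be >= 1")
  structure(list(learn = learn, search = search, ci_level = ci_level,
                 max_window = as.integer(max_window), sms_min = sms_min,
                 target = as.integer(target)),
            class = "scan_config")
}

#' @export
print.scan_config <- function(x, ...) {
  cat(sprintf(
    "scan_config: learn [%d, %d], search [%d, %d], ci %.3g, max window %d, SMS > %g, target [%d, %d]\n",
    x$learn[1], x$learn[2], x$search[1], x$search[2], x$ci_level,
    x$max_window, x$sms_min, x$target[1], x$target[2]))
  invisible(x)
}

# ---------------------------------------------------------------------------
# occurrence extraction

#' All occurrences of a motif (or degenerate pattern) in a promoter set
#'
#' Overlapping occurrences are reported; `N` bases never match. Degenerate
#' patterns are expanded and a promoter position matches when any expansion
#' motif starts there.
#'
#' @param set A `promoter_set`.
#' @param motif Concrete motif or IUPAC pattern.
#' @return data.frame with columns `promoter` (index into the set), `id`,
#'   `position` (TSS-relative first-base position).
#' @export
motif_occurrences <- function(set, motif) {
  stopifnot(inherits(set, "promoter_set"))
  occ <- .occ(set, motif)
  data.frame(promoter = occ$prom, id = set$ids[occ$prom], position = occ$pos,
             stringsAsFactors = FALSE)
}

# internal: list(prom = integer index, pos = TSS-relative first-base)
.occ <- function(set, motif) {
  members <- expand_pattern(motif)
  subj <- Biostrings::DNAStringSet(set$seq)
  prom <- integer(0); pos <- integer(0)
  for (m in members) {
    mi <- Biostrings::vmatchPattern(m, subj, fixed = TRUE)
    st <- Biostrings::startIndex(mi)
    nhit <- lengths(st)
    if (sum(nhit) == 0L) next
    prom <- c(prom, rep.int(seq_along(st), nhit))
    pos <- c(pos, unlist(st, use.names = FALSE) - set$upstream - 1L)
  }
  o <- order(prom, pos)
  list(prom = prom[o], pos = pos[o], k = nchar(members[1L]))
}

# ---------------------------------------------------------------------------
# windowed distinct-promoter counts

# occ: list(prom, pos); dmax: most downstream position per promoter
# (downstream - 1), indexed like occ$prom. Returns values/coverage over
# window starts p_lo..p_hi. A promoter is counted in window [p, p+w-1] when
# it covers the window (dmax >= p+w-1) and has an occurrence first base in
# it; multiple occurrences in one window count once.
.windowed_counts <- function(occ, dmax, w, p_lo, p_hi) {
  starts <- p_lo:p_hi
  np <- length(starts)
  values <- integer(np)
  if (length(occ$prom)) {
    cap <- pmin(p_hi, dmax[occ$prom] - w + 1L)   # last window start reachable
    keep <- occ$pos >= p_lo & occ$pos <= cap + w - 1L
    prom <- occ$prom[keep]; q <- occ$pos[keep]; cap <- cap[keep]
    if (length(prom)) {
      a <- pmax(q - w + 1L, p_lo)
      b <- pmin(q, cap)
      ok <- b >= a
      prom <- prom[ok]; a <- a[ok]; b <- b[ok]
      if (length(prom)) {
        # merge per-promoter intervals (inputs sorted by prom, pos; a and b
        # are then non-decreasing within a promoter)
        new_grp <- c(TRUE, prom[-1L] != prom[-length(prom)] |
                       a[-1L] > b[-length(b)] + 1L)
        A <- a[new_grp]
        # b is non-decreasing within a promoter, so each merged interval
        # ends at the last b of its group
        last <- c(which(new_grp)[-1L] - 1L, length(b))
        B <- b[last]
        ia <- A - p_lo + 1L
        ib <- B - p_lo + 2L
        d <- tabulate(ia, np + 1L) - tabulate(ib, np + 1L)
        values <- cumsum(d[-(np + 1L)])
      }
    }
  }
  dm <- sort(dmax)
  # coverage[p] = #promoters with dmax >= p + w - 1
  coverage <- length(dm) - findInterval(starts + w - 1L - 1L + 0.5, dm)
  list(starts = starts, values = as.integer(values),
       coverage = as.integer(coverage))
}

#' Positional distribution of a motif at one window size
#'
#' Counts, for every window start position over the union of the learning
#' and search regions, the number of distinct promoters with a motif
#' first-base inside the window `[p, p + window_size - 1]` (a promoter with
#' several occurrences in one window counts once), together with the number
#' of promoters whose sequence fully covers the window.
#'
#' @param set A `promoter_set`.
#' @param motif Concrete motif or IUPAC pattern.
#' @param window_size Sliding-window size in bases (shift is always 1).
#' @param config A [scan_config()].
#' @return An object of class `plm_dist` with fields `motif`, `window_size`,
#'   `starts`, `values`, `coverage`.
#' @export
positional_counts <- function(set, motif, window_size = 1,
                              config = scan_config()) {
  stopifnot(inherits(set, "promoter_set"))
  w <- as.integer(window_size)
  if (w < 1L) stop("'window_size' must be >= 1")
  if (set$upstream < -config$learn[1])
    stop("promoters do not cover the learning region (upstream ",
         set$upstream, " < ", -config$learn[1], ")")
  occ <- .occ(set, motif)
  if (occ$k > min(nchar(set$seq)))
    stop("motif longer than the shortest promoter")
  wc <- .windowed_counts(occ, set$downstream - 1L, w,
                         config$learn[1], config$search[2])
  structure(list(motif = toupper(motif), window_size = w, starts = wc$starts,
                 values = wc$values, coverage = wc$coverage,
                 k = occ$k, n_promoters = length(set),
                 learn = config$learn, search = config$search),
            class = "plm_dist")
}

#' @export
print.plm_dist <- function(x, ...) {
  cat(sprintf("plm_dist: %s, window %d, %d window starts [%d, %d], peak count %d\n",
              x$motif, x$window_size, length(x$starts), min(x$starts),
              max(x$starts), max(x$values)))
  invisible(x)
}

# ---------------------------------------------------------------------------
# background model

#' Fit the background model of a positional distribution
#'
#' Ordinary least squares of the window counts on the window start position
#' over the learning region, plus an upper prediction bound at
#' `config$ci_level`, taken family-wise over the number of searched windows
#' so that a "peak above the bound" is a single statement about the whole
#' scan rather than one window (see vignette).
#'
#' @param dist A `plm_dist`.
#' @param config A [scan_config()].
#' @return An object of class `plm_background` with `coef()` (intercept,
#'   slope) and `predict()` methods.
#' @export
fit_background <- function(dist, config = scan_config()) {
  stopifnot(inherits(dist, "plm_dist"))
  in_learn <- dist$starts >= config$learn[1] & dist$starts <= config$learn[2]
  p <- dist$starts[in_learn]
  y <- dist$values[in_learn]
  if (length(p) < 10L)
    stop("learning region holds fewer than 10 windows")
  if (length(unique(p)) < 2L)
    stop("degenerate learning region: fewer than 2 distinct positions")
  n <- length(p)
  pbar <- mean(p); ybar <- mean(y)
  sxx <- sum((p - pbar)^2)
  slope <- sum((p - pbar) * (y - ybar)) / sxx
  intercept <- ybar - slope * pbar
  res <- y - (intercept + slope * p)
  s <- sqrt(sum(res^2) / (n - 2L))
  m <- config$search[2] - config$search[1] + 1L  # searched windows
  z <- qnorm(1 - (1 - config$ci_level) / m)
  # window counts are right-skewed (Poisson-like); a plain normal quantile
  # under-covers the far tail, so the bound carries a Cornish-Fisher
  # third-moment correction from the residual skewness (clamped at 0: a
  # left skew never tightens the upper bound below the normal one)
  gamma <- if (s > 0) max(0, mean(res^3) / s^3) else 0
  structure(list(intercept = intercept, slope = slope, residual_scale = s,
                 z = z, gamma = gamma, n_learn = n, p_mean = pbar, sxx = sxx,
                 ci_level = config$ci_level, m = m),
            class = "plm_background")
}

#' @export
coef.plm_background <- function(object, ...)
  c(intercept = object$intercept, slope = object$slope)

#' Baseline and upper bound of a fitted background model
#'
#' @param object A `plm_background`.
#' @param positions Window start positions to evaluate at.
#' @param what `"baseline"` for the fitted base line, `"upper"` for the
#'   upper prediction bound.
#' @param ... Unused.
#' @return Numeric vector.
#' @export
predict.plm_background <- function(object, positions,
                                   what = c("baseline", "upper"), ...) {
  what <- match.arg(what)
  base <- object$intercept + object$slope * positions
  if (what == "baseline") return(base)
  pf <- sqrt(1 + 1 / object$n_learn +
               (positions - object$p_mean)^2 / object$sxx)
  g <- object$gamma %||% 0
  zc <- object$z + g * (object$z^2 - 1) / 6
  base + zc * object$residual_scale * pf
}

#' @export
print.plm_background <- function(x, ...) {
  cat(sprintf(
    "plm_background: baseline %.3f %+.3g * p, residual scale %.3f, z %.2f (ci %.3g over %d windows)\n",
    x$intercept, x$slope, x$residual_scale, x$z, x$ci_level, x$m))
  invisible(x)
}

# internal: peak index within the search region (ties -> most downstream)
.peak_index <- function(dist, config) {
  ok <- dist$starts >= config$search[1] & dist$starts <= config$search[2] &
    dist$coverage > 0L
  if (!any(ok)) return(NA_integer_)
  idx <- which(ok)
  v <- dist$values[idx]
  idx[max(which(v == max(v)))]
}

#' Score of Maximal Square of a positional distribution
#'
#' The SMS is evaluated at the search-region maximum p*:
#' `(count(p*) - baseline(p*)) / (bound(p*) - baseline(p*))`. A PLM requires
#' SMS strictly greater than `config$sms_min`. With a flat noiseless
#' background the bound equals the base line and the score is undefined; a
#' condition of class `plm_zero_denominator` is signalled and callers treat
#' the motif as a non-PLM.
#'
#' @param dist A `plm_dist`.
#' @param model A `plm_background` fitted on `dist`.
#' @param config A [scan_config()].
#' @return The SMS (a single number).
#' @export
compute_sms <- function(dist, model, config = scan_config()) {
  i <- .peak_index(dist, config)
  if (is.na(i)) stop("search region is empty (no covered window)")
  p <- dist$starts[i]
  base <- predict(model, p, "baseline")
  upper <- predict(model, p, "upper")
  if (upper - base <= 0)
    stop(structure(class = c("plm_zero_denominator", "error", "condition"),
                   list(message = "upper bound equals the base line (flat noiseless background); SMS undefined",
                        call = sys.call(-1))))
  (dist$values[i] - base) / (upper - base)
}

# ---------------------------------------------------------------------------
# detection

# minimal window size at which no learning-region window has a zero count,
# given the pooled occurrence positions (any promoter). Inf when the
# learning region cannot be made zero-free by any window size.
.min_zerofree_w <- function(pos, learn) {
  qs <- sort(unique(pos[pos >= learn[1]]))
  if (!length(qs)) return(Inf)
  # window [p, p+w-1] must contain an occurrence for every p in the learn
  # region; the binding starts are learn[1] and each q_i + 1 (q_i < learn[2])
  cand_p <- unique(c(learn[1], qs[qs < learn[2]] + 1L, learn[2]))
  cand_p <- cand_p[cand_p >= learn[1] & cand_p <= learn[2]]
  nxt <- qs[findInterval(cand_p - 0.5, qs) + 1L]
  if (anyNA(nxt)) return(Inf)
  max(nxt - cand_p + 1L)
}

# core detector working from an occurrence list; ids/dmax are parallel to
# the promoter indices used in occ$prom.
.plm_core <- function(occ, dmax, ids, config) {
  learn <- config$learn; search <- config$search
  p_lo <- learn[1]; p_hi <- search[2]
  w0 <- .min_zerofree_w(occ$pos, learn)
  if (!is.finite(w0) && !length(occ$pos)) return(NULL)
  w <- as.integer(min(max(w0, 1), config$max_window))
  repeat {
    wc <- .windowed_counts(occ, dmax, w, p_lo, p_hi)
    dist <- structure(list(motif = occ$motif %||% NA_character_,
                           window_size = w, starts = wc$starts,
                           values = wc$values, coverage = wc$coverage,
                           k = occ$k, n_promoters = length(ids),
                           learn = learn, search = search),
                      class = "plm_dist")
    model <- tryCatch(fit_background(dist, config), error = function(e) e)
    if (inherits(model, "error")) return(NULL)
    in_learn <- dist$starts >= learn[1] & dist$starts <= learn[2]
    lp <- dist$starts[in_learn]
    upper_l <- predict(model, lp, "upper")
    zero_trig <- any(dist$values[in_learn] == 0L)
    peak_trig <- any(dist$values[in_learn] > upper_l)
    if ((zero_trig || peak_trig) && w < config$max_window) {
      w <- w + 1L
      next
    }
    break
  }
  i <- .peak_index(dist, config)
  if (is.na(i)) return(NULL)
  p_star <- dist$starts[i]
  base <- predict(model, p_star, "baseline")
  upper <- predict(model, p_star, "upper")
  if (upper - base <= 0) return(NULL)
  sms <- (dist$values[i] - base) / (upper - base)
  if (!(dist$values[i] > upper) || !(sms > config$sms_min)) return(NULL)

  # functional window: maximal contiguous above-bound run containing p*
  in_search <- dist$starts >= search[1] & dist$starts <= search[2] &
    dist$coverage > 0L
  sidx <- which(in_search)
  above <- dist$values[sidx] >
    predict(model, dist$starts[sidx], "upper")
  pos_in_run <- which(sidx == i)
  lo <- pos_in_run; hi <- pos_in_run
  while (lo > 1L && above[lo - 1L] && sidx[lo - 1L] == sidx[lo] - 1L) lo <- lo - 1L
  while (hi < length(sidx) && above[hi + 1L] && sidx[hi + 1L] == sidx[hi] + 1L) hi <- hi + 1L
  fw <- c(dist$starts[sidx[lo]], dist$starts[sidx[hi]] + w - 1L)

  # refined preferential position: width-1 counts inside the maximal
  # window itself (a point source then localises exactly at any window
  # size, and distant secondary structure in a merged run cannot pull the
  # reported position away from the peak top)
  in_peak <- occ$pos >= p_star & occ$pos <= p_star + w - 1L
  tab <- table(occ$pos[in_peak])
  ppos <- as.integer(names(tab))
  pref <- ppos[max(which(tab == max(tab)))]

  inside <- occ$pos >= fw[1] & occ$pos <= fw[2]
  prom_in <- unique(occ$prom[inside])
  structure(list(motif = occ$motif %||% NA_character_, window_size = w,
                 preferential_position = pref, functional_window = fw,
                 sms = sms, promoter_ids = ids[prom_in],
                 n_promoters = length(prom_in),
                 peak_count = dist$values[i], baseline = base, upper = upper,
                 distribution = dist, model = model),
            class = "plm_record")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Detect whether a motif is a preferentially located motif (PLM)
#'
#' Runs the full detector: the sliding-window size starts at the smallest
#' value for which no learning-region window has a zero count (the zero
#' trigger is monotone in the window size, so this equals stepping the
#' window up from 1) and is increased further while the learning region
#' itself shows a window above the upper bound, up to `config$max_window`
#' (the largest window's result is then used). On the stable fit the
#' search-region maximum is located (ties broken toward the most downstream
#' window start); a PLM is returned when the maximum strictly exceeds the
#' upper bound and the SMS exceeds `config$sms_min`. The functional window
#' is the maximal contiguous above-bound run containing the maximum,
#' reported in base positions `[first start, last start + w - 1]`, and the
#' preferential position is refined by re-examining width-1 counts inside
#' the run, which localises a point source exactly at any window size.
#'
#' @param set A `promoter_set`.
#' @param motif Concrete motif or IUPAC pattern (a pattern counts a promoter
#'   when any expansion motif starts in the window).
#' @param config A [scan_config()].
#' @return A `plm_record` (motif, window size, preferential position,
#'   functional window, SMS, promoter ids) or `NULL` when the motif is not
#'   preferentially located.
#' @examples
#' sim <- sim_promoters(200, plantings = list(planting("TATAAA", -32, 0.3)),
#'                      seed = 1)
#' detect_plm(sim$set, "TATAAA")
#' @export
detect_plm <- function(set, motif, config = scan_config()) {
  stopifnot(inherits(set, "promoter_set"))
  if (set$upstream < -config$learn[1])
    stop("promoters do not cover the learning region")
  occ <- .occ(set, motif)
  occ$motif <- toupper(motif)
  rec <- tryCatch(.plm_core(occ, set$downstream - 1L, set$ids, config),
                  plm_zero_denominator = function(e) NULL)
  rec
}

#' @export
print.plm_record <- function(x, ...) {
  cat(sprintf("PLM %s: position %d, functional window [%d, %d], window size %d\n",
              x$motif, x$preferential_position, x$functional_window[1],
              x$functional_window[2], x$window_size))
  cat(sprintf("  SMS %.2f (peak %d, baseline %.2f, upper bound %.2f); %d promoters\n",
              x$sms, x$peak_count, x$baseline, x$upper, x$n_promoters))
  invisible(x)
}

#' Plot a positional distribution with its background model
#'
#' Counts per window start, the fitted base line (solid) and the upper
#' confidence bound (dashed).
#'
#' @param x A `plm_dist` or `plm_record`.
#' @param model Optional `plm_background` (fitted on the fly if missing and
#'   `x` is a `plm_dist`).
#' @param config A [scan_config()].
#' @param ... Passed to [plot()].
#' @return Invisibly, `x`.
#' @export
plot.plm_dist <- function(x, model = NULL, config = scan_config(), ...) {
  if (is.null(model)) model <- fit_background(x, config)
  plot(x$starts, x$values, type = "h", col = "grey60",
       xlab = "position relative to TSS",
       ylab = "promoters per window",
       main = sprintf("%s (window %d)", x$motif, x$window_size), ...)
  lines(x$starts, predict(model, x$starts, "baseline"), lwd = 2)
  lines(x$starts, predict(model, x$starts, "upper"), lty = 2, lwd = 2)
  abline(v = 0, col = "grey40", lty = 3)
  invisible(x)
}

#' @rdname plot.plm_dist
#' @export
plot.plm_record <- function(x, ...) {
  plot.plm_dist(x$distribution, model = x$model, ...)
  abline(v = x$preferential_position, col = "red3")
  invisible(x)
}

#' Is a PLM positioned within a target region?
#'
#' The TATA-like topological constraint used by the discovery cascade and
#' the extension step: the (refined) preferential position of the PLM lies
#' inside the closed target interval. The reported functional window scales
#' with the sliding-window size, so the peak-top position is the
#' window-size-invariant summary this check relies on (see vignette).
#'
#' @param record A `plm_record` or `NULL`.
#' @param region Closed position interval (default the TATA region
#'   `c(-39, -26)`).
#' @return `TRUE`/`FALSE` (`FALSE` for `NULL`).
#' @export
plm_in_region <- function(record, region = c(-39, -26)) {
  if (is.null(record)) return(FALSE)
  p <- record$preferential_position
  p >= region[1] && p <= region[2]
}
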