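# Synthetic promoter sets, expression clouds and orthologue tables with
# planted ground truth. The generators emulate the statistical structure the
# detector assumes: i.i.d. background bases, motifs planted at a point or
# jittered over an interval near the TATA region, and an optional
# pyrimidine (TC-microsatellite) tract downstream of the TSS that produces
# the broad Y-patch-like signal able to mask upstream TC peaks.

#' Describe a motif planting for [sim_promoters()]
#'
#' @param motif Concrete motif to plant (overwrites the background at the
#'   sampled position, so alignment coordinates are preserved).
#' @param position TSS-relative first-base position: the planting point, or
#'   the mean when `sd > 0`.
#' @param fraction Fraction of the pool planted (default 1).
#' @param subset Optional integer vector of promoter indices forming the
#'   pool (defaults to all promoters).
#' @param interval Optional closed interval: with `sd = 0` the position is
#'   uniform over it; with `sd > 0` it truncates the Gaussian jitter.
#' @param sd Gaussian jitter standard deviation (0 = no Gaussian jitter).
#' @return A `plm_planting` description.
#' @export
planting <- function(motif, position, fraction = 1, subset = NULL,
                     interval = NULL, sd = 0) {
  stopifnot(fraction >= 0, fraction <= 1, sd >= 0)
  structure(list(motif = toupper(motif), position = as.integer(position),
                 fraction = fraction, subset = subset,
                 interval = if (!is.null(interval)) as.integer(interval),
                 sd = sd),
            class = "plm_planting")
}

#' Describe a downstream pyrimidine tract for [sim_promoters()]
#'
#' Tracts are repeats of short pyrimidine units (TC-microsatellites)
#' overwritten downstream of the TSS, giving the broad T/C-rich signal seen
#' around plant start sites.
#'
#' @param fraction Fraction of the pool receiving a tract (default 1).
#' @param subset Optional promoter-index pool.
#' @param units Repeat units; one is sampled per promoter (default
#'   `c("TC", "TTC")`).
#' @param n_units Closed integer range for the repeat count (default
#'   `c(8, 16)`).
#' @param start Closed TSS-relative range for the tract start (default
#'   `c(5, 60)`).
#' @return A `plm_tract` description.
#' @export
tc_tract <- function(fraction = 1, subset = NULL, units = c("TC", "TTC"),
                     n_units = c(8, 16), start = c(5, 60)) {
  stopifnot(fraction >= 0, fraction <= 1)
  structure(list(fraction = fraction, subset = subset,
                 units = toupper(units), n_units = as.integer(n_units),
                 start = as.integer(start)),
            class = "plm_tract")
}

.with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  } else on.exit(rm(".Random.seed", envir = globalenv()))
  set.seed(seed)
  expr
}

.sample_int_range <- function(n, range) {
  if (length(range) == 1L || range[1] == range[2]) rep(range[1], n)
  else sample(range[1]:range[2], n, replace = TRUE)
}

#' Generate a synthetic TSS-aligned promoter set with ground truth
#'
#' Backgrounds are i.i.d. bases from `comp`; 5'UTR lengths are fixed or
#' uniform over a range (minimum 50); plantings and the optional tract
#' overwrite the background so TSS-relative coordinates stay exact. Given
#' the same configuration and seed the output is byte-identical.
#'
#' @param n Number of promoters.
#' @param upstream Upstream extent in bases (default 1000).
#' @param utr 5'UTR length: a single value or a `c(lo, hi)` uniform range
#'   (default `c(50, 500)`).
#' @param comp Base composition, probabilities for A, C, G, T (default
#'   uniform).
#' @param plantings List of [planting()] descriptions.
#' @param tract Optional [tc_tract()] description.
#' @param seed Random seed (restores the RNG state afterwards).
#' @param species Species label.
#' @param prefix Promoter id prefix.
#' @return A list with `set` (a `promoter_set`) and `truth`: `plantings`
#'   (data.frame id / motif / position), `tract` (id / unit / start /
#'   length) and `collisions` (plantings skipped because they would
#'   overwrite an earlier one; empty when all placements succeeded).
#' @export
sim_promoters <- function(n, upstream = 1000, utr = c(50, 500),
                          comp = c(A = 0.25, C = 0.25, G = 0.25, T = 0.25),
                          plantings = list(), tract = NULL, seed = NULL,
                          species = "synthetic", prefix = "p") {
  stopifnot(n >= 1, upstream >= 1)
  if (abs(sum(comp) - 1) > 1e-8) stop("'comp' must sum to 1")
  if (min(utr) < 50) stop("5'UTR lengths below 50 are excluded by construction")
  if (inherits(plantings, "plm_planting")) plantings <- list(plantings)
  .with_seed(seed, {
    ids <- sprintf("%s%0*d", prefix, nchar(as.character(n)) + 1L, seq_len(n))
    utr_len <- .sample_int_range(n, utr)
    lens <- upstream + utr_len
    bases <- c("A", "C", "G", "T")
    all_b <- sample(bases, sum(lens), replace = TRUE, prob = comp)
    seqs <- vapply(split(all_b, rep.int(seq_len(n), lens)), paste,
                   "", collapse = "")
    names(seqs) <- NULL

    occupied <- vector("list", n)   # planted spans, for collision checks
    truth <- list(); coll <- list()
    overlaps <- function(i, from, to) {
      oc <- occupied[[i]]
      !is.null(oc) && any(oc[, 1L] <= to & oc[, 2L] >= from)
    }
    for (pl in plantings) {
      stopifnot(inherits(pl, "plm_planting"))
      k <- nchar(pl$motif)
      pool <- if (is.null(pl$subset)) seq_len(n) else pl$subset
      n_plant <- round(pl$fraction * length(pool))
      chosen <- if (n_plant >= length(pool)) pool
                else sort(sample(pool, n_plant))
      random_rule <- !is.null(pl$interval) || pl$sd > 0
      for (i in chosen) {
        placed <- FALSE
        for (try in seq_len(if (random_rule) 50L else 1L)) {
          q <- if (pl$sd > 0) {
            qq <- as.integer(round(rnorm(1, pl$position, pl$sd)))
            iv <- pl$interval %||% c(pl$position - 3L * ceiling(pl$sd),
                                     pl$position + 3L * ceiling(pl$sd))
            min(max(qq, iv[1]), iv[2])
          } else if (!is.null(pl$interval)) {
            .sample_int_range(1L, pl$interval)
          } else pl$position
          from <- q + upstream + 1L
          to <- from + k - 1L
          if (from < 1L || to > lens[i]) next      # does not fit; retry
          if (overlaps(i, from, to)) next          # collision; retry
          substr(seqs[i], from, to) <- pl$motif
          occupied[[i]] <- rbind(occupied[[i]], c(from, to))
          truth[[length(truth) + 1L]] <-
            data.frame(id = ids[i], motif = pl$motif, position = q,
                       stringsAsFactors = FALSE)
          placed <- TRUE
          break
        }
        if (!placed)
          coll[[length(coll) + 1L]] <-
            data.frame(id = ids[i], motif = pl$motif,
                       position = pl$position, stringsAsFactors = FALSE)
      }
    }

    tr_truth <- data.frame(id = character(), unit = character(),
                           start = integer(), length = integer(),
                           stringsAsFactors = FALSE)
    if (!is.null(tract)) {
      stopifnot(inherits(tract, "plm_tract"))
      pool <- if (is.null(tract$subset)) seq_len(n) else tract$subset
      n_tr <- round(tract$fraction * length(pool))
      chosen <- if (n_tr >= length(pool)) pool else sort(sample(pool, n_tr))
      for (i in chosen) {
        unit <- if (length(tract$units) == 1L) tract$units
                else sample(tract$units, 1L)
        nu <- .sample_int_range(1L, tract$n_units)
        q <- .sample_int_range(1L, tract$start)
        s <- strrep(unit, nu)
        from <- q + upstream + 1L
        to <- min(from + nchar(s) - 1L, lens[i])
        if (from > lens[i]) next
        substr(seqs[i], from, to) <- substr(s, 1L, to - from + 1L)
        tr_truth[nrow(tr_truth) + 1L, ] <-
          list(ids[i], unit, q, to - from + 1L)
      }
    }

    truth_df <- if (length(truth)) do.call(rbind, truth)
                else data.frame(id = character(), motif = character(),
                                position = integer(), stringsAsFactors = FALSE)
    coll_df <- if (length(coll)) do.call(rbind, coll)
               else data.frame(id = character(), motif = character(),
                               position = integer(), stringsAsFactors = FALSE)
    if (nrow(coll_df))
      warning(nrow(coll_df), " planting(s) could not be placed (collisions)")
    list(set = promoter_set(ids, seqs, upstream, species = species),
         truth = list(plantings = truth_df, tract = tr_truth,
                      collisions = coll_df))
  })
}

#' Generate a synthetic expression cloud
#'
#' Hybridization percentages are uniform on `[0, 100]`; intensities follow
#' a cubic polynomial of the percentage plus Gaussian noise.
#'
#' @param n Number of genes.
#' @param coef Cubic coefficients `c(b0, b1, b2, b3)`.
#' @param noise_sd Gaussian noise standard deviation.
#' @param seed Random seed.
#' @return A list with `points` (data.frame `gene_id`,
#'   `hybridization_pct`, `median_intensity`) and `truth` (generating
#'   residual and its sign per gene).
#' @export
sim_expression <- function(n, coef = c(6, 0.08, -1e-3, 8e-6),
                           noise_sd = 1, seed = NULL) {
  stopifnot(n >= 1, length(coef) == 4L, noise_sd >= 0)
  .with_seed(seed, {
    x <- runif(n, 0, 100)
    mu <- coef[1] + coef[2] * x + coef[3] * x^2 + coef[4] * x^3
    eps <- rnorm(n, 0, noise_sd)
    gene_id <- sprintf("g%0*d", nchar(as.character(n)) + 1L, seq_len(n))
    list(points = data.frame(gene_id = gene_id, hybridization_pct = x,
                             median_intensity = mu + eps,
                             stringsAsFactors = FALSE),
         truth = data.frame(gene_id = gene_id, residual = eps,
                            sign = sign(eps), stringsAsFactors = FALSE))
  })
}

#' Generate synthetic orthologue conservation counts
#'
#' Per orthologous pair, presence of a promoter-element class in species A
#' is Bernoulli(`p_a`); presence in the B orthologue is Bernoulli
#' (`p_b_given_a`) when A has it and Bernoulli(`p_b_given_not_a`) otherwise.
#'
#' @param n_pairs Number of orthologous pairs.
#' @param p_a Class prevalence in species A.
#' @param p_b_given_a,p_b_given_not_a Conditional prevalences in B.
#' @param seed Random seed.
#' @return A list with `counts` (fields `a`, `b`, `c`, `n_pairs`, directly
#'   consumable by [conservation_stats()]) and `truth` (per-pair presence).
#' @export
sim_ortholog_counts <- function(n_pairs, p_a, p_b_given_a, p_b_given_not_a,
                                seed = NULL) {
  stopifnot(n_pairs >= 1,
            all(c(p_a, p_b_given_a, p_b_given_not_a) >= 0),
            all(c(p_a, p_b_given_a, p_b_given_not_a) <= 1))
  .with_seed(seed, {
    in_a <- runif(n_pairs) < p_a
    in_b <- runif(n_pairs) < ifelse(in_a, p_b_given_a, p_b_given_not_a)
    list(counts = list(a = sum(in_a & !in_b), b = sum(!in_a & in_b),
                       c = sum(in_a & in_b), n_pairs = n_pairs),
         truth = data.frame(pair = seq_len(n_pairs), in_a = in_a,
                            in_b = in_b))
  })
}
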